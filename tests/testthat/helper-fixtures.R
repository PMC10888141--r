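# Shared fixtures, built in code at test time.

# 100 nt toy template: ETS1 spacer 0-40, 18S mature 40-80, ITS1 spacer 80-100
toy_template <- function() {
  set.seed(99)
  seq <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  rdna_template(
    "toy", seq,
    data.frame(
      name = c("ETS1", "18S", "ITS1"),
      start = c(0L, 40L, 80L), end = c(40L, 80L, 100L),
      region_class = c("spacer", "mature", "spacer")
    )
  )
}

write_toy_fasta <- function(sequence, names = "toy") {
  path <- tempfile(fileext = ".fa")
  writeLines(c(rbind(paste0(">", names), sequence)), path)
  path
}

write_toy_regions <- function(rows, chrom = "toy") {
  path <- tempfile(fileext = ".bed")
  writeLines(
    sprintf("%s\t%d\t%d\t%s", chrom, rows$start, rows$end,
            paste0(rows$name, ":", rows$region_class)),
    path
  )
  path
}

# Reduced-scale simulation for fast unit tests (acceptance tests use the
# full-scale study conditions).
small_sim <- function(seed = 5L, ...) {
  simulate_reads(sim_config(
    seed = seed, template_length = 1500L, n_motifs = 5L,
    reads_per_replicate = 5000L, ...
  ))
}

# A median_profile built directly from values, for stage-level tests.
profile_of <- function(values, condition = "ref") {
  structure(list(condition = condition, values = values),
            class = "median_profile")
}

norm_track <- function(values, sample_id = "s", condition = "ref") {
  structure(
    list(sample_id = sample_id, condition = condition,
         values = values, degenerate = all(values == 0)),
    class = "normalized_track"
  )
}

read_df <- function(start, end, strand = "+", umi = "ACGTACGT",
                    reference = "toy", read_id = NULL) {
  n <- max(length(start), length(end))
  data.frame(
    read_id = if (is.null(read_id)) sprintf("r%03d", seq_len(n)) else read_id,
    reference = rep_len(reference, n),
    start = as.integer(rep_len(start, n)), end = as.integer(rep_len(end, n)),
    strand = rep_len(strand, n), umi = rep_len(umi, n),
    stringsAsFactors = FALSE
  )
}
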