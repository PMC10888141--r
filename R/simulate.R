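#' Configuration for the synthetic NET-seq generator
#'
#' The generator emulates the statistical structure a Pol I NET-seq experiment
#' presents to the analysis: per-position 3'-end (last incorporated
#' nucleotide, LNT) counts over a ~7 kb transcription unit with a periodic
#' baseline, condition-specific pause-strength multipliers at planted
#' T-run->G-run motifs in spacer regions, multinomial sampling noise across
#' replicates, PCR duplicates resolvable by UMI, and uniform mature-rRNA
#' contamination.
#'
#' @param seed Integer RNG seed; all randomness flows from it.
#' @param template_length Template length in nt.
#' @param t_run_length,g_run_length Lengths of the planted T-run and G-run;
#'   the motif LNT is the last base of the G-run.
#' @param n_motifs Number of planted motifs.
#' @param spacer_only Plant motifs only inside spacer regions.
#' @param period,amplitude Periodic baseline: unnormalized weight
#'   `w(i) = 1 + amplitude * (1 + sin(2*pi*i/period)) / 2`, so occupancy
#'   varies `(1 + amplitude)`-fold between troughs and crests.
#' @param base_pause_boost Multiplicative weight applied at motif LNT
#'   positions in both conditions (>= 1).
#' @param condition_multiplier Additional multiplicative weight at motif LNT
#'   positions in the perturbed condition only; 1 makes the two conditions
#'   identical.
#' @param n_replicates Replicates per condition (>= 2).
#' @param reads_per_replicate Unique (pre-PCR-duplication) reads per replicate.
#' @param pcr_duplicate_rate Fraction of the final read list that are verbatim
#'   copies (same coordinates and UMI) of already-emitted reads.
#' @param contamination_fraction Fraction of reads whose 3' ends are instead
#'   uniform over mature-region positions, emulating mature-rRNA
#'   contamination.
#' @param umi_length UMI length in nt.
#' @param read_length_range Two-element integer vector, min/max read length.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       template_length = 7000L,
                       t_run_length = 4L,
                       g_run_length = 4L,
                       n_motifs = 20L,
                       spacer_only = TRUE,
                       period = 200,
                       amplitude = 9,
                       base_pause_boost = 5,
                       condition_multiplier = 5,
                       n_replicates = 3L,
                       reads_per_replicate = 2e5,
                       pcr_duplicate_rate = 0.1,
                       contamination_fraction = 0.3,
                       umi_length = 8L,
                       read_length_range = c(20L, 60L)) {
  cfg <- list(
    seed = as.integer(seed),
    template_length = as.integer(template_length),
    t_run_length = as.integer(t_run_length),
    g_run_length = as.integer(g_run_length),
    n_motifs = as.integer(n_motifs),
    spacer_only = isTRUE(spacer_only),
    period = period,
    amplitude = amplitude,
    base_pause_boost = base_pause_boost,
    condition_multiplier = condition_multiplier,
    n_replicates = as.integer(n_replicates),
    reads_per_replicate = as.integer(reads_per_replicate),
    pcr_duplicate_rate = pcr_duplicate_rate,
    contamination_fraction = contamination_fraction,
    umi_length = as.integer(umi_length),
    read_length_range = as.integer(read_length_range)
  )
  stopifnot(
    cfg$template_length >= 1L,
    cfg$n_motifs >= 0L,
    cfg$amplitude >= 0,
    cfg$period > 0,
    cfg$base_pause_boost >= 1,
    cfg$condition_multiplier >= 1,
    cfg$n_replicates >= 2L,
    cfg$reads_per_replicate >= 1L,
    cfg$pcr_duplicate_rate >= 0, cfg$pcr_duplicate_rate <= 1,
    cfg$contamination_fraction >= 0, cfg$contamination_fraction <= 1,
    cfg$umi_length >= 1L,
    length(cfg$read_length_range) == 2L,
    cfg$read_length_range[1L] >= 1L,
    cfg$read_length_range[1L] <= cfg$read_length_range[2L]
  )
  class(cfg) <- "sim_config"
  cfg
}

# Default region layout: four spacers and three mature regions tiling the
# template in the 35S order, with approximate 35S-like proportions.
.default_region_fractions <- data.frame(
  name = c("ETS1", "18S", "ITS1", "5.8S", "ITS2", "25S", "ETS2"),
  region_class = c("spacer", "mature", "spacer", "mature", "spacer", "mature", "spacer"),
  fraction = c(0.10, 0.25, 0.05, 0.03, 0.07, 0.40, 0.10),
  stringsAsFactors = FALSE
)

# Minimum spacing between planted motif LNTs, beyond the motif length itself.
.motif_separation <- 25L

#' Generate a synthetic template with planted pause motifs
#'
#' Builds a uniform-random background sequence tiled by the seven canonical
#' 35S regions, then plants `n_motifs` non-overlapping T-run->G-run motifs in
#' spacer regions with at least 25 nt separation. Any chance background
#' occurrence of the motif string is disrupted so that planted motifs are the
#' only occurrences. The motif LNT position is the last base of the G-run.
#'
#' @param config A [sim_config()].
#' @return A list with elements `template` ([rdna_template]) and `truth`
#'   (motif positions, per-condition occupancy probability vectors).
#' @export
make_template <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$template_length
  frac <- .default_region_fractions
  ends <- round(cumsum(frac$fraction) * L)
  ends[length(ends)] <- L
  starts <- c(0L, ends[-length(ends)])
  regions <- data.frame(
    name = frac$name, start = as.integer(starts), end = as.integer(ends),
    region_class = frac$region_class, stringsAsFactors = FALSE
  )
  bases <- c("A", "C", "G", "T")
  seq_chars <- sample(bases, L, replace = TRUE)

  motif <- c(rep("T", config$t_run_length), rep("G", config$g_run_length))
  mlen <- length(motif)
  motif_lnts <- integer(0)
  if (config$n_motifs > 0L) {
    keep <- if (config$spacer_only) "spacer" else c("spacer", "mature")
    cand <- regions[regions$region_class %in% keep, , drop = FALSE]
    # eligible LNT positions: motif fully inside one region
    eligible <- unlist(lapply(seq_len(nrow(cand)), function(i) {
      lo <- cand$start[i] + mlen - 1L
      hi <- cand$end[i] - 1L
      if (hi >= lo) lo:hi else integer(0)
    }))
    if (length(eligible) < config$n_motifs) {
      stop("cannot place ", config$n_motifs, " motifs: only ",
           length(eligible), " eligible positions")
    }
    min_gap <- mlen + .motif_separation
    shuffled <- sample(eligible)
    for (p in shuffled) {
      if (length(motif_lnts) == config$n_motifs) break
      if (all(abs(motif_lnts - p) >= min_gap)) {
        motif_lnts <- c(motif_lnts, p)
      }
    }
    if (length(motif_lnts) < config$n_motifs) {
      stop(
        "cannot place ", config$n_motifs, " motifs with >= ", .motif_separation,
        " nt separation in the available spacer space; reduce n_motifs or ",
        "enlarge the template"
      )
    }
    motif_lnts <- sort(motif_lnts)
    for (p in motif_lnts) {
      seq_chars[(p - mlen + 2L):(p + 1L)] <- motif
    }
    # disrupt chance background occurrences so planted motifs are the only ones
    motif_str <- paste(motif, collapse = "")
    repeat {
      s <- paste(seq_chars, collapse = "")
      hits <- gregexpr(motif_str, s, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) break
      ends_hit <- as.integer(hits) + mlen - 2L # 0-based LNT of each occurrence
      spurious <- setdiff(ends_hit, motif_lnts)
      if (length(spurious) == 0L) break
      for (p in spurious) {
        seq_chars[p - mlen + 2L] <- "C" # break the T-run; cannot seed a new match
      }
    }
  }
  template <- rdna_template("synthetic_35S", paste(seq_chars, collapse = ""), regions)
  truth <- list(motif_positions = motif_lnts)
  truth$prob <- list(
    ref = occupancy_distribution(template, truth, "ref", config),
    perturbed = occupancy_distribution(template, truth, "perturbed", config)
  )
  list(template = template, truth = truth)
}

#' Per-position 3'-end sampling distribution for one condition
#'
#' Unnormalized weight `w(i) = 1 + amplitude*(1 + sin(2*pi*i/period))/2`
#' (positions `i` 0-based), multiplied by `base_pause_boost` at motif LNT
#' positions, and additionally by `condition_multiplier` when
#' `condition = "perturbed"`. The returned vector is `w` normalized to sum 1.
#'
#' @param template An [rdna_template].
#' @param truth Truth record holding `motif_positions` (0-based LNTs).
#' @param condition `"ref"` or `"perturbed"`.
#' @param config A [sim_config()].
#' @return Probability vector over template positions (sums to 1).
#' @export
occupancy_distribution <- function(template, truth, condition = c("ref", "perturbed"),
                                   config) {
  condition <- match.arg(condition)
  stopifnot(inherits(template, "rdna_template"), inherits(config, "sim_config"))
  i <- seq_len(template$length) - 1
  w <- 1 + config$amplitude * (1 + sin(2 * pi * i / config$period)) / 2
  mp <- truth$motif_positions
  if (length(mp) > 0L) {
    w[mp + 1L] <- w[mp + 1L] * config$base_pause_boost
    if (condition == "perturbed") {
      w[mp + 1L] <- w[mp + 1L] * config$condition_multiplier
    }
  }
  w / sum(w)
}

.random_umis <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate UMI-tagged aligned NET-seq reads for two conditions
#'
#' For each replicate, 3'-end positions are drawn multinomially from the
#' condition's occupancy distribution; a `contamination_fraction` of reads
#' instead get 3' ends uniform over mature-region positions. Read starts are
#' the 3' end minus a uniform length (clipped at 0), each unique read gets a
#' random UMI, and `pcr_duplicate_rate` of the final read list are verbatim
#' copies of already-emitted reads. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `netseq_sim` object: `config`, `template`, `truth` (with
#'   per-replicate bookkeeping in `truth$replicate_stats`) and `reads`, a list
#'   `reads$ref` / `reads$perturbed` of per-replicate read `data.frame`s with
#'   columns `read_id`, `reference`, `start`, `end`, `strand`, `umi`.
#' @export
simulate_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  made <- make_template(config) # seeds the RNG with config$seed
  template <- made$template
  truth <- made$truth
  L <- template$length
  mature <- which(!spacer_mask(template)) - 1L
  if (config$contamination_fraction > 0 && length(mature) == 0L) {
    stop("contamination requested but the template has no mature regions")
  }
  lmin <- config$read_length_range[1L]
  lmax <- config$read_length_range[2L]
  n <- config$reads_per_replicate
  reads <- list()
  stats_rows <- list()
  for (cond in c("ref", "perturbed")) {
    reads[[cond]] <- vector("list", config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
      contam <- stats::runif(n) < config$contamination_fraction
      lnt <- integer(n)
      if (any(!contam)) {
        lnt[!contam] <- sample.int(L, sum(!contam), replace = TRUE,
                                   prob = truth$prob[[cond]]) - 1L
      }
      if (any(contam)) {
        lnt[contam] <- mature[sample.int(length(mature), sum(contam), replace = TRUE)]
      }
      len <- sample(lmin:lmax, n, replace = TRUE)
      start <- pmax(0L, lnt - len + 1L)
      df <- data.frame(
        read_id = sprintf("%s_rep%d_r%07d", cond, r, seq_len(n)),
        reference = template$name,
        start = start,
        end = lnt + 1L,
        strand = "+",
        umi = .random_umis(n, config$umi_length),
        stringsAsFactors = FALSE
      )
      key <- paste(df$start, df$end, df$strand, df$umi)
      n_collisions <- n - length(unique(key))
      rate <- config$pcr_duplicate_rate
      n_dup <- if (rate > 0) as.integer(round(n * rate / (1 - rate))) else 0L
      if (n_dup > 0L) {
        df <- rbind(df, df[sample.int(n, n_dup, replace = TRUE), , drop = FALSE])
      }
      df <- df[sample.int(nrow(df)), , drop = FALSE]
      rownames(df) <- NULL
      reads[[cond]][[r]] <- df
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        condition = cond, replicate = r, n_unique = n,
        n_contaminant = sum(contam), n_duplicates = n_dup,
        n_umi_collisions = n_collisions, stringsAsFactors = FALSE
      )
    }
  }
  truth$replicate_stats <- do.call(rbind, stats_rows)
  structure(
    list(config = config, template = template, truth = truth, reads = reads),
    class = "netseq_sim"
  )
}

#' @export
print.netseq_sim <- function(x, ...) {
  cat(
    "netseq_sim: template ", x$template$length, " nt, ",
    length(x$truth$motif_positions), " planted motifs, ",
    x$config$n_replicates, " replicates x 2 conditions, ",
    x$config$reads_per_replicate, " reads/replicate\n", sep = ""
  )
  invisible(x)
}

#' Write a simulation to disk as analysis-ready files
#'
#' Emits the template FASTA, the region BED4 (`NAME:CLASS` names), one BED6
#' per replicate with the UMI appended to the name field as `READID#UMI`, a
#' truth TSV of planted motif positions, and a sample sheet TSV suitable for
#' [pipeline_config()].
#'
#' @param sim A `netseq_sim` from [simulate_reads()].
#' @param dir Output directory (created if needed).
#' @param umi_delim Delimiter between read id and UMI in the BED name field.
#' @return Invisibly, a named list of the written file paths.
#' @export
write_simulation <- function(sim, dir, umi_delim = "#") {
  stopifnot(inherits(sim, "netseq_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tpl <- sim$template
  fasta <- file.path(dir, "template.fa")
  seqs <- Biostrings::DNAStringSet(stats::setNames(tpl$sequence, tpl$name))
  Biostrings::writeXStringSet(seqs, fasta)
  regions <- file.path(dir, "regions.bed")
  write_regions_bed(tpl, regions)
  samples <- list()
  for (cond in names(sim$reads)) {
    for (r in seq_along(sim$reads[[cond]])) {
      sample_id <- sprintf("%s_rep%d", cond, r)
      path <- file.path(dir, paste0(sample_id, ".bed"))
      write_reads_bed(sim$reads[[cond]][[r]], path, umi_delim = umi_delim)
      samples[[length(samples) + 1L]] <- data.frame(
        sample_id = sample_id, condition = cond, replicate = r,
        path = path, stringsAsFactors = FALSE
      )
    }
  }
  sheet <- do.call(rbind, samples)
  sheet_path <- file.path(dir, "samples.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(
    data.frame(motif_lnt = sim$truth$motif_positions),
    truth_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(list(
    fasta = fasta, regions = regions, sample_sheet = sheet_path,
    truth = truth_path, reads = sheet$path
  ))
}
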