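#' Remove PCR duplicates by UMI and alignment coordinates
#'
#' Molecular identity is the key `(start, end, strand, umi)`: verbatim PCR
#' copies collapse to one read, while distinct molecules that happen to share
#' coordinates but differ in UMI survive. Retention is first-seen in input
#' order. The key deliberately includes the coordinates, not the UMI alone,
#' so that distinct positions sharing a UMI are never collapsed.
#'
#' @param reads Read `data.frame` (see [read_reads_bed()]).
#' @return A list with `reads` (the retained rows) and `n_removed`.
#' @export
deduplicate_umis <- function(reads) {
  if (nrow(reads) == 0L) {
    return(list(reads = reads, n_removed = 0L))
  }
  if (length(unique(reads$reference)) > 1L) {
    stop("reads map to more than one reference; deduplicate per reference")
  }
  key <- paste(reads$start, reads$end, reads$strand, reads$umi)
  keep <- !duplicated(key)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out, n_removed = as.integer(sum(!keep)))
}

#' Last-incorporated-nucleotide position of a read
#'
#' In NET-seq the aligned read's 3' end marks the nascent RNA's last
#' incorporated nucleotide and hence the polymerase active site. On the
#' transcription (+) strand this is `end - 1` (0-based). Reads on the
#' opposite strand are not valid input here; at the pipeline level they are
#' filtered with a logged count instead.
#'
#' @param reads Read `data.frame`; all rows must be `'+'` strand.
#' @return Integer vector of 0-based LNT positions.
#' @export
lnt_position <- function(reads) {
  if (any(reads$strand != "+")) {
    stop("lnt_position is defined for '+' strand reads only")
  }
  reads$end - 1L
}

#' Per-position LNT count track
#'
#' Counts deduplicated reads by LNT position. Opposite-strand reads and reads
#' whose LNT falls outside the template are dropped, with counts recorded in
#' the track's `dropped` field (not fatal, so real mixed BED files pass
#' through).
#'
#' @param reads Deduplicated read `data.frame`.
#' @param template An [rdna_template].
#' @param sample_id,condition Labels attached to the track.
#' @return An `occupancy_track`: `sample_id`, `condition`, `counts` (integer
#'   per template position), `n_reads` (retained), and `dropped` counts.
#' @export
raw_occupancy <- function(reads, template, sample_id, condition) {
  stopifnot(inherits(template, "rdna_template"))
  L <- template$length
  wrong_strand <- reads$strand != "+"
  lnt <- reads$end - 1L
  oob <- !wrong_strand & (lnt < 0L | lnt >= L)
  keep <- !wrong_strand & !oob
  counts <- tabulate(lnt[keep] + 1L, nbins = L)
  structure(
    list(
      sample_id = sample_id, condition = condition,
      counts = as.integer(counts), n_reads = as.integer(sum(keep)),
      dropped = list(
        wrong_strand = as.integer(sum(wrong_strand)),
        out_of_bounds = as.integer(sum(oob))
      )
    ),
    class = "occupancy_track"
  )
}

#' @export
print.occupancy_track <- function(x, ...) {
  cat(
    "occupancy_track '", x$sample_id, "' (", x$condition, "): ",
    x$n_reads, " reads over ", length(x$counts), " positions; dropped ",
    x$dropped$wrong_strand, " wrong-strand, ",
    x$dropped$out_of_bounds, " out-of-bounds\n", sep = ""
  )
  invisible(x)
}
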