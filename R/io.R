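#' Read aligned NET-seq reads from BED6
#'
#' The BED name field carries the UMI as `READID<delim>UMI` (default
#' `READID#UMI`). Coordinates are returned 0-based, half-open.
#'
#' @param path BED6 file path.
#' @param umi_delim Delimiter separating read id and UMI in the name field.
#' @return `data.frame` with columns `read_id`, `reference`, `start`, `end`,
#'   `strand`, `umi`.
#' @export
read_reads_bed <- function(path, umi_delim = "#") {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm) || anyNA(nm)) {
    stop("BED name field is required (READID", umi_delim, "UMI)")
  }
  has_umi <- grepl(umi_delim, nm, fixed = TRUE)
  if (!all(has_umi)) {
    stop(
      "malformed name field at line ", which(!has_umi)[1L],
      ": expected 'READID", umi_delim, "UMI'"
    )
  }
  parts <- strsplit(nm, umi_delim, fixed = TRUE)
  umi <- vapply(parts, function(p) p[length(p)], character(1))
  read_id <- vapply(parts, function(p) paste(p[-length(p)], collapse = umi_delim),
                    character(1))
  if (length(unique(nchar(umi))) > 1L) {
    stop("UMI length is not constant within the file")
  }
  if (any(grepl("[^ACGT]", umi))) {
    stop("UMIs must be strings over A/C/G/T")
  }
  data.frame(
    read_id = read_id,
    reference = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    umi = umi,
    stringsAsFactors = FALSE
  )
}

#' Write aligned reads to BED6
#'
#' @param reads Read `data.frame` as from [read_reads_bed()] or
#'   [simulate_reads()].
#' @param path Output path.
#' @param umi_delim Delimiter for the `READID<delim>UMI` name field.
#' @return Invisibly, `path`.
#' @export
write_reads_bed <- function(reads, path, umi_delim = "#") {
  gr <- GenomicRanges::GRanges(
    seqnames = reads$reference,
    ranges = IRanges::IRanges(start = reads$start + 1L, end = reads$end),
    strand = reads$strand
  )
  gr$name <- paste0(reads$read_id, umi_delim, reads$umi)
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a template's region annotation to BED4
#'
#' The name column is written as `NAME:CLASS`, the format [load_template()]
#' reads back.
#'
#' @param template An [rdna_template].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_regions_bed <- function(template, path) {
  rg <- template$regions
  gr <- GenomicRanges::GRanges(
    seqnames = template$name,
    ranges = IRanges::IRanges(start = rg$start + 1L, end = rg$end)
  )
  gr$name <- paste0(rg$name, ":", rg$region_class)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a per-position signal as bedGraph
#'
#' Emits 0-based, half-open records, one line per maximal run of equal
#' nonzero values; zero runs are omitted.
#'
#' @param values Numeric vector over template positions.
#' @param template An [rdna_template] (provides the sequence name and length).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(values, template, path) {
  stopifnot(inherits(template, "rdna_template"))
  if (length(values) != template$length) {
    stop("values length does not match template length")
  }
  r <- rle(as.numeric(values))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  df <- data.frame(
    chrom = template$name, start = starts[keep], end = ends[keep],
    value = vapply(r$values[keep], format, character(1),
                   digits = 15, scientific = FALSE, trim = TRUE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a data frame as TSV
#'
#' Plain tab-separated output with a header and no quoting or row names;
#' used for all pipeline report tables.
#'
#' @param df A `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
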