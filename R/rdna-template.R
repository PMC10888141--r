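#' Construct an rDNA transcription-unit template
#'
#' The template is the coordinate frame for the whole pipeline: a single
#' transcription unit stored 5'->3' in the direction of transcription, with a
#' set of named, non-overlapping regions each classed as `spacer` (transcribed
#' but excised, e.g. ETS1/ITS1/ITS2/ETS2) or `mature` (retained in the mature
#' rRNA, e.g. 18S/5.8S/25S). All coordinates are 0-based, half-open, matching
#' BED conventions.
#'
#' @param name Reference identifier (single string).
#' @param sequence Uppercase DNA string over `{A,C,G,T}`.
#' @param regions A `data.frame` with columns `name`, `start` (0-based
#'   inclusive), `end` (0-based exclusive) and `region_class`
#'   (`"spacer"` or `"mature"`).
#' @param allow_gaps If `FALSE` (default), the regions must tile the template
#'   contiguously from position 0 to its length.
#'
#' @return An object of class `rdna_template` with fields `name`, `sequence`,
#'   `length` and `regions`.
#' @export
rdna_template <- function(name, sequence, regions, allow_gaps = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 1L) {
    stop("template sequence must have length >= 1")
  }
  bad <- gsub("[ACGT]", "", sequence)
  if (nchar(bad) > 0L) {
    stop(
      "template sequence contains characters other than A/C/G/T ",
      "(found '", substr(bad, 1L, 1L), "'); ambiguity codes such as N are not supported"
    )
  }
  regions <- validate_regions(regions, L, allow_gaps = allow_gaps)
  structure(
    list(name = name, sequence = sequence, length = L, regions = regions),
    class = "rdna_template"
  )
}

# Canonical 35S region names carry a fixed class; user-defined names may take
# either class.
.canonical_class <- c(
  ETS1 = "spacer", `18S` = "mature", ITS1 = "spacer", `5.8S` = "mature",
  ITS2 = "spacer", `25S` = "mature", ETS2 = "spacer"
)

validate_regions <- function(regions, template_length, allow_gaps = FALSE) {
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  required <- c("name", "start", "end", "region_class")
  missing <- setdiff(required, names(regions))
  if (length(missing) > 0L) {
    stop("regions table lacks column(s): ", paste(missing, collapse = ", "))
  }
  regions <- regions[required]
  if (nrow(regions) == 0L) {
    stop("at least one region is required")
  }
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  if (!all(regions$region_class %in% c("spacer", "mature"))) {
    stop("region_class must be 'spacer' or 'mature'")
  }
  known <- regions$name %in% names(.canonical_class)
  wrong <- known & regions$region_class != .canonical_class[regions$name]
  if (any(wrong)) {
    stop(
      "region(s) ", paste(regions$name[wrong], collapse = ", "),
      " carry the wrong class (ETS/ITS are spacer; 18S/5.8S/25S are mature)"
    )
  }
  if (any(regions$start < 0L) || any(regions$end > template_length)) {
    stop("region coordinates fall outside the template (length ", template_length, ")")
  }
  if (any(regions$start >= regions$end)) {
    stop("region start must be < end (0-based, half-open)")
  }
  regions <- regions[order(regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  if (nrow(regions) > 1L) {
    if (any(regions$start[-1L] < regions$end[-nrow(regions)])) {
      stop("regions overlap")
    }
  }
  if (!allow_gaps) {
    covered <- c(regions$start[1L] == 0L,
                 regions$start[-1L] == regions$end[-nrow(regions)],
                 regions$end[nrow(regions)] == template_length)
    if (!all(covered)) {
      stop("regions do not tile the template contiguously (use allow_gaps = TRUE to permit gaps)")
    }
  }
  regions
}

#' Load a template from FASTA and BED region annotation
#'
#' Reads a single-record FASTA and a BED4 region file whose name column is
#' `"NAME:CLASS"` (e.g. `"ETS1:spacer"`, `"18S:mature"`). Lowercase bases are
#' uppercased on read.
#'
#' @param fasta_path Path to a FASTA file with exactly one record.
#' @param regions_path Path to a BED file; column 4 must be `"NAME:CLASS"`.
#' @param allow_gaps Permit uncovered template positions between regions.
#'
#' @return An [rdna_template] object.
#' @export
load_template <- function(fasta_path, regions_path, allow_gaps = FALSE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) {
    stop("ambiguous reference: FASTA must contain exactly one record, found ", length(seqs))
  }
  name <- sub("\\s.*$", "", names(seqs)[1L])
  sequence <- as.character(seqs[[1L]])
  gr <- rtracklayer::import(regions_path, format = "BED")
  if (length(gr) == 0L) {
    stop("region file contains no records")
  }
  nm <- gr$name
  if (is.null(nm) || anyNA(nm) || !all(grepl(":", nm, fixed = TRUE))) {
    stop("region BED name column must be 'NAME:CLASS' (e.g. 'ETS1:spacer')")
  }
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (!all(chrom == chrom[1L])) {
    stop("region file references more than one sequence")
  }
  regions <- data.frame(
    name = sub(":[^:]*$", "", nm),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    region_class = sub("^.*:", "", nm),
    stringsAsFactors = FALSE
  )
  rdna_template(name, sequence, regions, allow_gaps = allow_gaps)
}

#' Logical mask of spacer positions
#'
#' @param template An [rdna_template].
#' @return Logical vector of template length, `TRUE` exactly at positions
#'   inside spacer-class regions.
#' @export
spacer_mask <- function(template) {
  stopifnot(inherits(template, "rdna_template"))
  mask <- logical(template$length)
  sp <- template$regions[template$regions$region_class == "spacer", , drop = FALSE]
  for (i in seq_len(nrow(sp))) {
    mask[(sp$start[i] + 1L):sp$end[i]] <- TRUE
  }
  mask
}

#' Look up a region by name
#'
#' @param template An [rdna_template].
#' @param name Region name, e.g. `"ITS1"`.
#' @return A one-row region record (list with `name`, `start`, `end`,
#'   `region_class`).
#' @export
get_region <- function(template, name) {
  stopifnot(inherits(template, "rdna_template"))
  i <- match(name, template$regions$name)
  if (is.na(i)) {
    stop("no region named '", name, "'")
  }
  as.list(template$regions[i, , drop = FALSE])
}

#' Slice a per-position vector to a region
#'
#' @param values Numeric (or logical) vector of template length.
#' @param region A region record as returned by [get_region()] or a row of
#'   `template$regions`.
#' @return `values[start:end)` in template order.
#' @export
slice_region <- function(values, region) {
  region <- as.list(region)
  span <- region$end - region$start
  if (region$start < 0L || span < 1L) {
    stop("invalid region coordinates")
  }
  if (region$end > length(values)) {
    stop(
      "vector length (", length(values), ") does not cover region '",
      region$name, "' ending at ", region$end
    )
  }
  values[(region$start + 1L):region$end]
}

#' @export
print.rdna_template <- function(x, ...) {
  n_spacer <- sum(x$regions$region_class == "spacer")
  cat(
    "rdna_template '", x$name, "': ", x$length, " nt, ",
    nrow(x$regions), " regions (", n_spacer, " spacer)\n", sep = ""
  )
  print(x$regions)
  invisible(x)
}
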