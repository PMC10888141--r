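#' Library-normalize an occupancy track
#'
#' Divides the count at each position by the total count for the sample, so
#' values sum to 1. The default universe for the total is the analyzed
#' template; see the methods vignette for the rationale. An all-zero track is
#' returned as all zeros with `degenerate = TRUE`.
#'
#' @param track An `occupancy_track` from [raw_occupancy()].
#' @return A `normalized_track`: `sample_id`, `condition`, `values`,
#'   `degenerate`.
#' @export
normalize_track <- function(track) {
  stopifnot(inherits(track, "occupancy_track"))
  total <- sum(track$counts)
  degenerate <- total == 0L
  values <- if (degenerate) numeric(length(track$counts)) else track$counts / total
  structure(
    list(
      sample_id = track$sample_id, condition = track$condition,
      values = values, degenerate = degenerate
    ),
    class = "normalized_track"
  )
}

#' Position-wise median across replicate tracks
#'
#' For an even number of replicates, each position's value is the mean of the
#' two central order statistics.
#'
#' @param tracks List of >= 2 `normalized_track`s of one condition.
#' @return A `median_profile`: `condition`, `values`.
#' @export
median_profile <- function(tracks) {
  stopifnot(length(tracks) >= 2L)
  lens <- vapply(tracks, function(t) length(t$values), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("tracks differ in length")
  }
  conds <- unique(vapply(tracks, function(t) t$condition, character(1)))
  if (length(conds) != 1L) {
    stop("tracks mix conditions: ", paste(conds, collapse = ", "))
  }
  m <- matrix(unlist(lapply(tracks, function(t) t$values)), nrow = lens[1L])
  structure(
    list(condition = conds, values = apply(m, 1L, stats::median)),
    class = "median_profile"
  )
}

#' Centered moving average with shrinking edges
#'
#' Boxcar mean over a centered window. Where the full window does not fit
#' (near the edges), the mean of the available positions is used, so the
#' output has the input's length. For even windows the center is offset:
#' `floor((window-1)/2)` positions to the left, `floor(window/2)` to the
#' right.
#'
#' @param values Numeric vector.
#' @param window Window size in positions (>= 1, <= `length(values)`).
#' @return Numeric vector of `length(values)`.
#' @export
moving_average <- function(values, window) {
  n <- length(values)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (window > n) stop("window (", window, ") exceeds vector length (", n, ")")
  left <- (window - 1L) %/% 2L
  right <- window %/% 2L
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  s <- cumsum(c(0, values))
  (s[hi + 1L] - s[lo]) / (hi - lo + 1L)
}

#' Per-position report table
#'
#' Mirrors the per-position data frame the pipeline is organized around:
#' 1-based position, region name and class, each replicate's normalized
#' occupancy, and the per-condition medians. Internally everything is
#' 0-based; this human-readable table is the one place positions are emitted
#' 1-based inclusive.
#'
#' @param template An [rdna_template].
#' @param tracks List of `normalized_track`s (both conditions).
#' @param profiles Named list of `median_profile`s, one per condition.
#' @return A `data.frame` with one row per template position.
#' @export
positions_table <- function(template, tracks, profiles) {
  L <- template$length
  region_of <- rep(NA_character_, L)
  class_of <- rep(NA_character_, L)
  rg <- template$regions
  for (i in seq_len(nrow(rg))) {
    idx <- (rg$start[i] + 1L):rg$end[i]
    region_of[idx] <- rg$name[i]
    class_of[idx] <- rg$region_class[i]
  }
  out <- data.frame(
    position = seq_len(L), region = region_of, region_class = class_of,
    stringsAsFactors = FALSE
  )
  for (t in tracks) {
    out[[t$sample_id]] <- t$values
  }
  for (cond in names(profiles)) {
    out[[paste0("median_", cond)]] <- profiles[[cond]]$values
  }
  out
}
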