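#' Call top-quantile pause positions in spacer regions
#'
#' Restricts to spacer positions with nonzero median occupancy (zeros carry
#' no occupancy evidence and would dilute the quantile), ranks by median
#' descending with ties broken by ascending coordinate, and selects the first
#' `ceiling(q * n_eligible)` positions.
#'
#' @param profile A `median_profile` for one condition.
#' @param template An [rdna_template].
#' @param q Top fraction to call (default 0.025, the top 2.5%).
#' @return A `pause_set`: `condition`, `q`, `positions` (sorted 0-based),
#'   `threshold_value` (smallest selected median), `n_eligible`.
#' @export
call_pauses <- function(profile, template, q = 0.025) {
  stopifnot(inherits(profile, "median_profile"), inherits(template, "rdna_template"))
  if (!(q > 0 && q < 1)) stop("q must be in (0, 1)")
  if (length(profile$values) != template$length) {
    stop("profile length does not match template length")
  }
  mask <- spacer_mask(template)
  eligible <- which(mask & profile$values > 0) # 1-based indices
  if (length(eligible) == 0L) {
    stop("no eligible positions: no spacer position has nonzero median occupancy")
  }
  n_sel <- ceiling(q * length(eligible))
  ord <- order(-profile$values[eligible], eligible)
  sel <- eligible[ord[seq_len(n_sel)]]
  structure(
    list(
      condition = profile$condition, q = q,
      positions = sort(sel) - 1L,
      threshold_value = min(profile$values[sel]),
      n_eligible = length(eligible)
    ),
    class = "pause_set"
  )
}

#' @export
print.pause_set <- function(x, ...) {
  cat(
    "pause_set (", x$condition, "): top ", format(100 * x$q), "% of ",
    x$n_eligible, " eligible spacer positions = ", length(x$positions),
    " pauses; threshold ", format(x$threshold_value, digits = 4), "\n", sep = ""
  )
  invisible(x)
}

#' Extract LNT-centered sequence contexts around pause positions
#'
#' For each pause position `p`, the sense-strand window
#' `[p - (W-1)/2, p + (W-1)/2]`. Windows extending past either template end
#' are dropped and counted.
#'
#' @param pauses A `pause_set`.
#' @param template An [rdna_template].
#' @param W Odd window width >= 3 (default 21, i.e. LNT +/- 10 nt).
#' @return List with `sequences` (character vector of width-`W` windows),
#'   `n_dropped`, and `center` (1-based index of the LNT within each window).
#' @export
extract_contexts <- function(pauses, template, W = 21L) {
  stopifnot(inherits(pauses, "pause_set"), inherits(template, "rdna_template"))
  W <- as.integer(W)
  if (W < 3L || W %% 2L == 0L) stop("W must be odd and >= 3")
  h <- (W - 1L) %/% 2L
  p <- pauses$positions
  ok <- p - h >= 0L & p + h <= template$length - 1L
  seqs <- substring(template$sequence, p[ok] - h + 1L, p[ok] + h + 1L)
  list(sequences = seqs, n_dropped = as.integer(sum(!ok)), center = h + 1L)
}

.bases <- c("A", "C", "G", "T")

#' Base-frequency matrix of aligned sequence contexts
#'
#' Column frequencies are `(count_b + pseudocount) / (n + 4 * pseudocount)`;
#' the pseudocount guards against zero columns on small pause sets.
#'
#' @param contexts Character vector of equal-length sequences, or the list
#'   returned by [extract_contexts()].
#' @param pseudocount Per-cell additive count (default 0.5).
#' @param condition Optional label carried on the result.
#' @return A `context_pwm`: `condition`, `width`, `matrix` (4 rows A/C/G/T x
#'   width columns, each column summing to 1), `pseudocount`, `n_contexts`.
#' @export
build_pwm <- function(contexts, pseudocount = 0.5, condition = NA_character_) {
  if (is.list(contexts) && !is.null(contexts$sequences)) {
    contexts <- contexts$sequences
  }
  n <- length(contexts)
  if (n == 0L) stop("no contexts to build a PWM from")
  widths <- unique(nchar(contexts))
  if (length(widths) != 1L) stop("contexts differ in length")
  W <- widths
  chars <- matrix(unlist(strsplit(contexts, "", fixed = TRUE)), nrow = n, byrow = TRUE)
  counts <- vapply(seq_len(W), function(j) {
    tabulate(match(chars[, j], .bases), nbins = 4L)
  }, integer(4L))
  freq <- (counts + pseudocount) / (n + 4 * pseudocount)
  dimnames(freq) <- list(.bases, NULL)
  structure(
    list(condition = condition, width = W, matrix = freq,
         pseudocount = pseudocount, n_contexts = n),
    class = "context_pwm"
  )
}

.shannon_bits <- function(p) {
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Jensen-Shannon difference logo between two context PWMs
#'
#' Per column, with `p` the perturbed and `r` the reference base frequencies
#' and `m = (p + r) / 2`, the stack height is the Jensen-Shannon divergence
#' in bits, `JSD = H(m) - (H(p) + H(r)) / 2`, bounded by \[0, 1\] for two
#' distributions over four letters. Per-base signed heights partition the
#' JSD in proportion to the absolute frequency differences:
#' `height_b = sign(p_b - r_b) * JSD * |p_b - r_b| / sum_b' |p_b' - r_b'|`,
#' so a positive height means enrichment in the perturbed condition and
#' `sum_b |height_b| = JSD` at every column.
#'
#' @param pwm_perturbed,pwm_ref `context_pwm`s of equal width.
#' @return A `difflogo_result`: `width`, `offsets` (column offsets relative
#'   to the LNT at 0), `jsd` (bits per column), `heights` (4 x width signed
#'   matrix, rows A/C/G/T).
#' @export
difflogo <- function(pwm_perturbed, pwm_ref) {
  stopifnot(inherits(pwm_perturbed, "context_pwm"), inherits(pwm_ref, "context_pwm"))
  if (pwm_perturbed$width != pwm_ref$width) {
    stop("PWM widths differ (", pwm_perturbed$width, " vs ", pwm_ref$width, ")")
  }
  W <- pwm_perturbed$width
  P <- pwm_perturbed$matrix
  R <- pwm_ref$matrix
  M <- (P + R) / 2
  jsd <- vapply(seq_len(W), function(j) {
    v <- .shannon_bits(M[, j]) - (.shannon_bits(P[, j]) + .shannon_bits(R[, j])) / 2
    max(0, v) # clamp tiny negative rounding error
  }, numeric(1))
  d <- P - R
  heights <- matrix(0, nrow = 4L, ncol = W, dimnames = list(.bases, NULL))
  for (j in seq_len(W)) {
    tot <- sum(abs(d[, j]))
    if (jsd[j] > 0 && tot > 0) {
      heights[, j] <- sign(d[, j]) * jsd[j] * abs(d[, j]) / tot
    }
  }
  h <- (W - 1L) %/% 2L
  structure(
    list(width = W, offsets = seq_len(W) - 1L - h, jsd = jsd, heights = heights),
    class = "difflogo_result"
  )
}

#' @export
print.difflogo_result <- function(x, ...) {
  cat(
    "difflogo_result: width ", x$width, ", center JSD ",
    format(x$jsd[(x$width + 1L) %/% 2L], digits = 4), " bits, max JSD ",
    format(max(x$jsd), digits = 4), " bits\n", sep = ""
  )
  invisible(x)
}

#' Tabulate a difference logo
#'
#' @param logo A `difflogo_result`.
#' @return `data.frame` with `offset` (relative to the LNT at 0), `jsd`, and
#'   signed heights `height_A` .. `height_T`.
#' @export
difflogo_table <- function(logo) {
  stopifnot(inherits(logo, "difflogo_result"))
  out <- data.frame(offset = logo$offsets, jsd = logo$jsd)
  for (b in .bases) {
    out[[paste0("height_", b)]] <- logo$heights[b, ]
  }
  out
}
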