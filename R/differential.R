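.track_matrix <- function(tracks) {
  lens <- vapply(tracks, function(t) length(t$values), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("tracks differ in length")
  }
  m <- matrix(unlist(lapply(tracks, function(t) t$values)), nrow = lens[1L])
  colnames(m) <- vapply(tracks, function(t) t$sample_id, character(1))
  m
}

#' Replicate Spearman correlation matrix
#'
#' Rank correlation between all pairs of normalized tracks, with ties sharing
#' the mean rank. A constant track has zero rank variance, so its
#' correlations are undefined and reported as `NA` with a warning.
#'
#' @param tracks List of >= 2 `normalized_track`s.
#' @return Symmetric matrix of Spearman rho, dimnames = sample ids.
#' @export
spearman_matrix <- function(tracks) {
  stopifnot(length(tracks) >= 2L)
  m <- .track_matrix(tracks)
  const <- apply(m, 2L, function(x) stats::var(x) == 0)
  if (any(const)) {
    warning(
      "constant track(s) ", paste(colnames(m)[const], collapse = ", "),
      ": Spearman rho undefined, reported as NA"
    )
  }
  suppressWarnings(stats::cor(m, method = "spearman"))
}

#' Sample PCA on normalized occupancy tracks
#'
#' Samples are observations and template positions are features; features are
#' centered but not scaled, and components come from the singular value
#' decomposition (`stats::prcomp`).
#'
#' @param tracks List of >= 3 `normalized_track`s.
#' @param n_components Number of PCs to return coordinates for (default 2).
#' @return List with `coordinates` (`data.frame`: sample_id, condition, PC1,
#'   PC2, ...), `var_explained` (fraction per returned PC) and a `degenerate`
#'   flag (all samples identical: all fractions 0).
#' @export
pca_samples <- function(tracks, n_components = 2L) {
  if (length(tracks) < 3L) {
    stop("PCA requires at least 3 samples")
  }
  m <- t(.track_matrix(tracks)) # samples x positions
  pr <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  total_var <- sum(pr$sdev^2)
  degenerate <- total_var <= 0 || !is.finite(total_var)
  k <- min(n_components, ncol(pr$x))
  frac <- if (degenerate) rep(0, k) else (pr$sdev^2 / total_var)[seq_len(k)]
  coords <- as.data.frame(pr$x[, seq_len(k), drop = FALSE])
  coords <- cbind(
    data.frame(
      sample_id = vapply(tracks, function(t) t$sample_id, character(1)),
      condition = vapply(tracks, function(t) t$condition, character(1)),
      stringsAsFactors = FALSE
    ),
    coords
  )
  rownames(coords) <- NULL
  list(coordinates = coords, var_explained = frac, degenerate = degenerate)
}

#' Position-wise two-sample t-test between conditions
#'
#' At every template position, a two-sided pooled-variance (Student's)
#' two-sample t-test on the replicate normalized values, with
#' `df = n1 + n2 - 2`; Welch's unequal-variance form is available via
#' `var_equal = FALSE`. The t statistic is oriented as
#' `(reference mean - perturbed mean) / SE`; the `direction` call is by the
#' sign of the perturbed-minus-reference difference when `p < alpha`
#' (`up` = perturbed mean greater). Positions where both groups have zero
#' variance get `p = 1` if the means are equal and `p = 0` otherwise, with a
#' degeneracy flag; positions that are all-zero in both conditions are
#' additionally marked untestable (they carry no occupancy evidence).
#'
#' No multiple-testing correction is applied by default (per-position raw
#' p < alpha is reported); `adjust = "BH"` applies Benjamini-Hochberg to the
#' direction calls as an extension.
#'
#' @param ref_tracks,pert_tracks Lists of >= 2 `normalized_track`s per
#'   condition, equal template length.
#' @param alpha Significance threshold for direction calls (default 0.05).
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return List with `tests` (`data.frame`: `position` 0-based, `mean_ref`,
#'   `mean_pert`, `t_stat`, `p_value`, `direction`, `degenerate`, `testable`)
#'   and `track`, a `significance_track` (`alpha`, per-position `calls` in
#'   `up`/`down`/`none`).
#' @export
per_position_ttest <- function(ref_tracks, pert_tracks, alpha = 0.05,
                               var_equal = TRUE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (length(ref_tracks) < 2L || length(pert_tracks) < 2L) {
    stop("each condition needs at least 2 replicates")
  }
  R <- .track_matrix(ref_tracks)
  P <- .track_matrix(pert_tracks)
  if (nrow(R) != nrow(P)) {
    stop("conditions differ in template length")
  }
  n1 <- ncol(R); n2 <- ncol(P)
  m1 <- rowMeans(R); m2 <- rowMeans(P)
  v1 <- rowSums((R - m1)^2) / (n1 - 1)
  v2 <- rowSums((P - m2)^2) / (n2 - 1)
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t_stat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  degenerate <- se == 0
  equal_means <- m1 == m2
  p[degenerate & equal_means] <- 1
  p[degenerate & !equal_means] <- 0
  t_stat[degenerate & equal_means] <- 0
  t_stat[degenerate & !equal_means] <-
    ifelse(m1[degenerate & !equal_means] > m2[degenerate & !equal_means], Inf, -Inf)
  testable <- !(rowSums(R) == 0 & rowSums(P) == 0)
  p_call <- if (adjust == "BH") stats::p.adjust(p, method = "BH") else p
  direction <- rep("none", length(p))
  sig <- p_call < alpha & !equal_means
  direction[sig & m2 > m1] <- "up"
  direction[sig & m2 < m1] <- "down"
  tests <- data.frame(
    position = seq_along(p) - 1L,
    mean_ref = m1, mean_pert = m2,
    t_stat = t_stat, p_value = p,
    direction = direction, degenerate = degenerate, testable = testable,
    stringsAsFactors = FALSE
  )
  track <- structure(list(alpha = alpha, calls = direction),
                     class = "significance_track")
  list(tests = tests, track = track)
}

#' Two-sample Kolmogorov-Smirnov test on a region's occupancy values
#'
#' Compares the distributions of per-position median occupancy values of the
#' two conditions within one region: each condition contributes
#' `region length` observations, `D` is the supremum of the ECDF difference,
#' and the p-value comes from the asymptotic Kolmogorov distribution with the
#' standard two-sample effective n (`stats::ks.test`, `exact = FALSE`).
#'
#' @param ref_profile,pert_profile `median_profile`s of the two conditions.
#' @param region A region record ([get_region()]) of length >= 2.
#' @return List with `region`, `D`, `p_value`.
#' @export
ks_region_test <- function(ref_profile, pert_profile, region) {
  region <- as.list(region)
  if (region$end - region$start < 2L) {
    stop("region '", region$name, "' has fewer than 2 positions")
  }
  x <- slice_region(ref_profile$values, region)
  y <- slice_region(pert_profile$values, region)
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(region = region$name, D = unname(res$statistic),
       p_value = min(1, unname(res$p.value)))
}

#' KS tests across all spacer regions
#'
#' @param ref_profile,pert_profile `median_profile`s of the two conditions.
#' @param template An [rdna_template].
#' @return `data.frame` with one row per spacer region: `region`, `D`,
#'   `p_value`.
#' @export
spacer_ks_tests <- function(ref_profile, pert_profile, template) {
  sp <- template$regions[template$regions$region_class == "spacer", , drop = FALSE]
  rows <- lapply(seq_len(nrow(sp)), function(i) {
    res <- ks_region_test(ref_profile, pert_profile, sp[i, , drop = FALSE])
    data.frame(region = res$region, D = res$D, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
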