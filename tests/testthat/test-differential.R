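test_that("spearman_matrix handles ties by mean rank and monotone invariance", {
  t_self <- norm_track(c(0.1, 0.2, 0.3, 0.4), "a")
  sm <- spearman_matrix(list(t_self, norm_track(c(0.1, 0.2, 0.3, 0.4), "b")))
  expect_equal(unname(sm["a", "a"]), 1)
  expect_equal(unname(sm["a", "b"]), 1)

  # perfect anti-monotone pair
  sm2 <- spearman_matrix(list(norm_track(c(1, 2, 3, 4) / 10, "x"),
                              norm_track(c(4, 3, 2, 1) / 10, "y")))
  expect_equal(unname(sm2["x", "y"]), -1)

  # tied pair shares rank 2.5: rho = sqrt(0.9)
  sm3 <- spearman_matrix(list(norm_track(c(1, 2, 2, 3) / 8, "x"),
                              norm_track(c(1, 2, 3, 4) / 10, "y")))
  expect_equal(unname(sm3["x", "y"]), 0.9486832981, tolerance = 1e-9)

  # invariance under a strictly monotone transform
  set.seed(9)
  a <- runif(40); b <- runif(40)
  s1 <- spearman_matrix(list(norm_track(a, "a"), norm_track(b, "b")))
  s2 <- spearman_matrix(list(norm_track(exp(3 * a), "a"), norm_track(b, "b")))
  expect_equal(s1, s2)

  # constant track: undefined, NA with a warning
  expect_warning(
    smc <- spearman_matrix(list(norm_track(rep(0.25, 4), "const"),
                                norm_track(c(1, 2, 3, 4) / 10, "y"))),
    "constant"
  )
  expect_true(is.na(smc["const", "y"]))
})

test_that("per_position_ttest matches the pooled-variance Student form", {
  ref <- lapply(c(1, 2, 3), function(v) norm_track(v, condition = "ref"))
  pert <- lapply(c(4, 5, 6), function(v) norm_track(v, condition = "pert"))
  res <- per_position_ttest(ref, pert)
  expect_equal(res$tests$t_stat, -3.6742346141747673, tolerance = 1e-9)
  expect_equal(res$tests$p_value, 0.0213116411287567, tolerance = 1e-9)
  expect_equal(res$tests$direction, "up")
  expect_equal(res$track$calls, "up")

  # identical groups: t = 0, p = 1, none
  same <- per_position_ttest(ref, ref)
  expect_equal(same$tests$t_stat, 0)
  expect_equal(same$tests$p_value, 1)
  expect_equal(same$tests$direction, "none")

  # both groups all zero: degenerate, p = 1, untestable
  zr <- lapply(1:2, function(i) norm_track(c(0, 0)))
  zres <- per_position_ttest(zr, zr)
  expect_true(all(zres$tests$degenerate))
  expect_true(all(!zres$tests$testable))
  expect_equal(zres$tests$p_value, c(1, 1))

  # zero variance, unequal means: p = 0 with the degeneracy flag
  a <- lapply(1:2, function(i) norm_track(0.2))
  b <- lapply(1:2, function(i) norm_track(0.4))
  d <- per_position_ttest(a, b)
  expect_equal(d$tests$p_value, 0)
  expect_true(d$tests$degenerate)
  expect_equal(d$tests$direction, "up")

  expect_error(per_position_ttest(ref[1], pert), "2 replicates")
})

test_that("direction calls follow the sign of the perturbed - reference difference", {
  set.seed(31)
  n <- 200
  base <- matrix(runif(3 * n, 0.4, 0.6), ncol = 3)
  shift <- sample(c(-0.3, 0, 0.3), n, replace = TRUE)
  ref <- lapply(1:3, function(j) norm_track(base[, j], condition = "ref"))
  pert <- lapply(1:3, function(j) norm_track(base[, j] + shift + rnorm(n, 0, 0.01),
                                             condition = "pert"))
  res <- per_position_ttest(ref, pert)
  up <- res$tests$direction == "up"
  dn <- res$tests$direction == "down"
  expect_true(all(res$tests$mean_pert[up] > res$tests$mean_ref[up]))
  expect_true(all(res$tests$mean_pert[dn] < res$tests$mean_ref[dn]))
  # direction is none wherever p >= alpha
  expect_true(all(res$tests$direction[res$tests$p_value >= 0.05] == "none"))
})

test_that("ks_region_test computes the two-sample ECDF supremum", {
  reg <- list(name = "R", start = 0L, end = 3L, region_class = "spacer")
  same <- ks_region_test(profile_of(c(1, 2, 3)), profile_of(c(1, 2, 3), "p"), reg)
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)

  # interleaved values: D = 1/3
  res <- ks_region_test(profile_of(c(1, 2, 3)), profile_of(c(1.5, 2.5, 3.5), "p"), reg)
  expect_equal(res$D, 1 / 3, tolerance = 1e-12)

  # disjoint supports: D = 1
  res2 <- ks_region_test(profile_of(c(1, 2, 3)), profile_of(c(10, 11, 12), "p"), reg)
  expect_equal(res2$D, 1)

  short <- list(name = "S", start = 0L, end = 1L, region_class = "spacer")
  expect_error(ks_region_test(profile_of(1:3), profile_of(1:3, "p"), short),
               "fewer than 2")
})

test_that("pca_samples places duplicated samples together and flags degeneracy", {
  set.seed(12)
  v <- runif(30); v <- v / sum(v)
  w <- runif(30); w <- w / sum(w)
  tracks <- list(norm_track(v, "a"), norm_track(v, "b"), norm_track(w, "c"))
  res <- pca_samples(tracks)
  expect_equal(unlist(res$coordinates[1, c("PC1", "PC2")]),
               unlist(res$coordinates[2, c("PC1", "PC2")]), tolerance = 1e-9)
  expect_false(res$degenerate)
  expect_true(all(res$var_explained >= 0) && sum(res$var_explained) <= 1 + 1e-9)

  # all samples identical: degenerate, fractions 0
  same <- pca_samples(list(norm_track(v, "a"), norm_track(v, "b"), norm_track(v, "c")))
  expect_true(same$degenerate)
  expect_equal(same$var_explained, c(0, 0))

  expect_error(pca_samples(tracks[1:2]), "3 samples")
})
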