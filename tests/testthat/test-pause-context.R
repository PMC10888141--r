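# template whose single spacer spans the whole sequence, for profile-driven tests
flat_spacer_template <- function(seq) {
  rdna_template("sp", seq,
    data.frame(name = "ETS1", start = 0, end = nchar(seq), region_class = "spacer"))
}

test_that("call_pauses selects ceil(q * eligible) spacer positions, ties by coordinate", {
  set.seed(41)
  seq <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  tpl <- flat_spacer_template(seq)
  vals <- runif(1000, 0.1, 1)
  ps <- call_pauses(profile_of(vals), tpl, q = 0.025)
  expect_equal(ps$n_eligible, 1000L)
  expect_length(ps$positions, 25L) # top 2.5% of 1000
  # the selected positions are exactly the 25 largest values
  expect_setequal(ps$positions, order(-vals)[1:25] - 1L)
  expect_equal(ps$threshold_value, sort(vals, decreasing = TRUE)[25])

  # all values equal: the lowest-coordinate positions win
  tie <- call_pauses(profile_of(rep(0.5, 1000)), tpl, q = 0.025)
  expect_equal(tie$positions, 0:24)

  # zero-median positions are ineligible
  vals2 <- vals; vals2[1:500] <- 0
  ps2 <- call_pauses(profile_of(vals2), tpl, q = 0.025)
  expect_equal(ps2$n_eligible, 500L)
  expect_length(ps2$positions, 13L) # ceil(0.025 * 500)
  expect_true(all(ps2$positions >= 500L))

  expect_error(call_pauses(profile_of(rep(0, 1000)), tpl), "no eligible")
  expect_error(call_pauses(profile_of(vals), tpl, q = 0), "q must be")

  # only spacer positions are ever selected
  mixed <- toy_template()
  v3 <- rep(1e-3, 100); v3[45] <- 1 # huge peak inside the mature 18S
  ps3 <- call_pauses(profile_of(v3), mixed, q = 0.5)
  expect_true(all(spacer_mask(mixed)[ps3$positions + 1L]))
})

test_that("extract_contexts returns LNT-centered windows and drops edge cases", {
  seq <- paste(rep("A", 100), collapse = "")
  substr(seq, 49, 53) <- "ACGTA" # 0-based 48..52
  tpl <- flat_spacer_template(seq)
  ps <- structure(list(condition = "ref", q = 0.025, positions = 50L,
                       threshold_value = 1, n_eligible = 100L),
                  class = "pause_set")
  cx <- extract_contexts(ps, tpl, W = 5L)
  expect_equal(cx$sequences, "ACGTA")
  expect_equal(cx$center, 3L)
  expect_equal(cx$n_dropped, 0L)

  # near-edge windows are dropped and counted
  ps2 <- ps; ps2$positions <- c(1L, 50L, 99L)
  cx2 <- extract_contexts(ps2, tpl, W = 21L)
  expect_length(cx2$sequences, 1L)
  expect_equal(cx2$n_dropped, 2L)

  # conservation at W = 3 on fully in-bounds positions
  ps3 <- ps; ps3$positions <- as.integer(10:34)
  cx3 <- extract_contexts(ps3, tpl, W = 3L)
  expect_length(cx3$sequences, 25L)
  expect_true(all(nchar(cx3$sequences) == 3L))

  expect_error(extract_contexts(ps, tpl, W = 4L), "odd")
})

test_that("build_pwm computes pseudocounted column frequencies", {
  p1 <- build_pwm(c("AA", "AA"), pseudocount = 0)
  expect_equal(unname(p1$matrix[, 1]), c(1, 0, 0, 0))
  expect_equal(unname(p1$matrix[, 2]), c(1, 0, 0, 0))

  p2 <- build_pwm(c("A", "C", "G", "T"), pseudocount = 0)
  expect_equal(unname(p2$matrix[, 1]), rep(0.25, 4))

  p3 <- build_pwm(c("A", "A", "C"), pseudocount = 0.5)
  expect_equal(unname(p3$matrix[, 1]), c(0.5, 0.3, 0.1, 0.1))

  # columns always sum to 1; entries positive with a pseudocount
  set.seed(14)
  ctx <- replicate(30, paste(sample(c("A", "C", "G", "T"), 7, TRUE), collapse = ""))
  pw <- build_pwm(ctx)
  expect_equal(unname(colSums(pw$matrix)), rep(1, 7), tolerance = 1e-9)
  expect_true(all(pw$matrix > 0))

  expect_error(build_pwm(character(0)), "no contexts")
  expect_error(build_pwm(c("AA", "AAA")), "differ in length")
})

pwm_of <- function(m, condition = NA_character_) {
  dimnames(m) <- list(c("A", "C", "G", "T"), NULL)
  structure(list(condition = condition, width = ncol(m), matrix = m,
                 pseudocount = 0, n_contexts = 1L),
            class = "context_pwm")
}

test_that("difflogo computes per-column JSD in bits with signed partitioned heights", {
  # identical columns -> zero everywhere
  m <- matrix(c(0.4, 0.3, 0.2, 0.1), ncol = 1)
  z <- difflogo(pwm_of(m), pwm_of(m))
  expect_equal(z$jsd, 0)
  expect_equal(unname(z$heights[, 1]), rep(0, 4))

  # maximally divergent point masses: 1 bit, heights +1/2 and -1/2
  p <- matrix(c(1, 0, 0, 0), ncol = 1)
  r <- matrix(c(0, 1, 0, 0), ncol = 1)
  mx <- difflogo(pwm_of(p), pwm_of(r))
  expect_equal(mx$jsd, 1)
  expect_equal(unname(mx$heights[, 1]), c(0.5, -0.5, 0, 0))

  # numeric entropy oracle: H2(0.375,0.375,0.125,0.125) - (1 + 2)/2
  p2 <- matrix(c(0.5, 0.5, 0, 0), ncol = 1)
  r2 <- matrix(rep(0.25, 4), ncol = 1)
  res <- difflogo(pwm_of(p2), pwm_of(r2))
  expect_equal(res$jsd, 0.3112781245, tolerance = 1e-9)

  expect_error(difflogo(pwm_of(p2), pwm_of(cbind(r2, r2))), "width")
})

test_that("difflogo is antisymmetric, bounded, and partitions the JSD", {
  set.seed(15)
  for (i in 1:20) {
    a <- matrix(rgamma(4 * 9, 1), nrow = 4); a <- sweep(a, 2, colSums(a), "/")
    b <- matrix(rgamma(4 * 9, 1), nrow = 4); b <- sweep(b, 2, colSums(b), "/")
    fwd <- difflogo(pwm_of(a), pwm_of(b))
    rev <- difflogo(pwm_of(b), pwm_of(a))
    expect_equal(rev$jsd, fwd$jsd, tolerance = 1e-12)
    expect_equal(rev$heights, -fwd$heights, tolerance = 1e-12)
    expect_true(all(fwd$jsd >= 0 & fwd$jsd <= 1))
    expect_equal(colSums(abs(fwd$heights)), fwd$jsd, tolerance = 1e-9)
  }
})
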