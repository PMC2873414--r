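test_that("locality de-duplication keeps one copy per haplotype per locality", {
  # h1 five times in one locality, h2 once: mass entirely at their distance
  a <- aln_fix(c(rep("AAAAA", 5), "AATTA"),
               locality = c(rep("loc1", 5), "loc1"))
  x <- mismatch_distribution(a, dedup = TRUE)
  expect_equal(attr(x, "n_seq"), 2L)
  expect_equal(as.vector(x), c(0, 0, 1))           # all mass at 2 steps

  # h1 in two localities (3 + 2 copies) plus h2: dedup leaves h1, h1, h2
  b <- aln_fix(c(rep("AAAAA", 5), "AATTA"),
               locality = c("loc1", "loc1", "loc1", "loc2", "loc2", "loc1"))
  y <- mismatch_distribution(b, dedup = TRUE)
  expect_equal(attr(y, "n_seq"), 3L)
  expect_equal(as.vector(y), c(1 / 3, 0, 2 / 3))

  # a single haplotype in a single locality cannot form a pair
  expect_error(mismatch_distribution(
    aln_fix(rep("AAAA", 4), locality = rep("loc1", 4)), dedup = TRUE),
    "fewer than 2")
})

test_that("mismatch frequencies match the exhaustive pairwise count", {
  seqs <- c("AAAAAA", "AAAAAT", "AAAATT", "AAAAAA", "TTTAAA", "AAATTT")
  a <- aln_fix(seqs)
  x <- mismatch_distribution(a, dedup = FALSE)
  pairs <- utils::combn(6, 2)
  diffs <- apply(pairs, 2, function(ij) naive_diffs(seqs[ij[1]], seqs[ij[2]]))
  oracle <- tabulate(diffs + 1L, nbins = max(diffs) + 1L) / length(diffs)
  expect_equal(as.vector(x), oracle)
  expect_equal(sum(x), 1, tolerance = 1e-12)
})

test_that("raggedness follows its closed form", {
  expect_equal(raggedness(1), 1)                       # single class
  expect_equal(raggedness(c(0.5, 0.5)), 0.25)
  expect_equal(raggedness(c(0.2, 0.3, 0.5)),
               0.1^2 + 0.2^2 + 0.5^2)
  # bounded by 2 for any frequency vector
  set.seed(9)
  for (i in 1:20) {
    v <- stats::runif(sample(2:10, 1)); v <- v / sum(v)
    expect_lte(raggedness(v), 2)
    expect_gte(raggedness(v), 0)
  }
})

test_that("degenerate mismatch vectors are reported without a fit", {
  expect_warning(res <- fit_sudden_expansion(c(`0` = 1), n = 5, seed = 1),
                 "degenerate")
  expect_equal(res$raggedness, 1)
  expect_true(is.na(res$tau_hat))
})

test_that("the sudden-expansion fit recovers parameters of model-generated curves", {
  truth <- list(tau = 4, theta0 = 1)
  x <- wolfmtdna:::sudden_expansion_mismatch(truth$tau, truth$theta0, 25)
  x <- x / sum(x)
  fit <- wolfmtdna:::.fit_mismatch_lsq(x)
  expect_equal(fit$tau, truth$tau, tolerance = 0.05)
  expect_equal(fit$theta0, truth$theta0, tolerance = 0.05)
})

test_that("d from the full mismatch vector equals the diversity summary's d", {
  for (s in 1:10) {
    aln <- simulate_dataset(single_pop_cfg(25, 4, demography_constant(),
                                           700 + s))$alignment
    x <- mismatch_distribution(aln, dedup = FALSE)
    d_mm <- sum((seq_along(x) - 1) * x)
    expect_equal(d_mm, diversity_summary(aln)$d, tolerance = 1e-9)
  }
})

test_that("raggedness bootstrap p-values are roughly uniform under the model", {
  pv <- vapply(1:200, function(s) {
    x <- simulate_mismatch_null(30, tau = 5, theta0 = 1, seed = 81000 + s)
    if (length(x) < 3L) return(NA_real_)
    fit_sudden_expansion(x, n_reps = 100, seed = s)$p_value
  }, 0)
  frac <- mean(pv < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.12)
})
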