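test_that("exact binomial tail and point probabilities", {
  expect_equal(binomial_tail(2, 1, 0.5), 0.75)
  expect_equal(binomial_tail(10, 0, 0.3), 1)      # certain event
  expect_equal(binomial_tail(5, 5, 1), 1)
  expect_equal(binomial_tail(5, 1, 0), 0)
  # cross-check the log-space summation against stats::pbinom / dbinom
  set.seed(13)
  for (i in 1:25) {
    n <- sample(1:50, 1); k <- sample(0:n, 1); p <- stats::runif(1)
    expect_equal(binomial_tail(n, k, p),
                 stats::pbinom(k - 1, n, p, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(binomial_point(n, k, p), stats::dbinom(k, n, p),
                 tolerance = 1e-12)
    # tail + lower cdf = 1
    expect_equal(binomial_tail(n, k, p) + stats::pbinom(k - 1, n, p), 1,
                 tolerance = 1e-12)
  }
  # monotone increasing in p for fixed (n, k)
  ps <- seq(0.05, 0.95, by = 0.1)
  tails <- vapply(ps, function(p) binomial_tail(24, 23, p), 0)
  expect_true(all(diff(tails) > 0))
})

test_that("minimum plausible frequency matches closed form and grid search", {
  # k = n: point probability q^n, root alpha^(1/n)
  for (n in c(3, 10, 24))
    expect_equal(min_frequency_for_alpha(n, n, 0.05), 0.05^(1 / n),
                 tolerance = 1e-6)
  # grid-search oracle at 1e-6 resolution
  q_grid <- seq(1e-6, 8 / 10, by = 1e-6)
  oracle <- q_grid[which(stats::dbinom(8, 10, q_grid) >= 0.05)[1]]
  expect_equal(min_frequency_for_alpha(10, 8, 0.05), oracle, tolerance = 2e-6)
  # plugged back, the point probability returns alpha
  q <- min_frequency_for_alpha(24, 23, 0.05)
  expect_equal(binomial_point(24, 23, q), 0.05, tolerance = 1e-5)
  # unreachable alpha
  expect_warning(out <- min_frequency_for_alpha(10, 5, 0.5), "unreachable")
  expect_null(out)
})

test_that("frequency tables count haplogroups per stratum and drop unassigned", {
  s <- data.frame(label = c(rep("1", 7), rep("2", 3)), region = "europe")
  ft <- frequency_table(s, "region")
  expect_equal(ft$p1, 0.7); expect_equal(ft$p2, 0.3)
  expect_equal(ft$p1 + ft$p2, 1)

  s2 <- data.frame(label = c("1", "2", "unassigned"),
                   region = c("a", "a", "a"))
  expect_message(ft2 <- frequency_table(s2, "region"), "unassigned")
  expect_equal(ft2$n1 + ft2$n2, 2L)
  expect_equal(attr(ft2, "n_unassigned"), 1L)

  s3 <- data.frame(label = c("1", "unassigned"), region = c("a", "b"))
  expect_warning(expect_message(frequency_table(s3, "region")), "empty stratum")
})

test_that("ancient-vs-modern comparison reproduces exact enumeration", {
  # balanced modern frequencies, 12 of 24 ancient: tail ~ 0.58
  modern <- frequency_table(data.frame(label = rep(c("1", "2"), 50),
                                       region = "europe"), "region")
  ancient <- frequency_table(data.frame(label = rep(c("1", "2"), each = 12),
                                        region = "europe"), "region")
  rep1 <- compare_ancient_modern(modern, ancient)
  enum <- sum(choose(24, 12:24)) / 2^24          # exact summation oracle
  expect_equal(rep1$prob_tail, enum, tolerance = 1e-12)
  expect_equal(round(rep1$prob_tail, 2), 0.58)

  # ancient in the same proportion as modern: unremarkable configuration
  anc2 <- frequency_table(data.frame(label = c(rep("1", 12), rep("2", 12)),
                                     region = "europe"), "region")
  expect_gt(compare_ancient_modern(modern, anc2)$prob_tail, 0.05)
})
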