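test_that("identical seeds give byte-identical datasets", {
  cfg <- simulation_config(n_modern = 40, n_ancient = 6, seed = 77)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$alignment$seq, s2$alignment$seq)
  expect_identical(s1$truth$samples, s2$truth$samples)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_alignment(s1$alignment, f1)
  write_alignment(s2$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed gives a different dataset
  s3 <- simulate_dataset(simulation_config(n_modern = 40, n_ancient = 6,
                                           seed = 78))
  expect_false(identical(s1$alignment$seq, s3$alignment$seq))
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(n_ancient = 0), "ancient ages given")
  expect_error(simulation_config(n_ancient = 5, ancient_ages_bp = NULL),
               "no ancient ages")
  expect_error(simulation_config(ancient_window = c(0, 57)), "ancient_window")
  expect_error(simulation_config(ancient_window = c(10, 300)), "ancient_window")
  expect_error(simulation_config(hap2_fraction_modern = 1.2),
               "hap2_fraction_modern")
})

test_that("modern haplogroup-2 fraction matches its binomial sampling law", {
  n <- 947
  bounds <- stats::qbinom(c(0.005, 0.995), n, 0.24)
  inside <- 0L
  for (s in 1:50) {
    cfg <- simulation_config(n_modern = n, n_ancient = 0,
                             ancient_ages_bp = NULL, seed = 4200 + s)
    tr <- simulate_dataset(cfg)$truth$samples
    n2 <- sum(tr$haplogroup == "2")
    if (n2 >= bounds[1] && n2 <= bounds[2]) inside <- inside + 1L
  }
  expect_gte(inside, 46L)
})

test_that("peninsular regions are fixed for their haplogroup", {
  tr <- simulate_dataset(simulation_config(n_modern = 300, n_ancient = 0,
                                           ancient_ages_bp = NULL,
                                           seed = 5))$truth$samples
  expect_true(all(tr$haplogroup[tr$region == "iberia"] == "1"))
  expect_true(all(tr$haplogroup[tr$region == "apennine"] == "2"))
})

test_that("ancient subsamples honour bias, window and ages", {
  sim <- simulate_dataset(simulation_config(n_modern = 120, n_ancient = 0,
                                            ancient_ages_bp = NULL,
                                            hap2_fraction_modern = 0.4,
                                            seed = 91))
  sub <- make_ancient_subsample(sim$alignment, sim$truth, n = 10,
                                hap2_bias = 1, window = c(10, 66), seed = 2,
                                ages = c(44000, 1200))
  expect_equal(sub$L, 57L)
  lab <- stats::setNames(sim$truth$samples$haplogroup,
                         sim$truth$samples$sample_id)
  expect_true(all(lab[rownames(sub$seq)] == "2"))
  expect_true(all(!is.na(sub$meta$age_bp)))
  expect_error(make_ancient_subsample(sim$alignment, sim$truth, 10, 1,
                                      c(200, 300)), "out of range")
  # 23:1 bias: pooled composition over seeds stays within binomial bounds
  tot2 <- 0L
  for (s in 1:30) {
    sub2 <- make_ancient_subsample(sim$alignment, sim$truth, n = 24,
                                   hap2_bias = 23 / 24, window = c(1, 230),
                                   seed = 100 + s)
    tot2 <- tot2 + sum(lab[rownames(sub2$seq)] == "2")
  }
  bounds <- stats::qbinom(c(0.0005, 0.9995), 30 * 24, 23 / 24)
  expect_gte(tot2, bounds[1]); expect_lte(tot2, bounds[2])
})

test_that("constant-size simulations match neutral coalescent expectations", {
  theta <- 5; n <- 50; an <- sum(1 / seq_len(n - 1))
  d_bar <- 0; s_bar <- 0
  for (s in 1:100) {
    aln <- simulate_dataset(single_pop_cfg(n, theta, demography_constant(),
                                           8800 + s, L = 1000,
                                           indel = 0))$alignment
    dv <- diversity_summary(aln)
    d_bar <- d_bar + dv$d / 100
    s_bar <- s_bar + dv$s / 100
  }
  expect_lt(abs(d_bar - theta) / theta, 0.10)          # E[d] = theta
  expect_lt(abs(s_bar - theta * an) / (theta * an), 0.15)  # Watterson, finite sites
})

test_that("ancient samples enter the genealogy serially without breaking the run", {
  cfg <- simulation_config(n_modern = 30, n_ancient = 8, seed = 17)
  sim <- simulate_dataset(cfg)
  anc <- is_ancient(sim$alignment)
  expect_equal(sum(anc), 8L)
  expect_true(all(sim$alignment$meta$age_bp[anc] >= 1200))
  expect_gt(sim$truth$tmrca, 0)
})
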