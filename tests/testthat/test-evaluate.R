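test_that("per-sample efficacy is captured mutations per 10 kb of panel", {
  # one sample, 10 records, 4 inside a 10,000 bp panel -> efficacy 4.0
  ds <- chr1_dataset(c(101:104, 5001:5006), sample = rep("s1", 10))
  panel <- data.frame(chrom = "chr1", start = 1, end = 200)
  rep1 <- capture_efficacy(panel, ds, panel_bp = 10000)
  expect_equal(rep1$per_sample$captured, 4L)
  expect_equal(rep1$per_sample$total, 10L)
  expect_equal(rep1$per_sample$efficacy, 4.0)
})

test_that("a saturating panel captures every record of every sample", {
  set.seed(61)
  sim <- simulate_mutations(sim_config(n_samples = 15, mutations_per_sample = 8,
                                       seed = 4))
  ds <- sim$dataset
  full <- data.frame(chrom = paste0("chr", 1:10), start = 1, end = 2e6)
  rep1 <- capture_efficacy(full, ds)
  expect_equal(rep1$per_sample$captured, rep1$per_sample$total)
  expect_equal(rep1$summary$capture_fraction, 1)
})

test_that("efficacy scales as 1/panel_bp and ignores sample relabeling", {
  ds <- chr1_dataset(c(100, 150, 900), sample = c("a", "b", "a"))
  panel <- data.frame(chrom = "chr1", start = 50, end = 200)
  r1 <- capture_efficacy(panel, ds, panel_bp = 1000)
  r2 <- capture_efficacy(panel, ds, panel_bp = 2000)
  expect_equal(r1$per_sample$efficacy, 2 * r2$per_sample$efficacy)
  ds_swap <- chr1_dataset(c(100, 150, 900), sample = c("x", "y", "x"))
  r3 <- capture_efficacy(panel, ds_swap, panel_bp = 1000)
  expect_equal(sort(r1$per_sample$efficacy), sort(r3$per_sample$efficacy))
})

test_that("fold change follows the per-10kb efficacy ratio", {
  # 250 captured / 10,000 bp vs 1,000 captured / 390,000 bp -> 9.75
  ds <- chr1_dataset(1:1000, sample = rep("s1", 1000))
  small <- capture_efficacy(data.frame(chrom = "chr1", start = 1, end = 250),
                            ds, panel_bp = 10000)
  big <- capture_efficacy(data.frame(chrom = "chr1", start = 1, end = 1000),
                          ds, panel_bp = 390000)
  cmp <- compare_efficacy(small, big)
  expect_equal(cmp$fold_change, 9.75)
})

test_that("identical pairs give p = 1 with a warning", {
  expect_warning(res <- paired_wilcoxon(c(1, 2, 3), c(1, 2, 3)),
                 "zero")
  expect_equal(res$p_value, 1)
})

test_that("six strictly positive differences give exact p = 2/64", {
  res <- paired_wilcoxon(c(2, 4, 6, 8, 10, 12), c(1, 2, 3, 4, 5, 6))
  expect_equal(res$p_value, 2 / 64)
  expect_equal(res$statistic, 21)  # all positive ranks
})

test_that("the signed-rank p agrees with sign-pattern enumeration", {
  set.seed(63)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    d <- round(stats::rnorm(n, 0.4, 1), 3)
    d <- d[d != 0]
    if (length(d) < 2 || any(duplicated(abs(d)))) next
    got <- paired_wilcoxon(d, rep(0, length(d)))$p_value
    expect_equal(got, oracle_wilcoxon_p(d), tolerance = 1e-8)
  }
})

test_that("the two-sample KS p agrees with labeling enumeration", {
  set.seed(65)
  for (rep in 1:12) {
    n <- sample(4:6, 1); m <- sample(4:6, 1)
    x <- sort(stats::runif(n, 0, 1000))
    y <- sort(stats::runif(m, 0, 1000))
    got <- suppressWarnings(stats::ks.test(x, y)$p.value)
    expect_equal(got, oracle_ks_p(x, y), tolerance = 1e-8)
  }
})

test_that("repeated-split KS is deterministic and sane on identical structure", {
  sim <- simulate_mutations(sim_config(n_samples = 30, mutations_per_sample = 12,
                                       seed = 8))
  r1 <- suppressWarnings(ks_reproducibility(sim$dataset, n_splits = 10, seed = 99))
  r2 <- suppressWarnings(ks_reproducibility(sim$dataset, n_splits = 10, seed = 99))
  expect_identical(r1, r2)
  expect_true(all(r1$mean_p >= 0 & r1$mean_p <= 1))
  # chromosomes with enough records are tested on every split; sparse ones
  # may be skipped on some splits but never invent tests
  n_rec <- table(sim$dataset$records$chrom)[r1$chrom]
  expect_true(all(r1$n_tests[n_rec >= 10] == 10L))
  expect_true(all(r1$n_tests <= 10L))
})

test_that("sample size curve is reproducible and validates its grid", {
  sim <- simulate_mutations(sim_config(n_samples = 20, mutations_per_sample = 10,
                                       hotspot_fraction = 0.9, seed = 12))
  res1 <- sample_size_curve(sim$dataset, 125, 2000, n_grid = c(2, 4),
                            n_reps = 3, seed = 7)
  res2 <- sample_size_curve(sim$dataset, 125, 2000, n_grid = c(2, 4),
                            n_reps = 3, seed = 7)
  expect_identical(res1, res2)
  expect_error(sample_size_curve(sim$dataset, 125, 2000, n_grid = 50,
                                 n_reps = 2, seed = 7),
               "training")
})

test_that("designing from the full training set leaves no replicate variance", {
  sim <- simulate_mutations(sim_config(n_samples = 15, mutations_per_sample = 10,
                                       hotspot_fraction = 0.9, seed = 13))
  n_train <- max(1L, round(0.8 * length(sim$dataset$samples)))
  res <- sample_size_curve(sim$dataset, 125, 2000, n_grid = n_train,
                           n_reps = 4, seed = 3)
  expect_equal(res$curve$sd_p, 0)
})
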