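test_that("colony prevalence matches the exact interval oracle", {
  est <- prevalence_estimate(tibble::tibble(n_tested = 70, n_positive = 35))
  expect_equal(est$estimate_pct, 50)
  oracle <- 100 * oracle_clopper_pearson(35, 70)
  expect_equal(est$ci_low_pct, oracle[1], tolerance = 1e-6)
  expect_equal(est$ci_high_pct, oracle[2], tolerance = 1e-6)
  expect_equal(round(est$ci_low_pct, 1), 37.8)
  expect_equal(round(est$ci_high_pct, 1), 62.2)
  expect_true(is.na(est$rule_of_three_pct))
})

test_that("zero-positive assays report the rule-of-three bound", {
  est <- prevalence_estimate(tibble::tibble(n_tested = 300, n_positive = 0))
  expect_equal(est$estimate_pct, 0)
  expect_equal(est$rule_of_three_pct, 1)
})

test_that("the exact interval always contains the point estimate", {
  set.seed(13)
  n <- sample(5:500, 50, replace = TRUE)
  x <- vapply(n, function(ni) sample(0:ni, 1), integer(1))
  est <- prevalence_estimate(tibble::tibble(n_tested = n, n_positive = x))
  expect_true(all(est$ci_low_pct <= est$estimate_pct + 1e-9))
  expect_true(all(est$estimate_pct <= est$ci_high_pct + 1e-9))
})

test_that("stability statistics transform retention into a loss rate", {
  st <- stability_stats(tibble::tibble(n_tested = 450, n_positive = 448),
                        generations = 50)
  expect_equal(round(st$retention_pct, 1), 99.6)
  # log-transform oracle: lambda = 1 - exp(log(R)/G)
  expect_equal(st$loss_rate, 1 - exp(log(448 / 450) / 50), tolerance = 1e-12)
  expect_equal(1 - 0.996^(1 / 50), 8.015722e-05, tolerance = 1e-6)
  # interval is a monotone transform of the retention interval
  expect_lt(st$loss_rate_low, st$loss_rate)
  expect_gt(st$loss_rate_high, st$loss_rate)
  expect_true(is.na(st$loss_rate_bound))
})

test_that("lossless assays report zero loss with a rule-of-three bound", {
  st <- stability_stats(tibble::tibble(n_tested = 450, n_positive = 450),
                        generations = 50)
  expect_equal(st$loss_rate, 0)
  expect_equal(st$loss_rate_bound, 1 - (1 - 3 / 450)^(1 / 50))
  expect_warning(
    stability_stats(tibble::tibble(n_tested = 10, n_positive = 0), 5),
    "zero retention")
})

test_that("prevalence projection is constant when neutral, and matches the closed form", {
  traj <- project_prevalence(0, 0, p0 = 0.37, generations = 25)
  expect_true(all(traj$prevalence == 0.37))
  # with s = 0 the recursion reduces to p0 (1 - lambda)^t exactly
  lam <- 3e-3
  traj <- project_prevalence(lam, 0, p0 = 0.8, generations = 100)
  expect_equal(traj$prevalence, 0.8 * (1 - lam)^(0:100), tolerance = 1e-12)
  # the measured loss rate cannot explain a 50% prevalence after growth
  traj <- project_prevalence(8.9e-5, 0, p0 = 1, generations = 100)
  expect_gte(traj$prevalence[101], 0.99)
  # plasmid-free advantage drives prevalence strictly down
  traj <- project_prevalence(0, fitness_cost = 0.5, p0 = 0.9,
                             generations = 30)
  expect_true(all(diff(traj$prevalence) < 0))
})

test_that("plasmid burden is the product of genomic and energetic fractions", {
  expect_equal(plasmid_burden(2, 100, 0.03), 0.0006)
  expect_lt(plasmid_burden(2, 100, 0.03), 0.001)
  expect_equal(plasmid_burden(0, 100, 0.03), 0)
  expect_equal(plasmid_burden(100, 100, 0.03), 0.03)
  expect_error(plasmid_burden(101, 100, 0.03))
})

test_that("in-silico PCR finds the constructed amplicon and honors mismatch limits", {
  fwd <- "TCAACCAATCAAACGCGCC"
  rev <- "AACAACGCATCGCCCAAAG"
  set.seed(21)
  filler <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
  # forward site starts at 0-based 10; reverse site ends at 0-based 528
  template <- paste0(filler(10), fwd, filler(518 - nchar(fwd) - nchar(rev)),
                     ecrtools:::revcomp(rev), filler(72))
  hits <- insilico_pcr(template, fwd, rev)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 10L)
  expect_equal(hits$end, 528L)
  expect_equal(hits$length, 518L)
  # one mismatch in the forward primer
  fwd_mm <- sub("^T", "A", fwd)
  expect_equal(nrow(insilico_pcr(template, fwd_mm, rev, max_mismatch = 0)), 0L)
  expect_equal(insilico_pcr(template, fwd_mm, rev, max_mismatch = 1)$length,
               518L)
  expect_error(insilico_pcr(template, "ACGT", rev), "15 nt")
})

test_that("circular templates amplify across the origin with modular length", {
  fwd <- "TCAACCAATCAAACGCGCC"
  rev <- "AACAACGCATCGCCCAAAG"
  set.seed(22)
  filler <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
  linear <- paste0(filler(50), fwd, filler(200), ecrtools:::revcomp(rev),
                   filler(400))
  # rotation oracle: every rotation of a circular template must show one
  # product of the same modular length
  product_len <- nchar(fwd) + 200 + nchar(rev)
  for (rot in c(0, 100, 150)) {
    rotated <- paste0(substr(linear, rot + 1, nchar(linear)),
                      substr(linear, 1, rot))
    hits <- insilico_pcr(rotated, fwd, rev, circular = TRUE)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$length, product_len)
  }
  # linear scan of the wrapped rotation finds nothing
  rot <- 150
  rotated <- paste0(substr(linear, rot + 1, nchar(linear)),
                    substr(linear, 1, rot))
  expect_equal(nrow(insilico_pcr(rotated, fwd, rev, circular = FALSE)), 0L)
})
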