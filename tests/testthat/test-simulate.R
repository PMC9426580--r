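test_that("all generators are bit-reproducible under a seed", {
  g1 <- simulate_replicon_set(seed = 71)
  g2 <- simulate_replicon_set(seed = 71)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_identical(g1$cds, g2$cds)
  expect_identical(simulate_depth(seed = 72), simulate_depth(seed = 72))
  expect_identical(simulate_colony_assay(70, 0.5, seed = 73),
                   simulate_colony_assay(70, 0.5, seed = 73))
  expect_identical(simulate_de_tables(n_genes = 200, regulon_size = 50,
                                      seed = 74),
                   simulate_de_tables(n_genes = 200, regulon_size = 50,
                                      seed = 74))
  f1 <- simulate_rep_families(seed = 75)
  f2 <- simulate_rep_families(seed = 75)
  expect_identical(f1$repa, f2$repa)
  expect_identical(f1$segments, f2$segments)
})

test_that("a huge Dirichlet concentration gives near-uniform codon usage", {
  spec <- tibble::tibble(replicon_id = "r", n_genes = 60L,
                         gene_length_codons = 300L, alpha = 1e6)
  g <- simulate_replicon_set(spec, seed = 76)
  counts <- count_codons(cds_sequences(g))
  prof <- rscu_of_counts(counts)
  # uniform usage within a family of size n has per-codon frequency 1/n;
  # allow 3 multinomial standard deviations around RSCU = 1
  fam_tot <- dplyr::mutate(
    dplyr::group_by(prof, amino_acid),
    tot = sum(count), n_fam = dplyr::n())
  z <- with(fam_tot, (count - tot / n_fam) /
              sqrt(tot * (1 / n_fam) * (1 - 1 / n_fam)))
  expect_true(all(abs(z) < 3.8))
  # identical bias vectors give near-zero downstream RSCU distance
  spec2 <- tibble::tibble(replicon_id = c("r1", "r2"), n_genes = 60L,
                          gene_length_codons = 300L, alpha = 0.3,
                          bias_from = c(NA, "r1"))
  g2 <- simulate_replicon_set(spec2, seed = 77)
  m <- ecrtools:::rscu_matrix(replicon_rscu(g2))
  d_same <- sqrt(sum((m["r1", ] - m["r2", ])^2))
  expect_lt(d_same, 2)  # sampling noise only, versus O(10) for alien bias
  expect_error(simulate_replicon_set(
    tibble::tibble(replicon_id = "r", n_genes = 1L,
                   gene_length_codons = 10L, alpha = 0)), "alpha")
})

test_that("simulated depth has the configured ratio structure", {
  spec <- tibble::tibble(replicon_id = c("chr", "p1", "p2"),
                         copy_number = c(1L, 1L, 2L),
                         prevalence = c(1, 0.5, 1))
  ratios <- sapply(1:20, function(s) {
    d <- simulate_depth(spec, depth_mean_per_copy = 100, n_windows = 500,
                        seed = 80 + s)
    cr <- coverage_ratio(d, "chr", n_boot = 50, seed = s)
    cr$r[match(c("p1", "p2"), cr$replicon_id)]
  })
  expect_equal(mean(ratios[1, ]), 0.5, tolerance = 0.02)
  expect_equal(mean(ratios[2, ]), 2.0, tolerance = 0.05)
  expect_error(simulate_depth(spec, depth_mean_per_copy = 0), "positive")
})

test_that("colony assays are Binomial with the configured mean", {
  expect_equal(simulate_colony_assay(50, 1, seed = 1)$n_positive, 50L)
  expect_equal(simulate_colony_assay(50, 0, seed = 1)$n_positive, 0L)
  reps <- ecrtools:::with_seed(83, mean(
    replicate(3000, simulate_colony_assay(70, 0.5)$n_positive)))
  expect_equal(reps, 35, tolerance = 0.015)  # ~6 SE of the Monte-Carlo mean
})

test_that("passaging follows the deterministic recursion between bottlenecks", {
  sim <- simulate_passaging(0, 0, p0 = 0.6, generations = 20, seed = 84)
  expect_true(all(sim$trajectory$prevalence == 0.6))
  sim2 <- simulate_passaging(1e-3, 0, p0 = 1, generations = 30, seed = 85)
  expect_equal(sim2$trajectory$prevalence,
               project_prevalence(1e-3, 0, 1, 30)$prevalence)
  # bottlenecks add sampling noise but keep the trend
  sim3 <- simulate_passaging(0.05, 0, p0 = 1, generations = 40,
                             transfer_every = 10, bottleneck_size = 500,
                             seed = 86)
  expect_lt(sim3$trajectory$prevalence[41], 0.35)
  expect_equal(sim3$assay$n_tested, 450L)
})

test_that("DE generator hits its target correlation and rejects infeasible targets", {
  # null target: sample correlation within 3 / sqrt(n)
  de0 <- simulate_de_tables(n_genes = 2000, regulon_size = 500,
                            rho_target = 0, seed = 87)
  expect_lt(abs(fc_correlation(de0[[1]], de0[[2]])$r), 3 / sqrt(2000))
  # anchored target 0.76 recovered in expectation over 20 seeds
  rhos <- vapply(1:20, function(s) {
    de <- simulate_de_tables(seed = 90 + s)
    fc_correlation(de[[1]], de[[2]])$r
  }, numeric(1))
  expect_gte(mean(rhos), 0.71)
  expect_lte(mean(rhos), 0.81)
  # identical tables correlate perfectly
  de <- simulate_de_tables(n_genes = 500, regulon_size = 100, seed = 89)
  expect_equal(fc_correlation(de[[1]], de[[1]])$r, 1)
  # infeasible target names the attainable range
  expect_error(simulate_de_tables(n_genes = 1000, regulon_size = 10,
                                  rho_target = 0.9, seed = 1),
               "attainable")
  # regulon genes carry small p-values, nulls uniform
  expect_lt(median(de[[1]]$pvalue[1:100]), 0.05)
  expect_gt(median(de[[1]]$pvalue[-(1:100)]), 0.3)
})

test_that("rep-family generator encodes congruent vs swapped topologies", {
  fam <- simulate_rep_families(swap = list(), seed = 95)
  expect_equal(rf_distance(fam$guide_tree, fam$repc_tree)$rf, 0)
  fam2 <- simulate_rep_families(swap = list(c("t01", "t05")), seed = 95)
  expect_gt(rf_distance(fam2$guide_tree, fam2$repc_tree)$rf, 0)
  expect_error(simulate_rep_families(swap = list(c("t01", "zz"))),
               "unknown taxa")
  expect_error(simulate_rep_families(n_taxa = 3), "at least 4")
  # zero branch lengths: all sequences identical to the root
  fam0 <- simulate_rep_families(within_bl = 0, between_bl = 0, seed = 96)
  expect_equal(length(unique(fam0$repa)), 1L)
})
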