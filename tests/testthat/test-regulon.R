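de_fixture <- function(p, fc = NULL) {
  tibble::tibble(
    gene_id = sprintf("g%02d", seq_along(p)),
    replicon_id = "chr",
    log2fc = fc %||% rep(2, length(p)),
    pvalue = p
  )
}

test_that("significance thresholding follows raw-p and BH rules", {
  de <- de_fixture(c(0.01, 0.04, 0.2))
  expect_equal(nrow(significant_set(de, alpha = 0.05)), 2L)
  expect_equal(nrow(significant_set(de, alpha = 1)), 3L)
  # BH by hand: {0.01, 0.02, 0.9} -> {0.03, 0.03, 0.9}
  de2 <- de_fixture(c(0.01, 0.02, 0.9))
  expect_equal(nrow(significant_set(de2, alpha = 0.05, adjust = "BH")), 2L)
  # fold-change filter
  de3 <- de_fixture(c(0.01, 0.01), fc = c(0.5, 3))
  expect_equal(significant_set(de3, fc_threshold = 1)$gene_id, "g02")
})

test_that("venn partitions match hand counts and exhaustive tabulation", {
  v <- venn(list(A = c("1", "2", "3"), B = c("2", "3", "4"), C = "3"))
  get <- function(region) v$count[v$region == region]
  expect_equal(get("A"), 1L)
  expect_equal(get("B"), 1L)
  expect_equal(get("C"), 0L)
  expect_equal(get("A&B"), 1L)
  expect_equal(get("A&C"), 0L)
  expect_equal(get("B&C"), 0L)
  expect_equal(get("A&B&C"), 1L)
  expect_equal(sum(v$count), attr(v, "union_size"))

  ident <- venn(list(x = letters[1:5], y = letters[1:5]))
  expect_equal(ident$count[ident$region == "x&y"], 5L)
  expect_equal(sum(ident$count), 5L)

  set.seed(61)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    sets <- stats::setNames(
      lapply(seq_len(k), function(j) sample(letters, sample(3:15, 1))),
      LETTERS[seq_len(k)])
    v <- venn(sets)
    oracle <- brute_venn_counts(sets)
    for (r in seq_len(nrow(v))) {
      mask <- paste(as.integer(unlist(v[r, seq_len(k)])), collapse = "")
      expected <- if (mask %in% names(oracle)) oracle[[mask]] else 0L
      expect_equal(v$count[r], as.integer(expected))
    }
    expect_equal(sum(v$count), length(unique(unlist(sets))))
  }
  expect_error(venn(list(a = "x")), "between 2 and 4")
})

test_that("fold-change correlation matches hand computation and edge cases", {
  x <- de_fixture(rep(0.5, 4), fc = c(1, 2, 3, 4))
  y <- de_fixture(rep(0.5, 4), fc = c(1, 3, 2, 4))
  expect_equal(fc_correlation(x, y)$r, 0.8)
  expect_equal(fc_correlation(x, dplyr::mutate(x, log2fc = 2 * log2fc))$r, 1)
  expect_equal(fc_correlation(x, dplyr::mutate(x, log2fc = -log2fc))$r, -1)
  flat <- dplyr::mutate(x, log2fc = 5)
  expect_equal(fc_correlation(x, flat)$note, "zero variance")
  expect_error(fc_correlation(x[1:2, ], y[1:2, ]), "3 shared")
  # non-shared genes are excluded and counted
  y2 <- dplyr::mutate(y, gene_id = c("g01", "g02", "g03", "zz"))
  res <- fc_correlation(x, y2)
  expect_equal(res$n_shared, 3L)
  expect_equal(res$n_only_x, 1L)
  expect_equal(res$n_only_y, 1L)
})

test_that("hypergeometric enrichment matches combinatorial enumeration", {
  pop <- sprintf("g%02d", 1:10)
  cats <- tibble::tibble(gene_id = pop[1:4], category = "cat1")
  res <- enrichment(pop[c(1, 2, 3, 9, 10)], cats, pop)
  expect_equal(res$p_value, 66 / 252, tolerance = 1e-12)
  expect_equal(res$p_value, brute_hyper_upper(10, 4, 5, 3), tolerance = 1e-12)
  # k = 0 has upper-tail probability 1
  res0 <- enrichment(pop[9:10], cats, pop)
  expect_equal(res0$p_value, 1)
  # category = population: k = n always, p = 1
  all_cat <- tibble::tibble(gene_id = pop, category = "all")
  expect_equal(enrichment(pop[1:5], all_cat, pop)$p_value, 1)
  # invariance to gene relabeling
  relab <- stats::setNames(sprintf("x%02d", 1:10), pop)
  res_rel <- enrichment(unname(relab[pop[c(1, 2, 3, 9, 10)]]),
                        dplyr::mutate(cats, gene_id = unname(relab[gene_id])),
                        unname(relab))
  expect_equal(res_rel$p_value, res$p_value)
  # upper-tail probabilities over all k sum correctly / oracle agreement
  set.seed(62)
  for (i in 1:10) {
    N <- sample(10:40, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 brute_hyper_upper(N, K, n, k), tolerance = 1e-12)
  }
  expect_warning(
    enrichment(pop[1], tibble::tibble(gene_id = "nope", category = "empty"),
               pop),
    "skipped")
  expect_error(enrichment("absent", cats, pop), "subset")
})

test_that("RPKM follows its definition and summarizes per replicon", {
  counts <- tibble::tibble(gene_id = c("a", "b", "c"),
                           replicon_id = c("chr", "chr", "pl"),
                           reads = c(10, 20, 10),
                           length_bp = c(1000, 2000, 1000))
  res <- rpkm(counts, library_size = 1e6)
  expect_equal(res$rpkm, c(10, 10, 10))
  # doubling the library size halves RPKM
  expect_equal(rpkm(counts, library_size = 2e6)$rpkm, res$rpkm / 2)
  # direct-formula oracle on random tables
  set.seed(63)
  tab <- tibble::tibble(gene_id = sprintf("g%d", 1:50),
                        replicon_id = sample(c("chr", "pl"), 50, TRUE),
                        reads = rpois(50, 200),
                        length_bp = sample(300:3000, 50))
  got <- rpkm(tab)
  expect_equal(got$rpkm,
               tab$reads * 1e9 / (tab$length_bp * sum(tab$reads)))
  summ <- rpkm_replicon_summary(got, chromosome_id = "chr")
  expect_equal(summ$ratio_to_chromosome[summ$replicon_id == "chr"], 1)
  expect_error(rpkm(counts, library_size = 0), "positive")
  expect_error(rpkm(dplyr::mutate(counts, length_bp = 0)), "positive")
})
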