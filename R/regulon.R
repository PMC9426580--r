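# Cross-strain regulon structure from differential-expression tables:
# significant sets, Venn partitions, fold-change correlation,
# hypergeometric category enrichment, and RPKM expression summaries.

#' Significantly regulated genes of one strain
#'
#' @param de A DE tibble (`gene_id`, `replicon_id`, `log2fc`, `pvalue`).
#' @param alpha Significance level applied to (possibly adjusted)
#'   p-values.
#' @param fc_threshold Minimum absolute log2 fold change (default 0).
#' @param adjust `"none"` (raw p, mirroring a plain P <= 0.05 rule) or
#'   `"BH"` (Benjamini-Hochberg adjustment before thresholding,
#'   recommended).
#' @return The significant subset of `de`, with attributes `alpha`,
#'   `fc_threshold` and `adjust`.
#' @export
significant_set <- function(de, alpha = 0.05, fc_threshold = 0,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  check_columns(de, c("gene_id", "log2fc", "pvalue"), "DE table")
  stopifnot(alpha > 0, alpha <= 1)
  p <- if (adjust == "BH") p.adjust(de$pvalue, method = "BH") else de$pvalue
  out <- de[p <= alpha & abs(de$log2fc) >= fc_threshold, , drop = FALSE]
  attr(out, "alpha") <- alpha
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "adjust") <- adjust
  out
}

#' Venn partition of 2 to 4 gene sets
#'
#' Counts the disjoint regions of the Venn diagram of the given sets.
#'
#' @param sets Named list of 2-4 character vectors.
#' @return A tibble with one row per non-empty membership pattern
#'   (2^k - 1 rows): one logical column per set, a `region` label such as
#'   `"A&B"`, and `count`. Counts sum to the size of the union (stored in
#'   attribute `union_size`).
#' @export
venn <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 4L) stop_ecr("venn() takes between 2 and 4 sets")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop_ecr("sets must be named")
  }
  sets <- map(sets, unique)
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1,
                                             dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(patterns) <- names(sets)
  key <- apply(memb, 1, paste, collapse = ",")
  counts <- table(key)
  out <- as_tibble(patterns) |>
    mutate(
      region = apply(patterns, 1, function(r) {
        paste(names(sets)[as.logical(r)], collapse = "&")
      }),
      count = {
        pk <- apply(patterns, 1, paste, collapse = ",")
        as.integer(ifelse(pk %in% names(counts), counts[pk], 0L))
      }
    )
  attr(out, "union_size") <- length(universe)
  out
}

#' Fold-change correlation between two strains
#'
#' Pearson correlation of log2 fold changes over the genes shared by two
#' DE tables (all genes, not only significant ones).
#'
#' @param x,y DE tibbles with `gene_id` and `log2fc`.
#' @return One-row tibble: `r`, `n_shared`, `p_value`, `n_only_x`,
#'   `n_only_y`. `r` and `p_value` are `NA` when either vector has zero
#'   variance (reported in `note`).
#' @export
fc_correlation <- function(x, y) {
  check_columns(x, c("gene_id", "log2fc"), "DE table x")
  check_columns(y, c("gene_id", "log2fc"), "DE table y")
  shared <- inner_join(select(x, "gene_id", fc_x = "log2fc"),
                       select(y, "gene_id", fc_y = "log2fc"), by = "gene_id")
  if (nrow(shared) < 3L) stop_ecr("fewer than 3 shared genes")
  n_only_x <- nrow(x) - nrow(shared)
  n_only_y <- nrow(y) - nrow(shared)
  if (stats::sd(shared$fc_x) == 0 || stats::sd(shared$fc_y) == 0) {
    return(tibble(r = NA_real_, n_shared = nrow(shared), p_value = NA_real_,
                  n_only_x = n_only_x, n_only_y = n_only_y,
                  note = "zero variance"))
  }
  ct <- cor.test(shared$fc_x, shared$fc_y, method = "pearson",
                 alternative = "two.sided")
  tibble(r = unname(ct$estimate), n_shared = nrow(shared),
         p_value = ct$p.value, n_only_x = n_only_x, n_only_y = n_only_y,
         note = NA_character_)
}

#' Hypergeometric category enrichment of a gene set
#'
#' Upper-tail hypergeometric test P(X >= k) for each category, with
#' Benjamini-Hochberg adjustment across categories.
#'
#' @param genes Character vector of significant genes (or a tibble with a
#'   `gene_id` column), a subset of `population`.
#' @param categories Tibble with columns `gene_id`, `category` mapping
#'   population genes to categories (a gene may belong to several).
#' @param population Character vector: all genes eligible for selection.
#' @return A tibble with one row per category: `category`, `N`
#'   (population size), `K` (category size in the population), `n` (draw
#'   size), `k` (overlap), `p_value`, `q_value`. Categories with no
#'   population members are skipped with a warning.
#' @export
enrichment <- function(genes, categories, population) {
  if (is.data.frame(genes)) genes <- genes$gene_id
  genes <- unique(genes)
  population <- unique(population)
  if (!all(genes %in% population)) {
    stop_ecr("significant genes must be a subset of the population")
  }
  check_columns(categories, c("gene_id", "category"), "category map")
  N <- length(population)
  n_draw <- length(genes)
  cats <- split(categories$gene_id, categories$category)
  rows <- imap(cats, function(members, cat) {
    K <- length(intersect(unique(members), population))
    if (K == 0L) {
      warn(sprintf("category '%s' has no members in the population; skipped", cat))
      return(NULL)
    }
    k <- length(intersect(unique(members), genes))
    tibble(category = cat, N = N, K = K, n = n_draw, k = k,
           p_value = phyper(k - 1, K, N - K, n_draw, lower.tail = FALSE))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) return(out)
  mutate(out, q_value = p.adjust(.data$p_value, method = "BH"))
}

#' Per-gene RPKM
#'
#' RPKM = reads x 10^9 / (length_bp x library_size): reads per kilobase
#' of feature per million mapped reads.
#'
#' @param counts Tibble with columns `gene_id`, `replicon_id`, `reads`,
#'   `length_bp`.
#' @param library_size Total mapped reads; defaults to `sum(reads)`.
#' @return The input with an `rpkm` column appended.
#' @export
rpkm <- function(counts, library_size = NULL) {
  check_columns(counts, c("gene_id", "replicon_id", "reads", "length_bp"),
                "counts table")
  if (any(counts$length_bp <= 0)) stop_ecr("gene lengths must be positive")
  lib <- library_size %||% sum(counts$reads)
  if (lib <= 0) stop_ecr("library size must be positive")
  mutate(counts, rpkm = .data$reads * 1e9 / (.data$length_bp * lib))
}

#' Per-replicon RPKM summary
#'
#' Median per-gene RPKM for each replicon, and (when a chromosome id is
#' given) the ratio of each replicon's median to the chromosome's, which
#' operationalizes statements like "the plasmid's expression level is
#' about 50% lower than the chromosome's".
#'
#' @param gene_rpkm Output of [rpkm()].
#' @param chromosome_id Optional chromosome id.
#' @return A tibble with `replicon_id`, `n_genes`, `median_rpkm` and
#'   (optionally) `ratio_to_chromosome`.
#' @export
rpkm_replicon_summary <- function(gene_rpkm, chromosome_id = NULL) {
  check_columns(gene_rpkm, c("replicon_id", "rpkm"), "RPKM table")
  out <- gene_rpkm |>
    group_by(.data$replicon_id) |>
    summarise(n_genes = n(), median_rpkm = median(.data$rpkm),
              .groups = "drop")
  if (!is.null(chromosome_id)) {
    if (!chromosome_id %in% out$replicon_id) {
      stop_ecr("chromosome '", chromosome_id, "' absent from the table")
    }
    chr_med <- out$median_rpkm[out$replicon_id == chromosome_id]
    out <- mutate(out, ratio_to_chromosome = .data$median_rpkm / chr_med)
  }
  out
}
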