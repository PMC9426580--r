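# Relative synonymous codon usage (RSCU) and chromid/plasmid
# classification.
#
# RSCU_c = x_c * n_aa / sum(x_c' over the synonymous family), so a codon
# used exactly as often as its synonyms scores 1. ATG and TGG (single-codon
# families under the bacterial code, table 11) and the stop codons carry no
# usage signal and are excluded, leaving 59 informative sense codons.

# codon -> amino acid for the 61 sense codons (table 11 agrees with the
# standard code on all sense codons).
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  tibble(codon = names(gc), amino_acid = unname(gc)) |>
    filter(.data$amino_acid != "*")
}

informative_codons <- function() {
  ct <- codon_table()
  ct$codon[!ct$codon %in% c("ATG", "TGG")]
}

#' Count codons in coding sequences
#'
#' Tallies sense-codon occurrences over one or more in-frame coding
#' sequences. Codons containing ambiguous (non-ACGT) bases and stop codons
#' are skipped; a trailing partial codon is ignored.
#'
#' @param seqs A character vector or [Biostrings::DNAStringSet] of CDS
#'   sequences (already phase-adjusted and strand-corrected).
#' @return A named integer vector of counts over the 61 sense codons.
#' @export
count_codons <- function(seqs) {
  seqs <- as.character(seqs)
  sense <- codon_table()$codon
  counts <- setNames(integer(length(sense)), sense)
  for (s in seqs) {
    s <- str_to_upper(s)
    n_codon <- nchar(s) %/% 3L
    if (n_codon == 0L) next
    codons <- substring(s, 3L * (seq_len(n_codon) - 1L) + 1L, 3L * seq_len(n_codon))
    codons <- codons[codons %in% sense]  # drops stops and ambiguous codons
    tab <- table(codons)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  counts
}

#' RSCU profile from codon counts
#'
#' Computes RSCU over the 59 informative sense codons. Families with zero
#' observed codons have undefined RSCU, recorded as `NA` (not 0).
#'
#' @param counts Named numeric vector of sense-codon counts (codons absent
#'   from the vector count as 0).
#' @param owner_id Optional id (gene or replicon) stored as an attribute.
#' @return A tibble with columns `codon`, `amino_acid`, `count`, `rscu`.
#' @export
rscu_of_counts <- function(counts, owner_id = NULL) {
  if (any(counts < 0)) stop_ecr("negative codon counts")
  ct <- filter(codon_table(), .data$codon %in% informative_codons())
  x <- setNames(numeric(nrow(ct)), ct$codon)
  shared <- intersect(names(counts), names(x))
  x[shared] <- counts[shared]
  out <- ct |>
    mutate(count = unname(x[.data$codon])) |>
    group_by(.data$amino_acid) |>
    mutate(rscu = if (sum(.data$count) > 0) {
      .data$count * dplyr::n() / sum(.data$count)
    } else NA_real_) |>
    ungroup() |>
    arrange(.data$codon)
  attr(out, "owner_id") <- owner_id
  out
}

#' Per-replicon RSCU profiles
#'
#' Pools codon counts over all usable CDSs of each replicon (pooled
#' counts, not per-gene averages) and normalizes once per replicon.
#'
#' @param genome A `replicon_set`.
#' @param min_codons Minimum CDS length in codons for a CDS to be used.
#' @return A tibble with columns `replicon_id`, `codon`, `amino_acid`,
#'   `count`, `rscu`.
#' @export
replicon_rscu <- function(genome, min_codons = 6L) {
  stopifnot(inherits(genome, "replicon_set"))
  seqs <- cds_sequences(genome)
  out <- map(genome$replicons$replicon_id, function(rid) {
    genes <- genome$cds$gene_id[genome$cds$replicon_id == rid]
    use <- genes[Biostrings::width(seqs[genes]) >= 3L * min_codons]
    if (length(use) == 0L) {
      stop_ecr(sprintf("replicon '%s' has no usable CDS (>= %d codons)",
                       rid, min_codons))
    }
    rscu_of_counts(count_codons(seqs[use]), owner_id = rid) |>
      mutate(replicon_id = rid, .before = 1)
  })
  bind_rows(out)
}

# Long profile tibble -> replicons x 59 matrix; undefined families imputed
# at the no-bias value 1.
rscu_matrix <- function(profiles) {
  check_columns(profiles, c("replicon_id", "codon", "rscu"), "RSCU profile table")
  wide <- profiles |>
    select("replicon_id", "codon", "rscu") |>
    pivot_wider(names_from = "codon", values_from = "rscu") |>
    arrange(.data$replicon_id)
  m <- as.matrix(wide[, informative_codons(), drop = FALSE])
  rownames(m) <- wide$replicon_id
  m[is.na(m)] <- 1
  m
}

#' Cluster replicons by codon usage and classify chromids vs. plasmids
#'
#' Agglomerative clustering of per-replicon RSCU vectors. A replicon is
#' called a chromid when its cophenetic distance to the chromosome is at
#' most `tau` times the tree's maximum cophenetic distance, otherwise a
#' plasmid. Input rows are ordered lexicographically by id before
#' clustering so that ties resolve deterministically.
#'
#' @param profiles Long RSCU tibble from [replicon_rscu()] (or any tibble
#'   with `replicon_id`, `codon`, `rscu`).
#' @param chromosome_id Id of the chromosome replicon.
#' @param metric Distance metric passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`, i.e. UPGMA).
#' @param tau Chromid threshold as a fraction of the maximum cophenetic
#'   distance.
#' @return A `replicon_clustering` object with components `hclust`,
#'   `newick`, `classification` (tibble: `replicon_id`,
#'   `dist_to_chromosome`, `class`) and `params`. `tidy()`, `glance()` and
#'   `autoplot()` methods are available.
#' @export
cluster_replicons <- function(profiles, chromosome_id,
                              metric = "euclidean", linkage = "average",
                              tau = 0.5) {
  m <- rscu_matrix(profiles)
  if (nrow(m) < 2L) stop_ecr("need at least 2 replicon profiles to cluster")
  if (!chromosome_id %in% rownames(m)) {
    stop_ecr("chromosome_id '", chromosome_id, "' not among the profiles")
  }
  ok_metrics <- c("euclidean", "maximum", "manhattan", "canberra", "minkowski")
  if (!metric %in% ok_metrics) stop_ecr("unknown metric '", metric, "'")
  m <- m[order(rownames(m)), , drop = FALSE]
  d <- dist(m, method = metric)
  hc <- hclust(d, method = linkage)
  coph <- as.matrix(cophenetic(hc))
  max_h <- max(coph)
  dist_chr <- coph[chromosome_id, ]
  cls <- tibble(
    replicon_id = rownames(coph),
    dist_to_chromosome = unname(dist_chr),
    class = ifelse(rownames(coph) == chromosome_id, "chromosome",
                   ifelse(dist_chr <= tau * max_h, "chromid", "plasmid"))
  )
  structure(
    list(
      hclust = hc,
      newick = ape::write.tree(hclust_to_phylo(hc)),
      classification = cls,
      params = list(chromosome_id = chromosome_id, metric = metric,
                    linkage = linkage, tau = tau, max_cophenetic = max_h)
    ),
    class = "replicon_clustering"
  )
}

hclust_to_phylo <- function(hc) {
  if (length(hc$labels) == 2L) {
    # ape::as.phylo needs >= 3 leaves; build the 2-leaf tree directly
    h <- hc$height / 2
    return(ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
                                         hc$labels[1], h, hc$labels[2], h)))
  }
  ape::as.phylo(hc)
}

#' @export
print.replicon_clustering <- function(x, ...) {
  cat("<replicon_clustering>\n")
  cat("  ", x$newick, "\n", sep = "")
  print(x$classification)
  invisible(x)
}

#' @rdname cluster_replicons
#' @param x A `replicon_clustering` object.
#' @param ... Unused.
#' @export
tidy.replicon_clustering <- function(x, ...) x$classification

#' @rdname cluster_replicons
#' @export
glance.replicon_clustering <- function(x, ...) {
  tibble(
    n_replicons = nrow(x$classification),
    n_chromids = sum(x$classification$class == "chromid"),
    n_plasmids = sum(x$classification$class == "plasmid"),
    max_cophenetic = x$params$max_cophenetic,
    metric = x$params$metric,
    linkage = x$params$linkage,
    tau = x$params$tau
  )
}
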