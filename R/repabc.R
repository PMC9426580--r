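# RepABC compatibility-group typing.
#
# RepA/RepB (partitioning) and RepC (replicase) protein families are
# compared by p-distance, summarized as neighbor-joining trees, and their
# incongruence is scored by the Robinson-Foulds distance. Compatibility
# groups follow the partitioning proteins only: the averaged RepA/RepB
# distance matrix is clustered and cut at a configurable height.

#' Pairwise p-distances within a protein family
#'
#' For unaligned input every pair is globally aligned first (simple
#' match/mismatch scores with affine gaps); the p-distance is then the
#' number of mismatching columns divided by the number of columns where
#' both sequences have a residue.
#'
#' @param seqs Named character vector or [Biostrings::AAStringSet]. For
#'   `aligned = TRUE` all sequences must have equal length (gaps `-`).
#' @param aligned Are the sequences already aligned?
#' @param match,mismatch,gap_open,gap_extend Alignment scores used when
#'   `aligned = FALSE` (penalties given as positive numbers).
#' @return A symmetric numeric matrix with zero diagonal and values in
#'   \[0, 1\], dimnames = sequence names. For unaligned input the
#'   pairwise alignment scores are attached as attribute `"scores"`.
#' @export
pairwise_distances <- function(seqs, aligned = FALSE, match = 1,
                               mismatch = -1, gap_open = 5, gap_extend = 1) {
  seqs <- setNames(as.character(seqs), names(seqs))
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop_ecr("sequences must be named")
  }
  if (any(gsub("-", "", seqs) == "")) stop_ecr("empty sequence in family")
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  scores <- matrix(NA_real_, n, n, dimnames = dimnames(d))
  if (aligned && length(unique(nchar(seqs))) != 1L) {
    stop_ecr("aligned sequences must have equal lengths")
  }
  submat <- NULL
  if (!aligned) {
    letters_aa <- unique(unlist(strsplit(seqs, "")))
    submat <- matrix(mismatch, length(letters_aa), length(letters_aa),
                     dimnames = list(letters_aa, letters_aa))
    diag(submat) <- match
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (aligned) {
        a <- strsplit(seqs[[i]], "")[[1]]
        b <- strsplit(seqs[[j]], "")[[1]]
      } else {
        aln <- Biostrings::pairwiseAlignment(
          seqs[[i]], seqs[[j]], type = "global",
          substitutionMatrix = submat,
          gapOpening = gap_open, gapExtension = gap_extend)
        a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
        b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
        scores[i, j] <- scores[j, i] <- Biostrings::score(aln)
      }
      both <- a != "-" & b != "-"
      d[i, j] <- d[j, i] <- if (sum(both) == 0) 1 else {
        sum(a[both] != b[both]) / sum(both)
      }
    }
  }
  if (!aligned) attr(d, "scores") <- scores
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Wraps [ape::nj()] with deterministic label ordering (matrix rows sorted
#' lexicographically before agglomeration) and clamps negative branch
#' lengths to zero with a warning. Additive distance matrices are
#' recovered exactly.
#'
#' @param d Symmetric distance matrix (or `dist`) over at least 4 taxa.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop_ecr("distance matrix must be symmetric")
  if (nrow(d) < 4L) stop_ecr("neighbor joining needs at least 4 taxa")
  ord <- order(rownames(d))
  tr <- ape::nj(d[ord, ord])
  if (any(tr$edge.length < 0)) {
    warn("negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

# Non-trivial bipartitions of an unrooted tree as canonical membership
# strings over the (sorted) leaf set.
tree_bipartitions <- function(tree, leaves = sort(tree$tip.label)) {
  n_tip <- length(tree$tip.label)
  tip_of <- match(tree$tip.label, leaves)
  # leaves under each internal node via postorder accumulation
  post <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) below[[i]] <- tip_of[i]
  for (k in seq_len(nrow(post$edge))) {
    par <- post$edge[k, 1]; child <- post$edge[k, 2]
    below[[par]] <- c(below[[par]], below[[child]])
  }
  internal <- unique(post$edge[, 1])
  splits <- character(0)
  for (node in internal) {
    memb <- logical(length(leaves))
    memb[below[[node]]] <- TRUE
    size <- sum(memb)
    if (size <= 1L || size >= length(leaves) - 1L) next  # trivial
    if (memb[1]) memb <- !memb  # canonical side: excludes first leaf
    splits <- c(splits, paste(as.integer(memb), collapse = ""))
  }
  unique(splits)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the sets of non-trivial bipartitions, computed
#' by direct bipartition enumeration. Both trees must share the same leaf
#' set.
#'
#' @param t1,t2 [ape::phylo] trees on identical leaf sets.
#' @return A one-row tibble with `rf`, `max_rf` (total number of
#'   non-trivial bipartitions in the two trees) and `normalized`
#'   (`rf / max_rf`; 0 when both trees are stars).
#' @export
rf_distance <- function(t1, t2) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    stop_ecr("leaf sets differ: only in tree 1: {",
             paste(setdiff(l1, l2), collapse = ", "), "}; only in tree 2: {",
             paste(setdiff(l2, l1), collapse = ", "), "}")
  }
  s1 <- tree_bipartitions(t1, l1)
  s2 <- tree_bipartitions(t2, l1)
  rf <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  max_rf <- length(s1) + length(s2)
  tibble(rf = rf, max_rf = max_rf,
         normalized = if (max_rf > 0) rf / max_rf else 0)
}

#' Type RepABC modules into compatibility groups
#'
#' Groups taxa by their partitioning proteins only: the RepA and RepB
#' p-distance matrices (restricted to shared taxa) are averaged,
#' clustered by average linkage, and cut at `cut_height`. The RepA-vs-RepB
#' Robinson-Foulds distance is reported as a congruence check, and when a
#' RepC family is supplied, the RepAB-vs-RepC distance as the
#' incongruence score expected of independently exchanged replicases.
#'
#' @param repa,repb,repc Named sequence vectors (or `AAStringSet`) for
#'   each family; `repc` may be `NULL`. At least 4 taxa must be shared.
#' @param cut_height Height at which the average-linkage dendrogram of
#'   the averaged RepA/RepB distances is cut.
#' @param aligned Are the families already aligned (see
#'   [pairwise_distances()])?
#' @param ... Alignment scores passed to [pairwise_distances()].
#' @return A `compatibility_typing` object: list with `groups` (tibble:
#'   `taxon`, `group`), `congruence` (tibble of RF comparisons), `trees`
#'   (named list of `phylo`: repa, repb, repab, repc) and `params`.
#'   `tidy()` returns the groups, `glance()` a one-row summary.
#' @export
compatibility_groups <- function(repa, repb, repc = NULL, cut_height,
                                 aligned = FALSE, ...) {
  repa <- setNames(as.character(repa), names(repa))
  repb <- setNames(as.character(repb), names(repb))
  if (!is.null(repc)) repc <- setNames(as.character(repc), names(repc))
  taxa <- intersect(names(repa), names(repb))
  if (!is.null(repc)) taxa <- intersect(taxa, names(repc))
  taxa <- sort(taxa)
  if (length(taxa) < 4L) stop_ecr("need at least 4 shared taxa across families")
  da <- pairwise_distances(repa[taxa], aligned = aligned, ...)
  db <- pairwise_distances(repb[taxa], aligned = aligned, ...)
  dab <- (da + db) / 2
  hc <- hclust(stats::as.dist(dab), method = "average")
  if (cut_height < 0 || cut_height > max(hc$height)) {
    warn(sprintf(paste0("cut_height %.3g outside the observed merge-height ",
                        "range [0, %.3g]; grouping is all-singleton or ",
                        "a single group"), cut_height, max(hc$height)))
  }
  grp <- cutree(hc, h = cut_height)
  trees <- list(repa = nj_tree(da), repb = nj_tree(db), repab = nj_tree(dab))
  congruence <- bind_rows(
    mutate(rf_distance(trees$repa, trees$repb), comparison = "RepA vs RepB",
           .before = 1))
  if (!is.null(repc)) {
    dc <- pairwise_distances(repc[taxa], aligned = aligned, ...)
    trees$repc <- nj_tree(dc)
    congruence <- bind_rows(
      congruence,
      mutate(rf_distance(trees$repab, trees$repc),
             comparison = "RepAB vs RepC", .before = 1))
  }
  structure(
    list(
      groups = tibble(taxon = names(grp), group = unname(grp)),
      congruence = congruence,
      trees = trees,
      params = list(cut_height = cut_height, n_taxa = length(taxa))
    ),
    class = "compatibility_typing"
  )
}

#' @export
print.compatibility_typing <- function(x, ...) {
  cat(sprintf("<compatibility_typing> %d taxa, %d group(s), cut height %.3g\n",
              x$params$n_taxa, max(x$groups$group), x$params$cut_height))
  print(x$congruence)
  invisible(x)
}

#' @rdname compatibility_groups
#' @param x A `compatibility_typing` object.
#' @export
tidy.compatibility_typing <- function(x, ...) x$groups

#' @rdname compatibility_groups
#' @export
glance.compatibility_typing <- function(x, ...) {
  rfab <- x$congruence[x$congruence$comparison == "RepA vs RepB", ]
  rfc <- x$congruence[x$congruence$comparison == "RepAB vs RepC", ]
  tibble(
    n_taxa = x$params$n_taxa,
    n_groups = max(x$groups$group),
    cut_height = x$params$cut_height,
    rf_repa_repb = rfab$rf,
    rf_repab_repc = if (nrow(rfc) > 0) rfc$rf else NA_integer_
  )
}
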