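# Synthetic-data generators.
#
# Every generator emulates the statistical structure one analysis stage
# assumes -- codon-usage bias per replicon, depth given copy number x
# prevalence, Bernoulli colony assays, passage-wise segregational loss,
# correlated cross-strain log2FC tables with a shared regulon, and
# RepA/RepB/RepC families evolved on congruent vs. swapped topologies
# with group-specific palindromes. All generators are deterministic under
# a seed. Defaults are a scaled-down analogue of a six-ECR
# Rhodobacterales genome with a half-prevalent single-copy plasmid; see
# the methods vignette for the rationale behind each value.

default_replicon_spec <- function() {
  tibble(
    replicon_id = c("chromosome", "chromid_a", "chromid_b",
                    "plasmid_191k", "plasmid_126k", "plasmid_86k",
                    "plasmid_102k"),
    n_genes = c(120L, 25L, 20L, 35L, 25L, 20L, 25L),
    gene_length_codons = 200L,
    copy_number = 1L,
    prevalence = c(1, 1, 1, 1, 1, 1, 0.5),
    alpha = 0.3,
    bias_from = c(NA, "chromosome", "chromosome", NA, NA, NA, NA),
    declared_role = c("chromosome", "chromid", "chromid",
                      "plasmid", "plasmid", "plasmid", "plasmid")
  )
}

#' Simulate a multi-replicon genome with replicon-specific codon bias
#'
#' Each replicon draws one synonymous-codon distribution per amino-acid
#' family from a symmetric Dirichlet(alpha) and then samples its CDSs
#' codon-wise from it, so small `alpha` produces strong codon bias and
#' large `alpha` near-uniform usage. A replicon may instead inherit
#' another replicon's bias (`bias_from`), which makes chromids
#' chromosome-like while independent draws make plasmids alien. Every CDS
#' starts with ATG, ends with a single stop, and has length divisible
#' by 3.
#'
#' @param replicons Tibble with columns `replicon_id`, `n_genes`,
#'   `gene_length_codons`, `alpha` (> 0), optional `bias_from` and
#'   `declared_role`. The default is a scaled-down six-ECR genome whose
#'   chromids share the chromosome's bias.
#' @param seed Seed; the same seed reproduces the output exactly.
#' @return A `replicon_set` with an extra attribute `bias` (the per-
#'   replicon codon distributions used).
#' @export
simulate_replicon_set <- function(replicons = default_replicon_spec(),
                                  seed = NULL) {
  check_columns(replicons, c("replicon_id", "n_genes", "gene_length_codons",
                             "alpha"), "replicon spec")
  if (any(replicons$alpha <= 0)) stop_ecr("alpha must be positive")
  if (!"bias_from" %in% names(replicons)) replicons$bias_from <- NA_character_
  if (!"declared_role" %in% names(replicons)) {
    replicons$declared_role <- "unknown"
  }
  ct <- filter(codon_table(), !.data$codon %in% c("ATG", "TGG"))
  fams <- split(ct$codon, ct$amino_acid)
  with_seed(seed, {
    bias <- list()
    for (i in seq_len(nrow(replicons))) {
      rid <- replicons$replicon_id[i]
      src <- replicons$bias_from[i]
      if (!is.na(src)) {
        if (is.null(bias[[src]])) {
          stop_ecr("bias_from '", src, "' must be defined earlier in the spec")
        }
        bias[[rid]] <- bias[[src]]
      } else {
        a <- replicons$alpha[i]
        bias[[rid]] <- map(fams, function(codons) {
          w <- rgamma(length(codons), shape = a)
          setNames(w / sum(w), codons)
        })
      }
    }
    seqs <- character(nrow(replicons))
    cds_rows <- list()
    for (i in seq_len(nrow(replicons))) {
      rid <- replicons$replicon_id[i]
      b <- bias[[rid]]
      aas <- names(fams)
      genes <- character(replicons$n_genes[i])
      for (g in seq_len(replicons$n_genes[i])) {
        len <- replicons$gene_length_codons[i]
        aa_seq <- sample(aas, len, replace = TRUE)
        codons <- vapply(aa_seq, function(aa) {
          sample(names(b[[aa]]), 1L, prob = b[[aa]])
        }, character(1))
        genes[g] <- paste0("ATG", paste(codons, collapse = ""), "TAA")
      }
      lens <- nchar(genes)
      ends <- cumsum(lens)
      cds_rows[[i]] <- tibble(
        gene_id = sprintf("%s_g%03d", rid, seq_along(genes)),
        replicon_id = rid,
        start = ends - lens,
        end = ends,
        strand = "+",
        phase = 0L
      )
      seqs[i] <- paste(genes, collapse = "")
    }
    genome <- replicon_set(
      setNames(seqs, replicons$replicon_id),
      bind_rows(cds_rows),
      roles = setNames(replicons$declared_role, replicons$replicon_id)
    )
    attr(genome, "bias") <- bias
    genome
  })
}

#' Simulate per-window sequencing depth
#'
#' Window depths are Poisson with mean
#' `depth_mean_per_copy * copy_number * prevalence`, so the expected
#' replicon:chromosome depth ratio equals (c_i p_i) / (c_chr p_chr). An
#' optional negative-binomial dispersion knob adds overdispersion
#' (default off).
#'
#' @param replicons Tibble with `replicon_id`, `copy_number`,
#'   `prevalence` (the default spec's plasmid_102k has c = 1, p = 0.5).
#' @param depth_mean_per_copy Mean window depth contributed by one copy
#'   per cell.
#' @param n_windows Windows per replicon.
#' @param window_bp Window width used for the coordinate columns.
#' @param dispersion NB size parameter; `Inf` (default) gives pure
#'   Poisson.
#' @param seed Seed.
#' @return A windowed depth tibble (`replicon_id`, `window_start`,
#'   `window_end`, `depth`).
#' @export
simulate_depth <- function(replicons = default_replicon_spec(),
                           depth_mean_per_copy = 100, n_windows = 500L,
                           window_bp = 1000L, dispersion = Inf,
                           seed = NULL) {
  check_columns(replicons, c("replicon_id", "copy_number", "prevalence"),
                "replicon spec")
  if (depth_mean_per_copy <= 0) stop_ecr("depth_mean_per_copy must be positive")
  stopifnot(all(replicons$prevalence >= 0 & replicons$prevalence <= 1),
            all(replicons$copy_number >= 1))
  with_seed(seed, {
    rows <- map(seq_len(nrow(replicons)), function(i) {
      m <- depth_mean_per_copy * replicons$copy_number[i] *
        replicons$prevalence[i]
      d <- if (is.infinite(dispersion)) {
        rpois(n_windows, m)
      } else {
        stats::rnbinom(n_windows, size = dispersion, mu = m)
      }
      tibble(
        replicon_id = replicons$replicon_id[i],
        window_start = (seq_len(n_windows) - 1L) * window_bp,
        window_end = seq_len(n_windows) * window_bp,
        depth = as.double(d)
      )
    })
    bind_rows(rows)
  })
}

#' Simulate a Bernoulli colony assay
#'
#' @param n Number of colonies tested (>= 1).
#' @param carriage_prob True probability that a colony carries the
#'   replicon.
#' @param seed Seed.
#' @param label Assay label.
#' @return A one-row assay tibble (`label`, `n_tested`, `n_positive`).
#' @export
simulate_colony_assay <- function(n, carriage_prob, seed = NULL,
                                  label = "assay") {
  stopifnot(n >= 1, carriage_prob >= 0, carriage_prob <= 1)
  with_seed(seed, tibble(label = label, n_tested = as.integer(n),
                         n_positive = rbinom(1L, n, carriage_prob)))
}

#' Simulate a plasmid-stability passaging experiment
#'
#' Applies the deterministic prevalence recursion of
#' [project_prevalence()] generation by generation, with binomial
#' sampling of the carrier fraction at each transfer bottleneck, and
#' finishes with a Bernoulli colony assay of the final population.
#'
#' @param loss_rate Per-generation segregational loss probability.
#' @param fitness_cost Selective advantage of plasmid-free cells.
#' @param p0 Initial carrier fraction.
#' @param generations Total generations (>= 0).
#' @param transfer_every Generations between transfer bottlenecks
#'   (`NULL` for no bottleneck sampling).
#' @param bottleneck_size Number of founder cells at each transfer.
#' @param n_colonies Colonies tested at the end point.
#' @param seed Seed.
#' @return A list with `trajectory` (tibble: `generation`, `prevalence`)
#'   and `assay` (one-row assay tibble), plus the parameters used.
#' @export
simulate_passaging <- function(loss_rate, fitness_cost = 0, p0 = 1,
                               generations, transfer_every = NULL,
                               bottleneck_size = 1e4L, n_colonies = 450L,
                               seed = NULL) {
  stopifnot(loss_rate >= 0, loss_rate <= 1, p0 >= 0, p0 <= 1,
            generations >= 0)
  with_seed(seed, {
    p <- numeric(generations + 1)
    p[1] <- p0
    if (generations > 0) {
      for (t in seq_len(generations)) {
        kept <- p[t] * (1 - loss_rate)
        pt <- kept / (kept + (1 - kept) * (1 + fitness_cost))
        if (!is.null(transfer_every) && t %% transfer_every == 0L) {
          pt <- rbinom(1L, bottleneck_size, pt) / bottleneck_size
        }
        p[t + 1] <- pt
      }
    }
    list(
      trajectory = tibble(generation = 0:generations, prevalence = p),
      assay = simulate_colony_assay(n_colonies, p[generations + 1],
                                    label = "endpoint"),
      params = list(loss_rate = loss_rate, fitness_cost = fitness_cost,
                    p0 = p0, generations = generations)
    )
  })
}

# Largest whole-table correlation attainable for a given regulon fraction
# and effect/null SDs (all regulon effects perfectly correlated).
max_attainable_rho <- function(f, effect_sd, null_sd) {
  f * effect_sd^2 / (f * effect_sd^2 + (1 - f) * null_sd^2)
}

#' Simulate correlated differential-expression tables
#'
#' Generates one DE table per strain. A shared regulon of
#' `regulon_size` genes receives effects drawn from an equicorrelated
#' multivariate normal across strains, with the effect correlation chosen
#' in closed form so that the expected whole-table Pearson correlation
#' between any two strains equals `rho_target`; the remaining genes get
#' independent null noise. P-values are Beta(0.05, 1) for regulon genes
#' and Uniform(0, 1) for null genes.
#'
#' @param n_genes Genes per table.
#' @param regulon_size Number of shared-regulon genes.
#' @param rho_target Target whole-table Pearson correlation in \[0, 1\].
#'   Must not exceed the attainable maximum
#'   `f * effect_sd^2 / (f * effect_sd^2 + (1-f) * null_sd^2)` with
#'   `f = regulon_size / n_genes`; otherwise the attainable range is
#'   reported in the error.
#' @param effect_sd,null_sd Standard deviations of regulon effects and
#'   null noise (log2FC units).
#' @param strains Character vector of strain labels (>= 2).
#' @param seed Seed.
#' @return Named list of DE tibbles (`gene_id`, `replicon_id`, `log2fc`,
#'   `pvalue`), one per strain.
#' @export
simulate_de_tables <- function(n_genes = 3668L, regulon_size = 900L,
                               rho_target = 0.76, effect_sd = 2,
                               null_sd = 0.5,
                               strains = c("strain_a", "strain_b"),
                               seed = NULL) {
  stopifnot(rho_target >= 0, rho_target <= 1, regulon_size <= n_genes,
            length(strains) >= 2)
  f <- regulon_size / n_genes
  rho_max <- max_attainable_rho(f, effect_sd, null_sd)
  if (rho_target > rho_max) {
    stop_ecr(sprintf(
      "rho_target %.3f is not attainable; with these settings the whole-table correlation can reach at most %.3f (attainable range [0, %.3f])",
      rho_target, rho_max, rho_max))
  }
  rho_e <- rho_target / rho_max  # effect-level correlation
  with_seed(seed, {
    genes <- sprintf("gene_%05d", seq_len(n_genes))
    in_regulon <- seq_len(n_genes) <= regulon_size
    shared <- rnorm(regulon_size)
    tables <- map(strains, function(st) {
      fc <- numeric(n_genes)
      own <- rnorm(regulon_size)
      fc[in_regulon] <- effect_sd * (sqrt(rho_e) * shared +
                                       sqrt(1 - rho_e) * own)
      fc[!in_regulon] <- rnorm(n_genes - regulon_size, sd = null_sd)
      pv <- numeric(n_genes)
      pv[in_regulon] <- rbeta(regulon_size, 0.05, 1)
      pv[!in_regulon] <- runif(n_genes - regulon_size)
      tibble(gene_id = genes, replicon_id = "chromosome",
             log2fc = fc, pvalue = pv)
    })
    setNames(tables, strains)
  })
}

# Build a binary guide topology with n_groups clades (caterpillar within
# each clade) and the given branch lengths, as an ape phylo.
build_group_tree <- function(groups, within_bl, between_bl) {
  # caterpillar subtree; the returned string carries no outer branch length
  clade_str <- function(taxa) {
    if (length(taxa) == 1L) return(taxa)
    n <- length(taxa)
    sprintf("(%s:%f,%s:%f)", clade_str(taxa[-n]), within_bl, taxa[n], within_bl)
  }
  clades <- vapply(groups, clade_str, character(1))
  txt <- sprintf("(%s);",
                 paste(sprintf("%s:%f", clades, between_bl), collapse = ","))
  ape::read.tree(text = txt)
}

mutate_protein <- function(seq_chars, n_sub, alphabet) {
  if (n_sub == 0L) return(seq_chars)
  sites <- sample.int(length(seq_chars), n_sub, replace = TRUE)
  for (s in sites) {
    seq_chars[s] <- sample(setdiff(alphabet, seq_chars[s]), 1L)
  }
  seq_chars
}

# Evolve site-independent protein sequences down a tree: substitutions
# per branch ~ Poisson(branch_length * L), uniform over 20 letters.
evolve_on_tree <- function(tree, seq_length) {
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root]] <- sample(alphabet, seq_length, replace = TRUE)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(pre$edge))) {
    par <- pre$edge[k, 1]; child <- pre$edge[k, 2]
    n_sub <- rpois(1L, pre$edge.length[k] * seq_length)
    seqs[[child]] <- mutate_protein(seqs[[par]], n_sub, alphabet)
  }
  out <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""),
                character(1))
  setNames(out, tree$tip.label)
}

random_palindrome <- function(arm_len, loop_len) {
  arm <- paste(sample(c("A", "C", "G", "T"), arm_len, replace = TRUE),
               collapse = "")
  loop <- if (loop_len > 0) {
    paste(sample(c("A", "C", "G", "T"), loop_len, replace = TRUE),
          collapse = "")
  } else ""
  paste0(arm, loop, revcomp(arm))
}

mutate_dna <- function(x, n_mut) {
  if (n_mut == 0L) return(x)
  chars <- strsplit(x, "")[[1]]
  sites <- sample.int(length(chars), n_mut)
  for (s in sites) {
    chars[s] <- sample(setdiff(c("A", "C", "G", "T"), chars[s]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate RepA/RepB/RepC protein families with optional replicase
#' exchange
#'
#' RepA and RepB evolve on a shared guide topology (clades =
#' compatibility groups); RepC evolves on the same topology after the
#' configured taxon swaps, emulating independent exchange of the
#' replicase against the synchronously evolving partitioning operon. Each
#' group also receives a diagnostic palindrome: a group consensus is
#' embedded (with at most `palindrome_mut` point mutations per taxon) in
#' otherwise random DNA segments.
#'
#' @param n_taxa Number of taxa (>= 4), split evenly into `n_groups`
#'   clades.
#' @param n_groups Number of compatibility groups.
#' @param swap List of length-2 character vectors of taxa to exchange in
#'   the RepC topology (e.g. `list(c("t1", "t5"))`); empty for fully
#'   congruent families. Unknown taxa are an error.
#' @param seq_length Protein length (sites).
#' @param within_bl,between_bl Branch lengths (expected substitutions per
#'   site) inside clades and on the clade stems. Defaults keep pairwise
#'   divergence below the saturation range of an uncorrected p-distance.
#' @param segment_length Length of the palindrome-bearing DNA segments.
#' @param palindrome_arm,palindrome_loop Arm and loop length of each
#'   group's consensus palindrome.
#' @param palindrome_mut Maximum point mutations of the consensus per
#'   taxon.
#' @param seed Seed.
#' @return A list: `repa`, `repb`, `repc` (named character vectors of
#'   aligned protein sequences), `guide_tree` and `repc_tree`
#'   ([ape::phylo] truth topologies), `groups` (tibble: `taxon`,
#'   `group`), `segments` (named character vector of DNA segments) and
#'   `palindromes` (tibble: `group`, `consensus`).
#' @export
simulate_rep_families <- function(n_taxa = 8L, n_groups = 2L,
                                  swap = list(), seq_length = 400L,
                                  within_bl = 0.08, between_bl = 0.3,
                                  segment_length = 300L,
                                  palindrome_arm = 8L, palindrome_loop = 5L,
                                  palindrome_mut = 1L, seed = NULL) {
  if (n_taxa < 4L) stop_ecr("guide topology needs at least 4 taxa")
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  grp_id <- rep(seq_len(n_groups), length.out = n_taxa) |> sort()
  groups <- split(taxa, grp_id)
  bad <- setdiff(unlist(swap), taxa)
  if (length(bad) > 0) {
    stop_ecr("swap set references unknown taxa: ", paste(bad, collapse = ", "))
  }
  guide <- build_group_tree(groups, within_bl, between_bl)
  repc_tree <- guide
  for (pair in swap) {
    i <- match(pair[1], repc_tree$tip.label)
    j <- match(pair[2], repc_tree$tip.label)
    repc_tree$tip.label[c(i, j)] <- repc_tree$tip.label[c(j, i)]
  }
  with_seed(seed, {
    repa <- evolve_on_tree(guide, seq_length)
    repb <- evolve_on_tree(guide, seq_length)
    repc <- evolve_on_tree(repc_tree, seq_length)
    consensus <- vapply(seq_len(n_groups), function(g) {
      random_palindrome(palindrome_arm, palindrome_loop)
    }, character(1))
    segments <- vapply(seq_along(taxa), function(i) {
      pal <- mutate_dna(consensus[grp_id[i]],
                        sample.int(palindrome_mut + 1L, 1L) - 1L)
      flank_n <- segment_length - nchar(pal)
      left_n <- sample.int(flank_n - 1L, 1L)
      flank <- sample(c("A", "C", "G", "T"), flank_n, replace = TRUE)
      paste0(paste(flank[seq_len(left_n)], collapse = ""), pal,
             paste(flank[-seq_len(left_n)], collapse = ""))
    }, character(1))
    list(
      repa = repa, repb = repb, repc = repc,
      guide_tree = guide, repc_tree = repc_tree,
      groups = tibble(taxon = taxa, group = grp_id),
      segments = setNames(segments, taxa),
      palindromes = tibble(group = seq_len(n_groups), consensus = consensus)
    )
  })
}
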