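# Independent brute-force oracles used to validate the implementation.
# Each is written as a direct enumeration, deliberately sharing no code
# with the package internals.

# Exhaustive inverted-repeat scan: for every loop placement and loop
# length, try every arm length up to `max_arm` from scratch and keep the
# largest one within the mismatch budget.
brute_palindromes <- function(seq, min_arm, max_loop, max_mismatch,
                              max_arm = 25L) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A")[s]
  rows <- list()
  for (l in 0:max_loop) {
    for (j in 0:n) {
      if (j + l > n) next
      geom <- min(j, n - j - l)
      if (geom < min_arm) next
      best <- NULL
      for (a in seq_len(min(geom, max_arm))) {
        ok <- s[j - seq_len(a) + 1L] == comp[j + l + seq_len(a)]
        ok[is.na(ok)] <- FALSE
        mm <- sum(!ok)
        if (mm <= max_mismatch) best <- c(start = j - a, arm = a,
                                          loop = l, mism = mm)
      }
      if (!is.null(best) && best[["arm"]] >= min_arm) {
        rows[[length(rows) + 1L]] <- best
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(), arm = integer(),
                      loop = integer(), mism = integer()))
  }
  out <- as.data.frame(do.call(rbind, rows))
  out[order(out$start, out$loop), ]
}

# Exhaustive global-alignment score by enumerating every alignment path
# (affine gaps: a length-k gap costs gap_open + k * gap_ext; end gaps
# penalized). Exponential -- only for short strings.
brute_align_score <- function(a, b, match = 1, mismatch = -1,
                              gap_open = 5, gap_ext = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      sc <- if (a[i] == b[j]) match else mismatch
      best <- max(best, sc + rec(i + 1L, j + 1L, "m"))
    }
    if (i <= length(a)) {
      pen <- gap_ext + if (prev == "d") 0 else gap_open
      best <- max(best, -pen + rec(i + 1L, j, "d"))
    }
    if (j <= length(b)) {
      pen <- gap_ext + if (prev == "i") 0 else gap_open
      best <- max(best, -pen + rec(i, j + 1L, "i"))
    }
    best
  }
  rec(1L, 1L, "m")
}

# Venn region counts by per-element membership tabulation.
brute_venn_counts <- function(sets) {
  universe <- unique(unlist(sets))
  masks <- vapply(universe, function(el) {
    paste(as.integer(vapply(sets, function(s) el %in% s, logical(1))),
          collapse = "")
  }, character(1))
  table(masks)
}

# Upper-tail hypergeometric probability by direct combinatorial sum.
brute_hyper_upper <- function(N, K, n, k) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Clopper-Pearson endpoints by solving the exact binomial tail equations.
oracle_clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else {
    uniroot(function(p) pbinom(x - 1, n, p, lower.tail = FALSE) - a,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  hi <- if (x == n) 1 else {
    uniroot(function(p) pbinom(x, n, p) - a,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lo, hi)
}

# Small in-memory genome shared by io/rscu tests: two replicons, plus- and
# minus-strand CDSs.
toy_genome <- function() {
  # chrA: gene a1 = ATG TTA TTG CTG TAA at [0, 15); gene a2 on minus
  # strand whose coding sequence is also ATGTTATTGCTGTAA
  a1 <- "ATGTTATTGCTGTAA"
  a2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(a1)))
  chrA <- paste0(a1, a2)
  pB <- "ATGGGCGGAGGTGGCTAA"  # Gly codons GGC GGA GGT GGC
  replicon_set(
    c(chrA = chrA, pB = pB),
    tibble::tibble(
      gene_id = c("a1", "a2", "b1"),
      replicon_id = c("chrA", "chrA", "pB"),
      start = c(0L, 15L, 0L),
      end = c(15L, 30L, 18L),
      strand = c("+", "-", "+"),
      phase = 0L
    ),
    roles = c(chrA = "chromosome", pB = "plasmid")
  )
}
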