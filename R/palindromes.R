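# Inverted-repeat (palindrome) detection and consensus building.
#
# A palindromic site is a left arm, an optional loop, and a right arm
# whose reverse complement matches the left arm up to a mismatch budget.
# Such sites act as cis-acting anchors for RepB-mediated partitioning,
# and their consensus is diagnostic for a compatibility group.

# complement lookup for upper-case DNA (ambiguous bases never match)
.comp <- c(A = "T", C = "G", G = "C", T = "A")

#' Find inverted repeats in a DNA sequence
#'
#' For every loop placement (position and loop length up to `max_loop`)
#' the arms are grown outward from the loop while the cumulative number
#' of non-complementary arm pairs stays within `max_mismatch`; the site
#' with the maximal arm is reported when that arm reaches `min_arm`.
#' Since the definition is strand-symmetric, the hit set is invariant
#' under reverse-complementing the input (with positions mapped).
#'
#' @param sequence DNA string (character scalar or
#'   [Biostrings::DNAString]).
#' @param min_arm Minimum arm length (>= 3).
#' @param max_loop Maximum loop length between the arms.
#' @param max_mismatch Maximum number of mismatching arm pairs.
#' @return A tibble with columns `start` (0-based position of the left
#'   arm), `arm_length`, `loop_length`, `mismatches`, `arm` (left-arm
#'   sequence) and `site` (full site sequence).
#' @export
find_palindromes <- function(sequence, min_arm = 5L, max_loop = 10L,
                             max_mismatch = 1L) {
  if (min_arm < 3L) stop_ecr("min_arm must be at least 3")
  s <- strsplit(str_to_upper(as.character(sequence)), "")[[1]]
  n <- length(s)
  comp <- unname(.comp[s])  # NA for ambiguous bases -> never complementary
  hits <- list()
  for (loop_len in 0:max_loop) {
    for (j in seq_len(n + 1L) - 1L) {        # 0-based loop start
      if (j + loop_len > n) break
      a_max <- min(j, n - j - loop_len)
      if (a_max < min_arm) next
      mism <- 0L
      a <- 0L
      while (a < a_max) {
        # next outward pair: left s[j - a], right s[j + loop_len + a + 1] (1-based)
        pair_ok <- !is.na(comp[j + loop_len + a + 1L]) &&
          s[j - a] == comp[j + loop_len + a + 1L]
        new_mism <- mism + !pair_ok
        if (new_mism > max_mismatch) break
        mism <- new_mism
        a <- a + 1L
      }
      if (a >= min_arm) {
        hits[[length(hits) + 1L]] <- c(start = j - a, arm = a,
                                       loop = loop_len, mism = mism)
      }
    }
  }
  if (length(hits) == 0L) {
    return(tibble(start = integer(), arm_length = integer(),
                  loop_length = integer(), mismatches = integer(),
                  arm = character(), site = character()))
  }
  h <- as_tibble(do.call(rbind, hits))
  seq_str <- paste(s, collapse = "")
  h |>
    rename(arm_length = "arm", loop_length = "loop", mismatches = "mism") |>
    mutate(
      arm = str_sub(seq_str, .data$start + 1L, .data$start + .data$arm_length),
      site = str_sub(seq_str, .data$start + 1L,
                     .data$start + 2L * .data$arm_length + .data$loop_length)
    ) |>
    arrange(.data$start, .data$loop_length)
}

#' Consensus of palindromic sites
#'
#' Builds a per-column majority consensus of site sequences aligned on
#' their centers (shorter sites are padded symmetrically). Ties are
#' reported as the IUPAC ambiguity code covering the tied bases.
#'
#' @param sites Character vector of site sequences (e.g. the `site`
#'   column of [find_palindromes()]).
#' @return A single consensus string.
#' @export
palindrome_consensus <- function(sites) {
  stopifnot(length(sites) >= 1)
  sites <- str_to_upper(sites)
  width <- max(nchar(sites))
  # center-align: pad both ends; odd length differences pad right first
  padded <- vapply(sites, function(x) {
    extra <- width - nchar(x)
    left <- extra %/% 2L
    paste0(strrep("-", left), x, strrep("-", extra - left))
  }, character(1), USE.NAMES = FALSE)
  mat <- do.call(rbind, strsplit(padded, ""))
  iupac <- setNames(names(Biostrings::IUPAC_CODE_MAP),
                    Biostrings::IUPAC_CODE_MAP)
  cons <- apply(mat, 2, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) == 0L) return("-")
    tab <- table(col)
    top <- sort(names(tab)[tab == max(tab)])
    if (length(top) == 1L) top else iupac[[paste(top, collapse = "")]]
  })
  paste(cons, collapse = "")
}
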