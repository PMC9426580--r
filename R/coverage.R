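# Coverage ratios and their decomposition into copy number x prevalence.
#
# Sequencing an unsynchronized population measures copies per cell
# averaged over the population, so the replicon:chromosome depth ratio is
# modeled as r = c * p with c the integer per-cell copy number and p the
# fraction of cells carrying the replicon.

#' Per-replicon depth ratio relative to the chromosome
#'
#' The ratio is median window depth of the replicon over median window
#' depth of the chromosome (the median is robust to repeat-region
#' pileups). A 95% percentile-bootstrap interval is obtained by resampling
#' windows of both replicons independently.
#'
#' @param depth Windowed depth tibble (`replicon_id`, `window_start`,
#'   `window_end`, `depth`), as from [read_depth_table()] or
#'   [simulate_depth()].
#' @param chromosome_id Id of the chromosome; must have at least 20
#'   windows.
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Optional seed for the bootstrap.
#' @return A tibble with one row per replicon: `replicon_id`, `n_windows`,
#'   `median_depth`, `r`, `ci_low`, `ci_high`. The chromosome's own ratio
#'   is exactly 1 by construction.
#' @export
coverage_ratio <- function(depth, chromosome_id, n_boot = 2000L,
                           conf = 0.95, seed = NULL) {
  check_columns(depth, c("replicon_id", "window_start", "window_end", "depth"),
                "depth table")
  by_rep <- split(depth$depth, depth$replicon_id)
  if (!chromosome_id %in% names(by_rep)) {
    stop_ecr("chromosome '", chromosome_id, "' absent from depth table")
  }
  chr <- by_rep[[chromosome_id]]
  if (length(chr) < 20L) {
    stop_ecr("chromosome must have at least 20 windows (found ",
             length(chr), ")")
  }
  med_chr <- median(chr)
  if (med_chr == 0) stop_ecr("chromosome median depth is 0")
  alpha <- (1 - conf) / 2
  with_seed(seed, {
    rows <- imap(by_rep, function(d, rid) {
      if (rid == chromosome_id) {
        return(tibble(replicon_id = rid, n_windows = length(d),
                      median_depth = med_chr, r = 1, ci_low = 1, ci_high = 1))
      }
      if (length(d) < 5L) {
        warn(sprintf("replicon '%s' has only %d window(s); interval will be wide",
                     rid, length(d)))
      }
      boot_rep <- matrix(sample(d, length(d) * n_boot, replace = TRUE),
                         ncol = n_boot)
      boot_chr <- matrix(sample(chr, length(chr) * n_boot, replace = TRUE),
                         ncol = n_boot)
      ratios <- apply(boot_rep, 2, median) / apply(boot_chr, 2, median)
      qs <- quantile(ratios, c(alpha, 1 - alpha), names = FALSE)
      tibble(replicon_id = rid, n_windows = length(d),
             median_depth = median(d), r = median(d) / med_chr,
             ci_low = qs[1], ci_high = qs[2])
    })
    bind_rows(rows)
  })
}

#' Decompose depth ratios into copy number and prevalence
#'
#' Applies the model r = c * p. A ratio within `tol` of a positive
#' integer is read as that copy number fully carried by the population
#' (`integer_copy`). Otherwise, replicons under the single-copy
#' constraint (e.g. RepABC-type replicons, held at one copy per cell)
#' with r < 1 are read as a single-copy replicon carried by a fraction
#' r of cells (`single_copy_partial`). Anything else is flagged
#' `ambiguous` with c = max(1, round(r)) and p = r / c.
#'
#' @param ratios Tibble with at least `replicon_id` and `r` (as from
#'   [coverage_ratio()]); `ci_low`/`ci_high`, when present, are propagated
#'   to prevalence bounds for single-copy replicons.
#' @param single_copy Character vector of replicon ids known to be held at
#'   one copy per cell, or `TRUE` to apply the constraint to all.
#' @param tol Half-width of the integer acceptance band (0 < tol < 0.5).
#' @return The input with columns `copy_number`, `prevalence`,
#'   `prevalence_low`, `prevalence_high`, `mode` appended.
#' @export
decompose_ratio <- function(ratios, single_copy = character(), tol = 0.1) {
  check_columns(ratios, c("replicon_id", "r"), "ratio table")
  if (!(is_scalar_number(tol) && tol > 0 && tol < 0.5)) {
    stop_ecr("tol must be in (0, 0.5)")
  }
  if (any(ratios$r <= 0)) stop_ecr("depth ratios must be positive")
  constrained <- if (isTRUE(single_copy)) ratios$replicon_id else single_copy
  has_ci <- all(c("ci_low", "ci_high") %in% names(ratios))
  one <- function(r, sc) {
    if (abs(r - round(r)) <= tol && round(r) >= 1) {
      list(c = as.integer(round(r)), p = 1, mode = "integer_copy")
    } else if (sc && r < 1) {
      list(c = 1L, p = min(r, 1), mode = "single_copy_partial")
    } else {
      c_amb <- max(1L, as.integer(round(r)))
      list(c = c_amb, p = r / c_amb, mode = "ambiguous")
    }
  }
  dec <- map2(ratios$r, ratios$replicon_id %in% constrained, one)
  ratios |>
    mutate(
      copy_number = map_int(dec, "c"),
      prevalence = map_dbl(dec, "p"),
      prevalence_low = if (has_ci) {
        ifelse(map_chr(dec, "mode") == "single_copy_partial",
               pmin(.data$ci_low, 1), NA_real_)
      } else NA_real_,
      prevalence_high = if (has_ci) {
        ifelse(map_chr(dec, "mode") == "single_copy_partial",
               pmin(.data$ci_high, 1), NA_real_)
      } else NA_real_,
      mode = map_chr(dec, "mode")
    )
}

#' Exact binomial consistency test between a coverage estimate and a
#' colony assay
#'
#' Two-sided exact binomial test of `n_positive` carriers out of
#' `n_tested` colonies against the sequencing-derived prevalence, by
#' minimum-likelihood summation: the p-value is the sum of probabilities
#' of all outcomes no more likely than the observed one. (Definitions of
#' the two-sided exact test differ across software; this one is stated
#' explicitly and implemented directly.)
#'
#' @param assay Tibble with columns `n_tested`, `n_positive` (one or more
#'   rows).
#' @param prevalence Null carriage probability from the coverage
#'   decomposition, in \[0, 1\]. If 0 or 1 and the counts are discordant,
#'   the p-value is 0 by convention (with a warning).
#' @return The assay tibble with columns `null_prevalence` and `p_value`
#'   appended.
#' @export
consistency_test <- function(assay, prevalence) {
  check_columns(assay, c("n_tested", "n_positive"), "assay table")
  stopifnot(is_scalar_number(prevalence), prevalence >= 0, prevalence <= 1)
  pv <- map2_dbl_(assay$n_tested, assay$n_positive, function(n, x) {
    if (prevalence %in% c(0, 1)) {
      expected <- if (prevalence == 0) 0L else n
      if (x != expected) {
        warn("degenerate null prevalence with discordant counts; p-value 0")
        return(0)
      }
      return(1)
    }
    probs <- dbinom(0:n, n, prevalence)
    sum(probs[probs <= probs[x + 1L] * (1 + 1e-9)])
  })
  mutate(assay, null_prevalence = prevalence, p_value = pv)
}

map2_dbl_ <- function(x, y, f) vapply(seq_along(x), function(i) f(x[i], y[i]), numeric(1))
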