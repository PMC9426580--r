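# Colony-assay and plasmid-stability statistics, and the deterministic
# prevalence-dynamics model linking segregational loss, fitness cost and
# observed population prevalence.

# Clopper-Pearson (exact) binomial interval via Beta quantiles.
clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  low <- ifelse(x == 0, 0, qbeta(a, x, n - x + 1))
  high <- ifelse(x == n, 1, qbeta(1 - a, x + 1, n - x))
  cbind(low = unname(low), high = unname(high))
}

#' Prevalence estimate from colony counts
#'
#' Point estimate and exact (Clopper-Pearson) 95% confidence interval for
#' the fraction of colonies carrying a replicon, in percent. When no
#' positives (or no negatives) are observed, the rule-of-three bound 3/n
#' is reported alongside.
#'
#' @param assay Tibble with columns `n_tested`, `n_positive` and
#'   optionally `label`.
#' @param conf Confidence level for the exact interval.
#' @return The input with columns `estimate_pct`, `ci_low_pct`,
#'   `ci_high_pct` and `rule_of_three_pct` (NA unless the count is 0 or
#'   n) appended.
#' @export
prevalence_estimate <- function(assay, conf = 0.95) {
  check_columns(assay, c("n_tested", "n_positive"), "assay table")
  stopifnot(all(assay$n_tested >= 1),
            all(assay$n_positive >= 0 & assay$n_positive <= assay$n_tested))
  ci <- clopper_pearson(assay$n_positive, assay$n_tested, conf)
  mutate(assay,
         estimate_pct = 100 * .data$n_positive / .data$n_tested,
         ci_low_pct = 100 * as.vector(ci[, "low"]),
         ci_high_pct = 100 * as.vector(ci[, "high"]),
         rule_of_three_pct = ifelse(
           .data$n_positive %in% c(0L, .data$n_tested),
           100 * 3 / .data$n_tested, NA_real_))
}

#' Plasmid-stability statistics from a passaging assay
#'
#' Converts end-point retention counts after `generations` generations of
#' unselected growth into a per-generation segregational loss rate under
#' the pure-loss model R = (1 - lambda)^G, i.e. lambda = 1 - R^(1/G). The
#' confidence interval for lambda is the monotone transform of the exact
#' retention interval. With zero observed losses the point estimate is
#' lambda = 0 and the rule-of-three retention bound is transformed into an
#' upper bound on lambda instead.
#'
#' @param assay Tibble with columns `n_tested`, `n_positive` (colonies
#'   still carrying the plasmid).
#' @param generations Number of generations elapsed (>= 1). The package
#'   never guesses this: cultivation time alone does not determine it.
#' @param conf Confidence level.
#' @return The input with columns `retention_pct`, `retention_low_pct`,
#'   `retention_high_pct`, `generations`, `loss_rate`, `loss_rate_low`,
#'   `loss_rate_high`, `loss_rate_bound` (rule-of-three upper bound on
#'   lambda; NA unless retention is 100%).
#' @export
stability_stats <- function(assay, generations, conf = 0.95) {
  stopifnot(is_scalar_number(generations), generations >= 1)
  est <- prevalence_estimate(assay, conf)
  r_point <- est$estimate_pct / 100
  r_low <- est$ci_low_pct / 100
  r_high <- est$ci_high_pct / 100
  lam <- function(R) 1 - R^(1 / generations)
  if (any(r_point == 0)) {
    warn("zero retention observed; loss rate estimate is 1 per generation")
  }
  est |>
    rename(retention_pct = "estimate_pct",
           retention_low_pct = "ci_low_pct",
           retention_high_pct = "ci_high_pct") |>
    mutate(
      generations = generations,
      loss_rate = lam(r_point),
      loss_rate_low = lam(r_high),   # monotone decreasing transform
      loss_rate_high = lam(r_low),
      loss_rate_bound = ifelse(.data$n_positive == .data$n_tested,
                               lam(1 - 3 / .data$n_tested), NA_real_)
    ) |>
    select(-"rule_of_three_pct")
}

#' Project population prevalence under segregational loss and fitness
#' cost
#'
#' Deterministic per-generation recursion for the carrier fraction p of a
#' plasmid with segregational loss probability `loss_rate` per division
#' and selective advantage `fitness_cost` of plasmid-free cells:
#' \deqn{p_{t+1} = \frac{p_t (1-\lambda)}{p_t (1-\lambda) +
#'   (1 - p_t(1-\lambda)) (1+s)}}
#' With s = 0 the denominator is identically 1 and the recursion reduces
#' to the closed form p_t = p_0 (1-lambda)^t.
#'
#' @param loss_rate Per-generation segregational loss probability lambda
#'   in \[0, 1\].
#' @param fitness_cost Selective advantage s of plasmid-free cells (0 for
#'   neutral; negative if carriers grow faster).
#' @param p0 Initial carrier fraction.
#' @param generations Number of generations to project (>= 0).
#' @return A tibble with columns `generation` (0..G) and `prevalence`.
#' @export
project_prevalence <- function(loss_rate, fitness_cost = 0, p0 = 1,
                               generations) {
  stopifnot(loss_rate >= 0, loss_rate <= 1, p0 >= 0, p0 <= 1,
            is_scalar_number(generations), generations >= 0)
  p <- numeric(generations + 1)
  p[1] <- p0
  if (generations > 0) {
    for (t in seq_len(generations)) {
      kept <- p[t] * (1 - loss_rate)
      p[t + 1] <- kept / (kept + (1 - kept) * (1 + fitness_cost))
    }
  }
  tibble(generation = 0:generations, prevalence = p)
}

#' Energetic burden of carrying a plasmid
#'
#' The fraction of the cellular energy budget spent replicating a plasmid,
#' as the product of its genomic proportion and the fraction of the
#' energy budget consumed by DNA synthesis.
#'
#' @param plasmid_bp Plasmid size in bp.
#' @param genome_bp Total genome size in bp (>= plasmid_bp).
#' @param dna_energy_fraction Fraction of the energy budget spent on DNA
#'   synthesis (about 0.03 for bacteria).
#' @return The burden as a fraction of the total energy budget.
#' @export
plasmid_burden <- function(plasmid_bp, genome_bp, dna_energy_fraction) {
  stopifnot(plasmid_bp >= 0, genome_bp > 0, plasmid_bp <= genome_bp,
            dna_energy_fraction >= 0, dna_energy_fraction <= 1)
  (plasmid_bp / genome_bp) * dna_energy_fraction
}
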