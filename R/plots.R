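# ggplot2 displays for the main result types.

#' Plot coverage ratios with bootstrap intervals
#'
#' Point ranges of per-replicon depth ratios relative to the chromosome,
#' with guide lines at integer copy numbers.
#'
#' @param ratios Output of [coverage_ratio()] (optionally after
#'   [decompose_ratio()]).
#' @return A ggplot object.
#' @export
plot_coverage <- function(ratios) {
  check_columns(ratios, c("replicon_id", "r", "ci_low", "ci_high"),
                "ratio table")
  ggplot(ratios, aes(x = .data$replicon_id, y = .data$r)) +
    geom_hline(yintercept = c(0.5, 1, 2), linetype = "dotted",
               colour = "grey60") +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                  width = 0.2) +
    geom_point(size = 2) +
    coord_flip() +
    labs(x = NULL, y = "depth ratio to chromosome (r = c × p)") +
    theme_minimal()
}

#' Plot a projected prevalence trajectory
#'
#' @param trajectory Output of [project_prevalence()] (or the
#'   `trajectory` element of [simulate_passaging()]).
#' @return A ggplot object.
#' @export
plot_prevalence_trajectory <- function(trajectory) {
  check_columns(trajectory, c("generation", "prevalence"), "trajectory")
  ggplot(trajectory, aes(x = .data$generation, y = .data$prevalence)) +
    geom_line() +
    labs(x = "generation", y = "carrier fraction p") +
    theme_minimal()
}

#' Scatter plot of fold changes shared by two strains
#'
#' @param x,y DE tibbles with `gene_id` and `log2fc`.
#' @param labels Axis labels (defaults to "strain x"/"strain y").
#' @return A ggplot object annotated with the Pearson correlation of
#'   [fc_correlation()].
#' @export
plot_fc_correlation <- function(x, y, labels = c("strain x", "strain y")) {
  stats <- fc_correlation(x, y)
  shared <- inner_join(select(x, "gene_id", fc_x = "log2fc"),
                       select(y, "gene_id", fc_y = "log2fc"), by = "gene_id")
  ggplot(shared, aes(x = .data$fc_x, y = .data$fc_y)) +
    geom_point(alpha = 0.3, size = 0.8) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey50") +
    annotate("text", x = -Inf, y = Inf, hjust = -0.2, vjust = 1.5,
             label = sprintf("r = %.2f (n = %d)", stats$r, stats$n_shared)) +
    labs(x = bquote(log[2] ~ "FC," ~ .(labels[1])),
         y = bquote(log[2] ~ "FC," ~ .(labels[2]))) +
    theme_minimal()
}

#' @describeIn cluster_replicons Plot each replicon's cophenetic RSCU
#'   distance to the chromosome with the chromid threshold.
#' @param object A `replicon_clustering` object.
#' @export
autoplot.replicon_clustering <- function(object, ...) {
  cls <- object$classification
  thr <- object$params$tau * object$params$max_cophenetic
  ggplot(filter(cls, .data$class != "chromosome"),
         aes(x = stats::reorder(.data$replicon_id, .data$dist_to_chromosome),
             y = .data$dist_to_chromosome, fill = .data$class)) +
    geom_col() +
    geom_hline(yintercept = thr, linetype = "dashed") +
    coord_flip() +
    labs(x = NULL, y = "cophenetic RSCU distance to chromosome",
         fill = NULL,
         caption = sprintf("dashed: chromid threshold τ · max = %.3g",
                           thr)) +
    theme_minimal()
}
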