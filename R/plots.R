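#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the score evolution of an optimisation run
#'
#' Docking score as a function of the optimisation step, one line per ladder
#' slot, coloured by temperature — the score-evolution view of a sequence
#' optimisation run.
#'
#' @param object An `remc_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot remc_trajectory
#' @export
autoplot.remc_trajectory <- function(object, ...) {
  st <- object$steps
  mut <- st[st$move == "mutation", ]
  ggplot2::ggplot(mut, ggplot2::aes(x = .data$step, y = .data$score,
                                    colour = factor(.data$kBT),
                                    group = .data$replica)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "optimization step", y = "docking score (kcal/mol)",
                  colour = expression(k[B] * T ~ "(kcal/mol)"),
                  title = sprintf("REMC score evolution, run %d", object$meta$run)) +
    ggplot2::theme_minimal()
}

#' Plot a corrected-binding-energy ranking
#'
#' Point-range chart of BE +/- err per peptide, best (most negative) first;
#' entries statistically unresolved from the best are highlighted.
#'
#' @param object A `be_ranking` from [rank_candidates()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot be_ranking
#' @export
autoplot.be_ranking <- function(object, ...) {
  d <- as_tibble(object)
  d$peptide <- factor(d$peptide, levels = rev(d$peptide))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$be, y = .data$peptide,
                                  colour = .data$unresolved)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$be - .data$err,
                                          xmax = .data$be + .data$err)) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey30", `TRUE` = "firebrick"),
      labels = c(`FALSE` = "resolved", `TRUE` = "overlaps best")) +
    ggplot2::labs(x = "corrected binding energy BE (kcal/mol)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a theory-experiment comparison
#'
#' Experimental binding free energy against computed corrected binding
#' energy, with error bars on both axes and the Pearson correlation in the
#' subtitle.
#'
#' @param object A `theory_experiment` from [compare_theory_experiment()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot theory_experiment
#' @export
autoplot.theory_experiment <- function(object, ...) {
  d <- object$data
  if (!"err" %in% names(d)) d$err <- 0
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$be, y = .data$delta_g)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "computed BE (kcal/mol)",
      y = expression(Delta * G == RT ~ ln(K[D]) ~ "(kcal/mol)"),
      subtitle = sprintf("Pearson r = %.3f (n = %d)", object$r, nrow(d))
    ) +
    ggplot2::theme_minimal()
  if (any(d$err > 0, na.rm = TRUE)) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$be - .data$err, xmax = .data$be + .data$err),
      height = 0)
  }
  if (any(is.finite(d$sigma_delta_g))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$delta_g - .data$sigma_delta_g,
                   ymax = .data$delta_g + .data$sigma_delta_g),
      width = 0)
  }
  p
}
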