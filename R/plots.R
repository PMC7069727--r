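# ggplot2 methods for the package's result objects

#' @describeIn compute_trep Plot the timing profile along the genome
#'   (origins appear as valleys, terminations as peaks).
#' @param object,x A `replication_profile`.
#' @param ... Unused.
#' @export
autoplot.replication_profile <- function(object, ...) {
  ggplot2::ggplot(
    dplyr::filter(object, !.data$censored),
    ggplot2::aes(x = (.data$start + .data$end) / 2 / 1000, y = .data$t_rep)
  ) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (kb)", y = expression(t[rep] ~ "(min)"),
                  title = "Replication timing profile")
}

#' @method plot replication_profile
#' @export
plot.replication_profile <- function(x, ...) print(autoplot(x, ...))

#' @describeIn copy_change Plot the copy-number profile along the genome.
#' @param object,x A `cnv_profile`.
#' @param ... Unused.
#' @export
autoplot.cnv_profile <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = (.data$start + .data$end) / 2 / 1000,
                 y = .data$copy_change)
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.3, alpha = 0.5, colour = "#d95f02") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (kb)", y = "Copy number change",
                  title = "Copy-number change vs ancestor")
}

#' @method plot cnv_profile
#' @export
plot.cnv_profile <- function(x, ...) print(autoplot(x, ...))

#' @describeIn estimate_selection Plot per-replicate `ln r` against
#'   cumulative generations with the fitted regression lines.
#' @param object,x A `fitness_fit`.
#' @param ... Unused.
#' @export
autoplot.fitness_fit <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$g, y = .data$ln_ratio,
                               colour = factor(.data$replicate))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = object$replicates,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = factor(.data$replicate))
    ) +
    ggplot2::labs(x = "Generations", y = expression(ln ~ r),
                  colour = "Replicate",
                  title = sprintf("Selection coefficient s = %.3f", object$s))
}

#' @method plot fitness_fit
#' @export
plot.fitness_fit <- function(x, ...) print(autoplot(x, ...))

#' @describeIn convergence_scan Volcano-style plot of recurrence counts vs
#'   Poisson tail p-values, significant genes highlighted.
#' @param object,x A `convergence_scan`.
#' @param ... Unused.
#' @export
autoplot.convergence_scan <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$n, y = -log10(pmax(.data$p_value, 1e-300)),
                 colour = .data$sig_bh)
  ) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#d7191c")) +
    ggplot2::labs(x = "Mutations in gene", y = expression(-log[10] ~ p),
                  colour = "Significant (BH)",
                  title = "Convergently mutated genes")
}

#' @method plot convergence_scan
#' @export
plot.convergence_scan <- function(x, ...) print(autoplot(x, ...))

#' @describeIn trajectory_table Plot allele-frequency trajectories over
#'   generations, one line per locus, with per-direction bounds.
#' @param object,x An `allele_trajectory`.
#' @param ... Unused.
#' @export
autoplot.allele_trajectory <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$generation, y = .data$frequency,
                               colour = .data$locus)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper),
                             size = 0.3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Generation", y = "Mutant allele frequency",
                  colour = "Locus",
                  title = "Allele-frequency trajectories")
}

#' @method plot allele_trajectory
#' @export
plot.allele_trajectory <- function(x, ...) print(autoplot(x, ...))
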