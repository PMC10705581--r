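#' QQ plot of p-values against the Uniform(0,1) reference
#'
#' The diagnostic view of the type I error experiment: selective p-values
#' should hug the diagonal under the null, while naive p-values fall below
#' it (stochastically smaller than uniform).
#'
#' @param object A [type1_experiment()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.type1_experiment <- function(object, ...) {
  long <- object$replicates |>
    tidyr::pivot_longer(c("p_naive", "p_selective"),
                        names_to = "test", values_to = "p") |>
    dplyr::group_by(.data$method, .data$test) |>
    dplyr::arrange(.data$p, .by_group = TRUE) |>
    dplyr::mutate(uniform = (seq_along(.data$p) - 0.5) / dplyr::n()) |>
    dplyr::ungroup()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$uniform, y = .data$p,
                                     colour = .data$test)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "Uniform(0,1) quantiles", y = "observed p-value quantiles") +
    ggplot2::theme_minimal()
}

#' Conditional power curves across signal sizes
#'
#' @param object A tibble binding the `summary` components of several
#'   [power_experiment()] runs (one per `delta`), or a single
#'   `power_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_experiment <- function(object, ...) {
  plot_power_curves(object$summary)
}

#' @rdname autoplot.power_experiment
#' @param summaries Tibble with columns `delta`, `method`, `cond_power`.
#' @export
plot_power_curves <- function(summaries) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$delta, y = .data$cond_power,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean separation delta", y = "conditional power") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Truncated null density and observed statistic for one test
#'
#' Shades the truncation set, draws the (renormalised) null density over
#' it, and marks the observed statistic, making visible how much of the
#' null mass is as extreme as the observation.
#'
#' @param object A [test_feature()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.postclust_test <- function(object, ...) {
  s <- object$truncation
  lim <- max(abs(object$stat), object$null_sd * 4,
             abs(s[is.finite(s)])) * 1.1
  grid <- seq(-lim, lim, length.out = 600)
  inside <- interval_contains(s, grid, scale = 1 + abs(object$stat))
  dens <- stats::dnorm(grid, 0, object$null_sd)
  dens[!inside] <- 0
  df <- tibble::tibble(phi = grid, density = dens)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi, y = .data$density)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.5) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * abs(object$stat),
                        colour = "firebrick", linetype = 2) +
    ggplot2::labs(x = "difference in cluster means (phi)",
                  y = "truncated null density (unnormalised)",
                  subtitle = sprintf("p_selective = %.3g, p_naive = %.3g",
                                     object$p_selective, object$p_naive)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
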