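#' Plot baseline or PH hazard curves
#'
#' @param object A [ph_baseline()] or [ph_model()].
#' @param tmax Right end of the time grid.
#' @param x Covariate profile for a `ph_model` (default baseline subject).
#' @param n_grid Grid resolution.
#' @return A ggplot.
#' @export
plot_hazard <- function(object, tmax = 10, x = NULL, n_grid = 400) {
  t <- seq(tmax / n_grid, tmax, length.out = n_grid)
  h <- if (inherits(object, "ph_model")) hazard(object, t, x = x) else hazard(object, t)
  ggplot2::ggplot(tibble::tibble(t = t, hazard = h),
                  ggplot2::aes(x = .data$t, y = .data$hazard)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time", y = "hazard rate") +
    ggplot2::theme_minimal()
}

#' TTT plot for hazard-shape diagnosis
#'
#' Draws the scaled total-time-on-test curve of [ttt_statistic()] against the
#' diagonal. Concave above the diagonal suggests an increasing hazard,
#' convex below a decreasing one, convex-then-concave a unimodal hazard.
#'
#' @param data Data frame with a time column, or a numeric vector.
#' @param time Time column name when `data` is a data frame.
#' @return A ggplot.
#' @export
plot_ttt <- function(data, time = "time") {
  times <- if (is.data.frame(data)) data[[time]] else data
  g <- ttt_statistic(times)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$fraction, y = .data$ttt)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "i/n", y = "scaled TTT") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

draws_long <- function(object, parameters = NULL) {
  tb <- as_tibble(object)
  if (!is.null(parameters)) {
    tb <- tb[, c(".chain", ".iteration", parameters), drop = FALSE]
  }
  tidyr::pivot_longer(tb, cols = -c(".chain", ".iteration"),
                      names_to = "parameter", values_to = "value")
}

#' Diagnostic plots for posterior draws
#'
#' `autoplot()` on a `gllph_draws` object draws per-parameter panels:
#' `"trace"` (draw paths by chain), `"density"`, `"running_mean"` (ergodic
#' means by chain) or `"acf"` (chain-1 autocorrelations).
#'
#' @param object A `gllph_draws` object.
#' @param type One of `"trace"`, `"density"`, `"running_mean"`, `"acf"`.
#' @param parameters Optional subset of parameter names.
#' @param max_lag Lags shown for `type = "acf"`.
#' @param ... Unused.
#' @return A ggplot, faceted by parameter.
#' @export
#' @method autoplot gllph_draws
autoplot.gllph_draws <- function(object, type = c("trace", "density",
                                                  "running_mean", "acf"),
                                 parameters = NULL, max_lag = 30, ...) {
  type <- match.arg(type)
  if (is.null(parameters)) parameters <- object$par_names
  if (type == "acf") {
    df <- purrr::map_dfr(parameters, function(p) {
      tibble::tibble(parameter = p, lag = seq_len(max_lag),
                     acf = autocorr(object$draws[[1]][, p], max_lag = max_lag))
    })
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$acf)) +
        ggplot2::geom_col(width = 0.3) +
        ggplot2::facet_wrap(~parameter, scales = "free_y") +
        ggplot2::theme_minimal()
    )
  }
  df <- draws_long(object, parameters)
  df$.chain <- factor(df$.chain)
  p <- switch(type,
    trace = ggplot2::ggplot(df, ggplot2::aes(x = .data$.iteration, y = .data$value,
                                             colour = .data$.chain)) +
      ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
      ggplot2::labs(x = "retained iteration", y = NULL),
    density = ggplot2::ggplot(df, ggplot2::aes(x = .data$value, colour = .data$.chain)) +
      ggplot2::geom_density() +
      ggplot2::labs(x = NULL, y = "posterior density"),
    running_mean = {
      df2 <- df |>
        dplyr::group_by(.data$parameter, .data$.chain) |>
        dplyr::arrange(.data$.iteration, .by_group = TRUE) |>
        dplyr::mutate(value = cumsum(.data$value) / seq_along(.data$value)) |>
        dplyr::ungroup()
      ggplot2::ggplot(df2, ggplot2::aes(x = .data$.iteration, y = .data$value,
                                        colour = .data$.chain)) +
        ggplot2::geom_line(linewidth = 0.4) +
        ggplot2::labs(x = "retained iteration", y = "running mean")
    }
  )
  p + ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::theme_minimal()
}

#' Bias plot for a simulation study
#'
#' @param object A `gllph_sim_study`.
#' @param ... Unused.
#' @return A ggplot of per-parameter bias with MSE-derived error bars.
#' @export
#' @method autoplot gllph_sim_study
autoplot.gllph_sim_study <- function(object, ...) {
  perf <- object$performance
  ggplot2::ggplot(perf, ggplot2::aes(x = .data$parameter, y = .data$bias)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$bias - sqrt(.data$mse),
                                          ymax = .data$bias + sqrt(.data$mse))) +
    ggplot2::labs(y = "bias (posterior-mean estimator)", x = NULL) +
    ggplot2::theme_minimal()
}
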