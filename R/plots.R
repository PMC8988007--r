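# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an MSD curve (log-log), optionally with a power-law fit
#'
#' @param object an `msd_curve`.
#' @param fit optional `msd_fit` overlay.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.msd_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$lag_s, .data$msd_um2)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag (s)", y = expression(MSD ~ (mu * m^2)))
  if (!is.null(fit)) {
    xs <- exp(seq(log(min(object$lag_s)), log(max(object$lag_s)), length.out = 50))
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(lag_s = xs, msd_um2 = fit$D * xs^fit$alpha +
                              2 * fit$static_error^2),
      color = "red")
  }
  p
}

#' Plot a normalized FRAP curve
#'
#' @param object a `frap_curve` with a `normalized` column.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.frap_curve <- function(object, ...) {
  bf <- attr(object, "bleach_frame")
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$normalized)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$time_s[bf], linetype = 2) +
    ggplot2::labs(x = "time (s)", y = "normalized intensity") +
    ggplot2::coord_cartesian(ylim = c(-0.05, 1.2))
}

#' Plot an empirical fusion-time CDF
#'
#' @param object a `fusion_cdf`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fusion_cdf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$cum_fraction)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time after contact (s)", y = "cumulative fusion probability")
}

#' Plot settled volume per area vs concentration with the c_sat intercept
#'
#' @param data tibble with `conc_um`, `volume_per_area`.
#' @param fit optional `csat_fit` overlay.
#' @return a ggplot.
#' @export
plot_phase_titration <- function(data, fit = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(.data$conc_um, .data$volume_per_area)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(concentration ~ (mu * M)),
                  y = expression(settled ~ volume ~ (mu * m^3 / mu * m^2)))
  if (!is.null(fit)) {
    p <- p +
      ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                           color = "red") +
      ggplot2::geom_vline(xintercept = fit$c_sat, linetype = 2)
  }
  p
}

#' Plot a dilute-phase series with both fitted scaling models
#'
#' @param x a `dilute_fit`.
#' @return a ggplot.
#' @export
plot_dilute_fit <- function(x) {
  grid <- tibble::tibble(c_tot = seq(min(x$data$c_tot), max(x$data$c_tot),
                                     length.out = 100))
  lines <- purrr::imap_dfr(x$fits, function(f, nm) {
    fn <- dilute_model_fn(nm)
    tibble::tibble(c_tot = grid$c_tot,
                   c_dil = fn(grid$c_tot, as.list(f$coef)), model = nm)
  })
  ggplot2::ggplot(x$data, ggplot2::aes(.data$c_tot, .data$c_dil)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = lines, ggplot2::aes(color = .data$model)) +
    ggplot2::labs(x = "total concentration (A.U.)",
                  y = "dilute-phase concentration (A.U.)",
                  subtitle = paste("selected:", x$selected))
}
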