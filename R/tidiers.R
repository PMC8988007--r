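# broom-style tidiers for the fitted-object classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a saturation-concentration fit
#'
#' @param x a `csat_fit` from [fit_csat()].
#' @param ... unused.
#' @return one row per quantity (term, estimate, std.error).
#' @export
tidy.csat_fit <- function(x, ...) {
  tibble::tibble(
    term = c("c_sat", "slope", "intercept"),
    estimate = c(x$c_sat, x$slope, x$intercept),
    std.error = c(x$c_sat_se, x$slope_se, NA_real_)
  )
}

#' @rdname tidy.csat_fit
#' @export
glance.csat_fit <- function(x, ...) {
  tibble::tibble(c_sat = x$c_sat, c_sat_se = x$c_sat_se, slope = x$slope,
                 n_points = x$n_points,
                 conc_min = x$fit_range[1], conc_max = x$fit_range[2],
                 r.squared = summary(x$model)$r.squared)
}

#' Tidy an MSD power-law fit
#'
#' @param x an `msd_fit` from [fit_msd_powerlaw()].
#' @param ... unused.
#' @return tibble with one row per parameter.
#' @export
tidy.msd_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "D"),
    estimate = c(x$alpha, x$D),
    std.error = c(x$alpha_se, x$D_se)
  )
}

#' @rdname tidy.msd_fit
#' @export
glance.msd_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, alpha_se = x$alpha_se, D = x$D, D_se = x$D_se,
                 n_lags = x$n_lags, lag_min_s = x$fit_lag_range[1],
                 lag_max_s = x$fit_lag_range[2], static_error_um = x$static_error,
                 r.squared = summary(x$model)$r.squared)
}

#' Tidy a dilute-phase model comparison
#'
#' @param x a `dilute_fit` from [fit_dilute_models()].
#' @param ... unused.
#' @return per-model AICc table with fitted parameters.
#' @export
tidy.dilute_fit <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, nm) {
    tibble::tibble(model = nm, term = names(f$coef), estimate = unname(f$coef))
  })
}

#' @rdname tidy.dilute_fit
#' @export
glance.dilute_fit <- function(x, ...) {
  best <- x$aicc$aicc[1]
  tibble::tibble(selected = x$selected,
                 delta_aicc = if (nrow(x$aicc) > 1) x$aicc$aicc[2] - best else NA_real_,
                 n_models = nrow(x$aicc), n_points = nrow(x$data))
}
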