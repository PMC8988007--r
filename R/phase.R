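# Phase-diagram assembly and interpretation: saturation-concentration
# estimation by the linear x-intercept method, minimum visible concentration,
# reentrance classification, homotypic vs heterotypic dilute-phase model
# selection, and unit conversions for local concentration.

#' Saturation concentration from settled volume vs concentration
#'
#' Conditions whose mean settled volume per area exceeds `min_detectable` are
#' fit by ordinary least squares of volume on concentration; the x-intercept
#' `-intercept/slope` estimates the saturation concentration `c_sat` (the
#' minimum protein concentration producing condensates). The standard error
#' comes from the coefficient covariance by the delta method.
#'
#' @param data tibble with columns `conc_um` and `volume_per_area` (one row
#'   per replicate measurement).
#' @param min_detectable smallest measurable volume per area, um^3/um^2.
#' @return object of class `csat_fit` (use [tidy()] / [glance()]).
#' @export
fit_csat <- function(data, min_detectable = 0) {
  stopifnot(all(c("conc_um", "volume_per_area") %in% names(data)))
  cond_means <- dplyr::summarise(dplyr::group_by(data, .data$conc_um),
                                 m = mean(.data$volume_per_area), .groups = "drop")
  usable <- cond_means$conc_um[cond_means$m > min_detectable]
  if (length(usable) < 3)
    stop("insufficient data: need >= 3 conditions with measurable volume", call. = FALSE)
  d <- dplyr::filter(data, .data$conc_um %in% usable)
  fit <- lm(volume_per_area ~ conc_um, data = d)
  b <- coef(fit)
  V <- suppressWarnings(vcov(fit))   # a noiseless calibration line is legitimate
  if (b[2] <= 0) stop("no phase-separation trend: fitted slope <= 0", call. = FALSE)
  c_sat <- -b[1] / b[2]
  grad <- c(-1 / b[2], b[1] / b[2]^2)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  structure(
    list(c_sat = unname(c_sat), c_sat_se = unname(se),
         slope = unname(b[2]), slope_se = unname(sqrt(V[2, 2])),
         intercept = unname(b[1]),
         fit_range = range(usable), n_points = nrow(d), model = fit),
    class = "csat_fit"
  )
}

#' @export
print.csat_fit <- function(x, ...) {
  cat("c_sat = ", signif(x$c_sat, 4), " +/- ", signif(x$c_sat_se, 3),
      " uM (x-intercept of OLS over ", x$n_points, " points, conc ",
      x$fit_range[1], "-", x$fit_range[2], " uM)\n", sep = "")
  invisible(x)
}

#' Lowest concentration with visible condensates
#'
#' @param data tibble with `conc_um` and `volume_per_area`.
#' @param min_detectable detection floor, um^3/um^2.
#' @return smallest tested concentration whose mean volume exceeds the floor,
#'   or `NA` if none qualifies.
#' @export
min_visible_concentration <- function(data, min_detectable = 0) {
  cm <- dplyr::summarise(dplyr::group_by(data, .data$conc_um),
                         m = mean(.data$volume_per_area), .groups = "drop")
  vis <- cm$conc_um[cm$m > min_detectable]
  if (!length(vis)) NA_real_ else min(vis)
}

#' Classify phase behavior along a DNA titration
#'
#' With protein concentration fixed, condensation as a function of DNA
#' concentration is `"reentrant"` when the replicate-mean volume has an
#' interior maximum exceeding both endpoints by more than the pooled
#' replicate SD; `"monotone_increase"`/`"monotone_decrease"` when the
#' Spearman rank correlation of mean volume with concentration satisfies
#' |rho| >= 0.8 with the matching sign; otherwise `"flat"`.
#'
#' @param diagram tibble with columns `dna_conc_um`, `volume_per_area`, and
#'   optionally `protein_conc_um` (must be constant) and `replicate`.
#' @return one of `"monotone_increase"`, `"monotone_decrease"`, `"reentrant"`,
#'   `"flat"`.
#' @export
classify_reentrance <- function(diagram) {
  if ("protein_conc_um" %in% names(diagram) &&
      dplyr::n_distinct(diagram$protein_conc_um) > 1)
    stop("mixed protein concentrations: classify one protein level at a time",
         call. = FALSE)
  cm <- dplyr::arrange(
    dplyr::summarise(dplyr::group_by(diagram, .data$dna_conc_um),
                     m = mean(.data$volume_per_area),
                     s = stats::sd(.data$volume_per_area),
                     n = dplyr::n(), .groups = "drop"),
    .data$dna_conc_um)
  if (nrow(cm) < 4) stop("need >= 4 DNA concentrations", call. = FALSE)
  pooled_sd <- if (all(cm$n > 1)) sqrt(sum((cm$n - 1) * cm$s^2) / sum(cm$n - 1)) else 0
  k <- which.max(cm$m)
  if (k > 1 && k < nrow(cm) &&
      cm$m[k] > cm$m[1] + pooled_sd && cm$m[k] > cm$m[nrow(cm)] + pooled_sd)
    return("reentrant")
  if (stats::sd(cm$m) == 0) return("flat")
  rho <- suppressWarnings(cor(cm$dna_conc_um, cm$m, method = "spearman"))
  if (is.na(rho)) return("flat")
  if (rho >= 0.8) return("monotone_increase")
  if (rho <= -0.8) return("monotone_decrease")
  "flat"
}

# ---- dilute-phase model registry ----------------------------------------

.dilute_registry <- new.env(parent = emptyenv())

#' Register a dilute-phase scaling model
#'
#' Models live in a registry so the parametric forms can be swapped without
#' touching the fitting code. Each model supplies a prediction function
#' `fn(c_tot, params)`, a named start-value function `start(data)`, and lower
#' parameter bounds.
#'
#' @param name model name.
#' @param fn function of (c_tot, params list) returning predicted c_dil.
#' @param formula model formula in `c_tot` and the parameter names (used by
#'   the nonlinear least-squares backend).
#' @param start function of the data tibble returning a named list of starts.
#' @param lower named numeric vector of lower bounds.
#' @return `name`, invisibly.
#' @export
register_dilute_model <- function(name, fn, formula, start, lower) {
  assign(name, list(fn = fn, formula = formula, start = start, lower = lower),
         envir = .dilute_registry)
  invisible(name)
}

dilute_model <- function(name) {
  if (!exists(name, envir = .dilute_registry))
    stop("unknown dilute-phase model '", name, "'", call. = FALSE)
  get(name, envir = .dilute_registry)
}

dilute_model_fn <- function(name) dilute_model(name)$fn

#' @rdname register_dilute_model
#' @export
dilute_models <- function() ls(.dilute_registry)

register_default_dilute_models <- function() {
  register_dilute_model(
    "homotypic",
    fn = function(c_tot, p) pmin(c_tot + p$e, p$c_star),
    formula = c_dil ~ pmin(c_tot + e, c_star),
    start = function(d) list(c_star = stats::median(d$c_dil), e = 0.1 * stats::median(d$c_dil)),
    lower = c(c_star = 0, e = 0)
  )
  register_dilute_model(
    "heterotypic",
    fn = function(c_tot, p) c_tot - p$A * c_tot / (p$K + c_tot),
    formula = c_dil ~ c_tot - A * c_tot / (K + c_tot),
    start = function(d) list(A = max(d$c_tot - d$c_dil) * 2, K = stats::median(d$c_tot)),
    lower = c(A = 0, K = 1e-9)
  )
}

#' Fit and compare dilute-phase scaling models
#'
#' Fits every requested registered model to (c_tot, c_dil) pairs by nonlinear
#' least squares with multi-start (jittered starting values), then selects by
#' small-sample-corrected AIC. A difference |delta AICc| < 2 between the two
#' best models is declared `"indeterminate"` rather than over-claiming model
#' identity (this also covers the regime below the saturation point where the
#' homotypic and heterotypic curves coincide).
#'
#' @param series tibble with `c_tot` and `c_dil`; needs >= 6 points spanning
#'   at least a 3-fold range of `c_tot`.
#' @param models character vector of registered model names.
#' @param n_starts number of seeded starting points per model.
#' @param seed seed for the start jitter.
#' @return object of class `dilute_fit` with elements `selected`, `aicc`
#'   (tibble), `fits` (named list of `nls` objects), `data`.
#' @export
fit_dilute_models <- function(series, models = c("homotypic", "heterotypic"),
                              n_starts = 5, seed = 1) {
  stopifnot(all(c("c_tot", "c_dil") %in% names(series)))
  if (nrow(series) < 6) stop("need >= 6 points", call. = FALSE)
  if (max(series$c_tot) / max(min(series$c_tot), 1e-12) < 3)
    stop("c_tot must span at least a 3-fold range", call. = FALSE)
  n <- nrow(series)
  res <- withr::with_seed(seed, purrr::map(models, function(mn) {
    m <- dilute_model(mn)
    s0 <- m$start(series)
    rss_of <- function(par) {
      pred <- m$fn(series$c_tot, as.list(setNames(par, names(s0))))
      sum((series$c_dil - pred)^2)
    }
    best <- NULL
    for (i in seq_len(n_starts)) {
      st <- purrr::map(s0, function(v) v * exp(runif(1, -0.7, 0.7)))
      cf <- tryCatch({
        fit <- suppressWarnings(minpack.lm::nlsLM(
          m$formula, data = series, start = st,
          lower = m$lower[names(s0)],
          control = minpack.lm::nls.lm.control(maxiter = 200)))
        coef(fit)
      }, error = function(e) NULL)
      if (is.null(cf)) {
        # singular-gradient regimes (e.g. a parameter with no leverage):
        # fall back to bounded direct minimization of the RSS
        op <- tryCatch(
          suppressWarnings(stats::optim(unlist(st), rss_of, method = "L-BFGS-B",
                                        lower = m$lower[names(s0)])),
          error = function(e) NULL)
        if (!is.null(op)) cf <- setNames(op$par, names(s0))
      }
      if (!is.null(cf)) {
        rss <- rss_of(cf)
        if (is.null(best) || rss < best$rss)
          best <- list(coef = setNames(as.numeric(cf), names(s0)), rss = rss,
                       model = mn)
      }
    }
    best
  }))
  names(res) <- models
  ok <- !purrr::map_lgl(res, is.null)
  if (!any(ok)) stop("no dilute-phase model converged", call. = FALSE)
  aicc <- tibble::tibble(
    model = models[ok],
    n_par = purrr::map_int(res[ok], ~ length(.x$coef)),
    rss = purrr::map_dbl(res[ok], "rss"),
    aicc = purrr::map2_dbl(rss, n_par, ~ aicc_from_rss(.x, n, .y))
  )
  aicc <- dplyr::arrange(aicc, .data$aicc)
  delta <- if (nrow(aicc) > 1) aicc$aicc[1] - aicc$aicc[2] else -Inf
  selected <- if (nrow(aicc) > 1 && (is.nan(delta) || abs(delta) < 2))
    "indeterminate" else aicc$model[1]
  structure(list(selected = selected, aicc = aicc,
                 fits = res[ok], data = series),
            class = "dilute_fit")
}

#' @export
print.dilute_fit <- function(x, ...) {
  cat("dilute-phase scaling: selected model =", x$selected, "\n")
  print(x$aicc)
  invisible(x)
}

#' Local concentration of molecules in a sphere
#'
#' `c = n / (N_A * (4/3) pi r^3)` expressed in micromolar; used to estimate
#' the local protein concentration at a telomere from a molecule count and a
#' measured radius.
#'
#' @param n_molecules molecule count.
#' @param radius_um sphere radius, um.
#' @return concentration, uM.
#' @export
local_concentration <- function(n_molecules, radius_um) {
  stopifnot(n_molecules >= 0, radius_um > 0)
  avogadro <- 6.02214076e23
  vol_l <- 4 / 3 * pi * (radius_um * 1e-5)^3   # um -> dm; dm^3 = L
  n_molecules / (avogadro * vol_l) * 1e6
}
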