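# Telomere motion analysis: drift registration by phase correlation, LoG
# punctum detection with subpixel refinement, frame-to-frame linking by
# optimal assignment, time-averaged MSD, anomalous-diffusion power-law
# fitting, first-passage extrapolation, inter-telomere geometry, and FRAP
# double normalization.

#' Register a movie by translation (phase correlation)
#'
#' Each frame's 2D shift relative to the first frame is estimated by phase
#' correlation with subpixel refinement (local quadratic fit around the
#' correlation peak), then removed by bilinear interpolation. Featureless
#' (flat) frames get zero shift and are flagged.
#'
#' @param movie an [image_stack] with axes `"tyx"`.
#' @return list with `movie` (drift-corrected) and `shifts`
#'   (tibble: frame, dy_px, dx_px, flat).
#' @export
register_translation <- function(movie) {
  nf <- n_frames(movie)
  ref <- get_plane(movie, frame = 1)
  d <- dim(ref)
  Fref <- fft(ref)
  out <- movie
  shifts <- purrr::map_dfr(seq_len(nf), function(f) {
    img <- get_plane(movie, frame = f)
    if (f == 1 || sd(img) == 0 || sd(ref) == 0) {
      flat <- f > 1 && (sd(img) == 0 || sd(ref) == 0)
      if (flat) warning("frame ", f, " is featureless; zero shift assumed", call. = FALSE)
      return(tibble::tibble(frame = f, dy_px = 0, dx_px = 0, flat = flat))
    }
    cc <- Re(fft(Fref * Conj(fft(img)), inverse = TRUE))
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    # neighborhood with circular wrap for subpixel fit
    wrap <- function(i, n) ((i - 1) %% n) + 1
    fy <- cc[cbind(wrap(pk[1] + (-1:1), d[1]), rep(pk[2], 3))]
    fx <- cc[cbind(rep(pk[1], 3), wrap(pk[2] + (-1:1), d[2]))]
    dy <- (pk[1] - 1) + quad_subpixel(fy[1], fy[2], fy[3])
    dx <- (pk[2] - 1) + quad_subpixel(fx[1], fx[2], fx[3])
    if (dy > d[1] / 2) dy <- dy - d[1]
    if (dx > d[2] / 2) dx <- dx - d[2]
    if (abs(dy) < 1e-6) dy <- 0
    if (abs(dx) < 1e-6) dx <- 0
    # report the content displacement of frame f relative to frame 1
    tibble::tibble(frame = f, dy_px = -dy, dx_px = -dx, flat = FALSE)
  })
  # apply the negated shift: sample frame f at (y + dy, x + dx)
  ti <- axis_index(movie, "t")
  for (f in seq_len(nf)) {
    sh <- shifts[f, ]
    if (sh$dy_px == 0 && sh$dx_px == 0) next
    img <- get_plane(movie, frame = f)
    corr <- bilinear_shift(img, sh$dy_px, sh$dx_px)
    idx <- rep(list(quote(expr = )), 3)
    idx[[ti]] <- f
    out$data <- do.call(`[<-`, c(list(out$data), idx, list(corr)))
  }
  list(movie = out, shifts = shifts)
}

# Sample img at (y + dy, x + dx) with bilinear interpolation, replicating
# edges.
bilinear_shift <- function(img, dy, dx) {
  d <- dim(img)
  ys <- seq_len(d[1]) + dy
  xs <- seq_len(d[2]) + dx
  y0 <- pmin(pmax(floor(ys), 1), d[1]); y1 <- pmin(y0 + 1, d[1])
  x0 <- pmin(pmax(floor(xs), 1), d[2]); x1 <- pmin(x0 + 1, d[2])
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  a <- img[y0, x0]; b <- img[y0, x1]; cc <- img[y1, x0]; dd <- img[y1, x1]
  WY <- matrix(wy, d[1], d[2]); WX <- matrix(wx, d[1], d[2], byrow = TRUE)
  a * (1 - WY) * (1 - WX) + b * (1 - WY) * WX + cc * WY * (1 - WX) + dd * WY * WX
}

#' Detect diffraction-limited puncta (Laplacian of Gaussian)
#'
#' Filters the frame with a scale-normalized LoG kernel at
#' `sigma = diameter / (2 sqrt(2)) / pixel_size`, keeps local maxima above
#' mean + `threshold_sigmas` x SD of the filtered image, and refines each
#' peak to subpixel precision with a 3x3 quadratic fit.
#'
#' @param frame 2D intensity matrix.
#' @param pixel_size um per pixel.
#' @param diameter_um expected object diameter, um (default 0.5).
#' @param threshold_sigmas detection threshold in SDs of the filtered image.
#' @return tibble (y_px, x_px, y_um, x_um, score).
#' @export
detect_puncta <- function(frame, pixel_size = 0.106, diameter_um = 0.5,
                          threshold_sigmas = 2) {
  sigma <- diameter_um / (2 * sqrt(2)) / pixel_size
  stopifnot(sigma * 2 * sqrt(2) >= 1)  # diameter must be >= ~1 px
  resp <- conv2_clip(frame, log_kernel(sigma))
  thr <- mean(resp) + threshold_sigmas * sd(resp)
  mx <- local_maxima_2d(resp) & (resp > thr)
  # exclude a one-pixel border (no full 3x3 neighborhood)
  mx[c(1, nrow(mx)), ] <- FALSE; mx[, c(1, ncol(mx))] <- FALSE
  idx <- which(mx, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(tibble::tibble(y_px = numeric(), x_px = numeric(),
                          y_um = numeric(), x_um = numeric(), score = numeric()))
  }
  dy <- quad_subpixel(resp[cbind(idx[, 1] - 1, idx[, 2])],
                      resp[idx], resp[cbind(idx[, 1] + 1, idx[, 2])])
  dx <- quad_subpixel(resp[cbind(idx[, 1], idx[, 2] - 1)],
                      resp[idx], resp[cbind(idx[, 1], idx[, 2] + 1)])
  tibble::tibble(
    y_px = idx[, 1] + dy, x_px = idx[, 2] + dx,
    y_um = (idx[, 1] + dy - 1) * pixel_size,
    x_um = (idx[, 2] + dx - 1) * pixel_size,
    score = resp[idx]
  )
}

#' Link detections into trajectories
#'
#' Frame-to-frame assignment minimizing total squared displacement (optimal
#' bipartite matching via the Hungarian algorithm on the standard augmented
#' cost matrix, with links beyond `max_link_um` forbidden and a birth/death
#' cost of `max_link_um^2`). No gap closing: a missed detection terminates
#' the track. Tracks spanning less than `min_span_fraction` of the movie are
#' discarded.
#'
#' @param detections tibble with columns `frame`, `y_um`, `x_um` (and
#'   optionally `score`).
#' @param n_frames_total total movie frames (defaults to `max(frame)`).
#' @param max_link_um maximum linking distance, um.
#' @param min_span_fraction minimum fraction of movie frames a track must
#'   cover (default 0.5).
#' @param frame_interval s per frame (fills the `t_s` column).
#' @return tibble (track_id, frame, t_s, x_um, y_um, quality).
#' @export
link_trajectories <- function(detections, n_frames_total = NULL, max_link_um = 0.5,
                              min_span_fraction = 0.5, frame_interval = 1) {
  stopifnot(max_link_um > 0)
  if (!"score" %in% names(detections)) detections$score <- 1
  n_frames_total <- n_frames_total %||% max(detections$frame)
  b <- max_link_um^2
  BIG <- 1e9
  tracks <- list()      # each: list(rows = list of row tibbles, last_frame, y, x, open)
  for (f in seq_len(n_frames_total)) {
    det <- detections[detections$frame == f, , drop = FALSE]
    open <- which(purrr::map_lgl(tracks, ~ .x$open && .x$last_frame == f - 1L))
    n1 <- length(open); n2 <- nrow(det)
    assigned_det <- rep(FALSE, n2)
    if (n1 > 0 && n2 > 0) {
      ty <- purrr::map_dbl(tracks[open], "y")
      tx <- purrr::map_dbl(tracks[open], "x")
      dmat <- outer(ty, det$y_um, "-")^2 + outer(tx, det$x_um, "-")^2
      cost <- matrix(BIG, n1 + n2, n1 + n2)
      cost[seq_len(n1), seq_len(n2)] <- ifelse(dmat <= b, dmat, BIG)
      for (i in seq_len(n1)) cost[i, n2 + i] <- b          # track death
      for (j in seq_len(n2)) cost[n1 + j, j] <- b          # track birth
      cost[(n1 + 1):(n1 + n2), (n2 + 1):(n2 + n1)] <- 0    # dummies
      sol <- solve_assignment(cost)
      for (i in seq_len(n1)) {
        j <- sol[i]
        if (j <= n2 && dmat[i, j] <= b) {
          tr <- tracks[[open[i]]]
          tr$rows[[length(tr$rows) + 1]] <- det[j, ]
          tr$last_frame <- f; tr$y <- det$y_um[j]; tr$x <- det$x_um[j]
          tracks[[open[i]]] <- tr
          assigned_det[j] <- TRUE
        } else {
          tracks[[open[i]]]$open <- FALSE
        }
      }
    } else if (n1 > 0) {
      for (i in open) tracks[[i]]$open <- FALSE
    }
    for (j in which(!assigned_det)) {
      tracks[[length(tracks) + 1]] <- list(rows = list(det[j, ]), last_frame = f,
                                           y = det$y_um[j], x = det$x_um[j], open = TRUE)
    }
  }
  if (!length(tracks)) {
    return(tibble::tibble(track_id = integer(), frame = integer(), t_s = numeric(),
                          x_um = numeric(), y_um = numeric(), quality = numeric()))
  }
  out <- purrr::imap_dfr(tracks, function(tr, id) {
    rows <- dplyr::bind_rows(tr$rows)
    tibble::tibble(track_id = as.integer(id), frame = rows$frame,
                   t_s = (rows$frame - 1) * frame_interval,
                   x_um = rows$x_um, y_um = rows$y_um, quality = rows$score)
  })
  spans <- dplyr::summarise(dplyr::group_by(out, .data$track_id),
                            span = dplyr::n() / n_frames_total, .groups = "drop")
  keep <- spans$track_id[spans$span >= min_span_fraction]
  out <- dplyr::filter(out, .data$track_id %in% keep)
  out$track_id <- match(out$track_id, sort(unique(out$track_id)))
  out
}

#' Track puncta through a movie
#'
#' Convenience wrapper: [register_translation()] (optional),
#' [detect_puncta()] per frame, then [link_trajectories()].
#'
#' @param movie an [image_stack] with axes `"tyx"`.
#' @param register correct whole-cell drift first.
#' @param diameter_um,threshold_sigmas see [detect_puncta()].
#' @param max_link_um,min_span_fraction see [link_trajectories()].
#' @return tibble of trajectories.
#' @export
track_puncta <- function(movie, register = TRUE, diameter_um = 0.5,
                         threshold_sigmas = 2, max_link_um = 0.5,
                         min_span_fraction = 0.5) {
  if (register) movie <- register_translation(movie)$movie
  nf <- n_frames(movie)
  det <- purrr::map_dfr(seq_len(nf), function(f) {
    d <- detect_puncta(get_plane(movie, frame = f), pixel_size = movie$pixel_size,
                       diameter_um = diameter_um, threshold_sigmas = threshold_sigmas)
    d$frame <- f
    d
  })
  link_trajectories(det, n_frames_total = nf, max_link_um = max_link_um,
                    min_span_fraction = min_span_fraction,
                    frame_interval = movie$frame_interval)
}

#' Time-averaged mean squared displacement
#'
#' Per trajectory, the time-averaged squared displacement at each lag
#' (2D: x and y displacements summed), then the ensemble mean across
#' trajectories weighted by the number of displacement pairs. Lags are
#' limited to `max_lag_fraction` of each trajectory's length.
#'
#' @param traj trajectory tibble (track_id, t_s, x_um, y_um).
#' @param max_lag_fraction largest lag as a fraction of trajectory length.
#' @return tibble (lag_s, msd_um2, n_pairs) of class `msd_curve`.
#' @export
compute_msd <- function(traj, max_lag_fraction = 0.25) {
  stopifnot(all(c("track_id", "t_s", "x_um", "y_um") %in% names(traj)))
  per <- dplyr::group_split(dplyr::group_by(traj, .data$track_id))
  acc <- list()
  for (tr in per) {
    tr <- dplyr::arrange(tr, .data$t_s)
    n <- nrow(tr)
    dt <- diff(tr$t_s)
    if (n < 2) next
    step <- min(dt)
    max_lag <- max(1L, floor(n * max_lag_fraction))
    for (k in seq_len(max_lag)) {
      dx <- tr$x_um[(k + 1):n] - tr$x_um[1:(n - k)]
      dy <- tr$y_um[(k + 1):n] - tr$y_um[1:(n - k)]
      acc[[length(acc) + 1]] <- c(lag = k * step, ssd = sum(dx^2 + dy^2), np = n - k)
    }
  }
  if (!length(acc)) stop("no displacement pairs", call. = FALSE)
  m <- do.call(rbind, acc)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(m), .data$lag),
    msd_um2 = sum(.data$ssd) / sum(.data$np),
    n_pairs = sum(.data$np), .groups = "drop")
  out <- dplyr::arrange(dplyr::rename(agg, lag_s = "lag"), .data$lag_s)
  class(out) <- c("msd_curve", class(out))
  out
}

#' Fit an anomalous-diffusion power law to an MSD curve
#'
#' Ordinary least squares of `log(msd)` on `log(lag)` over the fit range:
#' `alpha` is the slope, `D = exp(intercept)` (units um^2 s^-alpha), with
#' standard errors propagated from the regression. When the localization
#' precision of the detections is known, pass it as `static_error` (um, SD of
#' the 2D error vector): the constant noise floor `2 * static_error^2` it
#' adds to every lag of a time-averaged MSD is subtracted before the log-log
#' fit, the standard static-error correction without which the slope of a
#' subdiffusive curve is biased downward at short lags.
#'
#' @param curve an `msd_curve` from [compute_msd()].
#' @param fit_range lag interval (s) to fit; default all lags.
#' @param static_error localization error SD, um (default 0 = no correction).
#' @return object of class `msd_fit` (use [tidy()] / [glance()]).
#' @export
fit_msd_powerlaw <- function(curve, fit_range = NULL, static_error = 0) {
  d <- tibble::as_tibble(curve)
  if (!is.null(fit_range))
    d <- dplyr::filter(d, .data$lag_s >= fit_range[1], .data$lag_s <= fit_range[2])
  d$msd_corr <- d$msd_um2 - 2 * static_error^2
  d <- dplyr::filter(d, .data$msd_corr > 0, .data$n_pairs > 0)
  if (nrow(d) < 4) stop("insufficient data: need >= 4 positive lags in range", call. = FALSE)
  fit <- lm(log(msd_corr) ~ log(lag_s), data = d)
  b <- coef(fit)
  se <- suppressWarnings(sqrt(diag(vcov(fit))))  # exact power laws are legitimate
  structure(
    list(alpha = unname(b[2]), alpha_se = unname(se[2]),
         D = unname(exp(b[1])), D_se = unname(exp(b[1]) * se[1]),
         fit_lag_range = range(d$lag_s), n_lags = nrow(d),
         static_error = static_error, model = fit),
    class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat("MSD(tau) = D tau^alpha: alpha = ", signif(x$alpha, 3), " +/- ",
      signif(x$alpha_se, 2), ", D = ", signif(x$D, 3), " +/- ",
      signif(x$D_se, 2), " um^2 s^-alpha (", x$n_lags, " lags, ",
      x$fit_lag_range[1], "-", x$fit_lag_range[2], " s)\n", sep = "")
  invisible(x)
}

#' First-passage encounter time under anomalous diffusion
#'
#' Extrapolates the fitted law MSD(tau) = D tau^alpha to the time at which a
#' telomere covers a given separation. In `"relative_pair"` mode (default)
#' both loci diffuse, so the relative MSD is doubled and the time solves
#' `2 D t^alpha = d^2`; `"single_locus"` solves `D t^alpha = d^2`. These are
#' order-of-magnitude extrapolations far beyond the observed lags and are
#' flagged as such.
#'
#' @param fit an `msd_fit`, or a list with elements `D` and `alpha`.
#' @param separation_um separation(s) to reach, um.
#' @param mode `"relative_pair"` or `"single_locus"`.
#' @return tibble (separation_um, mode, time_s, time_days, extrapolated).
#' @export
encounter_time <- function(fit, separation_um,
                           mode = c("relative_pair", "single_locus")) {
  mode <- match.arg(mode)
  D <- fit$D; alpha <- fit$alpha
  stopifnot(D > 0, all(separation_um > 0))
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  fac <- if (mode == "relative_pair") 2 else 1
  t_s <- (separation_um^2 / (fac * D))^(1 / alpha)
  tibble::tibble(separation_um = separation_um, mode = mode,
                 time_s = t_s, time_days = t_s / 86400,
                 extrapolated = TRUE)
}

#' Inter-telomere geometry within a nucleus
#'
#' Mean nearest-neighbor and mean all-pairs Euclidean distance between
#' punctum centroids, restricted to puncta inside the nucleus mask.
#'
#' @param puncta tibble with `y_um`, `x_um` (and `y_px`, `x_px` if a mask is
#'   supplied).
#' @param nucleus_mask optional logical matrix; puncta whose rounded pixel
#'   position falls outside are excluded.
#' @return one-row tibble (n_puncta, nn_mean_um, pairwise_mean_um).
#' @export
telomere_geometry <- function(puncta, nucleus_mask = NULL) {
  if (!is.null(nucleus_mask)) {
    iy <- pmin(pmax(round(puncta$y_px), 1), nrow(nucleus_mask))
    ix <- pmin(pmax(round(puncta$x_px), 1), ncol(nucleus_mask))
    puncta <- puncta[nucleus_mask[cbind(iy, ix)], , drop = FALSE]
  }
  if (nrow(puncta) < 2)
    stop("need >= 2 puncta inside the nucleus", call. = FALSE)
  dm <- as.matrix(stats::dist(cbind(puncta$y_um, puncta$x_um)))
  diag(dm) <- Inf
  nn <- mean(apply(dm, 1, min))
  pw <- mean(dm[upper.tri(dm)])
  tibble::tibble(n_puncta = nrow(puncta), nn_mean_um = nn, pairwise_mean_um = pw)
}

#' Double normalization of a FRAP curve
#'
#' Reference-corrected normalization followed by full-scale rescaling:
#' `F1(t) = (F(t) / <F>_pre) * (<W>_pre / W(t))` removes acquisition
#' photobleaching via the whole-cell reference `W`; then
#' `F2(t) = (F1(t) - F1(t0+)) / (<F1>_pre - F1(t0+))` anchors the pre-bleach
#' mean at 1 and the first post-bleach point at exactly 0. Frames with
#' non-positive reference intensity are rejected. If there is no bleach
#' (degenerate rescale), `F1` is returned with a warning and
#' `degenerate = TRUE`.
#'
#' @param curve tibble (time_s, bleach_roi, reference_roi) with attribute
#'   `bleach_frame`, or pass `bleach_frame` explicitly.
#' @param bleach_frame index of the first post-bleach frame.
#' @return the tibble with a `normalized` column; attributes `bleach_frame`,
#'   `degenerate`.
#' @export
frap_normalize <- function(curve, bleach_frame = attr(curve, "bleach_frame")) {
  stopifnot(!is.null(bleach_frame), bleach_frame >= 3)
  ok <- curve$reference_roi > 0
  if (!any(ok)) stop("all reference intensities non-positive", call. = FALSE)
  if (!all(ok)) {
    warning(sum(!ok), " frame(s) with non-positive reference rejected", call. = FALSE)
    curve <- curve[ok, , drop = FALSE]
    bleach_frame <- sum(ok[seq_len(bleach_frame)])
  }
  pre <- seq_len(bleach_frame - 1L)
  if (length(pre) < 2) stop("need >= 2 pre-bleach frames", call. = FALSE)
  F1 <- (curve$bleach_roi / mean(curve$bleach_roi[pre])) *
    (mean(curve$reference_roi[pre]) / curve$reference_roi)
  f0 <- F1[bleach_frame]
  denom <- mean(F1[pre]) - f0
  degenerate <- abs(denom) < 1e-9 * max(abs(F1))
  if (degenerate) {
    warning("no detectable bleach: full-scale rescale is degenerate", call. = FALSE)
    norm <- F1
  } else {
    norm <- (F1 - f0) / denom
  }
  out <- dplyr::mutate(curve, normalized = norm)
  attr(out, "bleach_frame") <- bleach_frame
  attr(out, "degenerate") <- degenerate
  class(out) <- unique(c("frap_curve", class(out)))
  out
}
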