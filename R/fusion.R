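# Scoring droplet fusion from time-lapse movies: per-frame aspect ratio of
# the largest segmented object, contact detection (last frame with two
# non-overlapping droplets), completion by sustained aspect-ratio relaxation,
# and the empirical fusion-time CDF with censoring.

#' Per-frame object count and aspect ratio
#'
#' Segments every frame of a 2D+time movie (Phansalkar threshold + labeling,
#' as for still fields) and reports the number of objects and the aspect
#' ratio of the largest object. Empty frames yield `NA` aspect ratio.
#'
#' @param movie an [image_stack] with axes `"tyx"`.
#' @param radius Phansalkar window radius, px.
#' @param min_area minimum object size, px.
#' @param ... passed to [threshold_phansalkar()].
#' @return tibble (frame, time_s, n_objects, aspect_ratio).
#' @export
aspect_ratio_series <- function(movie, radius = 30, min_area = 10, ...) {
  nf <- n_frames(movie)
  purrr::map_dfr(seq_len(nf), function(f) {
    img <- get_plane(movie, frame = f)
    seg <- label_droplets(threshold_phansalkar(img, radius = radius, ...),
                          image = img, pixel_size = movie$pixel_size,
                          min_area = min_area)
    recs <- seg$records
    tibble::tibble(
      frame = f, time_s = (f - 1) * movie$frame_interval,
      n_objects = nrow(recs),
      aspect_ratio = if (nrow(recs)) recs$aspect_ratio[which.max(recs$area_px)] else NA_real_
    )
  })
}

#' Detect a fusion event from an aspect-ratio series
#'
#' The contact frame is the last frame in which two separate droplets are
#' visible; fusion completes at the first subsequent frame whose aspect ratio
#' is at or below `ar_complete` ("appears spherical") sustained for
#' `hold_frames` consecutive frames, so single-frame noise spikes cannot end
#' an event. The fusion time is (completion - contact) x frame interval.
#' If the criterion is never sustained the event is reported with
#' `completed = FALSE` (gel-like relaxation).
#'
#' @param series output of [aspect_ratio_series()].
#' @param frame_interval s per frame.
#' @param ar_complete spherical criterion on the aspect ratio (default 1.1).
#' @param hold_frames consecutive frames the criterion must hold (default 2).
#' @return one-row tibble (contact_frame, completion_frame, fusion_time_s,
#'   final_aspect_ratio, completed).
#' @export
detect_fusion <- function(series, frame_interval = 1, ar_complete = 1.1,
                          hold_frames = 2) {
  two <- which(series$n_objects >= 2)
  if (!length(two)) stop("no fusion event: never saw two separate droplets", call. = FALSE)
  one_after <- which(series$n_objects == 1 & series$frame > min(series$frame[two]))
  if (!length(one_after))
    stop("no fusion event: the two droplets never merged", call. = FALSE)
  merge_start <- min(series$frame[one_after])
  contact <- max(series$frame[two][series$frame[two] < merge_start])
  post <- dplyr::filter(series, .data$frame >= merge_start, .data$n_objects == 1)
  ar <- post$aspect_ratio
  below <- !is.na(ar) & ar <= ar_complete
  completion <- NA_integer_; completed <- FALSE
  if (length(below) >= hold_frames) {
    run <- stats::filter(as.numeric(below), rep(1, hold_frames), sides = 1)
    hit <- which(run == hold_frames)
    if (length(hit)) {
      completion <- post$frame[hit[1] - hold_frames + 1L]
      completed <- TRUE
    }
  }
  tibble::tibble(
    contact_frame = contact,
    completion_frame = completion,
    fusion_time_s = if (completed) (completion - contact) * frame_interval else NA_real_,
    final_aspect_ratio = tail(ar[!is.na(ar)], 1),
    completed = completed
  )
}

#' Score a fusion movie end to end
#'
#' @param movie an [image_stack] with axes `"tyx"`.
#' @param ... passed to [aspect_ratio_series()] and [detect_fusion()].
#' @param ar_complete,hold_frames see [detect_fusion()].
#' @return as [detect_fusion()].
#' @export
score_fusion <- function(movie, ar_complete = 1.1, hold_frames = 2, ...) {
  s <- aspect_ratio_series(movie, ...)
  detect_fusion(s, frame_interval = movie$frame_interval,
                ar_complete = ar_complete, hold_frames = hold_frames)
}

#' Empirical cumulative distribution of fusion times
#'
#' Events not completed by the horizon are censored: they count in the
#' denominator but never in the numerator, so the CDF plateaus below 1.
#'
#' @param events tibble of fusion events (rows from [detect_fusion()]).
#' @param horizon censoring time, s.
#' @return tibble (time_s, cum_fraction), a non-decreasing step function on
#'   \[0, 1\]; class `fusion_cdf` for [autoplot()].
#' @export
fusion_cdf <- function(events, horizon = Inf) {
  if (!nrow(events)) stop("no fusion events", call. = FALSE)
  n <- nrow(events)
  done <- events$completed & !is.na(events$fusion_time_s) &
    events$fusion_time_s <= horizon
  tt <- sort(unique(events$fusion_time_s[done]))
  out <- tibble::tibble(
    time_s = c(0, tt),
    cum_fraction = c(0, vapply(tt, function(x) sum(events$fusion_time_s[done] <= x) / n,
                               numeric(1)))
  )
  class(out) <- c("fusion_cdf", class(out))
  out
}
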