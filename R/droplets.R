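# Segmentation and morphometrics of settled condensates in 2D fields:
# Phansalkar local adaptive thresholding, 8-connected labeling with a minimum
# size filter, equivalent-ellipse semi-axes from intensity-weighted second
# moments, settled volume per area, and partition coefficients.

#' Phansalkar local adaptive threshold
#'
#' A pixel is foreground iff its (min-max normalized) value strictly exceeds
#' the local threshold
#' `T = mu * (1 + p * exp(-q * mu) + k * (sd/r - 1))`,
#' where `mu` and `sd` are the mean and standard deviation over the window of
#' the given radius centered at the pixel. Windows are clipped at the image
#' edge. This is the low-contrast variant of local mean thresholding used for
#' detecting dim condensates; the constants default to the published values
#' (k = 0.25, r = 0.5, p = 2, q = 10), with a 30-pixel radius.
#'
#' @param image 2D numeric matrix.
#' @param radius window radius, px (>= 1 and smaller than the image).
#' @param k,r,p,q Phansalkar constants.
#' @param window `"circular"` (default) or `"square"` window shape.
#' @param normalize min-max normalize the image to \[0, 1\] first (the `r`
#'   constant presumes a normalized dynamic range).
#' @return logical matrix mask.
#' @export
threshold_phansalkar <- function(image, radius = 30, k = 0.25, r = 0.5,
                                 p = 2, q = 10,
                                 window = c("circular", "square"),
                                 normalize = TRUE) {
  window <- match.arg(window)
  if (length(dim(image)) != 2) stop("image must be 2D", call. = FALSE)
  if (radius < 1 || radius > max(dim(image)))
    stop("radius must be >= 1 and no larger than the image", call. = FALSE)
  img <- image
  if (normalize) {
    rng <- range(img)
    img <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  }
  st <- local_stats(img, window_kernel(radius, circular = window == "circular"))
  thr <- st$mean * (1 + p * exp(-q * st$mean) + k * (st$sd / r - 1))
  thr[abs(thr) < 1e-9] <- 0         # FFT round-off must not beat an exact zero
  img > thr
}

#' Ellipsoidal volume from in-plane semi-axes
#'
#' The out-of-plane semi-axis of a settled droplet is taken as the geometric
#' mean of the in-plane semi-axes, `c = sqrt(a*b)`, giving
#' `V = (4/3) * pi * a * b * sqrt(a*b)`. Symmetric in `a` and `b`.
#'
#' @param a,b in-plane semi-axes, um (vectorized).
#' @return volume, um^3.
#' @export
estimate_volume <- function(a, b) {
  stopifnot(all(a > 0), all(b > 0))
  4 / 3 * pi * a * b * sqrt(a * b)
}

#' Label condensates and compute per-droplet records
#'
#' 8-connected components of the mask; components smaller than `min_area`
#' pixels are discarded. Per component, the intensity-weighted centroid and
#' second central moments give equivalent-ellipse semi-axes (`a >= b`, in um;
#' for a solid disc of radius R, `a = b = R`). Volume uses
#' [estimate_volume()]. Records are sorted by label (top-left first).
#'
#' @param mask logical matrix (e.g. from [threshold_phansalkar()]).
#' @param image optional intensity image for weighting and photometry
#'   (defaults to the mask itself, i.e. unweighted).
#' @param pixel_size um per pixel.
#' @param min_area minimum component area, px.
#' @return list with `labels` (integer matrix) and `records` (tibble: label,
#'   y_um, x_um, area_px, area_um2, a_um, b_um, aspect_ratio, volume_um3,
#'   mean_intensity, integrated_intensity).
#' @export
label_droplets <- function(mask, image = NULL, pixel_size = 0.106, min_area = 10) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask > 0
  lab <- label_components(mask, connectivity = 8)
  if (max(lab) == 0) {
    return(list(labels = lab, records = droplet_record_template()))
  }
  img <- image %||% (mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  if (!length(keep)) {
    lab[] <- 0L
    return(list(labels = lab, records = droplet_record_template()))
  }
  # renumber surviving labels consecutively
  remap <- integer(max(lab)); remap[keep] <- seq_along(keep)
  lab <- array(ifelse(lab > 0, remap[pmax(lab, 1)], 0L), dim(lab))
  recs <- purrr::map_dfr(seq_along(keep), function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    w <- img[lab == i]
    w <- pmax(w, 0)
    if (sum(w) <= 0) w <- rep(1, length(w))
    W <- sum(w)
    yc <- sum(w * idx[, 1]) / W
    xc <- sum(w * idx[, 2]) / W
    mu20 <- sum(w * (idx[, 1] - yc)^2) / W + 1 / 12   # + pixel variance
    mu02 <- sum(w * (idx[, 2] - xc)^2) / W + 1 / 12
    mu11 <- sum(w * (idx[, 1] - yc) * (idx[, 2] - xc)) / W
    tr <- mu20 + mu02
    det_term <- sqrt(pmax((mu20 - mu02)^2 + 4 * mu11^2, 0))
    lam1 <- (tr + det_term) / 2
    lam2 <- (tr - det_term) / 2
    a_px <- 2 * sqrt(pmax(lam1, 1 / 12))
    b_px <- 2 * sqrt(pmax(lam2, 1 / 12))
    tibble::tibble(
      label = i,
      y_um = (yc - 1) * pixel_size, x_um = (xc - 1) * pixel_size,
      area_px = nrow(idx), area_um2 = nrow(idx) * pixel_size^2,
      a_um = a_px * pixel_size, b_um = b_px * pixel_size,
      aspect_ratio = a_px / b_px,
      volume_um3 = estimate_volume(a_px * pixel_size, b_px * pixel_size),
      mean_intensity = mean(img[lab == i]),
      integrated_intensity = sum(img[lab == i])
    )
  })
  list(labels = lab, records = recs)
}

droplet_record_template <- function() {
  tibble::tibble(label = integer(), y_um = numeric(), x_um = numeric(),
                 area_px = integer(), area_um2 = numeric(), a_um = numeric(),
                 b_um = numeric(), aspect_ratio = numeric(), volume_um3 = numeric(),
                 mean_intensity = numeric(), integrated_intensity = numeric())
}

#' Segment a droplet field end to end
#'
#' Convenience wrapper: [threshold_phansalkar()] then [label_droplets()].
#'
#' @param stack an [image_stack] with a single 2D plane (axes `"yx"`), or a
#'   plain matrix.
#' @param radius Phansalkar window radius, px.
#' @param min_area minimum condensate size, px.
#' @param ... passed to [threshold_phansalkar()].
#' @return as [label_droplets()].
#' @export
segment_droplets <- function(stack, radius = 30, min_area = 10, ...) {
  img <- if (inherits(stack, "image_stack")) get_plane(stack) else stack
  px <- if (inherits(stack, "image_stack")) stack$pixel_size else 0.106
  mask <- threshold_phansalkar(img, radius = radius, ...)
  label_droplets(mask, image = img, pixel_size = px, min_area = min_area)
}

#' Summarize a droplet field
#'
#' Total settled condensate volume per unit coverslip area, the quantity the
#' saturation-concentration fit consumes.
#'
#' @param records per-droplet tibble from [label_droplets()].
#' @param field_area_um2 imaged field area, um^2.
#' @param protein_conc_um,dna_conc_um,construct condition labels.
#' @return one-row tibble (n_droplets, total_volume_um3,
#'   total_volume_per_area, field_area_um2, condition columns).
#' @export
summarize_field <- function(records, field_area_um2, protein_conc_um = NA_real_,
                            dna_conc_um = NA_real_, construct = NA_character_) {
  stopifnot(field_area_um2 > 0)
  tv <- sum(records$volume_um3)
  tibble::tibble(
    n_droplets = nrow(records),
    total_volume_um3 = tv,
    total_volume_per_area = tv / field_area_um2,
    field_area_um2 = field_area_um2,
    protein_conc_um = protein_conc_um, dna_conc_um = dna_conc_um,
    construct = construct
  )
}

#' Partition coefficient of a query channel into droplets
#'
#' Mean query intensity inside the droplet mask over the mean in the
#' background mask, after subtracting the camera offset from both. The
#' default offset is 0; pass `offset = "mode"` to estimate it as the
#' histogram mode of the background region, or a number to use a calibrated
#' value.
#'
#' @param query 2D intensity matrix.
#' @param droplet_mask,background_mask disjoint non-empty logical masks.
#' @param offset 0 (default), a number, or `"mode"`.
#' @return partition coefficient (dimensionless).
#' @export
partition_coefficient <- function(query, droplet_mask, background_mask, offset = 0) {
  stopifnot(any(droplet_mask))
  if (!any(background_mask)) stop("empty background mask", call. = FALSE)
  if (any(droplet_mask & background_mask)) stop("masks must be disjoint", call. = FALSE)
  off <- if (identical(offset, "mode")) mode_estimate(query[background_mask]) else offset
  denom <- mean(query[background_mask]) - off
  if (denom <= 0) stop("background at or below the camera offset", call. = FALSE)
  (mean(query[droplet_mask]) - off) / denom
}

#' Partition-coefficient time course
#'
#' [partition_coefficient()] per frame of a 2D+time movie; the raw series is
#' returned without smoothing.
#'
#' @param movie an [image_stack] with axes `"tyx"`.
#' @param droplet_mask,background_mask as in [partition_coefficient()].
#' @param offset camera offset handling, as in [partition_coefficient()].
#' @return tibble (frame, time_s, pc).
#' @export
partition_timecourse <- function(movie, droplet_mask, background_mask, offset = 0) {
  nf <- n_frames(movie)
  purrr::map_dfr(seq_len(nf), function(f) {
    tibble::tibble(
      frame = f, time_s = (f - 1) * movie$frame_interval,
      pc = partition_coefficient(get_plane(movie, frame = f),
                                 droplet_mask, background_mask, offset)
    )
  })
}
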