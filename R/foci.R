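# 3D nuclear analysis: Otsu nucleus segmentation, LoG punctum detection in z-
# stacks with 26-connected labeling, per-nucleus damage-focus counting and
# telomere colocalization, coalescence intensity bookkeeping, locally-induced
# enrichment normalization, transfection-efficiency fractions, and dilute-
# phase measurement with condensates masked out.

#' Segment nuclei with Otsu's method
#'
#' Global threshold maximizing the between-class variance of a 256-bin
#' histogram; holes are filled and objects below a physical size floor
#' (20 um^2 in 2D, 50 um^3 in 3D) are removed. Labeling is 8-connected (2D)
#' or 26-connected (3D). A flat image yields an empty mask with a warning.
#'
#' @param img 2D matrix or 3D array (z, y, x) of the nuclear stain.
#' @param pixel_size lateral um/px.
#' @param z_step axial um/slice (3D).
#' @param min_size_um physical size floor; default 20 um^2 (2D) / 50 um^3 (3D).
#' @return integer label array (0 = background).
#' @export
segment_nuclei <- function(img, pixel_size = 0.106, z_step = pixel_size,
                           min_size_um = NULL) {
  d <- dim(img)
  is3d <- length(d) == 3
  min_size_um <- min_size_um %||% if (is3d) 50 else 20
  thr <- otsu_threshold(img)
  if (is.na(thr)) {
    warning("flat image: no nuclei found", call. = FALSE)
    return(array(0L, d))
  }
  mask <- img > thr
  mask <- fill_holes(mask)
  lab <- label_components(mask, connectivity = if (is3d) 26 else 8)
  if (max(lab) == 0) return(lab)
  unit <- if (is3d) pixel_size^2 * z_step else pixel_size^2
  sizes <- tabulate(lab[lab > 0]) * unit
  keep <- which(sizes >= min_size_um)
  remap <- integer(max(lab)); remap[keep] <- seq_along(keep)
  array(ifelse(lab > 0, remap[pmax(lab, 1)], 0L), d)
}

#' Detect bright objects in a z-stack
#'
#' Slice-wise scale-normalized LoG filtering (puncta are laterally
#' diffraction-limited; the axial extent is handled by the 26-connected
#' labeling of the thresholded 3D response), threshold at mean +
#' `threshold_sigmas` x SD of the response, then 26-connected components.
#'
#' @param vol 3D array (z, y, x).
#' @param sigma_px lateral LoG scale, px.
#' @param threshold_sigmas detection threshold in response SDs.
#' @param min_voxels minimum object size, voxels.
#' @return list with `labels` (3D integer array) and `objects` (tibble: id,
#'   z_px, y_px, x_px weighted centroid, n_voxels, integrated_intensity).
#' @export
detect_objects_3d <- function(vol, sigma_px = 1.3, threshold_sigmas = 2,
                              min_voxels = 2) {
  d <- dim(vol)
  resp <- array(0, d)
  kern <- log_kernel(sigma_px)
  for (z in seq_len(d[1])) resp[z, , ] <- conv2_clip(vol[z, , ], kern)
  thr <- mean(resp) + threshold_sigmas * sd(resp)
  mask <- resp > thr
  lab <- label_components(mask, connectivity = 26)
  if (max(lab) == 0)
    return(list(labels = lab,
                objects = tibble::tibble(id = integer(), z_px = numeric(),
                                         y_px = numeric(), x_px = numeric(),
                                         n_voxels = integer(),
                                         integrated_intensity = numeric())))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_voxels)
  remap <- integer(max(lab)); remap[keep] <- seq_along(keep)
  lab <- array(ifelse(lab > 0, remap[pmax(lab, 1)], 0L), d)
  if (!length(keep))
    return(list(labels = lab,
                objects = tibble::tibble(id = integer(), z_px = numeric(),
                                         y_px = numeric(), x_px = numeric(),
                                         n_voxels = integer(),
                                         integrated_intensity = numeric())))
  idx <- which(lab > 0)
  ids <- lab[idx]
  w <- pmax(vol[idx], 1e-12)
  zz <- (idx - 1) %% d[1] + 1
  rest <- (idx - 1) %/% d[1]
  yy <- rest %% d[2] + 1
  xx <- rest %/% d[2] + 1
  sw <- tapply(w, ids, sum)
  objects <- tibble::tibble(
    id = as.integer(names(sw)),
    z_px = as.numeric(tapply(w * zz, ids, sum) / sw),
    y_px = as.numeric(tapply(w * yy, ids, sum) / sw),
    x_px = as.numeric(tapply(w * xx, ids, sum) / sw),
    n_voxels = as.integer(tapply(w, ids, length)),
    integrated_intensity = as.numeric(tapply(vol[idx], ids, sum))
  )
  list(labels = lab, objects = dplyr::arrange(objects, .data$id))
}

#' Colocalization between two label volumes
#'
#' An object in `labels_a` is colocalized iff its voxel set shares at least
#' `min_voxels` voxels with any object in `labels_b` (and symmetrically).
#'
#' @param labels_a,labels_b integer label arrays of identical shape.
#' @param min_voxels minimum shared voxels (default 1).
#' @return logical vector, one entry per object id of `labels_a`.
#' @export
colocalize <- function(labels_a, labels_b, min_voxels = 1) {
  na <- max(labels_a)
  if (na == 0) return(logical(0))
  shared <- labels_a[labels_a > 0 & labels_b > 0]
  cnt <- tabulate(shared, nbins = na)
  cnt >= min_voxels
}

#' Per-nucleus counts of damage foci, telomeres, and colocalizations
#'
#' Detects puncta in the foci and telomere channels of a 3-channel z-stack,
#' assigns each object to the nucleus containing its weighted centroid
#' (objects outside every nucleus are dropped), and tabulates counts per
#' nucleus together with voxel-overlap colocalization.
#'
#' @param stack an [image_stack] with axes `"czyx"` and channels including
#'   `"dna"`, `"telomere"`, `"foci"`.
#' @param nuclei optional precomputed nucleus label array (else segmented
#'   from the `"dna"` channel).
#' @param threshold_sigmas,sigma_px,min_voxels detector settings
#'   (see [detect_objects_3d()]).
#' @return `foci_table` tibble (nucleus_id, n_foci, n_telomeres,
#'   n_colocalized, nucleus_volume_um3).
#' @export
count_foci <- function(stack, nuclei = NULL, threshold_sigmas = 2,
                       sigma_px = 1.3, min_voxels = 2) {
  if (is.null(stack$channels) || !all(c("telomere", "foci") %in% stack$channels))
    stop("stack must have 'telomere' and 'foci' channels", call. = FALSE)
  nuclei <- nuclei %||% segment_nuclei(get_plane(stack, channel = "dna"),
                                       pixel_size = stack$pixel_size,
                                       z_step = stack$z_step)
  telo <- detect_objects_3d(get_plane(stack, channel = "telomere"),
                            sigma_px, threshold_sigmas, min_voxels)
  foci <- detect_objects_3d(get_plane(stack, channel = "foci"),
                            sigma_px, threshold_sigmas, min_voxels)
  assign_nucleus <- function(objects) {
    if (!nrow(objects)) return(integer(0))
    d <- dim(nuclei)
    iz <- pmin(pmax(round(objects$z_px), 1), d[1])
    iy <- pmin(pmax(round(objects$y_px), 1), d[2])
    ix <- pmin(pmax(round(objects$x_px), 1), d[3])
    nuclei[cbind(iz, iy, ix)]
  }
  telo_nuc <- assign_nucleus(telo$objects)
  foci_nuc <- assign_nucleus(foci$objects)
  foci_coloc <- colocalize(foci$labels, telo$labels)
  n_nuc <- max(nuclei)
  unit <- stack$pixel_size^2 * stack$z_step
  out <- purrr::map_dfr(seq_len(n_nuc), function(i) {
    sel <- which(nuclei == i, arr.ind = TRUE)
    tibble::tibble(
      nucleus_id = i,
      n_foci = sum(foci_nuc == i),
      n_telomeres = sum(telo_nuc == i),
      n_colocalized = sum(foci_coloc[which(foci_nuc == i)]),
      nucleus_volume_um3 = nrow(sel) * unit,
      center_y_px = mean(sel[, 2]),
      center_x_px = mean(sel[, 3])
    )
  })
  class(out) <- unique(c("foci_table", class(out)))
  out
}

#' Fraction of nuclei above a damage threshold
#'
#' The damage classifier: the fraction of nuclei with strictly more than
#' `threshold` damage foci (default 10).
#'
#' @param table a `foci_table` (needs `n_foci`).
#' @param threshold focus-count threshold.
#' @return fraction in \[0, 1\].
#' @export
damage_classification <- function(table, threshold = 10) {
  stopifnot(nrow(table) > 0)
  mean(table$n_foci > threshold)
}

#' Integrated-intensity bookkeeping across a coalescence event
#'
#' For a movie in which two puncta merge into one: the background-subtracted
#' integrated intensity of each punctum is averaged over the pre-coalescence
#' frames (all frames with two detected objects) and summed to predict the
#' post-coalescence integrated intensity; standard errors of the means are
#' propagated in quadrature. Conservation passes when
#' |measured - predicted| <= 2 x combined SE.
#'
#' @param movie an [image_stack] with axes `"tyx"`.
#' @param threshold_sigmas,sigma_px detector settings.
#' @param background constant camera background; `"mode"` (default) estimates
#'   it per frame as the histogram mode.
#' @return object of class `coalescence_record`: list with `pre_intensities`
#'   (tibble), `predicted_post`, `predicted_se`, `measured_post`,
#'   `measured_se`, `merge_frame`, `conserved`.
#' @export
coalescence_bookkeeping <- function(movie, threshold_sigmas = 4, sigma_px = 1.6,
                                    background = "mode") {
  nf <- n_frames(movie)
  kern <- log_kernel(sigma_px)
  r_phot <- ceiling(4 * sigma_px)      # photometric aperture radius
  per_frame <- purrr::map(seq_len(nf), function(f) {
    img <- get_plane(movie, frame = f)
    bg <- if (identical(background, "mode")) mode_estimate(img) else background
    resp <- conv2_clip(img, kern)
    thr <- mean(resp) + threshold_sigmas * sd(resp)
    lab <- label_components(resp > thr, connectivity = 8)
    k <- max(lab)
    if (k == 0) return(tibble::tibble(frame = f, obj = integer(), x = numeric(),
                                      intensity = numeric()))
    sizes <- tabulate(lab[lab > 0])
    purrr::map_dfr(which(sizes >= 4), function(i) {
      idx <- which(lab == i, arr.ind = TRUE)
      w <- pmax(img[lab == i] - bg, 1e-12)
      yc <- sum(w * idx[, 1]) / sum(w); xc <- sum(w * idx[, 2]) / sum(w)
      # integrate over a generous aperture so the full point-spread is counted
      ys <- max(1, round(yc) - r_phot):min(nrow(img), round(yc) + r_phot)
      xs <- max(1, round(xc) - r_phot):min(ncol(img), round(xc) + r_phot)
      disc <- outer(ys - yc, xs - xc, function(a, b) a^2 + b^2 <= r_phot^2)
      tibble::tibble(frame = f, obj = i, x = xc,
                     intensity = sum((img[ys, xs] - bg)[disc]))
    })
  })
  counts <- purrr::map_int(per_frame, nrow)
  pre <- which(counts == 2)
  post <- which(counts == 1)
  if (!length(pre)) stop("no pre-coalescence frames with two objects", call. = FALSE)
  if (!length(post) || max(post) < max(pre))
    stop("no merge: never observed a single merged object", call. = FALSE)
  post <- post[post > max(pre)]
  pre_tbl <- dplyr::bind_rows(per_frame[pre])
  # identify the two objects across frames by x position (left/right)
  pre_tbl <- dplyr::mutate(dplyr::group_by(pre_tbl, .data$frame),
                           which_obj = rank(.data$x, ties.method = "first"))
  pre_stats <- dplyr::summarise(
    dplyr::group_by(dplyr::ungroup(pre_tbl), .data$which_obj),
    mean_intensity = mean(.data$intensity),
    se = stats::sd(.data$intensity) / sqrt(dplyr::n()),
    n_frames = dplyr::n(), .groups = "drop")
  pre_stats$se[is.na(pre_stats$se)] <- 0
  post_int <- dplyr::bind_rows(per_frame[post])$intensity
  predicted <- sum(pre_stats$mean_intensity)
  predicted_se <- sqrt(sum(pre_stats$se^2))
  measured <- mean(post_int)
  measured_se <- if (length(post_int) > 1) sd(post_int) / sqrt(length(post_int)) else 0
  comb <- sqrt(predicted_se^2 + measured_se^2)
  # 1% floor absorbs aperture cross-talk/rendering residue when SEs vanish
  tol <- 2 * comb + 0.01 * abs(predicted)
  structure(
    list(pre_intensities = pre_stats, predicted_post = predicted,
         predicted_se = predicted_se, measured_post = measured,
         measured_se = measured_se, merge_frame = min(post),
         conserved = abs(measured - predicted) <= tol),
    class = "coalescence_record")
}

#' @export
print.coalescence_record <- function(x, ...) {
  cat("coalescence: predicted ", signif(x$predicted_post, 4), " +/- ",
      signif(x$predicted_se, 3), ", measured ", signif(x$measured_post, 4),
      " +/- ", signif(x$measured_se, 3), " (merge at frame ", x$merge_frame,
      "); conserved: ", x$conserved, "\n", sep = "")
  invisible(x)
}

#' Enrichment of a locally activated region
#'
#' Background-subtracted mean intensity of the target region divided by the
#' average background-subtracted intensity of all other telomeres in the same
#' cell.
#'
#' @param frame 2D intensity matrix.
#' @param target_roi logical mask of the activated region.
#' @param other_rois list of logical masks, one per reference telomere.
#' @param background_roi logical mask of a background region.
#' @return dimensionless enrichment ratio.
#' @export
corelet_enrichment <- function(frame, target_roi, other_rois, background_roi) {
  if (!length(other_rois)) stop("need at least one reference telomere", call. = FALSE)
  stopifnot(any(target_roi), any(background_roi))
  bg <- mean(frame[background_roi])
  ref <- mean(purrr::map_dbl(other_rois, ~ mean(frame[.x]) - bg))
  if (ref == 0) stop("reference telomeres at background level", call. = FALSE)
  (mean(frame[target_roi]) - bg) / ref
}

#' Fraction of nuclei with signal above background
#'
#' Per-nucleus mean signal minus background; reports the fraction of nuclei
#' whose excess is at least `offset` (e.g. transfection efficiency at
#' 200 A.U. above background).
#'
#' @param nuclei integer label array.
#' @param signal intensity array, same shape.
#' @param offset required excess, A.U.
#' @param background background level; `"mode"` (default) uses the histogram
#'   mode of the out-of-nucleus voxels.
#' @return fraction in \[0, 1\].
#' @export
fraction_above_background <- function(nuclei, signal, offset = 200,
                                      background = "mode") {
  n <- max(nuclei)
  stopifnot(n > 0)
  bg <- if (identical(background, "mode")) mode_estimate(signal[nuclei == 0]) else background
  excess <- vapply(seq_len(n), function(i) mean(signal[nuclei == i]) - bg, numeric(1))
  mean(excess >= offset)
}

#' Total and dilute-phase concentration proxies for one nucleus
#'
#' `c_tot` is the mean signal over the whole nucleus; `c_dil` the mean over
#' the nucleoplasm with detected bright telomeres (dilated by 1 px) masked
#' out. Warns when the dilated telomere mask covers more than half the
#' nucleus.
#'
#' @param nucleus_mask logical matrix.
#' @param signal 2D intensity matrix.
#' @param pixel_size um per pixel.
#' @param diameter_um,threshold_sigmas telomere detector settings
#'   (see [detect_puncta()]).
#' @param dilate_px dilation of the telomere mask, px.
#' @return one-row tibble (c_tot, c_dil, n_telomeres, masked_fraction).
#' @export
dilute_phase_measurement <- function(nucleus_mask, signal, pixel_size = 0.106,
                                     diameter_um = 0.5, threshold_sigmas = 2,
                                     dilate_px = 1) {
  stopifnot(any(nucleus_mask))
  c_tot <- mean(signal[nucleus_mask])
  # fill the outside with the nuclear mean so the nucleus rim does not fire
  # the blob detector
  sig_in <- signal
  sig_in[!nucleus_mask] <- c_tot
  det <- detect_puncta(sig_in, pixel_size = pixel_size, diameter_um = diameter_um,
                       threshold_sigmas = threshold_sigmas)
  if (nrow(det)) {
    iy <- pmin(pmax(round(det$y_px), 1), nrow(signal))
    ix <- pmin(pmax(round(det$x_px), 1), ncol(signal))
    det <- det[nucleus_mask[cbind(iy, ix)], , drop = FALSE]
  }
  telo_mask <- matrix(FALSE, nrow(signal), ncol(signal))
  if (nrow(det)) {
    # mark the punctum footprint: disc of the detection scale around each peak
    r <- max(1, round(diameter_um / pixel_size / 2))
    for (i in seq_len(nrow(det))) {
      yy <- round(det$y_px[i]); xx <- round(det$x_px[i])
      ys <- max(1, yy - r):min(nrow(signal), yy + r)
      xs <- max(1, xx - r):min(ncol(signal), xx + r)
      sub <- outer(ys - yy, xs - xx, function(a, b) a^2 + b^2 <= r^2)
      telo_mask[ys, xs] <- telo_mask[ys, xs] | sub
    }
    telo_mask <- dilate_mask(telo_mask, iter = dilate_px)
  }
  masked_fraction <- sum(telo_mask & nucleus_mask) / sum(nucleus_mask)
  if (masked_fraction > 0.5)
    warning("telomere mask covers >50% of the nucleus; dilution suspect", call. = FALSE)
  dil_sel <- nucleus_mask & !telo_mask
  c_dil <- if (any(dil_sel)) mean(signal[dil_sel]) else NA_real_
  tibble::tibble(c_tot = c_tot, c_dil = c_dil, n_telomeres = nrow(det),
                 masked_fraction = masked_fraction)
}
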