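# Seeded generators for every input the pipeline consumes, each returning the
# rendered data plus a ground-truth table. All randomness flows from the
# explicit `seed` argument (the global RNG state is restored afterwards), so
# identical (params, seed) reproduce output bit-exactly.

# Add a blurred-edge disc/ellipse to an image. The edge profile is the
# integral of a Gaussian of SD `edge_sigma` px across the boundary, i.e.
# intensity = amp * pnorm((1 - rho) * r_eff / edge_sigma) with rho the
# elliptical radius. Works on a local bounding box for speed.
add_ellipse <- function(img, yc, xc, a_px, b_px, theta = 0, amp = 1, edge_sigma = 1) {
  ny <- nrow(img); nx <- ncol(img)
  half <- ceiling(max(a_px, b_px) + 4 * edge_sigma + 2)
  ys <- max(1, floor(yc - half)):min(ny, ceiling(yc + half))
  xs <- max(1, floor(xc - half)):min(nx, ceiling(xc + half))
  if (!length(ys) || !length(xs)) return(img)
  dy <- ys - yc
  dx <- xs - xc
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dy, dx, function(y, x)  y * ct + x * st)
  v <- outer(dy, dx, function(y, x) -y * st + x * ct)
  rho <- sqrt((u / a_px)^2 + (v / b_px)^2)
  r_eff <- sqrt(a_px * b_px)
  prof <- stats::pnorm((1 - rho) * r_eff / edge_sigma)
  prof[prof < 1e-4] <- 0            # compact support (sub-quantization tail)
  img[ys, xs] <- img[ys, xs] + amp * prof
  img
}

# Add an isotropic 2D Gaussian punctum with the given integrated intensity.
add_punctum <- function(img, yc, xc, total, sigma_px = 1.3) {
  ny <- nrow(img); nx <- ncol(img)
  half <- ceiling(5 * sigma_px)
  ys <- max(1, floor(yc - half)):min(ny, ceiling(yc + half))
  xs <- max(1, floor(xc - half)):min(nx, ceiling(xc + half))
  g <- outer(ys - yc, xs - xc, function(y, x) exp(-(y^2 + x^2) / (2 * sigma_px^2)))
  g[g < 1e-4] <- 0                  # compact support (sub-quantization tail)
  img[ys, xs] <- img[ys, xs] + total / (2 * pi * sigma_px^2) * g
  img
}

# Add a 3D Gaussian punctum (total = integrated intensity over voxels).
add_punctum_3d <- function(vol, zc, yc, xc, total, sigma_px = 1.3, sigma_z = 1) {
  d <- dim(vol)
  hz <- ceiling(4 * sigma_z); hy <- ceiling(4 * sigma_px)
  zs <- max(1, floor(zc - hz)):min(d[1], ceiling(zc + hz))
  ys <- max(1, floor(yc - hy)):min(d[2], ceiling(yc + hy))
  xs <- max(1, floor(xc - hy)):min(d[3], ceiling(xc + hy))
  gz <- exp(-(zs - zc)^2 / (2 * sigma_z^2))
  gy <- exp(-(ys - yc)^2 / (2 * sigma_px^2))
  gx <- exp(-(xs - xc)^2 / (2 * sigma_px^2))
  g <- outer(gz, outer(gy, gx))
  g[g < 1e-4] <- 0                  # compact support (sub-quantization tail)
  norm <- (2 * pi)^1.5 * sigma_z * sigma_px^2
  vol[zs, ys, xs] <- vol[zs, ys, xs] + total / norm * array(g, c(length(zs), length(ys), length(xs)))
  vol
}

# Poisson-Gaussian camera noise. SNR is defined as peak signal amplitude over
# the shot-noise SD at that amplitude; a small Gaussian read-noise floor
# (amp / (4 snr)) is added on top. snr = Inf returns the input unchanged.
apply_noise <- function(img, snr, amp) {
  if (!is.finite(snr)) return(img)
  stopifnot(snr > 0, amp > 0)
  gain <- snr^2 / amp                      # photons per intensity unit
  shot <- matrix(rpois(length(img), pmax(img, 0) * gain) / gain, nrow(img))
  shot + matrix(rnorm(length(img), sd = amp / (4 * snr)), nrow(img))
}

#' Simulate a field of settled droplets
#'
#' Renders non-overlapping bright discs with Gaussian edge blur (SD 1 px) on a
#' constant background, imitating a near-TIRF field of condensates settled on
#' a coverslip, with Poisson-Gaussian noise at the stated SNR. Droplets are
#' placed by rejection sampling; an impossible packing is an explicit error.
#'
#' @param n_droplets number of droplets (0 gives a blank noisy field).
#' @param radius_range min/max droplet radius, um.
#' @param pixel_size um per pixel.
#' @param snr peak-signal-to-noise ratio; `Inf` for noiseless.
#' @param field_size image side, px.
#' @param background background level relative to droplet amplitude 1.
#' @param seed integer seed.
#' @param min_area_px area below which a droplet is flagged `below_min_size`.
#' @return list with `image` (an [image_stack], axes `"yx"`) and `truth`
#'   (tibble: id, y_px, x_px, y_um, x_um, radius_um, area_px, volume_um3,
#'   below_min_size).
#' @export
sim_droplet_field <- function(n_droplets, radius_range = c(0.5, 2), pixel_size = 0.106,
                              snr = 10, field_size = 256, background = 0.1,
                              seed = 1, min_area_px = 10) {
  stopifnot(length(radius_range) == 2, radius_range[1] <= radius_range[2],
            radius_range[1] / pixel_size >= 1.5)
  withr::with_seed(seed, {
    img <- matrix(background, field_size, field_size)
    truth <- tibble::tibble(id = integer(), y_px = numeric(), x_px = numeric(),
                            radius_um = numeric())
    placed <- matrix(numeric(0), 0, 3) # y, x, r_px
    for (i in seq_len(n_droplets)) {
      r_um <- runif(1, radius_range[1], radius_range[2])
      r_px <- r_um / pixel_size
      ok <- FALSE
      for (try in 1:2000) {
        yc <- runif(1, r_px + 4, field_size - r_px - 3)
        xc <- runif(1, r_px + 4, field_size - r_px - 3)
        if (nrow(placed) == 0 ||
            all(sqrt((placed[, 1] - yc)^2 + (placed[, 2] - xc)^2) >
                placed[, 3] + r_px + 6)) { ok <- TRUE; break }
      }
      if (!ok) stop("impossible packing: cannot place ", n_droplets,
                    " non-overlapping droplets of radius ", signif(r_um, 3),
                    " um in a ", field_size, " px field", call. = FALSE)
      placed <- rbind(placed, c(yc, xc, r_px))
      img <- add_ellipse(img, yc, xc, r_px, r_px, amp = 1, edge_sigma = 1)
      truth <- dplyr::bind_rows(truth, tibble::tibble(id = i, y_px = yc, x_px = xc,
                                                      radius_um = r_um))
    }
    img <- apply_noise(img, snr, amp = 1)
    truth <- dplyr::mutate(
      truth,
      y_um = (.data$y_px - 1) * pixel_size,
      x_um = (.data$x_px - 1) * pixel_size,
      area_px = pi * (.data$radius_um / pixel_size)^2,
      volume_um3 = 4 / 3 * pi * .data$radius_um^3,
      below_min_size = .data$area_px < min_area_px
    )
    list(image = image_stack(img, "yx", pixel_size = pixel_size), truth = truth)
  })
}

#' Simulate a droplet fusion movie
#'
#' Two touching discs merge at the contact frame into a single ellipse whose
#' aspect ratio relaxes exponentially from 2 toward `ar_floor`, with the time
#' constant chosen so the aspect ratio first satisfies the spherical
#' criterion (`ar_complete`) exactly `t_fusion` seconds after the last frame
#' in which two separate droplets are visible. Area is conserved through the
#' merge. With `ar_floor` above `ar_complete` the pair adheres and relaxes but
#' never rounds up (gel-like). With `fuse = FALSE` the discs stay separated.
#'
#' @param t_fusion true fusion time, s (must exceed `dt`).
#' @param dt frame interval, s.
#' @param radius disc radius, um.
#' @param pixel_size um per pixel.
#' @param snr peak SNR (`Inf` = noiseless).
#' @param n_pre frames before contact.
#' @param ar_complete spherical criterion the generator calibrates against.
#' @param ar_floor asymptotic aspect ratio (1 = full fusion).
#' @param fuse if `FALSE` the discs never touch.
#' @param seed integer seed.
#' @return list with `image` (axes `"tyx"`) and `truth` (list incl.
#'   `t_fusion`, `contact_frame`).
#' @export
sim_fusion_movie <- function(t_fusion = 21, dt = 1, radius = 1.5, pixel_size = 0.106,
                             snr = Inf, n_pre = 5, ar_complete = 1.1, ar_floor = 1,
                             fuse = TRUE, seed = 1) {
  stopifnot(t_fusion > dt, radius > 0, n_pre >= 1)
  r_px <- radius / pixel_size
  ny <- round(6 * r_px); nx <- round(9 * r_px)
  yc <- ny / 2; xc <- nx / 2
  tau <- if (ar_floor < ar_complete) {
    (t_fusion - dt / 2) / log((2 - ar_floor) / (ar_complete - ar_floor))
  } else t_fusion / log(2)   # gel-like: never crosses the criterion
  n_post <- if (ar_floor < ar_complete) ceiling((t_fusion * 1.6) / dt) + 5 else
    ceiling((t_fusion * 3) / dt)
  n_tot <- if (fuse) n_pre + n_post else n_pre + 10
  withr::with_seed(seed, {
    frames <- array(0.05, c(n_tot, ny, nx))
    gap <- 3
    for (f in seq_len(if (fuse) n_pre else n_tot)) {
      img <- matrix(0.05, ny, nx)
      img <- add_ellipse(img, yc, xc - r_px - gap / 2, r_px, r_px)
      img <- add_ellipse(img, yc, xc + r_px + gap / 2, r_px, r_px)
      frames[f, , ] <- apply_noise(img, snr, 1)
    }
    if (fuse) {
      for (k in seq_len(n_post)) {
        ar <- ar_floor + (2 - ar_floor) * exp(-(k * dt) / tau)
        a <- r_px * sqrt(2 * ar); b <- r_px * sqrt(2 / ar)
        img <- add_ellipse(matrix(0.05, ny, nx), yc, xc, b, a) # long axis along x
        frames[n_pre + k, , ] <- apply_noise(img, snr, 1)
      }
    }
    list(
      image = image_stack(frames, "tyx", pixel_size = pixel_size, frame_interval = dt),
      truth = list(kind = "fusion_movie", t_fusion = if (fuse) t_fusion else NA_real_,
                   contact_frame = if (fuse) n_pre else NA_integer_,
                   ar_floor = ar_floor, dt = dt, fuse = fuse, seed = seed)
    )
  })
}

#' Simulate a 3-channel nuclear z-stack with telomeres and damage foci
#'
#' Channel 1 (`"dna"`): filled ellipsoid nuclei. Channel 2 (`"telomere"`):
#' small Gaussian puncta inside nuclei. Channel 3 (`"foci"`): damage foci,
#' a fraction of which are placed at telomere positions so their voxel sets
#' overlap. Ground truth records per-nucleus counts.
#'
#' @param n_nuclei number of nuclei.
#' @param foci_per_nucleus integer vector (recycled) of true foci counts.
#' @param n_telomeres telomere puncta per nucleus.
#' @param coloc_fraction fraction of foci sharing voxels with a telomere.
#' @param dims stack dimensions c(z, y, x) in voxels.
#' @param pixel_size lateral um/px; `z_step` axial um/slice.
#' @param z_step axial spacing, um.
#' @param snr peak SNR per channel (`Inf` = noiseless).
#' @param seed integer seed.
#' @return list with `image` (axes `"czyx"`, channels dna/telomere/foci) and
#'   `truth` (tibble: nucleus_id, n_foci, n_telomeres, n_colocalized,
#'   nucleus_volume_um3).
#' @export
sim_nucleus_stack <- function(n_nuclei = 3, foci_per_nucleus = 5, n_telomeres = 8,
                              coloc_fraction = 0.5, dims = c(10, 96, 96),
                              pixel_size = 0.2, z_step = 0.4, snr = Inf, seed = 1) {
  stopifnot(n_nuclei >= 1, coloc_fraction >= 0, coloc_fraction <= 1)
  foci_n <- rep_len(as.integer(foci_per_nucleus), n_nuclei)
  withr::with_seed(seed, {
    nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
    dna <- array(0, dims); telo <- array(0, dims); foci <- array(0, dims)
    # place nuclei on a jittered grid so they never overlap
    ncol_grid <- ceiling(sqrt(n_nuclei))
    nrow_grid <- ceiling(n_nuclei / ncol_grid)
    cell_y <- ny / nrow_grid; cell_x <- nx / ncol_grid
    ry <- 0.32 * min(cell_y, cell_x); rz <- max(2.2, nz * 0.3)
    truth <- vector("list", n_nuclei)
    centers <- vector("list", n_nuclei)
    for (i in seq_len(n_nuclei)) {
      gy <- (i - 1) %/% ncol_grid; gx <- (i - 1) %% ncol_grid
      yc <- cell_y * (gy + 0.5) + runif(1, -0.05, 0.05) * cell_y
      xc <- cell_x * (gx + 0.5) + runif(1, -0.05, 0.05) * cell_x
      zc <- nz / 2 + runif(1, -0.5, 0.5)
      rr <- ry * runif(1, 0.9, 1.1)
      zz <- slice.index(dna, 1); yy <- slice.index(dna, 2); xx <- slice.index(dna, 3)
      inside <- ((yy - yc) / rr)^2 + ((xx - xc) / rr)^2 + ((zz - zc) / rz)^2 <= 1
      dna[inside] <- 1
      centers[[i]] <- list(yc = yc, xc = xc, zc = zc, ry = rr, rz = rz)
      # puncta positions strictly inside (elliptical radius < 0.75);
      # colocalized foci reuse telomere positions, so they need no extra point
      n_coloc <- round(coloc_fraction * foci_n[i])
      if (n_coloc > n_telomeres)
        stop("nucleus ", i, ": more colocalized foci requested than telomeres", call. = FALSE)
      n_pts <- n_telomeres + foci_n[i] - n_coloc
      pts <- matrix(NA_real_, 0, 3)
      for (tries in 1:20000) {
        if (nrow(pts) >= n_pts) break
        cand <- c(zc + runif(1, -0.6, 0.6) * rz,
                  yc + runif(1, -0.75, 0.75) * rr,
                  xc + runif(1, -0.75, 0.75) * rr)
        rho <- ((cand[2] - yc) / rr)^2 + ((cand[3] - xc) / rr)^2 + ((cand[1] - zc) / rz)^2
        if (rho > 0.75^2) next
        if (nrow(pts) > 0 &&
            any(sqrt(colSums((t(pts) - cand)^2)) < 7)) next
        pts <- rbind(pts, cand)
      }
      if (nrow(pts) < n_pts)
        stop("nucleus ", i, " cannot fit the requested ", n_pts, " puncta", call. = FALSE)
      telo_pts <- pts[seq_len(n_telomeres), , drop = FALSE]
      for (p in seq_len(nrow(telo_pts)))
        telo <- add_punctum_3d(telo, telo_pts[p, 1], telo_pts[p, 2], telo_pts[p, 3], 80)
      if (foci_n[i] > 0) {
        coloc_at <- telo_pts[seq_len(n_coloc), , drop = FALSE]
        free_at <- if (foci_n[i] > n_coloc)
          pts[n_telomeres + seq_len(foci_n[i] - n_coloc), , drop = FALSE] else
          matrix(numeric(0), 0, 3)
        fp <- rbind(coloc_at, free_at)
        for (p in seq_len(nrow(fp)))
          foci <- add_punctum_3d(foci, fp[p, 1], fp[p, 2], fp[p, 3], 80)
      }
      vol_vox <- sum(inside)
      truth[[i]] <- tibble::tibble(
        nucleus_id = i, n_foci = foci_n[i], n_telomeres = n_telomeres,
        n_colocalized = if (foci_n[i] > 0) n_coloc else 0L,
        nucleus_volume_um3 = vol_vox * pixel_size^2 * z_step,
        center_y_px = yc, center_x_px = xc
      )
    }
    if (is.finite(snr)) {
      for (z in seq_len(nz)) {
        dna[z, , ]  <- apply_noise(dna[z, , ], snr, 1)
        telo[z, , ] <- apply_noise(telo[z, , ], snr, max(telo))
        foci[z, , ] <- apply_noise(foci[z, , ], snr, max(foci))
      }
    }
    arr <- array(0, c(3, nz, ny, nx))
    arr[1, , , ] <- dna; arr[2, , , ] <- telo; arr[3, , , ] <- foci
    list(
      image = image_stack(arr, "czyx", pixel_size = pixel_size, z_step = z_step,
                          channels = c("dna", "telomere", "foci")),
      truth = dplyr::bind_rows(truth)
    )
  })
}

#' Simulate a FRAP trace with known mobile fraction
#'
#' Produces raw bleach-ROI and whole-cell reference traces such that after
#' double normalization (reference-corrected, then rescaled so the pre-bleach
#' mean is 1 and the first post-bleach point is 0) the recovery is
#' `mobile_fraction * (1 - exp(-t/tau))`. Acquisition photobleaching of the
#' whole cell (`photobleach_rate`) multiplies both traces and cancels in the
#' normalization.
#'
#' @param mobile_fraction recovering fraction in (0, 1].
#' @param tau recovery time constant, s.
#' @param pre_frames,post_frames frame counts before/after the bleach.
#' @param dt frame interval, s.
#' @param noise_sd Gaussian noise SD added to both raw traces.
#' @param photobleach_rate exponential decay rate of the reference, 1/s.
#' @param gain arbitrary intensity scale of the raw traces.
#' @param seed integer seed.
#' @return tibble (time_s, frame, bleach_roi, reference_roi) with attributes
#'   `bleach_frame` (first post-bleach frame index) and `truth`.
#' @export
sim_frap_curve <- function(mobile_fraction = 0.6, tau = 30, pre_frames = 5,
                           post_frames = 100, dt = 2, noise_sd = 0,
                           photobleach_rate = 0, gain = 1000, seed = 1) {
  stopifnot(mobile_fraction >= 0, mobile_fraction <= 1, pre_frames >= 2, tau >= 0)
  n <- pre_frames + post_frames
  t <- (seq_len(n) - 1) * dt
  bleach_frame <- pre_frames + 1L
  tpost <- t - t[bleach_frame]
  rec <- if (tau == 0) {
    ifelse(t < t[bleach_frame], 1, ifelse(tpost <= 0, 0, mobile_fraction))
  } else {
    ifelse(t < t[bleach_frame], 1, mobile_fraction * (1 - exp(-tpost / tau)))
  }
  ref <- exp(-photobleach_rate * t)
  withr::with_seed(seed, {
    tibble::tibble(
      time_s = t, frame = seq_len(n),
      bleach_roi = gain * ref * rec + rnorm(n, sd = noise_sd),
      reference_roi = gain * ref + rnorm(n, sd = noise_sd)
    ) -> out
    attr(out, "bleach_frame") <- bleach_frame
    attr(out, "truth") <- list(kind = "frap_curve", mobile_fraction = mobile_fraction,
                               tau = tau, seed = seed)
    out
  })
}

#' Simulate a dilute-phase vs total-concentration series
#'
#' Homotypic model: the dilute phase tracks the total below the saturation
#' point and is buffered at `c_star` above it (an endogenous-protein offset
#' `e` adds to the total). Heterotypic model: the dilute phase keeps rising
#' sublinearly, `c_dil = c_tot - A * c_tot / (K + c_tot)`.
#'
#' @param model `"homotypic"` or `"heterotypic"`.
#' @param params named list of model parameters (`c_star`, `e` or `A`, `K`).
#' @param n_points number of (c_tot, c_dil) pairs.
#' @param c_tot_range range of total concentration sampled (even grid).
#' @param noise_sd additive Gaussian noise SD on c_dil (same units).
#' @param seed integer seed.
#' @return tibble (c_tot, c_dil) with attribute `truth`.
#' @export
sim_dilute_series <- function(model = c("heterotypic", "homotypic"),
                              params = NULL, n_points = 12,
                              c_tot_range = c(1, 10), noise_sd = 0, seed = 1) {
  model <- match.arg(model)
  params <- params %||% switch(model,
    homotypic = list(c_star = 4, e = 0.5),
    heterotypic = list(A = 4, K = 4))
  fn <- dilute_model_fn(model)
  withr::with_seed(seed, {
    c_tot <- seq(c_tot_range[1], c_tot_range[2], length.out = n_points)
    c_dil <- fn(c_tot, params) + rnorm(n_points, sd = noise_sd)
    c_dil <- pmin(pmax(c_dil, 0), c_tot)   # dilute phase cannot exceed total
    out <- tibble::tibble(c_tot = c_tot, c_dil = c_dil)
    attr(out, "truth") <- list(kind = "dilute_series", model = model,
                               params = params, noise_sd = noise_sd, seed = seed)
    out
  })
}

#' Simulate a coalescence movie with conserved integrated intensity
#'
#' Two Gaussian puncta of integrated intensities `I1`, `I2` merge at frame
#' `t_merge` into a single punctum of integrated intensity `I1 + I2` (or
#' `post_intensity`, to construct conservation violations). A merge frame
#' beyond the movie leaves two objects in every frame.
#'
#' @param I1,I2 integrated intensities of the two puncta.
#' @param t_merge first frame with a single merged punctum.
#' @param n_frames movie length.
#' @param post_intensity integrated intensity after the merge
#'   (default `I1 + I2`, i.e. conserving).
#' @param dims image side, px.
#' @param sigma_px punctum Gaussian SD, px.
#' @param noise_sd additive Gaussian noise SD.
#' @param background constant background level.
#' @param pixel_size um per pixel; `dt` frame interval, s.
#' @param dt frame interval, s.
#' @param seed integer seed.
#' @return list with `image` (axes `"tyx"`) and `truth`.
#' @export
sim_coalescence_movie <- function(I1 = 100, I2 = 50, t_merge = 10, n_frames = 20,
                                  post_intensity = I1 + I2, dims = 64,
                                  sigma_px = 1.6, noise_sd = 0, background = 2,
                                  pixel_size = 0.106, dt = 1, seed = 1) {
  stopifnot(n_frames >= 2, t_merge >= 2)
  withr::with_seed(seed, {
    frames <- array(0, c(n_frames, dims, dims))
    yc <- dims / 2
    x1 <- dims / 2 - 6; x2 <- dims / 2 + 6
    for (f in seq_len(n_frames)) {
      img <- matrix(background, dims, dims)
      if (f < t_merge) {
        if (I1 > 0) img <- add_punctum(img, yc, x1, I1, sigma_px)
        if (I2 > 0) img <- add_punctum(img, yc, x2, I2, sigma_px)
      } else {
        if (post_intensity > 0)
          img <- add_punctum(img, yc, (x1 + x2) / 2, post_intensity, sigma_px)
      }
      if (noise_sd > 0) img <- img + matrix(rnorm(dims * dims, sd = noise_sd), dims)
      frames[f, , ] <- img
    }
    list(
      image = image_stack(frames, "tyx", pixel_size = pixel_size, frame_interval = dt),
      truth = list(kind = "coalescence_movie", I1 = I1, I2 = I2,
                   t_merge = if (t_merge <= n_frames) t_merge else NA_integer_,
                   post_intensity = post_intensity, background = background, seed = seed)
    )
  })
}

#' Simulate an influx/partitioning movie
#'
#' A droplet region whose interior intensity rises as
#' `PC(t) = 1 + pc_gain * (1 - exp(-t/tau))` relative to a constant exterior,
#' for testing partition-coefficient time courses.
#'
#' @param tau influx time constant, s.
#' @param pc_gain asymptotic PC excess over 1.
#' @param n_frames frames; `dt` seconds per frame.
#' @param dt frame interval, s.
#' @param dims image side, px; `radius_px` droplet radius.
#' @param radius_px droplet radius, px.
#' @param outside intensity outside the droplet.
#' @param noise_sd additive Gaussian noise SD.
#' @param pixel_size um per pixel.
#' @param seed integer seed.
#' @return list with `image` (axes `"tyx"`), `droplet_mask`, `background_mask`,
#'   and `truth`.
#' @export
sim_influx_movie <- function(tau = 20, pc_gain = 4, n_frames = 60, dt = 2,
                             dims = 64, radius_px = 10, outside = 10,
                             noise_sd = 0, pixel_size = 0.106, seed = 1) {
  withr::with_seed(seed, {
    yy <- matrix(rep(seq_len(dims), dims), dims)
    xx <- t(yy)
    r <- sqrt((yy - dims / 2)^2 + (xx - dims / 2)^2)
    droplet <- r <= radius_px
    bg <- r >= radius_px + 6
    frames <- array(0, c(n_frames, dims, dims))
    for (f in seq_len(n_frames)) {
      t <- (f - 1) * dt
      pc <- 1 + pc_gain * (1 - exp(-t / tau))
      img <- matrix(outside, dims, dims)
      img[droplet] <- outside * pc
      if (noise_sd > 0) img <- img + matrix(rnorm(dims^2, sd = noise_sd), dims)
      frames[f, , ] <- img
    }
    list(image = image_stack(frames, "tyx", pixel_size = pixel_size, frame_interval = dt),
         droplet_mask = droplet, background_mask = bg,
         truth = list(kind = "influx_movie", tau = tau, pc_gain = pc_gain, seed = seed))
  })
}
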