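# Motion analysis: registration, detection, linking, MSD, power-law fits,
# first-passage extrapolation, geometry, FRAP normalization.

make_spot_scene <- function(n = 12, seed = 2, dims = 64) {
  img <- matrix(0, dims, dims)
  withr::with_seed(seed, {
    for (i in seq_len(n))
      img <- telodrop:::add_punctum(img, runif(1, 10, dims - 10),
                                    runif(1, 10, dims - 10), 50, 1.5)
  })
  img
}

test_that("registration recovers injected subpixel shifts", {
  img0 <- make_spot_scene()
  sh <- rbind(c(0, 0), c(1.6, -2.4), c(-3.2, 0.8), c(0.35, 3.2))
  frames <- array(0, c(4, 64, 64))
  for (f in 1:4) frames[f, , ] <- telodrop:::bilinear_shift(img0, -sh[f, 1], -sh[f, 2])
  reg <- register_translation(image_stack(frames, "tyx"))
  expect_lt(max(abs(as.matrix(reg$shifts[, c("dy_px", "dx_px")]) - sh)), 0.1)

  # identical frames: all shifts zero
  same <- array(0, c(3, 64, 64)); for (f in 1:3) same[f, , ] <- img0
  rs <- register_translation(image_stack(same, "tyx"))
  expect_true(all(rs$shifts$dy_px == 0 & rs$shifts$dx_px == 0))

  # single frame: identity
  one <- register_translation(image_stack(array(img0, c(1, 64, 64)), "tyx"))
  expect_equal(one$movie$data, array(img0, c(1, 64, 64)))

  # featureless frame: zero shift with a warning flag
  flat <- array(0, c(2, 64, 64)); flat[1, , ] <- img0
  expect_warning(rf <- register_translation(image_stack(flat, "tyx")), "featureless")
  expect_true(rf$shifts$flat[2])
})

test_that("LoG detection is precise and high-recall on rendered puncta", {
  expect_equal(nrow(detect_puncta(matrix(0, 50, 50))), 0)

  dims <- 128
  pos <- withr::with_seed(3, {
    p <- cbind(runif(60, 10, dims - 10), runif(60, 10, dims - 10))
    keep <- rep(TRUE, 60)
    for (i in 2:60)
      if (min(sqrt((p[1:(i - 1), 1] - p[i, 1])^2 +
                   (p[1:(i - 1), 2] - p[i, 2])^2)) < 10) keep[i] <- FALSE
    p[keep, ][1:min(40, sum(keep)), ]
  })
  img <- matrix(1, dims, dims)
  for (i in seq_len(nrow(pos)))
    img <- telodrop:::add_punctum(img, pos[i, 1], pos[i, 2], 60, 1.3)
  peak <- 60 / (2 * pi * 1.3^2)
  img <- img + withr::with_seed(4, matrix(rnorm(dims^2, sd = peak / 8), dims))
  det <- detect_puncta(img, pixel_size = 0.106, diameter_um = 0.5,
                       threshold_sigmas = 2)
  dm <- as.matrix(stats::dist(rbind(cbind(det$y_px, det$x_px), pos)))
  dm <- dm[seq_len(nrow(det)), nrow(det) + seq_len(nrow(pos)), drop = FALSE]
  recall <- mean(apply(dm, 2, min) < 1)
  precision <- mean(apply(dm, 1, min) < 1)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
  expect_lt(max(apply(dm, 2, min)[apply(dm, 2, min) < 1]), 0.5)

  # two puncta 10 px apart: both found, subpixel-accurate
  two <- matrix(0, 40, 40)
  two <- telodrop:::add_punctum(two, 20.3, 12.7, 50, 1.3)
  two <- telodrop:::add_punctum(two, 20.3, 22.7, 50, 1.3)
  d2 <- detect_puncta(two, pixel_size = 1, diameter_um = 3.7)
  expect_equal(nrow(d2), 2)
  expect_lt(max(abs(sort(d2$x_px) - c(12.7, 22.7))), 0.5)
})

test_that("linking matches exhaustive minimal-cost matching on small frames", {
  for (case in 1:25) {
    withr::with_seed(case, {
      n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
      A <- cbind(runif(n1), runif(n1))
      B <- cbind(runif(n2), runif(n2))
    })
    max_link <- 0.45
    det <- tibble::tibble(
      frame = c(rep(1L, nrow(A)), rep(2L, nrow(B))),
      y_um = c(A[, 1], B[, 1]), x_um = c(A[, 2], B[, 2]))
    tr <- link_trajectories(det, n_frames_total = 2, max_link_um = max_link,
                            min_span_fraction = 0)
    expect_equal(realized_link_cost(tr, A, B, max_link),
                 oracle_link_cost(A, B, max_link), tolerance = 1e-9)
  }
})

test_that("linking terminates tracks rather than jumping beyond max_link", {
  # one stationary spot
  det <- tibble::tibble(frame = 1:100, y_um = 5, x_um = 5)
  tr <- link_trajectories(det, n_frames_total = 100)
  expect_equal(max(tr$track_id), 1)
  expect_equal(nrow(tr), 100)

  # both spots move farther than max_link: all links forbidden, four tracks
  det2 <- tibble::tibble(frame = c(1L, 1L, 2L, 2L),
                         y_um = c(0, 0, 0, 0), x_um = c(0, 2, 5, 7))
  tr2 <- link_trajectories(det2, n_frames_total = 2, max_link_um = 0.5,
                           min_span_fraction = 0)
  expect_equal(max(tr2$track_id), 4)

  # a spot visible 40 of 100 frames is discarded at the default span rule
  det3 <- tibble::tibble(frame = 1:40, y_um = 1, x_um = 1)
  expect_equal(nrow(link_trajectories(det3, n_frames_total = 100)), 0)
})

test_that("MSD curves obey closed forms", {
  stat <- tibble::tibble(track_id = 1, frame = 1:50, t_s = 0:49,
                         x_um = 2, y_um = 3)
  expect_true(all(compute_msd(stat)$msd_um2 == 0))

  v <- 0.2
  drift <- tibble::tibble(track_id = 1, frame = 1:80, t_s = 0:79,
                          x_um = v * (0:79), y_um = 0)
  md <- compute_msd(drift)
  expect_equal(md$msd_um2, v^2 * md$lag_s^2, tolerance = 1e-10)
  fd <- fit_msd_powerlaw(md)
  expect_equal(fd$alpha, 2, tolerance = 1e-8)

  # n_pairs is non-increasing with lag
  expect_true(all(diff(md$n_pairs) <= 0))
})

test_that("power-law fits are exact on exact curves and guard their inputs", {
  lag <- 1:30
  curve <- tibble::tibble(lag_s = lag, msd_um2 = 2.8e-3 * lag^0.54,
                          n_pairs = rep(100L, 30))
  class(curve) <- c("msd_curve", class(curve))
  f <- fit_msd_powerlaw(curve)
  expect_equal(f$alpha, 0.54, tolerance = 1e-12)
  expect_equal(f$D, 2.8e-3, tolerance = 1e-12)

  lin <- dplyr::mutate(curve, msd_um2 = 0.42 * lag_s)
  fl <- fit_msd_powerlaw(lin)
  expect_equal(fl$alpha, 1, tolerance = 1e-12)
  expect_equal(fl$D, 0.42, tolerance = 1e-12)

  expect_error(fit_msd_powerlaw(curve[1:3, ]), "insufficient")

  # static-error correction strips a known noise floor exactly
  noisy <- dplyr::mutate(curve, msd_um2 = msd_um2 + 2 * 0.02^2)
  fn <- fit_msd_powerlaw(noisy, static_error = 0.02)
  expect_equal(fn$alpha, 0.54, tolerance = 1e-10)
})

test_that("encounter times follow the first-passage inversion", {
  fit <- list(D = 2.8e-3, alpha = 0.54)
  # Brownian closed form
  b <- list(D = 0.01, alpha = 1)
  expect_equal(encounter_time(b, 2)$time_s, 2^2 / (2 * 0.01))
  expect_equal(encounter_time(b, 2, mode = "single_locus")$time_s, 2^2 / 0.01)

  # strictly decreasing in D, increasing in separation
  t1 <- encounter_time(fit, 3)$time_s
  expect_gt(encounter_time(list(D = 2e-3, alpha = 0.54), 3)$time_s, t1)
  expect_gt(encounter_time(fit, 4)$time_s, t1)

  expect_error(encounter_time(list(D = 1, alpha = -1), 2), "alpha")
})

test_that("telomere geometry statistics match enumeration", {
  two <- tibble::tibble(y_um = c(0, 3), x_um = c(0, 4))
  g <- telomere_geometry(two)
  expect_equal(g$nn_mean_um, 5)
  expect_equal(g$pairwise_mean_um, 5)

  sq <- tibble::tibble(y_um = c(0, 0, 1, 1), x_um = c(0, 1, 0, 1))
  gs <- telomere_geometry(sq)
  expect_equal(gs$nn_mean_um, 1)
  expect_equal(gs$pairwise_mean_um, (4 + 2 * sqrt(2)) / 6)

  # puncta outside the nucleus mask are excluded
  mask <- matrix(FALSE, 20, 20); mask[1:10, 1:10] <- TRUE
  p <- tibble::tibble(y_um = c(2, 2, 15), x_um = c(2, 6, 15),
                      y_px = c(2, 2, 15), x_px = c(2, 6, 15))
  gm <- telomere_geometry(p, mask)
  expect_equal(gm$n_puncta, 2)
  expect_equal(gm$pairwise_mean_um, 4)

  expect_error(telomere_geometry(two[1, ]), ">= 2")
})

test_that("FRAP double normalization anchors and invariances hold", {
  fr <- sim_frap_curve(0.6, 30, noise_sd = 0, photobleach_rate = 0.002, seed = 1)
  nf <- frap_normalize(fr)
  bf <- attr(nf, "bleach_frame")
  expect_equal(mean(nf$normalized[seq_len(bf - 1)]), 1)
  expect_identical(nf$normalized[bf], 0)

  # photobleaching decay of the reference cancels exactly
  fr0 <- sim_frap_curve(0.6, 30, noise_sd = 0, photobleach_rate = 0, seed = 1)
  expect_equal(frap_normalize(fr0)$normalized, nf$normalized, tolerance = 1e-9)

  # global intensity scaling of both traces cancels
  sc <- dplyr::mutate(fr, bleach_roi = bleach_roi * 17,
                      reference_roi = reference_roi * 17)
  attr(sc, "bleach_frame") <- attr(fr, "bleach_frame")
  expect_equal(frap_normalize(sc)$normalized, nf$normalized, tolerance = 1e-12)

  # no-bleach trace: degenerate rescale flagged, curve ~ 1
  nob <- tibble::tibble(time_s = 0:19, bleach_roi = rep(100, 20),
                        reference_roi = rep(200, 20))
  attr(nob, "bleach_frame") <- 6L
  expect_warning(nn <- frap_normalize(nob), "degenerate")
  expect_true(all(abs(nn$normalized - 1) < 1e-12))
  expect_true(attr(nn, "degenerate"))

  bad <- dplyr::mutate(fr, reference_roi = -reference_roi)
  attr(bad, "bleach_frame") <- attr(fr, "bleach_frame")
  expect_error(frap_normalize(bad), "non-positive")
})

test_that("parameter recovery at the fitted subdiffusion law (reduced scale)", {
  res <- vapply(1:4, function(s) {
    sim <- sim_fbm_trajectories(0.54, 2.8e-3, n_traj = 80, n_frames = 300,
                                dt = 1, loc_noise = 0.02, seed = 400 + s)
    f <- fit_msd_powerlaw(compute_msd(sim$trajectories), fit_range = c(2, 30),
                          static_error = 0.02)
    c(f$alpha, f$D)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - 0.54), 0.05)
  expect_lt(abs(mean(res[2, ]) - 2.8e-3) / 2.8e-3, 0.2)
})

test_that("end-to-end tracking recovers trajectories from rendered movies", {
  # three well-separated slow spots, 40 frames
  nfr <- 40; dims <- 72
  centers <- rbind(c(18, 18), c(18, 54), c(54, 36))
  frames <- array(0, c(nfr, dims, dims))
  paths <- withr::with_seed(9, lapply(1:3, function(i) {
    cbind(centers[i, 1] + cumsum(rnorm(nfr, 0, 0.3)),
          centers[i, 2] + cumsum(rnorm(nfr, 0, 0.3)))
  }))
  for (f in seq_len(nfr)) {
    img <- matrix(0.5, dims, dims)
    for (i in 1:3) img <- telodrop:::add_punctum(img, paths[[i]][f, 1],
                                                 paths[[i]][f, 2], 60, 1.3)
    frames[f, , ] <- img
  }
  mv <- image_stack(frames, "tyx", pixel_size = 0.106)
  tr <- track_puncta(mv, register = FALSE, max_link_um = 0.5)
  expect_equal(dplyr::n_distinct(tr$track_id), 3)
  expect_true(all(table(tr$track_id) == nfr))
})
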