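# Droplet segmentation and morphometrics.

test_that("Phansalkar threshold matches a naive double-loop evaluation", {
  set.seed(101)
  for (trial in 1:12) {
    img <- matrix(runif(16 * 16), 16, 16)
    got <- threshold_phansalkar(img, radius = 3)
    expect_identical(got, bf_phansalkar(img, radius = 3))
  }
  # square window variant
  img <- matrix(runif(14 * 14), 14, 14)
  expect_identical(threshold_phansalkar(img, radius = 2, window = "square"),
                   bf_phansalkar(img, radius = 2, circular = FALSE))
})

test_that("Phansalkar degenerate and global-window cases behave", {
  expect_equal(sum(threshold_phansalkar(matrix(0, 9, 9), radius = 2)), 0)

  # a window covering the whole 7x7 image equals one global threshold
  set.seed(7)
  img <- matrix(runif(49), 7, 7)
  got <- threshold_phansalkar(img, radius = 7, window = "square")
  x <- (img - min(img)) / diff(range(img))
  mu <- mean(x); sdv <- sqrt(mean(x^2) - mu^2)
  thr <- mu * (1 + 2 * exp(-10 * mu) + 0.25 * (sdv / 0.5 - 1))
  expect_identical(got, x > thr)

  expect_error(threshold_phansalkar(array(0, c(3, 3, 3))), "2D")
  expect_error(threshold_phansalkar(matrix(0, 5, 5), radius = 0.5), "radius")
})

test_that("segmentation recovers synthetic droplets (Jaccard and counts)", {
  f <- sim_droplet_field(8, radius_range = c(1.1, 2), snr = 10, seed = 21)
  seg <- segment_droplets(f$image)
  expect_equal(nrow(seg$records), 8)
  px <- f$image$pixel_size
  yy <- row(seg$labels); xx <- col(seg$labels)
  for (i in seq_len(nrow(f$truth))) {
    tr <- f$truth[i, ]
    disc <- (yy - tr$y_px)^2 + (xx - tr$x_px)^2 <= (tr$radius_um / px)^2
    lbl <- seg$labels[round(tr$y_px), round(tr$x_px)]
    expect_gt(lbl, 0)
    comp <- seg$labels == lbl
    expect_gte(sum(comp & disc) / sum(comp | disc), 0.8)
  }

  # noiseless count recovery across seeds, against truth above the size floor
  for (s in 1:50) {
    fi <- sim_droplet_field(6, snr = Inf, seed = s)
    expect_equal(nrow(segment_droplets(fi$image)$records),
                 sum(!fi$truth$below_min_size))
  }
})

test_that("labeling applies the minimum-size rule and ellipse conventions", {
  m <- matrix(FALSE, 40, 40)
  yy <- row(m); xx <- col(m)
  m[(yy - 12)^2 + (xx - 12)^2 <= 4^2] <- TRUE    # ~50 px
  m[(yy - 30)^2 + (xx - 30)^2 <= 1.1^2] <- TRUE  # ~5 px
  out <- label_droplets(m, pixel_size = 1, min_area = 10)
  expect_equal(nrow(out$records), 1)

  # perfect disc: a = b = R within 5%, aspect ratio ~ 1
  R <- 10
  disc <- (yy - 20)^2 + (xx - 20)^2 <= R^2
  rec <- label_droplets(disc, pixel_size = 1, min_area = 10)$records
  expect_lt(abs(rec$a_um - R) / R, 0.05)
  expect_lt(abs(rec$b_um - R) / R, 0.05)
  expect_lte(rec$aspect_ratio, 1.05)

  # all-foreground mask: one record spanning the field
  allm <- matrix(TRUE, 20, 20)
  expect_equal(nrow(label_droplets(allm, pixel_size = 1)$records), 1)

  # empty mask: empty record list, not an error
  expect_equal(nrow(label_droplets(matrix(FALSE, 5, 5))$records), 0)
})

test_that("volume estimation follows the geometric-mean convention", {
  r <- 1.7
  expect_equal(estimate_volume(r, r), 4 / 3 * pi * r^3)
  expect_equal(estimate_volume(2, 0.5), 4 / 3 * pi)          # c = 1
  expect_equal(estimate_volume(2, 0.5), estimate_volume(0.5, 2))
  expect_error(estimate_volume(0, 1))
})

test_that("field summaries are additive and handle the empty case", {
  empty <- summarize_field(label_droplets(matrix(FALSE, 5, 5))$records, 100)
  expect_equal(empty$total_volume_per_area, 0)

  one <- tibble::tibble(volume_um3 = 4 / 3 * pi)  # sphere r = 1
  s1 <- summarize_field(one, 100)
  expect_equal(s1$total_volume_per_area, 4 / 3 * pi / 100)

  # concatenating two fields = area-weighted mean of their summaries
  recs_a <- tibble::tibble(volume_um3 = c(1, 2, 3))
  recs_b <- tibble::tibble(volume_um3 = c(4, 5))
  sa <- summarize_field(recs_a, 50); sb <- summarize_field(recs_b, 150)
  sab <- summarize_field(dplyr::bind_rows(recs_a, recs_b), 200)
  expect_equal(sab$total_volume_per_area,
               (sa$total_volume_per_area * 50 + sb$total_volume_per_area * 150) / 200)
})

test_that("dilating every droplet strictly increases volume per area", {
  f <- sim_droplet_field(6, snr = Inf, seed = 33)
  img <- telodrop::get_plane(f$image)
  mask <- threshold_phansalkar(img)
  v0 <- summarize_field(label_droplets(mask, img)$records, 100)$total_volume_per_area
  v1 <- summarize_field(label_droplets(telodrop:::dilate_mask(mask), img)$records,
                        100)$total_volume_per_area
  expect_gt(v1, v0)
})

test_that("partition coefficients behave arithmetically and scale-invariantly", {
  q <- matrix(5, 20, 20)
  dm <- matrix(FALSE, 20, 20); dm[5:8, 5:8] <- TRUE
  bm <- matrix(FALSE, 20, 20); bm[15:18, 15:18] <- TRUE
  expect_equal(partition_coefficient(q, dm, bm), 1)

  q2 <- matrix(1, 20, 20); q2[dm] <- 9
  expect_equal(partition_coefficient(q2, dm, bm), 9)
  expect_equal(partition_coefficient(q2 * 37, dm, bm), 9)   # scale invariance

  expect_error(partition_coefficient(q, dm, matrix(FALSE, 20, 20)), "background")
  expect_error(partition_coefficient(q, dm, dm), "disjoint")
})

test_that("partition time courses recover the influx time constant", {
  inf <- sim_influx_movie(tau = 20, noise_sd = 0, seed = 1)
  tc <- partition_timecourse(inf$image, inf$droplet_mask, inf$background_mask)
  expect_equal(nrow(tc), 60)
  fit <- minpack.lm::nlsLM(pc ~ 1 + g * (1 - exp(-time_s / tau)), data = tc,
                           start = list(g = 2, tau = 8))
  expect_lt(abs(coef(fit)[["tau"]] - 20) / 20, 0.15)

  # static movie -> constant series; single frame -> length 1
  static <- sim_influx_movie(tau = 1e9, n_frames = 5, noise_sd = 0, seed = 2)
  ts <- partition_timecourse(static$image, static$droplet_mask, static$background_mask)
  expect_lt(diff(range(ts$pc)), 1e-6)
  one <- sim_influx_movie(n_frames = 1, noise_sd = 0, seed = 3)
  expect_equal(nrow(partition_timecourse(one$image, one$droplet_mask,
                                         one$background_mask)), 1)
})
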