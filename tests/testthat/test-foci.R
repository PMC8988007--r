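# Nuclear segmentation, 3D counting, colocalization, damage classification,
# coalescence bookkeeping, enrichment and dilute-phase measurements.

test_that("Otsu threshold equals exhaustive between-class-variance search", {
  withr::with_seed(12, {
    for (trial in 1:100) {
      v <- switch(1 + trial %% 3,
                  runif(300),
                  c(rnorm(150, 0.3, 0.05), rnorm(150, 0.7, 0.05)),
                  rexp(300))
      expect_equal(otsu_threshold(v), bf_otsu(v), tolerance = 1e-12)
    }
  })
  # two-valued image: threshold strictly between the values
  img <- matrix(c(rep(10, 60), rep(200, 40)), 10, 10)
  thr <- otsu_threshold(img)
  expect_true(thr > 10 && thr < 200)
  expect_true(is.na(otsu_threshold(matrix(5, 4, 4))))
})

test_that("nucleus segmentation fills holes, sizes, and flags flat images", {
  img <- matrix(10, 60, 60)
  yy <- row(img); xx <- col(img)
  img[(yy - 30)^2 + (xx - 30)^2 <= 15^2] <- 200
  img[(yy - 30)^2 + (xx - 30)^2 <= 3^2] <- 10  # hole
  lab <- segment_nuclei(img, pixel_size = 0.5)
  expect_equal(max(lab), 1)
  expect_true(all(lab[(yy - 30)^2 + (xx - 30)^2 <= 3^2] == 1))  # hole filled

  expect_warning(empty <- segment_nuclei(matrix(1, 20, 20)), "flat")
  expect_equal(max(empty), 0)
})

test_that("per-nucleus counts are exact on noiseless stacks", {
  st <- sim_nucleus_stack(n_nuclei = 2, foci_per_nucleus = c(0, 7),
                          n_telomeres = 6, coloc_fraction = 0.5,
                          dims = c(10, 96, 192), seed = 1)
  ft <- count_foci(st$image)
  m <- match_nuclei(ft, st$truth)
  expect_equal(m$n_foci, m$n_foci.true)
  expect_equal(m$n_telomeres, rep(6L, 2))
  expect_equal(m$n_colocalized, m$n_colocalized.true)
  expect_true(all(m$n_colocalized <= pmin(m$n_foci, m$n_telomeres)))

  for (s in 2:12) {
    sti <- sim_nucleus_stack(n_nuclei = 2, foci_per_nucleus = c(0, 7),
                             n_telomeres = 6, coloc_fraction = 0.5,
                             dims = c(10, 96, 192), seed = s)
    mi <- match_nuclei(count_foci(sti$image), sti$truth)
    expect_equal(mi$n_foci, mi$n_foci.true)
    expect_equal(mi$n_telomeres, mi$n_telomeres.true)
    expect_equal(mi$n_colocalized, mi$n_colocalized.true)
  }
})

test_that("counting survives realistic noise (snr = 6)", {
  for (s in 1:3) {
    st <- sim_nucleus_stack(n_nuclei = 2, foci_per_nucleus = c(5, 9),
                            n_telomeres = 6, coloc_fraction = 0.5,
                            dims = c(10, 96, 192), snr = 6, seed = s)
    ft <- count_foci(st$image, threshold_sigmas = 4, min_voxels = 3)
    m <- match_nuclei(ft, st$truth)
    recovery <- sum(pmin(m$n_foci, m$n_foci.true)) / sum(m$n_foci.true)
    expect_gte(recovery, 0.95)
  }
})

test_that("full colocalization and disjoint channels give the boundary counts", {
  st <- sim_nucleus_stack(n_nuclei = 2, foci_per_nucleus = 4, n_telomeres = 6,
                          coloc_fraction = 1, dims = c(10, 96, 192), seed = 5)
  ft <- count_foci(st$image)
  expect_equal(ft$n_colocalized, ft$n_foci)

  st0 <- sim_nucleus_stack(n_nuclei = 2, foci_per_nucleus = 4, n_telomeres = 6,
                           coloc_fraction = 0, dims = c(10, 96, 192), seed = 6)
  expect_true(all(count_foci(st0$image)$n_colocalized == 0))

  # one shared voxel is enough
  a <- array(0L, c(3, 5, 5)); a[2, 2, 2] <- 1L; a[2, 2, 3] <- 1L
  b <- array(0L, c(3, 5, 5)); b[2, 2, 3] <- 1L
  expect_true(colocalize(a, b))
  b2 <- array(0L, c(3, 5, 5)); b2[1, 5, 5] <- 1L
  expect_false(colocalize(a, b2))
})

test_that("a focus outside every nucleus is excluded from the table", {
  st <- sim_nucleus_stack(n_nuclei = 1, foci_per_nucleus = 3, n_telomeres = 4,
                          coloc_fraction = 0, dims = c(10, 96, 96), seed = 7)
  img <- st$image
  # plant an extra focus in a corner far from the nucleus
  vol <- telodrop::get_plane(img, channel = "foci")
  vol <- telodrop:::add_punctum_3d(vol, 5, 6, 6, 80)
  img$data[3, , , ] <- vol
  ft <- count_foci(img)
  expect_equal(ft$n_foci, 3L)
})

test_that("damage classification counts strictly-greater nuclei", {
  tab <- tibble::tibble(n_foci = c(3L, 12L, 25L))
  expect_equal(damage_classification(tab), 2 / 3)
  expect_equal(damage_classification(tibble::tibble(n_foci = c(1L, 10L, 4L))), 0)
  expect_equal(damage_classification(tibble::tibble(n_foci = c(2L, 5L)), threshold = 0), 1)

  # invariant to ordering; non-increasing in threshold
  expect_equal(damage_classification(tab[c(3, 1, 2), ]), 2 / 3)
  fr <- vapply(0:30, function(th) damage_classification(tab, th), numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("coalescence conservation verdicts separate true from violated", {
  for (s in 1:4) {
    ok <- coalescence_bookkeeping(
      sim_coalescence_movie(I1 = 100, I2 = 50, noise_sd = 0.3, seed = s)$image)
    expect_true(ok$conserved)
    expect_lt(abs(ok$predicted_post - 150) / 150, 0.1)
    bad <- coalescence_bookkeeping(
      sim_coalescence_movie(I1 = 100, I2 = 50, post_intensity = 100,
                            noise_sd = 0.3, seed = s + 40)$image)
    expect_false(bad$conserved)
  }
})

test_that("locally-activated enrichment normalization is pure arithmetic", {
  fr <- matrix(10, 30, 30)          # background level 10
  tgt <- matrix(FALSE, 30, 30); tgt[5:7, 5:7] <- TRUE
  o1 <- matrix(FALSE, 30, 30); o1[15:17, 5:7] <- TRUE
  o2 <- matrix(FALSE, 30, 30); o2[25:27, 5:7] <- TRUE
  bg <- matrix(FALSE, 30, 30); bg[5:7, 25:27] <- TRUE
  fr[o1] <- 30; fr[o2] <- 50       # others average to 40 -> excess 30

  fr1 <- fr; fr1[tgt] <- 40
  expect_equal(corelet_enrichment(fr1, tgt, list(o1, o2), bg), 1)
  fr2 <- fr; fr2[tgt] <- 10
  expect_equal(corelet_enrichment(fr2, tgt, list(o1, o2), bg), 0)
  fr3 <- fr; fr3[tgt] <- 70        # excess 60 = 2x
  expect_equal(corelet_enrichment(fr3, tgt, list(o1, o2), bg), 2)
  expect_error(corelet_enrichment(fr1, tgt, list(), bg), "reference")
})

test_that("the above-background fraction counts nuclei correctly", {
  lab <- array(0L, c(40, 40))
  sig <- matrix(100, 40, 40)
  for (i in 1:10) lab[(4 * i - 3):(4 * i - 1), 2:4] <- i
  sig[lab %in% 1:3] <- 400     # 3 of 10 at background + 300
  expect_equal(fraction_above_background(lab, sig, offset = 200), 0.3)
  expect_equal(fraction_above_background(lab, matrix(100, 40, 40), offset = 200), 0)
  expect_equal(fraction_above_background(lab, sig, offset = 0), 1)
})

test_that("dilute-phase measurement masks condensates out of the nucleoplasm", {
  dims <- 96
  nuc <- matrix(FALSE, dims, dims)
  yy <- row(nuc); xx <- col(nuc)
  nuc[(yy - 48)^2 + (xx - 48)^2 <= 40^2] <- TRUE
  sig <- matrix(0, dims, dims)
  sig[nuc] <- 50                                    # dilute level
  pts <- rbind(c(30, 30), c(30, 66), c(66, 48))
  for (i in 1:3) sig <- telodrop:::add_punctum(sig, pts[i, 1], pts[i, 2], 3000, 1.5)
  res <- dilute_phase_measurement(nuc, sig, pixel_size = 0.106)
  expect_equal(res$n_telomeres, 3)
  expect_lt(abs(res$c_dil - 50) / 50, 0.02)
  expect_lte(res$c_dil, res$c_tot)

  # no telomeres -> c_dil equals c_tot
  flatsig <- matrix(0, dims, dims); flatsig[nuc] <- 50
  r0 <- dilute_phase_measurement(nuc, flatsig)
  expect_equal(r0$c_dil, r0$c_tot)
})
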