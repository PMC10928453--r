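# Preprocessing: band images, co-registration, interferent correction,
# quality filtering, fingerprint extraction.

test_that("amide-I image slices at the nearest axis point", {
  axis <- seq(990, 3800, by = 6)
  data <- array(rnorm(4 * 469), dim = c(2, 2, 469))
  cube <- hyperspectral_cube(axis, data, "A")
  k1650 <- which(axis == 1650)
  expect_equal(amide1_image(cube, 1650), data[, , k1650])
  expect_equal(amide1_image(cube, 1651), data[, , k1650]) # nearest rule
  expect_error(amide1_image(cube, 500), "outside")
  const <- hyperspectral_cube(c(1, 2), array(3.5, c(2, 2, 2)), "C")
  expect_true(all(amide1_image(const, 1) == 3.5))
})

test_that("co-registration recovers planted integer shifts", {
  co <- small_sim(seed = 21, n_patients = 2, core_size = 14, mask_shift = c(2, 3))
  img <- amide1_image(co$cubes[[1]])
  reg <- coregister(co$masks[[1]], img, max_shift = 4)
  expect_equal(reg$offset, c(-2, -3))
  # content clipped at the border during the planted shift cannot return;
  # the unclipped region must match the true mask exactly
  expect_equal(reg$mask$grid[1:12, 1:11], co$truth$masks[[1]]$grid[1:12, 1:11])

  # exhaustive-search oracle over all offsets
  binary <- (img >= spectrosurv:::otsu_threshold(img)) * 1
  best <- -Inf; best_off <- NULL
  for (dr in -4:4) for (dc in -4:4) {
    s <- spectrosurv:::shift_matrix(co$masks[[1]]$grid, dr, dc)
    r <- suppressWarnings(stats::cor(as.vector(s), as.vector(binary)))
    if (is.finite(r) && r > best + 1e-12) { best <- r; best_off <- c(dr, dc) }
  }
  expect_equal(reg$offset, best_off)

  # already aligned -> identity; zero radius forces identity
  aligned <- small_sim(seed = 21, n_patients = 2, core_size = 14)
  expect_equal(coregister(aligned$masks[[1]], amide1_image(aligned$cubes[[1]]),
                          max_shift = 4)$offset, c(0, 0))
  expect_equal(coregister(co$masks[[1]], img, max_shift = 0)$offset, c(0, 0))
  expect_error(coregister(annotation_mask(matrix(0, 14, 14), "z"), img),
               "degenerate")
})

test_that("internal Otsu thresholding segments like the EBImage reference", {
  skip_if_not_installed("EBImage")
  set.seed(1)
  for (i in 1:3) {
    img <- matrix(c(rnorm(600, 0.3, 0.05), rnorm(424, 0.8, 0.05)), 32, 32)
    mine <- spectrosurv:::otsu_threshold(img)
    ref <- EBImage::otsu(EBImage::Image(img), range = range(img), levels = 256)
    # both must land in the inter-class valley: identical segmentations
    expect_gte(mean((img > mine) == (img > ref)), 0.995)
  }
})

test_that("interferent correction solves the linear model exactly on exact data", {
  axis <- seq(990, 3800, by = 6)
  refs <- make_reference_spectra(axis)
  # pure scaled tissue: a = 2, everything else 0
  m <- rbind(2 * refs$tissue_base)
  out <- correct_spectra(m, refs)
  expect_equal(out$coefficients$a[1], 2, tolerance = 1e-10)
  expect_equal(drop(out$corrected), refs$tissue_base, tolerance = 1e-8)

  # tissue + paraffin: b recovered, corrected equals tissue
  m2 <- rbind(refs$tissue_base + 0.7 * refs$paraffin)
  out2 <- correct_spectra(m2, refs)
  expect_equal(out2$coefficients$b[1], 0.7, tolerance = 1e-10)
  expect_equal(drop(out2$corrected), refs$tissue_base, tolerance = 1e-8)

  # independent least-squares oracle via normal equations
  D <- cbind(refs$tissue_base, refs$paraffin, refs$atmospheric,
             1, (axis - axis[1]) / diff(range(axis)))
  s <- refs$tissue_base + 0.3 * refs$paraffin + 0.1 * refs$atmospheric + 0.02
  beta_oracle <- solve(crossprod(D), crossprod(D, s))
  out3 <- correct_spectra(rbind(s), refs)
  expect_equal(unlist(out3$coefficients[1, ], use.names = FALSE),
               drop(beta_oracle), tolerance = 1e-8)
})

test_that("planted simulation coefficients are recovered within 3 SE", {
  # effect_size 0: the interferent model is then exactly the generative model
  co <- small_sim(seed = 31, n_patients = 6, core_size = 10, effect_size = 0)
  for (i in seq_len(6)) {
    pp <- preprocess_cube(co$cubes[[i]], co$masks[[i]], co$refs)
    b <- pp$coefficients$b
    a <- pp$coefficients$a
    se_b <- stats::sd(b) / sqrt(length(b))
    expect_lt(abs(mean(b) - co$truth$paraffin_coeff[i]), 3 * se_b + 1e-6)
    # tumour pixels carry the density contrast on the thickness coefficient
    expected_a <- co$truth$thickness[i] * (1 + co$truth$tumour_contrast)
    se_a <- stats::sd(a) / sqrt(length(a))
    expect_lt(abs(mean(a) - expected_a), 3 * se_a + 1e-6)
  }
})

test_that("correction is idempotent and order-equivariant", {
  co <- small_sim(seed = 5, n_patients = 2, core_size = 8)
  flat <- matrix(co$cubes[[1]]$data, nrow = 64)
  out1 <- correct_spectra(flat, co$refs)
  out2 <- correct_spectra(out1$corrected, co$refs)
  expect_equal(out2$corrected, out1$corrected, tolerance = 1e-8)
  expect_equal(out2$coefficients$a, rep(1, 64), tolerance = 1e-8)
  expect_lt(max(abs(out2$coefficients$b)), 1e-8)

  perm <- sample(64)
  out_perm <- correct_spectra(flat[perm, ], co$refs)
  expect_equal(out_perm$corrected, out1$corrected[perm, ], tolerance = 1e-10)
})

test_that("with zero noise corrected tumour spectra equal the planted signal", {
  # no class effect: the generative model lies in the span of the design,
  # so correction must return tissue_base exactly (solver tolerance)
  co <- simulate_cohort(sim_config(n_patients = 4, core_size = 6, noise_sd = 0,
                                   effect_size = 0, class_prob = 0, seed = 13))
  flat <- matrix(co$cubes[[1]]$data, nrow = 36)
  tum <- as.vector(co$truth$masks[[1]]$grid) == 1
  out <- correct_spectra(flat[tum, , drop = FALSE], co$refs)
  for (r in seq_len(sum(tum))) {
    expect_equal(out$corrected[r, ], co$refs$tissue_base, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }

  # with a planted class effect the corrected excess is localised at the
  # perturbed peak (the analyte signal is not regressed away entirely)
  co2 <- simulate_cohort(sim_config(n_patients = 2, core_size = 6, noise_sd = 0,
                                    effect_size = 2, class_prob = 1, seed = 13))
  flat2 <- matrix(co2$cubes[[1]]$data, nrow = 36)
  tum2 <- as.vector(co2$truth$masks[[1]]$grid) == 1
  out2 <- correct_spectra(flat2[tum2, , drop = FALSE], co2$refs)
  excess <- out2$corrected[1, ] - co2$refs$tissue_base
  axis <- co2$refs$axis
  fp <- axis >= 1000 & axis <= 1800
  expect_lt(abs(axis[fp][which.max(abs(excess[fp]))] - 1240), 30)
})

test_that("quality filter applies the absorbance window and SNR rule", {
  axis <- seq(990, 3800, by = 6)
  refs <- make_reference_spectra(axis)
  amides <- c(0.05, 0.5, 1.0, 2.5, 1.5)
  m <- t(vapply(amides, function(a) a * refs$tissue_base, numeric(469)))
  flags <- quality_filter(m, axis)
  expect_equal(sum(flags), 3) # 0.5, 1.0, 1.5 inside [0.1, 2.0]
  expect_false(flags[1]); expect_false(flags[4])

  # noiseless unit spectrum retained; drowning noise rejected via SNR
  noisy <- refs$tissue_base + rnorm(469, 0, 0.5)
  flags2 <- quality_filter(rbind(refs$tissue_base, noisy), axis,
                           preprocess_config(snr_min = 10))
  expect_true(flags2[1])
  expect_false(flags2[2])
})

test_that("fingerprint extraction keeps the closed interval and mask pixels", {
  co <- small_sim(seed = 8, n_patients = 2, core_size = 6)
  ds <- extract_fingerprint(co$cubes[[1]], co$truth$masks[[1]])
  axis <- co$cubes[[1]]$axis
  expected_axis <- axis[axis >= 1000 & axis <= 1800]
  expect_equal(ds$axis, expected_axis)
  expect_equal(range(ds$axis), c(1002, 1800)) # endpoints: 1800 on-grid, kept
  expect_equal(nrow(ds$matrix), sum(co$truth$masks[[1]]$grid))
  expect_equal(nrow(ds$meta), nrow(ds$matrix))
  # retention flags drop rows one-for-one
  keep <- rep(c(TRUE, FALSE), length.out = sum(co$truth$masks[[1]]$grid))
  ds2 <- extract_fingerprint(co$cubes[[1]], co$truth$masks[[1]], retained = keep)
  expect_equal(nrow(ds2$matrix), sum(keep))
  expect_warning(
    extract_fingerprint(co$cubes[[1]], co$truth$masks[[1]],
                        retained = rep(FALSE, sum(co$truth$masks[[1]]$grid))),
    "zero retained")
})
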