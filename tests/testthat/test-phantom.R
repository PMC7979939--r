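test_that("generate_truth paints regions, blurs convexly, conserves mass", {
  # blur-free: exact two-level map
  spec <- phantom_spec(shape = c(16, 16),
                       regions = list(list(shape = "rect", rmin = 1, rmax = 16,
                                           cmin = 1, cmax = 16,
                                           class = "adipose"),
                                      list(shape = "rect", rmin = 6, rmax = 10,
                                           cmin = 6, cmax = 10,
                                           class = "tumour")),
                       blur_fwhm = 0, snr_db = Inf)
  tr <- generate_truth(spec)
  expect_setequal(unique(as.vector(tr$index$values)), c(1.90, 2.60))
  expect_equal(sum(tr$truth_mask), 25)
  expect_true(all(tr$support))

  # blurred edges lie strictly between the class values
  spec2 <- phantom_spec(shape = c(16, 16), regions = spec$regions,
                        blur_fwhm = 2, snr_db = Inf)
  tr2 <- generate_truth(spec2)
  edge <- tr2$index$values[5, 8]   # just outside the tumour square
  expect_gt(edge, 1.90); expect_lt(edge, 2.60)
  # Gaussian kernel is normalized: total mass conserved under reflection
  expect_equal(sum(tr2$index$values), sum(tr$index$values), tolerance = 1e-9)

  # unknown class signals
  bad <- spec; bad$regions[[2]]$class <- "bone"
  expect_error(generate_truth(bad), class = "thz_domain_error")
  # contrast ordering enforced
  expect_error(phantom_spec(class_indices = list(adipose = c(2.9, 0.1),
                                                 fibrous = c(2.2, 0.1),
                                                 tumour_margin = c(2.3, 0.1),
                                                 tumour = c(2.6, 0.2))),
               class = "thz_domain_error")
})

test_that("simulate_cube is deterministic and honours the requested SNR", {
  tr <- generate_truth(phantom_spec(blur_fwhm = 0))
  # noise off: seed is irrelevant
  a <- simulate_cube(tr, snr_db = Inf, seed = 1)
  b <- simulate_cube(tr, snr_db = Inf, seed = 99)
  expect_identical(a$cube$field, b$cube$field)
  # same seed: bit-identical
  c1 <- simulate_cube(tr, snr_db = 30, seed = 7)
  c2 <- simulate_cube(tr, snr_db = 30, seed = 7)
  expect_identical(c1$cube$field, c2$cube$field)
  # SNR calibration at 550 GHz over the 1024 pixels: per-pixel noise
  # realisations against the clean cube; the measured SNR (RMS over the
  # frequency bins, so the estimator itself carries ~1 dB noise) must
  # average to the request within 1 dB, and the noise scaled by the
  # injected per-pixel sigma must pool to unit RMS
  noise <- c1$cube$field - a$cube$field
  bin <- which.min(abs(a$cube$frequencies - 550e9))
  sig <- Mod(a$cube$field[, , bin])
  rms <- sqrt(apply(Mod(noise)^2, c(1, 2), mean))   # per pixel over 37 bins
  snr_meas <- 20 * log10(sig / rms)
  expect_lt(abs(mean(snr_meas) - 30), 1)
  sigma <- sig / 10^(30 / 20)
  z <- sweep(Mod(noise)^2, c(1, 2), sigma^2, "/")
  expect_equal(sqrt(mean(z)), 1, tolerance = 0.02)
})

test_that("noise-free on-grid phantom round-trips through the inversion", {
  ph <- clean_phantom()
  m <- extract_map(ph$cube, ph$reference, default_sapphire(),
                   support = ph$truth$support)
  expect_equal(m$values[ph$truth$support],
               ph$truth$index$values[ph$truth$support])
  expect_equal(m$kappa[ph$truth$support], ph$truth$kappa[ph$truth$support])
})

test_that("30 dB noise keeps the n error small on almost all pixels", {
  spec <- phantom_spec(shape = c(16, 16), blur_fwhm = 0, snr_db = 30, seed = 4)
  tr <- generate_truth(spec)
  sim <- simulate_cube(tr, snr_db = 30, seed = 4)
  m <- extract_map(sim$cube, sim$reference, default_sapphire(),
                   support = tr$support)
  err <- abs(m$values - tr$index$values)[tr$support]
  expect_gte(mean(err <= 0.05), 0.95)
})

test_that("make_pathology: identity, exact 90-degree lattice rotation, loop closure", {
  mask <- matrix(FALSE, 20, 20); mask[6:12, 8:15] <- TRUE
  expect_identical(make_pathology(mask, 1, 0), mask)
  # 90 degrees on a square centred mask: exact lattice rotation
  sq <- matrix(FALSE, 21, 21); sq[8:14, 6:16] <- TRUE
  rot <- make_pathology(sq, 1, 90)
  expect_equal(sum(rot), sum(sq))
  expect_equal(rot, make_pathology(rot, 1, -90) |> make_pathology(1, 90))
  # closes the loop with the registration module (sample outlines)
  ph <- generate_phantom(phantom_spec(shape = c(32, 32), blur_fwhm = 0,
                                      snr_db = Inf, pathology_scale = 3,
                                      pathology_angle = -8))
  reg <- register_images(ph$truth$support, ph$pathology_support)
  expect_equal(reg$result$scale, 1 / 3)
  expect_lte(abs(reg$result$angle + 8), 1)
})

test_that("phantom output is deterministic given the spec", {
  s <- phantom_spec(shape = c(16, 16), seed = 11)
  p1 <- generate_phantom(s)
  p2 <- generate_phantom(s)
  expect_identical(p1$cube$field, p2$cube$field)
  expect_identical(p1$pathology_mask, p2$pathology_mask)
  expect_identical(p1$truth$index$values, p2$truth$index$values)
})

test_that("pathology mask de-rotates back onto the truth footprint", {
  ph <- generate_phantom(phantom_spec(shape = c(24, 24), blur_fwhm = 0,
                                      snr_db = Inf, pathology_scale = 2,
                                      pathology_angle = 15))
  # undo the shared rigid transform (rotation about the footprint centroid)
  up_sup <- kronecker(ph$truth$support * 1, matrix(1, 2, 2)) > 0
  back <- rotate_mask(ph$pathology_mask, -15,
                      center = thzmargin:::mask_centroid(up_sup))
  down <- resize_bicubic(back * 1, c(24, 24)) >= 0.5
  # any mismatch lies within a 1-pixel band around the truth boundary:
  # pixels whose rank-1 neighbourhood is not uniformly inside or outside
  se1 <- make_structuring_element(1)
  truth <- ph$truth$truth_mask
  band <- dilate_mask(truth, se1) & dilate_mask(!truth, se1)
  mism <- down != truth
  expect_true(all(!mism | band))
})
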