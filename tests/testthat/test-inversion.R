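test_that("transfer_from_fields: identity, scaling, and round trip", {
  f <- seq(0.3e12, 1.5e12, by = 0.1e12)
  er <- spectral_trace(f, complex(real = rep(1, length(f)),
                                  imaginary = rep(0.2, length(f))))
  expect_equal(transfer_from_fields(er, er)$values,
               rep(1 + 0i, length(f)))
  half <- spectral_trace(f, 0.5 * er$field)
  expect_equal(transfer_from_fields(half, er)$values,
               rep(0.5 + 0i, length(f)))
  # forward-model round trip recovers the candidate transfer exactly
  sub <- default_sapphire()
  ts <- synth_transfer(2.3, 0.2, sub)
  expect_equal(ts$values,
               candidate_transfer(complex_index(2.3, 0.2), sub,
                                  2 * pi * ts$frequencies),
               tolerance = 1e-14)
  # SNR floor: all-zero reference band is rejected
  er0 <- spectral_trace(f, complex(real = c(1, rep(0, length(f) - 1))))
  expect_equal(length(transfer_from_fields(er0, er0,
                                           floor_rel = 0.5)$values), 1)
})

test_that("discrepancy and objective follow the log-magnitude definitions", {
  expect_equal(discrepancy(3 + 4i, 5i), 0)            # equal magnitudes
  expect_equal(discrepancy(exp(1) + 0i, 1 + 0i), 1)   # ratio e
  expect_equal(objective_chi(exp(2) * 1i, 1 + 0i), 4) # ratio e^2 squared
  set.seed(3)
  for (i in 1:10) {
    a <- complex(real = rnorm(1), imaginary = rnorm(1))
    b <- complex(real = rnorm(1), imaginary = rnorm(1))
    expect_equal(discrepancy(a, b), -discrepancy(b, a))
    expect_gte(objective_chi(a, b), 0)
    # invariant to phases of both arguments
    expect_equal(objective_chi(a * exp(1i * 0.7), b * exp(-1i * 1.2)),
                 objective_chi(a, b))
  }
  expect_error(discrepancy(0 + 0i, 1 + 0i), class = "thz_domain_error")
})

test_that("grid search recovers on-grid truth exactly in complex mode", {
  sub <- default_sapphire()
  grid <- search_grid()
  expect_length(grid$n_values, 151)
  expect_length(grid$kappa_values, 1001)
  cases <- list(c(2.30, 0.200), c(1.50, 0.000), c(3.00, 1.000), c(2.07, 0.013))
  for (cs in cases) {
    ts <- synth_transfer(cs[1], cs[2], sub)
    fit <- grid_search_pixel(ts, grid, sub, 550e9, mode = "complex")
    expect_equal(fit$n, cs[1])
    expect_equal(fit$kappa, cs[2])
  }
})

test_that("magnitude mode attains the best magnitude gap (degeneracy tolerated)", {
  sub <- default_sapphire()
  grid <- search_grid()
  ts <- synth_transfer(2.30, 0.200, sub)
  fit <- grid_search_pixel(ts, grid, sub, 550e9, mode = "magnitude")
  bin <- which.min(abs(ts$frequencies - 550e9))
  omega <- 2 * pi * ts$frequencies[bin]
  tc_fit <- candidate_transfer(complex_index(fit$n, fit$kappa), sub, omega)
  tc_true <- candidate_transfer(complex_index(2.30, 0.200), sub, omega)
  gap_fit <- abs(log(Mod(ts$values[bin]) / Mod(tc_fit)))
  gap_true <- abs(log(Mod(ts$values[bin]) / Mod(tc_true)))
  expect_lte(gap_fit, gap_true + 1e-12)
})

test_that("grid search equals a brute-force scan over all candidates", {
  sub <- default_sapphire()
  grid <- search_grid()
  set.seed(21)
  d <- sub$thickness
  ns <- complex_index(sub$n, sub$kappa)
  for (i in 1:3) {
    n0 <- sample(grid$n_values, 1); k0 <- sample(grid$kappa_values, 1)
    ts <- synth_transfer(n0, k0, sub)
    bin <- which.min(abs(ts$frequencies - 550e9))
    omega <- 2 * pi * ts$frequencies[bin]
    tsv <- ts$values[bin]
    for (mode in c("complex", "magnitude")) {
      # independent scan: outer loop over n, direct arithmetic over kappa
      best <- c(Inf, NA, NA)
      for (n in grid$n_values) {
        tc <- oracle_transfer(complex(real = n,
                                      imaginary = -grid$kappa_values),
                              ns, d, omega)
        chi <- log(Mod(tsv) / Mod(tc))^2
        if (mode == "complex") {
          dphi <- Arg(tsv) - Arg(tc)
          dphi <- ((dphi + pi) %% (2 * pi)) - pi
          chi <- chi + dphi^2
        }
        j <- which.min(chi)
        if (chi[j] < best[1]) best <- c(chi[j], n, grid$kappa_values[j])
      }
      fit <- grid_search_pixel(ts, grid, sub, 550e9, mode = mode)
      expect_equal(fit$chi, best[1], tolerance = 1e-9)
      expect_equal(fit$n, best[2])
      expect_equal(fit$kappa, best[3])
    }
  }
})

test_that("extract_map: constant cube, blockwise recovery, pixel independence", {
  sub <- default_sapphire()
  f <- seq(0.2e12, 2e12, by = 0.1e12)
  er <- reference_pulse(f)
  # 8x8 cube, all pixels (2.6, 0.3)
  tc <- candidate_transfer(complex_index(2.6, 0.3), sub, 2 * pi * f)
  field <- array(rep(tc * er$field, each = 64), dim = c(8, 8, length(f)))
  cube <- field_cube(field, f)
  m <- extract_map(cube, er, sub)
  expect_true(all(m$values == 2.6))
  expect_true(all(m$kappa == 0.3))

  # two-block phantom, noise-free: exact blockwise recovery
  nmat <- matrix(2.0, 6, 6); nmat[, 4:6] <- 2.6
  field2 <- array(0i, dim = c(6, 6, length(f)))
  for (j in seq_along(f)) {
    field2[, , j] <- matrix(candidate_transfer(complex_index(as.vector(nmat), 0.1),
                                               sub, 2 * pi * f[j]), 6, 6) *
      er$field[j]
  }
  cube2 <- field_cube(field2, f)
  m2 <- extract_map(cube2, er, sub)
  expect_equal(m2$values, nmat)

  # permuting pixels permutes outputs identically
  perm <- sample(36)
  field3 <- array(0i, dim = c(6, 6, length(f)))
  for (j in seq_along(f)) {
    pix <- matrix(field2[, , j], 6, 6)
    field3[, , j] <- matrix(as.vector(pix)[perm], 6, 6)
  }
  m3 <- extract_map(field_cube(field3, f), er, sub)
  expect_equal(as.vector(m3$values), as.vector(m2$values)[perm])
})

test_that("extract_map masks bad pixels and logs the count", {
  sub <- default_sapphire()
  f <- seq(0.2e12, 2e12, by = 0.1e12)
  er <- reference_pulse(f)
  tc <- candidate_transfer(complex_index(2.2, 0.15), sub, 2 * pi * f)
  field <- array(rep(tc * er$field, each = 16), dim = c(4, 4, length(f)))
  field[2, 3, ] <- NA_complex_
  field[4, 1, ] <- NA_complex_
  cube <- field_cube(field, f)
  expect_message(m <- extract_map(cube, er, sub), "2 support pixel")
  expect_true(is.na(m$values[2, 3]) && is.na(m$values[4, 1]))
  expect_false(m$support[2, 3] || m$support[4, 1])
  expect_equal(sum(m$support), 14)
})

test_that("characterize_substrate recovers sapphire and is idempotent", {
  nominal <- substrate_spec(2e-3, n = 3.0, kappa = 0)
  truth <- substrate_spec(2e-3, n = 3.07, kappa = 0.010)
  f <- seq(0.3e12, 1.2e12, by = 0.1e12)
  er <- reference_pulse(f)
  bare <- spectral_trace(f, bare_transfer(complex_index(3.07, 0.010),
                                          2e-3, 2 * pi * f) * er$field)
  fit <- characterize_substrate(bare, er, nominal, frequencies = c(550e9))
  expect_equal(fit$n, 3.07)
  expect_equal(fit$kappa, 0.010)
  # idempotence: re-characterizing with the fitted spec changes nothing
  fit2 <- characterize_substrate(bare, er, fit, frequencies = c(550e9))
  expect_equal(fit2$n, fit$n)
  expect_equal(fit2$kappa, fit$kappa)
  # grid-floor boundary: an air-like "substrate" pins to the grid corner
  grid_lo <- search_grid(c(1.5, 2), 0.01, c(0, 0.05), 0.001)
  bare_air <- spectral_trace(f, bare_transfer(complex_index(1.5, 0),
                                              2e-3, 2 * pi * f) * er$field)
  fit_lo <- characterize_substrate(bare_air, er, nominal, grid = grid_lo,
                                   frequencies = c(550e9))
  expect_equal(fit_lo$n, 1.5)
  expect_equal(fit_lo$kappa, 0)
})
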