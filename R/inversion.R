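# Per-pixel extraction of the complex refractive index from reflection-mode
# terahertz spectra by exhaustive grid search on a log-magnitude objective,
# and assembly of the refractive index map at the operating frequency.

#' Spectral trace: complex field versus frequency at one pixel
#'
#' @param frequencies frequency axis in Hz, strictly increasing.
#' @param field complex field values, same length.
#' @return an object of class `spectral_trace`.
#' @export
spectral_trace <- function(frequencies, field) {
  stopifnot(length(frequencies) == length(field))
  if (is.unsorted(frequencies, strictly = TRUE))
    stop_thz("frequency axis must be strictly increasing", "thz_domain_error")
  structure(list(frequencies = as.numeric(frequencies),
                 field = as.complex(field)),
            class = "spectral_trace")
}

#' Hyperspectral field cube
#'
#' @param field complex array of dimension (height, width, n_freq).
#' @param frequencies shared frequency axis in Hz.
#' @param pixel_pitch spatial sampling in metres per pixel.
#' @return an object of class `field_cube`.
#' @export
field_cube <- function(field, frequencies, pixel_pitch = 2.5e-4) {
  d <- dim(field)
  stopifnot(length(d) == 3, d[3] == length(frequencies), d[1] * d[2] > 0)
  if (is.unsorted(frequencies, strictly = TRUE))
    stop_thz("frequency axis must be strictly increasing", "thz_domain_error")
  structure(list(field = field, frequencies = as.numeric(frequencies),
                 height = d[1], width = d[2], pixel_pitch = pixel_pitch),
            class = "field_cube")
}

#' Candidate search grid for (n, kappa)
#'
#' Defaults reproduce the published candidate set: n in [1.5, 3] with step
#' 0.01 (151 values) and kappa in [0, 1] with step 0.001 (1001 values),
#' both endpoints included.
#'
#' @param n_range closed interval for n.
#' @param n_step grid step for n (> 0).
#' @param kappa_range closed interval for kappa.
#' @param kappa_step grid step for kappa (> 0).
#' @return an object of class `search_grid` with `n_values`, `kappa_values`.
#' @export
search_grid <- function(n_range = c(1.5, 3), n_step = 0.01,
                        kappa_range = c(0, 1), kappa_step = 0.001) {
  stopifnot(n_step > 0, kappa_step > 0,
            n_range[2] >= n_range[1], kappa_range[2] >= kappa_range[1])
  n_values <- seq(n_range[1], n_range[2], by = n_step)
  kappa_values <- seq(kappa_range[1], kappa_range[2], by = kappa_step)
  structure(list(n_values = n_values, kappa_values = kappa_values,
                 n_range = n_range, n_step = n_step,
                 kappa_range = kappa_range, kappa_step = kappa_step),
            class = "search_grid")
}

#' Experimental transfer function from sample and reference traces
#'
#' T(omega) = E_s(omega) / E_r(omega), restricted to frequencies where the
#' reference magnitude exceeds `floor_rel` times its maximum (the SNR floor).
#'
#' @param sample,reference `spectral_trace` objects on one frequency axis.
#' @param floor_rel relative reference-magnitude floor in (0, 1).
#' @return a list of class `transfer_spectrum` with `frequencies`, `values`.
#' @export
transfer_from_fields <- function(sample, reference, floor_rel = 1e-6) {
  if (!isTRUE(all.equal(sample$frequencies, reference$frequencies)))
    stop_thz("sample and reference must share one frequency axis",
             "thz_domain_error")
  keep <- Mod(reference$field) > floor_rel * max(Mod(reference$field))
  if (!any(keep))
    stop_thz("no frequency passes the reference SNR floor", "thz_empty_band")
  structure(list(frequencies = sample$frequencies[keep],
                 values = sample$field[keep] / reference$field[keep]),
            class = "transfer_spectrum")
}

#' Log-magnitude discrepancy between measured and candidate transfer values
#'
#' delta M = ln(|T_s| / |T_c|): antisymmetric in its arguments and more
#' penalizing than a plain magnitude difference.
#'
#' @param ts,tc complex transfer values (vectorized).
#' @return real discrepancy value(s).
#' @export
discrepancy <- function(ts, tc) {
  m1 <- Mod(ts); m2 <- Mod(tc)
  if (any(m1 == 0) || any(m2 == 0))
    stop_thz("discrepancy undefined at zero magnitude", "thz_domain_error")
  log(m1 / m2)
}

#' Objective function chi = (delta M)^2
#'
#' Non-negative; zero exactly when magnitudes match. Invariant to the phases
#' of both arguments.
#'
#' @inheritParams discrepancy
#' @return real objective value(s) >= 0.
#' @export
objective_chi <- function(ts, tc) {
  discrepancy(ts, tc)^2
}

# Precompute candidate transfer values over the whole (n, kappa) grid at one
# angular frequency. Linear storage order is kappa-major (n fastest), so the
# first index attaining a minimum realizes the smallest kappa, then the
# smallest n — the documented deterministic tie-break.
candidate_table <- function(grid, substrate, omega, mirror_sign = -1) {
  nk <- expand.grid(n = grid$n_values, kappa = grid$kappa_values,
                    KEEP.OUT.ATTRS = FALSE)
  nhat <- complex(real = nk$n, imaginary = -nk$kappa)
  tc <- candidate_transfer(nhat, substrate, omega, mirror_sign)
  list(n = nk$n, kappa = nk$kappa,
       log_abs = log(Mod(tc)), arg = Arg(tc))
}

# Argmin of the objective for one measured transfer value against a
# precomputed candidate table.
pick_candidate <- function(ts_value, tab, mode) {
  chi <- (log(Mod(ts_value)) - tab$log_abs)^2
  if (mode == "complex") {
    chi <- chi + wrap_angle(Arg(ts_value) - tab$arg)^2
  }
  if (all(!is.finite(chi)))
    stop_thz("objective non-finite for every candidate", "thz_inversion_error")
  chi[!is.finite(chi)] <- Inf
  i <- which.min(chi)
  list(n = tab$n[i], kappa = tab$kappa[i], chi = chi[i])
}

#' Grid-search inversion of one pixel at the operating frequency
#'
#' Scans every (n, kappa) candidate and returns the minimizer of the
#' objective at the frequency bin nearest `frequency`. `mode = "magnitude"`
#' is the published objective (log-magnitude only; its minimizer set is a
#' level curve, resolved by the smallest-kappa-then-smallest-n tie-break).
#' `mode = "complex"` augments chi with the wrapped squared phase residual,
#' making the single-frequency problem well-posed; it is the default.
#'
#' @param ts a `transfer_spectrum` for the pixel.
#' @param grid a `search_grid`.
#' @param substrate a `substrate_spec`.
#' @param frequency operating frequency in Hz (default 550 GHz).
#' @param mode `"complex"` or `"magnitude"`.
#' @param mirror_sign reference convention, see [candidate_transfer()].
#' @return list with `n`, `kappa`, `chi`, and `frequency` (the bin used).
#' @export
grid_search_pixel <- function(ts, grid, substrate, frequency = 550e9,
                              mode = c("complex", "magnitude"),
                              mirror_sign = -1) {
  mode <- match.arg(mode)
  if (frequency < min(ts$frequencies) || frequency > max(ts$frequencies))
    stop_thz("operating frequency outside the transfer band",
             "thz_domain_error")
  bin <- which.min(abs(ts$frequencies - frequency))
  omega <- 2 * pi * ts$frequencies[bin]
  tab <- candidate_table(grid, substrate, omega, mirror_sign)
  out <- pick_candidate(ts$values[bin], tab, mode)
  out$frequency <- ts$frequencies[bin]
  out
}

#' Refractive index map container
#'
#' @param values matrix of real refractive indices (NA where masked).
#' @param frequency the operating frequency in Hz.
#' @param support logical matrix of valid pixels.
#' @param kappa optional matrix of extinction coefficients.
#' @return an object of class `index_map`.
#' @export
index_map <- function(values, frequency, support = !is.na(values),
                      kappa = NULL) {
  stopifnot(is.matrix(values), identical(dim(values), dim(support)))
  structure(list(values = values, frequency = frequency,
                 support = support, kappa = kappa),
            class = "index_map")
}

#' Extract the refractive index map from a field cube
#'
#' Runs the per-pixel grid search at the operating frequency. Pixels outside
#' `support`, or whose trace fails the reference SNR floor or yields a
#' non-finite transfer value, are masked (NA) and counted in a message;
#' they are never interpolated.
#'
#' @param cube a `field_cube`.
#' @param reference the metal-plate reference `spectral_trace`.
#' @param substrate a `substrate_spec`.
#' @param frequency operating frequency in Hz (default 550 GHz).
#' @param grid a `search_grid` (default: the published candidate set).
#' @param mode `"complex"` (default) or `"magnitude"`.
#' @param support optional logical matrix restricting the pixels inverted.
#' @param floor_rel reference SNR floor, see [transfer_from_fields()].
#' @param mirror_sign reference convention, see [candidate_transfer()].
#' @return an `index_map` (with the fitted kappa map attached).
#' @export
extract_map <- function(cube, reference, substrate, frequency = 550e9,
                        grid = search_grid(), mode = c("complex", "magnitude"),
                        support = NULL, floor_rel = 1e-6, mirror_sign = -1) {
  mode <- match.arg(mode)
  if (!isTRUE(all.equal(cube$frequencies, reference$frequencies)))
    stop_thz("cube and reference must share one frequency axis",
             "thz_domain_error")
  keep <- Mod(reference$field) > floor_rel * max(Mod(reference$field))
  if (!any(keep))
    stop_thz("no frequency passes the reference SNR floor", "thz_empty_band")
  freqs <- cube$frequencies[keep]
  if (frequency < min(freqs) || frequency > max(freqs))
    stop_thz("operating frequency outside the usable band", "thz_domain_error")
  bin_all <- which(keep)[which.min(abs(freqs - frequency))]
  f_op <- cube$frequencies[bin_all]
  omega <- 2 * pi * f_op
  tab <- candidate_table(grid, substrate, omega, mirror_sign)

  if (is.null(support)) support <- matrix(TRUE, cube$height, cube$width)
  stopifnot(identical(dim(support), c(cube$height, cube$width)))

  ts_op <- matrix(cube$field[, , bin_all], cube$height, cube$width) /
    reference$field[bin_all]
  vals <- matrix(NA_real_, cube$height, cube$width)
  kmap <- matrix(NA_real_, cube$height, cube$width)
  ok <- support & is.finite(Re(ts_op)) & is.finite(Im(ts_op)) & Mod(ts_op) > 0
  for (i in which(ok)) {
    fit <- pick_candidate(ts_op[i], tab, mode)
    vals[i] <- fit$n
    kmap[i] <- fit$kappa
  }
  n_masked <- sum(support & !ok)
  if (n_masked > 0)
    message(sprintf("extract_map: %d support pixel(s) masked (SNR/validity)",
                    n_masked))
  index_map(vals, f_op, support = ok, kappa = kmap)
}

#' Characterize the substrate from a bare (no-sample) measurement
#'
#' Fits the substrate's complex index per frequency by the same grid-search
#' minimization used for tissue, with the tissue medium replaced by air.
#'
#' @param bare_trace `spectral_trace` of the bare substrate echo.
#' @param reference the metal-plate reference `spectral_trace`.
#' @param nominal a `substrate_spec` carrying the known thickness.
#' @param grid a `search_grid` spanning the expected substrate index;
#'   default n in [2.5, 3.5] step 0.01, kappa in [0, 0.1] step 0.001.
#' @param frequencies frequencies (Hz) at which to fit; default: the whole
#'   usable band of the transfer spectrum.
#' @param mode `"complex"` (default) or `"magnitude"`.
#' @param mirror_sign reference convention, see [candidate_transfer()].
#' @param floor_rel reference SNR floor.
#' @return a fitted `substrate_spec`.
#' @export
characterize_substrate <- function(bare_trace, reference, nominal,
                                   grid = search_grid(c(2.5, 3.5), 0.01,
                                                      c(0, 0.1), 0.001),
                                   frequencies = NULL,
                                   mode = c("complex", "magnitude"),
                                   mirror_sign = -1, floor_rel = 1e-6) {
  mode <- match.arg(mode)
  ts <- transfer_from_fields(bare_trace, reference, floor_rel)
  if (is.null(frequencies)) frequencies <- ts$frequencies
  nk <- expand.grid(n = grid$n_values, kappa = grid$kappa_values,
                    KEEP.OUT.ATTRS = FALSE)
  ns_hat <- complex(real = nk$n, imaginary = -nk$kappa)
  n_fit <- kappa_fit <- numeric(length(frequencies))
  for (j in seq_along(frequencies)) {
    bin <- which.min(abs(ts$frequencies - frequencies[j]))
    omega <- 2 * pi * ts$frequencies[bin]
    tc <- bare_transfer(ns_hat, nominal$thickness, omega, mirror_sign)
    tab <- list(n = nk$n, kappa = nk$kappa,
                log_abs = log(Mod(tc)), arg = Arg(tc))
    fit <- pick_candidate(ts$values[bin], tab, mode)
    n_fit[j] <- fit$n
    kappa_fit[j] <- fit$kappa
  }
  if (length(frequencies) == 1) {
    substrate_spec(nominal$thickness, n = n_fit, kappa = kappa_fit)
  } else {
    substrate_spec(nominal$thickness, n = n_fit, kappa = kappa_fit,
                   frequencies = frequencies)
  }
}
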