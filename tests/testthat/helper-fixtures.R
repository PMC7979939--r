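# Shared fixtures and independent oracles used across the suite.

# Synthesize a single-pixel trace pair from a known (n, kappa) through the
# forward model; returns the transfer spectrum seen by the inversion.
synth_transfer <- function(n, kappa, substrate = default_sapphire(),
                           frequencies = seq(0.2e12, 2e12, by = 0.05e12)) {
  er <- reference_pulse(frequencies)
  nhat <- complex(real = n, imaginary = -kappa)
  es <- spectral_trace(frequencies,
                       candidate_transfer(nhat, substrate,
                                          2 * pi * frequencies) * er$field)
  transfer_from_fields(es, er)
}

# Direct evaluation of the substrate-tissue echo transfer (independent of
# the package's candidate_transfer): one line of complex arithmetic.
oracle_transfer <- function(nt, ns, d, omega, sign = -1) {
  c0 <- 299792458
  (2 * 1 / (1 + ns)) * ((ns - nt) / (ns + nt)) * (2 * ns / (ns + 1)) *
    exp(-1i * omega * d * ns / c0)^2 / sign
}

# Brute-force Minkowski dilation oracle: place the element on every TRUE
# pixel, union, intersect support.
oracle_dilate <- function(mask, offsets, support) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c]) next
    for (i in seq_len(nrow(offsets))) {
      rr <- r + offsets[i, 1]; cc <- c + offsets[i, 2]
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) out[rr, cc] <- TRUE
    }
  }
  out & support
}

# Shoelace polygon-area oracle for AUC: polygon (0,0) -> curve points
# sorted by fpr -> (1,1) -> (1,0) -> close.
oracle_auc_shoelace <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  x <- c(0, fpr[o], 1, 1, 0)
  y <- c(0, tpr[o], 1, 0, 0)
  abs(sum(x[-length(x)] * y[-1] - x[-1] * y[-length(y)])) / 2
}

# Small noise-free, blur-free phantom used by several modules.
clean_phantom <- function(shape = c(24, 24)) {
  generate_phantom(phantom_spec(shape = shape, blur_fwhm = 0, snr_db = Inf,
                                pathology_angle = 0, pathology_scale = 2))
}

random_mask <- function(h, w, p = 0.3) {
  matrix(stats::runif(h * w) < p, h, w)
}
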