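# Synthetic phantom standing in for the undeposited clinical data: a
# ground-truth tissue map (adipose / fibrous / tumour), a simulated
# terahertz field cube produced by the forward optical model, and a
# distorted high-resolution "pathology" truth mask.

#' Phantom specification
#'
#' The defaults state the simulated world once: a 32x32 terahertz grid, an
#' adipose tissue ellipse containing a fibrous region and a tumour focus
#' whose index exceeds the benign classes at 550 GHz, diffraction-limited
#' blur of 2 pixels FWHM causing class overlap at region edges, 30 dB
#' additive complex noise, and a pathology mask rendered at 4x resolution
#' with a 12 degree unknown rotation.
#'
#' Class indices at 550 GHz default to adipose n = 1.90, fibrous n = 2.20,
#' tumour n = 2.60 (kappa 0.10 / 0.15 / 0.20): values inside the published
#' search range and consistent with the 2.1-2.6 range of tabulated best
#' thresholds, configurable, and not asserted as literature truth. They sit
#' exactly on the default grid so noise-free recovery can be exact.
#'
#' The default tumour carries a low-density margin ring (class
#' `tumour_margin`, n = 2.25, kappa = 0.160): malignant in the truth mask
#' but with a refractive index close to healthy fibrous tissue, emulating
#' the partial-volume dilution at sparsely populated tumour edges that
#' defeats bare thresholding and that dilation is meant to recover. Any
#' class whose name starts with "tumour" is malignant.
#'
#' @param shape (height, width) of the terahertz grid.
#' @param regions list of regions painted in order; each a list with
#'   `shape` ("ellipse" or "rect"), geometry (`center`+`radii`, or
#'   `rmin`/`rmax`/`cmin`/`cmax`), and `class` naming an entry of
#'   `class_indices`. NULL uses a default layout scaled to `shape`.
#' @param class_indices named list mapping class -> c(n, kappa) at 550 GHz;
#'   must satisfy tumour n > fibrous n > adipose n.
#' @param blur_fwhm Gaussian blur FWHM in pixels (diffraction surrogate).
#' @param snr_db per-pixel signal-to-noise ratio at 550 GHz in dB
#'   (Inf = noise-free).
#' @param seed integer RNG seed for the noise.
#' @param pathology_scale integer >= 1, pathology/terahertz resolution ratio.
#' @param pathology_angle rotation of the pathology mask in degrees.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 32), regions = NULL,
                         class_indices = list(adipose = c(1.90, 0.100),
                                              fibrous = c(2.20, 0.150),
                                              tumour_margin = c(2.25, 0.160),
                                              tumour = c(2.60, 0.200)),
                         blur_fwhm = 2, snr_db = 30, seed = 1,
                         pathology_scale = 4, pathology_angle = 12) {
  stopifnot(length(shape) == 2, all(shape >= 8),
            blur_fwhm >= 0, pathology_scale >= 1)
  ns <- vapply(class_indices, `[`, numeric(1), 1)
  if (!(ns[["tumour"]] > ns[["fibrous"]] && ns[["fibrous"]] > ns[["adipose"]]))
    stop_thz("class contrast must satisfy tumour n > fibrous n > adipose n",
             "thz_domain_error")
  malig <- startsWith(names(ns), "tumour")
  if (any(ns[malig] <= ns[["adipose"]]))
    stop_thz("every malignant class must exceed the adipose index",
             "thz_domain_error")
  if (is.null(regions)) {
    h <- shape[1]; w <- shape[2]
    # elongated slice footprint and anisotropic tumour: excised strips and
    # malignant foci are irregular, which also makes the sample outline an
    # identifiable registration feature (a circular footprint would leave
    # the rotation ill-determined)
    regions <- list(
      list(shape = "ellipse", center = c(h / 2 + 0.5, w / 2 + 0.5),
           radii = c(0.45 * h, 0.30 * w), class = "adipose"),
      list(shape = "ellipse", center = c(0.46 * h, 0.52 * w),
           radii = c(0.28 * h, 0.24 * w), class = "fibrous"),
      list(shape = "ellipse", center = c(0.42 * h, 0.52 * w),
           radii = c(0.24 * h, 0.13 * w), class = "tumour_margin"),
      list(shape = "ellipse", center = c(0.42 * h, 0.52 * w),
           radii = c(0.24 * h - 2, 0.13 * w - 2), class = "tumour")
    )
  }
  structure(list(shape = as.integer(shape), regions = regions,
                 class_indices = class_indices, blur_fwhm = blur_fwhm,
                 snr_db = snr_db, seed = as.integer(seed),
                 pathology_scale = as.integer(pathology_scale),
                 pathology_angle = pathology_angle),
            class = "phantom_spec")
}

# Logical raster of one region on an (h, w) grid, 1-based pixel centres.
rasterize_region <- function(region, shape) {
  h <- shape[1]; w <- shape[2]
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  if (region$shape == "ellipse") {
    ((rr - region$center[1]) / region$radii[1])^2 +
      ((cc - region$center[2]) / region$radii[2])^2 <= 1
  } else if (region$shape == "rect") {
    rr >= region$rmin & rr <= region$rmax & cc >= region$cmin & cc <= region$cmax
  } else {
    stop_thz(sprintf("unknown region shape '%s'", region$shape),
             "thz_domain_error")
  }
}

#' Generate the phantom's ground-truth tissue maps
#'
#' Paints the regions in order (later regions overwrite earlier ones) onto
#' an air background (n = 1, kappa = 0), then applies a Gaussian blur of
#' the stated FWHM to emulate the diffraction-limited smooth gradient
#' between areas. The malignant truth mask is the unblurred tumour
#' footprint; the support is the unblurred tissue footprint.
#'
#' @param spec a `phantom_spec`.
#' @return list of class `phantom_truth`: `index` (an `index_map` of the
#'   blurred n at 550 GHz with the tissue support), `kappa` (blurred kappa
#'   matrix), `truth_mask`, `support`.
#' @export
generate_truth <- function(spec) {
  h <- spec$shape[1]; w <- spec$shape[2]
  n_map <- matrix(1, h, w)
  k_map <- matrix(0, h, w)
  support <- matrix(FALSE, h, w)
  truth_mask <- matrix(FALSE, h, w)
  for (reg in spec$regions) {
    if (!reg$class %in% names(spec$class_indices))
      stop_thz(sprintf("region class '%s' has no index entry", reg$class),
               "thz_domain_error")
    px <- rasterize_region(reg, spec$shape)
    nk <- spec$class_indices[[reg$class]]
    n_map[px] <- nk[1]
    k_map[px] <- nk[2]
    support <- support | px
    truth_mask <- if (startsWith(reg$class, "tumour"))
      truth_mask | px else truth_mask & !px
  }
  n_map <- gaussian_blur(n_map, spec$blur_fwhm)
  k_map <- gaussian_blur(k_map, spec$blur_fwhm)
  structure(list(index = index_map(n_map, 550e9, support = support),
                 kappa = k_map, truth_mask = truth_mask, support = support),
            class = "phantom_truth")
}

#' Synthetic reference pulse spectrum
#'
#' Raised-cosine magnitude over the instrument band (zero at the band
#' edges, peak mid-band) with a linear phase. Its shape cancels in the
#' transfer-function ratio; it exists to exercise SNR floors realistically.
#'
#' @param frequencies frequency axis in Hz.
#' @param band length-2 band limits in Hz (default 0.2-2 THz).
#' @param delay linear-phase group delay in seconds.
#' @return a `spectral_trace`.
#' @export
reference_pulse <- function(frequencies, band = c(0.2e12, 2e12),
                            delay = 5e-12) {
  u <- (frequencies - band[1]) / (band[2] - band[1])
  mag <- ifelse(u >= 0 & u <= 1, 0.5 - 0.5 * cos(2 * pi * u), 0)
  spectral_trace(frequencies, mag * exp(-2i * pi * frequencies * delay))
}

#' Simulate the terahertz field cube from a phantom truth
#'
#' Per pixel, E_s(omega) = T_candidate(n^_pixel) * E_r(omega), using the
#' same forward model the inversion assumes. Additive i.i.d. complex
#' Gaussian noise is scaled per pixel so that the ratio of the 550 GHz
#' signal magnitude to the noise RMS equals `snr_db`; deterministic given
#' `seed`. Background (air) pixels carry the bare-substrate echo.
#'
#' @param truth a `phantom_truth`.
#' @param substrate a `substrate_spec` (default [default_sapphire()]).
#' @param frequencies frequency axis in Hz; default 0.2-2 THz step 50 GHz
#'   (550 GHz on-bin).
#' @param snr_db per-pixel SNR at 550 GHz in dB; Inf disables noise.
#' @param seed integer RNG seed.
#' @param mirror_sign reference convention, see [candidate_transfer()].
#' @return list with `cube` (a `field_cube`) and `reference`
#'   (a `spectral_trace`).
#' @export
simulate_cube <- function(truth, substrate = default_sapphire(),
                          frequencies = seq(0.2e12, 2e12, by = 0.05e12),
                          snr_db = 30, seed = 1, mirror_sign = -1) {
  band <- range(frequencies)
  if (band[1] < 0.2e12 - 1e6 || band[2] > 2e12 + 1e6)
    stop_thz("frequency axis outside the 0.2-2 THz instrument band",
             "thz_domain_error")
  er <- reference_pulse(frequencies, band = band)
  h <- nrow(truth$index$values); w <- ncol(truth$index$values)
  nhat <- complex(real = as.vector(truth$index$values),
                  imaginary = -as.vector(truth$kappa))
  nf <- length(frequencies)
  es <- array(0i, dim = c(h, w, nf))
  for (j in seq_len(nf)) {
    tc <- candidate_transfer(nhat, substrate, 2 * pi * frequencies[j],
                             mirror_sign)
    es[, , j] <- matrix(tc * er$field[j], h, w)
  }
  if (is.finite(snr_db)) {
    set.seed(seed)
    bin550 <- which.min(abs(frequencies - 550e9))
    sig <- Mod(matrix(es[, , bin550], h, w))
    sigma <- sig / 10^(snr_db / 20)          # per-pixel noise RMS
    for (j in seq_len(nf)) {
      noise <- complex(real = stats::rnorm(h * w, sd = 1 / sqrt(2)),
                       imaginary = stats::rnorm(h * w, sd = 1 / sqrt(2)))
      es[, , j] <- es[, , j] + matrix(noise, h, w) * sigma
    }
  }
  list(cube = field_cube(es, frequencies), reference = er)
}

#' Distorted high-resolution pathology mask
#'
#' Nearest-neighbour upscaling by an integer factor followed by rotation
#' about the mask centroid and re-binarization: the recoverable ground
#' truth for the registration stage.
#'
#' @param truth_mask logical malignant mask on the terahertz grid.
#' @param scale integer upscaling factor >= 1.
#' @param angle rotation in degrees.
#' @param center optional (row, col) rotation centre in the upscaled frame;
#'   default: centroid of the upscaled mask. Pass a shared centre when
#'   several masks must undergo one rigid transform.
#' @return logical mask of dimension `scale * dim(truth_mask)`.
#' @export
make_pathology <- function(truth_mask, scale = 4, angle = 12, center = NULL) {
  stopifnot(scale >= 1, scale == as.integer(scale))
  up <- kronecker(truth_mask * 1, matrix(1, scale, scale)) > 0
  if (angle == 0) return(up)
  rotate_mask(up, angle, center = center)
}

#' Generate the complete phantom bundle
#'
#' Everything the clinical study supplied, in one deterministic call:
#' truth maps, simulated cube + reference, and the distorted pathology
#' mask, with the spec echoed as provenance.
#'
#' @param spec a `phantom_spec`.
#' @param substrate a `substrate_spec`.
#' @param frequencies frequency axis in Hz (see [simulate_cube()]).
#' @return list of class `phantom_output`: `cube`, `reference`, `truth`
#'   (a `phantom_truth`), `pathology_mask` (malignant regions),
#'   `pathology_support` (whole-sample footprint under the same transform,
#'   the registration feature a pathology cliche offers), `provenance`.
#' @export
generate_phantom <- function(spec = phantom_spec(),
                             substrate = default_sapphire(),
                             frequencies = seq(0.2e12, 2e12, by = 0.05e12)) {
  truth <- generate_truth(spec)
  sim <- simulate_cube(truth, substrate, frequencies,
                       snr_db = spec$snr_db, seed = spec$seed)
  # one rigid transform for both pathology-frame masks: rotate about the
  # upscaled sample-footprint centroid
  up_support <- kronecker(truth$support * 1, matrix(1, spec$pathology_scale,
                                                    spec$pathology_scale)) > 0
  ctr <- mask_centroid(up_support)
  pathology <- make_pathology(truth$truth_mask, spec$pathology_scale,
                              spec$pathology_angle, center = ctr)
  pathology_support <- make_pathology(truth$support, spec$pathology_scale,
                                      spec$pathology_angle, center = ctr)
  structure(list(cube = sim$cube, reference = sim$reference, truth = truth,
                 pathology_mask = pathology,
                 pathology_support = pathology_support, provenance = spec),
            class = "phantom_output")
}
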