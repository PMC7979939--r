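# Internal numerical helpers shared across modules.

#' Speed of light in vacuum (m/s)
#' @keywords internal
.c_light <- 299792458

# Wrap angles to [-pi, pi). Squared phase residuals are insensitive to which
# half-open convention is used; the boundary set has measure zero on the grid.
wrap_angle <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_thz <- function(msg, class) {
  stop(structure(class = c(class, "thz_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Separable Gaussian blur with half-sample symmetric (reflective) boundary.
# The kernel is normalized, so reflective padding conserves the image sum.
gaussian_blur <- function(mat, fwhm) {
  if (fwhm <= 0) return(mat)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur1d <- function(v) {
    n <- length(v)
    idx <- c(rev(seq_len(min(r, n))), seq_len(n), rev(n - seq_len(min(r, n)) + 1L))
    # if r > n the reflection above is too short; recycle reflection
    while (length(idx) < n + 2 * r) idx <- c(idx[1], idx, idx[length(idx)])
    padded <- v[idx]
    out <- stats::filter(padded, k, sides = 2)
    as.numeric(out[(r + 1):(r + n)])
  }
  tmp <- apply(mat, 2, blur1d)
  t(apply(tmp, 1, blur1d))
}

# Shift a logical matrix by (dr, dc), filling exposed cells with FALSE.
shift_mask <- function(mask, dr, dc) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  rs <- seq_len(h) - dr
  cs <- seq_len(w) - dc
  rok <- rs >= 1 & rs <= h
  cok <- cs >= 1 & cs <= w
  if (any(rok) && any(cok)) {
    out[rok, cok] <- mask[rs[rok], cs[cok]]
  }
  out
}

# Fill interior holes of a logical mask: background connected (4-neighbourhood)
# to the image border stays FALSE, enclosed background becomes TRUE.
fill_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  bg <- !mask
  reach <- matrix(FALSE, h, w)
  reach[1, ] <- bg[1, ]; reach[h, ] <- bg[h, ]
  reach[, 1] <- reach[, 1] | bg[, 1]; reach[, w] <- reach[, w] | bg[, w]
  repeat {
    grown <- reach |
      shift_mask(reach, 1L, 0L) | shift_mask(reach, -1L, 0L) |
      shift_mask(reach, 0L, 1L) | shift_mask(reach, 0L, -1L)
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  mask | (bg & !reach)
}

# Centroid (row, col) of TRUE pixels, 1-based; image centre if mask is empty.
mask_centroid <- function(mask) {
  if (!any(mask)) return(c((nrow(mask) + 1) / 2, (ncol(mask) + 1) / 2))
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

# Inverse-mapped bilinear rotation of a numeric matrix about `center`
# (row, col, 1-based). Pixels sampled outside the source get `fill`.
# Positive angles rotate counter-clockwise in the (x = col right, y = row up)
# mathematical convention used throughout the registration module.
rotate_bilinear <- function(img, angle_deg, center = NULL, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  if (is.null(center)) center <- c((h + 1) / 2, (w + 1) / 2)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  rr <- matrix(seq_len(h), h, w) - center[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - center[2]
  # inverse map: rotate target offsets by -angle to find source coordinates
  sr <- ct * rr + st * cc + center[1]
  sc <- -st * rr + ct * cc + center[2]
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  at <- function(ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    v <- matrix(fill, h, w)
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  v00 <- at(r0, c0); v01 <- at(r0, c0 + 1)
  v10 <- at(r0 + 1, c0); v11 <- at(r0 + 1, c0 + 1)
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}
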