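# Feature-based registration of the reference (pathology) mask onto the
# terahertz frame: isoline contouring, bicubic resizing of the pathology
# side, and a rotation search maximizing the Pearson correlation between
# the two contour matrices. The terahertz image is never resampled.
#
# Coordinate convention: row-major matrices, origin top-left, 0-based pixel
# centres in contour coordinates; angles in degrees, counter-clockwise
# positive in the (x = col, y = row) frame used by rotate_bilinear().

#' Extract the closed isoline of a scalar field at a given level
#'
#' Linear interpolation along pixel edges (marching-squares semantics,
#' via [grDevices::contourLines()]). When several closed isolines exist,
#' the one with the longest perimeter is returned.
#'
#' @param field numeric matrix.
#' @param level contour level, strictly between the field min and max.
#' @return a list of class `thz_contour`: `polyline` (two-column matrix of
#'   (x = col, y = row) vertices, 0-based), `closed`, `level`.
#' @export
extract_isoline <- function(field, level) {
  if (!all(is.finite(field)))
    stop_thz("field must be finite", "thz_domain_error")
  if (level <= min(field) || level >= max(field))
    stop_thz("level must lie strictly inside the field range",
             "thz_domain_error")
  cl <- grDevices::contourLines(x = seq_len(nrow(field)) - 1,
                                y = seq_len(ncol(field)) - 1,
                                z = field, levels = level)
  if (!length(cl))
    stop_thz("no isoline exists at this level", "thz_empty_region")
  perim <- function(p) sum(sqrt(diff(p$x)^2 + diff(p$y)^2))
  is_closed <- vapply(cl, function(p) {
    d <- sqrt((p$x[1] - p$x[length(p$x)])^2 + (p$y[1] - p$y[length(p$y)])^2)
    d < 1e-9 || d <= 1
  }, logical(1))
  if (!any(is_closed))
    stop_thz("no closed isoline exists at this level", "thz_empty_region")
  cl <- cl[is_closed]
  best <- cl[[which.max(vapply(cl, perim, numeric(1)))]]
  poly <- cbind(x = best$y, y = best$x)  # contourLines: x indexes rows
  if (any(abs(poly[1, ] - poly[nrow(poly), ]) > 1e-9))
    poly <- rbind(poly, poly[1, ])
  structure(list(polyline = poly, closed = TRUE, level = level),
            class = "thz_contour")
}

# Keys bicubic convolution kernel, a = -1/2 (the classic 16-neighbour
# interpolator); reproduces affine functions exactly.
cubic_kernel <- function(t) {
  a <- -0.5
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# 1-D resampling matrix from n_src samples to n_tgt, centre-aligned, with
# the source extended 2 cells each side by linear extrapolation so affine
# signals stay affine up to the borders.
resample_matrix <- function(n_src, n_tgt) {
  s <- (seq_len(n_tgt) - 0.5) * n_src / n_tgt - 0.5   # 0-based source coords
  w <- matrix(0, n_tgt, n_src + 4)
  for (i in seq_len(n_tgt)) {
    base <- floor(s[i])
    taps <- base + (-1:2)
    w[i, taps + 3] <- cubic_kernel(s[i] - taps)       # +3: pad offset, 1-based
  }
  # fold the linear-extrapolation pad back onto interior samples:
  # x[-1] = 2 x[0] - x[1], x[-2] = 2 x[0] - x[2], and mirrored at the end
  fold <- matrix(0, n_src + 4, n_src)
  fold[cbind(3:(n_src + 2), 1:n_src)] <- 1
  fold[2, 1] <- 2; fold[2, 2] <- -1
  fold[1, 1] <- 2; fold[1, 3] <- -1
  fold[n_src + 3, n_src] <- 2; fold[n_src + 3, n_src - 1] <- -1
  fold[n_src + 4, n_src] <- 2; fold[n_src + 4, n_src - 2] <- -1
  w %*% fold
}

#' Bicubic image resizing
#'
#' 16-neighbour cubic convolution (Keys kernel, a = -1/2), centre-aligned.
#' Returns the input unchanged when the target shape equals the source
#' shape. Constants and linear ramps are reproduced exactly (borders
#' handled by linear extrapolation).
#'
#' @param image numeric matrix.
#' @param target_shape integer vector (height, width), both >= 2.
#' @return numeric matrix of dimension `target_shape`.
#' @export
resize_bicubic <- function(image, target_shape) {
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 2 || any(target_shape < 2))
    stop_thz("target shape must be (h, w) with both >= 2", "thz_domain_error")
  if (identical(dim(image), target_shape)) return(image)
  if (nrow(image) < 3 || ncol(image) < 3)
    stop_thz("source image too small for bicubic resampling",
             "thz_domain_error")
  rr <- resample_matrix(nrow(image), target_shape[1])
  cc <- resample_matrix(ncol(image), target_shape[2])
  rr %*% image %*% t(cc)
}

#' Rotate a binary mask about its centroid
#'
#' Bilinear resampling of the 0/1 image followed by re-binarization at 0.5.
#'
#' @param mask logical matrix.
#' @param angle_deg rotation angle in degrees (counter-clockwise positive).
#' @param center optional (row, col) rotation centre; default: centroid of
#'   the TRUE pixels.
#' @return logical matrix.
#' @export
rotate_mask <- function(mask, angle_deg, center = NULL) {
  if (is.null(center)) center <- mask_centroid(mask)
  rotate_bilinear(mask * 1, angle_deg, center = center, fill = 0) >= 0.5
}

# 1-pixel outline of a filled mask (pixels with a FALSE 4-neighbour or on
# the image border).
mask_outline <- function(mask) {
  inner <- mask &
    shift_mask(mask, 1L, 0L) & shift_mask(mask, -1L, 0L) &
    shift_mask(mask, 0L, 1L) & shift_mask(mask, 0L, -1L)
  mask & !inner
}

#' Registration result
#' @param angle recovered rotation of the moving image relative to the
#'   fixed one, in degrees.
#' @param scale resize factor applied to the moving (pathology) image.
#' @param correlation Pearson correlation at the optimum.
#' @param coarse_angle the user-supplied initial twist.
#' @return an object of class `registration_result`.
#' @export
registration_result <- function(angle, scale, correlation, coarse_angle = 0) {
  stopifnot(correlation >= -1 - 1e-12, correlation <= 1 + 1e-12)
  structure(list(angle = angle, scale = scale,
                 correlation = correlation, coarse_angle = coarse_angle),
            class = "registration_result")
}

#' Rotation search by Pearson correlation of contour matrices
#'
#' For each grid angle `a`, the moving mask is rotated by
#' `-(coarse_angle + a)` (undoing a hypothesized misalignment of
#' `coarse_angle + a`), re-binarized, and correlated with the fixed mask.
#' The angle with the highest positive correlation wins; ties go to the
#' smallest |angle|.
#'
#' @param fixed,moving logical masks of identical shape (moving already
#'   resized to the fixed frame).
#' @param angle_grid candidate angles in degrees (default -45..45 step 1).
#' @param coarse_angle initial twist in degrees (default 0).
#' @param representation correlate `"filled"` masks (default) or 1-pixel
#'   `"outline"` contour matrices.
#' @return a `registration_result` with `angle = coarse_angle + best grid
#'   angle`.
#' @export
rotation_search <- function(fixed, moving, angle_grid = seq(-45, 45, by = 1),
                            coarse_angle = 0,
                            representation = c("filled", "outline")) {
  representation <- match.arg(representation)
  if (!identical(dim(fixed), dim(moving)))
    stop_thz("fixed and moving shapes differ", "thz_shape_error")
  if (!length(angle_grid))
    stop_thz("angle grid is empty", "thz_domain_error")
  fixed_rep <- if (representation == "outline") mask_outline(fixed) else fixed
  if (stats::sd(fixed_rep) == 0)
    stop_thz("correlation undefined: fixed mask is constant",
             "thz_degenerate_mask")
  ctr <- mask_centroid(moving)
  cors <- vapply(angle_grid, function(a) {
    rot <- rotate_mask(moving, -(coarse_angle + a), center = ctr)
    rep_m <- if (representation == "outline") mask_outline(rot) else rot
    if (stats::sd(rep_m) == 0) return(-Inf)
    stats::cor(as.numeric(rep_m), as.numeric(fixed_rep))
  }, numeric(1))
  if (all(!is.finite(cors)))
    stop_thz("correlation undefined for every candidate angle",
             "thz_degenerate_mask")
  best <- max(cors)
  tie <- which(cors >= best - 1e-12)
  pick <- tie[which.min(abs(angle_grid[tie]))]
  registration_result(angle = coarse_angle + angle_grid[pick],
                      scale = 1, correlation = cors[pick],
                      coarse_angle = coarse_angle)
}

#' Register a pathology image onto the terahertz frame
#'
#' Pipeline: contour both images (filled supports at the given levels),
#' resize the pathology side bicubically to the terahertz shape, search the
#' rotation maximizing the Pearson correlation of the contour matrices, and
#' apply the winning rotation to the resized pathology mask. Only the
#' pathology side is ever resampled.
#'
#' @param thz_field terahertz-frame scalar field, or a logical mask.
#' @param pathology_image high-resolution pathology scalar field or mask.
#' @param levels length-2 contour levels (terahertz, pathology); NULL
#'   entries use the histogram-midpoint default of [tissue_support()].
#' @param angle_grid,coarse_angle,representation see [rotation_search()].
#' @param apply_to optional logical mask in the pathology frame (e.g. the
#'   malignant annotation) carried through the rigid transform estimated on
#'   the contour feature; default: the contoured feature itself.
#' @return list with `result` (a `registration_result`, `scale` = terahertz
#'   height / pathology height) and `mask` (registered pathology mask on
#'   the terahertz grid).
#' @export
register_images <- function(thz_field, pathology_image,
                            levels = c(NA, NA),
                            angle_grid = seq(-45, 45, by = 1),
                            coarse_angle = 0,
                            representation = c("filled", "outline"),
                            apply_to = NULL) {
  representation <- match.arg(representation)
  as_support <- function(img, level) {
    if (is.logical(img)) return(img)
    tissue_support(img, if (is.na(level)) NULL else level)
  }
  fixed <- as_support(thz_field, levels[1])
  moving_full <- as_support(pathology_image, levels[2])
  scale <- nrow(fixed) / nrow(moving_full)
  to_thz <- function(m) {
    if (identical(dim(m), dim(fixed))) m else
      resize_bicubic(m * 1, dim(fixed)) >= 0.5
  }
  moving <- to_thz(moving_full)
  rs <- rotation_search(fixed, moving, angle_grid, coarse_angle,
                        representation)
  rs$scale <- scale
  payload <- if (is.null(apply_to)) moving else {
    stopifnot(identical(dim(apply_to), dim(moving_full)))
    to_thz(apply_to)
  }
  # same rigid transform for the payload: rotate about the feature centroid
  registered <- rotate_mask(payload, -rs$angle, center = mask_centroid(moving))
  list(result = rs, mask = registered)
}
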