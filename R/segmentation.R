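# Binary classification of the refractive index map and its single-pass,
# contour-constrained morphological dilation.

#' Structuring element as a set of integer pixel offsets
#'
#' Offsets are (dr, dc) translations centred at (0, 0). The element must
#' contain the origin and be point-symmetric about it ("same impact in all
#' directions").
#'
#' @param offsets integer matrix with two columns (dr, dc).
#' @param rank optional rank label 0..3 (or NA for custom elements).
#' @return an object of class `structuring_element`.
#' @export
structuring_element <- function(offsets, rank = NA_integer_) {
  offsets <- matrix(as.integer(offsets), ncol = 2)
  offsets <- unique(offsets)
  key <- function(m) paste(m[, 1], m[, 2])
  if (!("0 0" %in% key(offsets)))
    stop_thz("structuring element must contain the origin", "thz_domain_error")
  if (!all(key(-offsets) %in% key(offsets)))
    stop_thz("structuring element must be point-symmetric about the origin",
             "thz_domain_error")
  structure(list(offsets = offsets, rank = rank),
            class = "structuring_element")
}

#' Nested family of classifier structuring elements
#'
#' Rank 0 is the identity element (no dilation): the bare-threshold
#' classifier. Ranks 1-3 are origin-symmetric discrete disks of increasing
#' radius acting in the close vicinity of a pixel with the same impact in
#' all directions:
#' rank 1 — the 3x3 cross (5 offsets, city-block radius 1);
#' rank 2 — the 3x3 square plus (+-2, 0), (0, +-2) (13 offsets);
#' rank 3 — the discrete disk of Euclidean radius <= 2.5 (21 offsets).
#' Alternative shapes can be supplied via [read_structuring_element()].
#'
#' @param rank integer in 0..3.
#' @return a `structuring_element`.
#' @export
make_structuring_element <- function(rank) {
  if (!rank %in% 0:3) stop_thz("rank must be in 0..3", "thz_domain_error")
  g <- expand.grid(dr = -2:2, dc = -2:2)
  keep <- switch(as.character(rank),
    "0" = g$dr == 0 & g$dc == 0,
    "1" = abs(g$dr) + abs(g$dc) <= 1,
    "2" = (pmax(abs(g$dr), abs(g$dc)) <= 1) |
          (abs(g$dr) + abs(g$dc) == 2 & (g$dr == 0 | g$dc == 0)),
    "3" = g$dr^2 + g$dc^2 <= 2.5^2
  )
  structuring_element(cbind(g$dr[keep], g$dc[keep]), rank = as.integer(rank))
}

#' Read a structuring element from a JSON offset list
#'
#' The file holds an array of two-element integer arrays `[dr, dc]`.
#'
#' @param path JSON file path.
#' @return a `structuring_element`.
#' @export
read_structuring_element <- function(path) {
  m <- jsonlite::fromJSON(path)
  structuring_element(matrix(as.integer(m), ncol = 2))
}

#' Write a structuring element to JSON
#' @param se a `structuring_element`.
#' @param path output JSON file path.
#' @export
write_structuring_element <- function(se, path) {
  jsonlite::write_json(se$offsets, path, matrix = "rowmajor")
  invisible(path)
}

#' Threshold a refractive index map into a malignant/benign mask
#'
#' Pixels with an index strictly higher than `t` and lying on the map's
#' support are classified malignant (TRUE).
#'
#' @param map an `index_map`.
#' @param t refractive index threshold.
#' @return logical matrix (the binary refractive index map).
#' @export
threshold_map <- function(map, t) {
  stopifnot(is.finite(t))
  out <- !is.na(map$values) & map$values > t & map$support
  out
}

#' Single-pass binary dilation constrained to the tissue support
#'
#' Computes the Minkowski sum (mask + element), then intersects with
#' `support` so no malignant pixel appears outside the sample contour.
#' Exactly one pass: pixels added by the dilation exert no further
#' influence; the function never iterates.
#'
#' @param mask logical matrix, must be a subset of `support`.
#' @param se a `structuring_element`.
#' @param support logical tissue-support matrix (default: everywhere).
#' @return logical matrix, a superset of `mask` within `support`.
#' @export
dilate_mask <- function(mask, se, support = NULL) {
  if (is.null(support)) support <- matrix(TRUE, nrow(mask), ncol(mask))
  if (!identical(dim(mask), dim(support)))
    stop_thz("mask and support shapes differ", "thz_shape_error")
  if (any(mask & !support))
    stop_thz("mask must be contained in support", "thz_domain_error")
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(se$offsets))) {
    out <- out | shift_mask(mask, se$offsets[i, 1], se$offsets[i, 2])
  }
  out & support
}

# Midpoint between the two modes of a field histogram via 1-D two-means.
two_class_midpoint <- function(v) {
  v <- v[is.finite(v)]
  c1 <- min(v); c2 <- max(v)
  if (c1 == c2) return(c1)
  for (it in 1:100) {
    mid <- (c1 + c2) / 2
    lo <- v[v <= mid]; hi <- v[v > mid]
    if (!length(lo) || !length(hi)) break
    n1 <- mean(lo); n2 <- mean(hi)
    if (isTRUE(all.equal(c(n1, n2), c(c1, c2)))) break
    c1 <- n1; c2 <- n2
  }
  (c1 + c2) / 2
}

#' Tissue support mask from a scalar field
#'
#' Returns the filled interior of the isoline at `level`: pixels above the
#' level plus any enclosed holes. The level choice is subjective; the
#' default is the midpoint between the background and tissue modes of the
#' field histogram (two-means).
#'
#' @param field numeric matrix (e.g. raw terahertz amplitude or index map).
#' @param level contour level; NULL (default) picks the histogram midpoint.
#' @return logical support mask.
#' @export
tissue_support <- function(field, level = NULL) {
  if (!all(is.finite(field)))
    stop_thz("field must be finite", "thz_domain_error")
  if (is.null(level)) level <- two_class_midpoint(field)
  raw <- field > level
  if (!any(raw))
    stop_thz("contour level yields an empty region", "thz_empty_region")
  fill_holes(raw)
}
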