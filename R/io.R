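# Plain-text serialization of the pipeline artifacts. Field cubes travel as
# JSON (frequency axis + real/imag parts), masks and index maps as CSV with
# a JSON sidecar. Binary containers (HDF5/TIFF) are deliberately avoided so
# every artifact stays inspectable and environment-independent.

#' Write a field cube (plus its reference trace) to JSON
#'
#' @param cube a `field_cube`.
#' @param reference the reference `spectral_trace`.
#' @param path output `.json` path.
#' @export
write_field_cube <- function(cube, reference, path) {
  payload <- list(
    height = cube$height, width = cube$width,
    pixel_pitch = cube$pixel_pitch,
    frequencies = cube$frequencies,
    field_real = as.vector(Re(cube$field)),
    field_imag = as.vector(Im(cube$field)),
    reference_real = Re(reference$field),
    reference_imag = Im(reference$field)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a field cube written by [write_field_cube()]
#'
#' @param path `.json` path.
#' @return list with `cube` and `reference`.
#' @export
read_field_cube <- function(path) {
  p <- jsonlite::fromJSON(path)
  nf <- length(p$frequencies)
  field <- array(complex(real = p$field_real, imaginary = p$field_imag),
                 dim = c(p$height, p$width, nf))
  list(cube = field_cube(field, p$frequencies, p$pixel_pitch),
       reference = spectral_trace(p$frequencies,
                                  complex(real = p$reference_real,
                                          imaginary = p$reference_imag)))
}

#' Write a binary mask as 0/1 CSV
#' @param mask logical matrix.
#' @param path output `.csv` path.
#' @export
write_mask <- function(mask, path) {
  utils::write.table(mask * 1L, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a 0/1 CSV mask
#' @param path `.csv` path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE)) > 0
  dimnames(m) <- NULL
  m
}

#' Write an index map (values CSV + JSON sidecar)
#'
#' `basename.csv` holds the n values (NA where masked); the sidecar
#' `basename.json` records the operating frequency and, when provided,
#' the grid and objective mode used.
#'
#' @param map an `index_map`.
#' @param basename output path without extension.
#' @param meta optional named list merged into the sidecar.
#' @export
write_index_map <- function(map, basename, meta = list()) {
  utils::write.table(map$values, paste0(basename, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(map$kappa))
    utils::write.table(map$kappa, paste0(basename, "_kappa.csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  side <- c(list(frequency = map$frequency), meta)
  jsonlite::write_json(side, paste0(basename, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(basename)
}

#' Read an index map written by [write_index_map()]
#' @param basename path without extension.
#' @return an `index_map`.
#' @export
read_index_map <- function(basename) {
  vals <- as.matrix(utils::read.table(paste0(basename, ".csv"), sep = ",",
                                      header = FALSE))
  dimnames(vals) <- NULL
  side <- jsonlite::fromJSON(paste0(basename, ".json"))
  kap_path <- paste0(basename, "_kappa.csv")
  kappa <- if (file.exists(kap_path)) {
    k <- as.matrix(utils::read.table(kap_path, sep = ",", header = FALSE))
    dimnames(k) <- NULL
    k
  } else NULL
  index_map(vals, side$frequency, kappa = kappa)
}

#' Write a ROC curve as CSV
#' @param curve a `roc_curve`.
#' @param path output `.csv` path.
#' @export
write_roc_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Write a per-classifier summary JSON
#'
#' Mirrors the tabulated layout: AUC plus the best two thresholds with
#' sensitivity/specificity as percentages.
#'
#' @param curve a `roc_curve`.
#' @param path output `.json` path.
#' @param k number of best thresholds (default 2).
#' @export
write_summary_json <- function(curve, path, k = 2) {
  bt <- best_thresholds(curve, k)
  payload <- list(
    classifier_rank = attr(curve, "classifier_rank"),
    auc = if (nrow(curve) >= 2) roc_auc(curve) else NA,
    best_thresholds = lapply(seq_len(nrow(bt)), function(i) list(
      threshold = bt$threshold[i],
      tpr_minus_fpr = bt$youden[i],
      sensitivity_pct = bt$sensitivity_pct[i],
      specificity_pct = bt$specificity_pct[i]
    ))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
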