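#' Write a hemoglobin series as delimited text with a JSON sidecar
#'
#' Writes `<path>.csv` with columns `hbo_<ch>...` then `hbr_<ch>...`, and
#' `<path>.json` holding the metadata (sampling frequency, channel labels).
#'
#' @param hemo A [hemoglobin_series()].
#' @param path Output path without extension.
#' @return `path`, invisibly.
#' @export
write_hemoglobin_series <- function(hemo, path) {
  stopifnot(inherits(hemo, "hemoglobin_series"))
  m <- cbind(hemo$hbo, hemo$hbr)
  colnames(m) <- c(paste0("hbo_", hemo$channels),
                   paste0("hbr_", hemo$channels))
  utils::write.csv(as.data.frame(m), paste0(path, ".csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(type = "hemoglobin_series", fs = hemo$fs,
                            channels = hemo$channels, units = "uM"),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a hemoglobin series written by [write_hemoglobin_series()]
#'
#' @param path Path without extension.
#' @return A [hemoglobin_series()].
#' @export
read_hemoglobin_series <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.csv(paste0(path, ".csv")))
  C <- length(meta$channels)
  hemoglobin_series(m[, seq_len(C), drop = FALSE],
                    m[, C + seq_len(C), drop = FALSE],
                    fs = meta$fs, channels = meta$channels)
}

#' Write a two-wavelength absorbance series (CSV + JSON sidecar)
#'
#' @param absorbance An [absorbance_series()].
#' @param path Output path without extension.
#' @return `path`, invisibly.
#' @export
write_absorbance_series <- function(absorbance, path) {
  stopifnot(inherits(absorbance, "absorbance_series"))
  a1 <- absorbance$delta_a[, , 1L]; a2 <- absorbance$delta_a[, , 2L]
  m <- cbind(matrix(a1, dim(absorbance$delta_a)[1L]),
             matrix(a2, dim(absorbance$delta_a)[1L]))
  colnames(m) <- c(paste0("w1_", absorbance$channels),
                   paste0("w2_", absorbance$channels))
  utils::write.csv(as.data.frame(m), paste0(path, ".csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(type = "absorbance_series", fs = absorbance$fs,
                            wavelengths = absorbance$wavelengths,
                            distance = absorbance$distance,
                            dpf = absorbance$dpf,
                            channels = absorbance$channels),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an absorbance series written by [write_absorbance_series()]
#'
#' @param path Path without extension.
#' @return An [absorbance_series()].
#' @export
read_absorbance_series <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.csv(paste0(path, ".csv")))
  C <- length(meta$channels)
  arr <- array(c(m[, seq_len(C)], m[, C + seq_len(C)]),
               dim = c(nrow(m), C, 2L))
  absorbance_series(arr, fs = meta$fs, wavelengths = meta$wavelengths,
                    distance = meta$distance, dpf = meta$dpf,
                    channels = meta$channels)
}

#' Write a labeled dataset (features CSV + labels CSV + JSON metadata)
#'
#' @param labeled A `labeled_dataset`.
#' @param path Output path without extension.
#' @return `path`, invisibly.
#' @export
write_labeled_dataset <- function(labeled, path) {
  stopifnot(inherits(labeled, "labeled_dataset"))
  utils::write.csv(as.data.frame(labeled$x), paste0(path, "_features.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(condition = labeled$condition,
                              class = labeled$class,
                              segment = labeled$segment,
                              trial = labeled$trial),
                   paste0(path, "_labels.csv"), row.names = FALSE)
  jsonlite::write_json(list(type = "labeled_dataset", fs = labeled$fs,
                            counts = as.list(stats::setNames(
                              labeled$counts, labeled$condition_levels))),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Serialize cell parameters to a named-array JSON archive
#'
#' Arrays are stored under their canonical names (`w_xi`, `w_hi`, `w_ci`,
#' `b_i`, ...) at full double precision (15 significant digits), together
#' with the structural flags, so [read_cell_parameters()] restores an
#' equivalent object.
#'
#' @param params A `cell_parameters` object.
#' @param path Output file path (`.json`).
#' @return `path`, invisibly.
#' @export
write_cell_parameters <- function(params, path) {
  stopifnot(inherits(params, "cell_parameters"))
  jsonlite::write_json(unclass(params), path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Restore cell parameters from [write_cell_parameters()] output
#'
#' @param path JSON file path.
#' @return A `cell_parameters` object.
#' @export
read_cell_parameters <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- raw
  for (nm in names(p)) {
    if (is.matrix(p[[nm]])) p[[nm]] <- matrix(as.numeric(p[[nm]]),
                                              nrow(p[[nm]]), ncol(p[[nm]]))
  }
  p$input_dim <- as.integer(p$input_dim)
  p$hidden_dim <- as.integer(p$hidden_dim)
  class(p) <- "cell_parameters"
  p
}

#' Write a training history as CSV
#'
#' @param history A `training_history` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_training_history <- function(history, path) {
  utils::write.csv(as.data.frame(history), path, row.names = FALSE)
  invisible(path)
}
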