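# Plain-text / flat-binary input-output for hyperspectral cubes, annotation
# masks and patient cohort tables. The cube format is a JSON sidecar header
# (`<base>.cube.json`: dimensions, wavenumber axis, patient id) plus a flat
# little-endian float64 payload (`<base>.cube.bin`) in row-major
# (row, col, wavenumber) order. Coordinates are 0-based (row, col) with row 0
# at the top, everywhere in the package.

CUBE_FORMAT <- "spectrosurv-cube"
CUBE_FORMAT_VERSION <- 1L

#' Construct a hyperspectral cube
#'
#' A cube holds one absorbance spectrum per pixel of a tissue-core image on a
#' shared, strictly increasing wavenumber axis.
#'
#' @param axis Numeric vector of wavenumbers in cm^-1, strictly increasing.
#' @param data Numeric array indexed `[row, col, wavenumber]`; the third
#'   dimension must match `length(axis)` and all values must be finite.
#' @param patient_id Scalar identifier.
#' @return An object of class `hyperspectral_cube`.
#' @export
hyperspectral_cube <- function(axis, data, patient_id) {
  axis <- as.numeric(axis)
  if (length(dim(data)) != 3) stop("cube data must be a 3-d array [row, col, wavenumber]")
  if (dim(data)[3] != length(axis)) {
    stop(sprintf("format error: axis length %d does not match spectral depth %d",
                 length(axis), dim(data)[3]))
  }
  if (any(diff(axis) <= 0)) stop("axis error: wavenumber axis must be strictly increasing")
  if (!all(is.finite(data))) stop("data error: cube contains non-finite values")
  structure(list(axis = axis, data = data, patient_id = as.character(patient_id)),
            class = "hyperspectral_cube")
}

#' @export
print.hyperspectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyperspectral_cube> patient %s: %d x %d pixels, %d wavenumbers (%.0f-%.0f cm^-1)\n",
              x$patient_id, d[1], d[2], d[3], min(x$axis), max(x$axis)))
  invisible(x)
}

#' Construct an annotation mask
#'
#' Binary pixel grid marking tumour regions on the section co-registered with
#' the infrared image.
#'
#' @param grid Matrix of 0/1 values.
#' @param patient_id Scalar identifier.
#' @return An object of class `annotation_mask`.
#' @export
annotation_mask <- function(grid, patient_id) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "double"
  if (!all(grid %in% c(0, 1))) stop("format error: mask values must be 0 or 1")
  structure(list(grid = grid, patient_id = as.character(patient_id)),
            class = "annotation_mask")
}

#' @export
print.annotation_mask <- function(x, ...) {
  cat(sprintf("<annotation_mask> patient %s: %d x %d, tumour fraction %.3f\n",
              x$patient_id, nrow(x$grid), ncol(x$grid), mean(x$grid)))
  invisible(x)
}

#' Fraction of pixels marked as tumour
#' @param mask An `annotation_mask`.
#' @return Fraction in \[0, 1\].
#' @export
tumour_fraction <- function(mask) mean(mask$grid)

cube_paths <- function(path) {
  base <- sub("\\.cube\\.(json|bin)$", "", path)
  list(json = paste0(base, ".cube.json"), bin = paste0(base, ".cube.bin"))
}

#' Write a hyperspectral cube
#'
#' Writes `<base>.cube.json` (header) and `<base>.cube.bin` (float64 payload,
#' little-endian, row-major row/col/wavenumber order). Serialisation is
#' canonical: writing the result of a read reproduces the files byte for byte.
#'
#' @param cube A `hyperspectral_cube`.
#' @param path Base path, with or without the `.cube.json` / `.cube.bin` suffix.
#' @return The header path, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  p <- cube_paths(path)
  d <- dim(cube$data)
  header <- list(format = CUBE_FORMAT, version = CUBE_FORMAT_VERSION,
                 patient_id = cube$patient_id,
                 n_row = d[1], n_col = d[2], n_wavenumber = d[3],
                 axis = cube$axis)
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), p$json)
  con <- file(p$bin, "wb")
  on.exit(close(con))
  # row-major (row, col, wavenumber): wavenumber varies fastest
  writeBin(as.vector(aperm(cube$data, c(3, 2, 1))), con, size = 8, endian = "little")
  invisible(p$json)
}

#' Read a hyperspectral cube
#'
#' Validates header/payload consistency and finiteness; a file stored with a
#' descending axis is reordered to ascending with the data permuted to match.
#'
#' @param path Base path or path to either component file.
#' @return A `hyperspectral_cube`.
#' @export
read_cube <- function(path) {
  p <- cube_paths(path)
  if (!file.exists(p$json)) stop(sprintf("I/O error: missing header %s", p$json))
  header <- jsonlite::fromJSON(p$json)
  n <- header$n_row * header$n_col * header$n_wavenumber
  if (length(header$axis) != header$n_wavenumber) {
    stop(sprintf("format error: header axis length %d does not match declared depth %d",
                 length(header$axis), header$n_wavenumber))
  }
  payload <- readBin(p$bin, what = "double", n = n + 1L, size = 8, endian = "little")
  if (length(payload) != n) {
    stop(sprintf("format error: payload has %d values, header declares %d",
                 length(payload), n))
  }
  data <- aperm(array(payload, dim = c(header$n_wavenumber, header$n_col, header$n_row)),
                c(3, 2, 1))
  axis <- as.numeric(header$axis)
  if (all(diff(axis) < 0)) { # stored descending: reorder consistently
    axis <- rev(axis)
    data <- data[, , rev(seq_along(axis)), drop = FALSE]
  }
  hyperspectral_cube(axis, data, header$patient_id)
}

mask_patient_id <- function(path) sub("\\.mask\\.(csv|png)$", "", basename(path))

#' Write an annotation mask
#'
#' Format chosen by extension: `*.mask.csv` (plain 0/1 CSV) or `*.mask.png`
#' (single-channel PNG).
#'
#' @param mask An `annotation_mask`.
#' @param path Output path ending in `.csv` or `.png`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "annotation_mask"))
  if (grepl("\\.csv$", path)) {
    utils::write.table(mask$grid, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else if (grepl("\\.png$", path)) {
    png::writePNG(mask$grid, path)
  } else stop("format error: mask path must end in .csv or .png")
  invisible(path)
}

#' Read an annotation mask
#'
#' @param path Path to a `*.mask.csv` or `*.mask.png` file.
#' @param patient_id Identifier; defaults to the file name stem.
#' @return An `annotation_mask`.
#' @export
read_mask <- function(path, patient_id = mask_patient_id(path)) {
  if (!file.exists(path)) stop(sprintf("I/O error: missing mask %s", path))
  if (grepl("\\.csv$", path)) {
    grid <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  } else if (grepl("\\.png$", path)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    grid <- round(img) # PNG stores intensities on [0,1]
    if (max(abs(img - grid)) > 1e-6) stop("format error: mask PNG is not binary")
  } else stop("format error: mask path must end in .csv or .png")
  dimnames(grid) <- NULL
  if (!all(grid %in% c(0, 1))) stop("format error: mask values must be 0 or 1")
  annotation_mask(grid, patient_id)
}

#' Validate a cohort table
#'
#' Checks the invariants of the per-patient outcome table: unique patient ids,
#' positive follow-up times, event indicator in \{0, 1\}, and (when present)
#' risk labels in \{high, low\} and scores in \[0, 1\].
#'
#' @param cohort A data frame with columns `patient_id`, `time_months`,
#'   `event`, and optionally `risk_label` and `score`.
#' @return The validated data frame (invisibly usable in pipelines).
#' @export
validate_cohort <- function(cohort) {
  req <- c("patient_id", "time_months", "event")
  missing <- setdiff(req, names(cohort))
  if (length(missing)) stop(sprintf("format error: cohort missing columns: %s",
                                    paste(missing, collapse = ", ")))
  cohort$patient_id <- as.character(cohort$patient_id)
  if (anyDuplicated(cohort$patient_id)) stop("data error: duplicate patient_id")
  if (!all(is.finite(cohort$time_months)) || any(cohort$time_months <= 0)) {
    stop("data error: time_months must be finite and > 0")
  }
  if (!all(cohort$event %in% c(0, 1))) stop("data error: event must be 0 or 1")
  if ("risk_label" %in% names(cohort)) {
    ok <- is.na(cohort$risk_label) | cohort$risk_label %in% c("high", "low")
    if (!all(ok)) stop("data error: risk_label must be 'high' or 'low'")
  }
  if ("score" %in% names(cohort)) {
    ok <- is.na(cohort$score) | (cohort$score >= 0 & cohort$score <= 1)
    if (!all(ok)) stop("data error: score must lie in [0, 1]")
  }
  cohort
}

#' Read a cohort table
#'
#' Tab-separated file with header `patient_id  time_months  event` and
#' optional `risk_label`, `score` columns.
#'
#' @param path Path to the TSV file.
#' @return A validated data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("I/O error: missing cohort %s", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' Write a cohort table
#'
#' @param cohort A cohort data frame (see [validate_cohort()]).
#' @param path Output TSV path.
#' @export
write_cohort_table <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
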