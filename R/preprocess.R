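# Spectral preprocessing: co-registration of the tumour annotation with the
# amide-I image, EMSC-style linear interferent correction (paraffin,
# atmosphere, baseline, multiplicative thickness), quality filtering, and
# extraction of fingerprint-region (1000-1800 cm^-1) tumour spectra.

#' Preprocessing configuration
#'
#' @param amide1_wavenumber Wavenumber of the amide-I band used for
#'   co-registration and quality checks, cm^-1.
#' @param quality_min,quality_max Acceptable corrected amide-I absorbance
#'   window (absorbance units).
#' @param snr_min Minimal amide-I height / noise ratio; noise is the standard
#'   deviation of first differences in the signal-poor 1750-1800 cm^-1 band
#'   divided by sqrt(2).
#' @param max_shift Co-registration search radius in pixels (integer
#'   translations only).
#' @param interferent_set Character subset of
#'   `c("paraffin", "atmospheric", "baseline")` to include in the correction
#'   model; the tissue component is always fitted.
#' @param fingerprint_range Closed wavenumber interval retained for
#'   modelling, cm^-1.
#' @param thickness_policy `"normalise"` divides each spectrum by its fitted
#'   multiplicative thickness coefficient; `"reject"` keeps the scale and
#'   relies on the quality filter to drop out-of-window spectra.
#' @return A validated list of class `preprocess_config`.
#' @export
preprocess_config <- function(amide1_wavenumber = 1650,
                              quality_min = 0.1, quality_max = 2.0,
                              snr_min = 5,
                              max_shift = 5L,
                              interferent_set = c("paraffin", "atmospheric",
                                                  "baseline"),
                              fingerprint_range = c(1000, 1800),
                              thickness_policy = c("normalise", "reject")) {
  thickness_policy <- match.arg(thickness_policy)
  interferent_set <- match.arg(interferent_set,
                               c("paraffin", "atmospheric", "baseline"),
                               several.ok = TRUE)
  if (!(quality_min < quality_max)) {
    stop("config error: quality_min must be < quality_max")
  }
  if (max_shift < 0) stop("config error: max_shift must be >= 0")
  structure(list(amide1_wavenumber = amide1_wavenumber,
                 quality_min = quality_min, quality_max = quality_max,
                 snr_min = snr_min, max_shift = as.integer(max_shift),
                 interferent_set = interferent_set,
                 fingerprint_range = fingerprint_range,
                 thickness_policy = thickness_policy),
            class = "preprocess_config")
}

#' Amide-I intensity image
#'
#' Slice of the cube at the axis point nearest the requested wavenumber
#' (default amide I, 1650 cm^-1), used as the infrared image against which
#' the histology annotation is co-registered.
#'
#' @param cube A `hyperspectral_cube`.
#' @param wavenumber Requested band, cm^-1; must lie within the axis range.
#' @return Matrix of absorbances with the cube's spatial shape.
#' @export
amide1_image <- function(cube, wavenumber = 1650) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  k <- nearest_axis_index(cube$axis, wavenumber)
  cube$data[, , k]
}

#' Co-register an annotation mask with an intensity image
#'
#' Searches integer translations within `+/- max_shift` pixels for the offset
#' maximising the Pearson correlation between the shifted mask and the image
#' thresholded at its Otsu level. Ties are broken by the smallest offset
#' magnitude, then by the row component before the column component.
#'
#' @param mask An `annotation_mask`, same shape as `image`.
#' @param image Intensity matrix (e.g. from [amide1_image()]).
#' @param max_shift Search radius in pixels.
#' @return List with `mask` (the aligned `annotation_mask`), `offset`
#'   (integer row/col translation applied) and `correlation` at the optimum.
#' @export
coregister <- function(mask, image, max_shift = 5L) {
  stopifnot(inherits(mask, "annotation_mask"))
  if (!all(dim(mask$grid) == dim(image))) {
    stop("format error: mask and image must have the same shape")
  }
  if (all(mask$grid == 0)) stop("degenerate-input error: all-zero mask")
  binary <- (image >= otsu_threshold(image)) * 1
  offsets <- expand.grid(dr = -max_shift:max_shift, dc = -max_shift:max_shift)
  score <- function(dr, dc) {
    shifted <- shift_matrix(mask$grid, dr, dc)
    if (stats::sd(shifted) == 0 || stats::sd(binary) == 0) return(-Inf)
    stats::cor(as.vector(shifted), as.vector(binary))
  }
  corr <- mapply(score, offsets$dr, offsets$dc)
  # deterministic tie-breaking: correlation, then offset magnitude, then
  # row before column
  ord <- order(-corr, offsets$dr^2 + offsets$dc^2,
               abs(offsets$dr), offsets$dr, abs(offsets$dc), offsets$dc)
  best <- ord[1]
  off <- c(offsets$dr[best], offsets$dc[best])
  aligned <- annotation_mask(shift_matrix(mask$grid, off[1], off[2]),
                             mask$patient_id)
  list(mask = aligned, offset = off, correlation = corr[best])
}

#' Correct spectra for interferents and thickness
#'
#' Per spectrum, fits the linear model
#' `s ~ a * tissue_base + b * paraffin + c * atmospheric + d0 + d1 * axis`
#' by ordinary least squares and returns
#' `(s - b*paraffin - c*atmospheric - d0 - d1*axis) / a`, i.e. additive
#' interferents are subtracted and the multiplicative thickness coefficient
#' `a` normalised away. Spectra whose fitted `a` falls at or below a small
#' positive floor are flagged unusable (and left unscaled) rather than
#' raising an error; the quality filter removes them downstream.
#'
#' @param matrix Numeric matrix, one raw spectrum per row.
#' @param refs A `reference_spectra` on the same axis.
#' @param config A `preprocess_config`.
#' @param a_floor Smallest admissible thickness coefficient.
#' @return List with `corrected` (matrix), `coefficients` (data frame with
#'   columns a, b, c, d0, d1; zero for interferents not fitted) and `usable`
#'   (logical per spectrum).
#' @export
correct_spectra <- function(matrix, refs, config = preprocess_config(),
                            a_floor = 1e-6) {
  stopifnot(inherits(refs, "reference_spectra"))
  if (ncol(matrix) != length(refs$axis)) {
    stop("format error: spectra and references must share one axis")
  }
  design <- list(a = refs$tissue_base)
  if ("paraffin" %in% config$interferent_set) design$b <- refs$paraffin
  if ("atmospheric" %in% config$interferent_set) design$c <- refs$atmospheric
  if ("baseline" %in% config$interferent_set) {
    design$d0 <- refs$baseline_basis[, 1]
    design$d1 <- refs$baseline_basis[, 2]
  }
  D <- do.call(cbind, design)
  qrD <- qr(D)
  beta <- qr.coef(qrD, t(matrix))           # one column of coefficients per spectrum
  full <- matrix(0, nrow = nrow(matrix), ncol = 5,
                 dimnames = list(NULL, c("a", "b", "c", "d0", "d1")))
  full[, colnames(D)] <- t(beta)
  interference <- t(beta[-1, , drop = FALSE]) %*% t(D[, -1, drop = FALSE])
  corrected <- matrix - interference
  a <- full[, "a"]
  usable <- is.finite(a) & a > a_floor
  if (config$thickness_policy == "normalise") {
    corrected[usable, ] <- corrected[usable, , drop = FALSE] / a[usable]
  }
  list(corrected = corrected,
       coefficients = as.data.frame(full),
       usable = usable)
}

#' Quality-filter spectra
#'
#' A spectrum is retained iff its amide-I absorbance lies within
#' `[quality_min, quality_max]` and the ratio of the amide-I height to the
#' noise estimate is at least `snr_min`. Noise is estimated as the standard
#' deviation of first differences over the signal-poor 1750-1800 cm^-1 band,
#' divided by sqrt(2); a numerically zero noise estimate passes the SNR test.
#'
#' @param matrix Spectra, one per row (typically corrected).
#' @param axis Wavenumber axis of the columns.
#' @param config A `preprocess_config`.
#' @return Logical retention flag per row.
#' @export
quality_filter <- function(matrix, axis, config = preprocess_config()) {
  k <- nearest_axis_index(axis, config$amide1_wavenumber)
  amide <- matrix[, k]
  in_window <- amide >= config$quality_min & amide <= config$quality_max
  noise_idx <- which(axis >= 1750 & axis <= 1800)
  if (length(noise_idx) >= 3) {
    d <- matrix[, noise_idx, drop = FALSE]
    noise <- apply(d, 1, function(s) stats::sd(diff(s))) / sqrt(2)
    snr_ok <- noise <= .Machine$double.eps | amide / pmax(noise, .Machine$double.eps) >= config$snr_min
  } else {
    snr_ok <- rep(TRUE, nrow(matrix))
  }
  in_window & snr_ok & apply(is.finite(matrix), 1, all)
}

#' Extract the fingerprint-region dataset from a corrected cube
#'
#' Rows are exactly the retained tumour-mask pixels; columns are restricted
#' to axis points inside the closed fingerprint interval (default
#' \[1000, 1800\] cm^-1). Pixel coordinates are 0-based (row, col).
#'
#' @param cube A corrected `hyperspectral_cube`.
#' @param mask The aligned `annotation_mask`.
#' @param config A `preprocess_config`.
#' @param retained Optional logical per tumour pixel (in cube pixel order,
#'   column-major) from [quality_filter()]; defaults to all retained.
#' @return A `spectral_dataset`: list with `matrix`, `axis`, `meta`
#'   (data frame patient_id, row, col).
#' @export
extract_fingerprint <- function(cube, mask, config = preprocess_config(),
                                retained = NULL) {
  stopifnot(inherits(cube, "hyperspectral_cube"), inherits(mask, "annotation_mask"))
  keep_wn <- which(cube$axis >= config$fingerprint_range[1] &
                   cube$axis <= config$fingerprint_range[2])
  idx <- which(mask$grid == 1, arr.ind = TRUE)
  if (is.null(retained)) retained <- rep(TRUE, nrow(idx))
  if (length(retained) != nrow(idx)) {
    stop("format error: retention flags must match the tumour pixel count")
  }
  idx <- idx[retained, , drop = FALSE]
  if (nrow(idx) == 0) {
    warning(sprintf("patient %s: zero retained datapoints; excluded",
                    cube$patient_id))
  }
  flat <- matrix(cube$data, nrow = prod(dim(cube$data)[1:2]))
  rows <- (idx[, 2] - 1L) * dim(cube$data)[1] + idx[, 1]
  structure(list(matrix = flat[rows, keep_wn, drop = FALSE],
                 axis = cube$axis[keep_wn],
                 meta = data.frame(patient_id = rep(cube$patient_id, nrow(idx)),
                                   row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                                   stringsAsFactors = FALSE)),
            class = "spectral_dataset")
}

#' Preprocess one patient's cube end to end
#'
#' Co-registers the mask against the amide-I image, corrects all pixel
#' spectra for interferents and thickness, quality-filters the tumour
#' pixels, and extracts the fingerprint-region dataset.
#'
#' @param cube Raw `hyperspectral_cube`.
#' @param mask Stored (possibly misaligned) `annotation_mask`.
#' @param refs `reference_spectra` on the cube's axis.
#' @param config A `preprocess_config`.
#' @return List with `dataset` (a `spectral_dataset`), `offset`, `n_tumour`,
#'   `n_retained` and the per-tumour-pixel `coefficients`.
#' @export
preprocess_cube <- function(cube, mask, refs, config = preprocess_config()) {
  reg <- coregister(mask, amide1_image(cube, config$amide1_wavenumber),
                    max_shift = config$max_shift)
  aligned <- reg$mask
  flat <- matrix(cube$data, nrow = prod(dim(cube$data)[1:2]))
  idx <- which(aligned$grid == 1, arr.ind = TRUE)
  rows <- (idx[, 2] - 1L) * dim(cube$data)[1] + idx[, 1]
  corr <- correct_spectra(flat[rows, , drop = FALSE], refs, config)
  keep <- corr$usable & quality_filter(corr$corrected, cube$axis, config)
  corrected_cube <- cube
  cflat <- flat
  cflat[rows, ] <- corr$corrected
  corrected_cube$data <- array(cflat, dim = dim(cube$data))
  ds <- extract_fingerprint(corrected_cube, aligned, config, retained = keep)
  list(dataset = ds, offset = reg$offset, n_tumour = nrow(idx),
       n_retained = sum(keep), coefficients = corr$coefficients)
}

#' Combine per-patient spectral datasets
#'
#' @param datasets List of `spectral_dataset` objects sharing one axis.
#' @return A single `spectral_dataset` with rows stacked.
#' @export
bind_datasets <- function(datasets) {
  datasets <- Filter(function(d) nrow(d$matrix) > 0, datasets)
  if (!length(datasets)) stop("data error: no datapoints retained in any patient")
  axis <- datasets[[1]]$axis
  for (d in datasets) {
    if (!isTRUE(all.equal(d$axis, axis))) stop("format error: axis mismatch across patients")
  }
  structure(list(matrix = do.call(rbind, lapply(datasets, `[[`, "matrix")),
                 axis = axis,
                 meta = do.call(rbind, lapply(datasets, `[[`, "meta"))),
            class = "spectral_dataset")
}
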