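# Synthetic FTIR tissue-core generator. Real infrared images of tumour cores
# cannot be redistributed, so every downstream stage is exercised on simulated
# cubes with known ground truth: Gaussian absorption peaks for tissue and
# paraffin, a narrow-line atmospheric component, per-patient multiplicative
# thickness and paraffin contamination, per-pixel baseline drift and noise,
# a localised class-dependent spectral effect of tunable size, and
# exponential survival with class-dependent hazards plus uniform censoring.

#' Simulation configuration
#'
#' Defaults define the emulated study conditions: a 29-patient cohort imaged
#' at 6 cm^-1 resolution over 990-3800 cm^-1 on 40 x 40 pixel cores with 40%
#' tumour content, and a latent high-risk class of prevalence 0.25 with
#' hazards 0.2 (high) and 0.005 (low) events/month — median survival 3.5
#' versus 139 months, i.e. roughly a quarter of patients die within the
#' first year while low-risk patients have ~74% five-year survival, the
#' outcome structure of an aggressive head-and-neck tumour cohort. Censoring
#' is uniform on (0, 120\] months. The class effect scales one fingerprint
#' peak (1240 cm^-1) by `+10% x effect_size` in tumour pixels of high-risk
#' patients.
#'
#' @param n_patients Number of patients (>= 2).
#' @param wavenumber_start,wavenumber_end,wavenumber_step Axis in cm^-1.
#' @param core_size Pixels per side of the square core image.
#' @param tumour_fraction Fraction of pixels marked tumour (0, 1].
#' @param tumour_contrast Class-independent relative increase of the tissue
#'   absorbance in tumour pixels (denser, more cellular regions); this is
#'   what makes the tumour region visible in the amide-I image and hence
#'   co-registrable.
#' @param effect_size Dimensionless scale of the class-dependent perturbation;
#'   0 plants no signal.
#' @param hazard_high,hazard_low Event hazards (events/month) of the latent
#'   high- and low-risk classes; `hazard_high >= hazard_low > 0`.
#' @param censor_max Upper bound of the uniform censoring time, months.
#' @param paraffin_coeff_range,thickness_range,baseline_slope_range
#'   Dimensionless uniform ranges for per-patient paraffin contamination,
#'   per-patient section thickness, and per-pixel baseline intercept/slope.
#' @param noise_sd Per-pixel Gaussian noise, absorbance units.
#' @param mask_shift Integer (row, col) offset applied to the stored mask
#'   relative to the cube, to exercise co-registration.
#' @param class_prob Probability that a patient is latent high-risk.
#' @param seed Root seed for the whole simulation.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 29L,
                       wavenumber_start = 990, wavenumber_end = 3800,
                       wavenumber_step = 6,
                       core_size = 40L, tumour_fraction = 0.4,
                       tumour_contrast = 0.15,
                       effect_size = 1,
                       hazard_high = 0.2, hazard_low = 0.005,
                       censor_max = 120,
                       paraffin_coeff_range = c(0.1, 0.5),
                       thickness_range = c(0.7, 1.3),
                       baseline_slope_range = c(-0.05, 0.05),
                       noise_sd = 0.01,
                       mask_shift = c(0L, 0L),
                       class_prob = 0.25,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              wavenumber_start = wavenumber_start,
              wavenumber_end = wavenumber_end,
              wavenumber_step = wavenumber_step,
              core_size = as.integer(core_size),
              tumour_fraction = tumour_fraction,
              tumour_contrast = tumour_contrast,
              effect_size = effect_size,
              hazard_high = hazard_high, hazard_low = hazard_low,
              censor_max = censor_max,
              paraffin_coeff_range = paraffin_coeff_range,
              thickness_range = thickness_range,
              baseline_slope_range = baseline_slope_range,
              noise_sd = noise_sd,
              mask_shift = as.integer(rep_len(mask_shift, 2L)),
              class_prob = class_prob,
              seed = as.integer(seed))
  if (cfg$n_patients < 2) stop("config error: n_patients must be >= 2")
  if (!(cfg$wavenumber_start < cfg$wavenumber_end)) {
    stop("config error: wavenumber_start must be < wavenumber_end")
  }
  if (cfg$wavenumber_step <= 0) stop("config error: wavenumber_step must be > 0")
  if (!(cfg$tumour_fraction > 0 && cfg$tumour_fraction <= 1)) {
    stop("config error: tumour_fraction must lie in (0, 1]")
  }
  if (!(cfg$hazard_high >= cfg$hazard_low && cfg$hazard_low > 0)) {
    stop("config error: need hazard_high >= hazard_low > 0")
  }
  if (cfg$noise_sd < 0) stop("config error: noise_sd must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Wavenumber axis of a simulation configuration
#' @param config A `sim_config`.
#' @return Numeric vector of wavenumbers in cm^-1.
#' @export
sim_axis <- function(config) {
  seq(config$wavenumber_start, config$wavenumber_end, by = config$wavenumber_step)
}

#' Reference spectra for simulation and interferent correction
#'
#' Builds the pure-component spectra on a given axis: a tissue base spectrum
#' as a sum of Gaussian absorption peaks dominated by amide I (1650 cm^-1)
#' and amide II (1550 cm^-1); a paraffin contaminant with its CH deformation
#' doublet near 1378 and 1467 cm^-1 and CH stretches near 2850/2920 cm^-1; a
#' narrow-line water-vapour/CO2-like atmospheric component; and a
#' constant-plus-linear baseline basis.
#'
#' @param axis Strictly increasing wavenumber axis, cm^-1.
#' @return A list of class `reference_spectra` with elements `axis`,
#'   `tissue_base`, `paraffin`, `atmospheric`, `baseline_basis` (matrix with
#'   constant and linear columns) and `class_effect` (the unit-scale
#'   perturbation applied to high-risk tumour pixels).
#' @export
make_reference_spectra <- function(axis) {
  axis <- as.numeric(axis)
  if (length(axis) < 2 || any(diff(axis) <= 0)) {
    stop("axis error: wavenumber axis must be strictly increasing")
  }
  g <- function(centre, sigma, height) gaussian_peak(axis, centre, sigma, height)
  tissue_base <-
    g(1650, 25, 1.00) +  # amide I
    g(1550, 22, 0.60) +  # amide II
    g(1450, 15, 0.28) +  # CH2/CH3 deformation
    g(1240, 18, 0.45) +  # amide III / phosphate
    g(1080, 15, 0.35) +  # PO2- symmetric stretch
    g(2930, 35, 0.50) +  # CH stretch
    g(3290, 80, 0.70)    # amide A
  paraffin <-
    g(1378, 10, 0.40) +
    g(1467, 12, 0.80) +
    g(2850, 18, 1.00) +
    g(2920, 18, 1.20)
  atm_lines <- c(1507, 1540, 1560, 1576, 1617, 1653, 1700, 1717, 1772,
                 2349, 2361, 3650, 3750)
  atmospheric <- Reduce(`+`, lapply(atm_lines, function(w) g(w, 2.5, 0.6)))
  axis_norm <- (axis - axis[1]) / (axis[length(axis)] - axis[1])
  baseline_basis <- cbind(constant = rep(1, length(axis)), linear = axis_norm)
  # class effect: +10% of the 1240 cm^-1 peak per unit effect_size
  class_effect <- 0.10 * g(1240, 18, 0.45)
  structure(list(axis = axis, tissue_base = tissue_base, paraffin = paraffin,
                 atmospheric = atmospheric, baseline_basis = baseline_basis,
                 class_effect = class_effect),
            class = "reference_spectra")
}

# Contiguous pseudo-circular tumour blob covering an exact pixel count.
tumour_blob <- function(core_size, tumour_fraction) {
  n <- core_size * core_size
  k <- max(1L, round(tumour_fraction * n))
  centre <- stats::runif(2, 0.3 * core_size, 0.7 * core_size)
  rows <- matrix(seq_len(core_size), core_size, core_size)
  cols <- t(rows)
  d <- (rows - centre[1])^2 + (cols - centre[2])^2
  grid <- matrix(0, core_size, core_size)
  grid[order(as.vector(d))[seq_len(k)]] <- 1
  grid
}

#' Simulate a synthetic cohort
#'
#' Draws latent risk classes, exponential survival with class-dependent
#' hazards and independent uniform censoring, and one hyperspectral cube plus
#' tumour mask per patient. Each pixel spectrum is
#' `thickness x (tissue_base + class_effect x effect_size [tumour pixels of
#' high-risk patients]) + paraffin_coeff x paraffin + atm x atmospheric +
#' baseline + N(0, noise_sd)`. The stored mask is translated by `mask_shift`
#' relative to the cube so that co-registration is exercised downstream.
#'
#' @param config A `sim_config`.
#' @return A list of class `synthetic_cohort` with elements `cubes`, `masks`,
#'   `cohort` (data frame: patient_id, time_months, event, true_class) and
#'   `truth` (per-patient planted coefficients and the unshifted masks).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  axis <- sim_axis(config)
  refs <- make_reference_spectra(axis)
  n <- config$n_patients
  ids <- sprintf("P%03d", seq_len(n))

  cls <- stats::rbinom(n, 1L, config$class_prob)
  hazard <- ifelse(cls == 1L, config$hazard_high, config$hazard_low)
  event_time <- stats::rexp(n, rate = hazard)
  censor_time <- stats::runif(n, 0, config$censor_max)
  time_months <- pmin(event_time, censor_time)
  event <- as.integer(event_time <= censor_time)

  paraffin_coeff <- stats::runif(n, config$paraffin_coeff_range[1],
                                 config$paraffin_coeff_range[2])
  thickness <- stats::runif(n, config$thickness_range[1],
                            config$thickness_range[2])

  npix <- config$core_size^2
  nw <- length(axis)
  axis_norm <- refs$baseline_basis[, "linear"]
  cubes <- vector("list", n); masks <- vector("list", n)
  true_masks <- vector("list", n)
  names(cubes) <- names(masks) <- names(true_masks) <- ids

  for (i in seq_len(n)) {
    grid <- tumour_blob(config$core_size, config$tumour_fraction)
    tum <- as.vector(grid) == 1
    base <- thickness[i] * refs$tissue_base + paraffin_coeff[i] * refs$paraffin
    spect <- matrix(base, nrow = npix, ncol = nw, byrow = TRUE)
    # tumour regions are denser/more cellular: amide-I contrast for
    # co-registration, plus the class effect in high-risk patients
    tum_tissue <- refs$tissue_base
    if (cls[i] == 1L && config$effect_size != 0) {
      tum_tissue <- tum_tissue + config$effect_size * refs$class_effect
    }
    tum_tissue <- thickness[i] * (1 + config$tumour_contrast) * tum_tissue
    spect[tum, ] <- matrix(tum_tissue, nrow = sum(tum), ncol = nw, byrow = TRUE) +
      matrix(paraffin_coeff[i] * refs$paraffin, nrow = sum(tum), ncol = nw,
             byrow = TRUE)
    atm_amp <- stats::runif(npix, 0, 0.05)
    b0 <- stats::runif(npix, config$baseline_slope_range[1],
                       config$baseline_slope_range[2])
    b1 <- stats::runif(npix, config$baseline_slope_range[1],
                       config$baseline_slope_range[2])
    spect <- spect + outer(atm_amp, refs$atmospheric) + b0 +
      outer(b1, axis_norm)
    if (config$noise_sd > 0) {
      spect <- spect + matrix(stats::rnorm(npix * nw, 0, config$noise_sd),
                              npix, nw)
    }
    cubes[[i]] <- hyperspectral_cube(axis,
                                     array(spect, dim = c(config$core_size,
                                                          config$core_size, nw)),
                                     ids[i])
    true_masks[[i]] <- annotation_mask(grid, ids[i])
    masks[[i]] <- annotation_mask(shift_matrix(grid, config$mask_shift[1],
                                               config$mask_shift[2]), ids[i])
  }

  cohort <- data.frame(patient_id = ids, time_months = time_months,
                       event = event, true_class = cls,
                       stringsAsFactors = FALSE)
  truth <- list(patient_id = ids, class = cls,
                paraffin_coeff = paraffin_coeff, thickness = thickness,
                tumour_contrast = config$tumour_contrast,
                masks = true_masks, mask_shift = config$mask_shift)
  structure(list(cubes = cubes, masks = masks, cohort = cohort, truth = truth,
                 config = config, refs = refs),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits, per patient, `<id>.cube.json`/`<id>.cube.bin` and `<id>.mask.csv`,
#' plus `cohort.tsv` (columns patient_id, time_months, event, true_class) and
#' `truth.json` with the planted per-patient coefficients.
#'
#' @param cohort A `synthetic_cohort`.
#' @param directory Output directory; created if needed.
#' @param mask_format `"csv"` (default) or `"png"`.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, directory, mask_format = c("csv", "png")) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  mask_format <- match.arg(mask_format)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop(sprintf("I/O error: cannot create %s", directory))
  for (id in names(cohort$cubes)) {
    write_cube(cohort$cubes[[id]], file.path(directory, id))
    write_mask(cohort$masks[[id]],
               file.path(directory, sprintf("%s.mask.%s", id, mask_format)))
  }
  write_cohort_table(cohort$cohort, file.path(directory, "cohort.tsv"))
  truth <- cohort$truth[c("patient_id", "class", "paraffin_coeff", "thickness")]
  truth$mask_shift <- cohort$truth$mask_shift
  writeLines(jsonlite::toJSON(truth, digits = NA),
             file.path(directory, "truth.json"))
  invisible(directory)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param directory Directory containing `*.cube.json`, `*.mask.*` and
#'   `cohort.tsv`.
#' @return A list with `cubes`, `masks` and `cohort`.
#' @export
read_cohort_dir <- function(directory) {
  cohort <- read_cohort(file.path(directory, "cohort.tsv"))
  ids <- cohort$patient_id
  cubes <- lapply(ids, function(id) read_cube(file.path(directory, id)))
  masks <- lapply(ids, function(id) {
    for (ext in c("csv", "png")) {
      p <- file.path(directory, sprintf("%s.mask.%s", id, ext))
      if (file.exists(p)) return(read_mask(p, patient_id = id))
    }
    stop(sprintf("I/O error: no mask found for patient %s", id))
  })
  names(cubes) <- names(masks) <- ids
  list(cubes = cubes, masks = masks, cohort = cohort)
}
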