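# Internal helpers shared across modules.

#' @keywords internal
gaussian_peak <- function(axis, centre, sigma, height) {
  height * exp(-0.5 * ((axis - centre) / sigma)^2)
}

# Index of the axis point nearest a requested wavenumber; error outside range.
#' @keywords internal
nearest_axis_index <- function(axis, wavenumber) {
  if (wavenumber < axis[1] || wavenumber > axis[length(axis)]) {
    stop(sprintf("wavenumber %g outside axis range [%g, %g]",
                 wavenumber, axis[1], axis[length(axis)]), call. = FALSE)
  }
  which.min(abs(axis - wavenumber))
}

# Integer translation of a matrix by (dr, dc), zero-filled at the borders.
# Positive dr moves content down (towards larger row index), positive dc right.
#' @keywords internal
shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

# Otsu's threshold on a numeric matrix/vector: maximises between-class
# variance over a fixed histogram grid.
#' @keywords internal
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.vector(x)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  w1 <- cumsum(counts)
  w2 <- sum(counts) - w1
  mu1 <- cumsum(counts * mids) / pmax(w1, 1)
  mu_tot <- sum(counts * mids) / sum(counts)
  mu2 <- (sum(counts * mids) - cumsum(counts * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (mu1 - mu2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(between)]
}

# Derive reproducible per-stage seeds from one root seed. Stages are looked
# up by name so a stage can be rerun in isolation with the same stream.
#' @keywords internal
stage_seeds <- function(seed, stages = c("simulate", "preprocess", "stratify",
                                         "classify", "survival")) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, length(stages))
  names(s) <- stages
  s
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
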