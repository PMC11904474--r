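#' @importFrom stats sd cor dnorm rnorm rexp rbinom runif quantile median
#'   pchisq pf pt lm coef anova as.formula reformulate complete.cases setNames
NULL

# Preprocessing defaults: the resting-state band 0.008-0.09 Hz and 5 mm
# FWHM spatial smoothing.
BAND_LOW_HZ  <- 0.008
BAND_HIGH_HZ <- 0.09
SMOOTH_FWHM_MM <- 5

#' Regress nuisance signals out of a BOLD series
#'
#' Replaces every voxel time series by its residual from a least-squares
#' regression on an intercept, optionally a linear trend, and the mean time
#' series of each nuisance mask (typically CSF and white matter).  Residuals
#' are exactly orthogonal to every regressor.
#'
#' @param bold `bold_series`.
#' @param nuisance_masks named list of binary `volume_image`s.
#' @param detrend include a linear time trend in the design (default `TRUE`).
#' @return `bold_series` of residuals.
#' @export
nuisance_regress <- function(bold, nuisance_masks = list(), detrend = TRUE) {
  tdim <- n_timepoints(bold)
  design <- cbind(intercept = rep(1, tdim))
  if (detrend)
    design <- cbind(design, trend = seq_len(tdim) - (tdim + 1) / 2)
  if (length(nuisance_masks)) {
    if (is.null(names(nuisance_masks)))
      names(nuisance_masks) <- paste0("nuisance", seq_along(nuisance_masks))
    for (nm in names(nuisance_masks)) {
      m <- nuisance_masks[[nm]]
      stop_unless_same_grid(bold, setNames(list(m), nm))
      if (sum(m$data != 0) == 0L)
        stop(sprintf("nuisance_regress: nuisance mask '%s' is empty", nm))
      design <- cbind(design, seed_mean_series(bold, m))
    }
  }
  vox <- which(if (is.null(bold$brain_mask)) array(TRUE, dim(bold$data)[1:3])
               else bold$brain_mask$data != 0)
  x <- flatten_bold(bold, vox)                      # T x V
  qd <- qr(design)
  res <- x - qr.fitted(qd, x)
  out <- bold
  out$data <- unflatten_bold(bold, vox, res)
  attr(out, "preprocessing") <- c(attr(bold, "preprocessing"),
                                  list(nuisance = list(
                                    masks = names(nuisance_masks),
                                    detrend = detrend)))
  out
}

seed_mean_series <- function(bold, mask) {
  vox <- which(mask$data != 0)
  rowMeans(flatten_bold(bold, vox))   # T x V -> one value per timepoint
}

# ---- Temporal bandpass -----------------------------------------------------

#' Butterworth bandpass coefficients for the analysis band
#'
#' A 4-pole Butterworth bandpass applied forward-backward (zero phase), so
#' the effective magnitude response is the square of the single-pass
#' response.
#'
#' @param repetition_time TR in seconds.
#' @param low_hz,high_hz band edges in Hz.
#' @param order overall single-pass filter order (even, default 4).
#' @return a `signal::butter` filter object.
#' @keywords internal
bandpass_coefficients <- function(repetition_time, low_hz = BAND_LOW_HZ,
                                  high_hz = BAND_HIGH_HZ, order = 4L) {
  nyq <- 1 / (2 * repetition_time)
  if (low_hz <= 0 || low_hz >= high_hz)
    stop("bandpass: need 0 < low_hz < high_hz")
  if (high_hz >= nyq)
    stop(sprintf("bandpass: high_hz (%g Hz) must be below Nyquist (%g Hz)",
                 high_hz, nyq))
  if (order %% 2L != 0L) stop("bandpass: order must be even")
  signal::butter(order / 2L, c(low_hz, high_hz) / nyq, type = "pass")
}

#' Bandpass-filter a single time series
#'
#' @param x numeric vector.
#' @param repetition_time sampling interval in seconds.
#' @inheritParams bandpass_coefficients
#' @return filtered numeric vector.
#' @export
bandpass_series <- function(x, repetition_time, low_hz = BAND_LOW_HZ,
                            high_hz = BAND_HIGH_HZ, order = 4L) {
  bf <- bandpass_coefficients(repetition_time, low_hz, high_hz, order)
  # the mean (0 Hz) is below the passband; removing it first avoids filter
  # edge transients from the DC offset
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

## The zero-phase filter is linear, so filtering T basis vectors yields an
## exact T x T operator; applying it to the T x V voxel matrix in one BLAS
## call is identical (to machine precision) to per-voxel filtfilt.
.op_cache <- new.env(parent = emptyenv())

bandpass_operator <- function(tdim, repetition_time, low_hz = BAND_LOW_HZ,
                              high_hz = BAND_HIGH_HZ, order = 4L) {
  key <- paste(tdim, repetition_time, low_hz, high_hz, order, sep = "|")
  if (!is.null(.op_cache[[key]])) return(.op_cache[[key]])
  bf <- bandpass_coefficients(repetition_time, low_hz, high_hz, order)
  op <- vapply(seq_len(tdim), function(i) {
    e <- numeric(tdim); e[i] <- 1
    as.numeric(signal::filtfilt(bf, e))
  }, numeric(tdim))
  .op_cache[[key]] <- op
  op
}

#' Temporal bandpass filter for a BOLD series
#'
#' Zero-phase (forward-backward) Butterworth bandpass, by default the
#' 0.008-0.09 Hz resting-state band.
#'
#' @param bold `bold_series`.
#' @inheritParams bandpass_coefficients
#' @return filtered `bold_series`; the band is recorded in the
#'   `"preprocessing"` attribute.
#' @export
bandpass <- function(bold, low_hz = BAND_LOW_HZ, high_hz = BAND_HIGH_HZ,
                     order = 4L) {
  tdim <- n_timepoints(bold)
  op <- bandpass_operator(tdim, bold$repetition_time, low_hz, high_hz, order)
  vox <- which(if (is.null(bold$brain_mask)) array(TRUE, dim(bold$data)[1:3])
               else bold$brain_mask$data != 0)
  x <- flatten_bold(bold, vox)
  x <- sweep(x, 2, colMeans(x))   # DC removed ahead of filtering
  out <- bold
  out$data <- unflatten_bold(bold, vox, op %*% x)
  attr(out, "preprocessing") <- c(attr(bold, "preprocessing"),
                                  list(band = c(low_hz, high_hz)))
  out
}

# ---- Spatial smoothing -----------------------------------------------------

## 1D Gaussian smoothing matrix with half-sample symmetric (reflective)
## boundary handling; columns sum to 1 so total mass is conserved.
smooth1d_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- ceiling(4 * sigma_vox)
  w <- dnorm(-r:r, sd = sigma_vox)
  w <- w / sum(w)
  # half-sample symmetric reflection, valid for any kernel radius
  reflect <- function(j) {
    j <- ((j - 1) %% (2 * n)) + 1
    ifelse(j > n, 2 * n - j + 1, j)
  }
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cols <- reflect((i - r):(i + r))
    for (k in seq_along(cols)) m[i, cols[k]] <- m[i, cols[k]] + w[k]
  }
  m
}

smooth3d_array <- function(a, sigma_vox) {
  d <- dim(a)
  mx <- smooth1d_matrix(d[1], sigma_vox[1])
  my <- smooth1d_matrix(d[2], sigma_vox[2])
  mz <- smooth1d_matrix(d[3], sigma_vox[3])
  a <- array(mx %*% matrix(a, d[1]), d)                       # along x
  a <- aperm(array(my %*% matrix(aperm(a, c(2, 1, 3)), d[2]),
                   d[c(2, 1, 3)]), c(2, 1, 3))                # along y
  a <- aperm(array(mz %*% matrix(aperm(a, c(3, 1, 2)), d[3]),
                   d[c(3, 1, 2)]), c(2, 3, 1))                # along z
  a
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian smoothing with `sigma = fwhm / (2 sqrt(2 log 2))` per
#' axis, converted to voxel units via the transform's voxel sizes.  Boundary
#' handling is reflective, which conserves the global sum.
#'
#' @param x a `volume_image` or `bold_series`.
#' @param fwhm_mm full width at half maximum in mm (default 5); 0 is the
#'   identity.
#' @return smoothed object of the same class.
#' @export
smooth_gaussian <- function(x, fwhm_mm = SMOOTH_FWHM_MM) {
  if (fwhm_mm < 0) stop("smooth_gaussian: fwhm_mm must be >= 0")
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_sizes(x)
  if (inherits(x, "volume_image")) {
    x$data <- smooth3d_array(x$data, sigma_vox)
    return(x)
  }
  if (inherits(x, "bold_series")) {
    for (t in seq_len(n_timepoints(x)))
      x$data[, , , t] <- smooth3d_array(x$data[, , , t], sigma_vox)
    attr(x, "preprocessing") <- c(attr(x, "preprocessing"),
                                  list(fwhm_mm = fwhm_mm))
    return(x)
  }
  stop("smooth_gaussian: unsupported input class")
}

#' Standard per-subject BOLD conditioning
#'
#' Applies, in order, nuisance regression (CSF/WM mean signals plus linear
#' detrend), temporal bandpass, and Gaussian smoothing.  The order and all
#' settings are recorded in the `"preprocessing"` attribute of the result.
#'
#' @param bold `bold_series`.
#' @param nuisance_masks named list of binary `volume_image`s (may be empty).
#' @param detrend include a linear trend in the nuisance design.
#' @param low_hz,high_hz temporal band in Hz.
#' @param fwhm_mm smoothing kernel FWHM in mm.
#' @return preprocessed `bold_series`.
#' @export
preprocess_bold <- function(bold, nuisance_masks = list(), detrend = TRUE,
                            low_hz = BAND_LOW_HZ, high_hz = BAND_HIGH_HZ,
                            fwhm_mm = SMOOTH_FWHM_MM) {
  out <- nuisance_regress(bold, nuisance_masks, detrend = detrend)
  out <- bandpass(out, low_hz = low_hz, high_hz = high_hz)
  if (fwhm_mm > 0) out <- smooth_gaussian(out, fwhm_mm = fwhm_mm)
  attr(out, "preprocessing") <-
    c(attr(out, "preprocessing"),
      list(order = c("nuisance", "bandpass", "smooth")))
  out
}
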