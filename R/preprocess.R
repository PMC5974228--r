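#' Spatial Gaussian smoothing of a BOLD series
#'
#' Convolves every volume with a separable 3D Gaussian whose per-axis sigma
#' (in voxels) is `fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size`, so the
#' kernel is isotropic in millimetres on anisotropic grids. Volume borders
#' use reflect padding, which preserves the volume mean of constant images
#' exactly. The convolution runs over the whole grid, but background voxels
#' (outside the brain mask) are restored to their input values afterwards,
#' so every preprocessing step leaves the background untouched.
#'
#' @param series A `bold_series`.
#' @param fwhm_mm Kernel full width at half maximum, mm (0 = identity).
#' @return The smoothed `bold_series`.
#' @export
smooth_gaussian <- function(series, fwhm_mm) {
  if (fwhm_mm < 0) stop("'fwhm_mm' must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(series)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / series$voxel_size
  d <- dim(series$data)
  x <- series$data
  for (ax in 1:3) {
    if (sig[ax] <= 0) next
    a <- gauss_band_matrix(d[ax], sig[ax])
    x <- apply_along_axis(x, ax, a)
  }
  if (!all(series$brain_mask)) {
    bg <- which(!series$brain_mask)
    xm <- matrix(x, prod(d[1:3]), d[4])
    xm[bg, ] <- matrix(series$data, prod(d[1:3]), d[4])[bg, ]
    x <- array(xm, dim = d)
  }
  series$data <- x
  series
}

# n x n dense convolution matrix for a 1D Gaussian with edge-inclusive
# reflect padding. Row i holds the kernel centred at i, out-of-range taps
# folded back in; the fold keeps the matrix symmetric, so both row and
# column sums are 1 and constants as well as the volume mean are preserved
# exactly.
gauss_band_matrix <- function(n, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (t in seq_along(k)) {
      j <- i + t - half - 1L
      while (j < 1L || j > n) j <- ifelse(j < 1L, 1L - j, 2L * n + 1L - j)
      a[i, j] <- a[i, j] + k[t]
    }
  }
  a
}

# Multiply matrix `a` along axis `ax` of 4D array `x`.
apply_along_axis <- function(x, ax, a) {
  d <- dim(x)
  perm <- c(ax, setdiff(1:4, ax))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- a %*% matrix(xp, dp[1], prod(dp[-1]))
  aperm(array(m, dim = dp), order(perm))
}

#' Temporal low-pass filtering of a BOLD series
#'
#' Zero-phase (forward-backward) low-pass Butterworth filter of order
#' `order` applied to every in-mask voxel time-course. Each time-course is
#' demeaned before filtering and its mean restored afterwards, so the DC
#' component passes exactly and the filter's zero-padded edge transients act
#' only on the fluctuation part. Background voxels are untouched.
#'
#' @param series A `bold_series`.
#' @param cutoff_hz Cutoff frequency (Hz), strictly below Nyquist 1/(2 tr).
#' @param order Butterworth order (default 4; forward-backward doubles the
#'   effective order).
#' @return The filtered `bold_series`.
#' @export
lowpass_filter <- function(series, cutoff_hz, order = 4L) {
  nyq <- 1 / (2 * series$tr)
  if (cutoff_hz <= 0 || cutoff_hz >= nyq)
    stop(sprintf("'cutoff_hz' must lie in (0, Nyquist = %.4g Hz)", nyq),
         call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  tc <- mask_matrix(series)
  mu <- colMeans(tc)
  for (v in seq_len(ncol(tc)))
    tc[, v] <- signal::filtfilt(bf, tc[, v] - mu[v]) + mu[v]
  set_mask_matrix(series, tc)
}

#' Global signal regression
#'
#' Regresses every in-mask voxel time-course on the unweighted mean
#' time-course over the brain mask (plus an intercept) and keeps the
#' residual. Any residual voxel is exactly uncorrelated with the global
#' mean. Background voxels are untouched.
#'
#' @param series A `bold_series`.
#' @return The residualized `bold_series`.
#' @export
regress_global_signal <- function(series) {
  if (!any(series$brain_mask)) stop("empty brain mask", call. = FALSE)
  tc <- mask_matrix(series)
  g <- rowMeans(tc)
  if (stats::sd(g) == 0)
    stop("global signal has zero variance", call. = FALSE)
  x <- cbind(1, g)
  beta <- solve(crossprod(x), crossprod(x, tc))
  set_mask_matrix(series, tc - x %*% beta)
}

#' Full preprocessing chain
#'
#' Applies, in order: spatial Gaussian smoothing, temporal low-pass
#' filtering, and (optionally) global signal regression. Defaults reproduce
#' a standard small-animal resting-state chain (FWHM 1.17 mm, 0.1 Hz).
#'
#' @param series A `bold_series`.
#' @param fwhm_mm Smoothing FWHM in mm (default 1.17).
#' @param lowpass_hz Low-pass cutoff in Hz (default 0.1).
#' @param global_regression Apply global signal regression (default TRUE).
#' @return The preprocessed `bold_series`.
#' @export
preprocess_bold <- function(series, fwhm_mm = 1.17, lowpass_hz = 0.1,
                            global_regression = TRUE) {
  series <- smooth_gaussian(series, fwhm_mm)
  series <- lowpass_filter(series, lowpass_hz)
  if (global_regression) series <- regress_global_signal(series)
  series
}
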