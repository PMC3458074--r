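#' Cleaning specification for voxel timeseries
#'
#' Parameters of the timeseries cleaner applied before connectivity
#' mapping: polynomial detrending order, temporal band-pass in Hz, and a
#' matrix of per-timepoint nuisance regressors (e.g. the global mean
#' signal). The passband must satisfy `0 <= low < high < 1/(2 * tr_s)`
#' (the Nyquist frequency).
#'
#' @param detrend_order 0 (demean) or 1 (remove linear trend).
#' @param band_hz numeric length-2 passband `(low, high)` in Hz, or `NULL`
#'   to skip filtering. Default 0.01-0.08 Hz, the conventional
#'   low-frequency resting-state band.
#' @param confounds optional numeric matrix, one row per timepoint, one
#'   column per nuisance regressor; `NULL` for none.
#' @param global_signal logical; if `TRUE` (default) the volume-wide mean
#'   series is appended to the confounds. Global-signal regression is
#'   standard but debated, hence the switch.
#' @param tr_s repetition time in seconds.
#' @return Object of class `cleaning_spec`.
#' @export
cleaning_spec <- function(detrend_order = 1L, band_hz = c(0.01, 0.08),
                          confounds = NULL, global_signal = TRUE, tr_s = 2) {
  if (!detrend_order %in% c(0L, 1L)) {
    stop("`detrend_order` must be 0 or 1", call. = FALSE)
  }
  if (!is.null(band_hz)) {
    nyq <- 1 / (2 * tr_s)
    if (length(band_hz) != 2L || band_hz[1] < 0 || band_hz[1] >= band_hz[2] ||
        band_hz[2] >= nyq) {
      stop("passband must satisfy 0 <= low < high < Nyquist (",
           signif(nyq, 3), " Hz)", call. = FALSE)
    }
  }
  if (!is.null(confounds)) confounds <- as.matrix(confounds)
  structure(list(detrend_order = as.integer(detrend_order), band_hz = band_hz,
                 confounds = confounds, global_signal = global_signal,
                 tr_s = tr_s),
            class = "cleaning_spec")
}

as_ts_matrix <- function(series) {
  if (is.matrix(series)) series else matrix(series, ncol = 1L)
}

#' Remove a polynomial trend from timeseries
#'
#' Least-squares removal of the best-fit polynomial of the given order from
#' each column. Order 0 removes the mean; order 1 removes an affine trend.
#' The output has mean zero for any `order >= 0`.
#'
#' @param series numeric vector or time-by-voxel matrix.
#' @param order polynomial order (0 or 1).
#' @return Detrended series, same shape as the input.
#' @export
detrend <- function(series, order = 1L) {
  x <- as_ts_matrix(series)
  n_t <- nrow(x)
  if (n_t < order + 2L) {
    stop("need at least order + 2 = ", order + 2L, " timepoints", call. = FALSE)
  }
  basis <- stats::poly(seq_len(n_t), degree = max(order, 1L), simple = TRUE)
  if (order == 0L) basis <- basis[, 0, drop = FALSE]
  q <- qr.Q(qr(cbind(1, basis)))
  out <- x - q %*% crossprod(q, x)
  if (is.matrix(series)) out else as.numeric(out)
}

#' Temporal band-pass filter by frequency-domain masking
#'
#' Filters each column by zeroing discrete Fourier bins whose frequency
#' falls outside `[low, high]` Hz (bin edges inclusive) and inverting the
#' transform. Masking the real FFT gives an exactly reproducible response:
#' an in-band sinusoid aligned with a bin is preserved exactly and an
#' out-of-band one is removed exactly. The DC bin is kept only when
#' `low == 0`.
#'
#' @param series numeric vector or time-by-voxel matrix.
#' @param band_hz length-2 passband `(low, high)` in Hz.
#' @param tr_s sampling interval (repetition time) in seconds.
#' @return Filtered series, same shape as input.
#' @export
bandpass <- function(series, band_hz = c(0.01, 0.08), tr_s = 2) {
  x <- as_ts_matrix(series)
  n_t <- nrow(x)
  nyq <- 1 / (2 * tr_s)
  if (band_hz[1] < 0 || band_hz[1] >= band_hz[2] || band_hz[2] >= nyq) {
    stop("passband must satisfy 0 <= low < high < Nyquist (",
         signif(nyq, 3), " Hz)", call. = FALSE)
  }
  freqs <- (seq_len(n_t) - 1L) / (n_t * tr_s)
  freqs <- pmin(freqs, 1 / tr_s - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= band_hz[1] & freqs <= band_hz[2]
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0
  out <- Re(stats::mvfft(xf, inverse = TRUE)) / n_t
  if (is.matrix(series)) out else as.numeric(out)
}

#' Regress nuisance confounds out of timeseries
#'
#' Projects each column onto the orthogonal complement of the confound
#' columns (an intercept is always included), returning residuals that are
#' orthogonal to every confound at machine precision.
#'
#' @param series numeric vector or time-by-voxel matrix.
#' @param confounds numeric matrix, one row per timepoint.
#' @return Residual series, same shape as input.
#' @export
regress_confounds <- function(series, confounds) {
  x <- as_ts_matrix(series)
  c_mat <- cbind(intercept = 1, as.matrix(confounds))
  if (nrow(c_mat) != nrow(x)) {
    stop("confounds have ", nrow(c_mat), " rows but series has ", nrow(x),
         " timepoints", call. = FALSE)
  }
  dec <- qr(c_mat)
  if (dec$rank < ncol(c_mat)) {
    stop("confound matrix is rank-deficient (rank ", dec$rank, " < ",
         ncol(c_mat), " columns after adding intercept)", call. = FALSE)
  }
  q <- qr.Q(dec)
  out <- x - q %*% crossprod(q, x)
  if (is.matrix(series)) out else as.numeric(out)
}

#' Clean a 4D BOLD volume
#'
#' Applies the full cleaner -- polynomial detrending, temporal band-pass,
#' and nuisance regression (optionally including the global mean signal)
#' -- to every voxel series of a 4D volume. The stages are enforced
#' jointly, as one orthogonal projection: the data are band-pass filtered,
#' and the trend basis and confounds are themselves filtered to the same
#' band before being regressed out. Sequentially chained stages would let
#' each step reintroduce part of what an earlier step removed (the trend
#' basis has in-band energy); the joint projection avoids that, and makes
#' the cleaner exactly idempotent. The output is therefore simultaneously
#' trend-free, in-band, and orthogonal to every confound.
#'
#' When `spec$global_signal` is `TRUE` the volume-wide mean of the
#' projected data is regressed out last; because every voxel receives the
#' same projection, the cleaned data then have an exactly zero global
#' mean series.
#'
#' @param bold 4D numeric array, time last.
#' @param spec a [cleaning_spec()].
#' @return Cleaned 4D array of the same dimensions.
#' @export
clean_bold <- function(bold, spec = cleaning_spec()) {
  stopifnot(length(dim(bold)) == 4L)
  d <- dim(bold)
  n_t <- d[4]
  x <- t(matrix(bold, prod(d[1:3]), n_t))   # time x voxels
  nuis <- cbind(rep(1, n_t),
                if (spec$detrend_order >= 1L)
                  stats::poly(seq_len(n_t), spec$detrend_order, simple = TRUE),
                spec$confounds)
  if (!is.null(spec$band_hz)) {
    x <- bandpass(x, spec$band_hz, spec$tr_s)
    nuis <- bandpass(nuis, spec$band_hz, spec$tr_s)
  }
  # drop nuisance components with no in-band energy: nothing to remove
  keep <- sqrt(colSums(nuis^2)) > 1e-10 * sqrt(n_t)
  if (any(keep)) {
    dec <- qr(nuis[, keep, drop = FALSE])
    q <- qr.Q(dec)[, seq_len(dec$rank), drop = FALSE]
    x <- x - q %*% crossprod(q, x)
  }
  if (isTRUE(spec$global_signal)) {
    g <- rowMeans(x)
    # the global series vanishes once it has been regressed out (the
    # projection commutes with voxel averaging); skip the null case
    if (stats::sd(g) > 1e-10 * max(stats::sd(x), 1e-300)) {
      x <- x - g %*% crossprod(g, x) / sum(g^2)
    }
  }
  array(t(x), d)
}
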