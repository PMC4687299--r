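# Time-series conditioning ahead of complexity estimation and
# connectivity: detrend -> nuisance regression -> band-pass, in that fixed
# order. Hyperbolic-tangent despiking is applied only in the connectivity
# pathway, never before ACF fitting (extra smoothing there would bias the
# fitted decay rate).

#' Band-pass filter specification
#'
#' A 10th-order Butterworth band-pass over the standard resting-state band
#' 0.01-0.1 Hz. `order` is the order of the band-pass filter itself (it
#' must be even: `order/2` analogue poles per band edge).
#'
#' @param low_hz lower passband edge in Hz
#' @param high_hz upper passband edge in Hz
#' @param order filter order (even)
#' @param sampling_hz sampling rate, 1/TR
#' @return object of class `filter_spec`
#' @export
filter_spec <- function(low_hz = 0.01, high_hz = 0.1, order = 10,
                        sampling_hz = 0.5) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < sampling_hz / 2))
    stop_acf("filter_spec: need 0 < low_hz < high_hz < sampling_hz/2")
  if (order < 2 || order %% 2 != 0)
    stop_acf("filter_spec: order must be a positive even integer")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 sampling_hz = sampling_hz),
            class = "filter_spec")
}

#' Remove a least-squares polynomial trend from a time series
#'
#' Default is linear detrending (intercept + slope); the residual has mean
#' (numerically) zero. A constant series detrends to all zeros.
#'
#' @param x numeric vector, or a T x V matrix (columns detrended jointly)
#' @param order polynomial order (1 = linear)
#' @return residual of the same shape as `x`
#' @export
detrend <- function(x, order = 1) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(X)
  if (n < 3) stop_acf("detrend: need at least 3 time points")
  tt <- seq_len(n)
  design <- stats::poly(tt, degree = order, raw = FALSE)
  design <- cbind(1, design)
  res <- qr.resid(qr(design), X)
  if (vec) drop(res) else res
}

#' Mean time series over a tissue mask
#'
#' Per-volume mean of the raw BOLD signal over the masked voxels, used to
#' build white-matter and CSF nuisance regressors.
#'
#' @param bold a [bold_image()]
#' @param mask logical 3D array or [volume_map()] on the same grid
#' @return numeric vector of length `n_volumes`
#' @export
extract_tissue_mean <- function(bold, mask) {
  m <- as_mask(mask)
  if (!all(dim(m) == dim(bold$data)[1:3]))
    stop_acf("extract_tissue_mean: mask shape does not match the image grid")
  idx <- which(m)
  if (!length(idx)) stop_acf("extract_tissue_mean: empty mask")
  rowMeans(bold_matrix(bold, idx))
}

#' Build a nuisance design matrix
#'
#' Columns: intercept, optional linear trend, six motion parameters,
#' optional motion first derivatives (backward differences, first row 0),
#' and mean white-matter / CSF signals.
#'
#' @param n_volumes number of time points
#' @param motion optional T x 6 motion matrix
#' @param wm,csf optional tissue-mean regressors
#' @param linear_trend include a linear trend column?
#' @param motion_derivatives include first derivatives of motion (the
#'   connectivity-pathway convention)?
#' @return numeric matrix with named columns
#' @export
nuisance_design <- function(n_volumes, motion = NULL, wm = NULL, csf = NULL,
                            linear_trend = FALSE, motion_derivatives = FALSE) {
  cols <- list(intercept = rep(1, n_volumes))
  if (linear_trend) cols$trend <- seq_len(n_volumes) - (n_volumes + 1) / 2
  if (!is.null(motion)) {
    motion <- unclass(motion)
    if (nrow(motion) != n_volumes || ncol(motion) != 6L)
      stop_acf("nuisance_design: motion must be ", n_volumes, " x 6")
    for (j in 1:6) cols[[paste0("motion", j)]] <- motion[, j]
    if (motion_derivatives) {
      d <- rbind(0, diff(motion))
      for (j in 1:6) cols[[paste0("dmotion", j)]] <- d[, j]
    }
  }
  if (!is.null(wm)) {
    stopifnot(length(wm) == n_volumes)
    cols$wm <- wm
  }
  if (!is.null(csf)) {
    stopifnot(length(csf) == n_volumes)
    cols$csf <- csf
  }
  design <- do.call(cbind, cols)
  if (any(!is.finite(design))) stop_acf("nuisance_design: non-finite column values")
  design
}

#' Regress nuisance signals out of a time series
#'
#' Ordinary-least-squares residualisation: the output is orthogonal to
#' every design column. A rank-deficient design is handled by projecting
#' onto its column space (collinear columns are effectively dropped) with a
#' warning.
#'
#' @param x numeric vector, or a T x V matrix of series
#' @param design T x k design matrix (see [nuisance_design()])
#' @return residual of the same shape as `x`
#' @export
regress_nuisance <- function(x, design) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  if (nrow(X) != nrow(design))
    stop_acf("regress_nuisance: series length and design rows disagree")
  qrd <- qr(design)
  if (qrd$rank < ncol(design))
    warning(sprintf("regress_nuisance: design is rank deficient (rank %d of %d columns); collinear columns dropped",
                    qrd$rank, ncol(design)), call. = FALSE)
  res <- qr.resid(qrd, X)
  if (vec) drop(res) else res
}

# Butterworth band-pass coefficients for a filter_spec.
.butter_coefs <- function(spec) {
  w <- c(spec$low_hz, spec$high_hz) / (spec$sampling_hz / 2)
  if (any(w <= 0) || any(w >= 1))
    stop_acf("bandpass: band infeasible for the sampling rate")
  signal::butter(spec$order / 2, w, type = "pass")
}

# Unit-step steady state of the direct-form II transposed filter: the
# initial state that lets a constant input pass without transient
# (companion-matrix solve).
.iir_steady_state <- function(b, a) {
  ns <- max(length(a), length(b)) - 1L
  bb <- c(b, rep(0, ns + 1 - length(b)))
  aa <- c(a, rep(0, ns + 1 - length(a)))
  A <- matrix(0, ns, ns)
  A[, 1] <- -aa[-1]
  if (ns > 1) A[cbind(seq_len(ns - 1), seq_len(ns - 1) + 1)] <- 1
  B <- bb[-1] - aa[-1] * bb[1]
  solve(diag(ns) - A, B)
}

# IIR filtering of every column of X with transient-minimising initial
# conditions, delegated to the compiled kernel.
.iir_filter_cols <- function(b, a, X) {
  .iir_filter_cpp(as.numeric(b), as.numeric(a), X, .iir_steady_state(b, a))
}

# Zero-phase (forward-backward) filtering with odd-reflection edge padding,
# applied to every column of X.
.filtfilt_cols <- function(b, a, X) {
  n <- nrow(X)
  p <- min(3L * length(a), n - 1L)
  top <- 2 * matrix(X[1, ], p, ncol(X), byrow = TRUE) - X[(p + 1):2, , drop = FALSE]
  bot <- 2 * matrix(X[n, ], p, ncol(X), byrow = TRUE) - X[(n - 1):(n - p), , drop = FALSE]
  ext <- rbind(top, X, bot)
  y <- .iir_filter_cols(b, a, ext)
  y <- .iir_filter_cols(b, a, y[nrow(y):1, , drop = FALSE])
  y <- y[nrow(y):1, , drop = FALSE]
  y[(p + 1):(p + n), , drop = FALSE]
}

#' Band-pass filter a time series
#'
#' Zero-phase (forward-backward) application of the Butterworth band-pass
#' in `spec` by default: phase distortion would deform the autocorrelation
#' shape fitted downstream. A single-pass causal variant is available via
#' `zero_phase = FALSE`. Edges are retained, not trimmed; the
#' odd-reflection padding keeps them usable.
#'
#' @param x numeric vector, or a T x V matrix filtered column-wise
#' @param spec a [filter_spec()]
#' @param zero_phase forward-backward (default) or single-pass causal
#' @return filtered series, same shape as `x`
#' @export
bandpass <- function(x, spec = filter_spec(), zero_phase = TRUE) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  if (nrow(X) <= 3 * spec$order)
    stop_acf("bandpass: series length must exceed 3 x filter order")
  bf <- .butter_coefs(spec)
  Y <- if (zero_phase) .filtfilt_cols(bf$b, bf$a, X) else .iir_filter_cols(bf$b, bf$a, X)
  if (vec) drop(Y) else Y
}

#' Root-mean-square head displacement
#'
#' Per-volume value: the square root of the sum of squares of the six raw
#' realignment parameters (mm and radians mixed, deliberately: this is the
#' conventional scalar motion summary used for the group motion
#' comparison). The subject-level value is the mean over volumes.
#'
#' @param motion T x 6 motion matrix from [read_motion()]
#' @return list with `per_volume` (vector) and `subject` (scalar)
#' @export
rms_displacement <- function(motion) {
  m <- unclass(motion)
  if (ncol(m) != 6L) stop_acf("rms_displacement: motion must have 6 columns")
  if (any(!is.finite(m))) stop_acf("rms_displacement: non-finite motion values")
  per_volume <- sqrt(rowSums(m^2))
  list(per_volume = per_volume, subject = mean(per_volume))
}

#' Despike a time series with a hyperbolic-tangent squashing function
#'
#' With `mu` the series mean and `c = c_mult * SD`, returns
#' `mu + c * tanh((x - mu)/c)`: a strictly monotone map that is nearly the
#' identity within about one SD of the mean but bounds the output in
#' `[mu - c, mu + c]`, taming outlier scans. A zero-variance series is
#' returned unchanged.
#'
#' @param x numeric vector, or a T x V matrix despiked column-wise
#' @param c_mult squashing width in units of the series SD
#' @return despiked series, same shape as `x`
#' @export
despike_tanh <- function(x, c_mult = 3) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  if (nrow(X) < 3) stop_acf("despike_tanh: need at least 3 time points")
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  cc <- c_mult * s
  out <- X
  nz <- which(cc > 0)
  if (length(nz)) {
    mu_m <- matrix(mu[nz], nrow(X), length(nz), byrow = TRUE)
    cc_m <- matrix(cc[nz], nrow(X), length(nz), byrow = TRUE)
    out[, nz] <- mu_m + cc_m * tanh((X[, nz, drop = FALSE] - mu_m) / cc_m)
  }
  if (vec) drop(out) else out
}

# Conditioning pipeline for the ACF pathway: detrend -> OLS residual
# against (intercept, 6 motion, WM mean, CSF mean) -> zero-phase band-pass.
.condition_acf_matrix <- function(X, motion = NULL, wm = NULL, csf = NULL,
                                  spec = NULL) {
  spec <- spec %||% filter_spec(sampling_hz = 0.5)
  X <- detrend(X)
  design <- nuisance_design(nrow(X), motion = motion, wm = wm, csf = csf)
  X <- regress_nuisance(X, design)
  bandpass(X, spec)
}

# Conditioning pipeline for the connectivity pathway: despike -> detrend ->
# OLS residual against (intercept, motion + first derivatives, WM, CSF) ->
# zero-phase band-pass.
.condition_conn_matrix <- function(X, motion = NULL, wm = NULL, csf = NULL,
                                   spec = NULL, c_mult = 3) {
  spec <- spec %||% filter_spec(sampling_hz = 0.5)
  X <- despike_tanh(X, c_mult = c_mult)
  X <- detrend(X)
  design <- nuisance_design(nrow(X), motion = motion, wm = wm, csf = csf,
                            motion_derivatives = !is.null(motion))
  X <- regress_nuisance(X, design)
  bandpass(X, spec)
}
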