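# The core statistic: per-voxel autocorrelation decay. The sample ACF over
# lags 0..8 (lag unit = 1 TR) is fitted with the exponential model
# ACF(k) = a * exp(-b k); b is the decay rate per TR and tau = TR / b the
# mean lifetime in seconds (tau = 0 for white noise). The frequency-domain
# analogue is the power-law exponent beta of P(f) ~ 1/f^beta, connected to
# the ACF through the Wiener-Khinchin theorem.

#' Sample autocorrelation function over lags 0..max_lag
#'
#' Biased estimator: `r_k = sum_t (x_t - xbar)(x_{t+k} - xbar) /
#' sum_t (x_t - xbar)^2` (denominator n, pooled-variance normalisation).
#' This estimator guarantees `|r_k| <= 1` and makes the discrete
#' Wiener-Khinchin identity exact.
#'
#' @param x numeric time series, longer than `max_lag + 1` and non-constant
#' @param max_lag largest lag (default 8, so 9 points feed the fit)
#' @return object of class `acf_curve`: lag values `r_0..r_max_lag`
#'   (`r_0 = 1`) plus the source length
#' @export
sample_acf <- function(x, max_lag = 8) {
  n <- length(x)
  if (n <= max_lag + 1) stop_acf("sample_acf: series too short for max_lag = ", max_lag)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) stop_acf("sample_acf: zero-variance series has no defined ACF")
  vals <- vapply(0:max_lag, function(k) {
    sum(xc[seq_len(n - k)] * xc[(k + 1):n]) / denom
  }, numeric(1))
  structure(list(values = vals, max_lag = max_lag, n_samples = n),
            class = "acf_curve")
}

# Vectorised sample ACF: X is T x V, returns (max_lag + 1) x V. Columns
# with zero variance come back as NA and must be handled by the caller.
.sample_acf_matrix <- function(X, max_lag = 8) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  denom <- colSums(Xc^2)
  out <- matrix(NA_real_, max_lag + 1, ncol(X))
  ok <- denom > 0
  if (!any(ok)) return(out)
  for (k in 0:max_lag) {
    num <- colSums(Xc[seq_len(n - k), , drop = FALSE] *
                     Xc[(k + 1):n, , drop = FALSE])
    out[k + 1, ok] <- num[ok] / denom[ok]
  }
  out
}

# Log-linear initial decay-rate guess per column: least-squares slope of
# log r_k on k over the strictly positive r_k. NA where fewer than 3
# positive points (the grid fallback covers those columns).
.loglin_init <- function(R, b_lower, b_upper) {
  k <- seq_len(nrow(R)) - 1
  W <- (R > 0) & is.finite(R)
  LR <- ifelse(W, log(pmax(R, 1e-300)), 0)
  Km <- matrix(k, nrow(R), ncol(R))
  np <- colSums(W)
  Sx <- colSums(W * Km); Sy <- colSums(LR)
  Sxx <- colSums(W * Km^2); Sxy <- colSums(LR * Km)
  den <- np * Sxx - Sx^2
  slope <- ifelse(np >= 3 & den > 0, (np * Sxy - Sx * Sy) / den, NA_real_)
  pmin(pmax(-slope, b_lower), b_upper)
}

# Vectorised bounded nonlinear least squares for r_k ~ a * exp(-b k),
# k = 0..L, one fit per column of R. The amplitude is profiled out
# (for fixed b the optimal a is a linear LS coefficient, clamped to
# (0, a_upper]), reducing each fit to a 1-D search over b: dense
# log-spaced grid seeded with the log-linear initial guess, golden-section
# refinement, then a short damped Gauss-Newton polish in (a, b).
.fit_exp_matrix <- function(R, b_lower = 1e-6, b_upper = 20, a_upper = 2,
                            grid_size = 64L, golden_iter = 60L, gn_iter = 6L) {
  L <- nrow(R) - 1L
  k <- 0:L
  V <- ncol(R)
  ss_tot <- colSums(R^2)

  # profile SSE from explicit residuals (an expanded quadratic form would
  # cancel catastrophically when the fit is near-exact)
  prof <- function(bv) {
    E <- exp(-outer(k, bv))
    num <- colSums(E * R)
    den <- colSums(E * E)
    a <- pmin(pmax(num / den, 1e-12), a_upper)
    sse <- colSums((R - E * rep(a, each = L + 1L))^2)
    list(a = a, sse = sse)
  }

  # dense grid + log-linear initial guess as candidate set
  bgrid <- exp(seq(log(b_lower), log(b_upper), length.out = grid_size))
  SSE <- matrix(NA_real_, grid_size, V)
  for (gi in seq_len(grid_size))
    SSE[gi, ] <- prof(rep(bgrid[gi], V))$sse
  best <- max.col(t(-SSE), ties.method = "first")
  binit <- .loglin_init(R, b_lower, b_upper)
  has_init <- is.finite(binit)
  if (any(has_init)) {
    pi_ <- prof(ifelse(has_init, binit, b_lower))
    sse_best <- SSE[cbind(best, seq_len(V))]
    use_init <- has_init & pi_$sse < sse_best
  } else use_init <- logical(V)

  lo <- bgrid[pmax(best - 1L, 1L)]
  hi <- bgrid[pmin(best + 1L, grid_size)]
  if (any(use_init)) {
    step <- log(bgrid[2] / bgrid[1])
    lo[use_init] <- pmax(binit[use_init] * exp(-step), b_lower)
    hi[use_init] <- pmin(binit[use_init] * exp(step), b_upper)
  }

  # golden-section refinement of b within [lo, hi], all columns in parallel
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- prof(x1)$sse
  f2 <- prof(x2)$sse
  for (it in seq_len(golden_iter)) {
    move1 <- f1 < f2
    hi[move1] <- x2[move1]
    x2[move1] <- x1[move1]
    f2[move1] <- f1[move1]
    x1[move1] <- hi[move1] - gr * (hi[move1] - lo[move1])
    lo[!move1] <- x1[!move1]
    x1[!move1] <- x2[!move1]
    f1[!move1] <- f2[!move1]
    x2[!move1] <- lo[!move1] + gr * (hi[!move1] - lo[!move1])
    fn <- prof(ifelse(move1, x1, x2))$sse
    f1[move1] <- fn[move1]
    f2[!move1] <- fn[!move1]
  }
  b <- (lo + hi) / 2
  pr <- prof(b)
  a <- pr$a
  sse <- pr$sse

  # damped Gauss-Newton polish on (a, b); steps accepted only when the
  # objective decreases, so the final objective can never exceed the
  # grid/golden (and hence the initialisation) objective
  for (it in seq_len(gn_iter)) {
    Eb <- exp(-outer(k, b))
    M <- Eb * rep(a, each = L + 1L)
    Rsd <- R - M
    J2 <- -(k * M)                      # d model / d b
    g11 <- colSums(Eb^2)
    g12 <- colSums(Eb * J2)
    g22 <- colSums(J2^2)
    g22 <- g22 * (1 + 1e-10) + 1e-300
    r1 <- colSums(Eb * Rsd)
    r2 <- colSums(J2 * Rsd)
    det_ <- g11 * g22 - g12^2
    ok <- det_ > 1e-300
    da <- ifelse(ok, (g22 * r1 - g12 * r2) / det_, 0)
    db <- ifelse(ok, (g11 * r2 - g12 * r1) / det_, 0)
    a_new <- pmin(pmax(a + da, 1e-12), a_upper)
    b_new <- pmin(pmax(b + db, b_lower), b_upper)
    E_new <- exp(-outer(k, b_new))
    sse_new <- colSums((R - E_new * rep(a_new, each = L + 1L))^2)
    acc <- sse_new < sse
    a[acc] <- a_new[acc]
    b[acc] <- b_new[acc]
    sse[acc] <- sse_new[acc]
  }

  rbar <- colMeans(R)
  sst <- colSums(sweep(R, 2, rbar)^2)
  r2 <- ifelse(sst > 0, pmax(0, pmin(1, 1 - sse / sst)), NA_real_)
  list(a = a, b = b, sse = sse, rmse = sqrt(sse / (L + 1L)), r2 = r2,
       converged = a > 1e-10)
}

#' Fit the exponential-decay model to an ACF curve
#'
#' Bounded nonlinear least squares of `a * exp(-b k)` against the 9 ACF
#' points at lags 0..8 (the lag-0 point, always 1, is included). Bounds:
#' `a` in (0, 2], `b` in (1e-6, 20] - the upper bound on `b` keeps
#' white-noise fits well-posed (a mean-lifetime floor of 0.1 s at
#' TR = 2 s). Initialisation is a log-linear regression on the strictly
#' positive ACF values with a dense grid fallback; the converged objective
#' never exceeds the objective at initialisation. If all positive-lag
#' values are non-positive the amplitude collapses to its lower bound and
#' the fit is flagged unconverged rather than raising.
#'
#' @param curve an [sample_acf()] curve with lags 0..8 (or more; the first
#'   9 points are used)
#' @param tr optional repetition time in seconds; when given, the mean
#'   lifetime `tau = tr / b` is included
#' @return object of class `acf_fit`: fields `a`, `b`, `rmse`, `r2`,
#'   `n_points`, `converged`, and `tau` when `tr` is supplied
#' @export
fit_exp_decay <- function(curve, tr = NULL) {
  vals <- if (inherits(curve, "acf_curve")) curve$values else as.numeric(curve)
  if (length(vals) < 9) stop_acf("fit_exp_decay: need ACF lags 0..8 (9 points)")
  vals <- vals[1:9]
  fit <- .fit_exp_matrix(matrix(vals, ncol = 1))
  out <- list(a = fit$a, b = fit$b, rmse = fit$rmse, r2 = fit$r2,
              n_points = 9L, converged = fit$converged)
  if (!is.null(tr)) out$tau <- tau_from_b(fit$b, tr)
  structure(out, class = "acf_fit")
}

#' @export
print.acf_fit <- function(x, ...) {
  cat(sprintf("<acf_fit> a = %.4f, b = %.4f per TR%s, rmse = %.3g\n",
              x$a, x$b,
              if (!is.null(x$tau)) sprintf(", tau = %.3f s", x$tau) else "",
              x$rmse))
  invisible(x)
}

#' Mean lifetime from a decay rate
#'
#' `tau = tr / b` seconds: the time over which a signal retains association
#' with its past. White noise has `tau` of essentially zero.
#'
#' @param b decay rate per TR (> 0)
#' @param tr repetition time in seconds (> 0)
#' @return mean lifetime in seconds
#' @export
tau_from_b <- function(b, tr) {
  if (any(!is.finite(b)) || any(b <= 0)) stop_acf("tau_from_b: b must be > 0")
  if (any(tr <= 0)) stop_acf("tau_from_b: tr must be > 0")
  tr / b
}

#' Voxel-wise decay-rate map
#'
#' Runs the full ACF pathway over every in-mask voxel: detrend -> nuisance
#' regression (intercept, six motion parameters, mean WM, mean CSF) ->
#' zero-phase band-pass -> sample ACF (lags 0..8) -> exponential fit.
#' Voxels with zero variance (before or after conditioning) or with
#' degenerate fits are removed from the output mask and counted, never
#' imputed.
#'
#' @param bold a [bold_image()]
#' @param brain_mask analysis mask (logical array or [volume_map()])
#' @param motion optional T x 6 motion matrix
#' @param wm_mask,csf_mask optional tissue masks for nuisance regressors
#' @param spec a [filter_spec()]; defaults to 0.01-0.1 Hz at the image TR
#' @param max_lag largest ACF lag fitted (default 8)
#' @param condition set `FALSE` to fit raw series (no detrend/regression/
#'   filtering); used for unfiltered parameter-recovery studies
#' @return object of class `bmap_result`: volume maps `b`, `a`, `tau`,
#'   `r2`, plus exclusion counts `n_fit`, `n_excluded`
#' @export
b_map <- function(bold, brain_mask, motion = NULL, wm_mask = NULL,
                  csf_mask = NULL, spec = NULL, max_lag = 8,
                  condition = TRUE) {
  mask <- as_mask(brain_mask)
  if (!all(dim(mask) == dim(bold$data)[1:3]))
    stop_acf("b_map: mask shape does not match the image grid")
  idx <- which(mask)
  dm <- dim(mask)
  empty <- function() {
    nanarr <- array(NaN, dm)
    warning("b_map: no analysable voxels in mask", call. = FALSE)
    structure(list(
      b = volume_map(nanarr, bold$affine, array(FALSE, dm)),
      a = volume_map(nanarr, bold$affine, array(FALSE, dm)),
      tau = volume_map(nanarr, bold$affine, array(FALSE, dm)),
      r2 = volume_map(nanarr, bold$affine, array(FALSE, dm)),
      n_fit = 0L, n_excluded = length(idx)), class = "bmap_result")
  }
  if (!length(idx)) return(empty())

  X <- bold_matrix(bold, idx)
  keep <- .col_vars(X) > 0
  if (condition && any(keep)) {
    spec <- spec %||% filter_spec(sampling_hz = 1 / bold$tr)
    wm <- if (!is.null(wm_mask)) extract_tissue_mean(bold, wm_mask)
    csf <- if (!is.null(csf_mask)) extract_tissue_mean(bold, csf_mask)
    X[, keep] <- .condition_acf_matrix(X[, keep, drop = FALSE],
                                       motion = motion, wm = wm, csf = csf,
                                       spec = spec)
    keep <- keep & .col_vars(X) > 0
  }
  if (!any(keep)) return(empty())

  R <- .sample_acf_matrix(X[, keep, drop = FALSE], max_lag = max_lag)
  fit <- .fit_exp_matrix(R)
  ok <- fit$converged & is.finite(fit$b)

  final_idx <- idx[keep][ok]
  mk <- function(v) {
    arr <- array(NaN, dm)
    arr[final_idx] <- v[ok]
    m <- array(FALSE, dm)
    m[final_idx] <- TRUE
    volume_map(arr, bold$affine, m)
  }
  structure(list(
    b = mk(fit$b), a = mk(fit$a), tau = mk(tau_from_b(pmax(fit$b, 1e-12), bold$tr)),
    r2 = mk(fit$r2),
    n_fit = length(final_idx),
    n_excluded = length(idx) - length(final_idx)), class = "bmap_result")
}

# Column variances without extra dependencies.
.col_vars <- function(X) {
  n <- nrow(X)
  cm <- colMeans(X)
  (colSums(X^2) - n * cm^2) / (n - 1)
}

#' @export
print.bmap_result <- function(x, ...) {
  cat(sprintf("<bmap_result> %d voxels fitted, %d excluded; median b = %.3f\n",
              x$n_fit, x$n_excluded,
              median(x$b$values[x$b$mask])))
  invisible(x)
}

#' Power-spectrum scale-invariance exponent
#'
#' Estimates `beta` in `P(f) ~ 1/f^beta` as the negative slope of the
#' ordinary-least-squares line fitted to the log10 periodogram against
#' log10 frequency, restricted to the analysis band (default 0.01-0.1 Hz).
#' The raw periodogram of the demeaned series is used.
#'
#' @param x numeric time series
#' @param sampling_hz sampling rate (1/TR)
#' @param band frequency band (Hz) for the log-log fit; needs >= 5 bins
#' @return object of class `spectral_fit`: `beta`, `band`, `r2`, `n_bins`
#' @export
pssi_beta <- function(x, sampling_hz, band = c(0.01, 0.1)) {
  n <- length(x)
  xc <- x - mean(x)
  P <- Mod(fft(xc))^2 / n
  j <- seq_len(floor(n / 2))
  f <- j * sampling_hz / n
  sel <- f >= band[1] & f <= band[2] & P[j + 1] > 0
  if (sum(sel) < 5)
    stop_acf("pssi_beta: fewer than 5 frequency bins in the band")
  lf <- log10(f[sel])
  lp <- log10(P[j + 1][sel])
  fit <- lm.fit(cbind(1, lf), lp)
  beta <- -fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) / sum((lp - mean(lp))^2)
  structure(list(beta = unname(beta), band = band, r2 = r2,
                 n_bins = sum(sel)),
            class = "spectral_fit")
}

#' Numerical check of the discrete Wiener-Khinchin identity
#'
#' The periodogram of a demeaned series equals the discrete Fourier
#' transform of its full-lag biased autocovariance sequence:
#' `I_j = c_0 + 2 * sum_k c_k cos(2 pi j k / n)`. This function computes
#' both routes and returns the maximum absolute difference, which is at
#' machine-precision level by construction.
#'
#' @param x numeric, non-constant time series
#' @return maximum absolute gap between the two spectral estimates
#' @export
wiener_khinchin_gap <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  if (sum(xc^2) == 0) stop_acf("wiener_khinchin_gap: constant series")
  # biased autocovariance at lags 0..n-1
  cv <- vapply(0:(n - 1), function(k) {
    sum(xc[seq_len(n - k)] * xc[(k + 1):n]) / n
  }, numeric(1))
  spec_acf <- 2 * Re(fft(cv)) - cv[1]
  periodogram <- Mod(fft(xc))^2 / n
  max(abs(spec_acf - periodogram))
}
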