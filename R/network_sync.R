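# Pairwise network synchrony: phase-locking values in a frequency band and
# sliding-window cross-correlation with lag estimation.

# analytic signal via the FFT (one-sided spectrum doubling)
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a trace in a frequency band
#'
#' Zero-phase band-pass filters the trace (4th-order Butterworth applied
#' forward and backward via `signal::filtfilt`), then takes the analytic
#' signal's phase.
#'
#' @param x numeric trace.
#' @param sampling_rate Hz.
#' @param band band name or list with `f_low`, `f_high` (must be below
#'   Nyquist).
#' @param order Butterworth prototype order (default 4).
#' @return List with `phase` (radians in (-pi, pi]), `band`, `filter`
#'   (description string).
#' @export
instantaneous_phase <- function(x, sampling_rate, band, order = 4) {
  b <- resolve_band(band)
  if (b$f_high >= sampling_rate / 2)
    fp_error("fluopipe_argument_error", "band upper edge at or above Nyquist")
  flt <- signal::butter(order, c(b$f_low, b$f_high) / (sampling_rate / 2),
                        type = "pass")
  flen <- max(length(flt$b), length(flt$a))
  if (length(x) < 3 * flen)
    fp_error("fluopipe_argument_error",
             sprintf("trace length %d shorter than 3 filter lengths (%d)",
                     length(x), 3 * flen))
  xf <- signal::filtfilt(flt, x - mean(x))
  phi <- Arg(analytic_signal(xf))
  list(phase = phi, band = b,
       filter = sprintf("butterworth order %d band-pass %g-%g Hz, zero-phase",
                        order, b$f_low, b$f_high))
}

#' Phase-locking value between two phase series
#'
#' `PLV = |mean(exp(i * (phi_a - phi_b)))|` over the retained samples: 1 for
#' perfectly locked phases (any constant offset), ~`sqrt(pi)/2/sqrt(N)` in
#' expectation for independent phases. Samples within `edge_zero_s` seconds
#' of either end are excluded from the mean — filter and Hilbert transients
#' concentrate there, and including them (or literally zeroing the phases)
#' would bias the PLV toward spurious locking.
#'
#' @param phases_a,phases_b phase series in radians, equal length.
#' @param sampling_rate Hz (needed when `edge_zero_s > 0`).
#' @param edge_zero_s seconds trimmed at each end (default 0).
#' @return Scalar in `[0, 1]` with attribute `n_samples_used`.
#' @export
plv <- function(phases_a, phases_b, sampling_rate = NULL, edge_zero_s = 0) {
  if (length(phases_a) != length(phases_b))
    fp_error("fluopipe_argument_error", "phase series lengths differ")
  n <- length(phases_a)
  drop <- if (edge_zero_s > 0) {
    if (is.null(sampling_rate))
      fp_error("fluopipe_argument_error", "edge_zero_s needs sampling_rate")
    round(edge_zero_s * sampling_rate)
  } else 0L
  if (2 * drop >= n)
    fp_error("fluopipe_argument_error", "edge trimming excludes every sample")
  keep <- (drop + 1L):(n - drop)
  v <- Mod(mean(exp(1i * (phases_a[keep] - phases_b[keep]))))
  structure(v, n_samples_used = length(keep))
}

#' Phase-locking value matrix over all cell pairs
#'
#' Extracts each cell's instantaneous phase in the chosen band and computes
#' the PLV for every unordered pair.
#'
#' @param traces a `TraceSet` with `dff` computed.
#' @param band band name or `f_low`/`f_high` list.
#' @param edge_zero_s seconds excluded at each end; default two periods of
#'   the band's lower edge.
#' @param order band-pass filter order (see [instantaneous_phase()]).
#' @return A `PLVMatrix`: list with `values` (symmetric `[cell, cell]`
#'   matrix, unit diagonal), `band`, `edge_zero_s`, `n_samples_used`,
#'   `cell_ids`.
#' @export
plv_matrix <- function(traces, band = "delta", edge_zero_s = NULL,
                       order = 4) {
  if (is.null(traces$dff))
    fp_error("fluopipe_stage_error", "stage not run: compute_dff")
  b <- resolve_band(band)
  fs <- 1 / traces$sampling_interval
  edge_zero_s <- edge_zero_s %||% (2 / b$f_low)
  nk <- ncol(traces$dff)
  phases <- matrix(NA_real_, nrow(traces$dff), nk)
  for (k in seq_len(nk))
    phases[, k] <- instantaneous_phase(traces$dff[, k], fs, b, order)$phase
  V <- diag(1, nk)
  nuse <- NA_integer_
  if (nk >= 2) {
    for (i in 1:(nk - 1)) for (j in (i + 1):nk) {
      v <- plv(phases[, i], phases[, j], fs, edge_zero_s)
      nuse <- attr(v, "n_samples_used")
      V[i, j] <- V[j, i] <- as.numeric(v)
    }
  }
  structure(list(values = V, band = b, edge_zero_s = edge_zero_s,
                 n_samples_used = nuse, cell_ids = traces$roi_ids),
            class = "PLVMatrix")
}

# Pearson cross-correlation of one window at every lag; returns the
# max-correlation and its lag with deterministic tie-breaking
window_xcorr <- function(a, b, start, W, lags, n) {
  idx <- start:(start + W - 1L)
  best_r <- -Inf; best_lag <- NA_integer_; any_ok <- FALSE
  rs <- rep(NA_real_, length(lags))
  for (li in seq_along(lags)) {
    l <- lags[li]
    if (start + l < 1L || start + W - 1L + l > n) next
    sa <- a[idx]; sb <- b[idx + l]
    if (sd(sa) == 0 || sd(sb) == 0) next
    rs[li] <- cor(sa, sb)
    any_ok <- TRUE
  }
  if (!any_ok) return(list(r = NA_real_, lag = NA_integer_, flagged = TRUE))
  mx <- max(rs, na.rm = TRUE)
  cand <- lags[!is.na(rs) & rs >= mx - 1e-12]
  cand <- cand[order(abs(cand), cand)]   # smallest |lag|, then negative first
  list(r = mx, lag = cand[1], flagged = FALSE)
}

#' Sliding-window cross-correlation between two traces
#'
#' Splits the recording into overlapping windows and, per window, computes
#' the Pearson correlation at every integer-sample lag in
#' `[-max_lag, +max_lag]`, reporting the maximum and its lag
#' (ties broken toward the smallest `|lag|`, negative first). Defaults
#' derive from the sampling interval: window 256 samples, step 64 samples,
#' max lag window/4.
#'
#' @param a,b numeric traces of equal length.
#' @param sampling_rate Hz.
#' @param window_s,step_s,max_lag_s window, step and maximum lag in seconds
#'   (defaults: 256, 64 and 64 samples).
#' @param exclude_zero_lag drop lag 0 from the argmax (used for
#'   autocorrelation).
#' @return data.frame with one row per window: `window_time` (centre, s),
#'   `max_corr`, `lag_s`, `lag_samples`, `flagged` (zero-variance or
#'   no-valid-lag windows).
#' @export
sliding_xcorr <- function(a, b, sampling_rate, window_s = NULL,
                          step_s = NULL, max_lag_s = NULL,
                          exclude_zero_lag = FALSE) {
  n <- length(a)
  if (length(b) != n)
    fp_error("fluopipe_argument_error", "traces must have equal length")
  W <- if (is.null(window_s)) 256L else as.integer(round(window_s * sampling_rate))
  S <- if (is.null(step_s)) 64L else max(1L, as.integer(round(step_s * sampling_rate)))
  L <- if (is.null(max_lag_s)) W %/% 4L else as.integer(round(max_lag_s * sampling_rate))
  if (W > n)
    fp_error("fluopipe_argument_error",
             sprintf("window of %d samples longer than trace (%d)", W, n))
  if (W < 4L * L)
    fp_error("fluopipe_argument_error", "window must be >= 4 x max_lag samples")
  lags <- (-L):L
  if (exclude_zero_lag) lags <- lags[lags != 0L]
  starts <- seq(1L, n - W + 1L, by = S)
  out <- data.frame(window_time = (starts - 1 + (W - 1) / 2) / sampling_rate,
                    max_corr = NA_real_, lag_s = NA_real_,
                    lag_samples = NA_integer_, flagged = FALSE)
  for (wi in seq_along(starts)) {
    r <- window_xcorr(a, b, starts[wi], W, lags, n)
    out$max_corr[wi] <- r$r
    out$lag_samples[wi] <- r$lag
    out$lag_s[wi] <- r$lag / sampling_rate
    out$flagged[wi] <- r$flagged
  }
  attr(out, "params") <- list(window = W, step = S, max_lag = L)
  out
}

#' Autocorrelation of one trace over sliding windows
#'
#' Same machinery as [sliding_xcorr()] with the trace against itself and
#' lag 0 excluded from the argmax (where it would trivially win).
#'
#' @inheritParams sliding_xcorr
#' @param x numeric trace.
#' @return See [sliding_xcorr()].
#' @export
autocorr <- function(x, sampling_rate, window_s = NULL, step_s = NULL,
                     max_lag_s = NULL) {
  sliding_xcorr(x, x, sampling_rate, window_s, step_s, max_lag_s,
                exclude_zero_lag = TRUE)
}

#' Sliding-window cross-correlation matrices over all cell pairs
#'
#' Each unordered pair is computed once; the mirrored entry gets the same
#' maximum correlation and the negated lag, so `max_corr` is exactly
#' symmetric and `lag_at_max` exactly antisymmetric per window. The
#' diagonal is correlation 1 at lag 0.
#'
#' @param traces a `TraceSet` with `dff` computed.
#' @inheritParams sliding_xcorr
#' @return An `XCorrResult`: list with `max_corr` and `lag_at_max`
#'   (`[window, cell, cell]` arrays, lags in seconds), `window_times`,
#'   `cell_ids`, `params`.
#' @export
xcorr_matrices <- function(traces, window_s = NULL, step_s = NULL,
                           max_lag_s = NULL) {
  if (is.null(traces$dff))
    fp_error("fluopipe_stage_error", "stage not run: compute_dff")
  fs <- 1 / traces$sampling_interval
  nk <- ncol(traces$dff)
  probe <- sliding_xcorr(traces$dff[, 1], traces$dff[, 1], fs,
                         window_s, step_s, max_lag_s)
  nw <- nrow(probe)
  mc <- array(NA_real_, c(nw, nk, nk))
  lg <- array(NA_real_, c(nw, nk, nk))
  for (k in seq_len(nk)) { mc[, k, k] <- 1; lg[, k, k] <- 0 }
  if (nk >= 2) {
    for (i in 1:(nk - 1)) for (j in (i + 1):nk) {
      r <- sliding_xcorr(traces$dff[, i], traces$dff[, j], fs,
                         window_s, step_s, max_lag_s)
      mc[, i, j] <- mc[, j, i] <- r$max_corr
      lg[, i, j] <- r$lag_s
      lg[, j, i] <- -r$lag_s
    }
  }
  structure(list(max_corr = mc, lag_at_max = lg,
                 window_times = probe$window_time,
                 cell_ids = traces$roi_ids,
                 params = attr(probe, "params")),
            class = "XCorrResult")
}
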