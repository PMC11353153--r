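# Continuous wavelet transform (complex Morlet) and physiological band
# summaries for calcium traces and ephys.

#' Default physiological frequency bands
#'
#' Delta 0.5-4 Hz, theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz. Band
#' intervals are half-open `[f_low, f_high)` so the four bands tile
#' 0.5-30 Hz without double-counting the shared endpoints.
#'
#' @return data.frame with columns `name`, `f_low`, `f_high`.
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta"),
             f_low = c(0.5, 4, 8, 13),
             f_high = c(4, 8, 13, 30),
             stringsAsFactors = FALSE)
}

resolve_band <- function(band) {
  if (is.character(band)) {
    db <- default_bands()
    i <- match(band, db$name)
    if (is.na(i)) fp_error("fluopipe_argument_error",
                           sprintf("unknown band '%s'", band))
    return(db[i, ])
  }
  band <- as.list(band)
  if (is.null(band$f_low) || is.null(band$f_high) ||
      !(band$f_low > 0) || !(band$f_low < band$f_high))
    fp_error("fluopipe_argument_error", "band needs 0 < f_low < f_high")
  band$name <- band$name %||% "custom"
  band
}

#' Continuous wavelet transform with a complex Morlet wavelet
#'
#' Computes the CWT on a log-spaced frequency grid via FFT convolution. The
#' wavelet is the analytic Morlet with centre-frequency parameter
#' `omega0 = 6`; each scale is L1-normalized (and doubled for the analytic
#' one-sided spectrum) so that a unit-amplitude sinusoid yields a ridge of
#' magnitude ~1 at its own frequency regardless of scale — magnitudes are
#' therefore directly comparable across frequencies. The signal mean is
#' removed before transforming.
#'
#' @param x numeric time series (no `NA`s; interpolate beforehand).
#' @param sampling_rate Hz.
#' @param f_min,f_max frequency grid limits in Hz; `f_max` must be below
#'   the Nyquist frequency.
#' @param n_freqs number of log-spaced grid frequencies (default 64).
#' @param omega0 Morlet centre-frequency parameter (default 6, the standard
#'   time-frequency resolution trade-off).
#' @return A `WaveletResult`: list with `coefficients` (complex
#'   `[frequency, time]`), `frequencies` (Hz, increasing), `magnitude`
#'   (`|coefficients|`), `coi` (logical matrix, `TRUE` where the sample is
#'   outside the cone of influence, i.e. trustworthy), `normalization`,
#'   `omega0`, `sampling_rate`, `time`.
#' @export
cwt_morlet <- function(x, sampling_rate, f_min = 0.5, f_max = 30,
                       n_freqs = 64, omega0 = 6) {
  if (anyNA(x))
    fp_error("fluopipe_argument_error", "signal contains NA; interpolate first")
  if (f_max >= sampling_rate / 2)
    fp_error("fluopipe_argument_error",
             sprintf("f_max %.3g Hz >= Nyquist %.3g Hz", f_max,
                     sampling_rate / 2))
  if (!(f_min > 0 && f_min < f_max))
    fp_error("fluopipe_argument_error", "need 0 < f_min < f_max")
  n <- length(x)
  if (n < 2 * sampling_rate / f_min)
    warning("signal shorter than 2 periods of f_min: edge-dominated transform")
  freqs <- exp(seq(log(f_min), log(f_max), length.out = n_freqs))
  m <- 2^ceiling(log2(2 * n))                 # zero-pad against wraparound
  X <- fft(c(x - mean(x), rep(0, m - n)))
  omega <- 2 * pi * sampling_rate * (0:(m - 1)) / m
  pos <- seq_len(m) <= (m / 2 + 1)            # analytic: positive freqs only
  coef <- matrix(0 + 0i, n_freqs, n)
  coi_mat <- matrix(FALSE, n_freqs, n)
  tt <- (seq_len(n) - 1) / sampling_rate
  total_t <- (n - 1) / sampling_rate
  for (i in seq_len(n_freqs)) {
    s <- omega0 / (2 * pi * freqs[i])         # scale in seconds
    K <- numeric(m)
    K[pos] <- 2 * exp(-((s * omega[pos] - omega0)^2) / 2)
    coef[i, ] <- fft(X * K, inverse = TRUE)[seq_len(n)] / m
    coi_mat[i, ] <- pmin(tt, total_t - tt) >= sqrt(2) * s
  }
  structure(list(coefficients = coef, frequencies = freqs,
                 magnitude = Mod(coef), coi = coi_mat,
                 normalization = "L1", omega0 = omega0,
                 sampling_rate = sampling_rate, time = tt, source = NULL),
            class = "WaveletResult")
}

#' @export
print.WaveletResult <- function(x, ...) {
  cat(sprintf("<WaveletResult> %d freqs (%.3g-%.3g Hz) x %d samples at %g Hz\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              length(x$time), x$sampling_rate))
  invisible(x)
}

#' Band power time series from a wavelet transform
#'
#' Sums the normalized wavelet magnitudes over the grid frequencies inside
#' the half-open band `[f_low, f_high)`.
#'
#' @param wavelet a `WaveletResult`.
#' @param band a band name (`"delta"`, `"theta"`, `"alpha"`, `"beta"`) or a
#'   list with `f_low`, `f_high`.
#' @return Numeric vector `P(t)` on the wavelet's time base.
#' @export
band_power <- function(wavelet, band) {
  b <- resolve_band(band)
  sel <- wavelet$frequencies >= b$f_low & wavelet$frequencies < b$f_high
  if (!any(sel))
    fp_error("fluopipe_argument_error",
             sprintf("band [%g, %g) Hz overlaps no grid frequency",
                     b$f_low, b$f_high))
  colSums(wavelet$magnitude[sel, , drop = FALSE])
}

#' Joint wavelet analysis of all cells and the ephys recording
#'
#' Runs [cwt_morlet()] on every cell's dF/F0 trace (imaging time base) and,
#' when provided, on the ephys samples (ephys time base), and summarizes
#' both into per-band power time series aligned to the shared t = 0.
#'
#' @param traces a `TraceSet` with `dff` computed.
#' @param ephys optional `EphysRecording` from [load_ephys()].
#' @param bands data.frame of bands as from [default_bands()].
#' @param f_min,f_max,n_freqs,omega0 passed to [cwt_morlet()]; `f_max` is
#'   clamped below the imaging Nyquist with a warning if necessary.
#' @param keep_wavelets keep the full complex transforms (memory-heavy).
#' @return A `SessionSpectra` list: `band_power` (`[cell, band, time]`),
#'   `cell_ids`, `time`, `bands`, `ephys_band_power` (`[band, time]` or
#'   `NULL`), `ephys_time`, and optionally `wavelets`.
#' @export
analyze_session <- function(traces, ephys = NULL, bands = default_bands(),
                            f_min = 0.5, f_max = 30, n_freqs = 64,
                            omega0 = 6, keep_wavelets = FALSE) {
  if (is.null(traces$dff))
    fp_error("fluopipe_stage_error", "stage not run: compute_dff")
  fs <- 1 / traces$sampling_interval
  fmax_i <- f_max
  if (fmax_i >= fs / 2) {
    fmax_i <- 0.45 * fs
    warning(sprintf("f_max clamped to %.3g Hz below the imaging Nyquist", fmax_i))
  }
  grid <- exp(seq(log(f_min), log(fmax_i), length.out = n_freqs))
  covered <- vapply(seq_len(nrow(bands)), function(b)
    any(grid >= bands$f_low[b] & grid < bands$f_high[b]), TRUE)
  if (!all(covered)) {
    warning(sprintf("band(s) %s above the usable grid: dropped",
                    paste(bands$name[!covered], collapse = ", ")))
    bands <- bands[covered, , drop = FALSE]
  }
  nk <- ncol(traces$dff)
  if (nk == 0L) {
    warning("no valid cells to analyze")
    return(structure(list(band_power = array(0, c(0, nrow(bands), 0)),
                          cell_ids = integer(0), time = numeric(0),
                          bands = bands, ephys_band_power = NULL,
                          ephys_time = NULL),
                     class = "SessionSpectra"))
  }
  nt <- nrow(traces$dff)
  bp <- array(NA_real_, c(nk, nrow(bands), nt),
              dimnames = list(NULL, bands$name, NULL))
  wl <- if (keep_wavelets) vector("list", nk) else NULL
  for (k in seq_len(nk)) {
    xk <- traces$dff[, k]
    if (anyNA(xk)) next
    w <- cwt_morlet(xk, fs, f_min, fmax_i, n_freqs, omega0)
    for (b in seq_len(nrow(bands)))
      bp[k, b, ] <- band_power(w, bands[b, ])
    if (keep_wavelets) wl[[k]] <- w
  }
  eph_bp <- NULL; eph_t <- NULL
  if (!is.null(ephys)) {
    fmax_e <- min(f_max, 0.45 * ephys$sampling_rate)
    we <- cwt_morlet(ephys$samples, ephys$sampling_rate, f_min, fmax_e,
                     n_freqs, omega0)
    eph_bp <- t(vapply(seq_len(nrow(bands)),
                       function(b) band_power(we, bands[b, ]),
                       numeric(length(we$time))))
    rownames(eph_bp) <- bands$name
    eph_t <- we$time + ephys$t0_offset
  }
  structure(list(band_power = bp, cell_ids = traces$roi_ids,
                 time = traces$time, bands = bands,
                 ephys_band_power = eph_bp, ephys_time = eph_t,
                 wavelets = wl),
            class = "SessionSpectra")
}
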