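# Ground-truthed synthetic data: two-channel movies (frame or line scan)
# with disk-shaped somata carrying oscillatory dF/F0 dynamics, and a coupled
# LFP-like ephys trace. Every fixture in the test suite is regenerated from
# a seed; nothing is stored.

# low-pass-filtered standardized noise used as a slow amplitude envelope
slow_envelope <- function(n, fs, bw) {
  x <- rnorm(n)
  if (bw < fs / 2) {
    flt <- signal::butter(2, bw / (fs / 2), type = "low")
    x <- signal::filtfilt(flt, x)
  }
  s <- sd(x)
  if (s > 0) x / s else x * 0
}

# disk pixel set around an integer centre
disk_pixels <- function(centre, radius, shape) {
  r0 <- max(1L, floor(centre[1] - radius)); r1 <- min(shape[1], ceiling(centre[1] + radius))
  c0 <- max(1L, floor(centre[2] - radius)); c1 <- min(shape[2], ceiling(centre[2] + radius))
  gr <- expand.grid(row = r0:r1, col = c0:c1)
  inside <- (gr$row - centre[1])^2 + (gr$col - centre[2])^2 <= radius^2
  as.matrix(gr[inside, , drop = FALSE])
}

#' Generate a synthetic two-channel calcium imaging movie
#'
#' Emulates the measurement regime of the real acquisitions: disk-shaped
#' somata on a noisy background, green (calcium indicator) intensity
#' oscillating per cell as `baseline * (1 + amp * env(t) * sin(2 pi f t +
#' phi))`, and a static red (astrocyte marker) channel in which astrocytes
#' carry a high red/green ratio and neurons a low one. Cells are placed on
#' a jittered grid so they never touch. Line mode renders a scan path that
#' crosses each cell twice (a horizontal and a vertical chord, mirroring
#' the inertia-compensating double crossing used in line-scan recordings)
#' and also returns a clean reference field image for ROI detection.
#'
#' @param n_cells number of somata (default 20).
#' @param fov `c(height, width)` in pixels (default 128 x 128).
#' @param radius soma radius in px (default 6, ~113 px area).
#' @param fs sampling rate in Hz: frames/s in frame mode (default 68),
#'   lines/s in line mode.
#' @param duration recording length in seconds (default 30).
#' @param baseline green-channel soma baseline intensity (default 100 AU).
#' @param background off-cell intensity in both channels (default 10 AU).
#' @param amp per-cell dF/F0 oscillation amplitude, scalar or vector
#'   (default 0.5).
#' @param freqs per-cell oscillation frequencies in Hz; default drawn
#'   log-uniformly between 0.8 and 12 Hz.
#' @param noise_sd per-pixel Gaussian noise SD (default 10 AU, i.e. SNR =
#'   baseline*amp/noise_sd = 5 at the defaults).
#' @param astro_frac fraction of cells planted as astrocytes (default 0.35).
#' @param astro_ratio,neuron_ratio planted red/green intensity ratios
#'   (defaults 3.0 and 0.2, both a factor >= 2 beyond the 1.5/0.75 decision
#'   boundaries).
#' @param env_bw amplitude-envelope bandwidth in Hz; 0 (default) means a
#'   constant-amplitude sinusoid.
#' @param env_depth envelope modulation depth in `[0, 1)` (default 0).
#' @param shared_env_cells integer ids of cells sharing one common envelope
#'   and phase (the "network source" that [make_ephys()] couples to).
#' @param mode `"frame"` or `"line"`.
#' @param seed RNG seed; the movie is bit-reproducible from it.
#' @return List with `session` (an `ImagingSession`; in line mode it also
#'   carries `reference_image`, a noisy snapshot of the field) and `truth`
#'   (a `GroundTruth` list: `cells` data.frame with centres, radii, labels,
#'   frequencies, amplitudes, ratios, phases; `envelopes` matrix
#'   `[time, cell]`; generator parameters; `seed`).
#' @export
make_movie <- function(n_cells = 20, fov = c(128, 128), radius = 6,
                       fs = 68, duration = 30, baseline = 100,
                       background = 10, amp = 0.5, freqs = NULL,
                       noise_sd = 10, astro_frac = 0.35,
                       astro_ratio = 3.0, neuron_ratio = 0.2,
                       env_bw = 0, env_depth = 0,
                       shared_env_cells = integer(0),
                       mode = c("frame", "line"), seed = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  if (any(!is.null(freqs)) && any(freqs >= fs / 2))
    fp_error("fluopipe_generation_error", "planted frequency at or above Nyquist")
  # jittered-grid placement: guarantees non-touching disks or fails loudly
  ngc <- ceiling(sqrt(n_cells)); ngr <- ceiling(n_cells / ngc)
  pitch <- c(fov[1] / ngr, fov[2] / ngc)
  if (any(pitch < 2 * radius + 4))
    fp_error("fluopipe_generation_error",
             sprintf("%d disks of radius %g do not fit a %dx%d field",
                     n_cells, radius, fov[1], fov[2]))
  jit <- pmax(0, (pitch - 2 * radius - 4) / 2)
  centres <- t(vapply(seq_len(n_cells) - 1L, function(k) {
    gr <- k %/% ngc; gc <- k %% ngc
    c(round((gr + 0.5) * pitch[1] + runif(1, -jit[1], jit[1])),
      round((gc + 0.5) * pitch[2] + runif(1, -jit[2], jit[2])))
  }, numeric(2)))
  n_astro <- round(astro_frac * n_cells)
  labels <- sample(c(rep("astrocyte", n_astro),
                     rep("neuron", n_cells - n_astro)))
  freqs <- if (is.null(freqs)) exp(runif(n_cells, log(0.8), log(12)))
           else rep_len(freqs, n_cells)
  amp <- rep_len(amp, n_cells)
  phases <- runif(n_cells, 0, 2 * pi)
  nt <- round(duration * fs)
  tt <- (seq_len(nt) - 1) / fs
  env <- matrix(1, nt, n_cells)
  if (env_depth > 0 && env_bw > 0) {
    shared <- NULL
    if (length(shared_env_cells)) shared <- slow_envelope(nt, fs, env_bw)
    for (k in seq_len(n_cells)) {
      e <- if (k %in% shared_env_cells) shared else slow_envelope(nt, fs, env_bw)
      env[, k] <- pmax(0.05, 1 + env_depth * e)
    }
    if (length(shared_env_cells))
      phases[shared_env_cells] <- phases[shared_env_cells[1]]
  }
  ratios <- ifelse(labels == "astrocyte", astro_ratio, neuron_ratio)
  pix <- lapply(seq_len(n_cells), function(k)
    disk_pixels(centres[k, ], radius, fov))
  dyn <- vapply(seq_len(n_cells), function(k)
    baseline * (1 + amp[k] * env[, k] * sin(2 * pi * freqs[k] * tt + phases[k])),
    numeric(nt))
  truth <- structure(list(
    cells = data.frame(id = seq_len(n_cells),
                       row = centres[, 1], col = centres[, 2],
                       radius = radius, label = labels, freq = freqs,
                       amp = amp, phase = phases, red_green_ratio = ratios,
                       stringsAsFactors = FALSE),
    envelopes = env, time = tt, fs = fs, baseline = baseline,
    background = background, noise_sd = noise_sd, fov = fov,
    shared_env_cells = shared_env_cells, mode = mode, seed = seed
  ), class = "GroundTruth")

  if (mode == "frame") {
    npix <- fov[1] * fov[2]
    G <- matrix(background, nt, npix)
    Rp <- rep(background, npix)
    for (k in seq_len(n_cells)) {
      lin <- (pix[[k]][, 2] - 1L) * fov[1] + pix[[k]][, 1]
      G[, lin] <- dyn[, k]
      Rp[lin] <- ratios[k] * baseline
    }
    G <- round(pmax(G + rnorm(nt * npix, sd = noise_sd), 0))
    R <- round(pmax(matrix(Rp, nt, npix, byrow = TRUE) +
                      rnorm(nt * npix, sd = noise_sd), 0))
    stack <- array(0, c(nt, fov[1], fov[2], 2))
    stack[, , , 1] <- G
    stack[, , , 2] <- R
    session <- new_imaging_session(stack, sampling_interval = 1 / fs,
                                   channel_roles = c(green = 1, red = 2),
                                   scan_mode = "frame",
                                   source_path = sprintf("synthetic(seed=%d)", seed))
  } else {
    # scan path: per cell one horizontal then one vertical chord through the
    # centre (two crossings per soma), extended past the soma edge so the
    # path also samples off-cell background
    reach <- radius + 4
    segs <- lapply(seq_len(n_cells), function(k) {
      ctr <- centres[k, ]
      cols <- max(1, ctr[2] - reach):min(fov[2], ctr[2] + reach)
      rows <- max(1, ctr[1] - reach):min(fov[1], ctr[1] + reach)
      rbind(cbind(rep(ctr[1], length(cols)), cols),
            cbind(rows, rep(ctr[2], length(rows))))
    })
    path <- do.call(rbind, segs)
    L <- nrow(path)
    owner <- rep(0L, L)
    for (k in seq_len(n_cells)) {
      inside <- (path[, 1] - centres[k, 1])^2 +
                (path[, 2] - centres[k, 2])^2 <= radius^2
      owner[inside] <- k
    }
    G <- matrix(background, nt, L)
    Rrow <- rep(background, L)
    for (k in seq_len(n_cells)) {
      sel <- owner == k
      G[, sel] <- dyn[, k]
      Rrow[sel] <- ratios[k] * baseline
    }
    G <- round(pmax(G + rnorm(nt * L, sd = noise_sd), 0))
    R <- round(pmax(matrix(Rrow, nt, L, byrow = TRUE) +
                      rnorm(nt * L, sd = noise_sd), 0))
    stack <- array(0, c(nt, 1, L, 2))
    stack[, 1, , 1] <- G
    stack[, 1, , 2] <- R
    session <- new_imaging_session(stack, sampling_interval = 1 / fs,
                                   channel_roles = c(green = 1, red = 2),
                                   scan_mode = "line", line_path = path,
                                   field_dim = fov,
                                   source_path = sprintf("synthetic(seed=%d)", seed))
    refG <- matrix(background, fov[1], fov[2])
    refR <- refG
    for (k in seq_len(n_cells)) {
      refG[pix[[k]]] <- baseline
      refR[pix[[k]]] <- ratios[k] * baseline
    }
    session$reference_image <- list(
      green = round(pmax(refG + rnorm(fov[1] * fov[2], sd = noise_sd / 2), 0)),
      red = round(pmax(refR + rnorm(fov[1] * fov[2], sd = noise_sd / 2), 0)))
  }
  list(session = session, truth = truth)
}

#' Generate an LFP-like ephys trace coupled to chosen cells
#'
#' The trace is the sum of the coupled cells' oscillatory components
#' (frequency, phase and amplitude envelope taken from the ground truth)
#' plus 1/f background noise, padded on both sides of the imaging interval.
#' A tagged marker is written at the imaging-segment start.
#'
#' @param truth a `GroundTruth` from [make_movie()].
#' @param fs_native native sampling rate in Hz (default 10000); decimation
#'   in [load_ephys()] brings it down by 10.
#' @param coupled integer ids of cells whose components enter the trace
#'   (default: the truth's `shared_env_cells`, else cell 1).
#' @param coupling amplitude per coupled component (default 1).
#' @param noise_scale 1/f noise RMS relative to the summed component RMS
#'   (default 0.3).
#' @param pad_s seconds of recording before and after the imaging interval
#'   (default 5).
#' @param marker_tag tag placed at the segment start (default `"seg1"`).
#' @param seed RNG seed (default `truth$seed + 1000`).
#' @return A `RawEphys` list (`samples`, `sampling_rate`, `t_start = 0`,
#'   `markers`) ready for [write_ephys_text()] or [load_ephys()].
#' @export
make_ephys <- function(truth, fs_native = 10000, coupled = NULL,
                       coupling = 1, noise_scale = 0.3, pad_s = 5,
                       marker_tag = "seg1", seed = NULL) {
  set.seed(seed %||% (truth$seed + 1000L))
  coupled <- coupled %||%
    (if (length(truth$shared_env_cells)) truth$shared_env_cells else 1L)
  dur <- length(truth$time) / truth$fs
  n <- round((dur + 2 * pad_s) * fs_native)
  tt <- (seq_len(n) - 1) / fs_native - pad_s      # imaging starts at t = 0 here
  x <- numeric(n)
  coupling <- rep_len(coupling, length(coupled))
  for (i in seq_along(coupled)) {
    k <- coupled[i]
    envk <- approx(truth$time, truth$envelopes[, k], xout = tt,
                   rule = 2)$y
    x <- x + coupling[i] * envk *
      sin(2 * pi * truth$cells$freq[k] * tt + truth$cells$phase[k])
  }
  # 1/f noise via spectral shaping of white noise
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))                        # avoid division by zero at DC
  W <- W / sqrt(pmin(f, n - f + 1))
  pink <- Re(fft(W, inverse = TRUE)) / n
  xr <- sqrt(mean(x^2))
  if (sd(pink) > 0 && xr > 0)
    pink <- pink / sd(pink) * noise_scale * xr
  # recording clock starts at 0; the imaging segment begins at pad_s and is
  # tagged by the marker
  structure(list(samples = x + pink, sampling_rate = fs_native,
                 t_start = 0,
                 markers = data.frame(time = pad_s, tag = marker_tag,
                                      stringsAsFactors = FALSE)),
            class = "RawEphys")
}
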