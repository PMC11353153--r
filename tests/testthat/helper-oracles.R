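# Shared fixtures and independent oracles. Fixtures are generated in code;
# nothing is stored on disk.

# --- independent oracles -----------------------------------------------------

# dominant frequency by raw periodogram (FFT), independent of the CWT path
fft_peak_freq <- function(x, fs) {
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))[2:floor(n / 2)]
  freqs <- (1:(floor(n / 2) - 1)) * fs / n
  freqs[which.max(sp)]
}

# Otsu by exhaustive sweep of candidate thresholds maximizing between-class
# variance (brute force; independent of EBImage)
otsu_bruteforce <- function(img) {
  v <- as.numeric(img)
  cand <- seq(min(v), max(v), length.out = 256)
  score <- vapply(cand, function(th) {
    lo <- v[v < th]; hi <- v[v >= th]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) * length(hi) * (mean(lo) - mean(hi))^2
  }, 0)
  # between-class variance is flat across the empty gap between modes:
  # report the plateau midpoint
  mean(cand[score >= max(score) * (1 - 1e-9)])
}

# all-lag Pearson correlation of one window, written independently of the
# package's window_xcorr (same tie-break convention: smallest |lag|, then
# negative first)
bruteforce_xcorr <- function(a, b, start, W, L, exclude_zero = FALSE) {
  n <- length(a)
  lags <- (-L):L
  if (exclude_zero) lags <- lags[lags != 0]
  rs <- sapply(lags, function(l) {
    if (start + l < 1 || start + W - 1 + l > n) return(NA_real_)
    stats::cor(a[start:(start + W - 1)], b[(start:(start + W - 1)) + l])
  })
  mx <- max(rs, na.rm = TRUE)
  cand <- lags[!is.na(rs) & rs >= mx - 1e-12]
  cand <- cand[order(abs(cand), cand)]
  list(max_corr = mx, lag = cand[1])
}

# --- fixture builders --------------------------------------------------------

disk_px <- function(centre, radius) {
  gr <- expand.grid(row = (centre[1] - radius):(centre[1] + radius),
                    col = (centre[2] - radius):(centre[2] + radius))
  as.matrix(gr[(gr$row - centre[1])^2 + (gr$col - centre[2])^2 <= radius^2, ])
}

# compact blob of an exact pixel count (pixels of a disk nearest the centre)
blob_px <- function(centre, area) {
  r <- ceiling(sqrt(area))
  gr <- expand.grid(row = (centre[1] - r):(centre[1] + r),
                    col = (centre[2] - r):(centre[2] + r))
  d <- (gr$row - centre[1])^2 + (gr$col - centre[2])^2
  as.matrix(gr[order(d)[1:area], c("row", "col")])
}

ellipse_px <- function(centre, a, b) {
  gr <- expand.grid(row = (centre[1] - ceiling(a)):(centre[1] + ceiling(a)),
                    col = (centre[2] - ceiling(b)):(centre[2] + ceiling(b)))
  keep <- ((gr$row - centre[1]) / a)^2 + ((gr$col - centre[2]) / b)^2 <= 1
  as.matrix(gr[keep, ])
}

# build an ROISet directly from pixel sets (bypasses detection)
roiset_from_pixels <- function(pixlist, shape) {
  rois <- lapply(seq_along(pixlist), function(k)
    fluopipe:::roi_record(k, pixlist[[k]], shape))
  lab <- matrix(0L, shape[1], shape[2])
  for (r in rois) lab[r$pixels] <- r$id
  fluopipe:::new_roiset(lab, rois, shape)
}

# nearest planted cell for each detected ROI (by centroid distance)
match_rois_to_truth <- function(roiset, truth) {
  cent <- t(vapply(roiset$rois, function(r) r$centroid, numeric(2)))
  vapply(seq_len(nrow(cent)), function(i)
    which.min((truth$cells$row - cent[i, 1])^2 +
              (truth$cells$col - cent[i, 2])^2), 0L)
}

# tiny constant-value session (frame mode)
constant_session <- function(value = 5, nf = 4, h = 16, w = 16, nc = 1,
                             dt = 0.1) {
  new_imaging_session(array(value, c(nf, h, w, nc)), sampling_interval = dt,
                      channel_roles = if (nc == 2) c(green = 1, red = 2)
                                      else c(green = 1))
}

# small analyzed state used by session/report tests
small_state <- function(seed = 7, n_cells = 3, fs = 20, duration = 10,
                        with_ephys = FALSE) {
  mv <- make_movie(n_cells = n_cells, fov = c(64, 64), radius = 6, fs = fs,
                   duration = duration, freqs = rep(2, n_cells), seed = seed)
  s <- mv$session
  refG <- make_reference(s, method = "average", channel = "green")
  refR <- make_reference(s, method = "average", channel = "red")
  rs <- extract_rois(threshold_reference(refG, "otsu"), 30, 2000)
  rs <- classify_cells(s, rs, refG, refR)
  tr <- compute_dff(compute_F(s, rs), background = "auto")
  eph <- NULL
  if (with_ephys) {
    eph <- load_ephys(make_ephys(mv$truth, fs_native = 1000), s,
                      marker = "seg1")
  }
  sp <- suppressWarnings(analyze_session(tr, eph))
  list(session = s, rois = rs, traces = tr, spectra = sp, ephys = eph,
       truth = mv$truth)
}
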