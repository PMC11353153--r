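# Session input/output: imaging movies, ephys recordings, saved analyses.

#' Construct an imaging session
#'
#' Low-level constructor for the container holding a fluorescence movie.
#' Most users obtain sessions from [load_image()] or [make_movie()].
#'
#' @param stack numeric 4-d array indexed `[frame, row, col, channel]`,
#'   arbitrary fluorescence units.
#' @param sampling_interval seconds per frame (frame mode) or per scanned
#'   line (line mode); must be positive.
#' @param channel_roles named integer vector mapping roles to channel
#'   indices, e.g. `c(green = 1, red = 2)`. Green is the calcium indicator,
#'   red the astrocyte marker.
#' @param scan_mode `"frame"` for full-frame raster movies, `"line"` for
#'   line-scan data where the stack is `[line, 1, path_position, channel]`.
#' @param line_path integer matrix with columns `row`, `col`: the ordered
#'   pixel coordinates of the scan path in the imaged field (line mode only).
#' @param field_dim `c(height, width)` of the imaged field; defaults to the
#'   stack's spatial dimensions. In line mode it describes the field the
#'   `line_path` coordinates refer to.
#' @param source_path provenance string.
#' @return An object of class `ImagingSession`: a list with elements `stack`,
#'   `n_frames`, `height`, `width`, `n_channels`, `channel_roles`,
#'   `scan_mode`, `sampling_interval`, `line_path`, `field_dim`,
#'   `source_path`.
#' @export
new_imaging_session <- function(stack, sampling_interval = 1.0,
                                channel_roles = c(green = 1),
                                scan_mode = c("frame", "line"),
                                line_path = NULL, field_dim = NULL,
                                source_path = "<memory>") {
  scan_mode <- match.arg(scan_mode)
  if (length(dim(stack)) == 3L) dim(stack) <- c(dim(stack), 1L)
  if (length(dim(stack)) != 4L)
    fp_error("fluopipe_argument_error", "stack must be [frame, row, col, channel]")
  d <- dim(stack)
  if (d[1] < 1L) fp_error("fluopipe_argument_error", "need at least one frame")
  if (!(d[4] %in% 1:2))
    fp_error("fluopipe_format_error",
             sprintf("unsupported channel count: %d (1 or 2 supported)", d[4]))
  if (!is.numeric(sampling_interval) || sampling_interval <= 0)
    fp_error("fluopipe_argument_error", "sampling_interval must be > 0")
  field_dim <- field_dim %||% c(d[2], d[3])
  if (scan_mode == "line") {
    if (is.null(line_path) || nrow(line_path) == 0L)
      fp_error("fluopipe_argument_error", "line mode requires a non-empty line_path")
    line_path <- cbind(row = as.integer(line_path[, 1]),
                       col = as.integer(line_path[, 2]))
    if (any(line_path[, 1] < 1L | line_path[, 1] > field_dim[1] |
            line_path[, 2] < 1L | line_path[, 2] > field_dim[2]))
      fp_error("fluopipe_argument_error", "line_path coordinates outside the field")
    if (nrow(line_path) != d[3])
      fp_error("fluopipe_argument_error",
               "line-mode stack column count must equal line_path length")
  } else if (!is.null(line_path)) {
    fp_error("fluopipe_argument_error", "line_path given for a frame-scan session")
  }
  roles <- channel_roles[!is.na(channel_roles)]
  if (any(roles < 1 | roles > d[4]))
    fp_error("fluopipe_argument_error", "channel_roles index outside stack channels")
  structure(list(
    stack = stack, n_frames = d[1], height = d[2], width = d[3],
    n_channels = d[4], channel_roles = roles, scan_mode = scan_mode,
    sampling_interval = sampling_interval, line_path = line_path,
    field_dim = field_dim, source_path = source_path
  ), class = "ImagingSession")
}

#' @export
print.ImagingSession <- function(x, ...) {
  cat(sprintf("<ImagingSession> %d frames of %dx%d, %d channel(s), %s scan, dt = %g s\n",
              x$n_frames, x$height, x$width, x$n_channels, x$scan_mode,
              x$sampling_interval))
  invisible(x)
}

#' Session duration in seconds
#' @param session an `ImagingSession`.
#' @return Duration in seconds (`n_frames * sampling_interval`).
#' @export
session_duration <- function(session) session$n_frames * session$sampling_interval

#' Time axis of a session
#' @param session an `ImagingSession`.
#' @return Numeric vector of frame times; frame i is at `(i - 1) * dt`.
#' @export
session_time <- function(session)
  (seq_len(session$n_frames) - 1) * session$sampling_interval

#' Load a multipage TIFF movie
#'
#' Reads a multipage grayscale TIFF into an [new_imaging_session()] container.
#' Two-channel recordings are stored either with alternating pages
#' (G, R, G, R, ...) or as two stacked halves; both dialects are supported.
#'
#' @param path path to the TIFF file.
#' @param n_channels 1 or 2.
#' @param channel_roles named channel map, defaults to
#'   `c(green = 1)` or `c(green = 1, red = 2)` depending on `n_channels`.
#' @param interleave page layout for 2-channel files: `"alternate"`
#'   (default) or `"split"` (first half channel 1).
#' @param sampling_interval seconds per frame. TIFF carries no timing
#'   metadata in this pipeline, so a missing value falls back to 1.0 s.
#' @param scan_mode,line_path,field_dim see [new_imaging_session()].
#' @return An `ImagingSession`.
#' @export
load_image <- function(path, n_channels = 1L, channel_roles = NULL,
                       interleave = c("alternate", "split"),
                       sampling_interval = NULL,
                       scan_mode = "frame", line_path = NULL,
                       field_dim = NULL) {
  interleave <- match.arg(interleave)
  if (!file.exists(path))
    fp_error("fluopipe_load_error", sprintf("no such file: %s", path))
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) fp_error(
      "fluopipe_load_error",
      sprintf("cannot read TIFF '%s' (corrupt page?): %s", path, conditionMessage(e))
    )
  )
  if (is.matrix(pages)) pages <- list(pages)
  if (length(pages) == 0L)
    fp_error("fluopipe_load_error", sprintf("no pages in %s", path))
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    fp_error("fluopipe_load_error", sprintf("inconsistent page dimensions in %s", path))
  n_channels <- as.integer(n_channels)
  if (n_channels > 2L)
    fp_error("fluopipe_format_error",
             sprintf("unsupported channel count: %d (1 or 2 supported)", n_channels))
  np <- length(pages)
  if (np %% n_channels != 0L)
    fp_error("fluopipe_load_error",
             sprintf("%d pages not divisible by %d channels", np, n_channels))
  nf <- np %/% n_channels
  h <- dims[1, 1]; w <- dims[2, 1]
  stack <- array(0, c(nf, h, w, n_channels))
  for (ch in seq_len(n_channels)) {
    sel <- if (n_channels == 1L) seq_len(np)
           else if (interleave == "alternate") seq(ch, np, by = n_channels)
           else ((ch - 1L) * nf + 1L):(ch * nf)
    for (i in seq_along(sel)) stack[i, , , ch] <- pages[[sel[i]]]
  }
  channel_roles <- channel_roles %||%
    (if (n_channels == 2L) c(green = 1L, red = 2L) else c(green = 1L))
  new_imaging_session(stack,
                      sampling_interval = sampling_interval %||% 1.0,
                      channel_roles = channel_roles, scan_mode = scan_mode,
                      line_path = line_path, field_dim = field_dim,
                      source_path = path)
}

#' Write a session's movie to a multipage TIFF
#'
#' Intensities are rounded and stored as 16-bit pages; two-channel stacks
#' are written with alternating pages (G, R, G, R, ...).
#'
#' @param session an `ImagingSession`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image <- function(session, path) {
  mx <- 65535
  pages <- vector("list", session$n_frames * session$n_channels)
  k <- 0L
  for (t in seq_len(session$n_frames)) {
    for (ch in seq_len(session$n_channels)) {
      k <- k + 1L
      pg <- pmin(pmax(round(session$stack[t, , , ch]), 0), mx)
      pages[[k]] <- matrix(pg / mx, nrow = dim(session$stack)[2],
                           ncol = dim(session$stack)[3])
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

SESSION_MAGIC <- "fluopipe-session"
SESSION_VERSION <- 1L

#' Save / load a full analysis state
#'
#' The session container is an open, versioned, lossless serialization of the
#' complete analysis state (movie, ROIs, labels, traces, spectra, synchrony
#' matrices). `save_session()` then `load_session()` reproduces every stored
#' field bit-exactly.
#'
#' @param state named list of analysis products; conventional element names
#'   are `session`, `ephys`, `rois`, `traces`, `spectra`, `sync`.
#' @param path file path (conventionally `.rds`).
#' @return `load_session()` returns the stored state; `save_session()`
#'   returns `path` invisibly.
#' @export
save_session <- function(state, path) {
  if (!is.list(state)) fp_error("fluopipe_argument_error", "state must be a list")
  saveRDS(list(magic = SESSION_MAGIC, version = SESSION_VERSION, state = state),
          path)
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  if (!file.exists(path))
    fp_error("fluopipe_load_error", sprintf("no such file: %s", path))
  obj <- tryCatch(readRDS(path), error = function(e)
    fp_error("fluopipe_version_error",
             sprintf("'%s' is not a fluopipe session container", path)))
  if (!is.list(obj) || !identical(obj$magic, SESSION_MAGIC))
    fp_error("fluopipe_version_error",
             sprintf("'%s' is not a fluopipe session container (bad magic)", path))
  if (!identical(obj$version, SESSION_VERSION))
    fp_error("fluopipe_version_error",
             sprintf("session schema version %s, this build reads version %d",
                     format(obj$version), SESSION_VERSION))
  obj$state
}

#' Read / write the plain-text ephys format
#'
#' The documented interchange format for electrophysiology is a text file:
#' comment headers `# sampling_rate_hz: <Hz>` and zero or more
#' `# marker: <time_s> <tag>` lines, followed by two whitespace-separated
#' columns, time (s) and voltage (arbitrary units).
#'
#' @param path file path.
#' @return `read_ephys_text()` returns a `RawEphys` list: `samples`,
#'   `sampling_rate` (Hz), `t_start` (s of the first sample), `markers`
#'   (data.frame `time`, `tag`).
#' @export
read_ephys_text <- function(path) {
  if (!file.exists(path))
    fp_error("fluopipe_load_error", sprintf("no such file: %s", path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  rate <- grep("sampling_rate_hz:", hdr, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0L)
    fp_error("fluopipe_load_error", sprintf("no samples in %s", path))
  dat <- read.table(text = body, col.names = c("time", "value"))
  sr <- if (length(rate)) as.numeric(sub(".*sampling_rate_hz:\\s*", "", rate[1]))
        else 1 / stats::median(diff(dat$time))
  mk <- grep("^#\\s*marker:", hdr, value = TRUE)
  markers <- if (length(mk)) {
    parts <- strsplit(sub("^#\\s*marker:\\s*", "", mk), "\\s+")
    data.frame(time = vapply(parts, function(p) as.numeric(p[1]), 0),
               tag = vapply(parts, function(p) paste(p[-1], collapse = " "), ""),
               stringsAsFactors = FALSE)
  } else data.frame(time = numeric(0), tag = character(0))
  structure(list(samples = dat$value, sampling_rate = sr,
                 t_start = dat$time[1], markers = markers,
                 source_path = path),
            class = "RawEphys")
}

#' @rdname read_ephys_text
#' @param ephys a `RawEphys`-style list with `samples`, `sampling_rate`,
#'   optionally `t_start` and `markers`.
#' @export
write_ephys_text <- function(ephys, path) {
  t0 <- ephys$t_start %||% 0
  tt <- t0 + (seq_along(ephys$samples) - 1) / ephys$sampling_rate
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# fluopipe-ephys v1",
               sprintf("# sampling_rate_hz: %.10g", ephys$sampling_rate)), con)
  if (!is.null(ephys$markers) && nrow(ephys$markers))
    writeLines(sprintf("# marker: %.10g %s", ephys$markers$time,
                       ephys$markers$tag), con)
  writeLines(sprintf("%.10g\t%.10g", tt, ephys$samples), con)
  invisible(path)
}

#' Locate an ephys segment by tagged marker
#'
#' Markers tag the start of each imaging session inside a continuous
#' recording; the segment runs from the marker time for one imaging duration.
#'
#' @param ephys a `RawEphys` recording with markers.
#' @param tag marker tag string to match exactly.
#' @param duration segment length in seconds (the imaging duration).
#' @return `c(start, end)` in seconds.
#' @export
find_segment_by_marker <- function(ephys, tag, duration) {
  mk <- ephys$markers
  if (is.null(mk) || nrow(mk) == 0L)
    fp_error("fluopipe_marker_error", "recording has no markers")
  hit <- which(mk$tag == tag)
  if (length(hit) == 0L)
    fp_error("fluopipe_marker_error", sprintf("marker tag '%s' not found", tag))
  if (length(hit) > 1L)
    fp_error("fluopipe_marker_error",
             sprintf("marker tag '%s' occurs %d times (at %s s)", tag,
                     length(hit), paste(mk$time[hit], collapse = ", ")))
  c(mk$time[hit], mk$time[hit] + duration)
}

#' Load and align an electrophysiological recording
#'
#' Extracts the ephys segment temporally matching the imaging session and
#' decimates it by a factor of 10 (zero-phase order-8 Chebyshev type-I
#' low-pass at 0.8x the target Nyquist, then every 10th sample), so a
#' 10 kHz recording is stored at 1 kHz alongside the movie.
#'
#' @param x path to a plain-text ephys file, or a `RawEphys` object.
#' @param session the `ImagingSession` to align with.
#' @param marker optional marker tag naming the segment start; when `NULL`
#'   the segment starts at `t_start`.
#' @param t_start segment start in seconds on the recording's clock
#'   (default: recording start).
#' @param factor decimation factor (default 10).
#' @return An `EphysRecording` list: `samples`, `sampling_rate`,
#'   `native_rate`, `t0_offset` (s of imaging frame 1 relative to sample 1,
#'   0 after alignment), `segment` (`c(start, end)` on the recording clock),
#'   `markers`, `filter` (decimation filter description).
#' @export
load_ephys <- function(x, session, marker = NULL, t_start = NULL, factor = 10L) {
  raw <- if (is.character(x)) read_ephys_text(x) else x
  dur <- session_duration(session)
  seg <- if (!is.null(marker)) find_segment_by_marker(raw, marker, dur)
         else { s0 <- t_start %||% (raw$t_start %||% 0); c(s0, s0 + dur) }
  rec_t0 <- raw$t_start %||% 0
  rec_t1 <- rec_t0 + length(raw$samples) / raw$sampling_rate
  if (seg[1] < rec_t0 - 1e-9 || seg[2] > rec_t1 + 1e-9)
    fp_error("fluopipe_alignment_error",
             sprintf("imaging interval [%g, %g] s not covered by recording [%g, %g] s",
                     seg[1], seg[2], rec_t0, rec_t1))
  i0 <- round((seg[1] - rec_t0) * raw$sampling_rate) + 1
  n <- floor(dur * raw$sampling_rate)
  n <- (n %/% factor) * factor          # trim so decimated length is exact
  segment <- raw$samples[i0:(i0 + n - 1)]
  dec <- signal::decimate(segment, factor, ftype = "iir")
  structure(list(
    samples = dec, sampling_rate = raw$sampling_rate / factor,
    native_rate = raw$sampling_rate, t0_offset = 0,
    segment = seg, markers = raw$markers,
    filter = sprintf("cheby1 order 8, cutoff 0.8/%d of native Nyquist, zero-phase", factor)
  ), class = "EphysRecording")
}

#' Import ROIs from a previously saved session
#'
#' Re-uses ROIs drawn on an earlier recording of the same field, e.g. to
#' track the same cells across sessions. Use [shift_rois()] afterwards to
#' compensate specimen or objective drift.
#'
#' @param session target `ImagingSession`.
#' @param other_session_path path to a saved session containing `rois`.
#' @return The imported `ROISet`, re-rendered on the target field.
#' @export
import_rois <- function(session, other_session_path) {
  state <- load_session(other_session_path)
  if (is.null(state$rois))
    fp_error("fluopipe_import_error",
             sprintf("'%s' contains no ROI set", other_session_path))
  rs <- state$rois
  fd <- session$field_dim
  if (any(fd < 1) ||
      all(vapply(rs$rois, function(r)
        all(r$pixels[, 1] > fd[1] | r$pixels[, 2] > fd[2]), TRUE)))
    fp_error("fluopipe_import_error",
             "imported ROIs have no overlap with the target field")
  if (!identical(unname(rs$shape), unname(fd)))
    rs <- shift_rois(rs, 0L, 0L, shape = fd)   # re-render with clipping
  rs
}

#' Rigid integer-pixel translation of an ROI set
#'
#' Shifts every ROI by `(dy, dx)` pixels. Pixels moved off the field are
#' dropped; an ROI whose remaining area falls below `min_area` is flagged
#' `"clipped"` (label identity is preserved either way).
#'
#' @param roiset an `ROISet`.
#' @param dy,dx integer shifts in rows and columns.
#' @param min_area remaining-area floor below which a clipped ROI is flagged
#'   (default 100 px, the cell-validation minimum).
#' @param shape optional `c(height, width)` of the target field (defaults to
#'   the ROI set's own shape).
#' @return A new `ROISet` with identical ids and labels.
#' @export
shift_rois <- function(roiset, dy, dx, min_area = 100, shape = NULL) {
  shape <- shape %||% roiset$shape
  lab <- matrix(0L, shape[1], shape[2])
  rois <- lapply(roiset$rois, function(r) {
    px <- cbind(r$pixels[, 1] + as.integer(dy), r$pixels[, 2] + as.integer(dx))
    keep <- px[, 1] >= 1 & px[, 1] <= shape[1] & px[, 2] >= 1 & px[, 2] <= shape[2]
    px <- px[keep, , drop = FALSE]
    r2 <- roi_record(r$id, px, shape)
    r2$line_pixel_indices <- integer(0)
    r2$flags <- r$flags
    if (nrow(px) < nrow(r$pixels) && nrow(px) < min_area)
      r2$flags <- union(r2$flags, "clipped")
    r2
  })
  for (r in rois)
    if (!is.null(r$pixels) && nrow(r$pixels))
      lab[r$pixels] <- r$id
  structure(list(label_image = lab, rois = rois, labels = roiset$labels,
                 shape = shape),
            class = "ROISet")
}
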