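# Per-cell fluorescence, dF/F0 and dG/R trace extraction.

#' Compute per-cell fluorescence traces
#'
#' Frame mode: `F[t, k, c]` is the mean intensity of ROI k's pixels in frame
#' t, channel c. Line mode: the mean over the ROI's line-path positions per
#' scanned line. A per-frame background series (mean over all pixels outside
#' every ROI) is computed at the same time for the automatic background mode
#' of [compute_dff()].
#'
#' @param session an `ImagingSession`.
#' @param roiset an `ROISet`; by default only ROIs not labelled `not_cell`
#'   are included.
#' @param include `"cells"` (default) or `"all"`.
#' @return A `TraceSet`: list with `F` (`[time, roi, channel]` array),
#'   `roi_ids`, `time`, `sampling_interval`, `channel_roles`,
#'   `background_auto` (`[time, channel]`), plus slots filled by
#'   [compute_dff()], [compute_dgr()] and [smooth_traces()].
#' @export
compute_F <- function(session, roiset, include = c("cells", "all")) {
  include <- match.arg(include)
  ids <- vapply(roiset$rois, `[[`, 0L, "id")
  if (include == "cells" && nrow(roiset$labels)) {
    excluded <- roiset$labels$roi_id[roiset$labels$label == "not_cell"]
    ids <- setdiff(ids, excluded)
  }
  d <- dim(session$stack)
  nt <- d[1]; h <- d[2]; w <- d[3]; nc <- d[4]
  line <- session$scan_mode == "line"
  flat <- matrix(session$stack, nt, h * w * nc)
  cols_for <- function(r) {
    base <- if (line) {
      if (length(r$line_pixel_indices) == 0L) return(integer(0))
      r$line_pixel_indices                  # stack cols are path positions
    } else (r$pixels[, 2] - 1L) * h + r$pixels[, 1]
    base
  }
  keep <- list()
  for (r in roiset$rois) {
    if (!(r$id %in% ids)) next
    if (length(cols_for(r)) == 0L) {
      warning(sprintf("ROI %d has no pixels on the scan path: excluded", r$id))
      next
    }
    keep[[length(keep) + 1L]] <- r
  }
  Fm <- array(NA_real_, c(nt, length(keep), nc))
  for (k in seq_along(keep)) {
    cols <- cols_for(keep[[k]])
    for (ch in seq_len(nc)) {
      cc <- cols + (ch - 1L) * h * w
      Fm[, k, ch] <- rowMeans(flat[, cc, drop = FALSE])
    }
  }
  # background: pixels outside every ROI (field pixels in frame mode, path
  # positions in line mode)
  bg <- matrix(NA_real_, nt, nc)
  out_cols <- if (line) {
    inside <- unique(unlist(lapply(roiset$rois, cols_for)))
    setdiff(seq_len(w), inside)
  } else which(roiset$label_image == 0L)
  if (length(out_cols)) {
    for (ch in seq_len(nc))
      bg[, ch] <- rowMeans(flat[, out_cols + (ch - 1L) * h * w, drop = FALSE])
  }
  structure(list(
    F = Fm, roi_ids = vapply(keep, `[[`, 0L, "id"),
    time = session_time(session),
    sampling_interval = session$sampling_interval,
    channel_roles = session$channel_roles,
    background_auto = bg,
    dff = NULL, dgr = NULL, F0 = NULL, control_range = NULL,
    background_mode = NULL, smoothing_window = 0L
  ), class = "TraceSet")
}

#' @export
print.TraceSet <- function(x, ...) {
  cat(sprintf("<TraceSet> %d ROIs x %d time points x %d channel(s); dff: %s\n",
              dim(x$F)[2], dim(x$F)[1], dim(x$F)[3],
              if (is.null(x$dff)) "not computed" else "computed"))
  invisible(x)
}

#' Compute relative fluorescence change (dF/F0)
#'
#' Background-corrects the green-channel fluorescence, establishes the
#' per-cell baseline F0 over a control range, and returns
#' `(F - F0) / F0` per cell and time point.
#'
#' @param traces a `TraceSet` from [compute_F()].
#' @param control_range frame indices over which F0 is taken; default the
#'   first tenth of the frames (at least one).
#' @param background `"auto"` (per-frame mean outside all ROIs), `"manual"`
#'   (user-supplied per-frame series in `bg_value`), `"constant"` (scalar
#'   `bg_value`) or `"none"`.
#' @param bg_value background value(s) for the manual/constant modes.
#' @param f0_stat `"mean"` (default) or `"median"` over the control range.
#' @return The `TraceSet` with `dff` (`[time, roi]`), `F0`, `control_range`
#'   and `background_mode` filled in. Cells whose baseline is not positive
#'   get an all-`NA` trace with a warning.
#' @export
compute_dff <- function(traces, control_range = NULL,
                        background = c("auto", "manual", "constant", "none"),
                        bg_value = NULL, f0_stat = c("mean", "median")) {
  background <- match.arg(background)
  f0_stat <- match.arg(f0_stat)
  g <- unname(traces$channel_roles["green"])
  if (is.na(g)) fp_error("fluopipe_argument_error", "no green channel role")
  nt <- dim(traces$F)[1]
  B <- switch(background,
    none = rep(0, nt),
    constant = {
      if (is.null(bg_value) || length(bg_value) != 1L)
        fp_error("fluopipe_argument_error", "constant mode needs scalar bg_value")
      rep(bg_value, nt)
    },
    manual = {
      if (is.null(bg_value) || length(bg_value) != nt)
        fp_error("fluopipe_argument_error",
                 "manual mode needs a per-frame background series")
      bg_value
    },
    auto = {
      b <- traces$background_auto[, g]
      if (anyNA(b))
        fp_error("fluopipe_argument_error",
                 "no background pixels available for auto mode")
      b
    })
  control_range <- control_range %||% seq_len(max(1L, floor(0.1 * nt)))
  if (length(control_range) == 0L || any(control_range < 1 | control_range > nt))
    fp_error("fluopipe_argument_error", "control_range outside the recording")
  Fb <- traces$F[, , g, drop = FALSE][, , 1, drop = TRUE]
  if (is.null(dim(Fb))) Fb <- matrix(Fb, nt, 1)
  Fb <- Fb - B
  stat <- if (f0_stat == "mean") colMeans else function(m) apply(m, 2, median)
  F0 <- stat(Fb[control_range, , drop = FALSE])
  dff <- sweep(sweep(Fb, 2, F0, "-"), 2, F0, "/")
  bad <- which(F0 <= 0)
  if (length(bad)) {
    warning(sprintf("F0 <= 0 for ROI(s) %s: dff undefined",
                    paste(traces$roi_ids[bad], collapse = ", ")))
    dff[, bad] <- NA_real_
  }
  traces$dff <- dff
  traces$F0 <- F0
  traces$control_range <- control_range
  traces$background_mode <- background
  traces$background_series <- B
  traces
}

#' Compute the green-to-red ratio change (dG/R)
#'
#' `dgr[t, k] = (G[t, k] - G[1, k]) / R[t, k]`: the green-channel change
#' from the first frame normalized by the static red channel. Because a
#' multiplicative movement artefact scales both channels alike, it largely
#' cancels in dG/R while it contaminates dF/F0.
#'
#' @param traces a `TraceSet` from a 2-channel session.
#' @return The `TraceSet` with `dgr` filled in; entries where the red
#'   intensity is not positive are `NA` with a warning.
#' @export
compute_dgr <- function(traces) {
  g <- unname(traces$channel_roles["green"])
  r <- unname(traces$channel_roles["red"])
  if (is.na(g) || is.na(r))
    fp_error("fluopipe_argument_error", "dG/R needs green and red channels")
  G <- traces$F[, , g, drop = FALSE][, , 1, drop = TRUE]
  R <- traces$F[, , r, drop = FALSE][, , 1, drop = TRUE]
  nt <- dim(traces$F)[1]
  if (is.null(dim(G))) { G <- matrix(G, nt, 1); R <- matrix(R, nt, 1) }
  bad <- R <= 0
  if (any(bad)) {
    warning("red intensity <= 0 on some ROI/time entries: dgr undefined there")
    R[bad] <- NA_real_
  }
  traces$dgr <- sweep(G, 2, G[1, ], "-") / R
  traces
}

#' Smooth dF/F0 traces with a centered moving average
#'
#' Window must be odd; edges use a symmetric window shrunk to fit.
#' `window = 1` is the identity.
#'
#' @param traces a `TraceSet` with `dff` computed.
#' @param window window length in frames (odd, >= 1, <= trace length).
#' @return The `TraceSet` with smoothed `dff` and `smoothing_window` set.
#' @export
smooth_traces <- function(traces, window) {
  if (is.null(traces$dff))
    fp_error("fluopipe_stage_error", "stage not run: compute_dff")
  nt <- dim(traces$dff)[1]
  if (window %% 2 != 1 || window < 1)
    fp_error("fluopipe_argument_error", "window must be odd and >= 1")
  if (window > nt)
    fp_error("fluopipe_argument_error", "window longer than the trace")
  if (window == 1) { traces$smoothing_window <- 1L; return(traces) }
  traces$dff <- apply(traces$dff, 2, moving_average, window = window)
  traces$smoothing_window <- as.integer(window)
  traces
}

# centered moving average, edges handled by shrinking the window
moving_average <- function(x, window) {
  n <- length(x); h <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(1, seq_len(n) - h); hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Export traces as a long-format CSV
#'
#' Columns: `time, roi_id, channel, F, dff, dgr`.
#'
#' @param traces a `TraceSet`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_traces_csv <- function(traces, path) {
  nt <- dim(traces$F)[1]; nk <- dim(traces$F)[2]; nc <- dim(traces$F)[3]
  role_of <- function(ch) {
    nm <- names(traces$channel_roles)[traces$channel_roles == ch]
    if (length(nm)) nm[1] else as.character(ch)
  }
  rows <- do.call(rbind, lapply(seq_len(nk), function(k) {
    do.call(rbind, lapply(seq_len(nc), function(ch) data.frame(
      time = traces$time, roi_id = traces$roi_ids[k], channel = role_of(ch),
      F = traces$F[, k, ch],
      dff = if (!is.null(traces$dff) && role_of(ch) == "green")
        traces$dff[, k] else NA_real_,
      dgr = if (!is.null(traces$dgr) && role_of(ch) == "green")
        traces$dgr[, k] else NA_real_)))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
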