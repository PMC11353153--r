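# HTML report generation (per-cell and network) and batch processing over
# folders of saved sessions.

#' Flag threshold-crossing events on a dF/F0 trace
#'
#' An event is a contiguous run of samples exceeding
#' `median(x) + k * mad(x)` (MAD scaled to be consistent with the SD for
#' normal data). This is the pipeline's "spike detection": a conservative
#' transient flag, not deconvolution.
#'
#' @param x numeric dF/F0 trace.
#' @param k threshold in MADs above the median (default 5).
#' @return List with `n_events`, `onsets` (sample indices), `threshold`.
#' @export
detect_events <- function(x, k = 5) {
  thr <- median(x, na.rm = TRUE) + k * mad(x, na.rm = TRUE)
  above <- !is.na(x) & x > thr
  onsets <- which(above & !c(FALSE, head(above, -1)))
  list(n_events = length(onsets), onsets = onsets, threshold = thr)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df) {
  hd <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                              collapse = ""), "</tr>")
  rows <- apply(df, 1, function(r)
    paste0("<tr>", paste0("<td>", html_escape(format(r)), "</td>",
                          collapse = ""), "</tr>"))
  paste0("<table border='1' cellpadding='3'>", hd,
         paste(rows, collapse = "\n"), "</table>")
}

label_colour <- function(lbl) {
  switch(lbl, astrocyte = "red", neuron = "darkgreen", "blue")
}

png_plot <- function(path, expr, width = 640, height = 300) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  force(expr)
  invisible(path)
}

state_require <- function(state, field, stage) {
  if (is.null(state[[field]]))
    fp_error("fluopipe_stage_error", sprintf("stage not run: %s", stage))
  state[[field]]
}

#' Per-cell HTML report
#'
#' One document per session: a settings header, a summary table
#' (label, origin, area, eccentricity, dF/F0 event count), and a section
#' per ROI with its location on the field of view, green/red crops, the
#' dF/F0 trace and per-band wavelet power panels. Deterministic output: no
#' timestamps are embedded.
#'
#' @param state analysis state list with at least `session`, `rois`,
#'   `traces` (dff computed) and `spectra` (from [analyze_session()]);
#'   `ephys` is optional and its section is simply omitted when absent.
#' @param out_path output HTML file; plot PNGs go into
#'   `<out_path>_files/`.
#' @param k_mad event-flagging threshold (see [detect_events()]).
#' @return `out_path`, invisibly; the summary data frame as attribute
#'   `"summary"`.
#' @export
report_cells <- function(state, out_path, k_mad = 5) {
  session <- state_require(state, "session", "load_image")
  rois <- state_require(state, "rois", "extract_rois")
  traces <- state_require(state, "traces", "compute_F")
  if (is.null(traces$dff)) fp_error("fluopipe_stage_error", "stage not run: compute_dff")
  spectra <- state_require(state, "spectra", "analyze_session")
  adir <- paste0(tools::file_path_sans_ext(out_path), "_files")
  dir.create(adir, showWarnings = FALSE, recursive = TRUE)
  bands <- spectra$bands
  refs <- if (session$scan_mode == "line" && !is.null(session$reference_image))
    session$reference_image
  else {
    out <- list(green = make_reference(session, channel = "green")$pixels)
    if (!is.na(session$channel_roles["red"]))
      out$red <- make_reference(session, channel = "red")$pixels
    out
  }

  summary_rows <- list()
  cell_sections <- character(0)
  for (ki in seq_along(traces$roi_ids)) {
    id <- traces$roi_ids[ki]
    roi <- get_roi(rois, id)
    li <- which(rois$labels$roi_id == id)
    lbl <- rois$labels$label[li]; org <- rois$labels$origin[li]
    ev <- detect_events(traces$dff[, ki], k_mad)
    summary_rows[[ki]] <- data.frame(
      roi_id = id, label = lbl, origin = org, area_px = roi$area,
      eccentricity = round(roi$eccentricity, 3), events = ev$n_events)
    loc_png <- file.path(adir, sprintf("roi%d_loc.png", id))
    png_plot(loc_png, {
      image(t(refs$green)[, nrow(refs$green):1], col = grDevices::gray.colors(64),
            axes = FALSE, main = sprintf("ROI %d location", id))
      bb <- roi$bbox; h <- nrow(refs$green); w <- ncol(refs$green)
      rect((bb["cmin"] - 1) / w, 1 - bb["rmax"] / h,
           bb["cmax"] / w, 1 - (bb["rmin"] - 1) / h, border = "white", lwd = 2)
    }, width = 320, height = 320)
    tr_png <- file.path(adir, sprintf("roi%d_dff.png", id))
    png_plot(tr_png, {
      plot(traces$time, traces$dff[, ki], type = "l", xlab = "time (s)",
           ylab = expression(Delta * F / F[0]), main = sprintf("ROI %d", id))
      abline(h = ev$threshold, col = "red", lty = 2)
      if (ev$n_events) points(traces$time[ev$onsets],
                              traces$dff[ev$onsets, ki], col = "red", pch = 19)
    })
    band_pngs <- character(nrow(bands))
    for (b in seq_len(nrow(bands))) {
      band_pngs[b] <- file.path(adir, sprintf("roi%d_%s.png", id, bands$name[b]))
      png_plot(band_pngs[b], {
        plot(spectra$time, spectra$band_power[ki, b, ], type = "l",
             xlab = "time (s)", ylab = "band power",
             main = sprintf("%s (%g-%g Hz)", bands$name[b],
                            bands$f_low[b], bands$f_high[b]))
      }, height = 200)
    }
    cell_sections <- c(cell_sections, paste0(
      sprintf("<h2>ROI %d — %s (%s)</h2>", id, html_escape(lbl), html_escape(org)),
      sprintf("<p>area %d px, eccentricity %.3f, %d flagged event(s)</p>",
              roi$area, roi$eccentricity, ev$n_events),
      sprintf("<img src='%s/%s'>", basename(adir), basename(loc_png)),
      sprintf("<img src='%s/%s'>", basename(adir), basename(tr_png)),
      paste(sprintf("<img class='band' src='%s/%s'>", basename(adir),
                    basename(band_pngs)), collapse = "\n")))
  }
  summary <- do.call(rbind, summary_rows)
  eph_html <- if (!is.null(state$ephys)) {
    sprintf("<p>Ephys: %d samples at %g Hz (native %g Hz, %s)</p>",
            length(state$ephys$samples), state$ephys$sampling_rate,
            state$ephys$native_rate, html_escape(state$ephys$filter))
  } else ""
  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>fluopipe cell report</title></head><body>",
    "<h1>Cell report</h1>",
    sprintf("<p>Source: %s — %d frames of %dx%d, %d channel(s), %s scan, dt = %g s</p>",
            html_escape(session$source_path), session$n_frames, session$height,
            session$width, session$n_channels, session$scan_mode,
            session$sampling_interval),
    eph_html,
    "<h2>Summary</h2>", html_table(summary),
    paste(cell_sections, collapse = "\n"),
    "</body></html>")
  writeLines(html, out_path)
  invisible(structure(out_path, summary = summary))
}

#' Network activity HTML report
#'
#' For each band, stacked per-cell band-power traces colour-coded by label
#' (astrocytes red, neurons green, anything else blue), with the ephys
#' band-power panel beneath on the shared time axis, and a summary table
#' giving each cell's Pearson correlation with the ephys band power.
#'
#' @param x one analysis state (as for [report_cells()]) or a
#'   `SessionCollection`; collections get one report section per session.
#' @param out_path output HTML file.
#' @return `out_path`, invisibly; summary data frame(s) as attribute
#'   `"summary"`.
#' @export
report_network <- function(x, out_path) {
  states <- if (inherits(x, "SessionCollection")) x$sessions else list(x)
  ids <- if (inherits(x, "SessionCollection")) x$ids else "session"
  adir <- paste0(tools::file_path_sans_ext(out_path), "_files")
  dir.create(adir, showWarnings = FALSE, recursive = TRUE)
  sections <- character(0)
  summaries <- list()
  for (si in seq_along(states)) {
    state <- states[[si]]
    spectra <- state_require(state, "spectra", "analyze_session")
    rois <- state_require(state, "rois", "extract_rois")
    bands <- spectra$bands
    nk <- length(spectra$cell_ids)
    lbls <- vapply(spectra$cell_ids, function(id) {
      i <- which(rois$labels$roi_id == id)
      if (length(i)) rois$labels$label[i] else NA_character_
    }, "")
    if (anyNA(lbls)) {
      warning("cells without labels rendered in the non-cell colour")
      lbls[is.na(lbls)] <- "unknown"
    }
    cols <- vapply(lbls, label_colour, "")
    rows <- list()
    for (b in seq_len(nrow(bands))) {
      fn <- file.path(adir, sprintf("%s_%s.png", ids[si], bands$name[b]))
      png_plot(fn, {
        op <- par(mfrow = c(2, 1), mar = c(2, 4, 2, 1))
        on.exit(par(op), add = TRUE)
        P <- spectra$band_power[, b, , drop = FALSE][, 1, , drop = TRUE]
        if (is.null(dim(P))) P <- matrix(P, nrow = 1)
        sc <- max(P, 1e-12)
        plot(NULL, xlim = range(spectra$time), ylim = c(0, nk + 1),
             xlab = "", ylab = "cell",
             main = sprintf("%s band (%g-%g Hz)", bands$name[b],
                            bands$f_low[b], bands$f_high[b]))
        for (k in seq_len(nk))
          lines(spectra$time, k + 0.8 * P[k, ] / sc, col = cols[k])
        if (!is.null(spectra$ephys_band_power)) {
          plot(spectra$ephys_time, spectra$ephys_band_power[b, ], type = "l",
               xlab = "time (s)", ylab = "LFP power")
        } else plot.new()
      }, height = 480)
      for (k in seq_len(nk)) {
        r <- NA_real_
        if (!is.null(spectra$ephys_band_power)) {
          Pk <- spectra$band_power[k, b, ]
          Pe <- approx(spectra$ephys_time, spectra$ephys_band_power[b, ],
                       xout = spectra$time, rule = 2)$y
          if (sd(Pk) > 0 && sd(Pe) > 0) r <- cor(Pk, Pe)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          session = ids[si], band = bands$name[b],
          roi_id = spectra$cell_ids[k], label = lbls[k],
          ephys_corr = round(r, 3))
      }
      sections <- c(sections, sprintf("<img src='%s/%s'>", basename(adir),
                                      basename(fn)))
    }
    summaries[[si]] <- do.call(rbind, rows)
    sections <- c(sections, html_table(summaries[[si]]))
  }
  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>fluopipe network report</title></head><body>",
    "<h1>Network report</h1>",
    paste(sprintf("<h2>%s</h2>", html_escape(ids)), collapse = ""),
    paste(sections, collapse = "\n"),
    "</body></html>")
  writeLines(html, out_path)
  invisible(structure(out_path, summary = do.call(rbind, summaries)))
}

#' Load every saved session in a folder
#'
#' Sessions are the files written by [save_session()]; they are loaded in
#' lexicographic filename order and keyed by base name.
#'
#' @param folder directory containing session containers.
#' @param pattern filename pattern (default `"\\.rds$"`).
#' @return A `SessionCollection`: list with `sessions`, `ids`, `folder`.
#' @export
load_data_from_folder <- function(folder, pattern = "\\.rds$") {
  files <- sort(list.files(folder, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L)
    fp_error("fluopipe_collection_error",
             sprintf("no session containers in %s", folder))
  sessions <- lapply(files, load_session)
  structure(list(sessions = sessions,
                 ids = tools::file_path_sans_ext(basename(files)),
                 folder = folder),
            class = "SessionCollection")
}

# the operations `apply_sessions` knows how to run on a loaded state
session_ops <- function() list(
  band_summary = function(state, bands = default_bands(), ...) {
    spectra <- state_require(state, "spectra", "analyze_session")
    out <- lapply(seq_len(nrow(spectra$bands)), function(b)
      mean(spectra$band_power[, b, ]))
    names(out) <- paste0("mean_power_", spectra$bands$name)
    as.data.frame(out)
  },
  event_counts = function(state, k = 5, ...) {
    traces <- state_require(state, "traces", "compute_dff")
    if (is.null(traces$dff)) fp_error("fluopipe_stage_error",
                                      "stage not run: compute_dff")
    data.frame(n_cells = ncol(traces$dff),
               total_events = sum(vapply(seq_len(ncol(traces$dff)), function(k2)
                 detect_events(traces$dff[, k2], k)$n_events, 0L)))
  },
  plv_summary = function(state, band = "delta", ...) {
    traces <- state_require(state, "traces", "compute_dff")
    pm <- plv_matrix(traces, band)
    v <- pm$values[upper.tri(pm$values)]
    data.frame(mean_plv = mean(v), max_plv = max(v))
  },
  cell_counts = function(state, ...) {
    rois <- state_require(state, "rois", "extract_rois")
    data.frame(n_rois = n_rois(rois),
               n_astrocytes = sum(rois$labels$label == "astrocyte"),
               n_neurons = sum(rois$labels$label == "neuron"))
  })

#' Apply one pipeline operation to every session of a collection
#'
#' Runs the named operation identically on each loaded state. A failure on
#' one session is recorded in its result row and does not abort the rest.
#'
#' @param collection a `SessionCollection`.
#' @param op operation name; one of `names(session_ops())`:
#'   `"band_summary"`, `"event_counts"`, `"plv_summary"`, `"cell_counts"`.
#' @param ... passed to the operation.
#' @return data.frame with one row per session: `session_id`, `status`
#'   (`"ok"` or `"error"`), `message`, plus the operation's columns.
#' @export
apply_sessions <- function(collection, op, ...) {
  ops <- session_ops()
  if (!op %in% names(ops))
    fp_error("fluopipe_catalogue_error",
             sprintf("unknown operation '%s'; available: %s", op,
                     paste(names(ops), collapse = ", ")))
  rows <- lapply(seq_along(collection$sessions), function(i) {
    res <- tryCatch(
      cbind(data.frame(session_id = collection$ids[i], status = "ok",
                       message = "", stringsAsFactors = FALSE),
            ops[[op]](collection$sessions[[i]], ...)),
      error = function(e) data.frame(
        session_id = collection$ids[i], status = "error",
        message = conditionMessage(e), stringsAsFactors = FALSE))
    res
  })
  nm <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (m in setdiff(nm, names(r))) r[[m]] <- NA
    r[nm]
  })
  do.call(rbind, rows)
}
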