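# Cell validation (area / eccentricity / contrast) and astrocyte-vs-neuron
# classification from two-channel intensity, with manual override and
# annotation round-trip.

#' Classification parameter set
#'
#' Validation thresholds follow the published rules: an ROI is a cell when
#' its area is strictly higher than 100 pixels, its eccentricity strictly
#' lower than 0.85 (somata are roughly round), and its mean intensity at
#' least two times the mean intensity of its close vicinity. The
#' astrocyte/neuron split uses the red(SR-101-like)/green(calcium indicator)
#' intensity ratio; the published rule is qualitative, so the numeric
#' boundaries default to 1.5 (astrocyte at or above) and 0.75 (neuron at or
#' below), leaving an explicit "unclassified" gap for user review.
#'
#' @param min_area px; cell requires area strictly greater (default 100).
#' @param max_eccentricity cell requires eccentricity strictly lower
#'   (default 0.85).
#' @param min_contrast_ratio cell requires inside/vicinity mean intensity
#'   ratio at least this (default 2).
#' @param vicinity_width px of morphological dilation forming the vicinity
#'   ring (default 5).
#' @param astro_red_green_ratio_min red/green at or above: astrocyte
#'   (default 1.5).
#' @param neuron_red_green_ratio_max red/green at or below: neuron
#'   (default 0.75).
#' @return A `ClassificationParams` list.
#' @export
classification_params <- function(min_area = 100, max_eccentricity = 0.85,
                                  min_contrast_ratio = 2.0,
                                  vicinity_width = 5,
                                  astro_red_green_ratio_min = 1.5,
                                  neuron_red_green_ratio_max = 0.75) {
  p <- list(min_area = min_area, max_eccentricity = max_eccentricity,
            min_contrast_ratio = min_contrast_ratio,
            vicinity_width = vicinity_width,
            astro_red_green_ratio_min = astro_red_green_ratio_min,
            neuron_red_green_ratio_max = neuron_red_green_ratio_max)
  if (any(unlist(p) <= 0) || max_eccentricity >= 1 ||
      astro_red_green_ratio_min <= neuron_red_green_ratio_max)
    fp_error("fluopipe_argument_error", "invalid classification parameters")
  structure(p, class = "ClassificationParams")
}

# vicinity ring: dilate the ROI by vicinity_width, subtract the ROI itself
# and every other ROI so neighbouring cells cannot inflate the background
vicinity_mask <- function(roi, roiset, width) {
  shape <- roiset$shape
  m <- matrix(0, shape[1], shape[2])
  m[roi$pixels] <- 1
  brush <- EBImage::makeBrush(2 * round(width) + 1, shape = "disc")
  dil <- EBImage::dilate(m, brush) > 0
  dil[roi$pixels] <- FALSE
  dil[roiset$label_image > 0] <- FALSE
  dil
}

#' Validate one ROI as a cell
#'
#' Applies the three validation rules (area strictly above `min_area`,
#' eccentricity strictly below `max_eccentricity`, mean inside intensity at
#' least `min_contrast_ratio` times the mean of the vicinity ring).
#'
#' @param roi an ROI record (see [get_roi()]).
#' @param ref_green green-channel `ReferenceImage` (or matrix) used for the
#'   contrast rule.
#' @param roiset the containing `ROISet` (other ROIs are excluded from the
#'   vicinity ring).
#' @param params a [classification_params()] list.
#' @return List with `is_cell` (logical) and `reasons` (character vector of
#'   every failed criterion among `"area"`, `"eccentricity"`, `"contrast"`).
#' @export
validate_roi <- function(roi, ref_green, roiset,
                         params = classification_params()) {
  img <- if (inherits(ref_green, "ReferenceImage")) ref_green$pixels else ref_green
  reasons <- character(0)
  if (!(roi$area > params$min_area)) reasons <- c(reasons, "area")
  if (!(roi$eccentricity < params$max_eccentricity))
    reasons <- c(reasons, "eccentricity")
  vic <- vicinity_mask(roi, roiset, params$vicinity_width)
  if (!any(vic))
    fp_error("fluopipe_validation_error",
             sprintf("ROI %d has an empty vicinity (fills the field?)", roi$id))
  inside <- mean(img[roi$pixels])
  around <- mean(img[vic])
  if (!(inside >= params$min_contrast_ratio * around))
    reasons <- c(reasons, "contrast")
  list(is_cell = length(reasons) == 0L, reasons = reasons,
       inside_mean = inside, vicinity_mean = around)
}

#' Classify ROIs as astrocytes or neurons
#'
#' Invalid ROIs become `not_cell`. Valid ROIs with red/green reference-image
#' mean ratio at or above `astro_red_green_ratio_min` are astrocytes, at or
#' below `neuron_red_green_ratio_max` neurons, and `unclassified` in the gap
#' between. Single-channel sessions label every valid cell `unclassified`.
#' ROIs carrying a `manual` or `imported` label are never overwritten.
#'
#' @param session the `ImagingSession` (channel count decides the mode).
#' @param roiset an `ROISet`.
#' @param ref_green green-channel reference image.
#' @param ref_red red-channel reference image (required for 2-channel
#'   sessions).
#' @param params a [classification_params()] list.
#' @return The `ROISet` with its `labels` data frame updated
#'   (`roi_id`, `label`, `origin`, `reasons`, `red_green_ratio`).
#' @export
classify_cells <- function(session, roiset, ref_green, ref_red = NULL,
                           params = classification_params()) {
  two_ch <- session$n_channels == 2L
  if (two_ch && is.null(ref_red))
    fp_error("fluopipe_argument_error",
             "2-channel session needs a red reference image")
  g <- if (inherits(ref_green, "ReferenceImage")) ref_green$pixels else ref_green
  r <- if (!is.null(ref_red)) {
    if (inherits(ref_red, "ReferenceImage")) ref_red$pixels else ref_red
  } else NULL
  lb <- roiset$labels
  if (!"reasons" %in% names(lb)) lb$reasons <- ""
  if (!"red_green_ratio" %in% names(lb)) lb$red_green_ratio <- NA_real_
  for (i in seq_len(nrow(lb))) {
    if (lb$origin[i] %in% c("manual", "imported")) next
    roi <- get_roi(roiset, lb$roi_id[i])
    v <- validate_roi(roi, g, roiset, params)
    lb$reasons[i] <- paste(v$reasons, collapse = ";")
    if (!v$is_cell) {
      lb$label[i] <- "not_cell"; lb$origin[i] <- "auto"; next
    }
    if (!two_ch || is.null(r)) {
      lb$label[i] <- "unclassified"; lb$origin[i] <- "auto"; next
    }
    gm <- mean(g[roi$pixels]); rm <- mean(r[roi$pixels])
    ratio <- if (gm > 0) rm / gm else NA_real_
    lb$red_green_ratio[i] <- ratio
    lb$label[i] <- if (gm <= 0) {
      if (rm > 0) "astrocyte" else "unclassified"
    } else if (ratio >= params$astro_red_green_ratio_min) "astrocyte"
      else if (ratio <= params$neuron_red_green_ratio_max) "neuron"
      else "unclassified"
    lb$origin[i] <- "auto"
  }
  roiset$labels <- lb
  roiset
}

#' Manually override a cell label
#'
#' Manual labels take precedence: subsequent [classify_cells()] runs leave
#' them untouched, and the `manual` origin survives session save/load.
#'
#' @param roiset an `ROISet`.
#' @param roi_id id of the ROI to relabel.
#' @param label one of `"astrocyte"`, `"neuron"`, `"not_cell"`,
#'   `"unclassified"`.
#' @return The updated `ROISet`.
#' @export
override_label <- function(roiset, roi_id,
                           label = c("astrocyte", "neuron", "not_cell",
                                     "unclassified")) {
  label <- match.arg(label)
  i <- which(roiset$labels$roi_id == roi_id)
  if (length(i) != 1L)
    fp_error("fluopipe_key_error", sprintf("no ROI with id %s", roi_id))
  roiset$labels$label[i] <- label
  roiset$labels$origin[i] <- "manual"
  roiset
}

#' Export per-cell image crops for external annotation
#'
#' Writes one multipage TIFF bounding-box crop per ROI (green page, then red
#' if present) named `<session>_<roiID>.tif`, plus a `manifest.csv` listing
#' `roi_id,file,label,origin`. The crops feed external classifiers or
#' machine-learning training; results come back via [import_annotations()].
#'
#' @param session an `ImagingSession`.
#' @param roiset an `ROISet`.
#' @param directory output directory (created if missing).
#' @param margin extra pixels around the bounding box (default 2).
#' @return Path of the manifest file, invisibly.
#' @export
export_cell_images <- function(session, roiset, directory, margin = 2L) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  base <- tools::file_path_sans_ext(basename(session$source_path))
  if (base %in% c("", "<memory>")) base <- "session"
  ref <- lapply(seq_len(session$n_channels), function(ch)
    make_reference(session, method = "average", channel = ch)$pixels)
  rows <- list()
  for (r in roiset$rois) {
    bb <- r$bbox
    r0 <- max(1L, bb["rmin"] - margin); r1 <- min(session$field_dim[1], bb["rmax"] + margin)
    c0 <- max(1L, bb["cmin"] - margin); c1 <- min(session$field_dim[2], bb["cmax"] + margin)
    pages <- lapply(ref, function(m) {
      crop <- m[r0:r1, c0:c1, drop = FALSE]
      mx <- max(crop, 1)
      crop / mx
    })
    fn <- sprintf("%s_%d.tif", base, r$id)
    tiff::writeTIFF(pages, file.path(directory, fn), bits.per.sample = 16L)
    i <- which(roiset$labels$roi_id == r$id)
    rows[[length(rows) + 1L]] <- data.frame(
      roi_id = r$id, file = fn,
      label = roiset$labels$label[i], origin = roiset$labels$origin[i],
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows) %||%
    data.frame(roi_id = integer(0), file = character(0),
               label = character(0), origin = character(0))
  mf <- file.path(directory, "manifest.csv")
  write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}

#' Import externally produced cell annotations
#'
#' Reads a CSV with columns `roi_id,label` and applies the labels with
#' origin `"imported"` (protected from later auto-classification). Rows
#' referencing unknown ids abort the import and are listed in the error.
#'
#' @param roiset an `ROISet`.
#' @param file annotation CSV path.
#' @return The updated `ROISet`.
#' @export
import_annotations <- function(roiset, file) {
  ann <- read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("roi_id", "label") %in% names(ann)))
    fp_error("fluopipe_import_error", "annotation file needs roi_id,label columns")
  unknown <- setdiff(ann$roi_id, roiset$labels$roi_id)
  if (length(unknown))
    fp_error("fluopipe_import_error",
             sprintf("annotation references unknown ROI id(s): %s",
                     paste(unknown, collapse = ", ")))
  for (i in seq_len(nrow(ann))) {
    j <- which(roiset$labels$roi_id == ann$roi_id[i])
    roiset$labels$label[j] <- ann$label[i]
    roiset$labels$origin[j] <- "imported"
  }
  roiset
}
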