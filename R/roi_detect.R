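# Reference images, thresholding, connected-component ROI extraction and
# line-scan mapping.

# 8-connected component labelling (BFS flood fill). EBImage::bwlabel is
# 4-connected, which splits diagonally touching somata, so this is done here.
label_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  queue <- integer(sum(mask))
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    lab[start] <- nxt
    queue[1] <- start
    qlo <- 1L; qhi <- 1L
    while (qlo <= qhi) {
      i <- queue[qlo]; qlo <- qlo + 1L
      r <- ((i - 1L) %% h) + 1L
      cc <- ((i - 1L) %/% h) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1L || r2 > h || c2 < 1L || c2 > w) next
        j <- (c2 - 1L) * h + r2
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- nxt
          qhi <- qhi + 1L
          queue[qhi] <- j
        }
      }
    }
  }
  lab
}

# geometry of one ROI from its pixel set: area, centroid, eccentricity of the
# ellipse with identical second central moments (regionprops convention,
# including the 1/12 unit-pixel variance term), bounding box
roi_record <- function(id, pixels, shape) {
  pixels <- matrix(as.integer(pixels), ncol = 2)
  colnames(pixels) <- c("row", "col")
  area <- nrow(pixels)
  if (area == 0L) {
    return(list(id = id, pixels = pixels, area = 0L,
                centroid = c(NA_real_, NA_real_), eccentricity = NA_real_,
                bbox = rep(NA_integer_, 4), line_pixel_indices = integer(0),
                flags = "empty"))
  }
  ctr <- colMeans(pixels)
  dr <- pixels[, 1] - ctr[1]; dc <- pixels[, 2] - ctr[2]
  mu20 <- mean(dr^2) + 1 / 12
  mu02 <- mean(dc^2) + 1 / 12
  mu11 <- mean(dr * dc)
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  ecc <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
  list(id = id, pixels = pixels, area = area,
       centroid = c(row = ctr[1], col = ctr[2]), eccentricity = ecc,
       bbox = c(rmin = min(pixels[, 1]), rmax = max(pixels[, 1]),
                cmin = min(pixels[, 2]), cmax = max(pixels[, 2])),
       line_pixel_indices = integer(0), flags = character(0))
}

new_roiset <- function(label_image, rois, shape,
                       labels = NULL) {
  ids <- vapply(rois, `[[`, 0L, "id")
  labels <- labels %||% data.frame(
    roi_id = ids,
    label = rep("unclassified", length(ids)),
    origin = rep("auto", length(ids)),
    stringsAsFactors = FALSE)
  structure(list(label_image = label_image, rois = rois,
                 labels = labels, shape = shape),
            class = "ROISet")
}

#' @export
print.ROISet <- function(x, ...) {
  cat(sprintf("<ROISet> %d ROIs on %dx%d field\n", length(x$rois),
              x$shape[1], x$shape[2]))
  if (nrow(x$labels)) print(table(x$labels$label))
  invisible(x)
}

#' Number of ROIs in a set
#' @param roiset an `ROISet`.
#' @return Integer count.
#' @export
n_rois <- function(roiset) length(roiset$rois)

#' Build a reference image from a frame range
#'
#' Collapses a chosen range of frames with a pixelwise average, maximum or
#' standard deviation, or wraps an externally supplied image. ROI detection
#' and the red/green classification ratios all operate on reference images.
#'
#' @param session an `ImagingSession`.
#' @param frames integer vector of frame indices (default: all frames).
#' @param method one of `"average"`, `"max"`, `"std"`, `"external"`.
#' @param channel channel index or role name (default the green channel).
#' @param external numeric matrix for `method = "external"`; must match the
#'   session's spatial dimensions.
#' @return A `ReferenceImage`: list with `pixels` (matrix), `method`,
#'   `frames_used`, `channel`.
#' @export
make_reference <- function(session, frames = NULL,
                           method = c("average", "max", "std", "external"),
                           channel = "green", external = NULL) {
  method <- match.arg(method)
  d <- dim(session$stack)
  if (method == "external") {
    if (is.null(external)) fp_error("fluopipe_argument_error", "external image missing")
    if (!identical(dim(external), as.integer(session$field_dim)))
      fp_error("fluopipe_dimension_error",
               sprintf("external image is %dx%d, field is %dx%d",
                       nrow(external), ncol(external),
                       session$field_dim[1], session$field_dim[2]))
    return(structure(list(pixels = external, method = method,
                          frames_used = integer(0), channel = NA),
                     class = "ReferenceImage"))
  }
  frames <- frames %||% seq_len(d[1])
  if (length(frames) == 0L)
    fp_error("fluopipe_argument_error", "empty frame range")
  if (any(frames < 1 | frames > d[1]))
    fp_error("fluopipe_argument_error", "frame indices out of range")
  if (is.character(channel)) {
    ch <- unname(session$channel_roles[channel])
    if (is.na(ch)) fp_error("fluopipe_argument_error",
                            sprintf("no channel with role '%s'", channel))
  } else ch <- as.integer(channel)
  flat <- matrix(session$stack[frames, , , ch], length(frames), d[2] * d[3])
  px <- switch(method,
    average = colMeans(flat),
    max = apply(flat, 2, max),
    std = if (length(frames) > 1) apply(flat, 2, sd) else rep(0, ncol(flat)))
  structure(list(pixels = matrix(px, d[2], d[3]), method = method,
                 frames_used = frames, channel = ch),
            class = "ReferenceImage")
}

#' Threshold a reference image to a binary mask
#'
#' @param ref a `ReferenceImage` (or plain matrix).
#' @param method `"otsu"` (between-class variance maximization via
#'   [EBImage::otsu()]), `"fraction_of_max"` (threshold =
#'   `value * max(image)`), or `"absolute"`.
#' @param value numeric parameter: fraction in (0, 1) for
#'   `"fraction_of_max"`, absolute intensity for `"absolute"`; ignored for
#'   `"otsu"`.
#' @return List with `mask` (logical matrix, `TRUE` where pixel >=
#'   threshold), `threshold` (the value actually applied, recorded for
#'   reporting) and `method`. A flat image under Otsu, or an absolute
#'   threshold above the image maximum, yields an all-`FALSE` mask with a
#'   warning rather than an error.
#' @export
threshold_reference <- function(ref, method = c("otsu", "fraction_of_max",
                                                "absolute"), value = NULL) {
  method <- match.arg(method)
  img <- if (inherits(ref, "ReferenceImage")) ref$pixels else ref
  rng <- range(img)
  th <- switch(method,
    otsu = {
      if (diff(rng) == 0) {
        warning("flat image: Otsu threshold undefined, returning empty mask")
        Inf
      } else {
        sc <- EBImage::otsu(EBImage::Image((img - rng[1]) / diff(rng)),
                            range = c(0, 1))
        rng[1] + sc * diff(rng)
      }
    },
    fraction_of_max = {
      if (is.null(value) || value <= 0 || value >= 1)
        fp_error("fluopipe_argument_error",
                 "fraction_of_max needs 0 < value < 1")
      value * rng[2]
    },
    absolute = {
      if (is.null(value)) fp_error("fluopipe_argument_error", "value missing")
      if (value > rng[2])
        warning(sprintf("absolute threshold %g above image maximum %g: empty mask",
                        value, rng[2]))
      value
    })
  list(mask = img >= th, threshold = th, method = method)
}

#' Extract candidate ROIs from a binary mask
#'
#' Finds 8-connected components of the mask, removes components outside the
#' cell-size window, and relabels the survivors 1..K in raster order (row by
#' row) of their first pixel.
#'
#' @param mask logical matrix, or the list returned by
#'   [threshold_reference()].
#' @param min_area,max_area inclusive size window in pixels; components with
#'   `area < min_area` or `area > max_area` are dropped.
#' @return An `ROISet`.
#' @export
extract_rois <- function(mask, min_area = 30, max_area = 5000) {
  if (is.list(mask)) mask <- mask$mask
  if (min_area < 1 || max_area < min_area)
    fp_error("fluopipe_argument_error", "need 1 <= min_area <= max_area")
  shape <- dim(mask)
  lab0 <- label_components8(mask)
  k0 <- max(lab0)
  comps <- list()
  if (k0 > 0) {
    idx <- which(lab0 > 0)
    by_lab <- split(idx, lab0[idx])
    areas <- lengths(by_lab)
    keep <- which(areas >= min_area & areas <= max_area)
    if (length(keep)) {
      h <- shape[1]; w <- shape[2]
      # raster order (row-major) of each component's first pixel
      first_raster <- vapply(by_lab[keep], function(ii) {
        r <- ((ii - 1L) %% h) + 1L; cc <- ((ii - 1L) %/% h) + 1L
        min((r - 1L) * w + cc)
      }, 0)
      ord <- keep[order(first_raster)]
      comps <- lapply(seq_along(ord), function(k) {
        ii <- by_lab[[ord[k]]]
        px <- cbind(((ii - 1L) %% h) + 1L, ((ii - 1L) %/% h) + 1L)
        roi_record(k, px, shape)
      })
    }
  }
  lab <- matrix(0L, shape[1], shape[2])
  for (r in comps) lab[r$pixels] <- r$id
  new_roiset(lab, comps, shape)
}

#' Map ROIs onto a line-scan path
#'
#' Annotates each ROI with the positions along the scan path whose pixels
#' fall inside it and removes ROIs the path barely grazes.
#'
#' @param roiset an `ROISet` defined on the imaged field.
#' @param line_path integer matrix of `(row, col)` path coordinates, or an
#'   `ImagingSession` in line mode.
#' @param min_line_pixels minimum number of path positions inside an ROI for
#'   it to be kept (default 3: enough for a usable trace while rejecting
#'   grazing intersections).
#' @return A filtered `ROISet` whose ROIs carry `line_pixel_indices`.
#' @export
map_rois_to_linescan <- function(roiset, line_path, min_line_pixels = 3) {
  if (inherits(line_path, "ImagingSession")) {
    if (line_path$scan_mode != "line")
      fp_error("fluopipe_mode_error", "session is not in line-scan mode")
    line_path <- line_path$line_path
  }
  if (is.null(line_path))
    fp_error("fluopipe_mode_error", "no line path available")
  h <- roiset$shape[1]
  lin_path <- (line_path[, 2] - 1L) * h + line_path[, 1]
  kept <- list()
  for (r in roiset$rois) {
    lin_roi <- (r$pixels[, 2] - 1L) * h + r$pixels[, 1]
    idx <- which(lin_path %in% lin_roi)
    if (length(idx) >= min_line_pixels) {
      r$line_pixel_indices <- idx
      kept[[length(kept) + 1L]] <- r
    }
  }
  ids <- vapply(kept, `[[`, 0L, "id")
  lab <- matrix(0L, roiset$shape[1], roiset$shape[2])
  for (r in kept) lab[r$pixels] <- r$id
  new_roiset(lab, kept, roiset$shape,
             labels = roiset$labels[roiset$labels$roi_id %in% ids, ,
                                    drop = FALSE])
}

#' Look up one ROI record by id
#' @param roiset an `ROISet`.
#' @param roi_id integer id.
#' @return The ROI record list.
#' @export
get_roi <- function(roiset, roi_id) {
  for (r in roiset$rois) if (r$id == roi_id) return(r)
  fp_error("fluopipe_key_error", sprintf("no ROI with id %s", roi_id))
}
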