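#' Visible/thermal frame pair
#'
#' One co-acquired pair from the integrated camera: the visible color image
#' (used for eye/face detection) and the per-pixel temperature raster in
#' degrees Celsius (already radiometrically decoded upstream). Pairs are
#' captured every ~2 s.
#'
#' @param visible `H x W x 3` numeric array, values in `[0, 255]`.
#' @param thermal `h x w` numeric matrix of temperatures (deg C).
#' @param timestamp Seconds from session start.
#' @return An object of class `thermal_pair`; `plausible_skin` flags whether
#'   all temperatures lie in the 0-60 deg C plausible-skin window.
#' @export
thermal_pair <- function(visible, thermal, timestamp = 0) {
  dv <- dim(visible)
  if (length(dv) != 3L || dv[3] != 3L) abort_biosense("`visible` must be H x W x 3.")
  if (!is.matrix(thermal)) abort_biosense("`thermal` must be a matrix.")
  if (!all(is.finite(thermal))) abort_biosense("Temperatures must be finite.")
  assert_number(timestamp, "timestamp", lower = 0)
  structure(
    list(visible = visible, thermal = thermal, timestamp = timestamp,
         plausible_skin = all(thermal >= 0 & thermal <= 60)),
    class = "thermal_pair"
  )
}

#' Detect the eye region, falling back to the whole face
#'
#' Fallback order is fixed: an eye-region box when the detector finds one,
#' else the whole-face box, else `NULL` ("no subject"; the caller skips and
#' logs the frame). The detector is pluggable; the shipped reference
#' detector ([detect_roi_reference()]) is a classical intensity/color
#' heuristic adequate for the synthetic scenes this package generates and
#' for controlled-booth imagery, not a general-purpose face detector.
#'
#' @param visible `H x W x 3` color image (values `[0, 255]`).
#' @param detector Detection function `(visible) -> detected_roi | NULL`.
#' @return A `detected_roi` (fields `box` ([face_roi()]), `kind` = `"eyes"`
#'   or `"face"`, `confidence` in `[0, 1]`), or `NULL` when no subject is
#'   found.
#' @export
detect_roi <- function(visible, detector = detect_roi_reference) {
  res <- detector(visible)
  if (is.null(res)) return(NULL)
  if (!inherits(res, "detected_roi")) abort_biosense("Detector must return a detected_roi or NULL.")
  res
}

#' @rdname detect_roi
#' @param box A [face_roi()].
#' @param kind `"eyes"` or `"face"`.
#' @param confidence Detection confidence in `[0, 1]`.
#' @export
detected_roi <- function(box, kind = c("eyes", "face"), confidence = 1) {
  kind <- match.arg(kind)
  assert_number(confidence, "confidence", lower = 0, upper = 1)
  structure(list(box = box, kind = kind, confidence = confidence),
            class = "detected_roi")
}

#' Reference sliding-window detector for booth scenes
#'
#' Finds the face as the bounding box of skin-colored pixels (red channel
#' dominant and bright), then looks for the eye band as a dark horizontal
#' stripe in the upper half of the face. Returns an eye-region
#' `detected_roi` when the dark band is found, a whole-face one when not,
#' and `NULL` when too few skin pixels exist.
#'
#' @param visible `H x W x 3` color image, values `[0, 255]`.
#' @param min_face_frac Minimum fraction of image pixels that must look like
#'   skin for a subject to be declared.
#' @param eye_contrast Minimum darkness contrast (intensity units) between
#'   the face median and the eye band.
#' @return A `detected_roi` or `NULL`.
#' @export
detect_roi_reference <- function(visible, min_face_frac = 0.005, eye_contrast = 40) {
  r <- visible[, , 1]; g <- visible[, , 2]; b <- visible[, , 3]
  v <- (r + g + b) / 3
  skin <- r > 100 & r > b & v > 60
  if (mean(skin) < min_face_frac) return(NULL)
  rows <- which(rowSums(skin) > 0)
  cols <- which(colSums(skin) > 0)
  face_box <- face_roi(x = min(cols) - 1L, y = min(rows) - 1L,
                       w = diff(range(cols)) + 1L, h = diff(range(rows)) + 1L)
  # eye band: dark pixels in the upper half of the face *interior* (between
  # the outermost skin pixels of each row, so background corners of the
  # bounding box cannot masquerade as eyes)
  face_med <- stats::median(v[skin])
  interior <- matrix(FALSE, nrow = nrow(v), ncol = ncol(v))
  upper_rows <- min(rows):floor(min(rows) + 0.55 * (diff(range(rows)) + 1L))
  for (r in upper_rows) {
    sc <- which(skin[r, ])
    if (length(sc) >= 2L) interior[r, min(sc):max(sc)] <- TRUE
  }
  dark <- interior & v < (face_med - eye_contrast)
  if (sum(dark) >= 0.002 * sum(skin)) {
    drows <- which(rowSums(dark) > 0)
    dcols <- which(colSums(dark) > 0)
    conf <- min(1, (face_med - stats::median(v[dark])) / 255)
    return(detected_roi(
      face_roi(x = min(dcols) - 1L, y = min(drows) - 1L,
               w = diff(range(dcols)) + 1L, h = diff(range(drows)) + 1L),
      kind = "eyes", confidence = conf))
  }
  detected_roi(face_box, kind = "face", confidence = 0.5)
}

#' Co-register the visible and thermal images
#'
#' Produces the affine transform mapping visible-image pixel coordinates to
#' thermal-raster coordinates. With the default calibration the transform is
#' an axis-aligned scale (ratio of the two image sizes) plus a configured
#' pixel offset; with landmark calibration it is the least-squares affine
#' over >= 3 corresponding point pairs.
#'
#' @param pair A [thermal_pair()].
#' @param calibration `NULL` (size-ratio scale, zero offset),
#'   `list(offset = c(dx, dy))` in thermal pixels, or
#'   `list(landmarks = list(visible = <n x 2>, thermal = <n x 2>))`.
#' @return An object of class `registration`: `A` (2 x 3 affine matrix,
#'   `thermal_xy = A %*% c(vis_x, vis_y, 1)`) and `residual` (RMS px).
#' @export
register <- function(pair, calibration = NULL) {
  if (!inherits(pair, "thermal_pair")) abort_biosense("`pair` must be a thermal_pair.")
  if (!is.null(calibration) && !is.null(calibration$landmarks)) {
    vis <- as.matrix(calibration$landmarks$visible)
    th <- as.matrix(calibration$landmarks$thermal)
    if (nrow(vis) < 3L || nrow(th) != nrow(vis)) {
      abort_biosense("Landmark calibration needs >= 3 corresponding point pairs.")
    }
    M <- cbind(vis, 1)
    # least-squares row-wise: th_x ~ M, th_y ~ M
    bx <- qr.solve(M, th[, 1])
    by <- qr.solve(M, th[, 2])
    A <- rbind(bx, by)
    fit <- M %*% t(A)
    residual <- sqrt(mean((fit - th)^2))
  } else {
    dv <- dim(pair$visible); dt <- dim(pair$thermal)
    sx <- dt[2] / dv[2]
    sy <- dt[1] / dv[1]
    off <- (calibration$offset %||% c(0, 0))
    A <- rbind(c(sx, 0, off[1]), c(0, sy, off[2]))
    residual <- 0
  }
  det2 <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (abs(det2) < 1e-12) abort_biosense("Registration transform is not invertible.")
  structure(list(A = unname(A), residual = residual), class = "registration")
}

#' Apply / invert a registration
#'
#' @param reg A [register()] result.
#' @param xy `n x 2` matrix of visible coordinates.
#' @return `n x 2` matrix of thermal coordinates.
#' @export
apply_registration <- function(reg, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  t(reg$A %*% rbind(t(xy), 1))
}

invert_registration <- function(reg) {
  A <- reg$A
  L <- A[, 1:2]
  Linv <- solve(L)
  cbind(Linv, -Linv %*% A[, 3])
}

#' Maximum temperature inside a detected region
#'
#' The region found in the visible image is mapped into the thermal raster
#' through the registration, and the maximum temperature over the thermal
#' pixels whose centers fall inside the mapped (half-open) box is returned —
#' the per-frame skin-temperature reading.
#'
#' @param pair A [thermal_pair()].
#' @param roi A [face_roi()] in visible coordinates (or a `detected_roi`).
#' @param reg A [register()] result.
#' @return Maximum temperature in deg C.
#' @export
max_temperature <- function(pair, roi, reg) {
  if (inherits(roi, "detected_roi")) roi <- roi$box
  th <- pair$thermal
  h <- nrow(th); w <- ncol(th)
  inv <- invert_registration(reg)
  # thermal pixel centers, 0-based
  cx <- rep(seq_len(w) - 0.5, each = h)
  cy <- rep(seq_len(h) - 0.5, times = w)
  vis <- inv %*% rbind(cx, cy, 1)
  inside <- vis[1, ] >= roi$x & vis[1, ] < roi$x + roi$w &
            vis[2, ] >= roi$y & vis[2, ] < roi$y + roi$h
  if (!any(inside)) abort_biosense("Transformed ROI covers no thermal pixels.")
  # cx/cy enumerate the raster in column-major order, matching as.vector(th)
  max(as.vector(th)[inside])
}

#' Skin-temperature series over a session
#'
#' Runs detection, registration and maximum-temperature extraction over a
#' sequence of visible/thermal pairs, yielding the skin-temperature-over-time
#' curve. Frames where no subject is detected are skipped and logged.
#'
#' @param pairs List of [thermal_pair()]s (>= 1), timestamps increasing.
#' @param detector Detection function, as in [detect_roi()].
#' @param calibration Registration calibration, as in [register()].
#' @return Tibble of class `temperature_series` with columns `time`,
#'   `temp_c`, `roi_kind`; skipped frames are recorded in the `failures`
#'   attribute (tibble of `time`, `reason`).
#' @export
temperature_series <- function(pairs, detector = detect_roi_reference,
                               calibration = NULL) {
  if (length(pairs) == 0L) abort_biosense("Need at least one thermal pair.")
  rows <- list()
  fails <- list()
  for (pair in pairs) {
    roi <- detect_roi(pair$visible, detector)
    if (is.null(roi)) {
      fails[[length(fails) + 1L]] <-
        tibble::tibble(time = pair$timestamp, reason = "no subject")
      next
    }
    reg <- register(pair, calibration)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      time = pair$timestamp,
      temp_c = max_temperature(pair, roi, reg),
      roi_kind = roi$kind)
  }
  fails <- if (length(fails)) dplyr::bind_rows(fails) else
    tibble::tibble(time = numeric(), reason = character())
  if (length(rows) == 0L) {
    abort_biosense(sprintf(
      "No subject detected in any of the %d frames (%s).",
      length(pairs), paste(unique(fails$reason), collapse = "; ")))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "failures") <- fails
  class(out) <- c("temperature_series", class(out))
  out
}

#' Read a temperature raster from CSV or 16-bit TIFF
#'
#' CSV rasters are read as-is (already in deg C unless a sidecar says
#' otherwise); TIFF rasters hold raw counts converted as
#' `deg C = raw * scale + offset`, with `scale`/`offset` taken from the
#' sidecar JSON (fields `scale`, `offset`). Proprietary radiometric formats
#' are out of scope — rasters are expected to be exported upstream.
#'
#' @param path Raster file (`.csv` or `.tif`/`.tiff`).
#' @param sidecar Optional path to a JSON sidecar with `scale` and `offset`.
#' @return Numeric temperature matrix (deg C).
#' @export
read_thermal_raster <- function(path, sidecar = NULL) {
  cal <- list(scale = 1, offset = 0)
  if (!is.null(sidecar)) {
    sc <- jsonlite::fromJSON(sidecar)
    cal$scale <- sc$scale %||% 1
    cal$offset <- sc$offset %||% 0
  }
  raw <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    as.matrix(utils::read.csv(path, header = FALSE))
  } else {
    tiff::readTIFF(path, as.is = TRUE)
  }
  unname(raw * cal$scale + cal$offset)
}
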