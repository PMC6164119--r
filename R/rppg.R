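#' Video clips and face regions of interest
#'
#' A `video_clip` holds a color frame sequence as an `H x W x 3 x T` numeric
#' array (values in `[0, 255]`) plus its frame rate. The default capture
#' profile of the integrated tablet camera is 1640 x 1232 px (4:3) at 30 fps;
#' [capture_profile()] exposes those defaults.
#'
#' @param frames Numeric `H x W x 3 x T` array of frames.
#' @param fps Frames per second (> 0).
#' @return An object of class `video_clip` with fields `frames`, `fps`,
#'   `width`, `height`, `n_frames`, `duration`.
#' @export
video_clip <- function(frames, fps) {
  assert_number(fps, "fps", lower = 1e-9)
  d <- dim(frames)
  if (length(d) != 4L || d[3] != 3L) {
    abort_biosense("`frames` must be an H x W x 3 x T array.")
  }
  structure(
    list(frames = frames, fps = fps, height = d[1], width = d[2],
         n_frames = d[4], duration = d[4] / fps),
    class = "video_clip"
  )
}

#' @export
print.video_clip <- function(x, ...) {
  cat(sprintf("<video_clip> %d x %d px, %d frames @ %g fps (%.1f s)\n",
              x$width, x$height, x$n_frames, x$fps, x$duration))
  invisible(x)
}

#' Default capture profile of the integrated camera
#'
#' @return List with `width` (1640 px), `height` (1232 px), `fps` (30) and
#'   `thermal_interval_s` (2 s between infrared thermal images).
#' @export
capture_profile <- function() {
  list(width = 1640L, height = 1232L, fps = 30L, thermal_interval_s = 2)
}

#' Read a clip from a directory of frame images
#'
#' Frames are read in lexicographic filename order; PNG and TIFF are
#' supported. Pixel values are rescaled to `[0, 255]`.
#'
#' @param dir Directory containing the frame images.
#' @param fps Frame rate to attach (images carry none).
#' @return A [video_clip()].
#' @export
read_frame_dir <- function(dir, fps = capture_profile()$fps) {
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L) abort_biosense(sprintf("No frame images found in '%s'.", dir))
  read1 <- function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
      png::readPNG(f)
    } else {
      tiff::readTIFF(f)
    }
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
    img[, , 1:3, drop = FALSE] * 255
  }
  first <- read1(files[[1]])
  frames <- array(0, dim = c(dim(first)[1:2], 3L, length(files)))
  frames[, , , 1L] <- first
  for (i in seq_along(files)[-1L]) frames[, , , i] <- read1(files[[i]])
  video_clip(frames, fps)
}

#' Face region of interest
#'
#' Pixel bounding box, origin top-left, 0-based, half-open: the box covers
#' columns `x .. x+w-1` and rows `y .. y+h-1` in 0-based indexing.
#'
#' @param x,y Top-left corner (0-based pixels).
#' @param w,h Width and height in pixels (> 0).
#' @return An object of class `face_roi`.
#' @export
face_roi <- function(x, y, w, h) {
  assert_number(x, "x", lower = 0); assert_number(y, "y", lower = 0)
  assert_number(w, "w", lower = 1); assert_number(h, "h", lower = 1)
  structure(list(x = as.integer(x), y = as.integer(y),
                 w = as.integer(w), h = as.integer(h)),
            class = "face_roi")
}

roi_in_frame <- function(roi, width, height) {
  roi$x >= 0 && roi$y >= 0 && roi$x + roi$w <= width && roi$y + roi$h <= height
}

#' Extract the green-channel photoplethysmographic signal
#'
#' The remote-PPG principle: blood-volume pulsation modulates skin
#' reflectance most strongly in the green color component, so the spatial
#' mean of the green channel over the face region, taken per frame, carries
#' the pulse. One sample per frame; the sample rate equals the frame rate.
#'
#' @param clip A [video_clip()].
#' @param roi A [face_roi()] inside the frame.
#' @return An object of class `ppg_signal`: `samples`, `rate`,
#'   `detrended = FALSE`, `band = NULL`.
#' @export
extract_green_signal <- function(clip, roi) {
  if (!inherits(clip, "video_clip")) abort_biosense("`clip` must be a video_clip.")
  if (!inherits(roi, "face_roi")) abort_biosense("`roi` must be a face_roi.")
  if (!roi_in_frame(roi, clip$width, clip$height)) {
    abort_biosense("ROI extends outside the frame bounds.")
  }
  if (clip$n_frames < 2L) abort_biosense("Need at least 2 frames.")
  rows <- (roi$y + 1L):(roi$y + roi$h)
  cols <- (roi$x + 1L):(roi$x + roi$w)
  green <- clip$frames[rows, cols, 2L, , drop = FALSE]
  samples <- apply(green, 4L, mean)
  ppg_signal(samples, clip$fps)
}

#' PPG signal container
#'
#' @param samples Numeric vector, one mean green intensity per frame.
#' @param rate Samples per second (equals the source fps).
#' @param detrended Has the signal been detrended/band-passed?
#' @param band Pass band in Hz after filtering, or `NULL`.
#' @return An object of class `ppg_signal`.
#' @export
ppg_signal <- function(samples, rate, detrended = FALSE, band = NULL) {
  if (!all(is.finite(samples))) abort_biosense("PPG samples must be finite.")
  assert_number(rate, "rate", lower = 1e-9)
  structure(list(samples = as.numeric(samples), rate = rate,
                 detrended = detrended, band = band,
                 duration = length(samples) / rate),
            class = "ppg_signal")
}

#' @export
print.ppg_signal <- function(x, ...) {
  cat(sprintf("<ppg_signal> %d samples @ %g Hz (%.1f s)%s\n",
              length(x$samples), x$rate, x$duration,
              if (x$detrended) sprintf(", band-passed %.2g-%.2g Hz",
                                       x$band[1], x$band[2]) else ", raw"))
  invisible(x)
}

#' Detrend and band-pass a PPG signal
#'
#' Removes the linear trend, then applies a zero-phase 4th-order Butterworth
#' band-pass (forward-backward filtering, so no phase distortion). The
#' default band 0.7-4.0 Hz is the conventional physiological pulse band
#' (42-240 beats/min).
#'
#' @param signal A [ppg_signal()].
#' @param band Pass band `c(low, high)` in Hz, inside `(0, rate/2)`.
#' @return A detrended, band-passed `ppg_signal` with near-zero mean.
#' @export
preprocess_ppg <- function(signal, band = c(0.7, 4.0)) {
  if (!inherits(signal, "ppg_signal")) abort_biosense("`signal` must be a ppg_signal.")
  nyq <- signal$rate / 2
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= nyq) {
    abort_biosense(sprintf(
      "Band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz).",
      band[1], band[2], nyq))
  }
  x <- signal$samples
  t <- seq_along(x)
  x <- stats::residuals(stats::lm.fit(cbind(1, t), x))
  bf <- signal::butter(2, band / nyq, type = "pass")
  y <- signal::filtfilt(bf, x)
  ppg_signal(y - mean(y), signal$rate, detrended = TRUE, band = band)
}

# Welch-averaged periodogram: Hann-windowed overlapping segments, zero-padded
# for fine frequency resolution. Returns one-sided freq/power.
welch_psd <- function(x, fs, segment_s = 10, overlap = 0.5, nfft = 4096) {
  n <- length(x)
  L <- min(n, max(8L, round(segment_s * fs)))
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  nfft <- max(nfft, L)
  acc <- numeric(nfft)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(c(seg, numeric(nfft - L))))^2
  }
  half <- seq_len(nfft %/% 2 + 1L)
  list(freq = (half - 1L) * fs / nfft,
       power = acc[half] / (length(starts) * sum(w^2) * fs))
}

#' Estimate heart rate from a preprocessed PPG signal
#'
#' Locates the dominant spectral peak inside the signal's pass band on a
#' Welch-averaged periodogram (10-s Hann segments, 50% overlap) and refines
#' it by parabolic interpolation of the three bins around the maximum.
#' Heart rate is 60 times the dominant frequency.
#'
#' @param signal A band-passed [ppg_signal()] (see [preprocess_ppg()]),
#'   at least 10 s long.
#' @param min_peak_ratio Minimum ratio of the peak power to the median
#'   in-band power; below it no pulse is declared.
#' @return Heart rate in beats/min, or `NA` (with a `biosense_no_pulse`
#'   warning) when no spectral peak rises above the noise floor.
#' @export
estimate_heart_rate <- function(signal, min_peak_ratio = 5) {
  if (!inherits(signal, "ppg_signal")) abort_biosense("`signal` must be a ppg_signal.")
  if (!signal$detrended) abort_biosense("Preprocess the signal first (preprocess_ppg).")
  if (signal$duration < 10) {
    abort_biosense("Heart-rate estimation needs at least 10 s of signal.")
  }
  band <- signal$band %||% c(0.7, 4.0)
  if (sqrt(mean(signal$samples^2)) < 1e-9) {
    warning(warningCondition("Flat signal; no pulse detected.",
                             class = "biosense_no_pulse"))
    return(NA_real_)
  }
  ps <- welch_psd(signal$samples, signal$rate)
  sel <- which(ps$freq >= band[1] & ps$freq <= band[2])
  p <- ps$power[sel]
  if (all(p <= 0) || max(p) < min_peak_ratio * stats::median(p[p > 0])) {
    warning(warningCondition("No spectral peak above the noise floor; no pulse detected.",
                             class = "biosense_no_pulse"))
    return(NA_real_)
  }
  k <- which.max(p)
  df <- ps$freq[2] - ps$freq[1]
  f0 <- ps$freq[sel[k]]
  if (k > 1L && k < length(p)) {
    denom <- p[k - 1L] - 2 * p[k] + p[k + 1L]
    if (denom < 0) f0 <- f0 + df * 0.5 * (p[k - 1L] - p[k + 1L]) / denom
  }
  f0 <- min(max(f0, band[1]), band[2])
  60 * f0
}

#' Sliding-window heart-rate track
#'
#' Repeats [estimate_heart_rate()] over sliding windows, yielding the
#' heart-rate-over-time curves used to follow a participant through a
#' tasting.
#'
#' @param signal A band-passed [ppg_signal()].
#' @param window_s Window length in seconds (>= 10).
#' @param step_s Step between window starts in seconds.
#' @return Tibble with columns `time` (window center, s) and `hr_bpm`.
#' @export
heart_rate_track <- function(signal, window_s = 15, step_s = 5) {
  if (!inherits(signal, "ppg_signal")) abort_biosense("`signal` must be a ppg_signal.")
  if (window_s < 10) abort_biosense("`window_s` must be at least 10 s.")
  if (window_s > signal$duration + 1e-9) {
    abort_biosense("Window is longer than the signal.")
  }
  n <- length(signal$samples)
  wlen <- round(window_s * signal$rate)
  step <- max(1L, round(step_s * signal$rate))
  starts <- seq(1L, n - wlen + 1L, by = step)
  hr <- vapply(starts, function(s) {
    win <- ppg_signal(signal$samples[s:(s + wlen - 1L)], signal$rate,
                      detrended = signal$detrended, band = signal$band)
    suppressWarnings(estimate_heart_rate(win))
  }, numeric(1))
  tibble::tibble(time = (starts - 1L + wlen / 2) / signal$rate, hr_bpm = hr)
}

#' Morphological and spectral PPG features
#'
#' Deterministic fixed-length feature vector fed to the vitals regressor:
#' dominant frequency and its peak power and half-power bandwidth, amplitude
#' statistics, inter-beat-interval mean and variability, and mean rise/fall
#' times between troughs and peaks. A flat signal yields zero amplitudes and
#' `low_quality = 1`.
#'
#' @param signal A band-passed [ppg_signal()].
#' @return Named numeric vector of class `ppg_features` with 11 entries:
#'   `f_dom_hz`, `peak_power`, `bandwidth_hz`, `rms`, `amp_mean`, `amp_sd`,
#'   `ibi_mean_s`, `ibi_sd_s`, `rise_time_s`, `fall_time_s`, `low_quality`.
#' @export
extract_features <- function(signal) {
  if (!inherits(signal, "ppg_signal")) abort_biosense("`signal` must be a ppg_signal.")
  if (!signal$detrended) abort_biosense("Preprocess the signal first (preprocess_ppg).")
  x <- signal$samples
  fs <- signal$rate
  band <- signal$band %||% c(0.7, 4.0)
  rms <- sqrt(mean(x^2))
  flat <- rms < 1e-12
  feats <- c(f_dom_hz = 0, peak_power = 0, bandwidth_hz = 0, rms = rms,
             amp_mean = 0, amp_sd = 0, ibi_mean_s = 0, ibi_sd_s = 0,
             rise_time_s = 0, fall_time_s = 0, low_quality = as.numeric(flat))
  if (flat) return(structure(feats, class = c("ppg_features", "numeric")))

  ps <- welch_psd(x, fs)
  sel <- which(ps$freq >= band[1] & ps$freq <= band[2])
  p <- ps$power[sel]
  k <- which.max(p)
  feats["f_dom_hz"] <- ps$freq[sel[k]]
  feats["peak_power"] <- p[k]
  half <- p >= p[k] / 2
  feats["bandwidth_hz"] <- sum(half) * (ps$freq[2] - ps$freq[1])

  mind <- max(1L, round(fs * 0.25))
  pk <- pracma::findpeaks(x, minpeakdistance = mind, minpeakheight = 0)
  tr <- pracma::findpeaks(-x, minpeakdistance = mind, minpeakheight = 0)
  if (!is.null(pk) && nrow(pk) >= 2L) {
    locs <- sort(pk[, 2])
    amps <- x[locs]
    feats["amp_mean"] <- mean(amps)
    feats["amp_sd"] <- stats::sd(amps)
    ibi <- diff(locs) / fs
    feats["ibi_mean_s"] <- mean(ibi)
    feats["ibi_sd_s"] <- stats::sd(ibi)
  } else {
    feats["low_quality"] <- 1
  }
  if (!is.null(pk) && !is.null(tr) && nrow(pk) >= 1L && nrow(tr) >= 1L) {
    plocs <- sort(pk[, 2]); tlocs <- sort(tr[, 2])
    rises <- vapply(plocs, function(pp) {
      prev <- tlocs[tlocs < pp]
      if (length(prev)) (pp - max(prev)) / fs else NA_real_
    }, numeric(1))
    falls <- vapply(plocs, function(pp) {
      nxt <- tlocs[tlocs > pp]
      if (length(nxt)) (min(nxt) - pp) / fs else NA_real_
    }, numeric(1))
    if (any(!is.na(rises))) feats["rise_time_s"] <- mean(rises, na.rm = TRUE)
    if (any(!is.na(falls))) feats["fall_time_s"] <- mean(falls, na.rm = TRUE)
  }
  structure(feats, class = c("ppg_features", "numeric"))
}
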