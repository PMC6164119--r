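#' Synthetic face video with an injected pulse
#'
#' Renders a parametric face — a skin-tone ellipse with a dark eye band on a
#' dark background — and modulates the green channel inside the face at the
#' requested pulse frequency, adding white Gaussian noise. The stated SNR is
#' defined at the pooled-signal level: it is the power ratio between the
#' pulse modulation and the noise remaining in the spatial mean over the
#' returned face box, so it is meaningful regardless of frame size.
#' Deterministic per seed.
#'
#' @param hr_bpm True heart rate (42-240 beats/min).
#' @param duration_s Clip length in seconds (a warning is given below 10 s,
#'   where spectral heart-rate estimation is unreliable).
#' @param fps Frames per second (default: capture profile, 30).
#' @param snr_db Pooled signal-to-noise ratio in dB; `Inf` for noise-free.
#' @param seed Integer seed (mandatory).
#' @param width,height Frame size in pixels (default: capture profile,
#'   1640 x 1232).
#' @param amplitude Peak green modulation in intensity units.
#' @return List: `clip` ([video_clip()]), `roi` (face box, [face_roi()]),
#'   `hr_bpm`, `f_hz` (ground truth).
#' @export
generate_face_video <- function(hr_bpm, duration_s = 30, fps = capture_profile()$fps,
                                snr_db = 10, seed,
                                width = capture_profile()$width,
                                height = capture_profile()$height,
                                amplitude = 2) {
  assert_number(hr_bpm, "hr_bpm", lower = 42, upper = 240)
  assert_number(seed, "seed")
  if (duration_s < 10) warning("Clips under 10 s give unreliable heart-rate estimates.")
  n <- max(2L, round(duration_s * fps))
  scene <- synth_face_scene(height, width)
  box <- mask_box(scene$face_mask)
  n_box <- box$w * box$h
  fill <- sum(scene$face_mask[(box$y + 1):(box$y + box$h),
                              (box$x + 1):(box$x + box$w)]) / n_box
  sigma_pix <- if (is.infinite(snr_db)) 0 else
    (amplitude * fill / sqrt(2)) / 10^(snr_db / 20) * sqrt(n_box)
  f_hz <- hr_bpm / 60
  tt <- (seq_len(n) - 1L) / fps
  mod <- amplitude * sin(2 * pi * f_hz * tt)
  frames <- with_local_seed(seed, {
    fr <- array(0, dim = c(height, width, 3L, n))
    for (i in seq_len(n)) {
      frame <- scene$base
      frame[, , 2] <- frame[, , 2] + mod[i] * scene$face_mask
      if (sigma_pix > 0) {
        frame <- frame + array(stats::rnorm(height * width * 3L, sd = sigma_pix),
                               dim = c(height, width, 3L))
      }
      fr[, , , i] <- pmin(pmax(frame, 0), 255)
    }
    fr
  })
  list(clip = video_clip(frames, fps),
       roi = face_roi(box$x, box$y, box$w, box$h),
       hr_bpm = hr_bpm, f_hz = f_hz)
}

# Base face scene: returns base HxWx3 image, face mask, eye mask.
synth_face_scene <- function(height, width, eyes = TRUE) {
  yy <- matrix(seq_len(height), nrow = height, ncol = width)
  xx <- matrix(seq_len(width), nrow = height, ncol = width, byrow = TRUE)
  cx <- width / 2; cy <- height / 2
  ax <- 0.30 * width; ay <- 0.40 * height
  face <- ((xx - cx) / ax)^2 + ((yy - cy) / ay)^2 <= 1
  eye_mask <- matrix(FALSE, height, width)
  if (eyes) {
    ey <- cy - 0.45 * ay
    eh <- max(1, round(0.08 * ay))
    ew <- max(1, round(0.22 * ax))
    for (ex in c(cx - 0.45 * ax, cx + 0.45 * ax)) {
      eye_mask <- eye_mask |
        (abs(yy - ey) <= eh & abs(xx - ex) <= ew & face)
    }
  }
  base <- array(40, dim = c(height, width, 3L))
  skin <- c(205, 150, 120)
  for (ch in 1:3) {
    plane <- base[, , ch]
    plane[face] <- skin[ch]
    plane[eye_mask] <- 25
    base[, , ch] <- plane
  }
  list(base = base, face_mask = face * 1, eye_mask = eye_mask)
}

mask_box <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  list(x = min(cols) - 1L, y = min(rows) - 1L,
       w = diff(range(cols)) + 1L, h = diff(range(rows)) + 1L)
}

#' Synthetic visible/thermal pair sequence
#'
#' Pairs at the 2-s capture interval. The visible image shows the parametric
#' face in one of three scene classes — `"eyes"` (dark eye band present),
#' `"occluded"` (face without a detectable eye band) and `"none"` (no
#' subject) — exercising the full detection fallback chain. The thermal
#' raster (half the visible resolution) places its hottest pixels, at the
#' requested ground-truth temperature, in the eye region; radiometric noise
#' defaults to 0.02 deg C (within the sensitivity of modern radiometric
#' cameras, and small enough that the upward bias of a maximum over the
#' few-dozen ROI pixels stays well inside a 0.1 deg C reading tolerance).
#'
#' @param n_pairs Number of pairs.
#' @param temps_c Ground-truth eye temperature per pair (deg C); defaults to
#'   a 34.0 -> 35.8 ramp.
#' @param scenes Scene class per pair (recycled), subset of
#'   `c("eyes", "occluded", "none")`.
#' @param interval_s Capture interval in seconds (default 2).
#' @param noise_sd Radiometric noise sd, deg C.
#' @param seed Integer seed (mandatory).
#' @param width,height Visible image size (thermal raster is half each way).
#' @return List: `pairs` (list of [thermal_pair()]) and `truth`
#'   (tibble `time`, `temp_c`, `scene`).
#' @export
generate_thermal_sequence <- function(n_pairs = 10,
                                      temps_c = seq(34.0, 35.8, length.out = n_pairs),
                                      scenes = "eyes", interval_s = 2,
                                      noise_sd = 0.02, seed,
                                      width = 80, height = 60) {
  assert_number(seed, "seed")
  if (length(temps_c) != n_pairs) abort_biosense("`temps_c` must have one value per pair.")
  scenes <- rep_len(scenes, n_pairs)
  th_h <- height %/% 2L; th_w <- width %/% 2L
  with_local_seed(seed, {
    pairs <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      scene_kind <- scenes[i]
      if (scene_kind == "none") {
        visible <- array(40 + stats::rnorm(height * width * 3L, sd = 2),
                         dim = c(height, width, 3L))
        thermal <- matrix(25 + stats::rnorm(th_h * th_w, sd = noise_sd), th_h, th_w)
      } else {
        sc <- synth_face_scene(height, width, eyes = scene_kind == "eyes")
        visible <- pmin(pmax(sc$base +
          array(stats::rnorm(height * width * 3L, sd = 2),
                dim = c(height, width, 3L)), 0), 255)
        # thermal: background 25, face 33.2, hot plateau at the eye line
        sc_th <- synth_face_scene(th_h, th_w, eyes = TRUE)
        thermal <- matrix(25, th_h, th_w)
        thermal[sc_th$face_mask > 0] <- temps_c[i] - 0.8
        hot <- sc_th$eye_mask
        thermal[hot] <- temps_c[i]
        thermal <- thermal + matrix(stats::rnorm(th_h * th_w, sd = noise_sd), th_h, th_w)
      }
      pairs[[i]] <- thermal_pair(visible, thermal, timestamp = (i - 1L) * interval_s)
    }
    list(pairs = pairs,
         truth = tibble::tibble(time = (seq_len(n_pairs) - 1L) * interval_s,
                                temp_c = temps_c, scene = scenes))
  })
}

#' Scenario specification for a full synthetic session
#'
#' Defines the study conditions emulated by [generate_session()]: the
#' samples (stimuli), per-sample ground-truth means for the conscious
#' responses, heart rate, blood pressure, skin temperature and emotion
#' components, and the noise levels around them.
#'
#' @param samples Character vector of sample names (k >= 1).
#' @param n_participants Number of participants (n >= 1).
#' @param questions Character vector of question descriptors asked per
#'   sample (answered on the face scale, 0-100).
#' @param liking_means `k x length(questions)` matrix of true mean responses.
#' @param liking_sd Participant response sd on the face scale.
#' @param hr_means,hr_sd True heart-rate means (bpm, within 42-240) and sd.
#' @param ir_means,ir_sd True skin-temperature means (deg C) and sd.
#' @param emotion_means `k x 13` matrix over [emotion_table] numeric
#'   components (eight emotions, valence, arousal, head x/y/z).
#' @param emotion_sd Participant sd on each emotion intensity.
#' @param classes Optional factor of planted sample classes (ground truth
#'   for cluster-recovery checks).
#' @param assessment Assessment kind written to response files.
#' @param seed Integer seed (mandatory).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(samples, n_participants, questions, liking_means,
                          liking_sd = 10, hr_means = NULL, hr_sd = 4,
                          ir_means = NULL, ir_sd = 0.3,
                          emotion_means = NULL, emotion_sd = 0.08,
                          classes = NULL, assessment = "Image", seed) {
  assert_number(n_participants, "n_participants", lower = 1)
  assert_number(seed, "seed")
  k <- length(samples)
  if (k < 1L) abort_biosense("Need at least one sample.")
  liking_means <- matrix(liking_means, nrow = k,
                         dimnames = list(samples, questions))
  hr_means <- hr_means %||% rep(72, k)
  if (any(hr_means < 42 | hr_means > 240)) {
    abort_biosense("hr_means must lie within 42-240 bpm.")
  }
  ir_means <- ir_means %||% rep(34.5, k)
  if (is.null(emotion_means)) {
    emotion_means <- matrix(rep(c(0.2, 0.5, 0.05, 0.03, 0.05, 0.04, 0.04, 0.05,
                                  0, 0.4, 0, 0, 0), each = k),
                            nrow = k)
  }
  colnames(emotion_means) <- emotion_numeric_cols()
  rownames(emotion_means) <- samples
  structure(
    list(samples = samples, n_participants = as.integer(n_participants),
         questions = questions, liking_means = liking_means,
         liking_sd = liking_sd, hr_means = hr_means, hr_sd = hr_sd,
         ir_means = ir_means, ir_sd = ir_sd,
         emotion_means = emotion_means, emotion_sd = emotion_sd,
         classes = classes, assessment = assessment, seed = as.integer(seed)),
    class = "scenario_spec")
}

# Class-conditional emotion profiles for affective image stimuli.
valence_class_profiles <- function() {
  rbind(
    positive = c(happy = 0.55, neutral = 0.25, sad = 0.03, scared = 0.02,
                 surprised = 0.08, angry = 0.02, contempt = 0.02,
                 disgusted = 0.03, valence = 0.5, arousal = 0.5,
                 x_head = 0, y_head = 0, z_head = 0),
    neutral = c(happy = 0.15, neutral = 0.60, sad = 0.05, scared = 0.03,
                surprised = 0.05, angry = 0.04, contempt = 0.04,
                disgusted = 0.04, valence = 0, arousal = 0.3,
                x_head = 0, y_head = 0, z_head = 0),
    negative = c(happy = 0.04, neutral = 0.20, sad = 0.20, scared = 0.15,
                 surprised = 0.10, angry = 0.12, contempt = 0.07,
                 disgusted = 0.22, valence = -0.5, arousal = 0.6,
                 x_head = 0, y_head = 0, z_head = 0))
}

#' Affective-image session scenario (three planted valence classes)
#'
#' Nine image stimuli — three positive, three neutral, three negative — shown
#' to `n_participants` panelists who answer one face-scale question per
#' image, emulating an affective-picture session. Face-scale means are 75 /
#' 50 / 25 by class and the emotion profiles are class-conditional, with
#' per-image offsets so images are distinct within a class.
#'
#' @param n_participants Panel size (default 59).
#' @param seed Integer seed.
#' @return A [scenario_spec()] with `classes` set to the planted classes.
#' @export
scenario_affective_images <- function(n_participants = 59, seed) {
  assert_number(seed, "seed")
  samples <- c("Baby", "Dog", "Beach", "Door", "Wheel", "Stairs",
               "Spider", "Dentist", "Dark room")
  classes <- factor(rep(c("positive", "neutral", "negative"), each = 3),
                    levels = c("positive", "neutral", "negative"))
  prof <- valence_class_profiles()[as.character(classes), ]
  fs_class <- c(positive = 75, neutral = 50, negative = 25)[as.character(classes)]
  with_local_seed(seed * 7919 + 1, {
    fs_means <- pmin(pmax(fs_class + stats::rnorm(9, sd = 4), 0), 100)
    emotion_means <- prof
    em8 <- emotion_names()
    emotion_means[, em8] <- pmin(pmax(
      prof[, em8] + matrix(stats::rnorm(9 * 8, sd = 0.02), 9, 8), 0), 1)
    hr_means <- c(positive = 72, neutral = 70, negative = 76)[as.character(classes)] +
      stats::rnorm(9, sd = 1)
    ir_means <- c(positive = 34.8, neutral = 34.5, negative = 34.2)[as.character(classes)] +
      stats::rnorm(9, sd = 0.05)
    scenario_spec(samples = samples, n_participants = n_participants,
                  questions = "FS", liking_means = fs_means, liking_sd = 12,
                  hr_means = hr_means, hr_sd = 5,
                  ir_means = ir_means, ir_sd = 0.3,
                  emotion_means = emotion_means, emotion_sd = 0.08,
                  classes = classes, assessment = "Image", seed = seed)
  })
}

#' Beer-tasting session scenario
#'
#' Nine commercial beer styles evaluated by `n_participants` consumers on
#' seven face-scale liking questions (foam stability and height, aroma,
#' bitterness, carbonation mouthfeel, flavor, overall), with per-style
#' physiological ground truth.
#'
#' @param n_participants Panel size (default 30).
#' @param seed Integer seed.
#' @return A [scenario_spec()].
#' @export
scenario_beer <- function(n_participants = 30, seed) {
  assert_number(seed, "seed")
  samples <- c("Porter", "Aged ale", "Kolsch", "Lager", "American lager",
               "Pilsner", "Lambic cassis", "Lambic framboise", "Lambic kriek")
  questions <- c("FStability", "FHeight", "Aroma", "TBitter", "MCarb",
                 "Flavor", "Overall")
  with_local_seed(seed * 7919 + 2, {
    liking_means <- matrix(pmin(pmax(stats::rnorm(9 * 7, mean = 55, sd = 12), 5), 95),
                           nrow = 9, dimnames = list(samples, questions))
    hr_means <- stats::rnorm(9, mean = 72, sd = 3)
    ir_means <- stats::rnorm(9, mean = 34.5, sd = 0.2)
    scenario_spec(samples = samples, n_participants = n_participants,
                  questions = questions, liking_means = liking_means,
                  liking_sd = 10, hr_means = hr_means, hr_sd = 4,
                  ir_means = ir_means, ir_sd = 0.3,
                  assessment = "Tasting", seed = seed)
  })
}

#' Generate a full synthetic session
#'
#' Draws per-(participant, sample) conscious and subconscious data from the
#' scenario's ground truth: face-scale responses from truncated normal
#' distributions, rankings consistent with each participant's own overall
#' draws, emotion rows correlated with the sample's emotion profile, heart
#' rate / blood pressure / skin temperature around the sample means. Blood
#' pressure follows the heart rate (sp = 90 + 0.45 hr, dp = 55 + 0.30 hr,
#' plus noise), so the vitals block is internally consistent.
#'
#' @param spec A [scenario_spec()].
#' @return List of tibbles keyed by `participant` and `sample`:
#'   `responses` (`question`, `value`, `time`), `rank` (`position` per
#'   participant), `emotions` ([emotion_table] components), `vitals`
#'   (`hr`, `sp`, `dp`), `temps` (`temp_c`), `response_files` (named
#'   character vector of Table-dialect file texts, one per participant),
#'   and `truth` (the generating [scenario_spec()]).
#' @export
generate_session <- function(spec) {
  if (!inherits(spec, "scenario_spec")) abort_biosense("`spec` must be a scenario_spec.")
  k <- length(spec$samples)
  nq <- length(spec$questions)
  with_local_seed(spec$seed * 7919 + 3, {
    rows <- vector("list", spec$n_participants)
    em_rows <- vector("list", spec$n_participants)
    vit_rows <- vector("list", spec$n_participants)
    tmp_rows <- vector("list", spec$n_participants)
    rank_rows <- vector("list", spec$n_participants)
    files <- character(spec$n_participants)
    names(files) <- sprintf("P%02d", seq_len(spec$n_participants))
    em8 <- emotion_names()
    for (p in seq_len(spec$n_participants)) {
      pid <- names(files)[p]
      order_codes <- randomize_presentation(spec$samples, pid, spec$seed)
      vals <- matrix(0, k, nq, dimnames = list(spec$samples, spec$questions))
      for (q in seq_len(nq)) {
        vals[, q] <- pmin(pmax(
          spec$liking_means[, q] + stats::rnorm(k, sd = spec$liking_sd), 0), 100)
      }
      t0 <- 10 * 3600 + (p - 1L) * 60
      times <- format_time_of_day(t0 + 90 * seq_len(k * nq))
      resp <- tibble::tibble(
        participant = pid,
        assessment = spec$assessment,
        sample = rep(order_codes, each = nq),
        question = rep(spec$questions, times = k),
        value = round(as.numeric(t(vals[order_codes, , drop = FALSE]))),
        time = times)
      rows[[p]] <- resp
      # ranking: most to least preferred by this participant's own draws
      pref <- vals[, nq]
      ord <- order(pref, decreasing = TRUE)
      rank_rows[[p]] <- tibble::tibble(participant = pid,
                                       sample = spec$samples[ord],
                                       position = seq_len(k))
      em <- spec$emotion_means +
        matrix(stats::rnorm(k * 13, sd = spec$emotion_sd), k, 13)
      em[, em8] <- pmin(pmax(em[, em8], 0), 1)
      em[, "valence"] <- pmin(pmax(em[, "valence"], -1), 1)
      em[, "arousal"] <- pmin(pmax(em[, "arousal"], 0), 1)
      em[, c("x_head", "y_head", "z_head")] <-
        em[, c("x_head", "y_head", "z_head")] +
        matrix(stats::rnorm(k * 3, sd = 5), k, 3)
      em_rows[[p]] <- dplyr::bind_cols(
        tibble::tibble(participant = pid, sample = spec$samples,
                       timestamp = (seq_len(k) - 1) * 10),
        tibble::as_tibble(em),
        tibble::tibble(gaze = sample(c("forward", "left", "right", "down"),
                                     k, replace = TRUE, prob = c(.7, .1, .1, .1))))
      hr <- spec$hr_means + stats::rnorm(k, sd = spec$hr_sd)
      sp <- 90 + 0.45 * hr + stats::rnorm(k, sd = 3)
      dp <- pmin(55 + 0.30 * hr + stats::rnorm(k, sd = 2), sp - 5)
      vit_rows[[p]] <- tibble::tibble(participant = pid, sample = spec$samples,
                                      hr = hr, sp = sp, dp = dp)
      tmp_rows[[p]] <- tibble::tibble(
        participant = pid, sample = spec$samples,
        temp_c = spec$ir_means + stats::rnorm(k, sd = spec$ir_sd))
      file_resp <- resp[, c("assessment", "sample", "question", "value", "time")]
      # "FS" is the analysis symbol; the dialect spells the scale out
      file_resp$question <- ifelse(file_resp$question == "FS", "Face scale",
                                   file_resp$question)
      files[p] <- write_response_file(file_resp,
                                      rank_rows[[p]][, c("sample", "position")])
    }
    list(responses = dplyr::bind_rows(rows),
         rank = dplyr::bind_rows(rank_rows),
         emotions = dplyr::bind_rows(em_rows),
         vitals = dplyr::bind_rows(vit_rows),
         temps = dplyr::bind_rows(tmp_rows),
         response_files = files,
         truth = spec)
  })
}

format_time_of_day <- function(secs) {
  secs <- round(secs) %% 86400
  sprintf("%02d:%02d:%02d", secs %/% 3600, (secs %% 3600) %/% 60, secs %% 60)
}

#' Write a generated session to disk
#'
#' One Table-dialect `.txt` response file and one emotion CSV per
#' participant, plus `truth.json` with the scenario's ground-truth means.
#'
#' @param session A [generate_session()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pid in names(session$response_files)) {
    cat(session$response_files[[pid]],
        file = file.path(dir, paste0(pid, "_responses.txt")))
    em <- session$emotions[session$emotions$participant == pid,
                           c("timestamp", emotion_numeric_cols(), "gaze")]
    write_emotion_table(em, file.path(dir, paste0(pid, "_emotions.csv")))
  }
  spec <- session$truth
  jsonlite::write_json(
    list(samples = spec$samples, n_participants = spec$n_participants,
         questions = spec$questions,
         liking_means = as.data.frame(spec$liking_means),
         hr_means = spec$hr_means, ir_means = spec$ir_means,
         classes = as.character(spec$classes %||% character(0)),
         seed = spec$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
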