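test_that("generated clips are deterministic per seed and carry ground truth", {
  a <- suppressWarnings(generate_face_video(72, duration_s = 2, snr_db = 10,
                                            seed = 5, width = 32, height = 24))
  b <- suppressWarnings(generate_face_video(72, duration_s = 2, snr_db = 10,
                                            seed = 5, width = 32, height = 24))
  expect_identical(a$clip$frames, b$clip$frames)
  c2 <- suppressWarnings(generate_face_video(72, duration_s = 2, snr_db = 10,
                                             seed = 6, width = 32, height = 24))
  expect_false(identical(a$clip$frames, c2$clip$frames))
  expect_equal(a$f_hz, 1.2)
  expect_warning(generate_face_video(72, duration_s = 2, seed = 1,
                                     width = 16, height = 12), "10 s")
  expect_error(generate_face_video(30, seed = 1, width = 16, height = 12),
               "42")
})

test_that("the noise-free generator inverts through the rPPG pipeline", {
  g <- generate_face_video(72, duration_s = 30, snr_db = Inf, seed = 3,
                           width = 48, height = 36)
  hr <- estimate_heart_rate(preprocess_ppg(extract_green_signal(g$clip, g$roi)))
  expect_equal(hr, 72, tolerance = 1 / 72)
})

test_that("heart-rate error does not improve as SNR falls", {
  err_at <- function(snr_db) {
    errs <- vapply(1:3, function(s) {
      g <- generate_face_video(80, duration_s = 20, snr_db = snr_db,
                               seed = 100 + s, width = 32, height = 24)
      sig <- preprocess_ppg(extract_green_signal(g$clip, g$roi))
      abs(suppressWarnings(estimate_heart_rate(sig)) - 80)
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }
  errs <- c(err_at(20), err_at(0), err_at(-15))
  expect_true(all(diff(errs) > -0.5))
  expect_lt(errs[1], 1)
})

test_that("thermal sequences are seeded and exercise all scene classes", {
  a <- generate_thermal_sequence(n_pairs = 3, temps_c = rep(35, 3), seed = 11)
  b <- generate_thermal_sequence(n_pairs = 3, temps_c = rep(35, 3), seed = 11)
  expect_identical(a$pairs[[2]]$thermal, b$pairs[[2]]$thermal)
  mixed <- generate_thermal_sequence(n_pairs = 3, temps_c = rep(35, 3),
                                     scenes = c("eyes", "occluded", "none"),
                                     seed = 12)
  kinds <- lapply(mixed$pairs, function(p) detect_roi(p$visible))
  expect_equal(kinds[[1]]$kind, "eyes")
  expect_equal(kinds[[2]]$kind, "face")
  expect_null(kinds[[3]])
  expect_true(all(vapply(mixed$pairs, function(p)
    p$timestamp, numeric(1)) == c(0, 2, 4)))
})

test_that("session generation matches the declared protocol shape", {
  spec <- scenario_spec(samples = paste0("S", 1:9), n_participants = 1,
                        questions = "FS", liking_means = seq(10, 90, 10),
                        liking_sd = 5, seed = 21)
  sess <- generate_session(spec)
  expect_equal(nrow(sess$responses), 9)
  lines <- strsplit(sess$response_files[[1]], "\n")[[1]]
  expect_equal(sum(startsWith(lines, "Assessment")), 9)
  expect_equal(sum(startsWith(lines, "Rank")), 1)
  parsed <- parse_response_file(sess$response_files[[1]])
  expect_equal(nrow(parsed$responses), 9)
  expect_equal(nrow(parsed$rank), 9)
})

test_that("rankings are consistent with the participant's own liking draws", {
  sess <- generate_session(scenario_affective_images(n_participants = 5, seed = 8))
  for (pid in unique(sess$rank$participant)) {
    r <- sess$rank[sess$rank$participant == pid, ]
    v <- sess$responses[sess$responses$participant == pid, ]
    liking <- v$value[match(r$sample, v$sample)]
    expect_true(all(diff(liking) <= 0))
    expect_equal(sort(r$position), 1:9)
  }
})

test_that("with zero noise the fused features equal the planted means", {
  spec <- scenario_spec(samples = c("A", "B", "C"), n_participants = 4,
                        questions = c("FS", "Overall"),
                        liking_means = cbind(c(20, 50, 80), c(30, 60, 90)),
                        liking_sd = 0, hr_means = c(60, 70, 80), hr_sd = 0,
                        ir_means = c(34, 34.5, 35), ir_sd = 0,
                        emotion_sd = 0, seed = 31)
  sess <- generate_session(spec)
  fm <- assemble_features(responses = sess$responses, vitals = sess$vitals,
                          temps = sess$temps)
  expect_equal(fm$FS, c(20, 50, 80))
  expect_equal(fm$Overall, c(30, 60, 90))
  expect_equal(fm$HR, c(60, 70, 80))
  expect_equal(fm$IR, c(34, 34.5, 35))
})

test_that("sessions are reproducible per seed and classes are planted", {
  s1 <- generate_session(scenario_affective_images(n_participants = 4, seed = 13))
  s2 <- generate_session(scenario_affective_images(n_participants = 4, seed = 13))
  expect_identical(s1$responses, s2$responses)
  expect_identical(s1$emotions, s2$emotions)
  expect_equal(as.character(s1$truth$classes),
               rep(c("positive", "neutral", "negative"), each = 3))
})

test_that("written sessions are readable back from disk", {
  dir <- withr::local_tempdir()
  sess <- generate_session(scenario_affective_images(n_participants = 2, seed = 17))
  write_session(sess, dir)
  files <- list.files(dir)
  expect_true("truth.json" %in% files)
  expect_equal(sum(grepl("_responses\\.txt$", files)), 2)
  expect_equal(sum(grepl("_emotions\\.csv$", files)), 2)
  parsed <- parse_response_file(file.path(dir, "P01_responses.txt"))
  expect_equal(nrow(parsed$responses), 9)
  em <- read_emotion_table(file.path(dir, "P01_emotions.csv"))
  expect_equal(nrow(em), 9)
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_equal(truth$n_participants, 2)
})
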