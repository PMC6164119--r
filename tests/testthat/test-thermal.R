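box_iou <- function(a, b) {
  ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- ix * iy
  inter / (a$w * a$h + b$w * b$h - inter)
}

test_that("eye region is found on clear scenes, with the face as fallback", {
  seq_eyes <- generate_thermal_sequence(n_pairs = 1, temps_c = 35, seed = 21,
                                        width = 160, height = 120)
  vis <- seq_eyes$pairs[[1]]$visible
  d <- detect_roi(vis)
  expect_s3_class(d, "detected_roi")
  expect_equal(d$kind, "eyes")
  # ground-truth eye band of the parametric face: upper part of the ellipse
  h <- 120; w <- 160
  truth <- list(x = round(w / 2 - 0.45 * 0.3 * w - 0.22 * 0.3 * w),
                y = round(h / 2 - 0.45 * 0.4 * h - 0.08 * 0.4 * h),
                w = round(2 * 0.45 * 0.3 * w + 2 * 0.22 * 0.3 * w),
                h = round(2 * 0.08 * 0.4 * h))
  expect_gt(box_iou(d$box, truth), 0.5)

  occ <- generate_thermal_sequence(n_pairs = 1, temps_c = 35, scenes = "occluded",
                                   seed = 22)
  d2 <- detect_roi(occ$pairs[[1]]$visible)
  expect_equal(d2$kind, "face")

  blank <- array(10, dim = c(40, 40, 3))
  expect_null(detect_roi(blank))
})

test_that("default registration is the size-ratio scale plus offset", {
  vis <- array(150, dim = c(40, 40, 3))
  same <- thermal_pair(vis, matrix(30, 40, 40))
  reg <- register(same)
  expect_equal(reg$A, rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(reg$residual, 0)

  half <- thermal_pair(vis, matrix(30, 20, 20))
  reg2 <- register(half)
  expect_equal(reg2$A, rbind(c(0.5, 0, 0), c(0, 0.5, 0)))

  off <- register(half, calibration = list(offset = c(2, -1)))
  expect_equal(off$A[, 3], c(2, -1))
  expect_equal(apply_registration(off, c(10, 10)), cbind(7, 4))
})

test_that("landmark registration recovers a known affine by least squares", {
  A_true <- rbind(c(0.52, 0.03, 4), c(-0.02, 0.47, 1.5))
  vis_pts <- withr::with_seed(5, cbind(runif(24, 0, 80), runif(24, 0, 60)))
  th_pts <- t(A_true %*% rbind(t(vis_pts), 1)) +
    withr::with_seed(4, matrix(rnorm(48, sd = 0.5), 24, 2))
  pair <- thermal_pair(array(150, dim = c(60, 80, 3)), matrix(30, 30, 40))
  reg <- register(pair, calibration = list(
    landmarks = list(visible = vis_pts, thermal = th_pts)))
  expect_lt(max(abs(reg$A[, 1:2] - A_true[, 1:2])) / max(abs(A_true[, 1:2])), 0.02)
  # round-trip: recovered transform reproduces targets within the residual
  fit <- apply_registration(reg, vis_pts)
  expect_lte(sqrt(mean((fit - th_pts)^2)), reg$residual + 1e-9)
  # independent least-squares route (lm per output coordinate)
  lm_fit <- stats::lm(th_pts ~ vis_pts)
  A_lm <- t(stats::coef(lm_fit))[, c(2, 3, 1)]
  expect_equal(unname(reg$A), unname(A_lm), tolerance = 1e-10)

  expect_error(register(pair, calibration = list(
    landmarks = list(visible = vis_pts[1:2, ], thermal = th_pts[1:2, ]))),
    ">= 3")

  # four landmarks -- the minimal over-determined case -- still within 2%
  reg4 <- register(pair, calibration = list(
    landmarks = list(visible = vis_pts[1:4, ], thermal = th_pts[1:4, ])))
  expect_lt(max(abs(reg4$A[, 1:2] - A_true[, 1:2])) / max(abs(A_true[, 1:2])),
            0.02)
})

test_that("maximum temperature respects the transformed ROI mask", {
  vis <- array(150, dim = c(20, 20, 3))
  uniform <- thermal_pair(vis, matrix(34, 10, 10))
  reg <- register(uniform)
  expect_equal(max_temperature(uniform, face_roi(0, 0, 20, 20), reg), 34)

  th <- matrix(33, 10, 10)
  th[3, 3] <- 36.2   # inside roi after 0.5x scaling
  th[9, 9] <- 40.0   # outside roi
  pair <- thermal_pair(vis, th)
  roi <- face_roi(2, 2, 8, 8)  # maps to thermal [1,5) x [1,5)
  expect_equal(max_temperature(pair, roi, register(pair)), 36.2)

  expect_error(max_temperature(pair, face_roi(0, 0, 1, 1), register(pair)),
               "no thermal pixels")
})

test_that("vectorized maximum matches a brute-force pixel scan", {
  for (seed in 1:40) {
    pair <- withr::with_seed(seed, {
      th <- matrix(runif(12 * 9, 28, 38), 9, 12)
      thermal_pair(array(150, dim = c(18, 24, 3)), th)
    })
    roi <- withr::with_seed(seed + 500, {
      x <- sample(0:12, 1); y <- sample(0:8, 1)
      face_roi(x, y, sample(2:(24 - x), 1), sample(2:(18 - y), 1))
    })
    calib <- if (seed %% 2 == 0) list(offset = c(0.3, -0.2)) else NULL
    reg <- register(pair, calib)
    oracle <- brute_force_max_temp(pair, roi, reg)
    if (is.na(oracle)) {
      expect_error(max_temperature(pair, roi, reg))
    } else {
      expect_equal(max_temperature(pair, roi, reg), oracle)
    }
  }
})

test_that("the temperature series recovers a planted ramp", {
  gen <- generate_thermal_sequence(n_pairs = 10, seed = 31)
  series <- temperature_series(gen$pairs)
  expect_equal(nrow(series), 10)
  expect_true(all(diff(series$time) == 2))
  expect_lt(max(abs(series$temp_c - gen$truth$temp_c)), 0.1)
  expect_true(all(diff(series$temp_c) > 0))
})

test_that("undetectable frames are skipped and logged", {
  gen <- generate_thermal_sequence(n_pairs = 3, temps_c = rep(35, 3),
                                   scenes = c("eyes", "none", "occluded"),
                                   seed = 33)
  series <- temperature_series(gen$pairs)
  expect_equal(nrow(series), 2)
  expect_equal(series$roi_kind, c("eyes", "face"))
  fails <- attr(series, "failures")
  expect_equal(fails$time, 2)
  expect_equal(fails$reason, "no subject")

  none <- generate_thermal_sequence(n_pairs = 2, temps_c = rep(35, 2),
                                    scenes = "none", seed = 34)
  expect_error(temperature_series(none$pairs), "No subject")
})

test_that("a constant scene yields a constant series", {
  gen <- generate_thermal_sequence(n_pairs = 6, temps_c = rep(35, 6),
                                   noise_sd = 0, seed = 35)
  series <- temperature_series(gen$pairs)
  expect_equal(series$temp_c, rep(35, 6))
})

test_that("rasters read back from CSV and TIFF with sidecar calibration", {
  m <- matrix(c(30.5, 31, 32, 33.25), 2, 2)
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(m, csv, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_equal(read_thermal_raster(csv), m)

  tif <- withr::local_tempfile(fileext = ".tif")
  raw <- matrix(as.integer(m * 100), 2, 2)
  tiff::writeTIFF(raw / 65535, tif, bits.per.sample = 16)
  sidecar <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(scale = 0.01, offset = 0),
                              auto_unbox = TRUE), sidecar)
  expect_equal(read_thermal_raster(tif, sidecar), m, tolerance = 0.01)
})
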