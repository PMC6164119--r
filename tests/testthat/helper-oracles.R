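# Independent oracles and small fixture builders used across tests.

# Brute-force maximum temperature: explicit double loop over thermal pixels,
# mapping each pixel center back to visible coordinates through the inverted
# affine and checking the half-open ROI box. Independent of max_temperature's
# vectorized path.
brute_force_max_temp <- function(pair, roi, reg) {
  if (inherits(roi, "detected_roi")) roi <- roi$box
  A <- reg$A
  L <- solve(A[, 1:2])
  best <- -Inf
  found <- FALSE
  for (col in seq_len(ncol(pair$thermal))) {
    for (row in seq_len(nrow(pair$thermal))) {
      vis <- L %*% (c(col - 0.5, row - 0.5) - A[, 3])
      if (vis[1] >= roi$x && vis[1] < roi$x + roi$w &&
          vis[2] >= roi$y && vis[2] < roi$y + roi$h) {
        found <- TRUE
        if (pair$thermal[row, col] > best) best <- pair$thermal[row, col]
      }
    }
  }
  if (!found) NA_real_ else best
}

# Brute-force correlation-matrix PCA: eigendecomposition route, independent
# of the prcomp/SVD route used by pca().
eigen_pca_oracle <- function(m) {
  R <- stats::cor(m)
  ev <- eigen(R, symmetric = TRUE)
  list(values = ev$values, explained_pct = 100 * ev$values / sum(ev$values))
}

# Exact recovery of a planted partition: memberships match up to relabeling.
same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    length(unique(paste(a, b))) == length(unique(a))
}

# Minimal hand-built clip: constant base frames with a per-frame green offset
# added uniformly inside the ROI.
make_clip <- function(green_series, width = 12, height = 10, fps = 30,
                      roi = face_roi(2, 2, 6, 5), base = 100) {
  n <- length(green_series)
  frames <- array(base, dim = c(height, width, 3, n))
  rows <- (roi$y + 1):(roi$y + roi$h)
  cols <- (roi$x + 1):(roi$x + roi$w)
  for (i in seq_len(n)) {
    frames[rows, cols, 2, i] <- base + green_series[i]
  }
  list(clip = video_clip(frames, fps), roi = roi)
}

random_emotion_table <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    timestamp = seq_len(n) - 1,
    happy = runif(n), neutral = runif(n), sad = runif(n), scared = runif(n),
    surprised = runif(n), angry = runif(n), contempt = runif(n),
    disgusted = runif(n),
    valence = runif(n, -1, 1), arousal = runif(n),
    x_head = rnorm(n, sd = 10), y_head = rnorm(n, sd = 10),
    z_head = rnorm(n, sd = 10),
    gaze = sample(c("forward", "left", "right"), n, replace = TRUE)))
}

table1_path <- function() {
  system.file("extdata", "example_session_output.txt", package = "biosense")
}
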