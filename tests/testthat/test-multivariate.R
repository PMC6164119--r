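test_that("feature assembly averages across participants per sample", {
  one <- tibble::tibble(participant = "P1",
                        sample = c("A", "A", "B", "B"),
                        question = c("FS", "Overall", "FS", "Overall"),
                        value = c(80, 70, 20, 30))
  fm <- assemble_features(responses = one)
  expect_equal(fm$FS, c(80, 20))
  expect_equal(fm$Overall, c(70, 30))

  two <- dplyr::bind_rows(one, dplyr::mutate(one, participant = "P2",
                                             value = value + 10))
  fm2 <- assemble_features(responses = two)
  expect_equal(fm2$FS, c(85, 25))

  vt <- tibble::tibble(participant = c("P1", "P2"), sample = "A",
                       hr = c(70, 74), sp = c(120, 124), dp = c(80, 82))
  tp <- tibble::tibble(participant = c("P1", "P2"), sample = "A",
                       temp_c = c(34.2, 34.6))
  fm3 <- assemble_features(responses = one, vitals = vt, temps = tp,
                           impute = TRUE)
  expect_equal(fm3$HR[fm3$sample == "A"], 72)
  expect_equal(fm3$IR[fm3$sample == "A"], 34.4)
})

test_that("samples missing from a source error unless imputation is on", {
  resp <- tibble::tibble(participant = "P1", sample = c("A", "B"),
                         question = "FS", value = c(10, 20))
  vt <- tibble::tibble(participant = "P1", sample = "A",
                       hr = 70, sp = 120, dp = 80)
  expect_error(assemble_features(responses = resp, vitals = vt), "vitals.*B")
  fm <- assemble_features(responses = resp, vitals = vt, impute = TRUE)
  expect_false(anyNA(as.data.frame(fm)))
  expect_equal(fm$HR, c(70, 70))
})

test_that("row count always equals the number of distinct samples", {
  for (seed in 1:6) {
    k <- withr::with_seed(seed, sample(3:8, 1))
    resp <- withr::with_seed(seed, tibble::tibble(
      participant = rep(sprintf("P%d", 1:4), each = k * 2),
      sample = rep(rep(paste0("S", 1:k), each = 2), 4),
      question = rep(c("FS", "Overall"), k * 4),
      value = runif(8 * k, 0, 100)))
    fm <- assemble_features(responses = resp)
    expect_equal(nrow(fm), k)
  }
})

test_that("emotion fusion uses the analysis symbols for head pose", {
  sess <- generate_session(scenario_affective_images(n_participants = 3, seed = 2))
  fm <- assemble_features(emotions = sess$emotions, responses = sess$responses)
  expect_true(all(c("X-Head", "Y-Head", "Z-Head", "happy", "valence", "FS")
                  %in% names(fm)))
  expect_false("GDir" %in% names(fm))  # categorical gaze stays out
})

test_that("explained variances match the eigendecomposition oracle", {
  for (seed in 1:5) {
    m <- withr::with_seed(seed, matrix(rnorm(9 * 20), 9, 20))
    colnames(m) <- paste0("V", 1:20)
    res <- pca(m)
    oracle <- eigen_pca_oracle(m)
    k <- length(res$explained_pct)
    expect_lt(max(abs(res$explained_pct - oracle$explained_pct[seq_len(k)])), 1e-8)
    expect_equal(sum(res$explained_pct), 100, tolerance = 1e-9)
    # reconstruction with all components reproduces the standardized matrix
    z <- scale(m)
    recon <- res$scores %*% t(res$loadings)
    expect_lt(max(abs(recon - z)), 1e-8)
    # loadings orthonormal
    expect_lt(max(abs(crossprod(res$loadings) - diag(ncol(res$loadings)))), 1e-8)
  }
})

test_that("two perfectly correlated variables put 100% on PC1", {
  x <- 1:6
  m <- cbind(a = x, b = 2 * x + 3)
  res <- pca(m)
  expect_equal(res$explained_pct[1], 100)
})

test_that("PCA input degeneracies are handled explicitly", {
  expect_error(pca(matrix(1:4, 1)), "2 rows")
  m <- withr::with_seed(8, cbind(a = rnorm(5), b = rnorm(5), const = rep(2, 5)))
  expect_warning(res <- pca(m), "const")
  expect_equal(nrow(res$loadings), 2)
  # deterministic sign convention: the largest loading is positive
  for (j in seq_len(ncol(res$loadings))) {
    expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
  }
  expect_identical(suppressWarnings(pca(m))$loadings, res$loadings)
})

test_that("clustering on scores has closed-form behavior for tiny inputs", {
  m <- rbind(S1 = c(0, 0, 1), S2 = c(3, 4, 2))
  res <- pca(m)
  tree <- cluster(res, n_components = 1)
  expect_equal(length(tree$height), 1)
  # two z-scored samples sit sqrt(2) apart per variable: distance sqrt(6)
  expect_equal(tree$height, sqrt(6), tolerance = 1e-8)

  same <- withr::with_seed(4, matrix(rnorm(8), 2, 4))[c(1, 1, 2, 2), ]
  rownames(same) <- paste0("S", 1:4)
  res2 <- pca(same)
  tree2 <- cluster(res2, n_components = 2)
  expect_equal(sort(tree2$height)[1:2], c(0, 0), tolerance = 1e-10)

  expect_error(cluster(res, n_components = 10), "available")
})

test_that("a planted two-group separation is recovered at the first cut", {
  for (seed in 1:5) {
    m <- withr::with_seed(seed, rbind(
      matrix(rnorm(5 * 6, mean = 0, sd = 0.5), 5, 6),
      matrix(rnorm(5 * 6, mean = 10, sd = 0.5), 5, 6)))
    rownames(m) <- paste0("S", 1:10)
    cl <- cut_clusters(cluster(pca(m)), k = 2)
    expect_true(same_partition(cl, rep(1:2, each = 5)))
  }
})

test_that("the cluster tree is invariant to row permutation", {
  m <- withr::with_seed(9, matrix(rnorm(9 * 5), 9, 5))
  rownames(m) <- paste0("S", 1:9)
  cl1 <- cut_clusters(cluster(pca(m)), k = 3)
  perm <- withr::with_seed(10, sample(9))
  cl2 <- cut_clusters(cluster(pca(m[perm, ])), k = 3)
  expect_true(same_partition(cl1[paste0("S", 1:9)], cl2[paste0("S", 1:9)]))
})

test_that("the biplot renders with explained-variance axis labels", {
  sess <- generate_session(scenario_beer(n_participants = 4, seed = 3))
  fm <- assemble_features(responses = sess$responses, vitals = sess$vitals,
                          temps = sess$temps, emotions = sess$emotions)
  res <- pca(fm)
  p <- pca_biplot(res)
  expect_s3_class(p, "ggplot")
  expect_match(p$labels$x, "PC1 \\(\\d+\\.\\d+%\\)")
  expect_match(p$labels$y, "PC2 \\(\\d+\\.\\d+%\\)")
  built <- ggplot2::ggplot_build(p)
  expect_gt(length(built$data), 0)
  # repeat-run layout equality (sign convention is deterministic)
  p2 <- pca_biplot(pca(fm))
  expect_equal(ggplot2::ggplot_build(p2)$data, built$data)
})
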