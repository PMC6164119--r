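#' Fuse conscious and subconscious responses into a per-sample feature matrix
#'
#' Builds the sample-by-variable table analyzed downstream: rows are samples
#' (stimuli), columns are the conscious liking/scale questions plus the
#' subconscious physiological variables — heart rate (HR), systolic/diastolic
#' pressure (SP/DP), skin temperature (IR), the eight emotion intensities,
#' valence, arousal and head orientation (X-Head/Y-Head/Z-Head). Every
#' source is averaged across participants within each sample.
#'
#' @param responses Optional tibble with columns `sample`, `participant`,
#'   `question`, `value`; each question becomes a column named by its
#'   descriptor (e.g. `FStability`, `Overall`, `FS`).
#' @param vitals Optional tibble with columns `sample`, `participant`, `hr`,
#'   `sp`, `dp`; becomes columns `HR`, `SP`, `DP`.
#' @param temps Optional tibble with columns `sample`, `participant`,
#'   `temp_c`; becomes column `IR`.
#' @param emotions Optional tibble with columns `sample`, `participant` and
#'   the numeric emotion-table components; head-pose columns are renamed to
#'   `X-Head`/`Y-Head`/`Z-Head`, and a numeric `gaze` column becomes `GDir`
#'   (a categorical gaze column is excluded from the numeric fusion).
#' @param impute Fill cells missing from one source with that variable's
#'   mean across samples instead of erroring.
#' @return A tibble of class `feature_matrix`: a `sample` column plus one
#'   numeric column per variable, no missing cells.
#' @export
assemble_features <- function(responses = NULL, vitals = NULL, temps = NULL,
                              emotions = NULL, impute = FALSE) {
  blocks <- list()
  if (!is.null(responses)) {
    wide <- tidyr::pivot_wider(
      dplyr::summarise(dplyr::group_by(responses, .data$sample, .data$question),
                       value = mean(.data$value), .groups = "drop"),
      names_from = "question", values_from = "value")
    blocks[["responses"]] <- wide
  }
  if (!is.null(vitals)) {
    blocks[["vitals"]] <- dplyr::summarise(
      dplyr::group_by(vitals, .data$sample),
      HR = mean(.data$hr), SP = mean(.data$sp), DP = mean(.data$dp),
      .groups = "drop")
  }
  if (!is.null(temps)) {
    blocks[["temps"]] <- dplyr::summarise(
      dplyr::group_by(temps, .data$sample),
      IR = mean(.data$temp_c), .groups = "drop")
  }
  if (!is.null(emotions)) {
    num <- intersect(emotion_numeric_cols(), names(emotions))
    if ("gaze" %in% names(emotions) && is.numeric(emotions$gaze)) {
      num <- c(num, "gaze")
    }
    em <- dplyr::summarise(dplyr::group_by(emotions, .data$sample),
                           dplyr::across(dplyr::all_of(num), mean),
                           .groups = "drop")
    rn <- c(x_head = "X-Head", y_head = "Y-Head", z_head = "Z-Head", gaze = "GDir")
    for (old in names(rn)) {
      if (old %in% names(em)) names(em)[names(em) == old] <- rn[[old]]
    }
    blocks[["emotions"]] <- em
  }
  if (length(blocks) == 0L) abort_biosense("No input sources given.")
  all_samples <- sort(unique(unlist(lapply(blocks, function(b) b$sample))))
  missing <- lapply(blocks, function(b) setdiff(all_samples, b$sample))
  missing <- missing[vapply(missing, length, integer(1)) > 0L]
  if (length(missing) > 0L && !impute) {
    abort_biosense(paste0(
      "Sample(s) absent from source(s): ",
      paste(vapply(names(missing), function(nm) sprintf(
        "%s (%s)", nm, paste(missing[[nm]], collapse = ", ")), character(1)),
        collapse = "; "),
      ". Set impute = TRUE to mean-impute."))
  }
  out <- Reduce(function(a, b) dplyr::full_join(a, b, by = "sample"), blocks)
  out <- dplyr::arrange(out, .data$sample)
  for (col in setdiff(names(out), "sample")) {
    miss <- is.na(out[[col]])
    if (any(miss)) out[[col]][miss] <- mean(out[[col]][!miss])
  }
  if (nrow(out) < 2L || ncol(out) < 3L) {
    abort_biosense("Feature matrix needs >= 2 samples and >= 2 variables.")
  }
  class(out) <- c("feature_matrix", class(out))
  out
}

feature_matrix_values <- function(x) {
  if (inherits(x, "feature_matrix") || ("sample" %in% names(as.data.frame(x)))) {
    df <- as.data.frame(x)
    m <- as.matrix(df[setdiff(names(df), "sample")])
    rownames(m) <- df$sample
  } else {
    m <- as.matrix(x)
    if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  }
  storage.mode(m) <- "double"
  m
}

#' Principal component analysis of the feature matrix
#'
#' Eigendecomposition of the correlation matrix (variables are z-scored by
#' default, since they mix units: liking scales, bpm, mmHg, deg C).
#' Components carry a deterministic sign convention — within each component
#' the loading of largest magnitude is positive — so results are stable
#' across runs and platforms. Explained variances are percentages of the
#' total and sum to 100 over the returned components.
#'
#' @param x A [assemble_features()] matrix, or any numeric matrix/data frame
#'   (rows = samples).
#' @param standardize Scale variables to unit variance (correlation PCA)?
#'   Constant columns are dropped with a warning.
#' @return An object of class `pca_result`: `loadings` (variables x
#'   components, orthonormal), `scores` (samples x components),
#'   `explained_pct`, plus the centers/scales used.
#' @export
pca <- function(x, standardize = TRUE) {
  m <- feature_matrix_values(x)
  if (nrow(m) < 2L) abort_biosense("PCA needs at least 2 rows (samples).")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds < 1e-12)) {
    warning(sprintf("Dropping constant column(s): %s.",
                    paste(colnames(m)[sds < 1e-12], collapse = ", ")))
    m <- m[, sds >= 1e-12, drop = FALSE]
  }
  if (ncol(m) < 2L) abort_biosense("PCA needs at least 2 non-constant variables.")
  fit <- stats::prcomp(m, center = TRUE, scale. = standardize)
  loadings <- fit$rotation
  scores <- fit$x
  # sign convention: largest-|loading| entry positive in every component
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- fit$sdev^2
  structure(
    list(loadings = loadings, scores = scores,
         explained_pct = 100 * ev / sum(ev),
         sdev = fit$sdev, center = fit$center,
         scale = if (standardize) fit$scale else NULL,
         standardized = standardize),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(3L, length(x$explained_pct))
  cat(sprintf("<pca_result> %d samples x %d variables; %s\n",
              nrow(x$scores), nrow(x$loadings),
              paste(sprintf("PC%d %.2f%%", seq_len(k), x$explained_pct[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' Hierarchical clustering of samples on PCA scores
#'
#' Agglomerative clustering with Euclidean distances computed on the first
#' `n_components` principal-component scores — the view in which related
#' stimuli (e.g. the negative images of an affective picture set) group
#' together. Average linkage by default; single, complete and Ward are
#' selectable.
#'
#' @param result A [pca()] result.
#' @param n_components Number of leading score columns to use (default 2).
#' @param linkage One of `"average"`, `"single"`, `"complete"`, `"ward"`.
#' @return An object of class `cluster_tree` (an `hclust` with the merge
#'   list, heights and leaf order; `$n_components` records the view).
#' @export
cluster <- function(result, n_components = 2, linkage = c("average", "single",
                                                          "complete", "ward")) {
  if (!inherits(result, "pca_result")) abort_biosense("`result` must be a pca_result.")
  linkage <- match.arg(linkage)
  k <- ncol(result$scores)
  if (n_components > k) {
    abort_biosense(sprintf("Only %d components available, %d requested.", k, n_components))
  }
  pts <- result$scores[, seq_len(n_components), drop = FALSE]
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::dist(pts, method = "euclidean"), method = method)
  hc$n_components <- n_components
  class(hc) <- c("cluster_tree", "hclust")
  hc
}

#' Cut a cluster tree
#'
#' @param tree A [cluster()] tree.
#' @param k Number of clusters, or
#' @param h height (linkage distance) at which to cut.
#' @return Named integer vector of cluster memberships.
#' @export
cut_clusters <- function(tree, k = NULL, h = NULL) {
  if (is.null(k) && is.null(h)) abort_biosense("Give `k` or `h`.")
  stats::cutree(structure(tree, class = "hclust"), k = k, h = h)
}

#' PCA biplot
#'
#' Samples as labeled points, variables as labeled loading vectors (scaled
#' to the score spread), axes annotated with the explained-variance
#' percentages. Layout is deterministic given the PCA's sign convention.
#'
#' @param result A [pca()] result with >= 2 components.
#' @param components Which two components to draw (default `c(1, 2)`).
#' @return A ggplot object.
#' @export
pca_biplot <- function(result, components = c(1, 2)) {
  if (!inherits(result, "pca_result")) abort_biosense("`result` must be a pca_result.")
  if (ncol(result$scores) < 2L) abort_biosense("Biplot needs >= 2 components.")
  i <- components[1]; j <- components[2]
  sc <- tibble::tibble(sample = rownames(result$scores),
                       x = result$scores[, i], y = result$scores[, j])
  r <- 0.8 * min(max(abs(sc$x)), max(abs(sc$y)))
  ld <- tibble::tibble(variable = rownames(result$loadings),
                       x = result$loadings[, i] * r / max(abs(result$loadings[, i])),
                       y = result$loadings[, j] * r / max(abs(result$loadings[, j])))
  ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "steelblue") +
    ggplot2::geom_text(data = ld,
                       ggplot2::aes(x = .data$x * 1.08, y = .data$y * 1.08,
                                    label = .data$variable),
                       colour = "steelblue", size = 3) +
    ggplot2::geom_point(data = sc, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_text(data = sc,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$sample),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = sprintf("PC%d (%.2f%%)", i, result$explained_pct[i]),
      y = sprintf("PC%d (%.2f%%)", j, result$explained_pct[j])) +
    ggplot2::theme_minimal()
}
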