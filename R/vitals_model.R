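#' Trainable vitals regressor (heart rate and blood pressure)
#'
#' Maps PPG feature vectors to mean heart rate (beats/min) and systolic /
#' diastolic blood pressure (mmHg). The default regressor is a ridge
#' (regularized linear) model fitted independently per target. The shipped
#' use is calibration on synthetic or user-supplied reference data; it is
#' not a clinically validated blood-pressure device.
#'
#' @param features List of [extract_features()] vectors (>= 10).
#' @param targets Data frame / tibble with numeric columns `hr`, `sp`, `dp`,
#'   one row per feature vector; `sp > dp > 0` expected.
#' @param lambda Ridge penalty (default `1e-3`; near-least-squares).
#' @return An object of class `vitals_model` with a `coefficients` matrix
#'   (intercept + one row per feature, columns `hr`, `sp`, `dp`).
#' @export
fit_vitals_model <- function(features, targets, lambda = 1e-3) {
  if (length(features) < 10L) {
    abort_biosense("Need at least 10 training examples to fit the vitals model.")
  }
  X <- do.call(rbind, lapply(features, as.numeric))
  colnames(X) <- names(features[[1]])
  targets <- as.data.frame(targets)
  needed <- c("hr", "sp", "dp")
  if (!all(needed %in% names(targets))) {
    abort_biosense("`targets` must have columns hr, sp, dp.")
  }
  if (nrow(targets) != nrow(X)) abort_biosense("features/targets length mismatch.")
  # drop features with zero variance (e.g. low_quality constant 0) -- ridge
  # on a constant column is ill-posed
  keep <- apply(X, 2L, function(col) stats::sd(col) > 1e-12)
  coefs <- matrix(0, nrow = ncol(X) + 1L, ncol = 3L,
                  dimnames = list(c("(Intercept)", colnames(X)), needed))
  for (tgt in needed) {
    y <- targets[[tgt]]
    if (stats::sd(y) < 1e-12) {
      warning(sprintf("Constant '%s' targets: fitting a constant model.", tgt))
      coefs["(Intercept)", tgt] <- y[1]
      next
    }
    df <- as.data.frame(X[, keep, drop = FALSE])
    df$y <- y
    fit <- MASS::lm.ridge(y ~ ., data = df, lambda = lambda)
    b <- stats::coef(fit)
    coefs["(Intercept)", tgt] <- b[1]
    coefs[which(keep) + 1L, tgt] <- b[-1]
  }
  structure(list(coefficients = coefs, lambda = lambda,
                 feature_names = colnames(X)),
            class = "vitals_model")
}

#' @export
print.vitals_model <- function(x, ...) {
  cat(sprintf("<vitals_model> ridge (lambda = %g), %d features -> hr/sp/dp\n",
              x$lambda, length(x$feature_names)))
  invisible(x)
}

#' Predict vitals from PPG features
#'
#' @param model A fitted [fit_vitals_model()].
#' @param features A single [extract_features()] vector or a list of them.
#' @param window Optional `c(start_s, end_s)` the features were computed over.
#' @return A tibble of class `vitals_estimate` with columns `hr`, `sp`, `dp`
#'   (and `window_start`, `window_end` when given). Predicted systolic
#'   pressure is kept strictly above diastolic (floored at `dp + 1` mmHg).
#' @export
predict_vitals <- function(model, features, window = NULL) {
  if (!inherits(model, "vitals_model")) {
    abort_biosense("Fit the model before predicting (fit_vitals_model).")
  }
  if (!is.list(features)) features <- list(features)
  X <- do.call(rbind, lapply(features, as.numeric))
  if (ncol(X) != length(model$feature_names)) {
    abort_biosense("Feature length does not match the fitted model.")
  }
  pred <- cbind(1, X) %*% model$coefficients
  dp <- pmax(pred[, "dp"], 1)
  sp <- pmax(pred[, "sp"], dp + 1)
  out <- tibble::tibble(hr = pred[, "hr"], sp = sp, dp = dp)
  if (!is.null(window)) {
    out$window_start <- window[1]
    out$window_end <- window[2]
  }
  class(out) <- c("vitals_estimate", class(out))
  out
}

#' Save / load a vitals model as a JSON document
#'
#' @param model A [fit_vitals_model()] object.
#' @param path File path for the JSON document.
#' @return `load_vitals_model` returns the restored `vitals_model`.
#' @export
save_vitals_model <- function(model, path) {
  doc <- list(format = "biosense-vitals-model", version = 1L,
              lambda = model$lambda,
              feature_names = model$feature_names,
              coefficients = as.data.frame(model$coefficients))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_vitals_model
#' @export
load_vitals_model <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (!identical(doc$format, "biosense-vitals-model")) {
    abort_biosense("Not a biosense vitals-model document.")
  }
  coefs <- as.matrix(doc$coefficients)
  rownames(coefs) <- c("(Intercept)", doc$feature_names)
  structure(list(coefficients = coefs, lambda = doc$lambda,
                 feature_names = doc$feature_names),
            class = "vitals_model")
}
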