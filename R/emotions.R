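#' Facial-emotion tables
#'
#' Facial-expression analysis software classifies each analyzed frame into
#' eight emotion intensities — happy, neutral, sad, scared, surprised,
#' angry, contempt, disgusted — each in `[0, 1]`, two affective dimensions —
#' valence in `[-1, 1]` and arousal in `[0, 1]` — plus head orientation
#' around the x/y/z axes (degrees) and a gaze-direction reading. The export
#' format of such software is proprietary, so this package defines its own
#' documented CSV dialect with columns:
#'
#' `timestamp, happy, neutral, sad, scared, surprised, angry, contempt,
#' disgusted, valence, arousal, x_head, y_head, z_head, gaze`
#'
#' `timestamp` is seconds from session start; `gaze` is free text (e.g.
#' `"forward"`) or a numeric angle. A mapping template from other exports is
#' a matter of column renaming before ingestion.
#'
#' @name emotion_table
NULL

emotion_names <- function() {
  c("happy", "neutral", "sad", "scared", "surprised", "angry", "contempt",
    "disgusted")
}

emotion_numeric_cols <- function() {
  c(emotion_names(), "valence", "arousal", "x_head", "y_head", "z_head")
}

#' Read and validate an emotion table
#'
#' @param csv Path to a CSV file in the dialect described in
#'   [emotion_table], or a literal CSV string.
#' @return Tibble with one validated row per analyzed frame, columns as in
#'   [emotion_table].
#' @export
read_emotion_table <- function(csv) {
  tab <- readr::read_csv(if (file.exists(csv)) csv else I(csv),
                         show_col_types = FALSE, progress = FALSE)
  needed <- c("timestamp", emotion_numeric_cols(), "gaze")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    abort_biosense(sprintf("Emotion table lacks column(s): %s.",
                           paste(missing, collapse = ", ")))
  }
  validate_emotion_rows(tab)
  tab[needed]
}

validate_emotion_rows <- function(tab) {
  check <- function(cols, lo, hi, what) {
    for (col in cols) {
      bad <- which(!is.finite(tab[[col]]) | tab[[col]] < lo | tab[[col]] > hi)
      if (length(bad)) {
        abort_biosense(sprintf(
          "%s '%s' outside [%s, %s] at row(s) %s.",
          what, col, lo, hi, paste(utils::head(bad, 5), collapse = ", ")))
      }
    }
  }
  check(emotion_names(), 0, 1, "Emotion intensity")
  check("valence", -1, 1, "Dimension")
  check("arousal", 0, 1, "Dimension")
  invisible(tab)
}

#' Write an emotion table
#'
#' @param tab Tibble in the [emotion_table] dialect.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_emotion_table <- function(tab, path) {
  validate_emotion_rows(tab)
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

#' Windowed means of emotion vectors
#'
#' Averages the numeric emotion components over consecutive time windows,
#' the form in which subconscious responses enter the multivariate fusion.
#' Summaries are permutation-invariant within a window and each mean lies
#' within the range of its inputs. The (possibly categorical) gaze column is
#' summarized by its within-window mode.
#'
#' @param tab Emotion table (see [read_emotion_table()]).
#' @param window Window length in seconds (> 0).
#' @return Tibble with `timestamp` at window centers and component-wise
#'   means; `n` gives the rows averaged per window.
#' @export
summarize_emotions <- function(tab, window = 5) {
  assert_number(window, "window", lower = 1e-9)
  if (nrow(tab) == 0L) abort_biosense("Empty emotion table.")
  t0 <- min(tab$timestamp)
  bin <- floor((tab$timestamp - t0) / window)
  num <- emotion_numeric_cols()
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(tab, .bin = bin), .data$.bin),
    dplyr::across(dplyr::all_of(num), mean),
    gaze = names(sort(table(.data$gaze), decreasing = TRUE))[1],
    n = dplyr::n(),
    .groups = "drop")
  out$timestamp <- t0 + (out$.bin + 0.5) * window
  dplyr::select(out, "timestamp", dplyr::all_of(num), "gaze", "n")
}
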