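#' Read and write the tablet response/ranking text dialect
#'
#' Session results are saved by the test devices as tab-delimited `.txt`
#' files, one line per answered question plus an optional ranking line.
#' An assessment line has eight tab-separated fields:
#'
#' ```
#' Assessment <kind> Sample <label> <question kind> Progress <value> Time: HH:MM:SS
#' ```
#'
#' and a ranking line alternates `Sample <label>` / `Position <n>` pairs:
#'
#' ```
#' Rank  Sample Baby  Position 1  Sample Dog  Position 2  ...
#' ```
#'
#' `Progress` is a literal per-line token of the dialect and `Time: ` is a
#' literal prefix of the time-of-day stamp; dates live in the enclosing
#' file/folder name, not in the records.
#'
#' @name response_file
NULL

# question kind -> numeric scale range used for validation; kinds outside
# this table are passed through unchecked.
question_kind_range <- function(kind) {
  switch(kind,
    "Face scale" = c(0, 100),
    "Continuous scale" = c(0, 15),
    NULL
  )
}

#' Parse a session response file
#'
#' @param text Response-file text (single string, character vector of lines,
#'   or a path to a `.txt` file).
#' @return A list with components:
#'   * `responses`: tibble with columns `assessment`, `sample`, `question`,
#'     `value` (numeric) and `time` (`"HH:MM:SS"`), one row per
#'     `Assessment` line, in file order;
#'   * `rank`: tibble with columns `sample`, `position`, or `NULL` when the
#'     file holds no ranking line.
#' @examples
#' path <- system.file("extdata", "example_session_output.txt", package = "biosense")
#' parsed <- parse_response_file(path)
#' parsed$responses
#' @export
parse_response_file <- function(text) {
  lines <- read_dialect_lines(text)
  responses <- list()
  rank <- NULL
  for (i in seq_along(lines)) {
    line <- sub("[\t[:space:]]+$", "", lines[i])
    if (!nzchar(line)) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    head_tok <- fields[[1]]
    if (head_tok == "Assessment") {
      responses[[length(responses) + 1L]] <- parse_assessment_line(fields, i)
    } else if (head_tok == "Rank") {
      if (!is.null(rank)) {
        abort_biosense(sprintf("Line %d: second Rank line in one file.", i))
      }
      rank <- parse_rank_line(fields, i)
    } else {
      abort_biosense(sprintf(
        "Line %d: unrecognized record type '%s' (expected Assessment or Rank).",
        i, head_tok))
    }
  }
  responses <- if (length(responses)) dplyr::bind_rows(responses) else
    tibble::tibble(assessment = character(), sample = character(),
                   question = character(), value = numeric(), time = character())
  list(responses = responses, rank = rank)
}

read_dialect_lines <- function(text) {
  if (length(text) == 1L && !grepl("[\t\n]", text) && file.exists(text)) {
    return(readLines(text, warn = FALSE))
  }
  if (length(text) == 1L) return(strsplit(text, "\n", fixed = TRUE)[[1]])
  as.character(text)
}

parse_assessment_line <- function(fields, lineno) {
  if (length(fields) != 8L || fields[3] != "Sample" || fields[6] != "Progress") {
    abort_biosense(sprintf(
      "Line %d: malformed Assessment line (expected 8 tab-separated fields with 'Sample' and 'Progress' tokens).",
      lineno))
  }
  value <- suppressWarnings(as.numeric(fields[7]))
  if (is.na(value)) {
    abort_biosense(sprintf(
      "Line %d: non-numeric value '%s' for sample '%s'.", lineno, fields[7], fields[4]))
  }
  time <- parse_time_field(fields[8], lineno)
  rng <- question_kind_range(fields[5])
  if (!is.null(rng) && (value < rng[1] || value > rng[2])) {
    abort_biosense(sprintf(
      "Line %d: value %s for sample '%s' outside the %s range [%s, %s].",
      lineno, value, fields[4], fields[5], rng[1], rng[2]))
  }
  tibble::tibble(assessment = fields[2], sample = fields[4],
                 question = fields[5], value = value, time = time)
}

parse_time_field <- function(field, lineno) {
  if (!startsWith(field, "Time: ")) {
    abort_biosense(sprintf("Line %d: timestamp field must start with 'Time: '.", lineno))
  }
  tm <- sub("^Time: ", "", field)
  if (!grepl("^([01][0-9]|2[0-3]):[0-5][0-9]:[0-5][0-9]$", tm)) {
    abort_biosense(sprintf("Line %d: '%s' is not a valid 24-h HH:MM:SS time.", lineno, tm))
  }
  tm
}

parse_rank_line <- function(fields, lineno) {
  body <- fields[-1]
  if (length(body) == 0L || length(body) %% 2L != 0L) {
    abort_biosense(sprintf(
      "Line %d: Rank line must hold Sample/Position pairs.", lineno))
  }
  samples <- body[seq(1L, length(body), by = 2L)]
  positions <- body[seq(2L, length(body), by = 2L)]
  if (!all(startsWith(samples, "Sample ")) || !all(startsWith(positions, "Position "))) {
    abort_biosense(sprintf(
      "Line %d: Rank fields must alternate 'Sample <label>' and 'Position <n>'.", lineno))
  }
  labels <- sub("^Sample ", "", samples)
  pos <- suppressWarnings(as.integer(sub("^Position ", "", positions)))
  if (anyNA(pos)) abort_biosense(sprintf("Line %d: non-integer rank position.", lineno))
  validate_rank(labels, pos, lineno)
  tibble::tibble(sample = labels, position = pos)
}

validate_rank <- function(labels, pos, lineno = NA) {
  where <- if (is.na(lineno)) "" else sprintf("Line %d: ", lineno)
  if (anyDuplicated(labels)) {
    abort_biosense(sprintf("%sduplicate sample label in ranking.", where))
  }
  if (!setequal(pos, seq_along(pos))) {
    abort_biosense(sprintf(
      "%srank positions must be 1..%d with no gaps or repeats.", where, length(pos)))
  }
  invisible(TRUE)
}

#' Write records back to the response-file dialect
#'
#' Inverse of [parse_response_file()]: `parse_response_file(write_response_file(r))`
#' reproduces the records, and writing a canonical parsed file reproduces its
#' text modulo trailing whitespace.
#'
#' @param responses Tibble/data frame with columns `assessment`, `sample`,
#'   `question`, `value`, `time`.
#' @param rank Optional tibble with columns `sample`, `position`.
#' @param path Optional output file path.
#' @return The file text (single string; invisibly when `path` is given).
#' @export
write_response_file <- function(responses, rank = NULL, path = NULL) {
  lines <- character(0)
  if (!is.null(responses) && nrow(responses) > 0L) {
    needed <- c("assessment", "sample", "question", "value", "time")
    missing <- setdiff(needed, names(responses))
    if (length(missing)) {
      abort_biosense(sprintf("`responses` lacks column(s): %s.",
                             paste(missing, collapse = ", ")))
    }
    for (i in seq_len(nrow(responses))) {
      rng <- question_kind_range(responses$question[i])
      v <- responses$value[i]
      if (!is.finite(v)) {
        abort_biosense(sprintf("Row %d: non-finite value.", i))
      }
      if (!is.null(rng) && (v < rng[1] || v > rng[2])) {
        abort_biosense(sprintf(
          "Row %d: value %s outside the %s range [%s, %s].",
          i, v, responses$question[i], rng[1], rng[2]))
      }
      lines <- c(lines, paste(
        "Assessment", responses$assessment[i], "Sample", responses$sample[i],
        responses$question[i], "Progress", format_dialect_number(v),
        paste0("Time: ", responses$time[i]),
        sep = "\t"))
    }
  }
  if (!is.null(rank) && nrow(rank) > 0L) {
    validate_rank(rank$sample, rank$position)
    pairs <- paste0("Sample ", rank$sample, "\tPosition ", rank$position)
    lines <- c(lines, paste0("Rank\t", paste(pairs, collapse = "\t")))
  }
  text <- if (length(lines)) paste0(paste(lines, collapse = "\n"), "\n") else ""
  if (!is.null(path)) {
    cat(text, file = path)
    return(invisible(text))
  }
  text
}

# integers print without decimals, otherwise 0.1-unit resolution
format_dialect_number <- function(v) {
  if (abs(v - round(v)) < 1e-9) format(round(v)) else format(round(v, 1))
}

#' Convert parsed responses to a flat CSV-ready table
#'
#' @param parsed Result of [parse_response_file()].
#' @return A tibble: the response rows, with ranking positions joined on
#'   sample label when a ranking line was present.
#' @export
responses_as_table <- function(parsed) {
  out <- parsed$responses
  if (!is.null(parsed$rank)) {
    out <- dplyr::left_join(out,
      dplyr::rename(parsed$rank, rank_position = "position"), by = "sample")
  }
  out
}
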