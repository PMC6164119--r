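#' Session configuration objects
#'
#' A session configuration describes one sensory test as presented on the
#' tablet: its title, the 3-digit blind codes of the samples, whether the
#' presentation order is randomized per participant, whether the same question
#' block is repeated for every sample, an optional ranking (preference) task,
#' and the ordered list of questions. The configuration round-trips through
#' the JSON document consumed by the test devices (see [build_config()]).
#'
#' @param title Assessment title shown to participants.
#' @param sample_codes Character vector of unique 3-digit sample codes
#'   (e.g. `c("356", "214", "879")`); sample names are also accepted.
#' @param questions List of [question_spec()] objects, in presentation order.
#' @param randomize Randomize the per-participant sample presentation order?
#' @param repeat_questions Repeat the question block for every sample?
#' @param ranking Optional [ranking_spec()].
#' @param seed Integer seed used (with the participant id) to derive the
#'   per-participant presentation order.
#' @return An object of class `session_config`.
#' @seealso [build_config()], [parse_config()], [randomize_presentation()]
#' @examples
#' cfg <- session_config(
#'   title = "Beer tasting",
#'   sample_codes = c("356", "214", "879"),
#'   questions = list(question_spec("Overall liking", "face")),
#'   ranking = ranking_spec(position = "end", n_samples = 3)
#' )
#' @export
session_config <- function(title, sample_codes, questions,
                           randomize = TRUE, repeat_questions = TRUE,
                           ranking = NULL, seed = 1L) {
  assert_string(title, "title")
  assert_flag(randomize, "randomize")
  assert_flag(repeat_questions, "repeat_questions")
  assert_number(seed, "seed")
  cfg <- structure(
    list(
      title = title,
      sample_codes = as.character(sample_codes),
      randomize = randomize,
      repeat_questions = repeat_questions,
      ranking = ranking,
      questions = questions,
      seed = as.integer(seed)
    ),
    class = "session_config"
  )
  validate_session_config(cfg)
}

#' Question specification
#'
#' @param descriptor Question text / descriptor (e.g. "Foam stability liking").
#' @param scale_kind One of `"categorical"`, `"continuous15"` (unstructured
#'   0–15 line scale) or `"face"` (continuous sad–neutral–happy scale, 0–100).
#' @param levels Category labels; required for categorical scales (>= 2).
#' @param conditional Optional `list(when =, goto =)`: if the submitted answer
#'   equals `when`, jump to the question whose descriptor is `goto`.
#' @param media Optional attachment reference (image/video/sound file name).
#' @param display_time Optional display time in seconds.
#' @return An object of class `question_spec`.
#' @export
question_spec <- function(descriptor, scale_kind = c("categorical", "continuous15", "face"),
                          levels = NULL, conditional = NULL, media = NULL,
                          display_time = NULL) {
  assert_string(descriptor, "descriptor")
  scale_kind <- match.arg(scale_kind)
  if (scale_kind == "categorical") {
    if (is.null(levels) || length(levels) < 2L) {
      abort_biosense(sprintf(
        "Categorical question '%s' needs at least 2 levels.", descriptor))
    }
  } else if (!is.null(levels)) {
    abort_biosense("`levels` only applies to categorical scales.")
  }
  if (!is.null(conditional)) {
    if (!is.list(conditional) || is.null(conditional$when) || is.null(conditional$goto)) {
      abort_biosense("`conditional` must be list(when =, goto =).")
    }
  }
  if (!is.null(display_time)) assert_number(display_time, "display_time", lower = 0)
  structure(
    list(descriptor = descriptor, scale_kind = scale_kind,
         levels = if (is.null(levels)) NULL else as.character(levels),
         conditional = conditional, media = media,
         display_time = display_time),
    class = "question_spec"
  )
}

#' Ranking task specification
#'
#' @param position Where the ranking screen appears: `"end"` or a 1-based
#'   question index.
#' @param n_samples How many samples the participant ranks.
#' @return An object of class `ranking_spec`.
#' @export
ranking_spec <- function(position = "end", n_samples) {
  assert_number(n_samples, "n_samples", lower = 1)
  structure(list(position = position, n_samples = as.integer(n_samples)),
            class = "ranking_spec")
}

#' Numeric range of a response scale
#'
#' Continuous line scales span 0–15 units; the face scale spans 0–100;
#' categorical answers are level indices (1..k).
#'
#' @param scale_kind Scale kind string.
#' @param n_levels Number of levels (categorical only).
#' @return Numeric `c(lower, upper)`.
#' @export
scale_range <- function(scale_kind, n_levels = NULL) {
  switch(scale_kind,
    continuous15 = c(0, 15),
    face = c(0, 100),
    categorical = c(1, n_levels %||% Inf),
    abort_biosense(sprintf("Unknown scale kind '%s'.", scale_kind))
  )
}

#' Validate a session configuration
#'
#' Checks the structural invariants: unique sample codes, at least one
#' question, a ranking count no larger than the number of samples, conditional
#' jump targets that exist, and no conditional cycles.
#'
#' @param cfg A `session_config`.
#' @return `cfg`, invisibly usable; errors describe the first violation.
#' @export
validate_session_config <- function(cfg) {
  if (!inherits(cfg, "session_config")) abort_biosense("Not a session_config.")
  codes <- cfg$sample_codes
  if (length(codes) == 0L) abort_biosense("At least one sample code is required.")
  dup <- codes[duplicated(codes)]
  if (length(dup) > 0L) {
    abort_biosense(sprintf("Duplicate sample code(s): %s.",
                           paste(unique(dup), collapse = ", ")),
                   class = "biosense_validation_error")
  }
  if (length(cfg$questions) == 0L) {
    abort_biosense("A session needs at least one question.",
                   class = "biosense_validation_error")
  }
  ok <- vapply(cfg$questions, inherits, logical(1), what = "question_spec")
  if (!all(ok)) abort_biosense("All questions must be question_spec objects.")
  descs <- vapply(cfg$questions, `[[`, character(1), "descriptor")
  # conditional targets must exist and not form a jump cycle
  goto <- vapply(cfg$questions, function(q) {
    if (is.null(q$conditional)) NA_character_ else as.character(q$conditional$goto)
  }, character(1))
  bad <- goto[!is.na(goto) & !(goto %in% descs)]
  if (length(bad) > 0L) {
    abort_biosense(sprintf("Conditional target(s) not in question list: %s.",
                           paste(unique(bad), collapse = ", ")),
                   class = "biosense_validation_error")
  }
  for (i in seq_along(descs)) {
    seen <- integer(0)
    j <- i
    while (!is.na(goto[j])) {
      if (j %in% seen) {
        abort_biosense(sprintf("Conditional questions form a cycle at '%s'.", descs[j]),
                       class = "biosense_validation_error")
      }
      seen <- c(seen, j)
      j <- match(goto[j], descs)
    }
  }
  if (!is.null(cfg$ranking)) {
    if (!inherits(cfg$ranking, "ranking_spec")) abort_biosense("`ranking` must be a ranking_spec.")
    if (cfg$ranking$n_samples > length(codes)) {
      abort_biosense(sprintf(
        "Ranking asks for %d samples but only %d codes are defined.",
        cfg$ranking$n_samples, length(codes)),
        class = "biosense_validation_error")
    }
  }
  cfg
}

#' Serialize a session configuration to its JSON document
#'
#' Emits the JSON configuration file deployed to the test devices. The
#' document round-trips: `parse_config(build_config(cfg))` reconstructs an
#' equal `session_config`, and invalid configurations are rejected before
#' serialization so schema violations cannot appear in output.
#'
#' @param cfg A validated [session_config()].
#' @param path Optional file path; when given the JSON is written there.
#' @return JSON text (invisibly when `path` is given).
#' @export
build_config <- function(cfg, path = NULL) {
  validate_session_config(cfg)
  doc <- list(
    format = "biosense-session",
    version = 1L,
    title = cfg$title,
    sample_codes = cfg$sample_codes,
    randomize = cfg$randomize,
    repeat_questions = cfg$repeat_questions,
    seed = cfg$seed,
    ranking = if (is.null(cfg$ranking)) NULL else
      list(position = cfg$ranking$position, n_samples = cfg$ranking$n_samples),
    questions = lapply(cfg$questions, function(q) {
      list(descriptor = q$descriptor, scale_kind = q$scale_kind,
           levels = q$levels, conditional = q$conditional,
           media = q$media, display_time = q$display_time)
    })
  )
  doc <- doc[!vapply(doc, is.null, logical(1))]
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' Parse a session-configuration JSON document
#'
#' @param json JSON text or a path to a `.json` file.
#' @return A validated [session_config()].
#' @export
parse_config <- function(json) {
  if (length(json) == 1L && !grepl("[{]", json) && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  doc <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(doc$format, "biosense-session")) {
    abort_biosense("Not a biosense session configuration document.")
  }
  questions <- lapply(doc$questions, function(q) {
    question_spec(
      descriptor = q$descriptor, scale_kind = q$scale_kind,
      levels = if (length(q$levels)) unlist(q$levels) else NULL,
      conditional = q$conditional,
      media = q$media %||% NULL,
      display_time = q$display_time %||% NULL
    )
  })
  ranking <- if (!is.null(doc$ranking)) {
    ranking_spec(position = doc$ranking$position, n_samples = doc$ranking$n_samples)
  }
  session_config(
    title = doc$title,
    sample_codes = unlist(doc$sample_codes),
    questions = questions,
    randomize = isTRUE(doc$randomize),
    repeat_questions = isTRUE(doc$repeat_questions),
    ranking = ranking,
    seed = doc$seed %||% 1L
  )
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf("<session_config> '%s'\n", x$title))
  cat(sprintf("  samples: %s\n", paste(x$sample_codes, collapse = ", ")))
  cat(sprintf("  questions: %d | randomize: %s | repeat: %s | ranking: %s\n",
              length(x$questions), x$randomize, x$repeat_questions,
              if (is.null(x$ranking)) "off"
              else sprintf("%d samples", x$ranking$n_samples)))
  invisible(x)
}

#' Per-participant sample presentation order
#'
#' Deterministic seeded permutation of the sample codes, keyed by the pair
#' (participant id, session seed): the same participant always sees the same
#' order, different participants get independent uniform permutations. The
#' caller's RNG state is untouched.
#'
#' @param codes Character vector of sample codes (non-empty).
#' @param participant_id Participant identifier string.
#' @param seed Session seed (integer).
#' @return A permutation of `codes`.
#' @export
randomize_presentation <- function(codes, participant_id, seed) {
  if (length(codes) == 0L) abort_biosense("`codes` must be non-empty.")
  assert_string(participant_id, "participant_id")
  assert_number(seed, "seed")
  key <- fnv1a32(paste(participant_id, seed, sep = "|"))
  with_local_seed(key, sample(codes, length(codes), replace = FALSE))
}
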