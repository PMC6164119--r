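# Internal helpers shared across modules.

abort_biosense <- function(msg, class = "biosense_error") {
  rlang::abort(msg, class = c(class, "biosense_error"))
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort_biosense(sprintf("`%s` must be a single TRUE/FALSE.", name))
  }
  invisible(x)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_biosense(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort_biosense(sprintf("`%s` must lie in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

assert_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    abort_biosense(sprintf("`%s` must be a non-empty string.", name))
  }
  invisible(x)
}

# 32-bit FNV-1a hash of a string, returned as a non-negative double < 2^31.
# Used to derive platform-stable RNG seeds from (participant_id, seed) keys.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    # 32-bit modular multiply by the FNV prime 16777619, done in doubles
    h <- (h * 16777619) %% 4294967296
  }
  h %% 2147483647
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
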