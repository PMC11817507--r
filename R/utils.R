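#' @keywords internal
"_PACKAGE"

# Validation helpers shared across modules. All user-facing errors go through
# stop_petvasc() so they carry a stable class for testing.

stop_petvasc <- function(msg, class = "petvasc_error", ...) {
  stop(structure(
    class = c(class, "petvasc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_petvasc(sprintf("`%s` must be a positive finite number", name),
                 class = "petvasc_validation_error")
  }
  invisible(x)
}

assert_in <- function(x, choices, name) {
  if (length(x) != 1L || !x %in% choices) {
    stop_petvasc(sprintf("`%s` must be one of: %s", name,
                         paste(choices, collapse = ", ")),
                 class = "petvasc_validation_error")
  }
  invisible(x)
}

#' Deterministic per-stage seed derived from a global seed
#'
#' Fans a single pipeline seed out to independent stage seeds so that any
#' stage can be re-run in isolation with the same random stream it saw inside
#' the full pipeline. The result is always a valid 32-bit integer seed.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. "phantom", "split", "cv").
#' @return An integer seed in [0, 2^31 - 1).
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 10007) %% 2147483629)
}

# Evaluate an expression under a local RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Segment labels in mask-integer order (labels 1:4).
SEGMENT_LEVELS <- c("ascending", "arch", "descending", "abdominal")

GROUP_LEVELS <- c("GCA", "ATHERO")
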