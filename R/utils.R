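#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Package logging
#'
#' Lightweight leveled logger. The threshold is controlled by
#' `options(slgeno.log_level = )`, one of `"debug"`, `"info"`, `"warn"`,
#' `"quiet"` (default `"warn"`). Warnings that the contracts require
#' (constant-prediction correlation, rank deficiency, indeterminate
#' residues) are emitted with [warning()] regardless of the log level.
#'
#' @param level one of "debug", "info", "warn"
#' @param ... message parts, pasted with no separator
#' @return invisibly, whether the message was emitted
#' @keywords internal
sl_log <- function(level = c("info", "debug", "warn"), ...) {
  level <- match.arg(level)
  threshold <- getOption("slgeno.log_level", "warn")
  ord <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  emit <- ord[[level]] >= ord[[match.arg(threshold, names(ord))]]
  if (emit) {
    message(sprintf("[slgeno %s] %s", level, paste0(...)))
  }
  invisible(emit)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded internals do not perturb
#' the caller's RNG stream. With `seed = NULL` the expression runs on the
#' current stream.
#'
#' @param seed integer seed or NULL
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Stable small-integer hash of a string
#'
#' Used for the seed fan-out: master seed + stable learner-name hash, so
#' adding a learner to a roster does not perturb the randomness of the
#' others. Plain polynomial rolling hash over UTF-8 code points, kept
#' below 2^31.
#'
#' @param x character scalar
#' @return non-negative integer < 2^28
#' @keywords internal
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 131 + ch) %% 268435399
  as.integer(h)
}

#' Derive a child seed from a master seed and string tags
#' @param master integer master seed (NULL propagates NULL)
#' @param ... character tags, e.g. learner name, "folds", k value
#' @keywords internal
derive_seed <- function(master, ...) {
  if (is.null(master)) return(NULL)
  tags <- vapply(list(...), as.character, character(1))
  h <- as.double(master) %% 268435399
  for (tag in tags) h <- (h * 7919 + stable_hash(tag)) %% 268435399
  as.integer(h)
}

stop_slgeno <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "slgeno_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
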