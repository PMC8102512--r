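#' @keywords internal
"_PACKAGE"

## NULL-default helper, used throughout for optional config fields.
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a validation error naming the offending field
#' @noRd
validation_error <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

assert_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) validation_error(field, msg)
  invisible(TRUE)
}

#' Derive a child RNG seed from a parent seed and a stage label
#'
#' Every stage of the pipeline draws its own seed deterministically from the
#' global seed so that stages can be rerun in isolation. Kept below 2^31.
#' @noRd
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 99991L)
}

#' Evaluate an expression with a temporary RNG seed, restoring global state
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## Minimal structured logger: one INFO line per event, to stderr (and a file
## when a run log is open).
.log_state <- new.env(parent = emptyenv())

log_open <- function(path) {
  .log_state$con <- file(path, open = "at")
  invisible(path)
}

log_close <- function() {
  if (!is.null(.log_state$con)) {
    close(.log_state$con)
    .log_state$con <- NULL
  }
  invisible(NULL)
}

log_info <- function(fmt, ...) {
  line <- sprintf("[%s] INFO %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(fmt, ...))
  message(line)
  if (!is.null(.log_state$con)) writeLines(line, .log_state$con)
  invisible(line)
}

#' md5 of a file, for stage input/output logging
#' @noRd
content_hash <- function(path) unname(tools::md5sum(path))
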