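#' Classed error conditions
#'
#' All user-facing errors raised by blindscore carry a condition class of the
#' form `bs_<kind>_error` below `bs_error`, so callers (and the HTTP layer)
#' can dispatch on the failure kind rather than matching message text.
#'
#' Kinds in use: `validation` (bad input), `not_found` (unknown id or token),
#' `access_denied` (known but disabled share token, cross-session frame
#' access), `unsupported_media` (undecodable payload), `incomplete_submission`
#' (answers missing for some question), `session_finished` (observer already
#' completed the pass), `empty_project` (no images to present), `generation`
#' (synthetic image could not be produced), `tally_only` (question has no
#' numeric encoding), `undefined_correlation` (constant rank vector).
#'
#' @param kind short kind string, e.g. "validation".
#' @param message human-readable message.
#' @param ... named fields attached to the condition.
#' @return never returns; signals the condition.
#' @keywords internal
bs_abort <- function(kind, message, ...) {
  cls <- paste0("bs_", kind, "_error")
  stop(structure(
    class = c(cls, "bs_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

bs_check <- function(ok, kind, message, ...) {
  if (!isTRUE(ok)) bs_abort(kind, message, ...)
  invisible(TRUE)
}

# Scalar helpers used by validators across modules.
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
is_flag   <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
is_num1   <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
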