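#' Workflow tokens
#'
#' Tokens are the unit of dataflow moving along workflow edges. A token has a
#' status: `DATA` carries a payload (inline text), `DUMMY` encodes a pure
#' execution dependency and carries nothing, `FAIL` marks a pruned branch
#' (e.g. the branch a multi-choice switch decided against). A token may
#' instead hold an ordered list of item tokens; lists nest recursively, so a
#' list of lists is a valid token.
#'
#' @param payload Character scalar payload for a `DATA` token.
#' @param items List of tokens for a list token.
#' @return An object of class `wf_token`.
#' @examples
#' token_data("ACGT")
#' token_list(list(token_data("a"), token_data("b")))
#' @name wf_token
NULL

new_token <- function(status, payload = NULL, items = NULL) {
  structure(list(status = status, payload = payload, items = items),
            class = "wf_token")
}

#' @rdname wf_token
#' @export
token_data <- function(payload) {
  stopifnot(is.character(payload), length(payload) == 1L)
  new_token("DATA", payload = payload)
}

#' @rdname wf_token
#' @export
token_dummy <- function() new_token("DUMMY")

#' @rdname wf_token
#' @export
token_fail <- function() new_token("FAIL")

#' @rdname wf_token
#' @export
token_list <- function(items = list()) {
  stopifnot(is.list(items))
  for (it in items) {
    if (!inherits(it, "wf_token")) {
      wf_stop("TYPE", "list token items must be wf_token objects")
    }
  }
  new_token("DATA", items = items)
}

#' @rdname wf_token
#' @param x Object to test.
#' @export
is_token <- function(x) inherits(x, "wf_token")

is_list_token <- function(x) is_token(x) && !is.null(x$items)
is_fail <- function(x) is_token(x) && identical(x$status, "FAIL")
is_dummy <- function(x) is_token(x) && identical(x$status, "DUMMY")
is_data <- function(x) is_token(x) && identical(x$status, "DATA")

#' @export
print.wf_token <- function(x, ...) {
  if (is_list_token(x)) {
    cat(sprintf("<wf_token list[%d]>\n", length(x$items)))
  } else if (is_data(x)) {
    p <- x$payload
    if (nchar(p) > 40) p <- paste0(substr(p, 1, 37), "...")
    cat(sprintf("<wf_token DATA %s>\n", deparse(p)))
  } else {
    cat(sprintf("<wf_token %s>\n", x$status))
  }
  invisible(x)
}

# Flatten a (possibly nested) list token into one text stream. Items are
# joined with the block separator on its own line; scalar tokens pass
# through. Used when a list token reaches a port that expects one object.
flatten_token <- function(tok, separator = "%%%") {
  if (!is_list_token(tok)) {
    if (is_data(tok)) return(tok$payload)
    return("")
  }
  parts <- vapply(tok$items, flatten_token, character(1), separator = separator)
  paste(parts, collapse = paste0("\n", separator, "\n"))
}

#' Extract the (nested) payload structure of a token
#'
#' Canonical comparison form: a scalar token yields its payload string, a
#' list token yields a (possibly nested) list of payloads.
#'
#' @param tok A [token_data()] or [token_list()].
#' @return Character scalar or nested list of payloads.
#' @export
token_payloads <- function(tok) {
  if (is_list_token(tok)) return(lapply(tok$items, token_payloads))
  tok$payload
}
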