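# Condition helpers. Every package error carries a short machine-readable
# code (e.g. CYCLE, DANGLING_EDGE, PREDICATE_FAILED) in the message and in
# the condition's `code` field. Errors raised while a workflow is running
# (class wf_run_error) are caught by the engine and turned into a failed
# RunResult; structural/configuration errors propagate as ordinary errors.

wf_stop <- function(code, msg, class = "wf_error", call. = FALSE) {
  cond <- structure(
    class = c(class, "wf_error", "error", "condition"),
    list(message = sprintf("[%s] %s", code, msg), call = NULL, code = code)
  )
  stop(cond)
}

wf_run_stop <- function(code, msg) wf_stop(code, msg, class = "wf_run_error")

wf_format_stop <- function(code, msg) wf_stop(code, msg, class = "wf_format_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
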