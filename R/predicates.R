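#' Branch and termination predicates
#'
#' Predicates drive the multi-choice switch, the data-select pattern and
#' iteration termination. Two kinds are supported:
#' \describe{
#'   \item{expression}{a small safe expression language over token payload
#'     text and the iteration counter. The expression is evaluated in an
#'     environment exposing only the bound variables (`payload`, `value`,
#'     `a`, `b`, `iteration`, `input(port)`) and a whitelist of pure base
#'     functions (comparisons, arithmetic, `grepl`, `nchar`, `len`,
#'     `substr`, `startsWith`, `toupper`, ...). No general code execution.}
#'   \item{program}{a path to a user program honoring the predicate CLI
#'     contract: it is invoked with the bound inputs staged as files (one
#'     argument per port, in port order), must print the chosen out-port
#'     name or `true`/`false` on stdout, and exit 0.}
#' }
#' Evaluation is deterministic for fixed inputs.
#'
#' @param source Expression text or program path.
#' @param kind `"expression"` or `"program"`.
#' @return A `wf_predicate` object.
#' @examples
#' wf_predicate("nchar(payload) >= 3")
#' wf_predicate('if (grepl("^[ACGTN]+$", payload)) "dna" else "protein"')
#' @export
wf_predicate <- function(source, kind = "expression") {
  if (!kind %in% c("expression", "program")) {
    wf_stop("PREDICATE_SPEC", sprintf("unknown predicate kind '%s'", kind))
  }
  structure(list(kind = kind, source = source), class = "wf_predicate")
}

predicate_whitelist <- c(
  "if", "(", "{", "==", "!=", ">=", "<=", ">", "<", "&&", "||", "&", "|",
  "!", "+", "-", "*", "/", "%%", "c", "grepl", "nchar", "substr", "substring",
  "startsWith", "endsWith", "toupper", "tolower", "as.numeric", "as.character",
  "as.integer", "paste", "paste0", "min", "max", "abs", "trimws", "isTRUE",
  "ifelse", "identical", "length", "xor")

predicate_env <- function(vars) {
  base_funs <- mget(predicate_whitelist, envir = baseenv())
  env <- list2env(base_funs, parent = emptyenv())
  env$len <- function(x) nchar(x)
  for (nm in names(vars)) assign(nm, vars[[nm]], envir = env)
  env
}

# Evaluate a predicate.
#   vars:   named list of variables for expression predicates
#   files:  character vector of staged input files for program predicates
# Returns whatever the expression yields (character port name or logical).
eval_predicate <- function(pred, vars = list(), files = character(0)) {
  if (is.null(pred)) wf_run_stop("PREDICATE_FAILED", "no predicate supplied")
  if (pred$kind == "expression") {
    expr <- tryCatch(parse(text = pred$source),
                     error = function(e) wf_run_stop("PREDICATE_FAILED",
                       sprintf("cannot parse predicate: %s", conditionMessage(e))))
    out <- tryCatch(eval(expr, envir = predicate_env(vars)),
                    error = function(e) wf_run_stop("PREDICATE_FAILED",
                      sprintf("predicate evaluation failed: %s", conditionMessage(e))))
    return(out)
  }
  # program contract
  if (!file.exists(pred$source)) {
    wf_run_stop("PREDICATE_FAILED", sprintf("predicate program '%s' not found", pred$source))
  }
  res <- suppressWarnings(system2(pred$source, shQuote(files), stdout = TRUE, stderr = FALSE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L) {
    wf_run_stop("PREDICATE_FAILED", sprintf("predicate program exited with status %d", status))
  }
  ans <- trimws(res[1] %||% "")
  if (tolower(ans) %in% c("true", "false")) return(identical(tolower(ans), "true"))
  ans
}
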