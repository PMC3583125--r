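#' List expansion operators: map, dot product, cross product
#'
#' Given list tokens, these operators produce the task-instance bindings
#' the wrapper dispatches independently (and in parallel, conceptually):
#' \itemize{
#'   \item map over one list of n items yields n bindings, order-preserving;
#'   \item dot product of lists `A[a1..an]`, `B[b1..bm]` with `n <= m`
#'     yields the n index-wise tuples `(a_i, b_i)`; trailing items of the
#'     longer list are ignored; with more than two lists, pairing is
#'     index-wise up to the shortest list;
#'   \item cross product yields all `n * m` tuples in row-major order (all
#'     pairs for `a1` first, the last list varying fastest).
#' }
#'
#' @param x,... List tokens ([token_list()]); `wf_combine_map()` takes one,
#'   the product operators take two or more.
#' @return A list of bindings: for map, a list of item tokens; for the
#'   products, a list of unnamed token tuples (lists).
#' @examples
#' a <- token_list(list(token_data("a1"), token_data("a2")))
#' b <- token_list(list(token_data("b1"), token_data("b2"), token_data("b3")))
#' length(wf_combine_dot(a, b))   # 2
#' length(wf_combine_cross(a, b)) # 6
#' @export
wf_combine_map <- function(x) {
  if (!is_list_token(x)) wf_run_stop("LIST_EXPECTED", "map needs a list token")
  x$items
}

#' @rdname wf_combine_map
#' @export
wf_combine_dot <- function(x, ...) {
  lists <- c(list(x), list(...))
  items <- lapply(lists, function(t) {
    if (!is_list_token(t)) wf_run_stop("LIST_EXPECTED", "dot product needs list tokens")
    t$items
  })
  n <- min(vapply(items, length, integer(1)))
  if (n == 0L) return(list())
  lapply(seq_len(n), function(i) lapply(items, `[[`, i))
}

#' @rdname wf_combine_map
#' @export
wf_combine_cross <- function(x, ...) {
  lists <- c(list(x), list(...))
  items <- lapply(lists, function(t) {
    if (!is_list_token(t)) wf_run_stop("LIST_EXPECTED", "cross product needs list tokens")
    t$items
  })
  lens <- vapply(items, length, integer(1))
  if (any(lens == 0L)) return(list())
  # row-major: first list outermost, last list varying fastest
  idx <- expand.grid(rev(lapply(lens, seq_len)), KEEP.OUT.ATTRS = FALSE)
  idx <- idx[, rev(seq_along(items)), drop = FALSE]
  idx <- idx[do.call(order, as.list(idx)), , drop = FALSE]
  lapply(seq_len(nrow(idx)), function(r) {
    lapply(seq_along(items), function(j) items[[j]][[idx[r, j]]])
  })
}

#' Data select pattern
#'
#' Returns exactly one of its two inputs: `a` if the predicate holds,
#' otherwise `b`. If exactly one input is FAIL, the other is returned
#' without evaluating the predicate — this one-sided bypass makes
#' switch -> branches -> select joins work without user predicate
#' boilerplate. If both inputs are FAIL, the result is FAIL.
#'
#' @param a,b Input tokens.
#' @param predicate A [wf_predicate()]; expression predicates see `a` and
#'   `b` bound to the input payloads, plus `payload` (alias for `a`).
#' @return One of the input tokens (or FAIL).
#' @examples
#' wf_data_select(token_data("xyz"), token_data("ab"),
#'                wf_predicate("nchar(a) >= nchar(b)"))
#' @export
wf_data_select <- function(a, b, predicate = NULL) {
  if (is_fail(a) && is_fail(b)) return(token_fail())
  if (is_fail(a)) return(b)
  if (is_fail(b)) return(a)
  vars <- list(a = a$payload %||% "", b = b$payload %||% "",
               payload = a$payload %||% "")
  res <- eval_predicate(predicate, vars = vars)
  if (!is.logical(res) || length(res) != 1L || is.na(res)) {
    wf_run_stop("PREDICATE_FAILED", "select predicate must yield TRUE or FALSE")
  }
  if (res) a else b
}

#' Data collect (merge) pattern
#'
#' Concatenates its inputs, in declared port order, into a list token.
#' List-valued inputs are kept as nested items, so collecting a list
#' creates a nested collection. FAIL inputs are dropped (they mark pruned
#' branches); if every input is FAIL the result is FAIL. DUMMY inputs
#' carry no data and are dropped as well.
#'
#' @param tokens Ordered list of input tokens.
#' @return A list token, or FAIL.
#' @examples
#' out <- wf_data_collect(list(token_data("a"), token_data("b")))
#' length(out$items)  # 2
#' @export
wf_data_collect <- function(tokens) {
  if (!length(tokens)) wf_run_stop("COLLECT", "collect needs at least one input")
  if (all(vapply(tokens, is_fail, logical(1)))) return(token_fail())
  keep <- Filter(function(t) !is_fail(t) && !is_dummy(t), tokens)
  token_list(keep)
}

#' Split a multi-FASTA input into a list token
#'
#' The list-defining node of the metagenomics case study: turns a
#' multi-FASTA payload into a list whose items are either single records
#' (`mode = "per_record"`) or blocks of at most `k` records
#' (`mode = "blocks"`, yielding `ceiling(N / k)` blocks). Record order is
#' preserved and records are never split across blocks.
#'
#' @param text Multi-FASTA text (or a [token_data()] holding it).
#' @param mode `"per_record"` or `"blocks"`.
#' @param k Block size (records per block), for `mode = "blocks"`.
#' @param separator Block separator symbol used when a list is later
#'   serialized to a single stream; kept with the node for that purpose.
#' @return A list token of FASTA text items.
#' @examples
#' fa <- ">a\nACGT\n>b\nGGGG\n>c\nTTTT"
#' length(wf_split_fasta(fa, "per_record")$items)      # 3
#' length(wf_split_fasta(fa, "blocks", k = 2)$items)   # 2
#' @export
wf_split_fasta <- function(text, mode = c("per_record", "blocks"), k = 1L,
                           separator = "%%%") {
  mode <- match.arg(mode)
  if (is_token(text)) text <- text$payload %||% ""
  if (mode == "blocks" && (!is.numeric(k) || k < 1)) {
    wf_stop("PARAM", "block size k must be >= 1")
  }
  seqs <- fa_parse(text)
  n <- length(seqs)
  if (n == 0L) return(token_list(list()))
  if (mode == "per_record") {
    items <- lapply(seq_len(n), function(i) token_data(fa_format(seqs[i])))
  } else {
    k <- as.integer(k)
    starts <- seq(1L, n, by = k)
    items <- lapply(starts, function(s) {
      token_data(fa_format(seqs[s:min(n, s + k - 1L)]))
    })
  }
  token_list(items)
}

#' Multi-choice switch decision
#'
#' Evaluates the switch predicate once and routes the input: the selected
#' out-port receives the data token (pass-through), every other out-port
#' receives a FAIL token, so the non-selected subtrees are subsequently
#' skipped by FAIL propagation. Expression predicates may return the
#' out-port name, or TRUE/FALSE for a two-branch switch (TRUE selects the
#' first out-port).
#'
#' @param node A switch [wf_node()].
#' @param inputs Named list of in-port tokens (all DATA or DUMMY).
#' @return A branch decision: `list(selected = <port>, emissions =
#'   <named list of tokens>)`.
#' @export
wf_eval_multi_choice <- function(node, inputs) {
  outs <- node_out_names(node)
  data_in <- Filter(function(p) identical(node_port_role(node, "in", p), "data"),
                    node_in_names(node))
  payload_tok <- if (length(data_in)) inputs[[data_in[1]]] else NULL
  payload <- if (!is.null(payload_tok) && is_data(payload_tok))
    payload_tok$payload %||% "" else ""
  vars <- list(
    payload = payload,
    value = suppressWarnings(as.numeric(payload)),
    input = function(port) {
      t <- inputs[[port]]
      if (is.null(t)) "" else t$payload %||% ""
    })
  files <- character(0)
  if (!is.null(node$predicate) && node$predicate$kind == "program") {
    dir <- tempfile("pred"); dir.create(dir)
    files <- vapply(names(inputs), function(p) {
      f <- file.path(dir, p)
      writeLines(inputs[[p]]$payload %||% "", f)
      f
    }, character(1))
  }
  res <- eval_predicate(node$predicate, vars = vars, files = files)
  selected <- if (is.logical(res)) {
    if (length(outs) != 2L) {
      wf_run_stop("PREDICATE_FAILED",
                  "boolean switch predicate requires exactly 2 out-ports")
    }
    if (isTRUE(res)) outs[1] else outs[2]
  } else as.character(res)
  if (!selected %in% outs) {
    wf_run_stop("PREDICATE_FAILED",
                sprintf("switch predicate chose '%s', not an out-port", selected))
  }
  pass <- payload_tok %||% token_dummy()
  emissions <- stats::setNames(lapply(outs, function(p) {
    if (identical(p, selected)) pass else token_fail()
  }), outs)
  list(selected = selected, emissions = emissions)
}

#' FAIL propagation through a skipped node
#'
#' When a required in-port holds a FAIL token the node's tool is not
#' invoked; the FAIL signal is passed on through every out-port so the
#' entire downstream subtree is pruned.
#'
#' @param node A [wf_node()].
#' @return Named list mapping every out-port to a FAIL token.
#' @export
wf_propagate_fail <- function(node) {
  outs <- node_out_names(node)
  stats::setNames(lapply(outs, function(p) token_fail()), outs)
}
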