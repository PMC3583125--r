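#' Static single-processor schedule
#'
#' Precomputes a sequential task order by topological traversal: a node is
#' appended only once all its predecessors have been appended, so when
#' tasks run one at a time the invocation order is known before execution.
#' Ties between simultaneously schedulable nodes are broken
#' lexicographically by node id, making the schedule deterministic.
#'
#' @param graph A [wf_graph()].
#' @return Character vector of node ids in topological order.
#' @examples
#' g <- wf_graph("diamond", nodes = list(
#'   wf_node("a", tool = "identity", in_ports = "in", out_ports = "out"),
#'   wf_node("b", tool = "identity", in_ports = "in", out_ports = "out"),
#'   wf_node("c", tool = "identity", in_ports = "in", out_ports = "out"),
#'   wf_node("d", kind = "collect", in_ports = c("in1", "in2"))),
#'   edges = list(wf_edge(c("a", "out"), c("b", "in")),
#'                wf_edge(c("a", "out"), c("c", "in")),
#'                wf_edge(c("b", "out"), c("d", "in1")),
#'                wf_edge(c("c", "out"), c("d", "in2"))),
#'   inputs = list(x = c("a", "in")), outputs = list(y = c("d", "out")))
#' wf_static_schedule(g)  # "a" "b" "c" "d"
#' @export
wf_static_schedule <- function(graph) {
  ids <- names(graph$nodes)
  succ <- node_successors(graph)
  indeg <- stats::setNames(integer(length(ids)), ids)
  for (u in ids) for (v in succ[[u]]) indeg[[v]] <- indeg[[v]] + 1L
  ready <- sort(ids[indeg[ids] == 0L])
  order <- character(0)
  while (length(ready)) {
    u <- ready[1]; ready <- ready[-1]
    order <- c(order, u)
    for (v in succ[[u]]) {
      indeg[[v]] <- indeg[[v]] - 1L
      if (indeg[[v]] == 0L) ready <- sort(c(ready, v))
    }
  }
  if (length(order) != length(ids)) {
    wf_stop("CYCLE", "cannot schedule a cyclic workflow")
  }
  order
}

new_run_ctx <- function(registry, scratch, workers = 1L, engine_cmd = NULL,
                        depth = 0L) {
  ctx <- new.env(parent = emptyenv())
  ctx$registry <- registry
  ctx$scratch <- scratch
  ctx$workers <- workers
  ctx$engine_cmd <- engine_cmd
  ctx$depth <- depth
  ctx$seq <- 0L
  ctx$trace <- list()
  ctx$invocations <- 0L
  ctx$delegations <- 0L
  dir.create(scratch, recursive = TRUE, showWarnings = FALSE)
  ctx
}

trace_event <- function(ctx, node_id, instance, event) {
  ctx$seq <- ctx$seq + 1L
  ctx$trace[[length(ctx$trace) + 1L]] <-
    list(seq = ctx$seq, time = as.numeric(Sys.time()),
         node_id = node_id, instance = instance, event = event)
  invisible(NULL)
}

trace_df <- function(ctx) {
  if (!length(ctx$trace)) {
    return(data.frame(seq = integer(0), time = numeric(0),
                      node_id = character(0), instance = integer(0),
                      event = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    seq = vapply(ctx$trace, `[[`, integer(1), "seq"),
    time = vapply(ctx$trace, `[[`, numeric(1), "time"),
    node_id = vapply(ctx$trace, `[[`, character(1), "node_id"),
    instance = vapply(ctx$trace, function(r) as.integer(r$instance %||% NA_integer_),
                      integer(1)),
    event = vapply(ctx$trace, `[[`, character(1), "event"),
    stringsAsFactors = FALSE)
}

merge_child_trace <- function(ctx, child, prefix) {
  tr <- child$trace
  if (nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      trace_event(ctx, paste0(prefix, "/", tr$node_id[i]), tr$instance[i],
                  tr$event[i])
    }
  }
  ctx$invocations <- ctx$invocations + child$invocations
  ctx$delegations <- ctx$delegations + child$delegations
  invisible(NULL)
}

as_token <- function(x) {
  if (is_token(x)) return(x)
  if (is.character(x) && length(x) == 1L) return(token_data(x))
  wf_stop("TYPE", "workflow inputs must be wf_token objects or character scalars")
}

#' Execute a workflow
#'
#' Data-availability-driven execution: a node fires when and only when
#' every in-port has received a token (DATA, DUMMY or FAIL). Ready nodes
#' are dispatched in lexicographic order, up to `workers` slots per round;
#' instances execute exactly once, FAIL tokens skip whole subtrees without
#' spawning any tool process, and with deterministic tools the outputs are
#' identical for every `workers` value. A nonzero tool exit is a run-level
#' error: the run stops (fail-fast) and the failing instance is identified
#' in the result. Sub-workflows (composite, iterate bodies, delegated
#' externals) are executed by recursive self-invocation of this engine,
#' with nesting depth capped at 32.
#'
#' @param graph A [wf_graph()].
#' @param inputs Named list binding every exposed input alias to a
#'   [token_data()] (character scalars are coerced).
#' @param workers Positive integer: concurrent dispatch slots.
#' @param registry Tool registry; defaults to the stub suite.
#' @param scratch Per-run scratch directory (created; defaults to a
#'   session temporary directory).
#' @param engine_cmd Optional command template (`{body} {inputs}
#'   {outputs}` placeholders) used to delegate external nodes to a foreign
#'   engine; when `NULL`, delegation runs in-process.
#' @param trace_file Optional path; the run trace is written there as
#'   tab-separated events.
#' @return A `wf_result`: list with `status` (`"success"`/`"failed"`),
#'   `outputs` (named tokens), `trace` (data.frame of timestamped events),
#'   `error`, `invocations`, `delegations`.
#' @examples
#' g <- wf_graph("rev", nodes = list(
#'   wf_node("r", tool = "revseq", in_ports = "in", out_ports = "out")),
#'   inputs = list(seq = c("r", "in")), outputs = list(res = c("r", "out")))
#' wf_run(g, list(seq = "abc"))$outputs$res$payload  # "cba"
#' @export
wf_run <- function(graph, inputs = list(), workers = 1L,
                   registry = wf_stub_registry(), scratch = NULL,
                   engine_cmd = NULL, trace_file = NULL, .depth = 0L) {
  if (.depth > 32L) {
    wf_stop("RECURSION_LIMIT", "sub-workflow nesting deeper than 32 levels")
  }
  if (!is.numeric(workers) || workers < 1L) {
    wf_stop("CONFIG", "workers must be a positive integer")
  }
  assert_valid(graph, registry)
  missing <- setdiff(names(graph$inputs), names(inputs))
  if (length(missing)) {
    wf_stop("INPUT_MISSING", sprintf("unbound exposed input(s): %s",
                                     paste(missing, collapse = ", ")))
  }
  scratch <- scratch %||% tempfile("wfrun")
  ctx <- new_run_ctx(registry, scratch, workers = as.integer(workers),
                     engine_cmd = engine_cmd, depth = .depth)

  inbox <- stats::setNames(
    lapply(graph$nodes, function(n) list()), names(graph$nodes))
  state <- stats::setNames(rep("waiting", length(graph$nodes)), names(graph$nodes))
  outbox <- stats::setNames(vector("list", length(graph$nodes)), names(graph$nodes))

  for (alias in names(graph$inputs)) {
    ref <- graph$inputs[[alias]]
    tok <- as_token(inputs[[alias]])
    if (identical(node_port_role(graph$nodes[[ref[1]]], "in", ref[2]), "control") &&
        is_data(tok)) {
      tok <- token_dummy()
    }
    inbox[[ref[1]]][[ref[2]]] <- tok
  }

  is_ready <- function(id) {
    n <- graph$nodes[[id]]
    state[[id]] == "waiting" &&
      all(node_in_names(n) %in% names(inbox[[id]]))
  }
  deliver <- function(id, outs) {
    outbox[[id]] <<- outs
    for (e in graph$edges) {
      if (e$src[1] != id) next
      tok <- outs[[e$src[2]]]
      if (is.null(tok)) tok <- token_dummy()
      dstn <- graph$nodes[[e$dst[1]]]
      if (identical(node_port_role(dstn, "in", e$dst[2]), "control") && is_data(tok)) {
        tok <- token_dummy()
      }
      inbox[[e$dst[1]]][[e$dst[2]]] <<- tok
    }
  }

  run_error <- NULL
  repeat {
    ready <- sort(Filter(is_ready, names(graph$nodes)))
    if (!length(ready)) break
    batch <- utils::head(ready, ctx$workers)
    for (id in batch) {
      node <- graph$nodes[[id]]
      state[[id]] <- "running"
      res <- tryCatch(
        exec_node(node, inbox[[id]], ctx, graph),
        wf_run_error = function(e) e)
      if (inherits(res, "wf_run_error")) {
        state[[id]] <- "failed"
        run_error <- list(code = res$code, message = conditionMessage(res),
                          node = id)
        break
      }
      if (isTRUE(attr(res, "skipped"))) {
        state[[id]] <- "skipped"
        trace_event(ctx, id, NA_integer_, "skip")
      } else {
        state[[id]] <- "done"
      }
      deliver(id, res)
    }
    if (!is.null(run_error)) break
  }

  outputs <- stats::setNames(
    lapply(graph$outputs, function(ref) {
      if (state[[ref[1]]] == "skipped") return(token_fail())
      outbox[[ref[1]]][[ref[2]]]
    }), names(graph$outputs))

  result <- structure(list(
    status = if (is.null(run_error)) "success" else "failed",
    outputs = outputs, trace = trace_df(ctx), error = run_error,
    invocations = ctx$invocations, delegations = ctx$delegations,
    node_state = state), class = "wf_result")
  if (!is.null(trace_file)) {
    utils::write.table(result$trace, trace_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  result
}

#' @export
print.wf_result <- function(x, ...) {
  cat(sprintf("<wf_result %s: %d outputs, %d trace events, %d invocations, %d delegations>\n",
              x$status, length(x$outputs), nrow(x$trace), x$invocations,
              x$delegations))
  if (!is.null(x$error)) {
    cat(sprintf("  error at node '%s': %s\n", x$error$node, x$error$message))
  }
  invisible(x)
}

#' Execute a sub-workflow
#'
#' Recursive self-invocation of the engine on a nested body graph — the
#' mechanism behind composite nodes, iteration bodies and in-process
#' delegation. Identical contract to [wf_run()]; re-entrant.
#'
#' @inheritParams wf_run
#' @param body A nested [wf_graph()] with at least one node.
#' @return A `wf_result`.
#' @export
wf_run_subworkflow <- function(body, inputs = list(), workers = 1L,
                               registry = wf_stub_registry(), scratch = NULL,
                               engine_cmd = NULL, .depth = 0L) {
  if (is.null(body) || length(body$nodes) == 0L) {
    wf_stop("EMPTY_BODY", "sub-workflow body has no nodes")
  }
  wf_run(body, inputs, workers = workers, registry = registry,
         scratch = scratch, engine_cmd = engine_cmd, .depth = .depth + 1L)
}

# run a nested body and merge its trace/counters into the parent context;
# a failed nested run re-raises as a run error in the parent
run_nested <- function(body, inputs, ctx, prefix) {
  if (is.null(body) || length(body$nodes) == 0L) {
    wf_stop("EMPTY_BODY", sprintf("node '%s': sub-workflow body has no nodes", prefix))
  }
  child <- wf_run(body, inputs, workers = ctx$workers, registry = ctx$registry,
                  scratch = file.path(ctx$scratch, prefix),
                  engine_cmd = ctx$engine_cmd, .depth = ctx$depth + 1L)
  merge_child_trace(ctx, child, prefix)
  if (child$status != "success") {
    wf_run_stop(child$error$code %||% "SUBWORKFLOW_FAILED",
                sprintf("sub-workflow '%s' failed: %s", prefix,
                        child$error$message %||% ""))
  }
  child
}

exec_node <- function(node, inputs, ctx, graph) {
  skippable <- !node$kind %in% c("select", "collect")
  if (skippable && any(vapply(inputs, is_fail, logical(1)))) {
    out <- wf_propagate_fail(node)
    attr(out, "skipped") <- TRUE
    return(out)
  }
  switch(node$kind,
    tool = wrap_invoke(node, inputs, ctx),
    external = exec_external(node, inputs, ctx),
    switch = {
      trace_event(ctx, node$id, 0L, "start")
      dec <- wf_eval_multi_choice(node, inputs)
      trace_event(ctx, node$id, 0L, "end")
      dec$emissions
    },
    select = {
      ins <- node_in_names(node)
      trace_event(ctx, node$id, 0L, "start")
      tok <- wf_data_select(inputs[[ins[1]]], inputs[[ins[2]]], node$predicate)
      trace_event(ctx, node$id, 0L, "end")
      stats::setNames(list(tok), node_out_names(node)[1])
    },
    collect = {
      ins <- node_in_names(node)
      trace_event(ctx, node$id, 0L, "start")
      tok <- wf_data_collect(lapply(ins, function(p) inputs[[p]]))
      trace_event(ctx, node$id, 0L, "end")
      stats::setNames(list(tok), node_out_names(node)[1])
    },
    split_list = {
      params <- effective_params(node)
      ins <- node_in_names(node)
      trace_event(ctx, node$id, 0L, "start")
      tok <- wf_split_fasta(inputs[[ins[1]]],
                            mode = params$mode %||% "per_record",
                            k = as.integer(params$k %||% 1L),
                            separator = params$separator %||% "%%%")
      trace_event(ctx, node$id, 0L, "end")
      stats::setNames(list(tok), node_out_names(node)[1])
    },
    composite = {
      trace_event(ctx, node$id, NA_integer_, "start")
      child <- run_nested(node$body, body_inputs(node, inputs), ctx, node$id)
      trace_event(ctx, node$id, NA_integer_, "end")
      body_outputs(node, child$outputs)
    },
    iterate = run_iteration(node, inputs, ctx),
    wf_stop("CONFIG", sprintf("node '%s': unknown kind '%s'", node$id, node$kind))
  )
}

# map node in-port tokens to body input aliases (matched by name)
body_inputs <- function(node, inputs) {
  aliases <- names(node$body$inputs)
  got <- stats::setNames(lapply(aliases, function(a) inputs[[a]]), aliases)
  missing <- aliases[vapply(got, is.null, logical(1))]
  if (length(missing)) {
    wf_stop("CONFIG", sprintf(
      "node '%s': body input alias(es) %s have no matching in-port",
      node$id, paste(sQuote(missing), collapse = ", ")))
  }
  got
}

body_outputs <- function(node, outs) {
  out_names <- node_out_names(node)
  stats::setNames(lapply(out_names, function(p) outs[[p]] %||% token_dummy()),
                  out_names)
}

# do-while iteration: execute the body, test the termination predicate,
# feed designated outputs back into inputs, repeat
run_iteration <- function(node, inputs, ctx) {
  carried <- body_inputs(node, inputs)
  outs <- NULL
  params <- effective_params(node)
  on_limit <- params$on_limit %||% "error"
  max_it <- as.integer(node$max_iterations %||% 1L)
  i <- 0L
  repeat {
    i <- i + 1L
    trace_event(ctx, node$id, i - 1L, "start")
    child <- run_nested(node$body, carried, ctx, node$id)
    trace_event(ctx, node$id, i - 1L, "end")
    outs <- child$outputs
    first_out <- if (length(outs)) outs[[1]] else NULL
    payload <- if (!is.null(first_out) && is_data(first_out))
      first_out$payload %||% "" else ""
    vars <- list(payload = payload,
                 value = suppressWarnings(as.numeric(payload)),
                 iteration = i,
                 output = function(a) {
                   t <- outs[[a]]
                   if (is.null(t)) "" else t$payload %||% ""
                 })
    halt <- eval_predicate(node$predicate, vars = vars)
    if (!is.logical(halt) || length(halt) != 1L || is.na(halt)) {
      wf_run_stop("PREDICATE_FAILED",
                  "iteration predicate must yield TRUE or FALSE")
    }
    if (isTRUE(halt)) break
    if (i >= max_it) {
      if (identical(on_limit, "warn")) {
        warning(sprintf("node '%s': iteration limit %d reached", node$id, max_it))
        break
      }
      wf_run_stop("ITERATION_LIMIT", sprintf(
        "node '%s': %d iterations without satisfying the termination predicate",
        node$id, max_it))
    }
    # atomic feedback overwrite between passes
    nxt <- carried
    for (out_alias in names(node$feedback %||% character(0))) {
      nxt[[node$feedback[[out_alias]]]] <- outs[[out_alias]]
    }
    carried <- nxt
  }
  body_outputs(node, outs)
}
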