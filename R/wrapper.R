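#' Generic tool wrapper
#'
#' Every tool node is invoked through this wrapper, which stands between
#' the engine and the tool. The wrapper gates on tokens (a FAIL on any
#' in-port means the tool is not invoked and FAIL is passed through every
#' out-port; DUMMY satisfies readiness but is not rendered into the
#' command), expands list inputs into task instances according to the
#' node's combination mode (SINGLE, MAP, DOT, CROSS), dispatches each
#' instance (builtin stubs run in-process; command tools are rendered with
#' [wf_render_command()] and run as an argv subprocess in a per-instance
#' scratch directory), and reassembles per-instance outputs into ordered
#' list tokens — output order equals input order regardless of completion
#' order.
#'
#' @param node A tool [wf_node()].
#' @param inputs Named list of in-port tokens.
#' @param registry Tool registry resolving `node$tool`.
#' @param scratch Scratch directory for command-tool staging.
#' @return Named list of out-port tokens. If the node was skipped via FAIL
#'   propagation the result carries the attribute `skipped = TRUE`.
#' @export
wf_wrap_invoke <- function(node, inputs, registry = wf_stub_registry(),
                           scratch = tempfile("wfwrap")) {
  ctx <- new_run_ctx(registry = registry, scratch = scratch)
  wrap_invoke(node, inputs, ctx)
}

wrap_invoke <- function(node, inputs, ctx) {
  if (any(vapply(inputs, is_fail, logical(1)))) {
    out <- wf_propagate_fail(node)
    attr(out, "skipped") <- TRUE
    return(out)
  }
  tool <- registry_get(ctx$registry, node$tool %||% "")
  if (is.null(tool)) {
    wf_stop("CONFIG", sprintf("node '%s': tool '%s' is not registered",
                              node$id, node$tool %||% "<none>"))
  }
  in_names <- node_in_names(node)
  if (is.null(node$in_ports)) in_names <- port_names(tool$in_ports)
  out_names <- node_out_names(node)
  if (is.null(node$out_ports)) out_names <- port_names(tool$out_ports)

  # edge-delivered parameter tokens
  port_params <- list()
  data_ports <- character(0)
  for (p in in_names) {
    role <- node_port_role(node, "in", p) %||%
      (if (p %in% port_names(tool$in_ports))
         tool$in_ports[[match(p, port_names(tool$in_ports))]]$role else "data")
    tok <- inputs[[p]]
    if (identical(role, "parameter")) {
      if (!is.null(tok) && is_data(tok)) port_params[[p]] <- tok$payload
    } else if (identical(role, "data")) {
      data_ports <- c(data_ports, p)
    } # control ports gate readiness only
  }
  params <- effective_params(node, tool, port_params)

  mode <- node$input_combination %||% "SINGLE"
  if (mode == "SINGLE") {
    binding <- stats::setNames(lapply(data_ports, function(p) inputs[[p]]), data_ports)
    res <- invoke_instance(node, tool, binding, params, ctx, 0L, out_names)
    return(res)
  }

  lp <- node$list_ports
  for (p in lp) {
    if (!is_list_token(inputs[[p]])) {
      wf_run_stop("LIST_EXPECTED",
                  sprintf("node '%s': port '%s' expects a list token", node$id, p))
    }
  }
  tuples <- switch(mode,
    MAP = lapply(wf_combine_map(inputs[[lp[1]]]), list),
    DOT = do.call(wf_combine_dot, lapply(lp, function(p) inputs[[p]])),
    CROSS = do.call(wf_combine_cross, lapply(lp, function(p) inputs[[p]])),
    wf_stop("CONFIG", sprintf("unknown input combination '%s'", mode)))

  broadcast <- setdiff(data_ports, lp)
  per_port_out <- stats::setNames(
    lapply(out_names, function(p) vector("list", length(tuples))), out_names)
  for (i in seq_along(tuples)) {
    binding <- stats::setNames(tuples[[i]], lp)
    for (p in broadcast) binding[[p]] <- inputs[[p]]
    if (any(vapply(binding, is_fail, logical(1)))) {
      # a FAIL item inside a list: the instance is pruned, not invoked
      for (p in out_names) per_port_out[[p]][[i]] <- token_fail()
      next
    }
    res <- invoke_instance(node, tool, binding, params, ctx, i - 1L, out_names)
    for (p in out_names) per_port_out[[p]][[i]] <- res[[p]]
  }
  stats::setNames(lapply(out_names, function(p) token_list(per_port_out[[p]])),
                  out_names)
}

# Execute one task instance. `binding` maps data in-ports to tokens.
invoke_instance <- function(node, tool, binding, params, ctx, idx, out_names) {
  trace_event(ctx, node$id, idx, "start")
  # DUMMY inputs gate execution but are not passed to the tool;
  # a list token reaching a scalar port is serialized to a single stream
  sep <- as.character(params$separator %||% "%%%")
  payloads <- list()
  for (p in names(binding)) {
    tok <- binding[[p]]
    if (is.null(tok) || is_dummy(tok)) next
    payloads[[p]] <- flatten_token(tok, separator = sep)
  }
  out_payloads <- if (is.null(tool$command)) {
    res <- tryCatch(tool$fun(payloads, params), error = function(e) e)
    if (inherits(res, "error")) {
      trace_event(ctx, node$id, idx, "fail")
      if (inherits(res, "wf_run_error")) stop(res)
      wf_run_stop("TOOL_FAILED", sprintf("tool '%s' (node '%s'): %s",
                                         tool$id, node$id, conditionMessage(res)))
    }
    ctx$invocations <- ctx$invocations + 1L
    res
  } else {
    run_command_instance(node, tool, payloads, params, ctx, idx)
  }
  trace_event(ctx, node$id, idx, "end")
  stats::setNames(lapply(out_names, function(p)
    token_data(as.character(out_payloads[[p]] %||% ""))), out_names)
}

run_command_instance <- function(node, tool, payloads, params, ctx, idx) {
  workdir <- file.path(ctx$scratch, sprintf("%s_%04d", node$id, idx))
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  input_files <- stats::setNames(
    file.path(workdir, paste0(names(payloads), ".in")), names(payloads))
  for (p in names(payloads)) writeLines(payloads[[p]], input_files[[p]])
  bind <- wf_render_command(tool, input_files, params, workdir)
  log <- file.path(workdir, "instance.log")
  status <- suppressWarnings(
    system2(bind$argv[1], bind$argv[-1], stdout = log, stderr = log))
  ctx$invocations <- ctx$invocations + 1L
  if (!identical(status, 0L)) {
    trace_event(ctx, node$id, idx, "fail")
    errtxt <- if (file.exists(log))
      paste(utils::tail(readLines(log, warn = FALSE), 5), collapse = " | ") else ""
    wf_run_stop("TOOL_FAILED", sprintf(
      "tool '%s' (node '%s', instance %d) exited with status %s: %s",
      tool$id, node$id, idx, status, errtxt))
  }
  out <- list()
  for (p in names(bind$output_files)) {
    f <- bind$output_files[[p]]
    if (!file.exists(f)) {
      trace_event(ctx, node$id, idx, "fail")
      wf_run_stop("OUTPUT_MISSING", sprintf(
        "tool '%s' (node '%s') did not produce declared output '%s'",
        tool$id, node$id, p))
    }
    out[[p]] <- paste(readLines(f, warn = FALSE), collapse = "\n")
  }
  out
}
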