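#' Maximal external sub-workflows
#'
#' Nodes marked external are executed by a foreign engine through the
#' delegation contract. Invoking that engine once per node is wasteful, so
#' the optimizer partitions the external nodes into *maximal external
#' sub-workflows*: weakly connected sets of external nodes that can each
#' be condensed to a single vertex without introducing a cycle, grown
#' greedily from lexicographically ordered seed nodes (an addition
#' rejected early is retried after the component grows, until a fixpoint).
#' Encapsulating each component into one composite external node means the
#' foreign engine is invoked exactly once per component.
#'
#' @param graph A valid [wf_graph()] with nodes labeled external
#'   (`kind = "external"`) or local.
#' @return A `wf_partition`: `list(components = <list of sorted id
#'   vectors>, component_of = <named integer>)`.
#' @examples
#' # E1 -> E2 via a local detour cannot be one component:
#' reg_port <- function(id, kind) wf_node(id, kind = kind, tool = "identity",
#'   in_ports = "in", out_ports = "out")
#' g <- wf_graph("mix", nodes = list(
#'   reg_port("E1", "external"), reg_port("E2", "external"),
#'   reg_port("L1", "tool")),
#'   edges = list(wf_edge(c("E1", "out"), c("L1", "in")),
#'                wf_edge(c("L1", "out"), c("E2", "in"))),
#'   inputs = list(x = c("E1", "in")), outputs = list(y = c("E2", "out")))
#' wf_find_external_subworkflows(g)$components  # list("E1", "E2")
#' @export
wf_find_external_subworkflows <- function(graph) {
  assert_valid(graph)
  ext <- sort(names(graph$nodes)[vapply(graph$nodes, is_external_node, logical(1))])
  succ <- node_successors(graph)
  pred <- node_predecessors(graph)
  neigh <- function(id) union(succ[[id]], pred[[id]])
  components <- list()
  assigned <- character(0)
  for (seed in ext) {
    if (seed %in% assigned) next
    comp <- seed
    repeat {
      cands <- sort(setdiff(
        intersect(unique(unlist(lapply(comp, neigh))), ext),
        c(comp, assigned)))
      added <- FALSE
      for (cand in cands) {
        trial <- c(components, list(c(comp, cand)))
        if (partition_condensed_acyclic(graph, trial)) {
          comp <- c(comp, cand)
          added <- TRUE
        }
      }
      if (!added) break
    }
    components[[length(components) + 1L]] <- sort(comp)
    assigned <- c(assigned, comp)
  }
  component_of <- stats::setNames(integer(0), character(0))
  for (i in seq_along(components)) {
    component_of[components[[i]]] <- i
  }
  structure(list(components = components, component_of = component_of),
            class = "wf_partition")
}

#' @export
print.wf_partition <- function(x, ...) {
  cat(sprintf("<wf_partition: %d component(s)>\n", length(x$components)))
  for (i in seq_along(x$components)) {
    cat(sprintf("  [%d] %s\n", i, paste(x$components[[i]], collapse = ", ")))
  }
  invisible(x)
}

# is the node-level graph acyclic after condensing each given component to
# a single vertex?
partition_condensed_acyclic <- function(graph, components) {
  grp <- stats::setNames(names(graph$nodes), names(graph$nodes))
  for (i in seq_along(components)) {
    grp[components[[i]]] <- sprintf(".C%d", i)
  }
  gids <- unique(unname(grp))
  succ <- stats::setNames(vector("list", length(gids)), gids)
  for (e in graph$edges) {
    a <- grp[[e$src[1]]]; b <- grp[[e$dst[1]]]
    if (a != b) succ[[a]] <- union(succ[[a]], b)
  }
  edges_acyclic(gids, succ)
}

# diagnostics for a candidate partition; character(0) when valid
check_partition <- function(graph, partition) {
  probs <- character(0)
  ext <- sort(names(graph$nodes)[vapply(graph$nodes, is_external_node, logical(1))])
  all_ids <- unlist(partition$components)
  if (anyDuplicated(all_ids)) probs <- c(probs, "components overlap")
  if (!setequal(all_ids, ext)) {
    probs <- c(probs, "components do not cover exactly the external nodes")
  }
  succ <- node_successors(graph); pred <- node_predecessors(graph)
  for (comp in partition$components) {
    if (length(comp) > 1L) {
      # weak connectivity within the component's induced subgraph
      seen <- comp[1]; frontier <- comp[1]
      while (length(frontier)) {
        nxt <- setdiff(intersect(
          unique(unlist(lapply(frontier, function(u) union(succ[[u]], pred[[u]])))),
          comp), seen)
        seen <- c(seen, nxt); frontier <- nxt
      }
      if (!setequal(seen, comp)) {
        probs <- c(probs, sprintf("component {%s} not weakly connected",
                                  paste(comp, collapse = ",")))
      }
    }
  }
  if (!partition_condensed_acyclic(graph, partition$components)) {
    probs <- c(probs, "condensing the components introduces a cycle")
  }
  probs
}

#' Encapsulate external components into single delegated nodes
#'
#' Replaces each component of the partition by one composite external node
#' whose body is the induced sub-graph (inner nodes become local — the
#' foreign engine executes them natively). Boundary edges are re-wired 1:1
#' to fresh ports on the composite node, and exposed graph inputs/outputs
#' touching a component are re-routed through it. Execution semantics are
#' preserved: the encapsulated workflow produces the same outputs, with
#' exactly one delegation per component.
#'
#' @param graph A valid [wf_graph()].
#' @param partition A partition from [wf_find_external_subworkflows()];
#'   defaults to computing it.
#' @return The re-wired [wf_graph()].
#' @export
wf_encapsulate <- function(graph, partition = wf_find_external_subworkflows(graph)) {
  probs <- check_partition(graph, partition)
  if (length(probs)) {
    wf_stop("PARTITION_ERROR", paste(probs, collapse = "; "))
  }
  if (!length(partition$components)) return(graph)
  nodes <- graph$nodes
  edges <- graph$edges
  inputs <- graph$inputs
  outputs <- graph$outputs
  for (ci in seq_along(partition$components)) {
    comp <- partition$components[[ci]]
    comp_id <- sprintf("xsub_%02d", ci)
    while (comp_id %in% names(nodes)) comp_id <- paste0(comp_id, "x")
    in_alias <- function(v, q) sprintf("in_%s_%s", v, q)
    out_alias <- function(u, p) sprintf("out_%s_%s", u, p)

    body_nodes <- lapply(nodes[comp], function(n) {
      if (is_external_node(n) && is.null(n$body)) n$kind <- "tool"
      n
    })
    body_edges <- list(); new_edges <- list()
    body_inputs <- list(); body_outputs <- list()
    comp_in <- character(0); comp_out <- character(0)

    for (e in edges) {
      s_in <- e$src[1] %in% comp; d_in <- e$dst[1] %in% comp
      if (s_in && d_in) {
        body_edges[[length(body_edges) + 1L]] <- e
      } else if (d_in) {
        a <- in_alias(e$dst[1], e$dst[2])
        body_inputs[[a]] <- e$dst
        comp_in <- union(comp_in, a)
        new_edges[[length(new_edges) + 1L]] <- wf_edge(e$src, c(comp_id, a))
      } else if (s_in) {
        a <- out_alias(e$src[1], e$src[2])
        body_outputs[[a]] <- e$src
        comp_out <- union(comp_out, a)
        new_edges[[length(new_edges) + 1L]] <- wf_edge(c(comp_id, a), e$dst)
      } else {
        new_edges[[length(new_edges) + 1L]] <- e
      }
    }
    for (alias in names(inputs)) {
      ref <- inputs[[alias]]
      if (ref[1] %in% comp) {
        a <- in_alias(ref[1], ref[2])
        body_inputs[[a]] <- ref
        comp_in <- union(comp_in, a)
        inputs[[alias]] <- c(comp_id, a)
      }
    }
    for (alias in names(outputs)) {
      ref <- outputs[[alias]]
      if (ref[1] %in% comp) {
        a <- out_alias(ref[1], ref[2])
        body_outputs[[a]] <- ref
        comp_out <- union(comp_out, a)
        outputs[[alias]] <- c(comp_id, a)
      }
    }
    body <- wf_graph(name = comp_id, nodes = body_nodes, edges = body_edges,
                     inputs = body_inputs, outputs = body_outputs)
    comp_node <- wf_node(comp_id, kind = "external",
                         in_ports = comp_in, out_ports = comp_out,
                         body = body)
    nodes <- c(nodes[setdiff(names(nodes), comp)],
               stats::setNames(list(comp_node), comp_id))
    edges <- new_edges
  }
  out <- wf_graph(graph$name, nodes = nodes, edges = edges,
                  inputs = inputs, outputs = outputs)
  assert_valid(out)
  out
}

#' Delegate a sub-workflow to an external engine
#'
#' Implements the command-line delegation contract: the body workflow and
#' its input tokens are staged to a directory (`body.json`,
#' `inputs/<alias>`), the external engine command is invoked once, and the
#' declared outputs are collected from `outputs/<alias>`. With
#' `engine_cmd = NULL` the native engine executes the body in-process
#' (the package's own engine then plays the role of the foreign one).
#'
#' @param body The sub-workflow to delegate.
#' @param inputs Named list of input tokens (or character payloads) bound
#'   to the body's exposed input aliases.
#' @param engine_cmd Command template with `{body}`, `{inputs}`,
#'   `{outputs}` placeholders, e.g.
#'   `"Rscript path/to/stub_engine.R {body} {inputs} {outputs}"`.
#' @param registry Tool registry for in-process execution.
#' @param workers Dispatch slots for in-process execution.
#' @param stage Staging directory (created).
#' @return Named list of output tokens, one per exposed body output.
#' @export
wf_delegate_execute <- function(body, inputs, engine_cmd = NULL,
                                registry = wf_stub_registry(), workers = 1L,
                                stage = tempfile("delegate")) {
  if (is.null(body) || length(body$nodes) == 0L) {
    wf_stop("EMPTY_BODY", "cannot delegate an empty sub-workflow")
  }
  inputs <- lapply(inputs, as_token)
  if (is.null(engine_cmd)) {
    res <- wf_run_subworkflow(body, inputs, workers = workers,
                              registry = registry)
    if (res$status != "success") {
      wf_run_stop("DELEGATION_FAILED",
                  sprintf("delegated run failed: %s", res$error$message %||% ""))
    }
    return(res$outputs)
  }
  dir.create(file.path(stage, "inputs"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(stage, "outputs"), recursive = TRUE, showWarnings = FALSE)
  body_path <- file.path(stage, "body.json")
  wf_save(body, body_path)
  for (alias in names(inputs)) {
    writeLines(flatten_token(inputs[[alias]]), file.path(stage, "inputs", alias))
  }
  words <- strsplit(engine_cmd, "[[:space:]]+")[[1]]
  words <- words[nzchar(words)]
  argv <- vapply(words, function(w) {
    w <- gsub("{body}", body_path, w, fixed = TRUE)
    w <- gsub("{inputs}", file.path(stage, "inputs"), w, fixed = TRUE)
    gsub("{outputs}", file.path(stage, "outputs"), w, fixed = TRUE)
  }, character(1), USE.NAMES = FALSE)
  log <- file.path(stage, "engine.log")
  status <- tryCatch(
    suppressWarnings(system2(argv[1], argv[-1], stdout = log, stderr = log)),
    error = function(e) -1L)
  if (!identical(status, 0L)) {
    errtxt <- if (file.exists(log))
      paste(utils::tail(readLines(log, warn = FALSE), 5), collapse = " | ") else ""
    wf_run_stop("DELEGATION_FAILED", sprintf(
      "external engine exited with status %s: %s", status, errtxt))
  }
  outs <- stats::setNames(lapply(names(body$outputs), function(alias) {
    f <- file.path(stage, "outputs", alias)
    if (!file.exists(f)) {
      wf_run_stop("OUTPUT_MISSING", sprintf(
        "external engine did not produce output '%s'", alias))
    }
    token_data(paste(readLines(f, warn = FALSE), collapse = "\n"))
  }), names(body$outputs))
  outs
}

# engine hook: execute an external node (leaf or encapsulated component)
exec_external <- function(node, inputs, ctx) {
  trace_event(ctx, node$id, NA_integer_, "delegate")
  ctx$delegations <- ctx$delegations + 1L
  if (!is.null(node$body)) {
    body <- node$body
    bound <- body_inputs(node, inputs)
  } else {
    # leaf external node: delegate a single-node body wrapping its tool
    inner <- node
    inner$kind <- "tool"
    ins <- node_in_names(node); outs <- node_out_names(node)
    body <- wf_graph(
      name = paste0(node$id, "_body"), nodes = list(inner),
      inputs = stats::setNames(lapply(ins, function(p) c(node$id, p)), ins),
      outputs = stats::setNames(lapply(outs, function(p) c(node$id, p)), outs))
    bound <- inputs
  }
  if (is.null(ctx$engine_cmd)) {
    child <- run_nested(body, bound, ctx, node$id)
    return(body_outputs(node, child$outputs))
  }
  stage <- file.path(ctx$scratch, paste0("delegate_", node$id))
  outs <- wf_delegate_execute(body, bound, engine_cmd = ctx$engine_cmd,
                              registry = ctx$registry, workers = ctx$workers,
                              stage = stage)
  body_outputs(node, outs)
}
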