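#' Workflow graph domain types
#'
#' A workflow is a directed acyclic graph whose nodes are computational
#' steps and whose edges carry tokens from an out-port of one node to an
#' in-port of another. Ports select which piece of data produced by a node
#' flows where; each in-port receives at most one edge, so token arrival is
#' unambiguous (fan-in goes through `collect`/`select` nodes).
#'
#' Node kinds:
#' \describe{
#'   \item{tool}{runs a registered tool through the generic wrapper.}
#'   \item{switch}{multi-choice fork: a predicate routes the input to one
#'     out-port (success) and emits FAIL on the others.}
#'   \item{iterate}{do-while loop over a nested body sub-workflow with
#'     feedback of designated outputs into inputs between passes.}
#'   \item{select}{returns one of its two inputs according to a predicate.}
#'   \item{collect}{concatenates its inputs into a list token.}
#'   \item{split_list}{splits a multi-FASTA payload into a list token.}
#'   \item{composite}{a nested sub-workflow executed in-process.}
#'   \item{external}{a node (leaf tool or encapsulated sub-workflow)
#'     executed by a foreign engine through the delegation contract.}
#' }
#'
#' @param name Port or graph name.
#' @param role Port role: `"data"`, `"parameter"` or `"control"`. Control
#'   ports only ever carry DUMMY or FAIL tokens (DATA arriving on a control
#'   port is coerced to DUMMY).
#' @return `wf_port()`, `wf_node()`, `wf_edge()` and `wf_graph()` return
#'   objects of class `wf_port`, `wf_node`, `wf_edge` and `wf_graph`.
#' @name wf_graph_types
NULL

#' @rdname wf_graph_types
#' @export
wf_port <- function(name, role = "data") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!role %in% c("data", "parameter", "control")) {
    wf_stop("PORT_ROLE", sprintf("unknown port role '%s'", role))
  }
  structure(list(name = name, role = role), class = "wf_port")
}

#' @rdname wf_graph_types
#' @param id Node identifier (case-sensitive, unique within a graph).
#' @param kind Node kind, see Details.
#' @param tool For `kind = "tool"` (and leaf external nodes) the id of a
#'   registered tool.
#' @param params Named list of design-time parameter values.
#' @param in_ports,out_ports Lists of [wf_port()] (or character vectors,
#'   taken as data-port names). For tool nodes they default to the tool's
#'   declared ports when resolved against a registry.
#' @param input_combination One of `"SINGLE"`, `"MAP"`, `"DOT"`, `"CROSS"`:
#'   how list-valued in-ports are expanded into task instances.
#' @param list_ports Character vector naming the in-ports treated as lists.
#' @param body Nested [wf_graph()] for `iterate`, `composite` and
#'   encapsulated `external` nodes.
#' @param predicate A [wf_predicate()] for `switch`, `select`, `iterate`.
#' @param feedback Named character vector mapping body output aliases to
#'   body input aliases, applied between iteration passes.
#' @param max_iterations Upper bound on iteration passes.
#' @param service For external nodes imported from a foreign document, a
#'   `list(operation =, endpoint =)` signature used for catalog matching.
#' @export
wf_node <- function(id, kind = "tool", tool = NULL, params = list(),
                    in_ports = NULL, out_ports = NULL,
                    input_combination = "SINGLE", list_ports = character(0),
                    body = NULL, predicate = NULL, feedback = NULL,
                    max_iterations = NULL, service = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  kinds <- c("tool", "switch", "iterate", "select", "collect", "split_list",
             "composite", "external")
  if (!kind %in% kinds) {
    wf_format_stop("UNKNOWN_KIND", sprintf("node '%s': unknown kind '%s'", id, kind))
  }
  as_ports <- function(p) {
    if (is.null(p)) return(NULL)
    if (is.character(p)) p <- lapply(p, wf_port)
    lapply(p, function(q) if (inherits(q, "wf_port")) q else do.call(wf_port, q))
  }
  in_ports <- as_ports(in_ports)
  out_ports <- as_ports(out_ports)
  # sensible port defaults for the pattern kinds
  if (is.null(in_ports)) {
    in_ports <- switch(kind,
      switch = list(wf_port("in")),
      select = list(wf_port("a"), wf_port("b")),
      split_list = list(wf_port("in")),
      NULL)
  }
  if (is.null(out_ports)) {
    out_ports <- switch(kind,
      select = list(wf_port("out")),
      collect = list(wf_port("out")),
      split_list = list(wf_port("out")),
      NULL)
  }
  structure(list(
    id = id, kind = kind, tool = tool, params = params,
    runtime_params = list(),
    in_ports = in_ports, out_ports = out_ports,
    input_combination = input_combination, list_ports = list_ports,
    body = body, predicate = predicate, feedback = feedback,
    max_iterations = max_iterations, service = service
  ), class = "wf_node")
}

#' @rdname wf_graph_types
#' @param src,dst Length-2 character vectors `c(node_id, port_name)` naming
#'   the source out-port and destination in-port.
#' @export
wf_edge <- function(src, dst) {
  stopifnot(length(src) == 2L, length(dst) == 2L)
  structure(list(src = as.character(src), dst = as.character(dst)),
            class = "wf_edge")
}

#' @rdname wf_graph_types
#' @param nodes List of [wf_node()].
#' @param edges List of [wf_edge()].
#' @param inputs Named list of exposed inputs: alias -> `c(node, in_port)`.
#' @param outputs Named list of exposed outputs: alias -> `c(node, out_port)`.
#' @export
wf_graph <- function(name = "workflow", nodes = list(), edges = list(),
                     inputs = list(), outputs = list()) {
  ids <- vapply(nodes, function(n) n$id, character(1))
  if (anyDuplicated(ids)) {
    wf_format_stop("DUP_NODE", sprintf("duplicate node id '%s'", ids[duplicated(ids)][1]))
  }
  names(nodes) <- ids
  structure(list(name = name, nodes = nodes, edges = edges,
                 inputs = inputs, outputs = outputs),
            class = "wf_graph")
}

#' @export
print.wf_graph <- function(x, ...) {
  cat(sprintf("<wf_graph '%s': %d nodes, %d edges, %d inputs, %d outputs>\n",
              x$name, length(x$nodes), length(x$edges),
              length(x$inputs), length(x$outputs)))
  invisible(x)
}

#' @export
print.wf_node <- function(x, ...) {
  cat(sprintf("<wf_node '%s' kind=%s%s>\n", x$id, x$kind,
              if (!is.null(x$tool)) paste0(" tool=", x$tool) else ""))
  invisible(x)
}

port_names <- function(ports) vapply(ports %||% list(), `[[`, character(1), "name")

node_in_names <- function(node) port_names(node$in_ports)
node_out_names <- function(node) port_names(node$out_ports)

node_port_role <- function(node, direction, name) {
  ports <- if (direction == "in") node$in_ports else node$out_ports
  for (p in ports %||% list()) if (p$name == name) return(p$role)
  NULL
}

is_external_node <- function(node) identical(node$kind, "external")

# adjacency on node level: list id -> character vector of successor ids
node_successors <- function(graph) {
  succ <- stats::setNames(vector("list", length(graph$nodes)), names(graph$nodes))
  for (e in graph$edges) {
    succ[[e$src[1]]] <- union(succ[[e$src[1]]], e$dst[1])
  }
  succ
}

node_predecessors <- function(graph) {
  pred <- stats::setNames(vector("list", length(graph$nodes)), names(graph$nodes))
  for (e in graph$edges) {
    pred[[e$dst[1]]] <- union(pred[[e$dst[1]]], e$src[1])
  }
  pred
}

# Kahn's algorithm restricted to detecting whether a node-level digraph
# given as successor lists is acyclic.
edges_acyclic <- function(ids, succ) {
  indeg <- stats::setNames(integer(length(ids)), ids)
  for (u in ids) for (v in succ[[u]]) indeg[[v]] <- indeg[[v]] + 1L
  queue <- ids[indeg[ids] == 0L]
  seen <- 0L
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (v in succ[[u]]) {
      indeg[[v]] <- indeg[[v]] - 1L
      if (indeg[[v]] == 0L) queue <- c(queue, v)
    }
  }
  seen == length(ids)
}

#' Validate a workflow graph
#'
#' Checks all structural invariants and returns a list of diagnostics, each
#' a `list(code, locus, message)`. An empty list means the graph is valid.
#' Codes include `CYCLE`, `DANGLING_EDGE`, `DUP_IN_EDGE`, `SELF_LOOP`,
#' `DANGLING_IO`, `UNBOUND_INPUT`, `TOOL_UNRESOLVED`, `SWITCH_PORTS`,
#' `ITERATE_SPEC`, `COMBINATION_SPEC`.
#'
#' @param graph A [wf_graph()].
#' @param registry Optional tool registry; when supplied, tool references
#'   are checked for resolvability.
#' @return List of diagnostics (empty when valid).
#' @export
wf_validate <- function(graph, registry = NULL) {
  diags <- list()
  note <- function(code, locus, msg) {
    diags[[length(diags) + 1L]] <<- list(code = code, locus = locus, message = msg)
  }
  ids <- names(graph$nodes)

  for (n in graph$nodes) {
    ins <- node_in_names(n); outs <- node_out_names(n)
    if (anyDuplicated(ins)) note("DUP_PORT", n$id, "duplicate in-port name")
    if (anyDuplicated(outs)) note("DUP_PORT", n$id, "duplicate out-port name")
    if (n$kind == "tool" && is.null(n$tool)) {
      note("TOOL_UNRESOLVED", n$id, "tool node without tool reference")
    }
    if (n$kind %in% c("tool", "external") && !is.null(registry) &&
        !is.null(n$tool) && is.null(registry_get(registry, n$tool))) {
      note("TOOL_UNRESOLVED", n$id, sprintf("tool '%s' not in registry", n$tool))
    }
    if (n$kind == "switch" && length(outs) < 2L) {
      note("SWITCH_PORTS", n$id, "switch node needs at least 2 out-ports")
    }
    if (n$kind %in% c("switch", "select", "iterate") && is.null(n$predicate) &&
        n$kind != "iterate") {
      note("PREDICATE_MISSING", n$id, sprintf("%s node without predicate", n$kind))
    }
    if (n$kind == "iterate") {
      if (is.null(n$body) || length(n$body$nodes) == 0L) {
        note("ITERATE_SPEC", n$id, "iterate node needs a non-empty body")
      }
      if (is.null(n$max_iterations) || n$max_iterations < 1L) {
        note("ITERATE_SPEC", n$id, "iterate node needs max_iterations >= 1")
      }
      if (is.null(n$predicate)) {
        note("ITERATE_SPEC", n$id, "iterate node needs a termination predicate")
      }
    }
    if (n$input_combination %in% c("DOT", "CROSS") && length(n$list_ports) < 2L) {
      note("COMBINATION_SPEC", n$id,
           sprintf("%s combination needs >= 2 list ports", n$input_combination))
    }
    if (n$input_combination == "MAP" && length(n$list_ports) != 1L) {
      note("COMBINATION_SPEC", n$id, "MAP combination needs exactly 1 list port")
    }
    if (!is.null(n$body) && n$kind %in% c("iterate", "composite", "external")) {
      for (d in wf_validate(n$body, registry)) {
        note(d$code, paste0(n$id, "/", d$locus), d$message)
      }
    }
  }

  seen_dst <- character(0)
  for (e in graph$edges) {
    locus <- sprintf("%s:%s->%s:%s", e$src[1], e$src[2], e$dst[1], e$dst[2])
    if (e$src[1] == e$dst[1]) note("SELF_LOOP", locus, "self-loop edge")
    ok <- TRUE
    if (!e$src[1] %in% ids || !e$src[2] %in% node_out_names(graph$nodes[[e$src[1]]])) {
      note("DANGLING_EDGE", locus, "edge source port does not exist"); ok <- FALSE
    }
    if (!e$dst[1] %in% ids || !e$dst[2] %in% node_in_names(graph$nodes[[e$dst[1]]])) {
      note("DANGLING_EDGE", locus, "edge destination port does not exist"); ok <- FALSE
    }
    if (ok) {
      key <- paste(e$dst[1], e$dst[2], sep = ":")
      if (key %in% seen_dst) note("DUP_IN_EDGE", locus, "in-port receives more than one edge")
      seen_dst <- c(seen_dst, key)
    }
  }

  for (alias in names(graph$inputs)) {
    ref <- graph$inputs[[alias]]
    if (!ref[1] %in% ids || !ref[2] %in% node_in_names(graph$nodes[[ref[1]]])) {
      note("DANGLING_IO", alias, "exposed input references a missing port")
    }
  }
  for (alias in names(graph$outputs)) {
    ref <- graph$outputs[[alias]]
    if (!ref[1] %in% ids || !ref[2] %in% node_out_names(graph$nodes[[ref[1]]])) {
      note("DANGLING_IO", alias, "exposed output references a missing port")
    }
  }

  # every in-port must be fed by exactly one edge or an exposed input
  fed <- c(vapply(graph$edges, function(e) paste(e$dst[1], e$dst[2], sep = ":"),
                  character(1)),
           vapply(graph$inputs, function(r) paste(r[1], r[2], sep = ":"),
                  character(1)))
  for (n in graph$nodes) {
    for (p in node_in_names(n)) {
      if (!paste(n$id, p, sep = ":") %in% fed) {
        note("UNBOUND_INPUT", n$id,
             sprintf("in-port '%s' is neither wired nor exposed", p))
      }
    }
  }

  if (!edges_acyclic(ids, node_successors(graph))) {
    note("CYCLE", graph$name, "workflow graph contains a cycle")
  }
  diags
}

# stop unless valid
assert_valid <- function(graph, registry = NULL) {
  d <- wf_validate(graph, registry)
  if (length(d)) {
    first <- d[[1]]
    wf_stop(first$code, sprintf("invalid workflow (%d diagnostics); first: %s: %s",
                                length(d), first$locus, first$message))
  }
  invisible(graph)
}
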