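#' Read and write native workflow documents
#'
#' The native carrier format is JSON (UTF-8) with a fixed schema: a
#' `format` tag, a `name`, an array of `nodes` (parameters as node
#' attributes, pattern kinds explicit), an array of `edges`
#' (`{"from": [node, out_port], "to": [node, in_port]}`), and named
#' `inputs`/`outputs` maps exposing ports externally. `wf_save()` is
#' canonical — nodes sorted by id, edges by destination, keys in fixed
#' order — so two serializations of the same graph are byte-identical and
#' `wf_load(wf_save(g))` round-trips.
#'
#' @param input Path to a JSON document, or a JSON string.
#' @param registry Optional tool registry used to fill in tool-node ports
#'   that the document omits.
#' @return `wf_load()` returns a validated [wf_graph()]; `wf_save()`
#'   returns the JSON text (invisibly when written to `path`).
#' @examples
#' g <- wf_graph("demo", nodes = list(
#'   wf_node("a", tool = "identity", in_ports = "in", out_ports = "out")),
#'   inputs = list(x = c("a", "in")), outputs = list(y = c("a", "out")))
#' doc <- wf_save(g)
#' identical(wf_save(wf_load(doc)), doc)
#' @export
wf_load <- function(input, registry = wf_stub_registry()) {
  txt <- if (length(input) == 1L && !grepl("[{\n]", input) && file.exists(input)) {
    paste(readLines(input, warn = FALSE), collapse = "\n")
  } else paste(input, collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) wf_format_stop("SCHEMA",
                    sprintf("not well-formed JSON: %s", conditionMessage(e))))
  graph_from_doc(doc, path = "$", registry = registry)
}

graph_from_doc <- function(doc, path, registry) {
  need <- function(x, field, where) {
    if (is.null(x[[field]])) {
      wf_format_stop("SCHEMA", sprintf("missing '%s' at %s", field, where))
    }
    x[[field]]
  }
  if (!is.list(doc)) wf_format_stop("SCHEMA", sprintf("expected object at %s", path))
  nodes_doc <- need(doc, "nodes", path)
  parse_ports <- function(x) {
    lapply(x %||% list(), function(p) {
      if (is.character(p)) wf_port(p) else wf_port(p$name, p$role %||% "data")
    })
  }
  chr2 <- function(x, where) {
    v <- unlist(x)
    if (length(v) != 2L) {
      wf_format_stop("SCHEMA", sprintf("expected [node, port] pair at %s", where))
    }
    as.character(v)
  }
  nodes <- lapply(seq_along(nodes_doc), function(i) {
    nd <- nodes_doc[[i]]
    where <- sprintf("%s.nodes[%d]", path, i)
    id <- need(nd, "id", where)
    kind <- nd$kind %||% "tool"
    body <- if (!is.null(nd$body)) {
      graph_from_doc(nd$body, paste0(where, ".body"), registry)
    }
    predicate <- if (!is.null(nd$predicate)) {
      wf_predicate(nd$predicate$source, nd$predicate$kind %||% "expression")
    }
    in_ports <- parse_ports(nd$in_ports)
    out_ports <- parse_ports(nd$out_ports)
    if (kind %in% c("tool", "external") && !is.null(nd$tool) &&
        (!length(in_ports) || !length(out_ports))) {
      spec <- registry_get(registry, nd$tool)
      if (!is.null(spec)) {
        if (!length(in_ports)) in_ports <- spec$in_ports
        if (!length(out_ports)) out_ports <- spec$out_ports
      }
    }
    n <- wf_node(id, kind = kind, tool = nd$tool, params = nd$params %||% list(),
                 in_ports = in_ports, out_ports = out_ports,
                 input_combination = nd$input_combination %||% "SINGLE",
                 list_ports = as.character(unlist(nd$list_ports %||% list())),
                 body = body, predicate = predicate,
                 feedback = if (!is.null(nd$feedback))
                   unlist(nd$feedback) else NULL,
                 max_iterations = nd$max_iterations,
                 service = nd$service)
    n$runtime_params <- nd$runtime_params %||% list()
    n
  })
  edges <- lapply(seq_along(doc$edges %||% list()), function(i) {
    ed <- doc$edges[[i]]
    where <- sprintf("%s.edges[%d]", path, i)
    wf_edge(chr2(need(ed, "from", where), where), chr2(need(ed, "to", where), where))
  })
  io <- function(field) {
    x <- doc[[field]] %||% list()
    out <- lapply(seq_along(x), function(i) {
      chr2(x[[i]], sprintf("%s.%s[%s]", path, field, names(x)[i]))
    })
    names(out) <- names(x)
    out
  }
  g <- wf_graph(doc$name %||% "workflow", nodes = nodes, edges = edges,
                inputs = io("inputs"), outputs = io("outputs"))
  assert_valid(g)
  g
}

scalar_list <- function(x) {
  # sorted named list of scalar values; returns NULL when empty
  if (!length(x)) return(NULL)
  x[order(names(x))]
}

node_to_doc <- function(n) {
  ports <- function(p) lapply(p %||% list(), function(q) list(name = q$name, role = q$role))
  out <- list(id = n$id, kind = n$kind)
  if (!is.null(n$tool)) out$tool <- n$tool
  if (length(n$params)) out$params <- scalar_list(n$params)
  if (length(n$runtime_params)) out$runtime_params <- scalar_list(n$runtime_params)
  out$in_ports <- ports(n$in_ports)
  out$out_ports <- ports(n$out_ports)
  out$input_combination <- n$input_combination
  if (length(n$list_ports)) out$list_ports <- I(as.character(n$list_ports))
  if (!is.null(n$service)) {
    out$service <- list(operation = n$service$operation, endpoint = n$service$endpoint)
  }
  if (!is.null(n$predicate)) {
    out$predicate <- list(kind = n$predicate$kind, source = n$predicate$source)
  }
  if (!is.null(n$feedback)) out$feedback <- as.list(n$feedback)[order(names(n$feedback))]
  if (!is.null(n$max_iterations)) out$max_iterations <- n$max_iterations
  if (!is.null(n$body)) out$body <- graph_to_doc(n$body)
  out
}

graph_to_doc <- function(graph) {
  ids <- sort(names(graph$nodes))
  edges <- graph$edges
  if (length(edges)) {
    key <- vapply(edges, function(e) paste(e$dst[1], e$dst[2], e$src[1], e$src[2]),
                  character(1))
    edges <- edges[order(key)]
  }
  io <- function(x) {
    if (!length(x)) return(NULL)
    x <- x[order(names(x))]
    lapply(x, function(r) I(as.character(r)))
  }
  doc <- list(format = "dagflow-workflow", version = 1L, name = graph$name,
              nodes = lapply(graph$nodes[ids], node_to_doc),
              edges = lapply(edges, function(e)
                list(from = I(e$src), to = I(e$dst))))
  inp <- io(graph$inputs); outp <- io(graph$outputs)
  if (!is.null(inp)) doc$inputs <- inp
  if (!is.null(outp)) doc$outputs <- outp
  doc
}

#' @rdname wf_load
#' @param graph A [wf_graph()].
#' @param path Optional output path; when `NULL` the JSON text is returned.
#' @export
wf_save <- function(graph, path = NULL) {
  assert_valid(graph)
  txt <- jsonlite::toJSON(graph_to_doc(graph), auto_unbox = TRUE,
                          digits = NA, pretty = TRUE, null = "null")
  txt <- paste0(as.character(txt), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Override node parameters from a runtime parameter file
#'
#' Applies a flat map of parameter values to one node, overriding its
#' design-time attribute values at run time. Parameter precedence is:
#' runtime file > edge-delivered parameter token > node attribute > tool
#' default. Unspecified parameters are unchanged.
#'
#' @param graph A [wf_graph()].
#' @param node_id Target node id.
#' @param params Named list of values, or path to a flat JSON map.
#' @param registry Tool registry used to resolve the declared parameter
#'   names (tool defaults count as declared).
#' @return The updated graph.
#' @export
wf_apply_params <- function(graph, node_id, params, registry = wf_stub_registry()) {
  if (!node_id %in% names(graph$nodes)) {
    wf_stop("PARAM", sprintf("no node '%s' in workflow", node_id))
  }
  if (is.character(params) && length(params) == 1L) {
    params <- jsonlite::fromJSON(params, simplifyVector = FALSE)
  }
  node <- graph$nodes[[node_id]]
  declared <- names(node$params)
  tool <- registry_get(registry, node$tool %||% "")
  if (!is.null(tool)) declared <- union(declared, names(tool$params))
  unknown <- setdiff(names(params), declared)
  if (length(unknown)) {
    wf_stop("PARAM", sprintf(
      "unknown parameter(s) %s for node '%s'; declared: %s",
      paste(sQuote(unknown), collapse = ", "), node_id,
      paste(sQuote(declared), collapse = ", ")))
  }
  node$runtime_params[names(params)] <- params
  graph$nodes[[node_id]] <- node
  graph
}

#' Effective parameters of a node
#'
#' Resolves the total parameter precedence order for one node:
#' runtime parameter file > edge-delivered parameter token > node
#' attribute > tool default.
#'
#' @param graph A [wf_graph()].
#' @param node_id Node id.
#' @param registry Tool registry supplying tool defaults.
#' @return Named list of effective parameter values.
#' @export
wf_effective_params <- function(graph, node_id, registry = wf_stub_registry()) {
  node <- graph$nodes[[node_id]]
  if (is.null(node)) wf_stop("PARAM", sprintf("no node '%s'", node_id))
  effective_params(node, registry_get(registry, node$tool %||% ""))
}

# Effective design-time + runtime parameters of a node (edge-delivered
# parameter tokens are merged on top of node attributes, under the runtime
# file, by the wrapper at invocation time).
effective_params <- function(node, tool = NULL, port_params = list()) {
  out <- list()
  if (!is.null(tool)) out[names(tool$params)] <- tool$params
  out[names(node$params)] <- node$params
  out[names(port_params)] <- port_params
  out[names(node$runtime_params)] <- node$runtime_params
  out
}
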