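#' Import foreign workflow documents
#'
#' Two simplified foreign dialects are supported and translated into
#' native workflow graphs:
#' \describe{
#'   \item{json_step}{a JSON step map: `{"steps": {"<id>": {"name", "type"
#'     ("tool"/"data_input"), "tool_id", "tool_state", "input_connections":
#'     {"<in_port>": {"id", "output_name"}}}}}`. One node per step,
#'     one edge per connection, `tool_state` becomes node parameters.}
#'   \item{xml_processor}{an XML document whose root holds `<processor>`
#'     elements (`type` local/remote/workflow), `<source>`/`<sink>`
#'     declarations, `<link from="a:out" to="b:in"/>` data links and
#'     `<conditional>` constructs. The rewrite rules: local processors
#'     become tool nodes; conditionals become switch nodes with
#'     FAIL-branch wiring; nested `<workflow>` processors become composite
#'     nodes; remote processors become external nodes, optionally
#'     substituted by catalog-matched local tools.}
#' }
#' These are documented subsets re-designed from the behavior of the real
#' SCUFL/t2flow and Galaxy formats, not byte-compatible parsers.
#'
#' @param input Path to the foreign document (or its text).
#' @return `wf_detect_dialect()` returns `"json_step"` or
#'   `"xml_processor"`; the importers return a validated [wf_graph()].
#' @export
wf_detect_dialect <- function(input) {
  txt <- read_doc_text(input)
  if (grepl("^\\s*[{[]", txt)) {
    doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                    error = function(e) NULL)
    if (!is.null(doc) && !is.null(doc$steps)) return("json_step")
    wf_format_stop("UNKNOWN_DIALECT", "JSON document without a 'steps' map")
  }
  doc <- tryCatch(xml2::read_xml(txt), error = function(e) NULL)
  if (!is.null(doc) &&
      length(xml2::xml_find_all(doc, "./processor | ./source | ./link"))) {
    return("xml_processor")
  }
  wf_format_stop("UNKNOWN_DIALECT", "document is neither a step map nor a processor workflow")
}

read_doc_text <- function(input) {
  if (length(input) == 1L && !grepl("[{<\n]", input) && file.exists(input)) {
    paste(readLines(input, warn = FALSE), collapse = "\n")
  } else paste(input, collapse = "\n")
}

#' @rdname wf_detect_dialect
#' @param registry Tool registry used to resolve tool ports.
#' @export
wf_import_json_step <- function(input, registry = wf_stub_registry()) {
  doc <- jsonlite::fromJSON(read_doc_text(input), simplifyVector = FALSE)
  steps <- doc$steps
  if (is.null(steps)) wf_format_stop("SCHEMA", "step document: missing 'steps'")
  keys <- names(steps)
  node_id <- stats::setNames(paste0("s", keys), keys)
  nodes <- list(); edges <- list(); inputs <- list(); outputs <- list()
  connected_out <- character(0)
  connected_in <- character(0)
  for (k in keys) {
    st <- steps[[k]]
    type <- st$type %||% "tool"
    id <- node_id[[k]]
    if (identical(type, "data_input")) {
      nodes[[id]] <- wf_node(id, kind = "tool", tool = "identity",
                             in_ports = "in", out_ports = "out")
      inputs[[st$name %||% id]] <- c(id, "in")
    } else {
      tool_id <- st$tool_id %||% st$name
      spec <- registry_get(registry, tool_id)
      nodes[[id]] <- wf_node(id, kind = "tool", tool = tool_id,
                             params = st$tool_state %||% list(),
                             in_ports = if (!is.null(spec)) spec$in_ports else "in",
                             out_ports = if (!is.null(spec)) spec$out_ports else "out")
    }
    for (port in names(st$input_connections %||% list())) {
      con <- st$input_connections[[port]]
      src_key <- as.character(con$id)
      if (!src_key %in% keys) {
        wf_format_stop("IMPORT_ERROR", sprintf(
          "step %s: connection on '%s' references missing step %s", k, port, src_key))
      }
      edges[[length(edges) + 1L]] <-
        wf_edge(c(node_id[[src_key]], con$output_name %||% "out"), c(id, port))
      connected_out <- c(connected_out, paste(node_id[[src_key]],
                                              con$output_name %||% "out"))
      connected_in <- c(connected_in, paste(id, port))
    }
  }
  # expose unwired in-ports as inputs and unwired out-ports as outputs
  for (id in unname(node_id)) {
    n <- nodes[[id]]
    for (p in node_in_names(n)) {
      key <- paste(id, p)
      if (!key %in% connected_in &&
          !any(vapply(inputs, function(r) identical(r, c(id, p)), logical(1)))) {
        inputs[[paste0(id, "_", p)]] <- c(id, p)
      }
    }
    for (p in node_out_names(n)) {
      if (!paste(id, p) %in% connected_out) {
        outputs[[paste0(id, "_", p)]] <- c(id, p)
      }
    }
  }
  g <- wf_graph(doc$name %||% "imported", nodes = nodes, edges = edges,
                inputs = inputs, outputs = outputs)
  assert_valid(g)
  g
}

#' @rdname wf_detect_dialect
#' @param catalog Optional [wf_load_catalog()] service catalog.
#' @param policy `"keep_remote"` (remote processors stay external) or
#'   `"substitute"` (catalog-matched services become local tools;
#'   unmatched ones remain external).
#' @export
wf_import_xml <- function(input, registry = wf_stub_registry(),
                          catalog = NULL, policy = c("keep_remote", "substitute")) {
  policy <- match.arg(policy)
  root <- xml2::read_xml(read_doc_text(input))
  g <- xml_workflow_to_graph(root, registry)
  if (policy == "substitute" && !is.null(catalog)) {
    g <- wf_substitute_remote(g, catalog, registry = registry)
  }
  assert_valid(g)
  g
}

xml_workflow_to_graph <- function(root, registry) {
  nodes <- list(); edges <- list(); inputs <- list(); outputs <- list()
  for (el in xml2::xml_children(root)) {
    tag <- xml2::xml_name(el)
    if (tag == "source") {
      nm <- xml2::xml_attr(el, "name")
      nodes[[nm]] <- wf_node(nm, kind = "tool", tool = "identity",
                             in_ports = "in", out_ports = "out")
      inputs[[nm]] <- c(nm, "in")
    } else if (tag == "processor") {
      nm <- xml2::xml_attr(el, "name")
      type <- xml2::xml_attr(el, "type")
      params <- list()
      for (pe in xml2::xml_find_all(el, "./param")) {
        params[[xml2::xml_attr(pe, "name")]] <- xml2::xml_text(pe)
      }
      if (identical(type, "local")) {
        tool_id <- xml2::xml_attr(el, "tool")
        spec <- registry_get(registry, tool_id)
        nodes[[nm]] <- wf_node(nm, kind = "tool", tool = tool_id, params = params,
                               in_ports = if (!is.null(spec)) spec$in_ports else "in",
                               out_ports = if (!is.null(spec)) spec$out_ports else "out")
      } else if (identical(type, "remote")) {
        op <- xml2::xml_attr(el, "operation")
        spec <- registry_get(registry, op)
        nodes[[nm]] <- wf_node(nm, kind = "external", tool = op, params = params,
                               in_ports = if (!is.null(spec)) spec$in_ports else "in",
                               out_ports = if (!is.null(spec)) spec$out_ports else "out",
                               service = list(operation = op,
                                              endpoint = xml2::xml_attr(el, "endpoint")))
      } else if (identical(type, "workflow")) {
        sub <- xml2::xml_find_first(el, "./workflow")
        body <- xml_workflow_to_graph(sub, registry)
        nodes[[nm]] <- wf_node(nm, kind = "composite",
                               in_ports = names(body$inputs),
                               out_ports = names(body$outputs),
                               body = body)
      } else {
        wf_format_stop("IMPORT_ERROR", sprintf(
          "processor '%s': unsupported type '%s'", nm, type %||% "<none>"))
      }
    } else if (tag == "conditional") {
      nm <- xml2::xml_attr(el, "name")
      cases <- xml2::xml_find_all(el, "./case")
      ports <- vapply(cases, function(cs) xml2::xml_attr(cs, "port"), character(1))
      nodes[[nm]] <- wf_node(nm, kind = "switch", in_ports = "in",
                             out_ports = ports,
                             predicate = wf_predicate(xml2::xml_attr(el, "test")))
      for (cs in cases) {
        to <- parse_ref(xml2::xml_attr(cs, "to"), "in")
        edges[[length(edges) + 1L]] <-
          wf_edge(c(nm, xml2::xml_attr(cs, "port")), to)
      }
    } else if (tag == "link") {
      from <- parse_ref(xml2::xml_attr(el, "from"), "out")
      to <- parse_ref(xml2::xml_attr(el, "to"), "in")
      edges[[length(edges) + 1L]] <- wf_edge(from, to)
    } else if (tag == "sink") {
      nm <- xml2::xml_attr(el, "name")
      outputs[[nm]] <- parse_ref(xml2::xml_attr(el, "from"), "out")
    } else {
      wf_format_stop("IMPORT_ERROR", sprintf("unsupported element <%s>", tag))
    }
  }
  # expose any unwired in-ports so the graph validates and can run
  fed <- c(vapply(edges, function(e) paste(e$dst[1], e$dst[2]), character(1)),
           vapply(inputs, function(r) paste(r[1], r[2]), character(1)))
  for (n in nodes) {
    for (p in node_in_names(n)) {
      if (!paste(n$id, p) %in% fed) {
        inputs[[paste0(n$id, "_", p)]] <- c(n$id, p)
      }
    }
  }
  nm <- xml2::xml_attr(root, "name")
  if (is.na(nm)) nm <- "imported"
  wf_graph(nm, nodes = nodes, edges = edges, inputs = inputs, outputs = outputs)
}

parse_ref <- function(txt, default_port) {
  parts <- strsplit(txt, ":", fixed = TRUE)[[1]]
  if (length(parts) == 1L) c(parts[1], default_port) else c(parts[1], parts[2])
}

#' Service catalog for remote-call substitution
#'
#' Maps remote service signatures — an operation name plus an endpoint
#' host pattern (glob; host matching is case-insensitive, operation
#' matching case-sensitive) — to local tool ids with a port mapping. Used
#' to replace remote web-service calls with calls to equivalent local
#' tools.
#'
#' @param input Path to a catalog JSON document
#'   (`{"entries": [{"operation", "host", "tool_id", "port_map"}]}`) or an
#'   equivalent list.
#' @return A `wf_catalog` object.
#' @export
wf_load_catalog <- function(input) {
  doc <- if (is.list(input)) input else
    jsonlite::fromJSON(read_doc_text(input), simplifyVector = FALSE)
  entries <- doc$entries %||% doc
  structure(list(entries = entries), class = "wf_catalog")
}

catalog_match <- function(catalog, service) {
  if (is.null(catalog) || is.null(service)) return(NULL)
  host <- sub("^[a-zA-Z]+://", "", service$endpoint %||% "")
  host <- sub("[/:].*$", "", host)
  for (entry in catalog$entries) {
    if (!identical(entry$operation, service$operation)) next
    pat <- utils::glob2rx(entry$host %||% "*")
    if (grepl(pat, host, ignore.case = TRUE)) return(entry)
  }
  NULL
}

#' Substitute remote calls by local tools
#'
#' Every external node whose service signature hits the catalog becomes a
#' local tool node with its ports remapped through the entry's port map
#' (which must be a bijection onto the local tool's declared ports); all
#' other nodes and all edges are otherwise preserved, and the result is
#' still a DAG. Externals without a catalog hit remain external.
#'
#' @param graph A valid [wf_graph()].
#' @param catalog A [wf_load_catalog()] object.
#' @param registry Tool registry declaring the local tools.
#' @return The substituted graph.
#' @export
wf_substitute_remote <- function(graph, catalog, registry = wf_stub_registry()) {
  for (id in names(graph$nodes)) {
    node <- graph$nodes[[id]]
    if (!is_external_node(node) || !is.null(node$body)) next
    entry <- catalog_match(catalog, node$service)
    if (is.null(entry)) next
    spec <- registry_get(registry, entry$tool_id)
    if (is.null(spec)) {
      wf_stop("SUBSTITUTION_ERROR", sprintf(
        "catalog maps '%s' to unregistered tool '%s'",
        node$service$operation, entry$tool_id))
    }
    pm <- unlist(entry$port_map)
    if (anyDuplicated(pm) || anyDuplicated(names(pm))) {
      wf_stop("SUBSTITUTION_ERROR", "port mapping is not a bijection")
    }
    old_ports <- c(node_in_names(node), node_out_names(node))
    mapped <- unname(pm[old_ports])
    if (anyNA(mapped) ||
        !setequal(pm[node_in_names(node)], port_names(spec$in_ports)) ||
        !setequal(pm[node_out_names(node)], port_names(spec$out_ports))) {
      wf_stop("SUBSTITUTION_ERROR", sprintf(
        "port mapping for '%s' is not a bijection onto tool '%s' ports",
        id, entry$tool_id))
    }
    node$kind <- "tool"
    node$tool <- entry$tool_id
    node$service <- NULL
    node$in_ports <- spec$in_ports
    node$out_ports <- spec$out_ports
    graph$nodes[[id]] <- node
    remap <- function(ref) {
      if (ref[1] == id && ref[2] %in% names(pm)) c(id, pm[[ref[2]]]) else ref
    }
    graph$edges <- lapply(graph$edges, function(e) {
      wf_edge(remap(e$src), remap(e$dst))
    })
    graph$inputs <- lapply(graph$inputs, remap)
    graph$outputs <- lapply(graph$outputs, remap)
  }
  assert_valid(graph)
  graph
}

#' @rdname wf_detect_dialect
#' @export
wf_import <- function(input, registry = wf_stub_registry(), catalog = NULL,
                      policy = "keep_remote") {
  dialect <- wf_detect_dialect(input)
  if (dialect == "json_step") {
    wf_import_json_step(input, registry)
  } else {
    wf_import_xml(input, registry, catalog = catalog, policy = policy)
  }
}
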