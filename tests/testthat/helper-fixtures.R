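# Shared builders and independent brute-force oracles for the suite.

simple_node <- function(id, tool = "concat", kind = "tool", ins = "in",
                        outs = "out", ...) {
  wf_node(id, kind = kind, tool = tool, in_ports = ins, out_ports = outs, ...)
}

chain_graph <- function(ids, tool = "identity") {
  nodes <- lapply(ids, simple_node, tool = tool)
  edges <- list()
  for (i in seq_along(ids)[-1]) {
    edges[[i - 1L]] <- wf_edge(c(ids[i - 1L], "out"), c(ids[i], "in"))
  }
  wf_graph("chain", nodes = nodes, edges = edges,
           inputs = stats::setNames(list(c(ids[1], "in")), "x"),
           outputs = stats::setNames(list(c(ids[length(ids)], "out")), "y"))
}

diamond_graph <- function() {
  wf_graph("diamond", nodes = list(
    simple_node("A", "identity"), simple_node("B", "revseq"),
    simple_node("C", "upper"),
    wf_node("D", kind = "collect", in_ports = c("in1", "in2"))),
    edges = list(
      wf_edge(c("A", "out"), c("B", "in")), wf_edge(c("A", "out"), c("C", "in")),
      wf_edge(c("B", "out"), c("D", "in1")), wf_edge(c("C", "out"), c("D", "in2"))),
    inputs = list(x = c("A", "in")), outputs = list(y = c("D", "out")))
}

# registry extended with a numeric increment stub for iteration tests
registry_with_incr <- function() {
  reg <- wf_stub_registry()
  extra <- wf_registry(
    wf_tool("incr", "in", "out", fun = function(inputs, params) {
      list(out = as.character(as.numeric(inputs[[1]]) + 1))
    }),
    wf_tool("slowid", "in", "out", fun = function(inputs, params) {
      # artificial pseudo-random delay: reassembly must not depend on
      # completion timing
      Sys.sleep(stats::runif(1, 0, 0.002))
      list(out = inputs[[1]])
    }))
  out <- c(reg, extra)
  class(out) <- "wf_registry"
  out
}

graph_inputs_for <- function(graph, tag = "v") {
  ins <- lapply(names(graph$inputs), function(a) token_data(paste0(tag, "_", a)))
  stats::setNames(ins, names(graph$inputs))
}

run_payloads <- function(res) {
  lapply(res$outputs, function(t) if (is.null(t)) NULL else token_payloads(t))
}

# ---- brute-force oracles -------------------------------------------------

# exhaustively enumerate every topological order of a workflow graph
all_topo_orders <- function(graph) {
  ids <- names(graph$nodes)
  pred <- list()
  for (id in ids) pred[[id]] <- character(0)
  for (e in graph$edges) {
    pred[[e$dst[1]]] <- union(pred[[e$dst[1]]], e$src[1])
  }
  rec <- function(done, remaining) {
    if (!length(remaining)) return(list(done))
    ready <- Filter(function(id) all(pred[[id]] %in% done), remaining)
    out <- list()
    for (r in ready) {
      out <- c(out, rec(c(done, r), setdiff(remaining, r)))
    }
    out
  }
  rec(character(0), ids)
}

# every run trace must respect edge precedence: u's end before v's start
trace_respects_edges <- function(graph, trace) {
  node_rows <- trace[is.na(trace$instance) | trace$instance >= 0, ]
  for (e in graph$edges) {
    u <- e$src[1]; v <- e$dst[1]
    u_end <- trace$seq[trace$node_id == u & trace$event %in% c("end", "skip")]
    v_start <- trace$seq[trace$node_id == v & trace$event %in% c("start", "skip")]
    if (!length(u_end) || !length(v_start)) next
    if (max(u_end) > min(v_start)) return(FALSE)
  }
  TRUE
}

# brute-force pair enumerators for the expansion operators
oracle_map_idx <- function(n) if (n == 0) list() else as.list(seq_len(n))
oracle_dot_idx <- function(lens) {
  n <- min(lens)
  if (n == 0) return(list())
  lapply(seq_len(n), function(i) rep(i, length(lens)))
}
oracle_cross_idx <- function(n, m) {
  out <- list()
  for (i in seq_len(n)) for (j in seq_len(m)) out[[length(out) + 1L]] <- c(i, j)
  out
}

# independent shared-kmer scorer (position loops, not set intersection)
oracle_kmer_score <- function(q, d, k = 3L) {
  q <- toupper(q); d <- toupper(d)
  if (nchar(q) < k || nchar(d) < k) return(0L)
  seen <- character(0)
  for (i in 1:(nchar(q) - k + 1L)) {
    km <- substr(q, i, i + k - 1L)
    if (km %in% seen) next
    for (j in 1:(nchar(d) - k + 1L)) {
      if (identical(km, substr(d, j, j + k - 1L))) {
        seen <- c(seen, km)
        break
      }
    }
  }
  length(seen)
}

# ---- partition brute force ----------------------------------------------

# all set partitions of a character vector
all_set_partitions <- function(items) {
  if (!length(items)) return(list(list()))
  first <- items[1]
  rest <- all_set_partitions(items[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(first, q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(first), p)
  }
  out
}

partition_obj <- function(components) {
  components <- lapply(components, sort)
  component_of <- stats::setNames(integer(0), character(0))
  for (i in seq_along(components)) component_of[components[[i]]] <- i
  structure(list(components = components, component_of = component_of),
            class = "wf_partition")
}

partition_valid <- function(graph, components) {
  length(dagflow:::check_partition(graph, partition_obj(components))) == 0L
}

# maximality: no extra external nodes can be added to any component, i.e.
# no two components of the partition can be merged into a single valid
# (weakly connected, condensable-without-cycle) component. This is the
# order-independent reading of maximality; several maximal partitions may
# coexist and the implementation's deterministic tie-break picks one.
partition_maximal <- function(graph, components) {
  if (length(components) < 2L) return(TRUE)
  for (i in seq_along(components)) {
    for (j in seq_along(components)) {
      if (i >= j) next
      merged <- components
      merged[[i]] <- c(merged[[i]], merged[[j]])
      merged[[j]] <- NULL
      if (partition_valid(graph, merged)) return(FALSE)
    }
  }
  TRUE
}

# write text to a temporary file and return the path
tmp_write <- function(text, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(text, f)
  f
}
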