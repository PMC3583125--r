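test_that("static schedule is a deterministic topological order", {
  single <- wf_graph("s", nodes = list(simple_node("A", "identity")),
                     inputs = list(x = c("A", "in")),
                     outputs = list(y = c("A", "out")))
  expect_identical(wf_static_schedule(single), "A")

  expect_identical(wf_static_schedule(chain_graph(c("A", "B", "C"))),
                   c("A", "B", "C"))

  # diamond: member of the enumerated topological-order set picked by the
  # lexicographic tie-break
  d <- diamond_graph()
  orders <- all_topo_orders(d)
  expect_true(any(vapply(orders, identical, logical(1), wf_static_schedule(d))))
  expect_identical(wf_static_schedule(d), c("A", "B", "C", "D"))

  cyc <- d
  cyc$edges <- c(cyc$edges, list(wf_edge(c("D", "out"), c("A", "in"))))
  expect_error(wf_static_schedule(cyc), "CYCLE")
})

test_that("schedule and trace are valid on random DAGs", {
  for (s in 1:60) {
    g <- gen_random_dag(2L + s %% 5L, edge_prob = 0.45, seed = s)
    sched <- wf_static_schedule(g)
    orders <- all_topo_orders(g)
    expect_true(any(vapply(orders, identical, logical(1), sched)))
    res <- wf_run(g, graph_inputs_for(g), workers = 1L + s %% 3L)
    expect_identical(res$status, "success")
    expect_true(trace_respects_edges(g, res$trace))
  }
})

test_that("schedules agree with an independent graph library", {
  for (s in 1:25) {
    g <- gen_random_dag(3L + s %% 5L, edge_prob = 0.5, seed = 700 + s)
    el <- do.call(rbind, lapply(g$edges, function(e) c(e$src[1], e$dst[1])))
    ig <- igraph::graph_from_data_frame(
      if (is.null(el)) data.frame(from = character(0), to = character(0))
      else data.frame(from = el[, 1], to = el[, 2]),
      directed = TRUE, vertices = names(g$nodes))
    expect_true(igraph::is_dag(ig))
    sched <- wf_static_schedule(g)
    pos <- match(names(g$nodes), sched)
    names(pos) <- names(g$nodes)
    for (e in g$edges) expect_lt(pos[[e$src[1]]], pos[[e$dst[1]]])
  }
})

test_that("execution fires nodes exactly once and fills outputs", {
  g <- chain_graph(c("A"))
  res <- wf_run(g, list(x = token_data("x")))
  expect_identical(res$outputs$y$payload, "x")

  # revseq -> upper composition, derived by composing the stubs by hand
  g2 <- wf_graph("p", nodes = list(simple_node("r", "revseq"),
                                   simple_node("u", "upper")),
    edges = list(wf_edge(c("r", "out"), c("u", "in"))),
    inputs = list(x = c("r", "in")), outputs = list(y = c("u", "out")))
  expect_identical(wf_run(g2, list(x = "abc"))$outputs$y$payload, "CBA")

  # exactly-once: one start per non-skipped (node, instance)
  res3 <- wf_run(diamond_graph(), list(x = "seq"), workers = 2L)
  starts <- res3$trace[res3$trace$event == "start", ]
  key <- paste(starts$node_id, starts$instance)
  expect_false(anyDuplicated(key) > 0)
})

test_that("readiness requires every in-port token", {
  # synchronous merge: D fires only after both B and C completed
  for (w in c(1L, 2L)) {
    res <- wf_run(diamond_graph(), list(x = "seq"), workers = w)
    tr <- res$trace
    d_start <- min(tr$seq[tr$node_id == "D" & tr$event == "start"])
    expect_gt(d_start, max(tr$seq[tr$node_id == "B" & tr$event == "end"]))
    expect_gt(d_start, max(tr$seq[tr$node_id == "C" & tr$event == "end"]))
  }
})

test_that("unresolvable tools are a configuration error before execution", {
  g <- wf_graph("u", nodes = list(simple_node("A", "no_such_tool")),
                inputs = list(x = c("A", "in")), outputs = list(y = c("A", "out")))
  expect_error(wf_run(g, list(x = "v")), "TOOL_UNRESOLVED")
})

test_that("a nonzero tool exit fails the run and identifies the instance", {
  reg <- wf_registry(wf_tool("failtool", "in", "out", command = "false"))
  g <- wf_graph("f", nodes = list(simple_node("f1", "failtool")),
                inputs = list(x = c("f1", "in")), outputs = list(y = c("f1", "out")))
  res <- wf_run(g, list(x = "v"), registry = reg)
  expect_identical(res$status, "failed")
  expect_identical(res$error$code, "TOOL_FAILED")
  expect_identical(res$error$node, "f1")
})

test_that("composite nodes behave exactly like the inlined chain", {
  body <- wf_graph("body", nodes = list(simple_node("r", "revseq"),
                                        simple_node("u", "upper")),
    edges = list(wf_edge(c("r", "out"), c("u", "in"))),
    inputs = list(seq = c("r", "in")), outputs = list(res = c("u", "out")))
  g <- wf_graph("outer", nodes = list(
    wf_node("comp", kind = "composite", in_ports = "seq", out_ports = "res",
            body = body)),
    inputs = list(seq = c("comp", "seq")), outputs = list(res = c("comp", "res")))
  expect_identical(wf_run(g, list(seq = "abc"))$outputs$res$payload, "CBA")

  # empty body errors
  expect_error(wf_run_subworkflow(wf_graph("empty"), list()), "EMPTY_BODY")
})

test_that("nested composites (depth 2) equal flat execution", {
  for (s in 1:10) {
    flat <- gen_random_dag(5, edge_prob = 0.4, seed = 100 + s)
    ins <- graph_inputs_for(flat)
    inner <- wf_node("inner", kind = "composite",
                     in_ports = names(flat$inputs),
                     out_ports = names(flat$outputs), body = flat)
    mid <- wf_graph("mid", nodes = list(inner),
                    inputs = stats::setNames(lapply(names(flat$inputs),
                      function(a) c("inner", a)), names(flat$inputs)),
                    outputs = stats::setNames(lapply(names(flat$outputs),
                      function(a) c("inner", a)), names(flat$outputs)))
    outer_node <- wf_node("outer", kind = "composite",
                          in_ports = names(mid$inputs),
                          out_ports = names(mid$outputs), body = mid)
    outer <- wf_graph("outer", nodes = list(outer_node),
                      inputs = stats::setNames(lapply(names(mid$inputs),
                        function(a) c("outer", a)), names(mid$inputs)),
                      outputs = stats::setNames(lapply(names(mid$outputs),
                        function(a) c("outer", a)), names(mid$outputs)))
    expect_identical(run_payloads(wf_run(outer, ins)),
                     run_payloads(wf_run(flat, ins)))
  }
})

test_that("sub-workflow recursion depth is capped", {
  g <- chain_graph("A")
  expect_error(wf_run(g, list(x = "v"), .depth = 40L), "RECURSION_LIMIT")
})

test_that("runs are stateless and worker-count deterministic", {
  g <- gen_random_dag(6, edge_prob = 0.4, seed = 7)
  ins <- graph_inputs_for(g)
  ref <- run_payloads(wf_run(g, ins, workers = 1L))
  for (w in c(1L, 2L, 8L)) {
    expect_identical(run_payloads(wf_run(g, ins, workers = w)), ref)
  }
  # repeated runs identical
  expect_identical(run_payloads(wf_run(g, ins)), ref)
})

test_that("trace files are written as tab-separated events", {
  f <- tempfile(fileext = ".log")
  res <- wf_run(chain_graph(c("A", "B")), list(x = "v"), trace_file = f)
  lines <- readLines(f)
  expect_gt(length(lines), 2L)
  expect_true(all(grepl("\t", lines)))
})
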