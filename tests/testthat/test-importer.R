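min_step_doc <- function() {
  jsonlite::toJSON(list(name = "jw", steps = list(
    "0" = list(name = "reads", type = "data_input"),
    "1" = list(name = "qc", type = "tool", tool_id = "lenfilter",
               tool_state = list(min_len = 5),
               input_connections = list("in" = list(id = 0, output_name = "out"))))),
    auto_unbox = TRUE)
}

min_xml_doc <- function() {
  paste0('<workflow name="w"><source name="seq"/>',
         '<processor name="p1" type="local" tool="revseq"/>',
         '<link from="seq" to="p1:in"/>',
         '<sink name="res" from="p1:out"/></workflow>')
}

test_that("dialect detection recognizes both dialects and rejects others", {
  expect_identical(wf_detect_dialect(min_step_doc()), "json_step")
  expect_identical(wf_detect_dialect(min_xml_doc()), "xml_processor")
  expect_error(wf_detect_dialect('{"name": "no steps here"}'),
               "UNKNOWN_DIALECT", class = "wf_format_error")
})

test_that("json_step import maps steps to nodes and connections to edges", {
  g <- wf_import_json_step(min_step_doc())
  expect_length(g$nodes, 2L)
  expect_length(g$edges, 1L)
  expect_length(wf_validate(g, wf_stub_registry()), 0L)
  # tool_state becomes node params
  expect_identical(wf_effective_params(g, "s1")$min_len, 5L)

  dangling <- jsonlite::toJSON(list(steps = list(
    "1" = list(name = "qc", type = "tool", tool_id = "lenfilter",
               input_connections = list("in" = list(id = 99, output_name = "out"))))),
    auto_unbox = TRUE)
  expect_error(wf_import_json_step(dangling), "IMPORT_ERROR",
               class = "wf_format_error")
})

test_that("json_step import round-trips through the native format", {
  set.seed(21)
  for (i in 1:50) {
    n_steps <- sample(2:5, 1)
    steps <- list()
    steps[["0"]] <- list(name = "input0", type = "data_input")
    tools <- c("identity", "revseq", "upper", "lenfilter")
    for (k in seq_len(n_steps - 1L)) {
      src <- sample(0:(k - 1L), 1)
      steps[[as.character(k)]] <- list(
        name = paste0("step", k), type = "tool", tool_id = sample(tools, 1),
        input_connections = list("in" = list(id = src, output_name = "out")))
    }
    doc <- jsonlite::toJSON(list(name = "gen", steps = steps), auto_unbox = TRUE)
    g <- wf_import_json_step(doc)
    expect_length(g$nodes, n_steps)
    expect_length(g$edges, n_steps - 1L)
    native <- wf_save(g)
    expect_identical(wf_save(wf_load(native)), native)
    # import is deterministic
    expect_identical(wf_save(wf_import_json_step(doc)), native)
  }
})

test_that("xml import translates processors, conditionals and nesting", {
  g <- wf_import_xml(min_xml_doc())
  expect_length(wf_validate(g, wf_stub_registry()), 0L)
  expect_identical(g$nodes[["p1"]]$kind, "tool")

  cond_doc <- paste0(
    '<workflow name="cw"><source name="seq"/>',
    '<conditional name="c1" test=\'if (nchar(payload) &gt; 3) "big" else "small"\'>',
    '<case port="big" to="p1:in"/><case port="small" to="p2:in"/></conditional>',
    '<processor name="p1" type="local" tool="upper"/>',
    '<processor name="p2" type="local" tool="revseq"/>',
    '<link from="seq" to="c1:in"/>',
    '<sink name="b" from="p1:out"/><sink name="s" from="p2:out"/></workflow>')
  gc <- wf_import_xml(cond_doc)
  sw <- gc$nodes[["c1"]]
  expect_identical(sw$kind, "switch")
  expect_length(sw$out_ports, 2L)
  # each case feeds its branch
  expect_true(any(vapply(gc$edges, function(e)
    identical(e$src, c("c1", "big")) && identical(e$dst, c("p1", "in")),
    logical(1))))
  # and the translated switch actually routes at run time
  res <- wf_run(gc, list(seq = "abcde"))
  expect_identical(res$outputs$b$payload, "ABCDE")
  expect_true(dagflow:::is_fail(res$outputs$s))

  nest_doc <- paste0(
    '<workflow name="nw"><source name="seq"/>',
    '<processor name="sub" type="workflow"><workflow name="inner">',
    '<source name="x"/><processor name="q" type="local" tool="upper"/>',
    '<link from="x" to="q:in"/><sink name="y" from="q:out"/>',
    '</workflow></processor>',
    '<link from="seq" to="sub:x"/>',
    '<sink name="res" from="sub:y"/></workflow>')
  gn <- wf_import_xml(nest_doc)
  expect_identical(gn$nodes[["sub"]]$kind, "composite")
  expect_identical(wf_run(gn, list(seq = "abc"))$outputs$res$payload, "ABC")

  expect_error(wf_import_xml('<workflow><mystery/></workflow>'),
               "IMPORT_ERROR", class = "wf_format_error")
})

test_that("remote processors stay external or substitute via the catalog", {
  remote_doc <- paste0(
    '<workflow name="rw"><source name="seq"/>',
    '<processor name="ws" type="remote" operation="revseq" ',
    'endpoint="http://Svc.Example.org/revseq"/>',
    '<link from="seq" to="ws:in"/>',
    '<sink name="res" from="ws:out"/></workflow>')
  g_keep <- wf_import_xml(remote_doc, policy = "keep_remote")
  expect_identical(g_keep$nodes[["ws"]]$kind, "external")

  catalog <- wf_load_catalog(list(entries = list(list(
    operation = "revseq", host = "*.example.org", tool_id = "revseq",
    port_map = list("in" = "in", out = "out")))))
  g_sub <- wf_import_xml(remote_doc, catalog = catalog, policy = "substitute")
  expect_identical(g_sub$nodes[["ws"]]$kind, "tool")
  expect_identical(g_sub$nodes[["ws"]]$tool, "revseq")

  # unmatched operations remain external (case-sensitive operation match)
  catalog2 <- wf_load_catalog(list(entries = list(list(
    operation = "REVSEQ", host = "*", tool_id = "revseq",
    port_map = list("in" = "in", out = "out")))))
  g_un <- wf_import_xml(remote_doc, catalog = catalog2, policy = "substitute")
  expect_identical(g_un$nodes[["ws"]]$kind, "external")
})

test_that("substitution preserves everything else and execution semantics", {
  mk_ext <- function(id, op, host) {
    wf_node(id, kind = "external", tool = op, in_ports = "in", out_ports = "out",
            service = list(operation = op, endpoint = paste0("http://", host, "/", op)))
  }
  g <- wf_graph("s", nodes = list(
    mk_ext("E1", "revseq", "svc.example.org"),
    mk_ext("E2", "mystery_op", "other.host")),
    edges = list(wf_edge(c("E1", "out"), c("E2", "in"))),
    inputs = list(x = c("E1", "in")), outputs = list(y = c("E2", "out")))
  catalog <- wf_load_catalog(list(entries = list(list(
    operation = "revseq", host = "*.example.org", tool_id = "revseq",
    port_map = list("in" = "in", out = "out")))))
  g2 <- wf_substitute_remote(g, catalog)
  expect_identical(g2$nodes[["E1"]]$kind, "tool")
  expect_identical(g2$nodes[["E2"]]$kind, "external")
  expect_length(g2$edges, 1L)

  # empty catalog: unchanged
  g3 <- wf_substitute_remote(g, wf_load_catalog(list(entries = list())))
  expect_identical(wf_save(g3), wf_save(g))

  # substituted graph behaves exactly like a directly built native one
  chain <- wf_graph("n", nodes = list(simple_node("E1", "revseq")),
                    inputs = list(x = c("E1", "in")),
                    outputs = list(y = c("E1", "out")))
  solo <- wf_graph("s1", nodes = list(mk_ext("E1", "revseq", "svc.example.org")),
                   inputs = list(x = c("E1", "in")),
                   outputs = list(y = c("E1", "out")))
  sub <- wf_substitute_remote(solo, catalog)
  expect_identical(wf_run(sub, list(x = "abc"))$outputs$y$payload,
                   wf_run(chain, list(x = "abc"))$outputs$y$payload)

  # a non-bijective port map is rejected
  badcat <- wf_load_catalog(list(entries = list(list(
    operation = "mystery_op", host = "*", tool_id = "revseq",
    port_map = list("in" = "in", out = "in")))))
  expect_error(wf_substitute_remote(g, badcat), "SUBSTITUTION_ERROR")
})
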