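tok_list <- function(xs) token_list(lapply(xs, token_data))

test_that("dot product pairs index-wise and ignores trailing items", {
  a <- tok_list(c("a1", "a2")); b <- tok_list(c("b1", "b2", "b3"))
  got <- wf_combine_dot(a, b)
  expect_length(got, 2L)
  expect_identical(got[[1]][[1]]$payload, "a1")
  expect_identical(got[[1]][[2]]$payload, "b1")
  expect_identical(got[[2]][[2]]$payload, "b2")

  expect_length(wf_combine_dot(tok_list(character(0)), b), 0L)

  eq <- wf_combine_dot(tok_list(paste0("x", 1:4)), tok_list(paste0("y", 1:4)))
  expect_length(eq, 4L)
  expect_identical(vapply(eq, function(p) p[[2]]$payload, ""), paste0("y", 1:4))
})

test_that("cross product enumerates all pairs in row-major order", {
  got <- wf_combine_cross(tok_list(c("a1", "a2")), tok_list(c("b1", "b2", "b3")))
  expect_identical(
    lapply(got, function(p) c(p[[1]]$payload, p[[2]]$payload)),
    list(c("a1", "b1"), c("a1", "b2"), c("a1", "b3"),
         c("a2", "b1"), c("a2", "b2"), c("a2", "b3")))
  expect_length(wf_combine_cross(tok_list("a"), tok_list("b")), 1L)
  expect_length(wf_combine_cross(tok_list(paste0("a", 1:11)),
                                 tok_list(paste0("b", 1:3))), 33L)
  # self-comparison A = B is allowed
  a <- tok_list(c("p", "q"))
  expect_length(wf_combine_cross(a, a), 4L)
})

test_that("expansion cardinalities match the brute-force enumerator", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(0:6, 1); m <- sample(0:6, 1)
    a <- tok_list(if (n) paste0("a", 1:n) else character(0))
    b <- tok_list(if (m) paste0("b", 1:m) else character(0))
    expect_length(wf_combine_map(a), length(oracle_map_idx(n)))
    expect_length(wf_combine_dot(a, b), length(oracle_dot_idx(c(n, m))))
    cross <- wf_combine_cross(a, b)
    oracle <- oracle_cross_idx(n, m)
    expect_length(cross, length(oracle))
    if (length(oracle)) {
      expect_identical(
        lapply(cross, function(p) c(p[[1]]$payload, p[[2]]$payload)),
        lapply(oracle, function(ij) c(paste0("a", ij[1]), paste0("b", ij[2]))))
    }
  }
})

test_that("data select returns one input, with one-sided FAIL bypass", {
  psel <- wf_predicate("nchar(a) >= nchar(b)")
  expect_identical(wf_data_select(token_data("xyz"), token_data("ab"), psel)$payload,
                   "xyz")
  expect_identical(wf_data_select(token_data("a"), token_data("long"), psel)$payload,
                   "long")
  expect_identical(wf_data_select(token_fail(), token_data("p"), NULL)$payload, "p")
  expect_true(dagflow:::is_fail(wf_data_select(token_fail(), token_fail(), psel)))
  expect_error(wf_data_select(token_data("a"), token_data("b"),
                              wf_predicate('"not a boolean"')),
               "PREDICATE_FAILED", class = "wf_run_error")
})

test_that("data collect concatenates in port order, nests lists, drops FAIL", {
  got <- wf_data_collect(list(token_data("a"), token_data("b")))
  expect_identical(token_payloads(got), list("a", "b"))

  nested <- wf_data_collect(list(tok_list(c("a1", "a2")), token_data("b")))
  expect_identical(token_payloads(nested), list(list("a1", "a2"), "b"))

  dropped <- wf_data_collect(list(token_fail(), token_data("b")))
  expect_identical(token_payloads(dropped), list("b"))

  expect_true(dagflow:::is_fail(wf_data_collect(list(token_fail(), token_fail()))))
})

test_that("the FASTA splitter honors per-record and block modes", {
  fa3 <- ">a\nACGT\n>b\nGG\n>c\nTTTT"
  expect_length(wf_split_fasta(fa3, "per_record")$items, 3L)

  fa10k <- gen_multifasta(10000, seed = 5, min_len = 20, max_len = 20)
  blocks <- wf_split_fasta(fa10k, "blocks", k = 1000)
  expect_length(blocks$items, 10L)
  # records are never split across blocks and order is preserved
  first_block <- dagflow:::fa_parse(blocks$items[[1]]$payload)
  expect_length(first_block, 1000L)
  expect_identical(names(first_block)[1], "seq_00001")

  expect_length(wf_split_fasta(fa3, "blocks", k = 10)$items, 1L)
  expect_identical(wf_split_fasta(fa3, "blocks", k = 10)$items[[1]]$payload, fa3)

  expect_error(wf_split_fasta("ACGT no header", "per_record"),
               "line 1", class = "wf_format_error")
})

test_that("multi-choice switch selects one branch and FAILs the rest", {
  sw <- wf_node("sw", kind = "switch", in_ports = "in",
                out_ports = c("dna", "protein"),
                predicate = wf_predicate(
                  'if (grepl("^[ACGTN]+$", payload)) "dna" else "protein"'))
  dec <- wf_eval_multi_choice(sw, list("in" = token_data("ACGT")))
  expect_identical(dec$selected, "dna")
  expect_identical(dec$emissions$dna$payload, "ACGT")
  expect_true(dagflow:::is_fail(dec$emissions$protein))

  # constant-true predicate always selects the first branch
  ct <- wf_node("ct", kind = "switch", in_ports = "in",
                out_ports = c("b1", "b2"), predicate = wf_predicate("TRUE"))
  for (x in c("a", "b", "c")) {
    expect_identical(wf_eval_multi_choice(ct, list("in" = token_data(x)))$selected,
                     "b1")
  }
})

test_that("exactly one switch branch subtree executes, for any payload", {
  g <- wf_graph("mc", nodes = list(
    wf_node("sw", kind = "switch", in_ports = "in", out_ports = c("yes", "no"),
            predicate = wf_predicate('nchar(payload) %% 2 == 0')),
    simple_node("B", "upper"), simple_node("C", "revseq"),
    wf_node("join", kind = "select", predicate = wf_predicate("TRUE"))),
    edges = list(
      wf_edge(c("sw", "yes"), c("B", "in")), wf_edge(c("sw", "no"), c("C", "in")),
      wf_edge(c("B", "out"), c("join", "a")), wf_edge(c("C", "out"), c("join", "b"))),
    inputs = list(x = c("sw", "in")), outputs = list(y = c("join", "out")))
  set.seed(99)
  for (i in 1:100) {
    payload <- paste(sample(letters, sample(1:8, 1), replace = TRUE), collapse = "")
    res <- wf_run(g, list(x = token_data(payload)))
    expect_identical(res$status, "success")
    started <- unique(res$trace$node_id[res$trace$event == "start"])
    expect_identical(sum(c("B", "C") %in% started), 1L)
    expected <- if (nchar(payload) %% 2 == 0) toupper(payload) else
      paste(rev(strsplit(payload, "")[[1]]), collapse = "")
    expect_identical(res$outputs$y$payload, expected)
  }
})

test_that("FAIL propagates transitively and skips whole subtrees", {
  outs <- wf_propagate_fail(simple_node("T", "identity"))
  expect_true(all(vapply(outs, dagflow:::is_fail, logical(1))))

  # chain of 3 behind a FAIL branch: all skipped, zero invocations
  g <- wf_graph("fp", nodes = c(list(
    wf_node("sw", kind = "switch", in_ports = "in", out_ports = c("go", "halt"),
            predicate = wf_predicate('"go"'))),
    lapply(c("h1", "h2", "h3"), simple_node, tool = "identity"),
    list(simple_node("g1", "identity"))),
    edges = list(
      wf_edge(c("sw", "go"), c("g1", "in")),
      wf_edge(c("sw", "halt"), c("h1", "in")),
      wf_edge(c("h1", "out"), c("h2", "in")),
      wf_edge(c("h2", "out"), c("h3", "in"))),
    inputs = list(x = c("sw", "in")),
    outputs = list(ok = c("g1", "out"), dead = c("h3", "out")))
  res <- wf_run(g, list(x = "v"))
  expect_identical(res$status, "success")
  skipped <- res$trace$node_id[res$trace$event == "skip"]
  expect_setequal(skipped, c("h1", "h2", "h3"))
  for (h in c("h1", "h2", "h3")) {
    expect_false(any(res$trace$node_id == h & res$trace$event == "start"))
  }
  expect_true(dagflow:::is_fail(res$outputs$dead))
  expect_identical(res$invocations, 1L)  # only g1 ran a tool
})

test_that("iteration implements a do-while with feedback", {
  reg <- registry_with_incr()
  body <- wf_graph("inc", nodes = list(simple_node("add", "incr")),
                   inputs = list(x = c("add", "in")),
                   outputs = list(x = c("add", "out")))
  mk_loop <- function(pred, maxit = 10L) {
    wf_graph("it", nodes = list(
      wf_node("loop", kind = "iterate", in_ports = "x", out_ports = "x",
              body = body, predicate = wf_predicate(pred),
              feedback = c(x = "x"), max_iterations = maxit)),
      inputs = list(start = c("loop", "x")), outputs = list(res = c("loop", "x")))
  }
  # counter loop: start 0, halt at >= 3 => exactly 3 passes, output "3"
  res <- wf_run(mk_loop("value >= 3"), list(start = "0"), registry = reg)
  expect_identical(res$outputs$res$payload, "3")
  expect_identical(sum(res$trace$node_id == "loop" & res$trace$event == "start"), 3L)

  # do-while lower bound: predicate true after the first pass
  res1 <- wf_run(mk_loop("TRUE"), list(start = "0"), registry = reg)
  expect_identical(sum(res1$trace$node_id == "loop" & res1$trace$event == "start"), 1L)

  # fixed-count mode via the iteration counter: 5 body passes
  res5 <- wf_run(mk_loop("iteration >= 5"), list(start = "0"), registry = reg)
  expect_identical(sum(res5$trace$node_id == "loop" & res5$trace$event == "start"), 5L)
  body_starts <- grepl("^loop/", res5$trace$node_id) & res5$trace$event == "start"
  expect_identical(sum(body_starts), 5L)

  # exhausting max_iterations is a run error by default
  resx <- wf_run(mk_loop("FALSE", maxit = 4L), list(start = "0"), registry = reg)
  expect_identical(resx$status, "failed")
  expect_identical(resx$error$code, "ITERATION_LIMIT")
})

test_that("downstream nodes fire only after iteration terminates", {
  reg <- registry_with_incr()
  body <- wf_graph("inc", nodes = list(simple_node("add", "incr")),
                   inputs = list(x = c("add", "in")),
                   outputs = list(x = c("add", "out")))
  g <- wf_graph("it2", nodes = list(
    wf_node("loop", kind = "iterate", in_ports = "x", out_ports = "x",
            body = body, predicate = wf_predicate("value >= 3"),
            feedback = c(x = "x"), max_iterations = 10L),
    simple_node("after", "identity")),
    edges = list(wf_edge(c("loop", "x"), c("after", "in"))),
    inputs = list(start = c("loop", "x")), outputs = list(res = c("after", "out")))
  res <- wf_run(g, list(start = "0"), registry = reg)
  expect_identical(res$outputs$res$payload, "3")
  after_start <- min(res$trace$seq[res$trace$node_id == "after" &
                                   res$trace$event == "start"])
  loop_ends <- res$trace$seq[res$trace$node_id == "loop" & res$trace$event == "end"]
  expect_gt(after_start, max(loop_ends))
})
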