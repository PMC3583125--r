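#' Synthetic multi-FASTA generator
#'
#' Reproducible toy sequence sets: `n` records with ids `<prefix>_0001`,
#' ..., lengths drawn uniformly from `[min_len, max_len]`, letters drawn
#' uniformly from the DNA or protein alphabet. Identical seeds give
#' identical bytes; the caller's RNG state is left untouched.
#'
#' @param n Number of records (>= 0).
#' @param seed Integer seed.
#' @param min_len,max_len Record length range.
#' @param alphabet `"DNA"` or `"protein"`.
#' @param prefix Record id prefix.
#' @param path Optional file path; when given the FASTA is written there.
#' @return FASTA text (invisibly when written to `path`).
#' @examples
#' cat(gen_multifasta(2, seed = 7, min_len = 10, max_len = 10))
#' @export
gen_multifasta <- function(n, seed = 1L, min_len = 50L, max_len = 80L,
                           alphabet = c("DNA", "protein"), prefix = "seq",
                           path = NULL) {
  alphabet <- match.arg(alphabet)
  if (n < 0) wf_stop("PARAM", "n must be >= 0")
  letters_ <- if (alphabet == "DNA") c("A", "C", "G", "T") else
    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  txt <- with_seed(seed, {
    if (n == 0L) "" else {
      width <- max(4L, nchar(as.character(n)))
      seqs <- vapply(seq_len(n), function(i) {
        len <- if (min_len == max_len) min_len else
          sample(seq.int(min_len, max_len), 1L)
        paste(sample(letters_, len, replace = TRUE), collapse = "")
      }, character(1))
      names(seqs) <- sprintf("%s_%0*d", prefix, width, seq_len(n))
      fa_format(seqs)
    }
  })
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random workflow-graph generator
#'
#' Random DAGs for property tests: nodes are assigned a random topological
#' rank and edges only run from lower to higher rank, so the result is
#' acyclic by construction. Every node runs the variable-arity `concat`
#' stub (one in-port per incoming edge); a fraction of nodes is labeled
#' external. Rank-source in-ports and sink out-ports are exposed, so the
#' graph always validates and runs.
#'
#' @param n Number of nodes (>= 1).
#' @param edge_prob Probability of an edge between each ordered rank pair.
#' @param external_frac Fraction of nodes labeled external.
#' @param seed Integer seed.
#' @return A valid [wf_graph()].
#' @examples
#' g <- gen_random_dag(5, edge_prob = 0.4, seed = 3)
#' length(wf_validate(g))  # 0
#' @export
gen_random_dag <- function(n, edge_prob = 0.3, external_frac = 0, seed = 1L) {
  if (n < 1) wf_stop("PARAM", "n must be >= 1")
  with_seed(seed, {
    ids <- sprintf("n%02d", seq_len(n))
    order_ids <- sample(ids)  # random topological order
    incoming <- stats::setNames(vector("list", n), ids)
    edge_pairs <- list()
    if (n > 1) {
      for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
          if (stats::runif(1) < edge_prob) {
            u <- order_ids[i]; v <- order_ids[j]
            incoming[[v]] <- c(incoming[[v]], u)
            edge_pairs[[length(edge_pairs) + 1L]] <- c(u, v)
          }
        }
      }
    }
    is_ext <- stats::runif(n) < external_frac
    names(is_ext) <- ids
    nodes <- lapply(ids, function(id) {
      ins <- if (length(incoming[[id]])) {
        paste0("in_", sort(incoming[[id]]))
      } else "in"
      wf_node(id, kind = if (is_ext[[id]]) "external" else "tool",
              tool = "concat", in_ports = ins, out_ports = "out")
    })
    edges <- lapply(edge_pairs, function(p) {
      wf_edge(c(p[1], "out"), c(p[2], paste0("in_", p[1])))
    })
    has_out <- unique(vapply(edge_pairs, `[`, character(1), 1))
    inputs <- list(); outputs <- list()
    for (id in ids) {
      if (!length(incoming[[id]])) inputs[[paste0(id, "_in")]] <- c(id, "in")
      if (!id %in% has_out) outputs[[paste0(id, "_out")]] <- c(id, "out")
    }
    g <- wf_graph(sprintf("random_dag_%d", seed), nodes = nodes, edges = edges,
                  inputs = inputs, outputs = outputs)
    assert_valid(g)
    g
  })
}

#' Case-study fixture workflows
#'
#' Two workflows re-expressing the shapes of published sequence-analysis
#' case studies over the deterministic stub suite:
#' \describe{
#'   \item{protein_analysis}{a homology-search-and-analysis pipeline: a
#'     multi-choice switch tests whether the input sequence is DNA and
#'     routes it through frame-1 translation (DNA) or a pass-through
#'     (protein); a data-select joins the branches; the sequence is
#'     searched against a bundled toy protein database (`toyblast`), hits
#'     on a user-supplied id exclusion list are dropped, the surviving
#'     database records are retrieved and summarized by a consensus node
#'     and by a composite "alignment" sub-workflow.}
#'   \item{metagenomics}{the list-pattern read-classification pipeline:
#'     length-filtered reads are split into blocks of `k = 10` records by
#'     the list-defining node, crossed (CROSS product) with a collected
#'     list of 3 toy databases so one search node fans out to
#'     blocks x databases task instances, per-instance coverage filtering,
#'     collection, and a taxon tally over the surviving hits. With the
#'     default 110 toy reads this yields 11 blocks and 33 search jobs.}
#' }
#'
#' @param name `"protein_analysis"` or `"metagenomics"`.
#' @return `build_case_study()` returns a valid [wf_graph()];
#'   `wf_case_inputs()` returns the matching named list of input tokens
#'   (toy reads generated from `seed`, toy databases bundled with the
#'   package).
#' @examples
#' g <- build_case_study("metagenomics")
#' length(wf_validate(g))  # 0
#' @export
build_case_study <- function(name = c("protein_analysis", "metagenomics")) {
  name <- match.arg(name)
  if (name == "protein_analysis") {
    aln_body <- wf_graph("alignment_body",
      nodes = list(
        wf_node("aln_upper", tool = "upper", in_ports = "in", out_ports = "out"),
        wf_node("aln_cons", tool = "consensus", in_ports = "in", out_ports = "out")),
      edges = list(wf_edge(c("aln_upper", "out"), c("aln_cons", "in"))),
      inputs = list(seq = c("aln_upper", "in")),
      outputs = list(out = c("aln_cons", "out")))
    g <- wf_graph("protein_analysis",
      nodes = list(
        wf_node("dna_check", kind = "switch", in_ports = "in",
                out_ports = c("dna", "protein"),
                predicate = wf_predicate(
                  'if (grepl("\n[ACGTNacgtn\n]+$", payload)) "dna" else "protein"')),
        wf_node("translate", tool = "translate1", in_ports = "in", out_ports = "out"),
        wf_node("as_protein", tool = "identity", in_ports = "in", out_ports = "out"),
        wf_node("merge_seq", kind = "select", predicate = wf_predicate("TRUE")),
        wf_node("db_in", tool = "identity", in_ports = "in", out_ports = "out"),
        wf_node("search", tool = "toyblast", in_ports = c("query", "db"),
                out_ports = "out"),
        wf_node("exclude", tool = "idexclude", in_ports = c("hits", "exclude"),
                out_ports = "out"),
        wf_node("retrieve_hits", tool = "retrieve", in_ports = c("hits", "db"),
                out_ports = "out"),
        wf_node("consensus_seq", tool = "consensus", in_ports = "in",
                out_ports = "out"),
        wf_node("alignment", kind = "composite", in_ports = "seq",
                out_ports = "out", body = aln_body)),
      edges = list(
        wf_edge(c("dna_check", "dna"), c("translate", "in")),
        wf_edge(c("dna_check", "protein"), c("as_protein", "in")),
        wf_edge(c("translate", "out"), c("merge_seq", "a")),
        wf_edge(c("as_protein", "out"), c("merge_seq", "b")),
        wf_edge(c("merge_seq", "out"), c("search", "query")),
        wf_edge(c("db_in", "out"), c("search", "db")),
        wf_edge(c("search", "out"), c("exclude", "hits")),
        wf_edge(c("exclude", "out"), c("retrieve_hits", "hits")),
        wf_edge(c("db_in", "out"), c("retrieve_hits", "db")),
        wf_edge(c("retrieve_hits", "out"), c("consensus_seq", "in")),
        wf_edge(c("retrieve_hits", "out"), c("alignment", "seq"))),
      inputs = list(sequence = c("dna_check", "in"),
                    database = c("db_in", "in"),
                    exclude_ids = c("exclude", "exclude")),
      outputs = list(consensus = c("consensus_seq", "out"),
                     alignment = c("alignment", "out"),
                     hits = c("exclude", "out")))
  } else {
    g <- wf_graph("metagenomics",
      nodes = list(
        wf_node("qc", tool = "lenfilter", in_ports = "in", out_ports = "out",
                params = list(min_len = 30)),
        wf_node("split", kind = "split_list",
                params = list(mode = "blocks", k = 10, separator = "%%%")),
        wf_node("dbs", kind = "collect", in_ports = c("db1", "db2", "db3")),
        wf_node("search", tool = "toyblast", in_ports = c("query", "db"),
                out_ports = "out", input_combination = "CROSS",
                list_ports = c("query", "db"), params = list(k = 3)),
        wf_node("coverage", tool = "covfilter", in_ports = "hits",
                out_ports = "out", input_combination = "MAP",
                list_ports = "hits", params = list(min_score = 1)),
        wf_node("gather", kind = "collect", in_ports = "in1"),
        wf_node("tax", tool = "taxcount", in_ports = "hits", out_ports = "out")),
      edges = list(
        wf_edge(c("qc", "out"), c("split", "in")),
        wf_edge(c("split", "out"), c("search", "query")),
        wf_edge(c("dbs", "out"), c("search", "db")),
        wf_edge(c("search", "out"), c("coverage", "hits")),
        wf_edge(c("coverage", "out"), c("gather", "in1")),
        wf_edge(c("gather", "out"), c("tax", "hits"))),
      inputs = list(reads = c("qc", "in"),
                    db_a = c("dbs", "db1"),
                    db_b = c("dbs", "db2"),
                    db_c = c("dbs", "db3")),
      outputs = list(taxonomy = c("tax", "out"),
                     hits = c("gather", "out")))
  }
  assert_valid(g, wf_stub_registry())
  g
}

#' @rdname build_case_study
#' @param seed Seed for the generated toy reads/sequence.
#' @param n_reads Number of toy reads for the metagenomics fixture
#'   (default 110: 11 blocks of 10).
#' @export
wf_case_inputs <- function(name = c("protein_analysis", "metagenomics"),
                           seed = 42L, n_reads = 110L) {
  name <- match.arg(name)
  extdata <- function(f) {
    p <- system.file("extdata", f, package = "dagflow")
    if (!nzchar(p)) wf_stop("CONFIG", sprintf("bundled fixture '%s' not found", f))
    paste(readLines(p, warn = FALSE), collapse = "\n")
  }
  if (name == "protein_analysis") {
    list(
      sequence = token_data(gen_multifasta(1, seed = seed, min_len = 60,
                                           max_len = 60, prefix = "query")),
      database = token_data(extdata("toy_protein_db.fasta")),
      exclude_ids = token_data("dbP_0002"))
  } else {
    list(
      reads = token_data(gen_multifasta(n_reads, seed = seed, min_len = 50,
                                        max_len = 80, prefix = "read")),
      db_a = token_data(extdata("toy_db_a.fasta")),
      db_b = token_data(extdata("toy_db_b.fasta")),
      db_c = token_data(extdata("toy_db_c.fasta")))
  }
}
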