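#' Deterministic stub tool suite
#'
#' Desk-scale stand-ins for the sequence-analysis programs a production
#' deployment would wire in (BLAST/MegaBLAST, ClustalW, MUSCLE, ...): every
#' stub is a pure, byte-deterministic function of its input payloads, so
#' workflows built from them can be executed and checked with no downloads
#' and no external binaries. Real tools plug in through the same
#' [wf_tool()] mechanism with a command template.
#'
#' The suite: `identity`, `revseq` (reverse each sequence), `upper`,
#' `translate1` (frame-1 standard-codon-table translation), `lenfilter`
#' (keep FASTA records with length >= `min_len`), `toyblast` (distinct
#' shared k-mer count, `k = 3`, of each query record against each database
#' record; tab-separated `query  db_record  score` rows), `covfilter`
#' (keep hits of query records whose best score >= `min_score`),
#' `consensus` (per-column majority over equal-length sequences,
#' alphabetical tie-break), `taxcount` (tally of database-record labels —
#' the id prefix before the first underscore — among hits), plus three
#' plumbing stubs: `concat` (joins its inputs in port order), `idexclude`
#' (drops hits whose database id is on an exclusion list) and `retrieve`
#' (extracts the database records named in a hits table).
#'
#' @return `wf_stub_registry()` returns a [wf_registry()] with all stubs.
#' @examples
#' reg <- wf_stub_registry()
#' names(reg)
#' @export
wf_stub_registry <- function() {
  wf_registry(
    wf_tool("identity", "in", "out", fun = function(inputs, params) {
      list(out = inputs[[1]] %||% "")
    }),
    wf_tool("revseq", "in", "out", fun = function(inputs, params) {
      list(out = stub_map_seq(inputs[[1]], function(s)
        paste(rev(strsplit(s, "")[[1]]), collapse = "")))
    }),
    wf_tool("upper", "in", "out", fun = function(inputs, params) {
      list(out = stub_map_seq(inputs[[1]], toupper))
    }),
    wf_tool("translate1", "in", "out", fun = function(inputs, params) {
      list(out = stub_map_seq(inputs[[1]], stub_translate))
    }),
    wf_tool("lenfilter", "in", "out", params = list(min_len = 0),
            fun = function(inputs, params) {
      seqs <- fa_parse(inputs[[1]] %||% "")
      keep <- nchar(seqs) >= as.numeric(params$min_len %||% 0)
      list(out = fa_format(seqs[keep]))
    }),
    wf_tool("toyblast", c("query", "db"), "out", params = list(k = 3),
            fun = function(inputs, params) {
      list(out = stub_toyblast(inputs$query %||% inputs[[1]],
                               inputs$db %||% inputs[[2]],
                               as.integer(params$k %||% 3)))
    }),
    wf_tool("covfilter", "hits", "out", params = list(min_score = 1),
            fun = function(inputs, params) {
      list(out = stub_covfilter(inputs[[1]] %||% "",
                                as.numeric(params$min_score %||% 1)))
    }),
    wf_tool("consensus", "in", "out", fun = function(inputs, params) {
      list(out = stub_consensus(inputs[[1]] %||% ""))
    }),
    wf_tool("taxcount", "hits", "out", fun = function(inputs, params) {
      list(out = stub_taxcount(inputs[[1]] %||% ""))
    }),
    wf_tool("concat", "in", "out", fun = function(inputs, params) {
      list(out = paste(unlist(inputs, use.names = FALSE), collapse = "|"))
    }),
    wf_tool("idexclude", c("hits", "exclude"), "out", fun = function(inputs, params) {
      rows <- stub_hit_rows(inputs$hits %||% inputs[[1]])
      excl <- trimws(strsplit(inputs$exclude %||% "", "\n")[[1]])
      excl <- excl[nzchar(excl)]
      keep <- rows[!vapply(rows, function(r) r[2] %in% excl, logical(1))]
      list(out = paste(vapply(keep, paste, character(1), collapse = "\t"),
                       collapse = "\n"))
    }),
    wf_tool("retrieve", c("hits", "db"), "out", fun = function(inputs, params) {
      rows <- stub_hit_rows(inputs$hits %||% inputs[[1]])
      wanted <- unique(vapply(rows, `[`, character(1), 2))
      db <- fa_parse(inputs$db %||% inputs[[2]])
      list(out = fa_format(db[names(db) %in% wanted]))
    })
  )
}

looks_fasta <- function(text) {
  lines <- strsplit(text %||% "", "\n", fixed = TRUE)[[1]]
  nb <- lines[nzchar(trimws(lines))]
  length(nb) > 0L && startsWith(trimws(nb[1]), ">")
}

# apply a per-sequence transform; FASTA payloads keep headers, raw text is
# transformed whole
stub_map_seq <- function(text, f) {
  text <- text %||% ""
  if (!looks_fasta(text)) return(f(text))
  seqs <- fa_parse(text)
  fa_format(stats::setNames(vapply(seqs, f, character(1)), names(seqs)))
}

stub_translate <- function(s) {
  s <- toupper(s)
  n <- (nchar(s) %/% 3L) * 3L
  if (n == 0L) return("")
  dna <- Biostrings::DNAStringSet(substr(s, 1L, n))
  as.character(Biostrings::translate(dna, if.fuzzy.codon = "solve"))
}

kmer_set <- function(s, k) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

stub_toyblast <- function(query, db, k = 3L) {
  q <- fa_parse(query); d <- fa_parse(db)
  rows <- character(0)
  for (qi in seq_along(q)) {
    qk <- kmer_set(q[[qi]], k)
    for (di in seq_along(d)) {
      score <- length(intersect(qk, kmer_set(d[[di]], k)))
      rows <- c(rows, paste(names(q)[qi], names(d)[di], score, sep = "\t"))
    }
  }
  paste(rows, collapse = "\n")
}

# parse hits TSV, tolerating blank and block-separator lines
stub_hit_rows <- function(text) {
  lines <- strsplit(text %||% "", "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^%+$", lines)]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  Filter(function(r) length(r) >= 3L, rows)
}

stub_covfilter <- function(text, min_score) {
  rows <- stub_hit_rows(text)
  if (!length(rows)) return("")
  qs <- vapply(rows, `[`, character(1), 1)
  sc <- as.numeric(vapply(rows, `[`, character(1), 3))
  best <- tapply(sc, qs, max)
  keep <- rows[qs %in% names(best)[best >= min_score]]
  paste(vapply(keep, paste, character(1), collapse = "\t"), collapse = "\n")
}

stub_consensus <- function(text) {
  seqs <- fa_parse(text)
  if (!length(seqs)) return(">consensus\n")
  if (length(unique(nchar(seqs))) != 1L) {
    wf_run_stop("TOOL_FAILED", "consensus requires equal-length sequences")
  }
  mat <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
  cons <- apply(mat, 2, function(col) {
    tab <- table(col)
    nm <- names(tab)[tab == max(tab)]
    sort(nm)[1]  # alphabetical tie-break
  })
  paste0(">consensus\n", paste(cons, collapse = ""))
}

stub_taxcount <- function(text) {
  rows <- stub_hit_rows(text)
  if (!length(rows)) return("")
  labels <- sub("_.*$", "", vapply(rows, `[`, character(1), 2))
  tab <- table(labels)
  paste(paste(names(tab), as.integer(tab), sep = "\t"), collapse = "\n")
}
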