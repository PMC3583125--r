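# FASTA helpers over inline text payloads. Parsing and formatting go
# through Biostrings; payloads move between nodes as text, so these
# helpers bridge text <-> BStringSet via temporary files.

# returns a named character vector (id -> sequence); errors carry the
# offending line number for malformed input
fa_parse <- function(text) {
  lines <- strsplit(text %||% "", "\n", fixed = TRUE)[[1]]
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) return(stats::setNames(character(0), character(0)))
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    wf_format_stop("FASTA", sprintf("not a FASTA record at line %d", nonblank[1]))
  }
  for (i in nonblank) {
    l <- trimws(lines[i])
    if (!startsWith(l, ">") && grepl(">", l, fixed = TRUE)) {
      wf_format_stop("FASTA", sprintf("unexpected '>' inside sequence at line %d", i))
    }
  }
  tf <- tempfile(fileext = ".fa")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  set <- Biostrings::readBStringSet(tf)
  stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
}

fa_format <- function(seqs) {
  if (!length(seqs)) return("")
  paste0(">", names(seqs), "\n", unname(seqs), collapse = "\n")
}

fa_write <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
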