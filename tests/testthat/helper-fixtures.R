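# small file-based fixtures built in code

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

ppi_file <- function(rows, header = "uidA\tuidB\tsource\tevidence") {
  write_lines_tmp(c(header, rows))
}

mapping_file <- function(...) {
  # named args: symbol = accession (vectors allowed)
  args <- list(...)
  rows <- unlist(lapply(names(args), function(s)
    sprintf("%s\t%s", s, args[[s]])))
  write_lines_tmp(rows)
}

symbols_file <- function(symbols) write_lines_tmp(symbols, ext = ".txt")

# tiny ontology: root -> A -> B, with gene counts 10 / 4 / 2 (B's genes a
# subset of A's, A's of root's) -- hand-checkable information content
toy_dag_annotations <- function() {
  genes <- sprintf("g%02d", 1:10)
  annotation_set(
    term_to_genes = list(root = genes, A = genes[1:4], B = genes[1:2]),
    ontology_parents = list(root = character(), A = "root", B = "A"))
}
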