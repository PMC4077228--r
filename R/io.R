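#' Interaction file dialect
#'
#' Column layout and vocabulary for tab-separated interaction files
#' (i2d-style exports). The default expects a header line and columns
#' (protein A, protein B, source database, evidence type); evidence values
#' are normalised to `"experimental"` / `"predicted"` through `evidence_map`.
#'
#' @param col_a,col_b,col_source,col_evidence 1-based column indices; the
#'   source/evidence columns may be `NA` when absent.
#' @param header Logical; skip a header line?
#' @param evidence_map Named character vector mapping raw evidence values to
#'   `"experimental"` or `"predicted"`.
#' @param default_evidence Evidence assigned when the column is absent or the
#'   value is not in `evidence_map`.
#' @return A list of class `interaction_dialect`.
#' @export
interaction_dialect <- function(col_a = 1L, col_b = 2L, col_source = 3L,
                                col_evidence = 4L, header = TRUE,
                                evidence_map = c(experimental = "experimental",
                                                 predicted = "predicted",
                                                 exp = "experimental",
                                                 pred = "predicted"),
                                default_evidence = "experimental") {
  stopifnot(all(evidence_map %in% c("experimental", "predicted")),
            default_evidence %in% c("experimental", "predicted"))
  structure(list(col_a = col_a, col_b = col_b, col_source = col_source,
                 col_evidence = col_evidence, header = isTRUE(header),
                 evidence_map = evidence_map,
                 default_evidence = default_evidence),
            class = "interaction_dialect")
}

#' Read protein-protein interaction records
#'
#' Parses a tab-separated interaction file into one record per data row.
#' Self-interactions and duplicate pairs are retained at this stage (they are
#' removed by [filter_interactions()]); malformed rows (fewer than two
#' non-empty accession fields) are counted and reported in a warning, never
#' silently dropped.
#'
#' @param path Path to the TSV file.
#' @param dialect An [interaction_dialect()] describing the column layout.
#' @return A data frame of class `interaction_records` with columns
#'   `protein_a`, `protein_b`, `source`, `evidence`, and attribute
#'   `n_malformed`.
#' @export
read_interactions <- function(path, dialect = interaction_dialect()) {
  if (!file.exists(path)) abort_io("interaction file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect$header && length(lines)) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- max(dialect$col_a, dialect$col_b)
  get <- function(f, i) if (!is.na(i) && length(f) >= i) trimws(f[[i]]) else ""
  a <- vapply(fields, get, "", i = dialect$col_a)
  b <- vapply(fields, get, "", i = dialect$col_b)
  ok <- nzchar(a) & nzchar(b) & lengths(fields) >= need
  n_bad <- sum(!ok)
  if (n_bad) warning(sprintf("%d malformed row(s) skipped in %s", n_bad, path))
  if (!any(ok)) abort_io("no parseable interaction rows in ", path)
  src <- vapply(fields, get, "", i = dialect$col_source)[ok]
  ev_raw <- vapply(fields, get, "", i = dialect$col_evidence)[ok]
  ev <- unname(dialect$evidence_map[ev_raw])
  ev[is.na(ev)] <- dialect$default_evidence
  out <- data.frame(protein_a = a[ok], protein_b = b[ok], source = src,
                    evidence = ev, stringsAsFactors = FALSE)
  attr(out, "n_malformed") <- n_bad
  class(out) <- c("interaction_records", class(out))
  out
}

#' Read a gene-symbol to accession mapping table
#'
#' @param path Two-column TSV (symbol, accession); a header line is detected
#'   and skipped when its second field is not accession-like, otherwise all
#'   rows are data.
#' @return Data frame with columns `symbol`, `accession`; a symbol may map to
#'   several accessions (one row each).
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) abort_io("mapping file not found: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("symbol", "accession"),
                   colClasses = "character")
  if (nrow(df) && tolower(df$symbol[1]) %in% c("symbol", "gene", "gene_symbol"))
    df <- df[-1, , drop = FALSE]
  df <- df[nzchar(df$symbol) & nzchar(df$accession), , drop = FALSE]
  if (!nrow(df)) abort_io("no mapping rows in ", path)
  unique(df)
}

#' Load and map a seed set
#'
#' Reads gene symbols (one per line) and maps them to protein accessions via
#' the mapping table. A symbol mapping to several accessions contributes all
#' of them (recall is preferred over precision: an ambiguous symbol still
#' anchors the network through every product it may denote). Symbols with no
#' mapping are recorded, with a warning, in `unmapped_symbols`.
#'
#' @param symbols_path File with one gene symbol per line (blank lines and
#'   `#` comments ignored).
#' @param mapping_path Symbol-to-accession TSV, see [read_mapping()].
#' @param label `"disease"` or `"drug_target"`.
#' @return A [seed_set()].
#' @export
load_seed_set <- function(symbols_path, mapping_path,
                          label = c("disease", "drug_target")) {
  label <- match.arg(label)
  if (!file.exists(symbols_path)) abort_io("symbol file not found: ", symbols_path)
  syms <- trimws(readLines(symbols_path, warn = FALSE))
  syms <- unique(syms[nzchar(syms) & !startsWith(syms, "#")])
  if (!length(syms)) abort_io("no seed symbols in ", symbols_path)
  map <- read_mapping(mapping_path)
  hit <- map[map$symbol %in% syms, , drop = FALSE]
  unmapped <- setdiff(syms, hit$symbol)
  if (length(unmapped))
    warning(sprintf("%d seed symbol(s) had no accession mapping: %s",
                    length(unmapped), paste(head(unmapped, 5), collapse = ", ")))
  if (!nrow(hit)) abort_io("no seed symbol could be mapped to an accession")
  seed_set(hit$accession, label = label, unmapped_symbols = unmapped)
}

#' Create an annotation set
#'
#' Term-to-gene annotations (e.g. Gene Ontology biological process), with
#' optional term labels and an optional `is_a` parent map forming a DAG.
#'
#' @param term_to_genes Named list: term ID -> character vector of gene IDs.
#' @param term_names Optional named character vector of term labels.
#' @param ontology_parents Optional named list: term ID -> parent term IDs.
#' @return Object of class `annotation_set`.
#' @export
annotation_set <- function(term_to_genes, term_names = NULL,
                           ontology_parents = NULL) {
  term_to_genes <- lapply(term_to_genes, function(g) sort(unique(as.character(g))))
  if (!length(term_to_genes) || any(lengths(term_to_genes) == 0))
    stop("every annotation term must have at least one annotated gene")
  obj <- structure(list(term_to_genes = term_to_genes,
                        term_names = term_names,
                        ontology_parents = ontology_parents),
                   class = "annotation_set")
  if (!is.null(ontology_parents)) assert_acyclic(ontology_parents)
  obj
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("Annotation set: %d terms over %d genes%s\n",
              length(x$term_to_genes),
              length(unique(unlist(x$term_to_genes, use.names = FALSE))),
              if (is.null(x$ontology_parents)) "" else " (with ontology DAG)"))
  invisible(x)
}

assert_acyclic <- function(parents) {
  state <- new.env(parent = emptyenv())
  visit <- function(t, stack) {
    if (t %in% stack) stop("ontology parent map contains a cycle at term ", t)
    if (isTRUE(state[[t]])) return(invisible())
    for (p in parents[[t]]) visit(p, c(stack, t))
    assign(t, TRUE, envir = state)
  }
  for (t in names(parents)) visit(t, character())
  invisible(TRUE)
}

#' Read term-gene annotations
#'
#' Two formats are supported: a plain two-column TSV (term ID, gene ID) and a
#' GAF 2.x subset where the gene/protein ID is column 2 and the term ID is
#' column 5 (`!` comment lines skipped). Duplicate (term, gene) pairs are
#' collapsed.
#'
#' @param path Annotation file.
#' @param format `"tsv"` or `"gaf"`.
#' @return An [annotation_set()] (without ontology parents).
#' @export
read_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_io("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "!")]
  if (!length(lines)) abort_io("no annotation rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "tsv") {
    term <- vapply(fields, function(f) trimws(f[[1]]), "")
    gene <- vapply(fields, function(f) if (length(f) >= 2) trimws(f[[2]]) else "", "")
  } else {
    term <- vapply(fields, function(f) if (length(f) >= 5) trimws(f[[5]]) else "", "")
    gene <- vapply(fields, function(f) if (length(f) >= 2) trimws(f[[2]]) else "", "")
  }
  keep <- nzchar(term) & nzchar(gene)
  if (!any(keep)) abort_io("no parseable annotation rows in ", path)
  annotation_set(split(gene[keep], term[keep]))
}

#' Read an ontology subset in OBO format
#'
#' Parses only `[Term]` stanzas with their `id:`, `name:` and `is_a:` tags —
#' enough to build the is_a DAG used for information-content similarity and
#' redundancy filtering. Obsolete terms are skipped.
#'
#' @param path OBO file.
#' @return List with components `parents` (named list term -> parent IDs) and
#'   `names` (named character vector of term labels).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) abort_io("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  parents <- list(); nm <- character(); id <- NULL; obsolete <- FALSE
  flush <- function() {
    if (!is.null(id) && !obsolete && is.null(parents[[id]]))
      parents[[id]] <<- character()
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); id <- NULL; obsolete <- FALSE; in_term <- TRUE; next }
    if (startsWith(ln, "[")) { flush(); id <- NULL; in_term <- FALSE; next }
    if (!in_term) next
    if (startsWith(ln, "id:")) id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "name:") && !is.null(id))
      nm[id] <- trimws(sub("^name:", "", ln))
    else if (startsWith(ln, "is_obsolete: true")) obsolete <- TRUE
    else if (startsWith(ln, "is_a:") && !is.null(id)) {
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      parents[[id]] <- c(parents[[id]], p)
    }
  }
  flush()
  if (!length(parents)) abort_io("no [Term] stanzas in ", path)
  assert_acyclic(parents)
  list(parents = parents, names = nm)
}

#' Export a network to file
#'
#' Writes an interactome in SIF, plain edge-list TSV, or GraphML. Each
#' undirected edge is written once under canonical (lexicographic) node
#' ordering; isolated nodes are preserved in every format (SIF: bare node
#' line; TSV: row with an empty second field; GraphML natively). Reading the
#' file back with [read_network()] reproduces the node and edge sets exactly.
#'
#' @param network An `interactome` (or igraph).
#' @param path Output file path.
#' @param format `"sif"`, `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("sif", "tsv", "graphml")) {
  format <- match.arg(format)
  g <- as_igraph(network)
  el <- network_edges(network)
  isolates <- sort(names(which(igraph::degree(g) == 0)))
  con <- NULL
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  lines <- if (format == "sif") {
    c(sprintf("%s\tpp\t%s", el[, 1], el[, 2]), isolates)
  } else {
    c("protein_a\tprotein_b",
      sprintf("%s\t%s", el[, 1], el[, 2]),
      sprintf("%s\t", isolates))
  }
  tryCatch(writeLines(lines, path),
           error = function(e) abort_io("cannot write network to ", path, ": ",
                                        conditionMessage(e)))
  invisible(path)
}

#' Read a network from file
#'
#' Inverse of [export_network()] for all three formats. Role labels are not
#' stored in these formats; all nodes come back as `"neighbor"`.
#'
#' @param path Network file.
#' @param format `"sif"`, `"tsv"` or `"graphml"`.
#' @return An `interactome`.
#' @export
read_network <- function(path, format = c("sif", "tsv", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_io("network file not found: ", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "collapse")
    return(interactome(igraph::as_edgelist(g), nodes = igraph::V(g)$name))
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "tsv" && length(lines)) lines <- lines[-1]  # header
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  a <- vapply(fields, function(f) trimws(f[[1]]), "")
  bcol <- if (format == "sif") 3L else 2L
  b <- vapply(fields, function(f) if (length(f) >= bcol) trimws(f[[bcol]]) else "", "")
  is_edge <- nzchar(b)
  interactome(cbind(a[is_edge], b[is_edge]), nodes = a[!is_edge])
}
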