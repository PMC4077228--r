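#' Packaged neurodegenerative-dementia disease-gene table
#'
#' The curated table of neurodegenerative dementia diseases with their
#' associated disease proteins (UniProt accessions), official gene symbols
#' and pathological protein marker, shipped as a plain-text fixture. It is
#' the disease seed input of the integration analysis; a row may share its
#' accession with another disease (e.g. MAPT anchors both frontotemporal
#' dementia and supranuclear palsy).
#'
#' @return Data frame with columns `disease`, `accession`, `symbol`,
#'   `marker` (32 rows).
#' @examples
#' head(dementia_seed_table())
#' @export
dementia_seed_table <- function() {
  path <- system.file("extdata", "dementia_disease_genes.tsv",
                      package = "seednet", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' Disease seed set from the packaged dementia table
#'
#' @param diseases Optional character vector restricting to a disease
#'   subgroup (matched against the `disease` column by substring, case
#'   insensitive) — e.g. `"Frontotemporal"` for the tauopathy-linked rows.
#' @param marker Optional marker restriction (`"Tau"`, `"Prion"`, ...),
#'   substring-matched.
#' @return A [seed_set()] of the corresponding accessions.
#' @examples
#' dementia_disease_seeds()
#' dementia_disease_seeds(marker = "Tau")
#' @export
dementia_disease_seeds <- function(diseases = NULL, marker = NULL) {
  tab <- dementia_seed_table()
  if (!is.null(diseases)) {
    keep <- Reduce(`|`, lapply(diseases, function(d)
      grepl(d, tab$disease, ignore.case = TRUE)))
    tab <- tab[keep, , drop = FALSE]
  }
  if (!is.null(marker))
    tab <- tab[grepl(marker, tab$marker, ignore.case = TRUE), , drop = FALSE]
  if (!nrow(tab)) stop("no seed rows match the restriction")
  seed_set(tab$accession, "disease")
}
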