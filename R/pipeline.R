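#' Run the full integration analysis
#'
#' Orchestrates the whole pipeline end-to-end from a single configuration:
#' (1) read, filter and integrate the interaction records with the two seed
#' sets and export the network; (2) topology statistics and degree ranking;
#' (3) mediator extraction with seed linkage; (4) annotation-term enrichment
#' of the mediator list and of the top-degree list; (5) overlay of the
#' mediators onto the reference network. Stage outputs consumed by later
#' stages are read back from the exported files, so the on-disk formats are
#' guaranteed sufficient. A run manifest with config hash, input digests and
#' per-stage counts is always written — also when a stage fails, in which
#' case the error is re-thrown tagged with the stage name.
#'
#' @param config Either a named list or the path to a YAML file with
#'   sections:
#' \describe{
#'   \item{inputs}{`ppi`, `disease_symbols`, `target_symbols`, `mapping`;
#'     optional `annotations`, `obo`, `reference`, `baits`.}
#'   \item{filters}{`exclude_predicted` (default `TRUE`).}
#'   \item{enrichment}{`alpha` (default 0.001), `kept_fraction` (default
#'     0.03), `method` (default `"jaccard"`), `degree_cutoff` (default 100:
#'     the "more than `degree_cutoff` interactions" list), optional
#'     `seed_subset` (seed accessions restricting the mediator linkage, e.g.
#'     one disease subgroup).}
#'   \item{overlap}{`top_k` (default 10).}
#'   \item{output}{`dir` (required).}
#' }
#' @param quiet Suppress progress messages?
#' @return The output directory path, invisibly. Files written:
#'   `network.sif`, `network.tsv`, `stats.json`, `degrees.tsv`,
#'   `mediators.tsv`, `linkage.tsv`, `enrich_mediators.tsv`,
#'   `enrich_top_degree.tsv`, `terms.graphml`, `overlap.tsv`,
#'   `manifest.json`.
#' @export
run_full_analysis <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$output$dir))
  out_dir <- config$output$dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[seednet] ", ...)
  op <- function(f) file.path(out_dir, f)

  inputs <- config$inputs
  in_files <- unlist(inputs[!vapply(inputs, is.null, TRUE)])
  manifest <- list(
    tool = "seednet",
    version = as.character(utils::packageVersion("seednet")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = unname(tools::md5sum(write_tmp_json(config))),
    inputs = as.list(tools::md5sum(in_files[file.exists(in_files)])),
    stages = list(),
    notes = character())
  finish <- function() {
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    outs <- list.files(out_dir, full.names = TRUE)
    outs <- outs[basename(outs) != "manifest.json"]
    manifest$outputs <- as.list(tools::md5sum(outs))
    jsonlite::write_json(manifest, op("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  stage <- function(name, expr) {
    say("stage: ", name)
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      finish()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    res
  }

  # -- stage: build ---------------------------------------------------------
  built <- stage("build", {
    exclude_pred <- config$filters$exclude_predicted %||% TRUE
    dialect <- do.call(interaction_dialect,
                       config$inputs$dialect %||% list())
    records <- read_interactions(inputs$ppi, dialect)
    filtered <- filter_interactions(records, exclude_predicted = exclude_pred)
    disease <- load_seed_set(inputs$disease_symbols, inputs$mapping, "disease")
    targets <- load_seed_set(inputs$target_symbols, inputs$mapping, "drug_target")
    net <- suppressWarnings(build_integrated_network(filtered, disease, targets))
    export_network(net, op("network.sif"), "sif")
    export_network(net, op("network.tsv"), "tsv")
    list(net = net, disease = disease, targets = targets,
         removed = attr(filtered, "removed"), n_records = nrow(records))
  })
  manifest$stages$build <- list(
    status = "ok", records_read = built$n_records,
    removed = as.list(built$removed),
    nodes = unname(network_size(built$net)[["nodes"]]),
    edges = unname(network_size(built$net)[["edges"]]))

  # -- stage: stats ---------------------------------------------------------
  stats_res <- stage("stats", {
    net <- read_network(op("network.tsv"), "tsv")  # read back through io
    st <- summarize_network(net)
    jsonlite::write_json(as.list(st), op("stats.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    deg <- degree_index(net)
    write.table(deg, op("degrees.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(stats = st, degrees = deg)
  })
  manifest$stages$stats <- list(status = "ok",
                                n_components = stats_res$stats$n_components)

  # -- stage: mediators -----------------------------------------------------
  meds <- stage("mediators", {
    net <- read_network(op("network.tsv"), "tsv")
    m <- suppressWarnings(mediator_set(net, built$disease, built$targets))
    write.table(data.frame(mediator = m$members), op("mediators.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    lk <- linkage_table(m, seeds = config$enrichment$seed_subset)
    write.table(lk, op("linkage.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    m
  })
  manifest$stages$mediators <- list(status = "ok",
                                    n_mediators = length(meds$members),
                                    n_linkage_rows = nrow(meds$linkage))

  # -- stages: enrichment ---------------------------------------------------
  if (is.null(inputs$annotations)) {
    say("no annotations configured; enrichment stages skipped")
    manifest$stages$enrich_mediators <- list(status = "skipped",
                                             reason = "no annotation input")
    manifest$stages$enrich_top_degree <- list(status = "skipped",
                                              reason = "no annotation input")
    manifest$notes <- c(manifest$notes,
                        "enrichment skipped: no annotation input configured")
  } else {
    enr_cfg <- config$enrichment
    alpha <- enr_cfg$alpha %||% 0.001
    kept <- enr_cfg$kept_fraction %||% 0.03
    method <- enr_cfg$method %||% "jaccard"
    cutoff <- enr_cfg$degree_cutoff %||% 100
    ann <- stage("enrich_mediators", read_annotations(inputs$annotations))
    if (!is.null(inputs$obo)) {
      obo <- read_obo(inputs$obo)
      ann <- annotation_set(ann$term_to_genes, term_names = obo$names,
                            ontology_parents = obo$parents)
    }
    enr_run <- function(name, query) {
      stage(name, {
        res <- suppressWarnings(enrich_terms(query, ann, alpha = alpha))
        if (!is.null(ann$ontology_parents))
          res <- prune_redundant_terms(res, ann)
        write.table(res, op(paste0(name, ".tsv")), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        res
      })
    }
    # queries are read back from the exported stage outputs
    res_med <- enr_run("enrich_mediators", read_mediator_list(op("mediators.tsv")))
    top <- read.delim(op("degrees.tsv"), stringsAsFactors = FALSE)
    top_list <- top$accession[top$degree > cutoff]
    res_top <- if (length(top_list)) enr_run("enrich_top_degree", top_list) else NULL
    if (is.null(res_top)) {
      manifest$stages$enrich_top_degree <-
        list(status = "skipped",
             reason = sprintf("no node exceeds degree cutoff %d", cutoff))
      manifest$notes <- c(manifest$notes,
                          "top-degree enrichment skipped: empty query")
    } else {
      manifest$stages$enrich_top_degree <-
        list(status = "ok", n_terms = nrow(res_top),
             n_significant = sum(res_top$significant))
    }
    manifest$stages$enrich_mediators <-
      list(status = "ok", n_terms = nrow(res_med),
           n_significant = sum(res_med$significant))
    tg <- stage("term_graph", {
      tg <- suppressWarnings(build_term_graph(res_med, ann,
                                              kept_fraction = kept,
                                              method = method))
      igraph::write_graph(tg$graph, op("terms.graphml"), format = "graphml")
      tg
    })
    manifest$stages$term_graph <- list(status = "ok",
                                       n_terms = igraph::vcount(tg$graph),
                                       n_edges = igraph::ecount(tg$graph))
  }

  # -- stage: overlap -------------------------------------------------------
  if (is.null(inputs$reference)) {
    say("no reference network configured; overlap stage skipped")
    manifest$stages$overlap <- list(status = "skipped",
                                    reason = "no reference network input")
    manifest$notes <- c(manifest$notes,
                        "overlap skipped: no reference network input")
  } else {
    ov <- stage("overlap", {
      ref_records <- read_interactions(inputs$reference)
      ref_net <- records_graph(filter_interactions(ref_records))
      baits <- if (!is.null(inputs$baits)) read_baits(inputs$baits) else NULL
      ref <- reference_network(ref_net, baits = baits)
      mediator_ids <- read_mediator_list(op("mediators.tsv"))
      rep <- suppressWarnings(
        overlap_report(mediator_ids, ref,
                       top_k = config$overlap$top_k %||% 10))
      write.table(rep, op("overlap.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      rep
    })
    manifest$stages$overlap <- list(
      status = "ok", n_in_reference = sum(ov$in_reference),
      n_top_k = sum(ov$in_top_k), effective_k = attr(ov, "effective_k"),
      n_articulation = sum(ov$is_articulation))
  }

  finish()
  say("done: ", out_dir)
  invisible(out_dir)
}

read_mediator_list <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  df$mediator
}

write_tmp_json <- function(x) {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
  f
}
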