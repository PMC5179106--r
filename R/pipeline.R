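# End-to-end orchestration: assemble -> network -> score -> rank ->
# drugs -> enrichment, reading a bundle directory of evidence tables and
# writing every stage output plus a run log with the row counts at each
# stage and a hash of the configuration.

.bundle_paths <- function(dir) {
  list(gwas = file.path(dir, "gwas.tsv"),
       epigenetics = file.path(dir, "epigenetics.tsv"),
       proteomics = file.path(dir, "proteomics.tsv"),
       metabolites = file.path(dir, "metabolites.tsv"),
       links = file.path(dir, "metabolite_protein_links.tsv"),
       gene_map = file.path(dir, "gene_map.tsv"),
       pathogenesis = file.path(dir, "pathogenesis.tsv"))
}

#' Pipeline configuration
#'
#' @param input_dir directory holding the evidence bundle (file names as
#'   written by [generate_bundle()] / [generate_worked_example()]).
#' @param out_dir output directory.
#' @param scoring a [scoring_config()].
#' @param resolution multi-platform resolution rule (`"max"` or
#'   `"priority"`).
#' @param min_links metabolomic inclusion threshold (default 2 changed
#'   metabolites).
#' @param hub_min_degree hub degree threshold (default 10).
#' @param alpha enrichment significance level on the adjusted p-value.
#' @param internal_control accession fixed at score 1, or `NULL`.
#' @param enrichment_query `"targets"` (all candidate gene symbols) or
#'   `"multiplatform"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            scoring = scoring_config(),
                            resolution = c("max", "priority"),
                            min_links = 2L, hub_min_degree = 10L,
                            alpha = 0.05, internal_control = NULL,
                            enrichment_query = c("targets",
                                                 "multiplatform")) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 scoring = scoring,
                 resolution = match.arg(resolution),
                 min_links = min_links,
                 hub_min_degree = hub_min_degree, alpha = alpha,
                 internal_control = internal_control,
                 enrichment_query = match.arg(enrichment_query)),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  plain <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(plain, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full drug-repositioning pipeline
#'
#' Reads the evidence bundle, assembles the candidate-target list,
#' builds and exports the metabolite-protein network, scores and ranks
#' the targets, joins them to the drug catalog, tests pathway
#' over-representation, and writes every output plus a run log to
#' `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a named list of the in-memory stage results
#'   (`targets`, `ranked`, `candidates`, `summary`, `enrichment`,
#'   `network`, `outputs`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("config_hash: %s", .config_hash(config)))
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  paths <- .bundle_paths(config$input_dir)
  bundle <- suppressWarnings(read_evidence_bundle(paths))
  bundle$pathogenesis <- suppressWarnings(
    read_pathogenesis(paths$pathogenesis))
  for (nm in c("gwas", "epigenetics", "proteomics", "metabolites",
               "links", "pathogenesis")) {
    note("read %s: %d rows accepted, %d rejected", nm, nrow(bundle[[nm]]),
         nrow(attr(bundle[[nm]], "rejected")))
  }
  catalog <- suppressWarnings(read_drug_catalog(
    file.path(config$input_dir, "drug_catalog.tsv")))
  note("read drug_catalog: %d rows", nrow(catalog))

  met_targets <- suppressWarnings(collect_metabolite_proteins(
    bundle$links, bundle$metabolites, min_links = config$min_links))
  note("metabolomic targets (>= %d changed metabolites): %d",
       config$min_links, nrow(met_targets))
  targets <- suppressWarnings(assemble_targets(
    bundle$gwas, bundle$epigenetics, bundle$proteomics, met_targets,
    gene_map = bundle$gene_map))
  multi <- multiplatform_targets(targets)
  note("targets assembled: %d (multi-platform: %d)", nrow(targets),
       nrow(multi))

  network <- suppressWarnings(
    build_bipartite(bundle$links, bundle$metabolites))
  out_net_sif <- file.path(config$out_dir, "metabolite_protein.sif")
  out_net_gml <- file.path(config$out_dir, "metabolite_protein.graphml")
  write_network(network, out_net_sif, "SIF")
  write_network(network, out_net_gml, "GraphML")
  note("bipartite network: %d nodes, %d edges",
       igraph::vcount(network), igraph::ecount(network))

  scores <- suppressWarnings(score_targets(
    targets, bundle, bundle$pathogenesis, config$scoring,
    config$resolution))
  ranked <- rank_targets(scores, config$internal_control)
  note("targets scored: %d of %d", nrow(ranked), nrow(targets))
  write_tsv(data.frame(ranked[, c("uniprot_id", "platform_used",
                                  "effect_term", "citation_term",
                                  "publication_term", "total", "rank",
                                  "is_internal_control")]),
            file.path(config$out_dir, "ranked_targets.tsv"))

  candidates <- suppressMessages(build_candidates(
    ranked, catalog, bundle$pathogenesis))
  summary_tbl <- summarize_candidates(candidates)
  note("repositioning candidates: %d drug rows on %d targets",
       nrow(candidates), nrow(summary_tbl))
  write_tsv(candidates, file.path(config$out_dir, "candidates.tsv"))
  write_tsv(summary_tbl, file.path(config$out_dir, "target_summary.tsv"))

  gene_sets <- read_gmt(file.path(config$input_dir, "pathways.gmt"))
  query_tbl <- if (config$enrichment_query == "multiplatform") multi
  else targets
  query <- unique(query_tbl$gene_symbol)
  query <- query[!is.na(query) & nzchar(query)]
  enrichment <- tryCatch(
    suppressWarnings(enrich(query, gene_sets, alpha = config$alpha)),
    error = function(e) {
      note("enrichment skipped: %s", conditionMessage(e))
      NULL
    })
  if (!is.null(enrichment)) {
    note("enrichment: %d pathways with overlap, %d significant at %g",
         nrow(enrichment), sum(enrichment$significant), config$alpha)
    write_tsv(enrichment, file.path(config$out_dir, "enrichment.tsv"))
  }

  log_path <- file.path(config$out_dir, "run_log.txt")
  writeLines(log_lines, log_path, useBytes = TRUE)
  outputs <- c(network_sif = out_net_sif, network_graphml = out_net_gml,
               ranked = file.path(config$out_dir, "ranked_targets.tsv"),
               candidates = file.path(config$out_dir, "candidates.tsv"),
               summary = file.path(config$out_dir, "target_summary.tsv"),
               log = log_path)
  if (!is.null(enrichment)) {
    outputs["enrichment"] <- file.path(config$out_dir, "enrichment.tsv")
  }
  invisible(list(targets = targets, multiplatform = multi,
                 ranked = ranked, candidates = candidates,
                 summary = summary_tbl, enrichment = enrichment,
                 network = network, outputs = outputs,
                 log = log_lines))
}
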