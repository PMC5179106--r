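# Readers, writers and row-level validation for every evidence table the
# pipeline consumes. All delimited I/O is UTF-8 with a required header and
# one observation per row; the delimiter (tab or comma) is auto-detected
# from the header line so tab and comma dialects of the same content parse
# identically.

# Column schemas, by platform. Names are matched case-insensitively.
.schemas <- list(
  gwas        = c("gene_symbol", "snp_id", "odds_ratio", "p_value",
                  "initial_n", "replication_n", "pubmed_id"),
  epigenetics = c("gene_symbol", "uniprot_id", "direction", "pubmed_id"),
  proteomics  = c("uniprot_id", "gene_symbol", "fold_change", "sample_type",
                  "pubmed_id"),
  metabolites = c("metabolite_id", "name", "fold_change", "sample_type"),
  links       = c("metabolite_id", "uniprot_id"),
  gene_map    = c("gene_symbol", "uniprot_id"),
  drugs       = c("drug_name", "target_uniprot", "stage", "mode_of_action",
                  "original_indication", "source_db"),
  pathogenesis = c("uniprot_id", "role", "citation_count",
                   "publication_count")
)

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L, encoding = "UTF-8", warn = FALSE)
  if (length(header) == 0L) return("\t")
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

# Read a delimited file, lower-case the header, and demand the schema.
.read_table <- function(path, schema, sep = NULL) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  if (is.null(sep)) sep <- .detect_sep(path)
  df <- read.delim(path, sep = sep, header = TRUE,
                   colClasses = "character", check.names = FALSE,
                   fileEncoding = "UTF-8", stringsAsFactors = FALSE,
                   blank.lines.skip = TRUE)
  names(df) <- tolower(trimws(names(df)))
  missing <- setdiff(schema, names(df))
  if (length(missing) > 0L) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), schema)
  if (length(extra) > 0L) {
    stop("unknown column(s) in ", basename(path), ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  df[, schema, drop = FALSE]
}

# Attach a per-row rejection report so accepted + rejected always accounts
# for every row read.
.finish_validation <- function(df, keep, reasons, key = NULL, what = "rows") {
  rejected <- data.frame(row = which(!keep),
                         reason = reasons[!keep],
                         stringsAsFactors = FALSE)
  out <- df[keep, , drop = FALSE]
  if (!is.null(key) && nrow(out) > 0L) {
    dup <- duplicated(out[, key, drop = FALSE])
    if (any(dup)) out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  attr(out, "n_read") <- nrow(df)
  if (nrow(rejected) > 0L) {
    warning(nrow(rejected), " invalid ", what, " rejected (rows ",
            paste(head(rejected$row, 10L), collapse = ", "),
            if (nrow(rejected) > 10L) ", ..." else "", ")", call. = FALSE)
  }
  out
}

.num <- function(x) suppressWarnings(as.numeric(x))
.int <- function(x) suppressWarnings(as.integer(round(as.numeric(x))))

#' Read a table of genetic associations
#'
#' Each row is one GWAS association: a gene symbol, an rs-identifier, a
#' per-risk-allele odds ratio, a p-value and the study sample sizes. Rows
#' violating the invariants (odds ratio > 0, p-value in (0, 1], non-empty
#' SNP id) are rejected with their row numbers recorded in the
#' `rejected` attribute; duplicated (gene, SNP) pairs keep the first row.
#'
#' @param path path to a tab- or comma-delimited file with columns
#'   `gene_symbol, snp_id, odds_ratio, p_value, initial_n, replication_n,
#'   pubmed_id` (case-insensitive).
#' @param sep field delimiter; auto-detected from the header when `NULL`.
#' @return a data frame of validated associations with attributes
#'   `rejected` (row, reason) and `n_read`.
#' @export
read_gwas <- function(path, sep = NULL) {
  df <- .read_table(path, .schemas$gwas, sep)
  df$odds_ratio <- .num(df$odds_ratio)
  df$p_value <- .num(df$p_value)
  df$initial_n <- .int(df$initial_n)
  df$replication_n <- .int(df$replication_n)
  reasons <- character(nrow(df))
  ok_or <- !is.na(df$odds_ratio) & df$odds_ratio > 0
  ok_p <- !is.na(df$p_value) & df$p_value > 0 & df$p_value <= 1
  ok_snp <- !is.na(df$snp_id) & nzchar(trimws(df$snp_id))
  ok_n <- !is.na(df$initial_n) & df$initial_n >= 0L &
    !is.na(df$replication_n) & df$replication_n >= 0L
  reasons[!ok_or] <- "odds_ratio must be > 0"
  reasons[!ok_p] <- "p_value must be in (0, 1]"
  reasons[!ok_n] <- "sample sizes must be non-negative integers"
  reasons[!ok_snp] <- "snp_id must be non-empty"
  .finish_validation(df, ok_or & ok_p & ok_snp & ok_n, reasons,
                     key = c("gene_symbol", "snp_id"), what = "GWAS rows")
}

# Shared fold-change validation: stored magnitudes are >= 1 with the sign
# carrying direction (positive = elevated in the disease group). Ratios r
# in (0, 1) optionally normalize to -1/r.
.validate_fold <- function(df, normalize, what) {
  df$fold_change <- .num(df$fold_change)
  sub_unity <- !is.na(df$fold_change) & df$fold_change > 0 &
    df$fold_change < 1
  if (normalize && any(sub_unity)) {
    df$fold_change[sub_unity] <- -1 / df$fold_change[sub_unity]
    warning(sum(sub_unity), " ", what,
            " fold-change ratio(s) in (0,1) normalized to -1/ratio",
            call. = FALSE)
  }
  df
}

#' Read a table of CSF proteomic changes
#'
#' Fold changes are stored as signed magnitudes: `|fold_change| >= 1`,
#' positive when the protein is elevated in the AD group. With
#' `normalize = TRUE` (default) a ratio r in (0, 1) is converted to
#' `-1/r` with a warning; otherwise such rows are rejected.
#'
#' @inheritParams read_gwas
#' @param normalize convert sub-unity ratios to negative magnitudes.
#' @return validated data frame with `rejected` and `n_read` attributes.
#' @export
read_proteomics <- function(path, sep = NULL, normalize = TRUE) {
  df <- .read_table(path, .schemas$proteomics, sep)
  df <- .validate_fold(df, normalize, "proteomic")
  reasons <- character(nrow(df))
  ok_f <- !is.na(df$fold_change) & abs(df$fold_change) >= 1
  ok_s <- toupper(trimws(df$sample_type)) == "CSF"
  ok_id <- nzchar(trimws(df$uniprot_id))
  reasons[!ok_f] <- "fold_change magnitude must be >= 1"
  reasons[!ok_s] <- "sample_type must be CSF"
  reasons[!ok_id] <- "uniprot_id must be non-empty"
  df$sample_type[ok_s] <- "CSF"
  .finish_validation(df, ok_f & ok_s & ok_id, reasons,
                     key = "uniprot_id", what = "proteomic rows")
}

#' Read a table of metabolite changes
#'
#' @inheritParams read_proteomics
#' @return validated data frame with `rejected` and `n_read` attributes.
#' @export
read_metabolites <- function(path, sep = NULL, normalize = TRUE) {
  df <- .read_table(path, .schemas$metabolites, sep)
  df <- .validate_fold(df, normalize, "metabolite")
  reasons <- character(nrow(df))
  ok_f <- !is.na(df$fold_change) & abs(df$fold_change) >= 1
  ok_id <- nzchar(trimws(df$metabolite_id))
  reasons[!ok_f] <- "fold_change magnitude must be >= 1"
  reasons[!ok_id] <- "metabolite_id must be non-empty"
  .finish_validation(df, ok_f & ok_id, reasons,
                     key = "metabolite_id", what = "metabolite rows")
}

#' Read a table of epigenetic events
#'
#' @inheritParams read_gwas
#' @return validated data frame; `direction` is one of
#'   `hyper`, `hypo`, `altered`.
#' @export
read_epigenetics <- function(path, sep = NULL) {
  df <- .read_table(path, .schemas$epigenetics, sep)
  df$direction <- tolower(trimws(df$direction))
  reasons <- character(nrow(df))
  ok_d <- df$direction %in% c("hyper", "hypo", "altered")
  ok_g <- nzchar(trimws(df$gene_symbol))
  reasons[!ok_d] <- "direction must be one of hyper/hypo/altered"
  reasons[!ok_g] <- "gene_symbol must be non-empty"
  .finish_validation(df, ok_d & ok_g, reasons,
                     key = c("gene_symbol", "uniprot_id"),
                     what = "epigenetic rows")
}

#' Read a metabolite-protein link table
#'
#' One row per HMDB-style association between a metabolite and a protein
#' that produces, consumes or transports it. Duplicate pairs collapse to
#' one link.
#'
#' @inheritParams read_gwas
#' @return validated data frame of unique (metabolite_id, uniprot_id)
#'   pairs.
#' @export
read_links <- function(path, sep = NULL) {
  df <- .read_table(path, .schemas$links, sep)
  reasons <- character(nrow(df))
  ok <- nzchar(trimws(df$metabolite_id)) & nzchar(trimws(df$uniprot_id))
  reasons[!ok] <- "metabolite_id and uniprot_id must be non-empty"
  .finish_validation(df, ok, reasons,
                     key = c("metabolite_id", "uniprot_id"),
                     what = "link rows")
}

#' Read a gene-symbol to UniProt accession mapping
#'
#' GWAS and epigenetic platforms report gene symbols; the accession is the
#' pipeline's primary key. This mapping externalizes the symbol-to-protein
#' choice (a locus tagging several genes is the supplier's call).
#'
#' @inheritParams read_gwas
#' @return data frame with columns `gene_symbol`, `uniprot_id`.
#' @export
read_gene_map <- function(path, sep = NULL) {
  df <- .read_table(path, .schemas$gene_map, sep)
  reasons <- character(nrow(df))
  ok <- nzchar(trimws(df$gene_symbol)) & nzchar(trimws(df$uniprot_id))
  reasons[!ok] <- "gene_symbol and uniprot_id must be non-empty"
  .finish_validation(df, ok, reasons, key = "gene_symbol",
                     what = "gene-map rows")
}

#' Read per-target pathogenesis annotations
#'
#' Each target's disease role (gain of function, loss of function or
#' unknown), the citation count C of the paper establishing its
#' pathogenesis, and the count H of publications linking it to the
#' disease.
#'
#' @inheritParams read_gwas
#' @return validated data frame with columns `uniprot_id`, `role`
#'   (`GOF`/`LOF`/`unknown`), `citation_count`, `publication_count`.
#' @export
read_pathogenesis <- function(path, sep = NULL) {
  df <- .read_table(path, .schemas$pathogenesis, sep)
  role <- toupper(trimws(df$role))
  role[role == "UNKNOWN"] <- "unknown"
  df$role <- role
  df$citation_count <- .int(df$citation_count)
  df$publication_count <- .int(df$publication_count)
  reasons <- character(nrow(df))
  ok_r <- df$role %in% c("GOF", "LOF", "unknown")
  ok_c <- !is.na(df$citation_count) & df$citation_count >= 0L &
    !is.na(df$publication_count) & df$publication_count >= 0L
  reasons[!ok_r] <- "role must be GOF, LOF or unknown"
  reasons[!ok_c] <- "citation/publication counts must be >= 0"
  .finish_validation(df, ok_r & ok_c, reasons, key = "uniprot_id",
                     what = "pathogenesis rows")
}

#' Read the complete evidence bundle for a run
#'
#' Convenience wrapper reading every platform table from a named list of
#' paths. Elements `gwas`, `epigenetics`, `proteomics`, `metabolites` and
#' `links` are required; `gene_map` and `pathogenesis` are optional.
#'
#' @param paths named list or character vector of file paths.
#' @param sep delimiter forwarded to each reader (auto-detected when
#'   `NULL`).
#' @param normalize forwarded to the fold-change readers.
#' @return named list of validated tables.
#' @export
read_evidence_bundle <- function(paths, sep = NULL, normalize = TRUE) {
  paths <- as.list(paths)
  need <- c("gwas", "epigenetics", "proteomics", "metabolites", "links")
  missing <- setdiff(need, names(paths))
  if (length(missing) > 0L) {
    stop("paths must name the tables: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bundle <- list(
    gwas = read_gwas(paths$gwas, sep),
    epigenetics = read_epigenetics(paths$epigenetics, sep),
    proteomics = read_proteomics(paths$proteomics, sep, normalize),
    metabolites = read_metabolites(paths$metabolites, sep, normalize),
    links = read_links(paths$links, sep)
  )
  if (!is.null(paths$gene_map)) {
    bundle$gene_map <- read_gene_map(paths$gene_map, sep)
  }
  if (!is.null(paths$pathogenesis)) {
    bundle$pathogenesis <- read_pathogenesis(paths$pathogenesis, sep)
  }
  bundle
}

#' Default development-stage synonym map
#'
#' Maps free-text stage labels (case-insensitive) onto the three-token
#' vocabulary `approved` / `clinical_trial` / `experimental`. Users can
#' extend it via a YAML file with the same three top-level keys.
#'
#' @param path optional YAML file overriding the shipped map.
#' @return named list of character vectors keyed by canonical stage.
#' @export
stage_synonyms <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stage_synonyms.yaml", package = "adrepo")
  }
  syn <- yaml::read_yaml(path)
  stopifnot(all(c("approved", "clinical_trial", "experimental") %in%
                  names(syn)))
  lapply(syn, tolower)
}

#' Mode-of-action vocabulary, partitioned by pharmacological direction
#'
#' Tokens are classed as `inhibiting` (reduce target activity),
#' `activating` (increase it) or `neutral` (no directional claim); the
#' classes drive the gain-/loss-of-function compatibility call.
#'
#' @param path optional YAML file overriding the shipped vocabulary.
#' @return named list with elements `inhibiting`, `activating`,
#'   `neutral`.
#' @export
moa_classes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "moa_classes.yaml", package = "adrepo")
  }
  cls <- yaml::read_yaml(path)
  stopifnot(all(c("inhibiting", "activating", "neutral") %in% names(cls)))
  lapply(cls, tolower)
}

#' Read a drug-target catalog
#'
#' Emulates a TTD/DrugBank export: one row per (drug, target, mode of
#' action). Free-text development stages are normalized through the
#' synonym map; an unmapped stage falls back to `experimental` with a
#' warning. Modes of action outside the vocabulary are normalized to
#' `unknown` with a warning.
#'
#' @inheritParams read_gwas
#' @param synonyms stage synonym map as returned by [stage_synonyms()].
#' @param vocabulary mode-of-action vocabulary as returned by
#'   [moa_classes()].
#' @return validated data frame of drug records.
#' @export
read_drug_catalog <- function(path, sep = NULL, synonyms = stage_synonyms(),
                              vocabulary = moa_classes()) {
  df <- .read_table(path, .schemas$drugs, sep)
  stage_raw <- tolower(trimws(df$stage))
  stage <- rep(NA_character_, length(stage_raw))
  for (canon in names(synonyms)) {
    stage[stage_raw %in% c(canon, synonyms[[canon]])] <- canon
  }
  unmapped <- is.na(stage)
  if (any(unmapped)) {
    warning(sum(unmapped), " drug row(s) with unmapped stage (",
            paste(unique(stage_raw[unmapped]), collapse = ", "),
            ") treated as experimental", call. = FALSE)
    stage[unmapped] <- "experimental"
  }
  df$stage <- stage
  moa <- tolower(trimws(df$mode_of_action))
  vocab <- unlist(vocabulary, use.names = FALSE)
  bad_moa <- !(moa %in% vocab)
  if (any(bad_moa)) {
    warning(sum(bad_moa), " drug row(s) with mode of action outside the ",
            "vocabulary (", paste(unique(moa[bad_moa]), collapse = ", "),
            ") treated as unknown", call. = FALSE)
    moa[bad_moa] <- "unknown"
  }
  df$mode_of_action <- moa
  src <- df$source_db
  src[!src %in% c("TTD", "DrugBank")] <- "other"
  df$source_db <- src
  reasons <- character(nrow(df))
  ok <- nzchar(trimws(df$drug_name)) & nzchar(trimws(df$target_uniprot))
  reasons[!ok] <- "drug_name and target_uniprot must be non-empty"
  .finish_validation(df, ok, reasons,
                     key = c("drug_name", "target_uniprot",
                             "mode_of_action"),
                     what = "drug rows")
}

#' Read pathway gene sets in GMT format
#'
#' Standard GMT: one pathway per line, tab-separated fields `name`,
#' `description`, then member genes. The gene universe defaults to the
#' union of all sets unless an explicit universe is supplied.
#'
#' @param path GMT file path.
#' @param universe optional character vector (or path to a one-gene-per-
#'   line file) overriding the default universe.
#' @return list with elements `sets` (named list of character vectors)
#'   and `universe` (character vector).
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, ": expected >= 3 tab-separated fields",
           call. = FALSE)
    }
    sets[[fields[[1]]]] <- unique(fields[-(1:2)])
  }
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)),
                     method = "radix")
  } else {
    if (length(universe) == 1L && file.exists(universe)) {
      universe <- readLines(universe, encoding = "UTF-8", warn = FALSE)
    }
    universe <- sort(unique(universe[nzchar(universe)]), method = "radix")
    outside <- setdiff(unlist(sets, use.names = FALSE), universe)
    if (length(outside) > 0L) {
      sets <- lapply(sets, intersect, y = universe)
      sets <- sets[vapply(sets, length, 1L) > 0L]
      warning(length(outside),
              " gene(s) outside the supplied universe dropped from sets",
              call. = FALSE)
    }
  }
  structure(list(sets = sets, universe = universe),
            class = "pathway_gene_sets")
}

#' Export a network for Cytoscape
#'
#' Writes an igraph network as SIF (one edge per line, relation token
#' `links`, lexicographically smaller endpoint first, edges sorted) or
#' GraphML (attributes preserved). Isolated nodes appear as single-field
#' SIF lines.
#'
#' @param graph an igraph object.
#' @param path output file.
#' @param format `"SIF"` or `"GraphML"` (case-insensitive).
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path, format = c("SIF", "GraphML")) {
  format <- tolower(format[[1]])
  if (!format %in% c("sif", "graphml")) {
    stop("unknown network format: ", format, call. = FALSE)
  }
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(graph, names = TRUE)
  lines <- character(0)
  if (nrow(el) > 0L) {
    a <- pmin(el[, 1], el[, 2])
    b <- pmax(el[, 1], el[, 2])
    ord <- order(a, b, method = "radix")
    lines <- paste(a[ord], "links", b[ord], sep = "\t")
  }
  deg <- igraph::degree(graph)
  isolated <- names(deg)[deg == 0]
  if (length(isolated) > 0L) {
    lines <- c(lines, sort(isolated, method = "radix"))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Re-read a network written by [write_network()]
#'
#' @param path file written by [write_network()].
#' @param format `"SIF"` or `"GraphML"`.
#' @return an igraph object.
#' @export
read_network <- function(path, format = c("SIF", "GraphML")) {
  format <- tolower(format[[1]])
  if (!format %in% c("sif", "graphml")) {
    stop("unknown network format: ", format, call. = FALSE)
  }
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  edges <- fields[vapply(fields, length, 1L) >= 3L]
  singles <- unlist(fields[vapply(fields, length, 1L) == 1L])
  el <- do.call(rbind, lapply(edges, function(f) f[c(1, 3)]))
  g <- igraph::make_empty_graph(directed = FALSE)
  nodes <- unique(c(as.vector(el), singles))
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (!is.null(el)) {
    g <- igraph::add_edges(g, t(el))
  }
  igraph::simplify(g)
}

#' Write a data frame as a UTF-8 TSV with deterministic formatting
#'
#' @param df data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
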