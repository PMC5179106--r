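# Build the unified candidate-target list from the four evidence
# platforms. Proteins qualify through metabolomics only when they link to
# at least `min_links` distinct changed metabolites (the >= 2 rule); for
# each such protein, n counts its linked changed metabolites and N all of
# its link-table partners, the two counts the metabolomic fold-change
# imputation consumes.

#' Proteins linked to changed metabolites
#'
#' Scans an HMDB-style metabolite-protein link table and returns the
#' proteins linked to at least `min_links` distinct changed metabolites.
#' For each protein, `n_changed_metabolites` (n) counts the distinct
#' changed metabolites linked to it and `total_linked_metabolites` (N)
#' counts all distinct metabolites linked to it anywhere in the link
#' table, changed or not.
#'
#' @param links data frame of links as from [read_links()].
#' @param changes data frame of metabolite changes as from
#'   [read_metabolites()], or a character vector of changed metabolite
#'   ids.
#' @param min_links minimum number of distinct changed metabolites
#'   (default 2).
#' @return data frame with columns `uniprot_id`,
#'   `linked_changed_metabolites` (pipe-joined, sorted),
#'   `n_changed_metabolites`, `total_linked_metabolites`, sorted by
#'   accession.
#' @export
collect_metabolite_proteins <- function(links, changes, min_links = 2L) {
  stopifnot(min_links >= 1L)
  changed <- if (is.data.frame(changes)) changes$metabolite_id else changes
  changed <- unique(changed)
  absent <- setdiff(changed, links$metabolite_id)
  if (length(absent) > 0L) {
    warning(length(absent), " changed metabolite(s) absent from the link ",
            "table contribute nothing: ",
            paste(head(absent, 5L), collapse = ", "),
            if (length(absent) > 5L) ", ..." else "", call. = FALSE)
  }
  pair <- unique(links[, c("metabolite_id", "uniprot_id")])
  if (nrow(pair) == 0L || length(changed) == 0L) {
    return(data.frame(uniprot_id = character(0),
                      linked_changed_metabolites = character(0),
                      n_changed_metabolites = integer(0),
                      total_linked_metabolites = integer(0),
                      stringsAsFactors = FALSE))
  }
  total <- tapply(pair$metabolite_id, pair$uniprot_id,
                  function(m) length(unique(m)))
  chg <- pair[pair$metabolite_id %in% changed, , drop = FALSE]
  by_prot <- split(chg$metabolite_id, chg$uniprot_id)
  by_prot <- lapply(by_prot, function(m) sort(unique(m), method = "radix"))
  n_chg <- vapply(by_prot, length, 1L)
  keep <- names(by_prot)[n_chg >= min_links]
  keep <- sort(keep, method = "radix")
  data.frame(
    uniprot_id = keep,
    linked_changed_metabolites = vapply(by_prot[keep], paste,
                                        character(1), collapse = "|"),
    n_changed_metabolites = unname(n_chg[keep]),
    total_linked_metabolites = unname(as.integer(total[keep])),
    stringsAsFactors = FALSE
  )
}

#' Assemble the unified candidate-target table
#'
#' One record per unique protein accession, with `platforms` the
#' pipe-joined union of the evidence platforms implicating it
#' (`genetics`, `epigenetics`, `proteomics`, `metabolomics`). GWAS and
#' epigenetic evidence arrives as gene symbols; `gene_map` translates
#' them to accessions (symbols without a mapping are kept under a
#' `GENE:<symbol>` placeholder accession with a warning, so no evidence
#' is silently dropped).
#'
#' @param genetic GWAS table from [read_gwas()] (or `NULL`).
#' @param epigenetic epigenetics table from [read_epigenetics()] (or
#'   `NULL`).
#' @param proteomic proteomics table from [read_proteomics()] (or
#'   `NULL`).
#' @param metabolite_targets output of [collect_metabolite_proteins()]
#'   (or `NULL`).
#' @param gene_map optional symbol-to-accession map from
#'   [read_gene_map()].
#' @return data frame of candidate targets sorted by accession, with
#'   columns `uniprot_id`, `gene_symbol`, `platforms`,
#'   `linked_changed_metabolites`, `n_changed_metabolites`,
#'   `total_linked_metabolites`.
#' @export
assemble_targets <- function(genetic = NULL, epigenetic = NULL,
                             proteomic = NULL, metabolite_targets = NULL,
                             gene_map = NULL) {
  map_symbol <- function(symbols) {
    if (is.null(gene_map)) {
      acc <- rep(NA_character_, length(symbols))
    } else {
      acc <- gene_map$uniprot_id[match(symbols, gene_map$gene_symbol)]
    }
    unmapped <- is.na(acc)
    if (any(unmapped)) {
      warning(sum(unmapped), " gene symbol(s) without accession mapping ",
              "kept under GENE:<symbol> placeholder", call. = FALSE)
      acc[unmapped] <- paste0("GENE:", symbols[unmapped])
    }
    acc
  }
  rows <- list()
  add <- function(uniprot, symbol, platform) {
    if (length(uniprot) == 0L) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      uniprot_id = uniprot, gene_symbol = symbol, platform = platform,
      stringsAsFactors = FALSE)
  }
  if (!is.null(genetic) && nrow(genetic) > 0L) {
    add(map_symbol(genetic$gene_symbol), genetic$gene_symbol, "genetics")
  }
  if (!is.null(epigenetic) && nrow(epigenetic) > 0L) {
    acc <- epigenetic$uniprot_id
    blank <- !nzchar(trimws(acc))
    acc[blank] <- map_symbol(epigenetic$gene_symbol[blank])
    add(acc, epigenetic$gene_symbol, "epigenetics")
  }
  if (!is.null(proteomic) && nrow(proteomic) > 0L) {
    add(proteomic$uniprot_id, proteomic$gene_symbol, "proteomics")
  }
  if (!is.null(metabolite_targets) && nrow(metabolite_targets) > 0L) {
    add(metabolite_targets$uniprot_id,
        rep(NA_character_, nrow(metabolite_targets)), "metabolomics")
  }
  empty <- data.frame(uniprot_id = character(0), gene_symbol = character(0),
                      platforms = character(0),
                      linked_changed_metabolites = character(0),
                      n_changed_metabolites = integer(0),
                      total_linked_metabolites = integer(0),
                      stringsAsFactors = FALSE)
  if (length(rows) == 0L) return(empty)
  long <- do.call(rbind, rows)
  accs <- sort(unique(long$uniprot_id), method = "radix")
  platforms <- vapply(accs, function(a) {
    p <- unique(long$platform[long$uniprot_id == a])
    paste(sort(p, method = "radix"), collapse = "|")
  }, character(1))
  symbol <- vapply(accs, function(a) {
    s <- long$gene_symbol[long$uniprot_id == a]
    s <- s[!is.na(s) & nzchar(s)]
    if (length(s) > 0L) s[[1]] else NA_character_
  }, character(1))
  out <- data.frame(uniprot_id = accs, gene_symbol = symbol,
                    platforms = platforms,
                    linked_changed_metabolites = "",
                    n_changed_metabolites = 0L,
                    total_linked_metabolites = 0L,
                    stringsAsFactors = FALSE)
  if (!is.null(metabolite_targets) && nrow(metabolite_targets) > 0L) {
    i <- match(metabolite_targets$uniprot_id, out$uniprot_id)
    out$linked_changed_metabolites[i] <-
      metabolite_targets$linked_changed_metabolites
    out$n_changed_metabolites[i] <-
      metabolite_targets$n_changed_metabolites
    out$total_linked_metabolites[i] <-
      metabolite_targets$total_linked_metabolites
  }
  if (!is.null(gene_map)) {
    na_sym <- is.na(out$gene_symbol)
    out$gene_symbol[na_sym] <- gene_map$gene_symbol[
      match(out$uniprot_id[na_sym], gene_map$uniprot_id)]
  }
  rownames(out) <- NULL
  out
}

#' Targets implicated by two or more platforms
#'
#' @param targets assembled table from [assemble_targets()].
#' @param min_platforms minimum number of distinct platforms (default 2).
#' @return subset of `targets`, same ordering rule (accession ascending).
#' @export
multiplatform_targets <- function(targets, min_platforms = 2L) {
  n_platforms <- lengths(strsplit(targets$platforms, "|", fixed = TRUE))
  out <- targets[n_platforms >= min_platforms, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Platforms of a candidate target as a character vector
#'
#' @param targets assembled table.
#' @return list of character vectors, one per row.
#' @export
target_platforms <- function(targets) {
  strsplit(targets$platforms, "|", fixed = TRUE)
}
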