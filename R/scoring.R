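# The weighted-sum target score. Each candidate target is scored on one
# evidence platform as
#
#   TS = w_effect * effect / effect_ref
#      + w_citation * C / c_ref
#      + w_publication * H / h_ref
#
# where the effect is the odds ratio (genetics), the fold-change
# magnitude (proteomics) or an imputed fold change averaged over all
# linked metabolites (metabolomics); C is the citation count of the paper
# establishing the target's pathogenesis and H the count of publications
# linking the target to the disease. The reference constants anchor the
# scale so that a target with all evidence at the internal-control
# references scores exactly 1.

#' Scoring configuration
#'
#' Houses the three criterion weights and the internal-control reference
#' constants: the CSF A-beta-42 fold change (2.37) for proteomic and
#' metabolomic effects, the APOE-e4 odds ratio (3.7) for genetic effects,
#' and the APP citation (4092) and publication (11294) counts.
#'
#' @param w_effect weight of the normalized effect size (default 0.33).
#' @param w_citation weight of the normalized citation count (default
#'   0.34).
#' @param w_publication weight of the normalized publication count
#'   (default 0.33).
#' @param f_ref reference fold-change magnitude (default 2.37).
#' @param or_ref reference odds ratio (default 3.7).
#' @param c_ref reference citation count (default 4092).
#' @param h_ref reference publication count (default 11294).
#' @return a `scoring_config` list.
#' @export
scoring_config <- function(w_effect = 0.33, w_citation = 0.34,
                           w_publication = 0.33, f_ref = 2.37,
                           or_ref = 3.7, c_ref = 4092, h_ref = 11294) {
  if (abs(w_effect + w_citation + w_publication - 1) > 1e-9) {
    stop("weights must sum to 1", call. = FALSE)
  }
  if (any(c(f_ref, or_ref, c_ref, h_ref) <= 0)) {
    stop("reference constants must be positive", call. = FALSE)
  }
  structure(list(w_effect = w_effect, w_citation = w_citation,
                 w_publication = w_publication, f_ref = f_ref,
                 or_ref = or_ref, c_ref = c_ref, h_ref = h_ref),
            class = "scoring_config")
}

#' Read or write a scoring configuration as YAML
#'
#' @param path YAML file path.
#' @return for `read_scoring_config`, a `scoring_config`; for
#'   `write_scoring_config`, `path` invisibly.
#' @export
read_scoring_config <- function(path) {
  do.call(scoring_config, yaml::read_yaml(path))
}

#' @rdname read_scoring_config
#' @param config a `scoring_config`.
#' @export
write_scoring_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.breakdown <- function(uniprot_id, platform, effect_term, citation_term,
                       publication_term) {
  if (length(effect_term) == 0L) {
    uniprot_id <- character(0)
    platform <- character(0)
    citation_term <- publication_term <- numeric(0)
  }
  data.frame(uniprot_id = uniprot_id, platform_used = platform,
             effect_term = effect_term, citation_term = citation_term,
             publication_term = publication_term,
             total = effect_term + citation_term + publication_term,
             stringsAsFactors = FALSE)
}

.check_counts <- function(C, H) {
  if (any(is.na(C)) || any(is.na(H)) || any(C < 0) || any(H < 0)) {
    stop("citation and publication counts must be non-negative",
         call. = FALSE)
  }
}

#' Score a target from genetic evidence
#'
#' Weighted sum of the odds ratio normalized to the reference odds ratio,
#' and the citation and publication counts normalized to the reference
#' counts. Scores are not capped: evidence stronger than the references
#' yields a score above 1.
#'
#' @param or_value per-risk-allele odds ratio (> 0); vectorized.
#' @param C citation count of the pathogenesis paper (>= 0).
#' @param H publication count linking target and disease (>= 0).
#' @param config a [scoring_config()].
#' @param uniprot_id optional accession label carried into the output.
#' @return data frame score breakdown with columns `uniprot_id`,
#'   `platform_used`, `effect_term`, `citation_term`, `publication_term`,
#'   `total`.
#' @export
score_genetic <- function(or_value, C = 0, H = 0, config = scoring_config(),
                          uniprot_id = NA_character_) {
  if (any(is.na(or_value)) || any(or_value <= 0)) {
    stop("odds ratio must be positive", call. = FALSE)
  }
  .check_counts(C, H)
  .breakdown(uniprot_id, "genetics",
             config$w_effect * (or_value / config$or_ref),
             config$w_citation * (C / config$c_ref),
             config$w_publication * (H / config$h_ref))
}

#' Score a target from proteomic evidence
#'
#' The effect is the fold-change magnitude `|F|` normalized to the
#' reference fold change; the sign of `F` (direction of change) does not
#' enter the score.
#'
#' @param F signed fold change with `|F| >= 1`; vectorized.
#' @inheritParams score_genetic
#' @return data frame score breakdown.
#' @export
score_proteomic <- function(F, C = 0, H = 0, config = scoring_config(),
                            uniprot_id = NA_character_) {
  if (any(is.na(F)) || any(abs(F) < 1)) {
    stop("fold-change magnitude must be >= 1 (normalize ratios first)",
         call. = FALSE)
  }
  .check_counts(C, H)
  .breakdown(uniprot_id, "proteomics",
             config$w_effect * (abs(F) / config$f_ref),
             config$w_citation * (C / config$c_ref),
             config$w_publication * (H / config$h_ref))
}

#' Impute a protein's fold change from its linked metabolites
#'
#' A protein implicated through metabolomics has no directly measured
#' fold change; it is imputed as the mean fold-change magnitude over all
#' N metabolites linked to the protein, counting the N - n metabolites
#' with no reported change as unchanged (magnitude 1):
#' `(sum(|F_i|) + (N - n)) / N`.
#'
#' @param fold_changes signed fold changes of the n linked changed
#'   metabolites (each `|F_i| >= 1`).
#' @param n_total N, the total number of distinct metabolites linked to
#'   the protein in the link table (`N >= n >= 1`).
#' @return the imputed positive fold-change magnitude.
#' @export
impute_metabolomic_fold <- function(fold_changes, n_total) {
  n <- length(fold_changes)
  if (n == 0L) {
    stop("no changed metabolites: metabolomic score undefined",
         call. = FALSE)
  }
  if (n_total < 1L) stop("total linked metabolites must be >= 1",
                         call. = FALSE)
  if (n_total < n) {
    stop("total linked metabolites (", n_total,
         ") cannot be fewer than changed ones (", n, ")", call. = FALSE)
  }
  if (any(abs(fold_changes) < 1)) {
    stop("fold-change magnitudes must be >= 1", call. = FALSE)
  }
  (sum(abs(fold_changes)) + (n_total - n)) / n_total
}

#' Score a target from metabolomic evidence
#'
#' The effect term uses the imputed fold change of
#' [impute_metabolomic_fold()] normalized to the reference fold change;
#' the citation and publication terms are as in the other platforms.
#' With a single linked metabolite (N = n = 1) the score reduces to the
#' proteomic score of that metabolite's fold change.
#'
#' @inheritParams impute_metabolomic_fold
#' @inheritParams score_genetic
#' @return data frame score breakdown.
#' @export
score_metabolomic <- function(fold_changes, n_total, C = 0, H = 0,
                              config = scoring_config(),
                              uniprot_id = NA_character_) {
  .check_counts(C, H)
  imputed <- impute_metabolomic_fold(fold_changes, n_total)
  .breakdown(uniprot_id, "metabolomics",
             config$w_effect * (imputed / config$f_ref),
             config$w_citation * (C / config$c_ref),
             config$w_publication * (H / config$h_ref))
}

# Gather the scoreable platform evidence available for one target.
.platform_scores <- function(target, bundle, C, H, config) {
  platforms <- strsplit(target$platforms, "|", fixed = TRUE)[[1]]
  out <- list()
  if ("proteomics" %in% platforms) {
    row <- bundle$proteomics[bundle$proteomics$uniprot_id ==
                               target$uniprot_id, , drop = FALSE]
    if (nrow(row) > 0L) {
      out$proteomics <- score_proteomic(row$fold_change[[1]], C, H, config,
                                        target$uniprot_id)
    }
  }
  if ("genetics" %in% platforms && !is.null(bundle$gwas)) {
    symbols <- target$gene_symbol
    if (!is.null(bundle$gene_map)) {
      mapped <- bundle$gene_map$gene_symbol[
        bundle$gene_map$uniprot_id == target$uniprot_id]
      symbols <- unique(c(symbols, mapped))
    }
    ors <- bundle$gwas$odds_ratio[bundle$gwas$gene_symbol %in% symbols]
    if (length(ors) > 0L) {
      # several associations can tag one gene; keep the strongest
      out$genetics <- score_genetic(max(ors), C, H, config,
                                    target$uniprot_id)
    }
  }
  if ("metabolomics" %in% platforms &&
      target$n_changed_metabolites >= 1L) {
    ids <- strsplit(target$linked_changed_metabolites, "|",
                    fixed = TRUE)[[1]]
    folds <- bundle$metabolites$fold_change[
      match(ids, bundle$metabolites$metabolite_id)]
    folds <- folds[!is.na(folds)]
    if (length(folds) > 0L) {
      out$metabolomics <- score_metabolomic(
        folds, max(target$total_linked_metabolites, length(folds)),
        C, H, config, target$uniprot_id)
    }
  }
  out
}

#' Score one candidate target
#'
#' Applies the platform-specific score equation. For a target implicated
#' by several scoreable platforms, `resolution` picks the single reported
#' score: `"max"` (default) keeps the highest-scoring platform,
#' `"priority"` prefers proteomics over genetics over metabolomics.
#' Epigenetic evidence never scores; a target with only epigenetic
#' evidence is an error.
#'
#' @param target one row of the [assemble_targets()] table.
#' @param bundle evidence bundle list (elements `gwas`, `proteomics`,
#'   `metabolites`, optionally `gene_map`).
#' @param annotation one row of the pathogenesis table for this target,
#'   or `NULL` (counts then default to 0).
#' @param config a [scoring_config()].
#' @param resolution `"max"` or `"priority"`.
#' @return one-row score breakdown data frame.
#' @export
score_target <- function(target, bundle, annotation = NULL,
                         config = scoring_config(),
                         resolution = c("max", "priority")) {
  resolution <- match.arg(resolution)
  C <- if (!is.null(annotation) && nrow(annotation) > 0L)
    annotation$citation_count[[1]] else 0
  H <- if (!is.null(annotation) && nrow(annotation) > 0L)
    annotation$publication_count[[1]] else 0
  scores <- .platform_scores(target, bundle, C, H, config)
  if (length(scores) == 0L) {
    stop("unscoreable platform: target ", target$uniprot_id,
         " has no genetic, proteomic or metabolomic evidence",
         call. = FALSE)
  }
  if (resolution == "max") {
    totals <- vapply(scores, function(s) s$total, numeric(1))
    # deterministic tie-break: platform name ascending
    ord <- order(-totals, names(scores), method = "radix")
    scores[[ord[[1]]]]
  } else {
    for (p in c("proteomics", "genetics", "metabolomics")) {
      if (!is.null(scores[[p]])) return(scores[[p]])
    }
  }
}

#' Score every scoreable target in an assembled table
#'
#' Targets with no scoreable evidence (epigenetics-only) are skipped with
#' a warning rather than erroring, so that an assembled list can always
#' be ranked.
#'
#' @param targets table from [assemble_targets()].
#' @param bundle evidence bundle list.
#' @param annotations pathogenesis table from [read_pathogenesis()], or
#'   `NULL`.
#' @inheritParams score_target
#' @return score breakdown data frame, one row per scored target.
#' @export
score_targets <- function(targets, bundle, annotations = NULL,
                          config = scoring_config(),
                          resolution = c("max", "priority")) {
  resolution <- match.arg(resolution)
  rows <- vector("list", nrow(targets))
  skipped <- character(0)
  for (i in seq_len(nrow(targets))) {
    target <- targets[i, , drop = FALSE]
    annotation <- NULL
    if (!is.null(annotations)) {
      annotation <- annotations[annotations$uniprot_id ==
                                  target$uniprot_id, , drop = FALSE]
    }
    res <- tryCatch(
      score_target(target, bundle, annotation, config, resolution),
      error = function(e) NULL)
    if (is.null(res)) skipped <- c(skipped, target$uniprot_id)
    rows[[i]] <- res
  }
  if (length(skipped) > 0L) {
    warning(length(skipped), " target(s) without scoreable evidence ",
            "skipped: ", paste(head(skipped, 5L), collapse = ", "),
            if (length(skipped) > 5L) ", ..." else "", call. = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- .breakdown(character(0), character(0), numeric(0), numeric(0),
                      numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Rank scored targets
#'
#' Orders score breakdowns by total descending (accession ascending on
#' ties) and assigns dense ranks 1..K. A designated internal control is
#' assigned a total of exactly 1 (overriding its computed value) and
#' flagged, anchoring the scale to the known disease protein.
#'
#' @param breakdowns score breakdown data frame from [score_targets()].
#' @param internal_control accession of the internal-control target, or
#'   `NULL` for none.
#' @return data frame of ranked targets with added columns `rank` and
#'   `is_internal_control`.
#' @export
rank_targets <- function(breakdowns, internal_control = NULL) {
  if (anyDuplicated(breakdowns$uniprot_id)) {
    stop("duplicate accession in score table: ",
         paste(unique(breakdowns$uniprot_id[
           duplicated(breakdowns$uniprot_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(breakdowns$total))) {
    stop("non-finite score", call. = FALSE)
  }
  out <- breakdowns
  out$is_internal_control <- rep(FALSE, nrow(out))
  if (!is.null(internal_control) && nrow(out) > 0L) {
    hit <- out$uniprot_id == internal_control
    out$total[hit] <- 1
    out$is_internal_control[hit] <- TRUE
  }
  ord <- order(-out$total, out$uniprot_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
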