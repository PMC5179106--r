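# Join ranked targets to the drug catalog, keep approved and
# clinical-trial drugs, and call mechanistic compatibility: a drug that
# inhibits a gain-of-function target (or activates a loss-of-function
# one) is compatible with a therapeutic rationale; the opposite pairing
# is incompatible; any unknown on either side is unknown.

#' Keep approved and clinical-trial drugs
#'
#' @param catalog drug table from [read_drug_catalog()].
#' @param keep stages to retain (default approved + clinical_trial).
#' @return filtered catalog; retained/removed counts in a message.
#' @export
filter_stage <- function(catalog,
                         keep = c("approved", "clinical_trial")) {
  sel <- catalog$stage %in% keep
  message(sum(sel), " of ", nrow(catalog),
          " drug rows kept (stages: ", paste(keep, collapse = ", "), ")")
  out <- catalog[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mechanistic compatibility of a drug with its target's disease role
#'
#' @param role target disease role: `"GOF"`, `"LOF"` or `"unknown"`;
#'   vectorized.
#' @param mode_of_action vocabulary token (see [moa_classes()]);
#'   vectorized, recycled against `role`.
#' @param classes mode-of-action class list from [moa_classes()].
#' @return character vector: `"compatible"`, `"incompatible"` or
#'   `"unknown"`.
#' @export
assess_compatibility <- function(role, mode_of_action,
                                 classes = moa_classes()) {
  n <- max(length(role), length(mode_of_action))
  role <- rep_len(toupper(role), n)
  role[role == "UNKNOWN"] <- "unknown"
  mode_of_action <- rep_len(tolower(mode_of_action), n)
  vocab <- unlist(classes, use.names = FALSE)
  bad <- !(mode_of_action %in% vocab)
  if (any(bad)) {
    stop("mode of action token(s) outside the vocabulary: ",
         paste(unique(mode_of_action[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!role %in% c("GOF", "LOF", "unknown"))) {
    stop("role must be GOF, LOF or unknown", call. = FALSE)
  }
  moa_dir <- ifelse(mode_of_action %in% classes$inhibiting, "inhibiting",
                    ifelse(mode_of_action %in% classes$activating,
                           "activating", "neutral"))
  out <- rep("unknown", n)
  out[role == "GOF" & moa_dir == "inhibiting"] <- "compatible"
  out[role == "LOF" & moa_dir == "activating"] <- "compatible"
  out[role == "GOF" & moa_dir == "activating"] <- "incompatible"
  out[role == "LOF" & moa_dir == "inhibiting"] <- "incompatible"
  out
}

#' Build the repositioning candidate table
#'
#' One row per (target, drug, mode of action) pair after the stage
#' filter, restricted to ranked targets and, by default, to targets with
#' pathogenesis information (a known GOF/LOF role). Known disease
#' targets are flagged `"validation"`; the rest are `"novel"`.
#'
#' @param ranked ranked target table from [rank_targets()].
#' @param catalog drug catalog (filtered by [filter_stage()] internally).
#' @param annotations pathogenesis table from [read_pathogenesis()].
#' @param classes mode-of-action class list.
#' @param exclude_unknown_role drop targets whose role is unknown or
#'   unannotated (default `TRUE`, the study's behavior; such proteins
#'   remain in the ranked list as future targets).
#' @param known_targets accessions of already-validated disease targets
#'   (flagged `"validation"`).
#' @return data frame ordered by target rank then drug name, with
#'   columns from both sides plus `compatibility`, `category` and
#'   `rationale_note`.
#' @export
build_candidates <- function(ranked, catalog, annotations,
                             classes = moa_classes(),
                             exclude_unknown_role = TRUE,
                             known_targets = c("P22303", "P05067")) {
  eligible <- filter_stage(catalog)
  ann <- annotations[match(ranked$uniprot_id, annotations$uniprot_id), ,
                     drop = FALSE]
  role <- ann$role
  role[is.na(role)] <- "unknown"
  keep_target <- rep(TRUE, nrow(ranked))
  if (exclude_unknown_role) keep_target <- role != "unknown"
  rows <- list()
  for (i in which(keep_target)) {
    drugs <- eligible[eligible$target_uniprot == ranked$uniprot_id[i], ,
                      drop = FALSE]
    drugs <- drugs[!duplicated(drugs[, c("drug_name", "mode_of_action")]), ,
                   drop = FALSE]
    if (nrow(drugs) == 0L) next
    compat <- assess_compatibility(role[i], drugs$mode_of_action, classes)
    rows[[length(rows) + 1L]] <- data.frame(
      uniprot_id = ranked$uniprot_id[i],
      rank = ranked$rank[i],
      total = ranked$total[i],
      platform_used = ranked$platform_used[i],
      role = role[i],
      drug_name = drugs$drug_name,
      stage = drugs$stage,
      mode_of_action = drugs$mode_of_action,
      original_indication = drugs$original_indication,
      source_db = drugs$source_db,
      compatibility = compat,
      category = if (ranked$uniprot_id[i] %in% known_targets)
        "validation" else "novel",
      rationale_note = paste0(role[i], " target + ", drugs$mode_of_action,
                              " -> ", compat),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(uniprot_id = character(0), rank = integer(0),
                      total = numeric(0), platform_used = character(0),
                      role = character(0), drug_name = character(0),
                      stage = character(0), mode_of_action = character(0),
                      original_indication = character(0),
                      source_db = character(0),
                      compatibility = character(0),
                      category = character(0),
                      rationale_note = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$rank, out$drug_name, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-target drug counts
#'
#' Summarizes the candidate table: distinct drugs per target, split by
#' development stage and by compatibility call. Duplicate (target, drug)
#' pairs (a drug with several modes of action) count once in `n_drugs`.
#'
#' @param candidates table from [build_candidates()].
#' @return data frame, one row per target, ordered by rank.
#' @export
summarize_candidates <- function(candidates) {
  if (nrow(candidates) == 0L) {
    return(data.frame(uniprot_id = character(0), rank = integer(0),
                      n_drugs = integer(0), n_approved = integer(0),
                      n_clinical_trial = integer(0),
                      n_compatible = integer(0),
                      n_incompatible = integer(0), n_unknown = integer(0),
                      stringsAsFactors = FALSE))
  }
  accs <- unique(candidates$uniprot_id)
  rows <- lapply(accs, function(a) {
    cand <- candidates[candidates$uniprot_id == a, , drop = FALSE]
    pairs <- cand[!duplicated(cand$drug_name), , drop = FALSE]
    data.frame(
      uniprot_id = a,
      rank = cand$rank[[1]],
      n_drugs = nrow(pairs),
      n_approved = sum(pairs$stage == "approved"),
      n_clinical_trial = sum(pairs$stage == "clinical_trial"),
      n_compatible = sum(cand$compatibility == "compatible"),
      n_incompatible = sum(cand$compatibility == "incompatible"),
      n_unknown = sum(cand$compatibility == "unknown"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$rank, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
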