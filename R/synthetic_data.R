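# Seeded generator emitting every input table the pipeline consumes, with
# planted ground truth. Background effect sizes emulate the field:
# odds ratios lognormal around typical GWAS effects with the reference
# APOE odds ratio as the heavy-tail anchor, fold-change magnitudes
# 1 + exponential below the reference CSF A-beta-42 fold change, and
# citation/publication counts power-law distributed below the APP
# reference counts. Planted targets have every score component multiplied
# by `plant_boost`, and the generator guarantees by construction that the
# planted targets carry the largest true scores, so planted-signal
# recovery isolates pipeline defects rather than sampling noise.

#' Generator configuration
#'
#' @param seed integer random seed; identical configurations produce
#'   byte-identical bundles.
#' @param n_targets number of candidate proteins.
#' @param n_metabolites number of metabolites in the link table.
#' @param n_drugs number of background drug rows.
#' @param planted_targets number of targets planted with boosted
#'   evidence.
#' @param plant_boost multiplier applied to every score component (odds
#'   ratio, fold magnitude, citation and publication counts) of a
#'   planted target.
#' @param link_degree_mean mean number of protein partners per
#'   metabolite.
#' @param platform_fractions named simplex weights over
#'   `genetics`, `epigenetics`, `proteomics`, `metabolomics`.
#' @param n_multiplatform number of targets implicated by a second
#'   platform.
#' @param changed_fraction fraction of metabolites with a reported
#'   change.
#' @param stage_mix named categorical probabilities over drug stages.
#' @param mode_mix named categorical probabilities over modes of action.
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1L, n_targets = 500L,
                             n_metabolites = 150L, n_drugs = 250L,
                             planted_targets = 5L, plant_boost = 3,
                             link_degree_mean = 3,
                             platform_fractions = c(genetics = 0.35,
                                                    epigenetics = 0.08,
                                                    proteomics = 0.27,
                                                    metabolomics = 0.30),
                             n_multiplatform = 8L,
                             changed_fraction = 0.5,
                             stage_mix = c(approved = 0.35,
                                           clinical_trial = 0.35,
                                           experimental = 0.30),
                             mode_mix = c(inhibitor = 0.30,
                                          antagonist = 0.10,
                                          antibody = 0.10,
                                          agonist = 0.15,
                                          activator = 0.10,
                                          substrate = 0.15,
                                          unknown = 0.10)) {
  if (planted_targets > n_targets) {
    stop("planted_targets cannot exceed n_targets", call. = FALSE)
  }
  for (p in list(platform_fractions, stage_mix, mode_mix)) {
    if (abs(sum(p) - 1) > 1e-9) {
      stop("probability mixes must sum to 1", call. = FALSE)
    }
  }
  if (plant_boost <= 0 || link_degree_mean <= 0) {
    stop("plant_boost and link_degree_mean must be positive",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "generator_config")
}

.fmt <- function(x, digits = 6) sprintf(paste0("%.", digits, "f"), x)

# Discrete power law (Pareto tail index ~2), truncated at `cap`.
.rpowerlaw <- function(n, scale, cap) {
  pmin(cap, floor(scale / runif(n)))
}

# Per-target true score as the pipeline will see it: the maximum over the
# platform scores implied by the emitted tables.
.true_scores <- function(state, config_sc) {
  n <- nrow(state$targets)
  score_of <- function(eff, ref, C, H) {
    config_sc$w_effect * eff / ref +
      config_sc$w_citation * C / config_sc$c_ref +
      config_sc$w_publication * H / config_sc$h_ref
  }
  best <- rep(-Inf, n)
  best_platform <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    tg <- state$targets[i, ]
    s <- c()
    if (!is.na(tg$or_value)) {
      s["genetics"] <- score_of(tg$or_value, config_sc$or_ref, tg$C, tg$H)
    }
    if (!is.na(tg$f_value)) {
      s["proteomics"] <- score_of(abs(tg$f_value), config_sc$f_ref,
                                  tg$C, tg$H)
    }
    idx <- state$link_changed_idx[[i]]
    if (length(idx) >= 2L) {
      m <- (sum(abs(state$met_fold[idx])) +
              (state$link_total[[i]] - length(idx))) /
        state$link_total[[i]]
      s["metabolomics"] <- score_of(m, config_sc$f_ref, tg$C, tg$H)
    }
    if (length(s) > 0L) {
      k <- which.max(s)
      best[i] <- s[[k]]
      best_platform[i] <- names(s)[[k]]
    }
  }
  list(score = best, platform = best_platform)
}

#' Generate a complete synthetic evidence bundle
#'
#' Writes every input table of the pipeline into `dir` (GWAS,
#' epigenetics, proteomics, metabolites, metabolite-protein links, drug
#' catalog, pathogenesis annotations, gene map and a GMT pathway file)
#' and returns the planted ground truth. Planted targets have all score
#' components boosted and each is guaranteed at least one approved or
#' clinical-trial drug with a mechanistically compatible mode of action.
#' Background targets whose implied score would exceed 90% of the lowest
#' planted score are deterministically shrunk, so the planted targets
#' carry the largest true scores by construction.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `dir`, `paths` (named file paths),
#'   `config` and `ground_truth` (planted accessions, per-target true
#'   components and scores, planted drug pairs).
#' @export
generate_bundle <- function(config = generator_config(), dir = tempfile()) {
  stopifnot(inherits(config, "generator_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  sc <- scoring_config()

  n <- config$n_targets
  acc <- sprintf("P%05d", 10000L + seq_len(n))
  sym <- sprintf("GN%04d", seq_len(n))
  met_id <- sprintf("HMDB%07d", seq_len(config$n_metabolites))

  platforms <- names(config$platform_fractions)
  platform <- sample(platforms, n, replace = TRUE,
                     prob = config$platform_fractions)
  planted_idx <- sort(sample.int(n, config$planted_targets))
  # planted targets must carry scoreable evidence
  scoreable <- c("genetics", "proteomics", "metabolomics")
  need_fix <- planted_idx[!platform[planted_idx] %in% scoreable]
  if (length(need_fix) > 0L) {
    platform[need_fix] <- sample(scoreable, length(need_fix),
                                 replace = TRUE)
  }
  second <- rep(NA_character_, n)
  pool <- setdiff(seq_len(n), planted_idx)
  n_multi <- min(config$n_multiplatform, length(pool))
  if (n_multi > 0L) {
    multi_idx <- sort(sample(pool, n_multi))
    for (i in multi_idx) {
      second[i] <- sample(setdiff(c("genetics", "proteomics",
                                    "epigenetics"), platform[i]), 1L)
    }
  }
  has_plat <- function(p) platform == p | (!is.na(second) & second == p)

  # --- background components ------------------------------------------
  or_value <- ifelse(has_plat("genetics"),
                     rlnorm(n, meanlog = log(1.15), sdlog = 0.15),
                     NA_real_)
  f_mag <- ifelse(has_plat("proteomics"), 1 + rexp(n, rate = 1 / 0.6),
                  NA_real_)
  f_sign <- sample(c(-1, 1), n, replace = TRUE)
  C <- .rpowerlaw(n, scale = 2, cap = sc$c_ref)
  H <- .rpowerlaw(n, scale = 5, cap = sc$h_ref)
  role <- sample(c("GOF", "LOF", "unknown"), n, replace = TRUE,
                 prob = c(0.4, 0.4, 0.2))

  # --- metabolites and links ------------------------------------------
  changed <- runif(config$n_metabolites) < config$changed_fraction
  met_fold <- (1 + rexp(config$n_metabolites, rate = 1 / 0.6)) *
    sample(c(-1, 1), config$n_metabolites, replace = TRUE)
  deg <- 1L + rpois(config$n_metabolites,
                    max(config$link_degree_mean - 1, 0.1))
  link_m <- rep(seq_len(config$n_metabolites), deg)
  link_p <- unlist(lapply(deg, function(d) sample.int(n, min(d, n))))
  links <- unique(data.frame(m = link_m, p = link_p))
  # every metabolomics-platform target needs >= 2 changed partners
  for (i in which(has_plat("metabolomics") &
                  !(seq_len(n) %in% planted_idx))) {
    have <- unique(links$m[links$p == i & changed[links$m]])
    need <- 2L - length(have)
    if (need > 0L) {
      cand <- setdiff(which(changed), have)
      add <- sample(cand, min(need, length(cand)))
      links <- rbind(links, data.frame(m = add, p = i))
    }
  }
  # planted metabolomics targets link only to dedicated boosted
  # metabolites, so later background shrinkage cannot touch them
  extra_m <- list()
  for (i in planted_idx[platform[planted_idx] == "metabolomics"]) {
    links <- links[links$p != i, , drop = FALSE]
    k <- 2L + rpois(1L, 1)
    ids <- length(met_id) + length(unlist(extra_m)) + seq_len(k)
    extra_m[[as.character(i)]] <- ids
    links <- rbind(links, data.frame(m = ids, p = i))
  }
  n_extra <- length(unlist(extra_m))
  if (n_extra > 0L) {
    met_id <- c(met_id, sprintf("HMDB%07d", length(met_id) + 900000L +
                                  seq_len(n_extra)))
    changed <- c(changed, rep(TRUE, n_extra))
    boosted <- config$plant_boost * (1 + rexp(n_extra, rate = 1 / 0.6))
    met_fold <- c(met_fold, boosted *
                    sample(c(-1, 1), n_extra, replace = TRUE))
  }
  links <- unique(links)

  # --- plant the signal -----------------------------------------------
  b <- config$plant_boost
  for (i in planted_idx) {
    if (!is.na(or_value[i])) or_value[i] <- or_value[i] * b
    if (!is.na(f_mag[i])) f_mag[i] <- f_mag[i] * b
    C[i] <- min(round(C[i] * b), sc$c_ref)
    H[i] <- min(round(H[i] * b), sc$h_ref)
    if (role[i] == "unknown") role[i] <- sample(c("GOF", "LOF"), 1L)
  }

  # --- background dominance guarantee ---------------------------------
  link_changed_idx <- lapply(seq_len(n), function(i) {
    unique(links$m[links$p == i & changed[links$m]])
  })
  link_total <- vapply(seq_len(n), function(i) {
    length(unique(links$m[links$p == i]))
  }, 1L)
  state <- list(targets = data.frame(or_value = or_value, f_value =
                                       f_mag * f_sign, C = C, H = H),
                met_fold = met_fold,
                link_changed_idx = link_changed_idx,
                link_total = link_total)
  # Planted floor from each planted target's assigned-platform score:
  # those components (own odds ratio / fold change / dedicated
  # metabolites, own C and H) are never shrunk, so the floor is stable.
  assigned_score <- vapply(planted_idx, function(i) {
    Cw <- sc$w_citation * C[i] / sc$c_ref
    Hw <- sc$w_publication * H[i] / sc$h_ref
    eff <- switch(platform[i],
                  genetics = or_value[i] / sc$or_ref,
                  proteomics = abs(f_mag[i] * f_sign[i]) / sc$f_ref,
                  metabolomics = {
                    idx <- link_changed_idx[[i]]
                    m <- (sum(abs(met_fold[idx])) +
                            (link_total[[i]] - length(idx))) /
                      link_total[[i]]
                    m / sc$f_ref
                  })
    sc$w_effect * eff + Cw + Hw
  }, numeric(1))
  # nothing to dominate when no targets are planted
  threshold <- if (length(assigned_score) > 0L)
    0.9 * min(assigned_score) else Inf
  for (iter in seq_len(6L)) {
    ts <- .true_scores(state, sc)
    offenders <- setdiff(which(ts$score > threshold), planted_idx)
    if (length(offenders) == 0L) break
    for (i in offenders) {
      base <- sc$w_effect *
        (if (ts$platform[i] == "genetics") 1 / sc$or_ref else
          1 / sc$f_ref)
      r <- max(0, (threshold - base) / (ts$score[i] - base))
      state$targets$C[i] <- floor(state$targets$C[i] * r)
      state$targets$H[i] <- floor(state$targets$H[i] * r)
      if (!is.na(state$targets$or_value[i]) &&
          state$targets$or_value[i] > 1) {
        state$targets$or_value[i] <- 1 +
          (state$targets$or_value[i] - 1) * r
      }
      if (!is.na(state$targets$f_value[i])) {
        s <- sign(state$targets$f_value[i])
        state$targets$f_value[i] <-
          s * (1 + (abs(state$targets$f_value[i]) - 1) * r)
      }
      idx <- state$link_changed_idx[[i]]
      if (length(idx) >= 2L) {
        state$met_fold[idx] <- sign(state$met_fold[idx]) *
          (1 + (abs(state$met_fold[idx]) - 1) * r)
      }
    }
  }
  or_value <- state$targets$or_value
  f_value <- state$targets$f_value
  C <- state$targets$C
  H <- state$targets$H
  met_fold <- state$met_fold
  ts <- .true_scores(state, sc)

  # --- emit tables -----------------------------------------------------
  paths <- list()
  emit <- function(name, df) {
    p <- file.path(dir, name)
    write_tsv(df, p)
    paths[[sub("[.].*$", "", name)]] <<- p
    p
  }
  gi <- which(has_plat("genetics"))
  emit("gwas.tsv", data.frame(
    gene_symbol = sym[gi],
    snp_id = sprintf("rs%07d", 1000000L + gi),
    odds_ratio = .fmt(or_value[gi]),
    p_value = sprintf("%.1e", 10^-runif(length(gi), 5, 20)),
    initial_n = 5000L + (gi %% 7L) * 1000L,
    replication_n = 2000L + (gi %% 5L) * 500L,
    pubmed_id = sprintf("PM%06d", 100000L + gi)))
  ei <- which(has_plat("epigenetics"))
  emit("epigenetics.tsv", data.frame(
    gene_symbol = sym[ei], uniprot_id = acc[ei],
    direction = c("hyper", "hypo")[1L + (ei %% 2L)],
    pubmed_id = sprintf("PM%06d", 200000L + ei)))
  pi_ <- which(has_plat("proteomics"))
  emit("proteomics.tsv", data.frame(
    uniprot_id = acc[pi_], gene_symbol = sym[pi_],
    fold_change = .fmt(f_value[pi_]), sample_type = "CSF",
    pubmed_id = sprintf("PM%06d", 300000L + pi_)))
  ci <- which(changed)
  emit("metabolites.tsv", data.frame(
    metabolite_id = met_id[ci],
    name = sprintf("metabolite_%03d", ci),
    fold_change = .fmt(met_fold[ci]), sample_type = "CSF"))
  emit("metabolite_protein_links.tsv", data.frame(
    metabolite_id = met_id[links$m], uniprot_id = acc[links$p]))
  emit("gene_map.tsv", data.frame(gene_symbol = sym, uniprot_id = acc))
  emit("pathogenesis.tsv", data.frame(
    uniprot_id = acc, role = role, citation_count = C,
    publication_count = H))

  # drug catalog: background rows plus a guaranteed compatible
  # approved/clinical drug for every planted target
  di <- seq_len(config$n_drugs)
  stage_label <- c(approved = "Approved", clinical_trial = "Phase II",
                   experimental = "experimental")
  drug <- data.frame(
    drug_name = sprintf("DRUG-%04d", di),
    target_uniprot = acc[sample.int(n, config$n_drugs, replace = TRUE)],
    stage = stage_label[sample(names(config$stage_mix), config$n_drugs,
                               replace = TRUE, prob = config$stage_mix)],
    mode_of_action = sample(names(config$mode_mix), config$n_drugs,
                            replace = TRUE, prob = config$mode_mix),
    original_indication = sample(c("oncology", "inflammation",
                                   "metabolic disease", "hypertension",
                                   "infection"), config$n_drugs,
                                 replace = TRUE),
    source_db = sample(c("TTD", "DrugBank"), config$n_drugs,
                       replace = TRUE), stringsAsFactors = FALSE)
  planted_pairs <- data.frame(uniprot_id = character(0),
                              drug_name = character(0),
                              mode_of_action = character(0),
                              stringsAsFactors = FALSE)
  for (j in seq_along(planted_idx)) {
    i <- planted_idx[j]
    moa <- if (role[i] == "GOF") "inhibitor" else "activator"
    nm <- sprintf("DRUG-P%03d", j)
    drug <- rbind(drug, data.frame(
      drug_name = nm, target_uniprot = acc[i], stage = "Approved",
      mode_of_action = moa, original_indication = "oncology",
      source_db = "TTD", stringsAsFactors = FALSE))
    planted_pairs <- rbind(planted_pairs, data.frame(
      uniprot_id = acc[i], drug_name = nm, mode_of_action = moa,
      stringsAsFactors = FALSE))
  }
  emit("drug_catalog.tsv", drug)

  # pathways over the gene-symbol universe
  gmt_lines <- vapply(seq_len(15L), function(k) {
    genes <- sym[sample.int(n, 10L + (k %% 3L) * 5L)]
    paste(c(sprintf("PATHWAY_%02d", k), "synthetic pathway", genes),
          collapse = "\t")
  }, character(1))
  gmt_path <- file.path(dir, "pathways.gmt")
  writeLines(gmt_lines, gmt_path, useBytes = TRUE)
  paths$pathways <- gmt_path

  components <- data.frame(
    uniprot_id = acc, gene_symbol = sym, platform = platform,
    second_platform = second, or_value = or_value, f_value = f_value,
    citation_count = C, publication_count = H,
    n_changed = lengths(link_changed_idx),
    n_total = link_total, role = role,
    true_score = ts$score, score_platform = ts$platform,
    planted = seq_len(n) %in% planted_idx,
    stringsAsFactors = FALSE)
  gt_path <- file.path(dir, "ground_truth.tsv")
  write_tsv(components, gt_path)

  invisible(list(dir = dir, paths = paths, config = config,
                 ground_truth = list(planted = acc[planted_idx],
                                     components = components,
                                     drug_pairs = planted_pairs)))
}
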