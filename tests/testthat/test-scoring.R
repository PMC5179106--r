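# Independent one-line oracles of the three score equations, coded
# directly from their definitions and kept separate from the package's
# implementation path.
oracle_g <- function(or, C, H) 0.33 * or / 3.7 + 0.34 * C / 4092 +
  0.33 * H / 11294
oracle_p <- function(f, C, H) 0.33 * abs(f) / 2.37 + 0.34 * C / 4092 +
  0.33 * H / 11294
oracle_m <- function(folds, N, C, H) {
  0.33 * ((sum(abs(folds)) + N - length(folds)) / N) / 2.37 +
    0.34 * C / 4092 + 0.33 * H / 11294
}

test_that("worked genetic scores match hand evaluation", {
  expect_equal(score_genetic(3.7, 4092, 11294)$total, 1.0)
  expect_equal(score_genetic(7.4, 0, 0)$total, 0.66)
  expect_equal(score_genetic(3.7, 2046, 0)$total, 0.50)
  expect_error(score_genetic(0), "positive")
  expect_error(score_genetic(-1.2), "positive")
})

test_that("worked proteomic scores match hand evaluation and use |F|", {
  expect_equal(score_proteomic(-2.37, 4092, 11294)$total, 1.0)
  expect_equal(score_proteomic(4.74, 2046, 5647)$total, 0.995)
  expect_equal(score_proteomic(2.37, 0, 0)$total, 0.33)
  expect_error(score_proteomic(0.5), "magnitude")
})

test_that("metabolomic imputation averages over all linked metabolites", {
  expect_equal(impute_metabolomic_fold(c(2, 3), 4), 1.75)
  expect_equal(impute_metabolomic_fold(c(1, 1, 1), 3), 1.0)
  expect_equal(impute_metabolomic_fold(2.37, 1), 2.37)
  expect_error(impute_metabolomic_fold(numeric(0), 3), "undefined")
  expect_error(impute_metabolomic_fold(c(2, 3), 1), "cannot be fewer")
  expect_error(impute_metabolomic_fold(c(2, 3), 0), ">= 1")
})

test_that("worked metabolomic scores match hand evaluation", {
  expect_equal(score_metabolomic(c(2, 3), 4, 0, 0)$total,
               0.33 * 1.75 / 2.37, tolerance = 1e-4)
  expect_equal(score_metabolomic(c(-2.37), 1, 4092, 11294)$total, 1.0)
  expect_equal(score_metabolomic(1, 1, 0, 0)$total, 0.33 / 2.37,
               tolerance = 1e-4)
})

test_that("imputation matches brute-force averaging on random instances", {
  set.seed(7)
  for (rep in 1:200) {
    N <- sample(1:20, 1)
    n <- sample(1:N, 1)
    folds <- (1 + rexp(n)) * sample(c(-1, 1), n, replace = TRUE)
    brute <- mean(c(abs(folds), rep(1, N - n)))
    expect_equal(impute_metabolomic_fold(folds, N), brute,
                 tolerance = 1e-12)
  }
})

test_that("each equation matches its independent oracle on random inputs", {
  set.seed(11)
  for (rep in 1:300) {
    or <- runif(1, 0.5, 12)
    f <- runif(1, 1, 10) * sample(c(-1, 1), 1)
    C <- sample(0:8000, 1)
    H <- sample(0:20000, 1)
    expect_equal(score_genetic(or, C, H)$total, oracle_g(or, C, H),
                 tolerance = 1e-12)
    expect_equal(score_proteomic(f, C, H)$total, oracle_p(f, C, H),
                 tolerance = 1e-12)
    N <- sample(1:15, 1); n <- sample(1:N, 1)
    folds <- 1 + rexp(n)
    expect_equal(score_metabolomic(folds, N, C, H)$total,
                 oracle_m(folds, N, C, H), tolerance = 1e-12)
  }
})

test_that("score terms always sum to the total and stay non-negative", {
  set.seed(12)
  for (rep in 1:50) {
    s <- score_genetic(runif(1, 0.5, 8), sample(0:5000, 1),
                       sample(0:15000, 1))
    expect_equal(s$total,
                 s$effect_term + s$citation_term + s$publication_term,
                 tolerance = 1e-12)
    expect_true(all(c(s$effect_term, s$citation_term,
                      s$publication_term) >= 0))
  }
})

test_that("scores are strictly monotone in each component", {
  cfg <- scoring_config()
  set.seed(13)
  for (rep in 1:50) {
    or <- runif(1, 0.5, 8); C <- sample(0:5000, 1)
    H <- sample(0:15000, 1); d <- runif(1, 0.01, 2)
    expect_gt(score_genetic(or + d, C, H, cfg)$total,
              score_genetic(or, C, H, cfg)$total)
    f <- 1 + runif(1, 0, 6)
    expect_gt(score_proteomic(f + d, C, H, cfg)$total,
              score_proteomic(f, C, H, cfg)$total)
    expect_gt(score_genetic(or, C + 10, H, cfg)$total,
              score_genetic(or, C, H, cfg)$total)
    expect_gt(score_genetic(or, C, H + 10, cfg)$total,
              score_genetic(or, C, H, cfg)$total)
  }
})

test_that("doubling both C and its reference leaves the citation term unchanged", {
  a <- score_genetic(1.5, 300, 200, scoring_config())
  b <- score_genetic(1.5, 600, 200, scoring_config(c_ref = 2 * 4092))
  expect_equal(a$citation_term, b$citation_term, tolerance = 1e-12)
})

test_that("the metabolomic score with N = n = 1 reduces to the proteomic score", {
  set.seed(14)
  for (rep in 1:20) {
    f <- 1 + rexp(1); C <- sample(0:4000, 1); H <- sample(0:10000, 1)
    expect_equal(score_metabolomic(f, 1, C, H)$total,
                 score_proteomic(f, C, H)$total, tolerance = 1e-12)
  }
})

test_that("config validation rejects bad weights and references", {
  expect_error(scoring_config(w_effect = 0.5), "sum to 1")
  expect_error(scoring_config(f_ref = -1), "positive")
  f <- tempfile(fileext = ".yaml")
  write_scoring_config(scoring_config(), f)
  expect_equal(read_scoring_config(f), scoring_config())
})

test_that("multi-platform resolution picks max by default, priority otherwise", {
  target <- data.frame(uniprot_id = "P1", gene_symbol = "G1",
                       platforms = "genetics|proteomics",
                       linked_changed_metabolites = "",
                       n_changed_metabolites = 0L,
                       total_linked_metabolites = 0L)
  bundle <- list(
    gwas = data.frame(gene_symbol = "G1", odds_ratio = 3.7 * 0.6 / 0.33),
    proteomics = data.frame(uniprot_id = "P1",
                            fold_change = 2.37 * 0.4 / 0.33),
    metabolites = data.frame(metabolite_id = character(0),
                             fold_change = numeric(0)))
  s_max <- score_target(target, bundle)
  expect_equal(s_max$platform_used, "genetics")
  expect_equal(s_max$total, 0.6, tolerance = 1e-12)
  s_pri <- score_target(target, bundle, resolution = "priority")
  expect_equal(s_pri$platform_used, "proteomics")
  expect_equal(s_pri$total, 0.4, tolerance = 1e-12)
})

test_that("epigenetics-only targets are unscoreable", {
  target <- data.frame(uniprot_id = "P1", gene_symbol = "G1",
                       platforms = "epigenetics",
                       linked_changed_metabolites = "",
                       n_changed_metabolites = 0L,
                       total_linked_metabolites = 0L)
  bundle <- list(gwas = NULL, proteomics = data.frame(
    uniprot_id = character(0), fold_change = numeric(0)),
    metabolites = data.frame(metabolite_id = character(0),
                             fold_change = numeric(0)))
  expect_error(score_target(target, bundle), "unscoreable")
})

test_that("ranking is total-descending with the internal control fixed at 1", {
  scores <- rbind(
    score_genetic(0.715 * 3.7 / 0.33, 0, 0, uniprot_id = "P20138"),
    score_proteomic(0.438 * 2.37 / 0.33, 0, 0, uniprot_id = "P14174"),
    score_proteomic(1.4, 100, 200, uniprot_id = "P05067"))
  ranked <- rank_targets(scores, internal_control = "P05067")
  expect_equal(ranked$uniprot_id, c("P05067", "P20138", "P14174"))
  expect_equal(ranked$total[1], 1.0)
  expect_true(ranked$is_internal_control[1])
  expect_equal(ranked$total[2:3], c(0.715, 0.438), tolerance = 1e-9)
  expect_equal(ranked$rank, 1:3)
})

test_that("rank ties break accession-alphabetically and duplicates are fatal", {
  scores <- rbind(score_genetic(3.7, 0, 0, uniprot_id = "PB"),
                  score_genetic(3.7, 0, 0, uniprot_id = "PA"))
  ranked <- rank_targets(scores)
  expect_equal(ranked$uniprot_id, c("PA", "PB"))
  expect_equal(ranked$rank, 1:2)
  expect_error(rank_targets(rbind(scores, scores[1, ])), "duplicate")
  empty <- rank_targets(score_genetic(numeric(0)))
  expect_equal(nrow(empty), 0L)
})
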