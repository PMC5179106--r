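toy_links <- data.frame(
  metabolite_id = c("A", "B", "C", "A", "D", "E"),
  uniprot_id = c("P1", "P1", "P1", "P2", "P3", "P3"),
  stringsAsFactors = FALSE)

test_that("the >=2 changed-metabolite filter returns exact n and N counts", {
  res <- suppressWarnings(
    collect_metabolite_proteins(toy_links, c("A", "B", "E"),
                                min_links = 2))
  expect_equal(res$uniprot_id, "P1")
  expect_equal(res$n_changed_metabolites, 2L)
  expect_equal(res$total_linked_metabolites, 3L)
  expect_equal(res$linked_changed_metabolites, "A|B")
})

test_that("min_links = 1 admits every protein with a changed partner", {
  res <- suppressWarnings(
    collect_metabolite_proteins(toy_links, c("A", "B", "E"),
                                min_links = 1))
  expect_equal(res$uniprot_id, c("P1", "P2", "P3"))
  expect_equal(res$n_changed_metabolites, c(2L, 1L, 1L))
  expect_equal(res$total_linked_metabolites, c(3L, 1L, 2L))
})

test_that("no changed metabolites yields an empty table; absent ones warn", {
  res <- collect_metabolite_proteins(toy_links, character(0))
  expect_equal(nrow(res), 0L)
  expect_warning(collect_metabolite_proteins(toy_links, c("A", "B", "ZZ")),
                 "absent")
})

test_that("filter equals a brute-force double loop on random link tables", {
  set.seed(101)
  for (rep in 1:25) {
    links <- random_links(sample(3:50, 1), sample(3:50, 1),
                          sample(5:120, 1))
    changed <- unique(sample(links$metabolite_id,
                             sample.int(nrow(links), 1), replace = TRUE))
    for (min_links in 1:3) {
      got <- suppressWarnings(
        collect_metabolite_proteins(links, changed, min_links))
      want <- brute_collect(links, changed, min_links)
      expect_setequal(got$uniprot_id, c(names(want), character(0)))
      for (p in got$uniprot_id) {
        expect_equal(got$n_changed_metabolites[got$uniprot_id == p],
                     unname(want[[p]]["n"]))
        expect_equal(got$total_linked_metabolites[got$uniprot_id == p],
                     unname(want[[p]]["N"]))
      }
    }
  }
})

test_that("raising min_links never adds a protein", {
  set.seed(202)
  for (rep in 1:10) {
    links <- random_links(20, 20, 60)
    changed <- unique(sample(links$metabolite_id, 15, replace = TRUE))
    prev <- NULL
    for (ml in 1:4) {
      cur <- suppressWarnings(
        collect_metabolite_proteins(links, changed, ml))$uniprot_id
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("assembly takes the union of platforms per accession", {
  prot <- data.frame(uniprot_id = "P1", gene_symbol = "G1",
                     fold_change = 1.5, sample_type = "CSF",
                     pubmed_id = "PM1")
  gwas <- data.frame(gene_symbol = c("G1", "G2"),
                     snp_id = c("rs1", "rs2"),
                     odds_ratio = c(1.2, 1.3), p_value = 1e-8,
                     initial_n = 10L, replication_n = 5L,
                     pubmed_id = "PM")
  map <- data.frame(gene_symbol = c("G1", "G2"),
                    uniprot_id = c("P1", "P2"))
  res <- assemble_targets(genetic = gwas, proteomic = prot,
                          gene_map = map)
  expect_equal(res$uniprot_id, c("P1", "P2"))
  expect_equal(res$platforms, c("genetics|proteomics", "genetics"))
  multi <- multiplatform_targets(res)
  expect_equal(multi$uniprot_id, "P1")
})

test_that("disjoint platforms assemble with no multi-platform targets", {
  gwas <- data.frame(gene_symbol = paste0("G", 1:3),
                     snp_id = paste0("rs", 1:3), odds_ratio = 1.2,
                     p_value = 1e-8, initial_n = 1L, replication_n = 1L,
                     pubmed_id = "PM")
  epi <- data.frame(gene_symbol = paste0("E", 1:3),
                    uniprot_id = paste0("PE", 1:3), direction = "hyper",
                    pubmed_id = "PM")
  prot <- data.frame(uniprot_id = paste0("PP", 1:3),
                     gene_symbol = paste0("H", 1:3), fold_change = 1.5,
                     sample_type = "CSF", pubmed_id = "PM")
  met <- suppressWarnings(collect_metabolite_proteins(
    data.frame(metabolite_id = rep(c("M1", "M2"), 3),
               uniprot_id = rep(paste0("PM", 1:3), each = 2)),
    c("M1", "M2")))
  map <- data.frame(gene_symbol = paste0("G", 1:3),
                    uniprot_id = paste0("PG", 1:3))
  res <- assemble_targets(gwas, epi, prot, met, map)
  expect_equal(nrow(res), 12L)
  expect_equal(nrow(multiplatform_targets(res)), 0L)
  expect_true(all(diff(order(res$uniprot_id)) > 0))
})

test_that("assembly is idempotent and input-order independent", {
  prot <- data.frame(uniprot_id = c("P2", "P1"),
                     gene_symbol = c("G2", "G1"), fold_change = 1.5,
                     sample_type = "CSF", pubmed_id = "PM")
  a <- assemble_targets(proteomic = prot)
  b <- assemble_targets(proteomic = prot[2:1, ])
  expect_identical(a, b)
  # a target on 3 platforms appears once
  gwas <- data.frame(gene_symbol = "G1", snp_id = "rs1",
                     odds_ratio = 1.2, p_value = 1e-8, initial_n = 1L,
                     replication_n = 1L, pubmed_id = "PM")
  epi <- data.frame(gene_symbol = "G1", uniprot_id = "P1",
                    direction = "hyper", pubmed_id = "PM")
  map <- data.frame(gene_symbol = "G1", uniprot_id = "P1")
  res <- assemble_targets(gwas, epi, prot, gene_map = map)
  expect_equal(sum(res$uniprot_id == "P1"), 1L)
  expect_equal(res$platforms[res$uniprot_id == "P1"],
               "epigenetics|genetics|proteomics")
})

test_that("unmapped gene symbols are kept under a placeholder with a warning", {
  gwas <- data.frame(gene_symbol = "ORPHAN", snp_id = "rs1",
                     odds_ratio = 1.2, p_value = 1e-8, initial_n = 1L,
                     replication_n = 1L, pubmed_id = "PM")
  expect_warning(res <- assemble_targets(genetic = gwas), "placeholder")
  expect_equal(res$uniprot_id, "GENE:ORPHAN")
})
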