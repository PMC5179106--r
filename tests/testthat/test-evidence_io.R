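test_that("GWAS tables parse with typed, validated records", {
  f <- tmp_lines(gwas_lines(list(
    c("CD33", "rs3865444", "1.22", "1e-9", "1000", "500", "PM1"),
    c("BIN1", "rs744373", "1.17", "2e-8", "1000", "500", "PM2"),
    c("CR1", "rs6656401", "1.18", "3e-7", "1000", "500", "PM3"))))
  g <- read_gwas(f)
  expect_equal(nrow(g), 3L)
  expect_equal(g$odds_ratio[1], 1.22)
  expect_type(g$initial_n, "integer")
  expect_equal(nrow(attr(g, "rejected")), 0L)
})

test_that("invalid GWAS rows are rejected with row numbers, accepted + rejected = read", {
  f <- tmp_lines(gwas_lines(list(
    c("A", "rs1", "1.2", "1e-9", "10", "5", "PM1"),
    c("B", "rs2", "-0.5", "1e-9", "10", "5", "PM2"),   # bad OR
    c("C", "rs3", "1.1", "1.5", "10", "5", "PM3"),     # bad p
    c("D", "", "1.1", "1e-3", "10", "5", "PM4"))))     # empty snp
  expect_warning(g <- read_gwas(f), "rejected")
  rej <- attr(g, "rejected")
  expect_equal(rej$row, c(2L, 3L, 4L))
  expect_equal(nrow(g) + nrow(rej), attr(g, "n_read"))
})

test_that("duplicate (gene, SNP) rows keep the first occurrence", {
  f <- tmp_lines(gwas_lines(list(
    c("A", "rs1", "1.2", "1e-9", "10", "5", "PM1"),
    c("A", "rs1", "1.9", "1e-9", "10", "5", "PM2"))))
  g <- read_gwas(f)
  expect_equal(nrow(g), 1L)
  expect_equal(g$odds_ratio, 1.2)
})

test_that("tab and comma dialects of the same content parse identically", {
  rows <- list(c("A", "rs1", "1.22", "1e-9", "10", "5", "PM1"),
               c("B", "rs2", "1.10", "1e-6", "20", "9", "PM2"))
  tsv <- read_gwas(tmp_lines(gwas_lines(rows, "\t")))
  csv <- read_gwas(tmp_lines(gwas_lines(rows, ","), ext = ".csv"))
  expect_identical(tsv, csv, ignore_srcref = TRUE)
})

test_that("header-only files give empty tables without error", {
  g <- read_gwas(tmp_lines(gwas_lines(list())))
  expect_equal(nrow(g), 0L)
})

test_that("missing files and unknown columns are fatal with names", {
  expect_error(read_gwas(tempfile()), "not found")
  f <- tmp_lines(c("gene_symbol\tsnp_id\todds_ratio\tp_value\tinitial_n\treplication_n\tpubmed_id\tbogus",
                   "A\trs1\t1.2\t1e-9\t1\t1\tPM1\tx"))
  expect_error(read_gwas(f), "bogus")
  f2 <- tmp_lines(c("gene_symbol\tsnp_id", "A\trs1"))
  expect_error(read_gwas(f2), "odds_ratio")
})

test_that("sub-unity fold ratios normalize to -1/ratio, or are rejected when disabled", {
  f <- tmp_lines(c("uniprot_id\tgene_symbol\tfold_change\tsample_type\tpubmed_id",
                   "P1\tG1\t0.5\tCSF\tPM1",
                   "P2\tG2\t1.4\tCSF\tPM2"))
  expect_warning(p <- read_proteomics(f), "normalized")
  expect_equal(p$fold_change, c(-2.0, 1.4))
  expect_warning(p2 <- read_proteomics(f, normalize = FALSE), "rejected")
  expect_equal(nrow(p2), 1L)
  expect_equal(attr(p2, "rejected")$row, 1L)
})

test_that("proteomic rows must be CSF with magnitude >= 1", {
  f <- tmp_lines(c("uniprot_id\tgene_symbol\tfold_change\tsample_type\tpubmed_id",
                   "P1\tG1\t1.5\tserum\tPM1",
                   "P2\tG2\t1.5\tcsf\tPM2"))
  expect_warning(p <- read_proteomics(f), "rejected")
  expect_equal(p$uniprot_id, "P2")
  expect_equal(p$sample_type, "CSF")
})

test_that("epigenetic directions are validated against the enum", {
  f <- tmp_lines(c("gene_symbol\tuniprot_id\tdirection\tpubmed_id",
                   "ANK1\tQ1\tHyper\tPM1",
                   "BDNF\tP2\tsideways\tPM2"))
  expect_warning(e <- read_epigenetics(f), "rejected")
  expect_equal(e$direction, "hyper")
})

test_that("drug catalog normalizes stages through the synonym map", {
  f <- tmp_lines(c(paste(c("drug_name", "target_uniprot", "stage",
                           "mode_of_action", "original_indication",
                           "source_db"), collapse = "\t"),
                   "D1\tP1\tApproved\tinhibitor\tcancer\tTTD",
                   "D2\tP1\tPhase I/II\tantibody\tcancer\tTTD",
                   "D3\tP2\tPreclinical\tagonist\tcancer\tDrugBank"))
  expect_warning(d <- read_drug_catalog(f), "unmapped stage")
  expect_equal(d$stage, c("approved", "clinical_trial", "experimental"))
})

test_that("modes of action outside the vocabulary fall back to unknown", {
  f <- tmp_lines(c(paste(c("drug_name", "target_uniprot", "stage",
                           "mode_of_action", "original_indication",
                           "source_db"), collapse = "\t"),
                   "D1\tP1\tApproved\tfrobnicator\tcancer\tTTD"))
  expect_warning(d <- read_drug_catalog(f), "vocabulary")
  expect_equal(d$mode_of_action, "unknown")
})

test_that("GMT parsing builds the universe as the union of sets", {
  f <- tmp_lines(c("S1\tdesc\tA\tB\tC",
                   "S2\tdesc\tC\tD\tE\tF\tG"), ext = ".gmt")
  gs <- read_gmt(f)
  expect_length(gs$universe, 7L)
  expect_setequal(gs$sets$S1, c("A", "B", "C"))
  f2 <- tmp_lines("S1\tA", ext = ".gmt")
  expect_error(read_gmt(f2), "line 1")
})

test_that("an explicit universe overrides the union", {
  f <- tmp_lines(c("S1\tdesc\tA\tB"), ext = ".gmt")
  expect_warning(gs <- read_gmt(f, universe = c("A", "X")), "dropped")
  expect_equal(gs$universe, c("A", "X"))
  expect_equal(gs$sets$S1, "A")
})

test_that("SIF export is deterministic and roundtrips", {
  g <- igraph::make_graph(~ M1 - P1, M2 - P1, M1 - P2)
  f <- tempfile(fileext = ".sif")
  write_network(g, f, "SIF")
  lines <- readLines(f)
  expect_equal(lines, c("M1\tlinks\tP1", "M1\tlinks\tP2",
                        "M2\tlinks\tP1"))
  g2 <- read_network(f, "SIF")
  expect_true(igraph::isomorphic(g, g2))
})

test_that("GraphML export roundtrips with node attributes", {
  g <- igraph::make_graph(~ A - B, B - C)
  igraph::V(g)$type <- c("metabolite", "protein", "protein")
  f <- tempfile(fileext = ".graphml")
  write_network(g, f, "GraphML")
  g2 <- read_network(f, "GraphML")
  expect_true(igraph::isomorphic(g, g2))
  expect_equal(igraph::V(g2)$type[match(igraph::V(g)$name,
                                        igraph::V(g2)$name)],
               igraph::V(g)$type)
})

test_that("empty graphs export to an empty SIF and a valid GraphML skeleton", {
  g <- igraph::make_empty_graph(directed = FALSE)
  f1 <- tempfile(fileext = ".sif")
  write_network(g, f1, "SIF")
  expect_equal(length(readLines(f1)), 0L)
  f2 <- tempfile(fileext = ".graphml")
  write_network(g, f2, "GraphML")
  expect_equal(igraph::vcount(read_network(f2, "GraphML")), 0L)
  expect_error(write_network(g, tempfile(), "dot"), "unknown")
})

test_that("isolated nodes survive a SIF roundtrip", {
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, 3, name = c("A", "B", "C"))
  g <- igraph::add_edges(g, c("A", "B"))
  f <- tempfile(fileext = ".sif")
  write_network(g, f, "SIF")
  g2 <- read_network(f, "SIF")
  expect_setequal(igraph::V(g2)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(g2), 1L)
})
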