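# A fixed, seed-free toy bundle with hand-checkable counts: 19 unique
# candidate targets (5 genetic, 6 proteomic, 6 metabolomic, 2
# epigenetic), one internal control (APP, P05067), and a small drug
# catalog in which 13 (target, eligible drug) pairs survive the stage
# filter. Accessions and names follow well-known AD biology (CD33, MIF,
# ACHE, CAD, the cholinergic and glutamate/GABA metabolites) so the
# output tables read naturally, but all numbers are illustrative.

#' Generate the fixed worked-example bundle
#'
#' Deterministic and seed-free: every table is a hand-written literal.
#' Documented counts: 19 assembled targets; the internal control P05067
#' scores exactly 1 both by computation (fold change 2.37, citation and
#' publication counts at the reference constants) and by designation; 13
#' eligible (target, drug) rows survive the approved/clinical-trial
#' stage filter.
#'
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `dir` and `paths` as in
#'   [generate_bundle()].
#' @export
generate_worked_example <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  emit <- function(name, df) {
    p <- file.path(dir, name)
    write_tsv(df, p)
    paths[[sub("[.].*$", "", name)]] <<- p
    p
  }
  emit("gwas.tsv", data.frame(
    gene_symbol = c("CD33", "BIN1", "PICALM", "CR1", "CACNA1G"),
    snp_id = c("rs3865444", "rs744373", "rs3851179", "rs6656401",
               "rs1999527"),
    odds_ratio = c("1.14", "1.17", "1.15", "1.18", "1.20"),
    p_value = c("1.6e-09", "2.6e-14", "2.8e-20", "5.7e-24", "8.0e-06"),
    initial_n = c(74046L, 74046L, 74046L, 74046L, 16000L),
    replication_n = c(25580L, 25580L, 25580L, 25580L, 8000L),
    pubmed_id = c("PM24162737", "PM24162737", "PM24162737", "PM24162737",
                  "PM26830138")))
  emit("proteomics.tsv", data.frame(
    uniprot_id = c("P05067", "P14174", "P00747", "P01009", "P15692",
                   "Q9HCB6"),
    gene_symbol = c("APP", "MIF", "PLG", "SERPINA1", "VEGFA", "SPON1"),
    fold_change = c("2.37", "1.80", "1.50", "1.60", "-1.40", "1.30"),
    sample_type = "CSF",
    pubmed_id = c("PM12771710", "PM18474103", "PM25832815", "PM25832815",
                  "PM21320563", "PM26402520")))
  emit("metabolites.tsv", data.frame(
    metabolite_id = c("HMDB0000097", "HMDB0000895", "HMDB0000148",
                      "HMDB0000112", "HMDB0000161", "HMDB0000191",
                      "HMDB0000687", "HMDB0000517"),
    name = c("choline", "acetylcholine", "glutamate", "GABA", "alanine",
             "aspartate", "leucine", "arginine"),
    fold_change = c("-1.30", "-1.60", "1.90", "-1.50", "1.40", "1.70",
                    "-1.20", "1.50"),
    sample_type = "CSF"))
  # link table: six proteins with >= 2 changed metabolites; lactate
  # (HMDB0000190) and citrulline (HMDB0000904) appear only here, so CAD
  # has N = 4, n = 3 and NOS2 has N = 3, n = 2
  emit("metabolite_protein_links.tsv", data.frame(
    metabolite_id = c("HMDB0000097", "HMDB0000895",
                      "HMDB0000148", "HMDB0000191", "HMDB0000161",
                      "HMDB0000190",
                      "HMDB0000148", "HMDB0000112",
                      "HMDB0000148", "HMDB0000112",
                      "HMDB0000517", "HMDB0000148", "HMDB0000904",
                      "HMDB0000112", "HMDB0000161"),
    uniprot_id = c("P22303", "P22303",
                   "P27708", "P27708", "P27708", "P27708",
                   "Q99259", "Q99259",
                   "Q05329", "Q05329",
                   "P35228", "P35228", "P35228",
                   "P80404", "P80404")))
  emit("epigenetics.tsv", data.frame(
    gene_symbol = c("ANK1", "BDNF"),
    uniprot_id = c("Q01484", "P23560"),
    direction = c("hyper", "hypo"),
    pubmed_id = c("PM25129075", "PM25282492")))
  emit("gene_map.tsv", data.frame(
    gene_symbol = c("CD33", "BIN1", "PICALM", "CR1", "CACNA1G", "APP",
                    "MIF", "PLG", "SERPINA1", "VEGFA", "SPON1", "ACHE",
                    "CAD", "GAD1", "GAD2", "NOS2", "ABAT", "ANK1",
                    "BDNF"),
    uniprot_id = c("P20138", "O00499", "Q13492", "P17927", "O43497",
                   "P05067", "P14174", "P00747", "P01009", "P15692",
                   "Q9HCB6", "P22303", "P27708", "Q99259", "Q05329",
                   "P35228", "P80404", "Q01484", "P23560")))
  # APP carries the reference counts, so its computed score is exactly 1
  # even before the internal-control designation
  emit("pathogenesis.tsv", data.frame(
    uniprot_id = c("P20138", "P14174", "P22303", "P05067", "P00747",
                   "P01009", "P15692", "Q9HCB6", "O00499", "Q13492",
                   "P17927", "O43497", "P27708", "Q99259", "Q05329",
                   "P35228", "P80404", "Q01484", "P23560"),
    role = c("GOF", "GOF", "GOF", "GOF", "GOF", "GOF", "LOF", "unknown",
             "GOF", "LOF", "GOF", "GOF", "GOF", "LOF", "LOF", "GOF",
             "LOF", "unknown", "LOF"),
    citation_count = c(350L, 280L, 1200L, 4092L, 150L, 120L, 200L, 0L,
                       180L, 160L, 140L, 90L, 60L, 110L, 85L, 210L, 75L,
                       40L, 310L),
    publication_count = c(420L, 150L, 2600L, 11294L, 90L, 80L, 160L,
                          10L, 210L, 140L, 130L, 60L, 25L, 95L, 70L,
                          240L, 50L, 30L, 580L)))
  emit("drug_catalog.tsv", data.frame(
    drug_name = c("Gemtuzumab ozogamicin", "Lintuzumab", "Imalumab",
                  "Donepezil", "Rivastigmine", "Galantamine",
                  "Physostigmine", "Edrophonium", "ELND005",
                  "GW274150", "L-NIL", "Bevacizumab", "Ethosuximide",
                  "Tranexamic acid"),
    target_uniprot = c("P20138", "P20138", "P14174", "P22303", "P22303",
                       "P22303", "P22303", "P22303", "P05067", "P35228",
                       "P35228", "P15692", "O43497", "P00747"),
    stage = c("Approved", "Phase II", "Phase I", "Approved", "Approved",
              "Approved", "Approved", "Approved", "Phase II",
              "Phase II", "experimental", "Approved", "Approved",
              "Approved"),
    mode_of_action = c("antibody", "antibody", "antibody", "inhibitor",
                       "inhibitor", "inhibitor", "inhibitor",
                       "inhibitor", "inhibitor", "inhibitor",
                       "inhibitor", "antibody", "blocker", "inhibitor"),
    original_indication = c("acute myeloid leukemia",
                            "acute myeloid leukemia", "solid tumors",
                            "Alzheimer's disease", "Alzheimer's disease",
                            "Alzheimer's disease", "glaucoma",
                            "myasthenia gravis", "Alzheimer's disease",
                            "inflammation", "inflammation", "cancer",
                            "epilepsy", "bleeding"),
    source_db = c("TTD", "TTD", "TTD", "DrugBank", "DrugBank",
                  "DrugBank", "DrugBank", "DrugBank", "TTD", "TTD",
                  "TTD", "DrugBank", "TTD", "TTD")))
  gmt <- c(paste(c("Alanine, aspartate and glutamate metabolism",
                   "KEGG-style toy set",
                   "CAD", "GAD1", "GAD2", "ABAT", "NOS2", "ASS1",
                   "ASL"), collapse = "\t"),
           paste(c("Cholinergic synapse", "KEGG-style toy set",
                   "ACHE", "CHAT", "CHRM1", "SLC5A7"), collapse = "\t"),
           paste(c("Complement and coagulation cascades",
                   "KEGG-style toy set",
                   "PLG", "CR1", "SERPINA1", "F2", "C3"),
                 collapse = "\t"))
  gmt_path <- file.path(dir, "pathways.gmt")
  writeLines(gmt, gmt_path, useBytes = TRUE)
  paths$pathways <- gmt_path
  # small protein-protein interaction edge list (String-style export)
  emit("ppi_edges.tsv", data.frame(
    node1 = c("CAD", "CAD", "CAD", "CAD", "GAD1", "APP", "APP"),
    node2 = c("GAD1", "GAD2", "ABAT", "NOS2", "GAD2", "MIF", "PLG"),
    combined_score = c(900L, 850L, 700L, 650L, 800L, 400L, 550L)))
  invisible(list(dir = dir, paths = paths))
}
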