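Package: adrepo
Title: Multi-Omics Target Prioritization and Drug Repositioning for
    Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates curated multi-omics evidence (genome-wide
    association studies, epigenetics, cerebrospinal-fluid proteomics and
    metabolomics) into a unified list of candidate anti-Alzheimer drug
    targets, scores and ranks the targets with a weighted-sum model
    anchored to internal-control reference constants, maps targets to
    approved and clinical-trial drugs with a gain-/loss-of-function
    compatibility rationale, builds metabolite-protein and
    protein-protein interaction networks with hub detection, and performs
    hypergeometric pathway over-representation testing with
    Benjamini-Hochberg correction. Ships a seeded synthetic-data
    generator with planted ground truth so the full pipeline is testable
    without any database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
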