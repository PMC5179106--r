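# adrepo

Multi-omics target prioritization and drug repositioning for
Alzheimer's disease (AD).

Drug development for AD is slow and failure-prone; repositioning —
redirecting approved or clinical-trial drugs to a new indication —
shortcuts much of that risk. `adrepo` is for computational biologists
who have curated omics evidence tables (GWAS associations, epigenetic
events, CSF proteomic changes, metabolite changes with an HMDB-style
metabolite–protein link table) and want a tested, reproducible pipeline
that turns them into a ranked list of candidate anti-AD targets and a
shortlist of mechanistically plausible drugs.

## The model

Every candidate target is scored on one evidence platform with a
weighted sum of three normalized criteria:

```
TS = w_e * effect/effect_ref + w_c * C/C_ref + w_h * H/H_ref
```

where *effect* is the odds ratio OR (genetics, reference 3.7, the
APOE-ε4 odds ratio), the fold-change magnitude |F| (proteomics,
reference 2.37, the CSF Aβ42 fold change), or — for metabolomics — the
imputed fold change `(Σ|F_i| + N − n)/N` averaged over all N linked
metabolites with the N − n unchanged ones counted as 1; C is the
citation count of the target's pathogenesis paper (reference 4092) and
H the count of publications linking target and disease (reference
11294), both APP anchors. Weights default to 0.33/0.34/0.33. A target
with all evidence at the references scores exactly 1, the value the
internal control (APP) is pinned to; scores are not capped above 1.

Around the score sit: candidate assembly with the ≥2-changed-metabolite
inclusion rule, a bipartite metabolite–protein network with hub
detection, a stage filter keeping approved/clinical-trial drugs, a
GOF/LOF-versus-mode-of-action compatibility call, and hypergeometric
pathway over-representation with Benjamini–Hochberg correction. A
seeded generator emits complete synthetic input bundles with planted
ground truth. See `vignettes/target-ranking.Rmd` for the full design.

## Worked example

The package ships a deterministic, hand-written toy bundle of 19
candidate targets (five genetic, six proteomic, six metabolomic, two
epigenetic) with familiar AD names — CD33, MIF, ACHE, CAD, the
cholinergic and glutamate/GABA metabolites — and a 14-row drug catalog:

```r
library(adrepo)
w   <- generate_worked_example("example_bundle")
res <- run_pipeline(pipeline_config("example_bundle", "example_out",
                                    internal_control = "P05067"))
head(res$ranked[, c("uniprot_id", "platform_used", "effect_term",
                    "citation_term", "publication_term", "total",
                    "rank")], 5)
#>   uniprot_id platform_used effect_term citation_term publication_term total rank
#> 1     P05067    proteomics       0.330       0.34000          0.33000 1.000    1
#> 2     P22303  metabolomics       0.202       0.09971          0.07597 0.378    2
#> 3     P14174    proteomics       0.251       0.02326          0.00438 0.278    3
#> 4     Q99259  metabolomics       0.237       0.00914          0.00278 0.249    4
#> 5     Q05329  metabolomics       0.237       0.00706          0.00205 0.246    5
```

The internal control APP (P05067) carries the reference fold change and
counts, so its computed score is exactly 1 and it anchors rank 1. The
known anti-AD target acetylcholinesterase (P22303) ranks second from
its two changed cholinergic metabolites, and MIF (P14174), elevated in
AD CSF, third. The drug join keeps the 13 approved/clinical-trial rows
on annotated targets:

```r
res$summary[1:3, c("uniprot_id", "rank", "n_drugs", "n_approved",
                   "n_clinical_trial", "n_compatible")]
#>   uniprot_id rank n_drugs n_approved n_clinical_trial n_compatible
#> 1     P05067    1       1          0                1            1
#> 2     P22303    2       5          5                0            5
#> 3     P14174    3       1          0                1            1
tail(res$log, 3)
#> [1] "targets scored: 17 of 19"
#> [2] "repositioning candidates: 13 drug rows on 8 targets"
#> [3] "enrichment: 3 pathways with overlap, 0 significant at 0.05"
```

All five ACHE inhibitors are compatible (GOF target + inhibitor); the
two epigenetics-only targets remain in the candidate list but are
unscored, and the one anti-VEGFA antibody is flagged incompatible with
its LOF role. For a full-scale synthetic run use
`generate_bundle(generator_config(seed = 7), "bundle_dir")` and point
`run_pipeline()` at it; a thin command-line wrapper lives at
`inst/cli/adrepo.R` (`simulate`, `example`, `run` subcommands).

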