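---
title: "Multi-omics target ranking and drug repositioning: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics target ranking and drug repositioning: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrepo)
```

## The problem

Candidate drug targets for Alzheimer's disease (AD) surface from four
kinds of curated evidence: genetic associations (GWAS odds ratios),
epigenetic events (differential DNA methylation), cerebrospinal-fluid
(CSF) proteomic changes, and metabolite changes mapped to the proteins
that produce, consume or transport them. `adrepo` integrates these
evidence tables into one candidate-target list, scores every target on a
common scale, and joins the ranked targets to a drug catalog to propose
repurposing candidates whose mode of action is mechanistically
compatible with the target's disease role.

## The weighted-sum target score

Each target is scored on a single evidence platform with a weighted sum
of three normalized criteria:

$$
TS \;=\; w_e \,\frac{\text{effect}}{\text{effect}_{ref}}
      \;+\; w_c \,\frac{C}{C_{ref}}
      \;+\; w_h \,\frac{H}{H_{ref}}
$$

* **effect** — the strength of the target–disease association on the
  platform's own scale: the per-allele odds ratio $OR$ (genetics), the
  fold-change magnitude $|F|$ between AD cases and controls
  (proteomics), or an imputed fold change (metabolomics, below).
* **C** — citations of the publication establishing the target's role in
  AD pathogenesis (a proxy for the quality of the pathogenesis
  evidence).
* **H** — publications linking the target to AD (a proxy for the
  confidence of the association).

The references anchor the scale to the best-established AD protein:
$\text{effect}_{ref}$ is the CSF A$\beta_{42}$ fold change 2.37 for
fold-change effects and the *APOE*-$\varepsilon4$ odds ratio 3.7 for
genetic effects; $C_{ref} = 4092$ and $H_{ref} = 11294$ are the APP
citation and publication counts. The default weights are
$w_e = 0.33$, $w_c = 0.34$, $w_h = 0.33$ exactly as stated (not 1/3),
and configurable through `scoring_config()`. A target whose evidence
sits exactly at the references scores exactly 1 — the same value the
internal control (APP) is pinned to during ranking — and scores are
deliberately *not* capped: evidence stronger than the references yields
scores above 1.

### Metabolomic imputation

A protein implicated only through metabolomics has no measured fold
change. If the protein is linked to $N$ metabolites of which $n$
changed with magnitudes $|F_1|,\dots,|F_n|$, the imputed fold change is
the mean magnitude over all $N$ linked metabolites, counting unchanged
ones as 1:

$$
\hat F \;=\; \frac{\sum_{i=1}^{n} |F_i| + (N - n)}{N}.
$$

This is the "assume the other linked metabolites did not change"
reading of the adjustment: with $N = n = 1$ the metabolomic score
reduces exactly to the proteomic score of that metabolite's fold
change, a reduction the test suite asserts. $N$ counts *all* link-table
partners of the protein, not only changed ones; the imputation is
undefined (and fatal) at $n = 0$.

### Platform resolution and ranking

Proteins implicated by several scoreable platforms are reported with a
single platform score. The default resolution keeps the maximum score
(ties broken by platform name); a `"priority"` rule preferring
proteomics > genetics > metabolomics is available, and the chosen
platform is always recorded in the output. Where several GWAS
associations tag one gene, the strongest (maximum) odds ratio is used —
the combination rule is otherwise unstated in the literature this
models. Epigenetic evidence has no score equation; it contributes
platform membership only, and epigenetics-only targets are reported
unscored.

`rank_targets()` orders by total descending with accession-ascending
tie-breaks and assigns dense ranks from 1. The designated internal
control is set to exactly 1 and flagged; this is a designation, not a
computation, so the control's stored term decomposition is left as
computed.

## Candidate assembly and the ≥ 2-metabolite rule

Metabolomic evidence admits a protein only when it links to at least
two *distinct* changed metabolites (`min_links = 2`; duplicate link
rows collapse). The assembled candidate table is keyed by UniProt
accession; gene symbols are display metadata, with a user-supplied
symbol-to-accession map for the gene-reporting platforms (GWAS,
epigenetics). A symbol with no mapping is retained under a
`GENE:<symbol>` placeholder with a warning rather than silently
dropped — which gene a multi-gene locus tags is the data supplier's
call, not the pipeline's.

## Drug repositioning logic

Only approved and clinical-trial drugs survive the stage filter;
free-text stages normalize through an extensible YAML synonym map, with
unmapped labels falling back to `experimental` (plus a warning).
Compatibility pairs the target's gain-/loss-of-function (GOF/LOF) role
with the drug's mode-of-action class: inhibiting modes (inhibitor,
antagonist, antibody, blocker, suppressor) are compatible with GOF
targets; activating modes (agonist, activator, inducer, stimulator)
with LOF targets; opposite pairings are incompatible; an unknown on
either side, or a neutral mode (substrate, binder, ...), yields
`unknown`. The class partition ships as editable YAML
(`inst/extdata/moa_classes.yaml`). A drug with several modes of action
on one target yields one row per mode, each with its own compatibility
call. Targets lacking pathogenesis information are excluded from the
drug join by default but stay in the ranked list as future targets.

## Networks and enrichment

The metabolite–protein graph is undirected, simple and strictly
bipartite; proteins linked to ≥ 2 changed metabolites carry a node flag
(the highlighted class of such network figures). Protein–protein
interaction networks are read from String-style edge exports (two node
columns plus a combined score rescaled from 0–1000 to [0, 1]); no
confidence cutoff is applied by default because none is claimed —
`min_score` is an explicit knob. Hubs are nodes with degree ≥ 10 by
default, the neighbor count of the CAD hub that motivates the
definition; there is no formal hub criterion in the source material.

Pathway over-representation uses the exact hypergeometric upper tail
$P(X \ge k)$ with Benjamini–Hochberg correction ("Benjamini corrected"
is read as the BH step-up, the default of the David tool this step
replaces). Two choices are deliberate: the universe defaults to the
union of all GMT sets (overridable by an explicit universe file, since
the original background is unstated), and the BH adjustment runs across
*all* pathways in the collection — every pathway is a performed test —
with zero-overlap rows dropped from the report afterwards. Note that BH
is not idempotent: re-adjusting an adjusted vector inflates non-tied
values again, so the tests assert the step-up's actual guarantees
(adjusted ≥ raw, capped at 1, monotone on sorted input) against an
independently coded oracle rather than a fixed-point property.

## The synthetic-data generator

`generate_bundle()` emits every input table with planted ground truth
so the whole pipeline is testable without database downloads. The
background laws emulate the field's typical values: odds ratios
lognormal($\log 1.15$, $0.15$) (small GWAS effects, heavy right tail
toward the APOE reference), fold magnitudes $1 + \text{Exp}(0.6)$
below the A$\beta_{42}$ reference scale, citation and publication
counts discrete power laws truncated at the APP references, and
metabolite link degrees Poisson (mean 3) deduplicated to a simple
bipartite graph. Defaults: 500 targets, 150 metabolites, 250 drugs,
5 planted targets with every component multiplied by `plant_boost = 3`,
8 deliberately multi-platform targets (echoing the handful of
two-platform proteins such studies report).

Two guarantees are enforced by construction rather than left to
chance. First, each planted target keeps a complete evidence trail:
metabolomics-planted targets link to dedicated boosted metabolites, and
every planted target receives at least one approved or clinical-trial
drug with a compatible mode of action. Second, planted dominance: after
sampling, any background target whose implied score exceeds 90% of the
lowest planted score is deterministically shrunk (linear rescale of its
evidence above the minimal-evidence baseline). Without this the heavy
background tails would routinely outscore a weakly-drawn planted
genetics target (a typical boosted odds ratio of ~3.5 yields an effect
term near 0.31, below the ~0.33 ceiling of a strong background
proteomic fold change), making planted recovery a coin flip that tests
nothing. With the guarantee, a failed recovery isolates a defect in
assembly, scoring or ranking. The recovery test runs the full
read–assemble–score–rank path over 100 seeds at 500 targets each and
requires all planted targets in the top 10 ranks in at least 95 seeds.

What the generator does **not** emulate: linkage structure among SNPs,
real metabolite chemistry or pathway structure, drug pharmacology
beyond the stage/mode vocabularies, and correlated evidence across
platforms. Passing tests therefore demonstrate the pipeline's
correctness on structurally faithful inputs, not biological validity of
any particular ranking on real data.

## Numerical and formatting choices

* Effect, citation and publication terms are computed as
  `weight * (value / reference)` — ratio first — so evidence exactly at
  a reference contributes exactly `weight` and the control identity
  `0.33 + 0.34 + 0.33 == 1` holds to the last bit in double arithmetic.
* Fold-change ratios in (0, 1) are normalized to $-1/r$ on read
  (optional, on by default, warned); stored magnitudes are always ≥ 1
  with sign carrying direction, and the scores use magnitudes only.
* All user-facing orderings use radix (C-locale) sorting, and emitted
  numerics are formatted with fixed precision, so identical seeds give
  byte-identical files across platforms and locales.
* Degenerate inputs are first-class: header-only tables parse to empty
  records, empty graphs export to valid files, empty candidate joins
  write empty outputs, and the pipeline completes on all of them.
* Row validation is total: every input row is either accepted or
  reported with its row number and reason (`rejected` attribute), and
  accepted + rejected always equals rows read.

## Known limitations

The headline counts of the study this design follows (hundreds of
AD-related proteins, specific drug/target tallies) depended on 2016
snapshots of HMDB, TTD, DrugBank, PubMed and KEGG and on manual
curation; they are logged by the pipeline for comparison but are not
reproducible from shipped data and are not asserted anywhere. Citation
and publication counts are time-varying and must be supplied by the
user for real runs. The GOF/LOF compatibility call is a coarse
mechanistic screen, not a pharmacological assessment.
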