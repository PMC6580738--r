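# crcevo

Multiregion evolutionary analysis of colitis-associated colorectal cancer
(CA-CRC) in R.

Patients with long-standing colitis develop colorectal cancer through a
distinctive route: somatic mutations accumulate in the inflamed,
non-dysplastic mucosa (a "field" from which the tumour later arises), and
the step from low-grade to high-grade dysplasia is often marked by an abrupt
burst of chromosomal copy-number change rather than gradual accrual.
`crcevo` provides the analysis toolkit for multiregion sequencing studies of
this process, for analysts working with per-patient mutation tables and
allele-specific copy-number segments from several biopsies per patient
(mucosa, dysplasia grades, carcinoma regions).

## What it computes

* **SNA phylogenies** — maximum-parsimony trees over mutation
  presence/absence rooted at an all-absent germline outgroup; exhaustive
  topology enumeration up to seven regions, stepwise addition + NNI beyond;
  per-character Fitch change counts, consistency/homoplasy index
  (HI = 1 − CI), column-bootstrap clade support with the blank/`+`/`++`
  banding, and gains-only driver annotation onto branches with a convergence
  flag.
* **Clonality and field statistics** — truncal / shared-subclonal / private
  classification, the fraction of truncal mutations shared with mucosa
  (field overlap), SNAs/Mb burden with a hypermutation flag, cancer cell
  fractions from VAF, purity and local copy number, convergent multi-hit
  gene detection, TP53 DNA-binding-domain (aa 102–292) classification, and
  per-gene cohort frequency tables with meta-analysis pooling.
* **Mutational signatures** — 96-channel trinucleotide catalogues
  (pyrimidine-centred, purine calls reverse-complemented) fitted by
  active-set non-negative least squares, `R² = 1 − SS_res/SS_tot`, overall
  and partitioned into field / truncal / branch epochs.
* **Copy-number burden** — percent genome altered with and without
  copy-neutral LOH against a diploid baseline, ploidy classes, arm-level
  calls, and cohort comparisons (Fisher exact + Benjamini–Hochberg per arm
  and direction; Kruskal–Wallis + pairwise Mann–Whitney across lesion
  grades).
* **Copy-number phylogenies** — 500-kbp binned integer copy states,
  ordered-cost (Sankoff, |a−b|) parsimony trees rooted at a diploid
  reference, bootstrap support, and a punctuation ratio
  (trunk changes / mean within-clade branch changes) that separates
  punctuated from gradual copy-number evolution.
* **Synthetic cohorts** — a generator with known clone trees,
  signature-driven SNAs, arm/focal/burst CNA events and a binomial VAF noise
  model, so every estimator above can be validated against ground truth.
* **Exact statistics** — self-contained Fisher exact 2×2
  (point-probability two-sided rule), exact Mann–Whitney U (complete
  enumeration for n ≤ 12), tie-corrected Kruskal–Wallis, and
  Benjamini–Hochberg, all cross-checked against enumeration oracles.

## Worked example

```r
library(crcevo)

## a synthetic patient: mucosa + LGD + HGD + 3 carcinoma regions,
## 200-bin copy-number burst at the LGD -> HGD transition
sp <- simulate_patient(sim_params(), seed = 42, patient_id = "UC_demo")

cm   <- build_character_matrix(sp$calls, sp$samples)
tree <- bootstrap_support(cm, B = 100, seed = 1)
tree
#> Maximum-parsimony tree (exhaustive search): 7 leaves, score 218, HI = 0.000
#>   bootstrap support attached

roles <- setNames(sp$samples$tissue_class, sp$samples$sample_id)
cl <- classify_clonality(cm, roles)
table(cl$cancer_pattern, useNA = "ifany")
#>          private shared_subclonal          truncal             <NA>
#>               63               22               79               54
field_overlap_fraction(cl)
#> [1] 0.2025316

fit_by_epoch(sp$calls, cl, example_signatures())$truncal
#> Signature fit over 59 mutations; R2 = 0.820
#>   SigA: 60.7%
#>   SigB: 28.3%
#>   SigC: 10.9%

binned <- bin_profiles(sp$segments, synthetic_genome())
punctuation_profile(cna_tree(binned), roles)$punctuation_ratio
#> [1] 6.296296
```

Reading the output: the parsimony tree is homoplasy-free (HI = 0, as it must
be for single-clone biopsies without noise beyond dropout), 79 mutations are
truncal and ~20% of them are shared with the mucosa (the mutational field),
the truncal epoch is dominated by the ageing-like bundled signature with a
good fit (R² = 0.82), and the copy-number tree has a trunk ~6× longer than
its in-clade branches — the punctuated pattern (under the no-burst control
this ratio drops to ~1).

`run_patient()` / `run_cohort()` orchestrate all stages from one
configuration and write TSV/newick/JSON-manifest outputs; a thin
command-line front end lives at `inst/cli/crcevo.R`
(`simulate`, `run`, `stats` subcommands).

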