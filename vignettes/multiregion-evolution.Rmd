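---
title: "Methods: multiregion evolutionary analysis of colitis-associated colorectal cancer"
author: "crcevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiregion evolutionary analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcevo)
```

# Scope

`crcevo` reconstructs the evolutionary history of colitis-associated
colorectal cancer (CA-CRC) from multiregion sequencing of one patient's
biopsies — non-dysplastic mucosa, low- and high-grade dysplasia (LGD, HGD)
and several carcinoma regions — and aggregates those reconstructions at
cohort level. The pipeline has five analytical stages (maximum-parsimony SNA
phylogenies, clonality/field classification, 96-channel mutational-signature
deconvolution, copy-number burden and arm-level statistics, and binned
copy-number phylogenies with a punctuation statistic), plus a synthetic
cohort generator that provides ground truth for every stage. Raw read
alignment, variant calling and copy-number segmentation are out of scope:
mutation tables and allele-specific segments are inputs.

# SNA phylogenies by maximum parsimony

Per patient, mutation calls are binarised into a samples-by-mutations
presence/absence matrix (`build_character_matrix()`); a mutation is present
in a sample when a call with VAF at or above the detection threshold
(default 0.05) exists. An all-absent germline row roots every tree: somatic
evolution starts from the non-mutated state.

`search_mp_tree()` minimises the number of character changes. Characters are
unweighted, unordered and binary; indels are included as characters even
though they are excluded from signature tallies. For up to seven in-group
samples all rooted topologies are enumerated (for `k` samples there are
`(2k-3)!!`, i.e. 10,395 at `k = 7`), which is exact and still fast because
identical character columns are collapsed to weighted patterns before Fitch
scoring. Beyond seven samples the search is random-order stepwise addition
followed by nearest-neighbour-interchange (NNI) hill climbing with 20 random
restarts. The NNI walk accepts strict improvements and up to 12 consecutive
sideways (equal-score) moves to unvisited topologies; without plateau moves
the landscape of small binary matrices has observable local optima. Rooted
NNI on the in-group tree is exactly unrooted NNI on the full tree with the
germline pendant, so the walk covers the standard neighbourhood.

Ties among equally parsimonious trees are resolved deterministically to the
lexicographically smallest canonical newick (children sorted recursively by
label). Branch lengths are the changes assigned by a deterministic
most-parsimonious reconstruction: the Fitch backtrack that keeps the parent
state whenever the child's state set allows it. For binary characters rooted
in the ancestral state this rule is unique and change-minimal; we prefer it
to ACCTRAN-style acceleration, which for binary data either requires
arbitrary choices or inflates change counts.

Fit quality is summarised by the consistency index CI = sum(m_i)/sum(s_i)
(minimum over observed changes) and the homoplasy index HI = 1 - CI; HI = 0
exactly when the matrix is compatible with the tree.

Bootstrap support (`bootstrap_support()`) resamples characters with
replacement, rebuilds the tree per replicate with identical settings, and
reports the percentage of replicates containing each original clade, banded
for display as blank (>95), `+` (65–95) and `++` (<65). The default is
B = 1000 for reports; the examples and tests use smaller B because the
quantity of interest there is the banding, not the third digit.

Driver annotation (`annotate_branches()`) places each driver-gene mutation
on the root edge of every maximal clade whose leaves all carry it. This is a
gains-only reconstruction: somatic point mutations do not revert, so a
reconstruction with a loss (which unrestricted parsimony sometimes prefers,
since gain+loss and gain+gain can tie) would be biologically misleading.
More than one gain edge means convergent acquisition and is flagged.

# Clonality, field and burden

Within a patient, a mutation is **truncal** when present in all carcinoma
regions, **shared subclonal** in two or more but not all, **private** in
exactly one; presence in non-dysplastic mucosa is tracked independently
(`in_mucosa`), and the per-patient field statistic is the fraction of
truncal mutations also found in mucosa (`field_overlap_fraction()`), the
quantitative signature of a mutational field from which the cancer arose.

Mutation burden is the non-synonymous count divided by the callable exome
footprint; the footprint default (34.7 Mb) is a configuration value chosen
to be consistent with cohort-scale burdens around 3 SNAs/Mb for ~100
non-synonymous calls, and should be set to the actual capture footprint
when known. A burden of 10 SNAs/Mb or more flags a sample as hypermutated
(MSI-like); this is a proxy classification — dedicated MSI assays are out of
scope — but it cleanly separates burdens near 3/Mb from the 30+/Mb regime
of mismatch-repair deficiency.

Cancer cell fractions use the standard diploid-normal mixture model:
`vaf = purity * mult / (purity * cn_total + 2 (1 - purity))`, inverted for
CCF with multiplicity rounded into `[1, cn_major]`. Reported CCFs are capped
at 1 with the raw value retained. Convergent genes are those with at least
two distinct non-synonymous mutations at CCF >= 0.8 ("near-clonal"; the
cut-off is a design choice exposed as a parameter). TP53 mutations are
classified by the DNA-binding domain window, amino acids 102–292 inclusive.

# Mutational signatures

Catalogues are 96-vectors over the pyrimidine-centred trinucleotide
channels; purine-centred calls are reverse complemented, indels and
unknown-context calls are skipped and counted. Exposures solve the
non-negative least-squares problem `min ||c - S e||, e >= 0` by the
active-set (Lawson–Hanson) algorithm, which is deterministic for fixed
input. Goodness of fit is `R^2 = 1 - SS_res/SS_tot`; the total sum of
squares is mean-centred by default, with an uncentred alternative, because
R-squared conventions for non-negative fits differ between tools and the
choice materially changes the number. Both absolute exposures (mutation
units) and relative contributions are reported. Signature subsets are
caller-specified: no automatic model selection is attempted.

Epoch-partitioned fits (`fit_by_epoch()`) split mutations into **field**
(present in mucosa — the precancer compartment), **truncal** (clonal in the
carcinoma, absent from mucosa) and **branch** (subclonal + private), and fit
each catalogue independently, allowing a change in process activity at the
precancer/cancer and clonal/subclonal boundaries to be read off directly.

The bundled `example_signatures()` are three near-orthogonal synthetic
processes (C>T-at-CpG-heavy, flat T>A/T>C, C>A/C>G-heavy). They caricature
ageing-like and damage-like processes but are *not* COSMIC signatures; a
real reference matrix can be supplied through `read_signature_matrix()`.

# Copy-number burden

Copy states are called against an absolute diploid-heterozygous baseline:
gain (`total > 2`), loss (`total < 2`), copy-neutral LOH (`total = 2`,
`minor = 0`). The absolute baseline (rather than sample-ploidy-relative) is
deliberate: near-tetraploid genomes should and do count as extensively
altered, matching how percent-genome-altered coexists with frequent
triploid/tetraploid states in this disease. A ploidy-relative mode would
hide exactly the genome doublings of interest. Percent genome altered is
reported with (`pga_full`) and without (`pga_gl`) cnLOH; low-pass profiles
cannot resolve cnLOH, so there `pga_full = pga_gl` and the result is
flagged. Ploidy is the length-weighted mean copy number with class bins
[1.6, 2.4) near-diploid, [2.6, 3.4] near-triploid, [3.6, 4.4]
near-tetraploid; the bin edges are this package's choice since the
categories are conventionally reported without thresholds.

Arms are defined by the centromere in the genome layout; an arm is called
gained/lost/cnLOH when at least half its length (configurable) is in that
state, with gain/loss taking precedence over cnLOH. Sex chromosomes are
excluded by default. Cohort arm-frequency comparisons run a 2x2 Fisher test
per arm and direction with Benjamini-Hochberg correction across all tests;
per sample, arms under 10% segment coverage are excluded.

# Copy-number phylogenies and punctuation

Profiles are binned into fixed 500-kbp windows; each bin takes the
length-weighted majority total copy number, ties resolved to the state
closer to diploid and then lower (so an exactly split 1/3 bin is called 1).
Bins uncovered in any sample are dropped from all. Trees are maximum
parsimony over these integer characters with ordered (Wagner) cost
`|a - b|`, scored by the Sankoff algorithm and rooted at a synthetic diploid
leaf; a 2 to 4 jump therefore costs two changes, consistent with sequential
single-copy events. An unordered mode (any change costs 1) is provided for
sensitivity, since the underlying event model is not observable; genome
doublings make the ordered cost an overcount, which is one reason the
punctuation statistic below uses a ratio rather than raw change counts.
Search, tie-breaking and bootstrap mirror the SNA engine.

`punctuation_profile()` quantifies the contrast between punctuated and
gradual copy-number evolution: `trunk_changes` (total change between the
attachment of the LGD lineage and the most recent common ancestor of the
HGD/carcinoma clade) divided by the mean branch length inside that clade
(floored at 1 change to keep the ratio finite). A burst of copy-number
change at the LGD to HGD transition that then stabilises gives a long trunk
and short in-clade branches — ratios far above 1 — while ongoing instability
gives ratios near 1. A single-sample clade makes the within-clade mean a
single leaf branch and is flagged low-confidence.

# Statistical machinery

The tests the pipeline relies on are implemented in the package with fully
pinned conventions, because their edge-case behaviour (two-sided rules, tie
handling) varies between implementations:

* **Fisher's exact 2x2** — two-sided p by the point-probability rule (sum of
  hypergeometric probabilities not exceeding the observed table's, with
  relative tolerance 1e-7); degenerate margins give p = 1.
* **Mann-Whitney U** — exact two-sided p by complete enumeration of group
  assignments for combined n <= 12 (ties handled by 1/2 counts); beyond
  that, normal approximation with tie correction and 0.5 continuity
  correction.
* **Kruskal-Wallis** — tie-corrected H on a chi-square with k-1 df.
* **Benjamini-Hochberg** — step-up q-values capped at 1.

Each is cross-checked in the test suite against base R and against
brute-force enumeration.

# The synthetic cohort generator

The generator exists because the study design it emulates is observational:
there is no public generative model, so every distributional choice here is
a documented stand-in, chosen once to reproduce the qualitative architecture
of multiregion CA-CRC data, and the defaults define the package's standard
study conditions.

* **Clone tree**: germline -> field ancestor (mucosa attaches here) ->
  truncal ancestor (LGD attaches) -> HGD ancestor -> a pectinate carcinoma
  subtree. Default regions: 1 mucosa, 1 LGD, 1 HGD, 3 carcinomas.
* **SNA counts** are Poisson per branch with means field 12, truncal 50,
  LGD-to-HGD 8, HGD-to-carcinoma 7, shared carcinoma branches 15, private
  leaf branches 20. These give long trunks and long, roughly equal branches,
  and a truncal-in-mucosa overlap of 12/77 (about 16%), the architecture
  reported for this disease.
* **Signature mixtures** are per epoch (precancer/truncal/branch) over the
  bundled three-signature set, defaulting to ageing-dominated mixtures that
  drift modestly across epochs.
* **CNAs**: Poisson arm-level gains/losses/cnLOH per branch (means 0.5, 0.5,
  0.25), 5 focally drifted bins per branch in runs of up to 5, and a
  punctuated burst of exactly 200 bins in contiguous runs of 20-60 on the
  LGD-to-HGD branch (disable with `punctuated_burst_bins = 0` for a gradual
  control). Copy number is tracked per 500-kbp bin, so emitted segments are
  bin-aligned and `bin_profiles()` recovers the simulated states exactly.
* **Observation model**: `vaf = purity * mult / (purity * cn_total +
  2 (1 - purity))` with multiplicity fixed at 1, binomial read sampling at
  depth 100, purity 0.7, and a 0.05 detection threshold. Noise enters only
  as dropout — there are no false-positive calls — and mutations on
  fully-deleted loci are lost.
* **Genome**: 22 autosomes at 10% of human scale (lengths and centromeres
  rounded to 500 kbp), i.e. 577 usable bins — numerous enough for arm-level
  structure, small enough that a full cohort simulates in seconds.

What the generator deliberately does **not** emulate: subclonal mixing
within a biopsy (each region is one clone), false-positive calls, multiplicity
above 1, selection, spatial growth, and sequencing artefacts. Passing the
recovery tests therefore shows the estimators are correct under a clean
clonal model, not that they are robust to every failure mode of real data.

# Problem sizes, determinism and limitations

The test-suite and acceptance analyses use deliberately compact problem
sizes — patients of six regions (the exhaustive-search regime), oracle
sweeps of 50-100 random 4-6 leaf matrices, 100-200 simulation seeds,
1000-mutation catalogues — chosen so the whole validation runs in minutes
while every comparison is still against an exact oracle (full enumeration,
brute-force per-base counting, or closed form). All stochastic steps are
seeded; identical inputs give bit-identical outputs, including the tie-break
rule for equally parsimonious trees.

Known limitations: parsimony trees treat each biopsy as one clone, so
heavily admixed biopsies violate the model; the CNA tree's ordered cost
over-counts changes across genome doublings; the MSI flag is a burden proxy;
the punctuation ratio depends on correct grade labels; and with fewer than
three in-group samples no tree is built (the remaining stages still run).
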