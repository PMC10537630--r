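---
title: "Methods: chemotype enrichment and imbalance-aware QSAR modeling for micronucleus endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemotype enrichment and imbalance-aware QSAR modeling for micronucleus endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

The micronucleus (MN) assay detects chromosome damage: in vitro in cultured
cells, in vivo in rodent erythrocytes. Building classification models for
these endpoints faces three recurring obstacles: noisy, duplicated chemical
records; strong class imbalance (MN in vitro collections tend to run around
70% positive, in vivo collections around 30% positive); and the need to
connect model predictions back to interpretable structural features.
`mnqsar` implements a complete pipeline for this setting:

1. record curation (standardization, salt stripping, neutralization,
   InChIKey deduplication with explicit conflict policies);
2. featurization (descriptor battery, MACCS / path / circular
   fingerprints, chemotype SMARTS fingerprints, correlation prefiltering,
   GA subset selection);
3. chemotype enrichment statistics (2x2 tables, odds ratios, one-sided
   Fisher exact tests, rule-based set-level prediction, cross-endpoint
   relevance tiers);
4. imbalance handling (inverse-frequency class weights, from-scratch
   SMOTE);
5. modeling (RF / SVM / XGB with inner grid search, stratified
   shuffle-split cross-validation, Butina cluster splits, majority-vote
   ensembling).

A synthetic-data module generates datasets with the statistical structure
the analysis assumes, so every stage is testable without proprietary assay
data.

# Curation rules

`standardize_structure()` applies, in order: polymer rejection (wildcard
atoms), SMILES parsing (OpenBabel), salt stripping (fragments without
carbon are discarded), the mixture rule (two or more carbon-containing
fragments remaining is a mixture), the metal rule, charge neutralization,
and InChIKey generation.

Design choices that were genuinely open:

* **Metal definition.** Any element outside H, B, C, N, O, F, Si, P, S,
  Cl, Se, Br, I counts as a metal. Organosilicon compounds are therefore
  retained — the common organic-subset convention in QSAR work. A
  metal-bearing species without an organic parent (e.g. cisplatin, which
  has no carbon) is classed organometallic; carbon-free, metal-free
  species are inorganic.
* **Identity.** The full 27-character InChIKey is used, so tautomers and
  stereoisomers with distinct keys are treated as distinct compounds. The
  14-character skeleton would merge them; nothing in the curation
  contract requires that, and the stricter key is reversible downstream.
* **Conflicts.** Duplicate records with conflicting labels are either
  dropped (`exclude_conflicts`, the default) or resolved toward the
  record marked guideline-compliant when exactly one is
  (`prefer_compliant`). Both policies log every affected record, so
  record conservation (input = curated + rejected + conflicting + merged)
  holds exactly and is asserted in the tests.

# Enrichment statistics

For a chemotype *c* and binary labels, the 2x2 table counts TP (carries
*c*, positive), FP (carries *c*, negative), FN, TN. The association
statistic is the odds ratio

$$\mathrm{ODDs} = \frac{TP \cdot TN}{FN \cdot FP},$$

with `Inf` when only the denominator vanishes and an undefined marker
(never enriched) when both products vanish; a Haldane +0.5 correction is
available but off by default since the plain ratio is the reference
formulation. Significance is the one-sided Fisher exact test in the
enrichment direction — the exact hypergeometric upper tail
$P(X \ge TP)$ with both margins fixed, no approximation. The default
filter is ODDs ≥ 3 and p < 0.05; the significance threshold is a plain
parameter (`enrichment_thresholds(p_max = 0.5)` reproduces the much
looser cut occasionally seen in screening practice).

PPV is implemented as $TP/(TP+FP)$ — the fraction of chemotype carriers
that are active. (A formulation sometimes printed as $(TP+TN)/TP$ is
unbounded and inconsistent with percentage-scale use; we document the
discrepancy and use the standard definition.) Cross-endpoint relevance
tiers cut PPV at 0.70 (high) and 0.50 (moderate above, poor at or below
0.50 — the moderate band is open on both sides, so the boundary value
0.50 falls to poor).

No multiple-testing correction is applied across chemotypes; the
workflow is a screening filter, and its false-flag rate under
independence is measured directly by the planted-signal tests below.

# Featurization

* **Descriptors.** `compute_descriptors()` produces a ~110-column
  1D/2D battery: OpenBabel physicochemical properties (MW, exact mass,
  logP, molar refractivity, TPSA, H-bond donor/acceptor counts), element
  / hybridization / ring / rotatable-bond counts, functional-group
  counts, counts of the bundled chemotype set, and substructure
  fractions (counts normalized by heavy atoms). The battery is smaller
  than the ~200-descriptor sets of some toolkits but spans the same
  physicochemical-plus-substructure-fraction design, and it is fully
  deterministic.
* **Prefiltering** removes constants, columns with sd below 0.5, and one
  member of every pair with squared Pearson correlation above 0.9. The
  dropped member is the one with the larger original column index — an
  arbitrary but deterministic rule; the survivor set provably contains
  no offending pair, which the tests assert by full pairwise scan.
* **Fingerprints.** MACCS uses the 166 public keys (OpenBabel's
  RDKit-derived SMARTS definitions; the key *i* ↔ bit *i* mapping was
  verified against the reference tool). The path fingerprint is the
  Daylight-style hashed linear-path fingerprint (paths to 7 atoms),
  native length 1024 with optional power-of-two fold-down. Circular
  fingerprints (ECFP/FCFP-style; diameter naming maps ECFP4 to radius 2)
  are computed natively on the connection table: iterated neighborhood
  hashing of atom invariants (element, heavy degree, bond-order sum,
  implicit H count, ring membership for ECFP; donor / acceptor /
  aromatic-like / halogen / charge roles for FCFP), hashed into 1024 or
  2048 bits. Ring membership comes from bridge detection (an edge on a
  cycle is not a bridge); the aromatic-like FCFP role is "in a ring and
  engaged in a double bond", an approximation adequate for hashed
  similarity features though not a full aromaticity perception.
* **GA selection** is a conventional generational GA (tournament
  selection, set-based uniform crossover, per-gene mutation, elitism 1)
  over fixed-size subsets, with fitness the mean inner-CV AUC of a
  random forest on the candidate subset. Defaults (population 50,
  30 generations, crossover 0.7, mutation 0.05, 5 inner folds) are
  conventional since no reference settings exist; everything is a
  `ga_config()` parameter and the search is seed-reproducible.

# Balancing

`class_weights()` uses $w_c = n / (2 n_c)$, equalizing weighted class
masses. `smote_resample()` is a from-scratch SMOTE: each synthetic point
is $x_i + u (x_{nn} - x_i)$ with $u \sim U(0,1)$ and $x_{nn}$ one of the
k = 5 Euclidean nearest minority neighbors; synthetic points are appended
until the minority/majority ratio reaches `target_ratio`. How far to
resample is a genuine modeling choice rather than a fixed convention, so
`target_ratio` is a first-class parameter defaulting to 1 (full
balance). Binary fingerprints are interpolated in
real space and left unrounded by default, preserving the algorithm's
definition; rounding to {0,1} is available. Balancing always happens
inside the training portion of a fold, never before splitting.

# Modeling

Cross-validation follows the stratified shuffle-split reading of
"ten-fold 90/10 validation": 10 independent stratified random 90/10
splits (per class, `round(0.1 n_c)` compounds to validation), rather
than a disjoint decade partition; a disjoint-partition helper exists for
inner loops. Hyperparameters come from an exhaustive inner grid search
scored by mean inner-fold AUC, ties broken by grid order. The Butina
split clusters compounds by the leader algorithm on Tanimoto distance of
radius-2/2048-bit circular fingerprints (cutoff 0.4) and assigns whole
clusters to one side, so near-duplicates never straddle the split.

The ensemble combines members (each its own feature block, balancing and
learner) by majority vote. Ties go to positive — a precautionary choice
for a hazard endpoint, exposed as the ensemble's `tie_rule`. A vote
ensemble emits labels, not scores, so no AUC is reported for it; member
AUCs use the rank (Wilcoxon) form, ties counted half.

# Synthetic data: what it emulates and what it does not

`generate_feature_dataset()` draws exact class counts and independent
Bernoulli chemotype bits at class-conditional prevalences; the implied
odds ratio of a planted feature is
$\frac{p_+(1-p_-)}{(1-p_+)p_-}$. An `exclusive` mode plants at most one
chemotype per compound (multinomial), which is the clean construction
when several chemotypes need independently controlled cross-endpoint
PPVs. `generate_molecule_dataset()` assembles valid SMILES from a
template grammar — alkyl backbone (2-5 carbons), branch fragments
(carbamate, nitroso, sulfonic ester, aziridine, quinone, alkyl halide,
plus inert decorations), optional ring scaffold — so planted SMARTS
content is guaranteed and every record survives curation.
`generate_paired_endpoints()` shares one compound set between two label
vectors and draws carrier labels in endpoint B at the target PPV,
filling non-carriers to B's class balance (erroring when the targets are
unattainable).

The generator reproduces the statistical skeleton of curated MN
datasets — imbalance, alert-driven activity, paired endpoints — but not
real chemical space: no property-matched decoys, no scaffold diversity
beyond the grammar, no assay noise structure beyond optional label
flips. The grammar also produces occasional duplicate structures, which
the curation stage merges (a n = 800 draw typically curates to roughly
500 unique compounds); that is deliberate, as it exercises
deduplication on realistic collision rates. Passing tests on these data
demonstrate correctness of the statistics and the absence of leakage,
not performance on real chemicals.

# Problem sizes and numerical choices

The test-suite and reproduction-script workloads were sized to make the
binomial margins decisive: enrichment recovery uses n = 1000 compounds
over 100 seeds (a 30%/5% planted chemotype has a generating odds ratio
near 8.1, far above the flag threshold of 3); tier recovery uses
n = 2000 over 100 seeds, where a per-chemotype carrier count near 300
puts the PPV standard error around 0.03, several standard errors inside
each tier band. The end-to-end demonstration plants carbamate and
nitroso at 55% prevalence in positives versus 3% in negatives on 800
molecules — a strong alert-driven regime (roughly 80% of positives carry
at least one alert) whose Bayes AUC ceiling, computed from the
generating model, is about 0.87; cross-validated member AUCs of 0.85-0.90
and shuffled-label AUCs near 0.5 are therefore the expected outcome.

Numerical conventions worth stating: Fisher p-values use the exact
hypergeometric tail (enumeration-checked to 1e-9); odds ratios encode
degenerate tables as `Inf`/`NaN` rather than applying a silent
correction; SMOTE nearest-neighbor ties break by index order; the
enrichment table sorts by descending odds then ascending p; and all
stochastic components (generators, splits, SMOTE, GA, learners) are
seed-controlled and reproduce bit-identically.

# Known limitations

* Neutralization relies on OpenBabel's model; fixed charges (quaternary
  N) are correctly retained, but exotic charge patterns may pass through
  unneutralized rather than being rejected.
* The FCFP-style role assignment approximates aromaticity and ignores
  formal charge on neutralized parents.
* The descriptor battery is deterministic and reproducible but not
  numerically identical to any other toolkit's battery; models trained
  on it are not transferable to descriptors computed elsewhere.
* The rule-based set-level classifier treats enriched chemotypes as
  exchangeable alerts; no weighting by effect size is attempted.
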