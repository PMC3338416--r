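---
title: "Differential screening and virtual target profiling: models and design choices"
author: "diviss package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential screening and virtual target profiling: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`diviss` implements a chemocentric route to cancer-target discovery: a
large compound library is screened for cytotoxicity on a tumor cell line
(HCT116-like) and a normal cell line (MRC-5-like); compounds that kill the
tumor line at least five times more potently than the normal line — and the
converse set — are profiled *in silico* against a panel of ligand-based
protein models; the difference between the two predicted target sets
(targets hit only by tumor-selective compounds) is the candidate cancer
target list, which is then prioritized by oncogene probability
(OncoScore), protein family composition, drug polypharmacology and pathway
membership.

The pipeline runs as six stages: `simulate` (optional, synthetic
campaign), `screen`, `fit`, `select`, `profile`, `differential`, under one
seed and one YAML configuration (`run_pipeline()`, `validate_config()`).

# Screening model and plate quality control

Viability is a control-anchored normalization of the raw fluorescence
signal,

$$ v = 100\,\frac{\mathrm{raw} - \mu_n}{\mu_p - \mu_n}, $$

where $\mu_p,\mu_n$ are the positive (untreated) and negative (background)
control means of the well's plate. Values outside $[0,100]$ are preserved,
never clipped — they carry QC signal. Plate quality is the standard
Z' factor, $Z' = 1 - 3(\sigma_p+\sigma_n)/|\mu_p-\mu_n|$ (Zhang, Chung &
Oldenburg 1999), together with the signal-to-background ratio
$\mu_p/\mu_n$. Z' is invariant under positive affine rescaling of the
signal, and so are all downstream hit calls.

A compound is a cytotoxic hit when its replicate-averaged viability at the
screening concentration (50 µM) is **at or below 20%** — the threshold is
inclusive by contract.

# Dose-response fitting and selectivity

Curves use the logistic (Hill) law
$v(c) = 100/(1 + (c/\mathrm{IC}_{50})^h)$ with bottom and top fixed at 0
and 100 and slope $h \in [0.3, 5]$. Six points in duplicate cannot support
four free parameters stably, so only $\mathrm{IC}_{50}$ and $h$ are free;
the fit is bounded least squares on $(\log_{10}\mathrm{IC}_{50}, h)$ with
a coarse grid start followed by L-BFGS-B. Replicates enter as individual
points. When the per-concentration mean viability never falls below 50%,
or the fitted midpoint lies above the top tested concentration, the result
is **censored** and reported as a bound (`> 50 µM`), never extrapolated.

The selectivity ratio is $R = \mathrm{IC}_{50}(\text{normal}) /
\mathrm{IC}_{50}(\text{tumor})$. Classes partition $(0,\infty)$:
$R \ge 5$ `tumor_strong` (inclusive), $2 \le R < 5$ `tumor_moderate`,
$0.5 < R < 2$ `unselective`, $0.2 < R \le 0.5$ `normal_moderate`,
$R \le 0.2$ `normal_strong`; a censored tumor IC50 is `NT`. A censored
normal line yields a lower bound $R \ge C_{\max}/\mathrm{IC}_{50}$
(tumor), classified by the bound itself — the bound can only understate
tumor selectivity.

**Dynamic range.** A consequence of refusing extrapolation: with
$C_{\max} = 50$ µM, a five-fold ratio is only resolvable (exactly or via
the censored bound) when the tumor IC50 is at most $C_{\max}/5 = 10$ µM.
Recovery tests therefore measure IC50 error over the whole tested range
[0.1, 25] µM but plant classification pairs inside the resolvable regime
[0.1, 10] µM; outside it, no bound-reporting method can see the planted
ratio.

# Chemotypes and library expansion

Compounds are clustered by Bemis–Murcko framework: iteratively pruning
degree-≤1 atoms leaves the ring systems plus their linkers, canonicalized
as the scaffold key; acyclic molecules are their own singleton chemotype.
The enrichment of a cluster is the fraction of its *tested* members that
were tumor-selective; untested members never change the score. Clusters
with enrichment **strictly above 20%** contribute their untested members
to the expansion set, complemented by a greedy MaxMin diversity pick
(Euclidean distance in SHED space; deterministic start at the compound
with maximal summed distance, ties by id, so selections nest:
$S_k \subset S_{k+1}$).

# Descriptors, target models and affinity prediction

Atoms carry pharmacophore features: donor (N/O with H), acceptor (N/O not
positively charged), positive/negative formal charge, hydrophobic (carbon
with no N/O neighbor), aromatic. Three 2D descriptor spaces of decreasing
fuzziness are built on the 21 unordered feature pairs:

* **SHED** — per pair, the Shannon entropy (bits) of the topological
  shortest-path distance distribution between atoms carrying the two
  features (distances capped at 10); a 21-vector, Euclidean metric.
* **FPD** — the normalized distance histograms themselves (bins 1–10,
  longer paths pooled), concatenated to a 210-vector, Euclidean metric.
* **PHRAG** — the bag of length-3 feature-label sequences along shortest
  paths, compared by multiset Jaccard distance.

All three depend only on the molecular graph, hence are invariant under
atom renumbering (tested by round-tripping randomized SMILES).

A target model is the ensemble of descriptors and pAct values
($-\log_{10}$ molar activity) of its known ligands, with a per-space
**applicability radius**: by default the 95th percentile of the ensemble's
nearest-neighbor distances, where a neighbor distance is the smallest
*positive* distance (exact duplicates are not informative neighbors);
targets whose ensemble is degenerate (one ligand, or all duplicates) fall
back to the pooled median nearest-neighbor distance — a degenerate
ensemble is maximally tight, so the typical spacing, not the pooled upper
tail, is the right default. Radii are fully configurable and logged.

Prediction is inverse-distance weighting over in-domain references:
$\hat p = \sum_i d_i^{-2} p_i / \sum_i d_i^{-2}$; an exact descriptor
match returns the mean pAct of the matching references; no neighbor means
no prediction (outside the applicability domain). Predictions are always
bounded by the neighbors' pAct range. The three spaces are fused
permissively: a target is reported if any space predicts, at the maximum
predicted pAct — the reading consistent with hit expansion. Profiles are
filtered at pAct ≥ 6 (1 µM or better, inclusive) before set comparison.

# Differential analytics

`venn_partition()` splits the tumor- and normal-profile target sets into
tumor-unique / shared / normal-unique. Composition percentages are counts
over the set size rounded to integers; OncoScore prioritization keeps
targets **strictly above** 0.7 (unscored targets stay in denominators, as
an explicit NA category); drug ranking keeps drugs with **more than** 5
qualifying targets at pAffinity ≥ 6, binned [6,7), [7,8), [8,9), [9,∞);
pathway analysis reports raw membership counts, not enrichment
statistics. Each comparison edge (inclusive vs strict) is fixed at its
operation and tested there.

# The synthetic campaign generator

No machine-readable compound or screening data accompanies the study this
package models, so the generator is a first-class module that emulates the
campaign's *statistical shape*:

* **Structures** come from a fixture grammar of 40 scaffolds × 38
  substituents with `{R1}`/`{R2}` attachment slots; every combination is
  chemically valid by construction.
* **Targets** (default 20 cancer, 10 normal-toxicity, 10 housekeeping)
  each own a scaffold, a *pharmacophore anchor* substituent present in
  every ligand and active, and a small pool of feature-light (alkyl /
  halogen) secondary decorations. The anchor design is what makes
  applicability domains discriminating with descriptors this fuzzy:
  intra-ensemble variation is peripheral and cheap in descriptor space,
  while foreign chemotypes differ in both scaffold and anchor. Cancer
  targets sit on aromatic scaffolds, normal-toxicity targets on saturated
  ones — mirroring the observed structural separation between the two
  selective sets.
* **Activities**: a compound's cellular IC50 derives from its planted
  binding potency and the target's cell-line relevance weight,
  $\mathrm{IC}_{50} = 10^{6-\mathrm{pAct}} \cdot s / w$ µM with shift
  $s = 10$ (one log unit between binding and cellular potency) and
  $w \in [0,1]$; cancer targets have tumor weight 1 and small normal
  weights, so their actives are tumor-selective by construction.
  Roles are drawn per compound: 13.9% cytotoxic, of which 10.7%
  tumor-selective and 10.1% normal-selective — the campaign's observed
  rates. Tumor-selective compounds are assigned to cancer targets
  round-robin, so every planted target is covered whenever there are at
  least 20 selective compounds.
* **Plates**: positive controls at 50,000 AU (CV 10%), negative at 5,000
  AU (CV 5.6%), giving S/B ≈ 10 and Z' ≈ 0.65 — between the reported
  screening (0.58) and validation (~0.72) figures. Viability noise is a
  single additive Gaussian (default sd 5%).
* **Dose-response**: 50 µM top, 3-fold dilution, 6 points, duplicates;
  the 3-fold factor is this package's choice (top concentration and point
  count are reported facts, the factor is not).

What the generator does **not** emulate: medicinal-chemistry realism of
structures, serum-masking effects (noise is one Gaussian term), plate
position effects, cell-biology mechanisms beyond the Hill law, or the
scale of the real chemogenomics databases (40 targets × 15 ligands rather
than 4,643 × ~300). Passing tests therefore demonstrate that the
*analysis* recovers what was planted under the campaign's statistical
conditions — not that the descriptors would discriminate targets on real
pharmacology.

# Numerical choices and degenerate inputs

* Potencies live on the pAct scale internally; µM/nM conversion happens
  only at I/O boundaries (`potency_to_plog()` is exact to 1e-12 on
  round-trip).
* Compound identity is canonical SMILES, computed at read time; gene and
  target symbols are upper-cased for matching.
* Duplicate (ligand, target) affinities aggregate by maximum pAct.
* Degenerate plates (equal control means) and unparseable structures are
  errors or counted rejections, never silent.
* Fit non-convergence returns a censored result flagged
  `converged = FALSE`.
* MaxMin ties break by compound id; all orderings in outputs are
  deterministic, making pipeline reruns byte-identical.

# Problem sizes used by the test suite

Module tests run on a shared 300-compound campaign; the end-to-end check
runs the full pipeline on 2,000 compounds with 20 planted cancer targets
and requires at least 80% of them to land in the tumor-unique list; IC50
recovery uses 200 noisy curves (5% viability noise, median relative error
below 20%); the IDW oracle comparison covers 100 randomized cases at
1e-9. These sizes keep the whole suite under a couple of minutes while
leaving every statistical check comfortably powered.

# Known limitations

* The SHED/FPD/PHRAG variants here are fully specified replacements with
  the published designs' intent (three fuzziness levels over feature
  pairs), not reproductions of the original implementations.
* The Murcko-framework chemotype stands in for the study's (uncited in
  detail) clustering method.
* Bound-reporting censoring cannot reproduce headline selectivity folds
  that required extrapolated normal-line IC50s (e.g. several-hundred-fold
  claims from a 50 µM range); such compounds classify `tumor_strong` via
  the bound, with the fold reported as a bound.
* Pathway overlap counts depend entirely on the supplied GMT; no
  statistical enrichment is computed, by design.
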