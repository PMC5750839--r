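---
title: "Gaussian shape and pharmacophore target fishing with shapefish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian shape and pharmacophore target fishing with shapefish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapefish)
```

## The problem

Given a bioactive compound, which proteins might it bind? shapefish answers
this by ligand-based reverse virtual screening ("target fishing"): the
query's 3D structure is superimposed onto every ligand of a curated,
target-annotated ligand database, and targets are nominated by their most
similar template ligand. The working axiom is that structurally similar
compounds tend to share targets. No receptor structure or docking is
involved, so predictions are available even where no experimental protein
structure exists; conversely everything rests on the quality of the ligand
database and on the 3D similarity measure.

## Shape model

Every heavy atom $i$ (hydrogens never enter the shape mathematics) is
represented by a spherical Gaussian density

$$ g_i(\mathbf r) = p \exp\!\left(-\alpha_i \lVert \mathbf r - \mathbf c_i
\rVert^2\right), \qquad
\alpha_i = \frac{\pi\,(3p/4\pi)^{2/3}}{R_i^2}, $$

with the prefactor fixed at $p = 2.7$ (configurable) and $\alpha_i$ chosen
so the Gaussian integrates exactly to the atom's hard-sphere volume
$\tfrac43\pi R_i^3$. Radii $R_i$ are Bondi van der Waals radii; an unknown
element falls back to 1.70 Å with a warning. The overlap of two atomic
Gaussians has the closed form

$$ O_{ij} = p_i p_j \left(\frac{\pi}{\alpha_i+\alpha_j}\right)^{3/2}
\exp\!\left(-\frac{\alpha_i\alpha_j}{\alpha_i+\alpha_j} d_{ij}^2\right), $$

and the molecular overlap is the *first-order* (pairwise-only) weighted sum
$O_{AB} = \sum_{i\in A}\sum_{j\in B} w_i w_j O_{ij}$. Higher-order product
terms (triple and beyond intersections) are never evaluated; the per-atom
weights are the sole correction for the overcounting they would have
removed. Similarity is reported as the shape Tanimoto
$T = O_{AB}/(O_{AA}+O_{BB}-O_{AB}) \in [0,1]$.

### Weights

The default weight rule is

$$ w_i = \frac{v_i}{v_i + \lambda \sum_{j \neq i} O_{ij}}, $$

with $v_i$ the single-Gaussian (= hard-sphere) volume and the sum running
over the atom's intramolecular neighbours. Weights depend only on
intramolecular distances, so they are rotation-invariant and computed once
per conformer, never during alignment. The correction factor $\lambda$
defaults to **0.65**. The naive inclusion–exclusion value 0.5 compensates
each pairwise overlap exactly once, which is right for isolated atom pairs
but leaves the multiply-overlapped interior of ring systems over-counted by
10–13%. $\lambda$ was therefore calibrated once against voxelized
hard-sphere union volumes (0.05 Å voxels) over a 20-molecule set of bonded
chains, rings and fused-sphere systems; at 0.65 the weighted first-order
volume $\sum_i w_i v_i$ stays within ±3.7% of the union volume across the
whole set, and this calibration is locked in as a package test. The scheme
is pluggable (`weight_scheme = "unit"` turns weighting off).

## Pharmacophore features

The "static" similarity channel types atoms and groups into six
conventional feature classes — donor, acceptor, cation, anion, hydrophobe,
aromatic — using a versioned rule file
(`system.file("extdata", "feature_rules.tsv", package = "shapefish")`).
Each rule pairs a feature type with a named graph-pattern detector
(N/O–H donors, N/O acceptors, pH-7.4 ionizable amine/carboxylate groups
without any pKa model, aromatic ring centroids, centroids of apolar carbon
groups). Features are idealized points: fixed 1.0 Å radius, unit weight,
the same Gaussian closed form as atoms, and only same-type pairs overlap.
The ruleset version is carried into every feature model and run sidecar, so
results always cite the typing scheme that produced them. Directional
features and excluded volumes are out of scope.

## Alignment and the three scores

Poses are rigid: a unit quaternion plus translation applied to the moving
molecule (conformational flexibility is handled upstream by scoring every
conformer of a multi-conformer ensemble, never by torsional optimization).
Three matching modes exist:

* **shape** — maximize $O_{AB}$;
* **feature** — maximize the same-type feature overlap;
* **combo** — maximize the sum of the two overlaps, each normalized by the
  mean of its two self-overlaps so neither scale dominates. The reported
  combo score is the arithmetic mean of the shape and feature Tanimotos at
  the combo-optimal pose. Featureless molecules make combo fall back to
  shape; *feature* mode instead refuses them by name.

Each conformer pair starts from four deterministic inertial orientations
(weighted-volume centroids superposed, principal axes aligned, the four
proper sign combinations), optionally plus seeded random restarts. From
each start a BFGS search driven by the analytic overlap gradient (pair
constants are precomputed, so each evaluation only recomputes distances)
runs until relative objective gains drop below 1e-6 or 200 iterations; the
line search accepts only improving steps, so the objective is monotone
across iterations, and the quaternion is renormalized at the end. A search
that fails or does not improve returns its start pose unchanged. The best final
pose by the mode's score wins; ties below 1e-9 go to lower conformer
indices, then earlier starts — which also implements the preference for
experimentally determined template conformers, because database conformers
are ordered experimental-first.

Degenerate cases: single-atom molecules get a translation-only start;
zero-self-overlap models are an error; scores are clamped to $[0,1]$
against floating-point drift.

## Database curation

Raw inputs are a multi-record SDF (multi-conformer via repeated records
sharing a `LIGAND_ID` tag, per-record `SOURCE` = experimental/generated)
plus TSV tables of activities and target metadata. Activity values are
normalized to micromolar at ingest (`nM`, `uM`, `M` accepted). Curation
then applies, in order:

1. drop activities whose UniProt accession is not in the user-supplied
   valid-accession list (no web service is consulted);
2. keep only the largest connected fragment of each ligand (counter-ion
   stripping — a modification, not a drop; ties by heavy atoms, then
   molecular weight, then first occurrence);
3. drop activity records with potency worse than the cutoff — strictly
   greater than 50 µM by default, so a record at exactly 50 µM survives;
4. drop ligands with fewer than 6 heavy atoms or molecular weight above
   1000 Da, both measured after stripping (the filter order follows the
   curation list order; whether size filters precede stripping is not
   observable for the shipped generators, which plant no undersized
   fragments inside salts).

Duplicate (ligand, target, type) records keep the most potent value and are
counted. The curation report reconciles exactly — input = kept + dropped at
both the ligand and the activity level — and `report_reconciles()` asserts
it. The persisted layout carries a manifest with layout version and md5
checksums; loading verifies both.

## Fishing

`fish_targets()` scores every ligand, discards evidence below the
similarity threshold (default 0.6 — templates below it are considered to
show low similarity to the query) and (ligand, target) pairs whose best
recorded potency is worse than the activity threshold (any positive value;
10, 20 and 50 µM are the conventional settings). A target's score is the
maximum over its surviving templates — the natural reading of ranking
targets "by score" when one score per target is reported — and ranking is
score-descending with UniProt-accession tie-break. When one template
ligand supports several predicted targets the co-ranked predictions carry
no extra meaning; the `shared_evidence` flag surfaces this instead of
hiding it. Exports are a `predictions.tsv`, a `run.json` sidecar (mode,
thresholds, rule version, seed) and per-target SDFs with the query posed by
the winning transform next to the template in its original frame, so
re-scoring the exported pose reproduces the reported score.

## Synthetic fixtures

`make_fixture_database()` plants a fully synthetic study: each target owns
a scaffold family (chain or ring core of a distinct size plus fixed
heteroatom decorations), members differ by Gaussian coordinate jitter
(σ = 0.1 Å by default) and torsion-perturbed extra conformers, and
activities are drawn log-uniformly over [0.001, 100] µM so both the 50 µM
curation filter and the 10/20/50 µM tailoring have events on either side.
Defaults are 5 targets × 5 ligands with seed 1337. Everything is derived
from one seed and the generated files are byte-identical across runs.

What the generator does *not* emulate: force-field-quality geometry,
realistic pharmacophore density, activity cliffs, or the scale (hundreds of
thousands of ligands) of a production bioactivity database. Passing the
planted-recovery tests therefore demonstrates that the machinery ranks a
genuinely similar scaffold first under noise — not that real-world recovery
rates reach any particular level.

## Numerical choices and problem sizes

* Distance cutoff: overlap terms with exponent below −27.6 (terms under
  ~1e-12 of their prefactor) are skipped in database scans; an exact
  cutoff-free mode backs the oracle comparisons.
* Grid oracles: product-density Riemann sums at 0.1 Å (overlap) and voxel
  counting at 0.05 Å (union volumes); Gaussian Riemann sums converge to
  machine precision at these steps, so the 1% comparison band is dominated
  by the closed form, not the oracle.
* Verification sizes were chosen to exercise every claim at small scale: a
  20-molecule calibration set, 50 random rigid transforms per molecule for
  invariance, 100 random poses for the gradient check, a 5 × 5 planted
  database with 20 held-out queries for recovery.
* All randomness flows through explicit seeds; fixture generation restores
  the caller's RNG state.

## Known limitations

Rigid-body scoring cannot rescue a badly wrong input conformer; supply
conformer ensembles for flexible queries. The pharmacophore scheme is
deliberately small (six types, no directionality, rule-list ionization).
Activity cliffs — large potency changes from small structural edits — are a
structural blind spot of every similarity-based method, this one included.
Ring perception uses spanning-tree fundamental cycles, adequate for simple
mono- and fused-ring systems but not for bridged polycycles.
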