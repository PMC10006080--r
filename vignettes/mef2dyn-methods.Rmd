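---
title: "Models and methods behind mef2dyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mef2dyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mef2dyn)
```

mef2dyn analyses how the dynamics of a short alternatively spliced segment —
the acidic β-domain of the MEF2D transcription factor, residues 286–292 in
full-protein (UniProt Q14814) numbering — propagate to ensemble structure,
condensate behaviour and transcriptional output. This vignette explains each
stage's model, its assumptions, the tunable parameters, and the design
choices made where the procedure was genuinely open.

## Residue numbering

Two frames coexist: full-protein numbering (the β-domain is 286–292) and
peptide-local numbering for the 37-residue construct spanning residues
265–301 (full 265 ↔ peptide 1). `map_numbering()` converts between them;
every function documents which frame it expects. Windows are 1-based and
inclusive on both ends.

## Variant design

Per-residue probability profiles — disorder in the free state
(p~D~), disordered binding (p~DD~), droplet-promoting propensity
(p~DP~) — are *inputs*, produced by external predictors; the package never
re-implements those models. A deliberately crude charge/hydropathy
surrogate (`toy_profile_predictor()`) exists only so end-to-end tests can
run from bare sequence; its absolute values are meaningless.

The β-domain is summarised by arithmetic window means, variants by
mutant-minus-wild-type deltas of those means. Classification rules:

* **order/disorder**: disordered iff mean p~D~ ≥ 0.3085, the published
  decision boundary of the disorder predictor. The boundary is inclusive.
* **dynamics class**: similar when |Δp~D~| < ε, mobile when Δp~D~ ≥ ε,
  rigid when Δp~D~ ≤ −ε. The similar/mobile/rigid grouping is qualitative in
  origin; ε defaults to 0.05 (half the smallest window effect the designed
  variant families display on this scale) and is configurable.
* **droplet landscape**: the signed perpendicular distance of
  (MBM, p~DP~) to the identity diagonal decides liquid-favoring (above) vs
  solid-favoring (below), with a ±0.05 band (normalized units) called
  "boundary" because points described as *at* the diagonal are exactly the
  ones able to switch between material states. How MBM is quantified on
  that axis is not fixed by any published normalization; when no scalar
  coordinate is supplied the package uses the window's fraction of
  MBM-flagged residues, which is bounded in [0, 1] by construction and
  reduces to 0/1 for unflagged/fully flagged windows.

Ranking uses decreasing |Δp~D~| — magnitude, not signed value, since the
design goal was variants with the *largest* dynamic perturbation in either
direction — with |Δp~DP~| as tie-breaker and input order as the final,
deterministic tie rule.

## Ensemble analysis

**Window selection.** Analysis windows are half-open in time,
[start, end) ns, with frame times starting at 0. This makes the accounting
exact: a 100 ns replica saved every 10 ps contributes 3000 frames to the
70–100 ns window, and three replicas pool to 9000 snapshots. Pooling
concatenates replica windows before clustering.

**Radius of gyration** is the mass-weighted RMS distance to the centre of
mass, computed per frame, in the coordinate unit (Angstrom for the built-in
generators). RMSD to the ensemble-average structure is provided for
equilibration diagnostics and assumes frames were superposed upstream.

**Contacts.** The default criterion declares residues i, j (|i−j| ≥ 3) in
contact when any inter-residue heavy-atom distance is ≤ 4.5 Å. The external
contact engine used in the original analyses does not print its criteria,
so the criterion object is pluggable (`criterion` argument) and the default
is the field's common heavy-atom cutoff. Contact sets are stored as sorted
integer pair keys, which keeps the set algebra vectorised.

**Similarity and clustering.** The contact-map similarity is
f~S~ = |C~i~ ∩ C~j~| / |(C~i~ ∪ C~j~) − (C~i~ ∩ C~j~)|, i.e.
J/(1−J) in terms of the Jaccard index, so the clustering threshold
f~S~ > 0.5 equals J > 1/3. The printed formula divides by zero for
identical sets; the package's documented conventions are: identical sets
(including two empty sets) → +∞, so they co-cluster at any threshold;
empty vs non-empty → 0. Stage 1 links snapshot pairs with f~S~ above the
threshold and takes connected components (via igraph; the test suite checks
this against a hand-rolled brute-force BFS oracle on hundreds of random
trajectories). "Joining clusters on the frequencies of their common
contacts" is not an algorithm until one fixes three choices; the package's
formalisation is: represent each component by its high-frequency contact
set (pairs in ≥ `merge_fraction` = 0.5 of member snapshots), merge
component pairs whose representatives again satisfy f~S~ > threshold, and
iterate to a fixed point (merging lowest-index pairs first, so the result
is deterministic). Single-pass merging was rejected because it makes the
outcome depend on component enumeration order.

**Domain contact fractions.** The share of contact occurrences (each pair
weighted by the number of snapshots sampling it) attributable to a residue
window is ambiguous in one respect: whether a contact "belongs" to the
window when both partners lie inside it or when at least one does. Both
definitions (`both_in`, `any_in`) are computed and reported side by side.

**Compactness** is classed against a reference Rg with a ±5% band:
compact / extended / mixed by the median of the series.

## NMR dynamics

**Secondary shifts** are observed minus random-coil reference shifts after
removing one scalar offset per nucleus (the median difference), which makes
them invariant to a global referencing error while leaving genuine
single-residue deviations intact. Missing references propagate as absent
values, never as zeros. The random-coil reference table is an input; no
temperature or pH correction is applied by default.

**RCI → S².** The random coil index is the inverse of the per-residue
weighted mean |secondary shift|, floored so that vanishing shifts give a
finite, maximal RCI, and mapped to order parameters through the published
monotone form S² = 1 − 0.4·ln(1 + 17.7·RCI), clamped to [0, 1]. The
nucleus weights (Cα 1, Cβ 1, Hα 5 — Hα shifts are roughly a factor five
smaller in ppm), the 0.5 ppm floor and the 0.1 RCI scale live in
`rci_config()` rather than in code, with the intent that a lab preferring a
different published coefficient table swaps the config object. Defaults
were chosen once so that zero secondary shifts give a baseline S² ≈ 0.4,
plausible for a disordered peptide; only the ordering and bounds of S² are
treated as scientifically meaningful, and those are what the tests assert.

**Relaxation.** T1/T2 series are fit per residue to I(t) = I₀·e^(−t/T) by
Levenberg–Marquardt started from the log-linear regression. Non-decaying
series are flagged failures — no silent clamping. Sparse residue coverage
is expected (the peptide constructs are ¹⁵N-labelled on leucines only) and
is handled without imputation. R2/R1 = T1/T2 exactly, and is unit-free in
the intensities.

**Reduced spectral density mapping** uses the standard three-frequency
reduction J(ω~H~±ω~N~) ≈ J(0.87ω~H~) with the ¹⁵N–¹H dipolar constant from
a 1.02 Å bond and −160 ppm ¹⁵N CSA (recorded in one internal constant
block). `relaxation_from_spectral_density()` is the exact forward model
under the same approximation, so Lorentzian round-trips are machine-exact —
that property, not agreement with any particular protein, is what the tests
check. Negative densities from unphysical inputs are flagged but reported.

**DOSY.** The Stejskal–Tanner decay I(g) = I₀·exp(−D(γgδ)²(Δ−δ/3)) is fit
in the log-intensity domain with weights I² (the delta-method variance of
log I under additive noise) by default; a raw-domain nonlinear fit is one
flag away. "Exponential fit" admits both readings; the log-domain route is
the default because it is convex and its failure modes are transparent.
The Δ−δ/3 rectangular-gradient correction is the default diffusion time;
other conventions can be passed explicitly. Defaults mirror the
acquisition: δ = 2 ms, Δ = 75 ms, 32 gradient increments spanning 5–95% of
57.7 G/cm.

## FRAP

Double normalization divides the background-corrected bleach-ROI signal,
referenced to its pre-bleach mean, by the equally referenced
whole-structure signal. Two exact properties follow and are tested at
machine precision: invariance to a global intensity scale, and exact
cancellation of any multiplicative acquisition-bleaching factor applied
equally to both ROIs. The reference time t₀ is taken as the mean over all
pre-bleach frames (the equation's t₀ is otherwise undefined; averaging is
the noise-robust reading).

Recovery is fit post-bleach to N(t) = N∞ − (N∞ − N₀)e^(−t/τ); mobile
fraction = (N∞ − N₀)/(1 − N₀) with the pre-bleach level 1, half-time
τ·ln 2. A double-exponential model is available behind `model = "double"`
(its half-time is located numerically). Flat curves are detected before
fitting (recovery amplitude within twice the first-difference noise) and
reported as mobile fraction 0 with τ absent. Classification: liquid-like
iff the mobile fraction reaches the 0.5 threshold (inclusive) within the
120 s horizon; both knobs are configurable because the liquid/solid
contrast is a qualitative distinction.

## Cell metrics

The fusion index is multinucleated-over-total nuclei per visual field;
pooling fields is the totals-weighted mean, which equals the index of the
pooled counts identically. Reporter activity is luciferase/galactosidase
per sample, normalized batch-wise to the in-batch wild-type mean and scaled
to percent — wild type is 100% in every batch by construction, and the
statistic is invariant to rescaling either raw signal. Group comparisons
use two-sided t-tests against wild type or one-way ANOVA with pooled-SD
pairwise posthoc and Holm adjustment. The disorder–activity relation is a
Spearman rank correlation by default: the claim it quantifies is a
monotone, direction-signed association, not linearity.

## Synthetic data

Every generator takes an explicit seed, restores the caller's RNG state,
and returns its ground truth with the data, so each pipeline stage is
tested as recover(generate(θ)) ≈ θ:

* `gen_profiles()` plants window-mean disorder effects on a wild-type
  profile over the 265–301 peptide region (wild-type window p~D~ 0.35,
  just above the disorder boundary, matching the disordered character of
  this region).
* `gen_contact_trajectory()` draws frames from k disjoint contact motifs
  plus Bernoulli noise contacts from a disjoint pool, and warns when the
  noise rate approaches the separation bound beyond which exact recovery
  is no longer guaranteed.
* `gen_conformers()` grows self-avoiding bead chains (one bead per
  residue, 3.8 Å bonds) whose step direction mixes a random unit vector
  with a pull toward the chain centroid; the collapse bias is annealed
  over placement retries so dense chains remain growable. Median Rg is
  monotone decreasing in the bias in expectation — the generator's only
  advertised guarantee.
* `gen_relaxation()`, `gen_dosy()`, `gen_frap()` are the exact forward
  models of their fitting counterparts at the default acquisition
  schedules, plus seeded noise; `gen_frap()` additionally wraps the true
  normalized curve into raw two-ROI channels with a shared
  acquisition-bleaching decay and camera offset.
* `gen_counts_and_readings()` emulates the assay design (4 experiments ×
  3 technical replicates; ~15 fields of ~120 nuclei) with lognormal batch
  factors and multiplicative noise.

What the generators do **not** emulate: force-field physics (bead chains
have no energetics beyond excluded volume), spectral artefacts (baseline,
overlap, phasing), ROI segmentation errors, cell-to-cell variability
structure beyond lognormal batches. Passing tests therefore demonstrate
the *estimators'* correctness and calibration under the stated models, not
robustness to every pathology of real data.

## Problem sizes and numerical notes

The test and acceptance runs use sizes chosen to exercise the algorithms
well past their edge cases while staying interactive: up to 200-snapshot
random trajectories (100 replicates) for the clustering-vs-oracle
equivalence, 300 snapshots for planted-motif recovery, 120-frame conformer
ensembles, 100-seed noisy-recovery sweeps for DOSY and relaxation. The
similarity matrix is built through a sparse snapshot-by-contact incidence
product, so clustering a few thousand snapshots remains feasible; the
brute-force oracle is the quadratic reference, not the implementation.
Ties and degeneracies are resolved deterministically everywhere (stable
ranking, lowest-index-first merging, inclusive thresholds), and every fit
reports either a standard error or an explicit failure flag.

## Known limitations

* Stage-2 cluster joining is one defensible formalisation of a verbal
  procedure; alternatives (e.g. frequency-weighted similarity between
  full cluster maps) would merge differently near the threshold. The
  strategy is isolated behind `merge_fraction`/`join` so it can be swapped.
* The RCI coefficient defaults are a calibrated package choice, not the
  cited laboratory's exact table; comparisons of absolute S² across
  software should re-derive the config from a common reference.
* `rmsd_to_average()` does not superpose frames.
* β-domain contact fractions of the real peptide ensembles require the
  archived MD trajectories, which are not shipped; the package computes
  the same statistic on any trajectory it is given.
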