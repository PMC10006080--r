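# mef2dyn

Analysis toolkit for studying how the dynamics of the alternatively spliced
**β-domain** of the MEF2D transcription factor — a seven-residue acidic
segment (residues 286–292, UniProt Q14814) inside the disordered
transactivation domain — shape MEF2D's higher-order assembly and
transcriptional activity. It is aimed at groups combining disorder/phase
-separation predictions, peptide molecular-dynamics ensembles, solution NMR
and live-cell FRAP and reporter assays around a single disordered motif.

The package implements five analysis stages plus a seeded synthetic-data
generator so every stage is testable with known ground truth:

1. **Variant design** — window means of per-residue descriptors
   (p<sub>D</sub>: disorder in the free state; p<sub>DD</sub>: disordered
   "fuzzy" binding; p<sub>DP</sub>: droplet-promoting propensity) over the
   β-domain; mutant-minus-wild-type deltas Δp = p(mut) − p(wt);
   order/disorder calls at the p<sub>D</sub> ≥ 0.3085 boundary;
   similar/mobile/rigid classification; placement on the droplet landscape
   (p<sub>DP</sub> vs the multiplicity-of-binding-modes coordinate, liquid
   above the diagonal, solid below); candidate ranking.
2. **Ensemble analysis** — equilibration windows (70–100 ns, half-open, so
   three replicas at 10 ps saves pool to exactly 9000 snapshots), radius of
   gyration, per-snapshot residue contacts, and clustering of snapshots by
   the contact-map similarity

   f<sub>S</sub> = |C<sub>i</sub> ∩ C<sub>j</sub>| /
   |(C<sub>i</sub> ∪ C<sub>j</sub>) − (C<sub>i</sub> ∩ C<sub>j</sub>)|

   (shared over non-shared contacts; f<sub>S</sub> = J/(1−J) for Jaccard
   index J). Snapshots with f<sub>S</sub> > 0.5 are linked, connected
   components form stage-1 clusters, and clusters are then joined on the
   similarity of their high-frequency contact sets. Per-cluster contact
   maps and β-domain contact fractions follow.
3. **NMR dynamics** — secondary shifts with offset correction, random coil
   index → S² order parameters, T1/T2 monoexponential fits at the built-in
   delay schedules, R2/R1, reduced spectral density mapping
   (J(0), J(ω<sub>N</sub>), J(0.87ω<sub>H</sub>)), and Stejskal–Tanner DOSY
   fits I(g) = I₀·exp(−D(γgδ)²(Δ−δ/3)).
4. **FRAP mobility** — the double normalization
   N(t) = [(I<sub>bleach</sub>−I<sub>bg</sub>)/(I<sub>bleach</sub>(t₀)−I<sub>bg</sub>(t₀))] /
   [(I<sub>total</sub>−I<sub>bg</sub>)/(I<sub>total</sub>(t₀)−I<sub>bg</sub>(t₀))],
   which cancels acquisition photobleaching exactly; curve averaging with
   SEM; single-exponential recovery fits (mobile fraction, half-time) and
   liquid-like vs solid-like classification.
5. **Cell metrics** — myotube fusion index, luciferase/galactosidase
   reporter activity normalized batch-wise to the wild-type control
   (% of wt), group statistics (t-tests, ANOVA with Holm posthoc), and the
   rank correlation between β-domain disorder and activity.

## Worked example

```r
library(mef2dyn)

# design: a variant whose beta-domain is rigidified by 0.2 in p_D
g <- gen_profiles(1, effects = c(var3 = 0.2, var8 = -0.2))
dynamics_summary(g$variants$var8, g$wt)
#> dynamics_summary: mean p_D 0.157 (ordered), delta p_D -0.200 (rigid)
#>   landscape: liquid-favoring (signed distance +0.247, MBM 0.000)

# ensemble: two planted contact motifs recovered from 120 snapshots
gc2 <- gen_contact_trajectory(1, n_snapshots = 120, k = 2, noise_rate = 1)
cluster_snapshots(gc2$ct)
#> cluster_result: 120 snapshots in 2 clusters; populations: 62, 58

# DOSY: diffusion coefficient from a noisy gradient decay
d <- gen_dosy(1, d_m2_s = 1.54e-10, noise_frac = 0.02)
f <- fit_dosy(d$gradients_g_cm, d$intensities)
sprintf("D = %.3g +/- %.2g m2/s", f$d_m2_s, f$se_m2_s)
#> "D = 1.54e-10 +/- 2.2e-12 m2/s"

# FRAP: mobile fraction and half-time from a noisy trace
tr <- gen_frap(1, mobile_fraction = 0.6, tau_s = 15, noise_frac = 0.02)
analyze_frap(tr)
#> frap_result: mobile fraction 0.589, half-time 10.8 s -> liquid-like
```

The first block reads: the mutant's β-domain window mean p<sub>D</sub> is
0.157, below the 0.3085 disorder threshold (so "ordered"), 0.200 below the
wild type (so classed "rigid"); its droplet-landscape point sits above the
diagonal (liquid-favoring). The FRAP fit recovers the planted kinetics
(true mobile fraction 0.6, half-time 15·ln 2 ≈ 10.4 s) within noise and
classifies the focus liquid-like.

A thin command-line wrapper with subcommands `design`, `ensemble`, `frap`,
`metrics` and `simulate` is installed at
`system.file("scripts", "mef2dyn-cli.R", package = "mef2dyn")`.

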