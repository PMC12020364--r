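---
title: "Methods: network states, dip binarization and ecological risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network states, dip binarization and ecological risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`benthicnet` classifies seafloor sediment samples by the dominance of two
opposing microbial co-occurrence networks — one centred on a
sulfur-oxidizing hub genus, one on an ammonia-oxidizing archaeon — and
relates those states to benthic macrofauna status (nEQR), chemistry and
geography. This vignette documents the statistical model, every tunable
that matters, the numerical choices, and what the bundled synthetic
generator does and does not emulate.

## The correlation network

All network inference happens at genus level on per-mille relative
abundance (each sample row rescaled to 1000 ‰). Pairwise association is
Spearman's ρ (Pearson correlation of midranks), with p-values from the
large-sample t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n−2`
degrees of freedom. At the cohort sizes this package targets (hundreds to
thousands of samples) the approximation is indistinguishable from exact
permutation; the test suite verifies ρ itself against a brute-force midrank
oracle, so only the p-value rests on the approximation.

Thresholds `rho_pos = +0.3` and `rho_neg = −0.3` define "moderate" edges.
The S-like hub is the genus with the most edges below `rho_neg`; the N-like
hub is the genus most negatively correlated with it. Subnetwork membership
uses the dual rule: a genus belongs to the N network iff
`rho(., hub_N) > rho_pos` **and** `rho(., hub_S) < rho_neg` (mirrored for
S). The two rules cannot both hold, so the member sets are disjoint by
construction. Benjamini–Hochberg q-values are computed over the upper
triangle and reported, but membership is gated on raw ρ only — the
reference analysis states its membership rule purely in terms of ρ, and we
follow that reading rather than guessing an FDR gate.

Two deliberate deviations from a fully literal reading:

* **Prevalence filter.** Genera detected in fewer than 5 % of samples or
  with mean abundance under 0.1 ‰ are excluded before correlation, because
  midrank Spearman on almost-all-zero columns is dominated by tie noise.
  Both knobs sit in `run_config()`; setting them to zero reproduces
  full-cohort behaviour. Unclassified-genus buckets are likewise excluded
  from the network (they are not biological genera) but retained in the ‰
  normalisation so abundance mass is conserved.
* **Hub degree cutoff.** The published "more than 500 negative edges" is a
  cohort-specific report (2387 genera); hub selection here is argmax of the
  negative degree, and the 500-edge figure is only echoed as a reporting
  flag scaled to the number of genera tested.

Correlations are computed on ‰ abundances, not CLR-transformed data,
matching the source procedure; compositional bias is acknowledged and a CLR
option (`use_clr`) is exposed but off by default. Chloroplast/organelle
genera are retained in the normalisation (the reference cohort reports
Bacillariophyta chloroplasts among dominant taxa); `exclude_chloroplast`
removes them if desired.

## The dip statistic and binarization

Per-sample network abundance (summed ‰ of hub + members) is tested for
departure from unimodality with Hartigan & Hartigan's dip statistic: the
smallest `d` such that some unimodal CDF (convex below its mode, concave
above, an atom at the mode allowed) stays within `d` of the empirical CDF
everywhere. The implementation (C++, exact) iterates greatest-convex-minorant
/ least-concave-majorant hulls over a shrinking candidate modal interval;
ties are handled in value blocks, so an atom at the mode costs nothing while
tied values away from the mode contribute their full block size. Invariants:
`1/(2n) ≤ D ≤ 1/4`; affine invariance; a point-mass sample is degenerate and
returns the lower bound with a warning. The test suite holds the
implementation to 1e-9 agreement with an independent linear-programming
oracle (minimax fit over piecewise-linear unimodal CDFs on the sample grid,
solved per candidate mode with verified-feasible simplex solutions) on
hundreds of randomized cases including heavy ties.

The bootstrap null is Hartigan's standard choice — uniform(0,1) samples of
the same size, conservative among unimodal nulls — with the add-one p-value
`(r+1)/(B+1)` and `B = 10000` by default. The null draws go through R's RNG,
so a seed makes the test bit-for-bit reproducible.

If and only if the dip rejects (α = 0.05), a binarization threshold is set
at the **kernel-density antimode**: the minimum of a Gaussian KDE
(Silverman's rule-of-thumb bandwidth) restricted to the interval between
the two largest density modes. The source describes the cut only as where
"a minimum value for the dip was reached", which is operationally
ambiguous; the KDE antimode is deterministic and lands in the density
valley that reading implies. As a consistency signal the threshold is
compared with the dip's modal interval — for a bimodal sample that interval
tracks one of the clusters, so a threshold cutting *through* it (more than
one bandwidth inside) warns that a mode is being split. Threshold
comparison is closed on the right (`abundance >= threshold` counts as
present), a convention the source leaves unstated. A network whose dip test
is not significant is marked absent in all samples, with a prominent
warning.

## Risk and association statistics

The deterioration odds ratio uses the 2×2 of network presence ×
dichotomized nEQR (`< 0.8` = deteriorated): `OR = (a/b)/(c/d)` with the
Altman log-scale 95 % interval `exp(ln OR ± 1.96·sqrt(1/a+1/b+1/c+1/d))`.
Any zero cell triggers the Haldane–Anscombe +0.5 correction on all four
cells, with a flag. Samples in state "both"/"neither" are *included* in the
exposure dichotomy — exposure is the presence flag, matching the source's
"presence of the networks" — and samples without nEQR are excluded and
counted. χ² tests of independence use no continuity correction (the MATLAB
`crosstab` convention); Kruskal–Wallis is tie-corrected. FDR families are
one per analysis table (tolerance profile, covariate family), never pooled
across the run. Alpha diversity is `1 − Σp²` and `−Σ p ln p` (0·ln 0 = 0);
beta diversity is Bray–Curtis with classical PCoA (Gower centering,
coordinates only on positive eigenvalues; negative eigenvalues are counted
and reported, with no Lingoes/Cailliez correction — transparency over
adjustment).

The nEQR model is an additive GAM on four components — S-network ‰,
N-network ‰, depth (m), distance to the nearest farm (m) — with cubic
regression splines (10 knots per component), smoothing chosen by GCV within
each of 10 cross-validation folds, every sample predicted by a model not
trained on it, and predictions clipped post hoc to the nEQR domain [0,1]
(raw values kept). Partial dependence is the pointwise mean of the ICE
curves, which are computed by sweeping one component over its observed
range with all others held at each sample's values. The hierarchical
station/region structure of real cohorts is deliberately ignored, as in the
source analysis; the MATLAB option of fitting a per-prediction standard
deviation has no analogue here and only point predictions are stored.

## What the synthetic generator emulates

`synthetic_scenario()` defines a cohort of 600 samples × 200 genera in four
latent states — S_only (45 %), N_only (45 %), both (4 %), neither (6 %) —
mirroring the strong two-state split with rare mixed samples reported for
the motivating cohort. Genus proportions are state-conditional Dirichlet
draws: the S hub plus 10 satellites get high concentration in S-state
samples while the N block (hub + 50 satellites) is suppressed, and
conversely; counts are multinomial at lognormal sequencing depth
(median 5·10⁴ reads). A Dirichlet-multinomial was chosen over a
lognormal-Poisson because block sums are then exactly Beta distributed,
which makes the compositional anticorrelation of the two hubs explicit and
gives closed-form ground truth. Concentrations were calibrated once so that
each network's cohort-level abundance is bimodal with *overlapping* low and
high modes (as in the source's description of two overlapping peaks), the
S-state has lower diversity (its hub absorbs most mass), and satellite-hub
rank correlations sit well clear of the ±0.3 membership thresholds.

nEQR is drawn by first flagging deterioration with the state-conditional
probabilities `P(nEQR<0.8 | state)` = 0.8 / 0.2 / 0.5 / 0.5 for
S_only / N_only / both / neither — giving a generative odds ratio ≈ 11 for
S-presence, the regime of the motivating study — then sampling the value
from a scaled beta on the matching side of 0.8 (deteriorated mean 0.6,
healthy mean 0.9; the continuous shape is ours, as only the dichotomy is
specified upstream). Chemistry couples to the drawn block proportions (TOC,
Cu, total N rise with the S block; pelite and Zn with the N block; distance
falls with the S block; depth is independent, so the GAM should find it
flat), and macrofauna counts are Poisson with log-rates monotone in state
across the seven AMBI tolerance groups (sensitive groups thrive with the N
block, opportunists with the S block).

Ground truth shipped with each cohort: the latent state per sample, the
true member sets, the generative odds ratios (closed form over state
fractions and deterioration probabilities), and two antimode thresholds per
network — the raw density minimum of the exact Beta mixture, and the
minimum after convolving that mixture with a Gaussian at the deterministic
Silverman bandwidth for the cohort size. The smoothed version is the
population functional the KDE estimator targets and is what
threshold-recovery checks compare against; both are reported.

What the generator does **not** emulate: sequence-level artefacts (chimeras,
PCR bias), spatial/station autocorrelation, genuinely compositional
chemistry covariation, taxonomic misassignment, or the long-tailed genus
richness of real sediments (200 genera, not thousands). Passing the
recovery tests therefore demonstrates that the pipeline identifies the
structure it assumes when that structure is present at realistic effect
sizes and noise — not that real cohorts satisfy those assumptions.

## Problem sizes and numerical conventions in the test suite

The suite validates the dip against its LP oracle at n ≤ 30 (200 randomized
cases, 1e-9), calibrates the dip test at n = 500 with B = 1000 over 1000
uniform-null simulations (rejection 5 % ± 2 %) plus 200 power simulations,
and checks recovery of hubs, memberships (Jaccard), antimode thresholds
(±10 %) and odds-ratio CI coverage (≥ 90 %) across 50 default cohorts.
GAM recovery uses n = 1000 simulated additive data with noise sd 0.05.
These sizes keep the full suite in the minutes range on one CPU while
leaving the statistical margins wide.

Other conventions: empty-vs-empty Bray–Curtis pairs are undefined and
flagged, never imputed; metadata missingness is preserved (samples are
dropped per stage, with a logged count, not globally); `run_all()` derives
all stage seeds from the single configured seed, so reruns are
byte-identical; and the run manifest records config, input hashes and
per-stage counts.

## Known limitations

* Compositional effects: correlations on ‰ shares can induce spurious
  negative dependence between large blocks; the CLR option mitigates but
  changes the meaning of the thresholds, hence is off by default.
* The antimode is undefined when the KDE merges the modes; the fallback
  (grid-end peaks) keeps the procedure total but such thresholds deserve
  inspection alongside the dip's modal interval.
* The dip's bootstrap null (uniform) is conservative for peaked unimodal
  alternatives; no alternative nulls are provided.
* Odds ratios treat samples as independent; with clustered monitoring
  designs the Altman intervals will be anti-conservative.
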