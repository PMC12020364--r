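# benthicnet

Seafloor sediments below and around coastal aquaculture sites tend to fall
into one of two mutually exclusive microbial configurations: a community
organised around a sulfur-oxidizing hub genus (*Sulfurovum*-like), associated
with organic enrichment and degraded benthic fauna, or a community organised
around an ammonia-oxidizing archaeon (*Nitrosopumilus*-like), associated with
oligotrophic, healthy seafloor. `benthicnet` classifies 16S rRNA-derived
sediment samples into these network states and quantifies how strongly the
states predict macrofauna ecological status, sediment chemistry and
geography. It is aimed at benthic monitoring and microbial ecology groups
working with genus-level count tables and standard monitoring metadata
(nEQR, AMBI, TOC, grain size, distance to farm).

## The method

Given a samples × genera count table, the pipeline:

1. **Normalises** to per-mille relative abundance per sample
   (row sums = 1000 ‰).
2. **Builds the co-occurrence network**: all-pairs Spearman ρ between genera,
   p-values from the large-sample t approximation
   t = ρ·√((n−2)/(1−ρ²)), Benjamini–Hochberg FDR across the upper triangle.
3. **Finds the opposing hub pair**: the genus with the most strong negative
   edges (ρ < −0.3) is the S-like hub; its most negative partner is the
   N-like hub. A genus joins the N subnetwork iff ρ(·, hub_N) > 0.3 **and**
   ρ(·, hub_S) < −0.3 (mirrored for S).
4. **Binarizes network abundance**: the per-sample summed ‰ abundance of each
   subnetwork is tested for departure from unimodality with Hartigan's dip
   statistic D = min over unimodal CDFs G of sup|F_n − G| (exact
   GCM/LCM computation, bootstrap null of uniform samples, p = (r+1)/(B+1)).
   If significant, the binarization threshold is the kernel-density antimode
   between the two dominant modes; samples are assigned the four-way state
   S_only / N_only / both / neither.
5. **Quantifies risk**: the odds ratio of a deteriorated ecological state
   (nEQR < 0.8) given network presence, OR = (a/b)/(c/d), with Altman 95% CI
   exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d)); plus AMBI tolerance-group
   correlation profiles, chemistry correlations, χ² crosstabs, Simpson and
   Shannon diversity, Bray–Curtis PCoA, and a 10-fold cross-validated GAM
   nEQR ~ s(abund_S) + s(abund_N) + s(depth) + s(distance) with
   partial-dependence and ICE curves.

A synthetic-community generator (`synthetic_scenario()`,
`generate_cohort()`) draws state-conditional Dirichlet-multinomial cohorts
with the full two-hub structure, coupled nEQR, chemistry and macrofauna, and
analytic ground truth (generative thresholds and odds ratios), so every
stage is testable without external data.

## Worked example

```r
library(benthicnet)

cohort  <- generate_cohort(synthetic_scenario(seed = 1))
genus   <- aggregate_to_genus(cohort$counts, cohort$taxonomy)
profile <- to_relative_permille(genus)

net  <- build_network(profile)
hubs <- find_hub_pair(net)
#> hubs: Sulfurovum vs Nitrosopumilus, rho = -0.67

nd <- assign_memberships(net, hubs)
#> assign_memberships: 10 S members, 50 N members, 138 unassigned
na <- network_abundance(profile, nd)

dip_N <- dip_test(na$abund_N, B = 10000, seed = 2)
dip_N
#> Hartigan dip test: D = 0.1117, p = 9.999e-05 (n = 600, B = 10000)
#> modal interval [37.46, 184.6]; significant at alpha = 0.05
thr_N <- antimode_threshold(na$abund_N, dip_N)$threshold
dip_S <- dip_test(na$abund_S, B = 10000, seed = 3)
thr_S <- antimode_threshold(na$abund_S, dip_S)$threshold
#> thresholds: S 261 permille, N 323 permille

st <- assign_states(na, thr_S, thr_N, cohort$metadata)
#> assign_states: S_only=265, N_only=273, both=23, neither=39
deterioration_risk(st, "S_present")
#> OR = 13.8 (95% CI 9.35-20.5)
deterioration_risk(st, "N_present")
#> OR = 0.0865 (95% CI 0.059-0.127)
```

Read: the two hub genera are strongly anticorrelated (ρ = −0.67); both
subnetwork abundances are significantly bimodal, so each sample can be
called present/absent per network at the density antimode (261 ‰ / 323 ‰);
samples carrying the sulfur-oxidizer network have ~14× the odds of a
deteriorated seafloor (nEQR < 0.8), while the ammonia-oxidizer network is
protective (OR ≈ 0.09) — recovering the structure the generator encoded
(generative OR ≈ 11).

`run_all(input_dir, output_dir, run_config(...))` chains all stages and
writes TSV outputs plus a JSON run manifest; `inst/cli/benthicnet.R` exposes
`simulate` and `run-all` verbs for shell use.

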