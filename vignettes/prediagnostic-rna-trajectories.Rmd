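---
title: "Modelling prediagnostic serum RNA trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling prediagnostic serum RNA trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serotraj)
library(dplyr)
```

## The scientific problem

Serum contains circulating RNA from ten broad classes — miRNA, miRNA
hairpin, isomiR, piRNA, tRNA, tRF, snoRNA, miscRNA, lncRNA and mRNA
fragments. In individuals who later develop lung cancer, the abundance of
some of these RNAs departs from that of cancer-free donors years before
diagnosis, and it does so *dynamically*: the differential signal waxes and
wanes as the tumour progresses rather than growing monotonically. Detecting
when, in which disease stage and in which histology these departures occur
requires a cohort of serum samples donated over a long prediagnostic span
(here 10 years = 120 months), matched cancer-free controls, and an analysis
that slices prediagnostic time into windows and tests each window
separately.

serotraj implements that analysis as a reusable pipeline:

1. **Cohort construction** — frequency matching at cohort level and optimal
   1:k age matching within analysis windows.
2. **Time windows** — seven fixed ~17-month windows covering the span
   (phases 2–3) and 17-month sliding windows advanced by 2.5 months
   (phase 4, 42 windows).
3. **Differential expression** — per-window covariate-adjusted
   negative-binomial Wald tests with Benjamini–Hochberg correction.
4. **Trajectories** — per-window counts of significant RNAs, stratified by
   RNA class, with peak detection and bootstrap stability summaries.
5. **Enrichment** — hypergeometric over-representation of pathways among DE
   mRNAs and predicted miRNA/isomiR targets.

Because the underlying human cohort is not public, the package ships a
synthetic-cohort generator with full ground truth; every statistical claim
the test suite makes is made against that generator.

## The synthetic cohort

`simulate_cohort()` emulates the structure of a serum-bank lung-cancer
cohort. Margins (case counts per histology × stage cell, sex per stage,
never-smoker cases per stage, control count, smoker controls) are
reproduced *exactly*; `janus_margins()` encodes the published full-scale
composition: 542 case samples (stage totals 103/141/279/19), 519 controls,
11 non-smoker cases so that the smoker restriction leaves 531 cases and 189
controls.

Counts for RNA $i$ in sample $j$ are negative binomial,

$$K_{ij} \sim \mathrm{NB}\!\left(\mu_{ij},\, \alpha_i\right),\qquad
\mu_{ij} = s_j\, 2^{\,\beta_{0i} + x_j^\top\beta_i + f_i(t_j)},$$

with per-RNA dispersion $\alpha_i$ (variance $\mu + \alpha\mu^2$),
log-normal library size factors $s_j$, and per-RNA log2 shifts for age (per
SD), sex, smoking and the blood-donor-group batch. The case effect
$f_i(t)$ is a Gaussian bump in log2 space,

$$f_i(t) = A\, e^{-(t - c)^2 / (2 w^2)},$$

peaking $c$ months before diagnosis with width $w$ and signed amplitude
$A$, applied only to case samples whose stage/histology fall in the
profile's subsets. A Gaussian bump is a modelling choice: the real signals
are only known as empirical peaks ("strongest around 7 years" for early
stage, "1–4 years" for advanced stage), and a smooth two-parameter bump
lets tests place peaks anywhere in the span and measure recovery.

Default generator settings, chosen once as realistic for serum small-RNA
sequencing and not revisited:

| parameter | default | why |
|---|---|---|
| baseline log2 mean | $3 + \mathrm{Exp}(\text{mean } 2.5)$, capped at 16 | long-tailed: a minority of RNAs dominates reads |
| dispersion $\alpha_i$ | log-uniform on $[0.05, 1]$ | spans tight to very noisy serum RNAs |
| size factors | log-normal, $\sigma = 0.3$ | typical depth variation |
| covariate shifts | $N(0, 0.15)$ per RNA; BDg uniform on $[-0.5, 0.5]$ | small enough to be realistic, large enough that unadjusted analyses would be confounded |
| times to diagnosis | uniform on $[0, 120]$ months | guarantees occupancy of every window (`uniform_times = FALSE` matches the published per-stage means instead) |
| ages | controls $N(49.9, 11.2)$; cases per-stage means 53–55 | published donation-age distributions |

What the generator does *not* emulate: sequencing-level artefacts (adapter
content, mapping bias), storage-time degradation, and correlation between
RNAs (counts are conditionally independent given the design). Passing tests
therefore demonstrate that the pipeline recovers what it claims under a
clean NB world with confounding — not that the same power holds on real
serum libraries.

## The matching model

At cohort level, `frequency_match()` stratifies on sex, blood-donor group
and 5-year age bins and samples controls uniformly so the case:control
ratio is constant across strata. Within analysis windows,
`optimal_match()` solves the exact 1:k assignment minimising total
absolute age difference, replicating each case $k$ times and running a
Hungarian solver; an optional caliper and exact-agreement variables
restrict admissible pairs. Optimality is verified in the test suite against
a dynamic-programming enumeration oracle on small instances.

Two deliberate choices:

* **Distance is absolute age difference in years.** Age is the single
  continuous matching variable; a Mahalanobis distance would reduce to it.
* **Within windowed pipeline runs the default exact variable is sex
  only.** After the smoker restriction the full-scale pool holds 189
  controls for 135 slots per window; demanding exact agreement on the
  blood-donor group as well is then routinely infeasible, and smoking is
  constant by construction. Exact matching on any covariate set remains
  available through `match_spec()`.
* **Controls may be reused across windows, never within one** (nor within
  a bootstrap iteration). Windows are analysed independently and the
  control pool is scarce; reuse across windows maximises feasibility.

## Time windows and sample selection

Windows are half-open `[start, end)` month intervals counted backwards from
diagnosis, so the seven fixed windows partition the span without double
counting; their year labels round to the familiar "0–1.4", "1.5–2.8", …
intervals. Sliding windows move in 2.5-month steps; with the 17-month width
this yields 42 windows whose consecutive overlaps are 14.5 months.

`select_window_samples()` draws the window's case quota with stages
allocated toward equal proportions by the largest-remainder rule,
backfilling from over-represented stages when a stratum runs short (the
"similar proportions when possible" rule). Controls have no prediagnostic
time and are eligible for every window. Quotas follow the published design:
27 cases / 135 controls per stage-mixed window; 9/45, 14/70 and 18/90 for
the early, locally advanced and advanced stage-specific analyses; 20
bootstrap iterations.

## The differential expression engine

The engine is a deliberately simplified, oracle-verifiable analogue of the
standard negative-binomial RNA-seq machinery:

* **Size factors** are plain median-of-ratios against the geometric-mean
  reference (cross-checked in the tests against the reference
  bioinformatics implementation).
* **Dispersions** are per-RNA method-of-moments estimates
  $\hat\alpha = \max(10^{-8}, (s^2-\bar\mu)/\bar\mu^2)$ on normalized
  counts, shrunk 50/50 in log space toward a fitted $a_0/\mu + a_1$
  mean-dispersion trend. Estimates at the floor stay at the floor, so
  constant or underdispersed RNAs are treated as (quasi-)Poisson.
* **Tests** fit, per RNA, an NB log-link regression with fixed dispersion
  and `log s_j` offsets by IRLS (tolerance $10^{-8}$, 100 iterations max),
  and report the case coefficient in log2 units with a standard-normal
  Wald p-value. SEs come from the unscaled information matrix, matching
  the fixed-dispersion model. Non-converging or all-zero RNAs are flagged
  with missing p and excluded from BH, never fatal.
* **No** Cox–Reid adjustment, dispersion-outlier refitting, fold-change
  shrinkage, independent filtering or outlier replacement. These refinements
  matter most at the margins of real data; omitting them keeps every step
  checkable against closed forms and simulations. Reproducing any real
  cohort's DE numbers is explicitly out of scope.

Covariates enter as standardized age, a male indicator, smoking indicators
(reference: former smoker) and blood-donor-group indicators (reference:
first label alphabetically); covariates constant in a window are dropped.
Phase 1 keeps samples with missing smoking as an explicit `"unknown"`
level; phases 2–4 restrict to current/former smokers. BH is applied within
each window only — there is no cross-window correction, mirroring the
original design (a known limitation of it).

Measured behaviour under the generator's conditions (recomputed by the
test suite and `scripts/acceptance.R` at every run): the Wald type-I error
at nominal 0.05 sits near 0.03–0.04 at the 27-vs-135 window size — slightly
conservative, driven by the trend-shrunk dispersions over-estimating
moderately at small n; a null cohort pushed through the full windowed
pipeline yields a median of zero significant RNAs per window.

## Trajectories, peaks, bootstrap

The per-window "signal" is the count of RNAs with adjusted p < 0.05
(matching how the original figures summarise windows); a class-stratified
table of those counts over window centers is the trajectory. Peak detection
is not specified by the source design (peaks were read visually), so the
package declares an explicit rule: local maxima of the total series of
height ≥ `min_height`, kept greedily in decreasing height order subject to
a minimum pairwise separation. Kernel smoothing is available for *plotting
only* and never feeds peak detection. `bootstrap_phase3()` reruns
selection, matching and testing per window with fresh draws and summarises
the spread of the signal; windows whose quota is infeasible report the
number of iterations actually completed.

## Pathway enrichment

Functional predictions exist only for mRNAs (their own gene) and for
miRNAs/isomiRs (predicted targets with score strictly > 60, isomiRs mapped
to their parent miRNA through an explicit map); piRNAs, tRFs and the other
classes contribute nothing. The over-representation test is the plain
one-sided hypergeometric tail with BH across pathways, and the universe is
all genes in the pathway annotation (not all detected RNAs — the measured
universe mixes RNA classes that can never map to genes). Because the exact
tail is discrete, the attained false-positive rate under random selection
falls slightly *below* the nominal level (≈ 0.03 at 0.05 in the calibration
runs); the test is conservative, never anticonservative. A toy synthetic
annotation (`simulate_annotation()`) stands in for real pathway/target
databases, which can be supplied as TSVs in the same layout.

## Numerical and reproducibility choices

* Half-open interval comparisons use exact floating-point boundaries; the
  sliding-window count adds a $10^{-9}$ guard against representation error
  in `floor()`.
* Assignment ties are broken by lexicographic (case id, control id) order,
  making matching fully deterministic; one global seed fans out to
  per-window and per-iteration child seeds by a fixed integer derivation,
  so any window's analysis can be reproduced in isolation.
* Log2 fold changes are *approximately* invariant to rescaling one
  sample's sequencing depth when size factors are re-estimated (the NB
  likelihood weighs a deeper library slightly differently); the measured
  shift is below 0.01 log2 units on the test cohorts.
* Problem sizes in the test suite are scaled to what the properties need:
  type-I error uses 2000 null RNAs at 27 vs 135; peak recovery uses 10
  cohorts of 200 RNAs × 600 samples with a 1.5-log2, 15%-of-RNAs bump at
  84 months (recovered within ±5 months in ≥ 80% of runs); stage
  specificity uses two cohorts with advanced-only effects.

## Worked example

```{r example, eval = FALSE}
prof <- do.call(rbind, lapply(sprintf("rna%04d", 1:20), function(id) {
  effect_profile(id, center_months = 84, width_months = 9,
                 amplitude_log2 = 1.5)
}))
coh <- simulate_cohort(
  n_rnas = 200,
  margins = cohort_margins(matrix(30, 3, 4), 240, n_control_smokers = 240),
  profiles = prof, seed = 1)

p4 <- run_phase(coh$samples, coh$counts, phase = 4,
                n_cases = 15, ratio_k = 3, seed = 1)
traj <- build_trajectory(p4)
detect_peaks(traj, min_height = 3, min_separation_months = 24)
autoplot(traj)
```

## Known limitations

* The DE engine's simplifications (above) mean its p-values are not
  interchangeable with full production RNA-seq pipelines at small counts.
* The generator draws RNAs independently; correlated RNA modules would
  lower the effective number of tests and change FDR behaviour.
* Repeated samples from one donor are simulated as independent given the
  covariates (the original design treated the overlap as negligible).
* Matching optimises age only; residual imbalance on unmodelled covariates
  is handled solely by the regression adjustment.
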