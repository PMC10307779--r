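---
title: "Ethogram analysis of pain sensitivity and opioid reward: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ethogram analysis of pain sensitivity and opioid reward: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethopain)
```

## The analysis problem

Behavioral pharmacology studies of opioid reward often collect a battery of
per-animal measures across weeks: thermal reflex pain sensitivity
(Hargreaves-type paw withdrawal latencies), locomotor responses to vehicle
and drug during place conditioning, the strength of the conditioned place
preference (CPP) it produces, the rate at which that preference extinguishes
under repeated drug-free testing, and the consequences of an induced chronic
neuropathic pain state (chronic constriction injury, CCI, of the sciatic
nerve versus sham surgery). Treating the battery as a multivariate
phenotype — an *ethogram* — lets one ask which behavioral dimensions travel
together across individuals.

`ethopain` implements that analysis as a tested pipeline with four layers:

1. **Measure derivation** — fourteen formula-defined outcome measures from
   tidy session-level records.
2. **Group statistics** — the inferential battery (one-sample, paired and
   pooled-variance t tests, within-subjects ANOVA, Shapiro–Wilk, Pearson,
   Mann–Whitney), all two-tailed and uncorrected.
3. **Data reduction** — Pearson correlation matrix, sign-blind
   $d = 1 - |r|$ distance, classical multidimensional scaling (MDS) to two
   dimensions, and k-means with a validity-index vote for the cluster count.
4. **Synthetic cohorts** — a generator with configurable latent trait
   correlation, standing in for animal data that are not publicly deposited,
   so every downstream stage is testable end to end.

## Outcome measures

Eight pre-surgery measures are derived per animal:

| Measure | Unit | Definition |
|---|---|---|
| Basal reflex pain | s | session-mean withdrawal latency of the first reflex session |
| Rate of change in reflex pain | s/session | $-1 \times$ OLS slope of session-mean latency over session index |
| Basal loco | counts | beam-break counts after vehicle on the first conditioning day |
| Rate of loco habituation | counts/session | $-1 \times$ OLS slope of vehicle counts over session index, square-root transformed cohort-wide if the raw slopes fail Shapiro–Wilk normality at $p < 0.05$ |
| Acute OXY loco | counts | first-day drug counts minus same-day vehicle counts |
| Rate of behavioral sensitization | counts/session | OLS slope (not inverted) of vehicle-normalized drug counts |
| CPP at first test | s | drug-paired compartment time at the first post-conditioning test minus the pre-test time |
| Rate of CPP extinction | s/day | $-1 \times$ OLS slope of pre-test-subtracted CPP scores over **calendar day** |

and six post-surgery measures: mean surgeried-paw latency over the three
post-surgery sessions, the same expressed as a percentage of the
non-surgeried paw, its change from the first pre-surgery session, and the
post-surgery drug-paired compartment time minus (respectively) the pre-test,
first-test and final-extinction-test times.

Several conventions deserve explicit statement because they are invisible in
a column of numbers:

* **Closest-pair trial reduction.** Each paw contributes two or more
  latency trials per session; the two numerically closest are averaged.
  When several pairs tie on the gap, the earliest pair in acquisition order
  wins — an arbitrary but deterministic rule (the alternatives differ only
  on exact ties).
* **Abscissae.** Reflex and conditioning slopes regress on session index
  (units "per session"); the extinction slope regresses on calendar day
  (unit "s/day"). Test days are unevenly spaced (17, 24, 28, 38, 45, 49,
  51), so the two abscissa choices are *not* equivalent for extinction.
  Whether day 17 enters as $x = 17$ or is re-zeroed is immaterial for the
  slope, which is the measure; only the intercept shifts.
* **Inversion.** Three slope measures are sign-inverted so that decline
  maps to a positive number (faster sensitization, habituation or
  extinction); behavioral sensitization is left uninverted so that a rising
  drug response is positive.
* **The square-root transform** is generalized to the signed root
  $\mathrm{sign}(s)\sqrt{|s|}$ so that cohorts containing negative raw
  habituation slopes remain transformable; the transform is monotone, is
  applied to all animals or none, and the decision (cohort-level
  Shapiro–Wilk $p < 0.05$ on the raw slopes) is recorded as a flag so either
  scale can be reconstructed.
* **Missing phases yield missing values**, never imputation: an animal
  without post-surgery records keeps its eight pre-surgery measures and gets
  `NA` in the six post-surgery columns.
* Measures are carried at full precision; rounding to one decimal is purely
  a reporting concern.

CPP supports three scorings — pre-test subtraction (the primary measure),
vehicle-compartment subtraction, and the proportion of time in the
drug-paired compartment among the two conditioning compartments — because
the choice materially affects conclusions when animals drift toward the
neutral center compartment during extended testing.

## Group statistics

All tests return `(statistic, df, two-tailed p)` uniformly. Choices that
pin down the printed degrees of freedom:

* The unpaired test is the pooled-variance Student t ($df = n_1 + n_2 - 2$),
  not Welch.
* The within-subjects ANOVA partitions total SS into subjects, sessions and
  error, with $F = MS_{sessions} / MS_{error}$ on $(k-1), (k-1)(n-1)$ df and
  **no sphericity correction** — hence integer df such as $F_{3,42}$ at
  $n = 15, k = 4$ and $F_{7,98}$ for eight CPP tests.
* Mann–Whitney uses the normal approximation with midrank ties,
  tie-corrected variance and no continuity correction, reporting Z.
* Correlation p values use the exact t transform
  $t = r\sqrt{n-2}/\sqrt{1-r^2}$; with pairwise-complete data the per-pair
  $n$ feeds the transform.
* Nothing is corrected for multiple testing; p values are reported raw.

The sham-vs-CCI comparisons switch from the pooled t to Mann–Whitney for a
measure whenever either surgery group fails Shapiro–Wilk at $p < 0.05$.
This codifies as a policy what a case-by-case analysis does by hand.

## Data reduction

The correlation matrix over chosen measure columns is displayed in
*angular order of the eigenvectors* (AOE): each measure is mapped to the
angle $\mathrm{atan2}(e_{2i}, e_{1i})$ of its loadings on the two leading
eigenvectors, and measures are sorted by angle so strongly inter-correlated
measures sit adjacently. Eigenvector signs are fixed by flipping any leading
eigenvector whose entries sum to a negative value, making the order
deterministic; a fully uncorrelated matrix keeps input order.

Distances are $d = 1 - |r|$: directionality is deliberately discarded so
that strongly anti-correlated measures are *close*. This matrix is
generally **not Euclidean**, so classical (Torgerson) MDS — double-center
the squared distances, eigendecompose, scale eigenvectors by root
eigenvalues — cannot reproduce it exactly in two dimensions. The maximum
absolute reconstruction error is therefore computed and reported with every
run rather than hidden (typical values on eight-measure panels are
0.3–0.5). Axis signs are fixed so the largest-magnitude coordinate on each
axis is positive. Negative eigenvalues are dropped; if fewer positive
eigenvalues than requested dimensions exist, fewer axes are returned with a
warning (a zero-distance matrix returns a single zero axis).

K-means runs on the 2-D MDS coordinates (the reduction output), not on the
distance matrix. The implementation is Lloyd's algorithm with greedy
spread-out (farthest-first) seeding from a random initial point, the best of
`restarts` runs by within-cluster SS kept, empty clusters refilled with the
farthest point, and labels canonicalized by first appearance. Within-cluster
SS is non-increasing across iterations by construction, and the whole
procedure is deterministic for a fixed seed.

The cluster count is chosen by a **four-index vote** over a configured range
(2–6 for the eight pre-surgery measures, 2–4 for the combined
fourteen-measure panel): mean silhouette width (max), Calinski–Harabasz
(max), Davies–Bouldin (min) and Dunn (max). Each index votes for its best
k; the majority wins; all ties break toward the smallest k. The four
indices were chosen to span the max-type and min-type internal-validity
families while staying fully documented — a deliberate replacement for a
thirty-index library vote, which reports only the winner anyway.

## The synthetic cohort generator

Eight per-animal latent traits are drawn from a multivariate normal with
configurable means, SDs and correlation (via a symmetric
eigendecomposition factor, so exactly singular correlation matrices are
accepted). Each trait is expressed in the units of the measure it drives,
and the session-level model maps traits to records linearly wherever
possible so that the measure pipeline inverts the generator:

* reflex trials: $\mathrm{clip}(\text{basal latency} - \text{decline}\cdot(s-1) + \varepsilon,\ 5,\ 20)$ s,
  with the clip applied per trial, mirroring the apparatus cutoff;
* vehicle counts: negative-binomial with mean
  $\text{basal loco} - \text{habituation}^2 (s-1)$ — the habituation trait
  enters squared so the planted value is recovered exactly on the
  square-root scale;
* drug counts: vehicle mean plus acute boost plus sensitization slope
  $\times (s-1)$, floored at zero;
* place tests: drug-compartment time
  $= \text{pre-test time} + \text{CPP strength} - \text{extinction rate}\cdot(\text{day}-17) + \varepsilon$,
  a linearly drifting center time, vehicle time as the remainder, the triple
  clipped at zero and renormalized to the 1200 s test length;
* a balanced sham/CCI assignment (alternating with a seed-derived phase) and
  post-surgery sessions in which only CCI animals lose `cci_effect_s`
  seconds from the surgeried paw.

Default trait means are anchored to the reported group means (18.7 s basal
latency declining to 16.7 s; 675 counts basal locomotion; acute drug
response ≈ 442 counts; sensitization ≈ 104 counts/session; extinction
4.4 s/day; pre-test 393.4 s) and trait SDs to the between-animal SDs implied
by the reported SEMs at $n = 15$. The default latent correlation embeds the
headline associations (−0.7 between basal latency and sensitization,
positive loco–habituation and sensitization–extinction correlations) and is
positive definite by construction.

Per-animal variance components are not reported anywhere, so the sampling
noise levels are the package's own choice, made once by a design
calculation: trial noise 0.5 s, count overdispersion 0.002 (variance
$\mu + 0.002\mu^2$), place-test noise 30 s — small enough that
between-animal trait variance dominates measurement error, the regime a
study detecting significant correlations at $n = 15$ must have been in.
One global seed drives per-animal, per-phase substreams, so enlarging a
cohort leaves existing animals' records bit-identical.

**Determinism at zero noise.** With `count_dispersion = 0` the generator
emits expected counts as real numbers rather than Poisson draws. This makes
the noise-free regime exactly invertible (slopes recovered to numerical
tolerance), at the price that the "counts are integers" property holds only
for sampled (dispersion > 0) data — a deliberate trade in favor of exact
round-trip testing.

## What the synthetic data do and do not establish

The generator emulates the *structure* of the study — phase timings,
bounded latencies, overdispersed counts, compositional place tests, balanced
surgery arms — but real data differ in ways the tests cannot speak to:
non-Gaussian trait distributions, within-session time courses, sex and age
effects (the study pooled sexes), handling effects on locomotion, and any
nonlinearity in how traits express across sessions. Passing recovery tests
therefore demonstrates that the *pipeline* is correct and stable, not that
the biological conclusions would replicate.

Two structural effects discovered during validation are worth knowing:

* **Censoring attenuation.** Under the paper-anchored trait SDs, the
  apparatus constraints themselves — the 20 s latency ceiling (the basal
  latency mean of 18.7 s sits close to it), the zero floor on counts with an
  acute-response SD of ≈ 594 counts, and the 1200 s composition of place
  tests — censor a few percent of extreme animals and attenuate
  derived-measure correlations by up to ≈ 0.08 below the planted latent
  values. Real instruments impose the same ceilings, so reported
  correlations in such designs are plausibly attenuated too. The
  correlation-recovery test suite consequently verifies the derivation
  machinery in a censoring-free trait regime at the same noise levels.
* **MDS degeneracy for equidistant blocks.** Four equally-inter-correlated
  measure blocks put their centroids on a regular 3-simplex; the
  double-centered matrix then has three equal eigenvalues and the 2-D
  projection direction is arbitrary, sometimes collapsing two blocks.
  Recovery of a four-cluster panel is therefore tested with heterogeneous
  between-block correlations (a planar block geometry), which is also what
  real measure panels look like.

## Numerical and degenerate-input choices

* OLS requires two distinct abscissae; constant series give slope 0.
* A constant sample is a hard error for Shapiro–Wilk, Pearson and the
  variance-based tests, except that an all-equal sample *at the hypothesized
  mean* (or identical groups) is reported as statistic 0, p = 1 — the
  natural limit of a null effect, needed so fully null synthetic cohorts
  produce a clean null battery.
* Within the ANOVA, session and error sums of squares at rounding level
  ($\le 10^{-12}\,\Sigma y^2$) are treated as exact zeros.
* `p_from_r(±1, n)` returns the boundary value 0.
* k-means ties (equal distances, equal inertia across restarts) resolve to
  the lowest index / earliest restart; the index vote resolves toward the
  smallest k.
* Problem sizes in the test suite — cohorts of 200 animals, 50–100 seeds for
  recovery properties, 20 restarts-per-k of at most six clusters on at most
  fourteen points — were chosen so the full suite exercises every stage in a
  few minutes on one core.

## Known limitations

* The Shapiro–Wilk implementation is the standard Royston approximation;
  borderline samples can differ from other implementations in the third
  decimal of W.
* The four-index vote is a documented stand-in for a broader index library;
  on weakly structured small panels (e.g. a single 15-animal cohort) the
  voted k is unstable, as script `analysis/04_cluster_measures.R` notes.
* No non-metric MDS, hierarchical clustering or bootstrap cluster-stability
  analysis; no pharmacokinetics; no sex-specific modeling.
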