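---
title: "Measuring social selection on arrival timing in winter bird networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring social selection on arrival timing in winter bird networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

In many territorial birds, individuals that settle in the study area early
gain familiarity, dominance and first pick of breeding sites, so late
arrival is selected against. But the *cost* of arriving late may depend on
who a bird ends up associating with: a late arriver surrounded by even
later arrivals is, locally, an early bird. `socsel` implements the full
analytical chain needed to ask whether the phenotypic composition of an
individual's social neighbourhood modulates selection on its own phenotype,
using winter feeder-visitation networks of RFID-tagged great tits as the
motivating system.

## The model

Write $z_i$ for individual $i$'s standardized arrival week (first sampling
week in which it was detected, z-scored with the population
divide-by-$n$ standard deviation so the phenotypic variance is $P = 1$
exactly), and $w_i \in \{0, 1\}$ for whether it acquired a breeding
territory the following spring. The social environment of $i$ is the
edge-weighted mean trait of its associates,
$\bar z_i = \sum_k \omega_{ik} z_k / \sum_k \omega_{ik}$,
with $\omega_{ik}$ the association weight. Gradients are estimated by the
multiple regression

$$w_i = \alpha + \beta_N z_i + \beta_S \bar z_i + \varepsilon_i,$$

fitted with a binomial error distribution (logit link) because fitness is
binary; a Gaussian option on relative fitness $w_i / \bar w$ gives the
classical linear selection-gradient analysis. Total selection on the trait
combines the nonsocial gradient with the selection transmitted through
phenotypic assortment:

$$s = P\,\beta_N + C^I \beta_S,$$

where $C^I$, the covariance of interacting phenotypes, is estimated by the
weighted assortativity coefficient of the trait on the association
network: the $\omega$-weighted Pearson correlation between the trait values
at the two ends of each edge, with every undirected edge contributing both
orientations so the measure is symmetric and lies in $[-1, 1]$. Positive
assortment plus a positive social gradient yields a positive
$C^I \beta_S$ term that can offset negative direct selection
($P\beta_N < 0$) on late arrival.

## From detections to networks

Associations are built by the gambit of the group: all individuals in the
same gathering event (flock) are taken to be associating.

* **Event detection.** Detection streams are segmented per location-day.
  The default detector starts a new event when the gap between consecutive
  reads exceeds `max_gap_s` (600 s); it is deterministic, fast, and exact
  when visitation is bursty. A BIC-selected one-dimensional Gaussian
  mixture (`method = "gmm"`, via mclust, components merged when their means
  are closer than `max_gap_s`) is provided for streams where bursts overlap.
  Downstream statistics consume only event membership, so the two detectors
  are interchangeable whenever they recover the same flocks.
* **Association index.** The simple ratio index
  $\omega_{AB} = x / (x + y)$, with $x$ the number of events containing
  both individuals and $y$ the number containing exactly one, estimates
  the probability that the two are found in the same flock. No edge
  thresholding is applied; field networks of this kind are sparse
  (densities around 0.06–0.08) without it.
* **Standardization scope.** The trait is standardized over *all*
  networked individuals (adults and juveniles), because the social
  environment $\bar z_i$ draws on the whole roster, while the selection
  regression is fitted on juveniles only — first-winter birds are the
  cohort for which territory acquisition is the relevant fitness measure
  and prior-residence effects of adult breeders are excluded. A flag allows
  juvenile-only standardization.

## Permutation null models

Whether assortment exceeds chance is judged against data-stream
permutations: a serial Markov chain of checkerboard swaps on the
group-by-individual matrix. A swap picks two events and two individuals
such that each individual sits in exactly one of the two events and
exchanges them, conserving all group sizes and every individual's number of
observations by construction. The upper-tail p-value uses the add-one
correction $(\#\{r_\mathrm{null} \ge r_\mathrm{obs}\} + 1)/(n_\mathrm{perm} + 1)$.

Three chain choices matter and are exposed:

* **Strata.** Swaps can be restricted to events sharing a stratum. The
  conservative default is location × sampling-day, which preserves all
  spatiotemporal structure. Note what this implies: each feeder's daily
  trait composition is held fixed, so the stratified null tests *within-
  feeder* association preference and is blind to spatial assortment.
  Restricting by day only (any feeder) randomizes space while still
  respecting arrival censoring — an individual is never moved into a day
  before its first detection — and is the appropriate null when the
  question is whether phenotypes are spatially assorted. Day-only swaps do
  break site fidelity, which makes them mildly anticonservative for
  site-faithful species; both options are deliberate, documented choices
  rather than a single hidden default.
* **Chain length.** The recorded permutations form a serial chain
  (`n_swaps` accepted swaps between records, default 1, with a burn-in of
  1000 accepted swaps). For calibration experiments we scale the burn-in
  to ten times the number of 1-entries of the matrix and thin by ten;
  mixing diagnostics on simulated data showed the fixed 1000-swap burn-in
  under-mixes matrices with more than a few thousand incidences, biasing
  p-values upward.
* **Uncertainty of the coefficient itself** is reported as a
  delete-one-edge jackknife standard error (the published coefficients
  carry SEs of ~0.003 at field scale; the method behind them is not
  specified, and the jackknife is the natural nonparametric choice; a
  bootstrap over events is a straightforward alternative).

### Arrival censoring is itself a source of assortment

A subtle property of gambit-of-the-group data deserves emphasis: because a
late arriver simply cannot co-occur with anyone before it arrives, pairs
with similar arrival times share more of their observation windows and
receive systematically higher simple-ratio weights. Raw weighted
assortativity on arrival time is therefore positive even when settlement is
completely random — in our simulations, coefficients of 0.2–0.35 arise with
*no* spatial assortment mechanism at all. This is precisely why the
package's tests assess the generator's null via permutation p-values
(which condition on observation counts and group sizes, and are uniform
under random settlement) rather than by expecting the raw coefficient to
vanish, and why empirical assortativity coefficients on arrival phenotypes
should always be interpreted against a data-stream null rather than
against zero.

## The synthetic-data generator

The generator produces populations with known ground truth under the
conditions the analysis assumes:

* **Two-wave arrivals.** A fraction `frac_early` (default 0.628) is
  present in week 1; the rest arrive on a discretised normal
  (mean 7.2 weeks, sd 3, clipped to `[2, n_weeks]`). The default sd of 3
  weeks was chosen so that roughly a tenth of all birds arrive in the
  final month of a 14-week winter, the magnitude of a late second wave.
* **Brood and year effects on the observed scale.** A single latent
  standard-normal arrival propensity per bird drives both wave membership
  (threshold at `qnorm(frac_early)`) and late timing. `brood_var_frac`
  (default 0.12) and `year_var_frac` (default 0.027) are defined as
  fractions of *arrival-week* variance; the generator calibrates the
  latent variance shares by closed-form truncated-normal moment matching
  (solved with `uniroot` at configuration time) so the realized week-scale
  fractions equal the configured ones. The calibration is the design's
  central choice: a naive additive construction — an independent Bernoulli
  early wave plus brood intercepts on late weeks only — attenuates a 0.12
  brood fraction to roughly 0.01–0.04 on the week scale because the point
  mass at week 1 carries no brood signal, making the parameter's name a
  lie. Tying both mixture components to one latent propensity is also the
  biologically coherent reading: broods that produce summer-resident
  (early) birds are the same broods whose late members return sooner.
  Rounding to whole weeks still costs a few percent of signal, which is
  why recovery tests accept a band around the nominal fraction.
* **Spatial assortment by settlement.** Feeders live on a square grid
  (default 65 feeders at 250 m — an idealisation of a stratified field
  grid with unpublished coordinates) with lognormal baseline
  attractiveness. The first wave settles by attractiveness alone;
  newcomers additionally avoid occupied feeders with strength
  `spatial_assortment_strength`, the mechanism by which later arrivals end
  up in low-density areas. Strength 0 makes settlement independent of
  phenotype; strength ~2–3 produces clearly detectable spatial assortment.
* **Bursty visitation.** Per feeder-day, a Poisson number of gathering
  events (default mean 40, matching ~74k events over 65 feeders × 28
  sampling days at field scale) occurs at near-regular jittered times;
  members are drawn from the feeder's local pool (home birds weighted 1,
  birds homed at adjacent feeders 0.15) among those already arrived, and
  each member is detected at the event time plus 20 s Gaussian jitter.
  Event spacing (~15 min at default intensity) comfortably exceeds the
  600 s gap threshold, so the default detector recovers the true flocks
  almost perfectly (adjusted Rand index ≥ 0.9 is asserted in the tests).
* **Fitness.** `bred ~ Bernoulli(plogis(alpha + beta_N z + beta_S zbar))`
  with the generating gradients stored for recovery tests; defaults
  (`alpha = -0.62`, about a third of juveniles succeeding, `beta_N = -0.8`,
  `beta_S = 1.1`) mirror the magnitude and signs of published estimates.
  Breeders then take the nearest unoccupied nest box to their home feeder,
  earlier arrivals choosing first.

What the generator does **not** emulate: mortality and within-winter
turnover (home feeders are fixed for a winter), dominance interactions,
mate choice, detection failure (every flock member is read), and the
spatial autocorrelation of habitat quality beyond feeder attractiveness.
Passing recovery tests on these simulations therefore demonstrates the
correctness of the estimators under the stated generative assumptions, not
robustness to the observation problems of real field data.

## Variance components for natal brood

Brood-level effects on arrival are quantified with an intercept-only
Gaussian model with crossed random intercepts for natal brood and year,
fitted by maximum likelihood with a parameter-expanded EM algorithm
(PX-EM). Plain EM is painfully slow exactly when a component is weakly
identified — with three year levels the year variance moves by ~1e-7 per
iteration near the optimum — whereas the expansion step rescales each
random-effect block each iteration and converges in tens of iterations.
Convergence is declared when the log-likelihood changes by less than 1e-8
(cap 500 iterations); estimates match `lme4::lmer(..., REML = FALSE)` to
four significant figures in the test suite, and the one-way balanced case
agrees with the ANOVA method-of-moments estimator. Components are floored
at zero; a design with one individual per brood triggers a
non-identifiability warning. REML would remove the small downward bias of
ML variance estimates but changes nothing at the tested scales; it is noted
as an extension.

## Breeding geography and competition

* **Connected vs non-connected dyads.** Over all unordered pairs of
  breeders in the network, the Euclidean distance between breeding boxes
  is compared between pairs ever observed together and pairs never
  observed together, with a Welch t-test (a pooled-variance option
  exists; Welch is the safer default where the paper-level method is
  unspecified). Dyads sharing a box (mates, distance 0) are excluded by
  default. Dyadic non-independence is deliberately left uncorrected — the
  test reproduces the published procedure and should be read as
  descriptive.
* **Edge-weight–distance slope.** OLS of dyadic breeding distance on edge
  weight over connected pairs, tested against `n_rand` datasets in which
  every breeder independently draws a uniformly random box from the full
  box list (with replacement across breeders; an exclusive-assignment
  option exists). The lower-tail randomization p asks whether stronger
  associates breed closer than box geography alone predicts.
* **Competition index.** Each box maps to its nearest feeder. An
  individual's time budget over feeders (the proportion of its detections
  at each) defines local population sizes; dividing by the number of used
  boxes serving each feeder gives local competition, and the
  time-weighted average over an individual's range gives its competition
  index. With a single feeder this collapses to birds-per-box for
  everyone, the global ratio printed in population summaries. Detections
  are the only time-use proxy available, and "boxes used" defaults to
  boxes with a breeding attempt, matching the procedure's wording; an
  all-boxes option exists.

## Numerical and interface choices

* Ties in nearest-feeder and nearest-box assignment break by lowest
  identifier; breeders choose boxes in arrival order.
* The swap chain rejects proposals until a checkerboard is found and
  reports a degenerate matrix after two million consecutive rejections.
* `standardize()` errors on constant input; the assortativity coefficient
  errors (rather than returning NaN) on edgeless networks or zero
  endpoint-trait variance; isolates carry `NA` social environments and are
  excluded (and counted) by the gradient fit.
* Orchestration: `run_pipeline()` executes simulate → events → GBI →
  network → assortativity (+ permutations) → standardize → social
  environment → gradients → decomposition → spatial tests → competition →
  brood variance, writes one JSON report per stage plus a summary table
  (cohort sizes, juvenile percentage, gradients with SEs and p-values,
  $C^I$, $P\beta_N$, $C^I\beta_S$, $s$), and derives per-stage child seeds
  from the global seed so stages can be re-run reproducibly. The package
  is an analysis library: the exported functions and `run_pipeline()` are
  the interface, with a thin optional script in `inst/scripts/`.

## Problem sizes used in the test suite

The validation experiments run at deliberately reduced scale, chosen so
each question is answered with adequate power by a compact simulation:
permutation calibration uses 100 winters of ~80 birds on 4 feeders with
200 recorded permutations each; gradient recovery uses 100 cohorts of
5000 birds with sparse simulated partner networks; brood recovery uses 50
replicates of three annual cohorts totalling ~200 broods of 6; spatial
tests use a 300-bird, 9-feeder winter with 500 box randomizations. The
field-scale magnitudes (74k events × 1053 birds) are exercised only where
scale itself is the property under test (sparse GBI construction).

## Known limitations

* The simple ratio index treats detection as perfect; with missed reads a
  corrected index would be needed.
* Raw assortativity on arrival time inherits the censoring bias described
  above; only permutation-referenced conclusions are safe.
* The decomposition multiplies logit-scale gradients by $P$ and $C^I$
  exactly as published selection analyses of this design do; no
  transformation to a linear-scale selection differential is attempted, so
  $s$ is comparable across cohorts analysed the same way rather than an
  absolute differential.
* Dyadic tests ignore the non-independence of pairs sharing an individual.
* The permutation p-value is one-tailed (upper) by design; disassortment
  would need the lower tail.
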