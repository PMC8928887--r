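---
title: "Methods: the allometric diet breadth model and its ABC parameterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the allometric diet breadth model and its ABC parameterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The foraging model

The allometric diet breadth model (ADBM) predicts the diet of every consumer
in a community from body masses alone. It assumes a foraging predator is
either searching for or handling prey, and that a consumer's optimal diet —
the prey set maximizing its energy intake rate — is the set of realized
trophic links. Four per-pair quantities are built allometrically from masses
$M_i$ (prey) and $M_j$ (consumer), in grams:

* energy content $E_i = e\,M_i$ (energy),
* prey density $N_i = n\,M_i^{n_i}$ with $n_i = -3/4$, the metabolic scaling
  of abundance with body mass (individuals per unit area or volume),
* space clearance (attack) rate $A_{ij} = a\,M_i^{a_i} M_j^{a_j}$ (area or
  volume per time),
* handling time $H_{ij} = h / (b - M_i/M_j)$ when $M_i/M_j < b$, and
  $H_{ij} = \infty$ otherwise (time). The threshold $b$ on the prey/predator
  mass ratio is the single most structurally important parameter: it bounds
  the feasible prey-size window and sets the most profitable prey size
  ($b M_j / 2$, from the maximum of the concave profitability parabola).

`optimal_diet()` implements the contingency model: rank feasible prey by
decreasing profitability $P_{ij} = E_i / H_{ij}$ and add them while the next
item's profitability strictly exceeds the intake rate of the diet so far,

$$R(D) = \frac{\sum_{i \in D} \lambda_{ij} E_i}{1 + \sum_{i \in D} \lambda_{ij} H_{ij}},
\qquad \lambda_{ij} = A_{ij} N_i ,$$

stopping at the first exclusion. Because the profitability rule and the rate
are those of the classical contingency model, the greedy prefix is the global
maximizer of $R$; the test suite verifies this against an exhaustive-subset
oracle for $S \le 8$. Two structural consequences follow and are also tested
as properties: every diet is a prefix of the profitability ranking, and —
because $P$ is a concave parabola in prey mass — every diet is contiguous in
prey-size order. The model therefore cannot predict size-discontiguous diets;
when observed diets have gaps in the size axis, the fitted model necessarily
over-predicts links, which is the mechanism behind connectance estimates that
exceed the observed value.

### Parameters

Free parameters, estimated by ABC: the space-clearance constant $a > 0$, the
prey- and predator-mass exponents $a_i$ and $a_j$ (dimensionless), and the
ratio threshold $b > 0$ (dimensionless). Fixed constants: $e = n = h = 1$ and
$n_i = -3/4$. Fixing $e$, $n$, $h$ loses no generality for structure: the
predicted web depends on $n$, $a$, $h$ only through the product $n a h$ (an
invariance the tests assert by scaling $n$ by $c$ and $a$ by $1/c$), and $e$
rescales profitability and intake rate identically, leaving every inclusion
decision unchanged.

Numerical notes: attack-rate powers are evaluated in log space
($\exp(\log a + a_i \log M_i + a_j \log M_j)$), so communities spanning ten or
more orders of magnitude in mass do not overflow double precision; infinite
handling times are stored as `+Inf`, never as a large sentinel; profitability
ties are broken toward the smaller prey, then label order (the community is
canonically sorted by non-decreasing mass with label-order tie-breaks), making
predictions fully deterministic. Cannibalism is evaluated like any other link:
the self-ratio is 1, so a self-link is feasible only when $b > 1$.

## The distance: 1 − TSS

Fit is measured with the true skill statistic over all $S^2$ cells of the
predation matrix (diagonal included, consistent with counting $S^2$ potential
links):

$$\mathrm{TSS} = \frac{TP \cdot TN - FP \cdot FN}{(TP+FN)(FP+TN)} \in [-1, 1],$$

and the ABC distance is $1 - \mathrm{TSS} \in [0, 2]$. TSS rewards correctly
predicted absences as well as presences, so the number of links — hence
connectance — is estimated rather than fixed. When observed connectance is
below 0.5 the statistic implicitly weights a link presence more than an
absence, which is appropriate: observing a feeding event is unambiguous
evidence of a link, while not observing one is weak evidence of absence.
TSS is undefined for degenerate observations (no links, or no absences);
`true_skill_statistic()` raises an error there rather than inventing a value,
since such webs are outside the method's domain. The numerator is computed in
exact (integer-valued double) arithmetic before the single division.

## Rejection ABC

`rejection_abc()` draws $\theta = (\log_{10} a, a_i, a_j, \log_{10} b)$ from
independent uniform priors, predicts the web, computes $d = 1 - \mathrm{TSS}$,
and accepts with probability equal to the normalized Epanechnikov kernel
$K(d)/K(0) = 1 - (d/\mathrm{tol})^2$ for $d \le \mathrm{tol}$ (0 beyond), via
a uniform variate per proposal. Acceptance is certain at $d = 0$ and
impossible at $d \ge \mathrm{tol}$. A single seeded RNG stream drives the four
parameter draws and the acceptance uniform in a fixed interleaved order, so
every run is bitwise reproducible from its seed; and because the ADBM is
deterministic, every accepted sample's distance and connectance regenerate
exactly from its stored parameters (asserted in the tests). Runs that exhaust
`max_attempts` (default $10^6$) fail with the minimum distance seen, which
diagnoses a threshold below the model's attainable distance — for a given web
there is a floor on $1-\mathrm{TSS}$ set by the contiguous-diet constraint.

### Priors

Defaults: $a_i \sim U(-1.5, 1.5)$, $a_j \sim U(0, 3)$ (ranges consistent with
empirical estimates of attack-rate scaling), $\log_{10} b \sim U(-15, 15)$
(mass ratios in a community spanning $10^{-8}$–$10^6$ g range over
$10^{\pm 14}$), and $\log_{10} a \sim U(-12, 10)$. The upper bound 10 reflects
that small $a$ is favored when fitting (lower attack rate raises connectance);
the lower bound is web-specific. `elicit_a_lower_bound()` proposes it by
scanning the best attainable TSS (maximized over a shared set of probe draws
of the other three parameters) on a grid of $\log_{10} a$ and returning the
largest grid value such that restricting the prior to $[\text{bound},
\max(\text{grid})]$ loses less than a plateau tolerance (default 0.02 TSS) of
the best TSS anywhere on the grid — i.e. extending the prior further down
gains essentially nothing. If even the bottom of the grid is still gaining,
no plateau was found: the function warns and returns the grid minimum.

### Threshold selection

`select_threshold()` implements the connectance criterion: the chosen `tol`
is the smallest value on an ascending grid at which the interval of accepted
predicted-connectance values contains the observed connectance. The "range"
is by default a central 95% interval (a min–max option exists); the coverage
level and grid are configuration knobs since neither is canonical. For
efficiency one large reference sample of (parameters, distance, connectance)
is drawn once and re-filtered per grid value with kernel-weighted acceptance,
reusing one acceptance uniform per draw; acceptance sets are then nested
across thresholds — harmless for independent proposals and it makes the
interval-width-vs-tol relationship monotone by construction under the min–max
option. A grid value needs at least `min_accept` acceptances (default 20)
before its interval is trusted, which also keeps the subsequent full run's
acceptance rate workable.

### Posterior outputs

Accepted samples are stored on the sampling scale (`log10_a`, `ai`, `aj`,
`log10_b`) with their distance, TSS and predicted connectance.
`summarize_posterior()` reports means and central intervals — credible for
parameters, posterior-predictive for TSS and connectance — using type-1
(inverse-ECDF) quantiles so the endpoints are observed sample values and match
a sort-based computation exactly; `level = 1` gives the min–max range.
`posterior_predictive()` regenerates all accepted webs and aggregates the
per-pair link frequencies, the histogram of link counts (summing to $S^2$)
and the number of never-predicted pairs.

## Structural properties

`structural_properties()` computes eleven metrics. Where the field has
competing definitions the package fixes one explicitly rather than chasing
numeric parity with any particular implementation:

* basal / intermediate / top classified from resource and consumer sets with
  self-links ignored, exhaustively (proportions sum to 1; an isolated species
  counts as basal);
* herbivores: consumers whose resources are all basal;
* omnivory: shortest-path trophic levels (basal = 1; otherwise 1 + shortest
  directed path to a basal species); a consumer's omnivory is the standard
  deviation of its resources' levels, 0 for a single resource (a deliberate
  choice where `sd()` of one value would be `NA`); mean over consumers;
  undefined when no basal species exists;
* clustering: average local clustering on the undirected simple projection,
  degree-deficient vertices contributing 0;
* sd of generality/vulnerability: sample sd of degree counts normalized by
  $L/S$, self-links included (consistent with $S^2$ potential links);
* diet similarity: mean pairwise Jaccard similarity of resource sets, with two
  empty diets counting as identical;
* mean path length: over ordered reachable pairs of distinct species,
  directed resource-to-consumer; undefined if no pair is reachable;
* nestedness: NODF on the 0–100 scale (via `vegan::nestednodf`); undefined
  for an empty web.

Undefined values are returned as `NA` markers. `standardized_errors()` divides
each property's absolute error by the maximum absolute error for that property
across the predicted set (all-zero error columns standardize to 0, not 0/0),
drops properties undefined in the observation, excludes per-web undefined
values pairwise, and averages per web. Mean and maximum trophic level are
deliberately not computed (path explosion on dense webs); the standardized
errors therefore typically exclude omnivory and path length for webs where
they are undefined, mirroring standard practice.

## The synthetic benchmark

`generate_community()` draws masses i.i.d. log-uniform over a configurable
interval — the simplest emulator of empirical communities whose masses span
many orders of magnitude. The packaged default scenario (read from
`extdata/default_scenario.yaml` so every test shares one baseline) uses
$S = 20$, $\log_{10} M \in (-6, 2)$, truth $\log_{10} a = -3$,
$a_i = a_j = 0.5$, $b = 0.1$, removal probability $q = 0.2$: a mid-sized
community whose truth web has connectance ≈ 0.17, inside the empirical range.
`generate_truth()` wraps the deterministic model, giving gold-standard webs
with known parameters; `degrade_web()` deletes each link independently with
probability $q$ (the simplest under-sampling model; effort- or
abundance-stratified deletion is out of scope). `recovery_experiment()` runs
the full loop — degrade, select threshold, fit, posterior-predict — and
reports TSS against the undegraded truth, estimated versus degraded and true
connectance, and credible-interval coverage of the generating parameters.

What passing these benchmarks does **not** show about real data: synthetic
truths are generated by the model itself, so diets are perfectly contiguous
in size and body mass is the only trait; real webs contain size-discontiguous
diets, interaction types that are weakly size-structured (parasitism,
terrestrial herbivory), and observation error that is not i.i.d. per link.
Recovery performance here is therefore an upper bound on what to expect
empirically.

## Problem sizes and reproducibility

The shipped tests run the full inference at $S = 20$ with 200 acceptances per
run (20 replicates for parameter-recovery coverage, 10 for the under-sampling
direction) and a 2000-draw reference sample for threshold selection — sizes
at which the posterior behavior of interest (coverage of $\log_{10} b$, its
relative narrowness, connectance over-estimation under link deletion) is
already stable across seeds. Production fits should use the default 1000
acceptances. All stochastic entry points (generators, sampler, threshold and
elicitation scans) take explicit integer seeds; the ADBM itself is
deterministic, so everything downstream of the accepted parameters is exactly
regenerable.

## Known limitations

* Body mass is the only trait; discontiguous diets are unrepresentable, so
  over-prediction of links against gappy observed diets is structural.
* No observation model: the fit cannot separate "link absent" from "link
  unobserved" except through the TSS's implicit weighting.
* Pure rejection sampling only; with very tight thresholds the acceptance
  rate can be impractically low (the sampler fails informatively rather than
  degrading silently).
* Property definitions are fixed choices among field variants; values are
  comparable within this package but not guaranteed to match other software
  numerically.
* TSS is undefined for observed webs with connectance 0 or 1, and the
  threshold-selection scan needs enough kernel-weighted acceptances at some
  grid value to form an interval.
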