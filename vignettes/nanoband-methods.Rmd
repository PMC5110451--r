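---
title: "Bayesian-network control banding: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian-network control banding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoband)
```

## The model

`nanoband` treats occupational nanomaterial risk as inference in a discrete
Bayesian network. Every variable is categorical or a discretized continuous
quantity; the joint distribution factorises into one conditional probability
table (CPT) per node given its parents. Risk characterisation runs in four
steps: hazard identification (evidence entered on physicochemical nodes),
dose-response (an occupational exposure limit, OEL), exposure assessment
(the posterior over airborne-concentration bins) and risk characterisation
(the hazard quotient HQ = concentration / OEL, in percent, mapped to a
control band). The inflection between acceptable and potentially risky is
HQ = 100%, applied strictly: 100% exactly is still "caution".

Assumptions worth stating plainly:

* **Discreteness.** Continuous quantities (concentration, OEL) live on
  labelled bins. Concentration uses width-growing bins
  (`make_concentration_bins()`, geometric width growth) because airborne
  values concentrate at the left tail; finer granularity there costs nothing
  at the right tail. Bins are half-open `[lo, hi)` with the final bin closed
  so the upper edge is assignable — a convention, stated so
  `assign_bin()` is deterministic at edges.
* **Bin representatives.** When a distribution over bins must act like a
  distribution over numbers (means, ratios), each positive bin is
  represented by its geometric midpoint `sqrt(lo*hi)`; a bin touching zero
  uses the arithmetic midpoint, where the geometric one is undefined. On
  ratio scales this is less biased than arithmetic midpoints.
* **Independence in the ratio.** The HQ distribution multiplies the exposure
  and OEL posteriors as if independent. Given evidence on the
  physicochemical block (in particular CMR and the parents of
  concentration), the two nodes are close to d-separated in the shipped
  structure; residual dependence is ignored. This is an approximation, not
  a theorem about arbitrary networks.
* **MCAR missingness.** EM's E-step conditions each row on its observed
  cells, which yields consistent estimates when cells go missing
  independently of their values. Literature-compiled tables plausibly
  violate this (informative missingness); no MAR/MNAR correction is
  attempted.

## Inference

Production queries use variable elimination with a min-fill elimination
order and lexicographic tie-breaks, making results deterministic. A
brute-force joint-enumeration oracle (`joint_enumeration()`, capped at 1e6
configurations) exists only for testing; the suite checks elimination
against it to 1e-9 on randomized networks. Evidence with zero probability
raises a dedicated condition (`nanoband_zero_evidence`) rather than
propagating NaN, so callers can distinguish impossible evidence from
numerical failure.

## Learning and experience

`em_fit()` computes exact expected sufficient statistics per row: rows are
grouped by their unique observed pattern and the joint over each group's
hidden variables is enumerated directly (the hidden sets are small at
realistic missingness; a size cap guards the pathological case). The M-step
sets each CPT row to `(expected counts + prior_strength) / normalizer`.

Parameters that matter:

* `prior_strength` (default 1, add-one smoothing): keeps cells away from
  exact zero, which would otherwise freeze EM (a zero stays zero under
  multiplicative updates). Set 0 for the pure maximum-likelihood estimate;
  with complete data that reproduces relative frequencies exactly.
* `tol` (default 1e-6) and `max_iter` (default 200): convergence is the
  relative change of the maximized objective. These are package defaults,
  chosen as conventional EM practice, not values taken from any data
  source.
* Initialization: the network's current CPTs. Exactly-uniform rows receive
  a seeded jitter of magnitude 0.01, because a perfectly symmetric start is
  a stationary point of EM.

The recorded trace is the objective EM actually ascends: the observed-data
log-likelihood plus, when `prior_strength > 0`, the Dirichlet term
`prior_strength * sum(log theta)`. Recording that objective (rather than
the bare likelihood) keeps the monotone-trace guarantee exact instead of
approximate; at `prior_strength = 0` the two coincide.

`update_with_cases()` implements confidence-weighted sequential updating:
CPT row × experience acts as Dirichlet pseudo-counts, new cases add their
(expected) counts, and experience accumulates the per-parent-configuration
case mass. Partially observed cases contribute fractional experience — each
case spreads its posterior mass across the parent configurations it might
occupy, consistent with expected sufficient statistics. Consequences the
tests assert: n complete cases into a zero-experience network leave total
experience n per variable; splitting a complete batch in two gives exactly
the concatenated result; and the more experience a row has, the less a
fixed new batch moves it.

## Dose-response and banding

`derive_oel()` composes documented factors: `POD / uncertainty_factor`
(default 100) for the threshold model; a further ×10 when the point of
departure is a LOAEL rather than a NOAEL; and a further ×10 in the linear
(CMR) mode, a deliberately simple stand-in for low-dose linear
extrapolation — a full slope-factor integration is an extension point, not
implemented. Alternatively the OEL can stay inside the network as a node
parameterized by CMR, in which case its posterior enters the HQ ratio as a
distribution and contributes to the interval width.

The control bands are negligible (≤ 10%), caution (10–100%], potential
risk (100–1000%] and high risk (> 1000%). Only the 100% inflection carries
scientific meaning (threshold exceedance); 10% and 1000% are reporting
conventions for heat-map granularity. The heat map places each forecast at
its mean OEL (x) and mean concentration (y) with dashed/solid segments for
the two 90% intervals. On heavily skewed posteriors (nearly all mass in one
bin) the discrete 90% interval can degenerate to a single representative
while the mean sits slightly off it; the point-inside-rectangle property is
therefore a property of reasonably symmetric posteriors, not of all inputs.

## The shipped networks and the synthetic generator

The shared 14-node structure carries the 12 characteristics, concentration
and OEL. Four links are fixed by the domain reasoning behind the tool:
aggregation → particle size, dispersibility → concentration, solubility →
concentration and CMR → OEL. Coating, pH and contamination are parentless
and uniform (the unbiased default when knowledge is lacking). Morphology is
also parentless but *not* uniform: it is material-intrinsic (CNTs are
fibrous), and no defensible parent exists for it in this block. The
remaining edges (coating/pH into aggregation, charge, solubility and
dispersibility; surface area and contamination into reactivity; morphology
and reactivity into CMR) are plausible editable defaults — the network is
data-driven via the JSON format, and nothing in the engine depends on this
particular layout.

The three materials share the structure and differ only in CPTs. Their
concentration and OEL parameterizations are lognormals discretized onto the
bins, centred so that mean HQ under empty evidence is ordered
TiO₂ < Ag < CNT by default (computed by the package itself: roughly 15%,
67% and 763%). That ordering matches the relative strictness of published
exposure recommendations for these materials (CNT limits are the most
stringent), but the direction is configurable (`hq_order`) because it is a
modelling choice, not an identity.

`generate_cases()` forward-samples complete cases in topological order and
masks cells independently (MCAR) at rate 0.3 by default, with the default
material row counts 46 (CNT), 39 (Ag) and 55 (TiO₂). Per-column missingness
weights are exposed (default uniform) since real literature gaps
concentrate on particular variables. What the generator deliberately does
*not* emulate: informative missingness, inter-study heterogeneity
(batch effects), measurement error in the recorded states, and any real
material's actual values. Passing tests on these fixtures therefore
demonstrates that the machinery is correct and calibrated under its own
assumptions — not that forecasts for real CNT exposure data are accurate.

## Calibration

`out_of_sample_check()` operationalizes predictive calibration: sample
fresh complete cases from the generating network, hide the concentration
bin, condition on everything else, and form the smallest posterior-mass set
reaching 0.90 (ties broken by state order). Discrete sets overshoot the
nominal mass, so a correctly specified model covers at *least* 90% — the
check is one-sided by construction. A uniform-CPT model also "covers", but
with near-vacuous sets; the reported mean set size flags that.

## Problem sizes and test design

The suite computes everything it asserts: oracle-equivalence sweeps use 100
random networks of up to 8 nodes; parameter recovery fits 5,000 rows of a
6-node ground truth at 30% missingness; the Monte-Carlo oracle for the HQ
forecaster uses 10⁶ draws; calibration uses 1,000 test cases. The 6-node
recovery truth is designed so every CPT row keeps comfortable sample
support after masking (skewed rows, minimum parent-configuration support
around a fifth of the sample): a per-row total-variation bound of 0.05 is a
roughly 3-sigma statement there, i.e. a real failure signal rather than a
coin flip over sampling noise.

## Known limitations

* Exact inference and exact E-steps limit network size; that is the scope
  of this tool (control-banding networks are small), and no approximate
  inference is provided.
* The Results-style hazard quotient (exposure / OEL) is used throughout and
  reported under both names; the older margin-of-exposure convention
  (NOAEL / predicted dose) is the reciprocal, and users comparing against
  that convention must invert.
* The linear dose-response mode is an effective divisor, not a slope-factor
  integral.
* Structure learning is out of scope: the graph is expert-specified, edited
  through the JSON network format. XMLBIF export preserves structure and
  CPTs only (no bin edges, tags or experience).
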