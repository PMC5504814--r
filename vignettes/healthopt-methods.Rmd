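---
title: "Methods: preference-weighted ranking, evidence pooling and single-subject analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preference-weighted ranking, evidence pooling and single-subject analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthopt)
```

`healthopt` is the computational core of a personal health-optimization
system for long-term conditions: a decision engine that ranks treatment
options by combining a patient's preference weights with performance
estimates from research, the clinician and the patient's own
self-monitoring, plus the longitudinal (n-of-1) machinery needed to keep
those estimates current. This vignette documents the models, the tunable
parameters and the design choices — including the places where the design
space was genuinely open and a convention had to be fixed.

## The decision model

An authored **condition template** holds treatment options, outcomes,
ratings and an attribute dictionary. All performance ratings live on a
common **0–100 scale with 100 = best attainable on that outcome**. The
scale is a package convention: it matches common MCDA dashboard practice,
and mapping every instrument onto it keeps weights interpretable across
outcomes. Instrument values map linearly; for lower-is-better outcomes
(weight gain, tremor) the map is mirrored so improvement is always an
increase in rating. `rating_to_instrument()` is the exact inverse, and a
round-trip property test holds to 1e-9.

Personalization rules (contraindications, outcome relevance) are
restricted to **AND-of-ORs of atomic comparisons** over declared patient
attributes. The restriction is deliberate: it is expressive enough for
clinical contraindication logic (severe renal impairment OR lithium
allergy excludes lithium) while remaining auditable and exhaustively
testable against a truth-table oracle. Two related conventions matter for
safety and predictability:

* a **missing profile attribute is an error**, never "rule false" —
  silently retaining a contraindicated drug is the dangerous failure
  mode;
* an outcome with no relevance rule is **relevant by default**; rules are
  the tested path for irrelevance (manual deselection would live in a UI
  layer, out of scope here).

A template is *complete* when a research rating exists for every
(option, outcome) pair — `n_options × n_outcomes` ratings; the packaged
demo template (17 options × 7 outcomes, 119 ratings, labelled synthetic
because its numbers are illustrative) exercises this at realistic scale.

## Ranking: expected value and confidence index

For retained outcomes `k` with normalized weights
`w_k = raw_k / Σ raw` (raw importances 0–100, elicitation UI out of
scope), options are scored by the weighted additive value model

* `EV(o) = Σ_k w_k s_ok` — expected value, 0–100;
* `CI(o) = Σ_k w_k c_ok` — confidence index, 0–1, the same weighted
  aggregation applied to the evidence-quality confidences.

These two formulas are the normative definitions for this package. The
confidence index is **displayed alongside** the expected value rather
than multiplied into it, so the ranking semantics stay transparent; a
confidence-adjusted ranking by `EV · CI` exists behind the explicit
`confidence_adjusted` flag of `rank_options()` (default off) for users
who want uncertainty to discount the ranking directly. Ties break by
higher CI, then lexicographic option id — determinism is a requirement,
not an afterthought, because what-if exploration compares rankings.

Properties guaranteed by construction and enforced by tests: scale
invariance in the raw importances; EV/CI inside the convex hull of their
inputs; a dominating option ranks first under every weight vector
(checked on a full 0.05-step simplex grid); agreement with an independent
brute-force implementation to 1e-9 on thousands of random models.

## Evidence integration

Patient and clinician observations for an (option, outcome) pair are
reduced to a mean rating and standard error (`sd/√n`) and pooled with the
research default by **fixed-effect inverse-variance pooling**:
`weight_i ∝ 1/se_i²`, `pooled_se = (Σ 1/se_i²)^(-1/2)`. Pooling is
permutation-invariant and contracts uncertainty (`pooled_se ≤ min se`).
Three parameters shape the pool, all in rating points and all
configurable:

* `se_floor = 2.5` — minimum SE of any source estimate. Without it a
  single self-report (or a zero-variance streak from a patient who
  always enters the same number) would carry infinite weight and
  overwhelm research evidence.
* `(se_min, se_max) = (2.5, 25)` — authored research confidence `c` maps
  to `se = se_max(1−c) + se_min·c`, so full confidence equals the
  tightest admissible patient estimate and zero confidence is treated as
  a ±25-point guess.
* pooled confidence `= clamp(1 − pooled_se/se_max, 0, 1)` — the
  complement of the same SE scale, so pooling and the confidence index
  stay mutually consistent: more or tighter evidence always reads as
  higher confidence.

Retrospective observations (about past treatments) pool identically but
are flagged in provenance; no recency weighting is applied by default.
Updating never changes the retained option/outcome sets — filtering is
`personalize()`'s job — and evidence referencing removed options is
ignored with a logged note rather than an error.

With these defaults, the patient's own data dominate quickly: at noise
SD 8 an option tried for two weeks already pools with ≈98% patient
weight against a weak (c ≈ 0.3) research default. That is intended
behaviour for an n-of-1 system: research defaults are priors for options
the patient has not tried.

## Single-subject analytics

Treatment-plan periods are **half-open intervals `[start, end)`**;
an observation dated exactly on a switch day belongs to the new plan.
The convention had to be fixed somewhere (timeline displays usually mark
switches without saying which side owns the day); half-open intervals
make periods partition time with no gaps or double-assignment, which the
tests exploit as a conservation property.

Per phase the package reports n, mean, SD and an OLS trend slope of
rating on day index. No autocorrelation correction is applied to the
slope — a documented limitation: day-to-day mood data are positively
autocorrelated, so the slope's *standard error* (not reported) would be
optimistic, while the slope itself remains unbiased.

The non-overlap effect measure is **NAP (non-overlap of all pairs)**:
all baseline × phase pairs are compared on the rating scale, ties credit
0.5, so `nap = (improving + 0.5·ties)/pairs`. NAP was chosen over
alternatives (PND, Tau-U, randomization tests) because it is
assumption-light, robust to non-normality, and brute-force verifiable by
enumeration; randomization tests are an explicit non-goal. For tie-free
data `nap(A,B) + nap(B,A) = 1`. On simulated data where treatment truly
improves the outcome by 2σ, mean NAP across 200 replicates exceeds 0.85.

Dosage effects group a single option's phases by dose label (ordered by
numeric prefix when parseable); life-event effects compare observations
inside the union of post-event windows against the background complement,
never double-counting under overlapping windows. The daily timeline
export carries explicit nulls for days without data and reconciles, row
by row, with phase segmentation and adherence.

## Adherence and alerts

Schedules expand deterministically: 08:00 for once daily, 08:00/20:00
for twice daily, evenly spaced between those anchors otherwise — pure
convention, configurable in the plan row. A taken intake event counts
toward the **nearest same-day slot of the same option not yet matched**;
unmatched events are logged, never counted, keeping rates in [0, 100] and
order-invariant. Monitoring fidelity applies the same matching at
day-level granularity to scheduled self-reports.

Alert rules fire **strictly below** threshold ("dropped below"):
boundary equality does not fire, and raising a threshold can only add
alerts (monotonicity, tested). Improvement snippets evaluate the trailing
14 days against a rule table shipped as editable CSV with default bands
at 90/75/50% (on-track / nudge / warning / urgent); one snippet per
metric, ordered by severity then metric name, with a single "on track"
message when nothing lags.

## The simulator and what passing tests mean

The synthetic-patient generator defines the study conditions for every
end-to-end check. Defaults: 5 options × 3 outcomes; true mean ratings
70 for the best option and a **10-point gap** to the runner-up; AR(1)
daily noise with innovation SD **σ = 8** and ρ = 0.3 (mood persists
day to day; ρ = 0.3 is a modest, defensible persistence for daily
self-ratings); adherence probability 0.9; one **30-day phase** per
option; research defaults displaced from truth by N(0, 8) per cell with
authored confidence 0.7; optional Poisson life events with linearly
decaying shifts. Non-adherent days revert to the untreated mean (40)
immediately — no pharmacokinetic carryover, the simplest defensible
default. One outcome uses a mirrored 0–10 instrument so polarity
rescaling is exercised inside the loop.

`recovery_experiment()` runs simulate → personalize → integrate → rank
per replicate and records whether rank 1 equals the truly best option
under the stated weights, against the baseline of ranking on the biased
research defaults alone. At the default conditions with 200 replicates
the integrated loop recovers the best option essentially always while
defaults-only ranking errs in a noticeable minority of replicates, and
recovery is non-decreasing in days per phase over {10, 30, 90} (checked
with common template seeds per replicate). Problem sizes used in the
test suite — ≤6×6 models for oracle equivalence, ~30 observations per
phase, 200 replicates for stochastic checks — were chosen as the scale
at which these systems actually operate.

What the simulator does **not** emulate: clinically calibrated bipolar
course dynamics (episode alternation, mania/depression asymmetry),
dropout, measurement reactivity, or informative missingness. Passing
recovery tests therefore show that the pipeline's arithmetic and pooling
behave correctly under honest noise — not that real patients' data will
identify the best treatment at these rates.

## Numerical and interface choices

* Weights must cover exactly the model's retained outcomes; mismatches
  are errors, not silent renormalizations.
* All-zero importance vectors are rejected ("no preferences expressed").
* JSON documents use UTF-8, lowercase token ids (`[a-z0-9_]+`),
  ISO-8601 dates; writers are read-back stable (round-trip tested on
  fuzzed documents). Validation reports structural problems as error
  lists, never crashes.
* Degenerate inputs follow "empty is absent, not an error" where the
  quantity is a summary (empty phase → n = 0 row; no planned slots →
  NA rate) and "error" where a decision would otherwise be made on
  nothing (empty pooling input, empty NAP phase, all options removed).

## Known limitations

Fixed-effect pooling assumes all sources estimate the same quantity for
this patient; a clinician's population-informed estimate and the
patient's own data are treated symmetrically given their SEs. The OLS
trend ignores autocorrelation. The rule language cannot express
cross-attribute arithmetic (e.g. age × dose interactions). The adherence
matcher is greedy per event; with multiple same-day slots and irregular
taken times a globally optimal assignment could differ by one match in
pathological cases.
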