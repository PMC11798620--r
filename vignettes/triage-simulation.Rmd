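---
title: "Simulating scarce-resource triage protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating scarce-resource triage protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triagesim)
```

## The model

`triagesim` simulates a single round of ventilator allocation under crisis
standards of care. The world it models: a hospital with a fixed number of
free ventilators, a cohort of critically ill adults all needing ventilation
*now*, and a triage protocol that must decide who receives one. The package
treats a protocol as a declarative rule set evaluated in three stages.

**1. Exclusion screening.** A patient is removed from eligibility when
their coded comorbidity is on the protocol's exclusion list, when their
SOFA total crosses the protocol's severity threshold (encoded as an
explicit comparator plus cutoff, because source protocols mix strict and
inclusive bounds — e.g. `SOFA > 14` versus `SOFA ≥ 10`), or when an
NE-style qualification bar (`qualify only if SOFA < c`) is missed.

**2. Priority scoring.** Eligible patients receive an additive integer
score: SOFA-band points + comorbidity points (assigned per severity class
`none` / `minor` / `severe_life_limiting`, with per-code overrides for
protocols that treat a condition unusually) + age-band points + a
non-positive pregnancy modifier. Lower score = higher priority, uniformly;
protocols whose sources orient the scale the other way are re-oriented in
their configuration, so a single comparator serves the whole package. A
protocol with a frontline *exemption* policy diverts healthcare workers and
first responders around scoring entirely. Every score carries an itemized
trace, and the invariant `score == sum(terms)` is enforced in the tests —
the audit trail is the reproducible analogue of two investigators checking
each other's manual protocol applications.

**3. Capacity-constrained allocation.** Priority groups are served in
order: frontline-exempt patients first (they consume capacity — exempted
workers are guaranteed treatment, not merely favoured), then equal-score
groups ascending. A group that fits the remaining capacity is wholly
allocated. A group straddling the boundary is resolved by the protocol's
tie-break chain — `younger_age`, `frontline`, `fcfs` (ascending arrival
rank), `lottery` (uniform draw without replacement) — each step
discriminating only among patients still tied after earlier steps. Losing
a straddling group's tie-break yields the distinct outcome `tied_lost`
(`**`); patients in groups wholly beyond capacity are simply
`not_allocated` (`O`). If the chain is empty or exhausted with the
boundary still tied, the entire straddling group becomes
`qualified_undetermined` (`*`) and *no* ventilator is assigned from it or
from any lower group — allocating past an unresolved tie would let a
lower-priority patient leapfrog a higher-priority one.

The NE-style configuration (qualification cutoff, no scoring, no
tie-break) is the degenerate case: all qualifiers form one
undifferentiated group, so at any capacity below the group size everyone
stays `qualified_undetermined` and zero ventilators are assigned. We encode
"undetermined" as genuinely undefined rather than as an implicit lottery;
a user wanting the lottery reading as a sensitivity analysis can load the
NE config and set `tiebreak_chain <- "lottery"` — the behaviour is a
configuration, not a hard-coded special case.

## The SOFA calculator

The protocols consume SOFA (Sequential Organ Failure Assessment) totals:
six organ-system subscores 0–4 summing to 0–24. The demonstration cohort
ships with totals only (no underlying vitals or labs exist for it), so the
calculator is validated against the standard published threshold table,
not against the cohort. That table ships as a versioned CSV
(`inst/extdata/sofa_thresholds.csv`, intervals `[lower, upper)`) so an
alternative dialect can be swapped in. Conventions adopted: respiration
subscores 3–4 assume ventilatory support (true by construction for a
cohort needing ventilation); cardiovascular scores 2–4 come from the
vasopressor tier (dopamine ≤ 5 / ≤ 15 / > 15 µg/kg/min; any dobutamine;
epinephrine or norepinephrine ≤ 0.1 / > 0.1 µg/kg/min) and override mean
arterial pressure; renal scoring takes the worse of the creatinine and
24-h urine-output criteria.

## Calibration: reconstructing under-specified protocols

The six source protocols are described qualitatively — which components
they use, a few cutoffs, who tie-breaks how — but not with exact point
values. The shipped configurations are therefore *calibrated*: an
exhaustive grid search (`calibrate()`) over bounded discrete neighbourhoods
of plausible parameterizations, constrained to reproduce the reference
allocation grid (`reference_allocation()`, patients 1–8) exactly. Design
choices that follow from making the search a trustworthy oracle:

* plain enumeration, no pruning and no heuristic optimizer — completeness
  over the grid is the point, and grids are small by construction
  (a configurable cap, default 10^6, refuses larger grids with the count);
* the result is always the full solution *set*: under-determined targets
  legitimately admit many parameterizations (e.g. exclusion cutoffs that
  only differ for patients the target marks `O` either way), and hiding
  that non-uniqueness would overstate what the reference grid pins down;
* comparison is restricted to the patients named in the target, which is
  how the grid accommodates the reference table's missing ninth patient.

Two reference-grid tensions are worth knowing. The qualitative narrative
lists metastatic cancer among commonly cited exclusions for MD-style
protocols, yet the reference grid allocates the metastatic-cancer patient
under MD; the calibration follows the grid (MD does not exclude metastatic
cancer). And the MD/NY severity cutoffs are encoded exactly as stated
(`> 14`, `> 11`) even though nearby values reproduce the same grid — the
stated values are preferred wherever the target cannot discriminate.

## The demonstration cohort and its arrival order

The nine-patient cohort spans ages 27–92, SOFA 2–14, one pregnant
patient (30 weeks), one nurse and one firefighter, and one low-SES flag.
Socioeconomic status and insurance are carried as metadata and consumed by
no rule — the simulated patients are all insured residents, and the flag
exists so that downstream equity analyses *could* stratify on it. No
arrival timestamps exist, so first-come-first-served needs an assumption:
the default order is ids 1, 2, 3, 5, 6, 7, 8, 9, 4 (patient 4 presents
last), calibrated so FCFS tie-breaks reproduce the reference grid, and
overridable per scenario (`scenario_config(arrival_order = ...)`).
Patient 9 (75 F, heart failure class IV, SOFA 8) has no reference
outcomes; her simulated outcomes are reported but never asserted against
the grid. She does qualify under NE (SOFA 8 < 10), so the full-cohort
NE count of qualified-undetermined patients is six, versus five among the
eight reference rows.

## Concordance: what "the same results" means

Two protocols are compared at two levels. *Set identity*: the same
patients receive definitive allocations. *Vector identity*: the full
five-valued status vectors (`allocated`, `tied_lost`,
`qualified_undetermined`, `not_allocated`, `excluded`) agree for every
patient. The distinction is not pedantic: PA and FL allocate to the same
three patients on the demonstration cohort, but FL reaches that set by
excluding six patients while PA excludes no one — identical symbols,
different reasons, different behaviour on any other cohort. The headline
claim that no two protocols agree holds at the vector level and is
reported alongside the set-level caveat, never silently merged with it.

## Chance analysis

`chance_analysis()` estimates per-patient allocation probability when the
chance elements are randomized: lottery draws, the arrival order
(uniformly permuted, making FCFS a lottery in disguise), or both. A single
seeded RNG stream drives all replicates — one long, well-tested
Mersenne-Twister stream rather than thousands of freshly seeded short
ones — so runs are reproducible from one master seed. Standard errors use
the binomial formula; the exact oracle for a g-way tie over k units is the
hypergeometric inclusion probability k/g, and the test suite checks the
empirical probabilities against it over 10,000 replicates. Exclusions and
scores are deterministic, so an excluded patient's estimate is exactly 0,
and expected ventilators used per replicate bounds the probability total.

## The synthetic generator

`generate_cohort()` emulates the demonstration cohort's *structure*, for
stress-testing the rule engine and allocator on arbitrary cohorts: adult
ages (default range 27–92, the fixture span), SOFA totals from a
configurable distribution (default uniform on 0–24 — the fixture is too
small to estimate a shape, and uniform exercises every band), single
coded comorbidities with fixture-informed prevalences (40% none, 25%
controlled hypertension, 10% dementia, 7% ESRD, 7% metastatic cancer, 5%
late-stage MS, 6% heart failure IV), pregnancy at rate 0.10 among females
18–45, a 0.20 frontline fraction, 0.10 low-SES rate, and a uniformly
random arrival order. These defaults were chosen once, from the fixture's
composition, and are not tuned.

What the generator does *not* emulate — and therefore what a green
property test does not establish: correlation between age, comorbidity and
SOFA (real ICU cohorts have plenty), multi-morbidity, longitudinal
deterioration, or arrival-time structure (low-SES patients arriving later
is precisely the disparity the FCFS critique worries about, and the
generator draws arrival independently of SES). Property tests over random
cohorts certify the machinery's invariants — conservation of capacity, no
leapfrogging, determinism under a fixed seed — not epidemiological realism.

## Numerical and degenerate-input choices

* Scores, cutoffs and band edges are integers throughout; there is no
  floating-point tie ambiguity. Lottery keys are `runif` draws, distinct
  with probability one.
* `tied_lost` applies only at the capacity boundary: a fully allocated
  group's internal ties are never "lost", matching the outcome symbols'
  semantics.
* Zero capacity allocates nothing but preserves status semantics
  (excluded stays `excluded`, NE qualifiers stay `*`).
* An empty cohort yields an empty ranking and an empty matrix; a
  zero-patient generator config yields an empty cohort.
* Patients whose SOFA or age falls outside a protocol's band coverage
  raise a configuration error rather than scoring silently — bands must
  cover whatever the exclusion rules let through.
* Scenario seeds drive every lottery; identical scenario + seed gives
  bit-identical outcomes, including which tie-break step is recorded.

## Limitations

A single allocation round: no reassessment, withdrawal, or patient
turnover, and one resource type. One comorbidity per patient. Six
protocols as configured in their early-pandemic versions, reconstructed
from qualitative descriptions rather than transcribed from the source
documents — the calibration guarantees reference-grid fidelity, not
clause-level fidelity. And the demonstration cohort is nine mock patients;
every headline number in this package is a property of that stated world,
not an estimate about any real patient population.
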