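# triagesim

Simulation of crisis-standards-of-care triage: rule-based scarce-resource
allocation (SRA) protocols applied to critically ill patients competing for
a limited number of ventilators.

## The problem

When demand for life-saving resources exceeds supply, hospitals activate
SRA protocols that decide who receives care. These protocols are defined by
state governments or hospital systems and vary widely: some exclude
patients with severe comorbidities or high illness severity outright, some
assign multi-principle priority scores, some favour the young, the
pregnant, or frontline workers, and ties at the capacity boundary are
broken by first-come-first-served queues or randomized lotteries — or not
at all. `triagesim` makes this variation computable. It represents each
protocol as a declarative rule set, applies it to a patient cohort under a
fixed ventilator capacity, and quantifies how much of a patient's fate is
protocol choice and how much is chance.

The severity input common to all protocols is the SOFA score (Sequential
Organ Failure Assessment): six organ-system subscores of 0–4
(respiration, coagulation, liver, cardiovascular, CNS, renal) summing to a
0–24 total, lower meaning less organ failure.

A protocol rule set combines, in package notation:

* **exclusion screening** — excluded iff comorbidity ∈ exclusion list, or
  SOFA crosses a comparator + cutoff (e.g. `> 14`, `≥ 10`), or an
  NE-style qualification bar (`qualify iff SOFA < c`) is missed;
* **priority score** — `score = sofa_band(SOFA) + comorbidity_points +
  age_band(age) + pregnancy_modifier`, lower = higher priority;
* **frontline policy** — ignored, tie-break-only, or full exemption
  (frontline workers receive ventilators before any scoring);
* **tie-break chain** — an ordered subset of `younger_age`, `frontline`,
  `fcfs`, `lottery` applied only to the priority group straddling the
  remaining capacity. An empty/exhausted chain leaves the whole straddling
  group *qualified-undetermined*: no ventilator can be assigned from it.

Six calibrated protocol configurations (ids `MD`, `PA`, `FL`, `NY`, `CA`,
`NE`) ship with the package, together with a nine-patient demonstration
cohort, a reference allocation grid, a synthetic cohort generator, a
Monte-Carlo chance analysis, and an exhaustive grid-search calibrator that
reconstructs under-specified protocol parameters from a target allocation
column.

## Worked example

Three ventilators remain for nine patients; run all six protocols:

```r
library(triagesim)
run <- run_scenario(ventilators = 3, seed = 17)
as.data.frame(run$matrix)
#>   id age    sex sofa  MD  PA  FL  NY  CA NE
#> 1  1  45 female   14   O   O   O   O ***  O
#> 2  2  65   male   10   O   O   O   O   O  O
#> 3  3  27 female   10 ***   O   O   O ***  O
#> 4  4  50   male    6   O *** ***  **   O  *
#> 5  5  92   male    4  ** *** *** ***   O  *
#> 6  6  40   male    8 ***   O   O   O   O  *
#> 7  7  28 female    5 *** *** *** *** *** *
#> 8  8  57   male    2   O   O   O ***   O  *
#> 9  9  75 female    8   O   O   O   O   O  *
```

`***` = allocated a ventilator, `**` = tied at the boundary but lost the
tie-break, `*` = qualified but the protocol gives no way to decide
(NE specifies no tie-break, so it assigns nothing), `O` = no ventilator
(excluded or outscored). Patient 7 (28 F, SOFA 5, no comorbidity) is
allocated under five of six protocols; the pregnant patient 3 only under
the two protocols that subtract points for pregnancy (MD, CA); patient 8
(late-stage MS, SOFA 2) is excluded by FL's comorbidity list yet allocated
under NY, which screens on SOFA alone.

```r
run$concordance
#> <sra_concordance> 15 protocol pair(s): 0 vector-identical, 1 set-identical
```

No two protocols produce the same outcome vector. PA and FL do allocate to
the same three patients (the one set-identical pair) while disagreeing on
*why* every other patient went without — exclusion versus outscoring.

How much is luck? Randomize the arrival order under NY, whose four
top-group patients tie for three ventilators and are ordered
first-come-first-served:

```r
chance_analysis(fixture_cohort(), "NY", scenario_config(),
                n_reps = 10000, seed = 17, randomize = "arrival")
#>   id   prob     se n_reps
#>    4 0.7490 0.0043  10000
#>    5 0.7530 0.0043  10000
#>    7 0.7454 0.0044  10000
#>    8 0.7526 0.0043  10000   (others exactly 0)
```

Each tied patient's survival chance is the combinatorial 3/4 — a lottery
in all but name.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch — the demonstration cohort under
all six shipped protocols at capacity 3, the concordance report,
per-patient allocation counts, and a 10,000-replicate chance analysis —
logging the allocation matrix and headline counts, and writes the JSON
result file to `--out`.

## Command line

A thin wrapper ships as `exec/triagesim`:

```sh
triagesim simulate --protocols all --ventilators 3 --seed 17 --out out/
triagesim calibrate --protocols MD --out out/calib
triagesim generate-cohort --n 20 --seed 1 --out out/
```

See `vignettes/triage-simulation.Rmd` for the model, calibration
methodology, and limitations.
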