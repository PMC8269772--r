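---
title: "Simulating computerised logMAR acuity testing and its agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating computerised logMAR acuity testing and its agreement statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acuitysim)
library(dplyr)
```

## The measurement problem

Visual acuity is the clinical endpoint of most ophthalmic care, and
telemedicine pushes its measurement onto whatever screen a patient has at
home. A computerised logMAR test displays size-calibrated, crowded letters
on a screen at a known viewing distance, adapts letter size to the
patient's responses, and scores the result in 0.02 logMAR units (one
letter). Before such a test can replace an in-clinic measurement, two
statistical questions must be answered: is there a systematic difference
(bias) between settings, and how repeatable is each setting (test-retest
variability, TRV)?

`acuitysim` implements the full measurement pipeline on *simulated*
observers: the optotype geometry and screen calibration, the two-phase
adaptive staircase with single-letter scoring, configurable psychometric
observers as the synthetic data source, Bland-Altman agreement statistics,
and an end-to-end simulator of the 2x2 clinic/home by test/retest design.
No clinical data are included or reproduced; the simulator targets
structural fidelity of the procedure, not any particular patient cohort.

## Optotype geometry and calibration

A logMAR 0.0 optotype subtends 5 arcminutes at the eye; its stroke width is
one fifth of its height, and height scales as $10^{\mathrm{logMAR}}$. At a
viewing distance $d$ the physical height is $d\tan(5'\cdot
10^{\mathrm{logMAR}})$ — the exact tangent, not the small-angle
approximation, so results are stable across distances:

```{r}
letter_height_mm(0, 3000) # mm at 3 m
letter_height_mm(1, 3000) # one decade larger
```

Letters are modelled as 5x5 stroke-width squares (real letter sets vary
slightly in width; the square is a documented simplification that makes
every layout ratio exact). Crowded presentation spaces letters half a
letter width (2.5 strokes) apart and surrounds them with a crowding box one
stroke thick at 2.5 strokes from the letter borders, so a single crowded
letter occupies 12 strokes in each dimension and a five-letter line is 42
strokes wide:

```{r}
crowded_footprint(0, 3000, c(1, 5))
```

Physical sizing on an uncharacterised display comes from a calibration
cross: the software knows its length in internal units, the user measures
it with a ruler, and the ratio fixes the mm-per-unit scale. A
mis-measurement by factor $c$ scales every displayed letter by $c$, which
is an additive $\log_{10} c$ logMAR offset on every presented size — the
bridge between calibration error and acuity error used by the observer
module. Derived scales implying fewer than 20 or more than 600 units per
inch are flagged as implausible (gross mis-measurement) but not blocked,
since unusual hardware exists.

When a line is too wide for the presentation window it is broken greedily
into triplets, pairs or singles — five letters are always presented and
scored, and chunking never affects scoring. The feasibility calculator
reports the largest grid size whose single crowded letter fits a window
occupying a configurable linear fraction (default 2/3) of each dimension of
a 16:9 screen:

```{r}
max_testable_logmar(screen_spec(24), 3000)
```

Published device tables for comparable systems are not reproducible from
any single geometric rule (the required window assumptions are not stated
alongside them), so this calculator documents its own assumptions — square
letters, crowding box included, 2/3 linear window — and makes no claim to
match any published table.

## The staircase

The test has two phases. **Range finding** presents a single crowded
letter in 0.2 logMAR steps from 0.8: descending while responses are
correct, ascending from an incorrect start until one is recognised. The
smallest recognised size sets the thresholding start 0.2 logMAR above it.
**Thresholding** presents five crowded letters per line, descending in 0.1
logMAR steps until all five letters on one line are wrong. If the first
line already contains errors, larger lines are presented until one is fully
correct, and the descent resumes from there — sizes attempted during the
ascent are not re-presented; their recorded responses are reused, so no
size ever contributes more than five scored letters.

Scoring gives 0.02 logMAR credit per correct letter: the anchor is the
largest fully-correct line, and every correct letter at sizes strictly
below it subtracts 0.02,

$$\mathrm{VA} = \mathrm{anchor} - 0.02 \times \#\{\text{correct letters below anchor}\}.$$

The exact anchoring convention of the scoring is not uniquely determined by
a verbal description of "credit for each correct letter"; this convention
was chosen because `0.02 x 5 = 0.1` makes a fully-correct line worth
exactly one line step, so an all-or-none observer with threshold $t$ scores
exactly the smallest 0.1-grid size at or above $t$ — a property the test
suite verifies by a brute-force sweep of thresholds. All grid arithmetic is
carried in integer hundredths of a logMAR internally, so the quantisation
invariant (every score is an exact multiple of 0.02) holds exactly rather
than to floating-point tolerance.

```{r}
res <- run_test(deterministic_observer(0.30))
glance(res)
```

Boundary behaviour: completing the floor line (default -0.3) without
triggering the five-wrong criterion ends the test with full credit and
status `ok`; an observer that cannot produce a clean line by the ceiling
(default 1.6) is reported `off_scale_high` with no numeric score, and such
sessions are carried as flagged rows through every downstream summary. An
optional refresh (off by default) re-presents one letter per line when the
first response was an error, the replacement overwriting the original — a
model of the clinical practice of repeating a presentation after a
suspected attention lapse.

## Synthetic observers

The data generator is a forced-choice letter identification model. Per
letter at size $s$,

$$P(\text{correct}) = \gamma + (1 - \gamma - \lambda)\,
\mathrm{logistic}\big(\beta (s - t)\big),$$

with threshold $t$, slope $\beta$ (per logMAR), guessing floor $\gamma$
(default 0.1 — letter tests use a small alternative set, and the exact set
size is a parameter, not a constant) and lapse rate $\lambda$ (default
0.01). The logistic was chosen over a Weibull for its simple midpoint
semantics (performance halfway between floor and ceiling at $t$); the
observer interface hides the choice, so other shapes can be swapped in.
Responses within a line are independent — the simplest defensible model,
and a known limitation: real crowding and fatigue correlate errors within a
line, which would widen simulated TRV slightly.

Each observer draws from its own seeded RNG stream, so a transcript is
reproducible from parameters plus seed, and simulation code never perturbs
the caller's RNG state. The default slope of 30/logMAR gives a single-test
measurement SD of roughly 0.03-0.04 logMAR, in the range reported for
five-letter-per-line computerised tests.

Setting effects ("at home" versus "in clinic") are modelled abstractly by
`condition_effect()`: a multiplicative calibration error on displayed sizes
(acting as $+\log_{10} c$ logMAR on every presentation) and a per-session
threshold jitter SD capturing uncontrolled viewing conditions — screen
brightness, room lighting, seating distance error. Both observer models
depend on size only through $s - t$, so the session jitter is applied as an
equal-and-opposite shift of the evaluated size.

A note on limits: a very steep observer ($\beta \to \infty$) reduces to the
all-or-none step observer *only* when $\gamma = \lambda = 0$; with the
default rates, lapses and lucky guesses still move individual runs by a
letter or more regardless of slope, and only the modal measured VA matches
the step observer. The tests check both statements separately.

## Agreement statistics

`bland_altman()` summarises paired measurements by their differences
(first-listed minus second-listed): bias (mean difference), the $n-1$
sample SD, a t-based 95% CI of the mean, and 95% limits of agreement
defined as mean $\pm$ 2 SD. The multiplier is exactly 2 by default — the
definition used in the clinical TRV literature this package models — with
1.96 available by option. The CI uses the t distribution because at
$n \approx 36$ the difference from z is visible at the second decimal and
the t form is the defensible small-sample choice. A Shapiro-Wilk test of
the differences is reported as a diagnostic only, never as a gate, and a
constant difference vector is reported as degenerate rather than an error.
Results print at 2 decimals (the field's reporting precision) but retain
full precision internally.

```{r}
pairs <- readr::read_csv(
  system.file("extdata", "synthetic_pairs.csv", package = "acuitysim"),
  show_col_types = FALSE
)
ba <- bland_altman(pairs) # differences a - b
ba
subgroup_summaries(pairs, group = group)
```

Divided by 0.02, a logMAR difference reads out in ETDRS letters:
`logmar_to_letters(0.12)` is `r logmar_to_letters(0.12)` letters.

## The simulated 2x2 study

`simulate_study()` regenerates the validation design end to end: `n`
subjects (default 36, one worse eye each) with true thresholds drawn
uniformly over a configurable range (default $-0.14$ to $1.06$ logMAR —
uniform is a deliberate default; real cohorts are skewed toward good
acuity, and the distribution is pluggable), each tested twice in clinic and
twice at home through the full staircase with the setting's condition
effect. A configurable fraction (default 58%) is recorded as clinic-first;
order is recorded but not modelled, since no order effect is part of the
model. Per-session seeds derive from a documented hash of the master seed,
subject id, setting and test index, so any single transcript is
reproducible in isolation and the whole dataset is bit-identical under the
same configuration.

The home condition's default `threshold_jitter_sd = 0.04` logMAR is
illustrative, not an estimate from data: it is the between-session SD that
would roughly double a clinic-only difference SD of 0.03, the general
magnitude reported when home testing is compared with clinic testing. Users
studying a specific deployment should calibrate it themselves.

```{r}
sim <- simulate_study(study_config(n_subjects = 36, master_seed = 7))
summarize_study(sim) |>
  select(comparison, n, bias, sd, loa_low, loa_high) |>
  mutate(across(where(is.numeric) & !n, ~ round(.x, 3)))
```

`summarize_study()` produces the three standard comparisons — clinic vs
home (first tests), clinic TRV, home TRV — excluding a subject from a
comparison only when one of its two sessions is off-scale, and reporting a
comparison with fewer than two usable pairs as skipped.

## What passing tests do and do not show

The test suite verifies, among others: exactness of the staircase for
all-or-none observers over a fine threshold sweep; the scoring identity on
every transcript; mean threshold-recovery error within 0.05 logMAR for
psychometric observers (slope 30, 200 seeded runs per threshold on a 0.05
grid in [0, 1]); exact degeneracy of a zero-noise study; widening of home
TRV under home threshold jitter in at least 95 of 100 replicates at n = 36;
and equality of the Bland-Altman summary with direct formula evaluation to
1e-12 relative tolerance on 1000 random datasets. These problem sizes run
the whole suite in about two minutes on one core.

Passing them shows the *procedure* is implemented faithfully and the
statistics are numerically exact. It does not show that simulated TRV
matches any real cohort: that depends on psychometric parameters and
home-condition noise that the simulator deliberately exposes as
configuration with illustrative defaults, and on simplifications noted
above (independent responses within a line, square letters, uniform
threshold distribution, no order or learning effects, no rendering or
luminance modelling).
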