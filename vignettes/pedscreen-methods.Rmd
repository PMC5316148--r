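---
title: "Methods: simplified overweight screening and its validation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simplified overweight screening and its validation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedscreen)
```

## The screening problem

Overweight in school-age children (5–19 years) is defined against a growth
reference: a child is overweight when their BMI-for-age z-score exceeds +1 SD
for their sex and age. Applying that definition requires computing BMI and
consulting a reference table, which in busy primary-care or dental settings
is a documented barrier to screening. The simplified instrument this package
implements removes the arithmetic: two sex-specific lookup tables give, for
each half-year age row and each of 11 reference height percentile columns,
the *screening weight* — the weight at which a child of that height crosses
the +1 SD BMI-for-age cutoff. Screening then needs only raw weight and
height.

`pedscreen` implements both classification arms, the construction of the
tables from any LMS growth reference, the agreement statistics used to
validate the instrument against the direct method, and a synthetic cohort
generator so the whole pipeline can be exercised without patient data.

## The LMS model

A growth reference parameterizes the distribution of a measurement $x$
(BMI in kg/m², or height in cm) at each sex and age by three quantities:
a Box–Cox power $L$, the median $M$, and a coefficient of variation $S$.
The z-score of a measurement is

$$z = \frac{(x/M)^L - 1}{L\,S} \quad (L \neq 0), \qquad
  z = \frac{\ln(x/M)}{S} \quad (L = 0),$$

and the inverse — the measurement sitting at a given z — is
$x = M(1 + LSz)^{1/L}$ (or $M e^{Sz}$ at $L = 0$). Percentile values map
$p$ through the standard normal quantile to $z$ and apply the inverse.
These transforms (`lms_zscore()`, `lms_value_at_zscore()`,
`lms_value_at_percentile()`) are the machinery everything else stands on.

Numerical choices:

* **Branch switch at $|L| < 10^{-7}$.** The $L \neq 0$ formula suffers
  catastrophic cancellation as $L \to 0$; below the switch the exact
  log-normal branch is used. Tests check continuity across the switch to
  $10^{-5}$ and round-trip invertibility to $10^{-9}$ relative tolerance.
* **Age interpolation.** References are tabulated at integer months.
  Queries on the grid return the tabulated record exactly; off-grid ages
  get component-wise linear interpolation of $L$, $M$, $S$ between the
  bracketing months — the convention of common growth-chart software, and
  exact on the grid, which is all published worked examples exercise.
* **Domain errors**, not silent values, for $x \le 0$, percentiles outside
  $(0,100)$, ages outside the reference range, and z-scores outside the
  transform's support ($1 + LSz \le 0$). Biologically implausible
  $|z| > 5$ results are warned about but not altered: the classification
  rule sets no plausibility filter.

## The two classification arms

**Direct ("with BMI calculation").** BMI is weight in kg over squared
height in meters — `compute_bmi()` accepts height in cm, the stadiometer's
unit, and converts. (A child of 38 kg and 146.2 cm has BMI
$38/1.462^2 = 17.8$.) `classify_who()` compares BMI against the +1 SD
cutoff at the child's sex and completed-month age row; *strictly exceeding*
the cutoff is `unhealthy`, so a BMI exactly on the cutoff is `healthy`.
Age is completed months (floored), matching how a 10-year-2-month-old is
looked up in the 122-month row.

**Simplified ("without BMI calculation").** `build_screening_table()`
constructs, per sex, the grid over half-year age rows $a \in \{5.0, 5.5,
\dots, 19.0\}$ years and height percentile columns
$p \in \{1, 3, 5, 15, 25, 50, 75, 85, 95, 97, 99\}$:

$$h_{a,p} = \mathrm{HFA}^{-1}(p;\ 12a), \qquad
  w_{a,p} = \mathrm{BMI}^{+1\mathrm{SD}}(12a) \times (h_{a,p}/100)^2 .$$

Heights are rendered to 0.1 cm and weights to 0.1 kg (half-up), the
resolution of the measuring instruments. A child of exactly that age and
height crosses the overweight cutoff exactly at $w_{a,p}$.

`locate_grid_cells()` matches a child to the one exact row when their
completed-month age falls on the half-year grid, otherwise the two
bracketing rows; within each row, to the one exact column or the two
bracketing columns — 1 to 4 cells. `classify_simplified()` labels the
child `unhealthy` when their weight **reaches the minimum** matched grid
weight (a `>=` comparison).

Two deliberate asymmetries against the direct arm:

* **Minimum of the matched cells.** Bracketing rows sit at or below the
  child's age and the lower bracketing column below their height, so the
  minimum matched weight can only sit at or below the exact cutoff weight.
  This is what gives the instrument its screening sensitivity: every child
  the direct method flags is flagged here too, and borderline children
  just under the exact cutoff may be flagged *only* here. In the 2×2
  cross-classification this makes the simplified-healthy /
  direct-unhealthy cell structurally empty, which the test suite checks on
  20 independent synthetic cohorts.
* **`>=` at the grid versus strict `>` at the cutoff.** A weight landing
  exactly on a printed grid value counts as "placed within the screening
  unit grid"; a BMI exactly on the +1 SD curve does not "exceed" it. Both
  follow the instrument's stated decision rules; the only children the two
  readings can disagree on are those inside the 0.1 kg rounding band of a
  grid cell.

Heights outside a row's column span (below the 1st or above the 99th
reference percentile) are clamped to the edge column and flagged
(`below_span` / `above_span`). For a below-span child the edge column
*overstates* the true cutoff weight, so such a screening verdict should be
confirmed by direct BMI calculation; the flag is retained in the classified
output for exactly that purpose.

## Measurement protocol

`reconcile_readings()` encodes the duplicate-measurement rule used when
recording weight (and optionally height): two readings agreeing within
0.1 kg are recorded as their mean; otherwise a third is required and the
mean of the two closest readings is recorded. Two choices the protocol
statement leaves open are resolved as: the *mean* of two agreeing readings
(unbiased, and identical to either reading when they agree exactly), and
the mean of all three readings when the third is equidistant from both
earlier ones (symmetric, avoids an arbitrary pair choice). Recorded values
round half-up to 0.1, with a $10^{-8}$ guard so that binary representation
of values like 32.55 does not flip the half case downward.

## Agreement statistics

`crosstab()` cross-classifies the simplified labels against the direct
labels into counts $a$ (both unhealthy), $b$, $c$, $d$ (both healthy), and
`percent_agreement()` computes

$$\text{overall} = 100\frac{a+d}{n}, \qquad
  \text{positive} = 100\frac{a}{a+c}, \qquad
  \text{negative} = 100\frac{d}{b+d},$$

with the direct BMI-for-age method as the reference classification.
Percent agreement (rather than kappa) is the primary output because the
comparison is between two *implementations of the same definition*, where
chance-corrected agreement answers a different question; `cohen_kappa()`
is available as a supplementary statistic. Values are carried unrounded
and presented integer-rounded; an empty denominator makes the statistic
undefined (`NA`), never zero.

## The synthetic cohort generator

`generate_cohort()` emulates the population of the validation study the
pipeline was built for: $n = 168$ healthy 6–11 year olds in a university
dental clinic. Defaults: ages uniform on 72–143 completed months, 47.6%
female, BMI-for-age z-scores $\mathcal{N}(0.4, 1.0^2)$, height-for-age
z-scores $\mathcal{N}(0.2, 1.0^2)$, correlation 0.3. Each child's height
and BMI come from the inverse LMS transforms at their drawn z's, and
weight is *derived* as $\mathrm{BMI} \times (h/100)^2$ — simulating BMI
rather than weight guarantees the reported BMI-z marginal and keeps
weight–height coherence. Weight and height are then recorded at 0.1
resolution, like the field measurements.

Choices where the study conditions leave room:

* **Height-z mean 0.2** places mean height slightly above the reference
  median, consistent with the cohort's descriptive statistics; its SD and
  the 0.3 height–BMI z correlation are realistic defaults, configurable
  and not a claim about the original children.
* **Uniform ages** on the eligibility window approximate the reported
  mean ± SD of age; the true age distribution is unknown.
* **Instrument-measurable heights.** In the validation cohort every child
  was locatable in the screening tables (all 168 appear in the 2×2 table),
  so the emulated population constrains height z-scores, by rejection
  sampling, to the span of the tabulated percentile columns
  ($z \in [\Phi^{-1}(0.01), \Phi^{-1}(0.99)]$). Without this constraint
  roughly 2% of children would fall off the instrument's height columns,
  where clamping can break the sensitivity-dominance property — a real
  limitation of the instrument for extreme statures, documented above,
  but not a feature of the study population. The truncation perturbs the
  height-z moments by well under 0.05.
* **Welch's t-test** for the sex comparisons in `summarize_cohort()`:
  the robust default when the equal-variance variant is not stated.

What the generator does *not* emulate: the skewness of real BMI beyond
what the LMS transform induces, measurement error beyond 0.1-resolution
rounding, sociodemographic structure, and any real child's data. Passing
pipeline tests on synthetic cohorts therefore demonstrates the *structural*
properties of the method (sensitivity dominance, agreement bookkeeping,
reproducibility), not the empirical agreement level of any particular
clinic population.

The bundled `synthetic_reference()` is likewise a clearly labelled
synthetic stand-in: smooth spline LMS curves with the shape and scale of
school-age growth references, covering 60–228 months. It is not a
published table, and checks that pin published cutoff values (e.g. the
19.16 kg/m² boys' cutoff at 122 months) run only when the real reference
files are supplied via `load_who2007()`.

## Problem sizes and determinism

The test suite runs the property checks at desk scale: 1000-tuple LMS
round trips, 20 default cohorts of 168 for the dominance property, one
5000-child cohort for parameter recovery (3-standard-error bands), chosen
so the full suite completes in well under a minute. All randomness flows
from a single explicit seed per cohort (`cohort_spec(seed=)`); identical
specs reproduce byte-identical cohorts and pipeline outputs, which the
tests assert literally on the written files.

## Known limitations

* Below-span heights (under the 1st percentile column) make the clamped
  screening threshold an overestimate; the verdict is flagged for direct
  confirmation rather than corrected, because the instrument's user has no
  grid to read there.
* The instrument's published column layout ties heights to reference
  percentiles; if the original tables used interval midpoints instead,
  grid weights can differ by a few hundred grams. Table construction is
  therefore checked against published grid values only to ±0.2 kg.
* Only the binary healthy/overweight split at +1 SD is implemented
  (obesity at +2 SD as an optional annotation); thinness cutoffs and
  under-5 standards are out of scope.
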