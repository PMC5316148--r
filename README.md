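# pedscreen

Overweight screening for school-age children without BMI arithmetic, and
the statistics to validate it against the direct BMI-for-age method.

## The problem

The standard definition of overweight in 5–19 year olds is a BMI-for-age
z-score above +1 SD of a growth reference, under the LMS parametrization:
at each sex and age the reference gives a Box–Cox power *L*, median *M*
and coefficient of variation *S*, and

    z = ((x/M)^L − 1) / (L·S)   (L ≠ 0),    z = ln(x/M) / S   (L = 0).

Applying it requires computing BMI and consulting a table — a documented
barrier to screening in primary-care and dental settings. A simplified
instrument removes the arithmetic: two sex-specific tables give, for each
half-year age row *a* and each of 11 reference height percentile columns
*p*, the screening weight

    w(a, p) = BMI⁺¹ˢᴰ(12a months) × (h(a, p) / 100)² ,

the weight at which a child of that age and height crosses the +1 SD
cutoff. A practitioner finds the child's age row(s) and height column(s)
and compares raw weight against the matched grid cells; weight at or above
the minimum matched cell screens positive. `pedscreen` implements:

* the LMS machinery (z-scores, inverse, percentiles, age interpolation)
  and loaders for delimited LMS reference tables, including the published
  per-sex WHO 2007 layout (`load_who2007()`; those files are not bundled);
* both classifiers: `classify_who()` (direct, strict `>` at the cutoff)
  and `classify_simplified()` (table lookup, `>=` at the minimum matched
  grid weight), plus `build_screening_table()` to construct the tables
  from any LMS reference;
* duplicate-measurement reconciliation (`reconcile_readings()`);
* overall / positive / negative percent agreement on the 2×2
  cross-classification (`crosstab()`, `percent_agreement()`), with the
  direct method as reference: 100·(a+d)/n, 100·a/(a+c), 100·d/(b+d);
* a synthetic cohort generator (`generate_cohort()`) emulating a clinic
  population of 6–11 year olds, and `run_comparison()` to drive the whole
  validation pipeline with audit-ready outputs.

A clearly labelled synthetic reference (`synthetic_reference()`) with
realistic smooth LMS curves lets everything run without external data.

## Worked example

Build a boys' screening table, look up a 10-year-2-month-old (122 months)
measuring 146 cm, then run the full two-method comparison on a synthetic
cohort of 168 children:

```r
library(pedscreen)
bmi_ref <- synthetic_reference("bmi_for_age")
hfa_ref <- synthetic_reference("height_for_age")

tab <- build_screening_table(bmi_ref, hfa_ref, "male")
tab
#> <screening_table> male - 29 age rows ( 5 - 19 y ) x 11 height-percentile columns
#>   grid weights 16.6 - 92.5 kg

locate_grid_cells(tab, age_months = 122, height_cm = 146)
#> <grid_lookup> 4 matched cell(s), threshold 39.1 kg
#>  age_years percentile height_cm weight_kg
#>       10.0         85     144.6      39.1
#>       10.0         95     148.2      41.1
#>       10.5         75     145.1      40.1
#>       10.5         85     147.3      41.3

res <- run_comparison(spec = cohort_spec(n = 168, seed = 42),
                      bmi_ref = bmi_ref, height_ref = hfa_ref)
res$report
#> Weight status comparison (test vs reference method), n = 168
#>                  reference
#> test              unhealthy  healthy
#>   unhealthy n (%) 43 (25.60) 17 (10.12)
#>   healthy n (%)   0 (0.00)   108 (64.29)
#> Overall percent agreement  = 100% x 151/168 = 90% (89.88)
#> Positive percent agreement = 100% x 43/43 = 100% (100.00)
#> Negative percent agreement = 100% x 108/125 = 86% (86.40)
```

The lookup falls between the 10 and 10.5-year rows and between two height
columns in each, so four grid cells match; the decision threshold is their
minimum (39.1 kg — this boy screens positive only at or above that
weight). In the cohort comparison the simplified-healthy /
direct-unhealthy cell is 0: every child the direct BMI method flags is
also flagged by the table, because the minimum of the bracketing cells can
only sit at or below the exact cutoff weight. The children in cell *b*
(17 here) are borderline cases just under the cutoff that only the more
sensitive simplified instrument flags.

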