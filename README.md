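# rowemg

Evaluation of cyclic exercise — indoor rowing strokes — from raw two-muscle
surface electromyography (sEMG). The package is for exercise scientists,
coaches and biosignal engineers who have quadriceps + biceps sEMG of a
rowing piece and want an objective, per-individual account of how the
exercise was performed, plus a statistical comparison between groups (e.g.
athletes vs non-athletes).

## What it computes

From a raw recording the pipeline extracts a smoothed RMS activation
envelope, detects the exercise window automatically, and splits it into
stroke cycles at envelope minima whose topographic prominence (on the
max-normalized envelope) reaches 0.3. Cycle boundaries at times
`t_0 = a < t_1 < ... < t_Nc = b` give durations `tc[i]` with
`sum(tc) = tt = b - a` exactly. Per individual it then reports:

| quantity | definition |
|---|---|
| `tt`, `Nc` | training time and stroke count |
| `t_bar`, `sigma` | mean and sample SD of cycle durations (rhythm stability) |
| `a_hat`, `b_hat` | slope/intercept of the regression line `tc[i] ~ a_hat*i + b_hat` (rhythm drift) |
| `EM[i]` | per-cycle muscle energy, the trapezoidal integral of the cycle's envelope (uV·s) |
| fatigue % | `100*(tt - t_peak)/tt`, where `t_peak` is the maximum of a quadratic trend fitted to `EM` over time; 0 when the maximum falls at/after `tt` |
| peaks / order | per-cycle activation peaks and whether the biceps principal peak ever precedes the quadriceps peak (arms-before-legs error) |

Groups are compared per variable with Student's pooled-variance unpaired
t-test, `sp^2 = ((n1-1)s1^2 + (n2-1)s2^2)/(n1+n2-2)`,
`t = (m1-m2)/(sp*sqrt(1/n1+1/n2))` — computable from raw metrics or
directly from printed group means/SDs.

Because clinical recordings of this kind are not publicly deposited, the
package includes a fully seeded synthetic-signal generator
(band-limited noise amplitude-modulated by per-cycle burst envelopes, with
ground truth for every injected parameter) that makes the entire pipeline
testable end to end. See `vignettes/rowemg-methods.Rmd` for the model,
parameter rationale and limitations.

## Worked example

```r
library(rowemg)

# a synthetic "vigorous amateur": erratic rhythm, arms before legs, early fatigue
sim <- generate_recording(athlete_and_amateur_presets()$vigorous_amateur, seed = 4)
ana <- analyze_recording(sim$recording)
ana$report
#> <metrics_report> sim (non_athlete)
#>   tt = 71.55 s over Nc = 40 cycles; t_bar = 1.789 s, sigma = 0.212 s
#>   drift a_hat = +0.0075 s/cycle, fatigue = 56.2%
#>   phase-order violations: 40 / 40 cycles
#>   recommendations: rhythm_work, endurance_path
```

Reading: 40 strokes over 71.6 s; the 0.21 s cycle-time SD and +7.5 ms/cycle
drift say the rower could not hold a rhythm and was slowing; 56% of the
piece happened after peak muscle power (early fatigue); in every cycle the
biceps fired before the quadriceps. The advisory flags suggest rhythm work
and an endurance-oriented programme.

Group comparison from printed summary statistics (the bundled 8 + 5
reference cohort):

```r
cohort <- read.csv(system.file("extdata", "rowing_cohort_summary.csv", package = "rowemg"))
compare_from_summary(cohort)
#> <group_comparison> group1 vs group2 (n = 8, 5; pooled t-test)
#>  variable     mean1      sd1   mean2      sd2 n1 n2       t df         p
#>        tt 119.58630 18.57840 82.9020 19.54500  8  5 3.39828 11 0.0059471
#>        Nc  63.25000 12.80000 62.2000 15.43000  8  5 0.13333 11 0.8963434
#>     sigma   0.13013  0.02988  0.0724  0.00961  8  5 4.12816 11 0.0016773
#>     t_bar   1.83880  0.29280  1.3380  0.10080  8  5 3.63973 11 0.0038899
#>     a_hat   4.21137  1.67834  1.7968  1.48083  8  5 2.63181 11 0.0233318
```

Every variable except the stroke count separates the two groups (p < 0.05):
rhythm stability and total time discriminate trained from untrained rowers;
how many strokes they take does not.

A command-line wrapper is installed as `exec/rowemg`:

```sh
RSCRIPT_EXEC=$(Rscript -e 'cat(file.path(find.package("rowemg"), "exec", "rowemg"))')
Rscript "$RSCRIPT_EXEC" simulate --preset athlete --seed 7 --out sim/
Rscript "$RSCRIPT_EXEC" analyze sim/athlete.csv --out reports/
Rscript "$RSCRIPT_EXEC" compare reports/ --out comparison/
```

Recordings are delimited text (comma or tab) with a `# fs_hz: <Hz>` header
line; reports are schema-versioned JSON.

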