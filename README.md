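# secsteps

Kinetic analysis of stepwise protein transport through the bacterial Sec
translocon.

In the split-NanoLuc transport assay, SecYEG-containing vesicles enclose the
large luciferase fragment (11S) and the pre-protein substrate carries the
complementary pep86 tag: luminescence appears the moment the tag crosses the
membrane, giving a high-resolution time course of transport completion.
`secsteps` is for researchers who want to turn those traces into mechanistic
numbers — how many kinetic steps transport takes, how fast each step is, and
how the proton-motive force (PMF) changes them — and to relate the answers
to substrate sequence properties.

## The model

Transport is a sequential chain with pre-equilibrated binding:

```
S + Y  ⇌(k_on, k_off)  C0  →(k_init)  I1  →(k_step)  …  →(k_step)  In  →(k_step)  F
```

Each translocating intermediate I1…I(n−1) can also fail and restart
(`k_fail`, substrate and site recycled) or become permanently trapped
(`k_block`, site lost). Arrival in F (tag across the membrane) produces
light: signal(t) = brightness · [F](t) / [sites]. With failure and blocking
off, the signal is exactly the Erlang(n+1, k_step) CDF, which serves as the
package's analytic oracle.

Model selection follows the normalised-RMSD scan: fit the model at each
candidate step count n (floating `k_step`, `k_fail`, `brightness`; fixing
`k_block` = 0.31 min⁻¹, `k_on` = 0.96 µM⁻¹ min⁻¹, `k_off` = 0.085 min⁻¹),
divide each RMSD by the scan minimum, and take the smallest n within 0.1% of
1. A two-segment variant (`fit_variant()`) freezes the native portion of an
engineered substrate and scans only the central variable domain's step
count. The empirical lag + single-exponential model, the PMF-effect
statistic `100 × (lag₋PMF/lag₊PMF − 1)`, proteome Lys/(Lys+Arg) bias
analysis with Sturges-rule histograms, and 9-residue sliding-window property
profiles complete the pipeline. Synthetic-data generators stand in for the
wet-lab assay so every analysis is testable end to end.

## Worked example

Generate a synthetic replicate set at the native best-fit parameters, then
recover the step count by scanning n:

```r
library(secsteps)

params <- rate_params(n = 6, k_step = 5.31)
params
#> Sequential transport model parameters
#>   n = 6 steps, k_step = 5.31 min^-1 (k_init = 5.31)
#>   k_fail = 0, k_block = 0.31 min^-1
#>   binding: k_on = 0.96 uM^-1 min^-1, k_off = 0.085 min^-1
#>   brightness = 1

cond <- assay_conditions(t_max = 10)
traces <- make_trace_dataset(params, cond, noise_sd = 0.01,
                             replicates = 12, seed = 42)
scan <- scan_steps(traces, n_range = 1:12, cond = cond, n_starts = 3)
scan
#> Step-number scan over n = 1..12 (average replicates)
#>   best n = 6, k_step = 5.324 min^-1, k_fail = 0.006577 min^-1, brightness = 0.9998

head(scan$table[, c("n", "normalized_rmsd", "k_step")], 8)
#>   n normalized_rmsd k_step
#> 1 1           17.37   1.53
#> 2 2           11.31   2.23
#> 3 3            7.24   2.98
#> 4 4            4.28   3.75
#> 5 5            2.08   4.52
#> 6 6            1.00   5.32
#> 7 7            1.41   6.20
#> 8 8            2.16   7.09
```

The scan recovers the generating step count (normalised RMSD is exactly 1 at
n = 6) and the step rate to 0.3%. The empirical trace summary and the PMF
statistic work on the same objects:

```r
fit_lag_exponential(average_traces(traces))
#> lag + single-exponential fit: A = 0.7559, lag = 0.749 min, lambda = 1.653 min^-1 (RMSD 0.0139)

pmf_effect(lag_measurement(0.64, 0.03), lag_measurement(0.33, 0.02))
#> PMF effect: 93.9% [74.3%, 116%]
```

The lag is the minimum transport time; a PMF effect of ~94% means the PMF
nearly halves the variable region's transport time, with bounds built from
the worst-case SEM combinations.

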