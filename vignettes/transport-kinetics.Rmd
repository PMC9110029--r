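---
title: "Counting the steps of protein translocation: model, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting the steps of protein translocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secsteps)
```

## The measurement and the model

In the split-NanoLuc transport assay, the large luciferase fragment (11S) is
enclosed in SecYEG-containing vesicles and the pre-protein substrate carries
the small complementary tag (pep86). Light appears the instant the tag
crosses the membrane, so a luminescence time course reports the distribution
of single-site transport completion times. `secsteps` models that time
course with a sequential-step kinetic scheme:

* Substrate S and transport sites Y pre-equilibrate into a complex
  C0 with rates `k_on` (µM⁻¹ min⁻¹) and `k_off` (min⁻¹); ATP addition
  defines t = 0.
* Initiation C0 → I₁ at `k_init` (taken equal to `k_step`), then transport
  steps I₁ → I₂ → … → Iₙ → F, each at `k_step` (min⁻¹). Arrival in F — the
  tag across the membrane — produces light. The chain from C0 to F therefore
  comprises n + 1 rate-`k_step` transitions, and with failure and blocking
  switched off the signal is exactly the Erlang(n + 1, `k_step`) CDF. That
  closed form is the package's analytic oracle
  (`erlang_completion_curve()`).
* Every translocating intermediate I₁…Iₙ₋₁ can also dissociate with restart
  (`k_fail`: substrate and site return to their free pools, with no memory
  of progress) or become permanently trapped (`k_block`: the site is lost).
  The final intermediate Iₙ is committed. Under this wiring the completion
  probability with `k_fail = 0` is `(k_step / (k_step + k_block))^(n-1)`,
  which the tests verify against the simulated amplitude.
* `brightness` scales signal per completed NanoLuc; the reported signal is
  `brightness · [F](t) / site_conc`.

The ODE system is integrated with the stiff-capable `lsoda` solver at
relative tolerance 1e-8 and absolute tolerance 1e-10 — rate constants span
about four orders of magnitude in the fast-segment limit tests, and looser
tolerances visibly distort those limits. Blocked states are lumped into one
absorbing pool because only their total affects the observable.

Two details of the wiring were genuinely open. First, whether failure and
blocking also act on the pre-initiation complex: here C0 loses substrate
only through `k_off`, which keeps the pre-equilibrium assumption exact.
Second, whether the best-fit step count includes initiation: here n counts
the post-initiation steps, and initiation adds one further `k_step`
transition, which is what makes the Erlang shape n + 1 and keeps the lag
arithmetic (lag ≈ sum of all per-transition time constants) consistent.

## Assay conditions

Defaults are 2 µM substrate (saturating) against 0.1 µM active sites — a
single-turnover regime with a 20-fold substrate excess — on a 0–30 min grid
at 0.1 min spacing, plate-reader cadence. The site concentration is not a
measured quantity; it is exposed in `assay_conditions()` and none of the
fitted rate constants are sensitive to it in the saturating regime.

## The empirical trace model

`fit_lag_exponential()` fits `s(t) = A(1 − exp(−λ(t − lag)))` for t ≥ lag
(zero before). The lag is the useful summary: it grows linearly with the
number of steps at fixed `k_step`, and subtracting the baseline construct's
lag isolates the transport time of the central, variable domain
(`variable_region_lag()`, SEMs combined in quadrature). One caution
established by the tests and frozen there as a regression bound: on an
exact Erlang trace the fitted lag sits at roughly 60% of the summed time
constants, because the single-exponential tail absorbs part of the rise.
Lag differences between matched constructs are much better behaved than
absolute lags, which is why the pipeline always works with differences.
Initialisation (lag at 10% of max, λ from the 10–90% rise time) is robust
for sigmoidal traces; flat traces are rejected rather than fitted.

## Step-number selection

`scan_steps()` fits the model at each candidate n, floating `k_step`,
`k_fail` and `brightness` while fixing `k_block` = 0.31 min⁻¹,
`k_on` = 0.96 µM⁻¹ min⁻¹ and `k_off` = 0.085 min⁻¹ (independently
determined constants of the assay), and normalises each fit's RMSD to the
scan minimum. Choices that matter:

* **Optimiser.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) on
  residual vectors, multi-started from log-spaced `k_step` values in
  [0.5, 50] min⁻¹, plus a warm start carried from the previous n rescaled
  so the chain's total transport time is preserved. The warm start is what
  keeps normalised-RMSD profiles smooth at large n, where the objective is
  extremely flat.
* **Replicates.** Default is to fit the replicate-averaged trace;
  `replicate_mode = "individual"` fits each replicate and averages.
* **Tie-break.** `best_n` is the smallest n within 0.1% of the minimum
  normalised RMSD.
* **Plateau.** When steps are uniformly fast relative to the sampling grid,
  every sufficiently large n fits equally well and no step count is
  resolvable. The scan flags this when the profile is non-increasing (up to
  0.2% optimiser jitter) over the last five n values and ends within 1% of
  the minimum.

`fit_variant()` applies the same scan to the two-segment model: every
native-segment parameter is frozen to a prior native-only fit, the variant's
measured relative brightness is fixed, and only the variable segment's
`k_step`, `k_fail` (optionally `k_block`) float. The variable segment is
inserted before the final native transition (the tag crossing); because the
completion-time distribution of an irreversible chain is order-invariant,
this placement choice is essentially unobservable, but it is exposed as
`insert_after`. With identical parameters the segmented model reduces
exactly — not approximately — to the uniform chain, which the tests assert.

## PMF statistics

`pmf_effect()` implements 100 × (lag₋PMF / lag₊PMF − 1) on
baseline-subtracted lags: 0% is no effect, 100% a halving of lag with PMF.
Error bars are the worst-case SEM combinations
((lag₋ + sem₋)/(lag₊ − sem₊) and its mirror), as bounds rather than a
first-order propagation — with lags of similar size to their SEMs the
bounds are honest where the delta method is not. The statistic is
scale-invariant, and the bounds collapse to the point estimate as SEMs
vanish. `transport_rate_from_positions()` fits lag against tag position for
tag-position series; the default fit is unweighted, with `1/sem²` weighting
available.

## Proteome lysine/arginine bias

For each protein the statistic is K/(K + R) on the mature sequence (signal
peptides stripped first; proteins with no K and no R are excluded — the
statistic is undefined and excluded proteins do not enter the histogram
denominator). Histograms span [0, 1] with the Sturges bin count
`round(1 + 3.322·log₁₀ n)` (log read as log₁₀, recovering Sturges'
1 + log₂ n), half-open bins with the last closed so 0 and 1 are assigned
deterministically. A single Gaussian is fitted to (bin centre, frequency)
pairs for display and summary. Class location differences use a two-tailed
Welch t-test by default — the natural unequal-variance companion to the
two-tailed t-tests used for the lag comparisons — with a
label-permutation test (difference of means, 10⁴ shuffles) as the
distribution-free cross-check; the tests require the two to agree within
Monte-Carlo error.

## Sliding-window properties

`window_profile()` computes unweighted means over a 9-residue window
(configurable, odd) of a per-residue scale; edge positions are undefined
rather than computed from shrunken windows, matching the common
ProtScale-style output span. Unknown residues (X) are excluded from window
means; a window with more than 20% unknowns is undefined. Three published
scales ship with the package: Kyte–Doolittle hydropathy, Deleage–Roux
helical propensity and Zimmerman bulkiness. `region_mean()` averages raw
per-residue values over a whole region — the mode used when correlating
PMF effects with variant hydrophobicity — and windowed averaging of the
same region is available through `window_profile()` if preferred.

## What the synthetic data do and do not show

`make_trace_dataset()` adds i.i.d. Gaussian noise (default SD 0.01 on a
unit-normalised trace) to model-generated signals — plate-reader-like noise
chosen to match the smoothness of replicate-averaged experimental traces.
It does not emulate baseline drift, pipetting offsets between replicates,
signal decay, or NanoLuc maturation kinetics. Parameter-recovery results on
these data therefore demonstrate that the fitting machinery is correct and
well-conditioned under the stated noise model, not that real traces carry
enough information to resolve every parameter; in particular `k_fail` and
`brightness` trade off against each other far more on real data.

`make_proteome()` controls only the K/(K + R) statistic (per-protein
targets from a truncated normal, realised to within 1/(K + R) by integer
rounding; roughly 10% of mature residues are positive); all other positions
are neutral background composition, and synthetic signal peptides are
hydrophobic-core-like with composition independent of the mature-domain
bias. Real proteome features — length/composition covariation, domain
structure, annotation errors — are absent by design.

`make_variant_panel()` reproduces the matched-baseline experimental design
(one baseline set, several variant sets with known ground truth) and stores
the generating parameters in its manifest, which is what the end-to-end
recovery tests consume.

## Problem sizes and determinism

The shipped tests and the acceptance script use 12 replicates, a 0–10 min
window at 0.1 min spacing, scans over n = 1…15 (single-segment) or up to 20
(two-segment), and proteomes of 500 proteins per class — sizes at which a
full scan takes tens of seconds and every stochastic check is stable across
seeds. All generators are pure functions of their arguments and a seed.

## Known limitations

* The restart pathway assumes complete loss of progress on failure;
  partial-progress restarts are not modelled.
* The two-segment fit fixes the native segment entirely; uncertainty in the
  native fit does not propagate into variant parameter errors.
* Normalised RMSD is the only model-selection criterion, by design — no
  information criteria are computed, so the scan inherits RMSD's
  insensitivity near flat minima (hence the explicit plateau flag).
* Real-data ingestion expects tidy CSV exports; vendor plate-reader formats
  are out of scope.
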