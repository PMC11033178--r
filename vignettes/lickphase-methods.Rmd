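---
title: "Methods: lick-cycle phase locking and event modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lick-cycle phase locking and event modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lickphase)
```

`lickphase` analyses single-unit activity recorded while an animal consumes
fluid rewards. This vignette explains the models and procedures the package
implements, the parameters that matter and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
numerical choices made where the method description left the design open.

## Event modulation

### PSTHs, z-scoring, smoothing

`build_psth()` bins spikes relative to each event:
rate in bin *b* is (total spikes across events in *b*) / (n_events × Δ).
The default bin width is Δ = 10 ms — fine enough to resolve responses within
a ~143 ms lick cycle, coarse enough that bins are not empty at typical
central-amygdala rates (~3 Hz). Events whose window would reach outside the
recording are dropped and counted, never silently truncated, because a
truncated window biases the average rate.

`zscore_psth()` computes `z_i = (F_i − F_mean) / F_SD` per unit, with
`F_mean`, `F_SD` taken over a 10 s baseline window, by default
[−10.5, −0.5] s before the event. The baseline is placed per event (each
event contributes its own baseline bins to the pooled mean/SD) and ends
0.5 s before the event so the anticipatory period stays out of the
reference. A unit whose baseline SD is zero (a pathologically regular or
silent unit) is flagged `baseline_defined = FALSE` with `z = NA`; silently
substituting 0 would fabricate a flat response.

`smooth_causal_halfnormal()` implements the causal half-normal filter:
`out_i = Σ_{j=0..J} w_j · in_{i−j}` with `w_j ∝ exp(−j² / (2σ²))`, σ = 6.6
bins, truncated at `J = ceil(4σ)` = 27 bins (beyond 4σ the weights are
numerically negligible) and normalised to unit DC gain. σ is interpreted in
bins: the filter acts on the binned PSTH, so with 10 ms bins the smoothing
scale is 66 ms — under half a lick cycle. Bins before the series start use
edge replication, which keeps the output unbiased for a stationary
baseline (zero padding would drag the first ~27 bins toward zero).
Statistics are always computed on unsmoothed data; smoothing exists for
display and population averaging.

### Classification

`classify_modulation()` compares, per event, the firing rate in a response
window against that event's own baseline-window rate with a two-tailed
paired Wilcoxon signed-rank test (α = 0.05). Response windows default to
−0.5..0.5 s (port entry/exit); for licks the convention is 0..0.03 s. That
30 ms lick window is unusually short — about a fifth of a lick cycle — and
is kept exactly as specified but worth knowing about: with one ~3 Hz unit
the expected count per lick is 0.1 spikes, so lick modulation is typically
detected over many licks, not per lick.

Zero paired differences carry no sign information and are dropped before
ranking (the standard signed-rank convention); when every pair is zero the
test is undefined and the unit is reported `none` with p = 1. The exact
null distribution is used up to 25 informative pairs without ties, the
normal approximation with continuity correction otherwise.

One honest property to be aware of: the null distribution of
(response rate − baseline rate) is *asymmetric*, because a count over 1 s
is a coarser lattice than a count over 10 s divided by 10. The signed-rank
test assumes symmetry under the null, and simulation with this package's
own generator measures the realised type-I rate at α = 0.05 as ≈ 0.05–0.065
rather than exactly 0.05. This is a property of the windowed design itself,
not of the implementation; the validation suite therefore checks the level
with an exact binomial 99% band around 0.05 over 200 null simulations,
which absorbs this mild anticonservativeness while still catching real
miscalibration.

## Lick entrainment

Licking is segmented into **bouts**: maximal runs with inter-lick intervals
strictly below 210 ms (a gap of exactly 210 ms splits — the criterion is a
strict inequality). Consecutive licks within a bout define **lick cycles**;
the final lick of a bout closes the last cycle and no cycle is extrapolated
beyond it. A spike at time *t* in cycle [s, e) gets phase
`θ = 2π(t − s)/(e − s)`; phase 0 is tongue contact with the spout. A spike
exactly at a cycle end belongs to the following cycle (phase 0) when one
starts there — within a bout, cycles tile the time axis — and is otherwise
outside all cycles and excluded.

Per unit, `test_lick_modulation()` requires ≥ 50 spikes in cycles; below
that the unit is *excluded* and carries no p-value at all, so exclusion can
never be confused with non-significance. Tested units get the Rayleigh test
(`Z = nR²`, modulated when p < 0.01) and a **preferred phase**: the centre
of the maximal bin of a 30-bin (12°) phase histogram, with ties broken by
the circular mean of the spikes in the tied bins. The histogram mode (rather
than the circular mean direction) is used because multimodal or skewed phase
distributions are common and the mode matches how preferred phases are read
off spike-probability heatmaps; 12° is fine enough to resolve the
population spread and coarse enough that single spikes do not set the mode.
Phases are per spike, not per cycle averaged: the quantity of interest is
the spike-phase distribution.

`population_summary()` reports the modulated proportion with *both*
denominators — among tested (post-exclusion) units and among all units —
because the two are routinely conflated in population percentages; the
fraction of modulated units preferring (0, π) (the retraction half of the
cycle); and the V test of preferred phases against 90°. With fewer than two
modulated units the V test is skipped with an explicit status rather than
returning a degenerate statistic.

## Circular statistics

The tests are implemented in-package (no circular-statistics dependency)
and validated two ways: exact identities on degenerate inputs, and
Monte-Carlo / permutation oracles at small n (see
`tests/testthat/test-acceptance.R`).

* **Rayleigh**: `Z = nR²`; p from the standard series
  `e^{−Z}[1 + (2Z − Z²)/(4n) − (24Z − 132Z² + 76Z³ − 9Z⁴)/(288n²)]`,
  clamped to [0, 1] (the series can stray outside on tiny samples).
* **V test**: `V = nR cos(θ̄ − μ0)`, `u = V√(2/n)`, one-sided upper-tail
  normal p — one-sided by construction since μ0 = 90° is specified a
  priori. The summary form (`n` plus `V`, or `R` and mean direction) lets
  printed statistics be re-evaluated directly.
* **Two-sample Kuiper**: `K = max(F̂_a − F̂_b) + max(F̂_b − F̂_a)` over the
  pooled sample — invariant to joint rotation, which is the point of using
  it on phases; p from the asymptotic series
  `2Σ_j (4j²λ² − 1)e^{−2j²λ²}` with
  `λ = K(√N_e + 0.155 + 0.24/√N_e)`, `N_e = mn/(m+n)`.
* **Two-proportion z**: pooled variance by default (the usual form for a
  null of equal proportions); an unpooled flag is available since the
  convention is often unstated in papers.

## Task logic

`simulate_port_task()` accrues port presence on a counter; each time the
counter reaches 2.0 s it resets and the pump delivers 0.1 mL over 2 s.
Accrual *continues during delivery* by default — the delivery rate was
designed to match the consumption rate, implying no accrual pause — but
whether the real controller pauses is not stated, so
`pause_during_delivery = TRUE` is available and changes the hand-traced
example from deliveries at 2, 4, 6, 8, 10 s to 2, 6, 10 s for a continuous
10 s occupancy. A counter that lands exactly on 2.0 (e.g. at port exit)
emits a delivery.

`simulate_closed_loop()` implements both optogenetic rules. Excite mode
("first lick each second"): the 1 s lockout is anchored at each trigger,
not at wall-clock second boundaries — a lick exactly at train end
retriggers. On a perfect 7 Hz lick grid this yields trains at 0, 1, 2, … s.
Inhibit mode: light on at the first lick of a run, off 1 s after its last
lick, where runs are maximal sequences with gaps strictly below 1 s (a gap
of exactly 1 s splits, mirroring the "no lick detected for 1 s" rule).

## Microstructure and intake

`lick_clusters()` segments at a configurable inter-lick interval, default
0.5 s: the cluster criterion for microstructure is deliberately longer than
the 210 ms cycle criterion (pauses of 0.2–0.5 s occur within what behavioural
work treats as one drinking burst), and 0.5 s is the conventional choice in
the lick-microstructure literature. The value used is always carried in the
output so results are never detached from their criterion. `intake_dose()`
converts bottle-weight change to g/kg: v/v solutions convert mass to volume
at a configurable solution density (default 1.0 g/mL) and multiply by
concentration × 0.789 g/mL (ethanol density); w/v solutes multiply volume
by concentration in g/mL. Negative weight changes (spillage, condensation)
are clamped to zero with a warning rather than reported as negative intake.

## The synthetic-session generator

`gen_session()` provides ground-truth inputs for every stage. It emulates:

* **Licking** in bouts: inter-bout gaps of 0.210 s plus an exponential
  margin (so the generator's bouts are *never* split by the 210 ms rule and
  bout recovery can be tested exactly), bout sizes 1 + Poisson(6), and
  within-bout inter-lick intervals from a lognormal truncated to
  [0.05, 0.205] s whose log-mean is calibrated numerically (by
  `uniroot` on the truncated-mean identity) so the realised mean ILI equals
  1/7 s — 7 Hz licking, in the 5–10 Hz physiological band. Only the mean
  rate is constrained by the source description; the truncated lognormal is
  this package's choice of a realistic right-skewed ILI shape.
* **Spiking** as an inhomogeneous Poisson process, sampled by thinning:
  `λ(t) = λ0 · g(t) · exp(κ cos(φ(t) − μ))/I0(κ)` inside lick cycles and
  `λ0 · g(t)` outside. The von Mises factor is normalised so its average
  over a full cycle is 1: phase locking redistributes spikes within the
  cycle without changing the mean rate, so rate-based and phase-based
  analyses can be validated independently. `g(t)` is a multiplicative step
  (default) or Gaussian bump of half-width 0.5 s around port entries and
  exits, mirroring the ±0.5 s analysis windows.
* **Task events**: port occupancy intervals placed 0.2–1 s around lick
  bouts (merged when they overlap, so entries/exits always alternate), pump
  activations from the accrual rule, and — for two-bottle sessions — laser
  intervals from the configured closed-loop rule.

Defaults describe one 40-min self-administration session: 40 units at
3.3 Hz (the recorded population's mean rate), κ = 1 at μ = π/2, 0.02
bouts/s of 7 licks (~340 licks/session, matching the reported per-session
lick counts). All randomness flows from one integer seed; per-unit
substreams are drawn deterministically from it, so a fixed configuration
reproduces byte-identical session files.

What the generator does **not** emulate: refractory periods and bursting
(spikes are Poisson conditional on the intensity), rate drift and
nonstationarity across a session, correlated noise between units, lick-rate
variation within bouts, electrode drift or sorting errors. Passing tests
therefore demonstrate that the analysis recovers what it claims from data
that satisfy its assumptions — not that real recordings satisfy them.

## Validation experiments and problem sizes

`run_validate()` and the acceptance suite run, at full scale:

* the printed-statistic worked example (V = 19.92, n = 38 → u ≈ 4.570,
  p < 10⁻⁵);
* null calibration: 2000 uniform samples per test, rejection rates inside
  exact binomial 99% bands (Rayleigh at α = 0.01, n = 100; V at α = 0.05,
  n = 38), plus analytic-vs-oracle agreement (Rayleigh vs a 100k-resample
  Monte-Carlo null at n = 30 within ±0.01 over 50 cases; Kuiper vs a
  50k-permutation null at n = m = 50 within ±0.02 over 30 cases);
* parameter recovery: 200 units at λ0 = 5 Hz, κ = 1, μ = π/2 over 600 s
  sessions; the circular mean of recovered preferred phases must fall
  within 0.15 rad of π/2, and the per-unit recovery error must decrease
  monotonically over κ ∈ {0.5, 1, 2, 4}. These recovery sessions use a
  drinking-dense lick train (0.1 bouts/s, ~40 s of cycle time) so that
  5 Hz units clear the 50-spike exclusion — with the sparser session
  default every unit would be excluded and the experiment would be vacuous;
* classifier operating characteristics: 200 null units (level inside the
  exact binomial 99% band around 0.05, see the caveat above) and 200 units
  each at gain 5 and 0.2 (power ≥ 95% in the correct direction, 30 events);
* the exact hand-traced fixtures for bout/cycle/cluster segmentation, the
  pump accrual rule and both closed-loop rules.

These sizes were chosen so each experiment's Monte-Carlo error is small
relative to its acceptance band while the whole suite stays interactive.
`run_validate(scaled = TRUE)` runs the same suite at reduced replicate
counts for a quick smoke test; its statistical rows are indicative only.

## Known limitations

* The 0–0.03 s lick response window is implemented exactly as specified
  despite spanning only a fifth of a lick cycle (see above).
* Whether the baseline is per-event or one session-level epoch is a genuine
  ambiguity in the method description; this package uses per-event
  baselines pooled per unit, which is what a paired signed-rank test
  requires.
* The signed-rank level inflation on asymmetric rate differences
  (≈ 0.05–0.065 at nominal 0.05) is inherited from the windowed design.
* Kuiper p-values use the asymptotic series with the standard finite-sample
  correction; below n ≈ 10 per sample the permutation route is preferable.
* The generator's bottle weights are derived deterministically from lick
  counts (5 µL/lick) — adequate for testing dose arithmetic, not a model of
  measurement error.
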