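---
title: "Modelling cytokine-specific refractory states in NF-kB signalling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cytokine-specific refractory states in NF-kB signalling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfkbpulse)
```

## The biological problem

NF-kB (p65/RelA) shuttles between cytoplasm and nucleus under the control
of its inhibitor IkBa: resting cells hold NF-kB in cytoplasmic
NF-kB:IkBa complexes, cytokine-activated IKK degrades IkBa and releases
NF-kB into the nucleus, and NF-kB-driven resynthesis of IkBa pulls it back
out — a delayed negative feedback that produces nuclear/cytoplasmic
oscillations with a period of roughly 100 minutes under continuous
TNF-alpha.

When TNF-alpha arrives as short, well-separated pulses, almost every cell
responds to every pulse. At shorter pulse spacings cells increasingly fail
to respond to the second pulse: each cell behaves as if it owned a fixed
*refractory period*, heterogeneous across the population but stable within
a cell over many hours and largely inherited by daughter cells. The
refractory state is cytokine-specific: cells refractory to a second TNF
pulse still respond to IL-1beta, implicating the signal-transduction layer
between receptor and IKK rather than the core NF-kB/IkBa loop.

`nfkbpulse` implements a mechanistic model of this behaviour, the
population and calibration machinery around it, the single-cell trace
statistics used to quantify it, a global sensitivity analysis, expression
utilities for panel-style count data whose condition means track NF-kB
activity, and synthetic-data generators that let the whole pipeline be
exercised and validated without access to the original recordings.

## Model structure

One cell is described by 15 ODE species in molecules per cell (time in
minutes), organised in two coupled modules.

**Signal transduction.** Each cytokine branch (TNF, IL-1) owns a
three-state IKKK pool — neutral, active, inactive — standing in for the
receptor-proximal network (TRAF adaptors, RIP/TAK1 kinases and their
regulators). A pulse converts neutral IKKK to active at rate
`ka_X * TR_X(t) * kA20_X / (kA20_X + A20)`, where `TR_X(t)` is the
receptor drive (a Hill function of dose during the pulse, exponential
washout with time constant `tau_w` afterwards) and the divisive A20 term
is the feedback gate. Active IKKK decays to the inactive state (`ki`),
which recovers to neutral slowly (`m3`). Both branches converge on a
single IKK cycle (neutral -> active -> inactive -> neutral): IKK
activation is a Hill-2 function of total active IKKK with half-maximum
`sIKKK`.

**Core feedback.** Active IKK degrades IkBa — free and complexed — as a
saturable enzyme (turnover `kc1`, `kc2`; Michaelis constant `Km_ikk` per
substrate pool). Freed NF-kB enters the nucleus, drives Hill-2
transcription of IkBa and A20 mRNA, and newly translated IkBa re-enters
the nucleus, captures NF-kB and exports it. Totals of NF-kB, IKK and
per-branch IKKK are conserved exactly by construction, which the
simulator verifies at every output sample (relative tolerance `1e-6`).

Two structural choices deserve emphasis:

* **Saturable IkBa degradation.** With mass-action degradation the
  continuous-stimulation system relaxes to a stable focus and
  oscillations die. Near-zero-order degradation of the complexed pool
  gives the titration-type switch that sustains relaxation oscillations —
  the behaviour the single-cell recordings show — so the Michaelis form
  is a load-bearing feature, not a refinement.
* **Free-IkBa routing.** The post-pulse IkBa overshoot must sit in the
  cytoplasm (fast nuclear export of free IkBa) where the next IKK burst
  can clear it; a nuclear excess pool would silently absorb released
  NF-kB and veto second responses at any IKKK level.

## What encodes the refractory period

After a first pulse the cell is refractory for two compounding reasons:
the TNF-branch IKKK pool sits in its inactive state (recovery `m3`, on
the tens-of-minutes scale) and induced A20 protein gates reactivation
(decay `c4`). Because IKK activation is steep in total active IKKK, a
cell responds to the second pulse only if its *total* IKKK exceeds a
threshold `theta(Delta)` that falls as the interval `Delta` grows. A
population with per-cell IKKK totals drawn once from a zero-truncated
normal (mean `1e6` molecules — the scale anchor) therefore reproduces a
graded fraction-versus-interval curve, and the quantile calibration in
`calibrate_ikkk_distribution()` inverts that logic: bisection finds
`theta(Delta)` per interval, then one standard deviation is fitted so the
truncated-normal tail probabilities match the measured fractions
(5/30/70/93% at 50/60/70/100 min).

The TNF/IL-1 asymmetry is carried by branch-specific A20 gates
(`kA20_T < kA20_I`: the TNF branch is an order of magnitude more
A20-sensitive) over a shared A20 pool, plus branch-specific IKKK pools.
The per-cell IL-1 total is tied to the same relative deviation as the
cell's TNF total — the imprinted "transduction capacity" is treated as
one cell state expressed in both branches. That single distribution then
carries all four 60-min sequence fractions (TT, TI, II, IT) with no
further per-sequence freedom.

## Calibration targets and how the nominal set was fixed

The nominal rate values are not copied from any published table: the
system above is this package's own formulation of the module structure,
and its rates were fixed by an explicit calibration step
(`analysis/02_calibrate_refractory.R` closes the loop) against
population-level kinetic constraints only:

* total-IkBa trough at ~20 min and rebound peak at ~2 h after a single
  5-min 10 ng/ml TNF pulse, return to within a few percent of baseline by
  300 min;
* sustained continuous-TNF oscillations, mean period ~100 min, per-cell
  dominant periods spread over roughly 80–140 min under all-parameter
  heterogeneity (sd = 0.3 of each mean);
* the fraction-versus-interval curve above, under the quantile-calibrated
  IKKK distribution;
* the 60-min cytokine-sequence fractions (TI ~95%, II ~75%, IT ~54%);
* the widened-distribution regime (sd = 0.9 mean) responding ~40% at the
  50-min interval;
* a resting nuclear NF-kB fraction well below the 15% responder
  threshold, and first-pulse responses in essentially all cells across
  the sampled IKKK range.

These constraints couple strongly (the oscillation period, the
single-pulse peak time and the second-response thresholds all ride on the
same feedback rates), and the nominal set in `nfkb_params()` is the
calibrated compromise. Remaining tensions are stated honestly in the
calibration output rather than hidden: the fitted curve is reported next
to its targets.

## Population heterogeneity and noise models

Extrinsic noise draws parameters once per cell — truncated-normal by
default (lognormal available) — and is deterministic afterwards; this is
the "imprinted state" hypothesis. Intrinsic noise keeps parameters fixed
and makes the two feedback genes stochastic two-state telegraph switches:
the on-propensity is `kon` scaled by the same NF-kB-dependent occupancy
that drives transcription, the off-propensity `koff` is constant, and an
on gene transcribes at `c1 * (occupancy + koff/kon)`. The additive term
compensates exactly for time spent off, so the quasi-static mean
transcription equals the deterministic rate at every occupancy, and both
limits — fast switching, or `koff = 0` with the gene on — reduce the
hybrid trajectory to the ODE. Switching is sampled on a 1-min grid
(piecewise-constant hazard) between deterministic integration segments.
Default switch rates (`kon = 0.2`, `koff = 0.1` per min) give ~10-min
off-switching and visibly bursty transcription at rest; they are
exposed, not asserted.

The two models are discriminated by the equilibrated four-pulse design
(pulse pairs at 70-min interval separated by an equilibration gap):
extrinsic noise predicts exactly zero cells discordant between the
second and fourth pulse once the cell has truly returned to rest;
intrinsic noise predicts a strictly positive discordant fraction. The
operation checks its own precondition — the gap must outlive the model's
slowest relaxation mode, the IkBa mRNA/protein tail, which here needs
~12 h rather than the experimental 4 h; at a 4-h gap a few percent of
borderline cells flip for deterministic reasons, a number the analysis
reports next to the experimental reference (3 of 79 cells). Formal
testing (Fisher's exact test) is left to the user, since the intrinsic
model's switch rates are not identified by the data.

## Trace analytics

All statistics operate on either simulated trajectories or long-format
trace tables (`cell_id`, `time_min`, `ikba_total`, `nfkb_nt`), with IkBa
intensity normalized to its t = 0 value on load:

* responder calls: the model rule (net nuclear NF-kB peak within 45 min
  of the pulse, relative to the level at stimulation, strictly above 15%
  of total NF-kB) and the experimental rule (non-positive least-squares
  gradient of total IkBa over `[pulse + 5, pulse + 25]` min — the printed
  rule names the gradient "at the time of stimulation"; the short offset
  window is this package's reading, configurable);
* `refractory_distribution()`: successive differences of the
  fraction-versus-interval curve, with open tails below the smallest and
  at/above the largest interval; negative increments from sampling noise
  are clipped and renormalized with a warning;
* amplitudes (P2/P1 ratios), baseline-corrected first-peak-normalized AUC,
  trough detection by prominence (5% of trace range, min 40-min
  separation, earliest-time tie-break), and power-spectrum dominant
  periods (t > 35 min discarded, mean and linear trend removed, 4x
  zero-padding, 40–300 min search band);
* 2-means clustering of post-pulse IkBa features (10 restarts, label
  fixed by mean dip depth), pooled z-scored PCA of 140-min
  sub-trajectories, and daughter-pair concordance.

## Sensitivity analysis

`lhs_sample()` builds a Latin hypercube over +/-50% ranges (each
parameter's range cut into k slices, one uniform draw per slice, slice
order permuted independently per parameter; the Latin property is
verified by construction check). Outputs per sample are the second-pulse
responder indicator, net amplitude, nuclear-NF-kB AUC after the second
pulse and the continuous-stimulation period; `spearman_sensitivity()`
computes rank correlations with average-rank ties and pairwise exclusion
of failed integrations. The reduced default (k = 200) keeps the routine
test and acceptance runs inside their runtime envelope; the full k = 1000
design is one flag away (`analysis/05_sensitivity.R --full`) and is the
size used for the headline ranking claims.

## Synthetic data: what it does and does not show

The generators emulate the *measured data products*, not the microscopy:
reporter traces get multiplicative lognormal noise (default sd 0.05,
scale-dependent as intensity noise is) and a slow linear drift on the
IkBa channel only (default -0.02%/min; the nuclear/total ratio is
self-normalizing), sampled at 5-min steps; count panels get
negative-binomial counts whose condition means are
`baseline * (1 + coef * activity)` with flat housekeeping/positive
controls and near-zero negative controls. Label-mode traces splice
model-run templates (never hand-drawn shapes): the responder template is
a high-IKKK cell that responds to the probed pulse by both classifier
rules, and the non-responder template is the same protocol with the
probed pulse omitted — refractory cells continue the single-pulse
profile, which is exactly how non-responders present in the recordings.
Every generator returns its ground-truth labels in a sidecar, never
inside the data table.

Passing the recovery tests therefore demonstrates that the analysis
chain is correct and well-conditioned under realistic noise — it cannot
certify performance on features the generators do not emulate
(segmentation artefacts, focal drift, cell crowding, heavy-tailed
intensity outliers, mitotic gaps in traces).

## Numerical choices

* Integration: `lsoda` via a compiled right-hand side, `rtol = 1e-8`,
  `atol = 1e-4` molecules; the solver is restarted at every pulse edge so
  5-min pulses are never stepped over; output on a uniform 1-min grid.
* Pre-equilibration: 2000 min from a generic initial condition, accepted
  only if the scaled derivative norm is below tolerance. Populations
  varying only IKKK totals share one resting state (the active/inactive
  pools are empty at rest, and the neutral pools are implicit), which
  removes the dominant cost of population runs.
* Threshold bisection: tolerance 0.1% of the mean IKKK; because extreme
  IKKK totals (several times the mean) produce first responses so large
  that A20 carry-over suppresses the second response again, the search
  first scans a coarse ascending grid and bisects inside the first
  upward crossing — the threshold reported is the minimal responding
  total, as defined.
* Degenerate inputs are errors, not guesses: empty response tables,
  all-constant traces in the period estimator, rank-deficient PCA
  matrices, unmatched pair ids, non-monotone fraction curves in the
  calibrator.

## Known limitations

The acceptance suite states these plainly rather than hiding them; the
corresponding checks are left red where the calibrated model cannot meet
them.

* The single-pulse IkBa rebound peaks near 95 min instead of ~125 min,
  and the return to baseline at 300 min carries a ~7% residual: in this
  topology the same feedback rates set the continuous-stimulation period
  (~106 min, on target) and the rebound timing, and the calibrated
  compromise favours the period, the trough time and the threshold
  curve. A slower rebound also stretches every re-equilibration
  statistic (see the noise-model section).
* The fraction-versus-interval curve is matched well at 60 min and in
  overall range, but its ends are over-steep relative to any single
  truncated-normal IKKK distribution: the fitted curve gives ~2% at
  50 min (measured 5%), ~55% at 70 min (measured 70%) and ~98% at
  100 min (measured 93%). The mid-curve slope between 60 and 70 min is
  structurally capped by the rising IkBa pool, which partially cancels
  IKKK/A20 recovery in exactly that window.
* Second-pulse amplitude sensitivity is dominated by core-feedback and
  IKK-layer parameters rather than by the A20/IKKK group: in this
  calibration the IKK burst at a second pulse is capacity-limited rather
  than signal-limited for most of the sampled range, so the headline
  upstream-dominance ranking is not reproduced (the period ranking is).
* The two IKKK pools are fully branch-specific; partial sharing of one
  pool between the TNF and IL-1 pathways would also be consistent with
  the cross-talk data and is not distinguishable here.
* The exact functional form of A20 inhibition (divisive here) and the
  telegraph-gene rates are not identified by the calibration targets.
* Receptor trafficking is deliberately absent (surface receptor level is
  constant in the data); dose enters only through a static Hill gain, so
  dose-escalation rescue experiments are outside the model's reach.
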