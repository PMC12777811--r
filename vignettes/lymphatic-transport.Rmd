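---
title: "Lymphatic transport pharmacokinetics: model, estimators and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lymphatic transport pharmacokinetics: model, estimators and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Highly lipophilic drugs (log P > 5) absorbed from the intestine are
incorporated into chylomicrons in the enterocyte and enter the lacteals
rather than the blood capillaries. This intestinal lymphatic route matters
twice over: it is an additional gateway into the systemic circulation, and
it bypasses hepatic first-pass extraction entirely. Measuring it requires a
lymph-duct-cannulated animal in which the central lymph flow is diverted
into an external collection vessel, so that lymph-transported drug is
recovered by direct mass balance instead of reaching the blood.

`lymphpk` implements the complete analysis of such a study — cannulated
animals dosed orally in a two-period cross-over (two formulations), with a
separate intravenously dosed animal as the systemic reference — together
with a mechanistic simulator of the same design, so that every estimator
can be validated by parameter recovery on data whose truth is known.

## Estimands

For an oral dose $D$ in a cannulated animal:

* **Absolute bioavailability via lymph**, by direct mass balance over the
  collection intervals $i$ with volume $V_i$ and aliquot concentration
  $C_i$:
  $$F_{AL} = \frac{100}{D}\sum_i C_i V_i .$$
* **Absolute bioavailability via the portal vein**, from dose-normalized
  AUCs against the intravenous reference (in a lymph-diverted animal the
  blood only sees the portal route):
  $$F_{AP} = 100\,\frac{AUC_{ent}/D_{ent}}{AUC_{iv}/D_{iv}} .$$
* **Total absolute bioavailability** $F = F_{AL} + F_{AP}$ (the two routes
  are disjoint in the cannulated animal), and the **relative
  bioavailability via lymph** $F_{RL} = 100\,F_{AL}/F$, the share of
  systemically available drug that traveled through lymph.

Both identities are asserted on every constructed result. All four
quantities are computed per animal and period first and summarized
afterwards; group means of ratios are therefore means of per-animal ratios
and do not compose from the group means of their components.

## Non-compartmental conventions

The NCA engine is deliberately conventional, and every run records its
settings ledger (`analysis_settings()`):

* **AUC** by the linear trapezoidal rule over the exact sampling times,
  including the descending limb (no lin-log switch). Window edges falling
  between samples are linearly interpolated, which makes the rule exactly
  additive over adjacent sub-windows.
* **Terminal slope** $\lambda_z$ by ordinary least squares on
  $\ln C$ versus $t$ over every suffix of at least 3 quantifiable points
  strictly after $T_{max}$; the suffix maximizing adjusted $R^2$ wins, ties
  going to more points, and a negative slope is required. On an exact
  mono-exponential this is exact regardless of the tie rule. When no
  admissible tail exists the fit is absent and AUC extrapolation is
  flagged rather than guessed.
* **Extrapolation** $AUC_\infty = AUC_{last} + C_{last}/\lambda_z$ with the
  *observed* last concentration (not the regression-predicted one); the
  choice is recorded in the settings ledger, and results with more than
  20 % of $AUC_\infty$ extrapolated carry an explicit flag.
* **IV bolus** profiles that do not start at $t=0$ get a log-linearly
  back-extrapolated $C_0$ from the first two samples (carried back flat if
  the profile starts rising), and disposition follows the bolus formulas
  $CL = D/AUC_\infty$, $MRT = AUMC_\infty/AUC_\infty$ (no infusion
  correction), $V_{ss} = CL \cdot MRT$.
* **BLQ policy** (LLOQ 1 ng/ml by default, matching the validated
  bioassay): below-limit values before the first quantifiable point become
  0, embedded and post-$T_{max}$ BLQ values are dropped, and each edit is
  logged. BLQ lymph concentrations contribute zero collected mass, which
  is conservative for $F_{AL}$. The alternative LLOQ/2 substitution was
  rejected because it manufactures mass in the dominant overnight interval.
* **Ties** in $C_{max}$ break to the earliest time.

## The simulator

The generator is a linear compartment model chosen as the minimal
mechanism that reproduces the cannulated design and makes the transport
fractions identifiable truths:

* a gut depot holding the absorbable fraction $f_a D$, releasing at
  first-order rate $k_a$ (the unabsorbable remainder never leaves the gut
  term);
* the absorbed flux splits: fraction $\phi_{lymph}$ to a lymph compartment
  drained at $k_{lt}$ into the cannula — drained mass is collected
  externally and permanently removed — and $(1-\phi_{lymph})$ to the
  portal route, of which the liver extracts $E_H$ before the remainder
  reaches the central compartment;
* central disposition with clearance $CL$, volume $V_c$ and optional
  peripheral exchange $k_{12}/k_{21}$.

The closed-form truths follow: $F_{AL} = 100 f_a \phi_{lymph}$,
$F_{AP} = 100 f_a (1-\phi_{lymph})(1-E_H)$. Mass balance
(gut + lymph + central + peripheral + collected + eliminated +
first-pass-extracted + unabsorbable $=$ dose) is enforced at every output
time to $10^{-6}$ relative, and any violation or negative state is a hard
failure naming the parameter set. The system is integrated with
`deSolve::lsoda` at relative tolerance $10^{-10}$; in the one-compartment
limit the output matches the analytic bi-exponential solution pointwise to
better than $10^{-6}$ relative (verified in the test suite).

Interval lymph volumes are `flow × width` with the flow drawn log-normally
around 70 ml/h (CV 25 % across intervals), mid-range of the 36–109 ml/h
observed in cannulated pigs. The interval concentration is the drained
mass over the volume, i.e. the flow-weighted mean over the interval, which
is exactly what the aliquot of a continuously collected interval measures;
the 2 ml aliquot itself is ignored in the balance (it is ≪ the interval
volumes). Measurement error is proportional log-normal,
$\sigma = \sqrt{\ln(1+CV^2)}$, applied to serum and lymph concentrations,
with BLQ flagging below the LLOQ. Between-animal variability applies
log-normal multipliers (shared across the animal's two periods) to
$f_a, \phi_{lymph}, k_a, k_{lt}, CL, V_c$.

### Default scenario and why

The defaults describe a ~64 kg pig and are simulation fixtures, not claims
about any measured animal:

| parameter | default | rationale |
|---|---|---|
| $CL$ | 33.6 l/h | anchored to intravenous cannabidiol kinetics in the pig |
| $V_c$, $k_{12}$, $k_{21}$ | 50 l, 1.532, 0.2924 /h | chosen so $V_{ss} = 312$ l and terminal $t_{1/2} = 8.5$ h match the same IV profile |
| $E_H$ | 0.70 | high-extraction compound; makes the lymph route disproportionately valuable |
| $f_a$, $\phi_{lymph}$ | 0.172, 0.070 (oil) / 0.277, 0.036 (nanoemulsion) | place the simulated study in the observed ranges: $F \approx 6$–9 %, $F_{RL} \approx 10$–20 %, lymph/serum concentration ratio $\sim 10^2$; the long-chain-triglyceride-rich oil stimulates the lymph split more, the nanoemulsion absorbs more completely |
| $k_a$ | 0.20 /h (oil), 0.45 /h (nanoemulsion) | slow enough for a mid-study serum peak, fast enough that the 24 h collection captures essentially all lymph-routed drug (gut residue $e^{-24 k_a} < 1\%$) |
| $k_{lt}$ | 0.4 /h | lymph transit of a few hours, peaking shortly after serum |
| LLOQ | 1 ng/ml | the validated bioassay limit |
| residual CV | 15 % | assay precision (~10 %) plus sampling/handling variability |
| inter-animal CV | 30 % | typical log-normal between-subject variability of PK parameters |

The default schedules are the study design itself: 13 serum samples and 13
contiguous lymph intervals at 1–12 and 24 h post-dose for oral periods;
13 IV samples from 5 min to 24 h; 200 mg oral and 20 mg IV doses.

## Truncation convention

For interspecies comparison the partition is additionally computed 8 h
after dosing: $F_{AL}$ restricted to intervals ending at or before 8 h and
the oral exposure taken as $AUC[0,8]$. The intravenous reference is always
dose-normalized by its full $AUC_\infty$ — the reference animal's
disposition is not truncated by the oral observation window. This choice
is not forced by the estimand definitions; it is configurable, always
recorded in the settings ledger, and the exposure *ratios* (lymph/serum
$C_{max}$, $T_{max}$, AUC) are always computed from the untruncated
profiles.

## Statistics

Formulation effects use a two-sided paired t-test on per-animal values (no
period/sequence adjustment — appropriate for a 2×2 cross-over analyzed
descriptively); interspecies contrasts use the two-sided two-sample
Student t-test (equal variances, the classical small-n reporting
convention; Welch is available behind a flag). No multiplicity correction
is applied across parameters. Zero-variance degenerate inputs are reported
explicitly instead of as $p = 0$ artifacts. Calibration is verified by
simulation: both tests hold the nominal 5 % size within Monte-Carlo bounds
at 2000 null replicates.

## Validation by parameter recovery, and what it does not show

The validation suite simulates, estimates, and compares against the truth
sidecar: a noise-free sweep across $\phi_{lymph} \in \{0.05,\dots,0.5\}$
(24 h collection) recovers $F_{AL}$ within ~2 % relative (the small deficit
is the mass still in transit in the lymph compartment at 24 h) and $F_{RL}$
within ~0.3 percentage points; with 15 % residual CV the median
$|F_{RL}|$ error over 200 simulated animals stays around 1 point. The
problem sizes (10-point sweep, 200 animals, 2000 test replicates) were
chosen as the smallest that make the Monte-Carlo bounds meaningful.

Passing these gates shows the estimators are faithful to the model's
assumptions; it does not certify them for everything real lymph data can
do. The generator does not emulate: blood contamination of the collected
lymph, catheter patency loss and interrupted collections, enterohepatic
recirculation, nonlinear (saturable) absorption or elimination,
food-triggered surges in lymph flow and chylomicron output, or assay
carry-over. Of these, the first two are the dominant practical failure
modes of real cannulated studies.

A limitation the simulation *does* expose: with a single IV reference
animal, every $F_{AP}$ (hence $F$ and $F_{RL}$) inherits that one
animal's between-animal deviation and the noise of its sparse terminal
samples as a fully correlated error. The direct mass-balance $F_{AL}$ is
immune. Within-study formulation comparisons are also unaffected, because
the shared reference cancels in paired differences.

## Degenerate inputs and numerical edges

* All-BLQ profiles are an error for serum NCA but only void the lymph
  ratio columns of a transport result ($F_{AL}$ is still defined — zero
  collected mass).
* A profile with no declining tail yields an absent terminal fit and
  `NA` extrapolated quantities with an explicit flag, never a fabricated
  slope.
* `relative_lymph_bioavailability(0, f > 0)` is 0 by convention;
  `f = 0` with `f_al > 0` is an inconsistency error.
* Overlapping lymph intervals, negative volumes, non-monotone sampling
  times and unknown configuration keys are rejected at the boundary with
  line-referenced messages.
* Every stochastic operation takes an explicit integer seed and restores
  the caller's RNG state; the full pipeline is bit-reproducible from one
  seed.
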