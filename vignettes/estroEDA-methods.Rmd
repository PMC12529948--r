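---
title: "Models and methods behind estroEDA"
author: "estroEDA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind estroEDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estroEDA)
```

`estroEDA` packages the computational chain of an effect-directed analysis
(EDA) of estrogenic elastomer leachates: nontarget screening (NTS) feature
prioritization, yeast-estrogen-screen (YES) dose–response modelling,
standard-addition quantification, redox-couple speciation kinetics, and the
closing effect balance. This vignette explains each model, its assumptions,
the defaults and why they were chosen, what the synthetic data emulate, and
where the package's guarantees end.

## The prioritization cascade

An NTS run yields thousands of features (m/z, retention time, intensity)
per ionization polarity. The cascade encodes the experimental logic that a
genuine effect driver must satisfy simultaneously:

1. it is detected in the extract at both enrichment levels (5× and 1×);
2. it survives the bioactivity-guided fractionation, i.e. appears in the
   upper or lower HPTLC fraction;
3. its intensity does not *decrease* with enrichment (1× intensity must
   not exceed the 5× intensity);
4. it is not explained by the fractionation process itself (process-blank
   subtraction, on any match — the strictest reading, since a fold-change
   rule would need a threshold the procedure does not define);
5. it appears in **both** fractions — the signature of a compound pair in
   chemical equilibrium smearing across the separation;
6. it carries more than 1 % of the summed feature intensity.

Steps are applied in this narrative order deliberately, rather than in a
set-theoretically equivalent but reordered form, so the per-step counts are
interpretable against the laboratory workflow. The 1 % denominator is the
summed intensity of all features in the 5×-extract table of the same
polarity: that table is the cascade's reference sample, and a ratio
threshold keeps the step invariant under uniform intensity rescaling.

Cross-table matching is tolerance-based (10 mDa MS1, 1 min RT — standard
QToF screening tolerances) with one-to-one assignment: admissible pairs are
ranked by m/z distance, ties by RT distance, then by row index, and
assigned greedily. The test suite checks this, and the whole cascade,
against an independent brute-force all-pairs implementation on every
synthetic scenario.

## Exact masses, peak picking, library matching

Monoisotopic masses are summed from CODATA atomic masses; ion m/z uses the
**electron-corrected proton mass** (1.0072765 Da) rather than the hydrogen
atom mass. The difference (~0.5 mDa) matters at screening precision: the
quinone-imine [M+H]⁺ of C₁₂H₉NO prints as 184.0757 only with the proton
convention, and positive and negative adducts of one formula differ by
exactly two proton masses.

Peak picking follows the screening settings (minimum apex 10 counts,
S/N ≥ 3, FWHM 5–60 s). The underlying vendor-side algorithm is not public,
so the noise estimator is an explicit, testable choice: the trace is
detrended by a running median much wider than the widest allowed peak, and
noise is the MAD-based sigma of the detrended baseline after masking
candidate signal. Maxima sharing one half-height region are merged to the
highest apex, which keeps noise on a peak top from splitting detections.

Library matching assigns identification confidence levels from the
available evidence: m/z + RT only → level 4; a feature MS2 spectrum with no
library spectrum to compare → 3; a library MS2 match → 2; the same with a
measured reference standard → 1. "MS2 match" means at least half of the
library entry's fragment peaks are recovered within the 15 mDa MS2
tolerance — the tolerance is prescribed by the screening settings, the
0.5 score bar is this package's documented default since no match-count
rule is prescribed anywhere.

## Dose–response and estradiol equivalents

Plate series are fitted with the four-parameter logistic
$$ r(c) = \theta_{min} + \frac{\theta_{max} - \theta_{min}}
   {1 + (EC_{50}/c)^{h}} $$
by Levenberg–Marquardt least squares with a fixed starting heuristic
(floor = min response, ceiling = max response, EC50 = geometric mid-dose,
hill = 1), which makes every fit deterministic. Effect concentrations are
defined relative to the fitted span (ISO-style induction ratio), with the
analytic inverse $EC_p = EC_{50}\,(p/(100-p))^{1/h}$; their 95 % CIs come
from the first-order delta method on the fit's parameter covariance with
the fit's t quantile. The tests cross-check these intervals against
parametric-bootstrap quantiles (agreement within 10 % on well-conditioned
fits) and verify ≥ 90 % empirical coverage over 200 simulated plates at
assay-like noise (CV 0.1, triplicate, seven 1:2 dilutions).

A sample of unknown composition is handled on a relative-concentration
axis (1/dilution factor). Its estradiol equivalent is
E2-EQ = EC10(PC) / c*, where c* is the relative concentration at which the
sample's own 4PL fit crosses the positive control's 10 % effect level; the
CI propagates through both (independent) fits by the delta method. A
sample whose fitted ceiling never reaches that level is reported as below
the effect threshold rather than extrapolated.

## Standard addition

The unspiked sample enters as spike level 0 — without it the x-intercept
construction is undefined. All replicates are pooled into one ordinary
least-squares line (the default; per-series fitting would propagate three
separate intervals instead), the in-assay concentration is |a/b|, and its
CI follows first-order (Fieller-type) propagation of the (a, b)
covariance. Dilution correction multiplies the point estimate and the CI
by total/aliquot volume (factor 6 for 20 µL in 120 µL). LOD and LOQ assume
S/N proportional to concentration — the only reading under which
extrapolating a measured (concentration, S/N) pair to S/N 3 and 10 gives
unique values — so LOQ/LOD is exactly 10/3.

## Speciation kinetics

The two redox species' chromatographic areas are normalized to an internal
standard; the reduced-species fraction is
$f = A_{red}/(A_{red} + A_{ox})$. Fractions are carried on the 0–1 scale
internally (percent is accepted and converted), so a fitted slope of
−6.6 × 10⁻⁴ h⁻¹ corresponds to the printed per-hour decline of a
percentage series — the only dimensionally consistent reading of such
slopes over a 173 h experiment spanning ~92 % → ~81 %.

Two models are offered per pH: a linear decline $f_0 + s\,t$ for the slow,
far-from-equilibrium regime, and an exponential approach to plateau
$f(t) = p + (f_0 - p)\,e^{-kt}$ (the closed-form solution of two-state
first-order interconversion) where equilibrium is reached. Model
assignment is configurable; the default maps pH ≤ 7 to linear and pH ≥ 8
to exponential, mirroring how such data are usually read, with an `auto`
mode selecting by R² (ties favour linear; `auto` warns below 6 points).
Exponential starts are deterministic (f0 = first value, plateau = last
value, k = 3/t_max) and f0 is left free rather than pinned to the first
observation. The mass-balance diagnostic — relative deviation of the
summed area ratios from their mean, pass below 4 % — flags losses to side
reactions. Acid–base speciation uses Henderson–Hasselbalch; the phenol's
pKa is a required input because no reliable value is assumed.

The electrochemical half-reactions behind the couple are represented only
as this two-state interconversion with a pH-dependent effective rate; no
electron/proton bookkeeping or Nernst modelling is attempted.

## Effect balance and error propagation

The closing chain is
$$ REP = \frac{EC_{10,E2}}{EC_{10,analyte}}, \qquad
   \text{E2-EQ}_{analyte} = REP \times C, \qquad
   \% = \frac{\text{E2-EQ}_{analyte}}{\text{E2-EQ}_{sample}} \times 100. $$
All four inputs are products/ratios, so first-order Gaussian propagation
reduces to adding relative 95 % half-widths in quadrature. The half-widths
are propagated directly (equivalent to treating them as proportional to
standard deviations under equal coverage), and the inputs are treated as
independent because they come from four separate experiments. Chaining the
three operations is then *exactly* equivalent to the single-formula
evaluation — the tests assert this composition law to machine precision,
and check the propagated half-widths against a 100,000-draw Monte-Carlo
quantile oracle (agreement within 5 % for input relative errors up to
20 %; beyond that the ratio distribution's skew makes a first-order
interval progressively optimistic).

```{r balance}
effectBalance(ValueWithCI(19, 3), ValueWithCI(329000, 59000),
              ValueWithCI(3e6, 1.7e5), ValueWithCI(140, 7))
```

## What the synthetic data emulate — and what they don't

The generators define the study conditions under which the pipeline is
exercised:

* **Feature scenarios** (default 100 background + 2 drivers, intensity CV
  0.05): drivers appear in both extracts with 5× intensity exactly
  proportional to enrichment before noise (the cascade's monotonicity
  assumption made literal), in both fractions, never in the blank, and far
  above the 1 % intensity bar; every background feature violates at least
  one named cascade criterion. Observed m/z and RT carry per-table jitter
  (2 mDa, 0.05 min) well inside the matching tolerances. Intensity noise
  is multiplicative log-normal — instrument-like and positivity-preserving.
* **YES plates**: 4PL responses with multiplicative log-normal noise
  (CV 0.1, triplicate). The positive-control grid is ten geometric steps
  from 0.66 to 500 ng/L — the nominal 1:2 serial dilution of the assay
  (step ratio 2.09; exact doublings from 0.66 would top out at 338). PC
  truth (EC50 120 ng/L, hill 1.2) is calibrated so EC10 ≈ 19 ng/L; analyte
  truth (EC50 820 µg/L, hill 2.4) so EC10 ≈ 329 µg/L; the synthetic
  leachate carries 140 ng/L E2-EQ.
* **Standard addition**: spikes 210/420/630/840 µg/L over a true in-assay
  concentration of 500 µg/L (×6 dilution → 3000 µg/L), linear response,
  CV 0.05.
* **Kinetics**: the 14-timepoint grid to 173 h, additive Gaussian noise
  (sd 0.01 on fractions) truncated so the summed areas stay within the 4 %
  mass-balance band by construction; per-pH parameters reproduce the
  observed regimes (f0 0.92–0.95; near-linear decline at pH 5–7 with
  effective slopes around −6.6 × 10⁻⁴ to −1.7 × 10⁻³ h⁻¹; plateaus 0.58
  and 0.53 reached within ~100 h at pH 8–9).

What passing tests on these data show is that the *computations* are
correct and well-calibrated under their stated noise models. What they do
not show: real feature tables contain adduct/isotope multiplicities,
retention-time drift, and intensities that scale sub-proportionally with
enrichment (matrix suppression); real plates show edge effects and
cytotoxicity masking; real kinetic replicates share correlated IS error.
None of these are simulated, and the cascade deliberately performs no
componentization or adduct grouping.

## Numerical choices and degenerate inputs

* All nonlinear fits use deterministic starting values; no restarts, no
  randomness. Two runs of `runPipeline()` with one seed are identical; the
  master seed forks per stage.
* Flat traces yield zero peaks (not an error); constant response series
  are a "no response" error in `fit4PL()` but a degenerate slope-0 fit in
  `fitKinetics()` (a legitimate no-conversion observation).
* A zero-area timepoint is an error naming the timepoint
  (`speciesFraction`), since a vanished total signals a measurement
  failure rather than a fraction of zero.
* Alignment ties (equal m/z distance) break by RT distance, then row
  index, making the one-to-one matching reproducible.
* Canonical units are ng/L, Da and minutes; conversions happen only at
  interfaces (e.g. µg/L quantification results are scaled by 1000 when
  entering the ng/L effect balance) to avoid silent 1000× unit errors.

## Problem sizes in the checks

The statistical guarantees quoted above are verified at fixed sizes chosen
to make the checks sharp yet quick: 50 cascade scenarios against the
brute-force oracle, 200 simulated plates / spike series / kinetic series
for coverage and recovery rates, 2,000-draw bootstraps and a 100,000-draw
Monte-Carlo oracle for interval cross-checks. These sizes are the
package's own test design; the estimators themselves have no built-in
limits.

## Known limitations

* Confidence levels 1–4 are assigned from tabular evidence only; there is
  no isotope-pattern scoring, in-silico fragmentation or RT prediction.
* The 4PL covariance (and hence every delta-method CI) assumes
  homoscedastic Gaussian residuals; the log-normal noise of real readouts
  is handled well at CV ≤ ~0.15 but intervals degrade beyond that.
* First-order propagation understates ratio uncertainty once relative
  errors exceed ~20 %.
* The pipeline starts at feature tables; raw vendor files, mzXML parsing
  and HPTLC image evaluation are out of scope.
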