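---
title: "Methods: response-surface, surrogate and film-theory analysis of microbubble esterification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response-surface, surrogate and film-theory analysis of microbubble esterification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbester)
```

## The system

Unrefined microalgae oil carries a high free-fatty-acid (FFA) load — about
32.5% by mass for the *Spirulina*-derived feed this package models — which
rules out direct base-catalyzed transesterification (soap formation) and
forces an acid-catalyzed esterification pretreatment: FFA + methanol →
methyl ester + water, here with p-toluenesulfonic acid. Conventionally this
step is slow because methanol and oil barely mix. Sparging the methanol as
*vapor microbubbles* through catalyst-primed oil changes the picture: the
bubbles present an enormous gas–liquid interface, rise slowly, and keep the
local methanol supply in excess at the interface, so the reaction completes
in tens of minutes at 3 L scale rather than hours.

The package implements the computational side of characterizing such a
reactor: a Box-Behnken design (BBD) over the three operating factors, a
quadratic response-surface model (RSM) of conversion, a gated-recurrent-unit
(GRU) surrogate trained on the same table, their comparison, gas–liquid
film-theory kinetics, Arrhenius activation-energy estimation, and the
titration arithmetic that turns acid values into conversions. Because the
study's run-level data (the 17-run response table, the measured
rate-constant series, the raw titrations) are not published, a seeded
synthetic-data module emulates each of them from the published summary
quantities; everything downstream is tested against those generators.

## Experimental design and factor coding

The three factors are the methanol:oil molar ratio $A \in [5, 25]$ (stored
as the numeric multiplier of the "1:N" notation), catalyst dosage
$B \in [0, 5]$ wt% of oil, and reaction time $C \in [10, 90]$ min. Coding is
linear: $x_\mathrm{coded} = (x - \bar{x}) / h$ with $\bar{x}$ the range
midpoint and $h$ the half-range, so −1/0/+1 are low/mid/high. `build_bbd()`
emits the 12 edge midpoints of the cube in lexicographic factor-pair order
— $(\pm1,\pm1,0), (\pm1,0,\pm1), (0,\pm1,\pm1)$ — followed by the center
replicates (5 by default, giving the classical 17-run table). The source
study does not report its run order, so the canonical order is
deterministic and an optional `shuffle_seed` provides reproducible
randomization. Coded columns of a generated table sum to zero, are mutually
orthogonal, and carry exactly four runs at each of ±1 per factor; the test
suite asserts all three properties.

## The quadratic response surface

`fit_quadratic()` solves ordinary least squares on the 10-term basis
$[1, A, B, C, AB, AC, BC, A^2, B^2, C^2]$ in coded units. Conventions worth
stating explicitly:

* **RMSE is $\sqrt{SSE/n}$** (divisor $n$, not $n-p$). This is the
  convention under which the reported full-data residual scale of 3.0832%
  is reproducible as a root-mean-square, and it matches the metrics module.
* **ANOVA uses sequential (Type-I) sums of squares** in the canonical term
  order. On the orthogonal coded BBD these coincide with partial (Type-III)
  SS for the linear and interaction terms; only the mutually correlated
  pure-quadratic block differs. Sequential SS were chosen because they keep
  the table exactly additive (term SS + residual SS = total SS), which
  partial SS cannot guarantee for the quadratic block. Lack-of-fit and pure
  error are split from the residual using replicated design points; with 5
  centers the pure-error row has 4 degrees of freedom. Without replicates
  the lack-of-fit rows are omitted with a warning. F-tests use the F
  distribution with no multiplicity correction.
* **Predictions are not clipped** to [0, 100] by default: the fitted
  quadratic exceeds 100% in parts of the cube, and hiding that would
  misrepresent the model. A `clip` flag exists for display.

`optimize_response()` maximizes the quadratic over $[-1,1]^3$ *exactly* by
active-set enumeration: each coordinate is either free or pinned at ±1 (27
cases); for each case the stationary point of the reduced quadratic is
solved in closed form, infeasible candidates are discarded, and the best
feasible candidate wins (ties broken by predicted value, then lexicographic
coded order). Faces on which the reduced quadratic is singular have no
isolated interior stationary point and are covered by their edge/vertex
cases. The report carries the Hessian eigenvalues so non-concave directions
are visible rather than being an error.

A subtlety the interface deliberately accommodates: the *reported* operating
optimum (ratio 1:23.73, 3.3 wt%, 59.79 min; coded ≈ (0.873, 0.32, 0.245))
is an interior point of the cube but **not** the stationary point of the
published quadratic — its gradient there is nonzero, and the true
box-constrained maximizer lies on the boundary with a predicted value above
100%. Whatever desirability weighting or constraint produced the reported
point is not stated, so the package does not try to reproduce it as an
optimum. Instead `optimize_response(model, at = ...)` evaluates an explicit
point (location kind `"evaluation point"`), which reproduces the reported
99.09–99.10% prediction there, while the default mode returns the honest
mathematical maximizer.

`model_hierarchy()` ranks the nested linear / two-factor-interaction / full
quadratic bases by adjusted R², the criterion under which the quadratic
class is preferred for this response.

## The GRU surrogate

The cell implements the bias-free gate equations exactly as printed for
this model class:

$$r_t = \sigma(W_r h_{t-1} + U_r x_t), \qquad
\tilde{h}_t = \tanh(W(r_t \odot h_{t-1}) + U x_t),$$
$$z_t = \sigma(W_z h_{t-1} + U_z x_t), \qquad
h_t = (1 - z_t) \odot h_{t-1} + z_t \odot \tilde{h}_t.$$

Design choices where the source is silent:

* **Sequence construction.** A DOE table has no natural sequence axis, so
  each run is a length-1 sequence whose single input is the coded factor
  triple, started from $h_0 = 0$, with a linear readout of $h_1$. Inputs
  are already in $[-1,1]$ and are not rescaled.
* **Loss and optimizer.** Mean-squared error, full-batch **Adam**
  (β₁ = 0.9, β₂ = 0.999, ε = 1e−8), with the gradient vector globally
  norm-clipped at the 0.1 threshold *before* the Adam update and the
  published step-decay schedule (0.01 for epochs 0–99, 0.002 for 100–149).
  The hyperparameter set — a gradient-norm threshold plus an initial rate
  with periodic drops — is the signature of the Adam-family trainers used
  by mainstream deep-learning toolboxes, and under plain gradient descent
  those same numbers cap total parameter movement at
  `epochs × lr × clip ≈ 0.15`, far too small to fit responses spanning
  30–99%. Adam is also what makes the 150-epoch budget sufficient.
* **Target standardization.** Responses are standardized to zero mean and
  unit variance for optimization (the clip threshold and learning rates are
  sensible on that scale); the transform is stored in the weights and
  undone at prediction time, so the public interface speaks raw % only.
  For a constant response (zero variance) the scale falls back to 1 and the
  model fits immediately through the readout offset.
* **Initialization.** Gate and candidate matrices are uniform on
  $(-1/\sqrt{n_h}, +1/\sqrt{n_h})$ from a private seeded stream (draw order
  $W_r, U_r, W_z, U_z, W, U$); the readout starts at zero with offset equal
  to the (standardized) mean response. Training is bitwise reproducible
  given (seed, hyperparameters, table).
* **Evaluation is in-sample** on all 17 runs: the study reports fit
  quality, not a held-out split, and with 17 observations a split would be
  noise.

Because $h_0 = 0$, the recurrent matrices $W_r, W_z, W$ (and $U_r$, which
only acts through $r \odot h_0$) receive exactly zero gradient on length-1
sequences; the analytic backward pass reproduces this, and the
finite-difference check in the test suite covers all eight parameter blocks.

## Comparison metrics

`score_metrics()` computes $R^2 = 1 - SSE/SST$, $RMSE = \sqrt{SSE/n}$,
$MAE$, and $MAPE = \mathrm{mean}(|a-p|/|a|)$ **as a fraction** (0.0465, not
4.65%) — the convention of the comparison it mirrors. MAPE is skipped with
a warning when any actual value is zero; zero variance in the actuals is an
error. `compare_metrics()` reports the MAE ratio and its integer rounding
(the published RSM/GRU pair 2.6847/0.045 rounds to 60). `parity_data()`
emits the predicted-vs-actual points and the 45° line spanning the pooled
range, ready for plotting.

## Film-theory kinetics

The extracted text of the source correlations is typographically damaged,
so each function documents and implements one canonical algebraic reading;
these readings are package decisions, not verbatim facts:

| quantity | adopted form |
|---|---|
| solubility at 25 °C | $M_{25} = 6.02\times10^{-5}\, V_l^{0.36}\, \mu_l^{0.61}\, V_g^{0.64}$ |
| solubility at $T$ | $M_T = 4.996\times10^{3}\, M_{25}\, e^{-2539/T}$ |
| film coefficient (< 2 mm bubbles) | $k_{bl} = 0.31\,(D^2 \rho g / \mu)^{1/3}$ |
| Hatta number | $Ha = \sqrt{M_T\, k\, C_b} / k_{bl}$ |
| instantaneous enhancement | $E_i = 1 + M_T C_b / (H_b P_g)$ |
| enhancement (Danckwerts) | $E = Ha\,(1 - (Ha-1)/(2E_i))$ |
| series-resistance rate | $-r_A = P_g \big/ \big(1/k_g\sigma + Ha/\sqrt{M_T k C_b}\big)$ |
| lumped rate | $-r_A = 1.32\times10^{-5} (P_A \times 101325)\, C_b$ |

The temperature correlation is self-consistent at 25 °C
(`solubility_T(M25, 298.15)` returns 1.0005·M25). The published constants
($k_g\sigma = 5.32\times10^{-3}$, $k_{bl} = 1.24\times10^{-4}$ m/s,
$H_b = 43.05$, $k_r = 1.32\times10^{-5}$) ship as `film_defaults()`. Units
are SI internally (K, Pa, m, s, kmol); the lumped rate law alone takes its
pressure in atm because its printed constant absorbs the ×101325
conversion. Regime classification is `surface` iff $Ha > 1$;
pseudo-first-order behavior is declared when $|E - Ha|/Ha \le 0.1$ (the
narrative criterion "almost equal" given a number). An enhancement factor
below 1 is outside the Danckwerts approximation's range and warns rather
than errors. Note that with pascal-scale pressures the additive $E_i$
reading stays ≈ 1, so realistic methanol conditions trigger that warning —
a direct consequence of the dimensional inconsistency in the printed
constants, preserved here rather than silently repaired.

`fit_arrhenius()` regresses $\ln k$ on $1/T$ and reports
$E_A = -\mathrm{slope} \times R$ in kJ/mol (R = 8.314 J mol⁻¹ K⁻¹) with the
slope's standard error. It is exact on exactly-Arrhenius data; the test
suite verifies a 10.01 kJ/mol round trip at 70/80/90 °C and unbiasedness
under 2% ln-scale noise over 200 seeded replicates (the Monte-Carlo
standard error of that 200-replicate mean is itself ≈ 1% of $E_A$, which is
why the check is a 3-standard-error bound rather than a fixed percentage).

## Titration assay

Acid value $AV = (F_A - F_B) \times N \times 56.11 / W$ (mg KOH per g);
FFA% $= AV/2$, the standard oleic-acid-basis factor (the printed "12×" in
the source rendering is typography for ½×, since only $AV/2$ reproduces the
32.5% FFA feed from plausible titration volumes — documented prominently
because the misreading is easy to make). Conversion is defined on FFA:
$X = 100\,(ffa_0 - ffa_t)/ffa_0$. The conversion–time model is
pseudo-first-order with $X(0) = 0$ enforced:
$X(t) = 100\,(1 - e^{-k_{obs} t})$, fitted by through-origin least squares
of $-\ln(1 - X/100)$ on $t$; a single informative point reduces to the
closed form $k_{obs} = -\ln(1 - X/100)/t$. Calibrated at the reported 97%
by 40 min, $k_{obs} = 0.08766$ min⁻¹ and the 60-min prediction is 99.48%,
inside the reported 99.45 ± 1.3% band.

## Synthetic data: what it emulates and what it does not

`synth_config()` defaults *are* the study conditions: generating surface =
the published quadratic; response noise σ = 3.0832% (the published
full-data RMSE, the best available proxy for the unavailable replicate
noise); Arrhenius $E_A$ = 10.01 kJ/mol at 343.15/353.15/363.15 K with
$\ln A_0$ chosen so $k(343.15\,\mathrm{K}) = 1$ in arbitrary units (only
the slope matters to the fit); time course $k_{obs} = -\ln(0.03)/40$
sampled every 10 min over 0–60 min (the study's sampling interval);
titrations built from a 32.5% FFA feed with 0.5 N titrant and 1 g samples.
Noise is Gaussian on responses and lognormal on rate constants
(positivity). Each generator draws from a private stream seeded at
`seed + offset` (101/202/303/404), so adding or reordering generator calls
never perturbs another generator's output, and the global RNG state is
restored afterwards.

At zero noise every generator is exactly inverted by its analysis module:
center responses are exactly 88.68, `fit_arrhenius()` recovers the
generating $E_A$ to machine precision, and the titration chain round-trips
conversions to 1e−10.

What the generator deliberately does **not** emulate: run-order or drift
effects, heteroscedastic or non-Gaussian measurement error, replicate
structure beyond the center points, any lack-of-fit (responses are drawn
*from* the quadratic, so the true surface is exactly quadratic), and the
bubble physics itself. Consequently, passing tests demonstrate that the
estimators recover what generated the data under the stated noise — they
cannot certify the published empirical fit statistics (R² 0.9844/0.9999,
RMSE 3.0832/0.0515, MAE 2.6847/0.045), the measured scale-up conversions
(99.12/99.55/99.45% at 1/2/3 L), or the measured $E_A$, all of which depend
on run-level data that were never published. Those printed values are used
only as generator calibration and as fixed inputs (e.g. the MAE ratio
arithmetic).

## Numerical conventions and problem sizes

Coding/decoding round-trips hold to 1e−12 relative; OLS recovery on
noiseless data is asserted at 1e−8 (observed ~1e−14); quadratic prediction
matches a term-by-term oracle at 1e−12; the GRU gradient check uses central
differences with step 1e−6 and a 1e−4 relative bound; gradient clipping
guarantees post-clip norm ≤ threshold + 1e−12. Optimization tie-breaks are
value first, then lexicographic coded order. Degenerate inputs fail loudly:
fewer than 3 factors, inverted factor ranges, rank-deficient designs
(naming the collinear columns), saturated conversions (X ≥ 100%), fewer
than 2 distinct temperatures, non-positive rate constants.

The test suite runs at the study's own scale — 17-run tables, 3-temperature
Arrhenius series, 7-point time courses — plus 400 seeded tables for the
center-mean calibration check and 200 replicates for the Arrhenius
Monte-Carlo study; the full suite completes in well under a minute.

## Known limitations

* The film-theory readings (Hatta, $E_i$, $E$, series-resistance rate) are
  canonical reconstructions of typographically damaged expressions; the
  published $H_b$ units are dimensionally inconsistent with a Henry
  constant, and the inputs behind $k_r = 1.32\times10^{-5}$ are not
  printed, so that constant is shipped as-is rather than re-derived.
* The GRU's training protocol (optimizer, loss, scaling, split) is a
  package decision, so its published fit metrics are a plausibility
  anchor, not a reproduction target.
* The box-constrained optimizer reports the mathematical maximizer of the
  fitted quadratic, which exceeds 100% conversion for the published
  surface; physical interpretation stops at the cube boundary.
* No other designs (central composite, factorial), no desirability-based
  multi-response optimization, no GC chromatogram processing, and no
  bubble-population or CFD modeling.
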