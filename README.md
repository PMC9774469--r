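# mbester

Analysis toolkit for semi-pilot-scale **microbubble-mediated esterification**
of high free-fatty-acid (FFA) microalgae oil with methanol vapor, catalyzed
by p-toluenesulfonic acid. Sparging methanol as vapor microbubbles through
acid-primed oil gives a large gas–liquid interfacial area and long bubble
residence times, so the pretreatment esterification (FFA + MeOH → FAME +
H₂O) that normally limits biodiesel production runs to completion in tens of
minutes. The package is aimed at reaction engineers characterizing such
reactors: it covers the design of experiments, the empirical response
models, the film-theory kinetics, and the wet-chemistry conversion
accounting, plus seeded synthetic-data generators for all of the inputs.

## What it computes

**Box-Behnken design and quadratic response surface.** Three factors —
methanol:oil molar ratio *A* (5–25), catalyst dosage *B* (0–5 wt% of oil),
time *C* (10–90 min) — in coded units (−1, 0, +1), 12 edge midpoints plus
replicated centers. The conversion surface is the full quadratic

    y = b0 + bA·A + bB·B + bC·C + bAB·AB + bAC·AC + bBC·BC
        + bAA·A² + bBB·B² + bCC·C²

fitted by OLS, with sequential ANOVA, a lack-of-fit test from the center
replicates, exact box-constrained maximization over [−1,1]³, and
perturbation traces. The reported surface for this system
(`mo_conversion_model()`) is

    Conversion(%) = 88.68 + 3.27A + 26.13B + 7.97C + 3.24AB + 3.49AC
                    + 3.98BC − 1.74A² − 29.76B² − 5.81C²

**GRU surrogate.** A from-scratch gated recurrent unit (reset gate
r = σ(Wr·h + Ur·x), candidate h̃ = tanh(W(r⊙h) + U·x), update gate
z = σ(Wz·h + Uz·x), state h′ = (1−z)⊙h + z⊙h̃, no biases) treating each
design run as a length-1 sequence of the coded triple, trained by
full-batch Adam under a global gradient-norm clip and a step-decay
learning-rate schedule (50 hidden units, clip 0.1, lr 0.01 ×0.2 every 100
epochs, 150 epochs).

**Model comparison.** R², RMSE (divisor *n*), MAE, and MAPE (as a
fraction), plus parity-plot data with the 45° reference line.

**Film-theory kinetics.** Solubility correlations, the small-bubble
liquid-film coefficient, the pseudo-first-order Hatta number
Ha = √(M·k·Cb)/k_bl, instantaneous and Danckwerts enhancement factors,
surface/bulk regime classification, two-film series-resistance and lumped
rate laws, and Arrhenius activation-energy fitting (ln k = ln A₀ − EA/RT).

**Titration assay.** Acid value (FA−FB)·N·56.11/W, FFA% = AV/2, conversion
accounting, and an origin-constrained pseudo-first-order conversion–time
model X(t) = 100(1 − e^(−k·t)).

**Synthetic data.** Seeded generators emulate every unpublished input: the
17-run response table (published quadratic + Gaussian noise at the reported
residual scale), Arrhenius rate-constant series over 70–90 °C,
conversion–time curves, and raw titration records. Generators use split RNG
streams, so outputs are reproducible independently of call order.

## Worked example

```r
library(mbester)
report <- run_pipeline(synth_config(seed = 42), hp = gru_hyperparams(seed = 42))
report
#> <pipeline_report>
#>   seed: 42
#>   runs: 17
#>   generating-model center prediction (%): 88.68
#>   RSM fit: R2 0.9895, adj R2 0.9760, RMSE 2.4773
#>   RSM optimum: coded (1.0000, 0.5875, 1.0000), predicted 109.73% (boundary)
#>   GRU in-sample: R2 0.9893, RMSE 2.5006
#>   MAE ratio RSM/GRU: 1.07 (~1 x)
#>   Arrhenius: EA 10.0100 kJ/mol (R2 1.000000)
#>   first-order k_obs: 0.087664 /min; predicted conversion at 60 min: 99.48%
```

Reading the output: the synthetic 17-run table is generated from the
published quadratic with σ = 3.0832% noise, so the refitted surface recovers
it to within that noise (R² 0.99, RMSE 2.48). The box-constrained maximizer
of the quadratic lies on the cube boundary and exceeds 100% — fitted
quadratics are not bounded by physics, which is why predictions are not
clipped by default. The Arrhenius stage recovers the generating activation
energy of 10.01 kJ/mol exactly from the noiseless default rate-constant
series, and the titration-derived first-order model calibrated at 97%
conversion by 40 min predicts 99.48% at 60 min. The published quadratic
itself evaluates to 88.68% at the design center and 99.09% at the reported
operating optimum (molar ratio 1:23.73, 3.3 wt% catalyst, 59.79 min):

```r
f <- esterification_factors()
predict(mo_conversion_model(),
        c(to_coded(23.73, f$A), to_coded(3.3, f$B), to_coded(59.79, f$C)))
#> [1] 99.08794
```

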