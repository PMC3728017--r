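# thmix

Tunable Th1–Th2 differentiation: gene-network motif analysis, a two-stage
stochastic cytokine model, and a calibrated synthetic flow-cytometry
toolkit, in one R package.

## The scientific problem

Naive CD4+ T cells differentiate towards the Th1 lineage under IL-12 and
towards Th2 under IL-4. When both cytokines are present, the classic
toggle-switch picture predicts a binary decision; single-cell measurements
instead show a *continuously tunable mixed state*, in which the two master
regulators T-bet and GATA3 are co-expressed at levels that track the input
mixture, while the effector cytokines IFN-γ and IL-4 switch on
stochastically and independently, with probabilities biased by the
corresponding TF.

`thmix` is for computational immunologists and systems biologists who want
to work with that picture quantitatively: analyse the core regulatory motif,
simulate realistic single-cell datasets over an IL-12 × IL-4 input matrix,
and compute the single-cell statistics that discriminate a tunable
monostable system from a bistable switch — without any external data.

## The model

**Stage 1 — deterministic TF dynamics.** Two lineage TFs x (T-bet) and
y (GATA3) cross-inhibit and auto-activate (time rescaled so degradation = 1):

    dx/dt = β₁ + b · xⁿ/(xⁿ+k_ax ⁿ) · k_cx ⁿ/(yⁿ+k_cx ⁿ) − x
    dy/dt = β₂ + b · yⁿ/(yⁿ+k_ay ⁿ) · k_cy ⁿ/(xⁿ+k_cy ⁿ) − y

β₁, β₂ carry the IL-12/IL-4 inputs (saturating map β = β_max·c/(c+K)).
The fixed-point structure is organised by the cross-to-auto threshold
ratios k̃ᵢ = k_c/k_a: for gradual feedback (n = 1) the (k̃₁, k̃₂) plane
splits into four regimes — single Th1-like state (I), single Th2-like
state (II), a single *co-expressed* state that tunes continuously with
inputs (III), and bistability (IV).

**Stage 2 — stochastic cytokine expression.** Given its TF levels, each
cell throws two independent biased coins: P(IFN-γ on) is a logistic in
log T-bet, P(IL-4 on) a logistic in log GATA3, each with a floor and
ceiling for TF-independent factors. "On" cytokine intensity is
condition-independent; only the positive fraction tunes with inputs.

**Synthetic cytometry.** Channel intensities are
`(background + F1(IL-12)·F2(IL-4)) × E × ε` with a shared per-cell
extrinsic factor E and per-channel intrinsic noise ε (lognormal, arbitrary
fluorescence units), plus isotype and T-bet-knockout control samples. The
analysis module provides asinh/logicle transforms, isotype-anchored
normalization (isotype median → 1, 95th percentile → 10, in log space),
the per-cell angle α = atan(T-bet/GATA3), MFI matrices, rank-1
separability decomposition, 500-cell binned bias curves, binary mutual
information, BIC modality, quadrant tables and the normalized GATA3/T-bet
ratio statistic.

## Worked example

```r
library(thmix)

## the default parameterization is gradual feedback, region III
find_fixed_points(grn_params())
#>          x        y stable       eig1       eig2
#> 1 0.430804 0.430804   TRUE -0.6818327 -0.3685174
classify_region(grn_params())
#> [1] "III"
```

A single stable fixed point with x = y = 0.43: both TFs co-expressed. The
four regimes appear in a sweep of the threshold-ratio plane at balanced
inputs, and the Th1 → Th2 input trajectory is continuous (no hysteresis):

```r
kg <- exp(seq(log(0.05), log(20), length.out = 15))
phase_diagram(kg, kg, grn_params(beta1 = 0.02, beta2 = 0.02))
#> Region map: 15 x 15 grid at inputs ( 0.02 , 0.02 )
#>   regimes present: I, II, III, IV

detect_sharp_transition(grn_params(),
                        c(beta_from_concentration(540), 0),
                        c(0, beta_from_concentration(540)))
#> Continuous response
#>   max jump 0.09591 (refined 0.05739) over dynamic range 2.115
#>   forward/backward hysteresis gap 4.578e-16
```

The refined jump is about half the coarse one (a continuity certificate);
a bistable parameterization (`k_cross = 0.125`) instead shows a persistent
jump and a finite forward/backward gap.

On the data side, `report_targets()` regenerates the calibrated Th1, Th2
and mixed populations (20,000 cells each) and recomputes the headline
statistics:

```r
sapply(report_targets(seed = 1), function(x) round(x$value, 2))
#>    t4    t5    t6    t7    t8    t9   t10   t11
#> 60.04 84.00 20.24 40.80  0.99  0.40 19.46 86.50
```

Reading: under Th1 conditions 60% of cells are IFN-γ⁺ overall and 84% in
the highest 500-cell T-bet bin; under Th2 conditions 20% are IL-4⁺ overall
and 41% at the highest GATA3 levels; the normalized GATA3/T-bet ratio is
≈1 under mixed conditions versus 0.40 (Th1) and 19.5 (Th2); and the Th1 α
distribution peaks at 86.5°, i.e. hugging the T-bet axis.

## Pipeline / CLI

```sh
Rscript inst/cli/thmix.R all --out out_dir --seed 1
```

Subcommands `simulate`, `model`, `analyze`, `report` run the individual
stages from a JSON configuration (`--config cfg.json`); outputs are plain
TSV/JSON plus a run log with the package version, configuration hash and
derived seeds. See `vignettes/thmix-methods.Rmd` for the model details,
calibration rationale and known limitations.
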