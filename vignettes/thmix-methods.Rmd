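---
title: "Methods: the thmix models, calibrations and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the thmix models, calibrations and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thmix)
```

This vignette is the package's own account of its science: the regulatory
motif and its assumptions, the two-stage stochastic cytokine model, what the
synthetic-data generator emulates (and deliberately does not), how the
default calibrations were obtained, and the numerical choices that a
maintainer would otherwise have to reverse-engineer from the code. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. The regulatory motif

Th1–Th2 lineage choice is modelled by the standard two-node motif: each
master regulator activates itself and represses the other, with external
inputs feeding basal production. In dimensionless form (time rescaled so
that the degradation rate is 1):

$$\dot x = \beta_1 + b\,\frac{x^n}{x^n+k_{ax}^n}\,
           \frac{k_{cx}^n}{y^n+k_{cx}^n} - x,
\qquad
\dot y = \beta_2 + b\,\frac{y^n}{y^n+k_{ay}^n}\,
           \frac{k_{cy}^n}{x^n+k_{cy}^n} - y.$$

Assumptions baked into this form:

* basal (input-driven) production is additive, while autoregulation and
  cross-inhibition combine multiplicatively into a single feedback term of
  maximal rate `b`;
* cross-inhibition acts on production only, not on degradation (the
  alternative is unstated in the source material; production-only is the
  parsimonious reading);
* a single effective Hill exponent `n` for all four links. `n = 1`
  ("gradual feedback") is the default and the regime of interest.

### Parameters, defaults, and why

| parameter | default | meaning / rationale |
|---|---|---|
| `beta1`, `beta2` | 0.05 | input-driven basal production (dimensionless rates). The input map `beta_from_concentration()` uses β = β_max·c/(c+K) with β_max = 0.9, K = 50 ng/ml, so the experimental 0–540 ng/ml range spans saturation (540 → 0.82). |
| `b` | 1 | maximal feedback production; sets the output scale (steady states ≲ β + b). |
| `k_auto_x`, `k_auto_y` | 0.5 | autoregulation half-activation, i.e. the positive feedback engages at sub-maximal expression. |
| `k_cross_x`, `k_cross_y` | 2 | cross-inhibition thresholds; the defaults give threshold ratios k̃ = 4, the monostable co-expression regime (III). |
| `n` | 1 | gradual feedback. Steep variants (n ≥ 2) are supported and used as the bistable/discrimination contrast. |

The phase diagram is organised by k̃₁ = k_cx/k_ax and k̃₂ = k_cy/k_ay.
With balanced weak inputs (β = 0.02) and the other defaults, a log-spaced
sweep of (k̃₁, k̃₂) over [0.05, 20]² produces exactly four regimes
(`test-acceptance.R`): a Th1-like monostable region (I, k̃₁ ≫ k̃₂), its
mirror (II), co-expression (III, both ratios large — positive feedback
dominates cross-inhibition) and bistability (IV, both ratios small).

Two structural findings of this implementation, documented because they
differ from the idealised picture:

* **Region IV is a band, not a cone.** On the symmetric diagonal,
  bistability occupies k̃ ∈ ≈[0.07, 0.55]; below the band the saturated
  cross-inhibition admits a single symmetric low state (re-entrant
  monostability). The tests therefore assert the existence of a critical
  k̃\* above which no tested input yields bistability, plus bistability
  inside the band, rather than downward-closedness.
* **Bistability lives at weak inputs.** Large balanced basal production
  floods the switch, so a full-amplitude Th1→Th2 input path through a
  region-IV parameterization is monostable throughout. The hysteresis
  demonstration (`detect_sharp_transition()`) runs the path at low
  amplitude, (0.03, 0.001) → (0.001, 0.03), where a bistable segment
  exists; a steep-feedback model (n = 4, k̃ = 1) shows the persistent jump
  on the full-amplitude path as well.

### Numerics

`find_fixed_points()` seeds a damped Newton iteration (analytic Jacobian,
step halving, 80 iterations max) from local minima of the drift norm on a
combined linear + logarithmic 48×48 grid over [0, max(β)+b+0.5]², plus the
box corners and (β₁, β₂). Roots are accepted at residual < 1e-9,
deduplicated at 1e-6 relative distance, and classified stable when both
Jacobian eigenvalue real parts are < −1e-8. The degenerate case b = 0 is
answered analytically. The test suite checks the finder against an
independent oracle — dense scans along both explicit nullcline reductions
with bisection and recursive refinement at the residual's domain edges —
on 130 random parameter draws, and verifies every reported stable point by
RK4 integration from a perturbation.

`classify_region()` calls a coordinate "high" above 0.5 × (largest stable
coordinate), mirroring the ≈50% expression threshold used for the
co-expression maps; `input_response_map()` thresholds each coordinate at
`T_frac` (default 0.5) of its maximum over the map. Trajectory continuity
is certified by halving of the maximum step-to-step jump under step-count
doubling; hysteresis by a persistent jump plus a forward/backward
continuation gap.

## 2. The two-stage cytokine model

Given a cell's TF levels, each cytokine is an independent Bernoulli draw
("two biased coins") with probability

$$p(v) = p_{\min} + (p_{\max}-p_{\min})\,
         \mathrm{logistic}\!\big(s\,(\log_{10} v - m)\big),$$

monotone in the driving TF v (IFN-γ ← T-bet; IL-4, IL-13, IL-5 ← GATA3).
The floor and ceiling absorb the TF-independent influences; no additional
latent variable is modelled. The logistic-in-log shape is a free choice —
only monotonicity and the endpoint percentages are constrained by the
source material — and is kept configurable via `bias_function()`.

**Calibration.** The shipped defaults were obtained by solving (by
deterministic 2-D Newton on exact Gaussian integrals, then frozen) for the
slope and midpoint that make the *measured, thresholded* statistics hit
the reference values under the default generator: the Th1 population
60% IFN-γ⁺ overall and 85% in its top 500-cell T-bet bin; the Th2
population 20% IL-4⁺ overall and 40% in its top GATA3 bin. "Measured"
matters: positivity is called at the 99th percentile of the isotype
channel, and because the extrinsic size factor is shared across channels,
cells in the top TF bin carry elevated off-state cytokine intensities too
(≈2–4% false-positive rate there versus 1% overall). The IL-4 calibration
therefore targets a latent E[p | top bin] of 0.377, not 0.40. Between its
endpoints the curve is unconstrained; one visible consequence is that
T-bet-knockout cells retain p(IFN-γ) ≈ 0.45 — the knockout lowers but does
not silence the cytokine.

**Sorting and re-culture.** `reculture_simulation()` keeps the sorted
cells' TF levels (optionally relaxing them towards the condition median
via the `persistence` parameter, default 1 = full retention) and re-throws
the coins. Because the coins are memoryless given TF state, every quadrant
repopulates all four quadrants whenever the biases are interior to (0, 1).
Sorting on a cytokine state does select on the driving TF, so quadrant
GATA3/T-bet ratios shift by up to ≈2-fold for the rarest gate; the tests
bound the shift at 2.5-fold, which is "similar" on the scale of the
≈50-fold separation between polarized Th1 and Th2 ratios. The
experimentally observed Th1-ward drift of IFN-γ⁺-sorted cultures
(secreted-cytokine feedback) is *not* modelled.

## 3. The synthetic-data generator

Each experiment sample draws, per cell,

$$v_{\text{TF}} = \big(B + F_1(\text{IL-12})\,F_2(\text{IL-4})\big)
                  \times E \times \varepsilon,$$

with B an additive background floor (autofluorescence + non-specific
staining), E a per-cell extrinsic size factor shared by all channels
(lognormal, 0.12 dex), and ε per-channel intrinsic noise (0.2193 dex;
total 0.25 dex). Cytokine channels are bimodal: off cells at a background
median (80 au), on cells at a condition-independent level (IFN-γ 2000 au,
IL-4 1500 au; 0.3 dex spread). Isotype samples sit at per-channel isotype
medians; the T-bet knockout replaces the T-bet median by the isotype
level and leaves everything else condition-driven.

Default response functions (au):

* T-bet: F₁ = 140.9·c₁₂/(c₁₂+30), F₂ = 1 − 0.25·c₄/(c₄+20), B = 100 —
  rising with IL-12, weakly repressed by IL-4;
* GATA3: F₁ = 1 + 0.3·c₁₂/(c₁₂+50), F₂ = 1506.8·c₄/(c₄+137.5), B = 100 —
  rising with IL-4, weakly *enhanced* by IL-12.

**Why these numbers.** Intensity units are arbitrary; the anchors are the
normalization convention and the printed summary statistics. Under the
log-space isotype/q95 normalization (section 4), the normalized ratio of
a channel depends only on its log-fold position between its isotype median
and its own 95th percentile. Requiring the normalized GATA3/T-bet ratio to
be 0.4 (Th1), 1 (mixed) and 20 (Th2) then fixes, given the 0.25 dex width:
the Th1 T-bet median 1.65× its isotype, the Th2 GATA3 median 12.4× its
isotype, equal log-folds for both TFs at the mixed condition
(100 ng/ml IL-12 + 4 ng/ml IL-4), and — because a ratio above 10 is
impossible if the T-bet floor sits at its isotype median — a T-bet isotype
level 0.15 dex *above* the specific-antibody floor (0.02 dex for GATA3),
interpreted as non-specific isotype binding. The response-curve constants
above are the unique saturating-Hill solution through those anchor points.
The same geometry yields the Th1 α mode at ≈87°: the α density of a
wide lognormal ratio distribution piles up against the 90° boundary even
though the median angle is lower.

Noise defaults: the 0.12 dex extrinsic share was chosen so that (i) T-bet
and GATA3 are visibly positively correlated within a condition (the
α statistic then removes that correlation, which the tests check), while
(ii) the correlation it induces between the two cytokine coins keeps the
plug-in mutual information at n = 10⁵ an order of magnitude below the
0.005-bit acceptance bound (measured ≈2×10⁻⁴ bits). SD/mean is constant
across the input grid by construction (max/min < 1.1).

**What a green test does *not* establish.** The generator emulates
unimodal lognormal TF channels, bimodal cytokines, a shared extrinsic
factor, and exact log-linear separability of the median matrix. Real
cytometry adds compensation/spillover, doublets and debris, acquisition
drift, non-lognormal tails, imperfect isotype controls and only
approximate separability — none of which are simulated. Passing tests
certify internal consistency of method + generator, not performance on
real FCS data. The mixed condition also inherits a low IL-4⁺ fraction
(≈2–4%): with one global bias curve calibrated at the Th2 endpoint, the
mixed-state GATA3 level (1.44× isotype, forced by the ratio-1 anchor)
sits far down the logistic. Real mixed cultures show richer quadrant
occupancy; all four quadrants are still populated here, which is what the
re-population and independence tests require.

## 4. Normalization and the α statistic

The Methods convention is applied in log space: with
z = log₁₀(v / isotype median) and z₉₅ the 95th percentile of z over the
experiment sample, the normalized value is w = 10^(z/z₉₅). Both anchor
invariants hold exactly (isotype median → 1, 95th percentile → 10) and
α = atan(w_Tbet/w_GATA3) reproduces the polarized behaviour (mode ≈87°
for Th1, <10° for Th2). The linear alternative — divide by isotype
median, rescale q95 → 10 — is implemented (`method = "linear"`) and is
exactly invariant to per-cell shared factors, but per-sample it is also
exactly scale-free: every condition lands at α ≈ 45°, so it cannot
separate Th1 from Th2. That is why the log convention is the default even
though a design note in the build contract suggested the linear one; the
α's extrinsic-factor suppression under the log convention is approximate
(exact when the two channels' z₉₅ scales coincide, as at the mixed
condition) and is tested there.

The α mode is estimated by a 1°-bin histogram smoothed with a 5-bin
moving average (`density_mode()`); kernel density estimates are biased at
the 90° boundary, histograms are not.

Other numerical choices: positivity thresholds default to the isotype
99th percentile; `bin_bias_curve()` drops (and flags) a trailing bin
shorter than the fixed 500-cell content; `bic_modality()` fits 1–2
component Gaussian mixtures to asinh-transformed values (cofactor 5, well
below every channel so the transform is effectively logarithmic) with 5
seeded EM restarts and BIC = −2ℓ + (3k−1)log N, ties to fewer components;
`decompose_separable()` takes the SVD of the *linear* background-subtracted
median matrix (separable ⇔ rank 1 there), normalizes F₂ to 1 at a
reference column, and reports 1 − s₁²/Σs² as residual. Near the zero-input
corner the TF signal sinks beneath the additive background and the factor
estimate is ill-conditioned; recovery tests run on strictly positive
concentration grids.

## 5. Reproducibility

Every stochastic routine takes an integer seed; per-sample seeds derive
deterministically from a master seed (`(master + 104729·i) mod (2³¹−2) + 1`),
and RNG state is saved and restored around every seeded block, so package
calls never perturb the caller's stream. `run_pipeline()` logs the package
version, an MD5 hash of the configuration and all derived seeds; identical
configurations produce byte-identical outputs. Dataset serialization is
plain TSV with a commented metadata header plus a JSON manifest; a missing
header field or column is a parse error, never a silent default.

## 6. Known limitations

* The closed-form boundary of the bistable region (the "hyperbola") is
  intentionally not implemented; all regime calls are numerical.
* No stochastic (Langevin/Gillespie) dynamics of the motif, no kinetic
  model of restimulation, no secreted-cytokine feedback by default.
* Cytokine *amounts* are binary states plus a fixed on-distribution; only
  positive fractions carry input information.
* The t7 statistic (top-bin IL-4⁺ fraction) has an irreducible ≈2-point
  sampling sd at the stated 500-cell bin and n = 20,000.
* FCS ingestion is out of scope; all I/O is plain text.
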