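---
title: "Discriminating induced fit from conformational selection with relaxation kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating induced fit from conformational selection with relaxation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxkin)
```

## The question and the two competing schemes

A receptor that exists in an inactive conformation R1 and an active
conformation R2 can shift its population toward R2 on agonist binding along
two kinetic pathways:

* **induced fit (IF)** — the ligand binds R1 first and the conformational
  change follows: R1 + L ⇌ R1L ⇌ R2L. The binding step has association and
  dissociation rate constants `k_plus` (/M/s) and `k_minus` (/s); the bound
  intermediate R1L relaxes to the final complex R2L with rate constant
  `k_r` and is re-excited with `k_e`.
* **conformational selection (CS)** — the conformational change precedes
  binding: R1 ⇌ R2 (excitation `k_e`, relaxation `k_r`), and only R2 binds:
  R2 + L ⇌ R2L.

Both schemes relax into binding equilibrium double-exponentially, with
characteristic rates `k1 >= k2` whose dependence on the total ligand
concentration `L0` differs between the schemes. That concentration
dependence, measured by stopped-flow fluorescence at a series of ligand
concentrations, is what discriminates the pathways. An independent check
comes from ¹⁹F saturation-transfer NMR on the bound complex, which measures
the conformational exchange rates between the two bound states directly.

## Closed-form relaxation rates

Linearising the mass-action rate equations around the equilibrium
concentrations gives, for any total receptor concentration `P0` and ligand
concentration `L0` (not only in ligand excess), the two relaxation rates.
With the binding-quadratic discriminant

$$\delta = \sqrt{(L_0 - P_0 + K_D)^2 + 4 P_0 K_D}$$

and the overall dissociation constants

$$K_D^{IF} = \frac{k_- k_e}{k_+ (k_e + k_r)}, \qquad
  K_D^{CS} = \frac{k_- (k_e + k_r)}{k_+ k_e},$$

the induced-fit rates are

$$k_{1,2} = k_e + k_r + \frac{\gamma}{2} \pm
  \frac{\sqrt{\gamma^2 + 4 k_- k_r}}{2}, \qquad
  \gamma = -k_e - k_r + k_- + k_+ (\delta - K_D),$$

and the conformational-selection rates are

$$k_{1,2} = k_e + \frac{\alpha}{2} \pm \frac{\sqrt{\alpha^2 + \beta}}{2}$$

with

$$\alpha = k_r - k_e + \frac{k_- \left((2 k_e + k_r)\,\delta +
  k_r (L_0 - P_0 - K_D)\right)}{2 k_e K_D}, \qquad
  \beta = 2 k_r \left(2 k_e - k_- -
  \frac{k_- (\delta - L_0 + P_0)}{K_D}\right).$$

Both reduce to the familiar pseudo-first-order expressions when
`L0 >> P0`; in particular the slow rate tends to `k_e + k_r` (IF) or `k_e`
(CS) at large ligand excess.

**A note on the induced-fit discriminant.** Several published statements
of the induced-fit rates carry `4 k_- k_e` under the square root. That
form is not consistent with the scheme itself: writing the linearised
2×2 Jacobian of the IF rate equations (with the convention
R1L → R2L at rate `k_r`, R2L → R1L at rate `k_e`, which is the convention
the overall `K_D^{IF}` above presumes), its trace is
`k_e + k_r + k_- + k_+(δ − K_D)` — matching the sum `k1 + k2` — but its
determinant forces the discriminant `γ² + 4 k_- k_r`. The package uses
the consistent form; it is validated to 1e-8 relative error against an
independent numerical eigenvalue computation (`eigenrate_oracle()`),
which locates the equilibrium, eliminates the two conservation laws
analytically, and differentiates the mass-action right-hand side by
central differences (exact for mass action up to round-off, since the
rate equations are quadratic in the concentrations). The
conformational-selection expressions agree with the same oracle
unmodified.

## Numerical choices

* **Units.** All function arguments are SI (molar, seconds). File formats
  carry concentrations in µM, converted at the I/O boundary. The symbols
  `[R]0` and `[P]0` seen for total receptor concentration in different
  sources are the same quantity; the package uses one argument `P0`.
* **Cancellation.** The smaller eigenvalue is computed as a quotient
  (`c / (|γ| + √(γ²+c))`) whenever the auxiliary rate is large, and the
  equilibrium free-ligand concentration uses the stable root of the
  binding quadratic, so no precision is lost at `L0 ≈ P0 >> K_D` or
  `P0 >> L0`.
* **Degenerate corners.** `k1 = k2` only in zero-rate corners; the
  accessors always return `k1 >= k2`. A negative CS radicand (impossible
  for physical parameters) raises a domain error carrying the
  intermediates α, β, δ for inspection.

## What the simulator emulates — and what it does not

`simulate_trace()` integrates the full nonlinear mass-action equations
(deSolve, relative tolerance 1e-9) from the post-mixing state: unbound
receptor at its apo conformational equilibrium (all R1 for IF; R1:R2 =
k_r:k_e for CS, imposed exactly at t = 0 rather than simulated through
mixing), free ligand `L0`, no complex. The fluorescence signal is
`background + Σ coefficient × concentration` with per-species coefficients;
bound species are 30% brighter than unbound by default (signal increases on
binding, as for intrinsic Trp fluorescence), and the ligand is dark. Noise
is additive, Gaussian, time-independent, and seeded; its default standard
deviation is 0.5% of the noiseless dynamic range of the trace. Sampling
starts at a 1.5 ms dead time (a typical value for the instrument class;
not a measured one) with 2000 points per trace by default.

The default `default_design()` reproduces the replicate/concentration
table of the study this package models: 55 traces over ten ligand
concentrations from 0.5 to 15 µM (after 1:1 mixing against 1 µM receptor),
with 20-s traces below 5 µM and 5-s traces at and above it.

Not emulated: instrument response convolution, photobleaching,
photon-shot (signal-dependent) noise, inner-filter effects, and partial
saturation efficiency in the saturation-transfer experiment. Passing tests
on this generator therefore demonstrates correctness of the analysis
chain under idealised noise, not robustness to every instrumental
artifact of real data.

**Transient bias.** The double-exponential form describes the *final*
relaxation into equilibrium. A stopped-flow mixing experiment starts far
from equilibrium, and when the ligand is not in large excess the early
part of the trace is visibly non-exponential. Full-trace fits at
`L0` within a few-fold of `P0` therefore carry a systematic upward bias
of the fitted fast rate (tens of percent at `L0 ≈ 2 P0` in noiseless
simulations), while the slow rate is much less affected. The package's
round-trip validation consequently uses ligand excess (`L0/P0 = 40`) and
fits from one fast relaxation time onward (`fit_start = 1/k1`), where
both rates are recovered within 2%. This bias is a property of the
experiment design, not of the fitting code, and it affects any analysis
that fits rate expressions for the asymptotic relaxation to full mixing
traces.

## Trace fitting and model selection

Single- and double-exponential models
`baseline + Σ amplitude_i exp(-rate_i t)` are fitted by a seeded
differential-evolution search (rand/1/bin, population 40, 150
generations) over rates in [1e-3, 1e3] /s and baseline/amplitudes within
±3 signal ranges, followed by Levenberg–Marquardt polishing; an
exponential-peeling estimate (tail log-linear regression, then the peeled
early residual) is injected into the starting population and also
polished directly. Fits are deterministic given the seed and invariant to
affine rescaling of the signal.

AIC uses the least-squares convention `n ln(RSS/n) + 2 (p + 1)` with the
residual variance counted as a parameter. Because any such convention
contains an arbitrary additive constant, only within-dataset orderings
and differences of AIC are meaningful; absolute AIC values from other
software are not comparable. Exact ties resolve to the single
exponential (parsimony).

Replicate aggregation follows the study's error rules: the reported rates
are means of per-trace fits in the 10-s window; the fast-rate 95% interval
is 1.96 × the standard error over traces; the slow-rate interval is 1.96 ×
the standard deviation of the per-window averages over the 5, 10 and 20-s
windows, because window choice dominates replicate scatter for the slow
rate. At and above a configurable threshold (default 5 µM) traces are
fitted single-exponentially in a 0.5-s window and only the fast rate is
reported — the operational high-concentration rule, expressed as a
concentration threshold rather than a post-hoc reliability test.

## Mechanism inference

`fit_mechanism()` minimises the error-weighted sum of squares
χ² = Σ (k_obs − k_model)²/σ² over the concentration series, with
σ = ci95/1.96 and slow-rate terms only where present (by default the
high-concentration rows carry none). The association rate constant is
**never** a free parameter: at every evaluation it is eliminated through
the fixed, externally measured overall `K_D` (6 nM in the study
configuration), leaving `k_e`, `k_r`, `k_minus` free. The constrained
conformational-selection variant reparameterises `k_r = c·k_e` with
`c >= 9`, confining the unbound active-state probability
`k_e/(k_e+k_r)` below 10%; the bound `c = 9` is reachable, and on data of
induced-fit character the constrained optimum typically sits on it.

Optimisation is a seeded multi-start: 32 log-uniform draws over
[1e-4, 1e2] /s are screened by objective value and the best quarter are
refined with box-constrained quasi-Newton iterations in log-parameter
space; ties resolve to the lower `k_e`. Standard errors come from the
curvature of χ² at the optimum (covariance = 2 H⁻¹, Gaussian likelihood
with known per-point σ), and AIC = χ² + 2p with p = 3.

`compare_mechanisms()` runs induced fit, unconstrained conformational
selection, and constrained conformational selection, and issues a
verdict: induced fit when its AIC beats the constrained CS fit *and* the
unconstrained CS fit needs an implausibly large unbound active-state
probability (> 10%); conformational selection when the constrained CS
fit beats induced fit; otherwise inconclusive. An unconverged branch
forces "inconclusive". Datasets whose slow rate is absent everywhere are
fitted on the fast rate alone but flagged under-determined.

At the study's design and a 5% replicate rate scatter, 100/100 synthetic
induced-fit datasets return the induced-fit verdict and the median
recovery error of `k_r` and `k_minus` is a few percent (the tests and
the acceptance script recompute these). The 5% scatter is the package's
characterisation of replicate-to-replicate fit variation at the default
0.5%-of-range trace noise; real data add model error (transient bias,
drifts), which is why published parameter uncertainties are much wider
than this synthetic-world recovery error.

## Saturation-transfer analysis

For a monitored spin S exchanging with a saturated partner I, the
on-resonance intensity decays as

$$I_S(t) = I_S(0)\left(\frac{k_{SI}}{k_{SI}+R_S}\,e^{-t (R_S+k_{SI})}
  + \frac{R_S}{k_{SI}+R_S}\right),$$

where `k_SI` is the exchange rate constant S → I and `R_S` the
longitudinal relaxation rate of S. Saturation is treated as instantaneous
and complete. Off-resonance effects are corrected before fitting; the
published description of the correction is ambiguous about operation
order, so the package fixes one dialect —
`corrected = reference·(on/reference − off/reference + 1)`, i.e.
`on − off + reference` — records it in every output, and offers a raw
mode that fits the on-resonance channel directly. The dialect leaves
artifact-free data unchanged and removes a common additive droop exactly.

The three parameters (`k_SI`, `R_S`, `I0`) are fitted by bounded
Levenberg–Marquardt from a heuristic start plus six seeded jittered
starts, with `k_SI` in [0, 100] /s and `R_S` in (0, 100] /s. Two
identifiability limits are worth knowing. First, with saturation times up
to 1 s the decay is resolved only when `k_SI + R_S` is at least ≈ 2.5 /s;
slower pairs leave `R_S` poorly determined. Second, near `k_SI = R_S` the
two rates trade off against each other and recovery of `R_S` degrades
even at low noise. The recovery validation therefore samples rate pairs
within a factor of 10 of each other with total decay rate ≥ 2.5 /s, at
noise equal to 1% of the curve's dynamic range (`I0·k_SI/(k_SI+R_S)`) —
the same relative-to-dynamic-range convention the trace generator uses.

Running both directions of the experiment (monitoring S1 while
saturating S2 and vice versa) gives the exchange pair (k12, k21), whose
detailed-balance populations `p1 = k21/(k12+k21)` complement the
lineshape populations. The pipeline tabulates k12 and k21 against the
induced-fit estimates of `k_r` and `k_e` — the cross-experiment
consistency argument — as ratios, without asserting a numeric bound:
when the bound states of the kinetic scheme correspond to the two NMR
states, k12 ≈ k_r and k21 ≈ k_e. Note that for one of the complexes the
published exchange rates imply detailed-balance populations opposite in
order to the published spectral populations; the package reports both
numbers side by side and leaves the state assignment to the user.

## Design choices that were genuinely open

* **Weights.** "Error-weighted" is implemented as σ = ci95/1.96 per
  point, matching error bars drawn as 1.96 × standard error.
* **Slow-rate rows at high concentration.** The joint fit excludes slow
  rates at and above the 5 µM threshold, since the trace analysis does
  not report them there.
* **Uncertainty type.** Reported parameter uncertainties are curvature
  standard errors; published ± values of unstated type are treated as
  comparable in magnitude only.
* **Verdict rule.** The AIC comparison uses the *constrained* CS fit —
  comparing against a mimic that needs an implausible unbound ensemble
  would not test the science — and the implausibility of the
  unconstrained fit is itself part of the induced-fit verdict.
* **Problem sizes.** The validation suite runs 1000 random parameter sets
  per scheme for the oracle check, 100 datasets per truth for the
  discrimination study, and 100 seeds per rate pair for the
  saturation-transfer recovery; trace-level round trips use four
  parameter sets at ligand excess. These sizes give stable medians and
  rates while keeping a full run in minutes.

## Known limitations

* The closed forms describe three-state schemes only; ternary complexes
  (e.g. with G protein), four-state mixed IF/CS schemes, and more than
  two conformations are out of scope.
* Full-trace exponential fits at strong ligand depletion carry the
  transient bias described above.
* The mechanism fit inherits the quality of the input uncertainties; rows
  with zero or missing intervals are rejected rather than guessed.
* Absolute AIC values are convention-bound and never reproduced; only
  orderings and differences are.
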