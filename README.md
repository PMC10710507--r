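# relaxkin

Kinetic discrimination of induced-fit and conformational-selection ligand
binding from stopped-flow relaxation rates and ¹⁹F saturation-transfer NMR.

## The problem

A receptor with an inactive conformation R1 and an active conformation R2
can shift its ensemble toward R2 on agonist binding along two pathways:

* **induced fit (IF)**: R1 + L ⇌ R1L ⇌ R2L — binding first, conformational
  change after;
* **conformational selection (CS)**: R1 ⇌ R2, R2 + L ⇌ R2L — conformational
  change first.

Both produce a double-exponential relaxation into binding equilibrium with
rates k1 ≥ k2 whose dependence on the total ligand concentration [L]₀
differs between the pathways. `relaxkin` implements, for both schemes, the
closed-form near-equilibrium relaxation rates valid at *all* receptor and
ligand concentrations,

k₁,₂(IF) = k_e + k_r + γ/2 ± √(γ² + 4 k₋k_r)/2,  γ = −k_e − k_r + k₋ + k₊(δ − K_D),

k₁,₂(CS) = k_e + α/2 ± √(α² + β)/2,

with δ = √(([L]₀ − [P]₀ + K_D)² + 4[P]₀K_D) and the overall dissociation
constants K_D(IF) = k₋k_e/(k₊(k_e+k_r)), K_D(CS) = k₋(k_e+k_r)/(k₊k_e). It
fits these jointly to a (k1, k2) concentration series by error-weighted
least squares with k₊ eliminated through an externally measured K_D, and
discriminates the mechanisms by AIC together with a plausibility bound on
the unbound active-state population (CS constrained to k_r ≥ 9 k_e). A
mass-action simulator, an independent eigenvalue oracle, seeded
differential-evolution exponential trace fitting, and Bloch-McConnell
saturation-transfer fitting (I_S(t) = I_S(0)(k_SI/(k_SI+R_S)·e^(−t(R_S+k_SI))
+ R_S/(k_SI+R_S))) complete the chain. The target audience is biophysicists
analysing receptor-ligand binding kinetics, in particular GPCR
ligand-recognition studies.

The `analysis/` directory holds the numbered workflow: simulate the
55-trace stopped-flow study, fit and aggregate the traces, infer the
mechanism, fit the saturation-transfer curves, and run the Monte-Carlo
discrimination-power study. Each script writes its tables under
`results/`.

## Worked example

```r
library(relaxkin)

# Induced-fit truth at the study operating point: K_D fixed at 6 nM
truth <- mechanism_params("IF", k_plus_from_kd(6e-9, 0.6, 0.01, 1.1, "IF"),
                          k_minus = 0.6, k_e = 0.01, k_r = 1.1)
relaxation_rates(truth, L0 = 1e-6, P0 = 1e-6)[c("k1", "k2")]
#> $k1
#> [1] 1.755976
#> $k2
#> [1] 0.0882902

# A replicate-design rate dataset (ten concentrations, 55 traces' worth)
ds <- simulate_rate_dataset(truth, default_design(), rate_noise = 0.05,
                            seed = 11)
cmp <- compare_mechanisms(ds, K_D = 6e-9, P0 = 1e-6, seed = 11)
cmp
#> <mechanism comparison> verdict: IF
#>   IF               AIC   18.182  chi2   12.182
#>   CS_unconstrained AIC   93.246  chi2   87.246
#>   CS_constrained   AIC 19782.354  chi2 19776.354
#>   unbound active-state probability (CS unconstrained): 0.647 (threshold 0.10)
cmp$fits$IF
#> <IF fit>
#>   k_e = 0.009867 +/- 0.00015 /s, k_r = 1.087 +/- 0.013 /s, k_minus = 0.5987 +/- 0.0082 /s
#>   K_D fixed at 6e-09 M (k_plus implied 8.977e+05 /M/s); chi2 = 12.18, AIC = 18.18
```

The verdict reads: the induced-fit model fits the rate series with
plausible conformational rate constants close to the generating truth,
while conformational selection either needs an implausibly active unbound
ensemble (65% R2, unconstrained) or, when constrained below 10%, fails to
fit the data (AIC 19782 vs 18).

Saturation-transfer side:

```r
cv <- simulate_std_curve(k_SI = 1.23, R_S = 2, I0 = 1,
                         noise_sigma = 0.0005, seed = 124)
fit_std(build_std_curve(cv))
#> <saturation-transfer fit> k_SI = 1.231 /s, R_S = 2.011 /s, I0 = 0.9996 (rss 1.8e-06)
```

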