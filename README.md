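# relkin — mechanism-decomposed drug-release kinetics

`relkin` fits cumulative drug-release profiles with a composite model that
attributes the release to three physical mechanisms, each with its own
kinetic constant and a simplex-constrained weight:

```
Mt/M∞(t) = μ1·F1(t) + μ2·F2(t) + μ3·F3(t),   Σμi = 1,  0 ≤ μi ≤ 1

F1(t) = 1 − exp(−k_b·t)                                  (burst release)
F2(t) = 1 − (8/π²) Σ_{n≥0} exp(−(2n+1)²π²·D_e·t/h²)/(2n+1)²   (Fickian
                                                 plane-sheet diffusion)
F3(t) = k_os·t,  k_os = γ·Δπ                             (osmotic pumping)
```

The weights μ report *how much* of the release each mechanism carries
(printed as percentages), while `k_b` (h⁻¹), `D_e` (m²/h) and the osmotic
pressure gradient `Δπ` (atm, through the conversion factor γ) report *how
fast* each mechanism runs. The package is aimed at drug-delivery scientists
characterising release from thin polymer films — the built-in reference
parameter sets describe diclofenac release from 2 mm polyurethane films at
several drug loads and flow rates — but the model and fitting machinery are
generic.

The constrained least-squares fit is solved by a sequential quadratic
programming (SQP) engine written for this package: active-set quadratic
subproblems, damped BFGS Hessian updates, an ℓ1 exact-penalty line search
and KKT-based convergence, run from a deterministic multistart grid.
Auxiliary modules cover porous-membrane hydraulics (Poiseuille pressure
drop, hydraulic permeability `Lp`, reflection coefficient σ), correlation
models linking the kinetic constants to drug load (Arrhenius-type,
`ln k = a + b/C`) and flow rate (linear, `k = a + b·Q`) for predicting
unseen conditions, a synthetic-profile generator, CSV/JSON I/O and a
command-line interface.

## Worked example

Generate a noisy synthetic profile from a built-in condition (20 % drug
load, 7.5 mL/s flow), refit it, and read off the mechanism decomposition:

```r
library(relkin)

prof <- generate_profile("PU-20DE-Q7.5", noise_sd = 0.02, seed = 1)
fit  <- fit_release(prof)
fit
#> Composite release fit 'PU-20DE-Q7.5' (converged, 14 starts)
#>   Burst      32.1 %   k_b  = 2.246 1/h
#>   Diffusion  62.1 %   D_e  = 1.339e-08 m^2/h
#>   Osmosis     5.9 %   k_os = 0.01123 1/h  (delta_pi = 0.0101 atm at gamma = 1.111)
#>   RMSE = 0.01768, R^2 = 0.9894
```

The burst/diffusion/osmosis rows are the fitted contribution percentages
(100·μ̂, summing to 100); the recovered constants sit within the noise of
the generating values (k_b = 2.5 h⁻¹, D_e = 1.62e-8 m²/h, Δπ = 0.009 atm).
RMSE and R² are computed against the observations being fitted.

Predicting a reserved condition (15 % load) from correlations fitted at
10/20/30 %:

```r
tab  <- builtin_conditions()
conc <- tab[tab$flow == 7.5, ]
models <- list(
  k_b  = fit_concentration_correlation(conc$drug_load, conc$k_b,  "k_b"),
  D_e  = fit_concentration_correlation(conc$drug_load, conc$D_e,  "D_e"),
  k_os = fit_concentration_correlation(conc$drug_load, conc$k_os, "k_os"))
w <- data.frame(x = conc$drug_load, mu_burst = conc$mu_burst,
                mu_diffusion = conc$mu_diffusion, mu_osmosis = conc$mu_osmosis)
pred <- predict_release_profile(models, w, x = 15, times = seq(0, 100, 10))
attr(pred, "params")
#> Composite release parameters
#>   weights: burst 0.2725, diffusion 0.6080, osmosis 0.1195
#>   k_b  = 2.18793 1/h
#>   D_e  = 1.44765e-08 m^2/h
#>   k_os = 0.0087825 1/h
```

A thin command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(relkin::relkin_cli_path())')
Rscript $CLI simulate --condition PU-20DE-Q7.5 --noise-sd 0.02 --seed 1 -o prof.csv
Rscript $CLI fit prof.csv -o report.json
Rscript $CLI physics sigma --phi 0.5     # prints 0.5625
```

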