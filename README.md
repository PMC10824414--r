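# hscdiv

Age-dependent division-mode kinetics of hematopoietic stem cells.

Hematopoietic stem cells (HSCs) maintain blood production through three modes
of division: symmetric self-renewal (S-S, two stem daughters), asymmetric
division (S-P, one stem and one progenitor daughter), and symmetric
differentiation (P-P, two progenitor daughters). The HSC pool in mice grows
steadily with age, but which division modes drive that growth cannot be read
off cell counts directly. `hscdiv` implements a quantitative pipeline that
infers the age-dependent balance of the three modes from two complementary
experiments:

* **Ex vivo**: single HSCs (CD34-CD150+KSL) are expanded clonally in
  PVA-based medium; after 14 days the fraction *x* of functional HSCs
  (CD201+CD150+KSL) among expanded cells in each well reflects the seeded
  cell's first division mode.
* **In vivo**: numbers of HSCs and of KSL cells per bone are censused across
  ages 6–72 weeks.

It is aimed at stem-cell biologists and modellers who want to re-analyse such
designs, or to probe the design itself with the built-in synthetic-data
generator.

## Model

The per-well proportion at age *t* is modelled as Beta(α(t), β(t)), with each
shape parameter following a biexponential decay in age,

    α(t) = b₁ᵅ e^(−a₁ᵅ (t−t₀)) + b₂ᵅ e^(−a₂ᵅ (t−t₀)),   t₀ = 4 weeks,

(and the same form for β). Per-age shapes (α_t, β_t) are estimated by maximum
likelihood (wells at exactly 0 or 1 are clamped to 0.001/0.999), then the
trajectories are fitted by nonlinear least squares. Two thresholds c₁ < c₂ on
a 0.1 grid convert the distribution into division-mode fractions through the
discretized beta CDF P_c (the sum of 0.1-bin masses, identically the
regularized incomplete beta function I_c):

    p(t)  = 1 − P_{c₂}(α(t), β(t))        (S-S)
    q(t)  = P_{c₂} − P_{c₁}               (S-P)
    1 − p − q = P_{c₁}                    (P-P)

These fractions drive a two-compartment ODE for stem (S) and progenitor (P)
cell numbers,

    dS/dt = r p(t) S − r (1 − p − q) S
    dP/dt = r q(t) S + 2 r (1 − p − q) S − d P,

with division rate *r*, fixed progenitor removal rate *d* (0.1 per week,
sensitivity 0.05/0.2), and KSL counts modelled as S + P. The census is fitted
on decadic-log counts: (r, S₀, P₀) by multi-start nonlinear least squares at
each of the 36 threshold pairs, the pair with the smallest sum of squared
residuals (SSR) selected, and posteriors for (r, S₀, P₀) sampled by adaptive
Metropolis MCMC.

## Worked example

Fit the model to a synthetic study generated under the default design
(11 ex vivo ages with 30 mice and 60 wells each; census at 7 ages × 3 mice;
true thresholds 0.3/0.8, true r = 0.172/week):

```r
library(hscdiv)

spec   <- paper_like_spec()           # seed = 1
wells  <- generate_wells(spec)
census <- generate_census(spec)
cfg    <- fit_config(mcmc = list(n_steps = 2000L, n_burn = 500L, n_chains = 2L))
fit    <- hsc_fit(wells, census, cfg)
summary(fit)
#> Estimated parameters of the HSC division-mode model
#>  parameter  estimate post_mean ci_lower  ci_upper
#>         c1 3.000e-01        NA       NA        NA
#>         c2 8.000e-01        NA       NA        NA
#>          r 1.372e-01 1.376e-01     0.13 1.457e-01
#>          d 1.000e-01        NA       NA        NA
#>         S0 5.488e+03 5.479e+03  5152.13 5.817e+03
#>         P0 1.043e+05 1.044e+05 97561.17 1.110e+05
#> SSR = 0.04284 (log10 scale), max split R-hat = 1.006
#>
#> Division-mode fractions (S-S, S-P, P-P):
#>    10.0 wk:  53.1%   23.7%   23.2%
#>    70.0 wk:  37.7%   12.7%   49.5%
```

The generating thresholds (0.3, 0.8) are recovered; the division rate is
estimated at 0.137/week against a truth of 0.172 (the thresholds and rate are
partially confounded — see the vignette); and the fitted fractions show
symmetric self-renewal dominant in young animals (53% at 10 weeks) giving way
to symmetric differentiation with age (49% P-P at 70 weeks). `plot(fit)`
draws the census fit and the fraction time courses; `predict()`,
`residuals()`, `simulate()` and `coef()` behave as for other fitted-model
classes, and `run_pipeline()` runs the same analysis file-to-file, writing
`shapes.csv`, `trajectory.json`, `ssr_grid.csv`, `fit_summary.csv`,
`posterior.csv` and `fractions.csv`.

## Documentation

`vignettes/division-modes.Rmd` describes the model, its assumptions, every
tunable parameter, the synthetic-data generator, and known limitations —
in particular the flatness of the threshold-selection SSR landscape under
realistic noise.
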