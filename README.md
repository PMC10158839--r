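# medtriplet

Measurement-error-aware mediation analysis for genetic triplets.

In genetic mapping studies, mediation analysis of a *triplet* — the genotype
`X` at a QTL, a candidate mediator `M` (transcript or protein abundance from
a co-locating gene), and a target trait `Y` — asks which causal structure
relates the three variables: **Causal** (`X→M→Y`, complete mediation),
**Independent** (`X→M`, `X→Y`), **Reactive** (`X→Y→M`), or **Complex** (all
edges, partial mediation). Measurement error does not propagate through the
causal graph, and standard likelihood-based selection ignores it; this
package models the consequences and provides diagnostics.

The generative model is parameterized by correlations. Causal correlations
ρ<sub>X\*M\*</sub>, ρ<sub>X\*Y\*</sub>, ρ<sub>Y\*M\*</sub> relate the
error-free variables; error correlations ρ<sub>X\*X</sub>, ρ<sub>M\*M</sub>,
ρ<sub>Y\*Y</sub> tie each variable to its measurement. The observable *data
correlations* compose as products:

    ρ_XY = ρ_X*X · ρ_X*Y* · ρ_Y*Y    (and cyclically for XM, YM)

Each constrained structure forces the correlation of its two non-middle
variables to equal the product of the other two — a constraint the *data*
correlations inherit **iff the middle variable is error-free**. Every
configuration is likelihood-equivalent to an error-free Complex
configuration, so with three variables the causal and error correlations are
not separately identifiable. What *is* estimable is the single-latent-factor
reparameterization ρ<sub>XU</sub>, ρ<sub>MU</sub>, ρ<sub>YU</sub> with
ρ<sub>XY</sub> = ρ<sub>XU</sub>·ρ<sub>YU</sub> etc., recovered in closed
form by tetrad ratios; the *strongest* latent correlation determines which
structure large-sample three-choice selection converges to.

Main entry points:

| function | purpose |
|---|---|
| `me_config()`, `implied_data_cor()`, `complex_equivalent()` | measurement-error model |
| `latent_from_config()`, `estimate_latent()`, `diagnose_consistency()` | latent-factor reparameterization |
| `triplet_bms()`, `weakest_correlation_rule()` | Bayesian model selection (S3 fit with `print`/`summary`/`plot`) |
| `sim_design()`, `simulate_triplet()`, `run_classification_study()` | simulation engine and rate studies |
| `bootstrap_correlations()`, `config_library()`, `filter_configs()`, `hdi()` | case-study diagnostics |

A thin command-line wrapper with `classify`, `simulate-study`, and
`diagnose` subcommands is installed at `inst/scripts/medtriplet-cli.R`.

## Worked example

A Causal configuration with moderate measurement error in the mediator:

```r
library(medtriplet)
cfg <- me_config("Causal", rho_xm = 0.9, rho_ym = 0.8,
                 err_x = 0.9, err_m = 0.8, err_y = 0.9)
implied_data_cor(cfg)
#> <corr_triple role=data> rho_xy=0.5832 rho_xm=0.648 rho_ym=0.576
latent_from_config(cfg)
#> <latent_triple> rho_xu=0.81 rho_mu=0.8 rho_yu=0.72
```

The data correlations are attenuated products of the causal and error
correlations, and the latent correlation of `X` (0.81) now exceeds that of
the mediator (0.8). That ordering decides the fate of model selection:

```r
dat <- simulate_triplet(cfg, n = 5000, seed = 1)
triplet_bms(dat, options = "three_choice")
#> Bayesian mediation model selection (three_choice options, N=5000)
#> Selected: Independent (model a+c, posterior 1.000)
#>
#>               label log_marginal posterior
#> a+b          Causal    -11763.22         0
#> a+c     Independent    -11748.55         1
#> c+b_rev    Reactive    -12057.46         0

diagnose_consistency(estimate_latent(estimate_data_cors(dat)), "Causal")
#> <latent_diagnosis> assumed=Causal strongest=rho_xu selected=Independent verdict=inconsistent
```

Even at N = 5,000 the generating Causal structure loses decisively to
Independent — exactly what the latent diagnosis predicts from the estimated
correlations alone. With the expanded option set the same dataset is called
Complex (posterior 1.000): any error in the middle variable makes measured
data look like partial mediation. Classification rates over the whole
Beta(5, 1.25) parameter regime:

```r
tab <- run_classification_study(
  sim_design(n_configs = 2000, sample_size = 200, seed = 7), "three_choice")
tab
#> Classification rates (%), three_choice options, N=200, 2000 configs/structure
#>             Causal Independent Reactive
#> Causal       61.15        18.7    22.25
#> Independent  19.80        64.3    20.30
#> Reactive     19.05        17.0    57.45
```

Roughly 62% of datasets are classified correctly at N = 200, and the
off-diagonal rates show the characteristic confusion pattern induced by
measurement error.

See `vignettes/measurement-error-mediation.Rmd` for the model, estimators,
priors, simulation design, and bootstrap diagnostics in full.

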