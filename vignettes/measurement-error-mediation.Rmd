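---
title: "Measurement error and mediation analysis of QTL triplets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement error and mediation analysis of QTL triplets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medtriplet)
```

## The problem

Genetic mediation analysis asks whether the effect of a QTL genotype $X$ on a
target trait $Y$ is transmitted through a candidate mediator $M$, typically
the abundance of a transcript or protein whose coding gene co-locates with
the QTL. Four causal structures are of interest for the triplet $(X, M, Y)$:

* **Causal** (complete mediation): $X \to M \to Y$, no direct $X \to Y$ edge;
* **Independent**: $X \to M$ and $X \to Y$, no $M \to Y$ edge;
* **Reactive**: $X \to Y \to M$, the mediator responds to the target;
* **Complex** (partial mediation): all three edges present.

Molecular measurements carry error, and error does not propagate through the
causal graph the way causal variation does. `medtriplet` models this
explicitly and quantifies how it distorts likelihood-based model selection.

## The measurement-error model

Each measured variable is a noisy surrogate of an error-free *causal
variable* ($X^*, M^*, Y^*$). The model is parameterized entirely by
correlations:

* *causal correlations* $\rho_{X^*M^*}, \rho_{X^*Y^*}, \rho_{Y^*M^*}$ among
  the causal variables;
* *error correlations* $\rho_{X^*X}, \rho_{M^*M}, \rho_{Y^*Y}$ between each
  causal variable and its measurement (inversely related to the usual error
  variances; 1 means error-free).

The population correlations among the measured variables (*data
correlations*) compose as products, e.g.
$\rho_{XY} = \rho_{X^*X}\,\rho_{X^*Y^*}\,\rho_{Y^*Y}$, so they are never
stronger than their causal counterparts
(`implied_data_cor()`). Each constrained structure forces the correlation of
its two non-middle variables to equal the product of the other two — the
*middle variable* being $M$, $X$, $Y$ for Causal, Independent, Reactive
respectively — equivalently, a zero partial correlation given the middle
variable (`structure_constraint()`).

Two consequences drive everything else:

1. The data correlations satisfy the structure's constraint **iff the middle
   variable is measured without error**. Any error in the middle variable
   makes the measured data look like partial mediation.
2. Every configuration is likelihood-equivalent to a Complex configuration
   with no measurement error (`complex_equivalent()`), so causal and error
   correlations are not separately identifiable from a single triplet.

```{r}
cfg <- me_config("Causal", rho_xm = 0.9, rho_ym = 0.8,
                 err_x = 0.9, err_m = 0.8, err_y = 0.9)
implied_data_cor(cfg)
structure_constraint(implied_data_cor(cfg), "Causal")$residual
```

## The latent single-factor model

Each constrained structure (five free parameters, three observables)
collapses to a three-parameter model in which one latent factor $U$ drives
all three measurements: $\rho_{XY} = \rho_{XU}\rho_{YU}$ and cyclically. The
middle variable's latent correlation equals its error correlation; the
others are products of an error and a causal correlation
(`latent_from_config()`). Unlike the causal and error correlations, the
latent correlations *are* estimable, by the tetrad formulas
$|\hat\rho_{XU}| = \sqrt{|r_{XY} r_{XM} / r_{YM}|}$ etc.
(`estimate_latent()`).

Their relative sizes determine the asymptotic outcome of three-choice model
selection: the structure whose middle variable has the strongest latent
correlation wins (`diagnose_consistency()`). This is the practical
diagnostic we recommend: transform estimated data correlations to latent
correlations and ask, for each assumed structure in turn, whether the
implied split into causal and error components is plausible for the
measurement technologies at hand.

```{r}
lat <- latent_from_config(cfg)
lat
diagnose_consistency(lat, assumed = "Causal")
```

Here moderate error in the mediator ($\rho_{M^*M} = 0.8$) makes
$\rho_{XU}$ the strongest latent correlation, so large-sample three-choice
selection converges on the *wrong* (Independent) structure even though the
generating structure is Causal.

### Numerical choices

* `estimate_latent()` requires all three input magnitudes $\ge$ `min_abs`
  (default `1e-6`); below that the tetrad ratios are numerically
  meaningless. The triple product must be positive for a one-factor model
  to be sign-consistent.
* The latent factor's orientation is arbitrary; we fix $\rho_{MU} \ge 0$ so
  output is deterministic, and transfer the signs of $r_{XM}$, $r_{YM}$ to
  $X$ and $Y$.
* Finite-sample estimates can exceed 1 (Heywood cases); they are clipped to
  1 and flagged rather than rejected so that resampling pipelines keep
  running.
* PSD checks accept the smallest eigenvalue down to `-1e-10`; the exact
  structure-constraint tolerance defaults to `1e-8` and should be loosened
  for estimated triples.
* Ties in `diagnose_consistency()` use a margin of 0 (strict argmax) by
  default; a positive margin is available for sensitivity analyses.

## Bayesian model selection

`triplet_bms()` scores mediation DAGs by a closed-form conjugate marginal
likelihood, factorized node-wise as $p(M \mid \mathrm{pa}(M))\,
p(Y \mid \mathrm{pa}(Y))$. Each factor is a Gaussian linear model with a
flat prior on the intercept and covariates, effect prior
$\beta \sim N(0, \phi^2\sigma^2)$ per standardized predictor, and
$\sigma^2 \sim \mathrm{IG}(\kappa/2, \lambda/2)$. Defaults are $\phi^2 = 1$
and $\kappa = \lambda = 0.001$ (`bms_priors()`); $\phi^2$ is the main knob
governing how strongly the expanded option set penalizes extra edges.
Responses and predictors are standardized first, which makes selection
invariant to measurement scale; covariates are absorbed identically across
models, so Bayes factors compare edge structure only. A multistate genotype
enters as its centered dosage block under the same ridge prior, which also
absorbs the block's one-dimensional redundancy with the intercept.

Two option sets are offered:

* **three-choice**: Causal, Independent, Reactive only. For univariate
  triplets this provably reduces to the *weakest-correlation rule*
  (`weakest_correlation_rule()`): select the structure with no direct edge
  between the pair whose estimated correlation is weakest in magnitude.
* **expanded**: all acyclic edge subsets over $\{a\!:X{\to}M,\;
  b\!:M{\to}Y,\; c\!:X{\to}Y,\; b_{rev}\!:Y{\to}M\}$, minus reversed models
  that duplicate a retained counterpart. The single-edge reversal
  ($\{b_{rev}\}$ vs $\{b\}$) is *exactly* likelihood-equivalent under the
  node-wise conjugate prior; the fully connected reversed triangle
  ($\{a, c, b_{rev}\}$ vs $\{a, b, c\}$) is Markov-equivalent — its score
  agrees asymptotically but not identically at finite $N$, because exact
  finite-sample score equivalence across all DAG factorizations would
  require a Wishart-type joint prior rather than independent per-node
  priors. Both duplicates are excluded; retaining the triangle would split
  the partial-mediation posterior mass across two interchangeable labels.
  Selections other than the four named models are reported as `"Other"`
  (nonmediation).

Because all marginal likelihoods for univariate standardized data depend
only on the three sample correlations and $N$, simulation studies use a
vectorized path (`classify_cors()`) that agrees exactly with the full fit.

## What the simulation engine emulates

`sim_design()` / `sample_configs()` draw the two free causal correlations
and three error correlations iid from Beta(5, 1.25) — mean 0.8, 95% highest
density interval (0.5, 1). This emulates the regime of local QTL with
moderate-to-strong effects and modern expression/proteomics assays; it
produces data-correlation patterns similar to those seen in mouse liver
QTL-transcript-protein data. `simulate_triplet()` builds standardized
linear-Gaussian triplets: $X^*$ standard normal, each downstream variable
$\rho \cdot \text{parent} + \sqrt{1-\rho^2}\cdot\text{noise}$, measured
variables generated from their causal counterparts the same way.

The multistate variant emulates eight-founder haplotype dosages: $X^*$ is a
uniform one-hot state, a mean-centered state-effect vector is scaled so the
squared multiple correlation with the child equals $\rho^2$ (the natural
multistate analog of the univariate effect size), and the same effect
vector is shared by both child edges so the Independent structure's product
constraint carries over. Genotype measurement error is a state
misassignment retaining the true state with probability $\rho_{X^*X}$:
conditioning gives $E[v(s^*) \mid s] = \rho_{X^*X}\, v(s)$ for the centered
effect vector $v$, so the canonical correlation between the measured dosage
block and a child is exactly $\rho_{X^*X}\rho$, matching the univariate
attenuation algebra. Dosage rows stay on the simplex.

Features of real data deliberately **not** emulated: kinship/population
structure, linkage between distinct loci, unbalanced state frequencies,
dosage uncertainty, non-Gaussian abundance distributions, and hidden
confounders. Passing simulations therefore validate the operating
characteristics of model selection under the stated generative model, not
robustness to those complications.

Reproducibility: one master seed spawns per-(structure, configuration)
substream seeds, so studies are order-independent and chunkable.

## The classification-rate studies

`run_classification_study()` samples configurations per structure,
simulates one dataset each, classifies, and tabulates percentages;
`rate_vs_latent_curve()` resolves rates by the middle latent correlation
(bin width 0.05), stratified by whether $\rho_{XU}$ or $\rho_{YU}$
dominates. The package's studies default to 10,000 configurations per
structure at $N = 200$, 5,000 per structure for the $N = 5{,}000$
three-choice sweep, and 2,000 per structure for the expanded sweep at
$N = 5{,}000$ — sizes at which every tabulated cell has a binomial standard
error below half a percentage point while a full study runs in about a
minute. `scripts/acceptance.R` recomputes the headline rates from scratch
at exactly these sizes.

## Bootstrap diagnostics for observed triplets

For a real triplet, `bootstrap_correlations()` case-resamples rows (10,000
times by default) and re-estimates the data correlations, giving an
empirical region — by default the central 95% interval per correlation.
"Jointly within the range" is implemented as joint membership in the three
per-coordinate intervals; the raw min/max range is available behind a flag
but is noisier and widens with the number of resamples. Degenerate
resamples are redrawn and counted; more than 1% aborts. A multistate
genotype uses the first canonical correlation, computed as
$\sqrt{R^2}$ of the regression of the (univariate) response on the dosage
block — the two are identical in that case, and the regression form is
numerically robust.

`config_library()` simulates a library of configurations at a sample size
matching the observed study (the realized *estimated* correlations at
finite $N$ are stored, not population values, since the region itself
reflects sampling noise). `filter_configs()` keeps configurations of an
assumed structure whose realized correlations fall jointly inside the
region and summarizes surviving parameters by median and 95% highest
density interval (`hdi()`, sorted-window method; with fewer than 20
survivors the plain range is reported). An empty survivor set is an
explicit result: the assumed structure cannot produce the observed
correlations at library resolution. No formal posterior over structures is
computed — the tool reports feasible parameter ranges, and the verdict
rests on biological context.

```{r}
dat <- simulate_triplet(cfg, n = 200, seed = 42)
boot <- bootstrap_correlations(dat, n_boot = 1000, seed = 1)
lib <- config_library("Causal", n_configs = 2000, sample_size = 200, seed = 2)
filter_configs(lib, boot)
```

## Design choices where the design was open

* **Complex parameterization.** The Complex structure is parameterized by
  marginal causal correlations (any PSD triple), with partial correlations
  available only as derived quantities; this keeps one container for all
  four structures.
* **Latent estimator.** The tetrad/product closed form is adopted as the
  estimator; for three indicators and one factor it is exact
  method-of-moments inversion, and no iterative one-factor fit can improve
  on it.
* **Signed correlations.** Parameters are stored signed even though the
  simulation study samples only positive Beta values — real triplets (e.g.
  negative regulation) need signs, and every formula is sign-correct as a
  product.
* **Error correlations in (0, 1].** Zero is rejected outright: a pure-noise
  variable has no data correlations and every downstream computation
  degenerates.
* **Model-set enumeration.** Reversed-edge duplicates are excluded by
  likelihood/Markov equivalence as described above; the enumeration retains
  $\{a, b_{rev}\}$ (a collider at $M$), which is not equivalent to any
  $M \to Y$ model.
* **Posterior ties** (gap below $10^{-12}$) resolve by fixed enumeration
  order and are flagged.
* **Library sample size.** Case-study libraries default to the observed
  $N$, since the filter compares finite-sample realized correlations with a
  finite-sample bootstrap region.

## Limitations

The package inherits the identifiability ceiling it quantifies: with three
observed variables, causal and error correlations cannot be separated, and
no selection procedure that ignores measurement error is consistent for the
causal structure once the middle variable is noisy. The bootstrap filter
inverts the generative model only up to the Beta-distributed library prior,
and its conclusions are qualitative. Kinship-aware QTL scans, allele-effect
estimation, technical-replicate error estimation, and Mendelian
randomization are out of scope.
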