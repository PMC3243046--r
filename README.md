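# cytotrans

Maximum-likelihood optimization of flow cytometry data transformations,
with the evaluation machinery to measure what optimized parameters buy
in an automated gating pipeline.

## The problem

Cytometry intensities span orders of magnitude and, after compensation,
include negative values. Automated gating (model-based clustering of
events into cell populations) is run on a transformed scale — linlog,
generalized arcsinh, biexponential/logicle, or signed generalized
Box-Cox — and the transformation parameters are usually left at
software defaults that fit no particular dataset. `cytotrans` fits them
per sample: model the *transformed* data $Y^{(\theta)}$ as multivariate
Gaussian and maximize the likelihood with the change-of-variables
Jacobian included, which reduces to minimizing

$$\log S(\theta) = \log\det\widehat\Sigma(\theta)
  - \tfrac{2}{n}\sum_i \log J_\theta(Y_i),$$

the transformed covariance log-determinant penalized by the geometric
mean of the squared Jacobians.

The package provides:

* `forward()`, `inverse()`, `log_jacobian()`, `biexp_function()` — the
  four parametric families (plus log/identity baselines), their
  inverses and log-Jacobians; the biexponential forward is computed by
  safeguarded monotone root finding.
* `profile_objective()`, `transform_loglik()`, `fit_transform()` — the
  Jacobian-corrected criterion and its constrained optimizer.
* `fit_t_mixture()`, `assign_events()` — a fixed-K multivariate-t
  mixture EM gater (fixed degrees of freedom, no merging or outlier
  component).
* `metacluster()`, `pop_mahalanobis()`,
  `intra_metacluster_variability()` — constrained single-linkage
  matching of gated populations across samples under asymmetric
  Mahalanobis distances.
* `simulate_dataset()`, `normalize_events()`,
  `misclassification_rate()`, `run_simulation_study()` — a synthetic
  benchmark (9-component multivariate-t mixture corrupted by random
  inverse-biexponential maps) and the full transformation-comparison
  study.
* `read_events()` / `write_events()` for CSV and FCS 3.0/3.1 input, and
  a command-line wrapper (`inst/cli/cytotrans`) with subcommands
  `simulate`, `fit`, `transform`, `gate`, `metacluster`, `study`.

## Worked example

```r
library(cytotrans)

sim <- simulate_dataset(seed = 7, n = 15000)  # corrupted + ground truth
fit <- fit_transform(sim$events, "biexp", seed = 11)
round(fit$spec$params, 3)
#>     a     b     c     d     f     w
#> 0.072 0.175 0.173 0.119 0.000 0.000

y <- normalize_events(forward(fit$spec, sim$events))
model <- fit_t_mixture(y, K = 9, nu = 4, seed = 2)
misclassification_rate(sim$true_labels, assign_events(model, y))
#> [1] 0.005866667

yc <- normalize_events(sim$clean_events)
clean <- fit_t_mixture(yc, K = 9, nu = 4, seed = 2)
misclassification_rate(sim$true_labels, assign_events(clean, yc))
#> [1] 0.0048
```

The fitted parameters differ from the corruption's (the criterion
identifies the biexponential only up to an affine post-composition —
see the vignette), yet gating after the fitted transform misclassifies
0.59% of events versus 0.48% on the never-corrupted data: the
transformation has been recovered in the sense that matters.

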