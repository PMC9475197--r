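# elasurf

Elastic shape analysis of closed, genus-zero surfaces in R — built for
subcortical brain structures (hippocampus, amygdala, putamen) segmented from
MRI, and for anyone who needs to compare, average and decompose shapes of
closed surfaces while remaining invariant to how those surfaces happen to be
parameterized.

## What it does

A surface is a map *f*: S² → ℝ³ sampled on a regular colatitude–longitude
grid. elasurf represents it by its **square-root normal field**

> q(s) = n(s) / |n(s)|^½,  n = f_u × f_v,

under which the elastic comparison of shapes becomes an L² problem: the
distance between two shapes is

> d_s([q₁],[q₂]) = inf over rotations O and sphere reparameterizations γ of
> ‖q₁ − O (q₂∘γ)√J_γ‖.

The infimum is computed by a Procrustes rotation step, a coarse search over
the 60 icosahedral placements of the pole axis, and gradient descent over
reparameterizations spanned by harmonic-gradient and rotational vector
fields. On top of the metric the package provides:

- **Spherical parameterization** of triangulated genus-zero meshes (VTK
  legacy / OFF / PLY readers, Tuette + conformal mapping, resampling to the
  grid);
- **geodesic deformation paths**, **Karcher means**, and **shape PCA** with
  invertible principal scores (`eshape_pca()` is a classed model with
  `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `simulate`
  and `plot` methods);
- **synthetic generators** — surface families with planted deformation
  modes, random sphere diffeomorphisms, a 40-surface one-mode "line"
  simulation, and clinical covariate tables (age, BDI, ICV, PSS, CTQTOT)
  with planted regression structure;
- the **regression layer**: the ten principal-score model designs for PTSD
  outcomes, OLS with adjusted R², bidirectional stepwise selection,
  pairwise distance matrices and classical MDS.

## Worked example

```r
library(elasurf)
set.seed(1)
g <- sphere_grid(32, 32)

# a synthetic family of 20 unit-area surfaces with 3 planted modes
fam <- generate_family(surface_family_spec(n = 20, n_modes = 3, seed = 1), g)

# hide the correspondence of one surface behind a random reparameterization,
# then recover it
f1 <- fam$surfaces[[1]]
dif <- random_diffeomorphism(g, amplitude = 0.3, seed = 2)
f2_warp <- center_and_scale(apply_reparam(fam$surfaces[[2]], dif))
register_pair(f1, f2_warp)
#> registration_result: d_s = 0.0882991 (unregistered 1.59444), 172 descent steps

# population model: Karcher mean + shape PCA
fit <- eshape_pca(fam$surfaces, k = 3, config = reg_config(max_iter = 30))
summary(fit)
#> Elastic shape PCA: n = 20, Karcher variance 0.0003655 (7 iterations)
#>  component singular_value proportion cumulative
#>          1      3.322e-02     0.8598     0.8598
#>          2      3.699e-03     0.0958     0.9556
#>          3      1.677e-03     0.0434     0.9990
#>          ...
```

The registration collapses the pre-shape distance from 1.59 (almost all of
it spurious, caused by the parameterization) to 0.088, and the shape PCA
concentrates 99.9% of the variance in three components — the three planted
modes. Principal scores of new surfaces come from
`predict(fit, surfaces)`; `reconstruct()` maps scores back to surfaces.

Clinical modeling on principal scores:

```r
scores <- list(hippocampus = coef(fit)[, 1:3])
planted <- data.frame(outcome = "PSS",
                      term = c("(Intercept)", "hippocampus_PS1"),
                      beta = c(15, 3))
tab <- simulate_clinical(scores, planted, noise_sd = 2, seed = 1)
fit_ols(build_design(tab, model_spec(4, structures = "hippocampus",
                                     n_scores = 3, n_interact = 3)))
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/elasurf` (subcommands `param`, `register`, `mean`, `pca`,
`reconstruct`, `simulate`, `regress`, `run`).

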