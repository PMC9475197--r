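---
title: "Elastic shape analysis of closed surfaces with elasurf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic shape analysis of closed surfaces with elasurf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elasurf)
```

## The model

elasurf analyzes shapes of closed, genus-zero surfaces — the kind produced by
model-based subcortical segmentation of brain MRI (hippocampus, amygdala,
putamen) — as parameterized embeddings \(f: S^2 \to \mathbb{R}^3\). A surface
is sampled on a regular colatitude–longitude grid; the partial derivative
fields \(f_u, f_v\) define the unnormalized normal
\(\mathbf{n}(s) = f_u \times f_v\), and the surface is represented by its
*square-root normal field* (SRNF)

\[
q(s) = \frac{\mathbf{n}(s)}{|\mathbf{n}(s)|^{1/2}},
\]

whose pointwise squared magnitude is the local area element, so
\(\|q\|^2\) equals the surface area exactly. The SRNF is invariant to
translation, and a reparameterization \(\gamma\) of the sphere acts by
\((q \circ \gamma)\sqrt{J_\gamma}\), which preserves the \(L^2\) norm. The
key property is that the \(L^2\) distance between two SRNFs is unchanged
when the *same* rotation and reparameterization act on both surfaces. That
invariance licenses the elastic shape distance

\[
d_s([q_1],[q_2]) \;=\; \inf_{(O,\gamma)\in SO(3)\times\Gamma}
  \left\| q_1 - O\,(q_2\circ\gamma)\sqrt{J_\gamma} \right\|,
\]

a metric on the quotient of the pre-shape space \(L^2(S^2,\mathbb{R}^3)\) by
rotations and orientation-preserving sphere diffeomorphisms. Before
optimizing, translation is removed with the area-weighted centroid and scale
by division by the square root of the area, so all surfaces have unit area.
(The notational shortcut "divide by the area" would scale the area by its
inverse square; dividing by its square root is what achieves unit area, and
that is what `center_and_scale()` does.)

On top of the metric the package builds population statistics: geodesic
deformation paths (linear interpolation after registration, which is the
standard practical surrogate for exact SRNF geodesics), the Karcher mean by
alternating registration and nodewise averaging, and shape PCA of the
registered, vectorized surfaces about the mean, with principal scores
\(z_d = \langle \mathrm{vec}(f-\mu), U_d\rangle\) that invert to
reconstructions \(\hat f_k = \mu + \sum_{d\le k} z_d U_d\). The scores feed
linear models of clinical outcomes (PTSD symptom scale, childhood trauma
score) with score-by-age and score-by-depression interactions.

## Integration measures

Two discrete measures coexist and are worth being explicit about. Quadrature
weights of the grid (`quad_weights`) are the spherical area elements
\(\sin\theta\,\Delta\theta\,\Delta\phi\); they sum to \(4\pi\) and back the
generic field inner product `inner_product_l2()`. Area and all SRNF-space
integrals, however, live over the parameter measure
\(\Delta\theta\,\Delta\phi\): with that convention the identities the
representation is prized for hold *exactly* in the discretization —
\(\|q\|^2 = \alpha_f\) to machine precision, the unit sphere has area
\(4\pi\), and the round sphere's SRNF is \(\sqrt{\sin\theta}\,f\). The
reparameterization action correspondingly uses the parameter-coordinate
Jacobian \(J_{par} = J_{sphere}\,\sin\theta / \sin\theta(\gamma)\), while
`sphere_diffeo()` stores the sphere-measure Jacobian, for which total-area
conservation (\(\int J\,dA = 4\pi\)) is the natural invariant.

## Numerical choices

**Grid.** Colatitudes sit at midpoints \(\theta_j = (j-\tfrac12)\pi/n_\theta\)
so the poles are never nodes and \(\sin\theta > 0\) everywhere; longitude is
periodic. Derivatives are central differences (periodic in \(\phi\),
second-order one-sided at the two boundary colatitude rows). Interpolation
is bilinear with periodic wrap in \(\phi\) and reflection across the poles
(a query beyond the last row blends with the antipodal-longitude values of
that row). Default resolution is 64×64 for single-pair geometry and 32×32
for population studies; these sizes keep the full validation suite in the
minutes range on one CPU while the convergence tests demonstrate the
first-order error decay under refinement.

**Registration.** The optimization interleaves three ingredients: a closed
form for the rotation (Procrustes via the SVD of the weighted 3×3
cross-covariance of the SRNFs); a coarse search over the 60 elements of the
icosahedral rotation group acting as rigid domain rotations (60 candidate
placements of the pole axis, each scored with its own optimal rotation; ties
go to the lowest element index, identity first); and a projected gradient
descent over reparameterizations. Increments are flows of smooth tangent
fields — tangential gradients of homogeneous harmonic polynomials up to
degree 4 (the same span as real-spherical-harmonic gradients, but
polynomial evaluation has no pole singularities) plus the three rotational
Killing fields, 27 fields in all — composed onto the current map on the
target side, \(\gamma \leftarrow \exp(\delta b)\circ\gamma\), so the basis
is always evaluated analytically at \(\gamma(s)\) rather than interpolated.
The energy gradient is computed by forward differences along each basis
field; the backtracking line search starts from the last accepted step
(capped at 0.1 radians) and halves at most 20 times; any step that would
make the Jacobian non-positive is rejected. Defaults are 300 outer
iterations with a relative-decrease tolerance of \(10^{-6}\): on moderately
distant pairs the two registration directions then agree to better than a
few percent, which a 100-iteration budget does not achieve. The composed
surface's SRNF is computed directly from finite differences of
\(f_2\circ\gamma\), so the Jacobian factor enters through the chain rule of
the stencils and the registered distance is exactly the pre-shape distance
of the output surfaces.

**A discretization floor, and what it implies.** Bilinear interpolation of
the moving surface makes the *derivatives* of the composed surface accurate
only to first order in the grid spacing. Consequently there is a floor on
the achievable registration energy that is not optimizer error: evaluating
the energy at the *exact* inverse of a planted amplitude-0.3
reparameterization on a 32×32 grid still leaves \(d_s \approx 0.05\) (and a
surface-space residual of \(\approx 0.16\) on a unit-area shape). Pushing
the q-space energy below this floor actively *misaligns* the surfaces (the
optimizer starts fitting interpolation noise), so running the descent far
beyond the floor is counterproductive. For shape differences comparable to
the floor — for example, a simulated family along a single unit-norm
principal direction — distance-based clustering after re-registration
recovers most but not all of the class structure at 32×32; when the planted
deformations are scaled above the floor, or the grid refined, recovery
approaches the aligned-family reference. The validation suite reports these
accuracies as measured.

**Karcher mean.** Initialized at the first surface (the choice is
arbitrary), registering all surfaces to the current mean, averaging
nodewise, and renormalizing the *registration target* to unit area; the
returned mean is the plain average of the final registered set, so training
scores are exactly mean-centered. The variance trace
\(\sum_i d_s(\mu, f_i)^2\) is recorded per iteration, and the iteration
stops (keeping the previous state) if an update fails to decrease it, which
makes the trace non-increasing by construction. Convergence tolerance is
\(10^{-4}\) relative change of the mean, at most 20 iterations. A
registration failure for one surface falls back to the identity with a
warning rather than dropping the surface. For families that are generated
already aligned (simulation studies), `register = FALSE` treats them as
registered, which is also how the line-simulation study handles its
surfaces; re-registering pre-aligned shapes is legitimate elastic matching
but deforms planted linear structure and therefore tests the wrong thing
there.

**Shape PCA.** The covariance of the paper's formulation,
\(C=\sum_i V_iV_i^\top\) with \(V_i = \mathrm{vec}(f_i^*-\mu)\), is never
formed: the thin SVD of the \(n \times 3n_\theta n_\phi\) data matrix gives
the same directions and the singular values of \(C\) as squared singular
values. Scores use the plain Euclidean inner product on vectorized surfaces,
matching the printed formulas (on these near-uniform grids an area-weighted
variant differs negligibly; it is not the default). Null directions
(singular values below \(10^{-10}\) of the total) are dropped, so at most
\(n-1\) components are exposed. Each direction's sign is fixed so its
largest-magnitude entry is positive.

## The synthetic-data generators

The MRI data the method was designed for are restricted, so the package
ships generators that emulate the relevant structure with known ground
truth.

*Surface families.* Analytic bases (an ellipsoid with hippocampus-like
axis ratios, or a bent tube) carry up to six smooth deformation modes
(elongation, bending, twist, shear, taper, bulge). Raw mode profiles are
pushed through the linearized center-and-scale map at the base shape — the
derivative of an idempotent normalization is a projection onto the tangent
space of the unit-area, zero-centroid manifold — and then Gram–Schmidt
orthonormalized in the vectorized Euclidean metric. Without that projection,
per-surface normalization injects spurious components *linear* in the
planted scores and corrupts subspace recovery. Default mode standard
deviations are \(0.02\,(2, \sqrt2, 1, \dots)\): planted energies in ratio
4:2:1, a few percent of the unit-area shape scale, comparable to the
population variability a first principal component of a subcortical
structure explains. Nodewise noise defaults to zero (smooth surfaces);
white nodewise noise is available but deliberately not default, because it
breaks the finite-difference convergence that several validations rely on.

*Line families.* `simulate_pc_line()` draws 40 surfaces
\(f_i = \mu + x_i v_1\) with \(x_i\) uniform in \((0,1]\) for the first 20
and \([-1,0)\) for the rest. Because the draw has no margin at zero,
2-medoid clustering of even the perfectly aligned family misassigns
boundary points whenever the midpoint between the cluster medoids is offset
from zero — across 40 generator seeds the probability of a perfect 20/20
split is only about 0.28. Reported clustering accuracies should be read
with that in mind: they measure the clustering geometry of a gapless
uniform sample as much as the registration.

*Reparameterizations.* A random icosahedral rotation composed with the flow
of a random degree-≤3 harmonic gradient field (10 Euler steps with
renormalization), scaled to a requested RMS speed; if the map folds, the
amplitude is halved until the Jacobian is positive everywhere.

*Clinical tables.* Age uniform on 18–61 years; BDI as a right-skewed gamma
score clipped to 0–63; intracranial volume normal around
\(1.45\times10^6\ \mathrm{mm}^3\); outcomes PSS (0–42) and CTQTOT (25–125)
generated from a user-specified linear model in score columns, age, BDI and
their products, plus Gaussian noise, clipped to the instrument ranges after
noise (clipping mildly attenuates coefficients near the boundaries, which
is why validation models keep linear predictors inside the ranges).

What the generators do *not* emulate: real segmentation noise and topology
defects, between-structure correlation, non-Gaussian score distributions,
and real anatomical templates. Passing validations demonstrates the
machinery is correct under the planted models, not that effect sizes on
real cohorts will match.

## The regression layer

`model_spec()` encodes the ten clinical designs (PSS and CTQTOT as
outcomes; age + BDI, scores only, both, both plus interactions, and the
interaction models augmented with ICV). Main effects use the first 15
scores per structure and interactions the first 5 per structure, crossed
with age and BDI; scores are z-scored before products are formed (a raw
option exists). Stepwise selection is bidirectional from the intercept-only
model and optimizes BIC by default rather than AIC: with AIC each null
predictor is admitted with probability \(\approx 0.16\), so a null design
with even a handful of predictors would almost never return an empty model,
contradicting the behavior the selection step is supposed to certify; BIC
admits nulls at \(\approx 2\%\) and still always recovers strong effects.
AIC and a p-enter/p-remove variant remain available. p-values are reported
unadjusted, as is conventional for these tables; a Benjamini–Hochberg
option exists but is off by default. The irrelevant-ICV stability check
(the augmented models matching the originals to two decimals) holds through
selection: an uninformative ICV column is simply never selected, so the
final fits coincide exactly.

## Validation studies and problem sizes

The `validate_*()` family runs the package's own acceptance studies; the
test suite asserts on their outputs and `scripts/acceptance.R` reports
them. Sizes were chosen so the full set completes in a few minutes on one
CPU: 20 surface pairs at 64×64 and 128×128 for the invariance study, 5
pairs at 24×24 for metric sanity, 50 random rotations, the 40-surface line
study at 32×32, a 100-surface three-mode family at 32×32 with an 80/20
train/test split (the same split ratio used for the real cohorts), and 100
Monte-Carlo replicates for the regression checks. The ±0.1 band on the
first cumulative-variance proportion corresponds to roughly two standard
errors of a variance ratio at 80 training samples.

## Known limitations

- The descent guarantees monotone energy decrease from the best coarse
  start, not a global optimum; for near-symmetric shapes different basins
  can yield slightly asymmetric distances.
- Bilinear interpolation caps registration accuracy at the first-order
  floor described above; a higher-order interpolant would lower it at some
  robustness cost.
- Geodesics are linear interpolations of registered surfaces, not exact
  SRNF geodesics (no SRNF inversion is attempted).
- Spherical parameterization assumes clean genus-zero input meshes and uses
  fixed-step projected descent; badly conditioned meshes (near-degenerate
  triangles) may need the subdivision option or more iterations.
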