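# Synthetic surface families, random sphere reparameterizations and synthetic
# clinical covariates. These stand in for restricted MRI-derived data: the
# generators plant known ground truth (deformation modes, parameterizations,
# regression coefficients) so every downstream stage can be validated against
# what was planted.

#' Analytic base shapes on a spherical grid
#'
#' `ellipsoid` is `diag(axes)` applied to the unit sphere; `bent_tube` is an
#' elongated ellipsoid whose long axis is bent in the x-z plane
#' (`z <- z + bend * x^2`), a stand-in for banana-shaped subcortical
#' structures such as the hippocampus. Surfaces are centered and scaled to
#' unit area.
#'
#' @param grid a [sphere_grid()].
#' @param shape `"ellipsoid"` or `"bent_tube"`.
#' @param axes length-3 semi-axes before normalization.
#' @param bend bending coefficient for `bent_tube`.
#' @return A unit-area [grid_surface()].
#' @export
base_surface <- function(grid, shape = c("ellipsoid", "bent_tube"),
                         axes = NULL, bend = 0.6) {
  shape <- match.arg(shape)
  if (is.null(axes)) {
    axes <- if (shape == "ellipsoid") c(1, 0.7, 0.55) else c(1, 0.35, 0.35)
  }
  P <- grid_directions(grid)
  M <- cbind(axes[1] * P[, 1], axes[2] * P[, 2], axes[3] * P[, 3])
  if (shape == "bent_tube") {
    M[, 3] <- M[, 3] + bend * M[, 1]^2
  }
  center_and_scale(grid_surface(M, grid, shape))
}

# Smooth deformation-mode fields over the grid. Each mode starts as a
# low-order polynomial scalar profile times a fixed direction, is made
# (first-order) neutral to translation and to global scaling/area change, and
# the set is then Gram-Schmidt orthonormalized in the plain Euclidean metric
# on vectorized fields (the metric shape PCA uses).
mode_fields <- function(grid, base, n_modes = 3) {
  if (n_modes > 6) stop("at most 6 built-in deformation modes")
  P <- grid_directions(grid)
  x <- P[, 1]; y <- P[, 2]; z <- P[, 3]
  profiles <- list(
    cbind(x, 0 * x, 0 * x),          # elongation along x
    cbind(0 * x, 0 * x, x^2),        # bending of the long axis
    cbind(0 * x, y * z, 0 * x),      # twist of the cross-section
    cbind(0 * x, 0 * x, z * x),      # shear
    cbind(x * y, 0 * x, 0 * x),      # asymmetric taper
    cbind(0 * x, y^2, 0 * x)         # bulge
  )[seq_len(n_modes)]
  fb <- field_as_matrix(base$f)
  n <- nrow(fb)
  eps <- 1e-4
  # push each raw profile through the linearized center-and-scale map at the
  # base shape. The derivative of an idempotent normalization is a projection
  # onto the tangent space of the unit-area/zero-centroid manifold, so the
  # projected modes survive per-surface normalization to first order.
  fb0 <- field_as_matrix(center_and_scale(base)$f)
  neutralize <- function(V) {
    fp <- field_as_matrix(center_and_scale(grid_surface(fb + eps * V, grid))$f)
    (fp - fb0) / eps
  }
  modes <- lapply(profiles, neutralize)
  # Gram-Schmidt, unit Euclidean norm
  out <- list()
  for (V in modes) {
    v <- as.vector(V)
    for (u in out) v <- v - sum(v * u) * u
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10) stop("degenerate mode construction")
    out[[length(out) + 1]] <- v / nv
  }
  do.call(cbind, out)  # (3*n) x n_modes, orthonormal columns
}

#' Specification of a synthetic surface family
#'
#' @param base base shape name (`"ellipsoid"` or `"bent_tube"`).
#' @param axes,bend base-shape parameters (see [base_surface()]).
#' @param n number of surfaces.
#' @param n_modes number of planted deformation modes (<= 6).
#' @param mode_sd per-mode standard deviations of the planted scores; the
#'   default `0.02 * c(2, sqrt(2), 1, ...)` gives mode energies in ratio
#'   4:2:1..., a few percent of the unit-area shape scale.
#' @param noise_sd nodewise isotropic Gaussian noise (default 0: smooth
#'   surfaces).
#' @param seed RNG seed.
#' @return A list of class `surface_family_spec`.
#' @export
surface_family_spec <- function(base = "ellipsoid", axes = NULL, bend = 0.6,
                                n = 20, n_modes = 3, mode_sd = NULL,
                                noise_sd = 0, seed = 1) {
  if (is.null(mode_sd)) mode_sd <- 0.02 * sqrt(2)^((n_modes:1) - 1)
  stopifnot(length(mode_sd) == n_modes, n >= 1)
  structure(
    list(
      base = base, axes = axes, bend = bend, n = n, n_modes = n_modes,
      mode_sd = mode_sd, noise_sd = noise_sd, seed = seed
    ),
    class = "surface_family_spec"
  )
}

#' Generate a synthetic surface family with planted modes
#'
#' Draws per-surface mode scores `z ~ N(0, sd_m^2)`, forms
#' `base + sum_m z_m mode_m (+ noise)` and normalizes each surface to zero
#' centroid and unit area. Deterministic given the spec's seed.
#'
#' @param spec a [surface_family_spec()].
#' @param grid a [sphere_grid()].
#' @return A list with `surfaces` (list of [grid_surface()]), `scores`
#'   (`n x n_modes` planted scores), `modes` (orthonormal mode matrix),
#'   `base_surface` and `spec`.
#' @export
generate_family <- function(spec, grid) {
  stopifnot(inherits(spec, "surface_family_spec"))
  base <- base_surface(grid, spec$base, spec$axes, spec$bend)
  modes <- mode_fields(grid, base, spec$n_modes)
  set.seed(spec$seed)
  z <- matrix(rnorm(spec$n * spec$n_modes), spec$n, spec$n_modes)
  z <- sweep(z, 2, spec$mode_sd, `*`)
  fb <- as.vector(field_as_matrix(base$f))
  surfaces <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    v <- fb + as.vector(modes %*% z[i, ])
    if (spec$noise_sd > 0) v <- v + rnorm(length(v), 0, spec$noise_sd)
    M <- matrix(v, ncol = 3)
    surfaces[[i]] <- center_and_scale(
      grid_surface(M, grid, sprintf("synth-%03d", i))
    )
  }
  list(surfaces = surfaces, scores = z, modes = modes,
       base_surface = base, spec = spec)
}

#' Simulated one-mode surface line
#'
#' Generates 40 surfaces along a single principal direction,
#' `f_i = mu + x_i * v1`, with `x_i` uniform in `(0, 1]` for the first 20
#' (class `+1`) and in `[-1, 0)` for the last 20 (class `-1`). Because the
#' family is collinear, pairwise L2 distances are exactly
#' `|x_i - x_j| * ||v1||`.
#'
#' @param mu a [grid_surface()] (the mean shape).
#' @param v1 unit-norm direction: a vector of length `3 * nt * np` or an
#'   `nt x np x 3` array (normalized internally).
#' @param seed RNG seed.
#' @param amplitude overall deformation scale multiplying `x_i * v1`
#'   (default 1, the unit-direction convention).
#' @return A list of class `simulated_line` with `surfaces`, `x`, `labels`.
#' @export
simulate_pc_line <- function(mu, v1, seed = 1, amplitude = 1) {
  g <- mu$grid
  v1 <- as.vector(v1)
  stopifnot(length(v1) == 3L * g$n_theta * g$n_phi)
  v1 <- v1 / sqrt(sum(v1^2))
  set.seed(seed)
  x <- c(1 - runif(20), -(1 - runif(20)))  # (0,1] then [-1,0)
  fmu <- as.vector(field_as_matrix(mu$f))
  surfaces <- lapply(seq_along(x), function(i) {
    grid_surface(matrix(fmu + amplitude * x[i] * v1, ncol = 3), g,
                 sprintf("line-%02d", i))
  })
  structure(
    list(surfaces = surfaces, x = x,
         labels = rep(c(1L, -1L), each = 20L), v1 = v1, mu = mu),
    class = "simulated_line"
  )
}

#' Random sphere diffeomorphism
#'
#' Composes a random icosahedral rotation of the domain with the flow of a
#' random tangent field (a combination of spherical-harmonic-type gradient
#' fields of degree <= `degree`), integrated in `nsteps` Euler steps with
#' renormalization. The field is scaled so its root-mean-square speed equals
#' `amplitude` (radians). If the resulting map folds (Jacobian <= 0 anywhere)
#' the amplitude is halved until it is valid.
#'
#' @param grid a [sphere_grid()].
#' @param amplitude RMS flow magnitude in radians.
#' @param seed RNG seed.
#' @param rotate include the random icosahedral rotation (default TRUE).
#' @param degree maximum harmonic degree of the flow field (default 3).
#' @param nsteps Euler integration steps (default 10).
#' @return A [sphere_diffeo()]; attribute `amplitude_used` records any
#'   internal halving.
#' @export
random_diffeomorphism <- function(grid, amplitude, seed = 1, rotate = TRUE,
                                  degree = 3, nsteps = 10) {
  set.seed(seed)
  basis <- get_tangent_basis(degree)
  n_grad <- basis$n_fields - 3L  # gradient fields only, no Killing fields
  coefs <- rnorm(n_grad)
  R <- if (rotate) icosahedral_group()[[sample.int(60, 1)]] else diag(3)
  P0 <- grid_directions(grid)
  flow_field <- function(P) {
    flds <- eval_tangent_basis(basis, P)
    V <- matrix(0, nrow(P), 3L)
    for (k in seq_len(n_grad)) V <- V + coefs[k] * flds[[k]]
    V
  }
  # calibrate to RMS speed = amplitude on the undeformed grid
  V0 <- flow_field(P0)
  rms <- sqrt(mean(rowSums(V0^2)))
  amp <- amplitude
  repeat {
    Pcur <- P0 %*% t(R)
    if (amp > 0 && rms > 0) {
      scale <- amp / rms / nsteps
      for (s in seq_len(nsteps)) {
        Pcur <- Pcur + scale * flow_field(Pcur)
        Pcur <- Pcur / sqrt(rowSums(Pcur^2))
      }
    }
    d <- sphere_diffeo(Pcur, grid)
    if (min(d$jac_det) > 0 || amp <= 1e-8) break
    amp <- amp / 2
    message(sprintf(
      "random_diffeomorphism: folded map, halving amplitude to %.4g", amp
    ))
  }
  attr(d, "amplitude_used") <- amp
  d
}

#' Synthetic clinical covariate table with planted regression structure
#'
#' Builds a per-subject table of demographic/exposure covariates and
#' principal-score columns, then generates the outcomes PSS (0-42) and CTQTOT
#' (25-125) from a planted linear model (main effects and optional
#' score-by-age / score-by-BDI products) plus Gaussian noise, clipped to the
#' instrument ranges afterwards. Ranges: age uniform on 18-61 years; BDI a
#' right-skewed depression score on 0-63; ICV (intracranial volume, mm^3)
#' approximately normal and independent of the outcomes.
#'
#' @param scores matrix of principal scores (`n x k`), or a named list of such
#'   matrices (one per structure, e.g. `list(hippocampus = ..., amygdala = ...)`).
#' @param coefficients data frame with columns `outcome` ("PSS"/"CTQTOT"),
#'   `term` (a column name, or `a:b` for a product) and `beta`. An
#'   `(Intercept)` term sets the intercept.
#' @param noise_sd residual standard deviation for both outcomes.
#' @param seed RNG seed.
#' @return A `data.frame` of class `clinical_table` with attributes
#'   `planted` (the coefficient table) and `structures`.
#' @export
simulate_clinical <- function(scores, coefficients, noise_sd = 3, seed = 1) {
  if (is.matrix(scores)) scores <- list(structure1 = scores)
  stopifnot(is.list(scores), length(scores) >= 1, !is.null(names(scores)))
  n <- nrow(scores[[1]])
  set.seed(seed)
  tab <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = runif(n, 18, 61),
    BDI = pmin(pmax(round(rgamma(n, shape = 2, scale = 8)), 0), 63),
    ICV = rnorm(n, 1.45e6, 1.3e5)
  )
  for (st in names(scores)) {
    m <- scores[[st]]
    colnames(m) <- sprintf("%s_PS%d", st, seq_len(ncol(m)))
    tab <- cbind(tab, as.data.frame(m))
  }
  eval_term <- function(term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    vals <- rep(1, n)
    for (p in parts) {
      if (p == "(Intercept)") next
      if (!p %in% names(tab)) {
        stop(sprintf("simulate_clinical: term references missing column '%s'", p))
      }
      vals <- vals * tab[[p]]
    }
    vals
  }
  for (oc in c("PSS", "CTQTOT")) {
    rows <- coefficients[coefficients$outcome == oc, , drop = FALSE]
    lp <- rep(0, n)
    for (r in seq_len(nrow(rows))) {
      lp <- lp + rows$beta[r] * eval_term(rows$term[r])
    }
    y <- lp + rnorm(n, 0, noise_sd)
    rng <- if (oc == "PSS") c(0, 42) else c(25, 125)
    tab[[oc]] <- pmin(pmax(y, rng[1]), rng[2])
  }
  structure(tab,
    class = c("clinical_table", "data.frame"),
    planted = coefficients, structures = names(scores)
  )
}
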