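# Validation-study drivers: each function runs one of the package's
# simulation-based checks end to end (generating its own synthetic inputs
# from a seed) and returns the measured quantities. The testthat suite
# asserts on these numbers; scripts/acceptance.R reports them.

# pairs of distinct smooth synthetic shapes (ellipsoid and bent-tube bases
# with planted modes), normalized, on the given grid
validation_pairs <- function(grid, n_pairs, seed) {
  famA <- generate_family(
    surface_family_spec(base = "ellipsoid", n = n_pairs, n_modes = 3,
                        mode_sd = c(0.06, 0.04, 0.03), seed = seed), grid
  )
  famB <- generate_family(
    surface_family_spec(base = "bent_tube", n = n_pairs, n_modes = 3,
                        mode_sd = c(0.06, 0.04, 0.03), seed = seed + 1), grid
  )
  lapply(seq_len(n_pairs), function(i) {
    list(f1 = famA$surfaces[[i]], f2 = famB$surfaces[[i]])
  })
}

#' Invariance of the SRNF distance under joint rotation and reparameterization
#'
#' For random synthetic surface pairs and random joint actions (a rotation
#' and a moderate-amplitude reparameterization applied to both surfaces),
#' measures the relative change of the pre-shape SRNF distance at two grid
#' resolutions. The change is pure discretization error and shrinks under
#' refinement.
#'
#' @param n_pairs number of surface pairs (default 20).
#' @param resolutions grid sizes (default c(64, 128)).
#' @param amplitude reparameterization RMS amplitude (default 0.3).
#' @param seed RNG seed.
#' @return A list with `rel_change` (matrix, pairs x resolutions), and the
#'   per-resolution means and maxima.
#' @export
validate_invariance <- function(n_pairs = 20, resolutions = c(64, 128),
                                amplitude = 0.3, seed = 1) {
  rel <- matrix(NA_real_, n_pairs, length(resolutions),
                dimnames = list(NULL, paste0("n", resolutions)))
  for (r in seq_along(resolutions)) {
    g <- sphere_grid(resolutions[r], resolutions[r])
    pairs <- validation_pairs(g, n_pairs, seed)
    for (i in seq_len(n_pairs)) {
      q1 <- srnf(pairs[[i]]$f1)
      q2 <- srnf(pairs[[i]]$f2)
      d0 <- preshape_distance(q1, q2)
      O <- rotation_from_seed(seed + 100 + i)
      dif <- random_diffeomorphism(g, amplitude, seed = seed + 200 + i)
      t1 <- apply_srnf_rotation(apply_reparam_srnf(q1, dif), O)
      t2 <- apply_srnf_rotation(apply_reparam_srnf(q2, dif), O)
      rel[i, r] <- abs(preshape_distance(t1, t2) - d0) / d0
    }
  }
  list(rel_change = rel, mean = colMeans(rel), max = apply(rel, 2, max))
}

rotation_from_seed <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

apply_srnf_rotation <- function(q, O) {
  q$q <- array(field_as_matrix(q$q) %*% t(O), dim(q$q))
  q
}

#' Metric sanity of the elastic shape distance
#'
#' Self-distance, monotonicity (registered vs unregistered) and the
#' two-directional asymmetry of the optimized distance on distinct synthetic
#' pairs.
#'
#' @param n_pairs number of pairs (default 5).
#' @param grid_n grid resolution (default 24).
#' @param config a [reg_config()].
#' @param seed RNG seed.
#' @return List with `self_distance`, `monotone` (all registered <=
#'   unregistered), `asymmetry` (per-pair relative), `distances`.
#' @export
validate_metric <- function(n_pairs = 5, grid_n = 24, config = reg_config(),
                            seed = 1) {
  g <- sphere_grid(grid_n, grid_n)
  pairs <- validation_pairs(g, n_pairs, seed)
  self_d <- register_pair(pairs[[1]]$f1, pairs[[1]]$f1, config)$distance
  asym <- numeric(n_pairs)
  d12s <- numeric(n_pairs)
  monotone <- TRUE
  for (i in seq_len(n_pairs)) {
    r12 <- register_pair(pairs[[i]]$f1, pairs[[i]]$f2, config)
    r21 <- register_pair(pairs[[i]]$f2, pairs[[i]]$f1, config)
    monotone <- monotone &&
      r12$distance <= r12$unregistered_distance + 1e-12 &&
      r21$distance <= r21$unregistered_distance + 1e-12
    asym[i] <- abs(r12$distance - r21$distance) / r12$distance
    d12s[i] <- r12$distance
  }
  list(self_distance = self_d, monotone = monotone, asymmetry = asym,
       distances = d12s)
}

#' Rotation recovery by the Procrustes step
#'
#' Applies known random rotations to an SRNF field and measures the recovery
#' error of [optimal_rotation()].
#'
#' @param n_rotations number of random rotations (default 50).
#' @param grid_n grid resolution (default 32).
#' @param seed RNG seed.
#' @return List with `max_matrix_error` and `max_distance`.
#' @export
validate_rotation_recovery <- function(n_rotations = 50, grid_n = 32,
                                       seed = 1) {
  g <- sphere_grid(grid_n, grid_n)
  f1 <- validation_pairs(g, 1, seed)[[1]]$f1
  q1 <- srnf(f1)
  errs <- numeric(n_rotations)
  dists <- numeric(n_rotations)
  for (i in seq_len(n_rotations)) {
    O <- rotation_from_seed(seed + 1000 + i)
    q2 <- apply_srnf_rotation(q1, t(O))
    Or <- optimal_rotation(q1, q2)
    errs[i] <- max(abs(Or - O))
    dists[i] <- attr(Or, "distance")
  }
  list(max_matrix_error = max(errs), max_distance = max(dists))
}

#' One-mode line simulation: registration and clustering study
#'
#' Reproduces the simulated-line experiment: 40 surfaces along a single
#' principal direction (20 per sign class), 2-medoid clustering of (i) the
#' raw distance matrix of the aligned family and its 2-D classical-MDS
#' embedding, (ii) the same after random reparameterizations of every
#' surface, and (iii) after elastic co-registration of the perturbed family
#' to a common reference (the state the aligned family starts from).
#'
#' @param grid_n grid resolution (default 32).
#' @param reparam_amplitude amplitude of the random reparameterizations
#'   (default 0.3).
#' @param amplitude deformation scale of the planted direction (default 1).
#' @param config a [reg_config()] for the co-registration.
#' @param seed RNG seed.
#' @return List of accuracies `acc_registered`, `acc_registered_mds`,
#'   `acc_perturbed`, `acc_restored`, plus `restored_distance_correlation`
#'   between the clean and restored distance matrices.
#' @export
validate_line_simulation <- function(grid_n = 32, reparam_amplitude = 0.3,
                                     amplitude = 1, config = reg_config(),
                                     seed = 1) {
  g <- sphere_grid(grid_n, grid_n)
  mu <- base_surface(g, "ellipsoid")
  v1 <- mode_fields(g, mu, 1)[, 1]
  line <- simulate_pc_line(mu, v1, seed = seed, amplitude = amplitude)
  D0 <- pairwise_distance_matrix(line$surfaces, "raw")
  acc0 <- medoid_cluster_accuracy(D0, line$labels)$accuracy
  acc0m <- medoid_cluster_accuracy(classical_mds(D0, 2), line$labels)$accuracy
  pert <- lapply(seq_along(line$surfaces), function(i) {
    apply_reparam(line$surfaces[[i]],
                  random_diffeomorphism(g, reparam_amplitude,
                                        seed = seed + 100 + i))
  })
  Dp <- pairwise_distance_matrix(pert, "raw")
  accp <- medoid_cluster_accuracy(Dp, line$labels)$accuracy
  regd <- register_to_reference(pert, config = config)
  Dr <- pairwise_distance_matrix(regd, "raw")
  accr <- medoid_cluster_accuracy(Dr, line$labels)$accuracy
  Dc <- pairwise_distance_matrix(lapply(line$surfaces, center_and_scale),
                                 "raw")
  ut <- upper.tri(Dc)
  list(
    acc_registered = acc0, acc_registered_mds = acc0m,
    acc_perturbed = accp, acc_restored = accr,
    restored_distance_correlation = stats::cor(Dc[ut], Dr[ut])
  )
}

#' Karcher-mean behavior on controlled inputs
#'
#' (a) mean of identical surfaces; (b) monotone variance trace on a small
#' family; (c) same shape under two parameterizations: the converged Karcher
#' variance versus the unregistered Euclidean variance of the pair.
#'
#' @param grid_n grid resolution (default 24).
#' @param config a [reg_config()].
#' @param seed RNG seed.
#' @return List with `identical_mean_error`, `variance_monotone`,
#'   `variance_ratio` (Karcher variance / unregistered Euclidean variance).
#' @export
validate_karcher <- function(grid_n = 24, config = reg_config(), seed = 1) {
  g <- sphere_grid(grid_n, grid_n)
  f <- validation_pairs(g, 1, seed)[[1]]$f1
  km_id <- karcher_mean(list(f, f, f), config = reg_config(max_iter = 30))
  err_id <- sqrt(sum((field_as_matrix(km_id$mu$f) -
                        field_as_matrix(center_and_scale(f)$f))^2))
  fam <- generate_family(surface_family_spec(n = 6, seed = seed + 3), g)
  km_fam <- karcher_mean(fam$surfaces, config = reg_config(max_iter = 30),
                         max_iter = 5)
  frp <- center_and_scale(
    apply_reparam(f, random_diffeomorphism(g, 0.3, seed = seed + 7))
  )
  fn <- center_and_scale(f)
  fbar <- euclidean_mean_surface(list(fn, frp))
  v_unreg <- sum((field_as_matrix(fn$f) - field_as_matrix(fbar$f))^2) +
    sum((field_as_matrix(frp$f) - field_as_matrix(fbar$f))^2)
  km2 <- karcher_mean(list(fn, frp), config = config)
  list(
    identical_mean_error = err_id,
    variance_monotone = all(diff(km_fam$variance_trace) <= 0) &&
      all(diff(km2$variance_trace) <= 0),
    variance_ratio = tail(km2$variance_trace, 1) / v_unreg
  )
}

#' Shape-PCA validation on a planted three-mode family
#'
#' Generates a family with three orthonormal planted modes (energy ratio
#' 4:2:1), fits the Karcher mean + shape PCA on a training split, and
#' measures subspace recovery (principal angles), the cumulative-variance
#' curve, orthonormality, reconstruction monotonicity, and the held-out
#' train/test protocol.
#'
#' The family is generated pre-aligned, so (as in the line simulation) it is
#' treated as registered: the fit uses the plain mean and unregistered
#' scores, isolating the PCA machinery from elastic-registration
#' deformation.
#'
#' @param n number of surfaces (default 100).
#' @param grid_n grid resolution (default 32).
#' @param train_fraction training split (default 0.8).
#' @param config a [reg_config()] for the held-out registration check.
#' @param seed RNG seed.
#' @return List with `max_principal_angle_deg`, `cumvar1`,
#'   `gram_error`, `roundtrip_error`, `monotone_reconstruction`,
#'   `heldout_mean_error`.
#' @export
validate_pca <- function(n = 100, grid_n = 32, train_fraction = 0.8,
                         config = reg_config(max_iter = 30), seed = 1) {
  g <- sphere_grid(grid_n, grid_n)
  fam <- generate_family(
    surface_family_spec(n = n, n_modes = 3,
                        mode_sd = 0.02 * c(2, sqrt(2), 1), seed = seed), g
  )
  set.seed(seed)
  n_train <- round(train_fraction * n)
  idx <- sample.int(n, n_train)
  train <- fam$surfaces[idx]
  test <- fam$surfaces[setdiff(seq_len(n), idx)]
  km <- karcher_mean(train, register = FALSE)
  basis <- shape_pca(km)
  U3 <- basis$directions[, 1:3, drop = FALSE]
  sv <- svd(crossprod(U3, fam$modes))$d
  angles <- acos(pmin(pmax(sv, -1), 1)) * 180 / pi
  cv <- cumulative_variance(basis)
  G <- crossprod(basis$directions)
  gram_err <- max(abs(G - diag(ncol(G))))
  z_full <- principal_scores(km$registered[[1]], basis)
  rt_err <- sqrt(sum((field_as_matrix(reconstruct(basis, z_full)$f) -
                        field_as_matrix(km$registered[[1]]$f))^2))
  errs <- vapply(0:min(10, ncol(basis$directions)), function(k) {
    rec <- reconstruct(basis, z_full[seq_len(k)])
    sqrt(sum((field_as_matrix(rec$f) -
                field_as_matrix(km$registered[[1]]$f))^2))
  }, numeric(1))
  heldout <- vapply(test, function(s) {
    s <- center_and_scale(s)
    z <- principal_scores(s, basis, k = 3)
    rec <- reconstruct(basis, z)
    sqrt(sum((field_as_matrix(rec$f) - field_as_matrix(s$f))^2))
  }, numeric(1))
  list(
    max_principal_angle_deg = max(angles),
    cumvar1 = cv[1],
    gram_error = gram_err,
    roundtrip_error = rt_err,
    monotone_reconstruction = all(diff(errs) <= 1e-10),
    heldout_mean_error = mean(heldout)
  )
}

#' Regression-layer validation on planted clinical tables
#'
#' Monte-Carlo checks of the clinical modeling stack: OLS confidence-interval
#' coverage for planted coefficients, stepwise recovery of strong predictors
#' and null-design behavior, the nested adjusted-R^2 ordering when
#' interactions are planted, and the irrelevant-ICV stability of the
#' stepwise-selected models.
#'
#' @param n_seeds Monte-Carlo replicates (default 100).
#' @param seed base RNG seed.
#' @return List with `coverage_min` (worst per-coefficient CI coverage),
#'   `stepwise_recovery`, `null_rate`, `ordering_holds`,
#'   `adj_r2_interactions`, `adj_r2_main`, `adj_r2_covariates`,
#'   `icv_delta` (|adjusted R^2 difference| of stepwise models with/without
#'   ICV, percentage points).
#' @export
validate_regression <- function(n_seeds = 100, seed = 1) {
  betas <- c(2.5, -2, 1.5, 0.06, -0.05)
  cover <- matrix(0L, n_seeds, 5)
  for (r in seq_len(n_seeds)) {
    set.seed(seed + 2000 + r)
    n <- 200
    scores <- list(hippocampus = matrix(rnorm(n * 3), n))
    coefs <- data.frame(
      outcome = rep("PSS", 6),
      term = c("(Intercept)", "hippocampus_PS1", "hippocampus_PS2",
               "hippocampus_PS3", "hippocampus_PS1:age",
               "hippocampus_PS2:BDI"),
      beta = c(18, betas)
    )
    tab <- simulate_clinical(scores, coefs, noise_sd = 2,
                             seed = seed + 2000 + r)
    X <- data.frame(
      z1 = tab$hippocampus_PS1, z2 = tab$hippocampus_PS2,
      z3 = tab$hippocampus_PS3,
      z1a = tab$hippocampus_PS1 * tab$age,
      z2b = tab$hippocampus_PS2 * tab$BDI
    )
    ci <- stats::confint(lm(tab$PSS ~ ., data = X))[-1, , drop = FALSE]
    cover[r, ] <- as.integer(ci[, 1] <= betas & betas <= ci[, 2])
  }
  coverage <- colMeans(cover)

  rec_hits <- 0L
  for (r in seq_len(n_seeds)) {
    set.seed(seed + 3000 + r)
    n <- 300
    X <- data.frame(matrix(rnorm(n * 23), n))
    names(X) <- paste0("p", 1:23)
    y <- 3 * X$p1 - 3 * X$p2 + 3 * X$p3 + rnorm(n)
    sel <- stepwise_select(X, y)
    if (all(c("p1", "p2", "p3") %in% sel$selected_terms)) {
      rec_hits <- rec_hits + 1L
    }
  }

  null_hits <- 0L
  for (r in seq_len(n_seeds)) {
    set.seed(seed + 4000 + r)
    X <- data.frame(matrix(rnorm(200 * 5), 200))
    sel <- stepwise_select(X, rnorm(200))
    if (length(sel$selected_terms) <= 1) null_hits <- null_hits + 1L
  }

  # nested ordering and ICV stability on planted-interaction tables
  ordering <- logical(3)
  adj <- c(NA_real_, NA_real_, NA_real_)
  icv_delta <- NA_real_
  for (r in 1:3) {
    tab <- planted_interaction_table(n = 200, seed = seed + 5000 + r)
    a1 <- fit_ols(build_design(tab, model_spec(1)))$adjusted_r2
    a2 <- fit_ols(build_design(tab, model_spec(2)))$adjusted_r2
    a3 <- fit_ols(build_design(tab, model_spec(3)))$adjusted_r2
    ordering[r] <- a1 > a2 && a2 > a3
    if (r == 1) {
      adj <- c(a1, a2, a3)
      s1 <- stepwise_select(build_design(tab, model_spec(1)))
      s9 <- stepwise_select(build_design(tab, model_spec(9)))
      icv_delta <- abs(s1$adjusted_r2 - s9$adjusted_r2) * 100
    }
  }

  list(
    coverage_min = min(coverage), coverage = coverage,
    stepwise_recovery = rec_hits / n_seeds,
    null_rate = null_hits / n_seeds,
    ordering_holds = all(ordering),
    adj_r2_interactions = adj[1] * 100,
    adj_r2_main = adj[2] * 100,
    adj_r2_covariates = adj[3] * 100,
    icv_delta = icv_delta
  )
}

planted_interaction_table <- function(n = 200, seed = 1) {
  set.seed(seed)
  scores <- list(
    hippocampus = matrix(rnorm(n * 15), n),
    amygdala = matrix(rnorm(n * 15), n),
    putamen = matrix(rnorm(n * 15), n)
  )
  coefs <- data.frame(
    outcome = "PSS",
    term = c("(Intercept)", "age", "BDI", "hippocampus_PS1", "amygdala_PS2",
             "putamen_PS1", "hippocampus_PS1:age", "amygdala_PS1:BDI",
             "putamen_PS2:age"),
    beta = c(6, 0.1, 0.25, 2.5, -2, 2, 0.1, 0.15, -0.08)
  )
  coefs <- rbind(coefs, data.frame(outcome = "CTQTOT",
                                   term = "(Intercept)", beta = 70))
  simulate_clinical(scores, coefs, noise_sd = 3, seed = seed)
}

#' Geometry oracles
#'
#' Sphere area against the analytic value, a smooth ellipsoid-like surface
#' against a fine triangulated-mesh oracle, and the exact SRNF norm-area
#' identity.
#'
#' @param grid_n grid resolution (default 64).
#' @return List with `sphere_area_rel_err`, `mesh_oracle_rel_err`,
#'   `norm_identity_gap`.
#' @export
validate_geometry <- function(grid_n = 64) {
  g <- sphere_grid(grid_n, grid_n)
  P <- grid_directions(g)
  sph <- grid_surface(P, g, "unit sphere")
  sphere_err <- abs(surface_area(sph) - 4 * pi) / (4 * pi)
  shape <- function(V) {
    r <- 1 + 0.2 * V[, 1] * V[, 3]
    cbind(1.3 * r * V[, 1], 0.8 * r * V[, 2], 1.1 * r * V[, 3])
  }
  surf <- grid_surface(shape(P), g, "bumpy ellipsoid")
  oracle <- mesh_area(icosphere(4, transform = shape))
  mesh_err <- abs(surface_area(surf) - oracle) / oracle
  q <- srnf(surf)
  gap <- abs(srnf_norm(q)^2 - surface_area(surf))
  list(sphere_area_rel_err = sphere_err, mesh_oracle_rel_err = mesh_err,
       norm_identity_gap = gap)
}
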