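small_family <- function(n = 8, seed = 2, grid = sphere_grid(16, 16),
                         n_modes = 2) {
  generate_family(surface_family_spec(n = n, seed = seed, n_modes = n_modes),
                  grid)
}

fast_cfg <- reg_config(max_iter = 30, tol = 1e-5)

test_that("geodesic path endpoints and degenerate case", {
  g <- sphere_grid(16, 16)
  fam <- small_family(grid = g)
  f1 <- fam$surfaces[[1]]
  f2 <- fam$surfaces[[2]]
  gp <- geodesic_path(f1, f2, m = 5, config = fast_cfg)
  expect_length(gp$steps, 5)
  expect_lt(vec_distance(gp$steps[[1]], center_and_scale(f1)), 1e-10)
  expect_lt(vec_distance(gp$steps[[5]], gp$registration$registered_surface), 1e-10)
  # f2 = f1: all steps equal f1
  gp0 <- geodesic_path(f1, f1, m = 4, config = fast_cfg)
  for (s in gp0$steps) expect_lt(vec_distance(s, center_and_scale(f1)), 1e-6)
})

test_that("registered geodesic between reparameterized bent tubes stays local", {
  g <- sphere_grid(24, 24)
  f1 <- base_surface(g, "bent_tube", bend = 0.4)
  f2raw <- base_surface(g, "bent_tube", bend = 0.7)
  dif <- random_diffeomorphism(g, 0.3, seed = 9)
  f2 <- center_and_scale(apply_reparam(f2raw, dif))
  unreg <- geodesic_path(f1, f2, m = 3, register = FALSE)
  reg <- geodesic_path(f1, f2, m = 3, config = reg_config(max_iter = 100))
  max_disp <- function(gp) {
    d <- gp$steps[[1]]$f - gp$steps[[length(gp$steps)]]$f
    max(sqrt(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2))
  }
  expect_lt(max_disp(reg), max_disp(unreg))
  # midpoint has sane area (no degenerate pinch)
  a_mid <- surface_area(reg$steps[[2]])
  expect_gt(a_mid, 0.5)
  expect_lt(a_mid, 2)
})

test_that("Karcher mean: identical inputs, single input, monotone variance", {
  g <- sphere_grid(16, 16)
  f <- center_and_scale(bumpy_ellipsoid_surface(g))
  km1 <- karcher_mean(list(f), config = fast_cfg)
  expect_lt(vec_distance(km1$mu, f), 1e-8)
  km <- karcher_mean(list(f, f, f), config = fast_cfg)
  expect_lt(vec_distance(km$mu, f), 1e-6)
  expect_lt(tail(km$variance_trace, 1), 1e-10)
  fam <- small_family()
  km2 <- karcher_mean(fam$surfaces, config = fast_cfg, max_iter = 5)
  expect_true(all(diff(km2$variance_trace) <= 0))
  expect_length(km2$registered, length(fam$surfaces))
})

test_that("same shape under different parameterizations averages correctly", {
  g <- sphere_grid(24, 24)
  f <- center_and_scale(bumpy_ellipsoid_surface(g))
  frp <- center_and_scale(apply_reparam(f, random_diffeomorphism(g, 0.3, seed = 4)))
  # unregistered Euclidean variance of the pair
  fbar <- euclidean_mean_surface(list(f, frp))
  v_unreg <- vec_distance(f, fbar)^2 + vec_distance(frp, fbar)^2
  km <- karcher_mean(list(f, frp), config = reg_config(max_iter = 150))
  expect_lt(tail(km$variance_trace, 1), 0.01 * v_unreg)
})

test_that("shape PCA recovers a planted single mode and is orthonormal", {
  g <- sphere_grid(16, 16)
  fam <- generate_family(surface_family_spec(n = 12, seed = 5, n_modes = 1),
                         g)
  # the family is generated aligned: feed it to shape_pca directly (planted
  # one-mode model oracle, independent of the registration pipeline)
  km <- list(mu = euclidean_mean_surface(fam$surfaces),
             registered = fam$surfaces)
  basis <- shape_pca(km)
  G <- crossprod(basis$directions)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  expect_true(all(diff(basis$singular_values) <= 1e-12))
  cosang <- abs(sum(basis$directions[, 1] * fam$modes[, 1]))
  expect_gt(cosang, 0.999)
  expect_gt(basis$singular_values[1] / sum(basis$singular_values), 0.95)
  # degenerate family: all surfaces identical
  f <- fam$surfaces[[1]]
  km0 <- karcher_mean(list(f, f, f), config = fast_cfg)
  b0 <- shape_pca(km0)
  expect_equal(ncol(b0$directions), 0)
})

test_that("cumulative variance arithmetic and monotonicity", {
  expect_equal(cumulative_variance(c(3, 1)), c(0.75, 1))
  set.seed(1)
  sv <- sort(rexp(7), decreasing = TRUE)
  cv <- cumulative_variance(sv)
  expect_true(all(diff(cv) >= 0))
  expect_equal(tail(cv, 1), 1)
  expect_error(cumulative_variance(numeric(0)))
})

test_that("principal scores and reconstruction invert each other", {
  g <- sphere_grid(16, 16)
  fam <- small_family(n = 10, seed = 8, n_modes = 3)
  km <- karcher_mean(fam$surfaces, config = fast_cfg, max_iter = 3)
  basis <- shape_pca(km)
  # f = mu -> zero scores; mu + 2 U1 -> scores (2, 0, ...)
  expect_lt(max(abs(principal_scores(km$mu, basis))), 1e-8)
  f_off <- reconstruct(basis, c(2))
  z <- principal_scores(f_off, basis)
  expect_equal(unname(z[1]), 2, tolerance = 1e-8)
  expect_lt(max(abs(z[-1])), 1e-8)
  # training scores have zero column means
  sc <- t(vapply(km$registered, function(s) principal_scores(s, basis),
                 numeric(ncol(basis$directions))))
  expect_lt(max(abs(colMeans(sc))), 1e-8)
  # full-rank round trip on a training surface
  i <- 3
  rec <- reconstruct(basis, principal_scores(km$registered[[i]], basis))
  expect_lt(vec_distance(km$registered[[i]], rec), 1e-6)
  # reconstruction error is non-increasing in k for every surface
  for (i in c(1, 5)) {
    errs <- vapply(0:ncol(basis$directions), function(k) {
      z <- principal_scores(km$registered[[i]], basis)
      rec <- reconstruct(basis, z[seq_len(k)])
      vec_distance(km$registered[[i]], rec)
    }, numeric(1))
    expect_true(all(diff(errs) <= 1e-10))
  }
  expect_error(principal_scores(km$mu, basis, k = 100))
})

test_that("deformation colormap normalizes and localizes", {
  g <- sphere_grid(16, 16)
  f <- center_and_scale(bumpy_ellipsoid_surface(g))
  expect_true(all(deformation_colormap(f, f) == 0))
  # localized bump: argmax of the field lands in the bumped patch
  f2 <- f
  idx <- c(8, 5)
  f2$f[idx[1], idx[2], ] <- f2$f[idx[1], idx[2], ] + 0.2
  cm <- deformation_colormap(f2, f, normalize_over = list(f2))
  expect_equal(max(cm), 1)
  expect_equal(which(cm == 1, arr.ind = TRUE)[1, ], c(row = 8, col = 5))
  expect_error(deformation_colormap(f2, f, normalize_over = list()))
})

test_that("eshape_pca model object: methods are consistent", {
  g <- sphere_grid(16, 16)
  fam <- small_family(n = 10, seed = 3, n_modes = 2)
  fit <- eshape_pca(fam$surfaces, k = 3, config = fast_cfg, max_iter = 3)
  expect_s3_class(fit, "eshape_pca")
  expect_output(print(fit), "eshape_pca")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.eshape_pca")
  expect_equal(dim(coef(fit)), c(10, ncol(fit$basis$directions)))
  # predict on training surfaces without re-registration == stored scores
  z <- predict(fit, fit$karcher_mean$registered[3], register = FALSE)
  expect_equal(unname(drop(z)), unname(fit$scores[3, seq_len(fit$k)]),
               tolerance = 1e-10)
  res <- residuals(fit)
  expect_length(res, 10)
  expect_true(all(res >= 0))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "grid_surface")
  # train/test protocol: fit on 8, score and reconstruct 2 held out
  train <- fam$surfaces[1:8]
  test <- fam$surfaces[9:10]
  fit_tr <- eshape_pca(train, config = fast_cfg, max_iter = 3)
  z_te <- predict(fit_tr, test, k = 3, register = TRUE)
  expect_equal(dim(z_te), c(2, 3))
  rec <- reconstruct(fit_tr$basis, z_te[1, ])
  expect_s3_class(rec, "grid_surface")
})
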