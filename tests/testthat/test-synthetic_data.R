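test_that("surface family generator is seeded, normalized and degenerate-safe", {
  g <- sphere_grid(16, 16)
  spec <- surface_family_spec(n = 5, seed = 42, n_modes = 2)
  fam1 <- generate_family(spec, g)
  fam2 <- generate_family(spec, g)
  expect_identical(fam1$scores, fam2$scores)
  expect_identical(fam1$surfaces[[3]]$f, fam2$surfaces[[3]]$f)
  for (s in fam1$surfaces) expect_equal(surface_area(s), 1, tolerance = 1e-8)
  # modes orthonormal in the vectorized Euclidean metric
  G <- crossprod(fam1$modes)
  expect_lt(max(abs(G - diag(2))), 1e-10)
  # n = 1, zero sds -> the base shape itself (after normalization)
  fam0 <- generate_family(
    surface_family_spec(n = 1, seed = 1, n_modes = 1, mode_sd = 0), g
  )
  expect_lt(vec_distance(fam0$surfaces[[1]], fam0$base_surface), 1e-10)
})

test_that("simulated line has the stated sign classes and exact collinearity", {
  g <- sphere_grid(16, 16)
  mu <- base_surface(g, "ellipsoid")
  v1 <- mode_fields(g, mu, 1)[, 1]
  line <- simulate_pc_line(mu, v1, seed = 7)
  expect_length(line$surfaces, 40)
  expect_equal(sum(line$x > 0 & line$x <= 1), 20)
  expect_equal(sum(line$x >= -1 & line$x < 0), 20)
  expect_identical(line$labels, rep(c(1L, -1L), each = 20L))
  D <- pairwise_distance_matrix(line$surfaces, "raw")
  expect_lt(max(abs(D - abs(outer(line$x, line$x, "-")))), 1e-10)
})

test_that("random diffeomorphisms are valid, seeded and area conserving", {
  g <- sphere_grid(24, 24)
  d1 <- random_diffeomorphism(g, 0.3, seed = 3)
  d2 <- random_diffeomorphism(g, 0.3, seed = 3)
  expect_identical(d1$gamma, d2$gamma)
  expect_gt(min(d1$jac_det), 0)
  # total area is conserved, with the discrete error shrinking under refinement
  err <- vapply(c(24, 48, 64), function(n) {
    gg <- sphere_grid(n, n)
    d <- random_diffeomorphism(gg, 0.3, seed = 3)
    abs(sum(d$jac_det * gg$quad_weights) - 4 * pi) / (4 * pi)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.01)
  # amplitude 0 with rotation disabled is the exact identity
  d0 <- random_diffeomorphism(g, 0, seed = 3, rotate = FALSE)
  expect_lt(max(abs(d0$gamma - elasurf:::grid_directions(g))), 1e-12)
})

test_that("clinical table respects ranges, seeds, and planted coefficients", {
  set.seed(10)
  n <- 120
  scores <- list(hippocampus = matrix(rnorm(n * 5), n),
                 amygdala = matrix(rnorm(n * 5), n))
  coefs <- data.frame(
    outcome = c("PSS", "PSS", "PSS", "CTQTOT"),
    term = c("(Intercept)", "hippocampus_PS1", "hippocampus_PS2:age",
             "(Intercept)"),
    beta = c(15, 3, 0.08, 70)
  )
  tab1 <- simulate_clinical(scores, coefs, noise_sd = 2, seed = 5)
  tab2 <- simulate_clinical(scores, coefs, noise_sd = 2, seed = 5)
  expect_identical(tab1, tab2)
  expect_true(all(tab1$age >= 18 & tab1$age <= 61))
  expect_true(all(tab1$BDI >= 0 & tab1$BDI <= 63))
  expect_true(all(tab1$PSS >= 0 & tab1$PSS <= 42))
  expect_true(all(tab1$CTQTOT >= 25 & tab1$CTQTOT <= 125))
  expect_true(all(tab1$ICV > 0))
  # zero coefficients, zero noise -> constant outcome at clipped intercept
  tab0 <- simulate_clinical(scores,
    data.frame(outcome = "PSS", term = "(Intercept)", beta = 50),
    noise_sd = 0, seed = 1
  )
  expect_true(all(tab0$PSS == 42))
  expect_error(simulate_clinical(scores,
    data.frame(outcome = "PSS", term = "missing_col", beta = 1)))
})

test_that("planted coefficients are recovered by OLS on the true design", {
  hits <- 0L
  n_rep <- 20
  betas <- c(2.5, -1.8, 0.06)
  for (r in seq_len(n_rep)) {
    set.seed(300 + r)
    n <- 200
    scores <- list(hippocampus = matrix(rnorm(n * 3), n))
    coefs <- data.frame(
      outcome = rep("PSS", 4),
      term = c("(Intercept)", "hippocampus_PS1", "hippocampus_PS2",
               "hippocampus_PS3:age"),
      beta = c(20, betas)
    )
    tab <- simulate_clinical(scores, coefs, noise_sd = 2, seed = 300 + r)
    X <- data.frame(
      z1 = tab$hippocampus_PS1, z2 = tab$hippocampus_PS2,
      z3a = tab$hippocampus_PS3 * tab$age
    )
    fit <- lm(tab$PSS ~ ., data = X)
    ci <- confint(fit)[-1, , drop = FALSE]
    if (all(ci[, 1] <= betas & betas <= ci[, 2])) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.8)
})
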