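make_clinical <- function(n = 200, seed = 1, noise_sd = 3,
                          with_interactions = TRUE) {
  set.seed(seed)
  scores <- list(
    hippocampus = matrix(rnorm(n * 15), n),
    amygdala = matrix(rnorm(n * 15), n),
    putamen = matrix(rnorm(n * 15), n)
  )
  terms <- data.frame(
    outcome = "PSS",
    term = c("(Intercept)", "age", "BDI", "hippocampus_PS1", "amygdala_PS2",
             "putamen_PS1"),
    beta = c(8, 0.12, 0.25, 3, -2.5, 2)
  )
  if (with_interactions) {
    terms <- rbind(terms, data.frame(
      outcome = "PSS",
      term = c("hippocampus_PS1:age", "amygdala_PS1:BDI"),
      beta = c(0.09, 0.12)
    ))
  }
  ct <- rbind(terms, data.frame(outcome = "CTQTOT",
                                term = "(Intercept)", beta = 70))
  simulate_clinical(scores, ct, noise_sd = noise_sd, seed = seed)
}

test_that("model specifications match the ten clinical designs", {
  expect_identical(model_spec(3)$terms, c("age", "BDI"))
  expect_identical(model_spec(3)$outcome, "PSS")
  expect_identical(model_spec(7)$outcome, "CTQTOT")
  expect_length(model_spec(4)$terms, 45)   # 15 scores x 3 structures
  m1 <- model_spec(1)$terms
  m2 <- model_spec(2)$terms
  expect_true(all(m2 %in% m1))
  expect_length(setdiff(m1, m2), 30)       # 2 x 5 x 3 interaction columns
  expect_identical(setdiff(model_spec(9)$terms, m1), "ICV")
  expect_identical(model_spec(10)$outcome, "CTQTOT")
  expect_error(model_spec(11))
})

test_that("design construction: columns, products, missing data", {
  tab <- make_clinical(n = 60)
  d3 <- build_design(tab, model_spec(3))
  expect_identical(names(d3$X), c("age", "BDI"))
  d4 <- build_design(tab, model_spec(4))
  expect_equal(ncol(d4$X), 45)
  d1 <- build_design(tab, model_spec(1), standardize = FALSE)
  expect_equal(ncol(d1$X), 2 + 45 + 30)
  # interaction column is the elementwise product
  expect_equal(d1$X[["hippocampus_PS1_x_age"]],
               tab$hippocampus_PS1 * tab$age)
  tab_bad <- tab
  tab_bad$age[5] <- NA
  expect_error(build_design(tab_bad, model_spec(3)), "S005")
  expect_error(build_design(tab[, 1:4], model_spec(4)), "missing columns")
})

test_that("OLS fit: exact fit, adjusted R^2 identity, aliased columns", {
  set.seed(2)
  n <- 80
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- 2 + 3 * X$a - X$b
  fit <- suppressWarnings(fit_ols(X, y))  # exact fit: summary.lm warns
  expect_gt(fit$adjusted_r2, 1 - 1e-10)
  expect_lt(max(abs(stats::residuals(fit$lm))), 1e-8)
  # identity on a noisy fit
  y2 <- y + rnorm(n)
  fit2 <- fit_ols(X, y2)
  expect_equal(fit2$adjusted_r2,
               1 - (1 - fit2$r2) * (fit2$n - 1) / (fit2$n - fit2$p - 1),
               tolerance = 1e-12)
  expect_lte(fit2$adjusted_r2, fit2$r2)
  expect_true(all(fit2$p_values >= 0 & fit2$p_values <= 1))
  # duplicated column is dropped with a warning
  X3 <- cbind(X, a2 = X$a)
  expect_warning(fit_ols(X3, y2), "aliased")
  expect_error(fit_ols(data.frame(a = 1:4, b = c(1, 2, 4, 8), c = rnorm(4)),
                       1:4), "n > p")
})

test_that("null-outcome fits give near-zero adjusted R^2 on average", {
  vals <- vapply(1:30, function(s) {
    set.seed(s)
    X <- data.frame(matrix(rnorm(200 * 5), 200))
    fit_ols(X, rnorm(200))$adjusted_r2
  }, numeric(1))
  expect_gt(mean(vals), -0.05)
  expect_lt(mean(vals), 0.05)
})

test_that("planted interactions produce the nested adjusted-R^2 ordering", {
  tab <- make_clinical(n = 250, seed = 4)
  a1 <- fit_ols(build_design(tab, model_spec(1)))$adjusted_r2
  a2 <- fit_ols(build_design(tab, model_spec(2)))$adjusted_r2
  a3 <- fit_ols(build_design(tab, model_spec(3)))$adjusted_r2
  expect_gt(a1, a2)
  expect_gt(a2, a3)
})

test_that("stepwise selection: forced pick, recovery, null behavior, determinism", {
  set.seed(5)
  n <- 300
  X <- data.frame(matrix(rnorm(n * 10), n))
  names(X) <- paste0("p", 1:10)
  y <- 5 * X$p3 + rnorm(n)
  sel <- stepwise_select(X, y)
  expect_true("p3" %in% sel$selected_terms)
  sel_b <- stepwise_select(X, y)
  expect_identical(sel$selected_terms, sel_b$selected_terms)
  # p-value variant agrees on the strong predictor
  sel_p <- stepwise_select(X, y, criterion = "pvalue")
  expect_true("p3" %in% sel_p$selected_terms)
  # recovery of 3 strong among 20 nulls
  hits <- 0L
  for (s in 1:10) {
    set.seed(400 + s)
    X <- data.frame(matrix(rnorm(n * 23), n))
    names(X) <- paste0("p", 1:23)
    y <- 3 * X$p1 - 3 * X$p2 + 3 * X$p3 + rnorm(n)
    sel <- stepwise_select(X, y)
    if (all(c("p1", "p2", "p3") %in% sel$selected_terms)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
  # pure-noise designs come back (near) empty most of the time
  empty <- 0L
  for (s in 1:20) {
    set.seed(500 + s)
    X <- data.frame(matrix(rnorm(200 * 5), 200))
    y <- rnorm(200)
    sel <- stepwise_select(X, y)
    if (length(sel$selected_terms) == 0) empty <- empty + 1L
  }
  expect_gte(empty / 20, 0.75)
})

test_that("distance matrices are symmetric with zero diagonal; elastic <= raw scale", {
  g <- sphere_grid(16, 16)
  fam <- generate_family(surface_family_spec(n = 4, seed = 6), g)
  D <- pairwise_distance_matrix(fam$surfaces, "raw")
  expect_true(isSymmetric(unname(unclass(D))))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0))
  # identical surfaces -> zero matrix
  D0 <- pairwise_distance_matrix(rep(fam$surfaces[1], 3), "raw")
  expect_true(all(D0 == 0))
  suppressMessages({
    De <- pairwise_distance_matrix(fam$surfaces[1:3], "elastic",
                                   config = reg_config(max_iter = 20))
  })
  expect_true(isSymmetric(unname(unclass(De))))
  expect_true(all(diag(De) == 0))
})

test_that("classical MDS reproduces exact line geometry and is centered", {
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  emb <- classical_mds(D, 1)
  gaps <- diff(sort(emb[, 1]))
  expect_equal(gaps, c(1, 1), tolerance = 1e-10)
  expect_lt(max(abs(colMeans(emb))), 1e-10)
  expect_warning(classical_mds(D, 3), "truncating")
})

test_that("2-medoid accuracy helper separates well-separated classes", {
  set.seed(8)
  x <- c(rnorm(15, -4), rnorm(15, 4))
  D <- as.matrix(dist(x))
  labels <- rep(c(1, 2), each = 15)
  expect_equal(medoid_cluster_accuracy(D, labels)$accuracy, 1)
})
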