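#' Geodesic deformation path between two surfaces
#'
#' Registers `f2` to `f1` elastically and linearly interpolates between `f1`
#' and the registered surface `f2*`:
#' `alpha_tau = (1 - tau) f1 + tau f2*`, `tau` on an `m`-point uniform grid.
#' The endpoints are exactly `f1` and `f2*`.
#'
#' @param f1,f2 [grid_surface()]s on a common grid.
#' @param m number of steps including endpoints (>= 2).
#' @param config a [reg_config()].
#' @param register if FALSE, interpolate without registration (for
#'   comparisons of registered vs unregistered paths).
#' @return An object of class `geodesic_path`: list of `m` surfaces and the
#'   registration result (if any).
#' @export
geodesic_path <- function(f1, f2, m = 5, config = reg_config(),
                          register = TRUE) {
  stopifnot(m >= 2)
  f1 <- center_and_scale(f1)
  f2 <- center_and_scale(f2)
  reg <- NULL
  f2s <- f2
  if (register) {
    reg <- register_pair(f1, f2, config, normalize = FALSE)
    f2s <- reg$registered_surface
  }
  tau <- seq(0, 1, length.out = m)
  a <- field_as_matrix(f1$f)
  b <- field_as_matrix(f2s$f)
  steps <- lapply(tau, function(t) {
    grid_surface((1 - t) * a + t * b, f1$grid,
                 sprintf("geodesic tau=%.3f", t))
  })
  structure(list(steps = steps, tau = tau, registration = reg),
            class = "geodesic_path")
}

#' @export
print.geodesic_path <- function(x, ...) {
  cat(sprintf("geodesic_path with %d steps%s\n", length(x$steps),
              if (is.null(x$registration)) " (unregistered)" else ""))
  invisible(x)
}

#' Nodewise Euclidean mean of surfaces (no registration)
#'
#' @param surfaces list of [grid_surface()]s on a common grid.
#' @return A [grid_surface()].
#' @export
euclidean_mean_surface <- function(surfaces) {
  g <- surfaces[[1]]$grid
  acc <- Reduce(`+`, lapply(surfaces, function(s) field_as_matrix(s$f)))
  grid_surface(acc / length(surfaces), g, "euclidean mean")
}

#' Karcher mean of a sample of surfaces
#'
#' Iterative mean-shape algorithm: starting from the first surface, each
#' iteration registers every surface to the current mean, replaces the mean
#' by the nodewise Euclidean average of the registered surfaces (renormalized
#' to unit area), and records the Karcher variance
#' `sum_i d_s(mu, f_i)^2`. Stops when the relative L2 change of the mean
#' falls below `tol` or after `max_iter` iterations.
#'
#' @param surfaces list of [grid_surface()]s on a common grid.
#' @param config a [reg_config()] passed to every registration.
#' @param tol relative-change stopping tolerance on the mean (default 1e-4).
#' @param max_iter maximum outer iterations (default 20).
#' @param register if FALSE, the surfaces are treated as already registered
#'   (the convention for pre-aligned simulated families): the mean is their
#'   plain average and distances are unoptimized SRNF distances.
#' @return An object of class `karcher_mean`: `mu`, `registered` (list, same
#'   order and length as input), `distances` (final d_s to the mean),
#'   `variance_trace` and `iterations`.
#' @export
karcher_mean <- function(surfaces, config = reg_config(), tol = 1e-4,
                         max_iter = 20, register = TRUE) {
  stopifnot(length(surfaces) >= 1)
  g <- surfaces[[1]]$grid
  surfaces <- lapply(surfaces, center_and_scale)
  if (!register) {
    mu <- euclidean_mean_surface(surfaces)
    qmu <- srnf(center_and_scale(mu))
    distances <- vapply(surfaces, function(s) {
      preshape_distance(qmu, srnf(s))
    }, numeric(1))
    mu$provenance <- "karcher mean"
    return(structure(
      list(mu = mu, registered = surfaces, distances = distances,
           variance_trace = sum(distances^2), iterations = 1L),
      class = "karcher_mean"
    ))
  }
  mu <- surfaces[[1]]
  n <- length(surfaces)
  variance_trace <- numeric(0)
  registered <- surfaces
  distances <- numeric(n)
  iterations <- 0L
  best <- NULL
  for (iter in seq_len(max_iter)) {
    iterations <- iter
    for (i in seq_len(n)) {
      reg <- tryCatch(
        register_pair(mu, surfaces[[i]], config, normalize = FALSE),
        error = function(e) {
          warning(sprintf(
            "karcher_mean: registration of surface %d failed (%s); using identity",
            i, conditionMessage(e)
          ))
          NULL
        }
      )
      if (is.null(reg)) {
        registered[[i]] <- surfaces[[i]]
        distances[i] <- preshape_distance(srnf(mu), srnf(surfaces[[i]]))
      } else {
        registered[[i]] <- reg$registered_surface
        distances[i] <- reg$distance
      }
    }
    v <- sum(distances^2)
    if (length(variance_trace) && v > tail(variance_trace, 1)) {
      # no further improvement: keep the previous (better) state so the
      # variance trace is honestly non-increasing, and stop
      registered <- best$registered
      distances <- best$distances
      mu <- best$mu
      iterations <- iter - 1L
      break
    }
    variance_trace <- c(variance_trace, v)
    best <- list(registered = registered, distances = distances, mu = mu)
    mu_new <- center_and_scale(euclidean_mean_surface(registered))
    delta <- sqrt(sum((field_as_matrix(mu_new$f) - field_as_matrix(mu$f))^2)) /
      max(sqrt(sum(field_as_matrix(mu$f)^2)), 1e-12)
    mu <- mu_new
    if (delta < tol) break
  }
  # the returned mean is the plain nodewise average of the final registered
  # set (the Karcher-mean update itself); the unit-area renormalized version
  # is only used as the registration target between iterations
  mu <- euclidean_mean_surface(registered)
  mu$provenance <- "karcher mean"
  structure(
    list(
      mu = mu, registered = registered, distances = distances,
      variance_trace = variance_trace, iterations = iterations
    ),
    class = "karcher_mean"
  )
}

#' @export
print.karcher_mean <- function(x, ...) {
  cat(sprintf(
    "karcher_mean of %d surfaces: %d iterations, Karcher variance %.4g\n",
    length(x$registered), x$iterations, tail(x$variance_trace, 1)
  ))
  invisible(x)
}

#' Shape PCA about a Karcher mean
#'
#' Builds the centered data matrix with rows `V_i = vec(f_i* - mu)` (the
#' registered surfaces about the mean, plain Euclidean vectorization) and
#' takes its thin SVD; the squared singular values of the data matrix are the
#' singular values of the covariance `C = sum_i V_i V_i^T`, which is never
#' formed explicitly. Directions are orthonormal; each direction's sign is
#' fixed so its largest-magnitude entry is positive.
#'
#' @param mean a [karcher_mean()] (or a list with `mu` and `registered`).
#' @return An object of class `shape_pca_basis`: `mu`, `directions` (columns,
#'   one per retained non-null component), `singular_values` (of C,
#'   descending), `n_train`, `grid`.
#' @export
shape_pca <- function(mean) {
  stopifnot(!is.null(mean$mu), length(mean$registered) >= 1)
  mu <- mean$mu
  g <- mu$grid
  vmu <- as.vector(field_as_matrix(mu$f))
  X <- t(vapply(mean$registered, function(s) {
    as.vector(field_as_matrix(s$f)) - vmu
  }, numeric(length(vmu))))
  sv <- svd(X, nu = 0)
  tot <- sum(sv$d^2)
  keep <- sv$d^2 > tot * 1e-10 & sv$d^2 > 1e-20
  U <- sv$v[, keep, drop = FALSE]
  if (ncol(U) > 0) {
    for (k in seq_len(ncol(U))) {
      if (U[which.max(abs(U[, k])), k] < 0) U[, k] <- -U[, k]
    }
  }
  structure(
    list(
      mu = mu, directions = U, singular_values = sv$d[keep]^2,
      n_train = nrow(X), grid = g
    ),
    class = "shape_pca_basis"
  )
}

#' @export
print.shape_pca_basis <- function(x, ...) {
  cat(sprintf(
    "shape_pca_basis: %d components from %d surfaces; PC1 explains %.1f%%\n",
    ncol(x$directions), x$n_train,
    if (length(x$singular_values)) 100 * x$singular_values[1] / sum(x$singular_values) else NA
  ))
  invisible(x)
}

#' Cumulative proportion of total singular values
#'
#' `c_k = sum_{d<=k} sigma_d / sum_d sigma_d`, the shape-variability curve
#' used to choose how many principal components represent a structure.
#'
#' @param basis a [shape_pca_basis()] (or a vector of singular values).
#' @return Non-decreasing vector ending at 1.
#' @export
cumulative_variance <- function(basis) {
  sv <- if (is.numeric(basis)) basis else basis$singular_values
  if (length(sv) == 0 || sum(sv) <= 0) {
    stop("cumulative_variance: no positive singular values")
  }
  cumsum(sv) / sum(sv)
}

#' Principal scores of a surface under a shape-PCA basis
#'
#' `z_d = <vec(f - mu), U(:, d)>` for `d = 1..k`. The surface should already
#' be registered to the mean; set `register = TRUE` to run [register_pair()]
#' against the mean first (the package's convention for held-out surfaces).
#'
#' @param f a [grid_surface()].
#' @param basis a [shape_pca_basis()].
#' @param k number of components (default: all).
#' @param register elastically register `f` to the mean first.
#' @param config a [reg_config()] when registering.
#' @return Named numeric vector of scores (`PC1`..`PCk`).
#' @export
principal_scores <- function(f, basis, k = NULL, register = FALSE,
                             config = reg_config()) {
  if (is.null(k)) k <- ncol(basis$directions)
  if (k < 1 || k > ncol(basis$directions)) {
    stop("principal_scores: k out of range")
  }
  if (register) {
    f <- register_pair(basis$mu, f, config)$registered_surface
  }
  v <- as.vector(field_as_matrix(f$f)) -
    as.vector(field_as_matrix(basis$mu$f))
  z <- drop(crossprod(basis$directions[, seq_len(k), drop = FALSE], v))
  names(z) <- paste0("PC", seq_len(k))
  z
}

#' Reconstruct a surface from principal scores
#'
#' The inverse of [principal_scores()]:
#' `f_hat = mu + sum_d z_d U(:, d)`.
#'
#' @param basis a [shape_pca_basis()].
#' @param scores numeric vector of scores (length <= number of directions).
#' @return A [grid_surface()].
#' @export
reconstruct <- function(basis, scores) {
  k <- length(scores)
  if (k > ncol(basis$directions)) stop("reconstruct: too many scores")
  v <- as.vector(field_as_matrix(basis$mu$f))
  if (k > 0) {
    v <- v + as.vector(basis$directions[, seq_len(k), drop = FALSE] %*% scores)
  }
  grid_surface(matrix(v, ncol = 3), basis$grid, "reconstruction")
}

#' Patch-wise deformation color map
#'
#' For each grid cell, the area-weighted magnitude of `f - ref`, normalized
#' by the largest such value across `normalize_over`, so values lie in [0, 1]
#' with 1 marking the largest patch-wise difference in the collection and 0
#' no difference.
#'
#' @param f a [grid_surface()].
#' @param ref reference surface (e.g. the mean).
#' @param normalize_over list of surfaces defining the normalization (must be
#'   non-empty; typically includes `f`).
#' @return `nt x np` matrix in [0, 1].
#' @export
deformation_colormap <- function(f, ref, normalize_over = list(f)) {
  if (length(normalize_over) == 0) {
    stop("deformation_colormap: empty normalization collection")
  }
  g <- f$grid
  patch_field <- function(s) {
    d <- s$f - ref$f
    sqrt(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2) * g$quad_weights
  }
  mx <- max(vapply(normalize_over, function(s) max(patch_field(s)), numeric(1)))
  if (mx <= 0) {
    return(matrix(0, g$n_theta, g$n_phi))
  }
  patch_field(f) / mx
}
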