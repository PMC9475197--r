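#' Square-root normal field of a surface
#'
#' The SRNF transform `q(s) = n(s) / |n(s)|^(1/2)`, where `n = f_u x f_v` is
#' the unnormalized normal. The squared pointwise magnitude of `q` equals the
#' local area element, so the squared L2 norm of `q` equals the surface area;
#' translations of the surface leave `q` unchanged.
#'
#' @param surface a [grid_surface()].
#' @return An object of class `srnf_field` with elements `q` (array
#'   `nt x np x 3`), `grid`, `n_mag` and `source` (the surface provenance).
#' @export
srnf <- function(surface) {
  stopifnot(inherits(surface, "grid_surface"))
  g <- surface$grid
  out <- cpp_srnf(surface$f, g$n_theta, g$n_phi, g$dtheta, g$dphi)
  if (!all(is.finite(out$q))) stop("srnf: non-finite values in the SRNF field")
  structure(
    list(q = out$q, n_mag = out$n_mag, grid = g, source = surface$provenance),
    class = "srnf_field"
  )
}

#' @export
print.srnf_field <- function(x, ...) {
  cat(sprintf(
    "srnf_field on %d x %d grid, ||q||^2 = %.4g\n",
    x$grid$n_theta, x$grid$n_phi, srnf_inner(x$q, x$q, x$grid)
  ))
  invisible(x)
}

#' Sphere reparameterization (diffeomorphism)
#'
#' Represents a map gamma from the sphere to itself by its values at the grid
#' nodes (unit vectors), together with the colatitude/longitude angle fields
#' and the Jacobian determinant relative to the spherical area element.
#'
#' @param gamma `(nt*np) x 3` matrix of unit vectors (image of each node), or
#'   an `nt x np x 3` array.
#' @param grid the [sphere_grid()] the map is sampled on.
#' @return An object of class `sphere_diffeo` with `gamma`, `gamma_theta`,
#'   `gamma_phi`, `jac_det` and `grid`.
#' @export
sphere_diffeo <- function(gamma, grid) {
  if (is.array(gamma) && length(dim(gamma)) == 3L) gamma <- field_as_matrix(gamma)
  stopifnot(is.matrix(gamma), ncol(gamma) == 3L,
            nrow(gamma) == grid$n_theta * grid$n_phi)
  gamma <- gamma / sqrt(rowSums(gamma^2))
  J <- cpp_jacobian(gamma, grid$n_theta, grid$n_phi, grid$dtheta, grid$dphi,
                    grid$sin_theta)
  gz <- pmin(pmax(gamma[, 3], -1), 1)
  th <- acos(gz)
  ph <- atan2(gamma[, 2], gamma[, 1])
  ph <- ifelse(ph < 0, ph + 2 * pi, ph)
  structure(
    list(
      gamma = gamma,
      gamma_theta = matrix(th, grid$n_theta, grid$n_phi),
      gamma_phi = matrix(ph, grid$n_theta, grid$n_phi),
      jac_det = J, grid = grid
    ),
    class = "sphere_diffeo"
  )
}

#' @rdname sphere_diffeo
#' @export
identity_diffeo <- function(grid) sphere_diffeo(grid_directions(grid), grid)

#' @export
print.sphere_diffeo <- function(x, ...) {
  cat(sprintf(
    "sphere_diffeo on %d x %d grid: J in [%.3f, %.3f], int J dA = %.4f\n",
    x$grid$n_theta, x$grid$n_phi, min(x$jac_det), max(x$jac_det),
    sum(x$jac_det * x$grid$quad_weights)
  ))
  invisible(x)
}

#' Reparameterize a surface or an SRNF field
#'
#' `apply_reparam()` composes the surface with the diffeomorphism
#' (`f o gamma`, by spherical bilinear interpolation). `apply_reparam_srnf()`
#' applies the SRNF action `(q o gamma) * sqrt(J_gamma)`, which preserves the
#' L2 norm of `q`.
#'
#' @param surface a [grid_surface()].
#' @param diffeo a [sphere_diffeo()] on the same grid.
#' @return A reparameterized [grid_surface()] / `srnf_field`.
#' @export
apply_reparam <- function(surface, diffeo) {
  g <- surface$grid
  stopifnot(same_grid(g, diffeo$grid))
  if (min(diffeo$jac_det) <= 0) stop("apply_reparam: diffeo has non-positive Jacobian")
  vals <- cpp_interp_sphere(
    surface$f, as.vector(diffeo$gamma_theta), as.vector(diffeo$gamma_phi),
    g$n_theta, g$n_phi, g$dtheta, g$dphi
  )
  grid_surface(vals, g, surface$provenance)
}

#' @rdname apply_reparam
#' @param q an `srnf_field`.
#' @export
apply_reparam_srnf <- function(q, diffeo) {
  g <- q$grid
  stopifnot(same_grid(g, diffeo$grid))
  if (min(diffeo$jac_det) <= 0) stop("apply_reparam_srnf: diffeo has non-positive Jacobian")
  vals <- cpp_interp_sphere(
    q$q, as.vector(diffeo$gamma_theta), as.vector(diffeo$gamma_phi),
    g$n_theta, g$n_phi, g$dtheta, g$dphi
  )
  # parameter-coordinate Jacobian: J_par = J_sphere * sin(theta) / sin(theta(gamma))
  st_src <- matrix(g$sin_theta, g$n_theta, g$n_phi)
  st_tgt <- pmax(sin(diffeo$gamma_theta), 1e-12)
  jpar <- diffeo$jac_det * st_src / st_tgt
  sj <- sqrt(as.vector(jpar))
  qnew <- array(vals * sj, c(g$n_theta, g$n_phi, 3L))
  structure(list(q = qnew, n_mag = NULL, grid = g, source = q$source),
            class = "srnf_field")
}

# SRNF-space (parameter-measure) inner product and norm: the L2 structure in
# which ||q||^2 equals the surface area exactly.
srnf_inner <- function(a, b, grid) {
  sum(a[, , 1] * b[, , 1] + a[, , 2] * b[, , 2] + a[, , 3] * b[, , 3]) *
    grid$dtheta * grid$dphi
}

#' SRNF-space norm
#'
#' L2 norm of an SRNF field under the parameter measure, so that
#' `srnf_norm(srnf(f))^2 == surface_area(f)` exactly.
#'
#' @param q an `srnf_field`.
#' @return Non-negative scalar.
#' @export
srnf_norm <- function(q) sqrt(srnf_inner(q$q, q$q, q$grid))

param_weights <- function(g) matrix(g$dtheta * g$dphi, g$n_theta, g$n_phi)

#' Pre-shape (L2) distance between two SRNF fields
#'
#' @param q1,q2 `srnf_field`s on the same grid.
#' @return Non-negative scalar.
#' @export
preshape_distance <- function(q1, q2) {
  stopifnot(same_grid(q1$grid, q2$grid))
  d <- q1$q - q2$q
  sqrt(srnf_inner(d, d, q1$grid))
}

#' Optimal rotation between SRNF fields (Procrustes)
#'
#' Solves `argmin_O ||q1 - O q2||` over SO(3) via the SVD of the weighted
#' cross-covariance `A = sum_s w(s) q1(s) q2(s)^T`.
#'
#' @param q1,q2 `srnf_field`s on the same grid.
#' @return A 3 x 3 rotation matrix with `attr(., "distance")` the
#'   post-rotation distance.
#' @export
optimal_rotation <- function(q1, q2) {
  stopifnot(same_grid(q1$grid, q2$grid))
  g <- q1$grid
  w <- g$dtheta * g$dphi
  M1 <- field_as_matrix(q1$q)
  M2 <- field_as_matrix(q2$q)
  A <- w * (t(M1) %*% M2)
  s1 <- w * sum(M1^2)
  s2 <- w * sum(M2^2)
  res <- procrustes_from_cov(A, s1, s2)
  O <- res$O
  attr(O, "distance") <- sqrt(max(res$E, 0))
  O
}

# rotation and minimized energy from the 3x3 cross-covariance
procrustes_from_cov <- function(A, s1, s2) {
  sv <- svd(A)
  if (sv$d[1] < 1e-14 * max(s1, s2, 1)) {
    warning("optimal_rotation: rank-deficient cross-covariance; returning identity")
    return(list(O = diag(3), E = s1 + s2))
  }
  dsign <- sign(det(sv$u %*% t(sv$v)))
  if (dsign == 0) dsign <- 1
  trmax <- sv$d[1] + sv$d[2] + dsign * sv$d[3]
  O <- sv$u %*% diag(c(1, 1, dsign)) %*% t(sv$v)
  list(O = O, E = s1 + s2 - 2 * trmax)
}

# rotate surface coordinates: f -> O f
rotate_surface <- function(surface, O) {
  M <- field_as_matrix(surface$f) %*% t(O)
  grid_surface(M, surface$grid, surface$provenance)
}

#' Icosahedral rotation group
#'
#' The 60 rotational symmetries of the regular icosahedron, generated by
#' closure from a 5-fold vertex rotation and a 2-fold edge rotation. The
#' identity is element 1; ordering is deterministic.
#'
#' @return List of 60 rotation matrices.
#' @export
icosahedral_group <- function() {
  cached <- .elasurf_cache$ico_group
  if (!is.null(cached)) return(cached)
  gr <- (1 + sqrt(5)) / 2
  axis_rot <- function(axis, ang) {
    a <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  }
  g1 <- axis_rot(c(0, 1, gr), 2 * pi / 5)   # vertex (5-fold) axis
  g2 <- axis_rot(c(0, 0, 1), pi)            # edge (2-fold) axis
  key <- function(M) paste(round(M, 8), collapse = ",")
  elems <- list(diag(3))
  names(elems) <- key(diag(3))
  repeat {
    added <- FALSE
    for (e in elems) for (g in list(g1, g2)) {
      M <- g %*% e
      k <- key(M)
      if (is.null(elems[[k]])) {
        elems[[k]] <- M
        added <- TRUE
      }
    }
    if (!added) break
  }
  stopifnot(length(elems) == 60L)
  mats <- unname(elems)
  idmat <- diag(3)
  d_id <- vapply(mats, function(M) sum((M - idmat)^2), numeric(1))
  keys <- vapply(mats, key, character(1))
  ord <- order(round(d_id, 10), keys)
  mats <- mats[ord]
  .elasurf_cache$ico_group <- mats
  mats
}

.elasurf_cache <- new.env(parent = emptyenv())

#' Registration configuration
#'
#' @param harmonic_degree maximum degree of the tangent-field basis (default 4).
#' @param max_iter outer gradient-descent iterations (default 300).
#' @param tol relative energy-decrease stopping tolerance (default 1e-6).
#' @param coarse run the 60-element icosahedral coarse search first (default TRUE).
#' @param step0 initial line-search step in radians (default 0.1).
#' @param max_halvings line-search halvings per iteration (default 20).
#' @param grad_eps finite-difference step for the energy gradient (default 1e-4).
#' @return A list of class `reg_config`.
#' @export
reg_config <- function(harmonic_degree = 4, max_iter = 300, tol = 1e-6,
                       coarse = TRUE, step0 = 0.1, max_halvings = 20,
                       grad_eps = 1e-4) {
  structure(
    list(
      harmonic_degree = harmonic_degree, max_iter = max_iter, tol = tol,
      coarse = coarse, step0 = step0, max_halvings = max_halvings,
      grad_eps = grad_eps
    ),
    class = "reg_config"
  )
}

# registration energy of a candidate gamma: E = min_O ||q1 - O srnf(f2 o gamma)||^2
reg_energy <- function(f2arr, gamma, q1arr, g, s1, return_f = FALSE) {
  parts <- cpp_reg_parts(
    f2arr, gamma, q1arr, param_weights(g),
    g$n_theta, g$n_phi, g$dtheta, g$dphi, return_f
  )
  pr <- procrustes_from_cov(parts$A, s1, parts$s2)
  list(E = max(pr$E, 0), O = pr$O, f2g = if (return_f) parts$f2g else NULL)
}

#' Coarse search over pole placements
#'
#' Evaluates the registration energy for each of the 60 icosahedral domain
#' rotations of the moving surface (each with its own Procrustes rotation) and
#' returns the winner as a rigid [sphere_diffeo()] (`J == 1`). Ties go to the
#' lowest group-element index (identity first).
#'
#' @param f1 fixed [grid_surface()] (normalized).
#' @param f2 moving [grid_surface()] (normalized, same grid).
#' @return A [sphere_diffeo()] with attributes `energy` (winning energy) and
#'   `energies` (all 60 values).
#' @export
coarse_domain_search <- function(f1, f2) {
  g <- f1$grid
  stopifnot(same_grid(g, f2$grid))
  q1 <- srnf(f1)
  s1 <- srnf_inner(q1$q, q1$q, g)
  P <- grid_directions(g)
  group <- icosahedral_group()
  w <- param_weights(g)
  energies <- vapply(group, function(R) {
    cpp_reg_energy(f2$f, P %*% t(R), q1$q, w,
                   g$n_theta, g$n_phi, g$dtheta, g$dphi, s1)
  }, numeric(1))
  # ties (within numerical noise) go to the lowest group-element index
  best <- which(energies <= min(energies) + 1e-10 * max(s1, 1))[1]
  d <- sphere_diffeo(P %*% t(group[[best]]), g)
  attr(d, "energy") <- energies[best]
  attr(d, "energies") <- energies
  attr(d, "element") <- best
  d
}

#' Gradient descent over sphere reparameterizations
#'
#' Minimizes the registration energy
#' `E(gamma) = min_O ||q1 - O srnf(f2 o gamma)||^2` by projected gradient
#' descent: increments are flows of tangent vector fields (harmonic-polynomial
#' gradients plus Killing fields, see [tangent_basis()]) composed onto the
#' current map, with a backtracking line search and a hard positivity
#' constraint on the Jacobian. The Procrustes rotation is refreshed at every
#' energy evaluation.
#'
#' @param f1 fixed [grid_surface()].
#' @param f2 moving [grid_surface()].
#' @param init initial [sphere_diffeo()] (e.g. from [coarse_domain_search()]);
#'   identity if NULL.
#' @param config a [reg_config()].
#' @return A [sphere_diffeo()] with attributes `energy` and `energy_trace`.
#' @export
reparam_gradient_descent <- function(f1, f2, init = NULL, config = reg_config()) {
  g <- f1$grid
  stopifnot(same_grid(g, f2$grid))
  q1 <- srnf(f1)
  s1 <- srnf_inner(q1$q, q1$q, g)
  gamma <- if (is.null(init)) grid_directions(g) else init$gamma
  basis <- get_tangent_basis(config$harmonic_degree)
  w <- param_weights(g)
  efun <- function(gm) {
    cpp_reg_energy(f2$f, gm, q1$q, w, g$n_theta, g$n_phi, g$dtheta, g$dphi, s1)
  }
  E <- efun(gamma)
  trace <- E
  eps <- config$grad_eps
  step_init <- config$step0
  for (iter in seq_len(config$max_iter)) {
    if (E < 1e-14) break
    fields <- eval_tangent_basis(basis, gamma)
    fmat <- do.call(cbind, fields)
    epert <- cpp_reg_energy_grad(
      f2$f, gamma, fmat, eps, q1$q, w,
      g$n_theta, g$n_phi, g$dtheta, g$dphi, s1
    )
    grads <- (epert - E) / eps
    if (all(abs(grads) < 1e-14)) break
    dirf <- matrix(0, nrow(gamma), 3L)
    for (k in seq_along(fields)) dirf <- dirf - grads[k] * fields[[k]]
    rms <- sqrt(mean(rowSums(dirf^2)))
    if (rms < 1e-14) break
    dirf <- dirf / rms
    step <- step_init
    accepted <- FALSE
    for (h in seq_len(config$max_halvings)) {
      cand <- gamma + step * dirf
      cand <- cand / sqrt(rowSums(cand^2))
      Ec <- efun(cand)
      if (Ec < E) {
        J <- cpp_jacobian(cand, g$n_theta, g$n_phi, g$dtheta, g$dphi, g$sin_theta)
        if (min(J) > 0) {
          gamma <- cand
          Eprev <- E
          E <- Ec
          accepted <- TRUE
          # carry the accepted step forward (with headroom) so the line
          # search adapts to the local scale instead of re-halving from
          # step0 every iteration
          step_init <- min(step * 2, config$step0)
          break
        }
      }
      step <- step / 2
    }
    if (!accepted) break
    trace <- c(trace, E)
    if ((Eprev - E) / max(Eprev, 1e-12) < config$tol) break
  }
  out <- sphere_diffeo(gamma, g)
  attr(out, "energy") <- E
  attr(out, "energy_trace") <- trace
  out
}

get_tangent_basis <- function(degree) {
  key <- paste0("basis_", degree)
  b <- .elasurf_cache[[key]]
  if (is.null(b)) {
    b <- tangent_basis(degree)
    .elasurf_cache[[key]] <- b
  }
  b
}

#' Elastic registration of a surface pair
#'
#' Computes the elastic shape distance
#' `d_s = inf over (O, gamma) of ||q1 - O srnf(f2 o gamma)||`
#' by the pipeline coarse icosahedral search -> reparameterization gradient
#' descent with interleaved Procrustes rotations. Inputs are normalized to
#' zero centroid and unit area unless `normalize = FALSE`.
#'
#' @param f1 fixed [grid_surface()].
#' @param f2 moving [grid_surface()].
#' @param config a [reg_config()].
#' @param normalize apply [center_and_scale()] to both inputs first.
#' @return An object of class `registration_result`: `rotation` (3x3),
#'   `diffeo` ([sphere_diffeo()]), `registered_surface` (f2 reparameterized
#'   and rotated onto f1), `distance` (d_s), `unregistered_distance`, and
#'   `energy_trace`.
#' @export
register_pair <- function(f1, f2, config = reg_config(), normalize = TRUE) {
  if (normalize) {
    f1 <- center_and_scale(f1)
    f2 <- center_and_scale(f2)
  }
  g <- f1$grid
  stopifnot(same_grid(g, f2$grid))
  q1 <- srnf(f1)
  s1 <- srnf_inner(q1$q, q1$q, g)
  d0 <- preshape_distance(q1, srnf(f2))
  init <- if (isTRUE(config$coarse)) coarse_domain_search(f1, f2) else NULL
  dif <- reparam_gradient_descent(f1, f2, init = init, config = config)
  fin <- reg_energy(f2$f, dif$gamma, q1$q, g, s1, return_f = TRUE)
  dist <- sqrt(max(fin$E, 0))
  if (dist > d0) {
    # cannot happen when the identity is reachable, kept as a hard guarantee
    dif <- identity_diffeo(g)
    fin <- reg_energy(f2$f, dif$gamma, q1$q, g, s1, return_f = TRUE)
    dist <- min(sqrt(max(fin$E, 0)), d0)
  }
  reg_surface <- rotate_surface(grid_surface(fin$f2g, g, f2$provenance), fin$O)
  structure(
    list(
      rotation = fin$O, diffeo = dif, registered_surface = reg_surface,
      distance = dist, unregistered_distance = d0,
      energy_trace = attr(dif, "energy_trace")
    ),
    class = "registration_result"
  )
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "registration_result: d_s = %.6g (unregistered %.6g), %d descent steps\n",
    x$distance, x$unregistered_distance, length(x$energy_trace) - 1L
  ))
  invisible(x)
}
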