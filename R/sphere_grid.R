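#' Regular colatitude-longitude grid on the unit sphere
#'
#' Builds the discrete domain used throughout the package: `n_theta` colatitude
#' rows at the midpoints `theta_j = (j - 1/2) * pi / n_theta` (the poles are
#' never nodes, so `sin(theta) > 0` everywhere) and `n_phi` periodic longitude
#' columns `phi_k = 2*pi*(k-1)/n_phi`. Quadrature weights are the midpoint-rule
#' area elements `sin(theta_j) * dtheta * dphi`, which sum to the sphere area
#' \eqn{4\pi} up to O(h^2).
#'
#' @param n_theta number of colatitude samples (>= 3).
#' @param n_phi number of longitude samples (>= 3).
#' @return An object of class `sphere_grid`: a list with `n_theta`, `n_phi`,
#'   `theta`, `phi`, `dtheta`, `dphi`, `sin_theta` and the `n_theta x n_phi`
#'   weight matrix `quad_weights`.
#' @examples
#' g <- sphere_grid(32, 32)
#' abs(sum(g$quad_weights) - 4 * pi) / (4 * pi)  # small
#' @export
sphere_grid <- function(n_theta, n_phi) {
  n_theta <- as.integer(n_theta)
  n_phi <- as.integer(n_phi)
  if (is.na(n_theta) || is.na(n_phi) || n_theta < 3L || n_phi < 3L) {
    stop("sphere_grid needs n_theta >= 3 and n_phi >= 3")
  }
  dtheta <- pi / n_theta
  dphi <- 2 * pi / n_phi
  theta <- (seq_len(n_theta) - 0.5) * dtheta
  phi <- (seq_len(n_phi) - 1L) * dphi
  st <- sin(theta)
  w <- matrix(st * dtheta * dphi, n_theta, n_phi)
  structure(
    list(
      n_theta = n_theta, n_phi = n_phi,
      theta = theta, phi = phi,
      dtheta = dtheta, dphi = dphi,
      sin_theta = st, quad_weights = w
    ),
    class = "sphere_grid"
  )
}

#' @export
print.sphere_grid <- function(x, ...) {
  cat(sprintf(
    "sphere_grid: %d x %d nodes, sum(w) = %.6f (4*pi = %.6f)\n",
    x$n_theta, x$n_phi, sum(x$quad_weights), 4 * pi
  ))
  invisible(x)
}

#' Closed surface sampled on a spherical grid
#'
#' A surface is a map f from the unit sphere into R^3 stored nodewise as an
#' `n_theta x n_phi x 3` array on a [sphere_grid()].
#'
#' @param f numeric array of dimension `c(n_theta, n_phi, 3)`.
#' @param grid a [sphere_grid()].
#' @param provenance free-text label carried through the pipeline.
#' @return An object of class `grid_surface`.
#' @export
grid_surface <- function(f, grid, provenance = "") {
  stopifnot(inherits(grid, "sphere_grid"))
  f <- as_field3(f, grid)
  if (!all(is.finite(f))) stop("grid_surface: non-finite coordinates")
  structure(list(grid = grid, f = f, provenance = as.character(provenance)[1]),
    class = "grid_surface"
  )
}

#' @export
print.grid_surface <- function(x, ...) {
  cat(sprintf(
    "grid_surface [%s]: %d x %d grid, area = %.4g\n",
    if (nzchar(x$provenance)) x$provenance else "unnamed",
    x$grid$n_theta, x$grid$n_phi, surface_area(x)
  ))
  invisible(x)
}

# coerce to nt x np x 3 array, validating dims against the grid
as_field3 <- function(f, grid) {
  nt <- grid$n_theta
  np <- grid$n_phi
  if (is.matrix(f) && ncol(f) == 3L && nrow(f) == nt * np) {
    dim(f) <- c(nt, np, 3L)
  }
  if (!(is.array(f) && length(dim(f)) == 3L && all(dim(f) == c(nt, np, 3L)))) {
    stop("field must be an n_theta x n_phi x 3 array on the given grid")
  }
  storage.mode(f) <- "double"
  f
}

# vectorize a field to a (nt*np) x 3 matrix
field_as_matrix <- function(f) {
  d <- dim(f)
  dim(f) <- c(d[1] * d[2], 3L)
  f
}

same_grid <- function(g1, g2) {
  g1$n_theta == g2$n_theta && g1$n_phi == g2$n_phi
}

# -- finite-difference stencils -----------------------------------------------
# theta: central differences on interior rows, second-order one-sided stencils
# on the two boundary rows; phi: central differences with periodic wrap.

deriv_theta <- function(m, dtheta) {
  nt <- nrow(m)
  out <- m
  if (nt < 3L) stop("need at least 3 theta rows for derivatives")
  out[2:(nt - 1), ] <- (m[3:nt, , drop = FALSE] - m[1:(nt - 2), , drop = FALSE]) / (2 * dtheta)
  out[1, ] <- (-3 * m[1, ] + 4 * m[2, ] - m[3, ]) / (2 * dtheta)
  out[nt, ] <- (3 * m[nt, ] - 4 * m[nt - 1, ] + m[nt - 2, ]) / (2 * dtheta)
  out
}

deriv_phi <- function(m, dphi) {
  np <- ncol(m)
  ip <- c(2:np, 1L)
  im <- c(np, 1:(np - 1))
  (m[, ip, drop = FALSE] - m[, im, drop = FALSE]) / (2 * dphi)
}

#' Tangent frame, normal field and area element of a surface
#'
#' Computes the partial-derivative fields `f_u` (colatitude direction) and
#' `f_v` (longitude direction) by finite differences, the unnormalized normal
#' `n = f_u x f_v` and its magnitude `n_mag` (the local area element).
#' Nodes where `n_mag` falls below `1e-12 * mean(n_mag)` are flagged as
#' degenerate and clamped to that floor so downstream SRNF division stays
#' finite.
#'
#' @param surface a [grid_surface()].
#' @return An object of class `tangent_frame` with fields `f_u`, `f_v`, `n`
#'   (arrays `nt x np x 3`), `n_mag` (matrix), and `degenerate` (logical
#'   matrix of clamped nodes).
#' @export
tangent_frame <- function(surface) {
  stopifnot(inherits(surface, "grid_surface"))
  g <- surface$grid
  f <- surface$f
  fu <- array(0, dim(f))
  fv <- array(0, dim(f))
  for (c in 1:3) {
    fu[, , c] <- deriv_theta(f[, , c], g$dtheta)
    fv[, , c] <- deriv_phi(f[, , c], g$dphi)
  }
  n <- cross_field(fu, fv)
  n_mag <- sqrt(n[, , 1]^2 + n[, , 2]^2 + n[, , 3]^2)
  floor_val <- 1e-12 * mean(n_mag)
  degenerate <- n_mag < floor_val
  n_mag_clamped <- pmax(n_mag, floor_val)
  structure(
    list(
      f_u = fu, f_v = fv, n = n,
      n_mag = n_mag_clamped, degenerate = degenerate
    ),
    class = "tangent_frame"
  )
}

cross_field <- function(a, b) {
  out <- array(0, dim(a))
  out[, , 1] <- a[, , 2] * b[, , 3] - a[, , 3] * b[, , 2]
  out[, , 2] <- a[, , 3] * b[, , 1] - a[, , 1] * b[, , 3]
  out[, , 3] <- a[, , 1] * b[, , 2] - a[, , 2] * b[, , 1]
  out
}

#' Surface area by quadrature
#'
#' Integrates the area element `|n(s)| = |f_u x f_v|` over the parameter
#' domain (`d theta d phi`); for the unit sphere this gives \eqn{4\pi}. This
#' is the true Euclidean area of the embedded surface and agrees with a
#' triangulated-mesh area as the grid is refined.
#'
#' @param surface a [grid_surface()].
#' @return Positive scalar area.
#' @export
surface_area <- function(surface) {
  fr <- tangent_frame(surface)
  g <- surface$grid
  a <- sum(fr$n_mag) * g$dtheta * g$dphi
  if (!is.finite(a) || a <= 0) stop("surface_area: degenerate surface (area <= 0)")
  a
}

#' L2 inner product of two fields over the sphere
#'
#' Quadrature-weighted inner product `sum_s <h1(s), h2(s)> w(s)`; the induced
#' norm is [norm_l2()].
#'
#' @param h1,h2 fields (`nt x np x 3` arrays or `(nt*np) x 3` matrices).
#' @param grid the common [sphere_grid()].
#' @return Scalar.
#' @export
inner_product_l2 <- function(h1, h2, grid) {
  h1 <- as_field3(h1, grid)
  h2 <- as_field3(h2, grid)
  w <- grid$quad_weights
  sum((h1[, , 1] * h2[, , 1] + h1[, , 2] * h2[, , 2] + h1[, , 3] * h2[, , 3]) * w)
}

#' @rdname inner_product_l2
#' @param h field whose L2 norm is required.
#' @export
norm_l2 <- function(h, grid) sqrt(inner_product_l2(h, h, grid))

#' Normalize a surface to zero centroid and unit area
#'
#' Removes translation (the area-weighted centroid is moved to the origin) and
#' global scale (coordinates divided by the square root of the area, so the
#' resulting surface has unit area). Idempotent up to floating error.
#'
#' @param surface a [grid_surface()].
#' @return A normalized [grid_surface()].
#' @export
center_and_scale <- function(surface) {
  g <- surface$grid
  fr <- tangent_frame(surface)
  dens <- fr$n_mag * g$dtheta * g$dphi
  a <- sum(dens)
  if (!is.finite(a) || a <= 0) stop("center_and_scale: degenerate surface")
  f <- surface$f
  centroid <- c(
    sum(f[, , 1] * dens), sum(f[, , 2] * dens), sum(f[, , 3] * dens)
  ) / a
  for (c in 1:3) f[, , c] <- (f[, , c] - centroid[c]) / sqrt(a)
  grid_surface(f, g, surface$provenance)
}

# unit direction vectors of all grid nodes, (nt*np) x 3
grid_directions <- function(grid) {
  st <- sin(grid$theta)
  ct <- cos(grid$theta)
  cp <- cos(grid$phi)
  sp <- sin(grid$phi)
  cbind(
    as.vector(outer(st, cp)),
    as.vector(outer(st, sp)),
    as.vector(outer(ct, rep(1, grid$n_phi)))
  )
}

#' Evaluate a gridded field at arbitrary sphere points
#'
#' Bilinear interpolation in (theta, phi) with periodic wrap in phi and
#' reflection across the poles (a query beyond the first/last colatitude row
#' blends with the antipodal-longitude values of that row, which is the smooth
#' continuation across the pole).
#'
#' @param f field array `nt x np x 3` (or matrix `nt x np` for scalars).
#' @param grid the [sphere_grid()] the field lives on.
#' @param theta,phi query coordinates (vectors of equal length).
#' @return A `length(theta) x 3` matrix (or vector for scalar fields).
#' @export
interp_sphere <- function(f, grid, theta, phi) {
  scalar <- is.matrix(f)
  if (scalar) {
    f <- array(c(f, f, f), c(grid$n_theta, grid$n_phi, 3L))
  } else {
    f <- as_field3(f, grid)
  }
  out <- cpp_interp_sphere(
    f, as.double(theta), as.double(phi),
    grid$n_theta, grid$n_phi, grid$dtheta, grid$dphi
  )
  if (scalar) out[, 1] else out
}
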