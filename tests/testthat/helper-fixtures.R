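# Shared fixtures: small grids and analytic surfaces built in code.

unit_sphere_surface <- function(grid) {
  grid_surface(elasurf:::grid_directions(grid), grid, "unit sphere")
}

ellipsoid_surface <- function(grid, axes = c(1.3, 0.8, 1.1)) {
  P <- elasurf:::grid_directions(grid)
  grid_surface(cbind(axes[1] * P[, 1], axes[2] * P[, 2], axes[3] * P[, 3]),
               grid, "ellipsoid")
}

bumpy_ellipsoid_surface <- function(grid, axes = c(1.3, 0.8, 1.1), bump = 0.2) {
  P <- elasurf:::grid_directions(grid)
  r <- 1 + bump * P[, 1] * P[, 3]
  grid_surface(cbind(axes[1] * r * P[, 1], axes[2] * r * P[, 2],
                     axes[3] * r * P[, 3]), grid, "bumpy ellipsoid")
}

# matching analytic transform for icosphere meshes
bumpy_ellipsoid_transform <- function(axes = c(1.3, 0.8, 1.1), bump = 0.2) {
  function(V) {
    r <- 1 + bump * V[, 1] * V[, 3]
    cbind(axes[1] * r * V[, 1], axes[2] * r * V[, 2], axes[3] * r * V[, 3])
  }
}

vec_distance <- function(a, b) {
  sqrt(sum((elasurf:::field_as_matrix(a$f) - elasurf:::field_as_matrix(b$f))^2))
}

random_rotation <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0.2, pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

rotate_srnf <- function(q, O) {
  q$q <- array(elasurf:::field_as_matrix(q$q) %*% t(O), dim(q$q))
  q
}
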