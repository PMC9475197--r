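# Tangent vector fields on the sphere used to parameterize incremental
# reparameterizations: tangential gradients of homogeneous harmonic
# polynomials up to a chosen degree (the span of real-spherical-harmonic
# gradients, evaluated in Cartesian form so there are no pole singularities)
# plus the three rotational Killing fields.

# exponent triples (a, b, c) with a + b + c = l
mono_exps <- function(l) {
  out <- NULL
  for (a in l:0) for (b in (l - a):0) {
    out <- rbind(out, c(a, b, l - a - b))
  }
  out
}

# matrix of the Laplacian acting on homogeneous degree-l polynomials,
# expressed in the monomial bases of degrees l and l-2
laplacian_matrix <- function(l) {
  el <- mono_exps(l)
  e2 <- mono_exps(l - 2)
  key <- function(e) paste(e[, 1], e[, 2], e[, 3])
  idx <- stats::setNames(seq_len(nrow(e2)), key(e2))
  L <- matrix(0, nrow(e2), nrow(el))
  for (j in seq_len(nrow(el))) {
    e <- el[j, ]
    for (c in 1:3) {
      if (e[c] >= 2) {
        tgt <- e
        tgt[c] <- tgt[c] - 2L
        L[idx[[paste(tgt[1], tgt[2], tgt[3])]], j] <-
          L[idx[[paste(tgt[1], tgt[2], tgt[3])]], j] + e[c] * (e[c] - 1)
      }
    }
  }
  L
}

# coefficients (in the monomial basis) of a basis of harmonic homogeneous
# polynomials of degree l; 2l + 1 columns
harmonic_coefs <- function(l) {
  if (l == 1) {
    return(diag(3))
  }
  L <- laplacian_matrix(l)
  eg <- eigen(crossprod(L), symmetric = TRUE)
  null_dim <- 2L * l + 1L
  eg$vectors[, (ncol(L) - null_dim + 1L):ncol(L), drop = FALSE]
}

#' Tangent-field basis for reparameterization descent
#'
#' Constructs the finite basis of smooth tangent vector fields on the sphere
#' used by [reparam_gradient_descent()]: tangential gradients of harmonic
#' polynomials of degree 1..`degree` (equivalently, gradients of the real
#' spherical harmonics up to that degree) together with the three rotational
#' Killing fields. Each field is scaled to unit root-mean-square magnitude
#' over the sphere.
#'
#' @param degree maximum polynomial degree (default 4).
#' @return An object of class `tangent_basis` usable with
#'   [eval_tangent_basis()]; its `n_fields` element gives the basis size
#'   (`sum(2l+1) + 3`).
#' @export
tangent_basis <- function(degree = 4) {
  stopifnot(degree >= 1)
  per_degree <- lapply(seq_len(degree), function(l) {
    list(exps = mono_exps(l), coefs = harmonic_coefs(l))
  })
  b <- structure(
    list(degree = degree, per_degree = per_degree, scales = NULL),
    class = "tangent_basis"
  )
  # calibrate RMS field magnitude on a moderate reference grid
  g <- sphere_grid(24, 24)
  P <- grid_directions(g)
  w <- as.vector(g$quad_weights)
  flds <- eval_tangent_basis(b, P, scaled = FALSE)
  b$scales <- vapply(flds, function(Fk) {
    sqrt(sum(w * rowSums(Fk^2)) / (4 * pi))
  }, numeric(1))
  b$n_fields <- length(flds)
  b
}

#' Evaluate a tangent-field basis at sphere points
#'
#' @param basis a [tangent_basis()].
#' @param P `n x 3` matrix of unit vectors.
#' @param scaled divide by the stored RMS scales (default TRUE).
#' @return List of `n x 3` tangent fields (each row orthogonal to `P`).
#' @export
eval_tangent_basis <- function(basis, P, scaled = TRUE) {
  n <- nrow(P)
  x <- P[, 1]; y <- P[, 2]; z <- P[, 3]
  maxd <- basis$degree
  powx <- outer(x, 0:maxd, `^`)
  powy <- outer(y, 0:maxd, `^`)
  powz <- outer(z, 0:maxd, `^`)
  fields <- list()
  for (l in seq_len(basis$degree)) {
    exps <- basis$per_degree[[l]]$exps
    coefs <- basis$per_degree[[l]]$coefs
    nm <- nrow(exps)
    gx <- matrix(0, n, nm); gy <- matrix(0, n, nm); gz <- matrix(0, n, nm)
    for (j in seq_len(nm)) {
      a <- exps[j, 1]; b <- exps[j, 2]; cc <- exps[j, 3]
      if (a > 0) gx[, j] <- a * powx[, a] * powy[, b + 1] * powz[, cc + 1]
      if (b > 0) gy[, j] <- b * powx[, a + 1] * powy[, b] * powz[, cc + 1]
      if (cc > 0) gz[, j] <- cc * powx[, a + 1] * powy[, b + 1] * powz[, cc]
    }
    GX <- gx %*% coefs; GY <- gy %*% coefs; GZ <- gz %*% coefs
    for (k in seq_len(ncol(coefs))) {
      G <- cbind(GX[, k], GY[, k], GZ[, k])
      rad <- rowSums(G * P)
      fields[[length(fields) + 1]] <- G - P * rad
    }
  }
  # rotational Killing fields e_a x p
  fields[[length(fields) + 1]] <- cbind(-z * 0, -z, y)
  fields[[length(fields) + 1]] <- cbind(z, x * 0, -x)
  fields[[length(fields) + 1]] <- cbind(-y, x, y * 0)
  if (scaled && !is.null(basis$scales)) {
    for (k in seq_along(fields)) fields[[k]] <- fields[[k]] / basis$scales[k]
  }
  fields
}
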