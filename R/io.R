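# Text-based containers for pipeline artifacts. Surfaces and PCA bases are
# stored as documented JSON (all numeric arrays in column-major order);
# scores and distance matrices as CSV.

#' Write / read a grid surface as JSON
#'
#' The container stores `n_theta`, `n_phi`, `theta`, `phi`, the flattened
#' coordinate field `f` (column-major, `nt x np x 3`) and the provenance
#' string.
#'
#' @param surface a [grid_surface()].
#' @param path output path.
#' @return `read_surface` returns a [grid_surface()].
#' @export
write_surface <- function(surface, path) {
  g <- surface$grid
  obj <- list(
    container = "elasurf-grid-surface-v1",
    n_theta = g$n_theta, n_phi = g$n_phi,
    theta = g$theta, phi = g$phi,
    f = as.vector(surface$f),
    provenance = surface$provenance
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$container, "elasurf-grid-surface-v1")) {
    stop("read_surface: not an elasurf surface container")
  }
  g <- sphere_grid(obj$n_theta, obj$n_phi)
  f <- array(as.numeric(obj$f), c(g$n_theta, g$n_phi, 3L))
  grid_surface(f, g, obj$provenance %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a shape-PCA basis as JSON
#'
#' @param basis a [shape_pca_basis()].
#' @param path output path.
#' @export
write_pca_basis <- function(basis, path) {
  g <- basis$grid
  obj <- list(
    container = "elasurf-pca-basis-v1",
    n_theta = g$n_theta, n_phi = g$n_phi,
    mu = as.vector(basis$mu$f),
    directions = as.vector(basis$directions),
    n_directions = ncol(basis$directions),
    singular_values = basis$singular_values,
    n_train = basis$n_train
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pca_basis
#' @export
read_pca_basis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$container, "elasurf-pca-basis-v1")) {
    stop("read_pca_basis: not an elasurf PCA container")
  }
  g <- sphere_grid(obj$n_theta, obj$n_phi)
  mu <- grid_surface(array(as.numeric(obj$mu), c(g$n_theta, g$n_phi, 3L)),
                     g, "karcher mean")
  D <- matrix(as.numeric(obj$directions), ncol = obj$n_directions)
  structure(
    list(mu = mu, directions = D,
         singular_values = as.numeric(obj$singular_values),
         n_train = obj$n_train, grid = g),
    class = "shape_pca_basis"
  )
}

#' Write principal scores as CSV
#'
#' @param scores matrix of scores (rows = subjects).
#' @param path output path.
#' @param ids optional subject ids.
#' @export
write_scores_csv <- function(scores, path, ids = NULL) {
  df <- as.data.frame(scores)
  names(df) <- paste0("z", seq_len(ncol(df)))
  df <- cbind(subject_id = ids %||% sprintf("S%03d", seq_len(nrow(df))), df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
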