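#' Fit an elastic shape-PCA model to a sample of surfaces
#'
#' The package's central estimator: computes the Karcher mean of the sample
#' under the elastic (SRNF) metric, registers every surface to it, and
#' performs shape PCA on the registered, vectorized surfaces. The fitted
#' object supports score extraction for new surfaces (`predict`),
#' reconstruction (`fitted`), residual reconstruction errors (`residuals`),
#' sampling of new shapes from the fitted Gaussian score model (`simulate`)
#' and a cumulative-variance plot (`plot`).
#'
#' @param surfaces list of [grid_surface()]s on a common grid.
#' @param k number of principal components to retain for prediction and
#'   reconstruction (default: all non-null components).
#' @param config a [reg_config()] used for all registrations.
#' @param tol,max_iter Karcher-mean stopping parameters (see [karcher_mean()]).
#' @return An object of class `eshape_pca` containing the `karcher_mean`
#'   fit, the `shape_pca_basis`, the retained `k`, and the training scores.
#' @examples
#' g <- sphere_grid(16, 16)
#' fam <- generate_family(surface_family_spec(n = 8, seed = 1), g)
#' fit <- eshape_pca(fam$surfaces, config = reg_config(max_iter = 5))
#' summary(fit)
#' @export
eshape_pca <- function(surfaces, k = NULL, config = reg_config(),
                       tol = 1e-4, max_iter = 20) {
  km <- karcher_mean(surfaces, config = config, tol = tol, max_iter = max_iter)
  basis <- shape_pca(km)
  if (is.null(k)) k <- ncol(basis$directions)
  k <- min(k, ncol(basis$directions))
  scores <- t(vapply(km$registered, function(s) {
    principal_scores(s, basis, k = ncol(basis$directions))
  }, numeric(ncol(basis$directions))))
  structure(
    list(
      karcher_mean = km, basis = basis, k = k, scores = scores,
      config = config, n = length(surfaces)
    ),
    class = "eshape_pca"
  )
}

#' @export
print.eshape_pca <- function(x, ...) {
  cv <- cumulative_variance(x$basis)
  cat(sprintf(
    "eshape_pca: %d surfaces, %d components (k = %d retained)\n",
    x$n, ncol(x$basis$directions), x$k
  ))
  cat(sprintf(
    "  PC1 explains %.1f%%; %d components reach 95%%\n",
    100 * cv[1], which(cv >= 0.95)[1]
  ))
  invisible(x)
}

#' @export
summary.eshape_pca <- function(object, ...) {
  sv <- object$basis$singular_values
  cv <- cumulative_variance(object$basis)
  out <- list(
    n = object$n, k = object$k,
    singular_values = sv,
    proportion = sv / sum(sv),
    cumulative = cv,
    karcher_variance = tail(object$karcher_mean$variance_trace, 1),
    iterations = object$karcher_mean$iterations
  )
  class(out) <- "summary.eshape_pca"
  out
}

#' @export
print.summary.eshape_pca <- function(x, ...) {
  cat(sprintf(
    "Elastic shape PCA: n = %d, Karcher variance %.4g (%d iterations)\n",
    x$n, x$karcher_variance, x$iterations
  ))
  m <- min(length(x$singular_values), 10L)
  tab <- data.frame(
    component = seq_len(m),
    singular_value = signif(x$singular_values[seq_len(m)], 4),
    proportion = round(x$proportion[seq_len(m)], 4),
    cumulative = round(x$cumulative[seq_len(m)], 4)
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.eshape_pca <- function(object, ...) object$scores

#' @export
#' @param object,newdata fitted model and list of new surfaces.
#' @param k number of components.
#' @param register elastically register new surfaces to the mean (default TRUE).
#' @rdname eshape_pca
predict.eshape_pca <- function(object, newdata = NULL, k = object$k,
                               register = TRUE, ...) {
  if (is.null(newdata)) {
    return(object$scores[, seq_len(k), drop = FALSE])
  }
  if (inherits(newdata, "grid_surface")) newdata <- list(newdata)
  t(vapply(newdata, function(s) {
    principal_scores(s, object$basis, k = k, register = register,
                     config = object$config)
  }, numeric(k)))
}

#' @export
fitted.eshape_pca <- function(object, k = object$k, ...) {
  lapply(seq_len(object$n), function(i) {
    reconstruct(object$basis, object$scores[i, seq_len(k)])
  })
}

#' @export
residuals.eshape_pca <- function(object, k = object$k, ...) {
  rec <- fitted(object, k = k)
  vapply(seq_len(object$n), function(i) {
    a <- field_as_matrix(object$karcher_mean$registered[[i]]$f)
    b <- field_as_matrix(rec[[i]]$f)
    sqrt(sum((a - b)^2))
  }, numeric(1))
}

#' @export
simulate.eshape_pca <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sv <- object$basis$singular_values[seq_len(object$k)]
  sds <- sqrt(sv / object$n)
  lapply(seq_len(nsim), function(i) {
    reconstruct(object$basis, rnorm(object$k, 0, sds))
  })
}

#' @export
plot.eshape_pca <- function(x, ...) {
  cv <- cumulative_variance(x$basis)
  plot(seq_along(cv), 100 * cv,
    type = "b", pch = 16,
    xlab = "number of principal components",
    ylab = "cumulative variance explained (%)",
    ylim = c(0, 100), ...
  )
  graphics::abline(h = 95, lty = 2)
  invisible(x)
}
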