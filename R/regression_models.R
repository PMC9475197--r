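# Regression layer: principal-score design matrices for the ten clinical
# model specifications, OLS fits with adjusted R^2, bidirectional stepwise
# selection, pairwise surface-distance matrices, and classical MDS.

#' Clinical model specifications (models 1-10)
#'
#' The ten linear models relating PTSD outcomes to principal shape scores:
#' \preformatted{
#'  1  PSS    ~ Age + BDI + PS + Interactions
#'  2  PSS    ~ Age + BDI + PS
#'  3  PSS    ~ Age + BDI
#'  4  PSS    ~ PS
#'  5  CTQTOT ~ Age + BDI + PS + Interactions
#'  6  CTQTOT ~ Age + BDI + PS
#'  7  CTQTOT ~ Age + BDI
#'  8  CTQTOT ~ PS
#'  9  PSS    ~ Age + BDI + PS + Interactions + ICV
#' 10  CTQTOT ~ Age + BDI + PS + Interactions + ICV
#' }
#' `PS` are the first `n_scores` principal scores per structure; interactions
#' are all pairwise products of the first `n_interact` scores per structure
#' with age and with BDI.
#'
#' @param model_no integer 1-10.
#' @param structures character vector of structure prefixes present in the
#'   table (score columns are `<structure>_PS<d>`).
#' @param n_scores main-effect scores per structure (default 15).
#' @param n_interact scores per structure entering interactions (default 5).
#' @return A list of class `model_spec` with `model_no`, `outcome`, `terms`.
#' @export
model_spec <- function(model_no,
                       structures = c("hippocampus", "amygdala", "putamen"),
                       n_scores = 15, n_interact = 5) {
  stopifnot(model_no %in% 1:10)
  outcome <- if (model_no %in% c(5, 6, 7, 8, 10)) "CTQTOT" else "PSS"
  ps <- as.vector(t(outer(structures, seq_len(n_scores),
                          function(s, d) sprintf("%s_PS%d", s, d))))
  inter <- as.vector(t(outer(structures, seq_len(n_interact),
                             function(s, d) sprintf("%s_PS%d", s, d))))
  inter <- c(paste0(inter, ":age"), paste0(inter, ":BDI"))
  terms <- switch(as.character(model_no),
    "1" = c("age", "BDI", ps, inter),
    "2" = c("age", "BDI", ps),
    "3" = c("age", "BDI"),
    "4" = ps,
    "5" = c("age", "BDI", ps, inter),
    "6" = c("age", "BDI", ps),
    "7" = c("age", "BDI"),
    "8" = ps,
    "9" = c("age", "BDI", ps, inter, "ICV"),
    "10" = c("age", "BDI", ps, inter, "ICV")
  )
  structure(list(model_no = model_no, outcome = outcome, terms = terms,
                 structures = structures, n_scores = n_scores,
                 n_interact = n_interact),
            class = "model_spec")
}

#' Build a regression design from a clinical table
#'
#' Expands the model terms against the table: plain columns are copied,
#' `a:b` terms become elementwise products. Principal-score columns are
#' z-scored before forming products (reduces interaction collinearity); set
#' `standardize = FALSE` for raw-scale scores. Rows with missing values are
#' rejected with their subject ids. The intercept is always included at fit
#' time.
#'
#' @param table a [simulate_clinical()] table (or any data frame with the
#'   needed columns).
#' @param spec a [model_spec()].
#' @param standardize z-score the principal-score columns first.
#' @return List with `X` (data frame of predictors, in spec order), `y`
#'   (outcome vector), `outcome`, `spec`.
#' @export
build_design <- function(table, spec, standardize = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  tab <- as.data.frame(table)
  base_cols <- unique(unlist(strsplit(spec$terms, ":", fixed = TRUE)))
  missing_cols <- setdiff(c(base_cols, spec$outcome), names(tab))
  if (length(missing_cols)) {
    stop("build_design: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  use <- tab[, c(base_cols, spec$outcome), drop = FALSE]
  bad <- !stats::complete.cases(use)
  if (any(bad)) {
    ids <- if ("subject_id" %in% names(tab)) tab$subject_id[bad] else which(bad)
    stop("build_design: rows with missing values: ", paste(ids, collapse = ", "))
  }
  if (standardize) {
    ps_cols <- grep("_PS[0-9]+$", base_cols, value = TRUE)
    for (cl in ps_cols) {
      s <- sd(tab[[cl]])
      if (s > 0) tab[[cl]] <- (tab[[cl]] - mean(tab[[cl]])) / s
    }
  }
  X <- lapply(spec$terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    Reduce(`*`, lapply(parts, function(p) tab[[p]]))
  })
  X <- as.data.frame(X, optional = TRUE)
  names(X) <- gsub(":", "_x_", spec$terms, fixed = TRUE)
  list(X = X, y = tab[[spec$outcome]], outcome = spec$outcome, spec = spec)
}

#' Ordinary least squares fit of a clinical design
#'
#' Fits the linear model by least squares (via [stats::lm()]) and reports
#' coefficients with two-sided t-test p-values and the adjusted R^2,
#' `1 - (1 - R^2)(n - 1)/(n - p - 1)`. Aliased (rank-deficient) columns are
#' dropped with a warning.
#'
#' @param design output of [build_design()], or a data frame / matrix of
#'   predictors when `y` is given.
#' @param y outcome vector (when `design` is a plain predictor table).
#' @return An object of class `esa_fit`: `coefficients`, `p_values`,
#'   `adjusted_r2`, `r2`, `n`, `p`, `selected_terms`, and the underlying
#'   `lm` fit.
#' @export
fit_ols <- function(design, y = NULL) {
  if (!is.null(design$X) && is.null(y)) {
    X <- design$X
    y <- design$y
  } else {
    X <- as.data.frame(design)
  }
  if (nrow(X) <= ncol(X) + 1) stop("fit_ols: need n > p + 1")
  dat <- cbind(.y = y, X)
  fit <- lm(.y ~ ., data = dat)
  if (any(is.na(coef(fit)))) {
    dropped <- names(coef(fit))[is.na(coef(fit))]
    warning("fit_ols: dropping aliased columns: ",
            paste(dropped, collapse = ", "))
  }
  as_esa_fit(fit, selected = setdiff(names(X), character(0)))
}

as_esa_fit <- function(fit, selected) {
  sm <- summary(fit)
  co <- sm$coefficients
  structure(
    list(
      coefficients = co[, 1],
      p_values = co[, 4],
      adjusted_r2 = sm$adj.r.squared,
      r2 = sm$r.squared,
      n = length(fit$fitted.values),
      p = length(stats::na.omit(coef(fit))) - 1L,
      selected_terms = selected,
      lm = fit
    ),
    class = "esa_fit"
  )
}

#' @export
print.esa_fit <- function(x, digits = 4, ...) {
  cat(sprintf(
    "esa_fit: n = %d, p = %d, adjusted R^2 = %.2f%%\n",
    x$n, x$p, 100 * x$adjusted_r2
  ))
  tab <- data.frame(
    term = names(x$coefficients),
    sign = ifelse(x$coefficients >= 0, "+", "-"),
    estimate = signif(x$coefficients, digits),
    p_value = signif(x$p_values, 2)
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.esa_fit <- function(object, ...) object$coefficients

#' Bidirectional stepwise predictor selection
#'
#' Add/drop search from the intercept-only model over the design's columns,
#' optimizing BIC by default (`criterion = "aic"` and a p-value
#' enter/remove variant `"pvalue"` are available). Deterministic given the
#' inputs: no randomness is involved.
#'
#' @param design output of [build_design()] (or data frame with `y`).
#' @param y optional outcome vector.
#' @param criterion `"bic"` (default), `"aic"`, or `"pvalue"`.
#' @param p_enter,p_remove thresholds for the p-value variant.
#' @return An `esa_fit` on the selected subset, with `selected_terms`.
#' @export
stepwise_select <- function(design, y = NULL,
                            criterion = c("bic", "aic", "pvalue"),
                            p_enter = 0.05, p_remove = 0.10) {
  criterion <- match.arg(criterion)
  if (!is.null(design$X) && is.null(y)) {
    X <- design$X
    y <- design$y
  } else {
    X <- as.data.frame(design)
  }
  dat <- cbind(.y = y, X)
  if (criterion %in% c("bic", "aic")) {
    k <- if (criterion == "bic") log(nrow(dat)) else 2
    null_fit <- lm(.y ~ 1, data = dat)
    full_scope <- as.formula(paste("~", paste(sprintf("`%s`", names(X)),
                                              collapse = " + ")))
    sel <- step(null_fit, scope = list(lower = ~1, upper = full_scope),
                direction = "both", trace = 0, k = k)
    selected <- setdiff(attr(stats::terms(sel), "term.labels"), character(0))
    selected <- gsub("`", "", selected)
    return(as_esa_fit(sel, selected))
  }
  # p-value threshold variant: forward entry / backward removal
  selected <- character(0)
  remaining <- names(X)
  repeat {
    changed <- FALSE
    if (length(remaining)) {
      pvals <- vapply(remaining, function(cl) {
        f <- lm(.y ~ ., data = dat[, c(".y", selected, cl), drop = FALSE])
        tail(summary(f)$coefficients[, 4], 1)
      }, numeric(1))
      if (min(pvals) < p_enter) {
        add <- remaining[which.min(pvals)]
        selected <- c(selected, add)
        remaining <- setdiff(remaining, add)
        changed <- TRUE
      }
    }
    if (length(selected)) {
      f <- lm(.y ~ ., data = dat[, c(".y", selected), drop = FALSE])
      pv <- summary(f)$coefficients[-1, 4]
      worst <- which.max(pv)
      if (pv[worst] > p_remove) {
        drop_cl <- selected[worst]
        selected <- setdiff(selected, drop_cl)
        remaining <- c(remaining, drop_cl)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fit <- lm(.y ~ ., data = dat[, c(".y", selected), drop = FALSE])
  as_esa_fit(fit, selected)
}

#' Pairwise distance matrix between surfaces
#'
#' `mode = "raw"`: plain L2 norms of surface differences
#' (`d_ij = ||f_i - f_j||` on the vectorized surfaces), the quantity that is
#' parameterization-sensitive. `mode = "elastic"`: the elastic shape distance
#' `d_s` from [register_pair()] for every ordered pair, symmetrized by
#' averaging the two directions (with a message; set
#' `symmetrize = "mirror"` to compute each unordered pair once).
#'
#' @param surfaces list of [grid_surface()]s on a common grid.
#' @param mode `"raw"` or `"elastic"`.
#' @param config a [reg_config()] for elastic mode.
#' @param symmetrize `"average"` (both directions) or `"mirror"`.
#' @param labels optional labels for rows/columns.
#' @return Symmetric non-negative matrix with zero diagonal, class
#'   `dist_matrix`.
#' @export
pairwise_distance_matrix <- function(surfaces, mode = c("raw", "elastic"),
                                     config = reg_config(),
                                     symmetrize = c("average", "mirror"),
                                     labels = NULL) {
  mode <- match.arg(mode)
  symmetrize <- match.arg(symmetrize)
  n <- length(surfaces)
  D <- matrix(0, n, n)
  if (mode == "raw") {
    V <- vapply(surfaces, function(s) as.vector(field_as_matrix(s$f)),
                numeric(3L * surfaces[[1]]$grid$n_theta * surfaces[[1]]$grid$n_phi))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- sqrt(sum((V[, i] - V[, j])^2))
      }
    }
  } else {
    if (symmetrize == "average") {
      message("pairwise_distance_matrix: symmetrizing elastic distances by averaging both directions")
    }
    norm_surfs <- lapply(surfaces, center_and_scale)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        dij <- register_pair(norm_surfs[[i]], norm_surfs[[j]], config,
                             normalize = FALSE)$distance
        if (symmetrize == "average") {
          dji <- register_pair(norm_surfs[[j]], norm_surfs[[i]], config,
                               normalize = FALSE)$distance
          dij <- (dij + dji) / 2
        }
        D[i, j] <- D[j, i] <- dij
      }
    }
  }
  if (!is.null(labels)) dimnames(D) <- list(labels, labels)
  class(D) <- c("dist_matrix", class(D))
  D
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centering of `-D^2/2` followed by eigendecomposition, via
#' [stats::cmdscale()]; the embedding is mean-centered. If `dim` exceeds the
#' number of positive eigenvalues the embedding is truncated with a warning.
#'
#' @param D a symmetric distance matrix.
#' @param dim embedding dimension (>= 1).
#' @return `n x dim` matrix of coordinates.
#' @export
classical_mds <- function(D, dim = 2) {
  stopifnot(dim >= 1)
  D <- unclass(D)
  k_eff <- min(dim, nrow(D) - 1L)
  emb <- suppressWarnings(cmdscale(D, k = k_eff))
  if (ncol(emb) < dim) {
    warning(sprintf(
      "classical_mds: only %d positive eigenvalues; truncating to that dimension",
      ncol(emb)
    ))
  }
  sweep(emb, 2, colMeans(emb))
}

#' 2-medoid clustering accuracy against known labels
#'
#' Partitions a distance matrix with [cluster::pam()] (k medoids) and returns
#' the best label-matching accuracy.
#'
#' @param D distance matrix (or 2-column embedding with `from_embedding`).
#' @param labels true class labels (two classes).
#' @param k number of clusters (default 2).
#' @return List with `accuracy`, `assignment`.
#' @export
medoid_cluster_accuracy <- function(D, labels, k = 2) {
  if (is.matrix(D) && nrow(D) == ncol(D) && isSymmetric(unname(unclass(D)))) {
    cl <- cluster::pam(stats::as.dist(unclass(D)), k = k, diss = TRUE,
                       cluster.only = TRUE)
  } else {
    cl <- cluster::pam(D, k = k, cluster.only = TRUE)
  }
  labs <- unique(labels)
  stopifnot(length(labs) == k)
  perms <- list(labs, rev(labs))
  acc <- max(vapply(perms, function(pm) {
    mean(pm[cl] == labels)
  }, numeric(1)))
  list(accuracy = acc, assignment = cl)
}
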