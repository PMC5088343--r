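#' Z-standardize a numeric vector
#'
#' Centers to mean zero and scales to sample standard deviation one
#' (denominator n - 1). Standardizing outcomes and predictors puts regression
#' coefficients on the interpretable per-SD scale.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Standardized numeric vector.
#' @export
zscore <- function(values) {
  if (anyNA(values)) abort("`values` must not contain NA")
  if (length(values) < 2L) abort("need at least 2 values to standardize")
  s <- sd(values)
  if (s == 0) abort("cannot z-score a constant vector")
  (values - mean(values)) / s
}

#' Economic-disadvantage factor score
#'
#' Composite of five area characteristics: percent female-headed households,
#' percent families in poverty, unemployment rate, percent college graduates
#' (reverse coded), and median family income (reverse coded). Each component
#' is z-scored (education and income negated), and the score is the first
#' principal component of the five, sign-oriented so that higher values mean
#' more disadvantage, rescaled to SD 1. A mean-of-z-scores variant is offered
#' for sensitivity checks.
#'
#' @param table Data frame with columns `pct_female_headed`, `pct_poverty`,
#'   `pct_unemployed`, `pct_college`, `median_income` (plus `area_id`).
#' @param method `"pca"` (first principal component, the default) or
#'   `"mean"` (mean of the five z-scores, rescaled to SD 1).
#' @return The input tibble with a `disadvantage` column appended.
#' @export
disadvantage_score <- function(table, method = c("pca", "mean")) {
  method <- match.arg(method)
  comp <- c("pct_female_headed", "pct_poverty", "pct_unemployed",
            "pct_college", "median_income")
  missing_cols <- setdiff(comp, names(table))
  if (length(missing_cols) > 0L) {
    abort(paste0("missing component column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  z <- vapply(comp, function(cl) zscore(table[[cl]]), numeric(nrow(table)))
  z[, "pct_college"] <- -z[, "pct_college"]
  z[, "median_income"] <- -z[, "median_income"]
  score <- if (method == "pca") {
    pc <- prcomp(z, center = FALSE, scale. = FALSE)
    pc$x[, 1L]
  } else {
    rowMeans(z)
  }
  # orient: higher score = more disadvantage (correlates positively with the
  # oriented component average)
  if (cor(score, rowMeans(z)) < 0) score <- -score
  out <- as_tibble(table)
  out$disadvantage <- score / sd(score)
  out
}

#' OLS with cluster-robust standard errors
#'
#' Ordinary least squares with the cluster-robust (sandwich) variance
#' estimator and the standard small-sample correction
#' `G/(G-1) * (n-1)/(n-k)`, where `G` is the number of clusters. Areas within
#' the same county share unobserved context, so their regression errors are
#' correlated; clustering at the county level keeps confidence intervals
#' honest under that correlation. Inference uses the normal approximation
#' (95% CI = estimate +/- 1.96 SE) by default, with a t(G-1) option.
#'
#' @param data Data frame holding outcome, predictors, and cluster ids.
#' @param formula Model formula, e.g. `pct_happy ~ disadvantage + pct_male`.
#' @param cluster Name of the cluster-id column (e.g. `"county_id"`).
#' @param df Reference distribution for CIs and p-values: `"normal"` or
#'   `"t"` (t with G-1 degrees of freedom).
#' @return An `ols_cluster` object; see [tidy.ols_cluster()].
#' @export
ols_cluster <- function(data, formula, cluster, df = c("normal", "t")) {
  df <- match.arg(df)
  stopifnot(is.data.frame(data))
  if (!cluster %in% names(data)) {
    abort(paste0("cluster column '", cluster, "' not found"))
  }
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, data = mf)
  n <- nrow(X); k <- ncol(X)
  if (n <= k) abort("need more observations than predictors")
  cl <- as.character(data[[cluster]][as.integer(rownames(mf))])
  G <- length(unique(cl))
  if (G < 2L) abort("need at least 2 clusters")
  qrX <- qr(X)
  if (qrX$rank < k) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):k]]
    abort(paste0("predictor matrix is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  XtX_inv <- chol2inv(qr.R(qrX))
  beta <- drop(XtX_inv %*% crossprod(X, y))
  resid <- drop(y - X %*% beta)

  # sandwich meat: sum over clusters of (X_g' e_g)(X_g' e_g)'
  meat <- matrix(0, k, k)
  for (g in unique(cl)) {
    sel <- cl == g
    sg <- drop(crossprod(X[sel, , drop = FALSE], resid[sel]))
    meat <- meat + tcrossprod(sg)
  }
  corr <- (G / (G - 1)) * ((n - 1) / (n - k))
  vcov_cl <- corr * XtX_inv %*% meat %*% XtX_inv
  se <- sqrt(pmax(diag(vcov_cl), 0))

  crit <- if (df == "normal") qnorm(0.975) else stats::qt(0.975, df = G - 1)
  z <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf))
  p <- if (df == "normal") 2 * pnorm(-abs(z)) else 2 * stats::pt(-abs(z), df = G - 1)
  coefs <- tibble(
    term = colnames(X), estimate = beta, std_error = se,
    conf_low = beta - crit * se, conf_high = beta + crit * se, p_value = p
  )
  structure(list(
    coefficients = coefs, vcov = vcov_cl, n_areas = n, n_clusters = G,
    df = df, formula = formula, residuals = resid,
    r_squared = 1 - sum(resid^2) / sum((y - mean(y))^2)
  ), class = "ols_cluster")
}

#' @export
print.ols_cluster <- function(x, ...) {
  cat("<ols_cluster: n = ", x$n_areas, ", clusters = ", x$n_clusters,
      ", R^2 = ", format(x$r_squared, digits = 3), ">\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Tidy / glance methods for cluster-robust OLS
#'
#' @param x An `ols_cluster` fit.
#' @param ... Unused.
#' @return `tidy()`: one row per term with estimate, cluster-robust SE, 95%
#'   CI, and p-value. `glance()`: one-row model summary.
#' @method tidy ols_cluster
#' @export
tidy.ols_cluster <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.ols_cluster
#' @method glance ols_cluster
#' @export
glance.ols_cluster <- function(x, ...) {
  tibble(r_squared = x$r_squared, n_areas = x$n_areas,
         n_clusters = x$n_clusters, df_method = x$df)
}

#' Build contiguity spatial weights for an area layer
#'
#' Adjacency by shared geometry: queen contiguity links areas sharing at
#' least one polygon vertex, rook contiguity requires at least two shared
#' vertices (a shared edge, exact for grid-aligned layers). Weights are
#' row-standardized; islands (areas with no neighbor) keep an all-zero row and
#' are reported.
#'
#' @param layer An [area_layer()].
#' @param rule `"queen"` (default) or `"rook"`.
#' @param digits Vertex coordinates are keyed after rounding to this many
#'   decimal places.
#' @return A `spatial_weights` object: row-standardized matrix `w`, binary
#'   adjacency `adjacency`, and `area_id`.
#' @export
build_contiguity_weights <- function(layer, rule = c("queen", "rook"),
                                     digits = 9L) {
  rule <- match.arg(rule)
  n <- nrow(layer$areas)
  keys <- lapply(layer$areas$geometry, function(rings) {
    v <- do.call(rbind, rings)
    unique(paste(round(v[, 1L], digits), round(v[, 2L], digits)))
  })
  adj <- matrix(0L, n, n, dimnames = list(layer$areas$area_id,
                                          layer$areas$area_id))
  min_shared <- if (rule == "queen") 1L else 2L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (length(intersect(keys[[i]], keys[[j]])) >= min_shared) {
        adj[i, j] <- adj[j, i] <- 1L
      }
    }
  }
  rs <- rowSums(adj)
  if (any(rs == 0L)) {
    inform(paste0("build_contiguity_weights: ", sum(rs == 0L),
                  " island area(s) with no neighbors"))
  }
  w <- adj / ifelse(rs == 0L, 1, rs)
  structure(list(w = w, adjacency = adj, area_id = layer$areas$area_id,
                 rule = rule), class = "spatial_weights")
}

#' Moran's I spatial autocorrelation
#'
#' Global Moran's I:
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with `S0` the sum of all weights. Under the permutation null its
#' expectation is `-1/(n-1)`; positive values indicate spatial clustering of
#' similar values.
#'
#' @param values Numeric vector, one value per area, in the weights' area
#'   order (or named by area id).
#' @param weights A `spatial_weights` object (or a bare matrix).
#' @return Moran's I statistic.
#' @export
morans_i <- function(values, weights) {
  w <- if (inherits(weights, "spatial_weights")) weights$w else as.matrix(weights)
  if (inherits(weights, "spatial_weights") && !is.null(names(values))) {
    values <- values[weights$area_id]
  }
  n <- length(values)
  if (n < 3L) abort("need at least 3 areas")
  if (nrow(w) != n) abort("weights dimension does not match values length")
  x <- values - mean(values)
  denom <- sum(x^2)
  if (denom == 0) abort("cannot compute Moran's I on constant values")
  s0 <- sum(w)
  (n / s0) * drop(crossprod(x, w %*% x)) / denom
}
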