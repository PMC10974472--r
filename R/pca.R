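#' Standardize a feature table
#'
#' Centres and scales each feature column to mean 0, SD 1. The 11 registry
#' variables mix seconds, metres, metres per second and newtons, so the
#' principal component analysis operates on z-scores (a correlation-matrix
#' PCA); raw covariance across incommensurate units would be meaningless.
#'
#' @param data Data frame containing the feature columns (other columns
#'   pass through untouched).
#' @param features Character vector of columns to standardize.
#' @return A tibble like `data` with the feature columns standardized;
#'   attributes `center` and `scale` hold the column means and SDs.
#' @export
standardize_features <- function(data, features = gi_features()) {
  check_feature_columns(data, features)
  x <- as.matrix(data[features])
  mu <- colMeans(x)
  sds <- apply(x, 2, sd)
  bad <- names(sds)[sds <= 0 | !is.finite(sds)]
  if (length(bad) > 0) {
    abort(sprintf("Zero-variance feature column(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  z <- sweep(sweep(x, 2, mu), 2, sds, "/")
  out <- as_tibble(data)
  out[features] <- as_tibble(z)
  attr(out, "center") <- mu
  attr(out, "scale") <- sds
  out
}

check_feature_columns <- function(data, features) {
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    abort(sprintf("Feature column(s) not found: %s.",
                  paste(missing, collapse = ", ")))
  }
  if (anyNA(data[features])) {
    abort("Feature table contains missing values.")
  }
  invisible(data)
}

#' Principal component analysis of a gait-initiation feature table
#'
#' Fits a correlation-matrix PCA: features are z-scored, and the loadings
#' are the right singular vectors of the standardized data matrix (the SVD
#' route is numerically stable even with fewer rows than features).
#' Loadings are orthonormal; each component's sign is fixed so its
#' largest-magnitude coefficient is positive, making results reproducible
#' across platforms. Explained-variance fractions are the normalized
#' eigenvalues of the sample correlation matrix.
#'
#' The model is fit once on the pooled table (both groups); bootstrap
#' resampling downstream reuses these fixed loadings.
#'
#' @param data Data frame of participants x features (id/group columns are
#'   carried along, not used in the fit).
#' @param features Feature columns to use.
#' @return A `gi_pca` object with elements `center`, `scale`, `loadings`
#'   (p x p), `eigenvalues`, `explained_fraction`, `features`, `n`, and
#'   `scores` (tibble of the training scores with pass-through columns).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(seed = 1))
#' pca <- fit_pca(cohort)
#' glance(pca)
fit_pca <- function(data, features = gi_features()) {
  check_feature_columns(data, features)
  n <- nrow(data)
  p <- length(features)
  if (n < 2) abort("PCA needs at least 2 rows.")
  z <- standardize_features(data, features)
  zm <- as.matrix(z[features])

  sv <- svd(zm, nu = 0, nv = p)
  lam <- rep(0, p)
  lam[seq_along(sv$d)] <- sv$d^2 / (n - 1)
  v <- sv$v
  # deterministic sign: largest-|coefficient| entry of each PC is positive
  for (j in seq_len(p)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  dimnames(v) <- list(features, paste0("PC", seq_len(p)))

  model <- structure(
    list(center = attr(z, "center"), scale = attr(z, "scale"),
         loadings = v, eigenvalues = lam,
         explained_fraction = lam / sum(lam),
         features = features, n = n),
    class = "gi_pca")
  model$scores <- project(model, data, k = p)
  model
}

#' Project a feature table onto principal components
#'
#' @param model A `gi_pca`.
#' @param data Data frame with the model's feature columns.
#' @param k Number of leading components to keep.
#' @return Tibble of non-feature pass-through columns plus `PC1..PCk`.
#' @export
project <- function(model, data, k = NULL) {
  stopifnot(inherits(model, "gi_pca"))
  feats <- model$features
  k <- k %||% length(feats)
  if (k < 1 || k > length(feats)) abort("`k` must be in 1..p.")
  check_feature_columns(data, feats)
  x <- as.matrix(data[feats])
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  s <- z %*% model$loadings[, seq_len(k), drop = FALSE]
  extras <- as_tibble(data)[setdiff(names(data), feats)]
  dplyr::bind_cols(extras, as_tibble(s))
}

#' Number of components needed to reach a cumulative-variance threshold
#'
#' @param model A `gi_pca`.
#' @param threshold Cumulative explained-variance fraction (default 0.999,
#'   the conventional near-lossless cut).
#' @return Integer component count.
#' @export
choose_k <- function(model, threshold = 0.999) {
  stopifnot(inherits(model, "gi_pca"))
  unname(which(cumsum(model$explained_fraction) >= threshold - 1e-12)[1])
}

#' @export
print.gi_pca <- function(x, ...) {
  cat(sprintf("<gi_pca> %d rows x %d features\n", x$n, length(x$features)))
  ev <- x$explained_fraction
  cat("explained variance:",
      paste(sprintf("PC%d %.1f%%", seq_len(min(4, length(ev))),
                    100 * ev[seq_len(min(4, length(ev)))]),
            collapse = ", "),
      if (length(ev) > 4) "...", "\n")
  invisible(x)
}

#' @rdname fit_pca
#' @param x A `gi_pca`.
#' @param ... Unused.
#' @method tidy gi_pca
#' @export
tidy.gi_pca <- function(x, ...) {
  l <- x$loadings
  tibble(
    feature = rep(rownames(l), times = ncol(l)),
    component = rep(colnames(l), each = nrow(l)),
    loading = as.vector(l))
}

#' @rdname fit_pca
#' @method glance gi_pca
#' @export
glance.gi_pca <- function(x, ...) {
  tibble(n = x$n, p = length(x$features),
         k_999 = choose_k(x, 0.999),
         pc1_fraction = x$explained_fraction[1],
         cum3_fraction = sum(x$explained_fraction[seq_len(min(3, length(x$explained_fraction)))]))
}

#' @rdname fit_pca
#' @param newdata Data frame to score; defaults to the training scores.
#' @method augment gi_pca
#' @export
augment.gi_pca <- function(x, newdata = NULL, ...) {
  if (is.null(newdata)) return(x$scores)
  dplyr::bind_cols(as_tibble(newdata),
                   project(x, newdata)[paste0("PC", seq_along(x$features))])
}

#' Serialize / restore a PCA model as JSON
#'
#' Flat-text persistence (means, SDs, loadings, explained fractions) so a
#' fitted decomposition can be reused by a later classification run.
#'
#' @param model A `gi_pca`.
#' @param path Output JSON path.
#' @return `path` invisibly; `pca_from_json()` returns the restored
#'   `gi_pca` (without training scores).
#' @export
pca_to_json <- function(model, path) {
  stopifnot(inherits(model, "gi_pca"))
  obj <- list(features = model$features,
              center = unname(model$center),
              scale = unname(model$scale),
              loadings = unname(model$loadings),
              eigenvalues = model$eigenvalues,
              n = model$n)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname pca_to_json
#' @export
pca_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- obj$features
  l <- obj$loadings
  if (!is.matrix(l)) {
    # stored row-major as a list of rows
    l <- matrix(unlist(l), nrow = length(feats), byrow = TRUE)
  }
  dimnames(l) <- list(feats, paste0("PC", seq_along(feats)))
  structure(
    list(center = stats::setNames(obj$center, feats),
         scale = stats::setNames(obj$scale, feats),
         loadings = l, eigenvalues = obj$eigenvalues,
         explained_fraction = obj$eigenvalues / sum(obj$eigenvalues),
         features = feats, n = obj$n),
    class = "gi_pca")
}
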