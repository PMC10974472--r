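#' Bootstrap the mean of a score table
#'
#' Resamples the rows of a score table with replacement `B` times and
#' stores each replicate's column-mean vector. The cloud of bootstrapped
#' means approximates the sampling distribution of the group mean; its 95\%
#' confidence ellipse is much tighter than that of the raw samples (SD
#' smaller by about `1/sqrt(n)`), which is what sharpens the downstream
#' group separation. The resampling unit is the participant (one row), and
#' the draw is deterministic given `seed`.
#'
#' @param data Data frame of scores (one row per participant).
#' @param cols Columns to bootstrap; defaults to all `PC*` columns, or all
#'   numeric columns if none match.
#' @param B Number of bootstrap replicates (default 10000).
#' @param seed Integer seed.
#' @param group Optional label carried into the result.
#' @return A `gi_boot`: list with `group`, `B`, `means` (tibble of
#'   `replicate` plus one column per score), `sample_mean` and `cov` (the
#'   cloud covariance).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(seed = 1))
#' scores <- project(fit_pca(cohort), cohort, k = 3)
#' cloud <- bootstrap_means(scores, B = 500, seed = 7)
#' cloud$sample_mean
bootstrap_means <- function(data, cols = NULL, B = 10000, seed = NULL,
                            group = NULL) {
  if (is.null(cols)) {
    cols <- grep("^PC[0-9]+$", names(data), value = TRUE)
    if (length(cols) == 0L) {
      cols <- names(data)[vapply(data, is.numeric, logical(1))]
    }
  }
  x <- as.matrix(as.data.frame(data)[cols])
  n <- nrow(x)
  if (n < 2L) abort("Bootstrapping needs at least 2 rows.")
  if (B < 1L) abort("`B` must be at least 1.")

  means <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    vapply(seq_along(cols),
           function(j) rowMeans(matrix(x[, j][idx], nrow = B)),
           numeric(B))
  })
  colnames(means) <- cols

  structure(
    list(group = group, B = as.integer(B),
         means = dplyr::bind_cols(tibble(replicate = seq_len(B)),
                                  as_tibble(means)),
         sample_mean = colMeans(x),
         cov = cov(means)),
    class = "gi_boot")
}

#' @export
print.gi_boot <- function(x, ...) {
  cat(sprintf("<gi_boot>%s %d replicates of a %d-D mean\n",
              if (is.null(x$group)) "" else paste0(" [", x$group, "]"),
              x$B, length(x$sample_mean)))
  invisible(x)
}

#' Bootstrap per-group mean score clouds
#'
#' Convenience wrapper running [bootstrap_means()] independently for each
#' level of `group_col`, on independent seeded streams.
#'
#' @param data Score table including a group column.
#' @param group_col Name of the grouping column.
#' @inheritParams bootstrap_means
#' @return Named list of `gi_boot`, one per group level.
#' @export
bootstrap_group_means <- function(data, group_col = "group", cols = NULL,
                                  B = 10000, seed = NULL) {
  if (!group_col %in% names(data)) {
    abort(sprintf("Column `%s` not found.", group_col))
  }
  levels <- unique(as.character(data[[group_col]]))
  out <- lapply(seq_along(levels), function(i) {
    g <- levels[i]
    sub <- data[data[[group_col]] == g, , drop = FALSE]
    bootstrap_means(sub, cols = cols, B = B,
                    seed = if (is.null(seed)) NULL else derive_seed(seed + i, "misc"),
                    group = g)
  })
  stats::setNames(out, levels)
}

#' Confidence ellipse of a 2-D point cloud
#'
#' Fits the Gaussian confidence ellipse: centre at the cloud mean, shape
#' given by the cloud covariance, boundary at the chi-square(2) quantile of
#' `level`. A point `x` is inside when its squared Mahalanobis distance
#' `(x - c)' S^{-1} (x - c)` is at most `qchisq(level, 2)`.
#'
#' @param points Data frame or matrix with two columns (at least 3 rows).
#' @param level Coverage probability (default 0.95).
#' @return A `gi_ellipse`: list with `center`, `shape` (2 x 2 covariance),
#'   `level` and `radius2` (the chi-square quantile).
#' @export
confidence_ellipse <- function(points, level = 0.95) {
  x <- as.matrix(as.data.frame(points))
  if (ncol(x) != 2L) abort("`points` must have exactly 2 columns.")
  if (nrow(x) < 3L) abort("Need at least 3 points to fit an ellipse.")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  s <- cov(x)
  r <- qr(s)$rank
  if (r < 2L || det(s) <= 0) {
    abort(sprintf("Cloud covariance is singular (rank %d); cannot form an ellipse.", r))
  }
  structure(
    list(center = colMeans(x), shape = s, level = level,
         radius2 = qchisq(level, df = 2)),
    class = "gi_ellipse")
}

#' @rdname confidence_ellipse
#' @param ellipse A `gi_ellipse`.
#' @return `in_ellipse()`: logical vector; `ellipse_area()`: the area
#'   enclosed by the boundary; `ellipse_path()`: tibble of boundary
#'   coordinates for plotting.
#' @export
in_ellipse <- function(ellipse, points) {
  stopifnot(inherits(ellipse, "gi_ellipse"))
  x <- as.matrix(as.data.frame(points))
  if (ncol(x) != 2L) abort("`points` must have exactly 2 columns.")
  mahalanobis(x, ellipse$center, ellipse$shape) <= ellipse$radius2
}

#' @rdname confidence_ellipse
#' @export
ellipse_area <- function(ellipse) {
  stopifnot(inherits(ellipse, "gi_ellipse"))
  pi * ellipse$radius2 * sqrt(det(ellipse$shape))
}

#' @rdname confidence_ellipse
#' @param n_points Boundary resolution.
#' @export
ellipse_path <- function(ellipse, n_points = 181) {
  stopifnot(inherits(ellipse, "gi_ellipse"))
  eg <- eigen(ellipse$shape, symmetric = TRUE)
  theta <- seq(0, 2 * pi, length.out = n_points)
  circ <- rbind(cos(theta), sin(theta)) * sqrt(ellipse$radius2)
  xy <- t(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * circ) + ellipse$center)
  tibble(x = xy[, 1], y = xy[, 2])
}

#' @export
print.gi_ellipse <- function(x, ...) {
  cat(sprintf("<gi_ellipse> level %.2f, center (%.3g, %.3g), area %.3g\n",
              x$level, x$center[1], x$center[2], ellipse_area(x)))
  invisible(x)
}

#' Jaccard overlap of two point clouds
#'
#' Quantifies cluster separation as the Jaccard similarity
#' `J = |A intersect B| / |A union B|` applied to the two clouds of
#' bootstrapped means. The set elements are the points of both clouds;
#' membership "in A" means lying inside cloud A's `level` confidence
#' ellipse (`method = "membership"`, the default, which uses only the
#' objects the analysis already constructs). `method = "area"` instead
#' estimates the geometric area Jaccard of the two ellipses by seeded
#' Monte-Carlo integration.
#'
#' `J = 1` when the clouds coincide, `J = 0` when the ellipses are
#' disjoint, and J decreases monotonically as the cloud centroids move
#' apart. The coefficient is symmetric in its arguments.
#'
#' @param cloud_a,cloud_b Two-column data frames/matrices of points (e.g.
#'   the `means` of a [bootstrap_means()] restricted to one PC pair).
#' @param level Confidence level of the per-cloud ellipses.
#' @param method `"membership"` (point counting) or `"area"` (ellipse area
#'   ratio by Monte-Carlo).
#' @param n_mc,seed Monte-Carlo sample size and seed for `method = "area"`.
#' @return Jaccard coefficient in `[0, 1]`.
#' @export
jaccard_overlap <- function(cloud_a, cloud_b, level = 0.95,
                            method = c("membership", "area"),
                            n_mc = 100000, seed = NULL) {
  method <- match.arg(method)
  a <- as.matrix(as.data.frame(cloud_a))
  b <- as.matrix(as.data.frame(cloud_b))
  if (ncol(a) != 2L || ncol(b) != 2L) {
    abort("Clouds must have exactly 2 columns.")
  }
  ea <- confidence_ellipse(a, level)
  eb <- confidence_ellipse(b, level)

  if (method == "membership") {
    pts <- rbind(a, b)
    in_a <- in_ellipse(ea, pts)
    in_b <- in_ellipse(eb, pts)
    union_n <- sum(in_a | in_b)
    if (union_n == 0L) {
      warn("No point of either cloud lies inside either ellipse; J set to 0.")
      return(0)
    }
    return(sum(in_a & in_b) / union_n)
  }

  # area method: uniform sampling over the joint bounding box
  box <- function(e) {
    half <- sqrt(diag(e$shape) * e$radius2)
    rbind(e$center - half, e$center + half)
  }
  bb <- rbind(box(ea), box(eb))
  lo <- apply(bb, 2, min)
  hi <- apply(bb, 2, max)
  with_seed(seed, {
    u <- cbind(runif(n_mc, lo[1], hi[1]), runif(n_mc, lo[2], hi[2]))
    in_a <- in_ellipse(ea, u)
    in_b <- in_ellipse(eb, u)
    union_n <- sum(in_a | in_b)
    if (union_n == 0L) {
      warn("Monte-Carlo union is empty; J set to 0.")
      return(0)
    }
    sum(in_a & in_b) / union_n
  })
}
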