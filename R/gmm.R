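#' Fit a Gaussian mixture model by expectation-maximization
#'
#' Full-covariance GMM for unsupervised classification of score clouds.
#' The E-step computes posterior responsibilities from the current
#' component densities; the M-step re-estimates weights, means and
#' covariances from the weighted data. The log-likelihood is guaranteed
#' non-decreasing across iterations; the fit stops when its relative
#' improvement falls below `tol` or after `max_iter` iterations.
#'
#' Means are initialized by k-means++-style seeding (spread-out data
#' points), weights uniformly, covariances at the pooled data covariance.
#' `n_init` independent seeded initializations are run and the best final
#' log-likelihood kept. Covariance eigenvalues are floored at `reg_floor`
#' to keep components from collapsing onto near-degenerate clouds; a
#' component that still collapses (vanishing weight) is re-seeded with a
#' warning, and the fit aborts if collapse repeats.
#'
#' @param data Data frame or matrix of points (rows) to cluster.
#' @param K Number of mixture components (default 2: one per group).
#' @param cols Columns to use; defaults to all numeric columns.
#' @param seed Integer seed controlling initialization.
#' @param tol Relative log-likelihood improvement defining convergence.
#' @param max_iter Maximum EM iterations per initialization.
#' @param n_init Number of random restarts.
#' @param reg_floor Eigenvalue floor for component covariances.
#' @return A `gi_gmm`: `weights`, `means` (K x d), `covariances` (list of
#'   d x d), `loglik`, `loglik_trace`, `converged`, `iterations`, plus the
#'   data dimension and column names.
#' @export
#' @examples
#' pts <- rbind(matrix(rnorm(200), ncol = 2),
#'              matrix(rnorm(200, mean = 5), ncol = 2))
#' fit <- fit_gmm(pts, K = 2, seed = 1)
#' glance(fit)
fit_gmm <- function(data, K = 2, cols = NULL, seed = NULL,
                    tol = 1e-8, max_iter = 500, n_init = 10,
                    reg_floor = 1e-8) {
  x <- gmm_matrix(data, cols)
  m <- nrow(x)
  d <- ncol(x)
  if (K < 1) abort("`K` must be at least 1.")
  if (m <= K * d) abort("Need more points than K * d to fit a GMM.")

  if (K == 1L) n_init <- 1L
  best <- NULL
  for (i in seq_len(n_init)) {
    init_seed <- if (is.null(seed)) NULL else derive_seed(seed + i, "gmm")
    fit <- with_seed(init_seed,
                     em_gmm(x, K, tol = tol, max_iter = max_iter,
                            reg_floor = reg_floor))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best$columns <- colnames(x)
  best$n <- m
  class(best) <- "gi_gmm"
  best
}

gmm_matrix <- function(data, cols = NULL) {
  d <- as.data.frame(data)
  if (is.null(cols)) {
    cols <- names(d)[vapply(d, is.numeric, logical(1))]
  }
  x <- as.matrix(d[cols])
  storage.mode(x) <- "double"
  if (anyNA(x)) abort("Points contain missing values.")
  x
}

# one EM run from a fresh k-means++ seeding; assumes RNG already seeded
em_gmm <- function(x, K, tol, max_iter, reg_floor) {
  m <- nrow(x)
  d <- ncol(x)
  pooled <- cov(x) + diag(reg_floor, d)

  mu <- x[kmeanspp_seeds(x, K), , drop = FALSE]
  w <- rep(1 / K, K)
  sig <- replicate(K, pooled, simplify = FALSE)

  trace <- numeric(0)
  converged <- FALSE
  collapses <- 0L
  ll_prev <- -Inf
  logdens <- matrix(0, m, K)

  for (iter in seq_len(max_iter)) {
    for (k in seq_len(K)) {
      logdens[, k] <- log(w[k]) + dmvnorm_log(x, mu[k, ], sig[[k]])
    }
    lmax <- apply(logdens, 1, max)
    lse <- lmax + log(rowSums(exp(logdens - lmax)))
    ll <- sum(lse)
    trace <- c(trace, ll)

    resp <- exp(logdens - lse)
    nk <- colSums(resp)

    if (any(nk < d + 1e-8)) {
      # component collapse: re-seed the starved component
      collapses <- collapses + 1L
      if (collapses > 5L) {
        abort("GMM component collapsed repeatedly; data cannot support K components.")
      }
      warn("GMM component collapsed; re-initializing it.")
      k_bad <- which.min(nk)
      mu[k_bad, ] <- x[sample.int(m, 1L), ]
      sig[[k_bad]] <- pooled
      w <- rep(1 / K, K)
      ll_prev <- -Inf
      next
    }

    w <- nk / m
    for (k in seq_len(K)) {
      mu[k, ] <- colSums(resp[, k] * x) / nk[k]
      xc <- sweep(x, 2, mu[k, ])
      s <- crossprod(xc * sqrt(resp[, k])) / nk[k]
      sig[[k]] <- floor_eigenvalues(s, reg_floor)
    }

    if (is.finite(ll_prev) && (ll - ll_prev) < tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }

  list(K = K, weights = w, means = mu, covariances = sig,
       loglik = trace[length(trace)], loglik_trace = trace,
       converged = converged, iterations = length(trace))
}

kmeanspp_seeds <- function(x, K) {
  m <- nrow(x)
  seeds <- sample.int(m, 1L)
  if (K > 1L) {
    for (k in 2:K) {
      d2 <- apply(x, 1, function(p) {
        min(colSums((t(x[seeds, , drop = FALSE]) - p)^2))
      })
      if (sum(d2) <= 0) {
        seeds <- c(seeds, sample.int(m, 1L))
      } else {
        seeds <- c(seeds, sample.int(m, 1L, prob = d2))
      }
    }
  }
  seeds
}

floor_eigenvalues <- function(s, floor_val) {
  eg <- eigen((s + t(s)) / 2, symmetric = TRUE)
  if (all(eg$values >= floor_val)) return((s + t(s)) / 2)
  v <- pmax(eg$values, floor_val)
  eg$vectors %*% (v * t(eg$vectors))
}

# log multivariate normal density via Cholesky
dmvnorm_log <- function(x, mean, sigma) {
  d <- ncol(x)
  ch <- chol(sigma)
  xc <- sweep(x, 2, mean)
  z <- backsolve(ch, t(xc), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

#' Classify points with a fitted mixture model
#'
#' Assigns each point to the component with the largest posterior
#' responsibility and reports the responsibilities themselves (each row
#' sums to 1).
#'
#' @param model A `gi_gmm`.
#' @param data Points to classify (same columns/dimension as the fit).
#' @return Tibble with `cluster` (integer) and `resp_1 .. resp_K`.
#' @export
classify <- function(model, data) {
  stopifnot(inherits(model, "gi_gmm"))
  cols <- intersect(model$columns, names(as.data.frame(data)))
  x <- gmm_matrix(data, if (length(cols) == ncol(model$means)) cols else NULL)
  if (ncol(x) != ncol(model$means)) {
    abort(sprintf("Dimension mismatch: model is %d-D, data is %d-D.",
                  ncol(model$means), ncol(x)))
  }
  ld <- vapply(seq_len(model$K), function(k) {
    log(model$weights[k]) + dmvnorm_log(x, model$means[k, ], model$covariances[[k]])
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) ld <- matrix(ld, nrow = 1)
  lmax <- apply(ld, 1, max)
  resp <- exp(ld - (lmax + log(rowSums(exp(ld - lmax)))))
  colnames(resp) <- paste0("resp_", seq_len(model$K))
  dplyr::bind_cols(tibble(cluster = max.col(resp)), as_tibble(resp))
}

#' @export
print.gi_gmm <- function(x, ...) {
  cat(sprintf("<gi_gmm> K = %d, %d-D, loglik %.2f after %d iterations (%s)\n",
              x$K, ncol(x$means), x$loglik, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @rdname fit_gmm
#' @param x A `gi_gmm`.
#' @param ... Unused.
#' @method tidy gi_gmm
#' @export
tidy.gi_gmm <- function(x, ...) {
  purrr::map_dfr(seq_len(x$K), function(k) {
    tibble(component = k, weight = x$weights[k],
           dimension = x$columns %||% paste0("x", seq_len(ncol(x$means))),
           mean = x$means[k, ],
           variance = diag(x$covariances[[k]]))
  })
}

#' @rdname fit_gmm
#' @method glance gi_gmm
#' @export
glance.gi_gmm <- function(x, ...) {
  d <- ncol(x$means)
  n_par <- (x$K - 1) + x$K * d + x$K * d * (d + 1) / 2
  tibble(K = x$K, loglik = x$loglik, iterations = x$iterations,
         converged = x$converged,
         bic = -2 * x$loglik + n_par * log(x$n))
}
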