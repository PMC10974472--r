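# Shared fixtures and oracles, all generated in code.

# isotropic Gaussian blob around a 2-D center
blob2d <- function(n, center = c(0, 0), sd = 1) {
  cbind(rnorm(n, center[1], sd), rnorm(n, center[2], sd))
}

# Independent brute-force membership Jaccard: literal count over the pooled
# points using explicit quadratic forms (no package ellipse machinery).
jaccard_bruteforce <- function(a, b, level = 0.95) {
  inside <- function(pts, cloud) {
    c0 <- colMeans(cloud)
    s <- stats::cov(cloud)
    si <- solve(s)
    r2 <- stats::qchisq(level, 2)
    apply(pts, 1, function(p) {
      d <- p - c0
      as.numeric(t(d) %*% si %*% d) <= r2
    })
  }
  pts <- rbind(a, b)
  ia <- inside(pts, a)
  ib <- inside(pts, b)
  if (sum(ia | ib) == 0) return(0)
  sum(ia & ib) / sum(ia | ib)
}

# Calibrate the cohort effect multiplier so the bootstrapped-mean ellipse
# overlap in one PC subspace reaches the target band: grid scan (J is not
# monotone in the effect for the later-PC subspaces, where separation also
# reflects finite-sample mean differences), refined around the best point.
calibrate_effect <- function(subspace, seed, target = 0.10, B = 1500,
                             grid = seq(0, 1.2, by = 0.05)) {
  eval_j <- function(effect) {
    co <- simulate_cohort(cohort_spec(effect = effect, seed = seed))
    pca <- fit_pca(co)
    sc <- project(pca, co, k = max(subspace))
    cl <- bootstrap_group_means(sc, "group", B = B, seed = seed + 1)
    pcs <- paste0("PC", subspace)
    jaccard_overlap(cl[[1]]$means[pcs], cl[[2]]$means[pcs])
  }
  js <- vapply(grid, eval_j, numeric(1))
  i <- which.min(abs(js - target))
  list(effect = grid[i], j = js[i])
}

# Pooled bootstrapped-mean clouds for a cohort in one PC pair, with labels.
pooled_cloud <- function(cohort, subspace, B, seed) {
  pca <- fit_pca(cohort)
  sc <- project(pca, cohort, k = max(subspace))
  cl <- bootstrap_group_means(sc, "group", B = B, seed = seed)
  pcs <- paste0("PC", subspace)
  dplyr::bind_rows(
    dplyr::mutate(cl[[1]]$means[pcs], group = cl[[1]]$group),
    dplyr::mutate(cl[[2]]$means[pcs], group = cl[[2]]$group))
}
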