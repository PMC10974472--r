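test_that("standardization gives exact z-scores and inverts cleanly", {
  co <- simulate_cohort(cohort_spec(seed = 11))
  z <- standardize_features(co)
  zm <- as.matrix(z[gi_features()])
  expect_true(all(abs(colMeans(zm)) < 1e-12))
  expect_equal(unname(apply(zm, 2, sd)), rep(1, 11))

  # unit invariance: rescaling a column does not change its z-scores
  co2 <- dplyr::mutate(co, fz_peak = fz_peak * 1000)
  z2 <- standardize_features(co2)
  expect_equal(z2$fz_peak, z$fz_peak, tolerance = 1e-12)

  # round trip
  back <- sweep(sweep(zm, 2, attr(z, "scale"), "*"), 2, attr(z, "center"), "+")
  expect_equal(unname(back), unname(as.matrix(co[gi_features()])),
               tolerance = 1e-12)

  co$apa_ml <- 0.5
  expect_error(standardize_features(co), "apa_ml")
})

test_that("PCA matches an independent eigendecomposition oracle", {
  set.seed(401)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    co <- simulate_cohort(cohort_spec(n_control = ceiling(n / 2),
                                      n_pd = floor(n / 2) + (n < 4),
                                      seed = 500 + rep))
    co <- co[seq_len(n), ]
    pca <- fit_pca(co)
    z <- as.matrix(standardize_features(co)[gi_features()])
    ev <- eigen(cov(z), symmetric = TRUE)
    expect_equal(pca$eigenvalues, pmax(ev$values, 0), tolerance = 1e-8)
    # leading subspaces agree: projector difference small for the
    # components with non-degenerate eigenvalues
    r <- sum(ev$values > 1e-10)
    gaps <- abs(diff(ev$values))
    for (j in seq_len(min(3, r))) {
      # eigenvectors are only identified when the eigenvalue is isolated
      gap <- min(if (j > 1) gaps[j - 1] else Inf, gaps[j])
      if (gap < 1e-4) next
      dot <- abs(sum(pca$loadings[, j] * ev$vectors[, j]))
      expect_equal(dot, 1, tolerance = 1e-8)
    }
  }
})

test_that("data on a line loads entirely on the first component", {
  set.seed(7)
  u <- rnorm(50)
  d <- tibble::tibble(a = 3 * u + 1, b = -2 * u + 5)
  z <- standardize_features(d, features = c("a", "b"))
  pca <- fit_pca(d, features = c("a", "b"))
  expect_equal(pca$explained_fraction, c(1, 0), tolerance = 1e-12)
  expect_equal(abs(pca$loadings[, 1]), c(a = 1, b = 1) / sqrt(2),
               tolerance = 1e-10)
})

test_that("isotropic data splits explained variance evenly", {
  set.seed(8)
  d <- tibble::tibble(a = rnorm(10000), b = rnorm(10000))
  pca <- fit_pca(d, features = c("a", "b"))
  expect_true(all(pca$explained_fraction > 0.49 &
                    pca$explained_fraction < 0.51))
})

test_that("loadings are orthonormal and projection preserves variance", {
  co <- simulate_cohort(cohort_spec(seed = 21))
  pca <- fit_pca(co)
  g <- t(pca$loadings) %*% pca$loadings
  expect_lt(max(abs(g - diag(11))), 1e-10)
  expect_equal(sum(pca$explained_fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(pca$explained_fraction) <= 1e-12))

  sc <- project(pca, co, k = 11)
  sm <- as.matrix(sc[paste0("PC", 1:11)])
  expect_equal(sum(apply(sm, 2, var)), 11, tolerance = 1e-10)
  # scores mutually uncorrelated where variance is non-degenerate
  keep <- pca$eigenvalues > 1e-12
  cc <- cor(sm[, keep])
  expect_lt(max(abs(cc - diag(sum(keep)))), 1e-8)
})

test_that("the sign convention makes each PC's largest coefficient positive", {
  co <- simulate_cohort(cohort_spec(seed = 31))
  pca <- fit_pca(co)
  for (j in 1:11) {
    l <- pca$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("row permutation permutes scores identically", {
  co <- simulate_cohort(cohort_spec(seed = 41))
  pca <- fit_pca(co)
  perm <- sample(nrow(co))
  s1 <- project(pca, co)[perm, paste0("PC", 1:3)]
  s2 <- project(pca, co[perm, ])[, paste0("PC", 1:3)]
  expect_equal(as.data.frame(s1), as.data.frame(s2), ignore_attr = TRUE)
})

test_that("estimated leading subspace converges to the population eigenspace", {
  spec <- cohort_spec(n_control = 20000, n_pd = 20000, effect = 0, seed = 51)
  co <- simulate_cohort(spec)
  pca <- fit_pca(co)
  # population correlation matrix of the generator
  sds <- sqrt(diag(spec$covariance))
  R <- diag(1 / sds) %*% spec$covariance %*% diag(1 / sds)
  pop <- eigen(R, symmetric = TRUE)
  angle <- acos(min(1, abs(sum(pca$loadings[, 1] * pop$vectors[, 1]))))
  expect_lt(angle * 180 / pi, 2)
})

test_that("a constructed 3-dominant spectrum reaches 99.9% with k = 3", {
  # covariance with three large eigenvalues carrying 99.95% of the trace
  set.seed(61)
  q <- qr.Q(qr(matrix(rnorm(121), 11)))
  lam <- c(60, 30, 10, rep(0.001, 8))
  sigma <- q %*% diag(lam) %*% t(q)
  # effect = 0 so all variance comes from the constructed covariance
  spec <- cohort_spec(n_control = 25, n_pd = 25, effect = 0,
                      covariance = sigma, seed = 62)
  co <- simulate_cohort(spec)
  pca <- fit_pca(co)
  expect_gte(cumsum(pca$explained_fraction)[3], 0.999)
  expect_lte(choose_k(pca, 0.999), 3)
})

test_that("PCA JSON serialization round-trips the model", {
  co <- simulate_cohort(cohort_spec(seed = 71))
  pca <- fit_pca(co)
  p <- withr::local_tempfile(fileext = ".json")
  pca_to_json(pca, p)
  back <- pca_from_json(p)
  expect_equal(back$loadings, pca$loadings, tolerance = 1e-12)
  expect_equal(back$center, pca$center, tolerance = 1e-12)
  expect_equal(back$scale, pca$scale, tolerance = 1e-12)
  s1 <- project(pca, co, k = 3)
  s2 <- project(back, co, k = 3)
  expect_equal(as.data.frame(s1), as.data.frame(s2), tolerance = 1e-12)
})

test_that("tidy, glance and augment expose the fit in broom style", {
  co <- simulate_cohort(cohort_spec(seed = 81))
  pca <- fit_pca(co)
  td <- tidy(pca)
  expect_equal(nrow(td), 121)
  expect_setequal(unique(td$feature), gi_features())
  gl <- glance(pca)
  expect_equal(gl$n, 20)
  expect_equal(gl$p, 11)
  au <- augment(pca)
  expect_true(all(paste0("PC", 1:11) %in% names(au)))
})
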