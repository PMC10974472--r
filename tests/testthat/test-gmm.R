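test_that("K = 1 reduces to the closed-form Gaussian fit", {
  set.seed(41)
  x <- matrix(rnorm(600), ncol = 2)
  fit <- fit_gmm(x, K = 1, seed = 1)
  expect_equal(as.numeric(fit$means), colMeans(x), tolerance = 1e-10)
  ml_cov <- cov(x) * (nrow(x) - 1) / nrow(x)
  expect_equal(unname(fit$covariances[[1]]), unname(ml_cov), tolerance = 1e-10)
  expect_equal(fit$weights, 1)
})

test_that("the EM log-likelihood trace is monotonically non-decreasing", {
  set.seed(42)
  x <- rbind(blob2d(300), blob2d(300, center = c(3, 1)))
  for (s in 1:5) {
    fit <- fit_gmm(x, K = 2, seed = s, n_init = 1)
    expect_true(all(diff(fit$loglik_trace) >= -1e-9 * abs(fit$loglik)))
  }
})

test_that("well-separated spherical clusters are recovered accurately", {
  set.seed(43)
  x <- rbind(blob2d(1000), blob2d(1000, center = c(10, 0)))
  fit <- fit_gmm(x, K = 2, seed = 7, n_init = 4)
  mu <- fit$means[order(fit$means[, 1]), ]
  expect_lt(max(abs(mu[1, ] - c(0, 0))), 0.1)
  expect_lt(max(abs(mu[2, ] - c(10, 0))), 0.1)
  expect_lt(max(abs(fit$weights - 0.5)), 0.02)
})

test_that("posteriors match a brute-force density oracle", {
  set.seed(44)
  x <- rbind(blob2d(200), blob2d(200, center = c(4, 2)))
  fit <- fit_gmm(x, K = 2, seed = 3, n_init = 2)
  cl <- classify(fit, x)

  dens <- function(p, mu, s) {
    d <- p - mu
    exp(-0.5 * as.numeric(t(d) %*% solve(s) %*% d)) /
      (2 * pi * sqrt(det(s)))
  }
  for (i in sample(nrow(x), 25)) {
    w <- vapply(1:2, function(k) {
      fit$weights[k] * dens(x[i, ], fit$means[k, ], fit$covariances[[k]])
    }, numeric(1))
    expect_equal(as.numeric(cl[i, c("resp_1", "resp_2")]), w / sum(w),
                 tolerance = 1e-12)
  }
  expect_equal(rowSums(as.matrix(cl[c("resp_1", "resp_2")])),
               rep(1, nrow(x)), tolerance = 1e-12)
})

test_that("classification is confident at means and ambivalent midway", {
  fit <- structure(
    list(K = 2L, weights = c(0.5, 0.5),
         means = rbind(c(0, 0), c(10, 0)),
         covariances = list(diag(2), diag(2)),
         loglik = 0, loglik_trace = 0, converged = TRUE,
         iterations = 1L, columns = c("x", "y"), n = 2L),
    class = "gi_gmm")
  at_mean <- classify(fit, rbind(c(0, 0)))
  expect_gt(at_mean$resp_1, 0.999)
  midway <- classify(fit, rbind(c(5, 0)))
  expect_equal(midway$resp_1, 0.5, tolerance = 1e-12)
  expect_error(classify(fit, rbind(c(1, 2, 3))), "[Dd]imension")
})

test_that("permuting input points permutes labels identically", {
  set.seed(45)
  x <- rbind(blob2d(150), blob2d(150, center = c(8, 0)))
  fit <- fit_gmm(x, K = 2, seed = 9, n_init = 2)
  perm <- sample(nrow(x))
  l1 <- classify(fit, x)$cluster[perm]
  l2 <- classify(fit, x[perm, ])$cluster
  expect_equal(l1, l2)
})

test_that("our EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(46)
  x <- rbind(blob2d(500), blob2d(500, center = c(6, -3)))
  fit <- fit_gmm(x, K = 2, seed = 11, n_init = 4)
  mc <- mclust::Mclust(x, G = 2, modelNames = "VVV", verbose = FALSE)
  mu_ours <- fit$means[order(fit$means[, 1]), ]
  mu_mc <- t(mc$parameters$mean)[order(mc$parameters$mean[1, ]), ]
  expect_equal(unname(mu_ours), unname(mu_mc), tolerance = 0.05)
})

test_that("confusion matrices are aligned optimally and row-normalized", {
  truth <- rep(c("control", "pd"), each = 5)
  perfect <- align_and_confuse(truth, c(rep(1, 5), rep(2, 5)))
  expect_equal(unname(diag(perfect$percent)), c(100, 100))
  expect_equal(perfect$accuracy, 1)

  # global label swap changes nothing after alignment
  swapped <- align_and_confuse(truth, c(rep(2, 5), rep(1, 5)))
  expect_equal(swapped$percent, perfect$percent)

  mixed <- align_and_confuse(truth, c(1, 1, 1, 1, 2, 2, 2, 2, 2, 1))
  expect_equal(rowSums(mixed$percent), c(control = 100, pd = 100))
  expect_equal(unname(mixed$group_accuracy), c(0.8, 0.8))

  expect_error(align_and_confuse(truth, c(1, 2, 3, rep(1, 7))),
               "More clusters")
  expect_error(align_and_confuse(truth[1:3], c(1, 2)), "length")
})

test_that("accuracy grows with group separation", {
  set.seed(47)
  accs <- vapply(c(0, 2, 6), function(d) {
    x <- rbind(blob2d(400), blob2d(400, center = c(d, 0)))
    truth <- rep(c("a", "b"), each = 400)
    fit <- fit_gmm(x, K = 2, seed = 13, n_init = 3)
    align_and_confuse(truth, classify(fit, x)$cluster)$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.02))
  expect_gt(accs[3], 0.99)
})
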