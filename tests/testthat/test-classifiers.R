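# The four supervised area classifiers.

two_blob_data <- function(n = 40, gap = 6, d = 2, seed = 21) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n * d), n, d),
               matrix(rnorm(n * d, mean = gap), n, d))
    list(x = x, y = rep(1:2, each = n))
  })
}

test_that("Gaussian Bayes classifier matches maximum-likelihood estimates", {
  # a class collapsed on one point has its mean at that point
  x <- rbind(matrix(rnorm(20), 10, 2), matrix(c(3, 4), 10, 2, byrow = TRUE))
  y <- rep(1:2, each = 10)
  m <- fit_bayes(x, y)
  expect_equal(m$models[[2]]$mean, c(3, 4))

  # far-separated classes classify held-out draws perfectly
  d <- two_blob_data()
  m2 <- fit_bayes(d$x, d$y)
  test <- two_blob_data(seed = 22)
  expect_equal(accuracy_pct(test$y, predict(m2, test$x)), 100)

  # log-density of the Gaussian at its mean with Sigma = I in 2-D
  pts <- rbind(c(sqrt(2), 0), c(-sqrt(2), 0), c(0, sqrt(2)), c(0, -sqrt(2)))
  mI <- fit_bayes(rbind(pts, pts + 100), rep(1:2, each = 4))
  sc <- predict(mI, matrix(c(0, 0), 1), type = "score")
  expect_equal(unname(sc[1, 1]), -log(2 * pi), tolerance = 1e-6)

  expect_error(fit_bayes(d$x, rep(1, nrow(d$x))),
               class = "visparc_missing_class_error")
})

test_that("GMM with one component reduces to the Gaussian MLE", {
  d <- two_blob_data()
  g <- fit_gmm(d$x, d$y, M = 1, seed = 3)
  b <- fit_bayes(d$x, d$y)
  for (k in 1:2) {
    expect_equal(as.numeric(g$mixtures[[k]]$means), b$models[[k]]$mean,
                 tolerance = 1e-8)
    expect_equal(g$mixtures[[k]]$covs[[1]], b$models[[k]]$cov,
                 tolerance = 1e-8)
    expect_equal(g$mixtures[[k]]$weights, 1)
  }
})

test_that("EM recovers a two-component mixture and is monotone", {
  withr::with_seed(31, {
    z <- rbinom(400, 1, 0.5)
    x <- cbind(rnorm(400, mean = 8 * z), rnorm(400))
  })
  g <- visparc:::gmm_em(x, M = 2, seed = 5)
  expect_equal(sort(g$weights), sort(c(mean(z == 0), mean(z == 1))),
               tolerance = 0.05)
  expect_true(all(diff(g$loglik) >= -1e-8 * abs(g$loglik[-length(g$loglik)])))

  # monotone log-likelihood on assorted seeded inputs
  for (s in 1:3) {
    xi <- withr::with_seed(s, matrix(rnorm(60 * 3), 60, 3))
    gi <- visparc:::gmm_em(xi, M = 3, seed = s)
    expect_true(all(diff(gi$loglik) >= -1e-8 * abs(gi$loglik[-length(gi$loglik)])))
  }

  expect_error(visparc:::gmm_em(matrix(rnorm(6), 3, 2), M = 5),
               class = "visparc_capacity_error")
})

test_that("SVM separates a margin toy and validates its cost parameter", {
  d <- two_blob_data(gap = 8)
  m <- fit_svm(d$x, d$y, C = 100, kernel = "linear")
  expect_equal(accuracy_pct(d$y, predict(m, d$x)), 100)

  # agreement with a brute-force max-margin line on a 2-D toy
  margin_of <- function(theta, b) {
    v <- c(cos(theta), sin(theta))
    s <- d$x %*% v - b
    if (all(sign(s) == ifelse(d$y == 1, -1, 1))) min(abs(s)) else -Inf
  }
  grid <- expand.grid(theta = seq(0, pi, length.out = 181),
                      b = seq(-2, 10, length.out = 241))
  margins <- mapply(margin_of, grid$theta, grid$b)
  best <- grid[which.max(margins), ]
  v <- c(cos(best$theta), sin(best$theta))
  test <- two_blob_data(gap = 8, seed = 99)
  oracle_pred <- ifelse(test$x %*% v - best$b > 0, 2, 1)
  expect_gt(mean(predict(m, test$x) == oracle_pred), 0.98)

  expect_error(fit_svm(d$x, d$y, C = 0), class = "visparc_param_error")
})

test_that("the neural network normalizes softmax outputs and fits separable data", {
  d <- two_blob_data(gap = 5)
  m <- fit_ann(d$x, d$y, epochs = 500, seed = 1)
  probs <- predict(m, matrix(rnorm(20), 10, 2), type = "score")
  expect_equal(rowSums(probs), rep(1, 10), tolerance = 1e-8)
  expect_gte(accuracy_pct(d$y, predict(m, d$x)), 95)
})

test_that("shuffled training labels drop the network to chance", {
  withr::with_seed(41, {
    x <- matrix(rnorm(600 * 3), 600, 3)
    y <- sample(rep(1:6, each = 100))
  })
  train <- seq_len(300); test <- 301:600
  m <- fit_ann(x[train, ], sample(y[train]), epochs = 200, seed = 2)
  acc <- accuracy_pct(y[test], predict(m, x[test, ]))
  expect_lt(abs(acc - 100 / 6), 6)
})

test_that("maximum-likelihood predictions match a brute-force density oracle", {
  withr::with_seed(51, {
    x <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 3), 30, 2),
               matrix(rnorm(60, -3), 30, 2))
    y <- rep(1:3, each = 30)
    pts <- matrix(rnorm(40, 1), 20, 2)
  })
  b <- fit_bayes(x, y)
  oracle_b <- apply(pts, 1, function(p) {
    which.max(vapply(b$models, function(m)
      oracle_mvn_logdens(p, m$mean, m$cov), numeric(1)))
  })
  expect_equal(predict(b, pts), as.integer(oracle_b))

  g <- fit_gmm(x, y, M = 2, seed = 9)
  oracle_g <- apply(pts, 1, function(p) {
    lls <- vapply(g$mixtures, function(mix) {
      comp <- vapply(seq_len(mix$M), function(k)
        log(mix$weights[k]) +
          oracle_mvn_logdens(p, as.numeric(mix$means[k, ]), mix$covs[[k]]),
        numeric(1))
      log(sum(exp(comp - max(comp)))) + max(comp)
    }, numeric(1))
    which.max(lls)
  })
  expect_equal(predict(g, pts), as.integer(oracle_g))
})

test_that("likelihood ties break to the lowest area code", {
  # identical per-area data give identical models for both areas (M = 1
  # so the fit is the deterministic Gaussian MLE, hence an exact tie)
  withr::with_seed(61, x <- matrix(rnorm(40), 20, 2))
  g <- fit_gmm(rbind(x, x), rep(c(2L, 5L), each = 20), M = 1, seed = 1)
  pred <- predict(g, matrix(rnorm(30), 15, 2))
  expect_true(all(pred == 2L))

  # a point equidistant from two symmetric class means with equal Sigma
  pts <- rbind(c(sqrt(2), 0), c(-sqrt(2), 0), c(0, sqrt(2)), c(0, -sqrt(2)))
  b <- fit_bayes(rbind(pts - 2, pts + 2), rep(c(3L, 6L), each = 4))
  expect_equal(predict(b, matrix(c(0, 0), 1)), 3L)
})

test_that("fits and predictions are reproducible under a fixed seed", {
  d <- two_blob_data()
  pts <- matrix(rnorm(40), 20, 2)
  for (fitter in list(
    function() fit_gmm(d$x, d$y, M = 2, seed = 7),
    function() fit_ann(d$x, d$y, epochs = 100, seed = 7))) {
    m1 <- fitter(); m2 <- fitter()
    expect_identical(predict(m1, pts), predict(m2, pts))
  }
})
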