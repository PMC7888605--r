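# Trial averaging, resting windows, and the PCA -> LDA front end.

test_that("trial averaging reduces to hand-computed means in canonical order", {
  # one unit, one stimulus, trials [0,2] and [2,4] -> [1,3]
  resp <- matrix(c(0, 2, 2, 4), nrow = 1)
  trials <- data.frame(stimulus_id = c(1L, 1L), onset_frame = c(0L, 2L),
                       n_frames = c(2L, 2L))
  rec <- toy_recording(resp, trials)
  expect_equal(trial_average(rec), matrix(c(1, 3), nrow = 1))

  # two identical trials reproduce either trial exactly
  resp2 <- matrix(rep(c(5, -1, 3), 2), nrow = 1)
  trials2 <- data.frame(stimulus_id = c(1L, 1L), onset_frame = c(0L, 3L),
                        n_frames = c(3L, 3L))
  rec2 <- toy_recording(resp2, trials2)
  expect_equal(trial_average(rec2), matrix(c(5, -1, 3), nrow = 1))

  # stimulus blocks are ordered by id, not request order
  rec3 <- small_widefield()
  expect_identical(trial_average(rec3, c(2, 1)), trial_average(rec3, c(1, 2)))

  expect_error(trial_average(rec3, 99), class = "visparc_input_error")
  # mismatched trial lengths within one stimulus
  trials_bad <- data.frame(stimulus_id = c(1L, 1L), onset_frame = c(0L, 2L),
                           n_frames = c(2L, 1L))
  expect_error(trial_average(toy_recording(resp, trials_bad)),
               class = "visparc_alignment_error")
})

test_that("resting-state extraction trims and truncates to the protocol lengths", {
  counts <- setNames(rep(2L, 6), c("V1", "LM", "AL", "RL", "AM", "PM"))
  p <- sim_params(n_stimuli = 0, resting_duration_s = 900, seed = 1)
  rec <- simulate_twophoton(counts, p)
  # 900 s segment, trim 50/50, keep 800 s -> 800 * frame_rate frames
  expect_equal(ncol(take_resting(rec, 50, 50, 800)), 800 * rec$frame_rate)

  p2 <- sim_params(n_stimuli = 0, resting_duration_s = 300, seed = 1)
  rec2 <- simulate_twophoton(counts, p2)
  expect_equal(ncol(take_resting(rec2, 30, 30, 240)), 240 * rec2$frame_rate)

  expect_error(take_resting(rec2, 30, 30, 500),
               class = "visparc_length_error")
})

test_that("PCA matches a direct covariance eigendecomposition", {
  # the four-point toy: eigenvalues 0.5 and 0.125 under 1/n normalization
  x <- rbind(c(1, 0), c(-1, 0), c(0, 0.5), c(0, -0.5))
  m <- fit_pca(x, n_kept = 2)
  oracle <- eigen(crossprod(sweep(x, 2, colMeans(x))) / nrow(x),
                  symmetric = TRUE)$values
  expect_equal(m$eigenvalues[1:2], oracle)
  expect_equal(m$eigenvalues[1:2], c(0.5, 0.125))

  # rank-1 data: one positive eigenvalue, the rest ~ 0
  y <- outer(rnorm(6), c(1, 2, -1))
  m1 <- fit_pca(y, n_kept = 3)
  expect_gt(m1$eigenvalues[1], 0)
  expect_lt(max(abs(m1$eigenvalues[-1])), 1e-10)

  # orthonormal components, energy conservation, Gram-trick consistency
  set.seed(42)
  z <- matrix(rnorm(8 * 20), 8, 20)   # more timepoints than units
  mz <- fit_pca(z, n_kept = 8)
  expect_equal(crossprod(mz$components), diag(mz$n_kept), tolerance = 1e-8)
  direct <- eigen(crossprod(sweep(z, 2, colMeans(z))) / nrow(z),
                  symmetric = TRUE)$values
  expect_equal(sum(mz$eigenvalues), sum(direct), tolerance = 1e-8)
  expect_equal(mz$eigenvalues[1:7], direct[1:7], tolerance = 1e-8)

  # full-rank projection then reconstruction reproduces centered data
  rec_hat <- project_pca(mz, z) %*% t(mz$components)
  expect_equal(rec_hat, sweep(z, 2, colMeans(z)), tolerance = 1e-8)

  expect_error(fit_pca(matrix(1, 5, 4), 2),
               class = "visparc_degenerate_error")
})

test_that("PCA projection behaves like coefficients in an orthonormal basis", {
  set.seed(7)
  x <- matrix(rnorm(12 * 6), 12, 6)
  m <- fit_pca(x, n_kept = 6)
  expect_equal(as.numeric(project_pca(m, m$mean)), rep(0, m$n_kept))
  e1 <- as.numeric(project_pca(m, m$mean + m$components[, 1]))
  expect_equal(e1, c(1, rep(0, m$n_kept - 1)), tolerance = 1e-10)

  # reconstruction error decreases monotonically with K (brute force)
  errs <- vapply(1:6, function(K) {
    mk <- fit_pca(x, n_kept = K)
    xc <- sweep(x, 2, mk$mean)
    sum((xc - project_pca(mk, x) %*% t(mk$components))^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))

  expect_error(project_pca(m, matrix(0, 2, 5)),
               class = "visparc_input_error")
})

test_that("LDA recovers the discriminant axis found by brute force", {
  set.seed(11)
  n <- 80
  x <- rbind(cbind(rnorm(n, -1, 0.3), rnorm(n, 0, 1)),
             cbind(rnorm(n, +1, 0.3), rnorm(n, 0, 1)))
  y <- rep(1:2, each = n)
  m <- fit_lda(x, y)
  w <- m$projection[, 1] / sqrt(sum(m$projection[, 1]^2))

  # oracle: maximize the Fisher ratio over a dense grid of directions
  fisher <- function(theta) {
    v <- c(cos(theta), sin(theta))
    proj <- x %*% v
    mu <- mean(proj); mus <- tapply(proj, y, mean)
    sb <- mean((mus - mu)^2)
    sb / mean((proj - mu)^2)
  }
  grid <- seq(0, pi, length.out = 2001)
  best <- c(cos(grid[which.max(vapply(grid, fisher, numeric(1)))]),
            sin(grid[which.max(vapply(grid, fisher, numeric(1)))]))
  expect_gt(abs(sum(w * best)), 0.999)

  # degenerate scatter and the C - 1 rank bound
  xx <- matrix(rnorm(60 * 4), 60, 4)
  expect_error(fit_lda(rbind(xx, xx), c(rep(1, 60), rep(2, 60))),
               class = "visparc_degenerate_error")
  y6 <- rep(1:6, each = 10)
  m6 <- fit_lda(matrix(rnorm(60 * 10), 60, 10), y6)
  expect_lte(m6$n_dims, 5)
  expect_error(fit_lda(matrix(rnorm(12), 6, 2), c(1, 1, 1, 1, 1, 2)),
               class = "visparc_class_size_error")
})

test_that("LDA projection centers on the global mean and separates classes", {
  set.seed(13)
  x <- rbind(matrix(rnorm(40 * 3, 0), 40, 3),
             matrix(rnorm(40 * 3, 2), 40, 3))
  y <- rep(1:2, each = 40)
  m <- fit_lda(x, y, n_dims = 1)
  expect_equal(as.numeric(project_lda(m, m$global_mean)), 0,
               tolerance = 1e-12)
  expect_equal(ncol(project_lda(m, x)), 1)

  # post-projection Fisher ratio beats any of 50 random directions
  ratio_along <- function(v) {
    proj <- x %*% v
    mus <- tapply(proj, y, mean); mu <- mean(proj)
    mean((mus - mu)^2) / mean((proj - mu)^2)
  }
  r_lda <- ratio_along(m$projection[, 1])
  r_rand <- replicate(50, ratio_along({v <- rnorm(3); v / sqrt(sum(v^2))}))
  expect_true(all(r_lda >= r_rand))
})

zscore_subset <- function(rec, idx) {
  in_map <- which(rec$unit_labels > 0L)
  b <- trial_average(rec)[in_map, , drop = FALSE]
  mu <- rowMeans(b); bc <- b - mu
  s <- sqrt(rowMeans(bc^2)); s[s == 0] <- 1
  (bc / s)[idx, , drop = FALSE]
}

test_that("the feature pipeline is deterministic and leak-free by construction", {
  rec <- small_widefield()
  f1 <- build_features(rec, n_pcs = 0.9, max_pcs = 20)
  f2 <- build_features(rec, n_pcs = 0.9, max_pcs = 20)
  expect_identical(f1$features, f2$features)
  expect_equal(nrow(f1$features), sum(rec$unit_labels > 0))
  expect_lte(ncol(f1$features), 5)

  # transforms fitted on a subset only use that subset
  idx <- seq_len(200)
  f3 <- build_features(rec, fit_idx = idx, n_pcs = 0.9, max_pcs = 20,
                       lda = FALSE)
  sub <- zscore_subset(rec, idx)
  p_ref <- fit_pca(sub, n_kept = 0.9, max_kept = 20)
  expect_equal(f3$transform$pca$eigenvalues, p_ref$eigenvalues)
})
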