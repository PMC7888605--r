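# UBM training, grid partition, seeding, MAP adaptation, merge scoring,
# region growing and boundary smoothing.

# small hand-built diagonal UBM for exact-arithmetic tests
tiny_ubm <- function() {
  structure(list(weights = c(0.5, 0.5),
                 means = rbind(c(-2, 0), c(2, 0)),
                 vars = rbind(c(1, 1), c(1, 1)),
                 M = 2L, d = 2L, loglik = NULL, seed = 0L),
            class = "vc_ubm")
}

test_that("UBM training enforces its preconditions and normalizes density", {
  withr::with_seed(71, x <- matrix(rnorm(400 * 2), 400, 2))
  expect_error(train_ubm(x, M_ubm = 3), class = "visparc_param_error")
  expect_error(train_ubm(x[1:40, ], M_ubm = 30),
               class = "visparc_capacity_error")

  ubm <- train_ubm(x, M_ubm = 8, seed = 1)
  expect_equal(sum(ubm$weights), 1, tolerance = 1e-10)
  # numeric integration of the 2-D mixture density over a wide grid
  gr <- seq(-8, 8, length.out = 161)
  pts <- as.matrix(expand.grid(gr, gr))
  dens <- exp(visparc:::gmm_logdens(visparc:::ubm_as_gmm(ubm), pts))
  integral <- sum(dens) * diff(gr)[1]^2
  expect_equal(integral, 1, tolerance = 0.02)

  # each seed is individually reproducible
  expect_identical(train_ubm(x, M_ubm = 8, seed = 5)$means,
                   train_ubm(x, M_ubm = 8, seed = 5)$means)
})

test_that("grid partition tiles the in-map pixels exactly once", {
  am <- default_map()
  st <- partition_grid(am, cell_px = 8)
  expect_lte(length(st$cells), 64)
  covered <- sort(unlist(st$cells))
  expect_identical(covered, which(am$labels > 0))
  # no undersized cells survive the edge merge
  expect_true(all(lengths(st$cells) >= ceiling(64 / 4)))
  # adjacency is symmetric
  for (a in seq_along(st$adjacency))
    for (b in st$adjacency[[a]])
      expect_true(a %in% st$adjacency[[b]])
  # per-area pixel totals across cells match a raster recount
  per_area_cells <- vapply(1:6, function(k)
    sum(vapply(st$cells, function(px) sum(am$labels[px] == k), numeric(1))),
    numeric(1))
  expect_equal(per_area_cells, vapply(1:6, function(k)
    sum(am$labels == k), numeric(1)))

  expect_error(partition_grid(am, 1), class = "visparc_param_error")
})

test_that("center seeding labels the interior pole cell of each area", {
  am <- small_map()
  st <- seed_centers(partition_grid(am, 6))
  expect_equal(sum(!is.na(st$labels)), 6)
  expect_setequal(st$labels[!is.na(st$labels)], 1:6)
  for (k in 1:6) {
    cell <- which(st$labels == k)
    # majority ground-truth pixel label of the seeded cell is the seed
    tb <- table(am$labels[st$cells[[cell]]])
    expect_equal(as.integer(names(tb)[which.max(tb)]), k)
    # the seeded cell contains the brute-force distance-transform argmax
    bd <- brute_distance_to_boundary(am$labels == k)
    expect_equal(st$cell_raster[which.max(bd)], cell)
  }
})

test_that("MAP adaptation interpolates between data and prior", {
  ubm <- tiny_ubm()
  x <- rbind(c(2.5, 0.3), c(1.9, -0.2), c(2.2, 0.1), c(1.7, 0), c(2.3, 0.2))

  # infinite relevance: the prior wins exactly
  a_inf <- map_adapt(ubm, x, relevance = Inf)
  expect_identical(a_inf$means, ubm$means)
  expect_equal(a_inf$weights, ubm$weights)

  # vanishing relevance with all data near one component: data wins
  a0 <- map_adapt(ubm, x, relevance = 1e-9)
  expect_equal(as.numeric(a0$means[2, ]), colMeans(x), tolerance = 1e-4)

  # alpha matches hand-computed responsibilities on the 5-point toy
  ld <- vapply(1:2, function(k)
    -log(2 * pi) - 0.5 * rowSums(sweep(x, 2, ubm$means[k, ])^2) + log(0.5),
    numeric(nrow(x)))
  gamma <- exp(ld - apply(ld, 1, function(r) max(r) + log(sum(exp(r - max(r))))))
  n_k <- colSums(gamma)
  r <- 16
  a16 <- map_adapt(ubm, x, relevance = r)
  expect_equal(a16$alpha, n_k / (n_k + r), tolerance = 1e-10)

  expect_error(map_adapt(ubm, x[0, , drop = FALSE]),
               class = "visparc_input_error")
})

test_that("the merge score is symmetric, zero under an infinite prior, and discriminative", {
  ubm <- tiny_ubm()
  withr::with_seed(81, {
    da <- matrix(rnorm(40, -2, 0.7), 20, 2)
    db <- matrix(rnorm(40, 2, 0.7), 20, 2)
  })
  expect_identical(merge_score(ubm, da, db, 16), merge_score(ubm, db, da, 16))
  expect_identical(merge_score(ubm, da, db, Inf), 0)

  # same-distribution pairs outscore cross-distribution pairs (sign test
  # over 20 seeded replicates)
  wins <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      a1 <- matrix(rnorm(60, -2, 0.7), 30, 2)
      a2 <- matrix(rnorm(60, -2, 0.7), 30, 2)
      b1 <- matrix(rnorm(60, 2, 0.7), 30, 2)
    })
    merge_score(ubm, a1, a2, 16) > merge_score(ubm, a1, b1, 16)
  }, logical(1))
  expect_gte(sum(wins), 15)
})

test_that("noise-free aligned areas are grown and smoothed exactly", {
  rec <- aligned_zero_noise()
  feats <- suppressWarnings(build_features(rec, lda = FALSE))
  ubm <- suppressWarnings(train_ubm(feats, M_ubm = 6, seed = 1))
  st <- seed_centers(partition_grid(rec$area_map, 8))
  st <- region_grow(st, ubm, feats)
  # termination contract: everything labeled with the six codes
  expect_false(anyNA(st$labels))
  expect_setequal(unique(st$labels), 1:6)
  # cell labels match ground truth exactly (cells never straddle areas)
  truth <- vapply(st$cells, function(px)
    as.integer(names(which.max(table(rec$area_map$labels[px])))), integer(1))
  expect_equal(st$labels, truth)

  # labeled regions stay 4-connected at every iteration (merge-log audit)
  lab_now <- seed_centers(partition_grid(rec$area_map, 8))$labels
  log <- st$merge_log[st$merge_log$action == "merge", ]
  check_regions <- function(labs) {
    raster <- st$cell_raster
    out <- matrix(NA_integer_, nrow(raster), ncol(raster))
    for (i in seq_along(st$cells)) out[st$cells[[i]]] <- labs[i]
    for (k in unique(labs[!is.na(labs)]))
      expect_true(is_connected4(!is.na(out) & out == k))
  }
  for (it in unique(log$iteration)) {
    rows <- log[log$iteration == it, ]
    for (j in seq_len(nrow(rows)))
      lab_now[rows$cell_b[j]] <- lab_now[rows$cell_a[j]]
    check_regions(lab_now)
  }

  # smoothing preserves the exact parcellation and covers every pixel
  raster <- suppressWarnings(smooth_boundaries(st, feats, seed = 1))
  in_map <- rec$area_map$labels > 0
  expect_true(all(raster[in_map] > 0))
  expect_equal(raster[in_map], rec$area_map$labels[in_map])
})

test_that("the full parcellation pipeline is reproducible", {
  rec <- small_widefield()
  p1 <- parcellate(rec, M_ubm = 16, cell_px = 8, seed = 2)
  p2 <- parcellate(rec, M_ubm = 16, cell_px = 8, seed = 2)
  expect_identical(p1$pixel_labels, p2$pixel_labels)
  expect_equal(p1$accuracy, p2$accuracy)
  expect_false(anyNA(p1$state$labels))
})
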