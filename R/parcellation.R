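# Semi-supervised parcellation of the cortical sheet.
#
# A universal background model (UBM) — a large diagonal-covariance GMM
# trained on the PCA features of every in-map pixel, with no labels — acts
# as the shared prior. The sheet is tiled into equal grid cells; the
# center-most cell of each area is the only supervised information. Cells
# are then absorbed into the seeded regions by iterative region growing:
# cell-specific models are obtained by MAP adaptation of the UBM means,
# candidate (labeled cell, unlabeled neighbor) pairs are scored by the
# gain in total log-likelihood from modeling the pair jointly versus
# separately (a modified BIC without penalty term), and the top x% of
# scores are merged each iteration, with x falling from 80% to 20% as the
# labeled fraction grows. A supervised mixture classifier trained on the
# final clusters smooths the pixel-level boundaries.

#' Train a universal background model
#'
#' Fits one large diagonal-covariance Gaussian mixture to the features of
#' all in-map pixels, ignoring labels. Because it must cover the whole
#' cortex, the UBM uses many more components than a per-area mixture.
#'
#' @param x Feature matrix (pixels x dims; PCA coefficients) or a
#'   `vc_features` built with `lda = FALSE`.
#' @param M_ubm Component count (>= 6; default 64).
#' @param seed Seed for the k-means initialization.
#' @return An object of class `vc_ubm`: `weights`, `means` (M x d), `vars`
#'   (M x d diagonal covariances), `M`, `seed`.
#' @export
train_ubm <- function(x, M_ubm = 64, seed = 1) {
  if (inherits(x, "vc_features")) x <- x$features
  x <- as.matrix(x)
  if (M_ubm < 6)
    stop_visparc("M_ubm must be >= 6", class = "visparc_param_error")
  if (nrow(x) < 10 * min(M_ubm, nrow(unique(x))))
    stop_visparc("need >= 10 samples per UBM component (%d samples, M = %d)",
                 nrow(x), M_ubm, class = "visparc_capacity_error")
  g <- gmm_em(x, M_ubm, seed = seed, cov_type = "diag")
  structure(list(weights = g$weights, means = g$means,
                 vars = do.call(rbind, g$covs), M = g$M, d = g$d,
                 loglik = g$loglik, seed = seed),
            class = "vc_ubm")
}

ubm_as_gmm <- function(ubm, means = NULL, weights = NULL) {
  list(weights = weights %||% ubm$weights, means = means %||% ubm$means,
       covs = lapply(seq_len(ubm$M), function(k) ubm$vars[k, ]),
       cov_type = "diag", M = ubm$M, d = ubm$d)
}

#' Log-likelihood of data under a (possibly adapted) UBM
#'
#' @param ubm A [train_ubm()] fit.
#' @param x Feature rows.
#' @param means,weights Optional replacement component means/weights (e.g.
#'   from [map_adapt()]); covariances always come from the UBM.
#' @return The summed log-density over rows.
#' @export
ubm_loglik <- function(ubm, x, means = NULL, weights = NULL) {
  x <- check_dims(x, ubm$d)
  sum(gmm_logdens(ubm_as_gmm(ubm, means, weights), x))
}

#' Partition the mapped sheet into grid cells
#'
#' Tiles the in-map pixels with square cells of `cell_px` x `cell_px`
#' pixels so each cell holds enough data for MAP adaptation. Edge cells
#' holding fewer than a quarter of the nominal cell area are merged into
#' their largest pixel-adjacent neighbor. Cell adjacency is the 4-
#' neighborhood of pixels across cell boundaries.
#'
#' @param area_map A `vc_area_map`.
#' @param cell_px Cell side length in pixels (>= 2).
#' @return An object of class `vc_cluster_state`: `cell_raster` (pixel ->
#'   cell id, NA outside the map), `cells` (per-cell pixel indices, in the
#'   row-major unit order of wide-field recordings), `adjacency`, `labels`
#'   (per-cell area code, NA until seeded/grown), `area_map`.
#' @export
partition_grid <- function(area_map, cell_px = 8) {
  if (cell_px < 2)
    stop_visparc("cell_px must be >= 2", class = "visparc_param_error")
  lab <- area_map$labels
  n_rows <- nrow(lab); n_cols <- ncol(lab)
  rr <- matrix(seq_len(n_rows), n_rows, n_cols)
  cc <- matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE)
  block <- (ceiling(rr / cell_px) - 1L) * ceiling(n_cols / cell_px) +
    ceiling(cc / cell_px)
  block[lab == 0L] <- NA_integer_
  # drop empty blocks, renumber
  ids <- sort(unique(block[!is.na(block)]))
  raster <- matrix(match(block, ids), n_rows, n_cols)
  # merge undersized edge cells into their largest adjacent neighbor
  min_px <- ceiling(cell_px^2 / 4)
  repeat {
    sizes <- tabulate(raster[!is.na(raster)], max(raster, na.rm = TRUE))
    small <- which(sizes > 0 & sizes < min_px)
    if (!length(small)) break
    adj <- cell_adjacency_counts(raster)
    moved <- FALSE
    for (s in small) {
      nb <- adj[[s]]
      nb <- nb[names(nb) != as.character(s)]
      if (!length(nb)) next
      target <- as.integer(names(nb)[which.max(nb)])
      raster[raster == s & !is.na(raster)] <- target
      moved <- TRUE
      break  # recompute sizes/adjacency after each merge
    }
    if (!moved) break
  }
  ids <- sort(unique(raster[!is.na(raster)]))
  raster <- matrix(match(raster, ids), n_rows, n_cols)
  n_cells <- length(ids)
  cells <- split(which(!is.na(raster)), raster[!is.na(raster)])
  names(cells) <- NULL
  adjacency <- lapply(cell_adjacency_counts(raster), function(nb)
    sort(as.integer(names(nb))))
  # warn when cells are wider than the thinnest area
  area_sizes <- tabulate(lab[lab > 0L], 6)
  if (cell_px^2 > min(area_sizes))
    warning("cell_px exceeds the smallest area's pixel count")
  structure(list(cell_raster = raster, cells = cells,
                 adjacency = adjacency,
                 labels = rep(NA_integer_, n_cells),
                 area_map = area_map, cell_px = cell_px, iteration = 0L),
            class = "vc_cluster_state")
}

# counts of 4-adjacent pixel contacts between cells; list indexed by cell,
# each element a named count vector of neighboring cells
cell_adjacency_counts <- function(raster) {
  n_rows <- nrow(raster); n_cols <- ncol(raster)
  pairs <- rbind(
    cbind(as.vector(raster[-n_rows, ]), as.vector(raster[-1, ])),
    cbind(as.vector(raster[, -n_cols]), as.vector(raster[, -1])))
  pairs <- pairs[!is.na(pairs[, 1]) & !is.na(pairs[, 2]) &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- rbind(pairs, pairs[, 2:1])
  n_cells <- max(raster, na.rm = TRUE)
  out <- vector("list", n_cells)
  if (nrow(pairs)) {
    tab <- table(pairs[, 1], pairs[, 2])
    for (a in rownames(tab)) {
      v <- tab[a, ]
      v <- v[v > 0]
      out[[as.integer(a)]] <- v
    }
  }
  for (i in seq_len(n_cells)) if (is.null(out[[i]])) out[[i]] <- integer(0)
  out
}

# Euclidean distance transform of a logical mask (distance to the nearest
# FALSE pixel); EBImage's distmap does the heavy lifting
dist_transform <- function(mask) {
  m <- EBImage::distmap(EBImage::Image(mask * 1, dim(mask)))
  matrix(EBImage::imageData(m), nrow(mask), ncol(mask))
}

# interior pole of each area: the pixel maximizing distance-to-boundary
# (row-major first on ties); returns a 6 x 2 matrix of (row, col)
area_poles <- function(area_map) {
  t(vapply(AREA_CODES, function(k) {
    dt <- dist_transform(area_map$labels == k)
    p <- which.max(dt)
    c((p - 1L) %% nrow(dt) + 1L, (p - 1L) %/% nrow(dt) + 1L)
  }, numeric(2)))
}

#' Seed the center cell of every area
#'
#' For each of the six areas, the grid cell containing the area's interior
#' pole (the pixel deepest inside the area by the distance transform)
#' receives that area's label; every other cell stays unlabeled. If two
#' areas claim the same cell, the smaller area is re-seeded at its
#' next-best interior pixel outside already-claimed cells.
#'
#' @param state A [partition_grid()] result.
#' @param area_map The ground-truth `vc_area_map` (defaults to the one in
#'   `state`).
#' @return The state with exactly six labeled cells.
#' @export
seed_centers <- function(state, area_map = state$area_map) {
  labels <- state$labels
  labels[] <- NA_integer_
  sizes <- tabulate(area_map$labels[area_map$labels > 0L], 6)
  if (any(sizes == 0))
    stop_visparc("all 6 areas must be present in the map",
                 class = "visparc_input_error")
  taken <- integer(0)
  for (k in order(sizes, decreasing = TRUE)) {   # big areas claim first
    dt <- dist_transform(area_map$labels == k)
    ord <- order(-dt, seq_along(dt))
    seeded <- FALSE
    for (p in ord) {
      if (dt[p] <= 0) break
      cell <- state$cell_raster[p]
      if (is.na(cell) || cell %in% taken) next
      labels[cell] <- k
      taken <- c(taken, cell)
      seeded <- TRUE
      break
    }
    if (!seeded)
      stop_visparc("could not seed a cell for area %s", AREA_NAMES[k],
                   class = "visparc_input_error")
  }
  state$labels <- labels
  state
}

#' MAP-adapt the UBM to a data subset
#'
#' Classical relevance-MAP adaptation: component responsibilities over the
#' subset give soft counts n_k and weighted means E_k; the adapted mean is
#' the convex combination `alpha_k * E_k + (1 - alpha_k) * ubm_mean_k`
#' with `alpha_k = n_k / (n_k + relevance)`, and the adapted weight is
#' `alpha_k * n_k / n + (1 - alpha_k) * w_k`, renormalized. Covariances
#' are kept from the UBM, so a cell with little data stays close to the
#' prior. Weight adaptation is what makes the merge score discriminative:
#' a subset drawn from one area concentrates its weight budget on that
#' area's components, while the joint model of a heterogeneous pair must
#' spread weight over both areas' components, costing every point
#' log-likelihood.
#'
#' @param ubm A [train_ubm()] fit.
#' @param x Feature rows of the subset (nonempty).
#' @param relevance Relevance factor (> 0; default 16).
#' @return A list with `means` (M x d), `weights`, `alpha`, `n_k`.
#' @export
map_adapt <- function(ubm, x, relevance = 16) {
  if (relevance <= 0)
    stop_visparc("relevance must be > 0", class = "visparc_param_error")
  x <- check_dims(x, ubm$d)
  if (nrow(x) == 0)
    stop_visparc("empty cell: no data to adapt to",
                 class = "visparc_input_error")
  st <- map_stats(ubm, x)
  map_combine(ubm, st, relevance)
}

# sufficient statistics of MAP adaptation; additive across subsets, which
# makes the merge score exactly symmetric in its two arguments
map_stats <- function(ubm, x) {
  n <- nrow(x)
  logcomp <- vapply(seq_len(ubm$M), function(k)
    mvn_logdens_diag(x, ubm$means[k, ], ubm$vars[k, ]) + log(ubm$weights[k]),
    numeric(n))
  logcomp <- matrix(logcomp, nrow = n)
  gamma <- exp(logcomp - logsumexp_rows(logcomp))
  list(n_k = colSums(gamma), sum_k = crossprod(gamma, x))
}

map_combine <- function(ubm, st, relevance) {
  n_k <- st$n_k
  alpha <- n_k / (n_k + relevance)
  E_k <- st$sum_k / pmax(n_k, 1e-12)
  E_k[n_k <= 1e-12, ] <- ubm$means[n_k <= 1e-12, ]
  means <- alpha * E_k + (1 - alpha) * ubm$means
  w <- alpha * n_k / sum(n_k) + (1 - alpha) * ubm$weights
  list(means = means, weights = w / sum(w), alpha = alpha, n_k = n_k)
}

#' Merge score between two cells (modified BIC)
#'
#' The gain in total log-likelihood from modeling the union of two data
#' subsets with a single MAP-adapted mixture versus modeling each subset
#' with its own adapted mixture:
#' `S = log p(D | lambda) - log p(Da | lambda_a) - log p(Db | lambda_b)`.
#' Similar subsets lose little by sharing a model (S near 0); dissimilar
#' subsets are penalized (S strongly negative). The adaptive per-iteration
#' threshold of [region_grow()] replaces the usual BIC penalty term. The
#' score is computed from additive sufficient statistics and is exactly
#' symmetric in its arguments.
#'
#' @param ubm A [train_ubm()] fit.
#' @param d_a,d_b Feature rows of the two cells (both nonempty).
#' @param relevance MAP relevance factor.
#' @return A scalar score in log-likelihood units.
#' @export
merge_score <- function(ubm, d_a, d_b, relevance = 16) {
  d_a <- check_dims(d_a, ubm$d)
  d_b <- check_dims(d_b, ubm$d)
  if (nrow(d_a) == 0 || nrow(d_b) == 0)
    stop_visparc("empty cell: no data to adapt to",
                 class = "visparc_input_error")
  st_a <- map_stats(ubm, d_a)
  st_b <- map_stats(ubm, d_b)
  st_u <- list(n_k = st_a$n_k + st_b$n_k, sum_k = st_a$sum_k + st_b$sum_k)
  la <- map_combine(ubm, st_a, relevance)
  lb <- map_combine(ubm, st_b, relevance)
  lu <- map_combine(ubm, st_u, relevance)
  (ubm_loglik(ubm, d_a, lu$means, lu$weights) +
     ubm_loglik(ubm, d_b, lu$means, lu$weights)) -
    ubm_loglik(ubm, d_a, la$means, la$weights) -
    ubm_loglik(ubm, d_b, lb$means, lb$weights)
}

#' Grow the seeded regions over the whole sheet
#'
#' Iterative semi-supervised region growing. Each iteration scores every
#' (labeled cell, unlabeled 4-neighbor) pair with [merge_score()], sorts
#' the scores descending, and merges the top x%, where x interpolates
#' linearly from `schedule[1]` (80%) at labeled fraction 0 to
#' `schedule[2]` (20%) at labeled fraction 1. An unlabeled cell contested
#' by two regions in one iteration joins the higher-scoring one (ties to
#' the lower area code). At least one merge happens per iteration, so the
#' loop always terminates; cells unreachable from any seed are assigned to
#' the nearest labeled cell at finalization with a warning.
#'
#' @param state A seeded `vc_cluster_state`.
#' @param ubm A [train_ubm()] fit.
#' @param features Pixel-level feature matrix, rows aligned with the
#'   recording's units (row-major pixels); cells index into it.
#' @param unit_index Mapping from pixel index (position in the raster) to
#'   feature row; default assumes features cover all raster pixels in
#'   row-major order restricted to in-map pixels (`vc_features$unit_index`).
#' @param schedule Start and end merge fractions (default `c(0.8, 0.2)`).
#' @param relevance MAP relevance factor (default 16).
#' @return The state with all cells labeled, plus a `merge_log`
#'   data.frame (iteration, cell_a, cell_b, score, threshold, action).
#' @export
region_grow <- function(state, ubm, features, unit_index = NULL,
                        schedule = c(0.8, 0.2), relevance = 16) {
  if (all(is.na(state$labels)))
    stop_visparc("state has no seeded cells; call seed_centers() first",
                 class = "visparc_input_error")
  feat_of <- make_feat_lookup(features, unit_index, state)
  cell_data <- lapply(state$cells, feat_of)
  score_cache <- new.env(parent = emptyenv())
  pair_score <- function(a, b) {
    key <- if (a < b) paste0(a, "_", b) else paste0(b, "_", a)
    if (!is.null(score_cache[[key]])) return(score_cache[[key]])
    s <- merge_score(ubm, cell_data[[a]], cell_data[[b]], relevance)
    score_cache[[key]] <- s
    s
  }
  labels <- state$labels
  n_cells <- length(labels)
  log_rows <- list()
  iter <- 0L
  while (anyNA(labels)) {
    iter <- iter + 1L
    lab_cells <- which(!is.na(labels))
    cand <- list()
    for (a in lab_cells) {
      for (b in state$adjacency[[a]]) {
        if (is.na(labels[b]))
          cand[[length(cand) + 1L]] <- c(a = a, b = b)
      }
    }
    if (!length(cand)) break   # unreachable remainder
    cand <- do.call(rbind, cand)
    scores <- vapply(seq_len(nrow(cand)), function(i)
      pair_score(cand[i, 1], cand[i, 2]), numeric(1))
    f <- mean(!is.na(labels))
    x_frac <- schedule[1] + (schedule[2] - schedule[1]) * f
    k <- max(1L, ceiling(x_frac * nrow(cand)))
    ord <- order(-scores, labels[cand[, 1]], cand[, 1], cand[, 2])
    thresh <- scores[ord[k]]
    claimed <- integer(0)
    for (i in seq_len(nrow(cand))) {
      ri <- ord[i]
      a <- cand[ri, 1]; b <- cand[ri, 2]
      act <- if (i <= k && !(b %in% claimed)) {
        labels[b] <- labels[a]
        claimed <- c(claimed, b)
        "merge"
      } else if (i <= k) "contested" else "skip"
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(iteration = iter, cell_a = a, cell_b = b,
                   score = scores[ri], threshold = thresh, action = act)
    }
  }
  if (anyNA(labels)) {
    warning("cells unreachable from any seed; assigning to nearest labeled cell")
    centers <- t(vapply(state$cells, function(px) {
      c(mean((px - 1L) %% nrow(state$cell_raster)),
        mean((px - 1L) %/% nrow(state$cell_raster)))
    }, numeric(2)))
    lab_cells <- which(!is.na(labels))
    for (b in which(is.na(labels))) {
      d2 <- (centers[lab_cells, 1] - centers[b, 1])^2 +
            (centers[lab_cells, 2] - centers[b, 2])^2
      labels[b] <- labels[lab_cells[which.min(d2)]]
    }
  }
  state$labels <- labels
  state$iteration <- iter
  state$merge_log <- do.call(rbind, log_rows)
  state
}

make_feat_lookup <- function(features, unit_index, state) {
  if (inherits(features, "vc_features")) {
    unit_index <- unit_index %||% features$unit_index
    features <- features$features
  }
  features <- as.matrix(features)
  if (is.null(unit_index)) {
    if (nrow(features) == length(state$cell_raster))
      unit_index <- seq_len(nrow(features))
    else
      unit_index <- which(!is.na(state$cell_raster))
  }
  row_of <- rep(NA_integer_, length(state$cell_raster))
  row_of[unit_index] <- seq_along(unit_index)
  function(px) features[row_of[px], , drop = FALSE]
}

#' Smooth cluster boundaries with a supervised classifier
#'
#' Step that converts cell-level labels to pixel-level ones: a fraction of
#' pixels is sampled from each final cluster, a Gaussian-mixture area
#' classifier is fitted to their features with the cluster labels as
#' classes, and every in-map pixel is re-predicted. This removes the
#' blocky grid artifacts of cell-level growing.
#'
#' @param state A fully labeled `vc_cluster_state`.
#' @param features Pixel features as in [region_grow()].
#' @param unit_index See [region_grow()].
#' @param train_frac Fraction of pixels sampled per cluster (default 0.2).
#' @param gmm_M Mixture components per cluster classifier (capped by the
#'   sample count).
#' @param seed Sampling/EM seed.
#' @return An integer raster of per-pixel area labels (0 = background).
#' @export
smooth_boundaries <- function(state, features, unit_index = NULL,
                              train_frac = 0.2, gmm_M = 4, seed = 1) {
  if (anyNA(state$labels))
    stop_visparc("all cells must be labeled before smoothing",
                 class = "visparc_input_error")
  feat_of <- make_feat_lookup(features, unit_index, state)
  in_map <- which(!is.na(state$cell_raster))
  pix_label <- rep(NA_integer_, length(state$cell_raster))
  for (i in seq_along(state$cells))
    pix_label[state$cells[[i]]] <- state$labels[i]
  train_px <- withr::with_seed(as.integer(seed), {
    unlist(lapply(sort(unique(state$labels)), function(k) {
      px <- in_map[pix_label[in_map] == k]
      n <- max(2L, round(train_frac * length(px)))
      sample(px, min(n, length(px)))
    }))
  })
  M_eff <- min(gmm_M, min(tabulate(pix_label[train_px], 6)[unique(pix_label[train_px])]))
  clf <- fit_gmm(feat_of(train_px), pix_label[train_px],
                 M = max(1L, M_eff), seed = seed)
  pred <- predict(clf, feat_of(in_map))
  out <- matrix(0L, nrow(state$cell_raster), ncol(state$cell_raster))
  out[in_map] <- pred
  out
}

#' Run the full semi-supervised parcellation pipeline
#'
#' Convenience wrapper: PCA features of every in-map pixel (no labels
#' used), UBM training, grid partition, center seeding, region growing
#' and boundary smoothing, with accuracy against the ground-truth map.
#'
#' @param rec A wide-field `vc_recording`.
#' @param stimuli,resting Response selection as in [build_features()].
#' @param M_ubm,cell_px,relevance,schedule,train_frac Algorithm knobs; see
#'   the stage functions.
#' @param n_pcs,max_pcs PCA retention rule.
#' @param seed Seed for the pixel sampling and EM of the smoothing stage.
#' @param ubm_seed Seed for the UBM initialization (defaults to `seed`);
#'   exposed separately so the consistency of the parcellation across UBM
#'   initializations can be probed in isolation.
#' @return An object of class `vc_parcellation`: `pixel_labels` raster,
#'   `state` (with merge log), `ubm`, `features`, `accuracy` (percent of
#'   in-map pixels matching ground truth), `cell_accuracy`.
#' @export
parcellate <- function(rec, stimuli = NULL, resting = NULL, M_ubm = 64,
                       cell_px = 8, relevance = 16, schedule = c(0.8, 0.2),
                       train_frac = 0.2, n_pcs = 0.95, max_pcs = 50,
                       seed = 1, ubm_seed = seed) {
  if (!identical(rec$mode, "widefield") || is.null(rec$area_map))
    stop_visparc("parcellation needs a wide-field recording with an area map",
                 class = "visparc_input_error")
  feats <- build_features(rec, stimuli = stimuli, resting = resting,
                          n_pcs = n_pcs, max_pcs = max_pcs, lda = FALSE)
  ubm <- train_ubm(feats, M_ubm = M_ubm, seed = ubm_seed)
  state <- partition_grid(rec$area_map, cell_px = cell_px)
  state <- seed_centers(state)
  state <- region_grow(state, ubm, feats, schedule = schedule,
                       relevance = relevance)
  raster <- smooth_boundaries(state, feats, train_frac = train_frac,
                              seed = seed)
  truth <- rec$area_map$labels
  in_map <- truth > 0L
  acc <- 100 * mean(raster[in_map] == truth[in_map])
  cell_pix <- rep(NA_integer_, length(truth))
  for (i in seq_along(state$cells)) cell_pix[state$cells[[i]]] <- state$labels[i]
  cell_acc <- 100 * mean(cell_pix[in_map] == truth[in_map])
  structure(list(pixel_labels = raster, state = state, ubm = ubm,
                 features = feats, accuracy = acc,
                 cell_accuracy = cell_acc, seed = seed),
            class = "vc_parcellation")
}

#' @export
print.vc_parcellation <- function(x, ...) {
  cat(sprintf(
    "<vc_parcellation> %d cells, %d iterations; accuracy %.1f%% (cells %.1f%%)\n",
    length(x$state$cells), x$state$iteration, x$accuracy, x$cell_accuracy))
  invisible(x)
}

#' @export
plot.vc_parcellation <- function(x, main = "Semi-supervised parcellation", ...) {
  image(t(x$pixel_labels[nrow(x$pixel_labels):1, ]),
        col = c("grey90", hcl.colors(6, "Dark 3")), axes = FALSE,
        main = main, ...)
  invisible(x)
}
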