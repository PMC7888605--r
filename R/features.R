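# Trial averaging and the PCA -> LDA dimensionality-reduction front end.
#
# Units (pixels or neurons) are the samples; timepoints are the variables.
# Covariances use the 1/n normalization of the expectation form, so tests
# against hand-computed eigendecompositions match exactly. Every
# eigenvector and discriminant direction is sign-fixed so that its
# largest-magnitude entry is positive, making fitted models reproducible.

#' Average responses across trials
#'
#' For each requested stimulus, averages the trial-aligned response windows
#' across its repetitions; per-stimulus blocks are concatenated along time
#' in ascending stimulus id order (the request order is irrelevant).
#'
#' @param rec A `vc_recording` with a trial table.
#' @param stimulus_ids Stimulus ids to include; default all.
#' @return A units x (sum of stimulus window lengths) matrix.
#' @export
trial_average <- function(rec, stimulus_ids = NULL) {
  if (is.null(rec$trials))
    stop_visparc("recording has no trials", class = "visparc_input_error")
  ids <- sort(unique(stimulus_ids %||% rec$trials$stimulus_id))
  unknown <- setdiff(ids, rec$trials$stimulus_id)
  if (length(unknown))
    stop_visparc("unknown stimulus id(s): %s",
                 paste(unknown, collapse = ", "),
                 class = "visparc_input_error")
  blocks <- lapply(ids, function(s) {
    tr <- rec$trials[rec$trials$stimulus_id == s, , drop = FALSE]
    if (length(unique(tr$n_frames)) != 1)
      stop_visparc("stimulus %d has trials of unequal length", s,
                   class = "visparc_alignment_error")
    nf <- tr$n_frames[1]
    acc <- matrix(0, nrow(rec$responses), nf)
    for (i in seq_len(nrow(tr))) {
      cols <- (tr$onset_frame[i] + 1L):(tr$onset_frame[i] + nf)
      acc <- acc + rec$responses[, cols, drop = FALSE]
    }
    acc / nrow(tr)
  })
  do.call(cbind, blocks)
}

#' Extract a resting-state window
#'
#' Returns the contiguous untrialed segment that follows the last trial
#' (or the whole recording when there are no trials), after trimming
#' non-stationary transients from both ends and truncating to the
#' requested duration.
#'
#' @param rec A `vc_recording`.
#' @param trim_start_s,trim_end_s Seconds discarded from the start and end
#'   of the untrialed segment.
#' @param duration_s Window length in seconds, or `"all"` for everything
#'   between the trims.
#' @return A units x frames matrix.
#' @export
take_resting <- function(rec, trim_start_s = 0, trim_end_s = 0,
                         duration_s = "all") {
  fr <- rec$frame_rate
  T <- ncol(rec$responses)
  start0 <- if (is.null(rec$trials)) 0L
            else max(rec$trials$onset_frame + rec$trials$n_frames)
  avail <- T - start0
  trim_s <- round(trim_start_s * fr)
  trim_e <- round(trim_end_s * fr)
  usable <- avail - trim_s - trim_e
  want <- if (identical(duration_s, "all")) usable else round(duration_s * fr)
  if (want < 1 || want > usable)
    stop_visparc(
      "resting segment too short: %d frames available after trimming, %s requested",
      max(usable, 0), as.character(want), class = "visparc_length_error")
  cols <- (start0 + trim_s + 1L):(start0 + trim_s + want)
  rec$responses[, cols, drop = FALSE]
}

# ---- PCA -------------------------------------------------------------------

fix_signs <- function(V) {
  sgn <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
  sgn[sgn == 0] <- 1
  sweep(V, 2, sgn, "*")
}

#' Fit principal components of a population response
#'
#' Eigendecomposition of the covariance over the time axis (units are
#' samples, timepoints are variables) with 1/n normalization. When there
#' are fewer units than timepoints the decomposition is obtained through
#' the unit-space Gram matrix, which shares the nonzero spectrum.
#'
#' @param x A units x timepoints matrix (at least 2 of each).
#' @param n_kept Number of components to keep (integer >= 1), or a variance
#'   fraction in (0, 1): the smallest K whose eigenvalue mass reaches it.
#' @param max_kept Upper cap on K (applied after the variance-fraction
#'   rule); `Inf` disables the cap.
#' @return An object of class `vc_pca`: `mean` (timepoint means),
#'   `components` (timepoints x K orthonormal columns), `eigenvalues`
#'   (full descending spectrum), `n_kept`.
#' @export
#' @examples
#' x <- rbind(c(1, 0), c(-1, 0), c(0, 0.5), c(0, -0.5))
#' fit_pca(x, n_kept = 2)$eigenvalues   # 0.5 and 0.125
fit_pca <- function(x, n_kept = 0.95, max_kept = Inf) {
  x <- as.matrix(x)
  n <- nrow(x); T <- ncol(x)
  if (n < 2 || T < 2)
    stop_visparc("need >= 2 units and >= 2 timepoints",
                 class = "visparc_input_error")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  if (T <= n) {
    S <- crossprod(xc) / n
    e <- eigen(S, symmetric = TRUE)
    vals <- e$values
    vecs <- e$vectors
  } else {
    G <- tcrossprod(xc) / n
    e <- eigen(G, symmetric = TRUE)
    vals <- e$values
    pos <- vals > max(vals[1], 0) * 1e-12
    vecs <- crossprod(xc, e$vectors[, pos, drop = FALSE])
    vecs <- sweep(vecs, 2, sqrt(n * vals[pos]), "/")
    vals <- c(vals[pos], rep(0, T - sum(pos)))[seq_len(min(n, T))]
  }
  vals <- pmax(vals, 0)
  total <- sum(vals)
  if (total <= 0)
    stop_visparc("data have zero covariance; PCA is degenerate",
                 class = "visparc_degenerate_error")
  K <- if (n_kept >= 1) as.integer(n_kept)
       else which(cumsum(vals) / total >= n_kept)[1]
  K <- min(K, ncol(vecs), max_kept)
  if (K < 1)
    stop_visparc("n_kept must select at least one component",
                 class = "visparc_input_error")
  structure(list(mean = mu,
                 components = fix_signs(vecs[, seq_len(K), drop = FALSE]),
                 eigenvalues = vals, n_kept = K),
            class = "vc_pca")
}

#' Project data onto fitted principal components
#'
#' Coefficients of the centered data in the retained component basis.
#'
#' @param model A [fit_pca()] result.
#' @param x A matrix whose columns match the fitted timepoints.
#' @return A units x K coefficient matrix.
#' @export
project_pca <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(model$mean))
    stop_visparc("x has %d columns, model expects %d", ncol(x),
                 length(model$mean), class = "visparc_input_error")
  sweep(x, 2, model$mean) %*% model$components
}

# ---- LDA -------------------------------------------------------------------

#' Fit a linear discriminant projection over areas
#'
#' Solves the generalized eigenproblem for the between-area scatter (the
#' unweighted 1/C average of squared class-mean offsets) against the total
#' covariance of the input features, keeping at most C - 1 discriminant
#' directions. The total covariance is ridge-regularized when
#' ill-conditioned.
#'
#' @param x A units x K feature matrix (typically PCA coefficients).
#' @param labels Per-unit area codes; each class needs >= 2 samples.
#' @param n_dims Number of discriminant directions (default C - 1).
#' @param ridge_cond Condition-number threshold beyond which a ridge of
#'   `1e-6 * trace / K` is added to the total covariance.
#' @return An object of class `vc_lda`: `projection` (K x N), `class_means`,
#'   `global_mean`, `n_dims`, `classes`.
#' @export
fit_lda <- function(x, labels, n_dims = NULL, ridge_cond = 1e8) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  C <- length(classes)
  if (C < 2)
    stop_visparc("need >= 2 classes", class = "visparc_input_error")
  sizes <- tabulate(match(labels, classes), C)
  if (any(sizes < 2))
    stop_visparc("class %d has < 2 samples", classes[which.min(sizes)],
                 class = "visparc_class_size_error")
  K <- ncol(x)
  mu <- colMeans(x)
  cmeans <- matrix(vapply(classes, function(cl)
    colMeans(x[labels == cl, , drop = FALSE]), numeric(K)),
    nrow = C, ncol = K, byrow = TRUE)
  offs <- sweep(cmeans, 2, mu)
  Sb <- crossprod(offs) / C
  if (max(abs(offs)) < 1e-12 * (1 + max(abs(mu))))
    stop_visparc("all class means identical: between-class scatter is zero",
                 class = "visparc_degenerate_error")
  xc <- sweep(x, 2, mu)
  Sigma <- crossprod(xc) / nrow(x)
  ev <- eigen(Sigma, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  if (vals[1] <= 0)
    stop_visparc("total covariance is zero", class = "visparc_degenerate_error")
  if (min(vals) <= 0 || vals[1] / min(vals) > ridge_cond) {
    tau <- 1e-6 * sum(vals) / K
    vals <- vals + tau
  }
  # whiten with Sigma^{-1/2}, then a symmetric eigenproblem on the scatter
  W_half <- ev$vectors %*% (t(ev$vectors) / sqrt(vals))
  Bt <- W_half %*% Sb %*% t(W_half)
  eb <- eigen((Bt + t(Bt)) / 2, symmetric = TRUE)
  N <- min(n_dims %||% (C - 1), C - 1, K)
  W <- t(W_half) %*% eb$vectors[, seq_len(N), drop = FALSE]
  structure(list(projection = fix_signs(W),
                 class_means = cmeans, global_mean = mu,
                 n_dims = N, classes = classes,
                 discriminability = eb$values[seq_len(N)]),
            class = "vc_lda")
}

#' Project features onto the discriminant directions
#'
#' @param model A [fit_lda()] result.
#' @param x Feature matrix with matching columns.
#' @param center Subtract the fitted global mean before projecting
#'   (default). `center = FALSE` returns the raw expansion coefficients,
#'   which retain the population-mean response; the correlation analysis
#'   of the discriminant domain uses this form so that shared response
#'   structure contributes to pairwise correlations just as it does in the
#'   raw signals.
#' @return A units x N matrix of discriminant coordinates.
#' @export
project_lda <- function(model, x, center = TRUE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != nrow(model$projection))
    stop_visparc("x has %d columns, model expects %d", ncol(x),
                 nrow(model$projection), class = "visparc_input_error")
  if (center) x <- sweep(x, 2, model$global_mean)
  x %*% model$projection
}

# ---- pipeline convenience --------------------------------------------------

#' Build the PCA -> LDA feature set of a recording
#'
#' Assembles the analysis matrix (trial-averaged stimulus windows or a
#' resting-state window), z-scores each unit across time, fits PCA (and
#' optionally LDA) on a training subset of units, and projects every unit.
#' Background units (label 0) are excluded.
#'
#' @param rec A `vc_recording`.
#' @param stimuli Stimulus ids for trial averaging (default all); ignored
#'   when `resting` is given.
#' @param resting `NULL`, or a list with `trim_start_s`, `trim_end_s`,
#'   `duration_s` passed to [take_resting()].
#' @param base Optionally, a precomputed units x time matrix (all units of
#'   the recording) to use instead of averaging.
#' @param fit_idx Indices (into the in-map units) used to fit the
#'   transforms; default all in-map units. Keeping the fit to training
#'   units avoids test-set leakage in evaluation protocols.
#' @param n_pcs Principal components to keep: count or variance fraction.
#' @param max_pcs Cap on retained components.
#' @param lda Fit the discriminant stage (default TRUE).
#' @param lda_dims Discriminant directions to keep (default C - 1).
#' @return An object of class `vc_features`: `features` (in-map units x N),
#'   `labels`, `unit_index` (rows of the recording retained), and
#'   `transform` (averaging config, `vc_pca`, `vc_lda` or NULL).
#' @export
build_features <- function(rec, stimuli = NULL, resting = NULL, base = NULL,
                           fit_idx = NULL, n_pcs = 0.95, max_pcs = 50,
                           lda = TRUE, lda_dims = NULL) {
  if (is.null(base)) {
    base <- if (is.null(resting)) trial_average(rec, stimuli)
            else take_resting(rec, resting$trim_start_s %||% 0,
                              resting$trim_end_s %||% 0,
                              resting$duration_s %||% "all")
  }
  in_map <- which(rec$unit_labels > 0L)
  labels <- rec$unit_labels[in_map]
  z <- zscore_rows(base[in_map, , drop = FALSE])
  fit_idx <- fit_idx %||% seq_along(in_map)
  pca <- fit_pca(z[fit_idx, , drop = FALSE], n_kept = n_pcs,
                 max_kept = max_pcs)
  F <- project_pca(pca, z)
  ldam <- NULL
  if (lda) {
    ldam <- fit_lda(F[fit_idx, , drop = FALSE], labels[fit_idx],
                    n_dims = lda_dims)
    F <- project_lda(ldam, F)
  }
  structure(list(features = F, labels = labels, unit_index = in_map,
                 transform = list(stimuli = stimuli, resting = resting,
                                  pca = pca, lda = ldam)),
            class = "vc_features")
}

#' Scatter units in the first two discriminant dimensions
#'
#' A quick visual check of area separability in feature space: each unit
#' is a point in the plane of the first two feature dimensions, colored
#' by its area.
#'
#' @param x A `vc_features` (needs >= 2 feature dimensions) or a matrix.
#' @param labels Area codes (taken from `x` when it is a `vc_features`).
#' @param main Plot title.
#' @return The input, invisibly.
#' @export
plot_feature_plane <- function(x, labels = NULL,
                               main = "Discriminant plane") {
  if (inherits(x, "vc_features")) { labels <- x$labels; x <- x$features }
  stopifnot(ncol(x) >= 2)
  cols <- hcl.colors(6, "Dark 3")
  graphics::plot(x[, 1], x[, 2], col = cols[labels], pch = 16, cex = 0.5,
                 xlab = "dimension 1", ylab = "dimension 2", main = main)
  legend("topright", legend = AREA_NAMES, col = cols, pch = 16, cex = 0.7)
  invisible(x)
}

#' @export
print.vc_features <- function(x, ...) {
  cat(sprintf("<vc_features> %d units x %d dims (%s)\n",
              nrow(x$features), ncol(x$features),
              if (is.null(x$transform$lda)) "PCA" else "PCA+LDA"))
  invisible(x)
}
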