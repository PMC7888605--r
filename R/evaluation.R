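# Evaluation protocols: train/test splits (per-area fraction sampling,
# radius-restricted training, label-shuffle control), rank-1 accuracy,
# row-normalized confusion matrices, unbiased and size-biased chance
# levels, intra-/inter-area correlation analysis, the supervised pipeline
# runner and the response-duration sweep.

#' Split specification
#'
#' @param mode `"fraction"` (per-area simple random sample),
#'   `"radius"` (training restricted to the center of each area), or
#'   `"shuffle"` (fraction split with the training labels permuted — the
#'   control that should drop accuracy to chance).
#' @param train_fraction Per-area training fraction; 0.05 is the wide-field
#'   default (pixels are spatially correlated, so sparse sampling keeps
#'   train and test nearly independent), 0.5 the two-photon default.
#' @param sample_radius_frac In radius mode, training pixels must lie
#'   within this fraction of the area radius from the area's interior pole.
#' @param n_repeats Random initializations to average over (default 5).
#' @param seed Base seed; repeat r uses a seed derived from `seed` and r.
#' @return A list of class `vc_split_spec`.
#' @export
split_spec <- function(mode = c("fraction", "radius", "shuffle"),
                       train_fraction = 0.05, sample_radius_frac = 1,
                       n_repeats = 5, seed = 1) {
  mode <- match.arg(mode)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_visparc("train_fraction must be in (0, 1)",
                 class = "visparc_param_error")
  if (n_repeats < 1)
    stop_visparc("n_repeats must be >= 1", class = "visparc_param_error")
  structure(list(mode = mode, train_fraction = train_fraction,
                 sample_radius_frac = sample_radius_frac,
                 n_repeats = n_repeats, seed = seed),
            class = "vc_split_spec")
}

#' Draw one train/test split
#'
#' @param labels Per-unit area codes (> 0).
#' @param coords Optional per-unit 0-based (row, col) pixel coordinates
#'   (required for radius mode).
#' @param area_map Optional `vc_area_map` (required for radius mode).
#' @param spec A [split_spec()].
#' @param repeat_i Which repeat (1-based); controls the derived seed.
#' @return A list with integer index vectors `train` and `test` (into
#'   `labels`) and, in shuffle mode, `train_labels` (the permuted labels).
#' @export
split_units <- function(labels, coords = NULL, area_map = NULL,
                        spec = split_spec(), repeat_i = 1) {
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  if (any(tabulate(match(labels, classes)) < 2))
    stop_visparc("every area needs >= 2 units",
                 class = "visparc_input_error")
  withr::with_seed(derive_seed(spec$seed, repeat_i), {
    train <- integer(0)
    if (spec$mode == "radius") {
      if (is.null(coords) || is.null(area_map))
        stop_visparc("radius mode needs coords and an area map",
                     class = "visparc_input_error")
      poles <- area_poles(area_map)
      for (k in classes) {
        idx <- which(labels == k)
        dt <- dist_transform(area_map$labels == k)
        radius <- max(dt)
        d <- sqrt((coords[idx, 1] + 1 - poles[k, 1])^2 +
                  (coords[idx, 2] + 1 - poles[k, 2])^2)
        elig <- idx[d <= spec$sample_radius_frac * radius]
        if (!length(elig))
          stop_visparc("area %s has no pixels within %.0f%% of its radius",
                       AREA_NAMES[k], 100 * spec$sample_radius_frac,
                       class = "visparc_radius_error")
        n_tr <- min(length(elig), max(1L, round(spec$train_fraction *
                                                length(idx))))
        train <- c(train, sample(elig, n_tr))
      }
    } else {
      for (k in classes) {
        idx <- which(labels == k)
        n_tr <- max(1L, round(spec$train_fraction * length(idx)))
        train <- c(train, sample(idx, n_tr))
      }
    }
    train <- sort(train)
    test <- setdiff(seq_along(labels), train)
    out <- list(train = train, test = test)
    if (spec$mode == "shuffle")
      out$train_labels <- sample(labels[train])
    out
  })
}

#' Rank-1 classification accuracy in percent
#'
#' @param actual,predicted Equal-length label vectors.
#' @return `100 * matches / n`.
#' @export
accuracy_pct <- function(actual, predicted) {
  if (length(actual) != length(predicted) || !length(actual))
    stop_visparc("actual and predicted must have equal positive length",
                 class = "visparc_input_error")
  100 * mean(actual == predicted)
}

#' Row-normalized confusion matrix
#'
#' Rows are actual areas, columns predicted; each row of an observed class
#' sums to 100. Rows of absent classes are zero and flagged in the
#' `"empty_rows"` attribute.
#'
#' @param actual,predicted Label vectors with values in `codes`.
#' @param codes Class codes spanning the matrix (default the 6 areas).
#' @return A 6 x 6 percent matrix (named by area).
#' @export
confusion_matrix <- function(actual, predicted, codes = AREA_CODES) {
  if (!all(c(actual, predicted) %in% codes))
    stop_visparc("labels outside the given codes",
                 class = "visparc_input_error")
  m <- matrix(0, length(codes), length(codes),
              dimnames = list(actual = AREA_NAMES[codes],
                              predicted = AREA_NAMES[codes]))
  tab <- table(factor(actual, levels = codes),
               factor(predicted, levels = codes))
  rs <- rowSums(tab)
  keep <- rs > 0
  m[keep, ] <- 100 * sweep(unclass(tab)[keep, , drop = FALSE], 1, rs[keep], "/")
  attr(m, "empty_rows") <- AREA_NAMES[codes][!keep]
  m
}

#' Unbiased chance level
#'
#' Accuracy of a fair n-faced die: `100 / n`, rounded to 2 decimals
#' (16.67% for the six areas).
#'
#' @param n_classes Number of classes (>= 2).
#' @return Percent.
#' @export
#' @examples
#' chance_unbiased(6)  # 16.67
chance_unbiased <- function(n_classes) {
  if (n_classes < 2)
    stop_visparc("need >= 2 classes", class = "visparc_input_error")
  round(100 / n_classes, 2)
}

#' Size-biased chance level
#'
#' Accuracy of a die biased by class proportions: `100 * sum(p_i^2)`.
#' Reported truncated to 1 decimal, matching the convention of printed
#' size-biased chance values (truncation, not rounding: the layer-4
#' Session C2 census gives 33.988… -> 33.9).
#'
#' @param class_counts Positive counts per class (>= 2 classes).
#' @param truncate Truncate to 1 decimal (default) or return full
#'   precision.
#' @return Percent.
#' @export
#' @examples
#' chance_biased(c(AL = 106, LM = 267, RL = 1023, AM = 115, PM = 234,
#'                 V1 = 149))  # 33.9
chance_biased <- function(class_counts, truncate = TRUE) {
  if (length(class_counts) < 2 || any(class_counts < 1))
    stop_visparc("need >= 2 classes with counts >= 1",
                 class = "visparc_input_error")
  p <- class_counts / sum(class_counts)
  v <- 100 * sum(p^2)
  if (truncate) floor(v * 10) / 10 else v
}

#' Intra- versus inter-area correlation analysis
#'
#' Pearson correlation over all unique unit pairs of the row vectors of
#' `x` (time series or feature vectors); the intra-area mean pools
#' same-label pairs, the inter-area mean different-label pairs. Constant
#' rows are excluded (their correlation is undefined) and counted.
#'
#' @param x Units x timepoints (or dims) matrix; >= 3 columns.
#' @param labels Per-unit area codes.
#' @return A list of class `vc_corr`: `intra`, `inter`, `ratio` (NA with
#'   `ratio_defined = FALSE` when the inter mean is <= 0), `n_excluded`.
#' @export
correlation_analysis <- function(x, labels) {
  x <- as.matrix(x)
  if (ncol(x) < 3)
    stop_visparc("need >= 3 timepoints/dims", class = "visparc_input_error")
  labels <- as.integer(labels)
  sds <- apply(x, 1, sd)
  keep <- sds > 0
  n_excluded <- sum(!keep)
  x <- x[keep, , drop = FALSE]
  labels <- labels[keep]
  if (length(unique(labels)) < 2 || nrow(x) < 2)
    stop_visparc("need >= 2 units in >= 2 areas",
                 class = "visparc_input_error")
  cm <- cor(t(x))
  ut <- upper.tri(cm)
  same <- outer(labels, labels, "==")
  intra_vals <- cm[ut & same]
  inter_vals <- cm[ut & !same]
  intra <- if (length(intra_vals)) mean(intra_vals) else NA_real_
  inter <- if (length(inter_vals)) mean(inter_vals) else NA_real_
  defined <- is.finite(inter) && inter > 0 && is.finite(intra)
  structure(list(intra = intra, inter = inter,
                 ratio = if (defined) intra / inter else NA_real_,
                 ratio_defined = defined,
                 n_intra_pairs = length(intra_vals),
                 n_inter_pairs = length(inter_vals),
                 n_excluded = n_excluded),
            class = "vc_corr")
}

#' @export
print.vc_corr <- function(x, ...) {
  cat(sprintf("<vc_corr> intra %.3f (n=%d)  inter %.3f (n=%d)  ratio %s\n",
              x$intra, x$n_intra_pairs, x$inter, x$n_inter_pairs,
              if (x$ratio_defined) sprintf("%.2f", x$ratio) else "undefined"))
  invisible(x)
}

# ---- supervised pipeline runner -------------------------------------------

# core protocol on a prepared (in-map, z-scored) base matrix
run_supervised_matrix <- function(z, labels, coords = NULL, area_map = NULL,
                                  classifier = "gmm", spec = split_spec(),
                                  n_pcs = 0.95, max_pcs = 50,
                                  lda_dims = NULL, gmm_M = 4, svm_C = 1,
                                  ann_epochs = 500) {
  accs <- numeric(spec$n_repeats)
  conf_actual <- integer(0)
  conf_pred <- integer(0)
  for (r in seq_len(spec$n_repeats)) {
    sp <- split_units(labels, coords, area_map, spec, repeat_i = r)
    y_tr <- sp$train_labels %||% labels[sp$train]
    pca <- fit_pca(z[sp$train, , drop = FALSE], n_kept = n_pcs,
                   max_kept = max_pcs)
    F <- project_pca(pca, z)
    lda <- fit_lda(F[sp$train, , drop = FALSE], y_tr, n_dims = lda_dims)
    F <- project_lda(lda, F)
    M_eff <- min(gmm_M, min(tabulate(factor(y_tr))))
    clf <- fit_area_classifier(classifier, F[sp$train, , drop = FALSE],
                               y_tr, seed = derive_seed(spec$seed, 100 + r),
                               gmm_M = max(1L, M_eff), svm_C = svm_C,
                               ann_epochs = ann_epochs)
    pred <- predict(clf, F[sp$test, , drop = FALSE])
    accs[r] <- accuracy_pct(labels[sp$test], pred)
    conf_actual <- c(conf_actual, labels[sp$test])
    conf_pred <- c(conf_pred, pred)
  }
  counts <- tabulate(labels, 6)
  structure(list(classifier = classifier, per_repeat = accs,
                 mean = mean(accs), sd = sd(accs),
                 confusion = confusion_matrix(conf_actual, conf_pred,
                                              codes = sort(unique(labels))),
                 chance_unbiased = chance_unbiased(length(unique(labels))),
                 chance_biased = chance_biased(counts[counts > 0]),
                 n_repeats = spec$n_repeats, spec = spec),
            class = "vc_eval")
}

#' Run the supervised classification protocol
#'
#' The full per-repeat protocol: split units into train/test, fit the
#' PCA and LDA transforms on the training units only (no test leakage),
#' project everything, fit the requested classifier, and score rank-1
#' accuracy on the held-out units; results are averaged over
#' `spec$n_repeats` random initializations.
#'
#' @param rec A `vc_recording`.
#' @param classifier One of `"bayes"`, `"gmm"`, `"svm"`, `"ann"`.
#' @param stimuli Stimulus ids for trial averaging (default all).
#' @param resting `NULL` or a [take_resting()] argument list; replaces the
#'   trial-averaged input with an untrialed window.
#' @param spec A [split_spec()].
#' @param n_pcs,max_pcs,lda_dims Feature front-end knobs.
#' @param gmm_M,svm_C,ann_epochs Classifier knobs.
#' @return An object of class `vc_eval`: per-repeat accuracies,
#'   mean ± SD, pooled confusion matrix, chance levels.
#' @export
run_supervised <- function(rec, classifier = c("gmm", "bayes", "svm", "ann"),
                           stimuli = NULL, resting = NULL,
                           spec = split_spec(), n_pcs = 0.95, max_pcs = 50,
                           lda_dims = NULL, gmm_M = 4, svm_C = 1,
                           ann_epochs = 500) {
  classifier <- match.arg(classifier)
  base <- if (is.null(resting)) trial_average(rec, stimuli)
          else take_resting(rec, resting$trim_start_s %||% 0,
                            resting$trim_end_s %||% 0,
                            resting$duration_s %||% "all")
  in_map <- which(rec$unit_labels > 0L)
  z <- zscore_rows(base[in_map, , drop = FALSE])
  coords <- if (!is.null(rec$unit_coords))
    rec$unit_coords[in_map, , drop = FALSE]
  run_supervised_matrix(z, rec$unit_labels[in_map], coords, rec$area_map,
                        classifier, spec, n_pcs, max_pcs, lda_dims,
                        gmm_M, svm_C, ann_epochs)
}

#' @export
print.vc_eval <- function(x, ...) {
  cat(sprintf("<vc_eval> %s: %.1f%% (±%.2f) over %d repeats  [chance %0.2f%% unbiased, %0.1f%% size-biased]\n",
              x$classifier, x$mean, x$sd, x$n_repeats,
              x$chance_unbiased, x$chance_biased))
  invisible(x)
}

#' Sweep response duration and trial handling
#'
#' Compares trial-averaged, single-trial and resting-state inputs of
#' matched durations: for each condition and duration the feature time
#' base is truncated to that duration and the supervised protocol is run.
#'
#' @param rec A `vc_recording`.
#' @param durations_s Window lengths in seconds.
#' @param conditions Subset of `c("trial_averaged", "single_trial",
#'   "resting")`.
#' @param classifier Classifier name (default `"gmm"`).
#' @param spec A [split_spec()].
#' @param resting_trim_s Seconds trimmed from both ends of the resting
#'   segment before truncation.
#' @param ... Passed to [run_supervised()]'s feature/classifier knobs.
#' @return A data.frame with one row per (condition, duration):
#'   `condition`, `duration_s`, `mean_accuracy`, `sd_accuracy`, `skipped`.
#' @export
duration_sweep <- function(rec, durations_s,
                           conditions = c("trial_averaged", "single_trial",
                                          "resting"),
                           classifier = "gmm", spec = split_spec(),
                           resting_trim_s = 5, ...) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  fr <- rec$frame_rate
  in_map <- which(rec$unit_labels > 0L)
  labels <- rec$unit_labels[in_map]
  coords <- if (!is.null(rec$unit_coords))
    rec$unit_coords[in_map, , drop = FALSE]
  base_of <- function(cond, dur) {
    want <- round(dur * fr)
    if (cond == "trial_averaged") {
      b <- trial_average(rec)
      if (want > ncol(b)) return(NULL)
      b[, seq_len(want), drop = FALSE]
    } else if (cond == "single_trial") {
      ids <- sort(unique(rec$trials$stimulus_id))
      b <- do.call(cbind, lapply(ids, function(s) {
        tr <- rec$trials[rec$trials$stimulus_id == s, , drop = FALSE]
        tr <- tr[which.min(tr$onset_frame), ]
        rec$responses[, (tr$onset_frame + 1L):(tr$onset_frame + tr$n_frames),
                      drop = FALSE]
      }))
      if (want > ncol(b)) return(NULL)
      b[, seq_len(want), drop = FALSE]
    } else {
      tryCatch(take_resting(rec, resting_trim_s, resting_trim_s, dur),
               visparc_length_error = function(e) NULL)
    }
  }
  rows <- list()
  for (cond in conditions) {
    for (dur in durations_s) {
      b <- base_of(cond, dur)
      if (is.null(b)) {
        rows[[length(rows) + 1L]] <-
          data.frame(condition = cond, duration_s = dur,
                     mean_accuracy = NA_real_, sd_accuracy = NA_real_,
                     skipped = TRUE)
        next
      }
      z <- zscore_rows(b[in_map, , drop = FALSE])
      ev <- run_supervised_matrix(z, labels, coords, rec$area_map,
                                  classifier, spec, ...)
      rows[[length(rows) + 1L]] <-
        data.frame(condition = cond, duration_s = dur,
                   mean_accuracy = ev$mean, sd_accuracy = ev$sd,
                   skipped = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Correlation ratios on raw responses and in the discriminant domain
#'
#' The discussion-figure analysis: intra- and inter-area correlations are
#' computed on the raw (trial-averaged) responses of held-out test units
#' and again on their discriminant features, with the PCA/LDA transforms
#' fitted on training units only. Note that centered discriminant
#' features of a balanced population have non-positive mean inter-area
#' correlation by construction (the count-weighted class means sum to
#' zero after centering), in which case the intra/inter ratio is flagged
#' undefined; see the methods vignette.
#'
#' @param rec A `vc_recording`.
#' @param stimuli,resting Response selection as in [build_features()].
#' @param spec A [split_spec()]; the first repeat's split is used.
#' @param n_pcs,max_pcs PCA retention rule.
#' @return A list with `raw` and `lda` [correlation_analysis()] results.
#' @export
lda_correlation_ratio <- function(rec, stimuli = NULL, resting = NULL,
                                  spec = split_spec(), n_pcs = 0.95,
                                  max_pcs = 50) {
  base <- if (is.null(resting)) trial_average(rec, stimuli)
          else take_resting(rec, resting$trim_start_s %||% 0,
                            resting$trim_end_s %||% 0,
                            resting$duration_s %||% "all")
  in_map <- which(rec$unit_labels > 0L)
  labels <- rec$unit_labels[in_map]
  z <- zscore_rows(base[in_map, , drop = FALSE])
  sp <- split_units(labels, spec = spec, repeat_i = 1)
  pca <- fit_pca(z[sp$train, , drop = FALSE], n_kept = n_pcs,
                 max_kept = max_pcs)
  F <- project_pca(pca, z)
  lda <- fit_lda(F[sp$train, , drop = FALSE], labels[sp$train])
  beta <- project_lda(lda, F)
  list(raw = correlation_analysis(base[in_map, ][sp$test, , drop = FALSE],
                                  labels[sp$test]),
       lda = correlation_analysis(beta[sp$test, , drop = FALSE],
                                  labels[sp$test]))
}
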