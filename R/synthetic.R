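# Synthetic cortical sheets and unit collections.
#
# The generators emulate the statistical structure the analysis assumes:
# per-unit dF/F traces are a sum of a shared global fluctuation, an
# area-specific latent signal, stimulus-locked area-specific response
# kernels inside trial windows, and independent per-unit noise (spatially
# smoothed in wide-field mode). All latent processes are unit-variance
# Gaussian and white in time, so intra-/inter-area correlations have the
# closed forms (sa^2+sg^2)/(sa^2+sg^2+sn^2) and sg^2/(sa^2+sg^2+sn^2)
# in the unsmoothed resting-state segment.

#' Simulation parameters
#'
#' Bundles every knob of the synthetic-data generators. Defaults describe
#' the package's reference simulation: a 64 x 64 pixel sheet imaged at
#' 10 Hz, 8 stimuli presented 10 times each in a block design (2 s stimulus,
#' 2 s blank), a 120 s resting-state tail, and unit-variance global,
#' area-specific and noise processes.
#'
#' @param n_rows,n_cols Sheet size in pixels (wide-field mode).
#' @param frame_rate Sampling rate in Hz.
#' @param n_stimuli Number of distinct stimuli; 0 gives a resting-state-only
#'   recording.
#' @param n_trials Trials (block repetitions) per stimulus.
#' @param stim_duration_s,blank_duration_s Stimulus and inter-stimulus blank
#'   durations in seconds.
#' @param resting_duration_s Length of the untrialed resting-state segment
#'   appended after the last trial block, in seconds.
#' @param sigma_area,sigma_global,sigma_noise Standard deviations (dF/F
#'   units) of the area-specific latent signal, the shared global signal
#'   and the per-unit noise.
#' @param sigma_stim Standard deviation of the fixed per-(area, stimulus)
#'   response kernels added inside trial windows.
#' @param spatial_smooth_px Gaussian smoothing radius (in pixels) applied to
#'   the noise field in wide-field mode; 0 disables smoothing.
#' @param per_area_counts Named integer vector of units per area for
#'   two-photon mode; names may be area names ("V1", ...) or codes. The
#'   default is the layer-4 (Nr5a1, Session C2) cell census used in the
#'   worked chance-level examples.
#' @param seed Integer seed; every generator is deterministic given it.
#'
#' @return A list of class `vc_sim_params`.
#' @export
#' @examples
#' p <- sim_params(n_stimuli = 2, n_trials = 3, seed = 1)
#' p$frame_rate
sim_params <- function(n_rows = 64, n_cols = 64, frame_rate = 10,
                       n_stimuli = 8, n_trials = 10,
                       stim_duration_s = 2, blank_duration_s = 2,
                       resting_duration_s = 120,
                       sigma_area = 1, sigma_global = 1, sigma_noise = 1,
                       sigma_stim = 1, spatial_smooth_px = 1,
                       per_area_counts = c(V1 = 149, LM = 267, AL = 106,
                                           RL = 1023, AM = 115, PM = 234),
                       seed = 1) {
  p <- list(n_rows = n_rows, n_cols = n_cols, frame_rate = frame_rate,
            n_stimuli = n_stimuli, n_trials = n_trials,
            stim_duration_s = stim_duration_s,
            blank_duration_s = blank_duration_s,
            resting_duration_s = resting_duration_s,
            sigma_area = sigma_area, sigma_global = sigma_global,
            sigma_noise = sigma_noise, sigma_stim = sigma_stim,
            spatial_smooth_px = spatial_smooth_px,
            per_area_counts = per_area_counts, seed = seed)
  validate_sim_params(p)
  structure(p, class = "vc_sim_params")
}

validate_sim_params <- function(p) {
  sig <- c(p$sigma_area, p$sigma_global, p$sigma_noise, p$sigma_stim)
  if (any(sig < 0))
    stop_visparc("signal standard deviations must be >= 0",
                 class = "visparc_param_error")
  if (p$n_stimuli > 0 && p$n_trials < 1)
    stop_visparc("n_trials must be >= 1", class = "visparc_param_error")
  if (length(p$per_area_counts) && any(p$per_area_counts < 1))
    stop_visparc("per-area unit counts must be >= 1",
                 class = "visparc_param_error")
  invisible(p)
}

#' Generate a six-area map of visual cortex
#'
#' Lays out a synthetic cortical sheet: an elliptical imaging field is
#' tiled into six 4-connected areas by budgeted breadth-first growth from
#' six seed points. The V1 seed receives at least twice the pixel budget of
#' each other seed, reproducing the dominance of V1 that drives the
#' size-biased chance level; the remaining five areas ring it. Pixels
#' outside the ellipse carry label 0 (background, non-visual cortex).
#'
#' @param n_rows,n_cols Raster size in pixels; both must be at least 32.
#' @param seed Integer seed controlling seed-point jitter.
#' @return An object of class `vc_area_map`: a list with `labels` (an
#'   `n_rows` x `n_cols` integer matrix with values 0..6), `area_names`,
#'   and `pixel_size` (mm/pixel, informational).
#' @export
#' @examples
#' am <- generate_area_map(64, 64, seed = 7)
#' table(am$labels)
generate_area_map <- function(n_rows, n_cols, seed = 1) {
  if (n_rows < 32 || n_cols < 32)
    stop_visparc("raster %dx%d too small to host 6 contiguous areas (need >= 32x32)",
                 n_rows, n_cols, class = "visparc_sizing_error")
  withr::with_seed(as.integer(seed), {
    cr <- (n_rows + 1) / 2
    cc <- (n_cols + 1) / 2
    a <- 0.48 * n_rows
    b <- 0.48 * n_cols
    rr <- matrix(seq_len(n_rows), n_rows, n_cols)
    cmat <- matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE)
    mask <- ((rr - cr) / a)^2 + ((cmat - cc) / b)^2 <= 1

    # V1 sits central-posterior; the five higher areas ring it.
    jit <- function(s) runif(1, -s, s)
    seeds <- rbind(
      c(cr + 0.18 * a + jit(2), cc + jit(2)),                  # V1
      c(cr + 0.55 * a + jit(1.5), cc - 0.45 * b + jit(1.5)),   # LM
      c(cr + 0.05 * a + jit(1.5), cc - 0.75 * b + jit(1.5)),   # AL
      c(cr - 0.55 * a + jit(1.5), cc - 0.35 * b + jit(1.5)),   # RL
      c(cr - 0.55 * a + jit(1.5), cc + 0.35 * b + jit(1.5)),   # AM
      c(cr + 0.05 * a + jit(1.5), cc + 0.75 * b + jit(1.5))    # PM
    )
    seeds[, 1] <- pmin(pmax(round(seeds[, 1]), 1), n_rows)
    seeds[, 2] <- pmin(pmax(round(seeds[, 2]), 1), n_cols)

    labels <- matrix(0L, n_rows, n_cols)
    total <- sum(mask)
    if (total < 6 * 25)
      stop_visparc("imaging field holds only %d pixels; need >= 150", total,
                   class = "visparc_sizing_error")
    w <- c(2, 1, 1, 1, 1, 1)
    budget <- floor(total * w / sum(w))
    budget[1] <- budget[1] + (total - sum(budget))

    # snap each seed to the nearest in-mask pixel not already claimed
    idx_of <- function(r, c) (c - 1L) * n_rows + r
    mask_idx <- which(mask)
    for (k in 1:6) {
      r0 <- seeds[k, 1]; c0 <- seeds[k, 2]
      d2 <- (((mask_idx - 1L) %% n_rows + 1L) - r0)^2 +
            (((mask_idx - 1L) %/% n_rows + 1L) - c0)^2
      ord <- order(d2, mask_idx)
      for (i in ord) {
        p <- mask_idx[i]
        if (labels[p] == 0L) { labels[p] <- k; break }
      }
    }

    queues <- lapply(1:6, function(k) which(labels == k))
    claimed <- budget * 0 + 1L
    nbr_offsets <- function(p) {
      r <- (p - 1L) %% n_rows + 1L
      c <- (p - 1L) %/% n_rows + 1L
      out <- c(if (r > 1) p - 1L, if (r < n_rows) p + 1L,
               if (c > 1) p - n_rows, if (c < n_cols) p + n_rows)
      out
    }
    grow_round <- function(respect_budget) {
      any_claim <- FALSE
      for (k in 1:6) {
        q <- queues[[k]]
        if (!length(q)) next
        if (respect_budget && claimed[k] >= budget[k]) next
        frontier <- integer(0)
        for (p in q) {
          for (nb in nbr_offsets(p)) {
            if (mask[nb] && labels[nb] == 0L) frontier <- c(frontier, nb)
          }
        }
        frontier <- unique(frontier)
        if (respect_budget) {
          room <- budget[k] - claimed[k]
          if (length(frontier) > room) frontier <- frontier[seq_len(room)]
        }
        if (length(frontier)) {
          labels[frontier] <<- k
          claimed[k] <<- claimed[k] + length(frontier)
          any_claim <- TRUE
        }
        queues[[k]] <<- frontier
      }
      any_claim
    }
    repeat if (!grow_round(TRUE)) break
    # pockets left when budgets bind: absorb into adjacent areas
    while (any(labels[mask] == 0L)) {
      queues <- lapply(1:6, function(k) which(labels == k))
      if (!grow_round(FALSE)) break
    }
    counts <- tabulate(labels[labels > 0L], 6)
    if (any(counts < 25))
      stop_visparc("area %s ended with %d < 25 pixels; raster too small",
                   AREA_NAMES[which.min(counts)], min(counts),
                   class = "visparc_sizing_error")
    structure(list(labels = labels,
                   area_names = setNames(AREA_NAMES, AREA_CODES),
                   pixel_size = 0.05),
              class = "vc_area_map")
  })
}

#' @export
print.vc_area_map <- function(x, ...) {
  counts <- tabulate(x$labels[x$labels > 0L], 6)
  cat(sprintf("<vc_area_map> %d x %d pixels, %d in-map\n",
              nrow(x$labels), ncol(x$labels), sum(x$labels > 0)))
  cat(paste(sprintf("%s=%d", x$area_names, counts), collapse = "  "), "\n")
  invisible(x)
}

#' @export
plot.vc_area_map <- function(x, main = "Synthetic visual cortex map", ...) {
  image(t(x$labels[nrow(x$labels):1, ]), col = c("grey90", hcl.colors(6, "Dark 3")),
        axes = FALSE, main = main, ...)
  invisible(x)
}

# shared latent/trial machinery --------------------------------------------

build_timeline <- function(p) {
  fr <- p$frame_rate
  stim_f <- round(p$stim_duration_s * fr)
  blank_f <- round(p$blank_duration_s * fr)
  trials <- NULL
  t0 <- 0L
  if (p$n_stimuli > 0) {
    rows <- vector("list", p$n_stimuli * p$n_trials)
    i <- 1L
    for (block in seq_len(p$n_trials)) {
      # each block presents every stimulus once, in a fresh random order
      for (s in sample.int(p$n_stimuli)) {
        rows[[i]] <- data.frame(stimulus_id = s, onset_frame = t0,
                                n_frames = stim_f)
        t0 <- t0 + stim_f + blank_f
        i <- i + 1L
      }
    }
    trials <- do.call(rbind, rows)
  }
  rest_f <- round(p$resting_duration_s * fr)
  list(trials = trials, n_frames = t0 + rest_f, stim_frames = stim_f)
}

# draws latents and assembles the units x T response matrix; `labels` is the
# per-unit area code (0 = background: global + noise only)
assemble_responses <- function(labels, p, timeline) {
  n_units <- length(labels)
  T <- timeline$n_frames
  if (T < 1)
    stop_visparc("simulation has zero frames", class = "visparc_param_error")
  if (p$sigma_area == 0 && p$sigma_global == 0 && p$sigma_noise == 0 &&
      (p$sigma_stim == 0 || is.null(timeline$trials)))
    stop_visparc("all signal components are zero: degenerate simulation",
                 class = "visparc_degenerate_error")
  g <- rnorm(T)
  A <- matrix(rnorm(6 * T), 6, T)
  kernels <- NULL
  if (!is.null(timeline$trials))
    kernels <- array(rnorm(6 * p$n_stimuli * timeline$stim_frames,
                           sd = p$sigma_stim),
                     dim = c(6, p$n_stimuli, timeline$stim_frames))
  R <- matrix(0, n_units, T)
  R <- R + p$sigma_global * matrix(g, n_units, T, byrow = TRUE)
  in_area <- labels > 0L
  if (p$sigma_area > 0 && any(in_area))
    R[in_area, ] <- R[in_area, ] + p$sigma_area * A[labels[in_area], , drop = FALSE]
  if (!is.null(kernels) && any(in_area)) {
    for (i in seq_len(nrow(timeline$trials))) {
      tr <- timeline$trials[i, ]
      cols <- (tr$onset_frame + 1L):(tr$onset_frame + tr$n_frames)
      R[in_area, cols] <- R[in_area, cols] +
        kernels[labels[in_area], tr$stimulus_id, , drop = FALSE][, 1, ]
    }
  }
  list(R = R, noise_sd = p$sigma_noise)
}

# separable Gaussian smoothing of a per-frame pixel field, as a sparse
# row-normalized operator applied to the (pixels x frames) noise matrix
smooth_operator <- function(n_rows, n_cols, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  band <- function(n) {
    i <- rep(seq_len(n), each = length(k))
    j <- i + rep(seq(-half, half), times = n)
    v <- rep(k, times = n)
    keep <- j >= 1 & j <= n
    m <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = v[keep],
                              dims = c(n, n))
    m / Matrix::rowSums(m)
  }
  Matrix::kronecker(band(n_cols), band(n_rows))
}

#' Simulate a wide-field recording
#'
#' Generates per-pixel dF/F traces over an area map. Each pixel's trace is
#' the sum of a shared global signal, its area's latent signal, fixed
#' stimulus-locked kernels inside trial windows, and per-pixel white noise
#' whose spatial field is Gaussian-smoothed to mimic the pixel-level
#' blurring of single-photon imaging. Background pixels carry only global
#' signal and noise. Trial blocks follow a block design with a fresh random
#' stimulus permutation per block; an untrialed resting-state segment
#' follows the last block.
#'
#' @param area_map A [generate_area_map()] result.
#' @param params A [sim_params()] object; `params$seed` makes the output
#'   fully reproducible.
#' @return An object of class `vc_recording` with elements `responses`
#'   (units x timepoints), `unit_coords` (0-based (row, col), row-major
#'   unit order), `unit_labels`, `trials` (0-based `onset_frame`, half-open
#'   windows), `frame_rate`, `mode = "widefield"`, and the `area_map`.
#' @export
#' @examples
#' am <- generate_area_map(32, 32, seed = 1)
#' rec <- simulate_widefield(am, sim_params(n_rows = 32, n_cols = 32,
#'   n_stimuli = 2, n_trials = 2, resting_duration_s = 10, seed = 1))
#' dim(rec$responses)
simulate_widefield <- function(area_map, params = sim_params()) {
  stopifnot(inherits(area_map, "vc_area_map"))
  validate_sim_params(params)
  n_rows <- nrow(area_map$labels)
  n_cols <- ncol(area_map$labels)
  labels <- as.integer(area_map$labels)   # column-major pixel order
  withr::with_seed(as.integer(params$seed), {
    tl <- build_timeline(params)
    parts <- assemble_responses(labels, params, tl)
    R <- parts$R
    if (params$sigma_noise > 0) {
      noise <- matrix(rnorm(length(labels) * tl$n_frames,
                            sd = params$sigma_noise),
                      length(labels), tl$n_frames)
      if (params$spatial_smooth_px > 0) {
        S <- smooth_operator(n_rows, n_cols, params$spatial_smooth_px)
        noise <- as.matrix(S %*% noise)
      }
      R <- R + noise
    }
    pix <- seq_along(labels)
    coords <- cbind(row = (pix - 1L) %% n_rows,
                    col = (pix - 1L) %/% n_rows)
    new_recording(responses = R, unit_coords = coords, unit_labels = labels,
                  trials = tl$trials, frame_rate = params$frame_rate,
                  mode = "widefield", area_map = area_map, params = params)
  })
}

#' Simulate a two-photon unit collection
#'
#' Same latent model as [simulate_widefield()] — shared global signal,
#' area-specific latents, stimulus-locked kernels, independent unit noise —
#' but units are exchangeable neurons without spatial coordinates or
#' smoothing, with per-area counts exactly as requested (unbalanced counts
#' mimic a cellular-resolution census pooled across sessions).
#'
#' @param per_area_counts Named vector of unit counts (names are area names
#'   or codes); overrides `params$per_area_counts` when given.
#' @param params A [sim_params()] object.
#' @return A `vc_recording` with `mode = "twophoton"` and `unit_coords = NULL`.
#' @export
#' @examples
#' rec <- simulate_twophoton(c(V1 = 10, LM = 10, AL = 10, RL = 10,
#'                             AM = 10, PM = 10),
#'   sim_params(n_stimuli = 2, n_trials = 2, resting_duration_s = 10, seed = 2))
#' length(rec$unit_labels)
simulate_twophoton <- function(per_area_counts = NULL, params = sim_params()) {
  validate_sim_params(params)
  counts <- per_area_counts %||% params$per_area_counts
  if (!length(counts))
    stop_visparc("per_area_counts is empty", class = "visparc_input_error")
  if (any(counts < 1))
    stop_visparc("per-area unit counts must be >= 1",
                 class = "visparc_input_error")
  codes <- names(counts)
  if (is.null(codes))
    stop_visparc("per_area_counts must be named by area name or code",
                 class = "visparc_input_error")
  code_of <- function(nm) {
    if (nm %in% AREA_NAMES) match(nm, AREA_NAMES)
    else as.integer(nm)
  }
  codes <- vapply(codes, code_of, integer(1))
  if (anyNA(codes) || any(codes < 1 | codes > 6))
    stop_visparc("unknown area in per_area_counts",
                 class = "visparc_input_error")
  labels <- rep(codes, times = counts)
  ord <- order(labels)
  labels <- labels[ord]
  withr::with_seed(as.integer(params$seed), {
    tl <- build_timeline(params)
    parts <- assemble_responses(labels, params, tl)
    R <- parts$R
    if (params$sigma_noise > 0)
      R <- R + matrix(rnorm(length(labels) * tl$n_frames,
                            sd = params$sigma_noise),
                      length(labels), tl$n_frames)
    new_recording(responses = R, unit_coords = NULL, unit_labels = labels,
                  trials = tl$trials, frame_rate = params$frame_rate,
                  mode = "twophoton", area_map = NULL, params = params)
  })
}

new_recording <- function(responses, unit_coords, unit_labels, trials,
                          frame_rate, mode, area_map = NULL, params = NULL) {
  rec <- structure(list(responses = responses, unit_coords = unit_coords,
                        unit_labels = as.integer(unit_labels),
                        trials = trials, frame_rate = frame_rate,
                        mode = mode, area_map = area_map, params = params),
                   class = "vc_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  T <- ncol(rec$responses)
  if (!is.null(rec$trials)) {
    if (any(rec$trials$onset_frame + rec$trials$n_frames > T))
      stop_visparc("trial window extends past the recording (%d frames)", T,
                   class = "visparc_validation_error")
    if (any(rec$trials$onset_frame < 0))
      stop_visparc("negative trial onset", class = "visparc_validation_error")
  }
  if (length(rec$unit_labels) != nrow(rec$responses))
    stop_visparc("unit_labels length != number of response rows",
                 class = "visparc_validation_error")
  if (identical(rec$mode, "widefield")) {
    cm <- rec$unit_coords
    if (is.null(cm))
      stop_visparc("widefield recording needs unit_coords",
                   class = "visparc_validation_error")
    if (anyDuplicated(cm))
      stop_visparc("duplicate unit coordinates",
                   class = "visparc_validation_error")
    if (!is.null(rec$area_map)) {
      lab <- rec$area_map$labels[cbind(cm[, 1] + 1L, cm[, 2] + 1L)]
      if (!all(lab == rec$unit_labels))
        stop_visparc("unit_labels disagree with the area map",
                     class = "visparc_validation_error")
    }
  }
  invisible(rec)
}

#' @export
print.vc_recording <- function(x, ...) {
  cat(sprintf("<vc_recording> %s: %d units x %d frames @ %g Hz\n",
              x$mode, nrow(x$responses), ncol(x$responses), x$frame_rate))
  if (!is.null(x$trials))
    cat(sprintf("  %d trials over %d stimuli\n", nrow(x$trials),
                length(unique(x$trials$stimulus_id))))
  cat(sprintf("  area counts: %s\n",
              paste(sprintf("%s=%d", AREA_NAMES,
                            tabulate(x$unit_labels[x$unit_labels > 0], 6)),
                    collapse = " ")))
  invisible(x)
}
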