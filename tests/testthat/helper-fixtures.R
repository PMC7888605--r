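# Shared fixtures (memoized across test files) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# the reference study conditions: 64x64 sheet, 8 stimuli x 10 trials,
# unit-variance global/area/noise processes, 120 s resting tail
default_map <- function() memo("map64", generate_area_map(64, 64, seed = 7))

default_widefield <- function() memo("wf64",
  simulate_widefield(default_map(), sim_params(seed = 3)))

# a lighter sheet for unit tests
small_map <- function() memo("map48", generate_area_map(48, 48, seed = 5))

small_widefield <- function() memo("wf48",
  simulate_widefield(small_map(),
    sim_params(n_rows = 48, n_cols = 48, n_stimuli = 4, n_trials = 5,
               resting_duration_s = 30, seed = 2)))

small_twophoton <- function() memo("tp",
  simulate_twophoton(setNames(rep(12L, 6), c("V1", "LM", "AL", "RL",
                                             "AM", "PM")),
    sim_params(n_stimuli = 3, n_trials = 4, resting_duration_s = 20,
               seed = 4)))

# 48x64 map of six rectangles aligned to an 8-px grid: no grid cell
# straddles an area border, so noise-free region growing has an exact
# ground truth at the cell level
aligned_map <- function() memo("aligned", {
  lab <- matrix(0L, 48, 64)
  lab[1:24, 1:16] <- 2L   # LM
  lab[1:24, 17:32] <- 3L  # AL
  lab[25:48, 1:16] <- 4L  # RL
  lab[25:48, 17:32] <- 5L # AM
  lab[1:24, 33:48] <- 6L  # PM
  lab[25:48, 33:48] <- 1L # V1 part
  lab[, 49:64] <- 1L      # V1 dominant
  structure(list(labels = lab,
                 area_names = setNames(c("V1", "LM", "AL", "RL", "AM", "PM"),
                                       1:6),
                 pixel_size = 0.05),
            class = "vc_area_map")
})

aligned_zero_noise <- function() memo("aligned0",
  simulate_widefield(aligned_map(),
    sim_params(n_rows = 48, n_cols = 64, sigma_noise = 0, sigma_global = 0,
               spatial_smooth_px = 0, n_stimuli = 2, n_trials = 2,
               resting_duration_s = 10, seed = 6)))

# hand-rolled recording for exact-arithmetic feature tests
toy_recording <- function(responses, trials, frame_rate = 1,
                          labels = NULL) {
  visparc:::new_recording(
    responses = responses, unit_coords = NULL,
    unit_labels = labels %||% rep(1L, nrow(responses)),
    trials = trials, frame_rate = frame_rate, mode = "twophoton")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- independent oracles ---------------------------------------------------

# 4-connectivity check by flood fill
is_connected4 <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(TRUE)
  n_rows <- nrow(mask)
  visited <- matrix(FALSE, n_rows, ncol(mask))
  queue <- idx[1]
  visited[queue] <- TRUE
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    r <- (p - 1) %% n_rows + 1; c <- (p - 1) %/% n_rows + 1
    for (nb in c(if (r > 1) p - 1, if (r < n_rows) p + 1,
                 if (c > 1) p - n_rows, if (c < ncol(mask)) p + n_rows)) {
      if (mask[nb] && !visited[nb]) { visited[nb] <- TRUE
                                      queue <- c(queue, nb) }
    }
  }
  all(visited[idx])
}

# brute-force Euclidean distance of every in-mask pixel to the nearest
# out-of-mask pixel (quadratic; for small rasters only)
brute_distance_to_boundary <- function(mask) {
  out <- matrix(0, nrow(mask), ncol(mask))
  outside <- which(!mask)
  ro <- (outside - 1) %% nrow(mask) + 1
  co <- (outside - 1) %/% nrow(mask) + 1
  for (p in which(mask)) {
    r <- (p - 1) %% nrow(mask) + 1; c <- (p - 1) %/% nrow(mask) + 1
    out[p] <- sqrt(min((ro - r)^2 + (co - c)^2))
  }
  out
}

# independent multivariate normal log-density (solve/determinant route,
# no shared code with the package's Cholesky implementation)
oracle_mvn_logdens <- function(x, mu, S) {
  d <- length(mu)
  xc <- x - mu
  as.numeric(-0.5 * d * log(2 * pi) - 0.5 * determinant(S)$modulus -
             0.5 * t(xc) %*% solve(S, xc))
}
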