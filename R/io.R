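# Recording container and result export.
#
# A recording is stored as a directory of plain-text files: TSV matrices
# written at 17 significant digits (which round-trips IEEE doubles
# exactly) plus a meta.json carrying frame rate, mode, schema version,
# seed and the simulation parameters. Every exported result embeds the
# seed and a configuration fingerprint.

SCHEMA_VERSION <- "1.0"

fwrite_matrix <- function(m, path) {
  dt <- data.table::as.data.table(
    matrix(sprintf("%.17g", m), nrow(m), ncol(m)))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
}

fread_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = "numeric", showProgress = FALSE)
  m <- as.matrix(dt)
  dimnames(m) <- NULL
  m
}

#' Write a recording container
#'
#' Serializes a `vc_recording` (and its area map, in wide-field mode) to
#' a directory of TSV/CSV/JSON files. Matrices are written at full double
#' precision so a read-back reproduces `responses` bit-exactly.
#'
#' @param rec A `vc_recording`.
#' @param path Directory to create (must not be a file).
#' @return `path`, invisibly.
#' @export
write_container <- function(rec, path) {
  stopifnot(inherits(rec, "vc_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fwrite_matrix(rec$responses, file.path(path, "responses.tsv"))
  data.table::fwrite(data.table::data.table(label = rec$unit_labels),
                     file.path(path, "unit_labels.tsv"), sep = "\t")
  if (!is.null(rec$unit_coords))
    data.table::fwrite(data.table::as.data.table(rec$unit_coords),
                       file.path(path, "unit_coords.tsv"), sep = "\t")
  if (!is.null(rec$trials))
    data.table::fwrite(rec$trials, file.path(path, "trials.csv"))
  if (!is.null(rec$area_map)) {
    data.table::fwrite(data.table::as.data.table(rec$area_map$labels),
                       file.path(path, "area_map.tsv"), sep = "\t",
                       col.names = FALSE)
  }
  params <- rec$params
  meta <- list(schema_version = SCHEMA_VERSION,
               mode = rec$mode, frame_rate_hz = rec$frame_rate,
               n_units = nrow(rec$responses),
               n_frames = ncol(rec$responses),
               seed = params$seed %||% NA,
               sim_params = if (!is.null(params)) unclass(params),
               config_hash = config_hash(params))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a recording container
#'
#' Loads and validates a directory written by [write_container()]: shapes
#' must be mutually consistent, labels in 0..6, trial windows inside the
#' recording, and wide-field coordinates unique, inside the raster, and
#' in agreement with the area map.
#'
#' @param path Container directory.
#' @return A `vc_recording` (with `area_map` when present).
#' @export
read_container <- function(path) {
  need <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp))
      stop_visparc("container is missing %s", f,
                   class = "visparc_schema_error")
    fp
  }
  meta <- jsonlite::read_json(need("meta.json"), simplifyVector = TRUE)
  if (is.null(meta$schema_version))
    stop_visparc("meta.json lacks schema_version",
                 class = "visparc_schema_error")
  if (!identical(as.character(meta$schema_version), SCHEMA_VERSION))
    stop_visparc("unsupported schema_version %s", meta$schema_version,
                 class = "visparc_schema_error")
  R <- fread_matrix(need("responses.tsv"))
  labels <- data.table::fread(need("unit_labels.tsv"))$label
  if (length(labels) != nrow(R))
    stop_visparc("unit_labels length %d != %d response rows",
                 length(labels), nrow(R), class = "visparc_validation_error")
  if (!all(labels %in% 0:6))
    stop_visparc("unit labels outside 0..6",
                 class = "visparc_validation_error")
  trials <- NULL
  if (file.exists(file.path(path, "trials.csv")))
    trials <- as.data.frame(data.table::fread(file.path(path, "trials.csv")))
  coords <- NULL; amap <- NULL
  if (identical(meta$mode, "widefield")) {
    coords <- as.matrix(fread_matrix_int(need("unit_coords.tsv"), header = TRUE))
    if (is.null(trials))
      stop_visparc("container is missing trials.csv",
                   class = "visparc_schema_error")
    am_lab <- fread_matrix_int(need("area_map.tsv"), header = FALSE)
    amap <- structure(list(labels = am_lab,
                           area_names = setNames(AREA_NAMES, AREA_CODES),
                           pixel_size = 0.05),
                      class = "vc_area_map")
    if (any(coords[, 1] < 0 | coords[, 1] >= nrow(am_lab) |
            coords[, 2] < 0 | coords[, 2] >= ncol(am_lab)))
      stop_visparc("unit coordinates outside the area-map raster",
                   class = "visparc_validation_error")
  }
  params <- meta$sim_params
  new_recording(responses = R, unit_coords = coords, unit_labels = labels,
                trials = trials, frame_rate = meta$frame_rate_hz,
                mode = meta$mode, area_map = amap, params = params)
}

fread_matrix_int <- function(path, header = FALSE) {
  dt <- data.table::fread(path, sep = "\t", header = header,
                          showProgress = FALSE)
  m <- as.matrix(dt)
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

# ---- result export ---------------------------------------------------------

#' Export evaluation and parcellation results
#'
#' Writes a `vc_eval` report as a per-repeat CSV plus a JSON summary, a
#' confusion matrix as CSV, a parcellation raster as a portable graymap
#' (PGM, P2) plus a (row, col, label) CSV, or a merge log as CSV. Every
#' file embeds the seed and configuration fingerprint (JSON fields, or a
#' `#`-comment header line).
#'
#' @param x A `vc_eval`, `vc_parcellation`, matrix (confusion), or the
#'   merge-log data.frame of a `vc_cluster_state`.
#' @param prefix Output path prefix (directories are created).
#' @param seed Seed to stamp into the outputs.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(x, prefix, seed = NA) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# seed=%s config=%s", seed, config_hash(unclass(x)))
  files <- character(0)
  emit_csv <- function(df, path) {
    # doubles go out at 17 significant digits so a re-read is exact
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
    writeLines(stamp, path)
    suppressWarnings(
      data.table::fwrite(df, path, append = TRUE, col.names = TRUE))
    files <<- c(files, path)
  }
  if (inherits(x, "vc_eval")) {
    emit_csv(data.frame(repeat_i = seq_along(x$per_repeat),
                        classifier = x$classifier,
                        accuracy = x$per_repeat),
             paste0(prefix, "_accuracy.csv"))
    emit_csv(as.data.frame(x$confusion), paste0(prefix, "_confusion.csv"))
    jsonlite::write_json(
      list(classifier = x$classifier, mean = x$mean, sd = x$sd,
           n_repeats = x$n_repeats, chance_unbiased = x$chance_unbiased,
           chance_biased = x$chance_biased, seed = seed,
           config_hash = config_hash(unclass(x))),
      paste0(prefix, "_summary.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, paste0(prefix, "_summary.json"))
  } else if (inherits(x, "vc_parcellation")) {
    files <- c(files, write_pgm(x$pixel_labels, paste0(prefix, ".pgm"), stamp))
    idx <- which(x$pixel_labels >= 0)
    emit_csv(data.frame(row = (idx - 1L) %% nrow(x$pixel_labels),
                        col = (idx - 1L) %/% nrow(x$pixel_labels),
                        label = as.integer(x$pixel_labels[idx])),
             paste0(prefix, "_labels.csv"))
    if (!is.null(x$state$merge_log))
      emit_csv(x$state$merge_log, paste0(prefix, "_merge_log.csv"))
    jsonlite::write_json(
      list(accuracy = x$accuracy, cell_accuracy = x$cell_accuracy,
           iterations = x$state$iteration, seed = seed,
           config_hash = config_hash(unclass(x$state$labels))),
      paste0(prefix, "_summary.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, paste0(prefix, "_summary.json"))
  } else if (inherits(x, "vc_area_map")) {
    files <- c(files, write_pgm(x$labels, paste0(prefix, ".pgm"), stamp))
    idx <- seq_along(x$labels)
    emit_csv(data.frame(row = (idx - 1L) %% nrow(x$labels),
                        col = (idx - 1L) %/% nrow(x$labels),
                        label = as.integer(x$labels[idx])),
             paste0(prefix, "_labels.csv"))
  } else if (is.matrix(x)) {
    emit_csv(as.data.frame(x), paste0(prefix, "_matrix.csv"))
  } else if (is.data.frame(x)) {
    emit_csv(x, paste0(prefix, ".csv"))
  } else {
    stop_visparc("don't know how to export objects of class %s",
                 paste(class(x), collapse = "/"),
                 class = "visparc_input_error")
  }
  invisible(files)
}

# plain-text (P2) portable graymap of an integer raster
write_pgm <- function(raster, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("P2", con)
  if (!is.null(comment)) writeLines(comment, con)
  writeLines(sprintf("%d %d", ncol(raster), nrow(raster)), con)
  writeLines(sprintf("%d", max(raster, 1)), con)
  apply(raster, 1, function(row)
    writeLines(paste(as.integer(row), collapse = " "), con))
  path
}

#' Read a run configuration
#'
#' Loads a YAML configuration with sections `simulate`, `features`,
#' `classifiers`, `semisup` and `evaluate` plus a global `seed`; unknown
#' top-level keys are rejected so typos fail loudly. Missing sections fall
#' back to package defaults; stage seeds derive deterministically from
#' the global seed.
#'
#' @param path YAML file.
#' @return A named list of class `vc_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("simulate", "features", "classifiers", "semisup",
               "evaluate", "seed")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop_visparc("unknown config section(s): %s", paste(bad, collapse = ", "),
                 class = "visparc_config_error")
  cfg$seed <- cfg$seed %||% 1
  structure(cfg, class = "vc_run_config")
}
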