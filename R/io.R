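# deterministic per-stage seed derivation from one root seed
.stage_seed <- function(root, stage) {
  offsets <- c(brain = 11L, activity = 23L, render = 37L, motion = 41L,
               analysis = 53L, cluster = 67L, misc = 79L)
  as.integer((as.numeric(root) * 1009 + offsets[[stage]]) %% 2147483647)
}

#' Write / read a trace matrix
#'
#' CSV keeps one row per trace (column `trace` then `t<k>` samples); HDF5
#' (`rhdf5` backend, if installed) stores the matrix with the sampling rate
#' as an attribute-style dataset.
#'
#' @param traces A [trace_matrix()].
#' @param path Output file; format chosen by extension (`.csv` or `.h5`).
#' @export
write_traces <- function(traces, path) {
  rate <- attr(traces, "rate")
  if (grepl("\\.h5$", path)) {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("rhdf5 is required for HDF5 output")
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(unclass(traces), path, "traces")
    rhdf5::h5write(rate, path, "rate")
    rhdf5::H5close()
  } else {
    df <- as.data.frame(unclass(traces))
    names(df) <- sprintf("t%d", seq_len(ncol(df)))
    df <- cbind(trace = seq_len(nrow(df)), df)
    utils::write.csv(cbind(df, rate = rate), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  if (grepl("\\.h5$", path)) {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("rhdf5 is required for HDF5 input")
    m <- rhdf5::h5read(path, "traces")
    rate <- as.numeric(rhdf5::h5read(path, "rate"))
    rhdf5::H5close()
    return(trace_matrix(m, rate = rate))
  }
  df <- utils::read.csv(path)
  rate <- df$rate[1]
  m <- as.matrix(df[, grepl("^t\\d+$", names(df)), drop = FALSE])
  dimnames(m) <- NULL
  trace_matrix(m, rate = rate)
}

#' Write a frame stream to HDF5
#'
#' Dataset `frames` is `t` x `y` x `x` (acquisition order) with `n_planes`
#' and `frame_rate` stored alongside, so plane membership (`frame mod
#' n_planes`) is recoverable.
#'
#' @param stream A `frame_stream`.
#' @param path HDF5 output file.
#' @export
write_stream_h5 <- function(stream, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("rhdf5 is required for HDF5 output")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(aperm(stream$frames, c(3, 1, 2)), path, "frames")
  rhdf5::h5write(stream$geometry$n_planes, path, "n_planes")
  rhdf5::h5write(stream$geometry$frame_rate, path, "frame_rate")
  rhdf5::H5close()
  invisible(path)
}

#' Write ground truth as JSON + CSV
#'
#' Cell table (positions, flags, motifs, amplitudes) as CSV; scalar
#' metadata (seed, minimum distance, volume extent) as JSON.
#'
#' @param truth A [generate_brain()] ground truth.
#' @param csv_path,json_path Output files (NULL to skip either).
#' @export
write_ground_truth <- function(truth, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    df <- data.frame(truth$cell_positions, responsive = truth$responsive,
                     motif = truth$motif, amplitude = truth$amplitude)
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(
      list(seed = truth$seed, min_distance = truth$min_distance,
           n_cells = nrow(truth$cell_positions),
           extent = c(truth$geometry$fov_x, truth$geometry$fov_y,
                      truth$geometry$z_range)),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(truth)
}

#' Write a stimulus protocol as YAML
#'
#' @param protocol A [stimulus_protocol()].
#' @param path YAML output file.
#' @export
write_protocol <- function(protocol, path) {
  yaml::write_yaml(list(
    onsets = protocol$presentations$onset,
    durations = protocol$presentations$offset - protocol$presentations$onset,
    dot_diameter = protocol$dot_diameter,
    screen_distance = protocol$screen_distance,
    size_to_speed = protocol$size_to_speed), path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  stimulus_protocol(onsets = unlist(y$onsets),
                    stim_duration = unlist(y$durations),
                    dot_diameter = y$dot_diameter %||% 50,
                    screen_distance = y$screen_distance %||% 30,
                    size_to_speed = y$size_to_speed %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
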