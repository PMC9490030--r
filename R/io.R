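#' Write / read a recording in flat binary format
#'
#' Raw signals are stored as 16-bit signed little-endian integers,
#' interleaved by channel (all channels of sample 1, then sample 2, ...),
#' with a YAML sidecar (`<path>.yaml`) holding the channel count, sampling
#' rate, tetrode map, scale factor, session offset and sample count. The
#' round trip is lossless for integer-valued samples within the int16 range
#' divided by the scale factor.
#'
#' @param rec a [recording_segment()].
#' @param path file path for the binary samples; the sidecar is written
#'   next to it.
#' @param scale multiplicative factor applied before rounding to int16;
#'   `NULL` picks the largest lossless power of two covering the data range.
#' @return `write_recording`: `path`, invisibly. `read_recording`: a
#'   [recording_segment()].
#' @export
write_recording <- function(rec, path, scale = NULL) {
  stopifnot(inherits(rec, "recording_segment"))
  if (is.null(scale)) {
    mx <- max(1e-12, max(abs(rec$samples)))
    scale <- 2^floor(log2(32000 / mx))
  }
  q <- round(rec$samples * scale)
  if (max(abs(q)) > 32767)
    stop("write_recording: samples exceed int16 range at this scale")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(t(q)), con, size = 2L, endian = "little")
  meta <- list(format = "int16-le-interleaved",
               n_channels = ncol(rec$samples),
               n_samples = nrow(rec$samples),
               fs = rec$fs, t0 = rec$t0, scale = scale,
               tetrodes = lapply(rec$tetrodes, as.integer))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta_path <- paste0(path, ".yaml")
  if (!file.exists(meta_path))
    stop("read_recording: missing sidecar metadata file ", meta_path)
  meta <- tryCatch(yaml::read_yaml(meta_path), error = function(e)
    stop("read_recording: corrupt metadata: ", conditionMessage(e)))
  for (f in c("n_channels", "n_samples", "fs", "scale", "tetrodes"))
    if (is.null(meta[[f]]))
      stop("read_recording: metadata missing field '", f, "'")
  n_val <- meta$n_channels * meta$n_samples
  expected_bytes <- 2 * n_val
  if (file.info(path)$size < expected_bytes)
    stop("read_recording: truncated file: expected ", expected_bytes,
         " bytes, found ", file.info(path)$size)
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = n_val, size = 2L, signed = TRUE,
                 endian = "little")
  if (length(raw) != n_val)
    stop("read_recording: channel-count mismatch or truncated data")
  samples <- t(matrix(raw, nrow = meta$n_channels)) / meta$scale
  recording_segment(samples, fs = meta$fs, tetrodes = meta$tetrodes,
                    t0 = if (is.null(meta$t0)) 0 else meta$t0)
}

#' Write / read tabular results
#'
#' Event, target and judgment tables are plain UTF-8 CSV with a header row;
#' times are in ms with 6 decimals, sample indices integer.
#'
#' @param df data frame.
#' @param path file path.
#' @return `write_table`: `path` invisibly; `read_table_csv`: data frame.
#' @export
write_table <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) round(x, 6))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_csv <- function(path) utils::read.csv(path)

run_config_defaults <- function() {
  list(
    # controller
    theta_trig = 0.99, N_test = 200, I_same = 1.0, I_diff = 0.5,
    latency_range_ms = c(1.6, 3.2),
    # stimulation / collection
    N_anti = 100, duration_ms = 1.0, T_range_ms = 30,
    # filtering / detection
    sigma_ms = 0.25, theta_sp = 4, tau_y_ms = 0.25, tau_v_s = 1.0,
    # inference
    width_ms = 1, W_jitter = 4, theta_win = 5, alpha = 1,
    theta_aggr = NULL, detect_sd = 5, max_targets = 12,
    # judgment
    R_max = 4, min_triggers = 15, cap = 10, sigma_mult = 5,
    jitter_max = 0.25,
    # misc
    fs = 20000, seed = 1
  )
}

check_run_config <- function(cfg) {
  if (cfg$theta_trig <= 0 || cfg$theta_trig >= 1)
    stop("load_config: 'theta_trig' must be in (0,1)")
  positive <- c("N_test", "I_same", "I_diff", "N_anti", "duration_ms",
                "T_range_ms", "sigma_ms", "theta_sp", "width_ms",
                "W_jitter", "theta_win", "alpha", "detect_sd", "R_max",
                "min_triggers", "cap", "sigma_mult", "jitter_max", "fs")
  for (f in positive)
    if (any(cfg[[f]] <= 0))
      stop("load_config: '", f, "' must be positive")
  cfg
}

#' Load a run configuration with defaults and overrides
#'
#' Reads a YAML configuration; absent keys take the standard defaults
#' (trigger criterion 0.99, 200 tests per target, 1.0 s / 0.5 s minimum
#' intervals, 100 collection stimulations per site, 30 ms peristimulus
#' range, 1 ms stimulus duration, 0.25 ms filter sigma, 4 SD detection,
#' 1 ms / W = 4 protocol-I window, alpha = 1 ms, 5 SD trial detection,
#' R_max = 4 ms, 15 minimum triggers, 10x no-trigger cap, 5 sigma and
#' 0.25 ms success criteria). Explicit `overrides` win over the file.
#' Unknown keys and out-of-range values raise validation errors naming the
#' key.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list of overriding values.
#' @return named list with the effective configuration.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  from_file <- if (!is.null(path)) {
    x <- yaml::read_yaml(path)
    if (is.null(x)) list() else x
  } else list()
  for (src in list(from_file, overrides)) {
    for (k in names(src)) {
      if (!k %in% names(cfg))
        stop("load_config: unknown configuration key '", k, "'")
      cfg[[k]] <- src[[k]]
    }
  }
  check_run_config(cfg)
}
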