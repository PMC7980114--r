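#' Read a uniformly sampled signal CSV
#'
#' Reads either a PPG stream (`time_s,ppg`) or a tri-axial accelerometer
#' stream (`time_s,ax_g,ay_g,az_g` with optional `label`). Timestamps must
#' be strictly increasing and uniform within 1%; the rate is taken from
#' `rate` when given, otherwise inferred from the timestamps.
#'
#' @param path CSV path.
#' @param type `"ppg"` or `"accel"`.
#' @param rate Optional sampling rate in Hz overriding inference.
#' @return A `raw_signal` (ppg) or `accel_stream` (accel; with `labels` if
#'   the CSV has a label column).
#' @export
read_signal_csv <- function(path, type = c("ppg", "accel"), rate = NULL) {
  type <- match.arg(type)
  if (!file.exists(path)) {
    stop("read_signal_csv: cannot read '", path, "'", call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- if (type == "ppg") c("time_s", "ppg") else
    c("time_s", "ax_g", "ay_g", "az_g")
  missing <- setdiff(expected, names(df))
  if (length(missing) > 0L) {
    stop("read_signal_csv: format error, missing columns: ",
         paste(missing, collapse = ", "), " (expected ",
         paste(expected, collapse = ","), ")", call. = FALSE)
  }
  tm <- df$time_s
  d <- diff(tm)
  bad <- which(d <= 0)
  if (length(bad) > 0L) {
    stop("read_signal_csv: format error, non-increasing time at row ",
         bad[1L] + 1L, call. = FALSE)
  }
  med <- stats::median(d)
  off <- which(abs(d - med) / med > 0.01)
  if (length(off) > 0L) {
    stop("read_signal_csv: format error, non-uniform sampling at row ",
         off[1L] + 1L, call. = FALSE)
  }
  r <- if (is.null(rate)) 1 / med else rate
  if (type == "ppg") {
    raw_signal(df$ppg, r, start_time = tm[1L])
  } else {
    out <- accel_stream(tm, df$ax_g, df$ay_g, df$az_g, r)
    if ("label" %in% names(df)) out$labels <- df$label
    out
  }
}

#' Write a PPG or accelerometer stream to CSV
#' @param x A `raw_signal` or `accel_stream`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path) {
  if (inherits(x, "raw_signal")) {
    utils::write.csv(data.frame(time_s = signal_times(x), ppg = x$samples),
                     path, row.names = FALSE)
  } else if (inherits(x, "accel_stream")) {
    df <- data.frame(time_s = x$t, ax_g = x$x, ay_g = x$y, az_g = x$z)
    if (!is.null(x$labels)) df$label <- x$labels
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    stop("write_signal_csv: unsupported object", call. = FALSE)
  }
  invisible(path)
}

#' Write the per-cycle quality table of a preprocessed session
#'
#' Emits the cycles table CSV
#' `cycle_id,start_s,peak_s,end_s,duration_s,correlation,norm_distance,keep`.
#'
#' @param prep Result of [ppg_preprocess()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cycles_csv <- function(prep, path) {
  rate <- if (length(prep$cycles) > 0L) prep$cycles[[1L]]$rate else NA_real_
  rows <- lapply(seq_along(prep$cycles), function(i) {
    cc <- prep$cycles[[i]]
    rp <- prep$reports[[i]]
    data.frame(cycle_id = i,
               start_s = cc$start_time,
               peak_s = cc$start_time + (cc$systolic_peak - cc$valley_start) / rate,
               end_s = cc$start_time + cc$duration,
               duration_s = cc$duration,
               correlation = rp$correlation,
               norm_distance = rp$norm_distance,
               keep = rp$keep)
  })
  df <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(cycle_id = integer(), start_s = numeric(), peak_s = numeric(),
               end_s = numeric(), duration_s = numeric(),
               correlation = numeric(), norm_distance = numeric(),
               keep = logical())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Minimal RIFF/WAVE reader for the package's audio front-end (mono,
#' PCM16 only).
#'
#' @param path WAV path.
#' @return A `speech_segment` with samples in \[-1, 1\].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("read_wav: not a RIFF file", call. = FALSE)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("read_wav: not a WAVE file", call. = FALSE)
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", sz %/% 2L, size = 2L, endian = "little",
                     signed = FALSE)
      channels <- fmt[2L]
      rate <- fmt[3L] + 65536 * fmt[4L]
      bits <- fmt[8L]
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", sz %/% 2L, size = 2L,
                         endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
  if (is.null(samples) || is.null(rate)) {
    stop("read_wav: missing fmt/data chunk", call. = FALSE)
  }
  if (!identical(as.integer(channels), 1L) || !identical(as.integer(bits), 16L)) {
    stop("read_wav: only 16-bit PCM mono supported", call. = FALSE)
  }
  speech_segment(samples / 32768, rate)
}

#' Write a speech segment as 16-bit PCM mono WAV
#' @param segment A `speech_segment` (samples clipped to \[-1, 1\]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(segment, path) {
  stopifnot(inherits(segment, "speech_segment"))
  x <- pmin(pmax(segment$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")   # PCM
  writeBin(1L, con, size = 2L, endian = "little")   # mono
  writeBin(as.integer(segment$rate), con, size = 4L, endian = "little")
  writeBin(as.integer(segment$rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")   # block align
  writeBin(16L, con, size = 2L, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Write a run manifest
#'
#' Every CLI run writes a JSON manifest with the configuration, seed,
#' package version, and MD5 digests of inputs and outputs, sufficient to
#' reproduce the run.
#'
#' @param path Manifest path.
#' @param command Command vector as invoked.
#' @param config Named list of parameters.
#' @param seed Integer seed.
#' @param inputs,outputs Character vectors of file paths to digest.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, config, seed, inputs = character(0),
                           outputs = character(0)) {
  digest <- function(paths) {
    paths <- paths[file.exists(paths)]
    as.list(tools::md5sum(paths))
  }
  manifest <- list(
    command = paste(command, collapse = " "),
    package = "pulseman",
    version = as.character(utils::packageVersion("pulseman")),
    seed = seed,
    config = config,
    input_digests = digest(inputs),
    output_digests = digest(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
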