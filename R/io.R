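#' Read a PCM WAV file
#'
#' Parses a RIFF/WAVE container holding 16-, 24- or 32-bit integer PCM or
#' 32-bit IEEE float samples. Integer samples are normalised to \[-1, 1\] by
#' the full-scale value of their bit depth; multi-channel audio is mixed
#' down to mono by the per-sample arithmetic mean of the channels; the
#' sampling rate is taken from the format chunk.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  riff_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      chunk <- readBin(con, "raw", size + size %% 2)
      to_int <- function(b) sum(as.integer(b) * 256^(seq_along(b) - 1))
      fmt <- list(
        audio_format = to_int(chunk[1:2]),
        channels = to_int(chunk[3:4]),
        rate = to_int(chunk[5:8]),
        bits = to_int(chunk[15:16])
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (length(data_raw) < size) {
        stop("truncated WAV payload: expected ", size, " bytes, got ",
          length(data_raw),
          call. = FALSE
        )
      }
      if (size %% 2 == 1) readBin(con, "raw", 1)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("missing fmt or data chunk in WAV file", call. = FALSE)
  }
  bytes_per <- fmt$bits / 8
  n_total <- length(data_raw) %/% bytes_per
  if (fmt$audio_format == 1 && fmt$bits == 16) {
    x <- readBin(data_raw, "integer", n_total, size = 2, signed = TRUE,
      endian = "little") / 32768
  } else if (fmt$audio_format == 1 && fmt$bits == 24) {
    m <- matrix(as.integer(data_raw[seq_len(n_total * 3)]), nrow = 3)
    v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
    v <- ifelse(v >= 2^23, v - 2^24, v)
    x <- v / 2^23
  } else if (fmt$audio_format == 1 && fmt$bits == 32) {
    x <- readBin(data_raw, "integer", n_total, size = 4, endian = "little") / 2^31
  } else if (fmt$audio_format == 3 && fmt$bits == 32) {
    x <- readBin(data_raw, "numeric", n_total, size = 4, endian = "little")
  } else {
    stop("unsupported WAV codec: format ", fmt$audio_format, ", ",
      fmt$bits, " bits",
      call. = FALSE
    )
  }
  if (fmt$channels > 1) {
    n_frames <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(n_frames * fmt$channels)],
      nrow = fmt$channels
    ))
  }
  audio_signal(x, fmt$rate)
}

#' Write an audio signal to a PCM WAV file
#'
#' @param audio An [audio_signal()]. Samples are clipped to \[-1, 1\].
#' @param path Output path.
#' @param bits Bit depth: 16 (integer PCM, default) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, bits = 16) {
  stopifnot(inherits(audio, "audio_signal"))
  if (!bits %in% c(16, 32)) stop("`bits` must be 16 or 32", call. = FALSE)
  x <- pmin(pmax(audio$samples, -1), 1)
  n <- length(x)
  data_size <- n * bits / 8
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(if (bits == 16) 1 else 3), con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(audio$rate), con, size = 4, endian = "little")
  writeBin(as.integer(audio$rate * bits / 8), con, size = 4, endian = "little")
  writeBin(as.integer(bits / 8), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16) {
    v <- pmin(32767, pmax(-32768, round(x * 32768)))
    writeBin(as.integer(v), con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

track_header <- function(rate, hop) {
  sprintf("#trackfile\tv1\trate=%g\thop=%g", rate, hop)
}

#' Write and read the per-frame track text file
#'
#' The track file (version 1) is the compact text representation of a pitch
#' track as uploaded instead of raw audio: a header line carrying the format
#' version, sampling rate and hop, then one tab-separated row per frame with
#' the frame time (3 decimals, s), F0 (2 decimals, Hz; `NA` on missing
#' frames) and pitch strength (3 decimals). A 30-s track at a 10-ms hop is
#' 3000 rows and well under 75 kB, versus roughly 6 MB for the raw PCM it
#' summarises.
#'
#' @param track A `pitch_track`.
#' @param path File path.
#' @return `write_track()` returns `path` invisibly; `read_track()` returns
#'   a `pitch_track` equal to the written one within the printed precision.
#' @export
write_track <- function(track, path) {
  rate <- attr(track, "rate")
  hop <- track_hop(track)
  rows <- sprintf(
    "%.3f\t%s\t%.3f",
    track$time,
    ifelse(is.na(track$f0), "NA", sprintf("%.2f", track$f0)),
    track$strength
  )
  writeLines(c(track_header(rate, hop), rows), path)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty track file: ", path, call. = FALSE)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 4 || hdr[1] != "#trackfile") {
    stop("not a track file (bad header): ", path, call. = FALSE)
  }
  if (hdr[2] != "v1") {
    stop("unsupported track file version: ", hdr[2], call. = FALSE)
  }
  get_num <- function(key) {
    hit <- grep(paste0("^", key, "="), hdr, value = TRUE)
    if (length(hit) != 1) stop("track header lacks ", key, call. = FALSE)
    as.numeric(sub(paste0(key, "="), "", hit))
  }
  rate <- get_num("rate")
  hop <- get_num("hop")
  body <- lines[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0) {
    stop("malformed track row at line ", bad[1] + 1L, call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
  time <- as.numeric(m[, 1])
  f0 <- suppressWarnings(as.numeric(ifelse(m[, 2] == "NA", NA, m[, 2])))
  strength <- as.numeric(m[, 3])
  bad_num <- which(is.na(time) | is.na(strength) |
    (is.na(f0) & m[, 2] != "NA"))
  if (length(bad_num) > 0) {
    stop("non-numeric track row at line ", bad_num[1] + 1L, call. = FALSE)
  }
  new_pitch_track(
    tibble::tibble(time = time, f0 = f0, strength = strength),
    rate = rate, hop = hop
  )
}

#' Write and read voiced segments as BED-like TSV
#'
#' Three tab-separated columns without header: start and end in seconds
#' (0-based, half-open) and a text label (`"voiced"`).
#'
#' @param segments Segment tibble.
#' @param path File path.
#' @param label Label written in the third column.
#' @return `write_segments()` returns `path` invisibly; `read_segments()`
#'   returns a segment tibble.
#' @export
write_segments <- function(segments, path, label = "voiced") {
  rows <- sprintf("%.6f\t%.6f\t%s", segments$start, segments$end, label)
  writeLines(rows, path)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(new_segments(numeric(0), numeric(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    stop("malformed segment row at line ", which(lengths(parts) < 2)[1],
      call. = FALSE
    )
  }
  m <- t(vapply(parts, function(p) as.numeric(p[1:2]), numeric(2)))
  if (anyNA(m)) {
    stop("non-numeric segment bounds at line ", which(is.na(m[, 1]) | is.na(m[, 2]))[1],
      call. = FALSE
    )
  }
  new_segments(m[, 1], m[, 2])
}

#' Write per-segment features as CSV
#'
#' Columns: `segment_id, start_s, end_s, n_frames, mean_f0_hz, std_f0_hz,
#' jitter`.
#'
#' @param features Feature tibble from [segment_features()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  out <- dplyr::transmute(features,
    segment_id = .data$segment_id,
    start_s = .data$start, end_s = .data$end,
    n_frames = .data$n_frames,
    mean_f0_hz = .data$mean_f0, std_f0_hz = .data$std_f0,
    jitter = .data$jitter
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  dplyr::transmute(df,
    segment_id = .data$segment_id,
    start = .data$start_s, end = .data$end_s,
    n_frames = .data$n_frames,
    mean_f0 = .data$mean_f0_hz, std_f0 = .data$std_f0_hz,
    jitter = .data$jitter
  )
}

#' Read clinician assessments from CSV
#'
#' Expects columns `session_id`, `date` (ISO-8601), `qid`, `ymrs`.
#'
#' @param path File path.
#' @return A tibble with those columns (`date` parsed to `Date`).
#' @export
read_assessments <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("session_id", "date", "qid", "ymrs")
  if (!all(needed %in% names(df))) {
    stop("assessments CSV needs columns: ", paste(needed, collapse = ", "),
      call. = FALSE
    )
  }
  dplyr::mutate(df, date = as.Date(.data$date))
}

#' Write and read a synthetic event script as plain text
#'
#' One event per line: `kind duration f0_start f0_end n_harmonics
#' jitter_level amplitude`, whitespace-separated, `NA` for fields that do
#' not apply. Lines starting with `#` are comments.
#'
#' @param script A `synth_script` tibble.
#' @param path File path.
#' @return `write_synth_script()` returns `path` invisibly;
#'   `read_synth_script()` returns a `synth_script`.
#' @export
write_synth_script <- function(script, path) {
  rows <- sprintf(
    "%s %g %s %s %d %g %g",
    script$kind, script$dur,
    ifelse(is.na(script$f0_start), "NA", sprintf("%g", script$f0_start)),
    ifelse(is.na(script$f0_end), "NA", sprintf("%g", script$f0_end)),
    script$n_harmonics, script$jitter_level, script$amplitude
  )
  writeLines(c("# kind dur f0_start f0_end n_harmonics jitter_level amplitude", rows), path)
  invisible(path)
}

#' @rdname write_synth_script
#' @export
read_synth_script <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty synth script: ", path, call. = FALSE)
  parts <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(parts) != 7)) {
    stop("malformed script line ", which(lengths(parts) != 7)[1], call. = FALSE)
  }
  m <- do.call(rbind, parts)
  num <- function(v) suppressWarnings(as.numeric(ifelse(v == "NA", NA, v)))
  synth_script(
    kind = m[, 1], dur = num(m[, 2]),
    f0_start = num(m[, 3]), f0_end = num(m[, 4]),
    n_harmonics = as.integer(num(m[, 5])),
    jitter_level = num(m[, 6]), amplitude = num(m[, 7])
  )
}

#' Read a key=value run configuration file
#'
#' Plain text, one `key=value` per line; `#` starts a comment. Numeric
#' values are converted; everything else stays character.
#'
#' @param path File path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2)
  if (length(bad) > 0) stop("malformed config line ", bad[1], call. = FALSE)
  vals <- lapply(kv, function(p) {
    v <- trimws(p[2])
    nv <- suppressWarnings(as.numeric(v))
    if (!is.na(nv)) nv else v
  })
  stats::setNames(vals, trimws(vapply(kv, `[`, "", 1)))
}
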