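# Audio and annotation I/O.
#
# Recordings follow the bedside protocol used for crackle auscultation
# studies: single-channel PCM WAV, nominally 16-bit at 44.1 kHz, captured at
# the two posterior lung bases while the subject paces 2 s inspirations and
# 2 s expirations. Time is in seconds, sample index 0 is at t = 0, and all
# phase intervals are half-open [start_s, end_s).

SITE_LABELS <- c("left_posterior_base", "right_posterior_base", "other")

#' Construct an audio recording
#'
#' Container for a calibrated single-channel signal with sampling metadata.
#' Amplitudes are dimensionless (integer PCM is rescaled to \[-1, 1) on read);
#' every analysis downstream is scale-invariant except the raw deflection
#' amplitudes A1-A3, which are reported in these normalized units.
#'
#' @param samples Numeric vector of amplitudes.
#' @param fs Sampling rate in Hz (> 0).
#' @param bit_depth Integer resolution of the source PCM (metadata only).
#' @param site_label One of `"left_posterior_base"`, `"right_posterior_base"`,
#'   `"other"`.
#' @return An object of class `audio_recording` with fields `samples`, `fs`,
#'   `bit_depth`, `channel_count` (always 1), `site_label`, `duration_s`.
#' @export
audio_recording <- function(samples, fs, bit_depth = 16L, site_label = "other") {
  ct_assert(is.numeric(samples), "samples must be numeric")
  ct_assert(is_scalar_num(fs) && fs > 0, "fs must be a positive number")
  site_label <- match.arg(site_label, SITE_LABELS)
  structure(
    list(
      samples = as.numeric(samples),
      fs = fs,
      bit_depth = as.integer(bit_depth),
      channel_count = 1L,
      site_label = site_label,
      duration_s = length(samples) / fs
    ),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf(
    "<audio_recording> %d samples @ %g Hz (%.3f s), %d-bit source, site %s\n",
    length(x$samples), x$fs, x$duration_s, x$bit_depth, x$site_label
  ))
  invisible(x)
}

# ---- WAV ------------------------------------------------------------------

#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed audio: 16/24/32-bit integer PCM
#' and 32-bit IEEE float. Integer samples are rescaled to \[-1, 1) by
#' 2^(bits-1). Multichannel files are handled per `multichannel`: rejected
#' (default, since the recording protocol stores one auscultation site per
#' file), reduced to the first channel, or split into one recording per
#' channel.
#'
#' @param path Path to a WAV file.
#' @param multichannel One of `"reject"`, `"first_channel"`, `"split"`.
#' @param site_label Site metadata to attach (see [audio_recording()]).
#' @return An `audio_recording`, or a list of them when `multichannel =
#'   "split"` and the file has more than one channel.
#' @export
read_wav <- function(path, multichannel = c("reject", "first_channel", "split"),
                     site_label = "other") {
  multichannel <- match.arg(multichannel)
  ct_assert(is.character(path) && length(path) == 1L && file.exists(path),
            sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))

  tag <- readChar(con, 4L, useBytes = TRUE)
  ct_assert(identical(tag, "RIFF"), "format error: not a RIFF file")
  readBin(con, "integer", 1L, size = 4L, endian = "little")
  ct_assert(identical(readChar(con, 4L, useBytes = TRUE), "WAVE"),
            "format error: not a WAVE file")

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id, type = "bytes") < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(sz) == 0L) break
    body <- readBin(con, "raw", n = sz)
    if (identical(id, "fmt ")) {
      ct_assert(sz >= 16L, "format error: truncated fmt chunk")
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1L, 2L, signed = FALSE,
                               endian = "little"),
        channels = readBin(body[3:4], "integer", 1L, 2L, signed = FALSE,
                           endian = "little"),
        fs = readBin(body[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(body[15:16], "integer", 1L, 2L, signed = FALSE,
                       endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- body
    }
    if (sz %% 2L == 1L) readBin(con, "raw", n = 1L) # chunk padding byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }

  ct_assert(!is.null(fmt), "format error: missing fmt chunk")
  ct_assert(!is.null(data_raw), "format error: missing data chunk")
  ct_assert(length(data_raw) > 0L, "empty input: WAV data chunk has no samples")
  ct_assert(fmt$audio_format %in% c(1L, 3L),
            "format error: compressed or unsupported WAV encoding")

  bits <- fmt$bits
  nch <- fmt$channels
  if (fmt$audio_format == 3L) {
    ct_assert(bits == 32L, "format error: only 32-bit float WAV is supported")
    x <- readBin(data_raw, "double", n = length(data_raw) %/% 4L, size = 4L,
                 endian = "little")
  } else if (bits == 16L) {
    x <- readBin(data_raw, "integer", n = length(data_raw) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little") / 2^15
  } else if (bits == 24L) {
    n <- length(data_raw) %/% 3L
    b <- as.integer(data_raw[seq_len(n * 3L)])
    v <- b[seq(1L, by = 3L, length.out = n)] +
      256 * b[seq(2L, by = 3L, length.out = n)] +
      65536 * b[seq(3L, by = 3L, length.out = n)]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    x <- v / 2^23
  } else if (bits == 32L) {
    x <- readBin(data_raw, "integer", n = length(data_raw) %/% 4L, size = 4L,
                 endian = "little") / 2^31
  } else {
    stop(sprintf("format error: unsupported bit depth %d", bits), call. = FALSE)
  }

  if (nch > 1L) {
    m <- matrix(x, nrow = nch)
    if (multichannel == "reject") {
      stop(sprintf("format error: %d-channel file (policy 'reject')", nch),
           call. = FALSE)
    }
    if (multichannel == "split") {
      return(lapply(seq_len(nch), function(k) {
        audio_recording(m[k, ], fmt$fs, bit_depth = bits, site_label = site_label)
      }))
    }
    x <- m[1L, ]
  }
  audio_recording(x, fmt$fs, bit_depth = bits, site_label = site_label)
}

#' Write a PCM WAV file
#'
#' Writes integer PCM (default 16-bit). Amplitudes are clipped to the
#' representable range and quantized by rounding, so a read/write round trip
#' is exact to within one quantization step.
#'
#' @param recording An `audio_recording` (or numeric vector with `fs` given).
#' @param path Output path.
#' @param bit_depth 16, 24 or 32.
#' @param fs Sampling rate, required when `recording` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(recording, path, bit_depth = 16L, fs = NULL) {
  if (is.numeric(recording)) {
    ct_assert(!is.null(fs), "fs is required when writing a bare numeric vector")
    recording <- audio_recording(recording, fs)
  }
  ct_assert(inherits(recording, "audio_recording"), "not an audio_recording")
  bit_depth <- as.integer(bit_depth)
  ct_assert(bit_depth %in% c(16L, 24L, 32L), "bit_depth must be 16, 24 or 32")

  scale <- 2^(bit_depth - 1L)
  v <- round(recording$samples * scale)
  v <- pmax(pmin(v, scale - 1), -scale)
  n <- length(v)
  bytes_per <- bit_depth %/% 8L
  data_sz <- n * bytes_per
  fs_i <- as.integer(round(recording$fs))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")            # PCM
  writeBin(1L, con, size = 2L, endian = "little")            # mono
  writeBin(fs_i, con, size = 4L, endian = "little")
  writeBin(as.integer(fs_i * bytes_per), con, size = 4L, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2L, endian = "little")
  writeBin(bit_depth, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4L, endian = "little")
  if (bit_depth == 24L) {
    u <- ifelse(v < 0, v + 2^24, v)
    raw3 <- as.raw(rbind(u %% 256, (u %/% 256) %% 256, u %/% 65536))
    writeBin(raw3, con)
  } else {
    writeBin(as.integer(v), con, size = bytes_per, endian = "little")
  }
  invisible(path)
}

# ---- Breath phases --------------------------------------------------------

#' Build the protocol breathing phases
#'
#' The recording protocol paces the subject with onscreen instructions:
#' `n_breaths` deep breaths, each one inspiration followed by one expiration
#' (defaults 2 s + 2 s, eight breaths, about 30 s per site). Phases start at
#' t = 0 and alternate inspiration/expiration with no gaps.
#'
#' @param n_breaths Number of breaths (>= 1).
#' @param t_insp_s Inspiration duration in seconds.
#' @param t_exp_s Expiration duration in seconds.
#' @return A data frame with columns `breath_index` (0-based), `kind`
#'   (`"inspiration"`/`"expiration"`), `start_s`, `end_s`; intervals are
#'   half-open `[start_s, end_s)`.
#' @export
protocol_phases <- function(n_breaths = 8L, t_insp_s = 2, t_exp_s = 2) {
  ct_assert(is_scalar_num(n_breaths) && n_breaths >= 1, "n_breaths must be >= 1")
  ct_assert(is_scalar_num(t_insp_s) && t_insp_s > 0, "t_insp_s must be > 0")
  ct_assert(is_scalar_num(t_exp_s) && t_exp_s > 0, "t_exp_s must be > 0")
  n_breaths <- as.integer(n_breaths)
  cycle <- t_insp_s + t_exp_s
  b <- rep(seq_len(n_breaths) - 1L, each = 2L)
  kind <- rep(c("inspiration", "expiration"), n_breaths)
  start <- b * cycle + ifelse(kind == "expiration", t_insp_s, 0)
  end <- start + ifelse(kind == "inspiration", t_insp_s, t_exp_s)
  data.frame(breath_index = b, kind = kind, start_s = start, end_s = end,
             stringsAsFactors = FALSE)
}

#' Validate a breath-phase table
#'
#' Checks the phase invariants: columns present, `0 <= start_s < end_s`,
#' time-ordered and non-overlapping, and (when `duration_s` is given) within
#' the recording.
#'
#' @param phases Data frame as produced by [protocol_phases()].
#' @param duration_s Optional recording duration to check against.
#' @return `phases`, invisibly; errors on violation.
#' @export
validate_phases <- function(phases, duration_s = NULL) {
  ct_assert(is.data.frame(phases), "phases must be a data frame")
  need <- c("breath_index", "kind", "start_s", "end_s")
  ct_assert(all(need %in% names(phases)),
            sprintf("phases must have columns: %s", paste(need, collapse = ", ")))
  ct_assert(all(phases$kind %in% c("inspiration", "expiration")),
            "phase kind must be inspiration or expiration")
  if (nrow(phases) > 0L) {
    ct_assert(all(phases$start_s >= 0), "phase start_s must be >= 0")
    ct_assert(all(phases$start_s < phases$end_s),
              "phase start_s must be < end_s")
    o <- order(phases$start_s)
    s <- phases$start_s[o]; e <- phases$end_s[o]
    if (nrow(phases) > 1L) {
      ct_assert(all(s[-1L] >= e[-length(e)] - 1e-12),
                "phases overlap")
    }
    if (!is.null(duration_s)) {
      ct_assert(all(phases$end_s <= duration_s + 1e-9),
                "phase extends past recording end")
    }
  }
  invisible(phases)
}

# ---- Annotation CSVs ------------------------------------------------------

PHASE_COLS <- c("recording_id", "breath_index", "kind", "start_s", "end_s")
EVENT_COLS <- c("recording_id", "breath_index", "onset_s", "relative_onset",
                "tercile", "tcd_ms", "idw_ms", "ldw_ms", "a1", "a2", "a3",
                "is_fine")

#' Write breath-phase and crackle-event annotations
#'
#' Writes two CSVs, `<prefix>_phases.csv` and `<prefix>_events.csv`, whose
#' columns round-trip through [read_annotations()] with times preserved to
#' better than 1 microsecond. Empty inputs produce header-only files.
#'
#' @param phases Phase data frame (see [protocol_phases()]); validated.
#' @param events Event data frame (columns of [read_annotations()]'s
#'   `events`); may be empty or `NULL`.
#' @param prefix Output path prefix.
#' @param recording_id Identifier stored in both files.
#' @return Character vector of the two paths, invisibly.
#' @export
write_annotations <- function(phases, events = NULL, prefix,
                              recording_id = "rec") {
  validate_phases(phases)
  pd <- data.frame(
    recording_id = rep(recording_id, nrow(phases)),
    breath_index = phases$breath_index,
    kind = phases$kind,
    start_s = sprintf("%.9f", phases$start_s),
    end_s = sprintf("%.9f", phases$end_s),
    stringsAsFactors = FALSE
  )
  if (nrow(pd) == 0L) pd <- pd[0L, ]
  p_path <- paste0(prefix, "_phases.csv")
  e_path <- paste0(prefix, "_events.csv")
  utils::write.csv(pd, p_path, row.names = FALSE)

  if (is.null(events)) events <- data.frame()
  ed <- data.frame(matrix(nrow = nrow(events), ncol = 0L))
  ed$recording_id <- rep(recording_id, nrow(events))
  for (col in setdiff(EVENT_COLS, "recording_id")) {
    v <- if (col %in% names(events)) events[[col]] else rep(NA, nrow(events))
    if (col %in% c("onset_s", "relative_onset")) {
      v <- ifelse(is.na(v), NA_character_, sprintf("%.9f", as.numeric(v)))
    }
    ed[[col]] <- v
  }
  utils::write.csv(ed, e_path, row.names = FALSE)
  invisible(c(phases = p_path, events = e_path))
}

#' Read annotation CSVs written by [write_annotations()]
#'
#' @param prefix Path prefix used at write time.
#' @return A list with data frames `phases` and `events`.
#' @export
read_annotations <- function(prefix) {
  p_path <- paste0(prefix, "_phases.csv")
  e_path <- paste0(prefix, "_events.csv")
  ct_assert(file.exists(p_path), sprintf("missing annotation file: %s", p_path))
  phases <- utils::read.csv(p_path, stringsAsFactors = FALSE)
  events <- if (file.exists(e_path)) {
    utils::read.csv(e_path, stringsAsFactors = FALSE)
  } else {
    ev <- as.data.frame(matrix(nrow = 0L, ncol = length(EVENT_COLS)))
    names(ev) <- EVENT_COLS
    ev
  }
  if (nrow(phases) > 0L) validate_phases(phases)
  list(phases = phases, events = events)
}
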