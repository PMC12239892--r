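# Plain-text and EDF interchange: BIDS-style electrodes.tsv / events.tsv,
# two-column hypnogram TSV, spectrum TSV, and a minimal EDF (16-bit)
# writer/reader for recordings.

#' Write / read a layout as a BIDS-style electrodes.tsv
#'
#' Columns `name`, `x`, `y`, `z` (mm) and `modality`.
#'
#' @param layout A [make_head_layout()] tibble.
#' @param path File path.
#' @return `write_layout_tsv` the path invisibly; `read_layout_tsv` a
#'   `head_layout` tibble.
#' @export
write_layout_tsv <- function(layout, path) {
  readr::write_tsv(
    tibble::tibble(
      name = layout$contact, x = layout$x, y = layout$y, z = layout$z,
      modality = layout$modality
    ),
    path
  )
  invisible(path)
}

#' @rdname write_layout_tsv
#' @param radius,scalp_thickness Head geometry restored onto the layout.
#' @export
read_layout_tsv <- function(path, radius = 92, scalp_thickness = 7) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  out <- tibble::tibble(
    contact = d$name, x = d$x, y = d$y, z = d$z, modality = d$modality
  )
  class(out) <- c("head_layout", class(out))
  attr(out, "radius") <- radius
  attr(out, "scalp_thickness") <- scalp_thickness
  out
}

#' Write / read a hypnogram as two-column TSV
#'
#' Columns `epoch_index` and `stage`.
#'
#' @param hypnogram A [hypnogram()].
#' @param path File path.
#' @export
write_hypnogram_tsv <- function(hypnogram, path) {
  readr::write_tsv(
    tibble::tibble(epoch_index = hypnogram$epoch, stage = hypnogram$stage),
    path
  )
  invisible(path)
}

#' @rdname write_hypnogram_tsv
#' @param epoch_length Epoch length in seconds restored on read.
#' @export
read_hypnogram_tsv <- function(path, epoch_length = 30) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  hypnogram(d$stage, epoch_length)
}

#' Write / read events as a BIDS-style events.tsv
#'
#' Columns `onset`, `duration`, `trial_type` and a JSON-encoded
#' `attributes` column.
#'
#' @param events Event tibble (`onset`, `duration`, `kind`, `attributes`).
#' @param path File path.
#' @export
write_events_tsv <- function(events, path) {
  readr::write_tsv(
    tibble::tibble(
      onset = events$onset, duration = events$duration,
      trial_type = events$kind,
      attributes = vapply(
        events$attributes %||% vector("list", nrow(events)),
        function(a) as.character(jsonlite::toJSON(a, auto_unbox = TRUE, digits = NA)),
        character(1)
      )
    ),
    path,
    quote = "none", escape = "none"
  )
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  tibble::tibble(
    onset = d$onset, duration = d$duration, kind = d$trial_type,
    attributes = purrr::map(d$attributes, function(a) {
      jsonlite::fromJSON(a, simplifyVector = TRUE)
    })
  )
}

#' Write a spectrum (or coherence spectrum) as TSV
#'
#' @param spectrum A tibble with a `frequency` column.
#' @param path File path.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  readr::write_tsv(tibble::as_tibble(spectrum), path)
  invisible(path)
}

pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write a recording to EDF
#'
#' Minimal EDF (16-bit, physical dimension uV) export: one data record per
#' second, per-channel symmetric physical range. Layout geometry is not
#' stored in EDF; use [write_layout_tsv()] alongside.
#'
#' @param recording An [eeg_recording()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_edf <- function(recording, path) {
  data <- recording$data
  fs <- recording$fs
  ns <- nrow(data)
  if (abs(fs - round(fs)) > 1e-9) abort("EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n_rec <- floor(ncol(data) / fs)
  if (n_rec < 1) abort("recording shorter than one 1-s EDF record")
  labels <- rownames(data) %||% sprintf("CH%d", seq_len(ns))
  pmax_v <- pmax(apply(abs(data), 1, max), 1e-6)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field("synthetic EEG recording", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(as.character(256 * (ns + 1)), 8),
    pad_field("", 44),
    pad_field(as.character(n_rec), 8),
    pad_field("1", 8),
    pad_field(as.character(ns), 4)
  ), con, eos = NULL)
  writeChar(paste0(
    paste0(pad_field(labels, 16), collapse = ""),
    paste0(rep(pad_field("", 80), ns), collapse = ""),
    paste0(rep(pad_field("uV", 8), ns), collapse = ""),
    paste0(pad_field(sprintf("%.6g", -pmax_v), 8), collapse = ""),
    paste0(pad_field(sprintf("%.6g", pmax_v), 8), collapse = ""),
    paste0(rep(pad_field("-32767", 8), ns), collapse = ""),
    paste0(rep(pad_field("32767", 8), ns), collapse = ""),
    paste0(rep(pad_field("", 80), ns), collapse = ""),
    paste0(rep(pad_field(as.character(fs), 8), ns), collapse = ""),
    paste0(rep(pad_field("", 32), ns), collapse = "")
  ), con, eos = NULL)
  scale <- 32767 / pmax_v
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- round(data[, idx, drop = FALSE] * scale)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @param layout Optional layout to attach (contacts must match labels).
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, layout = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  n_rec <- as.integer(substr(hdr, 237, 244))
  ns <- as.integer(substr(hdr, 253, 256))
  sig_hdr <- readChar(con, 256 * ns, useBytes = TRUE)
  # offsets in bytes within the per-signal header: labels 16, transducer 80,
  # dim 8, phys_min 8, phys_max 8, dig_min 8, dig_max 8, prefilter 80, n_samp 8
  off <- c(label = 0, transducer = 16 * ns, dim = 96 * ns, phys_min = 104 * ns,
           phys_max = 112 * ns, dig_min = 120 * ns, dig_max = 128 * ns,
           prefilter = 136 * ns, n_samp = 216 * ns)
  take <- function(key, width, i) {
    start <- off[[key]] + (i - 1) * width + 1
    trimws(substr(sig_hdr, start, start + width - 1))
  }
  labels <- vapply(seq_len(ns), function(i) take("label", 16, i), character(1))
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) take("phys_min", 8, i), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) take("phys_max", 8, i), character(1)))
  n_samp <- as.integer(vapply(seq_len(ns), function(i) take("n_samp", 8, i), character(1)))
  fs <- n_samp[1]
  raw <- readBin(con, "integer", n = n_rec * sum(n_samp), size = 2,
                 endian = "little", signed = TRUE)
  data <- matrix(0, ns, n_rec * fs)
  pos <- 0
  for (r in seq_len(n_rec)) {
    block <- matrix(raw[pos + seq_len(ns * fs)], nrow = fs)
    data[, ((r - 1) * fs + 1):(r * fs)] <- t(block)
    pos <- pos + ns * fs
  }
  scale <- phys_max / 32767
  data <- data * scale
  rownames(data) <- labels
  eeg_recording(data, fs, layout = layout)
}
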