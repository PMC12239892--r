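# The universal signal carrier: a channels x samples matrix in uV plus its
# sampling rate, electrode layout, event annotations and optional hypnogram.

#' Construct an EEG recording
#'
#' @param data Channels x samples numeric matrix in uV; row names (or the
#'   layout order) identify channels.
#' @param fs Sampling rate in Hz.
#' @param layout Optional [make_head_layout()] tibble; when given, its
#'   contact count must equal `nrow(data)` and its contacts name the rows.
#' @param events Optional event tibble (`onset`, `duration`, `kind`, ...).
#' @param hypnogram Optional hypnogram tibble (`epoch`, `stage`).
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, layout = NULL, events = NULL, hypnogram = NULL) {
  stopifnot(is.matrix(data), is.numeric(data), fs > 0)
  if (!all(is.finite(data))) abort("recording data must be finite")
  if (!is.null(layout)) {
    if (nrow(layout) != nrow(data)) {
      abort("row count of `data` must equal the layout contact count")
    }
    rownames(data) <- layout$contact
  }
  if (is.null(events)) {
    events <- tibble::tibble(
      onset = numeric(), duration = numeric(), kind = character(),
      attributes = list()
    )
  }
  structure(
    list(data = data, fs = fs, layout = layout, events = events,
         hypnogram = hypnogram),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples (%.1f s at %g Hz), %d events%s\n",
    nrow(x$data), ncol(x$data), ncol(x$data) / x$fs, x$fs, nrow(x$events),
    if (!is.null(x$hypnogram)) sprintf(", %d hypnogram epochs", nrow(x$hypnogram)) else ""
  ))
  invisible(x)
}

#' @export
as_tibble.eeg_recording <- function(x, ...) {
  chans <- rownames(x$data) %||% as.character(seq_len(nrow(x$data)))
  tibble::tibble(
    channel = rep(chans, times = ncol(x$data)),
    time = rep((seq_len(ncol(x$data)) - 1) / x$fs, each = nrow(x$data)),
    value = as.vector(x$data)
  )
}

#' Extract one channel as a numeric vector
#'
#' @param recording An [eeg_recording()].
#' @param contact Channel name.
#' @param from,to Optional time window in seconds.
#' @return Numeric vector of samples (uV).
#' @export
channel_signal <- function(recording, contact, from = NULL, to = NULL) {
  if (!contact %in% rownames(recording$data)) {
    abort(sprintf("channel '%s' not found in recording", contact))
  }
  x <- recording$data[contact, ]
  i0 <- if (is.null(from)) 1L else max(1L, as.integer(round(from * recording$fs)) + 1L)
  i1 <- if (is.null(to)) length(x) else min(length(x), as.integer(round(to * recording$fs)))
  x[i0:i1]
}

#' The five sleep-wake stage labels
#' @return `c("W", "N1", "N2", "N3", "REM")`
#' @export
sleep_stages <- function() c("W", "N1", "N2", "N3", "REM")

#' Construct a hypnogram
#'
#' @param stages Character vector of stage labels over consecutive epochs
#'   (subset of [sleep_stages()]).
#' @param epoch_length Epoch length in seconds (default 30, the scoring
#'   standard).
#' @return Tibble of class `hypnogram` with columns `epoch` and `stage`.
#' @export
hypnogram <- function(stages, epoch_length = 30) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), sleep_stages())
  if (length(bad)) {
    abort(sprintf("unknown stage label(s): %s", paste(bad, collapse = ", ")))
  }
  out <- tibble::tibble(epoch = seq_along(stages), stage = stages)
  class(out) <- c("hypnogram", class(out))
  attr(out, "epoch_length") <- epoch_length
  out
}

#' Generate a plausible night-sleep hypnogram
#'
#' Deterministic cycle template (W, N1, N2, N3, N2, REM blocks) truncated or
#' repeated to `n_epochs`; with a seed, block lengths are jittered by up to
#' 20% to vary the architecture across simulated nights.
#'
#' @param n_epochs Number of 30-s epochs.
#' @param epoch_length Epoch length in seconds.
#' @param seed Optional integer seed.
#' @return A [hypnogram()].
#' @export
make_hypnogram <- function(n_epochs, epoch_length = 30, seed = NULL) {
  template <- list(
    c("W", 10), c("N1", 4), c("N2", 20), c("N3", 20), c("N2", 10), c("REM", 15)
  )
  with_seed_if(seed, {
    stages <- character(0)
    while (length(stages) < n_epochs) {
      for (blk in template) {
        len <- as.integer(blk[2])
        if (!is.null(seed)) {
          len <- max(1L, as.integer(round(len * runif(1, 0.8, 1.2))))
        }
        stages <- c(stages, rep(blk[1], len))
      }
    }
    hypnogram(stages[seq_len(n_epochs)], epoch_length)
  })
}

#' Corrupt a hypnogram with random stage flips
#'
#' Each epoch is independently replaced, with probability `flip_rate`, by a
#' stage drawn uniformly from the four other labels. Emulates imperfect
#' visual scoring so kappa calibration is possible without human scorers.
#'
#' @param hypnogram A [hypnogram()].
#' @param flip_rate Flip probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A corrupted [hypnogram()].
#' @export
corrupt_hypnogram <- function(hypnogram, flip_rate, seed = NULL) {
  if (flip_rate < 0 || flip_rate > 1) abort("`flip_rate` must be in [0, 1]")
  with_seed_if(seed, {
    stages <- hypnogram$stage
    flip <- runif(length(stages)) < flip_rate
    if (any(flip)) {
      stages[flip] <- vapply(stages[flip], function(s) {
        sample(setdiff(sleep_stages(), s), 1)
      }, character(1))
    }
    out <- hypnogram
    out$stage <- stages
    out
  })
}
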