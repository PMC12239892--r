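# Event-locked analyses: evoked-potential averaging with global field
# power, peak-aligned interictal-spike averaging, the ictal closest-contact
# triplet, seizure coherence profiles, and ictal power-increase maps.

#' Trial-average a recording around stimulus events
#'
#' Extracts per-trial epochs, subtracts the per-channel baseline mean, and
#' averages. Trials whose epoch falls outside the recording are dropped and
#' counted.
#'
#' @param recording An [eeg_recording()].
#' @param onsets Stimulus onsets in seconds; defaults to the recording's
#'   `stimulus` events.
#' @param window Epoch window relative to the stimulus, seconds (default
#'   `c(-0.1, 0.3)`).
#' @param baseline Baseline window, seconds (default `c(-0.1, 0)`).
#' @return Object of class `evoked_average`: channels x time `data`,
#'   `times` (s), `n_trials`, `n_dropped`.
#' @export
epoch_average <- function(recording, onsets = NULL, window = c(-0.1, 0.3),
                          baseline = c(-0.1, 0)) {
  fs <- recording$fs
  onsets <- onsets %||% recording$events$onset[recording$events$kind == "stimulus"]
  if (length(onsets) < 1) abort("at least one stimulus event is required")
  rel <- seq(round(window[1] * fs), round(window[2] * fs))
  base_sel <- rel >= round(baseline[1] * fs) & rel <= round(baseline[2] * fs)
  n_samp <- ncol(recording$data)
  c0 <- as.integer(round(onsets * fs)) + 1L
  ok <- c0 + rel[1] >= 1L & c0 + rel[length(rel)] <= n_samp
  dropped <- sum(!ok)
  used <- sum(ok)
  if (used == 0L) abort("no usable trials: all events fall too close to the recording edge")
  # gather all epochs at once; per-trial baseline correction commutes with
  # averaging, so the baseline is removed from the trial average directly
  nc <- nrow(recording$data)
  idx <- rep(c0[ok], each = length(rel)) + rep.int(rel, used)
  arr <- array(recording$data[, idx, drop = FALSE], c(nc, length(rel), used))
  avg <- rowMeans(arr, dims = 2)
  avg <- avg - rowMeans(avg[, base_sel, drop = FALSE])
  structure(
    list(
      data = avg, times = rel / fs,
      n_trials = used, n_dropped = dropped,
      window = window, baseline = baseline,
      channels = rownames(recording$data)
    ),
    class = "evoked_average"
  )
}

#' @export
print.evoked_average <- function(x, ...) {
  cat(sprintf(
    "<evoked_average> %d channels, %d trials (%d dropped), %g to %g ms\n",
    nrow(x$data), x$n_trials, x$n_dropped, 1000 * x$window[1], 1000 * x$window[2]
  ))
  invisible(x)
}

#' Global field power of an evoked average
#'
#' Per-timepoint spatial standard deviation across channels.
#'
#' @param evoked An [epoch_average()] result (>= 2 channels).
#' @return Tibble with columns `time` (s) and `gfp` (uV).
#' @export
global_field_power <- function(evoked) {
  if (nrow(evoked$data) < 2) abort("global field power requires at least 2 channels")
  tibble::tibble(time = evoked$times, gfp = apply(evoked$data, 2, sd))
}

#' Peak-aligned average of interictal spikes
#'
#' Each spike epoch is shifted so that the extremum (maximal absolute value)
#' of the alignment channel, searched within `search_window` of the
#' annotated onset, sits at time 0; epochs whose extremum lands on the
#' search boundary are flagged and excluded. The per-channel signed
#' amplitude at time 0 of the average is the spike's peak potential.
#'
#' @param recording An [eeg_recording()].
#' @param onsets Spike onsets in seconds; defaults to the recording's
#'   `spike` events.
#' @param alignment_channel Channel whose extremum defines the alignment.
#' @param window Half-width of the output epoch in seconds (default 0.25).
#' @param search_window Half-width of the extremum search around the
#'   annotation (default 0.05 s).
#' @param n_max Use at most this many spikes (default 30).
#' @param align Set `FALSE` to average on the raw annotations (no peak
#'   alignment), e.g. to quantify smearing.
#' @return Object of class `spike_average`: `data`, `times`, `n_spikes`,
#'   `n_excluded`, and `peak_amplitudes` (tibble `contact`, `amplitude`).
#' @export
spike_peak_average <- function(recording, onsets = NULL, alignment_channel,
                               window = 0.25, search_window = 0.05,
                               n_max = 30, align = TRUE) {
  fs <- recording$fs
  onsets <- onsets %||% recording$events$onset[recording$events$kind == "spike"]
  if (length(onsets) < 1) abort("at least one spike is required")
  onsets <- head(sort(onsets), n_max)
  if (!alignment_channel %in% rownames(recording$data)) {
    abort(sprintf("alignment channel '%s' not found", alignment_channel))
  }
  half <- as.integer(round(window * fs))
  sh <- as.integer(round(search_window * fs))
  n_samp <- ncol(recording$data)
  ref <- recording$data[alignment_channel, ]
  acc <- NULL
  used <- 0L
  excluded <- 0L
  for (on in onsets) {
    c0 <- as.integer(round(on * fs)) + 1L
    if (align) {
      s_idx <- (c0 - sh):(c0 + sh)
      if (s_idx[1] < 1 || s_idx[length(s_idx)] > n_samp) {
        excluded <- excluded + 1L
        next
      }
      pk <- which.max(abs(ref[s_idx]))
      if (pk == 1L || pk == length(s_idx)) {
        excluded <- excluded + 1L
        next
      }
      c0 <- s_idx[pk]
    }
    idx <- (c0 - half):(c0 + half)
    if (idx[1] < 1 || idx[length(idx)] > n_samp) {
      excluded <- excluded + 1L
      next
    }
    seg <- recording$data[, idx, drop = FALSE]
    acc <- if (is.null(acc)) seg else acc + seg
    used <- used + 1L
  }
  if (used == 0L) abort("no usable spikes after boundary exclusion")
  avg <- acc / used
  structure(
    list(
      data = avg, times = seq(-half, half) / fs,
      n_spikes = used, n_excluded = excluded,
      alignment_channel = alignment_channel,
      peak_amplitudes = tibble::tibble(
        contact = rownames(recording$data),
        amplitude = avg[, half + 1L]
      )
    ),
    class = "spike_average"
  )
}

#' @export
print.spike_average <- function(x, ...) {
  cat(sprintf(
    "<spike_average> %d channels, %d spikes (%d excluded), aligned on %s\n",
    nrow(x$data), x$n_spikes, x$n_excluded, x$alignment_channel
  ))
  invisible(x)
}

#' Select the ictal closest-contact triplet
#'
#' Two-step nearest selection: first the subscalp contact closest to the
#' seizure-onset zone, then the scalp and intracranial contacts closest to
#' that subscalp contact. Distance ties break by contact name.
#'
#' @param layout A layout containing all three modalities.
#' @param soz_position SOZ position (3-vector, mm).
#' @return Tibble of class `ictal_triplet` with columns `role`
#'   (`subscalp`/`scalp`/`intracranial`), `contact`, `distance_mm`.
#' @export
select_ictal_triplet <- function(layout, soz_position) {
  mods <- c("subscalp", "scalp", "intracranial")
  missing <- setdiff(mods, unique(layout$modality))
  if (length(missing)) {
    abort(sprintf("layout is missing modality: %s", paste(missing, collapse = ", ")))
  }
  nearest <- function(sub_layout, ref) {
    P <- as.matrix(sub_layout[, c("x", "y", "z")])
    d <- sqrt(colSums((t(P) - ref)^2))
    m <- min(d)
    cand <- sort(sub_layout$contact[d <= m + 1e-9])
    list(contact = cand[1], dist = m)
  }
  sub <- nearest(dplyr::filter(layout, .data$modality == "subscalp"), soz_position)
  anchor <- as.numeric(layout[layout$contact == sub$contact, c("x", "y", "z")])
  sca <- nearest(dplyr::filter(layout, .data$modality == "scalp"), anchor)
  ic <- nearest(dplyr::filter(layout, .data$modality == "intracranial"), anchor)
  out <- tibble::tibble(
    role = mods,
    contact = c(sub$contact, sca$contact, ic$contact),
    distance_mm = c(sub$dist, sca$dist, ic$dist)
  )
  class(out) <- c("ictal_triplet", class(out))
  attr(out, "soz_position") <- soz_position
  out
}

#' Ictal coherence profile of a seizure
#'
#' Broadband (0.5-30 Hz by default) mean coherence of the triplet's
#' subscalp and scalp members with the intracranial SOZ and PZ reference
#' channels over the seizure segment, plus time-frequency coherence with a
#' high-coherence (> 0.3) contour mask for rendering. Segments too short
#' for 8 standard windows fall back to 2-s windows and are flagged.
#'
#' @param recording An [eeg_recording()].
#' @param seizure One-row event tibble (or list) with `onset` and
#'   `duration` in seconds.
#' @param triplet A [select_ictal_triplet()] result.
#' @param soz_channel,pz_channel Intracranial reference channel names.
#' @param range Coherence averaging range, Hz.
#' @param window Analysis window in seconds (default 5).
#' @param tf Also compute time-frequency coherence masks (default `TRUE`).
#' @return Object of class `ictal_profile`: `profile` tibble (`member`,
#'   `reference`, `coherence`), optional `tf` list, `window_used`,
#'   `short_segment` flag.
#' @export
ictal_coherence_profile <- function(recording, seizure, triplet,
                                    soz_channel, pz_channel,
                                    range = c(0.5, 30), window = 5, tf = TRUE) {
  fs <- recording$fs
  onset <- seizure$onset[[1]]
  duration <- seizure$duration[[1]]
  # 8 windows at 50% overlap need 4.5 window lengths of signal
  short <- duration < 4.5 * window
  window_used <- if (short) 2 else window
  members <- triplet$contact[triplet$role %in% c("subscalp", "scalp")]
  names(members) <- triplet$role[triplet$role %in% c("subscalp", "scalp")]
  refs <- c(soz = soz_channel, pz = pz_channel)
  seg <- function(ch) channel_signal(recording, ch, from = onset, to = onset + duration)
  trs <- lapply(c(members, refs), function(ch) {
    mt_transform(seg(ch), fs, window = window_used)
  })
  names(trs) <- c(names(members), names(refs))
  rows <- list()
  tf_out <- list()
  for (m in names(members)) {
    for (r in names(refs)) {
      co <- coherence_from_transforms(trs[[m]], trs[[r]])
      rows[[paste(m, r)]] <- tibble::tibble(
        member = members[[m]], modality = m,
        reference = refs[[r]], zone = r,
        coherence = band_mean_coherence(co, range)
      )
      if (tf) {
        tfc <- tf_coherence(trs[[m]], trs[[r]])
        tfc$mask <- tfc$coherence > 0.3
        tf_out[[paste(m, r)]] <- tfc
      }
    }
  }
  structure(
    list(
      profile = dplyr::bind_rows(rows),
      tf = if (tf) tf_out else NULL,
      window_used = window_used,
      short_segment = short,
      range = range
    ),
    class = "ictal_profile"
  )
}

#' @export
print.ictal_profile <- function(x, ...) {
  cat(sprintf(
    "<ictal_profile> %g-%g Hz mean coherence (%g-s windows%s)\n",
    x$range[1], x$range[2], x$window_used,
    if (x$short_segment) ", short-segment fallback" else ""
  ))
  print(x$profile)
  invisible(x)
}

#' Per-channel ictal power increase map
#'
#' Mean dB power over `range` during the seizure minus the same quantity
#' over a non-overlapping baseline segment, per extracranial channel,
#' returned as one topographic map per modality for spatial correlation.
#'
#' @param recording An [eeg_recording()] with a layout.
#' @param seizure Event with `onset`, `duration` (s).
#' @param baseline `c(start, end)` in seconds; must not overlap the seizure.
#' @param range Frequency range, Hz (default 0.5-30).
#' @param window PSD window (s); shortened automatically for short segments.
#' @return List of class `ictal_power_map` with elements `subscalp` and
#'   `scalp` ([topo_map()]s) and the combined `values` tibble.
#' @export
ictal_power_increase_map <- function(recording, seizure, baseline,
                                     range = c(0.5, 30), window = 5) {
  onset <- seizure$onset[[1]]
  duration <- seizure$duration[[1]]
  if (baseline[2] > onset && baseline[1] < onset + duration) {
    abort("baseline segment overlaps the seizure segment")
  }
  fs <- recording$fs
  seg_len <- min(duration, baseline[2] - baseline[1])
  if (seg_len < window) window <- max(1, seg_len / 2)
  layout <- recording$layout
  extr <- layout$contact[layout$modality %in% c("subscalp", "scalp")]
  mean_db <- function(ch, from, to) {
    ps <- multitaper_psd(channel_signal(recording, ch, from, to), fs, window = window)
    sel <- ps$frequency >= range[1] & ps$frequency <= range[2]
    mean(ps$power_db[sel])
  }
  vals <- vapply(extr, function(ch) {
    mean_db(ch, onset, onset + duration) - mean_db(ch, baseline[1], baseline[2])
  }, numeric(1))
  values <- tibble::tibble(
    contact = extr,
    modality = layout$modality[match(extr, layout$contact)],
    value = vals
  )
  maps <- lapply(c(subscalp = "subscalp", scalp = "scalp"), function(m) {
    sel <- values$modality == m
    topo_map(
      dplyr::filter(layout, .data$modality == m),
      setNames(values$value[sel], values$contact[sel])
    )
  })
  structure(
    c(maps, list(values = values)),
    class = "ictal_power_map"
  )
}
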