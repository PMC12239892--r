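# Synthetic multimodal EEG with known ground truth: stage-specific
# narrowband oscillations on a 1/f background, dipolar interictal spikes,
# propagating seizures with evolving frequency, and evoked responses.
#
# Spatial model: a single-sphere head. Extracranial channels (scalp and
# subscalp) sample the surface field at their radial direction, so with a
# subscalp gain factor of 1 a subscalp contact and a coincident scalp
# contact see the same expected signal -- the stated basis of the
# noninferiority recovery tests. Diffuse stage rhythms use a smooth profile
# floor + (1-floor)*exp(-d/spread); focal discharges (spikes, seizures) use
# exp(-d/lambda) with a hard visibility floor.

#' Distance-decaying gain for focal sources
#'
#' `exp(-d / lambda)`, set to zero below `floor` (sources whose surface gain
#' falls under the floor are invisible extracranially).
#'
#' @param d Euclidean distance(s) in mm.
#' @param lambda Decay length-scale in mm (default 35).
#' @param floor Visibility floor (default 0.01).
#' @return Gain value(s) in `[0, 1]`.
#' @export
spatial_gain <- function(d, lambda = 35, floor = 0.01) {
  g <- exp(-d / lambda)
  g[g < floor] <- 0
  g
}

# smooth spatial profile for diffuse stage rhythms
source_profile <- function(d, spread = 100, floor = 0.2) {
  floor + (1 - floor) * exp(-d / spread)
}

# smooth log-normal amplitude field over the sensing points: regional
# variability in how strongly a rhythm is expressed, spatially correlated
# (squared-exponential kernel) so neighbouring contacts see almost the same
# factor while distant regions decorrelate
heterogeneity_field <- function(sense, sd_log10 = 0.15, length_mm = 40) {
  n <- nrow(sense)
  if (sd_log10 <= 0) return(rep(1, n))
  D2 <- as.matrix(stats::dist(sense))^2
  K <- exp(-D2 / (2 * length_mm^2)) + diag(1e-8, n)
  field <- sd_log10 * drop(t(chol(K)) %*% rnorm(n))
  10^(field / 2)
}

# named topographic landmarks resolved to surface positions
resolve_center <- function(center, radius) {
  if (is.character(center)) {
    dir <- switch(center,
      occipital = sph_dir(72, 180),
      occipital_left = sph_dir(72, 205),
      occipital_right = sph_dir(72, 155),
      parietal = sph_dir(36, 180),
      central = ,
      vertex = c(0, 0, 1),
      frontocentral = sph_dir(20, 0),
      frontal = sph_dir(36, 0),
      temporal_left = sph_dir(85, 290),
      temporal_right = sph_dir(85, 70),
      abort(sprintf("unknown source centre '%s'", center))
    )
    radius * dir
  } else {
    stopifnot(is.numeric(center), length(center) == 3)
    center
  }
}

# synthesis FFTs run at the next 2-3-5-smooth length and truncate, so the
# cost never degenerates on awkward (near-prime) sample counts
good_fft_n <- function(n) stats::nextn(n, c(2L, 3L, 5L))

# 1/f^chi background noise by spectral shaping of white noise; `offset` is
# log10 of the one-sided density (uV^2/Hz) at 1 Hz
powerlaw_noise <- function(n, fs, exponent = 1.5, offset = log10(3)) {
  n2 <- good_fft_n(n)
  w <- fft(rnorm(n2))
  k <- seq_len(n2) - 1
  f <- pmin(k, n2 - k) * fs / n2
  H <- numeric(n2)
  pos <- f > 0
  H[pos] <- sqrt(10^offset * f[pos]^(-exponent) / 2 * fs)
  Re(fft(w * H, inverse = TRUE))[seq_len(n)] / n2
}

# band-limited unit-RMS noise built in the frequency domain
band_noise <- function(n, fs, band) {
  n2 <- good_fft_n(n)
  k <- seq_len(n2) - 1
  f <- pmin(k, n2 - k) * fs / n2
  sel <- f >= band[1] & f <= band[2]
  X <- complex(length.out = n2)
  half <- which(sel & k <= n2 / 2)
  X[half] <- complex(real = rnorm(length(half)), imaginary = rnorm(length(half)))
  mirror <- n2 - (half - 1) + 1
  keep <- mirror >= 1 & mirror <= n2 & mirror != half
  X[mirror[keep]] <- Conj(X[half[keep]])
  x <- Re(fft(X, inverse = TRUE))[seq_len(n)] / n2
  rms <- sqrt(mean(x^2))
  if (rms == 0) x else x / rms
}

default_stage_sources <- function(bands = eeg_bands()) {
  list(
    list(stage = "W", band = bands$alpha, center = "occipital", amplitude = 6),
    list(stage = "N1", band = bands$theta, center = "central", amplitude = 3),
    list(stage = "N2", band = bands$sigma, center = "central", amplitude = 5),
    list(stage = "N3", band = bands$delta, center = "frontal", amplitude = 15),
    list(stage = "REM", band = bands$beta, center = "frontal", amplitude = 3)
  )
}

#' Simulation configuration
#'
#' Collects every tunable of the session generator. Stage sources are lists
#' with `stage`, `band` (Hz), `center` (landmark name or 3-vector, mm),
#' `amplitude` (uV RMS at the source), and optional `spread` / `floor`
#' overriding the config-wide spatial profile.
#'
#' @param sampling_rate Hz (default 256).
#' @param band_definitions Named band list, see [eeg_bands()].
#' @param sources Stage source specs (default [eeg_bands()]-based wake
#'   alpha, N1 theta, N2 sigma, N3 delta, REM beta).
#' @param aperiodic List with `exponent` (default 1.5) and `offset` (log10
#'   uV^2/Hz at 1 Hz, default `log10(3)`).
#' @param sensor_noise Named per-modality white-noise SD in uV.
#' @param subscalp_gain Dimensionless amplitude factor applied to source
#'   projections on subscalp channels (default 1).
#' @param source_spread,source_floor Spatial profile of diffuse stage
#'   rhythms (mm; dimensionless floor).
#' @param source_heterogeneity SD (log10 power units) of the smooth random
#'   regional-expression field multiplying each source's amplitude; 0
#'   disables it.
#' @param heterogeneity_scale Correlation length of that field in mm.
#' @param eyes_closed Whether wake epochs carry the posterior alpha source.
#' @param seed Integer; together with the layout fully determines the output.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(sampling_rate = 256,
                              band_definitions = eeg_bands(),
                              sources = default_stage_sources(band_definitions),
                              aperiodic = list(exponent = 1.5, offset = log10(3)),
                              sensor_noise = c(subscalp = 0.5, scalp = 0.5, intracranial = 0.5),
                              subscalp_gain = 1,
                              source_spread = 100,
                              source_floor = 0.2,
                              source_heterogeneity = 0.25,
                              heterogeneity_scale = 70,
                              eyes_closed = TRUE,
                              seed = NULL) {
  nyq <- sampling_rate / 2
  for (s in sources) {
    if (s$amplitude < 0) abort("source amplitudes must be >= 0")
    if (s$band[1] >= s$band[2] || s$band[2] >= nyq) {
      abort("source bands must satisfy f_lo < f_hi < Nyquist")
    }
  }
  if (any(sensor_noise < 0)) abort("sensor noise SDs must be >= 0")
  structure(
    list(
      sampling_rate = sampling_rate, band_definitions = band_definitions,
      sources = sources, aperiodic = aperiodic, sensor_noise = sensor_noise,
      subscalp_gain = subscalp_gain, source_spread = source_spread,
      source_floor = source_floor,
      source_heterogeneity = source_heterogeneity,
      heterogeneity_scale = heterogeneity_scale,
      eyes_closed = eyes_closed, seed = seed
    ),
    class = "simulation_config"
  )
}

#' Simulate a sleep-wake EEG session
#'
#' Each epoch receives its stage's narrowband sources projected to the
#' sensors with the smooth spatial profile, on top of per-channel 1/f
#' background and white sensor noise. Subscalp channels receive source
#' projections scaled by the subscalp gain factor. Wake epochs carry the
#' posterior alpha source only when `eyes_closed` is set.
#'
#' @param layout A [make_head_layout()] result.
#' @param hypnogram A [hypnogram()]; its total duration sets the recording
#'   length.
#' @param config A [simulation_config()].
#' @param seed Overrides `config$seed`.
#' @return An [eeg_recording()].
#' @export
simulate_session <- function(layout, hypnogram, config = simulation_config(),
                             seed = NULL) {
  seed <- seed %||% config$seed
  fs <- config$sampling_rate
  epoch_len <- attr(hypnogram, "epoch_length") %||% 30
  bad <- setdiff(unique(hypnogram$stage), sleep_stages())
  if (length(bad)) abort(sprintf("unknown stage label(s): %s", paste(bad, collapse = ", ")))
  n <- as.integer(round(nrow(hypnogram) * epoch_len * fs))
  nc <- nrow(layout)
  radius <- attr(layout, "radius") %||% 92
  sense <- sensing_points(layout)
  sub_scale <- ifelse(layout$modality == "subscalp", config$subscalp_gain, 1)
  with_seed_if(seed, {
    data <- matrix(0, nc, n)
    # one regional-expression field per source, fixed for the session
    fields <- lapply(config$sources, function(src) {
      heterogeneity_field(sense, config$source_heterogeneity,
                          config$heterogeneity_scale)
    })
    runs <- rle(hypnogram$stage)
    ends <- cumsum(runs$lengths)
    starts <- c(1L, head(ends, -1) + 1L)
    for (r in seq_along(runs$values)) {
      stage <- runs$values[r]
      i0 <- as.integer(round((starts[r] - 1) * epoch_len * fs)) + 1L
      i1 <- as.integer(round(ends[r] * epoch_len * fs))
      len <- i1 - i0 + 1L
      for (si in seq_along(config$sources)) {
        src <- config$sources[[si]]
        if (src$stage != stage) next
        if (stage == "W" && !config$eyes_closed) next
        ctr <- resolve_center(src$center, radius)
        d <- sqrt(colSums((t(sense) - ctr)^2))
        w <- source_profile(d, src$spread %||% config$source_spread,
                            src$floor %||% config$source_floor) * fields[[si]]
        s <- band_noise(len, fs, src$band)
        data[, i0:i1] <- data[, i0:i1] + (src$amplitude * w * sub_scale) %o% s
      }
    }
    sig <- config$sensor_noise[layout$modality]
    for (ch in seq_len(nc)) {
      data[ch, ] <- data[ch, ] +
        powerlaw_noise(n, fs, config$aperiodic$exponent, config$aperiodic$offset) +
        rnorm(n, 0, sig[ch])
    }
    eeg_recording(data, fs, layout, hypnogram = hypnogram)
  })
}

# biphasic spike waveform: 20 ms rise to the positive peak, zero-crossing at
# 40 ms, then a shallower negative lobe; 70 ms total, peak amplitude 1
spike_template <- function(fs) {
  t <- seq(0, 0.07, by = 1 / fs)
  w <- numeric(length(t))
  first <- t <= 0.04
  w[first] <- sin(pi * t[first] / 0.04)
  second <- t > 0.04
  w[second] <- -0.5 * sin(pi * (t[second] - 0.04) / 0.03)
  w
}

#' Add interictal spikes to a recording
#'
#' Adds a biphasic spike template (70 ms, 20 ms rise) at non-overlapping
#' onsets, projected with signed dipolar weighting: channels on the moment
#' side of the dipole see a positive lobe, channels on the far side a
#' negative one. Onsets are appended to the recording's events.
#'
#' @param recording An [eeg_recording()] with a layout.
#' @param n_spikes Number of spikes (>= 1).
#' @param dipole_position 3-vector, mm.
#' @param dipole_moment Unit moment direction; default radial (outward).
#' @param amplitude Source peak amplitude in uV.
#' @param jitter SD of per-spike amplitude variation (uV).
#' @param onsets Optional explicit onsets (s); overlapping onsets are
#'   rejected.
#' @param min_spacing Minimum spacing between generated onsets (s).
#' @param lambda,gain_floor Focal [spatial_gain()] parameters.
#' @param subscalp_gain Amplitude factor for subscalp channels.
#' @param seed Optional integer seed.
#' @return The annotated recording.
#' @export
simulate_spikes <- function(recording, n_spikes, dipole_position,
                            dipole_moment = NULL, amplitude = 40, jitter = 0,
                            onsets = NULL, min_spacing = 1,
                            lambda = 35, gain_floor = 0.01,
                            subscalp_gain = 1, seed = NULL) {
  stopifnot(n_spikes >= 1)
  layout <- recording$layout
  if (is.null(layout)) abort("recording must carry a layout")
  fs <- recording$fs
  tmpl <- spike_template(fs)
  dur <- length(tmpl) / fs
  total <- ncol(recording$data) / fs
  with_seed_if(seed, {
    if (is.null(onsets)) {
      slots <- seq(0.5, total - dur - 0.5, by = min_spacing)
      if (length(slots) < n_spikes) {
        abort("spikes would overlap: recording too short for `n_spikes` at `min_spacing`")
      }
      onsets <- sort(sample(slots, n_spikes))
    } else {
      onsets <- sort(onsets)
      if (length(onsets) != n_spikes) abort("`onsets` length must equal `n_spikes`")
      if (any(diff(onsets) < dur)) abort("spikes would overlap: onsets closer than the template duration")
      if (any(onsets < 0) || any(onsets + dur > total)) abort("spike onsets fall outside the recording")
    }
    m <- unit(dipole_moment %||% dipole_position)
    sense <- sensing_points(layout)
    dvec <- t(sense) - dipole_position
    d <- sqrt(colSums(dvec^2))
    u <- sweep(dvec, 2, pmax(d, 1e-9), "/")
    w <- spatial_gain(d, lambda, gain_floor) * colSums(u * m)
    w <- w * ifelse(layout$modality == "subscalp", subscalp_gain, 1)
    amps <- pmax(0, amplitude + rnorm(n_spikes, 0, jitter))
    data <- recording$data
    for (i in seq_len(n_spikes)) {
      i0 <- as.integer(round(onsets[i] * fs)) + 1L
      idx <- i0:(i0 + length(tmpl) - 1L)
      data[, idx] <- data[, idx] + (amps[i] * w) %o% tmpl
    }
    new_events <- tibble::tibble(
      onset = onsets, duration = dur, kind = "spike",
      attributes = purrr::map(seq_len(n_spikes), function(i) {
        list(position = dipole_position, moment = m, amplitude = amps[i])
      })
    )
    recording$data <- data
    recording$events <- dplyr::bind_rows(recording$events, new_events)
    recording
  })
}

#' Add a propagating seizure to a recording
#'
#' A chirp whose frequency moves linearly from `freq_start` to `freq_end`
#' and whose amplitude ramps up over the first third of the seizure starts
#' at the seizure-onset zone; a phase-perturbed copy appears at the
#' propagation zone after `propagation_delay`. Channels receive
#' distance-weighted mixtures through the focal [spatial_gain()]; deep
#' sources whose surface gain falls below the floor are extracranially
#' invisible.
#'
#' @param recording An [eeg_recording()] with a layout.
#' @param soz,pz Seizure-onset and propagation-zone positions (3-vectors,
#'   mm); must differ.
#' @param onset Seizure onset in seconds.
#' @param duration Seizure duration in seconds (> 0).
#' @param freq_start,freq_end Chirp frequency trajectory in Hz.
#' @param propagation_delay Delay before PZ involvement (s).
#' @param amplitude Source amplitude in uV.
#' @param phase_jitter SD of the PZ random-walk phase perturbation
#'   (rad/sqrt(s)).
#' @inheritParams simulate_spikes
#' @return The annotated recording.
#' @export
simulate_seizure <- function(recording, soz, pz, onset, duration,
                             freq_start = 7, freq_end = 3,
                             propagation_delay = 8, amplitude = 25,
                             phase_jitter = 0.5, lambda = 35,
                             gain_floor = 0.01, subscalp_gain = 1,
                             seed = NULL) {
  fs <- recording$fs
  nyq <- fs / 2
  total <- ncol(recording$data) / fs
  if (duration <= 0) abort("seizure duration must be > 0")
  if (onset + duration > total) abort("seizure extends past the end of the recording")
  if (freq_start <= 0 || freq_end <= 0 || freq_start >= nyq || freq_end >= nyq) {
    abort("frequency trajectory must lie within (0, Nyquist)")
  }
  if (all(soz == pz)) abort("SOZ and PZ positions must differ")
  layout <- recording$layout
  if (is.null(layout)) abort("recording must carry a layout")
  with_seed_if(seed, {
    n_s <- as.integer(round(duration * fs))
    tt <- (seq_len(n_s) - 1) / fs
    chirp_phase <- function(t) 2 * pi * (freq_start * t + (freq_end - freq_start) * t^2 / (2 * duration))
    ramp <- pmin(1, tt / (duration / 3)) * pmin(1, pmax(0, (duration - tt) / 2))
    c1 <- amplitude * ramp * sin(chirp_phase(tt))
    active <- tt >= propagation_delay
    t2 <- pmax(0, tt - propagation_delay)
    ramp2 <- pmin(1, t2 / (duration / 3)) * pmin(1, pmax(0, (duration - tt) / 2))
    pn <- cumsum(rnorm(n_s, 0, phase_jitter / sqrt(fs)))
    c2 <- amplitude * ramp2 * sin(chirp_phase(t2) + pn) * active
    sense <- sensing_points(layout)
    g1 <- spatial_gain(sqrt(colSums((t(sense) - soz)^2)), lambda, gain_floor)
    g2 <- spatial_gain(sqrt(colSums((t(sense) - pz)^2)), lambda, gain_floor)
    sub <- ifelse(layout$modality == "subscalp", subscalp_gain, 1)
    i0 <- as.integer(round(onset * fs)) + 1L
    idx <- i0:(i0 + n_s - 1L)
    recording$data[, idx] <- recording$data[, idx] +
      (g1 * sub) %o% c1 + (g2 * sub) %o% c2
    recording$events <- dplyr::bind_rows(
      recording$events,
      tibble::tibble(
        onset = onset, duration = duration, kind = "seizure",
        attributes = list(list(
          soz = soz, pz = pz, freq_start = freq_start, freq_end = freq_end,
          propagation_delay = propagation_delay, amplitude = amplitude
        ))
      )
    )
    recording
  })
}

default_evoked_components <- function(modality) {
  switch(modality,
    visual = tibble::tibble(
      latency = c(0.075, 0.100, 0.120, 0.145),
      amplitude = c(-4, 8.5, -3, -5.5),
      center = c("occipital_left", "occipital", "occipital_right", "parietal")
    ),
    auditory = tibble::tibble(
      latency = c(0.050, 0.100, 0.200),
      amplitude = c(2, -6.5, 3.5),
      center = c("vertex", "frontocentral", "frontocentral")
    )
  )
}

#' Simulate a stimulation session with evoked responses
#'
#' Each stimulus adds Gaussian-windowed component peaks at the stated
#' latencies, spatially projected from their topographic centres, on top of
#' the background noise of `config`. Stimulus onsets are annotated.
#'
#' @param layout A [make_head_layout()] result.
#' @param n_trials Number of stimuli (>= 1).
#' @param modality `"visual"` or `"auditory"` (chooses default components).
#' @param components Tibble with `latency` (s), `amplitude` (uV), `center`
#'   (landmark or 3-vector) and optional `width` (Gaussian SD, s).
#' @param isi Inter-stimulus interval in seconds.
#' @param config A [simulation_config()] (background/noise only).
#' @param spread,floor Spatial profile of the component fields.
#' @param seed Optional integer seed.
#' @return An [eeg_recording()] with `stimulus` events.
#' @export
simulate_evoked <- function(layout, n_trials, modality = c("visual", "auditory"),
                            components = NULL, isi = 0.7,
                            config = simulation_config(),
                            spread = 100, floor = 0.1, seed = NULL) {
  modality <- match.arg(modality)
  stopifnot(n_trials >= 1)
  components <- components %||% default_evoked_components(modality)
  if (any(components$latency > 0.3)) {
    warn("component latency exceeds the 0-300 ms analysis window; simulated anyway")
  }
  fs <- config$sampling_rate
  radius <- attr(layout, "radius") %||% 92
  duration <- 1 + n_trials * isi + 1
  n <- as.integer(round(duration * fs))
  nc <- nrow(layout)
  sense <- sensing_points(layout)
  sub <- ifelse(layout$modality == "subscalp", config$subscalp_gain, 1)
  with_seed_if(seed, {
    post <- seq(0, 0.45, by = 1 / fs)
    tmpl <- matrix(0, nc, length(post))
    for (ci in seq_len(nrow(components))) {
      comp <- components[ci, ]
      ctr <- resolve_center(comp$center[[1]], radius)
      d <- sqrt(colSums((t(sense) - ctr)^2))
      # each component has its own regional-expression field
      field <- heterogeneity_field(sense, config$source_heterogeneity %||% 0.25,
                                   config$heterogeneity_scale %||% 70)
      w <- source_profile(d, spread, floor) * field * sub
      width <- if ("width" %in% names(comp)) comp$width else 0.015
      wave <- comp$amplitude * exp(-(post - comp$latency)^2 / (2 * width^2))
      tmpl <- tmpl + w %o% wave
    }
    data <- matrix(0, nc, n)
    sig <- config$sensor_noise[layout$modality]
    for (ch in seq_len(nc)) {
      data[ch, ] <- powerlaw_noise(n, fs, config$aperiodic$exponent, config$aperiodic$offset) +
        rnorm(n, 0, sig[ch])
    }
    onsets <- 1 + (seq_len(n_trials) - 1) * isi
    for (on in onsets) {
      i0 <- as.integer(round(on * fs)) + 1L
      idx <- i0:(i0 + length(post) - 1L)
      data[, idx] <- data[, idx] + tmpl
    }
    events <- tibble::tibble(
      onset = onsets, duration = 0, kind = "stimulus",
      attributes = purrr::map(onsets, function(o) list(modality = modality))
    )
    eeg_recording(data, fs, layout, events = events)
  })
}
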