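# Study orchestration: simulate a cohort of co-registered multimodal
# recordings and run the five concordance analyses (wake alpha, sleep
# oscillations, sleep scoring, evoked potentials, ictal and interictal
# discharges) end-to-end, emitting a noninferiority report.

#' Configure a concordance study
#'
#' The default ("demo") study emulates an early-feasibility cohort: 8 participants
#' carrying 1, 2, 2, 2, 4, 4, 4 and 4 subscalp tridents (23 tridents, 161
#' subscalp contacts, n = 161 subscalp-scalp pairs pooled), 120 s of
#' eyes-closed wake, one epoch each of N2/N3/REM, 30 interictal spikes and
#' 5 seizures per participant, visual (498 trials) and auditory (207
#' trials) stimulation in 2 and 3 participants, and 3 sleep scorers.
#'
#' @param seed Integer master seed; every stage derives a child seed from it.
#' @param subscalp_gain Amplitude gain factor applied to subscalp source
#'   projections (1 = identical sensitivity; `10^(-1.5/20)` injects a
#'   -1.5 dB power attenuation).
#' @param analyses Character subset of
#'   `c("wake", "sleep", "scoring", "evoked", "ictal", "interictal",
#'   "coherence", "topo")`; `topo` adds the topographic spatial-correlation
#'   analyses and `coherence` the per-pair wake alpha coherence.
#' @param n_tridents Per-participant trident counts (1-4 each).
#' @param n_seizures Seizures per participant.
#' @param n_spikes Spikes per full-head participant.
#' @param scorer_flip_rate Stage-flip probability emulating scorer noise.
#' @param night_epochs Epochs per scored night.
#' @param n_shuffles Shuffles for permutation tests.
#' @param rule Noninferiority bias rule, `"ci"` or `"point"`.
#' @param margins Named list: `peak_power_db`, `voltage_uv`, `coherence`.
#' @param break_subscalp Replace subscalp signals by independent noise
#'   (negative control: every agreement should collapse).
#' @return List of class `study_config`.
#' @export
study_config <- function(seed = 1,
                         subscalp_gain = 1,
                         analyses = c("wake", "sleep", "scoring", "evoked",
                                      "ictal", "interictal", "coherence", "topo"),
                         n_tridents = c(1, 2, 2, 2, 4, 4, 4, 4),
                         n_seizures = 5,
                         n_spikes = 30,
                         scorer_flip_rate = 0.10,
                         night_epochs = 960,
                         n_shuffles = 100,
                         rule = c("ci", "point"),
                         margins = list(peak_power_db = -0.5, voltage_uv = -1,
                                        coherence = -0.03),
                         break_subscalp = FALSE) {
  rule <- match.arg(rule)
  stopifnot(all(n_tridents >= 1 & n_tridents <= 4))
  n_p <- length(n_tridents)
  participants <- tibble::tibble(
    id = sprintf("P%d", seq_len(n_p)),
    n_tridents = as.integer(n_tridents),
    full_head = n_tridents == 4
  )
  # evoked sessions: visual in 2 full-head participants, auditory in 3
  fh <- which(participants$full_head)
  participants$visual <- seq_len(n_p) %in% head(fh, 2)
  participants$auditory <- seq_len(n_p) %in% head(fh, 3)
  structure(
    list(
      seed = as.integer(seed), subscalp_gain = subscalp_gain,
      analyses = analyses, participants = participants,
      n_intracranial = 6, n_seizures = n_seizures, n_spikes = n_spikes,
      # between-participant variability: spike strength, evoked response
      # scale and overall rhythm expression differ across people
      # extracranial spike fields are skull-smeared: longer gain length-scale
      # than the generic focal default
      spike_amplitude_range = c(20, 85), spike_depth = 46, spike_jitter = 5,
      spike_lambda = 55, spike_jitter_mm = 3,
      # VEP fields are focal-occipital, AEP fields broad frontocentral
      evoked_scale_range = c(0.7, 1.8),
      evoked_spread = c(visual = 70, auditory = 120),
      evoked_floor = c(visual = 0.05, auditory = 0.1),
      evoked_heterogeneity = 0.15, evoked_heterogeneity_scale = 100,
      rhythm_sd_log10 = 0.15,
      seizure_duration = 45, seizure_delay = 8,
      seizure_freqs = c(7, 3),
      evoked_trials = c(visual = 498, auditory = 207), evoked_isi = 0.7,
      n_scorers = 3, scorer_flip_rate = scorer_flip_rate,
      night_epochs = night_epochs,
      wake_epochs = 4, bands = eeg_bands(),
      margins = margins, icc_threshold = 0.75, kappa_margin = 0.60,
      rule = rule, n_shuffles = n_shuffles, grid_resolution = 32,
      break_subscalp = break_subscalp
    ),
    class = "study_config"
  )
}

#' @rdname study_config
#' @export
demo_study_config <- function(seed = 1, ...) study_config(seed = seed, ...)

#' Read a study configuration from YAML
#'
#' Top-level keys map onto [study_config()] arguments (`seed`,
#' `subscalp_gain`, `analyses`, `n_tridents`, `n_seizures`, `n_spikes`,
#' `scorer_flip_rate`, `night_epochs`, `n_shuffles`, `rule`, `margins`,
#' `break_subscalp`); unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(study_config)), "...")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    abort(sprintf("unknown study config key(s): %s", paste(bad, collapse = ", ")))
  }
  if (!is.null(raw$n_tridents)) raw$n_tridents <- as.numeric(unlist(raw$n_tridents))
  do.call(study_config, raw)
}

subset_layout <- function(layout, contacts) {
  out <- layout[layout$contact %in% contacts, ]
  class(out) <- class(layout)
  attr(out, "radius") <- attr(layout, "radius")
  attr(out, "scalp_thickness") <- attr(layout, "scalp_thickness")
  out
}

# negative control: overwrite subscalp rows with independent background noise
break_subscalp_rows <- function(recording, seed) {
  sel <- which(recording$layout$modality == "subscalp")
  withr::with_seed(seed, {
    for (ch in sel) {
      recording$data[ch, ] <- powerlaw_noise(ncol(recording$data), recording$fs)
    }
  })
  recording
}

# per-channel band peaks over a time segment, via one batched transform set
segment_band_peaks <- function(recording, channels, from, to, band,
                               fit_range = c(1, 45)) {
  vapply(channels, function(ch) {
    ps <- multitaper_psd(channel_signal(recording, ch, from, to), recording$fs)
    fit <- fit_aperiodic(ps, fit_range = fit_range, exclude_bands = list(band))
    band_peak_power(ps, fit, band)$peak_power_db
  }, numeric(1))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run a concordance study end-to-end
#'
#' Simulates every participant's recordings from the single master seed and
#' executes the configured analyses: per-contact band peak power in wake
#' and sleep, nearest-neighbour pairing, pooled ICC / Bland-Altman /
#' noninferiority per measure, per-pair alpha coherence, topographic
#' spatial correlations with permutation nulls, sleep-scoring kappa with a
#' paired sign test, evoked mean amplitudes, peak-aligned spike amplitudes,
#' and ictal triplet coherence against the intracranial SOZ/PZ references.
#'
#' @param config A [study_config()].
#' @return Object of class `study_report`; see [tidy.study_report()].
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  an <- config$analyses
  bands <- config$bands
  wake_dur <- config$wake_epochs * 30
  measures <- tibble::tibble(
    measure = c("wake_alpha", "n2_sigma", "n3_delta", "rem_beta"),
    stage = c("W", "N2", "N3", "REM"),
    band = list(bands$alpha, bands$sigma, bands$delta, bands$beta)
  )
  stage_list <- c(rep("W", config$wake_epochs), "N2", "N3", "REM")
  seg_from <- c(wake_alpha = 0, n2_sigma = wake_dur, n3_delta = wake_dur + 30,
                rem_beta = wake_dur + 60)
  seg_to <- seg_from + c(wake_dur, 30, 30, 30)

  pairs_rows <- list()
  spatial_rows <- list()
  kappa_rows <- list()
  coh_rows <- list()
  seizure_rows <- list()

  for (i in seq_len(nrow(config$participants))) {
    p <- config$participants[i, ]
    sp <- child_seed(config$seed, p$id)
    layout <- make_head_layout(p$n_tridents, config$n_intracranial, seed = sp)
    pairing <- nearest_neighbor_pairing(layout)
    pair_ch <- unique(c(pairing$subscalp, pairing$scalp))
    do_topo <- "topo" %in% an && p$full_head
    extr_ch <- layout$contact[layout$modality %in% c("subscalp", "scalp")]
    sess_ch <- if (do_topo) extr_ch else pair_ch
    # per-participant amplitude variability (drawn once per participant)
    pvar <- withr::with_seed(child_seed(sp, "pvar"), list(
      rhythm_scale = 10^(rnorm(1, 0, config$rhythm_sd_log10)),
      evoked_scale = runif(1, config$evoked_scale_range[1],
                           config$evoked_scale_range[2]),
      spike_amplitude = runif(1, config$spike_amplitude_range[1],
                              config$spike_amplitude_range[2])
    ))
    psources <- lapply(default_stage_sources(bands), function(s) {
      s$amplitude <- s$amplitude * pvar$rhythm_scale
      s
    })

    if (any(c("wake", "sleep") %in% an)) {
      run_stage(paste0(p$id, ":session"), {
        sess_layout <- subset_layout(layout, sess_ch)
        hyp <- hypnogram(stage_list)
        simcfg <- simulation_config(sources = psources,
                                    subscalp_gain = config$subscalp_gain)
        rec <- simulate_session(sess_layout, hyp, simcfg,
                                seed = child_seed(sp, "session"))
        if (config$break_subscalp) {
          rec <- break_subscalp_rows(rec, child_seed(sp, "break"))
        }
        todo <- measures
        if (!"wake" %in% an) todo <- todo[todo$measure != "wake_alpha", ]
        if (!"sleep" %in% an) todo <- todo[todo$measure == "wake_alpha", ]
        for (j in seq_len(nrow(todo))) {
          m <- todo$measure[j]
          band <- todo$band[[j]]
          use_ch <- if (do_topo) extr_ch else pair_ch
          pk <- segment_band_peaks(rec, use_ch, seg_from[[m]], seg_to[[m]], band)
          pairs_rows[[paste(p$id, m)]] <- tibble::tibble(
            measure = m, participant = p$id,
            unit = paste(p$id, pairing$subscalp, sep = ":"),
            value_subscalp = pk[pairing$subscalp],
            value_scalp = pk[pairing$scalp],
            units = "dB"
          )
          if (do_topo) {
            map_sub <- topo_map(
              subset_layout(layout, pairing$subscalp),
              setNames(pk[pairing$subscalp], pairing$subscalp)
            )
            sca_ch <- layout$contact[layout$modality == "scalp"]
            map_sca <- topo_map(
              subset_layout(layout, sca_ch), setNames(pk[sca_ch], sca_ch)
            )
            pt <- permutation_spatial_test(
              map_sub, map_sca, n_shuffles = config$n_shuffles,
              seed = child_seed(sp, paste0("perm_", m)),
              grid_resolution = config$grid_resolution
            )
            spatial_rows[[paste(p$id, m)]] <- dplyr::bind_cols(
              tibble::tibble(participant = p$id, measure = m), tidy(pt)
            )
          }
          if (m == "wake_alpha" && "coherence" %in% an) {
            pc <- vapply(seq_len(nrow(pairing)), function(k) {
              co <- coherence(
                channel_signal(rec, pairing$subscalp[k], 0, wake_dur),
                channel_signal(rec, pairing$scalp[k], 0, wake_dur),
                rec$fs
              )
              band_peak_coherence(co, bands$alpha)
            }, numeric(1))
            coh_rows[[p$id]] <- tibble::tibble(
              participant = p$id, pair = pairing$subscalp,
              alpha_peak_coherence = pc
            )
          }
        }
      })
    }

    if ("scoring" %in% an) {
      run_stage(paste0(p$id, ":scoring"), {
        truth <- make_hypnogram(config$night_epochs, seed = child_seed(sp, "night"))
        scored <- list()
        for (s in seq_len(config$n_scorers)) {
          for (mod in c("subscalp", "scalp")) {
            scored[[paste(s, mod)]] <- corrupt_hypnogram(
              truth, config$scorer_flip_rate,
              seed = child_seed(sp, paste("scorer", s, mod))
            )
          }
        }
        for (mod in c("subscalp", "scalp")) {
          combs <- utils::combn(config$n_scorers, 2)
          for (cc in seq_len(ncol(combs))) {
            kr <- cohens_kappa(
              scored[[paste(combs[1, cc], mod)]],
              scored[[paste(combs[2, cc], mod)]],
              margin = config$kappa_margin
            )
            kappa_rows[[paste(p$id, "inter", mod, cc)]] <- tibble::tibble(
              participant = p$id, type = "inter", modality = mod,
              scorer_pair = paste(combs[, cc], collapse = "-"),
              kappa = kr$kappa, pass = kr$pass
            )
          }
        }
        for (s in seq_len(config$n_scorers)) {
          kr <- cohens_kappa(
            scored[[paste(s, "subscalp")]], scored[[paste(s, "scalp")]],
            margin = config$kappa_margin
          )
          kappa_rows[[paste(p$id, "intra", s)]] <- tibble::tibble(
            participant = p$id, type = "intra", modality = "both",
            scorer_pair = as.character(s), kappa = kr$kappa, pass = kr$pass
          )
        }
      })
    }

    if ("evoked" %in% an && (p$visual || p$auditory)) {
      run_stage(paste0(p$id, ":evoked"), {
        mods <- c("visual", "auditory")[c(p$visual, p$auditory)]
        for (mod in mods) {
          elay <- subset_layout(layout, sess_ch)
          ecfg <- simulation_config(
            subscalp_gain = config$subscalp_gain,
            source_heterogeneity = config$evoked_heterogeneity,
            heterogeneity_scale = config$evoked_heterogeneity_scale
          )
          comps <- default_evoked_components(mod)
          comps$amplitude <- comps$amplitude * pvar$evoked_scale
          rec_e <- simulate_evoked(
            elay, config$evoked_trials[[mod]], mod, components = comps,
            isi = config$evoked_isi, spread = config$evoked_spread[[mod]],
            floor = config$evoked_floor[[mod]],
            config = ecfg, seed = child_seed(sp, paste0("evoked_", mod))
          )
          if (config$break_subscalp) {
            rec_e <- break_subscalp_rows(rec_e, child_seed(sp, paste0("bk_", mod)))
          }
          ev <- epoch_average(rec_e)
          # mean signed amplitude in a 50-ms window centred on the dominant
          # component (global-field-power peak within 0-300 ms)
          gfp <- global_field_power(ev)
          sel <- gfp$time >= 0 & gfp$time <= 0.3
          pk_t <- gfp$time[sel][which.max(gfp$gfp[sel])]
          win <- ev$times >= pk_t - 0.025 & ev$times <= pk_t + 0.025
          amp <- rowMeans(ev$data[, win, drop = FALSE])
          names(amp) <- ev$channels
          pairs_rows[[paste(p$id, mod)]] <- tibble::tibble(
            measure = paste0("evoked_", mod), participant = p$id,
            unit = paste(p$id, pairing$subscalp, sep = ":"),
            value_subscalp = amp[pairing$subscalp],
            value_scalp = amp[pairing$scalp],
            units = "uV"
          )
          if (do_topo) {
            map_sub <- topo_map(
              subset_layout(layout, pairing$subscalp), amp[pairing$subscalp]
            )
            sca_ch <- intersect(names(amp), layout$contact[layout$modality == "scalp"])
            map_sca <- topo_map(subset_layout(layout, sca_ch), amp[sca_ch])
            pt <- permutation_spatial_test(
              map_sub, map_sca, n_shuffles = config$n_shuffles,
              seed = child_seed(sp, paste0("perm_ev_", mod)),
              grid_resolution = config$grid_resolution
            )
            spatial_rows[[paste(p$id, mod)]] <- dplyr::bind_cols(
              tibble::tibble(participant = p$id, measure = paste0("evoked_", mod)),
              tidy(pt)
            )
          }
        }
      })
    }

    if ("interictal" %in% an && p$full_head) {
      run_stage(paste0(p$id, ":interictal"), {
        slay <- subset_layout(layout, sess_ch)
        qcfg <- simulation_config(eyes_closed = FALSE,
                                  subscalp_gain = config$subscalp_gain)
        quiet <- simulate_session(
          slay, hypnogram(rep("W", 2)), qcfg, seed = child_seed(sp, "quiet")
        )
        # dipole beneath a randomly chosen subscalp contact (a spike whose
        # field reaches the sampled convexity), jittered laterally
        dip_seed <- child_seed(sp, "dipole")
        sub_contacts <- layout[layout$modality == "subscalp", ]
        dip <- withr::with_seed(dip_seed, {
          anchor <- as.numeric(sub_contacts[sample(nrow(sub_contacts), 1),
                                            c("x", "y", "z")])
          config$spike_depth * unit(anchor + rnorm(3, 0, config$spike_jitter_mm))
        })
        spiked <- simulate_spikes(
          quiet, config$n_spikes, dip,
          amplitude = pvar$spike_amplitude, jitter = config$spike_jitter,
          lambda = config$spike_lambda,
          subscalp_gain = config$subscalp_gain,
          seed = child_seed(sp, "spikes")
        )
        if (config$break_subscalp) {
          spiked <- break_subscalp_rows(spiked, child_seed(sp, "bk_sp"))
        }
        sub_lay <- dplyr::filter(layout, .data$modality == "subscalp")
        dsub <- sqrt(colSums((t(as.matrix(sub_lay[, c("x", "y", "z")])) - dip)^2))
        align <- sub_lay$contact[which.min(dsub)]
        sa <- spike_peak_average(spiked, alignment_channel = align,
                                 n_max = config$n_spikes)
        amp <- setNames(sa$peak_amplitudes$amplitude, sa$peak_amplitudes$contact)
        pairs_rows[[paste(p$id, "spike")]] <- tibble::tibble(
          measure = "spike_amplitude", participant = p$id,
          unit = paste(p$id, pairing$subscalp, sep = ":"),
          value_subscalp = amp[pairing$subscalp],
          value_scalp = amp[pairing$scalp],
          units = "uV"
        )
        if (do_topo) {
          map_sub <- topo_map(
            subset_layout(layout, pairing$subscalp), amp[pairing$subscalp]
          )
          sca_ch <- intersect(names(amp), layout$contact[layout$modality == "scalp"])
          map_sca <- topo_map(subset_layout(layout, sca_ch), amp[sca_ch])
          pt <- permutation_spatial_test(
            map_sub, map_sca, n_shuffles = config$n_shuffles,
            seed = child_seed(sp, "perm_spike"),
            grid_resolution = config$grid_resolution
          )
          spatial_rows[[paste(p$id, "spike")]] <- dplyr::bind_cols(
            tibble::tibble(participant = p$id, measure = "spike_amplitude"),
            tidy(pt)
          )
        }
      })
    }

    if ("ictal" %in% an) {
      run_stage(paste0(p$id, ":ictal"), {
        soz <- as.numeric(layout[layout$contact == "IC1", c("x", "y", "z")])
        pz <- as.numeric(layout[layout$contact == "IC2", c("x", "y", "z")])
        triplet <- select_ictal_triplet(layout, soz)
        need <- unique(c(triplet$contact, "IC1", "IC2"))
        zcfg <- simulation_config(eyes_closed = FALSE,
                                  subscalp_gain = config$subscalp_gain)
        for (z in seq_len(config$n_seizures)) {
          zseed <- child_seed(sp, paste0("seizure", z))
          zamp <- withr::with_seed(zseed, runif(1, 10, 35))
          zl <- subset_layout(layout, need)
          rec_z <- simulate_session(
            zl, hypnogram(rep("W", 2)), zcfg, seed = child_seed(zseed, "bg")
          )
          rec_z <- simulate_seizure(
            rec_z, soz, pz, onset = 7, duration = config$seizure_duration,
            freq_start = config$seizure_freqs[1],
            freq_end = config$seizure_freqs[2],
            propagation_delay = config$seizure_delay, amplitude = zamp,
            subscalp_gain = config$subscalp_gain,
            seed = child_seed(zseed, "chirp")
          )
          if (config$break_subscalp) {
            rec_z <- break_subscalp_rows(rec_z, child_seed(zseed, "bk"))
          }
          prof <- ictal_coherence_profile(
            rec_z, list(onset = 7, duration = config$seizure_duration),
            triplet, soz_channel = "IC1", pz_channel = "IC2", tf = FALSE
          )
          wide <- tidyr::pivot_wider(
            prof$profile[, c("modality", "zone", "coherence")],
            names_from = "modality", values_from = "coherence"
          )
          seizure_rows[[paste(p$id, z)]] <- tibble::tibble(
            participant = p$id, seizure = z, zone = wide$zone,
            value_subscalp = wide$subscalp, value_scalp = wide$scalp
          )
        }
        if (do_topo) {
          zl <- subset_layout(layout, unique(c(extr_ch, "IC1", "IC2")))
          rec_m <- simulate_session(
            zl, hypnogram(rep("W", 2)), zcfg, seed = child_seed(sp, "mapbg")
          )
          mamp <- withr::with_seed(child_seed(sp, "mapamp"), runif(1, 20, 35))
          rec_m <- simulate_seizure(
            rec_m, soz, pz, onset = 7, duration = config$seizure_duration,
            freq_start = config$seizure_freqs[1],
            freq_end = config$seizure_freqs[2],
            propagation_delay = config$seizure_delay, amplitude = mamp,
            subscalp_gain = config$subscalp_gain,
            seed = child_seed(sp, "mapchirp")
          )
          if (config$break_subscalp) {
            rec_m <- break_subscalp_rows(rec_m, child_seed(sp, "bk_map"))
          }
          pm <- ictal_power_increase_map(
            rec_m, list(onset = 7, duration = config$seizure_duration),
            baseline = c(1, 6)
          )
          pt <- permutation_spatial_test(
            pm$subscalp, pm$scalp, n_shuffles = config$n_shuffles,
            seed = child_seed(sp, "perm_ictal"),
            grid_resolution = config$grid_resolution
          )
          spatial_rows[[paste(p$id, "ictal")]] <- dplyr::bind_cols(
            tibble::tibble(participant = p$id, measure = "ictal_power"),
            tidy(pt)
          )
        }
      })
    }
  }

  pairs <- dplyr::bind_rows(pairs_rows)
  seizures <- dplyr::bind_rows(seizure_rows)
  if (nrow(seizures)) {
    for (zone in unique(seizures$zone)) {
      sel <- seizures[seizures$zone == zone, ]
      pairs <- dplyr::bind_rows(pairs, tibble::tibble(
        measure = paste0("ictal_coherence_", zone),
        participant = sel$participant,
        unit = paste(sel$participant, sel$seizure, sep = ":"),
        value_subscalp = sel$value_subscalp,
        value_scalp = sel$value_scalp,
        units = "coherence"
      ))
    }
  }

  margin_for <- function(units) switch(units,
    dB = config$margins$peak_power_db,
    uV = config$margins$voltage_uv,
    coherence = config$margins$coherence
  )
  agreement_rows <- list()
  decision_rows <- list()
  for (m in unique(pairs$measure)) {
    run_stage(paste0("pool:", m), {
      sel <- pairs[pairs$measure == m, ]
      ag <- agreement(sel, units = sel$units[1])
      agreement_rows[[m]] <- dplyr::bind_cols(tibble::tibble(measure = m), tidy(ag))
      dec <- noninferiority(ag, margin_for(sel$units[1]),
                            icc_threshold = config$icc_threshold,
                            rule = config$rule)
      decision_rows[[m]] <- dplyr::bind_cols(tibble::tibble(measure = m), dec)
    })
  }

  kappa <- dplyr::bind_rows(kappa_rows)
  sign_test <- NULL
  if (nrow(kappa) && length(unique(kappa$participant)) >= 5) {
    med <- kappa |>
      dplyr::filter(.data$type == "inter") |>
      dplyr::group_by(.data$participant, .data$modality) |>
      dplyr::summarise(kappa = stats::median(.data$kappa), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "modality", values_from = "kappa")
    sign_test <- paired_sign_test(med$subscalp, med$scalp)
  }

  structure(
    list(
      config = config,
      pairs = pairs,
      agreement = dplyr::bind_rows(agreement_rows),
      noninferiority = dplyr::bind_rows(decision_rows),
      alpha_coherence = dplyr::bind_rows(coh_rows),
      spatial = dplyr::bind_rows(spatial_rows),
      kappa = kappa,
      sign_test = sign_test,
      seizures = seizures,
      provenance = list(
        seed = config$seed,
        config_hash = rlang::hash(config),
        package_version = as.character(utils::packageVersion("eegconcord"))
      )
    ),
    class = "study_report"
  )
}

#' Did every noninferiority check of a study pass?
#'
#' `TRUE` when every pooled measure passes its margin and ICC threshold and
#' every scoring kappa exceeds its margin.
#'
#' @param report A [run_study()] result.
#' @return Logical scalar.
#' @export
all_noninferior <- function(report) {
  stopifnot(inherits(report, "study_report"))
  ok <- all(report$noninferiority$overall)
  if (nrow(report$kappa)) ok <- ok && all(report$kappa$pass)
  ok
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf(
    "<study_report> seed %d: %d measures, %d pairs pooled, all noninferior: %s\n",
    x$provenance$seed, nrow(x$noninferiority), nrow(x$pairs),
    all_noninferior(x)
  ))
  print(x$noninferiority[, c("measure", "units", "icc", "bias", "margin",
                             "icc_pass", "bias_pass", "overall")])
  invisible(x)
}

#' Tidy a study report
#'
#' @param x A [run_study()] result.
#' @param ... Unused.
#' @return The noninferiority decision table joined with agreement CIs.
#' @export
tidy.study_report <- function(x, ...) {
  dplyr::left_join(
    x$agreement,
    x$noninferiority[, c("measure", "margin", "icc_pass", "bias_pass",
                         "overall", "rule_version")],
    by = "measure"
  )
}

#' @export
glance.study_report <- function(x, ...) {
  tibble::tibble(
    seed = x$provenance$seed,
    n_measures = nrow(x$noninferiority),
    n_pairs = nrow(x$pairs),
    all_noninferior = all_noninferior(x),
    median_inter_kappa = if (nrow(x$kappa)) {
      stats::median(x$kappa$kappa[x$kappa$type == "inter"])
    } else NA_real_
  )
}

#' Serialise a study report
#'
#' @param report A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` (one file per table), `"json"`, or `"markdown"`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, format = c("tsv", "json", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- list(
    agreement = report$agreement,
    noninferiority = report$noninferiority,
    pairs = report$pairs,
    spatial = report$spatial,
    kappa = report$kappa,
    seizures = report$seizures,
    alpha_coherence = report$alpha_coherence
  )
  tables <- tables[vapply(tables, function(t) !is.null(t) && nrow(t) > 0, logical(1))]
  paths <- character(0)
  if (format == "tsv") {
    for (nm in names(tables)) {
      path <- file.path(dir, paste0(nm, ".tsv"))
      readr::write_tsv(tables[[nm]], path)
      paths <- c(paths, path)
    }
  } else if (format == "json") {
    path <- file.path(dir, "report.json")
    payload <- c(tables, list(provenance = report$provenance))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    paths <- path
  } else {
    path <- file.path(dir, "report.md")
    lines <- c("# Concordance study report", "",
               sprintf("Master seed: %d; config hash: %s", report$provenance$seed,
                       report$provenance$config_hash), "")
    for (m in seq_len(nrow(report$noninferiority))) {
      d <- report$noninferiority[m, ]
      a <- report$agreement[report$agreement$measure == d$measure, ]
      lines <- c(lines, sprintf(
        "- %s: ICC %.2f [%.2f, %.2f], bias %.2f %s [%.2f, %.2f], margin %g %s: %s",
        d$measure, a$icc, a$icc_lower, a$icc_upper, a$bias, d$units,
        a$bias_lower, a$bias_upper, d$margin, d$units,
        if (d$overall) "noninferior" else "NOT noninferior"
      ))
    }
    writeLines(lines, path)
    paths <- path
  }
  invisible(paths)
}
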