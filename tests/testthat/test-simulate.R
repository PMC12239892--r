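test_that("head layouts honour the montage and trident contact counts", {
  lay <- make_head_layout(4, 6, seed = 1)
  counts <- table(lay$modality)
  expect_equal(unname(counts["scalp"]), 25)
  expect_equal(unname(counts["subscalp"]), 28)
  expect_equal(unname(counts["intracranial"]), 6)
  lay1 <- make_head_layout(1, 0, seed = 99)
  expect_equal(sum(lay1$modality == "subscalp"), 7)
  expect_equal(sum(lay1$modality == "scalp"), 25)
  expect_false(any(duplicated(lay$contact)))
})

test_that("layout geometry puts each modality at its radius", {
  lay <- make_head_layout(3, 4, seed = 7)
  r <- sqrt(lay$x^2 + lay$y^2 + lay$z^2)
  expect_equal(r[lay$modality == "scalp"], rep(92, 25), tolerance = 1e-9)
  expect_equal(r[lay$modality == "subscalp"], rep(85, 21), tolerance = 1e-9)
  expect_true(all(r[lay$modality == "intracranial"] < 85))
})

test_that("layout generation is deterministic in the seed and validates n_tridents", {
  a <- make_head_layout(2, 3, seed = 5)
  b <- make_head_layout(2, 3, seed = 5)
  expect_identical(a, b)
  c <- make_head_layout(2, 3, seed = 6)
  expect_false(identical(a, c))
  expect_error(make_head_layout(0), "between 1 and 4")
  expect_error(make_head_layout(5), "between 1 and 4")
})

test_that("simulated wake alpha is posterior-dominant", {
  lay <- make_head_layout(4, 0, seed = 2)
  cfg <- simulation_config(sensor_noise = c(subscalp = 0.2, scalp = 0.2,
                                            intracranial = 0.2))
  rec <- simulate_session(lay, hypnogram(rep("W", 4)), cfg, seed = 3)
  band_power <- function(ch) {
    ps <- multitaper_psd(channel_signal(rec, ch), rec$fs)
    sel <- ps$frequency >= 8 & ps$frequency <= 12
    sum(ps$power[sel]) * 0.2
  }
  expect_gt(band_power("O1"), band_power("Fp1"))
  expect_gt(band_power("O2"), band_power("Fp2"))
})

test_that("a zero-amplitude source leaves only the aperiodic background", {
  lay <- make_head_layout(1, 0, seed = 2)
  cfg <- simulation_config(
    sources = list(list(stage = "W", band = c(8, 12), center = "occipital",
                        amplitude = 0)),
    sensor_noise = c(subscalp = 0, scalp = 0, intracranial = 0)
  )
  rec <- simulate_session(lay, hypnogram(rep("W", 8)), cfg, seed = 4)
  ps <- multitaper_psd(channel_signal(rec, "O1"), rec$fs)
  sel <- ps$frequency >= 2 & ps$frequency <= 40
  predicted_db <- 10 * (log10(3) - 1.5 * log10(ps$frequency[sel]))
  expect_lt(mean(abs(ps$power_db[sel] - predicted_db)), 1)
})

test_that("N2 sigma peak power is recovered at its analytic SNR over repeated seeds", {
  lay <- make_head_layout(1, 0, seed = 2)
  A <- 5 # source amplitude, uV RMS
  cfg <- simulation_config(
    sources = list(list(stage = "N2", band = c(11, 16), center = "central",
                        amplitude = A)),
    source_heterogeneity = 0
  )
  peaks <- vapply(1:20, function(s) {
    rec <- simulate_session(lay, hypnogram(rep("N2", 2)), cfg, seed = s)
    ps <- multitaper_psd(channel_signal(rec, "Cz"), rec$fs)
    fit <- fit_aperiodic(ps, exclude_bands = list(c(11, 16)))
    band_peak_power(ps, fit, c(11, 16))$peak_power_db
  }, numeric(1))
  # at the vertex the profile gain is 1, the in-band source density is
  # A^2 / bandwidth, and the background density is the 1/f law mid-band
  snr <- (A^2 / 5) / (3 * 13.5^(-1.5))
  predicted <- 10 * log10(1 + snr)
  expect_lt(abs(mean(peaks) - predicted), 0.5)
  expect_true(all(abs(peaks - predicted) < 1.5))
})

test_that("sessions are bit-identical under a fixed seed", {
  lay <- make_head_layout(1, 0, seed = 1)
  hyp <- hypnogram(c("W", "N2"))
  cfg <- simulation_config()
  r1 <- simulate_session(lay, hyp, cfg, seed = 10)
  r2 <- simulate_session(lay, hyp, cfg, seed = 10)
  expect_identical(r1$data, r2$data)
  expect_error(
    simulate_session(lay, structure(tibble::tibble(epoch = 1, stage = "X"),
                                    epoch_length = 30), cfg),
    "unknown stage"
  )
})

test_that("doubling a source amplitude quadruples its band power at every channel", {
  lay <- make_head_layout(1, 0, seed = 1)
  mk <- function(a) {
    cfg <- simulation_config(
      sources = list(list(stage = "W", band = c(8, 12), center = "occipital",
                          amplitude = a)),
      aperiodic = list(exponent = 1.5, offset = -Inf),
      sensor_noise = c(subscalp = 0, scalp = 0, intracranial = 0)
    )
    simulate_session(lay, hypnogram(rep("W", 2)), cfg, seed = 5)
  }
  r1 <- mk(4); r2 <- mk(8)
  p1 <- rowSums(r1$data^2)
  p2 <- rowSums(r2$data^2)
  expect_equal(p2 / p1, rep(4, nrow(lay)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("focal gain decreases strictly with distance and respects the floor", {
  d <- seq(0, 150, by = 5)
  g <- spatial_gain(d, lambda = 35, floor = 0.01)
  nz <- g[g > 0]
  expect_true(all(diff(nz) < 0))
  expect_true(all(g[exp(-d / 35) < 0.01] == 0))
})

test_that("coincident subscalp and scalp channels see equal expected band power", {
  # matched positions: a subscalp contact directly beneath each scalp contact
  base <- make_head_layout(1, 0, seed = 3)
  sca <- base[base$modality == "scalp", ][1:10, ]
  sub <- sca
  sub$contact <- paste0("U", seq_len(nrow(sub)))
  sub$modality <- "subscalp"
  sub[, c("x", "y", "z")] <- sub[, c("x", "y", "z")] * (85 / 92)
  lay <- dplyr::bind_rows(sca, sub)
  class(lay) <- class(base)
  attr(lay, "radius") <- 92
  attr(lay, "scalp_thickness") <- 7
  cfg <- simulation_config(source_heterogeneity = 0)
  diffs <- vapply(1:8, function(s) {
    rec <- simulate_session(lay, hypnogram(rep("W", 4)), cfg, seed = s)
    bp <- vapply(lay$contact, function(ch) {
      ps <- multitaper_psd(channel_signal(rec, ch), rec$fs)
      sel <- ps$frequency >= 8 & ps$frequency <= 12
      10 * log10(sum(ps$power[sel]))
    }, numeric(1))
    mean(bp[sub$contact] - bp[sca$contact])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.25)
})

test_that("the subscalp gain factor scales only subscalp source projections", {
  lay <- make_head_layout(1, 0, seed = 3)
  cfg0 <- simulation_config(
    aperiodic = list(exponent = 1.5, offset = -Inf),
    sensor_noise = c(subscalp = 0, scalp = 0, intracranial = 0)
  )
  cfg1 <- simulation_config(
    subscalp_gain = 0.5,
    aperiodic = list(exponent = 1.5, offset = -Inf),
    sensor_noise = c(subscalp = 0, scalp = 0, intracranial = 0)
  )
  r0 <- simulate_session(lay, hypnogram("W"), cfg0, seed = 6)
  r1 <- simulate_session(lay, hypnogram("W"), cfg1, seed = 6)
  sub <- lay$modality == "subscalp"
  expect_equal(r1$data[sub, ], 0.5 * r0$data[sub, ], tolerance = 1e-12)
  expect_identical(r1$data[!sub, ], r0$data[!sub, ])
})

test_that("noiseless spike averaging recovers the projected template peak exactly", {
  lay <- make_head_layout(4, 0, seed = 4)
  quiet <- eeg_recording(matrix(0, nrow(lay), 256 * 40), 256, lay)
  dip <- 70 * unit(c(40, 30, 60))
  rec <- simulate_spikes(quiet, 30, dip, amplitude = 40, jitter = 0, seed = 8)
  sense <- eegconcord:::sensing_points(lay)
  dv <- t(sense) - dip
  dd <- sqrt(colSums(dv^2))
  w <- spatial_gain(dd) * colSums(sweep(dv, 2, dd, "/") * unit(dip))
  nearest <- lay$contact[which.max(abs(w))]
  sa <- spike_peak_average(rec, alignment_channel = nearest)
  got <- sa$peak_amplitudes$amplitude[sa$peak_amplitudes$contact == nearest]
  peak_cap <- max(eegconcord:::spike_template(256))
  expect_equal(unname(got), unname(40 * w[which.max(abs(w))] * peak_cap),
               tolerance = 1e-6)
  expect_equal(sa$n_spikes, 30)
})

test_that("averaging suppresses noise as sigma/sqrt(n)", {
  lay <- make_head_layout(1, 0, seed = 4)
  sigma <- 3
  resid_sd <- vapply(c(10, 30, 100), function(n_sp) {
    rec <- white_noise_recording(lay, duration = n_sp * 1.2 + 2, sd = sigma, seed = n_sp)
    rec <- simulate_spikes(rec, n_sp, 70 * unit(c(0, -40, 50)), amplitude = 0,
                           jitter = 0, seed = n_sp + 1)
    sa <- spike_peak_average(rec, alignment_channel = lay$contact[1],
                             n_max = n_sp, align = FALSE)
    sd(as.vector(sa$data))
  }, numeric(1))
  expect_equal(resid_sd, sigma / sqrt(c(10, 30, 100)), tolerance = 0.25)
  # strictly decreasing with n
  expect_true(all(diff(resid_sd) < 0))
})

test_that("overlapping spikes are rejected", {
  lay <- make_head_layout(1, 0, seed = 4)
  rec <- white_noise_recording(lay, duration = 5)
  expect_error(
    simulate_spikes(rec, 3, c(0, 0, 70), onsets = c(1, 1.02, 2)),
    "overlap"
  )
  expect_error(simulate_spikes(rec, 100, c(0, 0, 70), seed = 1), "overlap")
})

test_that("two dipoles produce distinct spike topographies", {
  lay <- make_head_layout(4, 0, seed = 5)
  quiet <- eeg_recording(matrix(0, nrow(lay), 256 * 80), 256, lay)
  rec <- simulate_spikes(quiet, 30, 70 * unit(c(60, 20, 40)), amplitude = 40,
                         onsets = seq(1, 30, by = 1), jitter = 0)
  rec2 <- simulate_spikes(rec, 30, 70 * unit(c(-60, -20, 40)), amplitude = 40,
                          onsets = seq(40, 69, by = 1), jitter = 0)
  sub <- lay$contact[lay$modality == "subscalp"]
  on1 <- rec2$events$onset[1:30]
  on2 <- rec2$events$onset[31:60]
  a1 <- spike_peak_average(rec2, on1, alignment_channel = sub[1])$peak_amplitudes
  a2 <- spike_peak_average(rec2, on2, alignment_channel = sub[1])$peak_amplitudes
  expect_lt(cor(a1$amplitude, a2$amplitude), 0.5)
})

test_that("seizures propagate to the PZ after the stated delay", {
  lay <- make_head_layout(1, 2, seed = 6)
  soz <- as.numeric(lay[lay$contact == "IC1", c("x", "y", "z")])
  pz <- as.numeric(lay[lay$contact == "IC2", c("x", "y", "z")])
  quiet <- eeg_recording(matrix(0, nrow(lay), 256 * 120), 256, lay)
  rec <- simulate_seizure(quiet, soz, pz, onset = 10, duration = 90,
                          propagation_delay = 10, amplitude = 20, seed = 7)
  onset_time <- function(ch) {
    x <- channel_signal(rec, ch)
    env <- stats::filter(x^2, rep(1 / 256, 256), sides = 2)
    thr <- 0.05 * max(env, na.rm = TRUE)
    (which(env > thr)[1] - 1) / 256
  }
  expect_gte(onset_time("IC2") - onset_time("IC1"), 8)
  # zero amplitude leaves the recording bit-identical
  rec0 <- simulate_seizure(quiet, soz, pz, onset = 10, duration = 90,
                           amplitude = 0, seed = 7)
  expect_identical(rec0$data, quiet$data)
})

test_that("deep seizures below the gain floor are extracranially invisible", {
  lay <- make_head_layout(4, 2, seed = 8)
  soz <- c(0, 10, 20)  # deep-seated source
  pz <- c(0, -10, 20)
  quiet <- eeg_recording(matrix(0, nrow(lay), 256 * 80), 256, lay)
  # with a short decay length the surface gain falls below the floor
  rec <- simulate_seizure(quiet, soz, pz, onset = 5, duration = 60,
                          amplitude = 30, lambda = 10, gain_floor = 0.01,
                          seed = 9)
  extr <- lay$modality %in% c("subscalp", "scalp")
  expect_equal(max(abs(rec$data[extr, ])), 0)
  # the same seizure at a superficial source is visible
  rec2 <- simulate_seizure(quiet, 80 * unit(c(50, 30, 40)),
                           70 * unit(c(30, 50, 40)), onset = 5, duration = 60,
                           amplitude = 30, lambda = 35, seed = 9)
  expect_gt(max(abs(rec2$data[extr, ])), 1)
})

test_that("seizure preconditions are enforced", {
  lay <- make_head_layout(1, 2, seed = 6)
  quiet <- eeg_recording(matrix(0, nrow(lay), 256 * 30), 256, lay)
  expect_error(simulate_seizure(quiet, c(0, 0, 50), c(0, 0, 50), 1, 10),
               "must differ")
  expect_error(simulate_seizure(quiet, c(0, 0, 50), c(10, 0, 50), 25, 10),
               "past the end")
  expect_error(simulate_seizure(quiet, c(0, 0, 50), c(10, 0, 50), 1, 10,
                                freq_start = 200), "Nyquist")
})

test_that("evoked averaging recovers components at the 1/sqrt(n) rate", {
  lay <- make_head_layout(4, 0, seed = 9)
  cfg <- simulation_config()
  for (case in list(list(mod = "visual", n = 498), list(mod = "auditory", n = 207))) {
    rec <- simulate_evoked(lay, case$n, case$mod, config = cfg, seed = 11)
    ev <- epoch_average(rec)
    # the dominant component peaks near its programmed latency
    gfp <- global_field_power(ev)
    pk <- gfp$time[gfp$time > 0][which.max(gfp$gfp[gfp$time > 0])]
    expect_lt(abs(pk - 0.1), 0.03)
  }
  # quadrupling the trial count halves the pre-stimulus residual noise
  # (ratio form: the baseline correction filters both runs identically)
  resid <- vapply(c(120, 480), function(n_tr) {
    rec <- simulate_evoked(lay, n_tr, "visual", config = cfg, seed = 14)
    ev <- epoch_average(rec)
    sd(as.vector(ev$data[, ev$times < 0]))
  }, numeric(1))
  expect_equal(resid[2] / resid[1], 0.5, tolerance = 0.25)
})

test_that("zero-amplitude evoked components average towards zero", {
  lay <- make_head_layout(1, 0, seed = 9)
  comps <- tibble::tibble(latency = 0.1, amplitude = 0, center = "occipital")
  rec <- simulate_evoked(lay, 100, "visual", components = comps, seed = 12)
  ev <- epoch_average(rec)
  raw_sd <- sd(as.vector(rec$data[, 1:512]))
  expect_lt(max(abs(ev$data)), 5 * raw_sd / sqrt(100))
})

test_that("late evoked components warn but still simulate", {
  lay <- make_head_layout(1, 0, seed = 9)
  comps <- tibble::tibble(latency = 0.35, amplitude = 5, center = "occipital")
  expect_warning(
    rec <- simulate_evoked(lay, 10, "visual", components = comps, seed = 13),
    "300 ms"
  )
  expect_equal(sum(rec$events$kind == "stimulus"), 10)
})

test_that("hypnogram corruption behaves at the flip-rate extremes", {
  h <- make_hypnogram(200, seed = 1)
  same <- corrupt_hypnogram(h, 0, seed = 2)
  expect_identical(same$stage, h$stage)
  expect_equal(cohens_kappa(h, same)$kappa, 1)
  flipped <- corrupt_hypnogram(h, 1, seed = 3)
  expect_true(all(flipped$stage != h$stage))
  expect_equal(cohens_kappa(h, flipped)$po, 0)
  expect_error(corrupt_hypnogram(h, 1.2), "flip_rate")
})

test_that("kappa after partial corruption matches its Monte-Carlo expectation", {
  h <- make_hypnogram(1000, seed = 4)
  ks <- vapply(1:200, function(i) {
    cohens_kappa(h, corrupt_hypnogram(h, 0.1, seed = 1000 + i))$kappa
  }, numeric(1))
  one <- cohens_kappa(h, corrupt_hypnogram(h, 0.1, seed = 5))$kappa
  expect_lt(abs(one - mean(ks)), 4 * sd(ks))
  # flipping 10% of epochs keeps roughly 90% observed agreement
  expect_gt(mean(ks), 0.75)
  expect_lt(mean(ks), 0.95)
})

test_that("hypnograms validate stage labels and record epoch length", {
  expect_error(hypnogram(c("W", "Q")), "unknown stage")
  h <- make_hypnogram(100, epoch_length = 30, seed = 1)
  expect_equal(nrow(h), 100)
  expect_equal(attr(h, "epoch_length"), 30)
  expect_true(all(h$stage %in% sleep_stages()))
  expect_identical(make_hypnogram(100, seed = 1)$stage, h$stage)
})
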