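test_that("noiseless trial averaging reproduces the template exactly", {
  lay <- tiny_layout()
  fs <- 256
  rec <- eeg_recording(matrix(0, nrow(lay), fs * 30), fs, lay)
  comps <- tibble::tibble(latency = 0.1, amplitude = 5, center = "occipital")
  cfg <- simulation_config(
    aperiodic = list(exponent = 1.5, offset = -Inf),
    sensor_noise = c(subscalp = 0, scalp = 0, intracranial = 0),
    source_heterogeneity = 0
  )
  recn <- simulate_evoked(lay, 20, "visual", components = comps, isi = 1,
                          config = cfg, seed = 1)
  ev <- epoch_average(recn)
  one <- recn$data[, (1 * fs + 1 + round(-0.1 * fs)):(1 * fs + 1 + round(0.3 * fs))]
  expect_equal(ev$data, one - rowMeans(one[, 1:26]), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(ev$n_trials, 20)
})

test_that("trials at the recording edge are dropped, and all-dropped errors", {
  lay <- tiny_layout()
  rec <- white_noise_recording(lay, duration = 10)
  ev <- epoch_average(rec, onsets = c(0.05, 5, 9.95))
  expect_equal(ev$n_trials, 1)
  expect_equal(ev$n_dropped, 2)
  expect_error(epoch_average(rec, onsets = c(0.01, 9.99)), "no usable trials")
  expect_error(epoch_average(rec, onsets = numeric(0)), "at least one")
})

test_that("global field power is the spatial SD across channels", {
  lay <- tiny_layout()
  t <- seq(0, 0.3, by = 1 / 256)
  v <- sin(2 * pi * 5 * t)
  ev <- structure(
    list(data = rbind(v, -v), times = t, n_trials = 1, channels = c("a", "b")),
    class = "evoked_average"
  )
  gfp <- global_field_power(ev)
  expect_equal(gfp$gfp, abs(v) * sqrt(2), tolerance = 1e-12)
  ev$data <- rbind(v, v, v)
  expect_equal(global_field_power(ev)$gfp, rep(0, length(t)), tolerance = 1e-12)
  # random matrix against the direct formula
  M <- withr::with_seed(3, matrix(rnorm(5 * 77), 5))
  ev$data <- M
  ev$times <- seq_len(77)
  expect_equal(global_field_power(ev)$gfp, apply(M, 2, sd), tolerance = 1e-12)
  ev$data <- M[1, , drop = FALSE]
  expect_error(global_field_power(ev), "2 channels")
})

test_that("peak alignment removes annotation jitter; disabling it smears the average", {
  lay <- tiny_layout()
  fs <- 256
  rec0 <- eeg_recording(matrix(0, nrow(lay), fs * 40), fs, lay)
  true_onsets <- seq(1, 30, by = 1)
  jit <- withr::with_seed(21, true_onsets + runif(30, -0.02, 0.02))
  dip <- 70 * unit(c(20, 20, 60))
  rec <- simulate_spikes(rec0, 30, dip, amplitude = 40,
                         jitter = 0, onsets = true_onsets)
  dv <- t(eegconcord:::sensing_points(lay)) - dip
  dd <- sqrt(colSums(dv^2))
  w <- abs(40 * eegconcord:::spatial_gain(dd) *
             colSums(sweep(dv, 2, dd, "/") * unit(dip)))
  align_ch <- lay$contact[which.max(w)]
  aligned <- spike_peak_average(rec, jit, alignment_channel = align_ch)
  smeared <- spike_peak_average(rec, jit, alignment_channel = align_ch,
                                align = FALSE)
  pk_a <- max(abs(aligned$peak_amplitudes$amplitude))
  pk_s <- max(abs(smeared$peak_amplitudes$amplitude))
  # discrete sampling of the template caps the attainable peak
  single <- max(w) * max(eegconcord:::spike_template(fs))
  expect_equal(pk_a, single, tolerance = 1e-6)
  expect_lt(pk_s, pk_a)
})

test_that("dipolar spike averages show opposite polarities across the dipole", {
  lay <- full_layout(seed = 31)
  rec0 <- eeg_recording(matrix(0, nrow(lay), 256 * 40), 256, lay)
  dip <- 60 * unit(c(60, 10, 30))
  rec <- simulate_spikes(rec0, 30, dip, amplitude = 40, jitter = 0, seed = 4)
  sense <- eegconcord:::sensing_points(lay)
  dv <- t(sense) - dip
  w <- eegconcord:::spatial_gain(sqrt(colSums(dv^2)), floor = 0) *
    colSums(sweep(dv, 2, sqrt(colSums(dv^2)), "/") * unit(dip))
  sa <- spike_peak_average(rec, alignment_channel = lay$contact[which.max(abs(w))])
  amps <- setNames(sa$peak_amplitudes$amplitude, sa$peak_amplitudes$contact)
  expect_gt(max(amps), 0)
  expect_lt(min(amps), 0)
  expect_gt(cor(sign(amps), sign(w)), 0.9)
})

test_that("ictal triplet selection matches exhaustive search on random layouts", {
  for (s in 1:100) {
    lay <- make_head_layout(sample(1:4, 1), sample(2:6, 1), seed = s)
    soz <- withr::with_seed(s, runif(1, 40, 70) * unit(rnorm(3)))
    tri <- select_ictal_triplet(lay, soz)
    P <- as.matrix(lay[, c("x", "y", "z")])
    d_soz <- sqrt(colSums((t(P) - soz)^2))
    sub_idx <- which(lay$modality == "subscalp")
    best_sub <- sub_idx[which.min(d_soz[sub_idx])]
    expect_identical(tri$contact[tri$role == "subscalp"], lay$contact[best_sub])
    anchor <- P[best_sub, ]
    d_anchor <- sqrt(colSums((t(P) - anchor)^2))
    for (m in c("scalp", "intracranial")) {
      idx <- which(lay$modality == m)
      expect_identical(tri$contact[tri$role == m],
                       lay$contact[idx[which.min(d_anchor[idx])]])
    }
  }
})

test_that("triplet selection is restricted to the implanted contacts and needs all modalities", {
  lay <- make_head_layout(1, 2, seed = 9)
  tri <- select_ictal_triplet(lay, c(0, 0, 60))
  expect_true(tri$contact[tri$role == "subscalp"] %in%
                lay$contact[lay$modality == "subscalp"])
  expect_error(select_ictal_triplet(lay[lay$modality != "intracranial", ],
                                    c(0, 0, 60)), "intracranial")
  # SOZ coincident with a subscalp contact selects that contact
  pos <- as.numeric(lay[lay$contact == "S03", c("x", "y", "z")])
  expect_identical(select_ictal_triplet(lay, pos)$contact[1], "S03")
})

test_that("ictal coherence is 1 for copied channels and near the floor for noise", {
  lay <- make_head_layout(1, 2, seed = 10)
  fs <- 256
  n <- fs * 60
  data <- withr::with_seed(11, matrix(rnorm(nrow(lay) * n), ncol = n))
  rec <- eeg_recording(data, fs, lay)
  tri <- select_ictal_triplet(lay, c(0, 0, 60))
  # copy the SOZ reference into the triplet's scalp member
  rec$data[tri$contact[tri$role == "scalp"], ] <- rec$data["IC1", ]
  prof <- ictal_coherence_profile(rec, list(onset = 2, duration = 50), tri,
                                  soz_channel = "IC1", pz_channel = "IC2")
  p <- prof$profile
  expect_equal(p$coherence[p$modality == "scalp" & p$zone == "soz"], 1,
               tolerance = 1e-9)
  noise_vals <- p$coherence[!(p$modality == "scalp" & p$zone == "soz")]
  expect_true(all(noise_vals < 0.1))
  expect_false(prof$short_segment)
  expect_equal(prof$window_used, 5)
})

test_that("short seizures fall back to 2-s windows and are flagged", {
  lay <- make_head_layout(1, 2, seed = 10)
  rec <- white_noise_recording(lay, duration = 30, seed = 12)
  tri <- select_ictal_triplet(lay, c(0, 0, 60))
  prof <- ictal_coherence_profile(rec, list(onset = 2, duration = 15), tri,
                                  soz_channel = "IC1", pz_channel = "IC2")
  expect_true(prof$short_segment)
  expect_equal(prof$window_used, 2)
  expect_true(all(prof$profile$coherence >= 0 & prof$profile$coherence <= 1))
})

test_that("time-frequency coherence masks are confined to the seizure", {
  lay <- make_head_layout(1, 2, seed = 13)
  fs <- 256
  quiet <- white_noise_recording(lay, duration = 90, seed = 14)
  soz <- as.numeric(lay[lay$contact == "IC1", c("x", "y", "z")])
  pz <- as.numeric(lay[lay$contact == "IC2", c("x", "y", "z")])
  rec <- simulate_seizure(quiet, soz, pz, onset = 20, duration = 60,
                          amplitude = 40, propagation_delay = 8, seed = 15)
  tri <- select_ictal_triplet(rec$layout, soz)
  prof <- ictal_coherence_profile(rec, list(onset = 15, duration = 70), tri,
                                  soz_channel = "IC1", pz_channel = "IC2",
                                  tf = TRUE)
  tfc <- prof$tf[["subscalp soz"]]
  in_seizure <- tfc$times >= 5 & tfc$times <= 65  # relative to segment start
  low <- tfc$freqs <= 10
  expect_gt(mean(tfc$mask[low, in_seizure]), mean(tfc$mask[low, !in_seizure]))
})

test_that("ictal power-increase maps localise superficial seizures and reject overlap", {
  lay <- make_head_layout(4, 2, seed = 16)
  quiet <- white_noise_recording(lay, duration = 70, sd = 2, seed = 17)
  soz <- 75 * unit(c(55, 20, 35))
  pz <- 70 * unit(c(35, 45, 35))
  rec <- simulate_seizure(quiet, soz, pz, onset = 12, duration = 45,
                          amplitude = 25, seed = 18)
  pm <- ictal_power_increase_map(rec, list(onset = 12, duration = 45),
                                 baseline = c(1, 11))
  expect_error(
    ictal_power_increase_map(rec, list(onset = 12, duration = 45),
                             baseline = c(5, 15)),
    "overlap"
  )
  # the hottest subscalp contact is the one closest to the SOZ
  sub <- rec$layout[rec$layout$modality == "subscalp", ]
  d <- sqrt(colSums((t(eegconcord:::sensing_points(sub)) - soz)^2))
  hot <- pm$subscalp$contact[which.max(pm$subscalp$value)]
  expect_lt(d[match(hot, sub$contact)], sort(d)[5])
  # no-seizure recording maps to ~0 everywhere
  pm0 <- ictal_power_increase_map(quiet, list(onset = 12, duration = 45),
                                  baseline = c(1, 11))
  expect_lt(max(abs(pm0$values$value)), 1.5)
})

test_that("deep seizures produce no extracranial power increase while superficial ones do", {
  lay <- make_head_layout(4, 2, seed = 19)
  quiet <- white_noise_recording(lay, duration = 70, sd = 2, seed = 20)
  deep <- simulate_seizure(quiet, c(0, 15, 10), c(0, -15, 10), onset = 12,
                           duration = 45, amplitude = 30, lambda = 10,
                           seed = 21)
  pm_deep <- ictal_power_increase_map(deep, list(onset = 12, duration = 45),
                                      baseline = c(1, 11))
  superficial <- simulate_seizure(quiet, 75 * unit(c(55, 20, 35)),
                                  70 * unit(c(35, 45, 35)), onset = 12,
                                  duration = 45, amplitude = 30, seed = 21)
  pm_sup <- ictal_power_increase_map(superficial, list(onset = 12, duration = 45),
                                     baseline = c(1, 11))
  expect_lt(max(pm_deep$values$value), 1.5)
  expect_gt(max(pm_sup$values$value), 3)
})
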