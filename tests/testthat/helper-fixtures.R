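# shared fixtures: tiny layouts, noise generators, and mini-recordings
# built in code at test time

tiny_layout <- function(seed = 1) {
  make_head_layout(n_tridents = 1, n_intracranial = 2, seed = seed)
}

full_layout <- function(seed = 1) {
  make_head_layout(n_tridents = 4, n_intracranial = 6, seed = seed)
}

# a minimal three-modality layout with hand-placed contacts for geometry
# tests (distances known exactly)
toy_layout <- function() {
  out <- tibble::tibble(
    contact = c("SA", "SB", "CA", "CB", "CC", "IA"),
    x = c(0, 30, 0, 40, -40, 0),
    y = c(0, 0, 0, 0, 0, 10),
    z = c(85, 79.5434, 92, 82.8578, 82.8578, 50),
    modality = c("subscalp", "subscalp", "scalp", "scalp", "scalp", "intracranial")
  )
  class(out) <- c("head_layout", class(out))
  attr(out, "radius") <- 92
  attr(out, "scalp_thickness") <- 7
  out
}

white_noise_recording <- function(layout, duration = 10, fs = 256, sd = 1,
                                  seed = 1) {
  withr::with_seed(seed, {
    data <- matrix(rnorm(nrow(layout) * duration * fs, sd = sd),
                   nrow = nrow(layout))
    eeg_recording(data, fs, layout)
  })
}

# exact power-law noise fixture used by the spectral tests
powerlaw_fixture <- function(n, fs, exponent = 1.5, offset = log10(3), seed = 1) {
  withr::with_seed(seed, eegconcord:::powerlaw_noise(n, fs, exponent, offset))
}

expect_tibble_cols <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}
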