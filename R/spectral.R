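# Multitaper spectral estimation: power spectral density, magnitude-squared
# coherence, aperiodic (1/f) fitting, band peak power, and spectrograms.
#
# All estimators share one contract: 5-second sliding windows with 50%
# overlap, DPSS tapers at time-bandwidth 4 (7 tapers), spectra pooled over
# tapers x windows. One-sided densities are normalised so that the integral
# over frequency equals the signal variance (Parseval contract).

.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computes the first `k` DPSS tapers of length `n` at time-bandwidth
#' product `nw` from the symmetric tridiagonal matrix that commutes with the
#' spectral concentration operator. Tapers are unit-energy columns ordered by
#' decreasing concentration and cached per `(n, nw, k)`.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (default 4).
#' @param k Number of tapers (default `2 * nw - 1`).
#' @return An `n` x `k` matrix whose columns are the tapers.
#' @export
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  n <- as.integer(n)
  k <- as.integer(k)
  stopifnot(n >= 2, k >= 1, k < n, nw > 0)
  key <- paste(n, nw, k, sep = "_")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  i <- seq_len(n) - 1
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  A[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  ev <- eigen(A, symmetric = TRUE)
  v <- ev$vectors[, seq_len(k), drop = FALSE]
  v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
  sgn <- ifelse(colSums(v) < 0, -1, 1)
  v <- sweep(v, 2, sgn, "*")
  .dpss_cache[[key]] <- v
  v
}

# Tapered sliding-window Fourier transform: the shared kernel behind PSD,
# coherence and spectrogram estimation. Returns positive-frequency
# coefficients as a (n_freq) x (n_windows * n_tapers) complex matrix with
# columns ordered window-fastest within taper.
mt_transform <- function(x, fs, window = 5, overlap = 0.5,
                         time_bandwidth = 4, n_tapers = NULL) {
  x <- as.numeric(x)
  w_samp <- as.integer(round(window * fs))
  if (w_samp < 16) abort("analysis window is too short for taper estimation")
  if (length(x) < w_samp) abort("signal length must cover at least one window")
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1)")
  k <- n_tapers %||% as.integer(2 * time_bandwidth - 1)
  step <- max(1L, as.integer(round(w_samp * (1 - overlap))))
  starts <- seq.int(1L, length(x) - w_samp + 1L, by = step)
  n_win <- length(starts)
  tap <- dpss_tapers(w_samp, time_bandwidth, k)
  idx <- rep(starts, each = w_samp) + rep.int(seq_len(w_samp) - 1L, n_win)
  M <- matrix(x[idx], nrow = w_samp)
  M <- sweep(M, 2, colMeans(M), "-")
  big <- M[, rep(seq_len(n_win), times = k), drop = FALSE] *
    tap[, rep(seq_len(k), each = n_win), drop = FALSE]
  X <- stats::mvfft(big)
  nf <- w_samp %/% 2L + 1L
  list(
    X = X[seq_len(nf), , drop = FALSE],
    freqs = (seq_len(nf) - 1) * fs / w_samp,
    fs = fs, w_samp = w_samp, starts = starts,
    n_windows = n_win, n_tapers = k,
    window = window, overlap = overlap,
    time_bandwidth = time_bandwidth
  )
}

# one-sided density scaling: double everything except DC (and Nyquist when
# the window length is even)
one_sided_factor <- function(w_samp) {
  nf <- w_samp %/% 2L + 1L
  f <- rep(2, nf)
  f[1] <- 1
  if (w_samp %% 2L == 0L) f[nf] <- 1
  f
}

psd_from_transform <- function(tr) {
  S <- rowMeans(Mod(tr$X)^2) / tr$fs * one_sided_factor(tr$w_samp)
  S
}

new_mt_spectrum <- function(freqs, power, tr, degenerate = FALSE) {
  out <- tibble::tibble(
    frequency = freqs,
    power = power,
    power_db = 10 * log10(power)
  )
  class(out) <- c("mt_spectrum", class(out))
  attr(out, "window") <- tr$window
  attr(out, "overlap") <- tr$overlap
  attr(out, "n_windows") <- tr$n_windows
  attr(out, "n_tapers") <- tr$n_tapers
  attr(out, "time_bandwidth") <- tr$time_bandwidth
  attr(out, "fs") <- tr$fs
  attr(out, "degenerate") <- degenerate
  out
}

#' Multitaper power spectral density
#'
#' DPSS-tapered spectra averaged over tapers and sliding windows. The
#' one-sided density (uV^2/Hz) is normalised so its integral over frequency
#' equals the signal variance; `power_db` is `10*log10` of the density. The
#' frequency grid spacing is `1/window` Hz.
#'
#' @param signal Numeric vector of samples (uV).
#' @param fs Sampling rate in Hz.
#' @param window Window length in seconds (default 5).
#' @param overlap Fractional overlap between consecutive windows (default 0.5).
#' @param time_bandwidth DPSS time-bandwidth product (default 4, 7 tapers).
#' @param n_tapers Number of tapers; default `2 * time_bandwidth - 1`.
#' @return A tibble of class `mt_spectrum` with columns `frequency`, `power`,
#'   `power_db` and estimation metadata in attributes. An all-constant input
#'   is flagged via the `degenerate` attribute (density `-Inf` dB off DC)
#'   rather than an error.
#' @export
#' @examples
#' x <- rnorm(2560)
#' ps <- multitaper_psd(x, fs = 256)
#' sum(ps$power) * (ps$frequency[2] - ps$frequency[1]) # ~ var(x)
multitaper_psd <- function(signal, fs, window = 5, overlap = 0.5,
                           time_bandwidth = 4, n_tapers = NULL) {
  tr <- mt_transform(signal, fs, window, overlap, time_bandwidth, n_tapers)
  S <- psd_from_transform(tr)
  degenerate <- var(as.numeric(signal)) == 0
  new_mt_spectrum(tr$freqs, S, tr, degenerate = degenerate)
}

#' Magnitude-squared coherence between two signals
#'
#' Cross- and auto-spectra are pooled over tapers and windows (Welch-style),
#' then combined as `|S_ab|^2 / (S_aa * S_bb)` and clipped to `[0, 1]`. At
#' least 8 windows are required; the expected bias floor for independent
#' signals, `1 / (n_windows * n_tapers)`, is recorded in the `bias_floor`
#' attribute.
#'
#' @inheritParams multitaper_psd
#' @param sig_a,sig_b Numeric vectors of equal length.
#' @return A tibble of class `coherence_spectrum` with columns `frequency`
#'   and `coherence`.
#' @export
coherence <- function(sig_a, sig_b, fs, window = 5, overlap = 0.5,
                      time_bandwidth = 4, n_tapers = NULL) {
  if (length(sig_a) != length(sig_b)) {
    abort("`sig_a` and `sig_b` must have the same length.")
  }
  tra <- mt_transform(sig_a, fs, window, overlap, time_bandwidth, n_tapers)
  trb <- mt_transform(sig_b, fs, window, overlap, time_bandwidth, n_tapers)
  coherence_from_transforms(tra, trb)
}

coherence_from_transforms <- function(tra, trb) {
  if (tra$n_windows < 8) {
    abort(sprintf(
      "coherence requires at least 8 windows; got %d. Use a longer segment or shorter window.",
      tra$n_windows
    ))
  }
  Saa <- rowMeans(Mod(tra$X)^2)
  Sbb <- rowMeans(Mod(trb$X)^2)
  Sab <- rowMeans(tra$X * Conj(trb$X))
  coh <- Mod(Sab)^2 / (Saa * Sbb)
  coh[!is.finite(coh)] <- 0
  coh <- pmin(pmax(coh, 0), 1)
  out <- tibble::tibble(frequency = tra$freqs, coherence = coh)
  class(out) <- c("coherence_spectrum", class(out))
  attr(out, "n_windows") <- tra$n_windows
  attr(out, "n_tapers") <- tra$n_tapers
  attr(out, "window") <- tra$window
  attr(out, "overlap") <- tra$overlap
  attr(out, "fs") <- tra$fs
  attr(out, "bias_floor") <- 1 / (tra$n_windows * tra$n_tapers)
  out
}

#' Fit the aperiodic (1/f) component of a spectrum
#'
#' Least-squares line through `(log10 f, log10 power)` over `fit_range`,
#' excluding any oscillation bands given in `exclude_bands`. The exponent is
#' minus the slope, so 1/f-like spectra give positive exponents.
#'
#' @param spectrum An [multitaper_psd()] result.
#' @param fit_range Length-2 numeric, Hz (default `c(1, 45)`).
#' @param exclude_bands List of `c(f_lo, f_hi)` bands removed before fitting
#'   (e.g. the oscillation band under analysis).
#' @return An object of class `aperiodic_fit` with elements `offset`
#'   (log10 power at 1 Hz), `exponent`, `fit_range`, `n_bins`, `residual_sd`.
#' @export
fit_aperiodic <- function(spectrum, fit_range = c(1, 45), exclude_bands = list()) {
  stopifnot(inherits(spectrum, "mt_spectrum") || all(c("frequency", "power_db") %in% names(spectrum)))
  f <- spectrum$frequency
  y <- spectrum$power_db / 10
  keep <- f >= fit_range[1] & f <= fit_range[2] & f > 0 & is.finite(y)
  if (length(exclude_bands) && !is.list(exclude_bands)) exclude_bands <- list(exclude_bands)
  for (b in exclude_bands) {
    keep <- keep & !(f >= b[1] & f <= b[2])
  }
  if (sum(keep) < 10) {
    abort("fewer than 10 frequency bins remain in the aperiodic fit range after exclusions")
  }
  lx <- log10(f[keep])
  ly <- y[keep]
  fit <- stats::lm.fit(cbind(1, lx), ly)
  structure(
    list(
      offset = unname(fit$coefficients[1]),
      exponent = -unname(fit$coefficients[2]),
      fit_range = fit_range,
      exclude_bands = exclude_bands,
      n_bins = sum(keep),
      residual_sd = sd(fit$residuals)
    ),
    class = "aperiodic_fit"
  )
}

#' Evaluate an aperiodic fit in dB
#'
#' @param fit An [fit_aperiodic()] object.
#' @param frequency Frequencies in Hz (must be > 0).
#' @return Fitted power in dB at each frequency.
#' @export
fitted_db <- function(fit, frequency) {
  stopifnot(inherits(fit, "aperiodic_fit"))
  10 * (fit$offset - fit$exponent * log10(frequency))
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf(
    "Aperiodic 1/f fit: exponent %.3f, offset %.3f (log10 uV^2/Hz at 1 Hz), %d bins over %g-%g Hz\n",
    x$exponent, x$offset, x$n_bins, x$fit_range[1], x$fit_range[2]
  ))
  invisible(x)
}

#' Band peak power above the aperiodic fit
#'
#' The oscillatory peak is the maximal departure of the spectrum from its
#' 1/f fit within the band: `max(power_db - fitted_db)`, reported together
#' with the frequency at which it occurs. The value can be negative when no
#' oscillation is present.
#'
#' @param spectrum An [multitaper_psd()] result.
#' @param fit An [fit_aperiodic()] object for the same spectrum.
#' @param band `c(f_lo, f_hi)` in Hz.
#' @param band_name Optional label stored in the output.
#' @return One-row tibble of class `band_peak` with columns `band`, `f_lo`,
#'   `f_hi`, `peak_frequency`, `peak_power_db`. If the band extends beyond
#'   the fit range the fit is extrapolated and the `extrapolated` attribute
#'   set.
#' @export
band_peak_power <- function(spectrum, fit, band, band_name = NULL) {
  check_band(band)
  f <- spectrum$frequency
  in_band <- f >= band[1] & f <= band[2] & f > 0
  if (!any(in_band)) abort("no frequency grid points fall inside `band`")
  dep <- spectrum$power_db[in_band] - fitted_db(fit, f[in_band])
  i <- which.max(dep)
  label <- band_name %||% sprintf("%g-%g Hz", band[1], band[2])
  lo <- band[1]
  hi <- band[2]
  out <- tibble::tibble(
    band = label,
    f_lo = lo, f_hi = hi,
    peak_frequency = f[in_band][i],
    peak_power_db = dep[i]
  )
  class(out) <- c("band_peak", class(out))
  attr(out, "extrapolated") <- band[1] < fit$fit_range[1] || band[2] > fit$fit_range[2]
  out
}

#' Peak coherence within a band
#'
#' @param coh A [coherence()] result.
#' @param band `c(f_lo, f_hi)` in Hz.
#' @return Maximum coherence over grid points in the band (scalar in `[0,1]`).
#' @export
band_peak_coherence <- function(coh, band) {
  check_band(band)
  sel <- coh$frequency >= band[1] & coh$frequency <= band[2]
  if (!any(sel)) abort("no frequency grid points fall inside `band`")
  max(coh$coherence[sel])
}

#' Mean coherence over a frequency range
#'
#' Arithmetic mean of the coherence over grid points in `range`; the default
#' 0.5-30 Hz is the broadband range used for ictal comparisons.
#'
#' @param coh A [coherence()] result.
#' @param range `c(f_lo, f_hi)` in Hz (default `c(0.5, 30)`).
#' @return Scalar mean coherence in `[0, 1]`.
#' @export
band_mean_coherence <- function(coh, range = c(0.5, 30)) {
  check_band(range)
  sel <- coh$frequency >= range[1] & coh$frequency <= range[2]
  if (!any(sel)) abort("no frequency grid points fall inside `range`")
  mean(coh$coherence[sel])
}

#' Multitaper spectrogram
#'
#' Per-window multitaper PSD on the sliding-window grid. With
#' `flatten = TRUE` the session-level aperiodic fit (estimated on the
#' time-averaged spectrum) is subtracted, in dB, from every time slice, so a
#' pure power-law input flattens to ~0 dB everywhere.
#'
#' @inheritParams multitaper_psd
#' @param flatten Remove the session 1/f fit (default `FALSE`).
#' @param fit_range Frequency range for the session fit when flattening.
#' @return Long tibble of class `eeg_spectrogram` with columns `time`
#'   (window centres, s), `frequency` (Hz) and `power_db`.
#' @export
spectrogram <- function(signal, fs, window = 5, overlap = 0.5,
                        time_bandwidth = 4, flatten = FALSE,
                        fit_range = NULL) {
  tr <- mt_transform(signal, fs, window, overlap, time_bandwidth)
  P <- Mod(tr$X)^2
  dim(P) <- c(nrow(tr$X), tr$n_windows, tr$n_tapers)
  P <- rowMeans(P, dims = 2) / tr$fs * one_sided_factor(tr$w_samp)
  times <- (tr$starts - 1 + tr$w_samp / 2) / fs
  power_db <- 10 * log10(P)
  fit <- NULL
  if (flatten) {
    session <- new_mt_spectrum(tr$freqs, rowMeans(P), tr)
    fit_range <- fit_range %||% c(1, min(45, max(tr$freqs)))
    fit <- fit_aperiodic(session, fit_range = fit_range)
    corr <- rep(NA_real_, length(tr$freqs))
    corr[tr$freqs > 0] <- fitted_db(fit, tr$freqs[tr$freqs > 0])
    power_db <- sweep(power_db, 1, corr, "-")
  }
  out <- tibble::tibble(
    time = rep(times, each = length(tr$freqs)),
    frequency = rep(tr$freqs, times = length(times)),
    power_db = as.vector(power_db)
  )
  class(out) <- c("eeg_spectrogram", class(out))
  attr(out, "flattened") <- flatten
  attr(out, "fit") <- fit
  attr(out, "window") <- window
  attr(out, "overlap") <- overlap
  attr(out, "time_step") <- window * (1 - overlap)
  out
}

# time-resolved coherence on the shared window grid, pooling tapers only:
# one MSC estimate per window, used for ictal time-frequency contours
tf_coherence <- function(tra, trb) {
  nf <- nrow(tra$X)
  nw <- tra$n_windows
  k <- tra$n_tapers
  Xa <- array(tra$X, c(nf, nw, k))
  Xb <- array(trb$X, c(nf, nw, k))
  Sab <- rowSums(Xa * Conj(Xb), dims = 2)
  Saa <- rowSums(Mod(Xa)^2, dims = 2)
  Sbb <- rowSums(Mod(Xb)^2, dims = 2)
  C <- Mod(Sab)^2 / (Saa * Sbb)
  C[!is.finite(C)] <- 0
  times <- (tra$starts - 1 + tra$w_samp / 2) / tra$fs
  list(times = times, freqs = tra$freqs, coherence = pmin(pmax(C, 0), 1))
}
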