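# internal helpers shared across modules

# derive a reproducible 32-bit child seed from a parent seed and a string key,
# so pipeline stages can be re-run in isolation
child_seed <- function(seed, key) {
  h <- rlang::hash(list(as.integer(seed), as.character(key)))
  strtoi(substr(h, 1, 7), base = 16L)
}

# run `expr` under a temporary RNG seed when `seed` is given, leaving the
# caller's RNG stream untouched; with seed = NULL use the current stream
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) return(v)
  v / n
}

#' Canonical EEG frequency bands
#'
#' Conventional clinical band edges used throughout the package: delta
#' 0.5-4 Hz, theta 4-8 Hz, alpha 8-12 Hz, sigma 11-16 Hz, beta 16-30 Hz.
#'
#' @return Named list of length-2 numeric vectors `c(f_lo, f_hi)` in Hz.
#' @export
#' @examples
#' eeg_bands()$alpha
eeg_bands <- function() {
  list(
    delta = c(0.5, 4),
    theta = c(4, 8),
    alpha = c(8, 12),
    sigma = c(11, 16),
    beta  = c(16, 30)
  )
}

check_band <- function(band) {
  if (!is.numeric(band) || length(band) != 2 || !all(is.finite(band)) ||
      band[1] >= band[2]) {
    abort("`band` must be a numeric vector c(f_lo, f_hi) with f_lo < f_hi.")
  }
  invisible(band)
}
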