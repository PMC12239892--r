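# Statistical acceptance machinery: intraclass correlation, Bland-Altman
# bias, margin-based noninferiority decisions, Cohen's kappa and the exact
# paired sign test.

resolve_pair_cols <- function(data, subscalp, scalp) {
  sub_q <- rlang::enquo(subscalp)
  sca_q <- rlang::enquo(scalp)
  sub <- if (rlang::quo_is_null(sub_q)) data[["value_subscalp"]] else rlang::eval_tidy(sub_q, data)
  sca <- if (rlang::quo_is_null(sca_q)) data[["value_scalp"]] else rlang::eval_tidy(sca_q, data)
  if (is.null(sub) || is.null(sca)) {
    abort("supply paired value columns (defaults `value_subscalp`, `value_scalp`)")
  }
  ok <- is.finite(sub) & is.finite(sca)
  list(sub = sub[ok], sca = sca[ok])
}

#' Construct a table of paired measurements
#'
#' One row per comparison unit (e.g. participant x electrode pair), holding
#' the value measured by each modality.
#'
#' @param unit Unit identifiers.
#' @param value_subscalp,value_scalp Paired numeric measurements.
#' @param units Measurement units label (e.g. `"dB"`, `"uV"`, `"coherence"`).
#' @return A tibble of class `paired_measurements`.
#' @export
paired_measurements <- function(unit, value_subscalp, value_scalp, units = "") {
  stopifnot(length(value_subscalp) == length(value_scalp))
  if (length(value_subscalp) < 3) abort("paired measurements require n >= 3 rows")
  out <- tibble::tibble(
    unit = unit,
    value_subscalp = value_subscalp,
    value_scalp = value_scalp
  )
  class(out) <- c("paired_measurements", class(out))
  attr(out, "units") <- units
  out
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measures: the variant
#' appropriate for method agreement because it is sensitive to constant
#' offsets between methods. Computed from the units x methods ANOVA
#' decomposition, with the standard F-distribution confidence interval.
#'
#' @param data Data frame with one row per unit.
#' @param subscalp,scalp Columns holding the two methods' values (defaults
#'   `value_subscalp` / `value_scalp`). Any two paired methods may be given.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `icc_fit`: `icc`, `ci_lower`, `ci_upper`, mean
#'   squares, `n`, and a `flagged` marker when total variance is zero.
#' @export
#' @examples
#' d <- tibble::tibble(value_subscalp = rnorm(10), value_scalp = rnorm(10))
#' icc(d)
icc <- function(data, subscalp = NULL, scalp = NULL, conf_level = 0.95) {
  v <- resolve_pair_cols(data, {{ subscalp }}, {{ scalp }})
  M <- cbind(v$sub, v$sca)
  n <- nrow(M)
  k <- ncol(M)
  if (n < 3) abort("ICC requires at least 3 units")
  icc_from_matrix(M, conf_level)
}

# core two-way ANOVA ICC; M is units x methods
icc_from_matrix <- function(M, conf_level = 0.95) {
  n <- nrow(M)
  k <- ncol(M)
  grand <- mean(M)
  row_m <- rowMeans(M)
  col_m <- colMeans(M)
  ss_total <- sum((M - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  flagged <- ss_total <= .Machine$double.eps * max(1, abs(grand))
  if (flagged) {
    est <- NA_real_
    lo <- NA_real_
    hi <- NA_real_
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    alpha <- 1 - conf_level
    # Shrout-Fleiss / McGraw-Wong interval with Satterthwaite df
    fj <- msc / mse
    if (!is.finite(fj) || mse == 0) {
      lo <- est
      hi <- est
    } else {
      a <- (k * est) / (n * (1 - est))
      b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
      v_num <- (a * msc + b * mse)^2
      v_den <- (a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1))
      v <- v_num / v_den
      f_l <- qf(1 - alpha / 2, n - 1, v)
      f_u <- qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - f_l * mse) /
        (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (f_u * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    }
  }
  structure(
    list(
      icc = est, ci_lower = lo, ci_upper = hi,
      msr = msr, msc = msc, mse = mse,
      n = n, k = k, conf_level = conf_level,
      variant = "ICC(2,1) two-way random, absolute agreement, single measures",
      flagged = flagged
    ),
    class = "icc_fit"
  )
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf(
    "ICC(2,1) = %.3f, %d%% CI [%.3f, %.3f], n = %d units x %d methods%s\n",
    x$icc, round(100 * x$conf_level), x$ci_lower, x$ci_upper, x$n, x$k,
    if (x$flagged) " [flagged: zero total variance]" else ""
  ))
  invisible(x)
}

#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(
    estimate = x$icc, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
    n = x$n, variant = "ICC(2,1)"
  )
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean paired difference (subscalp minus scalp) with a
#' t-distribution confidence interval; limits of agreement are
#' `bias +/- 1.96 * SD(diff)`.
#'
#' @inheritParams icc
#' @return Object of class `bland_altman`: `bias`, `ci_lower`, `ci_upper`,
#'   `sd_diff`, `loa_lower`, `loa_upper`, `n`.
#' @export
bland_altman <- function(data, subscalp = NULL, scalp = NULL, conf_level = 0.95) {
  v <- resolve_pair_cols(data, {{ subscalp }}, {{ scalp }})
  d <- v$sub - v$sca
  n <- length(d)
  if (n < 3) abort("Bland-Altman analysis requires n >= 3 pairs")
  bias <- mean(d)
  sdd <- sd(d)
  half <- qt(1 - (1 - conf_level) / 2, n - 1) * sdd / sqrt(n)
  structure(
    list(
      bias = bias, ci_lower = bias - half, ci_upper = bias + half,
      sd_diff = sdd,
      loa_lower = bias - 1.96 * sdd, loa_upper = bias + 1.96 * sdd,
      n = n, conf_level = conf_level
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman bias = %.3f, %d%% CI [%.3f, %.3f], LoA [%.3f, %.3f], n = %d\n",
    x$bias, round(100 * x$conf_level), x$ci_lower, x$ci_upper,
    x$loa_lower, x$loa_upper, x$n
  ))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    bias = x$bias, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
    sd_diff = x$sd_diff, loa_lower = x$loa_lower, loa_upper = x$loa_upper,
    n = x$n
  )
}

#' Combined agreement analysis (ICC + Bland-Altman)
#'
#' @inheritParams icc
#' @param units Measurement units label carried into reports.
#' @return Object of class `agreement_result` holding an `icc_fit` and a
#'   `bland_altman`.
#' @export
agreement <- function(data, subscalp = NULL, scalp = NULL, units = "",
                      conf_level = 0.95) {
  structure(
    list(
      icc = icc(data, {{ subscalp }}, {{ scalp }}, conf_level = conf_level),
      bland_altman = bland_altman(data, {{ subscalp }}, {{ scalp }}, conf_level = conf_level),
      units = units %||% attr(data, "units") %||% ""
    ),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  print(x$icc)
  print(x$bland_altman)
  invisible(x)
}

#' @export
tidy.agreement_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(units = x$units),
    dplyr::rename(tidy(x$icc), icc = "estimate", icc_lower = "ci_lower", icc_upper = "ci_upper"),
    dplyr::select(
      dplyr::rename(tidy(x$bland_altman), bias_lower = "ci_lower", bias_upper = "ci_upper"),
      -"n"
    )
  )
}

#' Margin-based noninferiority decision
#'
#' Noninferiority of the new modality is accepted when (1) the ICC point
#' estimate exceeds `icc_threshold` and (2) the bias does not fall below the
#' margin. Under the default `"ci"` rule the lower bound of the bias
#' confidence interval must be at or above the margin; `"point"` compares
#' the bias point estimate only.
#'
#' @param agreement An [agreement()] result.
#' @param margin Noninferiority margin in the measurement's units (negative,
#'   e.g. `-0.5` dB, `-1` uV, `-0.03` coherence points).
#' @param icc_threshold ICC threshold (default 0.75).
#' @param rule `"ci"` (default) or `"point"`.
#' @return One-row tibble of class `noninferiority_decision` with
#'   `icc_pass`, `bias_pass` and `overall = icc_pass & bias_pass`.
#' @export
noninferiority <- function(agreement, margin, icc_threshold = 0.75,
                           rule = c("ci", "point")) {
  stopifnot(inherits(agreement, "agreement_result"))
  rule <- match.arg(rule)
  if (!is.numeric(margin) || length(margin) != 1 || !is.finite(margin)) {
    abort("`margin` must be a single finite number in the measurement units")
  }
  icc_pass <- isTRUE(agreement$icc$icc > icc_threshold)
  bias_ref <- switch(rule,
    ci = agreement$bland_altman$ci_lower,
    point = agreement$bland_altman$bias
  )
  bias_pass <- isTRUE(bias_ref >= margin)
  out <- tibble::tibble(
    margin = margin,
    units = agreement$units,
    icc = agreement$icc$icc,
    icc_threshold = icc_threshold,
    bias = agreement$bland_altman$bias,
    bias_ci_lower = agreement$bland_altman$ci_lower,
    icc_pass = icc_pass,
    bias_pass = bias_pass,
    overall = icc_pass && bias_pass,
    rule_version = rule
  )
  class(out) <- c("noninferiority_decision", class(out))
  out
}

#' Cohen's kappa for sleep-stage (or any categorical) agreement
#'
#' Unweighted kappa over the confusion table of the two label sequences,
#' `(po - pe) / (1 - pe)`, reported against a noninferiority margin
#' (default 0.60, "substantial agreement").
#'
#' @param stages_a,stages_b Equal-length label vectors, factors, or
#'   hypnogram tibbles with a `stage` column.
#' @param margin Agreement margin (default 0.60).
#' @return Object of class `kappa_result`: `kappa`, `po` (observed
#'   agreement), `pe` (expected agreement), `n`, `pass`.
#' @export
cohens_kappa <- function(stages_a, stages_b, margin = 0.60) {
  a <- extract_stages(stages_a)
  b <- extract_stages(stages_b)
  if (length(a) != length(b)) {
    abort("stage sequences must have the same length (same epoch grid)")
  }
  lev <- sort(unique(c(a, b)))
  tab <- table(factor(a, lev), factor(b, lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kap <- if (pe >= 1) NA_real_ else (po - pe) / (1 - pe)
  structure(
    list(
      kappa = kap, po = po, pe = pe, n = n,
      margin = margin, pass = isTRUE(kap > margin),
      table = tab
    ),
    class = "kappa_result"
  )
}

extract_stages <- function(x) {
  if (is.data.frame(x)) {
    if (!"stage" %in% names(x)) abort("hypnogram input must have a `stage` column")
    x <- x$stage
  }
  as.character(x)
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf(
    "Cohen's kappa = %.3f (po = %.3f, pe = %.3f, n = %d epochs); margin %.2f: %s\n",
    x$kappa, x$po, x$pe, x$n, x$margin, if (x$pass) "pass" else "fail"
  ))
  invisible(x)
}

#' @export
tidy.kappa_result <- function(x, ...) {
  tibble::tibble(
    kappa = x$kappa, observed_agreement = x$po, expected_agreement = x$pe,
    n_epochs = x$n, margin = x$margin, pass = x$pass
  )
}

#' Exact paired sign test
#'
#' Two-sided exact binomial test on the signs of nonzero paired differences;
#' ties are dropped. The signed-rank (Wilcoxon) variant is available behind
#' the `variant` flag.
#'
#' @param values_a,values_b Equal-length numeric vectors of per-unit scores.
#' @param variant `"sign"` (default, exact binomial) or `"signed_rank"`.
#' @return Object of class `sign_test`: `p_value`, `n_nonzero`,
#'   `n_positive`, `all_ties` flag.
#' @export
paired_sign_test <- function(values_a, values_b, variant = c("sign", "signed_rank")) {
  variant <- match.arg(variant)
  if (length(values_a) != length(values_b)) abort("inputs must have equal length")
  if (length(values_a) < 5) abort("paired sign test requires n >= 5")
  d <- values_a - values_b
  nz <- d[d != 0]
  all_ties <- length(nz) == 0
  if (variant == "sign") {
    p <- if (all_ties) 1 else stats::binom.test(sum(nz > 0), length(nz), 0.5)$p.value
  } else {
    p <- if (all_ties) 1 else stats::wilcox.test(values_a, values_b, paired = TRUE, exact = FALSE)$p.value
  }
  structure(
    list(
      p_value = p, n_nonzero = length(nz), n_positive = sum(nz > 0),
      all_ties = all_ties, variant = variant
    ),
    class = "sign_test"
  )
}

#' @export
print.sign_test <- function(x, ...) {
  cat(sprintf(
    "Paired %s test: p = %.4g (%d positive of %d nonzero differences)%s\n",
    x$variant, x$p_value, x$n_positive, x$n_nonzero,
    if (x$all_ties) " [all ties]" else ""
  ))
  invisible(x)
}

#' @export
tidy.sign_test <- function(x, ...) {
  tibble::tibble(
    p_value = x$p_value, n_nonzero = x$n_nonzero, n_positive = x$n_positive,
    variant = x$variant
  )
}
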