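# Repeated-measures ANOVA with Greenhouse-Geisser handling, Bonferroni
# paired post-hocs, and two-way random-effects intraclass correlation.

.as_unit_condition <- function(values) {
  m <- as.matrix(values)
  if (!is.numeric(m) || anyNA(m))
    stop_data("unit x condition table must be numeric and complete (no imputation)")
  if (nrow(m) < 2L) stop_data("need at least 2 units")
  if (ncol(m) < 2L) stop_data("need at least 2 conditions")
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  m
}

# Greenhouse-Geisser epsilon from the double-centred condition covariance
.gg_epsilon <- function(m) {
  k <- ncol(m)
  S <- stats::cov(m)
  S_dc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  tr <- sum(diag(S_dc))
  eps <- tr^2 / ((k - 1) * sum(S_dc^2))
  min(1, max(1 / (k - 1), eps))
}

.mauchly_p <- function(m) {
  k <- ncol(m)
  if (k == 2L) return(1)  # sphericity trivially holds for two conditions
  mlm <- stats::lm(m ~ 1)
  # degenerate designs (n close to k) make the test statistic NaN
  out <- tryCatch(
    suppressWarnings(stats::mauchly.test(mlm, X = ~1)$p.value),
    error = function(e) NA_real_)
  if (!is.null(out) && is.nan(out)) out <- NA_real_
  out
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject F test of a single k-level factor measured on
#' each of n units, with partial eta-squared effect size and
#' Greenhouse-Geisser sphericity handling. In `auto` mode the correction is
#' applied when Mauchly's test rejects sphericity at alpha = 0.05; `always`
#' and `never` force the choice.
#'
#' @param values Complete numeric unit-by-condition matrix or data frame
#'   (n rows = units, k columns = conditions).
#' @param correct One of `"auto"`, `"never"`, `"always"`.
#' @return An object of class `rm_anova_result`: `F`, `df1`, `df2`
#'   (possibly non-integer after correction), `p`, `partial_eta_squared`,
#'   `epsilon`, `corrected`, `mauchly_p` and the condition means.
#' @export
rm_anova <- function(values, correct = c("auto", "never", "always")) {
  correct <- match.arg(correct)
  m <- .as_unit_condition(values)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  Fval <- if (ms_err == 0) {
    if (ms_cond == 0) 0 else Inf
  } else ms_cond / ms_err
  eps <- .gg_epsilon(m)
  mau_p <- .mauchly_p(m)
  corrected <- switch(correct,
                      never = FALSE,
                      always = TRUE,
                      auto = is.finite(mau_p) && mau_p < 0.05)
  if (corrected) { df1 <- eps * df1; df2 <- eps * df2 }
  p <- if (is.infinite(Fval)) 0 else stats::pf(Fval, df1, df2, lower.tail = FALSE)
  structure(list(F = Fval, df1 = df1, df2 = df2, p = p,
                 partial_eta_squared =
                   if (ss_cond == 0) 0 else ss_cond / (ss_cond + ss_err),
                 epsilon = eps, corrected = corrected, mauchly_p = mau_p,
                 means = colMeans(m), n = n, k = k),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%s, %s) = %.3f, p = %.4g, partial eta^2 = %.3f%s\n",
              format(round(x$df1, 3)), format(round(x$df2, 3)), x$F, x$p,
              x$partial_eta_squared,
              if (x$corrected)
                sprintf(" [Greenhouse-Geisser, epsilon = %.3f]", x$epsilon)
              else ""))
  invisible(x)
}

#' Bonferroni-corrected paired post-hoc comparisons
#'
#' Paired t-tests for every pair of conditions, with df = n - 1 and raw
#' p-values multiplied by the number of pairs C(k, 2) (capped at 1).
#'
#' @inheritParams rm_anova
#' @return An object of class `posthoc_table`: a data frame with one row
#'   per condition pair (`mean_diff`, `t`, `df`, `p_raw`, `p_bonferroni`).
#' @export
posthoc_bonferroni <- function(values) {
  m <- .as_unit_condition(values)
  n <- nrow(m); k <- ncol(m)
  pairs <- utils::combn(k, 2)
  m_comp <- ncol(pairs)
  rows <- lapply(seq_len(m_comp), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    d <- m[, a] - m[, b]
    sd_d <- stats::sd(d)
    tval <- if (sd_d == 0) {
      if (mean(d) == 0) 0 else Inf * sign(mean(d))
    } else mean(d) / (sd_d / sqrt(n))
    p <- if (tval == 0) 1 else 2 * stats::pt(-abs(tval), n - 1)
    data.frame(condition_a = colnames(m)[a], condition_b = colnames(m)[b],
               mean_diff = mean(d), t = tval, df = n - 1,
               p_raw = p, p_bonferroni = min(1, p * m_comp),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("posthoc_table", "data.frame"),
            m_comparisons = m_comp)
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' ICC(2,1) (single measures) and ICC(2,k) (average measures) from the
#' two-way random-effects mean-square decomposition with the absolute
#' agreement definition (rater mean offsets count as disagreement), with
#' F-based confidence bounds for the single-measure coefficient
#' (McGraw & Wong).
#'
#' @param ratings Complete numeric participant-by-stimulus matrix (raters
#'   in rows, rated targets in columns), at least 2 of each.
#' @param conf_level Confidence level for the bounds (default 0.95).
#' @return An object of class `icc_result`: `icc_single`, `icc_average`,
#'   `lower`, `upper` (single-measure bounds), mean squares, and the
#'   design sizes.
#' @export
icc_absolute_agreement <- function(ratings, conf_level = 0.95) {
  m <- as.matrix(ratings)
  if (!is.numeric(m) || anyNA(m))
    stop_data("rating matrix must be numeric and complete")
  k <- nrow(m)  # raters
  n <- ncol(m)  # stimuli
  if (k < 2L || n < 2L)
    stop_data("need at least 2 raters and 2 stimuli")
  y <- t(m)     # stimuli x raters
  grand <- mean(y)
  row_m <- rowMeans(y)  # per-stimulus
  col_m <- colMeans(y)  # per-rater
  msr <- k * sum((row_m - grand)^2) / (n - 1)          # between stimuli
  msc <- n * sum((col_m - grand)^2) / (k - 1)          # between raters
  sse <- sum((y - grand)^2) - k * sum((row_m - grand)^2) -
    n * sum((col_m - grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 0 || stats::sd(row_m) == 0)
    stop_data("undefined ICC: no between-stimulus variance")
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  icck <- (msr - mse) / (msr + (msc - mse) / n)
  alpha <- 1 - conf_level
  lower <- upper <- NA_real_
  if (mse > 0 && icc1 < 1) {
    a <- k * icc1 / (n * (1 - icc1))
    b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_u <- stats::qf(1 - alpha / 2, n - 1, v)
    f_l <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_u * mse) /
      (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_l * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_l * msr)
  } else if (mse == 0) {
    lower <- upper <- icc1
  }
  structure(list(icc_single = icc1, icc_average = icck,
                 lower = lower, upper = upper, conf_level = conf_level,
                 ms_stimuli = msr, ms_raters = msc, ms_error = mse,
                 n_raters = k, n_stimuli = n,
                 model = "two-way random", definition = "absolute agreement"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s, %s): single = %.3f [%.3f, %.3f], average (k=%d) = %.3f\n",
              x$model, x$definition, x$icc_single, x$lower, x$upper,
              x$n_raters, x$icc_average))
  invisible(x)
}

#' Exemplar-paired unit-by-condition table for one feature
#'
#' Arranges per-stimulus scalar feature values into the n-by-k table the
#' repeated-measures ANOVA consumes, pairing the i-th exemplar of each
#' emotion category as repeated measurements of unit i (exemplars are
#' paired by their index within category).
#'
#' @param table An averaged-mode `feature_table`.
#' @param feature One of [feature_names()].
#' @return Numeric matrix with `n_per_category` rows and 4 emotion columns.
#' @export
feature_anova_table <- function(table, feature) {
  stopifnot(inherits(table, "feature_table"))
  feature <- match.arg(feature, .FEATURES)
  counts <- tabulate(match(table$emotion, .EMOTIONS), 4L)
  if (length(unique(counts)) != 1L)
    stop_data("emotion categories are unbalanced: %s",
              paste(sprintf("%s=%d", .EMOTIONS, counts), collapse = ", "))
  sapply(.EMOTIONS, function(e) table[table$emotion == e, feature])
}
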