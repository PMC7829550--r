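stat_result <- function(test, statistic, df, p_value, estimate = NULL,
                        conf_int = NULL, direction = NULL, note = NULL) {
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value),
                 estimate = estimate, conf_int = conf_int,
                 direction = direction, note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(signif(x$df, 5), collapse = ", ")
  cat(sprintf("%s: statistic = %s, df = %s, p = %.4g%s\n", x$test,
              paste(signif(x$statistic, 5), collapse = ", "), dfs, x$p_value,
              if (!is.null(x$note)) paste0("  [", x$note, "]") else ""))
  invisible(x)
}

#' Independent two-sample t-test
#'
#' Pooled-variance by default (the classical independent-samples test);
#' Welch's correction optional.  The degenerate case of two constant,
#' identical samples is reported as `t = 0, p = 1` rather than an error.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param variance_mode `"pooled"` or `"welch"`.
#' @return A `"stat_result"` with the t statistic, df, two-sided p, the mean
#'   difference and its 95% CI.
#' @export
t_test_two_sample <- function(x, y, variance_mode = c("pooled", "welch")) {
  variance_mode <- match.arg(variance_mode)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least 2 finite values", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y)) {
    return(stat_result("two-sample t-test", 0, length(x) + length(y) - 2, 1,
                       estimate = 0, note = "both samples constant and equal"))
  }
  ht <- stats::t.test(x, y, var.equal = variance_mode == "pooled")
  stat_result("two-sample t-test", ht$statistic, ht$parameter, ht$p.value,
              estimate = unname(diff(rev(ht$estimate))),
              conf_int = unname(ht$conf.int),
              direction = sign(mean(x) - mean(y)))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the minimum-likelihood rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins that
#' are no more probable than the observed one.  Degenerate margins (an empty
#' row or column) give p = 1.
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @return A `"stat_result"` with the p-value and odds-ratio estimate.
#' @examples
#' fisher_exact_2x2(matrix(c(12, 9, 7, 4), 2))  # the sex-ratio table
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2) || any(table < 0) ||
      any(table != round(table)) || any(!is.finite(table))) {
    stop("fisher_exact_2x2() needs a 2x2 matrix of non-negative integers",
         call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(stat_result("Fisher's exact test", NA_real_, NA_real_, 1,
                       note = "degenerate margin"))
  }
  ht <- stats::fisher.test(table)
  stat_result("Fisher's exact test", NA_real_, NA_real_, min(ht$p.value, 1),
              estimate = unname(ht$estimate))
}

#' Pearson correlation with its t-based test
#'
#' @param x,y Numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return A `"stat_result"` whose `statistic` is r, with `df = n - 2` and
#'   the two-sided p from `t = r sqrt((n-2)/(1-r^2))`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  stat_result("Pearson correlation", ht$estimate, ht$parameter, ht$p.value,
              estimate = unname(ht$estimate), conf_int = unname(ht$conf.int))
}

#' Holm–Šidák step-down multiple-comparison decisions
#'
#' Orders the p-values ascending and, at step i of m, rejects while
#' `p_(i) < 1 - (1 - alpha)^(1/(m - i + 1))`, stopping at the first
#' non-rejection.  Decisions are mapped back to the input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @param alpha Family-wise error rate, in (0, 1).
#' @param labels Optional comparison labels.
#' @return A `data.frame` in input order: `comparison`, `p`, `threshold`
#'   (the step-down critical value applied to that p), `rejected`.
#' @examples
#' holm_sidak(c(0.01, 0.02, 0.20))
#' @export
holm_sidak <- function(pvals, alpha = 0.05, labels = NULL) {
  stopifnot(is.numeric(pvals), all(pvals >= 0 & pvals <= 1),
            alpha > 0, alpha < 1)
  m <- length(pvals)
  if (is.null(labels)) labels <- paste0("cmp", seq_len(m))
  ord <- order(pvals)
  thresholds <- 1 - (1 - alpha)^(1 / (m - seq_len(m) + 1))
  rejected_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (pvals[ord[i]] < thresholds[i]) rejected_sorted[i] <- TRUE else break
  }
  out <- data.frame(comparison = labels, p = pvals,
                    threshold = NA_real_, rejected = NA)
  out$threshold[ord] <- thresholds
  out$rejected[ord] <- rejected_sorted
  out
}

#' Switching cost
#'
#' The performance decrement on switch trials relative to sustained
#' (repeat) trials: `rt_switch - rt_sustained`, in the units of its inputs.
#' Applies equally to RT means and to non-decision-time estimates.
#'
#' @param rt_switch,rt_sustained Numeric (vectorised) condition means.
#' @return `rt_switch - rt_sustained`; positive values indicate a cost.
#' @export
switching_cost <- function(rt_switch, rt_sustained) {
  stopifnot(is.numeric(rt_switch), is.numeric(rt_sustained))
  rt_switch - rt_sustained
}

#' Squared correlation between observed and model-predicted cell values
#'
#' The observed-versus-expected fit check: the squared Pearson correlation
#' across subject x condition cells.  Returns `NA` with an `undefined`
#' attribute when either vector is constant.
#'
#' @param observed,predicted Paired numeric vectors, length >= 3.
#' @return A single r-squared in \[0, 1\] (possibly `NA`, flagged).
#' @export
fit_r2 <- function(observed, predicted) {
  ok <- is.finite(observed) & is.finite(predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  if (length(observed) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(observed) == 0 || stats::var(predicted) == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  structure(stats::cor(observed, predicted)^2, undefined = FALSE)
}

#' Observed-versus-predicted fit diagnostics for an EZ fit
#'
#' Computes the accuracy and RT fit r-squared across all fitted cells:
#' observed proportion correct against the forward model's predicted Pc,
#' and observed mean RT against predicted MDT + Ter.
#'
#' @param fit An [ez_fit()] object.
#' @return A list with `r2_accuracy` and `r2_rt`.
#' @export
fit_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "ez_fit"))
  pr <- predict(fit)
  p <- fit$parameters
  ok <- !p$unfit
  list(r2_accuracy = as.numeric(fit_r2(p$pc[ok], pr$pc_hat[ok])),
       r2_rt = as.numeric(fit_r2(p$mrt_ms[ok], pr$mrt_hat_ms[ok])))
}

#' Per-group sample size for a two-sample t-test
#'
#' Smallest integer n per group at which the two-sample t-test attains the
#' requested power for a standardized effect size d (the study's power
#' analysis used alpha = 0.05, one-tailed, power = 0.8).
#'
#' @param effect_size_d Cohen's d, > 0.
#' @param alpha Significance level.
#' @param power Target power.
#' @param tails 1 or 2.
#' @return Integer n per group (minimum 2).
#' @examples
#' sample_size_two_sample(1.0)  # about 13 per group
#' @export
sample_size_two_sample <- function(effect_size_d, alpha = 0.05, power = 0.8,
                                   tails = 1) {
  stopifnot(effect_size_d > 0, alpha > 0, alpha < 1, power > 0, power < 1,
            tails %in% c(1, 2))
  alt <- if (tails == 1) "one.sided" else "two.sided"
  if (power <= alpha) return(2L)
  n <- stats::power.t.test(delta = effect_size_d, sd = 1, sig.level = alpha,
                           power = power, type = "two.sample",
                           alternative = alt)$n
  n <- max(2L, floor(n))
  # exact integer search around the continuous solution
  while (stats::power.t.test(n = n, delta = effect_size_d, sd = 1,
                             sig.level = alpha, type = "two.sample",
                             alternative = alt)$power < power) {
    n <- n + 1L
  }
  while (n > 2L &&
         stats::power.t.test(n = n - 1L, delta = effect_size_d, sd = 1,
                             sig.level = alpha, type = "two.sample",
                             alternative = alt)$power >= power) {
    n <- n - 1L
  }
  as.integer(n)
}
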