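#' Fit the EZ-diffusion model to per-cell summary statistics
#'
#' The package's central estimator.  Takes a table of per subject x condition
#' summaries (one row per cell, as produced by [summarize_condition()]) and
#' applies the closed-form EZ inversion to every cell that is fit for
#' estimation, returning a classed model object with the usual accessor
#' methods (`print`, `summary`, `coef`, `predict`, `residuals`, `plot`,
#' `simulate`).
#'
#' Cells flagged `unfit` (too few correct trials, or zero RT variance) are
#' carried through with `NA` parameters.  Accuracies of 0, 1/2 or 1 are
#' edge-corrected by half a trial before inversion (see [edge_correct()]);
#' negative non-decision-time estimates are retained and flagged, never
#' clipped.
#'
#' @param summaries A `data.frame` with columns `n_trials`, `n_correct`,
#'   `pc`, `mrt` (seconds), `vrt` (seconds squared) and any identifier
#'   columns (typically `subject_id`, `group`, `task_id`, `condition`),
#'   optionally an `unfit` logical column.
#' @param s Within-trial noise scaling; the conventional 0.1.
#' @param correct_edges Edge-correct accuracies at 0, 1/2 and 1?
#' @return An object of class `"ez_fit"`: a list with `parameters` (one row
#'   per cell: identifiers, `v`, `a`, `ter_ms`, `mdt_ms`, `pc`, `mrt_ms`,
#'   `vrt_ms2`, `edge_corrected`, `negative_ter_flag`), `summaries` (the
#'   input), `s`, and `call`.
#' @examples
#' sim <- simulate_condition(diffusion_spec(0.25, 0.1, 0.3), n = 200, seed = 7)
#' trials <- data.frame(subject_id = "s1", group = "control", task_id = "demo",
#'                      condition = "c1", rt_ms = sim$rt * 1000,
#'                      correct = sim$correct, responded = 1)
#' fit <- ez_fit(summarize_condition(trials))
#' coef(fit)
#' @export
ez_fit <- function(summaries, s = 0.1, correct_edges = TRUE) {
  stopifnot(is.data.frame(summaries))
  needed <- c("n_trials", "n_correct", "pc", "mrt", "vrt")
  missing_cols <- setdiff(needed, names(summaries))
  if (length(missing_cols)) {
    stop("summaries is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  id_cols <- intersect(c("subject_id", "group", "task_id", "condition"),
                       names(summaries))
  unfit <- if ("unfit" %in% names(summaries)) summaries$unfit else
    rep(FALSE, nrow(summaries))
  unfit <- unfit | !is.finite(summaries$vrt) | summaries$vrt <= 0

  n <- nrow(summaries)
  v <- a <- ter <- mdt <- rep(NA_real_, n)
  edge <- neg <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (unfit[i]) next
    est <- ez_inverse(pc = summaries$pc[i], mrt = summaries$mrt[i],
                      vrt = summaries$vrt[i],
                      n_trials = summaries$n_trials[i], s = s,
                      correct_edges = correct_edges)
    v[i] <- est$v; a[i] <- est$a; ter[i] <- est$ter; mdt[i] <- est$mdt
    edge[i] <- est$edge_corrected; neg[i] <- est$negative_ter
  }
  parameters <- cbind(
    summaries[, id_cols, drop = FALSE],
    data.frame(v = v, a = a, ter_ms = 1000 * ter, mdt_ms = 1000 * mdt,
               pc = summaries$pc, mrt_ms = 1000 * summaries$mrt,
               vrt_ms2 = 1e6 * summaries$vrt,
               edge_corrected = as.integer(edge),
               negative_ter_flag = as.integer(neg),
               unfit = unfit))
  rownames(parameters) <- NULL
  structure(list(parameters = parameters, summaries = summaries, s = s,
                 call = match.call()),
            class = "ez_fit")
}

#' @export
print.ez_fit <- function(x, ...) {
  p <- x$parameters
  cat("EZ-diffusion fit (s =", format(x$s), ")\n")
  cat("  cells:", nrow(p), " fitted:", sum(!p$unfit),
      " edge-corrected:", sum(p$edge_corrected),
      " negative-Ter flags:", sum(p$negative_ter_flag), "\n")
  ok <- !p$unfit
  if (any(ok)) {
    cat(sprintf("  v   : median %.3f  [%.3f, %.3f]\n",
                stats::median(p$v[ok]), min(p$v[ok]), max(p$v[ok])))
    cat(sprintf("  a   : median %.3f  [%.3f, %.3f]\n",
                stats::median(p$a[ok]), min(p$a[ok]), max(p$a[ok])))
    cat(sprintf("  Ter : median %.0f ms [%.0f, %.0f]\n",
                stats::median(p$ter_ms[ok]), min(p$ter_ms[ok]),
                max(p$ter_ms[ok])))
  }
  invisible(x)
}

#' @export
coef.ez_fit <- function(object, ...) {
  p <- object$parameters
  p[, c(intersect(c("subject_id", "group", "task_id", "condition"), names(p)),
        "v", "a", "ter_ms", "mdt_ms")]
}

#' Summarise an EZ fit by group and condition
#'
#' Group x task x condition means with 95% confidence intervals
#' (mean +/- t[0.975, n-1] * SE) for each EZ parameter and the observed mean
#' RT, mirroring the study's reporting style.
#'
#' @param object An [ez_fit()] object.
#' @param ... Unused.
#' @return A `data.frame` of class `"summary.ez_fit"`.
#' @export
summary.ez_fit <- function(object, ...) {
  p <- object$parameters[!object$parameters$unfit, , drop = FALSE]
  by_cols <- intersect(c("group", "task_id", "condition"), names(p))
  if (!length(by_cols)) by_cols <- NULL
  ci <- function(x) {
    x <- x[is.finite(x)]
    n <- length(x)
    if (n < 2) return(c(mean = mean(x), lo = NA, hi = NA, n = n))
    se <- stats::sd(x) / sqrt(n)
    tq <- stats::qt(0.975, n - 1)
    c(mean = mean(x), lo = mean(x) - tq * se, hi = mean(x) + tq * se, n = n)
  }
  measures <- c("v", "a", "ter_ms", "mdt_ms", "mrt_ms")
  split_keys <- if (is.null(by_cols)) rep("all", nrow(p)) else
    interaction(p[by_cols], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(p, split_keys), function(cell) {
    ids <- if (is.null(by_cols)) data.frame(group = "all") else
      cell[1, by_cols, drop = FALSE]
    do.call(rbind, lapply(measures, function(m) {
      st <- ci(cell[[m]])
      cbind(ids, data.frame(measure = m, mean = st[["mean"]],
                            ci_lo = st[["lo"]], ci_hi = st[["hi"]],
                            n = st[["n"]]))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.ez_fit", "data.frame")
  out
}

#' @export
print.summary.ez_fit <- function(x, ...) {
  cat("Group summaries (mean [95% CI]):\n")
  df <- as.data.frame(x)
  df$mean <- signif(df$mean, 4)
  df$ci_lo <- signif(df$ci_lo, 4)
  df$ci_hi <- signif(df$ci_hi, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Predicted summary statistics from a fitted EZ model
#'
#' Pushes each cell's fitted parameters back through the forward model,
#' yielding the expected accuracy and mean RT used in the observed-versus-
#' expected fit check.
#'
#' @param object An [ez_fit()] object.
#' @param ... Unused.
#' @return A `data.frame` with the identifier columns plus `pc_hat`,
#'   `mdt_hat_ms`, `mrt_hat_ms` and `vrt_hat_ms2` (`NA` for unfit cells).
#' @export
predict.ez_fit <- function(object, ...) {
  p <- object$parameters
  id_cols <- intersect(c("subject_id", "group", "task_id", "condition"),
                       names(p))
  out <- p[, id_cols, drop = FALSE]
  pc_hat <- mdt_hat <- vrt_hat <- rep(NA_real_, nrow(p))
  ok <- !p$unfit & is.finite(p$v) & p$v != 0
  if (any(ok)) {
    fwd <- ez_forward(p$v[ok], p$a[ok], ter = 0, s = object$s)
    pc_hat[ok] <- fwd$pc
    mdt_hat[ok] <- fwd$mdt
    vrt_hat[ok] <- fwd$vrt
  }
  out$pc_hat <- pc_hat
  out$mdt_hat_ms <- 1000 * mdt_hat
  out$mrt_hat_ms <- 1000 * mdt_hat + p$ter_ms
  out$vrt_hat_ms2 <- 1e6 * vrt_hat
  out
}

#' @export
residuals.ez_fit <- function(object, ...) {
  pr <- predict(object)
  p <- object$parameters
  data.frame(pr[, setdiff(names(pr), c("pc_hat", "mdt_hat_ms", "mrt_hat_ms",
                                       "vrt_hat_ms2")), drop = FALSE],
             resid_pc = p$pc - pr$pc_hat,
             resid_mrt_ms = p$mrt_ms - pr$mrt_hat_ms)
}

#' Observed-versus-predicted diagnostic plot
#'
#' Two panels: observed against model-predicted accuracy, and observed
#' against predicted mean RT, across all fitted cells.  The identity line
#' marks perfect agreement.
#'
#' @param x An [ez_fit()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ez_fit <- function(x, ...) {
  pr <- predict(x)
  p <- x$parameters
  ok <- !p$unfit
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(pr$pc_hat[ok], p$pc[ok], xlab = "predicted Pc",
                 ylab = "observed Pc", main = "Accuracy", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::plot(pr$mrt_hat_ms[ok], p$mrt_ms[ok], xlab = "predicted MRT (ms)",
                 ylab = "observed MRT (ms)", main = "Mean RT", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Parametric bootstrap from a fitted EZ model
#'
#' Re-simulates each fitted cell's trials from its estimated parameters via
#' the Wiener diffusion simulator — the standard posterior-predictive-style
#' check for moment-based fits.
#'
#' @param object An [ez_fit()] object.
#' @param nsim Number of replicate data sets.
#' @param seed Optional integer seed.
#' @param dt Integration step for the simulator.
#' @param ... Unused.
#' @return A list of `nsim` data.frames of simulated cell summaries with the
#'   same identifier columns as the fit.
#' @export
simulate.ez_fit <- function(object, nsim = 1, seed = NULL, dt = 1e-3, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$parameters
  id_cols <- intersect(c("subject_id", "group", "task_id", "condition"),
                       names(p))
  reps <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    rows <- lapply(seq_len(nrow(p)), function(i) {
      base <- p[i, id_cols, drop = FALSE]
      if (p$unfit[i]) {
        return(cbind(base, data.frame(n_trials = NA, n_correct = NA, pc = NA,
                                      mrt = NA, vrt = NA)))
      }
      spec <- diffusion_spec(p$v[i], p$a[i], p$ter_ms[i] / 1000, s = object$s,
                             dt = dt)
      sim <- simulate_condition(spec, n = object$summaries$n_trials[i])
      ok <- sim$correct == 1
      cbind(base, data.frame(
        n_trials = nrow(sim), n_correct = sum(ok), pc = mean(sim$correct),
        mrt = mean(sim$rt[ok]),
        vrt = if (sum(ok) >= 2) stats::var(sim$rt[ok]) else NA_real_))
    })
    reps[[r]] <- do.call(rbind, rows)
  }
  reps
}
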