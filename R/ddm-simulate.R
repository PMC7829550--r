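#' Specify a Wiener diffusion process
#'
#' Bundles the generative parameters of the unbiased drift-diffusion process
#' that the EZ model assumes: evidence starts at `start_fraction * a`
#' (0.5, the unbiased midpoint, in the EZ-compatible regime), accumulates
#' with drift `v` and within-trial noise `s`, and a response is emitted when
#' it reaches 0 (error) or `a` (correct), after which the non-decision time
#' `ter` is added.
#'
#' @param v Drift rate.
#' @param a Boundary separation (> 0).
#' @param ter Non-decision time, seconds.
#' @param s Noise scaling (> 0), default 0.1.
#' @param start_fraction Relative start point in (0, 1); 0.5 for the
#'   unbiased EZ regime.
#' @param dt Integration step in seconds.  1e-3 is adequate for cohort
#'   generation; use 1e-4 (or `method = "exact_small_step"`) for oracle-grade
#'   moment checks.
#' @param method `"euler"` (plain Euler–Maruyama) or `"exact_small_step"`
#'   (Euler with the diffusion-bridge within-step crossing correction).
#' @param max_time Absorption deadline in seconds; trials that exceed it are
#'   resampled and counted.
#' @return An object of class `"diffusion_spec"`.
#' @export
diffusion_spec <- function(v, a, ter, s = 0.1, start_fraction = 0.5,
                           dt = 1e-3, method = c("euler", "exact_small_step"),
                           max_time = 20) {
  method <- match.arg(method)
  stopifnot(is.numeric(v), length(v) == 1, is.finite(v))
  if (a <= 0 || s <= 0 || dt <= 0 || max_time <= 0) {
    stop("a, s, dt and max_time must be positive", call. = FALSE)
  }
  if (start_fraction <= 0 || start_fraction >= 1) {
    stop("start_fraction must be inside (0, 1)", call. = FALSE)
  }
  structure(list(v = v, a = a, ter = ter, s = s,
                 start_fraction = start_fraction, dt = dt,
                 method = method, max_time = max_time),
            class = "diffusion_spec")
}

#' @export
print.diffusion_spec <- function(x, ...) {
  cat(sprintf(
    "Wiener diffusion spec: v = %g, a = %g, Ter = %g s, s = %g (%s, dt = %g s)\n",
    x$v, x$a, x$ter, x$s, x$method, x$dt))
  invisible(x)
}

#' Simulate diffusion trials for one condition
#'
#' Draws `n` independent first-passage trials from a [diffusion_spec()].
#' Uses R's global random number stream, so `set.seed()` (or the `seed`
#' argument) makes runs reproducible trial-for-trial.
#'
#' @param spec A [diffusion_spec()].
#' @param n Number of trials (>= 1).
#' @param seed Optional integer seed applied before simulating.
#' @return A `data.frame` with columns `rt` (seconds, including `ter`),
#'   `correct` (1 = upper boundary) and `decision_time`, with attribute
#'   `n_resampled` giving the number of timed-out attempts that were redrawn.
#' @examples
#' sim <- simulate_condition(diffusion_spec(0.2, 0.1, 0.3), n = 500, seed = 1)
#' mean(sim$correct)
#' @export
simulate_condition <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "diffusion_spec"))
  if (length(n) != 1 || !is.finite(n) || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  res <- ddm_sim_cpp(as.integer(n), spec$v, spec$a, spec$ter, spec$s,
                     spec$dt, spec$start_fraction, spec$max_time,
                     match(spec$method, c("euler", "exact_small_step")) - 1L)
  out <- data.frame(rt = res$rt, correct = res$correct,
                    decision_time = res$decision_time)
  attr(out, "n_resampled") <- res$n_resampled
  out
}

#' Simulate a single diffusion trial
#'
#' @inheritParams simulate_condition
#' @return A one-row `data.frame` as in [simulate_condition()].
#' @export
simulate_trial <- function(spec, seed = NULL) {
  simulate_condition(spec, n = 1, seed = seed)
}
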