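#' Log-odds transform
#'
#' Computes `log(p / (1 - p))`, the intermediate quantity of the EZ-diffusion
#' inversion.
#'
#' @param p Numeric vector of proportions, each strictly inside (0, 1).
#' @return Numeric vector of log-odds.
#' @examples
#' logit(0.5)
#' logit(1 / (1 + exp(-2)))
#' @export
logit <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("logit() requires proportions strictly inside (0, 1); ",
         "apply edge_correct() to observed accuracies first.", call. = FALSE)
  }
  log(p / (1 - p))
}

#' Edge-correct an observed proportion correct
#'
#' The EZ-diffusion inversion is undefined at proportions 0, 1/2 and 1.
#' Observed accuracies at those values are nudged inward by half a trial:
#' `1` becomes `1 - 1/(2n)`, `0` becomes `1/(2n)` and `1/2` becomes
#' `1/2 + 1/(2n)`, where `n` is the number of trials in the cell.  All other
#' values pass through unchanged.
#'
#' @param pc Numeric vector of proportions in \[0, 1\].
#' @param n_trials Integer vector (recycled) of per-cell trial counts, >= 1.
#' @return Numeric vector strictly inside (0, 1) and off 0.5.
#' @examples
#' edge_correct(1, 44)      # 1 - 1/88
#' edge_correct(0.75, 44)   # unchanged
#' @export
edge_correct <- function(pc, n_trials) {
  stopifnot(is.numeric(pc), all(pc >= 0 & pc <= 1))
  if (any(n_trials < 1)) stop("n_trials must be >= 1", call. = FALSE)
  n <- rep_len(as.numeric(n_trials), length(pc))
  out <- pc
  out[pc == 1] <- 1 - 1 / (2 * n[pc == 1])
  out[pc == 0] <- 1 / (2 * n[pc == 0])
  out[pc == 0.5] <- 0.5 + 1 / (2 * n[pc == 0.5])
  out
}

#' Forward EZ-diffusion moments
#'
#' Maps diffusion parameters to the three summary statistics the EZ model is
#' built on: the predicted proportion correct, the mean decision time and the
#' variance of decision times.  With `y = -v * a / s^2`:
#' \deqn{Pc = 1/(1+e^y)}
#' \deqn{MDT = (a/(2v)) (1-e^y)/(1+e^y)}
#' \deqn{VRT = (a s^2 / (2 v^3)) (2 y e^y - e^{2y} + 1)/(1+e^y)^2}
#' The predicted mean response time is `mdt + ter`.
#'
#' @param v Drift rate (evidence units per second; nonzero).
#' @param a Boundary separation (evidence units; > 0).
#' @param ter Non-decision time in seconds (carried through unchanged).
#' @param s Within-trial noise scaling; the conventional 0.1 by default.
#' @return A list of class `"ez_moments"` with elements `pc`, `mdt`, `vrt`
#'   and `mrt` (= `mdt + ter`).  All components are vectorised over the
#'   parameters.
#' @examples
#' ez_forward(v = 0.2, a = 0.1, ter = 0.3)
#' @export
ez_forward <- function(v, a, ter = 0, s = 0.1) {
  stopifnot(is.numeric(v), is.numeric(a), is.numeric(s))
  if (any(v == 0)) {
    stop("ez_forward() has no closed form at v = 0; ",
         "treat the cell as chance performance.", call. = FALSE)
  }
  if (any(a <= 0) || any(s <= 0)) stop("a and s must be positive", call. = FALSE)
  y <- -v * a / s^2
  ey <- exp(y)
  pc <- 1 / (1 + ey)
  mdt <- (a / (2 * v)) * (1 - ey) / (1 + ey)
  vrt <- (a * s^2 / (2 * v^3)) * (2 * y * ey - ey^2 + 1) / (1 + ey)^2
  structure(list(pc = pc, mdt = mdt, vrt = vrt, mrt = mdt + ter),
            class = "ez_moments")
}

#' Invert summary statistics to EZ-diffusion parameters
#'
#' The closed-form EZ inversion: given a cell's proportion correct, mean of
#' correct response times and variance of correct response times, recover the
#' drift rate, boundary separation and non-decision time.  With
#' `L = logit(pc)`:
#' \deqn{v = sign(pc - 1/2) \, s \, [L (pc^2 L - pc L + pc - 1/2) / VRT]^{1/4}}
#' \deqn{a = s^2 L / v}
#' MDT then follows from the forward map and `ter = mrt - mdt`.
#'
#' @param pc Proportion correct.  Must be inside (0, 1) and off 0.5 unless
#'   `correct_edges = TRUE`, in which case [edge_correct()] is applied first
#'   using `n_trials`.
#' @param mrt Mean of correct response times, in seconds.
#' @param vrt Variance of correct response times, in seconds squared; > 0.
#' @param n_trials Trial count of the cell (needed for edge correction).
#' @param s Noise scaling, default 0.1.
#' @param correct_edges Apply the edge correction to `pc` first?
#' @return A list of class `"ez_parameters"` with elements `v`, `a`, `ter`,
#'   `mdt`, `s`, `pc` (the possibly corrected value used), `edge_corrected`
#'   and `negative_ter` flags.  A negative `ter` estimate is retained and
#'   flagged, not clipped, so downstream group statistics stay unbiased.
#' @examples
#' m <- ez_forward(v = 0.2, a = 0.1, ter = 0.3)
#' ez_inverse(pc = m$pc, mrt = m$mrt, vrt = m$vrt)
#' @export
ez_inverse <- function(pc, mrt, vrt, n_trials = NULL, s = 0.1,
                       correct_edges = FALSE) {
  stopifnot(length(pc) == 1, length(mrt) == 1, length(vrt) == 1)
  if (!is.finite(vrt) || vrt <= 0) {
    stop("ez_inverse() requires vrt > 0", call. = FALSE)
  }
  edge <- FALSE
  if (isTRUE(correct_edges)) {
    if (is.null(n_trials)) {
      stop("edge correction needs the cell's n_trials", call. = FALSE)
    }
    pc_adj <- edge_correct(pc, n_trials)
    edge <- pc_adj != pc
    pc <- pc_adj
  }
  if (pc <= 0 || pc >= 1 || pc == 0.5) {
    stop("pc = ", format(pc), " is outside the EZ inversion's domain; ",
         "set correct_edges = TRUE to nudge edge cells inward.", call. = FALSE)
  }
  L <- logit(pc)
  x <- L * (pc^2 * L - pc * L + pc - 0.5) / vrt
  v <- sign(pc - 0.5) * s * x^0.25
  a <- s^2 * L / v
  mdt <- ez_forward(v, a, ter = 0, s = s)$mdt
  ter <- mrt - mdt
  structure(list(v = v, a = a, ter = ter, mdt = mdt, s = s, pc = pc,
                 edge_corrected = edge, negative_ter = ter < 0),
            class = "ez_parameters")
}

#' @export
print.ez_parameters <- function(x, ...) {
  cat("EZ-diffusion parameters (s =", format(x$s), ")\n")
  cat(sprintf("  v   = %8.4f   (drift rate)\n", x$v))
  cat(sprintf("  a   = %8.4f   (boundary separation)\n", x$a))
  cat(sprintf("  Ter = %8.1f ms (non-decision time)%s\n", 1000 * x$ter,
              if (isTRUE(x$negative_ter)) "  [negative: flagged]" else ""))
  cat(sprintf("  MDT = %8.1f ms (mean decision time)\n", 1000 * x$mdt))
  if (isTRUE(x$edge_corrected)) cat("  (accuracy was edge-corrected)\n")
  invisible(x)
}

#' @export
print.ez_moments <- function(x, ...) {
  cat("EZ-diffusion forward moments\n")
  cat(sprintf("  Pc  = %.4f\n  MDT = %.1f ms\n  VRT = %.5f s^2\n  MRT = %.1f ms\n",
              x$pc[1], 1000 * x$mdt[1], x$vrt[1], 1000 * x$mrt[1]))
  if (length(x$pc) > 1) cat("  ... (", length(x$pc), "parameter sets )\n")
  invisible(x)
}
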