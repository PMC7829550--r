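#' Build a randomized trial sequence for one of the four attentional tasks
#'
#' Encodes the study's four experiments exactly as specified and returns a
#' randomized sequence of planned trials:
#'
#' * `exp1` (spatial processing): 132 trials, 44 at each eccentricity
#'   (3.5, 5, 7 degrees); target orientation (0/90/180/270) and
#'   inside/outside placement balanced as evenly as integer counts allow
#'   within each eccentricity.
#' * `exp2` (attentional orienting): 146 trials; 96 valid (ipsilateral,
#'   65.8\%) and 50 invalid (contralateral, 34.2\%) at 7 degrees.
#' * `exp3` (stop signal): 208 trials; 112 GO (53.8\%) and 96 STOP (46.2\%),
#'   24 STOP trials at each SOA of 200/400/600/800 ms, sizes balanced
#'   (56/56 GO, 12/12 STOP per SOA).
#' * `exp4` (attention switching): 186 trials, 93 large and 93 small; the
#'   cue colour (red/green) is drawn independently per trial with
#'   probability 1/2, so switch/repeat counts are stochastic.
#'
#' Condition counts are invariant to the seed; only the ordering (and exp4's
#' cue colours) depend on it.
#'
#' @param task_id One of `"exp1"`, `"exp2"`, `"exp3"`, `"exp4"`.
#' @param seed Optional integer seed for the shuffle.
#' @return A `data.frame` of planned trials with a contiguous `index` column
#'   and task-specific condition columns; timing constants (fixation 500 ms,
#'   stimulus window 3000 ms — 1900 ms for exp3 GO — inter-trial 500 ms) are
#'   attached as the `"timing"` attribute.
#' @examples
#' d <- build_design("exp3", seed = 1)
#' table(d$trial_type)
#' @export
build_design <- function(task_id, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  design <- switch(as.character(task_id),
    exp1 = {
      per_ecc <- lapply(c(3.5, 5, 7), function(ecc) {
        # 44 trials: 8 orientation x placement cells, counts 6/5 arranged so
        # each orientation has 11 trials and each placement 22
        cells <- expand.grid(orientation_deg = c(0, 90, 180, 270),
                             placement = c("inside", "outside"),
                             stringsAsFactors = FALSE)
        n_cell <- ifelse((cells$orientation_deg %in% c(0, 90)) ==
                           (cells$placement == "inside"), 6L, 5L)
        cells[rep(seq_len(nrow(cells)), n_cell), , drop = FALSE] |>
          transform(eccentricity_deg = ecc)
      })
      do.call(rbind, per_ecc)
    },
    exp2 = {
      data.frame(
        validity = rep(c("valid", "invalid"), c(96L, 50L)),
        target_side = c(rep(c("left", "right"), 48L),
                        rep(c("left", "right"), 25L))
      )
    },
    exp3 = {
      go <- data.frame(trial_type = "go", soa_ms = NA_real_,
                       size = rep(c("large", "small"), 56L))
      stop_ <- expand.grid(soa_ms = c(200, 400, 600, 800),
                           size = c("large", "small"),
                           rep = 1:12, stringsAsFactors = FALSE)
      stop_ <- data.frame(trial_type = "stop", soa_ms = stop_$soa_ms,
                          size = stop_$size)
      rbind(go, stop_)
    },
    exp4 = {
      data.frame(size = rep(c("large", "small"), 93L))
    },
    stop("unknown task_id: ", task_id, call. = FALSE)
  )
  design <- design[sample.int(nrow(design)), , drop = FALSE]
  if (identical(as.character(task_id), "exp4")) {
    design$cue_color <- sample(c("red", "green"), nrow(design), replace = TRUE)
  }
  design$index <- seq_len(nrow(design))
  rownames(design) <- NULL
  design <- design[, c("index", setdiff(names(design), "index"))]
  attr(design, "task_id") <- as.character(task_id)
  attr(design, "timing") <- list(
    fixation_ms = 500,
    stimulus_ms = if (identical(as.character(task_id), "exp3")) 1900 else 3000,
    inter_trial_ms = 500)
  design
}

#' Tabulate a design's condition counts and percentages
#'
#' @param design A design from [build_design()] (or any non-empty trial
#'   table with factor columns).
#' @param factors Columns to tabulate; defaults to every condition column
#'   present (orientation and placement excluded for exp1, which is analysed
#'   by eccentricity only).
#' @return A `data.frame` with columns `factor`, `level`, `n` and `pct`
#'   (percentage of total trials, rounded to one decimal).
#' @examples
#' design_summary(build_design("exp2", seed = 1))
#' @export
design_summary <- function(design, factors = NULL) {
  if (!is.data.frame(design) || nrow(design) == 0) {
    stop("design must be a non-empty data.frame", call. = FALSE)
  }
  if (is.null(factors)) {
    skip <- c("index", "orientation_deg", "placement", "target_side",
              "subject_id", "group", "rt_ms", "correct", "responded")
    factors <- setdiff(names(design), skip)
  }
  total <- nrow(design)
  rows <- lapply(factors, function(f) {
    tab <- table(design[[f]], useNA = "no")
    data.frame(factor = f, level = names(tab), n = as.integer(tab),
               pct = round(100 * as.integer(tab) / total, 1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "total_trials") <- total
  out
}
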