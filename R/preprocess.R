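#' Filter trials by the response-time window
#'
#' Applies the study's cleaning rule: keep trials with a response and an RT
#' inside the window (200–3000 ms by default, bounds inclusive).  Incorrect
#' trials are retained here — they count toward accuracy — and are excluded
#' from RT summaries later, in [summarize_condition()].
#'
#' @param trials Trial table with columns `rt_ms` and `responded`.
#' @param rt_min_ms,rt_max_ms Window bounds in ms, `rt_min_ms < rt_max_ms`.
#' @return A list with `trials` (the retained rows) and `report`, a
#'   `"filter_report"` holding `n_input`, `n_retained`, `retention`
#'   (percentage) and per-reason exclusion counts.
#' @examples
#' tr <- data.frame(rt_ms = c(150, 200, 1000, 3000, 3500), responded = 1,
#'                  correct = 1)
#' filter_trials(tr)$report
#' @export
filter_trials <- function(trials, rt_min_ms = 200, rt_max_ms = 3000) {
  stopifnot(is.data.frame(trials))
  if (rt_min_ms >= rt_max_ms) stop("rt_min_ms must be < rt_max_ms", call. = FALSE)
  n_input <- nrow(trials)
  if (n_input == 0) {
    report <- structure(list(n_input = 0L, n_retained = 0L, retention = NA_real_,
                             excluded = c("no response" = 0L,
                                          "rt below min" = 0L,
                                          "rt above max" = 0L),
                             rt_min_ms = rt_min_ms, rt_max_ms = rt_max_ms),
                        class = "filter_report")
    return(list(trials = trials, report = report))
  }
  responded <- !is.na(trials$responded) & trials$responded == 1
  rt <- trials$rt_ms
  low <- responded & !is.na(rt) & rt < rt_min_ms
  high <- responded & !is.na(rt) & rt > rt_max_ms
  keep <- responded & !is.na(rt) & rt >= rt_min_ms & rt <= rt_max_ms
  report <- structure(list(
    n_input = n_input, n_retained = sum(keep),
    retention = 100 * sum(keep) / n_input,
    excluded = c("no response" = sum(!responded),
                 "rt below min" = sum(low), "rt above max" = sum(high)),
    rt_min_ms = rt_min_ms, rt_max_ms = rt_max_ms),
    class = "filter_report")
  list(trials = trials[keep, , drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("RT window filter [%g, %g] ms: retained %d of %d trials (%.2f%%)\n",
              x$rt_min_ms, x$rt_max_ms, x$n_retained, x$n_input, x$retention))
  for (r in names(x$excluded)) {
    if (x$excluded[[r]] > 0) cat(sprintf("  excluded (%s): %d\n", r, x$excluded[[r]]))
  }
  invisible(x)
}

#' Label switch and repeat trials in the attention-switching task
#'
#' A trial counts as `"switching"` when its cue colour differs from the
#' previous trial's, `"sustained"` when it repeats; each subject's first
#' trial has no predecessor and is labelled `"excluded"`.  Labelling uses
#' presentation order (`index`), so call this on the raw trial table before
#' any RT filtering.
#'
#' @param trials Trial table with columns `subject_id`, `cue_color` and
#'   `index` (presentation order).
#' @return The table with a `switch_label` column appended.
#' @examples
#' tr <- data.frame(subject_id = "s1", index = 1:5,
#'                  cue_color = c("red", "red", "green", "green", "red"))
#' classify_switch(tr)$switch_label
#' @export
classify_switch <- function(trials) {
  stopifnot(is.data.frame(trials))
  if (!"index" %in% names(trials)) {
    stop("classify_switch() needs the presentation-order column 'index'",
         call. = FALSE)
  }
  if (!all(c("subject_id", "cue_color") %in% names(trials))) {
    stop("classify_switch() needs 'subject_id' and 'cue_color' columns",
         call. = FALSE)
  }
  trials$switch_label <- NA_character_
  for (sid in unique(trials$subject_id)) {
    rows <- which(trials$subject_id == sid)
    rows <- rows[order(trials$index[rows])]
    cue <- trials$cue_color[rows]
    lab <- c("excluded",
             ifelse(cue[-1] == cue[-length(cue)], "sustained", "switching"))
    trials$switch_label[rows] <- lab
  }
  trials
}

#' Summarise trials into the EZ model's per-cell statistics
#'
#' For each grouping cell, computes the trial count, number correct,
#' proportion correct (over all retained responded trials), and the mean and
#' unbiased variance of *correct* RTs, converted to seconds.  Cells with
#' fewer correct trials than `min_correct`, or with zero RT variance, are
#' flagged `unfit` for EZ estimation.
#'
#' @param trials Filtered trial table with `rt_ms` and `correct` columns.
#' @param by Grouping columns; defaults to the identifiers present among
#'   `subject_id`, `group`, `task_id`, `condition`.
#' @param min_correct Minimum correct trials for a cell to be fit (default 5).
#' @return A `data.frame`, one row per cell: the grouping columns plus
#'   `n_trials`, `n_correct`, `pc`, `mrt`, `vrt`, `unfit`.
#' @examples
#' tr <- data.frame(subject_id = "s1", condition = "c1",
#'                  rt_ms = c(400, 500, 600, 700), correct = c(1, 1, 1, 0))
#' summarize_condition(tr, min_correct = 2)
#' @export
summarize_condition <- function(trials,
                                by = intersect(c("subject_id", "group",
                                                 "task_id", "condition"),
                                               names(trials)),
                                min_correct = 5) {
  stopifnot(is.data.frame(trials), length(by) >= 1,
            all(by %in% names(trials)),
            all(c("rt_ms", "correct") %in% names(trials)))
  keys <- interaction(trials[by], drop = TRUE, lex.order = TRUE)
  cells <- split(trials, keys)
  rows <- lapply(cells, function(cell) {
    ids <- cell[1, by, drop = FALSE]
    n <- nrow(cell)
    ok <- cell$correct == 1
    n_ok <- sum(ok)
    rt_s <- cell$rt_ms[ok] / 1000
    mrt <- if (n_ok >= 1) mean(rt_s) else NA_real_
    vrt <- if (n_ok >= 2) stats::var(rt_s) else NA_real_
    cbind(ids, data.frame(
      n_trials = n, n_correct = n_ok, pc = n_ok / n, mrt = mrt, vrt = vrt,
      unfit = n_ok < min_correct || !is.finite(vrt) || vrt <= 0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Attach the analysis condition label used for EZ fitting
#'
#' Maps each task's design descriptors onto the condition cells the analysis
#' estimates EZ parameters in: eccentricity for the spatial task, a single
#' pooled cell for the orienting task (valid and invalid trials are
#' integrated), and stimulus size crossed with the switch/sustained label
#' for the switching task.  Stop-signal trials get GO/STOP labels but are
#' not EZ-fitted.
#'
#' @param trials Trial table carrying `task_id` and the relevant design
#'   columns (`eccentricity_deg`, `size`, `switch_label`, `trial_type`).
#' @return The table with a `condition` column appended.
#' @export
label_conditions <- function(trials) {
  stopifnot(is.data.frame(trials), "task_id" %in% names(trials))
  cond <- rep(NA_character_, nrow(trials))
  i1 <- trials$task_id == "exp1"
  if (any(i1)) cond[i1] <- paste0("ecc_", trials$eccentricity_deg[i1])
  i2 <- trials$task_id == "exp2"
  if (any(i2)) cond[i2] <- "pooled"
  i3 <- trials$task_id == "exp3"
  if (any(i3)) {
    cond[i3] <- ifelse(trials$trial_type[i3] == "go", "go",
                       paste0("stop_", trials$soa_ms[i3]))
  }
  i4 <- trials$task_id == "exp4"
  if (any(i4)) {
    if (!"switch_label" %in% names(trials)) {
      stop("label_conditions() needs switch_label for exp4 rows; ",
           "run classify_switch() first", call. = FALSE)
    }
    cond[i4] <- paste(trials$size[i4], trials$switch_label[i4], sep = "_")
  }
  trials$condition <- cond
  trials
}
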