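#' Configure an end-to-end analysis run
#'
#' @param master_seed Integer seed for the whole run.
#' @param cohort A [cohort_config()] describing the synthetic cohort (or
#'   `NULL` when `trials` are supplied to [run_pipeline()] directly).
#' @param rt_min_ms,rt_max_ms RT window bounds, ms.
#' @param s EZ noise scaling.
#' @param fit_tasks Tasks fitted with the EZ model (the stop-signal task is
#'   analysed on accuracy/RT only and excluded by default).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(master_seed = 1, cohort = cohort_config(),
                       rt_min_ms = 200, rt_max_ms = 3000, s = 0.1,
                       fit_tasks = c("exp1", "exp2", "exp4")) {
  if (rt_min_ms >= rt_max_ms) stop("invalid RT window", call. = FALSE)
  if (!length(fit_tasks)) stop("fit_tasks must be non-empty", call. = FALSE)
  structure(list(master_seed = as.integer(master_seed), cohort = cohort,
                 rt_min_ms = rt_min_ms, rt_max_ms = rt_max_ms, s = s,
                 fit_tasks = fit_tasks),
            class = "run_config")
}

config_json <- function(config) {
  jsonlite::toJSON(list(
    master_seed = config$master_seed,
    rt_window_ms = c(config$rt_min_ms, config$rt_max_ms),
    s = config$s, fit_tasks = config$fit_tasks,
    cohort = if (is.null(config$cohort)) NULL else
      config$cohort[c("n_rp", "n_control", "between_sd_frac", "tasks",
                      "dt", "effect")]),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
}

sr_json <- function(x) {
  if (inherits(x, "stat_result")) {
    list(test = x$test, statistic = x$statistic, df = x$df,
         p_value = x$p_value, estimate = x$estimate, conf_int = x$conf_int,
         note = x$note)
  } else x
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate -> label -> filter -> summarize -> EZ-fit -> stats
#' -> report, writing every artifact to `out_dir`: `trials.csv`,
#' `truth.csv`, `parameters.csv`, `filter_report.json`,
#' `stats_report.json`, `fit_diagnostics.json`, `report.txt`, `config.json`
#' and `run.log`.  Every artifact is stamped (in the log) with the config's
#' MD5 hash and the master seed; rerunning the same configuration
#' reproduces identical outputs.
#'
#' The statistical layer mirrors the study's analysis: mixed-design group x
#' eccentricity ANOVAs with Holm–Šidák post hoc group contrasts and
#' eccentricity correlations for the spatial task; group t-tests on the
#' pooled orienting task; stop accuracy by SOA for the stop-signal task;
#' per-size switching costs (RT and Ter) with within- and between-group
#' tests for the switching task; and observed-versus-predicted fit
#' r-squared per fitted experiment.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param trials Optional pre-existing trial table (same schema as
#'   `generate_cohort()$trials`); when supplied the generation stage is
#'   skipped and `truth.csv` is omitted.
#' @return Invisibly, a list with all in-memory artifacts: `trials`,
#'   `truth`, `filter_report`, `summaries`, `fit`, `stats`, `diagnostics`,
#'   `paths`.
#' @export
run_pipeline <- function(config, out_dir, trials = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  log_add <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  cfg_path <- file.path(out_dir, "config.json")
  writeLines(config_json(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log_add("run: seed=", config$master_seed, " config_md5=", cfg_hash)

  truth <- NULL
  if (is.null(trials)) {
    if (is.null(config$cohort)) {
      stop("stage generate: run_config has no cohort and no trials were supplied",
           call. = FALSE)
    }
    coh <- generate_cohort(config$cohort, seed = config$master_seed)
    trials <- coh$trials
    truth <- coh$truth
    write_csv(truth, file.path(out_dir, "truth.csv"))
    log_add("stage generate: ", nrow(trials), " trials, ",
            length(unique(trials$subject_id)), " subjects")
  } else {
    log_add("stage generate: skipped (", nrow(trials), " trials supplied)")
  }

  if ("exp4" %in% trials$task_id) {
    ex4 <- trials$task_id == "exp4"
    labeled <- classify_switch(trials[ex4, , drop = FALSE])
    trials$switch_label <- NA_character_
    trials$switch_label[ex4] <- labeled$switch_label
  }
  trials <- label_conditions(trials)
  write_csv(trials, file.path(out_dir, "trials.csv"))

  filt <- filter_trials(trials, config$rt_min_ms, config$rt_max_ms)
  log_add(sprintf("stage filter: retained %d/%d (%.2f%%)",
                  filt$report$n_retained, filt$report$n_input,
                  filt$report$retention))
  jsonlite::write_json(
    filt$report[c("n_input", "n_retained", "retention", "excluded",
                  "rt_min_ms", "rt_max_ms")],
    file.path(out_dir, "filter_report.json"), auto_unbox = TRUE, digits = NA)

  fit_rows <- filt$trials$task_id %in% config$fit_tasks &
    !is.na(filt$trials$condition) &
    !grepl("excluded", filt$trials$condition)
  summaries <- summarize_condition(filt$trials[fit_rows, , drop = FALSE])
  log_add("stage summarize: ", nrow(summaries), " cells (",
          sum(summaries$unfit), " unfit)")

  fit <- ez_fit(summaries, s = config$s)
  write_csv(fit$parameters, file.path(out_dir, "parameters.csv"))
  log_add("stage fit: ", sum(!fit$parameters$unfit), " cells fitted, ",
          sum(fit$parameters$edge_corrected), " edge-corrected, ",
          sum(fit$parameters$negative_ter_flag), " negative-Ter flags")

  stats_rep <- analyze_cohort(fit, filt$trials, config)
  diagnostics <- lapply(
    split(seq_len(nrow(fit$parameters)), fit$parameters$task_id),
    function(idx) {
      sub <- fit
      sub$parameters <- fit$parameters[idx, , drop = FALSE]
      sub$summaries <- fit$summaries[idx, , drop = FALSE]
      fit_diagnostics(sub)
    })
  jsonlite::write_json(rapply(stats_rep, sr_json, how = "replace",
                              classes = "stat_result"),
                       file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  jsonlite::write_json(diagnostics, file.path(out_dir, "fit_diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  log_add("stage analyze: ", length(stats_rep), " result groups")

  report <- write_report(list(fit = fit, stats = stats_rep,
                              diagnostics = diagnostics,
                              filter_report = filt$report,
                              config = config, config_hash = cfg_hash))
  writeLines(report, file.path(out_dir, "report.txt"))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(trials = trials, truth = truth, filter_report = filt$report,
                 summaries = summaries, fit = fit, stats = stats_rep,
                 diagnostics = diagnostics, config_hash = cfg_hash,
                 paths = file.path(out_dir, c(
                   "trials.csv", "parameters.csv", "stats_report.json",
                   "fit_diagnostics.json", "report.txt", "run.log"))))
}

write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

# The study's statistical comparisons, computed from the fitted parameters
# and the filtered trials.
analyze_cohort <- function(fit, trials, config) {
  p <- fit$parameters[!fit$parameters$unfit, , drop = FALSE]
  res <- list()

  grp_t <- function(df, measure) {
    x <- df[[measure]][df$group == "RP"]
    y <- df[[measure]][df$group == "control"]
    if (sum(is.finite(x)) < 2 || sum(is.finite(y)) < 2) return(NULL)
    t_test_two_sample(x, y)
  }

  if ("exp1" %in% p$task_id) {
    e1 <- p[p$task_id == "exp1", , drop = FALSE]
    complete <- names(which(table(e1$subject_id) == 3))
    e1c <- e1[e1$subject_id %in% complete, , drop = FALSE]
    exp1 <- list()
    for (m in c("mrt_ms", "v", "a", "ter_ms", "mdt_ms")) {
      exp1[[paste0("anova_", m)]] <- if (length(complete) >= 4)
        as.data.frame(mixed_anova(e1c, m, "subject_id", "group", "condition"))
      else NULL
      # post hoc: group contrast at each eccentricity, Holm-Sidak corrected
      percond <- lapply(split(e1, e1$condition), grp_t, measure = m)
      percond <- percond[!vapply(percond, is.null, TRUE)]
      if (length(percond) >= 2) {
        exp1[[paste0("posthoc_group_by_ecc_", m)]] <- holm_sidak(
          vapply(percond, function(r) r$p_value, 0), labels = names(percond))
      }
    }
    ecc <- as.numeric(sub("ecc_", "", e1$condition))
    for (g in c("RP", "control")) {
      sel <- e1$group == g
      if (sum(sel) >= 3) {
        exp1[[paste0("cor_ecc_rt_", g)]] <-
          pearson_correlation(ecc[sel], e1$mrt_ms[sel])
        exp1[[paste0("cor_ecc_ter_", g)]] <-
          pearson_correlation(ecc[sel], e1$ter_ms[sel])
      }
    }
    res$exp1 <- exp1
  }

  if ("exp2" %in% p$task_id) {
    e2 <- p[p$task_id == "exp2", , drop = FALSE]
    res$exp2 <- lapply(stats::setNames(nm = c("mrt_ms", "v", "a", "ter_ms",
                                              "mdt_ms")),
                       function(m) grp_t(e2, m))
  }

  if ("exp3" %in% trials$task_id) {
    e3 <- trials[trials$task_id == "exp3", , drop = FALSE]
    go <- e3[e3$trial_type == "go" & e3$responded == 1, , drop = FALSE]
    go_rt <- stats::aggregate(rt_ms ~ subject_id + group, data = go, mean)
    exp3 <- list()
    if (all(table(go_rt$group) >= 2)) {
      exp3$go_rt_group <- t_test_two_sample(
        go_rt$rt_ms[go_rt$group == "RP"],
        go_rt$rt_ms[go_rt$group == "control"])
    }
    stp <- e3[startsWith(as.character(e3$condition), "stop_"), , drop = FALSE]
    if (nrow(stp)) {
      acc <- stats::aggregate(correct ~ subject_id + group + condition,
                              data = stp, mean)
      nsub <- length(unique(acc$subject_id))
      if (all(table(acc$subject_id) == 4) && nsub >= 4) {
        exp3$stop_acc_anova <- as.data.frame(
          mixed_anova(acc, "correct", "subject_id", "group", "condition"))
        # post hoc: 800 ms SOA against each shorter SOA
        p800 <- vapply(c("stop_200", "stop_400", "stop_600"), function(cc) {
          t_test_two_sample(acc$correct[acc$condition == cc],
                            acc$correct[acc$condition == "stop_800"])$p_value
        }, 0)
        exp3$posthoc_soa_800 <- holm_sidak(p800, labels = names(p800))
      }
    }
    res$exp3 <- exp3
  }

  if ("exp4" %in% p$task_id) {
    e4 <- p[p$task_id == "exp4", , drop = FALSE]
    parts <- strsplit(e4$condition, "_")
    e4$size <- vapply(parts, `[`, "", 1)
    e4$switch <- vapply(parts, `[`, "", 2)
    exp4 <- list()
    for (sz in c("large", "small")) {
      sub <- e4[e4$size == sz, , drop = FALSE]
      wide_ok <- names(which(table(sub$subject_id) == 2))
      sub <- sub[sub$subject_id %in% wide_ok, , drop = FALSE]
      if (!nrow(sub)) next
      for (m in c("mrt_ms", "ter_ms")) {
        cost <- merge(
          sub[sub$switch == "switching", c("subject_id", "group", m)],
          sub[sub$switch == "sustained", c("subject_id", m)],
          by = "subject_id", suffixes = c("_sw", "_su"))
        cost$cost <- switching_cost(cost[[paste0(m, "_sw")]],
                                    cost[[paste0(m, "_su")]])
        for (g in c("RP", "control")) {
          cg <- cost$cost[cost$group == g]
          if (length(cg) >= 2 && stats::sd(cg) > 0) {
            ht <- stats::t.test(cg)
            exp4[[paste0("cost_", m, "_", sz, "_", g)]] <- stat_result(
              "one-sample t-test (switching cost)", ht$statistic,
              ht$parameter, ht$p.value, estimate = unname(ht$estimate),
              conf_int = unname(ht$conf.int))
          }
        }
        if (all(table(cost$group) >= 2)) {
          exp4[[paste0("cost_", m, "_", sz, "_group")]] <- t_test_two_sample(
            cost$cost[cost$group == "RP"],
            cost$cost[cost$group == "control"])
        }
        if (length(unique(sub$subject_id)) >= 4) {
          exp4[[paste0("anova_", m, "_", sz)]] <- as.data.frame(
            mixed_anova(sub, m, "subject_id", "group", "switch"))
        }
      }
    }
    res$exp4 <- exp4
  }
  res
}

#' Render a human-readable run report
#'
#' @param artifacts The list assembled by [run_pipeline()] (needs `fit`,
#'   `stats`, `diagnostics`, `filter_report`, `config`).
#' @return A character vector of report lines.
#' @export
write_report <- function(artifacts) {
  need <- c("fit", "stats", "diagnostics", "filter_report", "config")
  miss <- setdiff(need, names(artifacts))
  if (length(miss)) {
    stop("write_report(): missing artifact(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  fr <- artifacts$filter_report
  out <- c(
    "EZ-diffusion analysis run report",
    "================================",
    sprintf("seed: %d   config md5: %s", artifacts$config$master_seed,
            if (is.null(artifacts$config_hash)) "-" else artifacts$config_hash),
    sprintf("RT window: [%g, %g] ms; retention %.2f%% (%d of %d trials)",
            fr$rt_min_ms, fr$rt_max_ms, fr$retention, fr$n_retained,
            fr$n_input),
    "")
  sm <- summary(artifacts$fit)
  out <- c(out, "Group means with 95% CI (per task x condition):",
           utils::capture.output(print(sm)), "")
  for (task in names(artifacts$diagnostics)) {
    dg <- artifacts$diagnostics[[task]]
    out <- c(out, sprintf("%s fit check: R^2 = %.3f (accuracy), %.3f (RT)",
                          task, dg$r2_accuracy, dg$r2_rt))
  }
  out <- c(out, "")
  for (task in names(artifacts$stats)) {
    out <- c(out, paste0("--- ", task, " ---"))
    blk <- artifacts$stats[[task]]
    for (nm in names(blk)) {
      x <- blk[[nm]]
      if (is.null(x)) next
      out <- c(out, paste0(nm, ":"),
               paste0("  ", utils::capture.output(print(x))))
    }
    out <- c(out, "")
  }
  if (!"exp4" %in% names(artifacts$stats)) {
    out <- c(out, "(no switching task in this run: switching-cost section omitted)")
  }
  out
}
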