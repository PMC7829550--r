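#' Mixed-design (split-plot) two-way ANOVA
#'
#' The classical mixed-design decomposition for one between-subjects factor
#' (group) and one within-subjects factor (condition), applied to
#' subject-level cell means.  Every subject must be observed exactly once in
#' every condition; group sizes may differ.
#'
#' Sums of squares are the definitional ones for this design (with `w`
#' within levels, `n_j` subjects in group j, N subjects in total):
#' * group: `w * sum_j n_j (mean_j - grand)^2`, tested against the
#'   subjects-within-group mean square;
#' * subjects(group): `w * sum_subj (subj mean - group mean)^2`;
#' * condition: `N * sum_k (mean_k - grand)^2` and
#'   group x condition: `sum_jk n_j (cell_jk - mean_j - mean_k + grand)^2`,
#'   both tested against the condition x subjects(group) residual.
#'
#' A zero residual (or subject) mean square makes the corresponding F
#' undefined; such tests are flagged `degenerate` and reported with `NA`
#' statistics, never infinities.
#'
#' @param data Long-format `data.frame` of subject-level cell means.
#' @param dv Name of the response column.
#' @param subject,between,within Names of the subject identifier, group
#'   factor and condition factor columns.
#' @return A `data.frame` of class `"mixed_anova"`: one row per source
#'   (`group`, `subjects(group)`, `condition`, `group:condition`,
#'   `residual`) with `df`, `ss`, `ms`, `F`, `p` and `degenerate`.
#' @examples
#' d <- expand.grid(subject = paste0("s", 1:6), cond = c("c1", "c2"))
#' d$grp <- ifelse(d$subject %in% c("s1", "s2", "s3"), "g1", "g2")
#' set.seed(1); d$y <- rnorm(nrow(d))
#' mixed_anova(d, "y", "subject", "grp", "cond")
#' @export
mixed_anova <- function(data, dv, subject, between, within) {
  stopifnot(is.data.frame(data),
            all(c(dv, subject, between, within) %in% names(data)))
  y <- data[[dv]]
  subj <- as.character(data[[subject]])
  grp <- as.character(data[[between]])
  cond <- as.character(data[[within]])
  if (any(!is.finite(y))) stop("response contains non-finite values", call. = FALSE)

  subj_grp <- tapply(grp, subj, function(g) unique(g))
  if (any(lengths(subj_grp) != 1)) {
    stop("each subject must belong to exactly one group", call. = FALSE)
  }
  tab <- table(subj, cond)
  if (any(tab != 1)) {
    stop("design must be balanced within subjects: every subject observed ",
         "exactly once in every condition", call. = FALSE)
  }
  if (any(table(unlist(subj_grp)) < 2)) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }

  w <- length(unique(cond))
  grand <- mean(y)
  subj_means <- tapply(y, subj, mean)
  grp_of_subj <- unlist(subj_grp)[names(subj_means)]
  grp_means <- tapply(y, grp, mean)
  cond_means <- tapply(y, cond, mean)
  cell_means <- tapply(y, list(grp, cond), mean)
  n_j <- table(unlist(subj_grp))
  N <- length(subj_means)
  g <- length(grp_means)

  ss_total <- sum((y - grand)^2)
  ss_group <- w * sum(n_j[names(grp_means)] * (grp_means - grand)^2)
  ss_subj <- w * sum((subj_means - grp_means[grp_of_subj])^2)
  ss_cond <- N * sum((cond_means - grand)^2)
  ss_int <- 0
  for (j in rownames(cell_means)) for (k in colnames(cell_means)) {
    ss_int <- ss_int + n_j[[j]] *
      (cell_means[j, k] - grp_means[[j]] - cond_means[[k]] + grand)^2
  }
  ss_res <- ss_total - ss_group - ss_subj - ss_cond - ss_int

  df <- c(group = g - 1, `subjects(group)` = N - g, condition = w - 1,
          `group:condition` = (g - 1) * (w - 1),
          residual = (N - g) * (w - 1))
  ss <- c(ss_group, ss_subj, ss_cond, ss_int, max(ss_res, 0))
  ms <- ss / df
  ms_subj <- ms[2]
  ms_res <- ms[5]
  eps <- sqrt(.Machine$double.eps)
  f <- c(if (ms_subj > eps * max(ss_total, 1)) ms[1] / ms_subj else NA,
         NA,
         if (ms_res > eps * max(ss_total, 1)) ms[3] / ms_res else NA,
         if (ms_res > eps * max(ss_total, 1)) ms[4] / ms_res else NA,
         NA)
  err_df <- c(df[2], NA, df[5], df[5], NA)
  p <- ifelse(is.na(f), NA, stats::pf(f, df, err_df, lower.tail = FALSE))
  out <- data.frame(
    term = names(df), df = as.numeric(df), ss = ss, ms = ms,
    F = f, df_error = err_df, p = p,
    degenerate = c(is.na(f[1]), NA, is.na(f[3]), is.na(f[4]), NA))
  rownames(out) <- NULL
  class(out) <- c("mixed_anova", "data.frame")
  attr(out, "ss_total") <- ss_total
  out
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("Mixed-design ANOVA (between: group; within: condition)\n")
  df <- as.data.frame(x)
  for (cc in c("ss", "ms", "F")) df[[cc]] <- signif(df[[cc]], 5)
  df$p <- signif(df$p, 4)
  print.data.frame(df, row.names = FALSE)
  if (any(x$degenerate, na.rm = TRUE)) {
    cat("note: degenerate error term; flagged F tests are undefined\n")
  }
  invisible(x)
}
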