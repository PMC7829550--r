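# Shared fixtures, built in code.

# Small trial table with known arithmetic: 3 correct RTs (400, 500, 600) ms
# and one incorrect response.
toy_cell_trials <- function() {
  data.frame(subject_id = "s1", group = "control", task_id = "demo",
             condition = "c1", rt_ms = c(400, 500, 600, 700),
             correct = c(1, 1, 1, 0), responded = 1)
}

# The split-plot toy data set with a zero residual stratum:
# 2 groups x 2 subjects x 2 conditions.
toy_anova_data <- function() {
  data.frame(
    subject = rep(c("s1", "s2", "s3", "s4"), each = 2),
    grp = rep(c("g1", "g2"), each = 4),
    cond = rep(c("c1", "c2"), 4),
    y = c(10, 12, 14, 16, 20, 26, 24, 30))
}

# Independent definitional oracle for the mixed-design SS decomposition,
# written against stats::aov's strata (Type I, Error(subject)).
aov_ss <- function(data, dv, subject, between, within) {
  d <- data.frame(y = data[[dv]], subj = factor(data[[subject]]),
                  grp = factor(data[[between]]), cond = factor(data[[within]]))
  fit <- stats::aov(y ~ grp * cond + Error(subj), data = d)
  sm <- summary(fit)
  btw <- sm[["Error: subj"]][[1]]
  wth <- sm[["Error: Within"]][[1]]
  ss_of <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    if (is.na(i)) NA_real_ else tab[i, "Sum Sq"]
  }
  c(group = ss_of(btw, "grp"), subjects = ss_of(btw, "Residuals"),
    condition = ss_of(wth, "cond"), interaction = ss_of(wth, "grp:cond"),
    residual = ss_of(wth, "Residuals"))
}

# Draw a random balanced-within cohort table for property tests.
random_anova_table <- function(n1, n2, w) {
  subj <- c(paste0("a", seq_len(n1)), paste0("b", seq_len(n2)))
  grp <- rep(c("g1", "g2"), c(n1, n2))
  d <- expand.grid(subject = subj, cond = paste0("c", seq_len(w)),
                   stringsAsFactors = FALSE)
  d$grp <- grp[match(d$subject, subj)]
  d$y <- stats::rnorm(nrow(d))
  d
}

# Enumeration oracle for the two-sided Fisher exact p (minimum-likelihood
# rule) on a 2x2 table.
fisher_enum_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
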