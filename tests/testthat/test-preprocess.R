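test_that("RT window filter keeps inclusive bounds and reports reasons", {
  tr <- data.frame(rt_ms = c(150, 200, 1000, 3000, 3500, NA),
                   responded = c(1, 1, 1, 1, 1, 0), correct = 1)
  out <- filter_trials(tr)
  expect_equal(out$report$n_retained, 3)
  expect_equal(out$trials$rt_ms, c(200, 1000, 3000))
  expect_equal(out$report$excluded[["no response"]], 1)
  expect_equal(out$report$excluded[["rt below min"]], 1)
  expect_equal(out$report$excluded[["rt above max"]], 1)
  expect_equal(out$report$retention, 100 * 3 / 6)

  all_in <- data.frame(rt_ms = c(300, 400), responded = 1, correct = 1)
  expect_equal(filter_trials(all_in)$report$retention, 100.0)

  empty <- filter_trials(data.frame(rt_ms = numeric(), responded = numeric()))
  expect_equal(empty$report$n_input, 0L)
  expect_equal(nrow(empty$trials), 0)
  expect_error(filter_trials(all_in, 3000, 200), "rt_min_ms")
})

test_that("filtering is idempotent and loses no trial to double counting", {
  set.seed(10)
  tr <- data.frame(rt_ms = runif(500, 0, 4000),
                   responded = rbinom(500, 1, 0.95), correct = 1,
                   subject_id = rep(c("s1", "s2"), 250), group = "g",
                   task_id = "demo", condition = rep(c("c1", "c2"), each = 250))
  once <- filter_trials(tr)
  twice <- filter_trials(once$trials)
  expect_identical(once$trials, twice$trials)
  expect_equal(twice$report$retention, 100)
  sums <- summarize_condition(once$trials)
  expect_equal(sum(sums$n_trials), once$report$n_retained)
  expect_equal(sums$pc, sums$n_correct / sums$n_trials)
})

test_that("switch classification follows the cue sequence rule", {
  tr <- data.frame(subject_id = "s1", index = 1:5,
                   cue_color = c("R", "R", "G", "G", "R"))
  expect_equal(classify_switch(tr)$switch_label,
               c("excluded", "sustained", "switching", "sustained",
                 "switching"))
  same <- data.frame(subject_id = "s1", index = 1:4, cue_color = "R")
  expect_equal(classify_switch(same)$switch_label,
               c("excluded", rep("sustained", 3)))
  alt <- data.frame(subject_id = "s1", index = 1:4,
                    cue_color = c("R", "G", "R", "G"))
  expect_equal(classify_switch(alt)$switch_label,
               c("excluded", rep("switching", 3)))
  # order column is required, and labelling respects it, not row order
  shuffled <- tr[c(3, 1, 5, 2, 4), ]
  expect_equal(classify_switch(shuffled)$switch_label,
               c("switching", "excluded", "switching", "sustained",
                 "sustained"))
  expect_error(classify_switch(tr[, c("subject_id", "cue_color")]), "index")
})

test_that("condition summaries match hand arithmetic", {
  s <- summarize_condition(toy_cell_trials(), min_correct = 2)
  expect_equal(s$n_trials, 4)
  expect_equal(s$pc, 0.75)
  expect_equal(s$mrt, 0.5)
  expect_equal(s$vrt, 0.01)   # unbiased variance of (0.4, 0.5, 0.6) s
  expect_false(s$unfit)

  ident <- data.frame(subject_id = "s1", condition = "c1",
                      rt_ms = rep(500, 6), correct = 1)
  si <- summarize_condition(ident)
  expect_equal(si$vrt, 0)
  expect_true(si$unfit)   # zero variance cannot be inverted

  few <- data.frame(subject_id = "s1", condition = "c1",
                    rt_ms = c(400, 500, 480), correct = 1)
  expect_true(summarize_condition(few, min_correct = 5)$unfit)
})

test_that("summaries of simulated cells converge to the forward moments", {
  set.seed(21)
  n <- 40000
  sim <- simulate_condition(diffusion_spec(0.25, 0.12, 0.28, dt = 5e-4), n)
  tr <- data.frame(subject_id = "s1", condition = "c1",
                   rt_ms = sim$rt * 1000, correct = sim$correct)
  s <- summarize_condition(tr)
  m <- ez_forward(0.25, 0.12, 0.28)
  se_pc <- sqrt(m$pc * (1 - m$pc) / n)
  expect_lt(abs(s$pc - m$pc), 4 * se_pc)
  expect_lt(abs(s$mrt - m$mrt), 0.01)
  expect_lt(abs(s$vrt - m$vrt) / m$vrt, 0.08)
})

test_that("analysis condition labels cover the four tasks", {
  tr <- data.frame(
    task_id = c("exp1", "exp2", "exp3", "exp3", "exp4"),
    eccentricity_deg = c(5, NA, NA, NA, NA),
    trial_type = c(NA, NA, "go", "stop", NA),
    soa_ms = c(NA, NA, NA, 400, NA),
    size = c(NA, NA, NA, NA, "large"),
    switch_label = c(NA, NA, NA, NA, "switching"))
  lab <- label_conditions(tr)
  expect_equal(lab$condition,
               c("ecc_5", "pooled", "go", "stop_400", "large_switching"))
  expect_error(label_conditions(tr[5, setdiff(names(tr), "switch_label")]),
               "classify_switch")
})
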