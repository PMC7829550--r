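test_that("logit matches its closed form and rejects the boundary", {
  expect_identical(logit(0.5), 0)
  expect_equal(logit(1 / (1 + exp(-2))), 2)
  expect_equal(logit(1 - 1 / (1 + exp(-2))), -2)
  p <- runif(20, 0.01, 0.99)
  expect_equal(logit(1 - p), -logit(p))
  expect_error(logit(0), "edge")
  expect_error(logit(1), "edge")
})

test_that("edge correction nudges 0, 1/2 and 1 inward by half a trial", {
  expect_equal(edge_correct(1, 44), 1 - 1 / 88)
  expect_equal(edge_correct(0, 44), 1 / 88)
  expect_equal(edge_correct(0.5, 100), 0.505)
  expect_equal(edge_correct(0.75, 44), 0.75)
  out <- edge_correct(c(0, 0.3, 0.5, 1), 10)
  expect_true(all(out > 0 & out < 1 & out != 0.5))
})

test_that("forward moments match the closed forms evaluated by hand", {
  # at v = 0.2, a = 0.1, s = 0.1: y = -2
  m <- ez_forward(v = 0.2, a = 0.1, ter = 0.3, s = 0.1)
  expect_equal(m$pc, 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(m$pc, 0.880797, tolerance = 1e-6)
  expect_equal(m$mdt, 0.190399, tolerance = 1e-5)
  expect_equal(m$vrt, 0.021351, tolerance = 2e-5)
  expect_equal(m$mrt, m$mdt + 0.3)
  expect_equal(ez_forward(v = 0.5, a = 0.2, ter = 0.2)$pc, 1 / (1 + exp(-10)))
})

test_that("reflected drift mirrors accuracy and keeps the time moments", {
  m_pos <- ez_forward(0.3, 0.12, 0.2)
  m_neg <- ez_forward(-0.3, 0.12, 0.2)
  expect_equal(m_pos$pc + m_neg$pc, 1)
  expect_equal(m_pos$mdt, m_neg$mdt)
  expect_equal(m_pos$vrt, m_neg$vrt)
})

test_that("forward model rejects v = 0 and bad a or s", {
  expect_error(ez_forward(0, 0.1, 0.3), "chance")
  expect_error(ez_forward(0.2, -0.1, 0.3), "positive")
})

test_that("inversion recovers the exact round-trip example", {
  est <- ez_inverse(pc = 0.880797, mrt = 0.490399, vrt = 0.021351)
  expect_equal(est$v, 0.2, tolerance = 1e-5)
  expect_equal(est$a, 0.1, tolerance = 1e-5)
  expect_equal(est$ter, 0.3, tolerance = 1e-5)
  # inner bracket of the drift formula is 16 at this point: fourth root 2
  L <- logit(est$pc)
  expect_equal((L * (est$pc^2 * L - est$pc * L + est$pc - 0.5) /
                  0.021351)^0.25, 2, tolerance = 1e-4)
})

test_that("inversion enforces its domain and flags negative Ter", {
  expect_error(ez_inverse(pc = 0.5, mrt = 0.4, vrt = 0.02), "domain")
  expect_error(ez_inverse(pc = 1, mrt = 0.4, vrt = 0.02), "domain")
  expect_error(ez_inverse(pc = 0.8, mrt = 0.4, vrt = 0), "vrt")
  est <- ez_inverse(pc = 0.5, mrt = 0.4, vrt = 0.02, n_trials = 44,
                    correct_edges = TRUE)
  expect_true(est$edge_corrected)
  # negative Ter is retained and flagged, not clipped
  m <- ez_forward(0.2, 0.1, 0)
  est <- ez_inverse(pc = m$pc, mrt = 0.05, vrt = m$vrt)
  expect_true(est$negative_ter)
  expect_lt(est$ter, 0)
})

test_that("forward/inverse round trip is exact on a parameter grid", {
  grid <- expand.grid(v = seq(0.05, 0.6, length.out = 6),
                      a = seq(0.05, 0.25, length.out = 5),
                      ter = seq(0.1, 0.6, length.out = 4))
  max_err <- 0
  for (i in seq_len(nrow(grid))) {
    m <- ez_forward(grid$v[i], grid$a[i], grid$ter[i])
    est <- ez_inverse(pc = m$pc, mrt = m$mrt, vrt = m$vrt)
    max_err <- max(max_err,
                   abs(est$v - grid$v[i]), abs(est$a - grid$a[i]),
                   abs(est$ter - grid$ter[i]),
                   abs(est$mdt + est$ter - m$mrt))
  }
  expect_lt(max_err, 1e-9)
})

test_that("predicted accuracy is monotone in drift and boundary", {
  v <- seq(0.05, 0.6, length.out = 20)
  pc_v <- ez_forward(v, a = 0.12, ter = 0.2)$pc
  expect_true(all(diff(pc_v) > 0))
  a <- seq(0.05, 0.25, length.out = 20)
  pc_a <- ez_forward(0.3, a, ter = 0.2)$pc
  expect_true(all(diff(pc_a) > 0))
})

test_that("moments are invariant to a common rescaling of s, v and a", {
  for (k in c(0.5, 2, 10)) {
    m1 <- ez_forward(0.25, 0.11, 0.3, s = 0.1)
    m2 <- ez_forward(0.25 * k, 0.11 * k, 0.3, s = 0.1 * k)
    expect_equal(m1$pc, m2$pc)
    expect_equal(m1$mdt, m2$mdt)
    expect_equal(m1$vrt, m2$vrt)
  }
})

test_that("ez_fit handles unfit cells and reports the spec's schema", {
  sums <- data.frame(
    subject_id = c("s1", "s2"), group = "control", task_id = "demo",
    condition = "c1",
    n_trials = c(44, 44), n_correct = c(40, 44), pc = c(40 / 44, 1),
    mrt = c(0.5, 0.45), vrt = c(0.012, 0))
  fit <- ez_fit(sums)
  expect_s3_class(fit, "ez_fit")
  p <- fit$parameters
  expect_true(all(c("v", "a", "ter_ms", "mdt_ms", "pc", "mrt_ms", "vrt_ms2",
                    "edge_corrected", "negative_ter_flag") %in% names(p)))
  expect_false(p$unfit[1])
  expect_true(p$unfit[2])      # zero variance cell is unfit
  expect_true(is.na(p$v[2]))
  expect_gt(p$v[1], 0)
  expect_equal(p$mdt_ms[1] + p$ter_ms[1], 500, tolerance = 1e-9)
})

test_that("ez_fit methods are coherent: coef, predict, residuals, simulate", {
  set.seed(42)
  sim <- simulate_condition(diffusion_spec(0.25, 0.1, 0.3), n = 400)
  tr <- data.frame(subject_id = "s1", group = "control", task_id = "demo",
                   condition = "c1", rt_ms = sim$rt * 1000,
                   correct = sim$correct, responded = 1)
  fit <- ez_fit(summarize_condition(tr))
  expect_equal(nrow(coef(fit)), 1)
  pr <- predict(fit)
  # the fit reproduces the observed summaries it was estimated from
  expect_equal(pr$pc_hat, fit$parameters$pc, tolerance = 1e-9)
  expect_equal(pr$mrt_hat_ms, fit$parameters$mrt_ms, tolerance = 1e-6)
  r <- residuals(fit)
  expect_equal(r$resid_pc, 0, tolerance = 1e-9)
  boot <- simulate(fit, nsim = 2, seed = 1)
  expect_length(boot, 2)
  expect_equal(boot[[1]]$n_trials, 400)
  expect_false(identical(boot[[1]]$pc, boot[[2]]$pc))
})
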