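test_that("the conventional critical value is analytic, exact, and m2-free", {
  d <- design5()
  expect_equal(conventional_critical(d), qnorm(1 - 0.025 / (5 / 6)))
  expect_equal(round(conventional_critical(d), 3), 1.881)
  d1 <- seam_design(K = 1, m1 = 10, m2 = 50, ell = -Inf, sigma = 1)
  expect_equal(conventional_critical(d1), qnorm(0.975), tolerance = 1e-9)
  for (m2 in c(70, 140, 280))
    expect_equal(conventional_critical(seam_design(5, 28, m2, 0, 5, 0.025)),
                 conventional_critical(d))
  ## a futility gate so strict that continuation is rarer than alpha
  expect_error(conventional_critical(seam_design(1, 100, 10, ell = 1, sigma = 1)),
               "cannot be calibrated")
})

test_that("the pooled statistic uses the stated weights and pools information", {
  d <- design5()
  w1 <- sqrt(28 / 168); w2 <- sqrt(140 / 168)
  expect_equal(w1, 0.4082483, tolerance = 1e-6)
  expect_equal(w2, 0.9128709, tolerance = 1e-6)
  r <- seam_rule("tse", d)
  expect_equal(r$w1, w1); expect_equal(r$w2, w2)
  tr <- make_trial(seam_design(5, 30, 30, 0, 5), c(0, 0, 0, 0, 2) * 1,
                   2 * 5 * sqrt(2) / sqrt(30))
  ## equal weights: w1 Z1 + w2 Z2 at Z1 = Z2 = 2 gives 2 sqrt(2)
  tr$z1[tr$selected] <- 2; tr$z2 <- 2
  expect_equal(tse_statistic(tr, 1 / sqrt(2), 1 / sqrt(2)), 2 * sqrt(2))
  ## z-scale statistic proportional to m1 * th1 + m2 * th2 on random trials
  set.seed(3)
  scale_const <- NULL
  for (i in 1:20) {
    th1 <- rnorm(5); th1[which.max(th1)] <- abs(max(th1))
    tr <- make_trial(d, th1, rnorm(1))
    pooled <- d$m1 * tr$theta_hat1[tr$selected] + d$m2 * tr$theta_hat2
    ratio <- tse_statistic(tr) / pooled
    if (is.null(scale_const)) scale_const <- ratio
    expect_equal(ratio, scale_const, tolerance = 1e-10)
  }
  expect_gt(scale_const, 0)
  expect_error(tse_statistic(make_trial(d, rep(-1, 5))), "stage-2")
})

test_that("rule evaluation dispatches correctly and guards its contracts", {
  d <- design5()
  conv <- seam_rule("conventional", d)
  stopped <- make_trial(d, rep(-2, 5))
  dec <- evaluate_rule(conv, stopped)
  expect_equal(dec$action, "A0"); expect_false(dec$rejected)
  tr <- make_trial(d, c(0, 0, 0, 0, 1), 3.0 * d$sigma * sqrt(2) / sqrt(d$m2))
  expect_true(evaluate_rule(conv, tr)$rejected)          # z2 = 3 vs 1.881
  expect_equal(evaluate_rule(conv, tr)$action, "A5")
  tr_low <- make_trial(d, c(0, 0, 0, 0, 1), 1.5 * d$sigma * sqrt(2) / sqrt(d$m2))
  expect_false(evaluate_rule(conv, tr_low)$rejected)
  ## design mismatch and uncalibrated rules are refused
  other <- make_trial(seam_design(5, 30, 140, 0, 5), c(0, 0, 0, 0, 1), 1)
  expect_error(evaluate_rule(conv, other), "does not match")
  expect_error(evaluate_rule(seam_rule("tse", d), tr), "calibrated")
})

test_that("calibrated rules reject at the nominal rate under the null", {
  d <- design5()
  R <- 1e5
  for (id in c("tse", "bk_invnormal_dunnett")) {
    r <- calibrate_critical(seam_rule(id, d), replications = R, seed = 111)
    chk <- estimate_fwer(r, replications = R, seed = 112)
    expect_lt(abs(chk$estimate - 0.025), 3 * chk$se + 3 * r$calibration$se)
  }
})

test_that("decisions are invariant to rescaling sigma with the responses", {
  d1 <- design5()
  d2 <- seam_design(5, 28, 140, 0, 5 * 3, 0.025)
  n <- simulate_null_normals(5e3, 5, seed = 121)
  b1 <- batch_from_normals(n, d1, c(0, 0, 0, 0, 1))
  b2 <- batch_from_normals(n, d2, c(0, 0, 0, 0, 3))  # everything scaled by 3
  sc1 <- make_scenario(0.3, delta = 1, kind = "single", K = 5)
  sc2 <- make_scenario(0.3, delta = 3, kind = "single", K = 5)
  nb1 <- batch_from_normals(simulate_null_normals(5e4, 5, 122), d1, rep(0, 5))
  nb2 <- batch_from_normals(simulate_null_normals(5e4, 5, 122), d2, rep(0, 5))
  for (spec in list(list("tse", NULL), list("optimal_single", sc1))) {
    r1 <- seam_rule(spec[[1]], d1, scenario = spec[[2]],
                    gamma = if (!is.null(spec[[2]])) spec[[2]]$gammas[1] else NULL)
    r2 <- seam_rule(spec[[1]], d2, scenario = if (!is.null(spec[[2]])) sc2 else NULL,
                    gamma = if (!is.null(spec[[2]])) 0.3 else NULL)
    r1 <- seamsel:::calibrate_on_batch(r1, nb1, 0.025)
    r2 <- seamsel:::calibrate_on_batch(r2, nb2, 0.025)
    expect_identical(seamsel:::evaluate_batch_critical(r1, b1, r1$critical),
                     seamsel:::evaluate_batch_critical(r2, b2, r2$critical))
  }
})

test_that("the rule registry serializes calibration provenance", {
  d <- design_small()
  r <- calibrate_critical(seam_rule("tse", d), replications = 2e4, seed = 131)
  path <- withr::local_tempfile(fileext = ".json")
  write_rule_registry(list(r, seam_rule("conventional", d)), path)
  reg <- jsonlite::read_json(path)
  expect_length(reg, 2)
  expect_equal(reg[[1]]$rule_id, "tse")
  expect_equal(reg[[1]]$calibration$seed, 131)
  expect_equal(reg[[1]]$critical, r$critical, tolerance = 1e-12)
})
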