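test_that("marginal and Simes p-values follow their closed forms", {
  expect_equal(marginal_pvalue(0), 0.5)
  expect_equal(marginal_pvalue(1.959964), 0.025, tolerance = 1e-6)
  expect_equal(marginal_pvalue(-Inf), 1)
  expect_equal(simes_pvalue(c(0.01, 0.04)), 0.02)
  expect_equal(simes_pvalue(0.37), 0.37)
  expect_equal(simes_pvalue(c(0.5, 0.5, 0.5)), 0.5)
  expect_error(simes_pvalue(numeric(0)), "empty")
  ## bounds: at least the smallest p, at most n times it
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(2:6, 1))
    s <- simes_pvalue(p)
    expect_gte(s, min(p))
    expect_lte(s, min(1, length(p) * min(p)))
  }
})

test_that("Dunnett p-values match exchangeability values and the marginal case", {
  expect_equal(dunnett_pvalue(1.959964), 0.025, tolerance = 1e-6)
  expect_equal(dunnett_pvalue(c(0, 0)), 2 / 3, tolerance = 1e-8)
  expect_equal(dunnett_pvalue(rep(0, 5)), 5 / 6, tolerance = 1e-8)
  expect_error(dunnett_pvalue(numeric(0)), "empty")
})

test_that("Dunnett quadrature agrees with an equicorrelated MVN oracle", {
  for (n in c(2, 4, 5)) for (t in c(-1.5, 0, 1.3, 2.8)) {
    expect_equal(dunnett_pvalue(c(rep(-5, n - 1), t)),
                 oracle_dunnett(c(rep(-5, n - 1), t), use_mvtnorm = TRUE),
                 tolerance = 1e-6)
  }
  ## vectorized interpolation path against the exact scalar path
  z <- seq(-6, 7, by = 0.37)
  vec <- seamsel:::dunnett_tail_vec(z, 5)
  exact <- vapply(z, function(t) dunnett_pvalue(c(rep(-50, 4), t)), 0)
  expect_lt(max(abs(vec - exact)), 1e-7)
})

test_that("combination functions follow their stated scales", {
  expect_equal(combine_pvalues(0.05, 0.05, "inverse_chisq"), -log(0.0025))
  ## unadjusted reference on the -ln(p1 p2) scale: chi^2_4 quantile over two
  expect_equal(qchisq(1 - 0.025, df = 4) / 2, 5.571643, tolerance = 1e-6)
  expect_equal(combine_pvalues(0.025, 0.025, "inverse_normal",
                               w1 = 1 / sqrt(2), w2 = 1 / sqrt(2)),
               sqrt(2) * qnorm(0.975), tolerance = 1e-6)
  expect_error(combine_pvalues(0.1, 0.1, "inverse_normal", w1 = 0.9, w2 = 0.9),
               "w1\\^2 \\+ w2\\^2")
  expect_warning(s <- combine_pvalues(0, 0.5, "inverse_chisq"), "saturates")
  expect_equal(s, Inf)
})

test_that("the closed test reduces to a single combination test for K = 1", {
  d <- seam_design(K = 1, m1 = 10, m2 = 20, ell = -Inf, sigma = 2)
  tr <- make_trial(d, 1.2, 0.8)
  w1 <- sqrt(10 / 30); w2 <- sqrt(20 / 30)
  stat <- combine_pvalues(marginal_pvalue(tr$z1), marginal_pvalue(tr$z2),
                          "inverse_normal", w1 = w1, w2 = w2)
  expect_true(closed_test_reject(tr, "inverse_normal", "simes", stat - 1e-9))
  expect_false(closed_test_reject(tr, "inverse_normal", "simes", stat + 1e-9))
})

test_that("overwhelming evidence is rejected and stopped trials are refused", {
  d <- design5()
  tr <- make_trial(d, c(0, 0, 0, 0, 30), 30)
  suppressWarnings({   # saturated p-values warn by design
    expect_true(closed_test_reject(tr, "inverse_normal", "dunnett", 4))
    expect_true(closed_test_reject(tr, "inverse_chisq", "simes", 20))
  })
  stopped <- make_trial(d, rep(-1, 5))
  expect_error(intersection_table(stopped), "continued")
})

test_that("the binding-subset reduction agrees with explicit enumeration", {
  d <- design5()
  set.seed(7)
  b <- simulate_batch(d, c(0.3, 0, 0.5, 0, 1), 300, seed = 91)
  for (meth in c("simes", "dunnett")) {
    M_fast <- seamsel:::max_stage1_pvalue(b$z1, b$selected, meth)
    M_slow <- vapply(seq_len(300), function(i)
      oracle_max_p1(b$z1[i, ], b$selected[i], meth), 0)
    expect_lt(max(abs(M_fast - M_slow)), 1e-7)
  }
})

test_that("closed-testing decisions match the brute-force full-closure oracle", {
  d <- seam_design(K = 4, m1 = 12, m2 = 36, ell = 0, sigma = 3)
  R <- 1e4
  b <- simulate_batch(d, c(0, 0.2, 0.4, 0.6), R, seed = 101)
  idx <- continuing(b)
  cases <- list(c("inverse_normal", "simes", 1.9),
                c("inverse_normal", "dunnett", 1.95),
                c("inverse_chisq", "simes", 5.3),
                c("inverse_chisq", "dunnett", 5.5))
  for (cs in cases) {
    meth <- cs[1]; int <- cs[2]; crit <- as.numeric(cs[3])
    id <- paste0("bk_", if (meth == "inverse_chisq") "invchisq" else "invnormal",
                 "_", int)
    rule <- seam_rule(id, d)
    fast <- seamsel:::evaluate_batch_critical(rule, b, crit)
    slow <- vapply(idx, function(i)
      oracle_closure_reject(trial_view(b, i), meth, int, crit), NA)
    expect_identical(unname(fast[idx]), unname(slow))
    expect_false(any(fast[-idx]))
  }
})

test_that("closed-test decisions are monotone in both stage statistics", {
  d <- design5()
  set.seed(5)
  for (i in 1:25) {
    th1 <- rnorm(5, 0, 1.5)
    th1[which.max(th1)] <- abs(max(th1)) + 0.2   # ensure continuation
    for (id in c("bk_invnormal_simes", "bk_invchisq_dunnett")) {
      rule <- seam_rule(id, d)
      crit <- if (grepl("chisq", id)) 5.4 else 1.9
      z2s <- seq(-1, 4, by = 0.5)
      dec2 <- vapply(z2s, function(z2) {
        tr <- make_trial(d, th1, z2 * d$sigma * sqrt(2) / sqrt(d$m2))
        closed_test_reject(tr, if (grepl("chisq", id)) "inverse_chisq" else "inverse_normal",
                           if (grepl("simes", id)) "simes" else "dunnett", crit)
      }, NA)
      expect_true(all(diff(dec2) >= 0))  # once rejecting, stays rejecting
    }
  }
})
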