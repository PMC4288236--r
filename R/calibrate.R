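## ---- critical-value calibration --------------------------------------------

## Conditional familywise error rate at a critical value, on a null stage-1
## ensemble: the stage-2 statistic is pivotal given continuation, so its tail
## probability beyond the per-replicate rejection threshold is integrated
## analytically. Returns the estimate and the MC standard error (over stage-1
## replicates only).
fwer_conditional <- function(rule, info, continued, critical) {
  thr <- rule_z2_threshold(rule, info, critical)
  p <- ifelse(continued, stats::pnorm(thr, lower.tail = FALSE), 0)
  list(estimate = mean(p), se = stats::sd(p) / sqrt(length(p)))
}

## per-replicate full statistics on a null batch (stopped trials -> -Inf)
null_statistics <- function(rule, batch) {
  info <- rule_stage1_info(rule, batch$theta_hat1, batch$z1, batch$selected)
  s <- rule_statistic_values(rule, info, batch$z2)
  s[!batch$continued] <- -Inf
  list(info = info, stats = s)
}

## empirical-quantile critical: midpoint between the order statistics that
## bracket a rejection fraction of alpha (largest attainable fraction <= alpha)
quantile_critical <- function(stats, alpha) {
  R <- length(stats)
  k <- max(1L, floor(alpha * R))
  ss <- sort(stats, decreasing = TRUE)[c(k, k + 1L)]
  mean(ss)
}

## Robbins-Monro stochastic approximation for the (1 - alpha) rejection
## boundary: one pass over the statistic stream with steps a/n, warm-started
## at a pilot quantile, with Polyak-Ruppert averaging of the second half.
## The asymptotically efficient gain is the reciprocal of the statistic's
## density at the target quantile, estimated from the pilot sample.
robbins_monro_critical <- function(stats, alpha) {
  R <- length(stats)
  pilot <- stats[seq_len(min(10000L, R))]
  pilot <- pilot[is.finite(pilot)]
  c_n <- stats::quantile(pilot, 1 - alpha, names = FALSE, type = 8)
  h <- max(stats::sd(pilot) / 4, 1e-3)
  dens <- max(mean(abs(pilot - c_n) <= h) / (2 * h), 1e-4)
  a <- 1 / dens
  trace_sum <- 0; half <- floor(R / 2)
  for (n in seq_len(R)) {
    c_n <- c_n + (a / n) * ((stats[n] >= c_n) - alpha)
    if (n > half) trace_sum <- trace_sum + c_n
  }
  trace_sum / (R - half)
}

#' Estimate a rule's familywise error rate by simulation
#'
#' Simulates a null ensemble (all effects zero) and evaluates the rule at the
#' supplied critical value; under the global null every rejection is a
#' familywise error. Supplying a non-null `theta` turns this into a
#' spot-check of the error rate elsewhere in the parameter space: rejections
#' are then counted only when the selected arm's effect is non-positive
#' (rejecting a false null is not an error).
#'
#' @param rule A `seam_rule`.
#' @param critical Critical value to evaluate (defaults to the rule's).
#' @param design Design to simulate under (defaults to the rule's).
#' @param replications Number of replicates; below 1e4 a warning is issued
#'   (the binomial standard error is then too large for calibration).
#' @param seed Integer seed.
#' @param theta Effect configuration (default all-zero).
#' @return A list with `estimate`, `se` (binomial), `replications`, `seed`.
#' @export
estimate_fwer <- function(rule, critical = rule$critical, design = rule$design,
                          replications = 1e5, seed = 1, theta = NULL) {
  if (replications < 1e4)
    warning("fewer than 1e4 replications: standard error is large for calibration purposes")
  if (is.null(theta)) theta <- rep(0, design$K)
  batch <- simulate_batch(design, theta, replications, seed,
                          permutation_randomized = FALSE)
  rej <- evaluate_batch_critical(rule, batch, critical)
  true_null <- theta[batch$selected] <= 0
  err <- rej & true_null
  p <- mean(err)
  list(estimate = p, se = sqrt(p * (1 - p) / replications),
       replications = replications, seed = seed)
}

#' Calibrate a rule's critical value to the familywise level
#'
#' Finds the critical value at which the rule's familywise error rate under
#' the global null equals `alpha`, adjusting for futility stopping. Three
#' methods share one simulated null ensemble:
#'
#' * `"conditional"` (default): given each replicate's stage-1 data, the
#'   rejection region is a z2 tail whose probability is computed exactly, so
#'   the error rate is a smooth monotone function of the critical value;
#'   the root is found deterministically. For the same replications this has
#'   strictly smaller Monte Carlo error than counting simulated stage-2
#'   rejections.
#' * `"quantile"`: the per-replicate minimal critical value that still
#'   rejects (the decision statistic itself, with simulated stage-2 data) is
#'   computed once, and the critical value is the empirical quantile giving
#'   the largest rejection fraction not exceeding `alpha`.
#' * `"robbins_monro"`: a stochastic-approximation pass over the statistic
#'   stream with steps proportional to `1/n`, warm-started at a pilot
#'   quantile and tail-averaged.
#'
#' The conventional rule has an analytic critical value and bypasses
#' simulation.
#'
#' @param rule A `seam_rule`.
#' @param design Design to calibrate for (defaults to the rule's; the
#'   returned rule carries this design).
#' @param alpha Familywise level (defaults to the design's).
#' @param replications Null replicates (default `1e6`, with `2e5` a
#'   reasonable fast mode).
#' @param seed Integer seed.
#' @param method See above.
#' @param revalidate Logical: re-estimate the error rate at the calibrated
#'   critical value with an independent seed and record it.
#' @return The rule with `critical` set and a `calibration` provenance record
#'   (method, replications, seed, estimated error rate and standard error).
#' @examples
#' \donttest{
#' d <- seam_design(K = 5, m1 = 28, m2 = 140, sigma = 5)
#' r <- calibrate_critical(seam_rule("tse", d), replications = 2e4, seed = 1)
#' r$critical
#' }
#' @export
calibrate_critical <- function(rule, design = rule$design, alpha = design$alpha,
                               replications = 1e6, seed = 1,
                               method = c("conditional", "quantile", "robbins_monro"),
                               revalidate = FALSE) {
  method <- match.arg(method)
  if (!identical(unclass(design), unclass(rule$design))) {
    rule$design <- design
    rule$w1 <- sqrt(design$m1 / (design$m1 + design$m2))
    rule$w2 <- sqrt(design$m2 / (design$m1 + design$m2))
  }
  if (rule$rule_id == "conventional") {
    rule$critical <- conventional_critical(design)
    rule$calibration <- list(method = "analytic", replications = 0L, seed = seed,
                             fwer = alpha, se = 0)
    return(rule)
  }
  batch <- simulate_batch(design, rep(0, design$K), replications, seed,
                          permutation_randomized = FALSE)
  rule <- calibrate_on_batch(rule, batch, alpha, method)
  if (revalidate) {
    chk <- estimate_fwer(rule, design = design, replications = replications,
                         seed = seed + 1L)
    rule$calibration$fwer_revalidated <- chk$estimate
    rule$calibration$fwer_revalidated_se <- chk$se
  }
  rule
}

## core calibrator on a pre-simulated null batch (shared for common random
## numbers across rules and design variants)
calibrate_on_batch <- function(rule, batch, alpha, method = "conditional") {
  ns <- null_statistics(rule, batch)
  c0 <- quantile_critical(ns$stats, alpha)
  if (method == "quantile") {
    crit <- c0
    rej <- mean(ns$stats >= crit)
    se <- sqrt(rej * (1 - rej) / length(ns$stats))
    fw <- rej
  } else if (method == "robbins_monro") {
    crit <- robbins_monro_critical(ns$stats, alpha)
    rej <- mean(ns$stats >= crit)
    se <- sqrt(rej * (1 - rej) / length(ns$stats))
    fw <- rej
  } else {
    f <- function(cc) fwer_conditional(rule, ns$info, batch$continued, cc)$estimate - alpha
    width <- max(1, 4 * stats::IQR(ns$stats[is.finite(ns$stats)]))
    crit <- stats::uniroot(f, c(c0 - width, c0 + width), extendInt = "yes",
                           tol = 1e-9)$root
    at <- fwer_conditional(rule, ns$info, batch$continued, crit)
    fw <- at$estimate; se <- at$se
  }
  if (!is.finite(crit)) stop("calibration failed: alpha unreachable for this rule")
  rule$critical <- crit
  rule$calibration <- list(method = method, replications = batch$replications,
                           seed = batch$seed, fwer = fw, se = se)
  rule
}
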