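## ---- power, efficiency, allocation, stage-1 value ---------------------------

## Resolve a scenario-or-vector power target into a per-replicate effect
## matrix plus the per-replicate index of the best arm. Scenario families are
## permuted independently per replicate (power averaged over placements of
## the best arm); plain vectors are fixed and must have a unique maximum.
resolve_theta <- function(target, K, replications, seed) {
  if (inherits(target, "seam_scenario")) {
    stopifnot(target$K == K)
    shape <- c(target$gammas, 1) * target$delta
    th <- permuted_theta_matrix(shape, replications, K, seed)
    return(list(theta = th, imax = max.col(th),
                delta = target$delta))
  }
  stopifnot(is.numeric(target), length(target) == K)
  mx <- max(target)
  if (sum(target == mx) != 1L)
    stop("power is defined only for configurations with a unique best arm")
  list(theta = target, imax = rep(which.max(target), replications),
       delta = mx)
}

## power engine on pre-drawn normals; stage2 = "integrate" replaces the
## simulated stage-2 decision by its exact conditional probability given
## stage-1 data (smaller MC error, same estimand)
power_on_normals <- function(rule, design, normals, theta, imax,
                             stage2 = "integrate", critical = rule$critical) {
  R <- nrow(normals$eps1)
  batch <- batch_from_normals(normals, design, theta)
  sel_ok <- batch$selected == imax
  ok <- sel_ok & batch$continued
  info <- rule_stage1_info(rule, batch$theta_hat1, batch$z1, batch$selected)
  thr <- rule_z2_threshold(rule, info, critical)
  if (stage2 == "integrate") {
    th_sel <- if (is.matrix(theta)) theta[cbind(seq_len(R), batch$selected)]
              else theta[batch$selected]
    drift <- th_sel * sqrt(design$m2 / 2) / design$sigma
    contrib <- ifelse(ok, stats::pnorm(thr - drift, lower.tail = FALSE), 0)
    power <- mean(contrib)
    se <- stats::sd(contrib) / sqrt(R)
  } else {
    rej <- ok & !is.na(batch$z2) & (batch$z2 >= thr)
    power <- mean(rej)
    se <- sqrt(power * (1 - power) / R)
  }
  list(power = power, se = se, p_select = mean(sel_ok),
       p_select_continue = mean(ok))
}

#' Estimate the power of a calibrated decision rule
#'
#' Power is the probability of selecting the truly best treatment and
#' rejecting its null hypothesis. For scenario families the effect vector is
#' an independent uniform permutation of the shape vector in each replicate
#' and success is judged against each replicate's own best arm.
#'
#' By default the stage-2 part of the decision is integrated analytically
#' given the simulated stage-1 data (every rule's rejection region is a
#' stage-2 tail), which reduces Monte Carlo error; `stage2 = "simulate"`
#' draws stage-2 data instead.
#'
#' @param rule A calibrated `seam_rule`.
#' @param theta A length-`K` effect vector with a unique maximum, or a
#'   [make_scenario()] object.
#' @param replications Number of replicates.
#' @param seed Integer seed.
#' @param design Design to simulate under (defaults to the rule's).
#' @param stage2 `"integrate"` (default) or `"simulate"`.
#' @return A `seam_power`: list with `power`, `se`, and the decomposition
#'   `p_select` (probability of selecting the best arm) and
#'   `p_reject_given_select` (their ratio; the product reproduces `power`
#'   exactly on the shared ensemble).
#' @export
estimate_power <- function(rule, theta, replications, seed,
                           design = rule$design,
                           stage2 = c("integrate", "simulate")) {
  stage2 <- match.arg(stage2)
  if (is.na(rule$critical)) stop("rule must be calibrated before power estimation")
  rt <- resolve_theta(theta, design$K, replications, seed)
  normals <- simulate_null_normals(replications, design$K, seed)
  pw <- power_on_normals(rule, design, normals, rt$theta, rt$imax, stage2)
  structure(list(power = pw$power, se = pw$se,
                 p_select = pw$p_select,
                 p_reject_given_select = if (pw$p_select > 0) pw$power / pw$p_select else NA_real_,
                 rule_id = rule$rule_id, replications = replications,
                 seed = seed, stage2 = stage2),
            class = "seam_power")
}

#' @export
print.seam_power <- function(x, ...) {
  cat(sprintf("power (%s): %.4f (se %.2g); select best %.4f, reject | select %.4f\n",
              x$rule_id, x$power, x$se, x$p_select, x$p_reject_given_select))
  invisible(x)
}

## design scaled by a common stage factor rho
scale_design <- function(design, rho) {
  seam_design(design$K, rho * design$m1, rho * design$m2, design$ell,
              design$sigma, design$alpha)
}

#' Relative efficiency of one rule against a benchmark
#'
#' The benchmark rule (typically an optimal or pseudo-optimal rule) is
#' calibrated and its power evaluated at the design's group sizes. The
#' comparison rule is then evaluated at scaled designs `(rho * m1, rho * m2)`
#' (recalibrated at each scale factor) and `rho` is root-found so that it
#' matches the benchmark power; its relative efficiency, as a percentage, is
#' `100 / rho`. All evaluations share the same underlying standard-normal
#' draws (common random numbers) and integrate the stage-2 decision
#' analytically, so the matched power comparison is tightly coupled.
#'
#' @param rule The comparison `seam_rule` (calibration is refreshed
#'   internally at each scale factor).
#' @param benchmark_rule The benchmark `seam_rule`.
#' @param theta Effect configuration or scenario family (see
#'   [estimate_power()]).
#' @param replications Replicates per power evaluation.
#' @param seed Integer seed.
#' @param design Reference design (defaults to the benchmark rule's).
#' @param rho_bracket Search interval for the inflation factor.
#' @param tol Root-finding tolerance on `rho`.
#' @return A `seam_efficiency`: list with the benchmark `power`, `rho`,
#'   `efficiency` (= `100 / rho` exactly), and provenance.
#' @export
relative_efficiency <- function(rule, benchmark_rule, theta, replications, seed,
                                design = benchmark_rule$design,
                                rho_bracket = c(0.3, 3), tol = 1e-4) {
  rt <- resolve_theta(theta, design$K, replications, seed)
  normals <- simulate_null_normals(replications, design$K, seed, stream = "scenario")
  null_norm <- simulate_null_normals(replications, design$K, seed, stream = "null")
  cal_on <- function(r, d) {
    nb <- batch_from_normals(null_norm, d, rep(0, d$K))
    nb$seed <- seed
    if (r$rule_id == "conventional") {
      r$design <- d; r$critical <- conventional_critical(d); r
    } else {
      r$design <- d
      r$w1 <- sqrt(d$m1 / (d$m1 + d$m2)); r$w2 <- sqrt(d$m2 / (d$m1 + d$m2))
      calibrate_on_batch(r, nb, d$alpha)
    }
  }
  bench <- cal_on(benchmark_rule, design)
  target <- power_on_normals(bench, design, normals, rt$theta, rt$imax)$power
  power_at <- function(rho) {
    d <- scale_design(design, rho)
    ## common random numbers: same eps, rescaled through the design
    r <- cal_on(rule, d)
    power_on_normals(r, d, normals, rt$theta, rt$imax)$power
  }
  f <- function(rho) power_at(rho) - target
  f1 <- f(1)
  if (abs(f1) < 1e-12) {
    rho <- 1
  } else {
    flo <- f(rho_bracket[1]); fhi <- f(rho_bracket[2])
    if (flo * fhi > 0)
      stop("bracket failure: the rule cannot match the benchmark power for rho in ",
           "[", rho_bracket[1], ", ", rho_bracket[2], "]")
    rho <- stats::uniroot(f, rho_bracket, tol = tol)$root
  }
  structure(list(power = target, rho = rho, efficiency = 100 / rho,
                 rule_id = rule$rule_id, benchmark_id = benchmark_rule$rule_id,
                 replications = replications, seed = seed),
            class = "seam_efficiency")
}

#' @export
print.seam_efficiency <- function(x, ...) {
  cat(sprintf("relative efficiency of '%s' vs '%s': %.1f%% (rho = %.4f) at benchmark power %.4f\n",
              x$rule_id, x$benchmark_id, x$efficiency, x$rho, x$power))
  invisible(x)
}

#' Optimal division of a fixed total sample size between stages
#'
#' With the total sample size constrained to `(K + 1) * m1 + 2 * m2 = N`, a
#' direct search over integer stage-1 group sizes `m1` (with real-valued
#' `m2 = (N - (K + 1) * m1) / 2`) finds the allocation maximizing the rule's
#' power. The rule is recalibrated at every grid point; all grid points share
#' the same standard-normal draws (common random numbers), and the reported
#' optimum is the argmax of a locally smoothed power curve (the maxima are
#' flat, so smoothing suppresses residual Monte Carlo jitter). The selection
#' and conditional-rejection decomposition of power is returned alongside.
#'
#' @param rule A `seam_rule` (its critical value is refreshed per grid
#'   point).
#' @param total_N Total sample size bound.
#' @param theta Effect configuration or scenario family.
#' @param replications Replicates per grid point.
#' @param seed Integer seed.
#' @param m1_grid Integer grid (default all feasible `m1 >= 1` with
#'   `m2 > 0`).
#' @param smooth_span `loess` span for the smoothed curve (skipped for very
#'   short grids).
#' @return A `seam_allocation`: list with `m1_opt`, `m2_opt`, `power_opt` and
#'   a data frame `curve` (`m1`, `m2`, `power`, `p_select`,
#'   `p_reject_given_select`, `power_smooth`).
#' @export
optimize_m1 <- function(rule, total_N, theta, replications, seed,
                        m1_grid = NULL, smooth_span = 0.35) {
  design0 <- rule$design
  K <- design0$K
  if (is.null(m1_grid))
    m1_grid <- seq_len(floor((total_N - 2) / (K + 1)))
  m1_grid <- as.integer(m1_grid)
  m2_grid <- (total_N - (K + 1) * m1_grid) / 2
  keep <- m2_grid > 0
  m1_grid <- m1_grid[keep]; m2_grid <- m2_grid[keep]
  if (!length(m1_grid)) stop("no feasible m1 values for this total sample size")
  rt <- resolve_theta(theta, K, replications, seed)
  normals <- simulate_null_normals(replications, K, seed, stream = "scenario")
  null_norm <- simulate_null_normals(replications, K, seed, stream = "null")
  rows <- lapply(seq_along(m1_grid), function(i) {
    d <- seam_design(K, m1_grid[i], m2_grid[i], design0$ell, design0$sigma,
                     design0$alpha)
    r <- rule
    r$design <- d
    r$w1 <- sqrt(d$m1 / (d$m1 + d$m2)); r$w2 <- sqrt(d$m2 / (d$m1 + d$m2))
    if (r$rule_id == "conventional") {
      r$critical <- conventional_critical(d)
    } else {
      nb <- batch_from_normals(null_norm, d, rep(0, K)); nb$seed <- seed
      r <- calibrate_on_batch(r, nb, d$alpha)
    }
    pw <- power_on_normals(r, d, normals, rt$theta, rt$imax)
    c(power = pw$power, p_select = pw$p_select,
      p_rej = if (pw$p_select > 0) pw$power / pw$p_select else NA_real_)
  })
  rows <- do.call(rbind, rows)
  curve <- data.frame(m1 = m1_grid, m2 = m2_grid, power = rows[, "power"],
                      p_select = rows[, "p_select"],
                      p_reject_given_select = rows[, "p_rej"])
  if (length(m1_grid) >= 20) {
    curve$power_smooth <- stats::fitted(stats::loess(power ~ m1, data = curve,
                                                     span = smooth_span,
                                                     degree = 2))
  } else {
    curve$power_smooth <- curve$power
  }
  opt <- which.max(curve$power_smooth)
  structure(list(total_N = total_N, curve = curve,
                 m1_opt = curve$m1[opt], m2_opt = curve$m2[opt],
                 power_opt = curve$power[opt],
                 rule_id = rule$rule_id, replications = replications,
                 seed = seed),
            class = "seam_allocation")
}

#' @export
print.seam_allocation <- function(x, ...) {
  cat(sprintf("allocation optimum (%s, N = %g): m1* = %d, m2 = %g, power %.4f\n",
              x$rule_id, x$total_N, x$m1_opt, x$m2_opt, x$power_opt))
  invisible(x)
}

#' Value of stage-1 data in the final analysis
#'
#' Quantifies the benefit of re-using the selection-stage data of the
#' selected arm and control in the final test. The pooled-z (TSE) rule with
#' group sizes `(m1, m2)` attains power `P`; a conventional analysis that
#' also selects on `m1` stage-1 observations per arm but tests with stage-2
#' data alone needs `m2~` stage-2 observations per arm to attain the same
#' power. The percentage value of the stage-1 observations on the selected
#' arm and control is
#' `r* = 100 * (m2~ - m2) / m1`,
#' the additional stage-2 observations required on each of the two stage-2
#' arms relative to their `m1` stage-1 observations apiece (equivalently,
#' `2 * (m2~ - m2)` extra observations against the `2 * m1` stage-1
#' observations on the selected arm and control). Values above 100 indicate
#' that stage-1 data from the non-selected arms also contribute.
#'
#' The matched size `m2~` is found by root search: the conventional power at
#' stage-2 size `m` factorizes into the (simulated) probability of selecting
#' the best arm and continuing, times an exact normal tail probability, and
#' is continuous and increasing in `m`.
#'
#' @param design A [seam_design()] supplying `(m1, m2)` when
#'   `total_N` is `NULL`.
#' @param theta Effect vector with a unique maximum (or single-shape
#'   scenario, interpreted as its canonical vector with the best arm last).
#' @param replications Replicates.
#' @param seed Integer seed.
#' @param total_N If supplied, `(m1, m2)` are first chosen to maximize the
#'   TSE power under this total sample size (see [optimize_m1()]).
#' @param comparison `"tse"` (default) or `"conventional"` (a degenerate
#'   self-comparison that returns `m2~ = m2` and `r* = 0`; useful as a
#'   consistency check).
#' @return A `seam_phase2`: list with `m1`, `m2`, `power`,
#'   `p_select_continue`, `m2_matched` and `r_star`.
#' @export
phase2_value <- function(design, theta, replications, seed, total_N = NULL,
                         comparison = c("tse", "conventional")) {
  comparison <- match.arg(comparison)
  K <- design$K
  if (inherits(theta, "seam_scenario")) {
    stopifnot(theta$kind == "single")
    theta <- c(rep(theta$gammas[1L], K - 1L), 1) * theta$delta
  }
  stopifnot(length(theta) == K)
  if (!is.null(total_N)) {
    alloc <- optimize_m1(seam_rule("tse", design), total_N, theta,
                         replications, seed)
    design <- seam_design(K, alloc$m1_opt, alloc$m2_opt, design$ell,
                          design$sigma, design$alpha)
  }
  rt <- resolve_theta(theta, K, replications, seed)
  imax <- rt$imax[1L]
  theta_max <- theta[imax]
  normals <- simulate_null_normals(replications, K, seed, stream = "scenario")
  null_norm <- simulate_null_normals(replications, K, seed, stream = "null")
  comp <- seam_rule(comparison, design)
  if (comparison != "conventional") {
    nb <- batch_from_normals(null_norm, design, rep(0, K)); nb$seed <- seed
    comp <- calibrate_on_batch(comp, nb, design$alpha)
  }
  pw <- power_on_normals(comp, design, normals, rt$theta, rt$imax)
  P <- pw$power
  A <- pw$p_select_continue
  c_conv <- conventional_critical(design)
  conv_power <- function(m) {
    A * stats::pnorm(c_conv - theta_max * sqrt(m / 2) / design$sigma,
                     lower.tail = FALSE)
  }
  if (P >= A)
    stop("matched power unattainable: the conventional test cannot exceed the ",
         "selection probability")
  upper <- design$m2
  while (conv_power(upper) < P) {
    upper <- upper * 2
    if (upper > 1e7) stop("matched stage-2 size exceeds the search bracket")
  }
  m2_matched <- stats::uniroot(function(m) conv_power(m) - P,
                               c(1e-9, upper), tol = 1e-7)$root
  structure(list(m1 = design$m1, m2 = design$m2, power = P,
                 p_select_continue = A, m2_matched = m2_matched,
                 r_star = 100 * (m2_matched - design$m2) / design$m1,
                 comparison = comparison,
                 replications = replications, seed = seed),
            class = "seam_phase2")
}

#' @export
print.seam_phase2 <- function(x, ...) {
  cat(sprintf("stage-1 value: (m1, m2) = (%g, %g), power %.4f, matched m2~ = %.2f, r* = %.1f%%\n",
              x$m1, x$m2, x$power, x$m2_matched, x$r_star))
  invisible(x)
}
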