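## Independent oracles used to freeze expected values. These deliberately
## avoid the package's analytic shortcuts: multivariate normal densities use
## generic solve()/determinant(), closure enumerates every subset, and
## selection probabilities come from direct quadrature.

## generic multivariate normal log density
oracle_mvn_logdens <- function(x, mean, V) {
  k <- length(x)
  q <- as.numeric(t(x - mean) %*% solve(V) %*% (x - mean))
  -0.5 * (k * log(2 * pi) + as.numeric(determinant(V)$modulus) + q)
}

## log prior-weighted likelihood ratio of a continuing trial's data under the
## treatment-favouring block (selected arm best) versus the null, from full
## densities; weights are prior masses relative to the null mass
oracle_lr_statistic <- function(trial, scenario, design) {
  sup <- scenario_support(scenario)
  V <- stage1_covariance(design)$V
  i_star <- trial$selected
  delta <- scenario$delta
  rows <- which(sup$theta[, i_star] == delta)
  sd2 <- design$sigma * sqrt(2 / design$m2)
  l0 <- oracle_mvn_logdens(trial$theta_hat1, rep(0, design$K), V) +
    stats::dnorm(trial$theta_hat2, 0, sd2, log = TRUE)
  terms <- vapply(rows, function(r) {
    oracle_mvn_logdens(trial$theta_hat1, sup$theta[r, ], V) +
      stats::dnorm(trial$theta_hat2, delta, sd2, log = TRUE) +
      log(sup$mass[r] / sup$mass[1L]) - l0
  }, 0)
  mx <- max(terms)
  mx + log(sum(exp(terms - mx)))
}

## plain re-implementations of the intersection p-values
oracle_simes <- function(p) {
  n <- length(p)
  min(1, min(sort(p) * n / seq_len(n)))
}
oracle_dunnett <- function(z, use_mvtnorm = FALSE) {
  n <- length(z); t <- max(z)
  if (use_mvtnorm && requireNamespace("mvtnorm", quietly = TRUE)) {
    S <- matrix(0.5, n, n); diag(S) <- 1
    return(1 - mvtnorm::pmvnorm(upper = rep(t, n), corr = S,
                                algorithm = mvtnorm::Miwa(steps = 512))[1])
  }
  1 - stats::integrate(function(u) stats::dnorm(u) *
                         stats::pnorm(u + sqrt(2) * t)^n,
                       -Inf, Inf, rel.tol = 1e-10)$value
}

## full-closure decision for the selected arm: enumerate every subset
## containing it and require all combined statistics to reach the critical
oracle_closure_reject <- function(trial, method, intersection, critical) {
  d <- trial$design
  K <- d$K
  w1 <- sqrt(d$m1 / (d$m1 + d$m2)); w2 <- sqrt(d$m2 / (d$m1 + d$m2))
  p2 <- 1 - stats::pnorm(trial$z2)
  others <- setdiff(seq_len(K), trial$selected)
  for (mask in 0:(2^length(others) - 1L)) {
    I <- c(trial$selected,
           others[bitwAnd(mask, bitwShiftL(1L, seq_along(others) - 1L)) != 0L])
    p1 <- if (intersection == "simes") oracle_simes(1 - stats::pnorm(trial$z1[I]))
          else oracle_dunnett(trial$z1[I])
    stat <- if (method == "inverse_chisq") -log(p1 * p2)
            else w1 * stats::qnorm(1 - p1) + w2 * stats::qnorm(1 - p2)
    if (stat < critical) return(FALSE)
  }
  TRUE
}

## max over subsets containing the selected arm of the stage-1 intersection
## p-value, by explicit enumeration
oracle_max_p1 <- function(z1, selected, intersection) {
  K <- length(z1)
  others <- setdiff(seq_len(K), selected)
  best <- 0
  for (mask in 0:(2^length(others) - 1L)) {
    I <- c(selected,
           others[bitwAnd(mask, bitwShiftL(1L, seq_along(others) - 1L)) != 0L])
    p1 <- if (intersection == "simes") oracle_simes(1 - stats::pnorm(z1[I]))
          else oracle_dunnett(z1[I])
    best <- max(best, p1)
  }
  best
}

## pr{best arm selected} by one-dimensional quadrature over its arm mean
oracle_select_prob <- function(design, theta) {
  imax <- which.max(theta)
  shifts <- (theta[imax] - theta[-imax]) * sqrt(design$m1) / design$sigma
  stats::integrate(function(v) {
    out <- stats::dnorm(v)
    for (s in shifts) out <- out * stats::pnorm(v + s)
    out
  }, -Inf, Inf, rel.tol = 1e-10)$value
}

## pr{best arm selected, continue} and conventional power by nested
## quadrature over (control mean u, best arm mean v), inner limits from the
## futility constraint so no discontinuity enters the integrand
oracle_joint <- function(design, theta, h) {
  imax <- which.max(theta)
  s <- design$sigma / sqrt(design$m1)
  tmax <- theta[imax] / s
  toth <- theta[-imax] / s
  ell_s <- design$ell / s
  f_outer <- function(u) {
    vapply(u, function(uu) {
      lo <- uu + ell_s
      hi <- max(tmax + 9, lo + 1e-9)
      inner <- stats::integrate(function(v) {
        out <- stats::dnorm(v - tmax) * h(v * s, uu * s)
        for (t in toth) out <- out * stats::pnorm(v - t)
        out
      }, lo, hi, rel.tol = 1e-9)$value
      stats::dnorm(uu) * inner
    }, 0)
  }
  stats::integrate(f_outer, -9, 9, rel.tol = 1e-8)$value
}

oracle_select_continue_prob <- function(design, theta) {
  oracle_joint(design, theta, function(v, u) rep(1, length(v)))
}

## conventional rule: selection and continuation by quadrature, stage-2 tail
## exact (stage-2 data independent of stage 1 given the selection)
oracle_conventional_power <- function(design, theta, critical) {
  imax <- which.max(theta)
  drift <- theta[imax] * sqrt(design$m2 / 2) / design$sigma
  oracle_select_continue_prob(design, theta) *
    stats::pnorm(critical - drift, lower.tail = FALSE)
}
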