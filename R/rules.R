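rule_ids <- c("conventional", "tse",
              "bk_invchisq_simes", "bk_invchisq_dunnett",
              "bk_invnormal_simes", "bk_invnormal_dunnett",
              "optimal_single", "optimal_permutation", "optimal_ordered")

#' Construct a final decision rule
#'
#' A decision rule maps a continuing trial's summary statistics (stage-1
#' standardized statistics, selected arm, stage-2 statistic) to the decision
#' of rejecting or retaining the selected arm's null hypothesis. All rules
#' share the same selection stage and futility gate, so power differences
#' isolate the final data-combination step. Available rules:
#'
#' * `"conventional"`: stage-2 statistic alone, with the analytic
#'   futility-adjusted critical value (see [conventional_critical()]).
#' * `"tse"`: weighted pooled z-statistic `w1 * Z1 + w2 * Z2` of the selected
#'   arm with `w_i = sqrt(m_i / (m1 + m2))`.
#' * `"bk_invchisq_simes"`, `"bk_invchisq_dunnett"`, `"bk_invnormal_simes"`,
#'   `"bk_invnormal_dunnett"`: closed testing procedures combining stage-wise
#'   p-values, see [closed_test_reject()] and [combine_pvalues()].
#' * `"optimal_single"`, `"optimal_permutation"`, `"optimal_ordered"`:
#'   Bayes-optimal likelihood-ratio rules for a scenario family, see
#'   [optimal_single_statistic()] and relatives. When the family's smallest
#'   statistic weight is negative ([min_fwer_coefficient()]), the rule is
#'   flagged pseudo-optimal: it bounds attainable power but null calibration
#'   does not guarantee strong familywise error control.
#'
#' Every rule except `"conventional"` must be calibrated (see
#' [calibrate_critical()]) before evaluation; the conventional rule's
#' critical value is attached on construction.
#'
#' @param rule_id One of the identifiers above.
#' @param design A [seam_design()].
#' @param scenario A [make_scenario()] object (required for the optimal
#'   rules; its kind must match the rule).
#' @param gamma Shape value for `"optimal_single"`, alternative to passing a
#'   single-kind scenario.
#' @return An object of class `seam_rule`.
#' @export
seam_rule <- function(rule_id, design, scenario = NULL, gamma = NULL) {
  rule_id <- match.arg(rule_id, rule_ids)
  stopifnot(inherits(design, "seam_design"))
  w1 <- sqrt(design$m1 / (design$m1 + design$m2))
  w2 <- sqrt(design$m2 / (design$m1 + design$m2))
  pseudo <- FALSE
  if (rule_id == "optimal_single") {
    if (is.null(gamma)) {
      if (is.null(scenario) || scenario$kind != "single")
        stop("optimal_single requires 'gamma' or a single-kind scenario")
      gamma <- scenario$gammas[1L]
    }
    if (gamma < 0 || gamma >= 1) stop("'gamma' must lie in [0, 1)")
    pseudo <- min_fwer_coefficient(gamma, design$K) < 0
  }
  if (rule_id %in% c("optimal_permutation", "optimal_ordered")) {
    kind_needed <- if (rule_id == "optimal_permutation") "permutation" else "ordered"
    if (is.null(scenario))
      stop(rule_id, " requires a scenario")
    if (scenario$kind == "single" && rule_id == "optimal_permutation") {
      ## collapsed degenerate family: the (K-1)! identical terms factor out
      return(seam_rule("optimal_single", design, gamma = scenario$gammas[1L]))
    }
    if (scenario$kind != kind_needed)
      stop(rule_id, " requires a ", kind_needed, "-kind scenario")
    stopifnot(scenario$K == design$K)
    pseudo <- !scenario$strong_fwer
  }
  r <- structure(list(rule_id = rule_id, design = design, w1 = w1, w2 = w2,
                      gamma = gamma, scenario = scenario,
                      pseudo_optimal = pseudo,
                      critical = NA_real_, calibration = NULL),
                 class = "seam_rule")
  if (rule_id == "conventional") {
    r$critical <- conventional_critical(design)
    r$calibration <- list(method = "analytic", replications = 0L, se = 0)
  }
  r
}

#' @export
print.seam_rule <- function(x, ...) {
  cat(sprintf("seam_rule '%s'%s: critical = %s\n", x$rule_id,
              if (x$pseudo_optimal) " (pseudo-optimal)" else "",
              if (is.na(x$critical)) "uncalibrated" else format(x$critical)))
  invisible(x)
}

#' Analytic critical value of the conventional rule
#'
#' The conventional rule ignores stage-1 data in the final test. Because a
#' rejection also requires the trial to continue past the futility analysis,
#' its null rejection probability is the continuation probability times the
#' stage-2 tail probability, so the familywise level `alpha` is attained
#' exactly at `qnorm(1 - alpha / p_cont)` with `p_cont` the null continuation
#' probability. The critical value does not depend on `m2` (the stage-2
#' statistic is pivotal under the null).
#'
#' @param design A [seam_design()].
#' @return The critical value on the z scale.
#' @examples
#' conventional_critical(seam_design(K = 5, m1 = 28, m2 = 140, sigma = 5))
#' @export
conventional_critical <- function(design) {
  p_cont <- continuation_probability(design)
  if (design$alpha >= p_cont)
    stop("alpha >= continuation probability: the conventional rule cannot be calibrated")
  stats::qnorm(1 - design$alpha / p_cont)
}

#' Pooled two-stage z statistic of the selected arm
#'
#' `w1 * Z1 + w2 * Z2` with `w_i = sqrt(m_i / (m1 + m2))`; up to a positive
#' constant this equals the information-weighted pooled effect estimate
#' `m1 * theta_hat1 + m2 * theta_hat2` of the selected arm.
#'
#' @param trial A continuing `seam_trial`.
#' @param w1,w2 Optional weights; default from the trial's design.
#' @return The pooled statistic.
#' @export
tse_statistic <- function(trial, w1 = NULL, w2 = NULL) {
  if (!isTRUE(trial$continued)) stop("the pooled statistic requires stage-2 data")
  d <- trial$design
  if (is.null(w1)) w1 <- sqrt(d$m1 / (d$m1 + d$m2))
  if (is.null(w2)) w2 <- sqrt(d$m2 / (d$m1 + d$m2))
  w1 * trial$z1[trial$selected] + w2 * trial$z2
}

## ---- vectorized rule engine -------------------------------------------------
## All rules reject, conditional on stage-1 data and continuation, exactly when
## z2 >= threshold(stage-1 data, critical), with the threshold monotone in the
## critical value. The engine computes per-replicate stage-1 summaries once and
## reuses them for calibration, error estimation and power.

rule_stage1_info <- function(rule, th1, z1, selected) {
  R <- nrow(th1)
  z1s <- z1[cbind(seq_len(R), selected)]
  switch(rule$rule_id,
    conventional = list(),
    tse = list(z1s = z1s),
    bk_invchisq_simes = ,
    bk_invnormal_simes = list(M = max_stage1_pvalue(z1, selected, "simes")),
    bk_invchisq_dunnett = ,
    bk_invnormal_dunnett = list(M = max_stage1_pvalue(z1, selected, "dunnett")),
    optimal_single = list(S1 = optimal_single_s1(th1, selected, rule$gamma, rule$design)),
    optimal_permutation = ,
    optimal_ordered = list(S1 = optimal_lr_s1(th1, selected, rule$scenario, rule$design))
  )
}

## z2 rejection threshold given the stage-1 summaries and a critical value
rule_z2_threshold <- function(rule, info, critical) {
  d <- rule$design
  switch(rule$rule_id,
    conventional = critical,
    tse = (critical - rule$w1 * info$z1s) / rule$w2,
    bk_invnormal_simes = ,
    bk_invnormal_dunnett =
      (critical - rule$w1 * stats::qnorm(1 - info$M)) / rule$w2,
    bk_invchisq_simes = ,
    bk_invchisq_dunnett =
      stats::qnorm(pmin(1, exp(-critical) / info$M), lower.tail = FALSE),
    optimal_single = {
      a <- d$m2 / (2 * d$sigma^2)              # theta_hat2 coefficient
      ((critical - info$S1) / a) * sqrt(d$m2) / (d$sigma * sqrt(2))
    },
    optimal_permutation = ,
    optimal_ordered = {
      delta <- rule$scenario$delta
      a <- d$m2 * delta / (2 * d$sigma^2)
      b <- d$m2 * delta^2 / (4 * d$sigma^2)
      ((critical - info$S1 + b) / a) * sqrt(d$m2) / (d$sigma * sqrt(2))
    })
}

## full decision statistic given realized stage-2 data
rule_statistic_values <- function(rule, info, z2) {
  d <- rule$design
  th2 <- z2 * d$sigma * sqrt(2) / sqrt(d$m2)
  switch(rule$rule_id,
    conventional = z2,
    tse = rule$w1 * info$z1s + rule$w2 * z2,
    bk_invnormal_simes = ,
    bk_invnormal_dunnett =
      rule$w1 * stats::qnorm(1 - info$M) + rule$w2 * z2,
    bk_invchisq_simes = ,
    bk_invchisq_dunnett =
      -log(info$M) - stats::pnorm(z2, lower.tail = FALSE, log.p = TRUE),
    optimal_single = info$S1 + (d$m2 / (2 * d$sigma^2)) * th2,
    optimal_permutation = ,
    optimal_ordered = {
      delta <- rule$scenario$delta
      info$S1 + (d$m2 / (4 * d$sigma^2)) * (2 * delta * th2 - delta^2)
    })
}

## batch decisions given a critical value
evaluate_batch_critical <- function(rule, batch, critical) {
  info <- rule_stage1_info(rule, batch$theta_hat1, batch$z1, batch$selected)
  thr <- rule_z2_threshold(rule, info, critical)
  out <- batch$continued & !is.na(batch$z2) & (batch$z2 >= thr)
  out[is.na(out)] <- FALSE
  out
}

#' Evaluate a calibrated rule on a batch of trials
#'
#' @param rule A calibrated `seam_rule`.
#' @param batch A `seam_batch` simulated under the same design.
#' @return Logical vector: rejection of the selected arm's hypothesis per
#'   replicate (`FALSE` for trials stopped at the futility analysis).
#' @export
evaluate_batch <- function(rule, batch) {
  check_design_match(rule, batch$design)
  if (is.na(rule$critical)) stop("rule must be calibrated before evaluation")
  evaluate_batch_critical(rule, batch, rule$critical)
}

check_design_match <- function(rule, design) {
  d <- rule$design
  if (d$K != design$K || d$m1 != design$m1 || d$m2 != design$m2 ||
      d$sigma != design$sigma || d$ell != design$ell)
    stop("trial design does not match the design the rule was calibrated for")
  invisible(TRUE)
}

#' Evaluate a calibrated rule on one trial
#'
#' Stopped trials map to the null action `A0`. Continuing trials are tested
#' with the rule's statistic against its calibrated critical value; the only
#' rejectable hypothesis is the selected arm's.
#'
#' @param rule A calibrated `seam_rule`.
#' @param trial A `seam_trial` from a matching design.
#' @return A `seam_decision`: list with `action` (`"A0"` or `"A<i>"`),
#'   `rejected`, `selected` and `rule_id`.
#' @export
evaluate_rule <- function(rule, trial) {
  stopifnot(inherits(trial, "seam_trial"))
  check_design_match(rule, trial$design)
  if (is.na(rule$critical)) stop("rule must be calibrated before evaluation")
  if (!trial$continued)
    return(structure(list(action = "A0", rejected = FALSE,
                          selected = trial$selected, rule_id = rule$rule_id),
                     class = "seam_decision"))
  info <- rule_stage1_info(rule, matrix(trial$theta_hat1, 1L),
                           matrix(trial$z1, 1L), trial$selected)
  rej <- trial$z2 >= rule_z2_threshold(rule, info, rule$critical)
  structure(list(action = if (rej) paste0("A", trial$selected) else "A0",
                 rejected = rej, selected = trial$selected,
                 rule_id = rule$rule_id),
            class = "seam_decision")
}

#' @export
print.seam_decision <- function(x, ...) {
  cat(sprintf("decision %s (%s): %s\n", x$action, x$rule_id,
              if (x$rejected) "reject selected arm's null" else "no rejection"))
  invisible(x)
}

#' Serialize rules (with calibration provenance) to JSON
#'
#' @param rules A list of `seam_rule` objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_rule_registry <- function(rules, path) {
  entry <- function(r) {
    list(rule_id = r$rule_id, design = unclass(r$design),
         gamma = r$gamma,
         scenario = if (!is.null(r$scenario))
           list(kind = r$scenario$kind, gammas = r$scenario$gammas,
                delta = r$scenario$delta),
         pseudo_optimal = r$pseudo_optimal,
         critical = r$critical, calibration = r$calibration)
  }
  jsonlite::write_json(lapply(rules, entry), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}
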