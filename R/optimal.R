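## ---- Bayes-optimal likelihood-ratio statistics ------------------------------
##
## Each optimal rule arises from a Bayes decision problem: a discrete prior
## over effect configurations (mass 1/(K+1) on the null, the rest on
## treatment-favouring configurations), a reward for correctly rejecting the
## best arm's hypothesis and a cost for a false rejection under the null. The
## Bayes rule rejects the selected arm's hypothesis when the prior-weighted
## likelihood ratio of the observed data under the treatment-favouring block
## versus the null exceeds a constant determined by the cost ratio; only that
## ratio matters, so rules are parameterized directly by a calibrated
## threshold. The stage-1 log likelihood ratio under configuration phi is
## linear in the effect estimates with coefficients
## lambda(phi) = V^{-1} phi = (m1/sigma^2)(phi - 1 * sum(phi)/(K+1)).

## lambda(phi)' theta_hat1 for each row of `phi`, as an R x n matrix
lambda_crossprod <- function(th1, phi, design) {
  Kp1 <- design$K + 1
  (design$m1 / design$sigma^2) *
    (th1 %*% t(phi) - rowSums(th1) %*% t(rowSums(phi)) / Kp1)
}

## -0.5 phi' V^{-1} phi (identical within a permutation family)
lr_quadratic <- function(phi_row, design) {
  -(design$m1 / (2 * design$sigma^2)) *
    (sum(phi_row^2) - sum(phi_row)^2 / (design$K + 1))
}

logsumexp_rows <- function(M) {
  mx <- do.call(pmax, as.data.frame(M))
  mx + log(rowSums(exp(M - mx)))
}

## Stage-1 part of the single-shape statistic on the delta-free scale:
## lambda(shape)' theta_hat1 with shape = (gamma,...,1 at selected,...,gamma).
optimal_single_s1 <- function(th1, selected, gamma, design) {
  K <- design$K
  R <- nrow(th1)
  sum_shape <- (K - 1) * gamma + 1
  (design$m1 / design$sigma^2) *
    (gamma * rowSums(th1) + (1 - gamma) * th1[cbind(seq_len(R), selected)] -
       sum_shape * rowSums(th1) / (K + 1))
}

## Stage-1 part of the permutation / ordered statistics: log of the
## prior-weighted sum of stage-1 likelihood ratios over the configurations
## with the selected arm best, including the quadratic normalizing term.
optimal_lr_s1 <- function(th1, selected, scenario, design) {
  R <- nrow(th1)
  out <- numeric(R)
  quad <- NULL
  for (s in seq_len(design$K)) {
    idx <- which(selected == s)
    if (!length(idx)) next
    terms <- scenario_terms(scenario, s)
    if (is.null(quad)) quad <- lr_quadratic(terms$phi[1L, ], design)
    M <- lambda_crossprod(th1[idx, , drop = FALSE], terms$phi, design)
    M <- sweep(M, 2L, terms$logw, "+")
    out[idx] <- logsumexp_rows(M) + quad
  }
  out
}

#' Optimal decision statistic for a single-shape effect family
#'
#' For effect configurations that are permutations of
#' `(gamma * delta, ..., gamma * delta, delta)`, the Bayes rule reduces to a
#' linear statistic in the selected arm's data and the other stage-1
#' estimates. Because the log likelihood ratio is proportional to `delta`
#' once its constants are absorbed into the threshold, the statistic is
#' computed on a `delta`-free scale: one calibrated threshold serves every
#' effect size, so this rule is uniformly optimal across `delta` for its
#' shape. The coefficient of each non-selected estimate is proportional to
#' `(2 * gamma - 1) / (K + 1)`: negative below `gamma = 0.5` (where the rule
#' down-weights strong competitors), zero at 0.5 (where it reduces to the
#' pooled z rule), positive above.
#'
#' @param trial A continuing `seam_trial`.
#' @param gamma Shape of the inferior arms, in `[0, 1)`.
#' @param design A [seam_design()]; defaults to the trial's design.
#' @return The statistic value (compare against a calibrated threshold).
#' @export
optimal_single_statistic <- function(trial, gamma, design = trial$design) {
  if (!isTRUE(trial$continued)) stop("optimal statistics require stage-2 data")
  if (gamma < 0 || gamma >= 1) stop("'gamma' must lie in [0, 1)")
  s1 <- optimal_single_s1(matrix(trial$theta_hat1, 1L), trial$selected, gamma, design)
  as.numeric(s1 + (design$m2 / (2 * design$sigma^2)) * trial$theta_hat2)
}

#' Optimal decision statistic averaged over shape permutations
#'
#' For a permutation family (strictly increasing shapes), the Bayes rule that
#' maximizes power averaged over all `K!` placements of the effects rejects
#' when the log of the prior-weighted sum, over the `(K-1)!` configurations
#' in which the selected arm is best, of likelihood ratios versus the null
#' exceeds a threshold `c(delta)` calibrated at the null. The sum is
#' evaluated with a max-subtracted log-sum-exp guard (the exponents scale
#' with `m1 * delta / sigma^2` and overflow otherwise). The threshold varies
#' with `delta`: no uniformly most powerful rule exists for these families.
#' When some statistic weights are negative (see [min_fwer_coefficient()])
#' the rule is pseudo-optimal: an upper bound on attainable power without
#' guaranteed strong familywise error control.
#'
#' @param trial A continuing `seam_trial`.
#' @param scenario A permutation-kind [make_scenario()].
#' @param design A [seam_design()]; defaults to the trial's design.
#' @return The log likelihood-ratio statistic.
#' @export
optimal_permutation_statistic <- function(trial, scenario, design = trial$design) {
  if (!isTRUE(trial$continued)) stop("optimal statistics require stage-2 data")
  stopifnot(inherits(scenario, "seam_scenario"))
  if (scenario$kind == "single")
    stop("degenerate (equal-shape) families collapse to the single-shape rule; ",
         "use optimal_single_statistic")
  if (scenario$kind != "permutation") stop("scenario must be of kind 'permutation'")
  s1 <- optimal_lr_s1(matrix(trial$theta_hat1, 1L), trial$selected, scenario, design)
  delta <- scenario$delta
  as.numeric(s1 + (design$m2 / (4 * design$sigma^2)) *
               (2 * delta * trial$theta_hat2 - delta^2))
}

#' Optimal decision statistic under a dose-ordered prior
#'
#' As [optimal_permutation_statistic()], but the prior mass of all
#' configurations whose best arm is arm `K` is concentrated on the single
#' dose-ordered vector, reflecting an anticipated monotone dose-response
#' relationship. When an arm below `K` is selected the statistic coincides
#' with the permutation-averaged one; when arm `K` is selected the sum
#' collapses to the single ordered configuration whose log prior weight is
#' larger by `log((K-1)!)`.
#'
#' @param trial A continuing `seam_trial`.
#' @param scenario An ordered-kind [make_scenario()].
#' @param design A [seam_design()]; defaults to the trial's design.
#' @return The log likelihood-ratio statistic.
#' @export
optimal_ordered_statistic <- function(trial, scenario, design = trial$design) {
  if (!isTRUE(trial$continued)) stop("optimal statistics require stage-2 data")
  stopifnot(inherits(scenario, "seam_scenario"))
  if (scenario$kind != "ordered") stop("scenario must be of kind 'ordered'")
  s1 <- optimal_lr_s1(matrix(trial$theta_hat1, 1L), trial$selected, scenario, design)
  delta <- scenario$delta
  as.numeric(s1 + (design$m2 / (4 * design$sigma^2)) *
               (2 * delta * trial$theta_hat2 - delta^2))
}
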