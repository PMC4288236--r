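#' One-sided normal p-value
#'
#' @param z Standardized statistic(s).
#' @return `1 - Phi(z)`, vectorized.
#' @export
marginal_pvalue <- function(z) stats::pnorm(z, lower.tail = FALSE)

#' Simes p-value for an intersection hypothesis
#'
#' With ordered p-values `p_(1) <= ... <= p_(n)`, the Simes combination is
#' `min_j n * p_(j) / j`, capped at one. Valid for positively dependent
#' one-sided tests, and conservative for many-to-one comparisons sharing a
#' control; the extra conservatism is removed downstream by calibrating the
#' decision rule's critical value.
#'
#' @param pvals Non-empty collection of p-values in `[0, 1]`.
#' @return The Simes p-value.
#' @examples
#' simes_pvalue(c(0.01, 0.04))
#' @export
simes_pvalue <- function(pvals) {
  if (length(pvals) == 0L) stop("empty p-value collection")
  stopifnot(all(pvals >= 0), all(pvals <= 1))
  n <- length(pvals)
  min(1, min(n * sort(pvals) / seq_len(n)))
}

## Exact one-sided Dunnett tail probability pr{max_i Z_i >= t} for n
## statistics versus a shared control (equicorrelation 1/2):
## integral phi(u) * (1 - Phi(u + sqrt(2) t)^n) du.
## integrate() loses relative accuracy below ~1e-13; there the Bonferroni
## tail n * (1 - Phi(t)) is exact to well beyond decision-relevant precision.
dunnett_tail <- function(t, n) {
  val <- tryCatch(
    stats::integrate(function(u) stats::dnorm(u) *
                       (1 - stats::pnorm(u + sqrt(2) * t)^n),
                     -Inf, Inf, rel.tol = 1e-10)$value,
    error = function(e) NA_real_)
  if (is.na(val) || val < 1e-13) val <- n * stats::pnorm(t, lower.tail = FALSE)
  min(1, val)
}

#' Dunnett p-value for an intersection hypothesis
#'
#' One-sided many-to-one p-value for the maximum of the supplied stage-1
#' statistics, which are equicorrelated at 1/2 through the common control arm:
#' `pr{max of n such statistics >= max(z_values)}` under the intersection
#' null, computed by adaptive quadrature (absolute accuracy better than 1e-8).
#'
#' @param z_values Stage-1 standardized statistics for the arms in the
#'   intersection (non-empty).
#' @return The Dunnett p-value.
#' @examples
#' dunnett_pvalue(c(0, 0))  # 2/3 by exchangeability of three arm means
#' @export
dunnett_pvalue <- function(z_values) {
  if (length(z_values) == 0L) stop("empty statistic collection")
  dunnett_tail(max(z_values), length(z_values))
}

## Vectorized Dunnett tail via cubic-spline interpolation of log p on a fine
## t-grid (error < 1e-8 on [-8, 7.5]); Bonferroni tail beyond. Interpolators
## are cached per n.
.dunnett_cache <- new.env(parent = emptyenv())
dunnett_tail_vec <- function(t, n) {
  key <- as.character(n)
  if (is.null(.dunnett_cache[[key]])) {
    tg <- seq(-8, 7.5, by = 0.01)
    .dunnett_cache[[key]] <- stats::splinefun(tg, log(vapply(tg, dunnett_tail, 0, n = n)))
  }
  f <- .dunnett_cache[[key]]
  out <- numeric(length(t))
  lo <- t < -8; hi <- t > 7.5; mid <- !lo & !hi
  out[lo] <- 1
  out[mid] <- pmin(1, exp(f(t[mid])))
  out[hi] <- n * stats::pnorm(t[hi], lower.tail = FALSE)
  out
}

#' Combine stage-wise p-values
#'
#' Two pre-specified combination functions for independent stage-wise
#' p-values, both returned on a "larger is more significant" scale:
#'
#' * `"inverse_chisq"` (Fisher): `-log(p1 * p2)`. The unadjusted alpha-level
#'   reference on this scale is the upper-alpha chi-squared(4 df) quantile
#'   divided by two; calibrated critical values of the selection design are
#'   directly comparable to (and smaller than) that reference.
#' * `"inverse_normal"`: `w1 * qnorm(1 - p1) + w2 * qnorm(1 - p2)` with
#'   pre-specified weights satisfying `w1^2 + w2^2 = 1`, here
#'   `w_i = sqrt(m_i / (m1 + m2))`; the null reference distribution is
#'   standard normal.
#'
#' @param p1,p2 Stage-wise p-values in `(0, 1]`. A zero p-value saturates the
#'   statistic at `+Inf` with a warning.
#' @param method `"inverse_chisq"` or `"inverse_normal"`.
#' @param w1,w2 Inverse-normal weights (checked to satisfy `w1^2 + w2^2 = 1`).
#' @return The combination statistic (vectorized over `p1`, `p2`).
#' @examples
#' combine_pvalues(0.05, 0.05, "inverse_chisq")
#' combine_pvalues(0.025, 0.025, "inverse_normal", w1 = 1/sqrt(2), w2 = 1/sqrt(2))
#' @export
combine_pvalues <- function(p1, p2, method = c("inverse_chisq", "inverse_normal"),
                            w1 = NULL, w2 = NULL) {
  method <- match.arg(method)
  if (any(p1 == 0, na.rm = TRUE) || any(p2 == 0, na.rm = TRUE))
    warning("zero p-value: combination statistic saturates at +Inf")
  if (method == "inverse_chisq") return(-log(p1 * p2))
  stopifnot(!is.null(w1), !is.null(w2))
  if (abs(w1^2 + w2^2 - 1) > 1e-8)
    stop("inverse normal weights must satisfy w1^2 + w2^2 = 1")
  w1 * stats::qnorm(1 - p1) + w2 * stats::qnorm(1 - p2)
}

## Stage-1 intersection p-value for the arms in `idx` (indices into z1)
stage1_intersection_pvalue <- function(z1, idx, intersection = c("simes", "dunnett")) {
  intersection <- match.arg(intersection)
  if (intersection == "simes") simes_pvalue(marginal_pvalue(z1[idx]))
  else dunnett_pvalue(z1[idx])
}

## All subsets of {1..K} containing i_star, as a list of index vectors
subsets_containing <- function(K, i_star) {
  others <- setdiff(seq_len(K), i_star)
  n <- length(others)
  lapply(0:(2^n - 1L), function(mask) {
    sort(c(i_star, others[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]))
  })
}

#' Full intersection table for a trial
#'
#' Enumerates every intersection hypothesis containing the selected arm and
#' tabulates its stage-1 p-value, stage-2 p-value and combination statistic.
#' Intersections not containing the selected arm are irrelevant to the closed
#' test of its hypothesis and are omitted.
#'
#' @param trial A `seam_trial` that continued to stage 2.
#' @param method Combination function, see [combine_pvalues()].
#' @param intersection `"simes"` or `"dunnett"` stage-1 intersection tests.
#' @return A data frame with one row per intersection: the index set, `p1`,
#'   `p2` and `combined`.
#' @export
intersection_table <- function(trial,
                               method = c("inverse_chisq", "inverse_normal"),
                               intersection = c("simes", "dunnett")) {
  method <- match.arg(method)
  intersection <- match.arg(intersection)
  if (!isTRUE(trial$continued))
    stop("closed testing applies only to trials that continued to stage 2")
  design <- trial$design
  w1 <- sqrt(design$m1 / (design$m1 + design$m2))
  w2 <- sqrt(design$m2 / (design$m1 + design$m2))
  p2 <- marginal_pvalue(trial$z2)
  sets <- subsets_containing(design$K, trial$selected)
  p1 <- vapply(sets, function(I) stage1_intersection_pvalue(trial$z1, I, intersection), 0)
  data.frame(I = vapply(sets, paste, "", collapse = ","),
             size = lengths(sets),
             p1 = p1, p2 = p2,
             combined = combine_pvalues(p1, p2, method, w1 = w1, w2 = w2))
}

#' Closed test of the selected treatment's hypothesis
#'
#' Rejects the selected arm's null hypothesis if and only if, for every
#' intersection hypothesis containing it (all `2^(K-1)` subsets), the
#' combination of the stage-1 intersection p-value and the stage-2 p-value
#' reaches the critical value. This is the closed testing construction that
#' gives strong familywise error control when each intersection test is valid
#' at the working level.
#'
#' @inheritParams intersection_table
#' @param critical Critical value on the combination scale.
#' @return Logical: is the selected arm's hypothesis rejected?
#' @export
closed_test_reject <- function(trial, method = c("inverse_chisq", "inverse_normal"),
                               intersection = c("simes", "dunnett"), critical) {
  tab <- intersection_table(trial, method, intersection)
  all(tab$combined >= critical)
}

## Fast batch path: the binding intersection is the one with the largest
## stage-1 p-value (both combiners are decreasing in p1 for fixed p2).
## * Dunnett: every subset containing i_star has the same max statistic
##   z1[i_star] (the selected arm maximizes z1), and the tail probability
##   increases with subset size, so the full set is binding.
## * Simes: the Simes p-value is componentwise nondecreasing in the inputs,
##   so for each subset size n the binding subset is i_star plus the n-1
##   largest other p-values; maximize over n.
## Returns, per replicate, max over intersections I containing the selected
## arm of the stage-1 intersection p-value.
max_stage1_pvalue <- function(z1, selected, intersection = c("simes", "dunnett")) {
  intersection <- match.arg(intersection)
  R <- nrow(z1); K <- ncol(z1)
  if (intersection == "dunnett")
    return(dunnett_tail_vec(z1[cbind(seq_len(R), selected)], K))
  p <- marginal_pvalue(z1)
  ## row-sort ascending; column 1 is the selected arm's p (the row minimum)
  psort <- matrix(p[order(row(p), p)], R, K, byrow = TRUE)
  M <- psort[, 1L]
  if (K >= 2L) for (n in 2:K) {
    ## subset: selected arm plus the n-1 largest remaining p-values
    mat <- psort[, c(1L, (K - n + 2L):K), drop = FALSE]
    sim <- mat[, 1L] * n
    for (j in 2:n) sim <- pmin(sim, mat[, j] * n / j)
    M <- pmax(M, pmin(sim, 1))
  }
  M
}
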