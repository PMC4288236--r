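#' Specify a seamless two-stage selection design
#'
#' A seamless phase II/III design compares `K` experimental treatments with a
#' common control. In stage 1, `m1` patients are randomized to each of the
#' `K + 1` arms and the treatment with the largest estimated effect versus
#' control is selected; the trial stops for futility if that estimate falls
#' below `ell`. In stage 2, a further `m2` patients are randomized to each of
#' the selected treatment and control, and a pre-specified final decision rule
#' tests the selected treatment's null hypothesis at familywise level `alpha`
#' using data from one or both stages.
#'
#' Responses are normal with known standard deviation `sigma`; the treatment
#' effects are differences in means versus control, and all hypotheses are
#' one-sided (`H0i: theta_i <= 0`). Group sizes may be non-integer: under the
#' known-variance normal model fractional sample sizes are well defined, which
#' keeps efficiency and sample-size-matching searches continuous.
#'
#' @param K Number of experimental arms (integer, at least 2; `K = 1` is
#'   accepted for degenerate single-arm checks).
#' @param m1 Per-arm stage-1 group size (positive, may be fractional).
#' @param m2 Per-arm stage-2 group size (positive, may be fractional).
#' @param ell Futility threshold on the effect-estimate scale; the trial stops
#'   after stage 1 if the best estimated effect is below `ell`. May be `-Inf`.
#' @param sigma Known response standard deviation (positive).
#' @param alpha One-sided familywise error level, in (0, 0.5).
#'
#' @return An object of class `seam_design`.
#' @examples
#' d <- seam_design(K = 5, m1 = 28, m2 = 140, ell = 0, sigma = 5, alpha = 0.025)
#' d
#' @export
seam_design <- function(K, m1, m2, ell = 0, sigma = 1, alpha = 0.025) {
  stopifnot(length(K) == 1L, K >= 1, K == round(K),
            length(m1) == 1L, m1 > 0, length(m2) == 1L, m2 > 0,
            length(ell) == 1L, !is.na(ell),
            length(sigma) == 1L, sigma > 0,
            length(alpha) == 1L, alpha > 0, alpha < 0.5)
  structure(list(K = as.integer(K), m1 = m1, m2 = m2, ell = ell,
                 sigma = sigma, alpha = alpha),
            class = "seam_design")
}

#' @export
print.seam_design <- function(x, ...) {
  cat(sprintf(
    "Seamless phase II/III design: K = %d arms + control\n  m1 = %g, m2 = %g, futility ell = %g, sigma = %g, alpha = %g\n",
    x$K, x$m1, x$m2, x$ell, x$sigma, x$alpha))
  invisible(x)
}

## all permutations of a vector, rows of a matrix; guarded for K <= 8
seam_permutations <- function(v) {
  n <- length(v)
  if (n > 8L)
    stop("permutation enumeration is limited to K <= 8 arms")
  if (n == 1L) return(matrix(v, 1L, 1L))
  do.call(rbind, lapply(seq_len(n), function(i) {
    sub <- seam_permutations(v[-i])
    cbind(rep(v[i], nrow(sub)), sub, deparse.level = 0)
  }))
}

#' Define a family of treatment-effect configurations
#'
#' A scenario family describes the configurations of treatment effects a
#' decision rule is optimized (or evaluated) for. All families are built from
#' a shape vector `(gamma_1, ..., gamma_{K-1}, 1)` scaled by `delta`, the
#' effect of the best treatment:
#'
#' * `"single"`: one shape value `gamma` shared by all inferior arms. The
#'   prior places mass `1/(K+1)` on the null configuration and `1/(K+1)` on
#'   each placement of the best arm.
#' * `"permutation"`: strictly increasing shapes; the support is the set `Q`
#'   of all `K!` permutations of the shape vector, each permutation receiving
#'   mass `1/{(K+1)(K-1)!}`, plus mass `1/(K+1)` on the null.
#' * `"ordered"`: as `"permutation"`, except that the mass assigned to
#'   configurations whose best arm is arm `K` is concentrated on the single
#'   dose-ordered vector `(gamma_1, ..., gamma_{K-1}, 1) * delta`, encoding a
#'   suspected monotone dose-response relationship.
#'
#' A `"permutation"` request with all shapes equal is collapsed to the
#' `"single"` kind: its `(K-1)!` identical permutation terms factor out of
#' every likelihood-ratio statistic.
#'
#' @param gammas Shape values in `[0, 1)`: a scalar for `"single"`, a strictly
#'   increasing vector of length `K - 1` otherwise.
#' @param delta Positive effect scale (the best arm's effect).
#' @param kind One of `"single"`, `"permutation"`, `"ordered"`.
#' @param K Number of experimental arms; required for `"single"`, otherwise
#'   inferred as `length(gammas) + 1`.
#'
#' @return An object of class `seam_scenario` with elements `kind`, `gammas`
#'   (length `K - 1`), `delta`, `K`, and the minimum familywise-error weight
#'   diagnostics `min_coefficient` / `strong_fwer` (see
#'   [min_fwer_coefficient()]).
#' @examples
#' make_scenario(0.5, delta = 2, kind = "single", K = 5)
#' make_scenario(c(0.75, 0.8125, 0.875, 0.9375), delta = 2, kind = "permutation")
#' @export
make_scenario <- function(gammas, delta, kind = c("single", "permutation", "ordered"),
                          K = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(gammas) || anyNA(gammas) || any(gammas < 0) || any(gammas >= 1))
    stop("'gammas' must lie in [0, 1)")
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta <= 0)
    stop("'delta' must be a positive scalar")
  if (kind == "single") {
    if (length(gammas) == 1L) {
      if (is.null(K)) stop("'K' is required for a single-shape scenario")
    } else {
      if (length(unique(gammas)) != 1L)
        stop("a single-shape scenario takes one gamma value")
      K <- if (is.null(K)) length(gammas) + 1L else K
      gammas <- gammas[1L]
    }
    K <- as.integer(K)
    if (K < 2L) stop("scenario families require K >= 2")
    gammas <- rep(gammas, K - 1L)
  } else {
    if (is.null(K)) K <- length(gammas) + 1L
    K <- as.integer(K)
    if (length(gammas) != K - 1L)
      stop("'gammas' must have length K - 1 for permutation/ordered scenarios")
    if (length(unique(gammas)) == 1L) {
      ## identical shapes: the (K-1)! permutation terms coincide; collapse
      return(make_scenario(gammas[1L], delta, "single", K = K))
    }
    if (any(diff(gammas) <= 0))
      stop("'gammas' must be strictly increasing for permutation/ordered scenarios")
  }
  mc <- min_fwer_coefficient(gammas, K)
  structure(list(kind = kind, gammas = gammas, delta = delta, K = K,
                 min_coefficient = mc, strong_fwer = mc >= 0),
            class = "seam_scenario")
}

#' @export
print.seam_scenario <- function(x, ...) {
  cat(sprintf("Effect scenario (%s%s): shape (%s, 1) x delta = %g, K = %d\n",
              x$kind, if (x$strong_fwer) "" else ", pseudo-optimal regime",
              paste(signif(x$gammas, 4), collapse = ", "), x$delta, x$K))
  invisible(x)
}

#' Prior support of a scenario family
#'
#' Enumerates the discrete prior over effect configurations implied by a
#' scenario: a matrix of support vectors and their prior masses. The null
#' configuration carries mass `1/(K+1)` in every family.
#'
#' @param scenario A [make_scenario()] object.
#' @return A list with `theta` (rows are support vectors, first row the null)
#'   and `mass` (prior masses, summing to one).
#' @export
scenario_support <- function(scenario) {
  stopifnot(inherits(scenario, "seam_scenario"))
  K <- scenario$K
  shape <- c(scenario$gammas, 1) * scenario$delta
  null_row <- matrix(0, 1L, K)
  if (scenario$kind == "single") {
    th <- do.call(rbind, lapply(seq_len(K), function(i) {
      v <- rep(scenario$gammas[1L] * scenario$delta, K); v[i] <- scenario$delta; v
    }))
    return(list(theta = rbind(null_row, th),
                mass = c(1, rep(1, K)) / (K + 1)))
  }
  Q <- seam_permutations(shape)
  if (scenario$kind == "permutation") {
    return(list(theta = rbind(null_row, Q),
                mass = c(1 / (K + 1),
                         rep(1 / ((K + 1) * factorial(K - 1)), nrow(Q)))))
  }
  ## ordered: mass of the block with best arm K concentrated on the sorted vector
  keep <- Q[, K] != scenario$delta
  list(theta = rbind(null_row, Q[keep, , drop = FALSE], matrix(shape, 1L, K)),
       mass = c(1 / (K + 1),
                rep(1 / ((K + 1) * factorial(K - 1)), sum(keep)),
                1 / (K + 1)))
}

## Likelihood-ratio terms relevant when arm `i_star` is selected: the support
## vectors phi with phi[i_star] = delta and their log prior weights, normalized
## so that the null configuration has weight one (log-weight zero).
scenario_terms <- function(scenario, i_star) {
  K <- scenario$K
  delta <- scenario$delta
  if (scenario$kind == "single") {
    phi <- matrix(scenario$gammas[1L] * delta, 1L, K)
    phi[1L, i_star] <- delta
    return(list(phi = phi, logw = 0))
  }
  shape <- c(scenario$gammas, 1) * delta
  if (scenario$kind == "ordered" && i_star == K)
    return(list(phi = matrix(shape, 1L, K), logw = 0))
  sub <- seam_permutations(shape[-length(shape)])
  n <- nrow(sub)
  phi <- matrix(0, n, K)
  phi[, i_star] <- delta
  phi[, -i_star] <- sub
  list(phi = phi, logw = rep(-lfactorial(K - 1), n))
}

#' Stage-1 covariance of the effect estimates
#'
#' The stage-1 effect estimates share the control-arm mean, giving variance
#' `2 sigma^2 / m1` and covariance `sigma^2 / m1`. The inverse has the closed
#' form `(m1 / sigma^2) (I - J/(K+1))` with `J` the all-ones matrix
#' (Sherman-Morrison applied to `I + J`).
#'
#' @param design A [seam_design()] object.
#' @return A list with the `K x K` matrix `V` and its analytic inverse
#'   `V_inverse`.
#' @examples
#' stage1_covariance(seam_design(K = 2, m1 = 1, sigma = 1))$V
#' @export
stage1_covariance <- function(design) {
  stopifnot(inherits(design, "seam_design"))
  K <- design$K
  s2m <- design$sigma^2 / design$m1
  V <- s2m * (diag(K) + matrix(1, K, K))
  Vinv <- (1 / s2m) * (diag(K) - matrix(1, K, K) / (K + 1))
  list(V = V, V_inverse = Vinv)
}

#' Smallest familywise-error weight of an optimal rule
#'
#' The likelihood-ratio statistics of the optimal decision rules are linear in
#' the stage-1 effect estimates with coefficient vectors
#' `(m1/sigma^2) (phi - 1 * sum(phi)/(K+1))` for support vectors `phi`. Strong
#' familywise error control from null calibration requires every coefficient
#' to be non-negative; otherwise increasing a true inferior effect can inflate
#' the error rate and the rule is only "pseudo-optimal" (an upper power
#' bound). This function returns the minimum coefficient over all support
#' vectors and components, expressed in units of
#' `m1 * delta / ((K + 1) * sigma^2)`:
#' `(K + 1) * min(gammas) - (1 + sum(gammas))`.
#'
#' For `K - 1` shapes equally spaced between `gamma_1` and 1 the minimum is
#' positive exactly when `gamma_1 > K / (K + 2)`.
#'
#' @param gammas Shape values (scalar for a single-shape family, or the
#'   `K - 1` shapes of a permutation family).
#' @param K Number of experimental arms.
#' @return The scaled minimum coefficient; non-negative values indicate that
#'   null calibration delivers strong familywise error control.
#' @export
min_fwer_coefficient <- function(gammas, K) {
  stopifnot(K >= 2, all(gammas >= 0), all(gammas < 1))
  g <- if (length(gammas) == 1L) rep(gammas, K - 1L) else gammas
  stopifnot(length(g) == K - 1L)
  (K + 1) * min(g) - (1 + sum(g))
}

#' Read a design and scenario from a YAML configuration file
#'
#' The configuration dialect is YAML with top-level keys `K`, `m1`, `m2`,
#' `ell`, `sigma`, `alpha` for the design and, optionally, `family`
#' (`single`/`permutation`/`ordered`), `gammas` and `delta` for a scenario.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `design` (a [seam_design()]) and `scenario`
#'   (a [make_scenario()] or `NULL`).
#' @export
read_design_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("K", "m1", "m2", "sigma")
  if (!all(need %in% names(cfg)))
    stop("config must provide keys: ", paste(need, collapse = ", "))
  design <- seam_design(K = cfg$K, m1 = cfg$m1, m2 = cfg$m2,
                        ell = if (is.null(cfg$ell)) 0 else cfg$ell,
                        sigma = cfg$sigma,
                        alpha = if (is.null(cfg$alpha)) 0.025 else cfg$alpha)
  scenario <- NULL
  if (!is.null(cfg$family))
    scenario <- make_scenario(unlist(cfg$gammas), cfg$delta, kind = cfg$family,
                              K = cfg$K)
  list(design = design, scenario = scenario)
}

#' Write a design (and optional scenario) to a YAML configuration file
#'
#' Inverse of [read_design_config()]; round-trips losslessly.
#'
#' @param design A [seam_design()].
#' @param scenario Optional [make_scenario()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design_config <- function(design, path, scenario = NULL) {
  cfg <- list(K = design$K, m1 = design$m1, m2 = design$m2, ell = design$ell,
              sigma = design$sigma, alpha = design$alpha)
  if (!is.null(scenario))
    cfg <- c(cfg, list(family = scenario$kind,
                       gammas = if (scenario$kind == "single")
                         scenario$gammas[1L] else scenario$gammas,
                       delta = scenario$delta))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
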