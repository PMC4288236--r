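#' Calibrated critical values for the six standard decision rules
#'
#' Calibrates the conventional, pooled-z (TSE) and four closed-testing
#' combination rules for one design, sharing a single simulated null ensemble
#' (common random numbers), and tabulates the critical values with their
#' error-rate standard errors. The conventional rule's critical value is
#' analytic and reported with zero standard error.
#'
#' @param design A [seam_design()]; the default is a five-arm migraine-dose
#'   style design with `m1 = 28`, `m2 = 140`, `sigma = 5`, `alpha = 0.025`.
#' @param replications Null replicates shared by all simulated calibrations
#'   (`2e5` is a fast mode; `1e6` matches the reported precision of the
#'   reference values).
#' @param seed Integer seed.
#' @param method Calibration method, see [calibrate_critical()].
#' @return A data frame with columns `rule`, `scale`, `critical`, `fwer`,
#'   `fwer_se`, `method`, `replications`, plus the calibrated rules as the
#'   `"rules"` attribute.
#' @examples
#' \donttest{
#' reproduce_table1(replications = 5e4, seed = 1)
#' }
#' @export
reproduce_table1 <- function(design = seam_design(K = 5, m1 = 28, m2 = 140,
                                                  ell = 0, sigma = 5,
                                                  alpha = 0.025),
                             replications = 2e5, seed = 1,
                             method = "conditional") {
  ids <- c("conventional", "tse",
           "bk_invchisq_simes", "bk_invchisq_dunnett",
           "bk_invnormal_simes", "bk_invnormal_dunnett")
  scale <- c(conventional = "z", tse = "z",
             bk_invchisq_simes = "-ln(p1*p2)", bk_invchisq_dunnett = "-ln(p1*p2)",
             bk_invnormal_simes = "z", bk_invnormal_dunnett = "z")
  batch <- simulate_batch(design, rep(0, design$K), replications, seed,
                          permutation_randomized = FALSE)
  rules <- lapply(ids, function(id) {
    r <- seam_rule(id, design)
    if (id == "conventional") return(r)
    calibrate_on_batch(r, batch, design$alpha, method)
  })
  names(rules) <- ids
  out <- data.frame(
    rule = ids,
    scale = unname(scale[ids]),
    critical = vapply(rules, function(r) r$critical, 0),
    fwer = vapply(rules, function(r)
      if (identical(r$calibration$method, "analytic")) design$alpha
      else r$calibration$fwer, 0),
    fwer_se = vapply(rules, function(r)
      if (identical(r$calibration$method, "analytic")) 0 else r$calibration$se, 0),
    method = vapply(rules, function(r) r$calibration$method, ""),
    replications = vapply(rules, function(r)
      as.numeric(r$calibration$replications), 0),
    row.names = NULL)
  attr(out, "rules") <- rules
  out
}

#' Generate deterministic trial fixtures
#'
#' Writes a CSV of simulated trial records (with a JSON provenance sidecar)
#' and a hand-constructed edge-case pack: an exact stage-1 tie (selection
#' breaks to the lowest index), a stopped trial, a best estimate exactly at
#' the futility threshold (classified as continuing) and an extreme trial
#' with saturated p-values.
#'
#' @param design A [seam_design()].
#' @param theta Effect configuration for the simulated records.
#' @param n Number of simulated records (at least 1).
#' @param seed Integer seed; identical seeds give byte-identical files.
#' @param path Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
generate_fixtures <- function(design, theta, n, seed, path) {
  if (n < 1) stop("'n' must be at least 1")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  batch <- simulate_batch(design, theta, n, seed, permutation_randomized = FALSE)
  batch$seed <- seed
  trials_path <- file.path(path, "trials.csv")
  export_batch(batch, trials_path)
  K <- design$K
  edge <- list(
    tie       = make_trial(design, c(1, 1, rep(0, K - 2))[seq_len(K)], 0.5),
    stopped   = make_trial(design, rep(design$ell - 1, K)),
    boundary  = make_trial(design, c(rep(design$ell - 1, K - 1), design$ell), 0.5),
    saturated = make_trial(design, c(rep(0, K - 1), 40 * design$sigma),
                           40 * design$sigma))
  edf <- do.call(rbind, lapply(names(edge), function(nm) {
    tr <- edge[[nm]]
    data.frame(case = nm,
               t(matrix(tr$theta_hat1, dimnames = list(paste0("theta_hat1_", seq_len(K))))),
               selected = tr$selected, continued = tr$continued,
               theta_hat2 = tr$theta_hat2)
  }))
  edge_path <- file.path(path, "edge_cases.csv")
  utils::write.csv(edf, edge_path, row.names = FALSE)
  invisible(c(trials_path, paste0(trials_path, ".json"), edge_path))
}
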