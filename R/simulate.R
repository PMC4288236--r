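## Deterministic sub-seed for a named stream: a small polynomial hash of the
## stream label folded into the user seed, kept below 2^31 so it is a valid
## integer seed on all platforms.
seam_stream_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seam_stream_seed(seed, stream))
  expr
}

## Standard-normal draws generated in fixed-size row chunks so that very large
## ensembles do not require a single allocation-and-fill; the chunk size is a
## constant, keeping the draws reproducible for a given seed.
seam_norm_matrix <- function(n, k, chunk = 1e6) {
  if (n <= chunk) return(matrix(stats::rnorm(n * k), n, k))
  starts <- seq(1L, n, by = chunk)
  do.call(rbind, lapply(starts, function(s) {
    rows <- min(chunk, n - s + 1L)
    matrix(stats::rnorm(rows * k), rows, k)
  }))
}

#' Standard-normal building blocks for coupled simulations
#'
#' Draws the per-replicate standard normal variates from which trial ensembles
#' are built: one column per arm mean (control first) plus one column for the
#' stage-2 estimate. Re-using the same draws across design variants (different
#' `m1`, `m2`, or scale factors) couples the compared simulations through
#' common random numbers, which sharply reduces the variance of estimated
#' differences in power.
#'
#' @param replications Number of replicates.
#' @param K Number of experimental arms.
#' @param seed Integer seed.
#' @param stream Stream label, so independent ensembles can be derived from
#'   one seed.
#' @return A list with matrices `eps1` (`replications x (K+1)`, arm-mean
#'   variates, control in column 1) and `eps2` (stage-2 variates, one column).
#' @export
simulate_null_normals <- function(replications, K, seed, stream = "ensemble") {
  stopifnot(replications >= 1)
  eps1 <- with_stream(seed, paste0(stream, ":stage1"),
                      seam_norm_matrix(replications, K + 1L))
  eps2 <- with_stream(seed, paste0(stream, ":stage2"),
                      seam_norm_matrix(replications, 1L))
  list(eps1 = eps1, eps2 = eps2)
}

## stage-1 argmax with deterministic lowest-index tie-breaking
select_best <- function(theta_hat1) {
  max.col(theta_hat1, ties.method = "first")
}

#' Build a trial ensemble from pre-drawn standard normals
#'
#' Applies a design and an effect configuration to standard-normal draws (see
#' [simulate_null_normals()]): stage-1 arm means are
#' `mu0 + theta_i + sigma/sqrt(m1) * eps`, effect estimates are differences
#' versus the control arm (which induces the common-control covariance
#' exactly), the best arm is selected with ties broken to the lowest index,
#' the futility rule stops the trial when the best estimate falls below
#' `ell` (an estimate exactly at `ell` continues), and stage-2 estimates are
#' drawn for continuing trials only.
#'
#' @param normals Output of [simulate_null_normals()].
#' @param design A [seam_design()].
#' @param theta Effect configuration: a length-`K` vector, or a
#'   `replications x K` matrix with one configuration per replicate.
#' @param mu0 Control-arm mean; decisions are invariant to it (all rules use
#'   arm-mean differences only) and it defaults to zero.
#' @return A `seam_batch`: column-oriented ensemble with `theta_hat1`
#'   (`R x K`), `z1` (`R x K` standardized stage-1 statistics), `selected`,
#'   `continued`, `theta_hat2`, `z2` (`NA` where the trial stopped), plus the
#'   design and the effect configuration.
#' @export
batch_from_normals <- function(normals, design, theta, mu0 = 0) {
  K <- design$K
  R <- nrow(normals$eps1)
  stopifnot(ncol(normals$eps1) == K + 1L)
  s1 <- design$sigma / sqrt(design$m1)
  arm <- mu0 + normals$eps1 * s1
  if (is.matrix(theta)) {
    stopifnot(nrow(theta) == R, ncol(theta) == K)
    arm[, -1L] <- arm[, -1L] + theta
  } else {
    stopifnot(length(theta) == K)
    arm[, -1L] <- sweep(arm[, -1L, drop = FALSE], 2L, theta, "+")
  }
  th1 <- arm[, -1L, drop = FALSE] - arm[, 1L]
  z1 <- th1 * sqrt(design$m1) / (design$sigma * sqrt(2))
  sel <- select_best(th1)
  best <- th1[cbind(seq_len(R), sel)]
  cont <- best >= design$ell
  th_sel <- if (is.matrix(theta)) theta[cbind(seq_len(R), sel)] else theta[sel]
  th2 <- th_sel + normals$eps2[, 1L] * design$sigma * sqrt(2 / design$m2)
  th2[!cont] <- NA_real_
  z2 <- th2 * sqrt(design$m2) / (design$sigma * sqrt(2))
  structure(list(design = design, theta = theta, theta_hat1 = th1, z1 = z1,
                 selected = sel, continued = cont, theta_hat2 = th2, z2 = z2,
                 replications = R),
            class = "seam_batch")
}

#' Simulate an ensemble of seamless trials
#'
#' Simulates `replications` independent trials under a fixed effect vector or
#' a scenario family. For a scenario, each replicate draws an independent
#' uniform permutation of the shape vector, so that power averaged over
#' placements of the best arm can be estimated; the per-replicate effect
#' matrix is stored in the result.
#'
#' @param design A [seam_design()].
#' @param theta A length-`K` numeric effect vector, or a [make_scenario()]
#'   object (its shape vector is permuted independently per replicate).
#' @param replications Number of replicates (at least 1).
#' @param seed Integer seed; identical seeds give identical batches.
#' @param permutation_randomized Logical; when `theta` is a scenario this is
#'   forced `TRUE`. A plain vector with `permutation_randomized = TRUE` is
#'   permuted per replicate as well.
#' @param mu0 Control-arm mean (default 0).
#' @return A `seam_batch` (see [batch_from_normals()]), with the seed recorded.
#' @examples
#' d <- seam_design(K = 5, m1 = 28, m2 = 140, sigma = 5)
#' b <- simulate_batch(d, rep(0, 5), replications = 100, seed = 1)
#' mean(b$continued)
#' @export
simulate_batch <- function(design, theta, replications, seed,
                           permutation_randomized = inherits(theta, "seam_scenario"),
                           mu0 = 0) {
  stopifnot(replications >= 1)
  normals <- simulate_null_normals(replications, design$K, seed)
  if (inherits(theta, "seam_scenario")) {
    stopifnot(theta$K == design$K)
    theta <- c(theta$gammas, 1) * theta$delta
    permutation_randomized <- TRUE
  }
  if (permutation_randomized) {
    theta <- permuted_theta_matrix(theta, replications, design$K, seed)
  }
  out <- batch_from_normals(normals, design, theta, mu0 = mu0)
  out$seed <- seed
  out$permutation_randomized <- permutation_randomized
  out
}

## R x K matrix of per-replicate uniform permutations of a shape vector
permuted_theta_matrix <- function(theta, replications, K, seed) {
  stopifnot(length(theta) == K)
  idx <- with_stream(seed, "perm", {
    m <- matrix(stats::runif(replications * K), replications, K)
    ord <- order(row(m), m)               # column-major linear indices
    matrix((ord - 1L) %/% replications + 1L, replications, K, byrow = TRUE)
  })
  matrix(theta[idx], replications, K)
}

#' Simulate a single trial
#'
#' Convenience wrapper around [simulate_batch()] for one replicate.
#'
#' @inheritParams simulate_batch
#' @param rng_seed Integer seed.
#' @return A `seam_trial`: list with `theta_hat1`, `z1`, `selected`,
#'   `continued`, `theta_hat2`, `z2` and the design.
#' @export
simulate_trial <- function(design, theta, rng_seed, mu0 = 0) {
  b <- simulate_batch(design, theta, 1L, rng_seed,
                      permutation_randomized = FALSE, mu0 = mu0)
  trial_view(b, 1L)
}

#' Extract one trial from a batch
#'
#' @param batch A `seam_batch`.
#' @param i Replicate index.
#' @return A `seam_trial` view of replicate `i`.
#' @export
trial_view <- function(batch, i) {
  stopifnot(inherits(batch, "seam_batch"), i >= 1, i <= batch$replications)
  structure(list(design = batch$design,
                 theta_hat1 = batch$theta_hat1[i, ],
                 z1 = batch$z1[i, ],
                 selected = batch$selected[i],
                 continued = batch$continued[i],
                 theta_hat2 = batch$theta_hat2[i],
                 z2 = batch$z2[i]),
            class = "seam_trial")
}

#' Construct a trial record from stage summaries
#'
#' Builds a `seam_trial` directly from stage-1 effect estimates and an
#' optional stage-2 estimate, applying the design's selection and futility
#' rules. Useful for edge-case fixtures (exact ties, boundary futility).
#'
#' @param design A [seam_design()].
#' @param theta_hat1 Length-`K` stage-1 effect estimates.
#' @param theta_hat2 Stage-2 effect estimate for the selected arm (ignored if
#'   the trial stops).
#' @return A `seam_trial`.
#' @export
make_trial <- function(design, theta_hat1, theta_hat2 = NA_real_) {
  stopifnot(length(theta_hat1) == design$K)
  sel <- select_best(matrix(theta_hat1, 1L))
  cont <- theta_hat1[sel] >= design$ell
  th2 <- if (cont) theta_hat2 else NA_real_
  structure(list(design = design,
                 theta_hat1 = theta_hat1,
                 z1 = theta_hat1 * sqrt(design$m1) / (design$sigma * sqrt(2)),
                 selected = sel,
                 continued = cont,
                 theta_hat2 = th2,
                 z2 = th2 * sqrt(design$m2) / (design$sigma * sqrt(2))),
            class = "seam_trial")
}

#' @export
print.seam_batch <- function(x, ...) {
  cat(sprintf("seam_batch: %d replicates, K = %d; continued %.1f%%\n",
              x$replications, x$design$K, 100 * mean(x$continued)))
  invisible(x)
}

#' Probability of continuing past the futility analysis under the null
#'
#' Under the global null the trial continues when the largest stage-1 effect
#' estimate reaches the futility threshold. Writing `u` for the standardized
#' control-arm mean, the stopping probability is
#' `integral phi(u) * Phi(u + ell * sqrt(m1) / sigma)^K du`; for `ell = 0`
#' exchangeability of the `K + 1` arm means gives the exact value
#' `K / (K + 1)` for the continuation probability.
#'
#' @param design A [seam_design()].
#' @return The continuation probability under the null configuration.
#' @examples
#' continuation_probability(seam_design(K = 5, m1 = 28, m2 = 140, sigma = 5))
#' @export
continuation_probability <- function(design) {
  if (design$ell == 0) return(design$K / (design$K + 1))
  if (design$ell == -Inf) return(1)
  shift <- design$ell * sqrt(design$m1) / design$sigma
  stopp <- stats::integrate(function(u) stats::dnorm(u) * stats::pnorm(u + shift)^design$K,
                            -Inf, Inf, rel.tol = 1e-11)$value
  1 - stopp
}

#' Export a batch to CSV with a JSON provenance sidecar
#'
#' One row per replicate: the stage-1 effect estimates, the selected arm, the
#' continuation flag and the stage-2 estimate. A JSON sidecar records the
#' design and seed so the file is reproducible from its provenance alone.
#'
#' @param batch A `seam_batch`.
#' @param path CSV output path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
export_batch <- function(batch, path) {
  df <- as.data.frame(batch$theta_hat1)
  names(df) <- paste0("theta_hat1_", seq_len(batch$design$K))
  df$selected <- batch$selected
  df$continued <- batch$continued
  df$theta_hat2 <- batch$theta_hat2
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(design = unclass(batch$design), seed = batch$seed,
               replications = batch$replications,
               permutation_randomized = isTRUE(batch$permutation_randomized),
               package = "seamsel",
               version = as.character(utils::packageVersion("seamsel")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
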