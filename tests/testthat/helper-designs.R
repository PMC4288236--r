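## shared design factories for the test suite

design5 <- function(alpha = 0.025)
  seam_design(K = 5, m1 = 28, m2 = 140, ell = 0, sigma = 5, alpha = alpha)

design_small <- function(K = 3, m1 = 10, m2 = 30, sigma = 2)
  seam_design(K = K, m1 = m1, m2 = m2, ell = 0, sigma = sigma, alpha = 0.025)

## continuing-trial batch restricted view: indices of continuing replicates
continuing <- function(batch) which(batch$continued)
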