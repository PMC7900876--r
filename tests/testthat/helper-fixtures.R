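# small admissible parameter sets and panel fixtures shared across tests

tiny_params <- function(n = 4, d = 0.05, seed_beta = c(0.03, -0.01, -0.01, -0.01)) {
  H <- diag(n) - 1 / n
  gamma <- H %*% diag(rep(d, n)) %*% H
  beta <- rep_len(seed_beta, n)
  beta <- beta - mean(beta)
  alpha <- rep(1 / n, n)
  iaids_params(alpha, beta, gamma)
}

# reorder a true parameter set to a fitted object's good order
align_params <- function(tr, labels) {
  iaids_params(tr$alpha[labels], tr$beta[labels], tr$gamma[labels, labels],
               alpha0 = tr$alpha0, beta0 = tr$beta0, labels = labels)
}

noise_free_cfg <- function(seed = 42) {
  synthetic_config(seed = seed, share_noise_sd = 0, gcm_spread_sd = 0)
}

# zero-gamma, zero-beta two-stage configuration: shares are constant
flat_share_cfg <- function(seed = 1) {
  cfg <- synthetic_config(seed = seed, share_noise_sd = 0)
  strip <- function(p) iaids_params(p$alpha, rep(0, p$n),
                                    matrix(0, p$n, p$n), labels = p$labels)
  cfg$true_params_stage1 <- strip(cfg$true_params_stage1)
  cfg$true_params_stage2 <- lapply(cfg$true_params_stage2, strip)
  cfg
}

# habitat trend table with one flat fractional change everywhere
uniform_trend <- function(species, trend) {
  expand.grid(species = species, rcp = c("RCP4.5", "RCP8.5"),
              bin = c("T1", "T2", "T3", "T4"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE) |>
    transform(trend = trend)
}
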