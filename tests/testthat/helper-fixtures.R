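# Shared fixtures: all synthetic, built in code at test time.

# Small two-temperature, one-condition study on a coarse FTIR grid (~50 rows).
tiny_sim_config <- function(seed = 1L, ...) {
  sim_config(conditions = "aerobic",
             condition_rate_factors = c(aerobic = 1),
             temperatures = c(0, 10),
             sampling_times = list(`0` = seq(0, 96, 24),
                                   `10` = seq(0, 96, 24)),
             replicates_range = c(2L, 3L),
             ftir_downsample = 60L,
             seed = seed, ...)
}

# Two-batch, two-condition study for partition/batch-validation tests.
two_condition_config <- function(seed = 1L, ...) {
  sim_config(conditions = c("aerobic", "vacuum"),
             condition_rate_factors = c(aerobic = 1, vacuum = 0.55),
             temperatures = c(0, 10),
             sampling_times = list(`0` = seq(0, 96, 48),
                                   `10` = seq(0, 96, 48)),
             replicates_range = c(2L, 3L),
             ftir_downsample = 60L,
             seed = seed, ...)
}

# Reduced-scale study for fusion-recovery experiments: the packaged
# experiment config/roster under their test-local names.
fusion_sim_config <- function(seed = 1L) fusion_recovery_config(seed)
reduced_model_specs <- function(oof_folds = 10L) fusion_recovery_specs(oof_folds)

# A config whose spectra are an exact affine function of TVC (no noise, no
# artifacts, no unique/shared components).
noiseless_config <- function(seed = 1L) {
  tiny_sim_config(
    seed = seed, tvc_noise_sd = 0, batch_gain_shift = 0,
    signal = signal_params(
      unique_sd = c(ftir = 0, msi = 0, msif = 0),
      shared_weight = c(ftir = 0, msi = 0, msif = 0),
      gain_sd = 0, offset_sd = 0,
      noise_sd = c(ftir = 0, msi = 0, msif = 0)
    )
  )
}

# Seeded random regression problem (tall, full rank).
random_problem <- function(n = 30L, p = 5L, seed = 1L, noise = 0.1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    beta <- rnorm(p)
    list(X = X, y = as.numeric(X %*% beta + rnorm(n, sd = noise)))
  })
}

# Brute-force two-sided exact Wilcoxon signed-rank p-value: enumerates every
# sign assignment of the |difference| ranks. Independent of the package's
# convolution-based implementation.
brute_force_wilcoxon_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_plus_all <- as.numeric(signs %*% r)
  obs <- sum(r[d > 0])
  min(1, 2 * min(mean(w_plus_all <= obs), mean(w_plus_all >= obs)))
}
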