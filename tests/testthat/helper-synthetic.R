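# Small fixture builders used across test files.

# A 13-block movie-layout schedule and matching smooth features.
movie_fixture <- function(seed = 1, smoothness = 2) {
  schedule <- generate_block_schedule(13, 30, seed = seed)
  features <- generate_feature_timecourses(schedule, fs_feat = 2,
                                           smoothness = smoothness,
                                           seed = seed)
  list(schedule = schedule, features = features)
}

# Forward-model dataset with known truth at a chosen noise level.
encoding_fixture <- function(seed = 1, noise_sd = 1, weight_sd = 0.15) {
  fx <- movie_fixture(seed)
  truth <- generate_ground_truth(weight_sd = weight_sd, noise_sd = noise_sd,
                                 seed = seed + 100)
  y <- synthesize_binned_hfb(fx$features, truth, seed = seed + 200)
  X <- build_lagged_design(fx$features)
  list(schedule = fx$schedule, features = fx$features, truth = truth,
       X = X, y = unlist(y, use.names = FALSE))
}

# A sample with exact mean/sd so its one-sample t statistic is `t_target`.
sample_with_t <- function(t_target, n, seed = 1) {
  z <- withr::with_seed(seed, rnorm(n))
  z <- (z - mean(z)) / sd(z)          # mean 0, sd exactly 1
  z + t_target / sqrt(n)
}

# Direct-formula t oracles, independent of stats::t.test.
oracle_one_sample_t <- function(x) {
  t <- mean(x) / (sd(x) / sqrt(length(x)))
  list(t = t, df = length(x) - 1,
       p = 2 * pt(-abs(t), length(x) - 1))
}
oracle_unpaired_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}
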