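test_that("movie layout yields 13 alternating blocks, 7 music + 6 speech, one flagged", {
  s <- generate_block_schedule(13, 30, seed = 1)
  expect_equal(nrow(s), 13)
  expect_equal(sum(s$trial_type == "music"), 7)
  expect_equal(sum(s$trial_type == "speech"), 6)
  expect_true(all(diff(s$onset) == 30))
  expect_true(all(s$trial_type[-1] != s$trial_type[-13]))
  flagged <- s[!s$features_present, ]
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$trial_type, "music")
  # the flagged block is the fifth music block in sequence
  expect_equal(which(s$block_index[s$trial_type == "music"] ==
                       flagged$block_index), 5)
})

test_that("short schedules alternate without flags and reject bad durations", {
  s <- generate_block_schedule(2, 30, seed = 0)
  expect_equal(nrow(s), 2)
  expect_true(all(s$features_present))
  expect_false(s$trial_type[1] == s$trial_type[2])
  expect_error(generate_block_schedule(5, -1), "duration")
  expect_identical(generate_block_schedule(13, 30, seed = 1),
                   generate_block_schedule(13, 30, seed = 1))
})

test_that("feature timecourses are bounded, correctly shaped, and reproducible", {
  fx <- movie_fixture(seed = 7)
  expect_length(fx$features, 12)
  for (m in fx$features) {
    expect_equal(dim(m), c(60, 48))
    expect_true(all(m >= 0 & m <= 1))
  }
  expect_identical(fx$features,
                   generate_feature_timecourses(fx$schedule, seed = 7))
  # flagged block contributes no features
  expect_false("9" %in% names(fx$features))
})

test_that("smoothness controls temporal autocorrelation; white-noise limit stays bounded", {
  s <- generate_block_schedule(13, 30, seed = 1)
  lag1 <- function(feats) {
    mean(vapply(feats, function(m)
      mean(apply(m, 2, function(x) cor(x[-1], x[-length(x)]))), numeric(1)))
  }
  smooth2 <- generate_feature_timecourses(s, smoothness = 2, seed = 11)
  rough <- generate_feature_timecourses(s, smoothness = 0.1, seed = 11)
  expect_gt(lag1(smooth2), lag1(rough))
  white <- generate_feature_timecourses(s, smoothness = 0, seed = 11)
  expect_true(all(vapply(white, function(m) all(m >= 0 & m <= 1), logical(1))))
})

test_that("forward model matches identity, null, and a loop-based oracle", {
  feats <- list("1" = matrix(runif(20 * 48), 20, 48,
                             dimnames = list(NULL, emotion_feature_set()$names)))
  # single feature, weight 1 at lag 0
  w <- matrix(0, 48, 1, dimnames = list(emotion_feature_set()$names, NULL))
  w[5, 1] <- 1
  tr <- list(weights = w, noise_sd = 0)
  y <- synthesize_binned_hfb(feats, tr, lags = 0)
  expect_equal(y[["1"]], unname(feats[["1"]][, 5]))
  # zero weights
  tr0 <- list(weights = matrix(0, 48, 3), noise_sd = 0)
  expect_equal(synthesize_binned_hfb(feats, tr0)[["1"]], rep(0, 20))
  # loop oracle over features and lags
  set.seed(42)
  W <- matrix(rnorm(48 * 3), 48, 3)
  tr <- list(weights = W, noise_sd = 0)
  lags <- c(0, 0.5, 1)
  got <- synthesize_binned_hfb(feats, tr, lags = lags)[["1"]]
  x <- feats[["1"]]
  expected <- numeric(20)
  for (t in 1:20)
    for (f in 1:48)
      for (l in 1:3) {
        s <- t - lags[l] * 2
        if (s >= 1) expected[t] <- expected[t] + W[f, l] * x[s, f]
      }
  expect_lt(max(abs(got - expected)), 1e-10)
  # linearity in the weights at zero noise
  tr2 <- list(weights = 3 * W, noise_sd = 0)
  expect_equal(synthesize_binned_hfb(feats, tr2)[["1"]], 3 * got)
  expect_error(synthesize_binned_hfb(feats, tr, lags = c(0, 0.5)), "lags")
})

test_that("lag-coherent truth has shared signs, bounded profiles, sparse scales", {
  tr <- generate_ground_truth(weight_sd = 0.2, noise_sd = 0, seed = 9,
                              lag_coherent = TRUE)
  W <- tr$weights
  expect_equal(dim(W), c(48, 3))
  # one sign per feature across all lags, never zero
  sgn <- sign(W)
  expect_true(all(sgn[, 1] == sgn[, 2] & sgn[, 1] == sgn[, 3]))
  expect_true(all(W != 0))
  # complex rows forced non-negative as in the default mode
  expect_true(all(W[emotion_feature_set()$complex_set, ] >= 0))
  # lag profile bounded: within a feature, |w| varies at most 2x (U(0.5, 1))
  ratio <- apply(abs(W), 1, function(v) max(v) / min(v))
  expect_true(all(ratio <= 2 + 1e-12))
  # effect sizes heterogeneous across features (exponential, not constant)
  expect_gt(max(abs(W)) / min(abs(W)), 5)
  expect_identical(W, generate_ground_truth(weight_sd = 0.2, seed = 9,
                                            lag_coherent = TRUE)$weights)
})

test_that("default cohort mirrors the study layout with known truths", {
  spec <- default_cohort_spec(seed = 2)
  pp <- spec$participants
  expect_equal(nrow(pp), 42)
  expect_equal(sum(pp$group == "childhood"), 11)
  expect_equal(sum(pp$group == "childhood" & pp$dlpfc), 8)
  expect_equal(sum(pp$group == "childhood" & pp$pstc), 4)
  expect_equal(sum(pp$group == "post_childhood" & pp$dlpfc), 13)
  expect_equal(sum(pp$group == "post_childhood" & pp$pstc), 25)
  expect_true(all(pp$age[pp$group == "childhood"] >= 5 &
                    pp$age[pp$group == "childhood"] <= 10))
  expect_error(cohort_spec(pp[0, ]), "non-empty")
  expect_error(default_cohort_spec(n_contacts = 3), "four contacts")
})

test_that("cohort generation builds age-graded complex weights and a childhood-DLPFC null", {
  spec <- default_cohort_spec(complex_age_slope = 0.05, seed = 3)
  coh <- generate_cohort(spec, seed = 3)
  expect_equal(nrow(coh$metadata), 42)
  fset <- emotion_feature_set()
  # childhood DLPFC truths are exactly zero
  ch_dlpfc <- coh$metadata$id[coh$metadata$group == "childhood" &
                                coh$metadata$n_contacts_dlpfc > 0]
  for (pid in ch_dlpfc)
    expect_true(all(coh$truth[[pid]][["DLPFC"]] == 0))
  # complex true-weight mean strictly increases with age in pSTC
  pstc <- coh$metadata$id[coh$metadata$n_contacts_pstc > 0]
  cxm <- vapply(pstc, function(pid)
    mean(coh$truth[[pid]][["pSTC"]][fset$complex_set, ]), numeric(1))
  ages <- coh$metadata$age[match(pstc, coh$metadata$id)]
  o <- order(ages)
  expect_true(all(diff(cxm[o]) >= 0))
  expect_gt(cor(ages, cxm), 0.99)
  # seeded determinism
  coh2 <- generate_cohort(spec, seed = 3)
  expect_identical(coh$data, coh2$data)
})

test_that("raw-signal synthesis enforces the Nyquist limit", {
  s <- generate_block_schedule(2, 30, seed = 1, movie_layout = FALSE)
  targets <- list(rep(0, 60), rep(0, 60))
  expect_error(synthesize_raw_signal(targets, s, fs_raw = 200), "Nyquist")
})
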