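test_that("t statistics match direct-formula oracles", {
  set.seed(40)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1))
    got <- one_sample_t(x)
    want <- oracle_one_sample_t(x)
    expect_lt(abs(got$t - want$t), 1e-10)
    expect_lt(abs(got$p - want$p), 1e-10)
    expect_equal(got$df, want$df)
    a <- rnorm(sample(5:20, 1)); b <- rnorm(sample(5:20, 1), mean = 0.5)
    gu <- unpaired_t(a, b); wu <- oracle_unpaired_t(a, b)
    expect_lt(abs(gu$t - wu$t), 1e-10)
    expect_lt(abs(gu$p - wu$p), 1e-10)
    n <- sample(5:20, 1)
    x2 <- rnorm(n); y2 <- rnorm(n)
    gp <- paired_t(x2, y2); wp <- oracle_one_sample_t(x2 - y2)
    expect_lt(abs(gp$t - wp$t), 1e-10)
    expect_lt(abs(gp$p - wp$p), 1e-10)
  }
})

test_that("degenerate inputs raise clear errors", {
  expect_error(one_sample_t(rep(0, 5)), "zero variance")
  expect_error(one_sample_t(1), "two values")
  expect_error(paired_t(1:5, 1:5), "zero variance")
  expect_error(paired_t(1:4, 1:5), "length")
  expect_error(unpaired_t(c(1, 1), c(2, 2)), "pooled variance")
  x <- c(1, 1, 2, 2)
  expect_equal(unpaired_t(x, x)$t, 0)
  expect_equal(unpaired_t(x, x)$p, 1)
})

test_that("one-sample t maintains its nominal type-I error rate", {
  set.seed(41)
  rej <- mean(vapply(1:10000, function(i)
    one_sample_t(rnorm(8))$p < 0.05, logical(1)))
  expect_gt(rej, 0.04)
  expect_lt(rej, 0.06)
})

test_that("unpaired t is calibrated under the null and powered under a shift", {
  set.seed(42)
  rej0 <- mean(vapply(1:10000, function(i)
    unpaired_t(rnorm(8), rnorm(13))$p < 0.05, logical(1)))
  expect_gt(rej0, 0.04)
  expect_lt(rej0, 0.06)
  pw <- mean(vapply(1:1000, function(i)
    unpaired_t(rnorm(8), rnorm(13, mean = 1.5))$p < 0.05, logical(1)))
  expect_gt(pw, 0.8)
})

test_that("paired t detects a one-sd paired shift", {
  set.seed(43)
  pw <- mean(vapply(1:1000, function(i) {
    x <- rnorm(25); paired_t(x + 1 + rnorm(25) * 0, x + rnorm(25))$p < 0.05
  }, logical(1)))
  expect_gt(pw, 0.9)
})

test_that("voice effect differences and contrast direction follow construction", {
  r <- runif(10)
  ve <- voice_effect(r, r)
  expect_equal(ve$difference, rep(0, 10))
  g <- rep(c("childhood", "post_childhood"), each = 5)
  rs <- c(rnorm(5, -0.2, 0.01), rnorm(5, 0.3, 0.01))
  rm_ <- rep(0, 10)
  ve2 <- voice_effect(rs, rm_, group = g)
  expect_lt(ve2$group_means[["childhood"]], 0)
  expect_gt(ve2$group_means[["post_childhood"]], 0)
  expect_lt(ve2$contrast$t, 0)
  expect_lt(ve2$contrast$p, 0.05)
})

test_that("shuffling preserves each feature's marginal distribution exactly", {
  fx <- movie_fixture(seed = 44)
  set.seed(44)
  sh <- ieegencode:::shuffle_features(fx$features)
  stacked0 <- do.call(rbind, fx$features)
  stacked1 <- do.call(rbind, sh)
  for (j in c(1, 17, 48))
    expect_equal(sort(stacked1[, j]), sort(stacked0[, j]))
  # joint shuffle: rows move as units
  key0 <- apply(stacked0, 1, function(r) paste(round(r[1:3], 12), collapse = "|"))
  key1 <- apply(stacked1, 1, function(r) paste(round(r[1:3], 12), collapse = "|"))
  expect_setequal(key1, key0)
  # condition-wise shuffle never moves bins across conditions
  cond <- fx$schedule$trial_type[match(as.integer(names(fx$features)),
                                       fx$schedule$block_index)]
  sh2 <- ieegencode:::shuffle_features(fx$features, condition_of_block = cond)
  stacked2 <- do.call(rbind, sh2)
  rows_sp <- rep(cond, each = 60) == "speech"
  expect_setequal(stacked2[rows_sp, 5], stacked0[rows_sp, 5])
})

test_that("permutation p-values respect the +1 floor and a strong signal is detected", {
  fx <- encoding_fixture(seed = 45, noise_sd = 0.2)
  binned <- matrix(fx$y, ncol = 1)
  pr <- permutation_test(fx$features, binned, lambda = 100, n_perm = 19,
                         seed = 45)
  expect_equal(pr$p_two_tailed, 1 / 20)
  expect_length(pr$null_r, 19)
  expect_gt(pr$observed_r, max(abs(pr$null_r)))
  expect_true(pr$p_two_tailed > 0 && pr$p_two_tailed <= 1)
  expect_error(permutation_test(fx$features, binned, 100, n_perm = 0),
               "n_perm")
})

test_that("circular-shift permutation mode also preserves marginals", {
  fx <- movie_fixture(seed = 46)
  set.seed(46)
  sh <- ieegencode:::shuffle_features(fx$features, unit = "circular")
  for (b in names(fx$features))
    expect_equal(sort(sh[[b]][, 1]), sort(fx$features[[b]][, 1]))
})

test_that("group-level permutation averages accuracies across participants", {
  fx <- movie_fixture(seed = 47)
  X <- build_lagged_design(fx$features)
  tru <- generate_ground_truth(weight_sd = 0.3, noise_sd = 1, seed = 47)
  mkd <- function(s) {
    y <- unlist(synthesize_binned_hfb(fx$features, tru, seed = s),
                use.names = FALSE)
    list(features = fx$features, binned = matrix(y, ncol = 1))
  }
  ds <- lapply(1:3, mkd)
  pr <- group_permutation_test(ds, lambda = 100, n_perm = 19, seed = 47)
  obs <- mean(vapply(ds, function(d)
    cv_evaluate(X, as.numeric(d$binned), 100, keep_weights = FALSE)$mean_r,
    numeric(1)))
  expect_equal(pr$observed_r, obs, tolerance = 1e-12)
  expect_lt(pr$p_two_tailed, 0.1)
})
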