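test_that("the penalty grid spans 10 to 10000 with 20 log-spaced values", {
  g <- ridge_lambda_grid()
  expect_length(g, 20)
  expect_equal(g[1], 10)
  expect_equal(g[20], 10000)
  expect_true(all(diff(log(g)) > 0))
  expect_equal(diff(range(diff(log10(g)))), 0)
})

test_that("ridge matches the normal-equations oracle and its limits", {
  set.seed(20)
  for (i in 1:5) {
    X <- matrix(rnorm(1000), 100, 10)
    y <- rnorm(100)
    lam <- sample(ridge_lambda_grid(), 1)
    w <- ridge_fit(X, y, lam, center = FALSE)$weights
    want <- solve(crossprod(X) + lam * diag(10), crossprod(X, y))
    expect_lt(max(abs(w - want)), 1e-8)
  }
  # shrinkage limit
  X <- matrix(rnorm(500), 50, 10); y <- rnorm(50)
  expect_lt(sqrt(sum(ridge_fit(X, y, 1e12)$weights^2)), 1e-6)
  # orthonormal design, lambda ~ 0: w = X'y
  Q <- qr.Q(qr(matrix(rnorm(500), 50, 10)))
  yq <- rnorm(50)
  expect_lt(max(abs(ridge_fit(Q, yq, 1e-10, center = FALSE)$weights -
                      crossprod(Q, yq))), 1e-6)
  expect_error(ridge_fit(X, c(y[-1], NA), 1), "finite")
})

test_that("ridge agrees with an iterative penalized least-squares solver", {
  set.seed(21)
  X <- matrix(rnorm(150), 30, 5)
  y <- rnorm(30)
  lam <- 5
  w0 <- ridge_fit(X, y, lam, center = FALSE)$weights
  obj <- function(w) sum((y - X %*% w)^2) + lam * sum(w^2)
  grad <- function(w) as.numeric(-2 * crossprod(X, y - X %*% w) + 2 * lam * w)
  opt <- optim(rep(0, 5), obj, grad, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  expect_lt(max(abs(w0 - opt$par)), 1e-6)
})

test_that("shrinkage is monotone in the penalty", {
  set.seed(22)
  X <- matrix(rnorm(2000), 200, 10)
  y <- rnorm(200)
  norms <- vapply(ridge_lambda_grid(),
                  function(l) sqrt(sum(ridge_fit(X, y, l)$weights^2)),
                  numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("cross-validation recovers a noiseless model nearly perfectly", {
  fx <- encoding_fixture(seed = 30, noise_sd = 0)
  res <- cv_evaluate(fx$X, fx$y, lambda = 1e-6)
  expect_gt(res$mean_r, 0.999)
  expect_equal(res$mean_r, mean(res$fold_r))
  expect_true(all(abs(res$fold_r) <= 1))
  expect_equal(dim(res$fold_weights), c(5, 144))
})

test_that("cross-validated r is near zero for pure noise", {
  fx <- movie_fixture(seed = 31)
  X <- build_lagged_design(fx$features)
  set.seed(31)
  rs <- vapply(1:100, function(i)
    cv_evaluate(X, rnorm(720), lambda = 100, keep_weights = FALSE)$mean_r,
    numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
  expect_true(all(abs(rs) < 0.35))
})

test_that("accuracy magnitude matches the population signal-to-noise level", {
  # population R^2 = 0.04 should give mean r around 0.2
  set.seed(32)
  rs <- vapply(1:10, function(i) {
    fx <- movie_fixture(seed = 320 + i)
    X <- build_lagged_design(fx$features)
    tru <- generate_ground_truth(weight_sd = 0.15, noise_sd = 0, seed = i)
    sig <- unlist(synthesize_binned_hfb(fx$features, tru), use.names = FALSE)
    noise_sd <- sqrt(var(sig) * (1 - 0.04) / 0.04)
    y <- sig + rnorm(720, sd = noise_sd)
    max(cv_grid(X, y, ridge_lambda_grid()))  # accuracy at the selected penalty
  }, numeric(1))
  expect_gt(mean(rs), 0.1)
  expect_lt(mean(rs), 0.3)
})

test_that("fold accuracies are invariant to affine rescaling of the response", {
  fx <- encoding_fixture(seed = 33)
  r1 <- cv_evaluate(fx$X, fx$y, lambda = 100, keep_weights = FALSE)
  r2 <- cv_evaluate(fx$X, 3.7 * fx$y + 2, lambda = 100, keep_weights = FALSE)
  expect_equal(r1$fold_r, r2$fold_r, tolerance = 1e-10)
})

test_that("fold assignment needs enough blocks and round-robins them", {
  fx <- movie_fixture(seed = 34)
  X <- build_lagged_design(fx$features[1:4])
  expect_error(cv_evaluate(X, rnorm(240), lambda = 10), "at least 5 blocks")
})

test_that("global penalty selection maximizes the across-dataset mean accuracy", {
  set.seed(35)
  grid <- ridge_lambda_grid(8, c(10, 10000))
  mk <- function(seed, noise) {
    fx <- movie_fixture(seed = seed)
    X <- build_lagged_design(fx$features)
    tru <- generate_ground_truth(weight_sd = 0.15, noise_sd = noise,
                                 seed = seed)
    y <- unlist(synthesize_binned_hfb(fx$features, tru, seed = seed + 1),
                use.names = FALSE)
    list(X = X, y = y, block_of_row = attr(X, "block_of_row"))
  }
  d1 <- mk(1, 0.5); d2 <- mk(2, 3)
  sel <- select_global_lambda(list(d1, d2), grid)
  # exhaustive oracle: mean of the two datasets' cv curves
  acc <- vapply(grid, function(l) mean(c(
    cv_evaluate(d1$X, d1$y, l, keep_weights = FALSE)$mean_r,
    cv_evaluate(d2$X, d2$y, l, keep_weights = FALSE)$mean_r)), numeric(1))
  expect_equal(sel$lambda, grid[which.max(acc)])
  expect_equal(sel$mean_r_by_lambda, acc, tolerance = 1e-8)
  # single dataset: the dataset's own best value
  sel1 <- select_global_lambda(list(d1), grid)
  acc1 <- vapply(grid, function(l)
    cv_evaluate(d1$X, d1$y, l, keep_weights = FALSE)$mean_r, numeric(1))
  expect_equal(sel1$lambda, grid[which.max(acc1)])
  # pure-noise datasets still return a grid member
  dn <- d1; dn$y <- rnorm(length(d1$y))
  expect_true(select_global_lambda(list(dn), grid)$lambda %in% grid)
  expect_error(select_global_lambda(list(), grid), "at least one")
})

test_that("zero-variance held-out data scores r = 0 with a warning", {
  fx <- movie_fixture(seed = 36)
  X <- build_lagged_design(fx$features)
  y <- rnorm(720)
  blocks <- attr(X, "block_of_row")
  # fold 1 holds blocks 1, 6 and 11 under the round-robin; make them constant
  y[blocks %in% unique(blocks)[c(1, 6, 11)]] <- 1
  expect_warning(res <- cv_evaluate(X, y, lambda = 10, keep_weights = FALSE),
                 "zero-variance")
  expect_equal(res$fold_r[1], 0)
})
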