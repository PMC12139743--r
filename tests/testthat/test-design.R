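fset <- emotion_feature_set()

test_that("max over faces takes per-frame maxima and zeroes faceless frames", {
  base <- as.data.frame(matrix(0, 3, 48, dimnames = list(NULL, fset$names)))
  tab <- cbind(data.frame(time_s = c(0, 0, 0.04), face_id = c(1, 2, NA)), base)
  tab$joy[1:2] <- c(0.2, 0.7)
  out <- max_over_faces(tab)
  expect_equal(unname(out$features[1, "joy"]), 0.7)
  expect_equal(unname(out$features[2, ]), rep(0, 48))
  one <- cbind(data.frame(time_s = 0, face_id = 1), base[1, ])
  one[1, fset$names] <- runif(48)
  expect_equal(max_over_faces(one)$features[1, ],
               unlist(one[1, fset$names]))
  bad <- tab; bad$joy[1] <- 1.5
  expect_error(max_over_faces(bad), "0, 1")
})

test_that("max over faces equals a brute-force per-frame loop", {
  set.seed(10)
  rows <- do.call(rbind, lapply(1:100, function(fr) {
    nf <- sample(0:3, 1)
    if (nf == 0)
      return(cbind(data.frame(time_s = fr / 25, face_id = NA),
                   as.data.frame(matrix(0, 1, 48,
                                        dimnames = list(NULL, fset$names)))))
    cbind(data.frame(time_s = fr / 25, face_id = seq_len(nf)),
          as.data.frame(matrix(runif(nf * 48), nf, 48,
                               dimnames = list(NULL, fset$names))))
  }))
  out <- max_over_faces(rows)
  for (i in seq_along(out$times)) {
    sub <- rows[rows$time_s == out$times[i] & !is.na(rows$face_id), fset$names]
    want <- if (nrow(sub) == 0) rep(0, 48) else apply(as.matrix(sub), 2, max)
    expect_equal(unname(out$features[i, ]), unname(want))
  }
})

test_that("2 Hz resampling bin-averages frames on the half-open grid", {
  times <- seq(0, 30 - 1 / 25, by = 1 / 25)
  const <- matrix(0.5, length(times), 2, dimnames = list(NULL, c("a", "b")))
  out <- resample_to_2hz(const, times, 0, 30)
  expect_equal(nrow(out), 60)
  expect_true(all(abs(out - 0.5) < 1e-12))
  # linear ramp: bin means match analytic midpoints
  ramp <- matrix(times / 30, ncol = 1, dimnames = list(NULL, "a"))
  out2 <- resample_to_2hz(ramp, times, 0, 30)
  mid <- (seq(0, 59) * 0.5 + 0.25) / 30
  expect_lt(max(abs(out2[, 1] - mid)), 0.02)
  expect_error(resample_to_2hz(ramp, numeric(0), 0, 30), "no frames")
})

test_that("lagged design has shift semantics with within-block zero padding", {
  fx <- movie_fixture(seed = 2)
  X0 <- build_lagged_design(fx$features, lags = 0)
  expect_equal(unname(X0), unname(do.call(rbind, fx$features)),
               ignore_attr = TRUE)
  X <- build_lagged_design(fx$features)
  expect_equal(dim(X), c(720, 144))
  # impulse feature: ones appear at rows k, k+1, k+2 across the lag columns
  imp <- matrix(0, 60, 48, dimnames = list(NULL, fset$names))
  imp[10, 3] <- 1
  Xi <- build_lagged_design(list("1" = imp))
  expect_equal(which(Xi[, 3] == 1), 10)
  expect_equal(which(Xi[, 48 + 3] == 1), 11)
  expect_equal(which(Xi[, 96 + 3] == 1), 12)
  # a lag 1 shift never leaks into the next block
  Xi2 <- build_lagged_design(list("1" = imp, "2" = imp * 0))
  expect_true(all(Xi2[61:120, ] == 0))
  expect_error(build_lagged_design(fx$features, lags = c(0, 0.3)), "grid")
})

test_that("response binning averages 200-sample windows at 400 Hz", {
  expect_equal(bin_response(rep(1, 12000), fs = 400), rep(1, 60))
  expect_equal(bin_response(rep(c(1, -1), 6000), fs = 400), rep(0, 60))
  set.seed(11)
  x <- rnorm(12000)
  got <- bin_response(x, fs = 400)
  want <- vapply(1:60, function(b) mean(x[((b - 1) * 200 + 1):(b * 200)]),
                 numeric(1))
  expect_lt(max(abs(got - want)), 1e-12)
  expect_error(bin_response(rnorm(123), fs = 400), "whole number")
})

test_that("contact concatenation replicates the design per contact", {
  fx <- movie_fixture(seed = 3)
  X <- build_lagged_design(fx$features)
  y1 <- matrix(rnorm(720), ncol = 1)
  cc1 <- concatenate_contacts(y1, X)
  expect_equal(cc1$X, X, ignore_attr = TRUE)
  expect_equal(cc1$y, as.numeric(y1))
  y4 <- matrix(rnorm(720 * 4), ncol = 4)
  cc4 <- concatenate_contacts(y4, X)
  expect_equal(length(cc4$y), 2880)
  expect_equal(dim(cc4$X), c(2880, 144))
  expect_equal(cc4$block_of_row, rep(attr(X, "block_of_row"), 4))
  expect_error(concatenate_contacts(y4[1:10, ], X), "match")
})

test_that("duplicated contacts with matched penalty scaling reproduce the single-contact fit", {
  fx <- movie_fixture(seed = 4)
  X <- build_lagged_design(fx$features)
  y <- rnorm(720)
  w1 <- ridge_fit(X, y, lambda = 100)$weights
  cc <- concatenate_contacts(cbind(y, y, y), X)
  w3 <- ridge_fit(cc$X, cc$y, lambda = 300)$weights
  expect_lt(max(abs(w1 - w3)), 1e-8)
})

test_that("condition split partitions design rows exactly", {
  fx <- movie_fixture(seed = 5)
  X <- build_lagged_design(fx$features)
  block <- attr(X, "block_of_row")
  cond <- fx$schedule$trial_type[match(as.integer(block),
                                       fx$schedule$block_index)]
  expect_equal(sum(cond == "speech") + sum(cond == "music"), nrow(X))
  expect_equal(sum(cond == "speech"), 360)  # 6 speech blocks x 60 bins
  expect_equal(sum(cond == "music"), 360)   # 6 feature-present music blocks
})
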