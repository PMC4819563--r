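test_that("log-linear init is exact on noiseless curves", {
  cv <- echoSeries(TE10, predictMono(100, 50, TE10))
  init <- linearInit(cv)
  expect_equal(init$s0, 100, tolerance = 1e-9)
  expect_equal(init$t2, 50, tolerance = 1e-9)
  # two points determine the line exactly
  init2 <- linearInit(echoSeries(c(10, 20), c(exp(-1), exp(-2))))
  expect_equal(init2$s0, 1, tolerance = 1e-12)
  expect_equal(init2$t2, 10, tolerance = 1e-12)
})

test_that("log-linear init matches closed-form OLS on noisy data", {
  cv <- noisyMonoCurve(100, 70, sigma = 2, seed = 11)
  init <- linearInit(cv)
  y <- log(signals(cv))
  x <- echoTimes(cv)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  expect_equal(init$t2, -1 / b, tolerance = 1e-10)
  expect_equal(init$s0, exp(a), tolerance = 1e-10)
})

test_that("non-positive and non-decaying curves take the declared fallbacks", {
  # one non-positive echo is dropped from the init only
  s <- predictMono(100, 50, TE10)
  s[10] <- -3
  init <- linearInit(echoSeries(TE10, s))
  expect_equal(init$t2, 50, tolerance = 1e-9)
  # fewer than two positive echoes: (max signal, 70 ms)
  init2 <- linearInit(echoSeries(c(10, 20, 30), c(5, -1, -2)))
  expect_equal(init2$s0, 5)
  expect_equal(init2$t2, 70)
  # rising (non-decaying) signal: flat-decay initialisation at 2000 ms
  init3 <- linearInit(echoSeries(c(10, 20, 30), c(10, 11, 12)))
  expect_equal(init3$t2, 2000)
})

test_that("Gauss-Newton recovers noiseless parameters to 1e-6 relative", {
  for (p in list(c(200, 80), c(100, 50), c(1500, 20), c(30, 120))) {
    fit <- gaussNewtonFit(echoSeries(TE10, predictMono(p[1], p[2], TE10)))
    expect_lt(abs(s0(fit) - p[1]) / p[1], 1e-6)
    expect_lt(abs(t2(fit) - p[2]) / p[2], 1e-6)
    expect_true(converged(fit))
    expect_lte(nIterations(fit), 2L)
  }
})

test_that("Gauss-Newton matches the grid-search SSE minimiser", {
  set.seed(21)
  for (i in 1:10) {
    cv <- noisyMonoCurve(100, 70, sigma = 3, seed = 100 + i)
    fit <- gaussNewtonFit(cv)
    oracle <- oracleMonoFit(cv)
    expect_lt(abs(t2(fit) - oracle$t2), 0.01)
  }
})

test_that("Gauss-Newton never ends above its own starting residual", {
  # noise strong enough that log-space and original-space optima differ
  cv <- noisyMonoCurve(100, 70, sigma = 12, seed = 77)
  init <- linearInit(cv)
  sseInit <- sum((signals(cv) -
    predictMono(init$s0, init$t2, echoTimes(cv)))^2)
  fit <- gaussNewtonFit(cv)
  expect_lte(residualNorm(fit), sseInit + 1e-12)
  expect_lte(nIterations(fit), 500L)
})

test_that("refitting from a converged solution is idempotent", {
  cv <- noisyMonoCurve(120, 65, sigma = 4, seed = 5)
  fit <- gaussNewtonFit(cv)
  refit <- gaussNewtonFit(cv, init = list(s0 = s0(fit), t2 = t2(fit)))
  expect_equal(t2(refit), t2(fit), tolerance = 1e-4)
  expect_equal(s0(refit), s0(fit), tolerance = 1e-4)
})

test_that("a mono fit of a myelinated mixture lands between the basis extremes", {
  b <- compartmentBasis()
  s <- predictMulti(1000, c(0.25, 0.72, 0.03), b, TE10)
  fit <- gaussNewtonFit(echoSeries(TE10, s))
  expect_gt(t2(fit), 20)
  expect_lt(t2(fit), 2000)
})

test_that("volume fitting agrees with per-curve fits and honours the mask", {
  te <- TE10
  grid <- c(4L, 4L, 2L)
  set.seed(9)
  nv <- prod(grid)
  S <- t(vapply(seq_len(nv), function(i) {
    predictMono(100, 60 + 2 * (i %% 5), te) + rnorm(length(te), 0, 1)
  }, numeric(length(te))))
  img <- array(S, c(grid, length(te)))
  res <- fitMonoVolume(img, te)
  scale <- res$scale
  for (i in c(1L, 7L, 20L)) {
    fit <- gaussNewtonFit(echoSeries(te, S[i, ]), scale = scale)
    expect_equal(res$t2[[i]], t2(fit), tolerance = 1e-8)
    expect_equal(res$s0[[i]], s0(fit), tolerance = 1e-8)
  }
  # masked-out voxels carry NA, exactly as many as were masked out
  mask <- array(TRUE, grid)
  mask[1:10] <- FALSE
  res2 <- fitMonoVolume(img, te, mask)
  expect_identical(sum(is.na(res2$t2)), 10L)
  expect_true(all(!is.na(res2$t2[11:nv])))
})

test_that("volume fitting is exact on a constant noiseless volume", {
  img <- array(rep(predictMono(100, 70, TE10), each = 8), c(2, 2, 2, 10))
  res <- fitMonoVolume(img, TE10)
  expect_equal(as.numeric(res$t2), rep(70, 8), tolerance = 1e-6)
  expect_true(all(res$converged))
})

test_that("volume fitting validates the echo dimension and empty masks", {
  img <- array(1, c(2, 2, 2, 9))
  expect_error(fitMonoVolume(img, TE10), "echo times")
  img10 <- array(1, c(2, 2, 2, 10))
  expect_warning(
    res <- fitMonoVolume(img10, TE10, mask = array(FALSE, c(2, 2, 2))),
    "empty mask"
  )
  expect_true(all(is.na(res$t2)))
})
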