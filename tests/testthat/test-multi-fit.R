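test_that("NNLS recovers noiseless basis-generated fractions", {
  b <- compartmentBasis()
  truth <- c(0.25, 0.70, 0.05)
  s <- predictMulti(1000, truth, b, TE10)
  fit <- nnlsFractions(echoSeries(TE10, s))
  expect_equal(unname(fractions(fit)), truth, tolerance = 1e-6)
  expect_equal(s0(fit), 1000, tolerance = 1e-3)
  expect_equal(mwf(fit), 0.25, tolerance = 1e-6)
  # against the dense simplex-grid least-squares oracle
  oracle <- simplexOracle(s)
  expect_lt(max(abs(unname(fractions(fit)) - oracle$fractions)), 0.001)
})

test_that("pure tissue decay yields a one-hot fraction vector", {
  fit <- nnlsFractions(echoSeries(TE10, predictMono(500, 80, TE10)))
  expect_equal(unname(fractions(fit)), c(0, 1, 0), tolerance = 1e-9)
  expect_equal(mwf(fit), 0, tolerance = 1e-9)
})

test_that("an all-zero curve is flagged degenerate", {
  fit <- nnlsFractions(echoSeries(TE10, rep(0, 10)))
  expect_true(fit@degenerate)
  expect_true(all(is.na(fit@fractions)))
  expect_true(is.na(mwf(fit)))
})

test_that("fractions always satisfy the simplex constraints", {
  set.seed(31)
  b <- compartmentBasis()
  for (i in 1:50) {
    v <- c(runif(1, 0, 0.5), runif(1, 0, 0.5), 0)
    v[3] <- 1 - v[1] - v[2]
    s <- predictMulti(800, v, b, TE10) + rnorm(10, 0, 8)
    fit <- nnlsFractions(echoSeries(TE10, s))
    if (!fit@degenerate) {
      expect_true(all(fractions(fit) >= 0))
      expect_equal(sum(fractions(fit)), 1, tolerance = 1e-9)
    }
  }
})

test_that("the three-compartment fit never lags the mono fit on basis curves", {
  b <- compartmentBasis()
  for (v in list(c(0.3, 0.65, 0.05), c(0, 1, 0), c(0.1, 0.8, 0.1))) {
    cv <- echoSeries(TE10, predictMulti(1000, v, b, TE10))
    expect_lte(residualNorm(nnlsFractions(cv)),
      residualNorm(gaussNewtonFit(cv)) + 1e-9)
  }
})

test_that("MWF recovery at SNR 200 has small median error", {
  set.seed(41)
  b <- compartmentBasis()
  errs <- replicate(1000, {
    v <- rgamma(3, c(2, 6, 0.5))
    v <- v / sum(v)
    s0v <- 1000
    sig <- predictMulti(s0v, v, b, TE10)
    noisy <- sig + rnorm(10, 0, sig[1] / 200)
    fit <- nnlsFractions(echoSeries(TE10, noisy))
    abs(mwf(fit) - v[1])
  })
  expect_lt(median(errs), 0.03)
})

test_that("volume multi-fit matches per-curve NNLS and partitions tissue maps", {
  b <- compartmentBasis()
  te <- TE10
  grid <- c(3L, 3L, 2L)
  set.seed(13)
  vs <- lapply(seq_len(prod(grid)), function(i) {
    v <- rgamma(3, c(2, 6, 1))
    v / sum(v)
  })
  S <- t(vapply(vs, function(v) {
    predictMulti(900, v, b, te) + rnorm(10, 0, 3)
  }, numeric(10)))
  img <- array(S, c(grid, 10L))
  res <- fitMultiVolume(img, te)
  for (i in c(2L, 9L, 18L)) {
    fit <- nnlsFractions(echoSeries(te, S[i, ]))
    expect_equal(res$mwf[[i]], mwf(fit), tolerance = 1e-9)
  }
  # fraction maps sum to one voxelwise
  sums <- apply(res$fractions, 1:3, sum)
  expect_equal(as.numeric(sums), rep(1, prod(grid)), tolerance = 1e-9)
  # mixing pure CSF and pure tissue voxels partitions exactly
  img2 <- array(0, c(2, 1, 1, 10))
  img2[1, 1, 1, ] <- predictMono(700, 2000, te)
  img2[2, 1, 1, ] <- predictMono(700, 80, te)
  res2 <- fitMultiVolume(img2, te)
  expect_equal(res2$fractions[1, 1, 1, ], c(0, 0, 1), tolerance = 1e-6)
  expect_equal(res2$fractions[2, 1, 1, ], c(0, 1, 0), tolerance = 1e-6)
  # background (all-zero) voxels are counted as degenerate
  img3 <- array(0, c(2, 1, 1, 10))
  img3[1, 1, 1, ] <- predictMono(700, 80, te)
  res3 <- fitMultiVolume(img3, te)
  expect_identical(res3$nDegenerate, 1L)
  expect_true(is.na(res3$mwf[2, 1, 1]))
})

test_that("the support-enumeration solver matches an iterative NNLS", {
  # independent active-set implementation as cross-check, on noisy
  # curves where the iterative solver is well behaved
  set.seed(71)
  b <- compartmentBasis()
  A <- exp(-outer(TE10, 1 / t2Values(b)))
  for (i in 1:25) {
    v <- rgamma(3, c(2, 6, 1))
    v <- v / sum(v)
    s <- predictMulti(1000, v, b, TE10) + rnorm(10, 0, 5)
    ours <- fractions(nnlsFractions(echoSeries(TE10, s)))
    ref <- pracma::lsqnonneg(A, s)$x
    expect_equal(unname(ours), ref / sum(ref), tolerance = 1e-7)
  }
})

test_that("underdetermined fits warn", {
  expect_warning(
    nnlsFractions(echoSeries(c(10, 20), c(5, 3))),
    "underdetermined"
  )
})

test_that("the long-T2 column makes the default design poorly conditioned", {
  rep3 <- basisConditionReport(compartmentBasis(), TE10)
  expect_gt(rep3$conditionNumber, 10)
  # dropping the near-flat 2000 ms column improves conditioning
  rep2 <- basisConditionReport(compartmentBasis(c(20, 80)), TE10)
  expect_lt(rep2$conditionNumber, rep3$conditionNumber)
  # a single column is perfectly conditioned once normalised
  rep1 <- basisConditionReport(compartmentBasis(80), TE10)
  expect_equal(rep1$conditionNumber, 1, tolerance = 1e-12)
  # the free-water and tissue columns are nearly collinear over 13-150 ms
  expect_gt(rep3$columnCorrelations["tissue", "free"], 0.8)
})
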