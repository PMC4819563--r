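mkTable <- function(a, b) {
  data.frame(
    subject_id = sprintf("s%02d", seq_len(length(a) + length(b))),
    group = rep(c("preterm", "term"), c(length(a), length(b))),
    sex = rep(c("male", "female"), length.out = length(a) + length(b)),
    y = c(a, b),
    stringsAsFactors = FALSE
  )
}

test_that("identical groups give t = 0, p = 1", {
  tab <- mkTable(c(1, 2, 3), c(1, 2, 3))
  res <- compareGroups(tab, "y", split = "prematurity")
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
})

test_that("fully separated groups are overwhelmingly significant", {
  tab <- mkTable(c(1, 2, 3), c(11, 12, 13))
  res <- compareGroups(tab, "y", split = "prematurity")
  expect_lt(res$p, 0.001)
})

test_that("the pooled t statistic matches the closed-form formula", {
  a <- c(68.2, 70.1, 71.3, 69.0)
  b <- c(66.5, 67.2, 68.8, 66.1)
  tab <- mkTable(a, b)
  res <- compareGroups(tab, "y", split = "prematurity")
  # hand-computed pooled two-sample t
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  tHand <- (mean(a) - mean(b)) /
    sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  pHand <- 2 * pt(-abs(tHand), length(a) + length(b) - 2)
  expect_equal(res$t, tHand, tolerance = 1e-12)
  expect_equal(res$p, pHand, tolerance = 1e-12)
  expect_equal(res$df, 6)
})

test_that("t-tests are invariant to affine rescaling and row order", {
  set.seed(4)
  tab <- mkTable(rnorm(8, 70, 3), rnorm(8, 68, 3))
  res <- compareGroups(tab, "y", split = "prematurity")
  tab2 <- tab
  tab2$y <- 5 + 2.3 * tab2$y
  res2 <- compareGroups(tab2, "y", split = "prematurity")
  expect_equal(res2$t, res$t, tolerance = 1e-10)
  expect_equal(res2$p, res$p, tolerance = 1e-10)
  tab3 <- tab[sample(nrow(tab)), ]
  res3 <- compareGroups(tab3, "y", split = "prematurity")
  expect_equal(res3$t, res$t, tolerance = 1e-12)
})

test_that("the four-way split produces all pairwise stratum contrasts", {
  set.seed(6)
  tab <- data.frame(
    subject_id = sprintf("s%02d", 1:16),
    group = rep(c("preterm", "term"), each = 8),
    sex = rep(c("male", "female"), 8),
    y = rnorm(16, 70, 2),
    stringsAsFactors = FALSE
  )
  res <- compareGroups(tab, "y", split = "both")
  expect_identical(nrow(res), 6L)  # choose(4, 2)
  # a stratum reduced to one subject is named in the error
  expect_error(compareGroups(tab[-c(2, 4, 6), ], "y",
    split = "both"), "fewer than 2")
})

test_that("adjusted comparisons match closed-form OLS on a small fixture", {
  tab <- data.frame(
    subject_id = sprintf("s%d", 1:6),
    group = rep(c("preterm", "term"), each = 3),
    sex = rep("male", 6),
    y = c(70.2, 69.1, 71.0, 67.3, 66.8, 68.0),
    vol = c(0.34, 0.36, 0.33, 0.42, 0.44, 0.41),
    stringsAsFactors = FALSE
  )
  res <- compareAdjusted(tab, "y", covariate = "vol")
  # independent normal-equations solution
  X <- cbind(1, as.numeric(tab$group == "term"), tab$vol)
  beta <- solve(t(X) %*% X, t(X) %*% tab$y)
  resid <- tab$y - X %*% beta
  s2 <- sum(resid^2) / (6 - 3)
  seBeta <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  tHand <- beta[2] / seBeta
  expect_equal(res$t, tHand, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(tHand), 3), tolerance = 1e-10)
  expect_true(res$adjusted)
  expect_identical(res$covariate, "vol")
  expect_error(compareAdjusted(transform(tab, vol = 0.4), "y",
    covariate = "vol"), "zero variance")
})

test_that("a variable that is pure covariate has no adjusted group effect", {
  set.seed(12)
  vol <- c(rnorm(10, 0.35, 0.02), rnorm(10, 0.42, 0.02))
  tab <- data.frame(
    subject_id = sprintf("s%02d", 1:20),
    group = rep(c("preterm", "term"), each = 10),
    sex = rep(c("male", "female"), 10),
    y = 80 - 30 * vol,  # exact linear function of the covariate
    vol = vol,
    stringsAsFactors = FALSE
  )
  res <- suppressWarnings(compareAdjusted(tab, "y", covariate = "vol"))
  expect_lt(abs(res$estimate), 1e-8)
  # while the unadjusted contrast is strongly significant
  expect_lt(compareGroups(tab, "y", split = "prematurity")$p, 1e-6)
})

test_that("volume-mediated group differences vanish under adjustment", {
  tab <- volumeMediatedCohort(nPerGroup = 25L, seed = 2)
  unadj <- compareGroups(tab, "wm_t2_ms", split = "prematurity")
  adj <- compareAdjusted(tab, "wm_t2_ms", covariate = "wm_volume_l")
  expect_lt(unadj$p, 0.05)
  expect_gt(adj$p, 0.05)
})

test_that("cohort reports summarise strata and volume ratios", {
  tab <- data.frame(
    subject_id = sprintf("s%d", 1:8),
    group = rep(c("preterm", "term"), each = 4),
    sex = rep(c("male", "male", "female", "female"), 2),
    wm_volume_l = c(0.38, 0.40, 0.34, 0.36, 0.42, 0.44, 0.37, 0.39),
    stringsAsFactors = FALSE
  )
  rep <- cohortReport(tab)
  expect_identical(nrow(rep$strata), 4L)
  # ratios are quotients of stratum means
  expect_equal(rep$wmVolumeRatios[["female"]],
    mean(c(0.34, 0.36)) / mean(c(0.37, 0.39)), tolerance = 1e-12)
  expect_equal(rep$wmVolumeRatios[["male"]],
    mean(c(0.38, 0.40)) / mean(c(0.42, 0.44)), tolerance = 1e-12)
  # single-subject strata warn and report sd 0
  tab1 <- tab[c(1, 3, 5, 7), ]
  warns <- capture_warnings(rep1 <- cohortReport(tab1))
  expect_true(any(grepl("single subject", warns)))
  expect_true(all(rep1$strata$wm_volume_l_sd == 0))
})

test_that("cohort tables are validated", {
  tab <- mkTable(c(1, 2), c(3, 4))
  tab$subject_id[2] <- tab$subject_id[1]
  expect_error(compareGroups(tab, "y", split = "prematurity"), "unique")
  tab2 <- mkTable(c(1, 2), c(3, 4))
  expect_error(compareGroups(tab2, "nope", split = "prematurity"),
    "no column")
})
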