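# Independent oracles and small fixture builders used across the suite.

TE10 <- c(13, 16, 20, 25, 30, 40, 50, 85, 100, 150)

noisyMonoCurve <- function(s0, t2, sigma, seed) {
  set.seed(seed)
  echoSeries(TE10, s0 * exp(-TE10 / t2) + rnorm(length(TE10), 0, sigma))
}

# Brute-force minimiser of the original-space SSE of the mono model.
# For each candidate T2 the optimal amplitude is the exact linear
# least-squares coefficient, so a dense 1D scan over T2 (coarse pass then
# 0.001 ms refinement) minimises over both parameters.
oracleMonoFit <- function(curve, t2Range = c(1, 500)) {
  S <- signals(curve)
  te <- echoTimes(curve)
  sseAt <- function(t2grid) {
    E <- exp(-outer(t2grid, te, function(t, x) x / t))
    s0hat <- (E %*% S) / rowSums(E * E)
    rowSums((matrix(S, length(t2grid), length(te), byrow = TRUE) -
      as.numeric(s0hat) * E)^2)
  }
  coarse <- seq(t2Range[1], t2Range[2], by = 0.1)
  t2c <- coarse[which.min(sseAt(coarse))]
  fine <- seq(max(t2Range[1], t2c - 0.2), t2c + 0.2, by = 0.001)
  t2f <- fine[which.min(sseAt(fine))]
  E <- exp(-te / t2f)
  list(t2 = t2f, s0 = sum(E * S) / sum(E * E))
}

# Dense simplex-grid least-squares oracle for the three-compartment
# model: enumerates fraction vectors at the given resolution, profiles
# out the amplitude in closed form, and returns the SSE-minimising
# fractions. Grid and model matrix are built once and memoised.
simplexOracleEnv <- new.env()

simplexOracle <- function(signals, te = TE10, basis = c(20, 80, 2000),
                          res = 0.0005) {
  key <- paste(c(te, basis, res), collapse = "_")
  cache <- simplexOracleEnv[[key]]
  if (is.null(cache)) {
    v1 <- seq(0, 1, by = res)
    g <- expand.grid(v1 = v1, v2 = v1)
    g <- g[g$v1 + g$v2 <= 1 + 1e-12, ]
    V <- cbind(g$v1, g$v2, pmax(1 - g$v1 - g$v2, 0))
    E <- exp(-outer(te, 1 / basis))
    M <- V %*% t(E)
    cache <- list(V = V, M = M, mm = rowSums(M * M))
    simplexOracleEnv[[key]] <- cache
  }
  ms <- as.numeric(cache$M %*% signals)
  s0hat <- ms / cache$mm
  sse <- sum(signals^2) - s0hat * ms
  best <- which.min(sse)
  list(fractions = cache$V[best, ], s0 = s0hat[[best]])
}

# Small cohort spec variants built in code.
tinySpec <- function(nPer = 1L, gridShape = c(12L, 12L, 6L), seed = 1L,
                     snr = NULL) {
  spec <- cohortSpec(seed = seed, gridShape = gridShape, snr = snr)
  spec@strata$n <- rep(as.integer(nPer), nrow(spec@strata))
  spec
}

nullSpec <- function(nPer = 15L) {
  spec <- cohortSpec()
  st <- spec@strata[c(1L, 3L), ]
  parCols <- setdiff(names(st), c("group", "sex", "n"))
  st[2L, parCols] <- st[1L, parCols]
  st$n <- rep(as.integer(nPer), 2L)
  spec@strata <- st
  spec
}
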