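#' Configure the compartment-fraction MCMC
#'
#' Builds a [ChainConfig-class]. The `"full"` preset is the long-run
#' protocol (100,000 burn-in, 100,000 sampling iterations, 5000 retained
#' samples after thinning); the `"test"` preset (2000 / 2000 / 500) runs in
#' seconds and is used throughout the test suite. Retention keeps every
#' `floor(nRun / nKeep)`-th post-burn-in state.
#'
#' @param preset `"full"` or `"test"`; sets `nBurn`, `nRun`, `nKeep`.
#' @param nBurn,nRun,nKeep chain lengths, overriding the preset.
#' @param proposalConcentration Dirichlet proposal concentration scale
#'   kappa; proposals are drawn from Dirichlet(kappa * current fractions).
#' @param noiseSd signal-space likelihood sigma, or NA to estimate it as
#'   the RMS residual of the NNLS fit to the same curve.
#' @param s0StepSd log-scale SD of the amplitude random walk (default 1%).
#' @param seed integer RNG seed.
#' @return a [ChainConfig-class].
#' @examples
#' chainConfig(preset = "test", seed = 7)
#' @export
chainConfig <- function(preset = c("full", "test"), nBurn = NULL,
                        nRun = NULL, nKeep = NULL,
                        proposalConcentration = 500, noiseSd = NA_real_,
                        s0StepSd = 0.01, seed = 1L) {
  preset <- match.arg(preset)
  def <- switch(preset,
    full = c(nBurn = 100000L, nRun = 100000L, nKeep = 5000L),
    test = c(nBurn = 2000L, nRun = 2000L, nKeep = 500L)
  )
  new("ChainConfig",
    nBurn = as.integer(nBurn %||% def[["nBurn"]]),
    nRun = as.integer(nRun %||% def[["nRun"]]),
    nKeep = as.integer(nKeep %||% def[["nKeep"]]),
    proposalConcentration = as.numeric(proposalConcentration),
    noiseSd = as.numeric(noiseSd),
    s0StepSd = as.numeric(s0StepSd),
    seed = as.integer(seed)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Dirichlet draws / log-density (no provider among the package's
# dependencies; via independent gammas).
.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s <= 0) {             # numerically degenerate draw: fall back to mode-ish
    g <- alpha / sum(alpha)
    s <- 1
  }
  g / s
}

.ddirichletLog <- function(x, alpha) {
  if (any(x <= 0)) return(-Inf)
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

#' Posterior sampling of compartment fractions for one decay curve
#'
#' Metropolis-Hastings sampler over the compartment fractions (on the
#' simplex) and the total amplitude, for a single - typically
#' ROI-averaged - decay curve. Fraction proposals are drawn from
#' `Dirichlet(kappa * current)` with the asymmetric proposal density
#' entering the Hastings ratio; the amplitude takes a log-normal random
#' walk (flat prior on the log amplitude, so the walk is symmetric). The
#' likelihood is Gaussian in signal space with standard deviation
#' `noiseSd` (estimated as the RMS residual of the NNLS fit when NA), and
#' the prior on the fractions is flat Dirichlet(1, ..., 1). The chain is
#' initialised at the NNLS point estimate, burn-in is discarded and every
#' `floor(nRun/nKeep)`-th state retained. The run is fully determined by
#' `config@seed`.
#'
#' Current fractions are floored at 1e-4 (and renormalised) before scaling
#' by kappa, so the proposal distribution stays proper at the simplex
#' boundary.
#'
#' @param curve an [EchoSeries-class] (e.g. from [roiMeanCurve()]).
#' @param basis a [CompartmentBasis-class].
#' @param config a [ChainConfig-class].
#' @return a [PosteriorSamples-class].
#' @examples
#' te <- defaultEchoTimes()
#' s <- predictMulti(1000, c(0.25, 0.7, 0.05), compartmentBasis(), te)
#' ps <- runChain(echoSeries(te, s), config = chainConfig("test"))
#' posteriorReport(ps)$table
#' @export
runChain <- function(curve, basis = compartmentBasis(),
                     config = chainConfig()) {
  stopifnot(is(curve, "EchoSeries"), is(basis, "CompartmentBasis"),
    is(config, "ChainConfig"))
  validObject(config)
  p <- length(basis@t2Values)
  A <- decayDesignMatrix(basis, curve@echoTimes)
  start <- nnlsFractions(curve, basis)
  if (start@degenerate) {
    stop("degenerate (zero-amplitude) curve: nothing to sample")
  }
  sigma <- config@noiseSd
  if (is.na(sigma)) {
    sigma <- sqrt(start@residualNorm / length(curve@signals))
    # floor for effectively noiseless curves so the likelihood is proper
    sigma <- max(sigma, 1e-9 * start@s0)
  }
  kappa <- config@proposalConcentration
  y <- curve@signals
  loglik <- function(v, s0v) {
    -sum((y - s0v * as.numeric(A %*% v))^2) / (2 * sigma^2)
  }
  propAlpha <- function(v) kappa * .propBase(v)
  v <- start@fractions
  s0v <- start@s0
  ll <- loglik(v, s0v)
  nTot <- config@nBurn + config@nRun
  stride <- max(1L, config@nRun %/% config@nKeep)
  keepAt <- config@nBurn + seq(stride, config@nRun, by = stride)
  keep <- matrix(NA_real_, length(keepAt), p)
  keepS0 <- numeric(length(keepAt))
  kptr <- 1L
  nAcc <- 0L
  set.seed(config@seed)
  for (it in seq_len(nTot)) {
    aCur <- propAlpha(v)
    vProp <- .rdirichlet(aCur)
    s0Prop <- s0v * exp(stats::rnorm(1L, 0, config@s0StepSd))
    llProp <- loglik(vProp, s0Prop)
    aProp <- propAlpha(vProp)
    logR <- llProp - ll +
      .ddirichletLog(v, aProp) - .ddirichletLog(vProp, aCur)
    if (is.finite(logR) && log(stats::runif(1L)) < logR) {
      v <- vProp
      s0v <- s0Prop
      ll <- llProp
      nAcc <- nAcc + 1L
    }
    if (kptr <= length(keepAt) && it == keepAt[kptr]) {
      keep[kptr, ] <- v
      keepS0[kptr] <- s0v
      kptr <- kptr + 1L
    }
  }
  colnames(keep) <- basis@compartmentNames
  new("PosteriorSamples",
    samples = keep, s0Samples = keepS0,
    acceptanceRate = nAcc / nTot, basis = basis, config = config
  )
}

# Floor + renormalise current fractions before forming the proposal
# concentration, keeping Dirichlet(kappa * v) proper near the boundary.
.propBase <- function(v, eps = 1e-4) {
  v <- pmax(v, eps)
  v / sum(v)
}

#' Summarise posterior samples
#'
#' Per-compartment posterior mean and sample standard deviation, plus
#' histogram data (counts over `breaks` bins per compartment) ready for
#' plotting the posterior fraction distributions.
#'
#' @param samples a [PosteriorSamples-class].
#' @param breaks number of histogram bins.
#' @return list with `table` (data.frame: compartment, t2_ms, mean, sd),
#'   `histograms` (list of `hist`-like objects per compartment) and
#'   `acceptanceRate`.
#' @export
posteriorReport <- function(samples, breaks = 40L) {
  stopifnot(is(samples, "PosteriorSamples"))
  x <- samples@samples
  if (nrow(x) < 1L) stop("empty sample set")
  tab <- data.frame(
    compartment = colnames(x),
    t2_ms = samples@basis@t2Values,
    mean = colMeans(x),
    sd = apply(x, 2L, stats::sd),
    row.names = NULL
  )
  hists <- lapply(seq_len(ncol(x)), function(i) {
    graphics::hist(x[, i], breaks = breaks, plot = FALSE)
  })
  names(hists) <- colnames(x)
  list(table = tab, histograms = hists,
    acceptanceRate = samples@acceptanceRate)
}
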