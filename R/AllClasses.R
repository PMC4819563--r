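#' @import methods
NULL

#' EchoSeries: one multi-echo decay curve
#'
#' Container for a single T2 decay measurement: echo times (ms) paired with
#' signal intensities (arbitrary units). Echo times must be strictly
#' increasing and positive; at least two echoes are required.
#'
#' @slot echoTimes numeric vector of echo times in ms, strictly increasing,
#'   all positive.
#' @slot signals numeric vector of signal intensities, same length as
#'   `echoTimes`.
#'
#' @seealso [echoSeries()], [predictMono()], [predictMulti()]
#' @exportClass EchoSeries
setClass("EchoSeries",
  representation(echoTimes = "numeric", signals = "numeric"),
  validity = function(object) {
    te <- object@echoTimes
    s <- object@signals
    if (length(te) < 2L) return("need at least 2 echo times")
    if (length(te) != length(s)) {
      return("echoTimes and signals must have equal length")
    }
    if (anyNA(te) || any(te <= 0)) return("echo times must be positive")
    if (any(diff(te) <= 0)) return("echo times must be strictly increasing")
    if (anyNA(s)) return("signals must not contain NA")
    TRUE
  }
)

#' CompartmentBasis: fixed T2 constants of a multi-compartment model
#'
#' The multi-compartment decay model is evaluated on a small fixed set of
#' T2 relaxation constants, one per water compartment. The default basis is
#' 20 / 80 / 2000 ms for myelin water, intra/extra-cellular tissue water and
#' free water (CSF); the myelin water fraction is by definition the signal
#' fraction assigned to the shortest basis T2.
#'
#' @slot t2Values numeric, strictly increasing positive T2 constants (ms).
#' @slot compartmentNames character, parallel labels.
#'
#' @seealso [compartmentBasis()], [nnlsFractions()]
#' @exportClass CompartmentBasis
setClass("CompartmentBasis",
  representation(t2Values = "numeric", compartmentNames = "character"),
  validity = function(object) {
    t2 <- object@t2Values
    if (length(t2) < 1L) return("basis must contain at least one T2")
    if (anyNA(t2) || any(t2 <= 0)) return("basis T2 values must be positive")
    if (any(diff(t2) <= 0)) {
      return("basis T2 values must be strictly increasing (no duplicates)")
    }
    if (length(object@compartmentNames) != length(t2)) {
      return("compartmentNames must parallel t2Values")
    }
    TRUE
  }
)

#' MonoFit: single-component T2 fit of one decay curve
#'
#' Result of the two-stage single-component fit: a log-linear least-squares
#' initialisation followed by Gauss-Newton refinement of the original-space
#' sum of squared residuals.
#'
#' @slot s0 fitted amplitude (signal at TE = 0).
#' @slot t2 fitted T2 in ms.
#' @slot residualNorm sum of squared residuals in original signal space.
#' @slot nIterations Gauss-Newton iterations used (<= maxIter).
#' @slot converged logical; TRUE when the residual-change criterion was met.
#' @slot initS0,initT2 the starting values from the linear initialisation.
#'
#' @seealso [gaussNewtonFit()], [linearInit()]
#' @exportClass MonoFit
setClass("MonoFit",
  representation(
    s0 = "numeric", t2 = "numeric", residualNorm = "numeric",
    nIterations = "integer", converged = "logical",
    initS0 = "numeric", initT2 = "numeric"
  ),
  validity = function(object) {
    if (length(object@s0) != 1L || length(object@t2) != 1L) {
      return("s0 and t2 must be scalars")
    }
    if (!is.na(object@t2) && object@t2 <= 0) return("t2 must be positive")
    if (object@nIterations < 0L) return("nIterations must be >= 0")
    TRUE
  }
)

#' MultiFit: multi-compartment decomposition of one decay curve
#'
#' Result of the non-negative least-squares fit of a decay curve on a fixed
#' T2 basis: total amplitude, compartment signal fractions (non-negative,
#' summing to one), and the myelin water fraction, i.e. the fraction at the
#' shortest basis T2. A curve with an all-zero amplitude solution is flagged
#' degenerate and carries NA fractions.
#'
#' @slot s0 total fitted amplitude (sum of compartment amplitudes).
#' @slot fractions numeric simplex vector, one per basis compartment
#'   (NA when degenerate).
#' @slot basis the [CompartmentBasis-class] used.
#' @slot residualNorm original-space sum of squared residuals.
#' @slot mwf fraction at the shortest basis T2 (NA when degenerate).
#' @slot degenerate logical flag for all-zero amplitude solutions.
#'
#' @seealso [nnlsFractions()]
#' @exportClass MultiFit
setClass("MultiFit",
  representation(
    s0 = "numeric", fractions = "numeric", basis = "CompartmentBasis",
    residualNorm = "numeric", mwf = "numeric", degenerate = "logical"
  ),
  validity = function(object) {
    nb <- length(object@basis@t2Values)
    if (length(object@fractions) != nb) {
      return("fractions must have one entry per basis compartment")
    }
    if (!object@degenerate) {
      v <- object@fractions
      if (any(v < -1e-12)) return("fractions must be non-negative")
      if (abs(sum(v) - 1) > 1e-9) return("fractions must sum to 1")
      if (!isTRUE(all.equal(object@mwf, v[[1L]], tolerance = 1e-12))) {
        return("mwf must equal the shortest-T2 fraction")
      }
    }
    TRUE
  }
)

#' ChainConfig: settings for the compartment-fraction MCMC
#'
#' Configuration of the Metropolis-Hastings sampler over compartment
#' fractions and amplitude. Defaults follow the long-run protocol
#' (100,000 burn-in iterations, 100,000 sampling iterations, 5000 retained
#' samples after thinning); `chainConfig(preset = "test")` gives a
#' scaled-down chain for fast runs.
#'
#' @slot nBurn integer, burn-in iterations.
#' @slot nRun integer, post-burn-in iterations.
#' @slot nKeep integer, retained samples after thinning (<= nRun).
#' @slot proposalConcentration Dirichlet proposal concentration scale
#'   (kappa > 0); proposals are Dirichlet(kappa * current).
#' @slot noiseSd signal-space likelihood sigma, or NA to estimate it as the
#'   RMS residual of the NNLS fit to the same curve.
#' @slot s0StepSd standard deviation of the log-normal random walk on the
#'   amplitude (log scale).
#' @slot seed integer RNG seed.
#'
#' @seealso [chainConfig()], [runChain()]
#' @exportClass ChainConfig
setClass("ChainConfig",
  representation(
    nBurn = "integer", nRun = "integer", nKeep = "integer",
    proposalConcentration = "numeric", noiseSd = "numeric",
    s0StepSd = "numeric", seed = "integer"
  ),
  validity = function(object) {
    if (object@nBurn < 0L) return("nBurn must be >= 0")
    if (object@nRun < 1L) return("nRun must be >= 1")
    if (object@nKeep < 1L || object@nKeep > object@nRun) {
      return("nKeep must be in [1, nRun]")
    }
    if (object@proposalConcentration <= 0) {
      return("proposalConcentration (kappa) must be > 0")
    }
    if (!is.na(object@noiseSd) && object@noiseSd <= 0) {
      return("noiseSd must be > 0 (or NA to estimate)")
    }
    if (object@s0StepSd <= 0) return("s0StepSd must be > 0")
    TRUE
  }
)

#' PosteriorSamples: retained MCMC draws of compartment fractions
#'
#' @slot samples numeric matrix, one retained fraction vector per row
#'   (columns named after the basis compartments).
#' @slot s0Samples numeric vector of retained amplitude draws.
#' @slot acceptanceRate fraction of proposals accepted over the whole run.
#' @slot basis the [CompartmentBasis-class] sampled over.
#' @slot config the [ChainConfig-class] used.
#'
#' @seealso [runChain()], [posteriorReport()]
#' @exportClass PosteriorSamples
setClass("PosteriorSamples",
  representation(
    samples = "matrix", s0Samples = "numeric",
    acceptanceRate = "numeric", basis = "CompartmentBasis",
    config = "ChainConfig"
  ),
  validity = function(object) {
    x <- object@samples
    if (nrow(x) < 1L) return("samples must be non-empty")
    if (ncol(x) != length(object@basis@t2Values)) {
      return("samples must have one column per basis compartment")
    }
    if (any(x < -1e-12)) return("all retained samples must be non-negative")
    if (any(abs(rowSums(x) - 1) > 1e-9)) {
      return("all retained samples must sum to 1")
    }
    if (length(object@s0Samples) != nrow(x)) {
      return("s0Samples must parallel samples rows")
    }
    ar <- object@acceptanceRate
    if (ar < 0 || ar > 1) return("acceptanceRate must lie in [0, 1]")
    TRUE
  }
)

#' CohortSpec: group-level ground truth for the synthetic cohort
#'
#' Stratum-level parameters (group x sex) of the synthetic study: numbers of
#' subjects, tissue volume means and SDs in liters, white matter composition
#' (myelin water fraction mean/SD, free-water fraction SD and target
#' effective mono-exponential T2 used to calibrate the free-water mean),
#' gray matter composition, first-echo SNR, echo times, nominal voxel
#' dimensions, grid shape and a voxel-volume scale factor.
#'
#' @slot strata data.frame with one row per stratum (columns documented in
#'   [cohortSpec()]).
#' @slot echoTimes numeric, echo times in ms.
#' @slot basis [CompartmentBasis-class] used by the decay model.
#' @slot voxelDims numeric length 3, nominal voxel dimensions in mm.
#' @slot gridShape integer length 3, image grid dimensions.
#' @slot voxelScale numeric scalar > 0, voxel-volume scale factor (the
#'   emitted pixdims are `voxelDims * voxelScale^(1/3)`), or NA for
#'   automatic selection so the largest plausible head fits the grid.
#' @slot snr first-echo white matter signal-to-noise ratio.
#' @slot s0 common proton-density amplitude (arbitrary units).
#' @slot seed base RNG seed.
#'
#' @seealso [cohortSpec()], [generateCohort()]
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    strata = "data.frame", echoTimes = "numeric",
    basis = "CompartmentBasis", voxelDims = "numeric",
    gridShape = "integer", voxelScale = "numeric",
    snr = "numeric", s0 = "numeric", seed = "integer"
  ),
  validity = function(object) {
    st <- object@strata
    need <- c(
      "group", "sex", "n",
      "wm_vol_mean", "wm_vol_sd", "gm_vol_mean", "gm_vol_sd",
      "csf_vol_mean", "csf_vol_sd",
      "wm_mwf_mean", "wm_mwf_sd", "wm_csf_frac_sd", "wm_t2_target",
      "gm_mwf_mean", "gm_t2_target"
    )
    miss <- setdiff(need, names(st))
    if (length(miss)) {
      return(paste("strata is missing columns:", paste(miss, collapse = ", ")))
    }
    if (nrow(st) < 1L) return("strata must have at least one row")
    if (any(st$n < 1L)) return("each stratum needs n >= 1")
    if (!all(st$group %in% c("preterm", "term"))) {
      return("group must be 'preterm' or 'term'")
    }
    if (!all(st$sex %in% c("male", "female"))) {
      return("sex must be 'male' or 'female'")
    }
    sdcols <- grep("_sd$", need, value = TRUE)
    if (any(unlist(st[sdcols]) < 0)) return("all sds must be >= 0")
    if (any(st$wm_mwf_mean <= 0 | st$wm_mwf_mean >= 1)) {
      return("wm_mwf_mean must lie in (0, 1)")
    }
    if (length(object@voxelDims) != 3L || any(object@voxelDims <= 0)) {
      return("voxelDims must be 3 positive lengths in mm")
    }
    if (length(object@gridShape) != 3L || any(object@gridShape < 4L)) {
      return("gridShape must be 3 integers >= 4")
    }
    if (!is.na(object@voxelScale) && object@voxelScale <= 0) {
      return("voxelScale must be > 0 (or NA for auto)")
    }
    if (object@snr <= 0) return("snr must be > 0")
    if (object@s0 <= 0) return("s0 must be > 0")
    TRUE
  }
)
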