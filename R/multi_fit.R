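#' Multi-compartment decomposition of one decay curve by NNLS
#'
#' Fits the multi-compartment model `S(TE) = sum_i a_i exp(-TE/T2_i)` with
#' non-negative amplitudes by non-negative least squares on the fixed basis
#' design matrix `A[j, i] = exp(-TE_j / T2_i)`, then sets
#' `s0 = sum(a)` and fractions `v_i = a_i / s0`, so the fractions are
#' non-negative and sum to one by construction. The myelin water fraction
#' is the fraction at the shortest basis T2. The non-negativity
#' constraint drives unsupported compartments exactly to zero, giving
#' sparse amplitude vectors without extra regularisation.
#'
#' A curve whose NNLS solution is all-zero (e.g. a flat-zero background
#' voxel) is flagged degenerate: fractions and MWF are `NA` and the voxel
#' is meant to be excluded from downstream ROI statistics.
#'
#' @param curve an [EchoSeries-class].
#' @param basis a [CompartmentBasis-class]; default `[20, 80, 2000]` ms.
#' @return a [MultiFit-class].
#' @examples
#' te <- defaultEchoTimes()
#' s <- predictMulti(1000, c(0.25, 0.70, 0.05), compartmentBasis(), te)
#' nnlsFractions(echoSeries(te, s))
#' @export
nnlsFractions <- function(curve, basis = compartmentBasis()) {
  stopifnot(is(curve, "EchoSeries"), is(basis, "CompartmentBasis"))
  p <- length(basis@t2Values)
  if (length(curve@echoTimes) < p) {
    warning(sprintf(
      "only %d echoes for %d compartments: fit is underdetermined",
      length(curve@echoTimes), p
    ))
  }
  A <- decayDesignMatrix(basis, curve@echoTimes)
  sol <- .nnlsExact(A, matrix(curve@signals, nrow = 1L))
  .multiFitFromAmplitudes(sol$amplitudes[1L, ], A, curve@signals, basis)
}

# Exact non-negative least squares for small fixed bases, solved by
# enumerating all column supports: the NNLS optimum restricted to its
# support is the unconstrained least-squares solution there, so the best
# support whose solution is feasible (all coefficients >= 0) is the
# global optimum. Enumerating 2^p - 1 supports is exact and, unlike an
# iterative active-set solver, cannot cycle on exactly representable
# curves; it is also vectorised across curves (rows of S).
.nnlsExact <- function(A, S) {
  m <- nrow(A)
  p <- ncol(A)
  if (p > 12L) stop("support enumeration is limited to <= 12 compartments")
  n <- nrow(S)
  normS2 <- rowSums(S^2)
  bestSse <- normS2            # empty support: all-zero amplitudes
  bestAmp <- matrix(0, n, p)
  for (maskBits in seq_len(2^p - 1L)) {
    cols <- which(bitwAnd(maskBits, bitwShiftL(1L, seq_len(p) - 1L)) > 0L)
    At <- A[, cols, drop = FALSE]
    G <- crossprod(At)
    Ginv <- tryCatch(solve(G), error = function(e) NULL)
    if (is.null(Ginv)) next  # rank-deficient support (underdetermined)
    SAt <- S %*% At
    C <- SAt %*% Ginv
    tol <- -1e-9 * (1 + apply(abs(C), 1L, max))
    feas <- rowSums(C < tol) == 0L
    sse <- pmax(normS2 - rowSums(C * SAt), 0)
    upd <- feas & sse < bestSse
    if (any(upd)) {
      bestSse[upd] <- sse[upd]
      bestAmp[upd, ] <- 0
      bestAmp[upd, cols] <- pmax(C[upd, , drop = FALSE], 0)
    }
  }
  list(amplitudes = bestAmp, sse = bestSse)
}

.multiFitFromAmplitudes <- function(a, A, signals, basis) {
  s0 <- sum(a)
  rn <- sum((signals - as.numeric(A %*% a))^2)
  if (s0 <= 0) {
    p <- length(basis@t2Values)
    return(new("MultiFit",
      s0 = 0, fractions = rep(NA_real_, p), basis = basis,
      residualNorm = rn, mwf = NA_real_, degenerate = TRUE
    ))
  }
  v <- a / s0
  new("MultiFit",
    s0 = s0, fractions = v, basis = basis,
    residualNorm = rn, mwf = v[[1L]], degenerate = FALSE
  )
}

#' Voxelwise multi-compartment fitting and MWF mapping
#'
#' Applies [nnlsFractions()] to every masked voxel of a 4D multi-echo
#' image, producing one fraction map per basis compartment, an S0 map and
#' the myelin water fraction map (the shortest-T2 fraction map). Degenerate
#' voxels (all-zero NNLS amplitude) carry `NA` fractions and are counted in
#' the returned QC summary.
#'
#' @param image 4D numeric array (x, y, z, echo).
#' @param echoTimes numeric vector of echo times in ms.
#' @param mask 3D logical/0-1 array; default all voxels.
#' @param basis a [CompartmentBasis-class].
#' @return list with `mwf` (3D array), `fractions` (4D array, x-y-z by
#'   compartment), `s0` (3D array), and `nDegenerate` (count of degenerate
#'   masked voxels).
#' @examples
#' te <- defaultEchoTimes()
#' s <- predictMulti(1000, c(0.25, 0.70, 0.05), compartmentBasis(), te)
#' img <- array(rep(s, each = 4), c(2, 2, 1, 10))
#' fitMultiVolume(img, te)$mwf[1, 1, 1]
#' @export
fitMultiVolume <- function(image, echoTimes, mask = NULL,
                           basis = compartmentBasis()) {
  image <- .as4d(image)
  d <- dim(image)
  if (d[[4L]] != length(echoTimes)) {
    stop(sprintf(
      "4th image dimension (%d) must equal the number of echo times (%d)",
      d[[4L]], length(echoTimes)
    ))
  }
  vol <- d[1:3]
  if (is.null(mask)) mask <- array(TRUE, vol)
  mask <- .asMask(mask, vol)
  p <- length(basis@t2Values)
  mwfMap <- s0Map <- array(NA_real_, vol)
  fracMaps <- array(NA_real_, c(vol, p))
  idx <- which(mask)
  if (!length(idx)) {
    warning("empty mask: returning all-NA maps")
    return(list(mwf = mwfMap, fractions = fracMaps, s0 = s0Map,
      nDegenerate = 0L))
  }
  S <- matrix(image, prod(vol), d[[4L]])[idx, , drop = FALSE]
  A <- decayDesignMatrix(basis, echoTimes)
  amp <- .nnlsExact(A, S)$amplitudes
  s0v <- rowSums(amp)
  degen <- s0v <= 0
  vfrac <- amp / ifelse(degen, NA_real_, s0v)
  nvox <- prod(vol)
  for (i in seq_len(p)) {
    fracMaps[idx + (i - 1L) * nvox] <- vfrac[, i]
  }
  s0Map[idx] <- s0v
  mwfMap[idx] <- vfrac[, 1L]
  list(mwf = mwfMap, fractions = fracMaps, s0 = s0Map,
    nDegenerate = sum(degen))
}

#' Conditioning of the multi-compartment design matrix
#'
#' Reports the condition number (after column normalisation to unit
#' Euclidean norm) and the pairwise column correlations of the decay design
#' matrix `A[j, i] = exp(-TE_j / T2_i)`. Over an echo-time range of
#' 13-150 ms the 2000 ms free-water column is nearly constant and strongly
#' correlated with the 80 ms column, which is why the three-compartment
#' problem is ill-conditioned and the NNLS sparsity is valuable.
#'
#' @param basis a [CompartmentBasis-class].
#' @param echoTimes numeric vector of echo times in ms.
#' @return list with `conditionNumber` (of the column-normalised design),
#'   `conditionNumberRaw`, and `columnCorrelations` (matrix).
#' @examples
#' basisConditionReport(compartmentBasis(), defaultEchoTimes())
#' @export
basisConditionReport <- function(basis = compartmentBasis(),
                                 echoTimes = defaultEchoTimes()) {
  stopifnot(is(basis, "CompartmentBasis"))
  A <- decayDesignMatrix(basis, echoTimes)
  An <- sweep(A, 2L, sqrt(colSums(A^2)), "/")
  svn <- svd(An, nu = 0, nv = 0)$d
  svr <- svd(A, nu = 0, nv = 0)$d
  cc <- suppressWarnings(stats::cor(A))
  if (ncol(A) == 1L) cc <- matrix(1, 1, 1)
  dimnames(cc) <- list(basis@compartmentNames, basis@compartmentNames)
  list(
    conditionNumber = max(svn) / min(svn),
    conditionNumberRaw = max(svr) / min(svr),
    columnCorrelations = cc
  )
}
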