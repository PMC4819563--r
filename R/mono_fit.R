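#' Log-linear initialisation of the single-component fit
#'
#' Ordinary least squares of `log(S)` on TE: under the mono-exponential
#' model `log S(TE) = log S0 - TE / T2`, so the slope gives `-1/T2` and the
#' intercept `log S0`. Echoes with non-positive signal are excluded from
#' the regression (the log is undefined there); if fewer than two positive
#' echoes remain the fallback `(s0 = max signal, t2 = 70 ms)` is returned,
#' and a non-decaying fit (slope >= 0, as seen in CSF-like voxels that are
#' essentially flat over 13-150 ms) returns `t2 = 2000 ms` with the
#' regression intercept as amplitude.
#'
#' @param curve an [EchoSeries-class].
#' @return list with elements `s0` and `t2` (ms).
#' @examples
#' te <- defaultEchoTimes()
#' linearInit(echoSeries(te, predictMono(100, 50, te)))
#' @export
linearInit <- function(curve) {
  stopifnot(is(curve, "EchoSeries"))
  res <- .linearInitMatrix(matrix(curve@signals, nrow = 1L),
    curve@echoTimes)
  list(s0 = res$s0[[1L]], t2 = res$t2[[1L]])
}

# Vectorised log-linear init. S: n_vox x n_echo matrix. Non-positive
# signals get weight zero; < 2 usable points falls back to
# (max signal, 70 ms); slope >= 0 falls back to t2 = 2000 ms.
.linearInitMatrix <- function(S, te) {
  n <- nrow(S)
  w <- (S > 0) * 1
  ly <- ifelse(S > 0, log(pmax(S, .Machine$double.xmin)), 0)
  teM <- matrix(te, n, length(te), byrow = TRUE)
  nw <- rowSums(w)
  sx <- rowSums(w * teM)
  sy <- rowSums(w * ly)
  sxx <- rowSums(w * teM * teM)
  sxy <- rowSums(w * teM * ly)
  denom <- nw * sxx - sx * sx
  usable <- nw >= 2 & denom > 0
  slope <- ifelse(usable, (nw * sxy - sx * sy) / denom, NA_real_)
  icpt <- ifelse(usable, (sy - slope * sx) / nw, NA_real_)
  s0 <- ifelse(usable, exp(icpt), apply(S, 1L, max))
  t2 <- ifelse(usable & slope < 0, -1 / slope, NA_real_)
  t2[usable & slope >= 0] <- 2000
  t2[!usable] <- 70
  s0[!usable & s0 <= 0] <- 0
  list(s0 = s0, t2 = t2)
}

#' Gauss-Newton refinement of the single-component fit
#'
#' Minimises the original-space sum of squared residuals of the
#' mono-exponential model by iterating the normal-equations update with
#' Jacobian columns `dS/dS0 = exp(-TE/T2)` and
#' `dS/dT2 = S0 * (TE/T2^2) * exp(-TE/T2)`. Iteration stops when the sum of
#' squared residuals changes by less than `tol` or after `maxIter`
#' iterations. Signals are internally normalised by `scale` (by default the
#' magnitude of the first-echo signal) so the absolute tolerance has a
#' consistent meaning across intensity scales; reported amplitudes and
#' residual norms are in the original units.
#'
#' Steps that would increase the residual or drive T2 non-positive are
#' backtracked by successive halving (up to 20 halvings, counted as one
#' iteration), so the residual norm is non-increasing across accepted
#' steps. A nearly singular normal matrix (condition number above 1e12)
#' receives Levenberg damping `1e-10 * trace`.
#'
#' @param curve an [EchoSeries-class].
#' @param init optional list with `s0` and `t2` starting values; defaults
#'   to [linearInit()] of the curve.
#' @param maxIter maximum number of iterations (default 500).
#' @param tol absolute tolerance on the change of the normalised sum of
#'   squared residuals (default 1e-6).
#' @param scale normalisation of the signal axis; default
#'   `abs(signals[1])` (1 if that vanishes).
#' @return a [MonoFit-class].
#' @examples
#' te <- defaultEchoTimes()
#' gaussNewtonFit(echoSeries(te, predictMono(200, 80, te)))
#' @export
gaussNewtonFit <- function(curve, init = NULL, maxIter = 500L,
                           tol = 1e-6, scale = NULL) {
  stopifnot(is(curve, "EchoSeries"), maxIter >= 1L, tol > 0)
  if (is.null(init)) init <- linearInit(curve)
  if (is.null(scale)) {
    scale <- abs(curve@signals[[1L]])
    if (scale <= 0) scale <- max(abs(curve@signals), 1)
  }
  fit <- .gnEngine(
    S = matrix(curve@signals, nrow = 1L), te = curve@echoTimes,
    initS0 = init$s0, initT2 = init$t2,
    maxIter = as.integer(maxIter), tol = tol, scale = scale
  )
  new("MonoFit",
    s0 = fit$s0[[1L]], t2 = fit$t2[[1L]],
    residualNorm = fit$sse[[1L]], nIterations = fit$iter[[1L]],
    converged = fit$converged[[1L]],
    initS0 = as.numeric(init$s0), initT2 = as.numeric(init$t2)
  )
}

# Vectorised Gauss-Newton engine shared by gaussNewtonFit() and
# fitMonoVolume(). S: n_vox x n_echo (original units). Works on
# S / scale internally; returns s0 and sse rescaled to original units.
.gnEngine <- function(S, te, initS0, initT2, maxIter, tol, scale) {
  n <- nrow(S)
  m <- length(te)
  Sn <- S / scale
  s0 <- as.numeric(initS0) / scale
  t2 <- pmax(as.numeric(initT2), .Machine$double.eps)
  E <- exp(-outer(1 / t2, te))
  sse <- rowSums((Sn - s0 * E)^2)
  iter <- integer(n)
  conv <- logical(n)
  active <- rep(TRUE, n)
  for (k in seq_len(maxIter)) {
    idx <- which(active)
    if (!length(idx)) break
    na <- length(idx)
    teM <- matrix(te, na, m, byrow = TRUE)
    Ei <- exp(-teM / t2[idx])
    d2 <- (s0[idx] / t2[idx]^2) * Ei * teM
    resi <- Sn[idx, , drop = FALSE] - s0[idx] * Ei
    a11 <- rowSums(Ei * Ei)
    a12 <- rowSums(Ei * d2)
    a22 <- rowSums(d2 * d2)
    b1 <- rowSums(Ei * resi)
    b2 <- rowSums(d2 * resi)
    # 2x2 condition via closed-form eigenvalues; damp when ill-conditioned
    tr <- a11 + a22
    dt <- a11 * a22 - a12 * a12
    disc <- sqrt(pmax(tr * tr - 4 * dt, 0))
    emin <- (tr - disc) / 2
    illc <- !(emin > 0) | ((tr + disc) / 2) > 1e12 * pmax(emin, 0)
    lam <- ifelse(illc, 1e-10 * tr, 0)
    dt2 <- (a11 + lam) * (a22 + lam) - a12 * a12
    dt2[dt2 == 0] <- .Machine$double.xmin
    stepS0 <- ((a22 + lam) * b1 - a12 * b2) / dt2
    stepT2 <- ((a11 + lam) * b2 - a12 * b1) / dt2
    # backtracking halving: accept the first step fraction that keeps
    # t2 positive and does not increase the SSE
    lamf <- rep(1, na)
    pend <- rep(TRUE, na)
    newS0 <- s0[idx]
    newT2 <- t2[idx]
    newSse <- sse[idx]
    for (h in 0:20) {
      p <- which(pend)
      if (!length(p)) break
      cs0 <- s0[idx][p] + lamf[p] * stepS0[p]
      ct2 <- t2[idx][p] + lamf[p] * stepT2[p]
      cE <- exp(-matrix(te, length(p), m, byrow = TRUE) /
        pmax(ct2, .Machine$double.xmin))
      csse <- rowSums((Sn[idx[p], , drop = FALSE] - cs0 * cE)^2)
      ok <- ct2 > 0 & csse <= sse[idx][p]
      acc <- p[ok]
      newS0[acc] <- cs0[ok]
      newT2[acc] <- ct2[ok]
      newSse[acc] <- csse[ok]
      pend[acc] <- FALSE
      lamf[p[!ok]] <- lamf[p[!ok]] / 2
    }
    dsse <- sse[idx] - newSse  # >= 0 by construction
    s0[idx] <- newS0
    t2[idx] <- newT2
    sse[idx] <- newSse
    iter[idx] <- k
    done <- dsse < tol
    conv[idx[done]] <- TRUE
    active[idx[done]] <- FALSE
  }
  list(
    s0 = s0 * scale, t2 = t2, sse = sse * scale^2,
    iter = iter, converged = conv
  )
}

#' Voxelwise single-component T2 mapping
#'
#' Applies [linearInit()] + [gaussNewtonFit()] to every voxel of a 4D
#' multi-echo image inside a mask, producing T2, S0 and convergence maps.
#' All masked voxels share one signal normalisation (the mean magnitude of
#' the first-echo signal over the mask) so the convergence tolerance is
#' comparable across the volume. Unmasked voxels carry `NA`.
#'
#' @param image 4D numeric array (x, y, z, echo); the 4th dimension must
#'   match `length(echoTimes)`. A `niftiImage` works as-is.
#' @param echoTimes numeric vector of echo times in ms.
#' @param mask 3D logical/0-1 array on the same grid; default all voxels.
#' @param maxIter,tol as in [gaussNewtonFit()].
#' @return list with 3D arrays `t2`, `s0`, `converged`, `nIterations`
#'   (NA outside the mask) and the scalar `scale` used for normalisation.
#' @examples
#' te <- defaultEchoTimes()
#' img <- array(rep(predictMono(100, 70, te), each = 8), c(2, 2, 2, 10))
#' fitMonoVolume(img, te)$t2[1, 1, 1]
#' @export
fitMonoVolume <- function(image, echoTimes, mask = NULL,
                          maxIter = 500L, tol = 1e-6) {
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
  t2map <- s0map <- itmap <- array(NA_real_, vol)
  cvmap <- array(NA, vol)
  idx <- which(mask)
  if (!length(idx)) {
    warning("empty mask: returning all-NA maps")
    return(list(t2 = t2map, s0 = s0map, converged = cvmap,
      nIterations = itmap, scale = 1))
  }
  S <- matrix(image, prod(vol), d[[4L]])[idx, , drop = FALSE]
  scale <- mean(abs(S[, 1L]))
  if (scale <= 0) scale <- max(abs(S), 1)
  init <- .linearInitMatrix(S, echoTimes)
  fit <- .gnEngine(S, echoTimes, init$s0, init$t2,
    as.integer(maxIter), tol, scale)
  t2map[idx] <- fit$t2
  s0map[idx] <- fit$s0
  cvmap[idx] <- fit$converged
  itmap[idx] <- fit$iter
  list(t2 = t2map, s0 = s0map, converged = cvmap, nIterations = itmap,
    scale = scale)
}

.as4d <- function(image) {
  image <- unclass(image)
  attributes(image) <- list(dim = dim(image))
  if (length(dim(image)) != 4L) stop("image must be a 4D array")
  storage.mode(image) <- "double"
  image
}

.asMask <- function(mask, vol) {
  mask <- unclass(mask)
  attributes(mask) <- list(dim = dim(mask))
  if (!identical(dim(mask)[1:3], as.integer(vol))) {
    stop("mask grid does not match the image grid")
  }
  array(as.logical(mask) & !is.na(mask), vol)
}
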