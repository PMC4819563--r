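#' Echo times of the reference multi-echo acquisition
#'
#' The ten echo times (ms) of the multi-echo T2-weighted protocol the
#' package defaults to: 13, 16, 20, 25, 30, 40, 50, 85, 100 and 150 ms.
#'
#' @return numeric vector of ten echo times in ms.
#' @examples
#' defaultEchoTimes()
#' @export
defaultEchoTimes <- function() {
  c(13, 16, 20, 25, 30, 40, 50, 85, 100, 150)
}

#' Construct an EchoSeries
#'
#' @param echoTimes numeric, strictly increasing positive echo times (ms).
#' @param signals numeric, signal intensities, same length.
#' @return an [EchoSeries-class].
#' @examples
#' echoSeries(defaultEchoTimes(), predictMono(100, 70, defaultEchoTimes()))
#' @export
echoSeries <- function(echoTimes, signals) {
  new("EchoSeries", echoTimes = as.numeric(echoTimes),
    signals = as.numeric(signals))
}

#' Construct a compartment basis
#'
#' Fixed T2 constants of the multi-compartment decay model. The default is
#' the literature three-compartment basis of 20 ms (myelin water), 80 ms
#' (intra/extra-cellular tissue water) and 2000 ms (free water / CSF); the
#' myelin water fraction is the signal fraction at the shortest basis T2.
#'
#' @param t2Values numeric, strictly increasing positive T2 constants (ms).
#' @param names character labels, one per compartment; defaults to
#'   myelin/tissue/free for the default basis and `t2_<value>ms` otherwise.
#' @return a [CompartmentBasis-class].
#' @examples
#' compartmentBasis()
#' compartmentBasis(c(20, 80))
#' @export
compartmentBasis <- function(t2Values = c(20, 80, 2000), names = NULL) {
  t2Values <- as.numeric(t2Values)
  if (is.null(names)) {
    names <- if (identical(t2Values, c(20, 80, 2000))) {
      c("myelin", "tissue", "free")
    } else {
      sprintf("t2_%gms", t2Values)
    }
  }
  new("CompartmentBasis", t2Values = t2Values,
    compartmentNames = as.character(names))
}

#' Validate a compartment fraction vector
#'
#' Checks the simplex constraints of a fraction vector: all entries
#' non-negative and summing to one (within `tol`).
#'
#' @param v numeric vector of compartment fractions.
#' @param tol tolerance on the sum-to-one constraint.
#' @return `v` invisibly, after validation.
#' @examples
#' fractionVector(c(0.25, 0.70, 0.05))
#' @export
fractionVector <- function(v, tol = 1e-9) {
  v <- as.numeric(v)
  if (length(v) < 1L || anyNA(v)) {
    stop("fractions must be a non-empty numeric vector without NA")
  }
  if (any(v < 0)) stop("all fractions must be >= 0")
  if (abs(sum(v) - 1) > tol) stop("fractions must sum to 1")
  invisible(v)
}

#' Mono-exponential decay model
#'
#' Forward model of single-component T2 decay:
#' `S(TE) = s0 * exp(-TE / t2)`.
#'
#' @param s0 amplitude at TE = 0 (>= 0, arbitrary units).
#' @param t2 T2 relaxation constant in ms (> 0).
#' @param echoTimes numeric vector of echo times in ms.
#' @return numeric vector of predicted signal intensities, one per echo.
#' @examples
#' predictMono(1, 80, 80)   # exp(-1)
#' @export
predictMono <- function(s0, t2, echoTimes) {
  stopifnot(length(s0) == 1L, length(t2) == 1L, s0 >= 0)
  if (is.na(t2) || t2 <= 0) stop("t2 must be positive")
  echoTimes <- as.numeric(echoTimes)
  if (anyNA(echoTimes) || any(echoTimes < 0)) {
    stop("echo times must be non-negative")
  }
  s0 * exp(-echoTimes / t2)
}

#' Multi-compartment decay model
#'
#' Forward model of multi-compartment T2 decay: a voxel's signal is a
#' non-negative mixture of exponentials on a fixed T2 basis,
#' `S(TE) = s0 * sum_i v_i * exp(-TE / T2_i)`, with fractions `v_i >= 0`
#' summing to one, so that `S(0) = s0`.
#'
#' @param s0 total amplitude at TE = 0 (>= 0).
#' @param fractions simplex vector of compartment fractions, one per basis
#'   compartment (validated with [fractionVector()]).
#' @param basis a [CompartmentBasis-class].
#' @param echoTimes numeric vector of echo times in ms.
#' @return numeric vector of predicted signal intensities, one per echo.
#' @examples
#' predictMulti(1000, c(0.25, 0.70, 0.05), compartmentBasis(),
#'              defaultEchoTimes())
#' @export
predictMulti <- function(s0, fractions, basis = compartmentBasis(),
                         echoTimes = defaultEchoTimes()) {
  stopifnot(is(basis, "CompartmentBasis"), length(s0) == 1L, s0 >= 0)
  v <- fractionVector(fractions)
  if (length(v) != length(basis@t2Values)) {
    stop("fractions must have one entry per basis compartment")
  }
  echoTimes <- as.numeric(echoTimes)
  if (anyNA(echoTimes) || any(echoTimes < 0)) {
    stop("echo times must be non-negative")
  }
  E <- exp(-outer(echoTimes, 1 / basis@t2Values))  # n_echo x n_comp
  as.numeric(s0 * (E %*% v))
}

# Design matrix of the multi-compartment model: A[j, i] = exp(-TE_j / T2_i).
decayDesignMatrix <- function(basis, echoTimes) {
  exp(-outer(as.numeric(echoTimes), 1 / basis@t2Values))
}
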