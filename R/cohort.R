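#' Build a synthetic cohort specification
#'
#' Reads stratum-level ground-truth parameters (group x sex stratum sizes,
#' tissue volume means/SDs in liters, white matter composition parameters
#' and effective-T2 targets, gray matter composition, first-echo SNR,
#' echo times, voxel dimensions, grid shape) from a YAML config. The
#' packaged default reproduces the summary statistics of an adolescent
#' extremely-preterm cohort with term-born controls; see the config file
#' for per-value notes.
#'
#' @param config path to a YAML config; default the packaged
#'   `cohort-defaults.yaml`.
#' @param seed overrides the config seed when not NULL.
#' @param gridShape overrides the config grid shape when not NULL.
#' @param snr overrides the config first-echo SNR when not NULL.
#' @return a [CohortSpec-class].
#' @examples
#' cohortSpec()
#' @export
cohortSpec <- function(config = NULL, seed = NULL, gridShape = NULL,
                       snr = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "cohort-defaults.yaml",
      package = "t2relax", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(config)
  strata <- do.call(rbind, lapply(cfg$strata, function(s) {
    as.data.frame(s, stringsAsFactors = FALSE)
  }))
  names(strata)[names(strata) == "n_subjects"] <- "n"
  strata$n <- as.integer(strata$n)
  vs <- cfg$voxel_scale
  vs <- if (is.null(vs) || identical(vs, "auto")) NA_real_ else
    as.numeric(vs)
  new("CohortSpec",
    strata = strata,
    echoTimes = as.numeric(cfg$echo_times_ms),
    basis = compartmentBasis(as.numeric(cfg$basis_t2_ms)),
    voxelDims = as.numeric(cfg$voxel_dims_mm),
    gridShape = as.integer(gridShape %||% cfg$grid_shape),
    voxelScale = vs,
    snr = as.numeric(snr %||% cfg$snr_first_echo),
    s0 = as.numeric(cfg$s0),
    seed = as.integer(seed %||% cfg$seed)
  )
}

# Inverse-CDF truncated normal draws on [lo, hi]. When the window holds
# almost no normal mass (CDF saturation in a far tail), the truncated
# distribution is concentrated at the boundary nearest the mean.
.rtruncnorm <- function(n, mean, sd, lo = 0, hi = Inf) {
  if (all(sd <= 0)) return(rep(pmin(pmax(mean, lo), hi), length.out = n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  x <- pmin(pmax(stats::qnorm(u, mean, sd), lo), hi)
  sat <- (phi - plo) < 1e-12
  if (any(sat)) {
    x[sat] <- ifelse(rep(mean, length.out = n)[sat] < lo, lo, hi)
  }
  x
}

# Quantile-midpoint grid of a truncated normal (deterministic quadrature).
.qtruncnorm <- function(p, mean, sd, lo = 0, hi = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), length(p)))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if ((phi - plo) < 1e-12) {
    return(rep(if (mean < lo) lo else hi, length(p)))
  }
  pmin(pmax(stats::qnorm(plo + p * (phi - plo), mean, sd), lo), hi)
}

# Effective single-component T2 of noiseless three-compartment mixtures:
# full Gauss-Newton fit of each mixture curve at the given echoes.
# fracs: matrix with columns (myelin, tissue, free).
.effectiveT2 <- function(fracs, basis, echoTimes, s0 = 1000) {
  A <- decayDesignMatrix(basis, echoTimes)
  S <- s0 * (fracs %*% t(A))
  init <- .linearInitMatrix(S, echoTimes)
  fit <- .gnEngine(S, echoTimes, init$s0, init$t2, 500L, 1e-9,
    scale = mean(abs(S[, 1L])))
  fit$t2
}

#' Calibrate the free-water fraction of a tissue composition
#'
#' Given a myelin water fraction mean (and the SDs of the per-subject
#' composition draws), finds the free-water fraction mean such that the
#' EXPECTED effective single-component T2 of the noiseless
#' three-compartment mixture, fitted at the given echo times, equals a
#' target value. The expectation over the truncated-normal subject draws
#' is computed by quantile-midpoint quadrature, so the calibration is
#' deterministic. Because the effective T2 at zero free water has a floor
#' (about 67 ms at MWF 0.25 for the default basis and echoes), a target
#' below the reachable range is answered with the boundary value and a
#' message.
#'
#' @param mwfMean,mwfSd mean and SD of the per-subject myelin water
#'   fraction draws.
#' @param csfSd SD of the per-subject free-water fraction draws.
#' @param targetT2 target expected effective T2 in ms.
#' @param basis a [CompartmentBasis-class] (three compartments).
#' @param echoTimes echo times in ms.
#' @param nq quadrature points per dimension.
#' @return the calibrated free-water fraction mean (possibly negative:
#'   the per-subject draws are truncated at 0, so a negative mean simply
#'   concentrates the draws near 0).
#' @export
calibrateCsfFraction <- function(mwfMean, mwfSd, csfSd, targetT2,
                                 basis = compartmentBasis(),
                                 echoTimes = defaultEchoTimes(),
                                 nq = 16L) {
  stopifnot(length(basis@t2Values) == 3L, targetT2 > 0)
  p <- (seq_len(nq) - 0.5) / nq
  mq <- .qtruncnorm(p, mwfMean, mwfSd, lo = 0.02, hi = 0.7)
  expT2 <- function(cbar) {
    cq <- .qtruncnorm(p, cbar, csfSd, lo = 0, hi = 0.5)
    g <- expand.grid(m = mq, c = cq)
    fr <- cbind(g$m, 1 - g$m - g$c, g$c)
    mean(.effectiveT2(fr, basis, echoTimes))
  }
  lo <- -0.05
  hi <- 0.4
  if (expT2(lo) >= targetT2) {
    message(sprintf(
      "target T2 %.2f ms is at/below the reachable floor (%.2f ms): %s",
      targetT2, expT2(lo), "using the boundary free-water mean"
    ))
    return(lo)
  }
  if (expT2(hi) <= targetT2) {
    message("target T2 above the reachable range: using the boundary")
    return(hi)
  }
  stats::uniroot(function(cc) expT2(cc) - targetT2, c(lo, hi),
    tol = 1e-6)$root
}

# Calibrated free-water means for every stratum. Memoised: the
# calibration is deterministic in the stratum parameters, basis and
# echo times, so repeated cohort draws reuse it.
.calibCache <- new.env(parent = emptyenv())

.calibrateStrata <- function(spec) {
  key <- paste(collapse = "|", c(
    format(unlist(spec@strata[c("wm_mwf_mean", "wm_mwf_sd",
      "wm_csf_frac_sd", "wm_t2_target", "gm_mwf_mean",
      "gm_t2_target")]), digits = 15),
    format(spec@basis@t2Values, digits = 15),
    format(spec@echoTimes, digits = 15)
  ))
  cached <- .calibCache[[key]]
  if (!is.null(cached)) return(cached)
  st <- spec@strata
  wmC <- gmC <- numeric(nrow(st))
  for (i in seq_len(nrow(st))) {
    wmC[[i]] <- calibrateCsfFraction(
      st$wm_mwf_mean[[i]], st$wm_mwf_sd[[i]], st$wm_csf_frac_sd[[i]],
      st$wm_t2_target[[i]], spec@basis, spec@echoTimes
    )
    gmC[[i]] <- calibrateCsfFraction(
      st$gm_mwf_mean[[i]], 0, 0, st$gm_t2_target[[i]],
      spec@basis, spec@echoTimes
    )
  }
  res <- list(wmCsfMean = wmC, gmCsfFrac = gmC)
  .calibCache[[key]] <- res
  res
}

#' Resolve the voxel-volume scale factor of a spec
#'
#' Returns the spec's voxel scale, or - when the spec says "auto" - the
#' smallest factor such that the largest plausible intracranial volume
#' (max stratum mean + 4 combined SDs) occupies at most 85% of the grid.
#' The emitted NIfTI pixdims are the nominal voxel dimensions times
#' `voxelScale^(1/3)`, so voxel counting on the emitted labels returns
#' true liters.
#'
#' @param spec a [CohortSpec-class].
#' @return numeric scale factor (>= 1).
#' @export
resolveVoxelScale <- function(spec) {
  if (!is.na(spec@voxelScale)) return(spec@voxelScale)
  st <- spec@strata
  icvHi <- max(
    st$wm_vol_mean + st$gm_vol_mean + st$csf_vol_mean +
      4 * sqrt(st$wm_vol_sd^2 + st$gm_vol_sd^2 + st$csf_vol_sd^2)
  )
  capacity <- prod(spec@gridShape) * prod(spec@voxelDims) / 1e6
  max(1, icvHi / (0.85 * capacity))
}

#' Draw one subject's ground truth
#'
#' Draws per-tissue volumes from truncated normals (truncated at zero) and
#' a white matter composition (myelin water fraction and free-water
#' fraction from truncated normals around the calibrated stratum means;
#' tissue water takes the remainder). Gray matter composition is the
#' calibrated stratum composition; CSF voxels are pure free water. Records
#' the implied noiseless effective single-component T2 per tissue and the
#' noise SD implied by the first-echo SNR.
#'
#' @param spec a [CohortSpec-class].
#' @param stratum integer row index into `spec@strata`.
#' @param subjectId character identifier.
#' @param seed integer seed for this subject's draws.
#' @param calib optional precomputed result of the stratum calibration
#'   (internal use; computed on the fly when NULL).
#' @return one-row data.frame of the subject's ground truth.
#' @export
sampleSubject <- function(spec, stratum, subjectId, seed,
                          calib = NULL) {
  stopifnot(is(spec, "CohortSpec"))
  st <- spec@strata[stratum, ]
  if (is.null(calib)) calib <- .calibrateStrata(spec)
  set.seed(seed)
  wmVol <- .rtruncnorm(1L, st$wm_vol_mean, st$wm_vol_sd, lo = 0)
  gmVol <- .rtruncnorm(1L, st$gm_vol_mean, st$gm_vol_sd, lo = 0)
  csfVol <- .rtruncnorm(1L, st$csf_vol_mean, st$csf_vol_sd, lo = 0)
  m <- .rtruncnorm(1L, st$wm_mwf_mean, st$wm_mwf_sd, lo = 0.02,
    hi = 0.7)
  cf <- .rtruncnorm(1L, calib$wmCsfMean[[stratum]], st$wm_csf_frac_sd,
    lo = 0, hi = 0.5)
  wmFrac <- c(m, 1 - m - cf, cf)
  gmCf <- calib$gmCsfFrac[[stratum]]
  gmFrac <- c(st$gm_mwf_mean, 1 - st$gm_mwf_mean - gmCf, gmCf)
  effT2 <- .effectiveT2(rbind(wmFrac, gmFrac), spec@basis,
    spec@echoTimes, spec@s0)
  wmFirstEcho <- predictMulti(spec@s0, wmFrac, spec@basis,
    spec@echoTimes[[1L]])
  data.frame(
    subject_id = as.character(subjectId),
    group = st$group, sex = st$sex, stratum = stratum, seed = seed,
    wm_volume_l = wmVol, gm_volume_l = gmVol, csf_volume_l = csfVol,
    wm_f_myelin = wmFrac[[1L]], wm_f_tissue = wmFrac[[2L]],
    wm_f_free = wmFrac[[3L]],
    gm_f_myelin = gmFrac[[1L]], gm_f_tissue = gmFrac[[2L]],
    gm_f_free = gmFrac[[3L]],
    wm_eff_t2_ms = effT2[[1L]], gm_eff_t2_ms = effT2[[2L]],
    noise_sd = wmFirstEcho / spec@snr,
    stringsAsFactors = FALSE
  )
}

#' Render one subject's label and multi-echo images
#'
#' Builds a schematic concentric head on the spec grid - a free-water
#' (CSF) core, surrounded by white matter, surrounded by a gray matter
#' shell - whose per-tissue voxel counts match the subject's volumes at
#' the resolved voxel scale exactly (voxels are ranked by physical
#' distance from the grid centre, ties broken by linear index). Every
#' voxel of a tissue decays as the subject's three-compartment mixture;
#' i.i.d. Gaussian noise of the subject's noise SD is added to all voxels
#' (background included).
#'
#' @param truth one-row data.frame from [sampleSubject()].
#' @param spec a [CohortSpec-class].
#' @param noise logical; set FALSE for a noiseless render.
#' @return list with `labels` (3D integer array), `image` (4D array),
#'   `pixdim` (emitted voxel dimensions in mm), `counts` (named voxel
#'   counts) and `volumes` (realized liters, i.e. counts x voxel volume).
#' @export
renderSubject <- function(truth, spec, noise = TRUE) {
  stopifnot(is(spec, "CohortSpec"), nrow(truth) == 1L)
  k <- resolveVoxelScale(spec)
  pixdim <- spec@voxelDims * k^(1 / 3)
  voxL <- prod(pixdim) / 1e6
  counts <- round(c(
    csf = truth$csf_volume_l, wm = truth$wm_volume_l,
    gm = truth$gm_volume_l
  ) / voxL)
  g <- spec@gridShape
  if (sum(counts) > prod(g)) {
    stop(sprintf(
      "head (%d voxels) exceeds the grid (%d voxels); %s",
      sum(counts), prod(g),
      sprintf("need a grid of at least %d voxels at this voxel scale",
        sum(counts))
    ))
  }
  ctr <- (g + 1) / 2
  ii <- (slice.index(array(0, g), 1L) - ctr[[1L]]) * pixdim[[1L]]
  jj <- (slice.index(array(0, g), 2L) - ctr[[2L]]) * pixdim[[2L]]
  kk <- (slice.index(array(0, g), 3L) - ctr[[3L]]) * pixdim[[3L]]
  d2 <- as.vector(ii^2 + jj^2 + kk^2)
  ord <- order(d2)  # stable: ties broken by linear index
  labels <- integer(prod(g))
  codes <- tissueCodes()
  take <- function(n, from) ord[seq.int(from, length.out = n)]
  labels[take(counts[["csf"]], 1L)] <- codes[["csf"]]
  labels[take(counts[["wm"]], counts[["csf"]] + 1L)] <- codes[["wm"]]
  labels[take(counts[["gm"]], counts[["csf"]] + counts[["wm"]] + 1L)] <-
    codes[["gm"]]
  labels <- array(labels, g)
  te <- spec@echoTimes
  img <- array(0, c(g, length(te)))
  fracs <- list(
    csf = c(0, 0, 1),
    gm = as.numeric(truth[1L, c("gm_f_myelin", "gm_f_tissue",
      "gm_f_free")]),
    wm = as.numeric(truth[1L, c("wm_f_myelin", "wm_f_tissue",
      "wm_f_free")])
  )
  nvox <- prod(g)
  for (tis in names(fracs)) {
    idx <- which(labels == codes[[tis]])
    if (!length(idx)) next
    sig <- predictMulti(spec@s0, fracs[[tis]], spec@basis, te)
    for (e in seq_along(te)) {
      img[idx + (e - 1L) * nvox] <- sig[[e]]
    }
  }
  if (noise) {
    img <- img + stats::rnorm(length(img), 0, truth$noise_sd)
  }
  list(
    labels = labels, image = img, pixdim = pixdim, counts = counts,
    volumes = c(counts * voxL, icv = sum(counts) * voxL)
  )
}

#' Generate a full synthetic cohort on disk
#'
#' Iterates [sampleSubject()] and [renderSubject()] over every stratum of
#' the spec with per-subject seeds derived from the spec seed, writing one
#' co-registered NIfTI pair per subject (`<id>_labels.nii.gz`,
#' `<id>_echoes.nii.gz`), a `truth.csv` ground-truth ledger (with realized
#' voxel counts and volumes) and a `manifest.json`. The same spec and seed
#' reproduce the cohort byte for byte.
#'
#' @param spec a [CohortSpec-class].
#' @param outDir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return invisibly, the manifest list (with `truth` as a data.frame).
#' @export
generateCohort <- function(spec, outDir, force = FALSE) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  if (dir.exists(outDir) && length(dir(outDir)) && !force) {
    stop("output directory exists and is not empty; use force = TRUE")
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  calib <- .calibrateStrata(spec)
  nTotal <- sum(spec@strata$n)
  set.seed(spec@seed)
  subjectSeeds <- sample.int(.Machine$integer.max - 1L, nTotal)
  rows <- list()
  files <- list()
  sidx <- 0L
  for (i in seq_len(nrow(spec@strata))) {
    st <- spec@strata[i, ]
    for (j in seq_len(st$n)) {
      sidx <- sidx + 1L
      id <- sprintf("sub-%03d", sidx)
      truth <- sampleSubject(spec, i, id, subjectSeeds[[sidx]], calib)
      rend <- renderSubject(truth, spec)
      truth$csf_volume_l <- rend$volumes[["csf"]]
      truth$wm_volume_l <- rend$volumes[["wm"]]
      truth$gm_volume_l <- rend$volumes[["gm"]]
      truth$n_csf_vox <- rend$counts[["csf"]]
      truth$n_wm_vox <- rend$counts[["wm"]]
      truth$n_gm_vox <- rend$counts[["gm"]]
      labPath <- file.path(outDir, paste0(id, "_labels.nii.gz"))
      echoPath <- file.path(outDir, paste0(id, "_echoes.nii.gz"))
      writeNiftiVolume(rend$labels, rend$pixdim, labPath)
      writeNiftiVolume(rend$image, rend$pixdim, echoPath)
      rows[[sidx]] <- truth
      files[[sidx]] <- list(subject_id = id, labels = basename(labPath),
        echoes = basename(echoPath))
    }
  }
  truth <- do.call(rbind, rows)
  utils::write.csv(truth, file.path(outDir, "truth.csv"),
    row.names = FALSE)
  manifest <- list(
    n_subjects = nTotal,
    echo_times_ms = spec@echoTimes,
    basis_t2_ms = spec@basis@t2Values,
    pixdim_mm = spec@voxelDims * resolveVoxelScale(spec)^(1 / 3),
    voxel_scale = resolveVoxelScale(spec),
    grid_shape = spec@gridShape,
    snr_first_echo = spec@snr,
    seed = spec@seed,
    subjects = files
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$truth <- truth
  invisible(manifest)
}

#' Draw a truth-level cohort table (no image rendering)
#'
#' Draws every subject's ground truth from the spec's distributional layer
#' and returns it in the cohort-table schema (volumes, noiseless effective
#' white matter T2, myelin water fraction). Useful for statistical
#' calibration studies where rendering and refitting images would only add
#' runtime: the group-level statistics operate on exactly this schema.
#'
#' @param spec a [CohortSpec-class].
#' @param seed integer seed.
#' @return cohort data.frame with one row per subject.
#' @export
drawTruthTable <- function(spec, seed = spec@seed) {
  calib <- .calibrateStrata(spec)
  nTotal <- sum(spec@strata$n)
  set.seed(seed)
  subjectSeeds <- sample.int(.Machine$integer.max - 1L, nTotal)
  rows <- list()
  sidx <- 0L
  for (i in seq_len(nrow(spec@strata))) {
    for (j in seq_len(spec@strata$n[[i]])) {
      sidx <- sidx + 1L
      rows[[sidx]] <- sampleSubject(spec, i, sprintf("sub-%03d", sidx),
        subjectSeeds[[sidx]], calib)
    }
  }
  tab <- do.call(rbind, rows)
  tab$wm_t2_ms <- tab$wm_eff_t2_ms
  tab$wm_mwf <- tab$wm_f_myelin
  tab$icv_l <- tab$wm_volume_l + tab$gm_volume_l + tab$csf_volume_l
  tab
}

#' Build a cohort with a purely volume-mediated T2 group difference
#'
#' Constructs a cohort table in which white matter T2 is a linear function
#' of white matter volume (plus independent noise) with IDENTICAL
#' conditional distribution in both groups, while the groups differ in
#' volume. Any unadjusted group difference in T2 is then entirely mediated
#' by volume: the two-sample t-test on T2 rejects, while the
#' volume-adjusted comparison does not.
#'
#' @param nPerGroup subjects per group.
#' @param seed integer seed.
#' @param volMeans named numeric, mean WM volume per group (liters).
#' @param volSd SD of WM volume within group.
#' @param slope T2 change per liter (ms/l).
#' @param intercept T2 at zero volume (ms).
#' @param residSd SD of the T2 residual around the linear relation (ms).
#' @return cohort data.frame with `wm_t2_ms` and `wm_volume_l`.
#' @export
volumeMediatedCohort <- function(nPerGroup = 25L, seed = 1L,
                                 volMeans = c(preterm = 0.35,
                                   term = 0.42),
                                 volSd = 0.03, slope = -30,
                                 intercept = 80, residSd = 0.6) {
  set.seed(seed)
  n <- 2L * nPerGroup
  group <- rep(c("preterm", "term"), each = nPerGroup)
  vol <- .rtruncnorm(n, volMeans[group], volSd, lo = 0.05)
  t2v <- intercept + slope * vol + stats::rnorm(n, 0, residSd)
  data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = group,
    sex = rep(rep(c("male", "female"), length.out = nPerGroup), 2L),
    wm_volume_l = vol, wm_t2_ms = t2v,
    stringsAsFactors = FALSE
  )
}
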