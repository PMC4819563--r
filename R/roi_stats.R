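#' Tissue label codes
#'
#' The 3-class label convention used throughout the package:
#' 0 background, 1 CSF, 2 gray matter, 3 white matter.
#'
#' @return named integer vector of label codes.
#' @examples
#' tissueCodes()["wm"]
#' @export
tissueCodes <- function() {
  c(background = 0L, csf = 1L, gm = 2L, wm = 3L)
}

.checkLabels <- function(labels) {
  labels <- unclass(labels)
  attributes(labels) <- list(dim = dim(labels))
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  bad <- setdiff(unique(as.vector(labels)), tissueCodes())
  if (length(bad)) {
    stop("unknown label codes: ", paste(bad, collapse = ", "))
  }
  labels
}

#' Tissue volumes from a label image
#'
#' Volume of each tissue class in liters: voxel count times voxel volume
#' (`dx * dy * dz` in mm^3; 1 l = 1e6 mm^3). Intracranial volume is the sum
#' of the three segmented classes (CSF + GM + WM), which in this 3-class
#' setting is an identity.
#'
#' @param labels 3D integer array with codes 0 (background), 1 (CSF),
#'   2 (GM), 3 (WM).
#' @param voxelDims numeric length 3, voxel dimensions in mm.
#' @return named numeric vector `csf`, `gm`, `wm`, `icv` in liters.
#' @examples
#' lab <- array(3L, c(10, 10, 10))
#' tissueVolumes(lab, c(2.5, 2.5, 3.0))["wm"]
#' @export
tissueVolumes <- function(labels, voxelDims) {
  labels <- .checkLabels(labels)
  stopifnot(length(voxelDims) == 3L, all(voxelDims > 0))
  voxL <- prod(voxelDims) / 1e6
  counts <- vapply(
    tissueCodes()[c("csf", "gm", "wm")],
    function(code) sum(labels == code), numeric(1)
  )
  vols <- counts * voxL
  c(vols, icv = sum(vols))
}

#' ROI-averaged decay curve
#'
#' Arithmetic mean, echo by echo, of the multi-echo signal over the voxels
#' of one tissue class. Voxels with a missing value at any echo are
#' skipped. This is the group/subject-average white matter signal used as
#' input for the posterior analysis of compartment fractions.
#'
#' @param image 4D numeric array (x, y, z, echo).
#' @param echoTimes numeric vector of echo times in ms.
#' @param labels 3D label array (see [tissueCodes()]).
#' @param tissue tissue name (`"csf"`, `"gm"`, `"wm"`) or integer code.
#' @return an [EchoSeries-class] of the ROI mean signal.
#' @export
roiMeanCurve <- function(image, echoTimes, labels, tissue = "wm") {
  image <- .as4d(image)
  labels <- .checkLabels(labels)
  if (!identical(dim(image)[1:3], dim(labels))) {
    stop("image and labels are on different grids")
  }
  if (dim(image)[[4L]] != length(echoTimes)) {
    stop("4th image dimension must equal the number of echo times")
  }
  code <- .tissueCode(tissue)
  idx <- which(labels == code)
  if (!length(idx)) stop("empty ROI: no voxels with code ", code)
  S <- matrix(image, prod(dim(labels)), dim(image)[[4L]])[idx, ,
    drop = FALSE]
  keep <- !apply(is.na(S), 1L, any)
  if (!any(keep)) stop("ROI contains only missing-valued voxels")
  echoSeries(echoTimes, colMeans(S[keep, , drop = FALSE]))
}

.tissueCode <- function(tissue) {
  codes <- tissueCodes()
  if (is.character(tissue)) {
    if (!tissue %in% names(codes)) {
      stop("unknown tissue name: ", tissue)
    }
    return(codes[[tissue]])
  }
  tissue <- as.integer(tissue)
  if (!tissue %in% codes) stop("unknown tissue code: ", tissue)
  tissue
}

#' ROI summary of a parameter map
#'
#' Mean, sample standard deviation (n - 1 denominator) and count of valid
#' voxels of a scalar map (e.g. a T2 or MWF map) over one tissue class.
#' Missing values - unmasked or degenerate voxels flagged by the fitters -
#' are skipped and reported via `nValid`.
#'
#' @param map 3D numeric array.
#' @param labels 3D label array (see [tissueCodes()]).
#' @param tissue tissue name or integer code.
#' @return list with `mean`, `sd`, `nValid` (and `nSkipped`).
#' @export
roiMapSummary <- function(map, labels, tissue = "wm") {
  map <- unclass(map)
  attributes(map) <- list(dim = dim(map))
  labels <- .checkLabels(labels)
  if (!identical(dim(map), dim(labels))) {
    stop("map and labels are on different grids")
  }
  code <- .tissueCode(tissue)
  vals <- map[labels == code]
  if (!length(vals)) stop("empty ROI: no voxels with code ", code)
  ok <- !is.na(vals)
  n <- sum(ok)
  if (n == 0L) {
    return(list(mean = NA_real_, sd = NA_real_, nValid = 0L,
      nSkipped = length(vals)))
  }
  list(
    mean = mean(vals[ok]),
    sd = if (n > 1L) stats::sd(vals[ok]) else 0,
    nValid = n,
    nSkipped = length(vals) - n
  )
}

#' Nearest-neighbour label resampling
#'
#' Transfers a label image onto a target grid by nearest-neighbour lookup
#' given both affines (voxel index -> world mm). No interpolation is
#' performed, so no label code absent from the source can appear in the
#' output; voxels mapping outside the source grid become background.
#'
#' @param labels 3D label array on the source grid.
#' @param sourceAffine,targetAffine 4x4 voxel-to-world matrices (0-based
#'   voxel indices).
#' @param targetDim integer length 3, target grid dimensions.
#' @return 3D label array on the target grid.
#' @export
resampleLabelsNN <- function(labels, sourceAffine, targetAffine,
                             targetDim) {
  labels <- .checkLabels(labels)
  targetDim <- as.integer(targetDim)
  stopifnot(length(targetDim) == 3L, all(targetDim >= 1L))
  g <- as.matrix(expand.grid(
    i = seq_len(targetDim[1L]) - 1L,
    j = seq_len(targetDim[2L]) - 1L,
    k = seq_len(targetDim[3L]) - 1L
  ))
  world <- cbind(g, 1) %*% t(targetAffine)
  src <- world %*% t(solve(sourceAffine))
  ijk <- round(src[, 1:3])
  d <- dim(labels)
  inside <- ijk[, 1L] >= 0 & ijk[, 1L] < d[1L] &
    ijk[, 2L] >= 0 & ijk[, 2L] < d[2L] &
    ijk[, 3L] >= 0 & ijk[, 3L] < d[3L]
  out <- integer(nrow(ijk))
  lin <- 1L + ijk[inside, 1L] + d[1L] * (ijk[inside, 2L] +
    d[2L] * ijk[inside, 3L])
  out[inside] <- labels[lin]
  array(out, targetDim)
}

#' Per-subject summary row
#'
#' Collects one subject's tissue volumes, ROI T2 means, and white matter
#' MWF / tissue-fraction means into the one-row data.frame format the
#' cohort table is built from.
#'
#' @param subjectId character subject identifier.
#' @param group `"preterm"` or `"term"`.
#' @param sex `"male"` or `"female"`.
#' @param labels 3D label array.
#' @param voxelDims numeric length 3, voxel dimensions in mm.
#' @param t2Map 3D T2 map (ms) from [fitMonoVolume()].
#' @param mwfMap 3D MWF map from [fitMultiVolume()].
#' @param tissueFractionMap optional 3D map of the mid-T2 (tissue water)
#'   fraction.
#' @return one-row data.frame (see [cohortReport()] for the column schema).
#' @export
subjectSummary <- function(subjectId, group, sex, labels, voxelDims,
                           t2Map, mwfMap, tissueFractionMap = NULL) {
  vols <- tissueVolumes(labels, voxelDims)
  row <- data.frame(
    subject_id = as.character(subjectId),
    group = match.arg(group, c("preterm", "term")),
    sex = match.arg(sex, c("male", "female")),
    csf_volume_l = vols[["csf"]],
    gm_volume_l = vols[["gm"]],
    wm_volume_l = vols[["wm"]],
    icv_l = vols[["icv"]],
    stringsAsFactors = FALSE
  )
  for (tis in c("csf", "gm", "wm")) {
    row[[paste0(tis, "_t2_ms")]] <-
      roiMapSummary(t2Map, labels, tis)$mean
  }
  row$wm_mwf <- roiMapSummary(mwfMap, labels, "wm")$mean
  row$wm_tissue_fraction <- if (is.null(tissueFractionMap)) {
    NA_real_
  } else {
    roiMapSummary(tissueFractionMap, labels, "wm")$mean
  }
  row
}
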