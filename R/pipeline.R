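#' Assemble a pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: the cohort spec (or an
#' existing cohort directory), fit tolerances, the MCMC chain settings,
#' the adjustment covariate and the master seed. The exact configuration
#' is serialised into every run directory, and a rerun with the same
#' configuration reproduces all numeric outputs.
#'
#' @param outDir run directory to create.
#' @param spec a [CohortSpec-class]; ignored when `cohortDir` points at an
#'   existing generated cohort.
#' @param cohortDir optional path to an existing cohort (as written by
#'   [generateCohort()]); when NULL the cohort is simulated into
#'   `<outDir>/cohort`.
#' @param chain a [ChainConfig-class] for the group-average posterior
#'   stage (its seed is re-derived from `seed`).
#' @param maxIter,tol single-component fit controls.
#' @param adjustCovariate covariate for the volume-adjusted comparison.
#' @param seed master seed; all pipeline randomness derives from it.
#' @return a list of class `t2relaxRunConfig`.
#' @export
runConfig <- function(outDir, spec = cohortSpec(), cohortDir = NULL,
                      chain = chainConfig(preset = "test"),
                      maxIter = 500L, tol = 1e-6,
                      adjustCovariate = "wm_volume_l",
                      seed = spec@seed) {
  structure(
    list(
      outDir = outDir, spec = spec, cohortDir = cohortDir,
      chain = chain, maxIter = as.integer(maxIter), tol = tol,
      adjustCovariate = adjustCovariate, seed = as.integer(seed)
    ),
    class = "t2relaxRunConfig"
  )
}

#' Run the full relaxometry pipeline
#'
#' Executes simulate (unless an existing cohort directory is given), the
#' voxelwise single-component and multi-compartment fits, per-subject ROI
#' statistics, cohort-level group comparisons (including the
#' volume-adjusted contrast), and the posterior analysis of the
#' group-averaged white matter signal - writing per-stage outputs, a log,
#' the exact configuration used, and a run summary JSON into the run
#' directory. A stage failure halts the run naming the failing subject
#' and stage; partial outputs are retained.
#'
#' @param config a configuration from [runConfig()].
#' @param force overwrite an existing non-empty run directory.
#' @return invisibly, a list with the cohort table, the comparison tables,
#'   the cohort report, the per-group posterior summaries and the summary
#'   list written to `summary.json`.
#' @export
runPipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "t2relaxRunConfig"))
  out <- config$outDir
  if (dir.exists(out) && length(dir(out)) && !force) {
    stop("run directory exists and is not empty; use force = TRUE")
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(out, "run.log")
  logLine <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S "), sprintf(...), "\n",
      sep = "", file = logPath, append = TRUE)
  }
  .writeRunConfig(config, file.path(out, "config.json"))

  # stage 1: cohort ----------------------------------------------------
  if (is.null(config$cohortDir)) {
    cohortDir <- file.path(out, "cohort")
    logLine("simulate: generating cohort (seed %d)", config$seed)
    spec <- config$spec
    spec@seed <- config$seed
    manifest <- generateCohort(spec, cohortDir, force = force)
    truth <- manifest$truth
  } else {
    cohortDir <- config$cohortDir
    logLine("simulate: using existing cohort at %s", cohortDir)
    manifest <- jsonlite::read_json(
      file.path(cohortDir, "manifest.json"), simplifyVector = TRUE)
    manifest$subjects <- split(manifest$subjects,
      seq_len(nrow(manifest$subjects)))
    truth <- utils::read.csv(file.path(cohortDir, "truth.csv"),
      stringsAsFactors = FALSE)
  }
  te <- as.numeric(manifest$echo_times_ms)
  basis <- compartmentBasis(as.numeric(manifest$basis_t2_ms))

  # stage 2 + 3: voxelwise fits and per-subject ROI summaries ----------
  mapsDir <- file.path(out, "maps")
  dir.create(mapsDir, showWarnings = FALSE)
  rows <- list()
  groupWm <- list()   # pooled WM signal accumulators per group
  for (s in manifest$subjects) {
    id <- s$subject_id
    row <- tryCatch({
      lab <- readNiftiVolume(file.path(cohortDir, s$labels))
      echo <- readNiftiVolume(file.path(cohortDir, s$echoes))
      labels <- array(as.integer(round(lab$data)), dim(lab$data))
      mask <- labels > 0L
      mono <- fitMonoVolume(echo$data, te, mask,
        maxIter = config$maxIter, tol = config$tol)
      multi <- fitMultiVolume(echo$data, te, mask, basis = basis)
      writeNiftiVolume(mono$t2, lab$pixdim,
        file.path(mapsDir, paste0(id, "_t2.nii.gz")))
      writeNiftiVolume(mono$s0, lab$pixdim,
        file.path(mapsDir, paste0(id, "_s0.nii.gz")))
      writeNiftiVolume(multi$mwf, lab$pixdim,
        file.path(mapsDir, paste0(id, "_mwf.nii.gz")))
      writeNiftiVolume(multi$fractions, lab$pixdim,
        file.path(mapsDir, paste0(id, "_fractions.nii.gz")))
      tisMap <- multi$fractions[, , , 2L]
      info <- truth[truth$subject_id == id, ]
      wmCurve <- roiMeanCurve(echo$data, te, labels, "wm")
      nWm <- sum(labels == tissueCodes()[["wm"]])
      acc <- groupWm[[info$group]] %||%
        list(sum = numeric(length(te)), n = 0)
      groupWm[[info$group]] <- list(
        sum = acc$sum + wmCurve@signals * nWm, n = acc$n + nWm)
      logLine("fit: %s done (%d WM voxels, %d degenerate)",
        id, nWm, multi$nDegenerate)
      subjectSummary(id, info$group, info$sex, labels, lab$pixdim,
        mono$t2, multi$mwf, tisMap)
    }, error = function(e) {
      stop(sprintf("stage fit/roi-stats failed for subject %s: %s",
        id, conditionMessage(e)), call. = FALSE)
    })
    rows[[id]] <- row
  }
  cohortTable <- do.call(rbind, rows)
  rownames(cohortTable) <- NULL
  utils::write.csv(cohortTable, file.path(out, "cohort.csv"),
    row.names = FALSE)
  logLine("roi-stats: cohort table with %d subjects", nrow(cohortTable))

  # stage 4: group statistics ------------------------------------------
  vars <- c("wm_t2_ms", "gm_t2_ms", "wm_mwf", "wm_volume_l",
    "gm_volume_l", "csf_volume_l", "icv_l")
  comparisons <- do.call(rbind, c(
    lapply(vars, function(v) compareGroups(cohortTable, v,
      split = "prematurity")),
    lapply(vars, function(v) compareGroups(cohortTable, v,
      split = "sex"))
  ))
  adjusted <- compareAdjusted(cohortTable, "wm_t2_ms",
    covariate = config$adjustCovariate)
  comparisons <- rbind(comparisons, adjusted)
  utils::write.csv(comparisons, file.path(out, "comparisons.csv"),
    row.names = FALSE)
  report <- cohortReport(cohortTable)
  utils::write.csv(report$strata, file.path(out, "strata-summary.csv"),
    row.names = FALSE)
  logLine("group-stats: %d contrasts", nrow(comparisons))

  # stage 5: posterior analysis of group-averaged WM signal ------------
  posterior <- list()
  chainSeedOffset <- 0L
  for (grp in sort(names(groupWm))) {
    chainSeedOffset <- chainSeedOffset + 1L
    cfg <- config$chain
    cfg@seed <- as.integer((config$seed + 7919L * chainSeedOffset) %%
      .Machine$integer.max)
    curve <- echoSeries(te, groupWm[[grp]]$sum / groupWm[[grp]]$n)
    ps <- runChain(curve, basis, cfg)
    rep <- posteriorReport(ps)
    posterior[[grp]] <- rep$table
    utils::write.csv(
      cbind(data.frame(draw = seq_len(nrow(ps@samples))),
        as.data.frame(ps@samples), s0 = ps@s0Samples),
      file.path(out, sprintf("posterior-%s.csv", grp)),
      row.names = FALSE
    )
    logLine("mcmc: %s acceptance rate %.3f", grp, ps@acceptanceRate)
  }

  summaryList <- list(
    n_subjects = nrow(cohortTable),
    group_means = lapply(split(cohortTable, cohortTable$group),
      function(d) lapply(d[vars], mean)),
    wm_volume_ratios = as.list(report$wmVolumeRatios),
    wm_t2_preterm_vs_term_p =
      comparisons$p[comparisons$variable == "wm_t2_ms" &
        !comparisons$adjusted][1],
    wm_t2_adjusted_p = adjusted$p,
    posterior_myelin_mean = lapply(posterior,
      function(tb) tb$mean[[1L]]),
    seed = config$seed
  )
  jsonlite::write_json(summaryList, file.path(out, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logLine("done")
  invisible(list(
    cohortTable = cohortTable, comparisons = comparisons,
    report = report, posterior = posterior, summary = summaryList,
    outDir = out
  ))
}

.writeRunConfig <- function(config, path) {
  spec <- config$spec
  jsonlite::write_json(
    list(
      seed = config$seed, maxIter = config$maxIter, tol = config$tol,
      adjustCovariate = config$adjustCovariate,
      cohortDir = config$cohortDir,
      chain = list(
        nBurn = config$chain@nBurn, nRun = config$chain@nRun,
        nKeep = config$chain@nKeep,
        proposalConcentration = config$chain@proposalConcentration,
        noiseSd = config$chain@noiseSd, s0StepSd = config$chain@s0StepSd
      ),
      spec = list(
        echo_times_ms = spec@echoTimes,
        basis_t2_ms = spec@basis@t2Values,
        voxel_dims_mm = spec@voxelDims,
        grid_shape = spec@gridShape,
        voxel_scale = spec@voxelScale,
        snr_first_echo = spec@snr, s0 = spec@s0,
        strata = spec@strata
      )
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
}
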