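#' Two-sample group comparisons over a cohort table
#'
#' Two-sided two-sample Student's t-tests (pooled variance by default,
#' Welch behind a flag) of one cohort variable between groups defined by
#' prematurity, sex, or their four-way cross. Significance is conventionally
#' read at p < 0.05; no multiple-testing correction is applied by default
#' (a Holm adjustment over the returned set is available but is beyond the
#' analysis this mirrors).
#'
#' @param table cohort data.frame with one row per subject; must contain
#'   `subject_id`, `group` (preterm/term), `sex` (male/female) and the
#'   variable to compare.
#' @param variable name of the numeric column to compare.
#' @param split `"prematurity"`, `"sex"` or `"both"`; `"both"` crosses the
#'   two factors into four strata and tests all pairwise contrasts.
#' @param welch logical, use the Welch (unequal-variance) variant.
#' @param holm logical, apply a Holm correction across the returned
#'   contrasts (off by default).
#' @return data.frame with one row per contrast: variable, the two group
#'   labels, per-group n / mean / sd, the mean difference (`estimate`,
#'   group a minus group b), t statistic, degrees of freedom and p value.
#' @examples
#' tab <- data.frame(
#'   subject_id = as.character(1:8),
#'   group = rep(c("preterm", "term"), each = 4),
#'   sex = rep(c("male", "female"), 4),
#'   wm_t2_ms = c(70, 71, 69, 72, 66, 67, 68, 66)
#' )
#' compareGroups(tab, "wm_t2_ms", split = "prematurity")
#' @export
compareGroups <- function(table, variable,
                          split = c("prematurity", "sex", "both"),
                          welch = FALSE, holm = FALSE) {
  split <- match.arg(split)
  .checkCohortTable(table, variable)
  fac <- switch(split,
    prematurity = factor(table$group, levels = c("preterm", "term")),
    sex = factor(table$sex, levels = c("male", "female")),
    both = factor(paste(table$group, table$sex, sep = "_"))
  )
  levs <- levels(droplevels(fac))
  pairs <- utils::combn(levs, 2L, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    xa <- table[[variable]][fac == pr[[1L]]]
    xb <- table[[variable]][fac == pr[[2L]]]
    .pairwiseT(variable, pr[[1L]], xa, pr[[2L]], xb, welch)
  }))
  if (holm) out$p_adjusted <- stats::p.adjust(out$p, method = "holm")
  out
}

.pairwiseT <- function(variable, la, xa, lb, xb, welch) {
  if (length(xa) < 2L || length(xb) < 2L) {
    stop(sprintf(
      "stratum '%s' or '%s' has fewer than 2 subjects",
      la, lb
    ))
  }
  tt <- stats::t.test(xa, xb, var.equal = !welch)
  data.frame(
    variable = variable,
    group_a = la, group_b = lb,
    n_a = length(xa), n_b = length(xb),
    mean_a = mean(xa), mean_b = mean(xb),
    sd_a = stats::sd(xa), sd_b = stats::sd(xb),
    estimate = mean(xa) - mean(xb),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value,
    adjusted = FALSE, covariate = NA_character_,
    stringsAsFactors = FALSE
  )
}

.checkCohortTable <- function(table, variable = NULL) {
  need <- c("subject_id", "group", "sex")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("cohort table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(table$subject_id)) {
    stop("subject_id values must be unique")
  }
  if (!all(table$group %in% c("preterm", "term"))) {
    stop("group must be 'preterm' or 'term'")
  }
  if (!all(table$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  if (!is.null(variable)) {
    if (!variable %in% names(table)) {
      stop("no column named '", variable, "' in the cohort table")
    }
    if (!is.numeric(table[[variable]])) {
      stop("'", variable, "' must be numeric")
    }
  }
  invisible(table)
}

#' Covariate-adjusted group comparison
#'
#' Linear model `variable ~ group + covariate`; the reported t and p are
#' those of the group coefficient, i.e. the group difference remaining
#' after adjusting for the covariate. This is the analysis behind
#' "no longer significant when controlling for brain volume": a group
#' difference mediated purely by a volume difference loses significance
#' once the volume enters the model.
#'
#' @param table cohort data.frame (see [compareGroups()]).
#' @param variable name of the numeric outcome column.
#' @param groupFactor name of the grouping column (default `"group"`).
#' @param covariate name of the numeric covariate column (default
#'   `"wm_volume_l"`, the white matter volume).
#' @return one-row data.frame in the [compareGroups()] schema with
#'   `adjusted = TRUE` and the covariate recorded.
#' @export
compareAdjusted <- function(table, variable, groupFactor = "group",
                            covariate = "wm_volume_l") {
  .checkCohortTable(table, variable)
  if (!covariate %in% names(table)) {
    stop("no covariate column named '", covariate, "'")
  }
  z <- table[[covariate]]
  if (!is.numeric(z) || anyNA(z)) {
    stop("covariate must be numeric and complete")
  }
  if (stats::sd(z) == 0) {
    stop("covariate '", covariate, "' has zero variance")
  }
  fac <- factor(table[[groupFactor]])
  if (nlevels(droplevels(fac)) != 2L) {
    stop("groupFactor must define exactly two groups")
  }
  df <- data.frame(y = table[[variable]], g = fac, z = z)
  fit <- stats::lm(y ~ g + z, data = df)
  co <- summary(fit)$coefficients
  gRow <- grep("^g", rownames(co))[[1L]]
  la <- levels(fac)[[1L]]
  lb <- levels(fac)[[2L]]
  data.frame(
    variable = variable,
    group_a = la, group_b = lb,
    n_a = sum(fac == la), n_b = sum(fac == lb),
    mean_a = mean(df$y[fac == la]), mean_b = mean(df$y[fac == lb]),
    sd_a = stats::sd(df$y[fac == la]), sd_b = stats::sd(df$y[fac == lb]),
    estimate = -co[gRow, "Estimate"],  # adjusted group_a - group_b
    t = co[gRow, "t value"], df = fit$df.residual,
    p = co[gRow, "Pr(>|t|)"],
    adjusted = TRUE, covariate = covariate,
    stringsAsFactors = FALSE
  )
}

#' Publication-style cohort summary
#'
#' Per-stratum (group x sex) means and sample SDs of the cohort variables
#' (tissue volumes, ROI T2 values, white matter MWF and tissue fraction),
#' plus the within-sex preterm/term ratios of mean white matter volume.
#'
#' @param table cohort data.frame (see [compareGroups()]).
#' @param variables character vector of numeric columns to summarise;
#'   defaults to every numeric column except identifiers.
#' @return list with `strata` (per-stratum n and mean/sd per variable),
#'   `groups` (the same split by prematurity only), `sexes` (by sex only)
#'   and `wmVolumeRatios` (named numeric: female, male).
#' @export
cohortReport <- function(table, variables = NULL) {
  .checkCohortTable(table)
  if (is.null(variables)) {
    variables <- setdiff(
      names(table)[vapply(table, is.numeric, logical(1))],
      c("subject_id")
    )
  }
  if (nrow(table) < 1L) stop("empty cohort table")
  summarise <- function(fac) {
    sp <- split(table, fac, drop = TRUE)
    do.call(rbind, lapply(names(sp), function(nm) {
      d <- sp[[nm]]
      row <- data.frame(stratum = nm, n = nrow(d),
        stringsAsFactors = FALSE)
      for (v in variables) {
        x <- d[[v]]
        row[[paste0(v, "_mean")]] <- mean(x, na.rm = TRUE)
        row[[paste0(v, "_sd")]] <- if (sum(!is.na(x)) > 1L) {
          stats::sd(x, na.rm = TRUE)
        } else {
          warning("stratum with a single subject: sd reported as 0")
          0
        }
      }
      row
    }))
  }
  strata <- summarise(factor(paste(table$group, table$sex, sep = "_")))
  groups <- summarise(factor(table$group))
  sexes <- summarise(factor(table$sex))
  ratios <- c(female = NA_real_, male = NA_real_)
  if ("wm_volume_l" %in% variables) {
    for (sx in c("female", "male")) {
      pre <- table$wm_volume_l[table$group == "preterm" &
        table$sex == sx]
      ter <- table$wm_volume_l[table$group == "term" & table$sex == sx]
      if (length(pre) && length(ter)) {
        ratios[[sx]] <- mean(pre) / mean(ter)
      }
    }
  }
  rownames(strata) <- rownames(groups) <- rownames(sexes) <- NULL
  list(strata = strata, groups = groups, sexes = sexes,
    wmVolumeRatios = ratios)
}
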