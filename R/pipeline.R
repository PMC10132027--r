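## Orchestration of the full study workflow: exclusions -> nested
## cause-specific fits + mortality fit -> 10-year absolute risks -> internal
## validation (2/3-1/3 split, bootstrap optimism, subgroups) -> external
## validation with recalibration -> sensitivity variants.

#' Pipeline configuration
#'
#' @param tiers esophageal-cancer model tiers to run, in nesting order.
#' @param split training fraction for the internal split (default 2/3).
#' @param bootstrap bootstrap replicates for optimism correction (default
#'   500; 0 skips the bootstrap).
#' @param horizon prediction horizon in years (default 10).
#' @param seed integer seed driving the split and the bootstrap.
#' @param cutoffs risk cutoffs for screening performance.
#' @param sensitivity list of switches: `exclude_first_year_cases` (logical),
#'   `case_filter` (one of `"all"`, `"pathology_confirmed"`, `"escc_only"`,
#'   `"non_escc"`), `region_specific_models` (logical).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(tiers = c("age_only", "simple", "intermediate",
                                      "full"),
                            split = 2 / 3, bootstrap = 500L, horizon = 10,
                            seed = 1L,
                            cutoffs = c(0.005, 0.01, 0.02, 0.05),
                            sensitivity = list(
                              exclude_first_year_cases = FALSE,
                              case_filter = "all",
                              region_specific_models = FALSE)) {
  stopifnot(split > 0, split < 1, bootstrap >= 0, horizon > 0)
  structure(list(tiers = tiers, split = split,
                 bootstrap = as.integer(bootstrap), horizon = horizon,
                 seed = as.integer(seed), cutoffs = cutoffs,
                 sensitivity = sensitivity),
            class = "pipeline_config")
}

## Tiers whose covariates are usable in a cohort (a column that exists but is
## entirely NA counts as unavailable, as in the external cohort).
.usable_tiers <- function(cohort, tiers) {
  ok <- vapply(tiers, function(tr) {
    covs <- tier_covariates(tr)
    all(covs %in% names(cohort)) &&
      !any(vapply(covs, function(v) all(is.na(cohort[[v]])), logical(1)))
  }, logical(1))
  list(usable = tiers[ok], skipped = tiers[!ok])
}

#' Fit the nested cancer models and the mortality model
#'
#' Fits each requested tier (age-only, simple, intermediate, full) as a
#' cause-specific esophageal-cancer model plus the all-cause-mortality model,
#' and checks that the nested log-likelihood ordering holds.
#'
#' @param cohort post-exclusion cohort data.frame.
#' @param config a [pipeline_config()].
#' @return list of class `fpm_development`: `fits` (per-tier `fpm_fit`),
#'   `mortality` (`fpm_fit`), `hr_tables`, `skipped_tiers`, `loglik_nested`.
#' @export
run_development <- function(cohort, config = pipeline_config()) {
  use <- .usable_tiers(cohort, config$tiers)
  if (length(use$skipped))
    message("tier(s) skipped for missing covariates: ",
            paste(use$skipped, collapse = ", "))
  fits <- list()
  for (tr in use$usable)
    fits[[tr]] <- fit_fpm(cohort, fpm_spec(tr))
  mort <- fit_fpm(cohort, fpm_spec("mortality"))
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  nested_ok <- !is.unsorted(ll)   # nesting order follows config$tiers order
  if (!nested_ok)
    warning("nested log-likelihood ordering violated across tiers")
  structure(list(fits = fits, mortality = mort,
                 hr_tables = lapply(fits, hazard_ratios),
                 skipped_tiers = use$skipped,
                 loglik_nested = nested_ok),
            class = "fpm_development")
}

## One tier's validation block on a scored cohort.
.validate_block <- function(risks, cohort, config) {
  el <- eligible_for_discrimination(cohort, config$horizon)
  keep <- el$included
  block <- list(
    n = nrow(cohort),
    n_eligible = sum(keep),
    auc = tryCatch(auc(risks[keep], el$label[keep]),
                   error = function(e) list(error = conditionMessage(e))),
    calibration = calibration_table(risks, cohort, config$horizon),
    cutoffs = cutoff_performance(risks[keep], el$label[keep], config$cutoffs))
  block
}

.subgroup_defs <- function(cohort) {
  list(
    region_risk = as.character(cohort$region_risk),
    residence = as.character(cohort$residence),
    sex = as.character(cohort$sex),
    age_group = cut(cohort$entry_age, c(30, 55, 65, 80), right = FALSE,
                    labels = c("30-54", "55-64", "65-79"),
                    include.lowest = TRUE),
    bphs_special = ifelse(cohort$bphs_special == 1, "special", "general"))
}

.subgroup_auc <- function(risks, cohort, config) {
  el <- eligible_for_discrimination(cohort, config$horizon)
  defs <- .subgroup_defs(cohort)
  out <- list()
  for (d in names(defs)) {
    g <- defs[[d]]
    for (lev in sort(unique(stats::na.omit(as.character(g))))) {
      ix <- el$included & !is.na(g) & g == lev
      key <- paste(d, lev, sep = ":")
      out[[key]] <- if (sum(el$label[ix] == 1, na.rm = TRUE) == 0 ||
                        sum(el$label[ix] == 0, na.rm = TRUE) == 0)
        list(status = "not estimable")
      else c(list(status = "ok"), auc(risks[ix], el$label[ix]))
    }
  }
  out
}

#' Internal validation: split, subgroups, bootstrap optimism
#'
#' Splits the cohort into a training fraction and a holdout (simple random
#' split by participant under `config$seed`), fits all tiers plus the
#' mortality model on the training part, scores the holdout with 10-year
#' absolute risks, and reports per-tier AUC, decile calibration, cutoff
#' performance, added-value NRI/IDI versus the previous tier, and subgroup
#' discrimination (region risk, residence, sex, age group, basic
#' public-health-service special population). Optionally adds
#' Harrell-style bootstrap optimism correction of the AUC (fit on the
#' resample, evaluate on resample and original).
#'
#' @param cohort post-exclusion cohort data.frame.
#' @param config a [pipeline_config()].
#' @return list of class `validation_report`.
#' @export
internal_validation <- function(cohort, config = pipeline_config()) {
  set.seed(config$seed)
  n <- nrow(cohort)
  tr_ix <- sample.int(n, round(config$split * n))
  train <- cohort[tr_ix, ]; hold <- cohort[-tr_ix, ]
  dev <- run_development(train, config)
  risks <- lapply(names(dev$fits), function(tr)
    predict_risk(dev$fits[[tr]], dev$mortality, hold, config$horizon)$ar)
  names(risks) <- names(dev$fits)
  tiers <- names(dev$fits)
  blocks <- lapply(tiers, function(tr) {
    b <- .validate_block(risks[[tr]], hold, config)
    b$subgroups <- .subgroup_auc(risks[[tr]], hold, config)
    b
  })
  names(blocks) <- tiers
  el <- eligible_for_discrimination(hold, config$horizon)
  added <- list()
  if (length(tiers) > 1L) {
    keep <- el$included
    for (i in seq_along(tiers)[-1L]) {
      key <- paste(tiers[i - 1L], tiers[i], sep = "->")
      added[[key]] <- list(
        nri = continuous_nri(risks[[tiers[i - 1L]]][keep],
                             risks[[tiers[i]]][keep], el$label[keep]),
        idi = idi(risks[[tiers[i - 1L]]][keep], risks[[tiers[i]]][keep],
                  el$label[keep]))
    }
  }
  boot <- NULL
  if (config$bootstrap > 0L) {
    full_dev <- run_development(cohort, config)
    el_full <- eligible_for_discrimination(cohort, config$horizon)
    apparent <- vapply(names(full_dev$fits), function(tr) {
      r <- predict_risk(full_dev$fits[[tr]], full_dev$mortality, cohort,
                        config$horizon)$ar
      auc(r[el_full$included], el_full$label[el_full$included])$auc
    }, numeric(1))
    opt <- matrix(NA_real_, config$bootstrap, length(apparent),
                  dimnames = list(NULL, names(apparent)))
    for (b in seq_len(config$bootstrap)) {
      bx <- sample.int(n, n, replace = TRUE)
      bdev <- suppressWarnings(run_development(cohort[bx, ], config))
      el_b <- eligible_for_discrimination(cohort[bx, ], config$horizon)
      for (tr in names(bdev$fits)) {
        rb <- predict_risk(bdev$fits[[tr]], bdev$mortality, cohort[bx, ],
                           config$horizon)$ar
        ro <- predict_risk(bdev$fits[[tr]], bdev$mortality, cohort,
                           config$horizon)$ar
        opt[b, tr] <-
          auc(rb[el_b$included], el_b$label[el_b$included])$auc -
          auc(ro[el_full$included], el_full$label[el_full$included])$auc
      }
    }
    boot <- list(replicates = config$bootstrap, apparent = apparent,
                 optimism = colMeans(opt, na.rm = TRUE),
                 corrected = apparent - colMeans(opt, na.rm = TRUE))
  }
  structure(list(kind = "internal", seed = config$seed,
                 n_train = nrow(train), n_holdout = nrow(hold),
                 tiers = blocks, added_value = added, bootstrap = boot),
            class = "validation_report")
}

#' External validation with recalibration
#'
#' Scores an external cohort with the development fits (tiers whose
#' covariates the external cohort lacks are skipped with an explicit
#' reason), reports discrimination and calibration before recalibration,
#' estimates the two-parameter recalibration from 5-year age-band observed
#' vs predicted risks, and reports calibration after recalibration. The AUC
#' is asserted identical before and after (recalibration is rank-preserving).
#'
#' @param dev an `fpm_development` from [run_development()].
#' @param external post-exclusion external cohort data.frame.
#' @param config a [pipeline_config()].
#' @return list of class `validation_report` with per-tier `pre`, `recal`
#'   (b, k) and `post` blocks.
#' @export
external_validation <- function(dev, external, config = pipeline_config()) {
  out <- list()
  for (tr in names(dev$fits)) {
    covs <- tier_covariates(tr)
    missing_cov <- covs[!covs %in% names(external) |
                        vapply(covs, function(v)
                          v %in% names(external) && all(is.na(external[[v]])),
                          logical(1))]
    if (length(missing_cov)) {
      out[[tr]] <- list(status = "skipped",
                        reason = paste("missing covariates:",
                                       paste(missing_cov, collapse = ", ")))
      message("external validation: tier ", tr, " skipped (",
              out[[tr]]$reason, ")")
      next
    }
    risks <- predict_risk(dev$fits[[tr]], dev$mortality, external,
                          config$horizon)$ar
    pre <- .validate_block(risks, external, config)
    rec <- recalibrate_cohort(external, risks, config$horizon)
    risks2 <- apply_recalibration(pmin(risks, 1 - 1e-12), rec)
    post <- .validate_block(risks2, external, config)
    stopifnot(abs(pre$auc$auc - post$auc$auc) < 1e-12)
    out[[tr]] <- list(status = "ok", pre = pre,
                      recal = list(b = rec$b, k = rec$k, table = rec$table),
                      post = post)
  }
  structure(list(kind = "external", n = nrow(external), tiers = out),
            class = "validation_report")
}

## Case filters for the sensitivity analyses: rows are dropped (not
## relabelled) when they are cancer cases failing the selected criterion.
.filter_cases <- function(cohort, case_filter) {
  keep <- switch(case_filter,
    all = rep(TRUE, nrow(cohort)),
    pathology_confirmed = cohort$event_ec == 0 |
      (!is.na(cohort$path_confirmed) & cohort$path_confirmed == 1),
    escc_only = cohort$event_ec == 0 |
      (!is.na(cohort$escc) & cohort$escc == 1),
    non_escc = cohort$event_ec == 0 |
      (!is.na(cohort$escc) & cohort$escc == 0),
    stop("unknown case_filter: ", case_filter))
  cohort[keep, , drop = FALSE]
}

#' Sensitivity analysis variants
#'
#' Re-runs development under the configured switches: restriction of cancer
#' cases by pathology status, exclusion of first-year cases (diagnoses within
#' one year of entry, possibly prevalent), and separate models per region
#' stratum (the region term is then dropped automatically as constant).
#'
#' @param cohort post-exclusion cohort data.frame.
#' @param config a [pipeline_config()]; switches read from
#'   `config$sensitivity`.
#' @return named list of variant results (each with `fits`, `hr_tables`,
#'   `n`, `cases`), plus `notes` for skipped pieces.
#' @export
run_sensitivity <- function(cohort, config = pipeline_config()) {
  sw <- config$sensitivity
  out <- list(notes = character(0))
  if (isTRUE(sw$exclude_first_year_cases)) {
    fu <- cohort$exit_age - cohort$entry_age
    keep <- !(cohort$event_ec == 1 & fu < 1)
    sub <- cohort[keep, , drop = FALSE]
    out$exclude_first_year <- c(
      run_development(sub, config)[c("fits", "hr_tables")],
      list(n = nrow(sub), cases = sum(sub$event_ec)))
  }
  cf <- sw$case_filter
  if (!is.null(cf) && cf != "all") {
    sub <- .filter_cases(cohort, cf)
    if (sum(sub$event_ec) == 0)
      stop("case filter '", cf, "' removed all cancer cases")
    out[[paste0("case_filter_", cf)]] <- c(
      run_development(sub, config)[c("fits", "hr_tables")],
      list(n = nrow(sub), cases = sum(sub$event_ec)))
  }
  if (isTRUE(sw$region_specific_models)) {
    for (rg in c("high", "low")) {
      sub <- cohort[cohort$region_risk == rg, , drop = FALSE]
      if (nrow(sub) == 0 || sum(sub$event_ec) == 0) {
        out$notes <- c(out$notes, paste0("region-specific model for '", rg,
                                         "' stratum skipped: no data"))
        message(utils::tail(out$notes, 1))
        next
      }
      out[[paste0("region_", rg)]] <- c(
        suppressWarnings(run_development(sub, config))[c("fits", "hr_tables")],
        list(n = nrow(sub), cases = sum(sub$event_ec)))
    }
  }
  out
}

#' Run the full study workflow
#'
#' Exclusions on both cohorts, nested development fits, internal validation,
#' external validation with recalibration, and (optionally) sensitivity
#' variants, assembled into a single report. Deterministic for fixed config
#' and seeds: rerunning writes byte-identical JSON.
#'
#' @param dev_cohort raw development cohort (pre-exclusion).
#' @param ext_cohort raw external cohort (pre-exclusion), or NULL.
#' @param config a [pipeline_config()].
#' @param sensitivity run the configured sensitivity variants.
#' @return list of class `study_report`.
#' @export
run_study <- function(dev_cohort, ext_cohort = NULL,
                      config = pipeline_config(), sensitivity = FALSE) {
  ex_dev <- apply_exclusions(dev_cohort)
  dev <- run_development(ex_dev$cohort, config)
  internal <- internal_validation(ex_dev$cohort, config)
  external <- NULL; ex_ext <- NULL
  if (!is.null(ext_cohort)) {
    ex_ext <- apply_exclusions(ext_cohort)
    external <- external_validation(dev, ex_ext$cohort, config)
  }
  sens <- if (sensitivity) run_sensitivity(ex_dev$cohort, config)
  structure(list(
    config = unclass(config),
    seed = config$seed,
    exclusions = list(
      development = c(as.list(ex_dev$log$removed),
                      input_n = attr(ex_dev$log, "input_n"),
                      remaining_n = attr(ex_dev$log, "remaining_n")),
      external = if (!is.null(ex_ext))
        c(as.list(ex_ext$log$removed),
          input_n = attr(ex_ext$log, "input_n"),
          remaining_n = attr(ex_ext$log, "remaining_n"))),
    development = list(
      tiers = names(dev$fits),
      loglik = vapply(dev$fits, `[[`, numeric(1), "loglik"),
      loglik_nested = dev$loglik_nested,
      hr_tables = dev$hr_tables,
      mortality_loglik = dev$mortality$loglik),
    internal = internal,
    external = external,
    sensitivity = if (sensitivity)
      lapply(sens[setdiff(names(sens), "notes")],
             function(v) v[c("hr_tables", "n", "cases")])
  ), class = "study_report")
}

#' Write a study report as JSON
#'
#' @param report a `study_report` (or `validation_report`).
#' @param path file path.
#' @export
write_study_report <- function(report, path) {
  jsonlite::write_json(.strip_for_json(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", force = TRUE)
  invisible(path)
}

## Drop fitted-model objects (closures, environments) before serialising.
.strip_for_json <- function(x) {
  if (inherits(x, "fpm_fit"))
    return(list(tier = x$spec$tier, par = as.list(x$par), loglik = x$loglik,
                converged = x$converged))
  if (is.list(x)) return(lapply(unclass(x), .strip_for_json))
  x
}
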