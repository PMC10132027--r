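## Discrimination, calibration, reclassification and cutoff-performance
## metrics, mirroring the study's validation battery: AUC at the 10-year
## horizon on a binary label (with DeLong intervals), Kaplan-Meier observed
## risk by predicted-risk decile (all rows, including short follow-up),
## continuous NRI / IDI, and sensitivity/specificity/PPV/NPV across cutoffs.

#' Eligibility for horizon-based discrimination measures
#'
#' Rows are kept when the 10-year (`horizon`-year) cancer status is settled:
#' a cancer diagnosis within the horizon (label 1), death cancer-free within
#' the horizon (label 0: the competing event settles the status), or
#' cancer-free follow-up reaching the horizon (label 0). Participants
#' censored alive and cancer-free before the horizon are excluded (reason
#' `"insufficient follow-up"`), because their horizon status is unknown; they
#' still contribute to Kaplan-Meier calibration.
#'
#' @param cohort cohort data.frame.
#' @param horizon years (default 10).
#' @return data.frame with `included` (logical), `label` (0/1 or NA) and
#'   `reason` for exclusions.
#' @export
eligible_for_discrimination <- function(cohort, horizon = 10) {
  stopifnot(horizon > 0)
  fu <- cohort$exit_age - cohort$entry_age
  case <- cohort$event_ec == 1 & fu <= horizon
  death <- cohort$event_death == 1 & fu <= horizon
  full_fu <- fu >= horizon
  included <- case | death | full_fu
  data.frame(
    included = included,
    label = ifelse(included, as.integer(case), NA_integer_),
    reason = ifelse(included, "", "insufficient follow-up"),
    stringsAsFactors = FALSE)
}

#' Area under the ROC curve with a DeLong confidence interval
#'
#' Mann-Whitney probability that a random case outranks a random non-case,
#' ties counted one half, with the DeLong placement-value variance for the
#' 95% interval.
#'
#' @param risks predicted risks (any monotone score).
#' @param labels 0/1 outcome labels; both classes must be present.
#' @return list: `auc`, `lower`, `upper`, `se`, `n_case`, `n_control`.
#' @export
auc <- function(risks, labels) {
  stopifnot(length(risks) == length(labels))
  case <- labels == 1
  n1 <- sum(case); n0 <- sum(!case)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: one outcome class is absent")
  r_all <- rank(risks)
  a <- (sum(r_all[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ## DeLong placement values via within-group ranks
  v10 <- (r_all[case] - rank(risks[case])) / n0
  v01 <- 1 - (r_all[!case] - rank(risks[!case])) / n1
  se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  list(auc = a,
       lower = max(0, a - 1.96 * se), upper = min(1, a + 1.96 * se),
       se = se, n_case = n1, n_control = n0)
}

#' Kaplan-Meier observed risk at a horizon
#'
#' `1 - S_KM(horizon)` with a Greenwood log-log confidence interval. With no
#' censoring before the horizon this equals the empirical event proportion.
#'
#' @param times follow-up times (years from entry).
#' @param events 0/1 event indicators (competing deaths enter as censored,
#'   per the study's Kaplan-Meier calibration convention).
#' @param horizon years.
#' @return list: `risk`, `lower`, `upper`, `n`, `events_by_horizon`.
#' @export
km_observed_risk <- function(times, events, horizon) {
  stopifnot(length(times) == length(events), all(times >= 0))
  if (!any(times >= horizon) && !any(events == 1 & times <= horizon))
    stop("Kaplan-Meier risk undefined: no subject at risk up to the horizon")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = "log-log")
  sm <- summary(sf, times = horizon, extend = TRUE)
  if (length(sm$surv) == 0 || is.na(sm$surv))
    stop("Kaplan-Meier risk undefined at the horizon")
  list(risk = 1 - sm$surv,
       lower = 1 - sm$upper,
       upper = 1 - sm$lower,
       n = length(times),
       events_by_horizon = sum(events == 1 & times <= horizon))
}

#' Per-decile calibration table
#'
#' For each predicted-risk decile: group size, mean predicted risk, and the
#' Kaplan-Meier observed risk at the horizon with its interval. All rows
#' contribute, including those with short follow-up (the study's calibration
#' rule); competing deaths are censored in the Kaplan-Meier estimate.
#'
#' @param risks predicted risks, one per cohort row.
#' @param cohort cohort data.frame.
#' @param horizon years (default 10).
#' @param deciles optional precomputed decile assignment; defaults to
#'   [risk_deciles()] of `risks`.
#' @return data.frame: `decile`, `n`, `mean_predicted`, `observed`, `lower`,
#'   `upper`.
#' @export
calibration_table <- function(risks, cohort, horizon = 10, deciles = NULL) {
  if (is.null(deciles)) deciles <- risk_deciles(risks)
  fu <- cohort$exit_age - cohort$entry_age
  levs <- sort(unique(deciles))
  if (length(levs) == 1L)
    warning("all rows fall in a single decile; one-row calibration table")
  rows <- lapply(levs, function(g) {
    ix <- deciles == g
    km <- km_observed_risk(fu[ix], cohort$event_ec[ix], horizon)
    data.frame(decile = g, n = sum(ix), mean_predicted = mean(risks[ix]),
               observed = km$risk, lower = km$lower, upper = km$upper)
  })
  do.call(rbind, rows)
}

#' Continuous net reclassification improvement
#'
#' `NRI = [P(new > old | case) - P(new < old | case)] +
#' [P(new < old | non-case) - P(new > old | non-case)]`; ties contribute
#' zero; range -2 to 2.
#'
#' @param risk_old,risk_new paired predicted risks from the two models.
#' @param labels 0/1 outcome labels, both classes present.
#' @return list: `nri`, `event_component`, `nonevent_component`.
#' @export
continuous_nri <- function(risk_old, risk_new, labels) {
  stopifnot(length(risk_old) == length(risk_new),
            length(labels) == length(risk_old))
  case <- labels == 1
  if (!any(case) || all(case))
    stop("NRI undefined: one outcome class is absent")
  d <- sign(risk_new - risk_old)
  ev <- mean(d[case] > 0) - mean(d[case] < 0)
  ne <- mean(d[!case] < 0) - mean(d[!case] > 0)
  list(nri = ev + ne, event_component = ev, nonevent_component = ne)
}

#' Integrated discrimination improvement
#'
#' `IDI = [mean(new | case) - mean(new | non-case)] -
#' [mean(old | case) - mean(old | non-case)]`.
#'
#' @inheritParams continuous_nri
#' @return the IDI value.
#' @export
idi <- function(risk_old, risk_new, labels) {
  case <- labels == 1
  if (!any(case) || all(case))
    stop("IDI undefined: one outcome class is absent")
  (mean(risk_new[case]) - mean(risk_new[!case])) -
    (mean(risk_old[case]) - mean(risk_old[!case]))
}

#' Bootstrap confidence intervals for NRI and IDI
#'
#' Percentile intervals over participant resamples (default 500 replicates).
#'
#' @inheritParams continuous_nri
#' @param B bootstrap replicates.
#' @param conf confidence level.
#' @return list with `nri` and `idi`, each `(estimate, lower, upper)`.
#' @export
nri_idi_ci <- function(risk_old, risk_new, labels, B = 500L, conf = 0.95) {
  n <- length(labels)
  stat <- function(ix) {
    l <- labels[ix]
    if (!any(l == 1) || all(l == 1)) return(c(NA_real_, NA_real_))
    c(continuous_nri(risk_old[ix], risk_new[ix], l)$nri,
      idi(risk_old[ix], risk_new[ix], l))
  }
  reps <- vapply(seq_len(B), function(b) stat(sample.int(n, n, replace = TRUE)),
                 numeric(2))
  q <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  est <- stat(seq_len(n))
  list(nri = list(estimate = est[1],
                  lower = stats::quantile(reps[1, ], q[1], na.rm = TRUE,
                                          names = FALSE),
                  upper = stats::quantile(reps[1, ], q[2], na.rm = TRUE,
                                          names = FALSE)),
       idi = list(estimate = est[2],
                  lower = stats::quantile(reps[2, ], q[1], na.rm = TRUE,
                                          names = FALSE),
                  upper = stats::quantile(reps[2, ], q[2], na.rm = TRUE,
                                          names = FALSE)))
}

#' Screening performance across risk cutoffs
#'
#' For each cutoff: sensitivity, specificity, positive and negative
#' predictive value, and the fraction of the population flagged
#' (`risk >= cutoff`). Sensitivity is nonincreasing and specificity
#' nondecreasing in the cutoff.
#'
#' @param risks predicted risks.
#' @param labels 0/1 outcome labels.
#' @param cutoffs risk cutoffs.
#' @return data.frame, one row per cutoff.
#' @export
cutoff_performance <- function(risks, labels,
                               cutoffs = c(0.005, 0.01, 0.02, 0.05)) {
  case <- labels == 1
  rows <- lapply(cutoffs, function(ct) {
    flag <- risks >= ct
    tp <- sum(flag & case); fn <- sum(!flag & case)
    fp <- sum(flag & !case); tn <- sum(!flag & !case)
    data.frame(cutoff = ct,
               sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
               ppv = if (tp + fp) tp / (tp + fp) else NA_real_,
               npv = if (tn + fn) tn / (tn + fn) else NA_real_,
               flagged = mean(flag))
  })
  do.call(rbind, rows)
}

#' Calibration plot (observed vs predicted risk by decile)
#'
#' @param tab a [calibration_table()].
#' @param title plot title.
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_calibration <- function(tab, title = "Calibration by decile of predicted risk") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_calibration requires the ggplot2 package")
  ggplot2::ggplot(tab, ggplot2::aes(x = mean_predicted, y = observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = lower, ymax = upper),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Mean predicted 10-year risk",
                  y = "Observed 10-year risk (Kaplan-Meier)",
                  title = title) +
    ggplot2::theme_minimal()
}
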