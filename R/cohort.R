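## Cohort table schema: one row per participant, ages in decimal years,
## categorical values drawn from the closed level sets below. Missing values
## are NA in R and the empty string in CSV files.

.cohort_levels <- list(
  sex                   = c("male", "female"),
  region_risk           = c("low", "high"),
  residence             = c("rural", "urban"),
  education             = c("primary_or_less", "middle_or_high", "college"),
  smoking               = c("non", "lt30", "ge30"),
  alcohol               = c("non", "lt30", "30to59", "ge60"),
  bmi_cat               = c("lt18.5", "18.5to23.9", "ge24"),
  physical_activity     = c("low", "high"),
  tea_temp              = c("warm_or_none", "hot", "burning"),
  fruit                 = c("daily", "weekly", "lt_weekly")
)

.cohort_columns <- c(
  "id", "entry_age", "exit_age", "event_ec", "event_death",
  names(.cohort_levels),
  "family_history_cancer", "prior_cancer_flag", "bphs_special",
  "path_confirmed", "escc"
)

#' Validate a cohort table
#'
#' Checks the per-participant schema used throughout the package: entry and
#' exit ages in decimal years with `exit_age > entry_age`, mutually exclusive
#' esophageal-cancer and death event indicators, and categorical covariates
#' drawn from their closed level sets. Missing covariate values (NA) are
#' allowed; structural violations are not.
#'
#' @param cohort a data.frame.
#' @param require_all if TRUE, all schema columns must be present; otherwise
#'   only the survival core (id, ages, event flags) is required.
#' @return the cohort, invisibly, with factor levels normalised.
#' @export
validate_cohort <- function(cohort, require_all = FALSE) {
  core <- c("id", "entry_age", "exit_age", "event_ec", "event_death")
  miss <- setdiff(if (require_all) .cohort_columns else core, names(cohort))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  ok <- cohort$exit_age > cohort$entry_age
  if (any(!ok, na.rm = TRUE))
    stop(sum(!ok, na.rm = TRUE), " rows have exit_age <= entry_age")
  if (any(cohort$event_ec == 1 & cohort$event_death == 1, na.rm = TRUE))
    stop("event_ec and event_death must not both be 1")
  for (v in intersect(names(.cohort_levels), names(cohort))) {
    vals <- cohort[[v]]
    if (is.factor(vals)) vals <- as.character(vals)
    bad <- !is.na(vals) & !(vals %in% .cohort_levels[[v]])
    if (any(bad))
      stop("column ", v, " contains values outside its closed set: ",
           paste(unique(vals[bad]), collapse = ", "))
    cohort[[v]] <- factor(vals, levels = .cohort_levels[[v]])
  }
  invisible(cohort)
}

#' Read / write a cohort CSV
#'
#' Fixed-header CSV interchange format for cohort tables: ages as decimal
#' years, categorical values as their closed string sets, missing values as
#' empty strings.
#'
#' @param path file path.
#' @param cohort a cohort data.frame.
#' @return `read_cohort` returns a validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  validate_cohort(x)
  for (v in intersect(names(.cohort_levels), names(x)))
    x[[v]] <- factor(x[[v]], levels = .cohort_levels[[v]])
  x
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (v in names(out)) if (is.factor(out[[v]])) out[[v]] <- as.character(out[[v]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

.exclusion_rules <- c("prior_cancer", "missing_bmi", "age_range",
                      "implausible_censor", "missing_predictors")

#' Apply the eligibility exclusion cascade
#'
#' Removes participants in the stated rule order, so a row removed by an
#' earlier rule is never recounted by a later one:
#' \describe{
#'   \item{prior_cancer}{`prior_cancer_flag == 1` (previous cancer diagnosis).}
#'   \item{missing_bmi}{missing BMI category.}
#'   \item{age_range}{entry age outside \[30, 79\] years.}
#'   \item{implausible_censor}{exit age missing or not after entry age.}
#'   \item{missing_predictors}{NA in any predictor column present in the data
#'     (from the covariate schema).}
#' }
#'
#' @param raw cohort data.frame (pre-exclusion).
#' @param rules character vector, a subset of the rules above, applied in the
#'   given order.
#' @return list with `cohort` (rows passing all rules) and `log`, a
#'   data.frame of per-rule removal counts plus attributes `input_n` and
#'   `remaining_n` satisfying `input_n - sum(removed) = remaining_n`.
#' @examples
#' raw <- data.frame(id = 1:4, entry_age = c(50, 50, 85, 50),
#'                   exit_age = c(60, 60, 90, 49), event_ec = 0,
#'                   event_death = 0, prior_cancer_flag = c(1, 0, 0, 0))
#' apply_exclusions(raw, c("prior_cancer", "age_range", "implausible_censor"))$log
#' @export
apply_exclusions <- function(raw, rules = .exclusion_rules) {
  bad <- setdiff(rules, .exclusion_rules)
  if (length(bad))
    stop("unknown exclusion rule(s): ", paste(bad, collapse = ", "))
  keep <- rep(TRUE, nrow(raw))
  removed <- integer(length(rules))
  names(removed) <- rules
  ## a column that is entirely NA was never collected in that cohort and is
  ## not a per-subject missing predictor
  predictor_cols <- intersect(
    c(names(.cohort_levels), "family_history_cancer"), names(raw))
  predictor_cols <- predictor_cols[
    !vapply(raw[predictor_cols], function(z) all(is.na(z)), logical(1))]
  for (r in rules) {
    flag <- switch(r,
      prior_cancer = !is.na(raw$prior_cancer_flag) & raw$prior_cancer_flag == 1,
      missing_bmi = is.na(raw$bmi_cat),
      age_range = is.na(raw$entry_age) | raw$entry_age < 30 | raw$entry_age > 79,
      implausible_censor = is.na(raw$exit_age) | raw$exit_age <= raw$entry_age,
      missing_predictors = if (length(predictor_cols))
        Reduce(`|`, lapply(raw[predictor_cols], is.na)) else rep(FALSE, nrow(raw))
    )
    hit <- keep & flag
    removed[[r]] <- sum(hit)
    keep <- keep & !hit
  }
  log <- data.frame(rule = rules, removed = as.integer(removed),
                    row.names = NULL)
  attr(log, "input_n") <- nrow(raw)
  attr(log, "remaining_n") <- sum(keep)
  stopifnot(nrow(raw) - sum(log$removed) == sum(keep))
  list(cohort = raw[keep, , drop = FALSE], log = log)
}
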