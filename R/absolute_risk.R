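## Competing-risk absolute risk: the probability of an esophageal-cancer
## diagnosis within a horizon, conditional on being alive and cancer-free at
## age a, combining the cause-specific cancer and all-cause-mortality models:
##   AR(a, h) = int_a^{a+h} h_EC(t|x) exp(-[H_EC(t|x) - H_EC(a|x)]
##                                        -[H_D(t|x_D) - H_D(a|x_D)]) dt.
## Conditioning at age a (left truncation at prediction time) means risk
## accrued before a never enters.

## Composite Simpson weights for an even number of panels.
.simpson_w <- function(m) {
  w <- rep(c(4, 2), length.out = m - 1L)
  c(1, w[-length(w)], 4, 1)
}

.ar_core <- function(fit_ec, fit_death, xb_ec, xb_death, age_a, horizon, step) {
  n <- length(age_a)
  m <- max(2L, 2L * ceiling(horizon / (2 * step)))  # even panel count
  s <- seq(0, horizon, length.out = m + 1L)
  ages <- outer(age_a, s, `+`)                      # n x (m+1)
  dim_a <- dim(ages)
  kn_ec <- fit_ec$spec$knots
  eta_ec <- fit_ec$gamma[1L] +
    matrix(rcs_basis(as.vector(ages), kn_ec) %*% fit_ec$gamma[-1L], n) + xb_ec
  Hec <- exp(eta_ec)
  ds <- matrix(rcs_derivative(as.vector(ages), kn_ec) %*% fit_ec$gamma[-1L], n)
  ## mild non-monotonicity of a fitted cumulative hazard in the sparse right
  ## tail is floored at hazard zero; gross violations are an error
  if (any(ds < -0.5))
    stop(sprintf("negative cancer hazard at age %.2f: cumulative hazard not monotone",
                 ages[which.min(ds)]))
  hec <- Hec * pmax(ds, 0)
  kn_d <- fit_death$spec$knots
  Hd <- exp(fit_death$gamma[1L] +
    matrix(rcs_basis(as.vector(ages), kn_d) %*% fit_death$gamma[-1L], n) +
    xb_death)
  surv <- exp(-(Hec - Hec[, 1L]) - (Hd - Hd[, 1L]))
  integrand <- hec * surv
  hstep <- horizon / m
  ar <- drop(integrand %*% .simpson_w(m)) * hstep / 3
  pmin(pmax(ar, 0), 1)
}

#' Ten-year absolute risk of esophageal cancer under competing mortality
#'
#' Integrates the cause-specific cancer hazard against joint cancer-free and
#' alive survival from age `age_a` to `age_a + horizon`, by composite Simpson
#' quadrature on a 0.1-year grid (halving the step is used as a convergence
#' check; the integrand is smooth, so the default grid is accurate to well
#' below 1e-8).
#'
#' @param fit_ec,fit_death converged `fpm_fit` objects for the cancer and
#'   all-cause-mortality cause-specific hazards.
#' @param x_ec,x_death covariate (dummy) vectors for the two models, or
#'   matrices with one row per subject.
#' @param age_a age(s) at prediction, years.
#' @param horizon prediction horizon in years (default 10).
#' @param step quadrature step in years (default 0.1).
#' @param extrapolate allow `age_a + horizon` beyond the upper boundary knot
#'   (the basis is linear out there); otherwise such input is an error.
#' @return absolute risk(s) in \[0, 1\].
#' @examples
#' \dontrun{
#' absolute_risk(fit_ec, fit_death, x, x_d, age_a = 55)
#' }
#' @export
absolute_risk <- function(fit_ec, fit_death, x_ec = NULL, x_death = NULL,
                          age_a, horizon = 10, step = 0.1,
                          extrapolate = FALSE) {
  if (!isTRUE(fit_ec$converged) || !isTRUE(fit_death$converged))
    warning("absolute risk computed from a fit flagged as not converged")
  kmax <- max(fit_ec$spec$knots$knots_years)
  if (!extrapolate && any(age_a + horizon > kmax + 1e-9))
    stop("age + horizon exceeds the upper boundary knot (", kmax,
         "); set extrapolate = TRUE to override")
  n <- length(age_a)
  xb_ec <- .fpm_xbeta(fit_ec, x_ec, n)
  xb_death <- .fpm_xbeta(fit_death, x_death, n)
  .ar_core(fit_ec, fit_death, xb_ec, xb_death, age_a, horizon, step)
}

#' Batch 10-year risk predictions for a cohort
#'
#' Builds both models' design matrices from the cohort covariates and
#' evaluates [absolute_risk()] at each participant's entry age, in chunks to
#' bound memory.
#'
#' @param fit_ec,fit_death fitted cause-specific models.
#' @param cohort cohort data.frame.
#' @param horizon years (default 10).
#' @param extrapolate passed to [absolute_risk()]; default TRUE because
#'   cohort entry ages near the upper knot are routine in batch scoring.
#' @param chunk rows per chunk.
#' @return data.frame: `id`, `age_a`, `horizon`, `ar`, `decile`, `model_tier`.
#' @export
predict_risk <- function(fit_ec, fit_death, cohort, horizon = 10,
                         extrapolate = TRUE, chunk = 20000L) {
  X_ec <- .design_for_fit(fit_ec, cohort)
  X_d <- .design_for_fit(fit_death, cohort)
  n <- nrow(cohort)
  ar <- numeric(n)
  for (i0 in seq(1L, n, by = chunk)) {
    ix <- i0:min(i0 + chunk - 1L, n)
    ar[ix] <- absolute_risk(fit_ec, fit_death,
                            X_ec[ix, , drop = FALSE], X_d[ix, , drop = FALSE],
                            cohort$entry_age[ix], horizon,
                            extrapolate = extrapolate)
  }
  out <- data.frame(id = cohort$id, age_a = cohort$entry_age,
                    horizon = horizon, ar = ar,
                    model_tier = fit_ec$spec$tier)
  out$decile <- risk_deciles(ar)
  out
}

## Design matrix matching a fit's beta (columns dropped at fit time get 0s).
.design_for_fit <- function(fit, cohort) {
  X <- build_design(cohort, fit$spec$covariates, drop_constant = FALSE)
  out <- matrix(0, nrow(cohort), length(fit$beta),
                dimnames = list(NULL, names(fit$beta)))
  common <- intersect(colnames(X), names(fit$beta))
  out[, common] <- X[, common]
  out
}

#' Decile assignment of predicted risks
#'
#' Cutpoints are the empirical 10th..90th percentiles of the predicted risks;
#' values tied with a cutpoint are assigned to the lower decile, so group
#' sizes differ by at most the tie-block size.
#'
#' @param risks numeric vector of predicted risks (length >= 10).
#' @return integer vector of deciles 1-10, with the cutpoints in
#'   `attr(, "cutpoints")`. A degenerate input where all risks are identical
#'   puts every row in decile 1, with a warning.
#' @export
risk_deciles <- function(risks) {
  if (length(risks) < 10L) stop("need at least 10 predictions to form deciles")
  cut <- stats::quantile(risks, probs = seq(0.1, 0.9, by = 0.1), names = FALSE,
                         type = 7)
  if (min(risks) == max(risks))
    warning("all predicted risks identical; every row assigned to decile 1")
  dec <- findInterval(risks, cut, left.open = TRUE) + 1L
  attr(dec, "cutpoints") <- cut
  dec
}
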