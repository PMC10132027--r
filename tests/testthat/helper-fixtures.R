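## Shared fixtures: hand-built model objects, small simulated survival data,
## and cached calibrated synthetic cohorts (generated once per test run).

## A flexible-parametric fit object with known coefficients, for closed-form
## checks. gamma = c(gamma0, spline coefficients); knots on the log-age scale
## unless told otherwise, so gamma = c(log(lambda), 1, 0, 0) is the constant
## hazard lambda and c(-k*log(sigma), k, 0, 0) is Weibull H = (t/sigma)^k.
make_fit <- function(gamma, beta = numeric(0), spec = NULL) {
  if (is.null(spec))
    spec <- fpm_spec("simple", covariates = names(beta))
  ns <- length(spec$knots$knots) - 1L
  stopifnot(length(gamma) == ns + 1L)
  structure(list(gamma = gamma, beta = beta,
                 par = c(gamma, beta), vcov = NULL,
                 loglik = NA_real_, converged = TRUE, monotone = TRUE,
                 spec = spec, n = 0L, events = 0L),
            class = "fpm_fit")
}

const_hazard_fit <- function(lambda) make_fit(c(log(lambda), 1, 0, 0))

## Weibull event times with delayed entry and a binary covariate, returned as
## a cohort data.frame (event_death = 0 throughout).
sim_weibull_cohort <- function(n, shape = 5, scale = 70, beta = 0,
                               seed = 1, entry = c(35, 70), fu = c(5, 12),
                               covariate = "family_history_cancer") {
  set.seed(seed)
  a <- runif(n, entry[1], entry[2])
  x <- rbinom(n, 1, 0.5)
  u <- runif(n)
  Ha <- (a / scale)^shape * exp(beta * x)
  tev <- scale * ((Ha - log(u)) / exp(beta * x))^(1 / shape)
  cens <- a + runif(n, fu[1], fu[2])
  d <- data.frame(id = seq_len(n), entry_age = a,
                  exit_age = pmin(tev, cens),
                  event_ec = as.integer(tev <= cens), event_death = 0L)
  d[[covariate]] <- x
  d
}

## Cached calibrated cohorts: built on first use, reused across test files.
.fixtures <- new.env(parent = emptyenv())

cached_ckb <- function() {
  if (is.null(.fixtures$ckb)) {
    cfg <- calibrate_baseline(
      generator_config("ckb", tier = "simple", n = 40000L, seed = 101L),
      mode = "stratum", n_cal = 30000L, iter = 14L)
    .fixtures$ckb <- list(config = cfg,
                          cohort = apply_exclusions(generate_cohort(cfg))$cohort)
  }
  .fixtures$ckb
}

cached_changzhou <- function() {
  if (is.null(.fixtures$chz)) {
    cfg <- calibrate_baseline(
      generator_config("changzhou", tier = "intermediate", n = 15000L,
                       seed = 102L),
      mode = "stratum", n_cal = 30000L, iter = 14L)
    .fixtures$chz <- list(config = cfg,
                          cohort = apply_exclusions(generate_cohort(cfg))$cohort)
  }
  .fixtures$chz
}
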