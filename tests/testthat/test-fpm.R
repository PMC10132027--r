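# Flexible parametric model: likelihood arithmetic, closed-form hazards,
# fitting, inference, and agreement with an independent implementation.

test_that("log cumulative hazard and hazard reproduce closed forms", {
  # H(t) = (t/70)^3 on the log-age scale
  fit <- make_fit(c(-3 * log(70), 3, 0, 0))
  expect_equal(log_cum_hazard(fit, 35), 3 * log(0.5), tolerance = 1e-12)
  ages <- c(40, 55, 63, 80)
  expect_equal(hazard(fit, ages), (3 / 70) * (ages / 70)^2, tolerance = 1e-12)
  # constant hazard: H = lambda t, h = lambda at all ages
  cf <- const_hazard_fit(0.07)
  expect_equal(hazard(cf, c(35, 50, 88)), rep(0.07, 3), tolerance = 1e-12)
  # finite-difference agreement for a genuinely curved spline
  set.seed(2)
  g <- c(-25, 5.5, -0.8, 0.4)
  fitc <- make_fit(g)
  for (a in runif(20, 35, 85)) {
    h_num <- (exp(log_cum_hazard(fitc, a + 1e-5)) -
              exp(log_cum_hazard(fitc, a - 1e-5))) / 2e-5
    expect_equal(hazard(fitc, a), h_num, tolerance = 1e-5)
  }
})

test_that("covariates act proportionally on the hazard", {
  fit <- make_fit(c(-25, 5.5, -0.8, 0.4), beta = c(region_risk.high = log(6.31)),
                  spec = fpm_spec("simple", covariates = "region_risk"))
  ages <- seq(35, 85, length.out = 50)
  lr <- log_cum_hazard(fit, ages, rep(1, 1)) - log_cum_hazard(fit, ages, 0)
  expect_equal(lr, rep(log(6.31), 50), tolerance = 1e-10)
  hr <- hazard(fit, ages, c(1)) / hazard(fit, ages, c(0))
  expect_equal(hr, rep(6.31, 50), tolerance = 1e-10)
})

test_that("the likelihood matches per-subject hand arithmetic", {
  lam <- 0.05
  spec <- fpm_spec("age_only")
  par <- c(log(lam), 1, 0, 0)
  one <- function(entry, exit, d)
    data.frame(id = 1, entry_age = entry, exit_age = exit,
               event_ec = d, event_death = 0L)
  # censored after w years: contribution lambda * w
  expect_equal(neg_log_likelihood(par, one(50, 58, 0L), spec), lam * 8,
               tolerance = 1e-12)
  # event after w years: lambda * w - log(lambda)
  expect_equal(neg_log_likelihood(par, one(50, 58, 1L), spec),
               lam * 8 - log(lam), tolerance = 1e-12)
  # 100-subject fixture against a literal summation oracle
  set.seed(14)
  d <- sim_weibull_cohort(100, shape = 4, scale = 65, beta = log(1.8), seed = 14)
  spec2 <- fpm_spec("simple", covariates = "family_history_cancer")
  par2 <- c(-19, 4.4, 0.2, -0.1, log(1.8))
  g0 <- par2[1]; g <- par2[2:4]; b <- par2[5]
  kn <- knot_spec()
  oracle <- 0
  for (i in seq_len(100)) {
    eta <- function(t) g0 + sum(rcs_basis(t, kn)[1, ] * g) +
      b * d$family_history_cancer[i]
    detadt <- function(t) sum(rcs_derivative(t, kn)[1, ] * g)
    ll_i <- -(exp(eta(d$exit_age[i])) - exp(eta(d$entry_age[i])))
    if (d$event_ec[i] == 1)
      ll_i <- ll_i + eta(d$exit_age[i]) + log(detadt(d$exit_age[i]))
    oracle <- oracle - ll_i
  }
  expect_equal(neg_log_likelihood(par2, d, spec2), oracle, tolerance = 1e-9)
  expect_error(neg_log_likelihood(par2[-1], d, spec2), "parameters")
  bad <- d; bad$exit_age[1] <- bad$entry_age[1] - 1
  expect_error(neg_log_likelihood(par2, bad, spec2), "exit_age")
})

test_that("fitting recovers an exponential hazard without covariates", {
  set.seed(5)
  n <- 20000
  a <- runif(n, 40, 70)
  tev <- a + rexp(n, 0.002)
  cens <- a + runif(n, 5, 12)
  d <- data.frame(id = 1:n, entry_age = a, exit_age = pmin(tev, cens),
                  event_ec = as.integer(tev <= cens), event_death = 0L)
  fit <- fit_fpm(d, fpm_spec("age_only"))
  expect_true(fit$converged)
  expect_equal(unname(hazard(fit, 50)), 0.002, tolerance = 0.1)
  expect_equal(unname(hazard(fit, 65)), 0.002, tolerance = 0.1)
})

test_that("Wald intervals cover a true hazard ratio at the nominal rate", {
  covered <- rep(NA, 250)
  for (r in seq_along(covered)) {
    d <- sim_weibull_cohort(2000, shape = 4, scale = 70, beta = log(2),
                            seed = 1000 + r, entry = c(40, 65), fu = c(6, 14))
    fit <- suppressWarnings(
      fit_fpm(d, fpm_spec("simple", covariates = "family_history_cancer")))
    if (is.null(fit$vcov)) next   # information not invertible: rare, flagged
    se <- sqrt(diag(fit$vcov)["family_history_cancer.yes"])
    if (!is.finite(se)) next
    ci <- fit$beta[1] + c(-1.96, 1.96) * se
    covered[r] <- ci[1] <= log(2) && log(2) <= ci[2]
  }
  expect_lte(sum(is.na(covered)), 15)
  expect_gte(mean(covered, na.rm = TRUE), 0.93)
})

test_that("hazard-ratio tables follow exp/CI arithmetic with reference rows", {
  fit <- make_fit(c(-25, 5.5, -0.8, 0.4),
                  beta = c(sex.female = log(2), region_risk.high = 0),
                  spec = fpm_spec("simple",
                                  covariates = c("sex", "region_risk")))
  fit$vcov <- diag(1e-12, 6)
  dimnames(fit$vcov) <- list(names(fit$par), names(fit$par))
  tab <- hazard_ratios(fit)
  expect_equal(tab$hr[tab$term == "sex.female"], 2, tolerance = 1e-4)
  expect_equal(tab$lower[tab$term == "sex.female"],
               tab$upper[tab$term == "sex.female"], tolerance = 1e-4)
  expect_equal(tab$hr[tab$term == "region_risk.high"], 1)
  expect_true(all(tab$hr[tab$reference] == 1))
  # manual arithmetic on a nontrivial se
  fit$vcov[5, 5] <- 0.01
  tab2 <- hazard_ratios(fit)
  expect_equal(tab2$lower[tab2$term == "sex.female"], exp(log(2) - 1.96 * 0.1),
               tolerance = 1e-9)
})

test_that("dropping the nonlinear terms gives an exact Weibull model", {
  d <- sim_weibull_cohort(12000, shape = 4, scale = 75, beta = 0, seed = 77,
                          entry = c(40, 65), fu = c(6, 14))
  spec <- fpm_spec("age_only", knots = knot_spec(internal_knots = numeric(0)))
  fit <- fit_fpm(d, spec)
  shape_hat <- unname(fit$gamma[2])
  scale_hat <- exp(-unname(fit$gamma[1]) / shape_hat)
  expect_equal(shape_hat, 4, tolerance = 0.06)
  expect_equal(scale_hat, 75, tolerance = 0.02)
})

test_that("the fitted optimum agrees with an independent implementation", {
  skip_if_not_installed("flexsurv")
  d <- sim_weibull_cohort(5000, shape = 5, scale = 70, beta = log(2), seed = 42)
  fit <- fit_fpm(d, fpm_spec("simple", covariates = "family_history_cancer"))
  fs <- flexsurv::flexsurvspline(
    survival::Surv(entry_age, exit_age, event_ec) ~ family_history_cancer,
    data = d, knots = log(c(60, 70)), bknots = log(c(30, 90)),
    scale = "hazard", inits = c(-21, 5, 0, 0, log(2)))
  # same likelihood surface: equal optimum and covariate estimate (the two
  # spline bases differ but span the same space)
  expect_equal(fit$loglik, as.numeric(stats::logLik(fs)), tolerance = 1e-4)
  expect_equal(unname(fit$beta), unname(stats::coef(fs)[["family_history_cancer"]]),
               tolerance = 1e-2)
  expect_gte(fit$loglik, as.numeric(stats::logLik(fs)) - 1e-3)
})

test_that("nested tiers have ordered log-likelihoods on the same cohort", {
  co <- cached_ckb()$cohort
  fits <- lapply(c("age_only", "simple"), function(tr) fit_fpm(co, fpm_spec(tr)))
  expect_lte(fits[[1]]$loglik, fits[[2]]$loglik)
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))
})

test_that("a single-stratum cohort drops the region term with a warning", {
  co <- cached_ckb()$cohort
  sub <- co[co$region_risk == "low", ]
  expect_warning(fit <- fit_fpm(sub, fpm_spec("simple")), "constant design")
  expect_false("region_risk.high" %in% names(fit$beta))
  tab <- hazard_ratios(fit)
  expect_equal(tab$hr[tab$term == "region_risk.high"], 1)  # emitted as reference-style row
})

test_that("model JSON round-trips losslessly", {
  d <- sim_weibull_cohort(2000, shape = 4, scale = 70, beta = log(1.5), seed = 8)
  fit <- suppressWarnings(
    fit_fpm(d, fpm_spec("simple", covariates = "family_history_cancer")))
  path <- tempfile(fileext = ".json")
  write_fpm(fit, path)
  back <- read_fpm(path)
  expect_equal(back$par, fit$par, tolerance = 1e-15)
  expect_equal(back$vcov, fit$vcov, tolerance = 1e-12)
  expect_equal(back$loglik, fit$loglik)
  expect_identical(back$spec$knots$knots_years, fit$spec$knots$knots_years)
  ages <- c(45, 60, 75)
  expect_equal(log_cum_hazard(back, ages, c(1)), log_cum_hazard(fit, ages, c(1)))
  unlink(path)
})

test_that("degenerate inputs are rejected with clear errors", {
  d <- sim_weibull_cohort(200, seed = 3)
  fit <- suppressWarnings(
    fit_fpm(d, fpm_spec("simple", covariates = "family_history_cancer")))
  expect_error(log_cum_hazard(fit, 50, c(1, 2)), "length")
  d0 <- d; d0$event_ec <- 0L
  expect_error(fit_fpm(d0, fpm_spec("age_only")), "no events")
})
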