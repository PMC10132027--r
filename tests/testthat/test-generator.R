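# Synthetic cohort generator: event-time inversion, covariate structure,
# follow-up and incidence behaviour, determinism.

test_that("event-age sampling matches closed forms under delayed entry", {
  set.seed(11)
  # constant hazard 0.1/yr from entry 50: conditional waiting time Exp(0.1)
  n <- 10000
  t1 <- simulate_event_time(rep(50, n), function(t) log(0.1 * t), t_max = 1000)
  expect_true(all(is.finite(t1)))
  expect_equal(mean(t1 - 50), 10, tolerance = 0.3)
  # zero hazard: the no-event sentinel
  t0 <- simulate_event_time(rep(50, 5), function(t) rep(-Inf, length(t)))
  expect_identical(t0, rep(Inf, 5))
  # Weibull H = (t/60)^3: Kolmogorov-Smirnov against the conditional CDF
  n <- 2000
  tw <- simulate_event_time(rep(50, n), function(t) 3 * (log(t) - log(60)),
                            t_max = 1000)
  cdf <- function(t) 1 - exp(-((t / 60)^3 - (50 / 60)^3))
  ks <- suppressWarnings(stats::ks.test(tw, cdf))
  expect_gt(ks$p.value, 0.01)
  # a decreasing cumulative hazard is a model error
  expect_error(simulate_event_time(rep(50, 3), function(t) -t),
               "nondecreasing")
})

test_that("generation is reproducible and degenerate strata behave", {
  cfg <- generator_config("ckb", tier = "simple", n = 2000L, seed = 33L,
                          fraction_high_risk = 0,
                          baseline = list(knots = knot_spec(),
                                          gamma = c(6, -1, 0.5),
                                          intercept = c(shared = -29)))
  co <- generate_cohort(cfg)
  expect_true(all(co$region_risk == "low"))
  expect_identical(co, generate_cohort(cfg))
  expect_identical(attr(co, "seed"), 33L)
  expect_true(all(co$exit_age > co$entry_age))
  expect_false(any(co$event_ec == 1 & co$event_death == 1))
  expect_true(all(co$entry_age >= 30 & co$entry_age <= 79))
})

test_that("covariate marginals of a large cohort match the configured probabilities", {
  cfg <- generator_config("ckb", tier = "simple", n = 1000000L, seed = 44L,
                          baseline = list(knots = knot_spec(),
                                          gamma = c(6, -1, 0.5),
                                          intercept = c(shared = -30)))
  co <- generate_cohort(cfg)
  n <- nrow(co)
  for (v in c("sex", "education", "smoking", "alcohol", "bmi_cat",
              "physical_activity", "tea_temp", "fruit")) {
    p <- cfg$covariate_model[[v]]$probs
    emp <- as.numeric(table(co[[v]])[names(p)]) / n
    tol <- 3 * sqrt(p * (1 - p) / n)
    expect_true(all(abs(emp - p) <= pmax(tol, 2 / n)),
                label = paste("marginals of", v))
  }
  expect_equal(mean(co$region_risk == "high"), 0.232,
               tolerance = 3 * sqrt(0.232 * 0.768 / n) / 0.232)
  expect_equal(mean(co$family_history_cancer), 0.168, tolerance = 0.01)
  # age/sex dependence present: smokers are overwhelmingly male
  expect_gt(mean(co$sex[co$smoking != "non"] == "male"), 0.7)
  # older participants are less educated
  expect_gt(mean(co$entry_age[co$education == "primary_or_less"]),
            mean(co$entry_age[co$education == "college"]))
})

test_that("pooled incidence is the person-year-weighted mixture of stratum incidences", {
  co <- cached_ckb()$cohort
  py <- tapply(co$exit_age - co$entry_age, co$region_risk, sum)
  rates <- sapply(c("low", "high"), function(s)
    incidence_rate(co[co$region_risk == s, ]))
  pooled <- sum(rates[names(py)] * py) / sum(py)
  expect_equal(incidence_rate(co), pooled, tolerance = 1e-12)
})

test_that("stratum calibration hits the configured incidences within Monte-Carlo error", {
  fx <- cached_ckb()
  co <- fx$cohort
  for (s in c("high", "low")) {
    sub <- co[co$region_risk == s, ]
    r <- incidence_rate(sub)
    target <- fx$config$target_incidence[[s]]
    se <- target / sqrt(sum(sub$event_ec))
    expect_lt(abs(r - target), 4 * se)
  }
})

test_that("median follow-up matches the two cohort profiles", {
  fu <- cached_ckb()$cohort
  expect_equal(median(fu$exit_age - fu$entry_age), 11.1, tolerance = 0.015)
  fz <- cached_changzhou()$cohort
  expect_equal(median(fz$exit_age - fz$entry_age), 13.6, tolerance = 0.015)
})

test_that("the generator respects proportional hazards in its truth", {
  # raising a subject's log-hazard by delta with the same uniform draw can
  # only advance the event age; with constant hazard the excess is exact
  set.seed(9)
  a <- runif(500, 40, 60)
  u <- runif(500)
  base <- function(t) log(0.01 * t)
  shifted <- function(t) log(0.01 * t) + log(2)
  t1 <- simulate_event_time(a, base, u = u, t_max = 1e5)
  t2 <- simulate_event_time(a, shifted, u = u, t_max = 1e5)
  expect_true(all(t2 <= t1 + 1e-8))
  # H(t2) - H(a) must equal half of H(t1) - H(a): 0.01(t2-a) = 0.01(t1-a)/2
  expect_equal(t2 - a, (t1 - a) / 2, tolerance = 1e-6)
})

test_that("invalid generator configurations are refused", {
  expect_error(generator_config("ckb", covariate_model = utils::modifyList(
    ecrisk:::.ckb_covariate_model(),
    list(sex = list(probs = c(male = 0.5, female = 0.6))))),
    "sum to 1")
  expect_error(generator_config("ckb", ltfu_rate = -1), ">= 0")
  expect_error(generator_config("changzhou", tier = "full"), "full-tier")
  expect_error(generator_config("ckb", nonsense = 1), "unknown config")
  cfg <- generator_config("ckb", n = 100L)
  expect_error(generate_cohort(cfg), "calibrate_baseline")
})
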