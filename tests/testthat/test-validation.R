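# Discrimination, calibration, reclassification and cutoff metrics.

test_that("horizon eligibility settles the ten-year status correctly", {
  co <- data.frame(
    id = 1:4, entry_age = 50,
    exit_age = c(57, 54, 62, 55),
    event_ec = c(0L, 1L, 0L, 0L),
    event_death = c(0L, 0L, 0L, 1L))
  el <- eligible_for_discrimination(co, horizon = 10)
  # censored cancer-free at 7 years: unknown status, excluded
  expect_false(el$included[1])
  expect_identical(el$reason[1], "insufficient follow-up")
  # cancer at 4 years: case
  expect_true(el$included[2]); expect_identical(el$label[2], 1L)
  # cancer-free at 12 years: non-case
  expect_true(el$included[3]); expect_identical(el$label[3], 0L)
  # died cancer-free at 5 years: status settled, non-case
  expect_true(el$included[4]); expect_identical(el$label[4], 0L)
})

test_that("AUC equals the brute-force pair enumeration with half ties", {
  pair_auc <- function(r, l) {
    cases <- which(l == 1); ctrls <- which(l == 0)
    s <- 0
    for (i in cases) for (j in ctrls)
      s <- s + (r[i] > r[j]) + 0.5 * (r[i] == r[j])
    s / (length(cases) * length(ctrls))
  }
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc,
               pair_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  set.seed(18)
  for (r in 1:5) {
    risks <- round(runif(40), 1)          # force ties
    labels <- rbinom(40, 1, 0.4)
    if (sum(labels) %in% c(0, 40)) next
    expect_equal(auc(risks, labels)$auc, pair_auc(risks, labels))
  }
  risks <- runif(20000); labels <- rbinom(20000, 1, 0.3)
  expect_equal(auc(risks, labels)$auc, 0.5, tolerance = 0.03)
  expect_error(auc(runif(5), rep(1, 5)), "class is absent")
})

test_that("DeLong intervals agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  risks <- runif(300)
  labels <- rbinom(300, 1, plogis(4 * risks - 2))
  ours <- auc(risks, labels)
  ref <- pROC::ci.auc(pROC::roc(labels, risks, quiet = TRUE), method = "delong")
  expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(ours$lower, as.numeric(ref[1]), tolerance = 1e-5)
  expect_equal(ours$upper, as.numeric(ref[3]), tolerance = 1e-5)
})

test_that("Kaplan-Meier risk matches hand computation and the no-censoring identity", {
  r <- km_observed_risk(times = c(2, 3, 5, 7, 11, 12, 12, 13),
                        events = c(0, 1, 0, 1, 0, 0, 1, 0),
                        horizon = 10)
  # hand product-limit: event at 3 (7 at risk), event at 7 (5 at risk)
  expect_equal(r$risk, 1 - (1 - 1 / 7) * (1 - 1 / 5), tolerance = 1e-12)
  # no censoring before the horizon: empirical proportion, exactly
  expect_equal(km_observed_risk(c(1, 2, 11, 11, 12, 13, 14, 15, 16, 17),
                                c(1, 1, rep(0, 8)), 10)$risk,
               0.2, tolerance = 1e-12)
  set.seed(7)
  tt <- runif(500, 0, 20); ev <- as.integer(tt < 12)  # events observed, rest past horizon
  expect_equal(km_observed_risk(tt, ev, 12)$risk, mean(tt < 12), tolerance = 1e-12)
  expect_error(km_observed_risk(rep(0.001, 5), rep(0, 5), 10), "undefined")
})

test_that("calibration tables reflect constructed miscalibration", {
  set.seed(41)
  n <- 20000
  p <- rbeta(n, 1.2, 30) * 0.5
  ev <- rbinom(n, 1, p)
  tt <- ifelse(ev == 1, runif(n, 0, 10), 10.5)  # no censoring before horizon
  co <- data.frame(id = 1:n, entry_age = 50, exit_age = 50 + pmax(tt, 0.01),
                   event_ec = ev, event_death = 0L)
  half <- p / 2
  tab <- calibration_table(half, co, horizon = 10)
  expect_identical(nrow(tab), 10L)
  expect_equal(sum(tab$n), n)
  expect_equal(tab$observed / tab$mean_predicted, rep(2, 10), tolerance = 0.25)
  # well-calibrated predictions sit on the diagonal
  tab2 <- calibration_table(p, co, horizon = 10)
  expect_equal(tab2$observed / tab2$mean_predicted, rep(1, 10), tolerance = 0.2)
  expect_warning(calibration_table(rep(0.1, 50), co[1:50, ], 10,
                                   deciles = rep(1L, 50)), "single decile")
})

test_that("continuous NRI matches exhaustive counting and is antisymmetric", {
  old <- c(0.10, 0.20, 0.30, 0.15, 0.25, 0.05)
  new <- c(0.15, 0.18, 0.30, 0.10, 0.30, 0.04)
  lab <- c(1, 1, 1, 0, 0, 0)
  # hand count: cases up 1 of 3, down 1 of 3, tie 1; non-cases down 2 of 3, up 1
  ev <- (1 - 1) / 3; ne <- (2 - 1) / 3
  got <- continuous_nri(old, new, lab)
  expect_equal(got$nri, ev + ne, tolerance = 1e-12)
  expect_equal(got$event_component, ev)
  expect_equal(got$nonevent_component, ne)
  expect_equal(continuous_nri(old, old, lab)$nri, 0)
  # maximal improvement
  up <- old + ifelse(lab == 1, 0.1, -0.1)
  expect_equal(continuous_nri(old, up, lab)$nri, 2)
  # antisymmetry
  expect_equal(continuous_nri(new, old, lab)$nri, -got$nri)
  expect_error(continuous_nri(old, new, rep(1, 6)), "class is absent")
})

test_that("IDI matches direct mean arithmetic", {
  old <- c(0.10, 0.20, 0.30, 0.15, 0.25, 0.05)
  lab <- c(1, 1, 1, 0, 0, 0)
  expect_equal(idi(old, old, lab), 0)
  new <- old + ifelse(lab == 1, 0.1, 0)
  expect_equal(idi(old, new, lab), 0.1, tolerance = 1e-12)
  set.seed(2)
  o <- runif(30); n2 <- runif(30); l <- rep(c(1, 0), 15)
  direct <- (mean(n2[l == 1]) - mean(n2[l == 0])) -
    (mean(o[l == 1]) - mean(o[l == 0]))
  expect_equal(idi(o, n2, l), direct, tolerance = 1e-12)
  expect_equal(idi(n2, o, l), -direct, tolerance = 1e-12)
})

test_that("cutoff performance reproduces contingency arithmetic and is monotone", {
  risks <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.5, 0.4, 0.35, 0.3, 0.25,
             0.2, 0.18, 0.15, 0.12, 0.1, 0.08, 0.06, 0.04, 0.02, 0.01)
  labels <- c(1, 1, 0, 1, 0, 1, 0, 0, 1, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0)
  tab <- cutoff_performance(risks, labels, cutoffs = c(0.5, 0.2))
  # at 0.5: flags the top 6 -> TP 4, FP 2, FN 2, TN 12
  expect_equal(tab$sensitivity[1], 4 / 6)
  expect_equal(tab$specificity[1], 12 / 14)
  expect_equal(tab$ppv[1], 4 / 6)
  expect_equal(tab$npv[1], 12 / 14)
  expect_equal(tab$flagged[1], 6 / 20)
  ext <- cutoff_performance(risks, labels, cutoffs = c(0, 1))
  expect_equal(ext$sensitivity, c(1, 0))
  expect_equal(ext$specificity, c(0, 1))
  grid <- cutoff_performance(risks, labels, cutoffs = seq(0.05, 0.85, by = 0.1))
  expect_true(all(diff(grid$sensitivity) <= 0))
  expect_true(all(diff(grid$specificity) >= 0))
})

test_that("AUC is invariant under any strictly increasing transform", {
  set.seed(9)
  risks <- runif(200, 0, 0.6)
  labels <- rbinom(200, 1, risks)
  if (sum(labels) %in% c(0, 200)) labels[1:2] <- c(0, 1)
  base <- auc(risks, labels)$auc
  expect_equal(auc(qlogis(pmin(risks + 1e-6, 1 - 1e-6)), labels)$auc, base)
  expect_equal(auc(apply_recalibration(risks, list(b = 1.7, k = 0.4)),
                   labels)$auc, base)
})

test_that("bootstrap NRI/IDI intervals bracket the point estimates", {
  set.seed(13)
  n <- 300
  old <- runif(n, 0, 0.4); lab <- rbinom(n, 1, old)
  new <- pmin(pmax(old + ifelse(lab == 1, 0.05, -0.02) + rnorm(n, 0, 0.02), 0), 1)
  ci <- nri_idi_ci(old, new, lab, B = 50)
  expect_lte(ci$nri$lower, ci$nri$estimate)
  expect_gte(ci$nri$upper, ci$nri$estimate)
  expect_lte(ci$idi$lower, ci$idi$estimate)
})
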