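test_that("identical specs give byte-identical cohorts", {
  spec <- cohort_spec(n = 300, seed = 42, truth = subgroup_truth())
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  spec2 <- cohort_spec(n = 300, seed = 43, truth = subgroup_truth())
  expect_false(identical(generate_cohort(spec), generate_cohort(spec2)))
})

test_that("with no censoring mechanism every record is an event", {
  co <- generate_cohort(cohort_spec(n = 200, seed = 1,
                                    censor_model = list(dist = "none")))
  expect_true(all(co$event == 1))
  expect_equal(summarize_cohort(co)$censor_fraction, 0)
})

test_that("marker prevalences and censor fraction land near their targets", {
  co <- generate_cohort(cohort_spec(n = 1465, seed = 9))
  expect_lt(abs(mean(co$er) - 0.758), 0.04)
  expect_lt(abs(mean(co$pr) - 0.725), 0.04)
  expect_lt(abs(mean(co$her2) - 0.19), 0.04)
  expect_lt(abs(mean(co$event == 0) - 0.86), 0.04)
})

test_that("age marginals: median ~54, ~10% below 39, minimum >= 20", {
  co <- generate_cohort(cohort_spec(n = 20000, seed = 17))
  expect_lt(abs(median(co$age) - 54), 1)
  expect_lt(abs(mean(co$age < 39) - 0.10), 0.02)
  expect_gte(min(co$age), 20)
  expect_lte(max(co$age), 90)
})

test_that("event times follow the stated generative law (LLN check)", {
  # single exponential segment with true mean 2.0, no censoring
  co <- quick_cohort(50000, 11, c(`(Intercept)` = log(2)),
                     censor = list(dist = "none"))
  expect_lt(abs(mean(co$time) - 2) / 2, 0.02)
})

test_that("segment rules route subjects to the right generative law", {
  truth <- cohort_truth(
    segments = list(truth_segment(~ her2 == 1, c(`(Intercept)` = log(0.5)))),
    default = truth_segment(coef = c(`(Intercept)` = log(8))))
  co <- generate_cohort(cohort_spec(n = 30000, seed = 13, truth = truth,
                                    prevalences = c(er = .5, pr = .5,
                                                    her2 = .5),
                                    censor_model = list(dist = "none")))
  expect_lt(abs(mean(co$time[co$her2 == 1]) - 0.5) / 0.5, 0.05)
  expect_lt(abs(mean(co$time[co$her2 == 0]) - 8) / 8, 0.05)
})

test_that("overlapping rules and bad configurations error", {
  overlap <- cohort_truth(
    segments = list(truth_segment(~ her2 == 1, c(`(Intercept)` = 1)),
                    truth_segment(~ pr == 1, c(`(Intercept)` = 2))),
    default = truth_segment(coef = c(`(Intercept)` = 0)))
  expect_error(generate_cohort(cohort_spec(n = 500, seed = 1,
                                           truth = overlap)),
               "mutually exclusive")
  expect_error(cohort_spec(n = 0), "positive integer")
  expect_error(cohort_spec(prevalences = c(er = 1.2, pr = .5, her2 = .1)),
               "\\[0, 1\\]")
  expect_error(cohort_spec(censor_model = list(dist = "gamma")),
               "unknown censoring")
  expect_error(truth_segment("her2 == 1", c(`(Intercept)` = 1)),
               "one-sided formula")
})

test_that("admin cap truncates follow-up and censors correctly", {
  co <- quick_cohort(2000, 21, c(`(Intercept)` = 2),
                     censor = list(dist = "none"))
  spec <- attr(co, "spec")
  spec$admin_cap <- 3
  capped <- generate_cohort(spec)
  expect_lte(max(capped$time), 3)
  expect_true(all(capped$event[capped$time < 3] == 1))
  expect_true(all(capped$event[capped$time == 3] == 0))
})

test_that("Kaplan-Meier summary matches hand-computed product limits", {
  d <- data.frame(time = c(1, 2, 3), event = 1)
  s <- summarize_cohort(d, horizons = 2.5)
  expect_equal(s$km$surv, 1 / 3, tolerance = 1e-12)
  expect_equal(s$median_time, 2)
  expect_equal(s$mean_time, 2)

  d2 <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0))
  s2 <- summarize_cohort(d2, horizons = 2.5)
  expect_equal(s2$km$surv, (3 / 4) * (2 / 3), tolerance = 1e-12)
  # CI contains the point estimate and sits inside [0, 1]
  expect_lte(s2$km$lower, s2$km$surv)
  expect_gte(s2$km$upper, s2$km$surv)
  expect_gte(s2$km$lower, 0)
  expect_lte(s2$km$upper, 1)
  expect_error(summarize_cohort(data.frame()), "nonempty")
})

test_that("KM with zero censoring equals the empirical survival function", {
  co <- quick_cohort(500, 19, c(`(Intercept)` = 1),
                     censor = list(dist = "none"))
  horizons <- quantile(co$time, c(.2, .5, .8))
  s <- summarize_cohort(co, horizons = horizons)
  expect_equal(s$km$surv, vapply(horizons, function(h) mean(co$time > h),
                                 numeric(1)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # KM non-increasing in the horizon
  expect_true(all(diff(s$km$surv) <= 0))
})

test_that("correlated markers via the Gaussian copula keep their marginals", {
  cor_m <- matrix(c(1, .6, 0, .6, 1, 0, 0, 0, 1), 3, 3)
  co <- generate_cohort(cohort_spec(n = 20000, seed = 23,
                                    marker_cor = cor_m))
  expect_lt(abs(mean(co$er) - 0.758), 0.02)
  expect_lt(abs(mean(co$pr) - 0.725), 0.02)
  expect_gt(cor(co$er, co$pr), 0.25)  # induced positive association
})

test_that("exponential-truth cohorts let the AFT intercept recover log mean", {
  # one-segment exponential truth, no censoring: over seeded replicates the
  # fitted intercept covers log(true mean) within 3 SE almost always
  hits <- vapply(1:200, function(s) {
    co <- quick_cohort(500, s, c(`(Intercept)` = log(3)),
                       censor = list(dist = "none"))
    f <- aft_fit(Surv(time, event) ~ 1, co, family = "exponential")
    abs(coef(f)[[1]] - log(3)) <= 3 * sqrt(vcov(f)[1, 1])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
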