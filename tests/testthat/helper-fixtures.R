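library(survival)

# Tiny hand-checkable censored dataset: times 1..4, first two are events.
hand_cohort <- function() {
  data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0))
}

# Quick single-segment cohort from an arbitrary coefficient vector.
quick_cohort <- function(n, seed, coef, family = "exponential", scale = 1,
                         censor = list(dist = "exponential", target = 0.5),
                         prevalences = c(er = 0.5, pr = 0.5, her2 = 0.5)) {
  generate_cohort(cohort_spec(
    n = n, seed = seed, prevalences = prevalences,
    truth = cohort_truth(default = truth_segment(coef = coef, scale = scale,
                                                 family = family)),
    censor_model = censor))
}

# Central finite differences of a scalar function, the numeric oracle for
# analytic gradients.
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

families4 <- c("exponential", "weibull", "loglogistic", "lognormal")
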