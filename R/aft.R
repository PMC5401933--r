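#' Fit a parametric accelerated failure time model
#'
#' Maximum-likelihood fit of the log-location-scale AFT model
#' \eqn{\log T = x'\beta + \sigma\varepsilon} to right-censored data, under one
#' of four residual laws (see [aft_family()]). The optimisation is carried out
#' by [survival::survreg()] over \eqn{(\beta, \log\sigma)}; the package then
#' recomputes the analytic per-subject score contributions at the optimum and
#' flags convergence by the gradient max-norm, so a fit is never reported as
#' converged on the optimiser's say-so alone.
#'
#' @param formula a model formula with a [survival::Surv()] response
#'   (right censoring), e.g. `Surv(time, event) ~ age + er + pr + her2`.
#' @param data a data frame with one row per subject.
#' @param family distribution family, see [aft_family()].
#' @param subset optional logical or integer subject subset.
#' @param grad_tol gradient max-norm tolerance for the convergence flag,
#'   interpreted per subject (the fit converged if
#'   \eqn{\max_j |\sum_i s_{ij}| \le} `grad_tol * n`).
#' @return An object of class `"aft_fit"`: a list with `coefficients`,
#'   `scale`, `vcov` (observed-information inverse for the free parameters,
#'   \eqn{\beta} and \eqn{\log\sigma}), `loglik`, `k` (free parameter count),
#'   `n`, `n_events`, `converged`, the family, and the model frame pieces
#'   needed by the methods.
#' @seealso [summary.aft_fit()], [predict.aft_fit()], [aft_scores()],
#'   [time_ratio()]
#' @examples
#' d <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0))
#' f <- aft_fit(survival::Surv(time, event) ~ 1, d, family = "exponential")
#' coef(f)          # log(total time / events) = log 5
#' @export
aft_fit <- function(formula, data, family = "weibull", subset = NULL,
                    grad_tol = 1e-4) {
  fam <- aft_family(family)
  if (!is.null(subset)) data <- data[subset, , drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!survival::is.Surv(y) || attr(y, "type") != "right")
    stop("the response must be a right-censored survival::Surv object")
  time <- y[, 1L]
  event <- y[, 2L]
  if (any(time <= 0)) stop("all observation times must be > 0")
  n <- length(time)
  n_events <- sum(event)
  if (n_events < 1) stop("no events: the censored likelihood is degenerate")
  X <- stats::model.matrix(stats::terms(mf), mf)
  k <- ncol(X) + !fam$scale_fixed
  if (n < k + 1) stop("need at least k + 1 subjects to fit ", k, " parameters")

  sr <- survival::survreg(formula, data = data, dist = fam$survreg_dist)
  beta <- stats::coef(sr)
  if (anyNA(beta))
    stop("singular design: covariate(s) ", paste(names(beta)[is.na(beta)],
         collapse = ", "), " not estimable")
  scale <- if (fam$scale_fixed) 1 else sr$scale

  s <- aft_score_contrib(fam, beta, scale, time, event, X)
  grad <- colSums(s)
  converged <- max(abs(grad)) <= grad_tol * n

  V <- sr$var  # free parameters; last row/col is Log(scale) when free
  free_names <- c(colnames(X), if (!fam$scale_fixed) "Log(scale)")
  dimnames(V) <- list(free_names, free_names)

  structure(list(
    coefficients = beta,
    scale = scale,
    vcov = V,
    loglik = sr$loglik[2L],
    k = k,
    n = n,
    n_events = n_events,
    converged = converged,
    gradient = grad,
    family = fam,
    terms = stats::terms(mf),
    x = X,
    time = time,
    event = event,
    call = match.call()
  ), class = "aft_fit")
}

#' @export
coef.aft_fit <- function(object, ...) object$coefficients

#' @export
vcov.aft_fit <- function(object, ...) object$vcov

#' @export
logLik.aft_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
nobs.aft_fit <- function(object, ...) object$n

#' @export
print.aft_fit <- function(x, digits = max(3, getOption("digits") - 3), ...) {
  cat("Parametric AFT model (", x$family$name, ")\n", sep = "")
  cat("Call: ", deparse(x$call), "\n\n")
  print(round(x$coefficients, digits))
  if (!x$family$scale_fixed) cat("Scale:", format(x$scale, digits = digits), "\n")
  cat("Log-likelihood:", format(x$loglik, digits = digits + 2),
      " AIC:", format(-2 * x$loglik + 2 * x$k, digits = digits + 2),
      " (k =", x$k, ", n =", x$n, ",", x$n_events, "events)\n")
  if (!x$converged) cat("WARNING: fit did not converge (gradient max-norm ",
                        format(max(abs(x$gradient))), ")\n", sep = "")
  invisible(x)
}

#' Wald coefficient tests for an AFT fit
#'
#' Per-coefficient estimates, standard errors from the observed-information
#' inverse, Wald z statistics, two-sided normal p-values and significance
#' flags at the 5% and 1% levels (`*` / `**`). The log-scale parameter, when
#' free, is reported on the same footing.
#'
#' @param object an [aft_fit()].
#' @param ... unused.
#' @return An object of class `"summary.aft_fit"` whose `coefficients`
#'   component is the test table.
#' @export
summary.aft_fit <- function(object, ...) {
  est <- object$coefficients
  if (!object$family$scale_fixed) est <- c(est, `Log(scale)` = log(object$scale))
  se <- sqrt(pmax(diag(object$vcov), 0))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  tab <- cbind(Estimate = est, `Std. Error` = se, z = z, `Pr(>|z|)` = p)
  structure(list(
    coefficients = tab,
    stars = sig_stars(p),
    family = object$family$name,
    loglik = object$loglik, k = object$k, n = object$n,
    n_events = object$n_events, converged = object$converged,
    call = object$call
  ), class = "summary.aft_fit")
}

sig_stars <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))

#' @export
print.summary.aft_fit <- function(x, digits = 4, ...) {
  cat("Parametric AFT model (", x$family, ")\n", sep = "")
  cat("Call: ", deparse(x$call), "\n\n")
  tab <- as.data.frame(round(x$coefficients, digits))
  tab[[" "]] <- x$stars
  print(tab)
  cat("---\n*  significant at 5% level; ** significant at 1% level\n")
  cat("Log-likelihood:", format(x$loglik, digits = digits + 3),
      " AIC:", format(-2 * x$loglik + 2 * x$k, digits = digits + 3),
      " (k =", x$k, ")\n")
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' Per-subject score contributions at the fitted parameters
#'
#' Returns the matrix of analytic score contributions
#' \eqn{\partial \log L_i / \partial \theta} evaluated at the maximum
#' likelihood estimate, one row per subject and one column per free parameter
#' (the \eqn{\beta}'s, plus \eqn{\log\sigma} when the scale is free). At an
#' interior optimum the column sums vanish up to convergence tolerance. These
#' contributions are the currency of the parameter-instability tests used to
#' grow trees: systematic drift of the partial sums of rows, when subjects are
#' ordered or grouped by a covariate, is evidence the model's parameters
#' differ across subgroups.
#'
#' @param object an [aft_fit()].
#' @return an `n` by `k` numeric matrix.
#' @export
aft_scores <- function(object) {
  stopifnot(inherits(object, "aft_fit"))
  aft_score_contrib(object$family, object$coefficients, object$scale,
                    object$time, object$event, object$x)
}

#' Predicted survival times from an AFT fit
#'
#' The median prediction is \eqn{\exp(x'\beta) \cdot m(\sigma)} with
#' \eqn{m(\sigma) = (\log 2)^\sigma} for Weibull/exponential and 1 for the
#' log-logistic and lognormal (whose residual laws are symmetric on the log
#' scale). The mean uses the family's moment factor instead (e.g.
#' \eqn{\Gamma(1+\sigma)} for Weibull, \eqn{e^{\sigma^2/2}} for lognormal; the
#' log-logistic mean is infinite for \eqn{\sigma \ge 1}).
#'
#' @param object an [aft_fit()].
#' @param newdata data frame of covariates; defaults to the training data.
#' @param type `"median"` (default), `"mean"`, or `"lp"` for the linear
#'   predictor \eqn{x'\beta}.
#' @param ... unused.
#' @return a numeric vector, in the time units of the training data (years for
#'   the cohorts generated by this package).
#' @export
predict.aft_fit <- function(object, newdata = NULL,
                            type = c("median", "mean", "lp"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$x else
    stats::model.matrix(stats::delete.response(object$terms), newdata)
  lp <- drop(X %*% object$coefficients)
  switch(type,
    lp = lp,
    median = exp(lp) * object$family$median_factor(object$scale),
    mean = exp(lp) * object$family$mean_factor(object$scale)
  )
}

#' Acceleration factor for a covariate shift
#'
#' The time ratio \eqn{\exp(\beta_j \Delta)}: the multiplicative change in
#' survival time associated with a `delta` increase in covariate `covariate`.
#' A ratio of 0.5 means the model predicts half the survival time; e.g. an age
#' coefficient of \eqn{\log(0.5)/22 \approx -0.0315} halves predicted survival
#' over a 22-year age acceleration.
#'
#' @param object an [aft_fit()], or a coefficient vector.
#' @param covariate name of the coefficient.
#' @param delta covariate shift (default 1 unit).
#' @return the scalar time ratio.
#' @export
time_ratio <- function(object, covariate, delta = 1) {
  beta <- if (inherits(object, "aft_fit")) object$coefficients else object
  if (!covariate %in% names(beta))
    stop("no coefficient named '", covariate, "'")
  unname(exp(beta[[covariate]] * delta))
}

#' @export
residuals.aft_fit <- function(object, type = c("standardized", "response"), ...) {
  type <- match.arg(type)
  z <- (log(object$time) - drop(object$x %*% object$coefficients)) / object$scale
  switch(type,
    standardized = z,
    response = object$time - predict(object, type = "median"))
}
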