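#' Accelerated failure time distribution families
#'
#' The four log-location-scale families used throughout the package. Each
#' family defines the law of the standardized residual in
#' \eqn{\log T = x'\beta + \sigma \varepsilon}: the standard (minimum)
#' extreme-value distribution for Weibull and exponential, the standard
#' logistic for log-logistic, and the standard normal for lognormal. The
#' exponential family is exactly the Weibull with \eqn{\sigma} fixed at 1.
#'
#' @param family one of `"exponential"`, `"weibull"`, `"loglogistic"`,
#'   `"lognormal"` (partial matching allowed).
#' @return A list of class `"aft_family"` with the family name, a
#'   `scale_fixed` flag, and the residual law's log-density, log-survival,
#'   hazard, density score and quantile functions, plus the factors that turn
#'   \eqn{\exp(x'\beta)} into the median and mean survival time.
#' @examples
#' fam <- aft_family("weibull")
#' fam$qres(0.5)           # median standardized residual
#' fam$median_factor(1)    # log(2): exponential median = mean * log 2
#' @export
aft_family <- function(family = c("exponential", "weibull", "loglogistic", "lognormal")) {
  if (inherits(family, "aft_family")) return(family)
  name <- match.arg(family)
  base <- switch(name,
    exponential = ,
    weibull = list(
      # standard minimum extreme value: F(z) = 1 - exp(-e^z)
      logf = function(z) z - exp(z),
      logS = function(z) -exp(z),
      dlogf = function(z) 1 - exp(z),  # d log f / dz
      haz = function(z) exp(z),        # f(z)/S(z)
      qres = function(p) log(-log1p(-p)),
      median_factor = function(sigma) log(2)^sigma,
      mean_factor = function(sigma) gamma(1 + sigma)
    ),
    loglogistic = list(
      logf = function(z) z - 2 * log1p(exp(pmin(z, 700))),
      logS = function(z) stats::plogis(z, lower.tail = FALSE, log.p = TRUE),
      dlogf = function(z) 1 - 2 * stats::plogis(z),
      haz = function(z) stats::plogis(z),
      qres = stats::qlogis,
      median_factor = function(sigma) rep(1, length(sigma)),
      mean_factor = function(sigma)
        ifelse(sigma < 1, pi * sigma / sin(pi * sigma), Inf)
    ),
    lognormal = list(
      logf = function(z) stats::dnorm(z, log = TRUE),
      logS = function(z) stats::pnorm(z, lower.tail = FALSE, log.p = TRUE),
      dlogf = function(z) -z,
      haz = function(z) exp(stats::dnorm(z, log = TRUE) -
                              stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)),
      qres = stats::qnorm,
      median_factor = function(sigma) rep(1, length(sigma)),
      mean_factor = function(sigma) exp(sigma^2 / 2)
    )
  )
  base$name <- name
  base$scale_fixed <- identical(name, "exponential")
  base$survreg_dist <- name
  structure(base, class = "aft_family")
}

#' Censored AFT log-likelihood at arbitrary parameters
#'
#' Evaluates \eqn{\sum_{\delta_i=1} \log f(t_i) + \sum_{\delta_i=0} \log S(t_i)}
#' for the log-location-scale model \eqn{\log T = x'\beta + \sigma\varepsilon},
#' where \eqn{f} and \eqn{S} are the density and survival function implied by
#' the family's residual law. Events contribute the log-density
#' \eqn{\log f_\varepsilon(z_i) - \log\sigma - \log t_i} with
#' \eqn{z_i = (\log t_i - x_i'\beta)/\sigma}; censored subjects contribute
#' \eqn{\log S_\varepsilon(z_i)}.
#'
#' @param family an [aft_family()] or its name.
#' @param beta coefficient vector on the log-time scale, aligned with the
#'   columns of `x` (intercept first when `x` has an intercept column).
#' @param scale the scale \eqn{\sigma > 0}; forced to 1 for the exponential.
#' @param time observed follow-up times, strictly positive.
#' @param event event indicators in \{0, 1\} (1 = event observed).
#' @param x model matrix, one row per subject. Defaults to an
#'   intercept-only design.
#' @return the log-likelihood (a scalar).
#' @export
aft_loglik <- function(family, beta, scale = 1, time, event,
                       x = matrix(1, length(time), 1)) {
  fam <- aft_family(family)
  if (fam$scale_fixed) scale <- 1
  stopifnot(scale > 0, length(event) == length(time), nrow(x) == length(time),
            ncol(x) == length(beta))
  if (any(time <= 0)) stop("all observation times must be > 0")
  if (!all(event %in% c(0, 1))) stop("event indicators must be 0 or 1")
  z <- (log(time) - drop(x %*% beta)) / scale
  d <- event == 1
  sum(fam$logf(z[d]) - log(scale) - log(time[d])) + sum(fam$logS(z[!d]))
}

# Per-subject score contributions d log L_i / d(beta, log sigma) at the given
# parameters. With u_i = delta_i * dlogf(z_i) - (1 - delta_i) * haz(z_i):
#   d l_i / d beta      = -u_i x_i / sigma
#   d l_i / d log sigma = -delta_i - u_i z_i
aft_score_contrib <- function(fam, beta, scale, time, event, x) {
  z <- (log(time) - drop(x %*% beta)) / scale
  u <- ifelse(event == 1, fam$dlogf(z), -fam$haz(z))
  s <- x * (-u / scale)
  colnames(s) <- colnames(x)
  if (!fam$scale_fixed) {
    s <- cbind(s, `Log(scale)` = -event - u * z)
  }
  s
}
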