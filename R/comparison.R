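#' Likelihood ratio test between nested models
#'
#' \eqn{\Lambda = 2(\ell_{full} - \ell_{nested})} referred to a chi-square law
#' with df equal to the parameter-count gap. A fitted tree is treated as a
#' high-interaction model in which the corresponding global parametric model
#' is nested; its df is the tree parameter count (terminal-node parameters
#' plus one per split), and the resulting p-value is nominal — the chi-square
#' reference ignores the data-driven tree selection.
#'
#' @param nested,full either fitted objects with a [stats::logLik()] method
#'   (e.g. [aft_fit()], [aft_mob()]) or numeric vectors `c(loglik, k)`.
#' @return an object of class `"aft_lrt"`: `statistic`, `df`, `p`.
#' @examples
#' lrt(c(-2043.60, 5), c(-2037.38, 6))   # statistic 12.44, df 1
#' @export
lrt <- function(nested, full) {
  get_llk <- function(x) {
    if (is.numeric(x) && length(x) == 2L) return(list(ll = x[1L], k = x[2L]))
    ll <- stats::logLik(x)
    list(ll = as.numeric(ll), k = attr(ll, "df"))
  }
  a <- get_llk(nested)
  b <- get_llk(full)
  if (b$k <= a$k) stop("the full model must have more free parameters")
  stat <- 2 * (b$ll - a$ll)
  if (stat < -1e-6)
    stop("nesting violation: the full model's log-likelihood is lower (",
         format(stat / 2), ")")
  stat <- max(stat, 0)
  df <- b$k - a$k
  structure(list(statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "aft_lrt")
}

#' @export
print.aft_lrt <- function(x, ...) {
  cat(sprintf("Likelihood ratio test: statistic %.4f, df %g, p %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Compare parametric AFT models and their recursive partitions
#'
#' For each requested family, fits the global parametric model and grows the
#' model-based recursive partition (same node-model covariates throughout),
#' then assembles the table-shaped report: the global coefficient block with
#' standard errors and significance stars, the fitness criteria
#' (log-likelihood and AIC) of both model classes, the tree-vs-global LRT per
#' family, and the overall AIC ranking across all fitted models.
#'
#' @param data cohort data frame.
#' @param global model formula for the global parametric fits, e.g.
#'   `Surv(time, event) ~ age + er + pr + her2`.
#' @param tree tree formula (`model covariates | partitioning covariates`),
#'   e.g. `Surv(time, event) ~ er + age | her2 + pr + age + er`.
#' @param families character vector of AFT families to compare.
#' @param control a [mob_control()] shared by all trees.
#' @return An object of class `"aft_comparison"`: per-family global fits and
#'   trees, a `fitness` data frame (family, class, loglik, df, aic, aic_rank,
#'   converged), an `lrt` data frame, and the coefficient block. Supports
#'   `print()` and [as.data.frame()].
#' @export
compare_models <- function(data,
                           global = survival::Surv(time, event) ~
                             age + er + pr + her2,
                           tree = survival::Surv(time, event) ~
                             er + age | her2 + pr + age + er,
                           families = c("exponential", "weibull",
                                        "loglogistic", "lognormal"),
                           control = mob_control()) {
  families <- vapply(families, function(f) aft_family(f)$name, character(1))
  fits <- list()
  trees <- list()
  rows <- list()
  lrt_rows <- list()
  coef_block <- NULL
  for (f in families) {
    gf <- aft_fit(global, data, family = f)
    tr <- aft_mob(tree, data, family = f, control = control)
    fits[[f]] <- gf
    trees[[f]] <- tr
    tree_conv <- all(vapply(tr$nodes[tr$terminal_ids], `[[`, logical(1),
                            "converged"))
    rows[[length(rows) + 1L]] <- data.frame(
      family = f, class = "parametric", loglik = gf$loglik, df = gf$k,
      aic = -2 * gf$loglik + 2 * gf$k, converged = gf$converged)
    rows[[length(rows) + 1L]] <- data.frame(
      family = f, class = "mobrp", loglik = tr$loglik, df = tr$df,
      aic = tr$aic, converged = tree_conv)
    lr <- if (tr$df > gf$k) lrt(gf, tr) else
      list(statistic = 0, df = 0, p = 1)
    lrt_rows[[length(lrt_rows) + 1L]] <- data.frame(
      family = f, statistic = lr$statistic, df = lr$df, p = lr$p)
    st <- summary(gf)$coefficients
    cb <- data.frame(family = f, term = rownames(st),
                     estimate = st[, "Estimate"], se = st[, "Std. Error"],
                     p = st[, "Pr(>|z|)"],
                     stars = sig_stars(st[, "Pr(>|z|)"]),
                     row.names = NULL)
    coef_block <- rbind(coef_block, cb)
  }
  fitness <- do.call(rbind, rows)
  # rank by AIC; deterministic, invariant to family evaluation order
  fitness <- fitness[order(fitness$family, fitness$class), ]
  fitness$aic_rank <- rank(fitness$aic, ties.method = "first")
  rownames(fitness) <- NULL
  structure(list(fits = fits, trees = trees, fitness = fitness,
                 lrt = do.call(rbind, lrt_rows), coefficients = coef_block,
                 families = families, call = match.call()),
            class = "aft_comparison")
}

#' @export
print.aft_comparison <- function(x, digits = 2, ...) {
  fams <- x$families
  cat("Comparison of models across survival-time distributions\n\n")
  terms <- unique(x$coefficients$term)
  wide <- matrix("", length(terms), length(fams),
                 dimnames = list(terms, fams))
  for (i in seq_len(nrow(x$coefficients))) {
    r <- x$coefficients[i, ]
    wide[r$term, r$family] <- sprintf("%.2f%s (%.2f)", r$estimate, r$stars,
                                      r$se)
  }
  cat("Participated covariates in parametric models\n")
  print(as.data.frame(wide), right = TRUE)
  line <- function(class, what, fmt = "%.2f") {
    v <- vapply(fams, function(f)
      sprintf(fmt, x$fitness[[what]][x$fitness$family == f &
                                       x$fitness$class == class]), character(1))
    cat(sprintf("  %-22s %s\n",
                paste(if (class == "mobrp") "MoBRP" else "Parametric", what),
                paste(formatC(v, width = 10), collapse = " ")))
  }
  cat("\nFitness criteria          ",
      paste(formatC(fams, width = 10), collapse = " "), "\n", sep = "")
  line("parametric", "loglik"); line("parametric", "aic")
  line("mobrp", "loglik"); line("mobrp", "aic")
  cat("\nMoBRP vs parametric LRT (nominal p-values)\n")
  print(transform(x$lrt, statistic = round(statistic, 2),
                  p = signif(p, 3)), row.names = FALSE)
  best <- x$fitness[x$fitness$aic_rank == 1, ]
  cat(sprintf("\nSmallest AIC: %s %s (AIC %.2f)%s\n", best$family,
              if (best$class == "mobrp") "recursive partitioning"
              else "parametric model", best$aic,
              if (best$converged) "" else " [flagged non-converged]"))
  nc <- x$fitness[!x$fitness$converged, ]
  if (nrow(nc))
    cat("Non-converged fits: ",
        paste(nc$family, nc$class, collapse = "; "), "\n", sep = "")
  cat("---\n* significant at 5% level; ** significant at 1% level\n")
  cat("Tree df = terminal-node parameters + one per split; tree-vs-global\n")
  cat("LRT p-values are nominal (the chi-square reference ignores tree\n")
  cat("selection).\n")
  invisible(x)
}

#' @export
as.data.frame.aft_comparison <- function(x, ...) {
  fit <- x$fitness
  lr <- x$lrt
  fit$lrt_statistic <- lr$statistic[match(fit$family, lr$family)]
  fit$lrt_df <- lr$df[match(fit$family, lr$family)]
  fit$lrt_p <- lr$p[match(fit$family, lr$family)]
  fit$lrt_statistic[fit$class == "parametric"] <- NA
  fit$lrt_df[fit$class == "parametric"] <- NA
  fit$lrt_p[fit$class == "parametric"] <- NA
  fit
}
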