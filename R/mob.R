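#' Control parameters for model-based recursive partitioning
#'
#' @param alpha significance level for the splitting decision (a node is split
#'   only if the smallest, Bonferroni-adjusted when `bonferroni = TRUE`,
#'   instability p-value is at most `alpha`).
#' @param bonferroni adjust instability p-values across the covariates tested
#'   at a node (`p_adj = min(1, p * n_tested)`), on by default.
#' @param min_node_size minimum subjects per node; `NULL` means ten times the
#'   number of free parameters of the node model.
#' @param min_events minimum observed events per node (censored likelihoods
#'   degenerate without events).
#' @param max_depth maximum tree depth; 0 forces a root-only tree.
#' @param trim fraction of subjects excluded at each end when scanning an
#'   ordered numeric partitioning covariate for instability.
#' @param n_perm permutation draws for the instability p-values.
#' @param seed integer seed for the permutation draws; growth is deterministic
#'   given (data, control).
#' @param verbose print a line per node while growing.
#' @return a list of class `"mob_control"`.
#' @export
mob_control <- function(alpha = 0.05, bonferroni = TRUE, min_node_size = NULL,
                        min_events = 5, max_depth = Inf, trim = 0.1,
                        n_perm = 999, seed = 1, verbose = FALSE) {
  stopifnot(alpha > 0, alpha < 1, trim >= 0, trim < 0.5, n_perm >= 19,
            min_events >= 1, max_depth >= 0)
  structure(list(alpha = alpha, bonferroni = bonferroni,
                 min_node_size = min_node_size, min_events = min_events,
                 max_depth = max_depth, trim = trim,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 verbose = isTRUE(verbose)), class = "mob_control")
}

# A covariate is handled as categorical (forced/bipartition splits, summed-LM
# instability) when it is a factor, logical, or has at most two distinct
# values in the node; otherwise as ordered numeric (supLM over the sorted
# cumulative score process, midpoint cutpoints).
covariate_kind <- function(x) {
  if (is.factor(x) || is.logical(x) || is.character(x)) return("categorical")
  if (length(unique(x)) <= 2L) return("categorical")
  "numeric"
}

#' Parameter-instability (score fluctuation) test along one covariate
#'
#' Tests whether the fitted node model's per-subject score contributions
#' fluctuate systematically along a partitioning covariate — the evidence the
#' tree algorithm uses that the model's parameters differ across subgroups.
#' For an ordered covariate the subjects are sorted by it and the statistic is
#' the supLM functional of the cumulative score process,
#' \deqn{\max_j \|W(j)\|^2 / ((j/n)(1 - j/n)), \quad
#'       W(j) = \hat I^{-1/2} n^{-1/2} \sum_{i \le j} s_{(i)},}
#' with \eqn{\hat I = n^{-1} \sum_i s_i s_i'} and the maximum taken over the
#' trimmed range, evaluated at the last index of each block of tied covariate
#' values. For a categorical covariate with levels \eqn{c} the statistic sums
#' the per-level Lagrange-multiplier components
#' \eqn{\sum_c n_c^{-1} S_c' \hat I^{-1} S_c} with
#' \eqn{S_c = \sum_{i \in c} s_i}. P-values come from within-node permutation
#' of the covariate against the (fixed) score rows:
#' `p = (1 + #permuted >= observed) / (n_perm + 1)`. A covariate constant in
#' the node gets statistic 0 and p = 1. An asymptotic chi-square p-value
#' (df = (C-1) k) is also reported for categorical covariates, for reference.
#'
#' @param fit an [aft_fit()] on the node's subjects.
#' @param z covariate values, one per subject of `fit` (same order).
#' @param n_perm permutation draws.
#' @param trim trimming fraction for the ordered scan.
#' @param scores optional precomputed [aft_scores()] matrix.
#' @return a list of class `"instability_test"`: `statistic`, `p`, `kind`,
#'   and `p_chisq` (categorical only).
#' @export
instability_test <- function(fit, z, n_perm = 999, trim = 0.1, scores = NULL) {
  stopifnot(inherits(fit, "aft_fit"), length(z) == fit$n)
  if (is.null(scores)) scores <- aft_scores(fit)
  kind <- covariate_kind(z)
  n <- nrow(scores)
  if (length(unique(z)) < 2L)
    return(structure(list(statistic = 0, p = 1, kind = kind,
                          p_chisq = NA_real_), class = "instability_test"))
  info <- crossprod(scores) / n
  info_inv <- safe_inverse(info)

  if (kind == "numeric") {
    stat_fun <- suplm_factory(z, n, trim, info_inv)
  } else {
    stat_fun <- catlm_factory(z, n, info_inv)
  }
  obs <- stat_fun(scores)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (stat_fun(scores[sample.int(n), , drop = FALSE]) >= obs - 1e-12)
      exceed <- exceed + 1L
  }
  p_chisq <- NA_real_
  if (kind == "categorical") {
    df <- (length(unique(z)) - 1L) * ncol(scores)
    p_chisq <- stats::pchisq(obs, df, lower.tail = FALSE)
  }
  structure(list(statistic = obs, p = (1 + exceed) / (n_perm + 1),
                 kind = kind, p_chisq = p_chisq),
            class = "instability_test")
}

#' @export
print.instability_test <- function(x, ...) {
  cat(sprintf("Score fluctuation test (%s): statistic %.4f, permutation p %.4g\n",
              if (x$kind == "numeric") "supLM" else "summed LM",
              x$statistic, x$p))
  invisible(x)
}

# supLM over the sorted cumulative score process; evaluation indices are the
# ends of tied blocks of the sorted covariate within the trimmed range, so a
# permutation of the covariate amounts to a row shuffle of the score matrix.
suplm_factory <- function(z, n, trim, info_inv) {
  ord <- order(z)
  zs <- z[ord]
  block_end <- which(diff(zs) != 0)  # last index of each tied block (< n)
  lo <- max(floor(trim * n), 1L)
  hi <- n - lo
  idx <- block_end[block_end >= lo & block_end <= hi]
  if (!length(idx)) idx <- block_end  # tiny nodes: fall back to all breaks
  frac <- idx / n
  weight <- 1 / (frac * (1 - frac))
  function(s) {
    cs <- apply(s[ord, , drop = FALSE], 2L, cumsum)
    cs <- cs[idx, , drop = FALSE] / sqrt(n)
    quad <- rowSums((cs %*% info_inv) * cs)
    max(quad * weight)
  }
  # note: `ord` is fixed; permuting the covariate is realized by shuffling s
}

catlm_factory <- function(z, n, info_inv) {
  g <- as.integer(factor(z))
  n_c <- tabulate(g)
  function(s) {
    S_c <- rowsum(s, g)
    sum(rowSums((S_c %*% info_inv) * S_c) / n_c)
  }
}

# Inverse with a pseudo-inverse fallback for near-singular information.
safe_inverse <- function(m) {
  out <- tryCatch(chol2inv(chol(m)), error = function(e) NULL)
  if (!is.null(out)) return(out)
  sv <- svd(m)
  pos <- sv$d > max(sv$d) * 1e-10
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' Likelihood-optimal split point for one partitioning covariate
#'
#' Scans every admissible cutpoint of `covariate` (midpoints of consecutive
#' distinct values for an ordered numeric covariate; level bipartitions for a
#' categorical one, which for a binary covariate is the single forced split),
#' refits the node model on both children, and returns the split maximizing
#' the summed children log-likelihood — equivalently minimizing the tree's
#' negative log-likelihood over its terminal nodes. Cutpoints whose children
#' would violate the size or event floors are not admissible. Ties go to the
#' smaller cutpoint (first bipartition).
#'
#' @param model a model formula for the node fits (Surv response).
#' @param data the node's subjects.
#' @param covariate name of the partitioning covariate in `data`.
#' @param family AFT family of the node models.
#' @param control a [mob_control()].
#' @return `NULL` if no admissible split exists, else a list with `breaks`
#'   (for numeric: the cutpoint; for categorical: the left-child level set),
#'   `kind`, `loglik` (summed children log-likelihood), and the two child
#'   row indices.
#' @export
search_split <- function(model, data, covariate, family = "weibull",
                         control = mob_control()) {
  z <- data[[covariate]]
  if (is.null(z)) stop("no covariate named '", covariate, "'")
  kind <- covariate_kind(z)
  fam <- aft_family(family)
  k_node <- node_k(model, data, fam)
  min_n <- control$min_node_size
  if (is.null(min_n)) min_n <- 10L * k_node

  candidates <- if (kind == "numeric") {
    v <- sort(unique(z))
    (v[-1] + v[-length(v)]) / 2
  } else {
    lev <- sort(unique(as.character(z)))
    if (length(lev) < 2L) return(NULL)
    level_bipartitions(lev)
  }

  best <- NULL
  for (cand in candidates) {
    left <- if (kind == "numeric") z <= cand else as.character(z) %in% cand
    n_l <- sum(left); n_r <- sum(!left)
    if (n_l < min_n || n_r < min_n) next
    if (sum(data$event[left]) < control$min_events ||
        sum(data$event[!left]) < control$min_events) next
    ll <- tryCatch(
      node_fit_quiet(model, data[left, , drop = FALSE], fam)$loglik +
        node_fit_quiet(model, data[!left, , drop = FALSE], fam)$loglik,
      error = function(e) NA_real_)
    if (is.na(ll)) next
    if (is.null(best) || ll > best$loglik + 1e-9) {
      best <- list(breaks = cand, kind = kind, loglik = ll, left = which(left),
                   right = which(!left))
    }
  }
  best
}

# All bipartitions of a level set, each identified by the levels sent left;
# the first level is anchored left to avoid mirror duplicates.
level_bipartitions <- function(lev) {
  others <- lev[-1]
  out <- list()
  for (size in 0:(length(others) - 1L)) {
    for (comb in utils::combn(length(others), size, simplify = FALSE)) {
      out[[length(out) + 1L]] <- c(lev[1L], others[comb])
    }
  }
  out
}

node_k <- function(model, data, fam) {
  X <- stats::model.matrix(stats::delete.response(stats::terms(model, data = data)),
                           utils::head(data, 2L))
  ncol(X) + !fam$scale_fixed
}

# Node fits reject a collapsing scale: a free-scale likelihood is unbounded
# as sigma -> 0 when a handful of events is fit almost exactly, and the
# split search must never reward that degeneracy.
node_fit_quiet <- function(model, data, fam) {
  fit <- suppressWarnings(aft_fit(model, data, family = fam))
  if (!fam$scale_fixed && fit$scale < 1e-3)
    stop("degenerate node fit: scale collapsed to ", format(fit$scale))
  fit
}

#' Grow a model-based recursive partition with AFT node models
#'
#' Implements the four-step growth procedure: (1) fit the node's AFT model
#' (the model covariates) to its subjects; (2) test the fitted parameters'
#' stability along every partitioning covariate with [instability_test()] and
#' pick the covariate with the most significant instability (smallest
#' adjusted p-value, ties broken by the declared covariate order) — if none
#' reaches `alpha` the node is terminal; (3) choose that covariate's split
#' point by maximizing the summed children log-likelihood
#' ([search_split()]); (4) recurse on the children. Variable selection thus
#' uses significance, cutpoint selection uses likelihood — two separate
#' criteria, which avoids the selection bias of exhaustive-search survival
#' trees that test every allowable split on every covariate.
#'
#' @param formula `Surv(time, event) ~ model covariates | partitioning
#'   covariates`, e.g. `Surv(time, event) ~ er + age | her2 + pr + age + er`.
#'   The two sets may overlap.
#' @param data one row per subject.
#' @param family AFT family for every node model, see [aft_family()].
#' @param control a [mob_control()].
#' @return An object of class `"aft_mob"`: the node table (splits, per-node
#'   fits and coefficient tables), tree log-likelihood (summed over terminal
#'   nodes), degrees of freedom (terminal-node parameters plus one per
#'   split), and AIC. Methods: [print.aft_mob()], [predict.aft_mob()],
#'   [logLik.aft_mob()], [mob_to_json()], [mob_to_dot()].
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(n = 600, seed = 7,
#'                                       truth = subgroup_truth()))
#' tr <- aft_mob(survival::Surv(time, event) ~ er + age | her2 + pr + age,
#'               cohort, family = "exponential",
#'               control = mob_control(n_perm = 99))
#' print(tr)
#' }
#' @export
aft_mob <- function(formula, data, family = "weibull",
                    control = mob_control()) {
  fam <- aft_family(family)
  parts <- parse_mob_formula(formula)
  part_vars <- parts$partitioning
  missing_vars <- setdiff(part_vars, names(data))
  if (length(missing_vars))
    stop("partitioning covariate(s) not in data: ",
         paste(missing_vars, collapse = ", "))
  model <- parts$model
  k_node <- node_k(model, data, fam)
  min_n <- control$min_node_size
  if (is.null(min_n)) min_n <- 10L * k_node

  set.seed(control$seed)
  nodes <- list()
  fits <- list()
  next_id <- 1L

  grow <- function(idx, depth, parent) {
    id <- next_id; next_id <<- next_id + 1L
    d <- data[idx, , drop = FALSE]
    fit <- tryCatch(node_fit_quiet(model, d, fam), error = function(e) e)
    if (inherits(fit, "error")) {
      if (is.null(parent)) stop("root model failed: ",
                                conditionMessage(fit))
      stop("node model failed on a searched child; this should not happen: ",
           conditionMessage(fit))
    }
    node <- list(id = id, parent = parent, depth = depth, n = nrow(d),
                 n_events = sum(d$event), terminal = TRUE,
                 split_var = NULL, split_kind = NULL, breaks = NULL,
                 instability = NULL, coef = fit$coefficients,
                 scale = fit$scale, loglik = fit$loglik, k = fit$k,
                 converged = fit$converged,
                 coef_table = summary(fit)$coefficients)
    fits[[id]] <<- fit
    if (control$verbose)
      message(sprintf("node %d (depth %d): n=%d, events=%d", id, depth,
                      nrow(d), sum(d$event)))

    can_split <- depth < control$max_depth &&
      nrow(d) >= 2L * min_n && sum(d$event) >= 2L * control$min_events &&
      fit$converged
    if (!fit$converged)
      warning(sprintf("node %d model did not converge; made terminal", id))

    if (can_split) {
      sc <- aft_scores(fit)
      tests <- lapply(part_vars, function(v)
        instability_test(fit, d[[v]], n_perm = control$n_perm,
                         trim = control$trim, scores = sc))
      p_raw <- vapply(tests, `[[`, numeric(1), "p")
      m <- length(part_vars)
      p_adj <- if (control$bonferroni) pmin(1, p_raw * m) else p_raw
      node$instability <- data.frame(
        covariate = part_vars,
        statistic = vapply(tests, `[[`, numeric(1), "statistic"),
        p = p_raw, p_adj = p_adj, stringsAsFactors = FALSE)
      sel <- select_split_variable(node$instability, control$alpha)
      if (!is.null(sel)) {
        sp <- search_split(model, d, sel, family = fam, control = control)
        if (!is.null(sp)) {
          node$terminal <- FALSE
          node$split_var <- sel
          node$split_kind <- sp$kind
          node$breaks <- sp$breaks
          nodes[[id]] <<- node
          left_id <- grow(idx[sp$left], depth + 1L, id)
          right_id <- grow(idx[sp$right], depth + 1L, id)
          nodes[[id]]$children <<- c(left_id, right_id)
          return(id)
        }
      }
    }
    nodes[[id]] <<- node
    id
  }
  grow(seq_len(nrow(data)), 0L, NULL)

  terminal_ids <- which(vapply(nodes, `[[`, logical(1), "terminal"))
  loglik <- sum(vapply(nodes[terminal_ids], `[[`, numeric(1), "loglik"))
  df <- sum(vapply(nodes[terminal_ids], `[[`, numeric(1), "k")) +
    (length(terminal_ids) - 1L)
  structure(list(
    nodes = nodes, fits = fits, terminal_ids = terminal_ids,
    loglik = loglik, df = df, aic = -2 * loglik + 2 * df,
    family = fam, model = model,
    model_rhs = deparse(parts$model_rhs),
    partitioning = part_vars, control = control, n = nrow(data),
    call = match.call()
  ), class = "aft_mob")
}

# Smallest adjusted p wins, ties broken by declared covariate order (the
# table's row order); NULL when nothing reaches alpha.
select_split_variable <- function(instability, alpha) {
  p <- instability$p_adj
  if (min(p) > alpha) return(NULL)
  instability$covariate[which.min(p)]
}

# "Surv(...) ~ model terms | partitioning terms"
parse_mob_formula <- function(formula) {
  rhs <- formula[[3L]]
  if (!(is.call(rhs) && identical(rhs[[1L]], as.name("|"))))
    stop("formula must have the form response ~ model terms | partitioning terms")
  model_rhs <- rhs[[2L]]
  part_rhs <- rhs[[3L]]
  model <- formula
  model[[3L]] <- model_rhs
  part_formula <- stats::as.formula(call("~", part_rhs),
                                    env = environment(formula))
  list(model = model, model_rhs = model_rhs,
       partitioning = all.vars(part_rhs))
}

#' Tree parameter counting
#'
#' The degrees of freedom of a fitted tree: the free parameters of the node
#' model summed over terminal nodes, plus one per split. For binary splits
#' this is `terminals * k_node + (terminals - 1)`; e.g. a two-terminal-node
#' Weibull tree with intercept, two regressors and a scale in each node
#' (k = 4) and one split has 9 parameters.
#'
#' @param terminals number of terminal nodes.
#' @param k_node free parameters of one node model.
#' @param splits number of splits (defaults to `terminals - 1`, the binary
#'   case).
#' @return the integer parameter count.
#' @export
tree_parameters <- function(terminals, k_node, splits = terminals - 1) {
  terminals * k_node + splits
}

#' @export
logLik.aft_mob <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n, class = "logLik")
}

#' @export
nobs.aft_mob <- function(object, ...) object$n
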