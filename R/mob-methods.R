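#' @export
print.aft_mob <- function(x, digits = 3, ...) {
  cat("AFT model-based recursive partition (", x$family$name, ")\n", sep = "")
  cat("Model: ", deparse(x$model), "\n", sep = "")
  cat("Partitioning covariates: ", paste(x$partitioning, collapse = ", "),
      "\n\n", sep = "")
  render <- function(id, prefix) {
    nd <- x$nodes[[id]]
    if (nd$terminal) {
      stars <- sig_stars(nd$coef_table[, "Pr(>|z|)"])
      lab <- paste(sprintf("%s=%s%s", rownames(nd$coef_table),
                           format(round(nd$coef_table[, "Estimate"], digits),
                                  trim = TRUE), stars), collapse = ", ")
      cat(sprintf("%s[%d] * n=%d (%d events): %s\n", prefix, nd$id, nd$n,
                  nd$n_events, lab))
    } else {
      p_line <- ""
      if (!is.null(nd$instability)) {
        row <- nd$instability[nd$instability$covariate == nd$split_var, ]
        p_line <- sprintf(" (p=%.4g)", row$p_adj)
      }
      cat(sprintf("%s[%d] split on %s%s\n", prefix, nd$id, nd$split_var,
                  p_line))
      labs <- split_labels(nd)
      kids <- nd$children
      cat(sprintf("%s|-- %s\n", prefix, labs[1]))
      render(kids[1], paste0(prefix, "|   "))
      cat(sprintf("%s`-- %s\n", prefix, labs[2]))
      render(kids[2], paste0(prefix, "    "))
    }
  }
  render(1L, "")
  cat(sprintf("\nTerminal nodes: %d  Log-likelihood: %s  df: %d  AIC: %s\n",
              length(x$terminal_ids), format(x$loglik, digits = digits + 4),
              x$df, format(x$aic, digits = digits + 4)))
  cat("* significant at 5% level; ** at 1% level (per-node Wald tests,\n",
      "  unadjusted for tree selection)\n", sep = "")
  invisible(x)
}

split_labels <- function(node) {
  if (node$split_kind == "numeric") {
    c(sprintf("%s <= %g", node$split_var, node$breaks),
      sprintf("%s > %g", node$split_var, node$breaks))
  } else {
    c(sprintf("%s in {%s}", node$split_var,
              paste(node$breaks, collapse = ", ")),
      sprintf("%s not in {%s}", node$split_var,
              paste(node$breaks, collapse = ", ")))
  }
}

#' Route subjects down a fitted tree and predict survival times
#'
#' Each subject is routed deterministically by the split rules to exactly one
#' terminal node; the prediction comes from that node's AFT fit. No surrogate
#' splits: a missing partitioning covariate is an error.
#'
#' @param object an [aft_mob()] (or a tree reloaded by [mob_from_json()]).
#' @param newdata covariates including every partitioning and model covariate.
#' @param type `"median"` (default), `"mean"`, `"lp"`, or `"node"` for the
#'   terminal node id alone.
#' @param ... unused.
#' @return A data frame with columns `node` (terminal node id) and, unless
#'   `type = "node"`, `pred` (predicted time in years, or the linear
#'   predictor).
#' @export
predict.aft_mob <- function(object, newdata,
                            type = c("median", "mean", "lp", "node"), ...) {
  type <- match.arg(type)
  needed <- unique(c(object$partitioning,
                     all.vars(stats::as.formula(paste("~", object$model_rhs)))))
  missing_vars <- setdiff(needed, names(newdata))
  if (length(missing_vars))
    stop("missing covariate(s): ", paste(missing_vars, collapse = ", "))
  node <- integer(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    id <- 1L
    repeat {
      nd <- object$nodes[[id]]
      if (nd$terminal) break
      v <- newdata[[nd$split_var]][i]
      if (is.na(v)) stop("missing value in split covariate '", nd$split_var,
                         "' (no surrogate splits)")
      left <- if (nd$split_kind == "numeric") v <= nd$breaks
              else as.character(v) %in% nd$breaks
      id <- nd$children[if (left) 1L else 2L]
    }
    node[i] <- id
  }
  if (type == "node") return(data.frame(node = node))
  X <- stats::model.matrix(stats::as.formula(paste("~", object$model_rhs)),
                           newdata)
  pred <- numeric(nrow(newdata))
  fam <- object$family
  for (id in unique(node)) {
    nd <- object$nodes[[id]]
    rows <- node == id
    lp <- drop(X[rows, names(nd$coef), drop = FALSE] %*% nd$coef)
    pred[rows] <- switch(type,
      lp = lp,
      median = exp(lp) * fam$median_factor(nd$scale),
      mean = exp(lp) * fam$mean_factor(nd$scale))
  }
  data.frame(node = node, pred = pred)
}

#' Serialize a tree as structured text (JSON) and reload it
#'
#' The JSON carries everything routing and prediction need: the family, the
#' node-model right-hand side, and per node the split rule, subject counts,
#' coefficients, scale, log-likelihood and the coefficient test table.
#' `mob_from_json()` reconstructs an `"aft_mob"` object whose predictions are
#' identical to the original's on any data (the full node fits, with their
#' covariance matrices and score machinery, are not serialized).
#'
#' @param tree an [aft_mob()].
#' @param file optional path; when `NULL` the JSON string is returned.
#' @return `mob_to_json()`: the JSON string (invisibly when written to file);
#'   `mob_from_json()`: an `"aft_mob"` object.
#' @export
mob_to_json <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "aft_mob"))
  nodes <- lapply(tree$nodes, function(nd) {
    ct <- nd$coef_table
    list(id = nd$id, parent = nd$parent, depth = nd$depth, n = nd$n,
         n_events = nd$n_events, terminal = nd$terminal,
         split_var = nd$split_var, split_kind = nd$split_kind,
         breaks = nd$breaks, children = nd$children,
         coef = as.list(nd$coef), scale = nd$scale, loglik = nd$loglik,
         k = nd$k, converged = nd$converged,
         coef_table = cbind(data.frame(term = rownames(ct)),
                            as.data.frame(ct, row.names = NULL)),
         instability = nd$instability)
  })
  obj <- list(format = "mobaft-tree", version = 1L,
              family = tree$family$name, model_rhs = tree$model_rhs,
              partitioning = tree$partitioning, n = tree$n,
              loglik = tree$loglik, df = tree$df, aic = tree$aic,
              nodes = nodes)
  # I(17) significant digits: doubles round-trip exactly through the text
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                          null = "null", pretty = TRUE)
  if (is.null(file)) return(as.character(txt))
  writeLines(txt, file)
  invisible(as.character(txt))
}

#' @rdname mob_to_json
#' @param x a JSON string or the path of a file written by [mob_to_json()].
#' @export
mob_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyDataFrame = FALSE,
                            simplifyVector = TRUE)
  if (!identical(obj$format, "mobaft-tree"))
    stop("not a serialized mobaft tree")
  nodes <- lapply(obj$nodes, function(nd) {
    ct <- NULL
    if (!is.null(nd$coef_table)) {
      cd <- as.data.frame(do.call(rbind, lapply(nd$coef_table, as.data.frame)))
      ct <- as.matrix(cd[setdiff(names(cd), "term")])
      rownames(ct) <- cd$term
    }
    inst <- if (!is.null(nd$instability))
      as.data.frame(do.call(rbind, lapply(nd$instability, as.data.frame)))
    list(id = nd$id, parent = nd$parent, depth = nd$depth, n = nd$n,
         n_events = nd$n_events, terminal = nd$terminal,
         split_var = nd$split_var, split_kind = nd$split_kind,
         breaks = nd$breaks, children = nd$children,
         coef = unlist(nd$coef), scale = nd$scale, loglik = nd$loglik,
         k = nd$k, converged = nd$converged, coef_table = ct,
         instability = inst)
  })
  terminal_ids <- which(vapply(nodes, `[[`, logical(1), "terminal"))
  structure(list(
    nodes = nodes, fits = NULL, terminal_ids = terminal_ids,
    loglik = obj$loglik, df = obj$df, aic = obj$aic,
    family = aft_family(obj$family),
    model = stats::as.formula(paste("~", obj$model_rhs)),
    model_rhs = obj$model_rhs, partitioning = obj$partitioning,
    control = NULL, n = obj$n, call = NULL
  ), class = "aft_mob")
}

#' Export a tree in DOT format for graph rendering
#'
#' Internal nodes are labeled by the split covariate and its adjusted
#' instability p-value; edges by the split rule; terminal nodes by their
#' subject/event counts and the node coefficients with significance stars.
#'
#' @param tree an [aft_mob()].
#' @param file optional path; when `NULL` the DOT source is returned.
#' @return the DOT source string (invisibly when written to file).
#' @export
mob_to_dot <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "aft_mob"))
  lines <- c("digraph mobaft_tree {",
             "  node [shape=box, fontname=\"Helvetica\"];")
  for (nd in tree$nodes) {
    if (nd$terminal) {
      stars <- sig_stars(nd$coef_table[, "Pr(>|z|)"])
      coefs <- paste(sprintf("%s = %.3g%s", rownames(nd$coef_table),
                             nd$coef_table[, "Estimate"], stars),
                     collapse = "\\n")
      lab <- sprintf("node %d\\nn = %d (%d events)\\n%s", nd$id, nd$n,
                     nd$n_events, coefs)
      lines <- c(lines, sprintf("  n%d [label=\"%s\", style=filled, fillcolor=gray92];",
                                nd$id, lab))
    } else {
      row <- nd$instability[nd$instability$covariate == nd$split_var, ]
      lab <- sprintf("%s\\np = %.4g", nd$split_var, row$p_adj)
      lines <- c(lines, sprintf("  n%d [label=\"%s\"];", nd$id, lab))
      labs <- gsub("\"", "\\\\\"", split_labels(nd))
      lines <- c(lines,
                 sprintf("  n%d -> n%d [label=\"%s\"];", nd$id,
                         nd$children[1], labs[1]),
                 sprintf("  n%d -> n%d [label=\"%s\"];", nd$id,
                         nd$children[2], labs[2]))
    }
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
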