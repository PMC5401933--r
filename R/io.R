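# Condition helpers: distinct classes let the CLI map failures to exit codes.
stop_config <- function(...) {
  stop(structure(class = c("mobaft_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
stop_data <- function(...) {
  stop(structure(class = c("mobaft_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Read and write cohort CSV files
#'
#' The interchange format is a comma-separated file with header
#' `time,event,age,er,pr,her2`, UTF-8, `.` decimal separator; `event` is
#' strictly 0 (right-censored) or 1 (event observed) and `time` strictly
#' positive. Validation failures name the offending column or the 1-based
#' data line.
#'
#' @param records a cohort data frame.
#' @param path file path.
#' @return `read_cohort_csv()` returns the validated data frame;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stop_data("malformed CSV: ",
                                              conditionMessage(e)))
  required <- c("time", "event")
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop_data("missing required column(s): ", paste(miss, collapse = ", "))
  for (v in intersect(c("time", "event", "age", "er", "pr", "her2"),
                      names(d))) {
    if (!is.numeric(d[[v]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(d[[v]]))))[1L]
      stop_data("column '", v, "': non-numeric value at data line ", bad)
    }
  }
  if (anyNA(d$time) || anyNA(d$event))
    stop_data("missing values in time/event at data line ",
              which(is.na(d$time) | is.na(d$event))[1L])
  bad <- which(!(d$event %in% c(0, 1)))
  if (length(bad))
    stop_data("column 'event': value not in {0,1} at data line ", bad[1L])
  bad <- which(d$time <= 0)
  if (length(bad))
    stop_data("column 'time': nonpositive value at data line ", bad[1L])
  d
}

#' Read a run configuration file
#'
#' Run configurations are YAML with up to five top-level sections — `seed`,
#' `verbosity`, and the subcommand sections `cohort`, `model`, `tree`,
#' `report` — validated strictly: unknown keys anywhere are a configuration
#' error, so typos never pass silently.
#'
#' @param path YAML file path.
#' @return a validated named list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("no such config file: ", path)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_config("invalid YAML: ",
                                                  conditionMessage(e)))
  if (is.null(cfg)) cfg <- list()
  check_keys(cfg, c("seed", "verbosity", "cohort", "model", "tree", "report"),
             "top level")
  # n_subjects rather than n: YAML 1.1 resolves a bare `n` key to a boolean
  check_keys(cfg$cohort, c("n_subjects", "seed", "age_model", "prevalences",
                           "marker_cor", "truth", "censor_model", "admin_cap"),
             "cohort")
  check_keys(cfg$cohort$age_model, c("mean", "sd", "min", "max", "integer"),
             "cohort.age_model")
  check_keys(cfg$cohort$censor_model, c("dist", "rate", "target"),
             "cohort.censor_model")
  check_keys(cfg$model, c("family", "covariates"), "model")
  check_keys(cfg$tree, c("family", "model_covariates",
                         "partitioning_covariates", "alpha", "bonferroni",
                         "min_node_size", "min_events", "max_depth", "trim",
                         "n_perm"), "tree")
  check_keys(cfg$report, c("formats"), "report")
  structure(cfg, class = "run_config")
}

check_keys <- function(x, allowed, where) {
  if (is.null(x)) return(invisible())
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop_config("unknown config key(s) at ", where, ": ",
                paste(unknown, collapse = ", "))
  invisible()
}

config_cohort_spec <- function(cfg, seed = NULL) {
  cc <- if (is.null(cfg$cohort)) list() else cfg$cohort
  truth <- if (is.null(cc$truth) || identical(cc$truth, "homogeneous"))
    homogeneous_truth()
  else if (identical(cc$truth, "subgroup")) subgroup_truth()
  else stop_config("unknown truth '", cc$truth,
                   "' (use 'homogeneous' or 'subgroup')")
  args <- list(truth = truth)
  if (!is.null(cc$n_subjects)) args$n <- cc$n_subjects
  args$seed <- if (!is.null(seed)) seed else
    if (!is.null(cc$seed)) cc$seed else
    if (!is.null(cfg$seed)) cfg$seed else 1L
  for (nm in c("age_model", "censor_model", "admin_cap"))
    if (!is.null(cc[[nm]])) args[[nm]] <- cc[[nm]]
  if (!is.null(cc$prevalences)) args$prevalences <- unlist(cc$prevalences)
  if (!is.null(cc$marker_cor))
    args$marker_cor <- matrix(unlist(cc$marker_cor), 3, 3)
  tryCatch(do.call(cohort_spec, args),
           error = function(e) stop_config(conditionMessage(e)))
}

config_model_formula <- function(cfg) {
  covs <- cfg$model$covariates
  if (is.null(covs)) covs <- c("age", "er", "pr", "her2")
  stats::as.formula(paste("survival::Surv(time, event) ~",
                          paste(covs, collapse = " + ")))
}

config_tree_pieces <- function(cfg, seed = NULL) {
  tc <- if (is.null(cfg$tree)) list() else cfg$tree
  model_covs <- if (is.null(tc$model_covariates)) c("er", "age")
                else tc$model_covariates
  part_covs <- if (is.null(tc$partitioning_covariates))
    c("her2", "pr", "age", "er") else tc$partitioning_covariates
  fmla <- stats::as.formula(paste(
    "survival::Surv(time, event) ~", paste(model_covs, collapse = " + "),
    "|", paste(part_covs, collapse = " + ")))
  args <- tc[intersect(names(tc), c("alpha", "bonferroni", "min_node_size",
                                    "min_events", "max_depth", "trim",
                                    "n_perm"))]
  args$seed <- if (!is.null(seed)) seed else
    if (!is.null(cfg$seed)) cfg$seed else 1L
  ctrl <- tryCatch(do.call(mob_control, args),
                   error = function(e) stop_config(conditionMessage(e)))
  family <- if (is.null(tc$family)) "exponential" else tc$family
  list(formula = fmla, control = ctrl, family = family)
}
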