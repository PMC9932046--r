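#' Validate a user-supplied data frame into a mediation dataset
#'
#' Checks the declared time/event/exposure columns and coerces the remaining
#' numeric columns into the covariate pool. Violations are reported as
#' itemized errors; zero-variance covariate columns are dropped with a
#' message.
#'
#' @param table A data.frame (e.g. read from CSV).
#' @param time,event,exposure Column names of the survival time, event
#'   indicator and binary exposure.
#' @param id Optional id column name to exclude from the covariate pool.
#' @return A `mediation_data` (with `truth = NULL`).
#' @export
validate_input <- function(table, time = "time", event = "event",
                           exposure = "exposure", id = NULL) {
  errs <- character(0)
  for (col in c(time, event, exposure))
    if (!col %in% names(table))
      errs <- c(errs, sprintf("missing required column '%s'", col))
  if (length(errs)) stop("invalid input:\n  - ",
                         paste(errs, collapse = "\n  - "))
  tt <- table[[time]]
  ev <- table[[event]]
  xx <- table[[exposure]]
  if (anyNA(table)) errs <- c(errs, "missing values are not allowed")
  if (!all(ev %in% c(0, 1), na.rm = TRUE))
    errs <- c(errs, "event indicator must be coded 0/1")
  if (!all(xx %in% c(0, 1), na.rm = TRUE))
    errs <- c(errs, "exposure must be coded 0/1")
  if (any(tt <= 0, na.rm = TRUE))
    errs <- c(errs, "survival times must be strictly positive")
  if (length(errs)) stop("invalid input:\n  - ",
                         paste(errs, collapse = "\n  - "))
  drop_cols <- c(time, event, exposure, id)
  covs <- table[, setdiff(names(table), drop_cols), drop = FALSE]
  nonnum <- names(covs)[!vapply(covs, is.numeric, logical(1))]
  if (length(nonnum))
    stop("invalid input:\n  - non-numeric covariate column(s): ",
         paste(nonnum, collapse = ", "))
  covs <- as.matrix(covs)
  s <- apply(covs, 2, sd)
  if (any(s < 1e-10)) {
    message("dropping ", sum(s < 1e-10), " zero-variance covariate column(s)")
    covs <- covs[, s >= 1e-10, drop = FALSE]
  }
  structure(list(time = as.numeric(tt), event = as.integer(ev),
                 exposure = as.integer(xx), covariates = covs,
                 hidden_confounders = NULL, truth = NULL),
            class = "mediation_data")
}

#' Write a mediation dataset to CSV (plus a JSON truth sidecar)
#'
#' Columns are `id, time, event, exposure, V0001, ...`. When the dataset
#' carries simulation truth, a `<path>.truth.json` sidecar records the true
#' instrument/mediator columns and the generating configuration.
#'
#' @param data A `mediation_data`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mediation_data <- function(data, path) {
  df <- data.frame(id = seq_along(data$time), time = data$time,
                   event = data$event, exposure = data$exposure)
  df <- cbind(df, as.data.frame(data$covariates))
  write.csv(df, path, row.names = FALSE)
  if (!is.null(data$truth)) {
    truth <- data$truth
    cfg <- truth$config
    cfg <- cfg[!vapply(cfg, is.null, logical(1))]
    jsonlite::write_json(
      list(true_ivs = truth$iv_cols, true_mediators = truth$mediator_cols,
           all_structured = truth$all_structured, lambda = truth$lambda,
           gamma = truth$gamma, indirect = truth$indirect,
           config = unclass(cfg)),
      paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a mediation dataset written by [write_mediation_data()]
#'
#' @param path CSV path; a `<path>.truth.json` sidecar is restored when
#'   present.
#' @return A `mediation_data`.
#' @export
read_mediation_data <- function(path) {
  df <- read.csv(path)
  data <- validate_input(df, id = "id")
  sidecar <- paste0(path, ".truth.json")
  if (file.exists(sidecar)) {
    tr <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    data$truth <- list(iv_cols = tr$true_ivs,
                       mediator_cols = tr$true_mediators,
                       all_structured = tr$all_structured,
                       lambda = tr$lambda, gamma = tr$gamma,
                       indirect = tr$indirect, config = tr$config)
  }
  data
}

#' Export the per-mediator results table of a pipeline run as CSV
#'
#' @param result An `ivmed_result`.
#' @param path Output CSV path.
#' @param positive_only Restrict to mediators with positive indirect
#'   estimates (reporting convention for methylation-style analyses);
#'   defaults to the pipeline configuration.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(result, path,
                              positive_only = result$config$positive_only) {
  tab <- result$tests
  if (is.null(tab)) tab <- data.frame()
  if (isTRUE(positive_only) && nrow(tab)) tab <- tab[tab$indirect > 0, ]
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
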