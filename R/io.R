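## CSV dataset exchange and configuration profiles.

#' Write a dataset to paired CSV files
#'
#' Long-format longitudinal file (`subject_id`, `time`, `value`, `x1`,
#' `x2`) and one-row-per-subject survival file (`subject_id`,
#' `observed_time`, `event`, `x1`, `x2`, plus simulation truth columns
#' when present).  UTF-8, header row, '.' decimal separator.
#'
#' @param data an `lcj_data` object (or compatible list).
#' @param longitudinal_file,survival_file output paths.
#' @export
write_dataset <- function(data, longitudinal_file, survival_file) {
  write.csv(data$longitudinal, longitudinal_file, row.names = FALSE,
            fileEncoding = "UTF-8")
  write.csv(data$survival, survival_file, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(data)
}

#' Read a dataset from paired CSV files
#'
#' @param longitudinal_file,survival_file paths written by
#'   [write_dataset()] or user files in the same layout.
#' @return an `lcj_data` object (without design/parameter metadata).
#' @export
read_dataset <- function(longitudinal_file, survival_file) {
  long <- read.csv(longitudinal_file, fileEncoding = "UTF-8")
  surv <- read.csv(survival_file, fileEncoding = "UTF-8")
  need_l <- c("subject_id", "time", "value")
  need_s <- c("subject_id", "observed_time", "event")
  if (!all(need_l %in% names(long)))
    stop("longitudinal file needs columns: ", paste(need_l, collapse = ", "))
  if (!all(need_s %in% names(surv)))
    stop("survival file needs columns: ", paste(need_s, collapse = ", "))
  structure(list(longitudinal = long, survival = surv),
            class = "lcj_data")
}

#' Write a simulation profile to JSON or YAML
#'
#' Serialises an [lcj_parameters()] / [lcj_design()] pair; the format is
#' chosen from the file extension (`.json` default, `.yaml`/`.yml` needs
#' the yaml package).
#'
#' @param params,design the profile to store.
#' @param file output path.
#' @export
write_config <- function(params, design, file) {
  cfg <- list(parameters = unclass(params), design = unclass(design))
  if (grepl("\\.ya?ml$", file)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML output")
    writeLines(yaml::as.yaml(cfg), file)
  } else {
    jsonlite::write_json(cfg, file, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
  }
  invisible(file)
}

#' Read a simulation profile from JSON or YAML
#'
#' @param file path written by [write_config()].
#' @return list with validated `params` and `design`.
#' @export
read_config <- function(file) {
  cfg <- if (grepl("\\.ya?ml$", file)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML input")
    yaml::read_yaml(file)
  } else {
    jsonlite::read_json(file, simplifyVector = TRUE)
  }
  p <- cfg$parameters
  as_mat <- function(m, nr) {
    if (is.matrix(m)) m
    else if (is.list(m)) do.call(rbind, lapply(m, unlist))
    else matrix(unlist(m), nrow = nr, byrow = TRUE)
  }
  params <- lcj_parameters(
    n_classes = p$n_classes,
    membership = as_mat(p$membership, max(p$n_classes - 1, 1)),
    beta = as_mat(p$beta, p$n_classes),
    ranef_variance = p$ranef_variance, resid_variance = p$resid_variance,
    treatment_effect = p$treatment_effect, association = p$association,
    weibull_shape = p$weibull_shape, weibull_scale = p$weibull_scale)
  d <- cfg$design
  design <- lcj_design(d$n_subjects, d$measurement_grid, d$censoring_offset,
                       d$censoring_width, d$seed,
                       d$drop_post_event_measurements)
  list(params = params, design = design)
}
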