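#' Read a bottle-observation CSV
#'
#' Validates the schema on read: all required columns present, roles and
#' populations among the allowed values, fractions in (0, 1], positive
#' incubation lengths and non-negative counts. Errors name the offending
#' column or row.
#'
#' @param path CSV path with one header row (UTF-8).
#' @return a \code{bottle_observation} data.frame.
#' @export
read_bottles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("scenario" %in% names(df))
    df$scenario <- as.character(df$scenario)  # all-NA column reads as logical
  new_bottles(df[, intersect(c(bottle_columns,
                               setdiff(names(df), bottle_columns)),
                             names(df)), drop = FALSE])
}

#' Write bottle observations to CSV
#'
#' @param bottles a \code{bottle_observation} data.frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_bottles <- function(bottles, path) {
  validate_bottles(bottles)
  utils::write.csv(as.data.frame(bottles), path, row.names = FALSE)
  invisible(path)
}

#' Collect rate estimates into a table
#'
#' @param estimates a list of \code{\link{rate_estimate}} objects.
#' @param scenario,treatment metadata columns recycled across rows.
#' @return data.frame with columns method, value, se, n, detectable, p,
#'   raw_value, t0, t1, mean_log10_P, treatment, scenario.
#' @export
rates_to_df <- function(estimates, scenario = NA_character_,
                        treatment = NA_character_) {
  if (inherits(estimates, "rate_estimate")) estimates <- list(estimates)
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(method = e$method, value = e$value, se = e$se, n = e$n,
               detectable = e$detectable, p = e$p,
               raw_value = e$raw_value,
               t0 = e$window[1], t1 = e$window[2],
               mean_log10_P = e$mean_log10_P,
               treatment = treatment, scenario = scenario,
               stringsAsFactors = FALSE)
  }))
}

#' Write a rate table to CSV
#' @param rates data.frame (e.g. from \code{\link{rates_to_df}}).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_rates <- function(rates, path) {
  utils::write.csv(rates, path, row.names = FALSE)
  invisible(path)
}

#' Read a rate table from CSV
#' @param path CSV path.
#' @return data.frame.
#' @export
read_rates <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

config_schema <- list(
  scenario = "character",
  params = "list",      # overrides; keys must be community_params fields
  sampling = c("analyzed_volume", "noise", "seed"),
  estimator = c("alpha", "fractions", "tracer_fraction",
                "tracer_abundance", "duration", "replicates"),
  comparison = c("iqr_k", "reference_log10", "window_lo", "window_hi",
                 "bin_width", "adjust"),
  seed = "numeric",
  out_dir = "character")

#' Read and validate a run configuration
#'
#' YAML configuration with sections \code{scenario}, \code{params}
#' (overrides of \code{\link{community_params}} fields, same key names),
#' \code{sampling}, \code{estimator}, \code{comparison}, \code{seed} and
#' \code{out_dir}. Unknown keys anywhere are rejected so silent typos
#' cannot change a run. Missing keys fall back to package defaults;
#' \code{seed} defaults to 0.
#'
#' @param path YAML file path.
#' @return validated configuration list with class \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(cfg$params)) {
    allowed <- names(formals(community_params))
    bad <- setdiff(names(cfg$params), allowed)
    if (length(bad))
      stop("unknown params key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  for (sect in c("sampling", "estimator", "comparison")) {
    if (!is.null(cfg[[sect]])) {
      bad <- setdiff(names(cfg[[sect]]), config_schema[[sect]])
      if (length(bad))
        stop("unknown ", sect, " key(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    }
  }
  if (is.null(cfg$seed)) cfg$seed <- 0L
  structure(cfg, class = "run_config")
}

#' Write the resolved configuration next to run outputs
#'
#' @param cfg a \code{run_config} (or plain list).
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write a field/lab report as JSON
#'
#' Serializes summary tables and test statistics to a plain-text JSON
#' report for downstream consumption.
#'
#' @param report a list (e.g. from \code{\link{field_report}}).
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
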