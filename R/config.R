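# Pipeline configuration: study window, pairing rules, thresholds.
# Defaults reproduce the published analysis settings.

#' Pipeline configuration
#'
#' All knobs of the record-to-assessment pipeline with their default values.
#' "12 months" is implemented as 365 actual days (no calendar-month
#' arithmetic).
#'
#' @param study_start,study_end study window (inclusive); records dated
#'   outside are excluded.
#' @param pairing_window_days maximum days between index creatinine and a
#'   urinary result for the pair to count.
#' @param pairing_direction `"both"` (symmetric, default), `"after"` (urinary
#'   on/after index only) or `"before"`.
#' @param diabetes_window_days lookup window for glycemic results around the
#'   index date (symmetric).
#' @param hba1c_threshold flag diabetes when HbA1c is strictly above this (%).
#' @param glucose_threshold flag diabetes when serum glucose is strictly
#'   above this (mg/dL).
#' @param require_chronicity if `TRUE`, eGFR-based CKD additionally requires a
#'   confirmatory eGFR < 60 at least `chronicity_days` after the index
#'   (otherwise downgraded to `indeterminate`). Default `FALSE`: single
#'   assessments classify, matching the source analysis.
#' @param chronicity_days minimum persistence for the chronicity rule.
#' @param condition_on_retest if `TRUE`, Kaplan-Meier curves are computed only
#'   among patients with at least one follow-up creatinine (the conditional
#'   variant used for plotted retest curves); default `FALSE` keeps all
#'   indexed patients with administrative censoring.
#' @param min_stratum_n strata smaller than this are flagged in KM output.
#' @return a named list of class `ckdlabscan_config`.
#' @export
pipeline_config <- function(study_start = "2018-06-01",
                            study_end = "2021-05-31",
                            pairing_window_days = 365L,
                            pairing_direction = c("both", "after", "before"),
                            diabetes_window_days = 365L,
                            hba1c_threshold = 6.5,
                            glucose_threshold = 200,
                            require_chronicity = FALSE,
                            chronicity_days = 90L,
                            condition_on_retest = FALSE,
                            min_stratum_n = 50L) {
  pairing_direction <- match.arg(pairing_direction)
  cfg <- list(
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    pairing_window_days = as.integer(pairing_window_days),
    pairing_direction = pairing_direction,
    diabetes_window_days = as.integer(diabetes_window_days),
    hba1c_threshold = as.numeric(hba1c_threshold),
    glucose_threshold = as.numeric(glucose_threshold),
    require_chronicity = isTRUE(require_chronicity),
    chronicity_days = as.integer(chronicity_days),
    condition_on_retest = isTRUE(condition_on_retest),
    min_stratum_n = as.integer(min_stratum_n)
  )
  if (is.na(cfg$study_start) || is.na(cfg$study_end) ||
      cfg$study_start > cfg$study_end) {
    stop("study_start must be a date on or before study_end", call. = FALSE)
  }
  if (cfg$pairing_window_days < 0 || cfg$diabetes_window_days < 0) {
    stop("window lengths must be non-negative", call. = FALSE)
  }
  class(cfg) <- c("ckdlabscan_config", "list")
  cfg
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; missing keys keep their
#' defaults. YAML files need the optional `yaml` package.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return a `ckdlabscan_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package; ",
           "use JSON instead", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' @export
print.ckdlabscan_config <- function(x, ...) {
  cat("<ckdlabscan pipeline config>\n")
  cat(sprintf("  study window      : %s .. %s\n", x$study_start, x$study_end))
  cat(sprintf("  pairing           : +/-%d days (%s)\n",
              x$pairing_window_days, x$pairing_direction))
  cat(sprintf("  diabetes          : HbA1c > %.1f%% or glucose > %.0f mg/dL, +/-%d d\n",
              x$hba1c_threshold, x$glucose_threshold, x$diabetes_window_days))
  cat(sprintf("  chronicity rule   : %s\n",
              if (x$require_chronicity) sprintf("on (>= %d d)", x$chronicity_days) else "off"))
  invisible(x)
}
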