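# Stage-stratified cumulative incidence of a repeat creatinine measurement:
# one minus the Kaplan-Meier product-limit survival estimate, with
# administrative censoring at the study close date. Standard tie convention:
# subjects censored at time t are still at risk for events at t.

#' Follow-up observations for the retest-incidence analysis
#'
#' For each indexed patient: time to the first creatinine on a strictly
#' later date than the index (event), or time to the study close date
#' (censored). Same-day repeats do not count as events.
#'
#' @param assessments assessment table from [build_assessments()].
#' @param creatinine_records creatinine lab records (the `records` element of
#'   [build_assessments()] works; other test types are ignored).
#' @param study_end administrative censoring date.
#' @return data.table with `patient_id`, `g_stage`, `time` (days) and
#'   `event` (logical).
#' @export
make_followup_observations <- function(assessments, creatinine_records,
                                       study_end) {
  a <- data.table::as.data.table(assessments)
  cre <- data.table::as.data.table(creatinine_records)
  cre <- cre[test_type == "creatinine",
             list(patient_id, collection_date = as.Date(collection_date))]
  study_end <- as.Date(study_end)

  cre <- merge(cre, a[, list(patient_id, index_date)], by = "patient_id")
  nxt <- cre[collection_date > index_date,
             list(first_retest = min(collection_date)), by = patient_id]
  obs <- merge(a[, list(patient_id, g_stage, index_date)], nxt,
               by = "patient_id", all.x = TRUE)
  obs[, event := !is.na(first_retest)]
  obs[, time := ifelse(event,
                       as.integer(first_retest - index_date),
                       as.integer(study_end - index_date))]
  stopifnot(all(obs$time >= 0))
  obs[, list(patient_id, g_stage, time = as.numeric(time), event)]
}

#' Kaplan-Meier cumulative incidence
#'
#' Product-limit estimate of the event-time distribution under right
#' censoring: `CI(t) = 1 - prod_{t_i <= t} (1 - d_i / n_i)` over distinct
#' event times `t_i` with `d_i` events and `n_i` subjects at risk
#' (censorings tied with an event time remain at risk for it).
#'
#' @param time non-negative event/censoring times.
#' @param event logical (or 0/1) event indicator; `FALSE` = censored.
#' @param stratum label stored on the curve (for stratified output).
#' @return object of class `km_curve`: distinct event `times` with
#'   `n_at_risk`, `n_events`, `surv`, `cuminc` and a Greenwood `se` column.
#' @examples
#' km <- km_cumulative_incidence(c(2, 4, 4, 6, 8), c(1, 1, 1, 0, 1))
#' km_ci_at(km, 5)  # 0.6
#' @export
km_cumulative_incidence <- function(time, event, stratum = "pooled") {
  time <- as.numeric(time)
  event <- as.logical(event)
  if (length(time) == 0L) stop("no observations", call. = FALSE)
  if (length(event) != length(time)) {
    stop("time and event must have equal length", call. = FALSE)
  }
  if (any(is.na(time) | is.na(event)) || any(time < 0)) {
    stop("times must be non-negative and non-missing", call. = FALSE)
  }
  if (!any(event)) {
    warning("all observations censored in stratum '", stratum,
            "'; cumulative incidence is identically 0", call. = FALSE)
    out <- list(stratum = stratum, times = numeric(0),
                n_at_risk = integer(0), n_events = integer(0),
                surv = numeric(0), cuminc = numeric(0), se = numeric(0),
                n = length(time), n_events_total = 0L,
                max_followup = max(time))
    class(out) <- "km_curve"
    return(out)
  }
  et <- sort(unique(time[event]))
  d <- tabulate(match(time[event], et), nbins = length(et))
  # at risk at t = subjects with time >= t (censorings tied at t included)
  n_risk <- length(time) - findInterval(et, sort(time), left.open = TRUE)
  s <- cumprod(1 - d / n_risk)
  # Greenwood variance of S(t); double precision (n^2 overflows int)
  nr <- as.numeric(n_risk)
  se <- s * sqrt(cumsum(d / (nr * (nr - d + (n_risk == d)))))
  out <- list(stratum = stratum, times = et, n_at_risk = n_risk,
              n_events = d, surv = s, cuminc = 1 - s, se = se,
              n = length(time), n_events_total = sum(d),
              max_followup = max(time))
  class(out) <- "km_curve"
  out
}

#' Evaluate a KM cumulative-incidence curve at given times
#'
#' Right-continuous step-function evaluation; 0 before the first event time.
#'
#' @param curve a `km_curve`.
#' @param t evaluation times (days).
#' @return numeric vector of cumulative incidences.
#' @export
km_ci_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  if (!length(curve$times)) return(rep(0, length(t)))
  idx <- findInterval(t, curve$times)
  ifelse(idx == 0, 0, curve$cuminc[pmax(idx, 1)])
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve '%s'>: n = %d, events = %d, max follow-up = %.0f d\n",
              x$stratum, x$n, x$n_events_total, x$max_followup))
  if (length(x$times)) {
    cat(sprintf("  CI at last event time (%.0f d): %.3f\n",
                max(x$times), x$cuminc[length(x$cuminc)]))
  }
  invisible(x)
}

#' Stage-stratified KM cumulative incidence
#'
#' One independent product-limit curve per G stage present in the
#' observations. Empty strata are omitted with a message; strata smaller
#' than `min_stratum_n` are flagged via the `small` attribute on the curve.
#'
#' @param observations output of [make_followup_observations()].
#' @param min_stratum_n flag threshold for small strata.
#' @param condition_on_retest if `TRUE`, drop patients without any follow-up
#'   creatinine before estimating (the conditional curve variant).
#' @return named list of `km_curve` objects (one per non-empty stage).
#' @export
stratify_km <- function(observations, min_stratum_n = 50L,
                        condition_on_retest = FALSE) {
  obs <- data.table::as.data.table(observations)
  if (condition_on_retest) obs <- obs[event == TRUE]
  out <- list()
  for (g in g_stage_levels()) {
    sub <- obs[g_stage == g]
    if (!nrow(sub)) {
      message("stratum ", g, " has no observations; omitted")
      next
    }
    cur <- km_cumulative_incidence(sub$time, sub$event, stratum = g)
    attr(cur, "small") <- nrow(sub) < min_stratum_n
    out[[g]] <- cur
  }
  out
}

#' Write per-stratum KM curves as CSV
#'
#' One file per stratum (`km_<stratum>.csv`) with columns time, n_at_risk,
#' n_events, cumulative_incidence, se.
#'
#' @param curves named list from [stratify_km()] (or a single `km_curve`).
#' @param outdir output directory.
#' @return invisibly, the paths written.
#' @export
write_km_csv <- function(curves, outdir) {
  if (inherits(curves, "km_curve")) curves <- setNames(list(curves),
                                                       curves$stratum)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(curves)) {
    cur <- curves[[nm]]
    dt <- data.table::data.table(time = cur$times, n_at_risk = cur$n_at_risk,
                                 n_events = cur$n_events,
                                 cumulative_incidence = cur$cuminc,
                                 se = cur$se)
    p <- file.path(outdir, paste0("km_", nm, ".csv"))
    data.table::fwrite(dt, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
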