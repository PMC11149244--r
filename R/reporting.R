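# Output surfaces: the KDIGO cross-tabulation and all headline proportions,
# plus the end-to-end pipeline composition.
#
# Denominator conventions (fixed and documented):
#   * CKD fraction and stage shares       -> paired (classifiable) patients
#   * per-stage pairing fractions         -> all indexed patients of the stage
#   * per-stage A3 fractions              -> paired patients of the stage
#   * specialty shares                    -> all index creatinine records
#   * age / diabetes by CKD status        -> paired classified patients

#' Summarise a cohort of index assessments
#'
#' Computes the Table-1-style G x A cross-tabulation (with a missing-A
#' column for unpaired patients) and every headline proportion of the
#' analysis, optionally attaching 6-month KM cumulative incidences.
#'
#' @param assessments assessment table from [build_assessments()].
#' @param km_curves optional named list from [stratify_km()].
#' @return object of class `stage_summary`.
#' @export
summarize_assessments <- function(assessments, km_curves = NULL) {
  a <- data.table::as.data.table(assessments)
  if (!nrow(a)) stop("no assessments to summarise", call. = FALSE)
  stages <- g_stage_levels()
  g <- factor(as.character(a$g_stage), levels = stages)
  acat <- factor(as.character(a$a_category), levels = .A_LEVELS)
  paired <- a$paired
  ckd <- as.character(a$ckd_status)

  cross <- table(g_stage = g,
                 a_category = factor(ifelse(is.na(as.character(acat)),
                                            "missing", as.character(acat)),
                                     levels = c(.A_LEVELS, "missing")))

  pairing_pct <- 100 * vapply(stages, function(s) mean(paired[g == s]),
                              numeric(1))
  a3_pct <- 100 * vapply(stages, function(s) {
    sub <- acat[g == s & paired]
    if (!length(sub)) NA_real_ else mean(sub == "A3")
  }, numeric(1))

  classified <- paired & ckd != "indeterminate"
  ckd_pct_among_paired <- 100 * mean(ckd[classified] == "ckd")
  ckd_paired <- classified & ckd == "ckd"
  stage_share_ckd <- 100 * vapply(stages, function(s) {
    mean(g[ckd_paired] == s)
  }, numeric(1))

  mean_age_by_ckd <- c(
    ckd = mean(a$age_at_index[ckd_paired]),
    no_ckd = mean(a$age_at_index[classified & ckd == "no_ckd"]))
  diabetes_pct_by_ckd <- c(
    ckd = 100 * mean(a$diabetes[ckd_paired]),
    no_ckd = 100 * mean(a$diabetes[classified & ckd == "no_ckd"]))

  spec_tab <- sort(table(a$specialty), decreasing = TRUE)
  specialty_pct <- 100 * as.numeric(spec_tab) / nrow(a)
  names(specialty_pct) <- names(spec_tab)
  specialty_pct_by_stage <- lapply(setNames(stages, stages), function(s) {
    sub <- a$specialty[g == s]
    if (!length(sub)) return(numeric(0))
    tb <- sort(table(sub), decreasing = TRUE)
    setNames(100 * as.numeric(tb) / length(sub), names(tb))
  })

  km_ci_6mo <- NULL
  if (!is.null(km_curves)) {
    km_ci_6mo <- vapply(stages, function(s) {
      if (is.null(km_curves[[s]])) NA_real_
      else 100 * km_ci_at(km_curves[[s]], 183)
    }, numeric(1))
  }

  out <- list(
    n_indexed = nrow(a),
    n_paired = sum(paired),
    n_unpaired = sum(!paired),
    unpaired_pct = 100 * mean(!paired),
    cross_tab = cross,
    ckd_pct_among_paired = ckd_pct_among_paired,
    n_ckd_paired = sum(ckd_paired),
    stage_share_among_ckd = stage_share_ckd,
    pairing_pct_by_stage = pairing_pct,
    a3_pct_by_stage_paired = a3_pct,
    mean_age_by_ckd = mean_age_by_ckd,
    diabetes_pct_by_ckd = diabetes_pct_by_ckd,
    specialty_pct = specialty_pct,
    specialty_pct_by_stage = specialty_pct_by_stage,
    km_ci_6mo_pct_by_stage = km_ci_6mo
  )
  class(out) <- "stage_summary"
  out
}

#' @export
print.stage_summary <- function(x, ...) {
  f1 <- function(v) sprintf("%.1f", v)
  cat("<stage_summary>\n")
  cat(sprintf("  indexed patients : %d (paired %d, unpaired %d = %s%%)\n",
              x$n_indexed, x$n_paired, x$n_unpaired, f1(x$unpaired_pct)))
  cat(sprintf("  CKD among paired : %s%% (n = %d)\n",
              f1(x$ckd_pct_among_paired), x$n_ckd_paired))
  cat("  stage shares among CKD (%):",
      paste(names(x$stage_share_among_ckd),
            f1(x$stage_share_among_ckd), collapse = ", "), "\n")
  cat("  pairing by stage (%)      :",
      paste(names(x$pairing_pct_by_stage),
            f1(x$pairing_pct_by_stage), collapse = ", "), "\n")
  cat("  A3 by stage, paired (%)   :",
      paste(names(x$a3_pct_by_stage_paired),
            f1(x$a3_pct_by_stage_paired), collapse = ", "), "\n")
  cat(sprintf("  mean age ckd/no_ckd       : %s / %s years\n",
              f1(x$mean_age_by_ckd[["ckd"]]),
              f1(x$mean_age_by_ckd[["no_ckd"]])))
  cat(sprintf("  diabetes ckd/no_ckd       : %s%% / %s%%\n",
              f1(x$diabetes_pct_by_ckd[["ckd"]]),
              f1(x$diabetes_pct_by_ckd[["no_ckd"]])))
  top <- utils::head(x$specialty_pct, 5)
  cat("  top specialties (%)       :",
      paste(names(top), f1(top), collapse = ", "), "\n")
  if (!is.null(x$km_ci_6mo_pct_by_stage)) {
    cat("  KM retest CI at 183 d (%) :",
        paste(names(x$km_ci_6mo_pct_by_stage),
              f1(x$km_ci_6mo_pct_by_stage), collapse = ", "), "\n")
  }
  invisible(x)
}

# stable JSON representation (6 significant digits, fixed key order)
.summary_to_json_list <- function(x) {
  sig <- function(v) {
    if (is.null(v)) return(NULL)
    if (is.table(v)) {
      m <- as.data.frame.matrix(unclass(v))
      return(lapply(stats::setNames(seq_len(nrow(m)), rownames(m)),
                    function(i) as.list(stats::setNames(as.numeric(m[i, ]),
                                                        colnames(m)))))
    }
    if (is.numeric(v)) {
      out <- signif(v, 6)
      if (!is.null(names(v))) return(as.list(stats::setNames(out, names(v))))
      return(out)
    }
    if (is.list(v)) return(lapply(v, sig))
    v
  }
  lapply(x[order(names(x))], sig)
}

#' Write a stage summary as JSON
#'
#' Deterministic serialisation: alphabetical key order, numbers at 6
#' significant digits — identical inputs give identical files.
#'
#' @param summary a `stage_summary`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "stage_summary"))
  jsonlite::write_json(.summary_to_json_list(unclass(summary)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the whole pipeline on a lab-record table
#'
#' filter -> index assessments -> follow-up observations -> stage-stratified
#' KM -> summary. When `outdir` is given, writes `assessments.csv`,
#' `flow.json`, `summary.json` and one `km_<stage>.csv` per stratum.
#'
#' @param records lab records: a data.table/data.frame or a CSV path.
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @return list with `assessments`, `flow`, `summary` (a `stage_summary`),
#'   `km` (list of `km_curve`) and `observations`.
#' @export
run_pipeline <- function(records, config = pipeline_config(),
                         outdir = NULL) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_lab_records(records)
  }
  built <- build_assessments(records, config)
  obs <- make_followup_observations(built$assessments, built$records,
                                    config$study_end)
  km <- stratify_km(obs, min_stratum_n = config$min_stratum_n,
                    condition_on_retest = config$condition_on_retest)
  summ <- summarize_assessments(built$assessments, km)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_assessments(built, outdir)
    write_summary_json(summ, file.path(outdir, "summary.json"))
    write_km_csv(km, outdir)
  }
  list(assessments = built$assessments, flow = built$flow, summary = summ,
       km = km, observations = obs)
}

#' Recompute every headline quantity from a fresh synthetic cohort
#'
#' One-command regeneration: generates a default-configured synthetic
#' cohort, runs the full pipeline on it, and returns the twelve headline
#' quantities (each with the size of its denominator). Nothing is read from
#' the latent truth — every value is re-derived by the pipeline from the
#' raw records.
#'
#' @param n_patients paired-patient count passed to [generator_config()].
#' @param seed RNG seed.
#' @return named list `t1`..`t12`, each `list(value =, n =)`:
#'   t1 CKD % among paired; t2/t3 G3a/G3b shares among CKD; t4/t5 pairing %
#'   in G3b/G5; t6 A3 % among paired G5; t7/t8 KM retest CI (%) at 183 days
#'   in G3b/G4; t9 overall unpaired %; t10 nephrology share of index tests
#'   (%); t11 diabetes % among CKD; t12 mean age among CKD (years).
#' @export
reproduce_targets <- function(n_patients = 200000L, seed = 1L) {
  cfg <- generator_config(n_patients = n_patients, seed = seed)
  cohort <- generate_cohort(cfg)
  res <- run_pipeline(cohort$records, pipeline_config())
  s <- res$summary
  a <- res$assessments
  n_stage <- table(factor(as.character(a$g_stage), levels = g_stage_levels()))
  n_paired_stage <- table(factor(as.character(a$g_stage[a$paired]),
                                 levels = g_stage_levels()))
  km_n <- function(g) if (is.null(res$km[[g]])) 0L else res$km[[g]]$n
  list(
    t1 = list(value = s$ckd_pct_among_paired, n = s$n_paired),
    t2 = list(value = s$stage_share_among_ckd[["G3a"]], n = s$n_ckd_paired),
    t3 = list(value = s$stage_share_among_ckd[["G3b"]], n = s$n_ckd_paired),
    t4 = list(value = s$pairing_pct_by_stage[["G3b"]],
              n = as.integer(n_stage[["G3b"]])),
    t5 = list(value = s$pairing_pct_by_stage[["G5"]],
              n = as.integer(n_stage[["G5"]])),
    t6 = list(value = s$a3_pct_by_stage_paired[["G5"]],
              n = as.integer(n_paired_stage[["G5"]])),
    t7 = list(value = s$km_ci_6mo_pct_by_stage[["G3b"]], n = km_n("G3b")),
    t8 = list(value = s$km_ci_6mo_pct_by_stage[["G4"]], n = km_n("G4")),
    t9 = list(value = s$unpaired_pct, n = s$n_indexed),
    t10 = list(value = unname(s$specialty_pct["nephrology"]),
               n = s$n_indexed),
    t11 = list(value = s$diabetes_pct_by_ckd[["ckd"]], n = s$n_ckd_paired),
    t12 = list(value = s$mean_age_by_ckd[["ckd"]], n = s$n_ckd_paired)
  )
}
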