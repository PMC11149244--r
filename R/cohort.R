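# Cohort construction: raw lab-record table -> one index assessment per
# patient. Index = chronologically first creatinine in the study window;
# urinary pairing and diabetes lookup use symmetric windows around it.

.TEST_TYPES <- c("creatinine", "acr", "pcr", "dipstick", "albumin_conc",
                 "glucose", "hba1c")
.REQUIRED_COLS <- c("patient_id", "sex", "birth_year", "test_type", "value",
                    "unit", "collection_date", "specialty", "setting",
                    "region")

#' Read a lab-record CSV
#'
#' Expected header:
#' `patient_id,sex,birth_year,test_type,value,unit,collection_date,specialty,setting,region`
#' with ISO-8601 dates, dipstick results as tokens accepted by
#' [normalize_dipstick()], and `test_type` one of creatinine, acr, pcr,
#' dipstick, albumin_conc, glucose, hba1c. Gzip-compressed files are read
#' transparently. An optional `record_id` column (used for deterministic
#' tie-breaking) is assigned from the row order when absent.
#'
#' @param path CSV path (optionally .gz).
#' @return a `data.table` of lab records.
#' @export
read_lab_records <- function(path) {
  if (!file.exists(path)) stop("lab record file not found: ", path,
                               call. = FALSE)
  rec <- data.table::fread(path, colClasses = list(character = "value"))
  as_lab_records(rec)
}

#' Coerce a data.frame to the lab-record layout
#'
#' Validates required columns, coerces types and assigns `record_id` from
#' row order when absent.
#'
#' @param rec data.frame/data.table of lab records.
#' @return a `data.table` with canonical column types.
#' @export
as_lab_records <- function(rec) {
  rec <- data.table::as.data.table(rec)
  missing_cols <- setdiff(.REQUIRED_COLS, names(rec))
  if (length(missing_cols)) {
    stop("lab record table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"record_id" %in% names(rec)) rec[, record_id := .I]
  rec[, `:=`(patient_id = as.character(patient_id),
             test_type = as.character(test_type),
             value = as.character(value),
             unit = as.character(unit),
             specialty = as.character(specialty),
             setting = as.character(setting),
             region = as.character(region),
             birth_year = suppressWarnings(as.integer(birth_year)))]
  rec
}

# strict ISO date parsing; malformed dates are structural errors that abort
# with the offending record ids (row numbers when record_id was implicit)
.parse_dates <- function(rec) {
  d <- as.Date(as.character(rec$collection_date), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(rec$collection_date) &
                 rec$collection_date != "")
  if (length(bad)) {
    stop("malformed collection_date at record(s) ",
         paste(utils::head(rec$record_id[bad], 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "",
         ": expected ISO-8601 YYYY-MM-DD", call. = FALSE)
  }
  if (any(is.na(d))) {
    stop("missing collection_date at record(s) ",
         paste(utils::head(rec$record_id[is.na(d)], 5), collapse = ", "),
         call. = FALSE)
  }
  rec[, collection_date := d]
  rec
}

# parse `value` per test_type into value_num (mg/dL for creatinine, mg/g for
# ratios); dipstick rows keep the token and get NA value_num. Returns a
# logical vector of rows that failed to parse.
.parse_values <- function(rec) {
  vnum <- suppressWarnings(as.numeric(rec$value))
  ok <- rep(FALSE, nrow(rec))
  out <- rep(NA_real_, nrow(rec))

  quant <- rec$test_type %in% c("creatinine", "acr", "pcr", "albumin_conc",
                                "glucose", "hba1c")
  pos <- !is.na(vnum) & is.finite(vnum) & vnum > 0
  ok[quant & pos] <- TRUE

  u <- tolower(trimws(rec$unit))
  u[is.na(u) | u == "na"] <- ""

  cre <- which(ok & rec$test_type == "creatinine")
  cre_known <- u[cre] %in% c("", "mg/dl", "umol/l", "µmol/l", "micromol/l")
  ok[cre[!cre_known]] <- FALSE
  cre <- cre[cre_known]
  out[cre] <- scr_to_mgdl(vnum[cre], u[cre])

  rat <- which(ok & rec$test_type %in% c("acr", "pcr"))
  rat_known <- u[rat] %in% c("", "mg/g", "mg/mmol")
  ok[rat[!rat_known]] <- FALSE
  rat <- rat[rat_known]
  out[rat] <- ratio_to_mgg(vnum[rat], u[rat])

  plain <- which(ok & rec$test_type %in% c("albumin_conc", "glucose", "hba1c"))
  out[plain] <- vnum[plain]

  dip <- which(rec$test_type == "dipstick")
  if (length(dip)) {
    tok <- tolower(trimws(rec$value[dip]))
    ok[dip] <- tok %in% unlist(.DIP_TOKENS)
  }
  rec[, value_num := out]
  !ok
}

#' Apply the inclusion/exclusion filters to a lab-record table
#'
#' Drops, in this order (each record counted once under its first matching
#' reason): records dated outside the study window, inpatient records,
#' records from patients younger than 18 at collection, and records whose
#' value (or demographics needed to interpret it) cannot be parsed.
#' Malformed dates abort with an error naming the offending rows.
#'
#' @param records lab records (see [read_lab_records()]).
#' @param config a [pipeline_config()].
#' @return list with `records` (kept rows, with a numeric `value_num` column
#'   normalised to mg/dL / mg/g) and `flow` (named exclusion counts).
#' @export
filter_records <- function(records, config = pipeline_config()) {
  rec <- as_lab_records(records)
  rec <- .parse_dates(data.table::copy(rec))

  n_in <- nrow(rec)
  reason <- rep(NA_character_, n_in)

  in_window <- rec$collection_date >= config$study_start &
    rec$collection_date <= config$study_end
  reason[!in_window] <- "window"

  setting <- tolower(trimws(rec$setting))
  reason[is.na(reason) & setting != "outpatient"] <- "inpatient"

  sex_ok <- !is.na(normalize_sex_quiet(rec$sex))
  by_ok <- !is.na(rec$birth_year)
  reason[is.na(reason) & (!sex_ok | !by_ok)] <- "unparseable"

  age_at_test <- as.integer(format(rec$collection_date, "%Y")) - rec$birth_year
  reason[is.na(reason) & by_ok & age_at_test < 18] <- "age"

  type_ok <- rec$test_type %in% .TEST_TYPES
  reason[is.na(reason) & !type_ok] <- "unparseable"

  bad_value <- .parse_values(rec)
  reason[is.na(reason) & bad_value] <- "unparseable"

  keep <- is.na(reason)
  flow <- list(
    n_records_in = n_in,
    n_excluded_window = sum(reason == "window", na.rm = TRUE),
    n_excluded_inpatient = sum(reason == "inpatient", na.rm = TRUE),
    n_excluded_age = sum(reason == "age", na.rm = TRUE),
    n_excluded_unparseable = sum(reason == "unparseable", na.rm = TRUE),
    n_records_kept = sum(keep)
  )
  if (!any(keep)) stop("no eligible records after filtering", call. = FALSE)
  list(records = rec[keep], flow = flow)
}

# sex normalisation that maps unknown tokens to NA instead of erroring
normalize_sex_quiet <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("female", "f")] <- "female"
  out[s %in% c("male", "m")] <- "male"
  out
}

.MODALITY_OF_TYPE <- c(acr = "acr_quantitative", pcr = "pcr_quantitative",
                       dipstick = "dipstick")

#' Select a patient's index creatinine
#'
#' The index is the chronologically first creatinine record; ties on the
#' same date are broken by the smallest `record_id`. Remaining creatinine
#' records are returned for follow-up analysis.
#'
#' @param records lab records of a single patient (other test types are
#'   ignored).
#' @return list with `index` (one-row data.table) and `later` (follow-up
#'   creatinine records, possibly empty).
#' @export
select_index_creatinine <- function(records) {
  rec <- data.table::as.data.table(records)
  cre <- rec[test_type == "creatinine"]
  if (!nrow(cre)) stop("patient has no creatinine record", call. = FALSE)
  data.table::setorder(cre, collection_date, record_id)
  list(index = cre[1], later = cre[-1])
}

#' Pair a urinary result to an index creatinine
#'
#' Among urinary records within `window_days` of the index date (direction
#' per config), chooses the one with the smallest absolute day gap; ties
#' prefer the later record, then quantitative ACR over PCR over dipstick,
#' then the smallest `record_id`.
#'
#' @param index_date the index creatinine date.
#' @param urinary urinary records of the patient (test_type acr/pcr/dipstick;
#'   other rows ignored).
#' @param window_days,direction pairing window and direction (see
#'   [pipeline_config()]).
#' @return the chosen record (one-row data.table) or `NULL` if none pairs.
#' @export
pair_urinary <- function(index_date, urinary, window_days = 365L,
                         direction = "both") {
  ur <- data.table::as.data.table(urinary)
  ur <- ur[test_type %in% names(.MODALITY_OF_TYPE)]
  if (!nrow(ur)) return(NULL)
  ur[, delta := as.integer(as.Date(collection_date) - as.Date(index_date))]
  ur <- switch(direction,
               both = ur[abs(delta) <= window_days],
               after = ur[delta >= 0 & delta <= window_days],
               before = ur[delta <= 0 & -delta <= window_days],
               stop("unknown pairing direction: ", direction, call. = FALSE))
  if (!nrow(ur)) return(NULL)
  ur[, modality_rank := match(test_type, names(.MODALITY_OF_TYPE))]
  ur[, abs_delta := abs(delta)]
  data.table::setorder(ur, abs_delta, -delta, modality_rank, record_id)
  ur[1][, c("abs_delta", "modality_rank") := NULL][]
}

#' Laboratory-based diabetes flag
#'
#' `TRUE` iff any HbA1c strictly above `hba1c_threshold` (%) or any serum
#' glucose strictly above `glucose_threshold` (mg/dL) lies within
#' `window_days` of the index date (symmetric window).
#'
#' @param index_date the index creatinine date.
#' @param glycemic glycemic records of the patient (test_type glucose/hba1c).
#' @param window_days lookup window, days.
#' @param hba1c_threshold,glucose_threshold strict thresholds.
#' @return logical scalar.
#' @export
diabetes_flag <- function(index_date, glycemic, window_days = 365L,
                          hba1c_threshold = 6.5, glucose_threshold = 200) {
  gl <- data.table::as.data.table(glycemic)
  gl <- gl[test_type %in% c("glucose", "hba1c")]
  if (!nrow(gl)) return(FALSE)
  if (!"value_num" %in% names(gl)) {
    gl[, value_num := suppressWarnings(as.numeric(value))]
  }
  gl[, delta := as.integer(as.Date(collection_date) - as.Date(index_date))]
  gl <- gl[abs(delta) <= window_days]
  any(gl$test_type == "hba1c" & gl$value_num > hba1c_threshold, na.rm = TRUE) ||
    any(gl$test_type == "glucose" & gl$value_num > glucose_threshold,
        na.rm = TRUE)
}

#' Build one index assessment per patient
#'
#' Composition of the whole cohort-construction step: filtering (unless
#' `filtered = TRUE`), index creatinine selection, eGFR and G stage,
#' urinary pairing and pACR conversion, A category, CKD status, diabetes
#' flag and specialty attribution. Patients without any creatinine record
#' are excluded and counted.
#'
#' @param records lab records.
#' @param config a [pipeline_config()].
#' @param filtered set `TRUE` when `records` already came out of
#'   [filter_records()] (avoids refiltering).
#' @return list with `assessments` (one row per patient), `flow` (telescoping
#'   counts) and `records` (the filtered record table, for follow-up
#'   analysis).
#' @export
build_assessments <- function(records, config = pipeline_config(),
                              filtered = FALSE) {
  if (filtered) {
    rec <- data.table::as.data.table(records)
    if (!"value_num" %in% names(rec)) {
      stop("filtered = TRUE requires records from filter_records()",
           call. = FALSE)
    }
    flow <- list(n_records_in = nrow(rec), n_excluded_window = 0L,
                 n_excluded_inpatient = 0L, n_excluded_age = 0L,
                 n_excluded_unparseable = 0L, n_records_kept = nrow(rec))
  } else {
    fr <- filter_records(records, config)
    rec <- fr$records
    flow <- fr$flow
  }

  cre <- rec[test_type == "creatinine"]
  all_patients <- unique(rec$patient_id)
  if (!nrow(cre)) stop("no creatinine records among eligible rows",
                       call. = FALSE)
  data.table::setorder(cre, patient_id, collection_date, record_id)
  idx <- cre[cre[, .I[1], by = patient_id]$V1]

  a <- data.table::data.table(
    patient_id = idx$patient_id,
    sex = normalize_sex_quiet(idx$sex),
    index_date = idx$collection_date,
    index_scr = idx$value_num,
    specialty = idx$specialty,
    age_at_index = as.integer(format(idx$collection_date, "%Y")) -
      idx$birth_year
  )
  a[, egfr := egfr_ckdepi_2021(index_scr, age_at_index, sex)]
  a[, g_stage := g_stage(egfr)]

  # nearest-in-time urinary pairing (vectorised across patients)
  ur <- rec[test_type %in% names(.MODALITY_OF_TYPE)]
  if (nrow(ur)) {
    ur <- merge(ur,
                a[, list(patient_id, index_date)],
                by = "patient_id")
    ur[, delta := as.integer(collection_date - index_date)]
    ur <- switch(config$pairing_direction,
                 both = ur[abs(delta) <= config$pairing_window_days],
                 after = ur[delta >= 0 & delta <= config$pairing_window_days],
                 before = ur[delta <= 0 & -delta <= config$pairing_window_days])
    if (nrow(ur)) {
      ur[, modality_rank := match(test_type, names(.MODALITY_OF_TYPE))]
      ur[, abs_delta := abs(delta)]
      data.table::setorder(ur, patient_id, abs_delta, -delta, modality_rank,
                           record_id)
      ur <- ur[ur[, .I[1], by = patient_id]$V1]
      ur[, modality := unname(.MODALITY_OF_TYPE[test_type])]
      pac <- pacr_from_any(ur$modality,
                           ifelse(ur$modality == "dipstick", ur$value,
                                  as.character(ur$value_num)))
      ur[, pacr := pac$value]
      pairing <- ur[, list(patient_id, pacr,
                           pacr_modality = modality,
                           pacr_date = collection_date,
                           pacr_specialty = specialty)]
      a <- merge(a, pairing, by = "patient_id", all.x = TRUE)
    } else {
      a[, `:=`(pacr = NA_real_, pacr_modality = NA_character_,
               pacr_date = as.Date(NA), pacr_specialty = NA_character_)]
    }
  } else {
    a[, `:=`(pacr = NA_real_, pacr_modality = NA_character_,
             pacr_date = as.Date(NA), pacr_specialty = NA_character_)]
  }
  a[, paired := !is.na(pacr)]
  a[, a_category := a_category(pacr)]
  a[, ckd_status := ckd_flag(g_stage, a_category)]

  if (config$require_chronicity) {
    a <- .apply_chronicity(a, cre, config)
  }

  # diabetes lookup
  gl <- rec[test_type %in% c("glucose", "hba1c")]
  if (nrow(gl)) {
    gl <- merge(gl, a[, list(patient_id, index_date)], by = "patient_id")
    gl[, delta := as.integer(collection_date - index_date)]
    gl <- gl[abs(delta) <= config$diabetes_window_days]
    dm <- gl[, list(diabetes = any(
      (test_type == "hba1c" & value_num > config$hba1c_threshold) |
        (test_type == "glucose" & value_num > config$glucose_threshold),
      na.rm = TRUE)), by = patient_id]
    a <- merge(a, dm, by = "patient_id", all.x = TRUE)
    a[is.na(diabetes), diabetes := FALSE]
  } else {
    a[, diabetes := FALSE]
  }

  n_alb_conc <- nrow(rec[test_type == "albumin_conc"])
  data.table::setorder(a, patient_id)
  flow$n_patients_no_creatinine <-
    length(setdiff(all_patients, a$patient_id))
  flow$n_patients <- nrow(a)
  flow$n_paired <- sum(a$paired)
  flow$n_unpaired <- sum(!a$paired)
  flow$n_albumin_conc_unusable <- n_alb_conc

  list(assessments = a[], flow = flow, records = rec)
}

# chronicity switch: eGFR-based CKD must be confirmed by a second eGFR < 60
# at least `chronicity_days` after the index; single-assessment evidence is
# downgraded to indeterminate (A-category evidence alone is likewise
# unconfirmed by construction: only one pACR is ever paired).
.apply_chronicity <- function(a, cre, config) {
  conf <- merge(cre[, list(patient_id, collection_date, value_num)],
                a[, list(patient_id, index_date, sex, age_at_index)],
                by = "patient_id")
  conf <- conf[as.integer(collection_date - index_date) >=
                 config$chronicity_days]
  if (nrow(conf)) {
    conf[, egfr := egfr_ckdepi_2021(value_num, age_at_index, sex)]
    confirmed <- unique(conf[egfr < 60, patient_id])
  } else {
    confirmed <- character(0)
  }
  low <- a$g_stage %in% c("G3a", "G3b", "G4", "G5")
  downgrade <- (low & !a$patient_id %in% confirmed) |
    (!low & a$ckd_status == "ckd")
  a[downgrade & ckd_status == "ckd",
    ckd_status := factor("indeterminate", levels = levels(a$ckd_status))]
  a
}

#' Write assessments and flow counts to disk
#'
#' @param built result of [build_assessments()].
#' @param outdir output directory (created if needed); writes
#'   `assessments.csv` and `flow.json`.
#' @return invisibly, the paths written.
#' @export
write_assessments <- function(built, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pa <- file.path(outdir, "assessments.csv")
  pf <- file.path(outdir, "flow.json")
  data.table::fwrite(built$assessments, pa)
  jsonlite::write_json(built$flow, pf, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(pa, pf))
}
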