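# cohort builder: filters, index selection, pairing, diabetes, composition

test_that("filter_records counts each exclusion once and telescopes", {
  recs <- rbind(
    toy_cohort_records(),                                   # 9 eligible rows
    lab_record("D", test_type = "creatinine", value = "1.0",
               collection_date = "2019-05-01", setting = "inpatient"),
    lab_record("D", test_type = "glucose", value = "90",
               collection_date = "2019-05-01", setting = "inpatient"),
    lab_record("E", birth_year = 2002L, test_type = "creatinine",
               value = "0.8", collection_date = "2019-05-01"),  # age 17
    lab_record("F", test_type = "creatinine", value = "1.0",
               collection_date = "2018-05-31"),             # before window
    lab_record("G", test_type = "creatinine", value = "abc",
               collection_date = "2019-05-01")              # bad value
  )
  out <- filter_records(recs)
  fl <- out$flow
  expect_equal(fl$n_records_in, 14)
  expect_equal(fl$n_excluded_inpatient, 2)
  expect_equal(fl$n_excluded_age, 1)
  expect_equal(fl$n_excluded_window, 1)
  expect_equal(fl$n_excluded_unparseable, 1)
  expect_equal(fl$n_records_kept, 9)
  expect_equal(fl$n_records_in,
               fl$n_excluded_window + fl$n_excluded_inpatient +
                 fl$n_excluded_age + fl$n_excluded_unparseable +
                 fl$n_records_kept)
})

test_that("window edges are inclusive and dipstick '++++' survives parsing", {
  recs <- rbind(
    lab_record("A", collection_date = "2018-06-01"),
    lab_record("A", collection_date = "2021-05-31", value = "1.1"),
    lab_record("A", test_type = "dipstick", value = "++++", unit = "",
               collection_date = "2019-01-01"))
  out <- filter_records(recs)
  expect_equal(out$flow$n_records_kept, 3)
  expect_equal(out$flow$n_excluded_window, 0)
})

test_that("malformed dates abort citing the record id", {
  recs <- rbind(lab_record("A"),
                lab_record("B", collection_date = "01/05/2019"))
  expect_error(filter_records(recs), "2.*ISO-8601")
  expect_error(filter_records(lab_record("A", collection_date = "2018-13-01")),
               "ISO-8601")
})

test_that("everything excluded raises the no-eligible-records error", {
  expect_error(filter_records(lab_record("A", setting = "inpatient")),
               "no eligible records")
})

test_that("index creatinine is the chronologically first, ties by record id", {
  recs <- rbind(
    lab_record("A", collection_date = "2019-03-01", value = "1.0"),
    lab_record("A", collection_date = "2018-07-10", value = "1.1"),
    lab_record("A", collection_date = "2020-01-01", value = "1.2"))
  sel <- select_index_creatinine(filter_records(recs)$records)
  expect_equal(as.Date("2018-07-10"), as.Date(sel$index$collection_date))
  expect_equal(nrow(sel$later), 2)

  tie <- rbind(
    lab_record("A", collection_date = "2019-01-01", value = "1.5",
               record_id = 7L),
    lab_record("A", collection_date = "2019-01-01", value = "1.0",
               record_id = 3L))
  sel <- select_index_creatinine(filter_records(tie)$records)
  expect_equal(sel$index$record_id, 3L)
  expect_equal(sel$index$value, "1.0")

  single <- filter_records(lab_record("A"))$records
  sel <- select_index_creatinine(single)
  expect_equal(nrow(sel$later), 0)
  expect_error(select_index_creatinine(
    filter_records(lab_record("A", test_type = "glucose",
                              value = "100"))$records),
    "no creatinine")
})

test_that("pairing picks the nearest urinary result with stated tie-breaks", {
  ur <- function(date, type = "acr", value = "45", id = NULL) {
    filter_records(lab_record("A", test_type = type, value = value,
                              unit = if (type == "dipstick") "" else "mg/g",
                              collection_date = date,
                              record_id = id))$records
  }
  idx <- as.Date("2019-06-01")
  # +100 d beats +400 d (outside window anyway)
  both <- rbind(ur("2019-09-09"), ur("2020-07-05"))
  expect_equal(pair_urinary(idx, both)$collection_date, as.Date("2019-09-09"))
  # -30 d beats +200 d
  both <- rbind(ur("2019-05-02"), ur("2019-12-18"))
  expect_equal(pair_urinary(idx, both)$collection_date, as.Date("2019-05-02"))
  # equal |delta|: prefer the later record
  both <- rbind(ur("2019-05-22"), ur("2019-06-11"))
  expect_equal(pair_urinary(idx, both)$collection_date, as.Date("2019-06-11"))
  # same day: quantitative ACR > PCR > dipstick
  same <- rbind(ur("2019-06-11", "dipstick", "++"),
                ur("2019-06-11", "pcr", "200"),
                ur("2019-06-11", "acr", "45"))
  expect_equal(pair_urinary(idx, same)$test_type, "acr")
  # none inside the window
  expect_null(pair_urinary(idx, ur("2020-07-05")))
  # window 0: only same-day pairs
  expect_null(pair_urinary(idx, ur("2019-06-02"), window_days = 0))
  expect_equal(pair_urinary(idx, ur("2019-06-01"),
                            window_days = 0)$test_type, "acr")
  # directional windows
  expect_null(pair_urinary(idx, ur("2019-05-02"), direction = "after"))
  expect_equal(pair_urinary(idx, ur("2019-05-02"),
                            direction = "before")$collection_date,
               as.Date("2019-05-02"))
})

test_that("diabetes flag applies strict thresholds within the window", {
  gl <- function(type, value, date) {
    lab_record("A", test_type = type, value = value,
               unit = if (type == "hba1c") "%" else "mg/dL",
               collection_date = date)
  }
  idx <- as.Date("2019-06-01")
  expect_true(diabetes_flag(idx, gl("hba1c", "6.6", "2019-08-30")))
  expect_false(diabetes_flag(idx, gl("glucose", "200", "2019-08-30")))
  expect_true(diabetes_flag(idx, gl("glucose", "200.1", "2019-08-30")))
  expect_false(diabetes_flag(idx, gl("hba1c", "7.2", "2020-07-05")))
  expect_false(diabetes_flag(idx, gl("hba1c", "6.5", "2019-06-01")))
  expect_false(diabetes_flag(idx, lab_record("A")))  # no glycemic rows
})

test_that("build_assessments reproduces the hand-computed toy cohort", {
  out <- build_assessments(toy_cohort_records())
  a <- out$assessments
  expect_equal(nrow(a), 3)
  expect_equal(out$flow$n_paired, 2)
  expect_equal(out$flow$n_unpaired, 1)
  expect_equal(out$flow$n_paired + out$flow$n_unpaired, out$flow$n_patients)

  A <- a[a$patient_id == "A", ]
  expect_equal(A$age_at_index, 49)
  expect_equal(A$egfr, oracle_egfr(1.0, 49, "female"), tolerance = 1e-12)
  expect_equal(as.character(A$g_stage), "G2")
  expect_equal(A$pacr, 45)
  expect_equal(as.character(A$a_category), "A2")
  expect_equal(as.character(A$ckd_status), "ckd")
  expect_true(A$diabetes)
  expect_equal(A$specialty, "cardiology")          # from the index record
  expect_equal(A$pacr_specialty, "nephrology")     # from the urinary record

  B <- a[a$patient_id == "B", ]
  expect_equal(B$index_scr, 0.9)                   # same-day tie-break
  expect_equal(as.character(B$g_stage), "G1")
  expect_equal(as.character(B$a_category), "A1")
  expect_equal(as.character(B$ckd_status), "no_ckd")
  expect_false(B$diabetes)

  C <- a[a$patient_id == "C", ]
  expect_false(C$paired)
  expect_true(is.na(C$pacr))
  expect_equal(as.character(C$ckd_status), "indeterminate")
})

test_that("a paired G2 patient with pACR 45 is classified CKD", {
  recs <- rbind(
    lab_record("Z", "female", 1970L, "creatinine", "1.0",
               collection_date = "2019-01-10"),
    lab_record("Z", "female", 1970L, "acr", "45", "mg/g", "2019-02-10"))
  a <- build_assessments(recs)$assessments
  expect_equal(as.character(a$g_stage), "G2")
  expect_equal(as.character(a$ckd_status), "ckd")
})

test_that("patients without creatinine are excluded and counted", {
  recs <- rbind(toy_cohort_records(),
                lab_record("H", test_type = "acr", value = "45",
                           unit = "mg/g", collection_date = "2019-04-01"))
  out <- build_assessments(recs)
  expect_equal(out$flow$n_patients, 3)
  expect_equal(out$flow$n_patients_no_creatinine, 1)
})

test_that("albumin concentration without urine creatinine never pairs", {
  recs <- rbind(
    lab_record("A", collection_date = "2019-01-10"),
    lab_record("A", test_type = "albumin_conc", value = "120", unit = "mg/L",
               collection_date = "2019-02-01"))
  out <- build_assessments(recs)
  expect_false(out$assessments$paired)
  expect_equal(out$flow$n_albumin_conc_unusable, 1)
})

test_that("build_assessments is idempotent and order-invariant", {
  recs <- toy_cohort_records()
  recs$record_id <- seq_len(nrow(recs))
  a1 <- build_assessments(recs)$assessments
  a2 <- build_assessments(recs)$assessments
  expect_identical(a1, a2)
  set.seed(99)
  for (i in 1:5) {
    shuffled <- recs[sample(nrow(recs)), ]
    expect_identical(build_assessments(shuffled)$assessments, a1)
  }
})

test_that("single-patient helpers agree with the vectorised builder", {
  set.seed(11)
  co <- generate_cohort(generator_config(n_patients = 60, seed = 11))
  out <- build_assessments(co$records)
  rec <- out$records
  for (pid in sample(unique(rec$patient_id), 10)) {
    sub <- rec[rec$patient_id == pid, ]
    sel <- select_index_creatinine(sub)
    row <- out$assessments[out$assessments$patient_id == pid, ]
    expect_equal(row$index_date, as.Date(sel$index$collection_date))
    pu <- pair_urinary(row$index_date, sub)
    if (is.null(pu)) {
      expect_false(row$paired)
    } else {
      expect_equal(row$pacr_date, as.Date(pu$collection_date))
    }
    expect_equal(row$diabetes, diabetes_flag(row$index_date, sub))
  }
})

test_that("chronicity switch downgrades unconfirmed single assessments", {
  cfg <- pipeline_config(require_chronicity = TRUE)
  # G4 index, no later creatinine -> unconfirmed
  one <- lab_record("A", "female", 1949L, "creatinine", "2.5",
                    collection_date = "2019-01-10")
  a <- build_assessments(one, cfg)$assessments
  expect_equal(as.character(a$ckd_status), "indeterminate")
  # confirmed by a second low eGFR 120 days later
  two <- rbind(one, lab_record("A", "female", 1949L, "creatinine", "2.4",
                               collection_date = "2019-05-10"))
  a <- build_assessments(two, cfg)$assessments
  expect_equal(as.character(a$ckd_status), "ckd")
  # default config: single assessment suffices
  a <- build_assessments(one)$assessments
  expect_equal(as.character(a$ckd_status), "ckd")
})
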