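# Independent reference implementations used as oracles. Deliberately
# written in a different style from the package (scalar loops, product
# forms, closed-form inverses) so agreement is evidence, not tautology.

# scalar 2021 CKD-EPI, product form
oracle_egfr <- function(scr, age, sex) {
  if (sex == "female") {
    k <- 0.7; a <- -0.241; s <- 1.012
  } else {
    k <- 0.9; a <- -0.302; s <- 1.0
  }
  r <- scr / k
  e <- 142
  if (r < 1) e <- e * r^a
  if (r > 1) e <- e * r^(-1.2)
  e * 0.9938^age * s
}

# closed-form inverse of the eGFR equation (piecewise power law)
oracle_invert_egfr <- function(target, age, sex) {
  if (sex == "female") {
    k <- 0.7; a <- -0.241; s <- 1.012
  } else {
    k <- 0.9; a <- -0.302; s <- 1.0
  }
  C <- 142 * 0.9938^age * s
  r <- target / C
  if (r >= 1) k * r^(1 / a) else k * r^(-1 / 1.2)
}

# scalar PCR -> pACR crosswalk, product form
oracle_pacr_pcr <- function(p) {
  t1 <- min(p / 50, 1)
  t2 <- max(min(p / 500, 1), 0.1)
  t3 <- max(p / 500, 1)
  exp(5.3920) * t1^0.3072 * t2^1.5793 * t3^1.1266
}

# scalar dipstick -> pACR crosswalk
oracle_pacr_dipstick <- function(tok) {
  exp(2.4738 + switch(tok, negative = 0, trace = 0.7539, `+` = 1.7243,
                      `++` = 3.3475, `>++` = 4.6399))
}

# naive O(n^2) Kaplan-Meier product-limit reference
naive_km <- function(time, event) {
  et <- sort(unique(time[event]))
  surv <- numeric(length(et))
  s <- 1
  for (i in seq_along(et)) {
    d <- 0L
    n <- 0L
    for (j in seq_along(time)) {
      if (event[j] && time[j] == et[i]) d <- d + 1L
      if (time[j] >= et[i]) n <- n + 1L
    }
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  list(times = et, surv = surv, cuminc = 1 - surv)
}

# one lab record with sensible defaults, for building toy tables
lab_record <- function(patient_id = "P1", sex = "female", birth_year = 1970L,
                       test_type = "creatinine", value = "1.0",
                       unit = "mg/dL", collection_date = "2019-01-10",
                       specialty = "internal_medicine",
                       setting = "outpatient", region = "SP",
                       record_id = NULL) {
  d <- data.frame(patient_id = patient_id, sex = sex,
                  birth_year = birth_year, test_type = test_type,
                  value = as.character(value), unit = unit,
                  collection_date = collection_date, specialty = specialty,
                  setting = setting, region = region,
                  stringsAsFactors = FALSE)
  if (!is.null(record_id)) d$record_id <- record_id
  d
}

# the three-patient toy table used across cohort tests:
#   A: G2 creatinine + quantitative ACR 45 (A2) -> ckd, diabetic (HbA1c 7.0)
#   B: two same-day creatinines (tie-break) -> G1, dipstick negative -> no_ckd
#   C: G1, no urinary -> unpaired, indeterminate
toy_cohort_records <- function() {
  rbind(
    lab_record("A", "female", 1970L, "creatinine", "1.0", "mg/dL",
               "2019-01-10", "cardiology"),
    lab_record("A", "female", 1970L, "acr", "45", "mg/g", "2019-03-01",
               "nephrology"),
    lab_record("A", "female", 1970L, "hba1c", "7.0", "%", "2019-02-01"),
    lab_record("A", "female", 1970L, "creatinine", "1.1", "mg/dL",
               "2020-01-10", "cardiology"),
    lab_record("B", "male", 1980L, "creatinine", "0.9", "mg/dL",
               "2018-07-10", "obgyn"),
    lab_record("B", "male", 1980L, "creatinine", "0.95", "mg/dL",
               "2018-07-10", "obgyn"),
    lab_record("B", "male", 1980L, "dipstick", "negative", "",
               "2018-09-01", "obgyn"),
    lab_record("B", "male", 1980L, "glucose", "150", "mg/dL", "2018-08-01"),
    lab_record("C", "female", 1969L, "creatinine", "0.7", "mg/dL",
               "2020-05-05", "internal_medicine")
  )
}
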