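# Seeded synthetic laboratory-record generator. Emulates the latent
# structure the analysis assumes: a paired (creatinine + urinary)
# subpopulation with a configured stage/albuminuria composition, unpaired
# patients added per stage so that per-stage pairing proportions hit their
# configured values, stage-dependent demographics, diabetes prevalence,
# specialty mix, and stage-specific exponential retest hazards with
# administrative truncation at the study close date.

.EGFR_BANDS <- list(G1 = c(90, 120), G2 = c(60, 90), G3a = c(45, 60),
                    G3b = c(30, 45), G4 = c(15, 30), G5 = c(4, 15))
.BAND_MARGIN <- 1e-6
.DAYS_PER_MONTH <- 365 / 12

#' Synthetic-cohort generator configuration
#'
#' Defaults encode the published composition of a nationwide outpatient
#' laboratory cohort: CKD fraction and stage shares among classifiable
#' (paired) patients, per-stage pairing and A3 proportions, specialty mix,
#' stage-dependent ages, diabetes prevalence, sex ratio and stage-specific
#' retest hazards. Quantities the source never reports (urinary modality
#' mix, the G1:G2 split of the non-CKD majority, the A1/A2 split of
#' non-A3 mass in G3+) are explicit calibration knobs documented here.
#'
#' @param n_patients number of *paired* (classifiable) patients; unpaired
#'   patients are added on top per stage so that the per-stage pairing
#'   proportions equal `pairing_prob_by_stage`.
#' @param seed integer RNG seed; the generator is fully reproducible.
#' @param study_start,study_end study window; index dates are uniform in it.
#' @param ckd_fraction fraction of the paired population classified CKD.
#' @param ckd_stage_shares stage composition (G1..G5) of the paired CKD
#'   subpopulation; must sum to 1.
#' @param nonckd_g1_share G1 share of the paired non-CKD subpopulation (the
#'   remainder is G2); a calibration knob, not a reported value.
#' @param pairing_prob_by_stage per-stage probability that an indexed
#'   patient has a urinary result within the pairing window.
#' @param a3_prob_by_stage per-stage probability (among paired patients of
#'   that stage) of an A3-level urinary result.
#' @param a1_share_of_residual_g3plus within G3a-G5, the A1 share of the
#'   non-A3 probability mass (remainder A2); calibration knob.
#' @param urinary_modality_mix probabilities for quantitative ACR,
#'   quantitative PCR and dipstick urinary records; calibration knob — all
#'   reported proportions are insensitive to it because values are drawn
#'   category-consistently within each modality.
#' @param retest_rate_per_month_by_stage stage-specific exponential hazards
#'   (per month of 365/12 days) of a repeat creatinine test.
#' @param specialty_mix overall requesting-specialty distribution.
#' @param specialty_mix_by_stage optional named list (by stage) of
#'   per-stage specialty distributions overriding `specialty_mix`.
#' @param age_mean_ckd,age_sd_ckd,age_mean_nonckd,age_sd_nonckd normal age
#'   models (years) by latent CKD status, truncated at `age_min`.
#' @param age_min minimum age (adult cohort).
#' @param diabetes_prev_ckd,diabetes_prev_nonckd diabetes prevalence by
#'   latent CKD status.
#' @param sex_female_prob overall female share.
#' @param region_mix distribution of the region field (plumbing only).
#' @param urinary_delta_days urinary and glycemic record dates are drawn
#'   uniformly within this many days of the index (intersected with the
#'   study window).
#' @param balanced_sampling if `TRUE` (default), categorical structure is
#'   allocated by largest-remainder rounding of expected counts and then
#'   randomly assigned to patients, so configured proportions are hit
#'   exactly up to rounding (continuous draws stay random); `FALSE` uses
#'   plain i.i.d. sampling.
#' @param emit_recurrent_retests if `TRUE`, repeat-creatinine records are
#'   emitted recurrently until the study close; `FALSE` emits at most one.
#' @return a validated list of class `ckdlabscan_gen_config`.
#' @export
generator_config <- function(
    n_patients = 10000L,
    seed = 1L,
    study_start = "2018-06-01",
    study_end = "2021-05-31",
    ckd_fraction = 0.108,
    ckd_stage_shares = c(G1 = 0.068, G2 = 0.083, G3a = 0.541, G3b = 0.221,
                         G4 = 0.061, G5 = 0.026),
    nonckd_g1_share = 0.55,
    pairing_prob_by_stage = c(G1 = 0.549, G2 = 0.612, G3a = 0.667,
                              G3b = 0.707, G4 = 0.702, G5 = 0.467),
    a3_prob_by_stage = c(G1 = 0.003, G2 = 0.004, G3a = 0.012, G3b = 0.025,
                         G4 = 0.073, G5 = 0.284),
    a1_share_of_residual_g3plus = 0.55,
    urinary_modality_mix = c(acr_quantitative = 0.5, pcr_quantitative = 0.3,
                             dipstick = 0.2),
    retest_rate_per_month_by_stage = c(G1 = 0.1407, G2 = 0.1407, G3a = 0.15,
                                       G3b = 0.1527, G4 = 0.2524, G5 = 0.40),
    specialty_mix = c(nephrology = 0.011, internal_medicine = 0.177,
                      cardiology = 0.160, obgyn = 0.160,
                      endocrinology = 0.088, other = 0.404),
    specialty_mix_by_stage = NULL,
    age_mean_ckd = 69, age_sd_ckd = 15.2,
    age_mean_nonckd = 47.2, age_sd_nonckd = 15.4,
    age_min = 18,
    diabetes_prev_ckd = 0.22, diabetes_prev_nonckd = 0.08,
    sex_female_prob = 0.60,
    region_mix = c(SP = 0.476, RJ = 0.226, PR = 0.093, other = 0.205),
    urinary_delta_days = 365L,
    balanced_sampling = TRUE,
    emit_recurrent_retests = TRUE) {
  cfg <- as.list(environment())
  cfg$n_patients <- as.integer(n_patients)
  cfg$seed <- as.integer(seed)
  cfg$study_start <- as.Date(study_start)
  cfg$study_end <- as.Date(study_end)
  class(cfg) <- c("ckdlabscan_gen_config", "list")
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#' @param cfg a [generator_config()] list.
#' @return `cfg`, invisibly, or an error.
#' @export
validate_generator_config <- function(cfg) {
  stages <- g_stage_levels()
  chk_prob_vec <- function(x, nm, names_expected = NULL) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop(nm, " must contain probabilities in [0, 1]", call. = FALSE)
    }
    if (!is.null(names_expected) && !identical(names(x), names_expected)) {
      stop(nm, " must be named ", paste(names_expected, collapse = ", "),
           call. = FALSE)
    }
  }
  chk_sum1 <- function(x, nm) {
    if (abs(sum(x) - 1) > 1e-9) stop(nm, " must sum to 1", call. = FALSE)
  }
  if (cfg$n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (cfg$study_start > cfg$study_end) {
    stop("study_start must precede study_end", call. = FALSE)
  }
  chk_prob_vec(cfg$ckd_fraction, "ckd_fraction")
  chk_prob_vec(cfg$ckd_stage_shares, "ckd_stage_shares", stages)
  chk_sum1(cfg$ckd_stage_shares, "ckd_stage_shares")
  chk_prob_vec(cfg$nonckd_g1_share, "nonckd_g1_share")
  chk_prob_vec(cfg$pairing_prob_by_stage, "pairing_prob_by_stage", stages)
  if (any(cfg$pairing_prob_by_stage <= 0)) {
    stop("pairing probabilities must be > 0 (unpaired counts are derived ",
         "from pairing odds)", call. = FALSE)
  }
  chk_prob_vec(cfg$a3_prob_by_stage, "a3_prob_by_stage", stages)
  chk_prob_vec(cfg$urinary_modality_mix, "urinary_modality_mix",
               urinary_modalities())
  chk_sum1(cfg$urinary_modality_mix, "urinary_modality_mix")
  if (any(cfg$retest_rate_per_month_by_stage <= 0)) {
    stop("retest hazards must be positive", call. = FALSE)
  }
  chk_prob_vec(cfg$specialty_mix, "specialty_mix")
  chk_sum1(cfg$specialty_mix, "specialty_mix")
  if (!is.null(cfg$specialty_mix_by_stage)) {
    for (g in names(cfg$specialty_mix_by_stage)) {
      chk_sum1(cfg$specialty_mix_by_stage[[g]],
               paste0("specialty_mix_by_stage$", g))
    }
  }
  chk_prob_vec(cfg$region_mix, "region_mix")
  chk_sum1(cfg$region_mix, "region_mix")
  # the G1/G2 CKD cells must be able to absorb their stage's A3 mass
  for (g in c("G1", "G2")) {
    cell <- .paired_cell_probs(cfg)
    ckd_cell <- cell[[paste0(g, "_ckd")]]
    stage_tot <- ckd_cell + cell[[paste0(g, "_no")]]
    if (stage_tot > 0 && cfg$a3_prob_by_stage[[g]] > ckd_cell / stage_tot) {
      stop("a3_prob_by_stage for ", g, " exceeds the stage's CKD cell mass",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

# latent cell probabilities of the paired population (sums to 1):
# non-CKD mass split G1/G2; CKD mass split across stages per the shares
.paired_cell_probs <- function(cfg) {
  f <- cfg$ckd_fraction
  s <- cfg$ckd_stage_shares
  c(G1_no = (1 - f) * cfg$nonckd_g1_share,
    G2_no = (1 - f) * (1 - cfg$nonckd_g1_share),
    G1_ckd = f * s[["G1"]], G2_ckd = f * s[["G2"]],
    G3a = f * s[["G3a"]], G3b = f * s[["G3b"]],
    G4 = f * s[["G4"]], G5 = f * s[["G5"]])
}

# largest-remainder integer allocation of n across probabilities
.alloc_counts <- function(n, probs) {
  raw <- n * probs / sum(probs)
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  as.integer(cnt)
}

# counts: balanced (largest remainder) or multinomial
.draw_counts <- function(n, probs, balanced) {
  if (n == 0) return(integer(length(probs)))
  if (balanced) .alloc_counts(n, probs)
  else as.integer(stats::rmultinom(1, n, probs))
}

# a random label vector realising the given counts
.assign_labels <- function(labels, counts) {
  v <- rep(labels, counts)
  if (length(v) > 1) v <- sample(v) else v
}

#' Invert the 2021 CKD-EPI equation for creatinine
#'
#' Bisection on the strictly decreasing creatinine -> eGFR map at fixed age
#' and sex, to within `tol` of the target eGFR. Used by the generator to
#' plant known-truth eGFR values, and as a round-trip check on
#' [egfr_ckdepi_2021()].
#'
#' @param target_egfr target eGFR in (1, 200), mL/min/1.73 m2.
#' @param age,sex as in [egfr_ckdepi_2021()].
#' @param tol absolute eGFR tolerance.
#' @return serum creatinine in mg/dL.
#' @export
invert_egfr_to_creatinine <- function(target_egfr, age, sex, tol = 1e-8) {
  n <- max(length(target_egfr), length(age), length(sex))
  target <- rep_len(as.numeric(target_egfr), n)
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  if (any(!is.finite(target) | target <= 1 | target >= 200)) {
    stop("target eGFR must lie in (1, 200)", call. = FALSE)
  }
  lo <- rep(0.05, n)
  hi <- rep(25, n)
  e_lo <- egfr_ckdepi_2021(lo, age, sex)
  e_hi <- egfr_ckdepi_2021(hi, age, sex)
  if (any(target > e_lo | target < e_hi)) {
    stop("target eGFR not achievable for the given age/sex within ",
         "creatinine range [0.05, 25] mg/dL", call. = FALSE)
  }
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    e <- egfr_ckdepi_2021(mid, age, sex)
    high <- e > target          # eGFR too high -> creatinine too low
    lo <- ifelse(high, mid, lo)
    hi <- ifelse(high, hi, mid)
    if (max(abs(e - target)) < tol) break
  }
  (lo + hi) / 2
}

#' Invert the PCR -> pACR crosswalk
#'
#' Piecewise closed-form inverse of the strictly increasing conversion in
#' [pacr_from_pcr()].
#'
#' @param target_pacr predicted ACR values, mg/g creatinine (> 0).
#' @return PCR values, mg/g creatinine.
#' @export
invert_pacr_to_pcr <- function(target_pacr) {
  t <- as.numeric(target_pacr)
  if (any(!is.finite(t) | t <= 0)) {
    stop("target pACR must be positive", call. = FALSE)
  }
  a_low <- exp(.PACR_PCR[["intercept"]] + .PACR_PCR[["mid"]] * log(0.1))
  b <- exp(.PACR_PCR[["intercept"]])
  ifelse(t <= a_low,
         50 * (t / a_low)^(1 / .PACR_PCR[["low"]]),
         ifelse(t <= b,
                500 * (t / b)^(1 / .PACR_PCR[["mid"]]),
                500 * (t / b)^(1 / .PACR_PCR[["high"]])))
}

# (lo, hi) pACR band per A category, kept strictly inside the thresholds
.A_BANDS <- list(A1 = c(3, 30), A2 = c(30, 300), A3 = c(300, 5000))

#' Draw a urinary result consistent with an albuminuria category
#'
#' Quantitative ACR is drawn log-uniform inside the category's mg/g band;
#' PCR is drawn so that the crosswalk lands inside the band (via
#' [invert_pacr_to_pcr()]); dipstick grades are drawn from the
#' category-compatible tokens (A1: negative/trace; A2: `+`; A3: `++`/`>++`).
#' Uses the current RNG state.
#'
#' @param a_cat character vector of `A1`/`A2`/`A3`.
#' @param modality character vector from [urinary_modalities()].
#' @return data.table with `test_type`, `value` (character) and `unit`.
#' @export
sample_urinary_for_category <- function(a_cat, modality) {
  n <- max(length(a_cat), length(modality))
  a_cat <- rep_len(as.character(a_cat), n)
  modality <- rep_len(as.character(modality), n)
  stopifnot(all(a_cat %in% names(.A_BANDS)),
            all(modality %in% urinary_modalities()))
  lo <- vapply(.A_BANDS[a_cat], `[`, numeric(1), 1) + .BAND_MARGIN
  hi <- vapply(.A_BANDS[a_cat], `[`, numeric(1), 2) - .BAND_MARGIN
  value <- character(n)
  unit <- character(n)
  test_type <- character(n)

  qa <- modality == "acr_quantitative"
  if (any(qa)) {
    v <- exp(runif(sum(qa), log(lo[qa]), log(hi[qa])))
    value[qa] <- as.character(v)
    unit[qa] <- "mg/g"
    test_type[qa] <- "acr"
  }
  qp <- modality == "pcr_quantitative"
  if (any(qp)) {
    plo <- invert_pacr_to_pcr(lo[qp])
    phi <- invert_pacr_to_pcr(hi[qp])
    v <- exp(runif(sum(qp), log(plo), log(phi)))
    value[qp] <- as.character(v)
    unit[qp] <- "mg/g"
    test_type[qp] <- "pcr"
  }
  dp <- modality == "dipstick"
  if (any(dp)) {
    tokens <- list(A1 = c("negative", "trace"), A2 = "+",
                   A3 = c("++", ">++"))
    picks <- vapply(a_cat[dp], function(ac) {
      tk <- tokens[[ac]]
      if (length(tk) == 1) tk else tk[sample.int(length(tk), 1)]
    }, character(1), USE.NAMES = FALSE)
    value[dp] <- picks
    unit[dp] <- ""
    test_type[dp] <- "dipstick"
  }
  data.table::data.table(test_type = test_type, value = value, unit = unit)
}

# truncated-normal ages via resampling
.draw_ages <- function(n, mean, sd, age_min) {
  if (n == 0) return(numeric(0))
  x <- rnorm(n, mean, sd)
  while (any(x < age_min)) {
    k <- x < age_min
    x[k] <- rnorm(sum(k), mean, sd)
  }
  round(x)
}

# uniform integer draws in [lo, hi] (vectorised bounds)
.runif_int <- function(n, lo, hi) {
  lo + floor(runif(n) * (hi - lo + 1))
}

#' Generate a synthetic lab-record cohort
#'
#' Builds the latent patient population implied by the configuration
#' (paired patients per the stage/albuminuria composition, unpaired
#' patients added per stage at `N_paired(G) * (1 - p_G) / p_G`), then emits
#' one index creatinine per patient (value obtained by inverting the eGFR
#' equation at a stage-consistent target), a urinary record for paired
#' patients, one glycemic record per patient, and repeat creatinine records
#' from stage-specific exponential hazards truncated at the study close.
#' Fully reproducible given `config$seed`.
#'
#' @param config a [generator_config()].
#' @return list with `records` (lab-record data.table in the CSV dialect of
#'   [read_lab_records()]) and `truth` (per-patient latent state).
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  stages <- g_stage_levels()
  bal <- config$balanced_sampling
  window_days <- as.integer(config$study_end - config$study_start) + 1L

  ## ---- latent population ------------------------------------------------
  cellp <- .paired_cell_probs(config)
  np_cell <- .draw_counts(config$n_patients, cellp, bal)
  names(np_cell) <- names(cellp)
  np_stage <- c(G1 = np_cell[["G1_no"]] + np_cell[["G1_ckd"]],
                G2 = np_cell[["G2_no"]] + np_cell[["G2_ckd"]],
                G3a = np_cell[["G3a"]], G3b = np_cell[["G3b"]],
                G4 = np_cell[["G4"]], G5 = np_cell[["G5"]])
  p_pair <- config$pairing_prob_by_stage[stages]
  nu_stage <- setNames(as.integer(round(np_stage * (1 - p_pair) / p_pair)),
                       stages)

  pat_list <- list()
  for (g in stages) {
    npg <- np_stage[[g]]
    if (npg > 0) {
      if (g %in% c("G1", "G2")) {
        n_ckd <- np_cell[[paste0(g, "_ckd")]]
        n_no <- np_cell[[paste0(g, "_no")]]
        # A3 mass of the stage lives inside the CKD cell; remainder A2
        n_a3 <- min(.draw_counts(npg, c(config$a3_prob_by_stage[[g]],
                                        1 - config$a3_prob_by_stage[[g]]),
                                 bal)[1], n_ckd)
        acat_ckd <- .assign_labels(c("A3", "A2"), c(n_a3, n_ckd - n_a3))
        pat_list[[length(pat_list) + 1L]] <- data.table::data.table(
          stage = g, latent_ckd = rep(c(TRUE, FALSE), c(n_ckd, n_no)),
          paired = TRUE, a_cat = c(acat_ckd, rep("A1", n_no)))
      } else {
        p3 <- config$a3_prob_by_stage[[g]]
        n_a3 <- .draw_counts(npg, c(p3, 1 - p3), bal)[1]
        n_rest <- npg - n_a3
        n_a1 <- .draw_counts(n_rest,
                             c(config$a1_share_of_residual_g3plus,
                               1 - config$a1_share_of_residual_g3plus),
                             bal)[1]
        pat_list[[length(pat_list) + 1L]] <- data.table::data.table(
          stage = g, latent_ckd = TRUE, paired = TRUE,
          a_cat = .assign_labels(c("A3", "A1", "A2"),
                                 c(n_a3, n_a1, n_rest - n_a1)))
      }
    }
    nug <- nu_stage[[g]]
    if (nug > 0) {
      if (g %in% c("G1", "G2")) {
        frac_ckd <- cellp[[paste0(g, "_ckd")]] /
          (cellp[[paste0(g, "_ckd")]] + cellp[[paste0(g, "_no")]])
        n_ckd_u <- .draw_counts(nug, c(frac_ckd, 1 - frac_ckd), bal)[1]
        lc <- .assign_labels(c(TRUE, FALSE), c(n_ckd_u, nug - n_ckd_u))
      } else {
        lc <- rep(TRUE, nug)
      }
      pat_list[[length(pat_list) + 1L]] <- data.table::data.table(
        stage = g, latent_ckd = lc, paired = FALSE, a_cat = NA_character_)
    }
  }
  pat <- data.table::rbindlist(pat_list)
  pat <- pat[sample(.N)]                 # detach structure from row order
  pat[, patient_id := sprintf("P%07d", .I)]
  n_tot <- nrow(pat)

  ## ---- demographics, comorbidity, attribution ---------------------------
  n_female <- .draw_counts(n_tot, c(config$sex_female_prob,
                                    1 - config$sex_female_prob), bal)[1]
  pat[, sex := .assign_labels(c("female", "male"),
                              c(n_female, n_tot - n_female))]
  pat[latent_ckd == TRUE,
      age := .draw_ages(.N, config$age_mean_ckd, config$age_sd_ckd,
                        config$age_min)]
  pat[latent_ckd == FALSE,
      age := .draw_ages(.N, config$age_mean_nonckd, config$age_sd_nonckd,
                        config$age_min)]
  pat[latent_ckd == TRUE, diabetes := .assign_labels(
    c(TRUE, FALSE),
    c(k <- .draw_counts(.N, c(config$diabetes_prev_ckd,
                              1 - config$diabetes_prev_ckd), bal)[1],
      .N - k))]
  pat[latent_ckd == FALSE, diabetes := .assign_labels(
    c(TRUE, FALSE),
    c(k <- .draw_counts(.N, c(config$diabetes_prev_nonckd,
                              1 - config$diabetes_prev_nonckd), bal)[1],
      .N - k))]
  if (is.null(config$specialty_mix_by_stage)) {
    cnt <- .draw_counts(n_tot, config$specialty_mix, bal)
    pat[, specialty := .assign_labels(names(config$specialty_mix), cnt)]
  } else {
    for (g in stages) {
      mix <- config$specialty_mix_by_stage[[g]]
      if (is.null(mix)) mix <- config$specialty_mix
      pat[stage == g, specialty := .assign_labels(
        names(mix), .draw_counts(.N, mix, bal))]
    }
  }
  cnt <- .draw_counts(n_tot, config$region_mix, bal)
  pat[, region := .assign_labels(names(config$region_mix), cnt)]

  pat[, index_date := config$study_start +
        .runif_int(n_tot, 0L, window_days - 1L)]
  pat[, birth_year := as.integer(format(index_date, "%Y")) - age]

  ## ---- index creatinine via eGFR inversion ------------------------------
  band_lo <- vapply(.EGFR_BANDS[pat$stage], `[`, numeric(1), 1) + .BAND_MARGIN
  band_hi <- vapply(.EGFR_BANDS[pat$stage], `[`, numeric(1), 2) - .BAND_MARGIN
  pat[, egfr_true := runif(n_tot, band_lo, band_hi)]
  pat[, scr := invert_egfr_to_creatinine(egfr_true, age, sex)]

  mk_rec <- function(p, test_type, value, unit, date, specialty) {
    data.table::data.table(
      patient_id = p$patient_id, sex = p$sex, birth_year = p$birth_year,
      test_type = test_type, value = value, unit = unit,
      collection_date = date, specialty = specialty,
      setting = "outpatient", region = p$region)
  }
  rec_index <- mk_rec(pat, "creatinine", as.character(pat$scr), "mg/dL",
                      pat$index_date, pat$specialty)

  ## ---- urinary records for paired patients ------------------------------
  pp <- pat[paired == TRUE]
  mod_cnt <- .draw_counts(nrow(pp), config$urinary_modality_mix, bal)
  pp_mod <- .assign_labels(urinary_modalities(), mod_cnt)
  ur <- sample_urinary_for_category(pp$a_cat, pp_mod)
  # records dated before Jan 1 of (birth_year + 18) would fail the adult
  # filter (year-based age); keep pre-index draws on the adult side
  adult_from <- function(p) {
    as.integer(as.Date(sprintf("%d-01-01", p$birth_year + 18L)) -
                 p$index_date)
  }
  dlo <- pmax(-config$urinary_delta_days,
              as.integer(config$study_start - pp$index_date),
              adult_from(pp))
  dhi <- pmin(config$urinary_delta_days,
              as.integer(config$study_end - pp$index_date))
  ur_date <- pp$index_date + .runif_int(nrow(pp), dlo, dhi)
  ur_spec <- sample(names(config$specialty_mix), nrow(pp), replace = TRUE,
                    prob = config$specialty_mix)
  rec_ur <- mk_rec(pp, ur$test_type, ur$value, ur$unit, ur_date, ur_spec)

  ## ---- glycemic records (one per patient) -------------------------------
  glo <- pmax(-config$urinary_delta_days,
              as.integer(config$study_start - pat$index_date),
              adult_from(pat))
  ghi <- pmin(config$urinary_delta_days,
              as.integer(config$study_end - pat$index_date))
  gl_date <- pat$index_date + .runif_int(n_tot, glo, ghi)
  gl_type <- sample(c("hba1c", "glucose"), n_tot, replace = TRUE)
  gl_val <- numeric(n_tot)
  dm <- pat$diabetes
  h <- gl_type == "hba1c"
  gl_val[h & dm] <- runif(sum(h & dm), 6.6, 12)      # strictly above 6.5
  gl_val[h & !dm] <- runif(sum(h & !dm), 4.8, 6.4)
  gl_val[!h & dm] <- runif(sum(!h & dm), 205, 400)   # strictly above 200
  gl_val[!h & !dm] <- runif(sum(!h & !dm), 70, 140)
  gl_spec <- sample(names(config$specialty_mix), n_tot, replace = TRUE,
                    prob = config$specialty_mix)
  rec_gl <- mk_rec(pat, gl_type, as.character(round(gl_val, 1)),
                   ifelse(h, "%", "mg/dL"), gl_date, gl_spec)

  ## ---- recurrent repeat-creatinine records ------------------------------
  rate_day <- config$retest_rate_per_month_by_stage[pat$stage] /
    .DAYS_PER_MONTH
  horizon <- as.integer(config$study_end - pat$index_date)
  t_cum <- rep(0L, n_tot)
  active <- rep(TRUE, n_tot)
  retest_idx <- integer(0)
  retest_day <- integer(0)
  while (any(active)) {
    ia <- which(active)
    gap <- pmax(1L, as.integer(ceiling(rexp(length(ia), rate_day[ia]))))
    t_cum[ia] <- t_cum[ia] + gap
    hit <- ia[t_cum[ia] <= horizon[ia]]
    retest_idx <- c(retest_idx, hit)
    retest_day <- c(retest_day, t_cum[hit])
    active[ia] <- t_cum[ia] <= horizon[ia]
    if (!config$emit_recurrent_retests) active[hit] <- FALSE
  }
  if (length(retest_idx)) {
    pr <- pat[retest_idx]
    rt_spec <- sample(names(config$specialty_mix), length(retest_idx),
                      replace = TRUE, prob = config$specialty_mix)
    # no within-patient trajectory model: repeat tests re-report the index
    # creatinine value (documented simplification)
    rec_rt <- mk_rec(pr, "creatinine", as.character(pr$scr), "mg/dL",
                     pr$index_date + retest_day, rt_spec)
  } else {
    rec_rt <- NULL
  }

  records <- data.table::rbindlist(
    Filter(Negate(is.null), list(rec_index, rec_ur, rec_gl, rec_rt)))
  data.table::setorder(records, patient_id, collection_date, test_type, value)
  records[, record_id := .I]

  truth <- pat[, list(patient_id, stage, latent_ckd, paired, a_cat, sex, age,
                      diabetes, index_date, egfr_true, scr, specialty)]
  data.table::setorder(truth, patient_id)
  list(records = records[], truth = truth[])
}

#' Generate and write a synthetic lab-record CSV
#'
#' Convenience wrapper around [generate_cohort()] that writes the record
#' table as CSV and, optionally, the latent truth as a JSON sidecar.
#'
#' @param config a [generator_config()].
#' @param out CSV output path (`.gz` supported by extension).
#' @param truth_out optional path for the latent-truth JSON sidecar.
#' @return invisibly, the generated list from [generate_cohort()].
#' @export
simulate_lab_records <- function(config = generator_config(), out,
                                 truth_out = NULL) {
  res <- generate_cohort(config)
  data.table::fwrite(res$records, out)
  if (!is.null(truth_out)) {
    tr <- data.table::copy(res$truth)
    tr[, index_date := as.character(index_date)]
    jsonlite::write_json(tr, truth_out, dataframe = "rows", digits = NA)
  }
  invisible(res)
}
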