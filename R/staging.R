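# KDIGO classification: G stage from eGFR, A category from albuminuria,
# CKD flag and the 18-cell prognosis ("heatmap") risk class.
#
# Boundary conventions (declared once, used everywhere):
#   G bands are half-open with the lower bound included:
#     G1 [90, Inf), G2 [60, 90), G3a [45, 60), G3b [30, 45), G4 [15, 30),
#     G5 (0, 15)
#   A categories: A1 (0, 30), A2 [30, 300], A3 (300, Inf)  [mg/g creatinine]

.G_LEVELS <- c("G1", "G2", "G3a", "G3b", "G4", "G5")
.A_LEVELS <- c("A1", "A2", "A3")
.RISK_LEVELS <- c("low", "moderately_increased", "high", "very_high")
.CKD_LEVELS <- c("ckd", "no_ckd", "indeterminate")

#' G stage labels in order of worsening kidney function
#' @return character vector `G1, G2, G3a, G3b, G4, G5`.
#' @export
g_stage_levels <- function() .G_LEVELS

#' KDIGO G stage from eGFR
#'
#' Bands are half-open with the lower bound included: G1 >= 90,
#' G2 60-89.99, G3a 45-59.99, G3b 30-44.99, G4 15-29.99, G5 < 15
#' (mL/min/1.73 m2).
#'
#' @param egfr positive finite eGFR values.
#' @return ordered factor with levels [g_stage_levels()].
#' @examples
#' g_stage(c(105.3, 59.9, 14.99))  # G1, G3a, G5
#' @export
g_stage <- function(egfr) {
  egfr <- as.numeric(egfr)
  if (any(!is.na(egfr) & (!is.finite(egfr) | egfr <= 0))) {
    stop("eGFR must be positive and finite", call. = FALSE)
  }
  cut(egfr, breaks = c(0, 15, 30, 45, 60, 90, Inf), right = FALSE,
      labels = rev(.G_LEVELS)) |>
    factor(levels = .G_LEVELS, ordered = TRUE)
}

#' KDIGO albuminuria category from (predicted) ACR
#'
#' A1 < 30, A2 30-300 (both ends included), A3 > 300 mg/g creatinine.
#'
#' @param pacr positive finite (predicted) ACR values, mg/g creatinine.
#' @return ordered factor with levels `A1, A2, A3`.
#' @export
a_category <- function(pacr) {
  if (is.data.frame(pacr)) pacr <- pacr$value
  pacr <- as.numeric(pacr)
  if (any(!is.na(pacr) & (!is.finite(pacr) | pacr <= 0))) {
    stop("pACR must be positive and finite (mg/g creatinine)", call. = FALSE)
  }
  lab <- ifelse(pacr < 30, "A1", ifelse(pacr <= 300, "A2", "A3"))
  factor(lab, levels = .A_LEVELS, ordered = TRUE)
}

#' CKD flag from G stage and albuminuria category
#'
#' Single-assessment rule (no chronicity requirement): any G3a-G5 stage is
#' CKD regardless of albuminuria; G1/G2 with A2 or A3 is CKD; G1/G2 with A1
#' is not; G1/G2 with no albuminuria result cannot be classified and is
#' `indeterminate`.
#'
#' @param g G stage factor/labels.
#' @param a A category factor/labels; may contain NA (no urinary result).
#' @return factor with levels `ckd, no_ckd, indeterminate`.
#' @export
ckd_flag <- function(g, a = NA) {
  n <- max(length(g), length(a))
  g <- factor(rep_len(as.character(g), n), levels = .G_LEVELS)
  a <- factor(rep_len(as.character(a), n), levels = .A_LEVELS)
  if (any(is.na(g))) stop("G stage must be present for every patient",
                          call. = FALSE)
  low_gfr <- g %in% c("G3a", "G3b", "G4", "G5")
  out <- rep(NA_character_, n)
  out[low_gfr] <- "ckd"
  out[!low_gfr & !is.na(a) & a != "A1"] <- "ckd"
  out[!low_gfr & !is.na(a) & a == "A1"] <- "no_ckd"
  out[!low_gfr & is.na(a)] <- "indeterminate"
  factor(out, levels = .CKD_LEVELS)
}

# 18-cell KDIGO prognosis grid (rows G1..G5, columns A1..A3)
.KDIGO_GRID <- matrix(
  c("low",                  "moderately_increased", "high",
    "low",                  "moderately_increased", "high",
    "moderately_increased", "high",                 "very_high",
    "high",                 "very_high",            "very_high",
    "very_high",            "very_high",            "very_high",
    "very_high",            "very_high",            "very_high"),
  nrow = 6, byrow = TRUE, dimnames = list(.G_LEVELS, .A_LEVELS))

#' KDIGO prognosis risk class from the G x A grid
#'
#' The standard 18-cell KDIGO heatmap: G1-G2/A1 low; G1-G2/A2 and G3a/A1
#' moderately increased; G1-G2/A3, G3a/A2 and G3b/A1 high; all remaining
#' cells very high.
#'
#' @param g G stage factor/labels.
#' @param a A category factor/labels (must be present).
#' @return ordered factor with levels
#'   `low < moderately_increased < high < very_high`.
#' @export
kdigo_risk <- function(g, a) {
  n <- max(length(g), length(a))
  g <- rep_len(as.character(g), n)
  a <- rep_len(as.character(a), n)
  if (any(is.na(g) | is.na(a))) {
    stop("both G stage and A category are required for risk classification",
         call. = FALSE)
  }
  if (any(!g %in% .G_LEVELS) || any(!a %in% .A_LEVELS)) {
    stop("unrecognized G stage or A category label", call. = FALSE)
  }
  factor(.KDIGO_GRID[cbind(g, a)], levels = .RISK_LEVELS, ordered = TRUE)
}
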