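# Unit normalisation for creatinine and albumin-to-creatinine ratios.
# Real lab exports mix conventional and SI units; the pipeline works
# internally in mg/dL (creatinine) and mg/g creatinine (ACR/PCR/pACR).

.SCR_UMOL_PER_MGDL <- 88.42   # 1 mg/dL creatinine = 88.42 umol/L
.ACR_MGG_PER_MGMMOL <- 8.84   # 1 mg/mmol = 8.84 mg/g (creatinine MW 113.12)

#' Normalise serum creatinine to mg/dL
#'
#' @param value numeric creatinine values.
#' @param unit unit string per element: `"mg/dL"` (passthrough) or
#'   `"umol/L"`/`"µmol/L"` (divided by 88.42). Case-insensitive; `""`/NA is
#'   treated as mg/dL.
#' @return numeric vector in mg/dL.
#' @export
scr_to_mgdl <- function(value, unit = "mg/dL") {
  n <- max(length(value), length(unit))
  value <- rep_len(as.numeric(value), n)
  u <- tolower(trimws(rep_len(as.character(unit), n)))
  u[is.na(u) | u == ""] <- "mg/dl"
  out <- rep(NA_real_, n)
  out[u == "mg/dl"] <- value[u == "mg/dl"]
  si <- u %in% c("umol/l", "µmol/l", "micromol/l")
  out[si] <- value[si] / .SCR_UMOL_PER_MGDL
  bad <- !u %in% c("mg/dl", "umol/l", "µmol/l", "micromol/l")
  if (any(bad)) {
    stop("unsupported creatinine unit(s): ",
         paste(unique(u[bad]), collapse = ", "),
         " (accepted: mg/dL, umol/L)", call. = FALSE)
  }
  out
}

#' Normalise an albumin- or protein-to-creatinine ratio to mg/g
#'
#' @param value numeric ratio values.
#' @param unit `"mg/g"` (passthrough) or `"mg/mmol"` (multiplied by 8.84).
#'   Case-insensitive; `""`/NA is treated as mg/g.
#' @return numeric vector in mg/g creatinine.
#' @export
ratio_to_mgg <- function(value, unit = "mg/g") {
  n <- max(length(value), length(unit))
  value <- rep_len(as.numeric(value), n)
  u <- tolower(trimws(rep_len(as.character(unit), n)))
  u[is.na(u) | u == ""] <- "mg/g"
  out <- rep(NA_real_, n)
  out[u == "mg/g"] <- value[u == "mg/g"]
  out[u == "mg/mmol"] <- value[u == "mg/mmol"] * .ACR_MGG_PER_MGMMOL
  bad <- !u %in% c("mg/g", "mg/mmol")
  if (any(bad)) {
    stop("unsupported ratio unit(s): ", paste(unique(u[bad]), collapse = ", "),
         " (accepted: mg/g, mg/mmol)", call. = FALSE)
  }
  out
}
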