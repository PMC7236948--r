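# Per-patient cohort assembly: panel TMB, dichotomizations, the four
# TMB x PHBR strata, and overall-benefit labelling.

#' TMB from a panel mutation count
#'
#' The panel interrogates a fixed genomic footprint (1.2 Mb by default) and
#' the somatic mutation count is extrapolated to a whole-exome density in
#' mutations per megabase. The count is expected to already exclude known or
#' likely oncogenic drivers and germline polymorphisms (caller's
#' responsibility).
#'
#' @param mutation_count Nonnegative somatic mutation count(s).
#' @param interrogated_mb Panel footprint in Mb, default 1.2.
#' @return TMB in mutations per Mb.
#' @export
tmb_from_panel <- function(mutation_count, interrogated_mb = 1.2) {
  if (!is_scalar_number(interrogated_mb) || interrogated_mb <= 0) {
    pkg_error("`interrogated_mb` must be a positive number", "domain_error")
  }
  if (any(mutation_count < 0, na.rm = TRUE)) {
    pkg_error("mutation counts must be nonnegative", "domain_error")
  }
  mutation_count / interrogated_mb
}

#' Add the continuous-analysis pseudocount to TMB
#'
#' A pseudocount (default 0.001) is added before log-scale or correlation
#' analyses. It is never applied before threshold dichotomization, and it
#' does not impute missing TMB: `NA` stays `NA`.
#'
#' @param tmb Numeric TMB vector, `NA` allowed.
#' @param pseudocount Default 0.001.
#' @export
add_pseudocount <- function(tmb, pseudocount = 0.001) {
  tmb + pseudocount
}

#' Dichotomize TMB at a threshold
#'
#' High iff TMB is present and >= threshold (the boundary value is high).
#' Patients with missing TMB are assigned to the low category.
#'
#' @param tmb Numeric TMB vector, `NA` allowed.
#' @param threshold Positive cutoff, conventionally 10, 20 or 50
#'   mutations/Mb.
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize_tmb <- function(tmb, threshold = 10) {
  if (!is_scalar_number(threshold) || threshold <= 0) {
    pkg_error("`threshold` must be positive", "domain_error")
  }
  factor(ifelse(!is.na(tmb) & tmb >= threshold, "high", "low"),
         levels = c("low", "high"))
}

#' Dichotomize minimum PHBR at a threshold
#'
#' Low (strong presentation) iff min-PHBR < threshold; the boundary value is
#' high (poor presentation). Default threshold 0.5.
#'
#' @param min_phbr Positive numeric vector of minimum PHBR scores.
#' @param threshold Default 0.5.
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize_phbr <- function(min_phbr, threshold = 0.5) {
  if (any(min_phbr <= 0, na.rm = TRUE)) {
    pkg_error("min PHBR must be positive", "domain_error")
  }
  factor(ifelse(min_phbr < threshold, "low", "high"), levels = c("low", "high"))
}

#' Joint TMB x PHBR stratum label
#'
#' @param tmb_class,phbr_class Factors/character in {"low","high"}.
#' @return Factor with the four joint labels; `TMB-high/PHBR-low` is the
#'   best-prognosis stratum.
#' @export
assign_stratum <- function(tmb_class, phbr_class) {
  tmb_class <- as.character(tmb_class); phbr_class <- as.character(phbr_class)
  ok <- tmb_class %in% c("low", "high") & phbr_class %in% c("low", "high")
  if (any(!ok)) {
    pkg_error("tmb_class and phbr_class must both be 'low' or 'high'",
              "invalid_input")
  }
  factor(paste0("TMB-", tmb_class, "/PHBR-", phbr_class),
         levels = c("TMB-low/PHBR-low", "TMB-low/PHBR-high",
                    "TMB-high/PHBR-low", "TMB-high/PHBR-high"))
}

RESPONSE_LEVELS <- c("CR", "PR", "SD>=6mo", "SD<6mo-ongoing", "SD<6mo", "PD")

#' Overall-benefit label from response category
#'
#' Benefit = complete/partial response or stable disease lasting at least
#' 6 months. Ongoing stable disease with less than 6 months of follow-up is
#' not evaluable and is excluded from overall-benefit-rate denominators;
#' if follow-up has in fact reached 6 months the patient counts as benefit.
#'
#' @param response Character vector over
#'   `c("CR","PR","SD>=6mo","SD<6mo-ongoing","SD<6mo","PD")`.
#' @param followup_months Optional numeric follow-up used to resolve
#'   ongoing stable disease.
#' @return Factor in {"benefit", "no_benefit", "not_evaluable"}.
#' @export
overall_benefit <- function(response, followup_months = NULL) {
  bad <- !response %in% RESPONSE_LEVELS
  if (any(bad)) {
    pkg_error(sprintf("unknown response category: %s",
                      paste(unique(response[bad]), collapse = ", ")),
              "invalid_input")
  }
  out <- ifelse(response %in% c("CR", "PR", "SD>=6mo"), "benefit",
         ifelse(response %in% c("PD", "SD<6mo"), "no_benefit", "not_evaluable"))
  if (!is.null(followup_months)) {
    resolved <- out == "not_evaluable" & !is.na(followup_months) &
      followup_months >= 6
    out[resolved] <- "benefit"
  }
  factor(out, levels = c("benefit", "no_benefit", "not_evaluable"))
}
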