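#' Exposure assumptions linking hazard quotients to percent of LD50
#'
#' The raw pollen hazard quotient (residue in ng/g divided by LD50 in
#' \eqn{\mu}g/bee) is converted to a percent-of-LD50 exposure under four
#' standard assumptions: pesticides act additively; an adult worker bee
#' weighs 100 mg; acute contact exposure corresponds to contacting one
#' body-weight equivalent of pollen (100 mg, the span of a laboratory
#' contact-LD50 study); and chronic oral exposure corresponds to ingesting
#' 9.4 mg pollen/day over a 10-day pollination period.
#'
#' @param bee_mass_mg Adult worker bee mass in mg. Default 100.
#' @param contact_mass_mg Mass of pollen (mg) contacted during the acute
#'   contact window. Default 100 (one body-weight equivalent).
#' @param oral_rate_mg_per_day Pollen ingestion rate, mg/day. Default 9.4.
#' @param duration_days Length of the chronic oral exposure window in days.
#'   Default 10 (the median mass-bloom pollination period).
#' @return An object of class `exposure_params`.
#' @seealso [pct_of_ld50()], [loc_thresholds()]
#' @export
#' @examples
#' exposure_params()
exposure_params <- function(bee_mass_mg = 100, contact_mass_mg = 100,
                            oral_rate_mg_per_day = 9.4, duration_days = 10) {
  vals <- c(bee_mass_mg = bee_mass_mg, contact_mass_mg = contact_mass_mg,
            oral_rate_mg_per_day = oral_rate_mg_per_day,
            duration_days = duration_days)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    abort("All exposure parameters must be finite and strictly positive.")
  }
  structure(as.list(vals), class = "exposure_params")
}

#' Regulatory levels of concern for pollinator exposure
#'
#' Exposure/toxicity ratios above which regulatory agencies flag risk:
#' the EPA Tier 1 acute-contact risk quotient (0.4), the EFSA
#' acute-contact exposure-to-toxicity ratio (0.2), and the EFSA chronic
#' oral trigger value (0.03, matched to a 10-day LC50 exposure).
#'
#' @param epa_acute_contact EPA Tier 1 acute contact risk quotient.
#' @param efsa_acute_contact EFSA acute contact ETR trigger.
#' @param efsa_chronic_oral EFSA chronic oral ETR trigger.
#' @return An object of class `loc_thresholds`.
#' @export
#' @examples
#' loc_thresholds()
loc_thresholds <- function(epa_acute_contact = 0.4,
                           efsa_acute_contact = 0.2,
                           efsa_chronic_oral = 0.03) {
  vals <- c(epa_acute_contact = epa_acute_contact,
            efsa_acute_contact = efsa_acute_contact,
            efsa_chronic_oral = efsa_chronic_oral)
  if (!all(is.finite(vals)) || any(vals <= 0) || any(vals >= 1)) {
    abort("Levels of concern must lie strictly between 0 and 1.")
  }
  structure(as.list(vals), class = "loc_thresholds")
}

#' @export
print.exposure_params <- function(x, ...) {
  cat("Exposure assumptions:\n",
      sprintf("  bee mass:        %g mg\n", x$bee_mass_mg),
      sprintf("  contact dose:    %g mg pollen\n", x$contact_mass_mg),
      sprintf("  oral intake:     %g mg pollen/day over %g days\n",
              x$oral_rate_mg_per_day, x$duration_days), sep = "")
  invisible(x)
}

#' @export
print.loc_thresholds <- function(x, ...) {
  cat("Levels of concern (exposure/toxicity):\n",
      sprintf("  EPA acute contact:   %g\n", x$epa_acute_contact),
      sprintf("  EFSA acute contact:  %g\n", x$efsa_acute_contact),
      sprintf("  EFSA chronic oral:   %g\n", x$efsa_chronic_oral), sep = "")
  invisible(x)
}

#' Round half away from zero
#'
#' Reporting convention for hazard tables: ties round away from zero
#' (so 1.25 prints as 1.3 at one decimal), unlike base [round()]'s
#' round-half-to-even. Internal computation is always full precision;
#' this is applied only when tables are written or compared at printed
#' precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(1.25, 4721.186), 1)
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
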