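#' Raw pollen hazard quotient
#'
#' The pollen hazard quotient (PHQ) for one compound is its residue
#' concentration in beebread (ng/g pollen, i.e. ppb) divided by the
#' route-specific honey bee LD50 (\eqn{\mu}g a.i./bee):
#' \deqn{PHQ = \frac{\mathrm{residue}\ (ng/g)}{LD_{50}\ (\mu g/bee)}}
#' No unit rescaling is applied — this is the conventional
#' "dimension-bending" hazard index; conversion to biologically
#' interpretable percent-of-LD50 happens in [pct_of_ld50()]. Site-level
#' PHQs are additive over compounds.
#'
#' @param concentration Residue concentration(s), ng/g (ppb), `>= 0`.
#' @param ld50 Route-specific LD50(s), ug/bee, `> 0`; `NA` means the
#'   value is unavailable and yields an `NA` quotient (a route-skip
#'   signal, not an error).
#' @return Numeric vector of dimensionless hazard quotients.
#' @export
#' @examples
#' phq_raw(557.1, 0.118)  # ~4721.2
#' phq_raw(69.9, 0.15)    # 466
phq_raw <- function(concentration, ld50) {
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    abort("Concentrations must be finite and non-negative.")
  }
  if (any(!is.na(ld50) & ld50 <= 0)) {
    abort("LD50 values must be strictly positive when present.")
  }
  concentration / ld50
}

#' Per-compound hazard quotients for a residue table
#'
#' Joins residue records to the toxicity database and computes contact
#' and oral PHQs per record. Every residue compound must be resolvable
#' in the database (hard error otherwise). A detected compound whose
#' LD50 is missing for a route is flagged as skipped for that route and
#' contributes nothing to route totals.
#'
#' @param residues Residue tibble as from [read_residues()].
#' @param toxdb Toxicity tibble as from [read_toxdb()].
#' @return The residue tibble with `pclass`, `contact_phq`, `oral_phq`
#'   (NA where the route's LD50 is missing), `contact_skipped`,
#'   `oral_skipped` columns added.
#' @export
compound_phq <- function(residues, toxdb) {
  missing <- setdiff(unique(residues$compound), toxdb$compound)
  if (length(missing) > 0) {
    abort(paste0("Compound(s) absent from the toxicity database: ",
                 paste(missing, collapse = ", ")))
  }
  residues |>
    left_join(select(toxdb, "compound", "pclass", "contact_ld50",
                     "oral_ld50"),
              by = "compound") |>
    mutate(
      contact_phq = phq_raw(.data$concentration, .data$contact_ld50),
      oral_phq = phq_raw(.data$concentration, .data$oral_ld50),
      contact_skipped = .data$detected & is.na(.data$contact_ld50),
      oral_skipped = .data$detected & is.na(.data$oral_ld50)
    ) |>
    select(-"contact_ld50", -"oral_ld50")
}

#' Convert a total hazard quotient to percent of LD50
#'
#' Multiplying a PHQ (ng of pesticide per g pollen per \eqn{\mu}g/bee)
#' by the grams of pollen a bee encounters gives ng of pesticide per
#' \eqn{\mu}g LD50; dividing by 1000 converts ng to \eqn{\mu}g, leaving
#' the fraction of the LD50 received, and multiplying by 100 expresses
#' it as a percent. Contact exposure uses the single body-weight
#' equivalent contact dose; oral exposure uses intake rate times
#' duration. At the default assumptions: contact percent = PHQ x 0.01
#' and oral percent = PHQ x 0.0094.
#'
#' @param total_phq Total (summed) PHQ for the route, `>= 0`.
#' @param route `"contact"` or `"oral"`.
#' @param exposure An [exposure_params()] object.
#' @return Percent of the route LD50 received (vectorised over
#'   `total_phq`).
#' @export
#' @examples
#' pct_of_ld50(4000, "contact")  # 40% -- the EPA acute boundary
#' pct_of_ld50(319.1489, "oral") # ~3% -- the EFSA chronic boundary
pct_of_ld50 <- function(total_phq, route = c("contact", "oral"),
                        exposure = exposure_params()) {
  route <- match.arg(route)
  if (any(!is.finite(total_phq)) || any(total_phq < 0)) {
    abort("Total PHQ must be finite and non-negative.")
  }
  pollen_mg <- switch(route,
    contact = exposure$contact_mass_mg,
    oral = exposure$oral_rate_mg_per_day * exposure$duration_days
  )
  # ppb * g pollen = ng a.i.; /1000 -> ug; *100 -> percent of LD50.
  # Folded into one division so the regulatory boundaries (e.g. a total
  # contact PHQ of 4000 -> exactly 40%) are exact in floating point.
  total_phq * pollen_mg / 1e4
}

#' Classify exposure against regulatory levels of concern
#'
#' Each agency/route trigger is evaluated independently; a flag is TRUE
#' iff the exposure fraction (percent / 100) strictly exceeds the
#' trigger, so boundary equality does not flag.
#'
#' @param pct_contact Percent of contact LD50 (vector).
#' @param pct_oral Percent of oral LD50 (vector, same length).
#' @param thresholds A [loc_thresholds()] object.
#' @return A tibble of logicals `epa_acute_contact`,
#'   `efsa_acute_contact`, `efsa_chronic_oral`.
#' @export
classify_loc <- function(pct_contact, pct_oral,
                         thresholds = loc_thresholds()) {
  if (any(pct_contact < 0) || any(pct_oral < 0)) {
    abort("Percent-of-LD50 values must be non-negative.")
  }
  tibble(
    epa_acute_contact = pct_contact / 100 > thresholds$epa_acute_contact,
    efsa_acute_contact = pct_contact / 100 > thresholds$efsa_acute_contact,
    efsa_chronic_oral = pct_oral / 100 > thresholds$efsa_chronic_oral
  )
}

#' Attribute site hazard to compounds sprayed vs not sprayed during bloom
#'
#' A compound counts as "sprayed" at a site iff the spray records contain
#' a during-bloom application of that compound at that site. The
#' non-spray fraction is the share of the site's summed hazard quotient
#' carried by compounds without such an application (0 when the total is
#' 0). Residues at sites with no spray records at all are attributed
#' entirely to non-spray sources.
#'
#' @param phq_tbl Per-compound PHQ tibble as from [compound_phq()].
#' @param sprays Spray tibble as from [read_sprays()], or `NULL` for no
#'   spray records anywhere.
#' @return A tibble `site_id`, `nonspray_fraction_contact`,
#'   `nonspray_fraction_oral`, with fractions in `[0, 1]`.
#' @export
attribute_spray_status <- function(phq_tbl, sprays = NULL) {
  sprayed <- if (is.null(sprays) || nrow(sprays) == 0) {
    tibble(site_id = character(), compound = character(),
           sprayed = logical())
  } else {
    sprays |>
      filter(.data$during_bloom) |>
      distinct(.data$site_id, .data$compound) |>
      mutate(sprayed = TRUE)
  }
  phq_tbl |>
    left_join(sprayed, by = c("site_id", "compound")) |>
    mutate(sprayed = !is.na(.data$sprayed)) |>
    group_by(.data$site_id) |>
    summarise(
      nonspray_fraction_contact = frac_unsprayed(.data$contact_phq,
                                                 .data$sprayed),
      nonspray_fraction_oral = frac_unsprayed(.data$oral_phq,
                                              .data$sprayed),
      .groups = "drop"
    )
}

frac_unsprayed <- function(phq, sprayed) {
  phq[is.na(phq)] <- 0
  total <- sum(phq)
  if (total == 0) 0 else sum(phq[!sprayed]) / total
}

#' Site-level pesticide risk from beebread residues
#'
#' Aggregates per-compound hazard quotients into site totals per route
#' (additively, over detected compounds with an available LD50), converts
#' totals to percent of LD50 under the exposure assumptions, flags
#' regulatory levels of concern, and partitions hazard between compounds
#' sprayed and not sprayed during bloom.
#'
#' @param residues Residue tibble as from [read_residues()].
#' @param toxdb Toxicity tibble as from [read_toxdb()].
#' @param sprays Optional spray tibble as from [read_sprays()].
#' @param exposure An [exposure_params()] object.
#' @param thresholds A [loc_thresholds()] object.
#' @return A tibble with one row per site: PHQ totals per route,
#'   `pct_ld50_contact`, `pct_ld50_oral`, the three LOC flags,
#'   `nonspray_fraction_contact`, `nonspray_fraction_oral`,
#'   `n_detected`, and semicolon-separated `skipped_contact` /
#'   `skipped_oral` compound lists (detected compounds lacking that
#'   route's LD50).
#' @export
site_risk <- function(residues, toxdb, sprays = NULL,
                      exposure = exposure_params(),
                      thresholds = loc_thresholds()) {
  per <- compound_phq(residues, toxdb)
  totals <- per |>
    group_by(.data$site_id) |>
    summarise(
      total_contact_phq = sum(.data$contact_phq[.data$detected],
                              na.rm = TRUE),
      total_oral_phq = sum(.data$oral_phq[.data$detected], na.rm = TRUE),
      n_detected = sum(.data$detected),
      skipped_contact = paste(
        sort(.data$compound[.data$contact_skipped]), collapse = ";"),
      skipped_oral = paste(
        sort(.data$compound[.data$oral_skipped]), collapse = ";"),
      .groups = "drop"
    ) |>
    mutate(
      pct_ld50_contact = pct_of_ld50(.data$total_contact_phq, "contact",
                                     exposure),
      pct_ld50_oral = pct_of_ld50(.data$total_oral_phq, "oral", exposure)
    )
  flags <- classify_loc(totals$pct_ld50_contact, totals$pct_ld50_oral,
                        thresholds)
  nonspray <- attribute_spray_status(per, sprays)
  totals |>
    bind_cols(flags) |>
    left_join(nonspray, by = "site_id") |>
    select("site_id", "n_detected", "total_contact_phq",
           "total_oral_phq", "pct_ld50_contact", "pct_ld50_oral",
           "epa_acute_contact", "efsa_acute_contact",
           "efsa_chronic_oral", "nonspray_fraction_contact",
           "nonspray_fraction_oral", "skipped_contact", "skipped_oral")
}

#' Pesticide Use Index from spray records
#'
#' The Pesticide Use Index (PUI) summarises spray-record risk at a site
#' as the sum over during-bloom applications of
#' \deqn{\frac{1}{LD_{50}} \times \frac{\%ai}{100} \times \mathrm{app\ rate}}
#' with the contact LD50 in ug/bee, percent active ingredient on a
#' 0-100 scale, and application rate in kg product per hectare. Events
#' whose compound lacks a contact LD50 are skipped with a warning. An
#' optional compound panel restricts a second sum to the compounds also
#' quantified in pollen, allowing the two variants to be compared.
#'
#' @param sprays Spray tibble as from [read_sprays()].
#' @param toxdb Toxicity tibble as from [read_toxdb()].
#' @param panel Optional character vector of compounds for the
#'   restricted index; `NULL` gives `pui_panel` equal to `pui_all`.
#' @param sites Optional character vector of site ids that must appear
#'   in the result even with zero during-bloom events (PUI 0).
#' @return A tibble `site_id`, `n_events` (during-bloom events used),
#'   `pui_all`, `pui_panel`.
#' @export
pui <- function(sprays, toxdb, panel = NULL, sites = NULL) {
  ev <- sprays |>
    filter(.data$during_bloom) |>
    left_join(select(toxdb, "compound", "contact_ld50"), by = "compound")
  no_ld50 <- is.na(ev$contact_ld50)
  if (any(no_ld50)) {
    warn(sprintf(
      "Skipping %d spray event(s) with no contact LD50: %s",
      sum(no_ld50),
      paste(sort(unique(ev$compound[no_ld50])), collapse = ", ")))
    ev <- ev[!no_ld50, ]
  }
  ev <- mutate(ev,
               term = (1 / .data$contact_ld50) * (.data$pct_ai / 100) *
                 .data$app_rate,
               in_panel = if (is.null(panel)) TRUE else
                 .data$compound %in% panel)
  out <- ev |>
    group_by(.data$site_id) |>
    summarise(n_events = n(),
              pui_all = sum(.data$term),
              pui_panel = sum(.data$term[.data$in_panel]),
              .groups = "drop")
  all_sites <- union(out$site_id, c(sites, unique(sprays$site_id)))
  out |>
    right_join(tibble(site_id = sort(all_sites)), by = "site_id") |>
    mutate(n_events = coalesce(.data$n_events, 0L),
           pui_all = coalesce(.data$pui_all, 0),
           pui_panel = coalesce(.data$pui_panel, 0)) |>
    arrange(.data$site_id)
}

#' Compound-level residue and hazard summary across sites
#'
#' For every compound in the toxicity database: the number of sites with
#' a positive detection, the mean residue over positive detections only
#' (0 when never detected), and the mean contact/oral hazard quotients
#' obtained by dividing that mean by the route LD50 (equivalently,
#' summing per-site PHQs and dividing by the number of positive
#' detections). Rows are ordered by descending mean contact PHQ with
#' missing values last — the conventional presentation of a residue
#' screening table.
#'
#' @param residues Residue tibble as from [read_residues()], covering
#'   all sites.
#' @param toxdb Toxicity tibble as from [read_toxdb()].
#' @return A tibble `compound`, `pclass`, `mean_residue`,
#'   `n_detections`, `mean_contact_phq`, `mean_oral_phq`.
#' @export
compound_summary <- function(residues, toxdb) {
  missing <- setdiff(unique(residues$compound), toxdb$compound)
  if (length(missing) > 0) {
    abort(paste0("Compound(s) absent from the toxicity database: ",
                 paste(missing, collapse = ", ")))
  }
  residues |>
    group_by(.data$compound) |>
    summarise(
      n_detections = sum(.data$detected),
      mean_residue = if (any(.data$detected)) {
        mean(.data$concentration[.data$detected])
      } else 0,
      .groups = "drop"
    ) |>
    right_join(select(toxdb, "compound", "pclass", "contact_ld50",
                      "oral_ld50"),
               by = "compound") |>
    mutate(
      n_detections = coalesce(.data$n_detections, 0L),
      mean_residue = coalesce(.data$mean_residue, 0),
      mean_contact_phq = .data$mean_residue / .data$contact_ld50,
      mean_oral_phq = .data$mean_residue / .data$oral_ld50
    ) |>
    select("compound", "pclass", "mean_residue", "n_detections",
           "mean_contact_phq", "mean_oral_phq") |>
    arrange(desc(.data$mean_contact_phq))
}
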