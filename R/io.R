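#' Read a compound toxicity database
#'
#' Reads a CSV with columns `compound,pclass,contact_ld50_ug_per_bee,`
#' `oral_ld50_ug_per_bee`. LD50 values are in micrograms of active
#' ingredient per bee; an empty cell means the value is unavailable for
#' that route (common for oral toxicity) and is kept as `NA`, never
#' coerced to zero or infinity. Downstream hazard computations skip and
#' flag routes with missing LD50.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `compound`, `pclass` (one of
#'   `"insecticide"`, `"fungicide"`, `"herbicide"`), `contact_ld50`,
#'   `oral_ld50` (ug/bee).
#' @export
read_toxdb <- function(path) {
  tb <- readr::read_csv(path, col_types = readr::cols(
    compound = readr::col_character(),
    pclass = readr::col_character(),
    contact_ld50_ug_per_bee = readr::col_double(),
    oral_ld50_ug_per_bee = readr::col_double()
  ))
  tb <- rename(tb, contact_ld50 = "contact_ld50_ug_per_bee",
               oral_ld50 = "oral_ld50_ug_per_bee")
  validate_toxdb(tb)
}

validate_toxdb <- function(tb) {
  dup <- tb$compound[duplicated(tb$compound)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate compound name(s) in toxicity database: ",
                 paste(unique(dup), collapse = ", ")))
  }
  bad_class <- setdiff(unique(tb$pclass),
                       c("insecticide", "fungicide", "herbicide"))
  if (length(bad_class) > 0) {
    abort(paste0("Unknown pesticide class(es): ",
                 paste(bad_class, collapse = ", ")))
  }
  for (col in c("contact_ld50", "oral_ld50")) {
    bad <- which(!is.na(tb[[col]]) & tb[[col]] <= 0)
    if (length(bad) > 0) {
      abort(sprintf("Non-positive %s for compound(s): %s", col,
                    paste(tb$compound[bad], collapse = ", ")))
    }
  }
  as_tibble(tb)
}

#' The bundled 25-compound apple-orchard screening panel
#'
#' Toxicity database for the 25 pesticides (14 insecticides, 10
#' fungicides, 1 herbicide) screened in beebread in a 30-orchard apple
#' bloom monitoring campaign. Honey bee contact and oral LD50 values were
#' compiled from the Tomlin Pesticide Manual, the US EPA ECOTOX database
#' and the French AgriTox database; oral LD50 is unavailable for
#' abamectin, atrazine and fenbuconazole.
#'
#' @return A toxicity tibble as from [read_toxdb()].
#' @export
#' @examples
#' orchard_toxdb()
orchard_toxdb <- function() {
  read_toxdb(system.file("extdata", "toxdb.csv", package = "pollenrisk"))
}

#' Bundled compound-level residue summary from the orchard campaign
#'
#' Per-compound summary of the same 30-site screening: mean residue
#' concentration over positive detections (ppb), the number of sites
#' with a detection, and the analytical limit of detection. Together
#' with [orchard_toxdb()] this is the worked example used throughout
#' the documentation.
#'
#' @return A tibble with columns `compound`, `mean_residue_ppb`,
#'   `n_detections`, `lod_ppb`.
#' @export
orchard_residue_summary <- function() {
  readr::read_csv(
    system.file("extdata", "residue_summary.csv", package = "pollenrisk"),
    col_types = readr::cols(
      compound = readr::col_character(),
      mean_residue_ppb = readr::col_double(),
      n_detections = readr::col_integer(),
      lod_ppb = readr::col_double()
    ))
}

#' Read per-site beebread residue records
#'
#' CSV schema: `site_id,compound,concentration_ppb,lod_ppb`. Concentrations
#' are ng/g pollen (ppb). A record is a detection iff its concentration is
#' at or above the compound's limit of detection; positive concentrations
#' below the LOD are coerced to 0 with a warning (the convention for
#' sub-LOD signals), so non-detects always carry concentration 0.
#'
#' @param path Path to the CSV file.
#' @return A tibble `site_id`, `compound`, `concentration` (ppb), `lod`
#'   (ppb), `detected` (logical).
#' @export
read_residues <- function(path) {
  tb <- readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    compound = readr::col_character(),
    concentration_ppb = readr::col_double(),
    lod_ppb = readr::col_double()
  ))
  tb <- rename(tb, concentration = "concentration_ppb", lod = "lod_ppb")
  validate_residues(tb)
}

validate_residues <- function(tb) {
  if (any(!is.finite(tb$concentration))) {
    abort("Residue concentrations must be finite.")
  }
  if (any(tb$concentration < 0)) {
    bad <- which(tb$concentration < 0)
    abort(sprintf("Negative residue concentration at row(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  if (any(!is.finite(tb$lod) | tb$lod <= 0)) {
    abort("Limits of detection must be finite and strictly positive.")
  }
  sub_lod <- tb$concentration > 0 & tb$concentration < tb$lod
  if (any(sub_lod)) {
    warn(sprintf(
      "%d residue record(s) below the limit of detection coerced to 0.",
      sum(sub_lod)))
    tb$concentration[sub_lod] <- 0
  }
  tb$detected <- tb$concentration >= tb$lod
  as_tibble(tb)
}

#' Read spray records
#'
#' CSV schema: `site_id,compound,date,pct_ai,app_rate_kg_per_ha,during_bloom`.
#' `pct_ai` is the percent of active ingredient in the applied product on a
#' 0-100 scale; `app_rate` is kg product per hectare; `during_bloom` marks
#' applications made while the focal crop was in bloom (an explicit column,
#' since bloom windows differ between sites). Dates are ISO-8601.
#'
#' @param path Path to the CSV file.
#' @return A tibble `site_id`, `compound`, `date` (Date), `pct_ai`,
#'   `app_rate`, `during_bloom`.
#' @export
read_sprays <- function(path) {
  tb <- readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    compound = readr::col_character(),
    date = readr::col_date(format = "%Y-%m-%d"),
    pct_ai = readr::col_double(),
    app_rate_kg_per_ha = readr::col_double(),
    during_bloom = readr::col_logical()
  ))
  tb <- rename(tb, app_rate = "app_rate_kg_per_ha")
  validate_sprays(tb)
}

validate_sprays <- function(tb) {
  if (any(!is.finite(tb$pct_ai) | tb$pct_ai <= 0 | tb$pct_ai > 100)) {
    abort("pct_ai must lie in (0, 100].")
  }
  if (any(!is.finite(tb$app_rate) | tb$app_rate <= 0)) {
    abort("Application rates must be strictly positive.")
  }
  if (any(is.na(tb$during_bloom))) abort("during_bloom must be TRUE/FALSE.")
  as_tibble(tb)
}

#' Read pollen morphotype counts
#'
#' Long CSV schema: `site_id,morphotype,count`, one row per morphotype
#' observed on a site's slide. Counts are grains classified along slide
#' transects (target 300 grains per pooled site sample).
#'
#' @param path Path to the CSV file.
#' @return A tibble `site_id`, `morphotype`, `count`.
#' @export
read_pollen <- function(path) {
  tb <- readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    morphotype = readr::col_character(),
    count = readr::col_integer()
  ))
  validate_pollen(tb)
}

validate_pollen <- function(tb) {
  if (any(is.na(tb$count) | tb$count < 0)) {
    abort("Pollen counts must be non-negative integers.")
  }
  if (anyDuplicated(tb[c("site_id", "morphotype")]) > 0) {
    abort("Duplicate (site_id, morphotype) pollen count rows.")
  }
  as_tibble(tb)
}

#' Total grains counted per site
#'
#' @param pollen A pollen count tibble as from [read_pollen()].
#' @return A tibble `site_id`, `total_counted`.
#' @export
pollen_totals <- function(pollen) {
  pollen |>
    group_by(.data$site_id) |>
    summarise(total_counted = sum(.data$count), .groups = "drop")
}

#' Read apiary site coordinates
#'
#' CSV schema: `site_id,x_m,y_m`, with coordinates in metres in the same
#' planar system as the land-cover grid.
#'
#' @param path Path to the CSV file.
#' @return A tibble `site_id`, `x_m`, `y_m`.
#' @export
read_sites <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    x_m = readr::col_double(),
    y_m = readr::col_double()
  ))
}

# ---- writers (canonical on-disk schemas; round-trip with the readers) ----

#' Write package tables in their canonical CSV schemas
#'
#' Inverse of the corresponding readers: column names and units on disk
#' match what [read_toxdb()], [read_residues()], [read_sprays()],
#' [read_pollen()] and [read_sites()] expect, so a write/read round trip
#' reproduces the table.
#'
#' @param tb The tibble to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
write_toxdb <- function(tb, path) {
  out <- tb |>
    select("compound", "pclass",
           contact_ld50_ug_per_bee = "contact_ld50",
           oral_ld50_ug_per_bee = "oral_ld50")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname writers
#' @export
write_residues <- function(tb, path) {
  out <- tb |>
    select("site_id", "compound",
           concentration_ppb = "concentration", lod_ppb = "lod")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname writers
#' @export
write_sprays <- function(tb, path) {
  out <- tb |>
    select("site_id", "compound", "date", "pct_ai",
           app_rate_kg_per_ha = "app_rate", "during_bloom")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname writers
#' @export
write_pollen <- function(tb, path) {
  readr::write_csv(select(tb, "site_id", "morphotype", "count"), path)
  invisible(path)
}

#' @rdname writers
#' @export
write_sites <- function(tb, path) {
  readr::write_csv(select(tb, "site_id", "x_m", "y_m"), path)
  invisible(path)
}
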