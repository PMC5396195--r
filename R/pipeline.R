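#' Run the full pesticide-risk analysis
#'
#' Orchestrates every stage on one study — either a directory of input
#' CSVs in the canonical schemas (see [read_residues()] and friends) or
#' a [generate_study()] object — and returns the result surfaces: the
#' compound-level residue/hazard summary, the per-site risk table with
#' level-of-concern flags and sprayed/non-sprayed attribution, the
#' spray-record use index, pollen composition, landscape buffer
#' composition with AIC-selected scale (when a grid is present), the
#' regression table, and an aggregate summary.
#'
#' When `out_dir` is given, each table is written as a flat CSV
#' (`compound_summary.csv` with hazard columns rounded half-up to one
#' decimal, the reporting convention; all other tables full precision)
#' plus a `summary.json`.
#'
#' @param input A `synth_study` object or a directory containing
#'   `toxdb.csv`, `residues.csv`, `sprays.csv`, `pollen_counts.csv`,
#'   `sites.csv` and optionally `grid.asc` + `class_map.csv`.
#' @param out_dir Optional output directory.
#' @param exposure An [exposure_params()] object.
#' @param thresholds A [loc_thresholds()] object.
#' @param focal Focal-crop morphotype (default `"Malus"`).
#' @param radii Candidate buffer radii in metres.
#' @param panel Compound panel for the restricted use index; defaults
#'   to the compounds present in the residue table (the compounds
#'   quantified in pollen).
#' @param config Optional path to a YAML file with keys
#'   `exposure.bee_mass_mg`, `exposure.contact_mass_mg`,
#'   `exposure.oral_rate_mg_per_day`, `exposure.duration_days`,
#'   `thresholds.epa_acute_contact`, `thresholds.efsa_acute_contact`,
#'   `thresholds.efsa_chronic_oral`, `focal_morphotype`; values given
#'   there override the corresponding arguments.
#' @return A list of class `risk_report`: `compound_summary`,
#'   `site_risk`, `pui`, `pollen_composition`, `buffers` (or `NULL`),
#'   `scale` (or `NULL`), `regressions`, `site_data` (the merged
#'   per-site analysis frame) and `summary`.
#' @export
run_pipeline <- function(input, out_dir = NULL,
                         exposure = exposure_params(),
                         thresholds = loc_thresholds(),
                         focal = "Malus",
                         radii = c(1000, 2000, 3000),
                         panel = NULL, config = NULL) {
  if (!is.null(config)) {
    cfg <- yaml::read_yaml(config)
    if (!is.null(cfg$exposure)) {
      exposure <- do.call(exposure_params, cfg$exposure)
    }
    if (!is.null(cfg$thresholds)) {
      thresholds <- do.call(loc_thresholds, cfg$thresholds)
    }
    if (!is.null(cfg$focal_morphotype)) focal <- cfg$focal_morphotype
  }

  if (inherits(input, "synth_study")) {
    toxdb <- input$toxdb
    residues <- input$residues
    sprays <- input$sprays
    pollen <- input$pollen
    sites <- input$sites
    grid <- input$grid
    seed <- input$truth$seed
  } else if (is.character(input) && dir.exists(input)) {
    toxdb <- read_toxdb(file.path(input, "toxdb.csv"))
    residues <- read_residues(file.path(input, "residues.csv"))
    sprays <- read_sprays(file.path(input, "sprays.csv"))
    pollen <- read_pollen(file.path(input, "pollen_counts.csv"))
    sites <- read_sites(file.path(input, "sites.csv"))
    grid_path <- file.path(input, "grid.asc")
    grid <- if (file.exists(grid_path)) {
      read_grid(grid_path, file.path(input, "class_map.csv"))
    } else NULL
    seed <- NA
  } else {
    abort("`input` must be a synth_study or an existing directory.")
  }

  if (is.null(panel)) panel <- unique(residues$compound)

  comp_sum <- compound_summary(residues, toxdb)
  risk <- site_risk(residues, toxdb, sprays, exposure, thresholds)
  pui_tbl <- pui(sprays, toxdb, panel = panel,
                 sites = unique(residues$site_id))
  composition <- pollen_composition(pollen, focal = focal)

  buffers <- NULL
  scale_sel <- NULL
  if (!is.null(grid)) {
    buffers <- buffer_composition(grid, sites, radii)
    scale_sel <- select_buffer_scale(
      buffers,
      composition |> transmute(.data$site_id,
                               value = 100 * .data$focal_fraction))
  }

  per <- compound_phq(residues, toxdb) |> filter(.data$detected)
  site_tot <- per |>
    group_by(.data$site_id) |>
    summarise(
      total_residue = sum(.data$concentration),
      total_fungicide = sum(.data$concentration[
        .data$pclass == "fungicide"]),
      total_insecticide = sum(.data$concentration[
        .data$pclass == "insecticide"]),
      .groups = "drop")

  site_data <- composition |>
    mutate(pct_focal_pollen = 100 * .data$focal_fraction) |>
    left_join(site_tot, by = "site_id") |>
    left_join(select(risk, "site_id", "total_contact_phq",
                     "total_oral_phq"), by = "site_id") |>
    left_join(select(pui_tbl, "site_id", "pui_all", "pui_panel"),
              by = "site_id") |>
    mutate(across(c("total_residue", "total_fungicide",
                    "total_insecticide"),
                  \(v) coalesce(v, 0)))
  if (!is.null(buffers)) {
    site_data <- site_data |>
      left_join(buffers |>
                  filter(.data$radius == scale_sel$radius) |>
                  select("site_id", "pct_natural", "pct_agricultural",
                         "pct_apple"),
                by = "site_id")
  }

  pairs <- tibble(
    response = c("pct_focal_pollen", "total_residue",
                 "total_fungicide", "total_insecticide",
                 "total_insecticide", "total_contact_phq",
                 "total_contact_phq"),
    predictor = c(rep("pct_apple", 2), "pct_focal_pollen",
                  "pct_focal_pollen", "richness", "richness",
                  "pui_panel"))
  # keep only identifiable pairs: both columns present and non-constant
  usable <- function(col) {
    col %in% names(site_data) &&
      sum(is.finite(site_data[[col]])) >= 3 &&
      sd(site_data[[col]], na.rm = TRUE) > 0
  }
  pairs <- filter(pairs, vapply(.data$predictor, usable, logical(1)),
                  vapply(.data$response, usable, logical(1)))
  regressions <- fit_regressions(site_data, pairs)

  overall_nonspray <- function(frac, tot) {
    if (sum(tot) == 0) 0 else sum(frac * tot) / sum(tot)
  }
  detected_pairs <- per |> distinct(.data$site_id, .data$compound)
  bloom <- sprays |>
    filter(.data$during_bloom) |>
    distinct(.data$site_id, .data$compound) |>
    mutate(sprayed = TRUE)
  det_unsprayed <- detected_pairs |>
    left_join(bloom, by = c("site_id", "compound")) |>
    summarise(frac = mean(is.na(.data$sprayed))) |>
    pull("frac")

  summary <- list(
    seed = seed,
    n_sites = nrow(risk),
    n_sites_epa_acute_contact = sum(risk$epa_acute_contact),
    n_sites_efsa_acute_contact = sum(risk$efsa_acute_contact),
    n_sites_efsa_chronic_oral = sum(risk$efsa_chronic_oral),
    overall_nonspray_share_contact = overall_nonspray(
      risk$nonspray_fraction_contact, risk$total_contact_phq),
    overall_nonspray_share_oral = overall_nonspray(
      risk$nonspray_fraction_oral, risk$total_oral_phq),
    fraction_detected_compounds_unsprayed = det_unsprayed,
    selected_radius_m = if (is.null(scale_sel)) NA else
      scale_sel$radius,
    exposure = unclass(exposure),
    thresholds = unclass(thresholds)
  )

  report <- structure(
    list(compound_summary = comp_sum, site_risk = risk, pui = pui_tbl,
         pollen_composition = composition, buffers = buffers,
         scale = scale_sel, regressions = regressions,
         site_data = site_data, summary = summary),
    class = "risk_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    comp_out <- comp_sum |>
      mutate(across(c("mean_contact_phq", "mean_oral_phq"),
                    \(v) round_half_up(v, 1)))
    readr::write_csv(comp_out, file.path(out_dir,
                                         "compound_summary.csv"),
                     na = "")
    readr::write_csv(risk, file.path(out_dir, "site_risk.csv"))
    readr::write_csv(pui_tbl, file.path(out_dir, "pui.csv"))
    readr::write_csv(composition,
                     file.path(out_dir, "pollen_composition.csv"))
    if (!is.null(buffers)) {
      readr::write_csv(buffers, file.path(out_dir, "buffers.csv"))
    }
    readr::write_csv(regressions,
                     file.path(out_dir, "regressions.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  report
}

#' @export
print.risk_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Pesticide risk report: %d sites\n", s$n_sites))
  cat(sprintf(
    "  sites above LOC: EPA acute contact %d, EFSA acute contact %d, EFSA chronic oral %d\n",
    s$n_sites_epa_acute_contact, s$n_sites_efsa_acute_contact,
    s$n_sites_efsa_chronic_oral))
  cat(sprintf(
    "  hazard share from compounds not sprayed during bloom: %.0f%% contact, %.0f%% oral\n",
    100 * s$overall_nonspray_share_contact,
    100 * s$overall_nonspray_share_oral))
  cat(sprintf(
    "  detected compounds not sprayed at their site: %.0f%%\n",
    100 * s$fraction_detected_compounds_unsprayed))
  invisible(x)
}
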