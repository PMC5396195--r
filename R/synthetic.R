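# Synthetic orchard studies with the statistical structure the analysis
# assumes: a focal-crop density gradient, pollen composition coupled to
# landscape, fungicide residues coupled to focal-crop pollen, insecticide
# residues coupled to pollen richness, and never-sprayed contaminant
# compounds appearing at a Poisson rate per site.

# 20-morphotype pollen pool (focal crop first)
synth_morphotypes <- function() {
  c("Malus", "Rhamnus", "Crataegus", "Rubus", "Aesculus", "Chicorieae",
    "Lonicera", "Fragaria", "Prunus", "Salix", paste0("Unknown_", 1:10))
}

# Compounds growers apply during bloom in the emulated system. Fungicide
# sprays dominate; insecticides are applied at a subset of sites. The
# fungicide panel is restricted to low-LOD compounds so share-splitting a
# site total rarely censors.
FUNG_SPRAYED <- c("Cyprodinil", "Difenoconazole", "Thiophanate-methyl",
                  "Penthiopyrad", "Trifloxystrobin")
INSECT_SPRAYED <- c("Acetamiprid", "Carbaryl", "Indoxacarb", "Phosmet",
                    "Spinetoram", "Spinosad", "Thiacloprid",
                    "Thiamethoxam")
# Compounds never sprayed during bloom anywhere: the source pool for
# "novel" per-site contamination.
NOVEL_INSECT <- c("Chlorantraniliprole", "Clothianidin", "Cyfluthrin",
                  "Fenpyroximate", "Imidacloprid")
NOVEL_FUNG <- c("Fluxapyroxad", "Myclobutanil", "Boscalid")
NOVEL_HERB <- "Atrazine"

#' Configuration for a synthetic orchard study
#'
#' Defaults emulate the study conditions the package targets: 30 orchard
#' sites with 4 pooled colonies each, 300-grain pollen slides, an
#' apple-area gradient spanning 0-35% of the foraging buffer, apple
#' pollen collection coupled to apple area at \eqn{R^2} 0.67, total
#' fungicide residues coupled to apple pollen at \eqn{R^2} 0.46, total
#' insecticide residues coupled to pollen richness at \eqn{R^2} 0.12,
#' and a mean of 2.8 never-sprayed compounds detected per site (which
#' leaves roughly 28 of 30 sites with at least one).
#'
#' @param n_sites Number of orchard sites.
#' @param colonies_per_site Colonies pooled per site sample.
#' @param grains_per_slide Pollen grains counted per site slide.
#' @param seed Master seed; one sub-stream per generator component is
#'   derived from it, so regenerating one component's parameters does
#'   not perturb the others.
#' @param r2_apple_pollen Target expected sample \eqn{R^2} for the
#'   apple-area to apple-pollen regression.
#' @param r2_fungicide Target for apple-pollen to total-fungicide.
#' @param r2_insecticide_richness Target for richness to
#'   total-insecticide. 0 switches the coupling off.
#' @param nonspray_rate Poisson mean of never-sprayed compounds
#'   detected per site.
#' @param nonspray_site_fraction Intended fraction of sites with at
#'   least one never-sprayed compound (informational; the Poisson draw
#'   at rate 2.8 already gives 0.939 vs the 28/30 = 0.933 target).
#' @param toxdb Toxicity database used for the compound panel.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_sites = 30, colonies_per_site = 4,
                         grains_per_slide = 300, seed = 1L,
                         r2_apple_pollen = 0.67, r2_fungicide = 0.46,
                         r2_insecticide_richness = 0.12,
                         nonspray_rate = 2.8,
                         nonspray_site_fraction = 28 / 30,
                         toxdb = orchard_toxdb()) {
  if (n_sites < 3) abort("Need at least 3 sites.")
  for (r2 in c(r2_apple_pollen, r2_fungicide, r2_insecticide_richness)) {
    if (!is.finite(r2) || r2 < 0 || r2 > 1) {
      abort("R-squared targets must lie in [0, 1].")
    }
  }
  if (nonspray_rate < 0) abort("nonspray_rate must be non-negative.")
  if (nonspray_site_fraction < 0 || nonspray_site_fraction > 1) {
    abort("nonspray_site_fraction must lie in [0, 1].")
  }
  structure(list(
    n_sites = as.integer(n_sites),
    colonies_per_site = as.integer(colonies_per_site),
    grains_per_slide = as.integer(grains_per_slide),
    seed = as.integer(seed),
    r2_apple_pollen = r2_apple_pollen,
    r2_fungicide = r2_fungicide,
    r2_insecticide_richness = r2_insecticide_richness,
    nonspray_rate = nonspray_rate,
    nonspray_site_fraction = nonspray_site_fraction,
    toxdb = toxdb
  ), class = "synth_config")
}

# Noise SD solving var(signal)/(var(signal)+var(noise)) = rho2, where
# rho2 is the population R2 whose EXPECTED SAMPLE R2 equals the target:
# E[R2_hat] ~ rho2 + (1 - rho2)/(n - 2), inverted here. `extra_var` is
# pre-existing measurement noise (e.g. multinomial counting variance)
# already sitting on top of the signal.
solve_noise_sd <- function(var_sig, r2_target, n, extra_var = 0) {
  if (r2_target >= 1) return(0)
  b <- 1 / (n - 2)
  rho2 <- (r2_target - b) / (1 - b)
  rho2 <- min(max(rho2, 1e-6), 1)
  sqrt(max(var_sig * (1 - rho2) / rho2 - extra_var, 0))
}

#' Generate a complete synthetic orchard study
#'
#' Deterministic given the config seed. Produces sites (with true
#' landscape composition), an optional categorical land-cover grid
#' realising that composition, during-bloom spray records, 300-grain
#' pollen counts, a full-panel residue table (censored at each
#' compound's limit of detection), and a ground-truth record for
#' parameter-recovery tests.
#'
#' @param config A [synth_config()] object.
#' @param include_grid Build the land-cover raster? Skipping it leaves
#'   every other component byte-identical (separate random stream) and
#'   is convenient in replicate loops that only need the tables.
#' @return An object of class `synth_study`: a list with `sites`,
#'   `grid` (or `NULL`), `sprays`, `pollen`, `residues`, `toxdb`,
#'   `truth`.
#' @export
#' @examples
#' study <- generate_study(synth_config(seed = 1), include_grid = FALSE)
#' head(study$residues)
generate_study <- function(config, include_grid = TRUE) {
  if (!inherits(config, "synth_config")) {
    abort("`config` must be a synth_config object.")
  }
  set.seed(config$seed)
  ss <- sample.int(2147483646L, 5)
  n <- config$n_sites
  grains <- config$grains_per_slide
  site_ids <- sprintf("S%02d", seq_len(n))
  panel_summary <- orchard_residue_summary()
  lods <- panel_summary |> select("compound", "lod_ppb")
  # Relative per-compound magnitude scales anchored to the screening
  # panel's observed mean residues, so the toxic insecticides do not
  # receive implausibly large mass shares.
  mag_scale <- setNames(pmax(panel_summary$mean_residue_ppb, 5),
                        panel_summary$compound)

  # ---- landscape stream: focal-crop gradient + site composition ----
  set.seed(ss[1])
  apple_area <- sample(seq(0.005, 0.35, length.out = n))
  w_nat <- rgamma(n, 4, 1)
  w_ag <- rgamma(n, 3, 1)
  w_oth <- rgamma(n, 1.5, 1)
  rest <- 1 - apple_area
  nat_frac <- rest * w_nat / (w_nat + w_ag + w_oth)
  ag_frac <- rest * w_ag / (w_nat + w_ag + w_oth)
  oth_frac <- rest - nat_frac - ag_frac

  tile_cells <- 210L                 # 6300 m tiles; 3 km buffers fit
  cell <- 30
  tiles_per_row <- ceiling(sqrt(n))
  tile_rows <- ceiling(n / tiles_per_row)
  tile_m <- tile_cells * cell
  total_h <- tile_rows * tile_m
  tr <- (seq_len(n) - 1) %/% tiles_per_row + 1
  tc <- (seq_len(n) - 1) %% tiles_per_row + 1
  sites <- tibble(
    site_id = site_ids,
    x_m = (tc - 0.5) * tile_m,
    y_m = total_h - (tr - 0.5) * tile_m,
    apple_area = apple_area,
    pct_apple_area = 100 * apple_area,
    pct_natural_area = 100 * nat_frac,
    pct_agricultural_area = 100 * (ag_frac + apple_area)
  )

  # ---- pollen stream: composition coupled to the landscape ----
  set.seed(ss[2])
  aP <- 0.01
  bP <- if (config$r2_apple_pollen > 0) 0.55 else 0
  mean_p <- aP + bP * mean(apple_area)
  mult_var <- mean_p * (1 - mean_p) / grains
  sdP <- if (bP == 0) 0.05 else {
    solve_noise_sd(bP^2 * var(apple_area), config$r2_apple_pollen, n,
                   extra_var = mult_var)
  }
  p_latent <- pmin(pmax(aP + bP * apple_area + rnorm(n, 0, sdP),
                        0.001), 0.95)
  pool <- synth_morphotypes()
  nonfocal <- setdiff(pool, "Malus")
  pollen_rows <- vector("list", n)
  for (i in seq_len(n)) {
    m_i <- sample(8:16, 1)
    chosen <- sample(nonfocal, m_i)
    w <- rgamma(m_i, shape = 0.7)
    probs <- c(p_latent[i], (1 - p_latent[i]) * w / sum(w))
    cnt <- as.integer(rmultinom(1, grains, probs))
    pollen_rows[[i]] <- tibble(site_id = site_ids[i],
                               morphotype = c("Malus", chosen),
                               count = cnt)
  }
  pollen <- list_rbind(pollen_rows)
  p_hat <- pollen |>
    group_by(.data$site_id) |>
    summarise(p = sum(.data$count[.data$morphotype == "Malus"]) /
                sum(.data$count), .groups = "drop") |>
    pull("p")

  # realized richness under the 3% sporadic rule (no RNG involved)
  rich <- pollen_composition(pollen)$richness

  # ---- spray stream: fungicide-dominated during-bloom records ----
  set.seed(ss[3])
  n_nospray <- round(0.1 * n)
  nospray_sites <- if (n_nospray > 0) sample(site_ids, n_nospray) else
    character()
  bloom_days <- seq(as.Date("2015-05-07"), as.Date("2015-05-22"), 1)
  pre_days <- seq(as.Date("2015-04-20"), as.Date("2015-05-05"), 1)
  spray_rows <- list()
  for (i in seq_len(n)) {
    sid <- site_ids[i]
    if (!sid %in% nospray_sites) {
      fungs <- sample(FUNG_SPRAYED, sample(2:4, 1))
      comps <- fungs
      if (runif(1) < 0.6) {
        comps <- c(comps, sample(INSECT_SPRAYED, sample(1:2, 1)))
      }
      spray_rows[[length(spray_rows) + 1]] <- tibble(
        site_id = sid, compound = comps,
        date = sample(bloom_days, length(comps), replace = TRUE),
        pct_ai = round(runif(length(comps), 20, 90), 1),
        app_rate = round(rlnorm(length(comps), 0.3, 0.4), 3),
        during_bloom = TRUE)
    }
    n_pre <- sample(0:2, 1)
    if (n_pre > 0) {
      spray_rows[[length(spray_rows) + 1]] <- tibble(
        site_id = sid,
        compound = sample(c(FUNG_SPRAYED, INSECT_SPRAYED), n_pre),
        date = sample(pre_days, n_pre, replace = TRUE),
        pct_ai = round(runif(n_pre, 20, 90), 1),
        app_rate = round(rlnorm(n_pre, 0.3, 0.4), 3),
        during_bloom = FALSE)
    }
  }
  sprays <- list_rbind(spray_rows) |> arrange(.data$site_id, .data$date)
  bloom_sets <- sprays |>
    filter(.data$during_bloom) |>
    distinct(.data$site_id, .data$compound)

  # ---- residue stream: totals coupled to pollen, split by compound ----
  set.seed(ss[4])
  aF <- 800
  bF <- if (config$r2_fungicide > 0) 8000 else 0
  sdF <- if (bF == 0) 600 else {
    solve_noise_sd(bF^2 * var(p_hat), config$r2_fungicide, n)
  }
  total_fung <- pmax(aF + bF * p_hat + rnorm(n, 0, sdF), 1)
  aI <- 60
  bI <- if (config$r2_insecticide_richness > 0) 9 else 0
  sdI <- if (bI == 0) 150 else {
    solve_noise_sd(bI^2 * var(rich), config$r2_insecticide_richness, n)
  }
  total_insect <- pmax(aI + bI * rich + rnorm(n, 0, sdI), 1)

  novel_pool <- c(NOVEL_INSECT, NOVEL_FUNG, NOVEL_HERB)
  residue_rows <- vector("list", n)
  n_novel <- integer(n)
  for (i in seq_len(n)) {
    sid <- site_ids[i]
    sprayed_here <- bloom_sets$compound[bloom_sets$site_id == sid]
    det_f <- intersect(sprayed_here, FUNG_SPRAYED)
    det_f <- det_f[runif(length(det_f)) < 0.8]
    det_i <- intersect(sprayed_here, INSECT_SPRAYED)
    det_i <- det_i[runif(length(det_i)) < 0.6]
    k <- min(rpois(1, config$nonspray_rate), length(novel_pool))
    novel <- if (k > 0) sample(novel_pool, k) else character()
    fung_set <- union(det_f, intersect(novel, NOVEL_FUNG))
    ins_set <- union(det_i, intersect(novel, NOVEL_INSECT))
    if (length(fung_set) == 0) fung_set <- "Cyprodinil"
    if (length(ins_set) == 0) {
      extra <- sample(NOVEL_INSECT, 1)
      ins_set <- extra
      novel <- union(novel, extra)
    }
    n_novel[i] <- length(novel)
    conc <- setNames(numeric(nrow(config$toxdb)), config$toxdb$compound)
    msc <- function(comps) coalesce(mag_scale[comps], 50)
    wf <- rgamma(length(fung_set), 1) * msc(fung_set)
    conc[fung_set] <- total_fung[i] * wf / sum(wf)
    wi <- rgamma(length(ins_set), 1) * msc(ins_set)
    conc[ins_set] <- total_insect[i] * wi / sum(wi)
    if (NOVEL_HERB %in% novel) conc[NOVEL_HERB] <- rlnorm(1, log(30), 0.5)
    residue_rows[[i]] <- tibble(site_id = sid,
                                compound = names(conc),
                                concentration = unname(conc))
  }
  residues <- list_rbind(residue_rows) |>
    left_join(lods, by = "compound") |>
    rename(lod = "lod_ppb") |>
    mutate(lod = coalesce(.data$lod, 1)) |>
    mutate(
      concentration = ifelse(.data$concentration < .data$lod, 0,
                             .data$concentration),
      detected = .data$concentration >= .data$lod)

  # ---- optional land-cover grid realising the site compositions ----
  grid <- NULL
  if (include_grid) {
    set.seed(ss[5])
    grid <- synth_grid(n, tile_cells, cell, tiles_per_row, tile_rows,
                       apple_area, nat_frac, ag_frac, oth_frac)
  }

  truth <- list(
    seed = config$seed,
    site_id = site_ids,
    apple_area = apple_area,
    p_apple_latent = p_latent,
    p_apple_measured = p_hat,
    richness = rich,
    total_fungicide = total_fung,
    total_insecticide = total_insect,
    n_novel = n_novel,
    coefficients = list(
      apple_pollen = c(intercept = aP, slope = bP, noise_sd = sdP),
      fungicide = c(intercept = aF, slope = bF, noise_sd = sdF),
      insecticide = c(intercept = aI, slope = bI, noise_sd = sdI)),
    nonspray = truth_nonspray(residues, bloom_sets, config$toxdb)
  )

  structure(list(sites = sites, grid = grid, sprays = sprays,
                 pollen = pollen, residues = residues,
                 toxdb = config$toxdb, truth = truth,
                 config = config),
            class = "synth_study")
}

# Plain-loop attribution of site hazard to never-sprayed compounds,
# independent of attribute_spray_status(): the generator's own account
# of its sprayed/non-sprayed hazard split.
truth_nonspray <- function(residues, bloom_sets, toxdb) {
  sids <- unique(residues$site_id)
  out <- tibble(site_id = sids,
                nonspray_fraction_contact = 0,
                nonspray_fraction_oral = 0)
  for (j in seq_along(sids)) {
    rr <- residues[residues$site_id == sids[j] & residues$detected, ]
    sprayed <- bloom_sets$compound[bloom_sets$site_id == sids[j]]
    for (route in c("contact", "oral")) {
      ld <- toxdb[[paste0(route, "_ld50")]][match(rr$compound,
                                                  toxdb$compound)]
      q <- rr$concentration / ld
      q[is.na(q)] <- 0
      tot <- sum(q)
      frac <- if (tot == 0) 0 else
        sum(q[!rr$compound %in% sprayed]) / tot
      out[[paste0("nonspray_fraction_", route)]][j] <- frac
    }
  }
  out
}

synth_grid <- function(n, tile_cells, cell, tiles_per_row, tile_rows,
                       apple_frac, nat_frac, ag_frac, oth_frac) {
  class_map <- default_class_map()
  nat_codes <- class_map$code[class_map$group == "natural"][1:3]
  ag_codes <- class_map$code[class_map$group == "agricultural"][1:3]
  apple_code <- class_map$code[class_map$group == "apple"][1]
  oth_codes <- class_map$code[class_map$group == "other"][1:2]
  codes_all <- c(nat_codes, ag_codes, apple_code, oth_codes)
  big <- matrix(-9999L, nrow = tile_rows * tile_cells,
                ncol = tiles_per_row * tile_cells)
  for (i in seq_len(n)) {
    r0 <- ((i - 1) %/% tiles_per_row) * tile_cells
    c0 <- ((i - 1) %% tiles_per_row) * tile_cells
    probs <- c(rep(nat_frac[i] / 3, 3), rep(ag_frac[i] / 3, 3),
               apple_frac[i], rep(oth_frac[i] / 2, 2))
    tile <- sample(codes_all, tile_cells^2, replace = TRUE,
                   prob = probs)
    big[r0 + seq_len(tile_cells), c0 + seq_len(tile_cells)] <-
      matrix(tile, tile_cells, tile_cells)
  }
  land_cover_grid(big, cell_size = cell, xll = 0, yll = 0,
                  nodata = -9999L, class_map = class_map)
}

#' Default land-cover class grouping
#'
#' A Cropland-Data-Layer-style class map in which forest, shrubland,
#' grassland/pasture, open/low-intensity developed land, wetlands,
#' fallow land and clover/wildflowers are grouped as natural; row and
#' tree crops as agricultural; apples as the focal crop; and water,
#' dense development and barren land as other.
#'
#' @return A tibble `code`, `name`, `group`.
#' @export
default_class_map <- function() {
  readr::read_csv(
    system.file("extdata", "class_map.csv", package = "pollenrisk"),
    col_types = readr::cols(code = readr::col_integer(),
                            name = readr::col_character(),
                            group = readr::col_character()))
}

#' Ground truth of a synthetic study
#'
#' The latent parameters behind a generated study: true coupling
#' coefficients and noise scales, latent and measured apple pollen
#' fractions, realized richness, pre-split residue totals, the number of
#' never-sprayed compounds per site, and the generator's own
#' sprayed/non-sprayed hazard attribution.
#'
#' @param study A `synth_study` object.
#' @return The ground-truth list.
#' @export
ground_truth <- function(study) {
  stopifnot(inherits(study, "synth_study"))
  study$truth
}

#' @export
print.synth_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic orchard study: %d sites (seed %d)\n",
    nrow(x$sites), x$truth$seed))
  cat(sprintf("  %d residue records (%d detections), %d spray events\n",
              nrow(x$residues), sum(x$residues$detected),
              nrow(x$sprays)))
  cat(sprintf("  pollen: %d count rows, grid: %s\n", nrow(x$pollen),
              if (is.null(x$grid)) "not built" else "built"))
  invisible(x)
}

#' Write a synthetic study to a directory in the canonical schemas
#'
#' Emits `toxdb.csv`, `residues.csv`, `sprays.csv`, `pollen_counts.csv`,
#' `sites.csv`, and (when the grid was built) `grid.asc` +
#' `class_map.csv`, plus a `truth.json` with the generator seed and
#' ground-truth record. Every file round-trips through the package
#' readers.
#'
#' @param study A `synth_study` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_toxdb(study$toxdb, file.path(dir, "toxdb.csv"))
  write_residues(study$residues, file.path(dir, "residues.csv"))
  write_sprays(study$sprays, file.path(dir, "sprays.csv"))
  write_pollen(study$pollen, file.path(dir, "pollen_counts.csv"))
  write_sites(study$sites, file.path(dir, "sites.csv"))
  if (!is.null(study$grid)) {
    write_grid(study$grid, file.path(dir, "grid.asc"),
               file.path(dir, "class_map.csv"))
  }
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
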