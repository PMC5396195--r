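# Independent brute-force oracles (plain loops, no dplyr) and small
# fixture builders used across the suite.

tiny_toxdb <- function(compound, pclass = "insecticide",
                       contact_ld50 = 1, oral_ld50 = 1) {
  tibble::tibble(compound = compound,
                 pclass = rep_len(pclass, length(compound)),
                 contact_ld50 = rep_len(contact_ld50, length(compound)),
                 oral_ld50 = rep_len(oral_ld50, length(compound)))
}

tiny_residues <- function(site_id, compound, concentration, lod = 1) {
  tibble::tibble(site_id = site_id, compound = compound,
                 concentration = concentration,
                 lod = rep_len(lod, length(compound)),
                 detected = concentration >= rep_len(lod, length(compound)))
}

tiny_sprays <- function(site_id, compound, during_bloom = TRUE,
                        pct_ai = 50, app_rate = 1) {
  tibble::tibble(site_id = site_id, compound = compound,
                 date = as.Date("2015-05-10"),
                 pct_ai = rep_len(pct_ai, length(compound)),
                 app_rate = rep_len(app_rate, length(compound)),
                 during_bloom = rep_len(during_bloom, length(compound)))
}

# Sequential double-loop recomputation of site_risk
brute_site_risk <- function(residues, toxdb, sprays = NULL,
                            exposure = exposure_params(),
                            thresholds = loc_thresholds()) {
  sites <- sort(unique(residues$site_id))
  out <- list()
  for (s in sites) {
    rr <- residues[residues$site_id == s, ]
    tc <- to <- 0
    uc <- uo <- 0
    sprayed <- character()
    if (!is.null(sprays)) {
      sprayed <- unique(sprays$compound[sprays$site_id == s &
                                          sprays$during_bloom])
    }
    for (j in seq_len(nrow(rr))) {
      if (!rr$detected[j]) next
      i <- match(rr$compound[j], toxdb$compound)
      is_sprayed <- rr$compound[j] %in% sprayed
      if (!is.na(toxdb$contact_ld50[i])) {
        q <- rr$concentration[j] / toxdb$contact_ld50[i]
        tc <- tc + q
        if (!is_sprayed) uc <- uc + q
      }
      if (!is.na(toxdb$oral_ld50[i])) {
        q <- rr$concentration[j] / toxdb$oral_ld50[i]
        to <- to + q
        if (!is_sprayed) uo <- uo + q
      }
    }
    pc <- tc * exposure$contact_mass_mg / 1e4
    po <- to * exposure$oral_rate_mg_per_day * exposure$duration_days /
      1e4
    out[[s]] <- tibble::tibble(
      site_id = s,
      total_contact_phq = tc, total_oral_phq = to,
      pct_ld50_contact = pc, pct_ld50_oral = po,
      epa_acute_contact = pc / 100 > thresholds$epa_acute_contact,
      efsa_acute_contact = pc / 100 > thresholds$efsa_acute_contact,
      efsa_chronic_oral = po / 100 > thresholds$efsa_chronic_oral,
      nonspray_fraction_contact = if (tc == 0) 0 else uc / tc,
      nonspray_fraction_oral = if (to == 0) 0 else uo / to)
  }
  do.call(rbind, out)
}

brute_compound_summary <- function(residues, toxdb) {
  out <- list()
  for (i in seq_len(nrow(toxdb))) {
    cp <- toxdb$compound[i]
    rr <- residues[residues$compound == cp & residues$detected, ]
    n <- nrow(rr)
    mr <- if (n == 0) 0 else sum(rr$concentration) / n
    out[[cp]] <- tibble::tibble(
      compound = cp, pclass = toxdb$pclass[i],
      mean_residue = mr, n_detections = n,
      mean_contact_phq = mr / toxdb$contact_ld50[i],
      mean_oral_phq = mr / toxdb$oral_ld50[i])
  }
  res <- do.call(rbind, out)
  res[order(-res$mean_contact_phq, na.last = TRUE), ]
}

brute_pui <- function(sprays, toxdb, panel = NULL) {
  sites <- sort(unique(sprays$site_id))
  out <- list()
  for (s in sites) {
    ev <- sprays[sprays$site_id == s & sprays$during_bloom, ]
    pa <- pp <- 0
    used <- 0
    for (j in seq_len(nrow(ev))) {
      ld <- toxdb$contact_ld50[match(ev$compound[j], toxdb$compound)]
      if (is.na(ld)) next
      used <- used + 1
      term <- (1 / ld) * (ev$pct_ai[j] / 100) * ev$app_rate[j]
      pa <- pa + term
      if (is.null(panel) || ev$compound[j] %in% panel) pp <- pp + term
    }
    out[[s]] <- tibble::tibble(site_id = s, n_events = used,
                               pui_all = pa, pui_panel = pp)
  }
  do.call(rbind, out)
}

brute_buffer <- function(grid, cx, cy, radius) {
  nr <- nrow(grid$codes)
  nc <- ncol(grid$codes)
  counts <- c(natural = 0, agricultural = 0, apple = 0, other = 0)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      x <- grid$xll + (c - 0.5) * grid$cell_size
      y <- grid$yll + (nr - r + 0.5) * grid$cell_size
      if ((x - cx)^2 + (y - cy)^2 > radius^2) next
      code <- grid$codes[r, c]
      if (code == grid$nodata) next
      g <- grid$class_map$group[match(code, grid$class_map$code)]
      counts[g] <- counts[g] + 1
    }
  }
  counts
}

# Random tiny hazard study: <= 5 sites x <= 5 compounds, missing LD50s,
# non-detects, and partial spray coverage.
random_small_study <- function(seed) {
  set.seed(seed)
  n_sites <- sample(1:5, 1)
  n_comp <- sample(2:5, 1)
  comps <- paste0("C", seq_len(n_comp))
  sids <- paste0("S", seq_len(n_sites))
  toxdb <- tibble::tibble(
    compound = comps,
    pclass = sample(c("insecticide", "fungicide", "herbicide"),
                    n_comp, replace = TRUE),
    contact_ld50 = ifelse(runif(n_comp) < 0.15, NA,
                          round(10^runif(n_comp, -2, 2), 4)),
    oral_ld50 = ifelse(runif(n_comp) < 0.3, NA,
                       round(10^runif(n_comp, -2, 2), 4)))
  grid <- expand.grid(site_id = sids, compound = comps,
                      stringsAsFactors = FALSE)
  lod <- 1
  conc <- ifelse(runif(nrow(grid)) < 0.7,
                 round(10^runif(nrow(grid), -1, 3), 2), 0)
  conc[conc < lod] <- 0
  residues <- tibble::tibble(site_id = grid$site_id,
                             compound = grid$compound,
                             concentration = conc, lod = lod,
                             detected = conc >= lod)
  spray_mask <- runif(nrow(grid)) < 0.3
  sprays <- tibble::tibble(
    site_id = grid$site_id[spray_mask],
    compound = grid$compound[spray_mask],
    date = as.Date("2015-05-10"),
    pct_ai = round(runif(sum(spray_mask), 1, 100), 1),
    app_rate = round(runif(sum(spray_mask), 0.1, 5), 3),
    during_bloom = runif(sum(spray_mask)) < 0.7)
  list(toxdb = toxdb, residues = residues, sprays = sprays)
}
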