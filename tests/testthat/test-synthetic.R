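test_that("generation is deterministic given the seed", {
  a <- generate_study(synth_config(seed = 5), include_grid = FALSE)
  b <- generate_study(synth_config(seed = 5), include_grid = FALSE)
  expect_identical(a$residues, b$residues)
  expect_identical(a$pollen, b$pollen)
  expect_identical(a$sprays, b$sprays)
  expect_identical(a$sites, b$sites)
  expect_identical(a$truth, b$truth)
  c <- generate_study(synth_config(seed = 6), include_grid = FALSE)
  expect_false(identical(a$residues, c$residues))

  # component streams are split: the grid does not perturb the tables
  g <- generate_study(synth_config(n_sites = 4, seed = 5))
  g2 <- generate_study(synth_config(n_sites = 4, seed = 5),
                       include_grid = FALSE)
  expect_identical(g$residues, g2$residues)
  expect_identical(g$pollen, g2$pollen)
})

test_that("generated tables validate against the io schemas", {
  st <- generate_study(synth_config(seed = 2), include_grid = FALSE)
  # residues arrive already censored: revalidation is silent
  expect_no_warning(pollenrisk:::validate_residues(st$residues))
  expect_no_warning(pollenrisk:::validate_sprays(st$sprays))
  expect_no_warning(pollenrisk:::validate_pollen(st$pollen))
  expect_equal(pollen_totals(st$pollen)$total_counted, rep(300L, 30))
  expect_true(all(st$residues$concentration >= 0))
  expect_true(all(st$residues$detected ==
                    (st$residues$concentration >= st$residues$lod)))
})

test_that("a written study round-trips through the readers", {
  st <- generate_study(synth_config(n_sites = 6, seed = 8))
  d <- withr::local_tempdir()
  write_study(st, d)
  expect_equal(read_residues(file.path(d, "residues.csv")),
               st$residues)
  expect_equal(read_sprays(file.path(d, "sprays.csv")), st$sprays)
  expect_equal(read_pollen(file.path(d, "pollen_counts.csv")),
               st$pollen)
  expect_equal(read_toxdb(file.path(d, "toxdb.csv")), st$toxdb)
  g <- read_grid(file.path(d, "grid.asc"),
                 file.path(d, "class_map.csv"))
  expect_equal(g$codes, st$grid$codes)
})

test_that("ground truth records the generating parameters coherently", {
  st <- generate_study(synth_config(seed = 4), include_grid = FALSE)
  tr <- ground_truth(st)
  # measured apple pollen fraction is literally counts over grains
  p_hat <- st$pollen |>
    dplyr::group_by(site_id) |>
    dplyr::summarise(p = sum(count[morphotype == "Malus"]) /
                       sum(count)) |>
    dplyr::pull(p)
  expect_equal(tr$p_apple_measured, p_hat)
  expect_equal(tr$richness, pollen_composition(st$pollen)$richness)
  expect_equal(tr$coefficients$apple_pollen[["slope"]], 0.55)
  expect_true(all(tr$n_novel >= 0))
})

test_that("noiseless latent coupling gives a perfect fit", {
  st <- generate_study(synth_config(seed = 10, r2_apple_pollen = 1),
                       include_grid = FALSE)
  tr <- ground_truth(st)
  expect_equal(tr$coefficients$apple_pollen[["noise_sd"]], 0)
  d <- tibble::tibble(x = tr$apple_area, y = tr$p_apple_latent)
  expect_equal(ols_fit(d, "y", "x")$r_squared, 1, tolerance = 1e-12)
})

test_that("switching off the richness coupling kills the fitted R2", {
  r2s <- vapply(1:25, function(s) {
    st <- generate_study(
      synth_config(seed = s, r2_insecticide_richness = 0),
      include_grid = FALSE)
    per <- compound_phq(st$residues, st$toxdb) |>
      dplyr::filter(detected)
    tot <- per |>
      dplyr::group_by(site_id) |>
      dplyr::summarise(ins = sum(concentration[pclass == "insecticide"]))
    d <- dplyr::left_join(pollen_composition(st$pollen), tot,
                          by = "site_id")
    ols_fit(d, "ins", "richness")$r_squared
  }, numeric(1))
  expect_lt(mean(r2s), 0.1)
})

test_that("the generator's spray attribution matches the pipeline's", {
  for (s in c(3, 12)) {
    st <- generate_study(synth_config(seed = s), include_grid = FALSE)
    tr <- ground_truth(st)
    att <- attribute_spray_status(compound_phq(st$residues, st$toxdb),
                                  st$sprays)
    merged <- dplyr::left_join(tr$nonspray, att, by = "site_id")
    expect_equal(merged$nonspray_fraction_contact.x,
                 merged$nonspray_fraction_contact.y)
    expect_equal(merged$nonspray_fraction_oral.x,
                 merged$nonspray_fraction_oral.y)
  }
})

test_that("never-sprayed contamination appears at the configured rate", {
  novel <- unlist(lapply(1:20, function(s) {
    ground_truth(generate_study(synth_config(seed = 100 + s),
                                include_grid = FALSE))$n_novel
  }))
  # Poisson(2.8) plus the occasional forced insecticide
  expect_gt(mean(novel), 2.4)
  expect_lt(mean(novel), 3.4)
  expect_gt(mean(novel >= 1), 0.85)
})

test_that("recovered slopes fall within three standard errors of truth", {
  hits <- vapply(1:60, function(s) {
    st <- generate_study(synth_config(seed = 300 + s),
                         include_grid = FALSE)
    d <- dplyr::left_join(st$sites, pollen_composition(st$pollen),
                          by = "site_id") |>
      dplyr::mutate(pct_focal = 100 * focal_fraction)
    f <- ols_fit(d, "pct_focal", "pct_apple_area")
    est <- f$coefficients[["slope"]]
    se <- f$std_errors[["slope"]]
    abs(est - 0.55) <= 3 * se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
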