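test_that("raw hazard quotient is residue over LD50, with route skips", {
  expect_equal(round_half_up(phq_raw(557.1, 0.118), 1), 4721.2)
  expect_equal(round_half_up(phq_raw(69.9, 0.15), 1), 466.0)
  expect_equal(phq_raw(0, 0.118), 0)
  expect_true(is.na(phq_raw(100, NA)))
  expect_error(phq_raw(-1, 1), "non-negative")
  expect_error(phq_raw(1, 0), "positive")
})

test_that("site risk aggregates additively and flags levels of concern", {
  tox <- tiny_toxdb(c("Indoxacarb", "B"), contact_ld50 = c(0.118, 1),
                    oral_ld50 = c(0.26, 1))

  # single detected compound reproduces its own quotient
  r1 <- tiny_residues("S1", "Indoxacarb", 557.1, lod = 35.5)
  sr <- site_risk(r1, tox)
  expect_equal(round_half_up(sr$total_contact_phq, 1), 4721.2)
  expect_equal(round_half_up(sr$total_oral_phq, 1), 2142.7)
  expect_true(sr$epa_acute_contact)   # 47.2% > 40%
  expect_true(sr$efsa_acute_contact)

  # no detected residues -> zero everywhere, all flags false
  r0 <- tiny_residues("S1", c("Indoxacarb", "B"), c(0, 0), lod = 1)
  sr0 <- site_risk(r0, tox)
  expect_equal(sr0$total_contact_phq, 0)
  expect_false(any(sr0$epa_acute_contact, sr0$efsa_acute_contact,
                   sr0$efsa_chronic_oral))
  expect_equal(sr0$nonspray_fraction_contact, 0)

  # additivity: 100 + 200 = 300
  tox2 <- tiny_toxdb(c("A", "B"), contact_ld50 = 1, oral_ld50 = 1)
  r2 <- tiny_residues("S1", c("A", "B"), c(100, 200))
  expect_equal(site_risk(r2, tox2)$total_contact_phq, 300)

  # unknown compound is a hard error
  expect_error(site_risk(tiny_residues("S1", "Zeta", 1), tox),
               "Zeta")
})

test_that("percent-of-LD50 conversion matches the closed-form constants", {
  expect_equal(pct_of_ld50(0, "contact"), 0)
  expect_equal(pct_of_ld50(4000, "contact"), 40)
  expect_equal(pct_of_ld50(1000, "oral"), 9.4)
  expect_equal(pct_of_ld50(0.03 / 9.4e-5, "oral"), 3)
  expect_error(pct_of_ld50(100, "dermal"))
  # linear in the exposure masses
  ex2 <- exposure_params(contact_mass_mg = 200)
  expect_equal(pct_of_ld50(4000, "contact", ex2), 80)
})

test_that("level-of-concern flags use strict exceedance per agency", {
  f <- classify_loc(47.2, 0)
  expect_true(f$epa_acute_contact)
  expect_true(f$efsa_acute_contact)
  expect_false(classify_loc(0, 2.9)$efsa_chronic_oral)
  expect_false(any(unlist(classify_loc(0, 0))))
  # boundary equality does not flag
  expect_false(classify_loc(40, 0)$epa_acute_contact)
  expect_false(classify_loc(20, 0)$efsa_acute_contact)
  expect_false(classify_loc(0, 3)$efsa_chronic_oral)
})

test_that("spray attribution partitions hazard by during-bloom status", {
  tox <- tiny_toxdb(c("A", "B"), contact_ld50 = 1, oral_ld50 = 1)
  res <- tiny_residues("S1", c("A", "B"), c(30, 70))
  phq <- compound_phq(res, tox)

  spr <- tiny_sprays("S1", "A")
  att <- attribute_spray_status(phq, spr)
  expect_equal(att$nonspray_fraction_contact, 0.7)

  # residues but zero spray events -> everything non-spray
  expect_equal(attribute_spray_status(phq, NULL)$nonspray_fraction_oral,
               1)
  # all compounds sprayed -> zero
  spr2 <- tiny_sprays(c("S1", "S1"), c("A", "B"))
  expect_equal(
    attribute_spray_status(phq, spr2)$nonspray_fraction_contact, 0)
  # a non-bloom application does not count as sprayed
  spr3 <- tiny_sprays(c("S1", "S1"), c("A", "B"),
                      during_bloom = c(TRUE, FALSE))
  expect_equal(
    attribute_spray_status(phq, spr3)$nonspray_fraction_contact, 0.7)
})

test_that("use index follows the spray-record formula and accumulates", {
  tox <- tiny_toxdb("Spinosad", contact_ld50 = 0.003, oral_ld50 = 0.057)
  one <- tiny_sprays("S1", "Spinosad", pct_ai = 100, app_rate = 1)
  expect_equal(pui(one, tox)$pui_all, 1 / 0.003)

  # no during-bloom events -> 0 for the site
  pre <- tiny_sprays("S1", "Spinosad", during_bloom = FALSE)
  expect_equal(pui(pre, tox)$pui_all, 0)
  expect_equal(pui(pre, tox, sites = "S2")$pui_all, c(0, 0))

  # two identical events double the index
  two <- dplyr::bind_rows(one, one)
  expect_equal(pui(two, tox)$pui_all, 2 / 0.003)

  # events without a contact LD50 are skipped with a warning
  tox2 <- tiny_toxdb(c("Spinosad", "NoTox"),
                     contact_ld50 = c(0.003, NA))
  both <- tiny_sprays("S1", c("Spinosad", "NoTox"), pct_ai = 100,
                      app_rate = 1)
  expect_warning(p <- pui(both, tox2), "NoTox")
  expect_equal(p$pui_all, 1 / 0.003)

  # panel restriction never exceeds the full index
  p2 <- pui(two, tox, panel = character())
  expect_equal(p2$pui_panel, 0)
  expect_lte(p2$pui_panel, p2$pui_all)
})

test_that("compound summary means use positive detections only", {
  tox <- tiny_toxdb(c("Indoxacarb", "Boscalid", "Abamectin"),
                    c("insecticide", "fungicide", "insecticide"),
                    contact_ld50 = c(0.118, 200, 0.03),
                    oral_ld50 = c(0.26, 166, NA))
  res <- tiny_residues(
    c("S1", "S2", "S1", "S2", "S1"),
    c("Indoxacarb", "Indoxacarb", "Boscalid", "Boscalid", "Abamectin"),
    c(500.0, 614.2, 0, 0, 21.9), lod = c(35.5, 35.5, 35.5, 35.5, 3.6))
  cs <- compound_summary(res, tox)

  ind <- cs[cs$compound == "Indoxacarb", ]
  expect_equal(ind$mean_residue, 557.1)
  expect_equal(ind$n_detections, 2L)
  expect_equal(round_half_up(ind$mean_contact_phq, 1), 4721.2)

  bos <- cs[cs$compound == "Boscalid", ]
  expect_equal(bos$n_detections, 0L)
  expect_equal(bos$mean_residue, 0)
  expect_equal(bos$mean_contact_phq, 0)

  # missing oral LD50 propagates as NA, not zero
  expect_true(is.na(cs$mean_oral_phq[cs$compound == "Abamectin"]))
  # descending by contact PHQ
  expect_equal(cs$compound[1], "Indoxacarb")
})

test_that("hazard metrics scale linearly with concentrations", {
  st <- random_small_study(404)
  scaled <- st$residues
  scaled$concentration <- scaled$concentration * 3
  a <- site_risk(st$residues, st$toxdb, st$sprays)
  b <- site_risk(scaled, st$toxdb, st$sprays)
  expect_equal(b$total_contact_phq, 3 * a$total_contact_phq)
  expect_equal(b$pct_ld50_oral, 3 * a$pct_ld50_oral)
  # attribution fractions are scale-free
  expect_equal(b$nonspray_fraction_contact, a$nonspray_fraction_contact)

  # adding a detected residue never decreases totals or flags
  extra <- dplyr::bind_rows(
    st$residues,
    tiny_residues("S1", "Cnew", 50, lod = 1))
  tox2 <- dplyr::bind_rows(st$toxdb,
                           tiny_toxdb("Cnew", contact_ld50 = 0.01,
                                      oral_ld50 = 0.01))
  c_ <- site_risk(extra, tox2, st$sprays)
  s1a <- a[a$site_id == "S1", ]
  s1c <- c_[c_$site_id == "S1", ]
  expect_gte(s1c$total_contact_phq, s1a$total_contact_phq)
  expect_gte(s1c$total_oral_phq, s1a$total_oral_phq)
  expect_true(s1c$epa_acute_contact >= s1a$epa_acute_contact)
})

test_that("compounds missing a route LD50 are skipped and recorded", {
  tox <- tiny_toxdb(c("Abamectin", "Carbaryl"),
                    contact_ld50 = c(0.03, 0.84),
                    oral_ld50 = c(NA, 0.15))
  res <- tiny_residues("S1", c("Abamectin", "Carbaryl"), c(21.9, 69.9))
  sr <- site_risk(res, tox)
  expect_equal(sr$skipped_oral, "Abamectin")
  expect_equal(sr$skipped_contact, "")
  expect_equal(sr$total_oral_phq, 69.9 / 0.15)
  expect_equal(sr$total_contact_phq, 21.9 / 0.03 + 69.9 / 0.84)
})
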