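cm4 <- tibble::tibble(code = 1:4,
                      name = c("forest", "corn", "apples", "water"),
                      group = c("natural", "agricultural", "apple",
                                "other"))

test_that("buffer composition matches brute-force cell enumeration", {
  set.seed(99)
  codes <- matrix(sample(c(1:4, -9999L), 40 * 50, replace = TRUE,
                         prob = c(0.3, 0.3, 0.2, 0.15, 0.05)),
                  40, 50)
  g <- land_cover_grid(codes, cell_size = 30, xll = 120, yll = -60,
                       class_map = cm4)
  for (k in 1:5) {
    cx <- runif(1, 300, 1200)
    cy <- runif(1, 100, 900)
    r <- runif(1, 100, 500)
    b <- buffer_composition(
      g, tibble::tibble(site_id = "S", x_m = cx, y_m = cy),
      radii = r, apple_in_agricultural = FALSE)
    counts <- brute_buffer(g, cx, cy, r)
    n <- sum(counts)
    expect_equal(b$n_cells, n)
    expect_equal(b$pct_natural, 100 * counts[["natural"]] / n)
    expect_equal(b$pct_agricultural,
                 100 * counts[["agricultural"]] / n)
    expect_equal(b$pct_apple, 100 * counts[["apple"]] / n)
    expect_equal(b$pct_other, 100 * counts[["other"]] / n)
    # exclusive grouping partitions the buffer
    expect_equal(b$pct_natural + b$pct_agricultural + b$pct_apple +
                   b$pct_other, 100, tolerance = 1e-9)
  }
})

test_that("uniform and half-plane grids give the expected percents", {
  uni <- land_cover_grid(matrix(3L, 100, 100), 30, class_map = cm4)
  s <- tibble::tibble(site_id = "S", x_m = 1500, y_m = 1500)
  b <- buffer_composition(uni, s, radii = c(400, 1000))
  expect_equal(b$pct_apple, c(100, 100))

  # in-buffer cell count close to pi r^2 / cell area
  expect_equal(b$n_cells[2], pi * (1000 / 30)^2, tolerance = 0.02)

  half <- land_cover_grid(
    cbind(matrix(3L, 200, 100), matrix(1L, 200, 100)), 30,
    class_map = cm4)
  bh <- buffer_composition(
    half, tibble::tibble(site_id = "S", x_m = 3000, y_m = 3000),
    radii = 1500)
  expect_equal(bh$pct_apple, 50, tolerance = 0.05)
  expect_equal(bh$pct_natural, 50, tolerance = 0.05)

  # focal crop counts inside agriculture under the default grouping
  expect_equal(bh$pct_agricultural, bh$pct_apple)
})

test_that("buffer membership is invariant to grid translation", {
  set.seed(7)
  codes <- matrix(sample(1:4, 900, replace = TRUE), 30, 30)
  g1 <- land_cover_grid(codes, 30, xll = 0, yll = 0, class_map = cm4)
  g2 <- land_cover_grid(codes, 30, xll = 5000, yll = -2000,
                        class_map = cm4)
  b1 <- buffer_composition(g1, tibble::tibble(site_id = "S",
                                              x_m = 450, y_m = 450),
                           radii = 300)
  b2 <- buffer_composition(g2, tibble::tibble(site_id = "S",
                                              x_m = 5450, y_m = -1550),
                           radii = 300)
  expect_equal(b1[-1], b2[-1])
})

test_that("off-grid or empty buffers are errors", {
  g <- land_cover_grid(matrix(1L, 5, 5), 30, class_map = cm4)
  s <- tibble::tibble(site_id = "S", x_m = 1e6, y_m = 1e6)
  expect_error(buffer_composition(g, s, radii = 100), "misses")
  gn <- land_cover_grid(matrix(-9999L, 5, 5), 30, class_map = cm4)
  expect_error(
    buffer_composition(gn, tibble::tibble(site_id = "S", x_m = 75,
                                          y_m = 75), radii = 100),
    "no valid cells")
})

scale_fixture <- function(truth_radius, noise_sd = 0, n = 12,
                          identical_predictors = FALSE) {
  set.seed(5)
  sids <- sprintf("S%02d", 1:n)
  mk <- function(r) {
    if (identical_predictors) set.seed(77)
    tibble::tibble(site_id = sids, radius = r,
                   pct_natural = runif(n, 0, 60),
                   pct_agricultural = runif(n, 0, 60),
                   pct_apple = runif(n, 0, 35))
  }
  buffers <- dplyr::bind_rows(lapply(c(1000, 2000, 3000), mk))
  truth <- buffers[buffers$radius == truth_radius, ]
  response <- tibble::tibble(
    site_id = sids,
    value = 2 + 0.5 * truth$pct_apple + rnorm(n, 0, noise_sd))
  list(buffers = buffers, response = response)
}

test_that("scale selection picks the radius that generated the response", {
  fx <- scale_fixture(3000)
  sel <- select_buffer_scale(fx$buffers, fx$response)
  expect_equal(sel$radius, 3000)

  fx1 <- scale_fixture(1000)
  expect_equal(select_buffer_scale(fx1$buffers, fx1$response)$radius,
               1000)

  # identical predictors at all radii tie; the largest radius wins
  fxt <- scale_fixture(2000, noise_sd = 1, identical_predictors = TRUE)
  expect_equal(select_buffer_scale(fxt$buffers, fxt$response)$radius,
               3000)
})
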