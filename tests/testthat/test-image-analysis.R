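noise_free_config <- function(conc = c(G12D = 300, WT = 1200), seed = 5,
                              lay = small_layout()) {
  simulation_config(layout = lay, panel = g12d_panel(),
                    species_concentrations = conc,
                    intensities = intensity_model(sigma_neg = 0,
                                                  sigma_pos = 0),
                    background_noise_sd = 0, seed = seed)
}

test_that("noise-free images round-trip to the exact truth table", {
  cfg <- noise_free_config()
  tr <- simulate_partition(cfg)
  rend <- render_images(tr)
  grid <- detect_grid(rend$images$Cy5, cfg$layout, cfg$pixel_scale)
  expect_equal(unname(grid$shift), c(0, 0))
  expect_true(all(abs(grid$centres$x_px - rend$centres$x_px) <= 0.5))
  expect_true(all(abs(grid$centres$y_px - rend$centres$y_px) <= 0.5))
  # extraction recovers the configured modes exactly
  x <- extract_intensities(rend$images$Cy5, grid, cfg$layout,
                           cfg$pixel_scale)
  expect_setequal(unique(x), c(5000, 30000))
  # full pipeline reproduces the truth bit-exactly on every channel
  calls <- analyze_chip(rend$images, cfg$layout, cfg$pixel_scale)
  expect_identical(unname(call_matrix(calls)), unname(tr$positive))
  expect_equal(nrow(calls), total_chambers(cfg$layout))
})

test_that("grid registration recovers a global translation", {
  cfg <- noise_free_config(seed = 6)
  tr <- simulate_partition(cfg)
  rend <- render_images(tr)
  img <- rend$images$Cy5
  h <- nrow(img); w <- ncol(img)
  shifted <- matrix(cfg$background_level, h, w)
  shifted[8:h, 1:(w - 4)] <- img[1:(h - 7), 5:w]  # dy = +7, dx = -4
  grid <- detect_grid(shifted, cfg$layout, cfg$pixel_scale)
  expect_equal(unname(grid$shift), c(-4, 7))
  expect_true(all(abs(grid$centres$x_px - (rend$centres$x_px - 4)) <= 1))
  expect_true(all(abs(grid$centres$y_px - (rend$centres$y_px + 7)) <= 1))
})

test_that("registration rejects images of the wrong size", {
  cfg <- noise_free_config(seed = 7)
  rend <- render_images(simulate_partition(cfg))
  expect_error(detect_grid(rend$images$Cy5[1:50, 1:50], cfg$layout,
                           cfg$pixel_scale), "px")
})

test_that("extraction averages disks and guards image bounds", {
  lay <- small_layout()
  dims <- c(286, 462)
  uni <- matrix(777, dims[1], dims[2])
  cen <- chamber_centres(lay, 5)
  x <- extract_intensities(uni, cen, lay, 5)
  expect_true(all(x == 777))
  cen_bad <- cen
  cen_bad$x_px[1] <- 2  # disk would leave the image
  expect_error(extract_intensities(uni, cen_bad, lay, 5), "bounds")
  expect_error(extract_intensities(uni, cen, lay, 5, shrink = 0), "shrink")
})

test_that("two-point clusters threshold at the centroid midpoint", {
  cl <- classify_chambers(c(100, 100, 900, 900))
  expect_equal(cl$threshold, 500)
  expect_identical(cl$calls, c(FALSE, FALSE, TRUE, TRUE))
  expect_false(cl$no_positive)
})

test_that("degenerate and unimodal intensity sets yield no positives", {
  cl <- classify_chambers(rep(42, 10))
  expect_true(cl$no_positive)
  expect_false(any(cl$calls))
  # a single Gaussian population must not be split into pos/neg
  set.seed(31)
  cl2 <- classify_chambers(rnorm(5000, 5000, 1500))
  expect_true(cl2$no_positive)
  expect_error(classify_chambers(numeric(0)), "no intensities")
  expect_error(classify_chambers(5), "at least 2")
})

test_that("classification is invariant to affine intensity rescaling", {
  set.seed(17)
  x <- c(rnorm(400, 5000, 1500), rnorm(100, 30000, 1500))
  base <- classify_chambers(x)
  for (ab in list(c(2, 0), c(0.001, 3), c(7, -12345))) {
    tr <- classify_chambers(ab[1] * x + ab[2])
    expect_identical(tr$calls, base$calls)
    expect_identical(tr$no_positive, base$no_positive)
  }
})

test_that("positive counts are monotone non-increasing in the threshold", {
  set.seed(23)
  x <- c(rnorm(300, 5000, 1500), rnorm(80, 30000, 1500))
  counts <- vapply(seq(0, 40000, by = 500),
                   function(t) sum(x >= t), numeric(1))
  expect_true(all(diff(counts) <= 0))
  cl <- classify_chambers(x)
  expect_equal(sum(cl$calls), sum(x >= cl$threshold))
})

test_that("otsu thresholding agrees with clustering on separated modes", {
  set.seed(19)
  x <- c(rnorm(500, 5000, 1500), rnorm(150, 30000, 1500))
  expect_identical(classify_chambers(x, method = "otsu")$calls,
                   classify_chambers(x, method = "kmeans")$calls)
})

test_that("noisy rendered chips are analyzed accurately", {
  cfg <- simulation_config(layout = small_layout(), panel = g12d_panel(),
                           species_concentrations = c(G12D = 300, WT = 1200),
                           seed = 21)
  tr <- simulate_partition(cfg)
  rend <- render_images(tr)
  grid <- detect_grid(rend$images$Cy5, cfg$layout, cfg$pixel_scale)
  expect_true(all(abs(grid$centres$x_px - rend$centres$x_px) <= 2))
  expect_true(all(abs(grid$centres$y_px - rend$centres$y_px) <= 2))
  # per-class intensity means sit within 3 SE of the configured modes
  x <- extract_intensities(rend$images$Cy5, grid, cfg$layout,
                           cfg$pixel_scale)
  pos <- tr$positive[, "Cy5"]
  se_pos <- 1500 / sqrt(sum(pos)); se_neg <- 1500 / sqrt(sum(!pos))
  expect_lt(abs(mean(x[pos]) - 30000), 3 * se_pos + 50)
  expect_lt(abs(mean(x[!pos]) - 5000), 3 * se_neg + 50)
  calls <- analyze_chip(rend$images, cfg$layout, cfg$pixel_scale)
  expect_gte(mean(call_matrix(calls) == tr$positive), 0.999)
})

test_that("call tables round-trip through CSV with stable columns", {
  cfg <- noise_free_config(seed = 25)
  tr <- simulate_partition(cfg)
  calls <- calls_from_truth(tr, use_intensities = TRUE)
  td <- withr::local_tempdir()
  p <- file.path(td, "calls.csv")
  write_calls_csv(calls, p)
  header <- names(utils::read.csv(p, nrows = 1))
  expect_identical(header[1:6],
                   c("chamber_id", "row", "col", "x_px", "y_px", "filled"))
  back <- read_calls_csv(p)
  expect_identical(call_channels(back), call_channels(calls))
  expect_identical(call_matrix(back), call_matrix(calls))
  expect_equal(attr(back, "thresholds"), attr(calls, "thresholds"))
})

test_that("truth-derived call tables respect filling and intensities", {
  cfg <- simulation_config(layout = small_layout(), panel = g12d_panel(),
                           species_concentrations = c(WT = 1500),
                           unfilled_fraction = 0.2, seed = 33)
  tr <- simulate_partition(cfg)
  calls <- calls_from_truth(tr)
  expect_identical(calls$filled, tr$filled)
  expect_true(all(is.na(calls$Cy5_call[!calls$filled])))
  expect_equal(chambers_counted(calls), sum(tr$filled))
  expect_equal(chambers_counted(calls, count_unfilled = TRUE), nrow(calls))
  expect_equal(positive_count(calls, "Cy5"), sum(tr$positive[, "Cy5"]))
  expect_error(positive_count(calls, "FAM"), "no such channel")
})
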