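test_that("zero concentration yields an all-negative chip", {
  cfg <- simulation_config(layout = small_layout(), panel = g12d_panel(),
                           species_concentrations = c(WT = 0), seed = 1)
  tr <- simulate_partition(cfg)
  expect_true(all(tr$counts == 0))
  expect_false(any(tr$positive))
})

test_that("positive fraction follows 1 - exp(-lambda) across seeds", {
  # lambda = ln 2 via C = 976.2 copies/uL in 7.1e-4 uL chambers
  lay <- small_layout()
  n <- total_chambers(lay)
  p_expected <- 1 - exp(-976.2636 * 7.1e-4)
  expect_equal(p_expected, 0.5, tolerance = 1e-5)
  pos <- vapply(1:100, function(s) {
    cfg <- simulation_config(layout = lay, panel = g12d_panel(),
                             species_concentrations = c(WT = 976.2636),
                             seed = s)
    sum(simulate_partition(cfg)$positive[, "Cy5"])
  }, numeric(1))
  n_tot <- 100 * n
  se <- sqrt(p_expected * (1 - p_expected) / n_tot)
  expect_lt(abs(sum(pos) / n_tot - p_expected), 3 * se)
})

test_that("the stock dilution gives the expected in-chamber loading", {
  # stock 2e4 copies/uL diluted 3.5/31.7 -> lambda = 1.5677, 79.15% positive
  conc <- in_chamber_concentration(2e4)
  expect_equal(conc, 2e4 * 3.5 / 31.7, tolerance = 1e-12)
  lam <- conc * 7.1e-4
  expect_equal(1 - exp(-lam), 0.7915, tolerance = 1e-3)
  cfg <- simulation_config(layout = chip_layout(2, 54, 198, 87, 120, 60, 55),
                           panel = g12d_panel(),
                           species_concentrations = c(WT = conc), seed = 3)
  tr <- simulate_partition(cfg)
  frac <- mean(tr$positive[, "Cy5"])
  se <- sqrt(0.7915 * (1 - 0.7915) / nrow(tr$counts))
  expect_lt(abs(frac - (1 - exp(-lam))), 4 * se)
})

test_that("mutation-channel positives are a subset of reference positives", {
  cfg <- simulation_config(layout = small_layout(), panel = g12d_panel(),
                           species_concentrations = c(G12D = 300, WT = 1200),
                           seed = 8)
  tr <- simulate_partition(cfg)
  expect_true(all(tr$positive[tr$positive[, "HEX"], "Cy5"]))
})

test_that("unfilled chambers carry no template and no positivity", {
  cfg <- simulation_config(layout = small_layout(), panel = g12d_panel(),
                           species_concentrations = c(WT = 2000),
                           unfilled_fraction = 0.3, seed = 4)
  tr <- simulate_partition(cfg)
  expect_gt(sum(!tr$filled), 0)
  expect_true(all(tr$counts[!tr$filled, ] == 0))
  expect_false(any(tr$positive[!tr$filled, ]))
})

test_that("detection efficiency below 1 reduces positives", {
  mk <- function(eff, seed) {
    cfg <- simulation_config(layout = small_layout(), panel = g12d_panel(),
                             species_concentrations = c(WT = 1000),
                             detection_efficiency = eff, seed = seed)
    sum(simulate_partition(cfg)$positive[, "Cy5"])
  }
  full <- mean(vapply(1:20, function(s) mk(1, s), numeric(1)))
  half <- mean(vapply(1:20, function(s) mk(0.5, s + 100), numeric(1)))
  expect_lt(half, full)
})

test_that("simulation is reproducible under a fixed seed and validated", {
  cfg <- simulation_config(layout = small_layout(), panel = g12d_panel(),
                           species_concentrations = c(WT = 500), seed = 9)
  expect_identical(simulate_partition(cfg)$counts,
                   simulate_partition(cfg)$counts)
  expect_error(simulation_config(species_concentrations = c(WT = -5)),
               ">= 0")
  expect_error(simulation_config(unfilled_fraction = 1.5), "probabilities")
  expect_error(intensity_model(mu_neg = 10, mu_pos = 5), "exceed")
})

test_that("mixture series respects the fraction contract", {
  pan <- g12d_panel()
  # f = 1: every template is mutant, so mutant positives = ref positives
  s1 <- simulate_mixture_series(1, 2e4, reps = 1, seed = 2, panel = pan,
                                layout = small_layout())
  tr <- s1[[1]]$chips[[1]]$truth
  expect_identical(tr$positive[, "HEX"], tr$positive[, "Cy5"])
  # f = 0: no mutant positives on any seed
  s0 <- simulate_mixture_series(0, 2e4, reps = 5, seed = 3, panel = pan,
                                layout = small_layout())
  for (chip in s0[[1]]$chips)
    expect_equal(sum(chip$truth$positive[, "HEX"]), 0)
  expect_error(simulate_mixture_series(1.5, 2e4), "fractions")
  expect_error(simulate_mixture_series(0.5, -1), "total concentration")
})

test_that("truth CSV and TIFF outputs round-trip", {
  cfg <- simulation_config(layout = small_layout(), panel = g12d_panel(),
                           species_concentrations = c(G12D = 300, WT = 900),
                           seed = 12)
  tr <- simulate_partition(cfg)
  td <- withr::local_tempdir()
  df <- write_truth_csv(tr, file.path(td, "truth.csv"))
  expect_equal(nrow(df), total_chambers(cfg$layout))
  back <- utils::read.csv(file.path(td, "truth.csv"))
  expect_equal(back$G12D, unname(tr$counts[, "G12D"]))
  expect_equal(back$true_Cy5, unname(tr$positive[, "Cy5"]))

  rend <- render_images(tr)
  paths <- write_channel_tiffs(rend$images, td, "t")
  expect_true(all(file.exists(paths)))
  img <- read_channel_image(paths[["Cy5"]])
  expect_equal(dim(img), dim(rend$images$Cy5))
  expect_equal(img, round(rend$images$Cy5), tolerance = 1e-12)
})
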