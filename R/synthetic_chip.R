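#' Default per-channel intensity model
#'
#' End-point fluorescence of a chamber is modelled as a two-component
#' distribution on a 16-bit scale: negatives around `mu_neg`, positives
#' around `mu_pos`, each with Gaussian spread. An optional "rain" fraction
#' of positive chambers is drawn uniformly between the two modes,
#' emulating partitions with intermediate amplification.
#'
#' @param mu_neg,mu_pos Mean intensity of negative/positive chambers
#'   (arbitrary fluorescence units on the 16-bit scale); `mu_pos > mu_neg`.
#' @param sigma_neg,sigma_pos Gaussian spread of each population.
#' @param rain_fraction Probability a positive chamber is "rain".
#' @return A list of class `intensity_model`.
#' @export
intensity_model <- function(mu_neg = 5000, mu_pos = 30000,
                            sigma_neg = 1500, sigma_pos = 1500,
                            rain_fraction = 0) {
  if (!(mu_pos > mu_neg)) stop("mu_pos must exceed mu_neg")
  if (sigma_neg < 0 || sigma_pos < 0) stop("sigmas must be >= 0")
  if (rain_fraction < 0 || rain_fraction > 1)
    stop("rain_fraction must be in [0, 1]")
  structure(list(mu_neg = mu_neg, mu_pos = mu_pos, sigma_neg = sigma_neg,
                 sigma_pos = sigma_pos, rain_fraction = rain_fraction),
            class = "intensity_model")
}

#' Convert a stock concentration to the in-chamber concentration
#'
#' The template enters the reaction mix diluted: by default 3.5 uL of
#' template in a 31.7 uL mix, the composition used on the reference chip.
#'
#' @param stock Stock concentration, copies/uL.
#' @param dilution_factor Unitless template volume fraction of the mix.
#' @return In-chamber (final mix) concentration, copies/uL.
#' @export
in_chamber_concentration <- function(stock, dilution_factor = 3.5 / 31.7) {
  stock * dilution_factor
}

#' Simulation configuration for a synthetic chip
#'
#' Bundles everything needed to generate a ground-truthed synthetic chip:
#' the chip geometry, the probe panel, per-species in-chamber template
#' concentrations, the stochastic loading/detection model and the image
#' rendering model.
#'
#' Species whose names appear in the panel's `target_map` are mutant
#' templates: they light the reference channel and their mapped mutation
#' channel. Any other species (conventionally `"WT"`) is detected by the
#' reference probe only.
#'
#' @param layout A [chip_layout()].
#' @param panel A [panel_config()].
#' @param species_concentrations Named numeric vector: species label ->
#'   in-chamber concentration, copies/uL. Use [in_chamber_concentration()]
#'   to convert stock values.
#' @param volume_ul Per-chamber volume in uL used for Poisson loading.
#'   Defaults to `7.1e-4` (the nominal 0.71 nL chamber).
#' @param dilution_factor Recorded stock->mix dilution (default 3.5/31.7);
#'   informational unless you convert stocks through it.
#' @param detection_efficiency Probability that one present template
#'   molecule yields signal on its channels.
#' @param unfilled_fraction Probability a chamber fails to fill.
#' @param intensities An [intensity_model()], or a named list of them
#'   (one per channel).
#' @param pixel_scale Rendering scale, um per pixel.
#' @param background_level,background_noise_sd Image background mean and
#'   per-pixel Gaussian noise SD (16-bit units).
#' @param max_pixels Guard against accidental huge renders.
#' @param seed Integer seed recorded in outputs; every simulation function
#'   seeds the RNG with it when non-NULL.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(layout = default_chip_layout(),
                              panel = default_panel(),
                              species_concentrations = c(WT = 0),
                              volume_ul = 7.1e-4,
                              dilution_factor = 3.5 / 31.7,
                              detection_efficiency = 1,
                              unfilled_fraction = 0,
                              intensities = intensity_model(),
                              pixel_scale = 5,
                              background_level = 2000,
                              background_noise_sd = 200,
                              max_pixels = 1.5e8,
                              seed = NULL) {
  stopifnot(inherits(layout, "chip_layout"), inherits(panel, "panel_config"))
  if (any(species_concentrations < 0))
    stop("species concentrations must be >= 0")
  if (is.null(names(species_concentrations)) ||
      any(names(species_concentrations) == ""))
    stop("species_concentrations must be named by species label")
  probs <- c(detection_efficiency = detection_efficiency,
             unfilled_fraction = unfilled_fraction)
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (volume_ul <= 0) stop("volume_ul must be > 0")
  if (inherits(intensities, "intensity_model"))
    intensities <- stats::setNames(
      rep(list(intensities), length(panel$channels)), panel$channels)
  if (!setequal(names(intensities), panel$channels))
    stop("intensities must cover exactly the panel channels")
  structure(list(layout = layout, panel = panel,
                 species_concentrations = species_concentrations,
                 volume_ul = volume_ul, dilution_factor = dilution_factor,
                 detection_efficiency = detection_efficiency,
                 unfilled_fraction = unfilled_fraction,
                 intensities = intensities, pixel_scale = pixel_scale,
                 background_level = background_level,
                 background_noise_sd = background_noise_sd,
                 max_pixels = max_pixels, seed = seed),
            class = "simulation_config")
}

#' Poisson partitioning of template molecules into chambers
#'
#' Loads each chamber with an independent Poisson number of molecules of
#' every species, mean `lambda_s = C_s * Vd` (concentration in copies/uL
#' times chamber volume in uL) — the dilute-limit model that absolute
#' quantification later inverts. The expected positive fraction for a
#' single species is `1 - exp(-lambda_s)`.
#'
#' True channel positivity follows the probe panel: the reference channel
#' is positive when any detected template is present; a mutation channel is
#' positive when its mapped mutant species has a detected molecule. Each
#' molecule is detected independently with probability
#' `detection_efficiency`. Unfilled chambers receive no template and are
#' never positive.
#'
#' @param config A [simulation_config()].
#' @return An object of class `chip_truth`: list with `counts` (chambers x
#'   species integer matrix), `filled` (logical), `positive` (chambers x
#'   channels logical), plus the layout/panel/config echo and seed.
#' @export
simulate_partition <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- total_chambers(config$layout)
  species <- names(config$species_concentrations)
  lambda <- config$species_concentrations * config$volume_ul

  filled <- stats::runif(n) >= config$unfilled_fraction
  counts <- matrix(0L, n, length(species), dimnames = list(NULL, species))
  detected <- counts
  for (s in seq_along(species)) {
    k <- stats::rpois(n, lambda[s])
    k[!filled] <- 0L
    counts[, s] <- k
    detected[, s] <- if (config$detection_efficiency >= 1) k
      else stats::rbinom(n, k, config$detection_efficiency)
  }

  channels <- config$panel$channels
  positive <- matrix(FALSE, n, length(channels),
                     dimnames = list(NULL, channels))
  positive[, config$panel$reference_channel] <- rowSums(detected) > 0
  tm <- config$panel$target_map
  for (m in names(tm))
    if (m %in% species)
      positive[, tm[[m]]] <- detected[, m] > 0

  structure(list(layout = config$layout, panel = config$panel,
                 counts = counts, filled = filled, positive = positive,
                 config = config, seed = config$seed),
            class = "chip_truth")
}

#' @export
print.chip_truth <- function(x, ...) {
  n <- nrow(x$counts)
  cat(sprintf("Synthetic chip truth: %d chambers, %d filled\n",
              n, sum(x$filled)))
  for (ch in colnames(x$positive))
    cat(sprintf("  %s: %d positive\n", ch, sum(x$positive[, ch])))
  invisible(x)
}

#' Draw per-chamber fluorescence intensities from the truth
#'
#' Generates the per-chamber, per-channel end-point intensities the imaging
#' model would produce, without rasterising an image: positives from the
#' positive component (with optional rain), negatives from the negative
#' component. Unfilled chambers are assigned the negative component.
#'
#' @param truth A `chip_truth`.
#' @param config The [simulation_config()] (defaults to the one recorded in
#'   `truth`).
#' @return Numeric matrix, chambers x channels.
#' @export
simulate_intensities <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "chip_truth"))
  n <- nrow(truth$positive)
  channels <- colnames(truth$positive)
  out <- matrix(NA_real_, n, length(channels),
                dimnames = list(NULL, channels))
  for (ch in channels) {
    im <- config$intensities[[ch]]
    pos <- truth$positive[, ch]
    x <- stats::rnorm(n, im$mu_neg, im$sigma_neg)
    npos <- sum(pos)
    if (npos > 0) {
      x[pos] <- stats::rnorm(npos, im$mu_pos, im$sigma_pos)
      if (im$rain_fraction > 0) {
        rain <- pos & (stats::runif(n) < im$rain_fraction)
        x[rain] <- stats::runif(sum(rain), im$mu_neg, im$mu_pos)
      }
    }
    out[, ch] <- pmin(pmax(x, 0), 65535)
  }
  out
}

#' Expected chamber-centre positions for rendering
#'
#' Chambers are laid out row-major from the top-left on a regular grid with
#' the layout's pitch, surrounded by a half-pitch margin. Coordinates are
#' pixels (x right, y down, 0-based image frame).
#'
#' @param layout A [chip_layout()].
#' @param pixel_scale um per pixel.
#' @return data.frame: `chamber_id`, `row`, `col`, `x_px`, `y_px`
#'   (row-major order, `chamber_id` starting at 1).
#' @export
chamber_centres <- function(layout, pixel_scale) {
  nr <- layout$n_rows; nc <- layout$chambers_per_row
  row <- rep(seq_len(nr), each = nc)
  col <- rep(seq_len(nc), times = nr)
  x <- (layout$pitch_x * (col - 0.5) + layout$pitch_x / 2) / pixel_scale
  y <- (layout$pitch_y * (row - 0.5) + layout$pitch_y / 2) / pixel_scale
  data.frame(chamber_id = seq_len(nr * nc), row = row, col = col,
             x_px = x, y_px = y)
}

image_dims <- function(layout, pixel_scale) {
  w <- ceiling(layout$pitch_x * (layout$chambers_per_row + 1) / pixel_scale)
  h <- ceiling(layout$pitch_y * (layout$n_rows + 1) / pixel_scale)
  c(h = h, w = w)
}

disk_offsets <- function(radius_px) {
  r <- floor(radius_px)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius_px^2, , drop = FALSE]
}

#' Render per-channel fluorescence images of a synthetic chip
#'
#' Draws each filled chamber as a disk of its channel intensity on a
#' uniform background, then adds per-pixel Gaussian background noise and
#' clips to the 16-bit range. One image per channel is produced, together
#' with the ground-truth chamber-centre table.
#'
#' @param truth A `chip_truth` from [simulate_partition()].
#' @param config The [simulation_config()] (defaults to the one in `truth`).
#' @param intensity Optional precomputed chambers x channels intensity
#'   matrix (from [simulate_intensities()]); drawn fresh when `NULL`.
#' @return List with `images` (named list of numeric matrices, 16-bit
#'   scale), `centres` (the ground-truth table with per-channel true calls
#'   appended) and `intensity`.
#' @export
render_images <- function(truth, config = truth$config, intensity = NULL) {
  stopifnot(inherits(truth, "chip_truth"))
  layout <- config$layout
  dims <- image_dims(layout, config$pixel_scale)
  if (prod(dims) > config$max_pixels)
    stop(sprintf("image of %d x %d pixels exceeds max_pixels cap",
                 dims["h"], dims["w"]))
  if (is.null(intensity)) intensity <- simulate_intensities(truth, config)

  cen <- chamber_centres(layout, config$pixel_scale)
  r_px <- layout$chamber_diameter / 2 / config$pixel_scale
  off <- disk_offsets(r_px)
  ri <- as.integer(round(cen$y_px)); ci <- as.integer(round(cen$x_px))
  draw <- truth$filled
  # flat pixel indices of every disk pixel of every drawn chamber
  rows <- rep(ri[draw], each = nrow(off)) + off$dy
  cols <- rep(ci[draw], each = nrow(off)) + off$dx
  idx <- rows + (cols - 1L) * dims[["h"]]

  images <- vector("list", length(truth$panel$channels))
  names(images) <- truth$panel$channels
  for (ch in truth$panel$channels) {
    img <- matrix(config$background_level, dims[["h"]], dims[["w"]])
    img[idx] <- rep(intensity[draw, ch], each = nrow(off))
    if (config$background_noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, config$background_noise_sd)
    images[[ch]] <- pmin(pmax(img, 0), 65535)
  }
  for (ch in colnames(truth$positive))
    cen[[paste0("true_", ch)]] <- truth$positive[, ch]
  cen$filled <- truth$filled
  list(images = images, centres = cen, intensity = intensity)
}

#' Write rendered channel images as 16-bit TIFF files
#'
#' Files are named `<chip_id>_<channel>.tif`.
#'
#' @param images Named list of image matrices (16-bit scale) from
#'   [render_images()].
#' @param dir Output directory (created if missing).
#' @param chip_id File-name prefix.
#' @return Named character vector of file paths, invisibly.
#' @export
write_channel_tiffs <- function(images, dir, chip_id = "chip") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in names(images)) {
    p <- file.path(dir, sprintf("%s_%s.tif", chip_id, ch))
    tiff::writeTIFF(round(images[[ch]]) / 65535, p, bits.per.sample = 16L)
    paths[ch] <- p
  }
  invisible(paths)
}

#' Read a 16-bit channel image
#'
#' Accepts TIFF or PNG; returns intensities on the native integer scale.
#'
#' @param path Image file path.
#' @return Numeric matrix of pixel intensities.
#' @export
read_channel_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the 'png' package is required to read PNG images")
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(img * 65535)
  }
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Simulate a mutant/wild-type mixture series
#'
#' For each mutation fraction `f`, the mutant species gets in-chamber
#' concentration `f * total` and the wild-type `(1 - f) * total`, where
#' `total` is the stock concentration scaled by the dilution factor. The
#' reference channel responds to both species; the mutation channel to the
#' mutant only.
#'
#' @param fractions Mutation fractions in `[0, 1]`.
#' @param total_stock_concentration Total template stock, copies/uL.
#' @param reps Chips simulated per fraction.
#' @param seed Integer seed for the whole series.
#' @param layout,panel Chip geometry and probe panel.
#' @param mutation Mutation label simulated (must be in the panel).
#' @param dilution_factor Stock -> in-chamber scaling.
#' @param render If `TRUE`, per-channel images are rendered for every chip
#'   (slow for full-size layouts); otherwise only truths are returned.
#' @param ... Further arguments to [simulation_config()].
#' @return List (one element per fraction) of lists with `fraction` and
#'   `chips`; each chip holds `truth` and (if rendered) `images`.
#' @export
simulate_mixture_series <- function(fractions, total_stock_concentration,
                                    reps = 1, seed = 1,
                                    layout = default_chip_layout(),
                                    panel = default_panel(),
                                    mutation = names(panel$target_map)[1],
                                    dilution_factor = 3.5 / 31.7,
                                    render = FALSE, ...) {
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1]")
  if (total_stock_concentration < 0)
    stop("total concentration must be >= 0")
  if (!mutation %in% names(panel$target_map))
    stop("mutation '", mutation, "' is not on the panel")
  total <- in_chamber_concentration(total_stock_concentration,
                                    dilution_factor)
  set.seed(seed)
  lapply(fractions, function(f) {
    conc <- stats::setNames(c(f * total, (1 - f) * total),
                            c(mutation, "WT"))
    chips <- lapply(seq_len(reps), function(i) {
      cfg <- simulation_config(layout = layout, panel = panel,
                               species_concentrations = conc,
                               dilution_factor = dilution_factor,
                               seed = NULL, ...)
      truth <- simulate_partition(cfg)
      if (render) list(truth = truth, images = render_images(truth, cfg))
      else list(truth = truth)
    })
    list(fraction = f, chips = chips)
  })
}

#' Write simulator ground truth as CSV
#'
#' One row per chamber: id, grid position, pixel centre, per-species
#' molecule counts and per-channel true calls, plus the filled flag.
#'
#' @param truth A `chip_truth`.
#' @param path Output CSV path.
#' @param pixel_scale um per pixel for the centre coordinates.
#' @return The written data.frame, invisibly.
#' @export
write_truth_csv <- function(truth, path,
                            pixel_scale = truth$config$pixel_scale) {
  cen <- chamber_centres(truth$layout, pixel_scale)
  df <- cbind(cen, as.data.frame(truth$counts))
  for (ch in colnames(truth$positive))
    df[[paste0("true_", ch)]] <- truth$positive[, ch]
  df$filled <- truth$filled
  df$seed <- if (is.null(truth$seed)) NA_integer_ else truth$seed
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
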