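#' Chip layout description
#'
#' Constructs a `chip_layout` object describing the geometry of a
#' chamber-array digital PCR chip: parallel fluid channels feeding rows of
#' cylindrical microchambers. The layout carries everything needed to derive
#' the chamber count `n` and the per-chamber volume `Vd` used by Poisson
#' quantification, plus the centre-to-centre pitch used only for image
#' rendering and grid registration.
#'
#' All lengths are in micrometres.
#'
#' @param n_channels Number of parallel fluid channels (each channel feeds
#'   two chamber rows on the default chip).
#' @param n_rows Number of chamber-array rows.
#' @param chambers_per_row Chambers in each row.
#' @param chamber_diameter Cylindrical chamber diameter, um.
#' @param chamber_height Chamber height, um.
#' @param channel_width,channel_height Fluid-channel cross-section, um.
#' @param pitch_x,pitch_y Centre-to-centre chamber spacing, um. Rendering
#'   parameters only; they have no effect on any statistical result.
#' @return An object of class `chip_layout`.
#' @seealso [default_chip_layout()], [total_chambers()], [chamber_volume()]
#' @export
chip_layout <- function(n_channels, n_rows, chambers_per_row,
                        chamber_diameter, chamber_height,
                        channel_width, channel_height,
                        pitch_x = 110, pitch_y = 110) {
  counts <- c(n_channels = n_channels, n_rows = n_rows,
              chambers_per_row = chambers_per_row)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("counts (n_channels, n_rows, chambers_per_row) must be integers >= 1")
  lens <- c(chamber_diameter = chamber_diameter,
            chamber_height = chamber_height,
            channel_width = channel_width, channel_height = channel_height,
            pitch_x = pitch_x, pitch_y = pitch_y)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all lengths must be finite and > 0")
  structure(
    list(n_channels = as.integer(n_channels),
         n_rows = as.integer(n_rows),
         chambers_per_row = as.integer(chambers_per_row),
         chamber_diameter = chamber_diameter,
         chamber_height = chamber_height,
         channel_width = channel_width,
         channel_height = channel_height,
         pitch_x = pitch_x, pitch_y = pitch_y),
    class = "chip_layout")
}

#' Default chip layout
#'
#' The reference 21,384-chamber chip: 54 parallel microchannels serving 108
#' rows of 198 cylindrical chambers each; chamber diameter 87 um, height
#' 120 um (nominal single-chamber volume about 0.71 nL); main channel
#' 60 um wide and 55 um high. Pitch defaults to 110 um in both directions,
#' a rendering-only choice larger than the chamber diameter so drawn
#' chambers do not touch.
#'
#' @return A `chip_layout`.
#' @export
default_chip_layout <- function() {
  chip_layout(n_channels = 54, n_rows = 108, chambers_per_row = 198,
              chamber_diameter = 87, chamber_height = 120,
              channel_width = 60, channel_height = 55,
              pitch_x = 110, pitch_y = 110)
}

#' @export
print.chip_layout <- function(x, ...) {
  cat("Chamber-array chip layout\n")
  cat(sprintf("  %d channels, %d rows x %d chambers = %d chambers\n",
              x$n_channels, x$n_rows, x$chambers_per_row, total_chambers(x)))
  cat(sprintf("  chamber: %g um diameter x %g um height (%.2f nL)\n",
              x$chamber_diameter, x$chamber_height, chamber_volume(x)))
  invisible(x)
}

#' Total number of chambers on a chip
#'
#' @param layout A [chip_layout()].
#' @return Integer: `n_rows * chambers_per_row`, the `n` of the Poisson
#'   quantification formula.
#' @export
total_chambers <- function(layout) {
  stopifnot(inherits(layout, "chip_layout"))
  layout$n_rows * layout$chambers_per_row
}

#' Volume of a single cylindrical chamber
#'
#' Computes `pi * (diameter/2)^2 * height` for the cylindrical chamber.
#' Full precision is always returned; round only for display.
#'
#' @param layout A [chip_layout()].
#' @param units `"nL"` (default) or `"uL"`. Quantification formulas take the
#'   volume in microlitres.
#' @return Chamber volume in the requested units.
#' @export
chamber_volume <- function(layout, units = c("nL", "uL")) {
  stopifnot(inherits(layout, "chip_layout"))
  units <- match.arg(units)
  # um^3; 1 nL = 1e6 um^3, 1 uL = 1e9 um^3
  v_um3 <- pi * (layout$chamber_diameter / 2)^2 * layout$chamber_height
  switch(units, nL = v_um3 / 1e6, uL = v_um3 / 1e9)
}

#' Fluorescence channel panel configuration
#'
#' Describes the probe-to-channel assignment of a multicolour detection
#' panel: an ordered set of fluorescence channels, one of which carries the
#' universal reference probe (detecting every template, wild-type or
#' mutant), and a mapping from mutation-type labels to the non-reference
#' channels carrying their specific probes. At most three mutation types fit
#' on one four-colour chip.
#'
#' @param channels Character vector of channel names (typically 4, e.g.
#'   Cy5/FAM/HEX plus a fourth dye).
#' @param reference_channel Name of the channel carrying the reference
#'   probe; must be one of `channels`.
#' @param target_map Named character vector or list: mutation label ->
#'   channel name. No mutation may map to the reference channel; each
#'   non-reference channel carries at most one mutation probe.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(channels, reference_channel, target_map) {
  channels <- as.character(channels)
  if (anyDuplicated(channels)) stop("duplicate channel names")
  if (!reference_channel %in% channels)
    stop("reference_channel must be one of the panel channels")
  target_map <- unlist(target_map)
  if (length(target_map) > 0) {
    if (is.null(names(target_map)) || any(names(target_map) == ""))
      stop("target_map must be named by mutation label")
    if (anyDuplicated(names(target_map)))
      stop("duplicate mutation labels in target_map")
    if (any(!target_map %in% channels))
      stop("target_map refers to unknown channel(s): ",
           paste(setdiff(target_map, channels), collapse = ", "))
    if (any(target_map == reference_channel))
      stop("no mutation type may map to the reference channel")
    if (anyDuplicated(target_map))
      stop("each channel may carry at most one mutation probe")
  }
  if (length(target_map) > 3)
    stop("at most 3 mutation types per panel (one chip)")
  structure(list(channels = channels,
                 reference_channel = reference_channel,
                 target_map = target_map),
            class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat("Probe panel:", paste(x$channels, collapse = ", "), "\n")
  cat("  reference:", x$reference_channel, "\n")
  for (m in names(x$target_map))
    cat(sprintf("  %s -> %s\n", m, x$target_map[[m]]))
  invisible(x)
}

#' Default three-plex KRAS panel
#'
#' A four-colour panel with the reference probe on Cy5 and three codon-12
#' mutation probes on the remaining channels. The fourth dye name is a
#' configuration choice; "ROX" is used by default.
#'
#' @param mutations Three mutation labels, assigned in order to the
#'   non-reference channels.
#' @return A `panel_config`.
#' @export
default_panel <- function(mutations = c("G12S", "G12C", "G12R")) {
  channels <- c("Cy5", "FAM", "HEX", "ROX")
  mutations <- as.character(mutations)
  tm <- stats::setNames(setdiff(channels, "Cy5")[seq_along(mutations)],
                        mutations)
  panel_config(channels, "Cy5", tm)
}

#' Read a chip layout and panel from a YAML or JSON config file
#'
#' The file holds a `layout:` block with the [chip_layout()] fields and an
#' optional `panel:` block with `channels`, `reference_channel` and
#' `target_map`. A bundled default reproducing the 21,384-chamber chip is at
#' `system.file("extdata", "chip_default.yaml", package = "chipdpcr")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `layout` (`chip_layout`) and `panel`
#'   (`panel_config` or `NULL`).
#' @export
read_chip_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$layout)) stop("config is missing a 'layout' block")
  layout <- do.call(chip_layout, cfg$layout)
  panel <- NULL
  if (!is.null(cfg$panel))
    panel <- panel_config(cfg$panel$channels, cfg$panel$reference_channel,
                          cfg$panel$target_map)
  list(layout = layout, panel = panel)
}
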