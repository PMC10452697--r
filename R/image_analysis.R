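#' Register the chamber grid in a channel image
#'
#' The chamber grid geometry is always known from the chip layout, so grid
#' detection is a registration problem, not blob detection: the nominal
#' centre grid is matched to the image by maximising the background-
#' subtracted row/column projection profiles over integer translations up
#' to half a pitch in each axis. This guarantees exactly
#' `total_chambers(layout)` centres, ordered row-major from the top-left.
#'
#' @param image Numeric pixel matrix (16-bit scale).
#' @param layout A [chip_layout()].
#' @param pixel_scale um per pixel used when the image was acquired.
#' @param max_shift Maximum translation searched, px; defaults to half the
#'   pitch.
#' @param size_tolerance Allowed relative mismatch between the image size
#'   and the size implied by `layout` and `pixel_scale`.
#' @return List: `centres` (data.frame `chamber_id`, `row`, `col`, `x_px`,
#'   `y_px`), `shift` (estimated `c(dx, dy)` in px) and `score` (peak to
#'   median ratio of the registration objective; higher is better).
#' @export
detect_grid <- function(image, layout, pixel_scale,
                        max_shift = NULL, size_tolerance = 0.2) {
  dims <- image_dims(layout, pixel_scale)
  if (abs(nrow(image) - dims[["h"]]) > size_tolerance * dims[["h"]] ||
      abs(ncol(image) - dims[["w"]]) > size_tolerance * dims[["w"]])
    stop(sprintf("image is %d x %d px but layout implies %d x %d px",
                 nrow(image), ncol(image), dims[["h"]], dims[["w"]]))
  if (is.null(max_shift))
    max_shift <- floor(min(layout$pitch_x, layout$pitch_y) /
                         pixel_scale / 2)
  cen <- chamber_centres(layout, pixel_scale)
  # smallest shifts first so which.max breaks exact ties towards 0
  shifts <- (-max_shift:max_shift)[order(abs(-max_shift:max_shift))]
  r_px <- layout$chamber_diameter / 2 / pixel_scale
  r <- floor(r_px)
  # chord-length kernel of the chamber disk: correlating the projection
  # profile with it gives a single sharp registration peak (a bare comb
  # ties across the disk's flat projection plateau)
  kernel <- vapply(-r:r, function(d)
    sum((-r:r)^2 + d^2 <= r_px^2), numeric(1))

  profile_score <- function(prof, pos) {
    prof <- prof - stats::median(prof)
    conv <- stats::filter(prof, rev(kernel), sides = 2)
    conv[is.na(conv)] <- 0
    vapply(shifts, function(s) {
      i <- pos + s
      sum(conv[i[i >= 1 & i <= length(conv)]])
    }, numeric(1))
  }
  sx <- profile_score(colSums(image), unique(round(cen$x_px)))
  sy <- profile_score(rowSums(image), unique(round(cen$y_px)))
  dx <- shifts[which.max(sx)]
  dy <- shifts[which.max(sy)]
  score <- min(max(sx) / max(stats::median(sx), 1e-12),
               max(sy) / max(stats::median(sy), 1e-12))
  if (!is.finite(score) || score <= 1.02)
    stop(sprintf("grid registration failed (diagnostic score %.3f)", score))
  cen$x_px <- cen$x_px + dx
  cen$y_px <- cen$y_px + dy
  list(centres = cen, shift = c(dx = dx, dy = dy), score = score)
}

#' Mean chamber intensities from a channel image
#'
#' Averages pixels within a disk centred on each chamber. The disk radius
#' is the chamber radius shrunk by `shrink` (default 0.8) so edge pixels,
#' where the rendered disk meets the background, are excluded.
#'
#' @param image Numeric pixel matrix.
#' @param centres Chamber-centre data.frame from [detect_grid()] (or the
#'   `$centres` element of its return value).
#' @param layout A [chip_layout()].
#' @param pixel_scale um per pixel.
#' @param shrink Radius shrink factor in (0, 1].
#' @return Numeric vector of per-chamber mean intensities, in chamber
#'   order.
#' @export
extract_intensities <- function(image, centres, layout, pixel_scale,
                                shrink = 0.8) {
  if (!is.null(centres$centres)) centres <- centres$centres
  if (shrink <= 0 || shrink > 1) stop("shrink must be in (0, 1]")
  r_px <- layout$chamber_diameter / 2 / pixel_scale * shrink
  off <- disk_offsets(r_px)
  ri <- as.integer(round(centres$y_px))
  ci <- as.integer(round(centres$x_px))
  if (any(ri - max(abs(off$dy)) < 1) || any(ri + max(abs(off$dy)) > nrow(image)) ||
      any(ci - max(abs(off$dx)) < 1) || any(ci + max(abs(off$dx)) > ncol(image)))
    stop("chamber disk exceeds image bounds")
  k <- nrow(off)
  rows <- rep(ri, each = k) + off$dy
  cols <- rep(ci, each = k) + off$dx
  vals <- image[rows + (cols - 1L) * nrow(image)]
  colMeans(matrix(vals, nrow = k))
}

#' Two-class intensity thresholding
#'
#' Splits a 1-D intensity sample into negative and positive populations by
#' exact two-class clustering: the split of the sorted sample minimising
#' the total within-class sum of squares (the global optimum of 1-D
#' two-means, found by scanning all splits). The calling threshold is the
#' midpoint of the two class centroids. When the centroid gap is smaller
#' than `separation_factor` times the pooled within-class spread — i.e.
#' there is no genuinely bimodal structure — every chamber is called
#' negative and the `no_positive` flag is set. An Otsu histogram threshold
#' is available as an alternative.
#'
#' The decision is invariant to affine rescaling `a*x + b` (`a > 0`) of the
#' intensities.
#'
#' @param intensity Numeric vector of per-chamber intensities (>= 2 values).
#' @param method `"kmeans"` (exact two-class split, default) or `"otsu"`
#'   (256-bin histogram Otsu).
#' @param separation_factor Minimum centroid gap in units of pooled
#'   within-class SD for a positive population to be declared.
#' @return List of class `chamber_classification`: `calls` (logical),
#'   `threshold`, `no_positive`, `centroids`, `method`.
#' @export
classify_chambers <- function(intensity, method = c("kmeans", "otsu"),
                              separation_factor = 3) {
  method <- match.arg(method)
  x <- intensity
  if (length(x) == 0) stop("no intensities supplied")
  if (length(x) < 2) stop("need at least 2 chambers to classify")
  if (anyNA(x)) stop("intensities contain NA")

  xs <- sort(x)
  n <- length(xs)
  if (xs[1] == xs[n]) {
    return(structure(list(calls = rep(FALSE, length(x)), threshold = Inf,
                          no_positive = TRUE,
                          centroids = c(neg = xs[1], pos = xs[1]),
                          method = method),
                     class = "chamber_classification"))
  }

  if (method == "kmeans") {
    cs <- cumsum(xs); cs2 <- cumsum(xs^2)
    k <- seq_len(n - 1)
    ss_lo <- cs2[k] - cs[k]^2 / k
    ss_hi <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
    best <- which.min(ss_lo + ss_hi)
    m_lo <- cs[best] / best
    m_hi <- (cs[n] - cs[best]) / (n - best)
    within_sd <- sqrt((ss_lo[best] + ss_hi[best]) / n)
    threshold <- (m_lo + m_hi) / 2
  } else {
    h <- graphics::hist(x, breaks = 256, plot = FALSE)
    w <- h$counts / n; mids <- h$mids
    omega <- cumsum(w); mu <- cumsum(w * mids); mu_t <- mu[length(mu)]
    between <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
    between[!is.finite(between)] <- 0
    threshold <- mids[which.max(between)]
    lo <- x < threshold
    m_lo <- mean(x[lo]); m_hi <- mean(x[!lo])
    within_sd <- sqrt((sum((x[lo] - m_lo)^2) +
                         sum((x[!lo] - m_hi)^2)) / n)
  }

  if (!is.finite(within_sd)) within_sd <- 0
  if ((m_hi - m_lo) <= separation_factor * within_sd) {
    return(structure(list(calls = rep(FALSE, length(x)),
                          threshold = Inf, no_positive = TRUE,
                          centroids = c(neg = m_lo, pos = m_hi),
                          method = method),
                     class = "chamber_classification"))
  }
  structure(list(calls = x >= threshold, threshold = threshold,
                 no_positive = FALSE,
                 centroids = c(neg = m_lo, pos = m_hi), method = method),
            class = "chamber_classification")
}

#' Build a chamber call table
#'
#' Internal constructor shared by the image pipeline and the truth-derived
#' path: one row per layout chamber, with per-channel mean intensities and
#' boolean calls, the filled flag, and per-channel thresholds stored as an
#' attribute. Calls are `NA` for unfilled chambers.
#'
#' @noRd
new_chamber_calls <- function(centres, intensity, calls, thresholds,
                              filled, channels) {
  df <- centres[, c("chamber_id", "row", "col", "x_px", "y_px")]
  df$filled <- filled
  for (ch in channels) {
    df[[paste0(ch, "_intensity")]] <-
      if (is.null(intensity)) NA_real_ else intensity[, ch]
    cc <- calls[, ch]
    cc[!filled] <- NA
    df[[paste0(ch, "_call")]] <- cc
  }
  structure(df, channels = channels, thresholds = thresholds,
            class = c("chamber_calls", "data.frame"))
}

#' @export
print.chamber_calls <- function(x, ...) {
  ch <- attr(x, "channels")
  cat(sprintf("Chamber call table: %d chambers (%d filled), channels: %s\n",
              nrow(x), sum(x$filled), paste(ch, collapse = ", ")))
  th <- attr(x, "thresholds")
  for (c0 in ch)
    cat(sprintf("  %s: %d positive (threshold %s)\n", c0,
                sum(x[[paste0(c0, "_call")]], na.rm = TRUE),
                format(th[[c0]], digits = 6)))
  invisible(x)
}

#' Channels of a chamber call table
#' @param calls A `chamber_calls` table.
#' @return Character vector of channel names.
#' @export
call_channels <- function(calls) attr(calls, "channels")

#' Per-channel positive call matrix
#' @param calls A `chamber_calls` table.
#' @return Logical matrix chambers x channels (`NA` for unfilled chambers).
#' @export
call_matrix <- function(calls) {
  ch <- attr(calls, "channels")
  m <- sapply(ch, function(c0) calls[[paste0(c0, "_call")]])
  colnames(m) <- ch
  m
}

#' Analyze a set of channel images into a chamber call table
#'
#' Runs the full image pipeline: grid registration on the reference (first)
#' channel, intensity extraction of every channel on the registered grid,
#' and per-channel two-class thresholding.
#'
#' @param images Named list of channel image matrices (names are channel
#'   names; the first, or `register_on`, is used for registration).
#' @param layout A [chip_layout()].
#' @param pixel_scale um per pixel.
#' @param register_on Channel name used for grid registration.
#' @param method,separation_factor Passed to [classify_chambers()].
#' @param shrink Passed to [extract_intensities()].
#' @param filled Optional logical vector of filled chambers (defaults to
#'   all filled; filling status is not inferred from images).
#' @return A `chamber_calls` table.
#' @export
analyze_chip <- function(images, layout, pixel_scale,
                         register_on = names(images)[1],
                         method = "kmeans", separation_factor = 3,
                         shrink = 0.8, filled = NULL) {
  if (is.null(names(images)) || any(names(images) == ""))
    stop("images must be a named list (channel names)")
  grid <- detect_grid(images[[register_on]], layout, pixel_scale)
  channels <- names(images)
  n <- nrow(grid$centres)
  if (is.null(filled)) filled <- rep(TRUE, n)
  intensity <- matrix(NA_real_, n, length(channels),
                      dimnames = list(NULL, channels))
  calls <- matrix(NA, n, length(channels), dimnames = list(NULL, channels))
  thresholds <- stats::setNames(numeric(length(channels)), channels)
  for (ch in channels) {
    intensity[, ch] <- extract_intensities(images[[ch]], grid$centres,
                                           layout, pixel_scale, shrink)
    cl <- classify_chambers(intensity[, ch], method = method,
                            separation_factor = separation_factor)
    calls[, ch] <- cl$calls
    thresholds[ch] <- cl$threshold
  }
  out <- new_chamber_calls(grid$centres, intensity, calls, thresholds,
                           filled, channels)
  attr(out, "registration") <- grid[c("shift", "score")]
  out
}

#' Chamber call table directly from simulator truth
#'
#' Bypasses image rendering: either uses the true per-channel positivity
#' (perfect detector), or draws per-chamber intensities from the configured
#' intensity model and thresholds them with [classify_chambers()] — the
#' "pre-extracted intensity table" input mode.
#'
#' @param truth A `chip_truth`.
#' @param use_intensities If `TRUE`, draw intensities and classify;
#'   otherwise copy the true calls.
#' @param method,separation_factor Passed to [classify_chambers()].
#' @return A `chamber_calls` table.
#' @export
calls_from_truth <- function(truth, use_intensities = FALSE,
                             method = "kmeans", separation_factor = 3) {
  stopifnot(inherits(truth, "chip_truth"))
  cfg <- truth$config
  cen <- chamber_centres(truth$layout, cfg$pixel_scale)
  channels <- colnames(truth$positive)
  thresholds <- stats::setNames(rep(NA_real_, length(channels)), channels)
  if (use_intensities) {
    intensity <- simulate_intensities(truth, cfg)
    calls <- matrix(NA, nrow(intensity), ncol(intensity),
                    dimnames = dimnames(intensity))
    for (ch in channels) {
      cl <- classify_chambers(intensity[, ch], method = method,
                              separation_factor = separation_factor)
      calls[, ch] <- cl$calls
      thresholds[ch] <- cl$threshold
    }
  } else {
    intensity <- NULL
    calls <- truth$positive
  }
  new_chamber_calls(cen, intensity, calls, thresholds, truth$filled,
                    channels)
}

#' Count positive chambers on a channel
#'
#' @param calls A `chamber_calls` table.
#' @param channel Channel name.
#' @param count_unfilled If `FALSE` (default) unfilled chambers are
#'   excluded.
#' @return Integer count of positive chambers.
#' @export
positive_count <- function(calls, channel, count_unfilled = FALSE) {
  cc <- calls[[paste0(channel, "_call")]]
  if (is.null(cc)) stop("no such channel in call table: ", channel)
  sum(cc, na.rm = TRUE)
}

#' Number of chambers counted for quantification
#'
#' @param calls A `chamber_calls` table.
#' @param count_unfilled Include unfilled chambers in the denominator.
#' @return Integer.
#' @export
chambers_counted <- function(calls, count_unfilled = FALSE) {
  if (count_unfilled) nrow(calls) else sum(calls$filled)
}

#' Write / read a chamber call table as CSV
#'
#' Column order is stable: `chamber_id`, `row`, `col`, `x_px`, `y_px`,
#' `filled`, then for each channel `<channel>_intensity`, `<channel>_call`,
#' `<channel>_threshold` (the threshold repeated on every row).
#'
#' @param calls A `chamber_calls` table.
#' @param path CSV path.
#' @return `write_calls_csv`: the path, invisibly. `read_calls_csv`: a
#'   `chamber_calls` table.
#' @export
write_calls_csv <- function(calls, path) {
  df <- as.data.frame(calls)
  th <- attr(calls, "thresholds")
  for (ch in attr(calls, "channels"))
    df[[paste0(ch, "_threshold")]] <- th[[ch]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_csv
#' @export
read_calls_csv <- function(path) {
  df <- utils::read.csv(path)
  ch <- sub("_call$", "", grep("_call$", names(df), value = TRUE))
  thresholds <- stats::setNames(rep(NA_real_, length(ch)), ch)
  for (c0 in ch) {
    tcol <- paste0(c0, "_threshold")
    if (tcol %in% names(df)) {
      thresholds[c0] <- df[[tcol]][1]
      df[[tcol]] <- NULL
    }
    df[[paste0(c0, "_call")]] <- as.logical(df[[paste0(c0, "_call")]])
  }
  df$filled <- as.logical(df$filled)
  structure(df, channels = ch, thresholds = thresholds,
            class = c("chamber_calls", "data.frame"))
}

#' Write a QC overlay image
#'
#' Renders the channel image in grayscale with called-positive chambers
#' circled, as an 8-bit RGB PNG.
#'
#' @param image Channel image matrix.
#' @param calls A `chamber_calls` table (provides centres and calls).
#' @param channel Channel to overlay.
#' @param path Output PNG path.
#' @param layout A [chip_layout()].
#' @param pixel_scale um per pixel.
#' @return The path, invisibly.
#' @export
qc_overlay <- function(image, calls, channel, path, layout, pixel_scale) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for QC overlays")
  g <- image / 65535
  rgb <- array(g, c(dim(g), 3))
  r_px <- layout$chamber_diameter / 2 / pixel_scale
  theta <- seq(0, 2 * pi, length.out = 64)
  pos <- which(calls[[paste0(channel, "_call")]] %in% TRUE)
  for (i in pos) {
    rr <- pmin(pmax(round(calls$y_px[i] + (r_px + 2) * sin(theta)), 1),
               nrow(g))
    cc <- pmin(pmax(round(calls$x_px[i] + (r_px + 2) * cos(theta)), 1),
               ncol(g))
    rgb[cbind(rr, cc, 1)] <- 1
    rgb[cbind(rr, cc, 2)] <- 0
    rgb[cbind(rr, cc, 3)] <- 0
  }
  png::writePNG(rgb, path)
  invisible(path)
}
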