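#' Wilson score interval for a binomial proportion
#'
#' Thin wrapper around `stats::prop.test(correct = FALSE)`, whose
#' confidence interval is the Wilson score interval. Chosen for its good
#' behaviour at very small positive counts, the regime of rare-mutation
#' digital PCR.
#'
#' @param d Successes (positive chambers).
#' @param n Trials (counted chambers).
#' @param conf_level Confidence level.
#' @return Numeric `c(low, high)`.
#' @keywords internal
wilson_interval <- function(d, n, conf_level = 0.95) {
  ci <- stats::prop.test(d, n, correct = FALSE,
                         conf.level = conf_level)$conf.int
  c(ci[1], ci[2])
}

#' Poisson absolute quantification from chamber counts
#'
#' Inverts the positive-chamber fraction to an absolute template
#' concentration under Poisson loading:
#' \deqn{C = -\ln(1 - d/n) / V_d}
#' with `d` positive chambers out of `n` counted chambers of volume `Vd`
#' (uL), giving `C` in copies/uL. This closed form is the maximum-
#' likelihood estimate of the per-chamber mean occupancy divided by the
#' chamber volume.
#'
#' The confidence interval is the Wilson score interval on `d/n`
#' transformed through the (monotone) concentration function. Edge
#' conventions: `d = 0` returns `C = 0` with an interval covering 0;
#' `d = n` (saturation) is flagged, the reported `C` is the finite lower
#' bound obtained with `d = n - 1`, and the upper confidence limit is
#' unbounded.
#'
#' @param d Number of positive chambers.
#' @param n Total number of counted chambers (>= 1).
#' @param volume_ul Chamber volume in uL (default `7.1e-4`, the nominal
#'   0.71 nL chamber).
#' @param conf_level Confidence level for the interval.
#' @return Object of class `quant_result`: list with `d`, `n`,
#'   `volume_ul`, `concentration` (copies/uL), `ci_low`, `ci_high`,
#'   `saturated`, `conf_level`.
#' @export
poisson_concentration <- function(d, n, volume_ul = 7.1e-4,
                                  conf_level = 0.95) {
  if (length(d) != 1 || length(n) != 1) stop("d and n must be scalars")
  if (n < 1 || n != round(n)) stop("n must be an integer >= 1")
  if (d < 0 || d > n || d != round(d)) stop("d must be an integer in [0, n]")
  if (volume_ul <= 0) stop("volume_ul must be > 0")

  conc_of <- function(p) -log(1 - p) / volume_ul
  saturated <- d == n
  ci <- wilson_interval(d, n, conf_level)
  if (saturated) {
    concentration <- conc_of((n - 1) / n)
    ci_low <- conc_of(ci[1]); ci_high <- Inf
  } else {
    concentration <- if (d == 0) 0 else conc_of(d / n)
    ci_low <- conc_of(ci[1])
    ci_high <- if (ci[2] >= 1) Inf else conc_of(ci[2])
  }
  structure(list(d = as.integer(d), n = as.integer(n),
                 volume_ul = volume_ul, concentration = concentration,
                 ci_low = ci_low, ci_high = ci_high,
                 saturated = saturated, conf_level = conf_level),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("Poisson quantification: %d / %d chambers positive\n",
              x$d, x$n))
  cat(sprintf("  C = %s copies/uL  [%s, %s] (%g%% CI)%s\n",
              format(x$concentration, digits = 6),
              format(x$ci_low, digits = 6), format(x$ci_high, digits = 6),
              100 * x$conf_level,
              if (x$saturated) "  [saturated: lower bound]" else ""))
  invisible(x)
}

#' Quantify a channel of a chamber call table
#'
#' Convenience wrapper: counts positives on one channel of a
#' [calls_from_truth()]/[analyze_chip()] table and applies
#' [poisson_concentration()]. Unfilled chambers are excluded from both
#' numerator and denominator unless `count_unfilled` is set (which adds
#' them to the denominator only).
#'
#' @param calls A `chamber_calls` table.
#' @param channel Channel name.
#' @param volume_ul Chamber volume, uL.
#' @param count_unfilled Include unfilled chambers in `n`.
#' @param conf_level Confidence level.
#' @return A `quant_result`.
#' @export
quantify_channel <- function(calls, channel, volume_ul = 7.1e-4,
                             count_unfilled = FALSE, conf_level = 0.95) {
  d <- positive_count(calls, channel, count_unfilled)
  n <- chambers_counted(calls, count_unfilled)
  poisson_concentration(d, n, volume_ul, conf_level)
}

#' Pool replicate chips before quantification
#'
#' Replicates are combined by summing positive and total chamber counts,
#' then applying the Poisson inversion once — equivalent to treating the
#' replicates as one larger chip.
#'
#' @param results List of `quant_result` objects with a common volume.
#' @param conf_level Confidence level for the pooled interval.
#' @return A `quant_result` on the pooled counts.
#' @export
pool_quant_results <- function(results, conf_level = 0.95) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, TRUE, "quant_result")))
  v <- unique(vapply(results, `[[`, numeric(1), "volume_ul"))
  if (length(v) != 1) stop("replicates have differing chamber volumes")
  poisson_concentration(sum(vapply(results, `[[`, integer(1), "d")),
                        sum(vapply(results, `[[`, integer(1), "n")),
                        v, conf_level)
}

#' Dilution-series linearity analysis
#'
#' Regresses log10 of the mean estimated concentration per dilution level
#' on log10 of the nominal (true) concentration, by ordinary least
#' squares. The log scale is the default because a serial dilution spans
#' several decades and a linear-scale fit would be dominated by the top
#' level; the linear-scale R-squared is also reported.
#'
#' Levels with a non-positive mean estimate cannot be log-transformed and
#' are dropped with a warning.
#'
#' @param true_concentration Numeric vector of nominal concentrations, one
#'   per dilution level (copies/uL).
#' @param estimates List parallel to `true_concentration`; each element is
#'   a numeric vector of per-chip estimated concentrations, a single
#'   `quant_result`, or a list of `quant_result`s (replicates).
#' @return List of class `linearity_result`: `slope`, `intercept`,
#'   `r_squared` (log-log), `r_squared_linear`, `fit` (the `lm`),
#'   `data` (per-level means).
#' @export
dilution_linearity <- function(true_concentration, estimates) {
  if (length(true_concentration) != length(estimates))
    stop("one estimate set per dilution level required")
  as_conc <- function(e) {
    if (inherits(e, "quant_result")) return(e$concentration)
    if (is.list(e)) return(vapply(e, function(q) q$concentration,
                                  numeric(1)))
    as.numeric(e)
  }
  mean_est <- vapply(estimates, function(e) mean(as_conc(e)), numeric(1))
  keep <- mean_est > 0 & true_concentration > 0
  if (!all(keep)) {
    warning(sum(!keep), " level(s) with non-positive estimates dropped")
    mean_est <- mean_est[keep]
    true_concentration <- true_concentration[keep]
  }
  if (length(mean_est) < 3)
    stop("at least 3 usable dilution levels are required")
  df <- data.frame(true = true_concentration, estimate = mean_est)
  fit <- stats::lm(log10(estimate) ~ log10(true), data = df)
  fit_lin <- stats::lm(estimate ~ true, data = df)
  # summary.lm warns on exact fits; a perfect series is a valid input here
  r2 <- function(f) suppressWarnings(summary(f)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2(fit),
                 r_squared_linear = r2(fit_lin),
                 fit = fit, data = df),
            class = "linearity_result")
}

#' @export
print.linearity_result <- function(x, ...) {
  cat(sprintf(
    "Dilution linearity (log10-log10): slope %.4f, intercept %.4f, R^2 = %.5f\n",
    x$slope, x$intercept, x$r_squared))
  cat(sprintf("  linear-scale R^2 = %.5f over %d levels\n",
              x$r_squared_linear, nrow(x$data)))
  invisible(x)
}

#' Plot a dilution series fit
#'
#' Log-log scatter of estimated versus nominal concentration with the
#' fitted line.
#'
#' @param x A `linearity_result`.
#' @param ... Passed to `plot`.
#' @export
plot.linearity_result <- function(x, ...) {
  graphics::plot(log10(x$data$true), log10(x$data$estimate),
                 xlab = "log10 nominal concentration (copies/uL)",
                 ylab = "log10 estimated concentration (copies/uL)",
                 pch = 19, ...)
  graphics::abline(x$intercept, x$slope, col = "red3")
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("slope %.3f, R^2 %.5f",
                                    x$slope, x$r_squared))
  invisible(x)
}

#' Detection power across mutation fractions (limit of detection)
#'
#' Simulates chips over a series of mutation fractions and reports, for
#' each fraction, the proportion of chips on which the mutant is detected.
#' The default detection rule is the reference-gated rule: at least
#' `min_double_positive` chambers positive in both the reference channel
#' and the mutation channel.
#'
#' @param fractions Mutation fractions in `[0, 1]`.
#' @param total_stock_concentration Total template stock, copies/uL.
#' @param reps Chips per fraction (>= 1).
#' @param seed Integer seed.
#' @param min_double_positive Detection rule threshold (chambers).
#' @param layout,panel,mutation,dilution_factor,... Passed to
#'   [simulate_mixture_series()].
#' @return data.frame: `fraction`, `reps`, `detected` (chips),
#'   `detection_rate`, `mean_double_positive`.
#' @export
lod_power <- function(fractions, total_stock_concentration, reps = 100,
                      seed = 1, min_double_positive = 1,
                      layout = default_chip_layout(),
                      panel = default_panel(),
                      mutation = names(panel$target_map)[1],
                      dilution_factor = 3.5 / 31.7, ...) {
  if (reps < 1) stop("reps must be >= 1")
  series <- simulate_mixture_series(fractions, total_stock_concentration,
                                    reps = reps, seed = seed,
                                    layout = layout, panel = panel,
                                    mutation = mutation,
                                    dilution_factor = dilution_factor,
                                    render = FALSE, ...)
  ref <- panel$reference_channel
  mch <- panel$target_map[[mutation]]
  rows <- lapply(series, function(lev) {
    dp <- vapply(lev$chips, function(chip) {
      sum(chip$truth$positive[, ref] & chip$truth$positive[, mch])
    }, numeric(1))
    data.frame(fraction = lev$fraction, reps = reps,
               detected = sum(dp >= min_double_positive),
               detection_rate = mean(dp >= min_double_positive),
               mean_double_positive = mean(dp))
  })
  do.call(rbind, rows)
}
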