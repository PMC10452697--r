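#' Reference-gated chamber classes per mutation
#'
#' For each mutation on the panel, partitions the filled chambers by the
#' joint state of the reference channel and the mutation channel:
#' \describe{
#'   \item{double_positive}{reference+ and mutation+ — evidence of a
#'     mutant template.}
#'   \item{wild_only}{reference+ and mutation- — wild-type template(s)
#'     only.}
#'   \item{empty}{reference- and mutation- — no template.}
#'   \item{anomalous}{reference- and mutation+ — suspect false positives
#'     (impurity interference or sampling irregularity); counted,
#'     reported, and excluded from mutant quantification.}
#' }
#'
#' @param calls A `chamber_calls` table containing the reference channel
#'   and every panel channel.
#' @param panel A [panel_config()].
#' @return List of class `gate_result`: `summary` (data.frame of class
#'   counts per mutation) and `classes` (character matrix, filled
#'   chambers x mutations).
#' @export
gate_chambers <- function(calls, panel) {
  stopifnot(inherits(panel, "panel_config"))
  have <- call_channels(calls)
  need <- unique(c(panel$reference_channel, unlist(panel$target_map)))
  missing <- setdiff(need, have)
  if (length(missing) > 0)
    stop("call table is missing channel(s): ",
         paste(missing, collapse = ", "))
  keep <- calls$filled
  ref <- calls[[paste0(panel$reference_channel, "_call")]][keep]
  muts <- names(panel$target_map)
  classes <- matrix(NA_character_, sum(keep), length(muts),
                    dimnames = list(NULL, muts))
  rows <- lapply(muts, function(m) {
    mc <- calls[[paste0(panel$target_map[[m]], "_call")]][keep]
    cl <- ifelse(ref & mc, "double_positive",
          ifelse(ref & !mc, "wild_only",
          ifelse(!ref & mc, "anomalous", "empty")))
    classes[, m] <<- cl
    data.frame(mutation = m,
               channel = unname(panel$target_map[[m]]),
               double_positive = sum(cl == "double_positive"),
               wild_only = sum(cl == "wild_only"),
               empty = sum(cl == "empty"),
               anomalous = sum(cl == "anomalous"),
               n = length(cl))
  })
  structure(list(summary = do.call(rbind, rows), classes = classes),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat("Reference-gated chamber classes:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Mutation-rate estimation from a chamber call table
#'
#' For each mutation on the panel, estimates the reference (total
#' template) concentration from reference-positive chambers and the
#' mutant concentration from double-positive chambers only (the reference
#' gate, which excludes anomalous reference-negative signals), both by
#' Poisson inversion. The mutation rate is
#' \deqn{P = C_{mut} / C_{ref} \times 100\%.}
#'
#' The confidence interval on `P` propagates the two Wilson-based
#' concentration intervals by interval arithmetic
#' (`[mut_low/ref_high, mut_high/ref_low]`), a deliberately conservative
#' (wider than exact) treatment of the ratio.
#'
#' @param calls A `chamber_calls` table.
#' @param panel A [panel_config()].
#' @param volume_ul Chamber volume, uL.
#' @param count_unfilled Include unfilled chambers in `n`.
#' @param gate If `TRUE` (default) the mutant count is the double-positive
#'   count; if `FALSE`, all mutation-channel positives are used
#'   (ungated comparison mode).
#' @param conf_level Confidence level.
#' @return data.frame of class `mutation_rate_result`, one row per
#'   mutation: `mutation`, `c_reference`, `c_mutant`, `P` (percent),
#'   `ci_low`, `ci_high` (percent), `double_positive_count`,
#'   `anomalous_count`, `zero_reference`.
#' @export
mutation_rate <- function(calls, panel, volume_ul = 7.1e-4,
                          count_unfilled = FALSE, gate = TRUE,
                          conf_level = 0.95) {
  g <- gate_chambers(calls, panel)
  n <- chambers_counted(calls, count_unfilled)
  d_ref <- positive_count(calls, panel$reference_channel, count_unfilled)
  q_ref <- poisson_concentration(d_ref, n, volume_ul, conf_level)
  rows <- lapply(seq_len(nrow(g$summary)), function(i) {
    s <- g$summary[i, ]
    d_mut <- if (gate) s$double_positive
      else s$double_positive + s$anomalous
    q_mut <- poisson_concentration(d_mut, n, volume_ul, conf_level)
    zero_ref <- q_ref$concentration <= 0
    if (zero_ref) {
      p <- NA_real_; lo <- NA_real_; hi <- NA_real_
    } else {
      p <- q_mut$concentration / q_ref$concentration * 100
      lo <- q_mut$ci_low / q_ref$ci_high * 100
      hi <- if (q_ref$ci_low <= 0) Inf
        else q_mut$ci_high / q_ref$ci_low * 100
    }
    data.frame(mutation = s$mutation, c_reference = q_ref$concentration,
               c_mutant = q_mut$concentration, P = p,
               ci_low = lo, ci_high = hi,
               double_positive_count = s$double_positive,
               anomalous_count = s$anomalous,
               zero_reference = zero_ref)
  })
  structure(do.call(rbind, rows),
            volume_ul = volume_ul, n = n, conf_level = conf_level,
            class = c("mutation_rate_result", "data.frame"))
}

#' Combine per-chip mutation results into a panel report
#'
#' Two three-plex chips cover six mutation types; this merges their
#' per-chip [mutation_rate()] results into one report and flags each
#' mutation whose double-positive count reaches the reporting threshold
#' as detected.
#'
#' Each mutation must appear on exactly one chip: duplicates are a
#' configuration error; if an expected mutation is missing (e.g. only one
#' chip was run), a partial report is returned with a warning.
#'
#' @param chips List of `mutation_rate_result` objects (one per chip).
#' @param mutations Character vector of expected mutation labels
#'   (defaults to those present).
#' @param reporting_threshold Minimum double-positive chambers for a
#'   mutation to be flagged detected (default 1, the rule used for
#'   rare-fraction detection).
#' @return data.frame: the merged rows plus `chip` and `detected`
#'   columns.
#' @export
panel_report <- function(chips, mutations = NULL,
                         reporting_threshold = 1) {
  stopifnot(length(chips) >= 1,
            all(vapply(chips, inherits, TRUE, "mutation_rate_result")))
  merged <- do.call(rbind, lapply(seq_along(chips), function(i) {
    df <- as.data.frame(chips[[i]])
    df$chip <- i
    df
  }))
  dup <- unique(merged$mutation[duplicated(merged$mutation)])
  if (length(dup) > 0)
    stop("mutation(s) assigned to more than one chip: ",
         paste(dup, collapse = ", "))
  if (is.null(mutations)) mutations <- merged$mutation
  missing <- setdiff(mutations, merged$mutation)
  if (length(missing) > 0)
    warning("partial report: no chip covers mutation(s) ",
            paste(missing, collapse = ", "))
  merged <- merged[merged$mutation %in% mutations, , drop = FALSE]
  merged$detected <- merged$double_positive_count >= reporting_threshold
  rownames(merged) <- NULL
  merged
}
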