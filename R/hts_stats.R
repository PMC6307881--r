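#' Z-prime (Z') assay-quality factor
#'
#' `z_prime = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|` with sample
#' (n-1) standard deviations. Values above ~0.4 indicate a screenable assay;
#' the statistic is bounded above by 1 and is invariant under adding a
#' constant to all values or jointly rescaling both groups.
#'
#' @param pos_values Percent-ciliated values of the positive-control wells
#'   (>= 2 values).
#' @param neg_values Percent-ciliated values of the negative-reference wells
#'   (>= 2 values).
#' @return The Z' factor (dimensionless, <= 1).
#' @export
z_prime <- function(pos_values, neg_values) {
  if (length(pos_values) < 2L || length(neg_values) < 2L)
    stopf("z_prime requires at least 2 values per control group")
  mu_p <- mean(pos_values); mu_n <- mean(neg_values)
  if (mu_p == mu_n)
    stopf("z_prime undefined: control means are equal (zero dynamic range)")
  1 - 3 * (stats::sd(pos_values) + stats::sd(neg_values)) / abs(mu_p - mu_n)
}

#' Toxicity filter
#'
#' A well is flagged toxic iff its cell count is strictly lower than
#' `toxicity_fraction` (default 0.80) times the mean cell count of the
#' positive-control wells; such wells are excluded from hit calling.
#'
#' @param cell_counts Numeric vector of per-well cell counts.
#' @param positive_control_counts Cell counts of the positive-control wells.
#' @param toxicity_fraction Survival fraction threshold (default 0.80).
#' @return Logical vector, `TRUE` = toxic.
#' @export
toxicity_filter <- function(cell_counts, positive_control_counts,
                            toxicity_fraction = 0.80) {
  if (length(positive_control_counts) < 1L)
    stopf("toxicity filter requires at least one positive-control well")
  cell_counts < toxicity_fraction * mean(positive_control_counts)
}

#' Per-well Z-scores against the negative-reference wells
#'
#' `z = (x - mean_ref) / sd_ref` with the sample SD of the negative-reference
#' (e.g. siVHL + DMSO) percent-ciliated values.
#'
#' @param well_values Numeric vector of per-well percent-ciliated values.
#' @param reference_values Percent-ciliated values of the negative-reference
#'   wells (>= 2 values with nonzero sample SD).
#' @return Numeric vector of Z-scores.
#' @export
z_scores <- function(well_values, reference_values) {
  if (length(reference_values) < 2L)
    stopf("z_scores requires at least 2 reference wells")
  sg <- stats::sd(reference_values)
  if (sg == 0) stopf("z_scores undefined: reference wells have zero SD")
  (well_values - mean(reference_values)) / sg
}

#' Hit calling
#'
#' A well is a hit iff it survived the toxicity filter and its Z-score lies
#' at least `k_sd` standard deviations above the negative-reference mean
#' (one-sided by default: restored ciliation increases the readout). Set
#' `two_sided = TRUE` to call `|z| >= k_sd`.
#'
#' @param z Numeric vector of Z-scores (NA for toxic wells is allowed).
#' @param toxic Logical vector of toxicity flags, aligned with `z`.
#' @param k_sd Hit threshold in SD units (default 3).
#' @param two_sided Call hits on both tails.
#' @return Logical vector, `TRUE` = hit.
#' @export
call_hits <- function(z, toxic, k_sd = 3, two_sided = FALSE) {
  if (length(z) != length(toxic)) stopf("z and toxic must be aligned")
  zz <- if (two_sided) abs(z) else z
  out <- !toxic & !is.na(zz) & zz >= k_sd
  out[is.na(out)] <- FALSE
  out
}

#' Plate-level screen statistics
#'
#' Builds the complete per-plate screen result from a per-well table:
#' Z' from the control wells, the 80%-survival toxicity filter (nucleus-based
#' cell counts against the positive controls), per-well Z-scores against the
#' negative-reference wells (defined only for non-toxic wells), and k-SD hit
#' calls on the compound wells.
#'
#' @param wells Data frame with columns `well`, `treatment`, `role`,
#'   `cell_count`, `ciliated_count`, `percent_ciliated` (one row per
#'   non-empty well; `percent_ciliated` may be NA for wells with no usable
#'   cells, which are excluded from statistics with a warning).
#' @param plate_id Plate identifier carried into the result.
#' @param k_sd Hit threshold in SD units (default 3).
#' @param toxicity_fraction Survival fraction for the toxicity filter.
#' @param two_sided Two-sided hit calling (default one-sided above).
#' @return An object of class `screen_result`: list with `plate_id`,
#'   `z_prime`, the augmented `wells` table (`toxic`, `z_score`, `hit`), and
#'   `controls` (per-role mean/SD/n summary).
#' @export
screen_stats <- function(wells, plate_id = "plate", k_sd = 3,
                         toxicity_fraction = 0.80, two_sided = FALSE) {
  need <- c("well", "role", "cell_count", "percent_ciliated")
  miss <- setdiff(need, names(wells))
  if (length(miss)) stopf("wells table lacks column(s): %s", paste(miss, collapse = ", "))
  wells <- wells[wells$role != "empty", , drop = FALSE]
  if (anyNA(wells$percent_ciliated)) {
    warnf("well(s) %s have undefined percent_ciliated and are excluded from statistics",
          paste(wells$well[is.na(wells$percent_ciliated)], collapse = ", "))
    wells <- wells[!is.na(wells$percent_ciliated), , drop = FALSE]
  }
  pos <- wells[wells$role == "positive_control", , drop = FALSE]
  neg <- wells[wells$role == "negative_reference", , drop = FALSE]
  if (nrow(pos) < 2L || nrow(neg) < 2L)
    stopf("screen statistics require >= 2 positive_control and >= 2 negative_reference wells")
  zp <- z_prime(pos$percent_ciliated, neg$percent_ciliated)
  wells$toxic <- toxicity_filter(wells$cell_count, pos$cell_count, toxicity_fraction)
  z <- z_scores(wells$percent_ciliated, neg$percent_ciliated)
  wells$z_score <- ifelse(wells$toxic, NA_real_, z)
  wells$hit <- call_hits(wells$z_score, wells$toxic, k_sd, two_sided) &
    wells$role == "compound"
  controls <- data.frame(
    role = c("positive_control", "negative_reference"),
    n = c(nrow(pos), nrow(neg)),
    mean_percent = c(mean(pos$percent_ciliated), mean(neg$percent_ciliated)),
    sd_percent = c(stats::sd(pos$percent_ciliated), stats::sd(neg$percent_ciliated)),
    mean_cell_count = c(mean(pos$cell_count), mean(neg$cell_count)))
  structure(list(plate_id = plate_id, z_prime = zp, wells = wells,
                 controls = controls, k_sd = k_sd,
                 toxicity_fraction = toxicity_fraction),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Screen result for plate '%s'\n", x$plate_id))
  cat(sprintf("  wells analyzed : %d\n", nrow(x$wells)))
  cat(sprintf("  Z'             : %.3f\n", x$z_prime))
  cat(sprintf("  toxic wells    : %d\n", sum(x$wells$toxic)))
  cat(sprintf("  hits (>= %g SD): %s\n", x$k_sd,
              if (any(x$wells$hit)) paste(x$wells$well[x$wells$hit], collapse = ", ")
              else "none"))
  invisible(x)
}
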