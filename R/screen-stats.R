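#' Ten-furthest-nuclei sprouting distance (D10)
#'
#' The screen's sprout-length statistic: the mean longitudinal position of
#' the ten sprout-region nuclei furthest from the micro-vessel. With fewer
#' than ten nuclei the mean is over all of them; with none it is 0.
#'
#' @param y Longitudinal positions (µm) of one chip's sprout-region nuclei.
#' @param n Number of furthest nuclei to average (default 10).
#' @return The D10 distance in µm.
#' @export
d10 <- function(y, n = 10L) {
  y <- y[is.finite(y)]
  if (!length(y)) return(0)
  mean(sort(y, decreasing = TRUE)[seq_len(min(n, length(y)))])
}

#' Per-chip D10 from a nuclei table
#'
#' @param nuclei Tibble of nucleus records (`chip_id`, `y_um`, `region`).
#' @return Tibble `chip_id`, `d10_um`, `n_sprout_nuclei`.
#' @export
chip_d10 <- function(nuclei) {
  nuclei |>
    group_by(.data$chip_id) |>
    summarise(d10_um = d10(.data$y_um[.data$region == "sprout"]),
              n_sprout_nuclei = sum(.data$region == "sprout"),
              .groups = "drop")
}

#' Vehicle-control plate statistics
#'
#' Median and raw (unscaled) median absolute deviation of the QC-passing
#' vehicle-control D10 values of each plate. Plates with fewer than
#' `min_vehicle` usable vehicle chips fall back to the batch-pooled vehicle
#' statistics, recorded in the `basis` column.
#'
#' @param measurements Chip-measurement tibble with `plate_id`, `role`,
#'   `d10_um`, `qc_score`.
#' @param min_vehicle Minimum per-plate vehicle count before falling back to
#'   pooled statistics.
#' @param min_qc QC score below which a chip is excluded from the statistics.
#' @param mad_scale Apply the 1.4826 normal-consistency constant to the MAD?
#'   Off by default: the Z* scale counts raw median absolute deviations.
#' @return Tibble `plate_id`, `vehicle_median_d10`, `vehicle_mad_d10`,
#'   `n_vehicle`, `basis` (`"plate"` or `"pooled"`), `degenerate` (TRUE when
#'   the MAD is 0).
#' @export
plate_stats <- function(measurements, min_vehicle = 4L, min_qc = 3L,
                        mad_scale = FALSE) {
  veh <- measurements |>
    filter(.data$role == "vehicle", .data$qc_score >= min_qc)
  if (!nrow(veh)) abort("no QC-passing vehicle-control chips in the batch")
  pooled_median <- stats::median(veh$d10_um)
  pooled_mad <- raw_mad(veh$d10_um, scale = mad_scale)
  pooled_n <- nrow(veh)

  measurements |>
    distinct(.data$plate_id) |>
    left_join(veh |>
                group_by(.data$plate_id) |>
                summarise(m = stats::median(.data$d10_um),
                          s = raw_mad(.data$d10_um, scale = mad_scale),
                          n = dplyr::n(), .groups = "drop"),
              by = "plate_id") |>
    mutate(use_plate = !is.na(.data$n) & .data$n >= min_vehicle,
           vehicle_median_d10 = ifelse(.data$use_plate, .data$m, pooled_median),
           vehicle_mad_d10 = ifelse(.data$use_plate, .data$s, pooled_mad),
           n_vehicle = ifelse(.data$use_plate, .data$n, pooled_n),
           basis = ifelse(.data$use_plate, "plate", "pooled"),
           degenerate = .data$vehicle_mad_d10 <= 0) |>
    select("plate_id", "vehicle_median_d10", "vehicle_mad_d10",
           "n_vehicle", "basis", "degenerate")
}

#' Robust Z* score
#'
#' Number of vehicle median absolute deviations separating a chip's D10 from
#' the vehicle-control median: `(d10 - median) / mad`. Negative values mean
#' sprouting inhibition. Invariant under a common rescaling of all distances.
#'
#' @param d10_um Chip D10 value(s), µm.
#' @param vehicle_median,vehicle_mad Vehicle-control statistics (µm).
#' @return Z* score(s), dimensionless.
#' @export
robust_z <- function(d10_um, vehicle_median, vehicle_mad) {
  if (any(!is.finite(vehicle_mad)) || any(vehicle_mad <= 0)) {
    abort("vehicle MAD must be > 0 (degenerate control spread)")
  }
  (d10_um - vehicle_median) / vehicle_mad
}

#' Inhibition level from a Z* score
#'
#' Maps Z* to the screen's ordinal inhibition classes: none (> -3),
#' mild (-9, -3], moderate (-15, -9], high (<= -15). Boundaries are assigned
#' to the more severe class, consistent with the hit gate requiring
#' Z* strictly below -3.
#'
#' @param z_star Finite Z* score(s).
#' @param breaks Class boundaries (negative, decreasing).
#' @return Ordered factor `none < mild < moderate < high`.
#' @export
classify_inhibition <- function(z_star, breaks = c(-3, -9, -15)) {
  if (any(!is.finite(z_star))) abort("`z_star` must be finite")
  lv <- c("none", "mild", "moderate", "high")
  # right-closed intervals (-Inf,-15], (-15,-9], (-9,-3], (-3,Inf):
  # a score exactly on a boundary takes the more severe class
  out <- cut(z_star, breaks = c(-Inf, sort(breaks), Inf),
             labels = rev(lv), right = TRUE)
  factor(as.character(out), levels = lv, ordered = TRUE)
}

#' Z-prime assay quality factor
#'
#' `1 - 3 * (sd_a + sd_b) / |mean_a - mean_b|` between two control groups;
#' 1 in the zero-spread limit, smaller as the groups' spreads grow relative
#' to their separation. Symmetric in the two groups.
#'
#' @param group_a,group_b Numeric vectors (n >= 2 each) of the two control
#'   groups' D10 values.
#' @return Z-prime, dimensionless (<= 1).
#' @export
z_prime <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("both control groups need at least 2 chips")
  }
  mu_a <- mean(group_a); mu_b <- mean(group_b)
  if (mu_a == mu_b) abort("control means are equal; separation undefined")
  1 - 3 * (stats::sd(group_a) + stats::sd(group_b)) / abs(mu_a - mu_b)
}

#' Coefficient of variation, percent
#'
#' @param x Numeric vector (n >= 2, positive mean).
#' @return `100 * sd(x) / mean(x)`.
#' @export
control_cv <- function(x) {
  if (length(x) < 2L) abort("need at least 2 values")
  m <- mean(x)
  if (m <= 0) abort("CV undefined for non-positive mean")
  100 * stats::sd(x) / m
}

#' Spearman correlation between screen replicates
#'
#' @param rep1,rep2 Paired per-compound scores (e.g. Z* of replicate 1 and
#'   2). Pairs with a missing member are dropped and counted.
#' @return A one-row tibble: `spearman`, `n_pairs`, `n_dropped`.
#' @export
replicate_spearman <- function(rep1, rep2) {
  if (length(rep1) != length(rep2)) abort("replicate vectors differ in length")
  ok <- is.finite(rep1) & is.finite(rep2)
  if (sum(ok) < 3L) abort("need at least 3 complete replicate pairs")
  tibble(spearman = stats::cor(rep1[ok], rep2[ok], method = "spearman"),
         n_pairs = sum(ok), n_dropped = sum(!ok))
}

#' Replicate concordance of ordinal integrity scores
#'
#' @param score1,score2 Paired ordinal scores (1-4) of the two replicates.
#' @return One-row tibble with the percentage of pairs that are identical
#'   (`same_pct`), adjacent (`adjacent_pct`, |difference| = 1), and discordant
#'   (`discordant_pct`, |difference| >= 2); the three sum to 100.
#' @export
integrity_concordance <- function(score1, score2) {
  ok <- is.finite(score1) & is.finite(score2)
  d <- abs(score1[ok] - score2[ok])
  n <- length(d)
  if (!n) return(tibble(same_pct = NA_real_, adjacent_pct = NA_real_,
                        discordant_pct = NA_real_, n_pairs = 0L))
  tibble(same_pct = 100 * sum(d == 0) / n,
         adjacent_pct = 100 * sum(d == 1) / n,
         discordant_pct = 100 * sum(d >= 2) / n,
         n_pairs = n)
}

#' Score every chip of a screen
#'
#' Joins per-chip D10 measurements with their plate's vehicle statistics and
#' computes Z* scores and inhibition classes. Chips failing QC receive
#' scores but are flagged excluded and do not contribute to any control
#' statistic.
#'
#' @param measurements Tibble with `chip_id`, `plate_id`, `role`,
#'   `compound_id`, `replicate`, `d10_um`, `qc_score`, `integrity_score` (and
#'   optionally `vessel_nuclei_count`).
#' @param min_vehicle,min_qc,mad_scale Passed to [plate_stats()].
#' @return The input with `z_star`, `inhibition_level`, `qc_excluded`, and
#'   the plate-statistics columns appended.
#' @export
score_chips <- function(measurements, min_vehicle = 4L, min_qc = 3L,
                        mad_scale = FALSE) {
  ps <- plate_stats(measurements, min_vehicle = min_vehicle, min_qc = min_qc,
                    mad_scale = mad_scale)
  if (any(ps$degenerate)) {
    abort(sprintf("degenerate vehicle spread (MAD = 0) on plate(s): %s",
                  paste(ps$plate_id[ps$degenerate], collapse = ", ")))
  }
  measurements |>
    left_join(ps, by = "plate_id") |>
    mutate(z_star = robust_z(.data$d10_um, .data$vehicle_median_d10,
                             .data$vehicle_mad_d10),
           inhibition_level = classify_inhibition(.data$z_star),
           qc_excluded = .data$qc_score < min_qc)
}
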