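#' Hit-selection criteria
#'
#' The three per-chip gates of the hit-calling procedure: a pre-exposure QC
#' gate on micro-vessel formation, a vessel-integrity (toxicity) gate on the
#' post-assay actin network score, and an efficacy gate on the Z* score.
#'
#' @param min_qc Minimum QC score (chips scoring below are excluded).
#' @param min_integrity Minimum integrity score (failing chips mark the
#'   compound vessel-toxic).
#' @param z_star_cutoff Efficacy cutoff; a chip passes with Z* strictly below
#'   it.
#' @param agreement_mode `"both_replicates_pass"` (default: each replicate
#'   must pass all three gates) or `"mean_z_with_both_gates"` (both
#'   replicates must pass QC and integrity; efficacy is judged on the mean
#'   Z* of the duplicate).
#' @return A list of class `hit_criteria`.
#' @export
hit_criteria <- function(min_qc = 3L, min_integrity = 3L, z_star_cutoff = -3,
                         agreement_mode = c("both_replicates_pass",
                                            "mean_z_with_both_gates")) {
  if (z_star_cutoff >= 0) abort("`z_star_cutoff` must be negative")
  if (!min_qc %in% 1:4 || !min_integrity %in% 1:4) {
    abort("ordinal gates must be in 1..4")
  }
  structure(list(min_qc = as.integer(min_qc),
                 min_integrity = as.integer(min_integrity),
                 z_star_cutoff = z_star_cutoff,
                 agreement_mode = match.arg(agreement_mode)),
            class = "hit_criteria")
}

#' Per-chip gate flags
#'
#' @param scored Scored chip tibble from [score_chips()] (needs `qc_score`,
#'   `integrity_score`, `z_star`).
#' @param criteria A [hit_criteria()].
#' @return The input with logical `qc_pass`, `integrity_pass`,
#'   `efficacy_pass` columns appended.
#' @export
gate_chips <- function(scored, criteria = hit_criteria()) {
  need <- c("qc_score", "integrity_score", "z_star")
  miss <- setdiff(need, names(scored))
  if (length(miss)) abort(sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  if (anyNA(scored[need])) abort("missing scores: every chip needs QC, integrity and Z*")
  scored |>
    mutate(qc_pass = .data$qc_score >= criteria$min_qc,
           integrity_pass = .data$integrity_score >= criteria$min_integrity,
           efficacy_pass = .data$z_star < criteria$z_star_cutoff)
}

#' Compound-level verdicts from duplicate chips
#'
#' Collapses the gated duplicate chips of every compound to a single verdict:
#' * `qc_excluded` - both replicates failed the QC gate;
#' * `toxic_excluded` - any QC-passing replicate failed the integrity gate
#'   (vessel toxicity dominates: a compound harming the vessel in either
#'   replicate cannot be a hit);
#' * `hit` - both replicates passed QC and integrity, and the efficacy rule
#'   of the agreement mode is met; requires two QC-passing replicates;
#' * `non_hit` - everything else, including compounds with a single
#'   QC-passing replicate (flagged `single_replicate`, no duplicate agreement
#'   possible).
#'
#' @param gated Output of [gate_chips()] (sample chips; controls are
#'   ignored).
#' @param criteria A [hit_criteria()].
#' @return One row per compound: `compound_id`, `verdict`, per-replicate
#'   evidence (`z_star_rep1/2`, `qc_rep1/2`, `integrity_rep1/2`), `z_star_mean`
#'   over QC-passing replicates, and `single_replicate`.
#' @export
call_compounds <- function(gated, criteria = hit_criteria()) {
  samples <- gated |>
    filter(.data$role == "sample", !is.na(.data$compound_id))
  too_many <- samples |> count(.data$compound_id) |> filter(.data$n > 2L)
  if (nrow(too_many)) {
    abort(sprintf("more than 2 replicate chips for: %s",
                  paste(too_many$compound_id, collapse = ", ")))
  }
  samples |>
    arrange(.data$compound_id, .data$replicate) |>
    group_by(.data$compound_id) |>
    summarise(
      z_star_rep1 = .data$z_star[match(1L, .data$replicate)],
      z_star_rep2 = .data$z_star[match(2L, .data$replicate)],
      qc_rep1 = .data$qc_score[match(1L, .data$replicate)],
      qc_rep2 = .data$qc_score[match(2L, .data$replicate)],
      integrity_rep1 = .data$integrity_score[match(1L, .data$replicate)],
      integrity_rep2 = .data$integrity_score[match(2L, .data$replicate)],
      n_qc_pass = sum(.data$qc_pass),
      any_toxic = any(.data$qc_pass & !.data$integrity_pass),
      all_integrity = all(.data$integrity_pass[.data$qc_pass]),
      all_efficacy = all(.data$efficacy_pass),
      z_star_mean = mean(.data$z_star[.data$qc_pass]),
      n_chips = dplyr::n(),
      .groups = "drop") |>
    mutate(
      efficacy_met = if (criteria$agreement_mode == "both_replicates_pass") {
        .data$all_efficacy
      } else {
        .data$z_star_mean < criteria$z_star_cutoff
      },
      verdict = dplyr::case_when(
        n_qc_pass == 0L ~ "qc_excluded",
        any_toxic ~ "toxic_excluded",
        n_qc_pass == 2L & n_chips == 2L & all_integrity & efficacy_met ~ "hit",
        TRUE ~ "non_hit"),
      single_replicate = .data$n_qc_pass == 1L | .data$n_chips == 1L) |>
    select("compound_id", "verdict", dplyr::starts_with("z_star_rep"),
           dplyr::starts_with("qc_rep"), dplyr::starts_with("integrity_rep"),
           "z_star_mean", "single_replicate")
}

#' Screen-level summary tables
#'
#' @param calls Compound calls from [call_compounds()].
#' @param scored Scored chip tibble from [score_chips()] (optional; enables
#'   the inhibition-level, integrity and per-plate QC summaries).
#' @return Named list of tibbles: `verdicts` (count and percent per verdict;
#'   counts partition the library), and when `scored` is given `inhibition`
#'   (chips per inhibition level), `integrity` (chips per integrity score)
#'   and `plates` (per-plate chip counts and QC pass rate).
#' @export
summarize_screen <- function(calls, scored = NULL) {
  verdict_levels <- c("hit", "non_hit", "toxic_excluded", "qc_excluded")
  n_lib <- nrow(calls)
  verdicts <- tibble(verdict = verdict_levels) |>
    left_join(calls |> count(.data$verdict), by = "verdict") |>
    mutate(n = tidyr::replace_na(.data$n, 0L),
           percent = if (n_lib) 100 * .data$n / n_lib else 0)
  out <- list(verdicts = verdicts)
  if (!is.null(scored)) {
    out$inhibition <- scored |>
      filter(!.data$qc_excluded) |>
      count(.data$role, .data$inhibition_level, .drop = FALSE)
    out$integrity <- scored |>
      filter(!.data$qc_excluded) |>
      count(.data$integrity_score)
    out$plates <- scored |>
      group_by(.data$plate_id) |>
      summarise(n_chips = dplyr::n(),
                n_qc_excluded = sum(.data$qc_excluded),
                qc_pass_rate = 1 - mean(.data$qc_excluded),
                .groups = "drop")
  }
  out
}
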