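#' Canonicalize a pathway set
#'
#' Splits a semicolon-separated pathway annotation, trims, deduplicates,
#' sorts, and rejoins, so that set-equal annotations map to an identical
#' label regardless of input order.
#'
#' @param pathways Character vector of annotations (`"Wnt;MAPK/ERK"`).
#' @return Canonical combination labels (`"MAPK/ERK + Wnt"`).
#' @export
canonical_combination <- function(pathways) {
  purrr::map_chr(pathways, function(p) {
    if (is.na(p) || !nzchar(p)) return(NA_character_)
    parts <- sort(unique(stringr::str_trim(strsplit(p, ";", fixed = TRUE)[[1]])))
    paste(parts[nzchar(parts)], collapse = " + ")
  })
}

#' Frequency of unique pathway combinations among hits
#'
#' Counts how many hit compounds share each unique (canonicalized) set of
#' annotated main pathways, with the mean and SD of the hits' Z* scores per
#' combination. Combination frequencies sum to the number of hits.
#'
#' @param hits Tibble with `compound_id` and a per-compound `z_star` (for
#'   screens in duplicate, the mean of the two replicate Z* scores).
#' @param annotations Tibble with `compound_id` and `pathways`
#'   (semicolon-separated labels).
#' @return Tibble ordered by decreasing frequency then label:
#'   `pathway_combination`, `n_hits`, `z_star_mean`, `z_star_sd`.
#' @export
combination_frequency <- function(hits, annotations) {
  joined <- hits |>
    left_join(annotations |> select("compound_id", "pathways"),
              by = "compound_id")
  missing <- joined |>
    filter(is.na(.data$pathways) | !nzchar(.data$pathways))
  if (nrow(missing)) {
    abort(sprintf("unannotated hit compound(s): %s",
                  paste(missing$compound_id, collapse = ", ")))
  }
  joined |>
    mutate(pathway_combination = canonical_combination(.data$pathways)) |>
    group_by(.data$pathway_combination) |>
    summarise(n_hits = dplyr::n(),
              z_star_mean = mean(.data$z_star),
              z_star_sd = stats::sd(.data$z_star),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$n_hits), .data$pathway_combination)
}

#' Per-pathway hit membership
#'
#' For every main pathway, the number of hit compounds whose annotation
#' contains it. A multi-pathway hit counts in each of its pathways, so counts
#' overlap; percentages are relative to the number of hits.
#'
#' @inheritParams combination_frequency
#' @return Tibble `pathway`, `n_hits`, `percent_of_hits`, ordered by
#'   decreasing count then label.
#' @export
pathway_membership <- function(hits, annotations) {
  n_total <- nrow(hits)
  if (!n_total) {
    return(tibble(pathway = character(), n_hits = integer(),
                  percent_of_hits = numeric()))
  }
  hits |>
    left_join(annotations |> select("compound_id", "pathways"),
              by = "compound_id") |>
    mutate(pathway = purrr::map(.data$pathways, function(p) {
      unique(stringr::str_trim(strsplit(p %||% "", ";", fixed = TRUE)[[1]]))
    })) |>
    tidyr::unnest("pathway") |>
    filter(nzchar(.data$pathway)) |>
    count(.data$pathway, name = "n_hits") |>
    mutate(percent_of_hits = 100 * .data$n_hits / n_total) |>
    arrange(dplyr::desc(.data$n_hits), .data$pathway)
}

#' Combinations shared by multiple hits
#'
#' @param summaries Output of [combination_frequency()].
#' @param min_hits Minimum number of hits per combination (default 2).
#' @return The filtered summaries, order preserved (frequency, then label).
#' @export
multi_hit_combinations <- function(summaries, min_hits = 2L) {
  summaries |> filter(.data$n_hits >= min_hits)
}
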