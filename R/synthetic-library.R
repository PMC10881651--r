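#' Default main-pathway vocabulary for synthetic compound libraries
#'
#' Fifteen main-pathway labels used to annotate simulated kinase-inhibitor
#' libraries. The first six are pathways commonly reported for
#' anti-angiogenic kinase inhibitors; the rest complete a vendor-style
#' controlled vocabulary.
#'
#' @return Character vector of 15 pathway labels.
#' @export
default_pathways <- function() {
  c("MAPK/ERK", "Wnt", "PI3K/Akt/mTOR", "Cell Cycle/DNA Damage",
    "Apoptosis", "Autophagy", "JAK/STAT", "Protein Tyrosine Kinase/RTK",
    "Angiogenesis", "TGF-beta/Smad", "Hedgehog", "Notch", "NF-kB",
    "Cytoskeletal Signaling", "Metabolism")
}

#' Simulate an annotated compound library with planted effects
#'
#' Each compound carries a ground-truth inhibition effect (a fraction in
#' \[0, 1\] multiplying the vehicle sprouting distance: 1 = inactive,
#' 0 = full inhibition), an ordinal toxicity class 1-4 governing the
#' micro-vessel integrity score (class 1 = benign, 4 = strongly toxic), and a
#' set of annotated main pathways.
#'
#' The default effect mixture plants a small fraction of strong inhibitors
#' over a mostly inactive library, and half the library carries vessel
#' toxicity, mirroring the composition reported for large kinase-inhibitor
#' screens where roughly half the library is excluded on vessel-toxicity
#' grounds and a few percent end up as hits.
#'
#' @param n_compounds Number of compounds.
#' @param seed Integer seed; the library is a pure function of
#'   `(arguments, seed)`.
#' @param p_strong,p_moderate Mixture weights for strong (effect uniform on
#'   \[0, 0.2\]) and moderate (effect uniform on \[0.3, 0.8\]) inhibitors; the
#'   remainder is near-inactive (effect uniform on \[0.9, 1\]).
#' @param toxicity_probs Probabilities of toxicity classes 1-4.
#' @param pathways Controlled vocabulary to draw annotations from.
#' @param max_pathways Maximum number of main pathways per compound.
#'
#' @return A tibble with columns `compound_id`, `inhibition_effect`,
#'   `toxicity_class`, `pathways` (semicolon-separated labels).
#' @export
simulate_library <- function(n_compounds, seed = 1L,
                             p_strong = 0.08, p_moderate = 0.12,
                             toxicity_probs = c(0.30, 0.20, 0.25, 0.25),
                             pathways = default_pathways(),
                             max_pathways = 3L) {
  stopifnot_scalar_number(n_compounds, "n_compounds", positive = TRUE)
  if (p_strong + p_moderate > 1) abort("effect mixture weights exceed 1")
  if (length(toxicity_probs) != 4L || any(toxicity_probs < 0)) {
    abort("`toxicity_probs` must be 4 non-negative probabilities")
  }
  with_seed(derive_seed(seed, "library"), {
    class_draw <- sample(c("strong", "moderate", "inactive"), n_compounds,
                         replace = TRUE,
                         prob = c(p_strong, p_moderate, 1 - p_strong - p_moderate))
    effect <- dplyr::case_when(
      class_draw == "strong"   ~ stats::runif(n_compounds, 0, 0.2),
      class_draw == "moderate" ~ stats::runif(n_compounds, 0.3, 0.8),
      TRUE                     ~ stats::runif(n_compounds, 0.9, 1.0))
    tox <- sample(1:4, n_compounds, replace = TRUE,
                  prob = toxicity_probs / sum(toxicity_probs))
    pw <- purrr::map_chr(seq_len(n_compounds), function(i) {
      k <- sample(seq_len(max_pathways), 1L)
      paste(sort(sample(pathways, k)), collapse = ";")
    })
    tibble(compound_id = sprintf("C%04d", seq_len(n_compounds)),
           inhibition_effect = effect,
           toxicity_class = as.integer(tox),
           pathways = pw)
  })
}

#' Generate duplicate-replicate plate layouts
#'
#' Lays a compound library out over 64-chip plates. Every plate carries
#' exactly 8 vehicle-control, 4 strong-inhibition (sunitinib-like) control,
#' and 4 unstimulated-control chips at seeded random positions; the remaining
#' 48 chips are sample slots. Each compound occupies exactly two sample chips
#' and the two replicates land on different plates whenever more than one
#' plate is available.
#'
#' @param n_plates Number of 64-chip plates.
#' @param n_compounds Number of compounds (each screened in duplicate).
#' @param seed Integer seed.
#' @return A tibble with one row per chip: `plate_id`, `chip_id`, `position`
#'   (1-64 within plate), `role` (`vehicle`, `sunitinib_control`,
#'   `unstimulated`, `sample`), `compound_id` (`NA` for controls and unused
#'   sample slots), `replicate` (1/2 for samples).
#' @export
generate_layout <- function(n_plates, n_compounds, seed = 1L) {
  stopifnot_scalar_number(n_plates, "n_plates", positive = TRUE)
  stopifnot_scalar_number(n_compounds, "n_compounds", positive = TRUE)
  capacity <- n_plates * 48L
  if (2L * n_compounds > capacity) {
    abort(sprintf(paste0(
      "%d compounds in duplicate need %d sample chips but %d plate(s) ",
      "provide only %d; at least %d plates are required."),
      n_compounds, 2L * n_compounds, n_plates, capacity,
      ceiling(2 * n_compounds / 48)))
  }
  roles_per_plate <- c(rep("vehicle", 8), rep("sunitinib_control", 4),
                       rep("unstimulated", 4), rep("sample", 48))

  plates <- purrr::map(seq_len(n_plates), function(p) {
    pos_roles <- with_seed(derive_seed(seed, "layout", p), sample(roles_per_plate))
    tibble(plate_id = sprintf("P%02d", p),
           position = seq_len(64L),
           role = pos_roles)
  }) |> purrr::list_rbind()
  plates$chip_id <- sprintf("%s_c%02d", plates$plate_id, plates$position)

  # Replicate 1 fills plates in order 1..n; replicate 2 walks the rotated
  # order 2..n,1 over the slots replicate 1 left free, so a compound's two
  # chips land on different plates whenever capacity allows.
  sample_slots <- plates |> filter(.data$role == "sample")
  order1 <- seq_len(n_plates)
  order2 <- if (n_plates > 1) c(order1[-1], order1[1]) else order1
  slot_seq <- function(plate_order) {
    unlist(lapply(plate_order, function(p) {
      which(sample_slots$plate_id == sprintf("P%02d", p))
    }))
  }
  ids <- sprintf("C%04d", seq_len(n_compounds))
  slots1 <- slot_seq(order1)[seq_len(n_compounds)]
  slots2 <- setdiff(slot_seq(order2), slots1)[seq_len(n_compounds)]
  assign <- tibble(
    slot = c(slots1, slots2),
    compound_id = rep(ids, 2L),
    replicate = rep(1:2, each = n_compounds))
  plates$compound_id <- NA_character_
  plates$replicate <- NA_integer_
  idx <- match(sample_slots$chip_id[assign$slot], plates$chip_id)
  plates$compound_id[idx] <- assign$compound_id
  plates$replicate[idx] <- assign$replicate
  plates |> select("plate_id", "chip_id", "position", "role",
                   "compound_id", "replicate")
}
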