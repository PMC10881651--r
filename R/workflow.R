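#' Screen run configuration
#'
#' Bundles every parameter of an end-to-end synthetic screen run. All
#' randomness in a run derives from the single top-level `seed`, with
#' per-stage and per-chip substreams, so a config reproduces its outputs
#' byte-identically. The config round-trips losslessly through YAML
#' ([write_config()] / [read_config()]).
#'
#' @param seed Top-level integer seed.
#' @param n_plates,n_compounds Screen size (compounds are run in duplicate).
#' @param geometry A [chip_geometry()] or its argument list.
#' @param phenotype A [phenotype_params()] or its argument list.
#' @param render A [render_params()] or its argument list.
#' @param detection A [detection_params()] or its argument list.
#' @param criteria A [hit_criteria()] or its argument list.
#' @param library_args Extra arguments to [simulate_library()].
#' @param render_images Render and detect nuclei images (`TRUE`) or run the
#'   measurement-level pipeline directly on ground-truth nucleus positions
#'   (`FALSE`, the default for large screens).
#' @param write_tiff Also write per-chip TIFF rasters (only with
#'   `render_images = TRUE`).
#' @param min_vehicle,mad_scale Normalization scope, see [plate_stats()].
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(seed = 1L, n_plates = 1L, n_compounds = 24L,
                          geometry = list(), phenotype = list(),
                          render = list(), detection = list(),
                          criteria = list(), library_args = list(),
                          render_images = FALSE, write_tiff = FALSE,
                          min_vehicle = 4L, mad_scale = FALSE) {
  as_args <- function(x, cls) if (inherits(x, cls)) unclass(x) else x
  cfg <- list(seed = as.integer(seed),
              n_plates = as.integer(n_plates),
              n_compounds = as.integer(n_compounds),
              geometry = as_args(geometry, "chip_geometry"),
              phenotype = phenotype,
              render = render,
              detection = as_args(detection, "detection_params"),
              criteria = as_args(criteria, "hit_criteria"),
              library_args = library_args,
              render_images = isTRUE(render_images),
              write_tiff = isTRUE(write_tiff),
              min_vehicle = as.integer(min_vehicle),
              mad_scale = isTRUE(mad_scale))
  structure(cfg, class = "screen_config")
}

#' @rdname screen_config
#' @param config A `screen_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname screen_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(screen_config, raw)
}

build_geometry <- function(config) {
  g <- config$geometry
  g <- g[setdiff(names(g), c("y_min", "y_max", "image_shape"))]
  do.call(chip_geometry, g)
}

#' Run a full synthetic screen
#'
#' Executes the whole pipeline: simulate the compound library, plate layout
#' and chip phenotypes; (optionally) render each chip's nuclei image and
#' detect nuclei; compute D10, Z* and inhibition classes; call hits with the
#' duplicate-agreement procedure; and summarise pathways over the hits.
#' Writes `library.csv`, `layout.csv`, `truth.csv`, `nuclei.csv`,
#' `chip_scores.csv`, `plate_report.csv`, `compound_calls.csv`,
#' `screen_summary.csv`, `pathway_combinations.csv`,
#' `pathway_membership.csv`, and a `manifest.json` capturing the config and
#' package version. Re-running the same config reproduces byte-identical
#' CSVs.
#'
#' @param config A [screen_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @return Invisibly, a list with every intermediate table (`library`,
#'   `layout`, `truth`, `nuclei`, `scores`, `plate_report`, `calls`,
#'   `summary`, `pathway_combinations`, `pathway_membership`, `out_dir`).
#' @export
run_screen <- function(config = screen_config(), out_dir = NULL) {
  geometry <- build_geometry(config)
  phen_par <- do.call(phenotype_params, config$phenotype)
  rend_par <- do.call(render_params, config$render)
  det_par <- do.call(detection_params,
                     c(config$detection,
                       if (!length(config$detection)) {
                         list(nucleus_diameter = rend_par$nucleus_diameter,
                              pixel_size = geometry$pixel_size)
                       }))
  criteria <- do.call(hit_criteria, config$criteria)

  library <- do.call(simulate_library,
                     c(list(n_compounds = config$n_compounds, seed = config$seed),
                       config$library_args))
  layout <- generate_layout(config$n_plates, config$n_compounds, config$seed)
  truth <- simulate_phenotypes(layout, library, geometry, phen_par, config$seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (config$write_tiff) {
      dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
    }
  }

  # --- nuclei table: detected from rendered images, or ground truth --------
  if (config$render_images) {
    nuclei <- purrr::map(seq_len(nrow(truth)), function(i) {
      ph <- list(nuclei = truth$nuclei[[i]])
      img <- render_image(ph, geometry, rend_par,
                          seed = derive_seed(config$seed, "render",
                                             truth$chip_id[i]))
      if (!is.null(out_dir) && config$write_tiff) {
        write_chip_tiff(img, file.path(out_dir, "images",
                                       paste0(truth$chip_id[i], ".tiff")))
      }
      detect_nuclei(img, det_par) |>
        mutate(chip_id = truth$chip_id[i], .before = 1)
    }) |> purrr::list_rbind()
  } else {
    nuclei <- truth |>
      select("chip_id", "nuclei") |>
      tidyr::unnest("nuclei") |>
      mutate(area_um2 = NA_real_) |>
      select("chip_id", "x_um", "y_um", "area_um2", "region")
  }

  measurements <- truth |>
    select("chip_id", "plate_id", "position", "role", "compound_id",
           "replicate", "true_d10", "qc_score", "integrity_score",
           "vessel_nuclei_count") |>
    left_join(chip_d10(nuclei), by = "chip_id") |>
    mutate(d10_um = tidyr::replace_na(.data$d10_um, 0),
           n_sprout_nuclei = tidyr::replace_na(.data$n_sprout_nuclei, 0L))

  # degenerate screens (e.g. a QC-failure rate of 1) have no usable vehicle
  # controls: nothing can be scored and every compound is QC-excluded
  usable_vehicle <- any(measurements$role == "vehicle" &
                          measurements$qc_score >= criteria$min_qc)
  if (!usable_vehicle) {
    calls <- measurements |>
      filter(.data$role == "sample", !is.na(.data$compound_id)) |>
      distinct(.data$compound_id) |>
      mutate(verdict = "qc_excluded", z_star_rep1 = NA_real_,
             z_star_rep2 = NA_real_, z_star_mean = NA_real_,
             single_replicate = FALSE)
    empty_res <- list(library = library, layout = layout,
                      truth = truth |> select(-"nuclei"),
                      nuclei = nuclei, scores = measurements[0, ],
                      plate_report = tibble(), calls = calls,
                      summary = summarize_screen(calls),
                      pathway_combinations = tibble(), pathway_membership = tibble(),
                      empty = TRUE, out_dir = out_dir)
    if (!is.null(out_dir)) {
      readr::write_csv(calls, file.path(out_dir, "compound_calls.csv"))
      readr::write_csv(empty_res$summary$verdicts,
                       file.path(out_dir, "screen_summary.csv"))
    }
    return(invisible(empty_res))
  }

  scores <- score_chips(measurements, min_vehicle = config$min_vehicle,
                        mad_scale = config$mad_scale)
  plate_report <- screen_plate_report(scores)
  gated <- gate_chips(scores, criteria)
  calls <- call_compounds(gated, criteria)
  summary <- summarize_screen(calls, scores)

  hits <- calls |>
    filter(.data$verdict == "hit") |>
    transmute(.data$compound_id, z_star = .data$z_star_mean)
  pw_comb <- if (nrow(hits)) combination_frequency(hits, library) else
    tibble(pathway_combination = character(), n_hits = integer(),
           z_star_mean = numeric(), z_star_sd = numeric())
  pw_mem <- pathway_membership(hits, library)

  result <- list(library = library, layout = layout,
                 truth = truth |> select(-"nuclei"),
                 nuclei = nuclei, scores = scores,
                 plate_report = plate_report, calls = calls,
                 summary = summary,
                 pathway_combinations = pw_comb,
                 pathway_membership = pw_mem,
                 out_dir = out_dir)

  if (!is.null(out_dir)) {
    wr <- function(x, f) readr::write_csv(x, file.path(out_dir, f))
    wr(library, "library.csv")
    wr(layout, "layout.csv")
    wr(result$truth, "truth.csv")
    wr(nuclei, "nuclei.csv")
    wr(scores |> mutate(inhibition_level = as.character(.data$inhibition_level)),
       "chip_scores.csv")
    wr(plate_report, "plate_report.csv")
    wr(calls, "compound_calls.csv")
    wr(summary$verdicts, "screen_summary.csv")
    wr(pw_comb, "pathway_combinations.csv")
    wr(pw_mem, "pathway_membership.csv")
    manifest <- list(package = "sproutscreen",
                     version = as.character(utils::packageVersion("sproutscreen")),
                     config = unclass(config))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(result)
}

#' Per-plate quality report
#'
#' @param scores Scored chips from [score_chips()].
#' @return Tibble with per-plate vehicle statistics, control CVs, Z-prime
#'   factors for both control pairs, and exclusion counts.
#' @export
screen_plate_report <- function(scores) {
  scores |>
    group_by(.data$plate_id) |>
    summarise(
      vehicle_median_d10 = .data$vehicle_median_d10[1],
      vehicle_mad_d10 = .data$vehicle_mad_d10[1],
      n_vehicle = .data$n_vehicle[1],
      basis = .data$basis[1],
      vehicle_cv_pct = safe_cv(.data$d10_um[.data$role == "vehicle" & !.data$qc_excluded]),
      unstimulated_cv_pct = safe_cv(.data$d10_um[.data$role == "unstimulated" & !.data$qc_excluded]),
      z_prime_vehicle_sunitinib = safe_zprime(
        .data$d10_um[.data$role == "vehicle" & !.data$qc_excluded],
        .data$d10_um[.data$role == "sunitinib_control" & !.data$qc_excluded]),
      z_prime_vehicle_unstimulated = safe_zprime(
        .data$d10_um[.data$role == "vehicle" & !.data$qc_excluded],
        .data$d10_um[.data$role == "unstimulated" & !.data$qc_excluded]),
      n_excluded = sum(.data$qc_excluded),
      .groups = "drop")
}

safe_cv <- function(x) if (length(x) >= 2 && mean(x) > 0) control_cv(x) else NA_real_
safe_zprime <- function(a, b) {
  if (length(a) >= 2 && length(b) >= 2 && mean(a) != mean(b)) z_prime(a, b) else NA_real_
}
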