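#' Detection-fidelity benchmark on rendered synthetic chips
#'
#' Renders a set of synthetic chips spanning a range of nuclei densities,
#' runs the full detection pipeline on each, and scores detections against
#' the generator's ground truth: greedy bipartite matching within a pixel
#' radius for F1, and the ten-furthest-nuclei distance computed from
#' detections versus from ground-truth positions.
#'
#' Chip densities are drawn per chip (seeded) so total nuclei counts span
#' roughly `n_range`; rendering uses default noise unless overridden.
#'
#' @param n_chips Number of chips to render.
#' @param seed Integer seed; the benchmark is fully reproducible.
#' @param geometry A [chip_geometry()].
#' @param render A [render_params()].
#' @param detection A [detection_params()].
#' @param match_radius_px Matching radius for truth/detection pairing, pixels.
#' @param n_range Approximate range of total nuclei per chip.
#' @return A tibble with one row per chip: `chip`, `n_truth`, `n_detected`,
#'   `f1`, `d10_true`, `d10_detected`, `d10_error`.
#' @export
detection_benchmark <- function(n_chips = 50, seed = 1L,
                                geometry = chip_geometry(),
                                render = render_params(),
                                detection = detection_params(),
                                match_radius_px = 2,
                                n_range = c(20, 150)) {
  purrr::map(seq_len(n_chips), function(i) {
    s <- derive_seed(seed, "bench", i)
    dens <- with_seed(s, {
      # expected counts spanning the target density range (vessel band plus
      # sprout region, the latter scaling with the drawn sprouting distance)
      list(vessel = stats::runif(1, 0.9 * n_range[1], 0.6 * n_range[2]),
           sprout = stats::runif(1, 0.6 * n_range[1], 0.36 * n_range[2]))
    })
    pp <- phenotype_params(vessel_nuclei_mean = dens$vessel,
                           sprout_nuclei_base = dens$sprout)
    ph <- sample_phenotype("vehicle", geometry, pp, seed = s + 1L)
    img <- render_image(ph, geometry, render, seed = s + 2L)
    det <- detect_nuclei(img, detection)
    m <- match_nuclei(img$truth, det,
                      radius_um = match_radius_px * geometry$pixel_size)
    d10_true <- d10(img$truth$y_um[img$truth$region == "sprout"])
    d10_det <- d10(det$y_um[det$region == "sprout"])
    tibble(chip = i, n_truth = m$n_truth, n_detected = m$n_detected,
           tp = m$tp, fp = m$fp, fn = m$fn, f1 = m$f1,
           d10_true = d10_true, d10_detected = d10_det,
           d10_error = abs(d10_det - d10_true))
  }) |> purrr::list_rbind()
}
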