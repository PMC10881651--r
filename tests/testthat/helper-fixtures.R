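# Small in-code fixtures shared across test files.

# a compact calibrated geometry for fast image tests: `rows` x `cols` pixels
# at 1 um/px, sprout region starting at y = 0 (row 4)
small_geometry <- function(rows = 60, cols = 60, pixel_size = 1) {
  chip_geometry(channel_width = cols * pixel_size,
                phaseguide_width = 1, vessel_band_depth = 2, margin = 1,
                x_margin = 0,
                sprout_region_depth = (rows - 4) * pixel_size,
                pixel_size = pixel_size)
}

# draw hard discs of value `value` on a zero background
disc_image <- function(rows, cols, centers, radius, value = 1, background = 0) {
  img <- matrix(background, rows, cols)
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(rows) - centers[i, 1])^2,
                (seq_len(cols) - centers[i, 2])^2, "+")
    img[d2 <= radius^2] <- value
  }
  img
}

# gaussian blob image (matrix indexed [row, col], blob centered at r0, c0)
blob_image <- function(rows, cols, r0, c0, sigma, peak = 100, background = 0) {
  outer(seq_len(rows), seq_len(cols), function(r, c) {
    background + peak * exp(-((r - r0)^2 + (c - c0)^2) / (2 * sigma^2))
  })
}

# a minimal scored-chips tibble for hit-calling tests: one compound in
# duplicate with the given scores, plus enough vehicle context
scored_pair <- function(qc, integrity, z) {
  tibble::tibble(
    chip_id = c("a", "b"), plate_id = "P01", role = "sample",
    compound_id = "C0001", replicate = 1:2,
    d10_um = 100, qc_score = qc, integrity_score = integrity, z_star = z,
    inhibition_level = classify_inhibition(z), qc_excluded = qc < 3)
}
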