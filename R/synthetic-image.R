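#' Default rendering parameters for synthetic chip images
#'
#' @param nucleus_diameter Apparent nucleus diameter in µm; nuclei are drawn
#'   as isotropic Gaussian blobs with `sigma = diameter / 4`.
#' @param diameter_jitter Relative SD of per-nucleus size jitter.
#' @param peak_intensity Peak signal of one nucleus, in counts.
#' @param background Flat background level, counts.
#' @param gradient_amplitude Amplitude of a linear illumination gradient along
#'   the chip (counts, from one image edge to the other).
#' @param poisson_noise Apply Poisson (shot) noise to the expected counts?
#' @param read_noise_sd SD of additive Gaussian read noise, counts.
#' @return Named list of rendering parameters.
#' @export
render_params <- function(nucleus_diameter = 10, diameter_jitter = 0.1,
                          peak_intensity = 400, background = 100,
                          gradient_amplitude = 30, poisson_noise = TRUE,
                          read_noise_sd = 5) {
  as.list(environment())
}

#' Render a chip phenotype into a nuclei-channel raster
#'
#' Draws every ground-truth nucleus as a smooth Gaussian blob at its chip
#' position over a background with an optional linear illumination gradient,
#' then applies Poisson shot noise and Gaussian read noise. The raster is a
#' pure function of `(phenotype, geometry, params, seed)`.
#'
#' @param phenotype A `chip_phenotype` from [sample_phenotype()], or any list
#'   with a `nuclei` tibble (`x_um`, `y_um`, `region`).
#' @param geometry A [chip_geometry()].
#' @param params A [render_params()].
#' @param seed Integer seed for the noise draws.
#' @return A list of class `chip_image`: `pixels` (rows x cols matrix of
#'   counts), `pixel_size`, `geometry`, and `truth`, the ground-truth nucleus
#'   table with both µm and pixel coordinates.
#' @export
render_image <- function(phenotype, geometry = chip_geometry(),
                         params = render_params(), seed = 1L) {
  nuc <- phenotype$nuclei
  shape <- geometry$image_shape
  nr <- shape[["rows"]]; nc <- shape[["cols"]]
  if (nrow(nuc)) {
    px <- um_to_pixel(nuc$x_um, nuc$y_um, geometry)
    if (any(px$row < 1 | px$row > nr | px$col < 1 | px$col > nc)) {
      abort("nuclei fall outside the image bounds; enlarge the geometry")
    }
  }
  with_seed(seed, {
    ramp <- (seq_len(nr) - 1) / max(nr - 1, 1)
    img <- matrix(params$background, nr, nc) +
      matrix(params$gradient_amplitude * ramp, nr, nc)
    if (nrow(nuc)) {
      sigma_px <- (params$nucleus_diameter / 4 / geometry$pixel_size) *
        pmax(0.5, 1 + stats::rnorm(nrow(nuc), 0, params$diameter_jitter))
      for (i in seq_len(nrow(nuc))) {
        r0 <- px$row[i]; c0 <- px$col[i]; s <- sigma_px[i]
        w <- ceiling(4 * s)
        rr <- max(1, floor(r0 - w)):min(nr, ceiling(r0 + w))
        cc <- max(1, floor(c0 - w)):min(nc, ceiling(c0 + w))
        gr <- exp(-(rr - r0)^2 / (2 * s^2))
        gc <- exp(-(cc - c0)^2 / (2 * s^2))
        img[rr, cc] <- img[rr, cc] + params$peak_intensity * outer(gr, gc)
      }
    }
    if (isTRUE(params$poisson_noise)) {
      img <- matrix(stats::rpois(length(img), pmax(img, 0)), nr, nc)
    }
    if (params$read_noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, params$read_noise_sd), nr, nc)
    }
    img <- pmax(img, 0)
    truth <- if (nrow(nuc)) {
      tibble(nucleus = seq_len(nrow(nuc)),
             x_um = nuc$x_um, y_um = nuc$y_um,
             row_px = px$row, col_px = px$col,
             region = nuc$region)
    } else {
      tibble(nucleus = integer(), x_um = numeric(), y_um = numeric(),
             row_px = numeric(), col_px = numeric(), region = character())
    }
    structure(list(pixels = img, pixel_size = geometry$pixel_size,
                   geometry = geometry, truth = truth),
              class = "chip_image")
  })
}

#' Write / read chip rasters as 16-bit TIFF
#'
#' Images are stored as single-channel 16-bit TIFF with counts scaled by
#' 1/65535; reading restores the count scale.
#'
#' @param image A `chip_image` (or bare matrix of counts).
#' @param path Output file path.
#' @return `write_chip_tiff()` returns `path` invisibly; `read_chip_tiff()`
#'   returns a `chip_image` (without ground truth).
#' @export
write_chip_tiff <- function(image, path) {
  px <- if (inherits(image, "chip_image")) image$pixels else image
  tiff::writeTIFF(pmin(px, 65535) / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_chip_tiff
#' @param geometry Geometry to attach on read.
#' @export
read_chip_tiff <- function(path, geometry = chip_geometry()) {
  px <- tiff::readTIFF(path, as.is = FALSE) * 65535
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  structure(list(pixels = px, pixel_size = geometry$pixel_size,
                 geometry = geometry, truth = NULL),
            class = "chip_image")
}

#' Match detected nuclei to ground truth
#'
#' Greedy nearest-first bipartite matching of detections to ground-truth
#' nuclei within a radius, and the resulting precision/recall/F1.
#'
#' @param truth Tibble with `x_um`, `y_um` (ground truth).
#' @param detected Tibble with `x_um`, `y_um` (detections).
#' @param radius_um Maximum centroid distance for a match, in µm.
#' @return A one-row tibble: `n_truth`, `n_detected`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
match_nuclei <- function(truth, detected, radius_um) {
  nt <- nrow(truth); nd <- nrow(detected)
  tp <- 0L
  if (nt && nd) {
    d2 <- outer(truth$x_um, detected$x_um, "-")^2 +
      outer(truth$y_um, detected$y_um, "-")^2
    cand <- which(d2 <= radius_um^2, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d2[cand]), , drop = FALSE]
      used_t <- logical(nt); used_d <- logical(nd)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_t[i] && !used_d[j]) {
          used_t[i] <- TRUE; used_d[j] <- TRUE; tp <- tp + 1L
        }
      }
    }
  }
  fp <- nd - tp; fn <- nt - tp
  tibble(n_truth = nt, n_detected = nd, tp = tp, fp = fp, fn = fn,
         precision = if (nd) tp / nd else NA_real_,
         recall = if (nt) tp / nt else NA_real_,
         f1 = if (tp + fp + fn) 2 * tp / (2 * tp + fp + fn) else NA_real_)
}
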