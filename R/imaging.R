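#' Nuclei detection parameters
#'
#' Tunable parameters of the nuclei-detection pipeline. Scale parameters are
#' in pixels; area gates are in µm² and applied after calibration.
#'
#' The difference-of-Gaussians scales default to a band-pass matched to the
#' expected nucleus profile: `sigma_small = nucleus_diameter / 4` (the
#' Gaussian scale of a nucleus-sized blob) converted to pixels, and
#' `sigma_large = 1.6 * sigma_small`, the classic difference-of-Gaussians
#' approximation to a Laplacian-of-Gaussian blob detector.
#'
#' @param rolling_ball_radius Structuring-element radius of the rolling-ball
#'   background estimate, pixels. Must exceed the nucleus radius.
#' @param dog_sigma_small,dog_sigma_large Gaussian scales of the DoG band-pass
#'   filter, pixels.
#' @param min_area,max_area Area gate for accepted nuclei, µm².
#' @param watershed_enabled Split touching nuclei with a watershed?
#' @param watershed_h Seed-depth tolerance of the shape-based (distance
#'   transform) watershed mode of [separate_watershed()], pixels.
#' @param watershed_tolerance Relative seed-depth tolerance of the
#'   intensity-seeded watershed used by the pipeline (fraction of the masked
#'   enhanced-intensity maximum).
#' @param min_snr Minimum ratio of the IsoData threshold to the robust noise
#'   scale (MAD) of the enhanced image; below it the image is treated as
#'   signal-free and no nuclei are reported.
#' @param nucleus_diameter Expected nucleus diameter, µm (used only for the
#'   DoG defaults).
#' @param pixel_size µm per pixel (used only for the DoG defaults).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(rolling_ball_radius = 50,
                             dog_sigma_small = NULL,
                             dog_sigma_large = NULL,
                             min_area = 25, max_area = 2000,
                             watershed_enabled = TRUE, watershed_h = 1,
                             watershed_tolerance = 0.1, min_snr = 4,
                             nucleus_diameter = 10, pixel_size = 0.65) {
  dog_sigma_small <- dog_sigma_small %||% (nucleus_diameter / 4 / pixel_size)
  dog_sigma_large <- dog_sigma_large %||% (1.6 * dog_sigma_small)
  if (dog_sigma_small >= dog_sigma_large) {
    abort("`dog_sigma_small` must be smaller than `dog_sigma_large`")
  }
  if (rolling_ball_radius <= 0) abort("`rolling_ball_radius` must be > 0")
  if (min_area <= 0 || max_area <= min_area) {
    abort("need 0 < min_area < max_area")
  }
  structure(list(rolling_ball_radius = rolling_ball_radius,
                 dog_sigma_small = dog_sigma_small,
                 dog_sigma_large = dog_sigma_large,
                 min_area = min_area, max_area = max_area,
                 watershed_enabled = isTRUE(watershed_enabled),
                 watershed_h = watershed_h,
                 watershed_tolerance = watershed_tolerance,
                 min_snr = min_snr),
            class = "detection_params")
}

as_pixels <- function(image) {
  if (inherits(image, "chip_image")) image$pixels else as.matrix(image)
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background as the grayscale opening of the image with
#' a disc of the given radius (the flat-disc limit of the classic rolling
#' ball) and subtracts it, clipping at zero. For radii above
#' `downsample_threshold` the background is estimated on a block-downsampled
#' image with a proportionally smaller disc and bilinearly upsampled, the
#' standard large-radius optimisation.
#'
#' @param image A `chip_image` or numeric matrix.
#' @param radius Ball radius in pixels; must exceed the nucleus radius.
#' @param downsample_threshold Radius above which the estimate runs on a
#'   downsampled image.
#' @return Background-subtracted image of the same class as the input.
#' @export
subtract_background <- function(image, radius = 50, downsample_threshold = 16) {
  if (!is.numeric(radius) || radius <= 0) abort("`radius` must be > 0")
  px <- as_pixels(image)
  shrink <- max(1L, floor(radius / downsample_threshold))
  if (shrink > 1L) {
    small <- as.matrix(EBImage::resize(px, w = ceiling(nrow(px) / shrink),
                                       h = ceiling(ncol(px) / shrink)))
    r <- max(1L, round(radius / shrink))
    bg <- gray_opening(small, r)
    bg <- as.matrix(EBImage::resize(bg, w = nrow(px), h = ncol(px)))
  } else {
    bg <- gray_opening(px, round(radius))
  }
  out <- pmax(px - bg, 0)
  rebuild_image(image, out)
}

# grayscale opening with a flat disc, on arbitrary intensity scales.
# EBImage's grayscale morphology clamps to [0, 1], so the image is
# normalized first; replicate-padding by the radius makes the border behave
# like a min/max over the in-image part of the window.
gray_opening <- function(px, r) {
  nr <- nrow(px); nc <- ncol(px)
  pad_r <- c(rep(1L, r), seq_len(nr), rep(nr, r))
  pad_c <- c(rep(1L, r), seq_len(nc), rep(nc, r))
  padded <- px[pad_r, pad_c]
  lo <- min(padded); hi <- max(padded)
  if (hi <= lo) return(px)
  scaled <- (padded - lo) / (hi - lo)
  op <- as.matrix(EBImage::opening(scaled, EBImage::makeBrush(2L * r + 1L, "disc")))
  op[r + seq_len(nr), r + seq_len(nc)] * (hi - lo) + lo
}

rebuild_image <- function(template, pixels) {
  if (inherits(template, "chip_image")) {
    template$pixels <- pixels
    template
  } else {
    pixels
  }
}

#' Difference-of-Gaussians enhancement
#'
#' Band-pass filters the image as `blur(sigma_small) - blur(sigma_large)`,
#' boosting blob-like structures of the matched scale and suppressing both
#' pixel noise and slowly varying background. Linear: zero-mean on constant
#' input, and `dog(a * I) = a * dog(I)`.
#'
#' @param image A `chip_image` or numeric matrix.
#' @param sigma_small,sigma_large Gaussian scales in pixels,
#'   `sigma_small < sigma_large`.
#' @return Filtered image (same class as input); values may be negative.
#' @export
enhance_dog <- function(image, sigma_small, sigma_large) {
  if (sigma_small >= sigma_large) {
    abort("`sigma_small` must be smaller than `sigma_large`")
  }
  px <- as_pixels(image)
  out <- as.matrix(EBImage::gblur(px, sigma = sigma_small)) -
    as.matrix(EBImage::gblur(px, sigma = sigma_large))
  rebuild_image(image, out)
}

#' IsoData automatic threshold
#'
#' Computes the IsoData threshold on a 256-bin histogram of the image: the
#' fixed point of `T = (mean(I <= T) + mean(I > T)) / 2`, iterated until the
#' threshold moves by less than half a bin. Returns the threshold; use
#' `image > threshold_isodata(image)` for the mask.
#'
#' @param image A `chip_image` or numeric matrix with at least two distinct
#'   values.
#' @param n_bins Histogram resolution.
#' @return The threshold (scalar, image units).
#' @export
threshold_isodata <- function(image, n_bins = 256L) {
  px <- as_pixels(image)
  lo <- min(px); hi <- max(px)
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
    abort("IsoData threshold is undefined on a constant image")
  }
  bin_w <- (hi - lo) / n_bins
  # bin centres and counts
  idx <- pmin(pmax(floor((px - lo) / bin_w) + 1L, 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  centers <- lo + (seq_len(n_bins) - 0.5) * bin_w
  csum_n <- cumsum(counts)
  csum_x <- cumsum(counts * centers)
  n_tot <- csum_n[n_bins]; x_tot <- csum_x[n_bins]

  t_bin <- n_bins %/% 2L
  t_new <- centers[t_bin]
  for (iter in seq_len(4L * n_bins)) {
    while (csum_n[t_bin] == 0L && t_bin < n_bins) t_bin <- t_bin + 1L
    while (csum_n[t_bin] == n_tot && t_bin > 1L) t_bin <- t_bin - 1L
    n_lo <- csum_n[t_bin]
    mu_lo <- csum_x[t_bin] / n_lo
    mu_hi <- (x_tot - csum_x[t_bin]) / (n_tot - n_lo)
    t_new <- (mu_lo + mu_hi) / 2
    new_bin <- min(max(floor((t_new - lo) / bin_w) + 1L, 1L), n_bins)
    if (new_bin == t_bin) break  # moved by less than one bin: fixed point
    t_bin <- new_bin
  }
  t_new
}

#' Watershed separation of touching nuclei
#'
#' Labels the connected components of a binary mask and splits touching
#' objects along watershed lines. With an `intensity` image (the enhanced
#' nuclei image), seeds are h-maxima of the masked intensity, which separates
#' close blob pairs by their individual brightness peaks; the tolerance
#' `rel_tol` is relative to the masked intensity maximum, keeping the split
#' invariant under intensity rescaling. Without `intensity`, seeds are
#' h-maxima of the Euclidean distance transform at depth `h` pixels, the
#' classic shape-based declumping.
#'
#' @param mask Logical/0-1 matrix from the thresholding step.
#' @param intensity Optional intensity matrix (same shape) to seed from.
#' @param h Seed-depth tolerance in distance-transform pixels (shape mode).
#' @param rel_tol Seed-depth tolerance as a fraction of the masked intensity
#'   maximum (intensity mode).
#' @return Integer label matrix; 0 is background. An empty mask yields an
#'   all-zero labeling.
#' @export
separate_watershed <- function(mask, intensity = NULL, h = 2, rel_tol = 0.1) {
  m <- as_pixels(mask) > 0
  if (!any(m)) return(matrix(0L, nrow(m), ncol(m)))
  if (is.null(intensity)) {
    lab <- EBImage::watershed(EBImage::distmap(m), tolerance = h, ext = 1L)
  } else {
    height <- as_pixels(intensity) * m
    lab <- EBImage::watershed(height / max(height), tolerance = rel_tol,
                              ext = 1L)
  }
  matrix(as.integer(as.matrix(lab)), nrow(m), ncol(m))
}

#' Extract nucleus records from a labeled mask
#'
#' Computes the centroid and area of every label, converts to calibrated chip
#' coordinates (µm), applies the area gate, and assigns each nucleus to the
#' vessel or sprouting region from the chip geometry.
#'
#' @param labels Integer label matrix (0 = background).
#' @param geometry A [chip_geometry()]; supplies the pixel size.
#' @param params A [detection_params()]; supplies the area gate.
#' @return Tibble with one row per accepted nucleus: `x_um`, `y_um`
#'   (centroid, chip coordinates), `area_um2`, `region`.
#' @export
extract_nuclei <- function(labels, geometry, params = detection_params()) {
  if (is.null(geometry$pixel_size) || !is.finite(geometry$pixel_size)) {
    abort("geometry must carry a finite `pixel_size` calibration")
  }
  idx <- which(labels > 0L)
  if (!length(idx)) {
    return(tibble(x_um = numeric(), y_um = numeric(),
                  area_um2 = numeric(), region = character()))
  }
  lab <- labels[idx]
  pos <- arrayInd(idx, dim(labels))
  n_px <- as.numeric(tapply(lab, lab, length))
  row_c <- as.numeric(tapply(pos[, 1], lab, mean))
  col_c <- as.numeric(tapply(pos[, 2], lab, mean))
  um <- pixel_to_um(row_c, col_c, geometry)
  out <- tibble(x_um = um$x, y_um = um$y,
                area_um2 = n_px * geometry$pixel_size^2) |>
    mutate(region = region_of(.data$y_um, geometry)) |>
    filter(.data$area_um2 >= params$min_area,
           .data$area_um2 <= params$max_area) |>
    arrange(.data$y_um, .data$x_um)
  out
}

#' Detect nuclei in a chip image
#'
#' The full detection pipeline: rolling-ball background subtraction,
#' difference-of-Gaussians enhancement, IsoData thresholding, watershed
#' separation of touching nuclei, and centroid/area extraction with region
#' assignment. Deterministic: identical inputs yield identical records.
#'
#' @param image A `chip_image` (or a bare matrix, with `geometry` supplying
#'   the calibration).
#' @param params A [detection_params()].
#' @param geometry Geometry override; defaults to the image's own.
#' @return Tibble of nucleus records as in [extract_nuclei()].
#' @export
detect_nuclei <- function(image, params = detection_params(), geometry = NULL) {
  geometry <- geometry %||%
    (if (inherits(image, "chip_image")) image$geometry else NULL)
  if (is.null(geometry)) abort("supply `geometry` when `image` is a bare matrix")
  px <- as_pixels(image)
  bg <- as_pixels(subtract_background(px, params$rolling_ball_radius))
  dog <- as_pixels(enhance_dog(bg, params$dog_sigma_small, params$dog_sigma_large))
  thr <- threshold_isodata(dog)
  noise_scale <- stats::mad(dog)
  if (thr < params$min_snr * noise_scale) {
    # no structure above the noise floor: a signal-free image
    return(extract_nuclei(matrix(0L, nrow(px), ncol(px)), geometry, params))
  }
  mask <- dog > thr
  labels <- if (params$watershed_enabled) {
    separate_watershed(mask, intensity = dog,
                       rel_tol = params$watershed_tolerance)
  } else {
    matrix(as.integer(as.matrix(EBImage::bwlabel(mask))), nrow(mask), ncol(mask))
  }
  extract_nuclei(labels, geometry, params)
}
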