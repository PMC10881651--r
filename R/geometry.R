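#' Chip geometry and coordinate calibration
#'
#' Describes the observation window of one microfluidic chip: a central
#' extracellular-matrix (gel) lane bounded by two phaseguides, with the
#' endothelial micro-vessel cultured against the vessel-side phaseguide.
#' All analysis happens in continuous micrometre chip coordinates:
#' `x` runs along the vessel, `y` is the longitudinal distance into the gel,
#' with `y = 0` at the inner edge of the vessel-side phaseguide (the boundary
#' of the sprouting region) and increasing toward the far phaseguide.
#'
#' The rendered/analysed raster covers the vessel nuclei band, the vessel-side
#' phaseguide, and the sprouting region: row 1 of the image is the most
#' negative `y`, and pixel centres sit at half-integer pixel offsets.
#'
#' @param channel_width Width of the gel lane along the vessel, in µm.
#' @param phaseguide_width Width of each phaseguide, in µm.
#' @param sprout_region_depth Distance from the vessel-side phaseguide to the
#'   far phaseguide, in µm. Must exceed the largest sprouting distance the
#'   generator can produce.
#' @param vessel_band_depth Depth of the imaged micro-vessel nuclei band on
#'   the vessel side of the phaseguide, in µm.
#' @param margin Extra imaged depth beyond the sprouting region, in µm.
#' @param x_margin Imaged width beyond each lateral edge of the gel lane, in
#'   µm (the acquisition window extends past the lane, so nuclei at the lane
#'   edge render without border clipping).
#' @param pixel_size Image calibration, µm per pixel.
#'
#' @return An object of class `chip_geometry`: a list with the arguments plus
#'   `y_min`/`y_max` (µm extent of the raster) and `image_shape`
#'   (rows, cols in pixels).
#' @export
chip_geometry <- function(channel_width = 400,
                          phaseguide_width = 100,
                          sprout_region_depth = 550,
                          vessel_band_depth = 120,
                          margin = 20,
                          x_margin = 20,
                          pixel_size = 0.65) {
  for (nm in c("channel_width", "phaseguide_width", "sprout_region_depth",
               "vessel_band_depth", "margin", "x_margin", "pixel_size")) {
    stopifnot_scalar_number(get(nm), nm, positive = !nm %in% c("margin", "x_margin"))
  }
  y_min <- -(phaseguide_width + vessel_band_depth)
  y_max <- sprout_region_depth + margin
  shape <- c(rows = as.integer(round((y_max - y_min) / pixel_size)),
             cols = as.integer(round((channel_width + 2 * x_margin) / pixel_size)))
  structure(
    list(channel_width = channel_width,
         phaseguide_width = phaseguide_width,
         sprout_region_depth = sprout_region_depth,
         vessel_band_depth = vessel_band_depth,
         margin = margin,
         x_margin = x_margin,
         pixel_size = pixel_size,
         y_min = y_min, y_max = y_max,
         image_shape = shape),
    class = "chip_geometry")
}

#' @export
print.chip_geometry <- function(x, ...) {
  cat("<chip_geometry>\n")
  cat(sprintf("  gel lane %g um wide, sprout region depth %g um, phaseguides %g um\n",
              x$channel_width, x$sprout_region_depth, x$phaseguide_width))
  cat(sprintf("  raster %d x %d px at %g um/px, y in [%g, %g] um\n",
              x$image_shape[["rows"]], x$image_shape[["cols"]],
              x$pixel_size, x$y_min, x$y_max))
  invisible(x)
}

# pixel (row, col) centres -> chip coordinates in um
pixel_to_um <- function(row, col, geometry) {
  list(x = (col - 0.5) * geometry$pixel_size - geometry$x_margin,
       y = geometry$y_min + (row - 0.5) * geometry$pixel_size)
}

um_to_pixel <- function(x, y, geometry) {
  list(row = (y - geometry$y_min) / geometry$pixel_size + 0.5,
       col = (x + geometry$x_margin) / geometry$pixel_size + 0.5)
}

#' Assign nuclei to the vessel or sprouting region
#'
#' A nucleus belongs to the sprouting region iff its centroid lies strictly
#' between the inner edges of the two phaseguides; nuclei over a phaseguide
#' (or on the vessel side of it) count as vessel nuclei.
#'
#' @param y Longitudinal positions in µm (`y = 0` at the vessel-side
#'   sprout-region boundary).
#' @param geometry A [chip_geometry()].
#' @return Character vector, `"sprout"` or `"vessel"`.
#' @export
region_of <- function(y, geometry) {
  ifelse(y > 0 & y < geometry$sprout_region_depth, "sprout", "vessel")
}
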