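#' Serial dilution series
#'
#' @param top Highest concentration (nM by convention).
#' @param fold Dilution factor between consecutive points.
#' @param n Number of points.
#' @return Concentrations in decreasing order, `top / fold^(0:(n-1))`.
#' @export
dilution_series <- function(top = 10000, fold = 4, n = 8) {
  stopifnot_scalar_number(top, "top", positive = TRUE)
  stopifnot_scalar_number(fold, "fold", positive = TRUE)
  top / fold^(seq_len(n) - 1)
}

#' Four-parameter logistic response
#'
#' `pl4(c) = bottom + (top - bottom) / (1 + (c / ic50)^hill)`: the response
#' equals `top` at low concentration, `bottom` at high concentration (for
#' `hill > 0`), and the midpoint `(top + bottom)/2` exactly at `c = ic50`.
#'
#' @param conc Concentrations (> 0).
#' @param ic50 Midpoint concentration.
#' @param hill Hill slope.
#' @param top,bottom Asymptotes.
#' @return Response values.
#' @export
pl4 <- function(conc, ic50, hill = 1, top = 100, bottom = 0) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Simulate a duplicate dose-response series
#'
#' Generates responses from a four-parameter logistic curve with
#' multiplicative log-normal noise, in duplicate per concentration, plus a
#' micro-vessel nuclei count per chip as the toxicity readout. The count is
#' stable across doses unless a decay is planted.
#'
#' @param ic50,hill,top,bottom True curve parameters; response units default
#'   to percent-of-vehicle sprouting.
#' @param series Concentrations (nM), default an 8-point 4-fold dilution from
#'   10 µM.
#' @param noise_cv CV of the multiplicative response noise.
#' @param n_replicates Chips per concentration.
#' @param vessel_nuclei_mean Expected vessel nuclei count per chip.
#' @param count_decay Fractional drop of the expected nuclei count at the top
#'   concentration (0 = stable; 0.5 halves the count at the top dose, with
#'   log-linear interpolation in between).
#' @param seed Integer seed.
#' @return Tibble with `concentration_nM`, `replicate`, `response`,
#'   `vessel_nuclei_count`.
#' @export
simulate_dose_response <- function(ic50 = 100, hill = 1, top = 100, bottom = 0,
                                   series = dilution_series(), noise_cv = 0.1,
                                   n_replicates = 2, vessel_nuclei_mean = 120,
                                   count_decay = 0, seed = 1L) {
  if (any(series <= 0)) abort("concentrations must be > 0")
  if (length(unique(series)) < 4L) abort("need at least 4 distinct concentrations")
  stopifnot_scalar_number(ic50, "ic50", positive = TRUE)
  with_seed(derive_seed(seed, "dose"), {
    grid <- tidyr::expand_grid(concentration_nM = sort(series, decreasing = TRUE),
                               replicate = seq_len(n_replicates))
    mu <- pl4(grid$concentration_nM, ic50, hill, top, bottom)
    noise <- if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      exp(stats::rnorm(nrow(grid), -sdlog^2 / 2, sdlog))
    } else 1
    lc <- log(grid$concentration_nM)
    decay_frac <- (lc - min(lc)) / max(max(lc) - min(lc), 1e-12)
    count_mu <- vessel_nuclei_mean * (1 - count_decay * decay_frac)
    grid$response <- mu * noise
    grid$vessel_nuclei_count <- stats::rpois(nrow(grid), pmax(count_mu, 0))
    grid
  })
}
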