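#' Default calibration of the synthetic phenotype generator
#'
#' The generator is anchored on control statistics observed in large
#' organ-on-a-chip angiogenesis screens: vehicle-control sprouting distance
#' with median 352.1 µm and CV 12.1%, sunitinib-like strong-inhibition
#' controls with median 62.2 µm, and unstimulated controls with CV 14.1%.
#' Sprouting distances are log-normal (positive support, CV-parameterised);
#' the two replicates of a compound share a latent effect draw with
#' correlation `rho` on the log scale.
#'
#' @param vehicle_median,vehicle_cv Vehicle-control D10 median (µm) and CV.
#' @param sunitinib_median,sunitinib_cv Strong-inhibition control calibration.
#'   No CV is reported for these controls; 20% separates them cleanly.
#' @param unstimulated_median,unstimulated_cv Unstimulated (no angiogenic
#'   cocktail) calibration; the median is not reported and is set below the
#'   sunitinib level.
#' @param rho Replicate correlation of the latent compound effect (log scale).
#' @param sprout_nuclei_base Expected number of sprout-region nuclei on a
#'   vehicle chip; sample chips scale it with sprouting extent.
#' @param vessel_nuclei_mean Expected micro-vessel nuclei count on a healthy
#'   chip within the imaged window.
#' @param toxicity_count_factor Multiplier of the vessel nuclei count for
#'   toxicity classes 1-4.
#' @param integrity_noise_sd Standard deviation of the (rounded, clamped)
#'   jitter applied to integrity scores; 0 keeps scores noiseless so a
#'   compound's integrity score is exactly `5 - toxicity_class`.
#' @param qc_fail_rate Fraction of chips failing pre-exposure quality control
#'   (drawn QC score 1-2).
#' @param min_separation Minimum centre-to-centre distance between nuclei,
#'   µm (hard-core placement: nuclei are physical bodies and do not
#'   interpenetrate).
#' @return Named list of generator parameters.
#' @export
phenotype_params <- function(vehicle_median = 352.1, vehicle_cv = 0.121,
                             sunitinib_median = 62.2, sunitinib_cv = 0.20,
                             unstimulated_median = 40, unstimulated_cv = 0.141,
                             rho = 0.85,
                             sprout_nuclei_base = 60,
                             vessel_nuclei_mean = 120,
                             toxicity_count_factor = c(1, 0.9, 0.7, 0.45),
                             integrity_noise_sd = 0,
                             qc_fail_rate = 0.02,
                             min_separation = 8) {
  if (rho < 0 || rho > 1) abort("`rho` must be in [0, 1]")
  as.list(environment())
}

lnorm_pars <- function(median, cv) {
  list(meanlog = log(median), sdlog = sqrt(log(1 + cv^2)))
}

# Sequential-inhibition (hard-core) sampling in a band: candidates are drawn
# uniformly and accepted when at least d_min from every accepted point; after
# `tries` rejections the farthest candidate seen is accepted, so the target
# count is always reached. A fraction of points may draw y from an alternate
# band (nuclei creeping over the phaseguide).
hardcore_points <- function(n, x_range, y_range, d_min,
                            y_alt_range = NULL, y_alt_frac = 0,
                            tries = 40L) {
  x <- y <- numeric(n)
  if (!n) return(list(x = x, y = y))
  for (i in seq_len(n)) {
    best <- NULL; best_d <- -Inf
    for (t in seq_len(tries)) {
      alt <- !is.null(y_alt_range) && stats::runif(1) < y_alt_frac
      cx <- stats::runif(1, x_range[1], x_range[2])
      cy <- if (alt) stats::runif(1, y_alt_range[1], y_alt_range[2]) else
        stats::runif(1, y_range[1], y_range[2])
      d <- if (i == 1L) Inf else
        sqrt(min((x[seq_len(i - 1L)] - cx)^2 + (y[seq_len(i - 1L)] - cy)^2))
      if (d > best_d) { best <- c(cx, cy); best_d <- d }
      if (d >= d_min) break
    }
    x[i] <- best[1]; y[i] <- best[2]
  }
  list(x = x, y = y)
}

# x-placement for sprout nuclei whose y is already fixed: each x is drawn to
# keep at least d_min from previously placed nuclei (best-of-`tries` fallback)
spread_x <- function(y, x_range, d_min, tries = 40L) {
  n <- length(y)
  x <- numeric(n)
  for (i in seq_len(n)) {
    best <- NULL; best_d <- -Inf
    for (t in seq_len(tries)) {
      cx <- stats::runif(1, x_range[1], x_range[2])
      d <- if (i == 1L) Inf else
        sqrt(min((x[seq_len(i - 1L)] - cx)^2 + (y[seq_len(i - 1L)] - y[i])^2))
      if (d > best_d) { best <- cx; best_d <- d }
      if (d >= d_min) break
    }
    x[i] <- best
  }
  list(x = x)$x
}

#' Simulate one chip's ground-truth phenotype
#'
#' Draws the true ten-furthest-nuclei sprouting distance (D10), ordinal
#' QC/integrity scores, and ground-truth nucleus positions for a single chip.
#' Controls draw D10 from the role's calibrated log-normal; sample chips
#' scale the vehicle median by the compound's planted inhibition effect and
#' share a latent log-scale draw `z_compound` across the two replicates
#' (correlation `rho`). Sprout-nuclei positions are rescaled so the mean of
#' the ten furthest ground-truth nuclei equals the drawn `true_d10` exactly.
#'
#' @param role One of `"vehicle"`, `"sunitinib_control"`, `"unstimulated"`,
#'   `"sample"`.
#' @param geometry A [chip_geometry()].
#' @param params A [phenotype_params()] list.
#' @param inhibition_effect,toxicity_class Planted compound truth (samples
#'   only).
#' @param z_compound Latent standard-normal draw shared by a compound's
#'   replicates; defaults to a fresh draw (no replicate coupling).
#' @param seed Integer seed for this chip's stream.
#' @return A list of class `chip_phenotype`: `true_d10` (µm), `qc_score`,
#'   `integrity_score`, `vessel_nuclei_count`, and `nuclei`, a tibble of
#'   ground-truth positions (`x_um`, `y_um`, `region`).
#' @export
sample_phenotype <- function(role, geometry = chip_geometry(),
                             params = phenotype_params(),
                             inhibition_effect = NULL, toxicity_class = NULL,
                             z_compound = NULL, seed = 1L) {
  roles <- c("vehicle", "sunitinib_control", "unstimulated", "sample")
  if (!is.character(role) || length(role) != 1L || !role %in% roles) {
    abort(sprintf("`role` must be one of: %s", paste(roles, collapse = ", ")))
  }
  if (role == "sample" && (is.null(inhibition_effect) || is.null(toxicity_class))) {
    abort("sample chips need `inhibition_effect` and `toxicity_class`")
  }
  with_seed(seed, {
    # --- true D10 -----------------------------------------------------------
    if (role == "sample") {
      lp <- lnorm_pars(params$vehicle_median * max(inhibition_effect, 0),
                       params$vehicle_cv)
      zc <- z_compound %||% stats::rnorm(1)
      z <- sqrt(params$rho) * zc + sqrt(1 - params$rho) * stats::rnorm(1)
      true_d10 <- if (inhibition_effect <= 0) 0 else exp(lp$meanlog + lp$sdlog * z)
      tox <- as.integer(toxicity_class)
    } else {
      cal <- switch(role,
        vehicle = lnorm_pars(params$vehicle_median, params$vehicle_cv),
        sunitinib_control = lnorm_pars(params$sunitinib_median, params$sunitinib_cv),
        unstimulated = lnorm_pars(params$unstimulated_median, params$unstimulated_cv))
      true_d10 <- exp(cal$meanlog + cal$sdlog * stats::rnorm(1))
      tox <- if (role == "sunitinib_control") 2L else 1L
    }
    # keep the sprouting front inside the gel region
    true_d10 <- min(true_d10, geometry$sprout_region_depth / 1.25)

    # --- ordinal scores -----------------------------------------------------
    qc <- if (stats::runif(1) < params$qc_fail_rate) sample(1:2, 1) else 4L
    integ <- 5L - tox
    if (params$integrity_noise_sd > 0) {
      integ <- integ + as.integer(round(stats::rnorm(1, 0, params$integrity_noise_sd)))
    }
    integ <- max(1L, min(4L, integ))

    # --- nuclei placement (hard-core: nuclei do not interpenetrate) ---------
    xmax <- geometry$channel_width
    d_min <- params$min_separation
    n_vessel <- stats::rpois(1, params$vessel_nuclei_mean *
                               params$toxicity_count_factor[tox])
    # the vessel hugs the phaseguide; a few nuclei creep over the phaseguide
    vessel_pts <- hardcore_points(
      n_vessel, x_range = c(2, xmax - 2),
      y_range = c(-(geometry$phaseguide_width + geometry$vessel_band_depth) + 2,
                  -geometry$phaseguide_width),
      d_min = d_min,
      y_alt_range = c(-geometry$phaseguide_width * 0.6, -1), y_alt_frac = 0.1)
    vessel <- tibble(x_um = vessel_pts$x, y_um = vessel_pts$y, region = "vessel")
    if (true_d10 > 0) {
      n_sprout <- max(5L, stats::rpois(1, params$sprout_nuclei_base *
                                         true_d10 / params$vehicle_median))
      y_raw <- stats::runif(n_sprout)
      k <- min(10L, n_sprout)
      top_mean <- mean(sort(y_raw, decreasing = TRUE)[seq_len(k)])
      y_um <- pmin(y_raw * true_d10 / top_mean, geometry$sprout_region_depth - 1)
      x_um <- spread_x(y_um, x_range = c(2, xmax - 2), d_min = d_min)
      sprout <- tibble(x_um = x_um, y_um = y_um, region = "sprout")
    } else {
      sprout <- tibble(x_um = numeric(), y_um = numeric(), region = character())
    }
    structure(
      list(true_d10 = true_d10,
           qc_score = as.integer(qc),
           integrity_score = integ,
           vessel_nuclei_count = n_vessel,
           nuclei = dplyr::bind_rows(vessel, sprout)),
      class = "chip_phenotype")
  })
}

#' Simulate ground-truth phenotypes for a whole layout
#'
#' Applies [sample_phenotype()] to every chip of a [generate_layout()] table,
#' looking planted effects up in the compound library and sharing the latent
#' replicate draw between a compound's two chips. Each chip draws from its
#' own seed substream, so regenerating a subset reproduces identical chips.
#'
#' @param layout Layout tibble from [generate_layout()].
#' @param library Compound tibble from [simulate_library()].
#' @param geometry A [chip_geometry()].
#' @param params A [phenotype_params()].
#' @param seed Top-level integer seed.
#' @return A tibble with one row per chip: layout columns plus `true_d10`,
#'   `qc_score`, `integrity_score`, `vessel_nuclei_count`, and a `nuclei`
#'   list-column of ground-truth positions.
#' @export
simulate_phenotypes <- function(layout, library = NULL,
                                geometry = chip_geometry(),
                                params = phenotype_params(), seed = 1L) {
  need <- unique(stats::na.omit(layout$compound_id))
  if (length(need) && (is.null(library) || !all(need %in% library$compound_id))) {
    abort("`library` must annotate every compound in `layout`")
  }
  zc <- purrr::map_dbl(need, function(id) {
    with_seed(derive_seed(seed, "zcomp", id), stats::rnorm(1))
  })
  names(zc) <- need

  res <- purrr::pmap(layout, function(plate_id, chip_id, position, role,
                                      compound_id, replicate, ...) {
    if (role == "sample" && is.na(compound_id)) return(NULL)
    eff <- tox <- NULL
    zi <- NULL
    if (role == "sample") {
      row <- library[match(compound_id, library$compound_id), ]
      eff <- row$inhibition_effect
      tox <- row$toxicity_class
      zi <- zc[[compound_id]]
    }
    ph <- sample_phenotype(role, geometry, params,
                           inhibition_effect = eff, toxicity_class = tox,
                           z_compound = zi,
                           seed = derive_seed(seed, "chip", plate_id, chip_id))
    tibble(plate_id = plate_id, chip_id = chip_id, position = position,
           role = role, compound_id = compound_id, replicate = replicate,
           true_d10 = ph$true_d10, qc_score = ph$qc_score,
           integrity_score = ph$integrity_score,
           vessel_nuclei_count = ph$vessel_nuclei_count,
           nuclei = list(ph$nuclei))
  })
  purrr::list_rbind(purrr::compact(res))
}
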