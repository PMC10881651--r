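#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `response = bottom + (top - bottom) /
#' (1 + (conc / ic50)^hill)` on log-concentration, with multi-start
#' initialization (a grid of candidate IC50s across the tested range and both
#' slope signs) and Levenberg-Marquardt refinement. Replicates are fit
#' jointly on pooled residuals, never averaged first. After fitting, the
#' parameterisation is normalized so `top >= bottom` (the model is invariant
#' under swapping the asymptotes and negating the slope). Data without any
#' dose dependence yield `converged = FALSE` rather than an error.
#'
#' @param data Tibble of dose-response points.
#' @param conc,response Column names (tidy-select style strings) of
#'   concentration (nM, > 0) and response.
#' @return An object of class `fit4pl`: coefficient list (`ic50`, `hill`,
#'   `top`, `bottom`), `converged`, `residual_sd`, `n`, and the data used.
#'   Methods: [tidy.fit4pl()], [glance.fit4pl()], [predict.fit4pl()],
#'   [autoplot.fit4pl()].
#' @export
fit_4pl <- function(data, conc = "concentration_nM", response = "response") {
  cc <- data[[conc]]; rr <- data[[response]]
  if (is.null(cc) || is.null(rr)) abort("`conc`/`response` columns not found")
  ok <- is.finite(cc) & is.finite(rr)
  cc <- cc[ok]; rr <- rr[ok]
  if (any(cc <= 0)) abort("concentrations must be > 0")
  if (length(unique(cc)) < 4L) abort("need at least 4 distinct concentrations")

  lx <- log(cc)
  df <- data.frame(lx = lx, y = rr)
  # model in log-ic50: y = bottom + (top-bottom)/(1+exp(hill*(lx - l50)))
  rng <- range(rr); span <- diff(rng)
  fit_try <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + exp(hill * (lx - l50))),
        data = df, start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  starts <- tidyr::expand_grid(
    l50 = stats::quantile(lx, c(0.2, 0.5, 0.8), names = FALSE),
    hill = c(-2, -1, -0.5, 0.5, 1, 2))
  fits <- purrr::pmap(starts, function(l50, hill) {
    fit_try(list(top = max(rr), bottom = min(rr), l50 = l50, hill = hill))
  }) |> purrr::compact()

  flat_sd <- stats::sd(rr)
  if (!length(fits) || span == 0) {
    return(new_fit4pl(list(ic50 = NA_real_, hill = NA_real_,
                           top = mean(rr), bottom = mean(rr)),
                      converged = FALSE, residual_sd = flat_sd %||% 0,
                      data = df))
  }
  best <- fits[[which.min(purrr::map_dbl(fits, stats::deviance))]]
  cf <- as.list(stats::coef(best))
  # orientation normalization: top is the low-concentration asymptote
  if (cf$top < cf$bottom) {
    tmp <- cf$top; cf$top <- cf$bottom; cf$bottom <- tmp
    cf$hill <- -cf$hill
  }
  rsd <- sqrt(stats::deviance(best) / max(stats::df.residual(best), 1))
  # honest convergence: the fitted curve must explain dose dependence and
  # keep its midpoint inside (well, near) the tested range
  dose_dependent <- abs(cf$top - cf$bottom) > 2 * rsd &&
    cf$l50 > min(lx) - log(100) && cf$l50 < max(lx) + log(100)
  new_fit4pl(list(ic50 = exp(cf$l50), hill = cf$hill,
                  top = cf$top, bottom = cf$bottom),
             converged = isTRUE(dose_dependent), residual_sd = rsd, data = df)
}

new_fit4pl <- function(coefs, converged, residual_sd, data) {
  structure(list(coefficients = coefs, converged = converged,
                 residual_sd = residual_sd, n = nrow(data), data = data),
            class = "fit4pl")
}

#' @export
print.fit4pl <- function(x, ...) {
  cf <- x$coefficients
  cat("<fit4pl>", if (!x$converged) "(not converged)", "\n")
  cat(sprintf("  ic50 = %.4g nM, hill = %.3g, top = %.4g, bottom = %.4g\n",
              cf$ic50, cf$hill, cf$top, cf$bottom))
  cat(sprintf("  residual sd %.3g on %d points\n", x$residual_sd, x$n))
  invisible(x)
}

#' Tidy a 4PL fit
#'
#' @param x A `fit4pl` object.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.fit4pl <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unlist(x$coefficients, use.names = FALSE))
}

#' One-row summary of a 4PL fit
#'
#' @param x A `fit4pl` object.
#' @param ... Unused.
#' @return Tibble: `ic50`, `hill`, `top`, `bottom`, `converged`,
#'   `residual_sd`, `n`.
#' @export
glance.fit4pl <- function(x, ...) {
  cf <- x$coefficients
  tibble(ic50 = cf$ic50, hill = cf$hill, top = cf$top, bottom = cf$bottom,
         converged = x$converged, residual_sd = x$residual_sd, n = x$n)
}

#' @export
predict.fit4pl <- function(object, newdata = NULL, ...) {
  cf <- object$coefficients
  conc <- if (is.null(newdata)) exp(object$data$lx) else {
    if (is.numeric(newdata)) newdata else newdata$concentration_nM
  }
  pl4(conc, cf$ic50, cf$hill, cf$top, cf$bottom)
}

#' Plot a fitted dose-response curve
#'
#' @param object A `fit4pl` object.
#' @param ... Unused.
#' @return A ggplot: points and fitted curve on log10 concentration.
#' @export
autoplot.fit4pl <- function(object, ...) {
  pts <- tibble(concentration_nM = exp(object$data$lx),
                response = object$data$y)
  grid <- tibble(concentration_nM = exp(seq(min(object$data$lx),
                                            max(object$data$lx),
                                            length.out = 200)))
  grid$response <- predict(object, grid)
  ggplot2::ggplot(pts, ggplot2::aes(.data$concentration_nM, .data$response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "#2166ac") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (nM)", y = "response",
                  subtitle = sprintf("IC50 = %.3g nM", object$coefficients$ic50)) +
    ggplot2::theme_minimal()
}

#' Micro-vessel nuclei-count toxicity profile of a dose series
#'
#' Summarises the vessel nuclei count per concentration and classifies the
#' series `"stable"` if no concentration's mean count falls below a fraction
#' of the vehicle-control mean, else `"declining"` with the lowest offending
#' concentration.
#'
#' @param series Dose-series tibble with `concentration_nM` and
#'   `vessel_nuclei_count`.
#' @param vehicle_mean Vehicle-control mean vessel nuclei count.
#' @param min_fraction Stability threshold as a fraction of `vehicle_mean`.
#' @return A list: `per_concentration` tibble (`concentration_nM`,
#'   `mean_count`, `sd_count`, `n`), `classification`, and
#'   `declining_from_nM` (NA when stable).
#' @export
toxicity_profile <- function(series, vehicle_mean, min_fraction = 0.8) {
  if (!"vessel_nuclei_count" %in% names(series) ||
      anyNA(series$vessel_nuclei_count)) {
    abort("every dose point needs a `vessel_nuclei_count`")
  }
  per <- series |>
    group_by(.data$concentration_nM) |>
    summarise(mean_count = mean(.data$vessel_nuclei_count),
              sd_count = stats::sd(.data$vessel_nuclei_count),
              n = dplyr::n(), .groups = "drop") |>
    arrange(.data$concentration_nM)
  low <- per$mean_count < min_fraction * vehicle_mean
  list(per_concentration = per,
       classification = if (any(low)) "declining" else "stable",
       declining_from_nM = if (any(low)) min(per$concentration_nM[low]) else NA_real_)
}
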