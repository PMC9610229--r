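# Closed-form reservoir-release model: membrane flux, cumulative release,
# Dk estimation from release curves, and inverse design of wall thickness.
#
# Unit conventions (enforced throughout the package):
#   lengths mm, areas mm^2, volumes mm^3, time days, mass mg.
#   Solubilities cross the public API in mg/mL (the units in which they are
#   tabulated and measured) and are converted to mg/mm^3 (/1000) internally,
#   so Dk carries mm^2/day and release rates carry mg/day.

MG_PER_ML_TO_MG_PER_MM3 <- 1e-3

#' Implant geometry and loading
#'
#' Describes one reservoir-style implant: an excipient-formulated drug core
#' enclosed in a polymer tube whose wall is the rate-controlling membrane.
#' The tube ends are treated as sealed, so release occurs only through the
#' lateral wall.
#'
#' @param length_mm Tube length in mm.
#' @param wall_thickness_mm Membrane wall thickness in mm (the diffusion
#'   path length of the steady-state flux model).
#' @param outer_diameter_mm Outer diameter in mm; defaults to 2.5 mm, the
#'   extruded-tube dimension used throughout.
#' @param drug_loading_mg Total drug mass loaded in the reservoir (mg), or
#'   `NA` when unknown.
#' @param drug_excipient_ratio Mass ratio label such as `"2:1"` (metadata).
#' @param polymer_grade Free-text polymer grade label (metadata).
#'
#' @return An object of class `"implant_config"`.
#' @examples
#' cfg <- implant_config(length_mm = 40, wall_thickness_mm = 0.2)
#' lateral_surface_area(cfg)
#' @export
implant_config <- function(length_mm, wall_thickness_mm, outer_diameter_mm = 2.5,
                           drug_loading_mg = NA_real_,
                           drug_excipient_ratio = NA_character_,
                           polymer_grade = NA_character_) {
  stopifnot(is.numeric(length_mm), length(length_mm) == 1L,
            is.numeric(wall_thickness_mm), length(wall_thickness_mm) == 1L,
            is.numeric(outer_diameter_mm), length(outer_diameter_mm) == 1L)
  if (!is.finite(length_mm) || length_mm <= 0)
    stop("invalid geometry: length_mm must be positive", call. = FALSE)
  if (!is.finite(wall_thickness_mm) || wall_thickness_mm <= 0 ||
      wall_thickness_mm >= outer_diameter_mm / 2)
    stop("invalid geometry: need 0 < wall_thickness_mm < outer_diameter_mm / 2",
         call. = FALSE)
  if (!is.na(drug_loading_mg) && drug_loading_mg <= 0)
    stop("invalid geometry: drug_loading_mg must be positive when provided",
         call. = FALSE)
  structure(
    list(length_mm = length_mm,
         wall_thickness_mm = wall_thickness_mm,
         outer_diameter_mm = outer_diameter_mm,
         drug_loading_mg = as.numeric(drug_loading_mg),
         drug_excipient_ratio = drug_excipient_ratio,
         polymer_grade = polymer_grade),
    class = "implant_config")
}

#' @export
print.implant_config <- function(x, ...) {
  cat(sprintf("Reservoir implant: L %.4g mm, wall %.4g mm, OD %.4g mm\n",
              x$length_mm, x$wall_thickness_mm, x$outer_diameter_mm))
  if (!is.na(x$drug_loading_mg))
    cat(sprintf("  drug loading %.4g mg", x$drug_loading_mg),
        if (!is.na(x$drug_excipient_ratio))
          sprintf(" (drug:excipient %s)", x$drug_excipient_ratio) else "",
        "\n", sep = "")
  if (!is.na(x$polymer_grade)) cat("  polymer:", x$polymer_grade, "\n")
  invisible(x)
}

#' Lateral release area of a tubular implant
#'
#' Area through which the membrane flux acts. The default is the mid-wall
#' lateral cylinder, `pi * (OD - wall) * length` (equivalently `2 * pi *
#' r_mid * length` with `r_mid` midway between the inner and outer radii),
#' with sealed ends. The thin-wall (slab) approximation is retained as the
#' default; `correction = "logmean"` substitutes the log-mean cylindrical
#' area `2 * pi * length * wall / log(r_outer / r_inner)` for users who want
#' the exact cylindrical-shell result.
#'
#' @param config An [implant_config()].
#' @param correction `"midwall"` (default) or `"logmean"`.
#' @return Area in mm^2.
#' @export
lateral_surface_area <- function(config, correction = c("midwall", "logmean")) {
  stopifnot(inherits(config, "implant_config"))
  correction <- match.arg(correction)
  r_out <- config$outer_diameter_mm / 2
  r_in <- r_out - config$wall_thickness_mm
  if (correction == "midwall") {
    pi * (config$outer_diameter_mm - config$wall_thickness_mm) * config$length_mm
  } else {
    2 * pi * config$length_mm * config$wall_thickness_mm / log(r_out / r_in)
  }
}

.check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stop(sprintf("domain error: %s must be positive and finite", nm),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Steady-state membrane release rate
#'
#' Zero-order release rate of a saturated reservoir: the steady-state
#' solution of Fickian membrane transport, `rate = Dk * CsE * A / L`, where
#' `Dk` is the lumped diffusion-partition parameter (mm^2/day), `CsE` the
#' drug's saturation solubility in the excipient, `A` the release area and
#' `L` the membrane thickness.
#'
#' @param dk Lumped diffusion-partition parameter, mm^2/day.
#' @param cse_mg_ml Saturation solubility in the excipient, mg/mL.
#' @param wall_thickness_mm Membrane thickness L, mm.
#' @param area_mm2 Release area A, mm^2.
#' @return Release rate in mg/day.
#' @seealso [membrane_flux()] for the per-area flux J = rate / A.
#' @export
release_rate <- function(dk, cse_mg_ml, wall_thickness_mm, area_mm2) {
  .check_positive(dk = dk, cse_mg_ml = cse_mg_ml,
                  wall_thickness_mm = wall_thickness_mm, area_mm2 = area_mm2)
  dk * (cse_mg_ml * MG_PER_ML_TO_MG_PER_MM3) * area_mm2 / wall_thickness_mm
}

#' Per-area membrane flux
#'
#' `J = Dk * CsE / L`, in mg/day/mm^2.
#'
#' @inheritParams release_rate
#' @export
membrane_flux <- function(dk, cse_mg_ml, wall_thickness_mm) {
  .check_positive(dk = dk, cse_mg_ml = cse_mg_ml,
                  wall_thickness_mm = wall_thickness_mm)
  dk * (cse_mg_ml * MG_PER_ML_TO_MG_PER_MM3) / wall_thickness_mm
}

#' Time-ordered cumulative release observations
#'
#' A `release_series` is a data frame with columns `time_days` (strictly
#' increasing, first value >= 0) and `cumulative_mass_mg` (non-decreasing),
#' optionally `mass_per_interval_mg`.
#'
#' @param time_days Observation times in days.
#' @param cumulative_mass_mg Cumulative released mass in mg.
#' @param mass_per_interval_mg Optional per-interval released mass in mg.
#' @return An object of classes `"release_series"` and `"data.frame"`.
#' @export
release_series <- function(time_days, cumulative_mass_mg,
                           mass_per_interval_mg = NULL) {
  stopifnot(is.numeric(time_days), is.numeric(cumulative_mass_mg),
            length(time_days) == length(cumulative_mass_mg))
  if (length(time_days)) {
    if (time_days[1L] < 0)
      stop("release series: first time must be >= 0", call. = FALSE)
    if (any(diff(time_days) <= 0))
      stop("release series: times must be strictly increasing", call. = FALSE)
    if (any(diff(cumulative_mass_mg) < -sqrt(.Machine$double.eps)))
      stop("release series: cumulative mass must be non-decreasing",
           call. = FALSE)
    if (any(cumulative_mass_mg < 0))
      stop("release series: cumulative mass must be non-negative",
           call. = FALSE)
  }
  df <- data.frame(time_days = as.numeric(time_days),
                   cumulative_mass_mg = as.numeric(cumulative_mass_mg))
  if (!is.null(mass_per_interval_mg)) {
    stopifnot(length(mass_per_interval_mg) == nrow(df))
    df$mass_per_interval_mg <- as.numeric(mass_per_interval_mg)
  }
  class(df) <- c("release_series", "data.frame")
  df
}

#' Predicted cumulative release under the zero-order model
#'
#' `Mt = rate * t` with `rate = Dk * CsE * A / L` from the implant geometry.
#' The model is unbounded; truncation at the loaded drug mass is opt-in and
#' flagged via the `"truncated"` attribute rather than applied silently.
#'
#' @inheritParams release_rate
#' @param config An [implant_config()]; supplies `L` and the release area.
#' @param times_days Non-negative, strictly increasing prediction times.
#' @param truncate_at_loading If `TRUE` and the config carries a drug
#'   loading, predictions are capped at that loading and the result carries
#'   `attr(, "truncated") = TRUE` when the cap was hit.
#' @return A [release_series()] of predictions.
#' @export
predict_cumulative <- function(dk, cse_mg_ml, config, times_days,
                               truncate_at_loading = FALSE) {
  stopifnot(inherits(config, "implant_config"), is.numeric(times_days))
  if (length(times_days) == 0L)
    return(release_series(numeric(0), numeric(0)))
  if (any(times_days < 0))
    stop("domain error: times must be non-negative", call. = FALSE)
  if (any(diff(times_days) <= 0))
    stop("domain error: times must be strictly increasing", call. = FALSE)
  rate <- release_rate(dk, cse_mg_ml, config$wall_thickness_mm,
                       lateral_surface_area(config))
  mt <- rate * times_days
  truncated <- FALSE
  if (truncate_at_loading && !is.na(config$drug_loading_mg)) {
    truncated <- any(mt > config$drug_loading_mg)
    mt <- pmin(mt, config$drug_loading_mg)
  }
  out <- release_series(times_days, mt)
  attr(out, "rate_mg_day") <- rate
  attr(out, "truncated") <- truncated
  out
}

#' Estimate Dk from a cumulative-release curve
#'
#' Fits an ordinary least-squares line to cumulative mass versus time and
#' converts the slope to the lumped diffusion-partition parameter:
#' `Dk = slope * L / (CsE * A)`. A free intercept is fitted by default so a
#' constant burst offset does not bias the slope; `intercept = FALSE`
#' constrains the line through the origin. The fit window can exclude, for
#' example, an initial burst phase.
#'
#' @param series A [release_series()] of observations.
#' @param config The matching [implant_config()].
#' @param cse_mg_ml Saturation solubility in the excipient, mg/mL.
#' @param fit_window Optional `c(first_day, last_day)`; only observations
#'   with `first_day <= t <= last_day` enter the fit. Default: full series.
#' @param intercept Fit a free intercept (default `TRUE`).
#' @return A `"dk_estimate"`: list with `dk` and `standard_error`
#'   (mm^2/day), `intercept_mg`, `slope_mg_day`, `fit_window`, `n_points`,
#'   and `flagged` (`TRUE` when the slope, hence `dk`, is non-positive).
#' @export
estimate_dk <- function(series, config, cse_mg_ml, fit_window = NULL,
                        intercept = TRUE) {
  stopifnot(inherits(series, "release_series"),
            inherits(config, "implant_config"))
  .check_positive(cse_mg_ml = cse_mg_ml)
  if (is.null(fit_window)) {
    fit_window <- c(min(series$time_days), max(series$time_days))
  }
  stopifnot(length(fit_window) == 2L)
  keep <- series$time_days >= fit_window[1L] & series$time_days <= fit_window[2L]
  t <- series$time_days[keep]
  m <- series$cumulative_mass_mg[keep]
  if (length(t) < 2L)
    stop("insufficient data: need at least 2 points inside the fit window",
         call. = FALSE)
  if (stats::var(m) == 0) {
    # constant cumulative mass: the release rate is exactly zero
    slope <- 0; slope_se <- 0
  } else {
    fit <- if (intercept) stats::lm(m ~ t) else stats::lm(m ~ t + 0)
    sm <- summary(fit)$coefficients
    slope <- sm["t", "Estimate"]
    slope_se <- sm["t", "Std. Error"]
  }
  scale <- config$wall_thickness_mm /
    ((cse_mg_ml * MG_PER_ML_TO_MG_PER_MM3) * lateral_surface_area(config))
  intercept_mg <- if (!intercept) 0
                  else if (stats::var(m) == 0) m[1L]
                  else unname(stats::coef(fit)[1L])
  est <- structure(
    list(dk = slope * scale,
         standard_error = slope_se * scale,
         intercept_mg = intercept_mg,
         slope_mg_day = slope,
         fit_window = fit_window,
         n_points = length(t),
         flagged = slope <= 0),
    class = "dk_estimate")
  est
}

#' @export
print.dk_estimate <- function(x, ...) {
  cat(sprintf("Dk = %.4g +/- %.3g mm^2/day  (slope %.4g mg/day, n = %d, window [%g, %g] d)\n",
              x$dk, x$standard_error, x$slope_mg_day, x$n_points,
              x$fit_window[1L], x$fit_window[2L]))
  if (x$flagged) cat("  WARNING: non-positive slope; estimate is not physical\n")
  invisible(x)
}

#' Wall thickness achieving a target release rate
#'
#' Inverts the zero-order rate law: `L = Dk * CsE * A / target_rate`.
#' `release_rate(dk, cse, design_wall_thickness(target, ...), area)` returns
#' the target exactly. Whether the resulting thickness is manufacturable
#' (or below the tube's physical cap) is left to the caller.
#'
#' @param target_rate_mg_day Desired release rate, mg/day.
#' @inheritParams release_rate
#' @return Wall thickness in mm.
#' @export
design_wall_thickness <- function(target_rate_mg_day, dk, cse_mg_ml, area_mm2) {
  .check_positive(target_rate_mg_day = target_rate_mg_day, dk = dk,
                  cse_mg_ml = cse_mg_ml, area_mm2 = area_mm2)
  dk * (cse_mg_ml * MG_PER_ML_TO_MG_PER_MM3) * area_mm2 / target_rate_mg_day
}

#' Cumulative release from sampled buffer concentrations
#'
#' Bookkeeping of the in vitro sampling protocol: at each buffer exchange
#' the mass released during the interval is `concentration x buffer
#' volume`; cumulative mass is the running sum; the daily release rate at
#' time `t_n` is cumulative mass divided by elapsed days.
#'
#' @param concentrations_mg_ml Measured drug concentration in the release
#'   buffer for each interval, mg/mL.
#' @param buffer_volumes_ml Buffer volume for each interval, mL.
#' @param interval_end_days End time of each interval, days (strictly
#'   increasing).
#' @return A [release_series()] with a `mass_per_interval_mg` column.
#' @seealso [daily_release_rate()]
#' @export
accumulate_samples <- function(concentrations_mg_ml, buffer_volumes_ml,
                               interval_end_days) {
  n <- length(concentrations_mg_ml)
  if (length(buffer_volumes_ml) != n || length(interval_end_days) != n)
    stop("input error: concentrations, volumes and interval times must have equal length",
         call. = FALSE)
  if (any(concentrations_mg_ml < 0) || any(buffer_volumes_ml < 0))
    stop("input error: concentrations and volumes must be non-negative",
         call. = FALSE)
  mass <- concentrations_mg_ml * buffer_volumes_ml
  release_series(interval_end_days, cumsum(mass), mass_per_interval_mg = mass)
}

#' Daily release rate implied by a cumulative series
#'
#' `cumulative mass / elapsed days` at each observation (NA at t = 0).
#'
#' @param series A [release_series()].
#' @return Numeric vector of mg/day.
#' @export
daily_release_rate <- function(series) {
  stopifnot(inherits(series, "release_series"))
  ifelse(series$time_days > 0,
         series$cumulative_mass_mg / series$time_days, NA_real_)
}
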