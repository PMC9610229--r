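# Synthetic-data generators with known ground truth: release curves under
# zero-order, burst, and reservoir-depletion regimes; interval-sampled
# buffer concentrations mimicking the twice-weekly dissolution protocol;
# and QSPR training tables drawn from a known linear model on the log10
# scale. All generators are pure functions of (parameters, seed).

#' Twice-weekly sampling schedule
#'
#' Buffer-exchange times at a constant 3.5-day spacing (two exchanges per
#' week), mirroring the in vitro dissolution protocol.
#'
#' @param duration_days Study length in days.
#' @param interval_days Spacing between exchanges (default 3.5).
#' @return Numeric vector of interval-end times in days.
#' @export
twice_weekly_schedule <- function(duration_days, interval_days = 3.5) {
  stopifnot(duration_days > 0, interval_days > 0)
  seq(interval_days, duration_days, by = interval_days)
}

#' Define a synthetic release scenario
#'
#' Bundles the ground truth for one simulated dissolution experiment.
#' Regimes:
#' * `zero_order` — ideal saturated reservoir, `Mt = rate * t`.
#' * `burst` — zero-order plus a saturating-exponential early excess
#'   `burst_mass * (1 - exp(-t / burst_tau))`, emulating a membrane
#'   pre-saturated during storage.
#' * `depletion` — zero-order until the dissolved reservoir falls below
#'   saturation (released mass reaches `loading - CsE * V_res`), then a
#'   first-order exponential approach to the loading with rate constant
#'   `Dk * A / (L * V_res)` (the same membrane conductance acting on the
#'   now sub-saturated reservoir concentration).
#'
#' @param regime `"zero_order"`, `"burst"`, or `"depletion"`.
#' @param dk_true Ground-truth Dk, mm^2/day.
#' @param cse_mg_ml Drug solubility in the excipient, mg/mL.
#' @param config An [implant_config()]; the depletion regime requires its
#'   `drug_loading_mg`.
#' @param duration_days Study length (default 70 days, ten weeks).
#' @param noise_sd_mg SD of additive Gaussian measurement noise (mg);
#'   default 0.
#' @param noise_model `"observation"` (default): independent noise on each
#'   cumulative observation. `"interval"`: noise on each per-interval
#'   released mass before accumulation, which makes the cumulative error a
#'   random walk — more faithful to how the assay propagates error, but
#'   the ordinary-least-squares slope standard error of [estimate_dk()]
#'   is then an underestimate (its iid assumption fails), so
#'   uncertainty-calibrated checks use the observation model.
#' @param reservoir_volume_mm3 Reservoir volume for the depletion regime;
#'   defaults to the tube's inner volume `pi * (ID/2)^2 * length`.
#' @param burst_mass_mg,burst_tau_days Burst magnitude (mg) and time
#'   constant (days); required for the burst regime.
#' @param schedule Sampling times; default [twice_weekly_schedule()].
#' @param seed Integer seed making the simulation reproducible.
#' @return A `"release_scenario"` list.
#' @export
release_scenario <- function(regime = c("zero_order", "burst", "depletion"),
                             dk_true, cse_mg_ml, config,
                             duration_days = 70, noise_sd_mg = 0,
                             reservoir_volume_mm3 = NULL,
                             burst_mass_mg = NULL, burst_tau_days = NULL,
                             schedule = NULL, seed = 1L,
                             noise_model = c("observation", "interval")) {
  regime <- match.arg(regime)
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(config, "implant_config"))
  .check_positive(dk_true = dk_true, cse_mg_ml = cse_mg_ml)
  if (noise_sd_mg < 0) stop("config error: noise_sd_mg must be >= 0", call. = FALSE)
  if (regime == "burst") {
    if (is.null(burst_mass_mg) || is.null(burst_tau_days))
      stop("config error: burst regime requires burst_mass_mg and burst_tau_days",
           call. = FALSE)
    .check_positive(burst_mass_mg = burst_mass_mg, burst_tau_days = burst_tau_days)
  }
  if (regime == "depletion") {
    if (is.na(config$drug_loading_mg))
      stop("config error: depletion regime requires drug_loading_mg in the config",
           call. = FALSE)
    if (is.null(reservoir_volume_mm3)) {
      r_in <- config$outer_diameter_mm / 2 - config$wall_thickness_mm
      reservoir_volume_mm3 <- pi * r_in^2 * config$length_mm
    }
    .check_positive(reservoir_volume_mm3 = reservoir_volume_mm3)
  }
  if (is.null(schedule)) schedule <- twice_weekly_schedule(duration_days)
  structure(
    list(regime = regime, dk_true = dk_true, cse_mg_ml = cse_mg_ml,
         config = config, duration_days = duration_days,
         noise_sd_mg = noise_sd_mg,
         reservoir_volume_mm3 = reservoir_volume_mm3,
         burst_mass_mg = burst_mass_mg, burst_tau_days = burst_tau_days,
         schedule = schedule, seed = as.integer(seed),
         noise_model = noise_model),
    class = "release_scenario")
}

#' Noise-free cumulative release curve of a scenario
#'
#' The closed-form mean curve (no measurement noise) at arbitrary times.
#'
#' @param scenario A [release_scenario()].
#' @param times_days Evaluation times.
#' @return Numeric vector of cumulative mass (mg).
#' @export
scenario_mean_curve <- function(scenario, times_days) {
  stopifnot(inherits(scenario, "release_scenario"))
  cfg <- scenario$config
  area <- lateral_surface_area(cfg)
  rate <- release_rate(scenario$dk_true, scenario$cse_mg_ml,
                       cfg$wall_thickness_mm, area)
  t <- times_days
  switch(scenario$regime,
    zero_order = rate * t,
    burst = rate * t +
      scenario$burst_mass_mg * (1 - exp(-t / scenario$burst_tau_days)),
    depletion = {
      loading <- cfg$drug_loading_mg
      v <- scenario$reservoir_volume_mm3
      m_sat <- (scenario$cse_mg_ml * MG_PER_ML_TO_MG_PER_MM3) * v
      # time at which the excess solid is exhausted; 0 if never saturated
      t_star <- max(0, (loading - m_sat) / rate)
      kd <- scenario$dk_true * area / (cfg$wall_thickness_mm * v)
      dissolved0 <- min(m_sat, loading)
      ifelse(t <= t_star, rate * t,
             loading - dissolved0 * exp(-kd * (t - t_star)))
    })
}

#' Simulate a release experiment
#'
#' Evaluates the scenario's mean curve at the sampling schedule, applies
#' additive Gaussian measurement noise `N(0, noise_sd_mg^2)` (to each
#' cumulative observation, or to each per-interval mass before
#' accumulation — see `noise_model` in [release_scenario()]), monotonizes
#' by running maximum, and — in the depletion regime — caps at the drug
#' loading. Noise lives in the assay, not in the physics: the mean curve
#' is always the closed form of [scenario_mean_curve()].
#'
#' @param scenario A [release_scenario()].
#' @return A [release_series()] with attribute `"ground_truth"` (regime,
#'   `dk_true`, zero-order `rate_mg_day`, and regime-specific constants);
#'   retrieve it with [ground_truth()].
#' @export
simulate_release <- function(scenario) {
  stopifnot(inherits(scenario, "release_scenario"))
  cfg <- scenario$config
  t <- scenario$schedule
  mean_cum <- scenario_mean_curve(scenario, t)
  cum <- mean_cum
  if (scenario$noise_sd_mg > 0) {
    set.seed(scenario$seed)
    eps <- stats::rnorm(length(t), 0, scenario$noise_sd_mg)
    cum <- if (identical(scenario$noise_model, "interval"))
      cumsum(diff(c(0, mean_cum)) + eps)
    else mean_cum + eps
  }
  cum <- cummax(pmax(cum, 0))
  if (scenario$regime == "depletion")
    cum <- pmin(cum, cfg$drug_loading_mg)
  out <- release_series(t, cum, mass_per_interval_mg = diff(c(0, cum)))
  area <- lateral_surface_area(cfg)
  rate <- release_rate(scenario$dk_true, scenario$cse_mg_ml,
                       cfg$wall_thickness_mm, area)
  truth <- list(regime = scenario$regime, dk_true = scenario$dk_true,
                rate_mg_day = rate, cse_mg_ml = scenario$cse_mg_ml,
                noise_sd_mg = scenario$noise_sd_mg, seed = scenario$seed)
  if (scenario$regime == "burst") {
    truth$burst_mass_mg <- scenario$burst_mass_mg
    truth$burst_tau_days <- scenario$burst_tau_days
  }
  if (scenario$regime == "depletion") {
    v <- scenario$reservoir_volume_mm3
    m_sat <- (scenario$cse_mg_ml * MG_PER_ML_TO_MG_PER_MM3) * v
    truth$reservoir_volume_mm3 <- v
    truth$t_star_days <- max(0, (cfg$drug_loading_mg - m_sat) / rate)
    truth$decay_rate_per_day <- scenario$dk_true * area /
      (cfg$wall_thickness_mm * v)
  }
  attr(out, "ground_truth") <- truth
  out
}

#' Ground truth attached to a simulated series or table
#' @param x An object produced by [simulate_release()] or
#'   [generate_qspr_table()].
#' @return The ground-truth list, or `NULL`.
#' @export
ground_truth <- function(x) attr(x, "ground_truth", exact = TRUE)

#' Convert a cumulative series into interval buffer concentrations
#'
#' The inverse of [accumulate_samples()]: given the cumulative curve and
#' the buffer volume, returns the drug concentration measured in the
#' release buffer for each sampling interval. Cumulative mass is linearly
#' interpolated at schedule points inside the series span, so
#' [accumulate_samples()] on the output reproduces the input cumulative
#' values at the schedule exactly.
#'
#' @param series A [release_series()].
#' @param buffer_volume_ml Release-buffer volume per interval, mL (scalar
#'   or one value per interval).
#' @param schedule Interval-end times; defaults to the series' own times.
#' @return Data frame with `interval_end_days`, `concentration_mg_ml`,
#'   `buffer_volume_ml`.
#' @export
sample_to_intervals <- function(series, buffer_volume_ml, schedule = NULL) {
  stopifnot(inherits(series, "release_series"))
  if (any(buffer_volume_ml <= 0))
    stop("domain error: buffer_volume_ml must be positive", call. = FALSE)
  if (is.null(schedule)) schedule <- series$time_days
  if (any(schedule < min(0, series$time_days[1L])) ||
      any(schedule > max(series$time_days)))
    stop("input error: schedule must lie within the series span", call. = FALSE)
  if (any(diff(schedule) <= 0))
    stop("input error: schedule must be strictly increasing", call. = FALSE)
  cum <- stats::approx(c(0, series$time_days), c(0, series$cumulative_mass_mg),
                       xout = schedule, rule = 2)$y
  vols <- rep_len(buffer_volume_ml, length(schedule))
  data.frame(interval_end_days = schedule,
             concentration_mg_ml = diff(c(0, cum)) / vols,
             buffer_volume_ml = vols)
}

#' Default property ranges for synthetic QSPR tables
#'
#' Brackets the span of the tabulated training and validation drugs:
#' MW 229-535 Da, CsP 0.0071-165.6 mg/mL, pKa 2.65-17.9, logP -1.4-3.8,
#' CsE 0.01-76 mg/mL.
#' @return Named list of `c(min, max)` ranges.
#' @export
qspr_property_ranges <- function() {
  list(mw = c(229, 535), csp = c(0.0071, 165.6), pka = c(2.65, 17.9),
       logp = c(-1.4, 3.8), cse = c(0.01, 76))
}

.runif_log <- function(n, range) 10^stats::runif(n, log10(range[1L]), log10(range[2L]))

#' Generate a QSPR training table from a known model
#'
#' Draws drug-level properties (MW, CsP, pKa, logP — one value per drug,
#' shared by that drug's rows) and row-level excipient solubilities CsE,
#' then sets `log10(Dk) = generator prediction + N(0, noise_sd_log10^2)`.
#' Solubilities (CsP, CsE) are drawn log-uniformly, the other properties
#' uniformly. The generating coefficients are attached as ground truth for
#' recovery tests.
#'
#' @param generator_model A `"qspr_model"` supplying the generating
#'   coefficients; default [published_model()].
#' @param n_drugs Number of synthetic drugs (>= 2); default 7, matching
#'   the size of the training panel.
#' @param excipients_per_drug Rows per drug (default 6).
#' @param property_ranges Named ranges as from [qspr_property_ranges()].
#' @param noise_sd_log10 SD of the log10-scale observation noise
#'   (default 0.3, the scale implied by a training MSE near 0.09).
#' @param seed Integer seed.
#' @return Data frame with columns `drug`, `excipient`, `mw_da`,
#'   `csp_mg_ml`, `pka`, `logp`, `cse_mg_ml`, `log10_dk`, `dk`; ground
#'   truth in `attr(, "ground_truth")`.
#' @export
generate_qspr_table <- function(generator_model = published_model(),
                                n_drugs = 7, excipients_per_drug = 6,
                                property_ranges = qspr_property_ranges(),
                                noise_sd_log10 = 0.3, seed = 1L) {
  stopifnot(inherits(generator_model, "qspr_model"))
  if (n_drugs < 2) stop("config error: n_drugs must be >= 2", call. = FALSE)
  if (excipients_per_drug < 1)
    stop("config error: excipients_per_drug must be >= 1", call. = FALSE)
  if (noise_sd_log10 < 0)
    stop("config error: noise_sd_log10 must be >= 0", call. = FALSE)
  for (nm in c("mw", "csp", "pka", "logp", "cse")) {
    rg <- property_ranges[[nm]]
    if (is.null(rg) || length(rg) != 2L || rg[2L] <= rg[1L])
      stop("config error: empty or invalid range for ", nm, call. = FALSE)
  }
  set.seed(seed)
  n <- n_drugs * excipients_per_drug
  drugs <- data.frame(
    drug = sprintf("drug_%02d", seq_len(n_drugs)),
    mw = stats::runif(n_drugs, property_ranges$mw[1L], property_ranges$mw[2L]),
    csp = .runif_log(n_drugs, property_ranges$csp),
    pka = stats::runif(n_drugs, property_ranges$pka[1L], property_ranges$pka[2L]),
    logp = stats::runif(n_drugs, property_ranges$logp[1L], property_ranges$logp[2L]))
  tab <- drugs[rep(seq_len(n_drugs), each = excipients_per_drug), ]
  tab$excipient <- rep(sprintf("excipient_%02d", seq_len(excipients_per_drug)),
                       times = n_drugs)
  tab$cse <- .runif_log(n, property_ranges$cse)
  mean_log10 <- predict_log10_dk(generator_model, tab)
  tab$log10_dk <- mean_log10 + stats::rnorm(n, 0, noise_sd_log10)
  tab$dk <- 10^tab$log10_dk
  out <- data.frame(drug = tab$drug, excipient = tab$excipient,
                    mw_da = tab$mw, csp_mg_ml = tab$csp, pka = tab$pka,
                    logp = tab$logp, cse_mg_ml = tab$cse,
                    log10_dk = tab$log10_dk, dk = tab$dk,
                    row.names = NULL)
  attr(out, "ground_truth") <- list(
    intercept = generator_model$intercept,
    coefficients = generator_model$coefficients,
    transforms = lapply(generator_model$transforms, `[[`, "transform"),
    noise_sd_log10 = noise_sd_log10, seed = as.integer(seed))
  out
}
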