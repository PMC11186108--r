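#' TLD relative energy-response curve
#'
#' Relative dose-normalized response versus beam mean energy, expressed
#' relative to a high-energy reference quality. The packaged default curve
#' (see [default_response_curve()]) is a plausible LiF:Mg,Ti shape rising
#' toward low energies (bounded by the documented up-to-40% over-response),
#' shipped as data and overridable; no quantitative claim rests on it.
#'
#' @param energies_kev anchor mean energies, keV, strictly increasing.
#' @param responses relative responses at the anchors (> 0).
#' @param reference name of the reference beam quality.
#' @return An `energy_response_curve`.
#' @export
energy_response_curve <- function(energies_kev, responses,
                                  reference = "Cs-137") {
  stopifnot(length(energies_kev) >= 2,
            length(responses) == length(energies_kev))
  if (any(energies_kev <= 0) || any(responses <= 0))
    stop("energies and responses must be positive")
  if (is.unsorted(energies_kev, strictly = TRUE))
    stop("anchor energies must be strictly increasing")
  structure(list(energies_kev = energies_kev, responses = responses,
                 reference = reference), class = "energy_response_curve")
}

#' Bundled LiF:Mg,Ti response curve
#' @param path optional CSV override with columns `energy_kev`, `response`.
#' @return An `energy_response_curve`.
#' @export
default_response_curve <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tld_response_synthetic.csv",
                        package = "rptdose", mustWork = TRUE)
  tab <- utils::read.csv(path)
  energy_response_curve(tab$energy_kev, tab$response)
}

# relative response at arbitrary mean energies, linear in log-energy
response_at <- function(curve, energy_kev) {
  if (any(energy_kev <= 0)) stop("energies must be positive")
  e <- curve$energies_kev
  if (any(energy_kev < min(e) * 0.8 | energy_kev > max(e) * 1.25))
    warning("extrapolating the energy-response curve")
  stats::approx(log(e), curve$responses, xout = log(energy_kev),
                rule = 2)$y
}

#' Beam-quality energy-correction factor
#'
#' Corrects a dose calibrated in one beam quality for use at another mean
#' energy: `factor = response(calibration_energy) / response(mean_energy)`,
#' with responses interpolated linearly in log-energy between the curve
#' anchors. The factor multiplies the calibrated dose.
#'
#' @param mean_energy_kev fluence-weighted mean energy at the measurement
#'   point, keV.
#' @param curve an `energy_response_curve`.
#' @param calibration_energy_kev mean energy of the calibration beam, keV
#'   (default 111, the 250 kVp reference beam's in-depth mean energy).
#' @return multiplicative correction factor.
#' @export
energy_correction <- function(mean_energy_kev, curve,
                              calibration_energy_kev = 111) {
  response_at(curve, calibration_energy_kev) / response_at(curve, mean_energy_kev)
}

#' Fit the linear TLD dose-response calibration
#'
#' Least-squares fit `dose = slope * signal + intercept` from calibration
#' chips given known reference doses spanning the measurement range. The
#' residual standard deviation (as percent of the mean dose) is reported as
#' an uncertainty-budget component.
#'
#' @param signals raw reader signals (arbitrary units).
#' @param reference_doses_gy delivered doses, Gy (>= 3 points).
#' @return list with `slope`, `intercept`, `residual_pct`, and the `fit`.
#' @export
fit_calibration <- function(signals, reference_doses_gy) {
  stopifnot(length(signals) == length(reference_doses_gy),
            length(signals) >= 3)
  if (stats::sd(signals) == 0) stop("degenerate calibration: all signals equal")
  fit <- stats::lm(reference_doses_gy ~ signals)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       residual_pct = 100 * stats::sd(stats::residuals(fit)) /
         mean(reference_doses_gy),
       fit = fit)
}

#' TLD group: readings and reduction state for one probe
#'
#' @param probe_id probe index.
#' @param readings raw signals for the chips in the probe (n >= 2; > 0).
#' @param calibration list with `slope` and `intercept` (from
#'   [fit_calibration()]).
#' @param mean_energy_kev fluence-weighted mean photon energy at the probe.
#' @return A `tld_group`.
#' @export
tld_group <- function(probe_id, readings, calibration, mean_energy_kev) {
  if (any(readings <= 0)) stop("readings must be positive")
  if (length(readings) < 2) stop("need at least 2 readings for statistics")
  structure(list(probe_id = probe_id, readings = readings,
                 calibration = calibration,
                 mean_energy_kev = mean_energy_kev,
                 corrected_doses_gy = NULL,
                 outlier_flags = rep(FALSE, length(readings))),
            class = "tld_group")
}

#' Apply calibration and energy correction to a TLD group
#'
#' Populates `corrected_doses_gy`:
#' `(slope * reading + intercept) * energy_correction_factor`.
#' Multiplicative factors commute, so the order of calibration and energy
#' correction does not matter.
#'
#' @param group a `tld_group`.
#' @param curve an `energy_response_curve`.
#' @param calibration_energy_kev calibration beam mean energy, keV.
#' @return the updated `tld_group`.
#' @export
correct_tld_group <- function(group, curve, calibration_energy_kev = 111) {
  f <- energy_correction(group$mean_energy_kev, curve, calibration_energy_kev)
  group$corrected_doses_gy <-
    (group$calibration$slope * group$readings + group$calibration$intercept) * f
  group$energy_correction_factor <- f
  group
}

#' Flag outlier readings in a group
#'
#' A reading is flagged when its deviation from the group mean exceeds
#' `threshold_pct` percent of that mean (default 6%, i.e. two standard
#' deviations of the expected ~3% repeatability). Flagged readings are
#' retained in all statistics; the flag is informational.
#'
#' @param group a `tld_group`.
#' @param threshold_pct flag threshold, percent of the group mean.
#' @return the `tld_group` with `outlier_flags` set.
#' @export
flag_outliers <- function(group, threshold_pct = 6) {
  x <- if (!is.null(group$corrected_doses_gy)) group$corrected_doses_gy
       else group$readings
  m <- mean(x)
  if (m == 0) stop("zero group mean")
  group$outlier_flags <- abs(x - m) / m > threshold_pct / 100
  group
}

#' Reduce a TLD group to a measured dose
#'
#' Mean of the corrected chip doses with the sample standard deviation as a
#' percent of the mean. Outliers are flagged but retained.
#'
#' @param group a `tld_group` with `corrected_doses_gy` populated.
#' @return list with `probe_id`, `dose_gy`, `sd_pct`, `n`, `n_outliers`.
#' @export
reduce_probe <- function(group) {
  x <- group$corrected_doses_gy
  if (is.null(x)) stop("corrected doses not populated; run correct_tld_group()")
  if (length(x) < 2) {
    warning("fewer than 2 readings: no standard deviation")
    return(list(probe_id = group$probe_id, dose_gy = mean(x), sd_pct = NA_real_,
                n = length(x), n_outliers = sum(group$outlier_flags)))
  }
  list(probe_id = group$probe_id, dose_gy = mean(x),
       sd_pct = 100 * stats::sd(x) / mean(x), n = length(x),
       n_outliers = sum(group$outlier_flags))
}

#' Combine an uncertainty budget in quadrature
#'
#' `combined = k * sqrt(sum(c_i^2))` for components `c_i` stated at k = 1.
#' When a conservative override is supplied, both the computed combination
#' and the adopted override are retained; downstream agreement verdicts use
#' the adopted value.
#'
#' @param components named numeric vector of components, percent at k = 1
#'   (>= 0).
#' @param k coverage factor (> 0; k = 2 is ~95% confidence).
#' @param conservative_override optional adopted expanded uncertainty,
#'   percent.
#' @return An `uncertainty_budget` with `combined_percent` and
#'   `adopted_percent`.
#' @export
combine_uncertainty <- function(components, k = 2,
                                conservative_override = NULL) {
  if (k <= 0) stop("coverage factor must be positive")
  if (any(components < 0)) stop("components must be >= 0")
  combined <- k * sqrt(sum(components^2))
  adopted <- if (!is.null(conservative_override)) conservative_override
             else combined
  structure(list(components = components, k = k,
                 combined_percent = combined,
                 conservative_override = conservative_override,
                 adopted_percent = adopted),
            class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf("<uncertainty_budget> k = %g: combined %.2f%%", x$k,
              x$combined_percent))
  if (!is.null(x$conservative_override))
    cat(sprintf(" (adopted conservative %.1f%%)", x$conservative_override))
  cat("\n  components (%, k = 1): ",
      paste(sprintf("%.2g", x$components), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Simulate raw TLD readings for a probe
#'
#' Synthetic measurement model: the chip signal is the true dose divided by
#' the calibration slope and scaled by the relative energy response at the
#' probe (so an uncorrected naive calibration would over-estimate), with
#' multiplicative Gaussian repeatability noise per chip.
#'
#' @param true_dose_gy absorbed dose at the probe, Gy.
#' @param n_chips chips per probe (default 4).
#' @param slope_gy_per_signal true reader calibration slope.
#' @param curve an `energy_response_curve`.
#' @param mean_energy_kev photon mean energy at the probe.
#' @param calibration_energy_kev calibration beam mean energy.
#' @param repeatability_pct per-chip repeatability, percent (default 3).
#' @return numeric vector of raw signals.
#' @export
simulate_tld_readings <- function(true_dose_gy, n_chips = 4,
                                  slope_gy_per_signal = 0.01,
                                  curve = default_response_curve(),
                                  mean_energy_kev = 200,
                                  calibration_energy_kev = 111,
                                  repeatability_pct = 3) {
  resp_ratio <- response_at(curve, mean_energy_kev) /
    response_at(curve, calibration_energy_kev)
  signal <- true_dose_gy / slope_gy_per_signal * resp_ratio
  signal * (1 + stats::rnorm(n_chips, 0, repeatability_pct / 100))
}
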