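#' Scattering power from the epithermal transmission plateau
#'
#' s = -ln(mean transmission) over the epithermal window, the product of
#' number density, thickness, and the stoichiometry-weighted free
#' cross-section once the curve has reached its impulse-approximation
#' plateau. The error is propagated from the per-point errors of the mean.
#'
#' @param curve a `transmission_curve`
#' @param window energy window, eV; defaults to the \[10, 100\] eV plateau
#' @return list with `value` (dimensionless) and `error`
#' @export
scattering_power <- function(curve, window = c(10, 100)) {
  stopifnot(inherits(curve, "transmission_curve"), length(window) == 2)
  inside <- curve$energies >= window[1] & curve$energies <= window[2]
  if (sum(inside) < 5) stop("fewer than 5 grid points inside the plateau window")
  tbar <- mean(curve$transmission[inside])
  se <- sqrt(sum(curve$errors[inside]^2)) / sum(inside)
  list(value = -log(tbar), error = se / tbar)
}

#' Convert a transmission curve to an effective cross-section curve
#'
#' sigma(E) = -ln T(E) / (n_fu d): corrects the transmission for the sample's
#' number density and thickness, expressing the result in barns per formula
#' unit.
#'
#' @param curve a `transmission_curve`
#' @param rho sample mass density, g/cm^3
#' @param stoich a [build_stoichiometry()] result
#' @return an `xs_curve`
#' @export
transmission_to_sigma <- function(curve, rho, stoich) {
  stopifnot(inherits(curve, "transmission_curve"),
            inherits(stoich, "stoichiometry"), rho > 0)
  if (any(curve$transmission <= 0)) stop("non-positive transmission values")
  nd <- .number_density(rho, stoich$molar_mass) * curve$thickness * .barn_cm2
  structure(list(energies = curve$energies,
                 sigma_total = -log(curve$transmission) / nd,
                 temperature = curve$temperature),
            class = "xs_curve")
}

#' Density series from calibrated transmission scattering powers
#'
#' rho(T) = rho_ref * s(T) / s(T_ref): with constant composition and
#' thickness the scattering power is proportional to the number density, so a
#' single-point calibration at the reference temperature converts the
#' scattering-power series into a mass-density series.
#'
#' @param series list of `transmission_curve` objects at distinct temperatures
#' @param T_ref calibration temperature, degrees C (must be in the series)
#' @param rho_ref tabulated density at `T_ref`, g/cm^3
#' @param window plateau window passed to [scattering_power()]
#' @return data frame of class `density_estimates` with columns
#'   `temperature`, `density`, `error`, `source`
#' @export
density_from_transmission <- function(series, T_ref = -20, rho_ref = 1.3,
                                      window = c(10, 100)) {
  temps <- vapply(series, `[[`, 0, "temperature")
  iref <- which(abs(temps - T_ref) < 1e-9)
  if (length(iref) == 0) stop("reference temperature ", T_ref, " not in series")
  sp <- lapply(series, scattering_power, window = window)
  s_ref <- sp[[iref[1]]]$value
  out <- data.frame(
    temperature = temps,
    density = rho_ref * vapply(sp, `[[`, 0, "value") / s_ref,
    error = rho_ref * vapply(sp, function(x)
      x$error / s_ref, 0),
    source = "transmission"
  )
  out <- out[order(out$temperature), ]
  rownames(out) <- NULL
  class(out) <- c("density_estimates", class(out))
  out
}

#' Integral of the incoherent diffraction background
#'
#' Trapezoidal integral of the counts over a d-spacing window, after checking
#' that the window keeps clear of every allowed aluminium reflection (the
#' container's Bragg peaks) by at least `margin` peak widths.
#'
#' @param pattern a `diffraction_pattern`
#' @param window d-spacing window, Angstrom
#' @param al_lattice_a aluminium lattice constant, Angstrom
#' @param peak_width Bragg peak width used for the exclusion margin, Angstrom
#' @param margin clearance required, in peak widths
#' @return list with `value` (counts * Angstrom) and `error`
#' @export
background_integral <- function(pattern, window = c(2.5, 3.5),
                                al_lattice_a = 4.0495, peak_width = 0.01,
                                margin = 3) {
  stopifnot(inherits(pattern, "diffraction_pattern"), length(window) == 2)
  peaks <- .fcc_d_spacings(al_lattice_a, d_min = 0.3)
  clash <- peaks$d > window[1] - margin * peak_width &
           peaks$d < window[2] + margin * peak_width
  if (any(clash)) {
    p <- peaks[which(clash)[1], ]
    stop(sprintf("window overlaps the aluminium (%d%d%d) reflection at d = %.3f A",
                 p$h, p$k, p$l, p$d))
  }
  inside <- pattern$d_spacings >= window[1] & pattern$d_spacings <= window[2]
  if (sum(inside) < 2) stop("fewer than 2 grid points inside the window")
  d <- pattern$d_spacings[inside]
  value <- pracma::trapz(d, pattern$counts[inside])
  dx <- mean(diff(d))
  err <- sqrt(sum((pattern$errors[inside] * dx)^2))
  list(value = value, error = err)
}

#' Density series from calibrated diffraction backgrounds
#'
#' rho(T) = rho_ref * B(T) / B(T_ref), where B is the incoherent background
#' integral: the featureless (hydrogen-dominated) diffraction background is
#' proportional to the amorphous sample's number density.
#'
#' @param series list of `diffraction_pattern` objects
#' @param T_ref calibration temperature, degrees C
#' @param rho_ref tabulated density at `T_ref`, g/cm^3
#' @param window integration window passed to [background_integral()]
#' @return data frame of class `density_estimates`
#' @export
density_from_diffraction <- function(series, T_ref = -20, rho_ref = 1.3,
                                     window = c(2.5, 3.5)) {
  temps <- vapply(series, `[[`, 0, "temperature")
  iref <- which(abs(temps - T_ref) < 1e-9)
  if (length(iref) == 0) stop("reference temperature ", T_ref, " not in series")
  bg <- lapply(series, background_integral, window = window)
  b_ref <- bg[[iref[1]]]$value
  out <- data.frame(
    temperature = temps,
    density = rho_ref * vapply(bg, `[[`, 0, "value") / b_ref,
    error = rho_ref * vapply(bg, `[[`, 0, "error") / b_ref,
    source = "diffraction"
  )
  out <- out[order(out$temperature), ]
  rownames(out) <- NULL
  class(out) <- c("density_estimates", class(out))
  out
}

#' Discrepancy between measured and modelled cross-section window integrals
#'
#' Delta I(T) = integral of the measured total cross-section over the
#' thermal window minus the functional-group model's prediction at the same
#' temperature. A growing discrepancy with temperature signals vibrational
#' softening the static model does not capture.
#'
#' @param measured list of `xs_curve` objects (e.g. from
#'   [transmission_to_sigma()])
#' @param model an [afga_model()]
#' @param lo,hi window bounds, meV
#' @return data frame with columns `temperature`, `integral_measured`,
#'   `integral_model`, `delta`
#' @export
afga_discrepancy <- function(measured, model, lo = 2.6, hi = 10) {
  stopifnot(length(measured) >= 1, inherits(model, "afga_model"))
  rows <- lapply(measured, function(curve) {
    stopifnot(inherits(curve, "xs_curve"))
    im <- window_integral(curve, lo, hi)
    pred_curve <- total_sigma(curve$energies, model, curve$temperature)
    ip <- window_integral(pred_curve, lo, hi)
    data.frame(temperature = curve$temperature, integral_measured = im,
               integral_model = ip, delta = im - ip)
  })
  out <- do.call(rbind, rows)
  out[order(out$temperature), ]
}

#' Bracket a glass-transition step in a series
#'
#' Two-segment changepoint bracketing on consecutive differences: the
#' transition is the contiguous run of inter-point drops around the largest
#' drop whose magnitude exceeds 3x the median absolute inter-point change.
#' Returns the two measured temperatures bracketing that run — never an
#' interpolated value.
#'
#' @param temperatures measured temperatures, degrees C, increasing
#' @param values series values (e.g. densities)
#' @param factor threshold multiplier on the median absolute change
#' @param both_directions also flag upward steps (for parameter trend
#'   scanning); default FALSE (drops only)
#' @return list with `found` (logical), `T_low`, `T_high`
#' @export
detect_transition_series <- function(temperatures, values, factor = 3,
                                     both_directions = FALSE) {
  stopifnot(length(temperatures) == length(values))
  if (length(temperatures) < 4) stop("at least 4 temperatures are required")
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("temperatures must be strictly increasing")
  dv <- diff(values)
  mag <- if (both_directions) abs(dv) else pmax(-dv, 0)
  thr <- factor * stats::median(abs(dv))
  big <- mag > thr & mag > 0
  if (!any(big)) return(list(found = FALSE, T_low = NA_real_, T_high = NA_real_))
  imax <- which.max(mag)
  lo <- imax
  while (lo > 1 && big[lo - 1]) lo <- lo - 1
  hi <- imax
  while (hi < length(dv) && big[hi + 1]) hi <- hi + 1
  list(found = TRUE, T_low = temperatures[lo], T_high = temperatures[hi + 1])
}

#' Bracket the glass transition in a density-estimate table
#'
#' @param estimates a `density_estimates` data frame (from
#'   [density_from_transmission()] or [density_from_diffraction()])
#' @param factor threshold multiplier on the median absolute change
#' @return list with `found`, `T_low`, `T_high`
#' @export
detect_transition <- function(estimates, factor = 3) {
  stopifnot(all(c("temperature", "density") %in% names(estimates)))
  o <- order(estimates$temperature)
  detect_transition_series(estimates$temperature[o], estimates$density[o],
                           factor = factor)
}
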