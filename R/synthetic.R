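#' FID acquisition settings
#'
#' @param n_points number of sampled points (>= 2)
#' @param dwell dwell time between points, microseconds
#' @param noise_sd additive Gaussian noise standard deviation, signal units
#' @param seed integer seed making the realisation reproducible
#' @return object of class `acquisition_settings`
#' @export
acquisition_settings <- function(n_points = 2048, dwell = 0.9,
                                 noise_sd = 0, seed = 1) {
  stopifnot(n_points >= 2, dwell > 0, noise_sd >= 0)
  structure(list(n_points = as.integer(n_points), dwell = dwell,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "acquisition_settings")
}

#' Generate a synthetic free induction decay
#'
#' Evaluates the chosen relaxation model on the uniform time grid
#' t_i = i * dwell, i = 0..n_points-1, and adds Gaussian noise.
#'
#' @param params ground-truth [relax_params()]
#' @param model_id 1 or 2; model 1 requires Sg = 0
#' @param acq an [acquisition_settings()]
#' @param temperature sample temperature tag, degrees C
#' @return object of class `fid_signal`: `times` (us), `amplitudes`,
#'   `sigma` (per-point noise sd, NULL when noise-free), `temperature`,
#'   `truth`, `model_id`, `seed`
#' @export
gen_fid <- function(params, model_id, acq = acquisition_settings(),
                    temperature = 25) {
  stopifnot(inherits(params, "relax_params"),
            inherits(acq, "acquisition_settings"))
  if (model_id == 1 && params$Sg > 0)
    stop("model 1 has no Gaussian component; Sg must be 0")
  t <- (seq_len(acq$n_points) - 1) * acq$dwell
  clean <- fid_model(model_id, params, t)
  if (acq$noise_sd > 0) {
    set.seed(acq$seed)
    amp <- clean + stats::rnorm(length(t), 0, acq$noise_sd)
    sigma <- rep(acq$noise_sd, length(t))
  } else {
    amp <- clean
    sigma <- NULL
  }
  structure(list(times = t, amplitudes = amp, sigma = sigma,
                 temperature = temperature, truth = params,
                 model_id = model_id, seed = acq$seed),
            class = "fid_signal")
}

#' Generate a synthetic Tg-versus-water dataset
#'
#' Evaluates the Gordon-Taylor model at the given water fractions and adds
#' Gaussian noise to the glass-transition temperatures.
#'
#' @param gt ground-truth [gt_params()]
#' @param water_fractions wet-basis water mass fractions in \[0, 1)
#' @param noise_sd Gaussian noise on Tg, degrees C
#' @param seed integer seed
#' @return data frame with columns `Xw` and `Tg`
#' @export
gen_dsc_dataset <- function(gt, water_fractions, noise_sd = 0, seed = 1) {
  stopifnot(inherits(gt, "gt_params"), noise_sd >= 0)
  if (any(water_fractions < 0 | water_fractions >= 1))
    stop("water fractions must lie in [0, 1)")
  tg <- gt_tg(water_fractions, gt)
  if (noise_sd > 0) {
    set.seed(seed)
    tg <- tg + stats::rnorm(length(tg), 0, noise_sd)
  }
  data.frame(Xw = water_fractions, Tg = tg)
}

#' Sigmoidal density-versus-temperature schedule
#'
#' A logistic interpolation between a low-temperature (glassy) and a
#' high-temperature (rubbery) mass density, the ground-truth density law the
#' synthetic neutron scenario is driven by.
#'
#' @param rho_glass glassy density, g/cm^3 (must exceed `rho_rubber`)
#' @param rho_rubber rubbery density, g/cm^3
#' @param t_mid transition midpoint, degrees C
#' @param width sigmoid width, degrees C
#' @return object of class `density_schedule`
#' @export
density_schedule <- function(rho_glass = 1.3, rho_rubber = 1.1,
                             t_mid = 50, width = 5) {
  stopifnot(rho_glass > rho_rubber, rho_rubber > 0, width > 0)
  structure(list(rho_glass = rho_glass, rho_rubber = rho_rubber,
                 t_mid = t_mid, width = width),
            class = "density_schedule")
}

#' Density at a temperature under a schedule
#'
#' rho(T) = rho_rubber + (rho_glass - rho_rubber) / (1 + exp((T - t_mid)/width));
#' continuous and monotone non-increasing in temperature.
#'
#' @param schedule a [density_schedule()]
#' @param T_C temperature, degrees C; vectorised
#' @return density, g/cm^3
#' @export
density_at <- function(schedule, T_C) {
  stopifnot(inherits(schedule, "density_schedule"))
  schedule$rho_rubber + (schedule$rho_glass - schedule$rho_rubber) /
    (1 + exp((T_C - schedule$t_mid) / schedule$width))
}

## formula-unit number density (1/cm^3) from mass density and molar mass
.number_density <- function(rho, molar_mass) {
  rho * .N_A / molar_mass
}

#' Generate a synthetic neutron transmission curve
#'
#' T(E) = exp(-n_fu d sigma_total(E)) + Gaussian noise, clipped to (0, 1\],
#' where n_fu is the formula-unit number density from the mass density and
#' the stoichiometric molar mass, d the sample thickness, and sigma_total the
#' functional-group model total cross-section at the sample temperature.
#'
#' @param stoich a [build_stoichiometry()] result
#' @param afga an [afga_model()] (built on the same stoichiometry)
#' @param rho mass density, g/cm^3
#' @param thickness sample thickness, cm
#' @param E_grid incident energies, eV, strictly increasing within
#'   \[1e-3, 1000\]
#' @param noise_sd Gaussian noise on the transmission fraction
#' @param seed integer seed
#' @param temperature sample temperature, degrees C
#' @return object of class `transmission_curve`: `energies` (eV),
#'   `transmission`, `errors`, `temperature`, `thickness`, `clipped`
#'   (TRUE when noise pushed any point out of (0, 1\])
#' @export
gen_transmission <- function(stoich, afga, rho, thickness = 0.3,
                             E_grid = 10^seq(-3, 3, length.out = 400),
                             noise_sd = 0, seed = 1, temperature = 25) {
  stopifnot(inherits(stoich, "stoichiometry"), inherits(afga, "afga_model"),
            rho > 0, thickness > 0, all(diff(E_grid) > 0),
            min(E_grid) >= 1e-3, max(E_grid) <= 1000)
  curve <- total_sigma(E_grid, afga, temperature)
  nd <- .number_density(rho, stoich$molar_mass) * thickness * .barn_cm2
  tr <- exp(-nd * curve$sigma_total)
  clipped <- FALSE
  if (noise_sd > 0) {
    set.seed(seed)
    tr <- tr + stats::rnorm(length(tr), 0, noise_sd)
    if (any(tr <= 0 | tr > 1)) clipped <- TRUE
    tr <- pmin(pmax(tr, 1e-12), 1)
  }
  structure(list(energies = E_grid, transmission = tr,
                 errors = rep(noise_sd, length(E_grid)),
                 temperature = temperature, thickness = thickness,
                 clipped = clipped, seed = seed),
            class = "transmission_curve")
}

## allowed fcc reflections (h,k,l all even or all odd), largest d first
.fcc_d_spacings <- function(a, d_min = 0.5) {
  hkl <- expand.grid(h = 0:6, k = 0:6, l = 0:6)
  hkl <- hkl[rowSums(hkl) > 0, ]
  parity <- (hkl %% 2 == 0)
  allowed <- rowSums(parity) %in% c(0, 3)
  hkl <- hkl[allowed, ]
  s2 <- hkl$h^2 + hkl$k^2 + hkl$l^2
  d <- a / sqrt(s2)
  o <- order(-d)
  out <- data.frame(h = hkl$h[o], k = hkl$k[o], l = hkl$l[o], d = d[o])
  out <- out[!duplicated(round(out$d, 9)) & out$d >= d_min, ]
  rownames(out) <- NULL
  out
}

#' Generate a synthetic neutron diffraction pattern
#'
#' Gaussian Bragg peaks at the allowed fcc aluminium d-spacings (container,
#' temperature-independent) on top of a flat incoherent background
#' proportional to the sample density, plus Gaussian noise.
#'
#' @param rho sample mass density, g/cm^3
#' @param al_scale peak-height scale of the aluminium reflections, counts
#' @param bg_scale incoherent background per unit density, counts/(g/cm^3)
#' @param d_grid d-spacing grid, Angstrom, increasing
#' @param noise_sd Gaussian noise, counts
#' @param seed integer seed
#' @param temperature temperature tag, degrees C
#' @param al_lattice_a aluminium lattice constant, Angstrom
#' @param peak_width Gaussian peak width, Angstrom
#' @return object of class `diffraction_pattern`: `d_spacings`, `counts`,
#'   `errors`, `temperature`, `al_lattice_a`
#' @export
gen_diffraction <- function(rho, al_scale = 500, bg_scale = 100,
                            d_grid = seq(0.8, 4, by = 0.005),
                            noise_sd = 0, seed = 1, temperature = 25,
                            al_lattice_a = 4.0495, peak_width = 0.01) {
  stopifnot(rho > 0, al_scale >= 0, bg_scale >= 0, all(diff(d_grid) > 0))
  counts <- rep(bg_scale * rho, length(d_grid))
  if (al_scale > 0) {
    peaks <- .fcc_d_spacings(al_lattice_a, d_min = min(d_grid))
    for (dpk in peaks$d)
      counts <- counts + al_scale * exp(-((d_grid - dpk) / peak_width)^2 / 2)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    counts <- counts + stats::rnorm(length(counts), 0, noise_sd)
  }
  structure(list(d_spacings = d_grid, counts = counts,
                 errors = rep(noise_sd, length(d_grid)),
                 temperature = temperature, al_lattice_a = al_lattice_a),
            class = "diffraction_pattern")
}

#' Generate synthetic NCS time-of-flight spectra
#'
#' Per detector: counts(t) = sum over masses of I_M * Gaussian(t; t_M, w_M)
#' + flat baseline + noise, with peak centres fixed by recoil kinematics,
#' TOF widths obtained by mapping the per-mass momentum width (resolution
#' added in quadrature) through the local Jacobian, and integrated peak
#' intensities proportional to atom count times free cross-section. The
#' hydrogen peak is omitted at detectors where its recoil kinematics have no
#' solution (theta >= 90 degrees). Noise is Gaussian with sqrt(counts)
#' scaling.
#'
#' @param stoich a [build_stoichiometry()] result (may include Al)
#' @param widths named momentum widths, 1/Angstrom, names = element symbols
#' @param detectors list of [detector_geometry()] objects
#' @param counts_scale overall intensity scale, counts * us
#' @param baseline flat baseline level, counts
#' @param noise logical: add sqrt(counts)-scaled Gaussian noise
#' @param noise_scale multiplier on the sqrt(counts) noise
#' @param seed integer seed
#' @param tof_grid TOF grid, microseconds
#' @param temperature temperature tag, degrees C
#' @return list of `ncs_spectrum` objects, one per detector, each with
#'   `tof`, `counts`, `errors`, `geometry`, `temperature`, `truth`
#' @export
gen_ncs_spectra <- function(stoich, widths, detectors, counts_scale = 1e4,
                            baseline = 5, noise = TRUE, noise_scale = 1,
                            seed = 1, tof_grid = seq(100, 500, by = 0.5),
                            temperature = 25) {
  stopifnot(inherits(stoich, "stoichiometry"), all(widths > 0),
            !is.null(names(widths)), length(detectors) >= 1)
  elements <- intersect(names(stoich$counts), names(widths))
  if (length(elements) == 0) stop("no overlap between stoichiometry and widths")
  set.seed(seed)
  lapply(seq_along(detectors), function(di) {
    geom <- detectors[[di]]
    stopifnot(inherits(geom, "detector_geometry"))
    counts <- rep(baseline, length(tof_grid))
    truth <- list()
    ## relative intensities: atoms x free cross-section, over reachable masses
    reach <- vapply(elements, function(el) {
      A <- mass_ratio(el)
      !(abs(A - 1) < 0.05 && geom$theta >= 90)
    }, TRUE)
    raw_int <- vapply(elements, function(el)
      stoich$counts[[el]] * free_cross_section(.sigma_bound[[el]], mass_ratio(el)), 0)
    rel_int <- raw_int[reach] / sum(raw_int[reach])
    for (el in elements[reach]) {
      A <- mass_ratio(el)
      if (A <= 1.05 && geom$theta >= 90) next
      I_el <- counts_scale * rel_int[[el]]
      counts <- counts + I_el * .tof_peak_profile(tof_grid, geom, A, widths[[el]])
      truth[[el]] <- list(mass = .atomic_mass[[el]], sigma_y = widths[[el]],
                          intensity = I_el, relative_intensity = rel_int[[el]])
    }
    errors <- rep(0, length(tof_grid))
    if (noise) {
      errors <- noise_scale * sqrt(pmax(counts, 1))
      counts <- counts + stats::rnorm(length(counts), 0, errors)
    }
    structure(list(tof = tof_grid, counts = counts, errors = errors,
                   geometry = geom, temperature = temperature, truth = truth),
              class = "ncs_spectrum")
  })
}
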