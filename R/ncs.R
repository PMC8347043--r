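#' Detector geometry of an inverse-geometry TOF spectrometer
#'
#' @param theta scattering angle, degrees, in (0, 180)
#' @param L0 incident flight path, m
#' @param L1 final flight path, m
#' @param E1 fixed final (analysed) neutron energy, meV
#' @param resolution_width detector momentum-resolution width, 1/Angstrom,
#'   added in quadrature to the physical momentum-distribution width
#' @return object of class `detector_geometry`
#' @export
detector_geometry <- function(theta, L0 = 11, L1 = 0.7, E1 = 4897,
                              resolution_width = 0.6) {
  stopifnot(theta > 0, theta < 180, L0 > 0, L1 > 0, E1 > 0,
            resolution_width >= 0)
  structure(list(theta = theta, L0 = L0, L1 = L1, E1 = E1,
                 resolution_width = resolution_width),
            class = "detector_geometry")
}

#' Incident energy of the recoil peak
#'
#' Solves the elastic-recoil (impulse-approximation centroid) condition
#' E0 - E1 = hbar^2 q^2 / (2 M) for the incident energy at which the recoil
#' peak of a nucleus of mass ratio A sits, given the fixed final energy and
#' scattering angle. For A = 1 the closed form is E0 = E1 / cos^2(theta),
#' which has no solution at theta >= 90 degrees: hydrogen recoil peaks are
#' kinematically absent from backscattering detectors.
#'
#' @param theta scattering angle, degrees
#' @param E1 final energy, meV
#' @param A atom-to-neutron mass ratio
#' @return incident energy E0, meV
#' @export
recoil_incident_energy <- function(theta, E1, A) {
  stopifnot(theta > 0, theta < 180, E1 > 0, A > 0)
  ct <- cos(theta * pi / 180)
  if (abs(A - 1) < 1e-9) {
    if (theta >= 90)
      stop("no recoil solution for mass ratio 1 at theta >= 90 degrees")
    return(E1 / ct^2)
  }
  ## (A-1) r^2 + 2 r cos(theta) - (A+1) = 0, r = sqrt(E0/E1); physical root > 0
  disc <- ct^2 + A^2 - 1
  if (disc < 0) stop("no recoil solution at this angle for A = ", A)
  r <- (-ct + sqrt(disc)) / (A - 1)
  if (r <= 0) stop("no physical recoil solution at this angle for A = ", A)
  E1 * r^2
}

#' Time of flight for a given incident energy
#'
#' t = L0/v0 + L1/v1 with v\[m/s\] = 437.39 sqrt(E\[meV\]).
#'
#' @param E0 incident energy, meV; vectorised
#' @param geometry a [detector_geometry()]
#' @return time of flight, microseconds
#' @export
tof_of <- function(E0, geometry) {
  stopifnot(all(E0 > 0), inherits(geometry, "detector_geometry"))
  v0 <- .v_const * sqrt(E0)
  v1 <- .v_const * sqrt(geometry$E1)
  (geometry$L0 / v0 + geometry$L1 / v1) * 1e6
}

## invert tof -> E0 (meV); NA where no physical solution
.e0_of_tof <- function(tof_us, geometry) {
  v1 <- .v_const * sqrt(geometry$E1)
  t0 <- tof_us * 1e-6 - geometry$L1 / v1
  E0 <- rep(NA_real_, length(tof_us))
  ok <- t0 > 0
  v0 <- geometry$L0 / t0[ok]
  E0[ok] <- (v0 / .v_const)^2
  E0
}

## momentum transfer q (1/A) at (E0, E1, theta)
.q_of <- function(E0, E1, theta_deg) {
  k0 <- sqrt(E0 / (.hbar2_over_mn / 2))
  k1 <- sqrt(E1 / (.hbar2_over_mn / 2))
  sqrt(pmax(k0^2 + k1^2 - 2 * k0 * k1 * cos(theta_deg * pi / 180), 0))
}

## longitudinal momentum y (1/A) of a TOF bin for a nucleus of mass ratio A
.y_of_tof <- function(tof_us, geometry, A) {
  E0 <- .e0_of_tof(tof_us, geometry)
  omega <- E0 - geometry$E1                       # meV
  q <- .q_of(E0, geometry$E1, geometry$theta)     # 1/A
  recoil <- (.hbar2_over_mn / A) * q^2 / 2        # meV
  A * (omega - recoil) / (.hbar2_over_mn * q)
}

## |dy/dt| (1/A per us) by central differences on the TOF grid
.dydt_of_tof <- function(tof_us, geometry, A) {
  h <- 1e-3
  abs(.y_of_tof(tof_us + h, geometry, A) - .y_of_tof(tof_us - h, geometry, A)) / (2 * h)
}

#' Transform a TOF spectrum to longitudinal momentum space
#'
#' Maps each TOF bin to the longitudinal momentum variable
#' y = (M/hbar q)(omega - hbar q^2/2M) of the chosen mass, applies the local
#' Jacobian to the intensities, and normalises the resulting momentum
#' distribution J(y) to unit area. Bins with no kinematic solution are
#' dropped with a warning.
#'
#' @param spectrum an `ncs_spectrum` (see [gen_ncs_spectra()])
#' @param mass atom mass, amu
#' @return data frame with columns `y` (1/Angstrom, increasing) and `J`
#'   (normalised to unit integral)
#' @export
y_transform <- function(spectrum, mass) {
  stopifnot(inherits(spectrum, "ncs_spectrum"), mass > 0)
  A <- mass / .m_neutron_amu
  geom <- spectrum$geometry
  y <- .y_of_tof(spectrum$tof, geom, A)
  dydt <- .dydt_of_tof(spectrum$tof, geom, A)
  ok <- is.finite(y) & is.finite(dydt) & dydt > 0
  if (!all(ok)) warning(sum(!ok), " TOF bins had no kinematic solution and were dropped")
  y <- y[ok]
  J <- spectrum$counts[ok] / dydt[ok]
  o <- order(y)
  y <- y[o]; J <- J[o]
  area <- pracma::trapz(y, J)
  if (!is.finite(area) || area == 0) stop("cannot normalise: zero integrated intensity")
  data.frame(y = y, J = J / area)
}

## TOF-domain peak description for one mass at one detector: centre (us) and
## the Jacobian scale mapping a momentum width (1/A) to a TOF width (us)
.peak_geometry <- function(geometry, A) {
  E0c <- recoil_incident_energy(geometry$theta, geometry$E1, A)
  tc <- tof_of(E0c, geometry)
  dydt <- .dydt_of_tof(tc, geometry, A)
  list(center = tc, dydt = dydt)
}

## unit-area Gaussian column in TOF for mass ratio A with momentum width
## sigma_y, detector resolution added in quadrature
.tof_peak_profile <- function(tof, geometry, A, sigma_y) {
  pg <- .peak_geometry(geometry, A)
  w_y <- sqrt(sigma_y^2 + geometry$resolution_width^2)
  w_t <- w_y / pg$dydt
  stats::dnorm(tof, mean = pg$center, sd = w_t)
}

## masses reachable at a detector (drops mass-ratio-1 for theta >= 90)
.reachable_masses <- function(masses, geometry) {
  keep <- vapply(masses, function(m) {
    A <- m / .m_neutron_amu
    !(abs(A - 1) < 0.05 && geometry$theta >= 90)
  }, TRUE)
  masses[keep]
}

#' Variable-projection fit of one NCS detector spectrum
#'
#' Separable nonlinear least squares: recoil-peak centres are fixed by the
#' scattering kinematics; for each trial vector of momentum widths the
#' relative peak intensities (and a flat baseline) are solved by nonnegative
#' linear least squares, and an outer bounded quasi-Newton search optimises
#' the widths only. Masses whose recoil kinematics have no solution at this
#' detector (hydrogen in backscattering) are excluded automatically.
#'
#' @param spectrum an `ncs_spectrum`
#' @param masses atom masses to fit, amu
#' @param init_widths named (by mass) or positional initial momentum widths,
#'   1/Angstrom
#' @param fix_widths logical: skip the outer width search and only solve the
#'   linear subproblem at `init_widths`
#' @return list with `masses`, `widths` (1/Angstrom), `intensities`
#'   (integrated peak areas, counts * us), `relative_intensities` (summing to
#'   1 over fitted masses), `baseline`, `rss`, `converged`
#' @export
varpro_fit_detector <- function(spectrum, masses, init_widths,
                                fix_widths = FALSE) {
  stopifnot(inherits(spectrum, "ncs_spectrum"), length(masses) >= 1,
            length(init_widths) == length(masses), all(init_widths > 0))
  geom <- spectrum$geometry
  keep <- masses %in% .reachable_masses(masses, geom)
  masses_fit <- masses[keep]
  widths0 <- init_widths[keep]
  if (length(masses_fit) == 0) stop("no fittable masses at this detector")
  tof <- spectrum$tof
  y <- spectrum$counts
  A_ratios <- masses_fit / .m_neutron_amu

  design <- function(widths) {
    cols <- vapply(seq_along(masses_fit), function(j)
      .tof_peak_profile(tof, geom, A_ratios[j], widths[j]), numeric(length(tof)))
    cbind(cols, baseline = 1)
  }
  centers <- vapply(A_ratios, function(A) .peak_geometry(geom, A)$center, 0)
  if (any(duplicated(round(centers, 6))))
    stop("coincident recoil peaks: design matrix is singular")

  solve_linear <- function(widths) {
    X <- design(widths)
    sol <- pracma::lsqnonneg(X, y)
    list(coef = sol$x, rss = sum((y - X %*% sol$x)^2))
  }

  if (fix_widths || length(masses_fit) == 0) {
    widths <- widths0
    converged <- TRUE
  } else {
    obj <- function(lw) solve_linear(exp(lw))$rss
    opt <- stats::optim(log(widths0), obj, method = "L-BFGS-B",
                        lower = log(widths0) - log(5),
                        upper = log(widths0) + log(5),
                        control = list(maxit = 200, factr = 1e4))
    widths <- exp(opt$par)
    converged <- opt$convergence == 0
  }
  lin <- solve_linear(widths)
  k <- length(masses_fit)
  intensities <- lin$coef[seq_len(k)]
  rel <- if (sum(intensities) > 0) intensities / sum(intensities)
         else rep(NA_real_, k)
  list(masses = masses_fit, widths = unname(widths),
       intensities = unname(intensities),
       relative_intensities = unname(rel),
       baseline = lin$coef[k + 1], rss = lin$rss, converged = converged)
}

#' Self-consistent aggregation of detector-by-detector NCS fits
#'
#' Iterates: fit every detector by [varpro_fit_detector()], combine the
#' per-detector momentum widths by an inverse-residual-weighted average,
#' restart each detector fit from the combined widths, until the widths
#' change by less than `tol` (relative) or `n_iterations` is reached.
#' Relative intensities are averaged across detectors that see each mass and
#' renormalised to sum to one.
#'
#' @param spectra list of `ncs_spectrum` objects (one per detector)
#' @param masses atom masses to fit, amu
#' @param init_widths initial momentum widths, 1/Angstrom (one per mass)
#' @param n_iterations maximum outer iterations
#' @param tol relative width-change convergence tolerance
#' @return object of class `nmd_result`: data frame `table` with one row per
#'   mass (`mass`, `width`, `width_se`, `relative_intensity`), plus
#'   `converged`, `n_iterations_used`, `detector_fits`
#' @export
aggregate_detectors <- function(spectra, masses, init_widths,
                                n_iterations = 10, tol = 1e-4) {
  stopifnot(length(spectra) >= 1, all(init_widths > 0))
  widths <- init_widths
  converged <- FALSE
  iter_used <- 0
  fits <- NULL
  for (it in seq_len(n_iterations)) {
    iter_used <- it
    fits <- lapply(spectra, function(sp) varpro_fit_detector(sp, masses, widths))
    new_widths <- widths
    for (j in seq_along(masses)) {
      vals <- c(); wts <- c()
      for (f in fits) {
        idx <- match(masses[j], f$masses)
        if (!is.na(idx) && f$intensities[idx] > 0) {
          vals <- c(vals, f$widths[idx])
          wts <- c(wts, 1 / max(f$rss, 1e-12))
        }
      }
      if (length(vals) > 0) new_widths[j] <- sum(vals * wts) / sum(wts)
    }
    delta <- max(abs(new_widths - widths) / widths)
    widths <- new_widths
    if (delta < tol) { converged <- TRUE; break }
  }
  ## relative intensities: average over detectors that see the full mass set
  ## (a detector blind to hydrogen would skew the mixture); fall back to
  ## per-mass averages renormalised when no detector sees everything
  full <- Filter(function(f) length(f$masses) == length(masses), fits)
  if (length(full) > 0) {
    rel <- Reduce(`+`, lapply(full, function(f)
      f$relative_intensities[match(masses, f$masses)])) / length(full)
  } else {
    rel <- vapply(seq_along(masses), function(j) {
      vals <- unlist(lapply(fits, function(f) {
        idx <- match(masses[j], f$masses)
        if (is.na(idx)) NULL else f$relative_intensities[idx]
      }))
      if (length(vals) > 0) mean(vals) else NA_real_
    }, 0)
  }
  rel <- rel / sum(rel, na.rm = TRUE)
  width_se <- vapply(seq_along(masses), function(j) {
    vals <- unlist(lapply(fits, function(f) {
      idx <- match(masses[j], f$masses)
      if (is.na(idx)) NULL else f$widths[idx]
    }))
    if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else 0
  }, 0)
  structure(
    list(table = data.frame(mass = masses, width = widths, width_se = width_se,
                            relative_intensity = rel),
         converged = converged, n_iterations_used = iter_used,
         detector_fits = fits),
    class = "nmd_result"
  )
}

#' Compare fitted hydrogen momentum widths with the functional-group model
#'
#' Tabulates, per temperature, the fitted hydrogen momentum-distribution
#' width against the harmonic functional-group prediction.
#'
#' @param ncs_results named list of `nmd_result` objects; names are
#'   temperatures in degrees C
#' @param model an [afga_model()]
#' @param h_mass hydrogen mass used in the fits, amu
#' @return data frame with columns `temperature`, `sigma_exp`, `sigma_model`,
#'   `delta`
#' @export
compare_widths_to_afga <- function(ncs_results, model, h_mass = 1.00794) {
  stopifnot(length(ncs_results) >= 1, !is.null(names(ncs_results)))
  temps <- as.numeric(names(ncs_results))
  rows <- lapply(seq_along(temps), function(i) {
    res <- ncs_results[[i]]
    idx <- which(abs(res$table$mass - h_mass) < 0.05)
    if (length(idx) == 0) stop("no hydrogen mass in fit at ", temps[i], " degC")
    sig_exp <- res$table$width[idx[1]]
    sig_mod <- afga_h_width(model, temps[i])
    data.frame(temperature = temps[i], sigma_exp = sig_exp,
               sigma_model = sig_mod, delta = sig_exp - sig_mod)
  })
  do.call(rbind, rows)
}
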