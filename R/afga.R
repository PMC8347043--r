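#' Sample stoichiometry from moisture content
#'
#' Builds the formula-unit stoichiometry C6H10O5 (H2O)_nu of a hydrated
#' anhydroglucose polymer. The number of water molecules per anhydroglucose
#' unit is nu = (g water / g dry matter) * M(C6H10O5) / M(H2O).
#'
#' @param moisture a [moisture_value()]; converted to dry-matter basis
#'   internally
#' @param include_al logical; add one aluminium atom per formula unit to
#'   represent a container contribution (off by default — the container is
#'   normally handled separately)
#' @return object of class `stoichiometry` with element counts per formula
#'   unit, the molar mass (g/mol), and `water_per_glucose` (nu)
#' @examples
#' build_stoichiometry(moisture_value(0.1069, "wet"))
#' @export
build_stoichiometry <- function(moisture, include_al = FALSE) {
  stopifnot(inherits(moisture, "moisture_value"))
  dm <- moisture_convert(moisture, "dry_matter")$value
  m_glucose <- 6 * .atomic_mass[["C"]] + 10 * .atomic_mass[["H"]] +
    5 * .atomic_mass[["O"]]
  m_water <- 2 * .atomic_mass[["H"]] + .atomic_mass[["O"]]
  nu <- dm * m_glucose / m_water
  counts <- c(H = 10 + 2 * nu, C = 6, O = 5 + nu)
  if (include_al) counts <- c(counts, Al = 1)
  molar_mass <- sum(counts * .atomic_mass[names(counts)])
  structure(
    list(counts = counts, molar_mass = unname(molar_mass),
         water_per_glucose = unname(nu)),
    class = "stoichiometry"
  )
}

#' @export
print.stoichiometry <- function(x, ...) {
  cat(sprintf("C%.4g H%.4g O%.4g%s  (nu = %.4g, M = %.2f g/mol)\n",
              x$counts[["C"]], x$counts[["H"]], x$counts[["O"]],
              if ("Al" %in% names(x$counts)) sprintf(" Al%.4g", x$counts[["Al"]]) else "",
              x$water_per_glucose, x$molar_mass))
  invisible(x)
}

#' Free-atom scattering cross-section
#'
#' Reduces a bound cross-section to the free-atom value by the reduced-mass
#' factor (A/(A+1))^2, where A is the atom-to-neutron mass ratio. This is the
#' epithermal (impulse) limit reached by total cross-section curves above a
#' few eV.
#'
#' @param sigma_bound bound cross-section, barns
#' @param A mass ratio of the atom to the neutron
#' @return free cross-section, barns
#' @export
free_cross_section <- function(sigma_bound, A) {
  if (any(A <= 0)) stop("mass ratio A must be positive")
  sigma_bound * (A / (A + 1))^2
}

#' Harmonic effective temperature of a mode set
#'
#' T* = sum_i w_i (hw_i / 2 kB) coth(hw_i / 2 kB T) / sum_i w_i, the
#' temperature a free gas must have for its mean kinetic energy to match the
#' harmonic oscillator average over the given modes. Reduces to T in the
#' classical limit and to the zero-point value hw/2kB as T -> 0.
#'
#' @param mode_energies vibrational mode energies, meV
#' @param weights degeneracy weights (one per mode)
#' @param T_K temperature, kelvin
#' @return effective temperature, kelvin
#' @export
effective_temperature <- function(mode_energies, weights = rep(1, length(mode_energies)), T_K) {
  stopifnot(length(mode_energies) == length(weights), T_K > 0,
            all(mode_energies > 0))
  z <- mode_energies / (2 * .kB_meV * T_K)
  t_star_modes <- (mode_energies / (2 * .kB_meV)) / tanh(z)
  sum(weights * t_star_modes) / sum(weights)
}

#' Functional group definition
#'
#' A hydrogen-bearing functional group (or heavy-atom pseudo-group) with its
#' vibrational mode energies, used by the additive functional-group
#' cross-section model.
#'
#' @param name group label; one of the built-in names (`"CH2"`, `"CH"`,
#'   `"OH"`, `"water_OH"`, `"C_heavy"`, `"O_heavy"`, `"Al_heavy"`) or custom
#' @param element scattering element of the group (`"H"` for hydrogen groups)
#' @param count atoms of that element contributed per formula unit
#' @param mode_energies mode energies, meV (defaults from the built-in table)
#' @param weights degeneracy weights; must sum to 3 (one per direction)
#' @return object of class `functional_group`
#' @export
functional_group <- function(name, element, count,
                             mode_energies = NULL, weights = NULL) {
  if (is.null(mode_energies)) {
    if (!name %in% names(.default_group_modes))
      stop("no default modes for group '", name, "'; supply mode_energies")
    mode_energies <- .default_group_modes[[name]]$energies
    weights <- .default_group_modes[[name]]$weights
  }
  if (is.null(weights)) weights <- rep(3 / length(mode_energies), length(mode_energies))
  if (abs(sum(weights) - 3) > 1e-9)
    stop("mode weights must sum to 3 (three momentum directions)")
  if (any(mode_energies <= 0)) stop("mode energies must be positive")
  stopifnot(element %in% names(.atomic_mass), count >= 0)
  structure(
    list(name = name, element = element, count = count,
         mode_energies = mode_energies, weights = weights,
         A = mass_ratio(element),
         sigma_free = free_cross_section(.sigma_bound[[element]], mass_ratio(element))),
    class = "functional_group"
  )
}

#' Additive functional-group cross-section model
#'
#' Assembles the per-formula-unit group decomposition of a hydrated
#' anhydroglucose stoichiometry: hydrogens split into CH2 (2), CH (5) and
#' matrix OH (3) per glucose unit plus 2*nu water hydrogens, and heavy atoms
#' carried as free-gas pseudo-groups. The model's total cross-section is the
#' stoichiometry-weighted sum of independent group contributions.
#'
#' @param stoich a [build_stoichiometry()] result
#' @param groups optional list of [functional_group()] objects overriding the
#'   default decomposition
#' @return object of class `afga_model`
#' @export
afga_model <- function(stoich, groups = NULL) {
  stopifnot(inherits(stoich, "stoichiometry"))
  nu <- stoich$water_per_glucose
  if (is.null(groups)) {
    groups <- list(
      functional_group("CH2", "H", 2),
      functional_group("CH", "H", 5),
      functional_group("OH", "H", 3),
      functional_group("water_OH", "H", 2 * nu),
      functional_group("C_heavy", "C", stoich$counts[["C"]]),
      functional_group("O_heavy", "O", stoich$counts[["O"]])
    )
    if ("Al" %in% names(stoich$counts))
      groups <- c(groups, list(functional_group("Al_heavy", "Al", stoich$counts[["Al"]])))
  }
  h_in_groups <- sum(vapply(groups, function(g) if (g$element == "H") g$count else 0, 0))
  if (abs(h_in_groups - stoich$counts[["H"]]) > 1e-6)
    stop(sprintf("group hydrogen count (%.4f) does not match stoichiometry (%.4f)",
                 h_in_groups, stoich$counts[["H"]]))
  structure(list(groups = groups, stoichiometry = stoich), class = "afga_model")
}

#' Free-gas Doppler-broadened total cross-section of one group
#'
#' Evaluates the ideal-gas total scattering cross-section at the group's
#' harmonic effective temperature:
#' sigma(E) = sigma_free * \[(1 + 1/(2x^2)) erf(x) + exp(-x^2)/(x sqrt(pi))\]
#' with x^2 = A E / (kB T*). Per atom of the group's element, multiplied by
#' the per-formula-unit count. Approaches sigma_free * count at epithermal
#' energies and follows the 1/v law as E -> 0.
#'
#' @param E incident neutron energy, eV; vectorised
#' @param group a [functional_group()]
#' @param T_C sample temperature, degrees C
#' @return cross-section, barns per formula unit
#' @export
group_sigma <- function(E, group, T_C) {
  stopifnot(inherits(group, "functional_group"), all(E > 0))
  T_star <- effective_temperature(group$mode_energies, group$weights, T_C + 273.15)
  E_meV <- E * 1000
  x2 <- group$A * E_meV / (.kB_meV * T_star)
  x <- sqrt(x2)
  broad <- (1 + 1 / (2 * x2)) * pracma::erf(x) + exp(-x2) / (x * sqrt(pi))
  group$count * group$sigma_free * broad
}

#' Total cross-section curve of a functional-group model
#'
#' @param E_grid incident energies, eV (increasing)
#' @param model an [afga_model()]
#' @param T_C temperature, degrees C
#' @return object of class `xs_curve` with fields `energies` (eV),
#'   `sigma_total` (barns per formula unit) and `temperature` (degrees C)
#' @export
total_sigma <- function(E_grid, model, T_C) {
  stopifnot(inherits(model, "afga_model"), all(diff(E_grid) > 0))
  sig <- Reduce(`+`, lapply(model$groups, function(g) group_sigma(E_grid, g, T_C)))
  structure(list(energies = E_grid, sigma_total = sig, temperature = T_C),
            class = "xs_curve")
}

#' Stoichiometry-weighted free cross-section per formula unit
#'
#' The epithermal plateau value Sigma_free = sum over elements of
#' count * sigma_free, barns per formula unit.
#'
#' @param stoich a [build_stoichiometry()] result
#' @return barns per formula unit
#' @export
sigma_free_total <- function(stoich) {
  stopifnot(inherits(stoich, "stoichiometry"))
  sum(vapply(names(stoich$counts), function(el) {
    stoich$counts[[el]] * free_cross_section(.sigma_bound[[el]], mass_ratio(el))
  }, 0))
}

#' Integral of a cross-section curve over a thermal-energy window
#'
#' Trapezoidal integral of sigma_total(E) over \[lo, hi\] meV, the fixed
#' low-energy window in which the thermal part of the total cross-section is
#' most sensitive to vibrational softening.
#'
#' @param curve an `xs_curve`
#' @param lo,hi window bounds, meV
#' @return integral, barns * meV; warns when the grid is coarser than a tenth
#'   of the window
#' @export
window_integral <- function(curve, lo = 2.6, hi = 10) {
  stopifnot(inherits(curve, "xs_curve"), hi > lo)
  E_meV <- curve$energies * 1000
  if (min(E_meV) > lo || max(E_meV) < hi)
    stop("energy grid does not cover the integration window")
  inside <- E_meV >= lo & E_meV <= hi
  E_w <- c(lo, E_meV[inside], hi)
  sig_w <- c(stats::approx(E_meV, curve$sigma_total, xout = lo)$y,
             curve$sigma_total[inside],
             stats::approx(E_meV, curve$sigma_total, xout = hi)$y)
  keep <- !duplicated(E_w)
  E_w <- E_w[keep]; sig_w <- sig_w[keep]
  if (max(diff(E_w)) > (hi - lo) / 10)
    warning("energy grid is coarse inside the window; integral may be inaccurate")
  pracma::trapz(E_w, sig_w)
}

#' Harmonic prediction of the nuclear momentum distribution width
#'
#' Width (standard deviation, 1/Angstrom) of the Gaussian momentum
#' distribution of an atom bound in a set of harmonic modes:
#' sigma_y^2 = (1/3) sum_i w_i * A hbar w_i coth(hbar w_i / 2 kB T) /
#' (2 hbar^2/m_n). Weights sum to 3; in the classical limit this reduces to
#' the Maxwell-Boltzmann width sqrt(A kB T / (hbar^2/m_n)).
#'
#' @param mode_energies mode energies, meV
#' @param weights degeneracy weights summing to 3
#' @param T_C temperature, degrees C
#' @param mass atom mass, amu
#' @return momentum-distribution width, 1/Angstrom
#' @export
nmd_width <- function(mode_energies, weights = rep(1, length(mode_energies)),
                      T_C, mass) {
  stopifnot(T_C > -273.15, all(mode_energies > 0), mass > 0)
  A <- mass / .m_neutron_amu
  T_K <- T_C + 273.15
  z <- mode_energies / (2 * .kB_meV * T_K)
  sigma2 <- sum(weights * A * mode_energies / tanh(z)) / (3 * 2 * .hbar2_over_mn)
  sqrt(sigma2)
}

#' Hydrogen momentum-width prediction of a functional-group model
#'
#' Averages the per-group harmonic width prediction over all hydrogen-bearing
#' groups, weighted by their hydrogen counts (widths combined in quadrature,
#' i.e. variances averaged — the observed distribution is the count-weighted
#' mixture of group distributions).
#'
#' @param model an [afga_model()]
#' @param T_C temperature, degrees C
#' @return hydrogen momentum-distribution width, 1/Angstrom
#' @export
afga_h_width <- function(model, T_C) {
  stopifnot(inherits(model, "afga_model"))
  hgroups <- Filter(function(g) g$element == "H" && g$count > 0, model$groups)
  if (length(hgroups) == 0) stop("model contains no hydrogen groups")
  counts <- vapply(hgroups, `[[`, 0, "count")
  vars <- vapply(hgroups, function(g)
    nmd_width(g$mode_energies, g$weights, T_C, .atomic_mass[["H"]])^2, 0)
  sqrt(sum(counts * vars) / sum(counts))
}
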