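test_that("recoil kinematics: heavy limit, hydrogen closed form, exclusion", {
  # heavy atom scatters elastically
  expect_equal(recoil_incident_energy(60, 4897, 1e6), 4897, tolerance = 1e-2)
  # hydrogen (A = 1): E0 = E1 / cos^2(theta)
  expect_equal(recoil_incident_energy(60, 4897, 1), 19588, tolerance = 1e-9)
  expect_error(recoil_incident_energy(135, 4897, 1), "no recoil")
  # numeric oracle for carbon: solve the conservation equation directly
  A <- 12.011 / 1.00866492
  E1 <- 4897; theta <- 60
  f <- function(E0) {
    k0 <- sqrt(E0 / 2.0717); k1 <- sqrt(E1 / 2.0717)
    q2 <- k0^2 + k1^2 - 2 * k0 * k1 * cos(theta * pi / 180)
    (E0 - E1) - 2.0717 * q2 / A
  }
  E0_num <- stats::uniroot(f, c(E1 + 1e-6, 10 * E1), tol = 1e-10)$root
  expect_equal(recoil_incident_energy(theta, E1, A), E0_num, tolerance = 1e-7)
})

test_that("time of flight: symmetry, worked value, monotonicity", {
  g_sym <- detector_geometry(60, L0 = 1, L1 = 1, E1 = 4897)
  v1 <- 437.39 * sqrt(4897)
  expect_equal(tof_of(4897, g_sym), 2 / v1 * 1e6, tolerance = 1e-9)
  g <- detector_geometry(60, L0 = 11, L1 = 0.7, E1 = 4897)
  expect_equal(tof_of(19588, g), 202.6, tolerance = 0.1)
  E <- seq(5000, 50000, length.out = 50)
  expect_true(all(diff(tof_of(E, g)) < 0))
})

test_that("momentum-space transform: peak at y = 0, width recovery, normalisation", {
  st <- pasta_stoich(TRUE)
  one <- gen_ncs_spectra(st, c(H = 4.9), list(detector_geometry(60)),
                         baseline = 0, noise = FALSE)[[1]]
  jy <- y_transform(one, 1.00794)
  expect_equal(pracma::trapz(jy$y, jy$J), 1, tolerance = 1e-6)
  mu <- pracma::trapz(jy$y, jy$y * jy$J)
  expect_lt(abs(mu), 0.15)
  s2 <- pracma::trapz(jy$y, (jy$y - mu)^2 * jy$J)
  # generator width + instrument resolution in quadrature
  expect_equal(sqrt(s2), sqrt(4.9^2 + 0.6^2), tolerance = 0.02 * 4.9)
})

test_that("single-mass noise-free variable projection is exact", {
  st <- pasta_stoich(TRUE)
  sp <- gen_ncs_spectra(st, c(H = 4.9), list(detector_geometry(60)),
                        counts_scale = 1e4, baseline = 2, noise = FALSE)[[1]]
  f <- varpro_fit_detector(sp, 1.00794, 4.2)
  expect_equal(f$widths, 4.9, tolerance = 1e-6)
  expect_equal(f$intensities, 1e4, tolerance = 1e-2)
  expect_equal(f$baseline, 2, tolerance = 1e-6)
})

test_that("intensities at fixed widths equal the linear-algebra oracle", {
  st <- pasta_stoich(TRUE)
  sp <- gen_ncs_spectra(st, ncs_widths, list(detector_geometry(55)),
                        counts_scale = 1e4, baseline = 3, noise = FALSE)[[1]]
  truth_w <- unname(ncs_widths[c("H", "C", "O", "Al")])
  f <- varpro_fit_detector(sp, ncs_masses, truth_w, fix_widths = TRUE)
  # oracle: direct normal-equations solve (interior solution, so the
  # nonnegativity constraint is inactive)
  X <- vapply(seq_along(ncs_masses), function(j)
    glassprobe:::.tof_peak_profile(sp$tof, sp$geometry,
                                   ncs_masses[j] / 1.00866492, truth_w[j]),
    numeric(length(sp$tof)))
  X <- cbind(X, 1)
  beta <- solve(crossprod(X), crossprod(X, sp$counts))
  expect_equal(unname(f$intensities), unname(beta[1:4, 1]), tolerance = 1e-8)
})

test_that("three-mass recovery at 1% noise over seeds", {
  st <- pasta_stoich()
  truth_w <- ncs_widths[c("H", "C", "O")]
  errs <- t(vapply(1:20, function(s) {
    sp <- gen_ncs_spectra(st, truth_w, list(detector_geometry(60)),
                          counts_scale = 2e5, baseline = 5,
                          noise = TRUE, noise_scale = 1, seed = s)[[1]]
    f <- varpro_fit_detector(sp, ncs_masses[1:3], unname(truth_w) * 1.15)
    abs(f$widths / unname(truth_w) - 1)
  }, numeric(3)))
  expect_true(all(apply(errs, 2, stats::median) < 0.05))
})

test_that("hydrogen is never fitted at backscattering angles", {
  st <- pasta_stoich(TRUE)
  for (theta in c(90, 120, 150, 170)) {
    sp <- gen_ncs_spectra(st, ncs_widths, list(detector_geometry(theta)),
                          noise = FALSE)[[1]]
    f <- varpro_fit_detector(sp, ncs_masses, unname(ncs_widths))
    expect_false(any(abs(f$masses - 1.00794) < 0.05))
  }
})

test_that("aggregation over identical detectors equals the single fit", {
  st <- pasta_stoich(TRUE)
  sp <- gen_ncs_spectra(st, ncs_widths, list(detector_geometry(60)),
                        counts_scale = 1e5, noise = FALSE)[[1]]
  single <- varpro_fit_detector(sp, ncs_masses, unname(ncs_widths) * 1.1)
  agg <- aggregate_detectors(list(sp, sp), ncs_masses,
                             unname(ncs_widths) * 1.1)
  expect_equal(agg$table$width, single$widths, tolerance = 1e-4)
  expect_equal(sum(agg$table$relative_intensity), 1, tolerance = 1e-12)
  expect_true(agg$converged)
})

test_that("fitted composition is constant across a temperature series", {
  st <- pasta_stoich()
  dets <- list(detector_geometry(50), detector_geometry(65))
  rels <- t(vapply(seq_along(neutron_temps), function(i) {
    sp <- gen_ncs_spectra(st, ncs_widths[c("H", "C", "O")], dets,
                          counts_scale = 2e5, noise = TRUE, seed = 300 + i,
                          temperature = neutron_temps[i])
    agg <- aggregate_detectors(sp, ncs_masses[1:3],
                               unname(ncs_widths[c("H", "C", "O")]))
    agg$table$relative_intensity
  }, numeric(3)))
  # composition does not drift: spread below 2% absolute per species
  expect_lt(max(apply(rels, 2, function(x) diff(range(x)))), 0.02)
  expect_equal(rowSums(rels), rep(1, nrow(rels)), tolerance = 1e-12)
})

test_that("fitted widths track the functional-group prediction when generated from it", {
  st <- pasta_stoich()
  model <- afga_model(st)
  temps <- c(-20, 20, 80)
  results <- lapply(temps, function(tt) {
    w_h <- afga_h_width(model, tt)
    sp <- gen_ncs_spectra(st, c(H = w_h, C = 14, O = 12.5),
                          list(detector_geometry(60)), counts_scale = 2e5,
                          noise = FALSE, temperature = tt)
    aggregate_detectors(sp, ncs_masses[1:3], c(w_h * 1.1, 15, 11))
  })
  names(results) <- temps
  cmp <- compare_widths_to_afga(results, model)
  expect_lt(max(abs(cmp$delta)), 0.05)
  # the prediction itself is flat to 2%
  expect_lt(diff(range(cmp$sigma_model)) / min(cmp$sigma_model), 0.02)
})
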