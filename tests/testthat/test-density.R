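test_that("scattering power inverts the plateau transmission", {
  st <- pasta_stoich(); mod <- afga_model(st)
  tc <- gen_transmission(st, mod, rho = 1.3, thickness = 0.3)
  s <- scattering_power(tc)
  n_fu_d <- 1.3 * 6.02214076e23 / st$molar_mass * 0.3
  expect_equal(s$value, n_fu_d * sigma_free_total(st) * 1e-24,
               tolerance = 2e-3)
  expect_equal(s$value, 0.389, tolerance = 1e-2)
  # unit transmission -> zero scattering power
  flat <- tc; flat$transmission[] <- 1
  expect_equal(scattering_power(flat)$value, 0)
  expect_error(scattering_power(tc, window = c(900, 999)), "5 grid points")
})

test_that("transmission-to-cross-section round trip and density scaling", {
  st <- pasta_stoich(); mod <- afga_model(st)
  tc <- gen_transmission(st, mod, rho = 1.3, temperature = 40)
  back <- transmission_to_sigma(tc, 1.3, st)
  truth <- total_sigma(tc$energies, mod, 40)
  expect_equal(back$sigma_total, truth$sigma_total,
               tolerance = 1e-10)
  half <- transmission_to_sigma(tc, 0.65, st)
  expect_equal(half$sigma_total, 2 * back$sigma_total, tolerance = 1e-12)
})

test_that("calibrated transmission densitometry recovers the schedule", {
  sc <- density_scenario()
  est <- density_from_transmission(sc$transmission)
  expect_equal(est$density[est$temperature == -20], 1.3)  # exact by construction
  truth <- density_at(sc$schedule, est$temperature)
  expect_lt(max(abs(est$density - truth)), 1e-3)
  # halved scattering power maps to 0.65
  tr <- sc$transmission
  s_ref <- scattering_power(tr[[1]])$value
  fake <- tr[[2]]
  fake$transmission <- exp(-0.5 * s_ref + 0 * fake$transmission)
  est2 <- density_from_transmission(list(tr[[1]], fake))
  expect_equal(est2$density[2], 0.65, tolerance = 1e-9)
  expect_error(density_from_transmission(tr, T_ref = 999), "reference")
})

test_that("background integral excludes aluminium reflections by name", {
  flat <- gen_diffraction(rho = 1.3, al_scale = 0, bg_scale = 100,
                          d_grid = seq(2.4, 3.6, by = 0.001))
  bi <- background_integral(flat, window = c(2.5, 3.5))
  expect_equal(bi$value, 130, tolerance = 1e-6)
  # largest allowed fcc d-spacing for a = 4.0495 is (111) at 2.338 A,
  # so [2.5, 3.5] is clean but a window containing 2.338 is rejected
  pat <- gen_diffraction(rho = 1.3)
  expect_error(background_integral(pat, window = c(2.2, 3.5)), "111")
})

test_that("calibrated diffraction densitometry is exact without noise", {
  sc <- density_scenario()
  est <- density_from_diffraction(sc$diffraction)
  expect_equal(est$density[est$temperature == -20], 1.3)
  # exact up to the calibration convention: the estimator pins -20 degC to
  # 1.3 while the sigmoid sits 1.7e-7 below its glassy asymptote there
  truth <- 1.3 * density_at(sc$schedule, est$temperature) /
    density_at(sc$schedule, -20)
  expect_lt(max(abs(est$density - truth)), 1e-9)
  expect_equal(est$density[est$temperature == 80],
               density_at(sc$schedule, 80), tolerance = 1e-6)
})

test_that("transmission and diffraction estimators agree on noise-free data", {
  sc <- density_scenario()
  et <- density_from_transmission(sc$transmission)
  ed <- density_from_diffraction(sc$diffraction)
  # agreement limited only by the weak temperature dependence of the
  # Doppler-broadened plateau (~2.5e-5 relative)
  expect_lt(max(abs(et$density - ed$density)), 1e-4)
})

test_that("calibration is idempotent", {
  sc <- density_scenario()
  est <- density_from_transmission(sc$transmission)
  ref <- est$density[est$temperature == -20]
  rescaled <- est$density * 1.3 / ref
  expect_equal(rescaled, est$density, tolerance = 1e-12)
})

test_that("density recovery under noise stays within 0.02 g/cm3 (median of seeds)", {
  errs <- vapply(1:20, function(s) {
    sc <- density_scenario(noise_trans = 0.002, noise_diff = 0.5, seed = s)
    et <- density_from_transmission(sc$transmission)
    ed <- density_from_diffraction(sc$diffraction)
    truth <- density_at(sc$schedule, et$temperature)
    max(abs(et$density - truth), abs(ed$density - truth))
  }, 0)
  expect_lt(stats::median(errs), 0.02)
})

test_that("model discrepancy series is null when data come from the model", {
  sc <- density_scenario()
  est <- density_from_transmission(sc$transmission)
  meas <- lapply(seq_along(sc$temps), function(i)
    transmission_to_sigma(sc$transmission[[i]],
                          est$density[est$temperature == sc$temps[i]],
                          sc$stoich))
  disc <- afga_discrepancy(meas, sc$model)
  expect_lt(max(abs(disc$delta / disc$integral_model)), 5e-3)
})

test_that("discrepancy departs from zero only above an injected softening", {
  sc <- density_scenario()
  # soften hydrogen modes above 40 degC: scale group mode energies down,
  # which raises the thermal cross-section window integral
  soft_groups <- function(st) list(
    functional_group("CH2", "H", 2, c(250, 120, 60), c(1, 1, 1)),
    functional_group("CH", "H", 5, c(250, 110, 70), c(1, 1, 1)),
    functional_group("OH", "H", 3, c(300, 140, 55), c(1, 1, 1)),
    functional_group("water_OH", "H", 2 * st$water_per_glucose,
                     c(300, 140, 55), c(1, 1, 1)),
    functional_group("C_heavy", "C", 6),
    functional_group("O_heavy", "O", st$counts[["O"]])
  )
  soft_model <- afga_model(sc$stoich, soft_groups(sc$stoich))
  meas <- lapply(sc$temps, function(tt) {
    m <- if (tt > 40) soft_model else sc$model
    total_sigma(10^seq(-3.05, 0, length.out = 300), m, tt)
  })
  disc <- afga_discrepancy(meas, sc$model)
  below <- disc$temperature <= 40
  expect_lt(max(abs(disc$delta[below])), 1e-6)
  expect_true(all(abs(disc$delta[!below]) > 10 * max(abs(disc$delta[below]))))
})

test_that("transition bracketing: step, linear, and sigmoid-on-grid cases", {
  # flat-then-flat with one drop between 40 and 60
  step <- list(temperature = neutron_temps,
               density = c(1.3, 1.3, 1.3, 1.3, 1.1, 1.1))
  res <- detect_transition_series(step$temperature, step$density)
  expect_true(res$found)
  expect_equal(c(res$T_low, res$T_high), c(40, 60))
  # strictly linear series: no changepoint
  lin <- detect_transition_series(neutron_temps, seq(1.3, 1.1, length.out = 6))
  expect_false(lin$found)
  # sigmoid schedule sampled on the six-temperature grid
  sch <- density_schedule()
  res2 <- detect_transition_series(neutron_temps,
                                   density_at(sch, neutron_temps))
  expect_true(res2$found)
  expect_equal(c(res2$T_low, res2$T_high), c(40, 60))
  expect_error(detect_transition_series(c(1, 2, 3), c(1, 2, 3)), "4")
})
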