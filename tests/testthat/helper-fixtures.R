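# Shared fixtures: the standard synthetic scenario used across modules.

default_truth <- function() {
  relax_params(Sg = 0.5, T2g_star = 12, Ss = 0.13, T2s_star = 25,
               b = 0.45, L = 0.37, T2L_star = 400)
}

paper_gt <- function() gt_params(Tgs = 112.4, Tgw = -135, k = 2.4)

neutron_temps <- c(-20, 0, 20, 40, 60, 80)

pasta_stoich <- function(include_al = FALSE) {
  build_stoichiometry(moisture_value(0.1069, "wet"), include_al = include_al)
}

ncs_masses <- c(1.00794, 12.011, 15.999, 26.9815385)
ncs_widths <- c(H = 4.9, C = 14, O = 12.5, Al = 15)

# transmission + diffraction series under the sigmoid schedule
density_scenario <- function(noise_trans = 0, noise_diff = 0, seed = 1,
                             temps = neutron_temps) {
  st <- pasta_stoich()
  mod <- afga_model(st)
  sched <- density_schedule()
  trans <- lapply(seq_along(temps), function(i)
    gen_transmission(st, mod, rho = density_at(sched, temps[i]),
                     noise_sd = noise_trans, seed = seed * 100 + i,
                     temperature = temps[i]))
  diffr <- lapply(seq_along(temps), function(i)
    gen_diffraction(rho = density_at(sched, temps[i]),
                    noise_sd = noise_diff, seed = seed * 100 + 50 + i,
                    temperature = temps[i]))
  list(stoich = st, model = mod, schedule = sched,
       transmission = trans, diffraction = diffr, temps = temps)
}
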