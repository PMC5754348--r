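# Shared fixtures built in code.

ara_architecture <- function(with_repressor = FALSE) {
  promoter_architecture(
    operator_site("AraO", "activator", -60L),
    spacer_operators = if (with_repressor)
      list(operator_site("LacO1", "repressor", -20L)) else list())
}

fixture_48_library <- function() {
  assemble_library(default_minus35_parts(), default_minus10_parts(),
                   ara_architecture())
}

# random single-activator + m-repressor parameter draw for oracle checks
random_params <- function(n_repressors = 1) {
  regs <- list(regulator_spec("Act", "activator", runif(1, 0, 200),
                              hill_n = runif(1, 0.5, 4),
                              half_conc = runif(1, 0.1, 10), ligand = "ligA"))
  if (n_repressors > 0)
    for (j in seq_len(n_repressors))
      regs <- c(regs, list(regulator_spec(paste0("Rep", j), "repressor",
                                          runif(1, 0, 200),
                                          hill_n = runif(1, 0.5, 4),
                                          half_conc = runif(1, 0.1, 10),
                                          ligand = paste0("lig", j))))
  thermo_params(site_energies(runif(1, -5, 5), runif(1, -5, 5)),
                alpha = runif(1, 1, 1e5), background = runif(1, 0, 100),
                omega = runif(1, 1, 1000), regulators = regs)
}

random_condition <- function(params) {
  ligs <- vapply(params$regulators, `[[`, "", "ligand")
  on <- runif(length(ligs)) < 0.7
  as_condition(stats::setNames(ifelse(on, runif(length(ligs), 0, 20), 0), ligs))
}

# brute-force occupancy: weight of sigma-containing states / total weight
enumeration_occupancy <- function(params, condition) {
  st <- enumerate_states(params, condition)
  has_sigma <- grepl("(^|\\+)sigma($|\\+)", st$occupants)
  sum(st$weight[has_sigma]) / sum(st$weight)
}

# thermo_params of one config variant, rebuilt from exported pieces
config_params_for_test <- function(cfg, variant_id) {
  lib <- fixture_48_library()
  i <- match(variant_id, lib$id)
  thermo_params(
    site_energies(dG_minus10 = cfg$minus10_energies[[lib$minus10[i]]],
                  dG_minus35 = cfg$minus35_energies[[lib$minus35[i]]]),
    alpha = cfg$alpha, background = cfg$background, omega = cfg$omega,
    regulators = cfg$regulators)
}

# three-input gate config: AraC + LacI + TetR on the fixture library
gate_config_3in <- function(noise_cv = 0, seed = 7) {
  synthetic_config(
    regulators = default_regulators()[c("AraC", "LacI", "TetR")],
    noise_cv = noise_cv, seed = seed)
}
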