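# Seeded synthetic plate-reader datasets with ground-truth annotation.
#
# Each generator evaluates the occupancy model on true parameters (shared
# code path with transcription_rate) and turns rates into raw plate wells:
# fluor_4h = fluor_2h + rate * noise * od600, so the implied per-OD gain
# (fluor_4h - fluor_2h)/od600 equals rate * noise. Noise is multiplicative
# lognormal with mean exactly 1 at the configured coefficient of variation.

#' Configure the synthetic-data generator
#'
#' Captures the study conditions: the fixture 6 x 8 library with true site
#' energies, regulator ground truth, rate scale alpha = 1e5 RPU and
#' background 10 RPU, biological triplicates and 10% multiplicative
#' lognormal measurement noise.
#'
#' @param minus35_energies,minus10_energies Named true free energies (k_BT)
#'   per site label; defaults from [default_site_energies()].
#' @param regulators List of [regulator_spec()]s with true parameters
#'   (default: AraC only).
#' @param alpha,background,omega True global model parameters.
#' @param conditions Named list of [inducer_condition()]s (default:
#'   `uninduced` = no ligand, `induced` = arabinose at its working
#'   concentration).
#' @param replicates Biological replicates per condition (default 3).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (default 0.10).
#' @param reference_rate True rate of the constitutive mid-strength
#'   reference standard, in RPU.
#' @param od600,fluor_2h Baseline optical density and 2 h fluorescence used
#'   for raw wells.
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   config including the seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(minus35_energies = default_site_energies()$minus35,
                             minus10_energies = default_site_energies()$minus10,
                             regulators = default_regulators()["AraC"],
                             alpha = 1e5, background = 10, omega = 100,
                             conditions = NULL, replicates = 3,
                             noise_cv = 0.10, reference_rate = 5000,
                             od600 = 0.5, fluor_2h = 100, seed = 1) {
  if (is.null(conditions)) {
    wc <- default_working_concentrations()
    lig <- regulators[[1L]]$ligand
    conditions <- list(
      uninduced = inducer_condition(),
      induced = as_condition(stats::setNames(wc[[lig]], lig)))
  }
  stopifnot(replicates >= 1, noise_cv >= 0, alpha > 0, background >= 0,
            reference_rate > 0, od600 > 0)
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    stop("'conditions' must be a named list")
  structure(list(minus35_energies = minus35_energies,
                 minus10_energies = minus10_energies,
                 regulators = regulators, alpha = alpha,
                 background = background, omega = omega,
                 conditions = lapply(conditions, as_condition),
                 replicates = as.integer(replicates), noise_cv = noise_cv,
                 reference_rate = reference_rate, od600 = od600,
                 fluor_2h = fluor_2h, seed = as.integer(seed)),
            class = "synthetic_config")
}

# lognormal multiplier with E[x] = 1 and sd/mean = cv
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# thermo_params for one (minus35, minus10) combination of the config
config_params <- function(config, dG35, dG10) {
  thermo_params(site_energies(dG_minus10 = dG10, dG_minus35 = dG35),
                alpha = config$alpha, background = config$background,
                omega = config$omega, regulators = config$regulators)
}

# evaluate true rates for a set of variants under the config's conditions
true_rate_table <- function(config, variants) {
  conds <- config$conditions
  rates <- matrix(NA_real_, nrow = nrow(variants), ncol = length(conds),
                  dimnames = list(variants$id, names(conds)))
  for (i in seq_len(nrow(variants))) {
    p <- config_params(config,
                       config$minus35_energies[[variants$minus35[i]]],
                       config$minus10_energies[[variants$minus10[i]]])
    for (j in seq_along(conds))
      rates[i, j] <- transcription_rate(p, conds[[j]])
  }
  rates
}

# assemble raw wells: one plate per (condition, replicate), each carrying
# every variant plus one reference and one blank well
build_plates <- function(config, variants, rates) {
  conds <- names(config$conditions)
  rows <- list(); k <- 0L
  for (cond in conds) {
    for (rep_i in seq_len(config$replicates)) {
      plate <- sprintf("%s_r%d", cond, rep_i)
      ids <- c(variants$id, "reference", "blank")
      true <- c(rates[, cond], config$reference_rate, 0)
      noise <- lognormal_noise(length(ids), config$noise_cv)
      noise[length(ids)] <- 1  # blank carries no promoter signal
      fluo <- true * noise
      k <- k + 1L
      rows[[k]] <- data.frame(
        plate = plate,
        well = sprintf("%s%02d", LETTERS[(seq_along(ids) - 1L) %/% 12 + 1L],
                       (seq_along(ids) - 1L) %% 12 + 1L),
        promoter = ids, condition = cond, replicate = rep_i,
        od600_4h = config$od600, fluor_2h = config$fluor_2h,
        fluor_4h = config$fluor_2h + fluo * config$od600,
        true_rate = true, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# shared generator core; 'variants' is a promoter_library-like data frame
generate_dataset <- function(config, variants) {
  set.seed(config$seed)
  rates <- true_rate_table(config, variants)
  plate <- build_plates(config, variants, rates)

  test <- plate[!plate$promoter %in% c("reference", "blank"), , drop = FALSE]
  i <- match(test$promoter, variants$id)
  observations <- data.frame(
    variant = test$promoter, minus35 = variants$minus35[i],
    minus10 = variants$minus10[i], condition = test$condition,
    replicate = test$replicate,
    rate_rpu = (test$fluor_4h - test$fluor_2h) / test$od600_4h,
    stringsAsFactors = FALSE)

  truth <- list(
    ln_keq = stats::setNames(
      -(config$minus35_energies[variants$minus35] +
          config$minus10_energies[variants$minus10]), variants$id),
    rates = rates,
    minus35_energies = config$minus35_energies,
    minus10_energies = config$minus10_energies,
    alpha = config$alpha, background = config$background,
    omega = config$omega, regulators = config$regulators,
    reference_rate = config$reference_rate)

  plate$true_rate <- NULL
  list(plate = plate, observations = observations, truth = truth)
}

#' Generate a combinatorial library dataset
#'
#' Emulates the plate assay of the full -35 x -10 library under the config's
#' conditions (by default uninduced / induced): one plate per (condition,
#' replicate) carrying all variants plus a reference-standard and a blank
#' well, with multiplicative lognormal noise on the implied per-OD gain.
#'
#' @param config A [synthetic_config()].
#' @param library Optional `promoter_library`; defaults to the packaged
#'   fixture library under an AraC architecture.
#' @return List with elements `plate` (raw wells), `observations`
#'   (fit-ready table of noisy rates) and `truth` (true ln(K_eq) per
#'   variant, true rate matrix and global parameters).
#' @export
generate_library_dataset <- function(config = synthetic_config(),
                                     library = NULL) {
  if (is.null(library)) library <- fixture_library(config)
  missing35 <- setdiff(library$minus35, names(config$minus35_energies))
  missing10 <- setdiff(library$minus10, names(config$minus10_energies))
  if (length(missing35) || length(missing10))
    stop("config lacks energies for site(s): ",
         paste(c(missing35, missing10), collapse = ", "))
  generate_dataset(config, library)
}

# packaged fixture library under the config's activator
fixture_library <- function(config) {
  act <- NULL
  for (r in config$regulators) if (r$mode == "activator") act <- r
  op_name <- if (is.null(act)) "AraO" else paste0(substr(act$name, 1, 3), "O")
  arch <- promoter_architecture(
    operator_site(op_name, "activator", -60L),
    spacer_operators = if (any(vapply(config$regulators, `[[`, "", "mode") ==
                                "repressor"))
      list(operator_site("LacO1", "repressor", -20L)) else list())
  assemble_library(default_minus35_parts(), default_minus10_parts(), arch)
}

#' Generate a dose-response titration dataset
#'
#' Titrates one ligand over a concentration series for selected variants
#' (by default the weak/medium/strong trio bD, dE, eG), all other ligands
#' absent.
#'
#' @param config A [synthetic_config()].
#' @param ligand Ligand to titrate.
#' @param concentrations Numeric concentrations; default 0 plus a log series
#'   up to the working concentration.
#' @param combos Character vector of `<minus35><minus10>` label pairs.
#' @return As [generate_library_dataset()]; condition ids are
#'   `<ligand>=<concentration>`.
#' @export
generate_dose_response <- function(config = synthetic_config(), ligand,
                                   concentrations = NULL,
                                   combos = c("bD", "dE", "eG")) {
  ligands <- vapply(config$regulators, `[[`, "", "ligand")
  if (!ligand %in% ligands)
    stop("unknown ligand '", ligand, "'; config regulators respond to: ",
         paste(ligands, collapse = ", "))
  if (is.null(concentrations)) {
    top <- default_working_concentrations()[[ligand]]
    concentrations <- c(0, top * 10^seq(-4, 0, length.out = 9))
  }
  if (any(concentrations < 0)) stop("concentrations must be >= 0")

  lib <- fixture_library(config)
  pick <- paste0(lib$minus35, lib$minus10) %in% combos
  variants <- lib[pick, , drop = FALSE]
  config$conditions <- stats::setNames(
    lapply(concentrations, function(conc)
      as_condition(stats::setNames(conc, ligand))),
    sprintf("%s=%g", ligand, concentrations))
  generate_dataset(config, variants)
}

#' Generate a multi-input AND-gate dataset
#'
#' Emulates the two- and three-input hybrid-promoter panels: one activator
#' plus one (two-input) or two (three-input) repressors, measured under
#' every on/off combination of the cognate inducers at their working
#' concentrations (2^n conditions, all-off first, all-on last).
#'
#' @param config A [synthetic_config()] whose `regulators` contain exactly
#'   one activator and `n_inputs - 1` repressors.
#' @param n_inputs 2 or 3.
#' @param combos `<minus35><minus10>` label pairs to include (default the
#'   gate set dE, dF, bD, eG).
#' @return As [generate_library_dataset()]; condition ids are binary strings
#'   over the inputs (e.g. `"101"`), inputs ordered activator ligand first.
#' @export
generate_gate_dataset <- function(config, n_inputs,
                                  combos = c("dE", "dF", "bD", "eG")) {
  if (!n_inputs %in% c(2L, 3L)) stop("'n_inputs' must be 2 or 3")
  modes <- vapply(config$regulators, `[[`, "", "mode")
  if (sum(modes == "activator") != 1L || sum(modes == "repressor") != n_inputs - 1L)
    stop("config must have 1 activator and ", n_inputs - 1L,
         " repressor(s) for a ", n_inputs, "-input gate")
  ligs <- vapply(config$regulators[order(modes != "activator")], `[[`, "", "ligand")
  conds <- enumerate_conditions(ligs)
  config$conditions <- conds

  lib <- fixture_library(config)
  pick <- paste0(lib$minus35, lib$minus10) %in% combos
  generate_dataset(config, lib[pick, , drop = FALSE])
}
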