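# Occupancy model of transcription initiation.
#
# The promoter is a set of sites for sigma70, at most one activator A and any
# number of repressors Rj. Relative to the empty promoter (weight 1), the
# Boltzmann weight of sigma70 binding is K_eq = exp(-(dG_-10 + dG_-35)) in
# k_BT units; an active activator contributes q_A = a * K_A and recruits
# sigma70 with cooperativity omega; each active repressor contributes
# q_Rj = rho_j * K_Rj and sterically excludes sigma70 (no state holds sigma70
# together with a repressor). Transcription is proportional to sigma70
# occupancy, plus an additive background from autofluorescence/reporter leak.

#' Specify a transcriptional regulator
#'
#' Describes one ligand-inducible transcription factor: an activator whose
#' ligand switches it on (AraC/arabinose, LasR/3O-C12-HSL, ...) or a
#' repressor whose ligand switches it off (LacI/IPTG, TetR/aTc).
#'
#' @param name Regulator name (e.g. `"AraC"`, `"LacI"`).
#' @param mode `"activator"` or `"repressor"`.
#' @param binding_weight Dimensionless Boltzmann weight K of the fully active
#'   regulator bound to its operator (K_A for activators, K_R for repressors);
#'   must be >= 0.
#' @param hill_n Hill coefficient of the ligand response; > 0.
#' @param half_conc Ligand concentration of half-maximal response (EC50 for
#'   activators, the deactivation midpoint for repressors); > 0, in the same
#'   units the ligand is dosed in.
#' @param ligand Ligand name keyed in inducer conditions.
#' @return An object of class `regulator_spec`.
#' @examples
#' regulator_spec("AraC", "activator", 50, hill_n = 2,
#'                half_conc = 0.5, ligand = "arabinose")
#' @export
regulator_spec <- function(name, mode = c("activator", "repressor"),
                           binding_weight, hill_n = 2, half_conc, ligand) {
  mode <- match.arg(mode)
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(binding_weight) || binding_weight < 0)
    stop("'binding_weight' must be >= 0")
  if (!is.numeric(hill_n) || hill_n <= 0) stop("'hill_n' must be > 0")
  if (!is.numeric(half_conc) || half_conc <= 0) stop("'half_conc' must be > 0")
  stopifnot(is.character(ligand), length(ligand) == 1L)
  structure(list(name = name, mode = mode,
                 binding_weight = as.numeric(binding_weight),
                 hill_n = as.numeric(hill_n),
                 half_conc = as.numeric(half_conc), ligand = ligand),
            class = "regulator_spec")
}

#' Per-site binding free energies
#'
#' Free energies of sigma70 binding contributed by the -10 and -35 hexamers,
#' in k_BT units and relative to the consensus anchors; the relative
#' equilibrium constant obeys `ln(K_eq) = -(dG_minus10 + dG_minus35)`.
#'
#' @param dG_minus10,dG_minus35 Free energies in k_BT.
#' @return An object of class `site_energies`.
#' @export
site_energies <- function(dG_minus10, dG_minus35) {
  stopifnot(is.numeric(dG_minus10), is.numeric(dG_minus35),
            is.finite(dG_minus10), is.finite(dG_minus35))
  structure(list(dG_minus10 = as.numeric(dG_minus10),
                 dG_minus35 = as.numeric(dG_minus35)),
            class = "site_energies")
}

#' Full parameter set of the occupancy model
#'
#' @param site_energies A [site_energies()] object.
#' @param alpha Maximal rate scale in RPU; > 0.
#' @param background Additive basal signal b in RPU (autofluorescence plus
#'   reporter leak); >= 0.
#' @param omega Activator-sigma70 cooperativity (dimensionless recruitment
#'   factor; >= 1 for activation).
#' @param regulators List of [regulator_spec()]s; at most one activator.
#' @return An object of class `thermo_params`.
#' @export
thermo_params <- function(site_energies, alpha, background = 0, omega = 1,
                          regulators = list()) {
  stopifnot(inherits(site_energies, "site_energies"))
  if (!is.numeric(alpha) || alpha <= 0) stop("'alpha' must be > 0")
  if (!is.numeric(background) || background < 0) stop("'background' must be >= 0")
  if (!is.numeric(omega) || omega < 0) stop("'omega' must be >= 0")
  if (inherits(regulators, "regulator_spec")) regulators <- list(regulators)
  for (r in regulators)
    if (!inherits(r, "regulator_spec")) stop("'regulators' must be regulator_spec objects")
  modes <- vapply(regulators, `[[`, "", "mode")
  if (sum(modes == "activator") > 1L)
    stop("unsupported architecture: at most one activator is allowed")
  structure(list(site_energies = site_energies, alpha = as.numeric(alpha),
                 background = as.numeric(background), omega = as.numeric(omega),
                 regulators = regulators),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf(
    "<thermo_params> ln(Keq) = %.3f (dG-10 = %.2f, dG-35 = %.2f k_BT)\n",
    ln_keq(x), x$site_energies$dG_minus10, x$site_energies$dG_minus35))
  cat(sprintf("  alpha = %.4g RPU, background = %.4g RPU, omega = %.4g\n",
              x$alpha, x$background, x$omega))
  for (r in x$regulators)
    cat(sprintf("  %s [%s] K = %.4g, n = %.2g, half = %.4g (%s)\n",
                r$name, r$mode, r$binding_weight, r$hill_n, r$half_conc, r$ligand))
  invisible(x)
}

#' Relative equilibrium constant of sigma70 binding
#'
#' `ln(K_eq) = -(dG_minus10 + dG_minus35)`.
#'
#' @param x A `thermo_params` or `site_energies` object.
#' @return Natural log of the relative equilibrium constant.
#' @export
ln_keq <- function(x) {
  se <- if (inherits(x, "thermo_params")) x$site_energies else x
  stopifnot(inherits(se, "site_energies"))
  -(se$dG_minus10 + se$dG_minus35)
}

#' Replace the sigma70 equilibrium constant of a parameter set
#'
#' Convenience for sweeps: returns params whose site energies give the
#' requested `ln(K_eq)` (all of it placed on the -10 site; only the sum
#' matters to the model).
#'
#' @param params A [thermo_params()] object.
#' @param ln_keq Target natural-log equilibrium constant.
#' @return Modified `thermo_params`.
#' @export
with_ln_keq <- function(params, ln_keq) {
  stopifnot(inherits(params, "thermo_params"), is.numeric(ln_keq), is.finite(ln_keq))
  params$site_energies <- site_energies(dG_minus10 = -ln_keq, dG_minus35 = 0)
  params
}

#' Define an inducer condition
#'
#' A named set of ligand concentrations (same units as each regulator's
#' `half_conc`); any ligand not named is at concentration 0, so
#' `inducer_condition()` is the all-off state.
#'
#' @param ... Named concentrations, e.g. `arabinose = 5, IPTG = 1`.
#' @return Named numeric vector of class `inducer_condition`.
#' @export
inducer_condition <- function(...) {
  x <- c(...)
  if (is.null(x)) x <- stats::setNames(numeric(0), character(0))
  if (length(x) && (is.null(names(x)) || any(!nzchar(names(x)))))
    stop("all concentrations must be named by ligand")
  if (any(x < 0)) stop("concentrations must be >= 0")
  structure(as.numeric(x), names = names(x), class = "inducer_condition")
}

as_condition <- function(x) {
  if (inherits(x, "inducer_condition")) return(x)
  if (is.null(x)) return(inducer_condition())
  do.call(inducer_condition, as.list(x))
}

#' Active fraction of a regulator under a condition
#'
#' Hill response to the regulator's ligand at concentration c: an activator is
#' active with fraction `a(c) = c^n / (c^n + half^n)` (0 without ligand); a
#' repressor with fraction `rho(c) = half^n / (c^n + half^n)` (1 without
#' ligand; the ligand deactivates it).
#'
#' @param reg A [regulator_spec()].
#' @param condition An [inducer_condition()] (or named vector / NULL).
#' @return Fraction in \[0, 1\].
#' @export
active_fraction <- function(reg, condition = NULL) {
  stopifnot(inherits(reg, "regulator_spec"))
  condition <- as_condition(condition)
  conc <- if (reg$ligand %in% names(condition)) condition[[reg$ligand]] else 0
  if (conc < 0) stop("negative concentration for ligand ", reg$ligand)
  cn <- conc^reg$hill_n
  hn <- reg$half_conc^reg$hill_n
  if (reg$mode == "activator") cn / (cn + hn) else hn / (cn + hn)
}

# Boltzmann weights q = active_fraction * K for each regulator
regulator_weights <- function(params, condition) {
  vapply(params$regulators, function(r)
    active_fraction(r, condition) * r$binding_weight, 0)
}

#' Enumerate promoter binding states
#'
#' All joint occupancy states of sigma70, the activator and the repressors,
#' excluding any state holding sigma70 together with a repressor (steric
#' exclusion from the spacer). Weights are relative to the empty promoter:
#' the activator contributes `q_A = a * K_A`, repressor j contributes
#' `q_Rj = rho_j * K_Rj`, sigma70 contributes `K_eq`, and sigma70 co-occurring
#' with the activator gains the cooperativity factor `omega`.
#'
#' @param params A [thermo_params()].
#' @param condition An [inducer_condition()].
#' @return Data frame with columns `occupants` (`+`-separated names, `""` for
#'   the empty state) and `weight`.
#' @examples
#' p <- default_thermo_params()
#' enumerate_states(p, inducer_condition(arabinose = 5))
#' @export
enumerate_states <- function(params, condition = NULL) {
  stopifnot(inherits(params, "thermo_params"))
  condition <- as_condition(condition)
  regs <- params$regulators
  modes <- vapply(regs, `[[`, "", "mode")
  if (sum(modes == "activator") > 1L)
    stop("unsupported architecture: at most one activator is allowed")
  q <- regulator_weights(params, condition)
  keq <- exp(ln_keq(params))
  m <- length(regs)
  names_r <- vapply(regs, `[[`, "", "name")

  occupants <- character(0); weight <- numeric(0)
  # iterate over subsets of regulators x {sigma absent, present}
  for (mask in 0:(2^m - 1)) {
    inset <- if (m) as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L))) else logical(0)
    w_tf <- prod(q[inset])
    occ_tf <- names_r[inset]
    occupants <- c(occupants, paste(occ_tf, collapse = "+"))
    weight <- c(weight, w_tf)
    if (!any(modes[inset] == "repressor")) {  # sigma may join
      has_act <- any(modes[inset] == "activator")
      w_sig <- w_tf * keq * if (has_act) params$omega else 1
      occupants <- c(occupants, paste(c("sigma", occ_tf), collapse = "+"))
      weight <- c(weight, w_sig)
    }
  }
  data.frame(occupants = occupants, weight = weight, stringsAsFactors = FALSE)
}

# closed-form occupancy core, vectorized over keq:
# P = keq (1 + qA w) / ((1 + qA) prod_j (1 + qRj) + keq (1 + qA w))
occupancy_closed_form <- function(keq, q_act, q_rep, omega) {
  num <- keq * (1 + q_act * omega)
  num / ((1 + q_act) * prod(1 + q_rep) + num)
}

#' Probability that sigma70 is bound
#'
#' Closed-form occupancy
#' `P = K_eq (1 + q_A w) / ((1 + q_A) prod_j (1 + q_Rj) + K_eq (1 + q_A w))`,
#' equal to the weight of sigma70-containing states over the full partition
#' function of [enumerate_states()].
#'
#' @inheritParams enumerate_states
#' @return Probability in \[0, 1\].
#' @export
p_sigma_bound <- function(params, condition = NULL) {
  stopifnot(inherits(params, "thermo_params"))
  condition <- as_condition(condition)
  modes <- vapply(params$regulators, `[[`, "", "mode")
  q <- regulator_weights(params, condition)
  as.numeric(occupancy_closed_form(
    exp(ln_keq(params)),
    q_act = if (any(modes == "activator")) q[modes == "activator"] else 0,
    q_rep = q[modes == "repressor"],
    omega = params$omega))
}

#' Transcription rate of a promoter
#'
#' `r = alpha * P(sigma70 bound) + background`, in RPU.
#'
#' @inheritParams enumerate_states
#' @return Rate in RPU; always >= `background`.
#' @export
transcription_rate <- function(params, condition = NULL) {
  params$alpha * p_sigma_bound(params, condition) + params$background
}

#' Fold-change induction between two conditions
#'
#' Ratio of the induced and uninduced transcription rates, `r(on) / r(off)`.
#'
#' @param params A [thermo_params()].
#' @param off,on [inducer_condition()]s.
#' @return Non-negative ratio.
#' @export
fold_change <- function(params, off, on) {
  r_off <- transcription_rate(params, off)
  if (r_off == 0)
    stop("uninduced rate is 0 and background is 0: fold change undefined")
  transcription_rate(params, on) / r_off
}

#' Dynamic range between two conditions
#'
#' Absolute difference between the ON and OFF transcription rates,
#' `r(on) - r(off)`, in RPU.
#'
#' @inheritParams fold_change
#' @return Rate difference in RPU.
#' @export
dynamic_range <- function(params, off, on) {
  transcription_rate(params, on) - transcription_rate(params, off)
}

#' Dose-response curve for one ligand
#'
#' Transcription rate at each concentration of the named ligand, all other
#' ligands absent. Non-decreasing in concentration both for activator ligands
#' and for repressor-deactivating ligands.
#'
#' @param params A [thermo_params()].
#' @param ligand Ligand name known to one of the regulators.
#' @param concentrations Numeric vector of concentrations (>= 0).
#' @return Data frame with columns `concentration` and `rate`.
#' @export
dose_response_curve <- function(params, ligand, concentrations) {
  ligands <- vapply(params$regulators, `[[`, "", "ligand")
  if (!ligand %in% ligands)
    stop("unknown ligand '", ligand, "'; regulators respond to: ",
         paste(ligands, collapse = ", "))
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  rate <- vapply(concentrations, function(conc) {
    transcription_rate(params, as_condition(stats::setNames(conc, ligand)))
  }, 0)
  data.frame(concentration = as.numeric(concentrations), rate = rate)
}

#' Sweep the sigma70 equilibrium constant
#'
#' Evaluates OFF/ON rates, fold change and dynamic range over a grid of
#' `ln(K_eq)` values at otherwise fixed parameters, reproducing the
#' three-regime behaviour: weak promoters (low K_eq) have low leak and poor
#' induction, strong promoters (high K_eq) high leak, and an intermediate
#' K_eq maximizes the dynamic range.
#'
#' @param params_template A [thermo_params()] whose site energies are replaced
#'   grid-point by grid-point.
#' @param ln_keq_grid Numeric grid of ln(K_eq) values.
#' @param off,on [inducer_condition()]s.
#' @return Data frame with columns `ln_keq`, `r_off`, `r_on`, `fold_change`,
#'   `dynamic_range`, rows in grid order.
#' @export
sweep_keq <- function(params_template, ln_keq_grid, off, on) {
  stopifnot(inherits(params_template, "thermo_params"),
            all(is.finite(ln_keq_grid)))
  rows <- lapply(ln_keq_grid, function(lk) {
    p <- with_ln_keq(params_template, lk)
    r_off <- transcription_rate(p, off)
    r_on <- transcription_rate(p, on)
    data.frame(ln_keq = lk, r_off = r_off, r_on = r_on,
               fold_change = r_on / r_off, dynamic_range = r_on - r_off)
  })
  do.call(rbind, rows)
}
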