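# Packaged fixture library and default regulator parameterization.
#
# Only the -35 site d (TTTACA), its engineered variant d* (TTTACT) and the
# -10 sites E (GATACT) and F (GATAAT) are authoritative part sequences; the
# remaining hexamers are synthetic placeholders chosen to carry plausible
# consensus-mismatch counts. Site free energies are likewise fixture values
# (not measurements), assigned so the documented phenotypes hold: bD is the
# weakest combination (low leak, low signal), eG the strongest (high leak,
# high signal), d a medium-affinity -35, and E weaker than F.

MINUS35_SEQS <- c(a = "TTGACC", b = "TCTAAA", c = "TTGATA",
                  d = "TTTACA", e = "TTGACA", f = "TCTACA")
MINUS10_SEQS <- c(A = "TATACT", B = "TACAAT", C = "GACAAT", D = "GCCACT",
                  E = "GATACT", F = "GATAAT", G = "TATAAT", H = "GACACT")

MINUS35_DG <- c(a = 0.7, b = 4.5, c = 1.5, d = 2.3, e = 0.0, f = 3.2)
MINUS10_DG <- c(A = 0.5, B = 1.0, C = 3.5, D = 6.0,
                E = 2.6, F = 1.8, G = 0.0, H = 4.6)

#' Default -35 and -10 promoter part lists
#'
#' The packaged 6 x 8 fixture library (48 combinations): -35 sites labelled
#' a-f, -10 sites labelled A-H. Sequences other than d/TTTACA, E/GATACT and
#' F/GATAAT are synthetic placeholders.
#'
#' @return A list of [promoter_part()]s.
#' @export
default_minus35_parts <- function() {
  mapply(promoter_part, names(MINUS35_SEQS), "minus35", MINUS35_SEQS,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' @rdname default_minus35_parts
#' @export
default_minus10_parts <- function() {
  mapply(promoter_part, names(MINUS10_SEQS), "minus10", MINUS10_SEQS,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Default ground-truth site energies of the fixture library
#'
#' Fixture free energies in k_BT, one value per -35 (a-f) and -10 (A-H)
#' label, chosen so the 48 ln(K_eq) values tile the whole dynamic-range
#' curve (from -10.5 for bD up to 0 for eG). The consensus-like anchors e
#' and G sit at 0.
#'
#' @return List with named numeric vectors `minus35` and `minus10`.
#' @export
default_site_energies <- function() {
  list(minus35 = MINUS35_DG, minus10 = MINUS10_DG)
}

#' Working inducer concentrations
#'
#' Final assay concentrations of each ligand: arabinose 5 mM, xylose 5 mM,
#' IPTG 1 mM, C4-HSL 10 uM, 3O-C6-HSL 0.1 uM, 3O-C12-HSL 0.1 uM,
#' aTc 100 ng/mL. Each ligand's unit is the one quoted here and is used
#' consistently for its `half_conc`.
#'
#' @return Named numeric vector of concentrations.
#' @export
default_working_concentrations <- function() {
  c(arabinose = 5, xylose = 5, IPTG = 1,
    `C4-HSL` = 10, `3O-C6-HSL` = 0.1, `3O-C12-HSL` = 0.1, aTc = 100)
}

#' Default regulator specifications
#'
#' One [regulator_spec()] per transcription factor used in the experiments:
#' activators AraC, XylR, RhlR, LasR, LuxR and repressors LacI, TetR. Hill
#' coefficient defaults to 2 and each half-maximal concentration to one
#' tenth of the working concentration of the cognate ligand, so every
#' regulator is near-saturated at its working dose.
#'
#' @param K_activator,K_repressor Default binding weights.
#' @return Named list of `regulator_spec` objects.
#' @export
default_regulators <- function(K_activator = 50, K_repressor = 50) {
  wc <- default_working_concentrations()
  act <- c(AraC = "arabinose", XylR = "xylose", RhlR = "C4-HSL",
           LasR = "3O-C12-HSL", LuxR = "3O-C6-HSL")
  rep <- c(LacI = "IPTG", TetR = "aTc")
  out <- c(
    lapply(names(act), function(nm)
      regulator_spec(nm, "activator", K_activator, hill_n = 2,
                     half_conc = wc[[act[[nm]]]] / 10, ligand = act[[nm]])),
    lapply(names(rep), function(nm)
      regulator_spec(nm, "repressor", K_repressor, hill_n = 2,
                     half_conc = wc[[rep[[nm]]]] / 10, ligand = rep[[nm]]))
  )
  stats::setNames(out, c(names(act), names(rep)))
}

#' Default single-activator model parameters
#'
#' A medium-affinity AraC-regulated promoter (the `dE`-like regime):
#' alpha = 1e5 RPU (the assay's maximum expression scale), background =
#' 10 RPU, omega = 100, K_A = 50.
#'
#' @param ln_keq Optional ln(K_eq) (default: the fixture dE value).
#' @param regulators Optional regulator list (default: AraC only).
#' @return A [thermo_params()] object.
#' @export
default_thermo_params <- function(ln_keq = NULL, regulators = NULL) {
  if (is.null(regulators)) regulators <- default_regulators()["AraC"]
  en <- default_site_energies()
  if (is.null(ln_keq)) ln_keq <- -(en$minus35[["d"]] + en$minus10[["E"]])
  p <- thermo_params(site_energies(dG_minus10 = 0, dG_minus35 = 0),
                     alpha = 1e5, background = 10, omega = 100,
                     regulators = regulators)
  with_ln_keq(p, ln_keq)
}
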