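# Least-squares fitting of binding free energies on log transcription rates.
#
# The additive model predicts ln(K_eq) of combination (i, j) as
# -(dG_-35(i) + dG_-10(j)); global parameters (alpha, background, omega and
# one binding weight per regulator) are shared across the library. The sum
# of squared differences of log rates is minimized by multistart BFGS.
# Site energies carry a one-dimensional gauge degeneracy
# (dG_-35 -> dG_-35 + d, dG_-10 -> dG_-10 - d leaves every ln(K_eq)
# unchanged); it is fixed by pinning one anchor site per family to 0 during
# optimization, by default the consensus-like sites.

#' Configure a free-energy fit
#'
#' @param free Character vector naming the free parameters, a subset of
#'   `"dG_minus35"`, `"dG_minus10"`, `"alpha"`, `"background"`, `"omega"`,
#'   `"K"` (one binding weight per regulator). Everything else is held at
#'   its template value.
#' @param gauge Named list with elements `minus35` and `minus10` giving the
#'   anchor site label of each family (pinned at dG = 0). `NULL` selects the
#'   site whose sequence matches the sigma70 consensus, else the
#'   alphabetically first label.
#' @param energy_model `"additive"` (per-site energies, the default) or
#'   `"per_combination"` (an unconstrained ln(K_eq) per variant).
#' @param n_starts Number of multistart points (>= 1; default 8).
#' @param max_iter Maximum optimizer iterations per start.
#' @param tol Relative convergence tolerance of the optimizer.
#' @param seed Seed for the multistart draws.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(free = c("dG_minus35", "dG_minus10", "alpha",
                                "background", "omega", "K"),
                       gauge = NULL,
                       energy_model = c("additive", "per_combination"),
                       n_starts = 8, max_iter = 500, tol = 1e-10, seed = 1) {
  energy_model <- match.arg(energy_model)
  allowed <- c("dG_minus35", "dG_minus10", "alpha", "background", "omega", "K")
  bad <- setdiff(free, allowed)
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  stopifnot(n_starts >= 1, max_iter >= 1, tol > 0)
  structure(list(free = free, gauge = gauge, energy_model = energy_model,
                 n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "fit_config")
}

validate_observation_table <- function(table) {
  need <- c("variant", "minus35", "minus10", "condition", "replicate", "rate_rpu")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("observation table lacks column(s): ", paste(miss, collapse = ", "))
  invisible(table)
}

#' Sum of squared log-rate residuals
#'
#' The fitting objective: `sum((ln r_obs - ln r_pred)^2)` over all rows of
#' an observation table, with predictions from per-variant model parameters.
#'
#' @param params_by_variant Named list mapping variant id to
#'   [thermo_params()].
#' @param table Observation table (columns `variant`, `condition`,
#'   `rate_rpu`).
#' @param conditions Named list of [inducer_condition()]s keyed by the
#'   table's condition ids.
#' @return Non-negative scalar loss.
#' @export
log_rate_loss <- function(params_by_variant, table, conditions) {
  validate_observation_table(table)
  if (any(table$rate_rpu <= 0))
    stop("observed rates must be > 0 before taking logs; floor non-positive ",
         "rates first (see floor_rates())")
  miss <- setdiff(unique(table$condition), names(conditions))
  if (length(miss)) stop("no condition definition for: ", paste(miss, collapse = ", "))
  pred <- mapply(function(v, cond) {
    p <- params_by_variant[[v]]
    if (is.null(p)) stop("no parameters for variant ", v)
    transcription_rate(p, conditions[[cond]])
  }, table$variant, table$condition)
  if (any(pred <= 0)) stop("predicted rates must be > 0")
  sum((log(table$rate_rpu) - log(pred))^2)
}

#' Floor non-positive observed rates
#'
#' Replaces rates <= 0 by half the smallest positive observed rate, so that
#' logs exist; the standard pre-processing before [fit_model()].
#'
#' @param table Observation table.
#' @return The table with floored `rate_rpu`.
#' @export
floor_rates <- function(table) {
  validate_observation_table(table)
  bad <- table$rate_rpu <= 0
  if (any(bad)) {
    if (all(bad)) stop("no positive rates in table")
    table$rate_rpu[bad] <- min(table$rate_rpu[!bad]) / 2
  }
  table
}

# pick consensus-like anchors from the observed site labels and, when
# available, the packaged sequences
default_gauge <- function(labels35, labels10) {
  pick <- function(labels, seqs, consensus) {
    hit <- labels[labels %in% names(seqs)][seqs[labels[labels %in% names(seqs)]] == consensus]
    if (length(hit)) hit[1L] else sort(labels)[1L]
  }
  list(minus35 = pick(labels35, MINUS35_SEQS, CONSENSUS_MINUS35),
       minus10 = pick(labels10, MINUS10_SEQS, CONSENSUS_MINUS10))
}

# --- parameter packing ------------------------------------------------------
# theta layout (additive): free non-anchor dG35, free non-anchor dG10,
# log(alpha), log(background), log(omega), log(K_reg) for each regulator --
# each global present only if free. per_combination: ln_keq per variant
# replaces the energy blocks.

pack_template <- function(table, config, template) {
  labels35 <- sort(unique(table$minus35))
  labels10 <- sort(unique(table$minus10))
  gauge <- config$gauge
  if (is.null(gauge)) gauge <- default_gauge(labels35, labels10)
  if (config$energy_model == "additive") {
    if (!gauge$minus35 %in% labels35)
      stop("gauge anchor '", gauge$minus35, "' not among -35 labels")
    if (!gauge$minus10 %in% labels10)
      stop("gauge anchor '", gauge$minus10, "' not among -10 labels")
  }
  variants <- unique(table[, c("variant", "minus35", "minus10")])
  list(labels35 = labels35, labels10 = labels10, gauge = gauge,
       variants = variants,
       regs = template$regulators,
       reg_names = vapply(template$regulators, `[[`, "", "name"))
}

# build the full parameter set (energies + globals) from theta
unpack_theta <- function(theta, layout, config, template) {
  free <- config$free
  g <- list(alpha = template$alpha, background = template$background,
            omega = template$omega,
            K = vapply(layout$regs, `[[`, 0, "binding_weight"))
  names(g$K) <- layout$reg_names
  pos <- 1L
  take <- function(n) {
    out <- theta[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  if (config$energy_model == "additive") {
    e35 <- stats::setNames(rep(0, length(layout$labels35)), layout$labels35)
    e10 <- stats::setNames(rep(0, length(layout$labels10)), layout$labels10)
    if ("dG_minus35" %in% free) {
      fr <- setdiff(layout$labels35, layout$gauge$minus35)
      if (length(fr)) e35[fr] <- take(length(fr))
    }
    if ("dG_minus10" %in% free) {
      fr <- setdiff(layout$labels10, layout$gauge$minus10)
      if (length(fr)) e10[fr] <- take(length(fr))
    }
    lnkeq <- if (!any(c("dG_minus35", "dG_minus10") %in% free))
      rep(ln_keq(template), nrow(layout$variants))  # all energies fixed
    else
      -(e35[layout$variants$minus35] + e10[layout$variants$minus10])
  } else {
    e35 <- NULL; e10 <- NULL
    lnkeq <- take(nrow(layout$variants))
  }
  names(lnkeq) <- layout$variants$variant
  if ("alpha" %in% free) g$alpha <- exp(take(1L))
  if ("background" %in% free) g$background <- exp(take(1L))
  if ("omega" %in% free) g$omega <- exp(take(1L))
  if ("K" %in% free && length(layout$regs)) g$K[] <- exp(take(length(layout$regs)))
  list(e35 = e35, e10 = e10, ln_keq = lnkeq, globals = g)
}

n_theta <- function(layout, config) {
  free <- config$free
  n <- 0L
  if (config$energy_model == "additive") {
    if ("dG_minus35" %in% free) n <- n + length(layout$labels35) - 1L
    if ("dG_minus10" %in% free) n <- n + length(layout$labels10) - 1L
  } else n <- n + nrow(layout$variants)
  n + ("alpha" %in% free) + ("background" %in% free) + ("omega" %in% free) +
    if ("K" %in% free) length(layout$regs) else 0L
}

# vectorized predicted rates for every table row
predict_rates <- function(par, layout, cond_info, row_variant_idx, row_cond_idx) {
  g <- par$globals
  keq <- exp(par$ln_keq)
  out <- numeric(length(row_variant_idx))
  for (j in seq_along(cond_info)) {
    ci <- cond_info[[j]]
    qa <- ci$a_act * if (ci$has_act) g$K[[ci$act_name]] else 0
    prod_r <- if (length(ci$rho_rep))
      prod(1 + ci$rho_rep * g$K[ci$rep_names]) else 1
    num <- keq * (1 + qa * g$omega)
    r <- g$alpha * num / ((1 + qa) * prod_r + num) + g$background
    sel <- row_cond_idx == j
    out[sel] <- r[row_variant_idx[sel]]
  }
  out
}

# precompute active fractions per condition (they do not depend on theta)
condition_info <- function(conditions, regs) {
  modes <- vapply(regs, `[[`, "", "mode")
  names_r <- vapply(regs, `[[`, "", "name")
  lapply(conditions, function(cond) {
    a <- vapply(regs, active_fraction, 0, condition = cond)
    act <- which(modes == "activator")
    list(has_act = length(act) > 0,
         act_name = if (length(act)) names_r[act[1L]] else NA_character_,
         a_act = if (length(act)) a[act[1L]] else 0,
         rho_rep = a[modes == "repressor"],
         rep_names = names_r[modes == "repressor"])
  })
}

# data-informed starting point: invert the OFF-condition occupancy for each
# variant, then project onto the additive structure by least squares
heuristic_start <- function(table, layout, config, template, cond_info) {
  log_obs <- log(table$rate_rpu)
  alpha0 <- max(table$rate_rpu)
  b0 <- max(min(table$rate_rpu) * 0.5, 1e-9)
  # per-variant crude Keq from the condition with the least regulatory input
  act_load <- vapply(cond_info, function(ci) ci$a_act, 0)
  base_cond <- which.min(act_load)
  sel <- (match(table$condition, names(cond_info)) == base_cond)
  agg <- tapply(table$rate_rpu[sel], table$variant[sel], mean)
  p_occ <- pmin(pmax((agg - b0) / alpha0, 1e-6), 1 - 1e-6)
  lnkeq0 <- log(p_occ / (1 - p_occ))
  lnkeq0 <- lnkeq0[layout$variants$variant]
  lnkeq0[is.na(lnkeq0)] <- -3

  theta <- numeric(0)
  if (config$energy_model == "additive") {
    # least-squares additive decomposition with anchors at 0
    X35 <- outer(layout$variants$minus35, setdiff(layout$labels35, layout$gauge$minus35), `==`) * 1
    X10 <- outer(layout$variants$minus10, setdiff(layout$labels10, layout$gauge$minus10), `==`) * 1
    X <- cbind(X35, X10)
    if (ncol(X)) {
      beta <- tryCatch(stats::coef(stats::lm.fit(X, -lnkeq0)),
                       error = function(e) rep(1, ncol(X)))
      beta[!is.finite(beta)] <- 1
    } else beta <- numeric(0)
    n35 <- length(setdiff(layout$labels35, layout$gauge$minus35))
    if ("dG_minus35" %in% config$free) theta <- c(theta, beta[seq_len(n35)])
    if ("dG_minus10" %in% config$free) theta <- c(theta, beta[seq_len(ncol(X) - n35) + n35])
  } else {
    theta <- c(theta, as.numeric(lnkeq0))
  }
  if ("alpha" %in% config$free) theta <- c(theta, log(alpha0))
  if ("background" %in% config$free) theta <- c(theta, log(b0))
  if ("omega" %in% config$free) theta <- c(theta, log(max(template$omega, 2)))
  if ("K" %in% config$free)
    theta <- c(theta, log(pmax(vapply(layout$regs, `[[`, 0, "binding_weight"), 1)))
  theta
}

# wide seeded prior for the remaining multistart points
random_start <- function(npar_energy, layout, config, table) {
  theta <- numeric(0)
  if (config$energy_model == "additive") {
    theta <- c(theta, stats::runif(npar_energy, 0, 8))
  } else {
    theta <- c(theta, stats::runif(npar_energy, -12, 2))
  }
  if ("alpha" %in% config$free)
    theta <- c(theta, log(max(table$rate_rpu)) + stats::rnorm(1, 0, 1))
  if ("background" %in% config$free)
    theta <- c(theta, log(max(min(table$rate_rpu), 1e-6)) + stats::rnorm(1, 0, 1))
  if ("omega" %in% config$free) theta <- c(theta, stats::runif(1, log(5), log(2000)))
  if ("K" %in% config$free)
    theta <- c(theta, stats::runif(length(layout$regs), log(1), log(500)))
  theta
}

#' Fit the occupancy model to an observation table
#'
#' Minimizes the sum of squared log-rate residuals over the configured free
#' parameters by multistart BFGS, sharing global parameters across the
#' library and pinning the gauge anchors at dG = 0. Deterministic given the
#' config seed.
#'
#' @param table Observation table with columns `variant`, `minus35`,
#'   `minus10`, `condition`, `replicate`, `rate_rpu`; needs at least two
#'   -35 and two -10 sites for the additive model to be identifiable.
#' @param conditions Named list of [inducer_condition()]s keyed by the
#'   table's condition ids.
#' @param config A [fit_config()].
#' @param template A [thermo_params()] supplying fixed parameter values and
#'   the regulator structure (Hill parameters are never fitted).
#' @return An object of class `promoter_fit`: per-site energy vectors
#'   (`energies_minus35`, `energies_minus10`; `NULL` for the
#'   per-combination model), `ln_keq` per variant, `globals`
#'   (alpha, background, omega, K), `loss`, `converged`, `start_losses`
#'   and the gauge used. Non-convergence across all starts is flagged, not
#'   an error.
#' @export
fit_model <- function(table, conditions, config = fit_config(),
                      template = default_thermo_params()) {
  validate_observation_table(table)
  table <- floor_rates(table)
  if (config$energy_model == "additive" &&
      (length(unique(table$minus35)) < 2L || length(unique(table$minus10)) < 2L))
    stop("additive fit needs >= 2 distinct -35 and -10 sites")
  miss <- setdiff(unique(table$condition), names(conditions))
  if (length(miss)) stop("no condition definition for: ", paste(miss, collapse = ", "))

  # canonical row order so the fit is invariant to input ordering
  table <- table[order(table$variant, table$condition, table$replicate), ,
                 drop = FALSE]

  layout <- pack_template(table, config, template)
  layout$variants <- layout$variants[order(layout$variants$variant), , drop = FALSE]
  cond_info <- condition_info(conditions, layout$regs)
  row_variant_idx <- match(table$variant, layout$variants$variant)
  row_cond_idx <- match(table$condition, names(conditions))
  log_obs <- log(table$rate_rpu)

  objective <- function(theta) {
    par <- unpack_theta(theta, layout, config, template)
    pred <- predict_rates(par, layout, cond_info, row_variant_idx, row_cond_idx)
    sum((log_obs - log(pred))^2)
  }

  npar <- n_theta(layout, config)
  npar_energy <- npar - (("alpha" %in% config$free) + ("background" %in% config$free) +
                           ("omega" %in% config$free) +
                           if ("K" %in% config$free) length(layout$regs) else 0L)
  set.seed(config$seed)
  starts <- c(list(heuristic_start(table, layout, config, template, cond_info)),
              lapply(seq_len(config$n_starts - 1L), function(i)
                random_start(npar_energy, layout, config, table)))

  best <- NULL
  start_losses <- numeric(length(starts))
  for (s in seq_along(starts)) {
    theta0 <- starts[[s]]
    if (length(theta0) != npar) theta0 <- rep_len(theta0, npar)
    res <- tryCatch(
      stats::optim(theta0, objective, method = "BFGS",
                   control = list(maxit = config$max_iter, reltol = config$tol)),
      error = function(e) list(par = theta0, value = Inf, convergence = 99L))
    start_losses[s] <- res$value
    if (is.null(best) || res$value < best$value) best <- res
  }

  par <- unpack_theta(best$par, layout, config, template)
  result <- structure(list(
    energies_minus35 = par$e35, energies_minus10 = par$e10,
    ln_keq = par$ln_keq,
    globals = par$globals,
    loss = best$value,
    converged = is.finite(best$value) && best$convergence == 0L,
    start_losses = start_losses,
    gauge = layout$gauge,
    energy_model = config$energy_model,
    variants = layout$variants,
    conditions = conditions,
    template = template),
    class = "promoter_fit")
  if (config$energy_model == "additive" &&
      any(c("dG_minus35", "dG_minus10") %in% config$free))
    result <- apply_gauge(result, config)
  result
}

#' @export
print.promoter_fit <- function(x, ...) {
  cat(sprintf("<promoter_fit> %s model, %d variants, loss = %.4g, %s\n",
              x$energy_model, length(x$ln_keq), x$loss,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  alpha = %.4g, background = %.4g, omega = %.4g\n",
              x$globals$alpha, x$globals$background, x$globals$omega))
  if (length(x$globals$K))
    cat("  K:", paste(sprintf("%s = %.4g", names(x$globals$K), x$globals$K),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Apply the energy gauge to a fit result
#'
#' Removes the additive shift degeneracy by moving the -35 anchor to
#' dG = 0 (shifting the whole -35 family by -delta and the -10 family by
#' +delta), which leaves every ln(K_eq) unchanged. Idempotent; results from
#' [fit_model()], whose anchors are pinned during optimization, pass
#' through unchanged.
#'
#' @param result A `promoter_fit` with additive energies.
#' @param config The [fit_config()] (for the gauge anchors; defaults to the
#'   anchors stored in the result).
#' @return The gauged `promoter_fit`.
#' @export
apply_gauge <- function(result, config = NULL) {
  stopifnot(inherits(result, "promoter_fit"))
  if (result$energy_model != "additive")
    stop("gauge applies to the additive energy model only")
  gauge <- if (!is.null(config) && !is.null(config$gauge)) config$gauge else result$gauge
  if (!gauge$minus35 %in% names(result$energies_minus35))
    stop("gauge anchor '", gauge$minus35, "' absent from -35 energies")
  if (!gauge$minus10 %in% names(result$energies_minus10))
    stop("gauge anchor '", gauge$minus10, "' absent from -10 energies")
  delta <- result$energies_minus35[[gauge$minus35]]
  result$energies_minus35 <- result$energies_minus35 - delta
  result$energies_minus10 <- result$energies_minus10 + delta
  result$gauge <- gauge
  # ln_keq reconstructed from (shifted) site energies: unchanged by the shift
  result$ln_keq <- stats::setNames(
    -(result$energies_minus35[result$variants$minus35] +
        result$energies_minus10[result$variants$minus10]),
    result$variants$variant)
  result
}

# thermo_params of one fitted variant
fit_params_for <- function(result, minus35, minus10) {
  lnk <- if (result$energy_model == "additive")
    -(result$energies_minus35[[minus35]] + result$energies_minus10[[minus10]])
  else {
    v <- result$variants$variant[result$variants$minus35 == minus35 &
                                   result$variants$minus10 == minus10][1L]
    result$ln_keq[[v]]
  }
  regs <- result$template$regulators
  for (i in seq_along(regs))
    regs[[i]]$binding_weight <- result$globals$K[[regs[[i]]$name]]
  p <- thermo_params(site_energies(0, 0), alpha = result$globals$alpha,
                     background = result$globals$background,
                     omega = result$globals$omega, regulators = regs)
  with_ln_keq(p, lnk)
}

#' Predicted rate and fold-change heat maps
#'
#' Evaluates the fitted model for every (-35, -10) combination under each
#' condition, returning one rate matrix per condition (rows = -35 labels,
#' columns = -10 labels, alphabetical as in [assemble_library()]) plus the
#' fold-change matrix of the last vs the first condition (or `on` vs `off`
#' if those names are present).
#'
#' @param result A `promoter_fit`.
#' @param conditions Named list of [inducer_condition()]s (default: the
#'   conditions the model was fitted to).
#' @return List with `rates` (named list of matrices) and `fold_change`.
#' @export
predict_heatmaps <- function(result, conditions = NULL) {
  stopifnot(inherits(result, "promoter_fit"))
  if (is.null(conditions)) conditions <- result$conditions
  labs35 <- sort(unique(result$variants$minus35))
  labs10 <- sort(unique(result$variants$minus10))
  rates <- lapply(conditions, function(cond) {
    m <- matrix(NA_real_, length(labs35), length(labs10),
                dimnames = list(labs35, labs10))
    for (i in labs35) for (j in labs10) {
      if (result$energy_model == "per_combination" &&
          !any(result$variants$minus35 == i & result$variants$minus10 == j))
        next
      m[i, j] <- transcription_rate(fit_params_for(result, i, j), cond)
    }
    m
  })
  nm <- names(conditions)
  i_off <- if ("off" %in% nm) which(nm == "off") else 1L
  i_on <- if ("on" %in% nm) which(nm == "on") else length(conditions)
  list(rates = rates, fold_change = rates[[i_on]] / rates[[i_off]])
}

#' Write a fit result to disk
#'
#' Saves parameters, loss and convergence as JSON plus a per-site energy
#' table as CSV.
#'
#' @param result A `promoter_fit`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fit_result <- function(result, dir) {
  stopifnot(inherits(result, "promoter_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(
    list(energy_model = result$energy_model,
         globals = result$globals,
         ln_keq = as.list(result$ln_keq),
         loss = result$loss, converged = result$converged,
         gauge = result$gauge),
    file.path(dir, "fit_result.json"), auto_unbox = TRUE, digits = NA)
  if (result$energy_model == "additive") {
    en <- rbind(
      data.frame(label = names(result$energies_minus35), kind = "minus35",
                 dG = as.numeric(result$energies_minus35)),
      data.frame(label = names(result$energies_minus10), kind = "minus10",
                 dG = as.numeric(result$energies_minus10)))
    utils::write.csv(en, file.path(dir, "site_energies.csv"), row.names = FALSE)
  }
  invisible(dir)
}
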