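two_cond <- function() {
  list(uninduced = inducer_condition(),
       induced = inducer_condition(arabinose = 5))
}

test_that("log-rate loss matches a naive double-loop oracle", {
  set.seed(7)
  cfg <- synthetic_config(noise_cv = 0.2, seed = 7)
  ds <- generate_library_dataset(cfg)
  obs <- ds$observations[sample(nrow(ds$observations), 60), ]
  params_by_variant <- lapply(
    stats::setNames(unique(obs$variant), unique(obs$variant)),
    function(v) config_params_for_test(cfg, v))
  loss <- log_rate_loss(params_by_variant, obs, cfg$conditions)

  # independent naive accumulation
  want <- 0
  for (i in seq_len(nrow(obs))) {
    pred <- transcription_rate(params_by_variant[[obs$variant[i]]],
                               cfg$conditions[[obs$condition[i]]])
    want <- want + (log(obs$rate_rpu[i]) - log(pred))^2
  }
  expect_lt(abs(loss - want), 1e-12 * max(1, want))

  # predictions equal to observations give zero loss
  exact <- obs
  exact$rate_rpu <- vapply(seq_len(nrow(obs)), function(i)
    transcription_rate(params_by_variant[[obs$variant[i]]],
                       cfg$conditions[[obs$condition[i]]]), 0)
  expect_equal(log_rate_loss(params_by_variant, exact, cfg$conditions), 0)

  # single row at e * prediction gives loss 1
  one <- exact[1, , drop = FALSE]
  one$rate_rpu <- one$rate_rpu * exp(1)
  expect_equal(log_rate_loss(params_by_variant, one, cfg$conditions), 1,
               tolerance = 1e-12)

  # non-positive rates are rejected with advice
  bad <- obs; bad$rate_rpu[1] <- 0
  expect_error(log_rate_loss(params_by_variant, bad, cfg$conditions),
               "floor")
  expect_gt(min(floor_rates(bad)$rate_rpu), 0)
})

test_that("noiseless data yield near-exact energy recovery", {
  cfg <- synthetic_config(noise_cv = 0, seed = 1)
  ds <- generate_library_dataset(cfg)
  fit <- fit_model(ds$observations, cfg$conditions, fit_config(seed = 1))
  expect_true(fit$converged)
  err <- fit$ln_keq[names(ds$truth$ln_keq)] - ds$truth$ln_keq
  expect_lt(max(abs(err)), 1e-3)
  # anchors pinned at zero: gauge matches the truth convention
  expect_equal(fit$energies_minus35[["e"]], 0)
  expect_equal(fit$energies_minus10[["G"]], 0)
  expect_equal(unname(fit$energies_minus35[names(cfg$minus35_energies)]),
               unname(cfg$minus35_energies), tolerance = 1e-3)
  # best-so-far: reported loss is the minimum over starts
  expect_true(all(fit$loss <= fit$start_losses + 1e-12))
})

test_that("fit is invariant to observation row order", {
  cfg <- synthetic_config(noise_cv = 0.1, seed = 21)
  ds <- generate_library_dataset(cfg)
  f1 <- fit_model(ds$observations, cfg$conditions, fit_config(seed = 5))
  set.seed(99)
  shuffled <- ds$observations[sample(nrow(ds$observations)), ]
  f2 <- fit_model(shuffled, cfg$conditions, fit_config(seed = 5))
  expect_equal(f1$ln_keq, f2$ln_keq)
  expect_equal(f1$loss, f2$loss)
})

test_that("an alpha-only fit of flat data recovers the common rate", {
  regs <- list()
  template <- with_ln_keq(
    thermo_params(site_energies(0, 0), alpha = 123, background = 7), 30)
  tab <- expand.grid(variant = c("x-aA", "x-aB", "x-bA", "x-bB"),
                     replicate = 1:2, stringsAsFactors = FALSE)
  tab$minus35 <- substr(tab$variant, 3, 3)
  tab$minus10 <- substr(tab$variant, 4, 4)
  tab$condition <- "only"
  tab$rate_rpu <- 500
  fit <- fit_model(tab, list(only = inducer_condition()),
                   fit_config(free = "alpha", n_starts = 4, seed = 2),
                   template = template)
  # ln Keq = 30 so occupancy is ~1: alpha matches rate minus background
  expect_equal(fit$globals$alpha, 500 - 7, tolerance = 1e-4)
})

test_that("the gauge shift is removed without touching ln Keq", {
  cfg <- synthetic_config(noise_cv = 0, seed = 3)
  ds <- generate_library_dataset(cfg)
  fit <- fit_model(ds$observations, cfg$conditions, fit_config(seed = 3))

  shifted <- fit
  shifted$energies_minus35 <- fit$energies_minus35 + 2
  shifted$energies_minus10 <- fit$energies_minus10 - 2
  regauged <- apply_gauge(shifted)
  expect_equal(regauged$energies_minus35, fit$energies_minus35)
  expect_equal(regauged$energies_minus10, fit$energies_minus10)
  # idempotence
  expect_equal(apply_gauge(regauged), regauged)
  # ln Keq invariant under gauging of an arbitrary shifted result
  set.seed(4)
  arb <- fit
  d <- runif(1, -3, 3)
  arb$energies_minus35 <- fit$energies_minus35 + d
  arb$energies_minus10 <- fit$energies_minus10 - d
  arb$ln_keq <- stats::setNames(
    -(arb$energies_minus35[arb$variants$minus35] +
        arb$energies_minus10[arb$variants$minus10]), arb$variants$variant)
  expect_equal(apply_gauge(arb)$ln_keq, fit$ln_keq, tolerance = 1e-12)

  bad <- fit_config(gauge = list(minus35 = "zz", minus10 = "G"))
  expect_error(apply_gauge(fit, bad), "anchor 'zz' absent")
})

test_that("per-combination model matches additive ln Keq on additive truth", {
  cfg <- synthetic_config(noise_cv = 0, seed = 6)
  ds <- generate_library_dataset(cfg)
  fit <- fit_model(ds$observations, cfg$conditions,
                   fit_config(energy_model = "per_combination", seed = 6))
  err <- fit$ln_keq[names(ds$truth$ln_keq)] - ds$truth$ln_keq
  # unconstrained per-variant Keq: looser than the additive fit but unbiased
  expect_lt(stats::median(abs(err)), 0.05)
})

test_that("site rankings agree between AraC- and LasR-like activators", {
  las <- regulator_spec("LasR", "activator", binding_weight = 200, hill_n = 1.5,
                        half_conc = 0.01, ligand = "3O-C12-HSL")
  cfg_ara <- synthetic_config(noise_cv = 0.1, seed = 31)
  cfg_las <- synthetic_config(regulators = list(LasR = las),
                              noise_cv = 0.1, seed = 32)
  ds_ara <- generate_library_dataset(cfg_ara)
  ds_las <- generate_library_dataset(cfg_las)
  f_ara <- fit_model(ds_ara$observations, cfg_ara$conditions,
                     fit_config(seed = 1), template = default_thermo_params())
  f_las <- fit_model(ds_las$observations, cfg_las$conditions,
                     fit_config(seed = 1),
                     template = default_thermo_params(regulators = list(las)))
  expect_gt(cor(f_ara$energies_minus35, f_las$energies_minus35,
                method = "spearman"), 0.95)
  expect_gt(cor(f_ara$energies_minus10, f_las$energies_minus10,
                method = "spearman"), 0.95)
})

test_that("predicted heat maps are consistent with per-cell fold change", {
  cfg <- synthetic_config(noise_cv = 0, seed = 8)
  ds <- generate_library_dataset(cfg)
  fit <- fit_model(ds$observations, cfg$conditions, fit_config(seed = 8))
  hm <- predict_heatmaps(fit)
  expect_equal(dim(hm$fold_change), c(6L, 8L))
  expect_equal(rownames(hm$fold_change), letters[1:6])
  expect_equal(colnames(hm$fold_change), LETTERS[1:8])
  # identical conditions give a matrix of ones
  same <- predict_heatmaps(fit, list(off = inducer_condition(),
                                     on = inducer_condition()))
  expect_equal(unname(same$fold_change), matrix(1, 6, 8))
  # two routes to fold change agree
  for (i in c("a", "d", "f")) for (j in c("A", "E", "G")) {
    p <- with_ln_keq(default_thermo_params(),
                     -(fit$energies_minus35[[i]] + fit$energies_minus10[[j]]))
    p$alpha <- fit$globals$alpha; p$background <- fit$globals$background
    p$omega <- fit$globals$omega
    p$regulators[[1]]$binding_weight <- fit$globals$K[["AraC"]]
    expect_equal(hm$fold_change[i, j],
                 fold_change(p, cfg$conditions$uninduced,
                             cfg$conditions$induced),
                 tolerance = 1e-12)
  }
})
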