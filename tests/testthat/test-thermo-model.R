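test_that("active fraction follows the Hill response", {
  act <- regulator_spec("AraC", "activator", 50, hill_n = 2,
                        half_conc = 0.5, ligand = "arabinose")
  rep <- regulator_spec("LacI", "repressor", 50, hill_n = 2,
                        half_conc = 0.1, ligand = "IPTG")
  expect_equal(active_fraction(act, inducer_condition()), 0)
  expect_equal(active_fraction(rep, inducer_condition()), 1)
  for (n in c(0.5, 1, 2, 4)) {
    a <- regulator_spec("A", "activator", 1, hill_n = n, half_conc = 0.5,
                        ligand = "x")
    expect_equal(active_fraction(a, inducer_condition(x = 0.5)), 0.5)
  }
  expect_error(active_fraction(act, c(arabinose = -1)), "negative|>= 0")
})

test_that("state enumeration has the exclusion-rule structure", {
  regs <- default_regulators()
  p_a   <- thermo_params(site_energies(1, 1), 100, regulators = regs["AraC"])
  p_ar  <- thermo_params(site_energies(1, 1), 100,
                         regulators = regs[c("AraC", "LacI")])
  p_arr <- thermo_params(site_energies(1, 1), 100,
                         regulators = regs[c("AraC", "LacI", "TetR")])
  p_0   <- thermo_params(site_energies(1, 1), 100)
  expect_equal(nrow(enumerate_states(p_0, NULL)), 2L)    # empty, sigma
  expect_equal(nrow(enumerate_states(p_a, NULL)), 4L)
  expect_equal(nrow(enumerate_states(p_ar, NULL)), 6L)   # no sigma+R states
  expect_equal(nrow(enumerate_states(p_arr, NULL)), 10L)
  # no state holds sigma together with a repressor
  st <- enumerate_states(p_arr, inducer_condition(arabinose = 5))
  sig <- grepl("sigma", st$occupants)
  rep <- grepl("LacI|TetR", st$occupants)
  expect_false(any(sig & rep))
  # empty state has weight 1; all weights non-negative
  expect_equal(st$weight[st$occupants == ""], 1)
  expect_true(all(st$weight >= 0))
  # two activators are unsupported
  expect_error(
    thermo_params(site_energies(1, 1), 100,
                  regulators = regs[c("AraC", "LasR")]),
    "at most one activator")
})

test_that("closed-form occupancy equals the brute-force state sum", {
  set.seed(101)
  for (i in 1:300) {
    p <- random_params(n_repressors = sample(0:3, 1))
    cond <- random_condition(p)
    probs_sum <- {
      st <- enumerate_states(p, cond)
      sum(st$weight)
    }
    expect_lt(abs(p_sigma_bound(p, cond) - enumeration_occupancy(p, cond)),
              1e-12)
  }
  # normalization: state probabilities sum to 1
  p <- random_params(2)
  st <- enumerate_states(p, random_condition(p))
  expect_equal(sum(st$weight / sum(st$weight)), 1)
})

test_that("transcription rate respects its limits", {
  regs <- default_regulators()["AraC"]
  p0 <- thermo_params(site_energies(40, 0), alpha = 1000,
                      background = 0, omega = 100, regulators = regs)
  expect_equal(transcription_rate(p0, NULL), 0, tolerance = 1e-12)
  # large K_eq, no activation: saturates at alpha + background
  psat <- with_ln_keq(thermo_params(site_energies(0, 0), alpha = 1000,
                                    background = 7, omega = 100,
                                    regulators = regs), 30)
  expect_equal(transcription_rate(psat, NULL), 1007, tolerance = 1e-6)
  # rate never drops below background
  set.seed(5)
  for (i in 1:50) {
    p <- random_params(1)
    expect_gte(transcription_rate(p, random_condition(p)), p$background)
  }
})

test_that("rate is monotone in K_eq, activation and repression", {
  regs <- default_regulators()[c("AraC", "LacI")]
  base <- thermo_params(site_energies(0, 0), alpha = 1e5, background = 10,
                        omega = 100, regulators = regs)
  cond <- inducer_condition(arabinose = 1, IPTG = 0.05)
  # K_eq
  rates <- vapply(seq(-10, 10, length.out = 41), function(lk)
    transcription_rate(with_ln_keq(base, lk), cond), 0)
  expect_true(all(diff(rates) >= -1e-9))
  # activation (omega >= 1): increasing arabinose
  p <- with_ln_keq(base, -3)
  r_act <- vapply(c(0, 0.1, 0.5, 2, 5, 50), function(conc)
    transcription_rate(p, inducer_condition(arabinose = conc)), 0)
  expect_true(all(diff(r_act) >= -1e-9))
  # repression: increasing active repressor fraction (less IPTG) lowers rate
  r_rep <- vapply(c(0, 0.05, 0.2, 1, 10), function(conc)
    transcription_rate(p, inducer_condition(arabinose = 5, IPTG = conc)), 0)
  expect_true(all(diff(r_rep) >= -1e-9))  # more IPTG -> less repression
})

test_that("active repressors compound and regulator labels are exchangeable", {
  regs <- default_regulators()[c("AraC", "LacI", "TetR")]
  p <- with_ln_keq(thermo_params(site_energies(0, 0), 1e5, 10, 100,
                                 regulators = regs), -3)
  on_all <- inducer_condition(arabinose = 5, IPTG = 1, aTc = 100)
  r_none <- transcription_rate(p, on_all)                               # both free
  r_lac <- transcription_rate(p, inducer_condition(arabinose = 5, aTc = 100))
  r_tet <- transcription_rate(p, inducer_condition(arabinose = 5, IPTG = 1))
  r_both <- transcription_rate(p, inducer_condition(arabinose = 5))
  expect_lte(r_both, min(r_lac, r_tet) + 1e-9)
  expect_lt(max(r_lac, r_tet), r_none)
  # symmetry: swapping the two repressors leaves outputs unchanged
  p_sw <- with_ln_keq(thermo_params(site_energies(0, 0), 1e5, 10, 100,
                                    regulators = regs[c("AraC", "TetR", "LacI")]), -3)
  for (cond in list(on_all, inducer_condition(arabinose = 5, IPTG = 1))) {
    expect_equal(transcription_rate(p, cond), transcription_rate(p_sw, cond))
  }
})

test_that("fold change and dynamic range behave at their limits", {
  p <- default_thermo_params()
  off <- inducer_condition()
  on <- inducer_condition(arabinose = 5)
  expect_equal(fold_change(p, off, off), 1)
  expect_equal(dynamic_range(p, off, off), 0)
  expect_gte(fold_change(p, off, on), 1)
  # K_eq -> infinity: both states saturate, fold change -> 1
  expect_equal(fold_change(with_ln_keq(p, 25), off, on), 1, tolerance = 1e-6)
  # K_eq = 0: both states at background
  p0 <- with_ln_keq(p, -50)
  expect_equal(dynamic_range(p0, off, on), 0, tolerance = 1e-9)
  # zero background and zero K_eq: undefined ratio errors
  pz <- thermo_params(site_energies(2000, 0), alpha = 100, background = 0,
                      omega = 100, regulators = p$regulators)
  expect_error(fold_change(pz, off, on), "undefined")
})

test_that("dose-response curves are monotone and consistent at the ends", {
  p <- default_thermo_params()
  conc <- c(0, 10^seq(-4, 2, length.out = 25))
  dr <- dose_response_curve(p, "arabinose", conc)
  expect_equal(dr$rate[1], transcription_rate(p, inducer_condition()))
  expect_true(all(diff(dr$rate) >= -1e-9))
  # saturation equals the rate with active_fraction = 1
  keq <- exp(ln_keq(p))
  q_sat <- p$regulators[[1]]$binding_weight  # a = 1
  r_sat <- p$alpha * keq * (1 + q_sat * p$omega) /
    ((1 + q_sat) + keq * (1 + q_sat * p$omega)) + p$background
  expect_equal(transcription_rate(p, inducer_condition(arabinose = 1e9)),
               r_sat, tolerance = 1e-6)
  expect_error(dose_response_curve(p, "xylose", conc), "unknown ligand")
  # repressor-deactivating ligand also raises the rate
  p2 <- thermo_params(site_energies(2, 1), 1e5, 10, 100,
                      regulators = default_regulators()[c("AraC", "LacI")])
  dr2 <- dose_response_curve(p2, "IPTG", c(0, 0.01, 0.1, 1, 10))
  expect_true(all(diff(dr2$rate) >= -1e-9))
})

test_that("K_eq sweep reproduces the three-regime dynamic-range picture", {
  p <- default_thermo_params()
  off <- inducer_condition(); on <- inducer_condition(arabinose = 5)
  grid <- seq(-25, 25, length.out = 121)
  sw <- sweep_keq(p, grid, off, on)
  expect_equal(names(sw), c("ln_keq", "r_off", "r_on", "fold_change",
                            "dynamic_range"))
  expect_true(all(diff(sw$r_on) >= -1e-9))
  expect_true(all(diff(sw$r_off) >= -1e-9))
  # single interior maximum of dynamic range
  imax <- which.max(sw$dynamic_range)
  expect_gt(imax, 1); expect_lt(imax, nrow(sw))
  signs <- sign(diff(sw$dynamic_range))
  expect_lte(sum(diff(signs[signs != 0]) != 0), 1)  # unimodal
  # fold change -> 1 at both extremes (background > 0)
  expect_equal(sw$fold_change[1], 1, tolerance = 1e-3)
  expect_equal(sw$fold_change[nrow(sw)], 1, tolerance = 1e-3)
  # low-K_eq regime: low leak, poor induction vs the optimum
  expect_lt(sw$r_off[1], sw$r_off[imax])
  expect_lt(sw$dynamic_range[1], sw$dynamic_range[imax])
  # high-K_eq regime: high leak
  expect_gt(sw$r_off[nrow(sw)], sw$r_off[imax])
})
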