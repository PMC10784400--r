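test_that("standard Gibbs energies are stoichiometric sums of dgf", {
  m <- make_model(
    mets = list(met("A", dgf = -100), met("B", dgf = -105),
                met("C", dgf = -90)),
    rxns = list(rx("R1", c(A = -1, B = 1)),
                rx("R2", c(A = -2, C = 1)),
                rx("EX", c(A = -1, B = 1), exchange = TRUE)))
  dg0 <- standard_gibbs(m)
  expect_equal(unname(dg0["R1"]), -5)
  expect_equal(unname(dg0["R2"]), -90 - 2 * (-100))
  expect_equal(unname(dg0["EX"]), -5)  # boundary species still contribute
})

test_that("2A(-50) -> B(-90) gives +10 kJ/mol", {
  m <- make_model(
    mets = list(met("A", dgf = -50), met("B", dgf = -90)),
    rxns = list(rx("R", c(A = -2, B = 1))))
  expect_equal(unname(standard_gibbs(m)["R"]), +10)
})

test_that("reaction Gibbs energy follows dG0' + RT log-term", {
  p <- thermo_params()
  m <- make_model(
    mets = list(met("S", dgf = 0), met("P", dgf = 0)),
    rxns = list(rx("R", c(S = -1, P = 1), reversible = TRUE)))
  # S = 10 mM, P = 1 mM -> dG = RT ln 0.1 = -5.842 kJ/mol
  dg <- reaction_gibbs(m, c(S = log(0.01), P = log(0.001)), p)
  expect_equal(unname(dg["R"]), -5.842, tolerance = 1e-3)
  # all concentrations 1 M -> standard state
  dg1 <- reaction_gibbs(m, c(S = 0, P = 0), p)
  expect_equal(unname(dg1["R"]), 0)
  # equilibrium concentrations -> dG = 0 (with nonzero dG0')
  m2 <- make_model(
    mets = list(met("S", dgf = 0), met("P", dgf = -5)),
    rxns = list(rx("R", c(S = -1, P = 1), reversible = TRUE)))
  lnr <- 5 / p$RT  # ln(P/S) at equilibrium
  dg2 <- reaction_gibbs(m2, c(S = 0, P = lnr), p)
  expect_equal(unname(dg2["R"]), 0, tolerance = 1e-10)
})

test_that("thermodynamics force closed-loop fluxes to zero", {
  m <- cycle_model()
  # seal the anchor exchange; only the internal 3-cycle remains
  st <- steady_state_record("s", rates = c(EX_A = 0), rate_sd = c(EX_A = 0),
                            is_reference = TRUE)
  res <- solve_tfa(m, st, objective = "EX_A", variability = TRUE,
                   var_targets = "flux")
  expect_equal(res$status, "optimal")
  expect_lt(max(abs(res$v_opt[c("RAB", "RBC", "RCA")])), 1e-6)
  expect_lt(max(abs(res$ranges$flux[c("RAB", "RBC", "RCA"), ])), 1e-6)
  # the LP relaxation without Gibbs coupling would allow the loop
  fva <- flux_variability(m, st)
  expect_gt(max(fva[c("RAB", "RBC", "RCA"), "max"]), 1)
})

test_that("a two-step chain splits the overall Gibbs drop", {
  p <- thermo_params()
  m <- chain_model()
  st <- steady_state_record("s", rates = c(R1 = 1), rate_sd = c(R1 = 0),
                            is_reference = TRUE)
  res <- solve_tfa(m, st, objective = "R2", variability = TRUE)
  expect_equal(res$status, "optimal")
  expect_equal(unname(res$v_opt[c("R1", "R2")]), c(1, 1), tolerance = 1e-5)
  total <- sum(res$dg_opt[c("R1", "R2")])
  expect_equal(total, p$RT * log(0.01), tolerance = 1e-4)  # -11.68 kJ/mol
  expect_true(all(res$dg_opt[c("R1", "R2")] < 0))
})

test_that("forcing flux against the Gibbs gradient is diagnosed as thermodynamic", {
  # same chain but boundary concentrations reversed: S = 0.1 mM, P = 10 mM
  m <- make_model(
    mets = list(met("S", boundary = TRUE, dgf = 0, conc_fixed = 1e-4),
                met("X", dgf = 0),
                met("P", boundary = TRUE, dgf = 0, conc_fixed = 1e-2)),
    rxns = list(rx("R1", c(S = -1, X = 1)),   # irreversible forward
                rx("R2", c(X = -1, P = 1))),
    objective = "R2")
  st <- steady_state_record("s", rates = c(R1 = 1), rate_sd = c(R1 = 0),
                            is_reference = TRUE)
  res <- solve_tfa(m, st, objective = "R2")
  expect_false(res$status == "optimal")
  expect_equal(res$diagnosis$family, "thermodynamic")
})

test_that("every TFA optimum satisfies mass balance and v-dG sign consistency", {
  net <- toy_net_fixture()
  ds <- toy_dataset_exact()
  res <- solve_tfa(net, ds$states[["REF"]])
  N <- stoichiometric_matrix(net)
  expect_lt(max(abs(N %*% res$v_opt)), 1e-7)
  exch <- vapply(net$reactions, `[[`, FALSE, "exchange")
  for (rid in reaction_ids(net)[!exch]) {
    v <- res$v_opt[[rid]]; dg <- res$dg_opt[[rid]]
    if (v > 1e-6) expect_lt(dg, 0)
    if (v < -1e-6) expect_gt(dg, 0)
  }
  expect_true(all(res$ranges$flux[, "min"] <= res$v_opt + 1e-6))
  expect_true(all(res$ranges$flux[, "max"] >= res$v_opt - 1e-6))
})

test_that("relaxing the objective fraction never narrows variability ranges", {
  net <- toy_net_fixture()
  ds <- toy_dataset_exact()
  st <- ds$states[["REF"]]
  tight <- solve_tfa(net, st, thermo_params(objective_fraction = 0.999),
                     var_targets = "flux")
  loose <- solve_tfa(net, st, thermo_params(objective_fraction = 0.9),
                     var_targets = "flux")
  expect_true(all(loose$ranges$flux[, "min"] <= tight$ranges$flux[, "min"] + 1e-6))
  expect_true(all(loose$ranges$flux[, "max"] >= tight$ranges$flux[, "max"] - 1e-6))
})

test_that("without binding thermodynamics TFA ranges match the plain FVA oracle", {
  # all-reversible triangle with an open exchange; dgf = 0 everywhere and
  # wide concentration bounds leave the Gibbs coupling unconstraining
  m <- make_model(
    mets = list(met("A", dgf = 0, conc_min = 1e-8, conc_max = 10),
                met("B", dgf = 0, conc_min = 1e-8, conc_max = 10),
                met("ZB", boundary = TRUE, dgf = 0)),
    rxns = list(rx("RAB", c(A = -1, B = 1), reversible = TRUE),
                rx("EXA", c(ZB = -1, A = 1), exchange = TRUE,
                   reversible = TRUE),
                rx("EXB", c(B = -1, ZB = 1), exchange = TRUE,
                   reversible = TRUE)),
    objective = "EXB")
  st <- steady_state_record("s", rates = c(EXA = -2), rate_sd = c(EXA = 0.1),
                            is_reference = TRUE)
  tfa <- solve_tfa(m, st, var_targets = "flux")
  fva <- flux_variability(m, st, objective = "EXB")
  expect_equal(tfa$ranges$flux[, "min"], fva[, "min"], tolerance = 1e-6)
  expect_equal(tfa$ranges$flux[, "max"], fva[, "max"], tolerance = 1e-6)
})
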