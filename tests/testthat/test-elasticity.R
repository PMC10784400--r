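test_that("thermokinetic elasticities follow n RT / dG with floor and cap", {
  p <- thermo_params()
  r <- list(id = "R", stoich = c(S = -1, P = 1), reversible = TRUE,
            effectors = character(0))
  e1 <- thermokinetic_elasticity(r, -p$RT, p)
  expect_equal(unname(e1["S"]), 1)
  expect_equal(unname(e1["P"]), -1)
  e2 <- thermokinetic_elasticity(r, -10 * p$RT, p)  # dG = -25.37 kJ/mol
  expect_equal(unname(e2["S"]), 0.1, tolerance = 1e-12)
  # magnitude decreases with |dG| and vanishes far from equilibrium
  mags <- sapply(c(-1, -5, -20, -100), function(dg)
    abs(thermokinetic_elasticity(r, dg, p)[["S"]]))
  expect_true(all(diff(mags) < 0))
  # floor + cap near equilibrium
  e3 <- thermokinetic_elasticity(r, -1e-6, p)
  expect_equal(unname(abs(e3["S"])), p$eps_cap)
  expect_error(thermokinetic_elasticity(r, +2, p), "inconsistent")
})

make_linlog_dataset <- function(eps_true, n_states = 12, noise = 0, seed = 1,
                                c0 = NULL) {
  mets <- names(eps_true)
  c0 <- c0 %||% stats::setNames(rep(1e-3, length(mets)), mets)
  set.seed(seed)
  states <- list(steady_state_record("REF", c0, is_reference = TRUE))
  vk <- c(REF = 1)
  for (k in seq_len(n_states)) {
    dln <- stats::rnorm(length(mets), 0, 0.25)
    ck <- c0 * exp(dln)
    v <- 1 + sum(eps_true * dln)
    obs <- ck * exp(stats::rnorm(length(mets), 0, noise))
    id <- paste0("S", k)
    states[[length(states) + 1L]] <- steady_state_record(id, obs)
    vk[id] <- v * exp(stats::rnorm(1, 0, noise))
  }
  list(ds = invivomca:::new_dataset(states), vk = vk)
}

test_that("lin-log regression interpolates noiseless data exactly", {
  z <- make_linlog_dataset(c(X = 0.7))
  fit <- linlog_fit(z$ds, z$vk, "X")
  expect_equal(unname(fit$eps["X"]), 0.7, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  # residual exactly zero with more participants than needed
  z2 <- make_linlog_dataset(c(X = 0.9, Y = -0.4))
  fit2 <- linlog_fit(z2$ds, z2$vk, c("X", "Y"))
  expect_equal(unname(fit2$eps), c(0.9, -0.4), tolerance = 1e-8)
})

test_that("lin-log regression is underdetermined on degenerate designs", {
  c0 <- c(X = 1e-3)
  states <- c(list(steady_state_record("REF", c0, is_reference = TRUE)),
              lapply(1:5, function(k)
                steady_state_record(paste0("S", k), c0)))
  ds <- invivomca:::new_dataset(states)
  vk <- stats::setNames(rep(1, 6), c("REF", paste0("S", 1:5)))
  expect_error(linlog_fit(ds, vk, "X"), "underdetermined")
  # zero reference concentration
  z <- make_linlog_dataset(c(X = 0.7))
  z$ds$states[["REF"]]$conc_intra["X"] <- 0
  expect_error(linlog_fit(z$ds, z$vk, "X"), "positive concentration")
})

test_that("lin-log recovery under 1% noise stays within +/- 0.1", {
  # tolerance checked against a repeated-simulation oracle at fixed seeds
  errs <- sapply(1:10, function(s) {
    z <- make_linlog_dataset(c(X = 0.9, Y = -0.4), noise = 0.01, seed = s)
    fit <- linlog_fit(z$ds, z$vk, c("X", "Y"))
    max(abs(fit$eps - c(X = 0.9, Y = -0.4)))
  })
  expect_lt(max(errs), 0.1)
})

test_that("lin-log elasticities depend only on concentration ratios", {
  z <- make_linlog_dataset(c(X = 0.6, Y = 0.3), seed = 7)
  fit1 <- linlog_fit(z$ds, z$vk, c("X", "Y"))
  zs <- z
  for (i in seq_along(zs$ds$states)) {
    zs$ds$states[[i]]$conc_intra <- zs$ds$states[[i]]$conc_intra * 137
  }
  fit2 <- linlog_fit(zs$ds, zs$vk, c("X", "Y"))
  expect_equal(fit1$eps, fit2$eps, tolerance = 1e-10)
})

test_that("assembly routes 14 thermokinetic and 23 lin-log rows on the canonical model", {
  m <- canonical_model()
  tfa <- synthetic_reference_tfa(m)
  samples <- sample_gibbs(tfa, m, n = 2000, seed = 5)
  status <- classify_equilibrium(samples, m)
  ds <- canonical_synthetic_dataset(m, seed = 3)
  E <- suppressWarnings(
    elasticity_matrix(m, status, tfa, ds, fluxes = attr(ds, "fluxes")))
  interior <- interior_reaction_ids(m)
  expect_equal(sum(E$regime[interior] == "thermokinetic"), 14)
  expect_equal(sum(E$regime[interior] == "linlog"), 23)
  # the sulfocysteine lyase row carries its NADPH cofactor dependence
  expect_true(E$eps["SCYSSL", "NADPH"] != 0)
  # elasticities only where participants are declared
  r <- get_reaction(m, "PGI")
  nonpart <- setdiff(colnames(E$eps), names(r$stoich))
  expect_true(all(E$eps["PGI", nonpart] == 0))
})

test_that("reactions without interior participants get a zero row and warning", {
  m <- make_model(
    mets = list(met("A", dgf = 0),
                met("B1", boundary = TRUE, dgf = 0),
                met("B2", boundary = TRUE, dgf = 0)),
    rxns = list(rx("RIN", c(B1 = -1, A = 1)),
                rx("RPASS", c(B1 = -1, B2 = 1), exchange = TRUE),
                rx("ROUT", c(A = -1, B2 = 1), exchange = TRUE)))
  status <- data.frame(reaction_id = "RIN", q1 = -20, q3 = -15,
                       status = "non_equilibrium", source = "quartile_rule",
                       row.names = "RIN")
  c0 <- c(A = 1e-3)
  states <- c(list(steady_state_record("REF", c0, is_reference = TRUE)),
              lapply(1:3, function(k)
                steady_state_record(paste0("S", k), c0 * exp(0.1 * k))))
  ds <- invivomca:::new_dataset(states)
  fl <- matrix(seq_len(12) / 6, 3, 4,
               dimnames = list(c("RIN", "RPASS", "ROUT"),
                               c("REF", "S1", "S2", "S3")))
  fl["RPASS", ] <- 1
  tfa <- list(dg_opt = c(RIN = -15, RPASS = -1, ROUT = -1))
  w <- capture_warnings(E <- elasticity_matrix(m, status, tfa, ds, fluxes = fl))
  expect_match(w, "no non-boundary participants", all = FALSE)
  expect_true(all(E$eps["RPASS", ] == 0))
})
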