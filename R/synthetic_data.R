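# Kinetic ground truth for validating the whole analysis chain: a small
# cysteine-branch toy pathway with known rate laws, a steady-state solver, a
# perturbation-experiment emulator, and a finite-difference control
# coefficient oracle.

#' Construct the kinetic toy model
#'
#' A 9-enzyme, 8-metabolite pathway (plus supply, respiration and product
#' export as boundary-condition steps) mirroring the L-cysteine branch
#' competition motif: a glycolysis-like backbone feeds a serine branch to an
#' O-acetylserine (OAS) analogue that is consumed by two competing synthases
#' with distinct boundary sulphur co-substrates (a direct synthase and a
#' two-step sulfocysteine route) and drained by an exporter. In the default
#' export-dominant parameterization the exporter's rate constant is at least
#' five times the synthases', reproducing the precursor-drain situation in
#' which the exporter holds negative control over synthesis.
#'
#' Rate laws: irreversible, far-from-equilibrium kinetics throughout
#' (saturable supply, mass action on the branches) with product inhibition
#' on the committed steps. The product-inhibition feedbacks propagate
#' downstream perturbations upstream, so the feeding regimes excite every
#' metabolite through at least two independent routes - the property that
#' makes the lin-log elasticity regression identifiable. Concentrations are
#' carried in mM.
#'
#' @param export_dominant logical; `FALSE` weakens the exporter about
#'   tenfold
#' @return object of class `kinetic_toy` with elements `mets`, `rxn_ids`,
#'   `k` (rate constants), `km` (saturation/inhibition constants), `e`
#'   (enzyme levels, reference 1), `boundary_ref` (mM), `N` (interior
#'   stoichiometry), `x_ref` (reference steady state, mM), `v_ref`
#' @export
toy_model <- function(export_dominant = TRUE) {
  mets <- c("G6P", "T3P", "PEP", "PYR", "SER", "OAS", "SSC", "CYS")
  rxn_ids <- c("UPT", "PUPT", "EMP1", "EMP2", "PYK", "RESP", "SERS", "SERAT",
               "CYSS", "SLCYSS", "SCYSSL", "SEREX", "CYSEX")
  k <- c(UPT = 1.5, PUPT = 1.5, EMP1 = 3, EMP2 = 4, PYK = 3, RESP = 2,
         SERS = 2.5, SERAT = 2, CYSS = 0.5, SLCYSS = 0.45, SCYSSL = 2,
         SEREX = if (export_dominant) 2.5 else 0.25, CYSEX = 3)
  Keq <- numeric(0)  # all steps operate far from equilibrium
  km <- c(UPT_ki = 0.6, EMP1_ki = 0.6, EMP2_ki = 0.6,
          PYK_ki = 0.6, PUPT_ki = 0.5, SERS_km = 1, SERS_ki = 0.4,
          SERAT_ki = 0.6, CYSS_ki = 0.4)
  N <- matrix(0, 8, 13, dimnames = list(mets, rxn_ids))
  N["G6P", c("UPT", "EMP1")] <- c(1, -1)
  N["T3P", c("EMP1", "EMP2", "SERS")] <- c(2, -1, -1)
  N["PEP", c("EMP2", "PYK")] <- c(1, -1)
  N["PYR", c("PUPT", "PYK", "RESP")] <- c(1, 1, -1)
  N["SER", c("SERS", "SERAT")] <- c(1, -1)
  N["OAS", c("SERAT", "CYSS", "SLCYSS", "SEREX")] <- c(1, -1, -1, -1)
  N["SSC", c("SLCYSS", "SCYSSL")] <- c(1, -1)
  N["CYS", c("CYSS", "SCYSSL", "CYSEX")] <- c(1, 1, -1)
  toy <- structure(
    list(mets = mets, rxn_ids = rxn_ids, k = k, Keq = Keq, km = km, N = N,
         e = stats::setNames(rep(1, 13), rxn_ids),
         boundary_ref = c(glc = 2, pyr = 0.3, ts = 1, h2s = 1),
         export_dominant = export_dominant),
    class = "kinetic_toy")
  ss <- toy_steady_state(toy)
  toy$x_ref <- ss$x
  toy$v_ref <- ss$v
  # strict stability of the reference state
  Jdyn <- toy_dynamics_jacobian(toy, ss$x, toy$boundary_ref)
  if (max(Re(eigen(Jdyn, only.values = TRUE)$values)) >= -1e-9) {
    stopf("toy reference steady state is not strictly stable")
  }
  toy
}

#' Rate laws of the toy model
#'
#' @param toy a `kinetic_toy`
#' @param x named concentrations, mM
#' @param boundary named boundary concentrations (glc, pyr, ts, h2s), mM
#' @param e enzyme levels (default: the toy's)
#' @return named flux vector
#' @export
toy_rates <- function(toy, x, boundary = toy$boundary_ref, e = toy$e) {
  k <- toy$k; km <- toy$km
  b <- boundary
  v <- c(
    UPT = e[["UPT"]] * k[["UPT"]] * b[["glc"]] / (1 + x[["G6P"]] / km[["UPT_ki"]]),
    PUPT = e[["PUPT"]] * k[["PUPT"]] * b[["pyr"]] / (1 + x[["PYR"]] / km[["PUPT_ki"]]),
    EMP1 = e[["EMP1"]] * k[["EMP1"]] * x[["G6P"]] / (1 + x[["T3P"]] / km[["EMP1_ki"]]),
    EMP2 = e[["EMP2"]] * k[["EMP2"]] * x[["T3P"]] / (1 + x[["PEP"]] / km[["EMP2_ki"]]),
    PYK = e[["PYK"]] * k[["PYK"]] * x[["PEP"]] / (1 + x[["PYR"]] / km[["PYK_ki"]]),
    RESP = e[["RESP"]] * k[["RESP"]] * x[["PYR"]],
    SERS = e[["SERS"]] * k[["SERS"]] * x[["T3P"]] / (km[["SERS_km"]] + x[["T3P"]]) /
      (1 + x[["SER"]] / km[["SERS_ki"]]),
    SERAT = e[["SERAT"]] * k[["SERAT"]] * x[["SER"]] / (1 + x[["OAS"]] / km[["SERAT_ki"]]),
    CYSS = e[["CYSS"]] * k[["CYSS"]] * x[["OAS"]] * b[["h2s"]] /
      (1 + x[["CYS"]] / km[["CYSS_ki"]]),
    SLCYSS = e[["SLCYSS"]] * k[["SLCYSS"]] * x[["OAS"]] * b[["ts"]],
    SCYSSL = e[["SCYSSL"]] * k[["SCYSSL"]] * x[["SSC"]],
    SEREX = e[["SEREX"]] * k[["SEREX"]] * x[["OAS"]],
    CYSEX = e[["CYSEX"]] * k[["CYSEX"]] * x[["CYS"]])
  v
}

toy_dynamics_jacobian <- function(toy, x, boundary, e = toy$e, h = 1e-6) {
  f0 <- drop(toy$N %*% toy_rates(toy, x, boundary, e))
  J <- matrix(0, length(x), length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h * max(abs(x[i]), 1)
    fp <- drop(toy$N %*% toy_rates(toy, xp, boundary, e))
    J[, i] <- (fp - f0) / (h * max(abs(x[i]), 1))
  }
  J
}

#' Solve the toy model to steady state
#'
#' Damped Newton iteration on `dx/dt = N v(x) = 0` from a positive starting
#' point; converged when `||N v|| < tol`.
#'
#' @param toy a `kinetic_toy`
#' @param regime one of `"glucose"`, `"pyruvate"`, `"mix_ts"`, `"mix_h2s"`,
#'   or `NULL` for the reference boundary
#' @param level feeding level 1, 2, 3 or 0 for the reference
#' @param e enzyme levels
#' @param x0 starting concentrations, mM
#' @param tol residual tolerance on `||N v||`
#' @param max_iter iteration cap
#' @return list with `x` (mM), `v`, `boundary`, `residual`
#' @export
toy_steady_state <- function(toy, regime = NULL, level = 0, e = toy$e,
                             x0 = NULL, tol = 1e-11, max_iter = 200) {
  boundary <- toy_boundary(toy, regime, level)
  x <- x0 %||% toy$x_ref %||% stats::setNames(rep(0.5, length(toy$mets)), toy$mets)
  f <- function(x) drop(toy$N %*% toy_rates(toy, x, boundary, e))
  fx <- f(x)
  for (it in seq_len(max_iter)) {
    if (max(abs(fx)) < tol) break
    J <- toy_dynamics_jacobian(toy, x, boundary, e)
    step <- tryCatch(solve(J, -fx), error = function(err) NULL)
    if (is.null(step)) stopf("singular Jacobian in toy steady-state solve")
    lam <- 1
    repeat {
      xn <- x + lam * step
      if (all(xn > 1e-12)) {
        fn <- f(xn)
        if (max(abs(fn)) < max(abs(fx)) || lam < 1e-6) break
      }
      lam <- lam / 2
      if (lam < 1e-10) stopf("toy steady-state solve stalled (residual %.3g)",
                             max(abs(fx)))
    }
    x <- xn; fx <- fn
  }
  if (max(abs(fx)) >= tol) {
    stopf("no convergence after %d iterations (residual %.3g)", max_iter,
          max(abs(fx)))
  }
  names(x) <- toy$mets
  list(x = x, v = toy_rates(toy, x, boundary, e), boundary = boundary,
       residual = max(abs(fx)))
}

toy_boundary <- function(toy, regime = NULL, level = 0) {
  b <- toy$boundary_ref
  if (is.null(regime) || level == 0) return(b)
  # geometric level factors centred on the reference supply (level 2), so
  # the three increasing steps bracket the reference symmetrically in log
  f <- 1.25^(level - 2)   # carbon-source factor for levels 1..3
  fp <- 1.6^(level - 2)   # pyruvate feed factor (reference feed is small)
  fs <- 1.5^(level - 2)   # sulphur-source factor
  switch(regime,
         glucose = { b["glc"] <- b["glc"] * f },
         pyruvate = { b["pyr"] <- b["pyr"] * fp },
         mix_ts = { b["glc"] <- b["glc"] * sqrt(f); b["ts"] <- b["ts"] * fs },
         mix_h2s = { b["pyr"] <- b["pyr"] * sqrt(fp); b["h2s"] <- b["h2s"] * fs },
         stopf("unknown regime '%s'", regime))
  b
}

#' Perturbation design for the synthetic feeding experiment
#'
#' Four substrate-supply regimes x three increasing feeding levels, with
#' multiplicative lognormal measurement noise, emulating a reference
#' production state plus 12 short feeding-step steady states.
#'
#' @param regimes character vector of regime names
#' @param levels integer feeding levels
#' @param noise_sd lognormal sd of concentration and rate measurements
#'   (default 0.05, a typical LC-MS replicate spread)
#' @param seed RNG seed
#' @return object of class `perturbation_design`
#' @export
perturbation_design <- function(regimes = c("glucose", "pyruvate",
                                            "mix_ts", "mix_h2s"),
                                levels = 1:3, noise_sd = 0.05, seed = 1) {
  stopifnot(noise_sd >= 0)
  structure(list(regimes = regimes, levels = levels, noise_sd = noise_sd,
                 seed = seed),
            class = "perturbation_design")
}

# measured transport rates: reaction id -> sign mapping q = sign * v
# (uptake negative convention)
toy_measured_map <- function() c(UPT = -1, PUPT = -1, SLCYSS = -1,
                                 SEREX = 1, CYSEX = 1)

#' Generate a synthetic steady-state dataset from the toy model
#'
#' Solves the exact steady state for the reference boundary and every
#' (regime, level) cell, converts concentrations to mol/L, applies
#' multiplicative lognormal noise to concentrations and measured transport
#' rates, and returns a `steady_state_dataset` with the exact truth attached
#' as `attr(, "truth")`.
#'
#' @param toy a `kinetic_toy`
#' @param design a [perturbation_design()]
#' @return a `steady_state_dataset` with 13 states; `attr(,"truth")` holds
#'   exact concentrations (mol/L), the exact flux matrix, and enzyme levels
#' @export
generate_dataset <- function(toy, design = perturbation_design()) {
  meas <- toy_measured_map()
  cells <- list(list(id = "REF", regime = NULL, level = 0))
  for (r in design$regimes) for (l in design$levels) {
    cells[[length(cells) + 1L]] <- list(
      id = sprintf("%s_L%d", toupper(r), l), regime = r, level = l)
  }
  exact <- lapply(cells, function(cl)
    toy_steady_state(toy, cl$regime, cl$level))
  bnd_map <- c(glc = "GLC_b", pyr = "PYR_b", ts = "TS_b", h2s = "H2S_b")
  ids <- vapply(cells, `[[`, "", "id")
  flux_truth <- vapply(exact, `[[`, numeric(length(toy$rxn_ids)), "v")
  dimnames(flux_truth) <- list(toy$rxn_ids, ids)
  conc_truth <- vapply(exact, function(s) s$x / 1000, numeric(length(toy$mets)))
  dimnames(conc_truth) <- list(toy$mets, ids)

  states <- with_seed(design$seed, lapply(seq_along(cells), function(i) {
    c_true <- conc_truth[, i]
    v_true <- flux_truth[, i]
    noise <- function(x) x * exp(stats::rnorm(length(x), 0, design$noise_sd))
    c_obs <- noise(c_true)
    q_true <- meas * v_true[names(meas)]
    q_obs <- sign(q_true) * noise(abs(q_true))
    b_true <- stats::setNames(exact[[i]]$boundary[names(bnd_map)] / 1000,
                              bnd_map)
    steady_state_record(
      id = ids[i],
      conc_intra = c_obs,
      conc_sd = design$noise_sd * c_obs,
      rates = q_obs,
      rate_sd = design$noise_sd * abs(q_obs),
      conc_extra = noise(b_true),
      is_reference = identical(ids[i], "REF"))
  }))
  ds <- new_dataset(states, design = design)
  attr(ds, "truth") <- list(conc = conc_truth, flux = flux_truth, e = toy$e)
  ds
}

#' Finite-difference flux control coefficient oracle
#'
#' Re-solves the toy steady state with each enzyme scaled by `1 +- delta`
#' and returns the central log-difference
#' `C^J = [ln J(e(1+d)) - ln J(e(1-d))] / [ln(1+d) - ln(1-d)]`, with a
#' Richardson consistency check at `delta/2`.
#'
#' @param toy a `kinetic_toy`
#' @param target_flux reaction id, or `NULL` for the full flux x enzyme
#'   matrix
#' @param delta relative perturbation (default 0.01)
#' @param richardson logical: attach the `delta/2` recomputation as
#'   `attr(, "richardson_diff")`
#' @return named FCC vector over enzymes (or matrix if `target_flux` is
#'   `NULL`)
#' @export
true_fcc <- function(toy, target_flux = NULL, delta = 0.01,
                     richardson = FALSE) {
  fcc_at <- function(d) {
    out <- matrix(NA_real_, length(toy$rxn_ids), length(toy$rxn_ids),
                  dimnames = list(toy$rxn_ids, toy$rxn_ids))
    for (enz in toy$rxn_ids) {
      ep <- toy$e; ep[enz] <- ep[enz] * (1 + d)
      em <- toy$e; em[enz] <- em[enz] * (1 - d)
      vp <- toy_steady_state(toy, e = ep)$v
      vm <- toy_steady_state(toy, e = em)$v
      out[, enz] <- (log(vp) - log(vm)) / (log(1 + d) - log(1 - d))
    }
    out
  }
  fcc <- fcc_at(delta)
  if (richardson) attr(fcc, "richardson_diff") <- max(abs(fcc - fcc_at(delta / 2)))
  if (!is.null(target_flux)) {
    if (!(target_flux %in% toy$rxn_ids)) stopf("unknown reaction id: %s", target_flux)
    r <- fcc[target_flux, ]
    attr(r, "richardson_diff") <- attr(fcc, "richardson_diff")
    return(r)
  }
  fcc
}

#' Exact local elasticities of the toy model
#'
#' Normalized sensitivities `d ln v_j / d ln x_i` at a steady state, by
#' central finite differences on the rate laws.
#'
#' @param toy a `kinetic_toy`
#' @param x concentrations (default: the reference steady state), mM
#' @param boundary boundary concentrations
#' @param h relative step
#' @return matrix reactions x metabolites
#' @export
toy_elasticities <- function(toy, x = toy$x_ref, boundary = toy$boundary_ref,
                             h = 1e-6) {
  v0 <- toy_rates(toy, x, boundary)
  eps <- matrix(0, length(toy$rxn_ids), length(toy$mets),
                dimnames = list(toy$rxn_ids, toy$mets))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] * (1 + h)
    xm <- x; xm[i] <- x[i] * (1 - h)
    dv <- (toy_rates(toy, xp, boundary) - toy_rates(toy, xm, boundary)) / (2 * h)
    eps[, i] <- dv / v0
  }
  eps
}

#' Convert the toy model to a `network_model` for TFA
#'
#' Formation energies are fitted so that every reversible reaction's
#' standard Gibbs energy matches `-RT ln Keq` (after mM -> M conversion) and
#' the irreversible steps get strongly negative assigned values; kinetic
#' direction and thermodynamic feasibility are then consistent by
#' construction.
#'
#' @param toy a `kinetic_toy`
#' @param params a [thermo_params()] object
#' @return a `network_model` with objective `CYSEX`
#' @export
toy_network <- function(toy, params = thermo_params()) {
  mk_met <- function(id, name, boundary = FALSE, conc_fixed = 1) {
    data.frame(id = id, name = name, dgf = NA_real_, boundary = boundary,
               conc_min = 1e-8, conc_max = 0.1, conc_fixed = conc_fixed,
               stringsAsFactors = FALSE)
  }
  mets <- rbind(
    mk_met("G6P", "hexose phosphate pool"),
    mk_met("T3P", "triose phosphate pool"),
    mk_met("PEP", "phosphoenolpyruvate"),
    mk_met("PYR", "pyruvate"),
    mk_met("SER", "serine"),
    mk_met("OAS", "O-acetylserine analogue"),
    mk_met("SSC", "sulfocysteine analogue"),
    mk_met("CYS", "cysteine analogue"),
    mk_met("GLC_b", "boundary carbon source", TRUE,
           conc_fixed = toy$boundary_ref[["glc"]] / 1000),
    mk_met("PYR_b", "boundary pyruvate feed", TRUE,
           conc_fixed = toy$boundary_ref[["pyr"]] / 1000),
    mk_met("TS_b", "boundary thiosulfate", TRUE,
           conc_fixed = toy$boundary_ref[["ts"]] / 1000),
    mk_met("H2S_b", "boundary sulfide", TRUE,
           conc_fixed = toy$boundary_ref[["h2s"]] / 1000),
    mk_met("CO2_b", "respiration sink", TRUE, conc_fixed = 1e-3),
    mk_met("NAS_b", "exported acetylserine", TRUE, conc_fixed = 1e-4),
    mk_met("CYS_b", "exported cysteine", TRUE, conc_fixed = 1e-3))
  rxn <- function(id, stoich, reversible = FALSE, exchange = FALSE,
                  uptake = FALSE, effectors = character(0)) {
    list(id = id, stoich = stoich, reversible = reversible,
         forced_nonequilibrium = FALSE, exchange = exchange, uptake = uptake,
         pathway = "toy", effectors = effectors)
  }
  # effectors declare the product-inhibition feedbacks of the rate laws
  rxns <- list(
    rxn("UPT", c(GLC_b = -1, G6P = 1), exchange = TRUE, uptake = TRUE,
        effectors = "G6P"),
    rxn("PUPT", c(PYR_b = -1, PYR = 1), exchange = TRUE, uptake = TRUE,
        effectors = "PYR"),
    rxn("EMP1", c(G6P = -1, T3P = 2), effectors = "T3P"),
    rxn("EMP2", c(T3P = -1, PEP = 1), effectors = "PEP"),
    rxn("PYK", c(PEP = -1, PYR = 1), effectors = "PYR"),
    rxn("RESP", c(PYR = -1, CO2_b = 1), exchange = TRUE),
    rxn("SERS", c(T3P = -1, SER = 1), effectors = "SER"),
    rxn("SERAT", c(SER = -1, OAS = 1), effectors = "OAS"),
    rxn("CYSS", c(OAS = -1, H2S_b = -1, CYS = 1), uptake = FALSE,
        effectors = "CYS"),
    rxn("SLCYSS", c(OAS = -1, TS_b = -1, SSC = 1), uptake = TRUE),
    rxn("SCYSSL", c(SSC = -1, CYS = 1)),
    rxn("SEREX", c(OAS = -1, NAS_b = 1)),
    rxn("CYSEX", c(CYS = -1, CYS_b = 1), exchange = TRUE))
  # per-reaction standard-Gibbs targets (kJ/mol): every step committed,
  # well below the -10 kJ/mol equilibrium window (product inhibition in the
  # rate laws is kinetic, not thermodynamic)
  targets <- c(UPT = -45, PUPT = -40, EMP1 = -18, EMP2 = -16, PYK = -20,
               RESP = -50, SERS = -20, SERAT = -25, CYSS = -40,
               SLCYSS = -35, SCYSSL = -30, SEREX = -15, CYSEX = -12)
  mets$dgf <- fit_dgf(mets, rxns, targets)
  validate_model(structure(list(metabolites = mets, reactions = rxns,
                                objective = "CYSEX"),
                           class = "network_model"))
}

# Least-squares fit of per-species formation energies to per-reaction
# standard-Gibbs targets (weak prior anchoring the gauge freedom at 0).
fit_dgf <- function(mets, rxns, targets, lambda = 1e-6) {
  ids <- mets$id
  A <- matrix(0, length(targets), length(ids),
              dimnames = list(names(targets), ids))
  for (k in seq_along(targets)) {
    r <- rxns[[match(names(targets)[k], vapply(rxns, `[[`, "", "id"))]]
    for (m in names(r$stoich)) A[k, m] <- A[k, m] + r$stoich[[m]]
  }
  g <- solve(crossprod(A) + lambda * diag(length(ids)),
             crossprod(A, targets))
  drop(g)[ids]
}

#' Synthetic reference-state TFA ranges for the canonical model
#'
#' Builds a `tfa_result`-shaped object whose Gibbs-energy ranges mirror the
#' canonical equilibrium / non-equilibrium split of the reference production
#' state: the fourteen near-equilibrium reactions get ranges inside
#' (-10, 0) kJ/mol, all other interior reactions strongly negative ranges.
#' This is a synthetic construction (the underlying fermentation data are
#' not public), used to exercise classification, elasticity assembly and
#' Monte-Carlo control analysis on the full-size model.
#'
#' @param model the canonical `network_model`
#' @param eq_range,noneq_range Gibbs ranges (kJ/mol)
#' @param lnc_halfwidth half-width of the log-concentration ranges
#' @return a `tfa_result`-shaped list (class `tfa_result`)
#' @export
synthetic_reference_tfa <- function(model, eq_range = c(-8, -1.5),
                                    noneq_range = c(-45, -12),
                                    lnc_halfwidth = 0.35) {
  eq_set <- c("PGI", "FBA", "TPI", "GAPD", "PGM", "ENO", "ACONT", "FUM",
              "MDH", "RPI", "TALA", "PGCD", "PSERT", "ATPS")
  rids <- reaction_ids(model)
  mids <- interior_metabolite_ids(model)
  exch <- vapply(model$reactions, `[[`, FALSE, "exchange")
  dg <- matrix(NA_real_, length(rids), 2, dimnames = list(rids, c("min", "max")))
  for (rid in rids[!exch]) {
    dg[rid, ] <- if (rid %in% eq_set) eq_range else noneq_range
  }
  v0 <- canonical_reference_flux(model)
  fl <- cbind(min = pmin(v0 * 0.8, v0 * 1.2), max = pmax(v0 * 0.8, v0 * 1.2))
  rownames(fl) <- rids
  c0 <- canonical_reference_conc(model)
  lnc <- cbind(min = log(c0) - lnc_halfwidth, max = log(c0) + lnc_halfwidth)
  rownames(lnc) <- mids
  structure(list(
    status = "optimal",
    objective_value = unname(v0[model$objective]),
    v_opt = v0, lnc_opt = log(c0),
    dg_opt = stats::setNames(rowMeans(dg), rids),
    ranges = list(flux = fl, lnc = lnc, dg = dg),
    params = thermo_params(), synthetic = TRUE),
    class = "tfa_result")
}

#' Reference flux distribution for the canonical model
#'
#' Minimum-norm steady-state flux with plausible fixed exchange rates
#' (glucose uptake via the PTS, thiosulfate uptake, cysteine export),
#' computed by pseudoinverse. Serves as normalization flux for synthetic
#' datasets on the full-size model.
#'
#' @param model the canonical `network_model`
#' @param fixed named fluxes to pin (mmol g-1 h-1)
#' @return named flux vector over all reactions
#' @export
canonical_reference_flux <- function(model,
                                     fixed = c(PTS = 3, TS_UPT = 0.45,
                                               CYS_EX = 0.9)) {
  N <- stoichiometric_matrix(model)
  rids <- colnames(N)
  E <- matrix(0, length(fixed), length(rids), dimnames = list(names(fixed), rids))
  for (f in names(fixed)) E[f, f] <- 1
  A <- rbind(N, E)
  b <- c(rep(0, nrow(N)), fixed)
  sv <- svd(A)
  pos <- sv$d > 1e-10 * max(sv$d)
  v <- drop(sv$v[, pos] %*% ((t(sv$u[, pos]) %*% b) / sv$d[pos]))
  names(v) <- rids
  resid <- max(abs(N %*% v))
  if (resid > 1e-8) stopf("reference flux violates mass balance (%.3g)", resid)
  v
}

# plausible reference concentrations (mol/L) for the canonical metabolites
canonical_reference_conc <- function(model) {
  defaults <- c(ATP = 3e-3, ADP = 8e-4, NAD = 2e-3, NADH = 1e-4,
                NADP = 1.5e-4, NADPH = 4e-4, G6P = 2e-3, F6P = 6e-4,
                FBP = 3e-3, PEP = 2e-4, PYR = 1e-3, `3PG` = 1e-3)
  mids <- interior_metabolite_ids(model)
  c0 <- stats::setNames(rep(5e-4, length(mids)), mids)
  hit <- intersect(names(defaults), mids)
  c0[hit] <- defaults[hit]
  c0
}

#' Synthetic perturbation dataset for the canonical model
#'
#' Draws a ground-truth elasticity pattern over each reaction's non-boundary
#' participants, perturbs reference concentrations lognormally per state, and
#' constructs per-state fluxes that follow the lin-log relation exactly, so
#' regression can recover the pattern. Rates for the exchange steps and the
#' measured transport reactions are attached with the uptake-negative sign
#' convention. Purely synthetic: a structural stand-in for the unavailable
#' fermentation tables.
#'
#' @param model the canonical `network_model`
#' @param n_states number of perturbation states (default 12)
#' @param spread sd of the per-state log-concentration perturbations
#' @param seed RNG seed
#' @return a `steady_state_dataset` with `attr(,"fluxes")` (reactions x
#'   states) and `attr(,"E_true")`
#' @export
canonical_synthetic_dataset <- function(model, n_states = 12, spread = 0.15,
                                        seed = 1) {
  mids <- interior_metabolite_ids(model)
  rids <- reaction_ids(model)
  c0 <- canonical_reference_conc(model)
  v0 <- canonical_reference_flux(model)
  with_seed(seed, {
    E <- matrix(0, length(rids), length(mids), dimnames = list(rids, mids))
    for (rid in rids) {
      r <- get_reaction(model, rid)
      part <- default_participants(r, mids)
      for (m in part) {
        sgn <- if ((r$stoich[m] %||% 0) < 0) 1 else -1
        E[rid, m] <- sgn * stats::runif(1, 0.2, 0.9)
      }
    }
    ids <- c("REF", sprintf("P%02d", seq_len(n_states)))
    dln <- cbind(REF = rep(0, length(mids)),
                 matrix(stats::rnorm(length(mids) * n_states, 0, spread),
                        ncol = n_states))
    rownames(dln) <- mids; colnames(dln) <- ids
    fluxes <- matrix(NA_real_, length(rids), length(ids),
                     dimnames = list(rids, ids))
    for (i in seq_along(ids)) {
      fluxes[, i] <- v0 * (1 + drop(E %*% dln[, i]))
    }
    meas <- rids[vapply(model$reactions, function(r) r$exchange || r$uptake ||
                          r$id %in% c("SEREX", "CYS_EX"), FALSE)]
    states <- lapply(seq_along(ids), function(i) {
      conc <- c0 * exp(dln[, i])
      q <- vapply(meas, function(rid) {
        r <- get_reaction(model, rid)
        if (r$uptake) -fluxes[rid, i] else fluxes[rid, i]
      }, numeric(1))
      steady_state_record(ids[i], conc_intra = conc, conc_sd = 0.05 * conc,
                          rates = q, rate_sd = 0.05 * abs(q),
                          is_reference = ids[i] == "REF")
    })
    ds <- new_dataset(states)
    attr(ds, "fluxes") <- fluxes
    attr(ds, "E_true") <- E
    ds
  })
}
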