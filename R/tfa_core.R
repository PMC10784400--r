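#' Thermodynamic parameters
#'
#' Container for the constants of the thermodynamic flux analysis and the
#' elasticity routines.
#'
#' @param T temperature in K (default 305.15 K, a 32 degC process)
#' @param big_M big-M coupling constant, kJ/mol
#' @param objective_fraction fraction of the optimal objective retained
#'   during variability analysis (default 0.999)
#' @param tol_dg strict-inequality surrogate for Gibbs-direction coupling,
#'   kJ/mol
#' @param flux_bound global flux bound, mmol g-1 h-1
#' @param conf half-width multiplier for measured-value windows (1.96 = 95%)
#' @param rel_floor relative uncertainty floor applied when an sd is absent
#' @param dg_floor |Gibbs energy| floor for thermokinetic elasticities, kJ/mol
#' @param eps_cap cap on |elasticity| for thermokinetic rows
#' @return object of class `thermo_params`
#' @export
thermo_params <- function(T = 305.15, big_M = 1000, objective_fraction = 0.999,
                          tol_dg = 1e-3, flux_bound = 100, conf = 1.96,
                          rel_floor = 0.1, dg_floor = 0.1, eps_cap = 25) {
  stopifnot(T > 0, objective_fraction > 0, objective_fraction <= 1, big_M > 0)
  structure(list(T = T, RT = rt_kj(T), big_M = big_M,
                 objective_fraction = objective_fraction, tol_dg = tol_dg,
                 flux_bound = flux_bound, conf = conf, rel_floor = rel_floor,
                 dg_floor = dg_floor, eps_cap = eps_cap),
            class = "thermo_params")
}

#' Standard Gibbs energies of reaction
#'
#' `dG0'_j = sum_i n_ij dGf_i` over all participants, boundary species
#' included.
#'
#' @param model a `network_model`
#' @return named numeric vector, kJ/mol
#' @export
standard_gibbs <- function(model) {
  g <- stats::setNames(model$metabolites$dgf, model$metabolites$id)
  vapply(model$reactions, function(r) {
    miss <- names(r$stoich)[!is.finite(g[names(r$stoich)])]
    if (length(miss)) stopf("missing dgf for metabolite(s): %s in reaction %s",
                            paste(miss, collapse = ", "), r$id)
    sum(r$stoich * g[names(r$stoich)])
  }, numeric(1)) |> stats::setNames(reaction_ids(model))
}

# dG0' folded with the RT*ln(conc) contribution of boundary species at their
# fixed configured concentrations: the "effective" constant of the affine
# dG(ln c) expression over interior metabolites only.
effective_standard_gibbs <- function(model, params) {
  dg0 <- standard_gibbs(model)
  cf <- stats::setNames(model$metabolites$conc_fixed, model$metabolites$id)
  bnd <- model$metabolites$id[model$metabolites$boundary]
  adj <- vapply(model$reactions, function(r) {
    b <- intersect(names(r$stoich), bnd)
    if (!length(b)) return(0)
    sum(r$stoich[b] * log(cf[b]))
  }, numeric(1))
  dg0 + params$RT * adj
}

#' Gibbs energies of reaction at given log-concentrations
#'
#' `dG_j = dG0'_j + RT sum_i n_ij ln c_i`, with boundary species held at
#' their fixed configured concentrations.
#'
#' @param model a `network_model`
#' @param ln_c named numeric vector of interior log-concentrations (ln mol/L);
#'   must cover all non-boundary participants
#' @param params a [thermo_params()] object
#' @return named numeric vector of reaction Gibbs energies, kJ/mol
#' @export
reaction_gibbs <- function(model, ln_c, params = thermo_params()) {
  dg0e <- effective_standard_gibbs(model, params)
  interior <- interior_metabolite_ids(model)
  vapply(seq_along(model$reactions), function(j) {
    r <- model$reactions[[j]]
    ii <- intersect(names(r$stoich), interior)
    miss <- setdiff(ii, names(ln_c))
    if (length(miss)) stopf("ln_c missing participant(s) %s of reaction %s",
                            paste(miss, collapse = ", "), r$id)
    dg0e[j] + params$RT * sum(r$stoich[ii] * ln_c[ii])
  }, numeric(1)) |> stats::setNames(reaction_ids(model))
}

# --- internal: bounds from a steady state ------------------------------------

lnc_bounds <- function(model, state, params) {
  mets <- model$metabolites[!model$metabolites$boundary, ]
  lo <- log(mets$conc_min); hi <- log(mets$conc_max)
  names(lo) <- names(hi) <- mets$id
  if (!is.null(state) && length(state$conc_intra)) {
    for (m in names(state$conc_intra)) {
      if (!(m %in% mets$id)) next
      c0 <- state$conc_intra[[m]]
      if (!is.finite(c0) || c0 <= 0) next
      s <- state$conc_sd[[m]] %||% NA_real_
      if (!is.finite(s)) s <- params$rel_floor * c0
      w <- params$conf * s
      lo[m] <- log(max(c0 - w, c0 * 0.01, mets$conc_min[match(m, mets$id)]))
      hi[m] <- log(c0 + w)
    }
  }
  list(lo = lo, hi = hi)
}

flux_bounds <- function(model, state, params) {
  rids <- reaction_ids(model)
  rev <- vapply(model$reactions, `[[`, FALSE, "reversible")
  lo <- ifelse(rev, -params$flux_bound, 0)
  hi <- rep(params$flux_bound, length(rids))
  names(lo) <- names(hi) <- rids
  if (!is.null(state) && length(state$rates)) {
    for (rid in names(state$rates)) {
      if (!(rid %in% rids)) next
      r <- get_reaction(model, rid)
      q <- state$rates[[rid]]
      v_c <- if (r$uptake) -q else q
      s <- state$rate_sd[[rid]] %||% NA_real_
      w <- if (is.finite(s)) {
        max(params$conf * s, 1e-6)
      } else {
        max(params$rel_floor * abs(v_c), 1e-3)  # sd absent: 10% relative floor
      }
      lo[rid] <- max(lo[rid], v_c - w)
      hi[rid] <- min(hi[rid], v_c + w)
      if (lo[rid] > hi[rid]) { lo[rid] <- v_c - w; hi[rid] <- v_c + w }
    }
  }
  list(lo = lo, hi = hi)
}

# Build the TFA MILP. Variable layout: [v (n_r)] [lnc (n_m)] [zf, zr per
# thermo reaction]. Returns the problem plus index bookkeeping.
build_tfa_problem <- function(model, state, params,
                              thermo = TRUE, use_conc = TRUE, use_rates = TRUE) {
  rids <- reaction_ids(model)
  mids <- interior_metabolite_ids(model)
  n_r <- length(rids); n_m <- length(mids)
  exch <- vapply(model$reactions, `[[`, FALSE, "exchange")
  thermo_set <- if (thermo) which(!exch) else integer(0)
  n_t <- length(thermo_set)

  fb <- flux_bounds(model, if (use_rates) state else NULL, params)
  cb <- lnc_bounds(model, if (use_conc) state else NULL, params)

  iv <- seq_len(n_r)
  ic <- n_r + seq_len(n_m)
  izf <- n_r + n_m + seq_len(n_t)
  izr <- n_r + n_m + n_t + seq_len(n_t)
  n <- n_r + n_m + 2 * n_t

  lb <- c(fb$lo, cb$lo, rep(0, 2 * n_t))
  ub <- c(fb$hi, cb$hi, rep(1, 2 * n_t))
  integrality <- c(rep(0L, n_r + n_m), rep(1L, 2 * n_t))
  # irreversible reactions can never run backwards
  rev <- vapply(model$reactions, `[[`, FALSE, "reversible")
  if (n_t) ub[izr][!rev[thermo_set]] <- 0

  prob <- milp_problem(n, lb, ub, integrality)

  N <- stoichiometric_matrix(model)
  for (i in seq_len(n_m)) {
    prob <- milp_add_row(prob, iv, N[i, ], 0, 0)
  }

  dg0e <- effective_standard_gibbs(model, params)
  dg_rows <- vector("list", n_r)  # per reaction: list(idx, coef, const)
  for (j in seq_len(n_r)) {
    st <- model$reactions[[j]]$stoich
    ii <- intersect(names(st), mids)
    dg_rows[[j]] <- list(idx = ic[match(ii, mids)],
                         coef = params$RT * unname(st[ii]),
                         const = dg0e[j])
  }

  if (n_t) {
    M <- params$big_M
    for (k in seq_len(n_t)) {
      j <- thermo_set[k]
      dr <- dg_rows[[j]]
      # dG_j + M*zf <= M - tol  (forward active => dG < 0)
      prob <- milp_add_row(prob, c(dr$idx, izf[k]), c(dr$coef, M),
                           -Inf, M - params$tol_dg - dr$const)
      # dG_j - M*zr >= tol - M  (reverse active => dG > 0)
      prob <- milp_add_row(prob, c(dr$idx, izr[k]), c(dr$coef, -M),
                           params$tol_dg - M - dr$const, Inf)
      # v_j <= ub_j * zf ; v_j >= lb_j * zr
      prob <- milp_add_row(prob, c(iv[j], izf[k]),
                           c(1, -max(fb$hi[j], 0)), -Inf, 0)
      prob <- milp_add_row(prob, c(iv[j], izr[k]),
                           c(1, -min(fb$lo[j], 0)), 0, Inf)
      prob <- milp_add_row(prob, c(izf[k], izr[k]), c(1, 1), -Inf, 1)
    }
  }

  list(prob = prob, iv = iv, ic = ic, rids = rids, mids = mids,
       dg_rows = dg_rows, n = n)
}

#' Solve the thermodynamic flux analysis problem
#'
#' Formulates and solves the TFA mixed-integer program: steady-state mass
#' balance over non-boundary metabolites, an affine Gibbs energy
#' `dG_j = dG0'_j + RT sum_i n_ij ln c_i` per interior reaction, big-M
#' direction coupling (`v_j > 0` forces `dG_j < 0` and vice versa, which also
#' excludes internal thermodynamic loops), measured extracellular rates and
#' intracellular concentrations as window constraints, and the configured
#' boundary demand flux as objective. Optionally performs variability
#' analysis at `objective_fraction` of the optimum for every flux,
#' log-concentration, and reaction Gibbs energy.
#'
#' @param model a `network_model`
#' @param state optional steady state (list with `conc_intra`, `conc_sd`,
#'   `rates`, `rate_sd`) supplying measurement windows
#' @param params a [thermo_params()] object
#' @param objective reaction id to maximise (default: the model objective)
#' @param variability logical: compute min/max ranges
#' @param var_targets which ranges to compute, subset of
#'   `c("flux", "lnc", "dg")`
#' @return object of class `tfa_result` with `v_opt`, `lnc_opt`, `dg_opt`,
#'   `objective_value`, `status` and `ranges` (`flux`, `lnc`, `dg`; each a
#'   two-column min/max matrix)
#' @export
solve_tfa <- function(model, state = NULL, params = thermo_params(),
                      objective = NULL, variability = TRUE,
                      var_targets = c("flux", "lnc", "dg")) {
  res <- solve_tfa_states(model, if (is.null(state)) list(NULL) else list(state),
                          params, objective = objective,
                          variability = variability, var_targets = var_targets)
  res[[1]]
}

#' Solve TFA for several steady states in one solver invocation
#'
#' @inheritParams solve_tfa
#' @param states list of steady states (elements may be `NULL` for an
#'   unconstrained solve)
#' @return list of `tfa_result`, one per state
#' @export
solve_tfa_states <- function(model, states, params = thermo_params(),
                             objective = NULL, variability = TRUE,
                             var_targets = c("flux", "lnc", "dg")) {
  objective <- objective %||% model$objective
  if (!nzchar(objective)) stopf("no objective reaction configured")
  built <- lapply(states, function(s) build_tfa_problem(model, s, params))
  jobj <- match(objective, built[[1]]$rids)
  if (is.na(jobj)) stopf("objective reaction '%s' not in model", objective)

  probs <- lapply(built, function(b)
    milp_add_objective(b$prob, b$iv[jobj], 1, "max"))
  phase1 <- milp_solve_batch(probs)

  out <- vector("list", length(states))
  var_probs <- list(); var_map <- list()
  for (s in seq_along(states)) {
    b <- built[[s]]; r1 <- phase1[[s]][[1]]
    if (r1$status != "optimal") {
      out[[s]] <- structure(
        list(status = r1$status, objective_value = NA_real_,
             diagnosis = diagnose_infeasible(model, states[[s]], params, objective),
             v_opt = NULL, lnc_opt = NULL, dg_opt = NULL, ranges = NULL,
             params = params),
        class = "tfa_result")
      next
    }
    v <- stats::setNames(r1$x[b$iv], b$rids)
    lnc <- stats::setNames(r1$x[b$ic], b$mids)
    dg <- vapply(seq_along(b$rids), function(j) {
      dr <- b$dg_rows[[j]]
      dr$const + sum(dr$coef * r1$x[dr$idx])
    }, numeric(1)) |> stats::setNames(b$rids)
    out[[s]] <- structure(
      list(status = "optimal", objective_value = r1$objective,
           v_opt = v, lnc_opt = lnc, dg_opt = dg, ranges = NULL,
           params = params),
      class = "tfa_result")
    if (variability) {
      p <- b$prob
      p <- milp_add_row(p, b$iv[jobj], 1,
                        params$objective_fraction * r1$objective, Inf)
      map <- list()
      if ("flux" %in% var_targets) {
        for (j in seq_along(b$rids)) for (sense in c("min", "max")) {
          p <- milp_add_objective(p, b$iv[j], 1, sense)
          map[[length(map) + 1L]] <- list(kind = "flux", id = b$rids[j],
                                          sense = sense, const = 0)
        }
      }
      if ("lnc" %in% var_targets) {
        for (i in seq_along(b$mids)) for (sense in c("min", "max")) {
          p <- milp_add_objective(p, b$ic[i], 1, sense)
          map[[length(map) + 1L]] <- list(kind = "lnc", id = b$mids[i],
                                          sense = sense, const = 0)
        }
      }
      if ("dg" %in% var_targets) {
        exch <- vapply(model$reactions, `[[`, FALSE, "exchange")
        for (j in which(!exch)) for (sense in c("min", "max")) {
          dr <- b$dg_rows[[j]]
          p <- milp_add_objective(p, dr$idx, dr$coef, sense)
          map[[length(map) + 1L]] <- list(kind = "dg", id = b$rids[j],
                                          sense = sense, const = dr$const)
        }
      }
      var_probs[[length(var_probs) + 1L]] <- p
      var_map[[length(var_probs)]] <- list(state = s, map = map)
    }
  }

  if (length(var_probs)) {
    var_res <- milp_solve_batch(var_probs)
    for (k in seq_along(var_probs)) {
      s <- var_map[[k]]$state; map <- var_map[[k]]$map
      rng <- list(
        flux = matrix(NA_real_, length(built[[s]]$rids), 2,
                      dimnames = list(built[[s]]$rids, c("min", "max"))),
        lnc = matrix(NA_real_, length(built[[s]]$mids), 2,
                     dimnames = list(built[[s]]$mids, c("min", "max"))),
        dg = matrix(NA_real_, length(built[[s]]$rids), 2,
                    dimnames = list(built[[s]]$rids, c("min", "max"))))
      for (q in seq_along(map)) {
        m <- map[[q]]; r <- var_res[[k]][[q]]
        val <- if (r$status == "optimal") r$objective + m$const else NA_real_
        rng[[m$kind]][m$id, m$sense] <- val
      }
      # numerical guard: optimal point must sit inside its own ranges
      out[[s]]$ranges <- rng
    }
  }
  out
}

# Staged relaxation to name the binding constraint family on infeasibility.
diagnose_infeasible <- function(model, state, params, objective) {
  stages <- list(
    thermodynamic = list(thermo = FALSE, use_conc = TRUE, use_rates = TRUE),
    concentration = list(thermo = FALSE, use_conc = FALSE, use_rates = TRUE),
    rate = list(thermo = FALSE, use_conc = FALSE, use_rates = FALSE))
  jobj <- match(objective, reaction_ids(model))
  probs <- lapply(stages, function(st) {
    b <- build_tfa_problem(model, state, params, thermo = st$thermo,
                           use_conc = st$use_conc, use_rates = st$use_rates)
    milp_add_objective(b$prob, b$iv[jobj], 1, "max")
  })
  res <- milp_solve_batch(probs)
  for (k in seq_along(stages)) {
    if (res[[k]][[1]]$status == "optimal") {
      return(list(family = names(stages)[k],
                  message = sprintf(
                    "infeasible; relaxing the %s constraint family restores feasibility",
                    names(stages)[k])))
    }
  }
  list(family = "stoichiometric",
       message = "infeasible even without thermodynamic, concentration and rate constraints")
}

#' Plain flux variability analysis (LP-only reference)
#'
#' Mass balance and flux bounds only - no Gibbs constraints, no binaries.
#' Serves as the LP oracle that [solve_tfa()] must reproduce on models
#' without thermodynamic restrictions.
#'
#' @param model a `network_model`
#' @param state optional steady state for rate windows
#' @param params a [thermo_params()] object
#' @param objective reaction id to maximise; `NULL` skips the optimality
#'   constraint (full FVA over the feasible flux cone)
#' @param objective_fraction fraction of the optimum to retain
#' @return matrix reactions x (min, max)
#' @export
flux_variability <- function(model, state = NULL, params = thermo_params(),
                             objective = NULL, objective_fraction = NULL) {
  rids <- reaction_ids(model)
  fb <- flux_bounds(model, state, params)
  n_r <- length(rids)
  prob <- milp_problem(n_r, fb$lo, fb$hi)
  N <- stoichiometric_matrix(model)
  for (i in seq_len(nrow(N))) prob <- milp_add_row(prob, seq_len(n_r), N[i, ], 0, 0)
  if (!is.null(objective)) {
    jobj <- match(objective, rids)
    p0 <- milp_add_objective(prob, jobj, 1, "max")
    r0 <- milp_solve(p0)[[1]]
    if (r0$status != "optimal") stopf("FVA objective solve failed: %s", r0$status)
    frac <- objective_fraction %||% params$objective_fraction
    prob <- milp_add_row(prob, jobj, 1, frac * r0$objective, Inf)
  }
  for (j in seq_len(n_r)) for (sense in c("min", "max")) {
    prob <- milp_add_objective(prob, j, 1, sense)
  }
  res <- milp_solve(prob)
  out <- matrix(NA_real_, n_r, 2, dimnames = list(rids, c("min", "max")))
  k <- 0
  for (j in seq_len(n_r)) for (sense in c("min", "max")) {
    k <- k + 1
    if (res[[k]]$status == "optimal") out[j, sense] <- res[[k]]$objective
  }
  out
}

#' @export
print.tfa_result <- function(x, ...) {
  cat(sprintf("tfa_result: status=%s objective=%.6g\n", x$status,
              x$objective_value))
  if (!is.null(x$diagnosis)) cat("diagnosis:", x$diagnosis$message, "\n")
  invisible(x)
}
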