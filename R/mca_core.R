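# Control coefficients by the matrix method, theorem checks, and Monte-Carlo
# uncertainty propagation.

#' Flux and concentration control coefficients (matrix method)
#'
#' Given the stoichiometric decomposition `N = L N0`, a reference flux `J`
#' (a steady-state flux, `N J = 0`), reference concentrations `s` and the
#' normalized elasticity matrix `E`, computes unscaled elasticities
#' `dv/ds = diag(J) E diag(s)^-1`, the unscaled concentration-control matrix
#' `Gamma = -L (N0 (dv/ds) L)^-1 N0`, the unscaled flux-control matrix
#' `Theta = I + (dv/ds) Gamma`, and returns the normalized
#' `CS = diag(s)^-1 Gamma diag(J)` and `CJ = diag(J)^-1 Theta diag(J)`.
#'
#' Rows of `CJ` sum to 1 and rows of `CS` to 0 (summation theorems); the
#' residuals are attached. Reactions with zero reference flux are excluded
#' from normalization: their rows/columns are computed with a unit
#' normalization flux and flagged.
#'
#' @param decomp a [decompose()] result
#' @param ref_flux named numeric reference fluxes over the decomposition's
#'   reactions, mmol g-1 h-1
#' @param ref_conc named numeric reference concentrations over the
#'   decomposition's metabolites, mol/L
#' @param E an `elasticity_matrix` or plain reactions x metabolites matrix
#' @param cond_limit condition-number threshold for the singularity error
#' @return object of class `control_coefficients`: list with `CJ`
#'   (flux through reaction x perturbed enzyme), `CS` (metabolite x enzyme),
#'   `J`, `s`, `zero_flux`, `condition`, `residuals`
#' @export
control_coefficients <- function(decomp, ref_flux, ref_conc, E,
                                 cond_limit = 1e10) {
  eps <- if (inherits(E, "elasticity_matrix")) E$eps else E
  rids <- colnames(decomp$N)
  mids <- rownames(decomp$N)
  J <- ref_flux[rids]
  s <- ref_conc[mids]
  if (any(!is.finite(J))) stopf("reference flux missing for: %s",
                                paste(rids[!is.finite(J)], collapse = ", "))
  if (any(!is.finite(s)) || any(s <= 0)) stopf("reference concentrations must be positive and complete")
  eps <- eps[rids, mids, drop = FALSE]

  zero_flux <- abs(J) < 1e-12
  Jn <- ifelse(zero_flux, 1, J)

  dvds <- diag(Jn) %*% eps %*% diag(1 / s)
  M <- decomp$N0 %*% dvds %*% decomp$L
  sv <- svd(M)
  cond <- if (min(sv$d) <= 0) Inf else max(sv$d) / min(sv$d)
  if (!is.finite(cond) || cond > cond_limit) {
    stopf("Jacobian N0 (dv/ds) L structurally singular at reference state (condition number %.3g)",
          cond)
  }
  Gamma <- -decomp$L %*% solve(M, decomp$N0)
  Theta <- diag(length(rids)) + dvds %*% Gamma
  CS <- diag(1 / s) %*% Gamma %*% diag(Jn)
  CJ <- diag(1 / Jn) %*% Theta %*% diag(Jn)
  dimnames(CJ) <- list(rids, rids)
  dimnames(CS) <- list(mids, rids)
  ok <- !zero_flux
  residuals <- list(
    summation_flux = if (any(ok)) max(abs(rowSums(CJ[ok, , drop = FALSE]) - 1)) else NA_real_,
    summation_conc = max(abs(rowSums(CS))))
  structure(list(CJ = CJ, CS = CS, J = J, s = s, zero_flux = zero_flux,
                 condition = cond, residuals = residuals),
            class = "control_coefficients")
}

#' Residuals of the MCA summation and connectivity theorems
#'
#' Reports `max |rowSums(CJ) - 1|`, `max |rowSums(CS)|`, and - on
#' moiety-free networks - the connectivity residuals
#' `max |sum_k CJ[j,k] eps[k,i]|` and `max |sum_k CS[m,k] eps[k,i] +
#' delta[m,i]|`. With conserved moieties the plain connectivity identities do
#' not apply and `NA` is reported for them.
#'
#' @param cc a [control_coefficients()] result
#' @param E an `elasticity_matrix` or plain matrix
#' @param decomp the [decompose()] result used to build `cc`
#' @return list of residuals (report only; no errors)
#' @export
theorem_check <- function(cc, E, decomp = NULL) {
  eps <- if (inherits(E, "elasticity_matrix")) E$eps else E
  eps <- eps[colnames(cc$CJ), rownames(cc$CS), drop = FALSE]
  moiety_free <- is.null(decomp) || nrow(decomp$conserved_moieties) == 0
  conn_flux <- conn_conc <- NA_real_
  if (moiety_free) {
    conn_flux <- max(abs(cc$CJ %*% eps))
    R <- cc$CS %*% eps
    conn_conc <- max(abs(R + diag(nrow(R))))
  }
  list(summation_flux = cc$residuals$summation_flux,
       summation_conc = cc$residuals$summation_conc,
       connectivity_flux = conn_flux,
       connectivity_conc = conn_conc)
}

# Approximate-uniform sampling of steady-state flux vectors inside the TFA
# box: hit-and-run in the null space of N starting from the optimal point.
sample_flux_space <- function(N, v_opt, v_min, v_max, n, steps = 10) {
  sv <- svd(N, nu = 0, nv = ncol(N))
  tol <- max(dim(N)) * max(sv$d, 0) * 1e-12
  r <- sum(sv$d > tol)
  if (r == ncol(N)) {
    return(matrix(v_opt, n, length(v_opt), byrow = TRUE,
                  dimnames = list(NULL, names(v_opt))))
  }
  K <- sv$v[, (r + 1):ncol(N), drop = FALSE]
  dof <- ncol(K)
  lo <- pmin(v_min, v_opt); hi <- pmax(v_max, v_opt)
  v <- v_opt
  out <- matrix(NA_real_, n, length(v_opt),
                dimnames = list(NULL, names(v_opt)))
  for (it in seq_len(n)) {
    for (st in seq_len(steps)) {
      d <- drop(K %*% stats::rnorm(dof))
      nd <- sqrt(sum(d^2))
      if (nd < 1e-12) next
      d <- d / nd
      # feasible segment v + t d within [lo, hi]
      with_d <- abs(d) > 1e-12
      t_hi <- suppressWarnings(min(((hi - v) / d)[with_d & d > 0],
                                   ((lo - v) / d)[with_d & d < 0], Inf))
      t_lo <- suppressWarnings(max(((lo - v) / d)[with_d & d > 0],
                                   ((hi - v) / d)[with_d & d < 0], -Inf))
      if (!is.finite(t_hi) || !is.finite(t_lo) || t_hi <= t_lo) next
      v <- v + stats::runif(1, t_lo, t_hi) * d
    }
    out[it, ] <- v
  }
  out
}

#' Monte-Carlo uncertainty propagation for control coefficients
#'
#' Each cycle draws reference log-concentrations uniformly within their TFA
#' ranges and a reference flux vector within the TFA flux box restricted to
#' the steady-state manifold (`N v = 0`, hit-and-run), recomputes reaction
#' Gibbs energies, re-routes elasticities (thermokinetic rows re-evaluated;
#' lin-log rows refit with per-state concentrations redrawn within their own
#' TFA ranges when `refit_linlog = TRUE`), recomputes control coefficients
#' and accumulates per-coefficient summaries. Singular draws are counted and
#' skipped, never imputed.
#'
#' @param model a `network_model`
#' @param tfa reference-state `tfa_result` (with ranges)
#' @param dataset a `steady_state_dataset`
#' @param status an [classify_equilibrium()] result
#' @param params a [thermo_params()] object
#' @param n Monte-Carlo cycles (default 10000)
#' @param seed RNG seed
#' @param fluxes per-state flux matrix (reactions x states)
#' @param state_tfa optional list of per-state `tfa_result` supplying
#'   per-state concentration ranges for the refit
#' @param refit_linlog logical: refit lin-log rows each cycle (default) or
#'   keep them at the point estimate
#' @param max_failed_frac error ceiling on the fraction of singular draws
#' @return object of class `mc_summary`: per-coefficient `median`, `q1`,
#'   `q3`, `sign_consistency` arrays for `CJ` and `CS`, plus `n`,
#'   `n_failed`, `seed`
#' @export
monte_carlo_mca <- function(model, tfa, dataset, status,
                            params = thermo_params(), n = 10000, seed = 1,
                            fluxes = NULL, state_tfa = NULL,
                            refit_linlog = TRUE, max_failed_frac = 0.2) {
  fluxes <- fluxes %||% attr(dataset, "fluxes")
  decomp <- decompose(model)
  rids <- colnames(decomp$N)
  mids <- rownames(decomp$N)
  lnc_rng <- tfa$ranges$lnc[mids, , drop = FALSE]
  flux_rng <- tfa$ranges$flux[rids, , drop = FALSE]
  ref_id <- reference_state(dataset)$id

  E0 <- elasticity_matrix(model, status, tfa, dataset, fluxes = fluxes,
                          params = params)
  eq_rows <- names(E0$regime)[E0$regime == "thermokinetic"]
  ll_rows <- names(E0$regime)[E0$regime == "linlog"]

  CJ_draws <- array(NA_real_, c(n, length(rids), length(rids)))
  CS_draws <- array(NA_real_, c(n, length(mids), length(rids)))
  n_failed <- 0L

  with_seed(seed, {
    flux_draws <- sample_flux_space(decomp$N, tfa$v_opt[rids],
                                    flux_rng[, "min"], flux_rng[, "max"], n)
    for (it in seq_len(n)) {
      lnc <- stats::runif(length(mids), lnc_rng[, "min"], lnc_rng[, "max"])
      names(lnc) <- mids
      s <- exp(lnc)
      J <- flux_draws[it, ]
      names(J) <- rids
      dg <- reaction_gibbs(model, lnc, params)
      eps <- E0$eps
      ok <- TRUE
      for (rid in eq_rows) {
        r <- get_reaction(model, rid)
        dgj <- dg[[rid]]
        if (dgj > 0) dgj <- -params$dg_floor  # drawn point crossed equilibrium
        e <- thermokinetic_elasticity(r, dgj, params, mids)
        eps[rid, ] <- 0
        eps[rid, names(e)] <- e
      }
      if (refit_linlog && !is.null(state_tfa)) {
        ds2 <- redraw_dataset(dataset, state_tfa)
        for (rid in ll_rows) {
          v0 <- fluxes[rid, ref_id]
          if (!is.finite(v0) || abs(v0) < 1e-9) next
          part <- default_participants(get_reaction(model, rid), mids)
          fit <- tryCatch(linlog_fit(ds2, fluxes[rid, ] / v0, part),
                          error = function(e) NULL)
          if (is.null(fit)) { ok <- FALSE; break }
          eps[rid, ] <- 0
          eps[rid, names(fit$eps)] <- fit$eps
        }
      }
      if (ok) {
        cc <- tryCatch(control_coefficients(decomp, J, s, eps),
                       error = function(e) NULL)
      } else cc <- NULL
      if (is.null(cc)) { n_failed <- n_failed + 1L; next }
      CJ_draws[it, , ] <- cc$CJ
      CS_draws[it, , ] <- cc$CS
    }
  })

  if (n_failed / n > max_failed_frac) {
    stopf("%d/%d Monte-Carlo draws singular or unfit; inspect the TFA ranges",
          n_failed, n)
  }
  summ <- function(draws, rn, cn) {
    qs <- apply(draws, c(2, 3), stats::quantile, probs = c(0.25, 0.5, 0.75),
                na.rm = TRUE)
    sgn <- apply(draws, c(2, 3), function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(NA_real_)
      max(mean(x > 0), mean(x < 0))
    })
    dimnames(sgn) <- list(rn, cn)
    med <- qs[2, , ]; q1 <- qs[1, , ]; q3 <- qs[3, , ]
    dimnames(med) <- dimnames(q1) <- dimnames(q3) <- list(rn, cn)
    list(median = med, q1 = q1, q3 = q3, sign_consistency = sgn)
  }
  structure(list(CJ = summ(CJ_draws, rids, rids),
                 CS = summ(CS_draws, mids, rids),
                 n = n, n_failed = n_failed, seed = seed,
                 point = control_coefficients(
                   decomp, tfa$v_opt[rids],
                   exp(tfa$lnc_opt[mids]), E0)),
            class = "mc_summary")
}

# Redraw every state's concentrations uniformly within its own TFA ranges.
redraw_dataset <- function(dataset, state_tfa) {
  states <- lapply(dataset$states, function(s) {
    tr <- state_tfa[[s$id]]
    if (is.null(tr) || is.null(tr$ranges)) return(s)
    rng <- tr$ranges$lnc
    m <- intersect(names(s$conc_intra), rownames(rng))
    if (length(m)) {
      draw <- stats::runif(length(m), rng[m, "min"], rng[m, "max"])
      s$conc_intra[m] <- exp(draw)
    }
    s
  })
  out <- dataset
  out$states <- states
  out
}

#' Rank enzymes by their control over a target flux
#'
#' Orders enzymes by median flux-control coefficient on the target flux,
#' descending; ties broken by sign-consistency, then id. A positive value
#' means increasing that enzyme's activity increases the target flux.
#'
#' @param cc_summary an [monte_carlo_mca()] result (or a
#'   [control_coefficients()] point estimate)
#' @param target_flux reaction id of the flux of interest
#' @return data.frame with `enzyme`, `fcc_median`, `q1`, `q3`,
#'   `sign_consistency`, ordered
#' @export
rank_targets <- function(cc_summary, target_flux) {
  if (inherits(cc_summary, "mc_summary")) {
    med <- cc_summary$CJ$median; q1 <- cc_summary$CJ$q1
    q3 <- cc_summary$CJ$q3; sgn <- cc_summary$CJ$sign_consistency
  } else if (inherits(cc_summary, "control_coefficients")) {
    med <- cc_summary$CJ; q1 <- q3 <- med
    sgn <- matrix(1, nrow(med), ncol(med), dimnames = dimnames(med))
  } else stopf("cc_summary must be an mc_summary or control_coefficients")
  if (!(target_flux %in% rownames(med))) {
    stopf("unknown reaction id: %s", target_flux)
  }
  out <- data.frame(enzyme = colnames(med),
                    fcc_median = med[target_flux, ],
                    q1 = q1[target_flux, ], q3 = q3[target_flux, ],
                    sign_consistency = sgn[target_flux, ],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fcc_median, -out$sign_consistency, out$enzyme), ]
  rownames(out) <- NULL
  out
}

#' @export
print.control_coefficients <- function(x, ...) {
  cat(sprintf("control_coefficients: %d fluxes x %d enzymes (summation residuals: CJ %.2e, CS %.2e)\n",
              nrow(x$CJ), ncol(x$CJ), x$residuals$summation_flux,
              x$residuals$summation_conc))
  invisible(x)
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("mc_summary: %d cycles (%d singular draws skipped), seed %s\n",
              x$n, x$n_failed, format(x$seed)))
  invisible(x)
}
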