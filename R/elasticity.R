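# Dual-regime elasticity estimation: thermokinetic affinity form for
# reactions near equilibrium, lin-log regression across perturbation steady
# states for reactions far from it.

#' Thermokinetic (affinity) elasticities for a near-equilibrium reaction
#'
#' Near equilibrium the normalized elasticity of rate with respect to each
#' participant reduces to `eps_ij = n_ij * R * T / dG_j`: a substrate
#' (n < 0) of an exergonic step (dG < 0) gets a positive elasticity that
#' diverges as the reaction approaches equilibrium. `|dG|` is floored at
#' `params$dg_floor` before division and `|eps|` capped at `params$eps_cap`.
#'
#' @param reaction a reaction record from a `network_model`
#' @param dG Gibbs energy of the reaction in the direction of flux, kJ/mol
#'   (must be negative)
#' @param params a [thermo_params()] object
#' @param interior_ids ids of non-boundary metabolites (participants outside
#'   this set are skipped)
#' @return named numeric vector of elasticities over interior participants
#' @export
thermokinetic_elasticity <- function(reaction, dG, params = thermo_params(),
                                     interior_ids = names(reaction$stoich)) {
  if (!is.finite(dG)) stopf("non-finite dG for reaction %s", reaction$id)
  if (dG > params$dg_floor) {
    stopf("reaction %s: dG = %.3g kJ/mol > 0 with forward flux (inconsistent state)",
          reaction$id, dG)
  }
  dG_eff <- -max(abs(dG), params$dg_floor)
  ii <- intersect(names(reaction$stoich), interior_ids)
  eps <- reaction$stoich[ii] * params$RT / dG_eff
  eps <- sign(eps) * pmin(abs(eps), params$eps_cap)
  eps
}

#' Lin-log elasticity regression across steady states
#'
#' Fits `v_k / v_0 - 1 = sum_i eps_i * ln(c_ik / c_i0)` by least squares
#' over the non-reference states k (the reference row is identically 0 = 0
#' and enters only as the normalization point). When the design matrix
#' condition number exceeds `cond_limit` a ridge penalty
#' `lambda = 1e-6 * s_max` (largest singular value) is applied.
#'
#' @param dataset a `steady_state_dataset`
#' @param reaction_flux named numeric: normalized flux `v_k / v_0` per state
#'   (names = state ids; the reference state may be present and is ignored)
#' @param participants metabolite ids entering the fit
#' @param ridge logical: allow the ridge fallback
#' @param cond_limit condition-number threshold for the fallback
#' @return list with `eps` (named), `r2`, `cond`, `ridge_used`, `n_states`
#' @export
linlog_fit <- function(dataset, reaction_flux, participants, ridge = TRUE,
                       cond_limit = 1e6) {
  lookup <- function(s, ids) {
    v <- s$conc_intra[ids]
    miss <- !is.finite(v)
    if (any(miss) && length(s$conc_extra)) {
      v[miss] <- s$conc_extra[ids[miss]]
    }
    stats::setNames(v, ids)
  }
  ref <- reference_state(dataset)
  c0 <- lookup(ref, participants)
  if (any(!is.finite(c0)) || any(c0 <= 0)) {
    stopf("reference state lacks a positive concentration for participant(s): %s",
          paste(participants[!is.finite(c0) | c0 <= 0], collapse = ", "))
  }
  pert <- nonreference_states(dataset)
  rows <- lapply(pert, function(s) {
    if (!(s$id %in% names(reaction_flux))) return(NULL)
    ck <- lookup(s, participants)
    if (any(!is.finite(ck)) || any(ck <= 0)) return(NULL)
    list(x = log(ck / c0), y = reaction_flux[[s$id]] - 1)
  })
  rows <- Filter(Negate(is.null), rows)
  p <- length(participants)
  if (length(rows) < p) {
    if (!ridge) stopf("underdetermined lin-log fit: %d usable states for %d participants",
                      length(rows), p)
  }
  if (length(rows) == 0) stopf("no usable perturbation states for lin-log fit")
  X <- do.call(rbind, lapply(rows, `[[`, "x"))
  y <- vapply(rows, `[[`, numeric(1), "y")
  if (max(abs(X)) < 1e-12) {
    stopf("all states identical to reference: lin-log fit underdetermined")
  }
  sv <- svd(X)
  smax <- sv$d[1]
  smin <- min(sv$d[sv$d > 0], Inf)
  cond <- if (length(sv$d) < p || min(sv$d) <= smax * 1e-14) Inf else smax / min(sv$d)
  ridge_used <- FALSE
  if (cond > cond_limit) {
    if (!ridge) stopf("lin-log design matrix ill-conditioned (cond = %.3g)", cond)
    lambda <- 1e-6 * smax
    Xa <- rbind(X, diag(lambda, p))
    ya <- c(y, rep(0, p))
    beta <- qr.coef(qr(Xa), ya)
    ridge_used <- TRUE
  } else {
    beta <- qr.coef(qr(X), y)
  }
  beta[is.na(beta)] <- 0
  names(beta) <- participants
  fitted <- drop(X %*% beta)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(eps = beta, r2 = r2, cond = cond, ridge_used = ridge_used,
       n_states = length(rows))
}

# Substrates always participate; products only for reversible reactions
# (an irreversible step is insensitive to its products unless they are
# declared regulators via the effectors field).
default_participants <- function(reaction, interior_ids) {
  st <- reaction$stoich
  ids <- if (reaction$reversible) names(st) else names(st)[st < 0]
  unique(c(intersect(ids, interior_ids),
           intersect(reaction$effectors, interior_ids)))
}

#' Assemble the full elasticity matrix
#'
#' Routes each reaction by its equilibrium status: near-equilibrium rows get
#' the thermokinetic affinity form evaluated at the TFA Gibbs energy of the
#' reference state; far-from-equilibrium rows are fitted by lin-log
#' regression across the perturbation steady states. Participants default to
#' each reaction's non-boundary substrates, products and declared cofactor
#' effectors.
#'
#' @param model a `network_model`
#' @param status an [classify_equilibrium()] result (reactions absent from it,
#'   e.g. exchange steps, default to the lin-log regime)
#' @param tfa the reference-state `tfa_result`
#' @param dataset a `steady_state_dataset`
#' @param fluxes matrix of per-state fluxes (reactions x states, mmol g-1
#'   h-1), typically the per-state TFA optima; defaults to
#'   `attr(dataset, "fluxes")`
#' @param params a [thermo_params()] object
#' @return object of class `elasticity_matrix`: list with `eps` (reactions x
#'   non-boundary metabolites), `regime` (named character), `diagnostics`
#' @export
elasticity_matrix <- function(model, status, tfa, dataset, fluxes = NULL,
                              params = thermo_params()) {
  fluxes <- fluxes %||% attr(dataset, "fluxes")
  if (is.null(fluxes)) stopf("per-state fluxes required (fluxes argument or attr(dataset, 'fluxes'))")
  rids <- reaction_ids(model)
  mids <- interior_metabolite_ids(model)
  ref_id <- reference_state(dataset)$id
  eps <- matrix(0, length(rids), length(mids), dimnames = list(rids, mids))
  regime <- stats::setNames(rep("linlog", length(rids)), rids)
  diags <- list()
  for (rid in rids) {
    r <- get_reaction(model, rid)
    part <- default_participants(r, mids)
    if (!length(part)) {
      warnf("reaction %s has no non-boundary participants; elasticity row is zero", rid)
      regime[rid] <- "none"
      next
    }
    st_row <- if (rid %in% rownames(status)) status[rid, ] else NULL
    if (!is.null(st_row) && st_row$status == "equilibrium") {
      regime[rid] <- "thermokinetic"
      dg <- tfa$dg_opt[[rid]]
      e <- tryCatch(
        thermokinetic_elasticity(r, dg, params, mids),
        error = function(err) stopf("reaction %s: %s", rid, conditionMessage(err)))
      eps[rid, names(e)] <- e
    } else {
      regime[rid] <- "linlog"
      v0 <- fluxes[rid, ref_id]
      if (!is.finite(v0) || abs(v0) < 1e-9) {
        warnf("reaction %s has (near) zero reference flux; lin-log row left zero", rid)
        diags[[rid]] <- list(skipped = "zero reference flux")
        next
      }
      # measured boundary co-substrates enter the regression so their effect
      # is not attributed to interior metabolites; their fitted columns are
      # parameter (not variable) elasticities and stay out of the matrix
      ref_extra <- reference_state(dataset)$conc_extra
      bnd_cand <- if (r$reversible) names(r$stoich) else names(r$stoich)[r$stoich < 0]
      bnd_part <- intersect(bnd_cand, names(ref_extra)[is.finite(ref_extra)])
      vk <- fluxes[rid, ] / v0
      fit <- tryCatch(
        linlog_fit(dataset, vk, c(part, bnd_part)),
        error = function(err) stopf("reaction %s: %s", rid, conditionMessage(err)))
      eps[rid, part] <- fit$eps[part]
      diags[[rid]] <- c(fit[c("r2", "cond", "ridge_used", "n_states")],
                        list(boundary_eps = fit$eps[bnd_part]))
    }
  }
  structure(list(eps = eps, regime = regime, diagnostics = diags),
            class = "elasticity_matrix")
}

#' @export
print.elasticity_matrix <- function(x, ...) {
  cat(sprintf("elasticity_matrix: %d reactions x %d metabolites (%d thermokinetic, %d lin-log)\n",
              nrow(x$eps), ncol(x$eps), sum(x$regime == "thermokinetic"),
              sum(x$regime == "linlog")))
  invisible(x)
}
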