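#' Describe one feeding-rate step
#'
#' @param substrate_conc named numeric: feed concentration of each fed
#'   compound, g/L
#' @param feed_rate feed rate, mL/h
#' @param duration step duration, h (default 7 min)
#' @param reactor_volume broth volume, L
#' @param biomass_conc biomass concentration, g dry cell weight / L
#' @return object of class `feed_step`
#' @export
feed_step <- function(substrate_conc = numeric(0), feed_rate = 0,
                      duration = 7 / 60, reactor_volume = 1,
                      biomass_conc = 1) {
  stopifnot(duration > 0, reactor_volume > 0, biomass_conc > 0, feed_rate >= 0)
  structure(list(substrate_conc = substrate_conc, feed_rate = feed_rate,
                 duration = duration, reactor_volume = reactor_volume,
                 biomass_conc = biomass_conc),
            class = "feed_step")
}

#' Biomass-specific transport rate from a feeding-step concentration change
#'
#' The medium concentration difference over a feeding step, corrected for the
#' mass added with the feed, divided by molecular weight, step duration and
#' biomass:
#' `rate = ((conc_end - conc_start) * V - fed_mass) / (MW * dt * X * V) * 1000`
#' with `fed_mass = feed_rate * dt * feed_conc` (0 for compounds not in the
#' feed). The small volume change from the feed addition is ignored. Sign
#' convention: uptake negative, secretion positive (flip with
#' `uptake_negative = FALSE`).
#'
#' @param conc_start,conc_end medium concentration at step start/end, g/L
#' @param step a [feed_step()]
#' @param compound_mw molecular weight, g/mol
#' @param compound compound id, used to look up the feed concentration
#' @param sd_start,sd_end optional measurement sd, g/L (propagated
#'   root-sum-square)
#' @param uptake_negative logical sign convention switch
#' @return list with `rate` and `sd`, both mmol g-1 h-1
#' @export
specific_rate <- function(conc_start, conc_end, step, compound_mw,
                          compound = NULL, sd_start = 0, sd_end = 0,
                          uptake_negative = TRUE) {
  if (!inherits(step, "feed_step")) stopf("step must be a feed_step")
  if (step$duration <= 0) stopf("step duration must be positive")
  if (conc_start < 0 || conc_end < 0) stopf("negative medium concentration")
  if (compound_mw <= 0) stopf("molecular weight must be positive")
  feed_conc <- 0
  if (!is.null(compound) && compound %in% names(step$substrate_conc)) {
    feed_conc <- step$substrate_conc[[compound]]
  }
  V <- step$reactor_volume
  fed_mass <- step$feed_rate / 1000 * step$duration * feed_conc  # g
  denom <- compound_mw * step$duration * step$biomass_conc * V
  rate <- ((conc_end - conc_start) * V - fed_mass) / denom * 1000
  sd <- sqrt(sd_start^2 + sd_end^2) * V / denom * 1000
  if (!uptake_negative) rate <- -rate
  list(rate = rate, sd = sd)
}

#' Construct one steady state
#'
#' @param id state label
#' @param conc_intra named numeric, intracellular concentrations mol/L
#' @param conc_sd named numeric, measurement sd mol/L
#' @param rates named numeric, boundary transport rates mmol g-1 h-1
#'   (uptake negative), keyed by model reaction id
#' @param rate_sd named numeric sd
#' @param conc_extra named numeric, measured extracellular (boundary)
#'   concentrations mol/L - used as additional lin-log regressors
#' @param is_reference logical
#' @return object of class `steady_state`
#' @export
steady_state_record <- function(id, conc_intra = numeric(0),
                                conc_sd = numeric(0), rates = numeric(0),
                                rate_sd = numeric(0),
                                conc_extra = numeric(0),
                                is_reference = FALSE) {
  if (any(conc_intra < 0, na.rm = TRUE)) {
    stopf("negative intracellular concentration in state %s", id)
  }
  structure(list(id = id, conc_intra = conc_intra, conc_sd = conc_sd,
                 rates = rates, rate_sd = rate_sd, conc_extra = conc_extra,
                 is_reference = is_reference),
            class = "steady_state")
}

new_dataset <- function(states, design = NULL) {
  refs <- vapply(states, `[[`, FALSE, "is_reference")
  if (sum(refs) != 1) {
    stopf("dataset must contain exactly one reference state (found %d)",
          sum(refs))
  }
  if (length(states) < 2) stopf("need at least 2 states for lin-log fitting")
  names(states) <- vapply(states, `[[`, "", "id")
  cov <- lapply(states, function(s) sort(names(s$conc_intra)))
  if (length(unique(cov)) > 1) {
    warnf("metabolite coverage differs across states; missing values fall back to default TFA bounds")
  }
  structure(list(states = states, design = design),
            class = "steady_state_dataset")
}

#' Assemble a steady-state dataset from feeding-step tables
#'
#' Computes biomass-specific extracellular rates for every (state, compound)
#' via [specific_rate()] and joins the intracellular metabolome table. A
#' metabolite missing from a state is left absent (TFA then applies its
#' default wide bounds); it is never imputed as zero.
#'
#' @param extracellular data.frame with columns `state_id`, `compound_id`,
#'   `conc_begin_g_l`, `conc_end_g_l`, `sd_g_l`
#' @param steps named list of [feed_step()] keyed by state id
#' @param intracellular data.frame with columns `state_id`, `metabolite_id`,
#'   `conc_mol_l`, `sd_mol_l`
#' @param compounds data.frame mapping `compound_id` to `mw_g_mol` and the
#'   model `reaction_id` its transport rate constrains
#' @param reference_id id of the reference state; its rates must be supplied
#'   directly via `reference_rates` / `reference_rate_sd` (they come from the
#'   production process, not from a feeding step)
#' @param reference_rates,reference_rate_sd named numeric vectors
#' @return a `steady_state_dataset` (13 states for the 4 regimes x 3 steps
#'   design plus reference)
#' @export
build_dataset <- function(extracellular, steps, intracellular, compounds,
                          reference_id = "REF",
                          reference_rates = numeric(0),
                          reference_rate_sd = numeric(0)) {
  state_ids <- unique(c(reference_id, intracellular$state_id))
  states <- lapply(state_ids, function(sid) {
    conc_rows <- intracellular[intracellular$state_id == sid, , drop = FALSE]
    conc <- stats::setNames(conc_rows$conc_mol_l, conc_rows$metabolite_id)
    csd <- stats::setNames(conc_rows$sd_mol_l, conc_rows$metabolite_id)
    if (sid == reference_id) {
      return(steady_state_record(sid, conc, csd, reference_rates,
                                 reference_rate_sd, is_reference = TRUE))
    }
    if (!sid %in% names(steps)) stopf("no feed_step supplied for state %s", sid)
    step <- steps[[sid]]
    ex <- extracellular[extracellular$state_id == sid, , drop = FALSE]
    rates <- numeric(0); rsd <- numeric(0)
    for (k in seq_len(nrow(ex))) {
      row <- ex[k, ]
      ci <- match(row$compound_id, compounds$compound_id)
      if (is.na(ci)) stopf("compound %s not in compound table", row$compound_id)
      sr <- specific_rate(row$conc_begin_g_l, row$conc_end_g_l, step,
                          compounds$mw_g_mol[ci], compound = row$compound_id,
                          sd_start = row$sd_g_l %||% 0,
                          sd_end = row$sd_g_l %||% 0)
      rid <- compounds$reaction_id[ci]
      rates[rid] <- sr$rate
      rsd[rid] <- sr$sd
    }
    steady_state_record(sid, conc, csd, rates, rsd)
  })
  new_dataset(states)
}

#' @export
print.steady_state_dataset <- function(x, ...) {
  refs <- vapply(x$states, `[[`, FALSE, "is_reference")
  cat(sprintf("steady_state_dataset: %d states (%d perturbation + reference '%s')\n",
              length(x$states), sum(!refs),
              x$states[[which(refs)]]$id))
  invisible(x)
}

#' Reference / perturbation state accessors
#' @param dataset a `steady_state_dataset`
#' @name dataset-accessors
NULL

#' @rdname dataset-accessors
#' @export
reference_state <- function(dataset) {
  refs <- vapply(dataset$states, `[[`, FALSE, "is_reference")
  dataset$states[[which(refs)]]
}

#' @rdname dataset-accessors
#' @export
nonreference_states <- function(dataset) {
  refs <- vapply(dataset$states, `[[`, FALSE, "is_reference")
  dataset$states[!refs]
}
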