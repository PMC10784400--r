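# Monte-Carlo sampling of reaction Gibbs energies within TFA ranges and the
# quartile rule that decides which elasticity regime a reaction gets.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Monte-Carlo sample of reaction Gibbs energies
#'
#' Draws log-concentrations independently and uniformly within their TFA
#' ranges, evaluates every interior reaction's Gibbs energy, and clips the
#' result to the reaction's TFA Gibbs-energy range. Reproducible under a
#' fixed seed.
#'
#' @param tfa a `tfa_result` with `ranges$lnc` and `ranges$dg`
#' @param model a `network_model`
#' @param params a [thermo_params()] object
#' @param n number of cycles (default 10000)
#' @param seed RNG seed
#' @return object of class `gibbs_samples`: list with `samples` (n x
#'   reactions matrix, kJ/mol), `n`, `seed`
#' @export
sample_gibbs <- function(tfa, model, params = thermo_params(), n = 10000,
                         seed = 1) {
  if (n < 100) warnf("n = %d Monte-Carlo cycles; quartiles will be unstable", n)
  lnc_rng <- tfa$ranges$lnc
  dg_rng <- tfa$ranges$dg
  if (is.null(lnc_rng) || is.null(dg_rng)) {
    stopf("tfa result carries no variability ranges; rerun solve_tfa(variability = TRUE)")
  }
  mids <- rownames(lnc_rng)
  exch <- vapply(model$reactions, `[[`, FALSE, "exchange")
  rids <- reaction_ids(model)[!exch]
  dg0e <- effective_standard_gibbs(model, params)
  names(dg0e) <- reaction_ids(model)

  lnc_draw <- with_seed(seed, {
    lo <- lnc_rng[, "min"]; hi <- lnc_rng[, "max"]
    w <- hi - lo
    m <- matrix(stats::runif(n * length(mids)), nrow = n)
    sweep(sweep(m, 2, w, `*`), 2, lo, `+`)
  })
  colnames(lnc_draw) <- mids

  samples <- matrix(NA_real_, n, length(rids), dimnames = list(NULL, rids))
  interior <- interior_metabolite_ids(model)
  for (rid in rids) {
    st <- get_reaction(model, rid)$stoich
    ii <- intersect(names(st), interior)
    dg <- rep(dg0e[rid], n)
    if (length(ii)) {
      dg <- dg + params$RT * drop(lnc_draw[, ii, drop = FALSE] %*% st[ii])
    }
    dg <- pmin(pmax(dg, dg_rng[rid, "min"]), dg_rng[rid, "max"])
    samples[, rid] <- dg
  }
  structure(list(samples = samples, n = n, seed = seed),
            class = "gibbs_samples")
}

#' Quartile-based equilibrium classification
#'
#' A reaction is classified `equilibrium` when both middle quartiles of its
#' sampled Gibbs energy lie between `threshold` and 0 kJ/mol (closed
#' interval, linear-interpolation quartiles), i.e. `threshold <= q1` and
#' `q3 <= 0`. Reactions flagged `forced_nonequilibrium` in the model (the
#' PTS) are always `non_equilibrium` with `source = "forced"`.
#'
#' @param samples a [sample_gibbs()] result
#' @param model a `network_model`
#' @param threshold lower quartile bound, kJ/mol (default -10)
#' @return object of class `equilibrium_status`: data.frame with
#'   `reaction_id`, `q1`, `q3`, `status`, `source`
#' @export
classify_equilibrium <- function(samples, model, threshold = -10) {
  rids <- colnames(samples$samples)
  out <- do.call(rbind, lapply(rids, function(rid) {
    q <- stats::quantile(samples$samples[, rid], c(0.25, 0.75), type = 7,
                         names = FALSE)
    forced <- get_reaction(model, rid)$forced_nonequilibrium
    if (forced) {
      status <- "non_equilibrium"; source <- "forced"
    } else {
      status <- if (q[1] >= threshold && q[2] <= 0) "equilibrium" else "non_equilibrium"
      source <- "quartile_rule"
    }
    data.frame(reaction_id = rid, q1 = q[1], q3 = q[2], status = status,
               source = source, stringsAsFactors = FALSE)
  }))
  rownames(out) <- out$reaction_id
  class(out) <- c("equilibrium_status", class(out))
  out
}

#' @export
print.equilibrium_status <- function(x, ...) {
  cat(sprintf("equilibrium_status: %d equilibrium / %d non-equilibrium\n",
              sum(x$status == "equilibrium"),
              sum(x$status == "non_equilibrium")))
  NextMethod()
}
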