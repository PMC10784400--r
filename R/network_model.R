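#' Load a reduced metabolic network model
#'
#' Reads the packaged JSON dialect (or, with `format = "sbml"`, a minimal
#' SBML Level-3 subset where `boundaryCondition` marks boundary species) and
#' validates it. Metabolite and reaction order follows file order and is the
#' deterministic public ordering used by every downstream matrix.
#'
#' @param path path to a model file
#' @param format `"json"` (default) or `"sbml"`
#' @return a `network_model` object: list with `metabolites` (data.frame:
#'   `id`, `name`, `dgf`, `boundary`, `conc_min`, `conc_max`, `conc_fixed`),
#'   `reactions` (list of reaction records with `id`, `stoich` named numeric,
#'   `reversible`, `forced_nonequilibrium`, `exchange`, `uptake`, `pathway`,
#'   `effectors`) and `objective` (reaction id maximised by TFA)
#' @export
load_model <- function(path, format = c("json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("model file not found: %s", path)
  raw <- if (format == "json") parse_model_json(path) else parse_model_sbml(path)
  validate_model(raw)
}

parse_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stopf("model schema violation: top-level 'metabolites' and 'reactions' required",
          class = "invivomca_validation_error")
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = as.character(m$id %||% NA),
               name = as.character(m$name %||% m$id %||% ""),
               dgf = as.numeric(m$dgf_kj_mol %||% NA),
               boundary = isTRUE(m$boundary),
               conc_min = as.numeric(m$conc_min %||% 1e-8),
               conc_max = as.numeric(m$conc_max %||% 0.1),
               conc_fixed = as.numeric(m$conc_fixed %||% 1),
               stringsAsFactors = FALSE)
  }))
  rxns <- lapply(doc$reactions, function(r) {
    st <- vapply(r$stoich, function(v) as.numeric(v), numeric(1))
    list(id = as.character(r$id %||% NA),
         stoich = st,
         reversible = isTRUE(r$reversible),
         forced_nonequilibrium = isTRUE(r$forced_nonequilibrium),
         exchange = isTRUE(r$exchange),
         uptake = isTRUE(r$uptake),
         pathway = as.character(r$pathway %||% ""),
         effectors = as.character(unlist(r$effectors %||% character(0))))
  })
  structure(list(metabolites = mets, reactions = rxns,
                 objective = as.character(doc$objective %||% "")),
            class = "network_model")
}

parse_model_sbml <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stopf("SBML import requires the xml2 package")
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- do.call(rbind, lapply(sp, function(s) {
    data.frame(id = xml2::xml_attr(s, "id"),
               name = xml2::xml_attr(s, "name") %||% xml2::xml_attr(s, "id"),
               dgf = suppressWarnings(as.numeric(xml2::xml_attr(s, "dgf_kj_mol"))),
               boundary = identical(xml2::xml_attr(s, "boundaryCondition"), "true"),
               conc_min = 1e-8, conc_max = 0.1, conc_fixed = 1,
               stringsAsFactors = FALSE)
  }))
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- lapply(rx, function(r) {
    subs <- xml2::xml_find_all(r, "./listOfReactants/speciesReference")
    prods <- xml2::xml_find_all(r, "./listOfProducts/speciesReference")
    coef <- function(nodes, sgn) {
      s <- suppressWarnings(as.numeric(xml2::xml_attr(nodes, "stoichiometry")))
      s[is.na(s)] <- 1
      stats::setNames(sgn * s, xml2::xml_attr(nodes, "species"))
    }
    st <- c(coef(subs, -1), coef(prods, +1))
    list(id = xml2::xml_attr(r, "id"), stoich = st,
         reversible = identical(xml2::xml_attr(r, "reversible"), "true"),
         forced_nonequilibrium = FALSE, exchange = FALSE, uptake = FALSE,
         pathway = "", effectors = character(0))
  })
  structure(list(metabolites = mets, reactions = rxns, objective = ""),
            class = "network_model")
}

#' Validate a network model
#'
#' Checks referential integrity (every stoichiometric entry names a declared
#' metabolite), finiteness of formation energies for non-boundary species,
#' concentration-bound sanity, and that every interior reaction has at least
#' one substrate, one product and one non-boundary participant. Unbalanced
#' lumped reactions are allowed.
#'
#' @param model a `network_model`
#' @return the model, invisibly validated (errors of class
#'   `invivomca_validation_error` on violation)
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  if (anyDuplicated(mets$id)) {
    stopf("duplicate metabolite ids: %s",
          paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "),
          class = "invivomca_validation_error")
  }
  rids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(rids)) {
    stopf("duplicate reaction ids: %s",
          paste(unique(rids[duplicated(rids)]), collapse = ", "),
          class = "invivomca_validation_error")
  }
  interior <- !mets$boundary
  bad_dgf <- interior & !is.finite(mets$dgf)
  if (any(bad_dgf)) {
    stopf("non-finite dgf for non-boundary metabolite(s): %s",
          paste(mets$id[bad_dgf], collapse = ", "),
          class = "invivomca_validation_error")
  }
  bad_b <- interior & (!(mets$conc_min > 0) | !(mets$conc_min < mets$conc_max))
  if (any(bad_b)) {
    stopf("invalid concentration bounds (need 0 < min < max) for: %s",
          paste(mets$id[bad_b], collapse = ", "),
          class = "invivomca_validation_error")
  }
  if (length(model$reactions) == 0) {
    stopf("no reactions", class = "invivomca_validation_error")
  }
  for (r in model$reactions) {
    unknown <- setdiff(names(r$stoich), mets$id)
    if (length(unknown)) {
      stopf("reaction %s references undeclared metabolite(s): %s", r$id,
            paste(unknown, collapse = ", "),
            class = "invivomca_validation_error")
    }
    if (length(r$stoich) == 0 || all(r$stoich == 0)) {
      stopf("reaction %s has an empty stoichiometry", r$id,
            class = "invivomca_validation_error")
    }
    if (!any(r$stoich < 0) || !any(r$stoich > 0)) {
      stopf("reaction %s needs at least one substrate and one product", r$id,
            class = "invivomca_validation_error")
    }
    if (!r$exchange) {
      part_interior <- names(r$stoich) %in% mets$id[interior]
      if (!any(part_interior)) {
        stopf("interior reaction %s touches no non-boundary metabolite", r$id,
              class = "invivomca_validation_error")
      }
    }
  }
  # orphan interior metabolites give an all-zero stoichiometric-matrix row
  used <- unique(unlist(lapply(model$reactions, function(r) names(r$stoich))))
  orphans <- setdiff(mets$id[interior], used)
  if (length(orphans)) {
    stopf("non-boundary metabolite(s) in no reaction: %s",
          paste(orphans, collapse = ", "),
          class = "invivomca_validation_error")
  }
  if (nzchar(model$objective) && !(model$objective %in% rids)) {
    stopf("objective reaction '%s' not in model", model$objective,
          class = "invivomca_validation_error")
  }
  model
}

#' Write a network model to JSON
#'
#' Inverse of [load_model()]; the packaged model round-trips exactly
#' (modulo whitespace).
#' @param model a `network_model`
#' @param path output path
#' @export
write_model <- function(model, path) {
  doc <- list(
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      out <- list(id = m$id, name = m$name, dgf_kj_mol = m$dgf,
                  boundary = m$boundary, conc_min = m$conc_min,
                  conc_max = m$conc_max)
      if (m$conc_fixed != 1) out$conc_fixed <- m$conc_fixed
      out
    }),
    reactions = lapply(model$reactions, function(r) {
      out <- list(id = r$id, stoich = as.list(r$stoich),
                  reversible = r$reversible,
                  forced_nonequilibrium = r$forced_nonequilibrium,
                  exchange = r$exchange, uptake = r$uptake,
                  pathway = r$pathway)
      if (length(r$effectors)) out$effectors <- as.list(r$effectors)
      out
    }),
    objective = model$objective)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Reaction and metabolite accessors
#'
#' `reaction_ids()` lists all reaction ids in model order;
#' `interior_reaction_ids()` drops the boundary exchange steps (the
#' enzymatic reactions of the reduced model); `interior_metabolite_ids()`
#' lists the non-boundary species; `get_reaction()` fetches one reaction
#' record by id.
#'
#' @param model a `network_model`
#' @param id a reaction id
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
reaction_ids <- function(model) vapply(model$reactions, `[[`, "", "id")

#' @rdname model-accessors
#' @export
interior_reaction_ids <- function(model) {
  rids <- reaction_ids(model)
  rids[!vapply(model$reactions, `[[`, FALSE, "exchange")]
}

#' @rdname model-accessors
#' @export
interior_metabolite_ids <- function(model) {
  model$metabolites$id[!model$metabolites$boundary]
}

#' @rdname model-accessors
#' @export
get_reaction <- function(model, id) {
  i <- match(id, reaction_ids(model))
  if (is.na(i)) stopf("unknown reaction id: %s", id)
  model$reactions[[i]]
}

#' Stoichiometric matrix (non-boundary rows)
#'
#' @param model a `network_model`
#' @param reactions optional character vector restricting/ordering columns
#' @return numeric matrix, rows = non-boundary metabolites (model order),
#'   columns = reactions (model order); boundary species omitted
#' @export
stoichiometric_matrix <- function(model, reactions = NULL) {
  if (length(model$reactions) == 0) stopf("no reactions")
  rids <- reaction_ids(model)
  if (!is.null(reactions)) {
    missing <- setdiff(reactions, rids)
    if (length(missing)) stopf("unknown reaction(s): %s", paste(missing, collapse = ", "))
    rids <- reactions
  }
  mids <- interior_metabolite_ids(model)
  N <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (rid in rids) {
    st <- get_reaction(model, rid)$stoich
    keep <- names(st) %in% mids
    N[names(st)[keep], rid] <- st[keep]
  }
  N
}

#' Decompose the stoichiometric matrix into independent rows and link matrix
#'
#' Computes a row-independent submatrix `N0`, the link matrix `L` with
#' `N = L %*% N0`, and a basis for the left null space of `N` (conserved
#' moieties, e.g. the adenylate and pyridine-nucleotide pools when both
#' members are interior). This is the decomposition required by the
#' matrix method for control coefficients.
#'
#' @param model a `network_model`
#' @param tol numeric rank tolerance
#' @return list with `N`, `N0`, `L`, `independent` (row ids of `N0`),
#'   `conserved_moieties` (matrix, one row per moiety, columns = metabolites)
#' @export
decompose <- function(model, tol = 1e-9) {
  N <- stoichiometric_matrix(model)
  qr_t <- qr(t(N), LAPACK = TRUE)
  d <- abs(diag(qr.R(qr_t)))
  r <- if (length(d)) sum(d > tol * max(d, 1)) else 0L
  ind <- sort(qr_t$pivot[seq_len(r)])
  dep <- setdiff(seq_len(nrow(N)), ind)
  N0 <- N[ind, , drop = FALSE]
  gram <- N0 %*% t(N0)
  L <- matrix(0, nrow(N), r, dimnames = list(rownames(N), rownames(N0)))
  L[ind, ] <- diag(r)
  moieties <- matrix(0, length(dep), nrow(N),
                     dimnames = list(NULL, rownames(N)))
  for (k in seq_along(dep)) {
    cd <- solve(gram, N0 %*% N[dep[k], ])
    L[dep[k], ] <- cd
    moieties[k, ind] <- -cd
    moieties[k, dep[k]] <- 1
  }
  resid <- max(abs(N - L %*% N0))
  if (resid > 1e-8) stopf("link-matrix decomposition failed (residual %.3g)", resid)
  structure(list(N = N, N0 = N0, L = L,
                 independent = rownames(N0),
                 conserved_moieties = moieties),
            class = "stoich_decomposition")
}

#' @export
print.network_model <- function(x, ...) {
  n_int_r <- length(interior_reaction_ids(x))
  n_exc <- length(x$reactions) - n_int_r
  cat(sprintf("network_model: %d interior reactions (+%d exchange), %d non-boundary metabolites (+%d boundary)\n",
              n_int_r, n_exc, sum(!x$metabolites$boundary),
              sum(x$metabolites$boundary)))
  if (nzchar(x$objective)) cat("objective:", x$objective, "\n")
  invisible(x)
}

#' Path to the packaged reduced E. coli central-carbon + cysteine model
#' @return file path of the canonical 37-reaction, 40-metabolite model JSON
#' @export
canonical_model_path <- function() {
  system.file("extdata", "ecoli_cysteine_reduced.json", package = "invivomca",
              mustWork = TRUE)
}
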