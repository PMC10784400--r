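# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

canonical_model <- function() {
  fixture("canonical", load_model(canonical_model_path()))
}

toy_fixture <- function() fixture("toy", toy_model())

toy_net_fixture <- function() fixture("toy_net", toy_network(toy_fixture()))

# exact (noise-free) synthetic dataset from the toy
toy_dataset_exact <- function() {
  fixture("ds_exact",
          generate_dataset(toy_fixture(), perturbation_design(noise_sd = 0)))
}

true_fcc_fixture <- function() fixture("fcc", true_fcc(toy_fixture()))

# one full pipeline run at zero noise (shared by several tests)
pipeline_sd0 <- function() {
  fixture("pipe_sd0", suppressWarnings(run_pipeline(
    run_config(noise_sd = 0, mc_n = 20, classify_n = 500, seed = 101))))
}

# minimal in-memory models -----------------------------------------------

make_model <- function(mets, rxns, objective = "") {
  m <- do.call(rbind, lapply(mets, function(x) {
    data.frame(id = x$id, name = x$id, dgf = x$dgf %||% 0,
               boundary = isTRUE(x$boundary),
               conc_min = x$conc_min %||% 1e-8,
               conc_max = x$conc_max %||% 0.1,
               conc_fixed = x$conc_fixed %||% 1,
               stringsAsFactors = FALSE)
  }))
  rl <- lapply(rxns, function(r) {
    list(id = r$id, stoich = r$stoich,
         reversible = isTRUE(r$reversible),
         forced_nonequilibrium = isTRUE(r$forced_nonequilibrium),
         exchange = isTRUE(r$exchange), uptake = isTRUE(r$uptake),
         pathway = r$pathway %||% "", effectors = r$effectors %||% character(0))
  })
  validate_model(structure(list(metabolites = m, reactions = rl,
                                objective = objective),
                           class = "network_model"))
}

met <- function(id, ...) c(list(id = id), list(...))
rx <- function(id, stoich, ...) c(list(id = id, stoich = stoich), list(...))

# S_b -> X -> P_b chain, both steps dG0' = 0, boundary S = 10 mM, P = 0.1 mM;
# R1 is the uptake step whose rate the experiment measures
chain_model <- function() {
  make_model(
    mets = list(met("S", boundary = TRUE, dgf = 0, conc_fixed = 0.01),
                met("X", dgf = 0),
                met("P", boundary = TRUE, dgf = 0, conc_fixed = 1e-4)),
    rxns = list(rx("R1", c(S = -1, X = 1), reversible = TRUE),
                rx("R2", c(X = -1, P = 1), reversible = TRUE)),
    objective = "R2")
}

# closed 3-cycle A -> B -> C -> A with a boundary "anchor" to keep the model
# valid; no exchange flux can feed the cycle
cycle_model <- function() {
  make_model(
    mets = list(met("A", dgf = -10), met("B", dgf = -12), met("C", dgf = -11),
                met("ZB", boundary = TRUE, dgf = 0)),
    rxns = list(rx("RAB", c(A = -1, B = 1), reversible = TRUE),
                rx("RBC", c(B = -1, C = 1), reversible = TRUE),
                rx("RCA", c(C = -1, A = 1), reversible = TRUE),
                rx("EX_A", c(ZB = -1, A = 1), exchange = TRUE,
                   reversible = TRUE)),
    objective = "")
}

# two-step linear pathway for the closed-form control-coefficient example:
# v1: -> X (elasticity e1 wrt X), v2: X -> (elasticity e2 wrt X)
two_step_cc <- function(e1, e2, J = 1, s = 1) {
  N <- matrix(c(1, -1), 1, 2, dimnames = list("X", c("v1", "v2")))
  decomp <- list(N = N, N0 = N, L = matrix(1, 1, 1, dimnames = list("X", "X")),
                 independent = "X",
                 conserved_moieties = matrix(0, 0, 1,
                                             dimnames = list(NULL, "X")))
  E <- matrix(c(e1, e2), 2, 1, dimnames = list(c("v1", "v2"), "X"))
  control_coefficients(decomp, c(v1 = J, v2 = J), c(X = s), E)
}
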