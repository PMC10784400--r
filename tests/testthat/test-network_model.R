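test_that("packaged reduced model has the expected dimensions and content", {
  m <- canonical_model()
  expect_length(interior_reaction_ids(m), 37)
  expect_length(interior_metabolite_ids(m), 40)
  # every reaction of the canonical equilibrium classification is present
  eq_named <- c("PGI", "FBA", "TPI", "GAPD", "PGM", "ENO", "ACONT", "FUM",
                "MDH", "RPI", "TALA", "PGCD", "PSERT", "ATPS")
  noneq_named <- c("PFK", "PSP", "PDH", "PPC", "CS", "ICDHyr", "AKGDH",
                   "SUCCOAS", "SUCDH", "G6PDH", "GND", "RPE", "TKT1", "TKT2",
                   "SERAT", "CYSS", "SLCYSS", "SCYSSL", "NADH5")
  expect_true(all(c(eq_named, noneq_named, "PTS") %in% reaction_ids(m)))
  expect_true(get_reaction(m, "PTS")$forced_nonequilibrium)
})

test_that("validation names the offending element", {
  expect_error(
    make_model(mets = list(met("A", dgf = 0)),
               rxns = list(rx("R1", c(A = -1, GHOST = 1)))),
    "GHOST", class = "invivomca_validation_error")
  expect_error(
    make_model(mets = list(met("A", dgf = NA)),
               rxns = list(rx("R1", c(A = -1)))),
    "dgf", class = "invivomca_validation_error")
})

test_that("stoichiometric matrix follows model order and omits boundary rows", {
  m <- make_model(
    mets = list(met("A", dgf = 0), met("B", dgf = 0)),
    rxns = list(rx("R", c(A = -1, B = 1))))
  N <- stoichiometric_matrix(m)
  expect_equal(unname(N[, "R"]), c(-1, 1))

  mc <- canonical_model()
  Nc <- stoichiometric_matrix(mc)
  tkt1 <- Nc[, "TKT1"]
  expect_equal(unname(tkt1[c("X5P", "R5P", "S7P", "GAP")]), c(-1, -1, 1, 1))
  expect_equal(sum(tkt1 != 0), 4)
  expect_false(any(rownames(Nc) %in% mc$metabolites$id[mc$metabolites$boundary]))

  empty <- structure(list(metabolites = mc$metabolites, reactions = list(),
                          objective = ""), class = "network_model")
  expect_error(stoichiometric_matrix(empty), "no reactions")
})

test_that("decomposition satisfies N = L N0 and finds conserved moieties", {
  # linear chain: no conservation
  chain <- make_model(
    mets = list(met("SB", boundary = TRUE, dgf = 0), met("X", dgf = 0),
                met("PB", boundary = TRUE, dgf = 0)),
    rxns = list(rx("R1", c(SB = -1, X = 1)), rx("R2", c(X = -1, PB = 1))))
  d <- decompose(chain)
  expect_equal(nrow(d$conserved_moieties), 0)
  expect_equal(d$L, diag(1), ignore_attr = TRUE)

  # closed pair X <-> Y with no exchange: one conserved moiety X + Y
  d2 <- decompose(make_model(
    mets = list(met("X", dgf = 0), met("Y", dgf = 0)),
    rxns = list(rx("R", c(X = -1, Y = 1), reversible = TRUE))))
  expect_equal(nrow(d2$conserved_moieties), 1)
  g <- d2$conserved_moieties[1, ]
  expect_equal(unname(g / g[["X"]]), c(1, 1))

  # canonical model: moiety count agrees with an independent SVD rank oracle
  mc <- canonical_model()
  d3 <- decompose(mc)
  N <- stoichiometric_matrix(mc)
  rank_svd <- sum(svd(N)$d > 1e-9 * max(svd(N)$d))
  expect_equal(nrow(d3$conserved_moieties), nrow(N) - rank_svd)
  expect_equal(nrow(d3$N0), rank_svd)
  expect_lt(max(abs(d3$N - d3$L %*% d3$N0)), 1e-10)
  # the three cofactor pools
  pools <- apply(d3$conserved_moieties, 1, function(g)
    paste(sort(names(g)[abs(g) > 1e-8]), collapse = "+"))
  expect_setequal(pools, c("ADP+ATP", "NAD+NADH", "NADP+NADPH"))
})

test_that("model JSON round-trips through write_model/load_model", {
  m <- canonical_model()
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_model(m, f)
  m2 <- load_model(f)
  expect_equal(m2$metabolites, m$metabolites)
  expect_equal(m2$objective, m$objective)
  expect_equal(length(m2$reactions), length(m$reactions))
  for (i in seq_along(m$reactions)) {
    expect_equal(m2$reactions[[i]]$stoich, m$reactions[[i]]$stoich)
    expect_equal(m2$reactions[[i]]$reversible, m$reactions[[i]]$reversible)
  }
})

test_that("minimal SBML documents import with boundary conditions", {
  sbml <- '<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
 <model id="mini">
  <listOfSpecies>
   <species id="A" boundaryCondition="false"/>
   <species id="B" boundaryCondition="false"/>
   <species id="Xb" boundaryCondition="true"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="R1" reversible="true">
    <listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>
   </reaction>
   <reaction id="EX" reversible="false">
    <listOfReactants><speciesReference species="B"/></listOfReactants>
    <listOfProducts><speciesReference species="Xb"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  f <- tempfile(fileext = ".xml")
  writeLines(sbml, f)
  m <- suppressWarnings(tryCatch(load_model(f, format = "sbml"),
                                 error = function(e) e))
  # dgf are absent in plain SBML: validation must flag them by name
  expect_s3_class(m, "invivomca_validation_error")
  expect_match(conditionMessage(m), "dgf")
  # with dgf attributes supplied the import succeeds
  sbml2 <- gsub('id="A"', 'id="A" dgf_kj_mol="-10"', sbml)
  sbml2 <- gsub('id="B"', 'id="B" dgf_kj_mol="-12"', sbml2)
  writeLines(sbml2, f)
  m2 <- load_model(f, format = "sbml")
  expect_equal(unname(stoichiometric_matrix(m2)[, "R1"]), c(-1, 2))
  expect_true(m2$metabolites$boundary[m2$metabolites$id == "Xb"])
  unlink(f)
})
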