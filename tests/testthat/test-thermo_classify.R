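# direct construction of a gibbs_samples object
gs <- function(...) {
  cols <- list(...)
  structure(list(samples = do.call(cbind, cols), n = length(cols[[1]]),
                 seed = 0), class = "gibbs_samples")
}

simple_model <- function(forced = FALSE) {
  make_model(
    mets = list(met("A", dgf = 0), met("B", dgf = 0)),
    rxns = list(rx("R", c(A = -1, B = 1), reversible = TRUE,
                   forced_nonequilibrium = forced)))
}

test_that("quartile rule classifies point masses and uniform spreads", {
  m <- simple_model()
  expect_equal(classify_equilibrium(gs(R = rep(-5, 1000)), m)$status,
               "equilibrium")
  expect_equal(classify_equilibrium(gs(R = rep(-20, 1000)), m)$status,
               "non_equilibrium")
  # uniform on [-12, -2]: q1 = -9.5, q3 = -4.5 -> inside the closed window
  u <- seq(-12, -2, length.out = 10001)
  st <- classify_equilibrium(gs(R = u), m)
  expect_equal(st$q1, -9.5, tolerance = 1e-6)
  expect_equal(st$q3, -4.5, tolerance = 1e-6)
  expect_equal(st$status, "equilibrium")
  # samples exactly at the bounds count as inside (closed interval)
  expect_equal(classify_equilibrium(gs(R = rep(-10, 100)), m)$status,
               "equilibrium")
  expect_equal(classify_equilibrium(gs(R = rep(0, 100)), m)$status,
               "equilibrium")
})

test_that("forced non-equilibrium overrides the quartile rule", {
  m <- simple_model(forced = TRUE)
  st <- classify_equilibrium(gs(R = rep(-5, 100)), m)
  expect_equal(st$status, "non_equilibrium")
  expect_equal(st$source, "forced")
})

test_that("classification is permutation-invariant and threshold-monotone", {
  m <- simple_model()
  set.seed(42)
  for (k in 1:20) {
    x <- stats::runif(400, -25, 2)
    a <- classify_equilibrium(gs(R = x), m)
    b <- classify_equilibrium(gs(R = sample(x)), m)
    expect_equal(a$status, b$status)
    # widening the window can only move non_equilibrium -> equilibrium
    wide <- classify_equilibrium(gs(R = x), m, threshold = -20)
    if (a$status == "equilibrium") expect_equal(wide$status, "equilibrium")
  }
})

test_that("Gibbs sampling is seeded, bounded, and degenerate-range aware", {
  net <- canonical_model()
  tfa <- synthetic_reference_tfa(net)
  s1 <- sample_gibbs(tfa, net, n = 500, seed = 11)
  s2 <- sample_gibbs(tfa, net, n = 500, seed = 11)
  expect_identical(s1$samples, s2$samples)
  s3 <- sample_gibbs(tfa, net, n = 500, seed = 12)
  expect_false(identical(s1$samples, s3$samples))
  for (rid in colnames(s1$samples)) {
    expect_true(all(s1$samples[, rid] >= tfa$ranges$dg[rid, "min"] - 1e-9))
    expect_true(all(s1$samples[, rid] <= tfa$ranges$dg[rid, "max"] + 1e-9))
  }
  # zero-width ln-concentration ranges give a point mass
  tfa0 <- tfa
  tfa0$ranges$lnc[, "min"] <- tfa0$ranges$lnc[, "max"]
  tfa0$ranges$dg[, "min"] <- -1e6; tfa0$ranges$dg[, "max"] <- 1e6
  s0 <- sample_gibbs(tfa0, net, n = 200, seed = 1)
  expect_equal(apply(s0$samples, 2, stats::sd), rep(0, ncol(s0$samples)),
               ignore_attr = TRUE)
  expect_warning(sample_gibbs(tfa, net, n = 50, seed = 1), "unstable")
})

test_that("the synthetic reference state reproduces the canonical equilibrium split", {
  m <- canonical_model()
  tfa <- synthetic_reference_tfa(m)
  samples <- sample_gibbs(tfa, m, n = 2000, seed = 5)
  st <- classify_equilibrium(samples, m)
  eq_named <- c("PGI", "FBA", "TPI", "GAPD", "PGM", "ENO", "ACONT", "FUM",
                "MDH", "RPI", "TALA", "PGCD", "PSERT", "ATPS")
  noneq_named <- c("PFK", "PSP", "PDH", "PPC", "CS", "ICDHyr", "AKGDH",
                   "SUCCOAS", "SUCDH", "G6PDH", "GND", "RPE", "TKT1", "TKT2",
                   "SERAT", "CYSS", "SLCYSS", "SCYSSL", "NADH5")
  expect_setequal(st$reaction_id[st$status == "equilibrium"], eq_named)
  expect_true(all(noneq_named %in%
                    st$reaction_id[st$status == "non_equilibrium"]))
  expect_equal(st["PTS", "source"], "forced")
})
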