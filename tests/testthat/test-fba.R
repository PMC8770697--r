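test_that("fba solves the uptake-limited chain", {
  m <- chain_model()
  s <- fba(m)
  expect_identical(s$status, "optimal")
  expect_equal(s$objective, 10)
  expect_equal(unname(s$fluxes["R1"]), 10)
  # no substrate, no growth
  expect_equal(fba(chain_model(uptake = 0))$objective, 0)
})

test_that("optimal solutions satisfy steady state and bounds on all fixtures", {
  models <- list(chain_model(), branch_model(), parallel_model(),
                 cycle_model(), toy_microbe(), toy_host())
  for (m in models) {
    s <- fba(m)
    expect_identical(s$status, "optimal")
    S <- stoichiometric_matrix(m, sparse = FALSE)
    expect_lt(max(abs(S %*% s$fluxes)), 1e-6)
    expect_true(all(s$fluxes >= m$reactions$lb - 1e-9))
    expect_true(all(s$fluxes <= m$reactions$ub + 1e-9))
  }
})

test_that("fba objective matches the vertex-enumeration oracle on random toys", {
  for (seed in 1:10) {
    m <- random_toy_lp_model(seed, n_mets = 3, n_rxns = 8)
    s <- fba(m)
    o <- oracle_fba(m)
    expect_identical(s$status, o$status)
    if (s$status == "optimal") {
      expect_equal(s$objective, o$objective, tolerance = 1e-6)
    }
  }
})

test_that("fva reproduces hand-derived spans", {
  # unique optimum: every span zero at gamma = 1
  fv <- fva(chain_model(), gamma = 1)
  expect_true(all(fv$span < 1e-5))
  # at 90% optimality one unit of A may divert to C
  fv <- fva(branch_model(), gamma = 0.9, reactions = "R2")
  expect_equal(fv$vmin, 0, tolerance = 1e-5)
  expect_equal(fv$vmax, 1, tolerance = 1e-5)
  # two parallel identical routes: alternate optima, each in [0, 10]
  fv <- fva(parallel_model(), gamma = 1, reactions = c("R1a", "R1b"))
  expect_equal(fv$vmin, c(0, 0), tolerance = 1e-5)
  expect_equal(fv$vmax, c(10, 10), tolerance = 1e-5)
})

test_that("fva envelopes contain the fba flux and are monotone in gamma", {
  for (m in list(branch_model(), toy_microbe())) {
    v <- fba(m)$fluxes
    f1 <- fva(m, gamma = 1)
    f9 <- fva(m, gamma = 0.9)
    expect_true(all(f1$vmin - 1e-6 <= v[f1$reaction_id]))
    expect_true(all(v[f1$reaction_id] <= f1$vmax + 1e-6))
    expect_true(all(f9$vmin <= f1$vmin + 1e-6))
    expect_true(all(f9$vmax >= f1$vmax - 1e-6))
  }
})

test_that("fva bounds match the vertex-enumeration oracle on random toys", {
  for (seed in 11:16) {
    m <- random_toy_lp_model(seed, n_mets = 3, n_rxns = 7)
    fv <- fva(m, gamma = 1)
    ov <- oracle_fva(m, gamma = 1)
    i <- match(fv$reaction_id, ov$reaction_id)
    expect_equal(fv$vmin, ov$vmin[i], tolerance = 1e-6)
    expect_equal(fv$vmax, ov$vmax[i], tolerance = 1e-6)
  }
})

test_that("min-norm solutions attain the optimum with minimal norm", {
  # symmetric parallel routes split evenly under the euclidean norm
  s <- min_norm_solution(parallel_model())
  expect_equal(s$objective, 10, tolerance = 1e-6)
  expect_equal(unname(s$fluxes["R1a"]), 5, tolerance = 1e-6)
  expect_equal(unname(s$fluxes["R1b"]), 5, tolerance = 1e-6)
  # unique optimum: min-norm equals fba
  m <- chain_model()
  expect_equal(min_norm_solution(m)$fluxes, fba(m)$fluxes,
               tolerance = 1e-6)
  # norm never exceeds the raw fba solution's
  for (mm in list(parallel_model(), cycle_model(), toy_microbe())) {
    mn <- min_norm_solution(mm)
    raw <- fba(mm)
    expect_equal(mn$objective, raw$objective, tolerance = 1e-6)
    expect_lte(sum(mn$fluxes^2), sum(raw$fluxes^2) + 1e-6)
  }
})

test_that("euclidean min-norm silences spurious internal cycles", {
  m <- cycle_model()
  s <- min_norm_solution(m)
  expect_equal(unname(s$fluxes[c("C1", "C2", "C3")]), c(0, 0, 0),
               tolerance = 1e-6)
  # grid oracle: adding t units around the cycle only increases the norm
  norms <- vapply(seq(0, 5, by = 0.5), function(t) {
    v <- s$fluxes
    v[c("C1", "C2", "C3")] <- v[c("C1", "C2", "C3")] + t
    sum(v^2)
  }, numeric(1))
  expect_equal(which.min(norms), 1L)
  # 1-norm variant also attains the optimum
  s1 <- min_norm_solution(m, norm = "one")
  expect_equal(s1$objective, 10, tolerance = 1e-6)
  expect_lte(sum(abs(s1$fluxes)), sum(abs(fba(m)$fluxes)) + 1e-6)
})

test_that("blocked reactions are detected exactly", {
  m <- metabolic_model(dplyr::bind_rows(
    rxn_row("EX_A", "A[c] ->", -10, 1000),
    rxn_row("R1", "A[c] -> B[c]", 0, 1000),
    rxn_row("EX_B", "B[c] ->", 0, 1000),
    rxn_row("R3", "A[c] -> D[c]", 0, 1000)),  # D has no consumer
    objective = c(EX_B = 1))
  expect_identical(find_blocked_reactions(m), "R3")
  m2 <- metabolic_model(dplyr::bind_rows(
    m$reactions, rxn_row("DM_D", "D[c] ->", 0, 1000, kind = "demand")),
    objective = c(EX_B = 1))
  expect_identical(find_blocked_reactions(m2), character(0))
})

test_that("blocked set matches the per-reaction oracle on random toys", {
  for (seed in 21:26) {
    m <- random_toy_lp_model(seed, n_mets = 3, n_rxns = 7)
    blocked <- find_blocked_reactions(m)
    S <- stoichiometric_matrix(m, sparse = FALSE)
    oracle <- character(0)
    for (j in seq_len(ncol(S))) {
      e <- numeric(ncol(S)); e[j] <- 1
      hi <- brute_force_lp(e, S, "=", rep(0, nrow(S)),
                           m$reactions$lb, m$reactions$ub,
                           maximize = TRUE)$objective
      lo <- brute_force_lp(e, S, "=", rep(0, nrow(S)),
                           m$reactions$lb, m$reactions$ub,
                           maximize = FALSE)$objective
      if (abs(hi) < 1e-6 && abs(lo) < 1e-6) {
        oracle <- c(oracle, colnames(S)[j])
      }
    }
    expect_setequal(blocked, oracle)
  }
})

test_that("dead-end classification honours reversibility", {
  m <- metabolic_model(dplyr::bind_rows(
    rxn_row("R1", "A[c] -> D[c]", 0, 1000),
    rxn_row("SK_A", "A[c] <=>", -1000, 1000, kind = "sink")))
  expect_identical(find_dead_end_metabolites(m), "D[c]")
  # a reversible consumer also produces: D no longer dead
  m2 <- metabolic_model(dplyr::bind_rows(
    m$reactions, rxn_row("R2", "D[c] <=> E[c]", -1000, 1000)))
  expect_false("D[c]" %in% find_dead_end_metabolites(m2))
  for (seed in 31:36) {
    mm <- random_toy_lp_model(seed)
    expect_setequal(find_dead_end_metabolites(mm), oracle_dead_ends(mm))
  }
})

test_that("sanity checks catch leaks and agree with blocked detection", {
  m <- toy_microbe()
  rep <- run_sanity_checks(m)
  expect_length(rep$leaking_metabolites, 0)
  expect_setequal(rep$blocked_reactions, find_blocked_reactions(m))
  leaky <- metabolic_model(dplyr::bind_rows(
    m$reactions, rxn_row("R_bad", "-> atp[c]", 0, 1000)),
    objective = m$objective)
  expect_true("atp[c]" %in% run_sanity_checks(leaky)$leaking_metabolites)
})

test_that("shadow prices expose the binding substrate", {
  m <- chain_model()
  s <- fba(m)
  sp <- shadow_prices(s)
  expect_true(all(c("A[c]", "B[c]") %in% sp$metabolite_id))
  expect_identical(glance(s)$status, "optimal")
  td <- tidy(s)
  expect_equal(nrow(td), 3)
})
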