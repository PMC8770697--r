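test_that("tagging prefixes ids, guards double application", {
  m <- toy_microbe()
  t1 <- tag_model(m, "M_")
  expect_true(all(startsWith(t1$reactions$id, "M_")))
  expect_true(all(startsWith(t1$metabolites$id, "M_")))
  expect_identical(t1$reactions$gpr, m$reactions$gpr)
  expect_error(tag_model(t1, "M_"), "already tagged")
  # compartment renames rewrite the bracket suffixes
  t2 <- tag_model(m, "X_", compartment_renames = c(e = "p"))
  expect_true("p" %in% t2$compartments)
  expect_false("e" %in% t2$compartments)
})

test_that("pairing bookkeeping matches the construction formula", {
  h <- toy_host(); m <- toy_microbe()
  p <- pair_models(h, m)
  e_ex <- function(mod) sum(mod$reactions$kind == "exchange" &
    vapply(mod$reactions$stoichiometry,
           function(s) grepl("\\[e\\]$", names(s)[1]), logical(1)))
  n_lumen <- length(unique(c(
    sub("^EX_(.*)\\[e\\]$", "\\1",
        h$reactions$id[grepl("^EX_.*\\[e\\]$", h$reactions$id)]),
    sub("^EX_(.*)\\[e\\]$", "\\1",
        m$reactions$id[grepl("^EX_.*\\[e\\]$", m$reactions$id)]))))
  # each organism exchange becomes one transport; one community exchange
  # per distinct lumen species
  expect_equal(n_reactions(p),
               n_reactions(h) + n_reactions(m) + n_lumen)
  expect_setequal(unique(p$organism_tags$organism),
                  c("host", "microbe", "community"))
  expect_equal(nrow(p$organism_tags), n_reactions(p))
  # organism attribution is a partition
  expect_equal(anyDuplicated(p$organism_tags$reaction_id), 0)
  # host body-fluid exchanges survive untouched
  expect_true("H_EX_lac[b]" %in% p$reactions$id)
  expect_true(isTRUE(is_clean(validate_model(p))))
})

test_that("pairing is neutral when the microbe is closed", {
  h <- toy_host(); m <- toy_microbe()
  diet <- medium_spec(c("EX_glc[u]" = -10, "EX_ser[u]" = -10,
                        "EX_fol[u]" = -1))
  p <- pair_models(h, m, lumen_medium = diet)
  closed <- close_organism(p, "microbe")
  expect_equal(fba(closed)$objective, fba(h)$objective,
               tolerance = 1e-6)
  # lumen metabolite balances hold at the paired optimum
  s <- fba(p)
  S <- stoichiometric_matrix(p, sparse = FALSE)
  lumen_rows <- grepl("\\[u\\]$", rownames(S))
  expect_lt(max(abs(S[lumen_rows, ] %*% s$fluxes)), 1e-6)
})

test_that("cross-feeding host grows only when paired", {
  h <- toy_host(toy_spec(host_nuc_synthesis = FALSE))
  m <- toy_microbe()
  expect_equal(fba(h)$objective, 0, tolerance = 1e-9)
  p <- pair_models(h, m, lumen_medium = toy_lumen_diet())
  z <- fba(p)$objective
  expect_gt(z, 1)
  # the nucleotide hand-off is obligate: its transport has vmin > 0
  ifv <- interaction_fva(p, targets = c("M_IEX_nuc[u]", "H_IEX_nuc[u]"))
  expect_gt(ifv$vmin[ifv$reaction_id == "M_IEX_nuc[u]"], 1e-6)
  expect_error(interaction_fva(p, targets = "nonexistent"), "unknown")
})

test_that("coupling constraints bind organism flux to organism growth", {
  h <- toy_host(); m <- toy_microbe()
  p <- pair_models(h, m, lumen_medium = toy_lumen_diet(),
                   coupling = coupling_spec(c_coupling = 400,
                                            u_coupling = 0.01))
  # biomass pinned to 0.01: coupled serine transport capped at 4.01
  i <- match(p$microbe_biomass, p$reactions$id)
  p$reactions$lb[i] <- 0.01; p$reactions$ub[i] <- 0.01
  fv <- fva(p, gamma = 0, reactions = "M_T_ser")
  expect_equal(fv$vmax, 400 * 0.01 + 0.01, tolerance = 1e-6)
  # biomass 0 with zero offset: every coupled flux vanishes
  p0 <- p
  p0$reactions$lb[i] <- 0; p0$reactions$ub[i] <- 0
  p0$coupling$rows$rhs <- 0
  fv0 <- fva(p0, gamma = 0,
             reactions = c("M_T_glc", "M_R_glyc", "M_T_ser"))
  expect_true(all(abs(c(fv0$vmin, fv0$vmax)) < 1e-6))
  # coupling rows touch only microbe reactions: with the microbe closed
  # the host flux ranges are identical with and without them
  pu <- close_organism(pair_models(h, m, lumen_medium = toy_lumen_diet()),
                       "microbe")
  pc <- close_organism(
    pair_models(h, m, lumen_medium = toy_lumen_diet(),
                coupling = coupling_spec()), "microbe")
  fu <- fva(pu, gamma = 1, reactions = c("H_T_fol_b", "H_R_glyc"))
  fc <- fva(pc, gamma = 1, reactions = c("H_T_fol_b", "H_R_glyc"))
  expect_equal(fc$vmin, fu$vmin, tolerance = 1e-5)
  expect_equal(fc$vmax, fu$vmax, tolerance = 1e-5)
})

test_that("tightening the coupling factor never widens organism spans", {
  h <- toy_host(); m <- toy_microbe()
  spans <- lapply(c(400, 40, 4), function(cc) {
    p <- pair_models(h, m, lumen_medium = toy_lumen_diet(),
                     coupling = coupling_spec(c_coupling = cc))
    fva(p, gamma = 0.9, reactions = c("M_T_ser", "M_T_glc", "M_R_scfa"))
  })
  for (k in 2:3) {
    expect_true(all(spans[[k]]$span <= spans[[k - 1]]$span + 1e-6))
  }
})
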