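test_that("GPR parsing and ordinal evaluation follow the min/max rules", {
  cats <- c(g1 = "high", g2 = "low", g3 = "high", g4 = NA)
  expect_identical(gpr_eval_category("g1 and g2", cats), "low")
  expect_identical(gpr_eval_category("g2 or g3", cats), "high")
  # unknown genes are skipped, not vetoing
  expect_identical(gpr_eval_category("g1 and g4", cats), "high")
  expect_identical(gpr_eval_category("g4", cats), NA_character_)
  expect_identical(gpr_eval_category("(g1 or g2) and g2", cats), "low")
  expect_setequal(gpr_genes("(g1 or g2) and (g3 and g4)"),
                  c("g1", "g2", "g3", "g4"))
  expect_error(gpr_parse("g1 and (g2"), "parenthes")
  expect_error(gpr_parse("g1 g2"), "trailing")
})

test_that("GPR evaluation agrees with exhaustive truth-assignment evaluation", {
  # oracle: evaluate over every completion of the NA genes; with the
  # skip-unknown rule the result must lie within the completion envelope
  rules <- c("g1 and g2", "g1 or (g2 and g3)", "(g1 or g2) and g3")
  lv <- c("low", "medium", "high")
  withr::with_seed(11, {
    for (rule in rules) {
      genes <- gpr_genes(rule)
      for (rep in 1:10) {
        cats <- stats::setNames(sample(c(lv, NA), length(genes), TRUE),
                                genes)
        got <- gpr_eval_category(rule, cats)
        known <- cats[!is.na(cats)]
        if (!length(known)) {
          expect_identical(got, NA_character_)
          next
        }
        # replacing every NA by each known value in turn must bracket got
        envelope <- vapply(lv, function(fill) {
          full <- cats; full[is.na(full)] <- fill
          gpr_eval_category(rule, full)
        }, character(1))
        expect_true(match(got, lv) >= min(match(envelope, lv)))
        expect_true(match(got, lv) <= max(match(envelope, lv)))
      }
    }
  })
})

test_that("expression mapping partitions reactions into evidence sets", {
  h <- toy_host()
  ev <- expression_evidence(c(HK1 = "high", PFK1 = "medium",
                              LDHA = "low", PDHA1 = "high"))
  rev <- map_expression_to_reactions(h, ev)
  get <- function(id) rev$evidence_set[rev$reaction_id == id]
  expect_identical(get("R_glyc"), "core_active")   # min(high, medium)
  expect_identical(get("R_ldh"), "core_inactive")
  expect_identical(get("R_pdh"), "core_active")
  expect_identical(get("R_shmt"), "uncategorized") # genes unmeasured
  expect_identical(get("R_biomass"), "uncategorized")
  # overrides force categories (literature-upregulated gene)
  rev2 <- map_expression_to_reactions(h, ev, overrides = c(LDHA = "high"))
  expect_identical(rev2$evidence_set[rev2$reaction_id == "R_ldh"],
                   "core_active")
})

test_that("iMAT attains the planted optimum with exact activity", {
  h <- toy_host()
  pe <- planted_expression(h)
  rev <- map_expression_to_reactions(h, pe$evidence)
  res <- imat_extract(h, rev, epsilon = 1)
  expect_equal(res$objective, pe$truth$imat_objective)
  act <- res$activity[match(pe$truth$imat_activity$reaction_id,
                            res$activity$reaction_id), ]
  expect_identical(act$state, pe$truth$imat_activity$state)
  # witness satisfies steady state and the activation threshold
  S <- stoichiometric_matrix(h, sparse = FALSE)
  expect_lt(max(abs(S %*% res$fluxes)), 1e-6)
  active <- act$reaction_id[startsWith(act$state, "active")]
  expect_true(all(abs(res$fluxes[active]) >= 1 - 1e-6))
})

test_that("iMAT equals exhaustive enumeration, including conflict instances", {
  # conflict: the only route feeding the core-active reaction runs
  # through the core-inactive one, so at most one term is satisfiable
  m <- metabolic_model(dplyr::bind_rows(
    rxn_row("EX_A", "A[c] ->", -10, 1000),
    rxn_row("R_low", "A[c] -> B[c]", 0, 1000),
    rxn_row("R_high", "B[c] -> C[c]", 0, 1000),
    rxn_row("EX_C", "C[c] ->", 0, 1000)),
    objective = c(EX_C = 1))
  rev <- list(core_active = "R_high", core_inactive = "R_low")
  res <- imat_extract(m, rev)
  bf <- imat_brute_force(m, rev)
  expect_equal(res$objective, 1L)
  expect_equal(bf$objective, 1L)
  # planted host fixture agrees with enumeration too
  h <- toy_host()
  pe <- planted_expression(h)
  rh <- map_expression_to_reactions(h, pe$evidence)
  expect_equal(imat_extract(h, rh)$objective,
               imat_brute_force(h, rh)$objective)
})

test_that("iMAT objective is monotone non-increasing in epsilon", {
  m <- metabolic_model(dplyr::bind_rows(
    rxn_row("EX_A", "A[c] ->", -10, 1000),
    rxn_row("R_cap", "A[c] -> B[c]", 0, 5),
    rxn_row("R_wide", "A[c] -> C[c]", 0, 1000),
    rxn_row("EX_B", "B[c] ->", 0, 1000),
    rxn_row("EX_C", "C[c] ->", 0, 1000)),
    objective = c(EX_B = 1))
  rev <- list(core_active = c("R_cap", "R_wide"),
              core_inactive = character(0))
  o1 <- imat_extract(m, rev, epsilon = 1)$objective
  o10 <- imat_extract(m, rev, epsilon = 10)$objective
  expect_equal(o1, 2L)
  expect_equal(o10, 1L)  # epsilon exceeds R_cap's upper bound of 5
  expect_equal(o10, imat_brute_force(m, rev, epsilon = 10)$objective)
  for (eps in c(0.5, 2, 6, 12)) {
    expect_lte(imat_extract(m, rev, epsilon = eps)$objective, o1)
  }
})

test_that("context-model building removes silenced reactions and repairs", {
  h <- toy_host()
  pe <- planted_expression(h)
  rev <- map_expression_to_reactions(h, pe$evidence)
  res <- imat_extract(h, rev)
  ctx <- build_context_model(h, res, repair = TRUE)
  expect_false("R_ldh" %in% ctx$model$reactions$id)
  expect_false("R_glydc" %in% ctx$model$reactions$id)
  # silencing the lactate branch kills its downstream transports
  expect_false("T_lac_b" %in% ctx$model$reactions$id)
  expect_false("EX_lac[b]" %in% ctx$model$reactions$id)
  expect_true("R_biomass" %in% ctx$model$reactions$id)
  expect_length(ctx$sanity$leaking_metabolites, 0)
  # repair = FALSE keeps blocked reactions but reports them
  ctx2 <- build_context_model(h, res, repair = FALSE)
  expect_true("T_lac_b" %in% ctx2$model$reactions$id)
  expect_true("T_lac_b" %in% ctx2$blocked)
  # growth is preserved by the context reduction here
  expect_equal(fba(ctx$model)$objective, fba(h)$objective,
               tolerance = 1e-6)
  expect_identical(tidy(res), res$activity)
  expect_equal(glance(res)$n_silenced, 2L)
})
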