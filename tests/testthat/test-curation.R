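test_that("quality-controlled addition registers, skips and rejects correctly", {
  m <- toy_microbe()
  out <- add_reactions_qc(m, ros_fixture())
  expect_equal(n_reactions(out$model), n_reactions(m) + 8)
  expect_equal(n_metabolites(out$model), n_metabolites(m) + 11)
  expect_length(out$added, 8)
  # re-adding identical content: skipped and logged, not an error
  out2 <- add_reactions_qc(out$model, ros_fixture())
  expect_length(out2$added, 0)
  expect_true(all(out2$log$action == "skip"))
  expect_true(isTRUE(model_equal(out$model, out2$model)))
  # id collision with different content is a hard error
  altered <- ros_fixture()
  altered$reactions$ub[1] <- 7
  expect_error(add_reactions_qc(out$model, altered), "collision")
  # unregistered metabolite named in the error
  bad <- reaction_set(rxn_row("R_x", "mystery[c] -> atp[c]", 0, 10))
  bad$new_metabolites <- bad$new_metabolites[0, ]
  expect_error(add_reactions_qc(m, bad), "mystery")
})

test_that("ROS expansion reports the blocked subset and matches the oracle", {
  m <- toy_microbe()
  exp <- expand_with_ros(m, ros_fixture())
  expect_setequal(exp$blocked, ros_reaction_ids())
  expect_setequal(exp$blocked,
                  find_blocked_reactions(exp$model,
                                         reactions = exp$added))
  # pre-existing reactions untouched by the expansion
  i <- match(m$reactions$id, exp$model$reactions$id)
  expect_equal(exp$model$reactions$lb[i], m$reactions$lb)
  expect_equal(exp$model$reactions$ub[i], m$reactions$ub)
})

test_that("auto-unblocking adds demands for products and sinks for reactants", {
  base <- metabolic_model(dplyr::bind_rows(
    rxn_row("EX_A", "A[c] ->", -10, 1000),
    rxn_row("EX_B", "B[c] ->", 0, 1000),
    rxn_row("R0", "A[c] -> B[c]", 0, 1000),
    rxn_row("R3", "A[c] -> D[c]", 0, 1000),   # orphan product
    rxn_row("R4", "E[c] -> B[c]", 0, 1000),   # orphan reactant
    rxn_row("R5", "F[c] -> G[c]", 0, 1000)),  # both orphaned
    objective = c(EX_B = 1))
  blocked <- find_blocked_reactions(base)
  expect_setequal(blocked, c("R3", "R4", "R5"))
  out <- unblock_reactions(base, blocked, mode = "auto")
  expect_length(out$still_blocked, 0)
  expect_true("DM_D[c]" %in% out$model$reactions$id)
  expect_true("SK_E[c]" %in% out$model$reactions$id)
  expect_true(all(c("SK_F[c]", "DM_G[c]") %in% out$model$reactions$id))
  acts <- out$log$action
  expect_equal(sum(acts == "add_demand"), 2)
  expect_equal(sum(acts == "add_sink"), 2)
  expect_true(all(out$log$reason[acts != "skip"] == "no literature evidence"))
  # every formerly blocked reaction now carries flux
  expect_length(find_blocked_reactions(out$model, reactions = blocked), 0)
  # replay reproduces the debugged model exactly
  expect_true(isTRUE(model_equal(replay_curation_log(base, out$log),
                                 out$model)))
})

test_that("literature-first unblocking consumes the supplied set before the fallback", {
  base <- metabolic_model(dplyr::bind_rows(
    rxn_row("EX_A", "A[c] ->", -10, 1000),
    rxn_row("EX_B", "B[c] ->", 0, 1000),
    rxn_row("R0", "A[c] -> B[c]", 0, 1000),
    rxn_row("R3", "A[c] -> D[c]", 0, 1000)),
    objective = c(EX_B = 1))
  lit <- reaction_set(rxn_row("R_Duse", "D[c] -> B[c]", 0, 1000),
                      provenance = "literature pathway")
  out <- unblock_reactions(base, "R3", mode = "literature_first",
                           rset = lit)
  expect_true("R_Duse" %in% out$model$reactions$id)
  expect_false(any(startsWith(out$model$reactions$id, "DM_")))
  expect_length(find_blocked_reactions(out$model, reactions = "R3"), 0)
})

test_that("curation log replay reproduces the full ROS debugging session", {
  m <- toy_microbe()
  exp <- expand_with_ros(m, ros_fixture())
  unb <- unblock_reactions(exp$model, exp$blocked, log = exp$log)
  expect_length(unb$still_blocked, 0)
  expect_length(find_blocked_reactions(unb$model,
                                       reactions = ros_reaction_ids()), 0)
  replayed <- replay_curation_log(m, unb$log)
  expect_true(isTRUE(model_equal(replayed, unb$model)))
  # the debugging protocol on this fixture: 6 demands and 2 sinks
  expect_equal(sum(unb$log$action == "add_demand"), 6)
  expect_equal(sum(unb$log$action == "add_sink"), 2)
})

test_that("apply_medium constrains listed exchanges and closes the rest", {
  m <- toy_microbe()
  med <- medium_spec(c("EX_glc[e]" = -4))
  m2 <- apply_medium(m, med)
  expect_equal(m2$reactions$lb[m2$reactions$id == "EX_glc[e]"], -4)
  expect_equal(m2$reactions$lb[m2$reactions$id == "EX_ser[e]"], 0)
  # idempotent
  expect_true(isTRUE(model_equal(apply_medium(m2, med), m2)))
  # close_others = FALSE leaves unlisted exchanges untouched
  m3 <- apply_medium(m, med, close_others = FALSE)
  expect_equal(m3$reactions$lb[m3$reactions$id == "EX_ser[e]"], -10)
  expect_error(apply_medium(m, medium_spec(c("EX_Z" = -1))), "EX_Z")
})

test_that("biomass editing removes and merges precursor terms", {
  m <- toy_host()
  out <- edit_biomass(m, remove = "nuc[c]", add = c("fol[c]" = -0.5))
  st <- out$model$reactions$stoichiometry[[
    match("R_biomass", out$model$reactions$id)]]
  expect_false("nuc[c]" %in% names(st))
  expect_equal(st[["fol[c]"]], -0.5)
  expect_error(edit_biomass(m, remove = "nonexistent[c]"),
               "not in biomass")
  # the edit drives the expected growth change: folate becomes limiting
  expect_equal(fba(out$model)$objective, 2, tolerance = 1e-6)
  # replay reproduces the edit
  expect_true(isTRUE(model_equal(replay_curation_log(m, out$log),
                                 out$model)))
})
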