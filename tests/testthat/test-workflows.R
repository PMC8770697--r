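test_that("oxidative-stress workflow recovers the planted truth end to end", {
  out <- run_ros_workflow(pipeline_config(seed = 1))
  pp <- perturbation_pair(toy_spec(seed = 1))
  expect_setequal(out$tables$affected$reaction_id,
                  pp$truth$affected$reaction_id)
  expect_length(out$still_blocked, 0)
  # the affected set is folate-enriched
  top <- out$tables$enrichment$subsystem[1]
  expect_identical(top, "Folate metabolism")
  expect_lt(out$tables$enrichment$p[1], 0.05)
  # min-norm deltas reported for the affected reactions
  expect_setequal(out$tables$minnorm_delta$reaction_id,
                  out$tables$affected$reaction_id)
})

test_that("workflow reruns are byte-identical", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_ros_workflow(pipeline_config(seed = 1, out_dir = d1))
  run_ros_workflow(pipeline_config(seed = 1, out_dir = d2))
  for (f in list.files(d1)) {
    if (f == "resolved_config.json") next # differs only in out_dir path
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
  expect_true(file.exists(file.path(d1, "resolved_config.json")))
})

test_that("host workflow contrasts the contexts and computes the percent increase", {
  hw <- run_host_workflow(pipeline_config(seed = 1))
  bio <- hw$tables$biomass
  z_colon <- bio$biomass_flux[bio$model == "colon"]
  z_crc <- bio$biomass_flux[bio$model == "crc"]
  expect_gt(z_crc, z_colon)
  expect_equal(bio$percent_increase[bio$model == "crc"],
               (z_crc - z_colon) / z_crc * 100, tolerance = 1e-9)
  # disease context keeps lactate secretion, healthy loses it
  expect_false("EX_lac[b]" %in% hw$colon$model$reactions$id)
  expect_true("EX_lac[b]" %in% hw$crc$model$reactions$id)
  expect_true(all(hw$tables$secretome$change %in%
                    c("increased", "same", "decreased")))
})

test_that("percent increase arithmetic matches its definition", {
  expect_equal(percent_biomass_increase(1, 4), 75)
  expect_equal(percent_biomass_increase(0.5, 0.5), 0)
})

test_that("empty evidence leaves every reaction uncategorized and completes", {
  h <- toy_host()
  ev <- expression_evidence(stats::setNames(character(0), character(0)))
  rev <- map_expression_to_reactions(h, ev)
  expect_true(all(rev$evidence_set == "uncategorized"))
  expect_warning(res <- imat_extract(h, rev), "no evidence")
  expect_equal(res$objective, 0L)
  ctx <- build_context_model(h, res)
  # nothing silenced; only reactions already blocked in the base model
  # (the idle nucleotide importer on the default diet) are pruned
  expect_length(ctx$removed, 0)
  expect_equal(n_reactions(ctx$model),
               n_reactions(h) - length(find_blocked_reactions(h)))
})

test_that("community workflow flags the obligate interaction and emits the matrix", {
  cfg <- pipeline_config(seed = 1)
  hw <- run_host_workflow(cfg)
  rw <- run_ros_workflow(cfg)
  cw <- run_community_workflow(cfg, host_bundle = hw, ros_bundle = rw)
  bio <- cw$tables$biomass
  expect_equal(nrow(bio), 4)
  expect_true(all(is.finite(bio$host_biomass_flux)))
  # one row per shared body-fluid exchange in each comparison
  mt <- cw$tables$secretome_matrix
  expect_true(all(table(mt$comparison, mt$exchange_id) <= 1))
  expect_true(all(mt$change %in% c("increased", "same", "decreased")))
  # coupling recorded in provenance
  expect_true(cw$provenance$coupling_enabled)
  # interaction table covers lumen transports of both organisms
  expect_true(any(grepl("^H_IEX_", cw$tables$interaction$reaction_id)))
  expect_true(any(grepl("^M_IEX_", cw$tables$interaction$reaction_id)))
})
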