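#' Configuration for the end-to-end workflows
#'
#' Collects every tunable the workflows consume: input paths (all
#' optional — when absent the deterministic toy generators stand in for
#' the study models), the FVA optimality fraction, the iMAT activation
#' threshold, the FSr classification band, tolerances, the coupling
#' specification for community models, an output directory and the seed.
#' The resolved configuration is stored on every result bundle (and
#' written beside the tables) so any run can be reproduced exactly.
#'
#' @param microbe_model,host_model,ros_set,medium,lumen_diet Optional
#'   paths (model dialects of [read_model()]; [read_reaction_set()];
#'   [read_medium()]).
#' @param gamma FVA optimality fraction.
#' @param epsilon iMAT activation flux.
#' @param fsr_low,fsr_high FSr classification thresholds.
#' @param tol Span/blocked tolerance.
#' @param rel_tol Secretome same-flux tolerance.
#' @param coupling `NULL` or a [coupling_spec()].
#' @param out_dir Optional directory for the TSV bundle.
#' @param seed Integer seed, forwarded to the toy generators.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(microbe_model = NULL, host_model = NULL,
                            ros_set = NULL, medium = NULL,
                            lumen_diet = NULL, gamma = 1.0, epsilon = 1.0,
                            fsr_low = 0.8, fsr_high = 2.0, tol = 1e-6,
                            rel_tol = 0.05, coupling = coupling_spec(),
                            out_dir = NULL, seed = 1L) {
  structure(list(microbe_model = microbe_model, host_model = host_model,
                 ros_set = ros_set, medium = medium,
                 lumen_diet = lumen_diet, gamma = gamma,
                 epsilon = epsilon, fsr_low = fsr_low,
                 fsr_high = fsr_high, tol = tol, rel_tol = rel_tol,
                 coupling = coupling, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.resolve_microbe <- function(config) {
  if (!is.null(config$microbe_model)) read_model(config$microbe_model)
  else toy_microbe(toy_spec(seed = config$seed))
}

.resolve_host <- function(config, ...) {
  if (!is.null(config$host_model)) read_model(config$host_model)
  else toy_host(toy_spec(seed = config$seed, ...))
}

.write_bundle <- function(bundle, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle$tables)) {
    readr::write_tsv(bundle$tables[[nm]],
                     file.path(out_dir, paste0(nm, ".tsv")))
  }
  cfg <- bundle$config
  cfg$coupling <- if (is.null(cfg$coupling)) NULL else
    unclass(cfg$coupling)
  jsonlite::write_json(c(unclass(cfg),
                         list(provenance = bundle$provenance)),
                       file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}

.flatten_log <- function(log) {
  tibble::tibble(step = log$step, action = log$action,
                 target = log$target, reason = log$reason,
                 citation = log$citation)
}

.provenance <- function(config) {
  list(package = "fluxspan",
       version = as.character(utils::packageVersion("fluxspan")),
       gamma = config$gamma, epsilon = config$epsilon,
       fsr_thresholds = c(config$fsr_low, config$fsr_high),
       tol = config$tol, seed = config$seed,
       coupling_enabled = !is.null(config$coupling))
}

#' Percent biomass increase of a disease model over its healthy reference
#'
#' `(z_disease - z_healthy) / z_disease * 100` — the headline growth
#' comparison between a transformed and a healthy tissue model.
#'
#' @param z_healthy,z_disease Biomass fluxes (mmol/g-DW/h).
#' @return Percent increase.
#' @export
percent_biomass_increase <- function(z_healthy, z_disease) {
  (z_disease - z_healthy) / z_disease * 100
}

#' Run the microbe oxidative-stress workflow
#'
#' End to end: expand the microbe model with the reactive-species set,
#' auto-debug the blocked additions with demand/sink reactions, constrain
#' to the medium when one is supplied, run FVA on both the original and
#' the expanded model, compute and classify flux span ratios, attribute
#' minimum-norm flux shifts to subsystems for the affected reactions, and
#' test the affected set for subsystem enrichment.
#'
#' @param config A [pipeline_config()].
#' @return A `ros_workflow` bundle: `model_a`, `model_b`, `log`,
#'   `still_blocked`, and `tables` (`fsr`, `affected`, `minnorm_delta`,
#'   `enrichment`, `curation_log`), plus the resolved `config` and
#'   `provenance`. Written as TSVs under `config$out_dir` when set.
#' @export
run_ros_workflow <- function(config = pipeline_config()) {
  model_a <- .resolve_microbe(config)
  ros <- if (!is.null(config$ros_set)) read_reaction_set(config$ros_set)
         else ros_fixture()
  if (!is.null(config$medium)) {
    model_a <- apply_medium(model_a, read_medium(config$medium))
  }
  exp <- expand_with_ros(model_a, ros)
  unb <- unblock_reactions(exp$model, exp$blocked, mode = "auto",
                           log = exp$log)
  model_b <- unb$model
  fva_a <- fva(model_a, gamma = config$gamma)
  fva_b <- fva(model_b, gamma = config$gamma)
  fsr <- classify_fsr(flux_span_ratio(fva_a, fva_b, tol = config$tol),
                      low = config$fsr_low, high = config$fsr_high)
  affected <- affected_reactions(fsr)
  mn <- minnorm_delta(model_a, model_b,
                      reactions = if (nrow(affected))
                        affected$reaction_id else NULL)
  enr <- flux_enrichment(affected$reaction_id, model_a)
  bundle <- list(model_a = model_a, model_b = model_b, log = unb$log,
                 still_blocked = unb$still_blocked,
                 tables = list(fsr = tibble::as_tibble(fsr),
                               affected = tibble::as_tibble(affected),
                               minnorm_delta = mn,
                               enrichment = tibble::as_tibble(enr),
                               curation_log = .flatten_log(unb$log)),
                 config = config, provenance = .provenance(config))
  class(bundle) <- "ros_workflow"
  .write_bundle(bundle, config$out_dir)
  bundle
}

.colon_evidence <- function(host) {
  pe <- planted_expression(host,
                           active_set = c("R_glyc", "R_pdh", "R_shmt"),
                           low_set = "R_ldh", seed = 1L)
  pe$evidence
}

.crc_evidence <- function(host) {
  pe <- planted_expression(host,
                           active_set = c("R_glyc", "R_pdh", "R_shmt",
                                          "R_nucsyn", "R_ldh"),
                           low_set = "R_glydc", seed = 1L)
  pe$evidence
}

.build_context <- function(model, evidence, config) {
  rev <- map_expression_to_reactions(model, evidence)
  res <- imat_extract(model, rev, epsilon = config$epsilon)
  ctx <- build_context_model(model, res, repair = TRUE)
  list(model = ctx$model, imat = res, log = ctx$log, sanity = ctx$sanity)
}

#' Run the host context-specific modeling workflow
#'
#' Builds the healthy-tissue and disease-tissue context models from the
#' generic host network and categorical expression evidence: for the
#' healthy model the biomass is first edited to drop the replicating
#' (nucleotide) precursor and depend more strongly on the cellular
#' folate pool; each evidence set is then integrated by iMAT, the
#' silenced reactions removed and the network repaired; finally the two
#' context biomass optima are compared (with the percent increase of the
#' disease model), FSr is computed between the contexts and the
#' body-fluid secretomes are profiled and compared.
#'
#' @param config A [pipeline_config()].
#' @param colon_evidence,crc_evidence Optional [expression_evidence]
#'   overrides; defaults emulate a healthy-colon (lactate dehydrogenase
#'   low) versus disease (lactate dehydrogenase and nucleotide synthesis
#'   high) contrast on the toy host.
#' @return A `host_workflow` bundle with the two context models, their
#'   iMAT results, `biomass` table (fluxes and percent increase), `fsr`
#'   and `secretome` tables.
#' @export
run_host_workflow <- function(config = pipeline_config(),
                              colon_evidence = NULL, crc_evidence = NULL) {
  host <- .resolve_host(config)
  colon_evidence <- colon_evidence %||% .colon_evidence(host)
  crc_evidence <- crc_evidence %||% .crc_evidence(host)
  colon_base <- edit_biomass(host, remove = "nuc[c]",
                             add = c("fol[c]" = -0.5))$model
  colon <- .build_context(colon_base, colon_evidence, config)
  crc <- .build_context(host, crc_evidence, config)
  z_colon <- fba(colon$model)$objective
  z_crc <- fba(crc$model)$objective
  biomass <- tibble::tibble(
    model = c("colon", "crc"),
    biomass_flux = c(z_colon, z_crc),
    percent_increase = c(NA_real_,
                         percent_biomass_increase(z_colon, z_crc)))
  fva_colon <- fva(colon$model, gamma = config$gamma)
  fva_crc <- fva(crc$model, gamma = config$gamma)
  fsr <- classify_fsr(flux_span_ratio(fva_colon, fva_crc,
                                      tol = config$tol),
                      low = config$fsr_low, high = config$fsr_high)
  sec_colon <- secretome_profile(colon$model, compartment_filter = "b",
                                 gamma = config$gamma,
                                 condition = "colon")
  sec_crc <- secretome_profile(crc$model, compartment_filter = "b",
                               gamma = config$gamma, condition = "crc")
  sec <- compare_secretomes(sec_colon, sec_crc, rel_tol = config$rel_tol)
  bundle <- list(colon = colon, crc = crc,
                 tables = list(biomass = biomass,
                               fsr = tibble::as_tibble(fsr),
                               affected = tibble::as_tibble(
                                 affected_reactions(fsr)),
                               secretome = sec),
                 config = config, provenance = .provenance(config))
  class(bundle) <- "host_workflow"
  .write_bundle(bundle, config$out_dir)
  bundle
}

#' Run the host-microbe community workflow
#'
#' Pairs the healthy-colon and disease context models (from
#' [run_host_workflow()]) with the reactive-species-expanded microbe
#' (from [run_ros_workflow()]) through a shared lumen on a common diet,
#' applies coupling constraints when configured, and contrasts the four
#' conditions: host biomass with and without the microbe, flux
#' variability of the interaction surface (lumen transports and
#' community exchanges), and the body-fluid secretome classification
#' matrix across the paired conditions.
#'
#' @param config A [pipeline_config()].
#' @param host_bundle,ros_bundle Optional precomputed [run_host_workflow()]
#'   / [run_ros_workflow()] bundles to avoid recomputation.
#' @return A `community_workflow` bundle: the paired models, `tables`
#'   (`biomass`, `interaction`, `secretome_matrix`).
#' @export
run_community_workflow <- function(config = pipeline_config(),
                                   host_bundle = NULL, ros_bundle = NULL) {
  host_bundle <- host_bundle %||% run_host_workflow(
    pipeline_config(seed = config$seed, gamma = config$gamma,
                    epsilon = config$epsilon, coupling = config$coupling))
  ros_bundle <- ros_bundle %||% run_ros_workflow(
    pipeline_config(seed = config$seed, gamma = config$gamma,
                    coupling = config$coupling))
  microbe <- ros_bundle$model_b
  diet <- if (!is.null(config$lumen_diet)) read_medium(config$lumen_diet)
          else toy_lumen_diet()
  pairs <- list(
    colon_microbe = pair_models(host_bundle$colon$model, microbe,
                                lumen_medium = diet,
                                coupling = config$coupling),
    crc_microbe = pair_models(host_bundle$crc$model, microbe,
                              lumen_medium = diet,
                              coupling = config$coupling))
  host_alone <- host_bundle$tables$biomass$biomass_flux
  z_paired <- vapply(pairs, function(p) fba(p)$objective, numeric(1))
  biomass <- tibble::tibble(
    condition = c("colon", "crc", "colon_microbe", "crc_microbe"),
    host_biomass_flux = c(host_alone, unname(z_paired)))
  inter <- dplyr::bind_rows(lapply(pairs, function(p) {
    tibble::as_tibble(interaction_fva(p, gamma = config$gamma))
  }), .id = "condition")
  sec <- lapply(pairs, function(p) {
    secretome_profile(p, compartment_filter = "b", gamma = config$gamma)
  })
  sec_host <- list(
    colon = secretome_profile(host_bundle$colon$model,
                              compartment_filter = "b",
                              gamma = config$gamma),
    crc = secretome_profile(host_bundle$crc$model,
                            compartment_filter = "b",
                            gamma = config$gamma))
  strip_prefix <- function(prof) {
    prof$exchange_id <- sub("^H_", "", prof$exchange_id)
    prof
  }
  comparisons <- list(
    colon_vs_crc = compare_secretomes(sec_host$colon, sec_host$crc,
                                      rel_tol = config$rel_tol),
    colon_microbe_vs_crc_microbe = compare_secretomes(
      strip_prefix(sec$colon_microbe), strip_prefix(sec$crc_microbe),
      rel_tol = config$rel_tol),
    colon_vs_colon_microbe = compare_secretomes(
      sec_host$colon, strip_prefix(sec$colon_microbe),
      rel_tol = config$rel_tol),
    crc_vs_crc_microbe = compare_secretomes(
      sec_host$crc, strip_prefix(sec$crc_microbe),
      rel_tol = config$rel_tol))
  matrix_tbl <- dplyr::bind_rows(comparisons, .id = "comparison")
  bundle <- list(pairs = pairs,
                 tables = list(biomass = biomass, interaction = inter,
                               secretome_matrix = matrix_tbl),
                 comparisons = comparisons,
                 config = config, provenance = .provenance(config))
  class(bundle) <- "community_workflow"
  .write_bundle(bundle, config$out_dir)
  bundle
}
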