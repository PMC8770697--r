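#' Specification for the deterministic toy networks
#'
#' The toy generators are hand-designed templates, not random graphs:
#' every flux optimum and span used in tests is derivable by hand, and
#' generation is a pure function of the spec (the seed only permutes
#' cosmetic aspects such as evidence row order, never network content).
#'
#' @param seed Integer seed for the cosmetic aspects.
#' @param n_branches Number of accessory amino-acid catabolism branches on
#'   the microbe (uptake, transport, degradation to acetyl-CoA each).
#' @param include_folate_branch Include the folate cycle (dihydrofolate
#'   synthesis and reduction, serine hydroxymethyltransferase,
#'   methylene-THF dehydrogenase/cyclohydrolase, folate release).
#' @param include_ros_targets Include the nucleotide branch whose product
#'   is one of the reactive-species targets.
#' @param biomass_precursors Optional named numeric overriding the biomass
#'   stoichiometry (negative coefficients for precursors).
#' @param host_nuc_synthesis Give the host its own nucleotide synthesis;
#'   set `FALSE` to build the cross-feeding variant that strictly depends
#'   on microbe-secreted nucleotide.
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(seed = 1L, n_branches = 2L,
                     include_folate_branch = TRUE,
                     include_ros_targets = TRUE,
                     biomass_precursors = NULL,
                     host_nuc_synthesis = TRUE) {
  structure(list(seed = as.integer(seed), n_branches = as.integer(n_branches),
                 include_folate_branch = include_folate_branch,
                 include_ros_targets = include_ros_targets,
                 biomass_precursors = biomass_precursors,
                 host_nuc_synthesis = host_nuc_synthesis),
            class = "toy_spec")
}

.rxn <- function(id, formula, lb, ub, subsystem, gpr = "",
                 kind = NA_character_) {
  p <- parse_reaction_formula(formula)
  tibble::tibble(id = id, name = id, stoichiometry = list(p$stoichiometry),
                 lb = lb, ub = ub, subsystem = subsystem, gpr = gpr,
                 kind = kind)
}

#' Toy gut-microbe metabolic model
#'
#' A ~30-reaction facultative-anaerobe stand-in: glucose and serine
#' uptake, a glycolysis-like backbone producing ATP, pyruvate oxidation
#' to acetyl-CoA, short-chain-fatty-acid (butyrate-like) secretion, a
#' folate cycle with a capacity-limited folate exporter, folate-dependent
#' nucleotide synthesis with a nucleotide exporter, and a biomass
#' reaction drawing ATP, glycine, acetyl-CoA, nucleotide and folate. On
#' its default rich medium the optimal biomass flux is 20/3 (glucose/ATP
#' limited). The serine, glycine, nucleotide and folate pools are the
#' species the reactive-species fixture attacks.
#'
#' @param spec A [toy_spec()].
#' @return A validated, feasible `metabolic_model`.
#' @export
toy_microbe <- function(spec = toy_spec()) {
  rx <- dplyr::bind_rows(
    .rxn("EX_glc[e]", "glc[e] ->", -10, 1000, "Exchange"),
    .rxn("EX_ser[e]", "ser[e] ->", -10, 1000, "Exchange"),
    .rxn("EX_but[e]", "but[e] ->", 0, 1000, "Exchange"),
    .rxn("EX_co2[e]", "co2[e] ->", 0, 1000, "Exchange"),
    .rxn("EX_for[e]", "for[e] ->", 0, 1000, "Exchange"),
    .rxn("T_glc", "glc[e] -> glc[c]", 0, 1000, "Transport"),
    .rxn("T_ser", "ser[e] -> ser[c]", 0, 1000, "Transport"),
    .rxn("T_but", "but[c] -> but[e]", 0, 1000, "Transport"),
    .rxn("T_co2", "co2[c] -> co2[e]", 0, 1000, "Transport"),
    .rxn("T_for", "for[c] -> for[e]", 0, 1000, "Transport"),
    .rxn("R_glyc", "glc[c] -> 2 pyr[c] + 2 atp[c]", 0, 1000, "Glycolysis"),
    .rxn("R_pdh", "pyr[c] -> accoa[c] + co2[c]", 0, 1000,
         "Pyruvate metabolism"),
    .rxn("R_scfa", "2 accoa[c] -> but[c]", 0, 1000, "SCFA metabolism"),
    .rxn("R_gly2accoa", "gly[c] -> accoa[c]", 0, 1000,
         "Amino acid metabolism"))
  for (i in seq_len(spec$n_branches)) {
    aa <- paste0("aa", i)
    rx <- dplyr::bind_rows(
      rx,
      .rxn(paste0("EX_", aa, "[e]"), paste0(aa, "[e] ->"), -5, 1000,
           "Exchange"),
      .rxn(paste0("T_", aa), paste0(aa, "[e] -> ", aa, "[c]"), 0, 1000,
           "Transport"),
      .rxn(paste0("R_", aa, "_cat"), paste0(aa, "[c] -> accoa[c]"),
           0, 1000, "Amino acid metabolism"))
  }
  if (spec$include_folate_branch) {
    rx <- dplyr::bind_rows(
      rx,
      .rxn("R_dhfsyn", "ser[c] -> dhf[c]", 0, 1000, "Folate metabolism"),
      .rxn("R_dhfr", "dhf[c] -> thf[c]", 0, 1000, "Folate metabolism"),
      .rxn("R_shmt", "ser[c] + thf[c] -> gly[c] + mlthf[c]", 0, 1000,
           "Folate metabolism"),
      .rxn("R_mthfd", "mlthf[c] -> methf[c]", 0, 1000,
           "Folate metabolism"),
      .rxn("R_ftcl", "methf[c] -> for[c] + thf[c]", 0, 1000,
           "Folate metabolism"),
      .rxn("R_folrel", "thf[c] -> fol[c]", 0, 1000, "Folate metabolism"),
      .rxn("T_fol", "fol[c] -> fol[e]", 0, 0.5, "Transport"),
      .rxn("EX_fol[e]", "fol[e] ->", 0, 1000, "Exchange"))
  }
  if (spec$include_ros_targets) {
    rx <- dplyr::bind_rows(
      rx,
      .rxn("R_nucsyn", "pyr[c] + atp[c] + mlthf[c] -> nuc[c] + thf[c]",
           0, 1000, "Nucleotide metabolism"),
      .rxn("T_nuc_sec", "nuc[c] -> nuc[e]", 0, 1000, "Transport"),
      .rxn("EX_nuc[e]", "nuc[e] ->", 0, 1000, "Exchange"))
  }
  bm <- spec$biomass_precursors %||% c(
    "atp[c]" = -2, "gly[c]" = -1, "accoa[c]" = -1,
    if (spec$include_ros_targets) c("nuc[c]" = -1),
    if (spec$include_folate_branch) c("fol[c]" = -0.1))
  rx <- dplyr::bind_rows(
    rx,
    tibble::tibble(id = "R_biomass", name = "microbial growth",
                   stoichiometry = list(bm), lb = 0, ub = 1000,
                   subsystem = "Biomass", gpr = "", kind = "biomass"))
  metabolic_model(rx, annotations = list(organism = "toy gut microbe",
                                         seed = spec$seed))
}

#' Toy host (colonocyte-like) metabolic model
#'
#' The epithelial counterpart of [toy_microbe()]: apical uptake of
#' glucose, serine, folate and (optionally) nucleotide from the `[e]`
#' compartment, a folate cycle fed by dietary folate, lactate and acetate
#' overflow secreted to a basolateral body-fluid compartment `[b]`
#' together with surplus folate, and a richer biomass. Every internal
#' reaction carries a parseable GPR so the model exercises
#' expression-driven context extraction; on the default DMEM-like diet
#' the optimal biomass flux is 5.
#'
#' @param spec A [toy_spec()]; `host_nuc_synthesis = FALSE` removes the
#'   host's own nucleotide synthesis, making growth strictly dependent on
#'   an external nucleotide source.
#' @return A validated `metabolic_model` with compartments `c`, `e`, `b`.
#' @export
toy_host <- function(spec = toy_spec()) {
  rx <- dplyr::bind_rows(
    .rxn("EX_glc[e]", "glc[e] ->", -10, 1000, "Exchange"),
    .rxn("EX_ser[e]", "ser[e] ->", -10, 1000, "Exchange"),
    .rxn("EX_fol[e]", "fol[e] ->", -1, 1000, "Exchange"),
    .rxn("EX_nuc[e]", "nuc[e] ->", 0, 1000, "Exchange"),
    .rxn("EX_co2[e]", "co2[e] ->", 0, 1000, "Exchange"),
    .rxn("EX_for[e]", "for[e] ->", 0, 1000, "Exchange"),
    .rxn("EX_lac[b]", "lac[b] ->", 0, 1000, "Exchange, body fluid"),
    .rxn("EX_ac[b]", "ac[b] ->", 0, 1000, "Exchange, body fluid"),
    .rxn("EX_fol[b]", "fol[b] ->", 0, 1000, "Exchange, body fluid"),
    .rxn("T_glc", "glc[e] -> glc[c]", 0, 1000, "Transport", "SLC2A1"),
    .rxn("T_ser", "ser[e] -> ser[c]", 0, 1000, "Transport", "SLC1A4"),
    .rxn("T_fol_up", "fol[e] -> fol[c]", 0, 1000, "Transport", "SLC19A1"),
    .rxn("T_nuc_up", "nuc[e] -> nuc[c]", 0, 1000, "Transport", "SLC29A1"),
    .rxn("T_co2", "co2[c] -> co2[e]", 0, 1000, "Transport"),
    .rxn("T_for", "for[c] -> for[e]", 0, 1000, "Transport"),
    .rxn("T_lac_b", "lac[c] -> lac[b]", 0, 1000, "Transport, body fluid",
         "SLC16A1"),
    .rxn("T_ac_b", "ac[c] -> ac[b]", 0, 1000, "Transport, body fluid",
         "SLC16A3"),
    .rxn("T_fol_b", "fol[c] -> fol[b]", 0, 1000, "Transport, body fluid",
         "SLC46A1"),
    .rxn("R_glyc", "glc[c] -> 2 pyr[c] + 2 atp[c]", 0, 1000, "Glycolysis",
         "HK1 and PFK1"),
    .rxn("R_ldh", "pyr[c] -> lac[c]", 0, 1000, "Glycolysis", "LDHA"),
    .rxn("R_pdh", "pyr[c] -> accoa[c] + co2[c]", 0, 1000,
         "Pyruvate metabolism", "PDHA1"),
    .rxn("R_acs", "accoa[c] -> ac[c]", 0, 1000, "Pyruvate metabolism",
         "ACOT12"),
    .rxn("R_glydc", "gly[c] -> co2[c]", 0, 1000, "Amino acid metabolism",
         "GLDC"))
  if (spec$include_folate_branch) {
    rx <- dplyr::bind_rows(
      rx,
      .rxn("R_dhfr", "fol[c] -> thf[c]", 0, 1000, "Folate metabolism",
           "DHFR"),
      .rxn("R_shmt", "ser[c] + thf[c] -> gly[c] + mlthf[c]", 0, 1000,
           "Folate metabolism", "SHMT1 or SHMT2"),
      .rxn("R_mthfd", "mlthf[c] -> methf[c]", 0, 1000, "Folate metabolism",
           "MTHFD1"),
      .rxn("R_ftcl", "methf[c] -> for[c] + thf[c]", 0, 1000,
           "Folate metabolism", "ATIC"))
  }
  if (spec$host_nuc_synthesis) {
    rx <- dplyr::bind_rows(
      rx,
      .rxn("R_nucsyn", "pyr[c] + atp[c] + mlthf[c] -> nuc[c] + thf[c]",
           0, 1000, "Nucleotide metabolism", "TYMS"))
  }
  bm <- spec$biomass_precursors %||% c(
    "atp[c]" = -3, "gly[c]" = -1, "accoa[c]" = -1, "nuc[c]" = -1,
    "fol[c]" = -0.05)
  rx <- dplyr::bind_rows(
    rx,
    tibble::tibble(id = "R_biomass", name = "host growth",
                   stoichiometry = list(bm), lb = 0, ub = 1000,
                   subsystem = "Biomass", gpr = "", kind = "biomass"))
  metabolic_model(rx, annotations = list(organism = "toy host colonocyte",
                                         seed = spec$seed))
}

#' Curated reactive-species reaction set
#'
#' A fixed eight-reaction, eleven-metabolite set of reactive
#' oxygen/nitrogen species chemistry: superoxide dismutation, a
#' Fenton-style hydroxyl-radical source, peroxynitrite formation from
#' superoxide and nitric oxide, and oxidative/nitrosative damage to the
#' serine, glycine, nucleotide and folate pools. Superoxide and nitric
#' oxide have no producer and several damage products have no consumer —
#' deliberately, so that grafting the set onto a model exercises the full
#' blocked-reaction debugging protocol (sinks for the radical sources,
#' demands for the damage products).
#'
#' @return A [reaction_set()] with 8 reactions and 11 new metabolites.
#' @export
ros_fixture <- function() {
  rx <- dplyr::bind_rows(
    .rxn("R_ros_sod", "2 o2s[c] -> h2o2[c] + o2[c]", 0, 1000,
         "ROS detoxification"),
    .rxn("R_ros_fenton", "h2o2[c] -> 2 oh1[c]", 0, 1000,
         "ROS detoxification"),
    .rxn("R_ros_onoo", "o2s[c] + no[c] -> onoo[c]", 0, 1000,
         "ROS detoxification"),
    .rxn("R_ros_serox", "ser[c] + oh1[c] -> ser_ox[c]", 0, 1000,
         "Oxidative damage"),
    .rxn("R_ros_glyox", "gly[c] + oh1[c] -> gly_ox[c]", 0, 1000,
         "Oxidative damage"),
    .rxn("R_ros_nucox", "nuc[c] + onoo[c] -> nuc_ox[c]", 0, 1000,
         "Oxidative damage"),
    .rxn("R_ros_folox", "fol[c] + oh1[c] -> fol_ox[c]", 0, 1000,
         "Oxidative damage"),
    .rxn("R_ros_serno", "ser[c] + no[c] -> ser_no[c]", 0, 1000,
         "Oxidative damage"))
  mets <- tibble::tibble(
    id = c("o2s[c]", "h2o2[c]", "o2[c]", "oh1[c]", "no[c]", "onoo[c]",
           "ser_ox[c]", "gly_ox[c]", "nuc_ox[c]", "fol_ox[c]",
           "ser_no[c]"),
    name = c("superoxide", "hydrogen peroxide", "oxygen",
             "hydroxyl radical", "nitric oxide", "peroxynitrite",
             "oxidised serine", "oxidised glycine", "oxidised nucleotide",
             "oxidised folate", "nitrosylated serine"),
    compartment = "c",
    formula = NA_character_,
    charge = c(-1L, 0L, 0L, 0L, -1L, -1L, 0L, 0L, 0L, 0L, 0L))
  reaction_set(rx, mets,
               provenance = "curated reactive-species chemistry (synthetic stand-in)")
}

#' Planted categorical expression evidence with known iMAT truth
#'
#' Marks the genes of a designated feasible active subnetwork as `high`,
#' the genes of a disjoint silenceable set as `low`, and everything else
#' as unmeasured (`NA`); the returned truth records the iMAT optimum this
#' construction guarantees (every evidence term satisfiable
#' simultaneously) and the expected activity states. The seed only
#' permutes the row order of the evidence table.
#'
#' @param model A `metabolic_model` with GPRs (normally [toy_host()]).
#' @param active_set Reaction ids that must be active at `epsilon`;
#'   defaults to the host's glycolysis/pyruvate/folate/nucleotide chain.
#' @param low_set Reaction ids plantable as inactive; defaults to the
#'   host's lactate and glycine overflow reactions.
#' @param seed Integer; cosmetic shuffling only.
#' @return A list with `evidence` ([expression_evidence]) and `truth`
#'   (a `perturbation_truth` with `imat_objective` and `imat_activity`).
#' @export
planted_expression <- function(model,
                               active_set = c("R_glyc", "R_pdh", "R_shmt",
                                              "R_nucsyn"),
                               low_set = c("R_ldh", "R_glydc"),
                               seed = 1L) {
  stopifnot(all(c(active_set, low_set) %in% model$reactions$id),
            !length(intersect(active_set, low_set)))
  gene_cat <- function(ids, cat) {
    genes <- unique(unlist(lapply(
      model$reactions$gpr[.rxn_index(model, ids)], gpr_genes)))
    stats::setNames(rep(cat, length(genes)), genes)
  }
  hi <- gene_cat(active_set, "high")
  lo <- gene_cat(low_set, "low")
  if (length(intersect(names(hi), names(lo)))) {
    stop("active and low sets share genes; pick disjoint reactions")
  }
  all_genes <- unique(unlist(lapply(model$reactions$gpr[
    nzchar(model$reactions$gpr)], gpr_genes)))
  rest <- setdiff(all_genes, c(names(hi), names(lo)))
  cats <- c(hi, lo, stats::setNames(rep(NA_character_, length(rest)), rest))
  ord <- withr::with_seed(seed, sample.int(length(cats)))
  ev <- expression_evidence(cats[ord], source = "planted")
  truth <- structure(
    list(affected = tibble::tibble(reaction_id = character(0),
                                   class = character(0)),
         imat_objective = length(active_set) + length(low_set),
         imat_activity = tibble::tibble(
           reaction_id = c(active_set, low_set),
           state = c(rep("active_fwd", length(active_set)),
                     rep("silenced", length(low_set))))),
    class = "perturbation_truth")
  list(evidence = ev, truth = truth)
}

#' Reference/perturbed model pair with known FSr ground truth
#'
#' Builds the study design in miniature: condition A is the toy microbe
#' on its rich medium; condition B is the same model expanded with the
#' [ros_fixture()] and auto-debugged ([unblock_reactions()]), which adds
#' the demand reactions for the oxidative damage products. The demand for
#' oxidised folate opens a drain on the folate pool that provably widens
#' the flux spans of the folate-branch reactions (`R_dhfsyn`, `R_dhfr`,
#' `R_folrel`) from 0.5 to 8/3 flux units at full optimality while every
#' other shared span is unchanged, so the planted truth is exactly those
#' three reactions with class `increased_in_b` (FSr = 0.1875). With
#' `include_demand = FALSE` the folate-oxidation reaction (and hence its
#' demand) is omitted from the expansion and no shared reaction changes
#' span — the negative control.
#'
#' @param spec A [toy_spec()].
#' @param include_demand Include the folate-oxidation route and its
#'   debugging demand.
#' @return A list with `model_a`, `model_b`, `log` (the curation log of
#'   the expansion) and `truth` (a `perturbation_truth` whose `affected`
#'   table lists the planted reaction classes).
#' @export
perturbation_pair <- function(spec = toy_spec(), include_demand = TRUE) {
  stopifnot(spec$include_folate_branch, spec$include_ros_targets)
  model_a <- toy_microbe(spec)
  rs <- ros_fixture()
  if (!include_demand) {
    keep <- rs$reactions$id != "R_ros_folox"
    rs$reactions <- rs$reactions[keep, ]
    rs$provenance <- rs$provenance[keep]
    rs$new_metabolites <-
      rs$new_metabolites[rs$new_metabolites$id != "fol_ox[c]", ]
  }
  exp <- expand_with_ros(model_a, rs)
  unb <- unblock_reactions(exp$model, exp$blocked, mode = "auto",
                           log = exp$log)
  affected <- if (include_demand) {
    tibble::tibble(reaction_id = c("R_dhfr", "R_dhfsyn", "R_folrel"),
                   class = "increased_in_b")
  } else {
    tibble::tibble(reaction_id = character(0), class = character(0))
  }
  truth <- structure(list(affected = affected,
                          imat_objective = NA_integer_,
                          imat_activity = NULL),
                     class = "perturbation_truth")
  list(model_a = model_a, model_b = unb$model, log = unb$log,
       truth = truth)
}

#' Default media and diets for the toy models
#'
#' `mrs_like_medium()` is the rich culture medium of the toy microbe
#' (glucose, serine and the accessory amino acids available);
#' `dmem_like_medium()` the defined mammalian diet of the toy host
#' (glucose, serine, folate); `toy_lumen_diet()` the shared-lumen diet
#' for a paired model (no free nucleotide, so nucleotide cross-feeding is
#' observable).
#'
#' @param n_branches Accessory amino-acid branches to feed, matching the
#'   [toy_spec()] used for the microbe.
#' @return A [medium_spec()].
#' @export
mrs_like_medium <- function(n_branches = 2L) {
  lb <- c("EX_glc[e]" = -10, "EX_ser[e]" = -10)
  if (n_branches > 0) {
    aa <- paste0("EX_aa", seq_len(n_branches), "[e]")
    lb <- c(lb, stats::setNames(rep(-5, length(aa)), aa))
  }
  medium_spec(lb)
}

#' @rdname mrs_like_medium
#' @export
dmem_like_medium <- function() {
  medium_spec(c("EX_glc[e]" = -10, "EX_ser[e]" = -10, "EX_fol[e]" = -1))
}

#' @rdname mrs_like_medium
#' @export
toy_lumen_diet <- function() {
  medium_spec(c("EX_glc[u]" = -20, "EX_ser[u]" = -20, "EX_fol[u]" = -1))
}
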