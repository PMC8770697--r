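#' Coupling-constraint parameters for community models
#'
#' Community-model convention: each organism reaction `j` is tied to its
#' organism's biomass flux by `|v_j| <= c * v_biomass + u`, so a
#' non-growing organism cannot carry arbitrary flux. Defaults follow the
#' microbiome-modeling convention (`c = 400`, `u = 0.01`).
#'
#' @param c_coupling Coupling factor, `> 0`.
#' @param u_coupling Coupling offset, `>= 0`.
#' @param couple_host Also couple the host's reactions to host biomass
#'   (by default only the microbe is coupled).
#' @return A `coupling_spec`.
#' @export
coupling_spec <- function(c_coupling = 400, u_coupling = 0.01,
                          couple_host = FALSE) {
  stopifnot(c_coupling > 0, u_coupling >= 0)
  structure(list(c_coupling = c_coupling, u_coupling = u_coupling,
                 couple_host = couple_host),
            class = "coupling_spec")
}

#' Tag a model with an organism prefix
#'
#' Prefixes every reaction and metabolite id (and the objective keys) so
#' two organisms can coexist in one merged network, optionally renaming
#' compartments. GPRs are left untouched. Re-tagging an already tagged
#' model is an error.
#'
#' @param model A `metabolic_model`.
#' @param prefix Non-empty id prefix, e.g. `"H_"`.
#' @param compartment_renames Named character vector, old tag -> new tag.
#' @return The tagged model.
#' @export
tag_model <- function(model, prefix, compartment_renames = character()) {
  stopifnot(nzchar(prefix))
  if (!is.null(model$annotations$organism_prefix)) {
    stop("model already tagged with prefix '",
         model$annotations$organism_prefix, "'")
  }
  rename_met <- function(ids) {
    cmp <- .compartment_of(ids)
    base <- .base_species(ids)
    new_cmp <- ifelse(cmp %in% names(compartment_renames),
                      compartment_renames[cmp], cmp)
    paste0(prefix, base, "[", new_cmp, "]")
  }
  met_map <- stats::setNames(rename_met(model$metabolites$id),
                             model$metabolites$id)
  model$metabolites$id <- unname(met_map)
  model$metabolites$compartment <-
    .compartment_of(model$metabolites$id)
  model$reactions$id <- paste0(prefix, model$reactions$id)
  model$reactions$stoichiometry <-
    lapply(model$reactions$stoichiometry, function(st) {
      stats::setNames(unname(st), unname(met_map[names(st)]))
    })
  if (length(model$objective)) {
    names(model$objective) <- paste0(prefix, names(model$objective))
  }
  model$compartments <- sort(unique(model$metabolites$compartment))
  model$annotations$organism_prefix <- prefix
  model
}

#' Add coupling constraints to a community model
#'
#' Appends, for every reaction in `organism_rxns` other than the biomass
#' itself, the two rows `v_j - c * v_bio <= u` and `-v_j - c * v_bio <= u`.
#' The rows ride on the model and are honoured by every LP-based analysis
#' ([fba()], [fva()], [min_norm_solution()], ...).
#'
#' @param model A `metabolic_model` (normally a paired community model).
#' @param organism_rxns Reaction ids of one organism.
#' @param biomass_id That organism's biomass reaction id (must be among
#'   `organism_rxns` or at least in the model).
#' @param spec A [coupling_spec()].
#' @return The model with coupling rows attached.
#' @export
add_coupling_constraints <- function(model, organism_rxns, biomass_id,
                                     spec = coupling_spec()) {
  stopifnot(all(organism_rxns %in% model$reactions$id),
            biomass_id %in% model$reactions$id)
  targets <- setdiff(organism_rxns, biomass_id)
  rows <- dplyr::bind_rows(lapply(targets, function(j) {
    tibble::tibble(
      id = paste0("cp_", j, c("_f", "_r")),
      coef = list(stats::setNames(c(1, -spec$c_coupling),
                                  c(j, biomass_id)),
                  stats::setNames(c(-1, -spec$c_coupling),
                                  c(j, biomass_id))),
      rhs = spec$u_coupling)
  }))
  old <- if (is.null(model$coupling)) NULL else model$coupling$rows
  model$coupling <- list(rows = dplyr::bind_rows(old, rows), spec = spec)
  model
}

#' Pair a host and a microbe model through a shared lumen
#'
#' Builds a two-organism community model: each organism keeps its own
#' intracellular network (ids prefixed `H_` / `M_`), every organism-level
#' extracellular exchange `EX_met[e]` is replaced by a reversible
#' intercellular transport between the organism's `met[e]` and a shared
#' lumen species `met[u]`, one community exchange `EX_met[u]` per lumen
#' species governs the diet via `lumen_medium`, and host body-fluid
#' (`[b]`) exchanges are retained untouched so the host secretome stays
#' readable. The community objective defaults to the host biomass.
#' Optional coupling constraints tie microbe fluxes to microbe growth.
#'
#' @param host,microbe Valid `metabolic_model`s with biomass reactions and
#'   an extracellular compartment `e`.
#' @param lumen_medium A [medium_spec()] over community exchange ids
#'   (`EX_met[u]`); unlisted lumen exchanges are closed to uptake
#'   (`lb = 0`, `ub = 1000`).
#' @param coupling Optional [coupling_spec()].
#' @param objective `"host"` (default) or `"both"` (sum of biomasses).
#' @return A `paired_model` (a `metabolic_model` subclass) carrying
#'   `organism_tags` (tibble `reaction_id`, `organism` in
#'   `{host, microbe, community}`), `host_biomass` and `microbe_biomass`.
#' @export
pair_models <- function(host, microbe, lumen_medium = NULL,
                        coupling = NULL, objective = c("host", "both")) {
  objective <- match.arg(objective)
  hb <- .biomass_id(host)
  mb <- .biomass_id(microbe)
  if (length(hb) != 1L || length(mb) != 1L) {
    stop("both organisms need exactly one biomass reaction")
  }
  th <- tag_model(host, "H_")
  tm <- tag_model(microbe, "M_")
  strip <- function(tagged, prefix) {
    rx <- tagged$reactions
    is_ex <- rx$kind == "exchange" &
      vapply(rx$stoichiometry,
             function(s) .compartment_of(names(s)[1]) == "e", logical(1))
    ex <- rx[is_ex, ]
    species <- vapply(ex$stoichiometry, function(s) names(s)[1],
                      character(1))
    base <- .base_species(sub(paste0("^", prefix), "", species))
    transports <- tibble::tibble(
      id = paste0(prefix, "IEX_", base, "[u]"),
      name = paste0("lumen transport of ", base),
      stoichiometry = lapply(seq_along(species), function(i) {
        stats::setNames(c(-1, 1), c(species[i], paste0(base[i], "[u]")))
      }),
      lb = -1000, ub = 1000, subsystem = "Transport, lumen", gpr = "",
      kind = "transport")
    tagged$reactions <- dplyr::bind_rows(rx[!is_ex, ], transports)
    list(model = tagged, lumen_species = paste0(base, "[u]"))
  }
  sh <- strip(th, "H_")
  sm <- strip(tm, "M_")
  lumen <- sort(unique(c(sh$lumen_species, sm$lumen_species)))
  lumen_ex <- tibble::tibble(
    id = paste0("EX_", lumen),
    name = paste0("community exchange of ", .base_species(lumen)),
    stoichiometry = lapply(lumen, function(m) stats::setNames(-1, m)),
    lb = 0, ub = 1000, subsystem = "Exchange, community", gpr = "",
    kind = "exchange")
  reactions <- dplyr::bind_rows(sh$model$reactions, sm$model$reactions,
                                lumen_ex)
  metabolites <- dplyr::bind_rows(
    sh$model$metabolites, sm$model$metabolites,
    tibble::tibble(id = lumen, name = .base_species(lumen),
                   compartment = "u", formula = NA_character_,
                   charge = NA_integer_))
  host_bio <- paste0("H_", hb)
  microbe_bio <- paste0("M_", mb)
  obj <- if (objective == "host") stats::setNames(1, host_bio) else
    stats::setNames(c(1, 1), c(host_bio, microbe_bio))
  model <- metabolic_model(reactions, metabolites, objective = obj,
                           annotations = list(paired = TRUE))
  if (!is.null(lumen_medium)) {
    missing <- setdiff(lumen_medium$exchange_id, lumen_ex$id)
    if (length(missing)) {
      stop("lumen medium names absent community exchange(s): ",
           paste(missing, collapse = ", "))
    }
    idx <- .rxn_index(model, lumen_medium$exchange_id)
    model$reactions$lb[idx] <- lumen_medium$lb
    model$reactions$ub[idx] <- lumen_medium$ub
  }
  organism_tags <- tibble::tibble(
    reaction_id = model$reactions$id,
    organism = dplyr::case_when(
      startsWith(model$reactions$id, "H_") ~ "host",
      startsWith(model$reactions$id, "M_") ~ "microbe",
      TRUE ~ "community"))
  model$organism_tags <- organism_tags
  model$host_biomass <- host_bio
  model$microbe_biomass <- microbe_bio
  class(model) <- c("paired_model", class(model))
  if (!is.null(coupling)) {
    microbe_rxns <- organism_tags$reaction_id[
      organism_tags$organism == "microbe"]
    model <- add_coupling_constraints(model, microbe_rxns, microbe_bio,
                                      spec = coupling)
    if (coupling$couple_host) {
      host_rxns <- organism_tags$reaction_id[
        organism_tags$organism == "host"]
      model <- add_coupling_constraints(model, host_rxns, host_bio,
                                        spec = coupling)
    }
  }
  model
}

#' @export
print.paired_model <- function(x, ...) {
  NextMethod()
  tab <- table(x$organism_tags$organism)
  cat("organisms: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Close one organism of a paired model
#'
#' Sets the named organism's lumen transports and biomass to zero flux —
#' the construction used to check pairing neutrality (a paired model with
#' its microbe fully closed must reproduce the standalone host optimum).
#'
#' @param paired A `paired_model`.
#' @param organism `"microbe"` or `"host"`.
#' @return The modified model.
#' @export
close_organism <- function(paired, organism = c("microbe", "host")) {
  organism <- match.arg(organism)
  prefix <- if (organism == "microbe") "M_" else "H_"
  bio <- if (organism == "microbe") paired$microbe_biomass else
    paired$host_biomass
  idx <- which(startsWith(paired$reactions$id, paste0(prefix, "IEX_")) |
                 paired$reactions$id == bio)
  paired$reactions$lb[idx] <- 0
  paired$reactions$ub[idx] <- 0
  paired
}

#' Flux variability of the host-microbe interaction surface
#'
#' FVA restricted to the reactions through which the organisms talk:
#' intercellular lumen transports and community exchanges (or an explicit
#' `targets` set). A transport with `vmin > 0` at full optimality is an
#' obligate interaction — the paired optimum cannot be reached without
#' that metabolite changing hands.
#'
#' @param paired A `paired_model`.
#' @param targets Optional reaction ids; an unknown id is an error.
#' @param gamma Optimality fraction, as in [fva()].
#' @return An `fva_result` over the interaction reactions.
#' @export
interaction_fva <- function(paired, targets = NULL, gamma = 1.0) {
  if (is.null(targets)) {
    targets <- paired$reactions$id[
      grepl("^(H|M)_IEX_", paired$reactions$id) |
        grepl("^EX_.*\\[u\\]$", paired$reactions$id)]
  } else {
    missing <- setdiff(targets, paired$reactions$id)
    if (length(missing)) {
      stop("unknown interaction target(s): ",
           paste(missing, collapse = ", "))
    }
  }
  fva(paired, gamma = gamma, reactions = targets)
}
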