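#' Bundle reactions for quality-controlled addition
#'
#' A `reaction_set` carries candidate reactions together with any new
#' metabolite records they introduce and a provenance string per reaction
#' (a literature citation, or the name of the curated collection). It is
#' the currency of [add_reactions_qc()] and [expand_with_ros()].
#'
#' @param reactions Reaction tibble in the [metabolic_model()] layout.
#' @param new_metabolites Metabolite tibble for species not expected in the
#'   target model; may be `NULL`.
#' @param provenance Character vector recycled over reactions.
#' @return A `reaction_set`.
#' @export
reaction_set <- function(reactions, new_metabolites = NULL,
                         provenance = "uncited") {
  reactions <- tibble::as_tibble(reactions)
  tmp <- metabolic_model(reactions,
                         objective = stats::setNames(numeric(0),
                                                     character(0)))
  reactions <- tmp$reactions
  if (!is.null(new_metabolites)) {
    new_metabolites <- metabolic_model(
      reactions, new_metabolites,
      objective = stats::setNames(numeric(0), character(0)))$metabolites
    new_metabolites <- new_metabolites[
      new_metabolites$id %in%
        unique(c(new_metabolites$id)), , drop = FALSE]
  }
  structure(list(reactions = reactions,
                 new_metabolites = new_metabolites %||%
                   tmp$metabolites[0, ],
                 provenance = rep_len(provenance, nrow(reactions))),
            class = "reaction_set")
}

#' @rdname reaction_set
#' @param path Directory in the TSV model dialect (see [read_model()]).
#' @export
read_reaction_set <- function(path, provenance = path) {
  m <- .read_model_tsv(path)
  reaction_set(m$reactions, m$metabolites, provenance = provenance)
}

#' @export
print.reaction_set <- function(x, ...) {
  cat("<reaction_set> ", nrow(x$reactions), " reactions, ",
      nrow(x$new_metabolites), " new metabolites\n", sep = "")
  invisible(x)
}

new_curation_log <- function() {
  structure(tibble::tibble(step = integer(0), action = character(0),
                           target = character(0), reason = character(0),
                           citation = character(0), payload = list()),
            class = c("curation_log", "tbl_df", "tbl", "data.frame"))
}

.log_add <- function(log, action, target, reason = "", citation = "",
                     payload = NULL) {
  rec <- tibble::tibble(step = nrow(log) + 1L, action = action,
                        target = target, reason = reason,
                        citation = citation, payload = list(payload))
  structure(dplyr::bind_rows(log, rec),
            class = c("curation_log", "tbl_df", "tbl", "data.frame"))
}

.add_metabolite_rows <- function(model, mets) {
  new <- mets[!mets$id %in% model$metabolites$id, , drop = FALSE]
  if (nrow(new)) {
    model$metabolites <- dplyr::bind_rows(model$metabolites, new)
    model$compartments <- sort(unique(c(model$compartments,
                                        new$compartment)))
  }
  model
}

.add_reaction_row <- function(model, rxn) {
  model$reactions <- dplyr::bind_rows(model$reactions,
                                      tibble::as_tibble(rxn))
  model
}

.same_reaction <- function(a, b) {
  sa <- a$stoichiometry[[1]]; sb <- b$stoichiometry[[1]]
  sa <- sa[order(names(sa))]; sb <- sb[order(names(sb))]
  isTRUE(all.equal(sa, sb)) && isTRUE(all.equal(a$lb, b$lb)) &&
    isTRUE(all.equal(a$ub, b$ub))
}

#' Add reactions to a model under quality control
#'
#' The audited route for model expansion: new metabolites are registered
#' before any reaction that uses them, duplicates (same id with identical
#' chemistry and bounds, or a different id with identical chemistry and
#' bounds) are skipped with a logged reason, an id collision with
#' *different* content is a hard error, and a reaction referencing a
#' metabolite that is neither in the model nor in the set's
#' `new_metabolites` is a hard error naming the metabolite.
#'
#' @param model A `metabolic_model`.
#' @param rset A [reaction_set()].
#' @param log An existing `curation_log` to append to.
#' @return A list with the expanded `model`, the `log`, and `added`, the
#'   ids actually inserted.
#' @export
add_reactions_qc <- function(model, rset, log = new_curation_log()) {
  added <- character(0)
  known_mets <- c(model$metabolites$id, rset$new_metabolites$id)
  for (k in seq_len(nrow(rset$reactions))) {
    rxn <- rset$reactions[k, ]
    cit <- rset$provenance[k]
    st <- rxn$stoichiometry[[1]]
    missing <- setdiff(names(st), known_mets)
    if (length(missing)) {
      stop("reaction ", rxn$id, " references unregistered metabolite(s): ",
           paste(missing, collapse = ", "))
    }
    hit <- which(model$reactions$id == rxn$id)
    if (length(hit)) {
      if (.same_reaction(rxn, model$reactions[hit[1], ])) {
        log <- .log_add(log, "skip", rxn$id,
                        reason = "duplicate id with identical content",
                        citation = cit)
        next
      }
      stop("reaction id collision with differing content: ", rxn$id)
    }
    same_chem <- which(vapply(seq_len(nrow(model$reactions)), function(i) {
      .same_reaction(rxn, model$reactions[i, ])
    }, logical(1)))
    if (length(same_chem)) {
      log <- .log_add(log, "skip", rxn$id,
                      reason = paste0("identical stoichiometry and bounds as ",
                                      model$reactions$id[same_chem[1]]),
                      citation = cit)
      next
    }
    need_mets <- rset$new_metabolites[
      rset$new_metabolites$id %in% names(st) &
        !rset$new_metabolites$id %in% model$metabolites$id, , drop = FALSE]
    model <- .add_metabolite_rows(model, need_mets)
    model <- .add_reaction_row(model, rxn)
    added <- c(added, rxn$id)
    log <- .log_add(log, "add_reaction", rxn$id, reason = "model expansion",
                    citation = cit,
                    payload = list(reaction = as.list(rxn),
                                   metabolites = need_mets))
  }
  list(model = model, log = log, added = added)
}

#' Expand a model with a reactive-species reaction set
#'
#' Adds a curated set of reactive-oxygen/nitrogen-species reactions via
#' [add_reactions_qc()], then immediately tests each newly added reaction
#' for blockage (zero attainable flux, [find_blocked_reactions()]) — the
#' expansion-then-debugging protocol for grafting stress chemistry onto a
#' metabolic reconstruction. The still-blocked subset is returned for
#' [unblock_reactions()].
#'
#' @inheritParams add_reactions_qc
#' @param ros_set A [reaction_set()] of reactive-species reactions.
#' @return A list with `model`, `log`, `added` and `blocked` (ids of added
#'   reactions that cannot carry flux yet).
#' @export
expand_with_ros <- function(model, ros_set, log = new_curation_log()) {
  out <- add_reactions_qc(model, ros_set, log = log)
  blocked <- if (length(out$added)) {
    find_blocked_reactions(out$model, reactions = out$added)
  } else character(0)
  list(model = out$model, log = out$log, added = out$added,
       blocked = blocked)
}

.production_status <- function(model) {
  mets <- model$metabolites$id
  produced <- consumed <- stats::setNames(rep(FALSE, length(mets)), mets)
  rx <- model$reactions
  for (k in seq_len(nrow(rx))) {
    st <- rx$stoichiometry[[k]]
    if (rx$lb[k] == 0 && rx$ub[k] == 0) next
    fwd <- rx$ub[k] > 0
    bwd <- rx$lb[k] < 0
    pos <- st > 0
    if (fwd) {
      produced[names(st)[pos]] <- TRUE
      consumed[names(st)[!pos]] <- TRUE
    }
    if (bwd) {
      consumed[names(st)[pos]] <- TRUE
      produced[names(st)[!pos]] <- TRUE
    }
  }
  list(produced = produced, consumed = consumed)
}

.boundary_reaction <- function(met, kind, bounds) {
  tibble::tibble(
    id = paste0(if (kind == "demand") "DM_" else "SK_", met),
    name = paste(if (kind == "demand") "demand for" else "sink for", met),
    stoichiometry = list(stats::setNames(-1, met)),
    lb = bounds[1], ub = bounds[2],
    subsystem = "Curation", gpr = "", kind = kind)
}

#' Unblock reactions by adding demand and sink reactions
#'
#' Resolves blocked reactions the way a curator debugging a freshly
#' expanded reconstruction would. In `literature_first` mode a
#' user-supplied [reaction_set()] of literature reactions is added first;
#' whatever remains blocked falls through to the automatic protocol, which
#' adds — greedily, in deterministic id-sorted order — a demand reaction
#' (`DM_met`) for each dead-end product and a sink reaction (`SK_met`) for
#' each dead-end reactant of the blocked reaction, re-testing after every
#' addition and widening to the model's remaining dead ends only if
#' needed. Every addition is logged with the reason "no literature
#' evidence". Reactions still blocked after all candidates are exhausted
#' are reported, never dropped.
#'
#' @param model A `metabolic_model`.
#' @param blocked Character vector of blocked reaction ids.
#' @param mode `"auto"` or `"literature_first"`.
#' @param rset Literature [reaction_set()] for `literature_first` mode.
#' @param demand_bounds,sink_bounds Bounds for the added boundary
#'   reactions: demands are consumption-only, sinks reversible.
#' @param log An existing `curation_log` to append to.
#' @return A list with `model`, `log` and `still_blocked`.
#' @export
unblock_reactions <- function(model, blocked,
                              mode = c("auto", "literature_first"),
                              rset = NULL,
                              demand_bounds = c(0, 1000),
                              sink_bounds = c(-1000, 1000),
                              log = new_curation_log()) {
  mode <- match.arg(mode)
  stopifnot(all(blocked %in% model$reactions$id))
  if (mode == "literature_first" && !is.null(rset)) {
    out <- add_reactions_qc(model, rset, log = log)
    model <- out$model
    log <- out$log
    blocked <- find_blocked_reactions(model, reactions = blocked)
  }
  still_blocked <- character(0)
  for (rid in sort(blocked)) {
    if (!rid %in% find_blocked_reactions(model, reactions = rid)) next
    st <- model$reactions$stoichiometry[[.rxn_index(model, rid)]]
    repeat {
      status <- .production_status(model)
      dead <- names(which(xor(status$produced, status$consumed)))
      own <- sort(intersect(names(st), dead))
      wide <- sort(setdiff(dead, own))
      cand <- c(own, wide)
      cand <- cand[!paste0("DM_", cand) %in% model$reactions$id |
                     !paste0("SK_", cand) %in% model$reactions$id]
      if (!length(cand)) {
        still_blocked <- c(still_blocked, rid)
        break
      }
      met <- cand[1]
      if (status$produced[[met]]) {
        rx <- .boundary_reaction(met, "demand", demand_bounds)
        act <- "add_demand"
      } else {
        rx <- .boundary_reaction(met, "sink", sink_bounds)
        act <- "add_sink"
      }
      if (rx$id %in% model$reactions$id) {
        still_blocked <- c(still_blocked, rid)
        break
      }
      model <- .add_reaction_row(model, rx)
      model <- .add_metabolite_rows(
        model, tibble::tibble(id = met, name = .base_species(met),
                              compartment = .compartment_of(met),
                              formula = NA_character_,
                              charge = NA_integer_))
      log <- .log_add(log, act, rx$id, reason = "no literature evidence",
                      payload = list(metabolite = met,
                                     bounds = c(rx$lb, rx$ub)))
      if (!length(find_blocked_reactions(model, reactions = rid))) break
    }
  }
  list(model = model, log = log, still_blocked = unique(still_blocked))
}

#' Constrain a model to a defined growth medium
#'
#' Applies a [medium_spec()] (an MRS- or DMEM-style bound table) to the
#' model's exchange reactions. By default every exchange *not* named in
#' the medium has its lower bound closed to zero, so the medium is the
#' complete statement of what the model may take up; secretion bounds are
#' untouched. The operation is idempotent.
#'
#' @param model A `metabolic_model`.
#' @param medium A `medium_spec`.
#' @param close_others Close uptake through unlisted exchanges.
#' @return The constrained model.
#' @export
apply_medium <- function(model, medium, close_others = TRUE) {
  ex <- model$reactions$id[model$reactions$kind == "exchange"]
  missing <- setdiff(medium$exchange_id, model$reactions$id)
  if (length(missing)) {
    stop("medium names exchange reaction(s) absent from the model: ",
         paste(missing, collapse = ", "))
  }
  idx <- .rxn_index(model, medium$exchange_id)
  model$reactions$lb[idx] <- medium$lb
  model$reactions$ub[idx] <- medium$ub
  if (close_others) {
    others <- setdiff(ex, medium$exchange_id)
    oi <- .rxn_index(model, others)
    model$reactions$lb[oi] <- 0
  }
  model
}

#' Edit the biomass reaction
#'
#' Removes precursor terms and merges new ones into the model's single
#' biomass reaction — the operation behind deriving a non-replicating
#' tissue objective (drop nucleotide precursors, add a folate-pool
#' dependency) from a generic growth objective.
#'
#' @param model A `metabolic_model` with exactly one biomass reaction.
#' @param remove Metabolite ids to drop from the biomass stoichiometry;
#'   an id not present is an error.
#' @param add Named numeric of coefficients to set (negative for
#'   precursors).
#' @param log An existing `curation_log` to append to.
#' @return A list with `model` and `log` (old and new coefficients in the
#'   payload).
#' @export
edit_biomass <- function(model, remove = character(),
                         add = stats::setNames(numeric(0), character(0)),
                         log = new_curation_log()) {
  bio <- .biomass_id(model)
  if (length(bio) != 1L) {
    stop("model must have exactly one biomass reaction, found ",
         length(bio))
  }
  bi <- .rxn_index(model, bio)
  st <- model$reactions$stoichiometry[[bi]]
  old <- st
  absent <- setdiff(remove, names(st))
  if (length(absent)) {
    stop("metabolite(s) not in biomass reaction: ",
         paste(absent, collapse = ", "))
  }
  st <- st[!names(st) %in% remove]
  for (m in names(add)) st[m] <- add[[m]]
  st <- st[abs(st) > 0]
  missing <- setdiff(names(st), model$metabolites$id)
  if (length(missing)) {
    stop("biomass addition references unknown metabolite(s): ",
         paste(missing, collapse = ", "))
  }
  model$reactions$stoichiometry[[bi]] <- st
  log <- .log_add(log, "edit_biomass", bio, reason = "objective revision",
                  payload = list(old = old, new = st,
                                 remove = remove, add = add))
  list(model = model, log = log)
}

#' Replay a curation log
#'
#' Re-applies every logged action to a base model. Replaying the log that
#' produced a curated model on the same base model reproduces the curated
#' model exactly (field by field) — the log is the auditable, executable
#' record of the curation session.
#'
#' @param model The base `metabolic_model`.
#' @param log A `curation_log`.
#' @return The re-curated model.
#' @export
replay_curation_log <- function(model, log) {
  for (k in seq_len(nrow(log))) {
    act <- log$action[k]
    pay <- log$payload[[k]]
    if (act == "skip") next
    if (act == "add_reaction") {
      mets <- pay$metabolites
      if (!is.null(mets) && nrow(mets)) {
        model <- .add_metabolite_rows(model, mets)
      }
      rxn <- tibble::as_tibble(pay$reaction)
      model <- .add_reaction_row(model, rxn)
    } else if (act %in% c("add_demand", "add_sink")) {
      kind <- if (act == "add_demand") "demand" else "sink"
      rx <- .boundary_reaction(pay$metabolite, kind, pay$bounds)
      model <- .add_reaction_row(model, rx)
      model <- .add_metabolite_rows(
        model, tibble::tibble(id = pay$metabolite,
                              name = .base_species(pay$metabolite),
                              compartment = .compartment_of(pay$metabolite),
                              formula = NA_character_,
                              charge = NA_integer_))
    } else if (act == "set_bound") {
      idx <- .rxn_index(model, log$target[k])
      model$reactions$lb[idx] <- pay$lb
      model$reactions$ub[idx] <- pay$ub
    } else if (act == "edit_biomass") {
      bi <- .rxn_index(model, log$target[k])
      model$reactions$stoichiometry[[bi]] <- pay$new
    } else if (act == "remove_reaction") {
      idx <- .rxn_index(model, log$target[k])
      model$reactions <- model$reactions[-idx, ]
      model$objective <-
        model$objective[names(model$objective) != log$target[k]]
      used <- unique(unlist(lapply(model$reactions$stoichiometry, names)))
      model$metabolites <-
        model$metabolites[model$metabolites$id %in% used, ]
    } else {
      stop("unknown curation action: ", act)
    }
  }
  model
}
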