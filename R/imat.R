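#' iMAT context-specific activity extraction
#'
#' Solves the integrative MILP that reconciles a metabolic network with
#' categorical expression evidence: over flux vectors `v` at steady state
#' within bounds, maximise the number of core-active reactions (`R_H`,
#' high/medium evidence) driven to a flux of magnitude at least `epsilon`
#' (binaries `y+`/`y-` for the forward and reverse direction) plus the
#' number of core-inactive reactions (`R_L`, low evidence) held at zero
#' (binary `z`). The constraints for a core-active reaction `i` are
#' `v_i + y+_i (lb_i - eps) >= lb_i`, `v_i + y-_i (ub_i + eps) <= ub_i`,
#' `y+_i + y-_i <= 1`; for a core-inactive reaction
#' `lb_i (1 - z_i) <= v_i <= ub_i (1 - z_i)`.
#'
#' Unbounded reactions are clamped to +/-1000 before the MILP. The
#' model's biomass reaction is never scored as core-inactive (it is
#' retained in every context model).
#'
#' @param model A `metabolic_model`.
#' @param revidence A `reaction_evidence` table from
#'   [map_expression_to_reactions()], or a list with character vectors
#'   `core_active` and `core_inactive`.
#' @param epsilon Activation flux threshold (flux units), `> 0`.
#' @return An `imat_result`: `objective` (satisfied evidence count),
#'   `activity` tibble (`reaction_id`, `evidence_set`, `state` in
#'   `{active_fwd, active_rev, silenced, unset}`), the witness `fluxes`,
#'   `epsilon` and solver `nodes`.
#' @export
imat_extract <- function(model, revidence, epsilon = 1.0) {
  stopifnot(epsilon > 0)
  if (inherits(revidence, "reaction_evidence") ||
      is.data.frame(revidence)) {
    RH <- revidence$reaction_id[revidence$evidence_set == "core_active"]
    RL <- revidence$reaction_id[revidence$evidence_set == "core_inactive"]
  } else {
    RH <- revidence$core_active
    RL <- revidence$core_inactive
  }
  bio <- .biomass_id(model, required = FALSE)
  RL <- setdiff(RL, bio)
  if (length(intersect(RH, RL))) {
    stop("core_active and core_inactive overlap: ",
         paste(intersect(RH, RL), collapse = ", "))
  }
  if (!length(RH) && !length(RL)) {
    warning("no evidence-supported reactions; the iMAT objective is ",
            "trivially zero and no reaction will be silenced")
  }
  lp <- .model_lp(model)
  n <- length(lp$rxn_ids)
  lb <- pmax(lp$lb, -1000)
  ub <- pmin(lp$ub, 1000)
  hi <- .rxn_index(model, RH)
  li <- .rxn_index(model, RL)
  nh <- length(hi); nl <- length(li)
  nb <- 2L * nh + nl
  nv <- n + nb
  pad <- function(row) c(row, numeric(nb))
  A <- t(vapply(seq_len(nrow(lp$A)), function(r) pad(lp$A[r, ]),
                numeric(nv)))
  if (nrow(lp$A) == 1L) A <- matrix(A, 1L, nv)
  sense <- lp$sense
  rhs <- lp$rhs
  addrow <- function(row, s, r) {
    A <<- rbind(A, row); sense <<- c(sense, s); rhs <<- c(rhs, r)
  }
  yp <- n + seq_len(nh)
  ym <- n + nh + seq_len(nh)
  zz <- n + 2L * nh + seq_len(nl)
  for (k in seq_len(nh)) {
    i <- hi[k]
    row <- numeric(nv); row[i] <- 1; row[yp[k]] <- lb[i] - epsilon
    addrow(row, ">=", lb[i])
    row <- numeric(nv); row[i] <- 1; row[ym[k]] <- ub[i] + epsilon
    addrow(row, "<=", ub[i])
    row <- numeric(nv); row[yp[k]] <- 1; row[ym[k]] <- 1
    addrow(row, "<=", 1)
  }
  for (k in seq_len(nl)) {
    i <- li[k]
    row <- numeric(nv); row[i] <- 1; row[zz[k]] <- lb[i]
    addrow(row, ">=", lb[i])
    row <- numeric(nv); row[i] <- 1; row[zz[k]] <- ub[i]
    addrow(row, "<=", ub[i])
  }
  obj <- c(numeric(n), rep(1, nb))
  lbv <- c(lb, numeric(nb))
  ubv <- c(ub, rep(1, nb))
  sol <- solve_milp(obj, A, sense, rhs, lbv, ubv,
                    int_idx = n + seq_len(nb), maximize = TRUE)
  if (sol$status != "optimal") {
    stop("iMAT MILP did not solve (status: ", sol$status,
         "); with all binaries free this should be impossible")
  }
  state_h <- ifelse(sol$x[yp] > 0.5, "active_fwd",
                    ifelse(sol$x[ym] > 0.5, "active_rev", "unset"))
  state_l <- ifelse(sol$x[zz] > 0.5, "silenced", "unset")
  activity <- tibble::tibble(
    reaction_id = c(RH, RL),
    evidence_set = c(rep("core_active", nh), rep("core_inactive", nl)),
    state = c(state_h, state_l))
  structure(list(objective = as.integer(round(sol$objective)),
                 activity = activity,
                 fluxes = stats::setNames(sol$x[seq_len(n)], lp$rxn_ids),
                 epsilon = epsilon, status = sol$status,
                 nodes = sol$nodes),
            class = "imat_result")
}

#' @export
print.imat_result <- function(x, ...) {
  cat("<imat_result> objective: ", x$objective, " satisfied evidence terms",
      " (epsilon = ", x$epsilon, ", ", x$nodes, " nodes)\n", sep = "")
  invisible(x)
}

#' Exhaustive reference solution of the iMAT program
#'
#' Enumerates every admissible assignment of the activity binaries (three
#' states per core-active reaction, two per core-inactive) and checks
#' feasibility of each induced LP. Exponential in the evidence size —
#' usable up to a dozen evidence reactions — and entirely independent of
#' the branch-and-bound path in [imat_extract()], which it exists to
#' verify.
#'
#' @inheritParams imat_extract
#' @return A list with the maximal `objective` and one optimal binary
#'   `assignment`.
#' @export
imat_brute_force <- function(model, revidence, epsilon = 1.0) {
  if (inherits(revidence, "reaction_evidence") ||
      is.data.frame(revidence)) {
    RH <- revidence$reaction_id[revidence$evidence_set == "core_active"]
    RL <- revidence$reaction_id[revidence$evidence_set == "core_inactive"]
  } else {
    RH <- revidence$core_active
    RL <- revidence$core_inactive
  }
  bio <- .biomass_id(model, required = FALSE)
  RL <- setdiff(RL, bio)
  lp <- .model_lp(model)
  n <- length(lp$rxn_ids)
  lb0 <- pmax(lp$lb, -1000)
  ub0 <- pmin(lp$ub, 1000)
  hi <- .rxn_index(model, RH)
  li <- .rxn_index(model, RL)
  h_states <- rev(expand.grid(rep(list(c("unset", "fwd", "rev")),
                                  length(hi)),
                              stringsAsFactors = FALSE))
  l_states <- rev(expand.grid(rep(list(c(0L, 1L)), length(li))))
  if (!length(hi)) h_states <- data.frame(row.names = 1)
  if (!length(li)) l_states <- data.frame(row.names = 1)
  best <- -1L
  best_assign <- NULL
  for (a in seq_len(nrow(h_states))) {
    for (b in seq_len(nrow(l_states))) {
      lb <- lb0; ub <- ub0
      score <- 0L
      ok <- TRUE
      for (k in seq_along(hi)) {
        st <- h_states[a, k]
        if (st == "fwd") {
          lb[hi[k]] <- max(lb[hi[k]], epsilon); score <- score + 1L
        } else if (st == "rev") {
          ub[hi[k]] <- min(ub[hi[k]], -epsilon); score <- score + 1L
        }
        if (lb[hi[k]] > ub[hi[k]]) ok <- FALSE
      }
      for (k in seq_along(li)) {
        if (l_states[b, k] == 1L) {
          lb[li[k]] <- max(lb[li[k]], 0)
          ub[li[k]] <- min(ub[li[k]], 0)
          score <- score + 1L
          if (lb[li[k]] > ub[li[k]]) ok <- FALSE
        }
      }
      if (!ok || score <= best) next
      feas <- solve_lp(numeric(n), lp$A, lp$sense, lp$rhs, lb, ub)
      if (feas$status == "optimal") {
        best <- score
        best_assign <- list(h = if (length(hi)) unlist(h_states[a, ])
                            else character(0),
                            l = if (length(li)) unlist(l_states[b, ])
                            else integer(0))
      }
    }
  }
  list(objective = as.integer(best), assignment = best_assign)
}

#' Build a context-specific model from an iMAT result
#'
#' Materialises the extraction: reactions the MILP silenced are removed
#' (the biomass reaction is always retained), optional literature
#' transport reactions are added, and — when `repair = TRUE` — reactions
#' left unable to carry flux by the removals are pruned and a blocked
#' biomass is rescued with demand/sink additions via
#' [unblock_reactions()]. With `repair = FALSE` newly blocked reactions
#' are retained but reported. A [run_sanity_checks()] report on the final
#' model is attached.
#'
#' @param model The parent `metabolic_model`.
#' @param result An [imat_extract()] result computed on `model`.
#' @param repair Prune newly blocked reactions and rescue the biomass.
#' @param transporters Optional [reaction_set()] of literature transport
#'   reactions to add before the consistency pass.
#' @param log A `curation_log` to append to.
#' @return A list with `model`, `log`, `removed`, `blocked` (ids blocked
#'   after removal; pruned when `repair`) and `sanity`.
#' @export
build_context_model <- function(model, result, repair = TRUE,
                                transporters = NULL,
                                log = new_curation_log()) {
  stopifnot(inherits(result, "imat_result"))
  bio <- .biomass_id(model, required = FALSE)
  silenced <- setdiff(
    result$activity$reaction_id[result$activity$state == "silenced"], bio)
  drop_rxn <- function(model, ids, log, reason) {
    for (id in ids) {
      idx <- .rxn_index(model, id)
      log <- .log_add(log, "remove_reaction", id, reason = reason,
                      payload = list(reaction =
                                       as.list(model$reactions[idx, ])))
      model$reactions <- model$reactions[-idx, ]
      model$objective <- model$objective[names(model$objective) != id]
    }
    used <- unique(unlist(lapply(model$reactions$stoichiometry, names)))
    model$metabolites <- model$metabolites[model$metabolites$id %in% used, ]
    list(model = model, log = log)
  }
  out <- drop_rxn(model, silenced, log, "silenced by expression evidence")
  model <- out$model; log <- out$log
  if (!is.null(transporters)) {
    out <- add_reactions_qc(model, transporters, log = log)
    model <- out$model; log <- out$log
  }
  blocked <- find_blocked_reactions(model)
  if (repair) {
    prune <- setdiff(blocked, bio)
    out <- drop_rxn(model, prune, log, "blocked after context extraction")
    model <- out$model; log <- out$log
    if (length(intersect(blocked, bio))) {
      ub <- unblock_reactions(model, intersect(blocked, bio), log = log)
      model <- ub$model; log <- ub$log
    }
  }
  list(model = model, log = log, removed = silenced, blocked = blocked,
       sanity = run_sanity_checks(model))
}
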