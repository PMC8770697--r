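.objective_vector <- function(model) {
  obj <- numeric(n_reactions(model))
  if (length(model$objective)) {
    obj[.rxn_index(model, names(model$objective))] <- unname(model$objective)
  }
  obj
}

# Assemble the LP data for a model: steady-state rows S v = 0 plus any
# coupling constraint rows the model carries (community models).
.model_lp <- function(model) {
  S <- stoichiometric_matrix(model, sparse = FALSE)
  A <- S
  sense <- rep("=", nrow(S))
  rhs <- rep(0, nrow(S))
  row_ids <- rownames(S)
  if (!is.null(model$coupling) && nrow(model$coupling$rows)) {
    cr <- model$coupling$rows
    Ac <- matrix(0, nrow(cr), ncol(S))
    for (k in seq_len(nrow(cr))) {
      co <- cr$coef[[k]]
      Ac[k, .rxn_index(model, names(co))] <- unname(co)
    }
    A <- rbind(A, Ac)
    sense <- c(sense, rep("<=", nrow(cr)))
    rhs <- c(rhs, cr$rhs)
    row_ids <- c(row_ids, cr$id)
  }
  list(A = A, sense = sense, rhs = rhs,
       lb = model$reactions$lb, ub = model$reactions$ub,
       rxn_ids = model$reactions$id, row_ids = row_ids,
       n_mets = nrow(S))
}

.new_flux_solution <- function(status, objective, fluxes, shadow_prices,
                               reduced_costs, sense) {
  structure(list(status = status, objective = objective, fluxes = fluxes,
                 shadow_prices = shadow_prices,
                 reduced_costs = reduced_costs, sense = sense),
            class = "flux_solution")
}

#' Flux balance analysis
#'
#' Solves `max (or min) c'v` subject to the steady-state constraint
#' `S v = 0`, the flux bounds `lb <= v <= ub`, and any coupling
#' constraints attached to the model.
#'
#' @param model A `metabolic_model` with a non-empty objective.
#' @param sense `"max"` (default) or `"min"`.
#' @return A `flux_solution` with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), the optimal objective `Z*`, the flux vector, and at
#'   optimality the metabolite shadow prices and per-reaction reduced
#'   costs. Use [generics::tidy()] / [generics::glance()] for tibble views.
#' @export
fba <- function(model, sense = c("max", "min")) {
  sense <- match.arg(sense)
  if (!length(model$objective)) stop("model objective is empty")
  lp <- .model_lp(model)
  obj <- .objective_vector(model)
  sol <- solve_lp(obj, lp$A, lp$sense, lp$rhs, lp$lb, lp$ub,
                  maximize = sense == "max")
  if (sol$status != "optimal") {
    return(.new_flux_solution(sol$status, NA_real_,
                              stats::setNames(rep(NA_real_, length(obj)),
                                              lp$rxn_ids),
                              NULL, NULL, sense))
  }
  .new_flux_solution(
    "optimal", sol$objective,
    stats::setNames(sol$x, lp$rxn_ids),
    stats::setNames(sol$y[seq_len(lp$n_mets)],
                    lp$row_ids[seq_len(lp$n_mets)]),
    stats::setNames(sol$dj, lp$rxn_ids),
    sense)
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status, sep = "")
  if (x$status == "optimal") cat(", objective: ", format(x$objective), sep = "")
  cat("\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' For each requested reaction, minimises and maximises its flux subject
#' to steady state, the bounds, and retention of at least the fraction
#' `gamma` of the optimal objective (`c'v >= gamma * Z*` for a maximised
#' objective, with a small absolute slack so floating-point optima do not
#' empty the feasible set). `gamma = 0` drops the objective floor
#' entirely, which is the setting used for blocked-reaction detection.
#'
#' @param model A `metabolic_model`.
#' @param gamma Optimality fraction in `[0, 1]`.
#' @param reactions Optional subset of reaction ids.
#' @return An `fva_result` tibble: `reaction_id`, `vmin`, `vmax`, `span`
#'   (`vmax - vmin`), with attributes `gamma` and `objective_floor`.
#' @export
fva <- function(model, gamma = 1.0, reactions = NULL) {
  lp <- .model_lp(model)
  ids <- reactions %||% lp$rxn_ids
  idx <- .rxn_index(model, ids)
  A <- lp$A; sense <- lp$sense; rhs <- lp$rhs
  floor_val <- NA_real_
  if (gamma > 0 && length(model$objective)) {
    sol <- fba(model, "max")
    if (sol$status != "optimal") {
      stop("fva requires an optimal fba solution (status: ", sol$status, ")")
    }
    zstar <- sol$objective
    floor_val <- gamma * zstar - 1e-6 * max(1, abs(zstar))
    A <- rbind(A, .objective_vector(model))
    sense <- c(sense, ">=")
    rhs <- c(rhs, floor_val)
  }
  n <- length(lp$rxn_ids)
  vmin <- vmax <- numeric(length(idx))
  for (k in seq_along(idx)) {
    e <- numeric(n); e[idx[k]] <- 1
    lo <- solve_lp(e, A, sense, rhs, lp$lb, lp$ub, maximize = FALSE)
    hi <- solve_lp(e, A, sense, rhs, lp$lb, lp$ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("fva failed for reaction ", ids[k], " (", lo$status, "/",
           hi$status, ")")
    }
    vmin[k] <- lo$objective
    vmax[k] <- hi$objective
  }
  structure(tibble::tibble(reaction_id = ids, vmin = vmin, vmax = vmax,
                           span = vmax - vmin),
            gamma = gamma, objective_floor = floor_val,
            class = c("fva_result", "tbl_df", "tbl", "data.frame"))
}

#' Minimum-norm optimal flux distribution
#'
#' Among the alternative optima of the FBA problem (flux vectors attaining
#' `Z*`), returns the one of minimal Euclidean norm (a strictly convex QP,
#' solved with \pkg{quadprog}) or minimal 1-norm (an LP). The Euclidean
#' solution suppresses arbitrary flux through parallel routes and
#' thermodynamically spurious internal cycles.
#'
#' @param model A `metabolic_model`.
#' @param norm `"euclidean"` (default) or `"one"`.
#' @return A `flux_solution` attaining the FBA optimum with minimal norm.
#' @export
min_norm_solution <- function(model, norm = c("euclidean", "one")) {
  norm <- match.arg(norm)
  ref <- fba(model, "max")
  if (ref$status != "optimal") {
    stop("min_norm_solution requires an optimal fba solution (status: ",
         ref$status, ")")
  }
  zstar <- ref$objective
  lp <- .model_lp(model)
  n <- length(lp$rxn_ids)
  obj <- .objective_vector(model)
  ztol <- 1e-8 * max(1, abs(zstar))
  if (norm == "euclidean") {
    # quadprog wants independent equality rows: reduce S (+ any equality
    # rows) by rank first
    eqA <- lp$A[lp$sense == "=", , drop = FALSE]
    qrd <- qr(t(eqA))
    eqA <- eqA[qrd$pivot[seq_len(qrd$rank)], , drop = FALSE]
    ineqA <- lp$A[lp$sense != "=", , drop = FALSE]
    ineq_sign <- ifelse(lp$sense[lp$sense != "="] == "<=", -1, 1)
    ineqA <- ineqA * ineq_sign
    ineq_rhs <- lp$rhs[lp$sense != "="] * ineq_sign
    rows <- rbind(eqA,
                  obj, -obj,
                  diag(n)[is.finite(lp$lb), , drop = FALSE],
                  -diag(n)[is.finite(lp$ub), , drop = FALSE],
                  ineqA)
    bvec <- c(rep(0, nrow(eqA)),
              zstar - ztol, -zstar - ztol,
              lp$lb[is.finite(lp$lb)],
              -lp$ub[is.finite(lp$ub)],
              ineq_rhs)
    qp <- quadprog::solve.QP(Dmat = diag(n), dvec = rep(0, n),
                             Amat = t(rows), bvec = bvec,
                             meq = nrow(eqA))
    v <- qp$solution
  } else {
    # minimise sum(t) with t_j >= |v_j|, holding c'v at Z*
    A2 <- cbind(lp$A, matrix(0, nrow(lp$A), n))
    s2 <- lp$sense; r2 <- lp$rhs
    A2 <- rbind(A2,
                c(obj, rep(0, n)),
                cbind(-diag(n), diag(n)),   # t - v >= 0
                cbind(diag(n), diag(n)))    # t + v >= 0
    s2 <- c(s2, ">=", rep(">=", 2 * n))
    r2 <- c(r2, zstar - ztol, rep(0, 2 * n))
    sol <- solve_lp(c(rep(0, n), rep(1, n)), A2, s2, r2,
                    c(lp$lb, rep(0, n)), c(lp$ub, rep(Inf, n)),
                    maximize = FALSE)
    if (sol$status != "optimal") {
      stop("1-norm minimisation failed: ", sol$status)
    }
    v <- sol$x[seq_len(n)]
  }
  .new_flux_solution("optimal", sum(obj * v),
                     stats::setNames(v, lp$rxn_ids), NULL, NULL, "max")
}

#' Find blocked reactions
#'
#' A reaction is blocked when it cannot carry flux beyond `tol` in either
#' direction under steady state and the bounds, with no objective floor
#' (flux variability at `gamma = 0`).
#'
#' @param model A `metabolic_model`.
#' @param reactions Optional subset to test.
#' @param tol Blocked-flux threshold.
#' @return Character vector of blocked reaction ids.
#' @export
find_blocked_reactions <- function(model, reactions = NULL, tol = 1e-6) {
  fv <- fva(model, gamma = 0, reactions = reactions)
  fv$reaction_id[abs(fv$vmin) < tol & abs(fv$vmax) < tol]
}

#' Find dead-end metabolites
#'
#' Topological classification: a metabolite is a dead end when it is
#' produced by some reaction but consumed by none, or consumed but never
#' produced. A reversible reaction (`lb < 0 < ub`) both produces and
#' consumes each of its metabolites; a reaction fixed to zero
#' (`lb = ub = 0`) does neither.
#'
#' @param model A `metabolic_model`.
#' @return Character vector of dead-end metabolite ids.
#' @export
find_dead_end_metabolites <- function(model) {
  mets <- model$metabolites$id
  produced <- consumed <- stats::setNames(rep(FALSE, length(mets)), mets)
  rx <- model$reactions
  for (k in seq_len(nrow(rx))) {
    st <- rx$stoichiometry[[k]]
    lb <- rx$lb[k]; ub <- rx$ub[k]
    if (lb == 0 && ub == 0) next
    fwd <- ub > 0
    bwd <- lb < 0
    for (i in seq_along(st)) {
      m <- names(st)[i]
      if (st[i] > 0) {
        if (fwd) produced[m] <- TRUE
        if (bwd) consumed[m] <- TRUE
      } else if (st[i] < 0) {
        if (fwd) consumed[m] <- TRUE
        if (bwd) produced[m] <- TRUE
      }
    }
  }
  mets[xor(produced, consumed)]
}

#' Run structural and flux sanity checks
#'
#' The standard quality battery for a curated model: a leak test (with
#' every exchange and sink closed to uptake, no metabolite should be
#' producible from nothing), the blocked-reaction set, and dead-end
#' metabolites.
#'
#' @param model A `metabolic_model`.
#' @param tol Producible-flux threshold for the leak test.
#' @return A `sanity_report` with `leaking_metabolites`,
#'   `blocked_reactions`, `dead_end_metabolites` and `notes`.
#' @export
run_sanity_checks <- function(model, tol = 1e-6) {
  closed <- model
  bdry <- closed$reactions$kind %in% c("exchange", "sink")
  closed$reactions$lb[bdry] <- pmax(closed$reactions$lb[bdry], 0)
  lp <- .model_lp(closed)
  leaks <- character(0)
  for (mi in seq_len(lp$n_mets)) {
    dm <- numeric(nrow(lp$A)); dm[mi] <- -1
    A2 <- cbind(lp$A, dm)
    obj <- c(numeric(length(lp$rxn_ids)), 1)
    sol <- solve_lp(obj, A2, lp$sense, lp$rhs,
                    c(lp$lb, 0), c(lp$ub, 1000), maximize = TRUE)
    if (sol$status == "optimal" && sol$objective > tol) {
      leaks <- c(leaks, lp$row_ids[mi])
    }
  }
  structure(list(leaking_metabolites = leaks,
                 blocked_reactions = find_blocked_reactions(model, tol = tol),
                 dead_end_metabolites = find_dead_end_metabolites(model),
                 notes = c(paste0("leak/blocked tolerance: ", tol),
                           "leak test run with exchange/sink uptake closed")),
            class = "sanity_report")
}

#' @export
print.sanity_report <- function(x, ...) {
  cat("<sanity_report>\n")
  cat("  leaking metabolites: ",
      if (length(x$leaking_metabolites))
        paste(x$leaking_metabolites, collapse = ", ") else "none", "\n",
      sep = "")
  cat("  blocked reactions:   ",
      if (length(x$blocked_reactions))
        paste(x$blocked_reactions, collapse = ", ") else "none", "\n",
      sep = "")
  cat("  dead-end metabolites: ",
      if (length(x$dead_end_metabolites))
        paste(x$dead_end_metabolites, collapse = ", ") else "none", "\n",
      sep = "")
  invisible(x)
}
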