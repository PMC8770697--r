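# Shared fixtures: all built in code, all hand-analysable.

rxn_row <- function(id, formula, lb, ub, subsystem = "test", gpr = "",
                    kind = NA_character_) {
  p <- parse_reaction_formula(formula)
  tibble::tibble(id = id, name = id, stoichiometry = list(p$stoichiometry),
                 lb = lb, ub = ub, subsystem = subsystem, gpr = gpr,
                 kind = kind)
}

# linear chain: uptake of A (up to 10), conversion to B, secretion of B
chain_model <- function(uptake = -10) {
  metabolic_model(dplyr::bind_rows(
    rxn_row("EX_A", "A[c] ->", uptake, 1000),
    rxn_row("R1", "A[c] -> B[c]", 0, 1000),
    rxn_row("EX_B", "B[c] ->", 0, 1000)),
    objective = c(EX_B = 1))
}

# branch: A can go to B (scored) or C (diversion)
branch_model <- function() {
  metabolic_model(dplyr::bind_rows(
    rxn_row("EX_A", "A[c] ->", -10, 1000),
    rxn_row("R1", "A[c] -> B[c]", 0, 1000),
    rxn_row("R2", "A[c] -> C[c]", 0, 1000),
    rxn_row("EX_B", "B[c] ->", 0, 1000),
    rxn_row("EX_C", "C[c] ->", 0, 1000)),
    objective = c(EX_B = 1))
}

# two identical parallel routes from A to B
parallel_model <- function() {
  metabolic_model(dplyr::bind_rows(
    rxn_row("EX_A", "A[c] ->", -10, 1000),
    rxn_row("R1a", "A[c] -> B[c]", 0, 1000),
    rxn_row("R1b", "A[c] -> B[c]", 0, 1000),
    rxn_row("EX_B", "B[c] ->", 0, 1000)),
    objective = c(EX_B = 1))
}

# chain plus a thermodynamically spurious internal cycle B -> C -> D -> B
cycle_model <- function() {
  metabolic_model(dplyr::bind_rows(
    rxn_row("EX_A", "A[c] ->", -10, 1000),
    rxn_row("R1", "A[c] -> B[c]", 0, 1000),
    rxn_row("C1", "B[c] -> C[c]", 0, 1000),
    rxn_row("C2", "C[c] -> D[c]", 0, 1000),
    rxn_row("C3", "D[c] -> B[c]", 0, 1000),
    rxn_row("EX_B", "B[c] ->", 0, 1000)),
    objective = c(EX_B = 1))
}

# random bounded steady-state toy instance for solver-oracle sweeps
random_toy_lp_model <- function(seed, n_mets = 3, n_rxns = 7) {
  withr::with_seed(seed, {
    repeat {
      S <- matrix(sample(-2:2, n_mets * n_rxns, replace = TRUE,
                         prob = c(.1, .2, .35, .2, .15)),
                  n_mets, n_rxns)
      if (all(rowSums(S != 0) > 0) && all(colSums(S != 0) > 0)) break
    }
    mets <- paste0("m", seq_len(n_mets), "[c]")
    lb <- sample(c(-10, -5, 0), n_rxns, replace = TRUE)
    ub <- sample(c(2, 5, 10), n_rxns, replace = TRUE)
    rx <- dplyr::bind_rows(lapply(seq_len(n_rxns), function(j) {
      st <- stats::setNames(S[, j], mets)
      st <- st[st != 0]
      tibble::tibble(id = paste0("v", j), name = paste0("v", j),
                     stoichiometry = list(st), lb = lb[j], ub = ub[j],
                     subsystem = "random", gpr = "",
                     kind = "internal")
    }))
    w <- stats::setNames(round(stats::rnorm(n_rxns), 2),
                         paste0("v", seq_len(n_rxns)))
    w <- w[abs(w) > 0.05]
    if (!length(w)) w <- c(v1 = 1)
    metabolic_model(rx, objective = w)
  })
}

# oracle: fba/fva extremes by exhaustive vertex enumeration, fully
# independent of the simplex
oracle_fba <- function(model) {
  S <- stoichiometric_matrix(model, sparse = FALSE)
  obj <- numeric(ncol(S))
  obj[match(names(model$objective), colnames(S))] <- model$objective
  brute_force_lp(obj, S, "=", rep(0, nrow(S)),
                 model$reactions$lb, model$reactions$ub, maximize = TRUE)
}

oracle_fva <- function(model, gamma = 1) {
  S <- stoichiometric_matrix(model, sparse = FALSE)
  n <- ncol(S)
  obj <- numeric(n)
  obj[match(names(model$objective), colnames(S))] <- model$objective
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  if (gamma > 0) {
    zstar <- oracle_fba(model)$objective
    floor_val <- gamma * zstar - 1e-6 * max(1, abs(zstar))
    # floor row as equality with a non-negative surplus variable
    A <- rbind(cbind(S, 0), c(obj, -1))
    lb <- c(lb, 0)
    ub <- c(ub, 1e6)
    b <- c(rep(0, nrow(S)), floor_val)
  } else {
    A <- S
    b <- rep(0, nrow(S))
  }
  V <- enumerate_vertices(A, b, lb, ub)
  tibble::tibble(reaction_id = colnames(S),
                 vmin = apply(V[, seq_len(n), drop = FALSE], 2, min),
                 vmax = apply(V[, seq_len(n), drop = FALSE], 2, max))
}

# oracle: dead ends by explicit reversibility expansion of the incidence
oracle_dead_ends <- function(model) {
  cols <- list()
  for (k in seq_len(nrow(model$reactions))) {
    st <- model$reactions$stoichiometry[[k]]
    lb <- model$reactions$lb[k]; ub <- model$reactions$ub[k]
    if (ub > 0) cols[[length(cols) + 1L]] <- st
    if (lb < 0) cols[[length(cols) + 1L]] <- -st
  }
  mets <- model$metabolites$id
  pos <- neg <- stats::setNames(rep(FALSE, length(mets)), mets)
  for (st in cols) {
    pos[names(st)[st > 0]] <- TRUE
    neg[names(st)[st < 0]] <- TRUE
  }
  mets[xor(pos, neg)]
}

ros_reaction_ids <- function() {
  c("R_ros_sod", "R_ros_fenton", "R_ros_onoo", "R_ros_serox",
    "R_ros_glyox", "R_ros_nucox", "R_ros_folox", "R_ros_serno")
}
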