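#' @keywords internal
#' @noRd
.slack_augment <- function(A, sense, rhs, lb, ub) {
  A <- as.matrix(A)
  m <- nrow(A)
  ineq <- which(sense != "=")
  if (length(ineq)) {
    Sl <- matrix(0, m, length(ineq))
    slb <- sub <- numeric(length(ineq))
    for (k in seq_along(ineq)) {
      i <- ineq[k]
      Sl[i, k] <- 1
      if (sense[i] == "<=") {
        slb[k] <- 0; sub[k] <- Inf
      } else if (sense[i] == ">=") {
        slb[k] <- -Inf; sub[k] <- 0
      } else {
        stop("unknown constraint sense: ", sense[i])
      }
    }
    A <- cbind(A, Sl)
    lb <- c(lb, slb)
    ub <- c(ub, sub)
  }
  list(A = A, b = rhs, lb = lb, ub = ub, n_slack = length(ineq))
}

# Core bounded-variable simplex iteration loop (minimisation).
# x: current full solution; basis: indices of basic vars; vstat: per-variable
# status in {"basic","lb","ub","free"}. Dantzig pricing with a Bland fallback
# after a run of degenerate pivots, lowest-index tie-breaks throughout so the
# pivot sequence (and hence the reported optimal vertex) is deterministic.
.simplex_iterate <- function(A, b, lb, ub, cvec, x, basis, vstat, tol = 1e-9,
                             maxit = 20000L) {
  m <- nrow(A)
  n <- ncol(A)
  degen <- 0L
  fixed <- (ub - lb) < tol # cannot leave their bound
  for (it in seq_len(maxit)) {
    AB <- A[, basis, drop = FALSE]
    y <- tryCatch(solve(t(AB), cvec[basis]), error = function(e) NULL)
    if (is.null(y)) {
      return(list(status = "singular", x = x, basis = basis, vstat = vstat))
    }
    d <- cvec - as.vector(crossprod(A, y))
    cand_up <- which((vstat == "lb" | vstat == "free") & d < -tol & !fixed)
    cand_dn <- which((vstat == "ub" | vstat == "free") & d > tol & !fixed)
    if (!length(cand_up) && !length(cand_dn)) {
      return(list(status = "optimal", x = x, basis = basis, vstat = vstat,
                  y = y, d = d))
    }
    cand <- c(cand_up, cand_dn)
    dirs <- c(rep(1, length(cand_up)), rep(-1, length(cand_dn)))
    if (degen > 40L) { # Bland's rule
      o <- which.min(cand)
    } else {
      score <- abs(d[cand])
      o <- which(score == max(score))
      if (length(o) > 1L) o <- o[which.min(cand[o])]
    }
    j <- cand[o]
    dir <- dirs[o]
    w <- solve(AB, A[, j])
    # entering variable moves by t >= 0 in direction dir; basic vars move
    # by -dir * w * t
    tflip <- if (is.finite(lb[j]) && is.finite(ub[j])) ub[j] - lb[j] else Inf
    tbest <- tflip
    leave <- 0L
    for (i in seq_len(m)) {
      wi <- dir * w[i]
      bi <- basis[i]
      if (wi > tol) {
        if (is.finite(lb[bi])) {
          ti <- (x[bi] - lb[bi]) / wi
          if (ti < tbest - tol || (ti < tbest + tol && (leave == 0L || basis[i] < basis[leave]))) {
            if (ti < tbest + tol) { tbest <- min(tbest, ti); leave <- i }
          }
        }
      } else if (wi < -tol) {
        if (is.finite(ub[bi])) {
          ti <- (ub[bi] - x[bi]) / (-wi)
          if (ti < tbest - tol || (ti < tbest + tol && (leave == 0L || basis[i] < basis[leave]))) {
            if (ti < tbest + tol) { tbest <- min(tbest, ti); leave <- i }
          }
        }
      }
    }
    if (!is.finite(tbest)) {
      return(list(status = "unbounded", x = x, basis = basis, vstat = vstat,
                  entering = j))
    }
    tbest <- max(tbest, 0)
    degen <- if (tbest < tol) degen + 1L else 0L
    x[j] <- x[j] + dir * tbest
    x[basis] <- x[basis] - dir * tbest * w
    if (leave > 0L && tbest <= tflip + tol) {
      out <- basis[leave]
      wi <- dir * w[leave]
      if (wi > 0) {
        x[out] <- lb[out]; vstat[out] <- "lb"
      } else {
        x[out] <- ub[out]; vstat[out] <- "ub"
      }
      basis[leave] <- j
      vstat[j] <- "basic"
    } else {
      # bound flip: entering variable runs to its opposite bound
      if (dir > 0) { x[j] <- ub[j]; vstat[j] <- "ub" } else { x[j] <- lb[j]; vstat[j] <- "lb" }
    }
  }
  list(status = "maxit", x = x, basis = basis, vstat = vstat)
}

#' Solve a linear program with bounded variables
#'
#' A dense two-phase bounded-variable simplex. This is the optimisation
#' engine behind [fba()], [fva()] and friends; it is exported so that small
#' linear programs (and the tests' independent checks) can be posed directly.
#'
#' @param obj Objective coefficient vector.
#' @param A Constraint matrix (dense or anything coercible by `as.matrix()`).
#' @param sense Character vector per row: `"="`, `"<="` or `">="`.
#' @param rhs Right-hand side vector.
#' @param lb,ub Variable bounds; `-Inf`/`Inf` allowed.
#' @param maximize Maximise instead of minimise.
#' @param tol Pivot/feasibility tolerance.
#'
#' @return A list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `objective`, the primal solution `x`, row duals `y`
#'   (shadow prices, signed for the requested sense) and reduced costs `dj`.
#' @export
solve_lp <- function(obj, A, sense, rhs, lb, ub, maximize = FALSE,
                     tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A)
  if (length(sense) == 1L) sense <- rep(sense, m)
  stopifnot(length(sense) == m, length(rhs) == m,
            length(obj) == ncol(A), length(lb) == ncol(A),
            length(ub) == ncol(A))
  n0 <- ncol(A)
  aug <- .slack_augment(A, sense, rhs, lb, ub)
  Ae <- aug$A; b <- aug$b; lbe <- aug$lb; ube <- aug$ub
  n <- ncol(Ae)
  cvec <- c(if (maximize) -obj else obj, rep(0, n - n0))

  # initial point: every structural/slack variable at a finite bound (0 for
  # free variables)
  x <- numeric(n)
  vstat <- character(n)
  for (j in seq_len(n)) {
    if (is.finite(lbe[j])) {
      x[j] <- lbe[j]; vstat[j] <- "lb"
    } else if (is.finite(ube[j])) {
      x[j] <- ube[j]; vstat[j] <- "ub"
    } else {
      x[j] <- 0; vstat[j] <- "free"
    }
  }
  r <- b - as.vector(Ae %*% x)
  sg <- ifelse(r >= 0, 1, -1)
  Aart <- cbind(Ae, diag(sg, m))
  art <- (n + 1L):(n + m)
  lba <- c(lbe, rep(0, m)); uba <- c(ube, rep(Inf, m))
  xa <- c(x, abs(r))
  vsa <- c(vstat, rep("basic", m))
  c1 <- c(rep(0, n), rep(1, m))
  ph1 <- .simplex_iterate(Aart, b, lba, uba, c1, xa, art, vsa, tol = tol)
  if (ph1$status != "optimal" || sum(ph1$x[art]) > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n0), y = rep(NA_real_, m),
                dj = rep(NA_real_, n0)))
  }
  # phase 2: pin artificials to zero and swap in the true objective
  lba[art] <- 0; uba[art] <- 0
  xa <- ph1$x; xa[art][abs(xa[art]) < 1e-7] <- 0
  c2 <- c(cvec, rep(0, m))
  ph2 <- .simplex_iterate(Aart, b, lba, uba, c2, xa, ph1$basis, ph1$vstat,
                          tol = tol)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", objective = if (maximize) Inf else -Inf,
                x = rep(NA_real_, n0), y = rep(NA_real_, m),
                dj = rep(NA_real_, n0)))
  }
  if (ph2$status != "optimal") {
    stop("simplex failed to converge (status: ", ph2$status, ")")
  }
  x <- ph2$x[seq_len(n0)]
  zmin <- sum(cvec[seq_len(n0)] * x)
  y <- ph2$y
  dj <- ph2$d[seq_len(n0)]
  if (maximize) {
    y <- -y; dj <- -dj
  }
  list(status = "optimal",
       objective = if (maximize) -zmin else zmin,
       x = x, y = as.numeric(y), dj = as.numeric(dj))
}

#' Solve a mixed-integer linear program by branch and bound
#'
#' Depth-first branch and bound over the integer variables, with the LP
#' relaxations solved by [solve_lp()]. Branching always takes the
#' lowest-index fractional integer variable and explores its rounded-up
#' branch first, so solutions are deterministic. Intended for the small
#' MILPs posed by [imat_extract()].
#'
#' @inheritParams solve_lp
#' @param int_idx Indices of integer-constrained variables.
#' @return As [solve_lp()], plus `nodes`, the number of explored nodes.
#' @export
solve_milp <- function(obj, A, sense, rhs, lb, ub, int_idx,
                       maximize = FALSE, tol = 1e-6) {
  sgn <- if (maximize) -1 else 1
  best <- Inf
  best_x <- NULL
  nodes <- 0L
  stack <- list(list(lb = lb, ub = ub))
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rel <- solve_lp(sgn * obj, A, sense, rhs, node$lb, node$ub,
                    maximize = FALSE)
    nodes <- nodes + 1L
    if (rel$status != "optimal") next
    if (rel$objective >= best - 1e-9) next
    xi <- rel$x[int_idx]
    frac <- abs(xi - round(xi))
    if (all(frac < tol)) {
      best <- rel$objective
      best_x <- rel$x
      best_x[int_idx] <- round(best_x[int_idx])
      next
    }
    j <- int_idx[which(frac >= tol)[1L]]
    lo <- node; hi <- node
    lo$ub[j] <- floor(rel$x[j])
    hi$lb[j] <- ceiling(rel$x[j])
    stack[[length(stack) + 1L]] <- lo
    stack[[length(stack) + 1L]] <- hi # explored first (LIFO)
  }
  if (is.null(best_x)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL,
                nodes = nodes))
  }
  list(status = "optimal", objective = sgn * best,
       x = best_x, nodes = nodes)
}

#' Enumerate the basic feasible solutions of a bounded linear system
#'
#' Exhaustively enumerates every basic solution of `A x = b`,
#' `lb <= x <= ub` (each choice of basis columns crossed with each
#' assignment of the non-basic variables to a finite bound) and keeps the
#' feasible ones. Optima of any linear objective over the polytope lie on
#' the returned vertices, which makes this an independent brute-force
#' reference for [solve_lp()] on small instances. Cost grows combinatorially;
#' keep `ncol(A)` at a dozen or so.
#'
#' @param A Equality-constraint matrix.
#' @param b Right-hand side.
#' @param lb,ub Variable bounds; every variable needs at least one finite
#'   bound.
#' @param tol Feasibility tolerance.
#' @return A matrix with one row per distinct basic feasible solution.
#' @export
enumerate_vertices <- function(A, b, lb, ub, tol = 1e-7) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(all(is.finite(lb) | is.finite(ub)))
  if (m == 0L) {
    grid <- as.matrix(expand.grid(lapply(seq_len(n), function(j) {
      unique(c(lb[j], ub[j])[is.finite(c(lb[j], ub[j]))])
    })))
    colnames(grid) <- colnames(A)
    return(grid)
  }
  out <- list()
  combos <- utils::combn(n, min(m, n))
  for (ci in seq_len(ncol(combos))) {
    B <- combos[, ci]
    AB <- A[, B, drop = FALSE]
    if (abs(det(AB)) < 1e-10) next
    N <- setdiff(seq_len(n), B)
    choices <- lapply(N, function(j) {
      v <- c(lb[j], ub[j])
      unique(v[is.finite(v)])
    })
    grid <- if (length(N)) expand.grid(choices) else data.frame(row.names = 1)
    for (gi in seq_len(nrow(grid))) {
      x <- numeric(n)
      if (length(N)) x[N] <- as.numeric(grid[gi, ])
      rhs <- b - if (length(N)) as.vector(A[, N, drop = FALSE] %*% x[N]) else 0
      xB <- solve(AB, rhs)
      x[B] <- xB
      if (all(x >= lb - tol) && all(x <= ub + tol)) {
        out[[length(out) + 1L]] <- pmin(pmax(x, lb), ub)
      }
    }
  }
  if (!length(out)) {
    return(matrix(numeric(0), 0L, n))
  }
  V <- do.call(rbind, out)
  V[!duplicated(round(V, 9)), , drop = FALSE]
}

#' Brute-force optimum of a small bounded linear program
#'
#' Evaluates the objective on every basic feasible solution found by
#' [enumerate_vertices()] (after converting inequality rows to slack form)
#' and returns the best. Independent of the simplex code path in
#' [solve_lp()].
#'
#' @inheritParams solve_lp
#' @return List with `status` (`"optimal"` or `"infeasible"`), `objective`
#'   and `x`.
#' @export
brute_force_lp <- function(obj, A, sense, rhs, lb, ub, maximize = FALSE) {
  A <- as.matrix(A)
  if (length(sense) == 1L) sense <- rep(sense, nrow(A))
  aug <- .slack_augment(A, sense, rhs, lb, ub)
  # slack bounds are half-infinite; cap the infinite side far outside any
  # attainable row activity so enumeration has a finite bound to sit on
  big <- max(1, sum(abs(aug$A) %*% pmin(pmax(abs(aug$lb), abs(aug$ub),
                                             na.rm = TRUE), 1e6))) * 10
  lbe <- ifelse(is.finite(aug$lb), aug$lb, -big)
  ube <- ifelse(is.finite(aug$ub), aug$ub, big)
  V <- enumerate_vertices(aug$A, aug$b, lbe, ube)
  if (!nrow(V)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  z <- as.vector(V[, seq_along(obj), drop = FALSE] %*% obj)
  k <- if (maximize) which.max(z) else which.min(z)
  list(status = "optimal", objective = z[k], x = V[k, seq_along(obj)])
}
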