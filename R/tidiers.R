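#' Tidy a flux solution
#'
#' @param x A `flux_solution` from [fba()] or [min_norm_solution()].
#' @param ... Unused.
#' @return One row per reaction: `reaction_id`, `flux`, `reduced_cost`.
#' @export
tidy.flux_solution <- function(x, ...) {
  tibble::tibble(
    reaction_id = names(x$fluxes),
    flux = unname(x$fluxes),
    reduced_cost = if (is.null(x$reduced_costs)) NA_real_ else
      unname(x$reduced_costs[names(x$fluxes)]))
}

#' @rdname tidy.flux_solution
#' @return For `glance()`: a one-row tibble with `status`, `objective`,
#'   `sense`, `n_reactions`.
#' @export
glance.flux_solution <- function(x, ...) {
  tibble::tibble(status = x$status, objective = x$objective,
                 sense = x$sense, n_reactions = length(x$fluxes))
}

#' @rdname tidy.flux_solution
#' @export
tidy.imat_result <- function(x, ...) x$activity

#' @rdname tidy.flux_solution
#' @export
glance.imat_result <- function(x, ...) {
  tibble::tibble(objective = x$objective, epsilon = x$epsilon,
                 status = x$status, nodes = x$nodes,
                 n_active = sum(startsWith(x$activity$state, "active")),
                 n_silenced = sum(x$activity$state == "silenced"))
}

#' Shadow prices of a flux solution
#'
#' @param solution An optimal `flux_solution`.
#' @return Tibble `metabolite_id`, `shadow_price` (the marginal change of
#'   the objective per unit relaxation of that metabolite's steady-state
#'   balance).
#' @export
shadow_prices <- function(solution) {
  if (is.null(solution$shadow_prices)) {
    stop("no duals available (solution not optimal or from a QP)")
  }
  tibble::tibble(metabolite_id = names(solution$shadow_prices),
                 shadow_price = unname(solution$shadow_prices))
}
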