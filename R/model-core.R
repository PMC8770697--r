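#' Parse a reaction formula string
#'
#' The tabular model dialect writes reaction chemistry as
#' `"A[c] + 2 B[c] -> C[e]"`, with `<=>` marking reversible reactions and a
#' missing side marking a boundary reaction (`"A[e] ->"` or `"-> A[c]"`).
#' Metabolite ids carry their compartment as a square-bracket suffix.
#'
#' @param formula A single formula string.
#' @return A list with `stoichiometry` (named numeric vector, negative for
#'   substrates) and `reversible` (logical).
#' @export
#' @examples
#' parse_reaction_formula("glc[c] -> 2 pyr[c] + 2 atp[c]")
parse_reaction_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  arrow <- if (grepl("<=>", formula, fixed = TRUE)) "<=>" else if
    (grepl("->", formula, fixed = TRUE)) "->" else
    stop("no '->' or '<=>' arrow in formula: ", formula)
  sides <- strsplit(formula, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (side == "") return(numeric(0))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(length(terms))
    ids <- character(length(terms))
    for (k in seq_along(terms)) {
      m <- regmatches(terms[k],
                      regexec("^([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?\\s+)?(\\S.*)$",
                              terms[k]))[[1]]
      if (length(m) == 0L || m[3] == "") {
        stop("cannot parse formula term '", terms[k], "' in: ", formula)
      }
      coef <- if (m[2] == "") 1 else as.numeric(trimws(m[2]))
      out[k] <- sign * coef
      ids[k] <- trimws(m[3])
    }
    stats::setNames(out, ids)
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], 1)
  st <- c(lhs, rhs)
  # merge repeated species (e.g. catalytic appearances on both sides)
  if (anyDuplicated(names(st))) {
    st <- tapply(st, names(st), sum)
    st <- stats::setNames(as.numeric(st), names(st))
    st <- st[abs(st) > 0]
  }
  if (!length(st)) stop("empty stoichiometry in formula: ", formula)
  list(stoichiometry = st, reversible = arrow == "<=>")
}

#' Write a stoichiometry back to the formula grammar
#'
#' @param stoichiometry Named numeric vector of signed coefficients.
#' @param reversible Use the `<=>` arrow.
#' @return A formula string; inverse of [parse_reaction_formula()].
#' @export
format_reaction_formula <- function(stoichiometry, reversible = FALSE) {
  fmt <- function(v) {
    if (!length(v)) return("")
    coefs <- abs(unname(v))
    paste(ifelse(abs(coefs - 1) < 1e-12, names(v),
                 paste(format(coefs, trim = TRUE, scientific = FALSE),
                       names(v))),
          collapse = " + ")
  }
  lhs <- fmt(stoichiometry[stoichiometry < 0])
  rhs <- fmt(stoichiometry[stoichiometry > 0])
  arrow <- if (reversible) "<=>" else "->"
  trimws(paste(lhs, arrow, rhs))
}

.compartment_of <- function(met_ids) {
  cmp <- stringr::str_match(met_ids, "\\[([^\\]]+)\\]$")[, 2]
  ifelse(is.na(cmp), "c", cmp)
}

.base_species <- function(met_ids) {
  sub("\\[[^]]+\\]$", "", met_ids)
}

.infer_kind <- function(id, stoich, lb, ub) {
  if (grepl("^(.*_)?EX_", id)) return("exchange")
  if (grepl("^(.*_)?DM_", id)) return("demand")
  if (grepl("^(.*_)?SK_", id)) return("sink")
  if (grepl("biomass", id, ignore.case = TRUE)) return("biomass")
  mets <- names(stoich)
  if (length(mets) == 1L) return("exchange")
  base <- .base_species(mets)
  cmp <- .compartment_of(mets)
  if (length(unique(cmp)) > 1L &&
      any(duplicated(base))) return("transport")
  "internal"
}

#' Assemble a metabolic model
#'
#' The central container: a reaction table and a metabolite table plus an
#' objective, mirroring the stoichiometric description `S`, `lb`, `ub`, `c`
#' of a flux balance problem. Reactions carry their chemistry as a
#' stoichiometry list-column (named coefficient vectors over metabolite
#' ids); reversibility is encoded purely by `lb < 0`.
#'
#' @param reactions Tibble with columns `id`, `name`, `stoichiometry`
#'   (list of named numeric), `lb`, `ub`, `subsystem`, `gpr`, `kind`.
#'   Missing optional columns are filled; `kind` is inferred from id
#'   prefixes (`EX_`/`DM_`/`SK_`, "biomass") and compartment structure
#'   when absent.
#' @param metabolites Tibble with columns `id`, `name`, `compartment`,
#'   `formula`, `charge`; may be omitted, in which case metabolite records
#'   are derived from the stoichiometries.
#' @param objective Named numeric vector of objective weights over reaction
#'   ids; defaults to weight 1 on the biomass reaction if one exists.
#' @param compartments Character vector of compartment tags; derived from
#'   metabolite ids when omitted.
#' @param annotations Free-form provenance list.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(reactions, metabolites = NULL, objective = NULL,
                            compartments = NULL, annotations = list()) {
  reactions <- tibble::as_tibble(reactions)
  stopifnot(all(c("id", "stoichiometry") %in% names(reactions)))
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"lb" %in% names(reactions)) reactions$lb <- -1000
  if (!"ub" %in% names(reactions)) reactions$ub <- 1000
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- ""
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  reactions$subsystem[is.na(reactions$subsystem)] <- ""
  if (!"kind" %in% names(reactions)) reactions$kind <- NA_character_
  need <- is.na(reactions$kind)
  if (any(need)) {
    reactions$kind[need] <- purrr::pmap_chr(
      list(reactions$id[need], reactions$stoichiometry[need],
           reactions$lb[need], reactions$ub[need]), .infer_kind)
  }
  reactions <- reactions[, c("id", "name", "stoichiometry", "lb", "ub",
                             "subsystem", "gpr", "kind")]
  met_ids <- sort(unique(unlist(lapply(reactions$stoichiometry, names))))
  if (is.null(met_ids)) met_ids <- character(0)
  if (is.null(metabolites)) {
    metabolites <- tibble::tibble(
      id = met_ids, name = .base_species(met_ids),
      compartment = .compartment_of(met_ids),
      formula = NA_character_, charge = NA_integer_)
  } else {
    metabolites <- tibble::as_tibble(metabolites)
    stopifnot("id" %in% names(metabolites))
    if (!"name" %in% names(metabolites)) {
      metabolites$name <- .base_species(metabolites$id)
    }
    if (!"compartment" %in% names(metabolites)) {
      metabolites$compartment <- .compartment_of(metabolites$id)
    }
    if (!"formula" %in% names(metabolites)) {
      metabolites$formula <- NA_character_
    }
    if (!"charge" %in% names(metabolites)) {
      metabolites$charge <- NA_integer_
    }
    metabolites <- metabolites[, c("id", "name", "compartment", "formula",
                                   "charge")]
  }
  if (is.null(objective)) {
    bio <- reactions$id[reactions$kind == "biomass"]
    objective <- if (length(bio)) stats::setNames(rep(1, length(bio)), bio)
                 else stats::setNames(numeric(0), character(0))
  }
  if (is.null(compartments)) {
    compartments <- sort(unique(metabolites$compartment))
  }
  structure(list(reactions = reactions, metabolites = metabolites,
                 objective = objective, compartments = compartments,
                 annotations = annotations, coupling = NULL),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites, compartments: ",
      paste(x$compartments, collapse = ", "), "\n", sep = "")
  if (length(x$objective)) {
    cat("objective:", paste(names(x$objective), collapse = " + "), "\n")
  }
  if (!is.null(x$coupling)) {
    cat("coupling constraints:", nrow(x$coupling$rows), "rows\n")
  }
  invisible(x)
}

#' @rdname metabolic_model
#' @param model A `metabolic_model`.
#' @export
reactions <- function(model) model$reactions

#' @rdname metabolic_model
#' @export
metabolites <- function(model) model$metabolites

#' @rdname metabolic_model
#' @export
n_reactions <- function(model) nrow(model$reactions)

#' @rdname metabolic_model
#' @export
n_metabolites <- function(model) nrow(model$metabolites)

.rxn_index <- function(model, ids) {
  idx <- match(ids, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  }
  idx
}

.biomass_id <- function(model, required = TRUE) {
  bio <- model$reactions$id[model$reactions$kind == "biomass"]
  if (!length(bio) && required) stop("model has no biomass reaction")
  bio
}

#' Build the stoichiometric matrix
#'
#' @param model A `metabolic_model`.
#' @param sparse Return a `Matrix` sparse matrix (default) rather than a
#'   dense base matrix.
#' @return The metabolites-by-reactions matrix `S` with dimnames.
#' @export
stoichiometric_matrix <- function(model, sparse = TRUE) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  if (!length(mets) || !length(rxns)) {
    S <- matrix(0, length(mets), length(rxns),
                dimnames = list(mets, rxns))
    return(if (sparse) Matrix::Matrix(S, sparse = TRUE) else S)
  }
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(rxns)) {
    st <- model$reactions$stoichiometry[[k]]
    ri <- match(names(st), mets)
    if (anyNA(ri)) {
      stop("reaction ", rxns[k], " references undeclared metabolite(s): ",
           paste(names(st)[is.na(ri)], collapse = ", "))
    }
    i <- c(i, ri); j <- c(j, rep(k, length(st))); x <- c(x, unname(st))
  }
  S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(mets), length(rxns)),
                            dimnames = list(mets, rxns))
  if (sparse) S else as.matrix(S)
}

#' Structural validation of a metabolic model
#'
#' Checks the container invariants and reports every violation; it never
#' throws on a malformed-but-representable model, so it can be used to
#' audit imported reconstructions the way curation tools do.
#'
#' @param model A `metabolic_model`.
#' @return A `validation_report`: lists `duplicate_ids`,
#'   `orphan_metabolites` (referenced in no reaction, or referenced but
#'   undeclared), `bound_violations` and `unbalanced_reactions`
#'   (structural boundary-reaction violations), each with messages.
#'   The report is "clean" iff all four are empty.
#' @export
validate_model <- function(model) {
  rx <- model$reactions
  mets <- model$metabolites
  dup <- c(rx$id[duplicated(rx$id)], mets$id[duplicated(mets$id)])
  used <- unique(unlist(lapply(rx$stoichiometry, names)))
  orphan <- c(
    setdiff(mets$id, used),                       # declared, never used
    setdiff(used, mets$id))                       # used, never declared
  bv <- rx$id[rx$lb > rx$ub]
  unb <- character(0)
  msg <- character(0)
  for (k in seq_len(nrow(rx))) {
    st <- rx$stoichiometry[[k]]
    if (!length(st)) {
      unb <- c(unb, rx$id[k])
      msg <- c(msg, paste0(rx$id[k], ": empty stoichiometry"))
      next
    }
    if (rx$kind[k] %in% c("exchange", "demand", "sink") && length(st) != 1L) {
      unb <- c(unb, rx$id[k])
      msg <- c(msg, paste0(rx$id[k], ": boundary reaction touches ",
                           length(st), " metabolites"))
    }
    if (rx$kind[k] == "demand" && rx$lb[k] < 0) {
      unb <- c(unb, rx$id[k])
      msg <- c(msg, paste0(rx$id[k], ": demand must be consumption-only"))
    }
  }
  bad_obj <- setdiff(names(model$objective), rx$id)
  if (length(bad_obj)) {
    msg <- c(msg, paste0("objective names unknown reaction(s): ",
                         paste(bad_obj, collapse = ", ")))
  }
  bad_cmp <- setdiff(mets$compartment, model$compartments)
  if (length(bad_cmp)) {
    msg <- c(msg, paste0("metabolite compartment(s) outside declared set: ",
                         paste(bad_cmp, collapse = ", ")))
  }
  structure(list(duplicate_ids = unique(dup),
                 orphan_metabolites = orphan,
                 bound_violations = bv,
                 unbalanced_reactions = unique(unb),
                 messages = msg),
            class = "validation_report")
}

#' @rdname validate_model
#' @param report A `validation_report`.
#' @export
is_clean <- function(report) {
  all(vapply(report[c("duplicate_ids", "orphan_metabolites",
                      "bound_violations", "unbalanced_reactions")],
             length, integer(1)) == 0L) && length(report$messages) == 0L
}

#' @export
print.validation_report <- function(x, ...) {
  if (is_clean(x)) {
    cat("<validation_report> clean\n")
  } else {
    cat("<validation_report>\n")
    for (f in c("duplicate_ids", "orphan_metabolites", "bound_violations",
                "unbalanced_reactions")) {
      if (length(x[[f]])) {
        cat("  ", f, ": ", paste(x[[f]], collapse = ", "), "\n", sep = "")
      }
    }
    for (m in x$messages) cat("  note: ", m, "\n", sep = "")
  }
  invisible(x)
}

#' Normalise exchange reactions to the secretion-positive convention
#'
#' Exchange reactions are written `met[e] ->`, i.e. a single metabolite with
#' coefficient -1, so that positive flux is secretion and negative flux is
#' uptake. Importer-style exchanges (coefficient +1) found in external files
#' are flipped, with their bounds negated and swapped.
#'
#' @param model A `metabolic_model`.
#' @return The model with all exchanges in the canonical orientation.
#' @export
normalize_exchanges <- function(model) {
  rx <- model$reactions
  for (k in which(rx$kind == "exchange")) {
    st <- rx$stoichiometry[[k]]
    if (length(st) == 1L && st > 0) {
      rx$stoichiometry[[k]] <- -st
      old <- c(rx$lb[k], rx$ub[k])
      rx$lb[k] <- -old[2]
      rx$ub[k] <- -old[1]
    }
  }
  model$reactions <- rx
  model
}

#' Compare two models field by field
#'
#' Structural equality: same reactions (ids, bounds, stoichiometries,
#' subsystems, GPRs, kinds), metabolites, objective and compartments,
#' ignoring row order.
#'
#' @param a,b `metabolic_model` objects.
#' @return `TRUE` or a character vector of differences.
#' @export
model_equal <- function(a, b) {
  diffs <- character(0)
  ra <- dplyr::arrange(a$reactions, .data$id)
  rb <- dplyr::arrange(b$reactions, .data$id)
  if (!identical(ra$id, rb$id)) {
    diffs <- c(diffs, "reaction id sets differ")
  } else {
    for (col in c("name", "lb", "ub", "subsystem", "gpr", "kind")) {
      if (!isTRUE(all.equal(ra[[col]], rb[[col]]))) {
        diffs <- c(diffs, paste0("reaction column differs: ", col))
      }
    }
    for (k in seq_len(nrow(ra))) {
      sa <- ra$stoichiometry[[k]]; sb <- rb$stoichiometry[[k]]
      sa <- sa[order(names(sa))]; sb <- sb[order(names(sb))]
      if (!isTRUE(all.equal(sa, sb))) {
        diffs <- c(diffs, paste0("stoichiometry differs: ", ra$id[k]))
      }
    }
  }
  ma <- dplyr::arrange(a$metabolites, .data$id)
  mb <- dplyr::arrange(b$metabolites, .data$id)
  if (!isTRUE(all.equal(as.data.frame(ma), as.data.frame(mb)))) {
    diffs <- c(diffs, "metabolite tables differ")
  }
  oa <- a$objective[order(names(a$objective))]
  ob <- b$objective[order(names(b$objective))]
  if (!isTRUE(all.equal(oa, ob))) diffs <- c(diffs, "objectives differ")
  if (!setequal(a$compartments, b$compartments)) {
    diffs <- c(diffs, "compartment sets differ")
  }
  if (length(diffs)) diffs else TRUE
}
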