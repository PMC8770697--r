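#' Read a metabolic model
#'
#' Three dialects are supported. `tsv` is the primary tabular dialect and
#' mirrors typical reconstruction spreadsheets: a directory holding
#' `reactions.tsv` (columns `id`, `name`, `formula`, `lb`, `ub`,
#' `subsystem`, `gpr`, `kind`, `objective`; `gpr`, `kind` and `objective`
#' optional) and `metabolites.tsv` (`id`, `name`, `compartment`, `formula`,
#' `charge`). Reaction chemistry uses the grammar of
#' [parse_reaction_formula()]. `json` reads the documented schema written
#' by [write_model()]; `sbml` reads SBML Level 3 core plus the FBC bounds
#' and gene-association subset.
#'
#' Imported exchange reactions are normalised to the secretion-positive
#' orientation (see [normalize_exchanges()]), and the result is checked
#' with [validate_model()]; structural errors abort with row-level
#' messages.
#'
#' @param path Directory (tsv) or file (json/sbml).
#' @param format One of `"tsv"`, `"json"`, `"sbml"`; inferred from `path`
#'   when missing.
#' @return A validated `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "tsv", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "tsv"
              else if (grepl("\\.json$", path)) "json"
              else if (grepl("\\.(xml|sbml)$", path)) "sbml"
              else stop("cannot infer model format from path: ", path)
  }
  model <- switch(format,
                  tsv  = .read_model_tsv(path),
                  json = .read_model_json(path),
                  sbml = .read_model_sbml(path))
  model <- normalize_exchanges(model)
  rep <- validate_model(model)
  if (length(rep$duplicate_ids)) {
    stop("duplicate ids in model file: ",
         paste(rep$duplicate_ids, collapse = ", "))
  }
  undeclared <- setdiff(unique(unlist(lapply(model$reactions$stoichiometry,
                                             names))),
                        model$metabolites$id)
  if (length(undeclared)) {
    rows <- which(vapply(model$reactions$stoichiometry,
                         function(s) any(names(s) %in% undeclared),
                         logical(1)))
    stop("stoichiometry references undeclared metabolite(s) ",
         paste(undeclared, collapse = ", "),
         " (reaction row(s) ", paste(rows, collapse = ", "), ")")
  }
  model
}

.read_model_tsv <- function(path) {
  rf <- file.path(path, "reactions.tsv")
  mf <- file.path(path, "metabolites.tsv")
  if (!file.exists(rf)) stop("missing reactions sheet: ", rf)
  rx <- readr::read_tsv(rf, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  for (col in c("id", "formula", "lb", "ub")) {
    if (!col %in% names(rx)) {
      stop("reactions.tsv missing mandatory column: ", col)
    }
  }
  rx$lb <- as.numeric(rx$lb)
  rx$ub <- as.numeric(rx$ub)
  parsed <- vector("list", nrow(rx))
  for (k in seq_len(nrow(rx))) {
    parsed[[k]] <- tryCatch(parse_reaction_formula(rx$formula[k]),
                            error = function(e) {
                              stop("reactions.tsv row ", k, " (",
                                   rx$id[k], "): ", conditionMessage(e),
                                   call. = FALSE)
                            })
  }
  reactions <- tibble::tibble(
    id = rx$id,
    name = if ("name" %in% names(rx)) rx$name else rx$id,
    stoichiometry = lapply(parsed, `[[`, "stoichiometry"),
    lb = rx$lb, ub = rx$ub,
    subsystem = if ("subsystem" %in% names(rx)) rx$subsystem else "",
    gpr = if ("gpr" %in% names(rx)) dplyr::coalesce(rx$gpr, "") else "",
    kind = if ("kind" %in% names(rx)) rx$kind else NA_character_)
  objective <- NULL
  if ("objective" %in% names(rx)) {
    w <- suppressWarnings(as.numeric(rx$objective))
    w[is.na(w)] <- 0
    if (any(w != 0)) objective <- stats::setNames(w[w != 0], rx$id[w != 0])
  }
  metabolites <- NULL
  if (file.exists(mf)) {
    mets <- readr::read_tsv(mf, show_col_types = FALSE,
                            col_types = readr::cols(.default = "c"))
    if (!"id" %in% names(mets)) stop("metabolites.tsv missing column: id")
    if ("charge" %in% names(mets)) mets$charge <- as.integer(mets$charge)
    metabolites <- mets
  }
  metabolic_model(reactions, metabolites, objective = objective)
}

.read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  reactions <- tibble::tibble(
    id = vapply(j$reactions, `[[`, character(1), "id"),
    name = vapply(j$reactions, function(r) r$name %||% r$id, character(1)),
    stoichiometry = lapply(j$reactions, function(r) {
      unlist(r$stoichiometry)
    }),
    lb = vapply(j$reactions, function(r) as.numeric(r$lb), numeric(1)),
    ub = vapply(j$reactions, function(r) as.numeric(r$ub), numeric(1)),
    subsystem = vapply(j$reactions, function(r) r$subsystem %||% "",
                       character(1)),
    gpr = vapply(j$reactions, function(r) r$gpr %||% "", character(1)),
    kind = vapply(j$reactions, function(r) r$kind %||% NA_character_,
                  character(1)))
  metabolites <- if (length(j$metabolites)) tibble::tibble(
    id = vapply(j$metabolites, `[[`, character(1), "id"),
    name = vapply(j$metabolites, function(m) m$name %||% m$id, character(1)),
    compartment = vapply(j$metabolites, function(m) m$compartment %||% "c",
                         character(1)),
    formula = vapply(j$metabolites, function(m) m$formula %||% NA_character_,
                     character(1)),
    charge = vapply(j$metabolites,
                    function(m) as.integer(m$charge %||% NA_integer_),
                    integer(1))) else NULL
  objective <- if (length(j$objective)) {
    stats::setNames(as.numeric(unlist(j$objective)), names(j$objective))
  } else NULL
  metabolic_model(reactions, metabolites, objective = objective,
                  compartments = if (length(j$compartments))
                    as.character(unlist(j$compartments)) else NULL,
                  annotations = j$annotations %||% list())
}

#' Write a metabolic model
#'
#' Inverse of [read_model()] for all three dialects; a written model reads
#' back structurally equal (see [model_equal()]). The JSON schema is an
#' object with `metabolites`, `reactions` (stoichiometry as a
#' metabolite-id-to-coefficient map), `objective`, `compartments` and
#' `annotations`. SBML output covers Level 3 core plus FBC flux bounds,
#' objectives and gene associations; bracketed metabolite ids are
#' sanitised to SBML identifiers with the original id kept in the `name`
#' attribute.
#'
#' @inheritParams read_model
#' @param model A `metabolic_model`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "tsv", "json",
                                                "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path)) "json"
              else if (grepl("\\.(xml|sbml)$", path)) "sbml"
              else "tsv"
  }
  switch(format,
         tsv = .write_model_tsv(model, path),
         json = .write_model_json(model, path),
         sbml = .write_model_sbml(model, path))
  invisible(path)
}

.write_model_tsv <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  rx <- model$reactions
  obj <- rep(0, nrow(rx))
  obj[match(names(model$objective), rx$id)] <- unname(model$objective)
  out <- tibble::tibble(
    id = rx$id, name = rx$name,
    formula = vapply(seq_len(nrow(rx)), function(k) {
      format_reaction_formula(rx$stoichiometry[[k]], rx$lb[k] < 0)
    }, character(1)),
    lb = rx$lb, ub = rx$ub, subsystem = rx$subsystem,
    gpr = rx$gpr, kind = rx$kind, objective = obj)
  readr::write_tsv(out, file.path(path, "reactions.tsv"))
  readr::write_tsv(model$metabolites, file.path(path, "metabolites.tsv"))
}

.write_model_json <- function(model, path) {
  rx <- model$reactions
  j <- list(
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(k) {
      m <- model$metabolites[k, ]
      out <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.na(m$formula)) out$formula <- m$formula
      if (!is.na(m$charge)) out$charge <- m$charge
      out
    }),
    reactions = lapply(seq_len(nrow(rx)), function(k) {
      list(id = rx$id[k], name = rx$name[k],
           stoichiometry = as.list(rx$stoichiometry[[k]]),
           lb = rx$lb[k], ub = rx$ub[k], subsystem = rx$subsystem[k],
           gpr = rx$gpr[k], kind = rx$kind[k])
    }),
    objective = as.list(model$objective),
    compartments = as.list(model$compartments),
    annotations = model$annotations)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

.sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

.write_model_sbml <- function(model, path) {
  fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = fbc, level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "model",
                             "fbc:strict" = "false")
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cmp in model$compartments) {
    xml2::xml_add_child(lc, "compartment", id = .sbml_id(cmp),
                        constant = "true")
  }
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (k in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[k, ]
    sp <- xml2::xml_add_child(
      ls, "species", id = paste0("M_", .sbml_id(m$id)), name = m$id,
      compartment = .sbml_id(m$compartment), constant = "false",
      boundaryCondition = "false", hasOnlySubstanceUnits = "false")
    if (!is.na(m$charge)) xml2::xml_set_attr(sp, "fbc:charge", m$charge)
    if (!is.na(m$formula)) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    }
  }
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  bounds <- unique(c(model$reactions$lb, model$reactions$ub))
  bid <- function(v) paste0("B_", gsub("[-.]", "_", format(v, trim = TRUE,
                                                           scientific = FALSE)))
  for (v in bounds) {
    xml2::xml_add_child(lp, "parameter", id = bid(v),
                        value = format(v, trim = TRUE, scientific = FALSE),
                        constant = "true")
  }
  genes <- sort(unique(unlist(lapply(model$reactions$gpr, function(g) {
    if (!nzchar(g)) character(0) else gpr_genes(g)
  }))))
  if (length(genes)) {
    lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(lg, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", .sbml_id(g)),
                          "fbc:label" = g)
    }
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (k in seq_len(nrow(model$reactions))) {
    r <- model$reactions[k, ]
    rn <- xml2::xml_add_child(
      lr, "reaction", id = paste0("R_", .sbml_id(r$id)), name = r$id,
      reversible = tolower(as.character(r$lb < 0)), fast = "false",
      "fbc:lowerFluxBound" = bid(r$lb), "fbc:upperFluxBound" = bid(r$ub))
    st <- r$stoichiometry[[1]]
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (i in seq_along(subs)) {
        xml2::xml_add_child(lre, "speciesReference",
                            species = paste0("M_", .sbml_id(names(subs)[i])),
                            stoichiometry = format(abs(subs[i]), trim = TRUE,
                                                   scientific = FALSE),
                            constant = "true")
      }
    }
    if (length(prods)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (i in seq_along(prods)) {
        xml2::xml_add_child(lpr, "speciesReference",
                            species = paste0("M_", .sbml_id(names(prods)[i])),
                            stoichiometry = format(prods[i], trim = TRUE,
                                                   scientific = FALSE),
                            constant = "true")
      }
    }
    if (nzchar(r$gpr)) {
      ga <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      .gpr_to_sbml(gpr_parse(r$gpr), ga)
    }
  }
  if (length(model$objective)) {
    lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    for (i in seq_along(model$objective)) {
      xml2::xml_add_child(
        lf, "fbc:fluxObjective",
        "fbc:reaction" = paste0("R_", .sbml_id(names(model$objective)[i])),
        "fbc:coefficient" = format(unname(model$objective[i]), trim = TRUE))
    }
  }
  xml2::write_xml(doc, path)
}

.gpr_to_sbml <- function(node, parent) {
  if (is.character(node)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", .sbml_id(node)))
  } else if (node$op == "and") {
    nd <- xml2::xml_add_child(parent, "fbc:and")
    for (ch in node$args) .gpr_to_sbml(ch, nd)
  } else {
    nd <- xml2::xml_add_child(parent, "fbc:or")
    for (ch in node$args) .gpr_to_sbml(ch, nd)
  }
}

.sbml_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) v <- xml2::xml_attr(node, paste0("fbc:", name))
  v
}

.sbml_from_gpr_node <- function(node) {
  nm <- sub("^.*:", "", xml2::xml_name(node))
  if (nm == "geneProductRef") {
    g <- .sbml_attr(node, "geneProduct")
    return(sub("^G_", "", g))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(seq_along(kids), function(i) {
    p <- .sbml_from_gpr_node(kids[[i]])
    if (grepl(" ", p)) paste0("(", p, ")") else p
  }, character(1))
  paste(parts, collapse = if (nm == "and") " and " else " or ")
}

.read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_id <- xml2::xml_attr(sp, "id")
  sp_name <- xml2::xml_attr(sp, "name")
  met_ids <- ifelse(is.na(sp_name) | sp_name == "", sub("^M_", "", sp_id),
                    sp_name)
  id_map <- stats::setNames(met_ids, sp_id)
  metabolites <- tibble::tibble(
    id = met_ids,
    name = .base_species(met_ids),
    compartment = .compartment_of(met_ids),
    formula = vapply(seq_along(sp), function(i) {
      .sbml_attr(sp[[i]], "chemicalFormula")
    }, character(1)),
    charge = vapply(seq_along(sp), function(i) {
      suppressWarnings(as.integer(.sbml_attr(sp[[i]], "charge")))
    }, integer(1)))
  rns <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  parse_rxn <- function(rn) {
    rid <- xml2::xml_attr(rn, "name")
    if (is.na(rid) || rid == "") rid <- sub("^R_", "",
                                            xml2::xml_attr(rn, "id"))
    sub_refs <- xml2::xml_find_all(rn, "./listOfReactants/speciesReference")
    prod_refs <- xml2::xml_find_all(rn, "./listOfProducts/speciesReference")
    st <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(sub_refs, "stoichiometry")),
                      id_map[xml2::xml_attr(sub_refs, "species")]),
      stats::setNames(as.numeric(xml2::xml_attr(prod_refs, "stoichiometry")),
                      id_map[xml2::xml_attr(prod_refs, "species")]))
    lbp <- .sbml_attr(rn, "lowerFluxBound")
    ubp <- .sbml_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]] else
      if (identical(xml2::xml_attr(rn, "reversible"), "true")) -1000 else 0
    ub <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else 1000
    ga <- xml2::xml_find_first(
      rn, "./*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(ga, "xml_missing")) "" else {
      kids <- xml2::xml_children(ga)
      if (length(kids)) .sbml_from_gpr_node(kids[[1]]) else ""
    }
    list(id = rid, stoichiometry = st, lb = lb, ub = ub, gpr = gpr)
  }
  parsed <- lapply(rns, parse_rxn)
  reactions <- tibble::tibble(
    id = vapply(parsed, `[[`, character(1), "id"),
    name = vapply(parsed, `[[`, character(1), "id"),
    stoichiometry = lapply(parsed, `[[`, "stoichiometry"),
    lb = vapply(parsed, `[[`, numeric(1), "lb"),
    ub = vapply(parsed, `[[`, numeric(1), "ub"),
    subsystem = "",
    gpr = vapply(parsed, `[[`, character(1), "gpr"),
    kind = NA_character_)
  fo <- xml2::xml_find_all(
    doc, ".//*[local-name()='fluxObjective']")
  objective <- NULL
  if (length(fo)) {
    rids <- sub("^R_", "",
                vapply(seq_along(fo),
                       function(i) .sbml_attr(fo[[i]], "reaction"),
                       character(1)))
    rids <- reactions$id[match(rids, .sbml_id(reactions$id))]
    objective <- stats::setNames(
      as.numeric(vapply(seq_along(fo),
                        function(i) .sbml_attr(fo[[i]], "coefficient"),
                        character(1))),
      rids)
  }
  metabolic_model(reactions, metabolites, objective = objective)
}

#' Read or write a medium specification
#'
#' A medium (for instance an MRS- or DMEM-style composition) is a table of
#' exchange-reaction bounds: columns `exchange_id`, `lb`, `ub`, with uptake
#' encoded as a negative lower bound under the secretion-positive
#' convention.
#'
#' @param path A TSV file.
#' @return A `medium_spec` tibble.
#' @export
read_medium <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(exchange_id = "c",
                                               lb = "d", ub = "d"))
  if (!all(c("exchange_id", "lb", "ub") %in% names(m))) {
    stop("medium file needs columns exchange_id, lb, ub: ", path)
  }
  medium_spec(stats::setNames(m$lb, m$exchange_id),
              stats::setNames(m$ub, m$exchange_id))
}

#' @rdname read_medium
#' @param medium A `medium_spec`.
#' @export
write_medium <- function(medium, path) {
  readr::write_tsv(medium, path)
  invisible(path)
}

#' @rdname read_medium
#' @param lb,ub Named numeric vectors of bounds over exchange-reaction ids
#'   (names of `lb` are used; `ub` defaults to 1000 for every entry).
#' @export
medium_spec <- function(lb, ub = NULL) {
  ids <- names(lb)
  stopifnot(!is.null(ids), all(nzchar(ids)))
  if (is.null(ub)) ub <- stats::setNames(rep(1000, length(ids)), ids)
  ub <- ub[ids]
  if (any(lb > ub)) {
    stop("medium entries with lb > ub: ",
         paste(ids[lb > ub], collapse = ", "))
  }
  structure(tibble::tibble(exchange_id = ids, lb = unname(lb),
                           ub = unname(ub)),
            class = c("medium_spec", "tbl_df", "tbl", "data.frame"))
}
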