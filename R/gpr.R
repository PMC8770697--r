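#' Gene-protein-reaction rule parsing and evaluation
#'
#' GPR rules are boolean expressions over gene identifiers, e.g.
#' `"(HK1 and PFK1) or GCK"`. `gpr_parse()` returns an expression tree
#' (gene id strings at the leaves, `list(op = "and"/"or", args = ...)`
#' internally), `gpr_genes()` lists the gene ids, and
#' `gpr_eval_category()` evaluates a rule over categorical expression
#' evidence on the ordinal scale low < medium < high: AND takes the
#' minimum and OR the maximum over genes whose category is known, so
#' unmeasured (`NA`) genes do not veto an otherwise-supported reaction. A
#' rule whose genes are all unknown evaluates to `NA`.
#'
#' @param gpr A GPR rule string. Empty strings are allowed and evaluate to
#'   `NA`.
#' @name gpr
NULL

.gpr_tokens <- function(gpr) {
  x <- gsub("\\(", " ( ", gpr)
  x <- gsub("\\)", " ) ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' @rdname gpr
#' @export
gpr_parse <- function(gpr) {
  toks <- .gpr_tokens(gpr)
  if (!length(toks)) return(NULL)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    t <- toks[pos]; pos <<- pos + 1L; t
  }
  is_op <- function(t, op) {
    !is.na(t) && tolower(t) %in% op
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of GPR rule: ", gpr)
    if (t == "(") {
      advance()
      node <- parse_or()
      if (!identical(peek(), ")")) stop("unbalanced parentheses in GPR: ", gpr)
      advance()
      return(node)
    }
    if (t == ")" || is_op(t, c("and", "or", "&", "&&", "|", "||"))) {
      stop("unexpected token '", t, "' in GPR: ", gpr)
    }
    advance()
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (is_op(peek(), c("and", "&", "&&"))) {
      advance()
      args[[length(args) + 1L]] <- parse_atom()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (is_op(peek(), c("or", "|", "||"))) {
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  node <- parse_or()
  if (!is.na(peek())) stop("trailing token '", peek(), "' in GPR: ", gpr)
  node
}

#' @rdname gpr
#' @export
gpr_genes <- function(gpr) {
  node <- gpr_parse(gpr)
  walk <- function(n) {
    if (is.null(n)) return(character(0))
    if (is.character(n)) return(n)
    unlist(lapply(n$args, walk))
  }
  unique(walk(node))
}

.category_levels <- c("low", "medium", "high")

#' @rdname gpr
#' @param categories Named character vector of categories (`"high"`,
#'   `"medium"`, `"low"` or `NA`) over gene ids.
#' @export
gpr_eval_category <- function(gpr, categories) {
  node <- if (is.character(gpr) && length(gpr) == 1L) gpr_parse(gpr) else gpr
  evl <- function(n) {
    if (is.null(n)) return(NA_integer_)
    if (is.character(n)) {
      v <- if (n %in% names(categories)) categories[[n]] else NA_character_
      if (is.na(v)) return(NA_integer_)
      m <- match(v, .category_levels)
      if (is.na(m)) stop("unknown expression category: ", v)
      return(m)
    }
    vals <- vapply(n$args, evl, integer(1))
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(NA_integer_)
    if (n$op == "and") min(vals) else max(vals)
  }
  r <- evl(node)
  if (is.na(r)) NA_character_ else .category_levels[r]
}

#' Build categorical expression evidence
#'
#' A thin constructor for the gene-to-category evidence table used by
#' [map_expression_to_reactions()], emulating protein-atlas style
#' categorical calls (`high` / `medium` / `low` / `NA`).
#'
#' @param categories Named character vector over gene ids.
#' @param source Free-text label for provenance.
#' @return An `expression_evidence` tibble with columns `gene_id`,
#'   `category`.
#' @export
expression_evidence <- function(categories, source = "unspecified") {
  stopifnot(!is.null(names(categories)))
  bad <- !(categories %in% .category_levels | is.na(categories))
  if (any(bad)) {
    stop("categories outside {high, medium, low, NA}: ",
         paste(unique(categories[bad]), collapse = ", "))
  }
  structure(tibble::tibble(gene_id = names(categories),
                           category = unname(categories)),
            source = source,
            class = c("expression_evidence", "tbl_df", "tbl", "data.frame"))
}

#' @rdname expression_evidence
#' @param path 2-column TSV (`gene_id`, `category`).
#' @export
read_expression_evidence <- function(path, source = path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  if (!all(c("gene_id", "category") %in% names(x))) {
    stop("evidence file needs columns gene_id, category: ", path)
  }
  cat <- x$category
  cat[cat %in% c("NA", "")] <- NA_character_
  expression_evidence(stats::setNames(cat, x$gene_id), source = source)
}

#' Map gene-level expression categories onto reactions
#'
#' Evaluates every reaction's GPR over the categorical evidence
#' (AND = min, OR = max on the low < medium < high scale, unknown genes
#' skipped) and partitions reactions into the core-active set (high or
#' medium support), the core-inactive set (low) and the uncategorized
#' remainder (no GPR, or no measured gene). `overrides` force categories
#' for named genes before evaluation — the hook for literature-curated
#' upregulated gene lists.
#'
#' @param model A `metabolic_model` with parseable GPRs.
#' @param evidence An [expression_evidence] table.
#' @param overrides Optional named character vector of forced categories.
#' @return A `reaction_evidence` tibble: `reaction_id`, `category`
#'   (evaluated gene category or `NA`), `evidence_set` in
#'   `{core_active, core_inactive, uncategorized}`.
#' @export
map_expression_to_reactions <- function(model, evidence, overrides = NULL) {
  categories <- stats::setNames(evidence$category, evidence$gene_id)
  if (!is.null(overrides)) {
    categories[names(overrides)] <- unname(overrides)
  }
  cat_per_rxn <- vapply(model$reactions$gpr, function(g) {
    if (!nzchar(g)) NA_character_ else gpr_eval_category(g, categories)
  }, character(1), USE.NAMES = FALSE)
  evidence_set <- dplyr::case_when(
    is.na(cat_per_rxn) ~ "uncategorized",
    cat_per_rxn %in% c("high", "medium") ~ "core_active",
    TRUE ~ "core_inactive")
  structure(tibble::tibble(reaction_id = model$reactions$id,
                           category = cat_per_rxn,
                           evidence_set = evidence_set),
            class = c("reaction_evidence", "tbl_df", "tbl", "data.frame"))
}
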