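#' Load a gene expression profile
#'
#' Reads a two-column delimited table (gene identifier, nonnegative
#' abundance, e.g. FPKM) into an `expression_profile`.
#'
#' @param path Path to a TSV/CSV file with a header line.
#' @param gene_col,value_col Column names (or 1-based positions) holding the
#'   gene identifier and the abundance; defaults are the first two columns.
#' @param sample_id Label for the sample; defaults to the file name.
#' @return An `expression_profile`: a tibble with columns `gene` and `value`
#'   plus a `sample_id` attribute.
#' @export
load_expression <- function(path, gene_col = 1, value_col = 2,
                            sample_id = NULL) {
  if (!file.exists(path)) {
    ph_abort(sprintf("Expression file not found: %s", path), "pheflux_io_error")
  }
  first <- readLines(path, n = 1)
  if (length(first) == 0) {
    ph_abort("Expression file is empty.", "pheflux_format_error")
  }
  sep <- if (grepl(",", first)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) {
    ph_abort("Expression file contains no data rows.", "pheflux_format_error")
  }
  genes <- as.character(df[[gene_col]])
  raw <- df[[value_col]]
  values <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(values))
  if (length(bad)) {
    ph_abort(
      sprintf("Non-numeric expression value '%s' at data row %d.",
              as.character(raw[bad[1]]), bad[1]),
      "pheflux_format_error"
    )
  }
  expression_profile(setNames(values, genes),
                     sample_id = sample_id %||% basename(path))
}

#' Construct an expression profile from a named vector
#'
#' @param values Named numeric vector: gene identifier to nonnegative
#'   abundance.
#' @param sample_id Sample label.
#' @return An `expression_profile` tibble (`gene`, `value`).
#' @export
expression_profile <- function(values, sample_id = "sample") {
  if (length(values) == 0) {
    ph_abort("Expression profile is empty.", "pheflux_validation_error")
  }
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    ph_abort("Expression values must be named by gene identifier.",
             "pheflux_validation_error")
  }
  neg <- which(values < 0)
  if (length(neg)) {
    ph_abort(
      sprintf("Negative expression value for gene(s): %s",
              paste(names(values)[head(neg, 5)], collapse = ", ")),
      "pheflux_validation_error"
    )
  }
  if (anyDuplicated(names(values))) {
    dup <- unique(names(values)[duplicated(names(values))])
    ph_abort(sprintf("Duplicate gene identifier(s): %s",
                     paste(head(dup, 5), collapse = ", ")),
             "pheflux_validation_error")
  }
  structure(
    tibble::tibble(gene = names(values), value = unname(values)),
    sample_id = sample_id,
    class = c("expression_profile", class(tibble::tibble()))
  )
}

# ---- GPR rules -------------------------------------------------------------

# Tokenize a boolean gene-association string: identifiers, "(", ")", and the
# operators and/or (case-insensitive; "&&"/"&" and "||"/"|" accepted).
gpr_tokenize <- function(rule) {
  rule <- gsub("&&|&", " and ", rule)
  rule <- gsub("\\|\\||\\|", " or ", rule)
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

# Recursive-descent parser.  Grammar (AND binds tighter than OR):
#   expr   := term { OR term }
#   term   := factor { AND factor }
#   factor := GENE | "(" expr ")"
# Returns a nested list tree: list(op = "and"/"or", args = ...) or
# list(gene = "id").
parse_gpr <- function(rule) {
  toks <- gpr_tokenize(rule)
  if (length(toks) == 0) return(NULL)
  pos <- 1
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() {
    t <- peek()
    pos <<- pos + 1
    t
  }
  is_op <- function(t, op) !is.na(t) && tolower(t) == op

  parse_expr <- function() {
    args <- list(parse_term())
    while (is_op(peek(), "or")) {
      take()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_op(peek(), "and")) {
      take()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) {
      ph_abort(sprintf("Unexpected end of GPR rule: '%s'", rule),
               "pheflux_gpr_syntax_error")
    }
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")")) {
        ph_abort(sprintf("Unbalanced parentheses in GPR rule: '%s'", rule),
                 "pheflux_gpr_syntax_error")
      }
      return(e)
    }
    if (t == ")" || is_op(t, "and") || is_op(t, "or")) {
      ph_abort(sprintf("Malformed GPR rule near '%s': '%s'", t, rule),
               "pheflux_gpr_syntax_error")
    }
    list(gene = t)
  }

  tree <- parse_expr()
  if (pos <= length(toks)) {
    ph_abort(sprintf("Trailing tokens in GPR rule: '%s'", rule),
             "pheflux_gpr_syntax_error")
  }
  tree
}

#' Evaluate a gene-protein-reaction rule against an expression profile
#'
#' AND nodes (enzyme complexes) evaluate to the minimum of their children;
#' OR nodes (isozymes) to the sum (or, optionally, the maximum).  Genes
#' absent from the profile are dropped from their node; a node whose
#' children are all missing is itself missing; an empty rule is missing
#' (`NA`).
#'
#' @param rule GPR string in the usual `and`/`or` grammar with parentheses.
#' @param profile An [expression_profile()] (or named numeric vector).
#' @param or One of `"sum"` (default: isozymes add catalytic capacity) or
#'   `"max"`.
#' @return A single abundance, or `NA_real_` when the rule cannot be
#'   evaluated.
#' @examples
#' p <- expression_profile(c(gA = 2, gB = 5, gC = 1))
#' evaluate_gpr("(gA and gB) or gC", p)  # min(2,5) + 1 = 3
#' @export
evaluate_gpr <- function(rule, profile, or = c("sum", "max")) {
  or <- match.arg(or)
  values <- if (is.data.frame(profile)) {
    setNames(profile$value, profile$gene)
  } else {
    profile
  }
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NA_real_)
  tree <- parse_gpr(rule)
  eval_node <- function(node) {
    if (!is.null(node$gene)) {
      if (node$gene %in% names(values)) return(values[[node$gene]])
      return(NA_real_)
    }
    vals <- vapply(node$args, eval_node, numeric(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) return(NA_real_)
    if (node$op == "and") {
      min(vals)
    } else if (or == "sum") {
      sum(vals)
    } else {
      max(vals)
    }
  }
  eval_node(tree)
}

#' Map gene expression onto the reactions of a split network
#'
#' Evaluates each original reaction's GPR against the profile; reactions
#' whose GPR is empty or evaluates to missing receive the median of the
#' GPR-derived values.  Both split directions of a reversible reaction share
#' the same value (one enzyme catalyzes both directions).  All values are
#' floored at `epsilon` so that downstream logarithms are defined.
#'
#' @param split A [split_reversible()] network.
#' @param profile An [expression_profile()].
#' @param epsilon Strictly positive floor; default `1e-8`.
#' @param or OR-node semantics passed to [evaluate_gpr()].
#' @return A `reaction_expression`: tibble with columns `reaction_id` (split
#'   identifiers), `g` (strictly positive abundance), `imputed` (logical),
#'   and attributes `G` (sum of `g`) and `sample_id`.
#' @export
map_expression <- function(split, profile, epsilon = 1e-8,
                           or = c("sum", "max")) {
  or <- match.arg(or)
  if (!inherits(split, "split_network")) {
    ph_abort("`split` must be a split_network.", "pheflux_validation_error")
  }
  if (epsilon <= 0) {
    ph_abort("`epsilon` must be strictly positive.", "pheflux_validation_error")
  }
  rx <- split$base$reactions
  vals <- vapply(rx$gpr, evaluate_gpr, numeric(1),
                 profile = profile, or = or, USE.NAMES = FALSE)
  assigned <- !is.na(vals)
  if (!any(assigned)) {
    ph_abort(
      "No reaction received a GPR-derived expression value; cannot impute a median.",
      "pheflux_mapping_error"
    )
  }
  med <- stats::median(vals[assigned])
  vals[!assigned] <- med
  vals <- pmax(vals, epsilon)

  g <- vals[split$orig_index]
  imputed <- !assigned[split$orig_index]
  out <- tibble::tibble(
    reaction_id = split$reaction_ids,
    g = g,
    imputed = imputed
  )
  structure(
    out,
    G = sum(g),
    sample_id = attr(profile, "sample_id") %||% "sample",
    epsilon = epsilon,
    class = c("reaction_expression", class(tibble::tibble()))
  )
}
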