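#' Construct a genome-scale metabolic network object
#'
#' Builds the in-memory representation of a constraint-based metabolic model:
#' a stoichiometric matrix together with per-reaction bounds, reversibility
#' flags, gene-protein-reaction (GPR) rules and pathway (subsystem)
#' annotations.  The steady-state polytope of the network is
#' \eqn{P = \{v : S v = 0, LB \le v \le UB\}}.
#'
#' @param S Stoichiometric matrix (metabolites x reactions); dense or sparse.
#'   Row names are metabolite identifiers, column names reaction identifiers
#'   (or supply `metabolite_ids` / `reaction_ids`).
#' @param reactions A data frame with one row per reaction and columns
#'   `id`, `lb`, `ub`, `reversible`, `gpr`, `subsystem`.  Missing columns are
#'   filled with defaults (bounds from reversibility, empty GPR/subsystem).
#' @param metabolite_ids,reaction_ids Identifier vectors; default taken from
#'   the dimnames of `S`.
#' @param biomass_reaction Optional identifier of the biomass reaction.
#' @return An object of class `metabolic_network` with elements
#'   `metabolites`, `reactions` (a tibble), `S` (sparse `dgCMatrix`),
#'   `biomass_reaction`, and `exchange_reactions`.
#' @examples
#' S <- matrix(c(1, -1, 0, 1, 0, 1, -1, -1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("A", "B"), c("v1", "v2", "v3", "v4")))
#' net <- metabolic_network(S)
#' net$exchange_reactions
#' @export
metabolic_network <- function(S, reactions = NULL, metabolite_ids = NULL,
                              reaction_ids = NULL, biomass_reaction = NULL) {
  metabolite_ids <- metabolite_ids %||% rownames(S)
  reaction_ids <- reaction_ids %||% colnames(S)
  if (is.null(metabolite_ids)) {
    metabolite_ids <- paste0("m", seq_len(nrow(S)))
  }
  if (is.null(reaction_ids)) {
    reaction_ids <- paste0("r", seq_len(ncol(S)))
  }
  S <- Matrix::Matrix(as(S, "CsparseMatrix"), sparse = TRUE)
  dimnames(S) <- list(metabolite_ids, reaction_ids)

  if (is.null(reactions)) {
    reactions <- tibble::tibble(id = reaction_ids)
  }
  reactions <- tibble::as_tibble(reactions)
  if (!"id" %in% names(reactions)) {
    ph_abort("`reactions` must have an `id` column.", "pheflux_validation_error")
  }
  if (!"reversible" %in% names(reactions)) {
    reactions$reversible <- if ("lb" %in% names(reactions)) {
      reactions$lb < 0
    } else {
      FALSE
    }
  }
  if (!"lb" %in% names(reactions)) {
    reactions$lb <- ifelse(reactions$reversible, -1000, 0)
  }
  if (!"ub" %in% names(reactions)) reactions$ub <- 1000
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  reactions$subsystem[is.na(reactions$subsystem)] <- ""
  reactions <- reactions[match(reaction_ids, reactions$id),
                         c("id", "lb", "ub", "reversible", "gpr", "subsystem")]

  net <- structure(
    list(
      metabolites = as.character(metabolite_ids),
      reactions = reactions,
      S = S,
      biomass_reaction = biomass_reaction,
      exchange_reactions = character(0)
    ),
    class = "metabolic_network"
  )
  net$exchange_reactions <- detect_exchanges(net)
  validate_network(net)
}

#' Validate a metabolic network
#'
#' Checks structural invariants: matching dimensions, at least one reaction
#' and metabolite, ordered bounds, and membership of the biomass reaction.
#'
#' @param network A `metabolic_network`.
#' @return The network, invisibly unchanged, if valid; otherwise an error of
#'   class `pheflux_validation_error`.
#' @export
validate_network <- function(network) {
  S <- network$S
  rx <- network$reactions
  if (ncol(S) == 0 || nrow(rx) == 0) {
    ph_abort("Model has zero reactions.", "pheflux_validation_error")
  }
  if (nrow(S) == 0) {
    ph_abort("Model has zero metabolites.", "pheflux_validation_error")
  }
  if (nrow(S) != length(network$metabolites) || ncol(S) != nrow(rx)) {
    ph_abort(
      sprintf(
        "Stoichiometric matrix is %d x %d but %d metabolites and %d reactions are declared.",
        nrow(S), ncol(S), length(network$metabolites), nrow(rx)
      ),
      "pheflux_validation_error"
    )
  }
  if (!identical(colnames(S), rx$id)) {
    ph_abort("Reaction identifiers do not match the columns of S.",
             "pheflux_validation_error")
  }
  if (anyDuplicated(rx$id)) {
    ph_abort("Duplicate reaction identifiers.", "pheflux_validation_error")
  }
  if (anyDuplicated(network$metabolites)) {
    ph_abort("Duplicate metabolite identifiers.", "pheflux_validation_error")
  }
  bad <- which(rx$lb > rx$ub)
  if (length(bad)) {
    ph_abort(
      sprintf("lower_bound > upper_bound for reaction(s): %s",
              paste(rx$id[bad], collapse = ", ")),
      "pheflux_validation_error"
    )
  }
  if (!is.null(network$biomass_reaction) &&
      !network$biomass_reaction %in% rx$id) {
    ph_abort(
      sprintf("Biomass reaction '%s' is not in the model.",
              network$biomass_reaction),
      "pheflux_validation_error"
    )
  }
  invisible(network)
}

# A reaction is an exchange (boundary) reaction if its stoichiometry has
# metabolites on only one side: all nonzero coefficients share a sign.
detect_exchanges <- function(network) {
  S <- network$S
  is_ex <- vapply(seq_len(ncol(S)), function(j) {
    s <- S[, j]
    s <- s[s != 0]
    length(s) > 0 && (all(s > 0) || all(s < 0))
  }, logical(1))
  network$reactions$id[is_ex]
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf(
    "<metabolic_network> %d metabolites, %d reactions (%d reversible, %d exchanges)\n",
    length(x$metabolites), nrow(x$reactions),
    sum(x$reactions$reversible), length(x$exchange_reactions)
  ))
  if (!is.null(x$biomass_reaction)) {
    cat("  biomass reaction:", x$biomass_reaction, "\n")
  }
  invisible(x)
}

#' Load a genome-scale metabolic model from file
#'
#' Reads either an SBML Level 3 document with the FBC package (gene products,
#' flux bounds, and optionally `groups` subsystems) or the common JSON
#' metabolic-model dialect used by constraint-based modeling toolkits.
#'
#' Reactions without an explicit bound receive the conventional defaults
#' (`-1000` or `0` lower, `1000` upper, depending on reversibility), so that
#' after splitting all bounds are `[0, 1000]`.
#'
#' @param path Path to the model file.
#' @param dialect One of `"auto"` (by file extension), `"sbml"`, `"json"`.
#' @return A validated [metabolic_network()].
#' @export
load_model <- function(path, dialect = c("auto", "sbml", "json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    ph_abort(sprintf("Model file not found: %s", path), "pheflux_io_error")
  }
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  switch(dialect,
    json = read_json_model(path),
    sbml = read_sbml_model(path)
  )
}

# JSON metabolic-model dialect: top-level lists `metabolites`, `reactions`
# (with a `metabolites` coefficient map, bounds, `gene_reaction_rule`,
# `subsystem`, `objective_coefficient`), and `genes`.
read_json_model <- function(path) {
  m <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      ph_abort(sprintf("Failed to parse JSON model '%s': %s", path,
                       conditionMessage(e)), "pheflux_format_error")
    }
  )
  if (is.null(m$reactions) || length(m$reactions) == 0) {
    ph_abort("JSON model declares no reactions.", "pheflux_validation_error")
  }
  met_ids <- vapply(m$metabolites, function(x) as.character(x$id), character(1))
  rxns <- m$reactions
  rx_ids <- vapply(rxns, function(x) as.character(x$id), character(1))

  triplets <- purrr::map(seq_along(rxns), function(j) {
    coefs <- rxns[[j]]$metabolites
    if (length(coefs) == 0) return(NULL)
    rows <- match(names(coefs), met_ids)
    if (anyNA(rows)) {
      ph_abort(
        sprintf("Reaction '%s' references undeclared metabolite(s): %s",
                rx_ids[j],
                paste(names(coefs)[is.na(rows)], collapse = ", ")),
        "pheflux_format_error"
      )
    }
    data.frame(i = rows, j = j, x = as.numeric(unlist(coefs)))
  })
  trip <- do.call(rbind, triplets)
  S <- Matrix::sparseMatrix(
    i = trip$i, j = trip$j, x = trip$x,
    dims = c(length(met_ids), length(rx_ids)),
    dimnames = list(met_ids, rx_ids)
  )

  num_or <- function(x, default) if (is.null(x)) default else as.numeric(x)
  chr_or <- function(x, default) if (is.null(x)) default else as.character(x)
  lb <- vapply(rxns, function(x) num_or(x$lower_bound, NA_real_), numeric(1))
  ub <- vapply(rxns, function(x) num_or(x$upper_bound, NA_real_), numeric(1))
  gpr <- vapply(rxns, function(x) chr_or(x$gene_reaction_rule, ""), character(1))
  subsystem <- vapply(rxns, function(x) chr_or(x$subsystem, ""), character(1))
  objc <- vapply(rxns, function(x) num_or(x$objective_coefficient, 0), numeric(1))
  rev_flag <- ifelse(is.na(lb), FALSE, lb < 0)
  lb[is.na(lb)] <- ifelse(rev_flag[is.na(lb)], -1000, 0)
  ub[is.na(ub)] <- 1000

  biomass <- if (any(objc != 0)) rx_ids[which(objc != 0)[1]] else NULL
  metabolic_network(
    S,
    reactions = tibble::tibble(id = rx_ids, lb = lb, ub = ub,
                               reversible = rev_flag, gpr = gpr,
                               subsystem = subsystem),
    biomass_reaction = biomass
  )
}

# SBML Level 3 + FBC reader built on xml2.  Elements are located by local
# name so the reader is tolerant of prefix choices; FBC attributes are read
# from the attribute set with or without their namespace prefix.
read_sbml_model <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      ph_abort(sprintf("Failed to parse SBML model '%s': %s", path,
                       conditionMessage(e)), "pheflux_format_error")
    }
  )
  attr_any <- function(attrs, name) {
    hit <- grep(paste0("(^|:)", name, "$"), names(attrs))
    if (length(hit)) attrs[[hit[1]]] else NA_character_
  }

  # global parameters: id -> numeric value (bound references)
  params <- xml2::xml_find_all(doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  param_val <- setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id")
  )

  # species; boundary-condition species are outside the mass balance
  species <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  sp_id <- xml2::xml_attr(species, "id")
  sp_boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  met_ids <- sp_id[!sp_boundary]

  # gene products: internal id -> label (fall back to the id itself)
  gps <- xml2::xml_find_all(doc, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  gp_label <- character(0)
  if (length(gps)) {
    ids <- labels <- character(length(gps))
    for (k in seq_along(gps)) {
      a <- xml2::xml_attrs(gps[[k]])
      ids[k] <- attr_any(a, "id")
      lb <- attr_any(a, "label")
      labels[k] <- if (is.na(lb)) ids[k] else lb
    }
    gp_label <- setNames(labels, ids)
  }

  gpr_from_node <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- attr_any(xml2::xml_attrs(node), "geneProduct")
      return(if (!is.na(ref) && ref %in% names(gp_label)) gp_label[[ref]] else ref)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpr_from_node, character(1))
    op <- switch(nm, "and" = " and ", "or" = " or ", " and ")
    paste0("(", paste(parts, collapse = op), ")")
  }

  rx_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rx_nodes) == 0) {
    ph_abort("SBML model declares no reactions.", "pheflux_validation_error")
  }
  n <- length(rx_nodes)
  rx_ids <- character(n)
  lb <- ub <- numeric(n)
  rev_flag <- logical(n)
  gpr <- subsystem <- character(n)
  trip_i <- trip_j <- integer(0)
  trip_x <- numeric(0)

  for (j in seq_len(n)) {
    node <- rx_nodes[[j]]
    a <- xml2::xml_attrs(node)
    rx_ids[j] <- attr_any(a, "id")
    rev_flag[j] <- identical(attr_any(a, "reversible"), "true")
    lb_ref <- attr_any(a, "lowerFluxBound")
    ub_ref <- attr_any(a, "upperFluxBound")
    lb[j] <- if (!is.na(lb_ref) && lb_ref %in% names(param_val)) {
      param_val[[lb_ref]]
    } else if (rev_flag[j]) -1000 else 0
    ub[j] <- if (!is.na(ub_ref) && ub_ref %in% names(param_val)) {
      param_val[[ub_ref]]
    } else 1000

    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(
        node, sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']", side)
      )
      for (r in refs) {
        sp <- xml2::xml_attr(r, "species")
        st <- xml2::xml_attr(r, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        if (side == "listOfReactants") st <- -st
        row <- match(sp, met_ids)
        if (is.na(row)) next  # boundary species: outside the balance
        trip_i <- c(trip_i, row)
        trip_j <- c(trip_j, j)
        trip_x <- c(trip_x, st)
      }
    }

    gpa <- xml2::xml_find_first(node, "./*[local-name()='geneProductAssociation']")
    gpr[j] <- if (inherits(gpa, "xml_missing")) {
      ""
    } else {
      kids <- xml2::xml_children(gpa)
      if (length(kids) == 0) "" else gpr_from_node(kids[[1]])
    }
    subsystem[j] <- ""
  }

  # subsystems from the `groups` package, when present
  groups <- xml2::xml_find_all(doc, ".//*[local-name()='listOfGroups']/*[local-name()='group']")
  for (g in groups) {
    a <- xml2::xml_attrs(g)
    label <- attr_any(a, "name")
    if (is.na(label)) label <- attr_any(a, "id")
    members <- xml2::xml_find_all(g, ".//*[local-name()='member']")
    for (mref in members) {
      idref <- attr_any(xml2::xml_attrs(mref), "idRef")
      hit <- match(idref, rx_ids)
      if (!is.na(hit)) subsystem[hit] <- label
    }
  }

  # biomass: the active FBC objective's flux objective, when present
  biomass <- NULL
  fobj <- xml2::xml_find_first(doc, ".//*[local-name()='listOfObjectives']//*[local-name()='fluxObjective']")
  if (!inherits(fobj, "xml_missing")) {
    ref <- attr_any(xml2::xml_attrs(fobj), "reaction")
    if (!is.na(ref) && ref %in% rx_ids) biomass <- ref
  }

  S <- Matrix::sparseMatrix(
    i = trip_i, j = trip_j, x = trip_x,
    dims = c(length(met_ids), n),
    dimnames = list(met_ids, rx_ids)
  )
  metabolic_network(
    S,
    reactions = tibble::tibble(id = rx_ids, lb = lb, ub = ub,
                               reversible = rev_flag, gpr = gpr,
                               subsystem = subsystem),
    biomass_reaction = biomass
  )
}

#' Update exchange bounds from a medium definition
#'
#' Applies uptake/secretion constraints to named reactions, leaving every
#' other bound untouched.
#'
#' @param network A `metabolic_network`.
#' @param uptakes A data frame with columns `reaction_id`, `lb` and
#'   optionally `ub`, or a named list whose elements are `c(lb, ub)` or a
#'   single lower bound.
#' @return The updated network.
#' @export
apply_medium <- function(network, uptakes) {
  validate_network(network)
  if (is.data.frame(uptakes)) {
    ids <- as.character(uptakes$reaction_id)
    lbs <- as.numeric(uptakes$lb)
    ubs <- if ("ub" %in% names(uptakes)) as.numeric(uptakes$ub) else rep(NA_real_, length(ids))
  } else {
    ids <- names(uptakes)
    lbs <- vapply(uptakes, function(x) as.numeric(x[1]), numeric(1))
    ubs <- vapply(uptakes, function(x) {
      if (length(x) > 1) as.numeric(x[2]) else NA_real_
    }, numeric(1))
  }
  if (length(ids) == 0) return(network)
  missing_ids <- setdiff(ids, network$reactions$id)
  if (length(missing_ids)) {
    ph_abort(sprintf("Unknown reaction(s) in medium: %s",
                     paste(missing_ids, collapse = ", ")),
             "pheflux_lookup_error")
  }
  rows <- match(ids, network$reactions$id)
  network$reactions$lb[rows] <- lbs
  keep <- !is.na(ubs)
  network$reactions$ub[rows[keep]] <- ubs[keep]
  network$reactions$reversible[rows] <- network$reactions$lb[rows] < 0
  validate_network(network)
}

#' Read a medium file
#'
#' Parses a two- or three-column delimited text file (`reaction_id`, `lb`,
#' optional `ub`) into the format accepted by [apply_medium()].
#'
#' @param path Path to the delimited file (tab or comma separated; a header
#'   line is detected automatically).
#' @return A tibble with columns `reaction_id`, `lb`, `ub`.
#' @export
read_medium <- function(path) {
  if (!file.exists(path)) {
    ph_abort(sprintf("Medium file not found: %s", path), "pheflux_io_error")
  }
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else "\t"
  header <- suppressWarnings(is.na(as.numeric(strsplit(first, sep)[[1]][2])))
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) {
    ph_abort("Medium file needs at least two columns (reaction_id, lb).",
             "pheflux_format_error")
  }
  names(df)[1:2] <- c("reaction_id", "lb")
  if (ncol(df) >= 3) names(df)[3] <- "ub" else df$ub <- NA_real_
  tibble::as_tibble(df[, c("reaction_id", "lb", "ub")])
}
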