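#' Toy network with a thermodynamically infeasible cycle
#'
#' A two-metabolite, four-reaction network: `v1` (uptake of A), `v2`
#' (A to B), `v3` (B to A, forming a thermodynamically infeasible cycle
#' with `v2`), and `v4` (secretion of B).  All reactions are irreversible
#' with bounds `[0, 1000]`, and each carries a one-gene GPR (`g1`..`g4`) so
#' expression scenarios map directly onto reactions.
#'
#' Steady state forces `v1 = v4 = v2 - v3`, so any exchange flux must
#' traverse the cycle pair; the network isolates how flux-inference methods
#' respond to highly expressed cycle enzymes.
#'
#' @return A [metabolic_network()] with `M = 2` metabolites and `N = 4`
#'   reactions.
#' @export
toy_tic_network <- function() {
  S <- matrix(
    c(1, -1, 1, 0,
      0, 1, -1, -1),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("A", "B"), c("v1", "v2", "v3", "v4"))
  )
  metabolic_network(
    S,
    reactions = tibble::tibble(
      id = c("v1", "v2", "v3", "v4"),
      lb = 0, ub = 1000, reversible = FALSE,
      gpr = c("g1", "g2", "g3", "g4"),
      subsystem = c("Exchange", "Cycle", "Cycle", "Exchange")
    )
  )
}

#' Expression presets for the toy cycle network
#'
#' Three scenarios: `"equal"` (all genes at 1), `"double"` (`g3` at twice
#' every other gene) and `"tenfold"` (`g3` one order of magnitude above the
#' rest).
#'
#' @param scenario One of `"equal"`, `"double"`, `"tenfold"`.
#' @return An [expression_profile()] over genes `g1`..`g4`.
#' @export
toy_expression <- function(scenario = c("equal", "double", "tenfold")) {
  scenario <- match.arg(scenario)
  g3 <- switch(scenario, equal = 1, double = 2, tenfold = 10)
  expression_profile(c(g1 = 1, g2 = 1, g3 = g3, g4 = 1),
                     sample_id = paste0("toy_", scenario))
}

#' Generate a random layered metabolic network
#'
#' Builds a feasible synthetic genome-scale-like network for benchmarking:
#' metabolites are arranged in layers; every metabolite of layer `l + 1` is
#' produced by at least one reaction consuming a random metabolite of layer
#' `l`, plus extra random intra/cross-layer conversions; the first layer is
#' fed by uptake exchanges and the last layer drained by secretions and a
#' biomass sink.  Every internal reaction carries a dedicated single-gene
#' GPR (`G_<reaction>`), so synthetic transcriptomes map one-to-one onto
#' reactions.  Layers are labeled with pathway names, the first two layers
#' as glycolysis and TCA so carbon-core scoring subsets are exercised.
#'
#' @param n_internal Number of internal conversion reactions (total reaction
#'   count is `n_internal` plus the exchanges); default 30.
#' @param n_layers Number of metabolite layers; default 4.
#' @param mets_per_layer Metabolites per layer; default 3.
#' @param uptake_ub Upper bound on uptake exchanges; default 10.
#' @param frac_reversible Fraction of internal reactions marked reversible;
#'   default 0.2.
#' @param seed Integer seed; the network is deterministic given it.
#' @return A [metabolic_network()] with one-gene-per-reaction GPRs and a
#'   biomass reaction.
#' @export
make_synthetic_network <- function(n_internal = 30, n_layers = 4,
                                   mets_per_layer = 3, uptake_ub = 10,
                                   frac_reversible = 0.2, seed = 1L) {
  withr::with_seed(seed, {
    layers <- lapply(seq_len(n_layers), function(l) {
      paste0("M", l, "_", seq_len(mets_per_layer))
    })
    mets <- unlist(layers)

    rx_list <- list()
    add_rx <- function(id, coefs, lb = 0, ub = 1000, reversible = FALSE,
                       subsystem = "", gpr = NULL) {
      rx_list[[length(rx_list) + 1]] <<- list(
        id = id, coefs = coefs, lb = lb, ub = ub, reversible = reversible,
        subsystem = subsystem, gpr = gpr %||% paste0("G_", id)
      )
    }

    pathway_names <- c("Glycolysis/Gluconeogenesis", "Citric Acid Cycle",
                       paste("Pathway", seq_len(max(1, n_layers - 2))))

    # spanning reactions: every non-source metabolite is producible
    k <- 0
    for (l in seq_len(n_layers - 1)) {
      for (m_to in layers[[l + 1]]) {
        k <- k + 1
        m_from <- sample(layers[[l]], 1)
        add_rx(sprintf("R%02d", k),
               setNames(c(-1, 1), c(m_from, m_to)),
               subsystem = pathway_names[min(l, length(pathway_names))])
      }
    }
    # additional random conversions until n_internal reactions exist
    while (k < n_internal) {
      k <- k + 1
      l <- sample(seq_len(n_layers - 1), 1)
      m_from <- sample(layers[[l]], 1)
      m_to <- sample(setdiff(unlist(layers[seq(l, min(l + 1, n_layers))]),
                             m_from), 1)
      rev_flag <- stats::runif(1) < frac_reversible
      add_rx(sprintf("R%02d", k),
             setNames(c(-1, 1), c(m_from, m_to)),
             lb = if (rev_flag) -1000 else 0,
             reversible = rev_flag,
             subsystem = pathway_names[min(l, length(pathway_names))])
    }
    # exchanges: uptake of layer 1, secretion of last layer
    for (m in layers[[1]]) {
      add_rx(paste0("EX_", m), setNames(1, m), ub = uptake_ub,
             subsystem = "Exchange")
    }
    for (m in layers[[n_layers]]) {
      add_rx(paste0("SEC_", m), setNames(-1, m), subsystem = "Exchange")
    }
    add_rx("BIOMASS", setNames(rep(-1, length(layers[[n_layers]])),
                               layers[[n_layers]]),
           subsystem = "Biomass", gpr = "")

    ids <- vapply(rx_list, `[[`, character(1), "id")
    trip <- purrr::map(seq_along(rx_list), function(j) {
      coefs <- rx_list[[j]]$coefs
      data.frame(i = match(names(coefs), mets), j = j, x = unname(coefs))
    })
    trip <- do.call(rbind, trip)
    S <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                              dims = c(length(mets), length(ids)),
                              dimnames = list(mets, ids))
    metabolic_network(
      S,
      reactions = tibble::tibble(
        id = ids,
        lb = vapply(rx_list, `[[`, numeric(1), "lb"),
        ub = vapply(rx_list, `[[`, numeric(1), "ub"),
        reversible = vapply(rx_list, `[[`, logical(1), "reversible"),
        gpr = vapply(rx_list, `[[`, character(1), "gpr"),
        subsystem = vapply(rx_list, `[[`, character(1), "subsystem")
      ),
      biomass_reaction = "BIOMASS"
    )
  })
}
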