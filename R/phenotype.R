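#' Glucose-to-lactate yield of a flux solution
#'
#' The Warburg-effect statistic \eqn{v_{lac}/v_{glc}}: absolute net lactate
#' secretion over absolute net glucose uptake.  Invariant to uniform
#' rescaling of the flux vector.
#'
#' @param solution A [flux_solution()].
#' @param lactate_rx,glucose_rx Identifiers of the lactate secretion and
#'   glucose uptake reactions.
#' @return The yield ratio, or `NA_real_` when the glucose flux is zero.
#' @export
lactate_yield <- function(solution, lactate_rx, glucose_rx) {
  net <- setNames(solution$fluxes$net_flux, solution$fluxes$reaction_id)
  for (id in c(lactate_rx, glucose_rx)) {
    if (!id %in% names(net)) {
      ph_abort(sprintf("Reaction '%s' not found in the solution.", id),
               "pheflux_lookup_error")
    }
  }
  vglc <- abs(net[[glucose_rx]])
  if (vglc == 0) return(NA_real_)
  abs(net[[lactate_rx]]) / vglc
}

#' Pathway enrichment indices of a flux solution
#'
#' For each pathway, the average net-flux magnitude over its member
#' reactions normalized by the sum of all net-flux magnitudes in the
#' network:
#' \deqn{E(p) = \frac{\mathrm{mean}_{i \in p} |v_i|}{\sum_j |v_j|}.}
#' Magnitudes use net fluxes (\eqn{|v^f - v^r|}), so a balanced
#' thermodynamically infeasible cycle contributes nothing.  Indices are
#' invariant to uniform flux rescaling and lie in `[0, 1]`.
#'
#' @param solution A [flux_solution()].
#' @param membership Named list mapping pathway label to a character vector
#'   of reaction identifiers, or `NULL` to derive it from the network
#'   subsystem annotations via [pathway_membership()].
#' @return A tibble with columns `pathway`, `n_reactions`, `enrichment`.
#' @export
pathway_enrichment <- function(solution, membership) {
  net <- setNames(abs(solution$fluxes$net_flux), solution$fluxes$reaction_id)
  total <- sum(net)
  if (total <= 0) {
    warn("Total flux magnitude is zero; all enrichment indices are zero.")
  }
  rows <- purrr::map(names(membership), function(p) {
    ids <- membership[[p]]
    ids <- ids[ids %in% names(net)]
    if (length(ids) == 0) {
      warn(sprintf("Pathway '%s' has no reactions in the solution; skipped.", p))
      return(NULL)
    }
    tibble::tibble(
      pathway = p,
      n_reactions = length(ids),
      enrichment = if (total > 0) mean(net[ids]) / total else 0
    )
  })
  dplyr::bind_rows(rows)
}

#' Pathway membership from subsystem annotations
#'
#' @param network A [metabolic_network()].
#' @param override Optional two-column data frame (`reaction_id`, `pathway`)
#'   replacing the model annotations.
#' @return Named list: pathway label to reaction identifiers.
#' @export
pathway_membership <- function(network, override = NULL) {
  if (!is.null(override)) {
    return(split(as.character(override$reaction_id),
                 as.character(override$pathway)))
  }
  rx <- network$reactions
  keep <- nzchar(rx$subsystem)
  split(rx$id[keep], rx$subsystem[keep])
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided Mann-Whitney U test with midrank tie handling.  For combined
#' sample sizes up to `exact_max` the null distribution is obtained by
#' exhaustive enumeration of all group assignments (exact even under ties);
#' larger samples use the normal approximation with the tie-corrected
#' variance.
#'
#' @param values_a,values_b Numeric vectors of observations.
#' @param exact_max Largest combined size for the exact null; default 20.
#' @return A one-row tibble: `statistic` (U for the first group), `p_value`,
#'   `n_a`, `n_b`, `method` (`"exact"` or `"normal"`).
#' @export
compare_groups <- function(values_a, values_b, exact_max = 20) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    ph_abort("Both groups must be nonempty.", "pheflux_domain_error")
  }
  m <- length(values_a)
  n <- length(values_b)
  pooled <- c(values_a, values_b)
  ranks <- rank(pooled)
  U <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2

  if (m + n <= exact_max) {
    assignments <- utils::combn(m + n, m)
    U_null <- colSums(matrix(ranks[assignments], nrow = m)) - m * (m + 1) / 2
    p_lo <- mean(U_null <= U + 1e-9)
    p_hi <- mean(U_null >= U - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- m * n / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / ((m + n) * (m + n - 1))
    sigma2 <- m * n / 12 * ((m + n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  tibble::tibble(statistic = U, p_value = p, n_a = m, n_b = n,
                 method = method)
}

#' Compare pathway enrichment between two groups of samples
#'
#' Runs [compare_groups()] per pathway on per-sample enrichment indices and
#' reports raw and Benjamini-Hochberg adjusted p values.
#'
#' @param enrichments A data frame with columns `sample_id`, `group`,
#'   `pathway`, `enrichment` (e.g. stacked [pathway_enrichment()] results).
#' @param group_a,group_b The two group labels to compare.
#' @return A tibble: `pathway`, `statistic`, `p_value`, `p_adjusted`,
#'   `n_a`, `n_b`.
#' @export
compare_enrichment <- function(enrichments, group_a, group_b) {
  pathways <- unique(enrichments$pathway)
  rows <- purrr::map(pathways, function(p) {
    d <- enrichments[enrichments$pathway == p, ]
    a <- d$enrichment[d$group == group_a]
    b <- d$enrichment[d$group == group_b]
    if (length(a) == 0 || length(b) == 0) return(NULL)
    res <- compare_groups(a, b)
    tibble::tibble(pathway = p, statistic = res$statistic,
                   p_value = res$p_value, n_a = res$n_a, n_b = res$n_b)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("pathway", "statistic", "p_value", "p_adjusted", "n_a", "n_b")]
}
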