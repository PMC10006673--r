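#' Generate a synthetic transcriptome from a reference fluxome
#'
#' Implements the benchmark generator: a seed-determined random fraction
#' `lambda_frac` of the reactions receives expression exactly proportional
#' to its net flux magnitude (proportionality constant 1), and every other
#' reaction draws from an exponential distribution whose mean equals the
#' mean flux magnitude, emulating the exponentially decaying distribution of
#' real gene expression.  Reaction-level values are pushed to gene level
#' through the reactions' GPRs, which in synthetic models are dedicated
#' one-gene-per-reaction rules.
#'
#' @param reference Named numeric vector of reference net fluxes over the
#'   network's reactions (e.g. one row of [sample_fluxomes()]).
#' @param network The [metabolic_network()] the reference lives on.
#' @param lambda_frac Fraction \eqn{\lambda \in [0, 1]} of flux-correlated
#'   reactions.
#' @param seed Integer seed; both the correlated set and the random values
#'   are deterministic given it.
#' @return An [expression_profile()] with attribute `correlated_set`
#'   (reaction identifiers whose expression tracks the flux).
#' @export
generate_expression <- function(reference, network, lambda_frac, seed = 1L) {
  if (lambda_frac < 0 || lambda_frac > 1) {
    ph_abort("`lambda_frac` must lie in [0, 1].", "pheflux_domain_error")
  }
  rx <- network$reactions
  ref <- reference[match(rx$id, names(reference))]
  if (anyNA(ref)) {
    ph_abort("`reference` must cover every reaction of the network.",
             "pheflux_validation_error")
  }
  N <- nrow(rx)
  n_corr <- round(lambda_frac * N)
  mean_abs <- mean(abs(ref))
  if (mean_abs <= 0) mean_abs <- 1

  withr::with_seed(seed, {
    correlated <- if (n_corr > 0) sample(rx$id, n_corr) else character(0)
    g_rx <- stats::rexp(N, rate = 1 / mean_abs)
    is_corr <- rx$id %in% correlated
    g_rx[is_corr] <- abs(ref[is_corr])

    # push reaction values onto their (single-gene) GPR genes
    has_gene <- nzchar(rx$gpr)
    genes <- rx$gpr[has_gene]
    vals <- g_rx[has_gene]
    vals <- vals[!duplicated(genes)]
    genes <- genes[!duplicated(genes)]
    profile <- expression_profile(
      setNames(vals, genes),
      sample_id = sprintf("synthetic_lambda%.2f_seed%d", lambda_frac, seed)
    )
    attr(profile, "correlated_set") <- sort(correlated)
    profile
  })
}

#' Pearson correlation between predicted and reference fluxes
#'
#' @param predicted A [flux_solution()] or a named numeric vector of net
#'   fluxes.
#' @param reference Named numeric vector of reference net fluxes.
#' @param subset Reaction identifiers to score on; defaults to all reactions
#'   present in both vectors.
#' @return The Pearson correlation coefficient, or `NA_real_` when either
#'   restricted vector is constant.
#' @export
score_prediction <- function(predicted, reference, subset = NULL) {
  pred <- if (inherits(predicted, "flux_solution")) {
    setNames(predicted$fluxes$net_flux, predicted$fluxes$reaction_id)
  } else {
    predicted
  }
  subset <- subset %||% intersect(names(pred), names(reference))
  if (length(subset) == 0) {
    ph_abort("`subset` must contain at least one reaction.",
             "pheflux_domain_error")
  }
  missing_ids <- setdiff(subset, intersect(names(pred), names(reference)))
  if (length(missing_ids)) {
    ph_abort(sprintf("Reactions absent from prediction or reference: %s",
                     paste(head(missing_ids, 5), collapse = ", ")),
             "pheflux_lookup_error")
  }
  x <- pred[subset]
  y <- reference[subset]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Identify carbon-core reactions from subsystem annotations
#'
#' Matches subsystem labels against glycolysis/gluconeogenesis and
#' citric-acid-cycle (TCA) patterns.
#'
#' @param network A [metabolic_network()].
#' @return Character vector of reaction identifiers.
#' @export
carbon_core_set <- function(network) {
  rx <- network$reactions
  hit <- grepl("glycoly|gluconeo|citric|citrate|tca|krebs", rx$subsystem,
               ignore.case = TRUE)
  rx$id[hit]
}

#' Run the lambda-sweep synthetic benchmark
#'
#' Samples `n_per_lambda` reference fluxomes uniformly from the network's
#' polytope (one shared pool, so the expression-blind baseline is evaluated
#' on identical samples at every lambda), generates a synthetic
#' transcriptome per (lambda, sample) with [generate_expression()], runs
#' each requested method, and scores predictions by Pearson correlation at
#' carbon-core and genome scales.
#'
#' @param network A [metabolic_network()] (one-gene-per-reaction GPRs for
#'   the expression-conditioned methods).
#' @param lambdas Numeric vector of lambda values in `[0, 1]`.
#' @param n_per_lambda Reference samples per lambda; default 200.
#' @param methods Subset of `c("pheflux", "spot", "fba_min_l2")`.
#' @param seed Integer master seed; the full sweep is deterministic given
#'   it.
#' @param V_total,epsilon Passed to the solvers.
#' @param thinning Passed to [sample_fluxomes()].
#' @param core_set Optional explicit carbon-core reaction list; defaults to
#'   [carbon_core_set()].
#' @return A tibble of class `lambda_sweep` with columns `lambda`, `method`,
#'   `scale` (`"core"`/`"genome"`), `mean_r`, `sd_r`, `n_ok`, `n_fail`.  The
#'   per-sample correlations are attached as attribute `detail`.
#' @export
run_lambda_sweep <- function(network, lambdas, n_per_lambda = 200,
                             methods = c("pheflux", "fba_min_l2"),
                             seed = 1L, V_total = 1000, epsilon = 1e-8,
                             thinning = 100, core_set = NULL) {
  bad <- setdiff(methods, c("pheflux", "spot", "fba_min_l2"))
  if (length(bad)) {
    ph_abort(sprintf("Unknown method(s): %s", paste(bad, collapse = ", ")),
             "pheflux_validation_error")
  }
  if (any(lambdas < 0 | lambdas > 1)) {
    ph_abort("All lambda values must lie in [0, 1].", "pheflux_domain_error")
  }
  core_set <- core_set %||% carbon_core_set(network)
  scales <- list(core = core_set, genome = network$reactions$id)
  scales <- scales[lengths(scales) > 0]

  refs <- sample_fluxomes(network, n_per_lambda, thinning = thinning,
                          seed = seed)
  split <- split_reversible(network)
  expr_seeds <- withr::with_seed(seed, {
    matrix(sample.int(.Machine$integer.max - 1, length(lambdas) * n_per_lambda),
           nrow = length(lambdas))
  })

  fba_sol <- NULL
  if ("fba_min_l2" %in% methods) {
    fba_sol <- solve_fba_min_l2(split)
  }

  detail <- list()
  for (li in seq_along(lambdas)) {
    lam <- lambdas[li]
    for (si in seq_len(n_per_lambda)) {
      ref <- refs[si, ]
      for (m in methods) {
        sol <- if (m == "fba_min_l2") {
          fba_sol
        } else {
          profile <- generate_expression(ref, network, lam,
                                         seed = expr_seeds[li, si])
          rx <- map_expression(split, profile, epsilon = epsilon)
          if (m == "pheflux") {
            solve_pheflux(split, rx, V_total = V_total, epsilon = epsilon)
          } else {
            solve_spot(split, rx, V_total = V_total)
          }
        }
        ok <- sol$status == "optimal"
        for (sc in names(scales)) {
          detail[[length(detail) + 1]] <- tibble::tibble(
            lambda = lam, method = m, scale = sc, sample = si,
            ok = ok,
            r = if (ok) score_prediction(sol, ref, scales[[sc]]) else NA_real_
          )
        }
      }
    }
  }
  detail <- dplyr::bind_rows(detail)
  out <- detail |>
    dplyr::group_by(.data$lambda, .data$method, .data$scale) |>
    dplyr::summarise(
      mean_r = mean(.data$r[.data$ok], na.rm = TRUE),
      sd_r = stats::sd(.data$r[.data$ok], na.rm = TRUE),
      n_ok = sum(.data$ok),
      n_fail = sum(!.data$ok),
      .groups = "drop"
    )
  structure(out, detail = detail,
            class = c("lambda_sweep", class(out)))
}

#' Plot a lambda sweep
#'
#' @param object A [run_lambda_sweep()] result.
#' @param ... Unused.
#' @return A ggplot: mean Pearson r (with one-sd ribbon) against lambda,
#'   faceted by scoring scale.
#' @method autoplot lambda_sweep
#' @export
autoplot.lambda_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$lambda, y = .data$mean_r, colour = .data$method,
    fill = .data$method
  )) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_r - .data$sd_r,
                                      ymax = .data$mean_r + .data$sd_r),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~scale) +
    ggplot2::labs(x = expression(lambda),
                  y = "Pearson r (prediction vs reference)") +
    ggplot2::theme_minimal()
}
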