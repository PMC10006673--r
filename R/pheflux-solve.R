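#' Infer a fluxome by maximum entropy conditioned on expression
#'
#' Solves the entropy program
#' \deqn{\max_v H_g(v) \quad \mathrm{s.t.}\quad S v = 0,\;
#'   lb \le v \le ub,\; \textstyle\sum_i v_i = V}
#' over the split (nonnegative) flux space, where \eqn{H_g} is the
#' [entropy_objective()] of fluxes per mRNA.  At fixed total flux `V` this is
#' a strictly convex program, so the optimum is unique and independent of
#' the starting point.
#'
#' The implementation maximizes the Lagrange dual of the equivalent
#' minimization of \eqn{\sum_i v_i \log((v_i+\epsilon)/(g_i+\epsilon))},
#' which is smooth and concave in the (metabolites + 1) dual multipliers;
#' the unique primal solution is then recovered coordinate-wise.
#'
#' @param split A [split_reversible()] network.
#' @param rx A [map_expression()] result aligned to `split`.
#' @param V_total Positive total-flux constant; default 1000.
#' @param epsilon Smoothing constant inside the logarithm; default `1e-8`.
#' @param solver_options Optional list: `start_dual` (numeric start for the
#'   dual multipliers), `max_iter` (default 3000), `tol` (relative residual
#'   target, default `1e-9`).
#' @return A [flux_solution()] with `method = "pheflux"`; the objective value
#'   is the entropy \eqn{H_g(v)} in nats.  Infeasibility is reported through
#'   `status`, not as an error.
#' @examples
#' net <- toy_tic_network()
#' sp <- split_reversible(net)
#' rx <- map_expression(sp, toy_expression("equal"))
#' sol <- solve_pheflux(sp, rx)
#' tidy(sol)
#' @export
solve_pheflux <- function(split, rx, V_total = 1000, epsilon = 1e-8,
                          solver_options = list()) {
  check_solve_inputs(split, rx, V_total, epsilon)
  fam <- obj_family_entropy(rx$g, epsilon, split$lb, split$ub)
  sol <- run_constrained_solve(split, fam, V_total, solver_options)
  obj <- if (sol$status %in% c("optimal", "iteration_limit")) {
    entropy_objective(sol$v, rx$g, V_total, epsilon)
  } else {
    NA_real_
  }
  flux_solution(split, rx, sol, method = "pheflux", V_total = V_total,
                objective_value = obj)
}

#' Infer a fluxome by minimum forward KL divergence
#'
#' Solves \eqn{\min_v \sum_i v_i \log(v_i/g_i)} under the same constraint
#' set as [solve_pheflux()].  Because
#' \eqn{\max H_g(v) = \min \sum_i v_i \log(v_i/g_i)} at fixed total flux,
#' the returned flux vector coincides with the entropy formulation's (up to
#' the \eqn{\epsilon} smoothing and solver tolerance); the reported
#' objective value is the divergence \eqn{D_{KL}(P\|Q)} of
#' [kl_objective()].
#'
#' @inheritParams solve_pheflux
#' @return A [flux_solution()] with `method = "pheflux_kl"`.
#' @export
solve_pheflux_kl <- function(split, rx, V_total = 1000, epsilon = 1e-8,
                             solver_options = list()) {
  check_solve_inputs(split, rx, V_total, epsilon)
  g <- pmax(rx$g, epsilon)
  fam <- obj_family_kl(g, split$lb, split$ub)
  sol <- run_constrained_solve(split, fam, V_total, solver_options)
  obj <- if (sol$status %in% c("optimal", "iteration_limit")) {
    kl_objective(sol$v, g)
  } else {
    NA_real_
  }
  flux_solution(split, rx, sol, method = "pheflux_kl", V_total = V_total,
                objective_value = obj)
}

check_solve_inputs <- function(split, rx, V_total, epsilon) {
  if (!inherits(split, "split_network")) {
    ph_abort("`split` must be a split_network.", "pheflux_validation_error")
  }
  if (!inherits(rx, "reaction_expression") ||
      nrow(rx) != length(split$reaction_ids)) {
    ph_abort("`rx` must be a reaction_expression aligned to `split`.",
             "pheflux_validation_error")
  }
  if (V_total <= 0) {
    ph_abort("`V_total` must be positive.", "pheflux_domain_error")
  }
  if (epsilon <= 0) {
    ph_abort("`epsilon` must be strictly positive.", "pheflux_domain_error")
  }
  invisible(TRUE)
}

run_constrained_solve <- function(split, fam, V_total, solver_options) {
  A <- rbind(split$S, rep(1, ncol(split$S)))
  b <- c(numeric(nrow(split$S)), V_total)
  y0 <- solver_options$start_dual %||% NULL
  solve_separable_dual(
    fam, A, b, split$lb, split$ub,
    y0 = y0,
    tol_res = solver_options$tol %||% 1e-9,
    max_iter = solver_options$max_iter %||% 3000
  )
}

#' Flux solution object
#'
#' Container for the result of a flux inference (`pheflux`, `pheflux_kl`,
#' `spot`, or `fba_min_l2`).  Use [tidy()] for the per-reaction flux table
#' and [glance()] for the one-row solve summary.
#'
#' @param split The `split_network` the solve ran on.
#' @param rx The `reaction_expression` used (or `NULL`).
#' @param sol Internal solver result.
#' @param method Method label.
#' @param V_total Total-flux constant used for reporting.
#' @param objective_value Method-specific objective at the solution.
#' @return An object of class `flux_solution`: a list with `fluxes` (tibble:
#'   `reaction_id`, `net_flux`, `forward_flux`, `reverse_flux`,
#'   `expression_g`, `imputed`), the split-flux vector `v`, `V_total`,
#'   `objective_value`, `status`, `method` and solver `diagnostics`.
#' @keywords internal
#' @export
flux_solution <- function(split, rx, sol, method, V_total,
                          objective_value = NA_real_) {
  v <- sol$v
  pairing <- split$pairing
  has_rev <- !is.na(pairing$reverse)
  fwd <- ifelse(is.na(v[pairing$forward]), 0, v[pairing$forward])
  rev_ <- numeric(nrow(pairing))
  rev_[has_rev] <- v[pairing$reverse[has_rev]]
  g_orig <- rep(NA_real_, nrow(pairing))
  imputed <- rep(NA, nrow(pairing))
  if (!is.null(rx)) {
    g_orig <- rx$g[pairing$forward]
    imputed <- rx$imputed[pairing$forward]
  }
  fluxes <- tibble::tibble(
    reaction_id = pairing$reaction_id,
    net_flux = fwd - rev_,
    forward_flux = fwd,
    reverse_flux = rev_,
    expression_g = g_orig,
    imputed = imputed
  )
  structure(
    list(
      fluxes = fluxes,
      v = setNames(v, split$reaction_ids),
      V_total = V_total,
      objective_value = objective_value,
      status = sol$status,
      method = method,
      diagnostics = list(
        iterations = sol$iterations %||% NA_integer_,
        max_constraint_residual = sol$residual %||% NA_real_
      )
    ),
    class = "flux_solution"
  )
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> method=%s status=%s\n", x$method, x$status))
  cat(sprintf("  objective: %.6g   total split flux: %.6g\n",
              x$objective_value, sum(x$v)))
  print(utils::head(x$fluxes, 10))
  if (nrow(x$fluxes) > 10) cat("  ...\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-reaction flux table of a solution
#'
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @return A tibble with one row per original reaction: `reaction_id`,
#'   `net_flux`, `forward_flux`, `reverse_flux`, `expression_g`, `imputed`.
#' @method tidy flux_solution
#' @export
tidy.flux_solution <- function(x, ...) {
  x$fluxes
}

#' One-row summary of a flux solve
#'
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `status`, `objective_value`,
#'   `V_total`, `total_split_flux`, `iterations`, `max_constraint_residual`.
#' @method glance flux_solution
#' @export
glance.flux_solution <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    status = x$status,
    objective_value = x$objective_value,
    V_total = x$V_total,
    total_split_flux = sum(x$v),
    iterations = x$diagnostics$iterations,
    max_constraint_residual = x$diagnostics$max_constraint_residual
  )
}

#' Write a flux solution to delimited text
#'
#' @param solution A `flux_solution`.
#' @param path Output file path (TSV).
#' @return `path`, invisibly.
#' @export
write_flux_table <- function(solution, path) {
  utils::write.table(tidy(solution), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bar plot of net fluxes
#'
#' @param object A `flux_solution`.
#' @param ... Unused.
#' @return A ggplot object showing net flux per reaction.
#' @method autoplot flux_solution
#' @export
autoplot.flux_solution <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$reaction_id, -abs(.data$net_flux)),
    y = .data$net_flux
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "reaction", y = "net flux (mmol/gDW/h)",
      title = sprintf("%s flux solution (%s)", object$method, object$status)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
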