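#' SPOT baseline: maximize flux-expression alignment on the unit ball
#'
#' Solves the Simplified Pearson cOrrelation with Transcriptomics (SPOT)
#' program
#' \deqn{\max_v g^\top v \quad \mathrm{s.t.}\quad S v = 0,\; v \ge 0,\;
#'   \|v\|_2 \le 1.}
#' Over the steady-state cone \eqn{K = \{v : Sv = 0, v \ge 0\}} the
#' maximizer on the unit ball is the normalized Euclidean projection of `g`
#' onto \eqn{K}, which is computed exactly as a strictly convex quadratic
#' program.  Finite flux bounds scale onto the unit-norm ball and are
#' therefore released (only nonnegativity is retained).  The result is
#' rescaled so the split fluxes sum to `V_total` for comparability with
#' [solve_pheflux()]; Pearson-based scoring is scale-invariant.
#'
#' @inheritParams solve_pheflux
#' @return A [flux_solution()] with `method = "spot"`; the objective value is
#'   \eqn{g^\top v / \|v\|_2} at the solution (before rescaling).
#' @export
solve_spot <- function(split, rx, V_total = 1000) {
  check_solve_inputs(split, rx, V_total, epsilon = 1e-8)
  g <- rx$g
  S <- as.matrix(split$S)
  n <- ncol(S)

  red <- independent_rows(S, numeric(nrow(S)))
  Sd <- as.matrix(red$A)
  Amat <- cbind(t(Sd), diag(n))
  bvec <- c(numeric(nrow(Sd)), numeric(n))
  proj <- tryCatch(
    quadprog::solve.QP(Dmat = diag(n), dvec = g, Amat = Amat, bvec = bvec,
                       meq = nrow(Sd)),
    error = function(e) NULL
  )
  if (is.null(proj)) {
    return(flux_solution(split, rx,
                         list(v = rep(NA_real_, n), status = "infeasible"),
                         method = "spot", V_total = V_total))
  }
  v <- pmax(proj$solution, 0)
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) {
    # expression lies in the polar cone: the zero flux vector is optimal
    return(flux_solution(split, rx, list(v = numeric(n), status = "optimal",
                                         iterations = 1L, residual = 0),
                         method = "spot", V_total = V_total,
                         objective_value = 0))
  }
  obj <- sum(g * v) / nrm
  v_scaled <- v * (V_total / sum(v))
  res <- max(abs(as.numeric(split$S %*% v_scaled)))
  flux_solution(split, rx,
                list(v = v_scaled, status = "optimal", iterations = 1L,
                     residual = res),
                method = "spot", V_total = V_total, objective_value = obj)
}

#' FBA followed by l2-norm flux minimization
#'
#' Expression-blind baseline: stage 1 maximizes the biomass flux over the
#' split polytope (linear program); stage 2 fixes biomass at its optimum and
#' minimizes \eqn{\sum_i v_i^2} (strictly convex quadratic program), which
#' selects a unique parsimonious flux vector and removes all cycle flux.
#'
#' @param network A [metabolic_network()] with `biomass_reaction` set, or a
#'   `split_network` whose base network has one.
#' @param biomass Optional reaction identifier overriding
#'   `network$biomass_reaction`.
#' @return A [flux_solution()] with `method = "fba_min_l2"`; the objective
#'   value is the stage-1 biomass optimum.
#' @export
solve_fba_min_l2 <- function(network, biomass = NULL) {
  split <- if (inherits(network, "split_network")) {
    network
  } else {
    split_reversible(network)
  }
  base <- split$base
  biomass <- biomass %||% base$biomass_reaction
  if (is.null(biomass)) {
    ph_abort("No biomass reaction set; FBA needs an objective reaction.",
             "pheflux_validation_error")
  }
  bio_col <- split$pairing$forward[match(biomass, split$pairing$reaction_id)]
  if (is.na(bio_col)) {
    ph_abort(sprintf("Biomass reaction '%s' not found.", biomass),
             "pheflux_lookup_error")
  }
  S <- as.matrix(split$S)
  n <- ncol(S)
  lb <- split$lb
  ub <- split$ub
  if (any(!is.finite(ub))) {
    ph_abort(
      "Infinite upper bounds make the biomass LP potentially unbounded; review the model bounds.",
      "pheflux_validation_error"
    )
  }

  # stage 1: LP max v_biomass on {Sv = 0, lb <= v <= ub}.  Shift w = v - lb
  # so the simplex solver's implicit w >= 0 applies, and eliminate fixed
  # variables (ub = lb): the solver mishandles zero-width inequality rows.
  free <- (ub - lb) > 1e-12
  v_fixed <- lb
  lp_ok <- FALSE
  v1 <- NULL
  if (!any(free)) {
    v1 <- v_fixed
    lp_ok <- max(abs(as.numeric(S %*% v1))) <= 1e-6
  } else {
    cc <- numeric(n)
    cc[bio_col] <- 1
    Sf <- S[, free, drop = FALSE]
    beq <- as.numeric(-S %*% lb)
    # the simplex backend breaks pivot ties randomly; pin its RNG stream
    # (for reproducibility) and retry under fresh pivot seeds if it stalls
    for (attempt in 1:5) {
      lp <- tryCatch(
        withr::with_seed(
          1000L + attempt,
          pracma::linprog(cc = cc[free], A = diag(sum(free)),
                          b = (ub - lb)[free], Aeq = Sf, beq = beq,
                          maximize = TRUE, maxiter = 200 * n)
        ),
        error = function(e) NULL
      )
      if (is.null(lp) || is.null(lp$x) || !isTRUE(lp$errno == 1)) next
      cand <- v_fixed
      cand[free] <- lp$x + lb[free]
      feasible <- max(abs(as.numeric(S %*% cand))) <= 1e-6 &&
        all(cand >= lb - 1e-6) && all(cand <= ub + 1e-6)
      if (feasible) {
        v1 <- pmin(pmax(cand, lb), ub)
        lp_ok <- TRUE
        break
      }
    }
  }
  if (!lp_ok) {
    feas <- find_feasible_point(S, numeric(nrow(S)), lb, ub)
    status <- if (is.null(feas)) "infeasible" else "numerical_failure"
    return(flux_solution(split, NULL,
                         list(v = rep(NA_real_, n), status = status),
                         method = "fba_min_l2", V_total = NA_real_))
  }
  biomass_opt <- v1[bio_col]

  # stage 2: min ||v||^2 with biomass pinned at its optimum
  red <- independent_rows(S, numeric(nrow(S)))
  Sd <- as.matrix(red$A)
  e_bio <- numeric(n)
  e_bio[bio_col] <- 1
  Aeq <- rbind(Sd, e_bio)
  beq2 <- c(numeric(nrow(Sd)), biomass_opt)
  Amat <- cbind(t(Aeq), diag(n), -diag(n))
  bvec <- c(beq2, lb, -ub)
  qp <- tryCatch(
    quadprog::solve.QP(Dmat = 2 * diag(n), dvec = numeric(n), Amat = Amat,
                       bvec = bvec, meq = nrow(Aeq)),
    error = function(e) NULL
  )
  v2 <- if (!is.null(qp)) {
    pmin(pmax(qp$solution, lb), ub)
  } else {
    # quadprog can misreport degenerate systems; least-norm solve through
    # the dual engine with the quadratic family
    fam <- obj_family_quadratic(numeric(n), lb, ub)
    dual <- solve_separable_dual(fam, Aeq, beq2, lb, ub, feas_check = FALSE)
    if (dual$status != "optimal") {
      return(flux_solution(split, NULL,
                           list(v = v1, status = "numerical_failure",
                                iterations = 1L,
                                residual = max(abs(as.numeric(S %*% v1)))),
                           method = "fba_min_l2", V_total = sum(v1),
                           objective_value = biomass_opt))
    }
    dual$v
  }
  res <- max(abs(as.numeric(S %*% v2)))
  flux_solution(split, NULL,
                list(v = v2, status = "optimal", iterations = 2L,
                     residual = res),
                method = "fba_min_l2", V_total = sum(v2),
                objective_value = biomass_opt)
}
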