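#' Uniformly sample the steady-state flux polytope
#'
#' Hit-and-run sampler over \eqn{\{v : Sv = 0, lb \le v \le ub\}} in the
#' original (pre-split) flux coordinates.  Directions are drawn isotropically
#' inside the null space of `S`, the step length uniformly over the feasible
#' chord, so the chain's stationary distribution is uniform on the polytope.
#' The chain starts from the Euclidean projection of the box midpoint onto
#' the polytope and records one sample every `thinning` steps after a
#' burn-in of `5 * thinning` steps.
#'
#' @param network A [metabolic_network()] with finite bounds.
#' @param n Number of samples.
#' @param thinning Steps between recorded samples; default 100.
#' @param seed Integer seed; samples are deterministic given it.
#' @return A numeric matrix with `n` rows and one column per reaction
#'   (named), each row a feasible flux vector.
#' @export
sample_fluxomes <- function(network, n, thinning = 100, seed = 1L) {
  validate_network(network)
  rx <- network$reactions
  if (any(!is.finite(rx$lb)) || any(!is.finite(rx$ub))) {
    ph_abort("Polytope is unbounded: all flux bounds must be finite.",
             "pheflux_validation_error")
  }
  N <- nrow(rx)
  out <- matrix(numeric(0), nrow = 0, ncol = N,
                dimnames = list(NULL, rx$id))
  if (n == 0) return(out)

  S <- as.matrix(network$S)
  lb <- rx$lb
  ub <- rx$ub
  Z <- MASS::Null(t(S))
  v0 <- interior_point(network$S, lb, ub)
  if (is.null(v0)) {
    ph_abort("Flux polytope is empty.", "pheflux_infeasible_error")
  }
  if (is.null(dim(Z)) || ncol(Z) == 0) {
    # zero-dimensional polytope: the single feasible point, repeated
    return(matrix(rep(v0, each = n), nrow = n,
                  dimnames = list(NULL, rx$id)))
  }

  withr::with_seed(seed, {
    v <- v0
    out <- matrix(NA_real_, nrow = n, ncol = N,
                  dimnames = list(NULL, rx$id))
    burn <- 5L * thinning
    total <- burn + n * thinning
    taken <- 0L
    for (step in seq_len(total)) {
      u <- stats::rnorm(ncol(Z))
      d <- as.numeric(Z %*% (u / sqrt(sum(u^2))))
      live <- abs(d) > 1e-11
      t_hi <- suppressWarnings(min(
        ((ub - v)[live & d > 0]) / d[live & d > 0],
        ((lb - v)[live & d < 0]) / d[live & d < 0]
      ))
      t_lo <- suppressWarnings(max(
        ((lb - v)[live & d > 0]) / d[live & d > 0],
        ((ub - v)[live & d < 0]) / d[live & d < 0]
      ))
      if (!is.finite(t_hi) || !is.finite(t_lo) || t_hi < t_lo) next
      v <- v + stats::runif(1, t_lo, t_hi) * d
      if (step > burn && (step - burn) %% thinning == 0) {
        taken <- taken + 1L
        out[taken, ] <- v
      }
    }
    out
  })
}
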