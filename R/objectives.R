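#' Shannon entropy of fluxes per mRNA
#'
#' Evaluates
#' \deqn{H_g(v) = -\sum_i \frac{v_i}{V}\,
#'   \log\frac{v_i + \epsilon}{(g_i + \epsilon)\,V}}
#' the entropy of the flux-per-enzyme-copy distribution
#' \eqn{P_g(v_i) = (v_i/g_i)/V}.  With `epsilon = 0` and strictly positive
#' entries this is the exact entropy; the smoothing keeps the logarithm
#' defined when a flux or expression value is zero.
#'
#' @param v Nonnegative flux vector (split reactions).
#' @param g Expression vector aligned to `v`.
#' @param V Positive total flux (the normalizing constant).
#' @param epsilon Nonnegative smoothing constant.
#' @return Entropy in nats.
#' @export
entropy_objective <- function(v, g, V, epsilon = 1e-8) {
  if (length(v) != length(g)) {
    ph_abort("`v` and `g` must have the same length.",
             "pheflux_dimension_error")
  }
  if (!is.numeric(V) || length(V) != 1 || V <= 0) {
    ph_abort("`V` must be a positive scalar.", "pheflux_domain_error")
  }
  if (epsilon < 0) {
    ph_abort("`epsilon` must be nonnegative.", "pheflux_domain_error")
  }
  if (epsilon == 0 && (any(v <= 0) || any(g <= 0))) {
    ph_abort("With epsilon = 0 all entries of `v` and `g` must be positive.",
             "pheflux_domain_error")
  }
  -sum((v / V) * log((v + epsilon) / ((g + epsilon) * V)))
}

#' Forward Kullback-Leibler divergence between fluxome and transcriptome
#'
#' Evaluates \eqn{D_{KL}(P \| Q) = \sum_i (v_i/V) \log\frac{v_i/V}{g_i/G}}
#' with \eqn{V = \sum_i v_i} and \eqn{G = \sum_i g_i}: the divergence of the
#' normalized flux distribution from the normalized per-reaction expression
#' distribution.  It is nonnegative and zero iff \eqn{v \propto g}.
#' Zero-flux entries contribute zero (\eqn{0 \log 0 = 0}).
#'
#' @param v Nonnegative flux vector with positive total.
#' @param g Strictly positive expression vector aligned to `v`.
#' @return Divergence in nats.
#' @export
kl_objective <- function(v, g) {
  if (length(v) != length(g)) {
    ph_abort("`v` and `g` must have the same length.",
             "pheflux_dimension_error")
  }
  if (any(g <= 0)) {
    ph_abort("All entries of `g` must be strictly positive.",
             "pheflux_domain_error")
  }
  if (any(v < 0) || sum(v) <= 0) {
    ph_abort("`v` must be nonnegative with a positive total.",
             "pheflux_domain_error")
  }
  V <- sum(v)
  G <- sum(g)
  p <- v / V
  q <- g / G
  pos <- p > 0
  sum(p[pos] * log(p[pos] / q[pos]))
}
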