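#' Split reversible reactions into forward and reverse components
#'
#' Rewrites the network over nonnegative fluxes: each reversible reaction
#' \eqn{i} becomes a forward column (stoichiometry \eqn{s_i}, bounds
#' \eqn{[\max(0, lb_i), \max(0, ub_i)]}) and a reverse column
#' (\eqn{-s_i}, bounds \eqn{[\max(0, -ub_i), \max(0, -lb_i)]}), so the net
#' flux is \eqn{v_i = v_i^f - v_i^r}.  Irreversible reactions map to a single
#' column.
#'
#' @param network A validated [metabolic_network()].  Reactions lacking
#'   explicit bounds receive the conventional defaults at load time, so all
#'   split bounds land in `[0, 1000]` for such models; bounds stated by the
#'   model (including deliberately closed reactions) are preserved exactly.
#' @return An object of class `split_network` with elements `base`,
#'   `reaction_ids` (length `N' >= N`), `S` (metabolites x split reactions),
#'   `lb`, `ub`, `orig_index` (original reaction per split column),
#'   `direction` (+1 forward / -1 reverse), and `pairing` (tibble with the
#'   forward/reverse column of each original reaction).
#' @examples
#' net <- toy_tic_network()
#' sp <- split_reversible(net)
#' length(sp$reaction_ids)
#' @export
split_reversible <- function(network) {
  validate_network(network)
  rx <- network$reactions
  n <- nrow(rx)
  rev_idx <- which(rx$reversible)

  cols <- vector("list", n)
  for (i in seq_len(n)) {
    if (rx$reversible[i]) {
      cols[[i]] <- data.frame(
        orig = i, direction = c(1, -1),
        id = c(rx$id[i], paste0(rx$id[i], "_rev")),
        lb = c(max(0, rx$lb[i]), max(0, -rx$ub[i])),
        ub = c(max(0, rx$ub[i]), max(0, -rx$lb[i]))
      )
    } else {
      cols[[i]] <- data.frame(
        orig = i, direction = 1, id = rx$id[i],
        lb = rx$lb[i], ub = rx$ub[i]
      )
    }
  }
  cols <- do.call(rbind, cols)

  S_split <- network$S[, cols$orig, drop = FALSE]
  S_split <- S_split %*% Matrix::Diagonal(nrow(cols), cols$direction)
  S_split <- methods::as(S_split, "CsparseMatrix")
  dimnames(S_split) <- list(network$metabolites, cols$id)

  pairing <- tibble::tibble(reaction_id = rx$id)
  pairing$forward <- vapply(seq_len(n), function(i) {
    which(cols$orig == i & cols$direction == 1)[1]
  }, integer(1))
  pairing$reverse <- vapply(seq_len(n), function(i) {
    j <- which(cols$orig == i & cols$direction == -1)
    if (length(j)) j[1] else NA_integer_
  }, integer(1))

  structure(
    list(
      base = network,
      reaction_ids = cols$id,
      S = S_split,
      lb = cols$lb,
      ub = cols$ub,
      orig_index = cols$orig,
      direction = cols$direction,
      pairing = pairing
    ),
    class = "split_network"
  )
}

#' @export
print.split_network <- function(x, ...) {
  cat(sprintf(
    "<split_network> %d metabolites, %d split reactions (from %d original)\n",
    nrow(x$S), length(x$reaction_ids), nrow(x$pairing)
  ))
  invisible(x)
}

#' Reconstruct net fluxes from a split flux vector
#'
#' @param split A `split_network`.
#' @param v Nonnegative flux vector over the split reactions.
#' @return Named numeric vector of net fluxes over the original reactions,
#'   `v_f - v_r`.
#' @export
net_fluxes <- function(split, v) {
  if (length(v) != length(split$reaction_ids)) {
    ph_abort("Flux vector length does not match the split network.",
             "pheflux_dimension_error")
  }
  net <- v[split$pairing$forward]
  has_rev <- !is.na(split$pairing$reverse)
  net[has_rev] <- net[has_rev] - v[split$pairing$reverse[has_rev]]
  setNames(net, split$pairing$reaction_id)
}

# Embed an original-space flux vector into split coordinates
# (positive part forward, negative part reverse).
split_embed <- function(split, v_orig) {
  v <- numeric(length(split$reaction_ids))
  fwd <- split$pairing$forward
  rev <- split$pairing$reverse
  v[fwd] <- pmax(v_orig, 0)
  has_rev <- !is.na(rev)
  v[rev[has_rev]] <- pmax(-v_orig[has_rev], 0)
  # irreversible columns carry the (possibly negative) flux directly
  v[fwd[!has_rev]] <- v_orig[!has_rev]
  v
}
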