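# Small networks and shared utilities used across the test files.

# in -> A -> out: a 1-dimensional polytope (v1 = v2).
make_chain_network <- function(ub = 1000) {
  S <- matrix(c(1, -1), nrow = 1,
              dimnames = list("A", c("up", "out")))
  metabolic_network(
    S,
    reactions = tibble::tibble(id = c("up", "out"), lb = 0, ub = ub,
                               reversible = FALSE,
                               gpr = c("gu", "go"), subsystem = "")
  )
}

# Three parallel uptakes feeding one secreted metabolite: intersected with
# the total-flux constraint the polytope has 2 free dimensions.
make_diamond_network <- function() {
  S <- matrix(c(1, 1, 1, -1), nrow = 1,
              dimnames = list("A", c("in1", "in2", "in3", "out")))
  metabolic_network(
    S,
    reactions = tibble::tibble(
      id = c("in1", "in2", "in3", "out"), lb = 0, ub = 1000,
      reversible = FALSE, gpr = c("ga", "gb", "gc", "gd"), subsystem = ""
    )
  )
}

# Branched network with a biomass sink and a pure cycle, for the FBA
# baseline: up -> A, A -> B (conv), B -> A (back, forming a cycle), B ->
# biomass.
make_fba_toy <- function(uptake_ub = 10) {
  S <- matrix(
    c(1, -1, 1, 0,
      0, 1, -1, -1),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("A", "B"), c("up", "conv", "back", "BIOMASS"))
  )
  metabolic_network(
    S,
    reactions = tibble::tibble(
      id = c("up", "conv", "back", "BIOMASS"),
      lb = 0, ub = c(uptake_ub, 1000, 1000, 1000),
      reversible = FALSE, gpr = "", subsystem = ""
    ),
    biomass_reaction = "BIOMASS"
  )
}

# Uniform positive expression over the genes of a network's GPRs.
flat_profile <- function(network, value = 1) {
  genes <- unique(network$reactions$gpr[nzchar(network$reactions$gpr)])
  expression_profile(stats::setNames(rep(value, length(genes)), genes))
}

# The packaged fixture solve set used by the equivalence / determinism
# checks: list of (split, reaction_expression) pairs.
fixture_solve_inputs <- function() {
  toy <- toy_tic_network()
  toy_sp <- split_reversible(toy)
  inputs <- lapply(c("equal", "double", "tenfold"), function(sc) {
    list(name = paste0("toy_", sc), split = toy_sp,
         rx = map_expression(toy_sp, toy_expression(sc)))
  })
  dia <- make_diamond_network()
  dia_sp <- split_reversible(dia)
  inputs[[length(inputs) + 1]] <- list(
    name = "diamond",
    split = dia_sp,
    rx = map_expression(dia_sp, expression_profile(
      c(ga = 5, gb = 1, gc = 0.2, gd = 2)
    ))
  )
  syn <- make_synthetic_network(seed = 42)
  syn_sp <- split_reversible(syn)
  ref <- sample_fluxomes(syn, 1, thinning = 50, seed = 8)[1, ]
  inputs[[length(inputs) + 1]] <- list(
    name = "synthetic",
    split = syn_sp,
    rx = map_expression(syn_sp, generate_expression(ref, syn, 0.5, seed = 3))
  )
  inputs
}

expect_steady_state <- function(sol, split, V, tol = 1e-6) {
  testthat::expect_lt(max(abs(as.numeric(split$S %*% sol$v))), tol * V)
  testthat::expect_true(all(sol$v >= split$lb - tol * V))
  testthat::expect_true(all(sol$v <= split$ub + tol * V))
}
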