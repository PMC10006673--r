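test_that("expression tables load with validation", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tfpkm", "gA\t2.5", "gB\t0", "gC\t11"), f)
  p <- load_expression(f)
  expect_s3_class(p, "expression_profile")
  expect_equal(nrow(p), 3)
  expect_equal(p$value[p$gene == "gA"], 2.5)

  neg <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tfpkm", "gA\t-1.0"), neg)
  expect_error(load_expression(neg), class = "pheflux_validation_error")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tfpkm", "gA\t1", "gA\t2"), dup)
  expect_error(load_expression(dup), class = "pheflux_validation_error")

  empty <- tempfile(fileext = ".tsv")
  writeLines("gene\tfpkm", empty)
  expect_error(load_expression(empty), class = "pheflux_format_error")

  junk <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tfpkm", "gA\tabc"), junk)
  expect_error(load_expression(junk), class = "pheflux_format_error",
               regexp = "row 1")
})

test_that("GPR evaluation: AND is min, OR is sum, missing genes drop out", {
  p <- expression_profile(c(gA = 2, gB = 5, gC = 1))
  expect_equal(evaluate_gpr("gA and gB", p), 2)
  expect_equal(evaluate_gpr("gA or gB", p), 7)
  expect_equal(evaluate_gpr("(gA and gB) or gC", p), 3)
  # AND binds tighter than OR
  expect_equal(evaluate_gpr("gA and gB or gC", p), 3)
  # absent gene dropped from its node; all-missing node is missing
  expect_equal(evaluate_gpr("gA and gZ", p), 2)
  expect_true(is.na(evaluate_gpr("gZ or gY", p)))
  expect_true(is.na(evaluate_gpr("", p)))
  # alternative OR semantics
  expect_equal(evaluate_gpr("gA or gB", p, or = "max"), 5)
  expect_error(evaluate_gpr("gA and (gB", p), class = "pheflux_gpr_syntax_error")
  expect_error(evaluate_gpr("and gA", p), class = "pheflux_gpr_syntax_error")
})

test_that("GPR evaluation matches a recursive reference evaluator on random trees", {
  # independent oracle: direct recursion over randomly generated expressions
  oracle <- function(expr, env) {
    if (is.character(expr)) {
      return(if (expr %in% names(env)) env[[expr]] else NA_real_)
    }
    vals <- vapply(expr$kids, oracle, numeric(1), env = env)
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(NA_real_)
    if (expr$op == "and") min(vals) else sum(vals)
  }
  to_string <- function(expr) {
    if (is.character(expr)) return(expr)
    paste0("(", paste(vapply(expr$kids, to_string, character(1)),
                      collapse = paste0(" ", expr$op, " ")), ")")
  }
  gen <- function(depth, genes) {
    if (depth == 0 || stats::runif(1) < 0.4) return(sample(genes, 1))
    list(op = sample(c("and", "or"), 1),
         kids = lapply(seq_len(sample(2:3, 1)), function(i) {
           gen(depth - 1, genes)
         }))
  }
  withr::with_seed(99, {
    genes <- paste0("g", 1:6)
    env <- as.list(stats::setNames(stats::runif(4, 0, 10), genes[1:4]))
    p <- expression_profile(unlist(env))
    for (k in 1:25) {
      tree <- gen(3, genes)
      expect_equal(evaluate_gpr(to_string(tree), p),
                   oracle(tree, env))
    }
  })
})

test_that("map_expression imputes the median of GPR-derived values", {
  S <- matrix(c(1, -1, 1, -1, 0, 0, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"),
                              c("r1", "r2", "r3", "r4")))
  net <- metabolic_network(
    S,
    reactions = tibble::tibble(
      id = c("r1", "r2", "r3", "r4"), lb = 0, ub = 1000, reversible = FALSE,
      gpr = c("gA", "gB", "", "gD"), subsystem = ""
    )
  )
  sp <- split_reversible(net)
  p <- expression_profile(c(gA = 2, gB = 4, gD = 6))
  rx <- map_expression(sp, p)
  expect_equal(rx$g[rx$reaction_id == "r3"], 4)  # median of {2, 4, 6}
  expect_true(rx$imputed[rx$reaction_id == "r3"])
  expect_equal(sum(rx$imputed), 1)
  expect_equal(attr(rx, "G"), sum(rx$g))

  # all GPRs resolvable: nothing imputed
  p_full <- expression_profile(c(gA = 2, gB = 4, gD = 6))
  net_full <- net
  net_full$reactions$gpr[3] <- "gA"
  rx_full <- map_expression(split_reversible(net_full), p_full)
  expect_false(any(rx_full$imputed))

  # idempotence
  rx2 <- map_expression(sp, p)
  expect_identical(as.data.frame(rx), as.data.frame(rx2))
})

test_that("zero expression is floored at epsilon", {
  toy <- toy_tic_network()
  sp <- split_reversible(toy)
  p <- expression_profile(c(g1 = 0, g2 = 1, g3 = 1, g4 = 1))
  rx <- map_expression(sp, p, epsilon = 1e-8)
  expect_equal(rx$g[rx$reaction_id == "v1"], 1e-8)
  expect_true(all(rx$g > 0))
})

test_that("both split directions of a reversible reaction share expression", {
  S <- matrix(c(1, -1), nrow = 1, dimnames = list("A", c("r1", "r2")))
  net <- metabolic_network(
    S, reactions = tibble::tibble(id = c("r1", "r2"), lb = c(0, -1000),
                                  ub = 1000, reversible = c(FALSE, TRUE),
                                  gpr = c("gA", "gB"), subsystem = "")
  )
  sp <- split_reversible(net)
  rx <- map_expression(sp, expression_profile(c(gA = 3, gB = 7)))
  pair <- sp$pairing[sp$pairing$reaction_id == "r2", ]
  expect_equal(rx$g[pair$forward], rx$g[pair$reverse])
  expect_equal(rx$g[pair$forward], 7)
})

test_that("mapping fails informatively when no GPR value exists", {
  net <- make_fba_toy()  # all GPRs empty
  sp <- split_reversible(net)
  expect_error(map_expression(sp, expression_profile(c(gX = 1))),
               class = "pheflux_mapping_error")
})
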