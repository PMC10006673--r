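fake_solution <- function(net_flux) {
  structure(
    list(fluxes = tibble::tibble(
      reaction_id = names(net_flux),
      net_flux = unname(net_flux),
      forward_flux = pmax(unname(net_flux), 0),
      reverse_flux = pmax(-unname(net_flux), 0),
      expression_g = NA_real_, imputed = NA
    ), status = "optimal", method = "pheflux"),
    class = "flux_solution"
  )
}

test_that("lactate yield is a guarded ratio of net exchange fluxes", {
  sol <- fake_solution(c(EX_lac = 2, EX_glc = -1, other = 5))
  expect_equal(lactate_yield(sol, "EX_lac", "EX_glc"), 2)
  sol0 <- fake_solution(c(EX_lac = 0, EX_glc = -1))
  expect_equal(lactate_yield(sol0, "EX_lac", "EX_glc"), 0)
  solz <- fake_solution(c(EX_lac = 2, EX_glc = 0))
  expect_true(is.na(lactate_yield(solz, "EX_lac", "EX_glc")))
  expect_error(lactate_yield(sol, "nope", "EX_glc"),
               class = "pheflux_lookup_error")
  # invariant to uniform rescaling
  sol2 <- fake_solution(c(EX_lac = 20, EX_glc = -10, other = 50))
  expect_equal(lactate_yield(sol, "EX_lac", "EX_glc"),
               lactate_yield(sol2, "EX_lac", "EX_glc"))
})

test_that("pathway enrichment is mean pathway |flux| over total network |flux|", {
  sol <- fake_solution(c(r1 = 1, r2 = 3, r3 = -2, r4 = 4))
  enr <- pathway_enrichment(sol, list(P = c("r1", "r2")))
  expect_equal(enr$enrichment, mean(c(1, 3)) / 10)  # = 0.2

  # symmetric two-pathway partition with equal mean |flux|
  sol_sym <- fake_solution(c(a1 = 2, a2 = 4, b1 = 4, b2 = 2))
  enr_sym <- pathway_enrichment(sol_sym, list(A = c("a1", "a2"),
                                              B = c("b1", "b2")))
  expect_equal(enr_sym$enrichment[1], enr_sym$enrichment[2])

  # a partition's indices sum to <= 1; singleton cover sums to exactly 1
  parts <- list(A = c("r1", "r2"), B = c("r3", "r4"))
  expect_lte(sum(pathway_enrichment(sol, parts)$enrichment), 1)
  singletons <- as.list(stats::setNames(c("r1", "r2", "r3", "r4"),
                                        c("p1", "p2", "p3", "p4")))
  expect_equal(sum(pathway_enrichment(sol, singletons)$enrichment), 1)

  # rescaling invariance
  sol10 <- fake_solution(c(r1 = 10, r2 = 30, r3 = -20, r4 = 40))
  expect_equal(pathway_enrichment(sol10, parts)$enrichment,
               pathway_enrichment(sol, parts)$enrichment)

  expect_warning(pathway_enrichment(sol, list(Empty = "zz")),
                 regexp = "skipped")
})

test_that("pathway membership derives from subsystems with optional override", {
  net <- toy_tic_network()
  mem <- pathway_membership(net)
  expect_setequal(mem$Cycle, c("v2", "v3"))
  expect_setequal(mem$Exchange, c("v1", "v4"))
  ov <- pathway_membership(net, override = data.frame(
    reaction_id = c("v1", "v2"), pathway = c("X", "X")
  ))
  expect_equal(ov, list(X = c("v1", "v2")))
})

test_that("Mann-Whitney U handles the textbook cases", {
  # identical multisets: symmetric null, p = 1
  res <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 4.5)  # ties at midranks: U = mn/2

  # complete separation: U = 0 for the lower group
  res2 <- compare_groups(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res2$statistic, 0)

  # a = {1,2}, b = {3,4}: 6 assignments, both extremes have mass 1/6
  res3 <- compare_groups(c(1, 2), c(3, 4))
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p_value, 2 / 6)

  expect_error(compare_groups(numeric(0), 1), class = "pheflux_domain_error")
})

test_that("Mann-Whitney U is symmetric under group exchange", {
  withr::with_seed(31, {
    for (k in 1:10) {
      a <- sample(1:8, sample(2:5, 1), replace = TRUE)
      b <- sample(1:8, sample(2:5, 1), replace = TRUE)
      ab <- compare_groups(a, b)
      ba <- compare_groups(b, a)
      expect_equal(ab$statistic + ba$statistic, length(a) * length(b))
      expect_equal(ab$p_value, ba$p_value)
    }
  })
})

test_that("exact p agrees with wilcox.test when there are no ties", {
  withr::with_seed(37, {
    for (k in 1:10) {
      a <- stats::runif(sample(3:6, 1))
      b <- stats::runif(sample(3:6, 1))
      mine <- compare_groups(a, b)
      ref <- stats::wilcox.test(a, b, exact = TRUE)
      expect_equal(mine$statistic, unname(ref$statistic))
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("large samples switch to the tie-corrected normal approximation", {
  withr::with_seed(41, {
    a <- sample(1:10, 30, replace = TRUE)
    b <- sample(2:11, 25, replace = TRUE)
    res <- compare_groups(a, b)
    expect_equal(res$method, "normal")
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  })
})

test_that("group comparison across pathways reports BH-adjusted p values", {
  withr::with_seed(43, {
    enr <- dplyr::bind_rows(lapply(1:12, function(i) {
      tibble::tibble(
        sample_id = paste0("s", i),
        group = if (i <= 6) "normal" else "tumor",
        pathway = rep(c("GG", "OXP", "TCA"), 2)[1:3],
        enrichment = stats::runif(3) + (i > 6) * c(0.5, 0, 0)
      )
    }))
    out <- compare_enrichment(enr, "normal", "tumor")
    expect_equal(nrow(out), 3)
    expect_true(all(out$p_value >= 0 & out$p_value <= 1))
    expect_true(all(out$p_adjusted >= out$p_value - 1e-12))
    expect_equal(out$p_adjusted,
                 stats::p.adjust(out$p_value, method = "BH"))
  })
})
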