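toy_json <- system.file("extdata", "toy_tic.json", package = "pheflux")
toy_xml <- system.file("extdata", "toy_tic.xml", package = "pheflux")

test_that("JSON and SBML serializations load to the same network", {
  nj <- load_model(toy_json)
  nx <- load_model(toy_xml)
  for (net in list(nj, nx)) {
    expect_length(net$metabolites, 2)
    expect_equal(nrow(net$reactions), 4)
    expect_equal(net$reactions$id, c("v1", "v2", "v3", "v4"))
    expect_equal(net$reactions$lb, rep(0, 4))
    expect_equal(net$reactions$ub, rep(1000, 4))
    expect_equal(net$reactions$gpr, c("g1", "g2", "g3", "g4"))
    expect_setequal(net$exchange_reactions, c("v1", "v4"))
  }
  expect_equal(as.matrix(nj$S), as.matrix(nx$S))
  expect_equal(nj$reactions$subsystem, nx$reactions$subsystem)
})

test_that("loaded fixture matches the in-code toy network", {
  nj <- load_model(toy_json)
  toy <- toy_tic_network()
  expect_equal(as.matrix(nj$S), as.matrix(toy$S))
  expect_equal(nj$reactions[c("id", "lb", "ub", "gpr")],
               toy$reactions[c("id", "lb", "ub", "gpr")])
})

test_that("degenerate and malformed models are rejected", {
  empty <- tempfile(fileext = ".json")
  writeLines('{"metabolites": [], "reactions": [], "genes": []}', empty)
  expect_error(load_model(empty), class = "pheflux_validation_error")

  broken <- tempfile(fileext = ".json")
  writeLines('{"metabolites": [', broken)
  expect_error(load_model(broken), class = "pheflux_format_error")

  bad_met <- tempfile(fileext = ".json")
  writeLines('{"metabolites": [{"id": "A"}],
               "reactions": [{"id": "r1", "metabolites": {"ZZZ": 1}}]}',
             bad_met)
  expect_error(load_model(bad_met), class = "pheflux_format_error",
               regexp = "ZZZ")

  expect_error(load_model("does/not/exist.json"), class = "pheflux_io_error")
})

test_that("network validation enforces bound ordering and biomass membership", {
  S <- matrix(c(1, -1), nrow = 1, dimnames = list("A", c("r1", "r2")))
  expect_error(
    metabolic_network(S, reactions = tibble::tibble(id = c("r1", "r2"),
                                                    lb = c(5, 0),
                                                    ub = c(1, 1000))),
    class = "pheflux_validation_error"
  )
  expect_error(
    metabolic_network(S, biomass_reaction = "nope"),
    class = "pheflux_validation_error"
  )
})

test_that("split_reversible counts, bounds and pairing follow the sign decomposition", {
  S <- matrix(c(1, -1, 0, 0, 1, -1), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("r1", "r2", "r3")))
  net <- metabolic_network(
    S, reactions = tibble::tibble(id = c("r1", "r2", "r3"),
                                  lb = c(0, -10, 0), ub = c(1000, 10, 1000),
                                  reversible = c(FALSE, TRUE, FALSE))
  )
  sp <- split_reversible(net)
  expect_length(sp$reaction_ids, 4)
  expect_true(all(sp$lb >= 0))
  rev_row <- sp$pairing[sp$pairing$reaction_id == "r2", ]
  expect_equal(sp$lb[rev_row$forward], 0)
  expect_equal(sp$ub[rev_row$forward], 10)
  expect_equal(sp$lb[rev_row$reverse], 0)
  expect_equal(sp$ub[rev_row$reverse], 10)
  # reverse column is the negated forward column
  expect_equal(as.numeric(sp$S[, rev_row$reverse]),
               -as.numeric(sp$S[, rev_row$forward]))

  # all-irreversible network: identity pairing
  toy <- toy_tic_network()
  tsp <- split_reversible(toy)
  expect_length(tsp$reaction_ids, 4)
  expect_true(all(is.na(tsp$pairing$reverse)))
})

test_that("net-flux reconstruction is the identity on feasible original fluxes", {
  net <- make_synthetic_network(seed = 5)
  sp <- split_reversible(net)
  samples <- sample_fluxomes(net, 5, thinning = 20, seed = 2)
  for (i in seq_len(nrow(samples))) {
    v_orig <- samples[i, ]
    v_split <- pheflux:::split_embed(sp, v_orig)
    expect_true(all(v_split >= 0))
    expect_equal(unname(net_fluxes(sp, v_split)), unname(v_orig),
                 tolerance = 1e-10)
  }
})

test_that("apply_medium updates only the named bounds", {
  net <- toy_tic_network()
  before <- net$reactions
  out <- apply_medium(net, list(v1 = c(0, 10)))
  expect_equal(out$reactions$ub[out$reactions$id == "v1"], 10)
  other <- out$reactions$id != "v1"
  expect_equal(out$reactions[other, ], before[other, ])

  expect_error(apply_medium(net, list(nope = c(0, 1))),
               class = "pheflux_lookup_error")
  expect_equal(apply_medium(net, list()), net)

  medium <- read_medium(system.file("extdata", "toy_medium.tsv",
                                    package = "pheflux"))
  out2 <- apply_medium(net, medium)
  expect_equal(out2$reactions$ub[out2$reactions$id == "v1"], 10)
})

test_that("closing all uptakes then reopening a subset leaves exactly that subset open", {
  net <- make_synthetic_network(seed = 3)
  uptakes <- grep("^EX_", net$reactions$id, value = TRUE)
  closed <- apply_medium(net, tibble::tibble(reaction_id = uptakes,
                                             lb = 0, ub = 0))
  expect_true(all(closed$reactions$ub[closed$reactions$id %in% uptakes] == 0))
  reopened <- apply_medium(closed, tibble::tibble(reaction_id = uptakes[1:2],
                                                  lb = 0, ub = 10))
  open_now <- reopened$reactions$id[
    reopened$reactions$id %in% uptakes & reopened$reactions$ub > 0
  ]
  expect_setequal(open_now, uptakes[1:2])
})
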