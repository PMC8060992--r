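test_that("constructors validate their invariants", {
  expect_error(metabolite(""), "non-empty")
  expect_identical(metabolite("glc")$name, "glc")  # name defaults to id
  expect_identical(metabolite("glc", name = "glucose")$name, "glucose")

  expect_error(reaction("Rx", c(A = 0), "B"), "coefficients must be > 0")
  expect_error(reaction("Rx", c(A = -2), "B"), "coefficients must be > 0")
  expect_error(reaction("Rx", "A", "B", direction = "SIDEWAYS"))

  expect_error(
    metabolic_network("n",
      metabolites = list(metabolite("A"), metabolite("A")),
      reactions = list()),
    "duplicate metabolite")
  expect_error(
    metabolic_network("n",
      metabolites = list(metabolite("A")),
      reactions = list(reaction("R9", "A", "ghost"))),
    "R9.*ghost")
  expect_error(
    metabolic_network("n", metabolites = list(metabolite("A")),
                      reactions = list(), ubiquitous_ids = "missing"),
    "missing")
})

test_that("participant resolution is enforced at construction, and ids are case-sensitive", {
  expect_error(
    metabolic_network("n",
      metabolites = list(metabolite("atp")),
      reactions = list(reaction("R1", "ATP", "atp"))),
    "R1.*ATP")
})

test_that("missing equations are synthesized from participants and direction", {
  net <- metabolic_network("n",
    metabolites = list(metabolite("A", name = "alpha"), metabolite("B", name = "beta"),
                       metabolite("C", name = "gamma")),
    reactions = list(
      reaction("R1", c(A = 2, B = 1), "C"),
      reaction("R2", "C", "A", direction = "REVERSIBLE"),
      reaction("R3", "A", "B", direction = "RIGHT_TO_LEFT"),
      reaction("R4", "A", "B", direction = "UNSPECIFIED"),
      reaction("R5", "A", "B", equation = "custom text")))
  expect_identical(net$reactions$R1$equation, "2 alpha + beta -> gamma")
  expect_identical(net$reactions$R2$equation, "gamma <=> alpha")
  expect_identical(net$reactions$R3$equation, "alpha <- beta")
  expect_identical(net$reactions$R4$equation, "alpha <?> beta")
  expect_identical(net$reactions$R5$equation, "custom text")
})

test_that("ubiquitous flags and the network-level set stay in sync", {
  net <- toy_network()
  expect_setequal(net$ubiquitous_ids, c("water", "pi"))
  expect_true(net$metabolites$water$is_ubiquitous)

  net2 <- set_ubiquitous(net, c("water", "Q"))
  expect_setequal(net2$ubiquitous_ids, c("water", "Q"))
  expect_false(net2$metabolites$pi$is_ubiquitous)
  expect_true(net2$metabolites$Q$is_ubiquitous)
  expect_error(set_ubiquitous(net, "nope"), "nope")
  # the override changes neighbor lists accordingly
  expect_false("Q" %in% names(neighborhood(net2, "D")$precursors))
})

test_that("network_equal ignores collection order but not content", {
  net <- toy_network()
  shuffled <- metabolic_network(net$id,
    metabolites = rev(unname(net$metabolites)),
    reactions = rev(unname(net$reactions)),
    ubiquitous_ids = rev(net$ubiquitous_ids))
  expect_true(network_equal(net, shuffled))

  altered <- net
  altered$reactions$R1$ec_number <- "9.9.9.9"
  expect_false(network_equal(net, altered))
})
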