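test_that("effective sides follow the direction semantics", {
  r <- reaction("R", "A", "B")
  expect_identical(lapply(effective_sides(r), `[[`, "reactants"), list("A"))
  r <- reaction("R", "A", "B", direction = "RIGHT_TO_LEFT")
  s <- effective_sides(r)
  expect_length(s, 1L)
  expect_identical(s[[1]]$reactants, "B")
  expect_identical(s[[1]]$products, "A")
  for (d in c("REVERSIBLE", "UNSPECIFIED")) {
    s <- effective_sides(reaction("R", "A", "B", direction = d))
    expect_length(s, 2L)
    expect_setequal(vapply(s, `[[`, character(1), "orientation"), c("f", "r"))
  }
})

test_that("toy neighborhoods match the stated precursor/successor definitions", {
  net <- toy_network()
  nb <- neighborhood(net, "B")
  # precursors of B: A via R1, C via the reversible R2, D via the
  # unspecified-direction R6, P via spontaneous R4
  expect_identical(lapply(nb$precursors, `[[`, "reactions")[order(names(nb$precursors))],
                   list(A = "R1", C = "R2", D = "R6", P = "R4"))
  # successors of B: C via R2, D via R5 and R6
  expect_identical(nb$successors$D$reactions, c("R5", "R6"))
  expect_setequal(names(nb$successors), c("C", "D"))
  # ubiquitous water (a reactant of R1) never appears
  expect_false("water" %in% names(nb$precursors))
  # isolated metabolite
  net2 <- metabolic_network("iso", list(metabolite("X"), metabolite("Y")),
                            list(reaction("R", "X", "Y")))
  nb2 <- neighborhood(net2, "Y")
  expect_length(neighborhood(net2, "X")$precursors, 0L)
  expect_identical(names(nb2$precursors), "X")
})

test_that("ubiquitous products/reactants are omitted but remain side metabolites", {
  net <- toy_network()
  # R3: C -> D + pi ; pi is ubiquitous
  expect_false("pi" %in% names(neighborhood(net, "C")$successors))
  sides <- side_metabolites(net$reactions$R3, "C", "D", "f")
  expect_identical(sides$co_products, "pi")
  sides1 <- side_metabolites(net$reactions$R1, "A", "B", "f")
  expect_identical(sides1$co_reactants, "water")
})

test_that("a reaction never makes a metabolite its own neighbor", {
  net <- metabolic_network("self",
    metabolites = list(metabolite("A"), metabolite("B")),
    reactions = list(reaction("R", c(A = 1), c(A = 1, B = 1), direction = "REVERSIBLE")))
  nb <- neighborhood(net, "A")
  expect_false("A" %in% names(nb$precursors))
  expect_false("A" %in% names(nb$successors))
  expect_true("B" %in% names(nb$successors))
})

test_that("entries are ordered by display name then id", {
  net <- metabolic_network("ord",
    metabolites = list(metabolite("M1", name = "zeta"), metabolite("M2", name = "alpha"),
                       metabolite("M3", name = "alpha"), metabolite("X")),
    reactions = list(reaction("Ra", "M1", "X"), reaction("Rb", "M2", "X"),
                     reaction("Rc", "M3", "X")))
  nb <- neighborhood(net, "X")
  expect_identical(names(nb$precursors), c("M2", "M3", "M1"))
})

test_that("connection classification applies the documented precedence", {
  net <- toy_network()
  expect_identical(classify_connection(net, "B", "A", "precursor"), "UNIDIRECTIONAL")
  expect_identical(classify_connection(net, "B", "C", "successor"), "BIDIRECTIONAL")
  expect_identical(classify_connection(net, "B", "P", "precursor"), "SPONTANEOUS")
  # two linking reactions, one of them unspecified-direction: MULTIPLE wins
  expect_identical(classify_connection(net, "B", "D", "successor"), "MULTIPLE")
  expect_identical(classify_connection(net, "Q", "D", "successor"), "UNIDIRECTIONAL")
  expect_error(classify_connection(net, "B", "Q", "successor"), "not a successor")
})

test_that("side_metabolites validates orientation and mains", {
  net <- metabolic_network("s",
    metabolites = list(metabolite("A"), metabolite("B"), metabolite("C")),
    reactions = list(reaction("R", c(A = 1), c(B = 1, C = 1), direction = "REVERSIBLE"),
                     reaction("Rf", "A", "B")))
  # A <=> B + C used right-to-left with mains (B, A): co-reactant C
  s <- side_metabolites(net$reactions$R, "B", "A", "r")
  expect_identical(s$co_reactants, "C")
  expect_length(s$co_products, 0L)
  s2 <- side_metabolites(net$reactions$Rf, "A", "B", "f")
  expect_length(s2$co_reactants, 0L)
  expect_length(s2$co_products, 0L)
  expect_error(side_metabolites(net$reactions$Rf, "A", "B", "r"), "orientation")
  expect_error(side_metabolites(net$reactions$R, "C", "A", "f"), "reactant side")
})

test_that("neighborhoods equal the brute-force oracle on random networks", {
  for (seed in 1:6) {
    net <- generate_network(small_spec(seed, p_reversible = 0.4, p_spontaneous = 0.1))
    pairs <- oracle_pairs(net)
    for (mid in names(net$metabolites)) expect_matches_oracle(net, mid, pairs)
  }
})

test_that("successor/precursor symmetry holds on random networks", {
  for (seed in 7:9) {
    net <- generate_network(small_spec(seed))
    for (mid in setdiff(names(net$metabolites), net$ubiquitous_ids)) {
      nb <- neighborhood(net, mid)
      for (e in nb$successors) {
        back <- neighborhood(net, e$neighbor_id)$precursors[[mid]]
        expect_identical(back$reactions, e$reactions)
      }
    }
  }
})

test_that("a single reversible link yields dual membership", {
  net <- metabolic_network("dual",
    metabolites = list(metabolite("M"), metabolite("N")),
    reactions = list(reaction("R", "M", "N", direction = "REVERSIBLE")))
  nb <- neighborhood(net, "M")
  expect_identical(names(nb$precursors), "N")
  expect_identical(names(nb$successors), "N")
})

test_that("the cache has no semantic effect", {
  net <- generate_network(small_spec(21))
  for (mid in sample(names(net$metabolites), 10)) {
    cached <- neighborhood(net, mid)               # fills / reads cache
    fresh <- neighborhood(net, mid, use_cache = FALSE)
    expect_identical(fresh, cached)
  }
})

test_that("unknown focal metabolites are rejected", {
  expect_error(neighborhood(toy_network(), "nope"), "nope")
})
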