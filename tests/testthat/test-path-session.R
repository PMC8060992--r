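# Network with an unambiguous A -> B -> C chain plus the branches needed
# for the replacement rules.
chain_network <- function() {
  metabolic_network("chain",
    metabolites = lapply(c("A", "B", "C", "D", "P"), metabolite),
    reactions = list(
      reaction("R_ab", "A", "B"),
      reaction("R_bc", "B", "C"),
      reaction("R_bd", "B", "D"),
      reaction("R_pa", "P", "A"),
      reaction("R_pb", "P", "B"),
      reaction("R_cd", "C", "D")))
}

abc_session <- function(net = chain_network()) {
  s <- start_session(net, "A")
  s <- add_metabolite(s, 1, "B", "successor")
  add_metabolite(s, 2, "C", "successor")
}

test_that("a session starts as a single-step path with empty history", {
  net <- chain_network()
  s <- start_session(net, "A")
  expect_identical(path_metabolites(s$current), "A")
  expect_length(s$previous_paths, 0L)
  expect_length(validate_path(net, s$current), 0L)
  expect_error(start_session(net, "nope"), "nope")
  # starting at a metabolite with no reactions is legal
  net2 <- metabolic_network("lonely", list(metabolite("Z")), list())
  s2 <- start_session(net2, "Z")
  expect_length(neighborhood(net2, "Z")$successors, 0L)
})

test_that("end extensions grow the path and never touch history", {
  s <- abc_session()
  expect_identical(path_metabolites(s$current), c("A", "B", "C"))
  expect_length(s$previous_paths, 0L)
  s <- add_metabolite(s, 3, "D", "successor")          # successor of last
  expect_identical(path_metabolites(s$current), c("A", "B", "C", "D"))
  expect_length(s$previous_paths, 0L)
  s2 <- add_metabolite(abc_session(), 1, "P", "precursor")  # precursor of first
  expect_identical(path_metabolites(s2$current), c("P", "A", "B", "C"))
  expect_length(s2$previous_paths, 0L)
})

test_that("attaching at an intermediate anchor replaces and archives", {
  # successor at intermediate B: downstream portion discarded
  s <- add_metabolite(abc_session(), 2, "D", "successor")
  expect_identical(path_metabolites(s$current), c("A", "B", "D"))
  expect_length(s$previous_paths, 1L)
  expect_identical(path_metabolites(s$previous_paths[[1]]), c("A", "B", "C"))
  expect_length(validate_path(s$network, s$current), 0L)

  # precursor at intermediate B: upstream portion discarded
  s2 <- add_metabolite(abc_session(), 2, "P", "precursor")
  expect_identical(path_metabolites(s2$current), c("P", "B", "C"))
  expect_length(s2$previous_paths, 1L)
  expect_identical(path_metabolites(s2$previous_paths[[1]]), c("A", "B", "C"))
})

test_that("bad anchors and unconnected neighbors are rejected", {
  s <- abc_session()
  expect_error(add_metabolite(s, 9, "D", "successor"), "anchor index")
  expect_error(add_metabolite(s, 1, "D", "successor"), "not a successor")
  expect_error(add_metabolite(s, 3, "C", "precursor"), "not a precursor")
  expect_error(add_metabolite(s, 3, "D", "successor", reaction_id = "R_ab"),
               "R_ab")
})

test_that("reaction selection changes the displayed reaction only", {
  net <- metabolic_network("multi",
    metabolites = lapply(c("A", "B"), metabolite),
    reactions = list(reaction("R5", "A", "B"), reaction("R9", "A", "B"),
                     reaction("RX", "B", "A")))
  s <- start_session(net, "A")
  s <- add_metabolite(s, 1, "B", "successor")
  expect_identical(s$current$steps[[1]]$successor_reaction, "R5")  # smallest id default
  s <- select_reaction(s, 1, "R9")
  expect_identical(s$current$steps[[1]]$successor_reaction, "R9")
  expect_identical(path_metabolites(s$current), c("A", "B"))
  s2 <- select_reaction(s, 1, "R9")                                # idempotent
  expect_identical(s2, s)
  expect_error(select_reaction(s, 1, "RX"), "does not link")       # wrong direction
  expect_error(select_reaction(s, 2, "R5"), "step index")
  expect_length(validate_path(net, s$current), 0L)
})

test_that("restore swaps current and history entries (involution)", {
  s <- add_metabolite(abc_session(), 2, "D", "successor")
  expect_error(restore_previous(s, 5), "history index")
  r1 <- restore_previous(s, 1)
  expect_identical(path_metabolites(r1$current), c("A", "B", "C"))
  expect_identical(path_metabolites(r1$previous_paths[[1]]), c("A", "B", "D"))
  r2 <- restore_previous(r1, 1)
  expect_identical(r2, s)
  expect_error(restore_previous(abc_session(), 1), "history is empty")
})

test_that("validate_path reports orientation and structure violations", {
  net <- chain_network()
  ok <- abc_session(net)$current
  expect_length(validate_path(net, ok), 0L)

  # reaction used against its direction
  bad <- ok
  bad$steps[[1]]$orientation <- "r"
  expect_match(validate_path(net, bad), "orientation 'r'")

  # dangling successor reaction on the last step
  bad2 <- ok
  bad2$steps[[3]]$successor_reaction <- "R_bc"
  expect_match(validate_path(net, bad2), "dangling")

  # a non-terminal step with no reaction
  bad3 <- ok
  bad3$steps[[2]]$successor_reaction <- NULL
  expect_match(validate_path(net, bad3), "no successor reaction")

  # unknown elements
  bad4 <- ok
  bad4$steps[[2]]$metabolite_id <- "ghost"
  expect_match(paste(validate_path(net, bad4), collapse = " "), "ghost")
})

test_that("random operation sequences preserve every session invariant", {
  net <- generate_network(small_spec(99, p_reversible = 0.4))
  with_local_seed <- get("with_local_seed", asNamespace("metnav"))
  with_local_seed(2024, {
    starts <- sample(names(net$metabolites), 30)
    for (start in starts) {
      session <- start_session(net, start)
      for (k in 1:12) {
        op <- random_session_op(session)
        if (is.null(op)) break
        h0 <- length(session$previous_paths)
        session <- op$session
        h1 <- length(session$previous_paths)
        if (op$kind == "replace") expect_identical(h1, h0 + 1L)
        if (op$kind %in% c("extend", "select")) expect_identical(h1, h0)
        expect_length(validate_path(net, session$current), 0L)
      }
      for (p in session$previous_paths) {
        expect_length(validate_path(net, p), 0L)
      }
    }
  })
})

test_that("sessions survive a JSON save/load round trip", {
  s <- add_metabolite(abc_session(), 2, "D", "successor")
  s$settings <- display_settings(show_structures = TRUE, candidates_mode = "ENDS_ONLY")
  f <- withr::local_tempfile(fileext = ".json")
  write_session(s, f)
  got <- read_session(s$network, f)
  expect_identical(got$current, s$current)
  expect_identical(got$previous_paths, s$previous_paths)
  expect_identical(got$settings, s$settings)
  other <- metabolic_network("other", list(metabolite("A")), list())
  expect_error(read_session(other, f), "other")
})
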