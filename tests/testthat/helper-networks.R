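# Shared fixtures and the independent brute-force neighborhood oracle.
# The oracle deliberately re-derives direction semantics from first
# principles (a literal per-metabolite scan over every reaction and
# effective side) and never calls effective_sides()/neighborhood().

# Small hand-built network exercising every direction value, a currency
# metabolite, a spontaneous reaction and a multiply-linked pair.
toy_network <- function() {
  metabolic_network(
    "toynet",
    metabolites = list(
      metabolite("A", name = "alanine"),
      metabolite("B", name = "benzoate", smiles = "c1ccccc1C(=O)O"),
      metabolite("C", name = "citrate"),
      metabolite("D", name = "dihydroxyacetone"),
      metabolite("P", name = "pyruvate"),
      metabolite("Q", name = "quinate"),
      metabolite("water", name = "H2O", is_ubiquitous = TRUE),
      metabolite("pi", name = "phosphate", is_ubiquitous = TRUE)
    ),
    reactions = list(
      reaction("R1", c(A = 1, water = 1), "B", ec_number = "1.1.1.1",
               enzymes = "alanase", genes = "alaA", pathways = "PWY-1"),
      reaction("R2", "B", "C", direction = "REVERSIBLE", ec_number = "2.2.2.2",
               enzymes = c("benzylase", "benzylase II"), genes = c("bnzA", "bnzB")),
      reaction("R3", "C", c(D = 1, pi = 1)),
      reaction("R4", "P", "B", spontaneous = TRUE),
      reaction("R5", "B", "D"),
      reaction("R6", "B", "D", direction = "UNSPECIFIED"),
      reaction("R7", "D", "Q", direction = "RIGHT_TO_LEFT")
    )
  )
}

# Effective (reactant-side, product-side) id pairs, re-derived literally.
oracle_side_pairs <- function(rxn) {
  l <- names(rxn$left)
  r <- names(rxn$right)
  if (rxn$direction == "LEFT_TO_RIGHT") return(list(list(l, r)))
  if (rxn$direction == "RIGHT_TO_LEFT") return(list(list(r, l)))
  list(list(l, r), list(r, l))  # REVERSIBLE / UNSPECIFIED: both categories
}

# All (reaction, effective side) pairs of a network, for per-metabolite
# scanning.
oracle_pairs <- function(network) {
  out <- list()
  for (rxn in network$reactions) {
    for (s in oracle_side_pairs(rxn)) {
      out[[length(out) + 1L]] <- list(rid = rxn$id, reac = s[[1]], prod = s[[2]])
    }
  }
  out
}

# Brute-force neighborhood of one metabolite: maps neighbor id -> sorted
# reaction ids, for each side.
oracle_neighborhood <- function(network, mid, pairs = oracle_pairs(network)) {
  skip <- c(mid, network$ubiquitous_ids)
  pre <- list()
  suc <- list()
  for (p in pairs) {
    if (mid %in% p$prod) {
      for (nb in setdiff(p$reac, skip)) pre[[nb]] <- c(pre[[nb]], p$rid)
    }
    if (mid %in% p$reac) {
      for (nb in setdiff(p$prod, skip)) suc[[nb]] <- c(suc[[nb]], p$rid)
    }
  }
  list(pre = lapply(pre, function(x) sort(unique(x))),
       suc = lapply(suc, function(x) sort(unique(x))))
}

# neighborhood() result as comparable maps (neighbor id -> reactions),
# id-sorted on both routes.
nbhd_as_map <- function(nb) {
  to_map <- function(entries) {
    if (!length(entries)) return(list())
    m <- lapply(entries, `[[`, "reactions")
    m[order(names(m), method = "radix")]
  }
  list(pre = to_map(nb$precursors), suc = to_map(nb$successors))
}

sort_map <- function(m) {
  if (!length(m)) return(list())
  lapply(m[order(names(m), method = "radix")], identity)
}

expect_matches_oracle <- function(network, mid, pairs = oracle_pairs(network)) {
  got <- nbhd_as_map(neighborhood(network, mid))
  want <- oracle_neighborhood(network, mid, pairs)
  expect_identical(got$pre, sort_map(want$pre))
  expect_identical(got$suc, sort_map(want$suc))
}

small_spec <- function(seed, ...) {
  fixture_spec(n_metabolites = 40L, n_reactions = 80L, seed = seed, ...)
}

# Random valid operation applied to a session; returns NULL if no move
# is possible from the current state. Used by the state-machine
# soundness properties.
random_session_op <- function(session) {
  ops <- c("add", "add", "add", "select", "restore")
  for (op in sample(ops)) {
    if (op == "add") {
      n <- length(session$current$steps)
      anchor <- sample.int(n, 1)
      side <- sample(c("successor", "precursor"), 1)
      nb <- neighborhood(session$network, session$current$steps[[anchor]]$metabolite_id)
      entries <- if (side == "successor") nb$successors else nb$precursors
      if (!length(entries)) next
      e <- entries[[sample.int(length(entries), 1)]]
      rid <- if (stats::runif(1) < 0.5) sample(e$reactions, 1) else NULL
      return(list(kind = if ((side == "successor" && anchor < n) ||
                             (side == "precursor" && anchor > 1)) "replace" else "extend",
                  session = add_metabolite(session, anchor, e$neighbor_id, side, rid)))
    }
    if (op == "select") {
      n <- length(session$current$steps)
      if (n < 2L) next
      i <- sample.int(n - 1L, 1)
      from <- session$current$steps[[i]]$metabolite_id
      to <- session$current$steps[[i + 1L]]$metabolite_id
      nb <- neighborhood(session$network, from)
      rxns <- nb$successors[[to]]$reactions
      if (is.null(rxns)) next
      return(list(kind = "select",
                  session = select_reaction(session, i, sample(rxns, 1))))
    }
    if (op == "restore") {
      h <- length(session$previous_paths)
      if (!h) next
      return(list(kind = "restore",
                  session = restore_previous(session, sample.int(h, 1))))
    }
  }
  NULL
}
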