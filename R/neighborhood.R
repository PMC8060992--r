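# Metabolic neighborhoods: for a focal metabolite M, every precursor P
# (some reaction has P on an effective reactant side and M on the
# corresponding product side) and every successor S (the symmetric
# notion), each entry carrying the full list of linking reactions.
# Reversible and unspecified-direction reactions contribute in both
# directions, so a neighbor can legitimately appear in both lists.
# Ubiquitous (currency) metabolites are omitted from neighbor lists --
# but only there: side-metabolite display still shows them.

#' Effective side assignments of a reaction
#'
#' A reaction's directionality determines which of its sides can act as
#' the reactant side: `LEFT_TO_RIGHT` yields one (left, right) assignment,
#' `RIGHT_TO_LEFT` the swapped one, and `REVERSIBLE` or `UNSPECIFIED`
#' both.
#'
#' @param rxn An `mn_reaction`.
#' @return A list of one or two orientations; each has `reactants` and
#'   `products` (character vectors of metabolite ids) and `orientation`
#'   (`"f"` for left-to-right, `"r"` for right-to-left).
#' @export
effective_sides <- function(rxn) {
  stopifnot(inherits(rxn, "mn_reaction"))
  fwd <- list(reactants = names(rxn$left), products = names(rxn$right), orientation = "f")
  rev <- list(reactants = names(rxn$right), products = names(rxn$left), orientation = "r")
  switch(rxn$direction,
    LEFT_TO_RIGHT = list(fwd),
    RIGHT_TO_LEFT = list(rev),
    REVERSIBLE = list(fwd, rev),
    UNSPECIFIED = list(fwd, rev))
}

# One pass over all reactions builds precursor/successor adjacency for
# every metabolite at once: env maps focal id -> list(pre = env, suc = env)
# where the inner envs map neighbor id -> character vector of reaction ids.
build_nbr_index <- function(network) {
  ubi <- network$ubiquitous_ids
  idx <- new.env(parent = emptyenv())
  slot <- function(mid) {
    s <- idx[[mid]]
    if (is.null(s)) {
      s <- list(pre = new.env(parent = emptyenv()),
                suc = new.env(parent = emptyenv()))
      idx[[mid]] <- s
    }
    s
  }
  for (rxn in network$reactions) {
    for (side in effective_sides(rxn)) {
      reac <- side$reactants
      prod <- side$products
      # focal on the product side: reactants are its precursors
      for (m in prod) {
        nbrs <- setdiff(reac, c(m, ubi))
        if (!length(nbrs)) next
        s <- slot(m)
        for (p in nbrs) s$pre[[p]] <- c(s$pre[[p]], rxn$id)
      }
      # focal on the reactant side: products are its successors
      for (m in reac) {
        nbrs <- setdiff(prod, c(m, ubi))
        if (!length(nbrs)) next
        s <- slot(m)
        for (p in nbrs) s$suc[[p]] <- c(s$suc[[p]], rxn$id)
      }
    }
  }
  idx
}

nbr_index <- function(network, use_cache = TRUE) {
  cache <- attr(network, "nbr_cache")
  if (use_cache && !is.null(cache) && !is.null(cache$index)) return(cache$index)
  idx <- build_nbr_index(network)
  if (use_cache && !is.null(cache)) cache$index <- idx
  idx
}

# Convert one side of the index into sorted NeighborEntry records:
# ordered by display name then id, reactions deduplicated and sorted.
entries_from_env <- function(env, network) {
  ids <- ls(env)
  if (!length(ids)) return(list())
  nms <- vapply(ids, function(i) network$metabolites[[i]]$name, character(1))
  ord <- order(nms, ids, method = "radix")
  ids <- ids[ord]
  out <- lapply(ids, function(i) {
    list(neighbor_id = i, reactions = sort(unique(env[[i]])))
  })
  stats::setNames(out, ids)
}

#' Compute the metabolic neighborhood of a metabolite
#'
#' Returns the focal metabolite's precursors and successors under the
#' reversibility-aware direction semantics of [effective_sides()], each
#' neighbor carrying the complete list of reactions that link it to the
#' focal metabolite in that direction. Ubiquitous metabolites are omitted,
#' and a reaction never makes a metabolite its own neighbor. Entries are
#' sorted by display name, then id. The full-network adjacency index is
#' computed once and cached on the network; the cache is a pure
#' optimization with no semantic effect.
#'
#' @param network An `mn_network`.
#' @param metabolite_id Focal metabolite id (must exist in the network).
#' @param use_cache Set `FALSE` to recompute the index from scratch.
#' @return An object of class `mn_neighborhood`: `focal_id`, `precursors`
#'   and `successors`, the latter two being named lists of entries with
#'   `neighbor_id` and `reactions`.
#' @examples
#' net <- metabolic_network("toy",
#'   metabolites = list(metabolite("A"), metabolite("B"), metabolite("C")),
#'   reactions = list(reaction("R1", "A", "B"),
#'                    reaction("R2", "B", "C", direction = "REVERSIBLE")))
#' nb <- neighborhood(net, "B")
#' names(nb$precursors)   # "A" "C"  (C via the reversible R2)
#' names(nb$successors)   # "C"
#' @export
neighborhood <- function(network, metabolite_id, use_cache = TRUE) {
  stopifnot(inherits(network, "mn_network"))
  get_metabolite(network, metabolite_id)  # errors on unknown id
  idx <- nbr_index(network, use_cache)
  s <- idx[[metabolite_id]]
  pre <- if (is.null(s)) list() else entries_from_env(s$pre, network)
  suc <- if (is.null(s)) list() else entries_from_env(s$suc, network)
  structure(
    list(focal_id = metabolite_id, precursors = pre, successors = suc),
    class = "mn_neighborhood"
  )
}

#' @export
print.mn_neighborhood <- function(x, ...) {
  cat(sprintf("<mn_neighborhood of '%s': %d precursors, %d successors>\n",
              x$focal_id, length(x$precursors), length(x$successors)))
  invisible(x)
}

nbr_entry <- function(network, focal_id, neighbor_id, side) {
  side <- match.arg(side, c("precursor", "successor"))
  nb <- neighborhood(network, focal_id)
  lst <- if (side == "precursor") nb$precursors else nb$successors
  entry <- lst[[neighbor_id]]
  if (is.null(entry)) {
    stop(sprintf("'%s' is not a %s of '%s'", neighbor_id, side, focal_id), call. = FALSE)
  }
  entry
}

#' Classify a focal--neighbor connection for display coding
#'
#' The class of a connection depends only on the multiset of reactions
#' linking the pair on the given side: `MULTIPLE` when more than one
#' reaction links them; otherwise `SPONTANEOUS` if the single linking
#' reaction is spontaneous; otherwise `BIDIRECTIONAL` if its direction is
#' `REVERSIBLE` or `UNSPECIFIED`; otherwise `UNIDIRECTIONAL`. Multiplicity
#' dominates because it is the only property of the reaction set rather
#' than of one reaction.
#'
#' @param network An `mn_network`.
#' @param focal_id,neighbor_id Metabolite ids; `neighbor_id` must be on
#'   the stated side of `focal_id`'s neighborhood.
#' @param side `"precursor"` or `"successor"`.
#' @return One of `"UNIDIRECTIONAL"`, `"BIDIRECTIONAL"`, `"SPONTANEOUS"`,
#'   `"MULTIPLE"`.
#' @export
classify_connection <- function(network, focal_id, neighbor_id,
                                side = c("precursor", "successor")) {
  entry <- nbr_entry(network, focal_id, neighbor_id, side)
  rxns <- entry$reactions
  if (length(rxns) > 1L) return("MULTIPLE")
  r <- get_reaction(network, rxns)
  if (r$spontaneous) return("SPONTANEOUS")
  if (r$direction %in% c("REVERSIBLE", "UNSPECIFIED")) return("BIDIRECTIONAL")
  "UNIDIRECTIONAL"
}

#' Side metabolites of a reaction relative to a displayed step
#'
#' For a reaction displayed as the link between two main-path metabolites,
#' the side metabolites are all other participants: co-reactants are the
#' effective reactant side minus the incoming main metabolite, co-products
#' the effective product side minus the outgoing one. Ubiquitous
#' metabolites ARE included here -- the currency omission applies only to
#' neighbor lists.
#'
#' @param rxn An `mn_reaction`.
#' @param main_in Id of the main metabolite on the effective reactant side.
#' @param main_out Id of the main metabolite on the effective product side.
#' @param orientation `"f"` (left side reacts) or `"r"` (right side
#'   reacts); must be an effective orientation of the reaction, with the
#'   mains on the required sides.
#' @return List with `co_reactants` and `co_products` (character vectors).
#' @export
side_metabolites <- function(rxn, main_in, main_out, orientation = c("f", "r")) {
  stopifnot(inherits(rxn, "mn_reaction"))
  orientation <- match.arg(orientation)
  sides <- effective_sides(rxn)
  chosen <- NULL
  for (s in sides) if (s$orientation == orientation) chosen <- s
  if (is.null(chosen)) {
    stop(sprintf("reaction '%s' (%s) has no effective orientation '%s'",
                 rxn$id, rxn$direction, orientation), call. = FALSE)
  }
  if (!main_in %in% chosen$reactants) {
    stop(sprintf("'%s' is not on the effective reactant side of '%s'", main_in, rxn$id), call. = FALSE)
  }
  if (!main_out %in% chosen$products) {
    stop(sprintf("'%s' is not on the effective product side of '%s'", main_out, rxn$id), call. = FALSE)
  }
  list(co_reactants = setdiff(chosen$reactants, main_in),
       co_products = setdiff(chosen$products, main_out))
}
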