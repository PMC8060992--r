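# A path is an ordered, non-empty list of steps; each step is a
# metabolite plus, for non-terminal steps, the successor reaction chosen
# to link it to the next step's metabolite and the orientation in which
# that reaction is used ("f" = left side reacts, "r" = right side reacts).
# Only a single linear path exists at a time; branches live solely in the
# candidate lists of each step's neighborhood.

path_step <- function(metabolite_id, successor_reaction = NULL, orientation = NULL) {
  list(metabolite_id = metabolite_id,
       successor_reaction = successor_reaction,
       orientation = orientation)
}

new_path <- function(steps) {
  structure(list(steps = steps), class = "mn_path")
}

#' Metabolite ids of a path, in step order
#'
#' @param path An `mn_path`.
#' @return Character vector of metabolite ids.
#' @export
path_metabolites <- function(path) {
  stopifnot(inherits(path, "mn_path"))
  vapply(path$steps, `[[`, character(1), "metabolite_id")
}

#' @export
print.mn_path <- function(x, ...) {
  cat(sprintf("<mn_path: %s>\n", paste(path_metabolites(x), collapse = " -> ")))
  invisible(x)
}

# Orientations in which rxn links `from` (effective reactant side) to
# `to` (effective product side). Zero, one or two of "f"/"r".
orientations_linking <- function(rxn, from, to) {
  out <- character(0)
  for (s in effective_sides(rxn)) {
    if (from %in% s$reactants && to %in% s$products) out <- c(out, s$orientation)
  }
  out
}

# All reactions of the network linking from -> to in some effective
# orientation, sorted; independent of the ubiquitous set.
linking_reactions <- function(network, from, to) {
  hits <- character(0)
  for (rxn in network$reactions) {
    if (length(orientations_linking(rxn, from, to))) hits <- c(hits, rxn$id)
  }
  sort(hits, method = "radix")
}

#' Validate a path against a network
#'
#' Checks every structural invariant of a linear path: all metabolites and
#' reactions exist, every adjacent pair is linked by its recorded reaction
#' in its recorded orientation, non-terminal steps carry a reaction, and
#' the last step carries none. Violations are returned, not raised, so
#' this is usable as a property check.
#'
#' @param network An `mn_network`.
#' @param path An `mn_path`.
#' @return Character vector of violation messages; empty if the path is
#'   valid.
#' @export
validate_path <- function(network, path) {
  stopifnot(inherits(network, "mn_network"))
  v <- character(0)
  if (!inherits(path, "mn_path") || length(path$steps) == 0L) {
    return("path must contain at least one step")
  }
  n <- length(path$steps)
  for (i in seq_len(n)) {
    st <- path$steps[[i]]
    if (is.null(network$metabolites[[st$metabolite_id]])) {
      v <- c(v, sprintf("step %d: unknown metabolite '%s'", i, st$metabolite_id))
      next
    }
    if (i == n) {
      if (!is.null(st$successor_reaction)) {
        v <- c(v, sprintf("step %d: last step carries a dangling successor reaction '%s'",
                          i, st$successor_reaction))
      }
      next
    }
    nxt <- path$steps[[i + 1L]]$metabolite_id
    if (is.null(st$successor_reaction)) {
      v <- c(v, sprintf("step %d: no successor reaction linking '%s' to '%s'",
                        i, st$metabolite_id, nxt))
      next
    }
    rxn <- network$reactions[[st$successor_reaction]]
    if (is.null(rxn)) {
      v <- c(v, sprintf("step %d: unknown reaction '%s'", i, st$successor_reaction))
      next
    }
    ok <- orientations_linking(rxn, st$metabolite_id, nxt)
    if (is.null(st$orientation) || !st$orientation %in% c("f", "r")) {
      v <- c(v, sprintf("step %d: missing or invalid orientation for reaction '%s'",
                        i, st$successor_reaction))
    } else if (!st$orientation %in% ok) {
      v <- c(v, sprintf(
        "step %d: reaction '%s' (%s) does not link '%s' to '%s' in orientation '%s'",
        i, rxn$id, rxn$direction, st$metabolite_id, nxt, st$orientation))
    }
  }
  v
}
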