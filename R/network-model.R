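# Domain types: metabolites, reactions, networks.
#
# All three are plain S3 lists validated at construction time: a
# metabolic_network() that exists is a network whose reaction participants
# all resolve. Queries never re-validate.

DIRECTIONS <- c("LEFT_TO_RIGHT", "RIGHT_TO_LEFT", "REVERSIBLE", "UNSPECIFIED")

#' Create a metabolite
#'
#' A metabolite is a node of the network: an id, a display name, an
#' optional SMILES structure string, and a flag marking it as a ubiquitous
#' (currency) molecule such as water, H+ or phosphate. Ubiquitous
#' metabolites are omitted from precursor/successor lists (but not from
#' side-metabolite display).
#'
#' @param id Unique identifier string (non-empty; compared case-sensitively).
#' @param name Display name; defaults to `id` when absent.
#' @param smiles Optional SMILES string, or `NULL`.
#' @param is_ubiquitous Logical; marks a currency metabolite.
#' @return An object of class `mn_metabolite`.
#' @examples
#' metabolite("atp", name = "ATP")
#' @export
metabolite <- function(id, name = NULL, smiles = NULL, is_ubiquitous = FALSE) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("metabolite id must be a single non-empty string", call. = FALSE)
  }
  if (is.null(name) || is.na(name) || !nzchar(name)) name <- id
  if (!is.null(smiles)) smiles <- as.character(smiles)
  structure(
    list(id = id, name = as.character(name), smiles = smiles,
         is_ubiquitous = isTRUE(is_ubiquitous)),
    class = "mn_metabolite"
  )
}

# Normalize a reaction side: accepts a named numeric vector
# (ids -> coefficients) or a bare character vector (all coefficients 1).
as_side <- function(x, what, rxn_id) {
  if (is.null(x) || length(x) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  if (is.character(x)) x <- stats::setNames(rep(1, length(x)), x)
  if (!is.numeric(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    stop(sprintf("reaction '%s': %s side must be a named numeric vector or character vector", rxn_id, what), call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("reaction '%s': all %s coefficients must be > 0", rxn_id, what), call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    x <- tapply(x, names(x), sum)
    x <- stats::setNames(as.numeric(x), names(x))
  }
  x
}

#' Create a reaction
#'
#' A reaction has two sides (`left`, `right`), each a set of metabolite ids
#' with positive stoichiometric coefficients, a directionality, and
#' optional annotations: a human-readable equation, an EC number, enzyme,
#' gene and pathway names, and a spontaneous flag (no enzyme required).
#'
#' Directionality is one of `"LEFT_TO_RIGHT"`, `"RIGHT_TO_LEFT"`,
#' `"REVERSIBLE"` or `"UNSPECIFIED"`. Reversible and unspecified reactions
#' contribute connections in both directions (see [effective_sides()]).
#'
#' @param id Unique identifier string.
#' @param left,right Participants: a named numeric vector of coefficients
#'   (names are metabolite ids), or a character vector of ids (all
#'   coefficients 1).
#' @param direction One of the four direction values.
#' @param equation Human-readable equation; synthesized from participants
#'   and direction by [metabolic_network()] when absent.
#' @param ec_number Optional EC number string, or `NULL`.
#' @param enzymes,genes,pathways Character vectors of names.
#' @param spontaneous Logical; `TRUE` for uncatalyzed reactions.
#' @return An object of class `mn_reaction`.
#' @examples
#' reaction("R1", left = c(akg = 1, ala = 1), right = c(glu = 1, pyr = 1),
#'          direction = "REVERSIBLE", ec_number = "2.6.1.2")
#' @export
reaction <- function(id, left, right, direction = "LEFT_TO_RIGHT",
                     equation = NULL, ec_number = NULL,
                     enzymes = character(), genes = character(),
                     pathways = character(), spontaneous = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("reaction id must be a single non-empty string", call. = FALSE)
  }
  direction <- match.arg(direction, DIRECTIONS)
  structure(
    list(
      id = id,
      left = as_side(left, "left", id),
      right = as_side(right, "right", id),
      direction = direction,
      equation = if (is.null(equation)) NULL else as.character(equation),
      ec_number = if (is.null(ec_number) || is.na(ec_number) || !nzchar(ec_number)) NULL else as.character(ec_number),
      enzymes = as.character(enzymes),
      genes = as.character(genes),
      pathways = as.character(pathways),
      spontaneous = isTRUE(spontaneous)
    ),
    class = "mn_reaction"
  )
}

arrow_for <- function(direction) {
  switch(direction,
    LEFT_TO_RIGHT = "->",
    RIGHT_TO_LEFT = "<-",
    REVERSIBLE    = "<=>",
    UNSPECIFIED   = "<?>")
}

format_side <- function(side, names_of) {
  if (length(side) == 0L) return("(none)")
  terms <- vapply(seq_along(side), function(i) {
    id <- names(side)[i]
    coef <- side[[i]]
    nm <- names_of(id)
    if (coef == 1) nm else paste(format(coef, trim = TRUE), nm)
  }, character(1))
  paste(terms, collapse = " + ")
}

# Deterministic equation text from participants + direction, using display
# names where the network knows them.
synthesize_equation <- function(rxn, names_of = identity) {
  paste(format_side(rxn$left, names_of), arrow_for(rxn$direction),
        format_side(rxn$right, names_of))
}

#' Assemble a metabolic network
#'
#' Collects metabolites and reactions into a validated network. Every
#' reaction participant must resolve to a metabolite id; violations are
#' reported naming the offending reaction. Metabolites flagged
#' `is_ubiquitous` and ids passed in `ubiquitous_ids` are merged into one
#' currency set, which [neighborhood()] omits from precursor/successor
#' lists. Reactions lacking an equation get one synthesized from their
#' participants' display names and direction.
#'
#' @param id Network identifier string.
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects.
#' @param ubiquitous_ids Character vector of currency-metabolite ids
#'   (must be a subset of the metabolite ids).
#' @return An object of class `mn_network` with fields `id`,
#'   `metabolites` (named list), `reactions` (named list) and
#'   `ubiquitous_ids`.
#' @examples
#' net <- metabolic_network("toy",
#'   metabolites = list(metabolite("A"), metabolite("B")),
#'   reactions = list(reaction("R1", "A", "B")))
#' @export
metabolic_network <- function(id, metabolites = list(), reactions = list(),
                              ubiquitous_ids = character()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("network id must be a single non-empty string", call. = FALSE)
  }
  stopifnot(is.list(metabolites), is.list(reactions))
  for (m in metabolites) {
    if (!inherits(m, "mn_metabolite")) stop("metabolites must be mn_metabolite objects", call. = FALSE)
  }
  for (r in reactions) {
    if (!inherits(r, "mn_reaction")) stop("reactions must be mn_reaction objects", call. = FALSE)
  }
  met_ids <- vapply(metabolites, `[[`, character(1), "id")
  if (anyDuplicated(met_ids)) {
    stop(sprintf("duplicate metabolite id(s): %s",
                 paste(unique(met_ids[duplicated(met_ids)]), collapse = ", ")), call. = FALSE)
  }
  rxn_ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rxn_ids)) {
    stop(sprintf("duplicate reaction id(s): %s",
                 paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", ")), call. = FALSE)
  }
  metabolites <- stats::setNames(metabolites, met_ids)
  reactions <- stats::setNames(reactions, rxn_ids)

  # Participant resolution, enforced here and never re-checked at query time.
  for (r in reactions) {
    missing <- setdiff(c(names(r$left), names(r$right)), met_ids)
    if (length(missing)) {
      stop(sprintf("reaction '%s' references unknown metabolite id(s): %s",
                   r$id, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }

  ubiquitous_ids <- unique(c(
    as.character(ubiquitous_ids),
    met_ids[vapply(metabolites, `[[`, logical(1), "is_ubiquitous")]
  ))
  bad_ubi <- setdiff(ubiquitous_ids, met_ids)
  if (length(bad_ubi)) {
    stop(sprintf("ubiquitous id(s) not in network: %s",
                 paste(bad_ubi, collapse = ", ")), call. = FALSE)
  }
  for (u in ubiquitous_ids) metabolites[[u]]$is_ubiquitous <- TRUE

  names_of <- function(mid) metabolites[[mid]]$name
  for (i in seq_along(reactions)) {
    if (is.null(reactions[[i]]$equation)) {
      reactions[[i]]$equation <- synthesize_equation(reactions[[i]], names_of)
    }
  }

  net <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         ubiquitous_ids = ubiquitous_ids),
    class = "mn_network"
  )
  attr(net, "nbr_cache") <- new.env(parent = emptyenv())
  net
}

#' Override a network's ubiquitous-metabolite set
#'
#' Replaces the currency set with `ids` (which must all exist in the
#' network) and clears the neighborhood cache. Use this to apply a custom
#' currency list, e.g. one read with [read_ubiquitous_list()].
#'
#' @param network An `mn_network`.
#' @param ids Character vector of metabolite ids; ids absent from the
#'   network are rejected.
#' @return The modified network.
#' @export
set_ubiquitous <- function(network, ids) {
  stopifnot(inherits(network, "mn_network"))
  ids <- unique(as.character(ids))
  bad <- setdiff(ids, names(network$metabolites))
  if (length(bad)) {
    stop(sprintf("ubiquitous id(s) not in network: %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (i in seq_along(network$metabolites)) {
    network$metabolites[[i]]$is_ubiquitous <- network$metabolites[[i]]$id %in% ids
  }
  network$ubiquitous_ids <- ids
  attr(network, "nbr_cache") <- new.env(parent = emptyenv())
  network
}

#' Structural equality of two networks
#'
#' Field-by-field comparison of id, metabolites (id, name, SMILES,
#' ubiquitous flag), reactions (participants, coefficients, direction and
#' all annotations) and the ubiquitous set. Ordering of the metabolite and
#' reaction collections is ignored; every other field must match exactly.
#' The neighborhood cache is excluded.
#'
#' @param a,b Networks to compare.
#' @return `TRUE` or `FALSE`.
#' @export
network_equal <- function(a, b) {
  stopifnot(inherits(a, "mn_network"), inherits(b, "mn_network"))
  strip <- function(net) {
    net$metabolites <- net$metabolites[order(names(net$metabolites))]
    net$reactions <- net$reactions[order(names(net$reactions))]
    net$reactions <- lapply(net$reactions, function(r) {
      r$left <- r$left[order(names(r$left))]
      r$right <- r$right[order(names(r$right))]
      r
    })
    net$ubiquitous_ids <- sort(net$ubiquitous_ids)
    attributes(net) <- list(names = names(net))
    net
  }
  isTRUE(all.equal(strip(a), strip(b), check.attributes = TRUE))
}

#' @export
print.mn_network <- function(x, ...) {
  cat(sprintf("<mn_network '%s': %d metabolites, %d reactions, %d ubiquitous>\n",
              x$id, length(x$metabolites), length(x$reactions),
              length(x$ubiquitous_ids)))
  invisible(x)
}

#' @export
print.mn_reaction <- function(x, ...) {
  eq <- if (is.null(x$equation)) synthesize_equation(x) else x$equation
  cat(sprintf("<mn_reaction '%s' [%s]%s> %s\n", x$id, x$direction,
              if (x$spontaneous) " spontaneous" else "", eq))
  invisible(x)
}

#' @export
print.mn_metabolite <- function(x, ...) {
  cat(sprintf("<mn_metabolite '%s' (%s)%s>\n", x$id, x$name,
              if (x$is_ubiquitous) " ubiquitous" else ""))
  invisible(x)
}

# Internal lookup helpers; callers guarantee existence was checked at the
# public boundary.
get_metabolite <- function(network, mid) {
  m <- network$metabolites[[mid]]
  if (is.null(m)) stop(sprintf("unknown metabolite id '%s'", mid), call. = FALSE)
  m
}

get_reaction <- function(network, rid) {
  r <- network$reactions[[rid]]
  if (is.null(r)) stop(sprintf("unknown reaction id '%s'", rid), call. = FALSE)
  r
}
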