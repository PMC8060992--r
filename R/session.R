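# The explorer session: one current linear path, a most-recent-first list
# of previous paths displaced by replacements, and display settings.
# Extension at the ends grows the path without touching history;
# replacement at an interior anchor saves the current path to history
# first. Restoring swaps rather than duplicates, so the user can switch
# back and forth among previous paths with bounded memory.

new_session <- function(network, current, previous_paths = list(),
                        settings = display_settings()) {
  structure(
    list(network = network, current = current,
         previous_paths = previous_paths, settings = settings),
    class = "mn_session"
  )
}

#' Start an exploration session at a metabolite
#'
#' @param network An `mn_network`.
#' @param start_id Id of the starting metabolite.
#' @param settings A [display_settings()] object.
#' @return An `mn_session` whose current path is the single starting
#'   step and whose history is empty.
#' @examples
#' net <- metabolic_network("toy",
#'   metabolites = list(metabolite("A"), metabolite("B")),
#'   reactions = list(reaction("R1", "A", "B")))
#' s <- start_session(net, "A")
#' path_metabolites(s$current)
#' @export
start_session <- function(network, start_id, settings = display_settings()) {
  stopifnot(inherits(network, "mn_network"))
  get_metabolite(network, start_id)
  new_session(network, new_path(list(path_step(start_id))), list(), settings)
}

#' @export
print.mn_session <- function(x, ...) {
  cat(sprintf("<mn_session on '%s'>\n  current: %s\n  history: %d previous path(s)\n",
              x$network$id, paste(path_metabolites(x$current), collapse = " -> "),
              length(x$previous_paths)))
  invisible(x)
}

# Choose the linking reaction (explicit or the lexicographically smallest)
# and its orientation (prefer "f") for the edge from -> to.
choose_link <- function(network, from, to, candidates, reaction_id) {
  rid <- if (is.null(reaction_id)) {
    sort(candidates, method = "radix")[1L]
  } else {
    if (!reaction_id %in% candidates) {
      stop(sprintf("reaction '%s' does not link '%s' and '%s' on that side",
                   reaction_id, from, to), call. = FALSE)
    }
    reaction_id
  }
  orients <- orientations_linking(get_reaction(network, rid), from, to)
  list(reaction = rid, orientation = orients[1L])
}

#' Add a neighbor metabolite to the current path
#'
#' Implements the extension/replacement rule of the explorer. If the new
#' metabolite is a precursor of the first step or a successor of the last
#' step, the path is extended in that direction and history is untouched.
#' If it attaches to an intermediate (or wrong-end) anchor, the current
#' path is first saved to history, the portion of the path on the side
#' where the neighbor attaches is discarded (a successor attachment
#' discards everything after the anchor, a precursor attachment everything
#' before it), and the new step is attached. The linking reaction is
#' `reaction_id` when given, otherwise the lexicographically smallest
#' reaction id linking the pair.
#'
#' @param session An `mn_session`.
#' @param anchor_index 1-based index of the path step the neighbor
#'   attaches to.
#' @param neighbor_id Metabolite to add; must be on the stated `side` of
#'   the anchor metabolite's [neighborhood()].
#' @param side `"successor"` or `"precursor"` -- the side of the anchor on
#'   which the neighbor sits.
#' @param reaction_id Optional linking reaction; must be among the
#'   reactions linking the pair on that side.
#' @return The updated session.
#' @export
add_metabolite <- function(session, anchor_index, neighbor_id,
                           side = c("successor", "precursor"),
                           reaction_id = NULL) {
  stopifnot(inherits(session, "mn_session"))
  side <- match.arg(side)
  steps <- session$current$steps
  n <- length(steps)
  if (!is.numeric(anchor_index) || length(anchor_index) != 1L ||
      anchor_index < 1L || anchor_index > n) {
    stop(sprintf("bad anchor index %s (path has %d step(s))",
                 paste(anchor_index, collapse = ","), n), call. = FALSE)
  }
  anchor_index <- as.integer(anchor_index)
  anchor_id <- steps[[anchor_index]]$metabolite_id
  nbr_side <- if (side == "successor") "successor" else "precursor"
  entry <- nbr_entry(session$network, anchor_id, neighbor_id, nbr_side)

  if (side == "successor") {
    link <- choose_link(session$network, anchor_id, neighbor_id,
                        entry$reactions, reaction_id)
    if (anchor_index < n) {
      session$previous_paths <- c(list(session$current), session$previous_paths)
      steps <- steps[seq_len(anchor_index)]
    }
    k <- length(steps)
    steps[[k]]$successor_reaction <- link$reaction
    steps[[k]]$orientation <- link$orientation
    steps[[k + 1L]] <- path_step(neighbor_id)
  } else {
    link <- choose_link(session$network, neighbor_id, anchor_id,
                        entry$reactions, reaction_id)
    if (anchor_index > 1L) {
      session$previous_paths <- c(list(session$current), session$previous_paths)
      steps <- steps[seq(anchor_index, n)]
    }
    steps <- c(list(path_step(neighbor_id, link$reaction, link$orientation)), steps)
  }
  session$current <- new_path(steps)
  session
}

#' Select which reaction is displayed for a path step
#'
#' When adjacent path metabolites are connected by multiple reactions,
#' any of them can be chosen for display; the path topology is unchanged.
#' Selecting the already-selected reaction is a no-op.
#'
#' @param session An `mn_session`.
#' @param step_index 1-based index of the step whose outgoing link is
#'   changed (must not be the last step).
#' @param reaction_id A reaction linking this step's metabolite to the
#'   next step's metabolite.
#' @return The updated session.
#' @export
select_reaction <- function(session, step_index, reaction_id) {
  stopifnot(inherits(session, "mn_session"))
  steps <- session$current$steps
  n <- length(steps)
  if (!is.numeric(step_index) || length(step_index) != 1L ||
      step_index < 1L || step_index >= n) {
    stop(sprintf("bad step index %s (path has %d step(s); the last step has no successor link)",
                 paste(step_index, collapse = ","), n), call. = FALSE)
  }
  step_index <- as.integer(step_index)
  from <- steps[[step_index]]$metabolite_id
  to <- steps[[step_index + 1L]]$metabolite_id
  rxn <- session$network$reactions[[reaction_id]]
  if (is.null(rxn)) {
    stop(sprintf("unknown reaction id '%s'", reaction_id), call. = FALSE)
  }
  orients <- orientations_linking(rxn, from, to)
  if (!length(orients)) {
    stop(sprintf("reaction '%s' does not link '%s' to '%s'", reaction_id, from, to),
         call. = FALSE)
  }
  steps[[step_index]]$successor_reaction <- reaction_id
  steps[[step_index]]$orientation <- orients[1L]
  session$current <- new_path(steps)
  session
}

#' Restore a path from the previous-paths history
#'
#' Swaps the current path with the chosen history entry: the displaced
#' current path takes the entry's place, so restoring the same slot twice
#' returns to the original state.
#'
#' @param session An `mn_session`.
#' @param history_index 1-based index into `previous_paths` (most recent
#'   first).
#' @return The updated session.
#' @export
restore_previous <- function(session, history_index) {
  stopifnot(inherits(session, "mn_session"))
  h <- length(session$previous_paths)
  if (h == 0L) stop("history is empty: nothing to restore", call. = FALSE)
  if (!is.numeric(history_index) || length(history_index) != 1L ||
      history_index < 1L || history_index > h) {
    stop(sprintf("bad history index %s (history has %d entries)",
                 paste(history_index, collapse = ","), h), call. = FALSE)
  }
  history_index <- as.integer(history_index)
  displaced <- session$current
  session$current <- session$previous_paths[[history_index]]
  session$previous_paths[[history_index]] <- displaced
  session
}

path_to_list <- function(path) {
  lapply(path$steps, function(st) {
    out <- list(metabolite = st$metabolite_id)
    if (!is.null(st$successor_reaction)) {
      out$reaction <- st$successor_reaction
      out$orientation <- st$orientation
    }
    out
  })
}

path_from_list <- function(lst) {
  new_path(lapply(lst, function(st) {
    path_step(as.character(st$metabolite),
              if (is.null(st$reaction)) NULL else as.character(st$reaction),
              if (is.null(st$orientation)) NULL else as.character(st$orientation))
  }))
}

#' Save a session as JSON
#'
#' Writes the network id, current path, history and display settings.
#' The network itself is not embedded; [read_session()] revalidates the
#' paths against the network it is given.
#'
#' @param session An `mn_session`.
#' @param path Output file path or connection.
#' @return Invisibly, the path.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "mn_session"))
  doc <- list(
    format = "metnav-session",
    version = 1L,
    network = session$network$id,
    current = path_to_list(session$current),
    previous_paths = lapply(session$previous_paths, path_to_list),
    settings = unclass(session$settings)
  )
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA),
             path, useBytes = TRUE)
  invisible(path)
}

#' Load a session saved by [write_session()]
#'
#' @param network The `mn_network` the session refers to; its id must
#'   match the one recorded in the file and every stored path must
#'   validate against it.
#' @param path Path to the JSON file.
#' @return An `mn_session`.
#' @export
read_session <- function(network, path) {
  stopifnot(inherits(network, "mn_network"))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "metnav-session")) {
    stop("not a metnav-session document", call. = FALSE)
  }
  if (!identical(as.character(doc$network), network$id)) {
    stop(sprintf("session was saved against network '%s', not '%s'",
                 doc$network, network$id), call. = FALSE)
  }
  current <- path_from_list(doc$current)
  history <- lapply(doc$previous_paths, path_from_list)
  for (p in c(list(current), history)) {
    v <- validate_path(network, p)
    if (length(v)) stop(paste(c("invalid session path:", v), collapse = "\n  "), call. = FALSE)
  }
  settings <- do.call(display_settings, doc$settings)
  new_session(network, current, history, settings)
}
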