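# Vertical linear pathway diagrams, in plain text and SVG 1.1.
#
# Both formats list the path metabolites top-to-bottom in step order and
# embed a stable machine-readable anchor for every element
# ("[@met:<id>]" markers in text, data-anchor attributes in SVG), so the
# rendering contract -- anchor sequence equals path order -- is testable.
# Each optional display element occupies its own line (text) or node
# (SVG), so toggling one settings flag changes exactly the elements it
# governs. The legend and codes are documented in RENDERING.md.

CONNECTION_CODES <- list(
  UNIDIRECTIONAL = list(code = "U", color = "#555555"),
  BIDIRECTIONAL  = list(code = "B", color = "#1f77b4"),
  SPONTANEOUS    = list(code = "S", color = "#2ca02c"),
  MULTIPLE       = list(code = "M", color = "#ff7f0e")
)

#' Display settings for pathway diagrams
#'
#' Defaults show side metabolites, enzymes/genes and EC numbers, keep
#' chemical structures off, show pathway links, and list
#' precursor/successor candidates at every step.
#'
#' @param show_side_metabolites Show co-reactants/co-products of each
#'   displayed reaction (currency metabolites included).
#' @param show_enzymes_genes Show enzyme and gene names per reaction.
#' @param show_ec Show EC numbers per reaction.
#' @param show_structures Show SMILES strings for path metabolites.
#' @param candidates_mode `"ALL_STEPS"`, `"ENDS_ONLY"` (candidates only at
#'   the first and last step) or `"NONE"`.
#' @param show_pathway_links Show pathway names per reaction.
#' @return An object of class `mn_display_settings`.
#' @export
display_settings <- function(show_side_metabolites = TRUE,
                             show_enzymes_genes = TRUE,
                             show_ec = TRUE,
                             show_structures = FALSE,
                             candidates_mode = c("ALL_STEPS", "ENDS_ONLY", "NONE"),
                             show_pathway_links = TRUE) {
  candidates_mode <- match.arg(candidates_mode)
  structure(
    list(show_side_metabolites = isTRUE(show_side_metabolites),
         show_enzymes_genes = isTRUE(show_enzymes_genes),
         show_ec = isTRUE(show_ec),
         show_structures = isTRUE(show_structures),
         candidates_mode = candidates_mode,
         show_pathway_links = isTRUE(show_pathway_links)),
    class = "mn_display_settings"
  )
}

# Connection class of a set of linking reactions (same precedence as
# classify_connection, usable for path links that bypass neighbor lists).
classify_rxn_set <- function(network, rxns) {
  if (length(rxns) > 1L) return("MULTIPLE")
  r <- get_reaction(network, rxns)
  if (r$spontaneous) return("SPONTANEOUS")
  if (r$direction %in% c("REVERSIBLE", "UNSPECIFIED")) return("BIDIRECTIONAL")
  "UNIDIRECTIONAL"
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

side_str <- function(ids, nm) {
  if (!length(ids)) return("(none)")
  paste("+", paste(vapply(ids, nm, character(1)), collapse = ", "))
}

show_candidates_at <- function(mode, i, n) {
  switch(mode,
    ALL_STEPS = TRUE,
    ENDS_ONLY = i == 1L || i == n,
    NONE = FALSE)
}

format_candidates <- function(network, entries, limit) {
  n <- length(entries)
  shown <- entries[seq_len(min(n, limit))]
  txt <- vapply(shown, function(e) {
    cls <- classify_rxn_set(network, e$reactions)
    sprintf("[@cand:%s] %s [%s]", enc_id(e$neighbor_id),
            network$metabolites[[e$neighbor_id]]$name,
            CONNECTION_CODES[[cls]]$code)
  }, character(1))
  if (n > limit) txt <- c(txt, sprintf("(+%d more)", n - limit))
  paste(txt, collapse = ", ")
}

# Per-step render model shared by the text and SVG backends.
diagram_model <- function(session, settings, candidate_limit) {
  network <- session$network
  steps <- session$current$steps
  n <- length(steps)
  lapply(seq_len(n), function(i) {
    st <- steps[[i]]
    m <- network$metabolites[[st$metabolite_id]]
    item <- list(index = i, id = m$id, name = m$name, smiles = m$smiles)
    if (show_candidates_at(settings$candidates_mode, i, n)) {
      nb <- neighborhood(network, m$id)
      item$precursors <- nb$precursors
      item$successors <- nb$successors
    }
    if (i < n) {
      nxt <- steps[[i + 1L]]$metabolite_id
      rxns <- linking_reactions(network, m$id, nxt)
      rxn <- get_reaction(network, st$successor_reaction)
      item$link <- list(
        reaction = rxn,
        orientation = st$orientation,
        n_reactions = length(rxns),
        class = classify_rxn_set(network, rxns),
        sides = side_metabolites(rxn, m$id, nxt, st$orientation)
      )
    }
    item
  })
}

render_text <- function(session, settings, candidate_limit) {
  network <- session$network
  model <- diagram_model(session, settings, candidate_limit)
  lines <- c(
    sprintf("Pathway diagram: %s (%d step%s)", network$id, length(model),
            if (length(model) == 1L) "" else "s"),
    "Legend: [U] unidirectional  [B] bidirectional  [S] spontaneous  [M] multiple reactions",
    ""
  )
  nm <- function(mid) network$metabolites[[mid]]$name
  for (item in model) {
    lines <- c(lines, sprintf("[@met:%s] %s", enc_id(item$id), item$name))
    if (settings$show_structures && !is.null(item$smiles)) {
      lines <- c(lines, sprintf("    structure: %s", item$smiles))
    }
    if (!is.null(item$precursors)) {
      lines <- c(lines, sprintf("    <- precursors: %s",
        if (length(item$precursors)) format_candidates(network, item$precursors, candidate_limit) else "(none)"))
      lines <- c(lines, sprintf("    -> successors: %s",
        if (length(item$successors)) format_candidates(network, item$successors, candidate_limit) else "(none)"))
    }
    link <- item$link
    if (!is.null(link)) {
      count <- if (link$n_reactions > 1L) {
        sprintf(" (showing 1 of %d reactions)", link$n_reactions)
      } else ""
      lines <- c(lines, sprintf("  | [@rxn:%s] %s [%s]%s",
                                enc_id(link$reaction$id), link$reaction$id,
                                CONNECTION_CODES[[link$class]]$code, count))
      if (settings$show_ec && !is.null(link$reaction$ec_number)) {
        lines <- c(lines, sprintf("  |   EC: %s", link$reaction$ec_number))
      }
      if (settings$show_enzymes_genes &&
          (length(link$reaction$enzymes) || length(link$reaction$genes))) {
        lines <- c(lines, sprintf("  |   enzymes: %s; genes: %s",
          if (length(link$reaction$enzymes)) paste(link$reaction$enzymes, collapse = ", ") else "-",
          if (length(link$reaction$genes)) paste(link$reaction$genes, collapse = ", ") else "-"))
      }
      if (settings$show_side_metabolites &&
          (length(link$sides$co_reactants) || length(link$sides$co_products))) {
        lines <- c(lines, sprintf("  |   side: %s => %s",
                                  side_str(link$sides$co_reactants, nm),
                                  side_str(link$sides$co_products, nm)))
      }
      if (settings$show_pathway_links && length(link$reaction$pathways)) {
        lines <- c(lines, sprintf("  |   pathways: %s",
                                  paste(link$reaction$pathways, collapse = ", ")))
      }
      lines <- c(lines, "  v")
    }
  }
  paste(lines, collapse = "\n")
}

svg_text_node <- function(x, y, content, anchor = NULL, fill = "#000000", size = 13) {
  attr_anchor <- if (is.null(anchor)) "" else sprintf(' data-anchor="%s"', xml_escape(anchor))
  sprintf('<text x="%d" y="%d" font-size="%d" fill="%s"%s>%s</text>',
          x, y, size, fill, attr_anchor, xml_escape(content))
}

render_svg <- function(session, settings, candidate_limit) {
  network <- session$network
  model <- diagram_model(session, settings, candidate_limit)
  cx <- 360L
  nodes <- character(0)
  y <- 40L
  nodes <- c(nodes, svg_text_node(20L, y, sprintf("Pathway diagram: %s", network$id), size = 15))
  y <- y + 20L
  leg <- paste(vapply(names(CONNECTION_CODES), function(k) {
    sprintf("[%s] %s", CONNECTION_CODES[[k]]$code, tolower(k))
  }, character(1)), collapse = "   ")
  nodes <- c(nodes, svg_text_node(20L, y, paste("Legend:", leg), size = 11, fill = "#333333"))
  y <- y + 30L
  nm <- function(mid) network$metabolites[[mid]]$name

  for (item in model) {
    nodes <- c(nodes, svg_text_node(cx, y, item$name,
                                    anchor = paste0("met:", enc_id(item$id)), size = 14))
    if (settings$show_structures && !is.null(item$smiles)) {
      y <- y + 16L
      nodes <- c(nodes, svg_text_node(cx, y, item$smiles, size = 10, fill = "#444444"))
    }
    if (!is.null(item$precursors)) {
      nodes <- c(nodes, svg_text_node(20L, y, paste("pre:",
        if (length(item$precursors)) format_candidates(network, item$precursors, candidate_limit) else "(none)"),
        size = 10, fill = "#666666"))
      y <- y + 14L
      nodes <- c(nodes, svg_text_node(20L, y, paste("suc:",
        if (length(item$successors)) format_candidates(network, item$successors, candidate_limit) else "(none)"),
        size = 10, fill = "#666666"))
    }
    link <- item$link
    if (!is.null(link)) {
      color <- CONNECTION_CODES[[link$class]]$color
      y0 <- y + 10L
      y1 <- y0 + 50L
      nodes <- c(nodes, sprintf(
        '<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="%s" stroke-width="2"/>',
        cx, y0, cx, y1, color))
      label <- link$reaction$id
      if (link$n_reactions > 1L) {
        label <- sprintf("%s (showing 1 of %d reactions)", label, link$n_reactions)
      }
      ly <- y0 + 14L
      nodes <- c(nodes, svg_text_node(cx + 12L, ly, label,
                                      anchor = paste0("rxn:", enc_id(link$reaction$id)),
                                      size = 11, fill = color))
      if (settings$show_ec && !is.null(link$reaction$ec_number)) {
        ly <- ly + 13L
        nodes <- c(nodes, svg_text_node(cx + 12L, ly, paste("EC:", link$reaction$ec_number),
                                        size = 10, fill = "#333333"))
      }
      if (settings$show_enzymes_genes &&
          (length(link$reaction$enzymes) || length(link$reaction$genes))) {
        ly <- ly + 13L
        nodes <- c(nodes, svg_text_node(cx + 12L, ly,
          sprintf("enzymes: %s; genes: %s",
                  paste(link$reaction$enzymes, collapse = ", "),
                  paste(link$reaction$genes, collapse = ", ")),
          size = 10, fill = "#333333"))
      }
      if (settings$show_side_metabolites &&
          (length(link$sides$co_reactants) || length(link$sides$co_products))) {
        ly <- ly + 13L
        nodes <- c(nodes, svg_text_node(cx + 12L, ly,
          sprintf("side: %s => %s",
                  side_str(link$sides$co_reactants, nm),
                  side_str(link$sides$co_products, nm)),
          size = 10, fill = "#333333"))
      }
      if (settings$show_pathway_links && length(link$reaction$pathways)) {
        ly <- ly + 13L
        nodes <- c(nodes, svg_text_node(cx + 12L, ly,
          paste("pathways:", paste(link$reaction$pathways, collapse = ", ")),
          size = 10, fill = "#333333"))
      }
      y <- y1 + 20L
    }
  }
  height <- y + 40L
  paste(c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="760" height="%d">', height),
          nodes, "</svg>"), collapse = "\n")
}

#' Render a session as a linear pathway diagram
#'
#' Draws the current path as a vertical diagram, metabolites
#' top-to-bottom in step order, each linking reaction annotated according
#' to the display settings and color/letter-coded by connection class.
#' For adjacent metabolites linked by several reactions the reaction
#' count is shown alongside the selected one. Candidate precursor and
#' successor lists appear per `candidates_mode`, truncated at
#' `candidate_limit` with an explicit `(+N more)` marker.
#'
#' @param session An `mn_session`.
#' @param settings A [display_settings()]; defaults to the session's own.
#' @param format `"text"` or `"svg"`.
#' @param candidate_limit Maximum candidates listed per side before
#'   truncation.
#' @return An object of class `mn_diagram`: `format`, `content` (a single
#'   string) and `legend` (the connection-class code/color mapping).
#' @export
render_diagram <- function(session, settings = session$settings,
                           format = c("text", "svg"), candidate_limit = 10L) {
  stopifnot(inherits(session, "mn_session"), inherits(settings, "mn_display_settings"))
  format <- match.arg(format)
  content <- if (format == "text") {
    render_text(session, settings, candidate_limit)
  } else {
    render_svg(session, settings, candidate_limit)
  }
  structure(list(format = toupper(format), content = content,
                 legend = CONNECTION_CODES),
            class = "mn_diagram")
}

#' @export
print.mn_diagram <- function(x, ...) {
  if (x$format == "TEXT") cat(x$content, "\n", sep = "")
  else cat(sprintf("<mn_diagram SVG, %d bytes>\n", nchar(x$content, type = "bytes")))
  invisible(x)
}

#' Extract anchor ids from a rendered diagram
#'
#' Returns the decoded anchor ids of one element kind in document order;
#' with `kind = "met"` this is the diagram's metabolite sequence, which
#' always equals the session's path order.
#'
#' @param diagram An `mn_diagram`.
#' @param kind `"met"`, `"rxn"` or `"cand"`.
#' @return Character vector of ids in order of appearance.
#' @export
diagram_anchors <- function(diagram, kind = c("met", "rxn", "cand")) {
  stopifnot(inherits(diagram, "mn_diagram"))
  kind <- match.arg(kind)
  if (diagram$format == "TEXT") {
    m <- gregexpr(sprintf("\\[@%s:([^]]+)\\]", kind), diagram$content)
    hits <- regmatches(diagram$content, m)[[1]]
    ids <- sub(sprintf("^\\[@%s:", kind), "", hits)
    ids <- sub("\\]$", "", ids)
  } else {
    doc <- xml2::read_xml(diagram$content)
    nodes <- xml2::xml_find_all(doc, sprintf("//*[starts-with(@data-anchor, '%s:')]", kind))
    ids <- sub(sprintf("^%s:", kind), "", xml2::xml_attr(nodes, "data-anchor"))
  }
  vapply(ids, dec_id, character(1), USE.NAMES = FALSE)
}

#' Detailed connection panel for a metabolite
#'
#' The data shown when a candidate metabolite is inspected before being
#' added to the path: the metabolite itself and, for every reaction it
#' participates in, the full equation, EC number, enzymes, genes and
#' pathways, verbatim from the network. Works for any metabolite,
#' including ubiquitous ones (currency omission applies to neighbor
#' lists, not direct queries).
#'
#' @param network An `mn_network`.
#' @param metabolite_id Metabolite to inspect.
#' @return An object of class `mn_panel`: `metabolite` (id, name, smiles,
#'   is_ubiquitous) and `connections`, one record per reaction with
#'   `reaction_id`, `equation`, `ec_number`, `enzymes`, `genes`,
#'   `pathways`, `direction`, `spontaneous`.
#' @export
candidate_panel <- function(network, metabolite_id) {
  stopifnot(inherits(network, "mn_network"))
  m <- get_metabolite(network, metabolite_id)
  conns <- list()
  for (rxn in network$reactions) {
    if (metabolite_id %in% c(names(rxn$left), names(rxn$right))) {
      conns[[length(conns) + 1L]] <- list(
        reaction_id = rxn$id,
        equation = rxn$equation,
        ec_number = rxn$ec_number,
        enzymes = rxn$enzymes,
        genes = rxn$genes,
        pathways = rxn$pathways,
        direction = rxn$direction,
        spontaneous = rxn$spontaneous
      )
    }
  }
  structure(list(metabolite = m, connections = conns), class = "mn_panel")
}

#' @export
print.mn_panel <- function(x, ...) {
  cat(sprintf("%s (%s)%s\n", x$metabolite$name, x$metabolite$id,
              if (x$metabolite$is_ubiquitous) " [ubiquitous]" else ""))
  if (!is.null(x$metabolite$smiles)) cat(sprintf("  structure: %s\n", x$metabolite$smiles))
  for (cn in x$connections) {
    cat(sprintf("  %s: %s\n", cn$reaction_id, cn$equation))
    if (!is.null(cn$ec_number)) cat(sprintf("    EC: %s\n", cn$ec_number))
    if (length(cn$enzymes)) cat(sprintf("    enzymes: %s\n", paste(cn$enzymes, collapse = ", ")))
    if (length(cn$genes)) cat(sprintf("    genes: %s\n", paste(cn$genes, collapse = ", ")))
    if (length(cn$pathways)) cat(sprintf("    pathways: %s\n", paste(cn$pathways, collapse = ", ")))
  }
  invisible(x)
}
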