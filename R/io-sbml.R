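# SBML Level 3 Version 1 core read/write, built on xml2.
#
# SBML core carries topology, names, stoichiometry and a reversibility
# boolean. Annotations the core cannot express (EC number, enzymes, genes,
# pathways, spontaneous flag, SMILES, the ubiquitous set, RIGHT_TO_LEFT /
# UNSPECIFIED directionality, custom equation text) are written as
# "KEY: value" paragraphs inside <notes> and restored best-effort by
# read_sbml(). A document without such notes loads with the plain SBML
# semantics: reversible="true" -> REVERSIBLE, "false" -> LEFT_TO_RIGHT.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
XHTML_NS <- "http://www.w3.org/1999/xhtml"

notes_lines <- function(kv) {
  kv <- kv[!vapply(kv, is.null, logical(1))]
  if (!length(kv)) return(NULL)
  paste0(names(kv), ": ", vapply(kv, as.character, character(1)))
}

parse_notes <- function(node) {
  ps <- xml2::xml_find_all(node, "./notes//p")
  out <- list()
  for (p in ps) {
    txt <- xml2::xml_text(p)
    m <- regmatches(txt, regexec("^([A-Z_]+): (.*)$", txt))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- m[3]
  }
  out
}

split_bar <- function(x) {
  if (is.null(x) || !nzchar(x)) character(0) else strsplit(x, " | ", fixed = TRUE)[[1]]
}

#' Read a network from SBML Level 3 core
#'
#' Species become metabolites and SBML reactions become reactions;
#' `reversible="true"` maps to direction `REVERSIBLE` and
#' `reversible="false"` to `LEFT_TO_RIGHT`, unless a notes paragraph
#' written by [write_sbml()] records a more specific original direction.
#' Boundary/exchange species are retained as ordinary metabolites.
#' Annotations carried in notes (EC, enzymes, genes, pathways,
#' spontaneous, SMILES, ubiquitous flags) are restored when present.
#'
#' @param path Path to an SBML file.
#' @return An `mn_network`.
#' @export
read_sbml <- function(path) {
  if (is.character(path) && !file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(sprintf("SBML parse failure: %s", conditionMessage(e)), call. = FALSE))
  doc <- xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, "//model")
  if (is.na(xml2::xml_name(model))) stop("SBML document has no <model>", call. = FALSE)
  net_id <- xml2::xml_attr(model, "id")
  if (is.na(net_id) || !nzchar(net_id)) net_id <- "sbml-model"

  species <- xml2::xml_find_all(model, "./listOfSpecies/species")
  if (length(species) == 0L) stop("SBML model contains zero species", call. = FALSE)

  mets <- lapply(species, function(s) {
    notes <- parse_notes(s)
    nm <- xml2::xml_attr(s, "name")
    metabolite(
      xml2::xml_attr(s, "id"),
      name = if (is.na(nm)) NULL else nm,
      smiles = notes[["SMILES"]],
      is_ubiquitous = identical(notes[["UBIQUITOUS"]], "true")
    )
  })

  read_side <- function(rnode, which) {
    refs <- xml2::xml_find_all(rnode, sprintf("./%s/speciesReference", which))
    if (!length(refs)) return(character(0))
    ids <- xml2::xml_attr(refs, "species")
    coefs <- suppressWarnings(as.numeric(xml2::xml_attr(refs, "stoichiometry")))
    coefs[is.na(coefs)] <- 1
    stats::setNames(coefs, ids)
  }

  rxns <- lapply(xml2::xml_find_all(model, "./listOfReactions/reaction"), function(rn) {
    notes <- parse_notes(rn)
    rev_attr <- identical(xml2::xml_attr(rn, "reversible"), "true")
    dir <- notes[["DIRECTION"]]
    if (is.null(dir) || !dir %in% DIRECTIONS) {
      dir <- if (rev_attr) "REVERSIBLE" else "LEFT_TO_RIGHT"
    }
    reaction(
      xml2::xml_attr(rn, "id"),
      left = read_side(rn, "listOfReactants"),
      right = read_side(rn, "listOfProducts"),
      direction = dir,
      equation = notes[["EQUATION"]],
      ec_number = notes[["EC"]],
      enzymes = split_bar(notes[["ENZYMES"]]),
      genes = split_bar(notes[["GENES"]]),
      pathways = split_bar(notes[["PATHWAYS"]]),
      spontaneous = identical(notes[["SPONTANEOUS"]], "true")
    )
  })

  metabolic_network(net_id, metabolites = mets, reactions = rxns)
}

add_notes <- function(node, kv) {
  lines <- notes_lines(kv)
  if (is.null(lines)) return(invisible(NULL))
  notes <- xml2::xml_add_child(node, "notes")
  body <- xml2::xml_add_child(notes, "body", xmlns = XHTML_NS)
  for (ln in lines) xml2::xml_add_child(body, "p", ln)
  invisible(NULL)
}

#' Write a network as SBML Level 3 core
#'
#' Emits an SBML L3V1 core document with one compartment. Direction maps
#' onto the `reversible` attribute (`REVERSIBLE` and `UNSPECIFIED` are
#' exported as `reversible="true"`, the rest as `"false"`); the exact
#' original direction and all annotations SBML core cannot express are
#' recorded in `<notes>` so that [read_sbml()] restores them.
#'
#' @param network An `mn_network`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_sbml <- function(network, path) {
  stopifnot(inherits(network, "mn_network"))
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = network$id)
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "c", constant = "true")

  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (m in network$metabolites) {
    s <- xml2::xml_add_child(los, "species", id = m$id, name = m$name,
                             compartment = "c", hasOnlySubstanceUnits = "false",
                             boundaryCondition = "false", constant = "false")
    add_notes(s, list(
      SMILES = m$smiles,
      UBIQUITOUS = if (m$is_ubiquitous) "true" else NULL
    ))
  }

  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (r in network$reactions) {
    reversible <- r$direction %in% c("REVERSIBLE", "UNSPECIFIED")
    rn <- xml2::xml_add_child(lor, "reaction", id = r$id,
                              reversible = if (reversible) "true" else "false",
                              fast = "false")
    add_notes(rn, list(
      DIRECTION = if (r$direction != if (reversible) "REVERSIBLE" else "LEFT_TO_RIGHT") r$direction else NULL,
      EQUATION = r$equation,
      EC = r$ec_number,
      ENZYMES = if (length(r$enzymes)) paste(r$enzymes, collapse = " | ") else NULL,
      GENES = if (length(r$genes)) paste(r$genes, collapse = " | ") else NULL,
      PATHWAYS = if (length(r$pathways)) paste(r$pathways, collapse = " | ") else NULL,
      SPONTANEOUS = if (r$spontaneous) "true" else NULL
    ))
    write_side <- function(side, tag) {
      if (!length(side)) return(invisible(NULL))
      lst <- xml2::xml_add_child(rn, tag)
      for (i in seq_along(side)) {
        xml2::xml_add_child(lst, "speciesReference",
                            species = names(side)[i],
                            stoichiometry = format(side[[i]], trim = TRUE),
                            constant = "true")
      }
    }
    write_side(r$left, "listOfReactants")
    write_side(r$right, "listOfProducts")
  }

  tryCatch(xml2::write_xml(doc, path),
           error = function(e) stop(sprintf("cannot write '%s': %s", path, conditionMessage(e)), call. = FALSE))
  invisible(path)
}
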