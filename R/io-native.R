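# Native annotated network format: versioned JSON, UTF-8, lossless.
# SBML core cannot carry EC/gene/pathway/spontaneous annotations, so this
# is the format of record; the machine-readable schema ships in
# inst/schemas/network-format-v1.json.

NATIVE_FORMAT <- "metnav-network"
NATIVE_VERSION <- 1L

#' Read a network from the native JSON format
#'
#' Parses and validates a network file written by [write_native()] (format
#' `metnav-network`, version 1). All annotations -- EC numbers, enzymes,
#' genes, pathways, spontaneous flags, SMILES, the ubiquitous set -- are
#' restored losslessly. Validation errors name the offending element.
#'
#' @param path Path to a JSON file, or a connection.
#' @return An `mn_network`.
#' @seealso [write_native()], [read_sbml()]
#' @export
read_native <- function(path) {
  if (is.character(path) && !file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop(sprintf("not valid JSON: %s", conditionMessage(e)), call. = FALSE)
  )
  parse_native(doc)
}

# Shared by read_native and the link-free JSON session loader.
parse_native <- function(doc) {
  if (!is.list(doc) || !identical(doc$format, NATIVE_FORMAT)) {
    stop(sprintf("not a %s document (missing or wrong 'format' field)", NATIVE_FORMAT), call. = FALSE)
  }
  if (is.null(doc$version) || doc$version != NATIVE_VERSION) {
    stop(sprintf("unsupported %s version: %s", NATIVE_FORMAT,
                 if (is.null(doc$version)) "<missing>" else doc$version), call. = FALSE)
  }
  if (!is.character(doc$id) && !is.null(doc$id)) doc$id <- as.character(doc$id)
  if (is.null(doc$id) || !nzchar(doc$id)) {
    stop("network document has no 'id'", call. = FALSE)
  }

  scalar_or_null <- function(x) if (is.null(x)) NULL else as.character(x)
  chr_vec <- function(x) as.character(unlist(x, use.names = FALSE))

  mets <- lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite entry with no 'id'", call. = FALSE)
    metabolite(as.character(m$id),
               name = scalar_or_null(m$name),
               smiles = scalar_or_null(m$smiles),
               is_ubiquitous = isTRUE(m$is_ubiquitous))
  })

  parse_side <- function(entries, rid, what) {
    if (length(entries) == 0L) return(character(0))
    ids <- vapply(entries, function(p) {
      if (is.null(p$metabolite)) {
        stop(sprintf("reaction '%s': %s participant with no 'metabolite' field", rid, what), call. = FALSE)
      }
      as.character(p$metabolite)
    }, character(1))
    coefs <- vapply(entries, function(p) {
      if (is.null(p$coefficient)) 1 else as.numeric(p$coefficient)
    }, numeric(1))
    stats::setNames(coefs, ids)
  }

  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("reaction entry with no 'id'", call. = FALSE)
    rid <- as.character(r$id)
    dir <- if (is.null(r$direction)) "LEFT_TO_RIGHT" else as.character(r$direction)
    if (!dir %in% DIRECTIONS) {
      stop(sprintf("reaction '%s': invalid direction '%s'", rid, dir), call. = FALSE)
    }
    reaction(rid,
             left = parse_side(r$left, rid, "left"),
             right = parse_side(r$right, rid, "right"),
             direction = dir,
             equation = scalar_or_null(r$equation),
             ec_number = scalar_or_null(r$ec_number),
             enzymes = chr_vec(r$enzymes),
             genes = chr_vec(r$genes),
             pathways = chr_vec(r$pathways),
             spontaneous = isTRUE(r$spontaneous))
  })

  metabolic_network(doc$id, metabolites = mets, reactions = rxns,
                    ubiquitous_ids = chr_vec(doc$ubiquitous))
}

#' Write a network to the native JSON format
#'
#' Serializes a network to a UTF-8 JSON document that [read_native()]
#' restores with structural equality ([network_equal()]). Every annotation
#' field survives the round trip, including non-ASCII display names.
#'
#' @param network An `mn_network`.
#' @param path Output file path or connection.
#' @return Invisibly, the path.
#' @export
write_native <- function(network, path) {
  stopifnot(inherits(network, "mn_network"))
  doc <- native_document(network)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  ok <- tryCatch({ writeLines(json, path, useBytes = TRUE); TRUE },
                 error = function(e) {
                   stop(sprintf("cannot write '%s': %s",
                                if (is.character(path)) path else "<connection>",
                                conditionMessage(e)), call. = FALSE)
                 })
  invisible(path)
}

native_document <- function(network) {
  side_list <- function(side) {
    lapply(seq_along(side), function(i) {
      list(metabolite = names(side)[i], coefficient = side[[i]])
    })
  }
  list(
    format = NATIVE_FORMAT,
    version = NATIVE_VERSION,
    id = network$id,
    ubiquitous = as.list(network$ubiquitous_ids),
    metabolites = lapply(unname(network$metabolites), function(m) {
      out <- list(id = m$id, name = m$name)
      if (!is.null(m$smiles)) out$smiles <- m$smiles
      if (m$is_ubiquitous) out$is_ubiquitous <- TRUE
      out
    }),
    reactions = lapply(unname(network$reactions), function(r) {
      out <- list(id = r$id,
                  left = side_list(r$left),
                  right = side_list(r$right),
                  direction = r$direction,
                  equation = r$equation)
      if (!is.null(r$ec_number)) out$ec_number <- r$ec_number
      if (length(r$enzymes)) out$enzymes <- as.list(r$enzymes)
      if (length(r$genes)) out$genes <- as.list(r$genes)
      if (length(r$pathways)) out$pathways <- as.list(r$pathways)
      if (r$spontaneous) out$spontaneous <- TRUE
      out
    })
  )
}

#' Serialize a network to a native-format JSON string
#'
#' Same document as [write_native()], returned as a single string. Useful
#' for piping and for byte-identity checks on seeded fixtures.
#'
#' @param network An `mn_network`.
#' @return A JSON string.
#' @export
network_to_json <- function(network) {
  stopifnot(inherits(network, "mn_network"))
  as.character(jsonlite::toJSON(native_document(network), auto_unbox = TRUE,
                                pretty = TRUE, digits = NA, null = "null"))
}
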