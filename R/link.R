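# Shareable link strings. Grammar (see LINKFORMAT.md):
#
#   v1;<network-id>;<met1>[,<rxn1>.<o1>,<met2>,...];<settings>
#
# Every id is percent-encoded (RFC 3986 unreserved characters pass
# through), so ';' and ',' are unambiguous separators. Each reaction
# token carries the selected orientation ('f'/'r') after its final dot,
# making encode/decode the identity on the full (path, selections,
# settings) triple. <settings> is five 0/1 flags plus a candidates-mode
# letter (A/E/N).

enc_id <- function(x) utils::URLencode(x, reserved = TRUE)
dec_id <- function(x) utils::URLdecode(x)

encode_settings <- function(s) {
  bit <- function(b) if (isTRUE(b)) "1" else "0"
  mode <- c(ALL_STEPS = "A", ENDS_ONLY = "E", NONE = "N")[[s$candidates_mode]]
  paste0(bit(s$show_side_metabolites), bit(s$show_enzymes_genes), bit(s$show_ec),
         bit(s$show_structures), bit(s$show_pathway_links), mode)
}

decode_settings <- function(txt) {
  if (!grepl("^[01]{5}[AEN]$", txt)) {
    stop(sprintf("malformed link: bad settings field '%s'", txt), call. = FALSE)
  }
  bits <- strsplit(txt, "")[[1]]
  mode <- c(A = "ALL_STEPS", E = "ENDS_ONLY", N = "NONE")[[bits[6]]]
  display_settings(
    show_side_metabolites = bits[1] == "1",
    show_enzymes_genes = bits[2] == "1",
    show_ec = bits[3] == "1",
    show_structures = bits[4] == "1",
    show_pathway_links = bits[5] == "1",
    candidates_mode = mode
  )
}

#' Encode a session as a shareable link string
#'
#' Produces a URL-safe, versioned string capturing the network id, the
#' ordered path metabolites, the selected reaction for each step with its
#' orientation, and the display settings. Deterministic: two sessions
#' with equal paths and settings yield equal strings.
#'
#' @param session An `mn_session`.
#' @return A single link string.
#' @seealso [decode_link()]; the grammar is documented in `LINKFORMAT.md`.
#' @export
encode_link <- function(session) {
  stopifnot(inherits(session, "mn_session"))
  steps <- session$current$steps
  tokens <- character(0)
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    tokens <- c(tokens, enc_id(st$metabolite_id))
    if (i < length(steps)) {
      tokens <- c(tokens, paste0(enc_id(st$successor_reaction), ".", st$orientation))
    }
  }
  paste("v1", enc_id(session$network$id),
        paste(tokens, collapse = ","), encode_settings(session$settings),
        sep = ";")
}

#' Decode a link string into a session
#'
#' Reconstructs the session a link was generated from. The link's network
#' id must match `network$id`, every metabolite and reaction must exist,
#' and the decoded path must validate; failures name the offending
#' element. The decoded session has an empty history.
#'
#' @param network The `mn_network` the link refers to.
#' @param link A string produced by [encode_link()].
#' @return An `mn_session`.
#' @export
decode_link <- function(network, link) {
  stopifnot(inherits(network, "mn_network"))
  if (!is.character(link) || length(link) != 1L) {
    stop("malformed link: not a single string", call. = FALSE)
  }
  parts <- strsplit(link, ";", fixed = TRUE)[[1]]
  if (length(parts) != 4L) {
    stop("malformed link: expected 4 ';'-separated fields", call. = FALSE)
  }
  if (!identical(parts[1], "v1")) {
    stop(sprintf("malformed link: unsupported version '%s'", parts[1]), call. = FALSE)
  }
  link_net <- dec_id(parts[2])
  if (!identical(link_net, network$id)) {
    stop(sprintf("link is for network '%s', not '%s'", link_net, network$id), call. = FALSE)
  }
  tokens <- strsplit(parts[3], ",", fixed = TRUE)[[1]]
  if (length(tokens) == 0L || length(tokens) %% 2L == 0L) {
    stop("malformed link: path field must alternate metabolite and reaction tokens", call. = FALSE)
  }
  steps <- list()
  for (i in seq_along(tokens)) {
    if (i %% 2L == 1L) {  # metabolite token
      mid <- dec_id(tokens[i])
      if (is.null(network$metabolites[[mid]])) {
        stop(sprintf("link references unknown metabolite '%s'", mid), call. = FALSE)
      }
      steps[[length(steps) + 1L]] <- path_step(mid)
    } else {              # reaction token rxn.orient
      m <- regmatches(tokens[i], regexec("^(.*)\\.([fr])$", tokens[i]))[[1]]
      if (length(m) != 3L) {
        stop(sprintf("malformed link: bad reaction token '%s'", tokens[i]), call. = FALSE)
      }
      rid <- dec_id(m[2])
      if (is.null(network$reactions[[rid]])) {
        stop(sprintf("link references unknown reaction '%s'", rid), call. = FALSE)
      }
      k <- length(steps)
      steps[[k]]$successor_reaction <- rid
      steps[[k]]$orientation <- m[3]
    }
  }
  path <- new_path(steps)
  v <- validate_path(network, path)
  if (length(v)) {
    stop(paste(c("link path is invalid under this network:", v), collapse = "\n  "),
         call. = FALSE)
  }
  new_session(network, path, list(), decode_settings(parts[4]))
}
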