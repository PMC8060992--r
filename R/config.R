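# Configuration: a flat TOML-style `key = value` file plus a plain-text
# ubiquitous-metabolite list. Precedence everywhere is CLI flag > config
# file > built-in default.

#' Read a flat TOML-style configuration file
#'
#' Supports the flat subset of TOML the CLI needs: `key = value` lines
#' with quoted strings, numbers and booleans, plus `#` comments and blank
#' lines. Tables/arrays are not supported and raise an error.
#'
#' @param path Path to the config file.
#' @return Named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  out <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L) {
      stop(sprintf("config line %d is not a flat 'key = value' entry: %s", i, lines[i]),
           call. = FALSE)
    }
    key <- m[2]
    raw <- trimws(m[3])
    val <- if (grepl('^".*"$', raw)) {
      gsub('^"|"$', "", raw)
    } else if (grepl("^'.*'$", raw)) {
      gsub("^'|'$", "", raw)
    } else if (raw %in% c("true", "false")) {
      raw == "true"
    } else if (grepl("^-?[0-9]+$", raw)) {
      as.integer(raw)
    } else if (grepl("^-?[0-9.eE+-]+$", raw) && !is.na(suppressWarnings(as.numeric(raw)))) {
      as.numeric(raw)
    } else {
      stop(sprintf("config line %d: unsupported value '%s'", i, raw), call. = FALSE)
    }
    out[[key]] <- val
  }
  out
}

#' Read a ubiquitous-metabolite list
#'
#' One metabolite id per line; blank lines and `#` comments are ignored.
#' Apply the result with [set_ubiquitous()].
#'
#' @param path Path to the list file.
#' @return Character vector of ids.
#' @export
read_ubiquitous_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("ubiquitous list not found: '%s'", path), call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

# flag > config > default
resolve_option <- function(flag, config, key, default) {
  if (!is.null(flag)) return(flag)
  if (!is.null(config[[key]])) return(config[[key]])
  default
}
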