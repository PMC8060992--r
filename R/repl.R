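# Script-replayable exploration REPL. The same command language works
# interactively (stdin) and from a script file, and the REPL is a thin
# shell over the session API: a replayed script yields a final session
# identical to the equivalent sequence of API calls.

repl_help <- function() {
  paste(
    "commands:",
    "  fwd <metabolite> [anchor] [reaction]   add a successor (default anchor: last step)",
    "  back <metabolite> [anchor] [reaction]  add a precursor (default anchor: first step)",
    "  select <step> <reaction>               choose the displayed reaction for a step",
    "  history                                list previous paths",
    "  restore <n>                            swap current path with history entry n",
    "  render [text|svg]                      draw the current path",
    "  link                                   print a shareable link string",
    "  set <flag> <value>                     flags: side/enzymes/ec/structures/pathways",
    "                                         (on|off), candidates (ALL_STEPS|ENDS_ONLY|NONE)",
    "  show                                   print the current session",
    "  help                                   this text",
    "  quit                                   leave the explorer",
    sep = "\n")
}

apply_setting <- function(settings, flag, value) {
  onoff <- function(v) {
    if (!v %in% c("on", "off")) stop(sprintf("expected on|off, got '%s'", v), call. = FALSE)
    v == "on"
  }
  s <- unclass(settings)
  switch(flag,
    side = { s$show_side_metabolites <- onoff(value) },
    enzymes = { s$show_enzymes_genes <- onoff(value) },
    ec = { s$show_ec <- onoff(value) },
    structures = { s$show_structures <- onoff(value) },
    pathways = { s$show_pathway_links <- onoff(value) },
    candidates = {
      if (!value %in% c("ALL_STEPS", "ENDS_ONLY", "NONE")) {
        stop(sprintf("expected ALL_STEPS|ENDS_ONLY|NONE, got '%s'", value), call. = FALSE)
      }
      s$candidates_mode <- value
    },
    stop(sprintf("unknown setting '%s'", flag), call. = FALSE)
  )
  do.call(display_settings, s)
}

#' Run the interactive exploration REPL
#'
#' Executes explorer commands (`fwd`, `back`, `select`, `history`,
#' `restore`, `render`, `link`, `set`, `show`, `help`, `quit`) against a
#' session. `input` may be a connection (e.g. `stdin()`), a file path, or
#' a character vector of command lines, so scripted replays and
#' interactive use share one code path. Command errors are reported and
#' the loop continues.
#'
#' @param network An `mn_network`.
#' @param start_id Starting metabolite id.
#' @param input Command source: connection, file path or character
#'   vector.
#' @param output Connection for command output (default `stdout()`).
#' @param settings Initial [display_settings()].
#' @return Invisibly, the final `mn_session`.
#' @export
explore_repl <- function(network, start_id, input = stdin(), output = stdout(),
                         settings = display_settings()) {
  session <- start_session(network, start_id, settings)
  lines <- if (is.character(input) && length(input) == 1L && file.exists(input)) {
    readLines(input, warn = FALSE)
  } else if (is.character(input)) {
    input
  } else {
    readLines(input, warn = FALSE)
  }
  out <- function(...) writeLines(sprintf(...), output)

  for (raw in lines) {
    ln <- trimws(raw)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    words <- strsplit(ln, "\\s+")[[1]]
    cmd <- words[1]
    args <- words[-1]
    if (cmd == "quit") break
    res <- tryCatch({
      switch(cmd,
        fwd = {
          anchor <- if (length(args) >= 2L) as.integer(args[2]) else length(session$current$steps)
          rid <- if (length(args) >= 3L) args[3] else NULL
          session <- add_metabolite(session, anchor, args[1], "successor", rid)
          out("path: %s", paste(path_metabolites(session$current), collapse = " -> "))
        },
        back = {
          anchor <- if (length(args) >= 2L) as.integer(args[2]) else 1L
          rid <- if (length(args) >= 3L) args[3] else NULL
          session <- add_metabolite(session, anchor, args[1], "precursor", rid)
          out("path: %s", paste(path_metabolites(session$current), collapse = " -> "))
        },
        select = {
          session <- select_reaction(session, as.integer(args[1]), args[2])
          out("step %s now shows reaction %s", args[1], args[2])
        },
        history = {
          if (!length(session$previous_paths)) out("(history empty)")
          for (i in seq_along(session$previous_paths)) {
            out("%d: %s", i,
                paste(path_metabolites(session$previous_paths[[i]]), collapse = " -> "))
          }
        },
        restore = {
          session <- restore_previous(session, as.integer(args[1]))
          out("path: %s", paste(path_metabolites(session$current), collapse = " -> "))
        },
        render = {
          fmt <- if (length(args) >= 1L) args[1] else "text"
          d <- render_diagram(session, session$settings, fmt)
          writeLines(d$content, output)
        },
        link = out("%s", encode_link(session)),
        set = {
          session$settings <- apply_setting(session$settings, args[1], args[2])
          out("settings updated")
        },
        show = {
          out("current: %s", paste(path_metabolites(session$current), collapse = " -> "))
          out("history: %d previous path(s)", length(session$previous_paths))
        },
        help = writeLines(repl_help(), output),
        stop(sprintf("unknown command '%s' (try 'help')", cmd), call. = FALSE)
      )
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) out("error: %s", res)
  }
  invisible(session)
}
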