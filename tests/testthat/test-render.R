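three_step_session <- function() {
  net <- toy_network()
  s <- start_session(net, "A")
  s <- add_metabolite(s, 1, "B", "successor")
  add_metabolite(s, 2, "C", "successor")
}

test_that("anchor sequence equals path order in both formats", {
  s <- three_step_session()
  for (fmt in c("text", "svg")) {
    d <- render_diagram(s, format = fmt)
    expect_identical(diagram_anchors(d, "met"), path_metabolites(s$current))
    expect_identical(diagram_anchors(d, "rxn"),
                     vapply(s$current$steps[1:2], `[[`, character(1), "successor_reaction"))
  }
  # single-metabolite session with no candidates: exactly one metabolite anchor
  s1 <- start_session(toy_network(), "Q")
  d1 <- render_diagram(s1, display_settings(candidates_mode = "NONE"), "text")
  expect_identical(diagram_anchors(d1, "met"), "Q")
  expect_length(diagram_anchors(d1, "cand"), 0L)
})

test_that("SVG output is well-formed XML for varied sessions", {
  s <- three_step_session()
  for (mode in c("ALL_STEPS", "ENDS_ONLY", "NONE")) {
    d <- render_diagram(s, display_settings(candidates_mode = mode,
                                            show_structures = TRUE), "svg")
    expect_silent(xml2::read_xml(d$content))
  }
  net <- generate_network(small_spec(3))
  sess <- start_session(net, names(net$metabolites)[1])
  expect_silent(xml2::read_xml(render_diagram(sess, format = "svg")$content))
})

test_that("annotations appear per settings and the reaction count is shown", {
  s <- three_step_session()
  txt <- render_diagram(s, format = "text")$content
  expect_match(txt, "EC: 1.1.1.1", fixed = TRUE)
  expect_match(txt, "EC: 2.2.2.2", fixed = TRUE)
  expect_match(txt, "enzymes: alanase", fixed = TRUE)
  expect_match(txt, "side: + H2O", fixed = TRUE)    # currency shown as side metabolite

  # B and D are linked by two reactions: the count must be rendered
  s2 <- add_metabolite(s, 2, "D", "successor")
  txt2 <- render_diagram(s2, format = "text")$content
  expect_match(txt2, "showing 1 of 2 reactions", fixed = TRUE)
  svg2 <- render_diagram(s2, format = "svg")$content
  expect_match(svg2, "showing 1 of 2 reactions", fixed = TRUE)
})

test_that("each settings flag changes only the elements it governs", {
  s <- three_step_session()
  base <- display_settings(show_structures = TRUE)
  base_lines <- strsplit(render_diagram(s, base, "text")$content, "\n")[[1]]
  flags <- list(
    show_ec = "EC:",
    show_enzymes_genes = "enzymes:",
    show_side_metabolites = "side:",
    show_pathway_links = "pathways:",
    show_structures = "structure:")
  for (flag in names(flags)) {
    args <- list(show_structures = TRUE)
    args[[flag]] <- FALSE
    off <- do.call(display_settings, args)
    off_lines <- strsplit(render_diagram(s, off, "text")$content, "\n")[[1]]
    removed <- setdiff(base_lines, off_lines)
    expect_gt(length(removed), 0)
    expect_true(all(grepl(flags[[flag]], removed, fixed = TRUE)),
                info = flag)
    expect_length(setdiff(off_lines, base_lines), 0L)
  }
})

test_that("candidate modes and truncation behave as documented", {
  s <- three_step_session()
  ends <- render_diagram(s, display_settings(candidates_mode = "ENDS_ONLY"), "text")$content
  all_steps <- render_diagram(s, display_settings(candidates_mode = "ALL_STEPS"), "text")$content
  none <- render_diagram(s, display_settings(candidates_mode = "NONE"), "text")$content
  expect_false(grepl("precursors:", none, fixed = TRUE))
  # ENDS_ONLY: candidates at A and C but not at intermediate B
  expect_lt(length(gregexpr("precursors:", ends, fixed = TRUE)[[1]]),
            length(gregexpr("precursors:", all_steps, fixed = TRUE)[[1]]))

  # truncation marker on a hub metabolite
  mets <- c(lapply(sprintf("S%02d", 1:15), metabolite), list(metabolite("hub")))
  rxns <- lapply(sprintf("S%02d", 1:15), function(m)
    reaction(paste0("R", m), m, "hub"))
  net <- metabolic_network("hubnet", mets, rxns)
  sess <- start_session(net, "hub")
  txt <- render_diagram(sess, display_settings(), "text", candidate_limit = 5)$content
  expect_match(txt, "(+10 more)", fixed = TRUE)
  expect_length(diagram_anchors(render_diagram(sess, display_settings(), "text",
                                               candidate_limit = 5), "cand"), 5L)
})

test_that("candidate panels report reaction data verbatim", {
  net <- toy_network()
  p <- candidate_panel(net, "A")
  expect_identical(p$metabolite$id, "A")
  r1 <- p$connections[[1]]
  expect_identical(r1$reaction_id, "R1")
  expect_identical(r1$equation, net$reactions$R1$equation)
  expect_identical(r1$ec_number, "1.1.1.1")
  expect_identical(r1$enzymes, "alanase")
  expect_identical(r1$genes, "alaA")
  expect_identical(r1$pathways, "PWY-1")

  # unannotated reaction: equation only, empty annotation slots
  p5 <- candidate_panel(net, "Q")
  conn <- p5$connections[[1]]
  expect_identical(conn$reaction_id, "R7")
  expect_null(conn$ec_number)
  expect_length(conn$enzymes, 0L)

  # ubiquitous metabolites can be queried directly
  pw <- candidate_panel(net, "water")
  expect_identical(vapply(pw$connections, `[[`, character(1), "reaction_id"), "R1")
  expect_error(candidate_panel(net, "nope"), "nope")
})
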