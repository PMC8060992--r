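# metnav — step-by-step exploration of metabolic networks

Metabolic networks are too dense to visualize whole: showing every
reaction produces a tangle, and tools that pre-select a subnetwork
(a curated pathway, a fixed-radius neighborhood) decide for you which
connections you get to see. `metnav` is for biologists and metabolic
engineers who want the opposite: start at any metabolite, see the
*complete* set of one-step continuations, and grow a single linear path
in either direction, one chosen reaction at a time.

## The method

For a metabolite *M* in a reaction network, define

* **precursors** P(M) = { P : some reaction has P on an effective
  reactant side and M on the corresponding product side },
* **successors** S(M) = { S : some reaction has M on an effective
  reactant side and S on the corresponding product side },

where the *effective sides* of a reaction follow its directionality —
irreversible reactions contribute one (reactant-side, product-side)
assignment, reversible or unspecified-direction reactions contribute
both, so such a neighbor appears in both lists. A configurable set of
**ubiquitous (currency) metabolites** — water, H⁺, phosphate and
friends — is omitted from neighbor lists (they would connect everything
to everything) but still shown as side metabolites of displayed
reactions. Each neighbor entry carries every linking reaction with its
equation, EC number, enzymes, genes and pathways, and is classed as
unidirectional, potentially bidirectional, spontaneous, or
multiply-linked for display coding.

On top of the neighborhoods sits a small state machine: a single linear
**path** of steps (metabolite + chosen successor reaction). Adding a
neighbor at an end extends the path; adding at an interior anchor
replaces the portion of the path on the attachment side, archiving the
old path in a restorable history. Paths serialize to URL-safe link
strings (`LINKFORMAT.md`) and render as vertical pathway diagrams in
text or SVG (`RENDERING.md`).

## A worked example

```r
library(metnav)

net <- metabolic_network("demo",
  metabolites = list(
    metabolite("akg", name = "2-oxoglutarate"),
    metabolite("glu", name = "L-glutamate"),
    metabolite("gln", name = "L-glutamine"),
    metabolite("ala", name = "L-alanine"),
    metabolite("pyr", name = "pyruvate"),
    metabolite("h2o", name = "H2O", is_ubiquitous = TRUE)),
  reactions = list(
    reaction("GDH",  c(akg = 1, h2o = 1), c(glu = 1), direction = "REVERSIBLE",
             ec_number = "1.4.1.2", enzymes = "glutamate dehydrogenase", genes = "gdhA"),
    reaction("GLNS", c(glu = 1), c(gln = 1), ec_number = "6.3.1.2",
             enzymes = "glutamine synthetase", genes = "glnA",
             pathways = "glutamine biosynthesis"),
    reaction("ALAT", c(glu = 1, pyr = 1), c(akg = 1, ala = 1), direction = "REVERSIBLE",
             ec_number = "2.6.1.2", enzymes = "alanine aminotransferase", genes = "alaC"),
    reaction("ALAT2", c(glu = 1, pyr = 1), c(akg = 1, ala = 1), direction = "REVERSIBLE",
             ec_number = "2.6.1.66", enzymes = "valine-pyruvate aminotransferase",
             genes = "avtA")))

s <- start_session(net, "akg")
s <- add_metabolite(s, 1, "glu", "successor", reaction_id = "GDH")
s <- add_metabolite(s, 2, "gln", "successor")
cat(render_diagram(s, display_settings(candidates_mode = "ENDS_ONLY"), "text")$content)
```

prints

```
Pathway diagram: demo (3 steps)
Legend: [U] unidirectional  [B] bidirectional  [S] spontaneous  [M] multiple reactions

[@met:akg] 2-oxoglutarate
    <- precursors: [@cand:glu] L-glutamate [M], [@cand:pyr] pyruvate [M]
    -> successors: [@cand:glu] L-glutamate [M], [@cand:pyr] pyruvate [M]
  | [@rxn:GDH] GDH [M] (showing 1 of 3 reactions)
  |   EC: 1.4.1.2
  |   enzymes: glutamate dehydrogenase; genes: gdhA
  |   side: + H2O => (none)
  v
[@met:glu] L-glutamate
  | [@rxn:GLNS] GLNS [U]
  |   EC: 6.3.1.2
  |   enzymes: glutamine synthetase; genes: glnA
  |   pathways: glutamine biosynthesis
  v
[@met:gln] L-glutamine
    <- precursors: [@cand:glu] L-glutamate [U]
    -> successors: (none)
```

Reading it: the path runs top to bottom (2-oxoglutarate → L-glutamate →
L-glutamine). The first step is linked by three reactions (GDH and the
two reversible aminotransferases), so the class code is `[M]` and the
count `showing 1 of 3 reactions` appears — `select_reaction()` switches
the displayed one. Water appears as a side metabolite of GDH even
though, being ubiquitous, it never shows up in a candidate list.
Candidate lists appear only at the path ends because the settings used
`ENDS_ONLY`. `encode_link(s)` serializes this display as

```
v1;demo;akg,GDH.f,glu,GLNS.f,gln;11101A
```

and `decode_link(net, ...)` reconstructs it exactly. A command-line
interface wrapping the same functions ships in `inst/cli/metnav.R`
(subcommands `neighbors`, `explore`, `render`, `convert`,
`gen-fixture`).

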