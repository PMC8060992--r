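# Diagram rendering

Both renderers draw the current path as a **vertical linear pathway
diagram**: path metabolites top-to-bottom in step order, one arrow per
linking reaction, candidate precursor/successor lists beside each step
according to the candidates mode.

## Connection-class legend

Every candidate and every path link is coded by the class of its
linking-reaction set:

Class          | Text code | SVG stroke/fill | Meaning
-------------- | --------- | --------------- | -------
UNIDIRECTIONAL | `[U]`     | `#555555`       | one irreversible reaction
BIDIRECTIONAL  | `[B]`     | `#1f77b4`       | one reversible / unspecified-direction reaction
SPONTANEOUS    | `[S]`     | `#2ca02c`       | one spontaneous (uncatalyzed) reaction
MULTIPLE       | `[M]`     | `#ff7f0e`       | more than one linking reaction

Precedence is MULTIPLE > SPONTANEOUS > BIDIRECTIONAL > UNIDIRECTIONAL:
multiplicity is a property of the whole reaction set, so it dominates.

## Anchors

Every rendered element carries a stable machine-readable anchor:

- text: `[@met:<id>]`, `[@rxn:<id>]`, `[@cand:<id>]` markers, ids
  percent-encoded;
- SVG: `data-anchor="met:<id>"` (etc.) attributes on the element.

`diagram_anchors(diagram, kind)` extracts and decodes them in document
order; the `met` anchor sequence always equals the session's path order,
in both formats.

## Display elements

Each optional element occupies its own line (text) or node (SVG) and is
governed by exactly one `display_settings()` flag: side metabolites
(currency metabolites *are* shown here), enzymes/genes, EC numbers,
SMILES structures, pathway names, and the candidate lists
(`ALL_STEPS`, `ENDS_ONLY`, `NONE`). When adjacent path metabolites are
linked by k > 1 reactions the step shows `showing 1 of k reactions`
next to the selected reaction. Candidate lists longer than the
configurable limit (default 10) end with an explicit `(+N more)`
marker. Layout metrics (spacing, fonts, arrowheads) are implementation
detail; only ordering and element presence are contractual.
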