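---
title: "Exploring metabolic networks one step at a time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exploring metabolic networks one step at a time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metnav)
```

## The problem

A genome-scale metabolic network contains thousands of reactions. Drawn
in full it is unreadable, and tools that pre-select a subnetwork (a
predefined pathway, a neighborhood of fixed radius) decide *for* the
user which connections matter. metnav takes the opposite stance: the
unit of display is a **single linear path** chosen interactively by the
user, and at every path metabolite the *complete* set of possible
one-step continuations is available as candidate lists. Nothing is
pre-selected; everything is reachable.

Two data structures carry the whole method:

* the **path**, an ordered list of steps, each a metabolite plus (for
  non-terminal steps) the reaction chosen to link it to the next step;
* the **neighborhood** of a metabolite $M$: every precursor $P$ (some
  reaction has $P$ on an effective reactant side and $M$ on the
  corresponding product side) and every successor $S$ (the symmetric
  notion), each neighbor carrying the full list of linking reactions
  with their EC numbers, enzymes, genes and pathways.

## Direction semantics

Each reaction has two participant sides and a directionality:
`LEFT_TO_RIGHT`, `RIGHT_TO_LEFT`, `REVERSIBLE` or `UNSPECIFIED`. The
*effective sides* of a reaction are the (reactant-side, product-side)
assignments compatible with its directionality — one assignment for the
irreversible values, both assignments for `REVERSIBLE` and
`UNSPECIFIED`. A consequence worth stating explicitly: when the only
link between $M$ and $N$ is a single reversible reaction, $N$ is *both*
a precursor and a successor of $M$, and appears in both lists.

SBML Level 3 core only carries a reversibility boolean, so SBML import
can produce only `REVERSIBLE` or `LEFT_TO_RIGHT`; the `RIGHT_TO_LEFT`
and `UNSPECIFIED` values can enter through the native JSON format (or
be restored from the notes our SBML writer emits). Keeping
`UNSPECIFIED` distinct from `REVERSIBLE` preserves the biological
distinction between "known to run both ways" and "direction not
curated", even though both traverse identically.

Stoichiometric coefficients are stored and round-tripped but play no
role in neighborhood computation: neighbor status is defined purely by
membership on a side. Flux-style semantics (bounds, objectives) are
deliberately out of scope.

## Currency metabolites

Water, protons, phosphate and the like participate in so many reactions
that including them in neighbor lists would connect everything to
everything. The network therefore carries a configurable
**ubiquitous set**; members are omitted from precursor/successor lists.
The omission is *only* there: a ubiquitous compound still renders as a
side metabolite of a displayed reaction, and can be queried directly
with `candidate_panel()`. We chose to show currency compounds in side
position because the displayed reaction equation would otherwise be
chemically wrong; this is an assumption the original display style
leaves open. The set defaults to whatever the network file declares and
can be overridden wholesale (`set_ubiquitous()`, or a one-id-per-line
file via the CLI).

Two smaller conventions: a reaction with $M$ on both effective sides
never makes $M$ its own neighbor (self-edges are display noise, and the
precursor/successor definitions name two distinct roles), and id
comparison is case-sensitive exact matching to avoid silent merges.

## The path state machine

`add_metabolite(session, anchor, neighbor, side)` implements one rule
with two regimes:

* **extension** — neighbor is a precursor of the *first* step or a
  successor of the *last* step: the path grows by one step, history is
  untouched;
* **replacement** — neighbor attaches anywhere else: the current path
  is first saved to the history, then the portion of the path on the
  side where the neighbor attaches is discarded (successor attachment
  discards everything after the anchor, precursor attachment everything
  before), and the new step is attached. This preserves the clicked
  connection and grows the path from the interior anchor.

Every replacement grows history by exactly one; restoring
(`restore_previous()`) *swaps* current and the chosen entry rather than
copying, so switching back and forth is an involution and memory stays
bounded. History is most-recent-first and is not deduplicated.

When several reactions link an adjacent pair, the default selection is
the lexicographically smallest reaction id — determinism matters more
than any particular choice — and `select_reaction()` changes the
displayed one without touching topology. A metabolite may appear more
than once in a path: forbidding repeats would silently block legal
biochemistry such as futile cycles.

All step and history indices in this API are 1-based, as R users
expect.

When a neighbor is connected to the anchor as both precursor and
successor (a reversible link), the caller must pass `side` explicitly;
the API never guesses the attachment direction.

## Link strings

`encode_link()` serializes (network id, ordered metabolites, selected
reactions, display settings) into a versioned, percent-encoded string
(grammar in `LINKFORMAT.md`). One detail is load-bearing: each reaction
token records the *orientation* in which the reaction is traversed.
Without it, a reversible reaction whose substrate also appears among
its products could decode into a different orientation than the one the
user selected, and `encode_link ∘ decode_link` would not be the
identity. `decode_link()` validates everything against the supplied
network and names the first offending element; a decoded path always
passes `validate_path()`.

## Rendering

Both renderers (text, SVG 1.1) draw the path vertically in step order
and code every connection by class — `MULTIPLE` (more than one linking
reaction), else `SPONTANEOUS`, else `BIDIRECTIONAL`
(reversible/unspecified), else `UNIDIRECTIONAL`. Multiplicity dominates
the precedence because it is the only property of the reaction *set*;
the other three describe the single linking reaction. Colors and letter
codes are documented in `RENDERING.md`; we deliberately use our own
documented legend rather than guessing another tool's palette.

Candidate lists are sorted by display name then id (the field shows
scrollable lists without stating an order; tests need determinism),
truncated at a configurable limit with an explicit `(+N more)` marker.
Every element carries a machine-readable anchor, which is what the
rendering tests assert against; exact layout metrics are not part of
the contract.

## The synthetic generator

`generate_network(fixture_spec(...))` produces every test input. The
defaults are the package's standard study condition: 200 metabolites,
500 reactions, up to 3 participants per side drawn uniformly without
replacement (sides disjoint), 30% reversible, 5% spontaneous, 5% of
metabolites ubiquitous, annotations synthesized from the seed. The 30%
reversibility and small spontaneous fraction are in the range curated
bacterial reconstructions typically show; the 5% currency fraction
matches the handful of inorganic hubs in a ~200-compound network. The
generator runs on a private, fully specified RNG (`set.seed` kind
pinned), so equal specs give byte-identical native serializations and
the caller's RNG stream is never disturbed.

What the generator does *not* emulate: the heavy-tailed degree
distribution of real metabolomes, compartments, mass balance, and
realistic chemistry in names/SMILES. Passing tests therefore establish
the correctness of the graph semantics, the state machine and the
serializations on arbitrary topologies — not biological plausibility of
any particular network.

## Verification strategy and problem sizes

The neighborhood implementation (one indexed pass over all reactions,
cached per network; the cache is semantics-free and tested as such) is
checked against an independent brute-force oracle that literally
re-derives the definitions by scanning every (reaction, effective side)
pair per metabolite. The test suite runs the oracle comparison on 100
networks at the standard 200×500 condition, exercises 10,000 random
operation sequences against `validate_path()`, 100 random
link round trips, and SBML/native file round trips; the whole suite
completes in about two minutes on one CPU.

## Known limitations

* SBML support covers Level 3 core topology plus notes-carried
  annotations; BioPAX, KGML and flat-file formats are out of scope, and
  compartmentalized species are distinct metabolites (merging is left
  to data preparation).
* No automatic path search: exploration is strictly user-driven, which
  is the point of the method.
* SVG depiction of chemical structures is limited to printing SMILES
  strings; drawing 2D structures would require a chemistry backend and
  is orthogonal to the method.
* Undo is limited to the previous-paths list; there is no redo stack
  beyond the swap semantics of restore.
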