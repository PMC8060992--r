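# Link string format (v1)

A link string captures everything needed to restore a displayed path:
the network it belongs to, the ordered metabolites, the selected
reaction and traversal orientation for every step, and the display
settings. It is plain ASCII, URL-safe, and deterministic: equal sessions
produce equal strings.

## Grammar

```
link      := "v1" ";" network ";" path ";" settings
network   := pct-id                        # percent-encoded network id
path      := met *( "," rxn "," met )      # alternating tokens, odd count
met       := pct-id                        # percent-encoded metabolite id
rxn       := pct-id "." orient             # percent-encoded reaction id
orient    := "f" | "r"                     # left side reacts | right side reacts
settings  := 5*5("0"|"1") mode             # flag bits + candidates mode
mode      := "A" | "E" | "N"               # ALL_STEPS | ENDS_ONLY | NONE
```

Percent-encoding is RFC 3986 with only unreserved characters
(`A-Z a-z 0-9 - _ . ~`) left literal, so `;`, `,` and `.` inside ids can
never collide with the separators (the orientation suffix is split off
at the *last* dot of the reaction token, and every encoded token is
decoded afterwards).

## Settings bits

Position | Flag
-------- | ----
1 | show_side_metabolites
2 | show_enzymes_genes
3 | show_ec
4 | show_structures
5 | show_pathway_links
6 | candidates mode letter (`A`/`E`/`N`)

## Example

```
v1;toynet;A,R1.f,B,R2.r,C;11101A
```

Network `toynet`, path A → B → C, linked by `R1` used left-to-right and
`R2` used right-to-left, default display settings.

## Decoding guarantees

`decode_link(network, link)` fails with a named cause when the link's
network id does not match, when a metabolite or reaction no longer
exists in the supplied network, or when the recorded reaction cannot
link its adjacent pair in the recorded orientation. A successfully
decoded session always carries a path for which `validate_path()`
returns no violations.
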