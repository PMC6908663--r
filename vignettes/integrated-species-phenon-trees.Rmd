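---
title: "Integrated species-phenon trees: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated species-phenon trees: model, algorithm, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotree)
```

## The two-tree model

`phenotree` works on paleontological datasets in which the same
organisms are described by two loosely coupled, time-calibrated
evolutionary trees:

* **Species lineages**: paleobiological species reconstructed by
  tracing morphological clusters along stratigraphic sequences
  (stratophenetics). Each is a time range from its first-appearance
  datum (FAD, the base, in Ma before present) to its last-appearance
  datum (LAD, the top); a descendant originates at a dated branch point
  on its ancestor's range and its base age equals that branch age.
* **Phena**: informal morphotaxa. A phenon's range is dated the same
  way, but its extent is governed by morphology, not by the species
  reconstruction — so a phenon may originate inside an ancestral
  species and persist into a descendant, crossing one or several
  speciation events.

Both trees are forests: multiple mutually unconnected trees, and
isolated ranges, are permitted and preserved. Ancestor-descendant
structure is a strict one-parent hierarchy (a unique rootward path;
cycles and second parents are validation errors).

The single datum that couples the trees is, per phenon, *the species in
which its range ends*. In the tab-delimited datapack dialect this rides
on the phenon's TOP row: column D is `TOP`, column G carries the flag
`phenon`, and column H names the species. Nothing else about
species-phenon membership is authored; it is all derived.

## The integration algorithm

For each phenon the algorithm starts at the TOP point, places it in its
terminal species, and walks the range rootward along the species'
ancestral chain. Whenever the remaining range extends past the current
species' origination age, the range is cut there: the covered part
stays in the current box and the remainder transfers to the parent box.
Cut ages are duplicated into both segments (closed intervals; the drawn
lines abut), and every attribute of the phenon — style intervals,
colour, pop-up text, label — is duplicated onto each part, with style
intervals re-cut at the break ages. Collecting all segments by host
species yields the one-to-many species-phenon relationship map, the
central data structure: it is what makes box widths computable at all,
since the number of breaks (and so of drawn slots) is not known
up-front.

Guide symbols annotate segment extremities so true range ends are never
confused with artificial breaks: a horizontal tick at the range origin,
a capped bar at an extinction, an arrowhead at age 0 for still-living
taxa, and paired open chevrons (upward in the older box, downward in
the younger) at each break. Symbol pairing is a package invariant:
exactly one origin and one non-broken top per phenon, and broken
tops/bases come in age-matched pairs.

Two boundary rules are worth stating precisely, both driven by the fact
that a zero-length segment is meaningless:

* **Origin tie.** If a phenon's base age equals a species' origination
  age — a common situation; in the case-study group roughly 40% of
  lineage origins coincide with a contained phenon — the origin stays
  in that species' box and no older segment is emitted.
* **Top tie.** If a phenon's TOP sits exactly at its terminal species'
  base age, the whole phenon in fact belongs to the ancestor; the data
  must then name the ancestor. This, like a TOP outside the species'
  range in either direction or a base predating the chain root, is an
  error rather than a silent clamp: the input encodes a contradiction
  the user should resolve.

Age comparisons throughout use an absolute tolerance of 1e-9 Ma.

Within one species box the break-up generally disconnects the phenon
tree: two segments are connected only where the phenon tree's branch
age falls inside the box's time extent and both endpoints are hosted
there; everything else roots its own subtree. Disconnected subtrees and
isolated ranges are ordered left to right by First Occurrence (oldest
base first) by default, with Last Occurrence and case-insensitive
Alphabetic order as alternatives; ties preserve authoring order, and
connected subtrees keep their internal structure.

Relationship ids are `species index - member index`, with species
indexed by a deterministic pre-order traversal of the species tree
(forest roots in First-Occurrence order) and members by the within-box
ordering. Ids are strictly sequential within a group; the exporter
never repeats an id.

## Layout

The chart is laid out in abstract canvas units (1 unit = 1 px at SVG
scale 1). Vertically, ages map linearly with the young end of the
plotted window at the top and age increasing downward at
`units_per_myr` (default 20) units per Myr; the default window runs
from 0 Ma back to the oldest base age rounded up to a whole Myr.

Horizontally, each species box's width comes from its phenon group: one
slot per segment, each slot `max(label width estimate, minimum slot
width, image width if thumbnails are shown)`, plus inter-slot gaps and
padding; a box with no phena gets a configured minimum width. Label
widths are estimated deterministically as characters x font size x 0.6
(configurable) — no font metrics, so layout is reproducible anywhere.

Subtree widths are computed recursively: a subtree's width is its own
box width plus each child subtree's width, separated by a fixed gap,
with the parent box placed leftmost and child subtrees to its right in
authored branch order (never permuted). The sum form is deliberate. An
ancestor here routinely survives past its branch points, so parent and
child boxes overlap in *time*; any layout that centres a parent over
its children would therefore collide with them, while the
parent-leftmost sum guarantees disjoint x-extents for all sibling
subtrees and collision-free boxes by construction — which the tests
assert exhaustively (O(n²) rectangle scan) on the worked example and on
randomized charts. Recomputing widths from final positions reproduces
the recursion's values (a fixpoint check in the test suite). Horizontal
branch connectors attach the parent box's right side to the child box's
centre at the child's origination age; as in large published charts of
this kind, a connector may pass across an intervening sibling subtree —
box rectangles never overlap, connectors are not constrained.

A phenon split across boxes gets an independently assigned slot in each
box; no cross-box x alignment is attempted.

## Rendering

The SVG document is standalone and deliberately audit-friendly: the
root records the age map (`data-units-per-myr`, window, top margin), so
any drawn y-coordinate can be inverted to an age; every box border and
segment line carries its style token and side as `data-*` attributes.
`svg_side_style_extents()` uses exactly this to measure, from the
emitted geometry, how far each style runs along a box side — the same
measurement the acceptance script reports.

Species boxes are rectangles filled with the colour inherited along
the species tree's branches (a branch colour applies to the child and
all its descendants until reassigned) at `box_alpha` opacity — default
0.25, chosen so black phenon lines and labels stay legible over any
fill. Borders are drawn as four separate per-side elements so each side
can carry the range's style runs: the vertical sides reproduce the
range's style intervals; the base and top edges take the style in force
at that end of the range.

Line styles map abundance tokens to stroke width and dash:
frequent = solid 2.0, common = solid 1.0, rare = dotted,
conjectured = dashed, sample-only = sparsely dotted (all configurable).
Species ranges default to "frequent" and phena to "common", so species
box borders are strictly thicker than phenon lines — the constructor
enforces the inequality. Unknown tokens fall back to "common" with a
warning. Guide symbols render in an accent colour (default red). The
glyph shapes (tick, bar, arrowhead, chevron pair) are this package's
conventions; any five-way distinguishable set would serve.

Pop-up text from the datapack is carried verbatim into SVG `<title>`
elements (no interactivity is attempted). Optional per-phenon thumbnail
images may be referenced from settings; missing files are skipped with
a note. A plain background with Ma gridlines is drawn by default;
user-supplied interval bands (age span, colour, label) can be layered
behind everything — chronostratigraphic stage colouring is left to the
user's band definitions.

Settings live in `chart_settings()` and can be loaded from a YAML file
(`read_settings()`); the `phenotree` command-line script exposes
validate/map/render/fixtures subcommands over the same functions.

## The fixture generators

`fig2_fixture()` rebuilds the canonical worked example. Its topology
and the Aa ages (13-5-0 Ma with the frequent/conjectured style change
at 5 Ma) are fixed by the example's description; the remaining ages are
package conventions chosen once to satisfy the drawn topology and the
documented relationship map (groups of 1, 2, 4, 3, 1 with phenon *b*
shared by Aa and Bb, *c* and *d* by Bb and Be, *f* by Bb and Bf).
Variant `"III"` adds a disconnected phenon tree (h-i) and an isolated
phenon (g) placed along the Bb-Be series, each within a single box.

`random_fixture()` draws species trees by recursive budding inside a
30-Myr window (ages on a 0.01 Myr grid, so near-ties exercise the
tolerance path without floating-point pathologies), then phena inside
the species. Defaults: 8 species, 20 phena, crossing probability 0.35
(the chance a phenon spans its species' origin), coincident-origin
probability 0.4 (mirroring the case-study figure above), living
fraction 0.25. Generated packs are valid by construction — every
module's precondition is satisfied — and the test suite runs 1000 of
them (5 species, 9 phena each, crossing 0.5) through the entire
pipeline, checking the splitter against an independent
interval-intersection oracle, interval conservation, symbol pairing,
collision-free boxes, write/parse round-trips, and inversion of
rendered y-extents to ages within 1e-6 Myr. Larger single runs (a
210-species / 339-phena synthetic chart, matching the scale of the
published foraminifer dataset) check that the pipeline holds up at
case-study size; these sizes keep the default test run comfortably
fast while covering depth, breadth and degenerate cases.

What the generator does *not* emulate: real datasets have strongly
non-uniform speciation and sampling through time, correlated range
lengths, curated colour/style schemes, and occasional inconsistencies
(the published case study's own compilation admitted a small percentage
of linkage errors). Passing the randomized suite therefore demonstrates
the algorithm's correctness on valid inputs and its error reporting on
invalid ones — not robustness to the editorial quirks of any particular
real datapack.

## Known limitations and open choices

* Phenon ranges can only transfer *rootward*; a phenon said to end in
  species `S` never reaches into `S`'s descendants. A phenon that
  should carry over into a budding descendant must be authored with
  that descendant as its terminal species.
* Branches between a species and a phenon are rejected; the two trees
  are coupled only through the TOP-row link.
* Duplicate range labels cannot be distinguished from multi-point
  ranges in the dialect; the enforced signal is that a label with more
  than one TOP (or phenon-link) row is an error.
* Label widths are estimates; long labels in exotic fonts may overflow
  their slots visually, though never into a neighbouring box.
* No width minimization or balancing is attempted beyond the
  deterministic recursion; sibling order is authoring order.
* SVG is the only output format (no rasterization), and interactivity
  is limited to standard `<title>` hover text.
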