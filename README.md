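# phenotree

Integrated species–phenon trees against geologic time.

## The problem

Paleontological datasets for groups with rich fossil records (the model
case is Cenozoic macroperforate planktonic foraminifera) often carry
**two** time-calibrated evolutionary trees for the same organisms:

* a tree of **species lineages** — paleobiological species reconstructed
  stratophenetically, each spanning a first-appearance datum (FAD, its
  base age) to a last-appearance datum (LAD, its top age) in Ma; and
* a tree of **phena** — informal morphotaxa whose ranges may start
  inside a species lineage, end inside another, and pass unbroken from
  an ancestral species into one of its descendants.

Because the two trees deliberately differ in both membership and
timing, reading which species contains which parts of the phenon tree
from side-by-side figures is a visual brain teaser. `phenotree` merges
them algorithmically: every species range is widened into a translucent
**species box**, every phenon range is **broken at the origination ages
of the species that contain it** and the parts transferred rootward
along the chain of ancestral species boxes, and the result is drawn as
a standalone, time-calibrated SVG chart. Guide symbols at segment
extremities distinguish true range origins/extinctions (and
still-living tops) from the artificial breaks where a phenon transfers
between boxes.

The only linking datum required is, for each phenon, *the species in
which its range ends*: the TOP row of a phenon range carries a
`phenon` flag (spreadsheet column G) and that species name (column H).
Everything else — the species–phenon relationship map, the break-up,
box widths, colours inherited along branches, per-interval line styles
— is derived.

## The algorithm in brief

For a phenon with range `[top, base]` (ages in Ma, larger = older)
ending in terminal species `S0` with ancestral chain
`S0, S1, …, Sk` (base ages `b0 < b1 < … < bk`):

* walk rootward from `S0`; whenever the remaining range extends past
  the current species' origination (`base > b_i`), cut at `b_i`,
  keep `[cut_prev, b_i]` in `S_i`, and transfer the rest to `S_{i+1}`;
* the number of segments is 1 + the number of chain origination ages
  strictly inside the open phenon interval; a phenon whose base
  coincides exactly with a speciation age keeps its origin in that
  species' box;
* grouping all segments by host species gives the one-to-many
  **species–phenon relationship map**, which in turn fixes every box's
  width (one slot per phenon segment) and hence the recursive layout of
  the whole chart.

## Worked example

The bundled example (`fig2_fixture("I")`) has five species
(ancestor 18–13 Ma → Aa 13–0 → Bb 10–2 → {Be 6–0, Bf 4–1}) and seven
phena linked to them:

```r
library(phenotree)
pack <- fig2_fixture("I")
res  <- integrate_trees(pack)
res$map
#> <relationship_map> 5 species, 11 phenon segments (first ordering)
#>   1 ancestor     [1] phenon
#>   2 Aa           [2] a, b
#>   3 Bb           [4] b, c, d, f
#>   4 Be           [3] c, d, e
#>   5 Bf           [1] f
```

Phenon *b* (12–8 Ma) ends in *Bb*, but *Bb* only originates at 10 Ma,
so *b* appears in two boxes: segment 12–10 in *Aa* (carrying the range
origin and a broken-top chevron) and 10–8 in *Bb* (broken-base chevron
and the extinction bar). Species *Be* ends up holding two disconnected
phenon subtrees — the singleton `{c}` and the subtree rooted at `d` —
because the breaks disrupt the phenon tree's own connections:

```r
subtrees <- subtrees_in_box(res$map, res$phenon_tree, "Be")
lapply(subtrees, function(s) vapply(s, `[[`, "", "phenon"))
#> [[1]]
#> [1] "c"
#> [[2]]
#> [1] "d" "e"
```

Render the chart (species boxes filled with their inherited colour at
25% opacity; box borders carry the range's line styles, e.g. *Aa* is
"frequent" for 8 Myr up its sides from the base and "conjectured" for
5 Myr down from the top):

```r
svg <- phenon_chart(pack)
writeLines(svg, "chart.svg")
```

Or from a shell, via the installed `exec/phenotree` script:

```sh
phenotree validate example.txt
phenotree map example.txt -o map.tsv
phenotree render example.txt -o chart.svg --mode integrated --order first
```

`map.tsv` mirrors the one-to-many relationship map:

```
relationship_id  species   group_size  phenon  relation
1-1              ancestor  1           phenon  ancestor ← phenon
2-1              Aa        2           a       Aa ← a
2-2              Aa        2           b       Aa ← b
3-1              Bb        4           b       Bb ← b
...
```

Randomized but always-valid datapacks for testing come from
`random_fixture(fixture_spec(seed = 1, n_species = 20, n_phena = 60))`.

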