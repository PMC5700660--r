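---
title: "Comparing gene neighborhoods across prokaryotic genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing gene neighborhoods across prokaryotic genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogview)
```

## The problem

Conserved gene order is one of the strongest desk-scale signals of
functional interaction in bacteria and archaea: co-transcribed genes stay
adjacent, and an operon that survives across distant lineages almost
always encodes a functional unit.  `cogview` makes that signal visible for
one protein family at a time.  It takes annotated genomes plus profile-HMM
hit tables, selects every gene of a queried COG or Pfam domain, and draws
the gene neighborhoods of all of them under each other, with co-occurring
families colored consistently.

This vignette explains the model behind each stage, the tunable parameters
with their defaults, the numerical choices, what the synthetic-data
generator does and does not emulate, and the known limitations.

## Hit filtering

A *hit* is one region of one protein matching a profile HMM, with
alignment coordinates, a bit score and an E-value.  Two significance
filters run first:

* **minimum score** — hits under 25.0 bits are ignored (`min_score`,
  bits);
* **minimum relative length** — hits shorter than 25 % of the profile HMM
  length are ignored (`min_len_frac`, fraction of model columns).

Both comparisons are strict on the reject side: a hit at exactly 25.0
bits, or covering exactly 25 % of its model, is retained.  The boundary
behavior is deliberate — the filters are phrased as "less than", so
equality passes — and is pinned by tests on a grid of scores and lengths
either side of both boundaries.

## Overlap resolution

Proteins often collect several significant hits on the same stretch of
sequence.  To reduce them to a consistent annotation — COG membership(s)
and an ordered Pfam domain architecture — overlapping hits are resolved by
a cascade:

1. a lower-scored hit overlapped by a higher-scored hit over more than
   50 % of **its own** length is dropped;
2. at equal score, the hit with the greater length *normalized on its
   model length* is preferred;
3. at equal score and normalized length, the longer hit is preferred.

Three readings of "overlapped for more than 50 %" are possible (fraction
of the lower-scored hit, of the shorter hit, or of the union); this
package measures against the lower-scored hit, whose removal the rule
describes.  The implementation is a greedy pass in priority order (score,
normalized length, raw length, then model accession and input position to
make the order total): each candidate is compared **only against
already-accepted hits**, so a hit that was itself rejected can never veto
a later one.  Normalized lengths are compared with a 1e-9 tolerance;
everything else is exact integer or IEEE arithmetic.

One consequence worth knowing: the output can still contain a
higher-scored *short* hit nested inside a lower-scored *long* hit (the
long hit survives because under half of *its* length is covered).  The
50 % guarantee applies to the lower-scored member of each surviving pair,
not to the shorter one.

COG hits and Pfam hits are resolved independently — the two annotation
systems describe different things (orthology vs. domain content), and a
strong COG hit should not erase the domain architecture.  Multi-COG
membership with non-overlapping hits is kept as is.

The test suite checks the greedy resolver against an independent
brute-force oracle (a memoized recursive evaluation of the same pairwise
rules) on 1,000 random instances of up to 8 heavily overlapping hits, and
checks permutation invariance of the result.

## Neighborhood extraction and orientation

A neighborhood is a window of `k` genes (default 9, accepted range 3–15,
target included) in gene-order index space.  `floor((k-1)/2)` genes sit on
the *rendered* left of the target and the rest on the rendered right: for
even `k` the extra gene falls downstream of the target's coding direction.
Defining the split in rendered (strand-relative) rather than genomic terms
makes extraction an exact involution — reverse-complementing every
replicon and re-extracting yields byte-identical figure rows for every
`k`, odd or even — which a genomic-side split would break for even `k`.

Windows truncate at the ends of linear replicons and wrap across the
origin of circular ones.  When the target lies on the reverse strand the
whole window is mirrored (`flipped = TRUE`), so the target arrow always
points right and flank arrows show their strand relative to the target.

Coordinates are 1-based inclusive throughout, the GenBank convention,
which GFF3 shares; origin-spanning genes of circular replicons are stored
with `start > end` and length `(L - start + 1) + end`.  Features without a
protein id are kept in the window as uncolored arrows as long as they
carry a product description.  The first two entries of the source taxonomy
lineage serve as the high-level taxonomy units shown next to each row.

## The occurrence statistic

For model *m*, `occ(m) = 100 · n_present / n_total`, where `n_present`
counts neighborhoods containing at least one gene annotated with *m* and
`n_total` is the number of neighborhoods.  Counting *presence* rather than
raw gene copies is what makes the 1–100 % threshold scale meaningful; a
tandem array inside one window still counts once.  The target gene itself
is included, so the query model always shows 100 % and is always colored.
Multi-COG proteins contribute presence to each of their COGs.

Models at or above the threshold get distinct colors from a fixed
20-color qualitative palette, assigned in order of decreasing percentage
(ties by accession) so the assignment is deterministic; the
`palette_seed` rotates the palette start.  If more models are colored than
the palette holds, the palette cycles with progressive darkening.  All
Pfam domains of one Pfam clan share the color of the first clan member
seen.  Below-threshold models are neutral gray.  A practical workflow is
to start at the minimal 1 % threshold and raise it until the picture is
readable.

## Row ordering

Two orderings are built in.  **Taxonomy** sorts rows lexicographically by
(lineage, organism, replicon, target coordinate), so paralogs of one
organism sit under each other.  **MSA** aligns the target protein
sequences and adopts the engine's output order; alignment engines emit
sequences grouped by their guide tree, which places similar targets on
adjacent rows.  The engine sits behind a one-function contract (named
sequences in, aligned named sequences out, engine order), so tests inject
a deterministic fake; the bundled default wraps `mafft` with two
refinement iterations and `--reorder` (without which that engine would
just preserve input order).  An engine failure falls back to input order
with a warning rather than an error.

## Rendering

Each neighborhood is one row: genes are arrows, intergenic regions are
lines, and both lengths are proportional to their nucleotide lengths at
`scale` pixels per kilobase (default 40).  Rows are aligned on the
target's left edge.  Arrow geometry (14 px body height, 8 px head, 30 px
row pitch) is configurable but fixed by default; coordinates are printed
with two decimals, so repeated renders are byte-identical and the
proportionality error is bounded by rounding (well under 1 px, verified
by parsing the polygons back out of the SVG).  Intergenic gaps longer
than `max_gap_nt` (default 5,000 nt) are clipped and marked with a `//`
break glyph so one rare huge gap cannot flatten the figure.  The legend
below the figure lists every colored accession with its description.  SVG
is the primary, testable output; PDF export draws the same geometry on a
PDF device.

A gene showing several colored models is filled with the highest-ranked
one (by occurrence, then accession) — the full model list for every gene
is in the JSON sidecar, which records, per rendered gene, the description,
coordinates, taxonomy, the accepted COG and Pfam hits verbatim
(coordinates, scores, E-values), and the protein and gene sequences; per
intergenic region it records coordinates, taxonomy, the gap sequence and
its reverse complement.  External database cross-references are
pass-through fields populated only when supplied with the input; no
remote lookup is performed.

## The synthetic-data generator

`make_dataset()` emulates the full input side: GenBank replicons (linear
and circular, roughly half each), whitespace-delimited per-domain hit
tables in the standard 22-column layout, a clan table and a YAML truth
record.  Default conditions: 10 genomes, 12 genes each, gene lengths
uniform over 300–2,400 nt (whole codons), gaps uniform over 0–300 nt, a
two-gene operon (`COG1009` target + `COG3002` companion) planted
contiguously in 4 genomes at a random locus on a random strand, the
target gene alone in the rest.  Reverse-strand planting mirrors the
member order, so the rendered operon layout is conserved — planting
strand is invisible in the normalized figure, which is exactly the
involution property the tests exploit.  Decoy hits — 24.9-bit hits, hits
covering 24 % of their model, lower-scored hits nested inside real ones —
exercise every rejection path end to end.

Because companions exist only inside planted operons and background genes
receive only decoy hits, the true occurrence of each companion is exactly
`100 · k_planted / (n_genomes · paralogs)`, which the pipeline must
recover exactly; the acceptance tests sweep `n ∈ {5, 10, 20}` with every
`k_planted` from 1 to `n` and check threshold selection at the exact
boundary.  Protein sequences are uniform random amino-acid strings:
sufficient for the statistic and for the aligner *contract*, but
carrying no phylogenetic signal — so passing tests say nothing about how
informative MSA ordering is on real families, nor about HMM search
sensitivity, annotation quality of real genomes, or horizontal transfer.
That is the main gap between the fixture world and real data.

Test problem sizes (a few dozen genomes, ≤ 15 genes each, ≤ 8-hit
resolution instances, 1,000-instance oracle sweeps) were chosen so the
whole suite runs in well under a minute while still covering every code
path; all randomness is seeded.

## Degenerate inputs and edge cases

* Empty hit tables parse to empty hit sets; a protein with no accepted
  hit is `unannotated` but still drawn (uncolored) in windows.
* An unknown query accession yields an empty target list with a warning,
  not an error; a query matching nothing at the pipeline level is an
  error, since there is nothing to draw.
* `k` outside 3–15 and thresholds outside 1–100 % are rejected.
* Overlapping genes produce an empty intergenic region (flagged, no
  sequence); abutting genes likewise.
* A `k` larger than the replicon's gene count truncates (linear) or
  returns each gene once (circular).

## Known limitations

* No statistical significance is attached to an occurrence percentage; a
  Monte-Carlo null over genome rearrangements would be the natural
  extension.
* Neighborhoods are not clustered or deduplicated across closely related
  genomes, by design — every paralog is shown.
* The GenBank reader covers the coordinate, strand, topology, taxonomy
  and qualifier subset this pipeline needs (including origin-spanning
  joins), not the full flat-file grammar; eukaryotic multi-exon features
  are out of scope.
* MSA row order depends on the chosen alignment engine's guide tree and
  is only deterministic for a fixed engine version.
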