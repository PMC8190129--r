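---
title: "Template-based RNA 2D layouts: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based RNA 2D layouts: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rna2d)
```

## The model

`rna2d` treats RNA 2D visualisation as a *transfer* problem, not a drawing
problem. A template fixes three things for an RNA family: a reference
sequence, a nested secondary structure, and a coordinate for every
nucleotide. Given a query that belongs to the family, the package does not
re-draw the structure; it maps the query onto the template and moves as
little as possible. The underlying assumptions are:

* the query's structured core is homologous to the template, so sequence
  alignment is a usable proxy for structural correspondence;
* pairing is dominated by nested Watson-Crick/GU pairs (pseudoknots are
  carried as annotations in higher bracket layers and drawn as dashed lines,
  never entering the layout tree — this keeps the layout planar);
* each position pairs at most once across all layers (templates contain only
  canonical pairs; base triples are out of scope);
* deviations from the template (insertions, deletions, substitutions) are
  local, so conservative local repairs — loop redistribution, hairpin
  rotation — suffice. Queries violating this (e.g. half the sequence
  unrelated) should be rejected, not force-fitted.

The pipeline is: local-alignment template selection → global alignment →
base-pair transfer → coordinate inheritance → insertion placement → overlap
resolution → SVG/dot-bracket/TSV output. Every stage is deterministic:
identical inputs yield byte-identical outputs.

## Alignment scoring and the acceptance line

Alignments use match $+2$, mismatch $-1$, affine gaps costing
$5 + (L-1)\cdot 1$ for a gap of length $L$ (identical characters count as a
match even for ambiguity codes; differing ones as mismatch). Global
alignments resolve ties deterministically — diagonal over deletion over
insertion — which places insertion gaps leftmost within runs of equal bases.

Template **acceptance** needs care. The scheme above is a stand-in for
profile-based bit scores, which are log-odds against a null model: for them,
a fixed cutoff (20) is meaningful at any length. A raw Smith–Waterman score
is not: under this scoring the optimal local alignment of two *unrelated*
random RNA sequences grows linearly, at a measured ≈ 0.23 per nucleotide of
the shorter sequence (means 15.6/25.3/40.8/64.1/97.7 at shorter-length
40/80/150/250/400 over 60 replicates each). A fixed raw threshold of 20
would therefore accept almost any query of realistic length. The package
keeps the raw score as the reported quantity but accepts a hit only when it
clears the **length-corrected acceptance line**

$$ S \ge 20 + \rho \cdot \min(|q|, |r|), \qquad \rho = 0.4 . $$

$\rho$ is fixed at 0.4 because it sits midway between the measured null rate
(≈ 0.23/nt) and the score rate of even weakly homologous sequences
(≈ 1/nt at 30% divergence; ≈ 1.7/nt at the 5%/2%/2% mutation load used in
the tests), giving a wide margin on both sides. Consequences: random queries
are rejected regardless of length, and self-queries are accepted for any
template longer than ~13 nt ($2n \ge 20 + 0.4n$).

Multiple-hit rejection re-uses the line: a query is refused when two
*disjoint* local hits each clear it and are separated by more than 50
unaligned query nucleotides. Because raw local alignments profit from
absorbing unrelated flanks (at ≈ the null rate), each hit is first trimmed
to its *null-corrected core* — the best contiguous stretch after charging
$\rho$ per consumed query nucleotide — before masking and before measuring
the separation.

## Layout parameters

| parameter | default | units | role |
|---|---|---|---|
| `d_min` | 0.7 × median backbone spacing | layout units | two non-adjacent, non-paired nucleotides closer than this overlap |
| `max_passes` | 5 | – | sweeps of the hairpin-rotation search |
| rotation grid | 30° | degrees | the twelve tested rigid rotations per hairpin |
| `eps_repos` | 1e-6 | layout units | displacement beyond which a nucleotide counts as repositioned |
| tail spacing | median backbone spacing | layout units | step used when extending 5'/3' tails |

The overlap metric is nucleotide-centre proximity, not glyph-polygon
intersection: it is cheap, monotone under rigid motion, and independent of
font choices. The rotation pivot is the midpoint of the hairpin's
closing-pair coordinates, so the hairpin stays attached to its stem.
Rotations are accepted only when they strictly reduce the global overlap
count (ties between equally good angles prefer the smaller rotation
magnitude, then the smaller angle), which makes the count non-increasing and
the search convergent. Deletions cause **no compaction**: surviving
nucleotides keep their exact template coordinates, because template fidelity
dominates real outputs and aggressive re-spacing would defeat the purpose of
template-based layout. Only hairpin segments are rotated; multibranch arms
are never moved (a possible extension, deliberately out of scope).

Insertion placement distinguishes three contexts. Inside a loop, the maximal
run of consecutive unpaired query positions containing the insertion is
redistributed uniformly by angle on a circle fitted to the loop's placed
coordinates (centre = centroid, radius = mean centre distance) between the
two placed anchors flanking the run, which never move; the sweep direction
follows the already-placed run members, or, failing that, the arc free of
other loop members. A hairpin loop has exactly one such run, so an insertion
there redistributes the whole loop; in internal and multibranch loops only
the run containing the insertion moves (conservative movement again — runs
without insertions have no reason to leave their template coordinates). In
the exterior (root) loop the run is spaced evenly on the chord between its
anchors, and 5'/3' tails extend the terminal backbone segment at the
template's median backbone spacing. Degenerate cases fall back to linear
interpolation (circle radius ≈ 0) or midpoint placement.

Colour coding: black = base identical to the template, green = changed base,
magenta = insertion, blue = automatically repositioned. When a changed base
was also repositioned, green wins: base identity is the rarer, more
informative signal, and the precedence (insertion > changed > repositioned >
match) is configurable in `render_options()`. Classification summaries use
*positional* categories: an unmoved nucleotide is "positioned exactly as in
the template" even when its base changed — the identity channel belongs to
the colours, not to the position statistics. Percentages are rounded to one
decimal, ties away from zero, matching published tables (note that
pre-aggregated published rows may carry a displayed-nucleotide total larger
than the three class counts; `summarize_classification()` honours an
explicit total on such input).

## The synthetic generator

`generate_random_structure()` expands a stochastic grammar (open a pair with
probability `pair_prob = 0.8` when at least five positions remain, span
chosen uniformly) that guarantees hairpin loops of ≥ 3 nt; at the default it
yields ≈ 45% paired nucleotides (calibrated mean 0.4502, sd 0.0308 at
n = 100), typical of structured RNAs. `random_sequence()` fills pairs with
Watson-Crick duos (10% GU wobble), so generated templates validate with zero
warnings. `radial_layout()` renders helices as parallel strands (backbone
spacing 10, strand separation 8 — hence the default `d_min` of 7) and loops
as circles sized to their member count. Loops are assembled bottom-up with
bounding-disc wedge allocation: each stem subtree is summarised by a disc,
and a loop's circle grows until every child disc owns a non-overlapping
angular wedge (8 units of slack), the spare angle going to the gaps flanking
stems so leaf runs keep spacing ≈ 10. This makes synthetic layouts
collision-free by construction (verified: zero overlaps at `d_min = 7` over
150 seeds at each of 30/60/120/300 nt), which in turn guarantees that
redrawing a template's own reference reproduces its coordinates bit-exactly
— the whole pipeline is then a no-op.

`mutate_target()` applies i.i.d. substitutions and deletions and
geometric-length insertions (mean 1.5 — small, since large insertions are
poorly accommodated by any template layout) after positions, and records a
per-position truth table. When an inserted base equals a neighbouring base,
several mutation histories emit the same query; the truth table reports the
canonical representative, with insertion runs shifted leftmost across equal
bases and across substituted positions — the same convention as the
aligner's deterministic traceback. Even so, label recovery against an
optimal global alignment is bounded below 100%: the affine scoring merges
two nearby indels into one gap plus mismatches whenever that is cheaper than
two gap opens, i.e. the generated history is not always the most
parsimonious explanation of its own output. At 5% substitutions, 2%
insertions, 2% deletions this irreducible ambiguity affects ≈ 0.9% of
non-inserted positions; measured recovery is ≈ 99.1%.

What the generator does **not** emulate: covariation-consistent mutation
(paired positions mutate independently, so real compensatory substitution
patterns are absent), biologically realistic expansion segments, sequence
composition bias, and the curated aesthetics of real templates. Passing
tests therefore demonstrate the mechanics of transfer, placement and
rotation — not that template selection would be as easy on real families,
where profile methods exploit structure signal this stand-in ignores.

## Numerical and testing choices

* All dynamic programmes are exact and verified against independent
  enumeration oracles: global alignment against a monotone-matching
  enumeration with closed-form affine gap costs (500 random pairs of ≤ 8
  nt), tree edit cost against exhaustive search over all order- and
  ancestry-preserving mappings (200 pairs of trees with ≤ 6 nodes), overlap
  counts against a double loop (100 random layouts), and every accepted
  hairpin rotation against an independent 12-angle evaluation (50
  constructed clash fixtures).
* The end-to-end study uses 20 templates of 100–300 nt and 200 mutated
  queries; identity fidelity uses 100 templates of 30–70 nt. These sizes
  exercise multibranch layouts and batch statistics while keeping the whole
  suite fast to re-run.
* Tree edit mapping follows the standard leftmost-leaf keyroot dynamic
  programme with unit costs (relabel = 1 between pair nodes and unpaired
  leaves); ties are fixed by the postorder enumeration and backtrack order,
  so mappings are reproducible. It is the fallback mapping; the pipeline
  itself always has the alignment-informed correspondence.
* RNG discipline: every stochastic function takes a `seed` and restores the
  caller's RNG state, so library calls never perturb user code.

## Known limitations

* Selection is sequence-only. Templates with near-identical references but
  different structures cannot be told apart (real pipelines use structure-
  aware covariance models); the 3D-provenance preference is the only
  structural prior.
* A single global alignment decides insertion placement; co-optimal
  placements are resolved by convention, not re-examined per structural
  context.
* Only hairpin segments rotate during overlap resolution; clashes between
  multibranch arms or with long exterior tails may persist (the overlap
  count before/after is reported so such diagrams are identifiable).
* Very large insertions distort loops: all run members are placed on one
  fitted circle regardless of run length.
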