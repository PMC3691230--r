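---
title: "Scaffold finishing with scaffoldsmith: model, coordinate arithmetic and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffold finishing with scaffoldsmith}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffoldsmith)
```

## The problem

A draft microbial genome arrives as a set of assembled, annotated contigs.
Finishing it means deciding an order and orientation for those contigs,
trimming low-quality ends, splicing in PCR products that close gaps, and
leaving explicit runs of `N` where the sequence is still unresolved — then
producing, from that arrangement, the draft genome FASTA, the annotations
in genome coordinates, and the GenBank submission file set. The edits are
conceptually tiny ("flip contig 7", "trim 14 bp off the start of contig
2") but operationally painful when applied to large sequence files, and
every edit invalidates the coordinates of every annotation downstream of
it.

scaffoldsmith's model: the *scaffold plan* is the single editable artifact,
a YAML file small enough to read in full and to version-control. Every
other file is derived from it by a pure, deterministic function, so edits
propagate by regeneration, never by hand-patching.

## The scaffold plan and its semantics

A plan is an ordered list of two entry kinds:

* `sequence` — place a contig. Optional keys: `reverse` (place the reverse
  complement), `start`/`stop` (1-based inclusive trim), `inserts` (a list
  of patches, each replacing host span `[open, close]` with the full
  sequence of another record in the contig FASTA).
* `unresolved` — a gap of known length, rendered as that many `N`s.

All coordinates anywhere in the system are 1-based and inclusive, matching
GFF3 and AGP, so no off-by-one conversions occur at format boundaries.

One processing order had to be fixed and is applied everywhere:
**inserts → trim → orientation**. `start`/`stop` are therefore interpreted
in *post-insert* coordinates: a patch that changes the contig's length
shifts the meaning of a downstream trim, and a trim may deliberately cut
into a patched region. This is the one rule a plan author must know; the
alternative (trim first) cannot express "patch near an end, then tidy the
end", which is the common gap-closing move.

Structural rules: a plan contains at least one contig placement and
neither starts nor ends with a gap (leading/trailing `N` runs are not part
of a scaffold; GenBank rejects them). Unknown keys in the YAML are hard
errors — a hand-edited format must fail loudly on typos, not guess.
`validate_scaffold()` returns the full list of problems (unresolvable
contig ids, insert spans outside the host or overlapping each other, trims
outside post-insert bounds) rather than stopping at the first, so a plan
can be repaired in one pass. Zero-gap joins between consecutive contigs
are allowed and assembled silently: the format permits them and AGP can
express them.

## Assembly and the coordinate layout

`assemble()` renders each entry and concatenates. The by-product that the
rest of the package runs on is the *layout*: for each entry, its scaffold
span `[scaffold_start, scaffold_stop]`, and for contig entries the placed
post-insert slice `[source_start, source_stop]` plus the orientation flag.
The layout provably tiles `[1, L]` — the test suite asserts tiling, gap
purity (gap slices all `N`) and slice identity on every assembly it
builds.

Assembly is held entirely in memory. For the intended scope (microbial
genomes, ≤ a few tens of Mbp) this is comfortable on any laptop; the
simplicity buys determinism and trivially reproducible output. `N` is
always upper case, matching GenBank convention.

## Lift-over

For an annotation `[a, b]` on contig `c`:

1. `c` must be placed exactly once. Unplaced → dropped
   (`contig-not-placed`); placed twice or more → dropped
   (`ambiguous-multiple-placements`), because duplicating a gene would
   duplicate its locus_tag and break submission.
2. Every position of `[a, b]` must survive insert replacement: the
   per-entry offset map sends original host positions to post-insert
   positions, with replaced spans mapping to nothing. Any overlap →
   dropped (`overlaps-insert-region`). This check runs first when a
   feature overlaps both an insert and a trim boundary.
3. The mapped interval must lie inside the placed slice
   `[source_start, source_stop]`; otherwise dropped
   (`overlaps-trimmed-region`).
4. Translation. Forward placement: add the scaffold offset. Reversed
   placement: the interval is mirrored within the slice,
   `new_start = scaffold_start + (source_stop − m_stop)`,
   `new_stop = scaffold_start + (source_stop − m_start)`, and the strand
   flips (`.` is left unchanged).

The deliberate design choice is **drop, never truncate**: silently
shortening a gene changes its biology invisibly, whereas a drop is loud
and auditable — `lift_all()` returns a report that partitions the input
exactly into lifted and dropped-with-reason, and the CLI prints the drop
list on stderr. Annotations on patch contigs are likewise not lifted:
patches are sequence donors, and their coordinate frame (the patch) is
not the frame the annotation pipeline annotated. Phase is carried through
unchanged in both orientations: under the single-interval, intron-less
gene model there is no exon structure over which phase could change.

The module's master property, asserted over hundreds of randomized
projects: every lifted feature's scaffold slice equals the original contig
subsequence exactly (reverse-complemented when the placement is reversed),
and lengths are preserved.

## Submission files

* **FASTA** is wrapped at 70 columns — a common GenBank-toolchain width,
  pinned so output is byte-stable and golden-file testable.
* **AGP 2.0**. Gap rows are `N` / `scaffold` / linkage `yes` /
  `linkage_evidence unspecified`, the standard vocabulary for unresolved
  scaffold gaps of known length. Component rows reference the *placed*
  slices: the contig FASTA emitted for submission contains the post-insert,
  trimmed, forward-orientation slice of each placement, so `component_beg`
  is 1, `component_end` the slice length, and orientation carries the
  reversal. The alternative — emitting original full-length contigs and
  carrying trim offsets in the AGP — cannot represent patched contigs at
  all (the patched sequence exists in no input file), so consistency
  between AGP and component FASTA was chosen over fidelity to the raw
  contig set. A contig placed more than once gets suffixed component ids
  (`id`, `id.2`, …) to keep the FASTA valid.
  `reconstruct_from_agp()` closes the loop: AGP + component FASTA rebuild
  the assembled sequence byte-for-byte, and the suite asserts this on
  every fixture.
* **Feature table**. Each gene yields a `gene` and a `CDS` row over the
  identical interval (no partials, no `codon_start`), since the model
  assumes no intron/exon structure. Minus strand is encoded as
  `start > stop`, per the 5-column format. `product` defaults to
  `"hypothetical protein"`. Locus tags renumber as `<prefix>_<n>`, `n`
  starting at 10 and stepping by 10 in scaffold order, zero-padded to five
  digits — the prokaryotic-annotation convention, leaving room for later
  insertions between neighbours.

## The command line

`scaffoldsmith view <type>` emits exactly one artifact per invocation on
stdout, diagnostics on stderr, and is a pure function of its input files
and flags — no timestamps, hostnames or ordering nondeterminism — so it
slots into GNU Make dependency graphs and produces clean git diffs. Exit
codes: 0 success, 1 validation failure, 2 usage error. Extension is by
adding subcommands to the in-process registry; no plugin mechanism is
provided.

## The synthetic-data generator

`generate_fixture()` produces a complete finishing project with known
ground truth: uniform-random contigs, non-overlapping gene intervals (one
per equal-width block of the contig), and a plan placing every contig once
in shuffled order, with reversal probability 0.5, trim probability 0.3 and
single-patch-insert probability 0.3 per placement; consecutive placements
are separated by an unresolved gap at 70% of junctions, so zero-gap joins
are exercised too. The defaults — 2–6
contigs of 1–10 kbp, 0–5 genes each, gaps of 100–500 bp — are the
package's reference study conditions, sized so that a full 500-fixture
property run completes in well under a minute on one CPU while still
exercising every combination of reversal × trim × insert many times over.

The point of the generator is its independence: the expected scaffold
interval and strand of every gene (or the reason it must be clipped) is
computed by a separate straight-line calculation — cumulative entry
offsets, a single shift for a passed insert, explicit mirror arithmetic —
that never calls the lift-over code. Agreement between `lift_all()` and
this ground truth is therefore a genuine two-implementation cross-check,
not a tautology.

What the generator does *not* emulate, and hence what passing tests do not
show: realistic base composition or repeats (the arithmetic under test is
coordinate, not sequence, arithmetic), multiple inserts per placement
(covered instead by targeted hand-written cases), overlapping genes,
multi-exon gene models, or annotations of non-gene types. Real projects
with those features exercise code paths (drop rules, type filtering) that
the hand-written unit tests cover, but not at fixture scale.

## Numerical and degenerate-input choices

* Coordinates are R integers throughout; scaffolds beyond 2 Gbp are out
  of scope.
* Sorting of lifted features is by (start, end, `ID`) with radix order, so
  ties are deterministic across platforms and locales.
* An annotation with `start > stop`, or extending beyond its contig, is a
  hard error (corrupt input), never a drop: drops are reserved for
  well-formed features that the plan's edits removed.
* `parse_scaffold` accepts a structurally valid file whose coordinates are
  inconsistent with the contig set (e.g. `close < open`); such problems
  are the province of `validate_scaffold`, which names all of them at
  once. `assemble` refuses a plan that does not validate cleanly.
* The same fixture seed always reproduces the identical project; the
  generator saves and restores the caller's RNG state.

## Known limitations

* Single-interval features only: no mRNA/exon hierarchies, no
  trans-splicing, no partial-feature (`<`/`>`) markup.
* No `.asn` generation — outputs are the *inputs* to tbl2asn/sequin.
* No automatic contig ordering: the plan is authored from external
  evidence (reference alignment, paired reads); scaffoldsmith takes it as
  authoritative and does no overlap merging or consensus recomputation at
  joins.
* Compatibility with any particular pre-existing scaffold-file dialect is
  not claimed; the YAML schema documented here is the format.
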