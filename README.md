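# scaffoldsmith

Finishing a microbial draft genome is mostly bookkeeping: contigs must be
ordered, oriented, trimmed and patched; gene annotations must follow every
edit; and GenBank wants a very specific file set at the end. Doing any of
this by editing multi-megabase FASTA or GFF3 files directly is slow and
error-prone.

`scaffoldsmith` keeps the scaffold as a small, human-editable YAML plan and
regenerates everything else from it, deterministically:

- **assembly** — the plan (contig order, orientation, `start`/`stop` trims,
  PCR-patch inserts, unresolved `N` gaps) is rendered into the draft genome
  sequence, with a coordinate layout tiling `[1, L]`;
- **annotation lift-over** — GFF3 gene features in contig coordinates are
  mapped onto the scaffold. On a reversed placement an interval `[a, b]` on
  a placed slice `[s, e]` maps to
  `[start + (e − b), start + (e − a)]` and the strand flips; features
  overlapping a trimmed-off or insert-replaced region are *dropped with a
  reason*, never silently truncated;
- **submission files** — assembled FASTA, placed-component FASTA, AGP 2.0
  ("golden path") and the NCBI 5-column feature table (`.tbl`) consumed by
  tbl2asn/sequin, including locus_tag renumbering
  (`<prefix>_00010, _00020, …` from the sequence origin).

Every output is a pure function of the input files, so the whole finishing
process can sit in a Makefile and a git repository: edit `scaffold.yml`,
rerun `view`, and all downstream files update.

Intended scope is in-memory assembly of microbial-sized genomes (up to a
few tens of Mbp) with single-interval (intron-less) gene models.

## Worked example

A three-contig project: contig1 placed as-is, contig2 reverse-complemented
after a 10 bp gap, contig3 trimmed to `[5, 24]` after a 5 bp gap.

```r
library(scaffoldsmith)

contigs <- c(
  contig1 = "ACGTACGTACGATTACAGATTACAGATTACAGGCCGGCCGTTTTAAAACCCCGGGGTTAA",
  contig2 = "TTGACATTGACATTGACATTGACAGGGGCCCCAATTGGAA",
  contig3 = "AAACCCGGGTTTACGTACGTACGTAAACCC")

plan <- parse_scaffold("
- sequence:
    source: contig1
- unresolved:
    length: 10
- sequence:
    source: contig2
    reverse: true
- unresolved:
    length: 5
- sequence:
    source: contig3
    start: 5
    stop: 24
")

asm <- assemble(plan, contigs, identifier = "chr1")
asm
#> <assembled_scaffold> chr1: 135 bp, 3 contig segment(s), 2 gap(s)

cat(render_agp(asm))
#> ##agp-version 2.0
#> chr1	1	60	1	W	contig1	1	60	+
#> chr1	61	70	2	N	10	scaffold	yes	unspecified
#> chr1	71	110	3	W	contig2	1	40	-
#> chr1	111	115	4	N	5	scaffold	yes	unspecified
#> chr1	116	135	5	W	contig3	1	20	+
```

The AGP says: positions 1–60 of `chr1` are component `contig1` forward,
61–70 a 10 bp scaffold gap, 71–110 `contig2` reverse-complemented, and so
on — part numbers sequential, object and component spans equal in length.

Three genes annotated on the contigs; the one at `contig3:1-8` falls in the
trimmed-off region:

```r
ann <- rbind(
  make_annotations("contig1", 11, 40, "+",
    attributes = list(c(ID = "g1", Name = "dnaE", locus_tag = "TMP_0001",
                        product = "DNA polymerase III"))),
  make_annotations("contig2", 5, 16, "+",
    attributes = list(c(ID = "g2", locus_tag = "TMP_0002"))),
  make_annotations("contig3", 1, 8, "+",
    attributes = list(c(ID = "g3", locus_tag = "TMP_0003"))))

rep <- lift_all(ann, asm)
rep
#> <lift_report> 2 lifted, 1 dropped
#>   dropped (overlaps-trimmed-region): 1
```

`g2` sat at 5–16 on the plus strand of a 40 bp contig placed
reverse-complemented at 71–110, so it lands at 95–106 on the minus strand —
and its scaffold slice is exactly the reverse complement of the original
subsequence. Renumbering locus tags and rendering the feature table:

```r
genes <- renumber_locus_tags(rep$lifted, "EXM")
cat(render_tbl("chr1", tbl_features_from_genes(genes), nchar(asm$seq)))
#> >Feature chr1
#> 11	40	gene
#> 			gene	dnaE
#> 			locus_tag	EXM_00010
#> 11	40	CDS
#> 			product	DNA polymerase III
#> 			locus_tag	EXM_00010
#> 106	95	gene
#> 			locus_tag	EXM_00020
#> 106	95	CDS
#> 			product	hypothetical protein
#> 			locus_tag	EXM_00020
```

Minus strand is encoded as `start > stop` (`106 95`); each gene derives a
CDS over the same interval, with `product` defaulting to
`"hypothetical protein"`.

## Command line

The same artifacts from a shell (files `scaffold.yml`, `contigs.fasta`,
`annotations.gff3` in the working directory, or passed via flags):

```sh
scaffoldsmith view fasta   > genome.fasta
scaffoldsmith view contigs > components.fasta
scaffoldsmith view agp     > genome.agp
scaffoldsmith view gff --annotations annotations.gff3 > genome.gff3
scaffoldsmith view table --annotations annotations.gff3 \
    --prefix EXM --reset-locus-numbering > genome.tbl
```

The wrapper script installs under `exec/scaffoldsmith` in the package
directory (`file.path(find.package("scaffoldsmith"), "exec")`); artifact
bytes go to stdout, all diagnostics (including the lift-over drop report)
to stderr. Exit codes: 0 success, 1 validation error, 2 usage error.

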