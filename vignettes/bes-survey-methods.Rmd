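---
title: "Methods: BAC-end sequence genome surveys with beskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BAC-end sequence genome surveys with beskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beskit)
```

## The survey model

A BAC-end sequence (BES) survey samples a genome by sequencing both ends of
large-insert (~100–150 kb) BAC clones. The reads are short (here 50–879 bp,
mean ≈ 543 bp) but their pairing carries long-range information: the two
reads of a clone face inward across the insert, so their joint placement on
another genome tests conserved local order at the 100-kb scale. From a few
tens of thousands of clones one obtains genome-wide estimates of GC content,
microsatellite density, transposable-element composition, coding fraction,
and microsynteny with sequenced relatives — all before any genome assembly
exists.

`beskit` implements every stage of such a survey as composable functions
over plain data frames, with a synthetic-data generator that plants each
feature class with a complete ground-truth ledger. The package also ships
the summary count tables of a published melon (*Cucumis melo*, 454 Mb
genome) BES survey as plain-text reference data, and
`recompute_survey_stats()` re-derives every printed ratio of that survey
from those counts through the same summary operations the pipeline applies
to fresh data.

## Coordinates, pairing and formats

Internally every span is 0-based half-open and strand is an explicit field;
1-based inclusive coordinates exist only at file boundaries (FASTA, the
12-column tabular homology format, the repeat-annotation dialect). The
read-pairing scheme (trailing `.f`/`.r` or `_F`/`_R`) is configurable via
`bes_id_scheme()` because naming conventions differ between sequencing
centres; pairing conserves every read (`2·pairs + unpaired = reads`) and
rejects duplicate (clone, end) combinations.

## Microsatellite scanning

`find_ssrs()` reports maximal perfect tandem runs of primitive 1–6 nt
units. Thresholds follow the survey convention: units of 1–3 nt must reach
12 nt of total length; units of 4–6 nt must reach four unit repetitions.
Partial final units are allowed, so copy number is real-valued
(`total_length / unit_length`). `N` terminates runs. Detection is exact, not
heuristic: a lag-*k* equality scan finds every maximal period-*k* run, runs
whose leading unit is non-primitive are left to the smaller period that
covers them, and nested candidates are suppressed deterministically —
longest span wins, ties to the smaller unit, then the leftmost start. By a
Fine–Wilf argument no sub-run of a different unit inside a perfect repeat
can itself reach the reporting thresholds, so suppression only ever removes
true duplicates of the same region.

Motif classes collapse strand and rotation: the canonical motif is the
lexicographic minimum over all rotations of the unit and of its reverse
complement (`canonical_motif("TTC")` is `"AAG"`, class `AAG/CTT`). Class I
microsatellites are those longer than 20 nt; length bins are inclusive of
their lower bound (12–20, 21–50, 51–100, > 100 nt), making 21 nt the class I
boundary. Density is reported as kb of sequence per SSR, rounded half-up to
one decimal.

The scanner is validated against an exhaustive per-position oracle on over a
thousand random sequences up to 5 kb, and summaries are invariant under
reverse complementation of the input.

## Redundancy reduction by greedy overlap clustering

BES sets are internally redundant (the restriction library especially, see
below), so all downstream statistics run on a non-redundant set built by
overlap clustering at deliberately strict thresholds: a minimum overlap of
80 aligned columns and a minimum match of 95%. We interpret the match
criterion as per-overlap identity with gaps counted as mismatches — the
stricter of the plausible readings. Alignment is ends-free (dovetail or
containment) with unit match/mismatch/gap scores, implemented in compiled
code because the property suites align hundreds of thousands of pairs; both
orientations are always tried since BES strands are arbitrary.

The clustering itself is greedy and deterministic: reads are processed by
descending length (ties by id), each read joins the first cluster whose
consensus accepts it, the consensus is updated by merging the read in
(mismatch columns resolve toward the longer sequence, which for two-member
contigs equals a column-majority vote), and clusters whose consensi now
overlap are merged to a fixpoint. The fixpoint step makes membership equal
the connected components of the all-pairs overlap graph on clean data,
which is exactly how the suite tests it (union–find over brute-force
all-pairs alignments, 200 random fragmentation instances). A lossless
12-mer shared-seed prefilter skips hopeless alignments: any 80-column
overlap at 95% identity must contain an exact 12-mer by pigeonhole.

Cross-assembly pools two assemblies' contigs and singletons as plain
sequences under disjoint ids and re-clusters; the redundancy report (input
minus output counts and bp) mirrors the survey's observation that almost no
redundancy exists *between* two well-made libraries even when each is
redundant internally.

## Repeat taxonomy and masking

Repeat detection itself is delegated to external screening tools; the
package consumes their annotation dialect and classifies each row into a
transposable-element taxonomy (retroelements: Ty1/Copia, Ty3/Gypsy, LINEs;
DNA transposons: hobo-Activator, En-Spm, MuDR, Harbinger; rolling circles:
Helitron; plus telomere-related and rRNA leaves). The label-to-leaf alias
table is shipped as editable plain-text config because label conventions
are tool- and version-dependent; unknown labels fall back to their declared
class's Unclassified leaf. The counting unit is the annotation row — a
homology match, not a reconstructed element — so fragmented elements are
deliberately not defragmented. Summary ratios follow the survey
conventions: retroelement share of TEs, Copia and Gypsy shares of
retroelements, En-Spm share of DNA transposons. Masking replaces the union
of annotated spans with `N` (hard, the default ahead of homology searches)
or lower-cases it (soft); masked bp counts overlaps once, and masking is
idempotent.

## Coding fraction by tiered EST homology

Genomic reads crossing intron–exon boundaries defeat stringent EST
matching, while loose matching inflates false positives, so the coding
estimate uses a double cutoff: a low-stringency E ≤ 1e-20 for detection and
a high-stringency E ≤ 1e-50 for a conservative bound. Databases are
consulted in precedence order (own species, then close relatives, then
everything else); a query moves to tier *k* only if no low-qualifying hit
existed in tiers 1..k−1, and the high flag is evaluated on the assigned
tier's best hit (lowest E, ties by bit score, then input order). The coding
fraction is then bracketed by the high- and low-stringency totals.

If the own-species unigene set were complete, every coding query would hit
it; its actual share of all coding hits therefore estimates the set's
completeness, and dividing the unigene count by that share estimates the
transcriptome size (rounded to the nearest 1,000). Only the low-stringency
(upper) estimate is asserted against the reference survey — the survey's
printed lower bound does not follow from any documented ratio of its
counts, so we compute our formula's value and make no equality claim.

A deliberately naive exact-substring search (`naive_homology_search()`,
both strands, nominal E-values) exists solely so synthetic end-to-end tests
can run without an external aligner; it is not a general homology tool.

## Paired-end microsynteny

Three criteria define a collinear pair against a subject genome: both ends
on the same subject sequence; separation within 50–500 kb (inclusive — the
insert-size scale); and correct relative orientation, which we define as
convergent opposite-strand placement, since the survey itself leaves
"correct orientation" undefined. Because a homology search returns several
fragmentary hits per read, hits on the same subject and strand within 10 kb
first merge into anchors (best-E representative); a mapping locus is any
same-subject anchor pair, and separation is measured between anchor
midpoints. Both the merge window and the midpoint convention are package
decisions — the survey never defines a "locus" operationally — and both are
exposed as parameters in `synteny_params()`.

The funnel (pairs with both ends hit ≥ same-subject ≥ in-window ≥
collinear) is monotone by construction, and dropping the orientation
criterion can only add pairs; both properties are tested on randomized
inputs. One subtlety found during design: inverting an entire collinear
block flips both ends of any contained pair together, so block-level
inversions do *not* break the orientation criterion — only inversions that
separate a pair's two ends do. The orientation-relaxation rate estimate is
therefore exercised at the locus level (orientation disrupted at a known
rate) rather than through block inversions.

## The synthetic-data generator

`simulate_genome()` plants features into an i.i.d. background at 35.2% GC
(the surveyed genome's value; configurable). Defaults for the planted
feature mixes are the study conditions: microsatellite motif classes are
drawn with the reference survey's class proportions, repeat elements with
its taxonomy proportions. Planted SSRs get flank bases chosen to break
their period, so each is maximal exactly as recorded; chance
microsatellites in the background (or inside planted fragments) are then
disrupted by point changes until a scan returns exactly the ledger. This
makes "noise-free recovery" a deterministic guarantee rather than a
high-probability event, at the cost of a background that is i.i.d. *except*
at sub-threshold repeat density — a caveat passing tests inherit: they
demonstrate correctness of the machinery, not performance on real genomic
repeat landscapes, sequencing error, or chimeric clones, none of which the
generator emulates.

`simulate_library()` mirrors the two survey designs. Read lengths are a
truncated normal on [50, 879] around mean 543 with sd chosen so ~99% of
mass lies inside the range ((max−min)/5.16 ≈ 161 bp); the asymmetric
truncation pulls the realized mean to ≈ 536 bp, within 2% of the target.
Insert sizes are normal truncated at ±3 sd (default sd 10% of the mean;
the survey gives only means). The number of sequenced clones is
`round(n_clones × (1 − empty_fraction))`, matching the reference survey's
true-clone arithmetic. Random-shear inserts start uniformly; restriction
inserts run between two BamHI (`GGATCC`) ledger sites whose distance is
within 3 sd of the draw, reproducing the stacked, non-uniform coverage that
motivated the second library design.

`simulate_related_genome()` copies non-overlapping source blocks into a
target genome with optional reverse complementation, per-base substitution
divergence (substitutions only, no indels — keeping ground-truth
coordinates exact), and a duplication multiplicity *m*: copy *j* of every
block lands on target pseudomolecule *j*, emulating whole-genome
duplication. This placement choice is what makes "mean mapping loci per
pair → *m*" hold: duplicated copies on one chromosome would instead produce
m² anchor combinations. Source blocks keep a minimum 100 kb separation so a
BAC insert cannot straddle two sampled blocks. `project_read_hits()` maps
reads through the block ledger with exact coordinate arithmetic, standing
in for a homology search wherever the truth is known.

## Numerical conventions and problem sizes

Percentages, densities and coverage round half-up to one decimal (base R
rounds half to even, which does not reproduce the reference survey's
printed values); integer counts are never rounded. Coverage is
`round(clones × true_fraction) × insert_kb / genome_kb`. Two of the
reference survey's printed coverages (5.7× and 6.4×) sit one decimal above
this arithmetic (5.6×, 6.3×), and a few printed percentages appear
truncated rather than rounded; the recomputation reports the arithmetic
value in those cases, and `genomic_coverage()` documents the convention
rather than matching irreproducible digits.

The test and acceptance workloads are scaled to the statistics they check:
SSR oracle equivalence on ~1,000 sequences of 30–300 bp plus a tail up to
5 kb; assembly-oracle equivalence on 200 instances of ~5–15 fragments;
planted-feature recovery over 5 seeds on 25–250 kb genomes; and the
duplication-multiplicity check on a 2 Mb genome with 1,000 clones, where
the mean loci per same-subject pair is required to fall within 10% of the
planted m = 2. The analysis scripts under `analysis/` run the same pipeline
at a 1:10 insert-size scale (13.9 kb inserts on 150 kb pseudomolecules) so
the whole narrative executes in seconds while keeping read geometry
unscaled.

## Known limitations

* Consensus sequences are built incrementally; for contigs of three or more
  members the column-majority rule is approximated by pairwise merging.
* The generator's divergence model has no indels, so identity thresholds
  are exercised but alignment gap handling is only covered by the
  mismatch-free property suites.
* Repeat discovery is out of scope by design: the package classifies and
  masks existing annotations; it does not find repeats.
* Scaffold adjacency is not inferred: each subject sequence id is its own
  "chromosome" for the synteny criteria, which undercounts collinearity on
  fragmented subject assemblies exactly as the reference survey notes for
  its most fragmented comparison.
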