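---
title: "Small RNA-seq miRNA discovery: models, criteria and design choices"
author: "equimir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small RNA-seq miRNA discovery: models, criteria and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equimir)
```

## The problem

Small RNA sequencing of animal tissues yields tens of millions of short
reads: mature microRNAs, but also adapter artefacts, degradation
fragments of rRNA/tRNA/snoRNA and mRNAs, and low-quality junk. The
analysis that turns these reads into a miRNA annotation has a canonical
shape, which this package implements end to end:

1. **Cleaning** — remove low-quality reads, 5' primer contaminants,
   reads without a 3' adapter or insert, poly-A reads, and inserts
   outside the analyzed 18–30 nt range.
2. **Collapsing** — merge identical inserts into unique *tags* carrying
   per-tissue read counts.
3. **Mapping** — find every perfect, full-length match of each tag on
   both strands of the genome.
4. **Annotation** — assign each tag to a category (known miRNA, rRNA,
   tRNA, snRNA, snoRNA, scRNA, srpRNA, repeat, exon, intron) by exact
   sequence identity/containment or genomic feature overlap. A tag
   identical to a cataloged mature miRNA, or contained in a cataloged
   hairpin, is a *known* miRNA.
5. **Novel-miRNA calling** — for unannotated mapped tags, excise
   candidate precursor windows, fold them, characterize the
   miRNA/miRNA\* duplex, and call a novel miRNA when ten structural and
   expression criteria all hold.
6. **Clustering** — chain miRNA loci lying within 3 kb of each other
   into polycistronic clusters.
7. **Composition** — first-nucleotide bias by length, per-position base
   composition (A+U vs C+G, seed region), and the three-tissue presence
   Venn partition.

## The ten calling criteria

A candidate precursor is accepted only if all ten criteria pass
(`criteria_config()` holds the thresholds):

| # | criterion          | default        | meaning |
|---|--------------------|----------------|---------|
| 1 | mature length      | 18–26 nt       | length of the candidate mature tag |
| 2 | reference length   | 20–24 nt       | length of the locus's most abundant tag |
| 3 | cut-site depth     | ≥ 3 reads      | reads sharing the mature 5' terminus |
| 4 | copy number        | ≤ 20 loci      | perfect genomic matches of the tag |
| 5 | free energy        | ≤ −18 kcal/mol | folding energy of the precursor |
| 6 | arm spacing        | ≤ 35 nt        | unpaired span between miRNA and miRNA\* |
| 7 | duplex pairs       | ≥ 14           | base pairs between the two arms |
| 8 | bulge              | ≤ 4 nt         | longest unpaired run inside the duplex |
| 9 | asymmetry          | ≤ 5 nt         | \|unpaired mature − unpaired star\| |
| 10| flank              | ≥ 10 nt        | precursor sequence beyond the duplex |

Three interpretation decisions were genuinely open and are resolved as
follows. The printed unit for criteria 3 and 4 ("3 nt", "20 nt") is
treated as a typo for a read count and a locus count respectively —
depth of a cut site and copy number on a reference are counts, not
lengths. The "reference sequence" of criterion 2 is read as the
locus-representative (most abundant) tag, since a per-locus consensus
is the only reference a de-novo caller has. Criterion 3 counts reads
whose 5' end coincides with the candidate mature 5' terminus, the
Dicer/Drosha precision signal; 3' ends are allowed to wobble.

The star arm is located as the interval of positions pairing with the
mature arm, extended by a 2-nt 3' overhang — the canonical Dicer
signature; the overhang does not count toward the arm spacing, which is
measured between the raw pairing extents across the loop.

## The folding engine

`fold()` computes the minimum-energy nested structure under a
deliberately small nearest-neighbour model: stacks of adjacent pairs
score −3.0 (GC/GC), −2.0 (GC/AU), −1.0 (AU/AU), or −0.5 kcal/mol when
either pair is a G:U wobble; every unpaired base enclosed by a pair
costs +0.5 kcal/mol; hairpin loops need ≥ 3 unpaired bases; exterior
bases are free. The published analyses rely on Mireap/RNAfold energies
whose parameterization they do not specify; this model is an explicit,
checkable stand-in with the same qualitative behaviour (GC-rich stems
fold far below −18 kcal/mol, random sequence does not).

Because the model is small, the dynamic program's optimality is testable
by brute force: the test suite enumerates *every* nested structure of
random sequences up to 25 nt, scores them directly, and checks the DP
returns the minimum. Ties are broken deterministically (exterior bases
prefer unpaired, helix interiors prefer the stacked continuation,
branch points take the leftmost minimal split), so folds are
reproducible. ViennaRNA's RNAfold can be swapped in through
`fold(..., engine = "rnafold")`; the calling machinery only relies on
the `fold_result` contract (sequence, dot-bracket, energy). Planted
simulator hairpins are designed with enough margin to clear
−18 kcal/mol under both models.

Candidate windows are excised in both orientations (tag as 5' arm and
as 3' arm): flank + tag + max spacing + max mature length + flank,
103 nt for a 22-nt tag at the defaults. After the duplex is located on
the window fold, the precursor is *refined* to the duplex plus flanks
and refolded; criteria are evaluated on the refined precursor, so the
reported energy describes the hairpin, not incidental structure in the
excision window. Windows shorter than the tag plus 20 nt after clipping
at contig bounds are dropped; overlapping passing candidates at one
locus are merged keeping the lowest-energy precursor (ties: higher read
support, then leftmost), and the reported mature is the locus's most
abundant tag.

## Cleaning rules

The published cleaning step names its filters but not its thresholds.
The defaults here (`cleaning_config()`) are conventional and
configurable: the 3' adapter is located by longest-prefix match with
minimum 6-nt overlap and at most one mismatch per 10 aligned bases;
poly-A means ≥ 80% adenine in the insert (a fractional rule is robust
to 3'-end jitter); low quality means more than half the insert bases
below Q10; the analyzed length range is 18–30 nt, the range the
published results report (the gel excision was 18–32 nt; the analyzed
range governs). Every read lands in exactly one bucket — clean or one
of six removal reasons — and the cleaning report reconciles exactly,
which the tests assert on every simulation.

## Annotation priority

When a tag matches several categories the first match in
known_mirna > rRNA > tRNA > snRNA > snoRNA > scRNA > srpRNA > repeat >
exon > intron wins. No precedence is stated in the published method;
this is the conventional small-RNA ordering (catalog identity beats
structural RNA beats genomic context) and is configurable. Known-miRNA
matching is strand-insensitive: a read that is the exact antisense of a
cataloged hairpin fragment is still a fragment of that locus.

## Clustering

Loci are chained per chromosome by single linkage: consecutive loci
(sorted by start) whose edge-to-edge gap is ≤ 3000 nt join the same
chain, and chains of ≥ 2 become clusters. Chaining is transitive — A
within 3 kb of B and B of C puts all three in one cluster even if A and
C are > 3 kb apart — which is what reproduces the large 9–14-member
chromosome-24 cluster spans in the bundled table. The gap is
edge-to-edge (end of the left locus to start of the right), the
stricter and more common convention, and strand is ignored. Equivalence
with an O(n²) transitive closure of the pairwise relation is asserted
on random fixtures up to 100 loci.

The printed cluster table ships as a plain-text transcription
(`inst/extdata/polycistron_clusters.tsv`). Two numbers printed about it
disagree with each other in the source: the text states 160 clustered
miRNAs (and "approximately 55%" of 292 known miRNAs in the Results,
"approximately 53%" in the Discussion), while the printed member lists
sum to 158 (54% of 292). `parse_cluster_table()` reports what the table
contains; tests pin the 51-row count and the per-chromosome counts, not
the irreconcilable total. Spans printed backwards (start > end) are
normalized and recorded as minus-strand, the only strand signal the
table carries.

## The synthetic-data generator

`generate_toy_genome()` + `simulate_reads()` build a fully specified
test world: a random multi-chromosome genome (default 120 kb over 4
contigs) carrying criteria-passing miRNA hairpins — "known" ones also
emitted into a mock mature+hairpin catalog, "novel" ones not — plus one
decoy hairpin per requested criterion and decoy annotation features
that shed degradation fragments. Reads are mature sequences with fixed
5' ends, 1-nt 3' jitter at rate 0.15, per-miRNA log-normal expression
(meanlog log 100, sdlog 0.8, floor 5) shared across tissues with
dropout (presence probability 0.7) to create the tissue-Venn structure,
uniform base error 0.002, and ~5% each of poly-A, short, adapterless
and low-quality junk. `noise = FALSE` zeroes jitter, error and junk so
recovery is exact. These values are not taken from the published study
(which reports no count model); they are conventional magnitudes for
tissue small-RNA libraries, fixed once.

Design points worth knowing:

* **Verified planting.** Every planted locus is evaluated with the
  package's own caller at build time and redrawn (bounded, seeded)
  until the verdict matches its design — passing hairpins pass all ten
  criteria with margin, and each decoy fails *exactly* its designed
  criterion.
* **Imperfect stars.** Star arms carry two well-separated non-pairing
  substitutions. Real duplexes are imperfect, and this serves two
  structural purposes: a planted mature maps to exactly one locus (its
  perfect antisense does not occur at the star), and no single
  sequencing error can turn a read into an exact antisense match.
* **No criterion-1 decoy.** Cleaned tags are 18–30 nt; any mature
  length in that range violating the 18–26 bound also violates the
  20–24 reference bound, so a *single*-criterion decoy for criterion 1
  cannot exist. The generator rejects requests for it with an
  explanation; decoys cover criteria 2–10.
* **Decoy mechanics.** The depth decoy is expressed at 2 reads; the
  copy-number decoy's mature (plus its two following bases, so jittered
  variants multi-map too) is planted at 21 loci; the flank decoy is
  planted flush with a contig start with its 5' flank truncated to
  3 nt; the energy decoy uses an A:U-only stem; the spacing decoy a
  40-nt loop over a short strong stem; the pairing, bulge and asymmetry
  decoys carry engineered partial stars and insertions.
* **Designed polycistrons.** The first four known loci are planted as
  two pairs 800 nt apart; all other known/novel loci keep > 3 kb
  separation, so the planted truth implies exactly the designed
  clusters.

What the simulation does *not* emulate: realistic quality-score
distributions, ligation and PCR bias, isomiR 5' heterogeneity,
non-templated additions, cross-mapping between paralogous families, and
genome-scale repeat structure. Passing recovery tests therefore shows
the machinery is correct on data satisfying the stated assumptions, not
that the criteria themselves are well-calibrated for real tissue
libraries — the thresholds are the published ones, taken as given.

## Validation and problem sizes

`simulate_and_validate()` is the one-command self-test: simulate, run
the full pipeline, and compare against the planted truth. Novel-call
precision and recall are measured by genomic overlap with
criterion-passing planted loci; known recovery through annotation; and
per-decoy, the verdict of the locus's dominant read stack is compared
with the designed failure. The test suite and `scripts/acceptance.R`
run this noiselessly (expecting exact recovery) and across five noisy
seeds (expecting mean precision and recall ≥ 0.95), on the default
problem size: 120 kb genome, 23 planted loci, three tissues,
~2–3 thousand reads per tissue. Fold-optimality enumeration uses random
sequences to 25 nt; clustering equivalence uses random fixtures to 100
loci. These sizes keep a full validation in tens of seconds on one CPU
while exercising every stage; they are scale models, not scaled-down
claims about the published dataset, whose headline counts (292 known,
329 novel miRNAs) depend on the real sequencing libraries and are out
of scope here.

## Composition statistics

`first_nucleotide_bias()` and `positional_composition()` are computed
over distinct mature sequences, unweighted — "all identified miRNAs"
reads most naturally as the sequence set — with an optional `weights`
argument for read-count weighting, since the published figures do not
state which was used. Ragged lengths are handled by computing position
*p* over the sequences long enough to reach it. The seed region is
positions 2–8. Tissue presence uses count ≥ 1 after cleaning by
default; the threshold is a parameter.

## Numerical and degenerate-input conventions

Internal coordinates are 0-based half-open everywhere; GFF3 output and
the printed cluster table are 1-based inclusive. Percentages are exact
ratios (tests allow 0.01 absolute for row sums); the clustered share is
rounded to the nearest integer percent. Empty inputs return empty,
well-typed results (empty tag lists, header-only GFF3, zero-count
reports); empty composition input is an error since a frequency over
nothing is undefined. A mature arm with no external partners yields a
"no duplex" result whose dependent measures are NA, and NA measures
fail their criterion. Verdict evaluation is monotone: relaxing any
single threshold can only turn failures into passes (property-tested).

## Limitations

The baseline energy model is a teaching-grade stand-in: its energies
correlate with but do not equal Turner-model energies, so criterion 5
decisions near the −18 kcal/mol boundary can differ between engines.
Exact-match mapping (the published pipeline's perfect-match rule) makes
recovery sensitive to sequencing error by construction — an error
anywhere in a read removes it from mapping rather than mismapping it.
Annotation containment is exact substring matching, not alignment, so
catalog entries must cover the read orientation (both strands are
checked for miRNA entries). The caller reports one merged call per
locus and does not perform arm-switch or isomiR analysis.
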