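---
title: "Classifying yeast mating compatibility systems and counting their evolutionary transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying yeast mating compatibility systems and counting their evolutionary transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological question

Cell type in budding yeasts is set by the genotype at the mating-type
(*MAT*) locus: a cell expressing the **a**-idiomorph genes (a1, a2) mates
with one expressing the α-idiomorph genes (α1, α2). Species differ in how
they manage this. Heterothallic species maintain two stable haploid mating
types. Homothallic species do not: either every cell carries both kinds of
*MAT* genes (primary homothallism), or cells switch their mating type by
rearranging DNA at the *MAT* locus (secondary homothallism). The genomic
machinery of switching is visible in an assembly: silent donor cassettes
flanked by X/Z direct repeats in the three-locus (3LOC) systems typified by
*Saccharomyces cerevisiae*, or invertible chromosomal segments bounded by
one or two inverted-repeat (IR) families in the flip/flop systems (FF1,
FF2) of species like *Ogataea polymorpha* and *Komagataella phaffii*.

This package implements that inference as a reproducible pipeline. Stage
one reads a genome assembly and emits one of seven calls — `HET`, `3LOC`,
`FF1`, `FF2`, `PHC`, `PHN`, `NOMAT` — with an auditable evidence trail.
Stage two places calls for many species on a rooted phylogeny,
reconstructs ancestral systems by parsimony, and counts transitions
between systems and independent origins of switching.

## Stage one: from assembly to call

### Translated homology search

*MAT* genes are short and fast-evolving, so the search must keep weak
signals. Every protein query is aligned (Smith–Waterman, BLOSUM62, gap
open 11, extend 1) against all six reading frames of every contig. Raw
scores are converted to E-values with the Karlin–Altschul model
$E = K m n e^{-\lambda S}$ using $K = 0.041$, $\lambda = 0.267$ and a
search space of six times the assembly length, mirroring common gapped
translated-search defaults so that the retention rule $E < 10$ has its
usual meaning. Every hit below that threshold is kept: genuinely diverged
genes and the gene *fragments* that IR and X/Z regions carry both matter.
Additional copies of a query on one frame are found by masking earlier
hits and re-aligning. Hits of one query on one contig and strand within
1,500 bp are chained before query coverage is computed, which tolerates
introns and frameshifts that split a gene across frames.

A region hit by more than one distinct MAT query within 2,000 bp becomes a
candidate *MAT* region; the 2 kb window reflects that a1/a2 and α1/α2
pairs are immediately adjacent in all known cassette layouts.

### Gene calls and loci

Call status is a total function of two measurements: query coverage and
internal stop codons. A chain covering at least 80% of its query with no
internal stops is `intact`; with stops it is a `pseudogene`; anything
shorter is a `fragment`. The 80% bound is a deliberate compromise — loose
enough to tolerate diverged termini, tight enough that the duplicated gene
pieces inside repeats never masquerade as genes. Intact MAT genes within
10 kb on one contig form one locus; a locus needs only *one* intact gene
of a pair (a1 *or* a2, α1 *or* α2) to establish its idiomorph, because
single-gene losses within a pair are common and must not block
classification.

### Repeats, telomeres, rDNA, allelism, coverage

Repeat detection runs on 50 kb windows around each locus, all-vs-all and
in both orientations, by exact 12-mer seeding on shared diagonals followed
by identity scoring over the seeded segment. This targets the
substitution-level divergence real MAT-flanking repeats show (90–100%
identity, 200 bp to several kb); indel-rich repeats would fragment into
several diagonal segments, which the family-merging step re-joins. The
thresholds (200 bp, 90%) bracket the known real repeats — down to a 213 bp
repeat at 100% identity, up to multi-kilobase IRs at ~97%. Inverted
families near the loci are IR evidence; direct families at cassette
boundaries are X/Z-like. Because the E &lt; 10 rule deliberately retains
junk alignments, a non-intact MAT call only counts as a degenerate
cassette when it is a *strong partial* alignment (coverage ≥ 0.2 and ≥ 50
bits).

Telomeres are called as tandem arrays (unit 5–30 bp, ≥ 3 copies) starting
within 2 kb of a contig end, with the unit reported in canonical rotation
so detection is phase-independent; `N` positions never match, so gap runs
cannot fake an array. rDNA landmarks are located by the same seeded
scanner; a locus within 20 kb of an rDNA hit (or of a telomeric end) is
context-flagged — 20 kb separates the "immediately beside" cases from
second loci ~100 kb away, which should not be flagged.

Two opposite-idiomorph loci on different contigs are tested for allelism:
they are two haplotypes of one diploid locus exactly when both flanks
(500 bp per side, ≥ 95% identity, either relative orientation) are shared.
Requiring both sides is what separates a diploid assembly from a genuine
second locus with one shared boundary repeat.

Finally, assemblies made from short reads usually collapse two-copy
repeats into a single contig at about twice the median coverage, sharing
exact k-mer-length end overlaps with its flanking contigs. A contig whose
coverage ratio lies in [1.6, 2.6] of the *length-weighted median* (the
median resists repeat-inflated tails; the published description says only
"approximately twice the average") and that shares an exact 55-base end
overlap with at least two other contigs becomes a contig link — IR
evidence that survives the repeat having been assembled only once.
Conversely, some assemblers (DISCOVAR) artifactually *extend* IRs: an
inverted pair ≥ 50 kb whose copies differ by ≤ 3 positions and run to the
contig ends is flagged as a likely artifact; it still counts as IR
evidence but marks the call provisional.

### The decision rules

Rules fire in fixed order; the first match decides, and every gate
evaluated is recorded in the evidence trail:

| # | condition | call |
|---|-----------|------|
| 1 | no intact MAT gene (after a completed search) | `NOMAT` |
| 2 | one idiomorph only | `HET` (haploid) |
| 3 | both idiomorphs, all opposite pairs allelic | `HET` (diploid) |
| 4 | ≥ 3 non-allelic cassettes (intact or strong degenerate) | `3LOC` |
| 5 | IR families spanning the idiomorphs: one family | `FF1` |
|   | two or more families | `FF2` |
| 6 | no qualifying repeats: a–α gap < 20 kb on one contig | `PHC` |
|   | otherwise | `PHN` |

Repeats trump distance (rule 5 precedes rule 6) because primary
homothallism is *defined* by the absence of a switching mechanism; a
repeat-linked pair is never PHC/PHN however close the genes are. Allelism
precedes cassette counting so diploid assemblies are never mistaken for
multi-locus systems. Cross-contig repeat families whose relative
orientation cannot be known, and artifact-flagged IRs, set
`provisional = TRUE` without changing the category.

## Stage two: parsimony on the species tree

Transitions are inferred by parsimony — appropriate here because
transitions are rare relative to the number of species and there is no
defensible prior weighting between system pairs. The bottom-up pass
computes Fitch state sets (equivalently, the states minimising the Sankoff
subtree cost; a cost matrix is accepted for sensitivity analyses). The
top-down pass gives each node its parent's state when that is in the set,
so ancestral states change only where the data demand it.

Remaining ties are resolved by an explicit, recorded policy:

* `default` — fixed priority HET > PHC > PHN > FF1 > FF2 > 3LOC > NOMAT.
  This encodes the strong empirical asymmetry that derived homothallic
  systems arise *from* heterothallic ancestors, while staying inside the
  set of most-parsimonious reconstructions.
* `prefer_gains` — enumerate *all* most-parsimonious reconstructions
  (exhaustive Sankoff backtracking; practical far beyond the default
  16-tip guard because only co-optimal states branch) and select the one
  with the most HET→non-HET gains, breaking residual ties by fewest
  losses, then lexicographic node order. This is the policy that arbitrates
  cases like the three FF1 clades of *Ogataea*, where three independent
  gains and one ancestral gain plus two losses are equally parsimonious
  and gene-order evidence favours the gains.

`NOMAT` is carried as a seventh character state by default (a flag can
drop such tips as missing data): the two NOMAT species sit on terminal
branches, so either choice only affects their own branch events.
Transition counting is then mechanical: one event per branch whose
endpoint states differ, aggregated into (from, to) counts, transitions to
and from heterothallism, and switching origins — events entering
{FF1, FF2, 3LOC} from outside.

## The synthetic-genome generator

Every detector above is exercised against genomes with *known* truth. The
generator plants each of the seven architectures into seeded random
background DNA at 40% GC (typical for yeast), using seven bundled toy
stand-in proteins (mutually < 10% identical, so cross-hits cannot confound
recovery tests) reverse-translated with CTG avoided, making planted genes
invariant under all three genetic-code tags (standard, CUG-Ser, CUG-Ala).
Planted invertible spans default to 12 kb rather than the 138–194 kb of
the real flip/flop regions: the geometry that drives every decision rule
(what is inside the IRs, cassette adjacency, the 20 kb contiguity bound)
is preserved at a size that keeps a full 140-genome recovery experiment in
minutes. IR copies are mutated per-base to a target identity (default
97%). PHN genomes plant the new cassette beside a heavily degraded SLA2
pseudogene near a telomeric array — or beside an rDNA unit — mirroring the
introgression architectures seen in real PHN species.

`emulate_assembler_collapse()` rebuilds a flip/flop genome the way a
short-read assembler would see it: the IR collapsed to a single 2×
coverage contig with exact 55-base end overlaps to its four junction
contigs. The classifier must (and does) return the same category on the
collapsed form, via the coverage-link evidence path.

What the generator does **not** emulate: sequencing error, indel-rich
repeat divergence, transposon landscapes, low-complexity background,
fragmented multi-hundred-contig assemblies, or real MAT protein evolution.
Passing the closure tests therefore demonstrates the decision logic and
the detectors' contracts, not field performance on arbitrary real
assemblies — on real data the query set, not the bundled toy set, must
carry the sensitivity.

## Phylogenetic fixtures

Four per-clade fixtures (Lipomycetaceae, *Ogataea*, Saccharomycetaceae,
*Saturnispora*) package tip sets and per-species categories transcribed
from published per-clade descriptions. Their branching orders, and
placeholder names of the form `*_sp_A`, are synthetic stand-ins — the full
332-taxon phylogeny is not redistributed — constrained to respect every
stated clade membership and sister relationship. Within *Ogataea*, the
placement of the PHC species *O. naganishii* (sister to another HET
lineage rather than adjacent to the FF1 core) follows from the requirement
that exactly the two published competing hypotheses about FF1 origins be
most parsimonious, which is a property of the real topology. The complete
332-species reconstruction requires a user-supplied transcription of the
full tree and state table (`paper_fixtures("full", ...)`); dataset-wide
totals that need it are out of desk-scale scope by design.

## Numerical and design choices

* Coordinates are 0-based half-open internally everywhere; conversion to
  1-based inclusive happens only when writing GFF3.
* "Approximately twice the average coverage" is implemented as a
  length-weighted median with gates [1.6, 2.6]; mean coverage would be
  inflated by collapsed repeats themselves.
* The intactness bound (0.80), repeat thresholds (200 bp, 90%), allelism
  flanks (500 bp, 95%) and telomere parameters are method decisions, not
  published constants; each is configurable (`default_config()`), and the
  package treats the published numbers — E < 10 and the 20 kb PHC/PHN
  bound — as fixed rules.
* Overlapping gene chains tie-break by bit score; repeat families merge
  when both copies lie within 500 bp; degenerate contigs, empty FASTA and
  unknown state symbols raise errors rather than guesses.
* Species only classifiable by synteny with relatives (broken assemblies)
  are handled by the `overrides` mechanism of `run_pipeline()`: the manual
  call replaces the computed one and is flagged in the evidence trail.

## Problem sizes used by the test suite

The suite regenerates everything it tests: 140 planted genomes (7
categories × 20 seeds) for category recovery, 20 collapse round trips, 50
random ≤ 7-tip trees checked against exhaustive enumeration (and against
an independent phangorn run), plus the four per-clade fixtures. These
sizes were chosen so the whole suite completes in minutes on one core
while still exercising every rule boundary; all of them scale up by
changing one loop bound.

## Known limitations

* FF1 vs FF2 relies on counting distinct repeat families; a fragmented
  assembly that splits one family into unmergeable pieces could inflate
  the count (the family-merge gap is configurable).
* Allelism testing needs the flanks to be assembled; very short MAT
  contigs fall back to `non_allelic`, which can turn a diploid HET into
  PHN. Real analyses should inspect provisional and near-threshold calls.
* The seeded repeat scanner assumes substitution-dominated divergence;
  repeats diverged mainly by indels are found as fragmented families.
* Parsimony reports one resolution per policy; when many MPRs exist the
  enumeration interface, not the point estimate, is the honest summary.
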