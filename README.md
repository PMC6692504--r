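# matsys

Infers the **mating compatibility system** of budding-yeast species from
their genome assemblies, and reconstructs how those systems evolved on a
species phylogeny.

Cell type in budding yeasts is determined by the *MAT* locus (**a** vs α
idiomorph). Species are either heterothallic (two stable mating types) or
homothallic, and homothallism comes in mechanistically distinct genomic
flavors. From an assembly's complement of canonical *MAT* genes (a1, a2,
α1, α2), the repeats around *MAT*-like loci, and genomic context, each
species is placed in one of seven categories:

| call | meaning |
|------|---------|
| `HET` | heterothallic: one idiomorph, or both on allelic contigs (diploid assembly) |
| `3LOC` | mating-type switching with silent cassettes flanked by X/Z direct repeats (as in *S. cerevisiae*) |
| `FF1` | flip/flop switching: invertible region bounded by **one** inverted-repeat family |
| `FF2` | flip/flop switching with **two** IR families (as in *Komagataella phaffii*) |
| `PHC` | primary homothallism, *MAT***a** and *MAT*α contiguous (< 20 kb apart), no repeats |
| `PHN` | primary homothallism, non-contiguous *MAT* loci, no repeats |
| `NOMAT` | no identifiable canonical *MAT* gene |

The annotation stage is built from a TBLASTN-like six-frame translated
search (Smith–Waterman + Karlin–Altschul statistics, retaining weak hits
at *E* < 10), intact/fragment/pseudogene calling, locus assembly,
seed-and-extend repeat detection, telomere and rDNA detectors, allelism
tests for diploid assemblies, and coverage-based inference of
assembler-collapsed repeat contigs. The phylogenetic stage reconstructs
ancestral systems by parsimony (Fitch sets / Sankoff DP), enumerates all
most-parsimonious reconstructions, resolves ties by explicit policies,
and counts transitions between systems (e.g. heterothallism →
homothallism) and independent origins of mating-type switching
(entries into {FF1, FF2, 3LOC}).

## Worked example

Generate a flip/flop genome with a planted IR, classify it, then place a
small set of species on a tree:

```r
library(matsys)

g  <- generate_genome("FF1", seed = 1)
cl <- classify_assembly(g$assembly)
print(cl)
#> <mating_system_call> FF1 (ploidy: unknown)
#>   evidence: rule1:intact_loci=2; rule2:both_idiomorphs_present;
#>   rule3:opposite_pairs=1,allelic=0;
#>   rule4:cassettes=2(intact=2,degenerate=0,allelic_merged=0);
#>   rule5:ir_families=1(same_contig=1,cross_contig=0,coverage_links=0,artifact=0);
#>   rule5:FF1
```

The evidence trail shows the decision path: two intact opposite-idiomorph
loci, not allelic, fewer than three cassettes, and exactly one inverted
repeat family spanning them — the FF1 signature.

```r
fx  <- paper_fixtures("lipomyces")          # 9 species, tip categories
rec <- reconstruct_states(fx$tree, fx$states)
count_transitions(rec)
#> <transition_summary> 3 event(s); to homothallism: 0, to heterothallism: 1,
#> switching origins: 0
#>   from  to n
#> 1  PHC HET 1
#> 2  PHC PHN 2
```

The genus is reconstructed as ancestrally PHC with two derived
transitions to PHN and one reversal to heterothallism.

For an end-to-end run over a directory of FASTA assemblies (with optional
per-species genetic codes, manual overrides and a tree), see
`run_pipeline()`. The `analysis/` directory holds numbered driver
scripts — simulate, classify, fixture transitions, dataset summary — each
writing its tables under `results/`.

## Notes

- Internal coordinates are 0-based half-open; GFF3 output is 1-based
  inclusive.
- The bundled protein queries are toy stand-ins used by the synthetic
  genomes and tests; real analyses must supply their own query FASTA
  (`read_queries()`, header convention `name|family|source`).
- The methods vignette (`vignettes/mating-systems.Rmd`) documents the
  model, thresholds, tie-break policies, generator scope and known
  limitations.
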