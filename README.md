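# multilocus

Phylogenetics with multiple genes in R: a harmonized container for per-locus
sequence alignments, plus the handling, marker-coding, distance, tree and
incongruence tools that make analysing many loci as straightforward as one.

## The problem

Organisms are increasingly sequenced at several independent loci. Biological
processes (incomplete lineage sorting, recombination, introgression) and
statistical noise can make different genes support different trees, so loci
should first be examined and compared *separately* before being concatenated
into a supermatrix. In practice that means a lot of fragile bookkeeping:
different loci rarely cover the same individuals, files use different
formats, and every per-locus analysis must be replicated and compared.

`multilocus` puts that bookkeeping into one S4 container. When a
`MultiLocusAlignment` is built, all individuals with at least one sequence
are enumerated and sorted alphanumerically, and each locus is padded with
**gap-only sequences** (`-` over the locus width) for every missing
individual. All loci then hold the same taxa in the same order, so per-locus
distances, trees and their comparison line up for free. On top of the
container:

- **Handling** — matrix-like subsetting `x[i, j]` over individuals and loci,
  and supermatrix concatenation with recorded partition boundaries.
- **Marker coding** — SNP extraction (a column is a SNP iff it shows ≥ 2
  distinct determinate bases; gaps/`N`/ambiguity codes are missing), and
  MLST-style haplotype coding where each unique full-length sequence at a
  locus is one allele.
- **Distances** — pairwise-deletion genetic distances: for a pair of
  sequences only columns where *both* carry a determinate residue are
  compared. Models: raw mismatch count, mismatch proportion *p* (Hamming),
  Jukes–Cantor *d* = −(3/4)·ln(1 − 4p/3), and Kimura two-parameter
  *d* = −(1/2)·ln(1 − 2P − Q) − (1/4)·ln(1 − 2Q) with *P*, *Q* the transition
  and transversion proportions.
- **Trees** — neighbour-joining per locus (gap-only rows dropped first) or on
  the pooled supermatrix, with non-negative branch lengths enforced and
  ladderized output; Newick I/O; Robinson–Foulds distances on shared leaf
  sets to quantify incongruence between gene trees.
- **Simulation** — a synthetic-data generator with controlled tree,
  divergence and per-locus missingness, so the whole pipeline is testable
  without any external data.
- **CLI** — `inst/cli/multilocus.R` exposes the workflow
  (`summary`/`concat`/`snps`/`haplotypes`/`trees`/`compare`/`plot`/`simulate`)
  as a thin shell command over the same functions.

## Worked example

An 8-individual, 4-locus data set in which only 5, 6, 8 and 5 individuals
were sequenced at the four loci:

```r
library(multilocus)
x <- workedExampleFixture(1)   # or: x <- readMulti(dir(pattern = "\\.fasta$"))
x
#> === MultiLocusAlignment ===
#> [32 DNA sequences in 4 genes]
#> @n.ind: 8 individuals
#> @n.seq: 32 sequences in total
#> @n.seq.miss: 8 gap-only (missing) sequences
#> @labels: tax_01.ab1 tax_02.ab1 tax_03.ab1 tax_04.ab1 tax_05.ab1 tax_06.ab1 ...
#> @loci: patr_poat43 patr_poat47 patr_poat48 patr_poat49
```

8 individuals × 4 loci = 32 sequences, of which 8 are gap-only padding for
the individuals missing at the incomplete loci. The real per-locus coverage:

```r
getNumSequences(x)
#> patr_poat43 patr_poat47 patr_poat48 patr_poat49
#>           5           6           8           5
```

Per-locus and pooled neighbour-joining trees (Hamming *p*-distance, pairwise
deletion, branch lengths clamped at zero, ladderized), and their
incongruence:

```r
trees <- buildTrees(x)              # one tree per locus, padding rows dropped
tree  <- buildTrees(x, pool = TRUE) # single tree from the concatenated alignment
writeNewick(tree)
#> (((((tax_02.ab1:0.00631393,tax_03.ab1:0.0242819):0.0177373,...,tax_08.ab1:0.0120549);
rfTable(c(trees, list(pooled = tree)))
#>             patr_poat43 patr_poat47 patr_poat48 patr_poat49 pooled
#> patr_poat43           0           0           0          NA      0
#> patr_poat47           0           0           0           0      0
#> ...
```

Every off-diagonal entry is the Robinson–Foulds distance between two trees
over their shared leaves (0 = same topology; `NA` = fewer than 4 shared
leaves, as for the two 5-taxon loci here). This synthetic data set evolves
all loci on one tree, so the gene trees agree; on real multi-gene data
non-zero entries flag phylogenetic incongruence worth investigating before
trusting the concatenated tree.

Haplotype (MLST-style) coding gives one marker per locus; here every
sequenced individual carries a distinct allele:

```r
numAlleles(codeHaplotypes(x))
#> patr_poat43 patr_poat47 patr_poat48 patr_poat49
#>           5           6           8           5
```

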