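---
title: "Multi-gene alignment containers: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-gene alignment containers: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multilocus)
```

This vignette documents the data model behind `multilocus`, the conventions
every function relies on, and the choices we made where the design was
genuinely open. It is the reference for "why does the package behave this
way"; the README shows the workflow itself.

## The harmonization model

A multi-gene data set is a list of per-locus alignments that rarely cover
the same individuals. The container's job is to make the loci directly
comparable, and it does so at construction time:

1. every individual with at least one sequence anywhere is enumerated;
2. labels are sorted **alphanumerically** into a canonical order;
3. each locus is padded with a **gap-only sequence** (`-` repeated over the
   locus width) for every individual it lacks, and its rows are re-ordered
   to the canonical order.

After this, `n.seq = n.ind × n.loci` always holds, and
`n.seq.miss` counts the gap-only rows — padding we inserted plus any all-gap
rows that were already in the input. Harmonization is idempotent: rebuilding
a container from its own loci changes nothing, which the test suite checks
on random presence masks.

Two conventions deserve emphasis:

- **Gap-only means all `-`, nothing else.** A row of all `N` or `?` is
  ambiguous *data* (the sites exist but could not be called), not a missing
  sequence, so it is never treated as padding: it counts in
  `getNumSequences`, it is kept when trees drop the padded rows, and under
  haplotype coding it is its own allele. Gaps and ambiguity codes meet the
  same fate only in distance computation and SNP calling, where both are
  indeterminate.
- **The collation rule is plain code-point order**, case-sensitive and
  locale-independent (`sort(method = "radix")`). Natural-numeric ordering
  was the alternative (`sample2` before `sample10`); we chose code-point
  order because it is stable across platforms and locales and matches what
  R users get from character comparison. Users with numeric label suffixes
  should zero-pad.

## Handling semantics

`x[i, j]` subsets individuals and loci with integer, label or logical
selectors. Subsetting never re-harmonizes: a locus whose every remaining row
is gap-only is retained, counts are simply recomputed, and metadata tables
are sliced. Individuals always stay in canonical order — an out-of-order
`i` is normalized — because the container's invariant is that labels are
sorted; loci, by contrast, keep selector order, so `j` can reorder genes.
With these semantics the composition law
`x[i1, j1][i2, j2] = x[i1 ∩ i2, ...]` holds, which the tests exercise.

`concatenateLoci` juxtaposes each individual's rows across the selected loci
and records the partition boundaries as 1-based closed intervals
(`getPartitions`, exportable as a RAxML-style block via `partitionText`).
Gap-padded rows concatenate as-is: the supermatrix deliberately shows where
data are missing.

`compressSitePatterns` stores the distinct alignment columns with integer
weights, the classic storage trick for likelihood/parsimony machinery;
expansion reproduces the column multiset, and weights always sum to the
alignment width.

## Input and output

FASTA (via Biostrings) and **relaxed Phylip** are supported. We parse Phylip
ourselves because the fixed 10-character name field of strict Phylip is an
anachronism no modern tool emits, and the installed parsers cover only parts
of the matrix we need (nucleotide-only, or interleaved-only, and fragile on
relaxed names in the other dialect); names are whitespace-delimited, both
sequential (records may wrap) and interleaved layouts are read, and the
writer emits relaxed sequential. FASTA output wraps at 80 columns —
cosmetic. Residues are uppercased on ingest and `U` is normalized to `T`,
so RNA input is tolerated.

Alphabet auto-detection calls a file nucleotide iff at least 90% of its
non-gap, non-`?` residues are nucleotide symbols (including IUPAC ambiguity
codes); anything less falls back to amino acid, the superset alphabet, which
can represent any sequence at the cost of disabling the DNA-only analyses.
The nucleotide-only analyses (SNP extraction, JC69/K80) pass through the
explicit `ensureNucleotide` gate, which names the offending locus.

Clustal `.aln` parsing is deliberately not implemented: the format adds no
semantic coverage over FASTA/Phylip.

## Marker coding

- **Haplotype (MLST-style) coding** treats each unique full-length sequence
  at a locus as one allele. Equality is **exact string match**, internal
  gaps included: two sequences differing only by `N` versus a called base
  are different alleles. We chose exactness over similarity-collapsing
  because any threshold would be arbitrary and silently merge real
  variation; callers who want collapsing can degap or mask first. Sequences
  are haploid — one allele per individual per marker — which matches
  sequence-per-taxon data.
- **SNP extraction** calls a column polymorphic iff it shows ≥ 2 distinct
  determinate bases. IUPAC ambiguity codes are treated as missing rather
  than expanded into their possible bases: expansion would require
  fractional or multi-state calls downstream, and "missing" is the simplest
  rule that never invents a genotype.
- Allele codes are consecutive integers from 1 in order of first appearance
  over individuals in canonical order, so codings are reproducible and
  permute predictably when the label set changes. Missing is `NA`, which is
  reserved and can never collide with an allele code.

## Distances, trees, incongruence

Distances use **pairwise deletion**: each pair of sequences is compared only
at columns where both carry a determinate residue. The models are the raw
mismatch count, the mismatch proportion *p* ("Hamming distance" — we
provide both the proportion, the default, and the count, since the term is
used both ways), JC69 and K80 (formulas in the README). Two failure modes
are flagged rather than imputed:

- a pair with **zero compared sites** is *undefined*;
- a pair whose log argument is non-positive is *saturated*.

Both are stored as `NA` with a status flag (`flaggedPairs`), and
`njTree` refuses a matrix containing them. Poisoning beats silent
imputation: an imputed distance would bias the tree with no trace.

Tree building follows the standard defaults: neighbour-joining
(Saitou–Nei/Studier–Keppler, via `ape::nj`) on per-locus *p*-distances,
with each locus's gap-only padding rows dropped first (they carry no data
and are undefined against everything), negative branch lengths clamped to
zero, and ladderization for reproducible display. Clamping — rather than
redistributing the negative length onto adjacent edges — is the simplest
rule that preserves the NJ topology. For the pooled tree we keep **all**
individuals, padding included: each individual has data at some locus, and
pairwise deletion confines the comparison to those sites; users should know
that individuals sharing few loci get noisier pooled distances. A locus
with fewer than 3 data-bearing rows is skipped with a warning, not an
error, so one thin locus cannot kill a batch run. NJ ties on the join
criterion resolve to the lowest-index pair (deterministic across runs);
ladderize breaks equal clade sizes by stable original order.

Incongruence is quantified by the Robinson–Foulds symmetric difference of
non-trivial bipartitions, computed on the induced subtrees over the leaves
two trees share (per-locus trees rarely share full taxon sets); fewer than
4 shared leaves means no non-trivial split exists and the comparison errors
explicitly. Newick output carries 6 significant digits and quotes labels
containing metacharacters.

## The synthetic-data generator

`simulateContainer` evolves sequences down a given tree under equal-rate
(Jukes–Cantor) substitution over `A/C/G/T` — branch lengths rescaled so the
mean root-to-tip path equals the requested expected substitutions per site
— or draws i.i.d. uniform sites when no tree is given, writes one FASTA
file per locus honouring a per-locus presence mask, and reads the files
back through the normal import path, so every fixture also exercises I/O
and harmonization. `workedExampleFixture` reproduces the structure of a
classic study of this kind: 8 individuals, 4 nuclear loci of realistic
intron length (632/540/702/584 bp; the published counts fix only the
coverage, not the lengths), per-locus coverage 5/6/8/5 with the third locus
complete, divergence 0.05 substitutions/site — modest within-genus
divergence. Which individuals are missing at the incomplete loci is drawn
from the seed, since only the counts are structural.

What the generator emulates: per-locus taxon coverage, low-divergence
nucleotide variation, shared or absent tree signal. What it does not:
indels and alignment error (sequences are simulated aligned; gaps only ever
come from harmonization), rate heterogeneity across sites and loci,
base-composition bias, ambiguity codes from base-calling. Passing tests on
these fixtures therefore demonstrate the bookkeeping, the estimators and
the tree machinery — not robustness to misalignment or model violation on
real data.

## Numerical and scale choices

Distance transforms are evaluated in double precision directly from integer
site counts; the transition and transversion proportions are computed from
separate counts (never as a difference of proportions), which keeps the
K80 log argument exact near saturation. The test suite checks the
closed-form agreement at 1e-12 on 1000 random draws, NJ topology recovery
on 100 random additive matrices (4–8 leaves, with an exhaustive
least-squares check over all three topologies at 4 leaves), harmonization
identities on 200 random presence masks, marker coding against brute-force
scans on 500 random fixtures, and serialization round-trips on 100 seeds —
sizes at which the full suite runs in well under a minute per property
while still exercising every code path; the estimators themselves are
scale-free, so nothing about the checks depends on these sizes.

## Known limitations

- Only raw/p/JC69/K80 distances; the wider family of model corrections, and
  minimum-evolution/BIONJ/likelihood/parsimony tree methods, are out of
  scope — export distances or Newick and continue in `ape`/`phangorn`.
- No byte-packed sequence storage: plain character strings, fine for
  hundreds of taxa × loci, not for thousands of genomes.
- Heterozygous (diploid-ambiguity) genotype calls are not modelled.
- Partial metadata tables are accepted and sliced, never validated against
  an external sample sheet.
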