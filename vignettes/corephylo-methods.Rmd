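---
title: "Methods: core-genome SNP phylogenetics in corephylo"
author: "corephylo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core-genome SNP phylogenetics in corephylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`corephylo` infers strain-level phylogenies from the core genome: the set
of reference positions at which every retained sample has an unambiguous
base. The design assumptions are those of closely related microbial
genomes — divergence on the order of 0.1–5% per site, mostly colinear
genomes, and vertical inheritance dominating at core positions. Within
that regime the package is built to be *exact*: on substitution-only
divergence without repeats, the aligner recovers planted SNPs with
precision and recall 1, and neighbor joining recovers any additive
distance matrix. The test suite enforces both properties.

Every sample is reduced to a call track over the reference coordinate
system, with one state per position:

* a base `A/C/G/T` — aligned (assembly) or called under thresholds
  (reads);
* `GAP` — unaligned, deleted, repeat-masked, or below the depth floor;
* `AMBIG` — an aligned `N`, an IUPAC ambiguity code, or a covered
  position where no allele reaches the required fraction.

The allele table (tracks for all samples, plus the repeat mask) is the
single persistent structure; core computation, SNP matrices, subset
re-analysis and incremental placement are all pure functions of it, which
is why subset and placement results are bit-identical to from-scratch
runs.

# Reference selection by MinHash

Each genome is sketched as the `s` smallest distinct hash values of its
canonical k-mers (the lexicographically smaller of a k-mer and its
reverse complement in 2-bit encoding). Defaults are `k = 21`,
`s = 1000`, the community-standard sketch parameters for bacterial-scale
genomes. The hash is splitmix64 of the 2-bit packed canonical k-mer with
no seed; the sketch stores the top 53 bits of each value so hashes are
exactly representable as R doubles and sketches are reproducible across
platforms. The Jaccard index is estimated from the bottom-`s` sketch of
the union, and distance is the Mash transform
$d = -\tfrac{1}{k}\ln\tfrac{2j}{1+j}$, with $j = 0$ saturating to a
sentinel distance of 1.0 rather than infinity. The reference is the
*complete* genome minimizing the total distance to all samples; draft
assemblies and read sets contribute to the sums but are never eligible,
because downstream coordinates must come from a trustworthy single
genome. Ties break to the lexicographically smallest sample id.

# Repeat masking

Orthology breaks down inside repeats, so the reference is self-compared
before any alignment: a position is masked iff it lies in a window of
length `minRepeatLen` (default 50) whose canonical k-mer occurs at least
twice in the genome (forward occurrences of the k-mer or its reverse
complement, across all contigs). This is equivalent to masking every
position covered by an off-diagonal exact self-match of length at least
`minRepeatLen` on either strand, and it masks both copies. Masked
positions are forced to `GAP` in every sample's track, so they can never
contribute SNPs or core columns.

# Pairwise whole-genome alignment

Assemblies are aligned to the reference per (reference contig, query
contig, strand) group:

1. **Anchors.** Maximal unique matches (exact matches occurring once in
   each sequence per strand, extendable in neither direction,
   length ≥ `minAnchorLen` = 20) are enumerated with a suffix array and
   LCP scan; `N` never matches.
2. **Chaining.** The maximum-weight strictly colinear chain (weight =
   anchored bases, overlaps charged to the later anchor) is kept per
   group; anchors off the chain are dropped. Ties resolve to the earliest
   ref-start sequence.
3. **Fill.** Inter-anchor segment pairs with both sides ≤ `maxFill`
   (default 10 kb) are aligned with banded affine-gap global alignment
   (match +1, mismatch −3, gap open −5, gap extend −2; opening a gap
   costs open + extend; band = length difference + 50). Larger segment
   pairs split the chain and the intervening reference interval stays
   unaligned. Chains are also extended to the sequence ends when both
   flanks are small (≤ 50 bp) or align at ≥ 70% identity — the guard
   keeps unrelated contig flanks from fabricating SNPs.

Conflicting claims on a reference position (multiple chains, both
strands, repeated query contigs) resolve in favor of the higher-weight
chain, applied position-by-position when tracks are painted. A
substitution becomes a SNP only when both bases are `A/C/G/T` and the
position is unmasked. Deletions in the query mark their reference
positions `GAP`, implementing removal of unaligned segments of any
length; insertions have no reference-space footprint and are dropped (the
core-SNP model is substitution-only). Query bases are always reported
reference-forward.

# Read mapping and consensus

The built-in mapper is seed-and-extend with a unique-best contract:
15-mer seeds (seeds above 64 reference hits are skipped as repetitive)
vote for diagonals on both strands; candidate loci are scored by banded
semi-global extension; a read is unmapped when its best score ties across
two distinct loci or its identity over the aligned span is below 0.85.
Dropping ties instead of picking randomly prevents repeat-driven false
SNPs, consistent with the repeat-masking intent. Mates of a pair are
mapped independently — consensus calling needs coverage, not fragment
inference.

Pileup columns count read bases at match/substitution columns; read
deletions consume reference without contributing (they only reduce
effective depth) and never produce consensus indel calls. The consensus
rule is: call base *b* iff depth ≥ `min_depth` (default 5) and
count(*b*)/depth ≥ `min_allele_fraction` (default 0.6); `AMBIG` when
covered but no allele qualifies; `GAP` below the depth floor. The 0.6
fraction is the standard reported-SNP threshold for this workflow; it
exceeds 0.5 so at most one allele can ever qualify, and a 5/9 majority
(0.556) is deliberately ambiguous. Raising either threshold can only
downgrade calls, never upgrade them — a property test.

# Core genome, matrices, distances, trees

Core columns are positions where every subset sample's call is a base;
ambiguity excludes a position exactly like a gap, protecting SNP-column
purity (the choice is deliberate: an under-supported call must not
silently become reference). SNP columns are core columns with ≥ 2
distinct bases. Monomorphic columns are retained in the core alignment,
and distances are computed over the *full* core (differing columns /
core length, optionally Jukes-Cantor corrected,
$d = -\tfrac34\ln(1-\tfrac43 p)$, saturating at `p ≥ 3/4` with a capped,
flagged value), so branch lengths are substitutions per site and
comparable across runs. Pairwise SNP matrices count differing core
columns overall and restricted to CDS/intergenic labels from the
reference annotation; the two partitions sum to the total when the
annotation covers the genome.

Trees come from Saitou-Nei neighbor joining with the standard
Q-criterion; ties break to the smallest index pair in the current
working order, so output is deterministic; negative branch estimates are
clamped to zero with a message. Bootstrap supports resample full-core
columns with replacement and report the percentage of replicate trees
containing each internal bipartition. NJ was chosen as the built-in
engine because it is fully specifiable, exact on additive inputs, and
statistically consistent in the closely related regime this tool
targets; maximum-likelihood programs remain usable through the
relaxed-PHYLIP/FASTA core exports (`tree = external` in the control
file).

# Annotation and the selection screen

SNPs inside CDS features get codon context on the coding strand
(reverse-complementing for minus-strand genes; overlapping genes yield
one annotation per gene, and an effect may differ between frames). Gene
eligibility for the selection screen follows the gap-free rule: every
sample unambiguous across the gene, at least one SNP inside it. Eligible
gene sequences are positionally extracted from the allele table, which
for gap-free genes is equivalent to a per-gene realignment.

The screen is the Nei-Gojobori (1986) counting method: per-codon
synonymous site counts by fractional weighting of all nine single-base
mutations (mutations to stop codons count as nonsynonymous), differences
averaged over all minimal mutational pathways with equal weighting,
Jukes-Cantor correction of the proportions, and a two-sided normal test
of pN − pS with binomial variances. Gene-level aggregation is the mean of
pairwise dN and dS over all sample pairs with ω the ratio of means —
symmetric in samples and robust to reference choice. p-values are
Benjamini-Hochberg corrected across genes (α = 0.05): positive requires
ω > 1 *and* q ≤ α; purifying ω < 1 and q ≤ α; otherwise neutral;
ω undefined (dS = 0 or saturated) is undetermined. Branch-site and
codon-model likelihood methods are out of scope; per-gene FASTA exports
are provided for external tools. A substitution that creates an internal
stop codon renders the gene `stop_codon`/undetermined rather than
failing the run.

# The simulator and what passing tests mean

The generator draws an i.i.d. root genome at a configurable GC content
(default 0.5), overwrites synthetic gene intervals with open reading
frames (ATG … TAA, no internal stops, frame 0, alternating strands,
tiling ~60% of the genome by default) so the selection screen operates on
translatable genes, then evolves the root along each branch under strict
Jukes-Cantor substitution: Poisson event counts, uniform positions,
uniform alternative bases. Defaults describe a small bacterial clade:
five taxa, 100 kb, 0.5% expected substitutions per site on every branch.
Planted truth is computed from the final sequences, so multiple hits and
reversions collapse to net differences. Optional indels are applied to
leaves in root coordinates after evolution (keeping the truth in one
frame); optional repeats are copied into the root before evolution.
Reads are uniform-start, both strands, constant-Q30 placeholders with a
uniform substitution error model; metagenome mixtures draw source counts
multinomially.

What the simulator does *not* emulate — rate heterogeneity, transition
bias, recombination, mobile elements, GC-biased coverage, quality-varying
errors, indel-rich long reads — bounds what a passing suite shows: the
pipeline is exact under its own model assumptions, not that it is robust
to every real-data pathology. The recombination and phage caveats that
apply to all core-SNP phylogenies apply here unchanged.

# Numerical and design choices

* Coordinates are 0-based half-open internally; every emitted report is
  1-based inclusive.
* The aligner's end-extension accepts a flank only when both sides are
  ≤ 50 bp or identity ≥ 0.7, so a terminal substitution is still
  recovered but unrelated flanks never align.
* The MinHash hash stores 53 of 64 bits; the collision probability at
  sketch scale (~10⁻⁶) is negligible and cannot affect the bottom-s
  ordering contract.
* Percentages in run reports are rounded half-up to one decimal; zero
  denominators report NA.
* Control-file keys are this package's own documented dialect
  (`reference`, `min_depth`, `min_allele_fraction`, `bootstrap`, `seed`,
  `genome/contig/reads` sample declarations, …); unknown keys warn and
  are ignored, out-of-range values are errors.
* Workflow stages cache their results with a JSON manifest; a completed
  stage is loaded, not recomputed, unless forced. Per-sample work merges
  in declared sample order, so concurrency can never change outputs.
* Problem sizes in the test suite were chosen to exercise the asymptotic
  behavior while staying desk-scale: the main study-condition clade is
  five taxa at 200 kb and 0.5% divergence, topology recovery uses ten
  eight-taxon clades at 20 kb, sister placement uses 100 kb with 100
  bootstrap replicates, and the metagenome scenario mixes 10% target
  reads with 90% random background at 30-50 kb.

# Known limitations

* Rearrangements are handled only as per-strand chain competition; an
  inversion's interior aligns on the minus strand but its breakpoints
  become gaps, and duplicated query segments map to a single reference
  locus.
* All-vs-all genome comparison (beyond reference-anchored alignment) is
  out of scope, as are soft-core definitions below 100% sample presence.
* The internal NJ engine does not model rate variation across sites; for
  publication-grade trees on deep divergences, export the core alignment
  and use an external maximum-likelihood program.
* dN/dS by counting is a screen, not a branch-site test; genes it flags
  deserve follow-up with likelihood methods on the exported alignments.
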