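---
title: "Models and methods behind mitocomparator"
author: "mitocomparator authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitocomparator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomparator)
```

# Scope and data model

`mitocomparator` reimplements, as a library, the analysis chain used to
characterise the mitochondrial genome of the calanoid copepod *Calanus
sinicus* and its intraspecific variation: annotation bookkeeping,
composition/skew profiling, divergence and dN/dS, gene-order
rearrangement metrics, phylogenomic dataset construction and a
polymorphism scan. Four S4 containers carry the data:

* `MitoFeatureTable` — an ordered annotation of one mitogenome.
  Coordinates are 1-based inclusive on the reference (heavy, H) strand
  throughout; conversion to other conventions happens only at I/O.
  Strands are `H`/`L` as defined by molecular weight (`+`/`-` accepted on
  input). The packaged *C. sinicus* table is a linear molecule: the
  sequenced contig misses the ends of its largest non-coding region, so
  the wrap-around spacer is reported with an `open` flag and is a lower
  bound, never a plain integer.
* `HaplotypeAlignment` — a rectangular intraspecific alignment whose
  optional annotation maps feature coordinates onto alignment columns
  (the reference haplotype is ungapped).
* `SignedGeneOrder` — a circular or linear permutation of oriented genes.
* `ConcatDataset` — a concatenated amino-acid supermatrix with per-gene
  partitions and optional 0–9 column-confidence scores.

# Annotation arithmetic

For consecutive features, `spacer = start(next) − end(prev) − 1`;
negative values are overlaps. Spacers above a threshold (default 100 nt,
configurable) are labelled long non-coding regions (LNRs) in genome
order, the wrap record first because it occupies the molecule head.
`validateFeatureTable()` audits declared lengths and spacers against the
coordinates and reports every inconsistency instead of failing: on the
packaged table it flags the two rRNA-adjacent spacers (the rRNA
boundaries were estimated by cross-species alignment, and the printed
values disagree with the printed coordinates by 3 nt) and, on request,
the prose claim of a 762 nt spacer upstream of *nad4* versus the 771 nt
the coordinates imply. The validator flags; it does not resolve.

# Composition and skew

AT-skew = (A−T)/(A+T) and GC-skew = (G−C)/(G+C). A zero denominator
makes a skew undefined; it is reported as `NA` with an explicit flag,
never as 0. Ambiguity codes are excluded from all denominators and their
count is reported. Per-gene profiles are computed on the sense (reading)
strand — light-strand features are reverse-complemented first — which is
what makes the uniform anti-A skew of the protein-coding genes visible
regardless of coding strand. Codon-position partitions ({1+2} vs {3})
cover complete codons only; the 1–2 nt of a truncated terminal stop are
excluded.

`skewFromComposition(..., asPercent = TRUE)` takes printed percentages at
face value (they are independently rounded and may sum slightly off
100), so the published whole-genome composition A 32.1 / C 19.1 /
G 19.3 / T 29.6 reproduces A+T = 61.7% exactly and yields skew
magnitudes 0.0405 (AT) and 0.00521 (GC). Note the published prose
attaches 0.00521 to the AT-skew; the printed composition implies the
opposite assignment, and this package always computes from composition.

# Genetic code and coding-sequence conventions

The invertebrate mitochondrial code (translation table 5, Biostrings
`"SGC4"`) is used throughout: ATA = Met, TGA = Trp, AGA/AGG = Ser,
stops TAA/TAG. Start codons come from ATD = {ATA, ATT, ATG}. Genes whose
length is not a multiple of three end in a truncated stop (`TA`/`T`),
completed to TAA by post-transcriptional polyadenylation; translation
drops the incomplete codon when the truncated flag is set.

Where several in-frame ATD candidates surround an annotated 5' boundary
(searched ±9 nt, a window chosen to keep candidate sets small and
deterministic), the start is the candidate that minimises overlap with
the upstream feature, ties broken by the most conserved gene length
(candidate closest to the annotated boundary) and then by the longer
reading frame. A pure longest-ORF tie-break was rejected during
development: with no overlap pressure it extends genes onto accidental
ATD triplets in intergenic sequence, contradicting the annotated starts
it is meant to recover. Mutations to or from stop codons are counted
nonsynonymous everywhere (an explicit policy; sources are usually silent
on it).

# Divergence and dN/dS

`pairwiseDivergence()` is the uncorrected p-distance with pairwise
deletion. The group summary (`groupDivergenceSummary()`) reports DW (mean
within-group nucleotide p-distance), DB (mean between-group divergence —
amino acids for protein-coding genes, nucleotides for structural RNAs, so
rRNA rows remain meaningful next to protein comparisons), and pooled
Nei–Gojobori ω for the within/between pair sets. Whether the original
distances carried a multiple-hit correction is not stated in the source
material; plain proportions were chosen and the choice is documented so
corrected variants can be added. Undefined cells (single-member groups,
RNA ω, dS = 0) are explicit `NA` flags, never zeros.

`ng86()` follows Nei & Gojobori (1986): per-codon synonymous-site
fractions averaged over both sequences; observed differences in
multiply-hit codons averaged over all orderings of the single-base steps
with equal weight; Jukes–Cantor correction `d = −3/4 log(1 − 4p/3)`,
undefined (flagged) at p ≥ 3/4. Codons containing gaps or ambiguity are
dropped pairwise. The counting is validated in the test suite against an
independent pathway-enumeration oracle and is exactly symmetric in its
arguments.

# Gene order

Adjacencies are unordered neighbour pairs on the circle (wrap pair
included for circular molecules). The inversion census anchors both
orders on a shared gene in + orientation (reflecting and sign-flipping
one order if needed) and counts orientation mismatches. The arthropod
ground pattern (the *Limulus* arrangement) ships as a built-in signed
order. On the packaged *C. sinicus* table the mechanical census finds
five retained boundaries — the well-known *atp6–atp8* and *nad6–cytb*
pairs plus three tRNA-involving boundaries (*rrnL–trnV*, *nad5–trnH*,
*trnN–trnS1*) that are genuinely adjacent in both arrangements — and 14
inverted genes. Published summaries of the same comparison quote smaller
counts (two boundaries, 12 inversions) without an extractable counting
rule; this package reports what the coordinates imply.

Common intervals are unsigned gene sets of size 2…n−1 contiguous in both
orders. Orders are linearised at a shared anchor (cox1 in + orientation
by default); whether intervals may span the linearisation cut is a
toggle (`circular =`), off by default since published pairwise counts go
as low as 0. The O(n²–n³) scan is the reference implementation — mitogenome
orders have n ≤ 40, so no optimised algorithm is warranted — and the test
suite checks it against an exhaustive 2^n-subset oracle.

# Population scan

A column is variable iff it shows ≥ 2 states, a gap counting as a state;
gap-bearing columns are indel sites, the rest substitutions.
Transition/transversion is tallied per distinct unordered state pair, so
multi-allelic columns contribute more than one pair; the per-site
`transition` flag is defined only for biallelic columns.
Parsimony-informative means ≥ 2 states each carried by ≥ 2 haplotypes.
Synonymous/nonsynonymous classification uses the observed haplotype
codons (never hypothetical mutants): a site is synonymous iff all
observed codons translate identically; sites under overlapping
annotations resolve to the protein-coding gene. Consecutive gap columns
are counted per column (each gap column is one indel site); run-level
event counting is derivable from the site table.

The sliding window (defaults 200 columns, step 2, trailing partial
window dropped) reports variable-column fractions;
`mean_frequency × alignment length` equals the total variable-site count
exactly. Hotspots are an operational definition of this package —
windows strictly above a frequency quantile (default 0.95), merged when
overlapping, ranked by bases-per-variable-site — because published
hotspot lists name regions without stating a rule; reports carry the
parameters. Note that a frequency plateau wider than the quantile tail
leaves nothing strictly above the cut, which is intended behaviour for
uniformly variable data.

Microsatellites are maximal perfect tandem repeats (motif length 1–6;
minimum repeat numbers 8/5/4/3/3/3 by motif length; motifs that are
powers of a shorter unit are rejected). Hits are mapped back to
alignment columns, merged across haplotypes by span overlap, and alleles
are the distinct full locus strings, capturing repeat-number and
internal variation. Control-region motifs: poly-T runs ≥ 8 nt and
hairpins, defined as inverted repeats with a Watson–Crick-only stem
≥ 8 bp and a 3–30 nt loop, found by extending every candidate innermost
pair outward (so every reported stem is maximal).

# Phylogenomic dataset construction

Column-confidence masking keeps columns with score strictly above 5 on
the 0–9 integer scale ("above five" read literally; the threshold is a
parameter because the scale statement in the source is terse). *atp8* is
excluded by default, the usual practice when it is missing from sampled
taxa. The strand-bias rule is this package's concrete rendering of a
one-line criterion: per gene and taxon, a two-sided exact binomial test
of G vs C at fourfold-degenerate third positions; a gene is excluded
when p < α (default 0.05) in more than half the testable taxa, and the
per-gene decision table makes the rule auditable. Genes without
degenerate sites are flagged and retained.

The slow–fast filter needs user-declared groups (the method requires
predefined monophyletic groups; the original grouping is not recoverable,
so none is hard-coded). The site rate is the summed within-group count
of distinct non-gap states minus one — a parsimony-step lower bound.
Sites are ranked into four equal-count quartiles and only the internal
two are retained; ties at either boundary are resolved towards inclusion
(every site sharing a boundary rate is kept), which is deterministic and
retains 40–60% of continuously-rated sites, exactly half when ranks are
untied. Compositional PCA is centred, unscaled `prcomp` on the four base
proportions, intended for taxon-sampling diagnostics, not inference.

# Synthetic data: what it emulates and what it does not

The generators are pure functions of (config, seed) on R's
Mersenne–Twister stream, so outputs are bit-reproducible across
platforms. Counts are *placed*, not drawn: the population generator
creates exactly `n_substitutions` biallelic substitution columns (the
first `round(0.87 × n)` transitions), exactly `n_indel_columns`
gap-bearing columns confined to non-coding regions (no indels ever fall
in coding sequence), and microsatellite loci with programmed
per-haplotype repeat numbers, insulated by guard bases so flanking
sequence cannot extend a programmed repeat. Recovery tests are therefore
exact, not statistical. Defaults mirror the study system: a 20,460 nt
35-feature template with the published coordinates and codons, target
composition A 0.321 / C 0.191 / G 0.193 / T 0.296, 11 haplotypes,
191 substitutions, 104 indel columns, transition fraction 0.87, and
three microsatellite loci carrying 7 distinct alleles in total. A repair
pass flips non-coding positions after CDS placement so the realised
genome-wide composition matches the target to rounding (stop-codon
rejection in coding bodies would otherwise bias it by ~0.5%).

What passing these tests shows is that the *bookkeeping and estimators*
are correct; the synthetic data deliberately omit features of real
mitogenomes — phylogenetic autocorrelation among haplotypes, rate
heterogeneity along the molecule, imperfect and interrupted repeats,
sequencing error — so they say nothing about robustness to those.

The codon-pair generator applies `round(0.15 × codons)` single-base
changes (at most one per codon) accepted so the realised
nonsynonymous:synonymous split matches the target ω against the
ancestor's NG86 site opportunities. NG86 re-estimates recover ω within a
few percent at these divergences (integer rounding of the quota and the
Jukes–Cantor correction account for the residual bias); the acceptance
suite runs 200 replicates per ω ∈ {0.05, 0.2, 1.0} at 300 codons, which
keeps the whole recovery check under ~5 s.

# Orchestration and reproducibility

`runReport()` chains the stages over one configuration (an R list or a
YAML file; unknown keys are rejected) and writes plain TSV tables, each
stamped with a parameter-provenance comment header and free of
timestamps, so re-running an identical configuration is byte-identical.
Any stage failure propagates with the stage name. The package's users
drive it from R, so the command-line surface is the function API plus
`scripts/acceptance.R`; a shell wrapper would add nothing over
`Rscript -e`.

Problem sizes used by the default test and acceptance runs — a single
20 kb genome, one 11 × 20,460 alignment scan, 200 oracle permutation
pairs at n ≤ 8, 100–200 NG86 pairs per setting — were chosen so the
whole suite completes in well under a minute on one core while leaving
every estimator's behaviour visible.

# Known limitations

* tRNA/rRNA structure prediction, alignment computation, tree inference
  and rearrangement-scenario reconstruction are out of scope; alignments
  and gene orders are consumed, not produced.
* DB/DW are uncorrected proportions; saturated comparisons understate
  divergence.
* The hairpin scan is Watson–Crick only (no GU) and ignores
  thermodynamics; it is a motif screen, not a folding prediction.
* The hotspot rule and the strand-bias test are this package's
  operational definitions, parameterised and reported rather than
  inferred from data.
* The GenBank reader covers the common single-span feature dialect
  (plain and `complement()` locations); joins across the origin are not
  parsed.
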