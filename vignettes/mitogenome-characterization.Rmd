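---
title: "Characterizing circular mitochondrial genomes with mitocharr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing circular mitochondrial genomes with mitocharr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocharr)
```

## The problem

Animal mitochondrial genomes are small circular molecules (~15 kb in
Lepidoptera) carrying a nearly fixed complement of 37 genes — 13
protein-coding genes (PCGs), 22 tRNAs, 2 rRNAs — plus one non-coding
control region that in moths and butterflies is so A+T-biased it is
simply called the A+T-rich region. A mitogenome "characterization"
paper reports a standard battery of statistics: per-region base
composition and strand skews, codon usage and relative synonymous
codon usage (RSCU), start/stop-codon classes, the ledger of gene
overlaps and intergenic spacers on the circle, conserved motifs in the
control region, the gene order relative to the ancestral insect
arrangement, and a phylogeny from the concatenated PCGs.

`mitocharr` implements that battery as a reusable, tested pipeline. It
is deliberately built to run at desk scale: published annotation
tables are first-class inputs (*table-only mode*), and a seeded
synthetic-genome generator stands in for sequences that papers ship
only as supplementary files.

## Statistics and conventions

**Skews.** For a sequence with base counts $A, T, G, C$:

$$\mathrm{AT\ skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\ skew} = \frac{G - C}{G + C}.$$

Both are scale-free, so they can be computed from printed percentages
as well as raw counts. Percentages are taken over unambiguous (ACGT)
bases only — published A%+C%+G%+T% sums imply that denominator — with
ambiguity codes counted separately. Rounding (2 d.p. for percentages,
3 d.p. for skews) happens only in the report layer; internal values
keep full precision.

**Per-class panels.** Class compositions (PCG, tRNA, rRNA, A+T-rich
region) are computed over the concatenated *F-strand* slices of all
features of the class, regardless of each gene's own strand, and
overlapping coverage is counted once per feature. This matches the
convention under which published per-class length sums are additive.

**Translation.** The invertebrate mitochondrial code (NCBI table 5:
AGA/AGG = Ser, ATA = Met, TGA = Trp; stops TAA/TAG) is used
throughout. A PCG may end in an incomplete codon — a bare `T` or `TA`
— completed to a functional TAA stop by polyadenylation of the
transcript; `translate_mt(complete_stop = TRUE)` models this by
A-completion. The problematic cox1 initiator is counted as annotated
(class `nonstandard`) and never "corrected".

**Codon usage.** Usage is reported as codons per thousand codons
(CDspT) and as RSCU, $\mathrm{RSCU}(c) = n_c \cdot k / \sum_{c' \in
F} n_{c'}$ for a codon $c$ in a synonymous family $F$ of size $k$.
Terminal stop codons and incomplete termini are excluded from the
denominators (the published usage figures carry no stop family; the
source never states whether incomplete termini were counted — we
exclude them and say so). Leucine and serine are split into the
two-tRNA families used in mitogenome work: Leu1 = CUN, Leu2 = UUR,
Ser1 = AGN, Ser2 = UCN. This split is a documented choice — the
underlying papers use the names without defining them.

**Topology.** For adjacent genes the gap is
$\mathrm{start}_{down} - \mathrm{end}_{up} - 1$: negative = overlap,
positive = spacer, zero = abutting. Coordinates mode computes gaps
modulo the circular length and includes the closing pair (control
region → first tRNA); printed mode copies the published intergenic
column verbatim, which has no closing entry — that is exactly why a
published "12 spacers" summary is reproducible only in printed mode.
Published tables are not always self-consistent: `consistency_report()`
lists every row whose printed size or intergenic value disagrees with
its own coordinates, and nothing is ever silently corrected. On the
shipped fixture that report has six rows, including two (cox3 size,
trnW gap) beyond the ones the source itself discusses.

**Control region scanning.** Only *perfect* repeats are detected:
maximal runs of period $u$ whose starting unit is primitive, with
possibly fractional copy numbers for a partial final unit and units
canonicalized to their least rotation. Alignment-scored imperfect
repeats (tandem repeats finder style) are a documented non-goal. The
ATAGA/poly-T element detector takes the motif, a 0–2 bp offset and a
minimum run length (default 10 bp; the published instance is 17 bp) as
configuration, not constants. One caption in the source says "ATATG"
where the text says "ATAGA"; the default is ATAGA with a config
override.

**Phylogeny.** The published ML/BI analyses are not reimplemented.
The package's claim is topology recovery with an implemented distance
method: concatenation of the 13 PCGs (in genome order — the source
does not state its order), p or Kimura two-parameter distances with
pairwise deletion of gapped/ambiguous columns, canonical Saitou–Nei
neighbor joining with exact ties broken by the lexicographically
smallest cluster-label pair (so results are deterministic), negative
branch lengths clamped to zero with the deficit moved to the sibling
edge, and column-bootstrap support counted over internal bipartitions.
A distance method cannot arbitrate the ML-vs-BI disagreement the
source reports about Bombycoidea's sister group; that question is out
of scope by construction.

## The synthetic world

`genome_spec()` states the world the generator emulates, and its
defaults are fixed, not tuned: a circular genome in the lepidopteran
trnM–trnI–trnQ gene order with near-published feature lengths and
gaps; whole-genome A+T 80.29%, AT skew 0.017, GC skew −0.231; ATN
starts plus a CGA cox1; incomplete-T stops at cox1, cox2, nad5, nad4;
a 7 bp ATGATAA junction across the atp8/atp6 overlap; ATACTAA inside
the trnS2–nad1 spacer; and a 351 bp A+T-rich region with ATAGA + 17 bp
poly-T, (AT)₉ and a 12 bp poly-A. PCG lengths are adjusted to the
nearest value compatible with their stop type (complete stops need
length ≡ 0 mod 3, incomplete T needs ≡ 1), so the synthetic genome is
15,238 bp rather than 15,247.

Implementation choices worth knowing:

* Background bases come from the closed-form inversion
  $p_A = \mathrm{AT}(1 + \mathrm{skew}_{AT})/2$ (etc.). PCG codons are
  sampled proportionally to per-position base probabilities with stops
  excluded; because the excluded stops are A+T-rich, the naive weights
  depress realized A+T by ~0.8 points, so the per-position
  probabilities are recalibrated by iterative proportional fitting
  until the expected codon composition matches the target. R-strand
  genes are sampled from the complemented probabilities so that
  F-strand skew targets survive reverse complementation.
* Planted elements are written with guard bases (a non-T after the
  poly-T, C's around the (AT)ₙ array, T's around the poly-A) so each
  planted repeat is *maximal* and recovered at exact coordinates, and
  a deterministic scrub pass removes accidental look-alikes (extra
  ATAGA copies, ≥10 bp A/T runs, ≥9-copy AT arrays) from the scanned
  non-coding regions. A repair pass removes any internal stop codons
  that motif overwriting created, never touching forced positions.
* Clade simulation evolves sites independently under K2P (default
  transition/transversion ratio 2, a typical mitochondrial order of
  magnitude) down a stated tree, with no indel process — that keeps
  the supermatrix preconditions satisfiable without implementing
  alignment. The default tree is six taxa in three cherries with
  0.05-substitution internal edges over 13 × 240 bp genes.

What a green test therefore establishes: the scanners recover exactly
what the generator planted, compositions meet their targets within
binomial noise, and NJ recovers generating topologies at the stated
divergences. What it does not establish: behavior on real lepidopteran
sequence — real control regions have imperfect repeats, real PCGs have
selection-driven codon bias, and real alignments have indels.

## Numerical and degenerate-input choices

* Exact Q-criterion ties in NJ (e.g. an equidistant star) resolve by
  label order; bootstrap replicates whose resampled distances saturate
  K2P are skipped (they count as not containing any bipartition).
* K2P is undefined when $1 - 2P - Q \le 0$; this is an error naming
  the pair, not an NA.
* Empty sequences, all-ambiguous sequences, classes with no features,
  non-overlapping pairs passed to `motif_at_overlap()`, and table-only
  genomes reaching sequence-requiring stages are all hard errors; the
  pipeline records the failing stage and marks its MANIFEST
  incomplete.
* Genome length in table-only mode is the maximum coordinate over
  records (start or end), so a feature wrapping the origin is
  representable.

## Known limitations

Annotation is an input, never inferred (the source annotated by
homology); GenBank support covers the minimal organelle dialect the
package itself writes; only perfect repeats are found; bootstrap
support is for the implemented NJ, not for the published ML/BI trees;
and the published between-superfamily relationships are reproducible only if users
supply the corresponding accessions, which the tests deliberately do
not require.
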