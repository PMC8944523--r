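---
title: "Methods and design choices in genefamkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in genefamkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`genefamkit` re-implements, as tested library code, the desk analysis used
to characterize plant gene families such as the soybean superoxide
dismutases and glutathione peroxidases: identify the members, describe the
proteins, reconstruct their phylogeny, inspect gene structure and
promoters, classify duplicates and the selective regime acting on them,
and summarize expression. This vignette records the models behind each
stage, the parameters that matter, and the choices we made where the
methodology is genuinely open.

## Family identification

A locus enters the analysis through three filters: (1) the longest
transcript (by CDS length) represents each locus, with ties broken by the
lexicographically smallest transcript id so the choice is reproducible;
(2) CDS shorter than 150 bp are eliminated (the boundary is inclusive: a
150 bp CDS survives); (3) genes with truncated proteins or an incomplete
family domain are discarded. The three filters commute, so their order
does not affect the surviving set.

"Truncated" is operationalized as: the CDS has no terminal stop codon, or
an internal stop, or the protein carries less than a completeness fraction
(default 0.8) of the domain model. The domain itself is scored with an
ungapped position-specific scoring matrix — by default built from an
amino-acid consensus with +2 match / −1 mismatch and a threshold of one
point per model position, i.e. half the consensus maximum. A profile-HMM
scanner would be more sensitive on remote homologs, but the nomination
criterion here is a completeness predicate on a known family signature,
for which an ungapped PSSM is sufficient and has an analyzable false
positive rate; externally produced domain hits can be imported through
`import_domain_hits()` when profile-HMM calls are preferred.

Accepted members are named `<prefix><family><chromosome>.<ordinal>`, the
ordinal counting genes of the family along each chromosome by ascending
start coordinate. Sequence names that are not recognizably numbered
chromosomes (scaffolds, contigs) are pooled under the pseudo-chromosome
"U", since published naming schemes do not cover unplaced genes.

## Protein properties

Molecular weight is the sum of average residue masses plus one water
(reported in kDa); `X` contributes the mean residue mass. The isoelectric
point is the root of the Henderson–Hasselbalch net charge over the
N-terminus, C-terminus and D/E/C/Y/H/K/R side chains, found by bisection
on [0, 14] to 10⁻⁴ pH units — the charge is strictly decreasing in pH so
the root is unique. The pKa table is an EMBOSS-style set shipped as a
constant and swappable per call; published tools differ by a few tenths of
a pH unit depending on their pKa sets, so our tests assert internal
consistency (zero charge at the returned pH, compositional monotonicity)
rather than third-party equality.

## Phylogenetics

Pairwise identity is computed from Needleman–Wunsch global alignments with
affine gaps (BLOSUM62, gap open 10, extension 0.5 by default; the matrix
and penalties are arguments). Identity is matches over all alignment
columns, gap columns included in the denominator. Sequences whose best
identity to any other candidate falls below 50% are removed before tree
building; we read the published "< 50% identity filtered out" rule as
max-identity-to-any-other because no reference sequence is named, which
keeps the operation symmetric and total (singletons are retained).

The multiple alignment is a deterministic progressive procedure: a UPGMA
guide tree on identity distances fixes the addition order, and each
sequence is aligned to the consensus of the running profile, with profile
gaps propagated to all rows (once a gap, always a gap). This is not
profile–profile dynamic programming; for the high-identity sets that
survive the 50% filter the difference is immaterial, and externally
computed alignments can be supplied wherever an MSA is accepted.

Distances are Poisson-corrected amino-acid distances d = −ln(1 − p), with
p the mismatch proportion over columns where neither row is gapped
(pairwise deletion; the gap treatment is a choice, as published methods
sections rarely state it). Trees are built with Saitou–Nei neighbor
joining: the pair minimizing the Q-criterion is joined at each step, ties
broken by the lexicographically smallest pair of cluster names; negative
branch lengths are clamped to zero with the deficit transferred to the
sibling edge so path lengths are preserved. On additive distances the
implementation recovers the generating tree exactly (tested against
path-length oracles up to 8 taxa). Bootstrap support resamples alignment
columns with replacement (default 1000 replicates, seeded), rebuilds the
NJ tree, and reports the percentage of replicates containing each
bipartition of the original tree.

## Gene structure and promoters

Structure summaries decompose the chosen transcript into 5'→3' UTR/CDS
segments with introns as inter-exon gaps, in gene-local coordinates.
Externally everything is GFF3 (1-based inclusive); positions reported to
users are always 1-based.

The promoter is the 2000 bp immediately 5' of the first CDS base (not the
transcription start), reported on the coding strand; windows cut by a
chromosome end are truncated with a warning. The cis-element dictionary is
an editable TSV of IUPAC consensi seeded with commonly reported
stress/hormone/light elements; it is deliberately not a verbatim copy of
any online database, so exact hit parity with web scanners is not a goal.
Both strands are scanned by default (a flag restricts to the forward
strand, since published scans often leave strandedness unstated);
reverse-complement twins such as TGACG-motif/CGTCA-motif are kept as
distinct entries, mirroring how such scans are usually reported. All
overlapping matches are reported, and the gene × element count matrix
supports the "total greater than 15" column filter used in family-scale
overviews.

## Duplication and molecular evolution

Candidate duplicates are unordered member pairs with global-alignment
protein identity strictly above 90%. A pair is tandem iff both genes lie
on one chromosome with at most 5 annotated genes between them in gene
order, otherwise segmental (including all cross-chromosome pairs);
unplaced members classify as "unknown".

Ka and Ks are estimated with Nei–Gojobori (1986) counting on a
protein-guided codon alignment (gapped codon columns excluded): potential
synonymous sites are each position's synonymous fraction among the three
alternative nucleotides, averaged over the two sequences, with changes to
stop codons counted as nonsynonymous; observed differences are averaged
over all minimal mutational pathways with equal weights, excluding
pathways through stop codons (if every pathway is blocked the stop steps
are counted as nonsynonymous rather than failing). Proportions are
corrected with Jukes–Cantor, d = −(3/4)·ln(1 − (4/3)p), which is
undefined at p ≥ 3/4 and raises an explicit error there. The
implementation is verified exhaustively against an independent
pathway-enumeration oracle over every sense-codon pair with ≤ 2
differences.

Selection classes use a neutral band on Ka/Ks of [0.95, 1.05] (exposed in
the API): below purifying, inside neutral, above positive. The band is the
narrowest symmetric interval that reproduces every label in the published
soybean SOD/GPX duplicate table from its printed ratios, including 0.941
(purifying), 0.970 (neutral) and 1.051 (positive). Ks = 0 with Ka > 0
leaves the ratio undefined; such pairs are reported as purifying and
flagged degenerate — with no synonymous change observed the ratio carries
no positive-selection signal — matching how the published table labels its
Ks = 0 row. Divergence times are T = Ks/(2λ) with λ = 6.1×10⁻⁹
synonymous substitutions per site per year (the soybean rate; overridable
per clade), reported in Mya to two decimals.

Synteny links score all query×subject protein pairs and keep those with
E ≤ 10⁻¹⁰, binned by identity (≤50/≤70/≤90/>90%). Significance uses a
Gumbel model whose location and scale are fit at startup on a
shuffled-sequence score null (method of moments); this is a pragmatic
stand-in for a full local-alignment statistics treatment and is intended
to separate family homologs (astronomically significant) from unrelated
sequences, not to reproduce BLAST E-values numerically.

## Expression and qPCR

Heatmap matrices are log₂(FPKM + 1) with per-gene mean-centering, so every
row mean is exactly zero. Relative expression follows the standard
2^−ΔΔCt convention: technical replicates are collapsed by mean to one Ct
per (gene, condition, biological replicate) — the usual convention for a
3×3 design — ΔCt subtracts the reference gene per biological replicate,
and ΔΔCt subtracts the mean calibrator ΔCt of the same treatment at 0 h.
Means and standard deviations are over biological replicates.

Duncan's multiple range test computes the one-way ANOVA error variance,
sorts means descending, and tests each span of p ordered means against the
least significant range Rₚ = q(αₚ, p, df)·√(MSE/n) with protection level
αₚ = 1 − (1−α)^(p−1); studentized-range quantiles come from `qtukey`
rather than printed tables so any df is exact. A span inside a homogeneous
span is homogeneous; letters mark the maximal homogeneous spans, "a" on
the largest mean. Unbalanced designs use the harmonic mean n (flagged).
Note the test's well-known liberality: under a global null with k groups
the widest-span test fires with probability exactly 1 − (1−α)^(k−1)
(≈ 0.14 for k = 4 at α = 0.05), which is the test's protection-level
design, not an implementation artifact; simulations in this package
measure ≈ 0.13–0.15 accordingly. Zero within-group variance with unequal
means yields all-distinct letters rather than an error.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, at
desk scale: by default 3 chromosomes of 150 kb carrying 6 family genes
(one tandem pair at Ks = 0.05, Ka = 0.01; one segmental pair at Ks = 0.10,
Ka = 0.03 — divergences within the range typical of recent soybean
paralogs), 8 decoy genes without the domain, 2 multi-isoform loci, and 2
short-CDS decoys (< 150 bp), with mixed strands and GFF3-consistent
coordinates. Duplicates are produced by `evolve_duplicate()`, which
back-transforms the target rates through the Jukes–Cantor correction to
difference proportions, converts them to mutation counts via the
sequence's potential site counts (stochastic rounding keeps the expected
counts on target), and applies at most one synonymous or nonsynonymous
single-nucleotide change per codon, never creating stops. This "uniform
sites, explicit fate" model makes NG86 recovery analytically predictable;
over 100 replicates the mean estimates sit within a few percent of the
targets.

Promoter and UTR backgrounds are low-complexity repeats (AC and CT
dinucleotides) that match no dictionary element on either strand, and
planted elements overwrite the promoter window at recorded positions —
so cis-element false positives on synthetic bundles are exactly zero and
recovery tests can assert exact counts. Intergenic sequence is i.i.d.
uniform. These are deliberate idealizations: synthetic bundles have no
repeats, isochores, splice-site realism or read-level noise, so passing
recovery tests demonstrates the correctness of the pipeline's logic and
arithmetic, not its robustness to the composition of real genomes.

qPCR tables follow a 3 biological × 3 technical replicate design over
treatments (H₂O₂, NaCl, PEG) and timepoints (0/3/6/12 h) with a reference
gene in every cell; planted ΔΔCt effects shift target Ct so the noiseless
round trip through `relative_expression()` is exact. Expression matrices
plant multiplicative tissue effects on lognormal baselines.

## Validation scale and reproducibility

The shipped tests and the acceptance script size their simulations to run
comfortably on a laptop: 500-codon sequences and 100 replicates for
parameter recovery, an exhaustive sweep of ≤2-difference sense-codon pairs
for the NG86 oracle, random additive trees up to 8 taxa for NJ, 2000
simulations for the Duncan null rate, and bootstrap replicate counts of
20–100 in pipeline tests (the 1000-replicate default matches published
practice and remains the API default). Every stochastic component takes an
explicit seed; a fixed seed makes bundles byte-identical and pipeline
reports reproducible.

## Known limitations

- The PSSM scan is ungapped; domains interrupted by insertions score low.
- The progressive aligner is consensus-based; on sets near the 50%
  identity floor a profile–profile or external aligner is preferable.
- The synteny E-value model is a Gumbel approximation on global-alignment
  scores, suitable for separating homologs from noise only.
- NG86 with equal pathway weights ignores transition/transversion bias;
  codon-model ML estimators will differ on deeply diverged pairs.
- Duncan's test is liberal by construction (see above); treat its letters
  as descriptive grouping, not familywise-controlled inference.
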