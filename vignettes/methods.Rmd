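---
title: "Methods: from filtered SNVs to proteome impact and SNV-based trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from filtered SNVs to proteome impact and SNV-based trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvproteo)
```

This vignette is the package's account of its methods: the models and
rules each stage implements, the parameters that matter and their
defaults, the numerical and design choices made where conventions differ,
and what the synthetic-data generator does and does not emulate.

## Coordinate model

All coordinates are 1-based and inclusive, the VCF convention; BED input
is converted on read (0-based half-open to 1-based inclusive, handled by
`rtracklayer`). A transcript model carries its exons as ascending genomic
intervals plus an explicit 5′ UTR length and CDS length (stop codon
included, divisible by 3). Supplying the UTR length directly, rather than
inferring a start codon, keeps the mapping purely arithmetic: an exonic
genomic position maps to an mRNA position by rank along the transcript
orientation, and a CDS position `m` maps to residue
`floor((m - utr5 - 1)/3) + 1` with codon offset `(m - utr5 - 1) mod 3 + 1`.
On the minus strand the mRNA is the reverse complement of the exon
concatenation, and VCF ref/alt alleles are complemented before any codon
arithmetic; a mirrored-transcript property test checks that plus- and
minus-strand encodings of the same gene yield identical protein-level
annotations.

Reference mismatches (an SNV whose stated reference base disagrees with
the genome or mRNA) raise errors rather than being skipped: silent skips
hide fixture and input bugs.

## Filtering

A record is kept iff depth > 10 **and** quality > 20 **and** (when
regions are supplied) its single base lies inside a target interval. Both
thresholds are strict inequalities and configurable. When a record fails
several tests the reported reason is the first failure in the fixed order
depth, quality, region, so reports are byte-reproducible. Indels and
other non-SNV alleles are separated at parse time and never enter the SNV
stream; multi-allelic lines are split into one record per alternate
allele. Records lacking any `DP` field carry depth 0 and therefore fail
the depth filter rather than passing silently.

## Consequence calling

One annotation row is emitted per (variant, transcript) pair — there is
no "most severe consequence" collapsing, so a variant hitting two
overlapping transcripts contributes two rows. The consequence partition
is: missense, synonymous, stop-gain, stop-loss for CDS positions; `utr`
for exonic positions outside the CDS; `splice` for intronic positions
within 2 nt of an internal exon boundary (the canonical GT/AG
dinucleotides; the window is a parameter); `intron` otherwise within the
transcript span; `intergenic` beyond it. Stop-loss is emitted under its
own label so that counts of the other categories are unaffected by its
inclusion. The translation table is the standard genetic code and codon
substitution is local: correctness is checked against a whole-CDS oracle
that mutates the full mRNA, translates the entire CDS and diffs the
protein, over 1,000 random variants on both strands.

Canonical protein mapping is a join against a user-supplied id map
(transcript protein id → canonical id + position offset); unmapped
proteins keep `NA` canonical fields and are counted, since several
transcript isoforms typically collapse onto one canonical entry.

## Cohort statistics

The cohort object is a binary variant-key × sample matrix with sorted,
deterministic row and column orders; every summary is invariant to sample
input order. Two key levels exist: nucleotide (`chrom:pos:ref:alt`) and
amino acid (`protein:pos:refaa:altaa`, canonical coordinates when
available).

*Novelty* is membership in a supplied catalog, summarized per sample,
pooled per arm and over all keys, and restricted to keys present in both
arms. Pooling known keys that recur across samples together with novel
keys that stay private necessarily lowers the pooled known fraction below
the per-sample fractions; the fixture suite checks this dilution
quantitatively (90 shared catalogued keys + 10 private novel keys per
sample across 5 samples give 0.9 per sample but 90/140 pooled).

*Common/rare*: a key is common when its cohort frequency strictly exceeds
10%. Two conventions for "common" circulate (frequency above 10% versus
presence in 90% of samples); the 10% rule is the default because it makes
common/rare an exhaustive partition, and the threshold is an argument so
the 90% convention is one call away.

*Case/control overlap* partitions keys into both / case-only /
control-only and emits a ternary keys × samples matrix (2 = present and
shared between arms, 1 = present and arm-unique, 0 = absent) intended for
heatmap rendering outside the package.

## Functional-site impact

The only motif with an operational loss rule is the N-linked
glycosylation sequon N-X-S/T with X ≠ P: a substitution anywhere in the
3-residue window is applied and the motif re-tested, so N→K, X→P and
S/T→(other) are losses while S→T is a retention. Overlapping sequons are
all evaluated. For every other site type (phosphorylation, acetylation,
methylation, ubiquitylation, O-linked glycosylation, active and binding
sites) the package counts any substitution at the annotated residue as a
loss — "unacceptable change" is not defined per-type by any rule we can
implement, and this single explicit convention is documented rather than
hidden. Sequon gains (substitutions creating a new N-X-S/T) are computed
but reported separately and never enter loss counts. Sequons running past
the protein C-terminus are skipped with a warning.

## Enrichment under a uniform null

For an annotation set with merged residue footprint `f` in a proteome of
`L` residues and `n` unique nsSNV positions, the expected count is
`E = n f / L` and the statistic is `z = (O − E)/√E` with two-sided
`p = 2Φ(−|z|)`, floored at the smallest positive double. The normal
approximation to the Poisson was chosen as the default because its
behavior matches the reporting conventions this type of analysis uses
(direction signs, p-value floors near 1.1e-16, i.e. the double-precision
complement floor); an exact two-sided Poisson tail is available via
`method = "poisson"`. Observed counts are unique residue positions after
deduplication, not sample-weighted; footprint proportionality is the
default with a protein-count alternative (`by = "protein_count"`).
Results flag `expected < 5`, where the normal approximation is poor, and
a Bonferroni column is emitted for convenience but never used for
filtering. A calibration test places 400 distinct variants uniformly on a
10,000-residue proteome 1,000 times and checks that the empirical type-I
error of ten expected-20 sets at nominal 0.05 stays within [0.03, 0.07].

## SNV-shrunk genome phylogenetics

The alignment construction: take the union of all samples' SNV positions;
for each union position every sample contributes the reference window of
width 2δ+1 centered there, with the sample's own alternate alleles
substituted at any of its SNV positions inside the window. A sample
without a call at the center contributes the reference base — absence of
a call is treated as homozygous reference, since genotype confidence is
out of scope. Chromosome-edge windows are N-padded so all rows stay equal
length, and N columns are excluded from distance computation. Overlapping
windows (two union positions closer than 2δ) are emitted independently,
duplicating shared context: fixed per-window width keeps columns
comparable across samples and makes window-level bootstrap well defined.
Heterozygosity is ignored (calls are unphased single alleles here), and δ
defaults to 0 with 0–2 the intended range.

Distances are p-distances by default; no substitution-model correction is
applied because shrunk genomes are ascertained, SNV-enriched sequence,
not neutrally evolving sites — a Jukes–Cantor option exists behind a
flag. Neighbor joining is implemented in the package (classical
Saitou–Nei: minimize `Q(i,j) = (m−2)d(i,j) − r(i) − r(j)`, standard
branch-length formulas, matrix reduction), with ties broken toward the
lowest index pair and negative branch lengths clamped to zero with the
length transferred to the sister edge. Correctness is checked two ways:
against an independent NJ implementation (`ape::nj`) and, for up to six
taxa, against exhaustive topology enumeration with least-squares branch
fitting, where the generating topology of an additive matrix must be the
unique near-zero-SSE fit.

Bootstrap resamples whole windows with replacement (with δ = 0 this is
column resampling), rebuilds the tree per replicate, and scores each
internal bipartition of the main tree by the percentage of replicates
containing it. Bipartitions are canonicalized by leaf labels, so supports
are invariant to sample input order, and the resampling stream is seeded
explicitly.

## Metadata curation

Barcodes are parsed positionally (project, tissue source site,
participant, sample type + vial, trailing fields kept verbatim); sample
type codes 01–09 classify as case and 10–19 as control, anything else is
an error rather than a guess. Experiment accessions are CA/CO + 5-digit
arm-local serial + cancer-type suffix, assigned in curation input order
(the ordering rule is otherwise unspecified, so input order is the
reproducible choice). GC QC pools a sample's sequences, excludes N from
the denominator, and passes within inclusive bounds 0.38–0.48 — the
bounds are stated without endpoint qualifiers in the conventions this
follows, and inclusivity is the choice that never rejects a sample
sitting exactly on a published bound.

## The synthetic-data generator

`make_reference()` tiles transcript loci along a single chromosome with
known geometry: random 5′ UTR (10–60 nt), CDS of 30–100 codons opened
with ATG, filled with non-stop codons and closed with a stop, random
3′ UTR (10–40 nt), 1–3 exons with 20–80 nt introns, alternating strands,
50–150 nt intergenic spacers. Proteins are exact CDS translations; every
sequon a protein contains is annotated as an N-linked glycosylation site,
other PTM/active/binding sites are placed at eligible residues, pathway
sets partition the proteome (so conservation of expected counts is exact)
and domain sets cover sub-intervals.

`make_cohort()` defaults to the emulated study design: 20 patients, 22
case and 33 control samples (every patient gets at least one of each,
extras distributed round-robin), with germline variants shared by all of
a patient's samples and somatic variants private to individual case
samples, all at distinct CDS positions so planted fractions are recovered
exactly. Where the emulated design gives no value, defaults were fixed
once at desk scale: 50 germline per patient, 10 somatic per case sample,
95% catalog fraction, a 100 kb genome with 20 transcripts. Planted record
depths (15–60) and qualities (25–60) clear the filters; each sample
additionally gets one record at depth 10, one at quality 20, one outside
the exome regions and one indel, which the default filters must remove.

What the generator does *not* emulate: sequencing error and
genotype-likelihood noise, linkage between variants, mutation-rate
heterogeneity along the genome, real transcript isoform structure,
population allele-frequency spectra, and read-level artifacts. Passing
tests therefore demonstrate algorithmic correctness on known structure —
exact recovery of planted quantities, agreement with oracles — not
robustness to the noise sources of real cohorts.

Both generators draw from an explicit seeded stream and restore the
global RNG state afterwards; the same spec yields byte-identical outputs.

## Problem sizes used by the test suite

The suite favors exact, planted-structure checks at deliberately small
scale: cohorts of 4–6 patients with 10–12 samples and 100–150 planted
variants, 30 kb–40 kb genomes with 8–12 transcripts, 1,000-variant
translation-oracle sweeps, 200 random additive matrices (4–8 taxa) for NJ
recovery, 10,000 random proteins for the sequon oracle, 1,000-replicate
null simulations for enrichment calibration, and 100-replicate bootstraps
for clade support. These sizes were chosen so every check is exact or
tightly calibrated while the whole suite runs in a couple of minutes.

## Known limitations

- Annotation is per supplied transcript; there is no isoform-resolution
  policy beyond annotating against everything provided.
- Loss semantics for non-sequon PTM types are the any-substitution rule
  described above, which will overcount losses for motifs with degenerate
  positions.
- The enrichment null assumes uniform placement over the proteome
  footprint; mutational hotspots violate it and will inflate
  significance.
- NJ returns a single tree; near-ties in the Q-criterion are resolved
  deterministically rather than enumerated.
- The shrunk-genome construction treats missing calls as reference, so
  systematic missingness (e.g. coverage dropouts in one arm) will bias
  distances toward the reference.
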