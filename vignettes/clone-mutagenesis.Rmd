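---
title: "Mutagenesis assays from isogenic clone genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutagenesis assays from isogenic clone genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonemut)
```

## The assay and its statistical model

A whole-genome mutagenesis assay treats cultured cells derived from a single
ancestral clone, isolates single-cell subclones after the treatment regimen,
and sequences several of them. Because every clone inherits the complete
germline variation of the ancestor, any variant observed in **exactly one**
clone — while all other clones look homozygous reference at that position —
arose after the clones diverged, i.e. during the treatment window. This
turns mutation calling into a cross-sample filtering problem and avoids the
need for validated SNP catalogues in organisms that lack them.

`clonemut` implements this caller and the downstream analyses it feeds:
trinucleotide mutation spectra, dinucleotide-mutation and indel
sequence-context classification, transcription-related mutation-density
statistics, and a small probability model for mutation-driven reversion of
inactivated genes. A synthetic cohort generator reproduces the statistical
structure every stage assumes, so the whole pipeline is testable without any
sequencing data.

## The unique-mutation caller

The caller consumes a per-position, per-sample pileup of quality-filtered
allele counts (bases below Phred 30 are dropped when converting mpileup
text). At each position the most supported non-reference allele of each
sample is evaluated (ties broken alphabetically), and a mutation is emitted
if and only if

1. in exactly one sample the candidate allele fraction is at least
   `min_mut_af` (default **0.33**) with coverage at least `min_cov_mutated`
   (default **10**), and
2. in every other sample the reference allele fraction is at least
   `min_other_ref_af` (default **0.9**).

The defaults are the published optimum for this filter family on stable
diploid genomes; they presuppose heterozygous mutations (expected allele
fraction 0.5, so 0.33 tolerates binomial sampling noise) and clean
homozygous-reference positions elsewhere. The same three filters apply to
insertion and deletion candidates, with two conventions the pileup format
forces us to choose: the allele-fraction denominator of an indel is the
spanning-read coverage at its anchor column, and the "reference fraction" of
another sample is the fraction of its reads not supporting any indel there.
A sample with zero coverage fails the other-sample filter — absence of
evidence of the reference state suppresses the call rather than passing it.

Threshold comparisons use a `1e-9` slack so that a fraction exactly at a
threshold (e.g. 18/20 against 0.9) passes despite floating-point rounding of
the product `0.9 * 20`.

Specificity comes from the cohort: a germline heterozygous variant appears
in all samples at fraction ~0.5, failing filter 2 in every other sample.
The package requires at least two samples and cohorts of three to five (or
pooling with additional sequenced clones) sharpen the filter further.

Called indels are reported **left-aligned** (shifted to their 5'-most
equivalent position within homopolymers and tandem repeats). For
sequence-context analysis on the opposite strand, events are first
**right-aligned**, because the 3'-most representation on the plus strand is
the 5'-most representation on the minus strand.

## Spectra

Single-nucleotide variants are classified into the standard 96 channels: six
pyrimidine-centred substitution classes (C>A, C>G, C>T, T>A, T>C, T>G), each
in 16 flanking-base contexts ordered alphabetically by 5' then 3' base.
Purine-reference SNVs are folded onto the reverse complement. SNVs whose
triplet window leaves the contig or contains a non-ACGT base are counted as
unassignable and excluded.

Channel counts are normalised by the genome's folded triplet occurrences
(`rate = count / occurrences of the context triplet`), which converts raw
counts into per-triplet mutation rates and makes spectra comparable between
genomes of different composition. Note that strand folding maps *every*
ACGT triplet onto one of the 32 pyrimidine-centred keys — a poly-A sequence
counts entirely under TTT — so the occurrence table is degenerate only when
no triplet is countable at all (e.g. an all-N genome).

Cross-species comparison multiplies each channel by the ratio of target to
source triplet frequencies (each table normalised to sum 1) and renormalises
the spectrum to unit sum. Renormalisation is a design choice; Pearson
correlation, the headline comparison statistic, is unaffected by overall
scale either way. Spectra are compared to signature catalogues by Pearson
correlation and cosine similarity; a zero-variance vector makes Pearson
undefined and is reported as NA with a warning rather than silently as 0.
The shipped `signatures_synthetic.tsv` is a synthetic catalogue in the
standard 96-row layout for examples and tests; it is not the human cancer
signature catalogue, which the package reads from the same format when
available.

Adjacent SNV pairs (dinucleotide events) remain in SNV totals and triplet
spectra and are additionally reported as DNVs; per-clone totals printed by
the pipeline are most consistent with that convention, and a caller output
filtered to isolated SNVs is available from `detect_dinucleotides()`.

## Dinucleotide and indel context conventions

Runs of adjacent mutated positions are merged per sample: runs of exactly
two become dinucleotide mutations, runs of three or more are reported
separately as multi-nucleotide events. A DNV is represented on the strand
whose *reference* dinucleotide carries more pyrimidines (GG>TT is reported
as CC>AA), with alphabetical tie-breaks on reference then alternate; this
convention makes complementary events share one label while keeping a
deterministic canonical form.

One-base insertions are classified by (two preceding bases, inserted base,
two following bases); one-base deletions by (preceding, deleted, following).
Inserted or deleted purines are analysed on the opposite strand — after
right alignment — so every context is reported as a T or C event. Two-base
deletions are tested for exact coincidence with AG or GG dinucleotides
(either strand, i.e. deleted pair in {AG, GG, CT, CC}), the motifs of
platinum intrastrand crosslinks; "exact coincidence" rather than mere
overlap is deliberate, since the mechanistic claim concerns the removal of
both crosslinked base pairs.

## Genic context and strand bias

Gene intervals (primary transcripts, introns included) are merged ignoring
strand before computing the genic genome fraction, and each mutation is
genic iff it falls inside a merged interval. Observed genic/intergenic
counts are tested against the genome-fraction expectation with a 1-df
chi-square; density enrichments are reported as observed-over-expected
fractions for both regions, which are two views of one 2x2 table and are
checked for consistency in the tests.

Expression stratification compares log10 FPKM of mutated genes against all
genes with a one-sided Mann–Whitney test (skew toward low expression, the
transcription-coupled-repair prediction). Zero-FPKM genes receive a 1e-3
pseudo-count that affects display values only — the rank test is invariant
to any monotone transform.

For strand bias, the strand carrying the mutated pyrimidine is compared
with the gene's template strand; SNVs inside overlapping genes of opposite
strand are excluded rather than double-counted, and the transcribed /
non-transcribed counts are tested against 50:50 with a 1-df chi-square.

## The reversion model

The model mirrors a deliberately simple back-of-envelope framing: induced
mutations fall uniformly on a genome of size `G` (default 3.1e9 bp,
configurable; any value in 3.0–3.2e9 reproduces the same one-significant-
figure outputs), and a reversion requires a hit inside a small window — 20
bp for a compensating frameshift, the 3 bases of a stop codon for an SNV
(any substitution of any stop base counts). Then

- per-event hit probability: `p = w / G`;
- events for a 50 % chance: `N = ln(0.5) / ln(1 - p)` (≈ `ln 2 / p` for
  small `p`, with relative error `p/2`);
- per-cell probability with burden `b` events: `p_cell = 1 - (1 - p)^b`,
  and cells for a 50 % chance: `ln(0.5) / ln(1 - p_cell)`, floored at one
  cell.

The measured four-cycle burdens (800 SNVs and 130 indels per Gb) are the
default `reversion_params()`. The uniform-placement assumption is knowingly
wrong in detail — measured spectra are highly non-uniform — and the model is
intended as an order-of-magnitude statement only. The Monte-Carlo oracle in
the test suite runs the same placement simulation at a scaled geometry
(G = 1e5, window 20, burden 50, 5e4 replicates) where the expected hit count
(~500) gives the binomial check real power; at the full genome scale the
expected hit count over any affordable replicate number is below one and a
3-sigma comparison would be vacuous.

## The synthetic cohort generator

The generator emulates exactly the structure the caller exploits:

- a random reference genome — IID bases, or a second-order Markov chain
  calibrated by iterative proportional fitting towards a target triplet
  table (matched as closely as the target's shift-consistency allows);
- shared heterozygous germline SNVs present in every clone;
- per-clone unique mutations drawn channel-by-channel from a 96-channel
  spectrum and placed uniformly among sites with the required triplet
  context (either strand), plus insertions/deletions placed per a context
  model, and an optional fraction of SNV draws emitted as adjacent
  dinucleotide pairs;
- pileups with Poisson(`coverage_mean`) coverage, Binomial(cov, 0.5)
  alternate reads at heterozygous sites, and uniform substitution errors at
  `base_error_rate` elsewhere.

Preset spectra (`mock`, `cisplatin`, `cyclophosphamide`) encode the printed
treatment proportions — e.g. 57 % C>A for cisplatin concentrated at NCC/NCT
contexts, a CpG-transition excess for mock, NTT-context T>A preference for
cyclophosphamide, GG-preceded T insertions followed by T, and a 68 %
AG/GG-motif fraction among two-base deletions. They are approximations read
from published figure proportions, padded to full distributions; they are
not ground truth. Sequencing depth of the original clones is not published;
`coverage_mean = 20` is the package default and is exposed in the config.

What the generator does **not** emulate: read-level artefacts (mapping
error, duplicates, indel-realignment noise), copy-number variation, and
correlated errors — the indel false positives of real data come mostly from
alignment, which is out of scope. Passing end-to-end tests therefore
demonstrates the correctness of the filter logic and the analysis
arithmetic under the assay's statistical model, not robustness to raw-read
artefacts. Implanted positions are kept a few bases apart (a small exclusion
buffer) so contexts remain intact; deletion support is injected at the
anchor column only, the caller's single observable.

Determinism: every stochastic step derives from the config seed, and
identical configs yield byte-identical FASTA, truth and pileup outputs
(covered by tests).

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen so the whole suite completes
in a few minutes: caller-vs-oracle equivalence on 0.4–10 kb cohorts of 2–5
samples; spectrum recovery on 0.2–1.5 Mb genomes with a few hundred events;
and an end-to-end sensitivity benchmark on a 2 Mb, 5-clone cohort with 200
implanted heterozygous SNVs per clone, 1000 shared germline variants,
coverage 20 and 0.3 % base error — the configuration `scripts/acceptance.R`
re-runs from scratch. At those settings the caller recovers over 90 % of
implanted SNVs with zero calls at germline sites; the residual misses are
dominated by binomial allele-fraction fluctuations below the 0.33 threshold
at coverage ~20, not by filter defects.

Other numerical details: threshold comparisons carry a `1e-9` slack (above);
alternate-allele ties break alphabetically; indel candidate ties break by
count then allele string; positions with non-ACGT reference are skipped by
the caller; empty inputs return empty, typed tables rather than NULL.

## Limitations

- The caller assumes a stable diploid genome and heterozygous mutations; it
  is not a general somatic caller and has no concept of subclonality,
  contamination or copy number.
- Spectra adjustment between species corrects composition only; it cannot
  correct replication-timing or chromatin effects.
- The reversion model is a uniform-placement approximation by construction.
- The synthetic generator validates logic, not robustness to alignment
  artefacts (above).
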