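---
title: "Authenticating Pueraria products with ITS2 barcodes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Authenticating Pueraria products with ITS2 barcodes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(its2auth)
```

`its2auth` authenticates processed products of *Pueraria montana* var.
*lobata* (Gegen) and var. *thomsonii* (Fenge) from the ITS2 nuclear
ribosomal spacer. This vignette is the package's account of the science:
the models it implements, the parameters that matter, what the synthetic
data do and do not emulate, and where the method's limits are.

## The marker and the diagnostic characters

The two subspecies carry ITS2 alleles of 246 bp (*lobata*) and 247 bp
(*thomsonii*). Aligned, they differ at exactly four columns: a 1-bp
indel at column 29 (*thomsonii* T, *lobata* gap — the polarity follows
from *thomsonii* being one base longer) and SNPs at columns 52 (A/G),
201 (C/T) and 244 (T/G). Column 244 is additionally polymorphic *within*
var. *lobata* (a T/G transversion between haplotypes), which makes it an
unreliable diagnostic on its own.

All printed site positions are 1-based columns of the pairwise alignment
of the two subspecies consensus sequences (247 columns). This is the only
frame in which a 246-bp and a 247-bp sequence share coordinates; because
the single gap sits in the *lobata* row, alignment columns coincide with
*thomsonii* sequence positions.

### Subspecies calling

`call_subspecies()` aligns a query to both group consensuses
(Needleman–Wunsch, match +1, mismatch −1, gap open −2, gap extend −0.5; a
gap of length L costs 2 + 0.5·L). Identity gates the call: below 0.90 the
query is outside the genus (`not_pueraria`); between 0.90 and 0.99 no
subspecies-level call is attempted. Above 0.99 the query's states at the
diagnostic columns are read off and each group receives the summed
*reliability weight* of the sites agreeing with its consensus state.
Weights are 1.0 for columns 29, 52 and 201 and 0.25 for the
intraspecifically polymorphic column 244; the down-weighting prevents the
*lobata* 244-G haplotype from being mistaken for *thomsonii* while still
letting the site break what the three reliable sites cannot. Ties are
`ambiguous`. With these weights no tie is reachable from pure site-state
combinations (no subset of {1, 1, 1, 0.25} sums to half of 3.25), so
calls are decided whenever the identity gate passes.

The thresholds are package choices, not literature constants: the two
subspecies sit at ≈ 98.4% mutual ITS2 identity, congeneric outgroups at
≈ 96%, and non-target genera below 80%, so 0.99/0.90 cleanly separate the
three regimes with margin for sequencing error.

## Distances, the barcoding gap, and trees

`k2p_distance()` implements the Kimura 2-parameter correction
d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q) with P and Q the transition and
transversion fractions over *comparable* columns. Gap handling is
pairwise deletion (a column is dropped for a pair if either row has a gap
or an ambiguous base), the common default of classic phylogenetics
software; saturation (a non-positive log argument) is an error rather
than an `NA`, since distances that saturate on an ITS2 alignment signal a
mis-built alignment, not evolution.

Distances are computed by default on the full aligned amplicon (ITS2 plus
the retained rRNA flanks, 477 comparable sites in the bundled fixtures)
rather than the trimmed spacer: one transversion over 477 sites gives
0.0021, the within-*lobata* maximum, whereas over 246 sites it would give
0.0041. The function is frame-agnostic — any alignment can be supplied —
but the fixtures and reports use the amplicon frame.

`barcoding_gap()` reports the per-group maximum intra-group distance, the
minimum inter-group distance, and whether the gap exists (min inter
strictly above every defined max intra). Singleton groups have no intra
statistic (`NA`, not 0). Pseudo-groups (`outgroup`, `contaminant`) are
excluded by default: a bin of assorted species has no meaningful
"intraspecific" spread.

`nj_tree()` is a from-scratch Saitou–Nei implementation: join the pair
minimising Q(i,j) = (n−2)·d(i,j) − r(i) − r(j), with ties broken on the
lexicographically smallest label pair (internal nodes inherit the
smallest leaf label of their clade) so topologies are reproducible.
Negative branch lengths — a known NJ artefact near zero-length splits —
are clamped to zero with the deficit transferred to the sister branch,
preserving the joined pair's path length. `bootstrap_support()` resamples
alignment columns with replacement, rebuilds the tree per replicate, and
annotates each internal bipartition of the point tree with the percentage
of replicates containing it; the resampling is driven by a single integer
seed and is bit-identical across runs. `ape` serves as an independent
cross-check in the test suite (additive-matrix recovery, K80 distances),
never as the implementation.

## The Sanger trace model and the A/B/C triage

Chromatograms are consumed as plain four-channel tables
(`pos A C G T`), not proprietary binary traces: base calling from raw
electropherogram physics is out of scope, intensities are taken as given.
`call_bases()` emits the strongest channel per position, or the two-base
IUPAC code when the second channel reaches 25% of the primary intensity;
`assemble_bidirectional()` reverse-complements the reverse read, aligns,
and merges by IUPAC set intersection (disjoint sets yield N; assembly
fails below 80% IUPAC-compatible overlap identity).

Mixed templates produce structured artefacts. Because the two subspecies
alleles differ in length by one base, a co-amplified minority template is
phase-shifted downstream of the indel and every later peak is *nested* —
this, not the SNP count, is what makes half-and-half mixtures
unsequenceable. `classify_trace()` quantifies it: the heterozygous
fraction overall, and the *nested score* (heterozygous fraction
downstream of the indel column). Labels: A when the heterozygous fraction
is ≤ 0.5% of positions; B when it is ≤ 5% and the nested score is below
0.3; C otherwise. The thresholds are calibrated to the trace generator —
the triage is defined qualitatively in the field — such that pure
templates land in A, ≈15% minor mixtures in B and ≈50% mixtures in C.

One modelling subtlety is worth stating plainly. At an 85:15 mixing
ratio the minor/major peak ratio is 15/85 ≈ 0.176, *below* the 0.25
calling threshold, so in a noise-free linear trace a 15% contaminant
would be invisible and the trace would classify A. Detection of the B
band rides on channel noise (default sd 3.5 on the 0–100 intensity
scale) pushing a small fraction of the nested minor peaks over the
threshold — typically 2–12 of 247 positions, i.e. inside the B band,
with low nested score. That detection is therefore intrinsically
stochastic, which mirrors practice: borderline contamination shows up as
"some heterozygous bases needing manual editing", not as a deterministic
signature. Since study panels are *defined* by their observed trace
types, `make_study_fixtures()` draws mixed traces conditional on
realizing their designed class (bounded redraws, still a pure function of
the seed).

## The metabarcoding pipeline

Reads are single-end amplicons tagged with 10-bp sample barcodes at the
5′ end. Pipeline order and the retention rules (boundary semantics read
literally off their exclusion statements):

1. **Demultiplex** — assign each read to the unique tag matching its
   first 10 bases within `max_mismatch` substitutions (default 0);
   ambiguous or unmatched reads go to an `unassigned` bin; tags must be
   pairwise farther apart than `max_mismatch`. Reads are conserved:
   samples + unassigned = input.
2. **Quality filter** — keep length ≥ 300 *and* arithmetic mean Phred
   ≥ 30 (the mean of the integer scores, not of error probabilities).
3. **ITS2 extraction** — locate the conserved 5.8S tail and 28S head
   flanking ITS2 with 25-bp position-weight-matrix anchors (score 1 per
   matching base, acceptance at ≤ 2 mismatches), on both strands, and
   return the enclosed region. Anchors rather than a full profile HMM:
   the flanks are strongly conserved, the anchor pair reproduces exact
   trimming on amplicons while remaining fully specified and
   dependency-free, and the model ships with the package and is
   overridable (`its2_anchor_model()`). Failure is a per-read value, not
   an error.
4. **Dereplicate** — exact-string collapse per sample; clusters with
   count ≥ 11 (strictly more than 10 repetitions) are retained, sorted by
   descending count then sequence. Counts are per sample, since tags are
   per sample.
5. **Assign** — best-identity global alignment against all reference
   ITS2 sequences; hits in the focal subspecies groups are refined
   through the diagnostic-site caller, others report the best reference's
   taxon at ≥ 0.90 identity, else `unassigned`.
6. **Compose** — per-sample read counts and proportions over retained
   clusters; in the authentication report the dominant *Pueraria*
   subspecies becomes the sample's call and non-*Pueraria* taxa at ≥ 1%
   of retained reads are listed as contaminants (the 1% is a reporting
   threshold, configurable, not a biological claim).

## What the generator emulates — and what it does not

`make_references()` builds ITS2 alleles on a random GC ≈ 55% backbone
(seed-deterministic, so the package is self-contained; user FASTA can be
swapped in without code changes) carrying exactly the four diagnostic
characters above, a second *lobata* haplotype with G at column 244, and
conserved flanks sized so the *lobata* amplicon is exactly 477 bases —
making the single-transversion K2P equal 0.0021 under the amplicon
convention. Congeneric outgroups diverge ≈ 3% from a common ancestor that
branches *between* the subspecies (ancestral state lobata-like at column
52, thomsonii-like elsewhere), so each subspecies clade keeps a
positive-length edge in distance trees — with only three substitutions
separating the subspecies, an outgroup attached exactly at one
subspecies' node would leave that clade's edge at zero length and its
recovery to tie-breaking. Contaminants (*Aspergillus*, *Hordeum
vulgare*, *Rosa*) are ≥ 15% divergent over ITS2 with conserved rRNA
flanks, as real fungal/plant co-amplicons would be.

`simulate_reads()` draws template counts multinomially, plants
substitution errors (default rate 0.002/base), and assigns Phred scores
from a two-state model (good reads ≈ Q35, a 10% fraction ≈ Q12 designed
to fail the QV-30 filter). **Not** emulated: Ion-Torrent homopolymer
indel errors, primer sequences, chimeras, or length truncation — so
passing tests demonstrate the pipeline's logic, not robustness to
platform-specific artefacts. `simulate_chromatogram()` lays templates
down without re-alignment (that is what produces nesting) and adds
clipped Gaussian channel noise; peak spacing, mobility and dye effects
are not modelled.

The study-scale panel (`make_study_fixtures()`) encodes the survey
design: 30 raw-material samples (21 labelled Gegen of which 2 are truly
Fenge, 9 labelled Fenge, all true), 10 food powders (5 of each
subspecies, so authentication yields 50% *lobata*), and 12 herbal
samples — 9 pure, 2 mixed at 85:15 within the amplifiable fraction, 1 at
50:50 — with *Aspergillus* in all three metabarcoded samples, *Rosa* in
the B-type one and *Hordeum vulgare* in the C-type one. Chromatograms
for mixed products are built from the *Pueraria* fraction renormalized
to 1, since only *Pueraria* templates amplify efficiently in the Sanger
assay.

## Numerical choices and problem sizes

* Alignment scoring as above; equal-scoring alignments are resolved by
  the alignment engine's deterministic preference order. Every asserted
  fixture alignment has a unique optimum by construction (the indel sits
  in a non-repetitive context), so no reported value depends on
  tie-breaking.
* Consensus building: strict per-column majority, ties resolved to the
  IUPAC code covering the tied bases.
* NJ tie-breaks lexicographic; negative branches clamped with deficit
  transfer; bootstrap supports rounded to integer percent, absent
  bipartitions unreported.
* Random draws all flow through a single integer seed per entry point
  (`withr::with_seed`), making every artefact byte-reproducible.
* Suite problem sizes: reference sets of 10 sequences; panels of 52
  samples; read batches of 600–5000 reads; 50-tree NJ recovery sweeps;
  2000 bootstrap replicates for the fixture tree. These sizes keep each
  property readable and the whole suite fast while leaving every rate
  estimate (composition recovery, detection at ≥10% abundance) with
  comfortable statistical margin.

## Known limitations

* Subspecies discrimination rests on four characters of which one is
  down-weighted; a query mutated at two high-weight diagnostic sites can
  be called ambiguously or wrongly — with real ITS2 error rates this is
  vanishingly rare, but the support value exposes it.
* The A/B/C triage thresholds are generator-calibrated; applying them to
  real chromatograms requires revisiting the ambiguity threshold against
  the instrument's noise floor.
* K2P saturates on deeply divergent pairs (it errors rather than
  reporting one); the distance module is built for within-genus scales.
* The metabarcoding pipeline does exact dereplication only — no OTU
  clustering below 100% identity, no chimera detection, no rarefaction —
  and treats reads as single-end.
* TLC/HPLC chemistry is carried as a user-supplied pass/fail annotation;
  the package never computes chemistry.
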