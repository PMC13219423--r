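---
title: "5' UTR length, alternative promoters and leaky ribosome scanning: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{5' UTR length, alternative promoters and leaky ribosome scanning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leakyscan)
```

## The model

Scanning ribosomes load at the 5' cap and initiate at the first AUG in a
favorable context. Two features weaken recognition of that first AUG: a
poor Kozak context (no purine at −3, no G at +4) and a very short 5'
leader — when the cap-to-AUG distance drops to roughly 40 nt or less, the
43S complex engages the mRNA in a way that occludes cap-proximal starts,
so a fraction of ribosomes scans past and initiates at the next in-frame
AUG. The product is an N-terminally truncated isoform, frequently with a
different localization (a cleavable mitochondrial presequence is exactly
the kind of N-terminal element such truncations remove).

`leakyscan` treats the spliced 5' UTR length as the central quantity and
asks three questions at genome scale:

1. Do genes with short leaders (≤ 40 nt, inclusive) produce N-terminal
   truncations more often? (initiation calls from start-site ribosome
   profiling are an *input*; the package bins genes by UTR length and
   compares proportions.)
2. Where does transcription actually start? CAGE read 5' ends give
   single-nucleotide transcription start sites (CTSS); each one is placed
   relative to a gene's start codon to detect alternative promoters that
   lengthen the leader, shorten it, or exclude the start codon entirely.
3. Which clinical variants move a transcript across the 40 nt boundary?
   A ClinVar-style indel screen computes signed UTR-length changes and
   classifies the predicted scanning consequence.

## Conventions and parameters

Coordinates are 1-based and closed internally — the native convention of
the GRanges/IRanges infrastructure this package is built on — with GTF read
as-is and all emitted BED/bedGraph converted to 0-based half-open form at
the boundary. On the minus strand the transcript 5' end is the maximal
exonic coordinate, and `cds_first_base` is the genomic coordinate of the
first base of the start codon in transcript orientation.

The tunable constants, with defaults:

| parameter | default | meaning |
|---|---|---|
| `short_utr_threshold_nt` | 40 | inclusive short-leader regime |
| `ctss_min_tpm` | 1.0 | CTSS filter, tags per million, inclusive |
| `ctss_min_count` | 5 | CTSS filter, raw reads, inclusive |
| `max_assignment_distance_nt` | 50 000 | CTSS-to-start-codon search radius |
| `tss_tolerance_nt` | 10 | window around the annotated UTR length still called `annotated` |
| `min_indel_size_bp` | 10 | inclusive minimum \|Δ\| for variant reports |
| `bin_edges` | 20, 40, 100, 200 | UTR-length bins `(0,20], …, (200,∞)` |

TPM is `count / total_mapped × 10⁶`, with `total_mapped` the accepted read
count of the same filtered stream (primary, mapped alignments only;
duplicates kept; MAPQ threshold configurable, default 0). A read's 5' end
is taken from its aligned span — soft-clipped bases do not shift it —
which is precisely what `bedtools genomecov -5` reports on the alignment;
the test suite asserts bit-level agreement with that tool on toy BAMs.

CTSS-to-gene assignment is same-strand, nearest start codon within the
search radius; ties go to the smaller absolute distance and then the
lexicographically smaller gene id. The signed distance is genomic and
strand-oriented (negative = upstream of the AUG). No CTSS clustering is
performed: positions stay at single-nucleotide resolution, and the
10 nt `annotated` tolerance absorbs focal promoter wobble.

### Implied UTR length

A CTSS upstream of the start codon implies a leader length for the
transcript that would start there. Three geometric cases:

- **inside the representative transcript's exons**: the implied length is
  the spliced distance to the start codon (introns between the CTSS and
  the AUG are excised, as they would be in the mature mRNA);
- **upstream of the annotated transcript 5' end**: the implied length is
  the annotated UTR length plus the genomic gap — the new 5' extension is
  treated as unspliced, which is the parsimonious assumption for a
  promoter a few tens of nt upstream;
- **inside an intron**: no spliced length is defined; classification
  falls back on the genomic distance and the record is classified on that
  basis alone.

The class is then a comparison of implied vs annotated UTR length
(within tolerance → `annotated`; larger → `utr_lengthening`; smaller →
`utr_shortening`), with any CTSS strictly downstream of the start codon
called `cds_truncating` regardless.

### Representative transcripts

One transcript represents each gene. Three strategies are provided:
`highest_expressed` (largest mean TPM over the supplied RNA-seq samples,
equal weight per sample, zero-filled for absent transcripts; if the gene
is entirely unexpressed the longest *spliced* transcript stands in),
`mane_select` (the `MANE_Select`-tagged transcript; genes without one are
excluded and counted), and `longest_cds` (largest spliced CDS length, stop
codon included only insofar as the CDS features include it). All ties
break deterministically: longer spliced transcript, then smaller
transcript id. Where the "longest transcript" fallback was ambiguous
(spliced vs genomic span) we chose spliced length, consistent with every
other length in the package.

### Kozak classification

The 10 nt window −6..+4 around the AUG is classified by the two dominant
determinants only: purine at −3 and G at +4 — both present `strong`,
exactly one `moderate`, neither `weak`. Leaders shorter than 6 nt are
left-padded with `N`, which never counts as a determinant; a leader
shorter than 3 nt therefore cannot be `strong`, which is a fact about
such mRNAs, not an implementation limit.

## The variant engine

From a `variant_summary`-style table the engine keeps the four indel
types on the requested assembly, then applies the literal both-ends rule:
a variant is "in the UTR" iff its start *and* stop coordinates each fall
inside a representative-transcript 5' UTR interval. A variant whose two
ends sit in different UTR exons passes this literal test but is flagged
`spans_intron`, since its effective spliced-length change is not the
genomic span; flagged records are kept visible rather than silently
resolved. Insertions at the UTR/CDS junction fail the rule (their stop
coordinate is the first CDS base) and are excluded.

Signed length changes use genomic coordinates for deletions
(`−(stop − start + 1)`, coordinates assumed to delimit the deleted bases
inclusively) and HGVS `c.` parsing for insertions (+len), duplications
(+span) and delins (len − span). The supported HGVS dialect is strictly
negative positions without intronic offsets; anything else — `c.-10+5del`,
inversions, junction insertions — is routed to an `unparsed` report,
never guessed. When both routes are computable for a deletion they must
agree or the record is flagged discordant; on synthetic data this
agreement is exact by construction and asserted at 100%.

The scanning prediction for a wild-type length `w` and change `Δ` (mutant
`m = w + Δ ≥ 0`, threshold 40 inclusive): `enhanced_leaky_scanning` when
`m ≤ 40 < w` or (`w ≤ 40` and `Δ < 0`); `suppressed_leaky_scanning` when
`w ≤ 40 < m`; otherwise `minimal`. The worked clinical case — a 57 nt
leader losing 30 nt to leave 27 nt — crosses the threshold from above:

```{r}
classify_scanning_effect(57, -30)
```

## The synthetic-data generator

`synth_config()` fixes the study conditions every simulation emulates.
UTR lengths come from a short/long mixture — geometric-like over
1..40 nt with weight 0.35, else a shifted exponential over 41..500 nt —
so that roughly a third of genes sit in the short regime and the long
tail averages near 200 nt, the shape of the human leader-length
distribution. Genes are laid out without overlap on toy chromosomes
(`chrS1..`), each with an alternative promoter of known class; introns
are confined to the CDS/3' region (in transcript orientation) so that
promoter-classification accuracy is measured on promoter geometry, not on
jitter stepping across UTR intron boundaries — unconstrained geometry,
including UTR introns on both strands, is exercised separately by
`random_transcript_models()` in the property tests. CAGE tags are
multinomial across genes, binomial between the two promoters per gene,
jittered `N(0, jitter_sd)` and rounded, with optional uniform background.
Initiation tables follow a two-rate leaky-scanning model
(`p_trunc_short = 0.5` for leaders ≤ 40 nt, `p_trunc_long = 0.1`), and
variant tables draw mostly 1–2 nt events with a heavy ≥ 10 nt tail —
mirroring the observation that most clinical UTR indels are tiny, with
rare large rearrangements.

One PRNG stream per run is forked per stage by fixed labels, so adding a
stage never perturbs earlier draws; identical seed and configuration
reproduce every output byte for byte.

What the generator does *not* emulate — realistic sequence composition,
splice signals, read errors, promoter shape (tag clusters rather than a
jittered point), expression-correlated promoter usage — bounds what
passing tests show: they certify the arithmetic and the classification
logic under known truth, not performance on real CAGE libraries, where
filter thresholds and the 10 nt tolerance interact with biological
dispersion the toy model does not contain.

## Problem sizes and numerical choices

The shipped checks run at desk scale, chosen to make binomial error bars
decisive: 50 toy BAMs of ≤ 1000 reads for the 5'-end oracle; 50 000 tags
across 60 genes for classification accuracy (100% required noise-free,
≥ 95% under ±3 nt jitter) and promoter-weight recovery (within 3 binomial
SE of the 0.5/0.5 truth); 1000 genes × 20 seeds for the truncation-bin
trend; 1000 variants for the round trip. The rank-sum test enumerates the
exact null when `min(n₁, n₂) ≤ 8` and there are no ties, otherwise it
uses the normal approximation with tie and continuity corrections; the
test suite checks the exact branch against full labeling enumeration and
the approximate branch against the exact tie-free null at n = 20
(within 0.01 absolute). Proportions in empty bins are `NA`, a gene with
no annotated-promoter reads gets an undefined (flagged) usage ratio
rather than an infinity, and a UTR of length 0 contributes an empty
interval set and falls in the lowest length bin.

## Known limitations

- Gene-symbol matching (MitoCarta-style lists, variant tables) is
  case-insensitive exact matching; aliases are out of scope.
- The nearest-start-codon assignment is distance-bounded and
  strand-restricted by construction; bidirectional promoters and
  antisense CTSS are left `unassigned`.
- The initiation-site caller's own thresholds are trusted as given; a
  single truncation-site read suffices to call a gene truncated.
- Enrichment analysis (GO/GSEA) and metagene plotting are deliberately
  not reimplemented; the package emits the tables such tools consume.
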