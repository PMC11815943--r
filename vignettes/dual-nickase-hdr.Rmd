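---
title: "Quantifying dual-nickase HDR editing outcomes: models and methods"
author: "nickhdr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dual-nickase HDR editing outcomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The editing system being modelled

nickhdr analyses precise correction of a heterozygous premature-stop point
variant — the model system is the junctional epidermolysis bullosa hotspot
*LAMB3* c.1903C>T (p.R635\*) — by a **dual Cas9-D10A nickase** strategy:
two sgRNAs in PAM-out orientation nick opposite strands ~66 bp apart,
creating a staggered break that is repaired from a short (~130–180 nt)
single-stranded oligodeoxynucleotide (ssODN) template. The template carries:

* the **corrective base** at the pathogenic position;
* one silent **blocking SNV** in each guide's seed/PAM, so the repaired
  allele can no longer be nicked;
* optionally, silent **bridging SNVs** between the proximal nick and the
  correction site (`low`/`medium`/`full` series), which extend the
  conversion tract and raise the incorporation of the distal edit.

Editing outcomes are read out by Nanopore sequencing of a ~700 bp
genotyping amplicon (per-read classification into perfect HDR, imperfect
HDR, indel and unedited), by a ~10.5 kb long amplicon (kilobase-scale
deletion spectrum, including alleles invisible to the short amplicon), by
amplicons over predicted off-target sites (control vs edited comparison),
and by cDNA amplicons (exon inclusion and transcript-level SNV
incorporation).

Coordinates are 1-based closed intervals on the forward strand of the
locus everywhere; genomic coordinates exist only at I/O boundaries through
the locus `coordinate_origin`. The locus sequence is the **target allele as
it exists before editing** (it carries the pathogenic base); the variant's
`alt_base` is the corrective base. This makes every planned SNV a
substitution *relative to the stored sequence*, including the correction.

## Alignment model

Short amplicon and cDNA reads are aligned by exact affine-gap semi-global
dynamic programming (`Biostrings::pairwiseAlignment`, pattern-global /
subject-local): match +2, mismatch −4, gap of length $L$ costs $4 + 2L$,
free end gaps on the reference. `N` mismatches every base and is never
counted as SNV evidence. Both strands are scored and the better one kept;
all coordinates are reported locus-forward.

Long (~10.5 kb) reads are aligned with **minimap2** (map-ont preset,
`--eqx`, secondary alignments suppressed) and ingested through Rsamtools.
minimap2 is the de facto standard for Nanopore amplicons and, under the
map-ont preset, retains even 6-kb deletions as single in-alignment `D`
operations, which is exactly what the deletion profiler consumes. The two
engines emit an identical per-read structure and are cross-checked against
each other in the test suite.

**Identity** is gap-compressed — matches / (matches + mismatches + gap
*events*) — so a single large deletion does not crater a read's identity.
The **full-length filter** retains a read iff its aligned reference span
covers ≥ 90% of the amplicon interval *and* identity ≥ 0.80; both
thresholds are arguments. Rejected reads are flagged with a reason, never
silently dropped.

## Outcome classification

The informative signal for HDR is the set of **silent** template SNVs.
The corrective base alone cannot distinguish a corrected target allele
from the unedited *non-target* allele of a compound-heterozygous patient,
which carries the same base at the variant position — that is precisely
why blocking/bridging SNVs make perfect HDR countable. Reads with no
silent SNV therefore classify as unedited or indel regardless of the
variant-position base.

Per planned SNV the read status is called `template_base`, `ref_base`,
`other`, `deleted` or `uncovered`. The call is a **local haplotype vote**:
the read segment aligned to ±5 bp around the SNV is compared by edit
distance against the two window haplotypes differing only in the focal
base. Single-column base lookup proved fragile in development: next to
short repeats (e.g. the C-run adjacent to a planted PAM) the optimal
alignment can absorb the template base into a gap when a sequencing error
lands nearby, mis-reading the column. The vote is robust to such ambiguous
gap placement; a tie (typically a third base from a sequencing error)
is `other` and carries no haplotype information, so it is excluded from
the decision rather than counted against perfect HDR. Excluding
uninformative columns keeps the error-induced perfect→imperfect leakage
symmetric and small instead of systematically deflating perfect HDR.

Window indels shorter than `min_indel_len` (default 3 bp) are attributed
to sequencing error: single-base indels are the dominant Nanopore error
mode and are indistinguishable per read from true 1-bp end-joining events
at these error rates. Real nick-site indels from a staggered dual-nick
break are typically larger. The decision rules, applied in order over the
quantification window (default: left nick −10 to right nick +10, indels
overlapping the boundary count as in-window):

1. window indel present and **no** silent SNV at the template base → `indel`;
2. ≥1 informative silent SNV, **every** informative planned SNV at the
   template base, no window indel → `perfect_hdr`;
3. ≥1 silent SNV at the template base otherwise (partial incorporation,
   or full incorporation with an indel) → `imperfect_hdr`;
4. otherwise → `indel` if a window indel is present, else `unedited`.

Reads are `discarded` (with a reason code) when the full-length filter
rejects them, the window is not covered, or the correction position lies
outside the aligned span. Fractions are computed over retained reads with
Wilson 95% CIs; a summary from fewer than `min_reads` (default 10,000)
retained reads is flagged low-coverage. Per-SNV incorporation is the
template-base fraction among informative covering reads — an SNV with no
informative coverage reports `NA`, not 0.

## Template design

`design_template()` centres the template on the correction position at the
requested `total_length`. Homology arms are measured from the outermost
planned SNV to the template ends and must each reach `arm_length`
(default 40 bp); otherwise the design errors as infeasible. With nicks
66 bp apart and blocking SNVs in the seeds, the outermost SNVs span more
than 52 bp, so a 132-nt template cannot satisfy 40-bp arms — the classic
132/40 geometry is feasible for more closely spaced pairs (demonstrated on
the compact toy locus), while the bundled full-size locus uses 160–180 nt
templates.

Deterministic selection rules (ties never fall to chance):

* **blocking SNV**: candidate positions are the 10 PAM-proximal protospacer
  bases (seed) then the PAM GG; within a tier, prefer third codon
  positions, then transitions, then PAM proximity. Every candidate must be
  synonymous under the locus CDS model and must not create a new NGG
  overlapping either guide footprint.
* **bridging SNVs**: synonymous positions strictly between the proximal
  nick (the nick closest to the variant) and the correction site, taken
  nick-proximal first; `low`/`medium`/`full` take 1/2/all. The series is
  nested by construction.
* `verify_silent()` translates the affected codon in frame (exon splicing
  and `cds_frame` respected) with and without the substitution; the tests
  check it against an independent whole-CDS translation oracle.
* every design must pass `renick_check()` for both guides (corrected
  haplotype no longer matches protospacer+PAM exactly).

The ssODN is emitted complementary to the proximal guide's non-target
(PAM-containing) strand, the orientation reported to maximise conversion
of PAM-out designs.

## The synthetic-data generator

The study deposited no sequencing data, so validation rests on a seedable
generator whose defaults encode the study conditions:

* **heterozygous baseline**: 50% target allele (T) : 50% non-target
  allele (C) at the variant position;
* **editing-outcome mixture** (`hdr_outcome_mixture()`): perfect HDR 0.48,
  imperfect HDR 0.12 (distal blocking SNV missing), nick-site deletion
  0.18 (21 bp at a nick), unedited target 0.11, non-target 0.11;
* **deletion mixture** (`large_deletion_mixture()`): intact 0.80, 1.5-kb
  deletion distal to the short amplicon 0.10, 6-kb deletion removing both
  short-amplicon primers 0.05, 300-bp deletion of the target exon 0.05;
* **error model**: i.i.d. per-base errors, substitutions 2%, insertions
  0.25%, deletions 0.25%, indel lengths geometric with 90% single-base
  events capped at 10 bp — the magnitude and 1-bp-dominated indel
  structure of current Nanopore chemistry. Qualities are a constant Q12
  placeholder; the analysis is alignment-based.

PCR capture is modelled physically: an allele whose primer footprint is
disrupted by a deletion or indel yields **no** product for that amplicon;
its weight is renormalised over capturable alleles (requested read counts
stay exact) and the capture table records the bias, so genotyping evasion
is an emergent property of the simulation, not an annotation. cDNA reads
are spliced-transcript sequences with independent per-read exon-inclusion
(default 0.40) and template-SNV carrier status.

What the generator does **not** emulate: context-dependent (homopolymer)
Nanopore error, chimeric reads, PCR duplicates and polymerase bias, or
partial conversion tracts with junction microhomology. Passing tests
demonstrate correctness of the analysis logic under realistic error
magnitudes, not performance on every artefact of real flow cells.

## Deletion spectrum

Per-read deletions ≥ `min_deletion_size` (default 50 bp, separating large
deletions from nick-site indels) are clustered when start *and* end lie
within `breakpoint_tol` (default 20 bp) of a cluster's breakpoints;
cluster breakpoints are support-weighted medians and clusters below
`min_support` (default 3 reads) are dropped. A read with several
qualifying deletions is binned once, by its largest, so read-weighted bin
proportions sum to 1; all events remain listed in the allele table. The
default size bins (50–500, 500–1000, 1–2 k, 2–5 k, ≥5 kb) expose the 1–2 kb
and >5 kb classes; the last bin is open-ended. **Evasion** is defined by
primer intersection — the physical mechanism by which PCR misses an
allele — not by amplicon-span overlap: a deletion strictly interior to the
amplicon is captured and therefore does not evade.

## Off-target comparison and group contrasts

Per site, the edited-call count (any window indel ≥ `min_indel_len` within
±10 bp of the predicted nick) is compared between control and edited
samples by a two-sided Fisher exact test (exact at near-zero rates),
Bonferroni-corrected across sites. A site is `editing_detected` only when
the corrected p-value clears `alpha` *and* the edited rate exceeds the
control rate. Group contrasts use the standard independent two-sample
t-test (pooled or Welch); the degenerate zero-variance equal-means case
returns p = 1 by convention.

## Transcript stage

Exon inclusion assigns each cDNA read to the exon-including or
exon-skipping isoform by alignment score with a margin rule (default 10
score units; smaller margins are ambiguous and discarded), making
assignment deterministic and testable. Transcript-level SNV incorporation
is restricted to exon-including reads and uses the same haplotype-vote SNV
caller in transcript coordinates, so genomic and transcript estimates are
directly comparable. ddPCR relative expression is target /
√(housekeeper₁ × housekeeper₂); droplet-level Poisson quantification is
upstream instrument software and out of scope. The monoallelic conversion
`expected_allelic_expression()` maps a genomic correction fraction to the
expected fraction of expressing alleles (0.54 on 1 of 2 alleles → 0.27).

## Problem sizes and numerical choices

The validation suite runs the short-amplicon round trip at 10,000 reads
(the conventional minimum analysed depth), the deletion spectrum at 5,000
long reads, and the transcript stage at 10,000 cDNA reads; unit tests use
hundreds of reads. Recovery tolerances follow the binomial scale of each
estimate (3σ bands; ±1.5 percentage points for outcome fractions at
n = 10,000). Wilson intervals are used throughout because outcome
fractions sit near 0 or 1 in several fixtures. Clustering is
order-independent for well-separated alleles and idempotent; all
tie-breaks in template design are lexicographic, never random.

## Known limitations

* Imperfect-HDR sub-events are not characterised (partial tracts are
  counted, not segmented); per-read categories are the deliverable.
* The classifier's error tolerance (`min_indel_len`) trades sensitivity to
  true 1–2 bp end-joining indels for robustness to Nanopore error; with
  short-read chemistry one would lower it.
* Off-target site prediction, BAM export for genome browsers, UMI
  deduplication and base-quality-aware genotyping are out of scope.
* The deletion profiler reports read-weighted frequencies; allele-weighted
  summaries can be derived from the allele table.
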