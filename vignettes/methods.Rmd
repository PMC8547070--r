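---
title: "Methods: comparative alternative splicing across fruit development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative alternative splicing across fruit development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures implemented in
`fruitsplice`, the parameters that matter, the design choices that were
genuinely open, and what the synthetic-data generator does and does not
emulate.

## Study design and scope

The pipeline analyzes a two-stage (immature, ripe), two-replicate design
over several species with fleshy fruits. Its inputs are the *outputs* of
standard upstream tools: per-stage assembled transcript models, a reference
annotation, a genome, transcript TPM tables, junction read-support tables,
and cross-species orthogroups, pairwise similarity hits, and synteny pairs.
Running aligners, assemblers, quantifiers or orthology inference is out of
scope; the package starts where those tools stop.

## Transcriptome filtering

Assembled transcripts are filtered per stage before any splicing analysis,
because spurious isoforms generate spurious events.

* **Junction support.** A junction is novel when its (chromosome, intron
  start, intron end, strand) tuple matches no reference intron (strand-aware
  by default; `ignore_strand` accommodates unstranded junction tables). The
  removal clause "fewer than 4 reads in both replicates or fewer than 10 in
  one replicate" is ambiguous under negation; the implemented KEEP rule is
  `(both >= 4) OR (either >= 10)` — the unique reading under which (4,4) and
  (0,10) survive while (3,9) does not. Junctions absent from the support
  table count as zero reads.
* **Expression.** A transcript needs TPM strictly greater than 1 in both
  replicates of its stage. Transcript-level (not gene-level) expression is
  used; the alternative reading is noted as an open point below.
* **Class codes.** Of the ~15 codes a transcript-comparison tool emits, only
  the behaviour-relevant subset is implemented: `=` (identical intron
  chain; exact coordinates for single-exon transcripts), `u`, `x`, `s`
  (removed), and `o` for every other same-strand overlap (kept), with
  precedence `= > x > s > o > u`.
* **Single-exon rule.** Single-exon transcripts survive only when an
  identical single-exon transcript exists in the reference.
* **Stage merge.** Transcripts are grouped by (chromosome, strand, ordered
  intron chain) — exact coordinates for single-exon models — and the
  transcript with the greatest summed exon length wins; ties break
  lexicographically on transcript id, making the merge deterministic.

The order of the four filters is not dictated by the data; the cascade runs
junction support, expression, class code, single exon. On fixtures the final
transcript set is invariant to reordering (tested), because each planted
artefact violates exactly one filter; pathological real data could be
order-sensitive, which is why the summary table reports per-step counts.

## Event detection and PSI

Events are local, derived from pairwise exon-chain comparison within genes:

* **ES** — a cassette exon with both flanking introns in one form and the
  single skipping intron (same outer boundaries) in another.
* **IR** — an intron whose flanking exons are exactly spanned by one
  continuous exon in the retaining form. Requiring exact outer-boundary
  agreement prevents alternative first/last exons from masquerading as
  retention.
* **A5SS / A3SS** — two introns sharing one boundary and differing at the
  other, with overlapping exons on the shared side (the overlap condition
  stops an inclusion/skip intron pair of an ES event from also being called
  A3SS). Donor/acceptor labels are assigned relative to the transcription
  direction, so the same genomic geometry is A5SS on `+` and A3SS on `-`.

Events are deduplicated by (type, coordinates); membership sets contain all
isoforms compatible with each form, and isoforms compatible with neither are
excluded from the PSI denominator. The inclusion convention is fixed — ES:
exon included; IR: intron retained; A5SS/A3SS: the longer-exon (shorter
intron) form — so that the sign of dPSI is stable.

PSI is the inclusion share of TPM, NA when all member transcripts are
silent. Stage PSI is the arithmetic mean of non-NA replicate PSIs (the
simplest symmetric aggregation; per-sample occurrence is used for the
profile analysis, see below). The occurrence window [0.05, 0.95] is
inclusive at both ends, applied with a numeric slack of 1e-9 so that
boundary values computed in floating point are never dropped. An event with
NA stage PSI gets no occurrence call and counts as "not occurring" in the
stage-specific partition.

Differential splicing reports dPSI = mean(ripe) − mean(immature) and an
empirical p-value: within-stage between-replicate |PSI| differences, pooled
across events inside total-abundance bins (tertiles by default, degrading
gracefully when few events are testable), form the null; the p-value is the
+1-smoothed rank of the observed |dPSI|. This stand-in preserves the
published decision gates (p < 0.05 AND |dPSI| > 0.1). With two replicates
the null is mildly over-dispersed relative to a difference of means, making
the test conservative. No multiple-testing correction is applied by default
(the gates operate on raw p-values); a BH option exists.

## Orthology

Single-copy orthogroups pass through unchanged. In multi-copy orthogroups,
cross-species pairs supported by reciprocal best hit (e-value ≤ 1e-10; ties
on bit score broken by e-value, then gene id) **and** synteny are assembled
into connected components; components with more than one gene per species
are dropped and logged. AND-combination is the strict reading and protects
downstream conservation claims; an OR mode exists for recall-oriented use.
Tuples need not span all species, since conservation only requires pairwise
orthology.

## Conserved events

Each event is represented by the exonic flanks of its representative
junction(s): the retained intron for IR, the skipping junction for ES, and
both alternative junctions for A5SS/A3SS (a match at either suffices).
These junctions uniquely identify each form; an all-junctions mode exists.
Flanks walk outward along the exon chain of a transcript carrying the
junction — for IR and ES that is the spliced (exclusion) form, the only form
in which the junction exists — collecting up to 300 bp of exonic sequence
per side and reverse-complementing on the minus strand; events with less
than 30 bp on either side at every representative junction are excluded and
logged.

Flanks are compared only within an AS type and across species, by local
nucleotide alignment (match +1, mismatch −1, gap open −2, gap extend −1). A
pair matches when **both** the donor-side and acceptor-side flanks align at
identity ≥ 0.6 over ≥ 100 aligned columns; both-flank agreement is the
strict reading of "the paired flanking sequences were similar" (a
single-flank mode exists). Two events are linked when, additionally, their
genes share an orthogroup; conserved clusters are connected components, and
clusters spanning every species are highly conserved.

The `min_len = 100` default deserves explanation, since the thresholds are
tunable and not dictated by any publication. The match rule must separate
orthologous flanks at realistic divergence (substitution rate ~0.1 per
branch, pairwise identity ~0.81) from deeply diverged or unrelated flanks
(rate 0.4, pairwise identity ~0.41). Identity alone cannot do this: at 41%
background identity the *optimal local alignment* is biased toward short,
high-identity segments, and segments of ≥ 30 columns at ≥ 60% identity occur
by chance. Alignment length is the discriminating statistic — at 81%
identity the expected per-column score is positive and alignments extend
essentially end-to-end, while at 41% it is negative and optimal local
alignments stay logarithmically short. With identity 0.6 over ≥ 100 columns
the package recovers 100% of planted clusters at divergence 0.1 and reports
zero matches at 0.4 across seeds (tested). The trade-off: genuinely
conserved events whose flanks are shorter than 100 bp on both
representative junctions cannot match; with 30–300 bp flanks walked across
introns this only affects events hard against a short terminal exon. An
adapter accepts precomputed translated-search hits in tabular form in place
of the built-in scorer.

The counts-table summarizer reports percentages with largest-remainder
rounding at two decimals, so each percentage set sums to exactly 100 — the
convention consistent with published tables of this shape (plain rounding
produces an off-by-0.01 row and a 100.01 total).

## Profiles and clustering

Profiles use the *per-sample* occurrence rule (PSI in window per replicate),
not stage means: the profile compares samples, so each sample must speak for
itself. Orthologue *i* gets bit 1 in a sample when any event of the
corresponding gene occurs there; all-zero orthologues are removed before
distance computation (they carry no information under the binary distance,
which ignores shared absences). A pair of all-zero profiles is assigned
distance 0. Complete linkage is the default (robust to chaining on binary
distances; single and average are available). Species coherence is defined
as the 4-cluster cut of the dendrogram equalling the species partition
exactly.

## The synthetic-data generator

The generator emulates the study's design: 4 species, 2 stages, 2
replicates, orthogroups with one gene per species sharing exon/intron
architecture (4–8 exons of 120–400 bp; background introns 500–2000 bp;
retained introns 80–150 bp so the intron-length contrast is planted), a
configurable event-type mix, conserved events planted at identical positions
in all species with exonic sequence copied from a common ancestor and
mutated per species at `flank_divergence`, species-specific events planted
in one species, stage-specific events with true PSI 0.5 at the "on" stage
and 0.99/0.01 at the other (placing one stage inside and one outside the
occurrence window deterministically), equal stage PSI for conserved events
and a +0.3 ripe shift for nonconserved ones, replicate PSI jitter on the
logit scale, multi-copy orthogroups with RBH/synteny structure, and one
artefact transcript per filter flavour. TPMs are drawn so that the expected
recomputed PSI equals the planted PSI; per-gene totals scale with
`tpm_depth` (default 100) times U(0.5, 2). A single integer seed drives
every draw; equal seeds give byte-identical bundles.

What it does **not** emulate: read-level noise and coverage gradients,
assembly fragmentation beyond the four planted artefact flavours, indels or
rearrangements between orthologous flanks (substitutions only), expression
changes between stages, unequal genome sizes, and paralog interference
beyond one duplicate per multi-copy orthogroup. Green tests therefore
establish the correctness of the *logic* under controlled conditions, not
robustness to every failure mode of real assemblies.

A second, profile-level generator (`simulate_as_profiles`) plants
species-dominant or stage-dominant occupancy directly with bit-flip noise;
it is used to measure the discriminating power of the clustering analysis
over many seeds cheaply.

## Numerical choices and problem sizes

Window bounds use a 1e-9 slack; PSI denominators below machine zero give
NA; merge and RBH ties break lexicographically; connected components use
union-find with order-independent results; percentage tables use
largest-remainder rounding. The test suite runs bundles of 10–40
orthogroups, the detection oracle on 500 random genes (≤ 5 isoforms, ≤ 8
exons), exhaustive Fisher enumeration to N = 20, exhaustive Wilcoxon
enumeration to n + m = 10, and 100 seeded clustering runs — sizes chosen to
exercise every code path while keeping the default suite fast; the same
machinery scales to genome-sized inputs linearly in transcripts and
quadratically in same-type flank pairs.

## Known limitations

Mutually exclusive exons and alternative first/last exons are not modelled.
PSI aggregation to stages is a plain mean; a precision-weighted mean would
need read-level uncertainty that TPM tables do not carry. The differential
test's empirical null is coarse with only two replicates. The conserved-AS
scorer is nucleotide-level; a translated search (via the adapter) is more
sensitive at high divergence. Whether the expression filter should act at
gene level, and whether occurrence for the published stage counts used
stage means or per-replicate calls, are not derivable from the available
description; the package fixes transcript-level and stage means
respectively, and exposes both rules by name.
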