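---
title: "Methods: rule-based amenability triage for splice-switching ASOs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based amenability triage for splice-switching ASOs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asotriage)
```

## Scope and model

`asotriage` decides whether a (likely) pathogenic loss-of-function variant
in a monogenic disorder is a candidate for one of two splice-switching
antisense-oligonucleotide (ssASO) strategies: blocking a variant-created
cryptic splice site, or skipping the internal exon that carries a
truncating variant. It is a *triage* tool, not a predictor: the splicing
outcome of a variant is an input that must have been established
functionally (RT-qPCR, RNA-seq or a minigene assay), and the engine
refuses to treat an unconfirmed splice claim as anything but
`INSUFFICIENT_EVIDENCE`. Out of scope by design: ASO sequence/chemistry
design, splice-effect prediction, gapmer/siRNA knockdown strategies, large
deletions/CNVs/repeat expansions, exon-inclusion compound design, and
UTR-stability ASOs. Gain-of-function and dominant-negative mechanisms are
flagged `OUT_OF_SCOPE` rather than evaluated.

The substrate is a single-transcript model: ordered exons with 1-based
inclusive genomic coordinates, derived introns, CDS bounds on the spliced
transcript, and an optional transcript-oriented sequence. Minus-strand
transcripts are normalized to transcript orientation at build time, so
every downstream rule is strand-agnostic; a property test asserts that
mirroring a transcript to the opposite strand changes no
transcript-coordinate answer. Variants are HGVS-c descriptors from an
explicitly enumerated subset (substitution, del, dup, ins, delins, with
intronic offsets and UTR anchors); anything outside the subset is a hard
parse error, because silently tolerating an unparsed descriptor would
corrupt triage.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `hard_cutoff_nt` | 5 | nt | below this distance to the nearest splice-critical landmark, a blocking ASO cannot spare canonical splicing: reject |
| `recommended_cutoff_nt` | 15 | nt | below this, amenable only conditionally (proximity caution) |
| `deep_intronic_nt` | 100 | nt | strictly beyond this distance from the nearest exon junction a position is deep intronic (the ideal cryptic-splice target) |
| donor region | −3..+6 | nt | exonic/intronic arms of the extended splice donor region |
| acceptor region | −20..+1 | nt | extended splice acceptor region, including the polypyrimidine tract |
| branch window | 18..40 | nt | distance upstream of the intron 3' end where branch points usually reside |
| `size_caution_pct` | 10 | % of CDS | in-frame removal above this attracts a caution (strong predicted-LoF criterion), never an automatic rejection — some proteins tolerate loss of 30 % or more, so the cut is per-gene overridable |
| `hotspot_window_nt` | 90 | nt | half-width of the coding-coordinate neighbourhood scanned around a missense variant |
| `hotspot_min_count` | 3 | count | minimum pathogenic missense records in the exon for a hotspot call |
| `hotspot_majority_fraction` | 0.5 | fraction | minimum missense share among the exon's pathogenic records |

The first seven rows encode published consensus values and are immutable
defaults (still config-exposed, so sensitivity can be explored). The three
hotspot parameters are this package's own operationalization of a
qualitative instruction ("is the exon a mutational hotspot?"); they are
flagged as non-consensus defaults inside every report that uses them.

## Decision trees and design choices

**Node order.** The source decision trees are figures without machinable
structure, so the engine reconstructs the order from the prose:
evidence gate → mechanism route → location gates → distance/frame gates →
domain/hotspot gates → cautions. Node IDs are stable strings
(`evidence_gate`, `canonical_site_gate`, `in_frame`, `domain_gate`, ...),
and every fired node is recorded as (id, question, answer, consequence),
making the verdict reproducible byte-for-byte and auditable from logs
alone.

**Extended splice regions vs the distance gate.** Canonical ±1/±2
dinucleotides and the branch-point window reject a cryptic-splice variant
outright: an ASO covering them would itself destroy canonical splicing.
For the *extended* donor/acceptor regions, the guidance's own
operationalization of "sufficiently removed from the splice regions" is
the 5/15-nt distance rule, so region membership is not an independent
rejection: those positions fall through to the distance gate (which
rejects everything closer than 5 nt anyway) and carry an explicit
splice-region caution. This keeps the behavioural change points exactly at
5 and 15 nt, which the acceptance sweeps verify.

**What distance is measured.** The clearance distance is taken to the
nearest splice-critical *landmark boundary* — the nearer of the nearest
exon junction and the branch-point window edge — and the report records
which one bound. User-supplied branch-point coordinates (e.g., from a
branch-point predictor or a lariat-sequencing experiment) replace the
positional window for their intron.

**Distance conventions.** An intronic offset ±k is k nt from its junction;
the terminal exonic base is at distance 1 (no zero distances). At the
exact midpoint of an odd-length intron the genomic-to-cDNA mapping anchors
on the donor side — a deterministic, documented tie-break matching common
annotation practice. Ranged variants are classified by walking every
pre-mRNA position they touch, so a deletion straddling a junction is
judged by the most constraining landmark inside it and tagged
`SPANS_JUNCTION`.

**Junction codons.** Exon boundaries need not be codon-aligned; skipping
an in-frame exon whose boundary splits a codon fuses two partial codons
into one new codon. The simulator reconstructs that codon locally and
classifies it as `stop_gained`, `junction_synonymous` (the fused codon
keeps the amino acid of the original upstream boundary codon — the residue
at that protein position keeps its identity) or `junction_missense`. A
junction stop is a mandatory rejection; a junction missense is a caution.
Local reconstruction is verified against an independent oracle that
re-translates the entire skipped CDS and diffs the proteins, across more
than a thousand random transcripts. Frameshifted skips report the frame
failure, not a junction event. If the transcript carries no sequence,
junction consequences are reported `undeterminable_no_sequence` rather
than guessed, and a specific "sequence required" error protects every
operation that needs nucleotides.

**Fraction of CDS removed** is denominated by the full CDS including the
stop codon: reproducible without protein-length bookkeeping, and the 10 %
boundary is exercised behaviourally (integer-percent sweep) rather than
assumed.

**Missense path.** All truncating-variant gates apply, then the hotspot
gates; survivors are capped at `CONDITIONALLY_AMENABLE` with a mandatory
expert-review follow-up. This class of variant is the hardest to judge —
if a single residue change abolishes function, removing the whole exon
usually does too — so the engine never auto-approves it.

**Population evidence.** A report that deletion/skipping of the exon is
itself pathogenic is a mandatory rejection, with one escape hatch: a
config-level override that requires an explicit free-text justification
(for gene–disease pairs where in-frame deletion carriers are known to be
substantially milder). Observation of the exon skipped in healthy
individuals is supportive, never gating.

**Allele specificity.** Only gated by zygosity and only for exon-skip
verdicts: a heterozygous exon-skip candidate gets a warning to consider
allele-selective designs; cryptic-splice verdicts get an informational
note that allele specificity is unnecessary (the ASO has no target on the
wild-type allele). Zygosity never changes the amenability category.

**Exon counting.** Exon ordinals count all exons of the transcript,
including non-coding ones; the convention is recorded in the fixture
bundle's metadata, since published variant reports are ambiguous on this
point.

**Conflicting assays** are not adjudicated: the evidence document carries
one consolidated observed effect, and reconciling discordant assays
(e.g., minigene vs patient RNA-seq) is left to the user.

## The synthetic fixture and what it does (not) show

`build_hypothetical_transcript()` is first-class, tested code, not a
stored file. It emulates the anatomy the decision trees care about: ten
exons with mixed frame phases (so junction reconstruction sees phases 0, 1
and 2), deep introns (3,000–5,200 nt, so the deep-intronic archetype sits
1,340 nt from the nearest junction), two functional-domain annotations,
one heterozygous truncating variant in a skippable exon, and a
pathogenic-missense cluster supporting the hotspot archetype. Sizes were
chosen once to be representative of a mid-sized disease gene; the sequence
is random sense codons under a fixed baked-in seed with the few archetype
codons pinned, so all golden results are bit-stable.

What it does not emulate: real splice-site strength, regulatory-element
sequence context, NMD efficiency, tissue-specific isoforms, or any
quantitative transcript fraction behind "partial" events. Passing the
golden suite therefore demonstrates that the rules are implemented
faithfully and deterministically — not that the clinical thresholds
themselves are optimal, which is a property of the underlying guidance,
not of this implementation. The four real-life descriptors (MFSD8, COASY,
NUBPL, TIMMDC1) are hosted on *surrogate* transcripts with the correct
exon/intron geometry around each variant; only parsed offsets and region
classes are asserted against them, never sequence-level claims about the
real genes.

## Numerical and degenerate-input choices

- All coordinates are integer 1-based inclusive; coordinate maps return
  integers and are verified by exhaustive position-by-position walks
  (every exonic and intronic base) on both strands, including the
  round-trip identity genomic → cDNA → genomic.
- BED domain input is 0-based half-open on disk and converted on read;
  the conversion is unit-tested at the off-by-one boundary.
- A transcript must have ≥ 1 exon, non-overlapping exons, introns ≥ 1 nt
  and a CDS divisible by 3; each violation raises a distinct error naming
  the offending exon or coordinate. Single-exon transcripts are valid and
  have no splice landmarks (infinite distances).
- Pure-UTR exons cannot be "skipped in the CDS" (specific error);
  UTR-anchored positional variants parse but route to `OUT_OF_SCOPE`.
- Malformed pathogenic-table rows are rejected individually with a logged
  reason and surface in the hotspot report; they are never dropped
  silently.
- Ranged variants longer than 10 kb are refused (only SNVs and small
  indels are in scope).

## Problem sizes

The test suite sweeps 200 intronic offsets per side for window recovery,
enumerates every base of multi-exon fixtures for the coordinate oracles,
checks junction events against the full-retranslation oracle on 120
random transcripts in the unit suite and 1,000 in the acceptance suite,
and validates 200 random transcripts for structural invariants; the whole
suite runs in a few minutes on one CPU. The acceptance script re-derives
the 5/15/100-nt change points, the 10 % caution boundary and the
worked-example classifications in seconds.

## Known limitations

- Single-ASO, single-exon scope: multi-exon skipping to restore frame
  after an out-of-frame exon loss is only ever emitted as a note.
- The hotspot statistic is a deliberately simple count/majority rule;
  it has no positional weighting and treats the ClinVar-like table as
  ground truth.
- Protein-level questions (foldability of the truncated product, repeat
  domain dispensability) are follow-ups for experts, not computed.
- Indel descriptors are taken as written; left-alignment against the
  transcript sequence is not performed, so equivalent right-aligned
  descriptors are treated as distinct positions.
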