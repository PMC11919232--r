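# asotriage

Deterministic, auditable triage of loss-of-function variants for
splice-switching antisense-oligonucleotide (ssASO) therapy.

## The problem

Individualized (n-of-1) ssASO treatments can rescue a patient's private
(likely) pathogenic variant in two ways:

- **Cryptic-splice blocking** — a variant that creates or activates a
  cryptic splice site (often deep intronic) is sterically masked, so the
  spliceosome reverts to the canonical sites and the full-length protein is
  restored.
- **Exon skipping** — the internal exon carrying a nonsense or frameshift
  variant is masked so it is spliced out, restoring the reading frame and
  yielding an internally truncated, potentially partially functional
  protein.

Whether either strategy applies is a multi-gate clinical judgement over
transcript anatomy and splice-regulatory geometry. For a variant at
distance *d* nucleotides from the nearest splice-critical landmark, the
cryptic-splice tree requires functional confirmation of the splicing
outcome, intact canonical splicing, a position off the canonical ±1/±2
dinucleotides and outside the branch-point window (18–40 nt upstream of the
intron 3' end), and then gates on *d*: *d* < 5 rejects, 5 ≤ *d* < 15 is
conditional, *d* ≥ 15 is amenable, and *d* > 100 (deep intronic) is ideal.
The exon-skipping tree requires an internal coding exon with coding length
*L* ≡ 0 (mod 3), no junction stop codon after fusing the flanking exons,
no overlap with a functional domain, no reports of the exon deletion
itself being pathogenic, and cautions when the skip removes > 10 % of the
coding sequence. Missense variants additionally face a pathogenic-missense
hotspot analysis and are never more than conditionally amenable.

`asotriage` implements this whole framework as a pure rule engine on an
exact transcript/reading-frame model (HGVS-c arithmetic with intronic
offsets, junction-codon reconstruction, strand-aware genomic mapping).
Every verdict carries the ordered trace of the decision nodes that fired,
so a triage call can be audited line by line.

## Worked example

The package ships a deterministic ten-exon hypothetical transcript that
hosts one variant of each archetype the decision trees distinguish
(canonical splice site, branch point, deep intronic cryptic, exonic
cryptic, splice-enhancer disruption, nonsense, missense-in-domain,
missense-in-hotspot):

```r
library(asotriage)
b <- build_hypothetical_transcript()
b$model
#> transcript_model HYP-TX-8V (HYPGENE, strand +)
#>   10 exons, 9 introns; transcript 1201 nt, CDS 951 nt (317 codons)
#>   sequence: present

a <- b$variants[[6]]          # heterozygous nonsense variant c.448C>T
triage(b$model, a$variant, a$evidence, domains = b$domains)
#> verdict: AMENABLE_EXON_SKIP  (c.448C>T)
#>   trace:
#>     1. [route] Which decision tree applies? -> exon_skip/nonsense (truncating variant without splice effect: exon-skipping tree)
#>     2. [internal_exon] Is the exon an internal coding exon (not first/last)? -> TRUE (continue)
#>     3. [in_frame] Is the exon in-frame (120 coding nt divisible by 3)? -> TRUE (continue)
#>     4. [junction_stop] Does the fused exon-exon junction create a stop codon? -> FALSE (continue)
#>     5. [domain_gate] Does the exon encode (part of) a known functional domain? -> FALSE (continue)
#>     6. [population_gate] Is skipping/deletion of this exon itself a reported pathogenic event? -> FALSE (continue)
#>   warning: Large in-frame removal: skipping removes 12.62% of the coding sequence (> 10% is a strong predicted-LoF criterion, though some proteins tolerate 30% or more).
#>   warning: Heterozygous variant: consider an allele-selective ASO so that skipping spares the wild-type allele's transcript.
#>   follow-up: Extensive functional validation of the internally truncated protein (localisation, enzymatic or downstream assays as appropriate for this protein) and exclusion of gain-of-function effects.
#>   follow-up: Consult a protein expert on tolerability of the removed segment (repeat domains may be dispensable).
```

The variant sits in exon 5 (120 coding nt, in-frame, domain-free,
codon-aligned boundaries), so skipping it is viable; the engine still
flags that 12.62 % of the CDS is removed and, because the patient is
heterozygous, that an allele-selective design should be considered.

The same API drives everything else: `classify_region()` for
splice-landmark annotation, `simulate_exon_skip()` /
`reconstruct_junction()` for frame and junction-codon consequences,
`hotspot_score()` for the missense path, `evaluate_patient()` for the
five-criterion patient checklist, and `triage()` as the dispatcher.

### Command line

```sh
Rscript inst/exec/asotriage fixtures export --dir demo
Rscript inst/exec/asotriage triage \
  --gene-model demo/gene_model.json --variants demo/variants.json \
  --domains demo/domains.json --pathogenic-table demo/pathogenic_table.tsv \
  --out-json demo/report.json --out-tsv demo/report.tsv
```

Exit status is 0 for any verdict (a rejection is a result) and 2 on input
validation errors. Transcripts can also be supplied as GFF3 + genomic
FASTA (`--gff3/--fasta/--transcript-id`) and variants as a VCF projected
onto the transcript (`--vcf`).

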