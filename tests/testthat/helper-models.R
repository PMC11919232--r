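# Shared fixture builders and independent oracles.
# Oracles deliberately avoid the package's own arithmetic: coordinate maps
# are checked against exhaustive position-by-position walks of the exon
# list, and junction-codon events against full-CDS re-translation with
# Biostrings.

# model from coding-exon lengths (plus optional UTRs folded into the first
# and last exon), explicit intron lengths
make_model <- function(coding_len, intron_len = NULL, strand = "+",
                       utr5 = 0, utr3 = 0, sequence = NULL, g0 = 1001,
                       id = "TST") {
  n <- length(coding_len)
  exon_len <- coding_len
  exon_len[1] <- exon_len[1] + utr5
  exon_len[n] <- exon_len[n] + utr3
  if (is.null(intron_len)) intron_len <- rep(2000, max(n - 1, 0))
  gs <- ge <- integer(n)
  g <- g0
  for (i in seq_len(n)) {
    gs[i] <- g
    ge[i] <- g + exon_len[i] - 1
    g <- ge[i] + 1 + if (i < n) intron_len[i] else 0
  }
  if (strand == "-") {
    # mirror the layout so that transcript order runs down the genome
    span <- ge[n] + 1000
    new_gs <- span - ge
    new_ge <- span - gs
    gs <- new_gs
    ge <- new_ge
  }
  build_transcript(list(
    transcript_id = id, gene_symbol = "TSTGENE", strand = strand,
    exons = data.frame(genomic_start = gs, genomic_end = ge),
    cds_start = utr5 + 1, cds_end = utr5 + sum(coding_len),
    sequence = sequence))
}

# deterministic CDS from codon overrides
make_cds_sequence <- function(n_codons, overrides = list(), seed = 7L) {
  codons <- asotriage:::with_seed(seed, {
    cd <- sample(setdiff(asotriage:::all_codons(), c("TAA", "TAG", "TGA")),
                 n_codons, replace = TRUE)
    cd
  })
  codons[1] <- "ATG"
  codons[n_codons] <- "TAA"
  for (k in names(overrides)) codons[as.integer(k)] <- overrides[[k]]
  paste(codons, collapse = "")
}

# --- oracle: exhaustive transcript-position walk ------------------------
# independently enumerates (transcript position -> genomic coordinate) by
# walking each exon base by base in transcript orientation
oracle_t2g_table <- function(model) {
  out <- integer(0)
  for (i in seq_len(nrow(model$exons))) {
    e <- model$exons[i, ]
    g <- if (model$strand == "+") seq(e$genomic_start, e$genomic_end)
         else seq(e$genomic_end, e$genomic_start)
    out <- c(out, g)
  }
  out  # index = transcript position
}

# --- oracle: full-CDS re-translation for junction events ----------------
oracle_translate <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     if.fuzzy.codon = "X"))
}

# expected junction event for skipping exon_index, derived only from the
# proteins before and after the skip
oracle_junction_event <- function(model, exon_index) {
  cds <- substr(model$sequence, model$cds_start, model$cds_end)
  e <- model$exons[exon_index, ]
  lo <- max(e$t_start, model$cds_start) - model$cds_start + 1
  hi <- min(e$t_end, model$cds_end) - model$cds_start + 1
  new_cds <- paste0(substr(cds, 1, lo - 1),
                    substr(cds, hi + 1, nchar(cds)))
  stopifnot(nchar(new_cds) %% 3 == 0)
  prot_old <- oracle_translate(cds)
  prot_new <- oracle_translate(new_cds)
  phase <- (lo - 1) %% 3
  if (phase == 0) {
    # removed codons lo..hi map to protein positions; remainder unchanged
    k1 <- (lo - 1) %/% 3
    k2 <- hi %/% 3
    expected <- paste0(substr(prot_old, 1, k1),
                       substr(prot_old, k2 + 1, nchar(prot_old)))
    stopifnot(identical(prot_new, expected))
    return("none")
  }
  k_up <- (lo - 1) %/% 3 + 1
  aa_new <- substr(prot_new, k_up, k_up)
  aa_old <- substr(prot_old, k_up, k_up)
  if (aa_new == "*") "stop_gained"
  else if (aa_new == aa_old) "junction_synonymous"
  else "junction_missense"
}

# expected consequence of a coding substitution via whole-CDS mutation and
# re-translation
oracle_substitution_consequence <- function(model, pos, alt) {
  cds <- substr(model$sequence, model$cds_start, model$cds_end)
  mut <- cds
  substr(mut, pos, pos) <- alt
  p_wt <- oracle_translate(cds)
  p_mut <- oracle_translate(mut)
  if (identical(p_wt, p_mut)) return("synonymous")
  k <- (pos - 1) %/% 3 + 1
  if (substr(p_mut, k, k) == "*") "nonsense" else "missense"
}

verdict_rank <- function(category) {
  match(category, c("AMENABLE_CRYPTIC_SPLICE_BLOCK", "AMENABLE_EXON_SKIP",
                    "CONDITIONALLY_AMENABLE", "NOT_AMENABLE"))
}

cryptic_ev <- function(effect = "cryptic_donor_created",
                       intact = "yes", assay = "rna_seq")
  splice_evidence(effect, intact, assay)
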