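#' @title Format readers and writers
#' @description Gene-model JSON, GFF3+FASTA, BED domains, ClinVar-like TSV
#'   tables, per-variant JSON documents, VCF input and the JSON/TSV report.
#'   On-disk BED intervals are 0-based half-open (the standard) and are
#'   converted to the internal 1-based inclusive convention on read.
#' @name io
NULL

#' Read a gene-model JSON document into a transcript model
#'
#' Schema: \code{transcript_id}, \code{gene_symbol}, \code{strand},
#' \code{exons} (array of \code{genomic_start}/\code{genomic_end}),
#' \code{cds_start}, \code{cds_end} (spliced-transcript coordinates of the
#' CDS bounds), optional \code{sequence} (spliced, transcript-oriented).
#'
#' @param path Path to the JSON file.
#' @return A \code{transcript_model}.
#' @export
read_gene_model_json <- function(path) {
  build_transcript(jsonlite::fromJSON(path))
}

#' Write a transcript model as gene-model JSON
#' @param model A \code{transcript_model}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gene_model_json <- function(model, path) {
  doc <- list(transcript_id = model$transcript_id,
              gene_symbol = model$gene_symbol,
              strand = model$strand,
              exons = model$exons[, c("genomic_start", "genomic_end")],
              cds_start = model$cds_start,
              cds_end = model$cds_end)
  if (!is.null(model$sequence)) doc$sequence <- model$sequence
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transcript model from GFF3 + genomic FASTA
#'
#' Reads the exon and CDS features of one mRNA and produces a model
#' identical to the JSON route for equivalent content, including the
#' spliced transcript sequence extracted from the FASTA (reverse-complement
#' for minus-strand transcripts).
#'
#' @param gff3_path GFF3 file with \code{exon} and \code{CDS} features
#'   whose \code{Parent} (or \code{transcript_id}) identifies the mRNA.
#' @param fasta_path Genomic FASTA containing the features' seqnames.
#' @param transcript_id The mRNA identifier to extract.
#' @return A \code{transcript_model}.
#' @export
read_gene_model_gff3 <- function(gff3_path, fasta_path, transcript_id) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  parent <- if ("Parent" %in% names(meta))
    vapply(meta$Parent, function(p) if (length(p)) as.character(p[1]) else
      NA_character_, character(1)) else rep(NA_character_, length(gr))
  belongs <- parent == transcript_id |
    (if ("ID" %in% names(meta)) meta$ID %in% transcript_id else FALSE)
  belongs[is.na(belongs)] <- FALSE
  feats <- gr[belongs]
  if (length(feats) == 0)
    stop("transcript '", transcript_id, "' absent from ", gff3_path)
  types <- as.character(S4Vectors::mcols(feats)$type)
  ex <- feats[types == "exon"]
  cds <- feats[types == "CDS"]
  if (length(ex) == 0) stop("no exon features for '", transcript_id, "'")
  if (length(cds) == 0)
    stop("no CDS features for '", transcript_id, "' (CDS/exon inconsistency)")
  strand <- as.character(BiocGenerics::strand(ex))[1]
  if (!strand %in% c("+", "-")) stop("transcript strand must be + or -")

  exdf <- data.frame(genomic_start = BiocGenerics::start(ex),
                     genomic_end = BiocGenerics::end(ex))
  exdf <- exdf[order(exdf$genomic_start), ]

  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  seqname <- as.character(GenomeInfoDb::seqnames(ex))[1]
  if (!seqname %in% names(genome))
    stop("seqname '", seqname, "' not in FASTA ", fasta_path)
  gseq <- genome[[seqname]]

  # spliced, transcript-oriented sequence
  pieces <- lapply(seq_len(nrow(exdf)), function(i)
    Biostrings::subseq(gseq, exdf$genomic_start[i], exdf$genomic_end[i]))
  spliced <- do.call(Biostrings::xscat, pieces)
  if (strand == "-")
    spliced <- Biostrings::reverseComplement(spliced)

  # CDS bounds in transcript coordinates from the CDS genomic extremes
  tx_order <- if (strand == "+") seq_len(nrow(exdf)) else rev(seq_len(nrow(exdf)))
  exo <- exdf[tx_order, , drop = FALSE]
  t_end <- cumsum(exo$genomic_end - exo$genomic_start + 1)
  t_start <- t_end - (exo$genomic_end - exo$genomic_start + 1) + 1
  g_to_t <- function(g) {
    i <- which(exo$genomic_start <= g & g <= exo$genomic_end)
    if (length(i) != 1) stop("CDS coordinate ", g, " outside exons ",
                             "(CDS/exon inconsistency)")
    if (strand == "+") t_start[i] + (g - exo$genomic_start[i])
    else t_start[i] + (exo$genomic_end[i] - g)
  }
  cds_g <- c(min(BiocGenerics::start(cds)), max(BiocGenerics::end(cds)))
  cds_t <- sort(c(g_to_t(cds_g[1]), g_to_t(cds_g[2])))

  gene <- S4Vectors::mcols(ex)$gene_symbol
  build_transcript(list(
    transcript_id = transcript_id,
    gene_symbol = if (!is.null(gene)) as.character(gene[1]) else
      NA_character_,
    strand = strand,
    exons = exdf,
    cds_start = cds_t[1], cds_end = cds_t[2],
    sequence = as.character(spliced)))
}

#' Write a transcript model as GFF3 + genomic FASTA
#'
#' Synthesizes a genomic sequence for the transcript's span (exonic bases
#' taken from the model's spliced sequence, intronic and flanking bases
#' random but reproducible from \code{seed}) and writes matching GFF3
#' exon/CDS features. Round-trips through [read_gene_model_gff3()].
#'
#' @param model A \code{transcript_model} carrying its sequence.
#' @param gff3_path,fasta_path Output paths.
#' @param seqname Contig name to use.
#' @param seed Seed for the synthetic intron/flank fill.
#' @return Invisible list of the two paths.
#' @export
write_gene_model_gff3 <- function(model, gff3_path, fasta_path,
                                  seqname = "chr_synthetic", seed = 1L) {
  if (is.null(model$sequence))
    stop("sequence required to export FASTA")
  span_end <- max(model$exons$genomic_end) + 100
  genome <- with_seed(seed, strsplit(random_bases(span_end), "")[[1]])
  for (i in seq_len(nrow(model$exons))) {
    e <- model$exons[i, ]
    piece <- substr(model$sequence, e$t_start, e$t_end)
    if (model$strand == "-")
      piece <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(piece)))
    genome[e$genomic_start:e$genomic_end] <- strsplit(piece, "")[[1]]
  }
  gseq <- Biostrings::DNAStringSet(paste(genome, collapse = ""))
  names(gseq) <- seqname
  Biostrings::writeXStringSet(gseq, fasta_path)

  cds_g <- range(vapply(c(model$cds_start, model$cds_end),
                        function(t) t_to_genomic(model, t), numeric(1)))
  # CDS feature per exon segment intersecting the CDS genomic span
  cds_rows <- list()
  for (i in seq_len(nrow(model$exons))) {
    e <- model$exons[i, ]
    lo <- max(e$genomic_start, cds_g[1])
    hi <- min(e$genomic_end, cds_g[2])
    if (lo <= hi) cds_rows[[length(cds_rows) + 1]] <- c(lo, hi)
  }
  mk <- function(type, s, e, id_attr) {
    sprintf("%s\tasotriage\t%s\t%d\t%d\t.\t%s\t.\t%s",
            seqname, type, s, e, model$strand, id_attr)
  }
  lines <- c("##gff-version 3",
             mk("mRNA", min(model$exons$genomic_start),
                max(model$exons$genomic_end),
                sprintf("ID=%s;gene_symbol=%s", model$transcript_id,
                        model$gene_symbol)),
             vapply(seq_len(nrow(model$exons)), function(i)
               mk("exon", model$exons$genomic_start[i],
                  model$exons$genomic_end[i],
                  sprintf("ID=%s:exon%d;Parent=%s;gene_symbol=%s",
                          model$transcript_id, i, model$transcript_id,
                          model$gene_symbol)), character(1)),
             vapply(seq_along(cds_rows), function(i)
               mk("CDS", cds_rows[[i]][1], cds_rows[[i]][2],
                  sprintf("ID=%s:cds%d;Parent=%s", model$transcript_id, i,
                          model$transcript_id)), character(1)))
  writeLines(lines, gff3_path)
  invisible(list(gff3 = gff3_path, fasta = fasta_path))
}

#' Read functional-domain annotations
#'
#' \code{read_domains_bed()} reads coding-coordinate BED (0-based,
#' half-open on disk: a domain covering coding nucleotides 60..180 is the
#' BED interval \code{59 180}) and converts to 1-based inclusive.
#' \code{read_domains_json()} reads a JSON array of
#' \code{name}/\code{start_c}/\code{end_c}/\code{source} objects already in
#' 1-based inclusive coding coordinates.
#'
#' @param path Input file.
#' @return A list of [domain_annotation()] objects.
#' @export
read_domains_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("domain BED needs >= 4 columns (chrom start end name)")
  lapply(seq_len(nrow(bed)), function(i)
    domain_annotation(bed[i, 4], bed[i, 2] + 1, bed[i, 3],
                      source = paste0("bed:", bed[i, 1])))
}

#' @rdname read_domains_bed
#' @export
read_domains_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(doc, function(d)
    domain_annotation(d$name, d$start_c, d$end_c, d$source %||% "json"))
}

#' Read a ClinVar-like pathogenic-variant table (TSV)
#'
#' Documented header: \code{position_c}, \code{consequence},
#' \code{classification}, optional \code{functional_lof} (TRUE/FALSE/NA).
#'
#' @param path TSV file with a header row.
#' @return A data frame ready for [hotspot_score()].
#' @export
read_pathogenic_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position_c", "consequence", "classification")
  if (!all(need %in% names(tab)))
    stop("pathogenic table must have columns ",
         paste(need, collapse = ", "))
  if (!is.null(tab$functional_lof))
    tab$functional_lof <- as.logical(tab$functional_lof)
  tab
}

#' Read per-variant documents (descriptor + evidence) from JSON
#'
#' A JSON array; each element carries \code{hgvs_c}, optional
#' \code{zygosity} and \code{mechanism}, an \code{evidence} object
#' (\code{observed_effect}, \code{canonical_splicing_intact}, \code{assay},
#' \code{affected_exon_index}) and an optional \code{population} object
#' (\code{seen_skipped_in_healthy}, \code{skip_known_pathogenic}).
#'
#' @param path JSON file.
#' @return A list of entries with \code{variant} (parsed),
#'   \code{evidence}, \code{mechanism}, \code{population}.
#' @export
read_variant_documents <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(doc, function(d) {
    if (is.null(d$hgvs_c)) stop("variant document lacks field 'hgvs_c'")
    ev <- d$evidence %||% list()
    pop <- d$population %||% list()
    list(
      variant = parse_hgvs_c(d$hgvs_c, zygosity = d$zygosity %||% "unknown"),
      evidence = splice_evidence(
        observed_effect = ev$observed_effect %||% "unknown",
        canonical_splicing_intact = ev$canonical_splicing_intact %||%
          "unknown",
        assay = ev$assay %||% "none",
        affected_exon_index = ev$affected_exon_index),
      mechanism = d$mechanism %||% "lof",
      population = population_evidence(
        pop$seen_skipped_in_healthy %||% NA,
        pop$skip_known_pathogenic %||% NA))
  })
}

#' Read variants from a VCF pre-mapped to a transcript
#'
#' Accepts plain-text VCF whose records lie on the transcript's contig in
#' the same genome the model's exon coordinates use (the package performs
#' the chromosomal-to-transcript projection; it does not lift over genome
#' builds). Only single-nucleotide substitutions plus simple
#' anchored indels are supported. Strand-aware: REF/ALT of minus-strand
#' transcripts are complemented into transcript orientation.
#'
#' @param vcf_path VCF file.
#' @param model The \code{transcript_model} mapping sidecar.
#' @param chrom Optional contig filter.
#' @return A list of \code{variant_descriptor} objects.
#' @export
read_variants_vcf <- function(vcf_path, model, chrom = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL,
    names(fx)))
  comp <- function(b) chartr("ACGT", "TGCA", b)
  out <- list()
  for (i in seq_len(nrow(fx))) {
    if (!is.null(chrom) && fx[i, "CHROM"] != chrom) next
    pos <- as.numeric(fx[i, "POS"])
    ref <- toupper(fx[i, "REF"])
    alt <- toupper(fx[i, "ALT"])
    if (nchar(ref) == 1 && nchar(alt) == 1) {
      loc <- map_genomic_to_c(model, pos)
      if (model$strand == "-") { ref <- comp(ref); alt <- comp(alt) }
      prefix <- switch(loc$region, utr5 = "-", utr3 = "*", "")
      off <- if (loc$offset == 0) "" else sprintf("%+d", loc$offset)
      out[[length(out) + 1]] <-
        parse_hgvs_c(sprintf("c.%s%d%s%s>%s", prefix, loc$pos, off, ref,
                             alt))
    } else if (nchar(ref) > 1 && nchar(alt) == 1 &&
               substr(ref, 1, 1) == alt) {
      if (model$strand == "-")
        stop("anchored indel projection is supported on plus-strand ",
             "transcripts only; supply HGVS-c directly for ", fx[i, "POS"])
      s <- map_genomic_to_c(model, pos + 1)
      e <- map_genomic_to_c(model, pos + nchar(ref) - 1)
      if (s$region != "coding" || e$region != "coding" ||
          s$offset != 0 || e$offset != 0)
        stop("indel at ", pos, " is not fully exonic-coding; supply HGVS-c ",
             "directly")
      out[[length(out) + 1]] <- parse_hgvs_c(
        if (s$pos == e$pos) sprintf("c.%ddel", s$pos)
        else sprintf("c.%d_%ddel", s$pos, e$pos))
    } else if (nchar(alt) > 1 && nchar(ref) == 1 &&
               substr(alt, 1, 1) == ref) {
      if (model$strand == "-")
        stop("anchored indel projection is supported on plus-strand ",
             "transcripts only; supply HGVS-c directly for ", fx[i, "POS"])
      s <- map_genomic_to_c(model, pos)
      if (s$region != "coding" || s$offset != 0)
        stop("insertion at ", pos, " is not exonic-coding; supply HGVS-c ",
             "directly")
      out[[length(out) + 1]] <- parse_hgvs_c(
        sprintf("c.%d_%dins%s", s$pos, s$pos + 1, substr(alt, 2,
                                                         nchar(alt))))
    } else {
      stop("unsupported VCF allele pair ", ref, ">", alt, " at ", pos)
    }
  }
  out
}

#' Write the triage report (JSON + TSV summary)
#'
#' The JSON report carries, per variant, the verdict category, warnings,
#' required follow-ups, notes and the full ordered rule trace, plus the
#' configuration snapshot and tool version; the TSV is a one-line-per-variant
#' summary.
#'
#' @param verdicts A list of \code{verdict} objects.
#' @param json_path,tsv_path Output paths (either may be \code{NULL}).
#' @return Invisible list of paths written.
#' @export
write_report <- function(verdicts, json_path = NULL, tsv_path = NULL) {
  version <- as.character(utils::packageVersion("asotriage"))
  if (!is.null(json_path)) {
    doc <- list(
      tool = "asotriage", version = version,
      config = verdicts[[1]]$config,
      results = lapply(verdicts, function(v) list(
        variant = v$variant, transcript_id = v$transcript_id,
        region_class = v$region_class, category = v$category,
        warnings = v$warnings, required_followups = v$required_followups,
        notes = v$notes, trace = v$trace)))
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    df <- do.call(rbind, lapply(verdicts, function(v) data.frame(
      variant = v$variant, transcript_id = v$transcript_id,
      region_class = v$region_class, category = v$category,
      n_warnings = length(v$warnings),
      warnings = paste(v$warnings, collapse = " | "),
      stringsAsFactors = FALSE)))
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(json = json_path, tsv = tsv_path))
}

#' Export a fixture bundle to disk
#'
#' Writes the gene-model JSON, the per-variant JSON documents, the domain
#' annotations (JSON), the pathogenic table (TSV) and optionally a
#' GFF3+FASTA pair, so the CLI can be exercised end-to-end from generated
#' files.
#'
#' @param bundle A [build_hypothetical_transcript()] bundle.
#' @param dir Output directory (created if needed).
#' @param gff3 Also write GFF3+FASTA?
#' @return Named list of paths.
#' @export
export_fixture_bundle <- function(bundle, dir, gff3 = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    gene_model = file.path(dir, "gene_model.json"),
    variants = file.path(dir, "variants.json"),
    domains = file.path(dir, "domains.json"),
    pathogenic_table = file.path(dir, "pathogenic_table.tsv"))
  write_gene_model_json(bundle$model, paths$gene_model)
  vdoc <- lapply(bundle$variants, function(a) list(
    hgvs_c = format_hgvs_c(a$variant),
    zygosity = a$variant$zygosity,
    evidence = list(
      observed_effect = a$evidence$observed_effect,
      canonical_splicing_intact = a$evidence$canonical_splicing_intact,
      assay = a$evidence$assay,
      affected_exon_index = a$evidence$affected_exon_index)))
  jsonlite::write_json(vdoc, paths$variants, auto_unbox = TRUE,
                       digits = NA, null = "null")
  jsonlite::write_json(lapply(bundle$domains, unclass), paths$domains,
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(bundle$pathogenic_table, paths$pathogenic_table,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (gff3) {
    paths$gff3 <- file.path(dir, "gene_model.gff3")
    paths$fasta <- file.path(dir, "genome.fa")
    write_gene_model_gff3(bundle$model, paths$gff3, paths$fasta)
  }
  paths
}
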