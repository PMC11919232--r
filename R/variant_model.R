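#' @title Variant descriptors and splicing evidence
#' @description Parse HGVS-c style variant descriptors (the supported subset
#'   is substitutions, deletions, insertions, duplications and delins, with
#'   intronic offsets and UTR anchors), derive protein-level consequences by
#'   direct codon arithmetic, and bundle variants with their functionally
#'   observed splicing outcome.
#' @name variant_model
NULL

VARIANT_KINDS <- c("substitution", "deletion", "insertion", "duplication",
                   "delins")
ZYGOSITIES <- c("heterozygous", "homozygous", "hemizygous", "unknown")
CONSEQUENCE_CLASSES <- c("missense", "nonsense", "frameshift", "synonymous",
                         "in_frame_indel", "none", "unknown")
OBSERVED_EFFECTS <- c("none", "cryptic_donor_created",
                      "cryptic_acceptor_created", "cryptic_exon_inclusion",
                      "partial_exon_skipping", "exon_skipping",
                      "intron_retention", "multi_exon_disruption", "unknown")
ASSAYS <- c("rt_qpcr", "rna_seq", "minigene", "none")

# position token: optional UTR marker, digits, optional signed intronic offset
POS_RE <- "([*-]?)(\\d+)([+-]\\d+)?"

parse_pos_token <- function(m) {
  region <- switch(m[1], "-" = "utr5", "*" = "utr3", "coding")
  list(region = region, pos = as.integer(m[2]),
       offset = if (m[3] == "") 0L else as.integer(m[3]))
}

#' Parse an HGVS-c variant descriptor
#'
#' Supports the subset needed for splice-ASO triage: \code{c.N}, \code{c.N+k},
#' \code{c.N-k}, \code{c.-N} / \code{c.*N} UTR anchors, ranges
#' (\code{c.N_M}), and the events \code{REF>ALT}, \code{del[BASES]},
#' \code{dup[BASES]}, \code{ins BASES}, \code{delins BASES}. Anything else —
#' protein-level notation, repeat notation, uncertain breakpoints,
#' whole-gene/multi-exon deletion syntax — is a hard parse error naming the
#' offending token: silent tolerance would corrupt triage.
#'
#' @param raw The descriptor string, e.g. \code{"c.754+2T>A"}.
#' @param zygosity One of \code{"heterozygous"}, \code{"homozygous"},
#'   \code{"hemizygous"}, \code{"unknown"} (default). Zygosity only gates
#'   the allele-specificity warning, never the amenability category.
#' @return A list of class \code{"variant_descriptor"} with fields
#'   \code{raw}, \code{kind}, \code{region}, \code{anchor_c}, \code{offset},
#'   \code{end_region}, \code{end_anchor_c}, \code{end_offset}, \code{ref},
#'   \code{alt}, \code{zygosity}.
#' @examples
#' parse_hgvs_c("c.754+2T>A")$offset      # 2
#' parse_hgvs_c("c.597-1340A>G")$offset   # -1340
#' parse_hgvs_c("c.1319del")$kind         # "deletion"
#' @export
parse_hgvs_c <- function(raw, zygosity = "unknown") {
  zygosity <- match.arg(zygosity, ZYGOSITIES)
  if (!is.character(raw) || length(raw) != 1 || is.na(raw))
    stop("variant descriptor must be a single string")
  s <- trimws(raw)
  if (!startsWith(s, "c."))
    stop("unsupported variant syntax (expected 'c.' prefix): '", raw, "'")
  body <- sub("^c\\.", "", s)

  pos1_re <- paste0("^", POS_RE)
  m <- regmatches(body, regexec(pos1_re, body))[[1]]
  if (length(m) == 0 || m[1] == "")
    stop("cannot parse position token in '", raw, "'")
  p1 <- parse_pos_token(m[-1])
  rest <- substr(body, nchar(m[1]) + 1, nchar(body))

  p2 <- NULL
  if (startsWith(rest, "_")) {
    rest2 <- substr(rest, 2, nchar(rest))
    m2 <- regmatches(rest2, regexec(pos1_re, rest2))[[1]]
    if (length(m2) == 0 || m2[1] == "")
      stop("cannot parse range end token in '", raw, "'")
    p2 <- parse_pos_token(m2[-1])
    rest <- substr(rest2, nchar(m2[1]) + 1, nchar(rest2))
  }

  v <- list(raw = s, region = p1$region, anchor_c = p1$pos,
            offset = p1$offset,
            end_region = (p2 %||% p1)$region,
            end_anchor_c = (p2 %||% p1)$pos,
            end_offset = (p2 %||% p1)$offset,
            ref = "", alt = "", zygosity = zygosity)

  base_re <- "^[ACGTacgt]+$"
  if (grepl("^[ACGTacgt]>[ACGTacgt]$", rest)) {
    if (!is.null(p2))
      stop("substitution cannot carry a position range: '", raw, "'")
    v$kind <- "substitution"
    v$ref <- toupper(substr(rest, 1, 1))
    v$alt <- toupper(substr(rest, 3, 3))
    if (v$ref == v$alt)
      stop("ref and alt are identical in '", raw, "'")
  } else if (grepl("^delins", rest)) {
    ins <- sub("^delins", "", rest)
    if (!grepl(base_re, ins))
      stop("delins requires inserted bases: '", raw, "'")
    v$kind <- "delins"
    v$alt <- toupper(ins)
  } else if (grepl("^del", rest)) {
    del <- sub("^del", "", rest)
    if (del != "" && !grepl(base_re, del))
      stop("unsupported token after 'del': '", raw, "'")
    v$kind <- "deletion"
    v$ref <- toupper(del)
  } else if (grepl("^dup", rest)) {
    dup <- sub("^dup", "", rest)
    if (dup != "" && !grepl(base_re, dup))
      stop("unsupported token after 'dup': '", raw, "'")
    v$kind <- "duplication"
    v$ref <- toupper(dup)
  } else if (grepl("^ins", rest)) {
    ins <- sub("^ins", "", rest)
    if (!grepl(base_re, ins))
      stop("insertion requires inserted bases: '", raw, "'")
    if (is.null(p2))
      stop("insertion requires a two-position flanking range: '", raw, "'")
    v$kind <- "insertion"
    v$alt <- toupper(ins)
  } else if (rest == "" ) {
    stop("descriptor carries no event (del/dup/ins/delins/REF>ALT): '",
         raw, "'")
  } else {
    stop("unsupported variant syntax near '", rest, "' in '", raw, "'")
  }

  # coherent ranges in plain coding coordinates
  if (v$region == "coding" && v$end_region == "coding" &&
      v$offset == 0 && v$end_offset == 0 &&
      v$end_anchor_c < v$anchor_c)
    stop("range end precedes range start in '", raw, "'")
  if (v$kind == "insertion" && v$region == "coding" &&
      v$end_region == "coding" && v$offset == 0 && v$end_offset == 0 &&
      v$end_anchor_c != v$anchor_c + 1)
    stop("insertion flanking positions must be adjacent in '", raw, "'")

  structure(v, class = "variant_descriptor")
}

#' Format a variant descriptor back to its canonical HGVS-c string
#'
#' Round-trip companion of [parse_hgvs_c()]: the produced string re-parses
#' to an identical descriptor.
#'
#' @param v A \code{variant_descriptor}.
#' @return Character scalar.
#' @export
format_hgvs_c <- function(v) {
  fmt_pos <- function(region, pos, offset) {
    prefix <- switch(region, utr5 = "-", utr3 = "*", "")
    off <- if (offset == 0) "" else sprintf("%+d", offset)
    paste0(prefix, pos, off)
  }
  start <- fmt_pos(v$region, v$anchor_c, v$offset)
  ranged <- !(v$end_region == v$region && v$end_anchor_c == v$anchor_c &&
              v$end_offset == v$offset)
  pos_str <- if (ranged)
    paste0(start, "_", fmt_pos(v$end_region, v$end_anchor_c, v$end_offset))
  else start
  ev <- switch(v$kind,
    substitution = paste0(v$ref, ">", v$alt),
    deletion = paste0("del", v$ref),
    duplication = paste0("dup", v$ref),
    insertion = paste0("ins", v$alt),
    delins = paste0("delins", v$alt))
  paste0("c.", pos_str, ev)
}

#' @export
print.variant_descriptor <- function(x, ...) {
  cat(sprintf("variant_descriptor %s (%s, %s)\n", format_hgvs_c(x), x$kind,
              x$zygosity))
  invisible(x)
}

# is the whole event exonic (both ends offset 0)?
variant_is_exonic <- function(v) v$offset == 0 && v$end_offset == 0

# net CDS length change of an indel event (substitutions -> 0)
variant_net_length_change <- function(v) {
  span <- function() {
    if (v$region != "coding" || v$end_region != "coding")
      stop("cannot derive event span for UTR-anchored range: ", v$raw)
    v$end_anchor_c - v$anchor_c + 1
  }
  switch(v$kind,
    substitution = 0L,
    deletion = -(if (nchar(v$ref) > 0) nchar(v$ref) else span()),
    duplication = (if (nchar(v$ref) > 0) nchar(v$ref) else span()),
    insertion = nchar(v$alt),
    delins = nchar(v$alt) - span())
}

codon_aa <- function(codon) {
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  if (any(is.na(aa))) stop("invalid codon(s): ",
                           paste(codon[is.na(aa)], collapse = ", "))
  aa
}

#' Derive the protein-level consequence of an exonic variant
#'
#' Direct codon arithmetic: substitutions are classified by translating the
#' affected codon before and after the change (requires the transcript
#' sequence); indels are classified by their net length change modulo 3.
#' Intronic and UTR variants return class \code{"none"}.
#'
#' @param model A \code{transcript_model}.
#' @param v A \code{variant_descriptor}.
#' @return One of \code{"missense"}, \code{"nonsense"}, \code{"frameshift"},
#'   \code{"synonymous"}, \code{"in_frame_indel"}, \code{"none"}.
#' @export
derive_protein_consequence <- function(model, v) {
  if (!variant_is_exonic(v)) return("none")
  if (v$region != "coding" || v$end_region != "coding") return("none")
  if (v$kind == "substitution") {
    if (is.null(model$sequence))
      stop("sequence required to classify a coding substitution")
    cds <- cds_sequence(model)
    pos <- v$anchor_c
    codon_i <- (pos - 1) %/% 3
    codon <- substr(cds, codon_i * 3 + 1, codon_i * 3 + 3)
    in_codon <- pos - codon_i * 3
    if (substr(codon, in_codon, in_codon) != v$ref)
      stop("reference mismatch at c.", pos, ": model has ",
           substr(codon, in_codon, in_codon), ", descriptor says ", v$ref)
    mut <- codon
    substr(mut, in_codon, in_codon) <- v$alt
    aa_old <- codon_aa(codon)
    aa_new <- codon_aa(mut)
    if (aa_new == aa_old) return("synonymous")
    if (aa_new == "*") return("nonsense")
    return("missense")
  }
  net <- variant_net_length_change(v)
  if (net %% 3 != 0) "frameshift" else "in_frame_indel"
}

#' Splicing-evidence document for one variant
#'
#' The functionally observed splicing outcome of a variant. Triage refuses
#' to treat a splice-affecting claim as confirmed unless an assay backs it
#' (functional confirmation, e.g. RT-qPCR, RNA-seq or a minigene assay, is
#' a precondition of the guidelines).
#'
#' @param observed_effect One of \code{"none"},
#'   \code{"cryptic_donor_created"}, \code{"cryptic_acceptor_created"},
#'   \code{"cryptic_exon_inclusion"}, \code{"partial_exon_skipping"},
#'   \code{"exon_skipping"}, \code{"intron_retention"},
#'   \code{"multi_exon_disruption"}, \code{"unknown"}.
#' @param canonical_splicing_intact One of \code{"yes"}, \code{"no"},
#'   \code{"partial"}, \code{"unknown"}.
#' @param assay One of \code{"rt_qpcr"}, \code{"rna_seq"}, \code{"minigene"},
#'   \code{"none"}.
#' @param affected_exon_index Optional exon ordinal the effect refers to.
#' @return A list of class \code{"splice_evidence"}.
#' @export
splice_evidence <- function(observed_effect = "unknown",
                            canonical_splicing_intact = "unknown",
                            assay = "none",
                            affected_exon_index = NULL) {
  observed_effect <- match.arg(observed_effect, OBSERVED_EFFECTS)
  canonical_splicing_intact <- match.arg(canonical_splicing_intact,
                                         c("yes", "no", "partial", "unknown"))
  assay <- match.arg(assay, ASSAYS)
  structure(list(observed_effect = observed_effect,
                 canonical_splicing_intact = canonical_splicing_intact,
                 assay = assay,
                 affected_exon_index = affected_exon_index),
            class = "splice_evidence")
}

# a splice-affecting claim counts as confirmed only with a real assay
evidence_confirmed <- function(evidence) {
  evidence$observed_effect == "none" || evidence$assay != "none"
}
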