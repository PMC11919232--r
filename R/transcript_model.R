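#' @title Transcript models
#' @description Build and query a single-transcript exon/intron/CDS model.
#'   All downstream coordinate and reading-frame arithmetic (HGVS-c mapping,
#'   splice-window annotation, exon-skip simulation) runs on this structure.
#' @name transcript_model
NULL

#' Build a validated transcript model
#'
#' Constructs the coordinate and reading-frame substrate for triage from a
#' gene-model document: one transcript's exon intervals, strand, CDS bounds
#' and (optionally) its spliced sequence.
#'
#' Conventions: all coordinates are 1-based and inclusive. Exons are stored
#' in transcript orientation (exon 1 is 5'-most on the mRNA); minus-strand
#' input is normalized at build time so that downstream logic is
#' strand-agnostic. \code{cds_start}/\code{cds_end} are positions on the
#' spliced transcript (1..transcript length) of the first and last CDS base
#' (the stop codon's last base).
#'
#' @param doc A list with fields \code{transcript_id}, \code{gene_symbol},
#'   \code{strand} (\code{"+"} or \code{"-"}), \code{exons} (a data frame or
#'   list of \code{genomic_start}/\code{genomic_end} pairs),
#'   \code{cds_start}, \code{cds_end} (transcript coordinates), and optional
#'   \code{sequence} (spliced, transcript-oriented nucleotide string).
#' @return An object of class \code{"transcript_model"} with derived intron
#'   intervals, cumulative transcript coordinates per exon, and CDS length.
#' @examples
#' m <- build_transcript(list(
#'   transcript_id = "TX1", gene_symbol = "GENE1", strand = "+",
#'   exons = data.frame(genomic_start = c(1001, 2001, 3001),
#'                      genomic_end   = c(1120, 2084, 3095)),
#'   cds_start = 1, cds_end = 300))
#' m$cds_length
#' @export
build_transcript <- function(doc) {
  for (f in c("transcript_id", "strand", "exons", "cds_start", "cds_end")) {
    if (is.null(doc[[f]])) stop("gene-model document lacks field '", f, "'")
  }
  strand <- as.character(doc$strand)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")

  ex <- doc$exons
  if (!is.data.frame(ex)) {
    ex <- do.call(rbind, lapply(ex, function(e)
      data.frame(genomic_start = as.numeric(e$genomic_start %||% e[[1]]),
                 genomic_end   = as.numeric(e$genomic_end %||% e[[2]]))))
  }
  ex <- ex[, c("genomic_start", "genomic_end")]
  ex$genomic_start <- as.integer(ex$genomic_start)
  ex$genomic_end <- as.integer(ex$genomic_end)
  if (nrow(ex) < 1) stop("transcript must have at least one exon")
  if (any(ex$genomic_start > ex$genomic_end)) {
    bad <- which(ex$genomic_start > ex$genomic_end)[1]
    stop("exon with genomic_start > genomic_end (input exon ", bad, ")")
  }
  # normalize to transcript orientation
  ord <- order(ex$genomic_start)
  if (strand == "-") ord <- rev(ord)
  ex <- ex[ord, , drop = FALSE]
  rownames(ex) <- NULL
  ex$index <- seq_len(nrow(ex))
  ex$length <- ex$genomic_end - ex$genomic_start + 1L

  # non-overlap / ordering: in genomic order, each exon must end before the
  # next starts (introns have length >= 1)
  g_ord <- ex[order(ex$genomic_start), ]
  if (nrow(g_ord) > 1) {
    gap <- g_ord$genomic_start[-1] - g_ord$genomic_end[-nrow(g_ord)] - 1
    if (any(gap < 1)) {
      i <- which(gap < 1)[1]
      if (gap[i] < 0)
        stop("overlapping exons: exon ending at ", g_ord$genomic_end[i],
             " overlaps exon starting at ", g_ord$genomic_start[i + 1])
      stop("zero-length intron between exon ending at ", g_ord$genomic_end[i],
           " and exon starting at ", g_ord$genomic_start[i + 1])
    }
  }

  ex$t_end <- cumsum(ex$length)
  ex$t_start <- ex$t_end - ex$length + 1L
  tx_len <- sum(ex$length)

  cds_start <- as.integer(doc$cds_start)
  cds_end <- as.integer(doc$cds_end)
  if (cds_start < 1 || cds_end > tx_len || cds_start > cds_end)
    stop("CDS outside exons: CDS bounds [", cds_start, ", ", cds_end,
         "] must lie within the spliced transcript (length ", tx_len, ")")
  cds_len <- cds_end - cds_start + 1
  if (cds_len %% 3 != 0)
    stop("CDS length ", cds_len, " is not divisible by 3")

  introns <- NULL
  if (nrow(ex) > 1) {
    up <- ex[-nrow(ex), ]
    dn <- ex[-1, ]
    introns <- data.frame(
      index = seq_len(nrow(ex) - 1),
      genomic_start = ifelse(rep(strand == "+", nrow(ex) - 1),
                             up$genomic_end + 1, dn$genomic_end + 1),
      genomic_end = ifelse(rep(strand == "+", nrow(ex) - 1),
                           dn$genomic_start - 1, up$genomic_start - 1)
    )
    introns$genomic_start <- as.integer(introns$genomic_start)
    introns$genomic_end <- as.integer(introns$genomic_end)
    introns$length <- introns$genomic_end - introns$genomic_start + 1L
  } else {
    introns <- data.frame(index = integer(0), genomic_start = numeric(0),
                          genomic_end = numeric(0), length = numeric(0))
  }

  sequence <- doc$sequence
  if (!is.null(sequence)) {
    sequence <- toupper(paste(unlist(sequence), collapse = ""))
    if (nchar(sequence) != tx_len)
      stop("sequence length ", nchar(sequence),
           " does not match spliced transcript length ", tx_len)
  }

  structure(list(
    transcript_id = as.character(doc$transcript_id),
    gene_symbol = as.character(doc$gene_symbol %||% NA_character_),
    strand = strand,
    exons = ex[, c("index", "genomic_start", "genomic_end", "length",
                   "t_start", "t_end")],
    introns = introns,
    cds_start = cds_start,
    cds_end = cds_end,
    cds_length = cds_len,
    transcript_length = tx_len,
    sequence = sequence
  ), class = "transcript_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s, strand %s)\n", x$transcript_id,
              x$gene_symbol, x$strand))
  cat(sprintf("  %d exons, %d introns; transcript %d nt, CDS %d nt (%d codons)\n",
              nrow(x$exons), nrow(x$introns), x$transcript_length,
              x$cds_length, x$cds_length %/% 3))
  cat(sprintf("  sequence: %s\n",
              if (is.null(x$sequence)) "absent" else "present"))
  invisible(x)
}

strand_sign <- function(model) if (model$strand == "+") 1L else -1L

# transcript coordinate -> genomic coordinate
t_to_genomic <- function(model, t) {
  i <- which(model$exons$t_start <= t & t <= model$exons$t_end)
  if (length(i) != 1) stop("transcript position ", t, " outside transcript")
  e <- model$exons[i, ]
  as.integer(if (model$strand == "+") e$genomic_start + (t - e$t_start)
             else e$genomic_end - (t - e$t_start))
}

# HGVS-c style (region, pos) -> transcript coordinate.
# region: "coding" (c.N), "utr5" (c.-N), "utr3" (c.*N)
c_to_t <- function(model, pos, region = "coding") {
  t <- switch(region,
    coding = model$cds_start + pos - 1,
    utr5   = model$cds_start - pos,
    utr3   = model$cds_end + pos,
    stop("unknown position region '", region, "'"))
  if (region == "coding" && (pos < 1 || pos > model$cds_length))
    stop("coding position ", pos, " outside CDS (1..", model$cds_length, ")")
  if (t < 1 || t > model$transcript_length)
    stop("position beyond transcript extent (t=", t, ")")
  t
}

t_to_c <- function(model, t) {
  if (t < model$cds_start) list(pos = model$cds_start - t, region = "utr5")
  else if (t > model$cds_end) list(pos = t - model$cds_end, region = "utr3")
  else list(pos = t - model$cds_start + 1, region = "coding")
}

#' Map an HGVS-c position (with optional intronic offset) to a genomic coordinate
#'
#' @param model A \code{transcript_model}.
#' @param pos Anchor position: coding position for \code{region = "coding"},
#'   distance into the UTR otherwise.
#' @param offset Signed intronic offset (0 for exonic positions). A positive
#'   offset must be anchored at the last base of an exon (donor side), a
#'   negative offset at the first base of an exon (acceptor side), matching
#'   HGVS-c anchoring.
#' @param region One of \code{"coding"}, \code{"utr5"}, \code{"utr3"}.
#' @return A single 1-based genomic coordinate, strand-aware.
#' @examples
#' m <- build_transcript(list(
#'   transcript_id = "TX1", gene_symbol = "G", strand = "+",
#'   exons = data.frame(genomic_start = c(1001, 3001),
#'                      genomic_end   = c(1120, 3120)),
#'   cds_start = 1, cds_end = 240))
#' map_c_to_genomic(m, 120)          # 1120, last base of exon 1
#' map_c_to_genomic(m, 120, 1)       # 1121, first intronic base
#' @export
map_c_to_genomic <- function(model, pos, offset = 0, region = "coding") {
  t <- c_to_t(model, pos, region)
  if (offset == 0) return(t_to_genomic(model, t))
  i <- which(model$exons$t_start <= t & t <= model$exons$t_end)
  e <- model$exons[i, ]
  if (offset > 0) {
    if (t != e$t_end)
      stop("positive intronic offset must anchor at an exon's last base ",
           "(anchor t=", t, " is not)")
    if (i == nrow(model$exons))
      stop("no intron downstream of the last exon")
    intr <- model$introns[i, ]
    if (offset > intr$length)
      stop("offset ", offset, " exceeds intron ", i, " length ", intr$length)
  } else {
    if (t != e$t_start)
      stop("negative intronic offset must anchor at an exon's first base ",
           "(anchor t=", t, " is not)")
    if (i == 1) stop("no intron upstream of the first exon")
    intr <- model$introns[i - 1, ]
    if (-offset > intr$length)
      stop("offset ", offset, " exceeds intron ", i - 1, " length ",
           intr$length)
  }
  as.integer(t_to_genomic(model, t) + offset * strand_sign(model))
}

#' Map a genomic coordinate into HGVS-c position-plus-offset form
#'
#' Inverse of [map_c_to_genomic()]. Intronic positions are expressed as an
#' anchor at the nearer exon boundary plus a signed offset; at the exact
#' midpoint of an odd-length intron, the donor-side (\code{+}) anchor wins.
#'
#' @param model A \code{transcript_model}.
#' @param gpos 1-based genomic coordinate within the transcript span.
#' @return A list with \code{pos}, \code{offset}, \code{region} and, for
#'   intronic positions, \code{intron_index}.
#' @export
map_genomic_to_c <- function(model, gpos) {
  span <- range(c(model$exons$genomic_start, model$exons$genomic_end))
  if (gpos < span[1] || gpos > span[2])
    stop("genomic position ", gpos, " outside transcript span [",
         span[1], ", ", span[2], "]")
  hit <- which(model$exons$genomic_start <= gpos &
               gpos <= model$exons$genomic_end)
  if (length(hit) == 1) {
    e <- model$exons[hit, ]
    t <- if (model$strand == "+") e$t_start + (gpos - e$genomic_start)
         else e$t_start + (e$genomic_end - gpos)
    out <- t_to_c(model, t)
    out$offset <- 0L
    return(out)
  }
  ih <- which(model$introns$genomic_start <= gpos &
              gpos <= model$introns$genomic_end)
  if (length(ih) != 1)
    stop("genomic position ", gpos, " outside transcript span")
  i <- model$introns$index[ih]
  donor_t <- model$exons$t_end[i]         # last base of upstream exon
  acceptor_t <- model$exons$t_start[i + 1] # first base of downstream exon
  d_donor <- abs(gpos - t_to_genomic(model, donor_t))
  d_acceptor <- abs(t_to_genomic(model, acceptor_t) - gpos)
  if (d_donor <= d_acceptor) {  # tie -> donor anchor
    out <- t_to_c(model, donor_t)
    out$offset <- d_donor
  } else {
    out <- t_to_c(model, acceptor_t)
    out$offset <- -d_acceptor
  }
  out$intron_index <- i
  out
}

#' Coding nucleotides contributed by one exon
#'
#' @param model A \code{transcript_model}.
#' @param exon_index 1-based exon ordinal in transcript orientation (all
#'   exons counted, including pure-UTR exons).
#' @return Number of coding nucleotides the exon contributes (0 for
#'   pure-UTR exons).
#' @export
exon_coding_length <- function(model, exon_index) {
  e <- get_exon(model, exon_index)
  max(0, min(e$t_end, model$cds_end) - max(e$t_start, model$cds_start) + 1)
}

get_exon <- function(model, exon_index) {
  if (!is.numeric(exon_index) || length(exon_index) != 1 ||
      exon_index < 1 || exon_index > nrow(model$exons) ||
      exon_index != as.integer(exon_index))
    stop("exon index ", exon_index, " out of range (1..",
         nrow(model$exons), ")")
  model$exons[exon_index, ]
}

#' Is an exon an internal coding exon?
#'
#' True iff the exon contributes coding sequence and is neither the exon
#' holding the CDS start nor the exon holding the stop codon. Only internal
#' coding exons are candidates for therapeutic skipping.
#'
#' @inheritParams exon_coding_length
#' @return Logical scalar.
#' @export
is_internal_coding_exon <- function(model, exon_index) {
  e <- get_exon(model, exon_index)
  if (exon_coding_length(model, exon_index) == 0) return(FALSE)
  first_cds_exon <- exon_of_t(model, model$cds_start)
  last_cds_exon <- exon_of_t(model, model$cds_end)
  exon_index != first_cds_exon && exon_index != last_cds_exon
}

exon_of_t <- function(model, t) {
  i <- which(model$exons$t_start <= t & t <= model$exons$t_end)
  if (length(i) != 1) stop("transcript position ", t, " outside transcript")
  i
}

# exon index containing an exonic HGVS-c anchor
exon_of_c <- function(model, pos, region = "coding") {
  exon_of_t(model, c_to_t(model, pos, region))
}

# coding interval [start_c, end_c] of an exon (NULL if pure UTR)
exon_coding_interval <- function(model, exon_index) {
  e <- get_exon(model, exon_index)
  lo <- max(e$t_start, model$cds_start)
  hi <- min(e$t_end, model$cds_end)
  if (lo > hi) return(NULL)
  c(lo - model$cds_start + 1, hi - model$cds_start + 1)
}

# CDS nucleotide string (requires sequence)
cds_sequence <- function(model) {
  if (is.null(model$sequence))
    stop("sequence required: transcript model carries no nucleotide sequence")
  substr(model$sequence, model$cds_start, model$cds_end)
}

#' Domain annotation
#'
#' A named functional-domain interval in coding-nucleotide coordinates
#' (1-based, inclusive, 1..CDS length).
#'
#' @param name Domain name.
#' @param start_c,end_c Coding-nucleotide interval.
#' @param source Free-text provenance.
#' @return A list of class \code{"domain_annotation"}.
#' @export
domain_annotation <- function(name, start_c, end_c, source = "user") {
  if (start_c < 1 || start_c > end_c)
    stop("domain '", name, "': need 1 <= start_c <= end_c")
  structure(list(name = as.character(name), start_c = as.integer(start_c),
                 end_c = as.integer(end_c), source = as.character(source)),
            class = "domain_annotation")
}

validate_domains <- function(model, domains) {
  for (d in domains) {
    if (!inherits(d, "domain_annotation"))
      stop("domains must be domain_annotation objects")
    if (d$end_c > model$cds_length)
      stop("domain '", d$name, "' extends beyond CDS length ",
           model$cds_length)
  }
  invisible(domains)
}
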