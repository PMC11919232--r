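#' @title Exon-skip simulation
#' @description Simulate the removal of one exon from the transcript and
#'   report every consequence the exon-skipping decision tree needs: frame
#'   preservation, fraction of coding sequence removed, the reading-frame
#'   event at the newly fused exon-exon junction, functional-domain overlap
#'   and population evidence.
#' @name exon_skip
NULL

#' Population evidence about skipping/deleting one exon
#'
#' @param seen_skipped_in_healthy \code{TRUE} if the exon is known to be
#'   deleted/skipped in healthy individuals, \code{FALSE} if known not to
#'   be, \code{NA} (default) if unknown.
#' @param skip_known_pathogenic \code{TRUE} if skipping/deletion of the exon
#'   has itself been reported as pathogenic.
#' @return A list of class \code{"population_evidence"}.
#' @export
population_evidence <- function(seen_skipped_in_healthy = NA,
                                skip_known_pathogenic = NA) {
  structure(list(seen_skipped_in_healthy = as.logical(seen_skipped_in_healthy),
                 skip_known_pathogenic = as.logical(skip_known_pathogenic)),
            class = "population_evidence")
}

#' Functional domains overlapping one exon's coding interval
#'
#' @param model A \code{transcript_model}.
#' @param exon_index Exon ordinal.
#' @param domains List of [domain_annotation()] objects (coding-nucleotide
#'   coordinates).
#' @return A data frame with one row per overlapping domain (\code{name},
#'   \code{start_c}, \code{end_c}, \code{overlap_start}, \code{overlap_end},
#'   \code{overlap_nt}, \code{source}); zero rows when nothing overlaps.
#' @export
domain_overlap <- function(model, exon_index, domains = list()) {
  validate_domains(model, domains)
  iv <- exon_coding_interval(model, exon_index)
  empty <- data.frame(name = character(0), start_c = integer(0),
                      end_c = integer(0), overlap_start = integer(0),
                      overlap_end = integer(0), overlap_nt = integer(0),
                      source = character(0))
  if (is.null(iv) || length(domains) == 0) return(empty)
  rows <- lapply(domains, function(d) {
    lo <- max(iv[1], d$start_c)
    hi <- min(iv[2], d$end_c)
    if (lo > hi) return(NULL)
    data.frame(name = d$name, start_c = d$start_c, end_c = d$end_c,
               overlap_start = lo, overlap_end = hi,
               overlap_nt = hi - lo + 1, source = d$source)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Reconstruct the fused codon context created by skipping an exon
#'
#' Exon boundaries are not always codon-aligned: the first or second base
#' of a codon can sit at the boundary. Removing an in-frame exon then fuses
#' the two flanking partial codons into one new codon at the junction. This
#' returns that context: the (up to 2) original boundary-spanning codons and
#' the single fused codon with its translation.
#'
#' @param model A \code{transcript_model} carrying its sequence.
#' @param exon_index Internal coding exon whose coding contribution is
#'   divisible by 3.
#' @return A list with \code{phase} (0, 1 or 2 upstream bases in the split
#'   codon), \code{old_codons}/\code{old_aas} (boundary codons pre-skip),
#'   \code{new_codon}/\code{new_aa} (the fused codon; \code{NA} when the
#'   boundary is codon-aligned) and \code{event} (\code{"none"},
#'   \code{"stop_gained"}, \code{"junction_synonymous"},
#'   \code{"junction_missense"}). A fused codon is called synonymous when
#'   it encodes the same amino acid as the original upstream boundary codon
#'   (the residue at that protein position keeps its identity).
#' @export
reconstruct_junction <- function(model, exon_index) {
  cds <- cds_sequence(model)  # errors when sequence absent
  iv <- exon_coding_interval(model, exon_index)
  if (is.null(iv)) stop("nothing to skip in CDS: exon ", exon_index,
                        " contributes no coding sequence")
  clen <- iv[2] - iv[1] + 1
  if (clen %% 3 != 0)
    stop("junction reconstruction requires a frame-preserving skip (exon ",
         exon_index, " contributes ", clen, " coding nt)")
  if (!is_internal_coding_exon(model, exon_index))
    stop("junction reconstruction requires an internal coding exon")
  s <- iv[1]; e <- iv[2]
  phase <- (s - 1) %% 3
  if (phase == 0) {
    return(list(phase = 0L, old_codons = character(0),
                old_aas = character(0), new_codon = NA_character_,
                new_aa = NA_character_, event = "none"))
  }
  k_up <- (s - 1) %/% 3 + 1   # old codon split at the 5' boundary
  k_dn <- (e - 1) %/% 3 + 1   # old codon split at the 3' boundary
  old_up <- substr(cds, (k_up - 1) * 3 + 1, k_up * 3)
  old_dn <- substr(cds, (k_dn - 1) * 3 + 1, k_dn * 3)
  fused <- paste0(substr(old_up, 1, phase), substr(old_dn, phase + 1, 3))
  new_aa <- codon_aa(fused)
  event <- if (new_aa == "*") "stop_gained"
           else if (new_aa == codon_aa(old_up)) "junction_synonymous"
           else "junction_missense"
  list(phase = as.integer(phase),
       old_codons = c(old_up, old_dn),
       old_aas = codon_aa(c(old_up, old_dn)),
       new_codon = fused, new_aa = new_aa, event = event)
}

#' Simulate skipping one exon
#'
#' @param model A \code{transcript_model}.
#' @param exon_index Exon ordinal to remove (must contribute coding
#'   sequence).
#' @param domains List of [domain_annotation()] objects.
#' @param population_evidence A [population_evidence()] object, or
#'   \code{NULL} for unknown.
#' @return A list of class \code{"skip_simulation_result"} with fields
#'   \code{exon_index}, \code{internal_exon}, \code{coding_nt_removed},
#'   \code{frame_preserved}, \code{fraction_cds_removed} (percent of the
#'   full CDS, stop codon included), \code{junction_event},
#'   \code{junction}, \code{domains_overlapped}, \code{population_flags}.
#'   Frameshifted skips report \code{junction_event = "none"}: the frame
#'   failure, not a junction codon, is the operative consequence.
#' @examples
#' b <- build_hypothetical_transcript()
#' res <- simulate_exon_skip(b$model, 5)
#' res$frame_preserved
#' round(res$fraction_cds_removed, 2)
#' @export
simulate_exon_skip <- function(model, exon_index, domains = list(),
                               population_evidence = NULL) {
  clen <- exon_coding_length(model, exon_index)
  if (clen == 0)
    stop("nothing to skip in CDS: exon ", exon_index,
         " contributes no coding sequence")
  frame_preserved <- clen %% 3 == 0
  internal <- is_internal_coding_exon(model, exon_index)
  junction <- NULL
  if (!frame_preserved || !internal) {
    junction_event <- "none"
  } else if (is.null(model$sequence)) {
    junction_event <- "undeterminable_no_sequence"
  } else {
    junction <- reconstruct_junction(model, exon_index)
    junction_event <- junction$event
  }
  pe <- population_evidence %||% population_evidence()
  structure(list(
    exon_index = as.integer(exon_index),
    internal_exon = internal,
    coding_nt_removed = clen,
    frame_preserved = frame_preserved,
    fraction_cds_removed = 100 * clen / model$cds_length,
    junction_event = junction_event,
    junction = junction,
    domains_overlapped = domain_overlap(model, exon_index, domains),
    population_flags = pe
  ), class = "skip_simulation_result")
}

#' @export
print.skip_simulation_result <- function(x, ...) {
  cat(sprintf("skip_simulation_result: exon %d\n", x$exon_index))
  cat(sprintf("  internal coding exon: %s; frame preserved: %s\n",
              x$internal_exon, x$frame_preserved))
  cat(sprintf("  removes %d coding nt (%.2f%% of CDS); junction event: %s\n",
              x$coding_nt_removed, x$fraction_cds_removed, x$junction_event))
  cat(sprintf("  domains overlapped: %d\n", nrow(x$domains_overlapped)))
  invisible(x)
}
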