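#' Triage one variant through the full decision framework
#'
#' The top-level dispatcher. Routes a variant by its functionally observed
#' splicing outcome and its protein-level consequence:
#' \itemize{
#'   \item declared gain-of-function / dominant-negative mechanism, or a
#'     purely UTR positional variant: \code{OUT_OF_SCOPE} (these guidelines
#'     cover loss-of-function splice correction and exon skipping only);
#'   \item cryptic-splice creation/activation: the cryptic-splice blocking
#'     tree ([evaluate_cryptic_splice()]);
#'   \item canonical-splicing disruption (exon skipping, partial exon
#'     skipping, intron retention, multi-exon disruption): rejection — a
#'     destroyed canonical signal cannot be restored by a blocking ASO; an
#'     exonic/intronic splice-regulatory-element disruption carries the
#'     exon-inclusion-exceptional warning;
#'   \item no splice effect, truncating consequence (nonsense/frameshift):
#'     the exon-skipping tree ([evaluate_truncating()]);
#'   \item no splice effect, missense/in-frame indel: the stricter missense
#'     path with hotspot analysis ([evaluate_missense()]);
#'   \item splice-affecting claims without a confirming assay, or an
#'     entirely unknown effect: \code{INSUFFICIENT_EVIDENCE}.
#' }
#' Identical inputs produce byte-identical verdicts and traces.
#'
#' @param model A \code{transcript_model}.
#' @param v A \code{variant_descriptor}.
#' @param evidence A [splice_evidence()].
#' @param domains List of [domain_annotation()] objects.
#' @param pathogenic_table ClinVar-like data frame for [hotspot_score()],
#'   or \code{NULL}.
#' @param population_evidence A [population_evidence()] object or
#'   \code{NULL}.
#' @param config A [triage_config()].
#' @param mechanism Declared disease mechanism: \code{"lof"} (default),
#'   \code{"gof"} or \code{"dominant_negative"}.
#' @param branch_points Optional per-intron branch-point coordinates (see
#'   [classify_region()]).
#' @return A \code{verdict} with the full ordered rule trace.
#' @examples
#' b <- build_hypothetical_transcript()
#' a <- b$variants[[6]]
#' triage(b$model, a$variant, a$evidence, domains = b$domains)$category
#' @export
triage <- function(model, v, evidence, domains = list(),
                   pathogenic_table = NULL, population_evidence = NULL,
                   config = triage_config(), mechanism = "lof",
                   branch_points = NULL) {
  mechanism <- match.arg(mechanism, c("lof", "gof", "dominant_negative"))
  stopifnot(inherits(model, "transcript_model"),
            inherits(v, "variant_descriptor"),
            inherits(evidence, "splice_evidence"))
  region <- classify_region(model, v, config, branch_points)
  trace <- new_trace()
  fin <- function(category, trace, ...) {
    new_verdict(category, trace, config, ...,
                variant = format_hgvs_c(v),
                transcript_id = model$transcript_id,
                region_class = region$primary_class)
  }

  if (mechanism != "lof") {
    trace <- add_node(trace, "mechanism_scope",
                      "Is the declared disease mechanism loss of function?",
                      FALSE,
                      "GoF/dominant-negative mechanisms need different considerations (transcript knockdown, allele-selective strategies)")
    return(finalize_verdict(
      fin("OUT_OF_SCOPE", trace,
          notes = "Exon skipping of a toxic GoF/DN allele can be considered under the same exon rules, but its therapeutic evaluation is outside this framework."),
      v))
  }

  if (region$primary_class == "UTR" && variant_is_exonic(v)) {
    trace <- add_node(trace, "utr_scope",
                      "Is the variant within the coding/splicing territory these guidelines cover?",
                      FALSE,
                      "UTR variant: transcript-stability ASOs are a different modality")
    return(finalize_verdict(fin("OUT_OF_SCOPE", trace), v))
  }

  eff <- evidence$observed_effect

  if (eff == "unknown") {
    trace <- add_node(trace, "evidence_gate",
                      "Has the variant's splicing outcome been assessed functionally?",
                      FALSE, "splicing outcome unknown; triage cannot proceed")
    return(finalize_verdict(
      fin("INSUFFICIENT_EVIDENCE", trace,
          followups = "Determine the splicing outcome functionally (RT-qPCR, RNA-seq or minigene assay)."),
      v))
  }

  if (eff %in% CRYPTIC_EFFECTS) {
    trace <- add_node(trace, "route",
                      "Which decision tree applies?", "cryptic_splice",
                      "variant creates/activates a cryptic splice site: cryptic-splice blocking tree")
    sub <- evaluate_cryptic_splice(model, v, evidence, region, config)
    sub$trace <- rbind(trace, sub$trace)
    return(finalize_verdict(sub, v))
  }

  if (eff %in% CANONICAL_DISRUPTION_EFFECTS) {
    check_evidence_consistency(model, v, evidence)
    confirmed <- evidence_confirmed(evidence)
    trace <- add_node(trace, "evidence_gate",
                      "Splice effect functionally confirmed (RT-qPCR/RNA-seq/minigene)?",
                      confirmed,
                      if (confirmed) "continue" else "insufficient evidence")
    if (!confirmed)
      return(finalize_verdict(
        fin("INSUFFICIENT_EVIDENCE", trace,
            followups = "Confirm the splicing outcome functionally (RT-qPCR, RNA-seq or minigene assay)."),
        v))
    at_landmark <- any(c("CANONICAL_DONOR", "CANONICAL_ACCEPTOR",
                         "DONOR_REGION", "ACCEPTOR_REGION",
                         "BRANCH_POINT_WINDOW") %in% region$tags)
    trace <- add_node(trace, "canonical_disruption",
                      sprintf("Variant disrupts canonical splicing (%s) from %s.",
                              eff,
                              if (at_landmark) "a splice site/region/branch-point position"
                              else "a splice-regulatory element"),
                      TRUE,
                      "a blocking ASO cannot restore a destroyed canonical splicing signal")
    warnings <- character(0)
    notes <- character(0)
    if (!at_landmark)
      warnings <- c(warnings,
                    "Splice-regulatory-element disruption causing exon skipping: only in exceptional cases can exon inclusion (masking a tandem splice silencer) counteract this; inclusion-compound design is outside this framework.")
    if (eff == "exon_skipping" && !is.null(evidence$affected_exon_index)) {
      clen <- exon_coding_length(model, evidence$affected_exon_index)
      if (clen %% 3 != 0)
        notes <- c(notes,
                   "The skipped exon is out-of-frame: the event behaves like a single-exon deletion with frameshift; skipping adjacent exon(s) to restore the frame could be considered but is outside these single-ASO guidelines.")
    }
    return(finalize_verdict(
      fin("NOT_AMENABLE", trace, warnings = warnings, notes = notes), v))
  }

  # observed_effect == "none": canonical splicing unaffected; route by the
  # protein-level consequence
  if (!variant_is_exonic(v) || v$region != "coding") {
    trace <- add_node(trace, "route",
                      "Which decision tree applies?", "none",
                      "non-coding variant with no splice effect: no in-scope loss-of-function mechanism")
    return(finalize_verdict(fin("OUT_OF_SCOPE", trace), v))
  }
  cons <- derive_protein_consequence(model, v)
  exon_idx <- exon_of_c(model, v$anchor_c)
  if (cons %in% c("nonsense", "frameshift")) {
    trace <- add_node(trace, "route",
                      "Which decision tree applies?",
                      paste0("exon_skip/", cons),
                      "truncating variant without splice effect: exon-skipping tree")
    skip <- simulate_exon_skip(model, exon_idx, domains, population_evidence)
    sub <- evaluate_truncating(model, v, skip, config)
    sub$trace <- rbind(trace, sub$trace)
    return(finalize_verdict(sub, v))
  }
  if (cons %in% c("missense", "in_frame_indel")) {
    trace <- add_node(trace, "route",
                      "Which decision tree applies?",
                      paste0("exon_skip_missense/", cons),
                      "missense/in-frame variant without splice effect: strict missense path")
    skip <- simulate_exon_skip(model, exon_idx, domains, population_evidence)
    hs <- hotspot_score(v, pathogenic_table,
                        exon_coding_interval(model, exon_idx), config)
    sub <- evaluate_missense(model, v, skip, hs, config)
    sub$trace <- rbind(trace, sub$trace)
    return(finalize_verdict(sub, v))
  }
  trace <- add_node(trace, "route",
                    "Which decision tree applies?", paste0("none/", cons),
                    "no loss-of-function mechanism in scope (no splice effect, no truncation, no amino-acid change)")
  finalize_verdict(fin("OUT_OF_SCOPE", trace), v)
}

# appends the allele-specificity outcome to a computed verdict
finalize_verdict <- function(verdict, v) {
  res <- assess_allele_specificity(v, verdict)
  if (length(res) > 0) verdict$warnings <- c(verdict$warnings, res)
  note <- attr(res, "note")
  if (!is.null(note)) verdict$notes <- c(verdict$notes, note)
  verdict
}
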