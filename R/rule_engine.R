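#' @title Amenability decision trees
#' @description The auditable rule engine: the cryptic-splice-blocking tree,
#'   the exon-skipping tree for truncating variants, the stricter missense
#'   path with mutational-hotspot analysis, the allele-specificity check and
#'   the patient-selection checklist. Every evaluation returns a verdict
#'   carrying the ordered trace of decision nodes fired.
#' @name rule_engine
NULL

VERDICT_CATEGORIES <- c("AMENABLE_CRYPTIC_SPLICE_BLOCK", "AMENABLE_EXON_SKIP",
                        "CONDITIONALLY_AMENABLE", "NOT_AMENABLE",
                        "INSUFFICIENT_EVIDENCE", "OUT_OF_SCOPE")

new_trace <- function() {
  data.frame(node_id = character(0), question = character(0),
             answer = character(0), consequence = character(0),
             stringsAsFactors = FALSE)
}

add_node <- function(trace, node_id, question, answer, consequence) {
  rbind(trace, data.frame(node_id = node_id, question = question,
                          answer = as.character(answer),
                          consequence = consequence,
                          stringsAsFactors = FALSE))
}

new_verdict <- function(category, trace, config, warnings = character(0),
                        followups = character(0), notes = character(0),
                        variant = NA_character_,
                        transcript_id = NA_character_,
                        region_class = NA_character_) {
  stopifnot(category %in% VERDICT_CATEGORIES)
  structure(list(category = category, trace = trace,
                 warnings = warnings, required_followups = followups,
                 notes = notes, config = config_snapshot(config),
                 variant = variant, transcript_id = transcript_id,
                 region_class = region_class),
            class = "verdict")
}

#' @export
print.verdict <- function(x, ...) {
  cat(sprintf("verdict: %s", x$category))
  if (!is.na(x$variant)) cat(sprintf("  (%s)", x$variant))
  cat("\n")
  if (nrow(x$trace) > 0) {
    cat("  trace:\n")
    for (i in seq_len(nrow(x$trace)))
      cat(sprintf("   %2d. [%s] %s -> %s (%s)\n", i, x$trace$node_id[i],
                  x$trace$question[i], x$trace$answer[i],
                  x$trace$consequence[i]))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  for (f in x$required_followups) cat("  follow-up:", f, "\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

CRYPTIC_EFFECTS <- c("cryptic_donor_created", "cryptic_acceptor_created",
                     "cryptic_exon_inclusion")
CANONICAL_DISRUPTION_EFFECTS <- c("exon_skipping", "partial_exon_skipping",
                                  "intron_retention", "multi_exon_disruption")

# evidence may name an exon the variant cannot plausibly touch
check_evidence_consistency <- function(model, v, evidence) {
  ae <- evidence$affected_exon_index
  if (is.null(ae)) return(invisible(TRUE))
  pts <- locate_variant_points(model, v)
  touchable <- unlist(lapply(pts, function(pt) {
    if (pt$type == "intronic") c(pt$intron_index, pt$intron_index + 1)
    else pt$exon_index
  }))
  if (!ae %in% touchable)
    stop("evidence/variant mismatch: evidence references exon ", ae,
         " which variant ", format_hgvs_c(v), " cannot touch (adjacent ",
         "exons: ", paste(sort(unique(touchable)), collapse = ", "), ")")
  invisible(TRUE)
}

#' Evaluate a confirmed cryptic-splice variant for ASO blocking
#'
#' The cryptic-splice decision tree: a variant that creates or activates a
#' cryptic splice site can be blocked with a ssASO to restore canonical
#' splicing, provided canonical splicing is intact, the variant does not sit
#' on a canonical dinucleotide or in the branch-point window, and it is far
#' enough from the nearest splice-critical landmark for an ASO to bind
#' without disturbing canonical splicing (hard cut-off 5 nt; recommended
#' 15 nt; ideally deep intronic, >100 nt). Positions inside the extended
#' donor/acceptor regions are not rejected outright — the distance gate is
#' the operational meaning of "sufficiently removed from the splice
#' regions" — but they carry a splice-region caution.
#'
#' @param model A \code{transcript_model}.
#' @param v A \code{variant_descriptor}.
#' @param evidence A [splice_evidence()] whose \code{observed_effect} is one
#'   of the cryptic-splice effects.
#' @param region Optional precomputed [classify_region()] report.
#' @param config A [triage_config()].
#' @return A \code{verdict}.
#' @export
evaluate_cryptic_splice <- function(model, v, evidence, region = NULL,
                                    config = triage_config()) {
  if (!evidence$observed_effect %in% CRYPTIC_EFFECTS)
    stop("evaluate_cryptic_splice requires cryptic-splice evidence ",
         "(observed_effect is '", evidence$observed_effect, "')")
  check_evidence_consistency(model, v, evidence)
  if (is.null(region)) region <- classify_region(model, v, config)
  trace <- new_trace()
  fin <- function(category, ...) {
    new_verdict(category, trace, config, ...,
                variant = format_hgvs_c(v),
                transcript_id = model$transcript_id,
                region_class = region$primary_class)
  }

  confirmed <- evidence_confirmed(evidence)
  trace <- add_node(trace, "evidence_gate",
                    "Splice effect functionally confirmed (RT-qPCR/RNA-seq/minigene)?",
                    confirmed, if (confirmed) "continue" else
                      "insufficient evidence")
  if (!confirmed)
    return(fin("INSUFFICIENT_EVIDENCE",
               followups = "Confirm the splicing outcome functionally (RT-qPCR, RNA-seq or minigene assay)."))

  intact <- evidence$canonical_splicing_intact != "no"
  trace <- add_node(trace, "canonical_intact",
                    "Is canonical splicing still intact?", intact,
                    if (intact) "continue" else
                      "canonical splicing destroyed; an ASO cannot restore it")
  if (!intact) return(fin("NOT_AMENABLE"))

  on_canonical <- any(c("CANONICAL_DONOR", "CANONICAL_ACCEPTOR") %in%
                        region$tags)
  trace <- add_node(trace, "canonical_site_gate",
                    "Variant on a canonical splice dinucleotide (+1/+2 or -1/-2)?",
                    on_canonical,
                    if (on_canonical) "blocking ASO would cover the canonical site"
                    else "continue")
  if (on_canonical) return(fin("NOT_AMENABLE"))

  in_branch <- "BRANCH_POINT_WINDOW" %in% region$tags
  trace <- add_node(trace, "branch_point_gate",
                    "Variant inside the branch-point window (18-40 nt upstream of the intron 3' end)?",
                    in_branch,
                    if (in_branch) "blocking ASO would disrupt the branch point"
                    else "continue")
  if (in_branch) return(fin("NOT_AMENABLE"))

  d <- region$landmark_distance
  warnings <- character(0)
  notes <- character(0)
  followups <- character(0)

  if (region$primary_class %in% c("EXONIC", "UTR")) {
    warnings <- c(warnings,
                  "Exonic cryptic-splice target: an ASO over the exon can cause skipping of the exon altogether; evaluate carefully preclinically.")
    cons <- tryCatch(derive_protein_consequence(model, v),
                     error = function(e) "unknown")
    if (cons %in% c("missense", "nonsense", "frameshift", "in_frame_indel"))
      warnings <- c(warnings,
                    sprintf("Nonsynonymous exonic variant (%s): the amino acid change itself may be disease-causing; splice correction alone may not be therapeutic.",
                            cons))
  }
  if (any(c("DONOR_REGION", "ACCEPTOR_REGION") %in% region$tags))
    warnings <- c(warnings,
                  "Variant lies within the extended splice donor/acceptor region; confirm that canonical splicing is truly unaffected.")

  below_hard <- d < config$hard_cutoff_nt
  trace <- add_node(trace, "distance_hard",
                    sprintf("Distance to nearest splice-critical landmark (%s) >= hard cut-off %d nt? (d = %s)",
                            region$bounding_landmark, config$hard_cutoff_nt,
                            format(d)),
                    !below_hard,
                    if (below_hard) "too close for an ASO to spare canonical splicing"
                    else "continue")
  if (below_hard) return(fin("NOT_AMENABLE", warnings = warnings))

  below_rec <- d < config$recommended_cutoff_nt
  trace <- add_node(trace, "distance_recommended",
                    sprintf("Distance >= recommended cut-off %d nt? (d = %s)",
                            config$recommended_cutoff_nt, format(d)),
                    !below_rec,
                    if (below_rec) "conditionally amenable with proximity caution"
                    else "amenable to cryptic-splice blocking")
  if (below_rec) {
    warnings <- c(warnings,
                  sprintf("Proximity caution: only %s nt from the nearest splice-critical landmark (recommended clearance %d nt).",
                          format(d), config$recommended_cutoff_nt))
    return(fin("CONDITIONALLY_AMENABLE", warnings = warnings,
               followups = "Verify during ASO design that canonical splicing is not disturbed."))
  }
  if (region$primary_class == "DEEP_INTRONIC" &&
      region$distance_to_nearest_splice_site > config$deep_intronic_nt)
    notes <- c(notes,
               sprintf("Deep intronic (%s nt from the nearest exon junction): ideal target; canonical protein restoration expected.",
                       format(region$distance_to_nearest_splice_site)))
  fin("AMENABLE_CRYPTIC_SPLICE_BLOCK", warnings = warnings, notes = notes,
      followups = followups)
}

# shared gates of the exon-skipping tree; returns NULL category when all pass
skip_gates <- function(skip, config, trace) {
  warnings <- character(0)
  notes <- character(0)

  trace <- add_node(trace, "internal_exon",
                    "Is the exon an internal coding exon (not first/last)?",
                    skip$internal_exon,
                    if (skip$internal_exon) "continue" else
                      "first/last coding exon cannot be skipped")
  if (!skip$internal_exon)
    return(list(category = "NOT_AMENABLE", trace = trace,
                warnings = warnings, notes = notes))

  trace <- add_node(trace, "in_frame",
                    sprintf("Is the exon in-frame (%d coding nt divisible by 3)?",
                            skip$coding_nt_removed),
                    skip$frame_preserved,
                    if (skip$frame_preserved) "continue" else
                      "skipping shifts the reading frame")
  if (!skip$frame_preserved) {
    notes <- c(notes,
               "Out-of-frame exon: a multi-exon skipping strategy restoring the frame could be considered but is outside these single-ASO guidelines.")
    return(list(category = "NOT_AMENABLE", trace = trace,
                warnings = warnings, notes = notes))
  }

  stop_gained <- identical(skip$junction_event, "stop_gained")
  trace <- add_node(trace, "junction_stop",
                    "Does the fused exon-exon junction create a stop codon?",
                    stop_gained,
                    if (stop_gained) "junction stop codon truncates the skipped product"
                    else "continue")
  if (stop_gained)
    return(list(category = "NOT_AMENABLE", trace = trace,
                warnings = warnings, notes = notes))

  n_dom <- nrow(skip$domains_overlapped)
  trace <- add_node(trace, "domain_gate",
                    "Does the exon encode (part of) a known functional domain?",
                    n_dom > 0,
                    if (n_dom > 0) sprintf("overlaps %d domain(s): %s", n_dom,
                                           paste(skip$domains_overlapped$name,
                                                 collapse = ", "))
                    else "continue")
  if (n_dom > 0)
    return(list(category = "NOT_AMENABLE", trace = trace,
                warnings = warnings, notes = notes))

  known_path <- isTRUE(skip$population_flags$skip_known_pathogenic)
  trace <- add_node(trace, "population_gate",
                    "Is skipping/deletion of this exon itself a reported pathogenic event?",
                    known_path,
                    if (!known_path) "continue"
                    else if (!is.null(config$skip_override_justification))
                      "override: milder deletion phenotype justified in config"
                    else "exon deletion known pathogenic; skip unlikely therapeutic")
  if (known_path) {
    if (!is.null(config$skip_override_justification)) {
      notes <- c(notes, paste0("Pathogenic-skip override active: ",
                               config$skip_override_justification))
      return(list(category = "CONDITIONALLY_AMENABLE", trace = trace,
                  warnings = warnings, notes = notes))
    }
    return(list(category = "NOT_AMENABLE", trace = trace,
                warnings = warnings, notes = notes))
  }

  if (skip$fraction_cds_removed > config$size_caution_pct)
    warnings <- c(warnings,
                  sprintf("Large in-frame removal: skipping removes %.2f%% of the coding sequence (> %g%% is a strong predicted-LoF criterion, though some proteins tolerate 30%% or more).",
                          skip$fraction_cds_removed, config$size_caution_pct))
  if (identical(skip$junction_event, "junction_missense"))
    warnings <- c(warnings,
                  sprintf("Junction missense: the fused junction codon changes %s to %s.",
                          skip$junction$old_aas[1], skip$junction$new_aa))
  if (identical(skip$junction_event, "undeterminable_no_sequence"))
    warnings <- c(warnings,
                  "Junction codon consequence undeterminable: transcript sequence not provided.")
  if (isTRUE(skip$population_flags$seen_skipped_in_healthy))
    notes <- c(notes,
               "Supportive: this exon is observed skipped/deleted in healthy individuals.")
  list(category = NULL, trace = trace, warnings = warnings, notes = notes)
}

#' Evaluate a truncating (nonsense/frameshift) variant for exon skipping
#'
#' The exon-skipping decision tree: skipping the exon that carries a
#' nonsense or frameshift variant yields a shortened in-frame mRNA and an
#' internally truncated, potentially partially functional protein — if the
#' exon is an internal coding exon, in-frame, free of relevant functional
#' domains, does not create a junction stop codon, and is not itself a
#' reported pathogenic deletion.
#'
#' @param model A \code{transcript_model}.
#' @param v A \code{variant_descriptor}.
#' @param skip A [simulate_exon_skip()] result for the variant's exon.
#' @param config A [triage_config()].
#' @return A \code{verdict}.
#' @export
evaluate_truncating <- function(model, v, skip, config = triage_config()) {
  if (missing(skip) || is.null(skip) ||
      !inherits(skip, "skip_simulation_result"))
    stop("missing skip simulation: run simulate_exon_skip() for the ",
         "variant's exon first")
  g <- skip_gates(skip, config, new_trace())
  fin <- function(category, ...) {
    new_verdict(category, g$trace, config, warnings = g$warnings,
                notes = g$notes, ...,
                variant = format_hgvs_c(v),
                transcript_id = model$transcript_id,
                region_class = "EXONIC")
  }
  if (!is.null(g$category)) return(fin(g$category))
  fin("AMENABLE_EXON_SKIP",
      followups = c("Extensive functional validation of the internally truncated protein (localisation, enzymatic or downstream assays as appropriate for this protein) and exclusion of gain-of-function effects.",
                    "Consult a protein expert on tolerability of the removed segment (repeat domains may be dispensable)."))
}

#' Evaluate a missense / in-frame-indel variant for exon skipping
#'
#' The most difficult class: if the single amino-acid change abolishes
#' protein function, removing the whole exon most likely does too. All
#' truncating-variant gates apply; additionally the exon must not be a
#' pathogenic-missense hotspot and no neighbouring variant may carry
#' functional loss-of-function evidence. Survivors are capped at
#' \code{CONDITIONALLY_AMENABLE} with a mandatory expert review — this path
#' never returns an outright amenable verdict.
#'
#' @inheritParams evaluate_truncating
#' @param hotspot A [hotspot_score()] report for the variant's exon.
#' @return A \code{verdict}.
#' @export
evaluate_missense <- function(model, v, skip, hotspot,
                              config = triage_config()) {
  if (missing(hotspot) || is.null(hotspot) ||
      !inherits(hotspot, "hotspot_report"))
    stop("missing hotspot report: run hotspot_score() for the variant first")
  if (missing(skip) || is.null(skip) ||
      !inherits(skip, "skip_simulation_result"))
    stop("missing skip simulation: run simulate_exon_skip() for the ",
         "variant's exon first")
  g <- skip_gates(skip, config, new_trace())
  fin <- function(category, trace, ...) {
    new_verdict(category, trace, config, warnings = g$warnings,
                notes = g$notes, ...,
                variant = format_hgvs_c(v),
                transcript_id = model$transcript_id,
                region_class = "EXONIC")
  }
  if (!is.null(g$category)) return(fin(g$category, g$trace))

  trace <- add_node(g$trace, "hotspot_gate",
                    sprintf("Is the exon a pathogenic-missense hotspot? (%d pathogenic missense in exon, density %.1f per 100 coding nt)",
                            hotspot$n_pathogenic_missense_in_exon,
                            hotspot$density_per_100nt),
                    hotspot$is_hotspot,
                    if (hotspot$is_hotspot)
                      "mutational hotspot implies the exon encodes an indispensable segment"
                    else "continue")
  if (hotspot$is_hotspot) return(fin("NOT_AMENABLE", trace))

  trace <- add_node(trace, "lof_evidence_gate",
                    "Do neighbouring pathogenic missense variants carry functional LoF evidence?",
                    hotspot$lof_evidence_nearby,
                    if (hotspot$lof_evidence_nearby)
                      "skipping the exon will most likely also cause loss of function"
                    else "continue")
  if (hotspot$lof_evidence_nearby) return(fin("NOT_AMENABLE", trace))

  fin("CONDITIONALLY_AMENABLE", trace,
      followups = c("Mandatory expert review: missense variants are the most difficult class; functional testing of both the variant and the skipped product is required.",
                    "Exclude a cryptic-splice or splice-regulatory mechanism functionally before committing to exon skipping."))
}

#' Attach the allele-specificity assessment to a verdict
#'
#' For heterozygous exonic variants heading to exon skipping, a
#' non-allele-selective ASO would also skip the exon from the healthy
#' allele; allele-selective designs should be considered. For cryptic-splice
#' blocking, allele specificity is not needed — on the wild-type allele the
#' ASO has no target effect.
#'
#' @param v A \code{variant_descriptor} (its \code{zygosity} gates the
#'   warning).
#' @param verdict A \code{verdict}.
#' @return A character vector: the warning (length 1) or \code{character(0)}.
#'   The informational cryptic-splice note is returned via attribute
#'   \code{"note"} when applicable.
#' @export
assess_allele_specificity <- function(v, verdict) {
  if (verdict$category == "AMENABLE_EXON_SKIP" &&
      v$zygosity == "heterozygous") {
    return("Heterozygous variant: consider an allele-selective ASO so that skipping spares the wild-type allele's transcript.")
  }
  if (verdict$category %in% c("AMENABLE_CRYPTIC_SPLICE_BLOCK")) {
    out <- character(0)
    attr(out, "note") <-
      "Allele specificity is not needed for cryptic-splice blocking: the ASO has no effect on the wild-type allele."
    return(out)
  }
  character(0)
}
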