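#' @title Splice-landmark region classification
#' @description Locate a variant relative to canonical splice sites, the
#'   extended donor/acceptor regions, the branch-point window and
#'   deep-intronic territory, and compute the distances the decision trees
#'   consume.
#' @name region_classifier
NULL

REGION_CLASSES <- c("CANONICAL_DONOR", "CANONICAL_ACCEPTOR", "DONOR_REGION",
                    "ACCEPTOR_REGION", "BRANCH_POINT_WINDOW",
                    "PROXIMAL_INTRONIC", "DEEP_INTRONIC", "EXONIC", "UTR")

# Place a single (pos, offset, region) point on the pre-mRNA.
# Intronic points carry both boundary distances: donor_index counts from the
# intron 5' end (+1 is the first intronic base), acceptor_index from the
# intron 3' end (-1 is the last intronic base -> index 1).
locate_point <- function(model, pos, offset, region) {
  t <- c_to_t(model, pos, region)
  e <- exon_of_t(model, t)
  if (offset == 0) {
    ex <- model$exons[e, ]
    idx <- t - ex$t_start + 1
    return(list(type = if (region == "coding") "exonic" else "utr_exonic",
                exon_index = e, exon_pos = idx, exon_length = ex$length,
                d_acceptor_side = idx, d_donor_side = ex$length - idx + 1))
  }
  # validates boundary anchoring and intron extent
  map_c_to_genomic(model, pos, offset, region)
  if (offset > 0) {
    i <- e
    donor_index <- offset
  } else {
    i <- e - 1
    donor_index <- model$introns$length[i] + offset + 1
  }
  len <- model$introns$length[i]
  list(type = "intronic", intron_index = i, intron_length = len,
       donor_index = donor_index, acceptor_index = len - donor_index + 1)
}

locate_variant_points <- function(model, v) {
  p1 <- locate_point(model, v$anchor_c, v$offset, v$region)
  ranged <- !(v$end_region == v$region && v$end_anchor_c == v$anchor_c &&
              v$end_offset == v$offset)
  if (!ranged) return(list(p1))
  # walk every pre-mRNA position the event touches, so a range straddling a
  # junction is judged by the most constraining landmark inside it
  g1 <- map_c_to_genomic(model, v$anchor_c, v$offset, v$region)
  g2 <- map_c_to_genomic(model, v$end_anchor_c, v$end_offset, v$end_region)
  if (abs(g2 - g1) > 10000)
    stop("ranged variant spans ", abs(g2 - g1) + 1,
         " nt; only small events are in scope")
  lapply(seq(g1, g2, by = strand_sign(model)), function(g) {
    loc <- map_genomic_to_c(model, g)
    locate_point(model, loc$pos, loc$offset, loc$region)
  })
}

# pre-mRNA distance from a located point to the branch-point window of the
# relevant intron(s); 0 when inside. Inf when no window can exist.
branch_window_distance <- function(model, pt, config, branch_points = NULL) {
  bw_for_intron <- function(i, a) {
    # a: acceptor-side index of the query position within intron i,
    # possibly extended virtually through a flanking exon
    len <- model$introns$length[i]
    bp <- branch_points[[as.character(i)]]
    if (!is.null(bp)) return(min(abs(a - bp)))
    if (len < config$branch_min_nt) return(Inf)
    lo <- config$branch_min_nt
    hi <- min(config$branch_max_nt, len)
    if (a < lo) lo - a else if (a > hi) a - hi else 0
  }
  if (pt$type == "intronic")
    return(bw_for_intron(pt$intron_index, pt$acceptor_index))
  # exonic: walk into the upstream intron (acceptor side) and the
  # downstream intron (donor side)
  e <- pt$exon_index
  d <- Inf
  if (e > 1) {
    # the position sits (exon_pos - 1) nt from the upstream intron's 3' end,
    # so intron base at acceptor-side index a is (exon_pos - 1 + a) nt away;
    # the window edge nearest the exon is a = branch_min
    len <- model$introns$length[e - 1]
    if (!is.null(branch_points[[as.character(e - 1)]])) {
      bp <- branch_points[[as.character(e - 1)]]
      d <- min(d, min(pt$d_acceptor_side - 1 + bp))
    } else if (len >= config$branch_min_nt) {
      d <- min(d, pt$d_acceptor_side - 1 + config$branch_min_nt)
    }
  }
  if (e < nrow(model$exons)) {
    len <- model$introns$length[e]
    bp <- branch_points[[as.character(e)]]
    if (!is.null(bp)) {
      d <- min(d, pt$d_donor_side - 1 + (len - bp + 1))
    } else if (len >= config$branch_min_nt) {
      nearest_donor_index <- max(len - config$branch_max_nt + 1, 1)
      d <- min(d, pt$d_donor_side - 1 + nearest_donor_index)
    }
  }
  d
}

classify_point <- function(model, pt, config, branch_points = NULL) {
  tags <- character(0)
  if (pt$type %in% c("exonic", "utr_exonic")) {
    primary <- if (pt$type == "exonic") "EXONIC" else "UTR"
    tags <- c(tags, primary)
    if (pt$d_donor_side <= config$donor_region_exonic &&
        pt$exon_index < nrow(model$exons))
      tags <- c(tags, "DONOR_REGION")
    if (pt$d_acceptor_side <= config$acceptor_region_exonic && pt$exon_index > 1)
      tags <- c(tags, "ACCEPTOR_REGION")
    d <- Inf
    if (pt$exon_index > 1) d <- min(d, pt$d_acceptor_side)
    if (pt$exon_index < nrow(model$exons)) d <- min(d, pt$d_donor_side)
    return(list(primary = primary, tags = tags, d_splice = d,
                d_branch = branch_window_distance(model, pt, config,
                                                  branch_points)))
  }
  a <- pt$acceptor_index
  dnr <- pt$donor_index
  bp <- branch_points[[as.character(pt$intron_index)]]
  in_branch <- if (!is.null(bp)) a %in% bp
               else a >= config$branch_min_nt & a <= config$branch_max_nt
  if (dnr <= 2) tags <- c(tags, "CANONICAL_DONOR")
  if (a <= 2) tags <- c(tags, "CANONICAL_ACCEPTOR")
  if (dnr <= config$donor_region_intronic) tags <- c(tags, "DONOR_REGION")
  if (a <= config$acceptor_region_intronic) tags <- c(tags, "ACCEPTOR_REGION")
  if (in_branch) tags <- c(tags, "BRANCH_POINT_WINDOW")
  d <- min(dnr, a)
  depth_tag <- if (d > config$deep_intronic_nt) "DEEP_INTRONIC"
               else "PROXIMAL_INTRONIC"
  if (length(tags) == 0) tags <- depth_tag
  primary <- REGION_CLASSES[min(match(tags, REGION_CLASSES))]
  list(primary = primary, tags = tags, d_splice = d,
       d_branch = branch_window_distance(model, pt, config, branch_points))
}

#' Classify a variant against splice-regulatory landmarks
#'
#' Produces the region report the decision trees consume: a single primary
#' class chosen by documented precedence (canonical dinucleotide > donor
#' region > acceptor region > branch-point window > proximal/deep intronic;
#' exonic positions are \code{EXONIC} with donor/acceptor-region tags when
#' they fall inside the exonic arms of those windows), the full tag set,
#' and exact distances. Ranged variants straddling an exon/intron boundary
#' are classified by the most constraining landmark touched and tagged
#' \code{SPANS_JUNCTION}.
#'
#' Distance conventions: intronic offset \eqn{k} is at distance \eqn{|k|}
#' from its junction; the terminal exonic base is at distance 1 (there are
#' no zero distances). \code{landmark_distance} is the distance to the
#' nearest splice-critical landmark boundary — the nearer of the nearest
#' exon junction and the branch-point window edge — and
#' \code{bounding_landmark} records which one bound.
#'
#' @param model A \code{transcript_model}.
#' @param v A \code{variant_descriptor}.
#' @param config A [triage_config()].
#' @param branch_points Optional list naming, per intron index (as character
#'   keys), experimentally or computationally determined branch-point
#'   positions as acceptor-side offsets; when supplied for an intron they
#'   replace the positional 18–40 window there.
#' @return A list of class \code{"region_report"}.
#' @examples
#' m <- build_transcript(list(
#'   transcript_id = "TX1", gene_symbol = "G", strand = "+",
#'   exons = data.frame(genomic_start = c(1001, 6001),
#'                      genomic_end   = c(1120, 6120)),
#'   cds_start = 1, cds_end = 240))
#' classify_region(m, parse_hgvs_c("c.120+2T>A"))$primary_class
#' @export
classify_region <- function(model, v, config = triage_config(),
                            branch_points = NULL) {
  pts <- locate_variant_points(model, v)
  cls <- lapply(pts, classify_point, model = model, config = config,
                branch_points = branch_points)
  tags <- unique(unlist(lapply(cls, `[[`, "tags")))
  feat <- vapply(pts, function(pt)
    paste(pt$type, pt$exon_index %||% "", pt$intron_index %||% ""),
    character(1))
  spans <- length(unique(feat)) > 1
  if (spans) tags <- c(tags, "SPANS_JUNCTION")
  primary <- REGION_CLASSES[min(match(
    intersect(tags, REGION_CLASSES), REGION_CLASSES))]
  d_splice <- min(vapply(cls, `[[`, numeric(1), "d_splice"))
  d_branch <- min(vapply(cls, `[[`, numeric(1), "d_branch"))
  landmark <- if (d_branch < d_splice) "branch_point_window" else
    "splice_site"
  exonic <- pts[[1]]$type %in% c("exonic", "utr_exonic")
  structure(list(
    primary_class = primary,
    tags = tags,
    distance_to_nearest_splice_site = d_splice,
    distance_to_branch_window = d_branch,
    landmark_distance = min(d_splice, d_branch),
    bounding_landmark = landmark,
    near_junction_exonic = exonic && is.finite(d_splice) &&
      d_splice < config$recommended_cutoff_nt,
    exon_index = if (exonic) pts[[1]]$exon_index else NA_integer_,
    intron_index = if (!exonic) pts[[1]]$intron_index else NA_integer_,
    spans_junction = spans,
    config = config_snapshot(config)
  ), class = "region_report")
}

#' @export
print.region_report <- function(x, ...) {
  cat(sprintf("region_report: %s [%s]\n", x$primary_class,
              paste(x$tags, collapse = ", ")))
  cat(sprintf("  distance to nearest splice site: %s nt\n",
              format(x$distance_to_nearest_splice_site)))
  cat(sprintf("  distance to branch-point window: %s nt (bound by %s)\n",
              format(x$distance_to_branch_window), x$bounding_landmark))
  invisible(x)
}

#' Distance from a variant to the nearest exon/intron junction
#'
#' Minimum over both flanking junctions. An intronic offset \eqn{k} is
#' \eqn{|k|} nt from its anchoring junction; an exonic position at index
#' \eqn{i} of an exon of length \eqn{L} is \eqn{\min(i, L - i + 1)} nt from
#' a junction (terminal base = distance 1). For ranged variants the minimum
#' over both endpoints is returned. Junctions flanked by nothing (upstream
#' of exon 1, downstream of the last exon) do not count.
#'
#' @param model A \code{transcript_model}.
#' @param v A \code{variant_descriptor}.
#' @return Distance in nucleotides (\code{Inf} for a single-exon
#'   transcript's exonic positions).
#' @export
distance_to_nearest_splice_site <- function(model, v) {
  pts <- locate_variant_points(model, v)
  min(vapply(pts, function(pt) {
    if (pt$type == "intronic") return(min(pt$donor_index, pt$acceptor_index))
    d <- Inf
    if (pt$exon_index > 1) d <- min(d, pt$d_acceptor_side)
    if (pt$exon_index < nrow(model$exons)) d <- min(d, pt$d_donor_side)
    d
  }, numeric(1)))
}
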