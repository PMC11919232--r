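#' Triage configuration
#'
#' All numeric windows and thresholds the region classifier, skip simulator
#' and rule engine consume. The defaults encode the published consensus
#' values used throughout the decision trees; the hotspot parameters are
#' this package's own operationalization of the qualitative
#' "mutational landscape" instruction and are flagged as such in reports.
#'
#' @param hard_cutoff_nt Minimum distance (nt) between an intronic/exonic
#'   cryptic-splice variant and the nearest splice-critical landmark for a
#'   blocking ASO to be considered at all. Default 5 (hard cut-off).
#' @param recommended_cutoff_nt Distance (nt) at and above which clearance is
#'   considered comfortable; below it the verdict carries a proximity
#'   caution. Default 15 (recommended cut-off).
#' @param deep_intronic_nt Distance (nt) from the nearest exon junction
#'   strictly above which a position counts as deep intronic. Default 100.
#' @param donor_region_exonic,donor_region_intronic Extent of the splice
#'   donor region: last \code{donor_region_exonic} exonic bases (default 3,
#'   i.e. -3..-1) and first \code{donor_region_intronic} intronic bases
#'   (default 6, i.e. +1..+6).
#' @param acceptor_region_intronic,acceptor_region_exonic Extent of the
#'   splice acceptor region: last \code{acceptor_region_intronic} intronic
#'   bases (default 20, i.e. -20..-1, including the polypyrimidine tract)
#'   and first \code{acceptor_region_exonic} exonic base(s) (default 1).
#' @param branch_min_nt,branch_max_nt Branch-point window, measured in
#'   nucleotides upstream of the intron 3' end. Defaults 18 and 40.
#' @param size_caution_pct Percentage of the coding sequence strictly above
#'   which an in-frame exon removal attracts the large-removal caution.
#'   Default 10.
#' @param hotspot_window_nt Half-width (nt, coding coordinates) of the
#'   neighbourhood around a missense variant scanned for pathogenic
#'   missense records. Default 90 (non-consensus default, config-exposed).
#' @param hotspot_min_count Minimum number of (likely) pathogenic missense
#'   records inside the exon for a hotspot call. Default 3 (non-consensus).
#' @param hotspot_majority_fraction Minimum fraction of missense among
#'   pathogenic records in the exon for a hotspot call. Default 0.5
#'   (non-consensus).
#' @param skip_override_justification Optional free-text justification that
#'   allows exon skipping to be considered despite reports of the skipped
#'   exon being pathogenic (the milder-phenotype escape hatch). \code{NULL}
#'   (default) disables the override.
#' @return A list of class \code{"triage_config"}.
#' @examples
#' cfg <- triage_config()
#' cfg$hard_cutoff_nt
#' @export
triage_config <- function(hard_cutoff_nt = 5,
                          recommended_cutoff_nt = 15,
                          deep_intronic_nt = 100,
                          donor_region_exonic = 3,
                          donor_region_intronic = 6,
                          acceptor_region_intronic = 20,
                          acceptor_region_exonic = 1,
                          branch_min_nt = 18,
                          branch_max_nt = 40,
                          size_caution_pct = 10,
                          hotspot_window_nt = 90,
                          hotspot_min_count = 3,
                          hotspot_majority_fraction = 0.5,
                          skip_override_justification = NULL) {
  cfg <- list(
    hard_cutoff_nt = hard_cutoff_nt,
    recommended_cutoff_nt = recommended_cutoff_nt,
    deep_intronic_nt = deep_intronic_nt,
    donor_region_exonic = donor_region_exonic,
    donor_region_intronic = donor_region_intronic,
    acceptor_region_intronic = acceptor_region_intronic,
    acceptor_region_exonic = acceptor_region_exonic,
    branch_min_nt = branch_min_nt,
    branch_max_nt = branch_max_nt,
    size_caution_pct = size_caution_pct,
    hotspot_window_nt = hotspot_window_nt,
    hotspot_min_count = hotspot_min_count,
    hotspot_majority_fraction = hotspot_majority_fraction,
    skip_override_justification = skip_override_justification,
    non_consensus_defaults = c("hotspot_window_nt", "hotspot_min_count",
                               "hotspot_majority_fraction")
  )
  if (cfg$hard_cutoff_nt > cfg$recommended_cutoff_nt)
    stop("hard_cutoff_nt must be <= recommended_cutoff_nt")
  numeric_fields <- setdiff(names(cfg),
                            c("skip_override_justification",
                              "non_consensus_defaults"))
  for (f in numeric_fields) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      stop("config field '", f, "' must be a single positive number")
  }
  if (cfg$branch_min_nt > cfg$branch_max_nt)
    stop("branch_min_nt must be <= branch_max_nt")
  structure(cfg, class = "triage_config")
}

#' @export
print.triage_config <- function(x, ...) {
  cat("ssASO triage configuration\n")
  cat(sprintf("  cryptic clearance : hard %d nt, recommended %d nt\n",
              x$hard_cutoff_nt, x$recommended_cutoff_nt))
  cat(sprintf("  deep intronic     : > %d nt from nearest junction\n",
              x$deep_intronic_nt))
  cat(sprintf("  donor region      : -%d..+%d\n",
              x$donor_region_exonic, x$donor_region_intronic))
  cat(sprintf("  acceptor region   : -%d..+%d\n",
              x$acceptor_region_intronic, x$acceptor_region_exonic))
  cat(sprintf("  branch window     : %d..%d nt upstream of intron 3' end\n",
              x$branch_min_nt, x$branch_max_nt))
  cat(sprintf("  size caution      : > %g%% of CDS removed\n",
              x$size_caution_pct))
  cat(sprintf("  hotspot           : window %d nt, min count %d, majority %.2f\n",
              x$hotspot_window_nt, x$hotspot_min_count,
              x$hotspot_majority_fraction))
  invisible(x)
}

# serializable snapshot embedded in reports
config_snapshot <- function(config) {
  cfg <- unclass(config)
  cfg$skip_override_justification <-
    if (is.null(cfg$skip_override_justification)) NA_character_
    else cfg$skip_override_justification
  cfg
}
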