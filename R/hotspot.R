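#' Pathogenic-missense hotspot analysis
#'
#' Scans a ClinVar-like table of classified variants for evidence that the
#' exon encodes an indispensable protein segment. An exon counts as a
#' hotspot when it holds at least \code{hotspot_min_count} (likely)
#' pathogenic missense records and missense makes up at least
#' \code{hotspot_majority_fraction} of its pathogenic records. The window
#' statistic additionally reports pathogenic missense within
#' \code{hotspot_window_nt} coding nucleotides of the variant and whether
#' any neighbouring record carries a functional loss-of-function flag. The
#' three thresholds operationalize a qualitative instruction and are
#' flagged as non-consensus defaults in every report.
#'
#' @param v A \code{variant_descriptor} (exonic, coding).
#' @param pathogenic_table A data frame with columns \code{position_c}
#'   (coding position), \code{consequence} (e.g. \code{"missense"},
#'   \code{"nonsense"}), \code{classification} (\code{"pathogenic"},
#'   \code{"likely_pathogenic"}, ...), and optional \code{functional_lof}
#'   (logical). Malformed rows are rejected individually with a logged
#'   reason, never dropped silently. \code{NULL} is treated as an empty
#'   table.
#' @param exon_interval Coding-nucleotide interval \code{c(start, end)} of
#'   the variant's exon (see \code{exon_coding_interval} via
#'   [exon_coding_length()] semantics), or the value returned by the
#'   internal helper used by [triage()].
#' @param config A [triage_config()].
#' @return A list of class \code{"hotspot_report"}.
#' @examples
#' tab <- data.frame(position_c = c(610, 625, 655),
#'                   consequence = "missense",
#'                   classification = "pathogenic",
#'                   functional_lof = c(TRUE, FALSE, FALSE))
#' hs <- hotspot_score(parse_hgvs_c("c.640G>C"), tab, c(598, 681))
#' hs$is_hotspot
#' @export
hotspot_score <- function(v, pathogenic_table, exon_interval,
                          config = triage_config()) {
  if (!variant_is_exonic(v) || v$region != "coding")
    stop("hotspot analysis requires an exonic coding variant")
  if (length(exon_interval) != 2 || exon_interval[1] > exon_interval[2])
    stop("exon_interval must be c(start_c, end_c)")
  tab <- pathogenic_table
  if (is.null(tab))
    tab <- data.frame(position_c = numeric(0), consequence = character(0),
                      classification = character(0),
                      functional_lof = logical(0))
  if (!all(c("position_c", "consequence", "classification") %in% names(tab)))
    stop("pathogenic table must have columns position_c, consequence, ",
         "classification")
  if (is.null(tab$functional_lof)) tab$functional_lof <- NA

  rejected <- data.frame(row = integer(0), reason = character(0))
  keep <- rep(TRUE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    pos <- suppressWarnings(as.numeric(tab$position_c[i]))
    reason <- NULL
    if (is.na(pos) || pos < 1 || pos != floor(pos))
      reason <- paste0("invalid position_c '", tab$position_c[i], "'")
    else if (!tolower(tab$consequence[i]) %in% CONSEQUENCE_CLASSES)
      reason <- paste0("unknown consequence '", tab$consequence[i], "'")
    else if (is.na(tab$classification[i]) || tab$classification[i] == "")
      reason <- "missing classification"
    if (!is.null(reason)) {
      keep[i] <- FALSE
      rejected <- rbind(rejected, data.frame(row = i, reason = reason))
      message("hotspot_score: rejecting table row ", i, ": ", reason)
    }
  }
  tab <- tab[keep, , drop = FALSE]
  tab$position_c <- as.numeric(tab$position_c)
  tab$consequence <- tolower(tab$consequence)
  patho <- tab[tolower(tab$classification) %in%
                 c("pathogenic", "likely_pathogenic"), , drop = FALSE]

  in_exon <- patho$position_c >= exon_interval[1] &
             patho$position_c <= exon_interval[2]
  in_window <- abs(patho$position_c - v$anchor_c) <= config$hotspot_window_nt

  n_patho_exon <- sum(in_exon)
  n_mis_exon <- sum(in_exon & patho$consequence == "missense")
  n_mis_window <- sum(in_window & patho$consequence == "missense")
  exon_len <- exon_interval[2] - exon_interval[1] + 1

  is_hotspot <- n_mis_exon >= config$hotspot_min_count &&
    n_patho_exon > 0 &&
    (n_mis_exon / n_patho_exon) >= config$hotspot_majority_fraction

  structure(list(
    window_nt = config$hotspot_window_nt,
    n_pathogenic_in_exon = n_patho_exon,
    n_pathogenic_missense_in_exon = n_mis_exon,
    n_pathogenic_missense_in_window = n_mis_window,
    density_per_100nt = 100 * n_mis_exon / exon_len,
    is_hotspot = is_hotspot,
    lof_evidence_nearby = any(in_window & patho$functional_lof %in% TRUE),
    exon_interval = as.integer(exon_interval),
    rejected_rows = rejected,
    non_consensus_defaults = TRUE
  ), class = "hotspot_report")
}

#' @export
print.hotspot_report <- function(x, ...) {
  cat(sprintf("hotspot_report: %s\n",
              if (x$is_hotspot) "HOTSPOT" else "not a hotspot"))
  cat(sprintf("  pathogenic missense: %d in exon (%.1f per 100 coding nt), %d within +/-%d nt\n",
              x$n_pathogenic_missense_in_exon, x$density_per_100nt,
              x$n_pathogenic_missense_in_window, x$window_nt))
  cat(sprintf("  functional LoF evidence nearby: %s\n",
              x$lof_evidence_nearby))
  invisible(x)
}
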