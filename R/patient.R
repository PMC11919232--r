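#' Patient profile for eligibility screening
#'
#' Variant amenability is only half of candidate selection; the disease and
#' the patient's clinical situation must justify an accelerated,
#' individualized development. All five fields are required — there are no
#' defaults, because an unstated criterion must not silently pass.
#'
#' @param severity One of \code{"life_threatening"},
#'   \code{"severely_debilitating"}, \code{"other"}.
#' @param monogenic Is the disorder monogenic? Logical.
#' @param primary_tissue One of \code{"brain"}, \code{"spinal_cord"},
#'   \code{"eye"}, \code{"other"} — the first three are reachable with
#'   local (intrathecal/intraventricular/intravitreal/subretinal) delivery.
#' @param treatable_in_two_years Will the patient still be in a treatable
#'   stage two years after enrolment (the expected ASO development time)?
#' @param outcome_measures_definable Can clinical outcome measures be
#'   predefined for this patient?
#' @return A list of class \code{"patient_profile"}.
#' @export
patient_profile <- function(severity, monogenic, primary_tissue,
                            treatable_in_two_years,
                            outcome_measures_definable) {
  if (missing(severity) || missing(monogenic) || missing(primary_tissue) ||
      missing(treatable_in_two_years) || missing(outcome_measures_definable))
    stop("all five patient criteria must be supplied; none defaults")
  severity <- match.arg(severity, c("life_threatening",
                                    "severely_debilitating", "other"))
  primary_tissue <- match.arg(primary_tissue,
                              c("brain", "spinal_cord", "eye", "other"))
  for (f in list(monogenic = monogenic,
                 treatable_in_two_years = treatable_in_two_years,
                 outcome_measures_definable = outcome_measures_definable)) {
    if (!is.logical(f) || length(f) != 1 || is.na(f))
      stop("monogenic, treatable_in_two_years and outcome_measures_definable ",
           "must each be TRUE or FALSE")
  }
  structure(list(severity = severity, monogenic = monogenic,
                 primary_tissue = primary_tissue,
                 treatable_in_two_years = treatable_in_two_years,
                 outcome_measures_definable = outcome_measures_definable),
            class = "patient_profile")
}

#' Patient-selection checklist
#'
#' A patient is eligible for an individualized ssASO development only when
#' all five conditions hold: a life-threatening or severely debilitating
#' disease, a monogenic disorder, a primary tissue reachable by local
#' delivery (brain, spinal cord or eye), a still-treatable stage two years
#' after enrolment, and predefinable clinical outcome measures.
#'
#' @param profile A [patient_profile()].
#' @return A list of class \code{"patient_eligibility"} with \code{eligible}
#'   and a per-criterion \code{trace} data frame.
#' @examples
#' p <- patient_profile("life_threatening", TRUE, "brain", TRUE, TRUE)
#' evaluate_patient(p)$eligible
#' @export
evaluate_patient <- function(profile) {
  if (!inherits(profile, "patient_profile"))
    stop("profile must be a patient_profile object")
  checks <- data.frame(
    criterion = c("severity", "monogenic", "primary_tissue",
                  "treatable_in_two_years", "outcome_measures_definable"),
    question = c(
      "Is the disease life-threatening or severely debilitating?",
      "Is the disorder monogenic?",
      "Does it predominantly affect the brain, spinal cord or eye?",
      "Will the patient still be in a treatable stage two years after enrolment?",
      "Can clinical outcome measures be predefined?"),
    value = c(profile$severity, profile$monogenic, profile$primary_tissue,
              profile$treatable_in_two_years,
              profile$outcome_measures_definable),
    satisfied = c(
      profile$severity %in% c("life_threatening", "severely_debilitating"),
      isTRUE(profile$monogenic),
      profile$primary_tissue %in% c("brain", "spinal_cord", "eye"),
      isTRUE(profile$treatable_in_two_years),
      isTRUE(profile$outcome_measures_definable)),
    stringsAsFactors = FALSE
  )
  structure(list(eligible = all(checks$satisfied), trace = checks),
            class = "patient_eligibility")
}

#' @export
print.patient_eligibility <- function(x, ...) {
  cat(sprintf("patient_eligibility: %s\n",
              if (x$eligible) "ELIGIBLE" else "NOT ELIGIBLE"))
  for (i in seq_len(nrow(x$trace)))
    cat(sprintf("  [%s] %-26s = %s\n",
                if (x$trace$satisfied[i]) "ok" else "FAIL",
                x$trace$criterion[i], x$trace$value[i]))
  invisible(x)
}
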