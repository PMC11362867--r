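#' Cohort exclusion reasons, in cascade order
#'
#' @keywords internal
PSNET_EXCLUSION_REASONS <- c(
  "no_incident_cancer", "prior_cancer_dx", "age_out_of_range",
  "enrollment_gap", "multiple_cancers", "bad_zip", "metastatic_90d",
  "neoadjuvant", "same_day_reconstruction", "no_surgery", "none"
)

#' Apply the study-cohort inclusion/exclusion cascade
#'
#' Screens every patient against the cohort rules in a fixed, documented
#' order and records the *first* failing rule, so exclusion tallies are
#' reproducible. The rules, in order:
#'
#' 1. incident cancer: a biopsy followed by at least 2 cancer diagnosis
#'    codes within 365 days (`no_incident_cancer` otherwise);
#' 2. no cancer diagnosis code in the 365 days before biopsy
#'    (`prior_cancer_dx`);
#' 3. age 66-99 at biopsy (`age_out_of_range`);
#' 4. continuous enrollment through the year before and after biopsy
#'    (`enrollment_gap`);
#' 5. a single primary cancer (`multiple_cancers`);
#' 6. a valid residential zip (`bad_zip`);
#' 7. no metastatic diagnosis within 90 days of biopsy (`metastatic_90d`);
#' 8. no chemotherapy/radiotherapy before the first surgery
#'    (`neoadjuvant`);
#' 9. no reconstruction on the day of a surgery
#'    (`same_day_reconstruction`);
#' 10. at least one cancer-directed surgery (`no_surgery`).
#'
#' Rules 8-9 only apply to patients with a surgery event; patients without
#' one fall through to `no_surgery`. Violations always become flags, never
#' errors.
#'
#' @param patients Patient table with `patient_id`, `age`,
#'   `enrolled_continuously`, `multiple_primaries`, `zip`.
#' @param encounters Encounter table.
#' @param days_after Days after biopsy within which the 2 confirmatory
#'   diagnoses must occur (365).
#' @param age_range Inclusive age bounds, default `c(66, 99)`.
#' @param met_window Days around biopsy within which a metastatic code
#'   excludes (90).
#' @return A tibble: `patient_id`, `excluded`, `exclusion_reason` (factor
#'   over the documented levels), `biopsy_date` (NA when absent).
#' @export
apply_cohort_filters <- function(patients, encounters,
                                 days_after = 365L,
                                 age_range = c(66L, 99L),
                                 met_window = 90L) {
  stopifnot(is.data.frame(patients), is.data.frame(encounters))
  enc <- dplyr::semi_join(encounters, patients, by = "patient_id")

  biopsy <- enc |>
    dplyr::filter(.data$event_class == "biopsy") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(biopsy_date = min(.data$service_date), .groups = "drop")

  x <- patients |>
    dplyr::select("patient_id", "age", "enrolled_continuously",
                  "multiple_primaries", "zip") |>
    dplyr::left_join(biopsy, by = "patient_id")

  per_patient_events <- enc |>
    dplyr::inner_join(biopsy, by = "patient_id")
  n_dx_after <- per_patient_events |>
    dplyr::filter(.data$event_class == "cancer_dx",
                  .data$service_date > .data$biopsy_date,
                  .data$service_date <= .data$biopsy_date + days_after) |>
    dplyr::count(.data$patient_id, name = "n_dx_after")
  prior_dx <- per_patient_events |>
    dplyr::filter(.data$event_class == "cancer_dx",
                  .data$service_date < .data$biopsy_date,
                  .data$service_date >= .data$biopsy_date - days_after) |>
    dplyr::distinct(.data$patient_id) |>
    dplyr::mutate(prior_dx = TRUE)
  met_dx <- per_patient_events |>
    dplyr::filter(.data$event_class == "metastatic_dx",
                  abs(.data$service_date - .data$biopsy_date) <= met_window) |>
    dplyr::distinct(.data$patient_id) |>
    dplyr::mutate(met_90d = TRUE)
  first_surgery <- per_patient_events |>
    dplyr::filter(.data$event_class == "surgery") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(first_surgery = min(.data$service_date),
                     .groups = "drop")
  neo <- per_patient_events |>
    dplyr::inner_join(first_surgery, by = "patient_id") |>
    dplyr::filter(.data$event_class %in% c("chemotherapy", "radiotherapy"),
                  .data$service_date < .data$first_surgery) |>
    dplyr::distinct(.data$patient_id) |>
    dplyr::mutate(neoadjuvant = TRUE)
  same_day <- per_patient_events |>
    dplyr::filter(.data$event_class == "reconstruction") |>
    dplyr::inner_join(
      dplyr::filter(enc, .data$event_class == "surgery"),
      by = c("patient_id", "service_date")
    ) |>
    dplyr::distinct(.data$patient_id) |>
    dplyr::mutate(same_day_recon = TRUE)

  x <- x |>
    dplyr::left_join(n_dx_after, by = "patient_id") |>
    dplyr::left_join(prior_dx, by = "patient_id") |>
    dplyr::left_join(met_dx, by = "patient_id") |>
    dplyr::left_join(first_surgery, by = "patient_id") |>
    dplyr::left_join(neo, by = "patient_id") |>
    dplyr::left_join(same_day, by = "patient_id") |>
    dplyr::mutate(
      n_dx_after = dplyr::coalesce(.data$n_dx_after, 0L),
      dplyr::across(c("prior_dx", "met_90d", "neoadjuvant",
                      "same_day_recon"),
                    \(v) dplyr::coalesce(v, FALSE))
    )

  reason <- dplyr::case_when(
    is.na(x$biopsy_date) | x$n_dx_after < 2 ~ "no_incident_cancer",
    x$prior_dx ~ "prior_cancer_dx",
    x$age < age_range[1] | x$age > age_range[2] ~ "age_out_of_range",
    !x$enrolled_continuously ~ "enrollment_gap",
    x$multiple_primaries ~ "multiple_cancers",
    is.na(x$zip) ~ "bad_zip",
    x$met_90d ~ "metastatic_90d",
    !is.na(x$first_surgery) & x$neoadjuvant ~ "neoadjuvant",
    !is.na(x$first_surgery) & x$same_day_recon ~ "same_day_reconstruction",
    is.na(x$first_surgery) ~ "no_surgery",
    .default = "none"
  )
  tibble(
    patient_id = x$patient_id,
    excluded = reason != "none",
    exclusion_reason = factor(reason, levels = PSNET_EXCLUSION_REASONS),
    biopsy_date = x$biopsy_date
  )
}

#' Exclusion-flow summary
#'
#' Counts patients per exclusion reason in cascade order, mirroring a
#' cohort flow diagram.
#'
#' @param flags Output of [apply_cohort_filters()].
#' @return Tibble `exclusion_reason`, `n`.
#' @export
exclusion_flow <- function(flags) {
  flags |>
    dplyr::count(.data$exclusion_reason, .drop = FALSE) |>
    as_tibble()
}

#' Identify treatment events for the surgery and adjuvant cohorts
#'
#' For cohort-included patients: the first cancer-directed surgery is the
#' earliest surgery event billed by a network surgeon; adjuvant therapy is
#' the earliest chemotherapy (by a medical oncologist) or radiotherapy (by
#' a radiation oncologist) event strictly after the last surgery, again
#' restricted to network physicians. Patients with no valid adjuvant event
#' simply have `first_adjuvant = NA` and belong to the surgery cohort
#' only. A surgery dated before biopsy is treated as a data fault: the
#' patient is dropped with a warning.
#'
#' @param encounters Encounter table.
#' @param cohort Tibble with `patient_id` and `biopsy_date` for included
#'   patients (e.g. the non-excluded rows of [apply_cohort_filters()]).
#' @param physicians Physician table with `physician_id`, `specialty`.
#' @param graph Optional [sharing_graph()]; when supplied, only physicians
#'   in the network count as treating physicians.
#' @return Tibble: `patient_id`, `biopsy_date`, `surgeon_id`,
#'   `first_surgery`, `last_surgery`, `first_adjuvant`,
#'   `adjuvant_modality`.
#' @export
identify_treatments <- function(encounters, cohort, physicians,
                                graph = NULL) {
  stopifnot(is.data.frame(encounters), is.data.frame(cohort))
  valid_ids <- physicians$physician_id
  if (!is.null(graph)) {
    stopifnot(inherits(graph, "sharing_graph"))
    valid_ids <- intersect(valid_ids, graph$nodes$physician_id)
  }
  spec_of <- setNames(physicians$specialty, physicians$physician_id)

  enc <- encounters |>
    dplyr::semi_join(cohort, by = "patient_id") |>
    dplyr::filter(.data$physician_id %in% valid_ids)

  surg <- enc |>
    dplyr::filter(.data$event_class == "surgery",
                  spec_of[.data$physician_id] == "surgeon") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      first_surgery = min(.data$service_date),
      last_surgery = max(.data$service_date),
      surgeon_id = .data$physician_id[which.min(.data$service_date)],
      .groups = "drop"
    )

  out <- cohort |>
    dplyr::select("patient_id", "biopsy_date") |>
    dplyr::inner_join(surg, by = "patient_id")

  bad <- out$first_surgery < out$biopsy_date
  if (any(bad)) {
    warn(sprintf("Dropping %d patient(s) with surgery before biopsy.",
                 sum(bad)))
    out <- out[!bad, ]
  }

  adj <- enc |>
    dplyr::inner_join(dplyr::select(out, "patient_id", "last_surgery"),
                      by = "patient_id") |>
    dplyr::filter(
      .data$service_date > .data$last_surgery,
      (.data$event_class == "chemotherapy" &
         spec_of[.data$physician_id] == "medical_oncologist") |
        (.data$event_class == "radiotherapy" &
           spec_of[.data$physician_id] == "radiation_oncologist")
    ) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      first_adjuvant = min(.data$service_date),
      adjuvant_modality = .data$event_class[which.min(.data$service_date)],
      .groups = "drop"
    )

  dplyr::left_join(out, adj, by = "patient_id") |>
    dplyr::select("patient_id", "biopsy_date", "surgeon_id",
                  "first_surgery", "last_surgery", "first_adjuvant",
                  "adjuvant_modality")
}

#' Treatment-delay indicator
#'
#' Delay means *strictly more than* `cutoff` days: an interval of exactly
#' 60 days is timely under the default, 61 is delayed. The sensitivity
#' cutoff of 90 behaves the same way.
#'
#' @param interval_days Non-negative integer vector of treatment
#'   intervals.
#' @param cutoff Positive number of days (default 60).
#' @return Logical vector.
#' @export
delay_flag <- function(interval_days, cutoff = 60) {
  if (any(interval_days < 0, na.rm = TRUE)) {
    abort("`interval_days` must be non-negative.")
  }
  if (length(cutoff) != 1 || cutoff <= 0) abort("`cutoff` must be positive.")
  interval_days > cutoff
}

#' Bin zip-level economic deprivation
#'
#' Percent of persons below the poverty line, binned as very low
#' (<5.00), low (5.00-9.99), medium (10.00-14.99), high (15.00-19.99) and
#' very high (>=20.00); lower bounds inclusive, upper bounds exclusive
#' except the open top bin.
#'
#' @param pct Numeric vector in \[0, 100\]; NA propagates.
#' @return Factor with levels very_low < low < medium < high < very_high.
#' @export
bin_deprivation <- function(pct) {
  pct <- as.numeric(pct)
  if (any(pct < 0 | pct > 100, na.rm = TRUE)) {
    abort("`pct` must lie in [0, 100].")
  }
  cut(pct, breaks = c(-Inf, 5, 10, 15, 20, Inf), right = FALSE,
      labels = c("very_low", "low", "medium", "high", "very_high"))
}

#' Nearest-rank tertile binning
#'
#' Cut points are the ceiling(n/3)-th and ceiling(2n/3)-th order
#' statistics; values at or below a cut fall in the lower bin, so ties
#' collapse downward (a constant vector is all `low`). With distinct
#' values the three bins differ in size by at most one.
#'
#' @param values Nonempty numeric vector (NA allowed, returned as NA).
#' @return Factor with levels low < medium < high.
#' @export
bin_tertiles <- function(values) {
  ok <- !is.na(values)
  if (!any(ok)) abort("`values` must contain at least one non-missing value.")
  s <- sort(values[ok])
  n <- length(s)
  q1 <- s[ceiling(n / 3)]
  q2 <- s[ceiling(2 * n / 3)]
  out <- ifelse(values <= q1, "low", ifelse(values <= q2, "medium", "high"))
  factor(out, levels = c("low", "medium", "high"))
}

#' Bin a comorbidity count as 0 / 1 / >=2
#' @param count Non-negative integer vector.
#' @return Factor with levels `0`, `1`, `2+`.
#' @export
bin_comorbidity <- function(count) {
  if (any(count < 0, na.rm = TRUE)) abort("`count` must be non-negative.")
  factor(ifelse(count >= 2, "2+", as.character(count)),
         levels = c("0", "1", "2+"))
}
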