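#' Care teams for a phase window
#'
#' The set of physicians with any encounter for the patient inside
#' `[start, end]` (both inclusive), optionally restricted to given
#' specialties. The preoperative team runs from 91 days before biopsy to
#' the first surgery and includes all specialties (second opinions and
#' diagnostic consults count); the postoperative team runs from the last
#' surgery to the first adjuvant therapy and is restricted to oncologists.
#'
#' @param encounters Encounter table.
#' @param windows Tibble with `patient_id`, `start`, `end` (integer days).
#' @param physicians Physician table (`physician_id`, `specialty`).
#' @param specialties Specialties retained (default all).
#' @return Tibble `patient_id`, `physician_id`, one row per team
#'   membership.
#' @export
care_teams <- function(encounters, windows, physicians,
                       specialties = PSNET_SPECIALTIES) {
  keep <- physicians$physician_id[physicians$specialty %in% specialties]
  encounters |>
    dplyr::inner_join(windows, by = "patient_id") |>
    dplyr::filter(.data$service_date >= .data$start,
                  .data$service_date <= .data$end,
                  .data$physician_id %in% keep) |>
    dplyr::distinct(.data$patient_id, .data$physician_id)
}

# visits inside a window, the encounter-count covariate
count_visits <- function(encounters, windows) {
  encounters |>
    dplyr::filter(.data$event_class == "visit") |>
    dplyr::inner_join(windows, by = "patient_id") |>
    dplyr::filter(.data$service_date >= .data$start,
                  .data$service_date <= .data$end) |>
    dplyr::count(.data$patient_id, name = "encounter_count")
}

# care-density exposure level: tertiles of defined densities plus the
# sole-clinician level; patients with no in-network team member get NA
cd_level <- function(cd, sole_clinician) {
  lev <- rep(NA_character_, length(cd))
  lev[sole_clinician] <- "sole_clinician"
  defined <- !is.na(cd)
  if (any(defined)) {
    lev[defined] <- as.character(bin_tertiles(cd[defined]))
  }
  factor(lev, levels = c("low", "medium", "high", "sole_clinician"))
}

#' Assemble regression-ready analysis rows for both treatment cohorts
#'
#' Joins exposures, outcome, covariates and cluster identifiers into one
#' row per patient and cohort. The surgery cohort uses the preoperative
#' care density (all physicians, 91 days before biopsy through first
#' surgery) with the sole-clinician fourth level; the adjuvant cohort —
#' the subset of patients with a valid adjuvant event — uses the
#' postoperative care density (oncologists only, last surgery through
#' first adjuvant). Delay is strictly more than `cutoff` days.
#' Encounter-count covariates are visit tallies over the same windows.
#' Physician-level continuous covariates (cohort patient volume,
#' oncologist supply, within/between-HSA degree) are tertile-binned across
#' the cohort's surgeons. Patients whose exposure cannot be measured (no
#' in-network team member, or a surgeon absent from the linchpin table)
#' are dropped with an informational count.
#'
#' @param patients Patient table (included patients are selected via
#'   `treatments`).
#' @param encounters Encounter table.
#' @param graph [sharing_graph()] with node attributes.
#' @param treatments Output of [identify_treatments()].
#' @param linchpin_flags Output of [flag_linchpins()] on surgeon scores.
#' @param over65_by_hrr Tibble `hrr`, `over65` for the supply measure.
#' @param physicians Physician table.
#' @param cutoff Delay cutoff in days (60).
#' @param days_before Preoperative window reach before biopsy (91).
#' @return List of tibbles `surgery` and `adjuvant`.
#' @export
assemble_analysis_rows <- function(patients, encounters, graph, treatments,
                                   linchpin_flags, over65_by_hrr,
                                   physicians, cutoff = 60,
                                   days_before = 91L) {
  stopifnot(inherits(graph, "sharing_graph"))

  # ---- surgeon-level covariates, tertiled across the cohort's surgeons --
  surgeon_ids <- unique(treatments$surgeon_id)
  deg <- degree_split(graph)
  supply <- oncologist_supply(physicians, over65_by_hrr)
  nodes <- graph$nodes
  surg_attr <- tibble(surgeon_id = surgeon_ids) |>
    dplyr::left_join(nodes, by = c(surgeon_id = "physician_id")) |>
    dplyr::left_join(deg, by = c(surgeon_id = "physician_id")) |>
    dplyr::left_join(dplyr::select(supply, "hrr", "oncologist_supply"),
                     by = "hrr") |>
    dplyr::mutate(
      surgeon_volume_bin = bin_tertiles(.data$n_cohort_patients),
      supply_bin = bin_tertiles(.data$oncologist_supply),
      within_hsa_bin = bin_tertiles(.data$within_hsa_degree),
      between_hsa_bin = bin_tertiles(.data$between_hsa_degree)
    ) |>
    dplyr::select("surgeon_id", surgeon_rurality = "rurality",
                  surgeon_gender = "gender", "surgeon_volume_bin",
                  "supply_bin", "within_hsa_bin", "between_hsa_bin")

  lf <- dplyr::select(linchpin_flags, "physician_id", "is_linchpin")

  base <- treatments |>
    dplyr::left_join(lf, by = c(surgeon_id = "physician_id")) |>
    dplyr::left_join(surg_attr, by = "surgeon_id") |>
    dplyr::left_join(
      dplyr::select(patients, "patient_id", "age_group", "race_ethnicity",
                    "comorbidity_count", "deprivation_pct",
                    patient_rurality = "rurality", "nci_affiliated_surgery",
                    "hrr"),
      by = "patient_id"
    ) |>
    dplyr::mutate(
      comorbidity_bin = bin_comorbidity(.data$comorbidity_count),
      deprivation_bin = bin_deprivation(.data$deprivation_pct)
    )

  dropped <- sum(is.na(base$is_linchpin))
  if (dropped > 0) {
    inform(sprintf(
      "Dropping %d patient(s) whose surgeon has no linchpin score.", dropped
    ))
    base <- dplyr::filter(base, !is.na(.data$is_linchpin))
  }

  covar_cols <- c("age_group", "race_ethnicity", "comorbidity_bin",
                  "deprivation_bin", "patient_rurality",
                  "nci_affiliated_surgery", "surgeon_volume_bin",
                  "surgeon_rurality", "supply_bin", "within_hsa_bin",
                  "between_hsa_bin", "surgeon_gender")

  finalise <- function(rows, cohort) {
    rows |>
      dplyr::mutate(
        cohort = cohort,
        delayed = delay_flag(.data$interval_days, cutoff),
        linchpin_exposed = .data$is_linchpin
      ) |>
      dplyr::select("patient_id", "cohort", "linchpin_exposed",
                    "care_density_level", "cd", "team_size", "delayed",
                    "interval_days", "encounter_count",
                    dplyr::all_of(covar_cols), "surgeon_id", "hrr")
  }

  # ---- surgery cohort ----------------------------------------------------
  pre_win <- tibble(patient_id = base$patient_id,
                    start = base$biopsy_date - days_before,
                    end = base$first_surgery)
  pre_team <- care_teams(encounters, pre_win, physicians)
  pre_cd <- care_density_table(graph, pre_team)
  surgery <- base |>
    dplyr::left_join(pre_cd, by = "patient_id") |>
    dplyr::left_join(
      count_visits(encounters,
                   dplyr::mutate(pre_win, start = base$biopsy_date)),
      by = "patient_id"
    ) |>
    dplyr::mutate(
      team_size = dplyr::coalesce(.data$team_size, 0L),
      encounter_count = dplyr::coalesce(.data$encounter_count, 0L),
      care_density_level = cd_level(.data$cd, .data$sole_clinician),
      interval_days = .data$first_surgery - .data$biopsy_date
    )
  no_team <- sum(is.na(surgery$care_density_level))
  if (no_team > 0) {
    inform(sprintf(
      "Dropping %d patient(s) with no in-network preoperative clinician.",
      no_team
    ))
    surgery <- dplyr::filter(surgery, !is.na(.data$care_density_level))
  }
  surgery <- finalise(surgery, "surgery")

  # ---- adjuvant cohort ---------------------------------------------------
  adj_base <- dplyr::filter(base, !is.na(.data$first_adjuvant))
  post_win <- tibble(patient_id = adj_base$patient_id,
                     start = adj_base$last_surgery,
                     end = adj_base$first_adjuvant)
  post_team <- care_teams(encounters, post_win, physicians,
                          specialties = PSNET_ONCOLOGIST_SPECIALTIES)
  post_cd <- care_density_table(graph, post_team)
  adjuvant <- adj_base |>
    dplyr::left_join(post_cd, by = "patient_id") |>
    dplyr::left_join(count_visits(encounters, post_win), by = "patient_id") |>
    dplyr::mutate(
      team_size = dplyr::coalesce(.data$team_size, 0L),
      encounter_count = dplyr::coalesce(.data$encounter_count, 0L),
      care_density_level = cd_level(.data$cd, .data$sole_clinician),
      interval_days = .data$first_adjuvant - .data$last_surgery
    )
  no_team <- sum(is.na(adjuvant$care_density_level))
  if (no_team > 0) {
    inform(sprintf(
      "Dropping %d patient(s) with no in-network postoperative oncologist.",
      no_team
    ))
    adjuvant <- dplyr::filter(adjuvant, !is.na(.data$care_density_level))
  }
  adjuvant <- finalise(adjuvant, "adjuvant")

  list(surgery = surgery, adjuvant = adjuvant)
}
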