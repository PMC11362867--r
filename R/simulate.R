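#' Generator settings for the synthetic claims stream
#'
#' Returns the full set of knobs controlling the synthetic population and
#' encounter stream, with defaults chosen to emulate a fee-for-service
#' claims cohort of older women with incident breast cancer: five-year age
#' bands from 66 up, a mostly urban population with a rural tail, zip ->
#' hospital service area (HSA) -> hospital referral region (HRR) geography,
#' and surgeon supply that thins out in rural areas when `rural_scarcity`
#' is positive. All "month" constants are fixed day counts: 3 months = 91
#' days, 12 months = 365 days.
#'
#' `exclusion_fractions` assigns disjoint random subsets of patients to
#' violate each cohort-entry rule (prior cancer diagnosis, age out of
#' range, an enrollment gap, multiple primaries, a missing zip, early
#' metastatic diagnosis, neoadjuvant therapy, same-day reconstruction) so
#' the downstream filter cascade is exercised; set them to 0 for a fully
#' clean cohort.
#'
#' @param n_patients Number of patients (0 allowed for an empty stream).
#' @param n_hrr,hsas_per_hrr,zips_per_hsa Geography sizes.
#' @param rural_fraction Fraction of HSAs that are rural (split across
#'   large rural / small rural / isolated); the first HSA of each HRR is
#'   always urban so every region has an urban core.
#' @param rural_scarcity In \[0, 1\]: 0 allocates surgeons proportional to
#'   population; 1 removes nearly all surgeon supply from rural HSAs.
#' @param n_surgeons,n_med_onc,n_rad_onc,n_other Physician roster sizes;
#'   by default scaled to `n_patients` (about one surgeon per 65
#'   patients) so network density stays realistic at any cohort size.
#' @param surgery_fraction Fraction of patients receiving cancer-directed
#'   surgery; the remainder never enter the surgery cohort.
#' @param adjuvant_fraction Fraction of surgical patients receiving
#'   adjuvant chemotherapy or radiotherapy.
#' @param sole_clinician_fraction Fraction of surgical patients whose only
#'   preoperative clinician is their surgeon.
#' @param pre_team_lambda,post_team_lambda Poisson means for the number of
#'   additional preoperative clinicians / postoperative oncologists.
#' @param exclusion_fractions Named list of per-rule violation fractions.
#' @param days_before,days_after Network window constants (91, 365).
#' @param cutoff Delay cutoff in days (60; 90 in sensitivity analyses).
#' @return A named list of class `psnet_config`.
#' @export
sim_config <- function(n_patients = 2000,
                       n_hrr = 5,
                       hsas_per_hrr = 4,
                       zips_per_hsa = 3,
                       rural_fraction = 0.35,
                       rural_scarcity = 0.5,
                       n_surgeons = NULL,
                       n_med_onc = NULL,
                       n_rad_onc = NULL,
                       n_other = NULL,
                       surgery_fraction = 0.97,
                       adjuvant_fraction = 0.55,
                       sole_clinician_fraction = 0.12,
                       pre_team_lambda = 2.5,
                       post_team_lambda = 1.5,
                       exclusion_fractions = list(
                         prior_cancer_dx = 0.015,
                         age_out_of_range = 0.01,
                         enrollment_gap = 0.01,
                         multiple_cancers = 0.01,
                         bad_zip = 0.005,
                         metastatic_90d = 0.015,
                         neoadjuvant = 0.015,
                         same_day_reconstruction = 0.01
                       ),
                       days_before = 91L,
                       days_after = 365L,
                       cutoff = 60L) {
  cfg <- as.list(environment())
  # rosters scale with the cohort so pairwise shared-patient counts keep
  # a realistic order of magnitude at any simulation size
  scale_n <- max(cfg$n_patients, 1000)
  cfg$n_surgeons <- cfg$n_surgeons %||% max(24, round(scale_n / 65))
  cfg$n_med_onc <- cfg$n_med_onc %||% max(30, round(scale_n / 50))
  cfg$n_rad_onc <- cfg$n_rad_onc %||% max(24, round(scale_n / 65))
  cfg$n_other <- cfg$n_other %||% max(120, round(scale_n / 13))
  structure(cfg, class = c("psnet_config", "list"))
}

#' Planted generative truth for the delay outcome
#'
#' Encodes the generative counterpart of the analysis model: the delay
#' indicator is drawn from a logistic model with the patient's true
#' exposures as fixed effects and independent Gaussian random intercepts
#' for the operating surgeon and the patient's HRR,
#' `logit P(delay) = logit(baseline_delay_prob) + beta_linchpin * linchpin
#'  + beta_caredensity_med * med + beta_caredensity_high * high
#'  + beta_caredensity_sole * sole + b_surgeon + b_hrr`.
#' The same structure generates both the biopsy-to-surgery and the
#' surgery-to-adjuvant gaps (with phase-specific care-density levels), so
#' planted odds ratios are recoverable by the regression layer.
#'
#' @param beta_linchpin Log odds ratio of delay for a (truly) linchpin
#'   surgeon vs not.
#' @param beta_caredensity_med,beta_caredensity_high Log odds ratios for
#'   medium / high care density vs low.
#' @param beta_caredensity_sole Log odds ratio for a sole-clinician
#'   preoperative phase vs low care density (surgery cohort only).
#' @param sigma_npi,sigma_hrr Standard deviations (>= 0) of the surgeon
#'   and HRR random intercepts.
#' @param baseline_delay_prob Delay probability in (0, 1) at reference
#'   exposure levels with zero random effects.
#' @param seed Integer recorded with the truth.
#' @return A list of class `planted_truth`.
#' @export
planted_truth <- function(beta_linchpin = log(1.3),
                          beta_caredensity_med = log(0.85),
                          beta_caredensity_high = log(0.77),
                          beta_caredensity_sole = log(0.35),
                          sigma_npi = 0.25,
                          sigma_hrr = 0.15,
                          baseline_delay_prob = 0.15,
                          seed = 1L) {
  if (sigma_npi < 0 || sigma_hrr < 0) {
    abort("`sigma_npi` and `sigma_hrr` must be non-negative.")
  }
  if (!(baseline_delay_prob > 0 && baseline_delay_prob < 1)) {
    abort("`baseline_delay_prob` must lie strictly in (0, 1).")
  }
  structure(as.list(environment()), class = c("planted_truth", "list"))
}

# rurality levels, most to least urban
PSNET_RURALITY <- c("urban", "large_rural", "small_rural", "isolated")
PSNET_AGE_GROUPS <- c("66-69", "70-74", "75-79", "80-84", ">=85")
PSNET_RACE_LEVELS <- c("asian", "black", "hispanic",
                       "north_american_native", "other", "unknown", "white")
# marginal shares of a Medicare breast-cancer cohort
PSNET_AGE_PROBS <- c(0.2515, 0.3191, 0.2242, 0.1280, 0.0772)
PSNET_RACE_PROBS <- c(0.0117, 0.0609, 0.0058, 0.0031, 0.0143, 0.0147, 0.8895)
PSNET_COMORB_PROBS <- c(0.542, 0.228, 0.230)  # 0 / 1 / >=2

check_config <- function(config) {
  if (!inherits(config, "psnet_config")) config <- do.call(sim_config, config)
  pos <- c("n_hrr", "hsas_per_hrr", "zips_per_hsa", "n_surgeons",
           "n_med_onc", "n_rad_onc", "n_other")
  for (f in pos) {
    if (config[[f]] <= 0) {
      abort(sprintf("Configuration error: `%s` must be positive.", f))
    }
  }
  if (config$n_patients < 0) {
    abort("Configuration error: `n_patients` must be >= 0.")
  }
  if (config$rural_scarcity < 0 || config$rural_scarcity > 1) {
    abort("Configuration error: `rural_scarcity` must lie in [0, 1].")
  }
  config
}

#' Generate the synthetic population and geography
#'
#' Builds the zip/HSA/HRR geography, a physician roster, and a patient
#' table. Rural HSAs carry less surgeon supply per capita whenever
#' `rural_scarcity > 0` (every HRR keeps at least one surgeon, placed in
#' its urban core), which is what later makes rural surgeons structural
#' linchpins. Patient attributes (age band, race and ethnicity, comorbidity
#' count, zip-level deprivation) are drawn with realistic Medicare
#' breast-cancer margins. Deterministic given `(config, seed)`.
#'
#' Patients pre-assigned to violate an attribute-level exclusion rule get
#' the violating attribute here (age out of 66-99, an enrollment gap,
#' multiple primaries, a missing zip); the planted class is recorded in
#' column `excl_class` ("none" for clean patients).
#'
#' @param config A [sim_config()] list.
#' @param seed Integer seed.
#' @return A list with tibbles `patients`, `physicians`, and `geography`
#'   (a list of `zips` and `hsas`).
#' @export
generate_population <- function(config = sim_config(), seed = 1L) {
  config <- check_config(config)
  set.seed(seed)

  # --- geography ----------------------------------------------------------
  n_hsa <- config$n_hrr * config$hsas_per_hrr
  hsas <- tibble(
    hsa = sprintf("HSA%03d", seq_len(n_hsa)),
    hrr = rep(sprintf("HRR%02d", seq_len(config$n_hrr)),
              each = config$hsas_per_hrr)
  )
  rural_levels <- sample(
    PSNET_RURALITY[2:4], n_hsa, replace = TRUE, prob = c(0.5, 0.3, 0.2)
  )
  is_rural <- runif(n_hsa) < config$rural_fraction
  first_of_hrr <- !duplicated(hsas$hrr)
  is_rural[first_of_hrr] <- FALSE  # every HRR keeps an urban core
  hsas$rurality <- ifelse(is_rural, rural_levels, "urban")
  hsas$over65 <- c(urban = 12000, large_rural = 5000,
                   small_rural = 3000, isolated = 2000)[hsas$rurality]

  zips <- hsas |>
    dplyr::slice(rep(seq_len(n_hsa), each = config$zips_per_hsa)) |>
    dplyr::mutate(zip = sprintf("Z%04d", dplyr::row_number()))
  depr_mean <- c(urban = 9, large_rural = 12, small_rural = 14,
                 isolated = 16)[zips$rurality]
  zips$deprivation_pct <- pmin(pmax(rnorm(nrow(zips), depr_mean, 5), 0), 100)
  zips$pop_weight <- c(urban = 5, large_rural = 2, small_rural = 1,
                       isolated = 0.7)[zips$rurality]
  zips <- dplyr::select(zips, "zip", "hsa", "hrr", "rurality",
                        "deprivation_pct", "pop_weight")

  # --- physicians ---------------------------------------------------------
  alloc_hsas <- function(n, rural_penalty) {
    w <- hsas$over65 * ifelse(hsas$rurality == "urban", 1, 1 - rural_penalty)
    sample(hsas$hsa, n, replace = TRUE, prob = pmax(w, 1e-9))
  }
  # Surgeon supply: one guaranteed surgeon per HRR urban core; each rural
  # HSA is staffed by a single solo surgeon with probability
  # 1 - rural_scarcity (the solo rural surgeon is the archetypal
  # linchpin); the rest concentrate in urban HSAs by population.
  core_hsas <- hsas$hsa[first_of_hrr]
  rural_hsas <- hsas$hsa[hsas$rurality != "urban"]
  staffed_rural <- rural_hsas[runif(length(rural_hsas)) <
                                1 - config$rural_scarcity]
  n_extra <- config$n_surgeons - length(core_hsas) - length(staffed_rural)
  if (n_extra < 0) {
    staffed_rural <- head(staffed_rural,
                          max(config$n_surgeons - length(core_hsas), 0))
    n_extra <- 0
  }
  urban_w <- ifelse(hsas$rurality == "urban", hsas$over65, 1e-9)
  surgeon_hsa <- c(core_hsas, staffed_rural,
                   sample(hsas$hsa, n_extra, replace = TRUE,
                          prob = urban_w))
  phys_hsa <- c(
    surgeon_hsa,
    alloc_hsas(config$n_med_onc, 0.4),
    alloc_hsas(config$n_rad_onc, 0.4),
    alloc_hsas(config$n_other, 0)
  )
  specialty <- rep(
    c("surgeon", "medical_oncologist", "radiation_oncologist", "other"),
    c(length(surgeon_hsa), config$n_med_onc, config$n_rad_onc,
      config$n_other)
  )
  n_phys <- length(specialty)
  physicians <- tibble(
    physician_id = sprintf("D%05d", seq_len(n_phys)),
    specialty = specialty,
    hsa = phys_hsa
  ) |>
    dplyr::left_join(dplyr::select(hsas, "hsa", "hrr", "rurality"),
                     by = "hsa") |>
    dplyr::group_by(.data$hsa) |>
    dplyr::mutate(zip = sample(zips$zip[zips$hsa == .data$hsa[1]],
                               dplyr::n(), replace = TRUE)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      gender = ifelse(runif(n_phys) < ifelse(.data$specialty == "surgeon",
                                             0.42, 0.50),
                      "woman", "man")
    ) |>
    dplyr::select("physician_id", "specialty", "gender", "zip", "hsa",
                  "hrr", "rurality")

  # --- patients -----------------------------------------------------------
  n <- config$n_patients
  if (n == 0) {
    patients <- tibble(
      patient_id = character(), age = integer(), age_group = character(),
      race_ethnicity = character(), zip = character(), hsa = character(),
      hrr = character(), rurality = character(), deprivation_pct = numeric(),
      comorbidity_count = integer(), enrolled_continuously = logical(),
      nci_affiliated_surgery = logical(), multiple_primaries = logical(),
      excl_class = character()
    )
    return(list(patients = patients, physicians = physicians,
                geography = list(zips = zips, hsas = hsas)))
  }

  zip_idx <- sample(nrow(zips), n, replace = TRUE, prob = zips$pop_weight)
  age_band <- sample(seq_along(PSNET_AGE_GROUPS), n, replace = TRUE,
                     prob = PSNET_AGE_PROBS)
  age_lo <- c(66, 70, 75, 80, 85)[age_band]
  age_hi <- c(69, 74, 79, 84, 99)[age_band]
  age <- age_lo + floor(runif(n) * (age_hi - age_lo + 1))
  comorb_band <- sample(0:2, n, replace = TRUE, prob = PSNET_COMORB_PROBS)
  comorbidity <- ifelse(comorb_band == 2, 2L + rpois(n, 0.8),
                        as.integer(comorb_band))

  patients <- tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    age = as.integer(age),
    race_ethnicity = sample(PSNET_RACE_LEVELS, n, replace = TRUE,
                            prob = PSNET_RACE_PROBS),
    zip = zips$zip[zip_idx],
    hsa = zips$hsa[zip_idx],
    hrr = zips$hrr[zip_idx],
    rurality = zips$rurality[zip_idx],
    deprivation_pct = zips$deprivation_pct[zip_idx],
    comorbidity_count = comorbidity,
    enrolled_continuously = TRUE,
    multiple_primaries = FALSE
  )
  patients$nci_affiliated_surgery <-
    runif(n) < ifelse(patients$rurality == "urban", 0.16, 0.03)

  # --- planted exclusion classes (disjoint) -------------------------------
  fr <- config$exclusion_fractions
  classes <- c("prior_cancer_dx", "age_out_of_range", "enrollment_gap",
               "multiple_cancers", "bad_zip", "metastatic_90d",
               "neoadjuvant", "same_day_reconstruction")
  counts <- vapply(classes, function(cl) round((fr[[cl]] %||% 0) * n), 0)
  excl_class <- rep("none", n)
  pool <- sample(n)  # random order, carve disjoint blocks
  offset <- 0
  for (i in seq_along(classes)) {
    k <- min(counts[i], length(pool) - offset)
    if (k > 0) excl_class[pool[offset + seq_len(k)]] <- classes[i]
    offset <- offset + k
  }
  patients$excl_class <- excl_class

  # inject attribute-level violations
  out_age <- excl_class == "age_out_of_range"
  if (any(out_age)) {
    patients$age[out_age] <- ifelse(runif(sum(out_age)) < 0.5,
                                    sample(60:65, sum(out_age), TRUE),
                                    sample(100:104, sum(out_age), TRUE))
  }
  patients$enrolled_continuously[excl_class == "enrollment_gap"] <- FALSE
  patients$multiple_primaries[excl_class == "multiple_cancers"] <- TRUE
  patients$zip[excl_class == "bad_zip"] <- NA_character_

  # age_group is the analysis banding of age, clamped into the study range
  band <- cut(pmin(pmax(patients$age, 66L), 99L),
              breaks = c(65, 69, 74, 79, 84, 99),
              labels = PSNET_AGE_GROUPS)
  patients$age_group <- as.character(band)
  patients <- dplyr::relocate(patients, "age_group", .after = "age")

  list(patients = patients, physicians = physicians,
       geography = list(zips = zips, hsas = hsas))
}

# gravity-weighted assignment of one candidate physician per patient,
# grouped by patient HSA so each group samples from one probability vector
assign_gravity <- function(patient_hsa, patient_hrr, candidates,
                           w_hsa = 100, w_hrr = 10, w_other = 1) {
  out <- character(length(patient_hsa))
  keys <- paste(patient_hsa, patient_hrr)
  for (key in unique(keys)) {
    idx <- which(keys == key)
    w <- ifelse(candidates$hsa == patient_hsa[idx[1]], w_hsa,
                ifelse(candidates$hrr == patient_hrr[idx[1]], w_hrr, w_other))
    out[idx] <- sample(candidates$physician_id, length(idx),
                       replace = TRUE, prob = w)
  }
  out
}

# sample k distinct extra team members per patient from a locality pool
sample_team_members <- function(pool_ids, k, exclude) {
  pool_ids <- setdiff(pool_ids, exclude)
  if (k <= 0 || length(pool_ids) == 0) return(character())
  sample(pool_ids, min(k, length(pool_ids)))
}

#' Generate the synthetic encounter stream with planted delay effects
#'
#' Emits one encounter row per patient-physician contact: a single biopsy
#' per patient, two confirmatory cancer diagnoses within 12 months,
#' cancer-directed surgery for `surgery_fraction` of patients, adjuvant
#' chemotherapy or radiotherapy for `adjuvant_fraction` of those, plus
#' preoperative and postoperative team visits. The biopsy-to-surgery and
#' surgery-to-adjuvant gaps are drawn so that the probability of a gap
#' exceeding the 60-day cutoff follows the logistic model encoded in
#' `truth`, with the patient's true exposures and the surgeon/HRR random
#' intercepts. Patients pre-assigned to an encounter-level exclusion class
#' receive the violating pattern (a pre-biopsy cancer code, an early
#' metastatic code, pre-surgery chemo/radiotherapy, or same-day
#' reconstruction).
#'
#' Linchpin exposure is planted structurally: a surgeon is a true linchpin
#' when no other surgeon practises in their HSA, which concentrates in
#' rural areas under surgeon scarcity. Care-density levels are planted per
#' patient and phase and steer how locally the extra team members are
#' drawn (high = within-HSA, medium = within-HRR, low = anywhere), so the
#' measured network exposures track the planted ones without being copies
#' of them.
#'
#' @param population Output of [generate_population()].
#' @param truth A [planted_truth()].
#' @param config The same [sim_config()] used for the population.
#' @param seed Integer seed.
#' @return A list: `encounters` (tibble `patient_id`, `physician_id`,
#'   `service_date`, `event_class`) and `truth` (the input truth augmented
#'   with per-patient `assignments` and per-cluster random intercepts).
#' @export
generate_encounters <- function(population, truth = planted_truth(),
                                config = sim_config(), seed = 1L) {
  stopifnot(inherits(truth, "planted_truth"))
  config <- check_config(config)
  if (!(truth$baseline_delay_prob > 0 && truth$baseline_delay_prob < 1)) {
    abort("`baseline_delay_prob` must lie strictly in (0, 1).")
  }
  set.seed(seed)

  pat <- population$patients
  phys <- population$physicians
  n <- nrow(pat)
  if (n == 0) {
    return(list(
      encounters = tibble(patient_id = character(),
                          physician_id = character(),
                          service_date = integer(),
                          event_class = character()),
      truth = c(truth, list(assignments = tibble(),
                            surgeon_effects = tibble(),
                            hrr_effects = tibble()))
    ))
  }

  surgeons <- dplyr::filter(phys, .data$specialty == "surgeon")
  med_onc <- dplyr::filter(phys, .data$specialty == "medical_oncologist")
  rad_onc <- dplyr::filter(phys, .data$specialty == "radiation_oncologist")
  others <- dplyr::filter(phys, .data$specialty == "other")
  oncs <- dplyr::filter(phys,
                        .data$specialty %in% PSNET_ONCOLOGIST_SPECIALTIES)

  # structural linchpin truth, fixed after the routing step below: a
  # surgeon some community depends on exclusively (sole surgeon of their
  # own HSA, or the designated surgeon of an HSA with none)

  # cluster random intercepts
  b_npi <- setNames(rnorm(nrow(surgeons), 0, truth$sigma_npi),
                    surgeons$physician_id)
  hrr_ids <- sort(unique(population$geography$hsas$hrr))
  b_hrr <- setNames(rnorm(length(hrr_ids), 0, truth$sigma_hrr), hrr_ids)

  # geography fallback for bad-zip patients: HSA/HRR retained internally
  pat_hsa <- pat$hsa
  pat_hrr <- pat$hrr

  # Surgeon choice concentrates locally: patients whose HSA has surgeons
  # pick among them; an HSA with no surgeon routes to one designated
  # regional surgeon (how single rural surgeons come to anchor whole
  # communities); a small leakage fraction shops further afield.
  hsa_ids <- population$geography$hsas$hsa
  designated <- vapply(hsa_ids, function(h) {
    local <- surgeons$physician_id[surgeons$hsa == h]
    if (length(local) > 0) return(local[1])
    hrr_h <- population$geography$hsas$hrr[hsa_ids == h]
    w <- ifelse(surgeons$hrr == hrr_h, 10, 1)
    sample(surgeons$physician_id, 1, prob = w)
  }, character(1))
  loyal <- runif(n) < 0.9
  surgeon_id <- character(n)
  for (h in unique(pat_hsa)) {
    idx <- which(pat_hsa == h)
    local <- surgeons$physician_id[surgeons$hsa == h]
    if (length(local) > 0) {
      surgeon_id[idx] <- sample(local, length(idx), replace = TRUE)
    } else {
      surgeon_id[idx] <- designated[[h]]
    }
  }
  stray <- which(!loyal)
  if (length(stray) > 0) {
    surgeon_id[stray] <- assign_gravity(pat_hsa[stray], pat_hrr[stray],
                                        surgeons)
  }

  surg_per_hsa <- table(surgeons$hsa)
  sole_in_hsa <- as.integer(surg_per_hsa[surgeons$hsa]) == 1L
  hsa_has_surgeon <- hsa_ids %in% surgeons$hsa
  serves_bare_hsa <- surgeons$physician_id %in% designated[!hsa_has_surgeon]
  linchpin_true_surgeon <- setNames(sole_in_hsa | serves_bare_hsa,
                                    surgeons$physician_id)
  has_surgery <- runif(n) < config$surgery_fraction &
    pat$excl_class != "no_surgery"
  has_adjuvant <- has_surgery & runif(n) < config$adjuvant_fraction

  sole_pre <- has_surgery & runif(n) < config$sole_clinician_fraction
  cd_pre <- ifelse(sole_pre, "sole_clinician",
                   sample(c("low", "medium", "high"), n, replace = TRUE))
  cd_post <- sample(c("low", "medium", "high"), n, replace = TRUE)

  lin_true <- unname(linchpin_true_surgeon[surgeon_id])

  eta_base <- qlogis(truth$baseline_delay_prob) +
    truth$beta_linchpin * lin_true +
    unname(b_npi[surgeon_id]) + unname(b_hrr[pat_hrr])
  eta_surg <- eta_base +
    truth$beta_caredensity_med * (cd_pre == "medium") +
    truth$beta_caredensity_high * (cd_pre == "high") +
    truth$beta_caredensity_sole * (cd_pre == "sole_clinician")
  eta_adj <- eta_base +
    truth$beta_caredensity_med * (cd_post == "medium") +
    truth$beta_caredensity_high * (cd_post == "high")

  delayed_surg <- runif(n) < plogis(eta_surg)
  delayed_adj <- runif(n) < plogis(eta_adj)
  # gaps: delayed draws exceed the 60-day cutoff, timely draws do not;
  # the delayed tail extends past 90 so the sensitivity cutoff bites
  gap_surg <- ifelse(delayed_surg, sample(61:150, n, TRUE),
                     sample(15:60, n, TRUE))
  gap_adj <- ifelse(delayed_adj, sample(61:150, n, TRUE),
                    sample(14:60, n, TRUE))

  biopsy_day <- sample(0:90, n, replace = TRUE)
  surgery_day <- biopsy_day + gap_surg
  adjuvant_day <- surgery_day + gap_adj

  # adjuvant modality and provider
  adj_is_chemo <- runif(n) < 0.5
  adj_provider <- character(n)
  idx <- which(adj_is_chemo)
  if (length(idx) > 0) {
    adj_provider[idx] <- assign_gravity(pat_hsa[idx], pat_hrr[idx], med_onc)
  }
  idx <- which(!adj_is_chemo)
  if (length(idx) > 0) {
    adj_provider[idx] <- assign_gravity(pat_hsa[idx], pat_hrr[idx], rad_onc)
  }

  # biopsy / diagnosis provider: the surgeon for sole-clinician patients,
  # otherwise a local non-oncologist
  biopsy_provider <- assign_gravity(pat_hsa, pat_hrr, others,
                                    w_hsa = 100, w_hrr = 5, w_other = 0.5)
  biopsy_provider[sole_pre] <- surgeon_id[sole_pre]

  # Extra team members, locality steered by the planted care-density
  # level: high-density teams stay inside the patient's HSA, medium
  # teams are a 70/30 HSA/HRR mixture, low-density teams scatter across
  # the whole roster. Localised teams re-use the same few colleagues, so
  # measured care density rises with the planted level; dispersed teams
  # rarely cross the shared-patient tie threshold anywhere.
  draw_members <- function(level, hsa, hrr, roster, k, exclude) {
    if (k <= 0) return(character())
    hsa_pool <- roster$physician_id[roster$hsa == hsa]
    hrr_pool <- roster$physician_id[roster$hrr == hrr]
    if (length(hsa_pool) == 0) hsa_pool <- hrr_pool
    if (level == "high") {
      return(sample_team_members(hsa_pool, k, exclude))
    }
    if (level == "medium") {
      k_local <- rbinom(1, k, 0.7)
      local <- sample_team_members(hsa_pool, k_local, exclude)
      regional <- sample_team_members(hrr_pool, k - k_local,
                                      c(exclude, local))
      return(c(local, regional))
    }
    sample_team_members(roster$physician_id, k, exclude)
  }
  k_pre <- ifelse(sole_pre, 0L, rpois(n, config$pre_team_lambda))
  k_post <- ifelse(has_adjuvant, rpois(n, config$post_team_lambda), 0L)
  pre_roster <- dplyr::filter(phys, .data$specialty != "surgeon")
  pre_members <- lapply(seq_len(n), function(i) {
    if (!has_surgery[i]) return(character())
    draw_members(cd_pre[i], pat_hsa[i], pat_hrr[i], pre_roster, k_pre[i],
                 c(surgeon_id[i], biopsy_provider[i]))
  })
  post_members <- lapply(seq_len(n), function(i) {
    if (!has_adjuvant[i]) return(character())
    draw_members(cd_post[i], pat_hsa[i], pat_hrr[i], oncs, k_post[i],
                 c(surgeon_id[i], adj_provider[i]))
  })

  # --- emit encounters ----------------------------------------------------
  rows <- list()
  add <- function(pid, did, day, class) {
    tibble(patient_id = pid, physician_id = did,
           service_date = as.integer(day), event_class = class)
  }
  rows$biopsy <- add(pat$patient_id, biopsy_provider, biopsy_day, "biopsy")
  rows$dx1 <- add(pat$patient_id, biopsy_provider, biopsy_day + 3, "cancer_dx")
  rows$dx2 <- add(pat$patient_id, biopsy_provider, biopsy_day + 10, "cancer_dx")

  surg_idx <- which(has_surgery)
  rows$consult <- add(pat$patient_id[surg_idx], surgeon_id[surg_idx],
                      biopsy_day[surg_idx] + 7, "visit")
  rows$surgery <- add(pat$patient_id[surg_idx], surgeon_id[surg_idx],
                      surgery_day[surg_idx], "surgery")

  pre_len <- lengths(pre_members)
  if (sum(pre_len) > 0) {
    i_rep <- rep(seq_len(n), pre_len)
    # visits spread through the preoperative window, before surgery
    vday <- biopsy_day[i_rep] +
      sample(-60:10, sum(pre_len), replace = TRUE)
    vday <- pmin(vday, surgery_day[i_rep] - 1)
    rows$pre_visits <- add(pat$patient_id[i_rep], unlist(pre_members),
                           vday, "visit")
  }

  adj_idx <- which(has_adjuvant)
  if (length(adj_idx) > 0) {
    rows$adjuvant <- add(
      pat$patient_id[adj_idx], adj_provider[adj_idx],
      adjuvant_day[adj_idx],
      ifelse(adj_is_chemo[adj_idx], "chemotherapy", "radiotherapy")
    )
    # follow-on cycles
    rows$adjuvant2 <- add(
      pat$patient_id[adj_idx], adj_provider[adj_idx],
      adjuvant_day[adj_idx] + 21,
      ifelse(adj_is_chemo[adj_idx], "chemotherapy", "radiotherapy")
    )
    post_len <- lengths(post_members)
    if (sum(post_len) > 0) {
      i_rep <- rep(seq_len(n), post_len)
      frac <- runif(sum(post_len), 0.2, 0.9)
      vday <- floor(surgery_day[i_rep] +
                      frac * (adjuvant_day[i_rep] - surgery_day[i_rep]))
      rows$post_visits <- add(pat$patient_id[i_rep], unlist(post_members),
                              vday, "visit")
    }
  }

  # exclusion-rule violating patterns
  cls <- pat$excl_class
  v <- which(cls == "prior_cancer_dx")
  if (length(v) > 0) {
    rows$viol_prior <- add(pat$patient_id[v], biopsy_provider[v],
                           biopsy_day[v] - 40, "cancer_dx")
  }
  v <- which(cls == "metastatic_90d")
  if (length(v) > 0) {
    rows$viol_met <- add(pat$patient_id[v], biopsy_provider[v],
                         biopsy_day[v] + 45, "metastatic_dx")
  }
  v <- which(cls == "neoadjuvant" & has_surgery)
  if (length(v) > 0) {
    neo_provider <- assign_gravity(pat_hsa[v], pat_hrr[v], med_onc)
    rows$viol_neo <- add(pat$patient_id[v], neo_provider,
                         biopsy_day[v] + 5, "chemotherapy")
  }
  v <- which(cls == "same_day_reconstruction" & has_surgery)
  if (length(v) > 0) {
    rows$viol_recon <- add(pat$patient_id[v], surgeon_id[v],
                           surgery_day[v], "reconstruction")
  }
  # benign reconstructions well after surgery for a few clean patients
  v <- which(cls == "none" & has_surgery & runif(n) < 0.05)
  if (length(v) > 0) {
    rows$late_recon <- add(pat$patient_id[v], surgeon_id[v],
                           surgery_day[v] + 45, "reconstruction")
  }

  encounters <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$patient_id, .data$service_date,
                   .data$event_class, .data$physician_id)

  assignments <- tibble(
    patient_id = pat$patient_id,
    surgeon_id = surgeon_id,
    hrr = pat_hrr,
    linchpin_true = lin_true,
    cd_pre_true = cd_pre,
    cd_post_true = cd_post,
    has_surgery = has_surgery,
    has_adjuvant = has_adjuvant,
    delayed_surg_true = delayed_surg,
    delayed_adj_true = delayed_adj,
    gap_surg = as.integer(gap_surg),
    gap_adj = as.integer(gap_adj),
    excl_class = cls
  )
  truth_out <- truth
  truth_out$assignments <- assignments
  truth_out$surgeon_effects <- tibble(
    physician_id = surgeons$physician_id,
    b_npi = unname(b_npi),
    linchpin_true = unname(linchpin_true_surgeon)
  )
  truth_out$hrr_effects <- tibble(hrr = hrr_ids, b_hrr = unname(b_hrr))
  class(truth_out) <- class(truth)

  list(encounters = encounters, truth = truth_out)
}

#' One-call synthetic claims simulation
#'
#' Convenience wrapper running [generate_population()] then
#' [generate_encounters()] with seeds derived from `seed`.
#'
#' @inheritParams generate_encounters
#' @param seed Integer seed driving both stages.
#' @return A list: `patients`, `physicians`, `geography`, `encounters`,
#'   `truth`.
#' @export
simulate_claims <- function(config = sim_config(), truth = planted_truth(),
                            seed = 1L) {
  pop <- generate_population(config, seed = seed)
  enc <- generate_encounters(pop, truth, config, seed = seed + 1L)
  c(pop, enc)
}

#' Serialise planted truth to JSON and back
#'
#' Round-trips the planted parameters and, when present, the per-patient
#' exposure assignments and per-cluster random intercepts, losslessly
#' (numbers are written at full precision).
#'
#' @param truth A [planted_truth()], possibly augmented by
#'   [generate_encounters()].
#' @param path File path for the JSON record.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` the
#'   reconstructed `planted_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "planted_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("assignments", "surgeon_effects", "hrr_effects")) {
    if (!is.null(x[[f]])) x[[f]] <- as_tibble(x[[f]])
  }
  structure(x, class = c("planted_truth", "list"))
}
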