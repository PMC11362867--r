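mk_patient <- function(pid, age = 72, enrolled = TRUE, multi = FALSE,
                       zip = "Z1") {
  tibble::tibble(patient_id = pid, age = age,
                 enrolled_continuously = enrolled,
                 multiple_primaries = multi, zip = zip)
}

# a clean incident-cancer record: biopsy day 100, two diagnoses, surgery
base_events <- function(pid, biopsy = 100, surgery = 140) {
  tibble::tibble(
    patient_id = pid,
    physician_id = "d1",
    service_date = as.integer(c(biopsy, biopsy + 3, biopsy + 10, surgery)),
    event_class = c("biopsy", "cancer_dx", "cancer_dx", "surgery")
  )
}

test_that("each exclusion rule fires with its documented reason", {
  pats <- dplyr::bind_rows(
    mk_patient("ok"), mk_patient("prior"), mk_patient("young", age = 64),
    mk_patient("old", age = 100), mk_patient("gap", enrolled = FALSE),
    mk_patient("multi", multi = TRUE), mk_patient("nozip", zip = NA),
    mk_patient("met"), mk_patient("neo"), mk_patient("recon"),
    mk_patient("nosurg"), mk_patient("nocase")
  )
  enc <- dplyr::bind_rows(
    base_events("ok"), base_events("prior"), base_events("young"),
    base_events("old"), base_events("gap"), base_events("multi"),
    base_events("nozip"), base_events("met"), base_events("neo"),
    base_events("recon"),
    # cancer diagnosis 30 days before biopsy
    tibble::tibble(patient_id = "prior", physician_id = "d1",
                   service_date = 70L, event_class = "cancer_dx"),
    # metastatic code 45 days after biopsy
    tibble::tibble(patient_id = "met", physician_id = "d1",
                   service_date = 145L, event_class = "metastatic_dx"),
    # chemotherapy before first surgery
    tibble::tibble(patient_id = "neo", physician_id = "d1",
                   service_date = 110L, event_class = "chemotherapy"),
    # reconstruction on the surgery day
    tibble::tibble(patient_id = "recon", physician_id = "d1",
                   service_date = 140L, event_class = "reconstruction"),
    # no surgery at all
    base_events("nosurg")[1:3, ],
    # biopsy but a single confirmatory diagnosis
    base_events("nocase")[c(1, 2, 4), ]
  )
  flags <- apply_cohort_filters(pats, enc)
  reason <- setNames(as.character(flags$exclusion_reason), flags$patient_id)
  expect_equal(reason[["ok"]], "none")
  expect_equal(reason[["prior"]], "prior_cancer_dx")
  expect_equal(reason[["young"]], "age_out_of_range")
  expect_equal(reason[["old"]], "age_out_of_range")
  expect_equal(reason[["gap"]], "enrollment_gap")
  expect_equal(reason[["multi"]], "multiple_cancers")
  expect_equal(reason[["nozip"]], "bad_zip")
  expect_equal(reason[["met"]], "metastatic_90d")
  expect_equal(reason[["neo"]], "neoadjuvant")
  expect_equal(reason[["recon"]], "same_day_reconstruction")
  expect_equal(reason[["nosurg"]], "no_surgery")
  expect_equal(reason[["nocase"]], "no_incident_cancer")
})

test_that("the first failing rule wins when several apply", {
  p <- mk_patient("both", age = 64)
  e <- dplyr::bind_rows(
    base_events("both"),
    tibble::tibble(patient_id = "both", physician_id = "d1",
                   service_date = 70L, event_class = "cancer_dx")
  )
  flags <- apply_cohort_filters(p, e)
  expect_equal(as.character(flags$exclusion_reason), "prior_cancer_dx")
})

test_that("filter tallies equal the generator's planted violation counts", {
  cl <- tiny_claims(seed = 12, n_patients = 800, surgery_fraction = 1)
  flags <- apply_cohort_filters(cl$patients, cl$encounters)
  planted <- table(cl$patients$excl_class)
  got <- table(as.character(flags$exclusion_reason))
  for (cls in setdiff(names(planted), "none")) {
    expect_equal(unname(got[cls]), unname(planted[cls]), info = cls)
  }
  expect_equal(unname(got["none"]), unname(planted["none"]))
})

test_that("the filter cascade is idempotent", {
  cl <- tiny_claims(seed = 13, n_patients = 500)
  flags <- apply_cohort_filters(cl$patients, cl$encounters)
  keep <- dplyr::semi_join(cl$patients,
                           dplyr::filter(flags, !excluded),
                           by = "patient_id")
  again <- apply_cohort_filters(keep, cl$encounters)
  expect_false(any(again$excluded))
})

test_that("treatment identification selects first/last surgery and first
          adjuvant", {
  phys <- tibble::tibble(
    physician_id = c("s1", "m1", "r1"),
    specialty = c("surgeon", "medical_oncologist", "radiation_oncologist")
  )
  enc <- tibble::tibble(
    patient_id = "p1",
    physician_id = c("s1", "s1", "m1", "m1"),
    service_date = c(10L, 30L, 75L, 96L),
    event_class = c("surgery", "surgery", "chemotherapy", "chemotherapy")
  )
  cohort <- tibble::tibble(patient_id = "p1", biopsy_date = 0L)
  tr <- identify_treatments(enc, cohort, phys)
  expect_equal(tr$first_surgery, 10)
  expect_equal(tr$last_surgery, 30)
  expect_equal(tr$first_adjuvant, 75)
  expect_equal(tr$surgeon_id, "s1")

  # no adjuvant event -> surgery cohort only
  tr2 <- identify_treatments(enc[1:2, ], cohort, phys)
  expect_true(is.na(tr2$first_adjuvant))

  # chemotherapy billed by a non-medical-oncologist never counts
  enc3 <- enc
  enc3$physician_id[3:4] <- "r1"
  tr3 <- identify_treatments(enc3, cohort, phys)
  expect_true(is.na(tr3$first_adjuvant))

  # surgery before biopsy is a data fault: dropped with a warning
  expect_warning(
    tr4 <- identify_treatments(
      enc, tibble::tibble(patient_id = "p1", biopsy_date = 20L), phys
    ),
    "before biopsy"
  )
  expect_equal(nrow(tr4), 0)
})

test_that("treatment identification matches a brute-force scan", {
  set.seed(91)
  phys <- tibble::tibble(
    physician_id = sprintf("d%d", 1:12),
    specialty = rep(c("surgeon", "medical_oncologist",
                      "radiation_oncologist", "other"), 3)
  )
  spec <- setNames(phys$specialty, phys$physician_id)
  for (rep in 1:5) {
    enc <- tibble::tibble(
      patient_id = sample(sprintf("p%d", 1:10), 120, TRUE),
      physician_id = sample(phys$physician_id, 120, TRUE),
      service_date = sample(1:300, 120, TRUE),
      event_class = sample(c("surgery", "chemotherapy", "radiotherapy",
                             "visit"), 120, TRUE)
    )
    cohort <- tibble::tibble(patient_id = sprintf("p%d", 1:10),
                             biopsy_date = 0L)
    tr <- identify_treatments(enc, cohort, phys)
    for (pid in cohort$patient_id) {
      e <- enc[enc$patient_id == pid, ]
      surg <- e$service_date[e$event_class == "surgery" &
                               spec[e$physician_id] == "surgeon"]
      if (length(surg) == 0) {
        expect_false(pid %in% tr$patient_id)
        next
      }
      row <- tr[tr$patient_id == pid, ]
      expect_equal(row$first_surgery, min(surg))
      expect_equal(row$last_surgery, max(surg))
      adj <- e$service_date[
        e$service_date > max(surg) &
          ((e$event_class == "chemotherapy" &
              spec[e$physician_id] == "medical_oncologist") |
             (e$event_class == "radiotherapy" &
                spec[e$physician_id] == "radiation_oncologist"))]
      if (length(adj) == 0) expect_true(is.na(row$first_adjuvant))
      else expect_equal(row$first_adjuvant, min(adj))
    }
  }
})

test_that("delay uses a strict cutoff at 60 and 90 days", {
  expect_false(delay_flag(60))
  expect_true(delay_flag(61))
  expect_false(delay_flag(90, cutoff = 90))
  expect_true(delay_flag(91, cutoff = 90))
  expect_false(delay_flag(0))
  expect_error(delay_flag(-1), "non-negative")
})

test_that("deprivation bins cut at 5/10/15/20 with an inclusive top bin", {
  expect_equal(as.character(bin_deprivation(c(4.99, 5, 9.99, 10, 15, 19.99,
                                              20, 100))),
               c("very_low", "low", "low", "medium", "high", "high",
                 "very_high", "very_high"))
  expect_error(bin_deprivation(101), "\\[0, 100\\]")
  expect_error(bin_deprivation(-2), "\\[0, 100\\]")
  expect_true(is.na(bin_deprivation(NA)))
})

test_that("tertile binning is nearest-rank with downward tie collapse", {
  expect_equal(as.vector(table(bin_tertiles(1:9))), c(3, 3, 3))
  expect_true(all(bin_tertiles(rep(4, 10)) == "low"))
  set.seed(8)
  for (rep in 1:25) {
    v <- sample(1:12, sample(5:40, 1), replace = TRUE)
    got <- bin_tertiles(v)
    s <- sort(v)
    q1 <- s[ceiling(length(s) / 3)]
    q2 <- s[ceiling(2 * length(s) / 3)]
    want <- ifelse(v <= q1, "low", ifelse(v <= q2, "medium", "high"))
    expect_equal(as.character(got), want)
  }
  # distinct values split as evenly as possible
  sizes <- table(bin_tertiles(sample(100, 20)))
  expect_lte(max(sizes) - min(sizes), 1)
})

test_that("analysis rows carry coherent exposures, outcomes and windows", {
  cl <- tiny_claims(seed = 3, n_patients = 1200)
  flags <- apply_cohort_filters(cl$patients, cl$encounters)
  included <- dplyr::filter(flags, !excluded)
  inc <- build_incidence(
    cl$encounters, dplyr::semi_join(cl$patients, included, by = "patient_id")
  )
  g <- project_sharing_graph(inc, cl$physicians)
  lin <- flag_linchpins(linchpin_scores(g, "surgeon"))
  tr <- identify_treatments(cl$encounters, included, cl$physicians, g)
  over65 <- cl$geography$hsas |>
    dplyr::group_by(hrr) |>
    dplyr::summarise(over65 = sum(over65), .groups = "drop")
  rows <- assemble_analysis_rows(cl$patients, cl$encounters, g, tr, lin,
                                 over65, cl$physicians)

  expect_true(all(rows$adjuvant$patient_id %in% rows$surgery$patient_id))
  expect_true(all(rows$surgery$interval_days >= 0))
  expect_equal(rows$surgery$delayed, rows$surgery$interval_days > 60)

  # sole-clinician level marks team size one, and cd is defined iff >= 2
  s <- rows$surgery
  expect_true(all(s$team_size[s$care_density_level == "sole_clinician"] == 1))
  expect_true(all(!is.na(s$cd[s$team_size >= 2])))

  # generator sole-clinician patients land in the sole-clinician level
  sole_truth <- cl$truth$assignments |>
    dplyr::filter(cd_pre_true == "sole_clinician",
                  patient_id %in% s$patient_id)
  got_levels <- s$care_density_level[match(sole_truth$patient_id,
                                           s$patient_id)]
  expect_gt(mean(got_levels == "sole_clinician"), 0.9)

  # a row's care density matches an independent recomputation of its
  # preoperative team
  spot <- s[sample(nrow(s), 25), ]
  tr_idx <- tr[match(spot$patient_id, tr$patient_id), ]
  for (i in seq_len(nrow(spot))) {
    win_enc <- cl$encounters[
      cl$encounters$patient_id == spot$patient_id[i] &
        cl$encounters$service_date >= tr_idx$biopsy_date[i] - 91 &
        cl$encounters$service_date <= tr_idx$first_surgery[i], ]
    want <- oracle_care_density(g$edges, g$nodes$physician_id,
                                unique(win_enc$physician_id))
    expect_equal(spot$cd[i], want$cd, info = spot$patient_id[i])
    expect_equal(spot$team_size[i], want$team_size)
  }

  # raising the cutoff to 90 never adds a delayed patient, in each cohort
  for (coh in c("surgery", "adjuvant")) {
    d60 <- sum(delay_flag(rows[[coh]]$interval_days, 60))
    d90 <- sum(delay_flag(rows[[coh]]$interval_days, 90))
    expect_lte(d90, d60)
  }
})
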