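#' Run the full pipeline: simulate, assemble, measure, fit, report
#'
#' End-to-end orchestration over the package's stages: synthetic claims
#' generation, network assembly, exposure measures, cohort construction,
#' bivariate tables, and the hierarchical delay models at the primary and
#' sensitivity cutoffs. Every stage output is written as delimited text
#' under `out_dir`, together with a JSON manifest holding the seed, a hash
#' of the configuration, and the file inventory, so a re-run with the same
#' configuration reproduces the same tables.
#'
#' @param config A [sim_config()].
#' @param truth A [planted_truth()].
#' @param seed Integer seed for the whole run.
#' @param out_dir Output directory (created if missing).
#' @param cutoffs Delay cutoffs to fit, default `c(60, 90)` (primary and
#'   sensitivity).
#' @param min_shared,min_patients,top_fraction Network and linchpin
#'   thresholds.
#' @return Invisibly, a list with the in-memory stage results (`claims`,
#'   `graph`, `linchpin`, `cohorts`, `fits`, `manifest`).
#' @export
run_pipeline <- function(config = sim_config(), truth = planted_truth(),
                         seed = 1L, out_dir = tempfile("psnet_run_"),
                         cutoffs = c(60, 90), min_shared = 3L,
                         min_patients = 5L, top_fraction = 0.15) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- character()

  # 1. simulate
  claims <- simulate_claims(config, truth, seed = seed)
  files <- c(files, tsv(claims$patients, "patients.tsv"),
             tsv(claims$physicians, "physicians.tsv"),
             tsv(claims$encounters, "encounters.tsv"),
             tsv(claims$geography$zips, "zips.tsv"),
             tsv(claims$geography$hsas, "hsas.tsv"))
  write_truth(claims$truth, file.path(out_dir, "truth.json"))
  files <- c(files, file.path(out_dir, "truth.json"))

  # 2. cohort entry + network assembly
  flags <- apply_cohort_filters(claims$patients, claims$encounters)
  included <- dplyr::filter(flags, !.data$excluded)
  incidence <- build_incidence(
    claims$encounters,
    dplyr::semi_join(claims$patients, included, by = "patient_id"),
    days_before = config$days_before, days_after = config$days_after
  )
  graph <- project_sharing_graph(incidence, claims$physicians,
                                 min_shared = min_shared,
                                 min_patients = min_patients)
  write_sharing_graph(graph, file.path(out_dir, "graph_edges.tsv"),
                      file.path(out_dir, "graph_nodes.tsv"))
  files <- c(files, tsv(exclusion_flow(flags), "exclusion_flow.tsv"),
             file.path(out_dir, c("graph_edges.tsv", "graph_nodes.tsv")))

  # 3. exposure measures
  linchpin <- flag_linchpins(linchpin_scores(graph, "surgeon"),
                             top_fraction = top_fraction)
  files <- c(files, tsv(linchpin, "linchpin_scores.tsv"))

  # 4. treatment cohorts and analysis rows
  treatments <- identify_treatments(claims$encounters, included,
                                    claims$physicians, graph)
  over65 <- claims$geography$hsas |>
    dplyr::group_by(.data$hrr) |>
    dplyr::summarise(over65 = sum(.data$over65), .groups = "drop")
  cohorts <- assemble_analysis_rows(
    claims$patients, claims$encounters, graph, treatments, linchpin,
    over65, claims$physicians, cutoff = cutoffs[1],
    days_before = config$days_before
  )
  files <- c(files, tsv(cohorts$surgery, "analysis_rows_surgery.tsv"),
             tsv(cohorts$adjuvant, "analysis_rows_adjuvant.tsv"))

  # 5. bivariate tables and hierarchical fits
  biv <- bivariate_report(
    cohorts$surgery,
    c("age_group", "race_ethnicity", "comorbidity_bin", "deprivation_bin",
      "nci_affiliated_surgery", "patient_rurality"),
    "linchpin_exposed"
  )
  files <- c(files, tsv(biv, "bivariate_surgery.tsv"))

  fits <- list()
  for (co in cutoffs) {
    for (coh in c("surgery", "adjuvant")) {
      key <- sprintf("%s_%d", coh, co)
      fit <- fit_delay_model(cohorts[[coh]], cutoff = co)
      fits[[key]] <- fit
      files <- c(files, write_model_report(
        fit, file.path(out_dir, sprintf("model_%s.tsv", key))
      ))
    }
  }

  manifest <- list(
    seed = seed,
    config_hash = rlang::hash(list(config = unclass(config),
                                   truth = unclass(truth[
                                     !names(truth) %in%
                                       c("assignments", "surgeon_effects",
                                         "hrr_effects")]),
                                   cutoffs = cutoffs,
                                   min_shared = min_shared,
                                   min_patients = min_patients,
                                   top_fraction = top_fraction)),
    cutoffs = cutoffs,
    n_patients = config$n_patients,
    files = basename(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(claims = claims, flags = flags, graph = graph,
                 linchpin = linchpin, treatments = treatments,
                 cohorts = cohorts, bivariate = biv, fits = fits,
                 manifest = manifest, out_dir = out_dir))
}
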