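#' Linchpin scores for every physician of a specialty
#'
#' The linchpin score of a focal physician of specialty `specialty` is the
#' fraction of its patient-sharing tie weight going to peers who depend on
#' it for that specialty: sum the weights of ties to neighbors who lack a
#' tie to any *other* physician of that specialty, and divide by the sum of
#' all the focal physician's tie weights. A score near 1 marks a locally
#' unique or scarce specialist; a score of 0 means every peer has an
#' alternative.
#'
#' Two conventions, both recorded here because the measure's verbal
#' definition leaves them open: a neighbor that is itself of the focal
#' specialty is never counted as dependent (it has that capacity itself),
#' and a focal physician with no ties at all scores 0 rather than NaN so
#' that quantile thresholds remain computable over the full roster.
#'
#' @param graph A [sharing_graph()] whose nodes carry a `specialty` column.
#' @param specialty Specialty over which scores are computed
#'   (default `"surgeon"`).
#' @return A tibble of class `psnet_linchpin` with columns `physician_id`,
#'   `score` (in \[0, 1\]), `n_ties`, `total_weight`, `dependent_weight`.
#' @seealso [linchpin_score()] for a single focal physician,
#'   [flag_linchpins()] for the top-fraction flag.
#' @export
linchpin_scores <- function(graph, specialty = "surgeon") {
  stopifnot(inherits(graph, "sharing_graph"))
  if (!"specialty" %in% names(graph$nodes)) {
    abort("Graph nodes carry no `specialty` attribute.")
  }
  focal_ids <- graph$nodes$physician_id[graph$nodes$specialty %in% specialty]
  spec_of <- setNames(graph$nodes$specialty, graph$nodes$physician_id)

  de <- directed_edges(graph)
  # number of ties each physician has to nodes of the focal specialty
  spec_tie_count <- de |>
    dplyr::filter(spec_of[.data$alter] %in% specialty) |>
    dplyr::count(.data$ego, name = "n_spec_ties")
  n_spec_ties <- setNames(
    rep(0L, nrow(graph$nodes)), graph$nodes$physician_id
  )
  n_spec_ties[spec_tie_count$ego] <- spec_tie_count$n_spec_ties

  per_focal <- de |>
    dplyr::filter(.data$ego %in% focal_ids) |>
    dplyr::mutate(
      # alter depends on ego iff alter is not itself of the focal specialty
      # and its only focal-specialty tie is ego
      dependent = !(spec_of[.data$alter] %in% specialty) &
        n_spec_ties[.data$alter] == 1L
    ) |>
    dplyr::group_by(physician_id = .data$ego) |>
    dplyr::summarise(
      n_ties = dplyr::n(),
      total_weight = sum(.data$weight),
      dependent_weight = sum(.data$weight[.data$dependent]),
      .groups = "drop"
    )

  out <- tibble(physician_id = focal_ids) |>
    dplyr::left_join(per_focal, by = "physician_id") |>
    dplyr::mutate(
      n_ties = dplyr::coalesce(.data$n_ties, 0L),
      total_weight = dplyr::coalesce(.data$total_weight, 0),
      dependent_weight = dplyr::coalesce(.data$dependent_weight, 0),
      score = ifelse(.data$total_weight > 0,
                     .data$dependent_weight / .data$total_weight, 0)
    ) |>
    dplyr::select("physician_id", "score", "n_ties", "total_weight",
                  "dependent_weight")
  class(out) <- c("psnet_linchpin", class(out))
  attr(out, "specialty") <- specialty
  out
}

#' Linchpin score of one focal physician
#'
#' @inheritParams linchpin_scores
#' @param focal A `physician_id` present in the graph.
#' @return The score, a number in \[0, 1\].
#' @examples
#' # the canonical worked example: a surgeon whose ties of weight 5, 3, 2
#' # go to peers with no other surgeon tie and ties of weight 6, 4 go to
#' # peers that do have one scores (5 + 3 + 2) / 20 = 0.5
#' g <- toy_linchpin_graph()
#' linchpin_score(g, "v", "surgeon")
#' @export
linchpin_score <- function(graph, focal, specialty = "surgeon") {
  stopifnot(inherits(graph, "sharing_graph"))
  if (!focal %in% graph$nodes$physician_id) {
    abort(sprintf("Physician '%s' is not a node of the graph.", focal))
  }
  true_spec <- graph$nodes$specialty[graph$nodes$physician_id == focal]
  if (!true_spec %in% specialty) {
    abort(sprintf("Physician '%s' has specialty '%s', not '%s'.",
                  focal, true_spec, paste(specialty, collapse = "/")))
  }
  sc <- linchpin_scores(graph, specialty)
  sc$score[sc$physician_id == focal]
}

#' Flag top-fraction linchpin physicians
#'
#' A physician is flagged when their score is at least the nearest-rank
#' upper-tail threshold: with `n` physicians, the `ceiling(top_fraction *
#' n)`-th largest score. Ties at the threshold are all flagged, so the
#' flagged share can exceed `top_fraction` (with all scores equal, everyone
#' is flagged). The default reproduces the "top 15%" linchpin definition.
#'
#' @param scores A `psnet_linchpin` tibble from [linchpin_scores()], or any
#'   tibble with `physician_id` and `score`.
#' @param top_fraction Upper-tail fraction to flag, in (0, 1). Default 0.15.
#' @return The input with logical column `is_linchpin` and the threshold in
#'   attribute `"threshold"`.
#' @export
flag_linchpins <- function(scores, top_fraction = 0.15) {
  stopifnot(is.data.frame(scores), "score" %in% names(scores))
  if (nrow(scores) == 0) abort("`scores` is empty.")
  if (!(top_fraction > 0 && top_fraction < 1)) {
    abort("`top_fraction` must lie strictly between 0 and 1.")
  }
  k <- ceiling(top_fraction * nrow(scores))
  threshold <- sort(scores$score, decreasing = TRUE)[k]
  out <- dplyr::mutate(scores, is_linchpin = .data$score >= threshold)
  attr(out, "threshold") <- threshold
  attr(out, "top_fraction") <- top_fraction
  out
}

#' Care density of one patient's care team
#'
#' Care density is the mean shared-patient tie weight over all unordered
#' pairs of physicians on the team: the numerator sums the sharing-graph
#' edge weights over team pairs (absent edges contribute 0) and the
#' denominator is `n * (n - 1) / 2` for a team of `n`. A team of one has no
#' pairs, so its care density is mathematically undefined; such patients
#' are returned as *sole clinician*, which downstream analyses treat as a
#' fourth exposure level rather than a missing value.
#'
#' Team members are first restricted to physicians present in the graph:
#' physicians dropped by the minimum-patient-count rule have no measurable
#' ties and would otherwise dilute the denominator with structurally absent
#' pairs.
#'
#' @param graph A [sharing_graph()].
#' @param team Character vector of physician ids (need not all be nodes).
#' @return A one-row tibble: `team_size` (after restriction to graph
#'   nodes), `cd` (NA for a sole clinician or empty team),
#'   `sole_clinician` (logical).
#' @examples
#' g <- toy_care_density_graph()
#' care_density(g, paste0("d", 1:5))  # 16 / 10 = 1.6
#' @export
care_density <- function(graph, team) {
  stopifnot(inherits(graph, "sharing_graph"))
  if (length(team) == 0) abort("`team` must contain at least one physician.")
  team <- unique(as.character(team))
  team <- team[team %in% graph$nodes$physician_id]
  n <- length(team)
  if (n <= 1) {
    return(tibble(team_size = n, cd = NA_real_, sole_clinician = n == 1))
  }
  e <- graph$edges
  w <- sum(e$weight[e$from %in% team & e$to %in% team])
  tibble(team_size = n, cd = w / (n * (n - 1) / 2), sole_clinician = FALSE)
}

#' Care density for many patients at once
#'
#' @param graph A [sharing_graph()].
#' @param teams Tibble with columns `patient_id` and `physician_id`, one
#'   row per team membership.
#' @return Tibble with one row per patient: `patient_id`, `team_size`,
#'   `cd`, `sole_clinician`. Patients whose whole team falls outside the
#'   graph get `team_size` 0 and `cd` NA.
#' @export
care_density_table <- function(graph, teams) {
  stopifnot(inherits(graph, "sharing_graph"), is.data.frame(teams))
  teams <- dplyr::distinct(teams, .data$patient_id, .data$physician_id)
  all_ids <- unique(teams$patient_id)
  teams <- dplyr::filter(teams,
                         .data$physician_id %in% graph$nodes$physician_id)

  sizes <- dplyr::count(teams, .data$patient_id, name = "team_size")
  # pair up team members per patient, then join edge weights
  pairs <- teams |>
    dplyr::inner_join(teams, by = "patient_id",
                      relationship = "many-to-many",
                      suffix = c("_a", "_b")) |>
    dplyr::filter(.data$physician_id_a < .data$physician_id_b) |>
    dplyr::left_join(
      graph$edges,
      by = c(physician_id_a = "from", physician_id_b = "to")
    ) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(total_weight = sum(.data$weight, na.rm = TRUE),
                     .groups = "drop")

  tibble(patient_id = all_ids) |>
    dplyr::left_join(sizes, by = "patient_id") |>
    dplyr::left_join(pairs, by = "patient_id") |>
    dplyr::mutate(
      team_size = dplyr::coalesce(.data$team_size, 0L),
      total_weight = dplyr::coalesce(.data$total_weight, 0),
      cd = ifelse(.data$team_size >= 2,
                  .data$total_weight / (.data$team_size * (.data$team_size - 1) / 2),
                  NA_real_),
      sole_clinician = .data$team_size == 1L
    ) |>
    dplyr::select("patient_id", "team_size", "cd", "sole_clinician")
}

#' Within- and between-HSA oncologist degree
#'
#' Splits each physician's unique patient-sharing ties to oncologists
#' (medical, radiation, and surgical) by whether the tied oncologist's
#' primary hospital service area (HSA) equals the physician's own —
#' separating local from regional professional reach. Ties are counted as
#' unique neighbors; weights are ignored.
#'
#' @param graph A [sharing_graph()] whose nodes carry `specialty` and `hsa`.
#' @param oncologist_specialties Specialties counted as oncologists.
#' @return Tibble: `physician_id`, `within_hsa_degree`,
#'   `between_hsa_degree`. Rows cover every node of the graph.
#' @export
degree_split <- function(graph,
                         oncologist_specialties = PSNET_ONCOLOGIST_SPECIALTIES) {
  stopifnot(inherits(graph, "sharing_graph"))
  need <- setdiff(c("specialty", "hsa"), names(graph$nodes))
  if (length(need) > 0) {
    abort(sprintf("Graph nodes lack attribute(s): %s",
                  paste(need, collapse = ", ")))
  }
  if (anyNA(graph$nodes$hsa)) abort("Some nodes have a missing `hsa`.")
  spec_of <- setNames(graph$nodes$specialty, graph$nodes$physician_id)
  hsa_of <- setNames(graph$nodes$hsa, graph$nodes$physician_id)

  counts <- directed_edges(graph) |>
    dplyr::filter(spec_of[.data$alter] %in% oncologist_specialties) |>
    dplyr::mutate(same_hsa = hsa_of[.data$ego] == hsa_of[.data$alter]) |>
    dplyr::group_by(physician_id = .data$ego) |>
    dplyr::summarise(
      within_hsa_degree = sum(.data$same_hsa),
      between_hsa_degree = sum(!.data$same_hsa),
      .groups = "drop"
    )
  tibble(physician_id = graph$nodes$physician_id) |>
    dplyr::left_join(counts, by = "physician_id") |>
    dplyr::mutate(
      within_hsa_degree = as.integer(dplyr::coalesce(.data$within_hsa_degree, 0L)),
      between_hsa_degree = as.integer(dplyr::coalesce(.data$between_hsa_degree, 0L))
    )
}

#' Oncologist supply per hospital referral region
#'
#' The ratio of oncologists (medical, radiation, surgical) practising in an
#' HRR to the number of persons older than 65 living there — a coarse
#' regional access measure, constant across physicians of the same HRR.
#'
#' @param physicians Tibble with `physician_id`, `specialty`, `hrr`.
#' @param over65_by_hrr Tibble with `hrr` and `over65` (persons older than
#'   65; must be positive), or a named numeric vector.
#' @param oncologist_specialties Specialties counted as oncologists.
#' @return Tibble: `hrr`, `n_oncologists`, `over65`, `oncologist_supply`.
#' @export
oncologist_supply <- function(physicians, over65_by_hrr,
                              oncologist_specialties = PSNET_ONCOLOGIST_SPECIALTIES) {
  stopifnot(is.data.frame(physicians))
  if (!is.data.frame(over65_by_hrr)) {
    over65_by_hrr <- tibble(hrr = names(over65_by_hrr),
                            over65 = as.numeric(over65_by_hrr))
  }
  hrrs <- unique(physicians$hrr)
  missing <- setdiff(hrrs, over65_by_hrr$hrr)
  if (length(missing) > 0) {
    abort(sprintf("No over-65 population supplied for HRR(s): %s",
                  paste(missing, collapse = ", ")))
  }
  bad <- over65_by_hrr$hrr[over65_by_hrr$over65 <= 0 |
                             is.na(over65_by_hrr$over65)]
  bad <- intersect(bad, hrrs)
  if (length(bad) > 0) {
    abort(sprintf("Non-positive over-65 population for HRR(s): %s",
                  paste(bad, collapse = ", ")))
  }
  onc <- physicians |>
    dplyr::filter(.data$specialty %in% oncologist_specialties) |>
    dplyr::count(.data$hrr, name = "n_oncologists")
  tibble(hrr = hrrs) |>
    dplyr::left_join(onc, by = "hrr") |>
    dplyr::mutate(n_oncologists = dplyr::coalesce(.data$n_oncologists, 0L)) |>
    dplyr::left_join(over65_by_hrr, by = "hrr") |>
    dplyr::mutate(oncologist_supply = .data$n_oncologists / .data$over65)
}

#' Toy graphs for the worked examples
#'
#' `toy_linchpin_graph()` builds the six-node network in which focal
#' surgeon `"v"` has ties of weight 5, 3 and 2 to physicians with no other
#' surgeon tie and ties of weight 6 and 4 to physicians tied to a second
#' surgeon, so `linchpin_score(g, "v")` is 10/20 = 0.5.
#' `toy_care_density_graph()` builds the five-physician team whose four
#' existing ties weigh 5, 3, 2 and 6, so the care density is 16/10 = 1.6.
#'
#' @return A [sharing_graph()].
#' @export
toy_linchpin_graph <- function() {
  nodes <- tibble(
    physician_id = c("v", "p1", "p2", "p3", "p4", "p5", "s2"),
    specialty = c("surgeon", rep("other", 5), "surgeon")
  )
  edges <- tibble(
    from = c("v", "v", "v", "v", "v", "p4", "p5"),
    to = c("p1", "p2", "p3", "p4", "p5", "s2", "s2"),
    weight = c(5, 3, 2, 6, 4, 3, 4)
  )
  sharing_graph(edges, nodes)
}

#' @rdname toy_linchpin_graph
#' @export
toy_care_density_graph <- function() {
  nodes <- tibble(
    physician_id = paste0("d", 1:5),
    specialty = c("surgeon", "medical_oncologist", "radiation_oncologist",
                  "other", "other")
  )
  edges <- tibble(
    from = c("d1", "d1", "d2", "d3"),
    to = c("d2", "d3", "d4", "d5"),
    weight = c(5, 3, 2, 6)
  )
  sharing_graph(edges, nodes)
}
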