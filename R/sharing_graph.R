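#' Bipartite physician-patient incidence within the network window
#'
#' Reduces an encounter stream to the deduplicated set of physician-patient
#' pairs that fall inside each patient's network window: from `days_before`
#' days before their biopsy through `days_after` days after it (both
#' boundaries inclusive). Only patients present in `patients` contribute;
#' a physician-patient pair appears once no matter how many encounters it
#' has in the window.
#'
#' Patients appearing in `encounters` without any biopsy event cannot be
#' anchored to a window; their encounters are skipped with a warning.
#'
#' @param encounters Tibble of encounter records with columns `patient_id`,
#'   `physician_id`, `service_date` (integer day index), `event_class`.
#' @param patients Tibble with at least `patient_id`; defines the cohort
#'   whose care is networked.
#' @param days_before,days_after Window half-widths in days around the
#'   biopsy. Defaults are the study constants: 91 days ("3 months") before
#'   and 365 days ("12 months") after.
#' @return A tibble with columns `physician_id`, `patient_id`, one row per
#'   unique in-window pair.
#' @examples
#' enc <- tibble::tibble(
#'   patient_id = c("p1", "p1", "p1"), physician_id = c("d1", "d1", "d2"),
#'   service_date = c(0L, 10L, 400L),
#'   event_class = c("biopsy", "visit", "visit")
#' )
#' build_incidence(enc, tibble::tibble(patient_id = "p1"))
#' @export
build_incidence <- function(encounters, patients,
                            days_before = 91L, days_after = 365L) {
  stopifnot(is.data.frame(encounters), is.data.frame(patients))
  if (days_before < 0 || days_after < 0) {
    abort("`days_before` and `days_after` must be non-negative.")
  }
  enc <- dplyr::semi_join(encounters, patients, by = "patient_id")
  biopsy <- enc |>
    dplyr::filter(.data$event_class == "biopsy") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(biopsy_date = min(.data$service_date), .groups = "drop")
  missing <- setdiff(unique(enc$patient_id), biopsy$patient_id)
  if (length(missing) > 0) {
    warn(sprintf(
      "Skipping %d patient(s) with encounters but no biopsy event.",
      length(missing)
    ))
  }
  enc |>
    dplyr::inner_join(biopsy, by = "patient_id") |>
    dplyr::filter(
      .data$service_date >= .data$biopsy_date - days_before,
      .data$service_date <= .data$biopsy_date + days_after
    ) |>
    dplyr::distinct(.data$physician_id, .data$patient_id)
}

#' Construct a patient-sharing graph directly from edges and nodes
#'
#' Low-level constructor used for worked examples, tests, and
#' deserialisation. [project_sharing_graph()] is the claims-facing builder
#' and enforces the shared-patient and patient-count thresholds;
#' `sharing_graph()` takes any weighted edge list as given.
#'
#' @param edges Tibble with columns `from`, `to`, `weight` (positive
#'   shared-patient counts). May have zero rows.
#' @param nodes Tibble with column `physician_id` plus any physician
#'   attributes (`specialty`, `hsa`, `hrr`, ...). Defaults to the
#'   physicians appearing in `edges`.
#' @param min_shared,min_patients Threshold metadata recorded on the graph
#'   (`NA` when constructed directly).
#' @return An object of class `sharing_graph`: a list with tibbles `nodes`
#'   and `edges` and an `igraph` representation.
#' @export
sharing_graph <- function(edges, nodes = NULL,
                          min_shared = NA_integer_,
                          min_patients = NA_integer_) {
  edges <- as_tibble(edges)
  if (nrow(edges) > 0) {
    stopifnot(all(c("from", "to", "weight") %in% names(edges)))
    if (any(edges$from == edges$to)) abort("Self-loops are not allowed.")
    if (any(edges$weight <= 0)) abort("Edge weights must be positive.")
    # canonical unordered representation
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    if (anyDuplicated(edges[c("from", "to")]) > 0) {
      abort("Duplicate edges supplied for the same physician pair.")
    }
  } else {
    edges <- tibble(from = character(), to = character(), weight = numeric())
  }
  if (is.null(nodes)) {
    nodes <- tibble(physician_id = sort(unique(c(edges$from, edges$to))))
  }
  nodes <- as_tibble(nodes)
  stopifnot("physician_id" %in% names(nodes))
  if (anyDuplicated(nodes$physician_id) > 0) {
    abort("`nodes` must have one row per physician_id.")
  }
  stray <- setdiff(unique(c(edges$from, edges$to)), nodes$physician_id)
  if (length(stray) > 0) {
    abort(sprintf("Edges refer to physicians absent from `nodes`: %s",
                  paste(head(stray, 3), collapse = ", ")))
  }
  g <- igraph::graph_from_data_frame(
    d = edges, directed = FALSE,
    vertices = as.data.frame(nodes)
  )
  structure(
    list(nodes = nodes, edges = edges, igraph = g,
         min_shared = min_shared, min_patients = min_patients),
    class = "sharing_graph"
  )
}

#' @export
print.sharing_graph <- function(x, ...) {
  cat(sprintf(
    "<sharing_graph> %d physicians, %d patient-sharing ties\n",
    nrow(x$nodes), nrow(x$edges)
  ))
  if (!is.na(x$min_shared)) {
    cat(sprintf("  thresholds: >= %d shared patients per tie, >= %d patients per physician\n",
                x$min_shared, x$min_patients))
  }
  invisible(x)
}

#' Project the bipartite incidence onto a weighted physician graph
#'
#' Physicians become nodes; two physicians are connected when they shared
#' at least `min_shared` unique cohort patients within the network window,
#' and the edge weight is the exact number of shared patients. To reduce
#' noise the node set is first restricted to physicians who cared for at
#' least `min_patients` cohort patients; edges are then formed among the
#' surviving nodes, so a retained physician may be isolated. Shared
#' patients are unique patients, never encounter counts.
#'
#' @param incidence Output of [build_incidence()].
#' @param physicians Optional tibble of physician attributes
#'   (`physician_id`, `specialty`, `hsa`, `hrr`, ...) attached to nodes.
#' @param min_shared Minimum number of unique shared patients for a tie
#'   (default 3).
#' @param min_patients Minimum number of cohort patients cared for within
#'   the window for a physician to enter the network (default 5).
#' @return A [sharing_graph()] object.
#' @export
project_sharing_graph <- function(incidence, physicians = NULL,
                                  min_shared = 3L, min_patients = 5L) {
  stopifnot(is.data.frame(incidence))
  if (min_shared < 1 || min_patients < 1) {
    abort("`min_shared` and `min_patients` must be >= 1.")
  }
  if (nrow(incidence) == 0) abort("`incidence` is empty.")
  inc <- dplyr::distinct(incidence, .data$physician_id, .data$patient_id)

  counts <- dplyr::count(inc, .data$physician_id)
  keep <- counts$physician_id[counts$n >= min_patients]
  inc <- dplyr::filter(inc, .data$physician_id %in% keep)

  phys_ids <- sort(unique(inc$physician_id))
  edges <- tibble(from = character(), to = character(), weight = numeric())
  if (length(phys_ids) >= 2) {
    pat_ids <- sort(unique(inc$patient_id))
    m <- Matrix::sparseMatrix(
      i = match(inc$physician_id, phys_ids),
      j = match(inc$patient_id, pat_ids),
      x = 1,
      dims = c(length(phys_ids), length(pat_ids))
    )
    shared <- Matrix::tcrossprod(m)  # physician x physician shared counts
    tri <- Matrix::which(upper.tri(shared) & shared >= min_shared,
                         arr.ind = TRUE)
    if (nrow(tri) > 0) {
      edges <- tibble(
        from = phys_ids[tri[, 1]],
        to = phys_ids[tri[, 2]],
        weight = as.numeric(shared[tri])
      )
    }
  }

  nodes <- tibble(physician_id = phys_ids)
  if (!is.null(physicians)) {
    nodes <- dplyr::left_join(nodes, as_tibble(physicians),
                              by = "physician_id")
  }
  nodes <- dplyr::left_join(
    nodes,
    dplyr::rename(counts, n_cohort_patients = "n"),
    by = "physician_id"
  )
  sharing_graph(edges, nodes,
                min_shared = as.integer(min_shared),
                min_patients = as.integer(min_patients))
}

#' Serialise / deserialise a sharing graph as plain text
#'
#' The edge list is written as tab-separated `from<TAB>to<TAB>weight`; node
#' attributes go to a second tab-separated table. `read_sharing_graph()`
#' round-trips exactly.
#'
#' @param graph A `sharing_graph`.
#' @param edge_file,node_file Paths for the two tables.
#' @return `write_sharing_graph()` returns the paths invisibly;
#'   `read_sharing_graph()` returns a `sharing_graph`.
#' @export
write_sharing_graph <- function(graph, edge_file, node_file) {
  stopifnot(inherits(graph, "sharing_graph"))
  utils::write.table(graph$edges, edge_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(graph$nodes, node_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(c(edges = edge_file, nodes = node_file))
}

#' @rdname write_sharing_graph
#' @export
read_sharing_graph <- function(edge_file, node_file) {
  edges <- as_tibble(utils::read.table(edge_file, header = TRUE, sep = "\t",
                                       colClasses = c("character", "character",
                                                      "numeric")))
  nodes <- as_tibble(utils::read.table(node_file, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE,
                                       colClasses = list(physician_id = "character")))
  sharing_graph(edges, nodes)
}

# Internal: neighbor table with both directions, one row per directed tie.
directed_edges <- function(graph) {
  e <- graph$edges
  dplyr::bind_rows(
    tibble(ego = e$from, alter = e$to, weight = e$weight),
    tibble(ego = e$to, alter = e$from, weight = e$weight)
  )
}
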