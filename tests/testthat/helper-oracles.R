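# Brute-force oracles, deliberately independent of the package internals:
# plain loops over rows and neighbor sets.

# filter-and-group scan over raw encounter rows
oracle_incidence <- function(encounters, patients, days_before = 91,
                             days_after = 365) {
  out <- list()
  for (pid in unique(patients$patient_id)) {
    e <- encounters[encounters$patient_id == pid, ]
    b <- e$service_date[e$event_class == "biopsy"]
    if (length(b) == 0) next
    b <- min(b)
    keep <- e[e$service_date >= b - days_before &
                e$service_date <= b + days_after, ]
    for (did in unique(keep$physician_id)) {
      out[[length(out) + 1]] <- data.frame(physician_id = did,
                                           patient_id = pid)
    }
  }
  if (length(out) == 0) {
    return(data.frame(physician_id = character(), patient_id = character()))
  }
  do.call(rbind, out)
}

# all-pairs set intersection projection
oracle_projection <- function(incidence, min_shared = 3, min_patients = 5) {
  sets <- split(incidence$patient_id, incidence$physician_id)
  sets <- lapply(sets, unique)
  sets <- sets[vapply(sets, length, 0L) >= min_patients]
  ids <- sort(names(sets))
  edges <- list()
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in (i + 1):length(ids)) {
        w <- length(intersect(sets[[ids[i]]], sets[[ids[j]]]))
        if (w >= min_shared) {
          edges[[length(edges) + 1]] <-
            data.frame(from = ids[i], to = ids[j], weight = w)
        }
      }
    }
  }
  list(
    nodes = ids,
    edges = if (length(edges) == 0) {
      data.frame(from = character(), to = character(), weight = numeric())
    } else do.call(rbind, edges)
  )
}

# neighbor-of-neighbor scan for the linchpin score
oracle_linchpin <- function(edges, specialties, focal, focal_specialty) {
  nbrs <- function(v) {
    c(edges$to[edges$from == v], edges$from[edges$to == v])
  }
  w_of <- function(u, v) {
    w <- edges$weight[(edges$from == u & edges$to == v) |
                        (edges$from == v & edges$to == u)]
    if (length(w) == 0) 0 else w
  }
  total <- 0
  dep <- 0
  for (p in nbrs(focal)) {
    w <- w_of(focal, p)
    total <- total + w
    if (specialties[[p]] == focal_specialty) next
    has_other <- FALSE
    for (q in nbrs(p)) {
      if (q != focal && specialties[[q]] == focal_specialty) has_other <- TRUE
    }
    if (!has_other) dep <- dep + w
  }
  if (total == 0) 0 else dep / total
}

# double loop over team pairs
oracle_care_density <- function(edges, node_ids, team) {
  team <- unique(team[team %in% node_ids])
  n <- length(team)
  if (n <= 1) return(list(team_size = n, cd = NA_real_))
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      w <- edges$weight[(edges$from == team[i] & edges$to == team[j]) |
                          (edges$from == team[j] & edges$to == team[i])]
      tot <- tot + (if (length(w) == 0) 0 else w)
    }
  }
  list(team_size = n, cd = tot / (n * (n - 1) / 2))
}

# neighbor filter-count for the degree split
oracle_degree_split <- function(edges, nodes, pid,
                                onc = c("medical_oncologist",
                                        "radiation_oncologist", "surgeon")) {
  nbr <- unique(c(edges$to[edges$from == pid], edges$from[edges$to == pid]))
  spec <- setNames(nodes$specialty, nodes$physician_id)
  hsa <- setNames(nodes$hsa, nodes$physician_id)
  nbr <- nbr[spec[nbr] %in% onc]
  c(within = sum(hsa[nbr] == hsa[[pid]]),
    between = sum(hsa[nbr] != hsa[[pid]]))
}

# direct double-sum chi-square, optional Yates correction
oracle_chi2 <- function(m, correct = FALSE) {
  n <- sum(m)
  stat <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      e <- sum(m[i, ]) * sum(m[, j]) / n
      d <- abs(m[i, j] - e)
      if (correct) d <- max(d - 0.5, 0)
      stat <- stat + d^2 / e
    }
  }
  stat
}

# random weighted physician graph with attributes
random_graph <- function(n_phys = 12, p_edge = 0.3, seed = 1,
                         specialties = c("surgeon", "medical_oncologist",
                                         "radiation_oncologist", "other")) {
  set.seed(seed)
  ids <- sprintf("R%02d", seq_len(n_phys))
  nodes <- tibble::tibble(
    physician_id = ids,
    specialty = sample(specialties, n_phys, replace = TRUE,
                       prob = c(0.3, 0.2, 0.2, 0.3)[seq_along(specialties)]),
    hsa = sample(sprintf("H%d", 1:3), n_phys, replace = TRUE),
    hrr = "HRR1"
  )
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p_edge
  edges <- tibble::tibble(
    from = pairs[keep, 1], to = pairs[keep, 2],
    weight = sample(1:10, sum(keep), replace = TRUE)
  )
  sharing_graph(edges, nodes)
}

# tiny deterministic claims fixture used across cohort tests
tiny_claims <- function(seed = 7, n_patients = 600, surgery_fraction = 1) {
  cfg <- sim_config(n_patients = n_patients,
                    surgery_fraction = surgery_fraction)
  simulate_claims(cfg, planted_truth(), seed = seed)
}

# analysis rows with a known logistic data-generating process,
# bypassing the claims generator (pure regression-layer fixture)
sim_rows <- function(n = 2500, beta = c(lin = log(1.3), med = log(0.85),
                                        high = log(0.77)),
                     sigma_npi = 0, sigma_hrr = 0, seed = 1) {
  set.seed(seed)
  surg <- sample(sprintf("s%02d", 1:40), n, TRUE)
  hrr <- sample(sprintf("h%d", 1:6), n, TRUE)
  b_s <- setNames(rnorm(40, 0, sigma_npi), sprintf("s%02d", 1:40))
  b_h <- setNames(rnorm(6, 0, sigma_hrr), sprintf("h%d", 1:6))
  lin <- runif(n) < 0.15
  cdl <- sample(c("low", "medium", "high"), n, TRUE)
  eta <- qlogis(0.18) + beta["lin"] * lin + beta["med"] * (cdl == "medium") +
    beta["high"] * (cdl == "high") + b_s[surg] + b_h[hrr]
  delayed <- runif(n) < plogis(eta)
  tibble::tibble(
    patient_id = seq_len(n),
    interval_days = ifelse(delayed, 61L + sample(0:80, n, TRUE),
                           15L + sample(0:45, n, TRUE)),
    linchpin_exposed = lin,
    care_density_level = factor(cdl, c("low", "medium", "high")),
    surgeon_id = surg, hrr = hrr
  )
}

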