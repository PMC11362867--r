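test_that("the worked linchpin example scores one half", {
  g <- toy_linchpin_graph()
  expect_equal(linchpin_score(g, "v", "surgeon"), 0.5)
})

test_that("linchpin score hits its extremes and error paths", {
  # every neighbor tied to another surgeon -> 0
  g0 <- sharing_graph(
    tibble::tibble(from = c("v", "v", "p1", "p2"),
                   to = c("p1", "p2", "s2", "s2"),
                   weight = c(4, 6, 3, 3)),
    tibble::tibble(physician_id = c("v", "p1", "p2", "s2"),
                   specialty = c("surgeon", "other", "other", "surgeon"))
  )
  expect_equal(linchpin_score(g0, "v", "surgeon"), 0)

  # no neighbor tied to another surgeon -> 1
  g1 <- sharing_graph(
    tibble::tibble(from = c("v", "v"), to = c("p1", "p2"),
                   weight = c(4, 6)),
    tibble::tibble(physician_id = c("v", "p1", "p2"),
                   specialty = c("surgeon", "other", "other"))
  )
  expect_equal(linchpin_score(g1, "v", "surgeon"), 1)

  # isolated focal node -> 0 by convention
  g2 <- sharing_graph(
    tibble::tibble(from = "a", to = "b", weight = 3),
    tibble::tibble(physician_id = c("a", "b", "v"),
                   specialty = c("other", "other", "surgeon"))
  )
  expect_equal(linchpin_score(g2, "v", "surgeon"), 0)

  expect_error(linchpin_score(g1, "zz", "surgeon"), "not a node")
  expect_error(linchpin_score(g1, "p1", "surgeon"), "specialty")
})

test_that("linchpin scores equal the neighbor-of-neighbor oracle", {
  for (s in 1:200) {
    g <- random_graph(n_phys = sample(6:14, 1), p_edge = runif(1, 0.15, 0.6),
                      seed = s)
    spec <- setNames(g$nodes$specialty, g$nodes$physician_id)
    sc <- linchpin_scores(g, "surgeon")
    for (i in seq_len(nrow(sc))) {
      want <- oracle_linchpin(g$edges, as.list(spec), sc$physician_id[i],
                              "surgeon")
      expect_equal(sc$score[i], want,
                   info = sprintf("seed %d focal %s", s, sc$physician_id[i]))
    }
  }
})

test_that("linchpin score never rises when a dependent peer gains an
          alternative surgeon", {
  g <- toy_linchpin_graph()  # p1 depends on v (weight 5)
  before <- linchpin_score(g, "v", "surgeon")
  edges2 <- dplyr::bind_rows(g$edges,
                             tibble::tibble(from = "p1", to = "s2",
                                            weight = 3))
  g2 <- sharing_graph(edges2, g$nodes)
  after <- linchpin_score(g2, "v", "surgeon")
  expect_lt(after, before)

  # removing the competing surgeon restores full dependence
  keep <- g$edges$from != "s2" & g$edges$to != "s2"
  g3 <- sharing_graph(g$edges[keep, ],
                      dplyr::filter(g$nodes, physician_id != "s2"))
  expect_gte(linchpin_score(g3, "v", "surgeon"), before)
})

test_that("top-fraction flagging follows the nearest-rank rule with
          inclusive ties", {
  sc <- tibble::tibble(physician_id = sprintf("d%03d", 1:100),
                       score = seq(0.001, 1, length.out = 100))
  fl <- flag_linchpins(sc, 0.15)
  expect_equal(sum(fl$is_linchpin), 15)

  all_same <- tibble::tibble(physician_id = c("a", "b", "c"),
                             score = c(0.4, 0.4, 0.4))
  expect_true(all(flag_linchpins(all_same)$is_linchpin))

  expect_error(flag_linchpins(sc[0, ]), "empty")
  expect_error(flag_linchpins(sc, 0), "between 0 and 1")

  # sort-and-cut oracle with tie inclusion on random tied vectors
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(10:60, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    fl <- flag_linchpins(tibble::tibble(physician_id = seq_len(n),
                                        score = scores), 0.15)
    thr <- sort(scores, decreasing = TRUE)[ceiling(0.15 * n)]
    expect_equal(fl$is_linchpin, scores >= thr)
    expect_gte(sum(fl$is_linchpin), ceiling(0.15 * n))
  }
})

test_that("the worked care-density example scores 1.6", {
  g <- toy_care_density_graph()
  cd <- care_density(g, paste0("d", 1:5))
  expect_equal(cd$cd, 1.6)
  expect_equal(cd$team_size, 5)
})

test_that("care density covers pairs, sole clinicians and team handling", {
  g <- sharing_graph(
    tibble::tibble(from = "a", to = "b", weight = 7),
    tibble::tibble(physician_id = c("a", "b", "c"),
                   specialty = "other")
  )
  expect_equal(care_density(g, c("a", "b"))$cd, 7)
  sole <- care_density(g, "a")
  expect_true(sole$sole_clinician)
  expect_true(is.na(sole$cd))
  expect_error(care_density(g, character()), "at least one")

  # invariant to team ordering and to graph nodes outside the team
  expect_equal(care_density(g, c("b", "a")), care_density(g, c("a", "b")))

  # members outside the graph are not counted
  cd <- care_density(g, c("a", "b", "zz"))
  expect_equal(cd$team_size, 2)
})

test_that("care density matches the pairwise-sum oracle on random teams", {
  set.seed(17)
  for (rep in 1:40) {
    g <- random_graph(n_phys = 12, p_edge = 0.4, seed = rep + 100)
    team <- sample(c(g$nodes$physician_id, "X1", "X2"), sample(1:8, 1))
    got <- care_density(g, team)
    want <- oracle_care_density(g$edges, g$nodes$physician_id, team)
    expect_equal(got$team_size, want$team_size)
    expect_equal(got$cd, want$cd)
  }
})

test_that("care_density_table agrees with per-team computation", {
  g <- random_graph(n_phys = 15, p_edge = 0.35, seed = 5)
  set.seed(50)
  teams <- tibble::tibble(
    patient_id = rep(sprintf("p%d", 1:25),
                     times = sample(1:6, 25, replace = TRUE))
  )
  teams$physician_id <- sample(g$nodes$physician_id, nrow(teams),
                               replace = TRUE)
  tab <- care_density_table(g, teams)
  for (i in seq_len(nrow(tab))) {
    members <- teams$physician_id[teams$patient_id == tab$patient_id[i]]
    one <- care_density(g, members)
    expect_equal(tab$cd[i], one$cd)
    expect_equal(tab$team_size[i], one$team_size)
  }
})

test_that("degree split counts oncologist ties by HSA equality", {
  nodes <- tibble::tibble(
    physician_id = c("x", "o1", "o2", "o3", "z"),
    specialty = c("surgeon", "medical_oncologist", "radiation_oncologist",
                  "surgeon", "other"),
    hsa = c("H1", "H1", "H1", "H2", "H1")
  )
  edges <- tibble::tibble(from = c("x", "x", "x", "x"),
                          to = c("o1", "o2", "o3", "z"),
                          weight = c(3, 4, 5, 6))
  g <- sharing_graph(edges, nodes)
  d <- degree_split(g)
  x <- d[d$physician_id == "x", ]
  expect_equal(x$within_hsa_degree, 2)  # o1, o2; z is not an oncologist
  expect_equal(x$between_hsa_degree, 1) # o3

  iso <- d[d$physician_id == "z", ]
  # z's only neighbor is x (a surgeon, oncologist specialty, same hsa)
  expect_equal(iso$within_hsa_degree + iso$between_hsa_degree, 1)

  g_bare <- sharing_graph(edges, dplyr::select(nodes, -hsa))
  expect_error(degree_split(g_bare), "hsa")
})

test_that("degree split matches the neighbor-filter oracle", {
  for (s in 1:30) {
    g <- random_graph(n_phys = 10, p_edge = 0.4, seed = s + 500)
    d <- degree_split(g)
    for (i in seq_len(nrow(d))) {
      want <- oracle_degree_split(g$edges, g$nodes, d$physician_id[i])
      expect_equal(d$within_hsa_degree[i], unname(want["within"]))
      expect_equal(d$between_hsa_degree[i], unname(want["between"]))
    }
  }
})

test_that("oncologist supply is a per-HRR ratio with strict inputs", {
  phys <- tibble::tibble(
    physician_id = sprintf("d%d", 1:8),
    specialty = c(rep("medical_oncologist", 3), "radiation_oncologist",
                  "surgeon", rep("other", 3)),
    hrr = c(rep("A", 5), rep("B", 3))
  )
  sup <- oncologist_supply(phys, tibble::tibble(hrr = c("A", "B"),
                                                over65 = c(10000, 5000)))
  expect_equal(sup$oncologist_supply[sup$hrr == "A"], 5 / 10000)
  expect_equal(sup$oncologist_supply[sup$hrr == "B"], 0)

  expect_error(
    oncologist_supply(phys, tibble::tibble(hrr = "A", over65 = 10000)),
    "B"
  )
  expect_error(
    oncologist_supply(phys, tibble::tibble(hrr = c("A", "B"),
                                           over65 = c(10000, 0))),
    "B"
  )
})

test_that("measured linchpin flags concentrate among rural surgeons", {
  cl <- simulate_claims(sim_config(n_patients = 2500), planted_truth(),
                        seed = 2)
  flags <- apply_cohort_filters(cl$patients, cl$encounters)
  included <- dplyr::filter(flags, !excluded)
  inc <- build_incidence(
    cl$encounters, dplyr::semi_join(cl$patients, included, by = "patient_id")
  )
  g <- project_sharing_graph(inc, cl$physicians)
  fl <- flag_linchpins(linchpin_scores(g, "surgeon"))
  m <- dplyr::left_join(fl, g$nodes, by = "physician_id")
  rural_rate <- mean(m$is_linchpin[m$rurality != "urban"])
  urban_rate <- mean(m$is_linchpin[m$rurality == "urban"])
  # positive association in direction only; magnitudes are seed-dependent
  expect_gte(rural_rate, urban_rate)

  # and the measured score ranks track the generator's structural truth
  truth <- dplyr::left_join(fl, cl$truth$surgeon_effects,
                            by = "physician_id")
  rho <- cor(truth$score, as.numeric(truth$linchpin_true),
             method = "spearman")
  expect_gt(rho, 0.3)
})
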