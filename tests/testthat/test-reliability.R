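test_that("repeat-encounter consistency follows its set-overlap definition", {
  rec <- rbind(make_records("P1", c("cat", "dog"),
                            list(c("a", "b", "c"), c("x", "y", "z"))),
               make_records("P1", c("cat", "dog"),
                            list(c("a", "b", "c"), c("x", "y", "z")),
                            is_repeat = TRUE))
  rec$encounter_index <- seq_len(nrow(rec))
  expect_equal(as.numeric(repeated_cue_consistency(rec)), 1)

  rec2 <- rbind(make_records("P1", "cat", list(c("a", "b", "c"))),
                make_records("P1", "cat", list(c("d", "e", "f")),
                             is_repeat = TRUE))
  rec2$encounter_index <- 1:2
  expect_equal(as.numeric(repeated_cue_consistency(rec2)), 0)

  rec3 <- rbind(make_records("P1", "cat", list(c("a", "b", "c"))),
                make_records("P1", "cat", list(c("a", "b", "x")),
                             is_repeat = TRUE))
  rec3$encounter_index <- 1:2
  expect_equal(as.numeric(repeated_cue_consistency(rec3)), 2 / 3)
  # order of responses within an encounter is irrelevant
  rec4 <- rec3
  rec4[2, c("r1", "r2", "r3")] <- c("x", "a", "b")
  expect_equal(as.numeric(repeated_cue_consistency(rec4)), 2 / 3)

  # direction matters when response counts differ
  rec5 <- rbind(make_records("P1", "cat", list(c("a", "b", "c"))),
                make_records("P1", "cat", list("a"), is_repeat = TRUE))
  rec5$encounter_index <- 1:2
  expect_equal(as.numeric(repeated_cue_consistency(rec5)), 1)
  expect_equal(as.numeric(
    repeated_cue_consistency(rec5, direction = "first_vs_second")), 1 / 3)

  expect_error(repeated_cue_consistency(make_records("P1", "cat",
                                                     list("a"))),
               "no repeated cue")
})

test_that("repeat-association profile counts distinct pairs, invariant to record order", {
  rec <- make_records("P1", c("a", "b", "c", "d"),
                      list(c("b", "c", "d"), c("e", "f", "g"),
                           c("h", "i", "j"), "k"))
  prof <- repeat_association_profile(rec)
  expect_equal(prof$pct_pairs_repeated, 0)
  expect_equal(prof$max_pair_count, 1)

  # one pair occurring three times among ten distinct pairs -> (10%, 3)
  rec2 <- make_records("P1", c("a", "a2", "a3", "z"),
                       list(c("b", "c", "d"), c("b2", "c2", "d2"),
                            c("b3", "c3", "d3"), "q"))
  extra <- make_records("P1", c("b", "q2"), list("a", "z"))
  rec2 <- rbind(rec2, extra)                 # (a,b) now 2x... make it 3x
  rec2 <- rbind(rec2, make_records("P1", "a", list("b")))
  rec2$encounter_index <- seq_len(nrow(rec2))
  prof2 <- repeat_association_profile(rec2)
  expect_equal(prof2$n_distinct_pairs, 11)
  expect_equal(prof2$max_pair_count, 3)
  shuf <- rec2[sample(nrow(rec2)), ]
  expect_equal(repeat_association_profile(shuf), prof2)
})

test_that("cross-network correlations have unit diagonal, symmetry, and separate the aggregate", {
  g1 <- rand_semnet(30, 0.25, seed = 61)
  shared <- igraph::V(g1)$name
  pr1 <- pagerank(g1)
  out <- cross_network_measure_correlation(
    list(a = pr1, b = pr1), shared, type = "vector")
  expect_equal(unname(out$cor_matrix["a", "b"]), 1)

  rev_pr <- stats::setNames(rev(sort(pr1)), names(sort(pr1)))
  out2 <- cross_network_measure_correlation(
    list(a = pr1, b = rev_pr), shared, type = "vector")
  expect_lt(out2$cor_matrix["a", "b"], 0)
  expect_equal(out2$cor_matrix, t(out2$cor_matrix))
  expect_equal(unname(diag(out2$cor_matrix)), c(1, 1))

  m1 <- walk_similarity(g1, use_ppmi = FALSE)
  g2 <- rand_semnet(30, 0.25, seed = 62)
  m2 <- walk_similarity(g2, use_ppmi = FALSE)
  out3 <- cross_network_measure_correlation(
    list(p1 = m1, p2 = m2, aggregate = m1), shared, type = "cosine")
  expect_equal(unname(out3$cor_matrix["p1", "aggregate"]), 1)
  expect_equal(out3$mean_individual_aggregate,
               mean(out3$cor_matrix["aggregate", c("p1", "p2")]))
  expect_equal(out3$mean_individual_individual, out3$cor_matrix["p1", "p2"])

  expect_error(cross_network_measure_correlation(list(a = pr1), shared),
               ">= 2")
  expect_error(cross_network_measure_correlation(list(a = pr1, b = pr1),
                                                 shared[1:2]), ">= 3")
})

test_that("cohorts sharing one ground truth correlate more with the aggregate than with each other", {
  ok <- 0
  for (s in 1:10) {
    coh <- simulate_cohort(n_per_group = 2, n_unique_cues = 300,
                           n_repeat_cues = 60,
                           young = group_params("young", scale = 0.25),
                           old = group_params("old", scale = 0.25),
                           include_behavior = FALSE, seed = 700 + s)
    by_pid <- split(coh$associations, coh$associations$participant_id)
    nets <- lapply(by_pid, build_individual_network)
    agg <- build_aggregate_network(coh$associations)
    shared <- Reduce(intersect, lapply(nets, function(g) igraph::V(g)$name))
    shared <- intersect(shared, igraph::V(agg)$name)
    meas <- lapply(nets, pagerank)
    meas$aggregate <- pagerank(agg)
    out <- cross_network_measure_correlation(meas, shared, type = "vector")
    ok <- ok + (out$mean_individual_aggregate >
                  out$mean_individual_individual)
  }
  expect_gte(ok, 9)
})
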