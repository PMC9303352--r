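test_that("generators are deterministic given parameters and seed", {
  gp <- group_params("young", scale = 0.1)
  g1 <- generate_truth_network(gp, seed = 12)
  g2 <- generate_truth_network(gp, seed = 12)
  expect_true(igraph::identical_graphs(g1, g2))

  rec1 <- simulate_associations(g1, 50, 10, behavior_params(), seed = 13)
  rec2 <- simulate_associations(g1, 50, 10, behavior_params(), seed = 13)
  expect_identical(rec1, rec2)

  pa1 <- simulate_paired(g1, walk_similarity(g1, use_ppmi = FALSE),
                         behavior_params(n_pairs = 10), seed = 14)
  pa2 <- simulate_paired(g1, walk_similarity(g1, use_ppmi = FALSE),
                         behavior_params(n_pairs = 10), seed = 14)
  expect_identical(pa1, pa2)
})

test_that("truth networks are connected, hit their degree target, and order clustering by control", {
  gp <- group_params("young", n_words = 500, target_mean_degree = 6,
                     hub_overlay = 1, category_size = 20)
  g <- generate_truth_network(gp, seed = 21)
  expect_equal(igraph::vcount(g), 500)
  expect_equal(igraph::components(g)$no, 1)
  k <- mean(igraph::degree(g))
  expect_lt(abs(k - 6) / 6, 0.10)

  high <- group_params("young", n_words = 500, clustering_control = 1,
                       category_size = 20, category_cohesion = 0)
  low <- group_params("young", n_words = 500, clustering_control = 0.3,
                      category_size = 20, category_cohesion = 0)
  C_hi <- macro_stats(generate_truth_network(high, seed = 22))$clustering
  C_lo <- macro_stats(generate_truth_network(low, seed = 22))$clustering
  expect_gt(C_hi, C_lo)

  expect_error(generate_truth_network(
    group_params("young", n_words = 50, target_mean_degree = 2,
                 hub_overlay = 1, n_categories = 2, category_size = 5),
    seed = 1), "unsatisfiable")
})

test_that("association simulation respects the design and the repeat-fidelity limits", {
  gp <- group_params("young", scale = 0.25)
  truth <- generate_truth_network(gp, seed = 31)

  rec <- simulate_associations(truth, 100, 20,
                               behavior_params(repeat_fidelity = 1),
                               seed = 32)
  expect_equal(nrow(rec), 120)
  expect_equal(sum(rec$is_repeat), 20)
  expect_equal(as.numeric(repeated_cue_consistency(rec)), 1)

  rec0 <- simulate_associations(truth, 100, 50,
                                behavior_params(repeat_fidelity = 0),
                                seed = 33)
  expect_lt(as.numeric(repeated_cue_consistency(rec0)), 0.05)

  expect_error(simulate_associations(truth, igraph::vcount(truth) + 1, 0,
                                     behavior_params(), seed = 1),
               "exceeds lexicon")
  expect_error(simulate_associations(truth, 10, 11, behavior_params(),
                                     seed = 1), "exceeds n_unique")
})

test_that("extreme centrality coupling makes fluency retrieve candidates in PageRank order", {
  gp <- group_params("young", scale = 0.25)
  truth <- generate_truth_network(gp, seed = 41)
  pr <- pagerank(truth)
  animals <- igraph::V(truth)$name[!is.na(igraph::V(truth)$category) &
                                     igraph::V(truth)$category == "animals"]
  bp <- behavior_params(beta_centrality = 1000, beta_similarity = 0,
                        fluency_length = 6)
  m <- walk_similarity(truth, use_ppmi = FALSE, rows = animals)
  flu <- simulate_fluency(pr, m, animals, bp, seed = 42)
  expect_equal(flu$word,
               names(sort(pr[animals], decreasing = TRUE))[1:6])
})

test_that("episodic simulation honours the intrusion rate and list design", {
  gp <- group_params("young", scale = 0.25)
  truth <- generate_truth_network(gp, seed = 51)
  pr <- pagerank(truth)
  epi0 <- simulate_episodic(truth, pr,
                            behavior_params(intrusion_rate = 0), seed = 52)
  studied <- epi0$word[epi0$phase == "studied"]
  recalled <- epi0$word[epi0$phase == "recalled"]
  expect_equal(length(studied), 20)
  expect_equal(length(setdiff(recalled, studied)), 0)   # no intrusions
})

test_that("cohort output passes schema validation unmodified and carries group structure", {
  out_dir <- withr::local_tempdir()
  coh <- simulate_cohort(n_per_group = 1, n_unique_cues = 120,
                         n_repeat_cues = 24,
                         young = group_params("young", scale = 0.2),
                         old = group_params("old", scale = 0.2),
                         behavior = behavior_params(fluency_length = 8,
                                                    n_pairs = 20),
                         seed = 61, out_dir = out_dir)
  rec <- load_associations(file.path(out_dir, "associations.csv"))
  expect_equal(nrow(rec), nrow(coh$associations))
  expect_silent(load_fluency(file.path(out_dir, "fluency.csv")))
  expect_silent(load_episodic(file.path(out_dir, "episodic.csv")))
  expect_silent(load_paired(file.path(out_dir, "paired.csv")))
  parts <- load_participants(file.path(out_dir, "participants.csv"))
  expect_setequal(parts$group, c("young", "old"))
  # shared cue list across participants
  cues <- split(coh$associations$cue[!coh$associations$is_repeat],
                coh$associations$participant_id[!coh$associations$is_repeat])
  expect_setequal(cues[[1]], cues[[2]])
})
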