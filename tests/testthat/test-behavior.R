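# shared fixture: a small network with known centrality structure
local_star_net <- function() {
  # hub connected to everything, plus a peripheral chain
  semnet_from_edges(c(rep("hub", 5), "p1", "p2"),
                    c("p1", "p2", "p3", "p4", "p5", "p2", "p3"))
}

test_that("fluency retrieval effect is positive by construction and guards its support", {
  g <- local_star_net()
  pr <- pagerank(g)
  cands <- c("hub", "p1", "p2", "p3", "p4", "p5")
  top2 <- names(sort(pr[cands], decreasing = TRUE))[1:2]
  eff <- fluency_retrieval_effect(pr, top2, cands, participant_id = "P1")
  expect_gt(eff$value, 0)
  expect_equal(eff$n_retrieved, 2)
  expect_equal(eff$n_comparison, 4)

  expect_error(fluency_retrieval_effect(pr, cands, cands), "empty comparison")
  expect_error(fluency_retrieval_effect(pr, "offnet", cands), "no retrieved")
  expect_error(fluency_retrieval_effect(pr, top2, c(cands, "ghost")),
               "subset of network nodes")
  # out-of-network items dropped and counted
  eff2 <- fluency_retrieval_effect(pr, c(top2, "ghost"), cands)
  expect_equal(attr(eff2, "n_items_dropped"), 1L)
  expect_equal(eff2$value, eff$value)
})

test_that("lag similarity decays with distance on a path and skips out-of-network items", {
  path <- semnet_from_edges(c("a", "b", "c"), c("b", "c", "d"))
  m <- walk_similarity(path, use_ppmi = FALSE)
  lag <- fluency_lag_similarity(m, c("a", "b", "c", "d"), max_lag = 3)
  expect_gt(lag$value[1], lag$value[3])
  expect_equal(lag$n_pairs, c(3L, 2L, 1L))

  # out-of-network item breaks its pairs but does not re-splice the sequence
  lag2 <- fluency_lag_similarity(m, c("a", "ghost", "b"), max_lag = 2)
  expect_equal(lag2$n_pairs, c(0L, 1L))
  expect_true(is.na(lag2$value[1]))
  expect_equal(lag2$value[2], cosine_similarity(m, "a", "b"))

  # mutually disconnected retrievals: all lags zero
  disc <- semnet_from_edges(c("a", "c", "e"), c("b", "d", "f"))
  md <- walk_similarity(disc, use_ppmi = FALSE)
  lag3 <- fluency_lag_similarity(md, c("a", "c", "e"), max_lag = 2)
  expect_equal(lag3$value, c(0, 0))
})

test_that("episodic profiles partition statuses and rank a hub intrusion high", {
  g <- local_star_net()
  pr <- pagerank(g)
  m <- walk_similarity(g, use_ppmi = FALSE)

  # perfect recall: no missing, no intrusions
  prof <- episodic_profile(pr, m, studied = c("p1", "p2"),
                           recalled = c("p1", "p2"))
  expect_equal(prof$n[prof$status == "missing"], 0)
  expect_equal(prof$n[prof$status == "intrusion"], 0)

  # hub intrusion adjacent to all retrieved words beats the missing words
  prof2 <- episodic_profile(pr, m, studied = c("p1", "p2", "p4", "p5"),
                            recalled = c("p1", "p2", "hub"))
  i_sim <- prof2$mean_cosine_to_retrieved[prof2$status == "intrusion"]
  m_sim <- prof2$mean_cosine_to_retrieved[prof2$status == "missing"]
  expect_gt(i_sim, m_sim)

  # no retrieved word in network: centrality profile survives, similarity NA
  prof3 <- episodic_profile(pr, m, studied = c("p1", "p2"),
                            recalled = "ghost")
  expect_false(is.na(prof3$mean_centrality[prof3$status == "missing"]))
  expect_true(all(is.na(prof3$mean_cosine_to_retrieved)))
  expect_error(episodic_profile(pr, m, studied = "ghost", recalled = "p1"),
               "no studied word")
})

test_that("paired-associate effect separates adjacent from cross-component pairs", {
  g <- semnet_from_edges(c("a", "c", "x"), c("b", "d", "y"))
  m <- walk_similarity(g, use_ppmi = FALSE)
  pairs <- data.frame(cue = c("a", "c", "a", "x"),
                      target = c("b", "d", "x", "c"),
                      recalled = c(TRUE, TRUE, FALSE, FALSE))
  eff <- paired_associate_effect(m, pairs)
  expect_gt(eff$value, 0)
  expect_equal(eff$n_retrieved, 2)

  allsame <- pairs
  allsame$recalled <- TRUE
  expect_error(paired_associate_effect(m, allsame), "both recalled")

  # random outcomes: mean effect within 2 SE of zero over replications
  set.seed(55)
  gg <- rand_semnet(40, 0.15, seed = 56)
  mm <- walk_similarity(gg, use_ppmi = FALSE)
  nodes <- igraph::V(gg)$name
  vals <- replicate(1000, {
    pw <- data.frame(cue = sample(nodes, 20, replace = TRUE),
                     target = sample(nodes, 20, replace = TRUE),
                     recalled = sample(c(TRUE, FALSE), 20, replace = TRUE))
    pw <- pw[pw$cue != pw$target, ]
    tryCatch(paired_associate_effect(mm, pw)$value, error = function(e) NA)
  })
  vals <- vals[!is.na(vals)]
  expect_lt(abs(mean(vals)), 2 * stats::sd(vals) / sqrt(length(vals)))
})

test_that("individual-vs-aggregate comparison is zero on identical inputs and validates coverage", {
  eff <- data.frame(participant_id = rep(c("P1", "P2"), 2),
                    task = rep(c("f", "p"), each = 2),
                    network_source = "individual",
                    statistic = "stat", value = c(1, 2, 3, 4),
                    n_retrieved = 5, n_comparison = 5,
                    stringsAsFactors = FALSE)
  eff2 <- eff
  eff2$network_source <- "aggregate"
  cmp <- compare_individual_vs_aggregate(eff, eff2)
  expect_equal(cmp$difference, c(0, 0))
  expect_equal(cmp$n_participants, c(2L, 2L))

  expect_error(compare_individual_vs_aggregate(eff, eff2[-1, ]),
               "different participants")
})

test_that("effects are invariant to candidate iteration order and participant relabeling", {
  g <- local_star_net()
  pr <- pagerank(g)
  cands <- c("hub", "p1", "p2", "p3", "p4", "p5")
  items <- c("hub", "p3")
  e1 <- fluency_retrieval_effect(pr, items, cands)
  e2 <- fluency_retrieval_effect(pr, items, rev(cands),
                                 participant_id = "other")
  expect_equal(e1$value, e2$value)
})
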