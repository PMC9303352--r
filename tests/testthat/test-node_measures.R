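test_that("PPMI matches its closed forms and a direct enumeration oracle", {
  # perfect diagonal association: two disjoint pairs with count 2 -> 1 bit
  g <- semnet_from_edges(c("a1", "a2"), c("b1", "b2"), weight = c(2, 2))
  out <- ppmi_transform(g)
  expect_equal(sort(igraph::E(out)$weight), c(1, 1))

  # joint equal to product of marginals: 4-cycle with equal weights has
  # p(i,j) = 1/4 and p(i)p(j) = 1/4 -> all PPMI 0, empty edge set
  cyc <- semnet_from_edges(c("a", "b", "c", "d"), c("b", "c", "d", "a"),
                           weight = 1)
  expect_equal(igraph::ecount(ppmi_transform(cyc)), 0)
  expect_equal(igraph::vcount(ppmi_transform(cyc)), 4)   # nodes retained

  # random count tables against the formula oracle
  for (s in 1:5) {
    g <- rand_semnet(12, 0.4, seed = 200 + s)
    g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
    out <- ppmi_transform(g)
    orc <- oracle_ppmi(igraph::as_data_frame(g))
    orc <- orc[orc$ppmi > 0, ]
    od <- igraph::as_data_frame(out)
    key <- function(d) paste(pmin(d$from, d$to), pmax(d$from, d$to))
    expect_setequal(key(od), key(orc))
    m <- match(key(orc), key(od))
    expect_equal(od$weight[m], orc$ppmi, tolerance = 1e-12)
  }
  expect_error(ppmi_transform(igraph::make_empty_graph(2, directed = FALSE)),
               "no edges")
})

test_that("scaled PageRank matches symmetry cases and the dense linear-solve oracle", {
  cyc <- semnet_from_edges(c("a", "b", "c", "d"), c("b", "c", "d", "a"))
  expect_equal(as.numeric(pagerank(cyc)), rep(1, 4), tolerance = 1e-10)

  path <- semnet_from_edges(c("a", "b"), c("b", "c"))
  pr <- pagerank(path, damping = 0.85, weighted = FALSE)
  expect_equal(as.numeric(pr), as.numeric(oracle_pagerank(path, 0.85, weighted = FALSE)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(as.numeric(round(pr, 4)), c(0.7703, 1.4595, 0.7703))

  lone <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(lone)$name <- "solo"
  expect_equal(as.numeric(pagerank(lone)), 1)

  for (s in 1:6) {
    g <- rand_semnet(sample(5:40, 1), 0.15, seed = 300 + s)
    for (w in c(TRUE, FALSE)) {
      pr <- pagerank(g, weighted = w)
      expect_lt(max(abs(pr - oracle_pagerank(g, weighted = w))), 1e-10)
      expect_equal(mean(pr), 1, tolerance = 1e-12)   # scaled mean exactly 1
      expect_equal(sum(attr(pr, "raw")), 1, tolerance = 1e-9)
    }
  }

  # independent implementation cross-check on a connected weighted graph
  g <- rand_semnet(30, 0.2, seed = 310)
  g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  ours <- pagerank(g, damping = 0.85, weighted = TRUE)
  ref <- igraph::page_rank(g, damping = 0.85,
                           weights = igraph::E(g)$weight)$vector
  expect_equal(as.numeric(ours), as.numeric(ref * igraph::vcount(g)),
               tolerance = 1e-6)
})

test_that("walk similarity reproduces the two-node closed form", {
  g <- semnet_from_edges("a", "b")
  m <- walk_similarity(g, alpha = 0.5, use_ppmi = FALSE)
  # (I - 0.5 P)^{-1} = [[4/3, 2/3], [2/3, 4/3]]; minus I
  expect_equal(m$S, matrix(c(1/3, 2/3, 2/3, 1/3), 2,
                           dimnames = list(c("a", "b"), c("a", "b"))),
               tolerance = 1e-12)
  expect_equal(cosine_similarity(m, "a", "b"), 0.8, tolerance = 1e-12)
  expect_equal(cosine_similarity(m, "a", "a"), 1)
  expect_equal(cosine_similarity(m, "a", "b"), cosine_similarity(m, "b", "a"))
})

test_that("exchangeable nodes have cosine 1 and separated components cosine 0", {
  # c and d have identical neighbourhoods {a, b} with equal weights
  g <- semnet_from_edges(c("a", "a", "b", "b"), c("c", "d", "c", "d"))
  m <- walk_similarity(g, use_ppmi = FALSE)
  expect_equal(cosine_similarity(m, "c", "d"), 1, tolerance = 1e-10)

  two <- semnet_from_edges(c("a", "x"), c("b", "y"))
  m2 <- walk_similarity(two, use_ppmi = FALSE)
  expect_equal(cosine_similarity(m2, "a", "x"), 0)
})

test_that("closed form, truncated series, row restriction and inverse identity agree", {
  for (s in 1:4) {
    g <- rand_semnet(sample(10:50, 1), 0.2, seed = 400 + s)
    for (ppmi in c(TRUE, FALSE)) {
      if (ppmi && igraph::ecount(g) == 0) next
      md <- walk_similarity(g, alpha = 0.75, use_ppmi = ppmi,
                            method = "dense")
      ms <- walk_similarity(g, alpha = 0.75, use_ppmi = ppmi,
                            method = "series", tol = 1e-12)
      expect_lt(max(abs(md$S - ms$S)), 1e-8)

      # (I - aP)(I + S) = I
      gg <- if (ppmi) ppmi_transform(g) else g
      P <- oracle_transition(gg)
      n <- igraph::vcount(g)
      expect_lt(max(abs((diag(n) - 0.75 * P) %*% (diag(n) + md$S) - diag(n))),
                1e-8)
      # 50-term series oracle
      expect_lt(max(abs(oracle_katz_series(P, 0.75, 100) - md$S)), 1e-8)

      rows <- sample(igraph::V(g)$name, 4)
      mr <- walk_similarity(g, alpha = 0.75, use_ppmi = ppmi, rows = rows,
                            tol = 1e-12)
      expect_lt(max(abs(mr$S - md$S[rows, , drop = FALSE])), 1e-8)
    }
  }
})

test_that("cosine matches brute-force vector algebra and rejects unknown nodes", {
  g <- rand_semnet(10, 0.35, seed = 77)
  m <- walk_similarity(g, use_ppmi = FALSE)
  nodes <- igraph::V(g)$name
  set.seed(78)
  for (k in 1:10) {
    ab <- sample(nodes, 2)
    expect_equal(cosine_similarity(m, ab[1], ab[2]),
                 brute_cosine(m, ab[1], ab[2]), tolerance = 1e-12)
  }
  expect_error(cosine_similarity(m, "nope", nodes[1]), "unknown node")
})
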