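# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (dense matrices, triple loops) so they cannot share a
# defect with the implementation they check.

semnet_from_edges <- function(from, to, weight = 1) {
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = weight,
               stringsAsFactors = FALSE), directed = FALSE)
}

rand_semnet <- function(n, p = 0.3, seed = 1, max_w = 5) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("w%03d", seq_len(n))
  if (igraph::ecount(g) > 0) {
    igraph::E(g)$weight <- sample.int(max_w, igraph::ecount(g), replace = TRUE)
  }
  g
}

# mean local clustering by explicit neighbour-pair enumeration; deg < 2 -> 0
oracle_clustering <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A <- (A > 0) * 1
  n <- nrow(A)
  loc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) links <- links + A[nb[a], nb[b]]
    }
    loc[i] <- links / (k * (k - 1) / 2)
  }
  mean(loc)
}

# Floyd-Warshall mean distance over unordered pairs of the largest component
oracle_path_length <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  if (length(keep) < 2) return(NA_real_)
  Dk <- D[keep, keep]
  mean(Dk[upper.tri(Dk)])
}

# dense linear solve of the damped stationary equations, dangling mass
# redistributed uniformly; returns scaled values
oracle_pagerank <- function(g, d = 0.85, weighted = TRUE) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(
    g, sparse = FALSE, attr = if (weighted && igraph::ecount(g) > 0) "weight"))
  s <- colSums(A)
  M <- matrix(0, n, n)
  nz <- s > 0
  M[, nz] <- sweep(A[, nz, drop = FALSE], 2, s[nz], "/")
  dang <- as.numeric(!nz)
  sys <- diag(n) - d * M - (d / n) * outer(rep(1, n), dang)
  r <- solve(sys, rep((1 - d) / n, n))
  r <- r / sum(r)
  stats::setNames(r * n, igraph::V(g)$name)
}

# row-stochastic transition matrix built independently with base matrix ops
oracle_transition <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(
    g, sparse = FALSE, attr = if (igraph::ecount(g) > 0) "weight"))
  rs <- rowSums(A)
  P <- A
  P[rs > 0, ] <- A[rs > 0, , drop = FALSE] / rs[rs > 0]
  P
}

oracle_katz_series <- function(P, alpha, n_terms = 50) {
  S <- matrix(0, nrow(P), ncol(P))
  term <- diag(nrow(P))
  for (t in seq_len(n_terms)) {
    term <- alpha * (term %*% P)
    S <- S + term
  }
  S
}

oracle_ppmi <- function(edges) {
  W <- sum(edges$weight)
  nodes <- unique(c(edges$from, edges$to))
  marg <- sapply(nodes, function(v) {
    sum(edges$weight[edges$from == v]) + sum(edges$weight[edges$to == v])
  })
  names(marg) <- nodes
  p <- marg / W
  val <- pmax(0, log2((edges$weight / W) / (p[edges$from] * p[edges$to])))
  data.frame(from = edges$from, to = edges$to, ppmi = as.numeric(val),
             stringsAsFactors = FALSE)
}

# association-record table builder: resp is a list of character vectors
make_records <- function(pid, cues, resp, is_repeat = NULL) {
  pad <- function(x) c(x, rep(NA_character_, 3 - length(x)))
  m <- t(vapply(resp, pad, character(3)))
  data.frame(participant_id = pid, encounter_index = seq_along(cues),
             cue = cues, r1 = m[, 1], r2 = m[, 2], r3 = m[, 3],
             is_repeat = if (is.null(is_repeat)) FALSE else is_repeat,
             stringsAsFactors = FALSE)
}

brute_cosine <- function(model, a, b) {
  va <- model$S[a, ]
  vb <- model$S[b, ]
  if (sqrt(sum(va^2)) == 0 || sqrt(sum(vb^2)) == 0) return(0)
  sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
}
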