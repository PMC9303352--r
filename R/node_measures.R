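#' Positive pointwise mutual information reweighting
#'
#' Reweights co-occurrence counts to de-bias high-frequency words: an edge
#' (i, j) with count w gets weight `max(0, log2(p(i,j) / (p(i) p(j))))`, where
#' `p(i,j) = w_ij / W`, `W` is the total edge weight, and the marginal
#' `p(i)` is node i's strength over `W` (each undirected edge contributes to
#' both endpoints' marginals). Edges whose PPMI is zero are dropped; nodes are
#' retained, so a node can end up isolated under the transformed weights.
#'
#' @param net Semantic network with positive integer `weight` counts.
#' @return The network with `weight` replaced by PPMI values (zero-weight
#'   edges removed).
#' @export
ppmi_transform <- function(net) {
  if (igraph::ecount(net) == 0) stop("network has no edges", call. = FALSE)
  w <- igraph::E(net)$weight
  W <- sum(w)
  p_node <- igraph::strength(net, weights = w) / W
  el <- igraph::ends(net, igraph::E(net), names = TRUE)
  ppmi <- pmax(0, log2((w / W) / (p_node[el[, 1]] * p_node[el[, 2]])))
  out <- igraph::set_edge_attr(net, "weight", value = as.numeric(ppmi))
  igraph::delete_edges(out, which(ppmi <= 0))
}

#' PageRank centrality, scaled by network size
#'
#' Solves the damped random-walk stationary distribution
#' `PR_i = (1 - d)/|V| + d * sum_j PR_j w_ij / s_j` on the undirected graph by
#' power iteration (dangling mass redistributed uniformly), then multiplies by
#' `|V|` so that networks of different sizes are comparable: the scaled values
#' have mean exactly 1.
#'
#' @param net Semantic network.
#' @param damping Damping factor d in (0, 1); default 0.85.
#' @param weighted Use edge weights (raw counts) in the transition
#'   probabilities? Default `TRUE`.
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter Iteration cap; non-convergence is an error carrying the
#'   residual.
#' @return Named numeric vector of scaled PageRank values with attributes
#'   `damping` and `raw` (the unscaled stationary probabilities, summing
#'   to 1).
#' @export
pagerank <- function(net, damping = 0.85, weighted = TRUE, tol = 1e-12,
                     max_iter = 10000L) {
  n <- igraph::vcount(net)
  if (n == 0) stop("empty network", call. = FALSE)
  stopifnot(damping > 0, damping < 1)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE,
                                   attr = if (weighted &&
                                              igraph::ecount(net) > 0) "weight")
  s <- Matrix::colSums(A)
  dangling <- s == 0
  inv_s <- ifelse(dangling, 0, 1 / s)
  # M %*% r with M_ij = w_ij / s_j (column-stochastic off the dangling set)
  M <- A %*% Matrix::Diagonal(x = inv_s)
  r <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    r_new <- as.numeric((1 - damping) / n +
                          damping * (M %*% r + sum(r[dangling]) / n))
    delta <- sum(abs(r_new - r))
    r <- r_new
    if (delta < tol) {
      r <- r / sum(r)
      scaled <- r * n
      names(scaled) <- igraph::V(net)$name
      attr(scaled, "damping") <- damping
      attr(scaled, "raw") <- stats::setNames(r, igraph::V(net)$name)
      return(scaled)
    }
  }
  stop("PageRank power iteration did not converge: residual ", delta,
       " after ", max_iter, " iterations", call. = FALSE)
}

#' Katz walk similarity
#'
#' Accumulates walks of every length with geometric decay alpha over the
#' row-normalized transition matrix P of the (optionally PPMI-reweighted)
#' network: `S = sum_t alpha^t P^t = (I - alpha P)^{-1} - I`. The identity is
#' subtracted so a node's vector reflects its walk profile through the rest of
#' the network, not trivial self-walks. Row vectors of S are the
#' representations compared with [cosine_similarity()].
#'
#' Because P is row-(sub)stochastic and `alpha < 1`, the Neumann series always
#' converges. Small networks are solved exactly by a dense linear solve; above
#' `dense_cutoff` nodes the truncated series is accumulated instead, to an
#' increment tolerance of `tol`; the two routes agree on sizes where both
#' apply.
#'
#' @param net Semantic network.
#' @param alpha Decay in (0, 1); default 0.75.
#' @param use_ppmi Reweight counts by PPMI before normalizing? Default `TRUE`.
#' @param method `"auto"`, `"dense"` or `"series"`.
#' @param dense_cutoff Largest node count solved densely under `"auto"`.
#' @param tol Series truncation tolerance (largest entry of the last added
#'   term).
#' @param rows Optional character vector of node names: compute only these
#'   rows of S (always via the series), which is cheap when only a small set
#'   of words will be compared. The resulting model can cosine-compare those
#'   words only.
#' @return Object of class `walk_similarity`: list with `S` (dense matrix,
#'   rownames = representable nodes, colnames = all nodes), `nodes` (the
#'   nodes whose rows are available), `alpha`, `use_ppmi`.
#' @export
walk_similarity <- function(net, alpha = 0.75, use_ppmi = TRUE,
                            method = c("auto", "dense", "series"),
                            dense_cutoff = 2000L, tol = 1e-10, rows = NULL) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1)
  n <- igraph::vcount(net)
  if (n == 0) stop("empty network", call. = FALSE)
  all_nodes <- igraph::V(net)$name
  g <- if (use_ppmi) ppmi_transform(net) else net
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE,
                                   attr = if (igraph::ecount(g) > 0) "weight")
  rs <- Matrix::rowSums(A)
  inv_rs <- ifelse(rs == 0, 0, 1 / rs)
  P <- Matrix::Diagonal(x = inv_rs) %*% A
  max_terms <- ceiling(log(tol) / log(alpha)) + 50L
  if (!is.null(rows)) {
    ridx <- match(rows, all_nodes)
    if (anyNA(ridx)) stop("rows contains unknown node names", call. = FALSE)
    tP <- Matrix::t(P)
    term <- alpha * as.matrix(tP[, ridx, drop = FALSE])
    S <- term
    for (t in seq_len(max_terms)) {
      term <- alpha * as.matrix(tP %*% term)
      S <- S + term
      if (max(abs(term)) < tol) break
    }
    S <- t(S)
    dimnames(S) <- list(rows, all_nodes)
    return(structure(list(S = S, nodes = rows, alpha = alpha,
                          use_ppmi = use_ppmi), class = "walk_similarity"))
  }
  if (method == "auto") method <- if (n <= dense_cutoff) "dense" else "series"
  if (method == "dense") {
    S <- solve(diag(n) - alpha * as.matrix(P)) - diag(n)
  } else {
    aP <- alpha * P
    term <- as.matrix(aP)
    S <- term
    for (t in seq_len(max_terms)) {
      term <- as.matrix(aP %*% term)
      S <- S + term
      if (max(abs(term)) < tol) break
    }
  }
  dimnames(S) <- list(all_nodes, all_nodes)
  structure(list(S = S, nodes = all_nodes, alpha = alpha,
                 use_ppmi = use_ppmi), class = "walk_similarity")
}

#' @export
print.walk_similarity <- function(x, ...) {
  cat("Katz walk similarity over", length(x$nodes), "nodes (alpha =", x$alpha,
      if (x$use_ppmi) ", PPMI weights)\n" else ", raw count weights)\n")
  invisible(x)
}

#' Cosine relatedness of two words
#'
#' Cosine of the walk-similarity row vectors of two nodes. Returns 0 whenever
#' either row is all-zero (e.g. nodes isolated under PPMI weights); nodes in
#' different components therefore have cosine 0, and any connected node has
#' cosine 1 with itself.
#'
#' @param model A [walk_similarity()] object.
#' @param a,b Character vectors of node names (recycled to common length).
#' @return Numeric vector of cosines in \[0, 1\].
#' @export
cosine_similarity <- function(model, a, b) {
  unknown <- setdiff(c(a, b), model$nodes)
  if (length(unknown) > 0) {
    stop("unknown node(s): ", paste(utils::head(unknown, 5), collapse = ", "),
         call. = FALSE)
  }
  k <- max(length(a), length(b))
  a <- rep_len(a, k)
  b <- rep_len(b, k)
  va <- model$S[a, , drop = FALSE]
  vb <- model$S[b, , drop = FALSE]
  num <- rowSums(va * vb)
  den <- sqrt(rowSums(va^2)) * sqrt(rowSums(vb^2))
  out <- ifelse(den == 0, 0, num / den)
  unname(out)
}

#' Pairwise cosine matrix over a node subset
#' @keywords internal
.cosine_matrix <- function(model, nodes) {
  V <- model$S[nodes, , drop = FALSE]
  nrm <- sqrt(rowSums(V^2))
  nz <- nrm > 0
  Vn <- V
  Vn[nz, ] <- V[nz, , drop = FALSE] / nrm[nz]
  Vn[!nz, ] <- 0
  M <- tcrossprod(Vn)
  diag(M)[nz] <- 1
  M
}
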