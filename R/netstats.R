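#' Macroscopic network statistics
#'
#' Computes the four macroscopic descriptors used to compare semantic
#' networks: node count, mean degree, mean local clustering coefficient and
#' average shortest path length. All four ignore edge weights. Nodes of degree
#' 0 or 1, whose local clustering is undefined, contribute 0 and are included
#' in the mean. Path length is averaged over unordered node pairs within the
#' largest connected component, so disconnected pairs never contribute
#' infinities.
#'
#' @param net A semantic network (igraph).
#' @return One-row data frame with columns `n_nodes`, `n_edges`, `mean_degree`
#'   (2E/V), `clustering`, `path_length`, and metadata columns `owner` and
#'   `group` when present on the network.
#' @export
macro_stats <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0) stop("empty network", call. = FALSE)
  e <- igraph::ecount(net)
  loc <- igraph::transitivity(net, type = "local", isolates = "zero")
  comp <- igraph::components(net)
  giant <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(net, which(comp$membership == giant))
  L <- if (igraph::vcount(sub) >= 2) {
    igraph::mean_distance(sub, weights = NA, directed = FALSE)
  } else {
    NA_real_
  }
  data.frame(
    owner = .graph_attr_or(net, "owner", NA_character_),
    group = .graph_attr_or(net, "group", NA_character_),
    n_nodes = n,
    n_edges = e,
    mean_degree = 2 * e / n,
    clustering = mean(loc),
    path_length = L,
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
.graph_attr_or <- function(g, name, default) {
  if (name %in% igraph::graph_attr_names(g)) igraph::graph_attr(g, name) else default
}

#' Group-level summary of macroscopic statistics
#'
#' Unweighted arithmetic means of each macroscopic statistic within groups,
#' e.g. to contrast older and younger adults' network structure.
#'
#' @param stats Data frame as returned by (rows of) [macro_stats()], with a
#'   non-missing `group` column.
#' @param groups Optional character vector of admissible group labels; labels
#'   outside it raise an error.
#' @return Data frame with one row per group: means of `n_nodes`,
#'   `mean_degree`, `clustering`, `path_length` and the member count `n`.
#' @export
group_summary <- function(stats, groups = NULL) {
  if (any(is.na(stats$group))) stop("missing group label", call. = FALSE)
  if (!is.null(groups) && !all(stats$group %in% groups)) {
    stop("unknown group label: ",
         paste(setdiff(stats$group, groups), collapse = ", "), call. = FALSE)
  }
  cols <- c("n_nodes", "mean_degree", "clustering", "path_length")
  cols <- intersect(cols, names(stats))
  agg <- stats::aggregate(stats[cols], by = list(group = stats$group), FUN = mean)
  agg$n <- as.vector(table(stats$group)[agg$group])
  agg
}

#' Degree-distribution similarity of two networks
#'
#' Pearson correlation of the two unweighted degree vectors over the
#' intersection of the node sets, used to quantify how similarly two
#' participants' lexicons are wired.
#'
#' @param net_a,net_b Semantic networks sharing at least two nodes.
#' @return Correlation in \[-1, 1\].
#' @export
degree_distribution_similarity <- function(net_a, net_b) {
  shared <- intersect(igraph::V(net_a)$name, igraph::V(net_b)$name)
  if (length(shared) < 2) {
    stop("need >= 2 shared nodes for a correlation", call. = FALSE)
  }
  da <- igraph::degree(net_a)[shared]
  db <- igraph::degree(net_b)[shared]
  stats::cor(da, db)
}

#' Louvain community detection
#'
#' Modularity-maximizing partition of the weighted network via the Louvain
#' method. The node order is fixed by a lexicographic sort and the random
#' number generator is seeded, so the partition is deterministic for a given
#' seed.
#'
#' @param net Semantic network.
#' @param seed Integer seed controlling tie-breaking.
#' @return Named integer vector: community id per node.
#' @export
detect_communities <- function(net, seed = 1L) {
  perm <- order(igraph::V(net)$name)
  g <- igraph::permute(net, order(perm))
  memb <- .with_seed(seed, {
    cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
    igraph::membership(cl)
  })
  out <- as.integer(memb)
  names(out) <- igraph::V(g)$name
  out[igraph::V(net)$name]
}

#' Evaluate an expression under a temporary RNG seed
#' @keywords internal
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
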