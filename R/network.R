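#' Spearman correlation screen for co-occurrence edges
#'
#' Tests every unordered taxon pair with Spearman rank correlation
#' (average-rank ties; asymptotic t p-value) and retains pairs with
#' `|rho| > rho_threshold` and `p < alpha`. No multiple-testing correction
#' is applied by default, matching the raw cutoff convention of
#' co-occurrence studies; set `fdr = TRUE` for a Benjamini-Hochberg screen.
#'
#' @param table relative-abundance `community_table`, typically pre-filtered
#'   with [filter_prevalence()].
#' @param rho_threshold absolute correlation cutoff (default 0.7).
#' @param alpha p-value cutoff (default 0.01).
#' @param fdr apply Benjamini-Hochberg adjustment before the alpha cut.
#' @return data.frame of retained edges: `taxon_u`, `taxon_v`, `rho`,
#'   `p_value`, `sign`; skipped constant taxa are attached as attribute
#'   `"skipped"`.
#' @export
correlation_screen <- function(table, rho_threshold = 0.7, alpha = 0.01,
                               fdr = FALSE) {
  stopifnot(inherits(table, "community_table"))
  x <- table$counts
  n <- ncol(x)
  if (n < 5) stop("correlation screen needs >= 5 samples")
  const <- apply(x, 1, function(v) length(unique(v)) == 1)
  if (any(const))
    warning("skipping ", sum(const), " constant taxon/taxa")
  x <- x[!const, , drop = FALSE]
  ranks <- t(apply(x, 1, rank))          # average-rank ties
  R <- cor(t(ranks))                     # Pearson on ranks == Spearman
  ut <- upper.tri(R)
  rho <- R[ut]
  idx <- which(ut, arr.ind = TRUE)
  tstat <- rho * sqrt((n - 2) / pmax(1e-300, 1 - rho^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  if (fdr) p <- p.adjust(p, "BH")
  keep <- abs(rho) > rho_threshold & p < alpha
  edges <- data.frame(taxon_u = rownames(x)[idx[keep, 1]],
                      taxon_v = rownames(x)[idx[keep, 2]],
                      rho = rho[keep], p_value = p[keep],
                      sign = ifelse(rho[keep] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  attr(edges, "skipped") <- rownames(table$counts)[const]
  edges
}

#' Build a co-occurrence network from screened edges
#'
#' Nodes are the taxa incident to at least one retained edge (isolated
#' candidates are excluded); edge weight is `|rho|`. Node attributes carry
#' taxonomy annotations and mean relative abundance when supplied.
#'
#' @param edges data.frame from [correlation_screen()].
#' @param table optional relative table for mean-abundance annotation.
#' @param taxonomy optional taxonomy data.frame for rank annotations.
#' @return an `igraph` graph with edge attributes `rho`, `p_value`, `sign`,
#'   `weight`.
#' @export
build_network <- function(edges, table = NULL, taxonomy = NULL) {
  if (!nrow(edges)) {
    warning("empty edge list: returning empty graph")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::E(g)$weight <- abs(igraph::E(g)$rho)
  if (!is.null(table)) {
    mra <- rowMeans(table$counts)
    igraph::V(g)$mean_ra <- unname(mra[igraph::V(g)$name])
  }
  if (!is.null(taxonomy)) {
    m <- match(igraph::V(g)$name, taxonomy$taxon_id)
    for (rk in intersect(.rank_ladder, names(taxonomy)))
      g <- igraph::set_vertex_attr(g, rk, value = taxonomy[[rk]][m])
  }
  g
}

#' Topology summary of a co-occurrence network
#'
#' Reports node/edge counts, average (weighted) degree, density, Louvain
#' modularity (best of `n_louvain` seeded runs on `|rho|` weights), average
#' clustering coefficient, average path length and diameter (computed on
#' the largest connected component, unweighted hops), number of connected
#' components, and the negative:positive edge ratio as a percentage.
#'
#' @param net igraph graph from [build_network()].
#' @param seed integer seed for the Louvain runs.
#' @param n_louvain number of seeded Louvain restarts.
#' @return one-row data.frame (class `topology_report`).
#' @export
topology <- function(net, seed = 1L, n_louvain = 10) {
  nn <- igraph::vcount(net); ne <- igraph::ecount(net)
  if (ne == 0) {
    warning("empty graph: topology is all zeros")
    return(data.frame(n_nodes = nn, n_edges = 0, average_degree = 0,
                      average_weighted_degree = 0, density = 0,
                      modularity = NA_real_,
                      average_clustering_coefficient = 0,
                      average_path_length = NA_real_, diameter = NA_real_,
                      n_connected_components = nn, neg_pos_ratio = NA_real_))
  }
  best_mod <- -Inf
  for (i in seq_len(n_louvain)) {
    set.seed(seed + i - 1L)
    cl <- igraph::cluster_louvain(net, weights = igraph::E(net)$weight)
    m <- igraph::modularity(cl)
    if (m > best_mod) best_mod <- m
  }
  comp <- igraph::components(net)
  giant <- igraph::induced_subgraph(net, which(comp$membership ==
                                                 which.max(comp$csize)))
  signs <- igraph::E(net)$sign
  npos <- sum(signs == "positive"); nneg <- sum(signs == "negative")
  data.frame(
    n_nodes = nn, n_edges = ne,
    average_degree = 2 * ne / nn,
    average_weighted_degree = sum(igraph::strength(net)) / nn,
    density = igraph::edge_density(net),
    modularity = best_mod,
    average_clustering_coefficient =
      igraph::transitivity(net, type = "localaverage", isolates = "zero"),
    average_path_length = igraph::mean_distance(giant, weights = NA),
    diameter = igraph::diameter(giant, weights = NA),
    n_connected_components = comp$no,
    neg_pos_ratio = if (npos > 0) 100 * nneg / npos else NA_real_)
}

#' Does a modularity value indicate modular structure?
#'
#' @param modularity numeric modularity value(s).
#' @return logical; `TRUE` iff modularity > 0.4 (strict).
#' @export
modular_structure_flag <- function(modularity) modularity > 0.4

#' Decompose edges around a focal class
#'
#' Partitions all edges incident to at least one node of the focal class
#' into intra-class (both endpoints in the class) and inter-class (exactly
#' one endpoint), split by correlation sign.
#'
#' @param net igraph graph with a `class` vertex attribute (see
#'   [build_network()] with `taxonomy`).
#' @param focal_class class label, e.g. `"Clostridia"`.
#' @return named list `intra_positive`, `intra_negative`, `inter_positive`,
#'   `inter_negative`.
#' @export
focal_class_edges <- function(net, focal_class) {
  cls <- igraph::vertex_attr(net, "class")
  if (is.null(cls)) stop("network has no `class` vertex attribute")
  if (!focal_class %in% cls) stop("unknown class label: ", focal_class)
  focal <- !is.na(cls) & cls == focal_class
  el <- igraph::as_edgelist(net, names = FALSE)
  signs <- igraph::E(net)$sign
  fu <- focal[el[, 1]]; fv <- focal[el[, 2]]
  touch <- fu | fv
  intra <- fu & fv
  list(intra_positive = sum(touch & intra & signs == "positive"),
       intra_negative = sum(touch & intra & signs == "negative"),
       inter_positive = sum(touch & !intra & signs == "positive"),
       inter_negative = sum(touch & !intra & signs == "negative"))
}

#' Random-removal robustness curve of a network
#'
#' For each removal fraction on a grid from 0 to 1, removes that fraction
#' of nodes uniformly at random, then drops nodes left with no remaining
#' neighbors (secondary extinction); the remaining-connected fraction is
#' surviving nodes / original nodes. The robustness score is the
#' trapezoidal area under the mean curve.
#'
#' @param net igraph graph.
#' @param step grid step; must divide 1 (default 0.05).
#' @param n_reps independent random draws per fraction (>= 2).
#' @param seed integer seed.
#' @return list with `removal_fractions`, `mean`, `sd`, `n_reps`,
#'   `robustness_score`.
#' @export
robustness <- function(net, step = 0.05, n_reps = 100, seed = 1L) {
  if (abs(1 / step - round(1 / step)) > 1e-9) stop("`step` must divide 1")
  if (n_reps < 2) stop("n_reps must be >= 2")
  nn <- igraph::vcount(net)
  if (nn < 5) stop("robustness needs >= 5 nodes")
  qs <- seq(0, 1, by = step)
  set.seed(seed)
  remaining <- matrix(NA_real_, n_reps, length(qs))
  for (r in seq_len(n_reps)) {
    for (qi in seq_along(qs)) {
      n_rm <- round(qs[qi] * nn)
      if (n_rm >= nn) { remaining[r, qi] <- 0; next }
      g <- if (n_rm > 0)
        igraph::delete_vertices(net, sample.int(nn, n_rm)) else net
      # secondary extinction: nodes with no surviving neighbor die
      g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
      remaining[r, qi] <- igraph::vcount(g) / nn
    }
  }
  mu <- colMeans(remaining)
  list(removal_fractions = qs, mean = mu, sd = apply(remaining, 2, sd),
       n_reps = n_reps,
       robustness_score = sum(diff(qs) * (head(mu, -1) + mu[-1]) / 2))
}

#' Network vulnerability
#'
#' Maximal relative drop in global efficiency caused by removing a single
#' node: \eqn{\max_i (E - E_i)/E}, with \eqn{E} the mean inverse shortest
#' path length over node pairs.
#'
#' @param net igraph graph with at least 3 nodes.
#' @return vulnerability value.
#' @export
vulnerability <- function(net) {
  nn <- igraph::vcount(net)
  if (nn < 3) stop("vulnerability needs >= 3 nodes")
  eff <- igraph::global_efficiency(net, weights = NA)
  drops <- vapply(seq_len(nn), function(i) {
    ei <- igraph::global_efficiency(igraph::delete_vertices(net, i),
                                    weights = NA)
    (eff - ei) / eff
  }, numeric(1))
  max(drops)
}

#' Natural connectivity (alternative stability index)
#'
#' Log of the average eigenvalue exponential of the adjacency matrix;
#' exposed as an alternative robustness measure.
#'
#' @param net igraph graph.
#' @return natural connectivity value.
#' @export
natural_connectivity <- function(net) {
  a <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  m <- max(ev)
  m + log(mean(exp(ev - m)))             # log-sum-exp stabilized
}

#' Write a network to GraphML and edge-list TSV
#'
#' @param net igraph graph.
#' @param graphml_path,edges_path output paths (either may be `NULL`).
#' @export
write_network <- function(net, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(net, graphml_path, format = "graphml")
  if (!is.null(edges_path)) {
    el <- igraph::as_edgelist(net)
    df <- data.frame(taxon_u = el[, 1], taxon_v = el[, 2],
                     rho = igraph::E(net)$rho,
                     p_value = igraph::E(net)$p_value,
                     sign = igraph::E(net)$sign)
    write.table(df, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(net)
}
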