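#' Connectance of the directed binary network
#'
#' `C = L / S^2` where `L` counts directed non-zero links: every
#' mutualistic or competitive pair contributes two, and every
#' consumer-resource pair contributes two (one gain, one loss).
#'
#' @param comm A non-empty [community()].
#' @return Connectance in `[0, 1)`.
#' @export
connectance <- function(comm) {
  S <- n_species(comm)
  if (S == 0) stop("connectance undefined for an empty community", call. = FALSE)
  2 * nrow(community_links(comm)) / S^2
}

#' Undirected projection of a community's interaction network
#'
#' One edge per interacting unordered pair, on all `S` nodes (isolated
#' species appear as degree-0 nodes). The weighted variant sums the pair's
#' two directed coefficients.
#'
#' @param comm A [community()].
#' @param weighted Attach summed-strength edge weights?
#' @return An [igraph::graph] with vertex attribute `species_id`.
#' @export
to_undirected <- function(comm, weighted = FALSE) {
  lk <- community_links(comm)
  ids <- comm$species$id
  g <- igraph::make_empty_graph(n = n_species(comm), directed = FALSE)
  igraph::V(g)$species_id <- ids
  if (nrow(lk) > 0) {
    ei <- rbind(match(lk$i, ids), match(lk$j, ids))
    g <- igraph::add_edges(g, as.vector(ei))
    if (weighted) igraph::E(g)$weight <- lk$w_ij + lk$w_ji
  }
  g
}

#' Read an undirected network from an edge-list TSV
#'
#' Expects columns `node_i`, `node_j` and optionally `weight`; isolated
#' nodes can be supplied via `n_nodes`.
#'
#' @param path TSV file path.
#' @param n_nodes Total node count (default: number of distinct endpoint
#'   labels).
#' @return An undirected [igraph::graph].
#' @export
read_network_tsv <- function(path, n_nodes = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("node_i", "node_j") %in% names(df)))
  labs <- sort(unique(c(df$node_i, df$node_j)))
  if (is.null(n_nodes)) n_nodes <- length(labs)
  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  ei <- rbind(match(df$node_i, labs), match(df$node_j, labs))
  g <- igraph::add_edges(g, as.vector(ei))
  if ("weight" %in% names(df)) igraph::E(g)$weight <- df$weight
  igraph::V(g)$name <- c(as.character(labs),
                         rep("", n_nodes - length(labs)))[seq_len(n_nodes)]
  g
}

#' Degree entropy
#'
#' Shannon entropy of the empirical degree distribution,
#' `H = -sum_k P(k) log(P(k))` with `0 log 0 := 0`. For weighted networks
#' node strength (sum of incident edge weights) is binned into
#' `n_bins` equal-width classes between the minimum and maximum strength
#' before applying the same formula.
#'
#' @param net An undirected [igraph::graph].
#' @param weighted Use binned node strengths instead of degrees.
#' @param n_bins Number of strength bins for the weighted variant.
#' @return Entropy in nats (`>= 0`).
#' @export
degree_entropy <- function(net, weighted = FALSE, n_bins = 20L) {
  stopifnot(igraph::vcount(net) >= 1)
  if (weighted) {
    st <- igraph::strength(net)
    if (max(st) == min(st)) return(0)
    k <- cut(st, breaks = seq(min(st), max(st), length.out = n_bins + 1L),
             include.lowest = TRUE)
  } else {
    k <- igraph::degree(net)
  }
  p <- table(k)
  p <- p[p > 0] / sum(p)
  H <- -sum(p * log(p))
  if (H == 0) H <- 0 # avoid signed zero
  H
}

#' Modularity of a partition (explicit formula)
#'
#' Evaluates `Mod = sum_c (L_c / m - epsilon * (k_c / 2m)^2)` on the given
#' partition of an unweighted undirected network: `L_c` intra-module edges,
#' `k_c` the summed degree of module `c`, `m` the total edge count, and
#' `epsilon` the resolution parameter.
#'
#' @param net An undirected [igraph::graph] with at least one edge.
#' @param partition Integer/factor membership vector over all nodes.
#' @param epsilon Resolution parameter (default 1).
#' @return The modularity value.
#' @export
modularity_score <- function(net, partition, epsilon = 1) {
  m <- igraph::ecount(net)
  if (m < 1) stop("modularity undefined for an edgeless network", call. = FALSE)
  stopifnot(length(partition) == igraph::vcount(net))
  partition <- as.integer(as.factor(partition))
  el <- igraph::as_edgelist(net, names = FALSE)
  Lc_full <- vapply(seq_len(max(partition)), function(cc) {
    sum(partition[el[, 1]] == cc & partition[el[, 2]] == cc)
  }, numeric(1))
  deg <- igraph::degree(net)
  kc <- vapply(seq_len(max(partition)), function(cc) sum(deg[partition == cc]),
               numeric(1))
  sum(Lc_full / m - epsilon * (kc / (2 * m))^2)
}

#' Louvain partition with seeded restarts
#'
#' Runs the Louvain community-detection algorithm at resolution 1 over
#' `n_restarts` seeded vertex-order shuffles and returns the partition with
#' the highest [modularity_score()].
#'
#' @param net An undirected [igraph::graph] with at least one edge.
#' @param seed RNG seed for the shuffles.
#' @param n_restarts Number of restarts.
#' @return Integer membership vector in vertex order.
#' @export
louvain_partition <- function(net, seed = NULL, n_restarts = 5L) {
  if (igraph::ecount(net) < 1) stop("cannot partition an edgeless network", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(net)
  best <- NULL
  best_mod <- -Inf
  for (k in seq_len(n_restarts)) {
    perm <- sample.int(n)
    gp <- igraph::permute(net, perm)
    memb <- igraph::membership(igraph::cluster_louvain(gp))
    memb_orig <- integer(n)
    memb_orig[perm] <- memb # back to original vertex order
    mod <- modularity_score(net, memb_orig)
    if (mod > best_mod) { best_mod <- mod; best <- memb_orig }
  }
  as.integer(as.factor(best))
}

#' Erdos-Renyi null distribution of entropy and modularity
#'
#' Generates `n_rep` G(S, p) undirected random graphs with `p` matched to
#' the observed undirected edge count (`p = E / (S (S - 1) / 2)`), and
#' computes degree entropy and Louvain modularity for each.
#'
#' @param S Number of nodes (>= 2).
#' @param n_edges Target undirected edge count of the observed network.
#' @param n_rep Number of null replicates (default 50).
#' @param seed RNG seed.
#' @return Tibble with one row per replicate (`H`, `Mod`, `n_edges`); `Mod`
#'   is `NA` for edgeless realizations.
#' @export
er_null <- function(S, n_edges, n_rep = 50L, seed = NULL) {
  stopifnot(S >= 2)
  if (!is.null(seed)) set.seed(seed)
  p <- min(1, n_edges / (S * (S - 1) / 2))
  purrr::map_dfr(seq_len(n_rep), function(k) {
    g <- igraph::sample_gnp(S, p)
    tibble::tibble(
      H = degree_entropy(g),
      Mod = if (igraph::ecount(g) >= 1)
        modularity_score(g, louvain_partition(g, n_restarts = 1L)) else NA_real_,
      n_edges = igraph::ecount(g))
  })
}

#' Effective increase of a metric over its null mean
#'
#' `Z_s = (Z - Z_r) / Z_r`: the relative elevation of an observed network
#' metric over the mean of matched random networks (1 = a 100% increase).
#'
#' @param Z Observed metric value.
#' @param Z_r Null-mean metric value (non-zero).
#' @return The effective-increase score.
#' @export
effective_increase <- function(Z, Z_r) {
  if (is.na(Z_r) || Z_r == 0) stop("effective increase undefined for a zero null mean", call. = FALSE)
  (Z - Z_r) / Z_r
}

#' Structural metrics report for a community
#'
#' Computes richness, directed link count, connectance, complexity
#' (`S * C`), interaction-type proportions, degree entropy and Louvain
#' modularity of the undirected projection, and (optionally) their
#' effective-increase scores against Erdos-Renyi nulls matched on `S` and
#' edge count.
#'
#' @param comm A [community()].
#' @param n_null Number of ER null replicates (0 skips the null scoring).
#' @param seed RNG seed for Louvain restarts and the nulls.
#' @param weighted Also compute the weighted (summed-strength) variants.
#' @return A one-row tibble of class `metrics_report`.
#' @export
metrics_report <- function(comm, n_null = 50L, seed = NULL, weighted = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  S <- n_species(comm)
  lk <- community_links(comm)
  L <- 2L * nrow(lk)
  C <- L / S^2
  pr <- if (nrow(lk) > 0) interaction_type_proportions(comm) else
    c(M = NA_real_, C = NA_real_, CR = NA_real_)
  net <- to_undirected(comm, weighted = weighted)
  H <- degree_entropy(net, weighted = weighted)
  Mod <- if (igraph::ecount(net) >= 1)
    modularity_score(net, louvain_partition(net)) else NA_real_
  out <- tibble::tibble(S = S, L = L, connectance = C, complexity = S * C,
                        prop_m = pr[["M"]], prop_c = pr[["C"]], prop_cr = pr[["CR"]],
                        H = H, Mod = Mod,
                        H_null = NA_real_, Mod_null = NA_real_,
                        H_score = NA_real_, Mod_score = NA_real_)
  if (n_null > 0 && S >= 2 && igraph::ecount(net) >= 1) {
    nulls <- er_null(S, igraph::ecount(net), n_rep = n_null)
    out$H_null <- mean(nulls$H)
    out$Mod_null <- mean(nulls$Mod, na.rm = TRUE)
    out$H_score <- if (out$H_null != 0) effective_increase(H, out$H_null) else NA_real_
    out$Mod_score <- if (!is.na(out$Mod) && !is.na(out$Mod_null) && out$Mod_null != 0)
      effective_increase(Mod, out$Mod_null) else NA_real_
  }
  class(out) <- c("metrics_report", class(out))
  out
}
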