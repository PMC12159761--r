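#' Filter taxa before network construction
#'
#' Retains taxa present (count > 0) in at least `min_prevalence` of the
#' samples and with mean relative abundance at least `min_mean_relabund`.
#' Zero-variance taxa are always dropped: Spearman correlation is
#' undefined for a constant vector.
#'
#' @param counts taxa x samples count matrix.
#' @param min_prevalence minimum fraction of samples with a non-zero count.
#' @param min_mean_relabund minimum mean relative abundance.
#' @return row-subset of `counts` (values untouched).
#' @export
filter_taxa <- function(counts, min_prevalence = 0, min_mean_relabund = 0) {
  counts <- validate_asv_table(counts)
  rel <- sweep(counts, 2, pmax(colSums(counts), 1), "/")
  prev <- rowMeans(counts > 0)
  keep <- prev >= min_prevalence &
    rowMeans(rel) >= min_mean_relabund &
    apply(counts, 1, function(x) length(unique(x)) > 1L)
  if (!any(keep)) stop("taxon filter removed all taxa")
  counts[keep, , drop = FALSE]
}

#' All-pairs Spearman correlation with BH-adjusted p-values
#'
#' Spearman rho is the Pearson correlation of mid-ranks (average ranks for
#' ties). Two-sided p-values use the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on \eqn{n - 2} degrees of
#' freedom; Benjamini-Hochberg adjustment is applied jointly over all
#' upper-triangle pairs.
#'
#' @param counts taxa x samples matrix; at least 4 samples and no
#'   zero-variance taxa (see [filter_taxa()]).
#' @param force allow fewer than 4 samples (p-values are then unreliable).
#' @return object of class `correlation_result`: list with symmetric
#'   matrices `rho`, `p_raw`, `p_adj` (diagonal `NA`, untested), plus
#'   `n_samples` and `n_pairs_tested`.
#' @export
spearman_matrix <- function(counts, force = FALSE) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  n <- ncol(counts)
  if (n < 4L && !force)
    stop("Spearman p-values are unreliable below 4 samples (use force = TRUE)")
  constant <- apply(counts, 1, function(x) length(unique(x)) <= 1L)
  if (any(constant))
    stop("zero-variance taxa present: ",
         paste(rownames(counts)[constant], collapse = ", "))

  rho <- stats::cor(t(counts), method = "spearman")
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  diag(rho) <- 1
  diag(p) <- NA_real_

  ut <- upper.tri(p)
  p_adj <- p
  p_adj[ut] <- stats::p.adjust(p[ut], method = "BH")
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]

  structure(list(rho = rho, p_raw = p, p_adj = p_adj,
                 n_samples = n, n_pairs_tested = sum(ut)),
            class = "correlation_result")
}

#' Build a signed co-occurrence network from a correlation result
#'
#' An edge joins two taxa iff `|rho| > rho_min` *and* `p_adj < alpha`
#' (strict inequalities). Taxa left without any edge are excluded from the
#' node set. Construction parameters are recorded on the object.
#'
#' @param corr a `correlation_result` from [spearman_matrix()].
#' @param rho_min correlation magnitude threshold (edges require strictly
#'   greater).
#' @param alpha adjusted-p threshold (edges require strictly smaller).
#' @param abundances optional named vector of mean relative abundances to
#'   attach to nodes.
#' @return object of class `co_network`: list with `graph` (undirected
#'   simple `igraph` whose edges carry `rho`, `p_adj`, `sign` and whose
#'   nodes may carry `mean_relabund`) and `params`. An empty edge set
#'   yields an empty graph, not an error.
#' @export
build_network <- function(corr, rho_min = 0.8, alpha = 0.05, abundances = NULL) {
  stopifnot(inherits(corr, "correlation_result"))
  rho <- corr$rho
  taxa <- rownames(rho)
  sel <- upper.tri(rho) & abs(rho) > rho_min & corr$p_adj < alpha
  idx <- which(sel, arr.ind = TRUE)
  if (nrow(idx)) {
    edges <- data.frame(from = taxa[idx[, 1]], to = taxa[idx[, 2]],
                        rho = rho[sel], p_adj = corr$p_adj[sel],
                        stringsAsFactors = FALSE)
    edges$sign <- ifelse(edges$rho > 0, "+", "-")
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  } else {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  }
  if (!is.null(abundances) && igraph::vcount(g) > 0)
    igraph::V(g)$mean_relabund <-
      unname(abundances[igraph::V(g)$name])
  structure(list(graph = g,
                 params = list(rho_min = rho_min, alpha = alpha,
                               n_samples = corr$n_samples)),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("co_network: %d nodes, %d edges (|rho| > %s, p_adj < %s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              format(x$params$rho_min), format(x$params$alpha)))
  invisible(x)
}

.as_igraph <- function(net) {
  if (inherits(net, "co_network")) net$graph
  else if (inherits(net, "igraph")) net
  else stop("expected a co_network or igraph object")
}

#' Topology metrics of a co-occurrence network
#'
#' Metrics are computed on the unweighted simple graph; correlation signs
#' and magnitudes stay as edge attributes only. Clustering is the mean of
#' local clustering coefficients with degree-<2 nodes counted as zero.
#' Average path length and diameter use unweighted shortest paths on the
#' largest connected component (disconnected graphs otherwise have
#' infinite paths); `*_per_node` columns divide by the node count as a
#' diagnostic for comparison with normalised conventions. Modularity is
#' Newman's Q of the best Louvain partition over `n_restarts` runs at
#' resolution 1, deterministic under `community_seed`.
#'
#' @param net `co_network` or `igraph`.
#' @param community_seed RNG seed for Louvain restarts.
#' @param n_restarts Louvain restarts; the highest-Q partition is kept.
#' @return object of class `topology_metrics` (a one-row `data.frame`):
#'   `n_nodes`, `n_edges`, `n_positive_edges`, `n_negative_edges`,
#'   `average_degree`, `density`, `clustering_coefficient`,
#'   `average_path_length`, `diameter`, `modularity`, `n_modules`,
#'   `n_components`, `average_path_length_per_node`, `diameter_per_node`.
#'   The winning membership vector is attached as attribute `membership`.
#' @export
topology <- function(net, community_seed = 7L, n_restarts = 10L) {
  g <- .as_igraph(net)
  nv <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  if (nv == 0L) stop("topology: empty graph")

  signs <- if (ne > 0 && !is.null(igraph::E(g)$sign)) igraph::E(g)$sign
           else character(0)
  n_pos <- sum(signs == "+")
  n_neg <- sum(signs == "-")
  if (ne > 0 && !length(signs)) { n_pos <- ne; n_neg <- 0L }

  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  clustering <- if (nv) mean(loc) else NA_real_

  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  apl <- if (igraph::vcount(sub) > 1) igraph::mean_distance(sub, directed = FALSE)
         else NA_real_
  diam <- if (igraph::vcount(sub) > 1) igraph::diameter(sub, unconnected = FALSE)
          else NA_real_

  if (ne > 0) {
    set.seed(community_seed)
    best <- NULL
    for (r in seq_len(n_restarts)) {
      cl <- igraph::cluster_louvain(g, resolution = 1)
      if (is.null(best) || igraph::modularity(cl) > igraph::modularity(best))
        best <- cl
    }
    q <- igraph::modularity(best)
    n_mod <- length(unique(igraph::membership(best)))
    memb <- igraph::membership(best)
  } else {
    q <- NA_real_; n_mod <- 0L; memb <- NULL
  }

  out <- data.frame(
    n_nodes = as.integer(nv), n_edges = as.integer(ne),
    n_positive_edges = as.integer(n_pos),
    n_negative_edges = as.integer(n_neg),
    average_degree = 2 * ne / nv,
    density = if (nv > 1) 2 * ne / (nv * (nv - 1)) else NA_real_,
    clustering_coefficient = clustering,
    average_path_length = apl, diameter = diam,
    modularity = q, n_modules = as.integer(n_mod),
    n_components = as.integer(comp$no),
    average_path_length_per_node = apl / nv,
    diameter_per_node = diam / nv
  )
  class(out) <- c("topology_metrics", class(out))
  attr(out, "membership") <- memb
  out
}

#' Percent reduction in modularity relative to a reference network
#'
#' `round(100 * (q_reference - q) / q_reference)`, reported as an integer
#' percentage (the convention used when stating, e.g., that a treatment
#' reduced modularity by 10%).
#'
#' @param q_reference modularity of the reference (e.g. control) network.
#' @param q modularity of the comparison network.
#' @return integer percent reduction (negative if modularity increased).
#' @export
modularity_reduction <- function(q_reference, q) {
  if (!is.finite(q_reference) || q_reference <= 0)
    stop("reference modularity must be positive")
  as.integer(round(100 * (q_reference - q) / q_reference))
}
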