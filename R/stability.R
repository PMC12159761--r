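#' Community cohesion from an abundance table
#'
#' Implements the connectedness/cohesion decomposition of community
#' structure. Taxon abundances are converted to per-sample relative
#' abundances and all pairwise Pearson correlations are computed. Under
#' the `taxa_shuffle` null model each taxon's abundance vector is permuted
#' across samples `n_null` times and the mean null correlation of each
#' pair is subtracted from the observed one (null-corrected r). A taxon's
#' positive connectedness is the mean of its strictly positive corrected
#' correlations with the other taxa (0 if none), and its negative
#' connectedness the mean of the strictly negative ones. Sample-level
#' cohesion weights connectedness by relative abundance:
#' \deqn{C^+(s) = \sum_j a_{sj} \, conn^+_j, \qquad
#'       C^-(s) = \sum_j a_{sj} \, conn^-_j.}
#'
#' @param counts taxa x samples count (or abundance) matrix.
#' @param null_model `"taxa_shuffle"` (default, null-corrected) or
#'   `"none"` (raw correlations; exactly hand-checkable).
#' @param n_null null permutations per taxon (>= 10) under `taxa_shuffle`.
#' @param seed RNG seed for the null permutations.
#' @return object of class `cohesion_result`: list with `samples`
#'   (data.frame: `sample_id`, `positive_cohesion`, `negative_cohesion`),
#'   `taxa` (data.frame: `taxon_id`, `connectedness_pos`,
#'   `connectedness_neg`), `null_model`, `n_null`, `seed`.
#' @export
cohesion <- function(counts, null_model = c("taxa_shuffle", "none"),
                     n_null = 200L, seed = 1L) {
  null_model <- match.arg(null_model)
  counts <- if (is.matrix(counts)) counts else as.matrix(counts)
  if (ncol(counts) < 3L) stop("cohesion needs at least 3 samples")
  if (null_model == "taxa_shuffle" && n_null < 10L)
    stop("taxa_shuffle requires n_null >= 10")
  if (any(colSums(counts) == 0))
    stop("cohesion undefined for all-zero samples")

  rel <- sweep(counts, 2, colSums(counts), "/")
  # constancy is judged on the relative-abundance scale the correlations use
  constant <- apply(rel, 1, function(x) stats::sd(x) == 0)
  if (any(constant)) {
    warning(sprintf("excluding %d constant taxa from cohesion", sum(constant)))
    rel <- rel[!constant, , drop = FALSE]
  }
  if (nrow(rel) < 2L) stop("cohesion needs at least 2 non-constant taxa")
  obs <- stats::cor(t(rel))

  nt <- nrow(rel)
  if (null_model == "taxa_shuffle") {
    set.seed(seed)
    ns <- ncol(rel)
    null_sum <- matrix(0, nt, nt)
    for (b in seq_len(n_null)) {
      shuf <- t(apply(rel, 1, function(x) x[sample.int(ns)]))
      null_sum <- null_sum + stats::cor(t(shuf))
    }
    r <- obs - null_sum / n_null
    diag(r) <- NA_real_
  } else {
    r <- obs
    diag(r) <- NA_real_
  }

  mean_part <- function(v, positive) {
    part <- if (positive) v[!is.na(v) & v > 0] else v[!is.na(v) & v < 0]
    if (length(part)) mean(part) else 0
  }
  conn_pos <- apply(r, 1, mean_part, positive = TRUE)
  conn_neg <- apply(r, 1, mean_part, positive = FALSE)

  coh_pos <- as.vector(crossprod(rel, conn_pos))
  coh_neg <- as.vector(crossprod(rel, conn_neg))

  structure(list(
    samples = data.frame(sample_id = colnames(rel),
                         positive_cohesion = coh_pos,
                         negative_cohesion = coh_neg,
                         row.names = NULL, stringsAsFactors = FALSE),
    taxa = data.frame(taxon_id = rownames(rel),
                      connectedness_pos = unname(conn_pos),
                      connectedness_neg = unname(conn_neg),
                      row.names = NULL, stringsAsFactors = FALSE),
    null_model = null_model,
    n_null = if (null_model == "taxa_shuffle") as.integer(n_null) else 0L,
    seed = seed), class = "cohesion_result")
}

#' Community stability ratio from cohesion
#'
#' The ratio of absolute negative to positive cohesion, per sample and as
#' a mean with standard error; higher ratios indicate a community whose
#' negative (stabilising) interactions better balance its positive ones.
#'
#' @param coh a `cohesion_result` from [cohesion()].
#' @return list with `samples` (data.frame: `sample_id`, `ratio`; `NA`
#'   where positive cohesion is not positive), `mean`, `se`.
#' @export
stability_ratio <- function(coh) {
  stopifnot(inherits(coh, "cohesion_result"))
  s <- coh$samples
  ratio <- ifelse(s$positive_cohesion > 0,
                  abs(s$negative_cohesion) / s$positive_cohesion, NA_real_)
  ok <- ratio[!is.na(ratio)]
  list(samples = data.frame(sample_id = s$sample_id, ratio = ratio,
                            row.names = NULL, stringsAsFactors = FALSE),
       mean = if (length(ok)) mean(ok) else NA_real_,
       se = if (length(ok) > 1) stats::sd(ok) / sqrt(length(ok)) else NA_real_)
}

#' Network robustness under simulated node removal
#'
#' For each removal fraction `f`, `floor(f * N)` nodes are removed per
#' repetition -- uniformly at random, or highest-degree-first (ties broken
#' randomly) for targeted attack -- and the connectivity statistic is the
#' fraction of remaining nodes that retain at least one edge. The value at
#' `f = 0.5` is the headline robustness.
#'
#' @param net `co_network` or `igraph`.
#' @param strategy `"random"`, `"degree"` (targeted by initial degree) or
#'   `"betweenness"` (targeted by initial betweenness).
#' @param fractions removal-fraction grid.
#' @param n_repetitions repetitions per fraction.
#' @param seed RNG seed.
#' @return object of class `robustness_curve`: list with `curve`
#'   (data.frame: `fraction`, `mean`, `sd`), `at_half` (mean statistic at
#'   the fraction closest to 0.5), `strategy`, `n_repetitions`, `seed`.
#' @export
robustness <- function(net, strategy = c("random", "degree", "betweenness"),
                       fractions = seq(0, 0.95, by = 0.05),
                       n_repetitions = 100L, seed = 1L) {
  strategy <- match.arg(strategy)
  g <- .as_igraph(net)
  N <- igraph::vcount(g)
  if (N == 0L || igraph::ecount(g) == 0L)
    stop("robustness: empty network")
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  score <- switch(strategy,
                  random = NULL,
                  degree = igraph::degree(g),
                  betweenness = igraph::betweenness(g))
  set.seed(seed)
  stat <- matrix(NA_real_, n_repetitions, length(fractions))
  for (rep_i in seq_len(n_repetitions)) {
    order_i <- if (is.null(score)) sample.int(N)
               else order(score + stats::runif(N), decreasing = TRUE)
    for (fi in seq_along(fractions)) {
      nrm <- floor(fractions[fi] * N)
      keep <- if (nrm) order_i[-seq_len(nrm)] else seq_len(N)
      if (!length(keep)) { stat[rep_i, fi] <- 0; next }
      deg <- rowSums(A[keep, keep, drop = FALSE])
      stat[rep_i, fi] <- mean(deg > 0)
    }
  }
  curve <- data.frame(fraction = fractions,
                      mean = colMeans(stat),
                      sd = apply(stat, 2, stats::sd))
  half <- which.min(abs(fractions - 0.5))
  structure(list(curve = curve, at_half = curve$mean[half],
                 strategy = strategy,
                 n_repetitions = as.integer(n_repetitions), seed = seed),
            class = "robustness_curve")
}

#' Global efficiency of a network
#'
#' Mean over unordered node pairs of the inverse unweighted shortest-path
#' length, with disconnected pairs contributing 0; computed on the full
#' node set.
#'
#' @param net `co_network` or `igraph`.
#' @return scalar in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  g <- .as_igraph(net)
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  d <- igraph::distances(g)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

#' Network vulnerability
#'
#' The maximal relative drop in global efficiency caused by deleting a
#' single node: \eqn{\max_i (E - E_i) / E}, where \eqn{E_i} is the
#' efficiency of the network with node \eqn{i} removed.
#'
#' @param net `co_network` or `igraph`.
#' @return list with `vulnerability` (scalar in `[0, 1]`), `node` (the
#'   most critical node's name), `efficiency` (the intact network's E).
#' @export
vulnerability <- function(net) {
  g <- .as_igraph(net)
  n <- igraph::vcount(g)
  if (n < 3L) stop("vulnerability needs at least 3 nodes")
  E0 <- global_efficiency(g)
  if (E0 == 0) stop("vulnerability undefined on an edgeless network")
  drops <- vapply(seq_len(n), function(i) {
    (E0 - global_efficiency(igraph::delete_vertices(g, i))) / E0
  }, numeric(1))
  best <- which.max(drops)
  nm <- igraph::V(g)$name
  list(vulnerability = drops[best],
       node = if (!is.null(nm)) nm[best] else as.character(best),
       efficiency = E0)
}

#' Network complexity (linkage density)
#'
#' Average degree `2E / N`, the standard complexity proxy for ecological
#' co-occurrence networks; identical to the `average_degree` column of
#' [topology()].
#'
#' @param net `co_network` or `igraph`.
#' @return scalar.
#' @export
complexity <- function(net) {
  g <- .as_igraph(net)
  if (igraph::vcount(g) == 0L) stop("complexity: empty network")
  2 * igraph::ecount(g) / igraph::vcount(g)
}
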