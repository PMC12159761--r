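# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and igraph where feasible) so that agreement is evidence,
# not tautology.

# Spearman rho by explicit mid-ranking followed by a hand-written Pearson.
oracle_spearman_pair <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

oracle_spearman_matrix <- function(counts) {
  nt <- nrow(counts)
  rho <- matrix(NA_real_, nt, nt, dimnames = dimnames(counts)[c(1, 1)])
  for (i in seq_len(nt)) for (j in seq_len(nt))
    rho[i, j] <- oracle_spearman_pair(counts[i, ], counts[j, ])
  rho
}

# Edge set by a double loop over pairs with per-pair cor.test-style p values
# (t approximation) and BH over the tested pairs.
oracle_edge_set <- function(counts, rho_min, alpha) {
  nt <- nrow(counts); n <- ncol(counts)
  pairs <- t(utils::combn(nt, 2))
  rho <- apply(pairs, 1, function(ij)
    oracle_spearman_pair(counts[ij[1], ], counts[ij[2], ]))
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  padj <- stats::p.adjust(p, "BH")
  keep <- abs(rho) > rho_min & padj < alpha
  if (!any(keep)) return(character(0))
  taxa <- rownames(counts)
  sort(paste(taxa[pairs[keep, 1]], taxa[pairs[keep, 2]], sep = "|"))
}

# All-pairs shortest hop counts by Floyd-Warshall on an adjacency matrix.
oracle_shortest_paths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_global_efficiency <- function(A) {
  D <- oracle_shortest_paths(A)
  inv <- 1 / D[upper.tri(D)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

oracle_vulnerability <- function(A) {
  E0 <- oracle_global_efficiency(A)
  drops <- sapply(seq_len(nrow(A)), function(i)
    (E0 - oracle_global_efficiency(A[-i, -i, drop = FALSE])) / E0)
  max(drops)
}

# Cohesion (null_model = "none") as a literal transcription:
# correlate -> average by sign -> weight by relative abundance.
oracle_cohesion_none <- function(counts) {
  rel <- apply(counts, 2, function(x) x / sum(x))
  nt <- nrow(rel)
  r <- matrix(NA_real_, nt, nt)
  for (i in seq_len(nt)) for (j in seq_len(nt))
    if (i != j) r[i, j] <- stats::cor(rel[i, ], rel[j, ])
  conn_pos <- conn_neg <- numeric(nt)
  for (i in seq_len(nt)) {
    v <- r[i, ][-i]
    conn_pos[i] <- if (any(v > 0)) mean(v[v > 0]) else 0
    conn_neg[i] <- if (any(v < 0)) mean(v[v < 0]) else 0
  }
  pos <- neg <- numeric(ncol(rel))
  for (s in seq_len(ncol(rel))) {
    pos[s] <- sum(rel[, s] * conn_pos)
    neg[s] <- sum(rel[, s] * conn_neg)
  }
  list(pos = pos, neg = neg, conn_pos = conn_pos, conn_neg = conn_neg)
}

oracle_shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  acc <- 0
  for (pi in p) acc <- acc - pi * log(pi)
  acc
}

# small deterministic random count table
random_table <- function(n_taxa, n_samples, seed = 1, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
              dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                              sprintf("s%02d", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  m
}

# igraph from an adjacency matrix, with the edge attributes build_network sets
graph_from_adj <- function(A, rho = 0.9) {
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
  igraph::E(g)$rho <- rho
  igraph::E(g)$p_adj <- 0.01
  igraph::E(g)$sign <- ifelse(rho > 0, "+", "-")
  g
}

# demo fixture config with absolute paths, staged into a temp dir
demo_config <- function(tmp = withr::local_tempdir(.local_envir = parent.frame())) {
  src <- system.file("extdata", package = "micronetstab")
  files <- c("synthetic_demo_table.tsv", "synthetic_demo_metadata.tsv",
             "synthetic_demo_tree.nwk", "demo_plspm.yml")
  file.copy(file.path(src, files), tmp)
  list(table = file.path(tmp, files[1]),
       metadata = file.path(tmp, files[2]),
       tree = file.path(tmp, files[3]),
       plspm_spec = file.path(tmp, files[4]),
       out_dir = file.path(tmp, "out"),
       n_permutations = 99L, n_null = 30L, n_repetitions = 20L,
       seed = 7L)
}
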