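#' Rarefy a count table to even depth
#'
#' Subsamples each sample's counts without replacement (multivariate
#' hypergeometric, via [vegan::rrarefy()]) so every column sums exactly to
#' `depth`. A single draw per sample is taken under the recorded seed;
#' `iterations > 1` is available to downstream index averaging via
#' [alpha_diversity()].
#'
#' @param counts taxa x samples count matrix.
#' @param depth target depth; must not exceed the smallest library unless
#'   `drop_small = TRUE`.
#' @param seed RNG seed for the subsample.
#' @param drop_small drop samples shallower than `depth` (with a warning)
#'   instead of erroring.
#' @return rarefied integer matrix, taxa x samples (possibly fewer samples).
#' @export
rarefy_counts <- function(counts, depth, seed = 1L, drop_small = FALSE) {
  counts <- validate_asv_table(counts)
  depth <- as.integer(depth)
  if (depth < 1L) stop("rarefaction depth must be positive")
  tot <- colSums(counts)
  if (any(tot < depth)) {
    shallow <- colnames(counts)[tot < depth]
    if (!drop_small)
      stop("samples shallower than depth ", depth, ": ",
           paste(shallow, collapse = ", "))
    warning(sprintf("dropping %d samples shallower than depth %d",
                    length(shallow), depth))
    counts <- counts[, tot >= depth, drop = FALSE]
    if (ncol(counts) < 2L) stop("fewer than 2 samples remain after depth filter")
  }
  set.seed(seed)
  # rrarefy's advisory "observed counts" warning fires on small fixtures
  rar <- withCallingHandlers(
    t(vegan::rrarefy(t(counts), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(rar) <- "integer"
  rar
}

#' Alpha diversity indices per sample
#'
#' Computes observed richness, bias-corrected Chao1
#' \eqn{S_{obs} + F_1(F_1 - 1) / (2 (F_2 + 1))} from singleton/doubleton
#' counts, Shannon entropy (natural log), Simpson concentration
#' \eqn{\sum p_i^2}, inverse Simpson, and (when a tree is supplied)
#' Faith's phylogenetic diversity including the root path. All-zero
#' samples yield `NA` (diversity is undefined, not zero).
#'
#' @param counts taxa x samples count matrix (typically rarefied).
#' @param tree optional rooted `phylo` covering all table taxa (extra tips
#'   are pruned, see [match_tree()]).
#' @return `data.frame` with one row per sample: `sample_id`,
#'   `observed_taxa`, `chao1`, `shannon`, `simpson`, `inv_simpson`, and
#'   `faith_pd` if a tree was given.
#' @export
alpha_diversity <- function(counts, tree = NULL) {
  counts <- validate_asv_table(counts)
  tot <- colSums(counts)
  if (any(tot == 0))
    warning("all-zero samples present; their indices are NA: ",
            paste(colnames(counts)[tot == 0], collapse = ", "))

  s_obs <- colSums(counts > 0)
  f1 <- colSums(counts == 1L)
  f2 <- colSums(counts == 2L)
  chao1 <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))

  comm <- t(counts)  # vegan convention: samples x taxa
  shannon <- vegan::diversity(comm, index = "shannon")
  simpson <- 1 - vegan::diversity(comm, index = "simpson")  # sum p^2
  inv_simpson <- vegan::diversity(comm, index = "invsimpson")

  out <- data.frame(sample_id = colnames(counts),
                    observed_taxa = as.integer(s_obs),
                    chao1 = chao1, shannon = shannon,
                    simpson = simpson, inv_simpson = inv_simpson,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    tree <- match_tree(tree, rownames(counts))
    pd <- picante::pd(comm, tree, include.root = TRUE)
    out$faith_pd <- pd$PD[match(out$sample_id, rownames(pd))]
  }
  empty <- tot == 0
  out[empty, setdiff(names(out), c("sample_id", "observed_taxa"))] <- NA_real_
  out
}

#' Bray-Curtis dissimilarity matrix between samples
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, computed on
#' counts (conventionally after rarefaction).
#'
#' @param counts taxa x samples count matrix.
#' @return a `dist` object over samples.
#' @export
bray_curtis <- function(counts) {
  counts <- validate_asv_table(counts)
  if (sum(colSums(counts) == 0) >= 2L)
    stop("Bray-Curtis undefined between two all-zero samples")
  vegan::vegdist(t(counts), method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: Gower double-centering of \eqn{-D^2/2},
#' eigendecomposition, coordinates scaled by the square root of each
#' positive eigenvalue. `proportion_explained` divides by the sum of
#' positive eigenvalues only; negative eigenvalues (non-Euclidean input)
#' are reported but excluded. A Cailliez additive correction is available
#' for strongly non-Euclidean matrices.
#'
#' @param dm `dist` or square symmetric matrix of distances.
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return object of class `pcoa_result`: list with `points` (samples x
#'   axes), `eigenvalues` (all, decreasing), `proportion_explained`
#'   (positive axes), `correction`.
#' @export
pcoa <- function(dm, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  D <- as.matrix(dm)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8))
    stop("pcoa requires a square symmetric distance matrix")
  if (any(diag(D) != 0)) stop("pcoa requires a zero diagonal")
  n <- nrow(D)
  if (correction == "cailliez") D <- .cailliez(D)

  center <- function(M) {
    rm <- rowMeans(M); cm <- colMeans(M); gm <- mean(M)
    M - outer(rm, rep(1, n)) - outer(rep(1, n), cm) + gm
  }
  B <- center(-0.5 * D^2)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  vals <- e$values
  tol <- 1e-9 * max(abs(vals), 1)
  pos <- vals > tol
  pts <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(vals[pos]), sum(pos))
  rownames(pts) <- rownames(D)
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  structure(list(points = pts,
                 eigenvalues = vals,
                 proportion_explained = vals[pos] / sum(vals[pos]),
                 correction = correction),
            class = "pcoa_result")
}

# Cailliez constant: largest real eigenvalue of the 2n x 2n companion
# matrix of delta_1 (centered -D^2/2) and delta_2 (centered -D/2);
# added to all off-diagonal distances.
.cailliez <- function(D) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  d1 <- J %*% (-0.5 * D^2) %*% J
  d2 <- J %*% (-0.5 * D) %*% J
  M <- rbind(cbind(matrix(0, n, n), 2 * d1),
             cbind(-diag(n), -4 * d2))
  ev <- eigen(M, only.values = TRUE)$values
  cc <- max(Re(ev[abs(Im(ev)) < 1e-8]))
  Dc <- D + cc
  diag(Dc) <- 0
  Dc
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA on a distance matrix: the total sum of squares is
#' \eqn{\sum_{i<j} d_{ij}^2 / N}, the within-group sum of squares pools
#' \eqn{\sum_{i<j \in g} d_{ij}^2 / n_g}, and the pseudo-F statistic is
#' \eqn{(SS_B / (k-1)) / (SS_W / (N-k))}. Significance comes from
#' permuting group labels across samples; the p-value uses the
#' \eqn{(1 + \#\{F^* \ge F\}) / (1 + n_{perm})} convention and so never
#' returns 0.
#'
#' @param dm `dist` or square symmetric distance matrix.
#' @param groups factor (or coercible) of group labels, in sample order.
#' @param n_permutations number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return object of class `permanova_result`: list with `pseudo_F`, `R2`,
#'   `p_value`, `ss_total`, `ss_between`, `ss_within`, `df`,
#'   `n_permutations`, `seed`.
#' @export
permanova <- function(dm, groups, n_permutations = 999, seed = 1L) {
  D2 <- as.matrix(dm)^2
  N <- nrow(D2)
  groups <- factor(groups)
  if (length(groups) != N) stop("groups length must match the distance matrix")
  k <- nlevels(groups)
  if (k < 2L) stop("PERMANOVA needs at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 samples")

  ss_within_for <- function(lab) {
    sw <- 0
    for (lev in levels(lab)) {
      idx <- which(lab == lev)
      sw <- sw + sum(D2[idx, idx]) / (2 * length(idx))
    }
    sw
  }
  ss_total <- sum(D2[upper.tri(D2)]) / N
  ss_within <- ss_within_for(groups)
  ss_between <- ss_total - ss_within
  f_from_sw <- function(sw) ((ss_total - sw) / (k - 1)) / (sw / (N - k))
  f_obs <- f_from_sw(ss_within)

  set.seed(seed)
  exceed <- 0L
  for (p in seq_len(n_permutations)) {
    perm <- groups[sample.int(N)]
    if (f_from_sw(ss_within_for(perm)) >= f_obs) exceed <- exceed + 1L
  }
  structure(list(pseudo_F = f_obs,
                 R2 = ss_between / ss_total,
                 p_value = (1 + exceed) / (1 + n_permutations),
                 ss_total = ss_total, ss_between = ss_between,
                 ss_within = ss_within,
                 df = c(between = k - 1L, within = N - k),
                 n_permutations = n_permutations, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g (df %d, %d), R2 = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$df[1], x$df[2], x$R2, x$p_value, x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA between all group pairs
#'
#' Runs [permanova()] on every pair of group levels (deterministic order:
#' level order of `groups`) and Benjamini-Hochberg adjusts the p-values.
#'
#' @inheritParams permanova
#' @return `data.frame` with one row per pair: `group1`, `group2`,
#'   `pseudo_F`, `R2`, `p_value`, `p_adj`.
#' @export
pairwise_permanova <- function(dm, groups, n_permutations = 999, seed = 1L) {
  D <- as.matrix(dm)
  groups <- factor(groups)
  levs <- levels(groups)
  if (length(levs) < 2L) stop("need at least 2 groups")
  pairs <- utils::combn(levs, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    sel <- groups %in% pairs[, i]
    r <- permanova(D[sel, sel], droplevels(groups[sel]),
                   n_permutations = n_permutations, seed = seed + i)
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               pseudo_F = r$pseudo_F, R2 = r$R2, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}
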