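test_that("cohesion with no null model matches hand computation", {
  # a and b keep proportional relative abundances (r = 1) while c moves
  # against them: connectedness+ = 1 for the pair and cohesion+(s) equals
  # the pair's total relative abundance
  tab3 <- matrix(c(1L, 2L, 10L, 2L, 4L, 5L, 4L, 8L, 1L), 3,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  coh <- cohesion(tab3, null_model = "none")
  rel3 <- sweep(tab3, 2, colSums(tab3), "/")
  expect_equal(coh$taxa$connectedness_pos[1:2], c(1, 1), tolerance = 1e-12)
  expect_equal(coh$taxa$connectedness_pos[3], 0)
  expect_equal(coh$samples$positive_cohesion,
               unname(colSums(rel3[c("a", "b"), ])), tolerance = 1e-12)
  expect_true(all(coh$taxa$connectedness_neg <= 0))

  # 6-taxon worked table against a literal-transcription oracle
  tab <- random_table(6, 8, seed = 21)
  coh6 <- cohesion(tab, null_model = "none")
  o <- oracle_cohesion_none(tab)
  expect_equal(coh6$samples$positive_cohesion, o$pos, tolerance = 1e-10)
  expect_equal(coh6$samples$negative_cohesion, o$neg, tolerance = 1e-10)
  expect_equal(coh6$taxa$connectedness_pos, o$conn_pos, tolerance = 1e-10)
  expect_equal(coh6$taxa$connectedness_neg, o$conn_neg, tolerance = 1e-10)
  expect_true(all(abs(coh6$taxa$connectedness_pos) <= 1))
  expect_true(all(coh6$samples$positive_cohesion >= 0))
  expect_true(all(coh6$samples$negative_cohesion <= 0))
})

test_that("cohesion is equivariant under taxon relabeling", {
  tab <- random_table(8, 10, seed = 3)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  a <- cohesion(tab, "none")
  b <- cohesion(tab[perm, ], "none")
  expect_equal(b$samples$positive_cohesion, a$samples$positive_cohesion,
               tolerance = 1e-12)
  expect_equal(b$taxa$connectedness_pos[order(b$taxa$taxon_id)],
               a$taxa$connectedness_pos[order(a$taxa$taxon_id)],
               tolerance = 1e-12)
})

test_that("null-corrected cohesion shrinks toward zero for independent taxa", {
  # independent taxa: corrected correlations are centred noise, so cohesion
  # magnitude decreases with sample count and stays within the noise scale
  mean_coh <- function(ns, seed) {
    set.seed(seed)
    tab <- matrix(rpois(12 * ns, 30), 12,
                  dimnames = list(sprintf("t%02d", 1:12),
                                  sprintf("s%02d", seq_len(ns))))
    coh <- cohesion(tab, "taxa_shuffle", n_null = 50, seed = seed)
    mean(coh$samples$positive_cohesion)
  }
  small <- vapply(1:8, function(s) mean_coh(10, s), numeric(1))
  large <- vapply(1:8, function(s) mean_coh(80, s), numeric(1))
  expect_lt(mean(large), mean(small))
  # noise scale of a Pearson r at n samples is ~ 1/sqrt(n - 1)
  expect_lt(mean(large), 2 / sqrt(79))
  expect_error(cohesion(random_table(5, 8), "taxa_shuffle", n_null = 5),
               "n_null")
})

test_that("constant relative-abundance taxa are excluded with a warning", {
  # equal library sizes make taxon d's relative abundance exactly constant
  set.seed(5)
  rest <- sapply(1:6, function(i) as.vector(stats::rmultinom(1, 75, rep(1, 3))))
  tab <- rbind(rest, d = 25L)
  rownames(tab) <- c("a", "b", "c", "d")
  colnames(tab) <- paste0("s", 1:6)
  storage.mode(tab) <- "integer"
  expect_warning(coh <- cohesion(tab, "none"), "constant")
  expect_false("d" %in% coh$taxa$taxon_id)
})

test_that("stability ratio divides |negative| by positive cohesion", {
  coh <- structure(list(samples = data.frame(
    sample_id = c("s1", "s2", "s3"),
    positive_cohesion = c(0.4, 0.5, 0),
    negative_cohesion = c(-0.2, 0, -0.1))), class = "cohesion_result")
  sr <- stability_ratio(coh)
  expect_equal(sr$samples$ratio, c(0.5, 0, NA))
  expect_equal(sr$mean, 0.25)

  # invariant to rescaling any sample's absolute abundances
  tab <- random_table(6, 9, seed = 6)
  scaled <- tab
  scaled[, 2] <- scaled[, 2] * 7L
  r1 <- stability_ratio(cohesion(tab, "none"))
  r2 <- stability_ratio(cohesion(scaled, "none"))
  expect_equal(r1$samples$ratio, r2$samples$ratio, tolerance = 1e-12)
})

test_that("robustness forced cases and curve invariants hold", {
  K10 <- matrix(1, 10, 10, dimnames = list(letters[1:10], letters[1:10]))
  diag(K10) <- 0
  rb <- robustness(graph_from_adj(K10), "random", fractions = c(0, 0.5),
                   n_repetitions = 20, seed = 1)
  expect_equal(rb$curve$mean, c(1, 1))  # survivors of K10 always keep edges

  # star: targeted removal of the hub disconnects every leaf
  star <- matrix(0, 11, 11,
                 dimnames = list(c("hub", paste0("l", 1:10)),
                                 c("hub", paste0("l", 1:10))))
  star["hub", -1] <- 1; star[-1, "hub"] <- 1
  rb2 <- robustness(graph_from_adj(star), "degree",
                    fractions = 1 / 11, n_repetitions = 5, seed = 1)
  expect_equal(rb2$curve$mean, 0)

  set.seed(30)
  A <- matrix(rbinom(40 * 40, 1, 0.1), 40)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]; diag(A) <- 0
  dimnames(A) <- list(sprintf("n%02d", 1:40), sprintf("n%02d", 1:40))
  g <- graph_from_adj(A)
  rb3 <- robustness(g, "random", n_repetitions = 60, seed = 2)
  expect_equal(rb3$curve$mean[1], 1)                  # f = 0
  expect_true(all(diff(rb3$curve$mean) <= 0.05))      # non-increasing in expectation

  # independent re-simulation oracle at f = 0.5
  set.seed(99)
  oracle <- replicate(400, {
    keep <- sample(40, 40 - floor(0.5 * 40))
    mean(rowSums(A[keep, keep]) > 0)
  })
  idx <- which(rb3$curve$fraction == 0.5)
  expect_lt(abs(rb3$curve$mean[idx] - mean(oracle)), 2 * sd(oracle))
})

test_that("targeted removal degrades connectivity at least as fast as random", {
  set.seed(14)
  # scale-free-ish graph
  g <- igraph::sample_pa(60, m = 2, directed = FALSE)
  igraph::V(g)$name <- paste0("v", 1:60)
  igraph::E(g)$rho <- 0.9; igraph::E(g)$p_adj <- 0.01; igraph::E(g)$sign <- "+"
  rr <- robustness(g, "random", n_repetitions = 60, seed = 5)
  rt <- robustness(g, "degree", n_repetitions = 60, seed = 5)
  mid <- rr$curve$fraction >= 0.2 & rr$curve$fraction <= 0.8
  expect_true(all(rt$curve$mean[mid] <= rr$curve$mean[mid] + 0.05))
})

test_that("vulnerability and efficiency match forced cases and brute force", {
  tri <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(tri) <- 0
  v <- vulnerability(graph_from_adj(tri))
  expect_equal(v$vulnerability, 0)
  expect_equal(v$efficiency, 1)

  path <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  path["a", "b"] <- path["b", "a"] <- path["b", "c"] <- path["c", "b"] <- 1
  vp <- vulnerability(graph_from_adj(path))
  expect_equal(vp$efficiency, 5 / 6)
  expect_equal(vp$vulnerability, 1)
  expect_identical(vp$node, "b")

  set.seed(31)
  A <- matrix(rbinom(15 * 15, 1, 0.25), 15)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]; diag(A) <- 0
  dimnames(A) <- list(sprintf("n%02d", 1:15), sprintf("n%02d", 1:15))
  g <- graph_from_adj(A)
  expect_equal(global_efficiency(g), oracle_global_efficiency(A),
               tolerance = 1e-12)
  expect_equal(vulnerability(g)$vulnerability, oracle_vulnerability(A),
               tolerance = 1e-12)
})

test_that("complexity is the average degree", {
  K4 <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(K4) <- 0
  expect_equal(complexity(graph_from_adj(K4)), 3)
  edge <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(complexity(graph_from_adj(edge)), 1)
  tab <- random_table(15, 10, seed = 17)
  net <- build_network(spearman_matrix(tab), rho_min = 0.3, alpha = 0.9)
  expect_equal(complexity(net), topology(net)$average_degree)
})
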