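test_that("rarefaction gives exact column sums and is seed-reproducible", {
  tab <- random_table(30, 6, seed = 1, lambda = 100)
  depth <- min(colSums(tab)) - 10L
  r1 <- rarefy_counts(tab, depth, seed = 42)
  r2 <- rarefy_counts(tab, depth, seed = 42)
  expect_identical(r1, r2)
  expect_true(all(colSums(r1) == depth))
  expect_true(all(r1 <= tab))

  # depth equal to a library leaves that sample unchanged
  expect_identical(rarefy_counts(tab, min(colSums(tab)), seed = 1)[, which.min(colSums(tab))],
                   tab[, which.min(colSums(tab))])

  # forced outcome on a single-support sample
  one <- matrix(c(10L, 0L, 0L, 10L, 0L, 0L), 3,
                dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_identical(rarefy_counts(one, 5, seed = 1)[, 1],
                   c(a = 5L, b = 0L, c = 0L))
  expect_error(rarefy_counts(tab, max(colSums(tab)) + 1L), "shallower")
  expect_warning(r3 <- rarefy_counts(tab, sort(colSums(tab))[2],
                                     drop_small = TRUE), "dropping")
  expect_identical(ncol(r3), ncol(tab) - 1L)
})

test_that("rarefaction subsampling matches the hypergeometric expectation", {
  tab <- matrix(c(5L, 5L, 5L, 5L), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  draws <- vapply(1:3000, function(s) rarefy_counts(tab, 4, seed = s)[1, 1],
                  integer(1))
  # E = 2, SE of the mean from hypergeometric variance 2/3
  se <- sqrt(4 * 0.5 * 0.5 * (10 - 4) / (10 - 1)) / sqrt(3000)
  expect_lt(abs(mean(draws) - 2), 3 * se)
})

test_that("alpha diversity matches closed forms and a loop oracle", {
  uni <- matrix(c(5L, 5L, 5L, 5L, 2L, 0L, 1L, 1L), 4,
                dimnames = list(letters[1:4], c("u", "v")))
  a <- alpha_diversity(uni)
  expect_equal(a$shannon[1], log(4), tolerance = 1e-12)
  expect_equal(a$inv_simpson[1], 4, tolerance = 1e-12)
  expect_equal(a$simpson[1], 0.25, tolerance = 1e-12)

  # chao1 on S_obs = 5, F1 = 2, F2 = 1
  ch <- matrix(c(1L, 1L, 2L, 3L, 4L, 0L, rep(1L, 6)), 6,
               dimnames = list(letters[1:6], c("x", "y")))
  expect_equal(alpha_diversity(ch)$chao1[1], 5.5)

  tab <- random_table(20, 5, seed = 7)
  a2 <- alpha_diversity(tab)
  for (s in seq_len(ncol(tab)))
    expect_equal(a2$shannon[s], oracle_shannon(tab[, s]), tolerance = 1e-12)
  expect_true(all(a2$chao1 >= a2$observed_taxa))
  expect_true(all(a2$inv_simpson >= 1 & a2$inv_simpson <= a2$observed_taxa))
})

test_that("all-zero samples yield NA diversity, not zero", {
  tab <- matrix(c(3L, 2L, 0L, 0L), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_warning(a <- alpha_diversity(tab), "all-zero")
  expect_true(is.na(a$shannon[2]))
  expect_false(is.na(a$shannon[1]))
})

test_that("Shannon is maximal at the uniform composition", {
  set.seed(10)
  base <- rep(50L, 8)
  uni_h <- oracle_shannon(base)
  for (i in 1:20) {
    pert <- as.integer(pmax(base + sample(c(-20, 20), 8, TRUE) *
                              rbinom(8, 1, 0.5), 1))
    if (all(pert == pert[1])) next
    expect_lt(oracle_shannon(pert), uni_h)
  }
  tab <- cbind(u = base, v = base + c(-20L, 20L, rep(0L, 6)))
  rownames(tab) <- letters[1:8]
  a <- alpha_diversity(tab)
  expect_gt(a$shannon[1], a$shannon[2])
})

test_that("Faith PD uses the rooted subtree branch length", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  tab <- matrix(c(1L, 1L, 0L, 0L, 1L, 1L, 1L, 1L), 4,
                dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  a <- alpha_diversity(tab, tr)
  expect_equal(a$faith_pd[2], 6)      # whole tree
  expect_equal(a$faith_pd[1], 3)      # A+B clade plus root path
})

test_that("Bray-Curtis matches its closed form and bounds", {
  x <- matrix(c(1L, 1L, 1L, 3L), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(as.vector(bray_curtis(x)), 1 / 3)
  same <- matrix(c(2L, 3L, 2L, 3L), 2, dimnames = list(c("a", "b"), c("p", "q")))
  expect_equal(as.vector(bray_curtis(same)), 0)
  disj <- matrix(c(4L, 0L, 0L, 7L), 2, dimnames = list(c("a", "b"), c("p", "q")))
  expect_equal(as.vector(bray_curtis(disj)), 1)
  tab <- random_table(15, 8, seed = 3)
  d <- as.vector(bray_curtis(tab))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("PCoA reproduces Euclidean geometry", {
  # two samples at distance d: one axis, coordinates +/- d/2
  d <- 0.8
  D <- matrix(c(0, d, d, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord <- pcoa(D)
  expect_identical(ncol(ord$points), 1L)
  expect_equal(unname(sort(ord$points[, 1])), c(-d / 2, d / 2),
               tolerance = 1e-12)

  # planar points: pairwise coordinate distances reproduce D
  pts <- matrix(c(0, 0, 3, 0, 0, 4), ncol = 2, byrow = TRUE)
  D3 <- as.matrix(stats::dist(pts))
  ord3 <- pcoa(D3)
  expect_equal(as.matrix(stats::dist(ord3$points)), D3,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(ord3$eigenvalues > -1e-9))

  set.seed(5)
  Dr <- as.matrix(stats::dist(matrix(rnorm(40), 10)))
  pr <- pcoa(Dr)$proportion_explained
  expect_true(all(diff(pr) <= 1e-12))
  expect_lte(sum(pr), 1 + 1e-12)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PCoA agrees with an independent implementation", {
  set.seed(8)
  tab <- random_table(25, 9, seed = 8)
  D <- bray_curtis(tab)
  mine <- pcoa(D)
  ref <- ape::pcoa(D)
  k <- min(ncol(mine$points), ncol(ref$vectors))
  for (ax in seq_len(k))
    expect_equal(abs(mine$points[, ax]), abs(ref$vectors[, ax]),
                 tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("PERMANOVA partitions variance consistently and bounds p", {
  set.seed(2)
  tab <- random_table(20, 12, seed = 2)
  D <- bray_curtis(tab)
  grp <- rep(c("A", "B", "C"), each = 4)
  r <- permanova(D, grp, n_permutations = 199, seed = 1)
  expect_equal(r$R2 + r$ss_within / r$ss_total, 1, tolerance = 1e-12)
  expect_gte(r$p_value, 1 / 200)

  # perfectly separated clusters: only label permutations that reproduce the
  # same partition tie the observed F, so p approaches the partition
  # probability 2 * 4!4! / 8! ~ 0.029 and can never beat it
  pts <- c(rnorm(4), 100 + rnorm(4))
  D2 <- as.matrix(stats::dist(pts))
  r2 <- permanova(D2, rep(c("lo", "hi"), each = 4),
                  n_permutations = 999, seed = 3)
  expect_gte(r2$p_value, 1 / 1000)
  expect_lte(r2$p_value, 0.05)
  expect_error(permanova(D2, c("a", rep("b", 7))), "at least 2 samples")
})

test_that("PERMANOVA agrees with vegan's adonis2 on F and R2", {
  tab <- random_table(30, 15, seed = 6)
  D <- bray_curtis(tab)
  grp <- factor(rep(c("A", "B", "C"), each = 5))
  mine <- permanova(D, grp, n_permutations = 99, seed = 1)
  ref <- vegan::adonis2(D ~ grp, permutations = 99)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)
})

test_that("pairwise PERMANOVA covers all pairs with BH adjustment", {
  tab <- random_table(20, 12, seed = 9)
  D <- bray_curtis(tab)
  grp <- rep(c("CK", "M", "bioM"), each = 4)
  pw <- pairwise_permanova(D, grp, n_permutations = 99, seed = 1)
  expect_identical(nrow(pw), 3L)
  expect_identical(pw$group1, c("CK", "CK", "M"))
  expect_identical(pw$group2, c("M", "bioM", "bioM"))
  expect_true(all(pw$p_adj >= pw$p_value))
  pw2 <- pairwise_permanova(D, grp, n_permutations = 99, seed = 1)
  expect_identical(pw, pw2)
})
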