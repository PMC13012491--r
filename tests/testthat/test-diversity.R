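test_that("alpha diversity matches hand-computed and closed-form values", {
  u <- alpha_diversity(c(10, 10, 10, 10))
  expect_equal(u$observed_richness, 4)
  expect_equal(u$shannon, log(4))
  expect_equal(u$chao1, 4) # no singletons

  h <- alpha_diversity(c(1, 1, 2, 5, 9)) # F1=2, F2=1
  expect_equal(h$observed_richness, 5)
  expect_equal(h$chao1, 5 + 2 * 1 / (2 * 2))

  expect_equal(alpha_diversity(c(0, 7, 0))$shannon, 0)
  expect_error(alpha_diversity(c(0, 0)), "all-zero")

  # invariants: chao1 >= richness, shannon <= ln(richness), permutation-safe
  set.seed(2)
  for (i in 1:10) {
    x <- rpois(30, 3)
    if (sum(x) == 0) next
    a <- alpha_diversity(x)
    expect_gte(a$chao1, a$observed_richness)
    expect_lte(a$shannon, log(a$observed_richness) + 1e-12)
    expect_equal(alpha_diversity(sample(x))$shannon, a$shannon)
  }
})

test_that("alpha diversity agrees with the vegan oracle on random tables", {
  skip_if_not_installed("vegan")
  ct <- rand_ct(40, 6, seed = 9, lambda = 8)
  tab <- alpha_diversity_table(ct)
  expect_equal(tab$shannon,
               unname(vegan::diversity(t(ct$counts), index = "shannon")))
  chao_vegan <- t(vegan::estimateR(t(ct$counts)))[, "S.chao1"]
  expect_equal(tab$chao1, unname(chao_vegan), tolerance = 1e-8)
})

test_that("Dunn letters separate a shifted group and only that group", {
  set.seed(31)
  # five groups, one shifted far away: it alone gets its own letter
  vals <- c(rnorm(40), rnorm(10, 10))
  grp <- c(rep(c("f1", "f2", "f3", "f5"), each = 10), rep("f4", 10))
  kd <- kruskal_dunn(vals, grp)
  expect_lt(kd$kw$p.value, 0.05)
  letters4 <- kd$letters["f4"]
  others <- kd$letters[setdiff(names(kd$letters), "f4")]
  expect_false(any(grepl(letters4, others, fixed = TRUE)))
  expect_identical(length(unique(others)), 1L)
})

test_that("identical groups share letters and adjusted p of 1", {
  x <- c(3, 1, 4, 1, 5)
  kd <- kruskal_dunn(c(x, x), rep(c("a", "b"), each = 5))
  expect_equal(kd$pairwise$p_adj, 1)
  expect_identical(unname(kd$letters["a"]), unname(kd$letters["b"]))
  expect_error(kruskal_dunn(1:5, c("a", "a", "b", "b", "c")), "< 2 obs")
})

test_that("null Dunn letters stay unified in at least 95% of replicates", {
  set.seed(17)
  unified <- replicate(1000, {
    kd <- kruskal_dunn(rnorm(50), rep(paste0("g", 1:5), each = 10))
    length(unique(kd$letters)) == 1
  })
  expect_gte(mean(unified), 0.95)
})

test_that("Bray-Curtis matches hand values, its invariants, and vegan", {
  # identical samples -> 0; disjoint supports -> 1
  m <- matrix(c(5, 3, 5, 3), 2, 2)
  expect_equal(bray_curtis(make_ct(m))[1, 2], 0)
  m2 <- matrix(c(4, 0, 0, 7), 2, 2)
  expect_equal(bray_curtis(make_ct(m2))[1, 2], 1)
  # hand evaluation on proportions: a=(1,1,0), b=(0,1,1) -> 1/2
  m3 <- matrix(c(1, 1, 0, 0, 1, 1), 3, 2)
  expect_equal(bray_curtis(make_ct(m3))[1, 2], 0.5)

  ct <- rand_ct(30, 8, seed = 5)
  d <- bray_curtis(ct)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))

  # brute-force pairwise loop oracle + vegan cross-check
  rel <- sweep(ct$counts, 2, colSums(ct$counts), "/")
  for (pair in list(c(1, 2), c(3, 7), c(5, 8))) {
    manual <- sum(abs(rel[, pair[1]] - rel[, pair[2]])) /
      sum(rel[, pair[1]] + rel[, pair[2]])
    expect_equal(d[pair[1], pair[2]], manual)
  }
  skip_if_not_installed("vegan")
  expect_equal(unname(d),
               unname(as.matrix(vegan::vegdist(t(rel), "bray"))),
               tolerance = 1e-12)

  bad <- make_ct(matrix(c(1, 0, 2, 0), 2, 2))
  bad$counts[, 2] <- 0L
  expect_error(bray_curtis(bad), "all-zero sample")
})

test_that("PERMANOVA matches the vegan oracle and handles degenerate input", {
  skip_if_not_installed("vegan")
  ct <- rand_ct(30, 12, seed = 8)
  g <- rep(c("a", "b", "c"), each = 4)
  d <- bray_curtis(ct)
  pm <- permanova(d, g, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(pm$pseudo_F, ref$F[1], tolerance = 1e-8)
  expect_equal(pm$R2, ref$R2[1], tolerance = 1e-8)

  # all pairwise distances equal: every permutation ties, p = 1
  deq <- matrix(0.7, 6, 6); diag(deq) <- 0
  pmd <- permanova(deq, rep(c("a", "b"), 3), n_perm = 49, seed = 1)
  expect_equal(pmd$p_value, 1)

  expect_error(permanova(deq, rep("a", 6), n_perm = 9), ">= 2 levels")
})

test_that("separated clusters give the minimal attainable p at 999 perms", {
  # with 10+10 the chance a random permutation preserves the cluster
  # partition (and so ties F_obs) is ~1e-5: the minimal p is attainable
  set.seed(12)
  x <- rbind(matrix(rnorm(10 * 3, 0, 0.05), 10),
             matrix(rnorm(10 * 3, 10, 0.05), 10))
  d <- as.matrix(dist(x))
  pm <- permanova(d, rep(c("a", "b"), each = 10), n_perm = 999, seed = 2)
  expect_equal(pm$p_value, 1 / (999 + 1))
})

test_that("tied permutations are counted: 5+5 clusters match tie arithmetic", {
  # a random relabelling preserves the two-cluster partition with
  # probability 2 * 5! * 5! / 10! = 1/126; each such permutation ties the
  # observed F, so p exceeds 1/1000 by exactly the tie count
  set.seed(12)
  x <- rbind(matrix(rnorm(5 * 3, 0, 0.05), 5),
             matrix(rnorm(5 * 3, 10, 0.05), 5))
  d <- as.matrix(dist(x))
  g <- rep(c("a", "b"), each = 5)
  pm <- permanova(d, g, n_perm = 999, seed = 2)
  perms <- attr(pm, "permutations")
  cluster <- rep(1:2, each = 5)
  ties <- sum(apply(perms, 1, function(p) {
    all(tapply(cluster[p], g, function(z) length(unique(z))) == 1)
  }))
  expect_equal(pm$p_value, (1 + ties) / 1000)
  expect_lt(pm$p_value, 0.05)
})

test_that("PERMANOVA p is invariant under consistent sample relabelling", {
  ct <- rand_ct(25, 10, seed = 14)
  g <- rep(c("a", "b"), each = 5)
  d <- bray_curtis(ct)
  p1 <- permanova(d, g, n_perm = 199, seed = 5)
  perm <- sample(10)
  p2 <- permanova(d[perm, perm], g[perm], n_perm = 199, seed = 5)
  expect_equal(p1$pseudo_F, p2$pseudo_F, tolerance = 1e-10)
})

test_that("strata restrict permutations to within-block exchanges", {
  ct <- rand_ct(20, 12, seed = 3)
  d <- bray_curtis(ct)
  g <- rep(c("a", "b"), 6)
  blocks <- rep(c("f1", "f2", "f3"), each = 4)
  pm <- permanova(d, g, n_perm = 50, seed = 7, strata = blocks)
  perms <- attr(pm, "permutations")
  for (b in seq_len(nrow(perms))) {
    expect_identical(blocks[perms[b, ]], blocks)
  }
})

test_that("unconstrained CAP reduces to classical PCoA", {
  ct <- rand_ct(30, 9, seed = 4)
  d <- bray_curtis(ct)
  ord <- cap_ordination(d)
  expect_false(ord$constrained)
  expect_true(all(diff(ord$eigenvalues) <= 1e-12))
  ref <- cmdscale(as.dist(d), k = 5, eig = TRUE)
  k <- min(5, ncol(ord$scores))
  for (ax in seq_len(k)) { # axes match up to sign
    expect_equal(abs(cor(ord$scores[, ax], ref$points[, ax])), 1,
                 tolerance = 1e-6)
  }
})

test_that("a single binary constraint yields exactly one constrained axis", {
  ct <- rand_ct(30, 10, seed = 6)
  d <- bray_curtis(ct)
  ord <- cap_ordination(d, data.frame(g = rep(c("x", "y"), 5)))
  expect_true(ord$constrained)
  expect_identical(ncol(ord$scores), 1L)
})

test_that("CAP axis 1 tracks a planted community gradient", {
  set.seed(23)
  n <- 30; n_taxa <- 40
  grad <- seq(0, 1, length.out = n)
  base <- rnorm(n_taxa, 0, 1)
  slope <- rnorm(n_taxa, 0, 2)
  counts <- sapply(grad, function(z) {
    eta <- base + slope * z + rnorm(n_taxa, 0, 0.2)
    rmultinom(1, 8000, exp(eta) / sum(exp(eta)))
  })
  ct <- make_ct(counts)
  d <- bray_curtis(ct)
  ord <- cap_ordination(d, data.frame(grad = grad))
  rho <- cor(ord$scores[, 1], grad, method = "spearman")
  expect_gt(abs(rho), 0.9)
})
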