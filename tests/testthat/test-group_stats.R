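test_that("PERMANOVA p-value equals exhaustive enumeration on 6 samples", {
  set.seed(10)
  pts <- c(rnorm(3, 0), rnorm(3, 1.5))
  d <- dist(pts)
  labels <- rep(c("a", "b"), each = 3)
  fit <- adonis_test(d, labels, n_perm = 999)
  # brute force over all C(6,3) = 20 distinct assignments
  f_obs <- oracle_adonis_F(d, labels)
  f_all <- vapply(enumerate_two_groups(6, 3),
                  function(l) oracle_adonis_F(d, l), numeric(1))
  expect_equal(fit$statistic, f_obs, tolerance = 1e-10)
  expect_equal(fit$p_value, mean(f_all >= f_obs - 1e-12),
               tolerance = 1e-12)
})

test_that("PERMANOVA puts all variance between separated groups", {
  d <- dist(c(0, 0, 0, 5, 5, 5))
  fit <- adonis_test(d, rep(c("a", "b"), each = 3), n_perm = 999)
  expect_gt(fit$effect_r2, 0.999)
  expect_lte(fit$p_value, 0.1)  # minimal attainable on 3|3
  expect_error(adonis_test(d, rep("a", 6)), "at least 2 groups")
})

test_that("PERMANOVA F matches classical one-way ANOVA on 1-D data", {
  set.seed(3)
  y <- c(rnorm(5, 0), rnorm(5, 1))
  g <- rep(c("a", "b"), each = 5)
  fit <- adonis_test(dist(y), g, n_perm = 99)
  f_aov <- summary(aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(fit$statistic, f_aov, tolerance = 1e-10)
})

test_that("PERMANOVA holds its nominal level on random labels", {
  set.seed(21)
  rejections <- vapply(1:400, function(i) {
    d <- dist(matrix(rnorm(12 * 2), 12))
    g <- sample(rep(c("a", "b"), each = 6))
    adonis_test(d, g, n_perm = 99)$p_value <= 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(mean(rejections) - 0.05), 3.5 * se)
})

test_that("ANOSIM matches a hand rank computation and maxes at R = 1", {
  d <- dist(c(0, 0.1, 0.2, 10, 10.1))
  g <- c("a", "a", "a", "b", "b")
  fit <- anosim_test(d, g, n_perm = 99, seed = 1)
  expect_equal(fit$statistic, oracle_anosim_R(d, g), tolerance = 1e-10)
  expect_equal(fit$statistic, 1)  # all between > all within
  # exchangeable labels: R near zero on average
  set.seed(5)
  r_null <- vapply(1:100, function(i) {
    dd <- dist(rnorm(8))
    anosim_test(dd, sample(rep(c("a", "b"), each = 4)),
                n_perm = 19)$statistic
  }, numeric(1))
  expect_lt(abs(mean(r_null)), 0.1)
})

test_that("MRPP delta and p match enumeration and closed forms", {
  # groups of identical points: delta = 0
  d <- dist(c(1, 1, 1, 4, 4, 4))
  g <- rep(c("a", "b"), each = 3)
  fit <- mrpp_test(d, g, n_perm = 999)
  expect_equal(fit$statistic, 0)
  # all points equidistant: delta = d whatever the grouping
  deq <- as.dist(matrix(2, 4, 4) - diag(2, 4))
  expect_equal(mrpp_test(deq, c("a", "a", "b", "b"),
                         n_perm = 99)$statistic, 2)
  # 6-sample case against exhaustive enumeration
  set.seed(8)
  pts <- c(rnorm(3), rnorm(3, 2))
  d6 <- dist(pts)
  fit6 <- mrpp_test(d6, g, n_perm = 999)
  delta_obs <- oracle_mrpp_delta(d6, g)
  delta_all <- vapply(enumerate_two_groups(6, 3),
                      function(l) oracle_mrpp_delta(d6, l), numeric(1))
  expect_equal(fit6$statistic, delta_obs, tolerance = 1e-10)
  expect_equal(fit6$p_value, mean(delta_all <= delta_obs + 1e-12),
               tolerance = 1e-12)
})

test_that("Mantel correlation is exact on self and affine images", {
  set.seed(2)
  d <- dist(matrix(rnorm(14), 7))
  expect_equal(mantel_test(d, d, n_perm = 99)$statistic, 1)
  expect_equal(mantel_test(d, 3 * d + 1, method = "pearson",
                           n_perm = 99)$statistic, 1, tolerance = 1e-12)
  d2 <- dist(matrix(rnorm(10), 5))
  expect_error(mantel_test(d, d2), "different sizes")
})

test_that("PCoA reproduces Euclidean configurations and closed forms", {
  d <- dist(c(0, 1, 3))
  ord <- pcoa_ord(d)
  rec <- dist(ord$coordinates)
  expect_lt(max(abs(as.numeric(rec) - as.numeric(d))), 1e-9)
  expect_equal(sum(ord$proportion_explained), 1)
  # three mutually equidistant points: two equal positive eigenvalues
  deq <- as.dist(matrix(1, 3, 3) - diag(1, 3))
  e <- pcoa_ord(deq)$eigenvalues
  expect_equal(e[1], e[2], tolerance = 1e-10)
  expect_gt(e[1], 0)
  expect_lt(abs(e[3]), 1e-10)
  # degenerate all-zero distances
  dz <- as.dist(matrix(0, 3, 3))
  expect_lt(max(abs(pcoa_ord(dz)$eigenvalues)), 1e-12)
  expect_error(pcoa_ord(matrix(c(0, 1, 2, 0), 2)), "not symmetric")
})

test_that("Wilcoxon rank-sum: exact enumeration, ties, and power", {
  one <- wilcoxon_test(1:3, 4:6, alternative = "less")
  expect_equal(one$p_value, 0.05, tolerance = 1e-12)  # 1 of C(6,3)=20
  two <- wilcoxon_test(1:3, 4:6)
  expect_equal(two$p_value, 0.1, tolerance = 1e-12)
  expect_gt(wilcoxon_test(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)
  set.seed(4)
  big <- wilcoxon_test(rnorm(200), rnorm(200, 1))
  expect_lt(big$p_value, 1e-10)
})

test_that("abundance-occupancy regression is exact on a constructed line", {
  m <- rbind(a = c(40L, 0L, 0L, 0L),
             b = c(100L, 300L, 0L, 0L),
             c = rep(10000L, 4))
  colnames(m) <- paste0("s", 1:4)
  fit <- suppressWarnings(abundance_occupancy(otu_table(m)))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  same_occ <- otu_table(rbind(a = c(1L, 2L), b = c(3L, 4L),
                              c = c(5L, 6L)))
  expect_error(abundance_occupancy(same_occ), "identical occupancy")
})

test_that("abundance-occupancy: strong on neutral tables, null when shuffled", {
  sim <- simulate_metacommunity(metacommunity_scenario(seed = 19))
  fit <- abundance_occupancy(sim$table)
  expect_gt(fit$slope, 0)
  expect_gt(fit$r_squared, 0.5)
  # destroy the relationship by shuffling occupancy against abundance
  set.seed(6)
  r2 <- vapply(1:50, function(i) {
    df <- fit$data
    df$occupancy <- sample(df$occupancy)
    summary(lm(log10(mean_abundance) ~ occupancy, data = df))$r.squared
  }, numeric(1))
  expect_lt(mean(r2), 0.05)
})

test_that("taxon composition normalizes within group and keeps the
           0.5% boundary", {
  tab <- tiny_table()
  groups <- c(OTU_1 = "core", OTU_2 = "core", OTU_3 = "satellite")
  comp <- taxon_composition(tab, groups, rank = 2, min_frac = 0.005)
  sums <- tapply(comp$fraction, comp$group, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  sat <- comp[comp$group == "satellite", ]
  expect_identical(sat$taxon, "p__Proteobacteria")
  expect_equal(sat$fraction, 1)
  # a taxon at exactly min_frac is retained, not collapsed to Other
  m <- rbind(a = c(995L, 0L), b = c(5L, 0L), c = c(0L, 7L))
  colnames(m) <- c("s1", "s2")
  tb <- otu_table(m, taxonomy = c(a = "k;PhyA", b = "k;PhyB",
                                  c = "k;PhyC"))
  comp2 <- taxon_composition(tb, c(a = "g", b = "g"),
                             rank = 2, min_frac = 0.005)
  expect_true("PhyB" %in% comp2$taxon)
  expect_error(taxon_composition(otu_table(m), c(a = "g")), "taxonomy")
})

test_that("permutation p-values respect the Monte-Carlo floor and seeds", {
  set.seed(1)
  d <- dist(matrix(rnorm(16), 8))
  g <- rep(c("a", "b"), each = 4)
  for (fun in list(adonis_test, anosim_test, mrpp_test)) {
    p <- fun(d, g, n_perm = 99, seed = 7)$p_value
    expect_gte(p, 1 / 100)
    expect_lte(p, 1)
    expect_identical(p, fun(d, g, n_perm = 99, seed = 7)$p_value)
  }
  # statistic invariant to sample reordering
  ord <- sample(8)
  d2 <- as.dist(as.matrix(d)[ord, ord])
  expect_equal(adonis_test(d2, g[ord], n_perm = 9)$statistic,
               adonis_test(d, g, n_perm = 9)$statistic,
               tolerance = 1e-12)
})
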