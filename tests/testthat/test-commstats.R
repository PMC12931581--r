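test_that("Bray-Curtis follows its definition and scale invariance", {
  rows <- rbind(a = c(1, 1), b = c(1, 3))
  expect_equal(bray_curtis(rows)["a", "b"], 1 / 3)
  same <- rbind(x = c(2, 5), y = c(2, 5))
  expect_equal(bray_curtis(same)["x", "y"], 0)
  disjoint <- rbind(x = c(3, 0), y = c(0, 9))
  expect_equal(bray_curtis(disjoint)["x", "y"], 1)
  # invariance to common rescaling of both rows
  expect_equal(bray_curtis(rows * 10)["a", "b"],
               bray_curtis(rows)["a", "b"])
  expect_warning(D <- bray_curtis(rbind(c(0, 0), c(0, 0), c(1, 2))),
                 "all-zero")
  expect_true(is.na(D[1, 2]))
})

test_that("Bray-Curtis agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(10)
  rows <- matrix(rpois(6 * 15, 4), 6, 15)
  expect_equal(unname(bray_curtis(rows)[lower.tri(diag(6))]),
               as.vector(vegan::vegdist(rows, "bray")), tolerance = 1e-12)
})

test_that("the PERMANOVA partition matches the hand-worked toy", {
  # 2 + 2 samples, within-pair distance 1, between-pair distance 2
  D <- matrix(2, 4, 4); diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 1; D[3, 4] <- D[4, 3] <- 1
  rownames(D) <- colnames(D) <- paste0("s", 1:4)
  g <- factor(c("A", "A", "B", "B"))
  res <- permanova(D, g, n_permutations = 50, seed = 1)
  expect_equal(res$pseudo_F, 7)
  expect_equal(res$R2, 3.5 / 4.5, tolerance = 1e-12)
  expect_equal(res$df, c(1, 2))
})

test_that("PERMANOVA pseudo-F matches an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(11)
  rows <- matrix(rpois(12 * 20, 5), 12, 20)
  g <- factor(rep(c("A", "B", "C"), each = 4))
  D <- bray_curtis(rows)
  mine <- permanova(D, g, n_permutations = 99, seed = 2)
  ref <- vegan::adonis2(as.dist(D) ~ g, permutations = 99)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-8)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-8)
})

test_that("the exact permutation p equals the brute-force enumeration", {
  set.seed(12)
  rows <- matrix(rpois(6 * 10, 3), 6, 10)
  g <- factor(rep(c("A", "B"), each = 3))
  D <- bray_curtis(rows)
  res <- permanova(D, g, n_permutations = 719, seed = 3)
  expect_true(res$exact)
  # brute force: all 20 distinct labelings of 3 + 3
  combs <- combn(6, 3)
  fs <- apply(combs, 2, function(ix) {
    gg <- factor(ifelse(seq_len(6) %in% ix, "A", "B"))
    permanova(D, gg, n_permutations = 1, seed = 1)$pseudo_F
  })
  p_brute <- mean(fs >= res$pseudo_F - 1e-12)
  expect_equal(res$p, p_brute, tolerance = 1e-12)
  # identical seeds reproduce identical p on the Monte-Carlo path
  big <- matrix(rpois(10 * 8, 3), 10, 8)
  gb <- factor(rep(c("A", "B"), each = 5))
  Db <- bray_curtis(big)
  expect_identical(permanova(Db, gb, n_permutations = 99, seed = 4)$p,
                   permanova(Db, gb, n_permutations = 99, seed = 4)$p)
})

test_that("PERMANOVA p is invariant to sample order given one seed", {
  set.seed(13)
  rows <- matrix(rpois(10 * 12, 4), 10, 12,
                 dimnames = list(paste0("s", 1:10), NULL))
  g <- factor(rep(c("A", "B"), each = 5))
  D <- bray_curtis(rows)
  r1 <- permanova(D, g, n_permutations = 199, seed = 5)
  ord <- sample(10)
  r2 <- permanova(D[ord, ord], g[ord], n_permutations = 199, seed = 5)
  expect_equal(r1$pseudo_F, r2$pseudo_F, tolerance = 1e-12)
  expect_identical(r1$p, r2$p)
})

test_that("R2 and the within-share partition the total exactly", {
  set.seed(14)
  rows <- matrix(rpois(9 * 10, 4), 9, 10)
  g <- factor(rep(c("A", "B", "C"), each = 3))
  res <- permanova(bray_curtis(rows), g, n_permutations = 49, seed = 1)
  # R2 + SS_within/SS_total = 1 by construction of the partition
  ssw_share <- 1 - res$R2
  expect_equal(res$R2 + ssw_share, 1, tolerance = 1e-12)
  expect_true(res$R2 >= 0 && res$R2 <= 1)
})

test_that("dispersion homogeneity sees spread differences, not mirrors", {
  # mirror-image groups: equal dispersion, high p
  pts <- rbind(c(0, 0), c(2, 0), c(0, 2), c(0, 0) + 10, c(2, 0) + 10,
               c(0, 2) + 10)
  D <- as.matrix(dist(pts))
  g <- factor(rep(c("A", "B"), each = 3))
  res <- dispersion_homogeneity(D, g, n_permutations = 199, seed = 1)
  expect_equal(unname(diff(res$group_dispersion)), 0, tolerance = 1e-6)
  expect_gt(res$p, 0.5)

  # one tight, one 10x spread group: power over a handful of seeds
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    tight <- matrix(rnorm(12, sd = 0.3), 6, 2)
    spread <- matrix(rnorm(12, sd = 3), 6, 2)
    Dp <- as.matrix(dist(rbind(tight, spread)))
    gp <- factor(rep(c("t", "s"), each = 6))
    if (dispersion_homogeneity(Dp, gp, 199, seed = s)$p <= 0.05)
      hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("dispersion distances match Euclidean geometry and vegan", {
  set.seed(15)
  pts <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(pts))
  g <- factor(rep(c("A", "B"), each = 5))
  res <- dispersion_homogeneity(D, g, n_permutations = 9, seed = 1,
                                type = "centroid")
  manual <- unlist(lapply(split(seq_len(10), g), function(ix) {
    cen <- colMeans(pts[ix, ])
    sqrt(rowSums((pts[ix, ] - rep(cen, each = length(ix)))^2))
  }))
  expect_equal(sort(unname(res$distances)), sort(unname(manual)),
               tolerance = 1e-6)
  skip_if_not_installed("vegan")
  bd <- vegan::betadisper(as.dist(D), g, type = "median")
  res_med <- dispersion_homogeneity(D, g, n_permutations = 9, seed = 1)
  expect_equal(sort(unname(res_med$distances)),
               sort(unname(bd$distances)), tolerance = 1e-4)
})

test_that("the Mantel correlogram is calibrated under the null", {
  set.seed(16)
  rejections <- 0
  for (s in 1:20) {
    set.seed(s + 100)
    rows <- matrix(rpois(15 * 25, 3), 15, 25)
    xy <- matrix(runif(30, 0, 50), 15, 2)
    D <- bray_curtis(rows)
    mc <- mantel_correlogram(D, xy, c(0, 15, 30, 75),
                             n_permutations = 99, seed = s)
    rejections <- rejections + sum(mc$p <= 0.05)
    expect_true(all(abs(mc$r) < 0.6))
  }
  # ~alpha x classes x seeds expected rejections; allow generous slack
  expect_lte(rejections, 10)
})
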