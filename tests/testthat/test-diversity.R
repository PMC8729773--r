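test_that("Bray-Curtis matches hand arithmetic and its boundary cases", {
  tb <- rbind(a = c(2, 1, 0), b = c(1, 1, 1), c = c(2, 1, 0),
              d = c(0, 0, 5))
  d <- as.matrix(bray_curtis(tb, transform = "none"))
  expect_equal(d["a", "b"], 1 / 3)
  expect_equal(d["a", "c"], 0)            # identical samples
  expect_equal(d["a", "d"], 1)            # disjoint OTU sets
  expect_true(all(d >= 0 & d <= 1))
})

test_that("Bray-Curtis rejects all-zero samples by name", {
  tb <- rbind(ok = c(1, 2), empty = c(0, 0))
  expect_error(bray_curtis(tb), "empty")
})

test_that("Bray-Curtis is zero for proportional samples after relative-abundance normalization", {
  x <- c(3, 1, 6, 0, 2)
  tb <- rbind(a = x, b = 5 * x)
  rel <- tb / rowSums(tb)
  expect_equal(as.numeric(bray_curtis(rel, transform = "none")), 0)
})

test_that("PCoA embeds Euclidean configurations exactly", {
  set.seed(7)
  pts <- matrix(rnorm(20), ncol = 2)
  rownames(pts) <- paste0("s", 1:10)
  D <- dist(pts)
  p <- pcoa(D)
  expect_true(all(p$eigenvalues > -1e-8))
  expect_null(p$imaginary_vectors)
  got <- as.matrix(dist(p$vectors))
  expect_lt(max(abs(got - as.matrix(D))), 1e-8)
  # collinear points: a single positive eigenvalue
  pc <- pcoa(dist(cbind(c(0, 1, 3))))
  expect_equal(sum(pc$eigenvalues > 1e-8), 1)
  expect_equal(as.matrix(dist(pc$vectors))[1, 3], 3)
})

test_that("PCoA eigenvalues agree with classical scaling (cmdscale)", {
  tb <- toy_table(n = 9, p = 12, seed = 3)
  D <- bray_curtis(tb)
  p <- pcoa(D)
  ref <- stats::cmdscale(D, k = 2, eig = TRUE)
  expect_equal(sort(p$eigenvalues, decreasing = TRUE)[1:5],
               sort(ref$eig, decreasing = TRUE)[1:5], tolerance = 1e-8)
})

test_that("PCoA negative eigenvalues reproduce non-Euclidean distances on imaginary axes", {
  # equilateral triangle of side 2 plus a point at distance 1 from all
  # three corners: impossible in Euclidean space (circumradius 2/sqrt(3) > 1),
  # so the configuration needs imaginary axes
  D <- matrix(2, 4, 4) - diag(2, 4)
  D[4, 1:3] <- D[1:3, 4] <- 1
  dimnames(D) <- list(letters[1:4], letters[1:4])
  p <- pcoa(D)
  expect_true(any(p$eigenvalues < -1e-8))
  sq_real <- as.matrix(dist(p$vectors))^2
  sq_imag <- as.matrix(dist(p$imaginary_vectors))^2
  expect_lt(max(abs((sq_real - sq_imag) - D^2)), 1e-8)
})

test_that("PCoA is equivariant under sample permutation and rejects asymmetry", {
  tb <- toy_table(n = 7, p = 10, seed = 5)
  D <- as.matrix(bray_curtis(tb))
  p1 <- pcoa(D)
  perm <- c(3, 1, 2, 6, 5, 7, 4)
  p2 <- pcoa(D[perm, perm])
  expect_equal(abs(p2$vectors), abs(p1$vectors[perm, ]), tolerance = 1e-8)
  D2 <- D; D2[1, 2] <- D2[1, 2] + 0.2
  expect_error(pcoa(D2), "symmetric")
})

test_that("permdisp distances match the independent betadisper implementation", {
  tb <- toy_table(n = 12, p = 20, seed = 2)
  groups <- rep(c("g1", "g2"), each = 6)
  D <- bray_curtis(tb)
  r <- permdisp(D, groups, n_perm = 99, seed = 1)
  ref <- vegan::betadisper(D, groups, type = "centroid")
  expect_equal(unname(r$distances), unname(ref$distances), tolerance = 1e-6)
})

test_that("permdisp: a group collapsed at its centroid has zero dispersion", {
  pts <- rbind(matrix(rnorm(10, sd = 2), 5, 2),
               matrix(rep(c(5, 5), each = 4), 4, 2))
  rownames(pts) <- paste0("s", 1:9)
  groups <- rep(c("spread", "point"), c(5, 4))
  r <- permdisp(dist(pts), groups, n_perm = 99, seed = 1)
  expect_equal(unname(r$group_means["point"]), 0)
  expect_gt(r$group_means["spread"], 0)
})

test_that("permdisp F increases when one group's spread is inflated", {
  set.seed(4)
  base <- matrix(rnorm(24), 12, 2)
  rownames(base) <- paste0("s", 1:12)
  groups <- rep(c("a", "b"), each = 6)
  r1 <- permdisp(dist(base), groups, n_perm = 99, seed = 1)
  infl <- base; infl[7:12, ] <- infl[7:12, ] * 3
  r2 <- permdisp(dist(infl), groups, n_perm = 99, seed = 1)
  expect_gt(r2$group_means["b"], r1$group_means["b"])
  expect_gt(r2$f_statistic, r1$f_statistic)
})

test_that("permdisp permutation p is stable across seeds", {
  set.seed(9)
  pts <- rbind(matrix(rnorm(16), 8, 2), matrix(rnorm(16, sd = 4), 8, 2))
  rownames(pts) <- paste0("s", 1:16)
  groups <- rep(c("a", "b"), each = 8)
  n_perm <- 499
  p1 <- permdisp(dist(pts), groups, n_perm = n_perm, seed = 1)$p_permutation
  p2 <- permdisp(dist(pts), groups, n_perm = n_perm, seed = 2)$p_permutation
  expect_lt(abs(p1 - p2), 2 / (n_perm + 1) + 1e-12)
})

test_that("permdisp validates its inputs", {
  pts <- matrix(rnorm(10), 5, 2)
  rownames(pts) <- paste0("s", 1:5)
  expect_error(permdisp(dist(pts), rep("a", 5), n_perm = 99, seed = 1),
               "two groups")
  expect_error(permdisp(dist(pts), c("a", "a", "a", "a", "b"),
                        n_perm = 99, seed = 1), "two samples")
  expect_error(permdisp(dist(pts), rep(c("a", "b"), c(3, 2)), n_perm = 99),
               "seed")
})

test_that("richness and Good's coverage handle their boundary cases", {
  tb <- rbind(a = c(5, 3, 0, 1), b = c(2, 0, 0, 0))
  expect_equal(unname(richness(tb)), c(3, 1))
  # one OTU with n >= 2 reads: coverage 1
  expect_equal(unname(goods_coverage(tb))[2], 1)
  # all singletons: coverage 0
  tb2 <- rbind(s = c(1, 1, 1))
  expect_equal(unname(goods_coverage(tb2)), 0)
  expect_equal(unname(goods_coverage(tb))[1], 1 - 1 / 9)
  expect_error(richness(rbind(a = c(0, 0))), "empty")
  expect_error(goods_coverage(rbind(a = c(0, 0))), "empty")
})
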