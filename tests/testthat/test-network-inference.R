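# a small table with two strongly associated OTU blocks for fast
# inference tests
planted_fixture <- function(n = 40, seed = 3) {
  cfg <- synthetic_config(
    n_otus_pool = 24, core_fraction = 1, replacement_fraction = 0,
    groups = data.frame(diet = "FN", stage = "larva", n = n),
    network_modules = 2, module_size = 5, within_module_rho = 0.9,
    n_keystones = 0, seed = seed)
  simulate_dataset(cfg)
}

test_that("prevalence filter keeps exactly the sufficiently present OTUs", {
  tb <- toy_table(n = 9, p = 6, seed = 1)
  expect_identical(prevalence_filter(tb, 0), tb)
  tb2 <- tb
  tb2[, 1] <- 0; tb2[1, 1] <- 5          # present in 1/9 samples
  out <- prevalence_filter(tb2, 0.3)
  expect_false("OTU_01" %in% colnames(out))
  expect_equal(ncol(out), 5)
})

test_that("score methods agree on duplicated profiles and flag constant OTUs", {
  tb <- toy_table(n = 12, p = 5, seed = 2)
  tb[, 2] <- tb[, 1]                      # duplicated OTU
  tb[, 5] <- 7                            # constant OTU
  sc <- score_methods(tb)
  expect_equal(sc$pearson["OTU_01", "OTU_02"], 1)
  expect_equal(sc$spearman["OTU_01", "OTU_02"], 1)
  expect_equal(sc$bray["OTU_01", "OTU_02"], 0)
  expect_false("OTU_05" %in% attr(sc, "constant"))  # constant counts but
  # relative abundances vary with library size; truly constant after
  # normalization (fixed library size, fixed count):
  set.seed(9)
  tb3 <- t(vapply(1:12, function(i) c(rmultinom(1, 90, rep(1, 4))[, 1], 10),
                  numeric(5)))
  colnames(tb3) <- paste0("OTU_0", 1:5)
  sc2 <- score_methods(tb3)
  expect_true("OTU_05" %in% attr(sc2, "constant"))
  expect_true(is.na(sc2$pearson["OTU_05", "OTU_01"]))
})

test_that("the permutation-renormalization null flags a perfect association at the floor", {
  set.seed(1)
  tb <- matrix(rpois(30 * 10, 50), 30, 10,
               dimnames = list(NULL, paste0("OTU_", 1:10)))
  tb[, 2] <- tb[, 1]
  r <- reboot_null(tb, c("OTU_1", "OTU_2"), "pearson", n_perm = 999, seed = 2)
  expect_equal(r$p, 1 / 1000)
  expect_equal(r$score, 1)
  expect_equal(r$sign, 1)
  r2 <- reboot_null(tb, c("OTU_1", "OTU_2"), "pearson", n_perm = 999, seed = 2)
  expect_identical(r, r2)                 # seed determinism
  expect_error(reboot_null(tb, 1:2, "pearson", n_perm = 10, seed = 1),
               "n_perm")
})

test_that("a planted mutual exclusion gets a negative sign and small p", {
  cfg <- synthetic_config(
    n_otus_pool = 24, core_fraction = 1, replacement_fraction = 0,
    groups = data.frame(diet = "FN", stage = "larva", n = 50),
    network_modules = 2, module_size = 5, within_module_rho = 0.9,
    n_keystones = 1, keystone_degree = 6, seed = 8)
  d <- simulate_dataset(cfg)
  gt <- d$ground_truth
  neg <- gt$edges[gt$edges$sign < 0, ][1, ]
  r <- reboot_null(d$counts, c(neg$source, neg$target), "pearson",
                   n_perm = 199, seed = 3)
  expect_equal(r$sign, -1)
  expect_lt(r$p, 0.05)
})

test_that("independent OTU pairs yield roughly uniform null p-values", {
  cfg <- synthetic_config(
    n_otus_pool = 20, core_fraction = 1, replacement_fraction = 0,
    groups = data.frame(diet = "FN", stage = "larva", n = 50),
    network_modules = 0, n_keystones = 0, seed = 21)
  d <- simulate_dataset(cfg)
  pairs <- utils::combn(20, 2)[, 1:120]
  res <- dysbionet:::.reboot_batch(d$counts, pairs, n_perm = 199,
                                   n_boot = 0, seed = 4)
  frac <- mean(vapply(res, function(r) r$p[["pearson"]], numeric(1)) < 0.05)
  # 95% binomial envelope around 0.05 for 120 pairs
  expect_lt(frac, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 120))
})

test_that("merging respects single-method input and empty significance", {
  tb <- toy_table(n = 10, p = 4, seed = 5)
  fake <- list(list(i = 1L, j = 2L,
                    obs = c(pearson = 0.9, spearman = NA, bray = NA),
                    p = c(pearson = 0.002, spearman = NA, bray = NA),
                    sign = c(pearson = 1, spearman = 1, bray = 1),
                    stable = c(pearson = TRUE, spearman = TRUE, bray = TRUE),
                    brown_cov = matrix(NA_real_, 3, 3),
                    null_mean = c(pearson = 0, spearman = 0, bray = 0.5)))
  net <- merge_and_correct(fake, tb, alpha = 0.05)
  expect_equal(net$candidates$merged_p, 0.002)
  expect_equal(nrow(net$edges), 1)
  # all-null input: no edges survive
  fake[[1]]$p <- c(pearson = 1, spearman = 1, bray = 1)
  net2 <- merge_and_correct(fake, tb, alpha = 0.05)
  expect_equal(nrow(net2$edges), 0)
})

test_that("inference recovers a strong two-module structure end to end", {
  d <- planted_fixture(n = 40, seed = 3)
  net <- infer_network(d$counts, taxonomy = d$taxonomy, n_perm = 99,
                       n_boot = 49, seed = 11)
  key <- function(s, t) paste(pmin(s, t), pmax(s, t))
  planted <- key(d$ground_truth$edges$source, d$ground_truth$edges$target)
  inferred <- key(net$edges$source, net$edges$target)
  expect_gt(length(inferred), 0)
  expect_gt(mean(inferred %in% planted), 0.7)
  expect_gt(mean(planted %in% inferred), 0.5)
  # every retained edge satisfies the q threshold and sign agreement
  expect_true(all(net$edges$q <= 0.05))
  expect_true(all(net$edges$methods >= 2))
  # node abundances attached
  expect_true(all(igraph::V(net$graph)$abundance > 0))
})

test_that("the inferred edge set is stable under sample reordering", {
  d <- planted_fixture(n = 40, seed = 3)
  key <- function(e) sort(paste(pmin(e$source, e$target),
                                pmax(e$source, e$target)))
  net1 <- infer_network(d$counts, n_perm = 99, n_boot = 0, seed = 11)
  perm <- sample(nrow(d$counts))
  net2 <- infer_network(d$counts[perm, ], n_perm = 99, n_boot = 0, seed = 11)
  k1 <- key(net1$edges); k2 <- key(net2$edges)
  jac <- length(intersect(k1, k2)) / length(union(k1, k2))
  expect_gt(jac, 0.9)
})

test_that("module detection finds planted block structure", {
  cl1 <- igraph::make_full_graph(5)
  cl2 <- igraph::make_full_graph(6)
  g <- igraph::disjoint_union(cl1, cl2)
  igraph::V(g)$name <- paste0("v", 1:11)
  memb <- detect_modules(g, seed = 1)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[1:5])), 1)
  # ring of cliques: one module per clique
  ring <- igraph::make_ring(4 * 5)
  cliq <- igraph::disjoint_union(lapply(1:4, function(i)
    igraph::make_full_graph(5)))
  for (i in 0:3) cliq <- igraph::add_edges(
    cliq, c(5 * i + 1, (5 * ((i + 1) %% 4)) + 1))
  igraph::V(cliq)$name <- paste0("v", 1:20)
  m2 <- detect_modules(cliq, seed = 1)
  expect_equal(length(unique(m2)), 4)
  # empty graph: every node its own module
  e <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(e)$name <- c("a", "b", "c")
  expect_equal(length(unique(detect_modules(e, seed = 1))), 3)
})
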