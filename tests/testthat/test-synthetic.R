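small_config <- function(...) {
  synthetic_config(
    n_otus_pool = 40,
    groups = default_groups(n = 4),
    network_modules = 3, module_size = 4, n_keystones = 2,
    keystone_degree = 6, seed = 1, ...)
}

test_that("pool construction realizes the core/replacement/offset arithmetic", {
  cfg <- synthetic_config(n_otus_pool = 100, core_fraction = 0.5,
                          replacement_fraction = 0.25,
                          richness_offset = c(FN = 0, NRF = 0, NRV = 10),
                          network_modules = 3, module_size = 4,
                          n_keystones = 2, keystone_degree = 6, seed = 1)
  p <- build_group_pools(cfg)
  expect_length(intersect(p$pools$FN, p$pools$NRV), 50)
  expect_equal(length(p$pools$NRV) - length(p$pools$FN), 10)
  expect_equal(length(p$pools$FN), 75)
  # unique sets are disjoint across diets
  expect_length(intersect(p$unique$FN, p$unique$NRF), 0)
})

test_that("degenerate pool fractions give identical or disjoint pools", {
  all_shared <- synthetic_config(n_otus_pool = 30, core_fraction = 1,
                                 replacement_fraction = 0,
                                 network_modules = 0, n_keystones = 0)
  p1 <- build_group_pools(all_shared)
  expect_identical(p1$pools$FN, p1$pools$NRV)
  disjoint <- synthetic_config(n_otus_pool = 30, core_fraction = 0,
                               replacement_fraction = 1,
                               network_modules = 0, n_keystones = 0)
  p2 <- build_group_pools(disjoint)
  expect_length(intersect(p2$pools$FN, p2$pools$NRF), 0)
  expect_length(p2$pools$FN, 30)
  # forced pure replacement downstream
  x <- as.numeric(p2$universe %in% p2$pools$FN)
  y <- as.numeric(p2$universe %in% p2$pools$NRF)
  expect_equal(unname(decompose_pair(x, y)["replacement"]), 1)
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(core_fraction = 0.8, replacement_fraction = 0.3),
               "must lie in")
  expect_error(synthetic_config(dirichlet_theta = 0), "dirichlet_theta")
  expect_error(synthetic_config(within_module_rho = 1), "within_module_rho")
  expect_error(synthetic_config(network_modules = 10, module_size = 8),
               "core pool too small")
  expect_error(synthetic_config(n_keystones = 1, module_size = 2,
                                keystone_degree = 8), "keystone_degree")
})

test_that("planted network has no self-loops or duplicates and keystones reach their degree", {
  cfg <- small_config()
  gt <- plant_network(cfg)
  e <- gt$edges
  expect_true(all(e$source != e$target))
  expect_false(any(duplicated(paste(e$source, e$target))))
  deg <- table(c(e$source, e$target))
  expect_true(all(deg[gt$keystones] >= cfg$keystone_degree))
  # both association signs are planted
  expect_setequal(unique(e$sign), c(-1L, 1L))
})

test_that("count tables are reproducible from the seed and vary across seeds", {
  cfg <- small_config()
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$counts, d2$counts)
  d3 <- simulate_dataset(cfg, seed = 2)
  expect_false(identical(d1$counts, d3$counts))
  expect_true(all(d1$counts >= 0))
  expect_true(is.integer(d1$counts))
  expect_equal(nrow(d1$counts), sum(cfg$groups$n))
})

test_that("OTUs outside a diet pool have zero counts in that diet", {
  cfg <- synthetic_config(n_otus_pool = 40, core_fraction = 0.5,
                          replacement_fraction = 0.5,
                          groups = default_groups(n = 3),
                          network_modules = 3, module_size = 4,
                          n_keystones = 2, keystone_degree = 6, seed = 4)
  d <- simulate_dataset(cfg)
  p <- d$pools
  fn_rows <- d$metadata$diet == "FN"
  not_fn <- setdiff(p$universe, p$pools$FN)
  expect_true(all(d$counts[fn_rows, not_fn] == 0))
  expect_true(any(d$counts[fn_rows, p$pools$FN] > 0))
})

test_that("planted correlations survive into the observed relative abundances", {
  cfg <- synthetic_config(n_otus_pool = 40, core_fraction = 1,
                          replacement_fraction = 0,
                          groups = data.frame(diet = "FN", stage = "larva",
                                              n = 60),
                          network_modules = 3, module_size = 4,
                          within_module_rho = 0.9, n_keystones = 0, seed = 2)
  d <- simulate_dataset(cfg)
  mem <- names(d$ground_truth$modules)[d$ground_truth$modules == 1][1:2]
  rel <- d$counts / rowSums(d$counts)
  expect_gt(cor(rel[, mem[1]], rel[, mem[2]], method = "spearman"), 0.5)
})

test_that("replicate similarity approaches the counting-noise floor as theta grows", {
  mk <- function(theta) {
    cfg <- synthetic_config(n_otus_pool = 30, core_fraction = 1,
                            replacement_fraction = 0,
                            groups = data.frame(diet = "FN", stage = "larva",
                                                n = 8),
                            lognormal_sigma = 0, dirichlet_theta = theta,
                            network_modules = 0, n_keystones = 0, seed = 6)
    d <- simulate_dataset(cfg)
    mean(bray_curtis(d$counts, transform = "none"))
  }
  # overdispersed replicates are farther apart than near-multinomial ones
  expect_gt(mk(5), mk(5e5))
})

test_that("bioassay generator respects its contracts", {
  b <- generate_bioassay(n_reps = 20, seed = 3)
  expect_true(all(b$W > b$R, b$R >= 0, b$B > 0, b$days >= 1))
  expect_identical(generate_bioassay(seed = 5), generate_bioassay(seed = 5))
  expect_false(identical(generate_bioassay(seed = 5),
                         generate_bioassay(seed = 6)))
  # no diet effect: equal configured means give close empirical means
  flat <- generate_bioassay(n_reps = 200, sr_mean = c(A = 50, B = 50),
                            eci_mean = c(A = 0.2, B = 0.2),
                            days_mean = c(A = 10, B = 10), seed = 7)
  m <- tapply(flat$B, flat$diet, mean)
  expect_lt(abs(m["A"] / m["B"] - 1), 0.05)
  # halving conversion efficiency halves recovered biomass
  half <- generate_bioassay(n_reps = 200, sr_mean = c(A = 50, B = 50),
                            eci_mean = c(A = 0.2, B = 0.1),
                            days_mean = c(A = 10, B = 10), seed = 8)
  mh <- tapply(half$B, half$diet, mean)
  expect_lt(abs(mh["B"] / mh["A"] - 0.5), 0.05)
})

test_that("synthetic writer emits readable TSV/CSV round trips", {
  cfg <- small_config()
  d <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_synthetic(d, dir)
  back <- read_otu_table(paths["otu"])
  expect_equal(unname(back), unname(d$counts[, colnames(back)]),
               ignore_attr = TRUE)
  expect_identical(colnames(back), colnames(d$counts))
  md <- read_metadata(paths["meta"])
  expect_identical(md$sample, d$metadata$sample)
  ed <- utils::read.csv(paths["edges"])
  expect_equal(nrow(ed), nrow(d$ground_truth$edges))
})
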