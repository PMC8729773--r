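#' Configuration for the synthetic diet-by-stage microbiome generator
#'
#' Builds a validated configuration for the synthetic data generator. The
#' defaults emulate a diet-restriction study design: three diets (full
#' nutrient `FN`, nutrient-restricted fruit `NRF` and vegetable `NRV`)
#' crossed with three developmental stages (larva, pupa, adult) at nine
#' replicates each, group-specific OTU pools with a controllable shared
#' core and diet-unique (replaced) fractions, overdispersed
#' Dirichlet-multinomial counts on top of a Gaussian-copula log-normal
#' abundance model, and a planted signed association network with modular
#' and keystone structure.
#'
#' @param n_otus_pool nominal per-diet pool size (basis for the core and
#'   replacement fractions).
#' @param groups data.frame with columns `diet`, `stage`, `n` (replicates).
#'   Default: 3 diets x 3 stages x 9 replicates.
#' @param core_fraction fraction of the pool shared by all diets.
#' @param replacement_fraction fraction of the pool unique to each diet.
#'   `core_fraction + replacement_fraction` must not exceed 1; the
#'   remainder of the nominal pool is simply absent from every diet, so a
#'   diet pool holds `round(core_fraction*n) + round(replacement_fraction*n)`
#'   OTUs (plus its `richness_offset`).
#' @param richness_offset named integer vector (one entry per diet) of
#'   extra/removed diet-unique OTUs, creating planted richness differences.
#' @param lognormal_mu,lognormal_sigma mean and sd of the per-OTU base
#'   log-abundance (natural-log scale).
#' @param dirichlet_theta Dirichlet concentration multiplier; smaller values
#'   give more replicate-to-replicate overdispersion.
#' @param library_size_mean,library_size_shape negative-binomial mean and
#'   shape for sequencing depth per sample.
#' @param network_modules number of planted association modules.
#' @param module_size OTUs per module (modules are drawn from the core pool).
#' @param within_module_rho latent correlation of OTUs within a module,
#'   in (-1, 1). When at least two modules exist the second module mirrors
#'   the first (shared factor with opposite sign), planting negative
#'   (mutual-exclusion) associations between the two.
#' @param n_keystones number of planted keystone OTUs; each bridges two
#'   modules with latent cross-correlation `within_module_rho/sqrt(2)`.
#' @param keystone_degree minimum planted degree a keystone must reach
#'   (`2 * module_size` must be at least this).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_otus_pool = 100,
                             groups = default_groups(),
                             core_fraction = 0.5,
                             replacement_fraction = 0.3,
                             richness_offset = NULL,
                             lognormal_mu = 0,
                             lognormal_sigma = 1.0,
                             dirichlet_theta = 2000,
                             library_size_mean = 20000,
                             library_size_shape = 5,
                             network_modules = 4,
                             module_size = 8,
                             within_module_rho = 0.7,
                             n_keystones = 3,
                             keystone_degree = 8,
                             seed = 1) {
  stopifnot(is.data.frame(groups), all(c("diet", "stage", "n") %in% names(groups)))
  diets <- unique(as.character(groups$diet))
  if (is.null(richness_offset)) {
    richness_offset <- stats::setNames(rep(0L, length(diets)), diets)
  }
  if (is.null(names(richness_offset)) || !all(diets %in% names(richness_offset)))
    stop("richness_offset must be a named vector covering every diet")
  if (core_fraction < 0 || replacement_fraction < 0 ||
      core_fraction + replacement_fraction > 1 + 1e-12)
    stop("core_fraction + replacement_fraction must lie in [0, 1]")
  if (dirichlet_theta <= 0) stop("dirichlet_theta must be > 0")
  if (abs(within_module_rho) >= 1) stop("|within_module_rho| must be < 1")
  if (any(c(n_otus_pool, groups$n, network_modules, module_size,
            n_keystones) < 0)) stop("counts must be non-negative")
  if (n_keystones > 0 && 2 * module_size < keystone_degree)
    stop("planted keystone degree 2*module_size is below keystone_degree")
  if (n_keystones > 0 && network_modules < 2)
    stop("keystones bridge two distinct modules; need network_modules >= 2")
  n_core <- round(core_fraction * n_otus_pool)
  if (network_modules * module_size + n_keystones > n_core && network_modules > 0)
    stop("core pool too small for the requested modules and keystones")
  structure(list(
    n_otus_pool = n_otus_pool, groups = groups,
    core_fraction = core_fraction, replacement_fraction = replacement_fraction,
    richness_offset = richness_offset,
    lognormal_mu = lognormal_mu, lognormal_sigma = lognormal_sigma,
    dirichlet_theta = dirichlet_theta,
    library_size_mean = library_size_mean,
    library_size_shape = library_size_shape,
    network_modules = network_modules, module_size = module_size,
    within_module_rho = within_module_rho,
    n_keystones = n_keystones, keystone_degree = keystone_degree,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Default diet-by-stage design
#'
#' Three diets crossed with three developmental stages, `n` replicates each.
#'
#' @param diets diet labels.
#' @param stages stage labels.
#' @param n replicates per diet-by-stage cell.
#' @return data.frame with columns `diet`, `stage`, `n`.
#' @export
default_groups <- function(diets = c("FN", "NRF", "NRV"),
                           stages = c("larva", "pupa", "adult"),
                           n = 9) {
  out <- expand.grid(diet = diets, stage = stages,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n <- n
  out
}

#' Build per-diet OTU pools
#'
#' Realizes the configured core/replacement/richness structure as explicit
#' OTU id sets: a core set shared by every diet plus disjoint diet-unique
#' sets whose sizes absorb the per-diet richness offsets. Pairwise pool
#' overlap therefore equals `round(core_fraction * n_otus_pool)` and the
#' pool-size difference between two diets equals the difference of their
#' richness offsets.
#'
#' @param config a [synthetic_config()].
#' @return list with `pools` (named list of OTU id vectors per diet),
#'   `core` (shared ids), `unique` (named list of diet-unique ids) and
#'   `universe` (all ids).
#' @export
build_group_pools <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  diets <- unique(as.character(config$groups$diet))
  n <- config$n_otus_pool
  n_core <- round(config$core_fraction * n)
  n_uniq <- round(config$replacement_fraction * n)
  sizes <- stats::setNames(n_uniq + as.integer(config$richness_offset[diets]), diets)
  if (any(sizes < 0)) stop("richness_offset removes more OTUs than the replacement pool holds")
  total <- n_core + sum(sizes)
  ids <- sprintf("OTU_%04d", seq_len(total))
  core <- ids[seq_len(n_core)]
  uniq <- vector("list", length(diets)); names(uniq) <- diets
  at <- n_core
  for (d in diets) {
    uniq[[d]] <- if (sizes[d] > 0) ids[at + seq_len(sizes[d])] else character(0)
    at <- at + sizes[d]
  }
  pools <- lapply(diets, function(d) c(core, uniq[[d]]))
  names(pools) <- diets
  list(pools = pools, core = core, unique = uniq, universe = ids)
}

#' Plant a ground-truth association network
#'
#' Assigns core OTUs to latent modules and keystones and derives the
#' planted signed edges from the implied latent correlation structure.
#' Module members load on one factor per module (within-module pairs
#' are positive, co-presence associations at correlation
#' `within_module_rho`). Each keystone bridges two modules, loading
#' positively on the first and negatively on the second, so it carries
#' both co-presence edges (to the first module) and mutual-exclusion
#' edges (to the second), with planted degree at least
#' `2 * module_size`; keystones with overlapping modules are also
#' linked to each other. The edge list enumerates every OTU pair whose
#' implied latent correlation magnitude reaches `min_abs_corr`, signed
#' by that correlation; only the magnitude of `within_module_rho` is
#' used.
#'
#' @param config a [synthetic_config()].
#' @param pools result of [build_group_pools()].
#' @param min_abs_corr planted-edge threshold on the implied latent
#'   correlation magnitude; default `0.3 * |within_module_rho|`.
#' @return list of class `ground_truth` with `edges`
#'   (data.frame source/target/sign/latent_corr), `modules` (named module
#'   index per member OTU), `keystones` (ids), `keystone_links` (module
#'   pair per keystone), `loadings` (latent factor loadings) and
#'   `taxonomy` (toy class labels for every OTU).
#' @export
plant_network <- function(config, pools = build_group_pools(config),
                          min_abs_corr = 0.3 * abs(config$within_module_rho)) {
  stopifnot(inherits(config, "synthetic_config"))
  k <- config$network_modules
  m <- config$module_size
  core <- pools$core
  taxonomy <- .toy_taxonomy(pools$universe, config$seed)
  empty <- data.frame(source = character(0), target = character(0),
                      sign = integer(0), latent_corr = numeric(0))
  if (k == 0 || abs(config$within_module_rho) == 0) {
    return(structure(list(
      edges = empty, modules = stats::setNames(integer(0), character(0)),
      keystones = character(0), keystone_links = NULL,
      loadings = matrix(0, 0, max(k, 1)), taxonomy = taxonomy),
      class = "ground_truth"))
  }
  members <- core[seq_len(k * m)]
  modules <- stats::setNames(rep(seq_len(k), each = m), members)
  keystones <- if (config$n_keystones > 0)
    core[k * m + seq_len(config$n_keystones)] else character(0)
  keystone_links <- NULL
  if (length(keystones)) {
    a <- ((seq_along(keystones) - 1L) %% k) + 1L
    b <- (a %% k) + 1L
    keystone_links <- cbind(a = a, b = b)
    rownames(keystone_links) <- keystones
  }
  lambda <- .planted_loadings(config, modules, keystones, keystone_links)
  R <- tcrossprod(lambda)
  ids <- rownames(lambda)
  pr <- which(upper.tri(R) & abs(R) >= min_abs_corr - 1e-12, arr.ind = TRUE)
  edges <- if (nrow(pr)) data.frame(
    source = ids[pr[, 1]], target = ids[pr[, 2]],
    sign = as.integer(sign(R[pr])), latent_corr = R[pr],
    stringsAsFactors = FALSE) else empty
  flip <- edges$source > edges$target
  tmp <- edges$source[flip]; edges$source[flip] <- edges$target[flip]
  edges$target[flip] <- tmp
  edges <- edges[order(edges$source, edges$target), ]
  rownames(edges) <- NULL
  structure(list(edges = edges, modules = modules, keystones = keystones,
                 keystone_links = keystone_links, loadings = lambda,
                 taxonomy = taxonomy),
            class = "ground_truth")
}

# factor loadings implementing the module/keystone design; rows are the
# OTUs that participate in the planted structure. Keystones load
# +sqrt(rho/2) on their first module's factor and -sqrt(rho/2) on their
# second (mutual exclusion), keeping every row norm below 1.
.planted_loadings <- function(config, modules, keystones, keystone_links) {
  k <- config$network_modules
  rho <- abs(config$within_module_rho)
  ids <- c(names(modules), keystones)
  lambda <- matrix(0, nrow = length(ids), ncol = k,
                   dimnames = list(ids, NULL))
  for (id in names(modules)) {
    lambda[id, modules[[id]]] <- sqrt(rho)
  }
  for (id in keystones) {
    lambda[id, keystone_links[id, "a"]] <- sqrt(rho / 2)
    lambda[id, keystone_links[id, "b"]] <- -sqrt(rho / 2)
  }
  lambda
}

# fixed toy lexicon of bacterial classes for keystone-report tests
.toy_taxonomy <- function(ids, seed) {
  lex <- c("Bacilli", "Gammaproteobacteria", "Clostridia",
           "Alphaproteobacteria", "Bacteroidia", "Actinobacteria")
  withr_seed <- .sub_seed(seed, 17L)
  old <- .Random.seed_save()
  set.seed(withr_seed)
  tax <- sample(lex, length(ids), replace = TRUE)
  .Random.seed_restore(old)
  stats::setNames(tax, ids)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Sample an OTU count table from the generator
#'
#' Draws, per diet-by-stage group, latent Gaussian-copula log-normal
#' abundances respecting the planted association structure, perturbs the
#' expected proportions with a Dirichlet draw of concentration
#' `dirichlet_theta * p`, and finally draws multinomial counts at a
#' negative-binomial library size. OTUs outside a diet's pool have zero
#' counts in that diet's samples. Identical seeds give identical tables.
#'
#' @param config a [synthetic_config()].
#' @param pools result of [build_group_pools()]; rebuilt when `NULL`.
#' @param ground_truth result of [plant_network()]; rebuilt when `NULL`.
#' @param seed overrides `config$seed` when given.
#' @return list with `counts` (integer matrix, samples x OTUs over the
#'   full universe), `metadata` (data.frame sample/diet/stage) and
#'   `taxonomy` (named class label per OTU).
#' @export
sample_counts <- function(config, pools = NULL, ground_truth = NULL,
                          seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(pools)) pools <- build_group_pools(config)
  if (is.null(ground_truth)) ground_truth <- plant_network(config, pools)
  universe <- pools$universe
  p_all <- length(universe)
  groups <- config$groups
  n_samples <- sum(groups$n)
  counts <- matrix(0L, nrow = n_samples, ncol = p_all,
                   dimnames = list(NULL, universe))
  meta <- data.frame(sample = character(n_samples),
                     diet = character(n_samples),
                     stage = character(n_samples), stringsAsFactors = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  # per-OTU base log-abundance, shared across groups; OTUs carrying the
  # planted association structure are drawn from the central +-1 sd band
  # so the planted truth is neither censored by rarity nor dominant
  # enough to distort the compositional total
  set.seed(.sub_seed(seed, 1L))
  base_mu <- stats::rnorm(p_all, config$lognormal_mu, config$lognormal_sigma)
  names(base_mu) <- universe
  planted_ids <- rownames(ground_truth$loadings)
  planted_ids <- planted_ids[planted_ids %in% universe]
  if (length(planted_ids)) {
    u <- stats::runif(length(planted_ids), stats::pnorm(-1), stats::pnorm(0))
    base_mu[planted_ids] <- config$lognormal_mu +
      config$lognormal_sigma * stats::qnorm(u)
  }
  row_at <- 0L
  for (g in seq_len(nrow(groups))) {
    diet <- as.character(groups$diet[g]); stage <- as.character(groups$stage[g])
    nrep <- groups$n[g]
    pool <- pools$pools[[diet]]
    p <- length(pool)
    set.seed(.sub_seed(seed, 100L + g))
    # stage-specific shift so stages differ compositionally
    stage_shift <- stats::rnorm(p, 0, 0.5)
    z <- .copula_latent(nrep, pool, config, ground_truth)
    logw <- sweep(z, 2, base_mu[pool] + stage_shift, `+`)
    w <- exp(logw)
    pr <- w / rowSums(w)
    theta <- config$dirichlet_theta
    for (r in seq_len(nrep)) {
      alpha <- theta * pr[r, ]
      gam <- stats::rgamma(p, shape = alpha, rate = 1)
      if (all(gam == 0)) gam <- alpha            # degenerate draw: fall back to mean
      q <- gam / sum(gam)
      size <- 0L
      while (size == 0L)
        size <- stats::rnbinom(1, mu = config$library_size_mean,
                               size = config$library_size_shape)
      cts <- stats::rmultinom(1, size = size, prob = q)[, 1]
      counts[row_at + r, pool] <- as.integer(cts)
    }
    idx <- row_at + seq_len(nrep)
    meta$sample[idx] <- sprintf("%s_%s_%02d", diet, stage, seq_len(nrep))
    meta$diet[idx] <- diet
    meta$stage[idx] <- stage
    row_at <- row_at + nrep
  }
  rownames(counts) <- meta$sample
  list(counts = counts, metadata = meta, taxonomy = ground_truth$taxonomy)
}

# latent Gaussian draw (n x p) with the planted correlation structure,
# via an explicit correlation matrix (nearest-PD repaired if degenerate)
.copula_latent <- function(n, pool, config, ground_truth) {
  p <- length(pool)
  R <- diag(p)
  dimnames(R) <- list(pool, pool)
  lambda <- ground_truth$loadings
  in_pool <- rownames(lambda)[rownames(lambda) %in% pool]
  if (length(in_pool)) {
    Rsub <- tcrossprod(lambda[in_pool, , drop = FALSE])
    diag(Rsub) <- 1
    R[in_pool, in_pool] <- Rsub
  }
  ch <- tryCatch(chol(R), error = function(e) {
    message("latent correlation matrix not positive definite; applying nearest-PD repair")
    chol(as.matrix(Matrix::nearPD(R, corr = TRUE)$mat))
  })
  matrix(stats::rnorm(n * p), nrow = n) %*% ch
}

#' Simulate a complete synthetic data set
#'
#' Convenience wrapper running [build_group_pools()], [plant_network()]
#' and [sample_counts()] from one configuration.
#'
#' @param config a [synthetic_config()].
#' @param seed overrides `config$seed` when given.
#' @return list with `counts`, `metadata`, `taxonomy`, `pools`,
#'   `ground_truth` and the `config` used.
#' @export
simulate_dataset <- function(config = synthetic_config(), seed = config$seed) {
  pools <- build_group_pools(config)
  gt <- plant_network(config, pools)
  dat <- sample_counts(config, pools, gt, seed = seed)
  c(dat, list(pools = pools, ground_truth = gt, config = config))
}

#' Generate synthetic bioassay records
#'
#' Draws per-replicate substrate-consumption records (food added W, food
#' remaining R, biomass B, feeding days) per diet. Defaults emulate a
#' full-nutrient versus nutrient-restricted contrast: restricted diets
#' consume a larger substrate fraction, convert it far less efficiently,
#' and take much longer to develop.
#'
#' @param n_reps replicates per diet.
#' @param w_total food added per replicate (g).
#' @param sr_mean named per-diet mean substrate reduction (percent).
#' @param eci_mean named per-diet mean conversion efficiency B/(W-R).
#' @param days_mean named per-diet mean feeding duration (days).
#' @param cv coefficient of variation applied to each drawn quantity.
#' @param seed integer seed.
#' @return data.frame with columns `diet`, `W`, `R`, `B`, `days`.
#' @export
generate_bioassay <- function(n_reps = 3,
                              w_total = 100,
                              sr_mean = c(FN = 60.5, NRF = 86.3, NRV = 91.1),
                              eci_mean = c(FN = 0.29, NRF = 0.04, NRV = 0.08),
                              days_mean = c(FN = 16, NRF = 66, NRV = 54),
                              cv = 0.03,
                              seed = 1) {
  diets <- names(sr_mean)
  stopifnot(!is.null(diets), identical(diets, names(eci_mean)),
            identical(diets, names(days_mean)),
            all(sr_mean > 0 & sr_mean <= 100), all(eci_mean >= 0),
            all(days_mean >= 1))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(.sub_seed(seed, 3L))
  out <- do.call(rbind, lapply(diets, function(d) {
    sr <- pmin(100, pmax(0.1, stats::rnorm(n_reps, sr_mean[d], cv * sr_mean[d])))
    eci <- pmax(0, stats::rnorm(n_reps, eci_mean[d], cv * max(eci_mean[d], 1e-9)))
    days <- pmax(1, stats::rnorm(n_reps, days_mean[d], cv * days_mean[d]))
    W <- rep(w_total, n_reps)
    R <- W * (1 - sr / 100)
    B <- eci * (W - R)
    data.frame(diet = d, W = W, R = R, B = B, days = days,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a synthetic data set to plain-text files
#'
#' Emits the OTU table as TSV (rows = OTUs, first column `otu`, optional
#' final `taxonomy` column), the metadata as TSV (`sample`, `diet`,
#' `stage`), the planted edge list as CSV (`source`, `target`, `sign`)
#' and the configuration as a YAML-like key-value file.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @param taxonomy include the taxonomy column in the OTU table.
#' @return invisibly, the paths written.
#' @export
write_synthetic <- function(dataset, dir, taxonomy = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(otu = file.path(dir, "otu_table.tsv"),
             meta = file.path(dir, "metadata.tsv"),
             edges = file.path(dir, "ground_truth_edges.csv"),
             config = file.path(dir, "config.yml"))
  write_otu_table(dataset$counts, paths["otu"],
                  taxonomy = if (taxonomy) dataset$taxonomy else NULL)
  utils::write.table(dataset$metadata, paths["meta"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(dataset$ground_truth$edges, paths["edges"], row.names = FALSE)
  cfg <- dataset$config
  scalar <- vapply(cfg, function(x) is.atomic(x) && length(x) == 1, logical(1))
  writeLines(c(paste0(names(cfg)[scalar], ": ",
                      vapply(cfg[scalar], as.character, character(1))),
               paste0("richness_offset: ",
                      paste(names(cfg$richness_offset), cfg$richness_offset,
                            sep = "=", collapse = ","))),
             paths["config"])
  invisible(paths)
}
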