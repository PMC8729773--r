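#' Decompose a pair's beta diversity into similarity, replacement and
#' richness difference
#'
#' Podani-family, Jaccard-based decomposition of the dissimilarity
#' between two community vectors. With `a` the shared component, and `b`
#' and `c` the components unique to each sample:
#' similarity `S = a/(a+b+c)`, replacement `Repl = 2*min(b,c)/(a+b+c)`,
#' richness difference `RichDiff = |b-c|/(a+b+c)`; the three always sum
#' to one. In the presence-absence family `a`, `b`, `c` are species
#' counts; in the quantitative (Ruzicka) family
#' `a = sum(min(x, y))`, `b = sum(pmax(x - y, 0))`,
#' `c = sum(pmax(y - x, 0))`.
#'
#' @param x,y non-negative abundance vectors on a common OTU set.
#' @param family `"podani_jaccard"` (presence-absence, default) or
#'   `"ruzicka"` (quantitative).
#' @return named numeric vector
#'   `c(similarity, replacement, richness_difference)`, each in `[0, 1]`
#'   and summing to 1.
#' @export
decompose_pair <- function(x, y, family = c("podani_jaccard", "ruzicka")) {
  family <- match.arg(family)
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  if (sum(x) == 0 && sum(y) == 0) stop("both vectors are empty")
  if (family == "podani_jaccard") {
    a <- sum(x > 0 & y > 0)
    b <- sum(x > 0 & y == 0)
    cc <- sum(x == 0 & y > 0)
  } else {
    a <- sum(pmin(x, y))
    b <- sum(pmax(x - y, 0))
    cc <- sum(pmax(y - x, 0))
  }
  den <- a + b + cc
  c(similarity = a / den,
    replacement = 2 * min(b, cc) / den,
    richness_difference = abs(b - cc) / den)
}

#' Beta-diversity triplets for every sample pair
#'
#' Applies [decompose_pair()] to all pairs of rows of an OTU table.
#'
#' @param table numeric matrix, samples x OTUs.
#' @param family decomposition family, see [decompose_pair()].
#' @return data.frame with columns `sample1`, `sample2`, `similarity`,
#'   `replacement`, `richness_difference`.
#' @export
pair_triplets <- function(table, family = c("podani_jaccard", "ruzicka")) {
  family <- match.arg(family)
  n <- nrow(table)
  ids <- rownames(table) %||% as.character(seq_len(n))
  pairs <- utils::combn(n, 2)
  trip <- apply(pairs, 2, function(ij)
    decompose_pair(table[ij[1], ], table[ij[2], ], family))
  out <- data.frame(sample1 = ids[pairs[1, ]], sample2 = ids[pairs[2, ]],
                    t(trip), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-group beta-diversity triplets and their centroids
#'
#' Computes the decomposition for all within-group sample pairs and the
#' per-group mean triplet (the centroid of each group's points in the
#' ternary diagram).
#'
#' @param table numeric matrix, samples x OTUs.
#' @param groups group label per sample.
#' @param family decomposition family, see [decompose_pair()].
#' @return list with `pairs` (per-pair triplets plus their `group`) and
#'   `means` (one mean triplet per group).
#' @export
group_triplets <- function(table, groups,
                           family = c("podani_jaccard", "ruzicka")) {
  family <- match.arg(family)
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(table))
  res <- list()
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    tg <- pair_triplets(table[idx, , drop = FALSE], family)
    tg$group <- g
    res[[g]] <- tg
  }
  pairs <- do.call(rbind, res)
  rownames(pairs) <- NULL
  comp <- c("similarity", "replacement", "richness_difference")
  means <- do.call(rbind, lapply(split(pairs[comp], pairs$group), colMeans))
  list(pairs = pairs, means = as.data.frame(means))
}

#' Permutation one-way F test on a beta-diversity component
#'
#' Tests whether a decomposition component (e.g. the replacement share
#' of within-group pairs) differs between groups, using the one-way F
#' statistic and a group-label permutation null.
#'
#' @param values component values (one per pair).
#' @param groups group label per value.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed (required).
#' @return list with `f_statistic`, `df`, `p_permutation`.
#' @export
test_component_difference <- function(values, groups, n_perm = 999, seed) {
  if (missing(seed)) stop("seed is required")
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  fobs <- .oneway_f(values, groups)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(.sub_seed(seed, 11L))
  fperm <- replicate(n_perm, .oneway_f(values, sample(groups)))
  list(f_statistic = fobs,
       df = c(nlevels(groups) - 1L, length(values) - nlevels(groups)),
       p_permutation = (sum(fperm >= fobs) + 1) / (n_perm + 1))
}

#' Ternary coordinates of OTUs across three diets
#'
#' For each OTU, the contribution of each diet to its total mean
#' relative abundance, normalized to sum to 100 (its position in a
#' ternary diagram), together with its occupancy frequency (number of
#' samples containing it).
#'
#' @param table numeric matrix, samples x OTUs.
#' @param diets diet label per sample; exactly three distinct diets.
#' @return data.frame with columns `otu`, one contribution column per
#'   diet (percent, rows summing to 100) and `frequency`. OTUs absent
#'   from every sample are dropped.
#' @export
ternary_coordinates <- function(table, diets) {
  diets <- as.factor(diets)
  stopifnot(length(diets) == nrow(table))
  if (nlevels(diets) != 3) stop("ternary coordinates require exactly three diets")
  rel <- table / rowSums(table)
  mean_by_diet <- vapply(levels(diets), function(d)
    colMeans(rel[diets == d, , drop = FALSE]), numeric(ncol(table)))
  keep <- rowSums(mean_by_diet) > 0
  mb <- mean_by_diet[keep, , drop = FALSE]
  contrib <- 100 * mb / rowSums(mb)
  out <- data.frame(otu = colnames(table)[keep], contrib,
                    frequency = colSums(table[, keep, drop = FALSE] > 0),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
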