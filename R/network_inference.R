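#' Prevalence filter
#'
#' Keeps OTUs present (count > 0) in at least a fraction
#' `min_prevalence` of the samples. Rare OTUs carry almost no
#' co-occurrence information and inflate the number of hypothesis
#' tests.
#'
#' @param table numeric matrix, samples x OTUs.
#' @param min_prevalence minimum presence fraction in `[0, 1]`.
#' @return the reduced table (possibly with zero columns).
#' @export
prevalence_filter <- function(table, min_prevalence = 1 / 3) {
  .assert_count_matrix(table)
  keep <- colMeans(table > 0) >= min_prevalence
  table[, keep, drop = FALSE]
}

#' Per-pair association scores for the method ensemble
#'
#' Computes, for every OTU pair, Pearson and Spearman correlations of
#' `log1p` relative abundances and the Bray-Curtis dissimilarity
#' between the two OTUs' relative-abundance profiles across samples.
#' OTUs that are constant across samples have undefined correlations;
#' their entries are `NA` and such pairs are skipped downstream.
#'
#' @param table numeric matrix, samples x OTUs.
#' @return list of three symmetric matrices `pearson`, `spearman`,
#'   `bray` (OTU x OTU), with an attribute `constant` naming constant
#'   OTUs.
#' @export
score_methods <- function(table) {
  .assert_count_matrix(table)
  rel <- table / rowSums(table)
  lp <- log1p(rel)
  constant <- apply(lp, 2, stats::sd) == 0
  pe <- suppressWarnings(stats::cor(lp, method = "pearson"))
  sp <- suppressWarnings(stats::cor(lp, method = "spearman"))
  pe[constant, ] <- pe[, constant] <- NA
  sp[constant, ] <- sp[, constant] <- NA
  br <- as.matrix(vegan::vegdist(t(rel), method = "bray"))
  diag(pe) <- diag(sp) <- 1; diag(br) <- 0
  out <- list(pearson = pe, spearman = sp, bray = br)
  attr(out, "constant") <- colnames(table)[constant]
  out
}

# select candidate pairs: per method, the n_top/2 highest and n_top/2
# lowest scores (mirroring the threshold-setting stage of ensemble
# co-occurrence tools); returns a 2 x m index matrix
.candidate_pairs <- function(scores, n_top = 1000) {
  p <- nrow(scores$pearson)
  ut <- which(upper.tri(scores$pearson), arr.ind = TRUE)
  ok <- !is.na(scores$pearson[ut]) & !is.na(scores$spearman[ut])
  ut <- ut[ok, , drop = FALSE]
  m <- nrow(ut)
  if (m <= n_top) return(t(ut))
  half <- ceiling(n_top / 2)
  sel <- logical(m)
  for (s in scores) {
    v <- s[ut]
    ord <- order(v)
    sel[ord[seq_len(min(half, m))]] <- TRUE
    sel[ord[seq(m - min(half, m) + 1, m)]] <- TRUE
  }
  t(ut[sel, , drop = FALSE])
}

# Vectorized permutation-renormalization (ReBoot-style) null plus
# bootstrap stability for a batch of OTU pairs.
#
# For each pair the two OTUs' counts are shuffled across samples
# independently, every sample's composition is renormalized (the other
# OTUs' totals stay fixed), and the three method scores are recomputed;
# the two-sided p compares the observed score's deviation from the null
# mean with the null deviations (+1 correction). A bootstrap over
# samples yields a score CI per method; an edge is "stable" for a
# method when that CI does not cross the null mean.
.reboot_batch <- function(table, pairs, n_perm = 999, n_boot = 999, seed = 1) {
  n <- nrow(table)
  tot <- rowSums(table)
  m <- ncol(pairs)
  methods <- c("pearson", "spearman", "bray")
  res <- vector("list", m)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(.sub_seed(seed, 23L))
  colwise_cor <- function(X, Y) {
    sx <- colSums(X); sy <- colSums(Y)
    num <- n * colSums(X * Y) - sx * sy
    den <- sqrt(pmax(n * colSums(X^2) - sx^2, 0) *
                pmax(n * colSums(Y^2) - sy^2, 0))
    ifelse(den > 0, num / den, NA_real_)
  }
  for (e in seq_len(m)) {
    i <- pairs[1, e]; j <- pairs[2, e]
    xi <- table[, i]; xj <- table[, j]
    rest <- tot - xi - xj
    pi_o <- xi / tot; pj_o <- xj / tot
    li <- log1p(pi_o); lj <- log1p(pj_o)
    if (stats::sd(li) == 0 || stats::sd(lj) == 0) next
    obs <- c(pearson = stats::cor(li, lj),
             spearman = stats::cor(li, lj, method = "spearman"),
             bray = sum(abs(pi_o - pj_o)) / sum(pi_o + pj_o))
    # permutation null with per-sample renormalization
    P1 <- matrix(xi[c(replicate(n_perm, sample.int(n)))], nrow = n)
    P2 <- matrix(xj[c(replicate(n_perm, sample.int(n)))], nrow = n)
    TT <- rest + P1 + P2
    Ai <- P1 / TT; Aj <- P2 / TT
    Li <- log1p(Ai); Lj <- log1p(Aj)
    null_s <- cbind(
      pearson = colwise_cor(Li, Lj),
      spearman = colwise_cor(apply(Ai, 2, rank), apply(Aj, 2, rank)),
      bray = colSums(abs(Ai - Aj)) / colSums(Ai + Aj))
    null_mean <- colMeans(null_s, na.rm = TRUE)
    dev_null <- abs(sweep(null_s, 2, null_mean))
    dev_obs <- abs(obs - null_mean)
    pvals <- (colSums(sweep(dev_null, 2, dev_obs, `>=`), na.rm = TRUE) + 1) /
      (n_perm + 1)
    signs <- c(sign(obs["pearson"]), sign(obs["spearman"]),
               if (obs["bray"] < null_mean["bray"]) 1 else -1)
    names(signs) <- methods
    # -2 log pseudo-p streams for Brown's covariance estimate
    Xs <- apply(dev_null, 2, function(d) {
      r <- rank(d, ties.method = "min", na.last = "keep")
      -2 * log((sum(!is.na(d)) - r + 2) / (sum(!is.na(d)) + 1))
    })
    brown_cov <- stats::cov(Xs, use = "pairwise.complete.obs")
    # bootstrap stability
    stable <- rep(TRUE, 3); names(stable) <- methods
    if (n_boot > 0) {
      idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
      Bi <- matrix(pi_o[idx], nrow = n); Bj <- matrix(pj_o[idx], nrow = n)
      boot_s <- cbind(
        pearson = colwise_cor(log1p(Bi), log1p(Bj)),
        spearman = colwise_cor(apply(Bi, 2, rank), apply(Bj, 2, rank)),
        bray = colSums(abs(Bi - Bj)) / colSums(Bi + Bj))
      ci <- apply(boot_s, 2, stats::quantile,
                  probs = c(0.025, 0.975), na.rm = TRUE)
      stable <- ci[1, ] > null_mean | ci[2, ] < null_mean
    }
    res[[e]] <- list(i = i, j = j, obs = obs, p = pvals, sign = signs,
                     stable = stable, brown_cov = brown_cov,
                     null_mean = null_mean)
  }
  res[!vapply(res, is.null, logical(1))]
}

#' Permutation-renormalization null p-value for one OTU pair
#'
#' Shuffles the two OTUs' counts across samples independently,
#' renormalizes every sample's composition after each shuffle,
#' recomputes the association score, and returns the two-sided
#' permutation p-value (deviation from the null mean, +1 correction).
#' The renormalization step makes the null compositionality-aware:
#' spurious correlations induced by the closure of relative abundances
#' are absorbed into the null mean.
#'
#' @param table numeric count matrix, samples x OTUs.
#' @param pair length-2 vector of OTU names or column indices.
#' @param method `"pearson"`, `"spearman"` or `"bray"`.
#' @param n_perm number of permutations, >= 20.
#' @param seed integer seed (required).
#' @return list with `p`, `score` (observed), `null_mean` and `sign`.
#' @export
reboot_null <- function(table, pair, method = c("pearson", "spearman", "bray"),
                        n_perm = 999, seed) {
  method <- match.arg(method)
  if (missing(seed)) stop("seed is required")
  if (n_perm < 20) stop("n_perm < 20 gives too coarse a p-value resolution")
  idx <- if (is.character(pair)) match(pair, colnames(table)) else as.integer(pair)
  if (any(is.na(idx))) stop("pair not found in table")
  r <- .reboot_batch(table, matrix(idx, nrow = 2), n_perm = n_perm,
                     n_boot = 0, seed = seed)
  if (!length(r)) stop("pair involves a constant OTU; correlation undefined")
  r <- r[[1]]
  list(p = unname(r$p[method]), score = unname(r$obs[method]),
       null_mean = unname(r$null_mean[method]),
       sign = unname(r$sign[method]))
}

#' Merge per-method p-values and build the significant network
#'
#' Combines the method ensemble per pair with Brown's method (a
#' dependence-aware extension of Fisher's combination, with the
#' inter-method covariance estimated from the permutation null
#' streams), corrects across pairs with Benjamini-Hochberg, and retains
#' edges with `q <= alpha`, at least two methods agreeing in sign, and
#' bootstrap-stable scores in at least two methods. The edge sign is
#' the consensus correlation sign (Bray-Curtis votes by its
#' below/above-null direction).
#'
#' @param candidates result of the internal scoring batch (see
#'   [infer_network()]).
#' @param table the count table the candidates were scored on
#'   (samples x OTUs), used for node abundances.
#' @param alpha BH threshold (default 0.05).
#' @param taxonomy optional named taxonomy string per OTU.
#' @return object of class `coocc_network`: list with `graph` (igraph,
#'   edge attributes `sign`, `q`, `p`, `methods`; vertex attributes
#'   `abundance`, `taxonomy`), `edges` (data.frame of retained edges)
#'   and `candidates` (all scored pairs with merged p and q).
#' @export
merge_and_correct <- function(candidates, table, alpha = 0.05,
                              taxonomy = NULL) {
  if (!length(candidates)) {
    return(.empty_network(table, taxonomy))
  }
  rows <- lapply(candidates, function(r) {
    p <- r$p; k <- sum(!is.na(p))
    merged <- if (k <= 1) {
      p[!is.na(p)][1]
    } else {
      X <- -2 * sum(log(p), na.rm = TRUE)
      E <- 2 * k
      cv <- r$brown_cov
      covsum <- sum(cv[upper.tri(cv)], na.rm = TRUE)
      V <- max(4 * k + 2 * covsum, 1e-8)
      cc <- V / (2 * E)
      df <- 2 * E^2 / V
      stats::pchisq(X / cc, df = df, lower.tail = FALSE)
    }
    sgns <- r$sign
    consensus <- sign(sum(sgns))
    n_agree <- if (consensus == 0) 1L else sum(sgns == consensus)
    data.frame(i = r$i, j = r$j,
               pearson = r$obs["pearson"], spearman = r$obs["spearman"],
               bray = r$obs["bray"],
               p_pearson = p["pearson"], p_spearman = p["spearman"],
               p_bray = p["bray"],
               merged_p = max(merged, .Machine$double.xmin),
               sign = as.integer(consensus),
               methods_agreeing = as.integer(n_agree),
               methods_stable = as.integer(sum(r$stable)),
               row.names = NULL)
  })
  cand <- do.call(rbind, rows)
  cand$q <- stats::p.adjust(cand$merged_p, method = "BH")
  keep <- cand$q <= alpha & cand$methods_agreeing >= 2 &
    cand$methods_stable >= 2 & cand$sign != 0
  ids <- colnames(table)
  edges <- data.frame(source = ids[cand$i[keep]], target = ids[cand$j[keep]],
                      sign = cand$sign[keep], q = cand$q[keep],
                      p = cand$merged_p[keep],
                      methods = cand$methods_agreeing[keep],
                      stringsAsFactors = FALSE)
  .build_network(edges, table, taxonomy, candidates = cand)
}

.empty_network <- function(table, taxonomy) {
  edges <- data.frame(source = character(0), target = character(0),
                      sign = integer(0), q = numeric(0), p = numeric(0),
                      methods = integer(0))
  .build_network(edges, table, taxonomy,
                 candidates = data.frame())
}

.build_network <- function(edges, table, taxonomy, candidates) {
  rel <- table / rowSums(table)
  used <- unique(c(edges$source, edges$target))
  nodes <- data.frame(name = used,
                      abundance = colMeans(rel[, used, drop = FALSE]),
                      stringsAsFactors = FALSE)
  nodes$taxonomy <- if (!is.null(taxonomy))
    unname(taxonomy[nodes$name]) else rep(NA_character_, nrow(nodes))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(graph = g, edges = edges, candidates = candidates),
            class = "coocc_network")
}

#' Infer a signed co-occurrence network from a count table
#'
#' End-to-end inference for one sample group: prevalence filtering,
#' scoring with the {Pearson, Spearman, Bray-Curtis} ensemble,
#' candidate selection by score quantiles, the permutation-
#' renormalization null with bootstrap stability per candidate, Brown's
#' p-value merge and BH correction ([merge_and_correct()]).
#'
#' @param table numeric count matrix, samples x OTUs.
#' @param taxonomy optional named taxonomy string per OTU.
#' @param min_prevalence prevalence filter threshold (default 1/3).
#' @param n_candidates candidate edges per method before permutation
#'   testing (default 1000; all pairs when fewer).
#' @param n_perm permutations for the null (default 999).
#' @param n_boot bootstrap resamples for edge stability (default 999;
#'   0 disables the stability screen).
#' @param alpha BH threshold on merged q-values (default 0.05).
#' @param seed integer seed (required).
#' @return a `coocc_network`, see [merge_and_correct()].
#' @export
infer_network <- function(table, taxonomy = NULL, min_prevalence = 1 / 3,
                          n_candidates = 1000, n_perm = 999, n_boot = 999,
                          alpha = 0.05, seed) {
  if (missing(seed)) stop("seed is required")
  ft <- prevalence_filter(table, min_prevalence)
  if (ncol(ft) < 2) return(.empty_network(ft, taxonomy))
  scores <- score_methods(ft)
  pairs <- .candidate_pairs(scores, n_top = n_candidates)
  cand <- .reboot_batch(ft, pairs, n_perm = n_perm, n_boot = n_boot,
                        seed = seed)
  net <- merge_and_correct(cand, ft, alpha = alpha, taxonomy = taxonomy)
  net$params <- list(min_prevalence = min_prevalence,
                     n_candidates = n_candidates, n_perm = n_perm,
                     n_boot = n_boot, alpha = alpha, seed = seed)
  net
}

#' Detect network modules
#'
#' Modularity-maximizing partition of the network by the Louvain
#' heuristic (on the unsigned topology), seeded for reproducibility.
#' Every node of an empty graph is its own module.
#'
#' @param network a `coocc_network` or igraph object.
#' @param seed integer seed.
#' @return named integer vector of module memberships; when given a
#'   `coocc_network`, the same object with a `module` vertex attribute
#'   and a `modules` element added.
#' @export
detect_modules <- function(network, seed = 1) {
  g <- if (inherits(network, "coocc_network")) network$graph else network
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(.sub_seed(seed, 29L))
  memb <- if (igraph::ecount(g) == 0) {
    stats::setNames(seq_len(igraph::vcount(g)), igraph::V(g)$name)
  } else {
    cl <- igraph::cluster_louvain(g)
    stats::setNames(igraph::membership(cl), igraph::V(g)$name)
  }
  if (inherits(network, "coocc_network")) {
    igraph::V(network$graph)$module <- as.integer(memb)
    network$modules <- memb
    return(network)
  }
  memb
}

#' Infer networks per group
#'
#' Splits the samples by a grouping variable (e.g. diet over the whole
#' life span, or diet-by-stage) and runs [infer_network()] per group.
#'
#' @param table numeric count matrix, samples x OTUs.
#' @param groups group label per sample.
#' @param ... passed to [infer_network()] (including `seed`).
#' @return named list of `coocc_network` objects.
#' @export
infer_networks_by_group <- function(table, groups, ...) {
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(table))
  out <- lapply(levels(groups), function(g)
    infer_network(table[groups == g, , drop = FALSE], ...))
  names(out) <- levels(groups)
  out
}
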