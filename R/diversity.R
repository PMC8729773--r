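#' Bray-Curtis dissimilarity between samples
#'
#' Computes pairwise Bray-Curtis dissimilarities
#' `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` between the rows
#' (samples) of an OTU count table, by default after a `log1p`
#' transform of the counts (the quantitative, log-transformed variant).
#'
#' @param table numeric matrix, samples x OTUs, non-negative.
#' @param transform `"log1p"` (default) or `"none"`.
#' @return a `dist` object labelled by sample id, values in `[0, 1]`.
#' @export
bray_curtis <- function(table, transform = c("log1p", "none")) {
  transform <- match.arg(transform)
  .assert_count_matrix(table)
  zero <- rowSums(table) == 0
  if (any(zero)) {
    bad <- rownames(table)[zero] %||% which(zero)
    stop("all-zero sample(s): ", paste(bad, collapse = ", "))
  }
  x <- if (transform == "log1p") log1p(table) else table
  vegan::vegdist(x, method = "bray")
}

#' Principal coordinates analysis with imaginary axes
#'
#' Classical metric scaling of a dissimilarity matrix: Gower
#' double-centering of `-D^2/2` followed by eigendecomposition. Axes are
#' ordered by decreasing eigenvalue; axes belonging to negative
#' eigenvalues (which arise for semimetric dissimilarities such as
#' Bray-Curtis) are retained separately as "imaginary" coordinates,
#' scaled by `sqrt(-eigenvalue)`. Squared inter-point distances are then
#' reproduced as the real-part squared distance minus the imaginary-part
#' squared distance.
#'
#' @param d a `dist` object or symmetric zero-diagonal matrix.
#' @param eps eigenvalues within `eps * max(|eigenvalue|)` of zero are
#'   dropped as numerical noise.
#' @return object of class `pcoa_result`: list with `vectors` (n x m
#'   real coordinates), `imaginary_vectors` (n x m' or NULL),
#'   `eigenvalues` (all, decreasing), `prop_explained` (relative to the
#'   sum of positive eigenvalues) and `labels`.
#' @export
pcoa <- function(d, eps = 1e-9) {
  D <- as.matrix(d)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8))
    stop("dissimilarity matrix must be symmetric")
  labels <- rownames(D) %||% as.character(seq_len(nrow(D)))
  n <- nrow(D)
  A <- -0.5 * D^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  eig <- eigen(G, symmetric = TRUE)
  vals <- eig$values
  tol <- eps * max(abs(vals), 1)
  pos <- which(vals > tol)
  neg <- which(vals < -tol)
  vectors <- if (length(pos))
    sweep(eig$vectors[, pos, drop = FALSE], 2, sqrt(vals[pos]), `*`)
  else matrix(0, n, 0)
  rownames(vectors) <- labels
  if (length(pos)) colnames(vectors) <- paste0("Axis.", seq_along(pos))
  imag <- NULL
  if (length(neg)) {
    imag <- sweep(eig$vectors[, neg, drop = FALSE], 2, sqrt(-vals[neg]), `*`)
    rownames(imag) <- labels
    colnames(imag) <- paste0("Imag.", seq_along(neg))
  }
  prop <- if (length(pos)) vals[pos] / sum(vals[pos]) else numeric(0)
  structure(list(vectors = vectors, imaginary_vectors = imag,
                 eigenvalues = vals, prop_explained = prop,
                 labels = labels),
            class = "pcoa_result")
}

# squared inter-point distances implied by a pcoa_result (real - imaginary)
.pcoa_sqdist <- function(p) {
  sq <- function(M) {
    if (is.null(M) || ncol(M) == 0) return(matrix(0, length(p$labels), length(p$labels)))
    as.matrix(stats::dist(M))^2
  }
  sq(p$vectors) - sq(p$imaginary_vectors)
}

#' Multivariate homogeneity of group dispersions (PERMDISP)
#'
#' Measures within-group dispersion as the distance of each sample from
#' its group centroid in principal-coordinate space, handling the
#' imaginary axes of semimetric dissimilarities: the squared distance to
#' the centroid is the real-part squared distance minus the
#' imaginary-part squared distance, floored at zero. Group differences
#' are tested with a one-way F statistic on the distances and a
#' permutation p-value obtained by shuffling group labels; pairwise
#' Tukey HSD comparisons with a compact letter display are also
#' returned.
#'
#' @param d `dist` object or symmetric dissimilarity matrix.
#' @param groups group label per sample (>= 2 groups, each with >= 2
#'   samples).
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed for the permutations (required).
#' @param type `"centroid"` (default) or `"median"` (spatial-median
#'   variant, delegated to [vegan::betadisper()]).
#' @return object of class `permdisp_result`: list with `distances`
#'   (per-sample distance to its group centroid), `group_means`,
#'   `f_statistic`, `df`, `p_permutation`, `tukey` (pairwise table) and
#'   `letters` (compact letter display).
#' @export
permdisp <- function(d, groups, n_perm = 999, seed,
                     type = c("centroid", "median")) {
  type <- match.arg(type)
  if (missing(seed)) stop("seed is required")
  groups <- as.factor(groups)
  D <- as.matrix(d)
  n <- nrow(D)
  if (length(groups) != n) stop("groups length must match the matrix")
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least two groups")
  if (any(tab < 2)) stop("every group needs at least two samples")
  if (type == "median") {
    bd <- vegan::betadisper(stats::as.dist(D), groups, type = "median")
    dist_c <- bd$distances
  } else {
    p <- pcoa(D)
    dist_c <- numeric(n)
    for (g in levels(groups)) {
      idx <- which(groups == g)
      cr <- colMeans(p$vectors[idx, , drop = FALSE])
      d2 <- rowSums(sweep(p$vectors[idx, , drop = FALSE], 2, cr)^2)
      if (!is.null(p$imaginary_vectors)) {
        ci <- colMeans(p$imaginary_vectors[idx, , drop = FALSE])
        d2 <- d2 - rowSums(sweep(p$imaginary_vectors[idx, , drop = FALSE], 2, ci)^2)
      }
      dist_c[idx] <- sqrt(pmax(d2, 0))
    }
    names(dist_c) <- rownames(D)
  }
  fstat <- .oneway_f(dist_c, groups)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(.sub_seed(seed, 5L))
  fperm <- replicate(n_perm, .oneway_f(dist_c, sample(groups)))
  p_val <- (sum(fperm >= fstat) + 1) / (n_perm + 1)
  aovfit <- stats::aov(dist_c ~ groups)
  tuk <- stats::TukeyHSD(aovfit)$groups
  diff_mat <- matrix(FALSE, nlevels(groups), nlevels(groups),
                     dimnames = list(levels(groups), levels(groups)))
  for (cmp in rownames(tuk)) {
    ab <- strsplit(cmp, "-", fixed = TRUE)[[1]]
    sig <- tuk[cmp, "p adj"] < 0.05
    diff_mat[ab[1], ab[2]] <- diff_mat[ab[2], ab[1]] <- sig
  }
  structure(list(
    distances = dist_c,
    group_means = tapply(dist_c, groups, mean),
    f_statistic = fstat,
    df = c(nlevels(groups) - 1L, n - nlevels(groups)),
    p_permutation = p_val,
    tukey = tuk,
    letters = .letter_display(diff_mat),
    type = type, n_perm = n_perm
  ), class = "permdisp_result")
}

.oneway_f <- function(y, g) {
  n <- length(y)
  k <- nlevels(g)
  gm <- tapply(y, g, mean)
  ns <- tabulate(g)
  ssb <- sum(ns * (gm - mean(y))^2)
  ssw <- sum((y - gm[as.integer(g)])^2)
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Per-sample OTU richness
#'
#' Number of OTUs observed (count > 0) in each sample.
#'
#' @param table numeric matrix, samples x OTUs.
#' @return named integer vector.
#' @export
richness <- function(table) {
  .assert_count_matrix(table)
  if (any(rowSums(table) == 0)) stop("empty sample(s) present")
  rowSums(table > 0)
}

#' Good's coverage per sample
#'
#' `1 - singletons / reads`: the estimated probability that the next
#' read belongs to an already-observed OTU.
#'
#' @param table integer count matrix, samples x OTUs.
#' @return named numeric vector in `[0, 1]`.
#' @export
goods_coverage <- function(table) {
  .assert_count_matrix(table)
  reads <- rowSums(table)
  if (any(reads == 0)) stop("empty sample(s) present")
  singletons <- rowSums(table == 1)
  1 - singletons / reads
}
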