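# Network robustness under stepwise node removal.

# connected node pairs of a graph (sum over components of C(size, 2))
.connected_pairs <- function(g) {
  sz <- igraph::components(g)$csize
  sum(sz * (sz - 1) / 2)
}

#' Robustness curve under a node-removal attack
#'
#' Removes nodes one at a time under a given strategy and records, after
#' each removal, the connectivity loss
#' `L = 1 - (connected node pairs remaining) / (connected node pairs initially)`
#' together with the raw edge loss. Strategies: `"random"` (uniform
#' order, averaged over `n_reps` repetitions), `"degree"` (descending
#' initial degree), `"betweenness"` (descending initial betweenness) and
#' `"cascading"` (the node of maximal betweenness, recomputed after
#' every removal). Ties are broken by ascending node id.
#'
#' @param network a `coocc_network` or igraph object with >= 2 nodes.
#' @param strategy attack strategy.
#' @param seed integer seed (required for `"random"`).
#' @param n_reps repetitions for the random strategy (default 100).
#' @return data.frame of class `robustness_curve` with columns
#'   `strategy`, `f` (fraction of nodes removed, 0..1), `L_pairs`,
#'   `L_edges` and, for the random strategy, `L_pairs_sd`.
#' @export
attack <- function(network,
                   strategy = c("random", "degree", "betweenness", "cascading"),
                   seed = NULL, n_reps = 100) {
  strategy <- match.arg(strategy)
  g0 <- .as_graph(network)
  n <- igraph::vcount(g0)
  if (n < 2) stop("need at least two nodes")
  if (is.null(igraph::V(g0)$name))
    g0 <- igraph::set_vertex_attr(g0, "name",
                                  value = as.character(seq_len(n)))
  pairs0 <- .connected_pairs(g0)
  edges0 <- igraph::ecount(g0)
  if (pairs0 == 0) stop("graph has no connected pairs (no edges)")
  one_run <- function(order_fun) {
    g <- g0
    Lp <- Le <- numeric(n + 1)
    for (m in seq_len(n)) {
      v <- order_fun(g)
      g <- igraph::delete_vertices(g, v)
      Lp[m + 1] <- 1 - .connected_pairs(g) / pairs0
      Le[m + 1] <- 1 - igraph::ecount(g) / edges0
    }
    list(Lp = Lp, Le = Le)
  }
  pick_max <- function(score, ids) ids[order(-score, ids)][1]
  f <- seq(0, n) / n
  if (strategy == "random") {
    if (is.null(seed)) stop("seed is required for the random strategy")
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(.sub_seed(seed, 31L))
    ids0 <- igraph::V(g0)$name
    runs_p <- matrix(0, nrow = n + 1, ncol = n_reps)
    runs_e <- matrix(0, nrow = n + 1, ncol = n_reps)
    for (r in seq_len(n_reps)) {
      ord <- sample(ids0)
      pos <- 0
      run <- one_run(function(g) ord[pos <<- pos + 1])
      runs_p[, r] <- run$Lp; runs_e[, r] <- run$Le
    }
    out <- data.frame(strategy = strategy, f = f,
                      L_pairs = rowMeans(runs_p),
                      L_edges = rowMeans(runs_e),
                      L_pairs_sd = apply(runs_p, 1, stats::sd))
  } else if (strategy == "degree") {
    k <- igraph::degree(g0)
    ord <- igraph::V(g0)$name[order(-k, igraph::V(g0)$name)]
    pos <- 0
    run <- one_run(function(g) ord[pos <<- pos + 1])
    out <- data.frame(strategy = strategy, f = f,
                      L_pairs = run$Lp, L_edges = run$Le)
  } else if (strategy == "betweenness") {
    b <- igraph::betweenness(g0, weights = NA)
    ord <- igraph::V(g0)$name[order(-b, igraph::V(g0)$name)]
    pos <- 0
    run <- one_run(function(g) ord[pos <<- pos + 1])
    out <- data.frame(strategy = strategy, f = f,
                      L_pairs = run$Lp, L_edges = run$Le)
  } else {
    run <- one_run(function(g) {
      b <- igraph::betweenness(g, weights = NA)
      pick_max(b, igraph::V(g)$name)
    })
    out <- data.frame(strategy = strategy, f = f,
                      L_pairs = run$Lp, L_edges = run$Le)
  }
  class(out) <- c("robustness_curve", class(out))
  out
}

#' Interpolated connectivity loss at a removal fraction
#'
#' Linear interpolation of a robustness curve at an arbitrary fraction
#' of removed nodes.
#'
#' @param curve a `robustness_curve` from [attack()].
#' @param fraction removal fraction(s) in `[0, 1]`.
#' @param measure `"pairs"` (connectivity loss, default) or `"edges"`.
#' @return interpolated loss value(s).
#' @export
loss_at <- function(curve, fraction, measure = c("pairs", "edges")) {
  measure <- match.arg(measure)
  stopifnot(all(fraction >= 0 & fraction <= 1))
  y <- if (measure == "pairs") curve$L_pairs else curve$L_edges
  stats::approx(curve$f, y, xout = fraction, rule = 2)$y
}

#' Compare robustness curves across networks
#'
#' Summarizes a set of attack curves (e.g. one per diet) by the area
#' under the loss curve (trapezoidal rule; higher AUC = less robust)
#' and the interpolated loss at chosen removal fractions, ranked from
#' most to least robust.
#'
#' @param curves named list of `robustness_curve` objects (same
#'   strategy).
#' @param fractions removal fractions to report (default 0.1, 0.3, 0.5).
#' @return data.frame with one row per network: `auc`,
#'   `loss_at_<fraction>` columns and `rank` (1 = most robust).
#' @export
compare_curves <- function(curves, fractions = c(0.1, 0.3, 0.5)) {
  stopifnot(length(names(curves)) == length(curves))
  rows <- lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    auc <- sum(diff(cv$f) * (utils::head(cv$L_pairs, -1) +
                               utils::tail(cv$L_pairs, -1)) / 2)
    losses <- loss_at(cv, fractions)
    out <- data.frame(network = nm, auc = auc)
    for (i in seq_along(fractions))
      out[[paste0("loss_at_", fractions[i])]] <- losses[i]
    out
  })
  out <- do.call(rbind, rows)
  out$rank <- rank(out$auc, ties.method = "min")
  out
}
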