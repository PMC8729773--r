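#' Aggregate an OTU table to taxonomic class level
#'
#' Sums relative abundances per class within each sample; rows sum to
#' 100 percent.
#'
#' @param table numeric count matrix, samples x OTUs.
#' @param taxonomy named character vector mapping OTU id to class label
#'   (OTUs without a label are pooled as `"Unclassified"`).
#' @return numeric matrix, samples x classes, rows summing to 100.
#' @export
aggregate_to_class <- function(table, taxonomy) {
  .assert_count_matrix(table)
  if (any(rowSums(table) == 0)) stop("empty sample(s) present")
  cls <- taxonomy[colnames(table)]
  cls[is.na(cls)] <- "Unclassified"
  rel <- 100 * table / rowSums(table)
  agg <- t(rowsum(t(rel), group = cls))
  agg[, order(colnames(agg)), drop = FALSE]
}

.stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Correlate an abundance vector with a covariate
#'
#' Pearson, Kendall and Spearman correlation tests (two-sided), with
#' significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param abundance numeric vector (e.g. a class's relative abundance
#'   across samples).
#' @param covariate numeric vector of the same length (e.g. a diet
#'   component replicated per sample).
#' @param methods subset of `c("pearson", "kendall", "spearman")`.
#' @return data.frame, one row per method, with `method`, `estimate`,
#'   `p_value`, `stars`.
#' @export
correlate <- function(abundance, covariate,
                      methods = c("pearson", "kendall", "spearman")) {
  stopifnot(length(abundance) == length(covariate))
  methods <- match.arg(methods, several.ok = TRUE)
  degenerate <- stats::sd(abundance) == 0 || stats::sd(covariate) == 0
  rows <- lapply(methods, function(m) {
    if (degenerate) {
      return(data.frame(method = m, estimate = NA_real_,
                        p_value = NA_real_, stars = "",
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(
      stats::cor.test(abundance, covariate, method = m, exact = FALSE))
    data.frame(method = m, estimate = unname(ct$estimate),
               p_value = ct$p.value, stars = .stars(ct$p.value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Class-by-covariate correlation grid
#'
#' Correlates every taxonomic class's relative abundance with every
#' covariate, per stage. Covariate values are replicated per sample
#' from its diet (each sample inherits its diet's component values), so
#' diet composition and class abundance are compared across samples.
#' Raw p-values carry the significance stars; a BH-adjusted column is
#' added as an extension.
#'
#' @param class_table samples x classes matrix (see
#'   [aggregate_to_class()]).
#' @param metadata data.frame with `sample`, `diet`, `stage` matching
#'   the rows of `class_table`.
#' @param diet_covariates data.frame with a `diet` column and one
#'   numeric column per covariate (e.g. moisture, protein, lipid...).
#' @param methods correlation methods, see [correlate()].
#' @return data.frame with columns `stage`, `class`, `covariate`,
#'   `method`, `estimate`, `p_value`, `stars`, `q_bh`.
#' @export
correlate_classes <- function(class_table, metadata, diet_covariates,
                              methods = c("pearson", "kendall", "spearman")) {
  stopifnot(nrow(class_table) == nrow(metadata),
            "diet" %in% names(diet_covariates))
  covs <- setdiff(names(diet_covariates), "diet")
  rows <- list()
  for (st in unique(metadata$stage)) {
    idx <- metadata$stage == st
    for (cl in colnames(class_table)) {
      ab <- class_table[idx, cl]
      for (cv in covs) {
        x <- diet_covariates[[cv]][match(metadata$diet[idx],
                                         diet_covariates$diet)]
        r <- correlate(ab, x, methods)
        r$stage <- st; r$class <- cl; r$covariate <- cv
        rows[[length(rows) + 1]] <- r
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q_bh <- stats::ave(out$p_value, out$stage, out$method,
                         FUN = function(p) stats::p.adjust(p, "BH"))
  out[, c("stage", "class", "covariate", "method", "estimate",
          "p_value", "stars", "q_bh")]
}
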