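# File formats and the end-to-end pipeline driver.

#' Read an OTU table from TSV
#'
#' Expects rows = OTUs with the id in the first column, one column per
#' sample, and optionally a final `taxonomy` column. Returns the table
#' in the internal orientation (samples x OTUs).
#'
#' @param path TSV file path.
#' @return numeric matrix samples x OTUs with a `taxonomy` attribute
#'   (named character vector or NULL).
#' @export
read_otu_table <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("OTU table needs an id column and at least one sample")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate OTU id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  tax <- NULL
  if (tolower(names(raw)[ncol(raw)]) == "taxonomy") {
    tax <- stats::setNames(as.character(raw[[ncol(raw)]]), ids)
    raw <- raw[, -ncol(raw), drop = FALSE]
  }
  num <- raw[, -1, drop = FALSE]
  for (cn in names(num)) {
    v <- suppressWarnings(as.numeric(num[[cn]]))
    bad <- which(is.na(v) & !is.na(num[[cn]]))
    if (length(bad))
      stop("non-numeric count in column '", cn, "', line ", bad[1] + 1)
    if (any(v < 0, na.rm = TRUE))
      stop("negative count in column '", cn, "', line ",
           which(v < 0)[1] + 1)
    num[[cn]] <- v
  }
  counts <- t(as.matrix(num))
  colnames(counts) <- ids
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id(s) in header")
  attr(counts, "taxonomy") <- tax
  counts
}

#' Write an OTU table to TSV
#'
#' Inverse of [read_otu_table()]: rows = OTUs, first column `otu`,
#' optional final `taxonomy` column.
#'
#' @param table numeric matrix samples x OTUs.
#' @param path output file.
#' @param taxonomy optional named taxonomy vector per OTU.
#' @return invisibly, `path`.
#' @export
write_otu_table <- function(table, path, taxonomy = NULL) {
  out <- data.frame(otu = colnames(table), t(table),
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(taxonomy)) out$taxonomy <- unname(taxonomy[colnames(table)])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Expects columns `sample`, `diet`, `stage`; sample ids must be unique
#' and no field may be missing. When vocabularies are supplied, diet
#' and stage labels are validated against them.
#'
#' @param path TSV file path.
#' @param diets optional allowed diet labels.
#' @param stages optional allowed stage labels.
#' @return data.frame with columns `sample`, `diet`, `stage`.
#' @export
read_metadata <- function(path, diets = NULL, stages = NULL) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "diet", "stage")
  if (!all(need %in% names(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  md <- md[need]
  if (anyDuplicated(md$sample))
    stop("duplicate sample id(s): ",
         paste(unique(md$sample[duplicated(md$sample)]), collapse = ", "))
  if (any(is.na(md)) || any(md == ""))
    stop("metadata contains missing values")
  if (!is.null(diets) && !all(md$diet %in% diets))
    stop("unknown diet label(s): ",
         paste(setdiff(md$diet, diets), collapse = ", "))
  if (!is.null(stages) && !all(md$stage %in% stages))
    stop("unknown stage label(s): ",
         paste(setdiff(md$stage, stages), collapse = ", "))
  md
}

#' Read bioassay records from CSV
#'
#' @param path CSV with columns `diet`, `W`, `R`, `B`, `days`.
#' @return validated data.frame.
#' @export
read_bioassay <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("diet", "W", "R", "B", "days")
  if (!all(need %in% names(rec)))
    stop("bioassay file must have columns: ", paste(need, collapse = ", "))
  if (any(rec$W <= 0 | rec$R < 0 | rec$R > rec$W | rec$B < 0 | rec$days < 1))
    stop("bioassay records violate W > 0, 0 <= R <= W, B >= 0, days >= 1")
  rec[need]
}

#' Export a network to GraphML
#'
#' Writes the network with its node attributes (abundance, taxonomy,
#' module) and edge attributes (sign, q) in GraphML, readable by
#' Cytoscape/Gephi and by [igraph::read_graph()].
#'
#' @param network a `coocc_network` or igraph object.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_graphml <- function(network, path) {
  g <- .as_graph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a pipeline report
#'
#' Serializes every result component: data frames as CSV, scalar
#' summaries as a single JSON file, networks as GraphML.
#'
#' @param results named list (data.frames, networks, scalars/lists).
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  scalars <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "coocc_network") || inherits(x, "igraph")) {
      f <- file.path(dir, paste0(nm, ".graphml"))
      write_graphml(x, f); files <- c(files, f)
    } else if (is.data.frame(x)) {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(x, f, row.names = FALSE); files <- c(files, f)
    } else {
      scalars[[nm]] <- x
    }
  }
  if (length(scalars)) {
    f <- file.path(dir, "summary.json")
    jsonlite::write_json(scalars, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Run the full analysis pipeline
#'
#' Orders the stages as the analysis design dictates: diversity
#' (Bray-Curtis, PCoA, dispersion per stage), beta-diversity
#' partitioning, per-diet network inference over the whole life span,
#' topology and keystones, robustness, and (when bioassay records are
#' given) bioconversion metrics. Deterministic given the configuration
#' and seed.
#'
#' @param counts numeric matrix samples x OTUs, or path to an OTU TSV.
#' @param metadata data.frame (`sample`, `diet`, `stage`) or path to a
#'   metadata TSV; row order must match `counts`.
#' @param taxonomy optional named taxonomy vector (overrides any
#'   taxonomy read from the OTU file).
#' @param bioassay optional data.frame or CSV path of bioassay records.
#' @param out_dir optional output directory; when given, every result
#'   is written via [write_report()].
#' @param seed global integer seed.
#' @param n_perm permutations for dispersion/component tests and the
#'   network null.
#' @param n_boot bootstrap resamples for network edge stability.
#' @param n_candidates candidate edges per method.
#' @param min_prevalence network prevalence filter.
#' @param alpha BH threshold for network edges.
#' @param attack_strategies robustness strategies to run per diet.
#' @return named list of results (also written to `out_dir` if given).
#' @export
run_pipeline <- function(counts, metadata, taxonomy = NULL, bioassay = NULL,
                         out_dir = NULL, seed = 1, n_perm = 999,
                         n_boot = 199, n_candidates = 1000,
                         min_prevalence = 1 / 3, alpha = 0.05,
                         attack_strategies = c("cascading", "betweenness")) {
  if (is.character(counts)) counts <- read_otu_table(counts)
  if (is.null(taxonomy)) taxonomy <- attr(counts, "taxonomy")
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  stopifnot(nrow(counts) == nrow(metadata))
  if (!is.null(rownames(counts)) &&
      !identical(rownames(counts), metadata$sample))
    counts <- counts[metadata$sample, , drop = FALSE]
  results <- list()
  # drop OTUs absent everywhere
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  # per-stage diversity and partitioning
  for (st in unique(metadata$stage)) {
    idx <- metadata$stage == st
    tab <- counts[idx, , drop = FALSE]
    diets <- metadata$diet[idx]
    d <- bray_curtis(tab)
    ord <- pcoa(d)
    disp <- permdisp(d, diets, n_perm = n_perm, seed = seed)
    gt <- group_triplets(tab, diets)
    repl_test <- test_component_difference(gt$pairs$replacement,
                                           gt$pairs$group,
                                           n_perm = n_perm, seed = seed)
    results[[paste0("ordination_", st)]] <-
      data.frame(sample = ord$labels, ord$vectors[, seq_len(
        min(2, ncol(ord$vectors))), drop = FALSE], diet = diets)
    results[[paste0("dispersion_", st)]] <- list(
      group_means = as.list(disp$group_means),
      f_statistic = disp$f_statistic, df = disp$df,
      p_permutation = disp$p_permutation,
      letters = as.list(disp$letters))
    results[[paste0("beta_pairs_", st)]] <- gt$pairs
    results[[paste0("beta_means_", st)]] <-
      cbind(group = rownames(gt$means), gt$means)
    results[[paste0("replacement_test_", st)]] <- repl_test
    results[[paste0("alpha_", st)]] <- data.frame(
      sample = rownames(tab), richness = richness(tab),
      goods_coverage = goods_coverage(tab), diet = diets)
  }
  if (length(unique(metadata$diet)) == 3) {
    results$ternary <- ternary_coordinates(counts, metadata$diet)
  }
  # per-diet networks over the whole life span
  nets <- infer_networks_by_group(counts, metadata$diet,
                                  taxonomy = taxonomy,
                                  min_prevalence = min_prevalence,
                                  n_candidates = n_candidates,
                                  n_perm = n_perm, n_boot = n_boot,
                                  alpha = alpha, seed = seed)
  nets <- lapply(nets, detect_modules, seed = seed)
  graphs_nonempty <- vapply(nets, function(nw)
    igraph::vcount(nw$graph) > 0, logical(1))
  if (any(graphs_nonempty))
    results$topology <- topology_table(nets[graphs_nonempty])
  for (d in names(nets)) {
    results[[paste0("network_", d)]] <- nets[[d]]
    results[[paste0("edges_", d)]] <- nets[[d]]$edges
    hk <- classify_hubs_keystones(nets[[d]])
    results[[paste0("keystones_", d)]] <- list(
      hubs = hk$hubs, keystones = hk$keystones,
      keystone_taxonomy = if (is.null(hk$keystone_taxonomy)) "unavailable"
        else as.list(as.numeric(hk$keystone_taxonomy)))
  }
  curves <- list()
  for (d in names(nets)[graphs_nonempty]) {
    if (igraph::vcount(nets[[d]]$graph) < 2 ||
        igraph::ecount(nets[[d]]$graph) == 0) next
    for (strat in attack_strategies) {
      cv <- attack(nets[[d]], strategy = strat, seed = seed)
      results[[paste0("robustness_", d, "_", strat)]] <- as.data.frame(cv)
      if (strat == attack_strategies[1]) curves[[d]] <- cv
    }
  }
  if (length(curves) >= 2) results$robustness_comparison <- compare_curves(curves)
  if (!is.null(bioassay)) {
    if (is.character(bioassay)) bioassay <- read_bioassay(bioassay)
    results$bioassay_summary <- bioassay_summary(bioassay)
    results$diet_energy_restriction <-
      as.list(diet_energy_restriction())
  }
  if (!is.null(out_dir)) write_report(results, out_dir)
  results
}
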