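## Community statistics for inoculated vs uninoculated plants: relative
## abundance, Bray-Curtis dissimilarity, principal coordinates, ANOSIM,
## per-OTU Kruskal-Wallis, displacement of the natural microbiota by the
## synthetic community, and the biomass response. Standard computations
## are delegated to vegan / base stats; this file owns the experiment
## bookkeeping around them.

#' Relative abundance table
#'
#' @param table counts matrix, samples as rows; every row sum must be > 0
#' @return matrix of fractions, rows summing to 1
#' @export
relative_abundance <- function(table) {
  rs <- rowSums(table)
  if (any(rs <= 0))
    stop_cbc("zero-sum sample(s): %s",
             paste(rownames(table)[rs <= 0], collapse = ", "))
  table / rs
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = 1 - 2 * sum(min(x, y)) / sum(x + y)`, computed with
#' `vegan::vegdist`.
#'
#' @param rel_table relative-abundance matrix, samples as rows
#' @return symmetric matrix with zero diagonal, values in `[0, 1]`
#' @export
bray_curtis <- function(rel_table) {
  as.matrix(vegan::vegdist(rel_table, method = "bray"))
}

#' Principal coordinates analysis
#'
#' Gower-centred eigendecomposition (via `stats::cmdscale`); axes are
#' scaled by the square roots of the positive eigenvalues and the
#' proportion explained is relative to the positive-eigenvalue total.
#'
#' @param d dissimilarity matrix or `dist`
#' @param k maximum number of axes (default: all positive)
#' @return list: `coordinates`, `eigenvalues` (all, negatives included),
#'   `proportion_explained` (over positive axes)
#' @export
pcoa_ordination <- function(d, k = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop_cbc("PCoA needs at least 3 samples")
  if (is.null(k)) k <- n - 1
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE))
  eig <- fit$eig
  pos <- eig > 1e-10
  coords <- fit$points[, seq_len(min(sum(pos), ncol(fit$points))),
                       drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = eig,
       proportion_explained = eig[pos][seq_len(ncol(coords))] /
         sum(eig[pos]))
}

#' Analysis of similarity (ANOSIM)
#'
#' Rank-based permutation test of between- vs within-group dissimilarity
#' (`vegan::anosim`); the permutation p-value carries the +1 correction.
#'
#' @param d dissimilarity matrix
#' @param groups group labels, one per sample (>= 2 groups of >= 2)
#' @param n_perm number of permutations (default 999)
#' @param seed integer seed for the permutations
#' @return list of class `cbc_test`: `statistic` (R), `p_value`,
#'   `n_permutations`
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2 || any(table(groups) < 2))
    stop_cbc("ANOSIM needs >= 2 groups with >= 2 samples each")
  set.seed(seed)
  fit <- vegan::anosim(stats::as.dist(as.matrix(d)), groups,
                       permutations = n_perm)
  structure(list(statistic = unname(fit$statistic),
                 p_value = fit$signif, n_permutations = n_perm,
                 method = "ANOSIM"), class = "cbc_test")
}

#' Kruskal-Wallis test on one variable
#'
#' Tie-corrected H with a chi-square p-value (base
#' `stats::kruskal.test`); identical values across all groups give
#' `H = 0`, `p = 1`.
#'
#' @param values numeric vector
#' @param groups group labels
#' @return list of class `cbc_test`: `statistic` (H), `p_value`, `df`
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2 || length(values) < 3)
    stop_cbc("Kruskal-Wallis needs >= 2 groups and n >= 3")
  if (length(unique(values)) == 1L)
    return(structure(list(statistic = 0, p_value = 1,
                          df = nlevels(droplevels(groups)) - 1,
                          method = "Kruskal-Wallis"), class = "cbc_test"))
  fit <- stats::kruskal.test(values, groups)
  structure(list(statistic = unname(fit$statistic),
                 p_value = fit$p.value, df = unname(fit$parameter),
                 method = "Kruskal-Wallis"), class = "cbc_test")
}

#' Per-OTU Kruskal-Wallis screen
#'
#' Applies [kruskal_wallis()] to every OTU column of a relative-abundance
#' table. Significance is called at unadjusted `p < alpha` (an optional
#' Benjamini-Hochberg flag is provided but off by default).
#'
#' @param rel_table relative-abundance matrix, samples as rows
#' @param groups group labels per sample
#' @param alpha significance level (default 0.05)
#' @param adjust apply BH-FDR before calling significance (default FALSE)
#' @return list: `results` (data frame `otu_id`, `H`, `p_value`,
#'   `significant`), `significant` (OTU ids)
#' @export
per_otu_kw <- function(rel_table, groups, alpha = 0.05, adjust = FALSE) {
  res <- do.call(rbind, lapply(colnames(rel_table), function(otu) {
    t <- kruskal_wallis(rel_table[, otu], groups)
    data.frame(otu_id = otu, H = t$statistic, p_value = t$p_value,
               stringsAsFactors = FALSE)
  }))
  p_use <- if (adjust) stats::p.adjust(res$p_value, "BH") else res$p_value
  res$significant <- p_use < alpha
  list(results = res, significant = res$otu_id[res$significant])
}

#' Displacement of the natural microbiota by the synthetic community
#'
#' Sums the relative abundance of the OTUs matched to synthetic-community
#' members, per habitat and treatment group, and identifies efficient
#' colonizers (per-OTU KW `p < alpha` with higher median relative
#' abundance in inoculated samples).
#'
#' @param rel_table relative-abundance matrix, samples as rows
#' @param syncom_otu_ids OTU columns matched to community members
#' @param groups treatment labels per sample
#' @param habitats habitat labels per sample
#' @param alpha significance level for the colonizer screen
#' @return list: `summary` (data frame `habitat`, `group`,
#'   `syncom_abundance_pct`), `per_sample` (named numeric sums),
#'   `colonizers` (OTU ids)
#' @export
displacement_summary <- function(rel_table, syncom_otu_ids, groups,
                                 habitats, alpha = 0.05) {
  found <- intersect(syncom_otu_ids, colnames(rel_table))
  if (!length(found)) {
    warning("no synthetic-community OTU found in the table", call. = FALSE)
    per_sample <- stats::setNames(rep(0, nrow(rel_table)),
                                  rownames(rel_table))
  } else {
    per_sample <- rowSums(rel_table[, found, drop = FALSE])
  }
  cells <- expand.grid(habitat = unique(habitats),
                       group = unique(groups),
                       stringsAsFactors = FALSE)
  cells$syncom_abundance_pct <- mapply(function(h, g) {
    sel <- habitats == h & groups == g
    100 * mean(per_sample[sel])
  }, cells$habitat, cells$group)
  colonizers <- character(0)
  if (length(found)) {
    kw <- per_otu_kw(rel_table[, found, drop = FALSE], groups,
                     alpha = alpha)
    for (otu in kw$significant) {
      med <- tapply(rel_table[, otu], groups, median)
      if (!is.na(med["inoculated"]) &&
          med[["inoculated"]] > med[["uninoculated"]])
        colonizers <- c(colonizers, otu)
    }
  }
  list(summary = cells, per_sample = per_sample, colonizers = colonizers)
}

#' Biomass response to inoculation
#'
#' @param weights data frame with columns `treatment`
#'   (inoculated/uninoculated) and `weight` (grams per plant)
#' @param test `"welch"` (default) or `"wilcoxon"`
#' @return list: `mean_inoculated`, `mean_uninoculated`, `fold_change`
#'   (1 decimal), `p_value`
#' @export
growth_response <- function(weights, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  w_in <- weights$weight[weights$treatment == "inoculated"]
  w_un <- weights$weight[weights$treatment == "uninoculated"]
  if (length(w_in) < 2 || length(w_un) < 2)
    stop_cbc("growth_response needs >= 2 plants per group")
  if (mean(w_un) == 0) stop_cbc("zero uninoculated mean weight")
  p <- if (identical(w_in, w_un)) 1 else if (test == "welch") {
    # constant groups break the t statistic; report NA rather than fail
    tryCatch(stats::t.test(w_in, w_un)$p.value, error = function(e)
      NA_real_)
  } else {
    stats::wilcox.test(w_in, w_un, exact = FALSE)$p.value
  }
  list(mean_inoculated = mean(w_in), mean_uninoculated = mean(w_un),
       fold_change = round(mean(w_in) / mean(w_un), 1), p_value = p)
}

#' @export
print.cbc_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.3f, p = %.4g\n", x$method %||% "test",
              x$statistic, x$p_value))
  invisible(x)
}
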