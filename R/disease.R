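#' Split query cells into low- and high-uncertainty strata
#'
#' Cells of a transferred type are partitioned into a low-uncertainty
#' stratum (below `low_max`), a high-uncertainty stratum (above
#' `high_min`) and an excluded middle band. The high stratum is where
#' disease-shifted states concentrate, since their neighbourhoods mix
#' reference annotations.
#'
#' @param result A [knn_transfer()] result (or a bare numeric vector of
#'   uncertainties).
#' @param low_max Upper bound (exclusive) of the low stratum (default
#'   0.2).
#' @param high_min Lower bound (exclusive) of the high stratum (default
#'   0.4).
#' @return List of integer index vectors `low`, `high`, `excluded`.
#' @export
uncertainty_strata <- function(result, low_max = 0.2, high_min = 0.4) {
  u <- if (inherits(result, "transfer_result"))
    result$table$uncertainty else as.numeric(result)
  low <- which(u < low_max)
  high <- which(u > high_min)
  if (!length(low) || !length(high))
    stop(sprintf("empty stratum: %d low (< %g), %d high (> %g)",
                 length(low), low_max, length(high), high_min))
  list(low = low, high = high,
       excluded = setdiff(seq_along(u), c(low, high)))
}

#' Disease signature genes from uncertainty strata
#'
#' Wilcoxon rank-sum test of high- versus low-uncertainty cells per
#' gene; genes with Benjamini-Hochberg adjusted p above `fdr` or mean
#' expression in the high stratum below `min_mean_high` are dropped, and
#' the `top_n` most upregulated genes by log-fold change are returned.
#'
#' @param expr_norm Log-normalized expression matrix (cells x genes).
#' @param low,high Index vectors from [uncertainty_strata()].
#' @param top_n Signature size (default 20).
#' @param fdr Adjusted-p cutoff (default 0.05).
#' @param min_mean_high Minimum mean expression in the high stratum
#'   (default 0.1).
#' @return Character vector of at most `top_n` genes (fewer, with a
#'   warning, when fewer survive), ordered by decreasing log-fold
#'   change.
#' @export
signature_genes <- function(expr_norm, low, high, top_n = 20, fdr = 0.05,
                            min_mean_high = 0.1) {
  res <- wilcox_test_cols(expr_norm, high, low)
  padj <- stats::p.adjust(res$p, method = "BH")
  keep <- padj <= fdr & res$lfc > 0 & res$mean_in >= min_mean_high
  keep[is.na(keep)] <- FALSE
  genes <- rownames(res)[keep][order(res$lfc[keep], decreasing = TRUE)]
  if (length(genes) < top_n)
    warning("only ", length(genes), " genes survive the filters")
  utils::head(genes, top_n)
}

#' Binned-control signature score per cell
#'
#' Genes are binned by their atlas-wide mean expression into `n_bins`
#' equal-size bins; for each signature gene, `ctrl_per_bin` control
#' genes are drawn from the same bin (excluding signature genes). The
#' score is the mean expression of the signature genes minus the mean
#' expression of the pooled control genes, so expression magnitude is
#' controlled for.
#'
#' @param expr_norm Log-normalized expression matrix (cells x genes).
#' @param gene_set Character vector of signature genes.
#' @param n_bins Number of expression bins (default 25).
#' @param ctrl_per_bin Control genes sampled per signature gene (default
#'   50).
#' @param seed Sampling seed.
#' @return Numeric vector of per-cell scores.
#' @export
score_cells <- function(expr_norm, gene_set, n_bins = 25, ctrl_per_bin = 50,
                        seed = 0L) {
  genes <- colnames(expr_norm)
  missing <- setdiff(gene_set, genes)
  if (length(missing)) stop("gene_set not in matrix: ",
                            paste(missing, collapse = ", "))
  avg <- Matrix::colMeans(expr_norm)
  bins <- cut(rank(avg, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  names(bins) <- genes
  set.seed(seed)
  ctrl <- character()
  for (g in gene_set) {
    pool <- genes[bins == bins[g]]
    pool <- setdiff(pool, gene_set)
    if (!length(pool)) {
      warning("no control genes available in bin of ", g)
      next
    }
    replace <- length(pool) < ctrl_per_bin
    if (replace) warning("bin of ", g, " has only ", length(pool),
                         " controls; sampling with replacement")
    ctrl <- c(ctrl, sample(pool, ctrl_per_bin, replace = replace))
  }
  ctrl <- unique(ctrl)
  sig_mean <- Matrix::rowMeans(expr_norm[, gene_set, drop = FALSE])
  ctrl_mean <- if (length(ctrl))
    Matrix::rowMeans(expr_norm[, ctrl, drop = FALSE]) else 0
  as.numeric(sig_mean - ctrl_mean)
}

#' Filtered per-cluster differential expression
#'
#' Raw counts are normalized to `target_sum` per cell (the source
#' atlas's median total, 7,666, by default) and log transformed; a
#' Wilcoxon rank-sum test compares the target cluster against all other
#' cells, and genes are kept only when expressed (count > 0) in at least
#' `min_in` of the cluster's cells, in at most `max_out` of the cells
#' outside it, and significant at BH-adjusted p <= `fdr`.
#'
#' @param atlas An [atlas_table()] (raw counts).
#' @param clusters Cluster ids per cell.
#' @param target_cluster Cluster of interest (>= 20 cells).
#' @param min_in,max_out Expressing-fraction bounds (defaults 0.3 and
#'   0.2).
#' @param fdr Adjusted-p cutoff (default 0.05).
#' @param target_sum Per-cell total for normalization (default 7666).
#' @return List: `table` (per-gene `gene`, `stat`, `p`, `padj`, `lfc`,
#'   `frac_in`, `frac_out`) and `genes` (the survivors, by decreasing
#'   log-fold change).
#' @export
cluster_de_filtered <- function(atlas, clusters, target_cluster,
                                min_in = 0.3, max_out = 0.2, fdr = 0.05,
                                target_sum = 7666) {
  stopifnot(inherits(atlas, "atlas_table"))
  in_idx <- which(clusters == target_cluster)
  out_idx <- which(clusters != target_cluster)
  if (length(in_idx) < 20) stop("target cluster has fewer than 20 cells")
  expr <- lognormalize(atlas, target_sum = target_sum)
  res <- wilcox_test_cols(expr, in_idx, out_idx)
  frac_in <- Matrix::colMeans(atlas$counts[in_idx, , drop = FALSE] > 0)
  frac_out <- Matrix::colMeans(atlas$counts[out_idx, , drop = FALSE] > 0)
  tab <- data.frame(gene = rownames(res), stat = res$stat, p = res$p,
                    padj = stats::p.adjust(res$p, method = "BH"),
                    lfc = res$lfc, frac_in = frac_in, frac_out = frac_out,
                    row.names = NULL, stringsAsFactors = FALSE)
  keep <- tab$frac_in >= min_in & tab$frac_out <= max_out &
    tab$padj <= fdr & tab$lfc > 0
  genes <- tab$gene[keep][order(tab$lfc[keep], decreasing = TRUE)]
  list(table = tab, genes = genes)
}

#' Drop donor-dominated clusters from differential expression
#'
#' Clusters whose donor entropy falls strictly below `entropy_max`
#' (by default the donor-entropy threshold for the observed number of
#' donors) are excluded: their states cannot be distinguished from
#' donor-specific biology or residual batch effect. A cluster exactly at
#' the threshold is kept.
#'
#' @param clusters Cluster ids per cell.
#' @param donors Donor ids per cell.
#' @param entropy_max Donor-entropy threshold; default derives from
#'   [entropy_thresholds()] with `dominance` and the observed donor
#'   count.
#' @param dominance Dominant-donor fraction used for the default
#'   threshold (default 0.95).
#' @return Character vector of surviving cluster ids.
#' @export
exclude_single_donor_clusters <- function(clusters, donors,
                                          entropy_max = NULL,
                                          dominance = 0.95) {
  if (is.null(entropy_max)) {
    n_donors <- length(unique(donors))
    entropy_max <- entropy_thresholds(donor_majority = dominance,
                                      n_donors = n_donors)$donor_threshold
  }
  rep_ <- cluster_entropies(clusters, rep("none", length(clusters)), donors,
                            min_labeled_frac = 0)
  rep_$cluster[!(rep_$donor_entropy < entropy_max)]
}
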