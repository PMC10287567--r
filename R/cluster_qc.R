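#' Shannon entropy of a proportion vector
#'
#' Natural-log Shannon entropy \eqn{-\sum_i p_i \log p_i} with the
#' convention \eqn{0 \log 0 = 0}. This is the statistic behind both the
#' label-disagreement and donor-diversity cluster scores.
#'
#' @param proportions Non-negative numeric vector summing to 1 (within
#'   1e-9).
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(proportions) {
  if (any(proportions < 0)) stop("proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1 (got ", sum(proportions), ")")
  p <- proportions[proportions > 0]
  -sum(p * log(p))
}

entropy_of_counts <- function(x) {
  x <- x[x > 0]
  if (!length(x)) return(NA_real_)
  shannon_entropy(x / sum(x))
}

#' Entropy thresholds for flagging clusters
#'
#' The high-label-entropy threshold is the entropy of a hypothetical
#' cluster where a fraction `label_split` of cells carries one label and
#' the rest a second label; clusters above it show substantial annotation
#' disagreement. The low-donor-entropy threshold is the entropy of a
#' cluster with `donor_majority` of cells from one donor and the
#' remainder spread uniformly over the other `n_donors - 1` donors;
#' clusters below it are donor-dominated. At the defaults with 107 donors
#' these round to 0.56 and 0.43.
#'
#' @param label_split Majority-label fraction defining the label
#'   threshold (default 0.75).
#' @param donor_majority Dominant-donor fraction defining the donor
#'   threshold (default 0.95).
#' @param n_donors Number of donors in the atlas.
#' @return Named list `label_threshold`, `donor_threshold` (nats).
#' @export
entropy_thresholds <- function(label_split = 0.75, donor_majority = 0.95,
                               n_donors) {
  stopifnot(n_donors >= 2)
  label_thr <- shannon_entropy(c(label_split, 1 - label_split))
  rest <- rep((1 - donor_majority) / (n_donors - 1), n_donors - 1)
  donor_thr <- shannon_entropy(c(donor_majority, rest))
  list(label_threshold = label_thr, donor_threshold = donor_thr)
}

#' Per-cluster label and donor entropies
#'
#' Label entropy is computed over labeled cells only (cells without a
#' label at the evaluated level are excluded) and reported as `NA` when
#' fewer than `min_labeled_frac` of the cluster's cells are labeled.
#' Donor entropy uses all cells.
#'
#' @param clusters Character/factor vector of cluster ids per cell.
#' @param labels Character vector of labels per cell at the evaluated
#'   level, with `"none"` marking unlabeled cells.
#' @param donors Character vector of donor ids per cell.
#' @param min_labeled_frac Labeled fraction below which label entropy is
#'   `NA` (default 0.2).
#' @param thresholds Optional output of [entropy_thresholds()]; when
#'   given, flag columns are filled.
#' @return Data.frame per cluster: `cluster`, `n_cells`, `labeled_frac`,
#'   `label_entropy`, `donor_entropy`, `high_label_entropy`,
#'   `low_donor_entropy`.
#' @export
cluster_entropies <- function(clusters, labels, donors,
                              min_labeled_frac = 0.2, thresholds = NULL) {
  stopifnot(length(clusters) == length(labels),
            length(clusters) == length(donors))
  ids <- sort(unique(as.character(clusters)))
  out <- lapply(ids, function(cl) {
    in_cl <- clusters == cl
    if (!any(in_cl)) stop("empty cluster: ", cl)
    lab <- labels[in_cl]
    labeled <- lab != "none" & !is.na(lab)
    lf <- mean(labeled)
    le <- if (lf < min_labeled_frac) NA_real_ else
      entropy_of_counts(table(lab[labeled]))
    de <- entropy_of_counts(table(donors[in_cl]))
    data.frame(cluster = cl, n_cells = sum(in_cl), labeled_frac = lf,
               label_entropy = le, donor_entropy = de,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(thresholds)) {
    out$high_label_entropy <- !is.na(out$label_entropy) &
      out$label_entropy > thresholds$label_threshold
    out$low_donor_entropy <- out$donor_entropy < thresholds$donor_threshold
  }
  out
}

# ---- clustering -----------------------------------------------------------

# kNN graph (undirected union of directed kNN edges, unit weights) +
# Leiden community detection; seeded for determinism.
leiden_partition <- function(embedding, k, resolution, seed) {
  n <- nrow(embedding)
  if (n <= k + 1) return(rep(0L, n))
  nn <- knn_search(embedding, embedding, k + 1L)
  from <- rep(seq_len(n), k)
  to <- as.vector(nn$index[, -1, drop = FALSE])  # drop self
  el <- cbind(pmin(from, to), pmax(from, to))
  el <- unique(el)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  set.seed(seed)
  memb <- igraph::membership(igraph::cluster_leiden(
    g, objective_function = "modularity",
    resolution = resolution, n_iterations = 5))
  as.integer(memb) - 1L
}

# relabel cluster ids 0,1,2,... by decreasing size (ties by old id)
rank_by_size <- function(memb) {
  tab <- sort(table(memb), decreasing = TRUE)
  stats::setNames(seq_along(tab) - 1L, names(tab))[as.character(memb)]
}

#' Nested Leiden clustering of an integrated embedding
#'
#' Level 1 clusters the full embedding; each deeper level recomputes the
#' kNN graph *within* every parent cluster and partitions it again.
#' Cluster ids are dot-separated paths ("1.2" is the third biggest
#' subcluster, counting from 0, of cluster 1), with siblings numbered by
#' decreasing size. Clusters smaller than `k + 1` at a level are left
#' unsplit. The default schedule is k = 30 with resolution 0.01 at level
#' 1, then k = 30, 15, 10, 10 with resolution 0.2 at levels 2-5.
#'
#' @param embedding Numeric matrix, cells x latent dimensions.
#' @param schedule List of `c(k, resolution)` pairs, one per level.
#' @param seed Integer seed controlling the community detection.
#' @return Character vector of hierarchical cluster ids per cell, with
#'   the schedule stored in attribute `"schedule"`.
#' @export
nested_cluster <- function(embedding,
                           schedule = list(c(30, 0.01), c(30, 0.2),
                                           c(15, 0.2), c(10, 0.2),
                                           c(10, 0.2)),
                           seed = 0L) {
  stopifnot(length(schedule) >= 1)
  embedding <- as.matrix(embedding)
  if (!all(is.finite(embedding))) stop("non-finite embedding coordinates")
  n <- nrow(embedding)
  lv <- schedule[[1]]
  memb <- leiden_partition(embedding, lv[1], lv[2], seed)
  ids <- as.character(rank_by_size(memb))
  if (length(schedule) > 1) {
    for (level in 2:length(schedule)) {
      lv <- schedule[[level]]
      new_ids <- ids
      for (parent in sort(unique(ids))) {
        rows <- which(ids == parent)
        if (length(rows) <= lv[1] + 1) next  # too small to split; keep as-is
        sub <- leiden_partition(embedding[rows, , drop = FALSE],
                                lv[1], lv[2], seed + level)
        new_ids[rows] <- paste(parent, rank_by_size(sub), sep = ".")
      }
      ids <- new_ids
    }
  }
  attr(ids, "schedule") <- schedule
  ids
}

#' Cluster id truncated to a coarser level
#'
#' @param ids Hierarchical cluster ids from [nested_cluster()].
#' @param level Depth to truncate to (1 = coarsest).
#' @return Character vector of truncated ids.
#' @export
cluster_at_level <- function(ids, level) {
  vapply(strsplit(as.character(ids), ".", fixed = TRUE), function(p) {
    paste(p[seq_len(min(level, length(p)))], collapse = ".")
  }, character(1))
}

# ---- doublets -------------------------------------------------------------

# per-cell mean expression of a marker set
module_expression <- function(expr, genes) {
  genes <- intersect(genes, colnames(expr))
  Matrix::rowSums(expr[, genes, drop = FALSE]) / length(genes)
}

#' Flag candidate doublet clusters
#'
#' A cluster is a doublet candidate when it (a) shows high label entropy
#' at the coarsest annotation level, (b) is small (at most `max_size`
#' cells) and (c) simultaneously expresses marker modules of two or more
#' distinct top-level lineages. A lineage counts as expressed when the
#' cluster's mean module expression reaches at least `pos_frac` of the
#' maximal cluster-level mean for that module — doublets formed by
#' averaging two parents sit near half the pure clusters' level, well
#' above this bar, while cross-lineage leakage in pure clusters stays
#' far below it.
#'
#' @param report Output of [cluster_entropies()] computed on level-1
#'   labels with thresholds, i.e. carrying `high_label_entropy`.
#' @param clusters Cluster ids per cell (same clustering as `report`).
#' @param lineage_markers Named list, lineage -> character vector of
#'   marker genes; at least two lineages.
#' @param expr Log-normalized expression matrix (cells x genes).
#' @param max_size Maximum cluster size to consider (default 1% of
#'   cells).
#' @param pos_frac Fraction of the maximal cluster module mean counting
#'   as expressed (default 0.25).
#' @return `report` with added `n_lineages_positive` and logical
#'   `doublet_candidate` columns.
#' @export
flag_doublet_clusters <- function(report, clusters, lineage_markers, expr,
                                  max_size = ceiling(0.01 * length(clusters)),
                                  pos_frac = 0.25) {
  if (length(lineage_markers) < 2)
    stop("markers for at least two lineages required")
  if (is.null(report$high_label_entropy))
    stop("report must carry high_label_entropy flags (pass thresholds)")
  scores <- lapply(lineage_markers, function(g) {
    missing <- setdiff(g, colnames(expr))
    if (length(missing))
      warning("dropping markers absent from matrix: ",
              paste(missing, collapse = ", "))
    module_expression(expr, g)
  })
  cluster_means <- vapply(scores, function(s)
    vapply(report$cluster, function(cl) mean(s[clusters == cl]), numeric(1)),
    numeric(nrow(report)))
  cluster_means <- matrix(cluster_means, nrow = nrow(report))
  peak <- apply(cluster_means, 2, max)
  positive <- sweep(cluster_means, 2, pmax(peak, 1e-12), "/") >= pos_frac
  report$n_lineages_positive <- rowSums(positive)
  report$doublet_candidate <- report$high_label_entropy &
    report$n_cells <= max_size & report$n_lineages_positive >= 2
  report
}

# ---- rare cell types ------------------------------------------------------

#' Per-cluster precision and recall for a rare cell type
#'
#' Recall is the fraction of all cells labeled as the rare type that fall
#' in the cluster; precision is the fraction of the cluster labeled as
#' the rare type.
#'
#' @param clusters Cluster ids per cell.
#' @param labels Labels per cell.
#' @param rare_label The label of interest (must occur at least once).
#' @return List: `table` (data.frame cluster, n, n_rare, precision,
#'   recall) and `best` (the max-recall cluster id).
#' @export
rare_type_pr <- function(clusters, labels, rare_label) {
  is_rare <- labels == rare_label
  if (!any(is_rare)) stop("rare_label not present: ", rare_label)
  ids <- sort(unique(as.character(clusters)))
  tab <- do.call(rbind, lapply(ids, function(cl) {
    in_cl <- clusters == cl
    data.frame(cluster = cl, n = sum(in_cl), n_rare = sum(in_cl & is_rare),
               stringsAsFactors = FALSE)
  }))
  tab$precision <- tab$n_rare / tab$n
  tab$recall <- tab$n_rare / sum(is_rare)
  list(table = tab, best = tab$cluster[which.max(tab$recall)])
}

# ---- recovery of externally annotated label sets --------------------------

# selection among candidate clusters: max recall unless it costs >33% of
# the runner-up's precision; a runner-up that doubles precision while
# losing <=20% recall wins outright
select_candidate_cluster <- function(cand) {
  if (!nrow(cand)) return(NULL)
  cand <- cand[order(-cand$recall, -cand$precision), , drop = FALSE]
  best <- cand[1, ]
  if (nrow(cand) >= 2) {
    second <- cand[2, ]
    if (second$precision >= 2 * best$precision &&
        second$recall >= 0.8 * best$recall) return(second)
    if (best$precision < (1 - 1 / 3) * second$precision) return(second)
  }
  best
}

#' Search multiple clustering resolutions for a cluster capturing a
#' target label set
#'
#' Used to test whether cells carrying an annotation absent from the
#' reference (e.g. spatially derived cell types in a mapped dataset) are
#' recovered as their own cluster after joint embedding. The embedding is
#' clustered at each resolution (k = 30 below resolution 25, k = 15 at or
#' above, so that very small clusters become detectable); clusters
#' reaching both minimum recall and minimum precision are candidates, and
#' the final choice follows the recall/precision trade-off rule of
#' `select_candidate_cluster` applied to the candidate with the highest
#' recall across all resolutions.
#'
#' Precision is evaluated among `query_mask` cells only (the dataset that
#' carries the annotation), recall over all `target_labels` cells.
#'
#' @param embedding Joint embedding matrix (cells x d).
#' @param query_mask Logical vector: cells belonging to the annotated
#'   query dataset.
#' @param target_labels Logical vector: cells carrying the target
#'   annotation (subset of the query).
#' @param resolutions Numeric vector of Leiden resolutions to scan.
#' @param min_recall,min_precision Candidate thresholds (default 0.25).
#' @param seed Clustering seed.
#' @return List `selected` (data.frame row or `NULL`) and `candidates`
#'   (all clusters passing the thresholds, across resolutions).
#' @export
recover_labelset_cluster <- function(embedding, query_mask, target_labels,
                                     resolutions = c(0.1, 0.2, 0.5, 1, 2, 3, 5,
                                                     10, 15, 20, 25, 30, 50,
                                                     80, 100),
                                     min_recall = 0.25, min_precision = 0.25,
                                     seed = 0L) {
  stopifnot(length(query_mask) == nrow(embedding),
            length(target_labels) == nrow(embedding))
  if (!any(target_labels)) stop("target label set is empty")
  cands <- list()
  for (r in resolutions) {
    k <- if (r < 25) 30L else 15L
    memb <- leiden_partition(as.matrix(embedding), k, r, seed)
    for (cl in unique(memb)) {
      in_cl <- memb == cl
      recall <- sum(in_cl & target_labels) / sum(target_labels)
      denom <- sum(in_cl & query_mask)
      precision <- if (denom > 0) sum(in_cl & target_labels) / denom else 0
      if (recall >= min_recall && precision >= min_precision) {
        cands[[length(cands) + 1]] <-
          data.frame(resolution = r, cluster = cl, n = sum(in_cl),
                     recall = recall, precision = precision)
      }
    }
  }
  cands <- if (length(cands)) do.call(rbind, cands) else
    data.frame(resolution = numeric(), cluster = integer(), n = integer(),
               recall = numeric(), precision = numeric())
  list(selected = select_candidate_cluster(cands), candidates = cands)
}
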