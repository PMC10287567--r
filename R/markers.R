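#' Per-sample, per-cell-type pseudo-bulks
#'
#' Aggregates log-normalized expression into one profile per (sample,
#' cell type) so that downstream tests weight samples, not cells. A
#' pseudo-bulk is formed only when the sample has at least `min_cells`
#' cells of the type; for cell types with fewer than `small_type_total`
#' cells atlas-wide the requirement is relaxed to `small_type_min`.
#' Alongside the mean expression, the fraction of expressing cells (raw
#' count > 0) is stored per gene.
#'
#' @param atlas An [atlas_table()] (raw counts; used for expressing-cell
#'   fractions and, by default, to compute log-normalized expression).
#' @param cell_types Character vector of cell-type labels per cell
#'   (cells labeled `"none"` are skipped).
#' @param expr Optional log-normalized matrix (cells x genes); defaults
#'   to `lognormalize(atlas)`.
#' @param min_cells Minimum cells per (sample, type) (default 10).
#' @param small_type_min Relaxed minimum for small types (default 3).
#' @param small_type_total Atlas-wide size below which a type counts as
#'   small (default 100).
#' @return Object of class `pseudobulk_set`: list with `mean` (pseudo-bulks
#'   x genes), `frac` (expressing-cell fractions, same shape) and `meta`
#'   (data.frame `sample`, `cell_type`, `n_cells`).
#' @export
build_pseudobulks <- function(atlas, cell_types, expr = NULL,
                              min_cells = 10, small_type_min = 3,
                              small_type_total = 100) {
  stopifnot(inherits(atlas, "atlas_table"),
            length(cell_types) == nrow(atlas$counts))
  if (is.null(expr)) expr <- lognormalize(atlas)
  samples <- atlas$cell_meta$sample
  type_totals <- table(cell_types)
  keys <- split(seq_along(cell_types), list(samples, cell_types), drop = TRUE)
  rows <- list(); meta <- list()
  for (nm in names(keys)) {
    idx <- keys[[nm]]
    ct <- cell_types[idx[1]]
    if (ct == "none") next
    need <- if (type_totals[ct] < small_type_total) small_type_min else min_cells
    if (length(idx) < need) next
    rows[[length(rows) + 1]] <- list(
      mean = Matrix::colMeans(expr[idx, , drop = FALSE]),
      frac = Matrix::colMeans(atlas$counts[idx, , drop = FALSE] > 0))
    meta[[length(meta) + 1]] <- data.frame(
      sample = samples[idx[1]], cell_type = ct, n_cells = length(idx),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no (sample, cell type) pair qualifies")
  meta <- do.call(rbind, meta)
  absent <- setdiff(unique(cell_types[cell_types != "none"]), meta$cell_type)
  if (length(absent))
    warning("cell types with no qualifying sample excluded: ",
            paste(absent, collapse = ", "))
  structure(list(
    mean = do.call(rbind, lapply(rows, `[[`, "mean")),
    frac = do.call(rbind, lapply(rows, `[[`, "frac")),
    meta = meta), class = "pseudobulk_set")
}

#' @export
print.pseudobulk_set <- function(x, ...) {
  cat(sprintf("pseudobulk_set: %d pseudo-bulks x %d genes, %d cell types\n",
              nrow(x$mean), ncol(x$mean), length(unique(x$meta$cell_type))))
  invisible(x)
}

subset_pseudobulks <- function(pb, keep_types) {
  keep <- pb$meta$cell_type %in% keep_types
  structure(list(mean = pb$mean[keep, , drop = FALSE],
                 frac = pb$frac[keep, , drop = FALSE],
                 meta = pb$meta[keep, , drop = FALSE]),
            class = "pseudobulk_set")
}

#' Welch t-test of one cell type's pseudo-bulks against the rest
#'
#' Pseudo-bulk means are approximately normal (means of many cells), so
#' a per-gene two-sample Welch t-test of the target type's pseudo-bulks
#' versus all other pseudo-bulks in the current reference scope is used.
#'
#' @param pseudobulks A [build_pseudobulks()] result (possibly already
#'   subset to a scope).
#' @param target_type Cell type to test.
#' @return Data.frame per gene: `gene`, `stat` (t), `p`, `lfc` (target
#'   minus rest difference of mean log expression), `mean_in`,
#'   `mean_out`.
#' @export
marker_ttest <- function(pseudobulks, target_type) {
  in_idx <- which(pseudobulks$meta$cell_type == target_type)
  out_idx <- which(pseudobulks$meta$cell_type != target_type)
  if (length(in_idx) < 2 || length(out_idx) < 2)
    stop("need >= 2 pseudo-bulks in target and in rest")
  res <- welch_test_cols(pseudobulks$mean, in_idx, out_idx)
  data.frame(gene = colnames(pseudobulks$mean), res,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expression-fraction marker filters
#'
#' From the significantly upregulated genes (Benjamini-Hochberg FDR
#' below `fdr`, positive fold change), keeps genes that are (1) expressed
#' (pseudo-bulk mean > 0) in at least `min_frac_pb_target` of the target
#' type's pseudo-bulks, (2) expressed in at least `min_frac_cells` of
#' cells per target pseudo-bulk on average, and (3) expressed in at most
#' `max_frac_pb_other` of all other pseudo-bulks in the scope.
#'
#' @param stats A [marker_ttest()] result for the target type.
#' @param pseudobulks The [build_pseudobulks()] result the stats came
#'   from.
#' @param target_type Cell type the stats refer to.
#' @param min_frac_pb_target,min_frac_cells,max_frac_pb_other The three
#'   fraction thresholds (defaults 0.8, 0.5, 0.2).
#' @param fdr FDR level for the significance pre-filter (default 0.05).
#' @return Character vector of surviving genes, ordered by decreasing t
#'   statistic.
#' @export
filter_markers <- function(stats, pseudobulks, target_type,
                           min_frac_pb_target = 0.8, min_frac_cells = 0.5,
                           max_frac_pb_other = 0.2, fdr = 0.05) {
  in_rows <- pseudobulks$meta$cell_type == target_type
  expressed <- pseudobulks$mean > 0
  frac_pb_target <- colMeans(expressed[in_rows, , drop = FALSE])
  frac_pb_other <- colMeans(expressed[!in_rows, , drop = FALSE])
  mean_cell_frac <- colMeans(pseudobulks$frac[in_rows, , drop = FALSE])
  padj <- stats::p.adjust(stats$p, method = "BH")
  keep <- padj < fdr & stats$lfc > 0 &
    frac_pb_target[stats$gene] >= min_frac_pb_target &
    mean_cell_frac[stats$gene] >= min_frac_cells &
    frac_pb_other[stats$gene] <= max_frac_pb_other
  keep[is.na(keep)] <- FALSE
  stats$gene[keep][order(stats$stat[keep], decreasing = TRUE)]
}

default_marker_iterations <- function() {
  list(
    list(scope = "atlas",       min_frac_pb_target = 0.8, min_frac_cells = 0.5, max_frac_pb_other = 0.2),
    list(scope = "compartment", min_frac_pb_target = 0.8, min_frac_cells = 0.5, max_frac_pb_other = 0.2),
    list(scope = "subtree",     min_frac_pb_target = 0.8, min_frac_cells = 0.5, max_frac_pb_other = 0.2),
    list(scope = "compartment", min_frac_pb_target = 0.6, min_frac_cells = 0.4, max_frac_pb_other = 0.3),
    list(scope = "subtree",     min_frac_pb_target = 0.5, min_frac_cells = 0.25, max_frac_pb_other = 0.4)
  )
}

#' Hierarchical marker-gene selection
#'
#' Marker iteration 1 tests each cell type against the whole atlas. For
#' types left without markers, iteration 2 restricts the reference scope
#' to the type's compartment (level-1 subtree), iteration 3 to the next
#' coarsest subtree within the compartment, and iterations 4-5 repeat
#' those scopes with loosened fraction thresholds (package defaults;
#' every threshold is configurable through `iterations`). Each returned
#' marker set records the iteration and scope that produced it; a type
#' failing all iterations gets an empty set flagged for manual curation.
#'
#' @param atlas An [atlas_table()].
#' @param labels Harmonized label data.frame from [harmonize_labels()].
#' @param tree The [label_tree()].
#' @param expr Optional log-normalized matrix; defaults to
#'   `lognormalize(atlas)`.
#' @param iterations List of per-iteration parameter lists (`scope`,
#'   `min_frac_pb_target`, `min_frac_cells`, `max_frac_pb_other`);
#'   default [default_marker_iterations()].
#' @param max_markers Truncate each marker set to this many genes
#'   (default 20).
#' @param fdr FDR level for the significance pre-filter.
#' @return Named list per cell type: list with `cell_type`, `genes`,
#'   `iteration` (`NA` if none succeeded), `scope`.
#' @export
hierarchical_markers <- function(atlas, labels, tree, expr = NULL,
                                 iterations = default_marker_iterations(),
                                 max_markers = 20, fdr = 0.05) {
  if (is.null(expr)) expr <- lognormalize(atlas)
  cell_types <- finest_label(labels)
  pb <- build_pseudobulks(atlas, cell_types, expr = expr)
  types <- sort(unique(pb$meta$cell_type))
  anc <- lapply(types, function(tp) tree_ancestry(tree, tp))
  names(anc) <- types
  type_anc_at <- function(tp, lvl) anc[[tp]][lvl]
  out <- list()
  for (tp in types) {
    found <- NULL
    for (it in seq_along(iterations)) {
      par <- iterations[[it]]
      scope_types <- switch(
        par$scope,
        atlas = types,
        compartment = types[vapply(types, function(o)
          type_anc_at(o, 1) == type_anc_at(tp, 1), logical(1))],
        subtree = {
          lvl <- max(which(anc[[tp]] != "none")) - 1L
          lvl <- max(lvl, 1L)
          types[vapply(types, function(o)
            !is.na(type_anc_at(o, lvl)) &&
              type_anc_at(o, lvl) == type_anc_at(tp, lvl), logical(1))]
        })
      if (length(scope_types) < 2) next
      pbs <- subset_pseudobulks(pb, scope_types)
      if (sum(pbs$meta$cell_type == tp) < 2 ||
          sum(pbs$meta$cell_type != tp) < 2) next
      st <- marker_ttest(pbs, tp)
      genes <- filter_markers(st, pbs, tp,
                              min_frac_pb_target = par$min_frac_pb_target,
                              min_frac_cells = par$min_frac_cells,
                              max_frac_pb_other = par$max_frac_pb_other,
                              fdr = fdr)
      if (length(genes)) {
        found <- list(cell_type = tp,
                      genes = utils::head(genes, max_markers),
                      iteration = it, scope = par$scope)
        break
      }
    }
    if (is.null(found))
      found <- list(cell_type = tp, genes = character(),
                    iteration = NA_integer_, scope = NA_character_)
    out[[tp]] <- found
  }
  out
}
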