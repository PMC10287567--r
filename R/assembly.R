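#' Filter low-coverage cells and rarely detected genes
#'
#' Removes cells with fewer than `min_genes_per_cell` detected genes
#' (count > 0), then genes detected in fewer than `min_cells_per_gene`
#' cells, one pass each, cells first. Because removing cells can push a
#' gene below its threshold (and vice versa), a single pass is not a fixed
#' point; set `fixed_point = TRUE` to iterate until neither filter removes
#' anything.
#'
#' @param atlas An [atlas_table()] with raw counts.
#' @param min_genes_per_cell Minimum number of genes detected per cell
#'   (default 200; a cell with exactly the minimum is kept).
#' @param min_cells_per_gene Minimum number of cells a gene must be
#'   detected in (default 10; a gene at exactly the minimum is kept).
#' @param fixed_point Iterate the two filters to convergence.
#' @return The filtered `atlas_table`, row/column order preserved.
#' @export
filter_cells_genes <- function(atlas, min_genes_per_cell = 200,
                               min_cells_per_gene = 10,
                               fixed_point = FALSE) {
  stopifnot(inherits(atlas, "atlas_table"))
  repeat {
    n_before <- dim(atlas$counts)
    det_genes <- Matrix::rowSums(atlas$counts > 0)
    keep_cells <- det_genes >= min_genes_per_cell
    if (!any(keep_cells)) stop("empty atlas: all cells removed by gene-count filter")
    atlas <- atlas_subset(atlas, cells = which(keep_cells))
    det_cells <- Matrix::colSums(atlas$counts > 0)
    keep_genes <- det_cells >= min_cells_per_gene
    atlas <- atlas_subset(atlas, genes = which(keep_genes))
    if (!fixed_point) break
    if (all(dim(atlas$counts) == n_before)) break
  }
  atlas
}

#' Screen cells on externally supplied size factors
#'
#' Cells with abnormally low size factors or abnormally high totals after
#' size-factor normalization are removed. Size-factor *estimation* is out
#' of scope; factors must be present in `cell_meta$size_factor`.
#'
#' @param atlas An [atlas_table()] whose `cell_meta` has a `size_factor`
#'   column.
#' @param min_sf Lower bound on the size factor (default 0.01; a cell
#'   strictly below is removed).
#' @param max_norm_total Upper bound on the normalized total count
#'   (default 1e6; strictly above is removed).
#' @return The screened `atlas_table`.
#' @export
screen_size_factors <- function(atlas, min_sf = 0.01, max_norm_total = 1e6) {
  stopifnot(inherits(atlas, "atlas_table"))
  sf <- atlas$cell_meta$size_factor
  if (is.null(sf) || anyNA(sf)) {
    bad <- if (is.null(sf)) atlas$cell_meta$cell_id else
      atlas$cell_meta$cell_id[is.na(sf)]
    stop("missing size factors for cells: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  norm_total <- Matrix::rowSums(atlas$counts) / sf
  keep <- sf >= min_sf & norm_total <= max_norm_total
  if (!any(keep)) stop("empty atlas: all cells removed by size-factor screen")
  atlas_subset(atlas, cells = which(keep))
}

#' Total-count normalization and log transform
#'
#' Scales every cell to `target_sum` total counts, then applies
#' `log(x + 1)` (natural log). All-zero cells are left as zero with a
#' warning.
#'
#' @param atlas An [atlas_table()] (or a bare non-negative matrix).
#' @param target_sum Per-cell total after scaling (default 1e4).
#' @return A sparse real-valued matrix of the same shape as the counts.
#' @export
lognormalize <- function(atlas, target_sum = 1e4) {
  x <- if (inherits(atlas, "atlas_table")) atlas$counts else
    methods::as(methods::as(methods::as(atlas, "dMatrix"), "generalMatrix"),
                "CsparseMatrix")
  if (any(x@x < 0)) stop("counts must be non-negative")
  totals <- Matrix::rowSums(x)
  if (any(totals == 0))
    warning(sum(totals == 0), " all-zero cell(s) left as zero")
  scale_f <- ifelse(totals > 0, target_sum / totals, 0)
  out <- Matrix::Diagonal(x = scale_f) %*% x
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(x)
  methods::as(out, "CsparseMatrix")
}

# ---- label hierarchy ------------------------------------------------------

#' Construct a hierarchical cell-identity reference
#'
#' A five-level hierarchy: level 1 holds the coarsest lineages
#' (compartments such as epithelial or immune), level 5 the finest
#' identities. Each non-root node's parent sits exactly one level above
#' it.
#'
#' @param nodes A data.frame with columns `name`, `level` (integer 1-5)
#'   and `parent` (`NA` for level-1 roots).
#' @param mappings Named list: per dataset, a named character vector from
#'   original label to node name (the value `"unlabeled"` is always
#'   allowed).
#' @return An object of class `label_tree`.
#' @export
label_tree <- function(nodes, mappings = list()) {
  stopifnot(is.data.frame(nodes),
            all(c("name", "level", "parent") %in% names(nodes)))
  nodes$level <- as.integer(nodes$level)
  if (anyDuplicated(nodes$name)) stop("duplicate node names")
  if (any(nodes$level < 1 | nodes$level > 5)) stop("levels must be 1..5")
  roots <- nodes$level == 1
  if (!any(roots)) stop("no level-1 root nodes")
  if (any(!is.na(nodes$parent[roots]))) stop("level-1 nodes cannot have parents")
  kids <- !roots
  if (any(is.na(nodes$parent[kids]))) stop("non-root nodes need a parent")
  pl <- nodes$level[match(nodes$parent[kids], nodes$name)]
  if (anyNA(pl)) stop("parent not found for some nodes")
  if (any(pl != nodes$level[kids] - 1L))
    stop("parent level must equal child level - 1")
  for (m in mappings) {
    unknown <- setdiff(setdiff(m, "unlabeled"), nodes$name)
    if (length(unknown))
      stop("mapping targets not in tree: ", paste(unknown, collapse = ", "))
  }
  structure(list(nodes = nodes, mappings = mappings), class = "label_tree")
}

#' @export
print.label_tree <- function(x, ...) {
  cat(sprintf("label_tree: %d nodes over %d levels, %d dataset mappings\n",
              nrow(x$nodes), max(x$nodes$level), length(x$mappings)))
  invisible(x)
}

#' Ancestor chain of a tree node
#'
#' @param tree A [label_tree()].
#' @param name Node name.
#' @return Character vector of length 5: the node's ancestors at levels
#'   1..node level, `"none"` below.
#' @export
tree_ancestry <- function(tree, name) {
  out <- rep("none", 5)
  nd <- tree$nodes
  cur <- name
  while (!is.na(cur) && cur != "") {
    i <- match(cur, nd$name)
    if (is.na(i)) stop("node not in tree: ", cur)
    out[nd$level[i]] <- cur
    cur <- nd$parent[i]
  }
  out
}

#' Harmonize original dataset labels onto the reference hierarchy
#'
#' Each cell's original label is looked up in its dataset's mapping; the
#' mapped node's full ancestor chain fills levels 1 up to the node's
#' level, with `"none"` below it. `"unlabeled"` gives `"none"` at every
#' level.
#'
#' @param tree A [label_tree()] whose `mappings` cover all labels observed
#'   in the atlas.
#' @param atlas An [atlas_table()].
#' @param allow_unlabeled If `TRUE`, labels absent from a dataset's
#'   mapping are treated as `"unlabeled"` instead of raising an error.
#' @return A data.frame with one row per cell and columns `level1` ..
#'   `level5`.
#' @export
harmonize_labels <- function(tree, atlas, allow_unlabeled = FALSE) {
  stopifnot(inherits(tree, "label_tree"), inherits(atlas, "atlas_table"))
  cm <- atlas$cell_meta
  node <- character(nrow(cm))
  for (ds in unique(cm$dataset)) {
    idx <- cm$dataset == ds
    map <- tree$mappings[[ds]]
    if (is.null(map)) {
      # identity mapping over tree nodes for datasets without an explicit map
      map <- stats::setNames(tree$nodes$name, tree$nodes$name)
    }
    lab <- cm$original_label[idx]
    hit <- map[lab]
    miss <- is.na(hit) & lab != "unlabeled"
    if (any(miss) && !allow_unlabeled)
      stop("dataset ", ds, " has unmapped labels: ",
           paste(unique(lab[miss]), collapse = ", "))
    hit[is.na(hit)] <- "unlabeled"
    node[idx] <- hit
  }
  uniq <- unique(node)
  chains <- vapply(uniq, function(n) {
    if (n == "unlabeled") rep("none", 5) else tree_ancestry(tree, n)
  }, character(5))
  out <- as.data.frame(t(chains[, match(node, uniq), drop = FALSE]),
                       stringsAsFactors = FALSE)
  names(out) <- paste0("level", 1:5)
  rownames(out) <- NULL
  out
}

#' Expand node names into a per-cell label data.frame
#'
#' Convenience for working with known labels (e.g. simulation truth):
#' each node name becomes its full ancestor chain across levels 1-5.
#'
#' @param tree A [label_tree()].
#' @param nodes Character vector of node names (one per cell).
#' @return Data.frame with columns `level1` .. `level5`.
#' @export
labels_from_nodes <- function(tree, nodes) {
  uniq <- unique(nodes)
  chains <- vapply(uniq, function(n) tree_ancestry(tree, n), character(5))
  out <- as.data.frame(t(chains[, match(nodes, uniq), drop = FALSE]),
                       stringsAsFactors = FALSE)
  names(out) <- paste0("level", 1:5)
  rownames(out) <- NULL
  out
}

#' Finest available harmonized label per cell
#'
#' @param labels Output of [harmonize_labels()].
#' @return Character vector, `"none"` where a cell is unlabeled at every
#'   level.
#' @export
finest_label <- function(labels) {
  out <- rep("none", nrow(labels))
  for (l in 1:5) {
    v <- labels[[paste0("level", l)]]
    out[v != "none"] <- v[v != "none"]
  }
  out
}

#' Sum gene columns that harmonize to the same target identifier
#'
#' @param atlas An [atlas_table()].
#' @param groups Named list: target gene id -> character vector of source
#'   gene ids currently present in the atlas. Groups must not overlap.
#' @return An `atlas_table` in which each group's columns are replaced by
#'   their element-wise sum, named by the target id. Per-cell grand totals
#'   are conserved exactly.
#' @export
sum_collided_genes <- function(atlas, groups) {
  stopifnot(inherits(atlas, "atlas_table"))
  if (!length(groups)) return(atlas)
  src <- unlist(groups, use.names = FALSE)
  unknown <- setdiff(src, atlas$gene_ids)
  if (length(unknown))
    stop("groups reference unknown genes: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(src)) stop("groups must not overlap")
  counts <- atlas$counts
  merged <- lapply(groups, function(g) {
    Matrix::rowSums(counts[, g, drop = FALSE])
  })
  merged <- do.call(cbind, merged)
  colnames(merged) <- names(groups)
  keep <- setdiff(atlas$gene_ids, src)
  out <- cbind(counts[, keep, drop = FALSE],
               methods::as(methods::as(merged, "generalMatrix"), "CsparseMatrix"))
  atlas_table(out, atlas$cell_meta, atlas$sample_meta)
}
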