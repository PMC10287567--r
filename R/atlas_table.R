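#' Construct an atlas table
#'
#' The central container consumed by every pipeline stage: a sparse
#' cell-by-gene matrix of raw counts together with per-cell and per-sample
#' metadata. Cells are rows, genes are columns.
#'
#' @param counts A non-negative integer matrix (cells x genes), coerced to
#'   [Matrix::sparseMatrix] (`dgCMatrix`). Row names are cell ids, column
#'   names gene ids.
#' @param cell_meta A data.frame with one row per cell and at least the
#'   columns `cell_id`, `dataset`, `donor`, `sample`, `original_label`.
#'   An optional `size_factor` column carries externally computed size
#'   factors.
#' @param sample_meta A data.frame with one row per sample and at least
#'   `sample`, `donor`, `dataset`. Anatomical and demographic columns
#'   (`location`, `ccf_score`, `age`, `sex`, `bmi`, `smoking`) are used by
#'   the covariate modules when present.
#'
#' @return An object of class `atlas_table` with elements `counts`,
#'   `cell_meta`, `sample_meta`, `gene_ids`.
#' @export
atlas_table <- function(counts, cell_meta, sample_meta) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  stopifnot(is.data.frame(cell_meta), is.data.frame(sample_meta))
  needed <- c("cell_id", "dataset", "donor", "sample", "original_label")
  missing_cols <- setdiff(needed, names(cell_meta))
  if (length(missing_cols))
    stop("cell_meta lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(cell_meta) != nrow(counts))
    stop("cell_meta rows (", nrow(cell_meta), ") != cells (", nrow(counts), ")")
  if (!all(c("sample", "donor", "dataset") %in% names(sample_meta)))
    stop("sample_meta needs sample, donor and dataset columns")
  bad <- setdiff(cell_meta$sample, sample_meta$sample)
  if (length(bad))
    stop("cells reference unknown samples: ", paste(utils::head(bad, 3), collapse = ", "))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("gene", seq_len(ncol(counts)))
  if (anyDuplicated(colnames(counts)))
    stop("gene ids must be unique")
  if (is.null(rownames(counts))) rownames(counts) <- cell_meta$cell_id
  structure(
    list(counts = counts,
         cell_meta = as.data.frame(cell_meta, stringsAsFactors = FALSE),
         sample_meta = as.data.frame(sample_meta, stringsAsFactors = FALSE),
         gene_ids = colnames(counts)),
    class = "atlas_table")
}

#' @export
print.atlas_table <- function(x, ...) {
  cat(sprintf("atlas_table: %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  datasets: %d  donors: %d  samples: %d\n",
              length(unique(x$cell_meta$dataset)),
              length(unique(x$cell_meta$donor)),
              length(unique(x$cell_meta$sample))))
  invisible(x)
}

#' @export
dim.atlas_table <- function(x) dim(x$counts)

#' Subset an atlas table
#'
#' @param atlas An [atlas_table()].
#' @param cells,genes Logical, integer or character indices into the cell
#'   rows / gene columns; `NULL` keeps everything. Order of survivors is
#'   preserved.
#' @return The subset `atlas_table`. Samples no longer referenced by any
#'   cell are dropped from `sample_meta`.
#' @export
atlas_subset <- function(atlas, cells = NULL, genes = NULL) {
  stopifnot(inherits(atlas, "atlas_table"))
  if (is.null(cells)) cells <- seq_len(nrow(atlas$counts))
  if (is.null(genes)) genes <- seq_len(ncol(atlas$counts))
  counts <- atlas$counts[cells, genes, drop = FALSE]
  if (nrow(counts) == 0L) stop("empty atlas: all cells removed")
  cm <- atlas$cell_meta[cells, , drop = FALSE]
  rownames(cm) <- NULL
  sm <- atlas$sample_meta[atlas$sample_meta$sample %in% unique(cm$sample), ,
                          drop = FALSE]
  rownames(sm) <- NULL
  atlas_table(counts, cm, sm)
}

#' Write / read an atlas table as plain-text files
#'
#' Counts go to MatrixMarket (`counts.mtx`) with gene and cell ids in
#' side-car TSVs; cell and sample metadata are TSVs. This is the on-disk
#' exchange format of the pipeline.
#'
#' @param atlas An [atlas_table()].
#' @param dir Output directory (created if absent).
#' @return `write_atlas` invisibly returns the vector of files written;
#'   `read_atlas` returns the reconstructed `atlas_table`.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "atlas_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(dir, c("counts.mtx", "cells.tsv", "genes.tsv",
                        "cell_meta.tsv", "sample_meta.tsv"))
  Matrix::writeMM(atlas$counts, f[1])
  writeLines(rownames(atlas$counts), f[2])
  writeLines(atlas$gene_ids, f[3])
  utils::write.table(atlas$cell_meta, f[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(atlas$sample_meta, f[5], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(f)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")),
                        "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "cells.tsv"))
  colnames(counts) <- readLines(file.path(dir, "genes.tsv"))
  cm <- utils::read.delim(file.path(dir, "cell_meta.tsv"),
                          stringsAsFactors = FALSE)
  sm <- utils::read.delim(file.path(dir, "sample_meta.tsv"),
                          stringsAsFactors = FALSE)
  atlas_table(counts, cm, sm)
}
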