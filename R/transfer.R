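#' k-nearest-neighbour label transfer with uncertainty
#'
#' Each query cell receives the label with the largest weighted
#' proportion among its `k` nearest reference neighbours in the joint
#' embedding (Euclidean distance), together with the uncertainty score
#' \eqn{u = 1 - p(Y = y | c, N_c)}, one minus that weighted proportion.
#' Label purity in the neighbourhood gives u = 0; neighbourhoods mixing
#' distinct reference annotations give high u, which is what flags novel
#' or disease-shifted states downstream.
#'
#' Neighbour weights use a Gaussian kernel on distance with a per-cell
#' bandwidth equal to the distance to the k-th neighbour
#' (`exp(-(d/d_k)^2)`); set `weighted = FALSE` for plain proportions.
#' Label ties are broken by larger summed weight at full precision, then
#' lexicographically.
#'
#' @param ref_embedding Reference embedding matrix (cells x d).
#' @param ref_labels Character vector of reference labels.
#' @param query_embedding Query embedding matrix (cells x d, same d).
#' @param k Number of neighbours (default 50).
#' @param weighted Use Gaussian kernel weights (default) or equal
#'   weights.
#' @return Object of class `transfer_result`: a list with `table` (a
#'   data.frame `cell`, `label`, `uncertainty`, `unknown`), plus neighbour
#'   matrices `nn_index`, `nn_dist`, `nn_weight` and the parameters used.
#' @export
knn_transfer <- function(ref_embedding, ref_labels, query_embedding,
                         k = 50, weighted = TRUE) {
  ref_embedding <- as.matrix(ref_embedding)
  query_embedding <- as.matrix(query_embedding)
  if (length(ref_labels) != nrow(ref_embedding))
    stop("ref_labels length does not match reference cells")
  if (!length(ref_labels)) stop("ref_labels is empty")
  nn <- knn_search(ref_embedding, query_embedding, k)
  w <- if (weighted) {
    bw <- nn$dist[, k]
    bw[bw == 0] <- 1  # degenerate: all neighbours coincide -> equal weights
    exp(-(nn$dist / bw)^2)
  } else {
    matrix(1, nrow(nn$dist), ncol(nn$dist))
  }
  nq <- nrow(query_embedding)
  lab <- character(nq)
  unc <- numeric(nq)
  ref_labels <- as.character(ref_labels)
  for (i in seq_len(nq)) {
    nl <- ref_labels[nn$index[i, ]]
    sums <- tapply(w[i, ], nl, sum)
    prop <- sums / sum(w[i, ])
    top <- names(prop)[prop == max(prop)]
    lab[i] <- sort(top)[1]
    unc[i] <- 1 - max(prop)
  }
  qn <- rownames(query_embedding)
  if (is.null(qn)) qn <- paste0("query", seq_len(nq))
  structure(list(
    table = data.frame(cell = qn, label = lab, uncertainty = unc,
                       unknown = NA, stringsAsFactors = FALSE),
    nn_index = nn$index, nn_dist = nn$dist, nn_weight = w,
    k = k, weighted = weighted), class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("transfer_result: %d query cells, k = %d, %s weights\n",
              nrow(x$table), x$k,
              if (x$weighted) "Gaussian" else "equal"))
  cat(sprintf("  mean uncertainty %.3f; unknown: %s\n",
              mean(x$table$uncertainty),
              if (all(is.na(x$table$unknown))) "not set" else
                sum(x$table$unknown)))
  invisible(x)
}

#' Mask uncertain transfers as unknown
#'
#' Sets the unknown flag where uncertainty exceeds `cutoff`; transferred
#' labels are preserved alongside for audit.
#'
#' @param result A [knn_transfer()] result.
#' @param cutoff Uncertainty cutoff in \[0, 1\].
#' @return The `transfer_result` with `table$unknown` filled and a
#'   `table$final_label` column (`"unknown"` where masked).
#' @export
apply_unknown_cutoff <- function(result, cutoff) {
  stopifnot(inherits(result, "transfer_result"),
            cutoff >= 0, cutoff <= 1)
  result$table$unknown <- result$table$uncertainty > cutoff
  result$table$final_label <- ifelse(result$table$unknown, "unknown",
                                     result$table$label)
  result$cutoff <- cutoff
  result
}

#' Calibrate the unknown cutoff from labelled query data
#'
#' Treats incorrectly transferred cells as positives and "uncertainty
#' above threshold" as the prediction, producing a receiver operating
#' characteristic over a threshold grid. Only cells whose original
#' annotation depth lies in `levels` (default 3 and 4) enter: coarser
#' levels are uninformative and the finest level flags granularity rather
#' than transfer failure. The chosen cutoff maximizes Youden's J
#' (TPR - FPR) among thresholds keeping FPR below `fpr_max`.
#'
#' @param result A [knn_transfer()] result.
#' @param true_labels Character vector of harmonized true labels per
#'   query cell, comparable to the transferred labels.
#' @param annotation_level Optional integer vector: depth of each cell's
#'   original annotation; combined with `levels` to select cells.
#' @param levels Annotation depths admitted to calibration.
#' @param fpr_max Upper bound on the admissible false positive rate.
#' @return Object of class `calibration_curve`: list with `curve`
#'   (data.frame `threshold`, `tpr`, `fpr`), `cutoff` (numeric or `NA`),
#'   `tpr`, `fpr` at the cutoff and `n_used`.
#' @export
calibrate_cutoff <- function(result, true_labels, annotation_level = NULL,
                             levels = c(3, 4), fpr_max = 0.5) {
  stopifnot(inherits(result, "transfer_result"))
  u <- result$table$uncertainty
  pred <- result$table$label
  stopifnot(length(true_labels) == length(u))
  keep <- rep(TRUE, length(u))
  if (!is.null(annotation_level)) keep <- annotation_level %in% levels
  u <- u[keep]; pred <- pred[keep]; truth <- true_labels[keep]
  positive <- pred != truth  # transfer error
  if (!any(positive)) {
    warning("all transfers correct; ROC is degenerate, no cutoff chosen")
    return(structure(list(curve = data.frame(threshold = numeric(),
                                             tpr = numeric(), fpr = numeric()),
                          cutoff = NA_real_, tpr = NA_real_, fpr = NA_real_,
                          n_used = length(u)),
                     class = "calibration_curve"))
  }
  grid <- sort(unique(c(0, u, 1)))
  # predict positive when u > t; evaluate just below each observed value
  thresholds <- c(-1e-12, grid)
  tpr <- fpr <- numeric(length(thresholds))
  for (j in seq_along(thresholds)) {
    flagged <- u > thresholds[j]
    tpr[j] <- sum(flagged & positive) / sum(positive)
    fpr[j] <- sum(flagged & !positive) / sum(!positive)
  }
  curve <- data.frame(threshold = thresholds, tpr = tpr, fpr = fpr)
  ok <- curve$fpr < fpr_max & curve$threshold >= 0
  cutoff <- NA_real_
  if (any(ok)) {
    j_stat <- curve$tpr - curve$fpr
    best <- which(ok)[which.max(j_stat[ok])]
    cutoff <- curve$threshold[best]
  }
  structure(list(curve = curve, cutoff = cutoff,
                 tpr = if (is.na(cutoff)) NA_real_ else curve$tpr[best],
                 fpr = if (is.na(cutoff)) NA_real_ else curve$fpr[best],
                 n_used = length(u)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve: %d cells, cutoff = %s (TPR %.3f, FPR %.3f)\n",
              x$n_used,
              if (is.na(x$cutoff)) "none" else format(x$cutoff, digits = 3),
              x$tpr, x$fpr))
  invisible(x)
}
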