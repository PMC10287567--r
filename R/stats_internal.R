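# Internal vectorized test statistics and kNN search. Scales here are
# hundreds of genes by thousands of cells, so plain dense linear algebra
# beats per-gene calls to stats:: by orders of magnitude; both routines
# are cross-checked against t.test()/wilcox.test() in the test suite.

as_dense <- function(x) {
  if (inherits(x, "sparseMatrix")) as.matrix(x) else as.matrix(x)
}

col_vars <- function(m) {
  n <- nrow(m)
  if (n < 2) return(rep(NA_real_, ncol(m)))
  mu <- colMeans(m)
  (colSums(m^2) - n * mu^2) / (n - 1)
}

# Welch two-sample t per column of `mat` (rows split by in_idx/out_idx).
welch_test_cols <- function(mat, in_idx, out_idx) {
  m <- as_dense(mat)
  x <- m[in_idx, , drop = FALSE]
  y <- m[out_idx, , drop = FALSE]
  n1 <- nrow(x); n2 <- nrow(y)
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- col_vars(x); v2 <- col_vars(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate: no variance anywhere
  zero <- !is.na(se2) & se2 == 0
  t[zero & (m1 - m2) == 0] <- 0
  p[zero & (m1 - m2) == 0] <- 1
  t[zero & (m1 - m2) != 0] <- sign(m1 - m2)[zero & (m1 - m2) != 0] * Inf
  p[zero & (m1 - m2) != 0] <- 0
  data.frame(stat = t, p = p, mean_in = m1, mean_out = m2,
             lfc = m1 - m2, row.names = colnames(m))
}

# Wilcoxon rank-sum per column, normal approximation with tie correction
# (no continuity correction), matching wilcox.test(exact=FALSE,
# correct=FALSE) up to that approximation.
wilcox_test_cols <- function(mat, in_idx, out_idx) {
  m <- as_dense(mat)
  idx <- c(in_idx, out_idx)
  m <- m[idx, , drop = FALSE]
  n1 <- length(in_idx); n2 <- length(out_idx); n <- n1 + n2
  z <- numeric(ncol(m)); p <- numeric(ncol(m))
  mu_u <- n1 * n2 / 2
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j])
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- rle(sort(m[, j]))$lengths
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) { z[j] <- 0; p[j] <- 1; next }
    z[j] <- (u - mu_u) / sqrt(sigma2)
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  m1 <- colMeans(m[seq_len(n1), , drop = FALSE])
  m2 <- colMeans(m[n1 + seq_len(n2), , drop = FALSE])
  data.frame(stat = z, p = p, mean_in = m1, mean_out = m2,
             lfc = m1 - m2, row.names = colnames(m))
}

# Exact k nearest neighbours of `query` rows among `ref` rows (Euclidean),
# chunked so the full distance matrix never materializes. Ties resolved by
# reference row index (stable order()).
knn_search <- function(ref, query, k, chunk = 512L) {
  ref <- as.matrix(ref); query <- as.matrix(query)
  if (!all(is.finite(ref)) || !all(is.finite(query)))
    stop("non-finite coordinates in embedding")
  if (k > nrow(ref)) stop("k (", k, ") exceeds reference size (", nrow(ref), ")")
  if (ncol(ref) != ncol(query)) stop("embedding dimensions differ")
  nq <- nrow(query)
  idx <- matrix(0L, nq, k)
  dst <- matrix(0, nq, k)
  rn2 <- rowSums(ref^2)
  for (start in seq(1L, nq, by = chunk)) {
    rows <- start:min(start + chunk - 1L, nq)
    q <- query[rows, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rn2, "+") - 2 * tcrossprod(q, ref)
    d2[d2 < 0] <- 0
    for (i in seq_along(rows)) {
      o <- order(d2[i, ])[seq_len(k)]
      idx[rows[i], ] <- o
      dst[rows[i], ] <- sqrt(d2[i, o])
    }
  }
  list(index = idx, dist = dst)
}
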