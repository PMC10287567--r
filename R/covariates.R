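# dummy-encode a covariate vector for regression; drops unused levels
dummy_matrix <- function(covariate) {
  if (is.numeric(covariate)) return(matrix(covariate, ncol = 1))
  f <- factor(covariate)
  if (nlevels(f) < 2) stop("single-valued covariate")
  stats::model.matrix(~ f)[, -1, drop = FALSE]
}

#' Fraction of embedding variance explained by a covariate
#'
#' For each component \eqn{i} of the supplied score matrix an ordinary
#' least squares regression of the scores on the (dummy-encoded)
#' covariate gives the variance explained for that component; the
#' statistic is
#' \deqn{PC_{expl} = \sum_i var_i^{expl} / \sum_i var(PC_i),}
#' the covariate-explained share of the total variance across all
#' components. Rows with a missing covariate value are dropped.
#'
#' @param components Numeric matrix, observations x components
#'   (principal-component or latent scores).
#' @param covariate Vector (numeric or categorical) of length
#'   `nrow(components)`.
#' @return Single number in \[0, 1\].
#' @export
pc_regression <- function(components, covariate) {
  components <- as.matrix(components)
  keep <- !is.na(covariate)
  components <- components[keep, , drop = FALSE]
  covariate <- covariate[keep]
  if (nrow(components) < 3) stop("need at least 3 observations with covariate values")
  x <- dummy_matrix(covariate)
  if (is.numeric(covariate) && stats::var(covariate) == 0)
    stop("single-valued covariate")
  fit <- stats::lm.fit(cbind(1, x), components)
  fitted <- as.matrix(fit$fitted.values)
  n <- nrow(components)
  var_fit <- apply(fitted, 2, stats::var)
  var_tot <- apply(components, 2, stats::var)
  sum(var_fit) / sum(var_tot)
}

#' Shuffle-null test for splitting a study on a technical covariate
#'
#' The observed `pc_regression` value is compared with a null built by
#' shuffling the covariate assignment across observations `n_shuffles`
#' times. The study is split (the covariate is treated as a batch) when
#' the observed value exceeds the null mean by more than `sd_mult` null
#' standard deviations.
#'
#' @param components Score matrix as in [pc_regression()].
#' @param covariate Covariate vector (at least two distinct values).
#' @param n_shuffles Number of random shuffles (default 10).
#' @param sd_mult Standard-deviation multiplier (default 1.5).
#' @param seed Seed for the shuffles.
#' @return List: `split` (logical), `observed`, `null_mean`, `null_sd`.
#' @export
shuffle_null_split <- function(components, covariate, n_shuffles = 10,
                               sd_mult = 1.5, seed = 0L) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (length(unique(covariate[!is.na(covariate)])) < 2)
    stop("covariate needs at least two levels")
  obs <- pc_regression(components, covariate)
  set.seed(seed)
  null <- vapply(seq_len(n_shuffles), function(i)
    pc_regression(components, sample(covariate)), numeric(1))
  mu <- mean(null); sdev <- stats::sd(null)
  if (sdev == 0) {
    warning("null standard deviation is zero; deciding on mean alone")
    return(list(split = obs > mu, observed = obs, null_mean = mu, null_sd = 0))
  }
  list(split = obs > mu + sd_mult * sdev,
       observed = obs, null_mean = mu, null_sd = sdev)
}

#' Dependence between two covariates
#'
#' If at least one covariate is continuous: the square root of the
#' variance in the continuous covariate explained by the (dummy-encoded)
#' other — equal to |Pearson r| for two continuous covariates. For two
#' categorical covariates both with more than two levels: normalized
#' mutual information (arithmetic normalization). For two binary
#' categoricals: the square root of the dummy-regression R^2, which
#' equals |phi|.
#'
#' @param a,b Paired covariate vectors (NAs dropped pairwise).
#' @return Dependence score in \[0, 1\].
#' @export
covariate_dependence <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3) stop("need at least 3 complete pairs")
  a_cont <- is.numeric(a); b_cont <- is.numeric(b)
  r2_of <- function(y, x) {
    xm <- dummy_matrix(x)
    fit <- stats::lm.fit(cbind(1, xm), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  if (a_cont || b_cont) {
    y <- if (a_cont) a else b
    x <- if (a_cont) b else a
    if (stats::var(y) == 0) return(0)
    return(sqrt(max(0, min(1, r2_of(y, x)))))
  }
  fa <- factor(a); fb <- factor(b)
  if (nlevels(fa) > 2 && nlevels(fb) > 2)
    return(normalized_mutual_information(fa, fb))
  sqrt(max(0, min(1, r2_of(as.numeric(fa == levels(fa)[1]), fb))))
}

# NMI with arithmetic-mean normalization: I(a;b) / mean(H(a), H(b))
normalized_mutual_information <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); p_j <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
  ha <- entropy_of_counts(rowSums(tab))
  hb <- entropy_of_counts(colSums(tab))
  if (ha == 0 && hb == 0) return(1)
  mi / mean(c(ha, hb))
}

#' Encode sample covariates for gene-level modeling
#'
#' Applies the atlas's covariate encodings: smoking status becomes a
#' continuous 0 / 0.5 / 1 scale (never / former / current); `nasal` is a
#' 0/1 indicator of nose samples; age is scaled linearly so that 25
#' years maps to 0 and 64 to 1 (unbounded outside); BMI likewise with
#' anchors 21.32 and 36.86; the CCF score passes through unchanged. The
#' anchors are the 10th and 90th percentiles observed across the source
#' atlas and are configurable.
#'
#' @param sample_meta Data.frame with (a subset of) the columns
#'   `smoking`, `location`, `age`, `bmi`, `ccf_score`, `sex`.
#' @param age_anchors,bmi_anchors Length-2 numeric vectors mapped to 0
#'   and 1.
#' @return Data.frame of encoded covariates, one row per input row.
#' @export
encode_covariates <- function(sample_meta,
                              age_anchors = c(25, 64),
                              bmi_anchors = c(21.32, 36.86)) {
  out <- data.frame(row.names = seq_len(nrow(sample_meta)))
  if (!is.null(sample_meta$smoking)) {
    map <- c(never = 0, former = 0.5, current = 1)
    s <- as.character(sample_meta$smoking)
    bad <- setdiff(unique(s[!is.na(s)]), names(map))
    if (length(bad)) stop("unknown smoking token: ", paste(bad, collapse = ", "))
    out$smoking <- unname(map[s])
  }
  if (!is.null(sample_meta$location))
    out$nasal <- as.numeric(sample_meta$location %in%
                              c("inferior_turbinate", "nasopharynx"))
  if (!is.null(sample_meta$age))
    out$age <- (sample_meta$age - age_anchors[1]) / diff(age_anchors)
  if (!is.null(sample_meta$bmi))
    out$bmi <- (sample_meta$bmi - bmi_anchors[1]) / diff(bmi_anchors)
  if (!is.null(sample_meta$ccf_score)) out$ccf_score <- sample_meta$ccf_score
  if (!is.null(sample_meta$sex))
    out$sex <- as.numeric(sample_meta$sex == "female")
  out
}

#' Variance-inflation-factor screen for multicollinearity
#'
#' Each covariate is regressed on all the others (ordinary least
#' squares); its VIF is \eqn{1 / (1 - R^2)}. If any VIF exceeds
#' `max_vif` the covariate set is declared too collinear and the cell
#' type is excluded from gene-level modeling. Perfect collinearity gives
#' VIF `Inf`.
#'
#' @param frame Numeric data.frame/matrix of encoded covariates
#'   (observations x covariates, at least 2 covariates).
#' @param max_vif Exclusion threshold (default 5).
#' @return List: `vif` (named numeric), `include` (logical).
#' @export
vif_screen <- function(frame, max_vif = 5) {
  x <- as.matrix(frame)
  if (ncol(x) < 2) stop("need at least 2 covariates")
  vif <- vapply(seq_len(ncol(x)), function(j) {
    y <- x[, j]
    if (stats::var(y) == 0) return(NA_real_)
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(x)
  list(vif = vif, include = all(is.na(vif) | vif <= max_vif))
}

#' Covariate variance attribution per cell type
#'
#' For every cell type, cells are grouped by sample; samples with fewer
#' than `min_cells` cells of the type are excluded; latent embedding
#' components are averaged per sample; and [pc_regression()] attributes
#' the sample-level embedding variance to each covariate. Entries are
#' masked (NA with a reason) when fewer than `min_samples` samples carry
#' the covariate or the covariate is single-valued — with few samples the
#' explained fractions are inflated and covariates confound each other.
#'
#' @param atlas An [atlas_table()] (supplies sample metadata).
#' @param embedding Latent embedding matrix (cells x d).
#' @param cell_types Cell-type labels per cell (`"none"` skipped).
#' @param covariates Character vector of `sample_meta` column names to
#'   attribute variance to; default every metadata column except ids.
#' @param min_cells Per-sample minimum cells of the type (default 10).
#' @param min_samples Minimum annotated samples per (type, covariate)
#'   (default 40).
#' @return List: `fractions` (cell type x covariate matrix), `mask`
#'   (character matrix of reason codes, `""` where unmasked),
#'   `n_samples` (cell type x covariate count matrix).
#' @export
variance_report <- function(atlas, embedding, cell_types,
                            covariates = NULL, min_cells = 10,
                            min_samples = 40) {
  stopifnot(inherits(atlas, "atlas_table"),
            nrow(embedding) == nrow(atlas$counts))
  sm <- atlas$sample_meta
  if (is.null(covariates))
    covariates <- setdiff(names(sm), c("sample", "donor", "dataset"))
  types <- sort(setdiff(unique(cell_types), "none"))
  fr <- matrix(NA_real_, length(types), length(covariates),
               dimnames = list(types, covariates))
  mask <- matrix("", length(types), length(covariates),
                 dimnames = list(types, covariates))
  ns <- matrix(0L, length(types), length(covariates),
               dimnames = list(types, covariates))
  for (tp in types) {
    idx <- which(cell_types == tp)
    by_sample <- split(idx, atlas$cell_meta$sample[idx])
    by_sample <- by_sample[lengths(by_sample) >= min_cells]
    if (!length(by_sample)) {
      mask[tp, ] <- "insufficient_samples"
      next
    }
    comp <- t(vapply(by_sample, function(i)
      colMeans(embedding[i, , drop = FALSE]), numeric(ncol(embedding))))
    meta <- sm[match(names(by_sample), sm$sample), , drop = FALSE]
    for (cv in covariates) {
      vals <- meta[[cv]]
      ok <- !is.na(vals)
      ns[tp, cv] <- sum(ok)
      if (sum(ok) < min_samples) {
        mask[tp, cv] <- "insufficient_samples"
        next
      }
      if (length(unique(vals[ok])) < 2) {
        mask[tp, cv] <- "single_valued"
        next
      }
      fr[tp, cv] <- pc_regression(comp[ok, , drop = FALSE], vals[ok])
    }
  }
  list(fractions = fr, mask = mask, n_samples = ns)
}
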