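# hand-constructable pseudobulk_set
make_pb <- function(mean_mat, types, frac_mat = NULL) {
  if (is.null(frac_mat)) frac_mat <- (mean_mat > 0) * 1
  structure(list(mean = mean_mat, frac = frac_mat,
                 meta = data.frame(sample = paste0("s", seq_along(types)),
                                   cell_type = types, n_cells = 50,
                                   stringsAsFactors = FALSE)),
            class = "pseudobulk_set")
}

test_that("pseudo-bulk inclusion thresholds follow the cell-count rules", {
  # one sample with 9 cells of a common type (>=100 atlas-wide) -> no
  # pseudo-bulk; a small type (80 cells total) qualifies with 3 cells
  set.seed(1)
  n <- 9 + 80 + 120
  counts <- matrix(rpois(n * 20, 2), n, 20)
  cm <- data.frame(cell_id = paste0("c", 1:n),
                   dataset = "d1", donor = "dn1",
                   sample = c(rep("s1", 9), rep("s2", 77), rep("s1", 3),
                              rep("s2", 120)),
                   original_label = "x", stringsAsFactors = FALSE)
  sm <- data.frame(sample = c("s1", "s2"), donor = "dn1", dataset = "d1")
  at <- atlas_table(counts, cm, sm)
  types <- c(rep("common", 9), rep("small", 80), rep("common", 120))
  # 'common' has 129 cells total: s1 has 9 (<10, dropped), s2 has 120;
  # 'small' has 80 (<100): s1 has 3 (>=3, kept), s2 has 77
  pb <- build_pseudobulks(at, types)
  key <- paste(pb$meta$sample, pb$meta$cell_type)
  expect_setequal(key, c("s2 common", "s1 small", "s2 small"))
  # means equal hand-computed column means of log-normalized expression
  expr <- lognormalize(at)
  idx <- which(types == "small" & cm$sample == "s1")
  expect_equal(pb$mean[key == "s1 small", ],
               colMeans(as.matrix(expr[idx, ])), tolerance = 1e-12)
  expect_equal(unname(pb$frac[key == "s1 small", ]),
               unname(colMeans(counts[idx, , drop = FALSE] > 0)),
               tolerance = 1e-12)
})

test_that("the pseudo-bulk t-test is Welch's and matches stats::t.test", {
  set.seed(2)
  m <- matrix(rnorm(8 * 6, mean = 2), 8, 6,
              dimnames = list(NULL, paste0("g", 1:6)))
  m[1:4, 1] <- m[1:4, 1] + 3
  pb <- make_pb(m, rep(c("tgt", "other"), each = 4))
  st <- marker_ttest(pb, "tgt")
  for (j in 1:6) {
    ref <- t.test(m[1:4, j], m[5:8, j])  # Welch by default
    expect_equal(st$stat[j], unname(ref$statistic), tolerance = 1e-9)
    expect_equal(st$p[j], ref$p.value, tolerance = 1e-9)
  }
  # constant gene -> t = 0, p = 1
  m2 <- m; m2[, 2] <- 1
  st2 <- marker_ttest(make_pb(m2, rep(c("tgt", "other"), each = 4)), "tgt")
  expect_equal(st2$stat[2], 0)
  expect_equal(st2$p[2], 1)
  expect_error(marker_ttest(make_pb(m, c("tgt", rep("other", 7))), "tgt"),
               ">= 2 pseudo-bulks")
})

test_that("expression-fraction filters enforce the 80/50/20 thresholds", {
  # 10 target + 10 other pseudo-bulks, 4 genes:
  # g1: perfect marker; g2: only 70% of target pbs expressed (< 80%);
  # g3: 30% of other pbs expressed (> 20%); g4: only 40% of cells express
  mean_mat <- matrix(0, 20, 4, dimnames = list(NULL, paste0("g", 1:4)))
  mean_mat[1:10, 1] <- 2
  mean_mat[1:10, 2] <- 2; mean_mat[1:3, 2] <- 0      # 7/10 target pbs
  mean_mat[1:10, 3] <- 2; mean_mat[11:13, 3] <- 0.5  # 3/10 = 30% others
  mean_mat[1:10, 4] <- 2
  frac <- (mean_mat > 0) * 0.9
  frac[1:10, 4] <- 0.4
  pb <- make_pb(mean_mat, rep(c("tgt", "other"), each = 10), frac)
  stats_df <- data.frame(gene = paste0("g", 1:4), stat = 5,
                         p = c(1e-6, 1e-6, 1e-6, 1e-6), lfc = 1.5)
  got <- filter_markers(stats_df, pb, "tgt")
  expect_equal(got, "g1")
  # exactly at the 80% bound a gene is kept: 8/10 target pbs
  mean_80 <- mean_mat; mean_80[3, 2] <- 2
  pb80 <- make_pb(mean_80, rep(c("tgt", "other"), each = 10))
  expect_true("g2" %in% filter_markers(stats_df, pb80, "tgt",
                                       min_frac_cells = 0))
  # loosen: 30% other-pb expression removed at 0.2, kept at 0.3
  got2 <- filter_markers(stats_df, pb, "tgt", max_frac_pb_other = 0.3,
                         min_frac_cells = 0)
  expect_true("g3" %in% got2)
  # monotonicity: loosening any threshold never drops a kept gene
  loose <- filter_markers(stats_df, pb, "tgt", min_frac_pb_target = 0.5,
                          min_frac_cells = 0.3, max_frac_pb_other = 0.4)
  expect_true(all(got %in% loose))
  # non-significant genes never pass
  stats_ns <- transform(stats_df, p = 0.9)
  expect_length(filter_markers(stats_ns, pb, "tgt"), 0)
})

test_that("hierarchical selection recovers planted markers and escalates scope", {
  fix <- small_sim()
  sim <- fix$sim
  labels <- labels_from_nodes(sim$truth$tree, sim$truth$cells$true_leaf)
  mk <- suppressWarnings(hierarchical_markers(sim$atlas, labels,
                                              sim$truth$tree))
  found <- Filter(function(m) length(m$genes) > 0, mk)
  expect_gt(length(found), 10)
  # precision vs planted lineage-linked genes
  prec <- vapply(found, function(m)
    mean(m$genes %in% sim$truth$lineage_marker_genes[[m$cell_type]]),
    numeric(1))
  expect_gt(mean(prec), 0.8)
  # recall of each type's exclusive planted markers
  rec <- vapply(found, function(m)
    mean(sim$truth$marker_genes[[m$cell_type]] %in% m$genes), numeric(1))
  expect_gt(mean(rec), 0.9)
  # exclusivity: a type's exclusive planted markers never surface in
  # another type's set (shared ancestor-block genes legitimately can)
  for (m in found) {
    other_exclusive <- unlist(sim$truth$marker_genes[
      setdiff(names(sim$truth$marker_genes), m$cell_type)])
    expect_length(intersect(m$genes, other_exclusive), 0)
  }
})

test_that("types indistinguishable at atlas scope fall back to iteration >= 2", {
  # two compartments; leaves have no exclusive markers, only programs
  # shared across compartments, so uniqueness only exists within-compartment
  spec <- tiny_tree_spec()
  cfg <- sim_config(
    n_datasets = 2, donors_per_dataset = 3, cells_per_donor = 120,
    n_genes = 200, label_tree_spec = spec, batch_effect_sd = 0,
    covariate_effects = list(), doublet_rate = 0, disease_states = list(),
    shared_programs = list(
      list(leaves = c("A", "C", "D"), n_genes = 5, log_mean = log(3)),
      list(leaves = c("B", "C"), n_genes = 5, log_mean = log(3)),
      list(leaves = c("C", "A", "B"), n_genes = 5, log_mean = log(3)),
      list(leaves = c("D", "A", "B"), n_genes = 5, log_mean = log(3))),
    marker_genes_per_leaf = 0, seed = 8)
  sim <- simulate_atlas(cfg)
  labels <- labels_from_nodes(sim$truth$tree, sim$truth$cells$true_leaf)
  mk <- hierarchical_markers(sim$atlas, labels, sim$truth$tree)
  # A's program genes appear in 2/3 of non-A pseudo-bulk types at atlas
  # scope (C and D), so iteration 1 must fail and compartment scope succeed
  expect_gte(mk[["A"]]$iteration, 2)
  expect_gt(length(mk[["A"]]$genes), 0)
})
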