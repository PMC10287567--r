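test_that("shannon entropy matches its definition and fixes natural log", {
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(rep(1 / 7, 7)), log(7))
  expect_equal(round(shannon_entropy(c(0.75, 0.25)), 2), 0.56)
  # the printed 0.56 pins the natural log: log2 would give 0.81
  expect_equal(round(-(0.75 * log2(0.75) + 0.25 * log2(0.25)), 2), 0.81)
  # brute-force oracle on random simplex draws
  set.seed(5)
  for (i in 1:25) {
    p <- rexp(sample(2:12, 1)); p <- p / sum(p)
    expect_equal(shannon_entropy(p), -sum(p * log(p)), tolerance = 1e-12)
  }
  expect_error(shannon_entropy(c(-0.1, 1.1)), "non-negative")
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
})

test_that("entropy thresholds reproduce the published anchor values", {
  thr <- entropy_thresholds(n_donors = 107)
  expect_equal(round(thr$label_threshold, 2), 0.56)
  expect_equal(round(thr$donor_threshold, 2), 0.43)
  expect_equal(entropy_thresholds(donor_majority = 1, n_donors = 10)$donor_threshold, 0)
})

test_that("cluster entropies respect labeling coverage and donor mixing", {
  # 20-cell fixture: cluster a has labels 10/6/4 -> hand-computed entropy
  clusters <- rep(c("a", "b"), each = 20)
  labels <- c(rep(c("x", "y", "z"), c(10, 6, 4)),
              c(rep("x", 3), rep("none", 17)))       # b: 15% labeled
  donors <- c(rep(c("d1", "d2"), 10), rep("d1", 20)) # b: single donor
  rep_ <- cluster_entropies(clusters, labels, donors)
  p <- c(10, 6, 4) / 20
  expect_equal(rep_$label_entropy[rep_$cluster == "a"], -sum(p * log(p)))
  expect_true(is.na(rep_$label_entropy[rep_$cluster == "b"]))
  expect_equal(rep_$donor_entropy[rep_$cluster == "b"], 0)
  expect_equal(rep_$donor_entropy[rep_$cluster == "a"], log(2))
  # flags attach when thresholds are supplied
  thr <- entropy_thresholds(n_donors = 2)
  repf <- cluster_entropies(clusters, labels, donors, thresholds = thr)
  expect_true(all(c("high_label_entropy", "low_donor_entropy") %in%
                    names(repf)))
})

test_that("nested clustering separates blobs, names children, refines", {
  bl <- two_blobs(n_per = 120, sep = 12)
  ids <- nested_cluster(bl$x, schedule = list(c(30, 0.01)), seed = 1)
  expect_equal(length(unique(ids)), 2)
  # perfect agreement with blob truth up to relabeling
  expect_equal(length(unique(paste(ids, bl$truth))), 2)
  # naming convention: depth-2 ids are parent.child with child from 0
  ids2 <- nested_cluster(bl$x, schedule = list(c(30, 0.01), c(15, 0.5)),
                         seed = 1)
  expect_true(all(grepl("^[0-9]+\\.[0-9]+$", ids2) | ids2 %in% unique(ids)))
  # refinement: every level-2 cluster sits inside exactly one level-1 cluster
  lev1 <- cluster_at_level(ids2, 1)
  expect_true(all(tapply(lev1, ids2, function(v) length(unique(v))) == 1))
  # determinism under fixed seed
  expect_identical(ids2, nested_cluster(bl$x, schedule = list(c(30, 0.01),
                                                              c(15, 0.5)),
                                        seed = 1))
  expect_error(nested_cluster(matrix(c(1, NA), 1), list(c(5, 1))),
               "non-finite")
})

test_that("rare-type precision/recall match brute-force confusion counts", {
  labels <- c(rep("rare", 6), rep("common", 14))
  clusters <- c(rep("c1", 4), rep("c2", 2), rep("c1", 2), rep("c2", 6),
                rep("c3", 6))
  pr <- rare_type_pr(clusters, labels, "rare")
  tab <- pr$table
  # brute force
  for (cl in unique(clusters)) {
    n_cl <- sum(clusters == cl)
    n_rare_cl <- sum(clusters == cl & labels == "rare")
    expect_equal(tab$precision[tab$cluster == cl], n_rare_cl / n_cl)
    expect_equal(tab$recall[tab$cluster == cl], n_rare_cl / 6)
  }
  expect_equal(pr$best, "c1")
  expect_equal(sum(tab$recall), 1)  # recalls sum to 1 over any partition
  # pure single cluster -> (1, 1)
  pr2 <- rare_type_pr(rep(c("a", "b"), c(3, 5)),
                      rep(c("rare", "o"), c(3, 5)), "rare")
  expect_equal(pr2$table$precision[pr2$table$cluster == "a"], 1)
  expect_equal(pr2$table$recall[pr2$table$cluster == "a"], 1)
  expect_error(rare_type_pr(clusters, labels, "absent"), "not present")
})

test_that("doublet flags need high entropy, small size and two lineages", {
  # constructed expression: 60 epithelial-ish, 60 immune-ish, 12 doublets,
  # 12 high-entropy but single-lineage cells
  set.seed(9)
  n <- 144
  expr <- matrix(rpois(n * 6, 0.2), n, 6,
                 dimnames = list(NULL, paste0("g", 1:6)))
  ep <- 1:60; im <- 61:120; db <- 121:132; he <- 133:144
  expr[ep, 1:2] <- expr[ep, 1:2] + 5
  expr[im, 3:4] <- expr[im, 3:4] + 5
  expr[db, 1:4] <- expr[db, 1:4] + 2.5
  expr[he, 1:2] <- expr[he, 1:2] + 5    # epithelial profile, mixed labels
  clusters <- rep(c("ep", "im", "db", "he"), c(60, 60, 12, 12))
  lab1 <- c(rep("epithelial", 60), rep("immune", 60),
            rep(c("epithelial", "immune"), 6),   # disagreement in db
            rep(c("epithelial", "immune"), 6))   # disagreement in he
  donors <- rep(c("d1", "d2"), n / 2)
  thr <- entropy_thresholds(n_donors = 2)
  rep_ <- cluster_entropies(clusters, lab1, donors, thresholds = thr)
  markers <- list(epithelial = c("g1", "g2"), immune = c("g3", "g4"))
  out <- flag_doublet_clusters(rep_, clusters, markers, expr, max_size = 20)
  expect_true(out$doublet_candidate[out$cluster == "db"])
  expect_false(out$doublet_candidate[out$cluster == "ep"])   # pure
  expect_false(out$doublet_candidate[out$cluster == "he"])   # one lineage
  # absent marker genes warn and are dropped
  expect_warning(
    flag_doublet_clusters(rep_, clusters,
                          list(epithelial = c("g1", "nope"),
                               immune = "g3"), expr, max_size = 20),
    "absent")
  expect_error(flag_doublet_clusters(rep_, clusters,
                                     list(epithelial = "g1"), expr),
               "two lineages")
})

test_that("label-set recovery applies the recall/precision trade-off rules", {
  pick <- atlaskit:::select_candidate_cluster
  # plain max recall when precisions are comparable
  cand <- data.frame(resolution = 1, cluster = 1:2, n = c(50, 40),
                     recall = c(0.9, 0.7), precision = c(0.5, 0.55))
  expect_equal(pick(cand)$cluster, 1)
  # doubling precision with <=20% recall drop wins
  cand2 <- data.frame(resolution = 1, cluster = 1:2, n = c(50, 40),
                      recall = c(0.9, 0.75), precision = c(0.3, 0.62))
  expect_equal(pick(cand2)$cluster, 2)
  # >33% precision loss versus runner-up dethrones the max-recall cluster
  cand3 <- data.frame(resolution = 1, cluster = 1:2, n = c(50, 40),
                      recall = c(0.9, 0.85), precision = c(0.3, 0.5))
  expect_equal(pick(cand3)$cluster, 2)
  expect_null(pick(cand3[0, ]))

  # end to end: a tight target blob is recovered with recall 1
  bl <- two_blobs(n_per = 80, sep = 14, seed = 3)
  query <- rep(TRUE, nrow(bl$x))
  target <- bl$truth == 2
  res <- recover_labelset_cluster(bl$x, query, target,
                                  resolutions = c(0.1, 1), seed = 1)
  expect_equal(res$selected$recall, 1)
  expect_equal(res$selected$precision, 1)
  # unreachable target -> none
  set.seed(4)
  scattered <- sample(which(bl$truth == 1), 8)
  target2 <- seq_len(nrow(bl$x)) %in% scattered
  res2 <- recover_labelset_cluster(bl$x, query, target2,
                                   resolutions = c(0.1), seed = 1)
  expect_null(res2$selected)
})
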