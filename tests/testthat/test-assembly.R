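test_that("cell and gene detection filters apply their exact thresholds", {
  # 3 cells: 199, 200 and 250 detected genes out of 260
  m <- matrix(0L, 3, 260)
  m[1, 1:199] <- 1L
  m[2, 1:200] <- 1L
  m[3, 1:250] <- 1L
  out <- filter_cells_genes(toy_atlas(m), min_genes_per_cell = 200,
                            min_cells_per_gene = 0)
  expect_equal(out$cell_meta$cell_id, c("c2", "c3"))

  # gene detected in exactly 10 cells kept, 9 removed
  m2 <- matrix(0L, 12, 3)
  m2[1:10, 1] <- 1L
  m2[1:9, 2] <- 1L
  m2[, 3] <- 1L
  out2 <- filter_cells_genes(toy_atlas(m2), min_genes_per_cell = 0,
                             min_cells_per_gene = 10)
  expect_equal(colnames(out2$counts), c("g1", "g3"))
})

test_that("toy matrix filtering matches hand enumeration and fixed point", {
  # 5 cells x 4 genes; gene g4 all-zero; thresholds 2 genes/cell, 2 cells/gene
  m <- rbind(c(1, 1, 1, 0),
             c(1, 1, 0, 0),
             c(1, 0, 1, 0),
             c(1, 0, 0, 0),   # only 1 gene detected -> cell dropped
             c(0, 1, 1, 0))
  out <- filter_cells_genes(toy_atlas(m), min_genes_per_cell = 2,
                            min_cells_per_gene = 2)
  # cells c1,c2,c3,c5 survive; genes g1 (3 cells), g2 (3), g3 (3) survive
  expect_equal(out$cell_meta$cell_id, c("c1", "c2", "c3", "c5"))
  expect_equal(colnames(out$counts), c("g1", "g2", "g3"))

  # fixed-point variant equals iterating the single-pass filter
  sim <- small_sim()$sim
  once <- filter_cells_genes(sim$atlas, 150, 10)
  twice <- filter_cells_genes(once, 150, 10)
  fp <- filter_cells_genes(sim$atlas, 150, 10, fixed_point = TRUE)
  # iterate manually until stable
  prev <- sim$atlas
  repeat {
    nxt <- filter_cells_genes(prev, 150, 10)
    if (all(dim(nxt$counts) == dim(prev$counts))) break
    prev <- nxt
  }
  expect_equal(dim(fp$counts), dim(prev$counts))
  expect_error(filter_cells_genes(toy_atlas(matrix(0L, 2, 3)), 1, 1),
               "empty atlas")
})

test_that("size-factor screen removes low factors and high normalized totals", {
  m <- matrix(5L, 4, 10)  # every cell total 50
  at <- toy_atlas(m, size_factor = c(1, 0.005, 1, 4e-5))
  # c2: sf < 0.01; c4: 50 / 4e-5 = 1.25e6 > 1e6 (and sf < 0.01 anyway)
  out <- screen_size_factors(at)
  expect_equal(out$cell_meta$cell_id, c("c1", "c3"))
  # identity when all factors are 1 and totals small
  at2 <- toy_atlas(m, size_factor = rep(1, 4))
  expect_equal(dim(screen_size_factors(at2)$counts), c(4L, 10L))
  # normalized-total bound alone
  at3 <- toy_atlas(m, size_factor = c(1, 1, 1, 50 / 1.1e6))
  expect_equal(screen_size_factors(at3)$cell_meta$cell_id,
               c("c1", "c2", "c3"))
  expect_error(screen_size_factors(toy_atlas(m)), "missing size factors")
})

test_that("lognormalize scales rows to the target then log-transforms", {
  at <- toy_atlas(rbind(c(2, 2, 6)))
  expect_equal(as.numeric(lognormalize(at, target_sum = 10)),
               log(c(2, 2, 6) + 1))
  # brute-force row-wise oracle on a random matrix
  set.seed(7)
  m <- matrix(rpois(60, 3), 6, 10)
  got <- as.matrix(lognormalize(toy_atlas(m), target_sum = 1e4))
  want <- t(apply(m, 1, function(r) log1p(r / sum(r) * 1e4)))
  dimnames(want) <- dimnames(got)
  expect_equal(got, want, tolerance = 1e-12)
  # all-zero cell stays zero with a warning
  m[2, ] <- 0
  expect_warning(out <- lognormalize(toy_atlas(m)), "all-zero")
  expect_true(all(as.matrix(out)[2, ] == 0))
})

test_that("label harmonization fills ancestor chains and respects mappings", {
  sim <- small_sim()$sim
  tree <- sim$truth$tree
  lab <- harmonize_labels(tree, sim$atlas)
  # level-4 mapped cells: levels 1-4 filled, level 5 none
  i <- which(sim$atlas$cell_meta$original_label == "CD8_T")[1]
  expect_equal(unlist(lab[i, ], use.names = FALSE),
               c("immune", "lymphoid", "T_lineage", "CD8_T", "none"))
  # unlabeled -> none everywhere
  j <- which(sim$atlas$cell_meta$original_label == "unlabeled")[1]
  expect_true(all(lab[j, ] == "none"))
  # parent-chain property: level L is the tree parent of level L+1
  nd <- tree$nodes
  for (l in 1:4) {
    a <- lab[[paste0("level", l)]]; b <- lab[[paste0("level", l + 1)]]
    both <- a != "none" & b != "none"
    expect_true(all(nd$parent[match(b[both], nd$name)] == a[both]))
  }
  # a dataset-specific remapping moves the cell to the mapped node's lineage
  tree2 <- label_tree(tree$nodes, mappings = stats::setNames(list(
    c(monocyte = "dendritic")), sim$atlas$cell_meta$dataset[1]))
  at <- atlas_subset(sim$atlas,
                     cells = which(sim$atlas$cell_meta$original_label ==
                                     "monocyte" &
                                   sim$atlas$cell_meta$dataset ==
                                     sim$atlas$cell_meta$dataset[1]))
  lab2 <- harmonize_labels(tree2, at)
  expect_true(all(lab2$level3 == "dendritic"))
  # unmapped labels error unless allowed
  at2 <- atlas_subset(sim$atlas, cells = 1:50)
  tree3 <- label_tree(tree$nodes, mappings = stats::setNames(list(
    c(nonexistent = "basal")), at2$cell_meta$dataset[1]))
  expect_error(harmonize_labels(tree3, at2), "unmapped")
  expect_silent(harmonize_labels(tree3, at2, allow_unlabeled = TRUE))
})

test_that("label_tree validates structure", {
  nodes <- tiny_tree_spec()$nodes
  expect_s3_class(label_tree(nodes), "label_tree")
  bad <- nodes; bad$level[3] <- 3  # parent level != child level - 1
  expect_error(label_tree(bad), "parent level")
  bad2 <- nodes; bad2$parent[1] <- "A"
  expect_error(label_tree(bad2), "level-1")
})

test_that("summing collided genes conserves per-cell totals", {
  at <- toy_atlas(cbind(c(1, 0), c(2, 3)))
  out <- sum_collided_genes(at, list(t1 = c("g1", "g2")))
  expect_equal(as.numeric(out$counts[, "t1"]), c(3, 3))
  # singleton group is identity up to renaming
  out2 <- sum_collided_genes(at, list(t1 = "g1"))
  expect_equal(as.numeric(out2$counts[, "t1"]), c(1, 0))
  # conservation on a random 8-gene fixture
  set.seed(3)
  m <- matrix(rpois(40, 2), 5, 8)
  at3 <- toy_atlas(m)
  out3 <- sum_collided_genes(at3, list(x = c("g1", "g4", "g7"),
                                       y = c("g2", "g3")))
  expect_equal(Matrix::rowSums(out3$counts), Matrix::rowSums(at3$counts))
  expect_error(sum_collided_genes(at3, list(x = c("g1", "nope"))),
               "unknown genes")
})
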