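# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# small planted atlas reused across modules (~1,800 cells)
small_sim <- function() {
  if (is.null(.fixtures$sim)) {
    cfg <- sim_config(n_datasets = 3, donors_per_dataset = 4,
                      cells_per_donor = 150, n_genes = 500, seed = 42)
    .fixtures$cfg <- cfg
    .fixtures$sim <- suppressWarnings(simulate_atlas(cfg))
  }
  list(cfg = .fixtures$cfg, sim = .fixtures$sim)
}

# minimal single-sample atlas around a given count matrix
toy_atlas <- function(counts, size_factor = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  cm <- data.frame(cell_id = paste0("c", seq_len(n)), dataset = "d1",
                   donor = "don1", sample = "s1", original_label = "x",
                   stringsAsFactors = FALSE)
  if (!is.null(size_factor)) cm$size_factor <- size_factor
  sm <- data.frame(sample = "s1", donor = "don1", dataset = "d1",
                   stringsAsFactors = FALSE)
  atlas_table(counts, cm, sm)
}

# two well-separated Gaussian blobs in d dimensions
two_blobs <- function(n_per = 100, d = 5, sep = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d), n_per),
             matrix(rnorm(n_per * d), n_per) + sep / sqrt(d))
  list(x = x, truth = rep(1:2, each = n_per))
}

# tiny four-leaf tree used by assembly/marker tests
tiny_tree_spec <- function() {
  nodes <- data.frame(
    name = c("comp1", "comp2", "A", "B", "C", "D"),
    level = c(1, 1, 2, 2, 2, 2),
    parent = c(NA, NA, "comp1", "comp1", "comp2", "comp2"),
    stringsAsFactors = FALSE)
  list(nodes = nodes, leaf_freq = c(A = 0.3, B = 0.3, C = 0.2, D = 0.2))
}
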