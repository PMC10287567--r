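# Synthetic multi-dataset atlas with planted ground truth.
#
# The generator reproduces the statistical structure the downstream
# stages assume: gamma-Poisson (negative binomial) counts with
# leaf-specific mean programs, multiplicative dataset (batch) shifts,
# donor random effects, covariate-linked log-linear gene modules, doublet
# cells averaging two lineages, and a latent embedding built from the
# true low-dimensional factors. Queries can carry disease-shifted states
# absent from the reference.

#' Default five-level cell-identity hierarchy used by the simulator
#'
#' A lung-like hierarchy: four compartments (epithelial, immune,
#' endothelial, stromal), finer lineages below, and leaves at depths 3-5
#' including one rare type (ionocyte, frequency 8e-4). Leaf frequencies
#' sum to 1.
#'
#' @return List with `nodes` (data.frame `name`, `level`, `parent`) and
#'   `leaf_freq` (named numeric).
#' @export
default_sim_tree <- function() {
  n <- function(name, level, parent) data.frame(name = name, level = level,
                                                parent = parent,
                                                stringsAsFactors = FALSE)
  nodes <- rbind(
    n("epithelial", 1, NA), n("immune", 1, NA),
    n("endothelial", 1, NA), n("stromal", 1, NA),
    n("airway_epithelial", 2, "epithelial"),
    n("alveolar_epithelial", 2, "epithelial"),
    n("myeloid", 2, "immune"), n("lymphoid", 2, "immune"),
    n("blood_vessel_ec", 2, "endothelial"),
    n("lymphatic_ec", 2, "endothelial"),
    n("fibroblast_lineage", 2, "stromal"),
    n("smooth_muscle_lineage", 2, "stromal"),
    n("basal", 3, "airway_epithelial"),
    n("secretory", 3, "airway_epithelial"),
    n("multiciliated", 3, "airway_epithelial"),
    n("rare_epithelial", 3, "airway_epithelial"),
    n("AT1", 3, "alveolar_epithelial"), n("AT2", 3, "alveolar_epithelial"),
    n("alveolar_macrophage", 3, "myeloid"), n("monocyte", 3, "myeloid"),
    n("dendritic", 3, "myeloid"),
    n("T_lineage", 3, "lymphoid"), n("NK", 3, "lymphoid"),
    n("B_lineage", 3, "lymphoid"),
    n("capillary_ec", 3, "blood_vessel_ec"),
    n("venous_ec", 3, "blood_vessel_ec"),
    n("lymphatic_ec_mature", 3, "lymphatic_ec"),
    n("alveolar_fibroblast", 3, "fibroblast_lineage"),
    n("adventitial_fibroblast", 3, "fibroblast_lineage"),
    n("smooth_muscle", 3, "smooth_muscle_lineage"),
    n("ionocyte", 4, "rare_epithelial"),
    n("CD8_T", 4, "T_lineage"), n("CD4_T", 4, "T_lineage"),
    n("naive_CD4_T", 5, "CD4_T"), n("memory_CD4_T", 5, "CD4_T"))
  leaf_freq <- c(basal = 0.06, secretory = 0.08, multiciliated = 0.06,
                 ionocyte = 8e-4, AT1 = 0.06, AT2 = 0.10,
                 alveolar_macrophage = 0.10, monocyte = 0.06,
                 dendritic = 0.025, CD8_T = 0.05, naive_CD4_T = 0.04,
                 memory_CD4_T = 0.03, NK = 0.05, B_lineage = 0.025,
                 capillary_ec = 0.04, venous_ec = 0.025,
                 lymphatic_ec_mature = 0.02, alveolar_fibroblast = 0.06,
                 adventitial_fibroblast = 0.05, smooth_muscle = 0.0642)
  list(nodes = nodes, leaf_freq = leaf_freq)
}

#' Simulation configuration
#'
#' The defaults define the standard study conditions used throughout the
#' package's validation: 8 datasets of 6 donors with 250 cells each, 800
#' genes, moderate batch effects, one rare cell type, two
#' covariate-linked gene modules, 1% doublets and one disease state
#' planted on alveolar fibroblasts.
#'
#' @param n_datasets,donors_per_dataset,cells_per_donor Atlas shape.
#' @param n_genes Number of genes.
#' @param label_tree_spec Hierarchy and leaf frequencies; see
#'   [default_sim_tree()].
#' @param batch_effect_sd SD of dataset-specific per-gene log-mean
#'   shifts.
#' @param donor_effect_sd SD of donor-specific per-gene log-mean shifts.
#' @param covariate_effects List of planted covariate modules, each
#'   `list(covariate, leaves, n_genes, gene_effect, latent_effect)`.
#' @param doublet_rate Fraction of cells replaced by doublets.
#' @param disease_states List of planted disease states, each
#'   `list(base, toward, n_program_genes, program_log_fc, shift_frac)`.
#' @param shared_programs List of gene programs shared across the listed
#'   leaves, each `list(leaves, n_genes, log_mean)`; lets tests construct
#'   types indistinguishable at atlas scope.
#' @param embed_dim Latent embedding dimension (default 30).
#' @param embed_batch_sd SD of residual per-dataset offsets added to the
#'   embedding; 0 emulates a well-integrated embedding.
#' @param within_sd Within-cell-type latent noise SD.
#' @param marker_genes_per_leaf,marker_genes_per_node Planted marker
#'   block sizes.
#' @param query_datasets,query_donors_per_dataset Shape of query sets
#'   from [simulate_query()].
#' @param unlabeled_frac Fraction of cells left unlabeled per dataset.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_datasets = 8, donors_per_dataset = 6,
                       cells_per_donor = 250, n_genes = 800,
                       label_tree_spec = default_sim_tree(),
                       batch_effect_sd = 0.15, donor_effect_sd = 0.08,
                       covariate_effects = list(
                         list(covariate = "age", leaves = "AT2",
                              n_genes = 30, gene_effect = 1.2,
                              latent_effect = 2.5),
                         list(covariate = "smoking", leaves = "secretory",
                              n_genes = 20, gene_effect = 1.0,
                              latent_effect = 1.5)),
                       doublet_rate = 0.01,
                       disease_states = list(
                         list(base = "alveolar_fibroblast",
                              toward = "adventitial_fibroblast",
                              n_program_genes = 10, program_log_fc = 5,
                              shift_frac = 0.5)),
                       shared_programs = list(),
                       embed_dim = 30, embed_batch_sd = 0, within_sd = 0.5,
                       marker_genes_per_leaf = 5, marker_genes_per_node = 5,
                       query_datasets = 2, query_donors_per_dataset = 6,
                       unlabeled_frac = 0.05, seed = 0L) {
  cfg <- as.list(environment())
  freq <- cfg$label_tree_spec$leaf_freq
  if (any(freq <= 0)) stop("all leaf frequencies must be > 0")
  if (abs(sum(freq) - 1) > 1e-8)
    stop("leaf frequencies must sum to 1 (got ", sum(freq), ")")
  nodes <- cfg$label_tree_spec$nodes
  parents <- unique(stats::na.omit(nodes$parent))
  leaves <- setdiff(nodes$name, parents)
  if (!setequal(names(freq), leaves))
    stop("leaf_freq names must be exactly the tree leaves")
  if (cfg$n_datasets < 1 || cfg$donors_per_dataset < 1 ||
      cfg$cells_per_donor < 1)
    stop("zero cells requested")
  for (ds in cfg$disease_states)
    if (!ds$base %in% leaves)
      stop("disease base leaf absent from tree: ", ds$base)
  structure(cfg, class = "sim_config")
}

# gene architecture, leaf programs and latent geometry, all drawn from
# the config seed; shared by reference and query generation
sim_blueprint <- function(config) {
  set.seed(config$seed)
  nodes <- config$label_tree_spec$nodes
  freq <- config$label_tree_spec$leaf_freq
  leaves <- names(freq)
  G <- config$n_genes
  genes <- sprintf("gene%04d", seq_len(G))
  tree <- label_tree(nodes)
  anc <- lapply(stats::setNames(nodes$name, nodes$name),
                function(n) tree_ancestry(tree, n))
  leaf_anc <- anc[leaves]

  next_gene <- 0L
  take <- function(k) {
    if (next_gene + k > G) stop("n_genes too small for the planted blocks")
    out <- next_gene + seq_len(k)
    next_gene <<- next_gene + k
    out
  }
  node_markers <- lapply(stats::setNames(nodes$name, nodes$name), function(n) {
    k <- if (n %in% leaves) config$marker_genes_per_leaf else
      config$marker_genes_per_node
    take(k)
  })
  cov_modules <- lapply(config$covariate_effects, function(ce) {
    ce$genes <- take(ce$n_genes); ce
  })
  disease_programs <- lapply(config$disease_states, function(ds) {
    ds$genes <- take(ds$n_program_genes); ds
  })
  shared <- lapply(config$shared_programs, function(sp) {
    sp$genes <- take(sp$n_genes); sp
  })
  planted <- seq_len(next_gene)

  base_log_mu <- stats::rnorm(G, mean = log(0.8), sd = 1)
  base_log_mu[planted] <- log(0.01)
  leaf_log_mu <- matrix(rep(base_log_mu, each = length(leaves)),
                        nrow = length(leaves), dimnames = list(leaves, genes))
  for (nd in nodes$name) {
    under <- leaves[vapply(leaf_anc, function(a) nd %in% a, logical(1))]
    lvl <- if (nd %in% leaves) log(3) else log(2)
    leaf_log_mu[under, node_markers[[nd]]] <- lvl
  }
  for (sp in shared)
    leaf_log_mu[sp$leaves, sp$genes] <- sp$log_mean
  size <- exp(stats::rnorm(G, log(5), 0.5))

  d <- config$embed_dim
  level_scale <- c(6, 3, 2, 1.5, 1.2)
  node_dir <- lapply(stats::setNames(nodes$name, nodes$name), function(n) {
    lvl <- nodes$level[match(n, nodes$name)]
    stats::rnorm(d) / sqrt(d) * level_scale[lvl]
  })
  centroids <- t(vapply(leaves, function(l) {
    Reduce(`+`, node_dir[setdiff(leaf_anc[[l]], "none")])
  }, numeric(d)))
  cov_modules <- lapply(cov_modules, function(ce) {
    ce$latent_dir <- stats::rnorm(d) / sqrt(d) * ce$latent_effect
    ce
  })
  list(genes = genes, leaves = leaves, freq = freq, tree = tree,
       leaf_anc = leaf_anc, node_markers = node_markers,
       cov_modules = cov_modules, disease_programs = disease_programs,
       shared = shared, base_log_mu = base_log_mu, leaf_log_mu = leaf_log_mu,
       size = size, centroids = centroids, d = d,
       level1 = vapply(leaf_anc, `[`, character(1), 1))
}

# encoded covariate value in [0,1] used for planted effects
encode_sim_covariate <- function(name, donor_row, sample_row) {
  switch(name,
         age = (donor_row$age - 20) / 60,
         bmi = (donor_row$bmi - 18) / 22,
         sex = as.numeric(donor_row$sex == "female"),
         smoking = c(never = 0, former = 0.5, current = 1)[donor_row$smoking],
         ccf_score = sample_row$ccf_score,
         stop("unknown simulated covariate: ", name))
}

sim_donor_table <- function(config, dataset_ids, donors_per_dataset, prefix) {
  n_donors <- length(dataset_ids) * donors_per_dataset
  anchors <- c("inferior_turbinate", "trachea", "generation_4",
               "generation_8", "generation_12", "alveolar_sac")
  donors <- data.frame(
    donor = sprintf("%sdonor%02d", prefix, seq_len(n_donors)),
    dataset = rep(dataset_ids, each = donors_per_dataset),
    age = stats::runif(n_donors, 20, 80),
    bmi = stats::runif(n_donors, 18, 40),
    sex = sample(c("male", "female"), n_donors, replace = TRUE),
    smoking = sample(c("never", "former", "current"), n_donors,
                     replace = TRUE),
    stringsAsFactors = FALSE)
  donors$sample <- paste0(donors$donor, "_s1")
  donors$location <- sample(anchors, n_donors, replace = TRUE)
  donors$ccf_score <- ccf_score(donors$location)
  donors
}

# core generator shared by reference and query; one sample per donor
sim_cells <- function(config, bp, donors, disease_fraction = 0,
                      displacement = NULL) {
  leaves <- bp$leaves
  freq <- bp$freq
  total_cells <- nrow(donors) * config$cells_per_donor
  drop_leaf <- names(freq)[freq * total_cells < 1]
  if (length(drop_leaf)) {
    warning("expected < 1 cell for rare type(s) ",
            paste(drop_leaf, collapse = ", "), "; emitting zero cells")
    freq <- freq[setdiff(names(freq), drop_leaf)]
    freq <- freq / sum(freq)
  }
  use_leaves <- names(freq)
  G <- config$n_genes
  datasets <- unique(donors$dataset)
  batch_shift <- matrix(stats::rnorm(length(datasets) * G, 0,
                                     config$batch_effect_sd),
                        nrow = length(datasets),
                        dimnames = list(datasets, NULL))
  donor_shift <- matrix(stats::rnorm(nrow(donors) * G, 0,
                                     config$donor_effect_sd),
                        nrow = nrow(donors),
                        dimnames = list(donors$donor, NULL))
  donor_latent <- matrix(stats::rnorm(nrow(donors) * bp$d, 0, 0.1),
                         nrow = nrow(donors),
                         dimnames = list(donors$donor, NULL))
  batch_latent <- matrix(stats::rnorm(length(datasets) * bp$d, 0,
                                      config$embed_batch_sd),
                         nrow = length(datasets),
                         dimnames = list(datasets, NULL))
  depth_cycle <- rep(c(3, 4, 5), length.out = length(datasets))
  names(depth_cycle) <- datasets

  counts_parts <- list(); latent_parts <- list(); meta_parts <- list()
  truth_parts <- list()
  for (di in seq_len(nrow(donors))) {
    dn <- donors[di, ]
    n <- config$cells_per_donor
    leaf <- sample(use_leaves, n, replace = TRUE, prob = freq)
    log_mu <- bp$leaf_log_mu[leaf, , drop = FALSE] +
      rep(batch_shift[dn$dataset, ], each = n) +
      rep(donor_shift[dn$donor, ], each = n)
    latent <- bp$centroids[leaf, , drop = FALSE] +
      matrix(stats::rnorm(n * bp$d, 0, config$within_sd), n) +
      rep(donor_latent[dn$donor, ], each = n) +
      rep(batch_latent[dn$dataset, ], each = n)
    for (ce in bp$cov_modules) {
      affected <- leaf %in% ce$leaves
      if (!any(affected)) next
      v <- encode_sim_covariate(ce$covariate, dn, dn) - 0.5
      log_mu[affected, ce$genes] <- log_mu[affected, ce$genes] +
        ce$gene_effect * v
      latent[affected, ] <- latent[affected, ] +
        rep(ce$latent_dir * v, each = sum(affected))
    }
    diseased <- rep(FALSE, n)
    if (disease_fraction > 0) {
      for (ds in bp$disease_programs) {
        base_cells <- which(leaf == ds$base)
        hit <- base_cells[stats::runif(length(base_cells)) < disease_fraction]
        if (!length(hit)) next
        diseased[hit] <- TRUE
        frac <- if (is.null(displacement)) ds$shift_frac else displacement
        delta <- bp$centroids[ds$toward, ] - bp$centroids[ds$base, ]
        latent[hit, ] <- latent[hit, ] + rep(frac * delta, each = length(hit))
        # expression follows the realized position along the disease axis:
        # cells whose latent noise kept them near the healthy centroid
        # express the program weakly (a severity continuum), cells deep in
        # the shifted state express it fully
        if (frac > 0) {
          t_eff <- as.numeric(
            (latent[hit, , drop = FALSE] -
               rep(bp$centroids[ds$base, ], each = length(hit))) %*% delta) /
            sum(delta^2)
          severity <- pmin(1, pmax(0, t_eff / frac))
        } else {
          severity <- rep(1, length(hit))
        }
        log_mu[hit, ds$genes] <- log_mu[hit, ds$genes] +
          ds$program_log_fc * severity
      }
    }
    cnt <- matrix(stats::rnbinom(n * G, mu = exp(log_mu),
                                 size = rep(bp$size, each = n)), n, G)
    # doublets: averaged pairs of profiles from distinct level-1 lineages,
    # re-Poissonized; they displace ordinary (non-diseased) cells
    n_dbl <- round(config$doublet_rate * n)
    dbl <- logical(n)
    if (length(unique(bp$level1[use_leaves])) < 2) n_dbl <- 0
    if (n_dbl > 0) {
      cand <- which(!diseased)
      slots <- cand[seq_len(min(n_dbl, length(cand)))]
      for (s in slots) {
        repeat {
          pair <- sample(use_leaves, 2, prob = freq)
          if (bp$level1[pair[1]] != bp$level1[pair[2]]) break
        }
        mu_pair <- exp(bp$leaf_log_mu[pair[1], ] +
                         batch_shift[dn$dataset, ] + donor_shift[dn$donor, ])
        mu_pair <- (mu_pair + exp(bp$leaf_log_mu[pair[2], ] +
                                    batch_shift[dn$dataset, ] +
                                    donor_shift[dn$donor, ])) / 2
        cnt[s, ] <- stats::rpois(G, mu_pair)
        latent[s, ] <- (bp$centroids[pair[1], ] + bp$centroids[pair[2], ]) / 2 +
          stats::rnorm(bp$d, 0, config$within_sd)
        leaf[s] <- pair[1]  # carried (mis)label of one parent
        dbl[s] <- TRUE
      }
    }
    depth <- depth_cycle[dn$dataset]
    orig <- vapply(leaf, function(l) {
      a <- bp$leaf_anc[[l]]
      lv <- min(depth, max(which(a != "none")))
      a[lv]
    }, character(1))
    orig[stats::runif(n) < config$unlabeled_frac] <- "unlabeled"
    cell_id <- sprintf("%s_c%04d", dn$donor, seq_len(n))
    counts_parts[[di]] <- methods::as(methods::as(cnt, "generalMatrix"),
                                      "CsparseMatrix")
    latent_parts[[di]] <- latent
    meta_parts[[di]] <- data.frame(
      cell_id = cell_id, dataset = dn$dataset, donor = dn$donor,
      sample = dn$sample, original_label = orig, stringsAsFactors = FALSE)
    truth_parts[[di]] <- data.frame(
      cell_id = cell_id, true_leaf = leaf, doublet = dbl,
      diseased = diseased, stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, counts_parts)
  colnames(counts) <- bp$genes
  meta <- do.call(rbind, meta_parts)
  rownames(counts) <- meta$cell_id
  totals <- Matrix::rowSums(counts)
  meta$size_factor <- totals / stats::median(totals)
  embedding <- do.call(rbind, latent_parts)
  rownames(embedding) <- meta$cell_id
  sample_meta <- donors[, c("sample", "donor", "dataset", "location",
                            "ccf_score", "age", "sex", "bmi", "smoking")]
  truth <- do.call(rbind, truth_parts)
  rownames(truth) <- NULL
  list(atlas = atlas_table(counts, meta, sample_meta),
       embedding = embedding, cell_truth = truth,
       batch_shift = batch_shift)
}

#' Simulate a reference atlas with planted ground truth
#'
#' @param config A [sim_config()].
#' @return List with `atlas` (an [atlas_table()]), `embedding` (cells x
#'   `embed_dim` latent matrix) and `truth`, which carries the per-cell
#'   true leaf labels, doublet and disease flags, the planted marker map
#'   (`marker_map`, leaf -> gene indices), per-covariate module gene
#'   sets (`covariate_modules`), lineage marker sets usable for doublet
#'   flagging (`lineage_markers`), per-dataset batch shifts, the label
#'   tree, and the generative `blueprint` reused by [simulate_query()].
#' @export
simulate_atlas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bp <- sim_blueprint(config)
  datasets <- sprintf("ds%02d", seq_len(config$n_datasets))
  donors <- sim_donor_table(config, datasets, config$donors_per_dataset, "")
  res <- sim_cells(config, bp, donors)
  leaves <- bp$leaves
  # a leaf's planted markers: its own block plus blocks of ancestors for
  # which it is the sole descendant leaf (those genes are unique to it too)
  marker_map <- lapply(stats::setNames(leaves, leaves), function(l) {
    own <- bp$node_markers[[l]]
    for (a in setdiff(bp$leaf_anc[[l]], c("none", l))) {
      under <- leaves[vapply(bp$leaf_anc, function(x) a %in% x, logical(1))]
      if (identical(under, l)) own <- c(own, bp$node_markers[[a]])
    }
    sort(own)
  })
  lineage_markers <- lapply(bp$node_markers[unique(bp$level1)],
                            function(i) bp$genes[i])
  # all planted genes linked to a leaf's identity at any level: its own
  # block plus every ancestor's block (shared with sibling descendants)
  lineage_map <- lapply(stats::setNames(leaves, leaves), function(l)
    sort(unlist(bp$node_markers[setdiff(bp$leaf_anc[[l]], "none")],
                use.names = FALSE)))
  truth <- list(
    cells = res$cell_truth,
    marker_map = marker_map,
    marker_genes = lapply(marker_map, function(i) bp$genes[i]),
    lineage_marker_genes = lapply(lineage_map, function(i) bp$genes[i]),
    covariate_modules = lapply(bp$cov_modules, function(ce)
      list(covariate = ce$covariate, leaves = ce$leaves,
           genes = bp$genes[ce$genes])),
    disease_programs = lapply(bp$disease_programs, function(ds)
      list(base = ds$base, genes = bp$genes[ds$genes])),
    lineage_markers = lineage_markers,
    batch_shift = res$batch_shift,
    tree = bp$tree,
    blueprint = bp)
  stopifnot(all(unlist(marker_map) <= config$n_genes),
            !any(truth$cells$doublet & truth$cells$diseased))
  list(atlas = res$atlas, embedding = res$embedding, truth = truth)
}

#' Simulate a query set, optionally with disease-shifted states
#'
#' Query cells are drawn from the same generative model (new datasets,
#' new donors, new batch shifts). A fraction `disease_fraction` of cells
#' of each planted disease state's base leaf receives the planted gene
#' program and a latent-space displacement toward a neighbouring type,
#' so their nearest reference neighbours mix labels and transfer
#' uncertainty rises.
#'
#' @param config The [sim_config()] used for the reference.
#' @param truth The `truth` element returned by [simulate_atlas()].
#' @param disease_fraction Fraction of base-leaf query cells shifted
#'   (in \[0, 1\]).
#' @param displacement Optional override of the latent shift fraction
#'   (0 = no displacement).
#' @param seed_offset Added to `config$seed` for the query draw.
#' @return List `atlas`, `embedding`, `truth` (per-cell data.frame with
#'   `true_leaf`, `doublet`, `diseased`).
#' @export
simulate_query <- function(config, truth, disease_fraction = 0,
                           displacement = NULL, seed_offset = 104729L) {
  stopifnot(inherits(config, "sim_config"),
            disease_fraction >= 0, disease_fraction <= 1)
  bp <- truth$blueprint
  set.seed(config$seed + seed_offset)
  datasets <- sprintf("qds%02d", seq_len(config$query_datasets))
  donors <- sim_donor_table(config, datasets,
                            config$query_donors_per_dataset, "q_")
  res <- sim_cells(config, bp, donors, disease_fraction = disease_fraction,
                   displacement = displacement)
  list(atlas = res$atlas, embedding = res$embedding, truth = res$cell_truth)
}
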