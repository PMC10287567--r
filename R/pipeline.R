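#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Global seed; with fixed inputs it fully determines every
#'   output artifact.
#' @param stages Character vector of stages to run, in dependency order;
#'   any subset of `c("simulate", "qc", "transfer", "markers",
#'   "covariates", "disease")`. Stages other than `simulate` require the
#'   simulated (or user-supplied) inputs.
#' @param sim Arguments passed to [sim_config()].
#' @param transfer_k Neighbour count for label transfer.
#' @param unknown_cutoff Uncertainty cutoff for unknown masking.
#' @param disease_fraction Disease fraction for the simulated query.
#' @return A named list usable by [run_pipeline()].
#' @export
pipeline_config <- function(out_dir, seed = 0L,
                            stages = c("simulate", "qc", "transfer",
                                       "markers", "covariates", "disease"),
                            sim = list(), transfer_k = 50,
                            unknown_cutoff = 0.2, disease_fraction = 0.5) {
  list(out_dir = out_dir, seed = seed, stages = stages, sim = sim,
       transfer_k = transfer_k, unknown_cutoff = unknown_cutoff,
       disease_fraction = disease_fraction)
}

pipe_log <- function(con, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
  writeLines(line, con)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the atlas pipeline end to end
#'
#' Executes the enabled stages in dependency order — synthetic data
#' generation (or loading), entropy-based cluster QC, kNN label
#' transfer with unknown masking, hierarchical marker selection,
#' covariate variance attribution and uncertainty-driven disease-state
#' analysis — writing each stage's outputs under `config$out_dir`
#' together with a parameter log and a manifest of artifact content
#' hashes (MD5). Rerunning with the same config and seed reproduces
#' every hash.
#'
#' @param config A [pipeline_config()] list. When `"simulate"` is not
#'   among the stages, `config$input_dir` must point to a directory
#'   written by a previous simulate stage.
#' @return Data.frame manifest: `artifact`, `path`, `md5`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  con <- file(log_path, "w")
  on.exit(close(con))
  artifacts <- character()
  add <- function(p) artifacts <<- c(artifacts, p)
  stage <- "init"
  tryCatch({
    sim <- NULL
    if ("simulate" %in% config$stages) {
      stage <- "simulate"
      pipe_log(con, "stage simulate: seed=", config$seed)
      cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
      sim <- simulate_atlas(cfg)
      qry <- simulate_query(cfg, sim$truth,
                            disease_fraction = config$disease_fraction)
      add(write_atlas(sim$atlas, file.path(config$out_dir, "reference")))
      emb <- data.frame(cell_id = rownames(sim$embedding), sim$embedding)
      add(write_tsv(emb, file.path(config$out_dir, "reference_embedding.tsv")))
      add(write_atlas(qry$atlas, file.path(config$out_dir, "query")))
      qemb <- data.frame(cell_id = rownames(qry$embedding), qry$embedding)
      add(write_tsv(qemb, file.path(config$out_dir, "query_embedding.tsv")))
      truth_json <- file.path(config$out_dir, "truth.json")
      jsonlite::write_json(list(
        reference_cells = sim$truth$cells, query_cells = qry$truth,
        marker_genes = sim$truth$marker_genes,
        disease_programs = sim$truth$disease_programs),
        truth_json, auto_unbox = TRUE, digits = NA)
      add(truth_json)
      labels <- harmonize_labels(sim$truth$tree, sim$atlas)
      sim$labels <- labels
      sim$query <- qry
    } else {
      stage <- "load"
      if (is.null(config$input_dir))
        stop("no input_dir configured and simulate stage disabled")
      stop("loading external inputs requires the simulate outputs at ",
           config$input_dir)
    }
    expr <- lognormalize(sim$atlas)

    if ("qc" %in% config$stages) {
      stage <- "qc"
      pipe_log(con, "stage qc: nested clustering + entropies")
      clusters <- nested_cluster(sim$embedding,
                                 schedule = list(c(30, 0.01), c(30, 0.2)),
                                 seed = config$seed)
      thr <- entropy_thresholds(
        n_donors = length(unique(sim$atlas$cell_meta$donor)))
      rep1 <- cluster_entropies(clusters, sim$labels$level1,
                                sim$atlas$cell_meta$donor, thresholds = thr)
      rep1 <- flag_doublet_clusters(rep1, clusters,
                                    sim$truth$lineage_markers, expr)
      add(write_tsv(data.frame(cell_id = rownames(sim$embedding),
                               cluster = clusters),
                    file.path(config$out_dir, "clusters.tsv")))
      add(write_tsv(rep1, file.path(config$out_dir, "cluster_entropy.tsv")))
      flags_json <- file.path(config$out_dir, "cluster_flags.json")
      jsonlite::write_json(list(
        label_threshold = thr$label_threshold,
        donor_threshold = thr$donor_threshold,
        doublet_candidates = rep1$cluster[rep1$doublet_candidate]),
        flags_json, auto_unbox = TRUE, digits = NA)
      add(flags_json)
    }

    transfer <- NULL
    if ("transfer" %in% config$stages) {
      stage <- "transfer"
      pipe_log(con, "stage transfer: k=", config$transfer_k)
      ref_lab <- finest_label(sim$labels)
      transfer <- knn_transfer(sim$embedding, ref_lab, sim$query$embedding,
                               k = config$transfer_k)
      transfer <- apply_unknown_cutoff(transfer, config$unknown_cutoff)
      add(write_tsv(transfer$table,
                    file.path(config$out_dir, "transfer.tsv")))
    }

    if ("markers" %in% config$stages) {
      stage <- "markers"
      pipe_log(con, "stage markers: hierarchical pseudo-bulk selection")
      mk <- hierarchical_markers(sim$atlas, sim$labels, sim$truth$tree,
                                 expr = expr)
      tab <- do.call(rbind, lapply(mk, function(m) if (length(m$genes))
        data.frame(cell_type = m$cell_type, gene = m$genes,
                   iteration = m$iteration, scope = m$scope)))
      add(write_tsv(tab, file.path(config$out_dir, "markers.tsv")))
    }

    if ("covariates" %in% config$stages) {
      stage <- "covariates"
      pipe_log(con, "stage covariates: variance attribution")
      vr <- variance_report(sim$atlas, sim$embedding,
                            finest_label(sim$labels),
                            covariates = c("age", "sex", "bmi", "smoking",
                                           "ccf_score", "dataset"),
                            min_samples = 20)
      out <- data.frame(cell_type = rownames(vr$fractions), vr$fractions)
      add(write_tsv(out, file.path(config$out_dir, "variance_report.tsv")))
    }

    if ("disease" %in% config$stages) {
      stage <- "disease"
      if (is.null(transfer)) stop("disease stage requires the transfer stage")
      pipe_log(con, "stage disease: uncertainty strata + signature")
      base <- sim$truth$disease_programs[[1]]$base
      sel <- which(transfer$table$label == base)
      strata <- uncertainty_strata(transfer$table$uncertainty[sel])
      qexpr <- lognormalize(sim$query$atlas)
      sig <- signature_genes(qexpr[sel, , drop = FALSE],
                             strata$low, strata$high)
      score <- score_cells(qexpr, sig, seed = config$seed)
      add(write_tsv(data.frame(gene = sig),
                    file.path(config$out_dir, "disease_signature.tsv")))
      add(write_tsv(data.frame(cell_id = transfer$table$cell, score = score),
                    file.path(config$out_dir, "disease_score.tsv")))
    }
  }, error = function(e) {
    pipe_log(con, "FAILED at stage ", stage, ": ", conditionMessage(e))
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  manifest <- data.frame(
    artifact = basename(artifacts), path = artifacts,
    md5 = unname(tools::md5sum(artifacts)), stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  manifest
}

#' Run the pipeline from a YAML configuration file
#'
#' Thin wrapper for shell use: reads the YAML, overrides seed/out_dir if
#' given, and calls [run_pipeline()].
#'
#' @param path Path to a YAML file with [pipeline_config()] fields.
#' @param out_dir,seed Optional overrides.
#' @return The manifest data.frame, invisibly.
#' @export
run_pipeline_yaml <- function(path, out_dir = NULL, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  base <- pipeline_config(out_dir = cfg$out_dir %||% "atlas_out")
  cfg <- utils::modifyList(base, cfg)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  invisible(run_pipeline(cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
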