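#' Cross-release gene identifier graph
#'
#' Gene identifiers from different annotation sources and releases are
#' nodes; matchings between them (same gene across releases, cross-source
#' links) are weighted edges. A designated set of target-namespace
#' identifiers is the naming scheme everything is harmonized to.
#'
#' Edge weights live in (0, 1]: where the matching provides a similarity
#' score `s` in `[0, 1]` it is converted to a weight `1 - s + eps`, so
#' better-supported matchings cost less along a path; unscored matchings
#' get weight 0.5.
#'
#' @param edges A data.frame with columns `from`, `to` and either
#'   `weight` (already in (0,1]) or `similarity` (in \[0,1\], converted as
#'   above). Extra columns (namespace, release) are kept as node metadata
#'   when named `from_*`/`to_*` but are not required.
#' @param target_ids Character vector of identifiers in the target
#'   namespace.
#' @param eps Floor added when converting similarities (default 1e-6).
#' @return An object of class `gene_name_graph`.
#' @export
gene_name_graph <- function(edges, target_ids, eps = 1e-6) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  if (!"weight" %in% names(edges)) {
    if ("similarity" %in% names(edges)) {
      s <- edges$similarity
      if (any(is.na(s) | s < 0 | s > 1)) stop("similarities must be in [0,1]")
      edges$weight <- 1 - s + eps
    } else {
      edges$weight <- 0.5
    }
  }
  if (any(edges$weight <= 0 | edges$weight > 1))
    stop("edge weights must be in (0, 1]")
  # parallel matchings between the same pair collapse to the best one
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  edges <- do.call(rbind, lapply(split(edges, key), function(e)
    e[which.min(e$weight), c("from", "to", "weight"), drop = FALSE]))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  target_ids <- intersect(target_ids, igraph::V(g)$name)
  structure(list(graph = g, target_ids = target_ids),
            class = "gene_name_graph")
}

# enumerate all simple paths from `src` to any target and score by mean
# edge weight; ties -> shorter path, then lexicographic target id
best_path_to_target <- function(g, src, targets) {
  best <- NULL
  for (tg in sort(targets)) {
    paths <- if (tg == src) list(src) else
      igraph::all_simple_paths(g, from = src, to = tg)
    for (p in paths) {
      vp <- if (is.character(p)) p else igraph::V(g)$name[as.integer(p)]
      if (length(vp) == 1L) {
        cand <- list(target = tg, mean_w = 0, len = 0L)
      } else {
        eids <- igraph::get_edge_ids(g, rbind(vp[-length(vp)], vp[-1]))
        w <- igraph::E(g)$weight[eids]
        cand <- list(target = tg, mean_w = mean(w), len = length(w))
      }
      if (is.null(best) ||
          cand$mean_w < best$mean_w - 1e-12 ||
          (abs(cand$mean_w - best$mean_w) <= 1e-12 &&
           (cand$len < best$len ||
            (cand$len == best$len && cand$target < best$target)))) {
        best <- cand
      }
    }
  }
  best
}

#' Harmonize source gene identifiers to the target namespace
#'
#' For each source id, among all simple paths through the identifier
#' graph ending at any target-namespace node, the path with the lowest
#' *mean* edge weight is selected; its endpoint becomes the harmonized
#' name. Ties are broken by shorter path, then lexicographically smaller
#' target id. Sources with no path to any target are reported as dropped.
#' When several sources land on one target, they are returned grouped so
#' their counts can be summed with [sum_collided_genes()].
#'
#' @param graph A [gene_name_graph()].
#' @param source_ids Character vector of identifiers to harmonize.
#' @return A list with `mapping` (named character vector source -> target,
#'   `NA` if dropped), `dropped` (character vector) and `groups` (named
#'   list target -> sources, only targets hit by two or more sources).
#' @export
harmonize_gene_names <- function(graph, source_ids) {
  stopifnot(inherits(graph, "gene_name_graph"))
  if (!length(graph$target_ids)) stop("no target-namespace nodes in graph")
  g <- graph$graph
  vnames <- igraph::V(g)$name
  mapping <- stats::setNames(rep(NA_character_, length(source_ids)), source_ids)
  comp <- igraph::components(g)$membership
  target_comp <- unique(comp[graph$target_ids])
  for (s in source_ids) {
    if (!s %in% vnames) next
    reachable <- graph$target_ids[comp[graph$target_ids] == comp[[s]]]
    if (!length(reachable)) next
    mapping[s] <- best_path_to_target(g, s, reachable)$target
  }
  dropped <- names(mapping)[is.na(mapping)]
  tab <- table(mapping)
  collided <- names(tab)[tab >= 2]
  groups <- lapply(collided, function(tg) names(mapping)[!is.na(mapping) & mapping == tg])
  names(groups) <- collided
  list(mapping = mapping, dropped = dropped, groups = groups)
}
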