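# End-to-end orchestration: nodes -> edges -> components -> scoring ->
# significance -> evaluation.

#' Build the alignment graph for two or three species
#'
#' Convenience wrapper: [build_nodes()] followed by [add_edges_pairwise()]
#' (2 species) or [add_edges_multiway()] (3 species).
#'
#' @inheritParams build_nodes
#' @param min_direct,max_indirect_distance Edge-rule parameters for the
#'   three-way case (ignored for pairwise, which requires direct
#'   interactions in both species).
#' @return An `alignment_graph`.
#' @export
align_networks <- function(networks, homologs,
                           mode = c("group_all_pairs", "best_pairs"),
                           similarity = NULL, cross_product_cap = 64L,
                           min_direct = 2L, max_indirect_distance = 2L) {
  mode <- match.arg(mode)
  nodes <- build_nodes(homologs, networks, mode = mode,
                       similarity = similarity,
                       cross_product_cap = cross_product_cap)
  if (length(networks) == 2L) {
    add_edges_pairwise(nodes, networks)
  } else {
    add_edges_multiway(nodes, networks, min_direct = min_direct,
                       max_indirect_distance = max_indirect_distance)
  }
}

#' Cluster-scoring callback for ICCF
#'
#' Builds the `score_fn` consumed by [iccf()]. The GO-coherence rule only
#' needs `F` (cluster-local, so ICCF converges in at most two passes); the
#' score-threshold rule needs the full combined score, re-normalized across
#' the surviving clusters each pass.
#'
#' @param rule `"go_coherence_nonzero"` or `"score_threshold"`.
#' @param annotations GO-BP [annotation_map()] (required by both rules).
#' @inheritParams score_clusters
#' @return A function `(clusters, graph) -> tibble`.
#' @export
iccf_score_fn <- function(rule = c("go_coherence_nonzero",
                                   "score_threshold"),
                          annotations,
                          confidence = "ortholog", ko = NULL,
                          similarity = NULL, weights = c(1, 1, 1) / 3,
                          normalize = c(S = FALSE, I = TRUE, F = FALSE)) {
  rule <- match.arg(rule)
  if (rule == "go_coherence_nonzero") {
    function(clusters, graph) {
      tibble::tibble(
        cluster_id = clusters$cluster_id,
        F = vapply(clusters$node_ids, functional_coherence, 0,
                   graph = graph, annotations = annotations))
    }
  } else {
    function(clusters, graph) {
      score_clusters(clusters, graph, confidence = confidence, ko = ko,
                     similarity = similarity, annotations = annotations,
                     weights = weights, normalize = normalize)
    }
  }
}

#' Run the full alignment pipeline
#'
#' Builds the alignment graph, finds conserved clusters as connected
#' components (optionally refined by [iccf()]), filters to the minimum
#' reported size, scores the clusters, and (optionally) attaches empirical
#' significance.
#'
#' @inheritParams align_networks
#' @param ko KO [annotation_map()] for ortholog confidence and evaluation.
#' @param go GO-BP [annotation_map()] for functional coherence.
#' @param confidence Node-confidence rule, see [score_clusters()].
#' @param weights Score weights.
#' @param iccf_rule `"none"` (plain components), `"go_coherence_nonzero"`,
#'   or `"score_threshold"`.
#' @param threshold Score threshold for the score-threshold ICCF rule and
#'   for the reported-cluster filter when `score_filter = TRUE`.
#' @param score_filter Drop reported clusters with combined score below
#'   `threshold`.
#' @param min_size Minimum reported cluster size (default 2).
#' @param significance_N Null-sample count for [score_significance()]; 0
#'   skips the resampling step.
#' @param seed Seed for the significance resampling.
#'
#' @return A `consnet_alignment` list: `graph`, `iccf` (or `NULL`),
#'   `clusters` (reported `cluster_set`), `scores`, `significance` (or
#'   `NULL`), and the call parameters.
#' @export
run_alignment <- function(networks, homologs, similarity = NULL, ko = NULL,
                          go = NULL,
                          mode = c("group_all_pairs", "best_pairs"),
                          confidence = c("ortholog", "blast",
                                         "ortholog_cluster"),
                          weights = c(1, 1, 1) / 3,
                          iccf_rule = c("none", "go_coherence_nonzero",
                                        "score_threshold"),
                          threshold = 0.5, score_filter = FALSE,
                          min_size = 2L, significance_N = 0L, seed = 1L,
                          min_direct = 2L, max_indirect_distance = 2L,
                          cross_product_cap = 64L) {
  mode <- match.arg(mode)
  confidence <- match.arg(confidence)
  iccf_rule <- match.arg(iccf_rule)
  graph <- align_networks(networks, homologs, mode = mode,
                          similarity = similarity,
                          cross_product_cap = cross_product_cap,
                          min_direct = min_direct,
                          max_indirect_distance = max_indirect_distance)
  iccf_res <- NULL
  if (iccf_rule != "none") {
    if (is.null(go)) stop("ICCF rules require GO annotations", call. = FALSE)
    fn <- iccf_score_fn(iccf_rule, annotations = go,
                        confidence = confidence, ko = ko,
                        similarity = similarity, weights = weights)
    iccf_res <- iccf(graph, fn, filter_rule = iccf_rule,
                     threshold = threshold)
    clusters <- iccf_res$clusters
    graph_for_scores <- iccf_res$graph
  } else {
    clusters <- connected_components(graph)
    graph_for_scores <- graph
  }
  clusters <- filter_clusters(clusters, min_size = min_size)
  scores <- score_clusters(clusters, graph_for_scores,
                           confidence = confidence, ko = ko,
                           similarity = similarity, annotations = go,
                           weights = weights)
  if (score_filter && nrow(scores) > 0L) {
    keep <- !is.na(scores$score) & scores$score >= threshold
    clusters <- clusters[match(scores$cluster_id[keep],
                               clusters$cluster_id), ]
    class(clusters) <- c("cluster_set", class(tibble::tibble()))
    scores <- scores[keep, ]
  }
  significance <- NULL
  if (significance_N > 0L && nrow(clusters) > 0L) {
    sig_conf <- if (confidence == "blast") "blast" else "ortholog"
    significance <- score_significance(
      clusters, graph_for_scores, confidence = sig_conf, ko = ko,
      similarity = similarity, annotations = go, weights = weights,
      N = significance_N, seed = seed)
  }
  structure(
    list(graph = graph, iccf = iccf_res, clusters = clusters,
         scores = scores, significance = significance,
         params = list(mode = mode, confidence = confidence,
                       weights = weights, iccf_rule = iccf_rule,
                       threshold = threshold, min_size = min_size,
                       significance_N = significance_N, seed = seed)),
    class = "consnet_alignment")
}

#' @export
print.consnet_alignment <- function(x, ...) {
  print(x$graph)
  cat(sprintf("  %d reported cluster(s) (min size %d)\n", nrow(x$clusters),
              x$params$min_size))
  if (nrow(x$scores) > 0L) {
    top <- x$scores[order(-x$scores$score), ][1L, ]
    cat(sprintf("  top score %.3f (cluster %d, size %d)\n", top$score,
                top$cluster_id, top$size))
  }
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `consnet_alignment`.
#' @param ... Unused.
#' @return One-row tibble: node/edge/cluster counts and score summary.
#' @export
glance.consnet_alignment <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$graph$nodes), n_edges = nrow(x$graph$edges),
    n_clusters = nrow(x$clusters),
    mean_score = if (nrow(x$scores) > 0L) mean(x$scores$score) else NA_real_,
    iccf_iterations = if (is.null(x$iccf)) NA_integer_ else
      x$iccf$iterations)
}
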