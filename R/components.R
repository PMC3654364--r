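#' Conserved clusters as connected components of the alignment graph
#'
#' Finds the connected components of the (undirected) alignment graph with a
#' Tarjan lowlink traversal over the symmetrized arc set — each undirected
#' edge contributes two arcs, under which strongly connected components
#' coincide with connected components — using an explicit stack, so the run
#' does not depend on the interpreter's recursion depth. Nodes are visited in
#' ascending `node_id`; cluster ids are assigned in emission order, so the
#' result is deterministic given the node ordering.
#'
#' @param graph An `alignment_graph`.
#' @return A `cluster_set` tibble: `cluster_id`, `node_ids` (list column of
#'   sorted integer node ids), `size` (number of nodes, \eqn{|C|}), and
#'   `edge_count` (number of alignment-graph edges inside the cluster,
#'   \eqn{i(C)}). Every node appears in exactly one cluster.
#' @export
connected_components <- function(graph) {
  ids <- sort(graph$nodes$node_id)
  n <- length(ids)
  if (n == 0L) return(empty_cluster_set())
  adj <- adjacency_list(ids, graph$edges)

  idx <- rep(NA_integer_, n)
  low <- integer(n)
  on_stack <- logical(n)
  comp_of <- integer(n)
  counter <- 0L
  n_comp <- 0L
  S <- integer(n)          # Tarjan node stack
  s_top <- 0L
  fv <- integer(n)         # explicit DFS frames: node and child cursor
  fi <- integer(n)
  f_top <- 0L

  for (root in seq_len(n)) {
    if (!is.na(idx[root])) next
    f_top <- 1L; fv[1L] <- root; fi[1L] <- 0L
    while (f_top > 0L) {
      v <- fv[f_top]
      if (fi[f_top] == 0L) {
        counter <- counter + 1L
        idx[v] <- counter
        low[v] <- counter
        s_top <- s_top + 1L
        S[s_top] <- v
        on_stack[v] <- TRUE
      }
      nb <- adj[[v]]
      advanced <- FALSE
      while (fi[f_top] < length(nb)) {
        fi[f_top] <- fi[f_top] + 1L
        w <- nb[fi[f_top]]
        if (is.na(idx[w])) {
          f_top <- f_top + 1L
          fv[f_top] <- w
          fi[f_top] <- 0L
          advanced <- TRUE
          break
        } else if (on_stack[w]) {
          low[v] <- min(low[v], idx[w])
        }
      }
      if (advanced) next
      # all successors done: emit SCC if v is a root, then return to parent
      if (low[v] == idx[v]) {
        n_comp <- n_comp + 1L
        repeat {
          w <- S[s_top]
          s_top <- s_top - 1L
          on_stack[w] <- FALSE
          comp_of[w] <- n_comp
          if (w == v) break
        }
      }
      f_top <- f_top - 1L
      if (f_top > 0L) {
        p <- fv[f_top]
        low[p] <- min(low[p], low[v])
      }
    }
  }
  partition_to_clusters(ids, comp_of, graph$edges)
}

#' Independent flood-fill component oracle
#'
#' Same partition semantics as [connected_components()], computed by an
#' independent breadth-first flood fill; intended for cross-checking in
#' tests, not for production use.
#'
#' @inheritParams connected_components
#' @return A `cluster_set` tibble (see [connected_components()]).
#' @export
components_oracle <- function(graph) {
  ids <- sort(graph$nodes$node_id)
  n <- length(ids)
  if (n == 0L) return(empty_cluster_set())
  adj <- adjacency_list(ids, graph$edges)
  comp_of <- integer(n)
  n_comp <- 0L
  for (start in seq_len(n)) {
    if (comp_of[start] != 0L) next
    n_comp <- n_comp + 1L
    queue <- start
    comp_of[start] <- n_comp
    while (length(queue) > 0L) {
      v <- queue[1L]
      queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (comp_of[w] == 0L) {
          comp_of[w] <- n_comp
          queue <- c(queue, w)
        }
      }
    }
  }
  partition_to_clusters(ids, comp_of, graph$edges)
}

empty_cluster_set <- function() {
  out <- tibble::tibble(cluster_id = integer(), node_ids = list(),
                        size = integer(), edge_count = integer())
  class(out) <- c("cluster_set", class(out))
  out
}

# position-indexed adjacency over sorted node ids (arcs in both directions)
adjacency_list <- function(ids, edges) {
  pos <- match(c(edges$u, edges$v), ids)
  if (anyNA(pos)) stop("edge references unknown node", call. = FALSE)
  u <- pos[seq_len(nrow(edges))]
  v <- pos[nrow(edges) + seq_len(nrow(edges))]
  adj <- split(c(v, u), c(u, v))
  out <- rep(list(integer()), length(ids))
  out[as.integer(names(adj))] <- lapply(adj, function(x) sort(unique(x)))
  out
}

partition_to_clusters <- function(ids, comp_of, edges) {
  groups <- split(ids, comp_of)
  node_ids <- lapply(groups, function(x) sort(as.integer(x)))
  ec <- integer(length(groups))
  if (nrow(edges) > 0L) {
    cu <- comp_of[match(edges$u, ids)]
    cv <- comp_of[match(edges$v, ids)]
    internal <- table(cu[cu == cv])
    ec[as.integer(names(internal))] <- as.integer(internal)
  }
  out <- tibble::tibble(
    cluster_id = as.integer(names(groups)),
    node_ids = unname(node_ids),
    size = lengths(node_ids),
    edge_count = ec)
  out <- out[order(out$cluster_id), ]
  class(out) <- c("cluster_set", class(tibble::tibble()))
  out
}

#' Keep clusters of at least a minimum size
#'
#' Reported conserved regions conventionally exclude singletons (minimum
#' size 2); some analyses use a stricter cutoff.
#'
#' @param clusters A `cluster_set` tibble.
#' @param min_size Minimum number of alignment nodes.
#' @return The filtered `cluster_set`.
#' @export
filter_clusters <- function(clusters, min_size = 2L) {
  out <- clusters[clusters$size >= min_size, ]
  class(out) <- class(clusters)
  out
}

# Induced alignment subgraph on a node subset.
induced_subgraph <- function(graph, node_ids) {
  nodes <- graph$nodes[graph$nodes$node_id %in% node_ids, ]
  edges <- graph$edges[graph$edges$u %in% node_ids &
                         graph$edges$v %in% node_ids, ]
  new_alignment_graph(nodes, edges, graph$species)
}

#' Iterative connected-components finding (ICCF)
#'
#' Alternates component detection, cluster scoring, and removal of clusters
#' that fail a filter rule, until a pass removes nothing (convergence) or
#' `max_iter` is reached. The whole node set of a failing cluster is removed;
#' nodes are never pruned individually. With the GO-coherence rule (remove a
#' cluster iff its intersection-over-union of biological-process terms is
#' zero) the score of a cluster does not depend on other clusters, so the
#' loop converges in at most two passes; the score-threshold rule
#' re-normalizes interaction conservation each pass, which couples clusters
#' and may need more.
#'
#' @param graph An `alignment_graph`.
#' @param score_fn Function `(clusters, graph) -> tibble` returning, per
#'   cluster (row-aligned), whatever the filter rule needs: a column `F` for
#'   `"go_coherence_nonzero"`, a column `score` for `"score_threshold"`.
#'   See [iccf_score_fn()].
#' @param filter_rule `"go_coherence_nonzero"` removes clusters with
#'   `F == 0`; `"score_threshold"` removes clusters with `score < threshold`.
#' @param threshold Score threshold for `"score_threshold"` (default 0.5).
#' @param max_iter Maximum number of passes.
#'
#' @return An `iccf_result`: list with `clusters` (final `cluster_set`),
#'   `graph` (surviving subgraph), `iterations`, `removed_per_iteration`
#'   (nodes removed per pass; last entry 0 on convergence), and `converged`.
#' @export
iccf <- function(graph, score_fn,
                 filter_rule = c("go_coherence_nonzero", "score_threshold"),
                 threshold = 0.5, max_iter = 10L) {
  filter_rule <- match.arg(filter_rule)
  current <- graph
  removed <- integer()
  iterations <- 0L
  converged <- FALSE
  repeat {
    iterations <- iterations + 1L
    comps <- connected_components(current)
    scores <- score_fn(comps, current)
    fails <- if (filter_rule == "go_coherence_nonzero") {
      scores$F == 0
    } else {
      scores$score < threshold
    }
    fails[is.na(fails)] <- TRUE
    drop_nodes <- unlist(comps$node_ids[fails], use.names = FALSE)
    removed <- c(removed, length(drop_nodes))
    if (length(drop_nodes) == 0L) {
      converged <- TRUE
      break
    }
    current <- induced_subgraph(
      current, setdiff(current$nodes$node_id, drop_nodes))
    if (iterations >= max_iter) break
  }
  structure(
    list(clusters = connected_components(current), graph = current,
         iterations = iterations, removed_per_iteration = removed,
         converged = converged),
    class = "iccf_result")
}

#' @export
print.iccf_result <- function(x, ...) {
  cat(sprintf(
    "<iccf_result> %d iteration(s), removed per pass: [%s], %s; %d cluster(s) remain\n",
    x$iterations, paste(x$removed_per_iteration, collapse = ", "),
    if (x$converged) "converged" else "NOT converged", nrow(x$clusters)))
  invisible(x)
}
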