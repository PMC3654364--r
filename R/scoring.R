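# Cluster scoring: sequence-similarity confidence S(C), interaction
# conservation I(C), functional coherence F(C), their combination, and
# empirical resampling significance.

# Long member table (species_id, protein_id, node_id) for a node subset.
cluster_members <- function(graph, node_ids) {
  nl <- nodes_long(graph$nodes)
  nl[nl$node_id %in% node_ids, ]
}

#' Cross-species e-value of each alignment node
#'
#' Pairwise alignment: the e-value of the node's two member proteins.
#' Three-way: the geometric mean over the three species-pair e-values.
#' Missing similarity records yield `NA`.
#'
#' @param nodes Node tibble from [build_nodes()].
#' @param similarity A [similarity_table()].
#' @return Numeric vector aligned with `nodes` rows.
#' @export
node_evalues <- function(nodes, similarity) {
  if (nrow(nodes) == 0L) return(double())
  mem <- do.call(rbind, nodes$members)
  r <- ncol(mem)
  pair_idx <- utils::combn(r, 2L)
  logs <- matrix(NA_real_, nrow(mem), ncol(pair_idx))
  for (j in seq_len(ncol(pair_idx))) {
    logs[, j] <- log(similarity_evalue(similarity,
                                       mem[, pair_idx[1L, j]],
                                       mem[, pair_idx[2L, j]]))
  }
  exp(rowMeans(logs))
}

#' BLAST-based node confidence within a cluster
#'
#' Let \eqn{\bar E} be the arithmetic mean of the cluster nodes' e-values.
#' A node whose e-value is at most \eqn{\bar E} gets confidence 1; otherwise
#' its confidence is \eqn{\bar E / E}, the ratio of the cluster average to
#' its own e-value. A node with no similarity record gets confidence 0.
#'
#' @param e_values Numeric vector of the cluster nodes' e-values (`NA` for
#'   missing records).
#' @return Numeric vector of confidences in \[0, 1\].
#' @export
node_confidence_blast <- function(e_values) {
  if (length(e_values) == 0L) stop("empty cluster", call. = FALSE)
  if (all(is.na(e_values))) return(rep(0, length(e_values)))
  e_bar <- mean(e_values, na.rm = TRUE)
  conf <- ifelse(e_values <= e_bar, 1, e_bar / e_values)
  conf[is.na(e_values)] <- 0
  conf
}

#' Ortholog-annotation node confidence
#'
#' A node's confidence is 1 iff all its member proteins share at least one
#' KO (ortholog) term, else 0; an unannotated member forces 0.
#'
#' @param nodes Node tibble from [build_nodes()].
#' @param ko An [annotation_map()] with namespace `"KO"`.
#' @return Numeric vector of 0/1 confidences aligned with `nodes` rows.
#' @export
node_confidence_ortholog <- function(nodes, ko) {
  if (annotation_namespace(ko) != "KO") {
    stop("ortholog confidence requires a KO annotation map", call. = FALSE)
  }
  if (nrow(nodes) == 0L) return(double())
  vapply(nodes$members, function(m) {
    sets <- annotation_terms(ko, unname(m))
    common <- Reduce(intersect, sets)
    as.double(length(common) > 0L)
  }, 0)
}

#' Sequence-similarity score S(C)
#'
#' The mean node confidence of a cluster:
#' \eqn{S(C) = \sum_k s(k) / |C|}.
#'
#' @param confidences Numeric vector of per-node confidences \eqn{s(k)}.
#' @return `S(C)` in \[0, 1\].
#' @export
sequence_similarity_score <- function(confidences) {
  if (length(confidences) == 0L) stop("empty cluster", call. = FALSE)
  mean(confidences)
}

#' Interaction-conservation score I(C)
#'
#' Cliqueness of a cluster: \eqn{I(C) = i(C) / (|C|(|C|-1)/2)}, the number
#' of conserved interactions over the edge count of a complete graph on the
#' cluster's nodes. A singleton has no pairs and is not scorable (`NA`).
#'
#' @param edge_count Conserved-interaction count \eqn{i(C)}.
#' @param size Cluster size \eqn{|C|} (number of alignment nodes).
#' @return `I(C)` in \[0, 1\], or `NA` for `size == 1`.
#' @export
interaction_conservation <- function(edge_count, size) {
  stopifnot(length(edge_count) == length(size))
  ifelse(size >= 2L, edge_count / (size * (size - 1) / 2), NA_real_)
}

#' Normalize scores over all clusters of an alignment
#'
#' A value above the across-cluster mean is reset to 1; a value at or below
#' the mean becomes its ratio to the mean (so the mean itself maps to 1).
#' `NA` values (unscorable clusters) are ignored in the mean and propagate.
#'
#' @param values Non-negative numeric vector, one value per cluster.
#' @return Normalized values in \[0, 1\].
#' @export
normalize_over_clusters <- function(values) {
  if (length(values) == 0L) stop("no clusters to normalize", call. = FALSE)
  m <- mean(values, na.rm = TRUE)
  if (is.nan(m) || m == 0) {
    warning("degenerate normalization: mean is zero", call. = FALSE)
    return(ifelse(is.na(values), NA_real_, 0))
  }
  pmin(values / m, 1)
}

#' GO biological-process coherence F(C)
#'
#' Within each species, over the cluster's member proteins of that species
#' that carry at least one BP term, the intersection-over-union of their
#' term sets; species with fewer than two annotated members are skipped.
#' `F(C)` is the mean over non-skipped species, or 0 when every species is
#' skipped.
#'
#' @param graph An `alignment_graph`.
#' @param node_ids Integer node ids of one cluster.
#' @param annotations An [annotation_map()] with namespace `"GO_BP"`.
#' @return `F(C)` in \[0, 1\].
#' @export
functional_coherence <- function(graph, node_ids, annotations) {
  if (annotation_namespace(annotations) != "GO_BP") {
    stop("functional coherence requires a GO_BP annotation map", call. = FALSE)
  }
  mem <- cluster_members(graph, node_ids)
  ius <- vapply(graph$species, function(s) {
    prots <- unique(mem$protein_id[mem$species_id == s])
    sets <- annotation_terms(annotations, prots)
    sets <- sets[lengths(sets) > 0L]
    if (length(sets) < 2L) return(NA_real_)
    length(Reduce(intersect, sets)) / length(Reduce(union, sets))
  }, 0)
  if (all(is.na(ius))) 0 else mean(ius, na.rm = TRUE)
}

#' Combined cluster score
#'
#' \eqn{Score(C) = w_1 S(C) + w_2 I(C) + w_3 F(C)}, a normalized score in
#' \[0, 1\]; equal weights of one third are the default.
#'
#' @param S,I_norm,F Score components in \[0, 1\] (vectors recycle).
#' @param weights Non-negative weight triple summing to 1.
#' @return Combined score(s) in \[0, 1\].
#' @export
combined_score <- function(S, I_norm, F, weights = c(1, 1, 1) / 3) {
  if (length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop("`weights` must be 3 non-negative values summing to 1",
         call. = FALSE)
  }
  weights[1L] * S + weights[2L] * I_norm + weights[3L] * F
}

#' Score every cluster of an alignment
#'
#' Computes S (node-confidence mean), I (cliqueness, normalized over
#' clusters), F (GO-BP coherence), and the combined score for each cluster.
#'
#' @param clusters A `cluster_set` tibble.
#' @param graph The `alignment_graph` the clusters came from.
#' @param confidence `"ortholog"` (per-node KO rule, default), `"blast"`
#'   (cluster-relative e-value rule), or `"ortholog_cluster"` (strict
#'   cluster-level KO rule: every protein of the cluster must share a term).
#' @param ko KO [annotation_map()] (ortholog modes).
#' @param similarity [similarity_table()] (blast mode).
#' @param annotations GO-BP [annotation_map()]; when `NULL`, `F` is 0.
#' @param weights Score weights, default `c(1, 1, 1) / 3`.
#' @param normalize Logical switches for across-cluster normalization of the
#'   three components; the interaction term is normalized by default, S and
#'   F are used as-is.
#'
#' @return A tibble with one row per cluster: `cluster_id`, `size`,
#'   `edge_count`, `s_k` (list of node confidences), `S`, `I_raw`, `I_norm`,
#'   `F`, `score`.
#' @export
score_clusters <- function(clusters, graph,
                           confidence = c("ortholog", "blast",
                                          "ortholog_cluster"),
                           ko = NULL, similarity = NULL, annotations = NULL,
                           weights = c(1, 1, 1) / 3,
                           normalize = c(S = FALSE, I = TRUE, F = FALSE)) {
  confidence <- match.arg(confidence)
  if (nrow(clusters) == 0L) {
    return(tibble::tibble(cluster_id = integer(), size = integer(),
                          edge_count = integer(), s_k = list(), S = double(),
                          I_raw = double(), I_norm = double(), F = double(),
                          score = double()))
  }
  s_k <- cluster_confidences(clusters, graph, confidence, ko, similarity)
  S <- vapply(s_k, sequence_similarity_score, 0)
  I_raw <- interaction_conservation(clusters$edge_count, clusters$size)
  I_norm <- if (isTRUE(normalize[["I"]])) {
    normalize_over_clusters(I_raw)
  } else {
    I_raw
  }
  F_val <- if (is.null(annotations)) {
    rep(0, nrow(clusters))
  } else {
    vapply(clusters$node_ids, functional_coherence, 0, graph = graph,
           annotations = annotations)
  }
  S_used <- if (isTRUE(normalize[["S"]])) normalize_over_clusters(S) else S
  F_used <- if (isTRUE(normalize[["F"]])) normalize_over_clusters(F_val) else F_val
  tibble::tibble(
    cluster_id = clusters$cluster_id, size = clusters$size,
    edge_count = clusters$edge_count, s_k = s_k,
    S = S_used, I_raw = I_raw, I_norm = I_norm, F = F_used,
    score = combined_score(S_used, I_norm, F_used, weights))
}

# Per-cluster list of node confidences under the chosen rule.
cluster_confidences <- function(clusters, graph, confidence, ko, similarity) {
  nodes <- graph$nodes
  if (confidence == "blast") {
    if (is.null(similarity)) {
      stop("blast confidence requires `similarity`", call. = FALSE)
    }
    ev <- node_evalues(nodes, similarity)
    lapply(clusters$node_ids, function(nid) {
      node_confidence_blast(ev[match(nid, nodes$node_id)])
    })
  } else if (confidence == "ortholog") {
    if (is.null(ko)) stop("ortholog confidence requires `ko`", call. = FALSE)
    conf <- node_confidence_ortholog(nodes, ko)
    lapply(clusters$node_ids, function(nid) conf[match(nid, nodes$node_id)])
  } else {
    if (is.null(ko)) stop("ortholog confidence requires `ko`", call. = FALSE)
    lapply(clusters$node_ids, function(nid) {
      prots <- cluster_members(graph, nid)$protein_id
      sets <- annotation_terms(ko, unique(prots))
      shared <- length(Reduce(intersect, sets)) > 0L
      rep(as.double(shared), length(nid))
    })
  }
}

#' Empirical p-value from a resampled null
#'
#' \eqn{P = (R + 1)/(N + 1)}, where `N` is the number of null samples and
#' `R` the number of samples with a statistic greater than or equal to the
#' observed value.
#'
#' @param actual Observed statistic.
#' @param null_values Numeric vector of null statistics (non-empty).
#' @return The p-value in (0, 1\].
#' @export
empirical_pvalue <- function(actual, null_values) {
  if (length(null_values) == 0L) {
    stop("empty null sample", call. = FALSE)
  }
  (sum(null_values >= actual, na.rm = TRUE) + 1) / (length(null_values) + 1)
}

#' Resampling significance of one cluster's scores
#'
#' Draws `N` uniform random node subsets of the cluster's size from the
#' alignment graph, computes S, I, and F on each, and converts the observed
#' cluster's components to empirical p-values `(R + 1)/(N + 1)`. The
#' p-value-combined score \eqn{\sum_i w_i (R_i + 1)/(N_i + 1)} is reported
#' alongside (smaller = more significant, unlike the \[0, 1\] quality
#' score).
#'
#' @param cluster One-row slice of a `cluster_set` (or a list with
#'   `node_ids`, `size`, `edge_count`).
#' @param graph The `alignment_graph`.
#' @param confidence,ko,similarity,annotations,weights As in
#'   [score_clusters()].
#' @param N Number of null samples (at least 100; 3000 by default, large
#'   enough for stable tail estimates).
#' @param seed Integer seed; the same seed reproduces the result exactly.
#'
#' @return One-row tibble: observed `S`, `I_raw`, `F`; `p_S`, `p_I`, `p_F`;
#'   exceedance counts `R_S`, `R_I`, `R_F`; sample counts `N_S`, `N_I`,
#'   `N_F`; `combined_p`; `seed`.
#' @export
significance_scores <- function(cluster, graph,
                                confidence = c("ortholog", "blast"),
                                ko = NULL, similarity = NULL,
                                annotations = NULL,
                                weights = c(1, 1, 1) / 3,
                                N = 3000L, seed = 1L) {
  confidence <- match.arg(confidence)
  if (N < 100L) stop("`N` must be at least 100", call. = FALSE)
  node_ids <- if (is.list(cluster$node_ids)) cluster$node_ids[[1L]] else cluster$node_ids
  k <- length(node_ids)
  n <- nrow(graph$nodes)
  if (k > n) stop("cluster larger than the alignment graph", call. = FALSE)

  all_ids <- graph$nodes$node_id
  # per-node ingredients, computed once
  conf_basis <- if (confidence == "blast") {
    if (is.null(similarity)) stop("blast confidence requires `similarity`",
                                  call. = FALSE)
    node_evalues(graph$nodes, similarity)
  } else {
    if (is.null(ko)) stop("ortholog confidence requires `ko`", call. = FALSE)
    node_confidence_ortholog(graph$nodes, ko)
  }
  eu <- match(graph$edges$u, all_ids)
  ev <- match(graph$edges$v, all_ids)
  term_sets <- per_node_term_sets(graph, annotations)

  stat_fn <- function(pos) {
    s_val <- if (confidence == "blast") {
      mean(node_confidence_blast(conf_basis[pos]))
    } else {
      mean(conf_basis[pos])
    }
    inb <- logical(n)
    inb[pos] <- TRUE
    i_count <- sum(inb[eu] & inb[ev])
    c(S = s_val,
      I = unname(interaction_conservation(i_count, length(pos))),
      F = subset_coherence(term_sets, pos, graph$species))
  }

  actual <- stat_fn(match(node_ids, all_ids))
  null_mat <- with_seed(seed, {
    vapply(seq_len(N), function(i) stat_fn(sample.int(n, k)), c(S = 0, I = 0,
                                                                F = 0))
  })
  R <- vapply(c("S", "I", "F"), function(nm) {
    sum(null_mat[nm, ] >= actual[[nm]], na.rm = TRUE)
  }, 0L)
  p <- (R + 1) / (N + 1)
  tibble::tibble(
    S = actual[["S"]], I_raw = actual[["I"]], F = actual[["F"]],
    p_S = p[["S"]], p_I = p[["I"]], p_F = p[["F"]],
    R_S = R[["S"]], R_I = R[["I"]], R_F = R[["F"]],
    N_S = N, N_I = N, N_F = N,
    combined_p = sum(weights * p), seed = as.integer(seed))
}

# Per node, per species: that member protein's BP term set (NULL annotations
# give empty sets, so F is 0 everywhere).
per_node_term_sets <- function(graph, annotations) {
  nodes <- graph$nodes
  lapply(graph$species, function(s) {
    prots <- vapply(nodes$members, function(m) m[[s]], "")
    if (is.null(annotations)) {
      rep(list(character()), length(prots))
    } else {
      annotation_terms(annotations, prots)
    }
  })
}

subset_coherence <- function(term_sets, pos, species) {
  ius <- vapply(seq_along(species), function(si) {
    sets <- term_sets[[si]][pos]
    sets <- sets[lengths(sets) > 0L]
    if (length(sets) < 2L) return(NA_real_)
    length(Reduce(intersect, sets)) / length(Reduce(union, sets))
  }, 0)
  if (all(is.na(ius))) 0 else mean(ius, na.rm = TRUE)
}

#' Resampling significance for every cluster
#'
#' Applies [significance_scores()] to each cluster with a per-cluster seed
#' derived deterministically from `seed`.
#'
#' @inheritParams significance_scores
#' @param clusters A `cluster_set` tibble.
#' @return Tibble with `cluster_id` and the [significance_scores()] columns.
#' @export
score_significance <- function(clusters, graph,
                               confidence = c("ortholog", "blast"),
                               ko = NULL, similarity = NULL,
                               annotations = NULL, weights = c(1, 1, 1) / 3,
                               N = 3000L, seed = 1L) {
  confidence <- match.arg(confidence)
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    res <- significance_scores(
      clusters[i, ], graph, confidence = confidence, ko = ko,
      similarity = similarity, annotations = annotations, weights = weights,
      N = N, seed = derive_seed(seed, clusters$cluster_id[i]))
    tibble::tibble(cluster_id = clusters$cluster_id[i], res)
  })
  dplyr::bind_rows(rows)
}
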