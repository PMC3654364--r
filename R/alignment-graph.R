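#' Number of unordered protein pairs among n proteins
#'
#' The size of the pairwise-test universe: testing every possible interaction
#' among `n` proteins requires `n (n - 1) / 2` tests, which is why exhaustive
#' experimental screening is infeasible and conserved-module inference pays.
#'
#' @param n Non-negative integer protein count.
#' @return `n * (n - 1) / 2` as a double.
#' @examples
#' interaction_universe(5000) # 12497500
#' @export
interaction_universe <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 0 || n != floor(n)) {
    stop("`n` must be a single non-negative integer", call. = FALSE)
  }
  n * (n - 1) / 2
}

#' Build alignment-graph nodes from homolog groups
#'
#' Each node is a tuple of proteins, exactly one per aligned species, drawn
#' from one homolog group. Proteins absent from their species' PPI network
#' are dropped first (a node must be alignable); groups that then fail to
#' cover every aligned species are skipped.
#'
#' @param homologs A [homolog_groups()] table.
#' @param networks List of [ppi_network()]s, one per aligned species (2 or 3).
#' @param mode `"group_all_pairs"` enumerates the full cross-product of a
#'   group's per-species member lists; `"best_pairs"` keeps, per group, the
#'   single member combination with the smallest e-value (product over
#'   species pairs; ties broken by lexicographic protein ids).
#' @param similarity A [similarity_table()]; required for `"best_pairs"`.
#' @param cross_product_cap Per-group cap on enumerated combinations in
#'   `"group_all_pairs"` mode (promiscuous groups are truncated with a
#'   warning, in deterministic order).
#'
#' @return A tibble of alignment nodes: `node_id`, `group_id`, `members`
#'   (list column of named character vectors, species -> protein).
#' @export
build_nodes <- function(homologs, networks,
                        mode = c("group_all_pairs", "best_pairs"),
                        similarity = NULL, cross_product_cap = 64L) {
  mode <- match.arg(mode)
  if (mode == "best_pairs" && is.null(similarity)) {
    stop("mode \"best_pairs\" requires a similarity table", call. = FALSE)
  }
  species <- vapply(networks, function(n) n$species_id, "")
  if (anyDuplicated(species)) stop("duplicate species in `networks`", call. = FALSE)
  universe <- lapply(networks, function(n) n$proteins)
  names(universe) <- species

  h <- dplyr::filter(homologs, .data$species_id %in% species)
  h <- dplyr::filter(
    h, mapply(function(s, p) p %in% universe[[s]], .data$species_id,
              .data$protein_id))
  if (nrow(h) == 0L) return(empty_nodes())

  per_group <- split(h, h$group_id)
  per_group <- per_group[order(names(per_group))]
  rows <- list()
  truncated <- 0L
  for (gid in names(per_group)) {
    g <- per_group[[gid]]
    mem <- lapply(species, function(s) unique(g$protein_id[g$species_id == s]))
    names(mem) <- species
    if (any(lengths(mem) == 0L)) next  # group does not span all species
    combos <- expand_members(mem)
    if (mode == "group_all_pairs") {
      if (nrow(combos) > cross_product_cap) {
        truncated <- truncated + 1L
        combos <- combos[seq_len(cross_product_cap), , drop = FALSE]
      }
    } else {
      combos <- best_combo(combos, species, similarity)
    }
    rows[[gid]] <- tibble::tibble(
      group_id = gid,
      members = lapply(seq_len(nrow(combos)), function(i) {
        stats::setNames(as.character(combos[i, ]), species)
      }))
  }
  if (truncated > 0L) {
    warning(sprintf("%d group(s) exceeded cross_product_cap = %d; truncated",
                    truncated, cross_product_cap), call. = FALSE)
  }
  if (length(rows) == 0L) return(empty_nodes())
  nodes <- dplyr::bind_rows(rows)
  tibble::tibble(node_id = seq_len(nrow(nodes)), nodes)
}

empty_nodes <- function() {
  tibble::tibble(node_id = integer(), group_id = character(),
                 members = list())
}

# All per-species member combinations of one group, lexicographic order:
# first species varies slowest, members in sorted order.
expand_members <- function(mem) {
  mem <- lapply(mem, sort)
  grid <- rev(expand.grid(rev(mem), stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE))
  names(grid) <- names(mem)
  grid
}

# Pick the combination with the smallest product of cross-species e-values
# (missing pair counts as E = 1); ties by lexicographic protein ids.
best_combo <- function(combos, species, similarity) {
  pair_idx <- utils::combn(length(species), 2L)
  loge <- rep(0, nrow(combos))
  for (j in seq_len(ncol(pair_idx))) {
    a <- combos[[pair_idx[1L, j]]]
    b <- combos[[pair_idx[2L, j]]]
    ev <- similarity_evalue(similarity, a, b)
    ev[is.na(ev)] <- 1
    loge <- loge + log(ev)
  }
  lab <- do.call(paste, c(combos, sep = "\r"))
  combos[order(loge, lab)[1L], , drop = FALSE]
}

#' Alignment nodes in long (one row per member protein) form
#'
#' @param nodes Node tibble from [build_nodes()].
#' @return Tibble with columns `node_id`, `species_id`, `protein_id`.
#' @export
nodes_long <- function(nodes) {
  if (nrow(nodes) == 0L) {
    return(tibble::tibble(node_id = integer(), species_id = character(),
                          protein_id = character()))
  }
  tidyr::unnest_longer(
    tibble::tibble(node_id = nodes$node_id,
                   protein_id = nodes$members),
    "protein_id", indices_to = "species_id")[, c("node_id", "species_id",
                                                 "protein_id")]
}

new_alignment_graph <- function(nodes, edges, species) {
  structure(list(nodes = nodes, edges = edges, species = species),
            class = "alignment_graph")
}

#' @export
print.alignment_graph <- function(x, ...) {
  cat(sprintf("<alignment_graph> %s: %d nodes, %d edges\n",
              paste(x$species, collapse = " / "),
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Add conserved-interaction edges for a pairwise alignment
#'
#' Two alignment nodes are joined iff they share no protein and, in each of
#' the two species, their member proteins interact directly in that species'
#' PPI network. Self-loops in the PPI networks are ignored.
#'
#' @param nodes Node tibble from [build_nodes()].
#' @param networks List of exactly 2 [ppi_network()]s.
#' @return An `alignment_graph`: list with the node tibble, an edge tibble
#'   (`u`, `v`, per-species `provenance` list column), and the species
#'   vector.
#' @export
add_edges_pairwise <- function(nodes, networks) {
  if (length(networks) != 2L) {
    stop("pairwise alignment requires exactly 2 networks", call. = FALSE)
  }
  build_alignment_edges(nodes, networks, min_direct = 2L,
                        max_indirect_distance = 1L)
}

#' Add conserved-interaction edges for a three-way alignment
#'
#' Two alignment nodes are joined iff they share no protein, at least
#' `min_direct` of the three species show a direct interaction between the
#' nodes' member proteins, and in every remaining species the members lie
#' within unweighted shortest-path distance `max_indirect_distance` of each
#' other. An unreachable pair simply yields no edge.
#'
#' @param nodes Node tibble from [build_nodes()].
#' @param networks List of exactly 3 [ppi_network()]s.
#' @param min_direct Minimum number of species with a direct interaction
#'   (1--3; default 2).
#' @param max_indirect_distance Maximum allowed distance in the remaining
#'   species (default 2).
#' @return An `alignment_graph`; edge provenance records `"direct"` or
#'   `"distance-k"` per species.
#' @export
add_edges_multiway <- function(nodes, networks, min_direct = 2L,
                               max_indirect_distance = 2L) {
  if (length(networks) != 3L) {
    stop("multiway alignment requires exactly 3 networks", call. = FALSE)
  }
  if (min_direct < 1L || min_direct > 3L) {
    stop("`min_direct` must be between 1 and 3", call. = FALSE)
  }
  build_alignment_edges(nodes, networks, min_direct = min_direct,
                        max_indirect_distance = max_indirect_distance)
}

# Shared edge engine. Direct = distance 1. A candidate node pair must be
# direct in >= min_direct species and within max_indirect_distance in every
# other species.
build_alignment_edges <- function(nodes, networks, min_direct,
                                  max_indirect_distance) {
  species <- vapply(networks, function(n) n$species_id, "")
  names(networks) <- species
  if (nrow(nodes) > 0L) {
    nl <- nodes_long(nodes)
    for (s in species) {
      missing <- setdiff(nl$protein_id[nl$species_id == s],
                         networks[[s]]$proteins)
      if (length(missing) > 0L) {
        stop(sprintf("node protein %s absent from network %s",
                     missing[1L], s), call. = FALSE)
      }
    }
  }
  empty_edges <- tibble::tibble(u = integer(), v = integer(),
                                provenance = list())
  if (nrow(nodes) < 2L) {
    return(new_alignment_graph(nodes, empty_edges, species))
  }

  member_mat <- do.call(rbind, nodes$members)[, species, drop = FALSE]

  # candidate pairs: direct in at least one species
  direct <- lapply(species, function(s) {
    direct_node_pairs(nodes, member_mat[, s], networks[[s]])
  })
  names(direct) <- species
  cand <- unique(do.call(rbind, direct))
  if (is.null(cand) || nrow(cand) == 0L) {
    return(new_alignment_graph(nodes, empty_edges, species))
  }

  # shared-protein exclusion: a protein cannot conserve an interaction with
  # itself across the same node pair
  shares <- vapply(seq_len(nrow(cand)), function(i) {
    any(member_mat[cand[i, 1L], ] %in% member_mat[cand[i, 2L], ])
  }, TRUE)
  cand <- cand[!shares, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(new_alignment_graph(nodes, empty_edges, species))
  }

  is_direct <- vapply(species, function(s) {
    k <- edge_key(member_mat[cand[, 1L], s], member_mat[cand[, 2L], s])
    k %in% network_edge_keys(networks[[s]])
  }, logical(nrow(cand)))
  if (nrow(cand) == 1L) is_direct <- matrix(is_direct, nrow = 1L,
                                            dimnames = list(NULL, species))
  n_direct <- rowSums(is_direct)
  keep <- n_direct >= min_direct
  cand <- cand[keep, , drop = FALSE]
  is_direct <- is_direct[keep, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(new_alignment_graph(nodes, empty_edges, species))
  }

  # indirect check for species without a direct interaction
  dist_tag <- matrix(NA_character_, nrow(cand), length(species),
                     dimnames = list(NULL, species))
  ok <- rep(TRUE, nrow(cand))
  for (s in species) {
    idx <- which(!is_direct[, s] & ok)
    dist_tag[is_direct[, s], s] <- "direct"
    if (length(idx) == 0L) next
    if (max_indirect_distance < 2L) { ok[idx] <- FALSE; next }
    d <- pair_distances(networks[[s]],
                        member_mat[cand[idx, 1L], s],
                        member_mat[cand[idx, 2L], s])
    within <- is.finite(d) & d <= max_indirect_distance
    ok[idx[!within]] <- FALSE
    dist_tag[idx[within], s] <- sprintf("distance-%d", d[within])
  }
  cand <- cand[ok, , drop = FALSE]
  dist_tag <- dist_tag[ok, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(new_alignment_graph(nodes, empty_edges, species))
  }

  ord <- order(cand[, 1L], cand[, 2L])
  edges <- tibble::tibble(
    u = cand[ord, 1L], v = cand[ord, 2L],
    provenance = lapply(ord, function(i) {
      stats::setNames(dist_tag[i, ], species)
    }))
  new_alignment_graph(nodes, edges, species)
}

# Node pairs whose members in one species interact directly.
direct_node_pairs <- function(nodes, member, net) {
  e <- network_edges(net)
  if (nrow(e) == 0L) return(cbind(u = integer(), v = integer()))
  by_protein <- split(nodes$node_id, member)
  pairs <- lapply(seq_len(nrow(e)), function(i) {
    us <- by_protein[[e$from[i]]]
    vs <- by_protein[[e$to[i]]]
    if (is.null(us) || is.null(vs)) return(NULL)
    g <- expand.grid(u = us, v = vs, KEEP.OUT.ATTRS = FALSE)
    g[g$u != g$v, , drop = FALSE]
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(cbind(u = integer(), v = integer()))
  }
  m <- cbind(u = pmin(pairs$u, pairs$v), v = pmax(pairs$u, pairs$v))
  unique(m)
}

# Unweighted shortest-path distances for specific protein pairs (igraph BFS).
pair_distances <- function(net, a, b) {
  e <- network_edges(net)
  g <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = FALSE,
                                     vertices = net$proteins)
  vapply(seq_along(a), function(i) {
    igraph::distances(g, v = a[i], to = b[i])[1L, 1L]
  }, 0)
}

#' One-line summary of an alignment graph
#'
#' @param x An `alignment_graph`.
#' @param ... Unused.
#' @return A one-row tibble with species, node, and edge counts.
#' @export
glance.alignment_graph <- function(x, ...) {
  tibble::tibble(species = paste(x$species, collapse = "/"),
                 n_nodes = nrow(x$nodes), n_edges = nrow(x$edges))
}
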