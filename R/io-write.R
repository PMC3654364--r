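# Writers (and matching readers) for the tool's tabular outputs. All output
# is UTF-8, tab-separated, deterministic.

# "spA:p1,spB:p2" label for one alignment node.
format_node_members <- function(graph, node_ids) {
  nodes <- graph$nodes[match(node_ids, graph$nodes$node_id), ]
  vapply(nodes$members, function(m) {
    paste(sprintf("%s:%s", names(m), m), collapse = ",")
  }, "")
}

#' Write a scored cluster report
#'
#' One row per cluster: id, size, member tuples (`species:protein` pairs
#' joined by `","` within a node, nodes joined by `";"`), the S / I / F
#' score components, the combined score, and the empirical p-values (`NA`
#' when significance was not run). Rows are ordered by descending score,
#' ties by cluster id.
#'
#' @param clusters A `cluster_set` tibble.
#' @param scores Matching tibble from [score_clusters()] (same clusters, any
#'   order; matched by `cluster_id`).
#' @param path Output file path.
#' @param graph The `alignment_graph` (for member tuples).
#' @param significance Optional tibble from [score_significance()].
#' @return The path, invisibly.
#' @export
write_clusters <- function(clusters, scores, path, graph,
                           significance = NULL) {
  if (nrow(clusters) != nrow(scores) ||
      !setequal(clusters$cluster_id, scores$cluster_id)) {
    stop("`clusters` and `scores` must describe the same clusters",
         call. = FALSE)
  }
  sc <- scores[match(clusters$cluster_id, scores$cluster_id), ]
  tbl <- tibble::tibble(
    cluster_id = clusters$cluster_id,
    size = clusters$size,
    members = vapply(clusters$node_ids, function(nid) {
      paste(format_node_members(graph, nid), collapse = ";")
    }, ""),
    S = sc$S, I_raw = sc$I_raw, I_norm = sc$I_norm, F = sc$F,
    Score = sc$score,
    p_S = NA_real_, p_I = NA_real_, p_F = NA_real_)
  if (!is.null(significance)) {
    sig <- significance[match(clusters$cluster_id, significance$cluster_id), ]
    tbl$p_S <- sig$p_S
    tbl$p_I <- sig$p_I
    tbl$p_F <- sig$p_F
  }
  tbl <- tbl[order(-tbl$Score, tbl$cluster_id), ]
  readr::write_tsv(tbl, path, na = "NA")
  invisible(path)
}

#' Read a cluster report written by [write_clusters()]
#'
#' @param path Path to the TSV report.
#' @return Tibble with the report columns; `members` is a list column of
#'   per-node `species:protein` label vectors.
#' @export
read_clusters <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tbl$members <- strsplit(as.character(tbl$members), ";", fixed = TRUE)
  tibble::as_tibble(tbl)
}

#' Export an alignment graph as node and edge tables
#'
#' The node table has columns `node_id`, `group_id`, then one protein
#' column per species; the edge table has `u`, `v`, then one provenance
#' column per species (`direct` / `distance-k`). Optionally mirrors the
#' graph to GraphML.
#'
#' @param graph An `alignment_graph`.
#' @param nodes_path,edges_path Output TSV paths.
#' @param graphml_path Optional GraphML output path.
#' @return Invisibly, the paths written.
#' @export
write_alignment_graph <- function(graph, nodes_path, edges_path,
                                  graphml_path = NULL) {
  nodes <- tibble::tibble(node_id = graph$nodes$node_id,
                          group_id = graph$nodes$group_id)
  for (s in graph$species) {
    nodes[[s]] <- vapply(graph$nodes$members, function(m) m[[s]], "")
  }
  readr::write_tsv(nodes, nodes_path)
  edges <- tibble::tibble(u = graph$edges$u, v = graph$edges$v)
  for (s in graph$species) {
    edges[[paste0("provenance_", s)]] <-
      vapply(graph$edges$provenance, function(p) p[[s]], "")
  }
  readr::write_tsv(edges, edges_path)
  if (!is.null(graphml_path)) {
    ig <- igraph::graph_from_data_frame(
      data.frame(from = as.character(graph$edges$u),
                 to = as.character(graph$edges$v)),
      directed = FALSE,
      vertices = data.frame(name = as.character(nodes$node_id),
                            group_id = nodes$group_id))
    igraph::write_graph(ig, graphml_path, format = "graphml")
  }
  invisible(c(nodes = nodes_path, edges = edges_path))
}

#' Read an alignment graph written by [write_alignment_graph()]
#'
#' @param nodes_path,edges_path Paths to the exported tables.
#' @return An `alignment_graph`.
#' @export
read_alignment_graph <- function(nodes_path, edges_path) {
  nodes <- readr::read_tsv(nodes_path, show_col_types = FALSE,
                           progress = FALSE)
  species <- setdiff(names(nodes), c("node_id", "group_id"))
  members <- lapply(seq_len(nrow(nodes)), function(i) {
    stats::setNames(vapply(species, function(s) as.character(nodes[[s]][i]),
                           ""), species)
  })
  node_tbl <- tibble::tibble(node_id = as.integer(nodes$node_id),
                             group_id = as.character(nodes$group_id),
                             members = members)
  edges <- readr::read_tsv(edges_path, show_col_types = FALSE,
                           progress = FALSE)
  prov_cols <- paste0("provenance_", species)
  provenance <- lapply(seq_len(nrow(edges)), function(i) {
    stats::setNames(vapply(prov_cols, function(cn) {
      as.character(edges[[cn]][i])
    }, ""), species)
  })
  edge_tbl <- tibble::tibble(u = as.integer(edges$u),
                             v = as.integer(edges$v),
                             provenance = provenance)
  new_alignment_graph(node_tbl, edge_tbl, species)
}

#' Write all benchmark inputs to a directory
#'
#' Emits the standard input files: one PPI edge list per species
#' (`ppi_<species>.tsv`), the homolog table (`homologs.tsv`), BLAST-style
#' similarity (`blast.tsv`, four-column dialect), one annotation TSV per
#' namespace, and the ground truth as JSON.
#'
#' @param bench A `ppi_benchmark` from [generate_benchmark()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of the paths written.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (net in bench$networks) {
    p <- file.path(dir, sprintf("ppi_%s.tsv", net$species_id))
    e <- network_edges(net)
    readr::write_tsv(e[, c("from", "to")], p, col_names = FALSE)
    paths[paste0("ppi_", net$species_id)] <- p
  }
  p <- file.path(dir, "homologs.tsv")
  readr::write_tsv(bench$homologs[, c("group_id", "species_id",
                                      "protein_id")], p, col_names = FALSE)
  paths["homologs"] <- p
  p <- file.path(dir, "blast.tsv")
  readr::write_tsv(bench$similarity[, c("query", "subject", "e_value",
                                        "bit_score")], p, col_names = FALSE)
  paths["blast"] <- p
  for (ns in names(bench$annotations)) {
    p <- file.path(dir, sprintf("%s.tsv", tolower(ns)))
    readr::write_tsv(bench$annotations[[ns]][, c("protein_id", "term_id")],
                     p, col_names = FALSE)
    paths[ns] <- p
  }
  p <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(planted_modules = bench$truth$planted_modules,
         ortholog_map = as.data.frame(bench$truth$ortholog_map),
         planted_terms = as.list(bench$truth$planted_terms),
         config = unclass(bench$config)),
    p, auto_unbox = TRUE, pretty = TRUE)
  paths["truth"] <- p
  invisible(paths)
}

#' Read benchmark-layout inputs from a directory
#'
#' Counterpart of [write_benchmark()]: loads whatever standard files are
#' present in `dir`.
#'
#' @param dir Directory holding the files written by [write_benchmark()].
#' @param weight_cutoff Optional load-time cutoff for weighted PPI files.
#' @return List with `networks`, `homologs`, `similarity`, `annotations`.
#' @export
read_benchmark_dir <- function(dir, weight_cutoff = NULL) {
  ppi_files <- sort(list.files(dir, pattern = "^ppi_.*\\.tsv$",
                               full.names = TRUE))
  networks <- lapply(ppi_files, function(p) {
    sp <- sub("^ppi_(.*)\\.tsv$", "\\1", basename(p))
    first <- readLines(p, n = 1L)
    dialect <- if (length(strsplit(first, "\t")[[1L]]) == 3L) {
      "tsv3col_weighted"
    } else {
      "tsv2col"
    }
    read_ppi_network(p, sp, dialect = dialect,
                     weight_cutoff = weight_cutoff)
  })
  names(networks) <- vapply(networks, function(n) n$species_id, "")
  out <- list(networks = networks,
              homologs = read_homolog_groups(file.path(dir, "homologs.tsv")))
  blast <- file.path(dir, "blast.tsv")
  if (file.exists(blast)) out$similarity <- read_blast_tabular(blast)
  ann <- list()
  for (ns in ANNOTATION_NAMESPACES) {
    p <- file.path(dir, sprintf("%s.tsv", tolower(ns)))
    if (file.exists(p)) ann[[ns]] <- read_annotations(p, ns)
  }
  out$annotations <- ann
  out
}
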