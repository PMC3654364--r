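# In-code fixtures: tiny networks and alignment graphs built from scratch.

tiny_network <- function(species, ...) {
  pairs <- list(...)
  if (length(pairs) == 0L) {
    return(ppi_network(tibble::tibble(from = character(), to = character()),
                       species))
  }
  df <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(from = p[1L], to = p[2L])
  }))
  ppi_network(df, species)
}

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Alignment graph with dummy members, for component/scoring tests that only
# need topology. Edges given as a 2-column matrix (or NULL).
toy_graph <- function(n, edges = NULL, species = c("spA", "spB")) {
  nodes <- tibble::tibble(
    node_id = seq_len(n),
    group_id = sprintf("G%03d", seq_len(n)),
    members = lapply(seq_len(n), function(i) {
      stats::setNames(sprintf("%s_p%03d", species, i), species)
    }))
  if (is.null(edges) || nrow(edges) == 0L) {
    e <- tibble::tibble(u = integer(), v = integer(), provenance = list())
  } else {
    u <- pmin(edges[, 1L], edges[, 2L])
    v <- pmax(edges[, 1L], edges[, 2L])
    keep <- !duplicated(paste(u, v)) & u != v
    e <- tibble::tibble(
      u = as.integer(u[keep]), v = as.integer(v[keep]),
      provenance = rep(list(stats::setNames(rep("direct", length(species)),
                                            species)), sum(keep)))
  }
  consnet:::new_alignment_graph(nodes, e, species)
}

random_toy_graph <- function(n, p) {
  if (n < 2L) return(toy_graph(n))
  all_pairs <- t(utils::combn(n, 2L))
  toy_graph(n, all_pairs[stats::runif(nrow(all_pairs)) < p, , drop = FALSE])
}

# Canonical partition representation for comparing component finders.
partition_sets <- function(clusters) {
  sets <- lapply(clusters$node_ids, function(x) paste(sort(x), collapse = ","))
  sort(unlist(sets))
}

# Small two-column annotation map from protein -> terms pairs.
ann_map <- function(namespace, ...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(protein_id = r[[1L]], term_id = r[[2L]])
  }))
  if (is.null(df)) df <- data.frame(protein_id = character(),
                                    term_id = character())
  annotation_map(df, namespace)
}
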