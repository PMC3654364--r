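# Validation metrics: KO-based specificity/sensitivity, GO process
# coherence via hypergeometric enrichment with BH-FDR, MIPS coverage.

# A node (equivalence class) is correct iff all its member proteins share
# at least one KO term.
node_correct <- function(nodes, ko) {
  node_confidence_ortholog(nodes, ko) == 1
}

#' KO-based specificity: Ceq and Cnode
#'
#' Equivalence classes are the alignment nodes; a class is correct if all
#' its member proteins lie in the same KO group. `Ceq` is the fraction of
#' classes (nodes appearing in the reported clusters) that are correct;
#' `Cnode` is the fraction of nodes lying in correct classes. With
#' single-node classes the two coincide.
#'
#' @param clusters A `cluster_set` of reported clusters.
#' @param graph The `alignment_graph`.
#' @param ko KO [annotation_map()].
#' @return One-row tibble with `Ceq`, `Cnode`, `n_nodes`, `n_correct`.
#' @export
ko_specificity <- function(clusters, graph, ko) {
  node_ids <- unlist(clusters$node_ids, use.names = FALSE)
  if (length(node_ids) == 0L) {
    stop("no nodes in the reported clusters", call. = FALSE)
  }
  nodes <- graph$nodes[match(node_ids, graph$nodes$node_id), ]
  correct <- node_correct(nodes, ko)
  tibble::tibble(Ceq = mean(correct), Cnode = mean(correct),
                 n_nodes = length(node_ids), n_correct = sum(correct))
}

#' KO-based sensitivity: Cor and Tot
#'
#' `Cor` counts the nodes in correct equivalence classes across all reported
#' clusters. `Tot` is the sensitivity denominator: the number of homolog
#' groups that span all aligned species with at least one member present in
#' each species' PPI network (groups eligible for alignment).
#'
#' @inheritParams ko_specificity
#' @param homologs The [homolog_groups()] table used for the alignment.
#' @param networks List of the aligned [ppi_network()]s.
#' @return One-row tibble with `Cor` and `Tot`.
#' @export
ko_sensitivity <- function(clusters, graph, ko, homologs, networks) {
  node_ids <- unlist(clusters$node_ids, use.names = FALSE)
  Cor <- if (length(node_ids) == 0L) {
    0L
  } else {
    nodes <- graph$nodes[match(node_ids, graph$nodes$node_id), ]
    sum(node_correct(nodes, ko))
  }
  species <- vapply(networks, function(n) n$species_id, "")
  universe <- lapply(networks, function(n) n$proteins)
  names(universe) <- species
  h <- dplyr::filter(homologs, .data$species_id %in% species)
  h <- dplyr::filter(
    h, mapply(function(s, p) p %in% universe[[s]], .data$species_id,
              .data$protein_id))
  spans <- dplyr::summarise(
    dplyr::group_by(h, .data$group_id),
    n_sp = dplyr::n_distinct(.data$species_id))
  tibble::tibble(Cor = as.integer(Cor),
                 Tot = sum(spans$n_sp == length(species)))
}

#' GO-term enrichment of a protein set (hypergeometric + BH)
#'
#' For every term annotated to at least one cluster protein, the upper-tail
#' hypergeometric probability of seeing at least `k` annotated proteins in a
#' draw of `n` cluster proteins from a background of `M` proteins of which
#' `K` carry the term; Benjamini-Hochberg adjustment across the tested
#' terms. No term propagation along the GO graph is performed: annotations
#' are taken as given.
#'
#' @param cluster_proteins Character vector, a subset of `background`.
#' @param background Character vector: the background protein universe
#'   (conventionally all proteins of the species' PPI network).
#' @param annotations An [annotation_map()].
#' @param alpha Significance level recorded in the result (default 0.05).
#' @return Tibble sorted by adjusted p-value: `term`, `k`, `K`, `n`, `M`,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
go_enrichment <- function(cluster_proteins, background, annotations,
                          alpha = 0.05) {
  cluster_proteins <- unique(cluster_proteins)
  background <- unique(background)
  if (!all(cluster_proteins %in% background)) {
    stop("cluster proteins must be a subset of the background", call. = FALSE)
  }
  M <- length(background)
  n <- length(cluster_proteins)
  ann <- annotations[annotations$protein_id %in% background, ]
  hit <- ann[ann$protein_id %in% cluster_proteins, ]
  if (nrow(hit) == 0L) {
    return(tibble::tibble(term = character(), k = integer(), K = integer(),
                          n = integer(), M = integer(), p_raw = double(),
                          p_adj = double(), significant = logical()))
  }
  k_tab <- dplyr::count(hit, term = .data$term_id, name = "k")
  K_tab <- dplyr::count(ann[ann$term_id %in% k_tab$term, ],
                        term = .data$term_id, name = "K")
  res <- dplyr::left_join(k_tab, K_tab, by = "term")
  res$n <- n
  res$M <- M
  res$p_raw <- stats::phyper(res$k - 1L, res$K, M - res$K, n,
                             lower.tail = FALSE)
  res$p_adj <- stats::p.adjust(res$p_raw, method = "BH")
  res$significant <- res$p_adj < alpha
  res <- dplyr::arrange(res, .data$p_adj, .data$p_raw, .data$term)
  tibble::as_tibble(res)
}

#' GO process-coherence specificity and sensitivity
#'
#' Per species, a cluster is process-coherent iff its species-projected
#' protein set has at least one BP term enriched at adjusted p < `alpha`
#' against that species' full network background; specificity is the
#' fraction of coherent clusters. Sensitivity is the number of distinct
#' terms enriched at adjusted p < `alpha` across all clusters and species.
#'
#' @param clusters A `cluster_set` of reported clusters.
#' @param graph The `alignment_graph`.
#' @param annotations GO-BP [annotation_map()].
#' @param networks List of the aligned [ppi_network()]s.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return List with `specificity` (tibble `species_id`, `coherent`,
#'   `n_clusters`, `specificity`; `NA` specificity when there are no
#'   clusters) and `sensitivity` (integer count of distinct enriched
#'   terms).
#' @export
go_specificity_sensitivity <- function(clusters, graph, annotations,
                                       networks, alpha = 0.05) {
  if (annotation_namespace(annotations) != "GO_BP") {
    stop("GO metrics require a GO_BP annotation map", call. = FALSE)
  }
  species <- vapply(networks, function(n) n$species_id, "")
  names(networks) <- species
  if (nrow(clusters) == 0L) {
    spec <- tibble::tibble(species_id = species, coherent = 0L,
                           n_clusters = 0L, specificity = NA_real_)
    return(list(specificity = spec, sensitivity = 0L))
  }
  enriched_terms <- character()
  spec_rows <- lapply(species, function(s) {
    bg <- networks[[s]]$proteins
    coherent <- 0L
    for (i in seq_len(nrow(clusters))) {
      mem <- cluster_members(graph, clusters$node_ids[[i]])
      prots <- unique(mem$protein_id[mem$species_id == s])
      prots <- intersect(prots, bg)
      if (length(prots) == 0L) next
      enr <- go_enrichment(prots, bg, annotations, alpha = alpha)
      sig <- enr$term[enr$significant]
      if (length(sig) > 0L) {
        coherent <- coherent + 1L
        enriched_terms <<- union(enriched_terms, sig)
      }
    }
    tibble::tibble(species_id = s, coherent = coherent,
                   n_clusters = nrow(clusters),
                   specificity = coherent / nrow(clusters))
  })
  list(specificity = dplyr::bind_rows(spec_rows),
       sensitivity = length(enriched_terms))
}

#' MIPS complex / FunCat coverage of clusters
#'
#' A cluster is covered iff all its member proteins (projected onto the
#' species being assessed, when `species` is given) share at least one
#' complex or FunCat term; an unannotated member leaves the cluster
#' uncovered. Returns the fraction of covered clusters.
#'
#' @param clusters A `cluster_set` of reported clusters.
#' @param graph The `alignment_graph`.
#' @param complexes An [annotation_map()] with namespace `"MIPS_COMPLEX"` or
#'   `"MIPS_FUNCAT"`.
#' @param species Optional species id to project onto; by default all member
#'   proteins are assessed.
#' @return Coverage fraction in \[0, 1\] (`NA` when there are no clusters).
#' @export
mips_coverage <- function(clusters, graph, complexes, species = NULL) {
  if (!annotation_namespace(complexes) %in% c("MIPS_COMPLEX", "MIPS_FUNCAT")) {
    stop("coverage requires a MIPS complex or FunCat annotation map",
         call. = FALSE)
  }
  if (nrow(clusters) == 0L) return(NA_real_)
  covered <- vapply(clusters$node_ids, function(nid) {
    mem <- cluster_members(graph, nid)
    if (!is.null(species)) mem <- mem[mem$species_id %in% species, ]
    prots <- unique(mem$protein_id)
    if (length(prots) == 0L) return(FALSE)
    sets <- annotation_terms(complexes, prots)
    if (any(lengths(sets) == 0L)) return(FALSE)
    length(Reduce(intersect, sets)) > 0L
  }, TRUE)
  mean(covered)
}

#' Full evaluation report for an alignment
#'
#' Bundles KO specificity (Ceq, Cnode), KO sensitivity (Cor, Tot), GO
#' process-coherence specificity and sensitivity, and (optionally) MIPS
#' coverage into one report.
#'
#' @param clusters Reported `cluster_set`.
#' @param graph The `alignment_graph`.
#' @param homologs The [homolog_groups()] table.
#' @param networks List of the aligned [ppi_network()]s.
#' @param ko KO [annotation_map()] (skip KO metrics when `NULL`).
#' @param go GO-BP [annotation_map()] (skip GO metrics when `NULL`).
#' @param mips_complex,mips_funcat Optional MIPS [annotation_map()]s.
#' @param alpha Enrichment significance level.
#' @return An `evaluation_report` list; see [glance.evaluation_report()].
#' @export
evaluate_alignment <- function(clusters, graph, homologs, networks,
                               ko = NULL, go = NULL, mips_complex = NULL,
                               mips_funcat = NULL, alpha = 0.05) {
  out <- list(n_clusters = nrow(clusters), alpha = alpha)
  if (!is.null(ko) && nrow(clusters) > 0L) {
    out$ko_specificity <- ko_specificity(clusters, graph, ko)
    out$ko_sensitivity <- ko_sensitivity(clusters, graph, ko, homologs,
                                         networks)
  }
  if (!is.null(go)) {
    gss <- go_specificity_sensitivity(clusters, graph, go, networks,
                                      alpha = alpha)
    out$go_specificity <- gss$specificity
    out$go_sensitivity <- gss$sensitivity
  }
  # coverage is assessed on the species the catalogue annotates (MIPS
  # complexes exist for one species only in a cross-species alignment)
  annotated_species <- function(ann) {
    sp <- vapply(networks, function(net) {
      any(net$proteins %in% ann$protein_id)
    }, TRUE)
    species <- vapply(networks, function(net) net$species_id, "")
    if (all(sp)) NULL else species[sp]
  }
  if (!is.null(mips_complex)) {
    out$mips_complex_coverage <- mips_coverage(
      clusters, graph, mips_complex,
      species = annotated_species(mips_complex))
  }
  if (!is.null(mips_funcat)) {
    out$mips_funcat_coverage <- mips_coverage(
      clusters, graph, mips_funcat,
      species = annotated_species(mips_funcat))
  }
  structure(out, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d cluster(s)\n", x$n_clusters))
  if (!is.null(x$ko_specificity)) {
    cat(sprintf("  KO: Ceq = %.3f, Cnode = %.3f; Cor = %d, Tot = %d\n",
                x$ko_specificity$Ceq, x$ko_specificity$Cnode,
                x$ko_sensitivity$Cor, x$ko_sensitivity$Tot))
  }
  if (!is.null(x$go_specificity)) {
    for (i in seq_len(nrow(x$go_specificity))) {
      cat(sprintf("  GO specificity (%s): %.3f\n",
                  x$go_specificity$species_id[i],
                  x$go_specificity$specificity[i]))
    }
    cat(sprintf("  GO categories enriched: %d\n", x$go_sensitivity))
  }
  if (!is.null(x$mips_complex_coverage)) {
    cat(sprintf("  MIPS complex coverage: %.3f\n", x$mips_complex_coverage))
  }
  if (!is.null(x$mips_funcat_coverage)) {
    cat(sprintf("  MIPS FunCat coverage: %.3f\n", x$mips_funcat_coverage))
  }
  invisible(x)
}

#' Flatten an evaluation report to one row
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return One-row tibble of the report's scalar metrics.
#' @export
glance.evaluation_report <- function(x, ...) {
  row <- tibble::tibble(n_clusters = x$n_clusters)
  if (!is.null(x$ko_specificity)) {
    row$Ceq <- x$ko_specificity$Ceq
    row$Cnode <- x$ko_specificity$Cnode
    row$Cor <- x$ko_sensitivity$Cor
    row$Tot <- x$ko_sensitivity$Tot
  }
  if (!is.null(x$go_specificity)) {
    for (i in seq_len(nrow(x$go_specificity))) {
      row[[paste0("go_specificity_", x$go_specificity$species_id[i])]] <-
        x$go_specificity$specificity[i]
    }
    row$go_categories_enriched <- x$go_sensitivity
  }
  if (!is.null(x$mips_complex_coverage)) {
    row$mips_complex_coverage <- x$mips_complex_coverage
  }
  if (!is.null(x$mips_funcat_coverage)) {
    row$mips_funcat_coverage <- x$mips_funcat_coverage
  }
  row
}
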