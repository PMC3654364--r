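# Synthetic cross-species benchmark with planted conserved modules and
# ground truth, so the whole alignment pipeline is testable without any
# database download.

#' Benchmark configuration
#'
#' Defaults describe a small but realistic two-species screen: 500 proteins
#' per species, eight planted clique modules of four 1:1 ortholog groups
#' each, sparse Erdos-Renyi background interactions (p = 0.005), 10%
#' per-species loss of conserved edges, 25 decoy ortholog groups, and 5%
#' annotation noise.
#'
#' @param n_species 2 or 3 aligned species.
#' @param n_proteins Proteins per species.
#' @param n_modules Number of planted conserved modules.
#' @param module_size Ortholog groups (proteins per species) per module.
#' @param module_topology `"clique"` or `"path"` within-species wiring of a
#'   module.
#' @param background_edge_prob Erdos-Renyi probability of a background edge.
#' @param conserved_edge_dropout Probability that a planted conserved edge
#'   is deleted in a given species (independently per species).
#' @param n_decoy_groups Ortholog groups linking random non-module proteins.
#' @param annotation_noise Probability that an emitted GO/KO annotation row
#'   has its term replaced by a random term of the same namespace.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(n_species = 2L, n_proteins = 500L,
                             n_modules = 8L, module_size = 4L,
                             module_topology = c("clique", "path"),
                             background_edge_prob = 0.005,
                             conserved_edge_dropout = 0.1,
                             n_decoy_groups = 25L, annotation_noise = 0.05,
                             seed = 1L) {
  module_topology <- match.arg(module_topology)
  cfg <- list(n_species = as.integer(n_species),
              n_proteins = as.integer(n_proteins),
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              module_topology = module_topology,
              background_edge_prob = background_edge_prob,
              conserved_edge_dropout = conserved_edge_dropout,
              n_decoy_groups = as.integer(n_decoy_groups),
              annotation_noise = annotation_noise,
              seed = as.integer(seed))
  if (!cfg$n_species %in% c(2L, 3L)) {
    stop("`n_species` must be 2 or 3", call. = FALSE)
  }
  if (cfg$n_modules * cfg$module_size + cfg$n_decoy_groups > cfg$n_proteins) {
    stop("infeasible config: modules plus decoys exceed the protein count",
         call. = FALSE)
  }
  probs <- c(background_edge_prob, conserved_edge_dropout, annotation_noise)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "benchmark_config")
}

#' Generate a synthetic alignment benchmark
#'
#' Each species receives the same protein count. Planted modules are blocks
#' of `module_size` 1:1 ortholog groups whose within-species induced
#' subgraph has the chosen topology, mirrored across species; each conserved
#' edge is deleted per species with probability `conserved_edge_dropout`.
#' Background edges are Erdos-Renyi. Decoy groups link random non-module
#' proteins. Ortholog pairs in planted groups receive e-values log-uniform
#' in \[1e-50, 1e-20\] (the close-homolog regime), decoy pairs in
#' \[1e-3, 1\]. Module members share one planted GO-BP term and one KO term
#' per group; non-module proteins carry random background GO terms; MIPS
#' complex (species A) and FunCat (all species) terms mirror the modules.
#'
#' @param config A [benchmark_config()].
#' @return A `ppi_benchmark` list: `networks` (list of [ppi_network()]),
#'   `homologs`, `similarity`, `annotations` (named list `GO_BP`, `KO`,
#'   `MIPS_COMPLEX`, `MIPS_FUNCAT`), `truth` (planted modules, ortholog
#'   map, planted terms), and `config`.
#' @export
generate_benchmark <- function(config = benchmark_config()) {
  stopifnot(inherits(config, "benchmark_config"))
  with_seed(config$seed, generate_benchmark_impl(config))
}

generate_benchmark_impl <- function(cfg) {
  species <- c("spA", "spB", "spC")[seq_len(cfg$n_species)]
  prot <- function(sp, i) sprintf("%s_p%04d", sp, i)
  n <- cfg$n_proteins
  n_mod_prot <- cfg$n_modules * cfg$module_size

  # planted 1:1 ortholog groups: module m occupies a contiguous index block
  module_of <- rep(seq_len(cfg$n_modules), each = cfg$module_size)
  planted_idx <- seq_len(n_mod_prot)
  planted_groups <- sprintf("M%02d_G%02d", module_of,
                            sequence(rep(cfg$module_size, cfg$n_modules)))

  # within-species module topology on protein indices
  topo_pairs <- function(idx) {
    if (length(idx) < 2L) return(cbind(integer(), integer()))
    if (cfg$module_topology == "clique") {
      t(utils::combn(idx, 2L))
    } else {
      cbind(idx[-length(idx)], idx[-1L])
    }
  }
  conserved <- do.call(rbind, lapply(seq_len(cfg$n_modules), function(m) {
    topo_pairs(planted_idx[module_of == m])
  }))

  networks <- lapply(species, function(sp) {
    kept <- conserved[stats::runif(nrow(conserved)) >=
                        cfg$conserved_edge_dropout, , drop = FALSE]
    bg <- sample_er_pairs(n, cfg$background_edge_prob)
    idx <- rbind(kept, bg)
    edges <- tibble::tibble(from = prot(sp, idx[, 1L]),
                            to = prot(sp, idx[, 2L]))
    ppi_network(edges, sp, proteins = prot(sp, seq_len(n)))
  })
  names(networks) <- species

  # decoy groups over distinct non-module proteins
  decoy_idx <- if (cfg$n_decoy_groups == 0L) {
    integer()
  } else {
    sort(sample((n_mod_prot + 1L):n, cfg$n_decoy_groups))
  }
  decoy_groups <- sprintf("D%03d", seq_len(cfg$n_decoy_groups))
  group_ids <- c(planted_groups, decoy_groups)
  group_idx <- c(planted_idx, decoy_idx)
  homologs <- homolog_groups(tibble::tibble(
    group_id = rep(group_ids, each = length(species)),
    species_id = rep(species, times = length(group_ids)),
    protein_id = unlist(lapply(group_idx, function(i) prot(species, i)),
                        use.names = FALSE)))

  # cross-species similarity: strong e-values for planted, weak for decoys
  pair_idx <- utils::combn(length(species), 2L)
  sim_rows <- lapply(seq_len(ncol(pair_idx)), function(j) {
    s1 <- species[pair_idx[1L, j]]
    s2 <- species[pair_idx[2L, j]]
    ev <- c(10^stats::runif(length(planted_idx), -50, -20),
            10^stats::runif(length(decoy_idx), -3, 0))
    tibble::tibble(query = prot(s1, group_idx), subject = prot(s2, group_idx),
                   e_value = ev,
                   bit_score = round(-10 * log10(ev) + 30, 1))
  })
  similarity <- similarity_table(dplyr::bind_rows(sim_rows))

  # annotations
  planted_go <- sprintf("GO:%07d", seq_len(cfg$n_modules))
  bg_go <- sprintf("GO:%07d", 1000L + seq_len(20L))
  go_rows <- dplyr::bind_rows(
    tibble::tibble(
      protein_id = unlist(lapply(planted_idx, function(i) prot(species, i)),
                          use.names = FALSE),
      term_id = rep(planted_go[module_of], each = length(species))),
    tibble::tibble(
      protein_id = unlist(lapply((n_mod_prot + 1L):n,
                                 function(i) prot(species, i)),
                          use.names = FALSE),
      term_id = rep(sample(bg_go, n - n_mod_prot, replace = TRUE),
                    each = length(species))))
  ko_terms <- sprintf("K%05d", seq_along(group_ids))
  ko_rows <- tibble::tibble(
    protein_id = unlist(lapply(group_idx, function(i) prot(species, i)),
                        use.names = FALSE),
    term_id = rep(ko_terms, each = length(species)))
  go_rows$term_id <- perturb_terms(go_rows$term_id, c(planted_go, bg_go),
                                   cfg$annotation_noise)
  ko_rows$term_id <- perturb_terms(ko_rows$term_id, ko_terms,
                                   cfg$annotation_noise)

  cpx_rows <- tibble::tibble(
    protein_id = prot(species[1L], planted_idx),
    term_id = sprintf("CPX%03d", module_of))
  fc_rows <- tibble::tibble(
    protein_id = unlist(lapply(planted_idx, function(i) prot(species, i)),
                        use.names = FALSE),
    term_id = rep(sprintf("FC%02d", module_of), each = length(species)))

  truth <- list(
    planted_modules = split(planted_groups, module_of),
    ortholog_map = homologs[homologs$group_id %in% planted_groups, ],
    planted_terms = stats::setNames(planted_go,
                                    sprintf("module_%02d",
                                            seq_len(cfg$n_modules))))
  structure(
    list(networks = networks, homologs = homologs, similarity = similarity,
         annotations = list(
           GO_BP = annotation_map(go_rows, "GO_BP"),
           KO = annotation_map(ko_rows, "KO"),
           MIPS_COMPLEX = annotation_map(cpx_rows, "MIPS_COMPLEX"),
           MIPS_FUNCAT = annotation_map(fc_rows, "MIPS_FUNCAT")),
         truth = truth, config = cfg),
    class = "ppi_benchmark")
}

# Sample Erdos-Renyi unordered pairs on 1..n with probability p, without
# materializing the full pair list.
sample_er_pairs <- function(n, p) {
  n_pairs <- n * (n - 1) / 2
  if (n_pairs == 0 || p <= 0) return(cbind(integer(), integer()))
  m <- stats::rbinom(1L, n_pairs, p)
  if (m == 0L) return(cbind(integer(), integer()))
  flat <- sort(sample(n_pairs, m))
  # map linear index to (i, j), i < j, row-major over i
  i <- findInterval(flat - 1, cumsum(c(0, (n - 1):1)), rightmost.closed = FALSE)
  offset <- flat - c(0, cumsum((n - 1):1))[i]
  cbind(i, i + offset)
}

perturb_terms <- function(terms, pool, noise) {
  if (noise <= 0 || length(terms) == 0L) return(terms)
  hit <- stats::runif(length(terms)) < noise
  terms[hit] <- sample(pool, sum(hit), replace = TRUE)
  terms
}

#' KO annotation map derived from a homolog group table
#'
#' Treats every group id as a KO term carried by all its member proteins.
#' Evaluating an alignment whose nodes were built from the same table
#' against this map realizes the all-correct benchmark condition
#' (Ceq = Cnode = 1).
#'
#' @param homologs A [homolog_groups()] table.
#' @return A KO [annotation_map()].
#' @export
ko_annotation <- function(homologs) {
  annotation_map(tibble::tibble(protein_id = homologs$protein_id,
                                term_id = homologs$group_id), "KO")
}

#' Ground-truth recovery metrics
#'
#' `module_recall`: the fraction of planted modules for which some cluster
#' contains at least half (rounded up) of the module's ortholog groups.
#' `node_precision`: the fraction of clustered alignment nodes that
#' originate from planted groups. An empty cluster list yields
#' `(0, 0)` with attribute `undefined_precision = TRUE`.
#'
#' @param clusters A `cluster_set` of reported clusters.
#' @param truth The `truth` element of a `ppi_benchmark`.
#' @param graph The `alignment_graph` the clusters came from.
#' @return One-row tibble with `module_recall` and `node_precision`.
#' @export
recovery_metrics <- function(clusters, truth, graph) {
  planted <- unlist(truth$planted_modules, use.names = FALSE)
  if (nrow(clusters) == 0L) {
    out <- tibble::tibble(module_recall = 0, node_precision = 0)
    attr(out, "undefined_precision") <- TRUE
    return(out)
  }
  cl_groups <- lapply(clusters$node_ids, function(nid) {
    graph$nodes$group_id[match(nid, graph$nodes$node_id)]
  })
  recall_hits <- vapply(truth$planted_modules, function(gids) {
    need <- ceiling(length(gids) / 2)
    any(vapply(cl_groups, function(cg) sum(unique(cg) %in% gids) >= need,
               TRUE))
  }, TRUE)
  all_groups <- unlist(cl_groups, use.names = FALSE)
  tibble::tibble(module_recall = mean(recall_hits),
                 node_precision = mean(all_groups %in% planted))
}
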