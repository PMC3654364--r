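test_that("interaction universe counts unordered pairs", {
  expect_equal(interaction_universe(1), 0)
  expect_equal(interaction_universe(4), 6)
  expect_error(interaction_universe(-1), "non-negative")
  expect_error(interaction_universe(2.5), "integer")
})

test_that("node building spans groups, cross-products, and best pairs", {
  netA <- tiny_network("sA", c("a1", "a2"), c("a1", "x1"))
  netB <- tiny_network("sB", c("b1", "b2"))
  h <- homolog_groups(tibble::tibble(
    group_id = c("K1", "K1", "K2", "K2", "K2"),
    species_id = c("sA", "sB", "sA", "sA", "sB"),
    protein_id = c("a1", "b1", "a1", "a2", "b1")))

  n1 <- build_nodes(h, list(netA, netB))
  expect_equal(nrow(n1), 3L)  # K1 gives 1 node, K2 the 2-way cross-product
  k2 <- n1[n1$group_id == "K2", ]
  expect_equal(nrow(k2), 2L)
  expect_setequal(vapply(k2$members, `[[`, "", "sA"), c("a1", "a2"))

  sim <- similarity_table(tibble::tibble(
    query = c("a1", "a2"), subject = c("b1", "b1"),
    e_value = c(1e-5, 1e-20), bit_score = c(40, 90)))
  nb <- build_nodes(h, list(netA, netB), mode = "best_pairs",
                    similarity = sim)
  expect_equal(nrow(nb), 2L)
  best_k2 <- nb$members[nb$group_id == "K2"][[1L]]
  expect_equal(unname(best_k2["sA"]), "a2")  # smallest e-value wins

  expect_error(build_nodes(h, list(netA, netB), mode = "best_pairs"),
               "similarity")
})

test_that("nodes are restricted to proteins present in the PPI networks", {
  netA <- tiny_network("sA", c("a1", "a2"))
  netB <- tiny_network("sB", c("b1", "b2"))
  h <- homolog_groups(tibble::tibble(
    group_id = c("K1", "K1", "K2", "K2"),
    species_id = c("sA", "sB", "sA", "sB"),
    protein_id = c("a1", "b1", "ghost", "b2")))
  nodes <- build_nodes(h, list(netA, netB))
  expect_equal(nodes$group_id, "K1")  # K2 loses its only sA member
})

test_that("pairwise edges require direct interaction in both species", {
  netA <- tiny_network("sA", c("a1", "a2"), c("a2", "a3"))
  netB <- tiny_network("sB", c("b1", "b2"))
  h <- homolog_groups(tibble::tibble(
    group_id = c("K1", "K1", "K2", "K2", "K3", "K3"),
    species_id = rep(c("sA", "sB"), 3),
    protein_id = c("a1", "b1", "a2", "b2", "a3", "b3")))
  netB2 <- tiny_network("sB", c("b1", "b2"), c("b3", "b9"))
  nodes <- build_nodes(h, list(netA, netB2))
  g <- add_edges_pairwise(nodes, list(netA, netB2))
  # (a1,b1)-(a2,b2): direct in both -> edge; (a2,b2)-(a3,b3): only in sA
  expect_equal(nrow(g$edges), 1L)
  pair <- sort(c(vapply(g$nodes$members[c(g$edges$u, g$edges$v)],
                        `[[`, "", "sA")))
  expect_equal(pair, c("a1", "a2"))
  expect_equal(g$edges$provenance[[1L]],
               c(sA = "direct", sB = "direct"))
})

test_that("nodes sharing a protein never get an edge", {
  netA <- tiny_network("sA", c("a1", "a1b"))
  netB <- tiny_network("sB", c("b1", "b2"))
  nodes <- tibble::tibble(
    node_id = 1:2, group_id = c("K1", "K1"),
    members = list(c(sA = "a1", sB = "b1"), c(sA = "a1", sB = "b2")))
  # a1 interacts with a1b, b1 with b2; but the nodes share a1
  g <- add_edges_pairwise(nodes, list(netA, netB))
  expect_equal(nrow(g$edges), 0L)
})

test_that("self-loops in PPI networks do not create alignment edges", {
  netA <- ppi_network(data.frame(from = c("a1", "a1"), to = c("a1", "a2")),
                      "sA")
  netB <- tiny_network("sB", c("b1", "b2"))
  nodes <- tibble::tibble(
    node_id = 1:2, group_id = c("K1", "K2"),
    members = list(c(sA = "a1", sB = "b1"), c(sA = "a2", sB = "b2")))
  g <- add_edges_pairwise(nodes, list(netA, netB))
  expect_equal(nrow(g$edges), 1L)  # only via the true (a1,a2)/(b1,b2) pair
})

test_that("edges referencing proteins missing from a network fail", {
  netA <- tiny_network("sA", c("a1", "a2"))
  netB <- tiny_network("sB", c("b1", "b2"))
  nodes <- tibble::tibble(
    node_id = 1:2, group_id = c("K1", "K2"),
    members = list(c(sA = "a1", sB = "b1"), c(sA = "zz", sB = "b2")))
  expect_error(add_edges_pairwise(nodes, list(netA, netB)), "absent")
})

test_that("conservation soundness: every alignment edge projects onto a PPI edge", {
  withr::with_seed(11, {
    b <- generate_benchmark(benchmark_config(n_proteins = 150L,
                                             n_modules = 4L, seed = 31L))
    g <- align_networks(b$networks, b$homologs)
    expect_gt(nrow(g$edges), 0L)
    for (s in g$species) {
      keys <- consnet:::network_edge_keys(b$networks[[s]])
      mu <- vapply(g$nodes$members[match(g$edges$u, g$nodes$node_id)],
                   `[[`, "", s)
      mv <- vapply(g$nodes$members[match(g$edges$v, g$nodes$node_id)],
                   `[[`, "", s)
      expect_true(all(consnet:::edge_key(mu, mv) %in% keys))
    }
  })
})

three_species_fixture <- function(third_edges) {
  netA <- tiny_network("sA", c("a1", "a2"))
  netB <- tiny_network("sB", c("b1", "b2"))
  netC <- do.call(tiny_network, c(list("sC"), third_edges))
  h <- homolog_groups(tibble::tibble(
    group_id = rep(c("K1", "K2"), each = 3),
    species_id = rep(c("sA", "sB", "sC"), 2),
    protein_id = c("a1", "b1", "c1", "a2", "b2", "c9")))
  nodes <- build_nodes(h, list(netA, netB, netC))
  list(nodes = nodes, networks = list(netA, netB, netC))
}

test_that("three-way edges: two direct plus one within distance two", {
  # c1..c9 direct
  fx <- three_species_fixture(list(c("c1", "c9")))
  g <- add_edges_multiway(fx$nodes, fx$networks)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$provenance[[1L]][["sC"]], "direct")

  # c1..c9 at distance 2
  fx2 <- three_species_fixture(list(c("c1", "cm"), c("cm", "c9")))
  g2 <- add_edges_multiway(fx2$nodes, fx2$networks)
  expect_equal(nrow(g2$edges), 1L)
  expect_equal(g2$edges$provenance[[1L]][["sC"]], "distance-2")

  # distance 3: no edge
  fx3 <- three_species_fixture(list(c("c1", "cm"), c("cm", "cn"),
                                    c("cn", "c9")))
  g3 <- add_edges_multiway(fx3$nodes, fx3$networks)
  expect_equal(nrow(g3$edges), 0L)

  # unreachable: no edge, no error
  fx4 <- three_species_fixture(list(c("c1", "cm"), c("c9", "cn")))
  expect_equal(nrow(add_edges_multiway(fx4$nodes, fx4$networks)$edges), 0L)

  expect_error(add_edges_multiway(fx$nodes, fx$networks, min_direct = 0L),
               "min_direct")
})

test_that("min_direct = 3 equals exhaustive all-pairs intersection", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      b <- generate_benchmark(benchmark_config(
        n_species = 3L, n_proteins = 60L, n_modules = 3L, module_size = 3L,
        n_decoy_groups = 5L, background_edge_prob = 0.02,
        conserved_edge_dropout = 0.2, seed = 600L + rep))
      nodes <- build_nodes(b$homologs, b$networks)
      expect_lte(nrow(nodes), 50L)
      g <- add_edges_multiway(nodes, b$networks, min_direct = 3L)
      # oracle: brute-force over all node pairs, all species direct
      keys <- lapply(b$networks, consnet:::network_edge_keys)
      species <- vapply(b$networks, function(x) x$species_id, "")
      expected <- 0L
      if (nrow(nodes) >= 2L) {
        for (i in seq_len(nrow(nodes) - 1L)) {
          for (j in (i + 1L):nrow(nodes)) {
            mi <- nodes$members[[i]]
            mj <- nodes$members[[j]]
            if (any(mi %in% mj)) next
            direct <- vapply(seq_along(species), function(k) {
              consnet:::edge_key(mi[[k]], mj[[k]]) %in% keys[[k]]
            }, TRUE)
            if (all(direct)) {
              expected <- expected + 1L
              expect_true(any(g$edges$u == i & g$edges$v == j))
            }
          }
        }
      }
      expect_equal(nrow(g$edges), expected)
    }
  })
})

test_that("edge construction is symmetric in node order", {
  netA <- tiny_network("sA", c("a1", "a2"))
  netB <- tiny_network("sB", c("b1", "b2"))
  nodes <- tibble::tibble(
    node_id = 1:2, group_id = c("K1", "K2"),
    members = list(c(sA = "a1", sB = "b1"), c(sA = "a2", sB = "b2")))
  g1 <- add_edges_pairwise(nodes, list(netA, netB))
  g2 <- add_edges_pairwise(nodes[2:1, ], list(netA, netB))
  expect_equal(g1$edges[, c("u", "v")], g2$edges[, c("u", "v")])
})

test_that("promiscuous groups are capped with a warning", {
  netA <- tiny_network("sA", c("a1", "a2"), c("a3", "a4"), c("a5", "a6"),
                       c("a7", "a8"), c("a9", "a10"))
  netB <- tiny_network("sB", c("b1", "b2"), c("b3", "b4"))
  h <- homolog_groups(tibble::tibble(
    group_id = "K1",
    species_id = c(rep("sA", 10), rep("sB", 4)),
    protein_id = c(paste0("a", 1:10), paste0("b", 1:4))))
  expect_warning(nodes <- build_nodes(h, list(netA, netB),
                                      cross_product_cap = 8L), "cap")
  expect_equal(nrow(nodes), 8L)
})
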