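test_that("KO specificity counts nodes whose members share a KO term", {
  g <- toy_graph(2, cbind(1, 2))
  ko_half <- ann_map("KO",
                     list("spA_p001", "K1"), list("spB_p001", "K1"),
                     list("spA_p002", "K2"), list("spB_p002", "K9"))
  cl <- connected_components(g)
  spec <- ko_specificity(cl, g, ko_half)
  expect_equal(spec$Ceq, 0.5)
  expect_equal(spec$Cnode, 0.5)

  ko_none <- ann_map("KO", list("zz", "K1"))
  spec0 <- ko_specificity(cl, g, ko_none)
  expect_equal(spec0$Ceq, 0)
  expect_equal(spec0$Cnode, 0)

  expect_error(ko_specificity(filter_clusters(cl, min_size = 5L), g,
                              ko_half), "no nodes")
})

test_that("nodes built from the KO table itself are all correct (Ceq = Cnode = 1)", {
  b <- generate_benchmark(benchmark_config(n_proteins = 200L,
                                           n_modules = 4L, seed = 8L))
  g <- align_networks(b$networks, b$homologs)
  cl <- filter_clusters(connected_components(g))
  expect_gt(nrow(cl), 0L)
  spec <- ko_specificity(cl, g, ko_annotation(b$homologs))
  expect_equal(spec$Ceq, 1)
  expect_equal(spec$Cnode, 1)
})

test_that("KO sensitivity counts correct nodes and eligible groups", {
  b <- generate_benchmark(benchmark_config(
    n_proteins = 120L, n_modules = 3L, module_size = 4L,
    conserved_edge_dropout = 0, background_edge_prob = 0,
    annotation_noise = 0, n_decoy_groups = 10L, seed = 5L))
  g <- align_networks(b$networks, b$homologs)
  cl <- filter_clusters(connected_components(g))
  sens <- ko_sensitivity(cl, g, ko_annotation(b$homologs), b$homologs,
                         b$networks)
  # all 12 planted nodes recovered and correct; 12 planted + 10 decoy
  # groups span both species
  expect_equal(sens$Cor, 12L)
  expect_equal(sens$Tot, 22L)

  none <- ko_sensitivity(filter_clusters(cl, min_size = 99L), g,
                         ko_annotation(b$homologs), b$homologs, b$networks)
  expect_equal(none$Cor, 0L)
  expect_equal(none$Tot, 22L)
})

test_that("hypergeometric enrichment matches the closed form and brute force", {
  bg <- sprintf("p%03d", 1:100)
  ann <- do.call(ann_map, c(list("GO_BP"),
                            lapply(bg[1:5], function(p) list(p, "t"))))
  res <- go_enrichment(bg[1:5], bg, ann)
  expect_equal(res$p_raw, 1 / choose(100, 5), tolerance = 1e-12)
  expect_equal(res$k, 5L)
  expect_equal(res$K, 5L)

  # brute force over all C(12, 4) subsets: P(X >= k) for K = 5 marked
  M <- 12L; K <- 5L; n <- 4L
  marked <- seq_len(K)
  subsets <- utils::combn(M, n)
  for (k in 1:4) {
    brute <- mean(vapply(seq_len(ncol(subsets)), function(j) {
      sum(subsets[, j] %in% marked) >= k
    }, TRUE))
    bg2 <- sprintf("q%02d", 1:M)
    ann2 <- do.call(ann_map, c(list("GO_BP"),
                               lapply(bg2[marked], function(p) {
                                 list(p, "tm")
                               })))
    # choose a cluster with exactly k marked proteins
    cluster <- c(bg2[seq_len(k)], bg2[K + seq_len(n - k)])
    res2 <- go_enrichment(cluster, bg2, ann2)
    expect_equal(res2$p_raw[res2$term == "tm"], brute, tolerance = 1e-12)
  }

  # a term with zero cluster hits is not tested
  ann3 <- ann_map("GO_BP", list(bg[50], "elsewhere"))
  expect_equal(nrow(go_enrichment(bg[1:5], bg, ann3)), 0L)

  expect_error(go_enrichment(c(bg, "extra"), bg, ann), "subset")
})

test_that("BH adjustment reproduces the step-up procedure", {
  bg <- sprintf("p%02d", 1:40)
  # three terms with different enrichment in the same cluster
  rows <- c(lapply(bg[1:4], function(p) list(p, "tA")),
            lapply(bg[c(1:3, 11:14)], function(p) list(p, "tB")),
            lapply(bg[c(1:2, 11:20)], function(p) list(p, "tC")))
  ann <- do.call(ann_map, c(list("GO_BP"), rows))
  res <- go_enrichment(bg[1:4], bg, ann)
  manual <- stats::p.adjust(res$p_raw, method = "BH")
  expect_equal(res$p_adj, manual)
  # worked step-up example
  p <- c(0.01, 0.02, 0.04)
  m <- length(p)
  stepup <- rev(cummin(rev(p * m / seq_len(m))))
  expect_equal(stepup, c(0.03, 0.03, 0.04))
  expect_equal(stats::p.adjust(p, method = "BH"), stepup)
})

test_that("GO specificity is 1 under uniquely coherent clusters and
           sensitivity counts distinct terms", {
  b <- generate_benchmark(benchmark_config(
    n_proteins = 120L, n_modules = 3L, module_size = 4L,
    conserved_edge_dropout = 0, background_edge_prob = 0,
    annotation_noise = 0, seed = 2L))
  g <- align_networks(b$networks, b$homologs)
  cl <- filter_clusters(connected_components(g))
  gss <- go_specificity_sensitivity(cl, g, b$annotations$GO_BP, b$networks)
  expect_equal(gss$specificity$specificity, c(1, 1))
  expect_equal(gss$sensitivity, 3L)

  empty <- go_specificity_sensitivity(filter_clusters(cl, 99L), g,
                                      b$annotations$GO_BP, b$networks)
  expect_true(all(is.na(empty$specificity$specificity)))
  expect_equal(empty$sensitivity, 0L)
})

test_that("shuffled annotations destroy apparent GO coherence", {
  b <- generate_benchmark(benchmark_config(
    n_proteins = 120L, n_modules = 3L, module_size = 4L,
    conserved_edge_dropout = 0, background_edge_prob = 0,
    annotation_noise = 0, seed = 12L))
  g <- align_networks(b$networks, b$homologs)
  cl <- filter_clusters(connected_components(g))
  go <- b$annotations$GO_BP
  rates <- withr::with_seed(13L, {
    vapply(1:10, function(i) {
      shuffled <- annotation_map(
        tibble::tibble(protein_id = sample(go$protein_id),
                       term_id = go$term_id), "GO_BP")
      gss <- go_specificity_sensitivity(cl, g, shuffled, b$networks)
      mean(gss$specificity$specificity)
    }, 0)
  })
  # under random annotation the coherent-cluster rate collapses toward the
  # false-positive level
  expect_lt(mean(rates), 0.25)
})

test_that("MIPS coverage requires a shared complex across all members", {
  g <- toy_graph(4, cbind(c(1, 3), c(2, 4)))
  full <- do.call(ann_map, c(list("MIPS_COMPLEX"),
                             unlist(lapply(1:4, function(i) {
                               list(list(sprintf("spA_p%03d", i), "CPX1"),
                                    list(sprintf("spB_p%03d", i), "CPX1"))
                             }), recursive = FALSE)))
  cl <- connected_components(g)
  expect_equal(mips_coverage(cl, g, full), 1)

  # cluster {3,4} has an unannotated member -> not covered
  partial <- do.call(ann_map, c(list("MIPS_COMPLEX"),
                                unlist(lapply(1:3, function(i) {
                                  list(list(sprintf("spA_p%03d", i), "CPX1"),
                                       list(sprintf("spB_p%03d", i), "CPX1"))
                                }), recursive = FALSE)))
  expect_equal(mips_coverage(cl, g, partial), 0.5)

  # assessed on one species only
  a_only <- do.call(ann_map, c(list("MIPS_COMPLEX"),
                               lapply(1:4, function(i) {
                                 list(sprintf("spA_p%03d", i), "CPX1")
                               })))
  expect_equal(mips_coverage(cl, g, a_only, species = "spA"), 1)
  expect_equal(mips_coverage(cl, g, a_only), 0)
  expect_true(is.na(mips_coverage(filter_clusters(cl, 99L), g, a_only)))
})

test_that("the bundled report collects every metric family", {
  b <- generate_benchmark(benchmark_config(n_proteins = 150L,
                                           n_modules = 4L, seed = 6L))
  g <- align_networks(b$networks, b$homologs)
  cl <- filter_clusters(connected_components(g))
  rep <- evaluate_alignment(cl, g, b$homologs, b$networks,
                            ko = ko_annotation(b$homologs),
                            go = b$annotations$GO_BP,
                            mips_complex = b$annotations$MIPS_COMPLEX,
                            mips_funcat = b$annotations$MIPS_FUNCAT)
  row <- glance(rep)
  expect_equal(row$Ceq, 1)
  expect_equal(row$Cnode, 1)
  expect_true(row$Cor <= row$Tot)
  expect_true(all(c("go_categories_enriched", "mips_complex_coverage",
                    "mips_funcat_coverage") %in% names(row)))
  long <- tidy(rep)
  expect_true(all(c("metric", "value") %in% names(long)))
})
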