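test_that("BLAST confidence: better-than-average nodes score 1, worse the ratio", {
  expect_equal(node_confidence_blast(c(1e-12, 1e-10))[1L], 1)
  # cluster mean 1e-10, node at 2e-10 -> ratio 0.5
  conf <- node_confidence_blast(c(2e-10, 0.5e-10, 0.5e-10))
  expect_equal(conf[1L], 0.5)
  expect_equal(conf[2L], 1)
  # all equal: everyone at the boundary E = mean -> 1
  expect_equal(node_confidence_blast(rep(3e-8, 4)), rep(1, 4))
  # missing similarity record -> 0
  expect_equal(node_confidence_blast(c(1e-10, NA))[2L], 0)
  expect_error(node_confidence_blast(double()), "empty")
})

test_that("ortholog confidence needs a shared KO term across all members", {
  ko <- ann_map("KO", list("a1", "K1"), list("b1", "K1"),
                list("a2", "K2"), list("b2", "K3"),
                list("a3", "K4"))
  nodes <- tibble::tibble(
    node_id = 1:3, group_id = c("G1", "G2", "G3"),
    members = list(c(sA = "a1", sB = "b1"), c(sA = "a2", sB = "b2"),
                   c(sA = "a3", sB = "b3")))  # b3 unannotated
  expect_equal(node_confidence_ortholog(nodes, ko), c(1, 0, 0))
})

test_that("S(C) is the mean node confidence", {
  expect_equal(sequence_similarity_score(c(1, 1, 0)), 2 / 3)
  expect_equal(sequence_similarity_score(rep(1, 5)), 1)
  withr::with_seed(4, {
    for (i in 1:20) {
      s <- stats::runif(sample(1:12, 1))
      expect_equal(sequence_similarity_score(s), sum(s) / length(s))
    }
  })
  expect_error(sequence_similarity_score(double()), "empty")
})

test_that("I(C) is edge count over cliqueness", {
  expect_equal(interaction_conservation(3, 3), 1)
  expect_equal(interaction_conservation(2, 3), 2 / 3)
  expect_equal(interaction_conservation(3, 4), 0.5)
  expect_true(is.na(interaction_conservation(0, 1)))
})

test_that("across-cluster normalization caps at the mean", {
  expect_equal(normalize_over_clusters(c(0.5, 1.0)), c(0.5 / 0.75, 1.0))
  expect_equal(normalize_over_clusters(c(0.4, 0.4)), c(1, 1))
  expect_equal(normalize_over_clusters(0.3), 1)
  expect_warning(z <- normalize_over_clusters(c(0, 0)), "degenerate")
  expect_equal(z, c(0, 0))
  # monotone on the sub-mean segment
  withr::with_seed(8, {
    for (i in 1:20) {
      v <- stats::runif(10)
      nv <- normalize_over_clusters(v)
      below <- v < mean(v)
      expect_equal(order(v[below]), order(nv[below]))
      expect_true(all(nv >= 0 & nv <= 1))
    }
  })
})

test_that("F(C) is per-species intersection-over-union of BP terms", {
  g <- toy_graph(2, cbind(1, 2))
  both <- ann_map("GO_BP",
                  list("spA_p001", "t1"), list("spA_p001", "t2"),
                  list("spA_p002", "t1"), list("spA_p002", "t2"),
                  list("spB_p001", "t1"), list("spB_p001", "t2"),
                  list("spB_p002", "t1"), list("spB_p002", "t2"))
  expect_equal(functional_coherence(g, 1:2, both), 1)

  one_sp <- ann_map("GO_BP",
                    list("spA_p001", "t1"), list("spA_p001", "t2"),
                    list("spA_p002", "t2"), list("spA_p002", "t3"))
  # spA: {t1,t2} vs {t2,t3} -> 1/3; spB has no annotated proteins: skipped
  expect_equal(functional_coherence(g, 1:2, one_sp), 1 / 3)

  none <- ann_map("GO_BP", list("zz", "t1"))
  expect_equal(functional_coherence(g, 1:2, none), 0)

  # a species with a single annotated protein is skipped, not counted
  single <- ann_map("GO_BP",
                    list("spA_p001", "t1"),
                    list("spB_p001", "t1"), list("spB_p002", "t1"))
  expect_equal(functional_coherence(g, 1:2, single), 1)
})

test_that("combined score is the weighted sum with validated weights", {
  expect_equal(combined_score(1, 1, 1), 1)
  expect_equal(combined_score(0.6, 0.9, 0.3), 0.6)
  expect_equal(combined_score(0.42, 0.9, 0.9, weights = c(1, 0, 0)), 0.42)
  expect_error(combined_score(1, 1, 1, weights = c(0.5, 0.5, 0.5)),
               "summing to 1")
})

test_that("score components and the combination stay in [0,1] and match
           independent recomputation", {
  withr::with_seed(21, {
    for (i in 1:30) {
      n <- sample(2:10, 1)
      g <- random_toy_graph(n, stats::runif(1, 0.1, 0.9))
      ko_rows <- unlist(lapply(seq_len(n), function(j) {
        term <- sample(c("K1", "K2"), 1)
        list(list(sprintf("spA_p%03d", j), term),
             list(sprintf("spB_p%03d", j), sample(c("K1", "K2"), 1)))
      }), recursive = FALSE)
      ko <- do.call(ann_map, c(list("KO"), ko_rows))
      go_rows <- unlist(lapply(seq_len(n), function(j) {
        lapply(sample(c("t1", "t2", "t3"), sample(1:2, 1)), function(t) {
          list(sprintf("%s_p%03d", sample(c("spA", "spB"), 1), j), t)
        })
      }), recursive = FALSE)
      go <- do.call(ann_map, c(list("GO_BP"), go_rows))
      cl <- connected_components(g)
      # all-singleton draws hit the (warned) degenerate normalization path
      sc <- suppressWarnings(score_clusters(cl, g, ko = ko,
                                            annotations = go))
      ok <- !is.na(sc$I_raw)
      expect_true(all(sc$S >= 0 & sc$S <= 1))
      expect_true(all(sc$F >= 0 & sc$F <= 1))
      expect_true(all(sc$I_norm[ok] >= 0 & sc$I_norm[ok] <= 1))
      expect_true(all(sc$score[ok] >= 0 & sc$score[ok] <= 1))
      # Eq identities, recomputed by hand
      for (r in which(ok)) {
        s_k <- sc$s_k[[r]]
        expect_equal(sc$S[r], sum(s_k) / length(s_k), tolerance = 1e-12)
        expect_equal(sc$I_raw[r],
                     sc$edge_count[r] / (sc$size[r] * (sc$size[r] - 1) / 2),
                     tolerance = 1e-12)
        expect_equal(sc$score[r],
                     (sc$S[r] + sc$I_norm[r] + sc$F[r]) / 3,
                     tolerance = 1e-12)
      }
      if (any(ok)) {
        m <- mean(sc$I_raw, na.rm = TRUE)
        if (m > 0) {
          expect_equal(sc$I_norm[ok], pmin(sc$I_raw[ok] / m, 1),
                       tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("scores are invariant to node relabeling", {
  withr::with_seed(31, {
    g <- random_toy_graph(8, 0.4)
    ko <- do.call(ann_map, c(list("KO"), unlist(lapply(1:8, function(i) {
      list(list(sprintf("spA_p%03d", i), "K1"),
           list(sprintf("spB_p%03d", i), if (i %% 2) "K1" else "K9"))
    }), recursive = FALSE)))
    cl <- connected_components(g)
    sc1 <- score_clusters(cl, g, ko = ko)
    # relabel: node i -> i + 100, same topology
    g2 <- g
    g2$nodes$node_id <- g$nodes$node_id + 100L
    g2$edges$u <- g$edges$u + 100L
    g2$edges$v <- g$edges$v + 100L
    sc2 <- score_clusters(connected_components(g2), g2, ko = ko)
    expect_equal(sort(sc1$score), sort(sc2$score))
    expect_equal(sort(sc1$S), sort(sc2$S))
    expect_equal(sort(sc1$I_raw), sort(sc2$I_raw))
  })
})

test_that("empirical p-values follow (R + 1) / (N + 1)", {
  null9 <- seq_len(999) / 1000
  expect_equal(empirical_pvalue(2, null9), 1 / 1000)
  expect_equal(empirical_pvalue(0, null9), 1)
  expect_error(empirical_pvalue(1, double()), "empty")
  # actual drawn from the same null -> approximately uniform p-values
  withr::with_seed(77, {
    null <- stats::rnorm(2000)
    p <- vapply(stats::rnorm(2000), empirical_pvalue, 0,
                null_values = null)
    ks <- suppressWarnings(stats::ks.test(p, "punif"))
    expect_gt(ks$p.value, 0.001)
  })
})
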