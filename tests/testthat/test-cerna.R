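test_that("Spearman correlation uses mid-ranks and monotone invariance", {
  expect_equal(spearman_cc(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_equal(spearman_cc(1:6, -(1:6)^3), -1)           # monotone decreasing
  x <- c(0.3, 1.2, 2.8, 3.1, 5.0)
  expect_equal(spearman_cc(x, exp(x)), 1)                # monotone transform
  expect_warning(r <- spearman_cc(rep(2, 4), 1:4), "undefined")
  expect_true(is.na(r))
  expect_error(spearman_cc(1:2, 1:2), ">= 3")
  expect_error(spearman_cc(1:4, 1:5), "equal length")
})

test_that("sponge hypergeometric test matches full enumeration for M <= 12", {
  expect_equal(sponge_hypergeom_test(10, 4, 5, 2), 186 / 252)
  expect_equal(sponge_hypergeom_test(6, 3, 3, 3), 1 / 20)
  expect_equal(sponge_hypergeom_test(7, 3, 4, 0), 1)
  for (M in c(5, 8, 12)) {
    for (K in c(2, floor(M / 2))) {
      for (n in c(2, M - 1)) {
        for (k in 0:min(K, n)) {
          expect_equal(sponge_hypergeom_test(M, K, n, k),
                       hyper_tail_enumerate(M, K, n, k),
                       tolerance = 1e-12,
                       info = sprintf("M=%d K=%d n=%d k=%d", M, K, n, k))
        }
      }
    }
  }
})

test_that("sponge p is monotone non-increasing in k and validates input", {
  for (cfg in list(c(20, 8, 10), c(50, 5, 7), c(12, 6, 6))) {
    ks <- 0:min(cfg[2], cfg[3])
    ps <- vapply(ks, function(k)
      sponge_hypergeom_test(cfg[1], cfg[2], cfg[3], k), numeric(1))
    expect_true(all(diff(ps) <= 1e-15))
  }
  expect_error(sponge_hypergeom_test(10, 11, 5, 2), "universe")
  expect_error(sponge_hypergeom_test(10, 4, 5, 5), "min\\(K, n\\)")
  expect_error(sponge_hypergeom_test(10, 4, 5, -1), "non-negative")
})

test_that("negative co-expression filter is strict and targeting-gated", {
  # rank permutation with SCC exactly -0.7: excluded by the strict rule
  feat <- rbind(f_boundary = c(1, 2, 3, 4, 5),
                f_strong = c(5, 4, 3, 2, 1),
                f_untargeted = c(5, 4, 3, 2, 1))
  mir <- rbind(m1 = c(5, 4, 2, 1, 3),
               m2 = c(1, 2, 3, 4, 5))
  colnames(feat) <- colnames(mir) <- paste0("s", 1:5)
  expect_equal(spearman_cc(feat["f_boundary", ], mir["m1", ]), -0.7)
  targets <- data.frame(mirna_id = c("m1", "m2", "m2"),
                        target_id = c("f_boundary", "f_strong", "f_ghost"),
                        target_class = "mRNA")
  expect_warning(
    kept <- negative_coexpression_pairs(feat, mir, targets),
    "skipped")
  expect_equal(kept$feature_id, "f_strong")     # SCC -1, targeted
  expect_equal(kept$scc, -1)
  # f_untargeted has SCC -1 with m2 but no target-table row: absent
  expect_false("f_untargeted" %in% kept$feature_id)
})

test_that("triplet assembly applies PCC and sponge thresholds strictly", {
  samples <- paste0("s", 1:8)
  z <- c(0.3, 1.1, 2.2, 2.9, 4.1, 5.2, 6.0, 7.5)
  m_expr <- matrix(2^z, 1, dimnames = list("m1", samples))
  l_expr <- matrix(3 * 2^z, 1, dimnames = list("l1", samples))
  mm <- data.frame(feature_id = "m1", mirna_id = "miR-1", scc = -1)
  lm <- data.frame(feature_id = "l1", mirna_id = "miR-1", scc = -1)
  # k=1, K=1, n=1, M=2: p = 0.5 >= 0.05, rejected
  expect_equal(nrow(build_cerna_triplets(mm, lm, m_expr, l_expr,
                                         universe = c("miR-1", "miR-2"))), 0)
  # large universe: p = 1/30 < 0.05, PCC = 1 > 0.9, retained
  uni <- sprintf("miR-%d", 1:30)
  tri <- build_cerna_triplets(mm, lm, m_expr, l_expr, universe = uni)
  expect_equal(nrow(tri), 1)
  expect_equal(tri$pcc_mrna_lncrna, 1)
  expect_equal(tri$p_sponge, 1 / 30)
  expect_equal(tri$k_shared, 1)
  # PCC at or below 0.9: rejected even with a tiny sponge p
  l_weak <- matrix(c(2^z[1:7], 2), 1, dimnames = list("l1", samples))
  pcc <- cor(m_expr[1, ], l_weak[1, ])
  expect_lt(pcc, 0.9)
  expect_equal(nrow(build_cerna_triplets(mm, lm, m_expr, l_weak,
                                         universe = uni)), 0)
  expect_error(build_cerna_triplets(mm, lm, m_expr, l_expr,
                                    universe = character(0)), "universe")
})

test_that("triplet assembly is invariant under feature relabeling", {
  set.seed(5)
  samples <- paste0("s", 1:9)
  z <- rnorm(9)
  m_expr <- rbind(mA = 2^z, mB = 2^rnorm(9))
  l_expr <- rbind(lA = 5 * 2^z, lB = 2^rnorm(9))
  colnames(m_expr) <- colnames(l_expr) <- samples
  mm <- data.frame(feature_id = c("mA", "mB"), mirna_id = c("mi1", "mi2"),
                   scc = c(-0.95, -0.8))
  lm <- data.frame(feature_id = c("lA", "lB"), mirna_id = c("mi1", "mi2"),
                   scc = c(-0.9, -0.75))
  uni <- sprintf("u%d", 1:25)
  t1 <- build_cerna_triplets(mm, lm, m_expr, l_expr, universe = uni)
  # relabel: swap row order everywhere
  t2 <- build_cerna_triplets(mm[2:1, ], lm[2:1, ],
                             m_expr[2:1, ], l_expr[2:1, ], universe = uni)
  expect_equal(t1, t2)
})

test_that("ceRNA network export types nodes and counts distinct ids", {
  tri <- data.frame(mrna_id = "m1", lncrna_id = "l1", mirna_ids = "mi1",
                    k_shared = 1, K_lncrna = 1, n_mrna = 1,
                    scc_mrna_mirna = -1, scc_lncrna_mirna = -1,
                    pcc_mrna_lncrna = 1, p_sponge = 0.01)
  net <- export_cerna_network(tri)
  expect_equal(net$counts$n_mrna, 1)
  expect_equal(net$counts$n_mirna, 1)
  expect_equal(net$counts$n_lncrna, 1)
  expect_equal(net$counts$n_edges, 3)   # m-mi, l-mi, l-m
  expect_equal(igraph::vcount(net$graph), 3)
  # empty triplet list gives empty valid files
  tmp <- tempfile(fileext = ".graphml")
  net0 <- export_cerna_network(tri[0, ], graphml_path = tmp)
  expect_equal(net0$counts$n_edges, 0)
  expect_true(file.exists(tmp))
})
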