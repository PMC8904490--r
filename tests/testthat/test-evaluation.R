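# Enrichment statistics, ground-truth expansion, method comparison,
# correlation and recovery metrics.

test_that("ground-truth expansion adds TF targets and keeps direct provenance", {
  direct <- data.frame(mirna_id = c("miR-a", "miR-b"), gene_id = c("TF1", "g9"))
  tf <- data.frame(tf_id = "TF1", target_id = c("g1", "g2", "g9"))
  gt <- expand_ground_truth(direct, tf)
  expect_setequal(paste(gt$mirna_id, gt$gene_id),
                  c("miR-a TF1", "miR-a g1", "miR-a g2", "miR-a g9", "miR-b g9"))
  expect_identical(gt$provenance[gt$mirna_id == "miR-a" & gt$gene_id == "g1"],
                   "tf_expanded")
  # gene that is not a TF: no expansion; a pair that is already direct stays direct
  expect_identical(gt$provenance[gt$mirna_id == "miR-b" & gt$gene_id == "g9"], "direct")
  direct2 <- rbind(direct, data.frame(mirna_id = "miR-a", gene_id = "g1"))
  gt2 <- expand_ground_truth(direct2, tf)
  expect_identical(gt2$provenance[gt2$mirna_id == "miR-a" & gt2$gene_id == "g1"],
                   "direct")
  expect_equal(sum(gt2$mirna_id == "miR-a" & gt2$gene_id == "g1"), 1)
})

test_that("hypergeometric upper tail matches enumeration on known cases", {
  expect_identical(hypergeom_upper(0, 5, 3, 10), 1)
  expect_equal(hypergeom_upper(4, 4, 5, 10), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_upper(2, 2, 2, 5), 1 / 10, tolerance = 1e-12)
  expect_error(hypergeom_upper(3, 2, 2, 5), "<=")
})

test_that("hypergeometric and Fisher match exhaustive enumeration for small universes", {
  for (N in c(4, 7, 11)) {
    for (K in 0:N) for (n in 0:N) for (k in max(0, K + n - N):min(n, K)) {
      expect_equal(hypergeom_upper(k, n, K, N), hyper_enum(k, n, K, N),
                   tolerance = 1e-10)
    }
  }
  set.seed(15)
  for (rep in 1:200) {
    cells <- as.integer(rmultinom(1, sample(2:20, 1), rep(1, 4)))
    expect_equal(fisher_two_sided(cells[1], cells[2], cells[3], cells[4]),
                 fisher_enum(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
  }
})

test_that("Fisher handles symmetric and degenerate tables", {
  expect_equal(fisher_two_sided(5, 5, 5, 5), 1)
  expect_equal(fisher_two_sided(3, 1, 1, 3), 34 / 70, tolerance = 1e-10)
  expect_equal(fisher_two_sided(0, 0, 3, 7), 1)   # zero row: single possible table
  expect_error(fisher_two_sided(-1, 2, 3, 4), "non-negative")
})

test_that("per-miRNA target enrichment applies the eligibility rule on computed targets", {
  universe <- paste0("g", 1:20)
  truth <- data.frame(mirna_id = c(rep("mA", 4), "mB"),
                      gene_id = c("g1", "g2", "g3", "g4", "g5"))
  edges <- data.frame(mirna_id = c(rep("mA", 4), rep("mB", 3), "mC"),
                      gene_id = c("g1", "g2", "g3", "g4", "g10", "g11", "g12", "g13"))
  res <- mirna_target_enrichment(edges, truth, universe)
  a <- res[res$subject_id == "mA", ]
  expect_true(a$eligible)
  expect_equal(a$p_value, hyper_enum(4, 4, 4, 20), tolerance = 1e-12)
  expect_true(a$significant)
  # mB has known targets, but none among its computed ones -> not eligible
  expect_false(res$eligible[res$subject_id == "mB"])
  expect_false(res$significant[res$subject_id == "mB"])
  expect_false(res$eligible[res$subject_id == "mC"])
  expect_equal(attr(res, "pct_significant"), 100)
  empty <- mirna_target_enrichment(edges[0, ], truth, universe)
  expect_equal(nrow(empty), 0)
})

test_that("oncogenic-miRNA Fisher enrichment detects planted overlap and is calibrated", {
  bg <- paste0("m", 1:200)
  onco <- paste0("m", 1:80)
  hit <- fisher_oncomirna_enrichment(paste0("m", 1:40), onco, bg)
  expect_lt(hit$p, 0.05)
  expect_equal(sum(hit$table), 200)
  expect_warning(deg <- fisher_oncomirna_enrichment(paste0("m", 1:5), "absent", bg),
                 "disjoint")
  expect_equal(deg$p, 1)
  set.seed(16)
  ps <- replicate(1000, {
    fisher_oncomirna_enrichment(sample(bg, 60), onco, bg)$p
  })
  frac <- mean(ps < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.07)
})

test_that("method comparison restricts to shared eligible miRNAs and is antisymmetric", {
  universe <- paste0("g", 1:30)
  truth <- data.frame(mirna_id = rep(c("m1", "m2", "m3"), each = 3),
                      gene_id = paste0("g", 1:9))
  ea <- data.frame(mirna_id = c("m1", "m1", "m2", "m3"), gene_id = c("g1", "g2", "g4", "g7"))
  eb <- data.frame(mirna_id = c("m1", "m2", "m3"), gene_id = c("g1", "g20", "g7"))
  ab <- suppressMessages(compare_methods(ea, eb, truth, universe))
  ba <- suppressMessages(compare_methods(eb, ea, truth, universe))
  expect_true(ab$verdict %in% c("a_wins", "b_wins", "draw"))
  expect_identical(ab$sig_a, ba$sig_b)
  expect_identical(ab$sig_b, ba$sig_a)
  if (ab$verdict == "a_wins") expect_identical(ba$verdict, "b_wins")
  same <- suppressMessages(compare_methods(ea, ea, truth, universe))
  expect_identical(same$verdict, "draw")
  disj <- data.frame(mirna_id = "m9", gene_id = "g25")
  expect_identical(suppressMessages(compare_methods(ea, disj, truth, universe))$verdict,
                   "not_comparable")
})

test_that("over-representation analysis ranks the exact term first and controls errors", {
  universe <- paste0("g", 1:50)
  gs <- paste0("g", 1:5)
  ann <- list(exact = gs, half = c("g1", "g2", "g20", "g21"),
              off = paste0("g", 30:40))
  res <- ora(gs, ann, universe)
  expect_identical(res$term[1], "exact")
  expect_true(res$significant[1])
  e0 <- ora(character(0), ann, universe)
  expect_true(all(e0$p_value == 1))
  set.seed(17)
  any_sig <- replicate(500, {
    g <- sample(universe, 8)
    a <- lapply(1:10, function(i) sample(universe, 10))
    names(a) <- paste0("t", 1:10)
    any(ora(g, a, universe)$significant)
  })
  expect_lte(mean(any_sig), 0.07)
})

test_that("CN-expression Spearman correlation handles monotone and degenerate input", {
  expr <- matrix(c(1:6, 6:1, rep(2, 6)), 3, 6, byrow = TRUE,
                 dimnames = list(c("up", "down", "flat"), paste0("s", 1:6)))
  cn <- matrix(rep(seq(0, 1, length.out = 6), 3), 3, 6, byrow = TRUE,
               dimnames = dimnames(expr))
  out <- cn_expression_correlation(rownames(expr), cn, expr)
  expect_equal(unname(out$rho["up"]), 1)
  expect_equal(unname(out$rho["down"]), -1)
  expect_true(is.na(out$rho["flat"]))
  expect_equal(out$median_rho, 0)
})

test_that("recovery metrics follow their definitions", {
  truth <- data.frame(mirna_id = paste0("m", 1:5), gene_id = paste0("g", 1:5), sign = "-")
  edges <- data.frame(mirna_id = paste0("m", c(1:4, 9)), gene_id = paste0("g", c(1:4, 9)),
                      sign = c(rep("negative", 4), "positive"))
  r <- recovery_metrics(edges, truth)
  expect_equal(r$precision, 0.8)
  expect_equal(r$recall, 0.8)
  expect_equal(r$sign_accuracy, 1)
  perfect <- data.frame(mirna_id = paste0("m", 1:5), gene_id = paste0("g", 1:5),
                        sign = "negative")
  expect_equal(unlist(recovery_metrics(perfect, truth)), c(precision = 1, recall = 1,
                                                           sign_accuracy = 1))
  none <- recovery_metrics(edges[0, ], truth)
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)
  expect_true(is.na(none$sign_accuracy))
})
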