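# miRNA prevalence filter, cis/trans annotation, methylation aggregation,
# predictor-set assembly.

test_that("miRNA prevalence filter keeps >=min_rpm in >=min_fraction of samples", {
  m <- rbind(keep40 = c(rep(0.02, 4), rep(0, 6)),   # 40% at 0.02 -> kept
             drop20 = c(rep(0.02, 2), rep(0, 8)),   # 20% -> dropped
             zero = rep(0, 10),
             high = rep(5, 10))
  colnames(m) <- paste0("s", 1:10)
  out <- filter_mirnas(expression_matrix(m, "rpm"), 0.01, 0.30)
  expect_setequal(rownames(out), c("keep40", "high"))

  m2 <- expression_matrix(matrix(c(rep(0.02, 29), rep(0, 71)), 1, 100,
                                 dimnames = list("m29", paste0("s", 1:100))), "rpm")
  expect_warning(out2 <- filter_mirnas(m2), "no miRNA")
  expect_equal(nrow(out2), 0)
  m3 <- expression_matrix(matrix(c(rep(0.02, 30), rep(0, 70)), 1, 100,
                                 dimnames = list("m30", paste0("s", 1:100))), "rpm")
  expect_equal(rownames(filter_mirnas(m3)), "m30")
})

test_that("cis/trans annotation partitions DE genes by region overlap", {
  feats <- features(data.frame(
    feature_id = c("gin", "gspan", "gout", "gother", "m_in", "m_out"),
    kind = c("gene", "gene", "gene", "gene", "mirna", "mirna"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr1", "chr2"),
    start = c(1500, 900, 5000, 100, 1200, 50),
    end = c(1800, 1100, 6000, 400, 1300, 100),
    strand = "+"))
  region <- list(region_id = "r", chrom = "chr1", start = 1000, end = 2000)
  de <- data.frame(gene_id = c("gin", "gspan", "gout", "gother", "ghost"),
                   is_de = TRUE)
  expect_warning(ann <- annotate_cis_trans(region, de, feats, c("m_in", "m_out")),
                 "absent from the feature annotation")
  expect_setequal(ann$cis_genes, c("gin", "gspan"))     # any-overlap rule
  expect_setequal(ann$trans_genes, c("gout", "gother"))
  expect_identical(ann$cis_mirnas, "m_in")              # no DE requirement on miRNAs
  expect_setequal(c(ann$cis_genes, ann$trans_genes),
                  setdiff(de$gene_id, "ghost"))         # exact partition
  ann2 <- suppressWarnings(annotate_cis_trans(region, de, feats, c("m_in", "m_out"),
                                              rule = "containment"))
  expect_identical(ann2$cis_genes, "gin")               # boundary-straddler now trans
  expect_true("gspan" %in% ann2$trans_genes)
})

test_that("methylation aggregates promoter probes (450K) or all probes (27K)", {
  feats <- features(data.frame(
    feature_id = c("gp", "gm"), kind = "gene", chrom = "chr1",
    start = c(10000, 50000), end = c(14000, 54000), strand = c("+", "-")))
  manifest <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "p5"),
    gene_id = c("gp", "gp", "gp", "gm", "gm"),
    position = c(9000, 9500, 20000, 54100, 40000))
  beta <- expression_matrix(matrix(c(0.2, 0.4, 0.9, 0.3, 0.5), 5, 1,
                                   dimnames = list(paste0("p", 1:5), "s1")), "beta")
  g450 <- gene_level_methylation(beta, manifest, feats, "p450k")
  expect_equal(unname(g450["gp", "s1"]), 0.3)     # mean of the two promoter probes
  # gm is on the minus strand: TSS = end; p4 at 54100 is 100 bp upstream -> in window
  expect_equal(unname(g450["gm", "s1"]), 0.3)
  # a gene whose only probes fall outside the window is missing
  man2 <- manifest[manifest$probe_id == "p3", ]
  b2 <- expression_matrix(beta["p3", , drop = FALSE], "beta")
  expect_true(is.na(gene_level_methylation(b2, man2, feats, "p450k")["gp", "s1"]))

  b27 <- expression_matrix(matrix(c(0.1, 0.2, 0.9), 3, 1,
                                  dimnames = list(c("q1", "q2", "q3"), "s1")), "beta")
  man27 <- data.frame(probe_id = c("q1", "q2", "q3"), gene_id = "gx",
                      position = c(1, 5000, 9000))
  g27 <- gene_level_methylation(b27, man27, platform = "p27k")
  expect_equal(unname(g27["gx", "s1"]), 0.4)
})

test_that("predictor assembly enforces eligibility, dedup and class bookkeeping", {
  samples <- paste0("s", 1:30)
  set.seed(8)
  gene_expr <- matrix(rnorm(5 * 30), 5, 30,
                      dimnames = list(c("t1", "cg1", "tfA", "tfB", "t2"), samples))
  mir_expr <- matrix(rnorm(2 * 30), 2, 30, dimnames = list(c("m1", "m2"), samples))
  cn <- matrix(rnorm(30), 1, 30, dimnames = list("t1", samples))
  meth <- matrix(runif(30), 1, 30, dimnames = list("t1", samples))
  tf <- data.frame(tf_id = c("tfA", "tfB", "cg1"), target_id = "t1",
                   confidence = c("A", "C", "A"))
  ann <- list(region_id = "r", cis_genes = "cg1", trans_genes = c("t1", "t2"),
              cis_mirnas = c("m1", "m2"))

  ps <- suppressMessages(assemble_predictors(ann, gene_expr, mir_expr, cn, meth, tf,
                                             tf_confidence_keep = c("A", "B")))
  expect_named(ps, c("t1", "t2"))
  p1 <- ps[["t1"]]
  # cg1 is both cis gene and grade-A TF of t1: one column, recorded cis_gene
  expect_equal(sum(names(p1$column_class) == "cg1"), 1)
  expect_identical(unname(p1$column_class["cg1"]), "cis_gene")
  expect_identical(unname(p1$column_class["tfA"]), "tf")
  expect_false("tfB" %in% names(p1$column_class))   # grade C filtered out
  expect_gte(sum(p1$column_class == "cis_mirna"), 1)
  expect_equal(sum(p1$column_class == "cn"), 1)
  expect_equal(sum(p1$column_class == "methylation"), 1)
  expect_identical(names(p1$response), rownames(p1$predictors))
  expect_identical(rownames(p1$predictors), samples)
  # t2 has no cn/meth rows: columns simply absent
  expect_false(any(ps[["t2"]]$column_class %in% c("cn", "methylation")))

  # a region without cis miRNAs emits nothing
  ann0 <- modifyList(ann, list(cis_mirnas = character(0)))
  expect_length(assemble_predictors(ann0, gene_expr, mir_expr, cn, meth, tf), 0)

  # constant predictor columns are dropped with a message
  ge2 <- gene_expr; ge2["cg1", ] <- 1
  expect_message(ps2 <- assemble_predictors(ann, ge2, mir_expr, cn, meth, NULL),
                 "constant")
  expect_false("cg1" %in% names(ps2[["t1"]]$column_class))
})

test_that("predictor sets round-trip through their TSV form", {
  co <- small_cohort()
  gene_expr <- normalized_log_expression(co$gene_counts)
  mir_expr <- log2(unclass(filter_mirnas(co$mirna_rpm)) + 1)
  ann <- list(region_id = "r1", cis_genes = co$roles$cis_genes$r1,
              trans_genes = co$roles$target_genes[1],
              cis_mirnas = co$roles$cis_mirnas$r1)
  cn <- feature_cn_matrix(co$features[co$features$feature_id == ann$trans_genes, ],
                          co$segments, colnames(gene_expr))
  ps <- suppressMessages(assemble_predictors(ann, gene_expr, mir_expr, cn,
                                             co$methylation, co$tf_table))[[1]]
  f <- tempfile(fileext = ".tsv")
  write_predictor_set(ps, f)
  back <- read_predictor_set(f)
  expect_identical(back$trans_gene, ps$trans_gene)
  expect_identical(back$region_id, ps$region_id)
  expect_equal(back$predictors, ps$predictors, tolerance = 1e-9)
  expect_equal(unname(back$response), unname(ps$response), tolerance = 1e-9)
  expect_identical(back$column_class, ps$column_class)
})
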