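# Solver oracles, CV penalty selection, stability accounting, edge
# extraction and the two-phase residual mode.

std_design <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  sweep(sweep(X, 2, colMeans(X)), 2, sqrt(colMeans(sweep(X, 2, colMeans(X))^2)), "/")
}

test_that("coefficients are exactly zero at and above lambda_max", {
  X <- std_design(60, 5, seed = 2)
  y <- rnorm(60); y <- y - mean(y)
  lmax <- max(abs(crossprod(X, y))) / 60
  B <- lasso_path(X, y, lambdas = c(2 * lmax, lmax))
  expect_identical(unname(B[1, ]), rep(0, 5))
  expect_identical(unname(B[2, ]), rep(0, 5))
})

test_that("orthonormal designs reproduce the soft-threshold closed form", {
  n <- 64
  X <- qr.Q(qr(matrix(rnorm(n * 4), n, 4))) * sqrt(n)
  colnames(X) <- paste0("x", 1:4)
  set.seed(3)
  y <- X %*% c(2, -1, 0.4, 0) + rnorm(n, 0, 0.2)
  y <- y - mean(y)
  z <- crossprod(X, y) / n
  for (lam in c(0.05, 0.3, 0.8)) {
    B <- lasso_path(X, y, lambdas = c(max(abs(z)), lam))
    expect_equal(unname(B[2, ]), as.numeric(sign(z) * pmax(abs(z) - lam, 0)),
                 tolerance = 1e-6)
  }
})

test_that("the unpenalized limit recovers least squares", {
  X <- std_design(50, 1, seed = 4)
  y <- 3 * X[, 1] + rnorm(50, 0, 0.5)
  y <- y - mean(y)
  B <- lasso_path(X, y, lambdas = c(max(abs(crossprod(X, y))) / 50, 0))
  expect_equal(unname(B[2, 1]), unname(coef(lm(y ~ X[, 1] - 1))), tolerance = 1e-8)
})

test_that("the path agrees with an independent solver on a random problem", {
  skip_if_not_installed("glmnet")
  n <- 80; p <- 8
  X <- std_design(n, p, seed = 6)
  set.seed(7)
  y <- X %*% c(1.5, -1, 0.5, rep(0, p - 3)) + rnorm(n)
  y <- y - mean(y)
  lmax <- max(abs(crossprod(X, y))) / n
  grid <- exp(seq(log(lmax), log(lmax * 1e-2), length.out = 30))
  ours <- lasso_path(X, y, lambdas = grid)
  g <- glmnet::glmnet(X, y, lambda = grid, standardize = FALSE, intercept = FALSE,
                      thresh = 1e-12)
  theirs <- t(as.matrix(g$beta))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("KKT conditions hold on refits and errors are raised for bad input", {
  X <- std_design(70, 6, seed = 8)
  set.seed(9)
  y <- X %*% c(2, -1, rep(0, 4)) + rnorm(70); y <- y - mean(y)
  lmax <- max(abs(crossprod(X, y))) / 70
  grid <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 50))
  B <- lasso_path(X, y, lambdas = grid)
  for (i in c(5, 20, 45))
    expect_lt(regmir:::.kkt_violation(X, y, B[i, ], grid[i]), 1e-5)
  # nonzero count never decreases along the descending grid here
  nz <- rowSums(abs(B) > 1e-9)
  expect_equal(nz[1], 0)
  expect_true(all(diff(nz) >= 0))
  expect_error(lasso_path(cbind(X, const = 1), y), "constant")
  Xb <- X; Xb[1, 1] <- NA
  expect_error(lasso_path(Xb, y), "non-finite")
})

test_that("CV lambda selection is deterministic, breaks ties upward and quiets noise", {
  X <- std_design(100, 10, seed = 10)
  set.seed(11)
  y <- rnorm(100)
  cfg <- stability_config(lambda_rule = "min", base_seed = 1)
  a <- cv_select_lambda(X, y, cfg, run_seed = 5)
  b <- cv_select_lambda(X, y, cfg, run_seed = 5)
  expect_identical(a$index, b$index)
  # identical CV error at the top of the grid (all-zero fits) -> larger lambda wins
  lmax <- max(abs(crossprod(scale(X), scale(y, scale = FALSE)))) / 100
  grid <- c(4 * lmax, 2 * lmax, exp(seq(log(lmax), log(lmax * 1e-3), length.out = 40)))
  cv <- cv_select_lambda(X, y, cfg, run_seed = 5, lambdas = grid)
  if (cv$cvm[1] == min(cv$cvm)) expect_identical(cv$index, 1L)

  hits_upper <- 0; none_selected <- 0
  for (s in 1:10) {
    cv <- cv_select_lambda(X, y, cfg, run_seed = s)
    hits_upper <- hits_upper + (cv$index <= length(cv$lambdas) / 2)
    std <- regmir:::.standardize(X)
    B <- lasso_path(std$X, y - mean(y), lambdas = cv$lambdas)
    none_selected <- none_selected + (sum(abs(B[cv$index, ]) > 1e-9) == 0)
  }
  expect_gte(hits_upper, 8)
  expect_gte(none_selected, 8)
})

test_that("stability selection keeps planted predictors and refuses decoys", {
  n <- 150
  set.seed(12)
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(sprintf("s%03d", 1:n),
                              c("mirA", "mirB", "cg", "cn", "me", "tf")))
  y <- -0.9 * scale(X[, "mirA"])[, 1] + 0.8 * scale(X[, "cg"])[, 1] + rnorm(n, 0, 0.4)
  ps <- structure(list(region_id = "r1", trans_gene = "g1",
                       response = setNames(y, rownames(X)), predictors = X,
                       column_class = setNames(c("cis_mirna", "cis_mirna", "cis_gene",
                                                 "cn", "methylation", "tf"),
                                               colnames(X))),
                  class = "predictor_set")
  hits <- 0; rejections <- 0
  for (bs in 1:5) {
    rec <- stability_select(ps, stability_config(n_runs = 50, keep_threshold = 35,
                                                 base_seed = bs * 1000))
    expect_lt(attr(rec, "max_kkt"), 1e-5)
    a <- rec[rec$predictor == "mirA", ]
    hits <- hits + (nrow(a) == 1 && a$selection_count >= 35 && a$sign == "negative")
    b <- rec[rec$predictor == "mirB", ]
    rejections <- rejections + (nrow(b) == 0 || b$selection_count < 35)
  }
  expect_gte(hits, 4)
  expect_gte(rejections, 4)
})

test_that("stability selection is deterministic given base_seed", {
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
  cfg <- stability_config(n_runs = 25, keep_threshold = 18, base_seed = 77)
  expect_identical(stability_select(ps, cfg), stability_select(ps, cfg))
})

test_that("edge extraction enforces the threshold, class restriction and merge rule", {
  rec <- data.frame(
    region_id = c("r1", "r1", "r1", "r2", "r1"),
    trans_gene = c("gy", "gy", "gz", "gy", "gy"),
    predictor = c("mx", "m69", "mx", "mx", "tfq"),
    predictor_class = c("cis_mirna", "cis_mirna", "cis_mirna", "cis_mirna", "tf"),
    selection_count = c(85L, 69L, 70L, 72L, 100L),
    mean_coef = c(-0.4, -0.2, -0.3, -0.1, 0.9),
    sign = c("negative", "negative", "negative", "negative", "positive"))
  cfg <- stability_config()
  edges <- extract_edges(rec, cfg)
  expect_setequal(paste(edges$mirna_id, edges$gene_id), c("mx gy", "mx gz"))
  # count exactly 70 kept, 69 dropped, tf class never an edge
  expect_true("mx gz" %in% paste(edges$mirna_id, edges$gene_id))
  expect_false("m69 gy" %in% paste(edges$mirna_id, edges$gene_id))
  expect_false(any(edges$mirna_id == "tfq"))
  # duplicate pair across regions: union of regions, max count, its coefficient
  e <- edges[edges$gene_id == "gy", ]
  expect_identical(e$region_ids, "r1,r2")
  expect_identical(e$selection_count, 85L)
  expect_equal(e$mean_coef, -0.4)
  expect_identical(e$sign, "negative")
})

test_that("two-phase mode separates transcriptional and miRNA signal", {
  n <- 150
  set.seed(13)
  cn <- rnorm(n)
  mir <- rnorm(n)
  y <- 1 * scale(cn)[, 1] + 1 * scale(mir)[, 1] + rnorm(n, 0, 0.5)
  X <- cbind(cnx = cn, mirx = mir, noise = rnorm(n))
  rownames(X) <- sprintf("s%03d", 1:n)
  ps <- structure(list(region_id = "r", trans_gene = "g",
                       response = setNames(y, rownames(X)), predictors = X,
                       column_class = setNames(c("cn", "cis_mirna", "cis_mirna"),
                                               colnames(X))),
                  class = "predictor_set")
  cfg <- stability_config(n_runs = 40, keep_threshold = 28, base_seed = 5,
                          two_phase = TRUE)
  expect_error(two_phase_select(ps, stability_config()), "two_phase")
  rec <- two_phase_select(ps, cfg)
  expect_true(all(rec$phase[rec$predictor == "cnx"] == 1))
  m <- rec[rec$predictor == "mirx" & rec$phase == 2, ]
  expect_equal(nrow(m), 1)
  expect_gte(m$selection_count, 28)

  # without transcriptional covariates phase 2 equals single-phase on miRNAs
  ps2 <- ps
  ps2$predictors <- X[, c("mirx", "noise")]
  ps2$column_class <- ps$column_class[c("mirx", "noise")]
  expect_message(rec2 <- two_phase_select(ps2, cfg), "no transcriptional")
  direct <- stability_select(ps2, cfg)
  expect_equal(rec2[names(direct)], direct, ignore_attr = TRUE)
})
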