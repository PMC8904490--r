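# Stability-selection LASSO: per trans gene, the L1 regression is repeated
# n_runs times; each run re-draws the cross-validation folds, picks the
# penalty giving the simplest model at the minimal CV error, and refits on
# the full data. Predictors selected in at least keep_threshold runs form
# the consensus; cis-miRNA consensus predictors become signed edges.
#
# Randomness across runs comes solely from the seeded fold assignment: the
# data and the lambda grid are fixed, so the full-data path is computed once
# and each run only reads off the coefficients at its own lambda*.

#' Stability-selection configuration
#'
#' Defaults encode the selection rule: 100 runs, keep predictors selected at
#' least 70 times, 10-fold cross-validation, penalty chosen as the largest
#' lambda attaining the minimal CV error ("simplest model at the minimum").
#'
#' @param n_runs number of repeated CV+fit runs
#' @param keep_threshold minimum selection count to keep a predictor
#' @param n_folds CV folds
#' @param lambda_grid_size points on the log-spaced lambda grid
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max
#' @param lambda_rule `"one_se"` (largest lambda within one standard error of
#'   the minimal CV error; the default reading of "the simplest model at the
#'   minimum") or `"min"` (largest lambda attaining the minimum exactly)
#' @param standardize standardize predictors per run (recommended; predictor
#'   classes live on different scales)
#' @param zero_tol coefficients with |beta| above this count as selected
#' @param base_seed seed; run r uses base_seed + r
#' @param two_phase enable the two-phase residual mode (see
#'   [two_phase_select()])
#' @return config list
#' @export
stability_config <- function(n_runs = 100L, keep_threshold = 70L, n_folds = 10L,
                             lambda_grid_size = 100L, lambda_min_ratio = 1e-3,
                             lambda_rule = c("one_se", "min"), standardize = TRUE,
                             zero_tol = 1e-9, base_seed = 1L, two_phase = FALSE) {
  lambda_rule <- match.arg(lambda_rule)
  if (!.is_count(keep_threshold) || !.is_count(n_runs) || keep_threshold > n_runs)
    .stopf("keep_threshold must be an integer in [1, n_runs]")
  if (!.is_count(n_folds) || n_folds < 2) .stopf("n_folds must be >= 2")
  if (!.is_prob(lambda_min_ratio)) .stopf("lambda_min_ratio must be in (0,1)")
  list(n_runs = as.integer(n_runs), keep_threshold = as.integer(keep_threshold),
       n_folds = as.integer(n_folds), lambda_grid_size = as.integer(lambda_grid_size),
       lambda_min_ratio = lambda_min_ratio, lambda_rule = lambda_rule,
       standardize = isTRUE(standardize), zero_tol = zero_tol,
       base_seed = as.integer(base_seed), two_phase = isTRUE(two_phase))
}

## population standardization: mean 0, sum of squares == n per column
.standardize <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, "-")
  s <- sqrt(colSums(Xc^2) / n)
  ok <- s > 1e-12
  Xs <- sweep(Xc[, ok, drop = FALSE], 2, s[ok], "/")
  list(X = Xs, mu = mu, s = s, ok = ok)
}

#' LASSO coefficient path by coordinate descent
#'
#' @param X predictor matrix, columns standardized (mean 0, mean square 1)
#' @param y centered response
#' @param lambdas descending penalty grid; computed from
#'   `lambda_max = max|X'y|/n` when NULL
#' @param nlambda,lambda_min_ratio grid shape when `lambdas` is NULL
#' @param tol convergence tolerance on the maximum coefficient change
#' @return coefficient matrix (grid x predictors) with the grid as an
#'   attribute `"lambdas"`
#' @export
lasso_path <- function(X, y, lambdas = NULL, nlambda = 100L, lambda_min_ratio = 1e-3,
                       tol = 1e-7) {
  if (!all(is.finite(X)) || !all(is.finite(y))) .stopf("non-finite values in X or y")
  if (any(apply(X, 2, stats::sd) < 1e-12))
    .stopf("constant predictor column reached the solver; drop it upstream")
  n <- nrow(X)
  if (is.null(lambdas)) {
    lmax <- max(abs(crossprod(X, y))) / n
    lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
  }
  B <- .lasso_path_cd(X, as.numeric(y), as.numeric(lambdas), tol, 100000L)
  out <- t(B)
  dimnames(out) <- list(NULL, colnames(X))
  attr(out, "lambdas") <- as.numeric(lambdas)
  out
}

## max KKT violation of a lasso solution (standardized X, centered y)
.kkt_violation <- function(X, y, beta, lambda) {
  n <- nrow(X)
  g <- as.numeric(crossprod(X, y - X %*% beta)) / n
  act <- abs(beta) > 0
  v <- 0
  if (any(act)) v <- max(abs(g[act] - lambda * sign(beta[act])))
  if (any(!act)) v <- max(v, max(pmax(abs(g[!act]) - lambda, 0)))
  v
}

#' Select the penalty by K-fold cross-validation
#'
#' Folds are assigned by a seeded shuffle. Under the `"min"` rule the
#' returned lambda is the largest one attaining the minimal mean CV error
#' (ties break toward the sparser model); `"one_se"` returns the largest
#' lambda within one standard error of the minimum.
#'
#' @param X raw predictor matrix (no constant columns)
#' @param y response
#' @param cfg [stability_config()]
#' @param run_seed seed for the fold shuffle
#' @param lambdas optional fixed grid (computed from the full data when NULL)
#' @return list(lambda, index, cvm, cvse, lambdas)
#' @export
cv_select_lambda <- function(X, y, cfg = stability_config(), run_seed = 1L,
                             lambdas = NULL) {
  n <- nrow(X)
  if (n < cfg$n_folds) .stopf("need at least n_folds samples")
  std <- .standardize(X)
  yc <- y - mean(y)
  if (is.null(lambdas)) {
    lmax <- max(abs(crossprod(std$X, yc))) / n
    lambdas <- exp(seq(log(lmax), log(lmax * cfg$lambda_min_ratio),
                       length.out = cfg$lambda_grid_size))
  }
  k <- cfg$n_folds
  if (floor(n / k) < 2) {
    k <- max(2L, floor(n / 2))
    .warnf("fold size below 2; reducing n_folds to %d", k)
  }
  fold <- .with_seed(as.integer(run_seed), sample(rep(seq_len(k), length.out = n)))
  cvres <- .cv_path_mse(X, as.numeric(y), as.numeric(lambdas),
                        as.integer(fold), as.integer(k))
  fold_mse <- cvres$fold_mse
  cvm <- as.numeric((as.numeric(cvres$fold_n) / n) %*% fold_mse)
  cvse <- apply(fold_mse, 2, stats::sd) / sqrt(k)
  idx <- if (cfg$lambda_rule == "min") {
    which(cvm <= min(cvm))[1]          # grid descends: first hit = largest lambda
  } else {
    im <- which.min(cvm)
    which(cvm <= cvm[im] + cvse[im])[1]
  }
  list(lambda = lambdas[idx], index = idx, cvm = cvm, cvse = cvse, lambdas = lambdas)
}

#' Stability selection for one predictor set
#'
#' Runs `n_runs` seeded CV rounds; in run r (seed `base_seed + r`) the
#' penalty lambda* is chosen by [cv_select_lambda()] and the full-data fit
#' at lambda* defines the run's selected predictors (|coefficient| >
#' `zero_tol`). Counts and mean coefficients (standardized scale, over the
#' runs where selected) are aggregated. Deterministic given `base_seed`.
#'
#' The returned records carry attribute `"max_kkt"`: the largest KKT
#' residual over the distinct full-data refits used.
#'
#' @param ps predictor set from [assemble_predictors()]
#' @param cfg [stability_config()]
#' @return data.frame region_id, trans_gene, predictor, predictor_class,
#'   selection_count, mean_coef, sign (one row per predictor ever selected;
#'   zero rows is a valid outcome)
#' @export
stability_select <- function(ps, cfg = stability_config()) {
  X <- ps$predictors
  y <- as.numeric(ps$response)
  n <- nrow(X)
  if (n <= cfg$n_folds) .stopf("need more samples than folds")
  std <- .standardize(X)
  yc <- y - mean(y)
  lmax <- max(abs(crossprod(std$X, yc))) / n
  lambdas <- exp(seq(log(lmax), log(lmax * cfg$lambda_min_ratio),
                     length.out = cfg$lambda_grid_size))
  full_B <- .lasso_path_cd(std$X, yc, lambdas, 1e-7, 100000L)  # p x L
  counts <- integer(ncol(std$X))
  coef_sum <- numeric(ncol(std$X))
  used_idx <- integer(0)
  for (r in seq_len(cfg$n_runs)) {
    cv <- cv_select_lambda(X, y, cfg, run_seed = cfg$base_seed + r, lambdas = lambdas)
    b <- full_B[, cv$index]
    sel <- abs(b) > cfg$zero_tol
    counts <- counts + sel
    coef_sum <- coef_sum + ifelse(sel, b, 0)
    used_idx <- union(used_idx, cv$index)
  }
  kkt <- if (length(used_idx))
    max(vapply(used_idx, function(i) .kkt_violation(std$X, yc, full_B[, i], lambdas[i]),
               numeric(1))) else 0
  keep <- counts > 0
  ids <- colnames(std$X)[keep]
  if (!length(ids)) {
    out <- data.frame(region_id = character(0), trans_gene = character(0),
                      predictor = character(0), predictor_class = character(0),
                      selection_count = integer(0), mean_coef = numeric(0),
                      sign = character(0), stringsAsFactors = FALSE)
    attr(out, "max_kkt") <- kkt
    return(out)
  }
  mean_coef <- ifelse(counts[keep] > 0, coef_sum[keep] / counts[keep], 0)
  out <- data.frame(region_id = ps$region_id, trans_gene = ps$trans_gene,
                    predictor = ids,
                    predictor_class = unname(ps$column_class[ids]),
                    selection_count = counts[keep],
                    mean_coef = mean_coef,
                    sign = ifelse(mean_coef >= 0, "positive", "negative"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$selection_count, out$predictor), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "max_kkt") <- kkt
  out
}

#' Two-phase residual stability selection
#'
#' Phase 1 runs stability selection of the response on the transcriptional
#' covariates only (cis genes, copy number, methylation, TFs); the consensus
#' predictors (selection count >= `keep_threshold`) are refit by least
#' squares and the residual becomes the phase-2 response, regressed on the
#' cis miRNA columns alone. When phase 1 selects nothing the residual is the
#' centered response (logged), so phase 2 coincides with single-phase
#' selection restricted to miRNAs.
#'
#' @param ps predictor set
#' @param cfg [stability_config()] with `two_phase = TRUE`
#' @return records as in [stability_select()], with an extra `phase` column
#' @export
two_phase_select <- function(ps, cfg) {
  if (!isTRUE(cfg$two_phase)) .stopf("two_phase_select requires cfg$two_phase = TRUE")
  covar <- names(ps$column_class)[ps$column_class != "cis_mirna"]
  mir <- names(ps$column_class)[ps$column_class == "cis_mirna"]
  y <- as.numeric(ps$response)
  phase1 <- NULL
  resid <- y - mean(y)
  if (length(covar) >= 1) {
    ps1 <- ps
    ps1$predictors <- ps$predictors[, covar, drop = FALSE]
    ps1$column_class <- ps$column_class[covar]
    phase1 <- stability_select(ps1, cfg)
    consensus <- phase1$predictor[phase1$selection_count >= cfg$keep_threshold]
    if (length(consensus)) {
      Xc <- cbind(1, ps$predictors[, consensus, drop = FALSE])
      fit <- stats::lm.fit(Xc, y)
      resid <- fit$residuals
    } else {
      message("phase-1 consensus empty; phase-2 response is the centered response")
    }
    phase1$phase <- rep(1L, nrow(phase1))
  } else {
    message("no transcriptional covariates; phase-2 response is the centered response")
  }
  ps2 <- ps
  ps2$response <- stats::setNames(resid, names(ps$response))
  ps2$predictors <- ps$predictors[, mir, drop = FALSE]
  ps2$column_class <- ps$column_class[mir]
  phase2 <- stability_select(ps2, cfg)
  phase2$phase <- rep(2L, nrow(phase2))
  out <- rbind(phase1, phase2)
  rownames(out) <- NULL
  attr(out, "max_kkt") <- max(attr(phase2, "max_kkt") %||% 0,
                              if (!is.null(phase1)) attr(phase1, "max_kkt") else 0)
  out
}

#' Extract miRNA -> gene edges from selection records
#'
#' Keeps cis-miRNA records with selection count >= `keep_threshold`; a pair
#' reaching the threshold in several regions yields one edge with the union
#' of region ids, the maximum count, and the coefficient of the
#' maximum-count record. Records of any other predictor class never become
#' edges.
#'
#' @param records row-bound output of [stability_select()] across all
#'   regions and trans genes
#' @param cfg [stability_config()]
#' @return data.frame mirna_id, gene_id, region_ids (comma-joined),
#'   selection_count, mean_coef, sign
#' @export
extract_edges <- function(records, cfg = stability_config()) {
  empty <- data.frame(mirna_id = character(0), gene_id = character(0),
                      region_ids = character(0), selection_count = integer(0),
                      mean_coef = numeric(0), sign = character(0))
  if (is.null(records) || !nrow(records)) return(empty)
  r <- records[records$predictor_class == "cis_mirna" &
                 records$selection_count >= cfg$keep_threshold, , drop = FALSE]
  if (!nrow(r)) return(empty)
  key <- paste(r$predictor, r$trans_gene, sep = "\r")
  out <- do.call(rbind, lapply(split(r, key), function(d) {
    top <- d[which.max(d$selection_count), ]
    data.frame(mirna_id = top$predictor, gene_id = top$trans_gene,
               region_ids = paste(sort(unique(d$region_id)), collapse = ","),
               selection_count = max(d$selection_count),
               mean_coef = top$mean_coef,
               sign = ifelse(top$mean_coef >= 0, "positive", "negative"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
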