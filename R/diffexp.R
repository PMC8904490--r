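# Region-wise differential expression from raw counts.
#
# The engine is the classic count-data stack: TMM normalization factors, a
# common negative-binomial dispersion estimated by conditional maximum
# likelihood on library-size-equalized pseudo-counts, and an exact
# conditional test on the per-group sums. Statistical behaviour (type-I
# error, power, sign conventions), not numerical identity with any
# particular implementation, is the contract. BH adjustment is applied per
# region, the unit at which DE gene lists feed the downstream steps.

#' Differential-expression configuration
#'
#' Defaults encode the pipeline's DE filter: |log2 fold change| >= 1 and
#' BH-adjusted p < 0.05.
#'
#' @param method `"nb_exact"` (NB exact conditional test) or `"wilcoxon"`
#'   (distribution-free rank-sum fallback on log-normalized counts)
#' @param de_lfc_min minimum absolute log2 fold change
#' @param de_alpha adjusted-p cutoff
#' @param min_group_size smallest group size for a region to be testable
#' @param prior_count prior added to group means for logFC stabilization
#' @return config list
#' @export
de_config <- function(method = c("nb_exact", "wilcoxon"), de_lfc_min = 1,
                      de_alpha = 0.05, min_group_size = 3L, prior_count = 0.5) {
  method <- match.arg(method)
  if (!.is_prob(de_alpha)) .stopf("de_alpha must be in (0,1)")
  if (!.is_count(min_group_size) || min_group_size < 2) .stopf("min_group_size must be >= 2")
  list(method = method, de_lfc_min = de_lfc_min, de_alpha = de_alpha,
       min_group_size = as.integer(min_group_size), prior_count = prior_count)
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors against a reference sample (the one whose
#' upper quartile of library-size-scaled counts is closest to the mean upper
#' quartile). Per sample, M = log2 ratio of scaled counts vs the reference
#' and A = average log2 abundance over genes positive in both; the central
#' 40% of M (30% trimmed each tail) intersected with the central 90% of A
#' (5% each tail) is averaged with inverse-variance (delta-method) weights.
#' Factors are rescaled to geometric mean 1.
#'
#' @param counts raw-count matrix (genes x samples)
#' @return named numeric vector of factors, one per sample
#' @export
tmm_factors <- function(counts) {
  if (ncol(counts) < 2) .stopf("TMM needs at least 2 samples")
  libs <- colSums(counts)
  if (any(libs <= 0)) .stopf("every sample needs a positive library size")
  uq <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(s) {
    if (s == ref) return(1)
    y <- counts[, s]; yr <- counts[, ref]
    keep <- y > 0 & yr > 0
    if (!any(keep)) .stopf("sample %s shares no positive gene with the reference", colnames(counts)[s])
    y <- y[keep]; yr <- yr[keep]
    Ns <- libs[s]; Nr <- libs[ref]
    M <- log2((y / Ns) / (yr / Nr))
    A <- 0.5 * log2((y / Ns) * (yr / Nr))
    w <- (Ns - y) / (Ns * y) + (Nr - yr) / (Nr * yr)
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    n <- length(M)
    if (!n) return(1)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep2)) return(1)
    fval <- 2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
    if (!is.finite(fval) || abs(log2(fval)) < 1e-6) 1 else fval
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

## counts scaled to a common effective library size (geometric mean)
.pseudo_counts <- function(counts, factors) {
  eff <- colSums(counts) * factors
  geo <- exp(mean(log(eff)))
  sweep(counts, 2, geo / eff, "*")
}

## conditional NB log-likelihood of a common dispersion, summed over groups;
## pseudo-counts treated as continuous via lgamma
.cond_loglik <- function(pseudo, groups, phi) {
  r <- 1 / phi
  ll <- 0
  for (g in unique(groups)) {
    y <- pseudo[, groups == g, drop = FALSE]
    n <- ncol(y)
    z <- rowSums(y)
    keep <- z > 0
    if (!any(keep)) next
    y <- y[keep, , drop = FALSE]; z <- z[keep]
    ll <- ll + sum(rowSums(lgamma(y + r))) - nrow(y) * n * lgamma(r) +
      nrow(y) * lgamma(n * r) - sum(lgamma(z + n * r))
  }
  ll
}

#' Estimate a common NB dispersion by conditional maximum likelihood
#'
#' Maximizes the conditional log-likelihood of a single dispersion shared by
#' all genes, on pseudo-counts equalized to a common effective library size,
#' over a log-spaced grid refined by [stats::optimize()]. Returns 0 when the
#' likelihood is maximized at the Poisson boundary.
#'
#' @param counts raw-count matrix
#' @param groups group label per sample (two groups)
#' @param factors optional TMM factors (computed if missing)
#' @return dispersion estimate phi >= 0
#' @export
estimate_common_dispersion <- function(counts, groups, factors = NULL) {
  if (all(counts == 0)) .stopf("all-zero count matrix")
  factors <- factors %||% tmm_factors(counts)
  pseudo <- .pseudo_counts(counts, factors)
  obj <- function(lphi) .cond_loglik(pseudo, groups, 10^lphi)
  grid <- seq(-6, log10(5), length.out = 25)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(obj, interval = c(lo, hi), maximum = TRUE, tol = 1e-4)
  if (obj(-8) >= opt$objective - 1e-8 || opt$maximum <= grid[1] + 0.05) return(0)
  10^opt$maximum
}

#' NB exact conditional test per gene
#'
#' Counts are scaled to a common effective library size; per gene, the split
#' of the (rounded) pseudo-count total between the two groups is tested
#' against its conditional distribution under a common-dispersion NB model
#' (binomial when `dispersion = 0`). The two-sided p-value is the sum of the
#' probabilities of all splits at most as probable as the observed one (with
#' a 1 + 1e-7 slack factor for floating-point ties). logFC is
#' log2((mean_A + prior)/(mean_B + prior)) on the normalized scale,
#' group A vs group B.
#'
#' @param counts raw-count matrix
#' @param groups two-level factor/character vector per sample; the first
#'   level encountered is group A (numerator)
#' @param dispersion common NB dispersion phi
#' @param factors optional TMM factors
#' @param prior_count logFC prior
#' @return data.frame gene_id, logFC, p_value
#' @export
exact_test <- function(counts, groups, dispersion, factors = NULL, prior_count = 0.5) {
  factors <- factors %||% tmm_factors(counts)
  lv <- if (is.factor(groups)) levels(groups) else unique(as.character(groups))
  if (length(lv) != 2) .stopf("exact_test needs exactly two groups")
  pseudo <- .pseudo_counts(counts, factors)
  ia <- which(groups == lv[1]); ib <- which(groups == lv[2])
  na <- length(ia); nb <- length(ib)
  sa <- rowSums(pseudo[, ia, drop = FALSE])
  sb <- rowSums(pseudo[, ib, drop = FALSE])
  a_obs <- round(sa); b_obs <- round(sb)
  p <- vapply(seq_len(nrow(counts)), function(g) {
    Tg <- a_obs[g] + b_obs[g]
    if (Tg == 0) return(1)
    a <- 0:Tg
    if (dispersion <= 0) {
      lw <- stats::dbinom(a, Tg, na / (na + nb), log = TRUE)
    } else {
      ra <- na / dispersion; rb <- nb / dispersion
      lw <- lgamma(a + ra) - lgamma(a + 1) - lgamma(ra) +
        lgamma(Tg - a + rb) - lgamma(Tg - a + 1) - lgamma(rb)
      lw <- lw - max(lw)
      lw <- lw - log(sum(exp(lw)))
    }
    obs <- lw[a_obs[g] + 1]
    min(1, sum(exp(lw)[lw <= obs + log1p(1e-7)]))
  }, numeric(1))
  lfc <- log2((sa / na + prior_count) / (sb / nb + prior_count))
  data.frame(gene_id = rownames(counts), logFC = lfc, p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

## rank-sum fallback on log2 normalized counts
.wilcoxon_test <- function(counts, groups, factors, prior_count) {
  lv <- if (is.factor(groups)) levels(groups) else unique(as.character(groups))
  pseudo <- .pseudo_counts(counts, factors)
  ia <- which(groups == lv[1]); ib <- which(groups == lv[2])
  ln <- log2(pseudo + prior_count)
  p <- vapply(seq_len(nrow(counts)), function(g) {
    suppressWarnings(stats::wilcox.test(ln[g, ia], ln[g, ib], exact = TRUE)$p.value)
  }, numeric(1))
  sa <- rowSums(pseudo[, ia, drop = FALSE]); sb <- rowSums(pseudo[, ib, drop = FALSE])
  lfc <- log2((sa / length(ia) + prior_count) / (sb / length(ib) + prior_count))
  data.frame(gene_id = rownames(counts), logFC = lfc, p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Region-wise differential expression
#'
#' Tests every gene between the region's aberrated and non-aberrated sample
#' groups (aberrated = group A, so positive logFC means higher expression in
#' aberrated samples), BH-adjusts within the region and applies the DE
#' filter |logFC| >= `de_lfc_min` and adjusted p < `de_alpha`. Regions whose
#' smaller group is below `min_group_size` are skipped (zero rows, warning),
#' not failed.
#'
#' @param region_id region identifier (carried through to the results)
#' @param status named status vector from [assign_status()]
#' @param counts raw-count matrix (genes x samples; columns must cover the
#'   status samples)
#' @param cfg [de_config()]
#' @param factors optional TMM factors for `counts`
#' @param dispersion optional fixed dispersion (estimated when NULL)
#' @return data.frame region_id, gene_id, logFC, p_value, adj_p, is_de,
#'   sorted by adj_p
#' @export
run_region_de <- function(region_id, status, counts, cfg = de_config(),
                          factors = NULL, dispersion = NULL) {
  samples <- intersect(colnames(counts), names(status))
  status <- status[samples]
  counts <- counts[, samples, drop = FALSE]
  groups <- ifelse(status == "aberrated", "aberrated", "non_aberrated")
  n1 <- sum(groups == "aberrated"); n0 <- sum(groups == "non_aberrated")
  empty <- data.frame(region_id = character(0), gene_id = character(0),
                      logFC = numeric(0), p_value = numeric(0),
                      adj_p = numeric(0), is_de = logical(0))
  if (min(n1, n0) < cfg$min_group_size) {
    .warnf("region %s skipped: group sizes %d aberrated / %d non_aberrated below min_group_size %d",
           region_id, n1, n0, cfg$min_group_size)
    return(empty)
  }
  groups <- factor(groups, levels = c("aberrated", "non_aberrated"))
  factors <- factors %||% tmm_factors(counts)
  res <- if (cfg$method == "nb_exact") {
    phi <- dispersion %||% estimate_common_dispersion(counts, groups, factors)
    exact_test(counts, groups, phi, factors, cfg$prior_count)
  } else {
    .wilcoxon_test(counts, groups, factors, cfg$prior_count)
  }
  res$adj_p <- stats::p.adjust(res$p_value, method = "BH")
  res$is_de <- abs(res$logFC) >= cfg$de_lfc_min & res$adj_p < cfg$de_alpha
  res <- cbind(region_id = region_id, res, stringsAsFactors = FALSE)
  res <- res[order(res$adj_p, res$p_value, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
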