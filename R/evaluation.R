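# Evaluation statistics for inferred miRNA-gene networks: ground-truth
# expansion through TF targets, hypergeometric target enrichment with
# eligible/significant bookkeeping, Fisher enrichment of oncogenic miRNAs,
# pairwise method comparison, generic over-representation analysis, copy
# number vs expression correlation, and planted-truth recovery metrics.

#' Expand ground-truth miRNA-gene pairs through TF targets
#'
#' For each direct pair (m, g) where g is a TF with known targets, every
#' (m, target-of-g) pair is added with provenance `tf_expanded` -- an
#' inferred edge to an indirect (downstream) target is still a hit. A pair
#' that is both direct and expanded keeps the `direct` tag.
#'
#' @param direct_pairs data.frame mirna_id, gene_id
#' @param tf_table TF interaction table (tf_id, target_id)
#' @return data.frame mirna_id, gene_id, provenance
#' @export
expand_ground_truth <- function(direct_pairs, tf_table) {
  direct <- unique(data.frame(mirna_id = as.character(direct_pairs$mirna_id),
                              gene_id = as.character(direct_pairs$gene_id),
                              stringsAsFactors = FALSE))
  direct$provenance <- "direct"
  is_tf <- direct$gene_id %in% tf_table$tf_id
  exp_list <- lapply(which(is_tf), function(i) {
    tg <- tf_table$target_id[tf_table$tf_id == direct$gene_id[i]]
    if (!length(tg)) return(NULL)
    data.frame(mirna_id = direct$mirna_id[i], gene_id = tg,
               provenance = "tf_expanded", stringsAsFactors = FALSE)
  })
  out <- rbind(direct, do.call(rbind, exp_list))
  out <- out[order(out$provenance), , drop = FALSE]  # direct sorts first, wins dedup
  out <- out[!duplicated(out[c("mirna_id", "gene_id")]), , drop = FALSE]
  out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) when drawing `n` from a universe of `N` containing `K`
#' successes; computed in log space via [stats::phyper()].
#'
#' @param k observed overlap
#' @param n draws
#' @param K successes in the universe
#' @param N universe size
#' @return p-value in \[0, 1\]
#' @export
hypergeom_upper <- function(k, n, K, N) {
  if (k < 0 || n < 0 || K < 0 || k > n || n > N || K > N)
    .stopf("hypergeom_upper: need 0 <= k <= n <= N and K <= N")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Sum of the probabilities, over all tables with the observed margins, that
#' do not exceed the observed table's probability (standard float-tie slack).
#'
#' @param a,b,c,d non-negative integer cells, row-wise
#' @return p-value in \[0, 1\]
#' @export
fisher_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    .stopf("fisher_two_sided needs non-negative integer cells")
  stats::fisher.test(matrix(cells, 2, 2, byrow = TRUE))$p.value
}

#' Per-miRNA hypergeometric target enrichment
#'
#' For each miRNA with inferred targets: n = inferred targets in the
#' universe, K = the miRNA's known targets in the universe, k = overlap,
#' N = universe size. A miRNA is eligible iff at least one of its inferred
#' targets is a known target (k >= 1); significant iff eligible and
#' p < alpha. miRNAs with no inferred target inside the universe are skipped
#' (logged).
#'
#' @param edges edge table (mirna_id, gene_id)
#' @param truth ground-truth pairs (mirna_id, gene_id), e.g. from
#'   [expand_ground_truth()]
#' @param universe gene-id universe of the test
#' @param alpha significance cutoff
#' @return data.frame subject_id, k, n, K, N, p_value, eligible, significant;
#'   attribute `"pct_significant"` holds 100 * significant/eligible
#' @export
mirna_target_enrichment <- function(edges, truth, universe, alpha = 0.05) {
  if (!length(universe)) .stopf("empty universe")
  universe <- unique(universe)
  N <- length(universe)
  empty <- data.frame(subject_id = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p_value = numeric(0),
                      eligible = logical(0), significant = logical(0))
  if (is.null(edges) || !nrow(edges)) {
    attr(empty, "pct_significant") <- NA_real_
    return(empty)
  }
  out <- do.call(rbind, lapply(split(edges$gene_id, edges$mirna_id), function(tg) {
    tg <- intersect(unique(tg), universe)
    data.frame(n = length(tg), stringsAsFactors = FALSE,
               k = NA_integer_, K = NA_integer_, genes = I(list(tg)))
  }))
  out$subject_id <- names(split(edges$gene_id, edges$mirna_id))
  skipped <- out$subject_id[out$n == 0]
  if (length(skipped))
    message(sprintf("%d miRNA(s) with no inferred target in the universe skipped", length(skipped)))
  out <- out[out$n > 0, , drop = FALSE]
  if (!nrow(out)) {
    attr(empty, "pct_significant") <- NA_real_
    return(empty)
  }
  res <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
    m <- out$subject_id[i]
    tg <- out$genes[[i]]
    known <- intersect(unique(truth$gene_id[truth$mirna_id == m]), universe)
    k <- length(intersect(tg, known)); K <- length(known); n <- length(tg)
    p <- hypergeom_upper(k, n, K, N)
    data.frame(subject_id = m, k = k, n = n, K = K, N = N, p_value = p,
               eligible = k >= 1, significant = k >= 1 & p < alpha,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  ne <- sum(res$eligible)
  attr(res, "pct_significant") <- if (ne) 100 * sum(res$significant) / ne else NA_real_
  res
}

#' Fisher enrichment of inferred miRNAs in an oncogenic-miRNA list
#'
#' Two-sided Fisher's exact test of the 2x2 table (inferred x oncogenic)
#' against a background of all miRNAs that entered the selection step.
#'
#' @param computed_mirnas inferred miRNA ids (must lie in the background)
#' @param onco_list oncogenic miRNA ids
#' @param background_mirnas background miRNA universe
#' @return list(table = 2x2 matrix, p = p-value)
#' @export
fisher_oncomirna_enrichment <- function(computed_mirnas, onco_list, background_mirnas) {
  computed <- unique(computed_mirnas)
  bg <- unique(background_mirnas)
  if (!all(computed %in% bg)) .stopf("computed miRNAs must be a subset of the background")
  onco <- intersect(unique(onco_list), bg)
  if (!length(onco)) {
    .warnf("oncogenic list is disjoint from the background; p = 1")
    tab <- matrix(c(0L, length(computed), 0L, length(bg) - length(computed)), 2, 2)
    dimnames(tab) <- list(c("onco", "other"), c("computed", "rest"))
    return(list(table = tab, p = 1))
  }
  a <- length(intersect(computed, onco))
  b <- length(setdiff(computed, onco))
  c_ <- length(setdiff(onco, computed))
  d <- length(bg) - a - b - c_
  tab <- matrix(c(a, c_, b, d), 2, 2,
                dimnames = list(c("onco", "other"), c("computed", "rest")))
  list(table = tab, p = fisher_two_sided(a, b, c_, d))
}

#' Compare two methods by significant miRNAs on the shared eligible set
#'
#' Both edge sets are scored with [mirna_target_enrichment()]; the
#' comparison is restricted to miRNAs eligible under BOTH methods, counting
#' each method's significant miRNAs inside that overlap. An empty overlap is
#' `not_comparable`.
#'
#' @param edges_a,edges_b edge tables of the two methods
#' @param truth ground-truth pairs
#' @param universe gene universe
#' @param alpha significance cutoff
#' @return list(verdict, n_overlap, sig_a, sig_b) with verdict in
#'   a_wins/b_wins/draw/not_comparable
#' @export
compare_methods <- function(edges_a, edges_b, truth, universe, alpha = 0.05) {
  ra <- mirna_target_enrichment(edges_a, truth, universe, alpha)
  rb <- mirna_target_enrichment(edges_b, truth, universe, alpha)
  ov <- intersect(ra$subject_id[ra$eligible], rb$subject_id[rb$eligible])
  if (!length(ov))
    return(list(verdict = "not_comparable", n_overlap = 0L, sig_a = NA_integer_, sig_b = NA_integer_))
  sa <- sum(ra$significant[ra$subject_id %in% ov])
  sb <- sum(rb$significant[rb$subject_id %in% ov])
  verdict <- if (sa > sb) "a_wins" else if (sb > sa) "b_wins" else "draw"
  list(verdict = verdict, n_overlap = length(ov), sig_a = sa, sig_b = sb)
}

#' Over-representation analysis of a gene set against term annotations
#'
#' Upper-tail hypergeometric test per term with BH correction across terms.
#' Terms with no gene in the universe are skipped.
#'
#' @param gene_set genes of interest (subset of `universe`)
#' @param annotation named list term -> gene-id vector
#' @param universe gene universe
#' @param alpha adjusted-p cutoff
#' @return data.frame term, k, n, K, N, p_value, adj_p, significant
#' @export
ora <- function(gene_set, annotation, universe, alpha = 0.05) {
  universe <- unique(universe)
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% universe)) .stopf("gene_set must be a subset of the universe")
  N <- length(universe); n <- length(gene_set)
  rows <- lapply(names(annotation), function(tm) {
    K_genes <- intersect(unique(annotation[[tm]]), universe)
    if (!length(K_genes)) return(NULL)
    k <- length(intersect(gene_set, K_genes))
    data.frame(term = tm, k = k, n = n, K = length(K_genes), N = N,
               p_value = hypergeom_upper(k, n, length(K_genes), N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(term = character(0), k = integer(0), n = integer(0),
                                      K = integer(0), N = integer(0), p_value = numeric(0),
                                      adj_p = numeric(0), significant = logical(0)))
  out$adj_p <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$adj_p < alpha
  out <- out[order(out$adj_p, out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spearman correlation of miRNA copy number and expression
#'
#' Per miRNA, the Spearman rank correlation (mid-ranked ties) across samples
#' between its feature-centric copy number and its expression; constant
#' vectors or fewer than 3 paired samples give NA. Reports the cohort
#' median over defined values.
#'
#' @param mirna_ids miRNAs to correlate
#' @param mirna_cn named list or matrix: per-miRNA copy-number vector over samples
#' @param mirna_expr expression matrix (miRNAs x samples)
#' @return list(rho = named vector, median_rho)
#' @export
cn_expression_correlation <- function(mirna_ids, mirna_cn, mirna_expr) {
  rho <- vapply(mirna_ids, function(m) {
    cn <- if (is.matrix(mirna_cn)) mirna_cn[m, ] else mirna_cn[[m]]
    if (is.null(cn) || !m %in% rownames(mirna_expr)) return(NA_real_)
    ex <- mirna_expr[m, names(cn)]
    ok <- is.finite(cn) & is.finite(ex)
    if (sum(ok) < 3) return(NA_real_)
    if (stats::sd(cn[ok]) == 0 || stats::sd(ex[ok]) == 0) return(NA_real_)
    stats::cor(cn[ok], ex[ok], method = "spearman")
  }, numeric(1))
  list(rho = rho, median_rho = stats::median(rho, na.rm = TRUE))
}

#' Recovery metrics against planted truth
#'
#' @param edges inferred edge table (mirna_id, gene_id, sign)
#' @param truth planted edges (mirna_id, gene_id, sign)
#' @return list(precision, recall, sign_accuracy); precision and
#'   sign_accuracy are NA when no edge was inferred
#' @export
recovery_metrics <- function(edges, truth) {
  tkey <- paste(truth$mirna_id, truth$gene_id)
  if (is.null(edges) || !nrow(edges))
    return(list(precision = NA_real_, recall = 0, sign_accuracy = NA_real_))
  ekey <- paste(edges$mirna_id, edges$gene_id)
  hit <- ekey %in% tkey
  precision <- mean(hit)
  recall <- length(intersect(ekey, tkey)) / length(unique(tkey))
  sign_acc <- if (any(hit)) {
    esign <- edges$sign[hit]
    tsign <- truth$sign[match(ekey[hit], tkey)]
    tsign <- ifelse(tsign %in% c("-", "negative"), "negative", "positive")
    mean(esign == tsign)
  } else NA_real_
  list(precision = precision, recall = recall, sign_accuracy = sign_acc)
}
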