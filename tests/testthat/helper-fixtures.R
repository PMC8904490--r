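# Shared fixtures: a small synthetic cohort for module tests and helpers to
# run the pipeline on a cohort directory. Heavyweight objects are cached for
# the session.

.fixture_cache <- new.env(parent = emptyenv())

small_sim_config <- function(seed = 5, ...) {
  sim_config(n_samples = 80L, n_genes = 100L, n_mirnas = 12L, n_regions = 2L,
             n_true_edges = 3L, seed = seed, ...)
}

small_cohort <- function() {
  if (is.null(.fixture_cache$small)) .fixture_cache$small <- generate_cohort(small_sim_config())
  .fixture_cache$small
}

cohort_dir <- function(co) {
  d <- tempfile("cohort")
  suppressMessages(write_cohort(co, d))
  d
}

cohort_pipeline_config <- function(d, seed = 1L, with_truth = FALSE, ...) {
  paths <- list(seg = file.path(d, "segments.seg"),
                counts = file.path(d, "gene_counts.tsv"),
                mirna = file.path(d, "mirna_rpm.tsv"),
                features = file.path(d, "features.bed"),
                meth = file.path(d, "methylation.tsv"),
                tf = file.path(d, "tf_table.tsv"))
  if (with_truth) paths$truth_edges <- file.path(d, "truth_edges.tsv")
  pipeline_config(paths = paths, global_seed = seed, ...)
}

read_edges <- function(rundir) {
  utils::read.delim(file.path(rundir, "edges.tsv"), comment.char = "#",
                    stringsAsFactors = FALSE)
}

## run the full pipeline on a freshly generated cohort; returns edges + truth
run_planted <- function(seed, edge_effect = 0.9, stability = list(), sim_args = list()) {
  co <- generate_cohort(do.call(sim_config, c(list(seed = seed, edge_effect = edge_effect),
                                              sim_args)))
  d <- cohort_dir(co)
  cfg <- cohort_pipeline_config(d, seed = seed, stability = stability)
  rd <- tempfile("run")
  suppressMessages(run_all(cfg, rd))
  list(edges = read_edges(rd), truth = co$truth, rundir = rd, cohort = co)
}

edge_hits <- function(edges, truth) {
  tkey <- paste(truth$true_edges$mirna_id, truth$true_edges$gene_id)
  paste(edges$mirna_id, edges$gene_id) %in% tkey
}

## independent brute-force BH for oracle comparisons
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

## enumeration oracle for the upper-tail hypergeometric probability
hyper_enum <- function(k, n, K, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

## enumeration oracle for the two-sided Fisher test (probability-mass rule)
fisher_enum <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; kk <- a + b
  xs <- max(0, kk - nn):min(kk, m)
  probs <- dhyper(xs, m, nn, kk)
  sum(probs[probs <= dhyper(a, m, nn, kk) * (1 + 1e-7)])
}
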