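# Synthetic multi-omics cohort with planted recurrent copy-number regions
# and planted miRNA -> trans-gene effects, so that every pipeline stage and
# every evaluation statistic can be exercised against known truth.
#
# Planted structure per region: a fixed carrier subset whose segments over
# the region sit at amp_log2/del_log2 (plus small segment noise), cis genes
# and cis miRNAs inside the region whose log-expression follows the dosage,
# trans target genes (outside any region, repressed by a cis miRNA's
# standardized expression), and decoy trans genes driven by a cis gene's
# realized expression -- differentially expressed through the region, but
# with no miRNA involvement, so that edge selection has something to refuse.

#' Simulation configuration
#'
#' Defaults are the package's reference cohort: 150 samples, 300 genes, 30
#' miRNAs, 3 planted regions (two amplifications, one deletion) of 1 Mb on
#' 10 Mb chromosomes, 60% recurrence, and 5 true miRNA->gene edges with a
#' standardized effect of 0.9 (negative: canonical miRNA-mediated
#' repression).
#'
#' @param n_samples,n_genes,n_mirnas,n_regions cohort dimensions
#' @param region_recurrence fraction of samples carrying each planted region
#' @param amp_log2 carrier log2 ratio of amplified regions (> 0.1)
#' @param del_log2 carrier log2 ratio of deleted regions (< -0.1)
#' @param n_true_edges planted miRNA -> trans-gene edges
#' @param edge_effect standardized magnitude of the planted (negative) effect
#' @param dosage_effect copy-number -> log2-expression slope for in-region features
#' @param methyl_effect beta -> log2-expression slope (negative) for the
#'   methylation-responsive gene subset
#' @param nb_dispersion NB dispersion of gene counts (0 = Poisson)
#' @param mean_library_size expected per-sample total count
#' @param mirna_noise_sd per-sample log2 noise of miRNA expression
#' @param region_length,chrom_length geometry in bp
#' @param seed RNG seed; the cohort is a pure function of the config
#' @return config list
#' @export
sim_config <- function(n_samples = 150L, n_genes = 300L, n_mirnas = 30L,
                       n_regions = 3L, region_recurrence = 0.6,
                       amp_log2 = 1.3, del_log2 = -1.3, n_true_edges = 5L,
                       edge_effect = 0.9, dosage_effect = 1.0,
                       methyl_effect = -2.0, nb_dispersion = 0.1,
                       mean_library_size = 15000, mirna_noise_sd = 0.7,
                       region_length = 1e6, chrom_length = 1e7, seed = 1L) {
  stopifnot(.is_count(n_samples), .is_count(n_genes), .is_count(n_mirnas),
            .is_count(n_regions), .is_count(n_true_edges) || n_true_edges == 0)
  if (!(region_recurrence > 0 && region_recurrence <= 1))
    .stopf("region_recurrence must be in (0, 1]")
  if (round(region_recurrence * n_samples) < 2)
    .stopf("region_recurrence * n_samples must be >= 2")
  if (amp_log2 <= 0.1 || del_log2 >= -0.1)
    .stopf("planted carriers must pass the status rule: amp_log2 > 0.1, del_log2 < -0.1")
  if (n_true_edges > n_mirnas * n_genes) .stopf("n_true_edges exceeds n_mirnas * n_genes")
  if (n_mirnas < n_true_edges + n_regions)
    .stopf("need n_mirnas >= n_true_edges + n_regions (one decoy cis miRNA per region)")
  if (n_genes < 7 * n_regions + n_true_edges + 12)
    .stopf("n_genes too small for the planted role layout (need >= %d)",
           7 * n_regions + n_true_edges + 12)
  if (nb_dispersion < 0) .stopf("nb_dispersion must be >= 0")
  if (region_length + 2e6 > chrom_length)
    .stopf("infeasible placement: region_length %g does not fit on chromosomes of %g bp",
           region_length, chrom_length)
  as.list(environment())
}

#' Generate a synthetic multi-omics cohort
#'
#' Deterministic given `cfg$seed`. Each planted region has exactly
#' `round(region_recurrence * n_samples)` carrier samples whose segments over
#' the region average `amp_log2` (or `del_log2`); all other segment means are
#' N(0, 0.03). Gene counts are negative binomial around log2 means composed
#' of dosage, methylation, TF and planted-edge effects; miRNA expression is
#' generated directly on the RPM scale (log-normal), the scale on which the
#' pipeline uses it.
#'
#' @param cfg [sim_config()]
#' @return list with segments, features, gene_counts, mirna_rpm, methylation
#'   (gene-level beta), tf_table, truth (true_edges, true_regions,
#'   carrier_samples, true_de_genes), roles, config
#' @export
generate_cohort <- function(cfg = sim_config()) {
  .with_seed(as.integer(cfg$seed), .generate_cohort_impl(cfg))
}

.generate_cohort_impl <- function(cfg) {
  n_chrom <- max(4L, cfg$n_regions + 1L)
  chroms <- paste0("chr", seq_len(n_chrom))
  samples <- sprintf("S%03d", seq_len(cfg$n_samples))
  gene_ids <- sprintf("g%03d", seq_len(cfg$n_genes))
  mir_ids <- sprintf("mir%03d", seq_len(cfg$n_mirnas))

  ## planted regions: region r on chromosome r at [2e6, 2e6 + region_length)
  reg_chrom <- chroms[((seq_len(cfg$n_regions) - 1L) %% (n_chrom - 1L)) + 1L]
  reg_start <- rep(2e6, cfg$n_regions)
  reg_end <- reg_start + cfg$region_length
  reg_dir <- rep(c("amp", "amp", "del"), length.out = cfg$n_regions)
  reg_id <- sprintf("r%d", seq_len(cfg$n_regions))
  true_regions <- data.frame(region_id = reg_id, chrom = reg_chrom,
                             start = reg_start, end = reg_end,
                             direction = reg_dir, stringsAsFactors = FALSE)
  n_carr <- round(cfg$region_recurrence * cfg$n_samples)
  carriers <- lapply(seq_len(cfg$n_regions), function(r) sort(sample(samples, n_carr)))
  names(carriers) <- reg_id

  ## roles ------------------------------------------------------------------
  n_cis <- min(4L, max(1L, (cfg$n_genes - 60L) %/% (3L * cfg$n_regions)))
  cis_genes <- split(gene_ids[seq_len(n_cis * cfg$n_regions)],
                     rep(seq_len(cfg$n_regions), each = n_cis))
  names(cis_genes) <- reg_id
  nxt <- n_cis * cfg$n_regions
  take <- function(k) { ids <- gene_ids[nxt + seq_len(k)]; nxt <<- nxt + k; ids }
  target_genes <- take(cfg$n_true_edges)
  decoy_genes <- split(take(cfg$n_regions), seq_len(cfg$n_regions))
  names(decoy_genes) <- reg_id
  meth_genes <- take(max(0L, min(20L, cfg$n_genes - nxt - 40L)))
  tf_genes <- take(8L)
  plain_genes <- gene_ids[(nxt + 1L):cfg$n_genes]

  ## edge miRNAs round-robin over regions; one extra cis miRNA per region
  edge_region <- ((seq_len(cfg$n_true_edges) - 1L) %% cfg$n_regions) + 1L
  edge_mirs <- mir_ids[seq_len(cfg$n_true_edges)]
  extra_cis_mirs <- mir_ids[cfg$n_true_edges + seq_len(cfg$n_regions)]
  n_used <- cfg$n_true_edges + cfg$n_regions
  free_mirs <- if (n_used < cfg$n_mirnas) mir_ids[(n_used + 1L):cfg$n_mirnas] else character(0)
  low_mirs <- utils::head(free_mirs, 2L)
  cis_mirnas <- lapply(seq_len(cfg$n_regions), function(r)
    c(edge_mirs[edge_region == r], extra_cis_mirs[r]))
  names(cis_mirnas) <- reg_id

  ## feature coordinates ----------------------------------------------------
  glen <- 1e4
  feat <- list()
  for (r in seq_len(cfg$n_regions)) {
    ids <- cis_genes[[r]]
    feat[[length(feat) + 1]] <- data.frame(
      feature_id = ids, kind = "gene", chrom = reg_chrom[r],
      start = reg_start[r] + 1e4 + (seq_along(ids) - 1) * 2.2e5)
  }
  outside <- c(target_genes, unlist(decoy_genes, use.names = FALSE),
               meth_genes, tf_genes, plain_genes)
  slot <- seq_along(outside) - 1L
  feat[[length(feat) + 1]] <- data.frame(
    feature_id = outside, kind = "gene",
    chrom = chroms[(slot %% n_chrom) + 1L],
    start = 3.2e6 + (slot %/% n_chrom) * 2.5e4)
  for (r in seq_len(cfg$n_regions)) {
    ids <- cis_mirnas[[r]]
    feat[[length(feat) + 1]] <- data.frame(
      feature_id = ids, kind = "mirna", chrom = reg_chrom[r],
      start = reg_start[r] + 5e4 + (seq_along(ids) - 1) * 4e4)
  }
  if (length(free_mirs))
    feat[[length(feat) + 1]] <- data.frame(
      feature_id = free_mirs, kind = "mirna", chrom = chroms[n_chrom],
      start = 1e5 + (seq_along(free_mirs) - 1) * 5e4)
  feat <- do.call(rbind, feat)
  feat$end <- feat$start + ifelse(feat$kind == "gene", glen, 200)
  feat$strand <- rep_len(c("+", "-"), nrow(feat))
  feats <- features(feat)

  ## segments ---------------------------------------------------------------
  grid <- 1e4
  seg_rows <- vector("list", cfg$n_samples * n_chrom)
  ix <- 0
  for (s in samples) {
    for (ci in seq_len(n_chrom)) {
      ch <- chroms[ci]
      rhere <- which(reg_chrom == ch & vapply(carriers, function(x) s %in% x, logical(1)))
      bp <- sort(sample(seq(grid, cfg$chrom_length - grid, by = grid), 2))
      cuts <- c(0, bp, cfg$chrom_length)
      if (length(rhere)) {
        keep <- !(cuts > reg_start[rhere[1]] & cuts < reg_end[rhere[1]])
        cuts <- sort(unique(c(cuts[keep], reg_start[rhere[1]], reg_end[rhere[1]])))
      }
      st <- cuts[-length(cuts)]; en <- cuts[-1]
      lr <- stats::rnorm(length(st), 0, 0.03)
      if (length(rhere)) {
        k <- which(st == reg_start[rhere[1]] & en == reg_end[rhere[1]])
        base <- if (reg_dir[rhere[1]] == "amp") cfg$amp_log2 else cfg$del_log2
        lr[k] <- base + stats::rnorm(1, 0, 0.03)
      }
      ix <- ix + 1
      seg_rows[[ix]] <- data.frame(sample_id = s, chrom = ch, start = st, end = en,
                                   log2_ratio = lr, stringsAsFactors = FALSE)
    }
  }
  segs <- segment_table(do.call(rbind, seg_rows))

  ## realized per-sample copy number over each region
  region_cn <- vapply(seq_len(cfg$n_regions), function(r) {
    sc <- segs[segs$chrom == reg_chrom[r], , drop = FALSE]
    vapply(samples, function(s)
      .weighted_region_mean(sc[sc$sample_id == s, ], reg_start[r], reg_end[r]),
      numeric(1))
  }, numeric(cfg$n_samples))
  colnames(region_cn) <- reg_id

  ## miRNA expression (log2 RPM scale) --------------------------------------
  base_m <- stats::setNames(stats::runif(cfg$n_mirnas, 2, 8), mir_ids)
  base_m[low_mirs] <- -8   # fails the RPM prevalence filter
  E <- matrix(base_m, cfg$n_mirnas, cfg$n_samples, dimnames = list(mir_ids, samples))
  for (r in seq_len(cfg$n_regions))
    E[cis_mirnas[[r]], ] <- E[cis_mirnas[[r]], , drop = FALSE] +
      matrix(cfg$dosage_effect * region_cn[, r], length(cis_mirnas[[r]]),
             cfg$n_samples, byrow = TRUE)
  E <- E + matrix(stats::rnorm(length(E), 0, cfg$mirna_noise_sd), nrow(E))
  mirna_rpm <- expression_matrix(2^E, "rpm")

  ## methylation (gene-level beta) ------------------------------------------
  prec <- 30
  base_beta <- stats::setNames(stats::runif(cfg$n_genes, 0.2, 0.8), gene_ids)
  beta <- matrix(stats::rbeta(cfg$n_genes * cfg$n_samples,
                              rep(base_beta * prec, cfg$n_samples),
                              rep((1 - base_beta) * prec, cfg$n_samples)),
                 cfg$n_genes, cfg$n_samples, dimnames = list(gene_ids, samples))
  methylation <- expression_matrix(beta, "beta")

  ## gene log2 means ---------------------------------------------------------
  base_g <- stats::setNames(stats::runif(cfg$n_genes, 3, 8), gene_ids)
  M <- matrix(base_g, cfg$n_genes, cfg$n_samples, dimnames = list(gene_ids, samples))
  for (r in seq_len(cfg$n_regions))
    M[cis_genes[[r]], ] <- M[cis_genes[[r]], , drop = FALSE] +
      matrix(cfg$dosage_effect * region_cn[, r], length(cis_genes[[r]]),
             cfg$n_samples, byrow = TRUE)
  M[meth_genes, ] <- M[meth_genes, , drop = FALSE] +
    cfg$methyl_effect * (beta[meth_genes, , drop = FALSE] - base_beta[meth_genes])
  zscore <- function(v) { s <- stats::sd(v); if (s == 0) v * 0 else (v - mean(v)) / s }
  lm_mir <- log2(2^E + 1)
  for (e in seq_len(cfg$n_true_edges))
    M[target_genes[e], ] <- M[target_genes[e], ] -
      cfg$edge_effect * zscore(lm_mir[edge_mirs[e], ])

  ## TF table ----------------------------------------------------------------
  tf_targets <- lapply(tf_genes, function(f) sample(plain_genes, min(4L, length(plain_genes))))
  tf_table <- data.frame(
    tf_id = rep(tf_genes, lengths(tf_targets)),
    target_id = unlist(tf_targets, use.names = FALSE),
    confidence = sample(c("A", "B", "C"), sum(lengths(tf_targets)), replace = TRUE),
    stringsAsFactors = FALSE)

  ## counts: stage A (everything observable), then genes driven by realized
  ## expression of stage-A genes (TF targets, decoys)
  lf <- exp(stats::rnorm(cfg$n_samples, 0, 0.15))
  sc <- cfg$mean_library_size / sum(2^base_g)
  draw <- function(mu) {
    if (cfg$nb_dispersion > 0) stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
    else stats::rpois(length(mu), mu)
  }
  stageB <- unique(c(unlist(tf_targets, use.names = FALSE),
                     unlist(decoy_genes, use.names = FALSE)))
  stageA <- setdiff(gene_ids, stageB)
  counts <- matrix(0L, cfg$n_genes, cfg$n_samples, dimnames = list(gene_ids, samples))
  muA <- sweep(2^M[stageA, , drop = FALSE] * sc, 2, lf, "*")
  counts[stageA, ] <- draw(muA)
  ## drivers are the observable scale: library-normalized log2 expression
  zA <- t(apply(log2(sweep(counts[stageA, , drop = FALSE], 2, lf, "/") + 1), 1, zscore))
  for (f in seq_along(tf_genes))
    for (t in tf_targets[[f]])
      M[t, ] <- M[t, ] + 0.4 * zA[tf_genes[f], ]
  for (r in seq_len(cfg$n_regions)) {
    conf <- cis_genes[[r]][1]
    for (d in decoy_genes[[r]])
      M[d, ] <- M[d, ] + 0.9 * zA[conf, ]
  }
  muB <- sweep(2^M[stageB, , drop = FALSE] * sc, 2, lf, "*")
  counts[stageB, ] <- draw(muB)
  gene_counts <- expression_matrix(counts, "raw_count")

  truth <- list(
    true_edges = data.frame(mirna_id = edge_mirs, gene_id = target_genes,
                            sign = "-", region_id = reg_id[edge_region],
                            stringsAsFactors = FALSE),
    true_regions = true_regions,
    carrier_samples = carriers,
    true_de_genes = stats::setNames(lapply(seq_len(cfg$n_regions), function(r)
      c(cis_genes[[r]], decoy_genes[[r]], target_genes[edge_region == r])), reg_id))
  roles <- list(cis_genes = cis_genes, cis_mirnas = cis_mirnas,
                target_genes = target_genes, decoy_genes = decoy_genes,
                meth_genes = meth_genes, tf_genes = tf_genes,
                plain_genes = plain_genes, low_expressed_mirnas = low_mirs)
  list(segments = segs, features = feats, gene_counts = gene_counts,
       mirna_rpm = mirna_rpm, methylation = methylation, tf_table = tf_table,
       truth = truth, roles = roles, config = cfg)
}

#' Write a cohort to disk
#'
#' All tables go through the package writers; a manifest records the files,
#' the seed and the config hash. Refuses to overwrite an existing cohort
#' (manifest present) unless `force = TRUE`.
#'
#' @param cohort output of [generate_cohort()]
#' @param outdir output directory (created if needed)
#' @param force overwrite an existing cohort
#' @return path of the manifest, invisibly
#' @export
write_cohort <- function(cohort, outdir, force = FALSE) {
  manifest_path <- file.path(outdir, "manifest.json")
  if (file.exists(manifest_path) && !force)
    .stopf("cohort already present in %s (manifest.json exists); use force = TRUE", outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c(segments = "segments.seg", features = "features.bed",
             gene_counts = "gene_counts.tsv", mirna_rpm = "mirna_rpm.tsv",
             methylation = "methylation.tsv", tf_table = "tf_table.tsv",
             truth_edges = "truth_edges.tsv", truth_regions = "truth_regions.tsv",
             carriers = "carriers.json")
  p <- function(f) file.path(outdir, f)
  write_seg(cohort$segments, p(files["segments"]))
  write_features(cohort$features, p(files["features"]))
  write_matrix(cohort$gene_counts, p(files["gene_counts"]), id_col = "gene_id")
  write_matrix(cohort$mirna_rpm, p(files["mirna_rpm"]), id_col = "mirna_id")
  write_matrix(cohort$methylation, p(files["methylation"]), id_col = "gene_id")
  write_tf_table(cohort$tf_table, p(files["tf_table"]))
  .write_tsv(cohort$truth$true_edges, p(files["truth_edges"]))
  write_region_table(cohort$truth$true_regions, p(files["truth_regions"]))
  jsonlite::write_json(cohort$truth$carrier_samples, p(files["carriers"]))
  manifest <- list(files = as.list(files), seed = cohort$config$seed,
                   config_hash = config_hash(cohort$config),
                   tool = sprintf("regmir %s", as.character(utils::packageVersion("regmir"))))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest_path)
}

#' Read a cohort written by [write_cohort()]
#' @param outdir cohort directory
#' @return list with the on-disk tables (truth included)
#' @export
read_cohort <- function(outdir) {
  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"), simplifyVector = TRUE)
  p <- function(f) file.path(outdir, manifest$files[[f]])
  list(segments = read_seg(p("segments")),
       features = read_features(p("features"), "bed"),
       gene_counts = read_matrix(p("gene_counts"), "raw_count"),
       mirna_rpm = read_matrix(p("mirna_rpm"), "rpm"),
       methylation = read_matrix(p("methylation"), "beta"),
       tf_table = read_tf_table(p("tf_table")),
       truth = list(
         true_edges = .read_tsv(p("truth_edges")),
         true_regions = read_region_table(p("truth_regions"),
                                          dialect = "one_based_inclusive"),
         carrier_samples = jsonlite::read_json(p("carriers"), simplifyVector = TRUE)),
       manifest = manifest)
}
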