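# End-to-end orchestration: regions -> diffexp -> regulator -> lasso
# (-> evaluate when planted truth is supplied), driven by one structured
# config. Every stage reads and writes plain files under the run directory,
# so a run can be entered at any stage (e.g. with an externally computed
# region table) and a rerun with an identical config hash skips completed
# stages. All randomness derives from global_seed and stable stage/unit
# identifiers, never from scheduling order.

.DIRECTION_MODES <- c("both", "amp_only", "del_only", "up_only", "down_only")

#' Pipeline configuration
#'
#' Nested stage configs keep their own defaults (the DE filter |logFC| >= 1,
#' adjusted p < 0.05; the miRNA prevalence filter RPM >= 0.01 in >= 30% of
#' samples; 100 LASSO runs with keep threshold 70 and 10-fold CV; status
#' thresholds +0.1/-0.1).
#'
#' @param paths named list of input files: `seg`, `counts`, `mirna`,
#'   `features` required; `meth`, `meth_manifest`, `tf`, `external_regions`,
#'   `truth_edges`, `onco` optional
#' @param region_caller [region_caller_config()] (or a list of its fields)
#' @param diffexp [de_config()] (or field list)
#' @param stability [stability_config()] (or field list)
#' @param mirna_filter list(min_rpm, min_fraction)
#' @param promoter_window c(upstream, downstream) bp for 450K aggregation
#' @param meth_platform NULL when `paths$meth` is already gene-level, else
#'   `"p450k"`/`"p27k"` (requires `paths$meth_manifest`)
#' @param direction_mode restrict the run: `both`, `amp_only`, `del_only`
#'   (region direction), `up_only`, `down_only` (DE sign)
#' @param tf_confidence_keep TF confidence grades to keep (NULL = all)
#' @param cis_rule cis assignment rule, see [annotate_cis_trans()]
#' @param global_seed master seed; all stage seeds derive from it
#' @return validated config list
#' @export
pipeline_config <- function(paths, region_caller = list(), diffexp = list(),
                            stability = list(), mirna_filter = list(),
                            promoter_window = c(upstream = 2000, downstream = 500),
                            meth_platform = NULL,
                            direction_mode = "both", tf_confidence_keep = NULL,
                            cis_rule = "any_overlap", global_seed = 1L) {
  required <- c("seg", "counts", "mirna", "features")
  known_paths <- c(required, "meth", "meth_manifest", "tf", "external_regions",
                   "truth_edges", "onco")
  unknown <- setdiff(names(paths), known_paths)
  if (length(unknown)) .stopf("unknown path key: %s", unknown[1])
  miss <- setdiff(required, names(paths))
  if (length(miss)) .stopf("missing required path: %s", miss[1])
  for (nm in names(paths)) {
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]]))
      .stopf("input file for '%s' does not exist: %s", nm, paths[[nm]])
  }
  build <- function(ctor, args, what) {
    if (!is.list(args)) .stopf("%s must be a list of settings", what)
    unknown <- setdiff(names(args), names(formals(ctor)))
    if (length(unknown)) .stopf("unknown %s key: %s", what, unknown[1])
    do.call(ctor, args)
  }
  mf <- mirna_filter
  unknown <- setdiff(names(mf), c("min_rpm", "min_fraction"))
  if (length(unknown)) .stopf("unknown mirna_filter key: %s", unknown[1])
  mirna_filter <- list(min_rpm = mf$min_rpm %||% 0.01,
                       min_fraction = mf$min_fraction %||% 0.30)
  direction_mode <- match.arg(direction_mode, .DIRECTION_MODES)
  cis_rule <- match.arg(cis_rule, c("any_overlap", "containment"))
  if (!is.null(meth_platform)) {
    meth_platform <- match.arg(meth_platform, c("p450k", "p27k"))
    if (is.null(paths$meth)) .stopf("meth_platform given without a meth path")
    if (meth_platform == "p450k" && is.null(paths$meth_manifest))
      .stopf("p450k aggregation needs a meth_manifest path")
  }
  structure(list(
    paths = paths,
    region_caller = build(region_caller_config, region_caller, "region_caller"),
    diffexp = build(de_config, diffexp, "diffexp"),
    stability = build(stability_config, stability, "stability"),
    mirna_filter = mirna_filter,
    promoter_window = promoter_window,
    meth_platform = meth_platform,
    direction_mode = direction_mode,
    tf_confidence_keep = tf_confidence_keep,
    cis_rule = cis_rule,
    global_seed = as.integer(global_seed)
  ), class = "pipeline_config")
}

#' Validate a YAML pipeline config file
#'
#' Reads the structured config, fills every default, and rejects unknown
#' keys by name. Referenced input files must exist.
#'
#' @param path YAML file
#' @return validated [pipeline_config()]
#' @export
validate_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) .stopf("unknown config key: %s", unknown[1])
  if (!is.null(raw$promoter_window)) raw$promoter_window <- unlist(raw$promoter_window)
  do.call(pipeline_config, raw)
}

## ---- stage plumbing --------------------------------------------------------

.read_status_matrix <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

.write_status_matrix <- function(status, path, hash) {
  df <- data.frame(region_id = rownames(status),
                   ifelse(status == "aberrated", 1L, 0L), check.names = FALSE)
  .write_tsv(df, path, hash)
}

.read_features_auto <- function(path) {
  fmt <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3lite" else "bed"
  read_features(path, fmt)
}

## overlap-weighted mean CN per feature x sample, with per-chromosome
## pre-splitting of segments (fast path for whole-matrix computation)
.feature_cn_fast <- function(feats, segs, samples, fill = 0) {
  out <- matrix(fill, nrow(feats), length(samples),
                dimnames = list(feats$feature_id, samples))
  for (ch in unique(feats$chrom)) {
    sc <- segs[segs$chrom == ch, , drop = FALSE]
    if (!nrow(sc)) next
    by_sample <- split(sc, sc$sample_id)
    fi <- which(feats$chrom == ch)
    for (s in intersect(samples, names(by_sample))) {
      d <- by_sample[[s]]
      for (i in fi) {
        v <- .weighted_region_mean(d, feats$start[i], feats$end[i])
        if (!is.na(v)) out[i, s] <- v
      }
    }
  }
  out
}

.stage_regions <- function(cfg, rundir, hash) {
  segs <- read_seg(cfg$paths$seg)
  regions <- if (!is.null(cfg$paths$external_regions)) {
    read_region_table(cfg$paths$external_regions)
  } else {
    call_regions(segs, cfg$region_caller, seed = .derive_seed(cfg$global_seed, "regions"))
  }
  if (cfg$direction_mode == "amp_only") regions <- regions[regions$direction == "amp", , drop = FALSE]
  if (cfg$direction_mode == "del_only") regions <- regions[regions$direction == "del", , drop = FALSE]
  status <- region_status_matrix(regions, segs,
                                 amp_threshold = cfg$region_caller$amp_threshold,
                                 del_threshold = cfg$region_caller$del_threshold)
  write_region_table(regions, file.path(rundir, "regions.tsv"))
  .write_status_matrix(status, file.path(rundir, "status.tsv"), hash)
  c("regions.tsv", "status.tsv")
}

.stage_diffexp <- function(cfg, rundir, hash) {
  counts <- read_matrix(cfg$paths$counts, "raw_count")
  regions <- read_region_table(file.path(rundir, "regions.tsv"))
  status <- .read_status_matrix(file.path(rundir, "status.tsv"))
  dir.create(file.path(rundir, "de"), showWarnings = FALSE)
  factors <- if (ncol(counts) > 1) tmm_factors(counts) else NULL
  outs <- character(0)
  for (rid in regions$region_id) {
    st <- ifelse(status[rid, colnames(counts)] == 1, "aberrated", "non_aberrated")
    names(st) <- colnames(counts)
    de <- run_region_de(rid, st, counts, cfg$diffexp, factors = factors)
    if (nrow(de)) {
      if (cfg$direction_mode == "up_only") de$is_de <- de$is_de & de$logFC > 0
      if (cfg$direction_mode == "down_only") de$is_de <- de$is_de & de$logFC < 0
    }
    f <- file.path("de", paste0(rid, ".tsv"))
    .write_tsv(de, file.path(rundir, f), hash)
    outs <- c(outs, f)
  }
  outs
}

.stage_regulator <- function(cfg, rundir, hash) {
  counts <- read_matrix(cfg$paths$counts, "raw_count")
  segs <- read_seg(cfg$paths$seg)
  feats <- .read_features_auto(cfg$paths$features)
  regions <- read_region_table(file.path(rundir, "regions.tsv"))
  mirna <- read_matrix(cfg$paths$mirna, "rpm")
  mirna_f <- filter_mirnas(mirna, cfg$mirna_filter$min_rpm, cfg$mirna_filter$min_fraction)
  mirna_expr <- log2(mirna_f + 1)
  gene_expr <- normalized_log_expression(counts)
  gene_meth <- NULL
  if (!is.null(cfg$paths$meth)) {
    beta <- read_matrix(cfg$paths$meth, "beta")
    gene_meth <- if (is.null(cfg$meth_platform)) beta else {
      man <- .read_tsv(cfg$paths$meth_manifest)
      gene_level_methylation(beta, man, feats, cfg$meth_platform, cfg$promoter_window)
    }
  }
  tf <- if (!is.null(cfg$paths$tf)) read_tf_table(cfg$paths$tf) else NULL
  dir.create(file.path(rundir, "predictors"), showWarnings = FALSE)
  outs <- character(0)
  ann_rows <- list()
  gene_feats <- feats[feats$kind == "gene", , drop = FALSE]
  for (i in seq_len(nrow(regions))) {
    rid <- regions$region_id[i]
    de <- .read_tsv(file.path(rundir, "de", paste0(rid, ".tsv")))
    if (!nrow(de) || !any(de$is_de)) next
    ann <- annotate_cis_trans(regions[i, ], de, feats, rownames(mirna_f), cfg$cis_rule)
    ann_rows[[rid]] <- data.frame(region_id = rid,
                                  n_cis_genes = length(ann$cis_genes),
                                  n_trans_genes = length(ann$trans_genes),
                                  n_cis_mirnas = length(ann$cis_mirnas),
                                  cis_mirnas = paste(ann$cis_mirnas, collapse = ","))
    if (!length(ann$trans_genes) || !length(ann$cis_mirnas)) next
    need <- intersect(ann$trans_genes, gene_feats$feature_id)
    gene_cn <- .feature_cn_fast(gene_feats[gene_feats$feature_id %in% need, , drop = FALSE],
                                segs, colnames(gene_expr))
    ps_list <- assemble_predictors(ann, gene_expr, mirna_expr, gene_cn, gene_meth,
                                   tf, cfg$tf_confidence_keep)
    for (ps in ps_list) {
      f <- file.path("predictors", sprintf("%s__%s.tsv", rid, ps$trans_gene))
      write_predictor_set(ps, file.path(rundir, f))
      outs <- c(outs, f)
    }
  }
  ann_df <- if (length(ann_rows)) do.call(rbind, ann_rows) else
    data.frame(region_id = character(0), n_cis_genes = integer(0),
               n_trans_genes = integer(0), n_cis_mirnas = integer(0),
               cis_mirnas = character(0))
  .write_tsv(ann_df, file.path(rundir, "annotations.tsv"), hash)
  c("annotations.tsv", outs)
}

.stage_lasso <- function(cfg, rundir, hash) {
  files <- sort(list.files(file.path(rundir, "predictors"), pattern = "\\.tsv$",
                           full.names = TRUE))
  records <- list()
  kkt <- 0
  for (f in files) {
    bits <- strsplit(sub("\\.tsv$", "", basename(f)), "__", fixed = TRUE)[[1]]
    ps <- read_predictor_set(f, region_id = bits[1])
    scfg <- cfg$stability
    scfg$base_seed <- .derive_seed(cfg$global_seed, "lasso", ps$region_id, ps$trans_gene)
    rec <- if (scfg$two_phase) two_phase_select(ps, scfg) else stability_select(ps, scfg)
    kkt <- max(kkt, attr(rec, "max_kkt") %||% 0)
    records[[f]] <- rec
  }
  rec_df <- if (length(records)) do.call(rbind, records) else
    data.frame(region_id = character(0), trans_gene = character(0),
               predictor = character(0), predictor_class = character(0),
               selection_count = integer(0), mean_coef = numeric(0),
               sign = character(0))
  rownames(rec_df) <- NULL
  edges <- extract_edges(rec_df, cfg$stability)
  .write_tsv(rec_df, file.path(rundir, "records.tsv"), hash)
  .write_tsv(edges, file.path(rundir, "edges.tsv"), hash)
  jsonlite::write_json(list(max_kkt = kkt), file.path(rundir, "kkt.json"),
                       auto_unbox = TRUE, digits = NA)
  c("records.tsv", "edges.tsv", "kkt.json")
}

.stage_evaluate <- function(cfg, rundir, hash) {
  edges <- .read_tsv(file.path(rundir, "edges.tsv"))
  segs <- read_seg(cfg$paths$seg)
  feats <- .read_features_auto(cfg$paths$features)
  summary <- list(n_edges = nrow(edges))
  if (!is.null(cfg$paths$truth_edges)) {
    truth <- .read_tsv(cfg$paths$truth_edges)
    summary$recovery <- recovery_metrics(edges, truth)
  }
  ## CN vs expression of the cis miRNAs of the called regions
  ann <- .read_tsv(file.path(rundir, "annotations.tsv"))
  cm <- as.character(ann$cis_mirnas)
  cis_mirs <- unique(unlist(strsplit(cm[!is.na(cm) & nzchar(cm)], ",")))
  if (length(cis_mirs)) {
    mirna <- read_matrix(cfg$paths$mirna, "rpm")
    mir_feats <- feats[feats$kind == "mirna" & feats$feature_id %in% cis_mirs, , drop = FALSE]
    cn <- .feature_cn_fast(mir_feats, segs, colnames(mirna))
    corr <- cn_expression_correlation(rownames(cn), cn, log2(mirna + 1))
    summary$cn_expression <- list(median_rho = corr$median_rho,
                                  n_mirnas = sum(is.finite(corr$rho)))
  }
  if (!is.null(cfg$paths$onco) && nrow(edges)) {
    onco <- readLines(cfg$paths$onco)
    onco <- onco[!grepl("^#", onco) & nzchar(onco)]
    mirna <- read_matrix(cfg$paths$mirna, "rpm")
    bg <- rownames(filter_mirnas(mirna, cfg$mirna_filter$min_rpm, cfg$mirna_filter$min_fraction))
    fe <- fisher_oncomirna_enrichment(intersect(unique(edges$mirna_id), bg), onco, bg)
    summary$onco_fisher_p <- fe$p
  }
  jsonlite::write_json(summary, file.path(rundir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  "evaluation.json"
}

#' Run the full pipeline
#'
#' Executes regions -> diffexp -> regulator -> lasso (-> evaluate when a
#' truth/onco file is configured) under `rundir`. Rerunning with an
#' identical config against the same directory skips stages whose outputs
#' are present (reported `cached`); outputs are byte-identical across reruns
#' with the same config and seed.
#'
#' @param cfg [pipeline_config()] or a YAML path
#' @param rundir run directory (created)
#' @return run manifest (invisibly written to `rundir/manifest.json`)
#' @export
run_all <- function(cfg, rundir) {
  if (is.character(cfg)) cfg <- validate_config(cfg)
  if (!inherits(cfg, "pipeline_config")) .stopf("cfg must be a pipeline_config")
  dir.create(rundir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(cfg))
  manifest_path <- file.path(rundir, "manifest.json")
  old <- if (file.exists(manifest_path))
    tryCatch(jsonlite::read_json(manifest_path, simplifyVector = TRUE),
             error = function(e) NULL) else NULL
  reuse <- !is.null(old) && identical(old$config_hash, hash)
  stages <- c("regions", "diffexp", "regulator", "lasso")
  if (!is.null(cfg$paths$truth_edges) || !is.null(cfg$paths$onco))
    stages <- c(stages, "evaluate")
  fns <- list(regions = .stage_regions, diffexp = .stage_diffexp,
              regulator = .stage_regulator, lasso = .stage_lasso,
              evaluate = .stage_evaluate)
  manifest <- list(tool = sprintf("regmir %s", as.character(utils::packageVersion("regmir"))),
                   config_hash = hash, stages = list())
  for (st in stages) {
    prev <- if (reuse) old$stages[[st]] else NULL
    outs <- prev$outputs
    cached <- !is.null(outs) && all(file.exists(file.path(rundir, outs)))
    if (cached) {
      message(sprintf("stage %s: cached", st))
    } else {
      message(sprintf("stage %s: running", st))
      outs <- fns[[st]](cfg, rundir, hash)
    }
    manifest$stages[[st]] <- list(outputs = outs, cached = cached)
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
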