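# Predictor assembly: cis/trans annotation of DE genes, the miRNA expression
# filter, gene-level methylation aggregation, and construction of one
# response + class-labelled predictor matrix per eligible trans gene.

#' Filter miRNAs by expression prevalence
#'
#' Keeps miRNAs with RPM >= `min_rpm` in at least `min_fraction` of samples
#' (both bounds inclusive).
#'
#' @param mirna_rpm RPM matrix (miRNAs x samples, `value_kind` rpm)
#' @param min_rpm RPM threshold
#' @param min_fraction minimum fraction of the cohort at or above `min_rpm`
#' @return filtered matrix (possibly zero rows, with a warning)
#' @export
filter_mirnas <- function(mirna_rpm, min_rpm = 0.01, min_fraction = 0.30) {
  if (!identical(value_kind(mirna_rpm), "rpm"))
    .stopf("filter_mirnas expects a matrix with value_kind 'rpm'")
  frac <- rowMeans(mirna_rpm >= min_rpm)
  keep <- frac >= min_fraction
  if (!any(keep)) .warnf("no miRNA passes the expression filter")
  out <- mirna_rpm[keep, , drop = FALSE]
  attr(out, "value_kind") <- "rpm"
  out
}

#' Annotate a region's DE genes as cis or trans and collect cis miRNAs
#'
#' A DE gene is cis iff its interval overlaps the region by >= 1 bp
#' (`rule = "any_overlap"`, default) or lies fully inside it
#' (`rule = "containment"`); otherwise trans. Cis miRNAs are all
#' expression-filtered miRNAs overlapping the region -- miRNAs are not
#' subject to any differential-expression requirement.
#'
#' @param region one-row region table with region_id, chrom, start, end
#' @param de DE result table for this region (only `is_de` rows are used)
#' @param feats feature table covering genes and miRNAs
#' @param mirna_ids ids of expression-filtered miRNAs
#' @param rule cis assignment rule
#' @return list with region_id, cis_genes, trans_genes, cis_mirnas
#' @export
annotate_cis_trans <- function(region, de, feats, mirna_ids,
                               rule = c("any_overlap", "containment")) {
  rule <- match.arg(rule)
  de_genes <- unique(de$gene_id[de$is_de])
  genes <- feats[feats$kind == "gene", , drop = FALSE]
  missing <- setdiff(de_genes, genes$feature_id)
  if (length(missing))
    .warnf("%d DE gene(s) absent from the feature annotation were excluded (e.g. %s)",
           length(missing), missing[1])
  de_genes <- intersect(de_genes, genes$feature_id)
  g <- genes[match(de_genes, genes$feature_id), , drop = FALSE]
  same <- g$chrom == region$chrom
  cis <- if (rule == "any_overlap") {
    same & g$start < region$end & g$end > region$start
  } else {
    same & g$start >= region$start & g$end <= region$end
  }
  mir <- feats[feats$kind == "mirna" & feats$feature_id %in% mirna_ids, , drop = FALSE]
  cis_mir <- mir$feature_id[mir$chrom == region$chrom &
                              mir$start < region$end & mir$end > region$start]
  list(region_id = region$region_id,
       cis_genes = de_genes[cis],
       trans_genes = de_genes[!cis],
       cis_mirnas = cis_mir)
}

#' Aggregate probe-level methylation to gene level
#'
#' For the 450K platform only probes inside the strand-aware promoter window
#' around the TSS (default TSS - 2000 bp to TSS + 500 bp) are averaged; for
#' the 27K platform, whose coverage is sparser, all of a gene's probes are
#' averaged. Genes without a qualifying probe are missing (NA row).
#'
#' @param beta probe-level beta matrix (probes x samples)
#' @param manifest data.frame probe_id, gene_id, position (internal 0-based bp)
#' @param feats feature table (for TSS and strand; 450K only)
#' @param platform `"p450k"` or `"p27k"`
#' @param promoter_window c(upstream, downstream) in bp around the TSS
#' @return gene-level beta matrix (genes x samples, NA where no probe qualifies)
#' @export
gene_level_methylation <- function(beta, manifest, feats = NULL,
                                   platform = c("p450k", "p27k"),
                                   promoter_window = c(upstream = 2000, downstream = 500)) {
  platform <- match.arg(platform)
  missing_probe <- setdiff(rownames(beta), manifest$probe_id)
  if (length(missing_probe))
    .stopf("manifest does not cover probe(s): %s", missing_probe[1])
  man <- manifest[match(rownames(beta), manifest$probe_id), , drop = FALSE]
  genes <- unique(man$gene_id)
  if (platform == "p450k") {
    if (is.null(feats)) .stopf("450K aggregation needs gene features for TSS positions")
    gtab <- feats[feats$kind == "gene", , drop = FALSE]
    unknown <- setdiff(genes, gtab$feature_id)
    if (length(unknown)) {
      .warnf("%d probe gene(s) absent from features skipped (e.g. %s)",
             length(unknown), unknown[1])
      genes <- intersect(genes, gtab$feature_id)
    }
    up <- promoter_window[[1]]; down <- promoter_window[[2]]
    rows <- lapply(genes, function(g) {
      ge <- gtab[match(g, gtab$feature_id), ]
      if (identical(ge$strand, "-")) {
        win <- c(ge$end - down, ge$end + up)
      } else {
        win <- c(ge$start - up, ge$start + down)
      }
      pr <- man$probe_id[man$gene_id == g & man$position >= win[1] & man$position < win[2]]
      if (!length(pr)) rep(NA_real_, ncol(beta))
      else colMeans(beta[pr, , drop = FALSE], na.rm = TRUE)
    })
  } else {
    rows <- lapply(genes, function(g) {
      pr <- man$probe_id[man$gene_id == g]
      colMeans(beta[pr, , drop = FALSE], na.rm = TRUE)
    })
  }
  m <- do.call(rbind, rows)
  m[is.nan(m)] <- NA
  dimnames(m) <- list(genes, colnames(beta))
  attr(m, "value_kind") <- "beta"
  m
}

#' Log2 normalized expression
#'
#' Counts scaled to a common effective library size (library size x TMM
#' factor, rescaled to the mean library size), then log2(x + 1). The scale
#' used for expression predictors and responses throughout the LASSO step.
#'
#' @param counts raw-count matrix
#' @param factors optional TMM factors
#' @return log2 matrix
#' @export
normalized_log_expression <- function(counts, factors = NULL) {
  factors <- factors %||% tmm_factors(counts)
  eff <- colSums(counts) * factors
  norm <- sweep(counts, 2, mean(colSums(counts)) / eff, "*")
  log2(norm + 1)
}

#' Assemble predictor sets for a region's eligible trans genes
#'
#' One predictor set per trans gene that has at least one cis miRNA
#' available as a predictor; trans genes without any cis miRNA are omitted.
#' Columns: the region's cis genes (expression), the region's cis miRNAs
#' (expression), the trans gene's own gene-centric copy number, its
#' gene-level methylation beta (omitted, with a message, when missing --
#' never imputed), and the expression of TFs whose target list contains the
#' trans gene (after the optional confidence filter). A predictor appearing
#' in two roles (a cis gene that is also a TF of the target) yields a single
#' column recorded as cis_gene. Constant columns are dropped with a message.
#'
#' @param region_ann annotation from [annotate_cis_trans()]
#' @param gene_expr log2 normalized gene expression (genes x samples)
#' @param mirna_expr log2 miRNA expression (miRNAs x samples)
#' @param gene_cn gene-centric copy-number matrix (genes x samples)
#' @param gene_meth gene-level methylation beta matrix or NULL
#' @param tf_table TF interaction table (tf_id, target_id, confidence)
#' @param tf_confidence_keep confidence grades to keep (NULL = keep all)
#' @return list of predictor sets; each has region_id, trans_gene, response,
#'   predictors (samples x columns), column_class
#' @export
assemble_predictors <- function(region_ann, gene_expr, mirna_expr, gene_cn,
                                gene_meth = NULL, tf_table = NULL,
                                tf_confidence_keep = NULL) {
  if (!length(region_ann$cis_mirnas)) return(list())
  mats <- list(colnames(gene_expr), colnames(mirna_expr), colnames(gene_cn))
  if (!is.null(gene_meth)) mats <- c(mats, list(colnames(gene_meth)))
  samples <- Reduce(intersect, mats)
  samples <- colnames(gene_expr)[colnames(gene_expr) %in% samples]
  if (length(samples) < length(colnames(gene_expr)))
    message(sprintf("predictor assembly: sample intersection keeps %d of %d samples",
                    length(samples), ncol(gene_expr)))
  tf <- tf_table
  if (!is.null(tf) && !is.null(tf_confidence_keep))
    tf <- tf[!is.na(tf$confidence) & tf$confidence %in% tf_confidence_keep, , drop = FALSE]
  out <- list()
  for (g in region_ann$trans_genes) {
    if (!g %in% rownames(gene_expr)) {
      .warnf("trans gene %s absent from expression matrix; excluded", g)
      next
    }
    resp <- gene_expr[g, samples]
    cis_g <- intersect(region_ann$cis_genes, rownames(gene_expr))
    cis_g <- setdiff(cis_g, g)
    cis_m <- intersect(region_ann$cis_mirnas, rownames(mirna_expr))
    if (!length(cis_m)) next
    cols <- list(); cls <- character(0)
    add <- function(id, class, vec) {
      if (id %in% names(cols)) {
        message(sprintf("predictor %s duplicated for %s; kept once as %s", id, g, cls[[id]]))
        return()
      }
      cols[[id]] <<- vec
      cls[[id]] <<- class
    }
    for (id in cis_g) add(id, "cis_gene", gene_expr[id, samples])
    for (id in cis_m) add(id, "cis_mirna", mirna_expr[id, samples])
    if (g %in% rownames(gene_cn)) add(paste0("cn_", g), "cn", gene_cn[g, samples])
    if (!is.null(gene_meth) && g %in% rownames(gene_meth)) {
      mv <- gene_meth[g, samples]
      if (anyNA(mv)) message(sprintf("methylation for %s missing; column omitted", g))
      else add(paste0("meth_", g), "methylation", mv)
    } else if (!is.null(gene_meth)) {
      message(sprintf("methylation for %s missing; column omitted", g))
    }
    if (!is.null(tf)) {
      tfs <- setdiff(unique(tf$tf_id[tf$target_id == g]), g)
      for (id in intersect(tfs, rownames(gene_expr))) add(id, "tf", gene_expr[id, samples])
    }
    X <- do.call(cbind, cols)
    if (is.null(X)) next
    colnames(X) <- names(cols)
    const <- apply(X, 2, stats::sd) < 1e-10
    if (any(const)) {
      message(sprintf("dropping %d constant predictor column(s) for %s", sum(const), g))
      X <- X[, !const, drop = FALSE]
      cls <- cls[colnames(X)]
    }
    if (!any(cls == "cis_mirna")) {
      .warnf("trans gene %s lost all cis miRNA predictors; omitted", g)
      next
    }
    out[[g]] <- structure(list(region_id = region_ann$region_id, trans_gene = g,
                               response = resp, predictors = X,
                               column_class = cls),
                          class = "predictor_set")
  }
  out
}

#' @export
print.predictor_set <- function(x, ...) {
  cat(sprintf("predictor set: %s / %s, %d samples, %d predictors (%s)\n",
              x$region_id, x$trans_gene, length(x$response), ncol(x$predictors),
              paste(sprintf("%s=%d", names(table(x$column_class)),
                            table(x$column_class)), collapse = ", ")))
  invisible(x)
}

#' Write a predictor set as TSV
#'
#' Samples x columns; the response column is named `response:<gene>` and each
#' predictor column `<class>:<id>`, so the file is self-describing.
#'
#' @param ps predictor set
#' @param path output path
#' @return `path`, invisibly
#' @export
write_predictor_set <- function(ps, path) {
  df <- data.frame(sample_id = names(ps$response),
                   ps$response, ps$predictors, check.names = FALSE)
  names(df) <- c("sample_id", paste0("response:", ps$trans_gene),
                 paste0(ps$column_class, ":", colnames(ps$predictors)))
  .write_tsv(df, path, hash = ps$region_id)
}

#' Read a predictor set written by [write_predictor_set()]
#' @param path file path
#' @param region_id region the set belongs to (stored in the file's comment
#'   line; pass explicitly when reading files from elsewhere)
#' @return predictor set
#' @export
read_predictor_set <- function(path, region_id = NULL) {
  if (is.null(region_id)) {
    l1 <- readLines(path, n = 1)
    region_id <- sub(".*config=", "", l1)
  }
  df <- .read_tsv(path)
  spec <- strsplit(names(df)[-1], ":", fixed = TRUE)
  cls <- vapply(spec, `[`, "", 1)
  ids <- vapply(spec, `[`, "", 2)
  ri <- which(cls == "response")
  X <- as.matrix(df[, -c(1, ri + 1), drop = FALSE])
  colnames(X) <- ids[-ri]
  rownames(X) <- df$sample_id
  structure(list(region_id = region_id, trans_gene = ids[ri],
                 response = stats::setNames(df[[ri + 1]], df$sample_id),
                 predictors = X,
                 column_class = stats::setNames(cls[-ri], ids[-ri])),
            class = "predictor_set")
}
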