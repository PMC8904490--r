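# Readers and writers for the external tables the pipeline touches.
#
# Internal coordinate convention: 0-based half-open [start, end), the BED
# interchange convention. SEG and GFF3 are 1-based inclusive on disk and are
# converted on read/write; BED is passed through. All validation happens at
# the boundary so downstream modules only ever see the internal convention.

.VALUE_KINDS <- c("raw_count", "rpm", "beta", "log2ratio")

#' Construct a validated expression matrix
#'
#' A plain numeric matrix (features x samples) with a `value_kind` attribute
#' declaring its unit: `raw_count` (non-negative integers, no missing values),
#' `rpm` (non-negative), `beta` (in \[0,1\], missing allowed -- methylation
#' coverage differs between platforms), or `log2ratio` (finite).
#'
#' @param values numeric matrix with unique row and column names
#' @param value_kind one of `"raw_count"`, `"rpm"`, `"beta"`, `"log2ratio"`
#' @return the matrix with a `value_kind` attribute
#' @export
expression_matrix <- function(values, value_kind) {
  value_kind <- match.arg(value_kind, .VALUE_KINDS)
  if (!is.matrix(values) || !is.numeric(values))
    .stopf("expression matrix must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .stopf("expression matrix needs row (feature) and column (sample) names")
  if (anyDuplicated(rownames(values))) .stopf("duplicate feature ids in matrix")
  if (anyDuplicated(colnames(values))) .stopf("duplicate sample ids in matrix")
  v <- values[is.finite(values)]
  if (value_kind == "raw_count") {
    if (anyNA(values)) .stopf("raw_count matrix may not contain missing values")
    if (any(values < 0) || any(abs(values - round(values)) > 1e-8))
      .stopf("raw_count values must be non-negative integers")
  } else if (value_kind == "beta") {
    if (any(v < 0 | v > 1)) .stopf("beta values must lie in [0, 1]")
  } else if (value_kind == "rpm") {
    if (anyNA(values)) .stopf("rpm matrix may not contain missing values")
    if (any(values < 0)) .stopf("rpm values must be non-negative")
  } else {
    if (anyNA(values) || any(!is.finite(values))) .stopf("log2ratio values must be finite")
  }
  attr(values, "value_kind") <- value_kind
  values
}

#' Value kind of an expression matrix
#' @param x matrix produced by [expression_matrix()] or [read_matrix()]
#' @return character scalar
#' @export
value_kind <- function(x) attr(x, "value_kind")

# ---- SEG -------------------------------------------------------------------

.seg_col_map <- c(
  sample = "sample_id", id = "sample_id", sample_id = "sample_id",
  chrom = "chrom", chromosome = "chrom",
  start = "start", loc.start = "start",
  end = "end", loc.end = "end",
  seg.mean = "log2_ratio", segment_mean = "log2_ratio", seg_mean = "log2_ratio",
  log2_ratio = "log2_ratio"
)

#' Read a SEG table of per-sample copy-number segments
#'
#' Expects a tab-separated header with sample, chromosome, start, end and
#' segment-mean columns (common spellings accepted, extra columns ignored).
#' Coordinates are normalized to the internal 0-based half-open convention;
#' the `dialect` argument states the convention of the file.
#'
#' Overlapping segments within one sample are rejected rather than silently
#' merged: how such overlaps arose upstream is unknowable here.
#'
#' @param path file path
#' @param dialect coordinate convention of the file; SEG files are 1-based
#'   inclusive by default
#' @return data.frame with columns sample_id, chrom, start, end, log2_ratio
#' @export
read_seg <- function(path, dialect = c("one_based_inclusive", "zero_based_half_open")) {
  dialect <- match.arg(dialect)
  df <- .read_tsv(path)
  nm <- tolower(names(df))
  hit <- match(names(.seg_col_map), nm)
  cols <- stats::setNames(hit, .seg_col_map[names(.seg_col_map)])
  need <- c("sample_id", "chrom", "start", "end", "log2_ratio")
  idx <- vapply(need, function(f) {
    i <- cols[names(cols) == f]
    i <- i[!is.na(i)]
    if (!length(i)) .stopf("SEG file %s lacks a '%s' column", path, f)
    i[[1]]
  }, integer(1))
  out <- df[, idx]
  names(out) <- need
  out$sample_id <- as.character(out$sample_id)
  out$chrom <- as.character(out$chrom)
  for (f in c("start", "end", "log2_ratio")) {
    x <- suppressWarnings(as.numeric(out[[f]]))
    bad <- which(!is.finite(x))
    if (length(bad))
      .stopf("SEG parse error in %s: non-numeric '%s' at data line %d", path, f, bad[1])
    out[[f]] <- x
  }
  if (dialect == "one_based_inclusive") out$start <- out$start - 1
  segment_table(out)
}

#' Construct a validated segment table (internal coordinates)
#'
#' @param df data.frame with sample_id, chrom, start, end, log2_ratio in the
#'   internal 0-based half-open convention
#' @return validated data.frame, sorted by sample, chrom, start
#' @export
segment_table <- function(df) {
  need <- c("sample_id", "chrom", "start", "end", "log2_ratio")
  if (!all(need %in% names(df))) .stopf("segment table needs columns: %s", paste(need, collapse = ", "))
  df <- df[need]
  bad <- which(df$end <= df$start)
  if (length(bad))
    .stopf("segment validation error: end <= start at row %d (%s %s:[%s,%s))",
           bad[1], df$sample_id[bad[1]], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]])
  if (any(!is.finite(df$log2_ratio))) .stopf("segment log2 ratios must be finite")
  df <- df[order(df$sample_id, df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  sp <- split(df, list(df$sample_id, df$chrom), drop = TRUE)
  for (g in sp) {
    if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)]))
      .stopf("overlapping segments within sample %s on %s", g$sample_id[1], g$chrom[1])
  }
  df
}

#' Write a SEG table
#' @param segs segment table in internal coordinates
#' @param path output path
#' @param dialect coordinate convention to write
#' @return `path`, invisibly
#' @export
write_seg <- function(segs, path, dialect = c("one_based_inclusive", "zero_based_half_open")) {
  dialect <- match.arg(dialect)
  out <- data.frame(Sample = segs$sample_id, Chromosome = segs$chrom,
                    Start = .as_coord(if (dialect == "one_based_inclusive") segs$start + 1 else segs$start),
                    End = .as_coord(segs$end), Segment_Mean = segs$log2_ratio)
  .write_tsv(out, path)
}

# ---- matrices --------------------------------------------------------------

#' Read a features-x-samples TSV matrix
#'
#' First column holds feature ids, remaining columns one sample each.
#' Rows must be rectangular; values are validated against `value_kind`
#' (see [expression_matrix()]).
#'
#' @param path file path
#' @param value_kind declared unit of the values
#' @return matrix with a `value_kind` attribute
#' @export
read_matrix <- function(path, value_kind = .VALUE_KINDS) {
  value_kind <- match.arg(value_kind)
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#", quote = "")
  if (length(unique(nf)) != 1)
    .stopf("ragged matrix file %s: rows have %s fields", path,
           paste(unique(nf), collapse = "/"))
  df <- .read_tsv(path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) .stopf("duplicate feature ids in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) .stopf("non-numeric values in matrix %s", path)
  rownames(m) <- ids
  expression_matrix(m, value_kind)
}

#' Write a features-x-samples matrix as TSV
#' @param mat matrix (row/col names required)
#' @param path output path
#' @param id_col header name for the feature-id column
#' @return `path`, invisibly
#' @export
write_matrix <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  .write_tsv(df, path)
}

# ---- features --------------------------------------------------------------

.FEATURE_KINDS <- c("gene", "mirna")

#' Construct a validated feature table
#' @param df data.frame with feature_id, kind, chrom, start, end, strand
#'   (internal 0-based half-open coordinates)
#' @return validated data.frame
#' @export
features <- function(df) {
  need <- c("feature_id", "kind", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df))) .stopf("feature table needs columns: %s", paste(need, collapse = ", "))
  df <- df[need]
  if (!all(df$kind %in% .FEATURE_KINDS))
    .stopf("unknown feature kind(s): %s (accepted: %s)",
           paste(setdiff(unique(df$kind), .FEATURE_KINDS), collapse = ", "),
           paste(.FEATURE_KINDS, collapse = ", "))
  df$strand[!(df$strand %in% c("+", "-"))] <- "*"
  if (any(df$end <= df$start)) .stopf("feature with end <= start")
  if (any(is.na(df$feature_id) | df$feature_id == "" | df$feature_id == "."))
    .stopf("feature with missing id")
  for (k in unique(df$kind)) {
    ids <- df$feature_id[df$kind == k]
    if (anyDuplicated(ids))
      .stopf("duplicate feature_id within kind '%s': %s", k, ids[duplicated(ids)][1])
  }
  rownames(df) <- NULL
  df
}

#' Read gene/miRNA annotations from BED or GFF3
#'
#' BED input (0-based half-open) is read with a 7th `kind` column when
#' present, else `default_kind` applies to the whole file. GFF3 input
#' (1-based inclusive, converted) takes the id from the `ID` attribute and
#' the kind from a `kind` attribute, falling back to the type column
#' (`miRNA` records map to kind `mirna`, everything else to `gene` unless a
#' kind is given).
#'
#' @param path file path
#' @param format `"bed"` or `"gff3lite"`
#' @param default_kind kind to assume when the file does not state one
#' @return feature table in internal coordinates (see [features()])
#' @export
read_features <- function(path, format = c("bed", "gff3lite"), default_kind = NULL) {
  format <- match.arg(format)
  if (format == "bed") {
    first <- readLines(path, n = 50)
    first <- first[!grepl("^(#|track|browser)", first)]
    if (!length(first)) .stopf("no records in %s", path)
    ncols <- length(strsplit(first[1], "\t", fixed = TRUE)[[1]])
    extra <- if (ncols >= 7) c(kind = "character") else character(0)
    gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
    d <- as.data.frame(gr)
    kind <- if ("kind" %in% names(d)) d$kind else {
      if (is.null(default_kind)) .stopf("BED %s has no kind column and no default_kind given", path)
      default_kind
    }
    out <- data.frame(feature_id = as.character(d$name), kind = kind,
                      chrom = as.character(d$seqnames),
                      start = d$start - 1L, end = d$end,  # back to 0-based half-open
                      strand = as.character(d$strand), stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
    d <- as.data.frame(gr)
    id <- if ("ID" %in% names(d)) as.character(d$ID) else NA_character_
    kind <- if ("kind" %in% names(d)) as.character(d$kind) else {
      k <- ifelse(tolower(as.character(d$type)) %in% c("mirna", "mirna_gene"), "mirna", "gene")
      if (!is.null(default_kind)) default_kind else k
    }
    out <- data.frame(feature_id = id, kind = kind,
                      chrom = as.character(d$seqnames),
                      start = d$start - 1L, end = d$end,
                      strand = as.character(d$strand), stringsAsFactors = FALSE)
  }
  features(out)
}

#' Write a feature table as BED6 + kind column
#' @param feats feature table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_features <- function(feats, path) {
  out <- data.frame(feats$chrom, .as_coord(feats$start), .as_coord(feats$end), feats$feature_id,
                    0L, ifelse(feats$strand %in% c("+", "-"), feats$strand, "."),
                    feats$kind)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- TF table --------------------------------------------------------------

.TF_GRADES <- c("A", "B", "C", "D", "E")

#' Read a TF -> target interaction table
#'
#' TSV with columns `tf_id`, `target_id` and an optional `confidence` grade
#' (A..E). Duplicate pairs are collapsed, keeping the best (earliest) grade.
#'
#' @param path file path
#' @return data.frame tf_id, target_id, confidence (NA when absent)
#' @export
read_tf_table <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("tf_id", "target_id") %in% names(df)))
    .stopf("TF table %s needs tf_id and target_id columns", path)
  conf <- if ("confidence" %in% names(df)) as.character(df$confidence) else NA_character_
  out <- data.frame(tf_id = as.character(df$tf_id),
                    target_id = as.character(df$target_id),
                    confidence = conf, stringsAsFactors = FALSE)
  bad <- !is.na(out$confidence) & !(out$confidence %in% .TF_GRADES)
  if (any(bad)) .stopf("unknown TF confidence grade '%s' (accepted: %s)",
                       out$confidence[bad][1], paste(.TF_GRADES, collapse = ", "))
  out <- out[order(out$tf_id, out$target_id, out$confidence), , drop = FALSE]
  out <- out[!duplicated(out[c("tf_id", "target_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a TF -> target interaction table
#' @param tf data.frame with tf_id, target_id, optional confidence
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tf_table <- function(tf, path) .write_tsv(tf, path)
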