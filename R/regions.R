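# Recurrent-aberration region calling and per-sample aberration status.
#
# The caller is a deliberately simple GISTIC-like scorer: per fixed-width bin
# and direction it sums, over samples, the excess of the sample's
# overlap-weighted mean log2 ratio beyond the amplification (or below the
# deletion) threshold, and compares each bin's score against an empirical
# null built from random cyclic shifts of every sample's bin profile within
# each chromosome. Significant (BH) contiguous bins are merged into regions.
# It stands in for an upstream region caller; externally computed region
# tables are first-class input via read_region_table().

#' Region-caller configuration
#'
#' @param bin_size bin width in bp
#' @param amp_threshold log2-ratio excess threshold for amplification scoring
#' @param del_threshold log2-ratio threshold for deletion scoring (negative)
#' @param n_permutations cyclic-shift permutations for the empirical null
#' @param q_cutoff BH q-value cutoff for significant bins
#' @param min_region_bins minimum run length of significant bins
#' @return config list
#' @export
region_caller_config <- function(bin_size = 50000L, amp_threshold = 0.1,
                                 del_threshold = -0.1, n_permutations = 200L,
                                 q_cutoff = 0.25, min_region_bins = 2L) {
  stopifnot(amp_threshold > 0, del_threshold < 0)
  if (!.is_count(n_permutations) || n_permutations < 100)
    .stopf("n_permutations must be an integer >= 100")
  stopifnot(.is_count(bin_size), .is_prob(q_cutoff), .is_count(min_region_bins))
  list(bin_size = as.integer(bin_size), amp_threshold = amp_threshold,
       del_threshold = del_threshold, n_permutations = as.integer(n_permutations),
       q_cutoff = q_cutoff, min_region_bins = as.integer(min_region_bins))
}

## samples x bins matrix of overlap-weighted mean log2 per chromosome
.bin_profile <- function(segs, samples, bin_size) {
  chroms <- sort(unique(segs$chrom))
  lapply(stats::setNames(chroms, chroms), function(ch) {
    sc <- segs[segs$chrom == ch, , drop = FALSE]
    lo <- floor(min(sc$start) / bin_size) * bin_size
    hi <- ceiling(max(sc$end) / bin_size) * bin_size
    starts <- seq(lo, hi - bin_size, by = bin_size)
    nb <- length(starts)
    V <- matrix(0, length(samples), nb, dimnames = list(samples, NULL))
    W <- matrix(0, length(samples), nb)
    for (i in seq_len(nrow(sc))) {
      s <- match(sc$sample_id[i], samples)
      if (is.na(s)) next
      b0 <- floor((sc$start[i] - lo) / bin_size) + 1
      b1 <- floor((sc$end[i] - 1 - lo) / bin_size) + 1
      idx <- b0:b1
      ov <- .overlap_len(sc$start[i], sc$end[i], starts[idx], starts[idx] + bin_size)
      V[s, idx] <- V[s, idx] + ov * sc$log2_ratio[i]
      W[s, idx] <- W[s, idx] + ov
    }
    X <- V / W
    X[W == 0] <- NA
    list(x = X, starts = starts)
  })
}

#' Call recurrent aberration regions from segmented profiles
#'
#' Amplifications and deletions are scored independently; a locus may yield
#' both an amp and a del region. Bins covered in fewer than half the samples
#' are skipped. Deterministic given `seed`.
#'
#' @param segs segment table (internal coordinates, see [segments()])
#' @param cfg [region_caller_config()]
#' @param seed integer seed for the permutation null
#' @return data.frame region_id, chrom, start, end, direction, score, q_value
#'   (zero rows when nothing is significant)
#' @export
call_regions <- function(segs, cfg = region_caller_config(), seed = 1L) {
  samples <- sort(unique(segs$sample_id))
  if (length(samples) < 2) .stopf("region calling needs at least 2 samples")
  prof <- .bin_profile(segs, samples, cfg$bin_size)
  chroms <- names(prof)
  nb_chr <- vapply(prof, function(p) length(p$starts), integer(1))
  X <- do.call(cbind, lapply(prof, `[[`, "x"))
  starts <- unlist(lapply(prof, `[[`, "starts"), use.names = FALSE)
  chrom_of <- rep(chroms, nb_chr)
  tested <- colSums(!is.na(X)) >= 0.5 * length(samples)

  score_mat <- function(thr, dir) {
    P <- if (dir == "amp") pmax(X - thr, 0) else pmax(thr - X, 0)
    P[is.na(P)] <- 0
    P
  }
  Pa <- score_mat(cfg$amp_threshold, "amp")
  Pd <- score_mat(cfg$del_threshold, "del")
  Ga <- colSums(Pa); Gd <- colSums(Pd)

  ## permutation null: per permutation, cyclic-shift each sample's profile
  ## within each chromosome; pool permuted bin scores across bins & perms
  blocks <- split(seq_along(chrom_of), chrom_of)[chroms]
  nulls_a <- matrix(0, cfg$n_permutations, ncol(X))
  nulls_d <- matrix(0, cfg$n_permutations, ncol(X))
  .with_seed(as.integer(seed), {
    for (p in seq_len(cfg$n_permutations)) {
      ga <- numeric(ncol(X)); gd <- numeric(ncol(X))
      for (s in seq_along(samples)) {
        for (bl in blocks) {
          nb <- length(bl)
          k <- sample.int(nb, 1L) - 1L
          idx <- bl[((seq_len(nb) - 1L + k) %% nb) + 1L]
          ga[bl] <- ga[bl] + Pa[s, idx]
          gd[bl] <- gd[bl] + Pd[s, idx]
        }
      }
      nulls_a[p, ] <- ga
      nulls_d[p, ] <- gd
    }
  })

  emp_p <- function(obs, null_pool) {
    ns <- sort(null_pool)
    n <- length(ns)
    (1 + n - findInterval(obs, ns, left.open = TRUE)) / (1 + n)
  }
  regions_for <- function(G, nulls, dir) {
    idx <- which(tested)
    if (!length(idx)) return(NULL)
    p <- emp_p(G[idx], as.vector(nulls[, idx]))
    p[G[idx] <= 0] <- 1
    q <- stats::p.adjust(p, method = "BH")
    sig <- idx[q <= cfg$q_cutoff & G[idx] > 0]
    qv <- stats::setNames(q, idx)
    if (!length(sig)) return(NULL)
    runs <- split(sig, cumsum(c(1, diff(sig) != 1)))
    runs <- Filter(function(r) length(r) >= cfg$min_region_bins &&
                     length(unique(chrom_of[r])) == 1, runs)
    if (!length(runs)) return(NULL)
    do.call(rbind, lapply(runs, function(r) {
      data.frame(chrom = chrom_of[r[1]],
                 start = starts[r[1]],
                 end = starts[r[length(r)]] + cfg$bin_size,
                 direction = dir,
                 score = max(G[r]),
                 q_value = min(qv[as.character(r)]),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(regions_for(Ga, nulls_a, "amp"), regions_for(Gd, nulls_d, "del"))
  if (is.null(out) || !nrow(out)) {
    return(data.frame(region_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0), direction = character(0),
                      score = numeric(0), q_value = numeric(0)))
  }
  out <- out[order(out$direction, out$chrom, out$start), , drop = FALSE]
  out <- cbind(region_id = sprintf("%s_%s_%d", out$direction, out$chrom,
                                   stats::ave(seq_len(nrow(out)),
                                              paste(out$direction, out$chrom),
                                              FUN = seq_along)),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read an externally computed region table
#'
#' TSV with region_id, chrom, start, end, direction (`amp`/`del`), optional
#' score and q columns. Coordinates are taken as 1-based inclusive unless
#' `dialect` says otherwise.
#'
#' @param path file path
#' @param dialect coordinate convention of the file
#' @return region table as from [call_regions()] (status not yet assigned)
#' @export
read_region_table <- function(path, dialect = c("one_based_inclusive", "zero_based_half_open")) {
  dialect <- match.arg(dialect)
  df <- .read_tsv(path)
  need <- c("region_id", "chrom", "start", "end", "direction")
  if (!all(need %in% names(df))) .stopf("region table needs columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$region_id)) .stopf("duplicate region_id in %s", path)
  bad <- setdiff(unique(df$direction), c("amp", "del"))
  if (length(bad)) .stopf("unknown direction '%s' (accepted tokens: amp, del)", bad[1])
  out <- data.frame(region_id = as.character(df$region_id), chrom = as.character(df$chrom),
                    start = as.numeric(df$start), end = as.numeric(df$end),
                    direction = as.character(df$direction),
                    score = if ("score" %in% names(df)) as.numeric(df$score) else NA_real_,
                    q_value = if ("q_value" %in% names(df)) as.numeric(df$q_value) else NA_real_,
                    stringsAsFactors = FALSE)
  if (dialect == "one_based_inclusive") out$start <- out$start - 1
  if (any(out$end <= out$start)) .stopf("region with end <= start in %s", path)
  out
}

#' Write a region table
#' @param regions region table
#' @param path output path
#' @param dialect coordinate convention to write
#' @return `path`, invisibly
#' @export
write_region_table <- function(regions, path,
                               dialect = c("one_based_inclusive", "zero_based_half_open")) {
  dialect <- match.arg(dialect)
  out <- regions
  if (dialect == "one_based_inclusive") out$start <- out$start + 1
  out$start <- .as_coord(out$start)
  out$end <- .as_coord(out$end)
  .write_tsv(out, path)
}

## overlap-weighted mean log2 of one sample's segments over [start,end)
.weighted_region_mean <- function(sc, start, end) {
  ov <- .overlap_len(sc$start, sc$end, start, end)
  keep <- ov > 0
  if (!any(keep)) return(NA_real_)
  sum(sc$log2_ratio[keep] * ov[keep]) / sum(ov[keep])
}

#' Assign per-sample aberration status for one region
#'
#' A sample is `aberrated` iff its overlap-weighted mean log2 ratio over the
#' region is strictly above `amp_threshold` (amp regions) or strictly below
#' `del_threshold` (del regions); values exactly at the threshold, and
#' samples with no overlapping segment, are `non_aberrated`.
#'
#' @param region one-row region table (or list) with chrom, start, end, direction
#' @param segs segment table
#' @param samples sample universe; defaults to samples present in `segs`
#' @param amp_threshold,del_threshold status thresholds
#' @return named character vector over samples with values
#'   `"aberrated"`/`"non_aberrated"`
#' @export
assign_status <- function(region, segs, samples = NULL,
                          amp_threshold = 0.1, del_threshold = -0.1) {
  samples <- samples %||% sort(unique(segs$sample_id))
  sc <- segs[segs$chrom == region$chrom, , drop = FALSE]
  means <- vapply(samples, function(s) {
    .weighted_region_mean(sc[sc$sample_id == s, , drop = FALSE], region$start, region$end)
  }, numeric(1))
  if (all(is.na(means)))
    .warnf("region %s overlaps no segments in any sample; all non_aberrated",
           region$region_id %||% "?")
  else if (anyNA(means))
    message(sprintf("region %s: %d sample(s) without overlapping segments set non_aberrated",
                    region$region_id %||% "?", sum(is.na(means))))
  ab <- if (region$direction == "amp") !is.na(means) & means > amp_threshold
        else !is.na(means) & means < del_threshold
  stats::setNames(ifelse(ab, "aberrated", "non_aberrated"), samples)
}

#' Aberration status matrix for a set of regions
#' @param regions region table
#' @param segs segment table
#' @param samples optional sample universe
#' @param amp_threshold,del_threshold status thresholds
#' @return character matrix regions x samples
#' @export
region_status_matrix <- function(regions, segs, samples = NULL,
                                 amp_threshold = 0.1, del_threshold = -0.1) {
  samples <- samples %||% sort(unique(segs$sample_id))
  m <- t(vapply(seq_len(nrow(regions)), function(i) {
    assign_status(regions[i, ], segs, samples, amp_threshold, del_threshold)
  }, character(length(samples))))
  rownames(m) <- regions$region_id
  m
}

#' Feature-centric copy number
#'
#' Per sample, the overlap-weighted mean log2 ratio of the segments
#' intersecting the feature; samples without any overlapping segment get the
#' `fill` value (logged).
#'
#' @param feature one-row feature table (or list) with chrom, start, end
#' @param segs segment table
#' @param samples optional sample universe
#' @param fill value for samples with zero overlap
#' @return named numeric vector over samples
#' @export
feature_centric_cn <- function(feature, segs, samples = NULL, fill = 0) {
  if (feature$end <= feature$start) .stopf("feature must have positive length")
  samples <- samples %||% sort(unique(segs$sample_id))
  sc <- segs[segs$chrom == feature$chrom, , drop = FALSE]
  means <- vapply(samples, function(s) {
    .weighted_region_mean(sc[sc$sample_id == s, , drop = FALSE], feature$start, feature$end)
  }, numeric(1))
  if (anyNA(means))
    message(sprintf("feature %s: %d sample(s) without overlapping segment, filled with %s",
                    feature$feature_id %||% "?", sum(is.na(means)), format(fill)))
  means[is.na(means)] <- fill
  means
}

#' Feature-centric copy-number matrix for many features
#' @inheritParams feature_centric_cn
#' @param feats feature table
#' @return numeric matrix features x samples
#' @export
feature_cn_matrix <- function(feats, segs, samples = NULL, fill = 0) {
  samples <- samples %||% sort(unique(segs$sample_id))
  m <- t(vapply(seq_len(nrow(feats)), function(i) {
    suppressMessages(feature_centric_cn(feats[i, ], segs, samples, fill))
  }, numeric(length(samples))))
  rownames(m) <- feats$feature_id
  m
}
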