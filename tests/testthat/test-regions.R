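# Region calling, status assignment and feature-centric copy number.

seg1 <- function(sample, chrom, start, end, lr) {
  data.frame(sample_id = sample, chrom = chrom, start = start, end = end,
             log2_ratio = lr, stringsAsFactors = FALSE)
}

test_that("aberration status follows the strict +/-0.1 weighted-mean rule", {
  reg_amp <- list(region_id = "ra", chrom = "chr1", start = 1000, end = 2000,
                  direction = "amp")
  reg_del <- modifyList(reg_amp, list(region_id = "rd", direction = "del"))
  segs <- segment_table(rbind(
    seg1("S1", "chr1", 0, 5000, 0.15),
    seg1("S2", "chr1", 0, 5000, 0.0),
    seg1("S3", "chr1", 0, 5000, -0.25),
    seg1("S4", "chr1", 0, 5000, 0.1)))   # exactly at the boundary
  st <- assign_status(reg_amp, segs)
  expect_identical(unname(st[c("S1", "S2", "S4")]),
                   c("aberrated", "non_aberrated", "non_aberrated"))
  sd_ <- assign_status(reg_del, segs)
  expect_identical(unname(sd_["S3"]), "aberrated")
  expect_identical(unname(sd_["S1"]), "non_aberrated")
})

test_that("status uses the overlap-weighted mean and is monotone in log2", {
  reg <- list(region_id = "r", chrom = "chr1", start = 0, end = 1000, direction = "amp")
  base <- rbind(seg1("S1", "chr1", 0, 600, 0.5), seg1("S1", "chr1", 600, 1000, -0.5))
  # 60/40 split: weighted mean = 0.1, not strictly above -> non_aberrated
  expect_identical(unname(assign_status(reg, segment_table(base))["S1"]), "non_aberrated")
  prev <- -Inf
  for (bump in c(0, 0.05, 0.2, 1)) {
    segs <- base; segs$log2_ratio <- segs$log2_ratio + bump
    st <- assign_status(reg, segment_table(segs))["S1"]
    # increasing log2 never flips aberrated back to non_aberrated
    expect_gte(match(st, c("non_aberrated", "aberrated")), prev)
    prev <- match(st, c("non_aberrated", "aberrated"))
  }
})

test_that("feature-centric CN is the overlap-weighted segment mean with documented fill", {
  segs <- segment_table(rbind(
    seg1("S1", "chr1", 0, 600, 0.5), seg1("S1", "chr1", 600, 1000, -0.5),
    seg1("S2", "chr1", 0, 1000, 0.3),
    seg1("S3", "chr2", 0, 1000, 0.9)))
  gene <- list(feature_id = "g", chrom = "chr1", start = 0, end = 1000)
  cn <- suppressMessages(feature_centric_cn(gene, segs))
  expect_equal(unname(cn["S2"]), 0.3)        # fully inside one segment
  expect_equal(unname(cn["S1"]), 0.1)        # 60%/40% of 0.5/-0.5
  expect_equal(unname(cn["S3"]), 0)          # no overlap -> fill
  expect_message(feature_centric_cn(gene, segs), "without overlapping segment")
  # coincides with the status weighted mean when the feature is the region
  reg <- list(region_id = "r", chrom = "chr1", start = 0, end = 1000, direction = "amp")
  st <- assign_status(reg, segs, samples = c("S1", "S2"))
  expect_identical(unname(st["S2"]), "aberrated")  # 0.3 > 0.1 == cn
})

test_that("a flat cohort yields no regions and one sample is rejected", {
  samples <- sprintf("S%02d", 1:10)
  segs <- segment_table(do.call(rbind, lapply(samples, function(s)
    seg1(s, "chr1", 0, 1e6, 0))))
  cfg <- region_caller_config(bin_size = 5e4, n_permutations = 100)
  out <- call_regions(segs, cfg, seed = 1)
  expect_equal(nrow(out), 0)
  expect_error(call_regions(segs[segs$sample_id == "S01", ], cfg), "2 samples")
})

make_planted_segs <- function(seed, n = 50, chrom_len = 5e6, r0 = 1e6, r1 = 2e6,
                              lr = 0.8, frac = 0.6) {
  set.seed(seed)
  carriers <- sample(sprintf("S%02d", 1:n), round(frac * n))
  rows <- lapply(sprintf("S%02d", 1:n), function(s) {
    if (s %in% carriers) {
      rbind(seg1(s, "chr1", 0, r0, rnorm(1, 0, 0.03)),
            seg1(s, "chr1", r0, r1, lr + rnorm(1, 0, 0.03)),
            seg1(s, "chr1", r1, chrom_len, rnorm(1, 0, 0.03)))
    } else {
      seg1(s, "chr1", 0, chrom_len, rnorm(1, 0, 0.03))
    }
  })
  list(segs = segment_table(do.call(rbind, rows)), carriers = carriers)
}

test_that("the caller recovers a planted amp region and its mirror deletion", {
  fx <- make_planted_segs(seed = 42)
  cfg <- region_caller_config(bin_size = 2e4, n_permutations = 150, q_cutoff = 0.25)
  out <- call_regions(fx$segs, cfg, seed = 7)
  amp <- out[out$direction == "amp", ]
  expect_equal(nrow(amp), 1)
  expect_lte(abs(amp$start - 1e6), cfg$bin_size)
  expect_lte(abs(amp$end - 2e6), cfg$bin_size)
  expect_equal(nrow(out[out$direction == "del", ]), 0)

  flipped <- fx$segs; flipped$log2_ratio <- -flipped$log2_ratio
  out2 <- call_regions(flipped, cfg, seed = 7)
  del <- out2[out2$direction == "del", ]
  expect_equal(nrow(del), 1)
  expect_equal(del$start, amp$start)
  expect_equal(del$end, amp$end)
})

test_that("external region tables are validated on ingestion", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("region_id\tchrom\tstart\tend\tdirection", "r1\tchr2\t100\t200\tamp"), f)
  rt <- read_region_table(f)
  expect_equal(rt$start, 99)   # 1-based inclusive input
  expect_equal(rt$end, 200)

  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("region_id\tchrom\tstart\tend\tdirection", "r1\tchr2\t100\t200\tgain"), f2)
  expect_error(read_region_table(f2), "amp, del")

  f3 <- tempfile(fileext = ".tsv")
  writeLines(c("region_id\tchrom\tstart\tend\tdirection",
               "r1\tchr2\t100\t200\tamp", "r1\tchr3\t1\t50\tdel"), f3)
  expect_error(read_region_table(f3), "duplicate region_id")
})
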