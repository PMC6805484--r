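test_that("weighted_center applies count weighting and the 5' tie-break", {
  expect_equal(weighted_center(102L, 10), 102L)
  # tie at x.5 rounds toward 5': left on plus, right on minus
  expect_equal(weighted_center(c(10L, 11L), c(5, 5), "+"), 10L)
  expect_equal(weighted_center(c(10L, 11L), c(5, 5), "-"), 11L)
  # brute-force weighted mean over positions 0..10 with counts {0:1, 10:9}
  expect_equal(weighted_center(c(0L, 10L), c(1, 9), "+"), 9L)
  expect_error(weighted_center(c(1L, 2L), c(0, 0)), "all-zero")
})

test_that("NB upper tails match brute-force mass summation", {
  # oracle: P(X >= c) = 1 - sum_{k < c} dnbinom(k)
  for (r in c(0.5, 2, 18)) for (p in c(0.2, 0.6, 0.9)) {
    for (c_ in c(1L, 5L, 100L, 1000L)) {
      brute <- 1 - sum(stats::dnbinom(0:(c_ - 1), size = r, prob = p))
      fast <- stats::pnbinom(c_ - 1, size = r, prob = p, lower.tail = FALSE)
      expect_lt(abs(brute - fast), 1e-10)
    }
  }
})

test_that("resize_to_uniform_window builds centered windows and drops edges", {
  sl <- c(chr1 = 1000)
  peaks <- GRanges("chr1", IRanges(c(100, 3, 998), width = 1), strand = "+",
                   center = c(100L, 3L, 998L))
  seqlengths(peaks) <- sl
  w <- resize_to_uniform_window(peaks, width = 9)
  expect_equal(length(w), 1L)
  expect_equal(BiocGenerics::start(w), 96L)
  expect_equal(BiocGenerics::end(w), 104L)
  expect_equal(attr(w, "n_dropped"), 2L)

  w1 <- resize_to_uniform_window(peaks[1], width = 1)
  expect_equal(GenomicRanges::width(w1), 1L)
  expect_error(resize_to_uniform_window(peaks, width = 8), "odd")
})

test_that("sparse filter keeps exactly >= 3 covered positions", {
  win <- GRanges("chr1", IRanges(96, 104), strand = "+")
  mk <- function(npos) {
    make_track(data.frame(chrom = "chr1", pos = 96 + seq_len(npos) - 1,
                          count = 5, strand = "+"))
  }
  expect_false(sparse_filter(win, mk(2)))
  expect_true(sparse_filter(win, mk(3)))
  expect_true(sparse_filter(win, mk(9)))
  # exhaustive over all 2^9 coverage patterns vs the counting oracle
  for (mask in 0:511) {
    on <- which(bitwAnd(mask, 2^(0:8)) > 0)
    track <- if (length(on)) {
      make_track(data.frame(chrom = "chr1", pos = 95 + on, count = 1,
                            strand = "+"))
    } else {
      GRanges(count = integer(0))
    }
    expect_equal(unname(sparse_filter(win, track)), length(on) >= 3)
  }
})

test_that("merge_windows implements the cumulative half-maximum rule", {
  # windows centered 100 and 105, counts only at 100: merged center 100
  track <- make_track(data.frame(chrom = "chr1", pos = 100, count = 10,
                                 strand = "+"))
  w <- GRanges("chr1", IRanges(c(96, 101), width = 9), strand = "+")
  m <- merge_windows(w, track)
  expect_equal(length(m), 1L)
  expect_equal(BiocGenerics::start(m) + 4L, 100L)

  # identical windows collapse to themselves
  w2 <- GRanges("chr1", IRanges(c(96, 96), width = 9), strand = "+")
  m2 <- merge_windows(w2, track)
  expect_equal(length(m2), 1L)
  expect_equal(BiocGenerics::start(m2), 96L)

  # disjoint windows unchanged
  w3 <- GRanges("chr1", IRanges(c(96, 200), width = 9), strand = "+")
  m3 <- merge_windows(w3, track)
  expect_equal(length(m3), 2L)

  # idempotence and non-overlap
  m4 <- merge_windows(m, track)
  expect_identical(BiocGenerics::start(m4), BiocGenerics::start(m))
  expect_true(all(GenomicRanges::countOverlaps(m4, m4) == 1))
})

test_that("merge_windows output is independent of input order", {
  set.seed(21)
  for (rep in 1:20) {
    centers <- sort(sample(100:200, 8))
    counts <- data.frame(chrom = "chr1",
                         pos = sample(90:210, 40, TRUE),
                         count = sample(1:5, 40, TRUE), strand = "+")
    counts <- aggregate(count ~ chrom + pos + strand, counts, sum)
    track <- make_track(counts)
    w <- GRanges("chr1", IRanges(centers - 4, centers + 4), strand = "+")
    ref <- merge_windows(w, track)
    perm <- merge_windows(w[sample(length(w))], track)
    expect_identical(BiocGenerics::start(ref), BiocGenerics::start(perm))
    expect_true(all(GenomicRanges::countOverlaps(ref, ref) == 1))
  }
})

test_that("gene/region assignment follows single-gene rule and precedence", {
  ann <- tiny_annotation()
  w <- GRanges("chr1", IRanges(c(1500, 300, 5500, 3600, 210), width = 9),
               strand = c("+", "+", "+", "-", "-"))
  asg <- assign_gene_region(w, ann)
  expect_equal(asg$gene_id[1], "geneA")
  expect_equal(asg$region[1], "three_prime_utr")
  expect_equal(asg$region[2], "CDS")
  # intergenic: excluded
  expect_true(asg$excluded[3])
  expect_equal(asg$reason[3], "no_gene")
  # minus-strand gene, its 3' UTR
  expect_equal(asg$gene_id[4], "geneB")
  expect_equal(asg$region[4], "three_prime_utr")
  # window inside geneA's CDS but on the wrong strand: no same-strand gene
  expect_true(asg$excluded[5])

  # intron of the two-exon gene
  wi <- GRanges("chr2", IRanges(800, 808), strand = "+")
  expect_equal(assign_gene_region(wi, ann)$region, "intron")

  # a window overlapping two genes is excluded: build overlapping genes
  ann2 <- c(ann, tiny_annotation()[1:6])
  ann2$gene_id[seq(length(ann) + 1, length(ann2))] <- "geneA2"
  ann2$transcript_id[seq(length(ann) + 1, length(ann2))] <-
    ifelse(ann2$type[seq(length(ann) + 1, length(ann2))] == "gene", NA, "txA2")
  asg2 <- assign_gene_region(w[1], ann2)
  expect_true(asg2$excluded)
  expect_equal(asg2$reason, "multi_gene")

  ann_bad <- ann
  ann_bad$gene_type <- NULL
  expect_error(assign_gene_region(w, ann_bad), "gene_type")
})

test_that("reproducibility filter demands min events in every replicate", {
  win <- GRanges("chr1", IRanges(96, 104), strand = "+")
  mk <- function(n) make_track(data.frame(chrom = "chr1", pos = 98:100,
                                          count = c(n - 2, 1, 1),
                                          strand = "+"))
  tracks <- list(rep1 = mk(3), rep2 = mk(3), rep3 = mk(3))
  expect_true(reproducibility_filter(win, tracks, min_events = 3))
  tracks$rep3 <- make_track(data.frame(chrom = "chr1", pos = 98:99,
                                       count = 1, strand = "+"))
  expect_false(reproducibility_filter(win, tracks, min_events = 3))
  expect_true(reproducibility_filter(win, tracks, min_events = 0))
  # single-replicate mode reduces to a plain threshold
  expect_true(reproducibility_filter(win, tracks["rep1"], min_events = 3))
  expect_false(reproducibility_filter(win, tracks["rep3"], min_events = 3))
})

test_that("uniform track yields no raw peaks; a spike yields a 1-nt peak", {
  ann <- tiny_annotation()
  uni <- make_track(data.frame(chrom = "chr1", pos = 101:3000, count = 1,
                               strand = "+"))
  peaks <- call_raw_peaks(uni, ann)
  expect_equal(length(peaks), 0L)

  spike <- make_track(data.frame(
    chrom = "chr1",
    pos = c(seq(101, 3000, by = 20), 1500),
    count = c(rep(1, length(seq(101, 3000, by = 20))), 50),
    strand = "+"))
  peaks <- call_raw_peaks(spike, ann)
  expect_equal(length(peaks), 1L)
  expect_equal(BiocGenerics::start(peaks), 1500L)
  expect_equal(GenomicRanges::width(peaks), 1L)
  expect_equal(peaks$center, 1500L)
})

test_that("final sites are uniform, non-overlapping and fully annotated", {
  cfg <- simulation_config(n_genes = 30, seed = 23)
  ref <- generate_reference(cfg)
  tracks <- simulate_crosslink_tracks(ref$annotation, ref$truth, cfg)
  sites <- call_binding_sites(tracks, ref$annotation)
  expect_gt(length(sites), 0)
  expect_true(all(GenomicRanges::width(sites) == 9))
  expect_true(all(GenomicRanges::countOverlaps(sites, sites) == 1))
  expect_false(any(is.na(sites$gene_id)))
  expect_true(all(sites$region %in%
                    c("three_prime_utr", "five_prime_utr", "CDS")))
  expect_equal(sites$center, BiocGenerics::start(sites) + 4L)
  # merged count equals the sum of per-replicate window counts
  rep_cols <- paste0("count_", names(tracks))
  expect_equal(sites$merged_count,
               as.integer(rowSums(as.matrix(mcols(sites)[, rep_cols]))))
})

test_that("raw peaks fall back to Poisson when variance <= mean", {
  ann <- tiny_annotation()
  # constant counts except one spike: local variance can dip below the mean
  df <- data.frame(chrom = "chr1", pos = 1001:1600, count = 1L, strand = "+")
  df$count[300] <- 30L
  peaks <- call_raw_peaks(make_track(df), ann)
  expect_gte(attr(peaks, "n_poisson_fallback"), 0L)
  expect_true(1300 %in% BiocGenerics::start(peaks))
})
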