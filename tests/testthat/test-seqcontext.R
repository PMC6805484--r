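test_that("A-rich search honors thresholds, hierarchy, and ties", {
  p <- stretch_search_params()
  # all C: nothing survives
  expect_null(find_arich_stretch_seq(strrep("C", 55), p))
  # 30 A then 25 C: the full 30-nt A window at offset 0 wins (LCA 30)
  st <- find_arich_stretch_seq(paste0(strrep("A", 30), strrep("C", 25)), p)
  expect_equal(st$offset, 0)
  expect_equal(st$width, 30)
  expect_equal(st$lca, 30)
  # CC + 12 A + C...: 12-nt all-A stretch at offset 2
  st2 <- find_arich_stretch_seq(
    paste0("CC", strrep("A", 12), strrep("C", 41)), p)
  expect_equal(st2$offset, 2)
  expect_equal(st2$width, 12)
  expect_equal(st2$a_content, 1)
  expect_equal(st2$weighted_a, 12)
  # a pure 10-A run fails the default weighted-A floor (10 < 11)
  expect_null(find_arich_stretch_seq(
    paste0(strrep("A", 10), strrep("C", 45)), p))
  # but survives under the all-fail exclusion reading
  p_all <- stretch_search_params(exclusion = "all_fail")
  st3 <- find_arich_stretch_seq(
    paste0(strrep("A", 10), strrep("C", 45)), p_all)
  expect_false(is.null(st3))
})

test_that("A-rich search agrees with the exhaustive oracle", {
  set.seed(41)
  p <- stretch_search_params()
  for (i in 1:400) {
    s <- random_seq(55, p_a = runif(1, 0.1, 0.9))
    got <- find_arich_stretch_seq(s, p)
    want <- arich_oracle(s)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got[c("offset", "width", "lca")],
                   want[c("offset", "width", "lca")])
      expect_equal(got$weighted_a, want$weighted_a)
    }
    # every returned stretch satisfies its keep-thresholds
    if (!is.null(got)) {
      expect_gte(got$a_content, p$min_a_content)
      expect_gte(got$weighted_a, p$min_weighted_a)
      expect_gte(got$lca, p$min_lca)
    }
  }
})

test_that("genomic stretch search maps coordinates strand-aware", {
  # genome: plus-strand site at center 101 with 14 A's at +10;
  # minus-strand site at center 300 with the complement layout
  plusseq <- paste0(strrep("C", 100), strrep("G", 10), strrep("A", 14),
                    strrep("C", 120),
                    strrep("T", 14), strrep("C", 10), strrep("G", 160))
  genome <- Biostrings::DNAStringSet(c(chrT = plusseq))
  sites <- GRanges("chrT", IRanges(c(97, 296), width = 9),
                   strand = c("+", "-"), center = c(101L, 300L),
                   site_id = c("S1", "S2"))
  st <- find_arich_stretches(sites, genome)
  expect_equal(length(st), 2L)
  # plus: A-run at genomic 111..124, offset 10 from center 101
  expect_equal(BiocGenerics::start(st)[1], 111L)
  expect_equal(BiocGenerics::end(st)[1], 124L)
  expect_equal(st$offset[1], 10L)
  # minus: the T-run at genomic 245..258 reads as A on the minus strand, but
  # the 55-nt search space [246..300] clips its last base: 13 A's remain,
  # offset = 300 - 258 = 42
  expect_equal(BiocGenerics::start(st)[2], 246L)
  expect_equal(BiocGenerics::end(st)[2], 258L)
  expect_equal(st$offset[2], 42L)
  expect_equal(st$lca, c(14L, 13L))
})

test_that("overlapping stretches merge to the highest-scoring one", {
  mk <- function(start, end, lca, wa, id) {
    gr <- GRanges("chr1", IRanges(start, end), strand = "+")
    gr$site_ids <- IRanges::CharacterList(list(id))
    gr$a_content <- 0.9; gr$lca <- lca; gr$weighted_a <- wa
    gr$offset <- 0L
    gr
  }
  # identical stretches: one survivor linked to both sites
  s <- suppressWarnings(c(mk(100, 115, 12, 13, "S1"), mk(100, 115, 12, 13, "S2")))
  m <- merge_neighboring_stretches(s)
  expect_equal(length(m), 1L)
  expect_setequal(unlist(m$site_ids), c("S1", "S2"))
  # LCA 12 beats LCA 8
  s2 <- suppressWarnings(c(mk(100, 115, 12, 13, "S1"), mk(110, 125, 8, 14, "S2")))
  m2 <- merge_neighboring_stretches(s2)
  expect_equal(m2$lca, 12L)
  expect_equal(BiocGenerics::start(m2), 100L)
  # non-overlapping stretches are kept as-is
  s3 <- suppressWarnings(c(mk(100, 115, 12, 13, "S1"), mk(200, 215, 8, 14, "S2")))
  m3 <- merge_neighboring_stretches(s3)
  expect_equal(length(m3), 2L)
  # output is non-overlapping and a subset of the input
  expect_true(all(GenomicRanges::countOverlaps(m2, m2) == 1))
  expect_true(all(BiocGenerics::start(m2) %in% BiocGenerics::start(s2)))
})

test_that("positional k-mer profile counts offsets exactly", {
  # all sites identical: AAAA planted at offset +10 from center
  seqline <- paste0(strrep("C", 200), "G", strrep("C", 9), "AAAA",
                    strrep("C", 200))
  genome <- Biostrings::DNAStringSet(c(chrT = seqline))
  # center at the G (position 201); kmer starts at +10 relative to center
  sites <- GRanges("chrT", IRanges(197, 205), strand = "+",
                   center = 201L, site_id = "S1")
  prof <- kmer_positional_profile(sites, genome, halfwindow = 50)
  expect_equal(unname(prof["10", "AAAA"]), 1)
  expect_equal(sum(prof[, "AAAA"]), 1)  # only one placement matches
  expect_equal(sum(prof[, "GGGG"]), 0)  # absent k-mer: all-zero profile
  # uniform random background: mean frequency near (1/4)^4
  ra <- random_genome_annotation(n_genes = 4, seed = 43)
  set.seed(44)
  ctr <- sample(2000:8000, 400)
  rs <- GRanges("chrS", IRanges(ctr - 4, ctr + 4), strand = "+",
                center = ctr, site_id = sprintf("r%d", seq_along(ctr)))
  profr <- kmer_positional_profile(rs, ra$genome, kmers = "ACGT",
                                   halfwindow = 50)
  expect_lt(abs(mean(profr) - 0.25^4), 3 * sqrt(0.25^4 / (400 * 101)) + 1e-3)
})

test_that("k-mer z-scores are seed-deterministic and detect planted signal", {
  ra <- random_genome_annotation(n_genes = 12, seed = 45,
                                 base_prob = c(A = .15, C = .3, G = .3,
                                               T = .25))
  genome <- ra$genome
  ann <- ra$annotation
  # plant a 15-A run 12 nt downstream of each site center, sites in 3' UTRs
  u3 <- ann[ann$type == "three_prime_utr" & strand(ann) == "+"]
  ctr <- BiocGenerics::start(u3) + 300L
  chars <- strsplit(as.character(genome[[1]]), "")[[1]]
  for (c_ in ctr) chars[(c_ + 12):(c_ + 26)] <- "A"
  genome2 <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome2) <- "chrS"
  sites <- GRanges("chrS", IRanges(ctr - 4, ctr + 4), strand = "+",
                   center = ctr, site_id = sprintf("S%d", seq_along(ctr)))
  z1 <- kmer_zscores(sites, genome2, ann, bg_windows = 200, bg_repeats = 40,
                     seed = 5)
  z2 <- kmer_zscores(sites, genome2, ann, bg_windows = 200, bg_repeats = 40,
                     seed = 5)
  expect_identical(z1, z2)
  za <- z1[z1$kmer == "AAAA" & z1$class == "downstream", "z"]
  expect_gt(za, 5)
  # a new seed must not flip the conclusion: z stays high, and the relative
  # change stays within ~3x the z estimator's own relative s.d. (the
  # background s.d. of a rare k-mer is a skewed small-count statistic, so
  # its relative s.d. well exceeds the Gaussian 1/sqrt(2(B-1)); a factor-2
  # skew allowance gives 3 * 2 / sqrt(2 * 39) ~ 0.68, tested at 0.5)
  z3 <- kmer_zscores(sites, genome2, ann, bg_windows = 200, bg_repeats = 40,
                     seed = 6)
  zb <- z3[z3$kmer == "AAAA" & z3$class == "downstream", "z"]
  expect_gt(zb, 5)
  expect_lt(abs(za - zb) / max(za, zb), 0.5)
  # observed equal to background mean implies z = 0 by construction
  fake <- z1[1, ]
  expect_equal((fake$bg_mean - fake$bg_mean) / max(fake$bg_sd, 1), 0)
})

test_that("SOB stratification by LCA does its bookkeeping", {
  sites <- GRanges("chr1", IRanges(c(100, 200, 300) - 4,
                                   c(100, 200, 300) + 4), strand = "+",
                   site_id = c("S1", "S2", "S3"),
                   sob = c(10, 20, 30), sob_defined = TRUE)
  st <- GRanges("chr1", IRanges(c(110, 210), width = 14), strand = "+")
  st$site_ids <- IRanges::CharacterList(list("S1", "S2"))
  st$lca <- c(8L, 8L)
  out <- stratify_sob_by_lca(sites, st)
  expect_equal(out$n[out$lca == "8"], 2L)
  expect_equal(out$mean_sob[out$lca == "8"], 15)
  # the "none" group holds exactly the stretch-less sites
  expect_equal(out$n[out$lca == "none"], 1L)
  expect_equal(out$mean_sob[out$lca == "none"], 30)
  # constant SOB: all groups share the mean; sd 0 where n > 1 (NA at n = 1)
  sites$sob <- 7
  out2 <- stratify_sob_by_lca(sites, st)
  expect_true(all(out2$mean_sob == 7))
  expect_true(all(out2$sd_sob[out2$n > 1] == 0))
})
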