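# Shared fixtures, all built in code.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# A hand-built two-chromosome annotation:
#   geneA (chr1, +): 1-exon, 5'UTR 101-200, CDS 201-1000, 3'UTR 1001-3000
#   geneB (chr1, -): 1-exon, 3'UTR 3501-3800, CDS 3801-4400, 5'UTR 4401-4500
#   geneC (chr2, +): 2 exons 101-600 and 1101-1600 (intron 601-1100),
#                    CDS 101-1350 (split), 3'UTR 1351-1600
tiny_annotation <- function(seqlen = c(chr1 = 6000, chr2 = 3000)) {
  df <- rbind(
    data.frame(chrom = "chr1", start = 101, end = 3000, strand = "+",
               type = c("gene", "transcript", "exon")),
    data.frame(chrom = "chr1", start = 101, end = 200, strand = "+",
               type = "five_prime_utr"),
    data.frame(chrom = "chr1", start = 201, end = 1000, strand = "+",
               type = "CDS"),
    data.frame(chrom = "chr1", start = 1001, end = 3000, strand = "+",
               type = "three_prime_utr")
  )
  df$gene_id <- "geneA"; df$transcript_id <- "txA"
  db <- rbind(
    data.frame(chrom = "chr1", start = 3501, end = 4500, strand = "-",
               type = c("gene", "transcript", "exon")),
    data.frame(chrom = "chr1", start = 4401, end = 4500, strand = "-",
               type = "five_prime_utr"),
    data.frame(chrom = "chr1", start = 3801, end = 4400, strand = "-",
               type = "CDS"),
    data.frame(chrom = "chr1", start = 3501, end = 3800, strand = "-",
               type = "three_prime_utr")
  )
  db$gene_id <- "geneB"; db$transcript_id <- "txB"
  dc <- rbind(
    data.frame(chrom = "chr2", start = 101, end = 1600, strand = "+",
               type = c("gene", "transcript")),
    data.frame(chrom = "chr2", start = c(101, 1101), end = c(600, 1600),
               strand = "+", type = "exon"),
    data.frame(chrom = "chr2", start = c(101, 1101), end = c(600, 1350),
               strand = "+", type = "CDS"),
    data.frame(chrom = "chr2", start = 1351, end = 1600, strand = "+",
               type = "three_prime_utr")
  )
  dc$gene_id <- "geneC"; dc$transcript_id <- "txC"
  d <- rbind(df, db, dc)
  ann <- GRanges(d$chrom, IRanges(d$start, d$end), strand = d$strand,
                 type = d$type, gene_id = d$gene_id,
                 transcript_id = ifelse(d$type == "gene", NA, d$transcript_id),
                 gene_type = "protein_coding", level = 1L,
                 transcript_support_level = ifelse(d$type == "gene",
                                                   NA_integer_, 1L))
  seqlevels(ann) <- names(seqlen)
  seqlengths(ann) <- seqlen
  ann
}

# Track from a compact table: data.frame(chrom, pos, count, strand).
make_track <- function(df, seqlen = c(chr1 = 6000, chr2 = 3000)) {
  crosslink_track(df$chrom, df$pos, df$count, df$strand, seqlengths = seqlen)
}

# Uniform-random genome with a given A probability, plus a matching
# single-gene-per-block annotation whose 3' UTRs tile most of each gene.
# Used for k-mer null tests.
random_genome_annotation <- function(n_genes = 20, gene_len = 3000,
                                     utr3_len = 2000, gap = 400,
                                     base_prob = c(A = .25, C = .25,
                                                   G = .25, T = .25),
                                     seed = 1) {
  set.seed(seed)
  chrom_len <- n_genes * (gene_len + gap) + 2000
  chars <- sample(names(base_prob), chrom_len, TRUE, prob = base_prob)
  genome <- DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- "chrS"
  rows <- list()
  for (i in seq_len(n_genes)) {
    gstart <- 1000 + (i - 1) * (gene_len + gap)
    gend <- gstart + gene_len - 1
    strand <- if (i %% 2 == 0) "-" else "+"
    cds_len <- gene_len - utr3_len - 100
    u3 <- if (strand == "+") c(gend - utr3_len + 1, gend) else
      c(gstart, gstart + utr3_len - 1)
    gid <- sprintf("g%02d", i)
    rows[[i]] <- data.frame(
      chrom = "chrS",
      start = c(gstart, gstart, gstart, u3[1]),
      end = c(gend, gend, gend, u3[2]),
      strand = strand,
      type = c("gene", "transcript", "exon", "three_prime_utr"),
      gene_id = gid, transcript_id = paste0("t", gid))
  }
  d <- do.call(rbind, rows)
  ann <- GRanges(d$chrom, IRanges(d$start, d$end), strand = d$strand,
                 type = d$type, gene_id = d$gene_id,
                 transcript_id = ifelse(d$type == "gene", NA, d$transcript_id),
                 gene_type = "protein_coding", level = 1L,
                 transcript_support_level = ifelse(d$type == "gene",
                                                   NA_integer_, 1L))
  seqlevels(ann) <- "chrS"
  seqlengths(ann) <- c(chrS = chrom_len)
  list(genome = genome, annotation = ann)
}

# Literal brute-force oracle for the A-rich stretch search: enumerates every
# (window size, offset) placement, applies thresholds and the selection
# hierarchy exactly as stated, sharing no code with the implementation.
arich_oracle <- function(seq, min_size = 8, max_size = 30,
                         min_a_content = 0.70, min_weighted_a = 11,
                         min_lca = 4, exclusion = "any_fail") {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  per_size <- list()
  for (w in min_size:min(max_size, n)) {
    best <- NULL
    for (off in 0:(n - w)) {
      win <- chars[(off + 1):(off + w)]
      ac <- sum(win == "A") / w
      if (is.null(best) || ac > best$ac) {   # strict >: ties keep earlier
        r <- rle(win == "A")
        lca <- if (any(r$values)) max(r$lengths[r$values]) else 0
        best <- list(off = off, w = w, ac = ac, lca = lca,
                     wa = ac * sum(win == "A"))
      }
    }
    per_size[[length(per_size) + 1]] <- best
  }
  keep <- Filter(function(b) {
    fa <- b$ac < min_a_content; fw <- b$wa < min_weighted_a
    fl <- b$lca < min_lca
    if (exclusion == "any_fail") !(fa || fw || fl) else !(fa && fw && fl)
  }, per_size)
  if (length(keep) == 0) return(NULL)
  df <- do.call(rbind, lapply(keep, as.data.frame))
  df <- df[order(-df$lca, -df$wa, df$w, df$off), ]
  list(offset = df$off[1], width = df$w[1], a_content = df$ac[1],
       lca = df$lca[1], weighted_a = df$wa[1])
}

random_seq <- function(n, p_a = 0.25) {
  other <- (1 - p_a) / 3
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c(p_a, other, other, other)), collapse = "")
}
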