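#' Simulation configuration
#'
#' Bundles every tunable of the synthetic iCLIP world: a small two-chromosome
#' genome of single-exon protein-coding genes, negative-binomial crosslink
#' background scaled by log-normal per-gene expression, 9-nt enriched
#' footprints planted a fixed distance upstream of A-rich stretches in 3'
#' UTRs, and unmapped-style reads carrying untemplated terminal A-runs.
#'
#' @param n_genes Number of genes.
#' @param gene_length_range Min/max gene length (nt).
#' @param utr5_length 5' UTR length (nt, fixed).
#' @param utr3_length_range Min/max 3' UTR length (nt).
#' @param n_replicates Number of iCLIP replicates sharing site positions.
#' @param background_rate Expected crosslink events per exonic nt per
#'   replicate, before expression scaling.
#' @param site_enrichment Fold-increase of the crosslink rate inside planted
#'   footprints. A single number applies to all sites; a length-2 vector
#'   gives a range from which per-site enrichments are drawn log-uniformly.
#' @param dispersion Negative-binomial size parameter of the background.
#' @param frac_genes_with_stretch Fraction of genes whose 3' UTR carries a
#'   planted A-rich stretch (every gene carries one planted site).
#' @param stretch_length_range Min/max planted stretch length, within 8-30 nt.
#' @param stretch_purity Fraction of A inside a planted stretch (>= 0.7).
#' @param site_offset Distance (nt) from the planted footprint center to the
#'   stretch start; the footprint sits upstream.
#' @param polyA_read_fraction Fraction of simulated reads ending in >= 10
#'   untemplated A's.
#' @param read_length Read length (nt), including the 9-nt barcode.
#' @param n_reads Number of simulated reads.
#' @param experimental_barcode 4-nt sample barcode at read positions 4-7.
#' @param base_quality Phred score written for every base of simulated reads.
#' @param intergenic_gap Gap between adjacent genes (nt).
#' @param chrom_margin Gene-free margin at each chromosome end (nt).
#' @param seed Integer seed; identical seed + config gives byte-identical
#'   outputs.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 200,
                              gene_length_range = c(1500, 3000),
                              utr5_length = 150,
                              utr3_length_range = c(300, 800),
                              n_replicates = 3,
                              background_rate = 0.05,
                              site_enrichment = 50,
                              dispersion = 2,
                              frac_genes_with_stretch = 0.5,
                              stretch_length_range = c(15, 25),
                              stretch_purity = 0.95,
                              site_offset = 10,
                              polyA_read_fraction = 0.06,
                              read_length = 50,
                              n_reads = 10000,
                              experimental_barcode = "GGTT",
                              base_quality = 38,
                              intergenic_gap = 600,
                              chrom_margin = 1200,
                              seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    utr5_length = as.integer(utr5_length),
    utr3_length_range = as.integer(utr3_length_range),
    n_replicates = as.integer(n_replicates),
    background_rate = background_rate,
    site_enrichment = site_enrichment,
    dispersion = dispersion,
    frac_genes_with_stretch = frac_genes_with_stretch,
    stretch_length_range = as.integer(stretch_length_range),
    stretch_purity = stretch_purity,
    site_offset = as.integer(site_offset),
    polyA_read_fraction = polyA_read_fraction,
    read_length = as.integer(read_length),
    n_reads = as.integer(n_reads),
    experimental_barcode = experimental_barcode,
    base_quality = as.integer(base_quality),
    intergenic_gap = as.integer(intergenic_gap),
    chrom_margin = as.integer(chrom_margin),
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot_scalar(cfg$n_genes, "n_genes", min = 1)
  stopifnot_scalar(cfg$background_rate, "background_rate", min = 0)
  stopifnot_scalar(cfg$dispersion, "dispersion", min = 1e-9)
  stopifnot_scalar(cfg$frac_genes_with_stretch, "frac_genes_with_stretch",
                   min = 0, max = 1)
  stopifnot_scalar(cfg$polyA_read_fraction, "polyA_read_fraction",
                   min = 0, max = 1)
  stopifnot_scalar(cfg$stretch_purity, "stretch_purity", min = 0.7, max = 1)
  if (!all(cfg$site_enrichment >= 0)) stop("site_enrichment must be >= 0")
  if (!length(cfg$site_enrichment) %in% c(1L, 2L)) {
    stop("site_enrichment must be a scalar or a length-2 range")
  }
  r <- cfg$stretch_length_range
  if (length(r) != 2 || r[1] > r[2] || r[1] < 8 || r[2] > 30) {
    stop("stretch_length_range must lie within [8, 30]")
  }
  if (diff(cfg$gene_length_range) < 0 || diff(cfg$utr3_length_range) < 0) {
    stop("length ranges must be non-decreasing")
  }
  min_gene <- cfg$utr5_length + 300 + cfg$utr3_length_range[1]
  if (cfg$gene_length_range[1] < min_gene) {
    stop(sprintf("gene_length_range[1] must be >= %d to fit UTRs + 300-nt CDS",
                 min_gene))
  }
  if (cfg$stretch_length_range[2] + cfg$site_offset + 10 >
      cfg$utr3_length_range[1]) {
    stop("stretch longer than its host 3' UTR allows (configuration error)")
  }
  invisible(cfg)
}

sample_bases <- function(n, prob = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  sample(names(prob), n, replace = TRUE, prob = prob)
}

# Transcript coordinate (1-based, 5'->3') to genomic position.
t2g <- function(t, gstart, gend, strand) {
  if (strand == "+") gstart + t - 1L else gend - t + 1L
}

longest_a_run <- function(x) {
  # x: character vector of single bases, or a string
  if (length(x) == 1 && nchar(x) > 1) x <- strsplit(x, "")[[1]]
  r <- rle(x == "A")
  runs <- r$lengths[r$values]
  if (length(runs)) max(runs) else 0L
}

#' Generate a synthetic reference genome, annotation and ground truth
#'
#' Builds a two-chromosome genome of single-exon protein-coding genes, plants
#' one 9-nt binding-site footprint per gene in the 3' UTR and, for a
#' configured fraction of genes, an A-rich stretch beginning `site_offset` nt
#' downstream of the footprint center. Non-stretch 3' UTR sequence has an A
#' frequency of 0.2 so the planted stretches are the only A-rich signal.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `genome` (named `DNAStringSet`),
#'   `annotation` (GTF-style `GRanges` with gene/transcript/exon/CDS/UTR
#'   features), and `truth` (planted sites, stretches, per-gene expression,
#'   config echo).
#' @export
generate_reference <- function(config) {
  validate_simulation_config(config)
  with_seed(derive_seed(config$seed, 1), generate_reference_impl(config))
}

generate_reference_impl <- function(cfg) {
  n <- cfg$n_genes
  chrom <- rep(c("chr1", "chr2"), length.out = n)
  strand <- rep(c("+", "-"), length.out = n)
  glen <- if (diff(cfg$gene_length_range) == 0) rep(cfg$gene_length_range[1], n) else
    sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]), n, TRUE)
  u3 <- if (diff(cfg$utr3_length_range) == 0) rep(cfg$utr3_length_range[1], n) else
    sample(seq(cfg$utr3_length_range[1], cfg$utr3_length_range[2]), n, TRUE)
  u5 <- rep(cfg$utr5_length, n)
  has_stretch <- rep(FALSE, n)
  n_str <- round(cfg$frac_genes_with_stretch * n)
  if (n_str > 0) has_stretch[seq_len(n_str)] <- TRUE  # deterministic choice
  slen <- integer(n)
  if (any(has_stretch)) {
    r <- cfg$stretch_length_range
    slen[has_stretch] <- if (diff(r) == 0) r[1] else
      sample(seq(r[1], r[2]), sum(has_stretch), TRUE)
  }
  expression <- stats::rlnorm(n, 0, 1)
  enr <- if (length(cfg$site_enrichment) == 2) {
    exp(stats::runif(n, log(cfg$site_enrichment[1]),
                     log(cfg$site_enrichment[2])))
  } else {
    rep(cfg$site_enrichment, n)
  }

  # lay genes along their chromosome
  gstart <- integer(n); gend <- integer(n)
  cursor <- c(chr1 = cfg$chrom_margin + 1L, chr2 = cfg$chrom_margin + 1L)
  for (i in seq_len(n)) {
    gstart[i] <- cursor[chrom[i]]
    gend[i] <- gstart[i] + glen[i] - 1L
    cursor[chrom[i]] <- gend[i] + cfg$intergenic_gap + 1L
  }
  seqlen <- c(chr1 = max(gend[chrom == "chr1"], 0) + cfg$chrom_margin,
              chr2 = max(gend[chrom == "chr2"], 0) + cfg$chrom_margin)
  seqlen <- vapply(seqlen, as.integer, integer(1))

  chars <- lapply(seqlen, function(L) sample_bases(L))

  utr_prob <- c(A = 0.2, C = 0.3, G = 0.3, T = 0.2)
  site_center_t <- integer(n)   # transcript coordinate of footprint center
  stretch_start_t <- integer(n) # transcript coordinate of stretch start
  stretch_seqs <- character(n)
  for (i in seq_len(n)) {
    L <- glen[i]
    cds <- L - u5[i] - u3[i]
    u3start <- u5[i] + cds + 1L
    tx_seq <- sample_bases(L)
    tx_seq[u3start:L] <- sample_bases(u3[i], utr_prob)
    if (has_stretch[i]) {
      w <- slen[i]
      lo <- u3start + cfg$site_offset + 4L  # footprint fully inside 3' UTR
      hi <- L - w + 1L - 10L
      ss <- if (hi <= lo) lo else sample(seq(lo, hi), 1)
      stretch <- ifelse(stats::runif(w) < cfg$stretch_purity, "A",
                        sample(c("C", "G", "T"), w, TRUE))
      stretch[1] <- "A"
      tx_seq[ss:(ss + w - 1L)] <- stretch
      # keep the immediate neighborhood of the stretch non-A so the planted
      # boundaries are the true boundaries
      if (ss > 1L) tx_seq[ss - 1L] <- sample(c("C", "G", "T"), 1)
      if (ss + w <= L) tx_seq[ss + w] <- sample(c("C", "G", "T"), 1)
      stretch_start_t[i] <- ss
      stretch_seqs[i] <- paste(stretch, collapse = "")
      site_center_t[i] <- ss - cfg$site_offset
    } else {
      lo <- u3start + 5L
      hi <- L - 60L
      site_center_t[i] <- if (hi <= lo) lo else sample(seq(lo, hi), 1)
    }
    gseq <- if (strand[i] == "+") tx_seq else
      rev(chartr("ACGT", "TGCA", tx_seq))
    chars[[chrom[i]]][gstart[i]:gend[i]] <- gseq
  }

  genome <- Biostrings::DNAStringSet(vapply(chars, paste, character(1),
                                            collapse = ""))
  names(genome) <- names(seqlen)

  gene_id <- sprintf("gene%03d", seq_len(n))
  tx_id <- sprintf("tx%03d", seq_len(n))
  ann <- build_annotation(gene_id, tx_id, chrom, strand, gstart, gend,
                          u5, glen - u5 - u3, u3, seqlen)

  # truth tables (genomic coordinates, 1-based closed)
  ctr_g <- mapply(t2g, site_center_t, gstart, gend, strand)
  sites <- data.frame(
    gene_id = gene_id, chrom = chrom, strand = strand,
    center = as.integer(ctr_g),
    start = as.integer(ctr_g - 4L), end = as.integer(ctr_g + 4L),
    enrichment = enr, has_stretch = has_stretch,
    stringsAsFactors = FALSE
  )
  ws <- which(has_stretch)
  stretches <- data.frame(
    gene_id = gene_id[ws], chrom = chrom[ws], strand = strand[ws],
    start = integer(length(ws)), end = integer(length(ws)),
    length = slen[ws],
    purity = vapply(stretch_seqs[ws], function(s) {
      mean(strsplit(s, "")[[1]] == "A")
    }, numeric(1)),
    lca = vapply(stretch_seqs[ws], longest_a_run, integer(1)),
    stringsAsFactors = FALSE
  )
  if (length(ws)) {
    g1 <- mapply(t2g, stretch_start_t[ws], gstart[ws], gend[ws], strand[ws])
    g2 <- mapply(t2g, stretch_start_t[ws] + slen[ws] - 1L,
                 gstart[ws], gend[ws], strand[ws])
    stretches$start <- as.integer(pmin(g1, g2))
    stretches$end <- as.integer(pmax(g1, g2))
  }
  rownames(stretches) <- NULL

  truth <- list(sites = sites, stretches = stretches,
                expression = stats::setNames(expression, gene_id),
                config = cfg)
  class(truth) <- "synthetic_truth"
  list(genome = genome, annotation = ann, truth = truth)
}

build_annotation <- function(gene_id, tx_id, chrom, strand, gstart, gend,
                             u5, cds, u3, seqlen) {
  n <- length(gene_id)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    L <- u5[i] + cds[i] + u3[i]
    # transcript-coordinate blocks
    blocks <- rbind(
      c(1L, L),                        # gene
      c(1L, L),                        # transcript
      c(1L, L),                        # exon
      c(u5[i] + 1L, u5[i] + cds[i]),   # CDS
      c(1L, u5[i]),                    # five_prime_utr
      c(u5[i] + cds[i] + 1L, L)        # three_prime_utr
    )
    types <- c("gene", "transcript", "exon", "CDS",
               "five_prime_utr", "three_prime_utr")
    if (strand[i] == "+") {
      s <- gstart[i] + blocks[, 1] - 1L; e <- gstart[i] + blocks[, 2] - 1L
    } else {
      s <- gend[i] - blocks[, 2] + 1L; e <- gend[i] - blocks[, 1] + 1L
    }
    rows[[i]] <- data.frame(
      chrom = chrom[i], start = s, end = e, strand = strand[i],
      type = types, gene_id = gene_id[i], transcript_id = tx_id[i],
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, rows)
  ann <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand,
    type = df$type,
    gene_id = df$gene_id,
    transcript_id = ifelse(df$type == "gene", NA_character_,
                           df$transcript_id),
    gene_type = "protein_coding",
    level = 1L,
    transcript_support_level = ifelse(df$type == "gene", NA_integer_, 1L)
  )
  GenomeInfoDb::seqlevels(ann) <- names(seqlen)
  GenomeInfoDb::seqlengths(ann) <- seqlen
  ann
}

#' Simulate per-replicate crosslink tracks over a synthetic reference
#'
#' Background counts are drawn per exonic nucleotide from a negative binomial
#' with mean `background_rate * expression[gene]` and size `dispersion`;
#' positions inside planted footprints use the same mean multiplied by the
#' (per-site) enrichment. Counts outside exons are zero. Replicates are drawn
#' independently from seeds derived from `config$seed`.
#'
#' @param annotation Annotation `GRanges` from [generate_reference()].
#' @param truth `synthetic_truth` from the same reference.
#' @param config The same [simulation_config()].
#' @return Named list of crosslink tracks, one per replicate.
#' @export
simulate_crosslink_tracks <- function(annotation, truth, config) {
  exons <- annotation[annotation$type == "exon"]
  exons <- exons[order(match(exons$gene_id, truth$sites$gene_id))]
  seqlen <- GenomeInfoDb::seqlengths(annotation)
  tracks <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    tracks[[r]] <- with_seed(
      derive_seed(config$seed, 100 + r),
      simulate_one_track(exons, truth, config, seqlen)
    )
  }
  names(tracks) <- sprintf("rep%d", seq_len(config$n_replicates))
  tracks
}

simulate_one_track <- function(exons, truth, config, seqlen) {
  pos_all <- integer(0); cnt_all <- integer(0)
  chr_all <- character(0); str_all <- character(0)
  for (i in seq_along(exons)) {
    g <- truth$sites$gene_id[match(exons$gene_id[i], truth$sites$gene_id)]
    expr <- truth$expression[[exons$gene_id[i]]]
    mu <- config$background_rate * expr
    p <- seq(BiocGenerics::start(exons)[i], BiocGenerics::end(exons)[i])
    counts <- stats::rnbinom(length(p), size = config$dispersion, mu = mu)
    srow <- match(exons$gene_id[i], truth$sites$gene_id)
    if (!is.na(srow)) {
      fp <- seq(truth$sites$start[srow], truth$sites$end[srow])
      idx <- match(fp, p)
      idx <- idx[!is.na(idx)]
      counts[idx] <- stats::rnbinom(
        length(idx), size = config$dispersion,
        mu = mu * truth$sites$enrichment[srow]
      )
    }
    keep <- counts > 0
    if (any(keep)) {
      pos_all <- c(pos_all, p[keep])
      cnt_all <- c(cnt_all, counts[keep])
      chr_all <- c(chr_all, rep(as.character(GenomeInfoDb::seqnames(exons)[i]),
                                sum(keep)))
      str_all <- c(str_all, rep(as.character(BiocGenerics::strand(exons)[i]),
                                sum(keep)))
    }
  }
  if (length(pos_all) == 0) {
    gr <- GenomicRanges::GRanges(seqlengths = seqlen)
    gr$count <- integer(0)
    return(gr)
  }
  crosslink_track(chr_all, pos_all, cnt_all, str_all, seqlengths = seqlen)
}

#' Simulate unmapped-style reads with a 9-nt barcode layout
#'
#' Reads carry a 9-nt 5' barcode (random positions 1-3 and 8-9, a fixed
#' experimental barcode at positions 4-7) followed by random insert sequence.
#' A configured fraction of reads ends in an untemplated run of at least 10
#' terminal A's, emulating reads that stem from poly(A) tails and therefore
#' fail genomic mapping.
#'
#' @param truth `synthetic_truth` (used only for the config echo/seed; reads
#'   are not tied to genomic positions).
#' @param config A [simulation_config()].
#' @return A data.frame with columns `id`, `seq`, `qual`, and a logical
#'   `polyA` truth column.
#' @export
simulate_reads <- function(truth, config) {
  with_seed(derive_seed(config$seed, 500), {
    n <- config$n_reads
    ins_len <- config$read_length - 9L
    stopifnot(ins_len >= 15)
    is_pa <- stats::runif(n) < config$polyA_read_fraction
    rand1 <- replicate(n, paste(sample_bases(3), collapse = ""))
    rand2 <- replicate(n, paste(sample_bases(2), collapse = ""))
    inserts <- character(n)
    for (i in seq_len(n)) {
      body <- sample_bases(ins_len)
      if (is_pa[i]) {
        k <- sample(10:min(ins_len - 2L, 25L), 1)
        body[(ins_len - k + 1L):ins_len] <- "A"
        body[ins_len - k] <- sample(c("C", "G", "T"), 1)
      } else if (body[ins_len] == "A") {
        # keep accidental terminal A-runs short in non-poly(A) reads
        body[ins_len] <- sample(c("C", "G", "T"), 1)
      }
      inserts[i] <- paste(body, collapse = "")
    }
    seqs <- paste0(rand1, config$experimental_barcode, rand2, inserts)
    qual <- strrep(rawToChar(as.raw(config$base_quality + 33L)),
                   config$read_length)
    data.frame(
      id = sprintf("read%06d", seq_len(n)),
      seq = seqs,
      qual = qual,
      polyA = is_pa,
      stringsAsFactors = FALSE
    )
  })
}
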