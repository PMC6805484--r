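# File-format I/O. External conventions: bedGraph/BED are 0-based half-open,
# GTF is 1-based closed; internal containers are GRanges (1-based closed).

#' Write a genome to FASTA
#' @param genome Named `DNAStringSet`.
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA file.
#' @return Named `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write an annotation GRanges as GTF
#'
#' Emits gene/transcript/exon/CDS/five_prime_utr/three_prime_utr features
#' with `gene_id`, `transcript_id`, `gene_type`, `level` and
#' `transcript_support_level` attributes.
#'
#' @param annotation Annotation `GRanges` (see [generate_reference()]).
#' @param path Output file.
#' @export
write_annotation_gtf <- function(annotation, path) {
  a <- annotation
  attr_str <- vapply(seq_along(a), function(i) {
    parts <- sprintf('gene_id "%s"', a$gene_id[i])
    if (!is.na(a$transcript_id[i])) {
      parts <- c(parts, sprintf('transcript_id "%s"', a$transcript_id[i]))
    }
    parts <- c(parts, sprintf('gene_type "%s"', a$gene_type[i]),
               sprintf('level %d', a$level[i]))
    if (!is.na(a$transcript_support_level[i])) {
      parts <- c(parts, sprintf('transcript_support_level "%d"',
                                a$transcript_support_level[i]))
    }
    paste0(paste(parts, collapse = "; "), ";")
  }, character(1))
  lines <- sprintf("%s\tarichclip\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   as.character(GenomeInfoDb::seqnames(a)), a$type,
                   BiocGenerics::start(a), BiocGenerics::end(a),
                   as.character(BiocGenerics::strand(a)), attr_str)
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF annotation
#'
#' Loads via [rtracklayer::import()] and normalizes the attribute columns the
#' pipeline requires. Fails if `gene_type` is absent (region assignment and
#' the protein-coding filter need it).
#'
#' @param path GTF file.
#' @return Annotation `GRanges`.
#' @export
read_annotation_gtf <- function(path) {
  ann <- rtracklayer::import(path, format = "gtf")
  if (is.null(ann$gene_type)) {
    stop("annotation lacks the gene_type attribute required for the ",
         "protein-coding gene filter")
  }
  ann$type <- as.character(ann$type)
  if (!is.null(ann$level)) ann$level <- as.integer(as.character(ann$level))
  if (!is.null(ann$transcript_support_level)) {
    ann$transcript_support_level <-
      suppressWarnings(as.integer(as.character(ann$transcript_support_level)))
  }
  ann
}

#' Write a crosslink track as a stranded bedGraph pair
#'
#' Two files per track (plus/minus strand), 0-based half-open, one line per
#' covered nucleotide.
#'
#' @param track Crosslink track `GRanges`.
#' @param plus_path,minus_path Output files.
#' @export
write_track_bedgraph <- function(track, plus_path, minus_path) {
  for (s in c("+", "-")) {
    part <- track[BiocGenerics::strand(track) == s]
    lines <- sprintf("%s\t%d\t%d\t%d",
                     as.character(GenomeInfoDb::seqnames(part)),
                     BiocGenerics::start(part) - 1L,
                     BiocGenerics::end(part),
                     part$count)
    writeLines(lines, if (s == "+") plus_path else minus_path)
  }
  invisible(c(plus_path, minus_path))
}

#' Read a stranded bedGraph pair into a crosslink track
#' @param plus_path,minus_path bedGraph files for the two strands.
#' @param seqlengths Optional named contig lengths.
#' @return Crosslink track `GRanges`.
#' @export
read_track_bedgraph <- function(plus_path, minus_path, seqlengths = NULL) {
  read_one <- function(path, s) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) == 0) return(NULL)
    # expand multi-nt intervals to per-nt positions
    pos <- unlist(mapply(seq, BiocGenerics::start(gr), BiocGenerics::end(gr),
                         SIMPLIFY = FALSE))
    reps <- GenomicRanges::width(gr)
    data.frame(chrom = rep(as.character(GenomeInfoDb::seqnames(gr)), reps),
               pos = pos, count = rep(gr$score, reps), strand = s,
               stringsAsFactors = FALSE)
  }
  df <- rbind(read_one(plus_path, "+"), read_one(minus_path, "-"))
  if (is.null(df) || nrow(df) == 0) {
    gr <- GenomicRanges::GRanges()
    gr$count <- integer(0)
    return(gr)
  }
  crosslink_track(df$chrom, df$pos, df$count, df$strand,
                  seqlengths = seqlengths)
}

#' Write reads to FASTQ
#' @param reads data.frame with `id`, `seq`, `qual` columns.
#' @param path Output file.
#' @export
write_reads_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ file (uncompressed).
#' @return data.frame with `id`, `seq`, `qual`.
#' @export
read_reads_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) stop("malformed FASTQ: line count not 4n")
  idx <- seq(1, length(lines), by = 4)
  data.frame(id = sub("^@", "", lines[idx]),
             seq = lines[idx + 1],
             qual = lines[idx + 3],
             stringsAsFactors = FALSE)
}

#' Write binding sites as BED6+
#'
#' Columns: chrom, start (0-based), end, site id, merged count, strand,
#' then gene id, region, per-replicate window counts and (if present) SOB.
#'
#' @param sites Binding-site `GRanges` from [call_binding_sites()].
#' @param path Output file.
#' @param extra_comment Optional `#`-prefixed provenance line (e.g. the
#'   pipeline config hash).
#' @export
write_sites_bed <- function(sites, path, extra_comment = NULL) {
  mc <- S4Vectors::mcols(sites)
  rep_cols <- grep("^count_rep", colnames(mc), value = TRUE)
  extra <- do.call(cbind, c(
    list(gene = mc$gene_id, region = mc$region),
    lapply(rep_cols, function(cn) mc[[cn]]),
    if ("sob" %in% colnames(mc)) {
      list(ifelse(is.na(mc$sob), "NA", format(mc$sob, trim = TRUE)))
    }
  ))
  header <- paste0("#chrom\tstart\tend\tname\tscore\tstrand\tgene\tregion\t",
                   paste(rep_cols, collapse = "\t"),
                   if ("sob" %in% colnames(mc)) "\tsob" else "")
  body <- paste(
    as.character(GenomeInfoDb::seqnames(sites)),
    BiocGenerics::start(sites) - 1L, BiocGenerics::end(sites),
    mc$site_id, mc$merged_count,
    as.character(BiocGenerics::strand(sites)),
    apply(extra, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  if (!is.null(extra_comment)) header <- c(paste0("# ", extra_comment), header)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write A-rich stretches as BED6+
#' @param stretches Stretch `GRanges` (score column = LCA; extra columns
#'   `a_content`, `weighted_a`, linked `site_ids`).
#' @param path Output file.
#' @param extra_comment Optional `#`-prefixed provenance line.
#' @export
write_stretches_bed <- function(stretches, path, extra_comment = NULL) {
  mc <- S4Vectors::mcols(stretches)
  header <- "#chrom\tstart\tend\tname\tscore\tstrand\ta_content\tweighted_a\tsite_ids"
  if (!is.null(extra_comment)) header <- c(paste0("# ", extra_comment), header)
  body <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%.4f\t%.4f\t%s",
                  as.character(GenomeInfoDb::seqnames(stretches)),
                  BiocGenerics::start(stretches) - 1L,
                  BiocGenerics::end(stretches),
                  sprintf("AS%04d", seq_along(stretches)),
                  mc$lca,
                  as.character(BiocGenerics::strand(stretches)),
                  mc$a_content, mc$weighted_a,
                  vapply(mc$site_ids, paste, character(1), collapse = ","))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the synthetic ground truth as tab-separated tables
#'
#' `sites.tsv`: planted footprints (BED6+ layout, 0-based start, with
#' enrichment and stretch-link columns). `stretches.tsv`: planted A-rich
#' stretches with purity and LCA. `expression.tsv`: per-gene scalars.
#'
#' @param truth `synthetic_truth`.
#' @param dir Output directory (created if needed).
#' @export
write_truth_tables <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- truth$sites
  site_lines <- c(
    "#chrom\tstart\tend\tname\tscore\tstrand\tgene_id\tcenter\tenrichment\thas_stretch",
    sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s\t%d\t%.6g\t%s",
            s$chrom, s$start - 1L, s$end, paste0("truth_", s$gene_id), 0L,
            s$strand, s$gene_id, s$center, s$enrichment,
            ifelse(s$has_stretch, "yes", "no"))
  )
  writeLines(site_lines, file.path(dir, "sites.tsv"))
  st <- truth$stretches
  stretch_lines <- c(
    "#chrom\tstart\tend\tname\tscore\tstrand\tgene_id\tlength\tpurity\tlca",
    if (nrow(st)) sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s\t%d\t%.4f\t%d",
                          st$chrom, st$start - 1L, st$end,
                          paste0("truthAS_", st$gene_id), st$lca, st$strand,
                          st$gene_id, st$length, st$purity, st$lca)
  )
  writeLines(stretch_lines, file.path(dir, "stretches.tsv"))
  expr_lines <- c("#gene_id\texpression",
                  sprintf("%s\t%.8g", names(truth$expression),
                          truth$expression))
  writeLines(expr_lines, file.path(dir, "expression.tsv"))
  invisible(dir)
}

write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an alignment table
#'
#' The 5-column tab-separated equivalent of a deduplication-ready alignment
#' set: read id, contig, strand, 1-based genomic position of the read 5' end,
#' and the 5-nt random barcode recovered from the read header.
#'
#' @param path TSV file with columns id, chrom, strand, five_prime_pos,
#'   barcode (header optional, `#`-prefixed comments ignored).
#' @return data.frame of alignment records.
#' @export
read_alignment_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) != 5) stop("alignment TSV must have 5 columns")
  names(df) <- c("id", "chrom", "strand", "five_prime_pos", "barcode")
  df$five_prime_pos <- as.integer(df$five_prime_pos)
  df
}
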