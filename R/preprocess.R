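#' Barcode scheme for read-quality filtering
#'
#' iCLIP reads start with a 9-nt barcode: a random barcode at positions 1-3
#' and 8-9 (used for PCR-duplicate removal) and an experimental barcode at
#' positions 4-7 (used for demultiplexing, which is out of scope here). The
#' quality filter keeps a read only if at most `max_low_experimental`
#' experimental positions fall below `min_qual_experimental` and no random
#' position falls below `min_qual_random`.
#'
#' @param random_positions 1-based read positions of the random barcode.
#' @param experimental_positions 1-based positions of the sample barcode.
#' @param min_qual_random Phred floor for random-barcode positions.
#' @param min_qual_experimental Phred floor for experimental positions.
#' @param max_low_experimental Allowed number of experimental positions below
#'   the floor.
#' @return An object of class `barcode_scheme`.
#' @export
barcode_scheme <- function(random_positions = c(1:3, 8:9),
                           experimental_positions = 4:7,
                           min_qual_random = 17,
                           min_qual_experimental = 20,
                           max_low_experimental = 1) {
  if (length(intersect(random_positions, experimental_positions))) {
    stop("random and experimental barcode positions must be disjoint")
  }
  structure(list(random_positions = as.integer(random_positions),
                 experimental_positions = as.integer(experimental_positions),
                 min_qual_random = min_qual_random,
                 min_qual_experimental = min_qual_experimental,
                 max_low_experimental = max_low_experimental),
            class = "barcode_scheme")
}

#' Filter reads on barcode sequencing quality
#'
#' @param qual Character vector of Phred quality strings (ASCII offset 33),
#'   or a list of integer quality vectors.
#' @param scheme A [barcode_scheme()].
#' @return Logical vector: `TRUE` = keep. Reads shorter than the barcode
#'   region raise an error rather than being dropped silently.
#' @export
filter_barcode_quality <- function(qual, scheme = barcode_scheme()) {
  q <- if (is.character(qual)) phred_to_int(qual) else qual
  needed <- max(scheme$random_positions, scheme$experimental_positions)
  vapply(q, function(qi) {
    if (length(qi) < needed) {
      stop(sprintf("read quality string shorter (%d) than barcode region (%d)",
                   length(qi), needed))
    }
    n_low_exp <- sum(qi[scheme$experimental_positions] <
                       scheme$min_qual_experimental)
    any_low_rand <- any(qi[scheme$random_positions] < scheme$min_qual_random)
    n_low_exp <= scheme$max_low_experimental && !any_low_rand
  }, logical(1))
}

#' Remove technical duplicates by random barcode
#'
#' Among alignment records sharing contig, strand, 5'-end position and random
#' barcode, exactly one survives (technical duplicates); records sharing a
#' position but differing in barcode are all kept (biological duplicates).
#'
#' @param records data.frame with columns `id`, `chrom`, `strand`,
#'   `five_prime_pos`, `barcode`.
#' @return The deduplicated data.frame.
#' @export
dedup_random_barcode <- function(records) {
  if (nrow(records) == 0) return(records)
  key <- paste(records$chrom, records$strand, records$five_prime_pos,
               records$barcode, sep = "\r")
  records[!duplicated(key), , drop = FALSE]
}

#' Extract crosslink events from deduplicated alignments
#'
#' Each read contributes one event at the nucleotide directly upstream of its
#' 5' end — the position where reverse transcription truncated at the
#' protein-RNA crosslink. Upstream is strand-aware: `five_prime_pos - 1` on
#' the plus strand, `five_prime_pos + 1` on the minus strand. Events falling
#' outside the contig are counted in the `n_skipped` attribute and skipped.
#'
#' @param records Deduplicated alignment data.frame.
#' @param replicate Replicate label stored on the result.
#' @param seqlengths Named integer vector of contig lengths.
#' @return Crosslink track `GRanges` with attributes `replicate` and
#'   `n_skipped`.
#' @export
extract_crosslinks <- function(records, replicate = "rep1",
                               seqlengths = NULL) {
  bad <- !records$strand %in% c("+", "-")
  if (any(bad)) {
    stop("unknown strand symbol(s): ",
         paste(unique(records$strand[bad]), collapse = ", "))
  }
  pos <- ifelse(records$strand == "+",
                records$five_prime_pos - 1L,
                records$five_prime_pos + 1L)
  oob <- pos < 1L
  if (!is.null(seqlengths)) {
    oob <- oob | pos > seqlengths[records$chrom]
  }
  n_skipped <- sum(oob)
  records <- records[!oob, , drop = FALSE]
  pos <- pos[!oob]
  if (nrow(records) == 0) {
    gr <- GenomicRanges::GRanges(seqlengths = seqlengths)
    gr$count <- integer(0)
  } else {
    key <- paste(records$chrom, records$strand, pos, sep = "\r")
    agg <- rowsum(rep(1L, length(key)), key, reorder = FALSE)
    first <- !duplicated(key)
    gr <- crosslink_track(records$chrom[first], pos[first],
                          agg[match(key[first], rownames(agg)), 1],
                          records$strand[first], seqlengths = seqlengths)
  }
  attr(gr, "replicate") <- replicate
  attr(gr, "n_skipped") <- n_skipped
  gr
}
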