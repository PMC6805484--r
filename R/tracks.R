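#' Crosslink tracks
#'
#' A crosslink track stores stranded per-nucleotide crosslink-event counts as
#' a `GRanges` of width-1 positions with an integer `count` metadata column.
#' Positions with zero events are omitted. Replicate sets are plain named
#' lists of tracks (`rep1`, `rep2`, ...).
#'
#' @param chrom Character vector of contig names.
#' @param pos Integer vector of 1-based positions.
#' @param count Integer vector of positive event counts.
#' @param strand Character vector of `"+"`/`"-"`.
#' @param seqlengths Named integer vector of contig lengths (optional but
#'   recommended; enables bounds checks downstream).
#' @return A `GRanges` track.
#' @export
crosslink_track <- function(chrom, pos, count, strand,
                            seqlengths = NULL) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(count),
            length(strand) %in% c(1L, length(pos)))
  if (any(count <= 0)) stop("track counts must be positive integers")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pos, width = 1L),
    strand = strand,
    count = as.integer(count)
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
    if (any(pos < 1L | pos > seqlengths[as.character(chrom)])) {
      stop("track positions outside contig bounds")
    }
  }
  GenomicRanges::sort(gr)
}

#' Sum crosslink tracks position-wise
#'
#' @param tracks List of track `GRanges` (see [crosslink_track()]).
#' @return A single merged track whose `count` at each position is the sum
#'   over replicates.
#' @export
merge_tracks <- function(tracks) {
  all <- suppressWarnings(do.call(c, unname(tracks)))
  if (length(all) == 0) return(all)
  key <- paste(GenomeInfoDb::seqnames(all), BiocGenerics::strand(all),
               BiocGenerics::start(all))
  agg <- rowsum(as.numeric(all$count), key, reorder = FALSE)
  first <- !duplicated(key)
  out <- all[first]
  out$count <- as.integer(agg[match(key[first], rownames(agg)), 1])
  GenomicRanges::sort(out)
}

# Sum of track counts inside each query range (same strand required).
track_sum_in <- function(track, windows) {
  hits <- GenomicRanges::findOverlaps(track, windows, ignore.strand = FALSE)
  out <- numeric(length(windows))
  if (length(hits)) {
    s <- rowsum(as.numeric(track$count[S4Vectors::queryHits(hits)]),
                S4Vectors::subjectHits(hits))
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

# Number of covered (count > 0) positions inside each query range.
track_covered_in <- function(track, windows) {
  GenomicRanges::countOverlaps(windows, track, ignore.strand = FALSE)
}

# Per-position count vector over a single range, in genomic left-to-right
# order. `window` must be a length-1 GRanges; strand-matched.
track_position_counts <- function(track, window) {
  stopifnot(length(window) == 1)
  x <- integer(GenomicRanges::width(window))
  hits <- GenomicRanges::findOverlaps(track, window, ignore.strand = FALSE)
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    idx <- BiocGenerics::start(track)[q] - BiocGenerics::start(window) + 1L
    x[idx] <- track$count[q]
  }
  x
}

total_events <- function(track) sum(as.numeric(track$count))
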