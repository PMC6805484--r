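# Poly(A)-tail diagnostics on unmapped reads and crosslink metaprofiles
# around polyadenylation sites and A-rich stretch starts.

#' Cumulative A-content curve of a read set
#'
#' For each threshold, the fraction of reads whose A-fraction is at least
#' that threshold. The headline statistic — the fraction of reads in which
#' more than half of all nucleotides are A — is reported separately.
#'
#' @param seqs Character vector of read sequences.
#' @param thresholds A-content threshold grid (default 0 to 1 by 0.05).
#' @return List with `n_reads`, `curve` (data.frame threshold/fraction, the
#'   curve is non-increasing), and `frac_over_half`.
#' @export
read_a_content_curve <- function(seqs, thresholds = seq(0, 1, by = 0.05)) {
  if (length(seqs) == 0) stop("empty read set")
  af <- as.numeric(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(seqs), "A")) / nchar(seqs)
  curve <- data.frame(
    threshold = thresholds,
    fraction = vapply(thresholds, function(t) mean(af >= t), numeric(1))
  )
  list(n_reads = length(seqs), curve = curve,
       frac_over_half = mean(af > 0.5))
}

# Length of the terminal A-run of each read (as stored, no reverse
# complement).
terminal_a_run <- function(seqs) {
  nchar(seqs) - nchar(sub("A*$", "", seqs))
}

#' Cumulative terminal-A curve of a read set
#'
#' For each k, the percentage of reads whose 3'-terminal run of continuous
#' A's has length at least k. `k = 0` is always 100.
#'
#' @param seqs Character vector of read sequences.
#' @param max_k Largest k reported (default: the longest observed run).
#' @return data.frame with columns `k` and `pct` (non-increasing).
#' @export
terminal_a_curve <- function(seqs, max_k = NULL) {
  runs <- terminal_a_run(seqs)
  if (is.null(max_k)) max_k <- max(runs, 0L)
  ks <- 0:max_k
  data.frame(k = ks,
             pct = vapply(ks, function(k) 100 * mean(runs >= k), numeric(1)))
}

# Accumulate per-offset crosslink counts over anchored windows.
# anchors: data.frame chrom/strand/pos. Returns list(matrix regions x
# offsets, offsets).
profile_matrix <- function(track, anchors, radius) {
  n <- nrow(anchors)
  offsets <- seq(-radius, radius)
  win <- GenomicRanges::GRanges(
    anchors$chrom,
    IRanges::IRanges(anchors$pos - radius, anchors$pos + radius),
    strand = anchors$strand)
  mat <- matrix(0, n, length(offsets),
                dimnames = list(NULL, offsets))
  hits <- GenomicRanges::findOverlaps(track, win, ignore.strand = FALSE)
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    off <- BiocGenerics::start(track)[q] - anchors$pos[s]
    neg <- anchors$strand[s] == "-"
    off[neg] <- -off[neg]
    col <- off + radius + 1L
    lin <- (col - 1L) * n + s
    agg <- rowsum(as.numeric(track$count[q]), lin)
    mat[as.integer(rownames(agg))] <- agg[, 1]
  }
  list(mat = mat, offsets = offsets)
}

#' Metaprofile of crosslink events around polyadenylation sites
#'
#' Anchors are annotated 3' ends of confidence-filtered protein-coding
#' transcripts whose 3' UTR is at least `min_utr3` nt long. Crosslink events
#' are accumulated strand-aware at offsets `-radius..radius`; regions holding
#' fewer than `min_events` events in the window are dropped. The summed
#' profile is divided by the number of retained regions and smoothed with a
#' running mean of width `smooth`. The enrichment factor compares the
#' smoothed mean over `signal_window` (just upstream of the poly(A) site) to
#' the smoothed mean over `body_window` (3' UTR body).
#'
#' @param track Crosslink track (typically the merged track).
#' @param annotation Annotation `GRanges`.
#' @param radius Window radius in nt (default 1000, i.e. 2001-nt windows).
#' @param min_events Per-region event floor (default 10).
#' @param min_utr3 Minimum 3' UTR length (default 1000 nt).
#' @param smooth Running-mean width (default 50; 0/1 disables).
#' @param signal_window,body_window Offset intervals for the enrichment
#'   factor (defaults -150..-50 and -750..-650).
#' @param max_level,max_tsl,direction See [qualifying_transcripts()].
#' @return List with `profile` (unsmoothed, per-offset), `smoothed`,
#'   `offsets`, `n_regions`, `total_counted`, `enrichment_factor` (`Inf`
#'   when the body window is empty but the signal window is not; `NA` when
#'   both are empty), `anchor = "polyA_site"`.
#' @export
polyA_site_metaprofile <- function(track, annotation, radius = 1000,
                                   min_events = 10, min_utr3 = 1000,
                                   smooth = 50,
                                   signal_window = c(-150, -50),
                                   body_window = c(-750, -650),
                                   max_level = 2, max_tsl = 3,
                                   direction = "le") {
  tx_ids <- qualifying_transcripts(annotation, max_level, max_tsl, direction)
  u3 <- annotation[annotation$type == "three_prime_utr" &
                     annotation$transcript_id %in% tx_ids]
  utr_len <- tapply(GenomicRanges::width(u3), u3$transcript_id, sum)
  long <- names(utr_len)[utr_len >= min_utr3]
  tx <- annotation[annotation$type == "transcript" &
                     annotation$transcript_id %in% long]
  if (length(tx) == 0) {
    stop(sprintf("no transcript with a 3' UTR >= %d nt", min_utr3))
  }
  strand_tx <- as.character(BiocGenerics::strand(tx))
  pos <- ifelse(strand_tx == "+", BiocGenerics::end(tx),
                BiocGenerics::start(tx))
  anchors <- unique(data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(tx)),
    strand = strand_tx, pos = as.integer(pos),
    stringsAsFactors = FALSE))
  pm <- profile_matrix(track, anchors, radius)
  totals <- rowSums(pm$mat)
  keep <- totals >= min_events
  if (!any(keep)) {
    stop(sprintf(
      "no region with >= %d events in the window (%d regions inspected)",
      min_events, nrow(anchors)))
  }
  mat <- pm$mat[keep, , drop = FALSE]
  n_regions <- sum(keep)
  profile <- colSums(mat) / n_regions
  smoothed <- if (smooth > 1) running_mean(profile, smooth) else profile
  ef <- {
    sig <- pm$offsets >= signal_window[1] & pm$offsets <= signal_window[2]
    body <- pm$offsets >= body_window[1] & pm$offsets <= body_window[2]
    if (!any(sig) || !any(body)) NA_real_ else {
      denom <- mean(smoothed[body])
      num <- mean(smoothed[sig])
      if (denom == 0) {
        if (num > 0) Inf else NA_real_   # signal over an empty body
      } else {
        num / denom
      }
    }
  }
  list(profile = profile, smoothed = smoothed, offsets = pm$offsets,
       n_regions = n_regions, total_counted = sum(mat),
       enrichment_factor = ef, anchor = "polyA_site")
}

#' Metaprofile of crosslink events around A-rich stretch starts
#'
#' Strand-aware mean crosslink count per offset across stretch start
#' positions (the stretch's 5'-most base), plus the per-stretch matrix over a
#' narrower window for heatmap display.
#'
#' @param track Crosslink track (typically the merged track).
#' @param stretches Stretch `GRanges`.
#' @param radius Profile radius (default 100, i.e. 201-nt window).
#' @param matrix_radius Heatmap-matrix radius (default 50, 101-nt window).
#' @return List with `profile` (mean events per nt), `offsets`, `n_regions`,
#'   `matrix` (stretches x offsets), `matrix_offsets`,
#'   `anchor = "stretch_start"`.
#' @export
stretch_start_metaprofile <- function(track, stretches, radius = 100,
                                      matrix_radius = 50) {
  if (length(stretches) == 0) {
    stop("no stretches supplied")
  }
  strand_s <- as.character(BiocGenerics::strand(stretches))
  pos <- ifelse(strand_s == "+", BiocGenerics::start(stretches),
                BiocGenerics::end(stretches))
  anchors <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(stretches)),
    strand = strand_s, pos = as.integer(pos), stringsAsFactors = FALSE)
  pm <- profile_matrix(track, anchors, radius)
  pm_small <- profile_matrix(track, anchors, matrix_radius)
  list(profile = colMeans(pm$mat), offsets = pm$offsets,
       n_regions = nrow(anchors),
       matrix = pm_small$mat, matrix_offsets = pm_small$offsets,
       anchor = "stretch_start")
}
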