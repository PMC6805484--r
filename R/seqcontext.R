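# Sequence context of binding sites: positional 4-mer profiles, empirical
# 4-mer enrichment z-scores against resampled 3' UTR backgrounds, the A-rich
# stretch maximization search, stretch merging, and SOB stratified by the
# longest continuous A-run (LCA).

# Strand-aware sequence fetch: for each row of `df` (chrom, strand, start,
# end; 1-based closed, genomic), return the transcript-orientation sequence
# (reverse complement on the minus strand). Out-of-contig rows return NA.
fetch_seqs <- function(genome, chrom, strand, start, end) {
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  n <- length(chrom)
  out <- rep(NA_character_, n)
  ok <- start >= 1L & end <= lens[chrom] & !is.na(lens[chrom])
  if (any(ok)) {
    gs <- as.character(Biostrings::subseq(
      genome[chrom[ok]], start = start[ok], end = end[ok]))
    neg <- strand[ok] == "-"
    if (any(neg)) {
      gs[neg] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(gs[neg])))
    }
    out[ok] <- gs
  }
  out
}

all_kmers <- function(k = 4) {
  b <- c("A", "C", "G", "T")
  apply(expand.grid(rep(list(b), k))[, k:1, drop = FALSE], 1, paste,
        collapse = "")
}

count_kmers <- function(seqs, k = 4) {
  seqs <- seqs[!is.na(seqs) & nchar(seqs) >= k]
  if (length(seqs) == 0) {
    return(stats::setNames(rep(0, 4^k), all_kmers(k)))
  }
  m <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = k)
  colSums(m)
}

#' Positional k-mer frequency profile around site centers
#'
#' For each offset in `-halfwindow..halfwindow`, the fraction of sites whose
#' k-mer starting at that offset (transcript orientation, relative to the
#' site center) equals the query k-mer.
#'
#' @param sites Binding-site `GRanges` with a `center` column.
#' @param genome Named `DNAStringSet`.
#' @param kmers Character vector of query k-mers (equal length).
#' @param halfwindow Half-window in nt (default 50, i.e. a 101-nt window).
#' @return Numeric matrix, rows = offsets (named `-halfwindow..halfwindow`),
#'   columns = k-mers. Attribute `n_skipped` counts sites too close to a
#'   contig edge.
#' @export
kmer_positional_profile <- function(sites, genome,
                                    kmers = c("AAAA", "CCCC", "GGGG", "TTTT"),
                                    halfwindow = 50) {
  k <- unique(nchar(kmers))
  if (length(k) != 1) stop("all query k-mers must have equal length")
  ctr <- sites$center
  chrom <- as.character(GenomeInfoDb::seqnames(sites))
  strand <- as.character(BiocGenerics::strand(sites))
  # fetch enough sequence for k-mers starting at +halfwindow
  start <- ifelse(strand == "+", ctr - halfwindow, ctr - halfwindow - k + 1L)
  end <- ifelse(strand == "+", ctr + halfwindow + k - 1L, ctr + halfwindow)
  seqs <- fetch_seqs(genome, chrom, strand, start, end)
  skipped <- sum(is.na(seqs))
  seqs <- seqs[!is.na(seqs)]
  n <- length(seqs)
  offsets <- seq(-halfwindow, halfwindow)
  out <- matrix(0, length(offsets), length(kmers),
                dimnames = list(offsets, kmers))
  if (n > 0) {
    for (j in seq_along(offsets)) {
      sub <- substring(seqs, j, j + k - 1L)
      for (q in seq_along(kmers)) out[j, q] <- mean(sub == kmers[q])
    }
  }
  attr(out, "n_skipped") <- skipped
  out
}

# Positions (1-based along the genome, transcript-oriented layout) of a
# flank+window+flank layout around a window start. Returns the fetched
# layout sequence split by region class.
layout_classes <- function(seqs, flank, width, k = 4) {
  list(
    upstream = substring(seqs, 1, flank),
    site = substring(seqs, flank + 1L, flank + width),
    downstream = substring(seqs, flank + width + 1L, 2L * flank + width),
    combined = seqs
  )
}

# Fetch the flank+width+flank layout sequence around window centers.
fetch_layout <- function(genome, chrom, strand, center, flank, width) {
  half <- (width - 1L) %/% 2L
  start <- center - half - flank
  end <- center + half + flank
  fetch_seqs(genome, chrom, strand,
             ifelse(strand == "+", start, start),
             end)
}

#' Empirical 4-mer enrichment z-scores
#'
#' Counts every 4-mer inside the 9-nt site windows and within `flank` nt
#' before and after (per region class, plus a pooled "combined" class). The
#' background repeats the identical counting on `bg_windows` 9-nt windows
#' drawn uniformly from annotated 3' UTRs, `bg_repeats` times; the mean and
#' standard deviation over repeats give each 4-mer's z-score. All counts are
#' normalized to "per window" so observed and background are on one scale.
#'
#' @param sites Binding-site `GRanges` with `center`.
#' @param genome Named `DNAStringSet`.
#' @param annotation Annotation `GRanges` (3' UTR features required).
#' @param flank Flank width in nt (default 40).
#' @param width Site-window width (default 9).
#' @param bg_windows Background windows per draw (default 1000).
#' @param bg_repeats Number of background draws (default 100).
#' @param seed RNG seed (reproducible).
#' @param max_level,max_tsl,direction See [qualifying_transcripts()].
#' @return data.frame with columns `kmer`, `class`, `observed` (per-window),
#'   `bg_mean`, `bg_sd`, `z` (NA with `flagged = TRUE` when `bg_sd` is 0).
#' @export
kmer_zscores <- function(sites, genome, annotation, flank = 40, width = 9,
                         bg_windows = 1000, bg_repeats = 100, seed = 1,
                         max_level = 2, max_tsl = 3, direction = "le") {
  tx_ids <- qualifying_transcripts(annotation, max_level, max_tsl, direction)
  u3 <- GenomicRanges::reduce(
    gene_features(annotation, "three_prime_utr", tx_ids),
    ignore.strand = FALSE)
  if (sum(GenomicRanges::width(u3)) < width) {
    stop("3' UTR space smaller than one background window")
  }
  half <- (width - 1L) %/% 2L
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  # background centers must keep the whole layout inside the contig
  pad <- half + flank
  u3chrom <- as.character(GenomeInfoDb::seqnames(u3))
  lo <- pmax(BiocGenerics::start(u3), pad + 1L)
  hi <- pmin(BiocGenerics::end(u3), lens[u3chrom] - pad)
  ok <- hi >= lo
  u3 <- u3[ok]; lo <- lo[ok]; hi <- hi[ok]
  blk_n <- hi - lo + 1L
  if (sum(blk_n) <= 0) stop("no eligible 3' UTR background positions")

  obs_seqs <- fetch_layout(genome,
                           as.character(GenomeInfoDb::seqnames(sites)),
                           as.character(BiocGenerics::strand(sites)),
                           sites$center, flank, width)
  n_obs <- sum(!is.na(obs_seqs))
  obs_cls <- layout_classes(obs_seqs, flank, width)
  observed <- lapply(obs_cls, function(s) count_kmers(s) / n_obs)

  cum <- c(0, cumsum(as.numeric(blk_n)))
  draw_bg <- function() {
    u <- sample.int(sum(blk_n), bg_windows, replace = TRUE)
    blk <- findInterval(u - 0.5, cum)
    ctr <- lo[blk] + (u - cum[blk]) - 1L
    s <- fetch_layout(genome, u3chrom[blk],
                      as.character(BiocGenerics::strand(u3))[blk],
                      as.integer(ctr), flank, width)
    cls <- layout_classes(s, flank, width)
    lapply(cls, function(x) count_kmers(x) / bg_windows)
  }
  draws <- with_seed(derive_seed(seed, 9000), {
    replicate(bg_repeats, draw_bg(), simplify = FALSE)
  })

  classes <- names(observed)
  out <- do.call(rbind, lapply(classes, function(cl) {
    mat <- do.call(rbind, lapply(draws, `[[`, cl))
    bg_mean <- colMeans(mat)
    bg_sd <- apply(mat, 2, stats::sd)
    z <- ifelse(bg_sd > 0, (observed[[cl]] - bg_mean) / bg_sd, NA_real_)
    data.frame(kmer = names(bg_mean), class = cl,
               observed = as.numeric(observed[[cl]]),
               bg_mean = bg_mean, bg_sd = bg_sd, z = z,
               flagged = bg_sd == 0,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}

#' Parameters of the A-rich stretch search
#'
#' @param search_space Search space length downstream of the site center
#'   (default 55 nt, center inclusive).
#' @param min_size,max_size Candidate window sizes (default 8-30 nt).
#' @param min_a_content A-content keep-threshold (fraction, default 0.70).
#' @param min_weighted_a Weighted A-content keep-threshold (default 11;
#'   weighted A-content = A-content x number of A's, A-content on the 0-1
#'   scale).
#' @param min_lca LCA keep-threshold (default 4).
#' @param exclusion `"any_fail"` (default: a candidate is dropped if it fails
#'   any threshold) or `"all_fail"` (dropped only if it fails all three).
#' @return An object of class `stretch_search_params`.
#' @export
stretch_search_params <- function(search_space = 55, min_size = 8,
                                  max_size = 30, min_a_content = 0.70,
                                  min_weighted_a = 11, min_lca = 4,
                                  exclusion = c("any_fail", "all_fail")) {
  exclusion <- match.arg(exclusion)
  if (max_size > search_space) stop("window sizes must fit the search space")
  structure(list(search_space = as.integer(search_space),
                 min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 min_a_content = min_a_content,
                 min_weighted_a = min_weighted_a,
                 min_lca = min_lca,
                 exclusion = exclusion),
            class = "stretch_search_params")
}

#' Find the A-rich stretch downstream of one site (sequence form)
#'
#' Maximization search: for every window size in `min_size..max_size`, the
#' placement within the search-space sequence with maximal A-content is
#' selected (ties resolved toward the site, i.e. the smaller offset). Each
#' per-size candidate is scored by LCA and weighted A-content; candidates
#' failing the keep-thresholds are dropped. Among survivors the stretch is
#' chosen hierarchically: maximal LCA, then maximal weighted A-content, then
#' the smaller window, then the smaller offset.
#'
#' @param seq Search-space sequence (transcript orientation, starting at the
#'   site center); may be shorter than `search_space` near contig ends.
#' @param params [stretch_search_params()].
#' @return List with `offset` (0-based from the site center), `width`,
#'   `a_content`, `lca`, `weighted_a`, `n_a` — or `NULL` when no candidate
#'   survives.
#' @export
find_arich_stretch_seq <- function(seq, params = stretch_search_params()) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < params$min_size) return(NULL)
  a <- as.integer(chars == "A")
  cs <- c(0L, cumsum(a))
  cand <- list()
  for (w in params$min_size:min(params$max_size, n)) {
    n_a <- cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
    best <- which.max(n_a)   # first maximum = smallest offset
    off <- best - 1L
    na_best <- n_a[best]
    ac <- na_best / w
    lca <- longest_a_run(chars[best:(best + w - 1L)])
    wa <- ac * na_best
    cand[[length(cand) + 1L]] <- c(offset = off, width = w, a_content = ac,
                                   lca = lca, weighted_a = wa, n_a = na_best)
  }
  m <- do.call(rbind, cand)
  fail_ac <- m[, "a_content"] < params$min_a_content
  fail_wa <- m[, "weighted_a"] < params$min_weighted_a
  fail_lca <- m[, "lca"] < params$min_lca
  drop <- if (params$exclusion == "any_fail") {
    fail_ac | fail_wa | fail_lca
  } else {
    fail_ac & fail_wa & fail_lca
  }
  m <- m[!drop, , drop = FALSE]
  if (nrow(m) == 0) return(NULL)
  ord <- order(-m[, "lca"], -m[, "weighted_a"], m[, "width"], m[, "offset"])
  as.list(m[ord[1], ])
}

#' Find A-rich stretches downstream of binding sites
#'
#' Applies [find_arich_stretch_seq()] to the strand-aware `search_space`-nt
#' genomic sequence starting at each site center (center inclusive,
#' extending 3'). Intended for 3' UTR sites; the caller chooses the subset.
#'
#' @param sites Binding-site `GRanges` with `center` and `site_id`.
#' @param genome Named `DNAStringSet`.
#' @param params [stretch_search_params()].
#' @return Stretch `GRanges` with columns `site_ids` (CharacterList),
#'   `a_content`, `lca`, `weighted_a`, `offset`. Sites without a surviving
#'   stretch are absent.
#' @export
find_arich_stretches <- function(sites, genome,
                                 params = stretch_search_params()) {
  chrom <- as.character(GenomeInfoDb::seqnames(sites))
  strand <- as.character(BiocGenerics::strand(sites))
  ctr <- sites$center
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  start <- ifelse(strand == "+", ctr,
                  pmax(1L, ctr - params$search_space + 1L))
  end <- ifelse(strand == "+",
                pmin(lens[chrom], ctr + params$search_space - 1L), ctr)
  seqs <- fetch_seqs(genome, chrom, strand, as.integer(start),
                     as.integer(end))
  rows <- list()
  for (i in seq_along(seqs)) {
    if (is.na(seqs[i])) next
    st <- find_arich_stretch_seq(seqs[i], params)
    if (is.null(st)) next
    if (strand[i] == "+") {
      gs <- ctr[i] + st$offset
      ge <- gs + st$width - 1L
    } else {
      ge <- ctr[i] - st$offset
      gs <- ge - st$width + 1L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom[i], start = gs, end = ge, strand = strand[i],
      site_id = sites$site_id[i], a_content = st$a_content, lca = st$lca,
      weighted_a = st$weighted_a, offset = st$offset,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    gr <- GenomicRanges::GRanges()
    gr$site_ids <- IRanges::CharacterList()
    gr$a_content <- numeric(0); gr$lca <- integer(0)
    gr$weighted_a <- numeric(0); gr$offset <- integer(0)
    return(gr)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$site_ids <- IRanges::CharacterList(as.list(df$site_id))
  gr$a_content <- df$a_content
  gr$lca <- as.integer(df$lca)
  gr$weighted_a <- df$weighted_a
  gr$offset <- as.integer(df$offset)
  GenomeInfoDb::seqlevels(gr) <- names(genome)
  GenomeInfoDb::seqlengths(gr) <- lens
  gr
}

#' Merge overlapping A-rich stretches of neighboring sites
#'
#' Among overlapping stretches, the one with maximal LCA survives (ties:
#' maximal weighted A-content, then the 5'-most); all contributing sites are
#' linked to the survivor. Output stretches are non-overlapping.
#'
#' @param stretches Stretch `GRanges` from [find_arich_stretches()].
#' @return Non-overlapping stretch `GRanges`, a subset of the input, with
#'   `site_ids` pooled per cluster.
#' @export
merge_neighboring_stretches <- function(stretches) {
  if (length(stretches) <= 1) return(stretches)
  red <- GenomicRanges::reduce(stretches, ignore.strand = FALSE)
  ov <- GenomicRanges::findOverlaps(stretches, red, ignore.strand = FALSE)
  grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  keep_idx <- integer(0)
  linked <- list()
  for (k in unique(grp)) {
    idx <- which(grp == k)
    strand_k <- as.character(BiocGenerics::strand(stretches[idx[1]]))
    five_key <- if (strand_k == "-") {
      -BiocGenerics::end(stretches)[idx]
    } else {
      BiocGenerics::start(stretches)[idx]
    }
    ord <- order(-stretches$lca[idx], -stretches$weighted_a[idx], five_key)
    win <- idx[ord[1]]
    keep_idx <- c(keep_idx, win)
    linked[[length(linked) + 1L]] <-
      unique(unlist(stretches$site_ids[idx]))
  }
  out <- stretches[keep_idx]
  out$site_ids <- IRanges::CharacterList(linked)
  GenomicRanges::sort(out)
}

#' Stratify binding-site strength by A-run length
#'
#' Groups sites by the LCA of their linked A-rich stretch (sites without a
#' stretch form the `"none"` group) and summarizes SOB per group.
#'
#' @param sites Binding-site `GRanges` with `sob` (from [compute_sob()]).
#' @param stretches Stretch `GRanges` with `site_ids` links.
#' @return data.frame with columns `lca` (character; `"none"` or the run
#'   length), `n`, `mean_sob`, `sd_sob`. Empty bins are omitted; sites with
#'   undefined SOB are excluded from the summaries.
#' @export
stratify_sob_by_lca <- function(sites, stretches) {
  lca_of <- rep(NA_integer_, length(sites))
  if (length(stretches)) {
    links <- data.frame(
      site_id = unlist(stretches$site_ids),
      lca = rep(stretches$lca, lengths(stretches$site_ids)),
      stringsAsFactors = FALSE)
    m <- match(sites$site_id, links$site_id)
    lca_of <- links$lca[m]
  }
  grp <- ifelse(is.na(lca_of), "none", as.character(lca_of))
  ok <- sites$sob_defined & !is.na(sites$sob)
  levels_order <- c("none", sort(unique(lca_of[!is.na(lca_of)])))
  out <- do.call(rbind, lapply(levels_order, function(g) {
    sel <- grp == g & ok
    if (!any(sel)) return(NULL)
    data.frame(lca = g, n = sum(sel), mean_sob = mean(sites$sob[sel]),
               sd_sob = stats::sd(sites$sob[sel]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(lca = character(0), n = integer(0),
                      mean_sob = numeric(0), sd_sob = numeric(0))
  }
  out
}
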