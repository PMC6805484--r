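# Signal-over-background (SOB): an abundance-corrected binding-strength
# statistic. Per replicate, a site's SOB is its 9-nt window count divided by
# the gene's background crosslink density (events outside site windows +/- 5
# nt, over the merged exon length after 3' UTR truncation); replicate values
# are averaged.

# Genomic region contributing to a gene's effective exon length: the union
# of qualifying-transcript exons, with the 3' UTR truncated 10 nt past the
# 3'-most binding site in the UTR, or at `utr3_fallback` nt when the UTR
# holds no site. Truncation is strand-aware and measured along the UTR.
effective_exon_region <- function(gene_id, annotation, sites,
                                  utr3_fallback = 500, past_site = 10,
                                  max_level = 2, max_tsl = 3,
                                  direction = "le") {
  tx_ids <- qualifying_transcripts(annotation, max_level, max_tsl, direction)
  ex <- gene_features(annotation, "exon", tx_ids, gene_id)
  if (length(ex) == 0) stop("gene without exons: ", gene_id)
  exons_u <- GenomicRanges::reduce(ex)
  u3 <- gene_features(annotation, "three_prime_utr", tx_ids, gene_id)
  if (length(u3) == 0) return(exons_u)
  u3u <- GenomicRanges::reduce(u3)
  strand_g <- as.character(BiocGenerics::strand(exons_u))[1]
  # UTR blocks in transcript (5'->3') order
  ord <- order(BiocGenerics::start(u3u),
               decreasing = (strand_g == "-"))
  u3u <- u3u[ord]
  utr_len <- sum(GenomicRanges::width(u3u))

  gsites <- sites[!is.na(sites$gene_id) & sites$gene_id == gene_id]
  in_utr <- gsites[GenomicRanges::countOverlaps(gsites, u3u,
                                                ignore.strand = FALSE) > 0]
  if (length(in_utr) == 0) {
    cut <- min(utr_len, utr3_fallback)
  } else {
    # UTR coordinate of the 3'-most covered base of the 3'-most site
    edge <- if (strand_g == "+") max(BiocGenerics::end(in_utr)) else
      min(BiocGenerics::start(in_utr))
    offs <- 0L
    cut <- utr_len
    for (i in seq_along(u3u)) {
      s <- BiocGenerics::start(u3u)[i]; e <- BiocGenerics::end(u3u)[i]
      wi <- e - s + 1L
      inside <- edge >= s && edge <= e
      if (inside) {
        d <- if (strand_g == "+") edge - s + 1L else e - edge + 1L
        cut <- offs + d + past_site
        break
      }
      offs <- offs + wi
    }
    cut <- min(utr_len, cut)
  }
  if (cut >= utr_len) return(exons_u)
  # genomic span of the UTR part beyond the cut, walking blocks 5'->3'
  drop <- GenomicRanges::GRanges()
  offs <- 0L
  for (i in seq_along(u3u)) {
    s <- BiocGenerics::start(u3u)[i]; e <- BiocGenerics::end(u3u)[i]
    wi <- e - s + 1L
    if (offs + wi <= cut) { offs <- offs + wi; next }
    keep_in_block <- max(0L, cut - offs)
    if (strand_g == "+") {
      ds <- s + keep_in_block; de <- e
    } else {
      ds <- s; de <- e - keep_in_block
    }
    drop <- c(drop, GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(u3u)[i], IRanges::IRanges(ds, de),
      strand = strand_g))
    offs <- offs + wi
  }
  GenomicRanges::setdiff(exons_u, drop, ignore.strand = FALSE)
}

#' Effective exon length of a gene for SOB background
#'
#' Merged (union) exon length in nt, with the 3' UTR contribution truncated
#' at 10 nt past the 3'-most binding site in the UTR, or at 500 nt of UTR if
#' the UTR holds no site (never extending beyond the annotated UTR).
#'
#' @param gene_id Gene identifier.
#' @param annotation Annotation `GRanges`.
#' @param sites Binding-site `GRanges` (with `gene_id` column).
#' @param utr3_fallback UTR length used when the UTR holds no site.
#' @param past_site Extension past the last site (nt).
#' @param max_level,max_tsl,direction See [qualifying_transcripts()].
#' @return Length in nt.
#' @export
effective_exon_length <- function(gene_id, annotation, sites,
                                  utr3_fallback = 500, past_site = 10,
                                  max_level = 2, max_tsl = 3,
                                  direction = "le") {
  sum(GenomicRanges::width(effective_exon_region(
    gene_id, annotation, sites, utr3_fallback, past_site,
    max_level, max_tsl, direction)))
}

#' Per-gene, per-replicate background density
#'
#' Sums crosslink events at exonic positions (within the effective region)
#' not covered by any binding-site window expanded by `buffer` nt on each
#' side, and divides by the effective exon length.
#'
#' @param gene_id Gene identifier.
#' @param track One replicate's crosslink track.
#' @param sites Binding-site `GRanges`.
#' @param annotation Annotation `GRanges`.
#' @param buffer Exclusion buffer around site windows (default 5 nt).
#' @param ... Passed to [effective_exon_length()].
#' @return List with `background_count`, `effective_length`, `density`.
#' @export
gene_background <- function(gene_id, track, sites, annotation, buffer = 5,
                            ...) {
  region <- effective_exon_region(gene_id, annotation, sites, ...)
  eff_len <- sum(GenomicRanges::width(region))
  if (eff_len == 0) stop("effective length 0 for gene ", gene_id)
  gsites <- sites[!is.na(sites$gene_id) & sites$gene_id == gene_id]
  excl <- GenomicRanges::GRanges()
  if (length(gsites)) {
    excl <- GenomicRanges::reduce(gsites + buffer)
  }
  bg_region <- GenomicRanges::setdiff(region, excl, ignore.strand = FALSE)
  bg <- sum(track_sum_in(track, bg_region))
  list(background_count = bg, effective_length = eff_len,
       density = bg / eff_len)
}

#' SOB value of one site
#'
#' Per replicate, the ratio of the site's window count to the gene's
#' background density for that replicate. Replicates whose gene background
#' holds fewer than `min_background` events (or whose density is zero) are
#' undefined; the mean is taken over defined replicates. Under
#' `rule = "per_replicate"` (default) the site-level SOB is undefined only
#' when no replicate qualifies; `rule = "all"` requires every replicate to
#' qualify.
#'
#' @param window_counts Numeric vector: the site's window count per replicate.
#' @param backgrounds List of per-replicate [gene_background()] results.
#' @param min_background Background-event floor (default 10).
#' @param rule `"per_replicate"` or `"all"`.
#' @return List with `ratios` (NA where undefined), `mean_sob`, `defined`,
#'   `reason`.
#' @export
site_sob <- function(window_counts, backgrounds, min_background = 10,
                     rule = c("per_replicate", "all")) {
  rule <- match.arg(rule)
  bg_counts <- vapply(backgrounds, `[[`, numeric(1), "background_count")
  dens <- vapply(backgrounds, `[[`, numeric(1), "density")
  ok <- bg_counts >= min_background & dens > 0
  ratios <- ifelse(ok, window_counts / dens, NA_real_)
  defined <- if (rule == "per_replicate") any(ok) else all(ok)
  reason <- if (defined) NA_character_
  else if (any(dens == 0 & window_counts > 0)) "zero_density"
  else "low_background"
  list(ratios = ratios,
       mean_sob = if (defined) mean(ratios[ok]) else NA_real_,
       defined = defined, reason = reason)
}

#' Compute SOB for all binding sites
#'
#' @param sites Binding-site `GRanges` from [call_binding_sites()].
#' @param tracks Named list of per-replicate tracks.
#' @param annotation Annotation `GRanges`.
#' @param min_background Background-event floor (default 10).
#' @param rule See [site_sob()].
#' @param buffer Site-window exclusion buffer (default 5 nt).
#' @param utr3_fallback,past_site See [effective_exon_length()].
#' @return `sites` with added columns `sob` (mean over defined replicates,
#'   NA when undefined), `sob_defined`, `sob_reason`, and per-replicate
#'   `sob_rep*` columns.
#' @export
compute_sob <- function(sites, tracks, annotation, min_background = 10,
                        rule = "per_replicate", buffer = 5,
                        utr3_fallback = 500, past_site = 10) {
  n <- length(sites)
  reps <- names(tracks)
  ratio_mat <- matrix(NA_real_, n, length(reps),
                      dimnames = list(NULL, reps))
  mean_sob <- rep(NA_real_, n)
  defined <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  rep_counts <- as.matrix(S4Vectors::mcols(sites)[
    , paste0("count_", reps), drop = FALSE])
  for (g in unique(sites$gene_id)) {
    idx <- which(sites$gene_id == g)
    # the effective region depends on sites and annotation only: compute it
    # once per gene and reuse it across replicates
    region <- effective_exon_region(g, annotation, sites,
                                    utr3_fallback = utr3_fallback,
                                    past_site = past_site)
    eff_len <- sum(GenomicRanges::width(region))
    gsites <- sites[idx]
    bg_region <- GenomicRanges::setdiff(
      region, GenomicRanges::reduce(gsites + buffer), ignore.strand = FALSE)
    bgs <- lapply(tracks, function(tr) {
      bg <- sum(track_sum_in(tr, bg_region))
      list(background_count = bg, effective_length = eff_len,
           density = bg / eff_len)
    })
    for (i in idx) {
      sv <- site_sob(rep_counts[i, ], bgs, min_background = min_background,
                     rule = rule)
      ratio_mat[i, ] <- sv$ratios
      mean_sob[i] <- sv$mean_sob
      defined[i] <- sv$defined
      reason[i] <- sv$reason
    }
  }
  sites$sob <- mean_sob
  sites$sob_defined <- defined
  sites$sob_reason <- reason
  for (j in seq_along(reps)) {
    S4Vectors::mcols(sites)[[paste0("sob_", reps[j])]] <- ratio_mat[, j]
  }
  sites
}
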