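---
title: "Methods: binding-site definition, SOB, and A-rich sequence context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding-site definition, SOB, and A-rich sequence context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`arichclip` analyzes iCLIP data for an RNA-binding protein that contacts
mRNAs immediately upstream of adenosine-rich elements — A-rich stretches in
3' UTRs and, ultimately, poly(A) tails. In iCLIP, reverse transcription
truncates at the crosslinked amino-acid–RNA adduct, so the nucleotide
directly upstream of a read's 5' mapping position is taken as the
protein–RNA contact site ("crosslink event"). All statistics in this
package are built on per-nucleotide, strand-specific counts of such events,
one track per replicate.

The pipeline has five analytical layers:

1. **Read-level filters** (`filter_barcode_quality`, `dedup_random_barcode`,
   `extract_crosslinks`): the 9-nt read barcode holds a random barcode
   (positions 1–3, 8–9) and a sample barcode (4–7). A read is kept when at
   most one sample-barcode position has Phred < 20 and no random-barcode
   position has Phred < 17. After mapping (external), reads sharing contig,
   strand, 5'-end position *and* random barcode are PCR duplicates — one
   survives; equal positions with different barcodes are biological
   duplicates and all survive. Each surviving read contributes one crosslink
   event at `five_prime_pos - 1` (plus strand) or `five_prime_pos + 1`
   (minus strand).
2. **Binding-site definition** (`call_binding_sites`): local
   negative-binomial peak detection on the merged track, then a refinement
   cascade — resize to uniform 9-nt windows around count-weighted centers,
   drop windows with events on fewer than 3 nucleotides, iteratively merge
   overlapping windows at the cumulative half-maximum position, keep windows
   inside exactly one protein-coding gene with a single region label
   (3' UTR > 5' UTR > CDS > intron precedence), drop intronic sites, and
   keep sites with ≥ 3 events in *every* replicate.
3. **Binding strength** (`compute_sob`): per replicate, SOB = (site window
   count) / (gene background density), where the background density is the
   gene's crosslink count outside site windows ± 5 nt divided by the merged
   exon length after 3' UTR truncation (10 nt past the 3'-most UTR site, or
   500 nt of UTR when none). Replicate values are averaged; genes with < 10
   background events give an *undefined* (not zero) SOB.
4. **Sequence context** (`find_arich_stretches`, `kmer_zscores`,
   `kmer_positional_profile`, `stratify_sob_by_lca`): the A-rich stretch
   search maximizes A-content per window size (8–30 nt) in a 55-nt space
   beginning at the site center; candidates failing A-content ≥ 0.70,
   weighted A-content ≥ 11, or longest-continuous-A (LCA) ≥ 4 are dropped;
   survivors are ranked by LCA, then weighted A-content. 4-mer enrichment is
   scored as empirical z-scores against 100 independent draws of 1000
   random 9-nt 3' UTR windows with the same 40-nt flank layout.
5. **Poly(A) diagnostics and metaprofiles** (`terminal_a_curve`,
   `read_a_content_curve`, `polyA_site_metaprofile`,
   `stretch_start_metaprofile`): cumulative curves of read A-content and
   3'-terminal A-run length on unmapped reads; strand-aware crosslink
   metaprofiles in 2001-nt windows around annotated polyadenylation sites
   (3' UTR ≥ 1 kb, ≥ 10 events per window, region-normalized, 50-nt running
   mean) with an enrichment factor mean(−150..−50) / mean(−750..−650), and
   201-nt profiles around A-rich stretch starts.

# Peak detection and the per-window significance test

For each covered position the caller fits a negative binomial by method of
moments (`r = m²/(v − m)`, `p = m/v`) to all counts in the surrounding
500 nt of the same gene's exonic territory and flags positions with
`P(X ≥ c) < alpha` (default 0.01); maximal runs of flagged positions are the
raw peaks. When the sample variance does not exceed the mean the NB is
undefined and a Poisson tail is used for that window (counted and reported).

A per-*position* threshold alone is too liberal: in a well-expressed gene,
roughly 1% of its thousands of exonic positions clear `alpha` by chance, and
in genes with high background those windows also pass the coverage and
reproducibility filters. We therefore test each candidate *window* after
merging: the window sum is compared against the sum distribution NB(9·r, p)
fitted to the window's 500-nt exonic context *excluding the window's own
positions* (as in any local-background peak test), at
`alpha / (gene exonic length / 9)` (a per-gene Bonferroni bound). On
synthetic data this reduces false calls from ~25% to < 1% of calls while
leaving every site that can pass the reproducibility filter intact: a site
with ≥ 9 events concentrated in 9 nt is always far beyond this threshold
when the local background is low, and scales with it when it is high. This
peak-level test is also closer in spirit to the original peak caller, which
assigned p-values to peaks, not positions.

Deterministic conventions, since ± 1-nt drift matters at 9-nt scale:

* Weighted centers round exact halves toward the transcript 5' end (genomic
  left on plus, right on minus).
* The cumulative half-maximum during merging accumulates genomic
  left-to-right by default; `merge_direction = "transcript"` switches to
  5'→3'. The new center is the first position where the cumulative sum
  reaches half the span total.
* Internal coordinates are 1-based closed (`GRanges` convention — the
  idiomatic choice for an R implementation); bedGraph/BED I/O converts to
  0-based half-open, GTF stays 1-based closed.
* Windows whose 9-nt span would cross a contig edge are dropped and counted,
  never clipped.

# Annotation-confidence filter

The annotation filter keeps transcripts with annotation level ≤ 2 and
transcript support level ≤ 3 — the high-confidence reading; the comparison
direction is configurable (`direction = "ge"`) because the opposite reading
also circulates. Genes enter the analysis when they are protein-coding and
have at least one qualifying transcript; region labels are evaluated over
the union of qualifying transcripts.

# The A-rich stretch search: resolved ambiguities

* **Exclusion logic.** The three keep-thresholds are applied conjunctively:
  a candidate survives only with A-content ≥ 0.70 *and* weighted A-content
  ≥ 11 *and* LCA ≥ 4 (`exclusion = "any_fail"`, the default). The
  alternative reading — excluded only when *all three* fail — is available
  as `exclusion = "all_fail"`. Note the default implies a minimum stretch
  length of 11 nt, which is in tension with descriptions of 8-nt stretches;
  both behaviors are selectable rather than silently guessed.
* **Weighted A-content scale.** A-content enters as a fraction (0–1), so
  weighted A-content ≈ the A count discounted by purity; the threshold 11
  only makes dimensional sense on that scale.
* **Search space.** The 55-nt space begins at the site center (inclusive)
  and extends 3' strand-aware, matching the observed 5–50-nt downstream
  enrichment of A-homopolymers.
* **Ties.** Within one window size, equal A-content prefers the placement
  closer to the site (smaller offset; implemented as first maximum). Across
  sizes, after LCA and weighted A-content, the smaller window and then the
  smaller offset win — the final-step tie-break is not specified anywhere,
  so it is fixed and documented here.
* **Merging.** Overlapping stretches of neighboring sites keep the one with
  maximal LCA (then maximal weighted A-content, then 5'-most); all
  contributing sites stay linked to the survivor.

# SOB: resolved ambiguities

* The ratio is (events per 9-nt window) / (events per nt of background) and
  is reported without dividing by the window length; only ratios are ever
  compared.
* The "< 10 background events" rule is applied per replicate; the mean is
  taken over qualifying replicates and a site is undefined only when no
  replicate qualifies. `rule = "all"` gives the stricter reading. Undefined
  is a flagged state, never coerced to 0.
* The background denominator is the full effective (truncated) exon length,
  not length minus site windows, following the letter of the definition.

# The synthetic world

The generator is a first-class module: every downstream stage is tested
against planted ground truth. Its defaults are the stated conditions of the
analysis it emulates, chosen once:

* **200 genes** on 2 chromosomes, alternating strand, single-exon
  (gene length 1500–3000 nt, 5' UTR 150 nt, 3' UTR 300–800 nt) — exercises
  strand-aware coordinate logic; splice isoforms are out of scope.
* **Background**: negative binomial per exonic nt, mean
  `0.05 × expression` per replicate, size 2 — NB rather than Poisson so the
  caller's model family is exercised.
* **Expression**: log-normal(0, 1) per gene, forcing SOB to do real
  abundance correction. This choice caps site recovery: with 3 replicates
  and the ≥ 3-events-per-replicate filter, the expected fraction of planted
  sites that can pass at this depth is 93.1% (exact integral over the
  log-normal), so the ≥ 90% recovery acceptance bound is met with ~3 points
  of head-room and per-run binomial noise of ~2 points; the acceptance test
  pools ten simulations for that reason.
* **Footprints**: one 9-nt footprint per gene in the 3' UTR, rate multiplied
  by 50 (or a per-site log-uniform range when a range is configured),
  uniform across the footprint — the simplest shape satisfying the
  3-covered-nt sparse filter.
* **A-rich stretches**: planted in half the genes by default, length 15–25
  nt at purity 0.95, starting exactly 10 nt 3' of the footprint center.
  Lengths below ~14 nt at this purity could not pass the default weighted-A
  threshold, so the planted range stays above it; purity keeps planted LCA
  well above 4. Non-stretch 3' UTR sequence has A-frequency 0.2 so planted
  stretches are the only A-rich signal.
* **Reads**: 50 nt with the 9-nt barcode layout; 6% end in ≥ 10 untemplated
  terminal A's (run length uniform in 10–25); non-poly(A) reads are kept
  from ending in A so the planted fraction is exactly binomial.

What the generator does *not* emulate: PCR duplication structure beyond
what dedup tests need, splice isoform diversity, sequencing errors,
crosslinking sequence bias (e.g. the uridine preference of 4SU), and
chromatin-scale covariates. A green recovery test therefore establishes the
*algorithmic* contract (the cascade finds what its model says it should find
at this depth), not performance on real libraries.

# Numerical choices

* NB tails use `pnbinom(c − 1, …, lower.tail = FALSE)`; agreement with
  brute-force mass summation is tested to 1e-10.
* The running-mean smoother truncates its window at the profile edges
  rather than padding; consequently the profile mean is preserved exactly
  only away from the edges (tested with edge-free fixtures, documented
  here).
* Empirical k-mer z-scores normalize observed and background counts to
  "per window" so the two are on one scale regardless of the number of
  sites; k-mers with zero background s.d. are flagged and get no z.
  K-mers spanning a class boundary (site edge) count only in the pooled
  "combined" class.
* All randomness flows through explicit seeds; child streams (replicates,
  background draws, reads) use fixed derived seeds below 2^31, so identical
  seed + config is byte-identical output.

# Monotonicity reading

The site-count monotonicity property is tested as: *stricter* filters never
increase the number of final sites (raising `min_events`, lowering
`alpha`). The inverse phrasing ("raising alpha") that sometimes appears
describes the same property from the permissive side.

# Known limitations

* The peak caller is a documented minimal re-implementation, not a wrapper
  of the original tool; its expression-coupled mode is out of scope.
* Real-data headline counts (thousands of sites, replicate correlations)
  depend on deposited raw data and external mappers and are not reproduced
  here; all quantitative guarantees are on synthetic truth or closed-form
  oracles.
* Demultiplexing, adapter trimming, and mapping are external; the package
  starts at quality-filtered reads / aligned records.
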